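# Session-level engagement quantification.
#
# EPM (engagement percentage, model): engaged frames / total frames * 100,
# computed per task from the per-frame classifier output.
# EPT (engagement percentage, therapist): assessment points / maximum
# points * 100, computed per task from the 8-item, 0-3 scale sheet
# (24 points maximum per task).
# Per-child overalls are unweighted means of the per-task percentages,
# rounded half-up to integers.

#' Compute the per-task engagement percentage from frame labels (EPM)
#'
#' `EPM = 100 * engaged frames / total frames`. Frames without a detected
#' face are resolved by the no-face policy: `"count_not_engaged"`
#' (default) keeps them in the denominator as not engaged;
#' `"exclude"` removes them from numerator and denominator.
#'
#' @param labels output of [classifyFrames()] (a data.frame with `engaged`
#'   and `face_present` columns), or a logical vector of per-frame
#'   engagement with `NA` for no-face frames.
#' @param noFacePolicy `"count_not_engaged"` or `"exclude"`.
#' @param taskId identifier recorded in the result.
#' @return a one-row data.frame: `task_id`, `n_frames_total`,
#'   `n_frames_engaged`, `n_frames_no_face`, `epm_percent`, `policy`.
#' @examples
#' computeTaskEPM(c(rep(TRUE, 121), rep(FALSE, 65)), taskId = "task01")
#' @export
computeTaskEPM <- function(labels,
                           noFacePolicy = c("count_not_engaged", "exclude"),
                           taskId = "task") {
  noFacePolicy <- match.arg(noFacePolicy)
  if (is.data.frame(labels)) {
    stopIfNot(all(c("engaged", "face_present") %in% names(labels)),
              "labels data.frame needs 'engaged' and 'face_present' columns")
    engaged <- labels$engaged
    noFace <- !labels$face_present
  } else {
    stopIfNot(is.logical(labels), "labels must be a logical vector (NA = no face)")
    engaged <- labels
    noFace <- is.na(labels)
  }
  stopIfNot(length(engaged) >= 1, "at least one frame record is required")
  nNoFace <- sum(noFace)
  if (noFacePolicy == "exclude") {
    engaged <- engaged[!noFace]
    if (length(engaged) == 0) {
      stop("EPM undefined: no frames left after excluding no-face frames",
           call. = FALSE)
    }
  }
  nTotal <- length(engaged)
  nEngaged <- sum(engaged %in% TRUE)
  data.frame(task_id = taskId,
             n_frames_total = nTotal,
             n_frames_engaged = nEngaged,
             n_frames_no_face = nNoFace,
             epm_percent = 100 * nEngaged / nTotal,
             policy = noFacePolicy)
}

#' Aggregate per-task percentages to a per-child integer percentage
#'
#' The unweighted arithmetic mean of the per-task percentages, rounded
#' half-up to an integer. The same rule serves model percentages (EPM)
#' and therapist percentages (EPT).
#'
#' @param taskPercents numeric vector of per-task percentages in `[0, 100]`.
#' @return an integer percentage.
#' @examples
#' aggregateChildEPM(c(65, 88, 98))  # 84
#' aggregateChildEPM(c(7, 22, 16))   # 15
#' @export
aggregateChildEPM <- function(taskPercents) {
  stopIfNot(is.numeric(taskPercents) && length(taskPercents) >= 1,
            "at least one task percentage is required")
  stopIfNot(all(is.finite(taskPercents)) &&
              all(taskPercents >= 0 & taskPercents <= 100),
            "task percentages must be in [0, 100]")
  as.integer(roundHalfUp(mean(taskPercents)))
}

#' @rdname aggregateChildEPM
#' @export
aggregateChildEPT <- function(taskPercents) {
  aggregateChildEPM(taskPercents)
}

#' Compute the per-task engagement percentage from a therapist sheet (EPT)
#'
#' `EPT = 100 * sum of points / maximum possible points`, with 8 items on
#' the 0-3 agreement scale, hence a 24-point maximum per task.
#'
#' @param items integer vector of 8 item scores in `{0, 1, 2, 3}`, or a
#'   one-row sheet data.frame with columns `item_1` ... `item_8` (as from
#'   [simulateAssessment()]).
#' @return the task EPT percentage in `[0, 100]`.
#' @examples
#' computeEPT(rep(3, 8))         # 100
#' computeEPT(c(3, 3, 2, 2, 2, 2, 2, 2))  # 75
#' @export
computeEPT <- function(items) {
  if (is.data.frame(items)) {
    cols <- paste0("item_", 1:8)
    stopIfNot(all(cols %in% names(items)) && nrow(items) == 1,
              "sheet must be one row with columns item_1 ... item_8")
    items <- as.numeric(items[1, cols])
  }
  stopIfNot(is.numeric(items) && length(items) == 8,
            "exactly 8 item scores are required")
  if (any(!is.finite(items)) || any(items != round(items)) ||
      any(items < 0 | items > 3)) {
    stop("item scores must be integers in {0, 1, 2, 3}", call. = FALSE)
  }
  100 * sum(items) / 24
}

#' Analyze a session frame directory into per-task and overall EPM
#'
#' Groups frames by the task prefix of their filenames (everything before
#' the first underscore, the layout written by [simulateSession()]),
#' classifies every frame, computes per-task EPM and aggregates to the
#' child's overall integer EPM. A failed frame never aborts the session:
#' it is flagged no-face and counted by the policy.
#'
#' @param framesDir directory of frame images.
#' @param model a trained [EngagementClassifier-class].
#' @param noFacePolicy no-face policy, see [computeTaskEPM()].
#' @param childId identifier for the report.
#' @param nativeFps native frame rate of the recording.
#' @return a list: `child_id`, `task_metrics` (data.frame of per-task
#'   [computeTaskEPM()] rows), `overall_epm_percent`, `policy`, `n_frames`.
#' @export
analyzeSession <- function(framesDir, model,
                           noFacePolicy = c("count_not_engaged", "exclude"),
                           childId = "child", nativeFps = 10) {
  noFacePolicy <- match.arg(noFacePolicy)
  frames <- extractFrames(framesDir, nativeFps = nativeFps)
  taskOf <- vapply(frames, function(f) {
    sub("_.*$", "", basename(f$path))
  }, character(1))
  tasks <- unique(taskOf)
  metrics <- do.call(rbind, lapply(tasks, function(tk) {
    labs <- classifyFrames(model, frames[taskOf == tk])
    computeTaskEPM(labs, noFacePolicy = noFacePolicy, taskId = tk)
  }))
  list(child_id = childId,
       task_metrics = metrics,
       overall_epm_percent = aggregateChildEPM(metrics$epm_percent),
       policy = noFacePolicy,
       n_frames = sum(metrics$n_frames_total))
}
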