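#' @title Synthetic therapy-session configuration
#'
#' @description S4 container for the parameters of the synthetic session
#' generator: task structure, frame rate, engagement dynamics, landmark
#' noise, face-dropout probability, image geometry and seed. Defaults
#' emulate a three-task session of a face-visible ~10 fps robot-camera
#' recording with task durations in the 2-20 s range.
#'
#' @slot nTasks number of tasks in the session.
#' @slot taskDurationsS per-task durations in seconds.
#' @slot fps frames per second, recycled over tasks.
#' @slot engageStayProb probability of staying engaged frame-to-frame.
#' @slot disengageStayProb probability of staying disengaged.
#' @slot landmarkNoisePx landmark noise standard deviation in pixels.
#' @slot noFaceProb per-frame probability of a faceless frame.
#' @slot imageSize frame size as (height, width) pixels.
#' @slot seed integer RNG seed.
#' @export
setClass("SessionConfig",
  representation(
    nTasks = "integer",
    taskDurationsS = "numeric",
    fps = "numeric",
    engageStayProb = "numeric",
    disengageStayProb = "numeric",
    landmarkNoisePx = "numeric",
    noFaceProb = "numeric",
    imageSize = "integer",
    seed = "integer"
  ),
  validity = function(object) {
    msgs <- character()
    if (object@nTasks < 1L) msgs <- c(msgs, "nTasks must be >= 1")
    if (length(object@taskDurationsS) != object@nTasks)
      msgs <- c(msgs, "taskDurationsS must have one entry per task")
    if (any(!is.finite(object@taskDurationsS)) ||
        any(object@taskDurationsS <= 0))
      msgs <- c(msgs, "task durations must be positive")
    if (any(!is.finite(object@fps)) || any(object@fps <= 0))
      msgs <- c(msgs, "fps must be positive")
    for (p in c("engageStayProb", "disengageStayProb")) {
      if (!isProb(slot(object, p))) msgs <- c(msgs, paste(p, "must be in [0, 1]"))
    }
    if (!is.finite(object@landmarkNoisePx) || object@landmarkNoisePx < 0)
      msgs <- c(msgs, "landmarkNoisePx must be non-negative")
    if (!isProb(object@noFaceProb) || object@noFaceProb >= 1)
      msgs <- c(msgs, "noFaceProb must be in [0, 1)")
    if (length(object@imageSize) != 2L || any(object@imageSize < 48L))
      msgs <- c(msgs, "imageSize must be (height, width), each >= 48 so the face template fits")
    if (length(msgs)) msgs else TRUE
  }
)

#' Create a synthetic-session configuration
#'
#' @param taskDurationsS per-task durations in seconds (one task per entry).
#' @param fps frames per second; scalar or one value per task.
#' @param engageStayProb,disengageStayProb frame-to-frame stay probabilities
#'   of the two-state (engaged/disengaged) Markov chain.
#' @param landmarkNoisePx landmark noise standard deviation in pixels;
#'   perturbs the rendered face geometry and adds annotation jitter to the
#'   recorded ground-truth landmarks.
#' @param noFaceProb per-frame probability of emitting a faceless
#'   background frame (face lost from view).
#' @param imageSize frame (height, width) in pixels.
#' @param seed integer seed controlling the whole session.
#' @return a [SessionConfig-class] object.
#' @examples
#' cfg <- sessionConfig(taskDurationsS = c(19, 8, 19), fps = 10, seed = 7)
#' @export
sessionConfig <- function(taskDurationsS = c(19, 8, 19),
                          fps = 10,
                          engageStayProb = 0.9,
                          disengageStayProb = 0.9,
                          landmarkNoisePx = 0,
                          noFaceProb = 0.05,
                          imageSize = c(96L, 96L),
                          seed = 1L) {
  new("SessionConfig",
      nTasks = length(taskDurationsS),
      taskDurationsS = as.numeric(taskDurationsS),
      fps = as.numeric(fps),
      engageStayProb = as.numeric(engageStayProb),
      disengageStayProb = as.numeric(disengageStayProb),
      landmarkNoisePx = as.numeric(landmarkNoisePx),
      noFaceProb = as.numeric(noFaceProb),
      imageSize = as.integer(imageSize),
      seed = as.integer(seed))
}

setMethod("show", "SessionConfig", function(object) {
  cat("SessionConfig:", object@nTasks, "task(s),",
      paste(object@taskDurationsS, collapse = "/"), "s at",
      paste(object@fps, collapse = "/"), "fps\n")
  cat("  stay probs (engaged/disengaged):", object@engageStayProb, "/",
      object@disengageStayProb, "\n")
  cat("  landmark noise:", object@landmarkNoisePx, "px; no-face prob:",
      object@noFaceProb, "\n")
  cat("  frames:", object@imageSize[1], "x", object@imageSize[2],
      "; seed:", object@seed, "\n")
})

# Pixels per canonical unit and skin-centre placement for a frame size.
renderScale <- function(imageSize) {
  0.30 * min(imageSize)
}

# --- trajectory ------------------------------------------------------------

# Uses the current RNG state; the exported wrapper scopes a seed around it.
simulateVATrajectoryImpl <- function(nFrames, engageStayProb,
                                     disengageStayProb,
                                     start = c("random", "engaged",
                                               "disengaged")) {
  start <- match.arg(start)
  e <- engageStayProb; d <- disengageStayProb
  engaged <- logical(nFrames)
  engaged[1] <- switch(start,
    engaged = TRUE,
    disengaged = FALSE,
    random = {
      # stationary probability of the engaged state
      pStat <- if (e == 1 && d == 1) 0.5 else (1 - d) / ((1 - e) + (1 - d))
      stats::runif(1) < pStat
    })
  if (nFrames > 1) {
    u <- stats::runif(nFrames - 1)
    for (i in 2:nFrames) {
      engaged[i] <- if (engaged[i - 1]) u[i - 1] < e else u[i - 1] >= d
    }
  }
  # emissions: engaged -> (+, +) quadrant; disengaged -> uniform over the
  # other three quadrants (keeps the non-engaged class symmetric)
  v <- stats::runif(nFrames)
  a <- stats::runif(nFrames)
  quad <- sample.int(3L, nFrames, replace = TRUE)
  flipV <- !engaged & quad %in% c(1L, 2L)
  flipA <- !engaged & quad %in% c(2L, 3L)
  v[flipV] <- -v[flipV]
  a[flipA] <- -a[flipA]
  data.frame(valence = v, arousal = a, engaged = engaged)
}

#' Simulate a valence/arousal engagement trajectory
#'
#' A two-state Markov chain over \{engaged, disengaged\}. The engaged state
#' emits valence and arousal uniformly from the strictly positive quadrant;
#' the disengaged state emits uniformly from one of the three remaining
#' quadrants (chosen uniformly). Identical inputs and seed give an
#' identical trajectory.
#'
#' @param nFrames number of frames (>= 1).
#' @param engageStayProb,disengageStayProb stay probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @param start initial state: `"random"` (stationary draw), `"engaged"` or
#'   `"disengaged"`.
#' @return a data.frame with columns `valence`, `arousal`, `engaged`.
#' @examples
#' tr <- simulateVATrajectory(50, 1, 0.5, seed = 1, start = "engaged")
#' all(tr$valence > 0 & tr$arousal > 0)  # absorbing engaged state
#' @export
simulateVATrajectory <- function(nFrames, engageStayProb = 0.9,
                                 disengageStayProb = 0.9, seed = 1L,
                                 start = c("random", "engaged",
                                           "disengaged")) {
  stopIfNot(is.numeric(nFrames) && length(nFrames) == 1 &&
              is.finite(nFrames) && nFrames >= 1,
            "nFrames must be a positive integer")
  stopIfNot(isProb(engageStayProb), "engageStayProb must be in [0, 1]")
  stopIfNot(isProb(disengageStayProb), "disengageStayProb must be in [0, 1]")
  start <- match.arg(start)
  withr::with_seed(seed,
    simulateVATrajectoryImpl(as.integer(nFrames), engageStayProb,
                             disengageStayProb, start))
}

# --- rendering -------------------------------------------------------------

# Rasterize one schematic face. Uses the current RNG state for geometry
# noise, annotation jitter and face dropout.
renderFaceFrameImpl <- function(valence, arousal, config) {
  H <- config@imageSize[1]; W <- config@imageSize[2]
  s <- renderScale(config@imageSize)
  centre <- c((W - 1) / 2, (H - 1) / 2)
  noisePx <- config@landmarkNoisePx

  if (config@noFaceProb > 0 && stats::runif(1) < config@noFaceProb) {
    return(list(
      image = matrix(0.05, H, W),
      truth = list(valence = valence, arousal = arousal,
                   engaged = valence > 0 && arousal > 0,
                   facePresent = FALSE, bbox = NULL, landmarks = NULL)))
  }

  g <- faceGeometry(valence, arousal)
  g <- perturbGeometry(g, noisePx / s)
  gp <- transformGeometry(g, s, centre)

  xg <- matrix(rep(0:(W - 1), each = H), nrow = H)
  yg <- matrix(rep(0:(H - 1), times = W), nrow = H)
  img <- matrix(0.05, H, W)

  inSkin <- ((xg - gp$skinC[1]) / gp$skinA)^2 +
            ((yg - gp$skinC[2]) / gp$skinB)^2 <= 1
  img[inSkin] <- 0.85

  # nose drawn slightly darker than skin: visible but above the feature
  # threshold, so it never contaminates feature components
  bridge <- abs(xg - gp$noseX) <= 0.02 * s &
    yg >= gp$noseBridgeY[1] & yg <= gp$noseBridgeY[4] & inSkin
  base <- abs(yg - gp$noseBaseY) <= 0.02 * s &
    xg >= min(gp$noseBaseX) & xg <= max(gp$noseBaseX) & inSkin
  img[bridge | base] <- 0.65

  dark <- (abs(xg - gp$browL[1]) <= gp$browHalf &
             abs(yg - gp$browL[2]) <= gp$browThick) |
          (abs(xg - gp$browR[1]) <= gp$browHalf &
             abs(yg - gp$browR[2]) <= gp$browThick) |
          (((xg - gp$eyeL[1]) / gp$ew)^2 +
             ((yg - gp$eyeL[2]) / gp$eh)^2 <= 1) |
          (((xg - gp$eyeR[1]) / gp$ew)^2 +
             ((yg - gp$eyeR[2]) / gp$eh)^2 <= 1)
  tM <- (xg - gp$mouthC[1]) / gp$mw
  yuM <- gp$mouthC[2] - gp$o / 2 + (gp$cOff + gp$o / 2) * tM^2
  ylM <- gp$mouthC[2] + gp$o / 2 + (gp$cOff - gp$o / 2) * tM^2
  dark <- dark | (abs(tM) <= 1 & yg >= yuM & yg <= ylM)
  img[dark & inSkin] <- 0.15

  lm <- landmarksFromGeometry(gp)
  if (noisePx > 0) {
    lm <- lm + matrix(stats::rnorm(136, 0, noisePx), 68, 2)
  }
  # bbox: union of the skin-ellipse box and the landmark extent, clipped
  x0 <- max(0, floor(min(gp$skinC[1] - gp$skinA, lm[, 1])))
  x1 <- min(W - 1, ceiling(max(gp$skinC[1] + gp$skinA, lm[, 1])))
  y0 <- max(0, floor(min(gp$skinC[2] - gp$skinB, lm[, 2])))
  y1 <- min(H - 1, ceiling(max(gp$skinC[2] + gp$skinB, lm[, 2])))

  list(image = img,
       truth = list(valence = valence, arousal = arousal,
                    engaged = valence > 0 && arousal > 0,
                    facePresent = TRUE,
                    bbox = c(x = x0, y = y0, w = x1 - x0 + 1,
                             h = y1 - y0 + 1),
                    landmarks = lm))
}

#' Render one synthetic face frame
#'
#' Draws the schematic face (skin ellipse, brows, eyes, nose, mouth) for a
#' valence/arousal state and returns the grayscale image together with the
#' ground truth (exact landmarks, bounding box, engagement flag). With
#' probability `noFaceProb` a faceless background frame is emitted instead.
#'
#' @param valence,arousal affect coordinates in `[-1, 1]`.
#' @param config a [SessionConfig-class].
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (as inside [simulateSession()]).
#' @return `list(image = H x W matrix in [0, 1], truth = list(...))`.
#' @examples
#' fr <- renderFaceFrame(0.8, 0.5, sessionConfig(noFaceProb = 0), seed = 1)
#' dim(fr$image)
#' @export
renderFaceFrame <- function(valence, arousal, config = sessionConfig(),
                            seed = NULL) {
  stopIfNot(is(config, "SessionConfig"), "config must be a SessionConfig")
  validObject(config)
  if (is.null(seed)) {
    renderFaceFrameImpl(valence, arousal, config)
  } else {
    withr::with_seed(seed, renderFaceFrameImpl(valence, arousal, config))
  }
}

# --- session ---------------------------------------------------------------

manifestColumns <- function() {
  c("frame_id", "task_id", "t_seconds", "valence", "arousal", "engaged",
    "face_present", "bbox_x", "bbox_y", "bbox_w", "bbox_h",
    as.vector(t(outer(paste0("lm_", 0:67), c("x", "y"), paste, sep = "_"))))
}

#' Simulate a full labelled therapy session on disk
#'
#' Writes `round(duration * fps)` grayscale PNG frames per task under
#' `dir/frames/` plus a `manifest.csv` with one row per frame: the frame
#' id, task id, timestamp, true valence/arousal, the engagement flag
#' (defined from valence/arousal alone, so a frame can be engaged while
#' the face is out of view), face presence, bounding box and the 68
#' ground-truth landmark coordinates (0-based pixels). The whole session
#' is a deterministic function of the configuration (including its seed).
#'
#' @param config a [SessionConfig-class].
#' @param dir output directory (created if needed).
#' @param childId identifier recorded in return value metadata.
#' @return (invisibly) a list with `framesDir`, `manifestPath`, `manifest`
#'   (the data.frame) and `childId`.
#' @examples
#' \donttest{
#' cfg <- sessionConfig(taskDurationsS = c(2, 2), seed = 3)
#' out <- simulateSession(cfg, tempfile("sess"))
#' nrow(out$manifest)  # sum of round(duration * fps)
#' }
#' @export
simulateSession <- function(config = sessionConfig(), dir, childId = "C1") {
  stopIfNot(is(config, "SessionConfig"), "config must be a SessionConfig")
  validObject(config)
  stopIfNot(is.character(dir) && length(dir) == 1, "dir must be a path")
  framesDir <- file.path(dir, "frames")
  ok <- dir.create(framesDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(framesDir)) {
    stop("cannot create output directory: ", framesDir, call. = FALSE)
  }
  fps <- rep_len(config@fps, config@nTasks)

  rows <- vector("list", config@nTasks)
  withr::with_seed(config@seed, {
    frameId <- 0L
    for (t in seq_len(config@nTasks)) {
      taskId <- sprintf("task%02d", t)
      n <- as.integer(floor(config@taskDurationsS[t] * fps[t] + 0.5))
      traj <- simulateVATrajectoryImpl(n, config@engageStayProb,
                                       config@disengageStayProb, "random")
      taskRows <- matrix(NA_real_, n, length(manifestColumns()) - 1L)
      for (i in seq_len(n)) {
        fr <- renderFaceFrameImpl(traj$valence[i], traj$arousal[i], config)
        png::writePNG(fr$image,
                      file.path(framesDir,
                                sprintf("%s_%05d.png", taskId, i - 1L)))
        tru <- fr$truth
        lmFlat <- if (tru$facePresent) as.vector(t(tru$landmarks)) else
          rep(NA_real_, 136)
        bbox <- if (tru$facePresent) tru$bbox else rep(NA_real_, 4)
        taskRows[i, ] <- c(frameId, (i - 1L) / fps[t], tru$valence,
                           tru$arousal, as.numeric(tru$engaged),
                           as.numeric(tru$facePresent), bbox, lmFlat)
        frameId <- frameId + 1L
      }
      df <- as.data.frame(taskRows)
      names(df) <- setdiff(manifestColumns(), "task_id")
      df$task_id <- taskId
      rows[[t]] <- df[, manifestColumns()]
    }
  })
  manifest <- do.call(rbind, rows)
  manifest$frame_id <- as.integer(manifest$frame_id)
  manifest$engaged <- as.integer(manifest$engaged)
  manifest$face_present <- as.integer(manifest$face_present)
  manifestPath <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifestPath, row.names = FALSE)
  invisible(list(framesDir = framesDir, manifestPath = manifestPath,
                 manifest = manifest, childId = childId,
                 seed = config@seed))
}

#' Simulate therapist behaviour-assessment sheets
#'
#' One sheet per task: 8 items on the 0-3 agreement scale (0 = strongly
#' disagree, 3 = strongly agree; 24 points maximum per task). Each item is
#' scored as `clip(round(3 * (fraction + noise)), 0, 3)` where `fraction`
#' is the task's true engaged fraction and `noise` is Gaussian rater noise,
#' so sheet totals correlate with the underlying engagement.
#'
#' @param trueTaskFractions true engaged fractions in `[0, 1]`, one per task.
#' @param raterNoiseSd standard deviation of the per-item rater noise (on
#'   the fraction scale).
#' @param seed integer seed.
#' @param childId identifier recorded in the sheet.
#' @return a data.frame with columns `child_id`, `task_id`,
#'   `item_1` ... `item_8`.
#' @examples
#' simulateAssessment(c(0.9, 0.2), raterNoiseSd = 0, seed = 1)
#' @export
simulateAssessment <- function(trueTaskFractions, raterNoiseSd = 0.1,
                               seed = 1L, childId = "C1") {
  stopIfNot(is.numeric(trueTaskFractions) && length(trueTaskFractions) >= 1 &&
              all(is.finite(trueTaskFractions)) &&
              all(trueTaskFractions >= 0 & trueTaskFractions <= 1),
            "trueTaskFractions must be in [0, 1]")
  stopIfNot(is.numeric(raterNoiseSd) && length(raterNoiseSd) == 1 &&
              is.finite(raterNoiseSd) && raterNoiseSd >= 0,
            "raterNoiseSd must be non-negative")
  withr::with_seed(seed, {
    sheets <- lapply(seq_along(trueTaskFractions), function(t) {
      noisy <- trueTaskFractions[t] + stats::rnorm(8, 0, raterNoiseSd)
      items <- pmin(pmax(round(3 * noisy), 0), 3)
      row <- data.frame(child_id = childId,
                        task_id = sprintf("task%02d", t))
      row[paste0("item_", 1:8)] <- as.list(as.integer(items))
      row
    })
    do.call(rbind, sheets)
  })
}
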