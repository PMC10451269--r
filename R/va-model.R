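#' Map valence/arousal to the binary engagement label
#'
#' Engagement is defined on the circumplex model of affect: a state is
#' `engaged` exactly when valence and arousal are both strictly positive
#' (the positive-valence, high-arousal quadrant). States on an axis
#' (valence or arousal exactly zero) are conservatively labelled
#' `not_engaged`. The map is invariant to positive rescaling of the
#' coordinates.
#'
#' @param valence numeric vector of valence coordinates in `[-1, 1]`
#'   (pleasure-displeasure axis).
#' @param arousal numeric vector of arousal coordinates in `[-1, 1]`
#'   (activation axis), recycled against `valence`.
#' @return a factor with levels `c("not_engaged", "engaged")`.
#' @examples
#' mapVAToEngagement(0.7, 0.6)    # engaged
#' mapVAToEngagement(-0.5, -0.5)  # not_engaged
#' mapVAToEngagement(0, 0.9)      # boundary -> not_engaged
#' @export
mapVAToEngagement <- function(valence, arousal) {
  if (!is.numeric(valence) || !is.numeric(arousal)) {
    stop("valence and arousal must be numeric", call. = FALSE)
  }
  n <- max(length(valence), length(arousal))
  valence <- rep_len(valence, n)
  arousal <- rep_len(arousal, n)
  if (any(!is.finite(valence)) || any(!is.finite(arousal))) {
    stop("valence and arousal must be finite", call. = FALSE)
  }
  engaged <- valence > 0 & arousal > 0
  factor(ifelse(engaged, "engaged", "not_engaged"),
         levels = c("not_engaged", "engaged"))
}
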