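# Canonical schematic-face geometry.
#
# Coordinates follow the image convention: origin top-left, x rightward,
# y downward. The canonical unit is the inter-ocular distance (eye-centre
# to eye-centre), with the origin at the inter-ocular midpoint. The 68
# landmark points follow the iBUG-300W ordering (0-16 jaw, 17-26 brows,
# 27-35 nose, 36-47 eyes, 48-67 mouth; 1-based rows 1-68 in R).
#
# Affect is encoded monotonically in the geometry:
#   * mouth-corner vertical offset rises (smaller y) with valence;
#   * eye opening and mouth opening grow with arousal.

#' Face geometry parameters for a valence/arousal state
#'
#' Returns the parametric description of the schematic face used by the
#' synthetic renderer and the landmark template: eye centres and openings,
#' brow segments, nose, the mouth arcs (corner offset driven by valence,
#' opening driven by arousal), the jaw ellipse and the skin ellipse. All
#' lengths are in canonical units (inter-ocular distance = 1).
#'
#' @param valence valence in `[-1, 1]`.
#' @param arousal arousal in `[-1, 1]`.
#' @return a named list of geometry elements.
#' @keywords internal
faceGeometry <- function(valence, arousal) {
  stopIfNot(is.numeric(valence) && length(valence) == 1 && is.finite(valence) &&
              abs(valence) <= 1, "valence must be a finite scalar in [-1, 1]")
  stopIfNot(is.numeric(arousal) && length(arousal) == 1 && is.finite(arousal) &&
              abs(arousal) <= 1, "arousal must be a finite scalar in [-1, 1]")
  aro01 <- (arousal + 1) / 2
  o <- 0.06 + 0.22 * aro01                      # outer-lip opening
  list(
    eyeL   = c(-0.5, 0),
    eyeR   = c(0.5, 0),
    ew     = 0.18,                              # eye half-width
    eh     = 0.06 + 0.10 * aro01,               # eye half-height (arousal)
    browL  = c(-0.5, -0.28),                    # brow centres
    browR  = c(0.5, -0.28),
    browHalf  = 0.22,
    browThick = 0.025,                          # half-thickness
    noseX  = 0,
    noseBridgeY = c(0.05, 0.22, 0.38, 0.55),
    noseBaseY   = 0.62,
    noseBaseX   = c(-0.16, -0.08, 0, 0.08, 0.16),
    mouthC = c(0, 0.95),                        # mouth centre
    mw     = 0.42,                              # mouth half-width
    cOff   = -0.28 * valence,                   # corner offset (valence)
    o      = o,
    oi     = max(o - 0.08, 0.01),               # inner-lip opening
    jawC   = c(0, 0.35), jawA = 1.05, jawB = 1.15,
    skinC  = c(0, 0.25), skinA = 1.12, skinB = 1.35
  )
}

# Rescale a canonical geometry into pixel units: `s` pixels per canonical
# unit, with the skin-ellipse centre mapped to `centre` (0-based pixels).
# All formulas downstream are affine-covariant, so the same landmark and
# render code runs in either unit system.
transformGeometry <- function(g, s, centre) {
  shift <- function(p) centre + (p - g$skinC) * s
  out <- g
  out$eyeL <- shift(g$eyeL); out$eyeR <- shift(g$eyeR)
  out$ew <- g$ew * s; out$eh <- g$eh * s
  out$browL <- shift(g$browL); out$browR <- shift(g$browR)
  out$browHalf <- g$browHalf * s; out$browThick <- g$browThick * s
  out$noseX <- centre[1] + (g$noseX - g$skinC[1]) * s
  out$noseBridgeY <- centre[2] + (g$noseBridgeY - g$skinC[2]) * s
  out$noseBaseY <- centre[2] + (g$noseBaseY - g$skinC[2]) * s
  out$noseBaseX <- centre[1] + (g$noseBaseX - g$skinC[1]) * s
  out$mouthC <- shift(g$mouthC)
  out$mw <- g$mw * s; out$cOff <- g$cOff * s
  out$o <- g$o * s; out$oi <- g$oi * s
  out$jawC <- shift(g$jawC); out$jawA <- g$jawA * s; out$jawB <- g$jawB * s
  out$skinC <- centre; out$skinA <- g$skinA * s; out$skinB <- g$skinB * s
  out
}

# Gaussian perturbation of the feature parameters (noise in canonical
# units). This is the "camera/detector sees a noisy geometry" half of the
# landmark-noise model; per-point annotation jitter is added separately.
perturbGeometry <- function(g, sigma) {
  if (sigma <= 0) return(g)
  shift <- stats::rnorm(2, 0, sigma)
  wiggle <- function(p) p + shift + stats::rnorm(length(p), 0, sigma / 2)
  g$eyeL <- wiggle(g$eyeL)
  g$eyeR <- wiggle(g$eyeR)
  g$eh <- max(g$eh + stats::rnorm(1, 0, sigma / 2), 0.02)
  g$browL <- g$browL + shift; g$browR <- g$browR + shift
  g$noseX <- g$noseX + shift[1]
  g$noseBridgeY <- g$noseBridgeY + shift[2]
  g$noseBaseY <- g$noseBaseY + shift[2]
  g$noseBaseX <- g$noseBaseX + shift[1]
  g$mouthC <- wiggle(g$mouthC)
  g$cOff <- g$cOff + stats::rnorm(1, 0, sigma / 2)
  g$o <- max(g$o + stats::rnorm(1, 0, sigma / 2), 0.02)
  g$oi <- max(g$o - 0.08, 0.01)
  g$jawC <- g$jawC + shift
  g$skinC <- g$skinC + shift
  g
}

# 68 x 2 landmark matrix from a geometry list (any unit system).
landmarksFromGeometry <- function(g) {
  lm <- matrix(NA_real_, 68, 2)

  theta <- seq(pi, 0, length.out = 17)          # jaw: left ear -> chin -> right
  lm[1:17, 1] <- g$jawC[1] + g$jawA * cos(theta)
  lm[1:17, 2] <- g$jawC[2] + g$jawB * sin(theta)

  bx <- seq(-g$browHalf, g$browHalf, length.out = 5)
  lm[18:22, 1] <- g$browL[1] + bx; lm[18:22, 2] <- g$browL[2]
  lm[23:27, 1] <- g$browR[1] + bx; lm[23:27, 2] <- g$browR[2]

  lm[28:31, 1] <- g$noseX; lm[28:31, 2] <- g$noseBridgeY
  lm[32:36, 1] <- g$noseBaseX; lm[32:36, 2] <- g$noseBaseY

  ang <- c(180, 120, 60, 0, -60, -120) * pi / 180
  lm[37:42, 1] <- g$eyeL[1] + g$ew * cos(ang)
  lm[37:42, 2] <- g$eyeL[2] - g$eh * sin(ang)
  lm[43:48, 1] <- g$eyeR[1] + g$ew * cos(ang)
  lm[43:48, 2] <- g$eyeR[2] - g$eh * sin(ang)

  # mouth arcs: upper lip runs corner -> corner through (centre, my - o/2),
  # lower through (centre, my + o/2); corners sit at my + cOff.
  yu <- function(t, my, c0, o) my - o / 2 + (c0 + o / 2) * t^2
  yl <- function(t, my, c0, o) my + o / 2 + (c0 - o / 2) * t^2
  my <- g$mouthC[2]; mx <- g$mouthC[1]
  tU <- c(-0.6, -0.3, 0, 0.3, 0.6); tL <- c(0.6, 0.3, 0, -0.3, -0.6)
  lm[49, ] <- c(mx - g$mw, my + g$cOff)
  lm[50:54, 1] <- mx + tU * g$mw; lm[50:54, 2] <- yu(tU, my, g$cOff, g$o)
  lm[55, ] <- c(mx + g$mw, my + g$cOff)
  lm[56:60, 1] <- mx + tL * g$mw; lm[56:60, 2] <- yl(tL, my, g$cOff, g$o)
  mwi <- 0.8 * g$mw
  tUi <- c(-0.5, 0, 0.5); tLi <- c(0.5, 0, -0.5)
  lm[61, ] <- c(mx - mwi, my + g$cOff)
  lm[62:64, 1] <- mx + tUi * mwi; lm[62:64, 2] <- yu(tUi, my, g$cOff, g$oi)
  lm[65, ] <- c(mx + mwi, my + g$cOff)
  lm[66:68, 1] <- mx + tLi * mwi; lm[66:68, 2] <- yl(tLi, my, g$cOff, g$oi)
  lm
}

#' Canonical 68-point face template for a valence/arousal state
#'
#' The template in canonical coordinates (inter-ocular distance 1, origin
#' at the inter-ocular midpoint, y downward). Mouth-corner height is
#' strictly increasing in valence (corners move up, i.e. to smaller y);
#' eye opening and mouth opening are strictly increasing in arousal.
#'
#' @inheritParams faceGeometry
#' @return a 68 x 2 matrix of (x, y) canonical coordinates.
#' @examples
#' lm <- faceTemplate(0.9, 0.2)
#' plot(lm[, 1], -lm[, 2], asp = 1)  # flip y for plotting
#' @export
faceTemplate <- function(valence, arousal) {
  landmarksFromGeometry(faceGeometry(valence, arousal))
}
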