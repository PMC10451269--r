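# Internal helpers shared across modules.

# Round half away from zero (for non-negative percentages this is the
# conventional "half-up" rule; base::round() rounds half to even).
roundHalfUp <- function(x) {
  floor(x + 0.5)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# 68-point iBUG-300W region index sets (1-based row indices into a 68x2
# landmark matrix; the scheme itself is 0-based: jaw 0-16, brows 17-26,
# nose 27-35, eyes 36-47, mouth 48-67).
lmRegions <- function() {
  list(
    jaw       = 1:17,
    browLeft  = 18:22,
    browRight = 23:27,
    nose      = 28:36,
    eyeLeft   = 37:42,
    eyeRight  = 43:48,
    mouth     = 49:68,
    mouthOuter = 49:60,
    mouthInner = 61:68
  )
}

assertLandmarks <- function(lm, what = "landmarks") {
  stopIfNot(is.matrix(lm) && nrow(lm) == 68 && ncol(lm) == 2,
            sprintf("%s must be a 68 x 2 numeric matrix", what))
  stopIfNot(all(is.finite(lm)), sprintf("%s must be all finite", what))
  invisible(lm)
}

isProb <- function(p) {
  is.numeric(p) && length(p) == 1 && is.finite(p) && p >= 0 && p <= 1
}
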