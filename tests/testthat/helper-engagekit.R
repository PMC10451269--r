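# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# A small trained classifier for pipeline-level tests (the acceptance
# suite trains its own full-size model). Landmark-path training keeps
# unit tests fast.
tinyModel <- function() {
  if (is.null(.fixtures$tinyModel)) {
    ds <- engagementTrainingSet(400, noisePx = 0, seed = 101,
                                method = "landmarks")
    .fixtures$tinyModel <- trainClassifier(
      buildClassifier(classifierSpec(seed = 101)),
      ds$x, ds$y, epochs = 3, seed = 101)
  }
  .fixtures$tinyModel
}

# A small zero-noise synthetic session on disk, shared across tests.
tinySession <- function() {
  if (is.null(.fixtures$tinySession)) {
    dir <- file.path(tempdir(), "engagekit-tiny-session")
    cfg <- sessionConfig(taskDurationsS = c(3, 2), fps = 10,
                         landmarkNoisePx = 0, noFaceProb = 0, seed = 11)
    .fixtures$tinySession <- simulateSession(cfg, dir)
  }
  .fixtures$tinySession
}

# Independent brute-force Cohen's kappa from the 2x2 contingency table,
# coded separately from the package implementation (counts, not means).
bruteForceKappa <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1); n00 <- sum(a == 0 & b == 0)
  n10 <- sum(a == 1 & b == 0); n01 <- sum(a == 0 & b == 1)
  po <- (n11 + n00) / n
  pe <- ((n11 + n10) * (n11 + n01) + (n00 + n01) * (n00 + n10)) / n^2
  if (pe >= 1) return(1)            # both raters constant and identical
  (po - pe) / (1 - pe)
}

# Count strict local maxima over the 8-neighbourhood of positive pixels.
countLocalMaxima <- function(img) {
  H <- nrow(img); W <- ncol(img)
  cnt <- 0L
  for (i in 2:(H - 1)) {
    for (j in 2:(W - 1)) {
      v <- img[i, j]
      if (v <= 0) next
      nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v >= max(nb) && sum(nb == v) == 1) cnt <- cnt + 1L
    }
  }
  cnt
}

boxIoU <- function(box, bb) {
  ix0 <- max(box@x, bb["x"]); iy0 <- max(box@y, bb["y"])
  ix1 <- min(box@x + box@w, bb["x"] + bb["w"])
  iy1 <- min(box@y + box@h, bb["y"] + bb["h"])
  inter <- max(0, ix1 - ix0) * max(0, iy1 - iy0)
  unname(inter / (box@w * box@h + bb["w"] * bb["h"] - inter))
}
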