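test_that("an absorbing engaged state stays in the positive quadrant", {
  tr <- simulateVATrajectory(50, engageStayProb = 1, disengageStayProb = 0.5,
                             seed = 1, start = "engaged")
  expect_true(all(tr$valence > 0 & tr$arousal > 0))
  expect_true(all(tr$engaged))
})

test_that("trajectories are deterministic given the seed", {
  t1 <- simulateVATrajectory(200, 0.8, 0.7, seed = 42)
  t2 <- simulateVATrajectory(200, 0.8, 0.7, seed = 42)
  expect_identical(t1, t2)
  t3 <- simulateVATrajectory(200, 0.8, 0.7, seed = 43)
  expect_false(identical(t1, t3))
})

test_that("the long-run engaged fraction matches the stationary distribution", {
  # symmetric chain: stationary engaged probability 1/2; the mean of a
  # 2-state chain has variance p(1-p)(1+rho)/((1-rho) n), rho = e + d - 1
  n <- 20000
  tr <- simulateVATrajectory(n, 0.9, 0.9, seed = 7)
  rho <- 0.8
  se <- sqrt(0.25 * (1 + rho) / (1 - rho) / n)
  expect_lt(abs(mean(tr$engaged) - 0.5), 3 * se)
  # engagement flag is consistent with the emitted quadrant
  expect_identical(tr$engaged, tr$valence > 0 & tr$arousal > 0)
})

test_that("trajectory rejects invalid arguments", {
  expect_error(simulateVATrajectory(0, 0.5, 0.5, seed = 1), "positive")
  expect_error(simulateVATrajectory(10, 1.5, 0.5, seed = 1), "\\[0, 1\\]")
})

test_that("rendering is deterministic and monotone in affect", {
  cfg <- sessionConfig(noFaceProb = 0)
  f1 <- renderFaceFrame(0.4, -0.2, cfg, seed = 5)
  f2 <- renderFaceFrame(0.4, -0.2, cfg, seed = 5)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth$landmarks, f2$truth$landmarks)

  # mouth corners rise (smaller y) with valence at fixed arousal
  reg <- list(cornerL = 49, cornerR = 55)
  lmLow <- faceTemplate(-0.9, 0.1)
  lmHigh <- faceTemplate(0.9, 0.1)
  expect_lt(lmHigh[reg$cornerL, 2], lmLow[reg$cornerL, 2])
  expect_lt(lmHigh[reg$cornerR, 2], lmLow[reg$cornerR, 2])

  # strict monotonicity on a grid: corner height in valence, eye opening
  # and mouth opening in arousal
  vGrid <- seq(-1, 1, by = 0.25)
  cornerY <- vapply(vGrid, function(v) faceTemplate(v, 0)[49, 2], numeric(1))
  expect_true(all(diff(cornerY) < 0))
  aGrid <- seq(-1, 1, by = 0.25)
  eyeOpen <- vapply(aGrid, function(a) {
    lm <- faceTemplate(0, a)
    max(lm[37:42, 2]) - min(lm[37:42, 2])
  }, numeric(1))
  mouthOpen <- vapply(aGrid, function(a) {
    lm <- faceTemplate(0, a)
    lm[58, 2] - lm[52, 2]   # lower-lip centre minus upper-lip centre
  }, numeric(1))
  expect_true(all(diff(eyeOpen) > 0))
  expect_true(all(diff(mouthOpen) > 0))
})

test_that("truth landmarks lie inside the truth bounding box", {
  cfg <- sessionConfig(noFaceProb = 0, landmarkNoisePx = 1)
  set.seed(12)
  for (i in 1:100) {
    v <- runif(1, -1, 1); a <- runif(1, -1, 1)
    fr <- renderFaceFrame(v, a, cfg, seed = i)
    lm <- fr$truth$landmarks; bb <- fr$truth$bbox
    expect_true(all(lm[, 1] >= bb["x"] - 1e-9 &
                      lm[, 1] <= bb["x"] + bb["w"] - 1 + 1e-9))
    expect_true(all(lm[, 2] >= bb["y"] - 1e-9 &
                      lm[, 2] <= bb["y"] + bb["h"] - 1 + 1e-9))
  }
})

test_that("a too-small image is rejected", {
  expect_error(sessionConfig(imageSize = c(32L, 32L)), "face template")
})

test_that("sessions conserve frame counts and are byte-identical per seed", {
  out <- tinySession()
  files <- list.files(out$framesDir)
  expect_equal(length(files), nrow(out$manifest))
  expect_equal(nrow(out$manifest), sum(floor(c(3, 2) * 10 + 0.5)))
  # quadrant consistency across the manifest
  expect_identical(out$manifest$engaged == 1,
                   out$manifest$valence > 0 & out$manifest$arousal > 0)
  # no-face probability zero -> every frame has a face
  expect_true(all(out$manifest$face_present == 1))

  cfg <- sessionConfig(taskDurationsS = c(3, 2), fps = 10,
                       landmarkNoisePx = 0, noFaceProb = 0, seed = 11)
  d2 <- file.path(tempdir(), "engagekit-tiny-session-rerun")
  out2 <- simulateSession(cfg, d2)
  expect_identical(readLines(out$manifestPath), readLines(out2$manifestPath))
  expect_identical(readBin(file.path(out$framesDir, files[1]), "raw", 1e6),
                   readBin(file.path(out2$framesDir, files[1]), "raw", 1e6))
  unlink(d2, recursive = TRUE)
})

test_that("per-task frame counts reproduce the published session layout", {
  cfg <- sessionConfig(taskDurationsS = c(19, 8, 19),
                       fps = c(9.8, 10.5, 9.85), seed = 2)
  d <- tempfile("counts")
  out <- simulateSession(cfg, d)
  counts <- as.vector(table(factor(out$manifest$task_id,
                                   levels = unique(out$manifest$task_id))))
  expect_equal(counts, c(186, 84, 187))
  expect_equal(nrow(out$manifest), 457)
  unlink(d, recursive = TRUE)
})

test_that("fps 10 for 10 s gives exactly 100 frames", {
  cfg <- sessionConfig(taskDurationsS = 10, fps = 10, seed = 3)
  d <- tempfile("hundred")
  out <- simulateSession(cfg, d)
  expect_equal(nrow(out$manifest), 100)
  unlink(d, recursive = TRUE)
})

test_that("no-face frames appear at the configured rate and carry no bbox", {
  cfg <- sessionConfig(taskDurationsS = 20, fps = 10, noFaceProb = 0.3,
                       seed = 9)
  d <- tempfile("nf")
  out <- simulateSession(cfg, d)
  noFace <- out$manifest$face_present == 0
  expect_gt(sum(noFace), 0)
  # binomial 3-sigma band around 0.3
  expect_lt(abs(mean(noFace) - 0.3), 3 * sqrt(0.3 * 0.7 / 200))
  expect_true(all(is.na(out$manifest$bbox_x[noFace])))
  expect_true(all(is.na(out$manifest$lm_0_x[noFace])))
  expect_true(all(!is.na(out$manifest$bbox_x[!noFace])))
  unlink(d, recursive = TRUE)
})

test_that("assessment sheets hit the scale endpoints and track engagement", {
  s1 <- simulateAssessment(1.0, raterNoiseSd = 0, seed = 1)
  expect_equal(as.numeric(s1[1, paste0("item_", 1:8)]), rep(3, 8))
  expect_equal(computeEPT(s1), 100)
  s0 <- simulateAssessment(0.0, raterNoiseSd = 0, seed = 1)
  expect_equal(as.numeric(s0[1, paste0("item_", 1:8)]), rep(0, 8))

  # Monte-Carlo: totals correlate strongly with the true fractions
  set.seed(31)
  frac <- runif(200)
  sheets <- simulateAssessment(frac, raterNoiseSd = 0.1, seed = 33)
  totals <- rowSums(sheets[, paste0("item_", 1:8)])
  expect_gt(cor(totals, frac), 0.8)

  expect_error(simulateAssessment(0.5, raterNoiseSd = -1), "non-negative")
  expect_error(simulateAssessment(1.5), "\\[0, 1\\]")
})
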