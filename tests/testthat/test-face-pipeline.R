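test_that("detection recovers the rendered face with high overlap", {
  cfg <- sessionConfig(noFaceProb = 0, landmarkNoisePx = 0)
  set.seed(8)
  for (i in 1:50) {
    fr <- renderFaceFrame(runif(1, -1, 1), runif(1, -1, 1), cfg, seed = i)
    box <- detectFace(fr$image)
    expect_false(is.null(box))                       # 100% recall
    expect_gte(boxIoU(box, fr$truth$bbox), 0.8)
  }
})

test_that("blank frames yield no detection", {
  expect_null(detectFace(matrix(0.05, 96, 96)))
  expect_null(detectFace(matrix(0, 64, 64)))
})

test_that("with two faces the larger one wins", {
  cfg <- sessionConfig(noFaceProb = 0, imageSize = c(96L, 96L))
  small <- renderFaceFrame(0.5, 0.5, sessionConfig(noFaceProb = 0,
                                                   imageSize = c(48L, 48L)),
                           seed = 1)
  big <- renderFaceFrame(0.5, 0.5, cfg, seed = 1)
  canvas <- matrix(0.05, 96, 200)
  canvas[1:96, 1:96] <- big$image
  canvas[1:48, 105:152] <- small$image
  box <- detectFace(canvas)
  expect_lt(box@x, 96)           # the larger (left) face was chosen
  expect_gt(box@w, 50)
})

test_that("unknown backends are configuration errors", {
  expect_error(detectFace(matrix(0.5, 8, 8), backend = "dlib68"), "backend")
  fr <- renderFaceFrame(0, 0, sessionConfig(noFaceProb = 0), seed = 1)
  box <- detectFace(fr$image)
  expect_error(extractLandmarks(fr$image, box, backend = "dlib68"), "backend")
})

test_that("landmark extraction is accurate on clean frames", {
  cfg <- sessionConfig(noFaceProb = 0, landmarkNoisePx = 0)
  set.seed(13)
  errs <- vapply(1:40, function(i) {
    fr <- renderFaceFrame(runif(1, -1, 1), runif(1, -1, 1), cfg, seed = 100 + i)
    box <- detectFace(fr$image)
    lm <- extractLandmarks(fr$image, box)
    mean(sqrt(rowSums((lm - fr$truth$landmarks)^2)))
  }, numeric(1))
  expect_lt(max(errs), 2)        # mean landmark error <= 2 px per frame
})

test_that("extraction scales with the face (affine equivariance)", {
  f1 <- renderFaceFrame(0.6, 0.3, sessionConfig(noFaceProb = 0,
                                                imageSize = c(96L, 96L)),
                        seed = 2)
  f2 <- renderFaceFrame(0.6, 0.3, sessionConfig(noFaceProb = 0,
                                                imageSize = c(192L, 192L)),
                        seed = 2)
  b1 <- detectFace(f1$image); b2 <- detectFace(f2$image)
  lm1 <- extractLandmarks(f1$image, b1)
  lm2 <- extractLandmarks(f2$image, b2)
  # compare box-relative coordinates: double image -> double offsets
  # (pixel quantization of the feature refinement doubles along with it)
  rel1 <- sweep(lm1, 2, c(b1@x, b1@y))
  rel2 <- sweep(lm2, 2, c(b2@x, b2@y))
  expect_lt(max(abs(rel2 - 2 * rel1)), 6)
  # and the normalized (scale-free) landmarks agree across scales
  expect_lt(max(abs(normalizeLandmarks(lm2) - normalizeLandmarks(lm1))), 0.08)
})

test_that("degenerate boxes and out-of-frame boxes are argument errors", {
  fr <- renderFaceFrame(0, 0, sessionConfig(noFaceProb = 0), seed = 1)
  expect_error(new("FaceBox", x = 10, y = 10, w = 0, h = 5, score = 1),
               "positive")
  bad <- new("FaceBox", x = 90, y = 90, w = 20, h = 20, score = 1)
  expect_error(extractLandmarks(fr$image, bad), "outside")
})

test_that("eye centroid sits above the mouth centroid on upright faces", {
  cfg <- sessionConfig(noFaceProb = 0)
  set.seed(77)
  for (i in 1:10) {
    fr <- renderFaceFrame(runif(1, -1, 1), runif(1, -1, 1), cfg, seed = 300 + i)
    lm <- extractLandmarks(fr$image, detectFace(fr$image))
    expect_lt(mean(lm[37:48, 2]), mean(lm[49:68, 2]))
  }
})

test_that("normalization is idempotent and fixes the inter-ocular distance", {
  lm <- faceTemplate(0.3, -0.4) * 37 + 100   # arbitrary similarity placement
  n1 <- normalizeLandmarks(lm)
  n2 <- normalizeLandmarks(n1)
  expect_lt(max(abs(n2 - n1)), 1e-9)
  eyeL <- colMeans(n1[37:42, ]); eyeR <- colMeans(n1[43:48, ])
  expect_equal(sqrt(sum((eyeR - eyeL)^2)), 1, tolerance = 1e-9)
})

test_that("normalization removes exactly the similarity component", {
  lm <- faceTemplate(-0.2, 0.8)
  base <- normalizeLandmarks(lm)
  set.seed(21)
  for (i in 1:20) {
    s <- runif(1, 0.3, 5); tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
    moved <- lm * s
    moved[, 1] <- moved[, 1] + tx
    moved[, 2] <- moved[, 2] + ty
    expect_lt(max(abs(normalizeLandmarks(moved) - base)), 1e-9)
  }
  # non-similarity distortion does change the output
  warped <- lm
  warped[, 2] <- warped[, 2] * 1.5
  expect_gt(max(abs(normalizeLandmarks(warped) - base)), 0.01)
})

test_that("coincident eye centroids raise a degenerate-geometry error", {
  lm <- matrix(1, 68, 2)
  expect_error(normalizeLandmarks(lm), "degenerate")
})
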