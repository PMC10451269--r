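test_that("rasterization draws one blob per well-separated landmark", {
  # 68 points on a coarse grid of exact pixel centres (avoids two-pixel
  # plateau ties in the strict local-maximum count)
  cols <- seq(5, 61, by = 7)
  rows <- seq(5, 61, by = 8)
  grid <- expand.grid(col = cols, row = rows)[1:68, ]
  pts <- cbind((grid$col - 1) / 63 * 3.2 - 1.6,
               (grid$row - 1) / 63 * 3.2 - 1.35)
  img <- rasterizeLandmarks(pts, size = c(64L, 64L), sigma = 1)
  expect_equal(countLocalMaxima(img), 68)
  expect_equal(max(img), 1)
  expect_equal(min(img), 0)
})

test_that("rasterization validates inputs and reports clipping", {
  expect_error(rasterizeLandmarks(matrix(0, 0, 2)), "68")
  expect_error(rasterizeLandmarks(faceTemplate(0, 0), size = c(16L, 16L)),
               ">= 32")
  far <- faceTemplate(0, 0)
  far[1, ] <- c(50, 50)
  expect_warning(img <- rasterizeLandmarks(far), "clipped")
  expect_equal(attr(img, "nClipped"), 1)
  expect_silent(rasterizeLandmarks(far, warn = FALSE))
})

test_that("the built model realizes the printed architecture", {
  m <- buildClassifier(classifierSpec(seed = 7))
  layers <- classifierLayers(m)
  expect_equal(layers$layer,
               c("conv1", "relu1", "pool1", "conv2", "relu2", "pool2",
                 "conv3", "relu3", "pool3", "flatten", "dense"))
  expect_equal(layers$filters[layers$type == "conv2d"], c(32, 32, 64))
  expect_true(all(layers$kernel_h[layers$type == "conv2d"] == 3))
  expect_true(all(layers$kernel_w[layers$type == "conv2d"] == 3))
  expect_equal(layers$units[layers$layer == "dense"], 2)
  # 2-way output head
  x <- array(runif(64 * 64), c(64, 64, 1))
  logits <- engagekit:::cnn_forward_logits(m@params, x)
  expect_equal(dim(logits), c(1, 2))
})

test_that("weight initialization is deterministic per seed", {
  m1 <- buildClassifier(classifierSpec(seed = 7))
  m2 <- buildClassifier(classifierSpec(seed = 7))
  expect_identical(m1@params, m2@params)
  m3 <- buildClassifier(classifierSpec(seed = 8))
  expect_false(identical(m1@params, m3@params))
})

test_that("undersized inputs are configuration errors", {
  expect_error(classifierSpec(inputSize = c(16L, 16L)), ">= 32")
  expect_error(engagekit:::convDims(c(20L, 20L)), "receptive-field")
})

test_that("analytic gradients match finite differences", {
  m <- buildClassifier(classifierSpec(c(32L, 32L), seed = 3))
  set.seed(9)
  X <- array(runif(32 * 32 * 2), c(32, 32, 2))
  y <- c(0L, 1L)
  lg <- engagekit:::cnn_loss_grad(m@params, X, y)
  eps <- 1e-6
  for (nm in names(m@params)) {
    ks <- sample(length(m@params[[nm]]), min(4, length(m@params[[nm]])))
    for (k in ks) {
      pp <- m@params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- m@params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (engagekit:::cnn_loss_grad(pp, X, y)$loss -
                engagekit:::cnn_loss_grad(pm, X, y)$loss) / (2 * eps)
      ana <- lg$grads[[nm]][k]
      # ReLU/max-pool kinks limit attainable agreement
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 0.02)
    }
  }
})

test_that("training is deterministic and learns a separable problem", {
  ds <- engagementTrainingSet(400, noisePx = 0, seed = 101,
                              method = "landmarks")
  expect_equal(dim(ds$x)[3], length(ds$y))
  m <- tinyModel()
  expect_true(m@trained)
  expect_equal(nrow(m@history), 3)
  expect_gte(m@valAccuracy, 0.85)
  expect_lt(m@history$loss[3], m@history$loss[1])
  # same data + seeds -> identical final loss and weights
  m2 <- trainClassifier(buildClassifier(classifierSpec(seed = 101)),
                        ds$x, ds$y, epochs = 3, seed = 101)
  expect_identical(m@history$loss[3], m2@history$loss[3])
  expect_identical(m@params, m2@params)
})

test_that("permuted labels drop held-out accuracy to chance", {
  ds <- engagementTrainingSet(600, noisePx = 0, seed = 55,
                              method = "landmarks")
  yPerm <- withr::with_seed(56, sample(ds$y))
  m <- trainClassifier(buildClassifier(classifierSpec(seed = 55)),
                       ds$x, yPerm, epochs = 2, seed = 55)
  # 120 held-out samples: a generous 3-sigma band around 0.5
  expect_gte(m@valAccuracy, 0.35)
  expect_lte(m@valAccuracy, 0.65)
})

test_that("degenerate training inputs are rejected", {
  ds <- engagementTrainingSet(40, seed = 1, method = "landmarks")
  oneClass <- rep(TRUE, length(ds$y))
  m0 <- buildClassifier(classifierSpec(seed = 1))
  expect_error(trainClassifier(m0, ds$x, oneClass), "both classes")
  expect_error(trainClassifier(m0, ds$x, ds$y[-1]), "match")
  bad <- array(0, c(48, 48, 4))
  expect_error(trainClassifier(m0, bad, c(0, 1, 0, 1)), "does not match")
})

test_that("classifyFrames preserves order and flags faceless frames", {
  m <- tinyModel()
  out <- tinySession()
  frames <- extractFrames(out$framesDir)
  labs <- classifyFrames(m, frames)
  expect_equal(nrow(labs), length(frames))            # record conservation
  expect_equal(labs$frame_index, out$manifest$frame_id)
  expect_true(all(labs$face_present))
  # all-blank session -> everything flagged no-face, labels NA
  blanks <- lapply(1:5, function(i) matrix(0.05, 96, 96))
  labsB <- classifyFrames(m, blanks)
  expect_equal(nrow(labsB), 5)
  expect_true(all(!labsB$face_present))
  expect_true(all(is.na(labsB$engaged)))
})

test_that("checkpoints round-trip through save/load", {
  m <- tinyModel()
  path <- tempfile(fileext = ".rds")
  saveClassifier(m, path)
  m2 <- loadClassifier(path)
  expect_identical(m2@params, m@params)
  expect_identical(m2@spec@inputSize, m@spec@inputSize)
  expect_true(m2@trained)
  ds <- engagementTrainingSet(10, seed = 3, method = "landmarks")
  expect_identical(predictEngagement(m2, ds$x), predictEngagement(m, ds$x))
  unlink(path)
})
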