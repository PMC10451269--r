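#' @title Convolutional classifier specification
#'
#' @description S4 description of the frame classifier: a single-channel
#' raster input of rasterized normalized landmarks, three convolution
#' blocks (32, 32 and 64 filters, all 3x3 kernels, each followed by a ReLU
#' rectifier and a 2x2 max-pool), a flatten, and a dense 2-way head
#' (engaged / not engaged). Filter counts, kernel size and the 2-class
#' output are fixed by validity.
#'
#' @slot inputSize raster (height, width); both at least 32.
#' @slot filters per-block filter counts, fixed at (32, 32, 64).
#' @slot kernel kernel size, fixed at (3, 3).
#' @slot seed integer seed for weight initialization.
#' @export
setClass("ClassifierSpec",
  representation(inputSize = "integer", filters = "integer",
                 kernel = "integer", seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@inputSize) != 2L || any(object@inputSize < 32L))
      msgs <- c(msgs, "inputSize must be (H, W) with both >= 32")
    if (!identical(object@filters, c(32L, 32L, 64L)))
      msgs <- c(msgs, "filter counts are fixed at (32, 32, 64)")
    if (!identical(object@kernel, c(3L, 3L)))
      msgs <- c(msgs, "kernel size is fixed at (3, 3)")
    if (length(msgs)) msgs else TRUE
  })

#' Create a classifier specification
#'
#' @param inputSize raster (height, width), both at least 32.
#' @param seed integer seed for deterministic weight initialization.
#' @return a [ClassifierSpec-class].
#' @export
classifierSpec <- function(inputSize = c(64L, 64L), seed = 0L) {
  new("ClassifierSpec", inputSize = as.integer(inputSize),
      filters = c(32L, 32L, 64L), kernel = c(3L, 3L),
      seed = as.integer(seed))
}

setMethod("show", "ClassifierSpec", function(object) {
  d <- convDims(object@inputSize)
  cat("ClassifierSpec:", object@inputSize[1], "x", object@inputSize[2],
      "x 1 input\n")
  cat("  conv(32, 3x3) + ReLU + maxpool(2x2)\n")
  cat("  conv(32, 3x3) + ReLU + maxpool(2x2)\n")
  cat("  conv(64, 3x3) + ReLU + maxpool(2x2)\n")
  cat("  flatten (", d$flat, ") + dense -> 2 classes; seed ",
      object@seed, "\n", sep = "")
})

# Spatial sizes through the three conv/pool blocks (valid convolutions,
# 2x2 pooling flooring odd sizes).
convDims <- function(inputSize) {
  h <- inputSize[1]; w <- inputSize[2]
  out <- list()
  for (b in 1:3) {
    h <- h - 2L; w <- w - 2L           # 3x3 valid conv
    if (h < 2L || w < 2L) {
      stop("input smaller than the receptive-field minimum of the ",
           "three-block architecture", call. = FALSE)
    }
    h <- h %/% 2L; w <- w %/% 2L       # 2x2 max-pool
    out[[paste0("block", b)]] <- c(h, w)
  }
  out$flat <- h * w * 64L
  out
}

#' @title Engagement classifier (untrained or trained)
#' @description S4 container holding a [ClassifierSpec-class], the model
#' parameters, the training history (per-epoch loss and accuracy) and the
#' held-out validation accuracy.
#' @slot spec the [ClassifierSpec-class].
#' @slot params named list of weight matrices and bias vectors.
#' @slot trained logical flag.
#' @slot history data.frame with per-epoch `loss` and `accuracy`.
#' @slot valAccuracy held-out accuracy after training (NA before).
#' @slot trainSeed seed used for the training run (NA before).
#' @export
setClass("EngagementClassifier",
  representation(spec = "ClassifierSpec", params = "list",
                 trained = "logical", history = "data.frame",
                 valAccuracy = "numeric", trainSeed = "integer"))

setMethod("show", "EngagementClassifier", function(object) {
  show(object@spec)
  if (object@trained) {
    n <- nrow(object@history)
    cat(sprintf("  trained %d epoch(s); final loss %.4f, train acc %.3f",
                n, object@history$loss[n], object@history$accuracy[n]))
    if (!is.na(object@valAccuracy)) {
      cat(sprintf(", val acc %.3f", object@valAccuracy))
    }
    cat("\n")
  } else {
    cat("  untrained\n")
  }
})

# Raster window in canonical (inter-ocular) units; covers the whole
# normalized face template with margin.
rasterWindow <- function() {
  list(x = c(-1.6, 1.6), y = c(-1.35, 1.85))
}

#' Rasterize normalized landmarks to a classifier input image
#'
#' Each landmark is drawn as a small Gaussian blob on a zero background
#' inside a fixed canonical window, and the image is scaled so its maximum
#' is 1. Landmarks outside the window are clipped to its edge; the number
#' clipped is recorded in the `"nClipped"` attribute (with a warning when
#' `warn = TRUE`).
#'
#' @param lm a 68 x 2 normalized landmark matrix (from
#'   [normalizeLandmarks()]).
#' @param size raster (height, width); both at least 32.
#' @param sigma blob standard deviation in raster pixels.
#' @param warn warn when landmarks fall outside the canonical window.
#' @return an `size[1] x size[2]` matrix in `[0, 1]` with attribute
#'   `nClipped`.
#' @export
rasterizeLandmarks <- function(lm, size = c(64L, 64L), sigma = 1.2,
                               warn = TRUE) {
  assertLandmarks(lm)
  stopIfNot(length(size) == 2 && all(size >= 32),
            "raster size must be (H, W) with both >= 32")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  win <- rasterWindow()
  cx <- (lm[, 1] - win$x[1]) / diff(win$x) * (W - 1) + 1
  cy <- (lm[, 2] - win$y[1]) / diff(win$y) * (H - 1) + 1
  nClipped <- sum(cx < 1 | cx > W | cy < 1 | cy > H)
  if (nClipped > 0 && warn) {
    warning(nClipped, " landmark(s) outside the canonical window were ",
            "clipped", call. = FALSE)
  }
  cx <- pmin(pmax(cx, 1), W)
  cy <- pmin(pmax(cy, 1), H)
  img <- matrix(0, H, W)
  r <- ceiling(4 * sigma)
  for (k in 1:68) {
    r0 <- max(1L, floor(cy[k] - r)); r1 <- min(H, ceiling(cy[k] + r))
    c0 <- max(1L, floor(cx[k] - r)); c1 <- min(W, ceiling(cx[k] + r))
    rows <- r0:r1; cols <- c0:c1
    blob <- exp(-(outer((rows - cy[k])^2, (cols - cx[k])^2, "+")) /
                  (2 * sigma^2))
    img[rows, cols] <- img[rows, cols] + blob
  }
  img <- img / max(img)
  attr(img, "nClipped") <- nClipped
  img
}

#' Build an (untrained) engagement classifier
#'
#' Realizes the layer sequence of the specification and initializes the
#' weights (He-scaled Gaussians, biases zero) deterministically from the
#' spec seed: two builds from the same spec are bit-identical.
#'
#' @param spec a [ClassifierSpec-class].
#' @return an untrained [EngagementClassifier-class].
#' @export
buildClassifier <- function(spec = classifierSpec()) {
  stopIfNot(is(spec, "ClassifierSpec"), "spec must be a ClassifierSpec")
  validObject(spec)
  d <- convDims(spec@inputSize)
  he <- function(nout, nin) {
    matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
  }
  params <- withr::with_seed(spec@seed, list(
    W1 = he(32L, 9L),          b1 = numeric(32),
    W2 = he(32L, 32L * 9L),    b2 = numeric(32),
    W3 = he(64L, 32L * 9L),    b3 = numeric(64),
    W4 = he(2L, d$flat),       b4 = numeric(2)))
  new("EngagementClassifier", spec = spec, params = params,
      trained = FALSE, history = data.frame(), valAccuracy = NA_real_,
      trainSeed = NA_integer_)
}

#' Audit the realized layer sequence of a classifier
#'
#' Reads the layer structure back from the realized parameters (not from
#' the specification), so it reports what the model actually computes.
#'
#' @param model an [EngagementClassifier-class].
#' @return a data.frame with one row per layer: `layer`, `type`,
#'   `filters`, `kernel_h`, `kernel_w`, `pool_h`, `pool_w`, `units`.
#' @export
classifierLayers <- function(model) {
  stopIfNot(is(model, "EngagementClassifier"),
            "model must be an EngagementClassifier")
  p <- model@params
  kern <- function(W, cin) {
    k <- sqrt(ncol(W) / cin)
    c(k, k)
  }
  d <- convDims(model@spec@inputSize)
  rows <- list()
  cins <- c(1L, nrow(p$W1), nrow(p$W2))
  Ws <- list(p$W1, p$W2, p$W3)
  for (b in 1:3) {
    k <- kern(Ws[[b]], cins[b])
    rows[[length(rows) + 1]] <- data.frame(
      layer = paste0("conv", b), type = "conv2d",
      filters = nrow(Ws[[b]]), kernel_h = k[1], kernel_w = k[2],
      pool_h = NA_real_, pool_w = NA_real_, units = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      layer = paste0("relu", b), type = "relu", filters = NA_real_,
      kernel_h = NA_real_, kernel_w = NA_real_,
      pool_h = NA_real_, pool_w = NA_real_, units = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      layer = paste0("pool", b), type = "maxpool", filters = NA_real_,
      kernel_h = NA_real_, kernel_w = NA_real_,
      pool_h = 2, pool_w = 2, units = NA_real_)
  }
  rows[[length(rows) + 1]] <- data.frame(
    layer = "flatten", type = "flatten", filters = NA_real_,
    kernel_h = NA_real_, kernel_w = NA_real_,
    pool_h = NA_real_, pool_w = NA_real_, units = ncol(p$W4))
  rows[[length(rows) + 1]] <- data.frame(
    layer = "dense", type = "dense", filters = NA_real_,
    kernel_h = NA_real_, kernel_w = NA_real_,
    pool_h = NA_real_, pool_w = NA_real_, units = nrow(p$W4))
  do.call(rbind, rows)
}

coerceRasters <- function(x, inputSize) {
  if (is.list(x)) x <- simplify2array(x)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopIfNot(is.array(x) && length(dim(x)) == 3,
            "rasters must be an H x W x N array or a list of matrices")
  if (dim(x)[1] != inputSize[1] || dim(x)[2] != inputSize[2]) {
    stop(sprintf("raster size %d x %d does not match the classifier input %d x %d",
                 dim(x)[1], dim(x)[2], inputSize[1], inputSize[2]),
         call. = FALSE)
  }
  x
}

coerceLabels <- function(y) {
  if (is.factor(y)) y <- y == "engaged"
  if (is.logical(y)) y <- as.integer(y)
  stopIfNot(is.numeric(y) && all(y %in% c(0, 1)),
            "labels must be logical, 0/1, or a factor with level 'engaged'")
  as.integer(y)
}

#' Train the engagement classifier
#'
#' Minimizes the 2-class cross-entropy with minibatch Adam on a fixed-seed
#' shuffled 80/20 train/validation split. The run is fully deterministic
#' given the model (including its init seed), the data and `seed`:
#' identical inputs give identical final loss and weights.
#'
#' @param model an [EngagementClassifier-class] from [buildClassifier()].
#' @param x rasters: an `H x W x N` array or list of matrices.
#' @param y labels: logical, 0/1, or a factor with level `"engaged"`.
#' @param epochs number of training epochs (>= 1).
#' @param seed integer seed for the split, shuffling and batching.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param validationSplit held-out fraction in `[0, 0.5]`.
#' @return the trained [EngagementClassifier-class] with filled history.
#' @export
trainClassifier <- function(model, x, y, epochs = 5L, seed = 1L,
                            batchSize = 32L, lr = 1e-3,
                            validationSplit = 0.2) {
  stopIfNot(is(model, "EngagementClassifier"),
            "model must be an EngagementClassifier")
  stopIfNot(is.numeric(epochs) && epochs >= 1, "epochs must be >= 1")
  x <- coerceRasters(x, model@spec@inputSize)
  y <- coerceLabels(y)
  n <- dim(x)[3]
  stopIfNot(length(y) == n, "labels must match the number of rasters")
  if (length(unique(y)) < 2) {
    stop("training requires both classes in the dataset", call. = FALSE)
  }
  stopIfNot(is.numeric(validationSplit) && validationSplit >= 0 &&
              validationSplit <= 0.5, "validationSplit must be in [0, 0.5]")

  fit <- withr::with_seed(seed, {
    idx <- sample.int(n)
    nVal <- floor(validationSplit * n)
    valIdx <- idx[seq_len(nVal)]
    trIdx <- idx[setdiff(seq_len(n), seq_len(nVal))]
    order <- vapply(seq_len(epochs),
                    function(e) sample.int(length(trIdx)),
                    integer(length(trIdx)))
    res <- cnn_train(model@params, x[, , trIdx, drop = FALSE], y[trIdx],
                     matrix(order, ncol = epochs), as.integer(batchSize),
                     lr, 0.9, 0.999, 1e-8)
    valAcc <- NA_real_
    if (nVal > 0) {
      logits <- cnn_forward_logits(res$params,
                                   x[, , valIdx, drop = FALSE])
      pred <- as.integer(logits[, 2] > logits[, 1])
      valAcc <- mean(pred == y[valIdx])
    }
    list(res = res, valAcc = valAcc)
  })
  model@params <- fit$res$params
  model@trained <- TRUE
  model@history <- data.frame(epoch = seq_len(epochs),
                              loss = as.numeric(fit$res$loss),
                              accuracy = as.numeric(fit$res$accuracy))
  model@valAccuracy <- fit$valAcc
  model@trainSeed <- as.integer(seed)
  model
}

#' Predict engagement labels for landmark rasters
#'
#' Arg-max over the 2-way head; ties break toward `not_engaged`.
#'
#' @param model a trained [EngagementClassifier-class].
#' @param x rasters as in [trainClassifier()].
#' @return a factor with levels `c("not_engaged", "engaged")`.
#' @export
predictEngagement <- function(model, x) {
  stopIfNot(is(model, "EngagementClassifier"),
            "model must be an EngagementClassifier")
  x <- coerceRasters(x, model@spec@inputSize)
  logits <- cnn_forward_logits(model@params, x)
  factor(ifelse(logits[, 2] > logits[, 1], "engaged", "not_engaged"),
         levels = c("not_engaged", "engaged"))
}

#' Classify every frame of a session stream
#'
#' Chains face detection, landmark extraction, normalization and
#' rasterization, then classifies all face-bearing frames in one batch.
#' Output is order-preserving with exactly one record per input frame;
#' frames where no face is detected (or landmark extraction fails) carry
#' `face_present = FALSE` and an `NA` label, to be resolved by the no-face
#' policy of [computeTaskEPM()].
#'
#' @param model a trained [EngagementClassifier-class].
#' @param frames a list of frames from [extractFrames()], or a list of
#'   grayscale matrices.
#' @param backend detector/extractor backend (see [detectFace()]).
#' @return a data.frame with columns `frame_index`, `face_present`,
#'   `engaged` (logical, `NA` when no face) and `n_clipped`.
#' @export
classifyFrames <- function(model, frames, backend = "synthetic") {
  stopIfNot(is(model, "EngagementClassifier") && model@trained,
            "model must be a trained EngagementClassifier")
  stopIfNot(is.list(frames) && length(frames) >= 1,
            "frames must be a non-empty list")
  n <- length(frames)
  facePresent <- logical(n)
  nClipped <- integer(n)
  rasters <- vector("list", n)
  for (i in seq_len(n)) {
    px <- framePixels(frames[[i]])
    box <- detectFace(px, backend = backend)
    if (is.null(box)) next
    lm <- tryCatch(extractLandmarks(px, box, backend = backend),
                   error = function(e) NULL)
    if (is.null(lm)) next
    ras <- rasterizeLandmarks(normalizeLandmarks(lm),
                              size = model@spec@inputSize, warn = FALSE)
    facePresent[i] <- TRUE
    nClipped[i] <- attr(ras, "nClipped")
    rasters[[i]] <- ras
  }
  engaged <- rep(NA, n)
  if (any(facePresent)) {
    pred <- predictEngagement(model,
                              simplify2array(rasters[facePresent]))
    engaged[facePresent] <- pred == "engaged"
  }
  idx <- vapply(seq_len(n), function(i) {
    f <- frames[[i]]
    if (is.list(f) && !is.null(f$index)) as.integer(f$index) else i - 1L
  }, integer(1))
  data.frame(frame_index = idx, face_present = facePresent,
             engaged = as.logical(engaged), n_clipped = nClipped)
}

#' Generate a labelled training set for the classifier
#'
#' Samples valence/arousal states (engaged states uniform in the positive
#' quadrant, disengaged uniform over the other three quadrants), renders
#' each state with the synthetic face renderer and runs the full face
#' pipeline (detection, landmark extraction, normalization,
#' rasterization), so the training distribution matches what
#' [classifyFrames()] sees at analysis time. `method = "landmarks"` skips
#' rendering and rasterizes the (jittered) landmark template directly,
#' which is faster but bypasses the imaging pipeline.
#'
#' @param n number of examples.
#' @param noisePx landmark noise in pixels (as in [sessionConfig()]).
#' @param seed integer seed.
#' @param spec the [ClassifierSpec-class] whose input size to target.
#' @param method `"render"` (full pipeline) or `"landmarks"`.
#' @param imageSize rendered frame size for `method = "render"`.
#' @param engagedProb marginal probability of the engaged class.
#' @return `list(x = H x W x n array, y = factor labels, valence, arousal)`.
#' @export
engagementTrainingSet <- function(n, noisePx = 0, seed = 1L,
                                  spec = classifierSpec(),
                                  method = c("render", "landmarks"),
                                  imageSize = c(96L, 96L),
                                  engagedProb = 0.5) {
  method <- match.arg(method)
  stopIfNot(is.numeric(n) && n >= 1, "n must be >= 1")
  validObject(spec)
  cfg <- sessionConfig(landmarkNoisePx = noisePx, noFaceProb = 0,
                       imageSize = imageSize)
  s <- renderScale(imageSize)
  centre <- c((imageSize[2] - 1) / 2, (imageSize[1] - 1) / 2)
  withr::with_seed(seed, {
    engaged <- stats::runif(n) < engagedProb
    v <- stats::runif(n); a <- stats::runif(n)
    quad <- sample.int(3L, n, replace = TRUE)
    flipV <- !engaged & quad %in% c(1L, 2L)
    flipA <- !engaged & quad %in% c(2L, 3L)
    v[flipV] <- -v[flipV]; a[flipA] <- -a[flipA]

    x <- array(0, c(spec@inputSize[1], spec@inputSize[2], n))
    ok <- logical(n)
    for (i in seq_len(n)) {
      lm <- if (method == "render") {
        fr <- renderFaceFrameImpl(v[i], a[i], cfg)
        box <- detectFace(fr$image)
        if (is.null(box)) next
        tryCatch(extractLandmarks(fr$image, box), error = function(e) NULL)
      } else {
        g <- perturbGeometry(faceGeometry(v[i], a[i]), noisePx / s)
        landmarksFromGeometry(transformGeometry(g, s, centre)) +
          matrix(stats::rnorm(136, 0, noisePx + 0.5), 68, 2)
      }
      if (is.null(lm)) next
      x[, , i] <- rasterizeLandmarks(normalizeLandmarks(lm),
                                     size = spec@inputSize, warn = FALSE)
      ok[i] <- TRUE
    }
    list(x = x[, , ok, drop = FALSE],
         y = factor(ifelse(engaged[ok], "engaged", "not_engaged"),
                    levels = c("not_engaged", "engaged")),
         valence = v[ok], arousal = a[ok])
  })
}

#' Save / load a classifier checkpoint
#'
#' A single-file checkpoint holding the specification, the weights, the
#' training history and the seeds.
#'
#' @param model an [EngagementClassifier-class].
#' @param path checkpoint file path.
#' @return `saveClassifier` returns `path` invisibly; `loadClassifier`
#'   returns the restored [EngagementClassifier-class].
#' @export
saveClassifier <- function(model, path) {
  stopIfNot(is(model, "EngagementClassifier"),
            "model must be an EngagementClassifier")
  saveRDS(list(inputSize = model@spec@inputSize, specSeed = model@spec@seed,
               params = model@params, trained = model@trained,
               history = model@history, valAccuracy = model@valAccuracy,
               trainSeed = model@trainSeed,
               version = as.character(packageVersion("engagekit"))),
          path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  obj <- readRDS(path)
  new("EngagementClassifier",
      spec = classifierSpec(obj$inputSize, obj$specSeed),
      params = obj$params, trained = obj$trained, history = obj$history,
      valAccuracy = obj$valAccuracy, trainSeed = obj$trainSeed)
}
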