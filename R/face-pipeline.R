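#' @title Detected face bounding box
#' @description S4 record for one detected face: top-left corner `(x, y)`
#' in 0-based pixels, width/height, and a detection score in `[0, 1]`.
#' @slot x,y top-left corner (0-based pixels).
#' @slot w,h box width and height in pixels (positive).
#' @slot score detection score in `[0, 1]`.
#' @export
setClass("FaceBox",
  representation(x = "numeric", y = "numeric", w = "numeric", h = "numeric",
                 score = "numeric"),
  validity = function(object) {
    if (object@w <= 0 || object@h <= 0) return("w and h must be positive")
    if (!isProb(object@score)) return("score must be in [0, 1]")
    TRUE
  })

setMethod("show", "FaceBox", function(object) {
  cat(sprintf("FaceBox: (%g, %g) %g x %g px, score %.3f\n",
              object@x, object@y, object@w, object@h, object@score))
})

framePixels <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.list(frame) && is.matrix(frame$pixels)) return(frame$pixels)
  stop("frame must be a grayscale matrix or a frame record with $pixels",
       call. = FALSE)
}

#' Detect the face in a frame
#'
#' The built-in `"synthetic"` backend locates the rendered face as the
#' largest bright connected component (intensity thresholding followed by
#' connected-component labelling); when several faces are present the
#' larger-area component wins. Returns `NULL` when no face is found (e.g.
#' a uniform blank frame). A custom detector can be plugged in by passing
#' a function `frame_matrix -> list(x, y, w, h, score)` (the pretrained
#' contract).
#'
#' @param frame a grayscale matrix in `[0, 1]` or a frame record from
#'   [extractFrames()].
#' @param backend `"synthetic"` or a detector function.
#' @param threshold intensity threshold separating face from background
#'   for the synthetic backend.
#' @return a [FaceBox-class] or `NULL`.
#' @export
detectFace <- function(frame, backend = "synthetic", threshold = 0.4) {
  px <- framePixels(frame)
  if (is.function(backend)) {
    box <- backend(px)
    if (is.null(box)) return(NULL)
    return(new("FaceBox", x = box$x, y = box$y, w = box$w, h = box$h,
               score = if (is.null(box$score)) 1 else box$score))
  }
  if (!identical(backend, "synthetic")) {
    stop("unknown detector backend: ", backend,
         " (use \"synthetic\" or supply a detector function)",
         call. = FALSE)
  }
  mask <- px > threshold
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  idx <- which(lab == best, arr.ind = TRUE)
  y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1]) - 1L
  x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2]) - 1L
  w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
  new("FaceBox", x = x0, y = y0, w = w, h = h,
      score = min(1, sizes[best] / (w * h)))
}

# Centroids and bounding boxes (0-based pixels) of dark feature components
# within the face box.
featureComponents <- function(px, box, gp) {
  H <- nrow(px); W <- ncol(px)
  xg <- matrix(rep(0:(W - 1), each = H), nrow = H)
  yg <- matrix(rep(0:(H - 1), times = W), nrow = H)
  inEllipse <- ((xg - gp$skinC[1]) / gp$skinA)^2 +
               ((yg - gp$skinC[2]) / gp$skinB)^2 <= 1.05
  mask <- px < 0.5 & inEllipse &
    xg >= box@x & xg <= box@x + box@w - 1 &
    yg >= box@y & yg <= box@y + box@h - 1
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  ids <- sort(unique(lab[lab > 0]))
  comps <- lapply(ids, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
    list(cx = mean(xs), cy = mean(ys),
         x0 = min(xs), x1 = max(xs), y0 = min(ys), y1 = max(ys),
         xs = xs, ys = ys, area = length(xs))
  })
  comps[order(vapply(comps, `[[`, 0, "area"), decreasing = TRUE)]
}

# Greedy nearest-centroid assignment of components to expected feature
# positions; NULL where nothing lies within `maxDist`.
assignComponents <- function(comps, targets, maxDist) {
  used <- rep(FALSE, length(comps))
  out <- vector("list", length(targets))
  names(out) <- names(targets)
  for (nm in names(targets)) {
    best <- NA_integer_; bestD <- maxDist
    for (i in seq_along(comps)) {
      if (used[i]) next
      d <- sqrt((comps[[i]]$cx - targets[[nm]][1])^2 +
                (comps[[i]]$cy - targets[[nm]][2])^2)
      if (d < bestD) { bestD <- d; best <- i }
    }
    if (!is.na(best)) { out[[nm]] <- comps[[best]]; used[best] <- TRUE }
  }
  out
}

#' Extract the 68 facial landmarks from a detected face
#'
#' The `"synthetic"` backend fits the schematic face template into the
#' detected box (scale and centre from the box), then refines the
#' affect-bearing features from the image itself: eye centres/openings
#' from the dark eye components and mouth corners/opening from the mouth
#' component, so valence and arousal remain measurable downstream. Jaw,
#' brow and nose points come from the fitted template. A custom extractor
#' can be plugged in as a function `(frame_matrix, box) -> 68 x 2 matrix`.
#'
#' @param frame a grayscale matrix or frame record.
#' @param box the [FaceBox-class] from [detectFace()] on the same frame.
#' @param backend `"synthetic"` or an extractor function.
#' @return a 68 x 2 matrix of (x, y) 0-based pixel coordinates in
#'   iBUG-300W order.
#' @export
extractLandmarks <- function(frame, box, backend = "synthetic") {
  px <- framePixels(frame)
  stopIfNot(is(box, "FaceBox"), "box must be a FaceBox from detectFace()")
  validObject(box)
  H <- nrow(px); W <- ncol(px)
  if (box@x < 0 || box@y < 0 || box@x + box@w > W || box@y + box@h > H) {
    stop("box lies outside the frame", call. = FALSE)
  }
  if (is.function(backend)) {
    return(assertLandmarks(backend(px, box), "extracted landmarks"))
  }
  if (!identical(backend, "synthetic")) {
    stop("unknown landmark backend: ", backend, call. = FALSE)
  }

  # scale and centre implied by the box (the skin ellipse spans 2.24 x 2.70
  # canonical units, and a box spanning pixel centres adds one pixel)
  sEst <- mean(c((box@w - 1) / 2.24, (box@h - 1) / 2.70))
  centre <- c(box@x + (box@w - 1) / 2, box@y + (box@h - 1) / 2)
  gp <- transformGeometry(faceGeometry(0, 0), sEst, centre)

  comps <- featureComponents(px, box, gp)
  if (is.null(comps)) {
    stop("landmark extraction failed: no facial features found in box",
         call. = FALSE)
  }
  hit <- assignComponents(
    comps,
    list(eyeL = gp$eyeL, eyeR = gp$eyeR, mouth = gp$mouthC,
         browL = gp$browL, browR = gp$browR),
    maxDist = 0.45 * sEst)

  if (!is.null(hit$eyeL) && !is.null(hit$eyeR)) {
    gp$eyeL <- c(hit$eyeL$cx, hit$eyeL$cy)
    gp$eyeR <- c(hit$eyeR$cx, hit$eyeR$cy)
    gp$ew <- mean(c(hit$eyeL$x1 - hit$eyeL$x0,
                    hit$eyeR$x1 - hit$eyeR$x0)) / 2
    gp$eh <- max(mean(c(hit$eyeL$y1 - hit$eyeL$y0,
                        hit$eyeR$y1 - hit$eyeR$y0)) / 2, 0.5)
  }
  for (side in c("browL", "browR")) {
    if (!is.null(hit[[side]])) {
      gp[[side]] <- c(hit[[side]]$cx, hit[[side]]$cy)
    }
  }
  if (!is.null(hit$mouth)) {
    m <- hit$mouth
    mx <- (m$x0 + m$x1) / 2
    gp$mw <- max((m$x1 - m$x0) / 2, 1)
    cornerY <- mean(c(m$ys[m$xs == m$x0], m$ys[m$xs == m$x1]))
    centreCol <- m$xs[which.min(abs(m$xs - mx))]
    ysC <- m$ys[m$xs == centreCol]
    yTop <- min(ysC); yBot <- max(ysC)
    myEst <- (yTop + yBot) / 2
    gp$mouthC <- c(mx, myEst)
    gp$o <- max(yBot - yTop, 0.5)
    gp$cOff <- cornerY - myEst
    gp$oi <- max(gp$o - 0.08 * sEst, 0.01 * sEst)
  }
  assertLandmarks(landmarksFromGeometry(gp), "extracted landmarks")
}

#' Normalize landmarks to the canonical frame
#'
#' Translates the landmark set so the inter-ocular midpoint (midpoint of
#' the two eye centroids) is the origin and rescales so the inter-ocular
#' distance is exactly 1. This removes translation and scale, making the
#' downstream classifier invariant to face position and size. Idempotent
#' up to numerical tolerance.
#'
#' @param lm a 68 x 2 landmark matrix.
#' @return a 68 x 2 matrix in canonical units.
#' @export
normalizeLandmarks <- function(lm) {
  assertLandmarks(lm)
  reg <- lmRegions()
  eyeL <- colMeans(lm[reg$eyeLeft, , drop = FALSE])
  eyeR <- colMeans(lm[reg$eyeRight, , drop = FALSE])
  d <- sqrt(sum((eyeR - eyeL)^2))
  if (d < 1e-9) {
    stop("degenerate geometry: coincident eye centroids", call. = FALSE)
  }
  mid <- (eyeL + eyeR) / 2
  sweep(lm, 2, mid, "-") / d
}
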