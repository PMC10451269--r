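# Frame input: directories of still frames (the tested path) or, in
# principle, video files. No video codec backend ships with the package;
# video sources raise an informative error telling the user to pre-extract
# frames (e.g. `ffmpeg -i session.mp4 frames/f_%05d.png`). Directory
# sources are fully supported and are pixel-exact round trips of frames
# written by simulateSession().

imageExts <- c("png", "jpg", "jpeg")
videoExts <- c("mp4", "avi", "mov", "mkv")

listFrameFiles <- function(source) {
  files <- list.files(source, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% imageExts]
  sort(files, method = "radix")   # lexicographic, locale-independent
}

readFrameImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("reading JPEG frames requires the 'jpeg' package; PNG frames ",
           "are supported natively: ", path, call. = FALSE)
    }
    jpeg::readJPEG(path)
  }
  toGrayscale(px)
}

# ITU-R BT.601 luma conversion for colour frames.
toGrayscale <- function(px) {
  if (length(dim(px)) == 2) return(px)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) {
      return(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
    }
    return(px[, , 1])
  }
  stop("unsupported image array shape", call. = FALSE)
}

# Internal: build Frame records from explicit file paths.
framesFromFiles <- function(files, nativeFps) {
  lapply(seq_along(files), function(i) {
    list(index = i - 1L,
         timestamp = (i - 1L) / nativeFps,
         path = files[i],
         pixels = readFrameImage(files[i]))
  })
}

#' Extract an ordered frame stream from a session recording
#'
#' Directory sources are read in lexicographic filename order (the order in
#' which [simulateSession()] writes them). When `targetFps` is below the
#' native rate, frames are subsampled by nearest-timestamp selection: for
#' each target time `k / targetFps` the frame with the closest native
#' timestamp is kept. Frame indices and timestamps always refer to the
#' native stream.
#'
#' @param source a directory of PNG/JPEG frames (a video file raises an
#'   error directing the user to pre-extract frames).
#' @param targetFps `"native"` or a positive frame rate to subsample to.
#' @param nativeFps the native frame rate used to assign timestamps to
#'   directory sources (default 10).
#' @return a list of frames; each frame is
#'   `list(index, timestamp, path, pixels)` with `pixels` a grayscale
#'   matrix in `[0, 1]`.
#' @examples
#' \donttest{
#' out <- simulateSession(sessionConfig(taskDurationsS = 2, seed = 1),
#'                        tempfile())
#' frames <- extractFrames(out$framesDir)
#' length(frames)
#' }
#' @export
extractFrames <- function(source, targetFps = "native", nativeFps = 10) {
  stopIfNot(is.character(source) && length(source) == 1,
            "source must be a single path")
  if (!file.exists(source)) {
    stop("source does not exist: ", source, call. = FALSE)
  }
  if (!dir.exists(source)) {
    if (tolower(tools::file_ext(source)) %in% videoExts) {
      stop("no video codec backend is available; extract frames to a ",
           "directory first (e.g. with ffmpeg) and pass that directory: ",
           source, call. = FALSE)
    }
    stop("source must be a directory of frames: ", source, call. = FALSE)
  }
  files <- listFrameFiles(source)
  if (length(files) == 0) {
    stop("no decodable frames found in: ", source, call. = FALSE)
  }
  stopIfNot(is.numeric(nativeFps) && nativeFps > 0, "nativeFps must be > 0")
  keep <- seq_along(files)
  if (!identical(targetFps, "native")) {
    stopIfNot(is.numeric(targetFps) && length(targetFps) == 1 &&
                is.finite(targetFps) && targetFps > 0,
              "targetFps must be \"native\" or a positive number")
    if (targetFps < nativeFps) {
      maxT <- (length(files) - 1) / nativeFps
      tk <- seq(0, by = 1 / targetFps,
                length.out = floor(maxT * targetFps) + 1)
      keep <- unique(as.integer(pmin(pmax(round(tk * nativeFps) + 1, 1),
                                     length(files))))
    }
  }
  frames <- framesFromFiles(files[keep], nativeFps)
  for (i in seq_along(frames)) {
    frames[[i]]$index <- as.integer(keep[i] - 1L)
    frames[[i]]$timestamp <- (keep[i] - 1) / nativeFps
  }
  frames
}

#' Count the frames of a session recording
#'
#' Equals `length(extractFrames(source, "native"))` without decoding any
#' pixels. An empty directory counts 0 with a warning.
#'
#' @inheritParams extractFrames
#' @return a non-negative integer.
#' @export
countFrames <- function(source) {
  stopIfNot(is.character(source) && length(source) == 1,
            "source must be a single path")
  if (!file.exists(source)) {
    stop("source does not exist: ", source, call. = FALSE)
  }
  if (!dir.exists(source)) {
    stop("source must be a directory of frames: ", source, call. = FALSE)
  }
  n <- length(listFrameFiles(source))
  if (n == 0) warning("no frames found in: ", source, call. = FALSE)
  n
}
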