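## Kymograph construction from calibrated image stacks. Coordinates are
## 0-based with pixel centres at integer positions; image frames are matrices
## indexed [y + 1, x + 1]. Kymograph rows are time (frames), columns are
## positions along the sampled line.

#' ImageStack: a calibrated multi-frame image stack
#'
#' @slot frames Numeric array `height x width x nFrames` in acquisition
#'   order.
#' @slot pixelSize Pixel size (um/px).
#' @slot frameInterval Frame interval (s).
#' @slot channel Channel name.
#'
#' @seealso [readStack()], [buildKymograph()]
#' @export
setClass("ImageStack",
  representation(frames = "array", pixelSize = "numeric",
                 frameInterval = "numeric", channel = "character"),
  prototype(channel = "unnamed")
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "'frames' must be a height x width x nFrames array")
  if (object@pixelSize <= 0 || object@frameInterval <= 0)
    msg <- c(msg, "'pixelSize' and 'frameInterval' must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn ImageStack Number of frames.
#' @param object,x An `ImageStack`.
#' @export
nFrames <- function(x) dim(x@frames)[3]

#' @describeIn ImageStack Extract one frame as a matrix.
#' @param i Frame index.
#' @export
getFrame <- function(x, i) x@frames[, , i]

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack [%s]: %d frames of %d x %d px\n", object@channel,
              d[3], d[1], d[2]))
  cat(sprintf("  calibration: %.4g um/px, %.4g s/frame\n",
              object@pixelSize, object@frameInterval))
})

#' Read a calibrated TIFF stack
#'
#' Reads a multi-page TIFF and attaches pixel-size and frame-interval
#' calibration. Interleaved multi-channel stacks are de-interleaved by
#' giving the number of channels and the (1-based) channel to keep.
#'
#' @param path Path to a multi-page TIFF file.
#' @param pixelSize Pixel size (um/px, > 0).
#' @param frameInterval Frame interval (s, > 0).
#' @param nChannels Number of interleaved channels in the file.
#' @param channel Which interleaved channel to keep (1-based).
#' @param channelName Name to attach to the returned stack.
#' @return An [ImageStack-class].
#' @export
readStack <- function(path, pixelSize, frameInterval, nChannels = 1,
                      channel = 1, channelName = "unnamed") {
  if (!file.exists(path))
    stop("image stack not found: ", path)
  if (pixelSize <= 0 || frameInterval <= 0)
    stop("calibration must be positive")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in ", path)
  if (channel > nChannels) stop("'channel' exceeds 'nChannels'")
  sel <- seq(channel, length(pages), by = nChannels)
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(sel)))
  for (i in seq_along(sel)) {
    p <- pages[[sel[i]]]
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse RGB-style pages
    arr[, , i] <- p
  }
  new("ImageStack", frames = arr, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      channel = as.character(channelName))
}

#' Write an image stack (or kymograph) as a 16-bit multi-page TIFF
#'
#' Values are clipped to `[0, 65535]` and stored as 16-bit integers.
#'
#' @param x An [ImageStack-class], a [Kymograph-class], or a list of
#'   matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeStackTiff <- function(x, path) {
  frames <- if (is(x, "ImageStack")) {
    lapply(seq_len(nFrames(x)), function(i) getFrame(x, i))
  } else if (is(x, "Kymograph")) {
    list(kymoData(x))
  } else x
  scaled <- lapply(frames, function(f) {
    f <- round(pmin(pmax(f, 0), 65535))
    f / 65535
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

## bilinear interpolation at 0-based coords; out-of-bounds -> NA
bilinearSample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1 & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), W - 2); y0 <- pmin(floor(ys), H - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- xs - x0; fy <- ys - y0
  i00 <- y0 + 1 + x0 * H          # column-major linear index
  v <- (1 - fx) * (1 - fy) * img[i00] +
       fx       * (1 - fy) * img[i00 + H] +
       (1 - fx) * fy       * img[i00 + 1] +
       fx       * fy       * img[i00 + H + 1]
  out[ok] <- v
  out
}

## sample coordinates along a polyline at ~unit spacing, plus the unit
## normal at each sample; returns list(x, y, nx, ny), all length nSamples
polylineSamples <- function(vertices) {
  d <- diff(vertices)
  segLen <- sqrt(rowSums(d^2))
  if (all(segLen == 0)) stop("degenerate polyline: zero length")
  cum <- c(0, cumsum(segLen))
  Ltot <- cum[length(cum)]
  nCols <- as.integer(round(Ltot)) + 1L
  s <- seq(0, Ltot, length.out = max(nCols, 2L))
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
              length(segLen))
  frac <- (s - cum[seg]) / segLen[seg]
  x <- vertices[seg, 1] + frac * d[seg, 1]
  y <- vertices[seg, 2] + frac * d[seg, 2]
  ux <- d[seg, 1] / segLen[seg]
  uy <- d[seg, 2] / segLen[seg]
  list(x = x, y = y, nx = -uy, ny = ux, n = length(s))
}

#' Build a kymograph along a line ROI
#'
#' For each frame, the image intensity is sampled along the polyline at unit
#' spacing (bilinear interpolation) and averaged across the ROI's `width`
#' perpendicular 1-pixel offsets (mean projection; offsets `-2..+2` for the
#' conventional 5-pixel-wide line). Samples that fall outside the image are
#' dropped from the mean rather than zero-padded. The result has one row per
#' frame and `round(arc length) + 1` columns.
#'
#' @param stack An [ImageStack-class].
#' @param roi A [LineRoi-class] whose vertices lie inside the image.
#' @return A [Kymograph-class].
#' @examples
#' img <- array(1, c(16, 64, 4))
#' st <- new("ImageStack", frames = img, pixelSize = 0.1, frameInterval = 2)
#' k <- buildKymograph(st, LineRoi(rbind(c(2, 8), c(60, 8))))
#' dim(kymoData(k))  # 4 x 59
#' @export
buildKymograph <- function(stack, roi) {
  stopifnot(is(stack, "ImageStack"), is(roi, "LineRoi"))
  validObject(roi)
  H <- dim(stack@frames)[1]; W <- dim(stack@frames)[2]
  v <- roi@vertices
  if (any(v[, 1] < 0 | v[, 1] > W - 1 | v[, 2] < 0 | v[, 2] > H - 1))
    stop("ROI vertices fall outside the image bounds")

  ps <- polylineSamples(v)
  half <- (roi@width - 1) / 2
  offsets <- seq(-half, half, by = 1)
  nS <- ps$n
  ## all sample coordinates: nS samples x nOffsets
  X <- outer(ps$x, rep(1, length(offsets))) + outer(ps$nx, offsets)
  Y <- outer(ps$y, rep(1, length(offsets))) + outer(ps$ny, offsets)

  nT <- dim(stack@frames)[3]
  data <- matrix(0, nrow = nT, ncol = nS)
  for (f in seq_len(nT)) {
    vals <- bilinearSample(stack@frames[, , f], as.vector(X), as.vector(Y))
    vals <- matrix(vals, nrow = nS)
    data[f, ] <- rowMeans(vals, na.rm = TRUE)
  }
  if (anyNA(data))
    stop("ROI samples fall entirely outside the image for some positions")
  Kymograph(data, stack@pixelSize, stack@frameInterval,
            sourceLine = v, channel = stack@channel)
}

#' Extract per-frame intensity time courses from a kymograph
#'
#' Averages, for every frame (row), the kymograph intensity over the columns
#' crossed by a measurement line and by a nearby background line (the
#' 1-pixel-wide-line convention for intensity-versus-time profiles). Both
#' lines are given in kymograph coordinates (x = position column, y = frame
#' row, 0-based); only their column extent is used, so a vertical line along
#' the time axis reads out a single column.
#'
#' @param kymo A [Kymograph-class].
#' @param line A [LineRoi-class] over the signal region.
#' @param backgroundLine A [LineRoi-class] over a background region.
#' @return data.frame with columns `t_s`, `intensity`, `background`.
#' @export
extractIntensityTimecourse <- function(kymo, line, backgroundLine) {
  stopifnot(is(kymo, "Kymograph"))
  colsOf <- function(roi) {
    v <- roi@vertices
    ps <- polylineSamples(v)
    cols <- unique(pmin(pmax(round(ps$x), 0), ncol(kymo@data) - 1)) + 1L
    if (!length(cols)) stop("line of zero length")
    cols
  }
  cSig <- colsOf(line)
  cBg <- colsOf(backgroundLine)
  nT <- nrow(kymo@data)
  data.frame(
    t_s = (seq_len(nT) - 1) * kymo@frameInterval,
    intensity = rowMeans(kymo@data[, cSig, drop = FALSE]),
    background = rowMeans(kymo@data[, cBg, drop = FALSE]))
}

#' Write a kymograph as CSV
#'
#' One row per frame; the first column is time in seconds, remaining columns
#' are positions (`pos_<k>_px`).
#'
#' @param kymo A [Kymograph-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeKymographCsv <- function(kymo, path) {
  d <- as.data.frame(kymo@data)
  names(d) <- sprintf("pos_%d_px", seq_len(ncol(d)) - 1L)
  d <- cbind(t_s = (seq_len(nrow(d)) - 1) * kymo@frameInterval, d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
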