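#' @import methods
NULL

## Central S4 containers. Derived tabular records (phase segments, particle
## tracks, event records, dwell tables) are plain data.frames with documented
## column contracts; see the respective constructors below.

#' FilamentTrajectory: a microtubule tip position versus time
#'
#' The raw object behind all dynamic-instability statistics: the position of
#' a filament tip along its axis (micrometres) at strictly increasing time
#' points (seconds), together with the position of the stable seed end.
#'
#' @slot times Numeric vector of time points in seconds, strictly increasing.
#' @slot tipPositions Numeric vector of tip positions in micrometres, same
#'   length as `times`. Positions are measured from the seed base, so the
#'   stabilized seed occupies `[0, seedReference]`.
#' @slot seedReference Length of the stabilized seed segment in micrometres;
#'   the dynamic lattice lives above this position.
#'
#' @seealso [simulateDynamicInstability()], [segmentAuto()]
#' @export
setClass("FilamentTrajectory",
  representation(
    times = "numeric",
    tipPositions = "numeric",
    seedReference = "numeric"
  ),
  prototype(seedReference = 0)
)

setValidity("FilamentTrajectory", function(object) {
  msg <- character()
  if (length(object@times) != length(object@tipPositions))
    msg <- c(msg, "'times' and 'tipPositions' must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (anyNA(object@times) || anyNA(object@tipPositions))
    msg <- c(msg, "trajectory coordinates must be finite")
  if (length(object@seedReference) != 1 || !is.finite(object@seedReference) ||
      object@seedReference < 0)
    msg <- c(msg, "'seedReference' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a FilamentTrajectory
#'
#' @param times Time points in seconds, strictly increasing.
#' @param tipPositions Tip positions in micrometres (from the seed base).
#' @param seedReference Seed length in micrometres (default 0).
#' @return A [FilamentTrajectory-class] object.
#' @examples
#' tr <- FilamentTrajectory(times = c(0, 60, 120),
#'                          tipPositions = c(0, 2, 4))
#' trajectoryTimes(tr)
#' @export
FilamentTrajectory <- function(times, tipPositions, seedReference = 0) {
  new("FilamentTrajectory",
      times = as.numeric(times),
      tipPositions = as.numeric(tipPositions),
      seedReference = as.numeric(seedReference))
}

#' @describeIn FilamentTrajectory Time points (s).
#' @param object,x A `FilamentTrajectory`.
#' @export
trajectoryTimes <- function(x) x@times

#' @describeIn FilamentTrajectory Tip positions (um).
#' @export
tipPositions <- function(x) x@tipPositions

#' @describeIn FilamentTrajectory Seed length (um).
#' @export
seedReference <- function(x) x@seedReference

setMethod("show", "FilamentTrajectory", function(object) {
  n <- length(object@times)
  cat("FilamentTrajectory with", n, "time points\n")
  if (n) {
    cat(sprintf("  time range: %.3g - %.3g s\n",
                object@times[1], object@times[n]))
    cat(sprintf("  tip position range: %.3g - %.3g um\n",
                min(object@tipPositions), max(object@tipPositions)))
  }
  cat(sprintf("  seed length: %.3g um\n", object@seedReference))
})

#' Kymograph: a time-by-position intensity matrix with calibration
#'
#' Rows are time frames, columns are positions along the sampled line.
#'
#' @slot data Numeric matrix of intensities; rows = frames, columns =
#'   position samples (one pixel apart along the line).
#' @slot pixelSize Pixel size in micrometres per pixel.
#' @slot frameInterval Frame interval in seconds.
#' @slot sourceLine Numeric matrix of the polyline vertices (x, y columns, in
#'   image pixel coordinates) the kymograph was built along; may have zero
#'   rows for rendered kymographs.
#' @slot channel Channel name.
#'
#' @seealso [buildKymograph()], [renderKymograph()]
#' @export
setClass("Kymograph",
  representation(
    data = "matrix",
    pixelSize = "numeric",
    frameInterval = "numeric",
    sourceLine = "matrix",
    channel = "character"
  ),
  prototype(sourceLine = matrix(numeric(), ncol = 2), channel = "unnamed")
)

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!is.numeric(object@data) || anyNA(object@data) ||
      any(!is.finite(object@data)))
    msg <- c(msg, "'data' must be a finite numeric matrix")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    msg <- c(msg, "'frameInterval' must be a single positive number")
  if (ncol(object@sourceLine) != 2)
    msg <- c(msg, "'sourceLine' must have two columns (x, y)")
  if (length(msg)) msg else TRUE
})

#' Construct a Kymograph
#'
#' @param data Intensity matrix (rows = frames, columns = positions).
#' @param pixelSize Pixel size (um/px).
#' @param frameInterval Frame interval (s).
#' @param sourceLine Optional polyline vertices (x, y) in image coordinates.
#' @param channel Channel name.
#' @return A [Kymograph-class] object.
#' @export
Kymograph <- function(data, pixelSize, frameInterval,
                      sourceLine = matrix(numeric(), ncol = 2),
                      channel = "unnamed") {
  new("Kymograph", data = as.matrix(data), pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      sourceLine = as.matrix(sourceLine), channel = as.character(channel))
}

#' @describeIn Kymograph Intensity matrix (rows = frames).
#' @param object,x A `Kymograph`.
#' @export
kymoData <- function(x) x@data

#' @describeIn Kymograph Pixel size (um/px).
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn Kymograph Frame interval (s).
#' @export
frameInterval <- function(x) x@frameInterval

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph [%s]: %d frames x %d positions\n",
              object@channel, nrow(object@data), ncol(object@data)))
  cat(sprintf("  calibration: %.4g um/px, %.4g s/frame\n",
              object@pixelSize, object@frameInterval))
})

#' LineRoi: a polyline region of interest with a sampling width
#'
#' The line along which a kymograph is built. Intensities are averaged
#' across `width` perpendicular 1-pixel offsets, the convention being a
#' 5-pixel-wide line. Coordinates are 0-based with pixel centres at integer
#' positions.
#'
#' @slot vertices Numeric matrix with columns x, y (pixels); at least two
#'   vertices.
#' @slot width Odd integer line width in pixels (default 5).
#'
#' @export
setClass("LineRoi",
  representation(vertices = "matrix", width = "numeric"),
  prototype(width = 5)
)

setValidity("LineRoi", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 2 || nrow(object@vertices) < 2)
    msg <- c(msg, "'vertices' must be a matrix of >= 2 (x, y) rows")
  w <- object@width
  if (length(w) != 1 || w < 1 || w %% 2 != 1)
    msg <- c(msg, "'width' must be an odd integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a LineRoi
#'
#' @param vertices Matrix (or two-column data.frame) of x, y pixel
#'   coordinates, 0-based, at least two rows.
#' @param width Odd line width in pixels; intensities are averaged across
#'   the perpendicular offsets `-(width-1)/2 .. +(width-1)/2`.
#' @return A [LineRoi-class] object.
#' @examples
#' roi <- LineRoi(rbind(c(0, 2), c(30, 2)), width = 5)
#' @export
LineRoi <- function(vertices, width = 5) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  new("LineRoi", vertices = v, width = as.numeric(width))
}

setMethod("show", "LineRoi", function(object) {
  cat(sprintf("LineRoi: %d vertices, width %d px\n",
              nrow(object@vertices), as.integer(object@width)))
})

#' FrapTrace: a FRAP region-of-interest intensity time series
#'
#' @slot times Time points in seconds (uniformly spaced).
#' @slot intensities Intensities (arbitrary units, or normalized units after
#'   [normalizeFrap()]).
#' @slot bleachIndex 1-based index of the bleach frame (for raw traces) or of
#'   the post-bleach minimum frame (for normalized traces, where it is the
#'   fit origin `t = 0`).
#' @slot roiId ROI identifier.
#' @slot condition Experimental condition label.
#' @slot normalized Logical; `TRUE` after [normalizeFrap()].
#'
#' @seealso [simulateFrapTrace()], [normalizeFrap()], [fitKoff()]
#' @export
setClass("FrapTrace",
  representation(
    times = "numeric",
    intensities = "numeric",
    bleachIndex = "integer",
    roiId = "character",
    condition = "character",
    normalized = "logical"
  ),
  prototype(roiId = "roi", condition = "unspecified", normalized = FALSE)
)

setValidity("FrapTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@intensities) != n)
    msg <- c(msg, "'times' and 'intensities' must have equal length")
  if (n >= 2) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "'times' must be strictly increasing")
    else if (diff(range(dt)) > 1e-6 * max(abs(dt)))
      msg <- c(msg, "'times' must be uniformly spaced (1e-6 relative)")
  }
  bi <- object@bleachIndex
  if (length(bi) != 1 || is.na(bi) || bi < 3 || bi > n - 2)
    msg <- c(msg, "'bleachIndex' must leave >= 2 pre- and post-bleach frames")
  if (length(msg)) msg else TRUE
})

#' Construct a FrapTrace
#'
#' @param times Time points (s), uniformly spaced.
#' @param intensities Intensity values (a.u.).
#' @param bleachIndex 1-based frame index at which the bleach occurred; must
#'   leave at least two frames on either side.
#' @param roiId,condition Identification labels.
#' @param normalized Whether the trace is already normalized.
#' @return A [FrapTrace-class] object.
#' @export
FrapTrace <- function(times, intensities, bleachIndex, roiId = "roi",
                      condition = "unspecified", normalized = FALSE) {
  new("FrapTrace", times = as.numeric(times),
      intensities = as.numeric(intensities),
      bleachIndex = as.integer(bleachIndex), roiId = as.character(roiId),
      condition = as.character(condition), normalized = as.logical(normalized))
}

#' @describeIn FrapTrace Time points (s).
#' @param object,x A `FrapTrace`.
#' @export
frapTimes <- function(x) x@times

#' @describeIn FrapTrace Intensity values.
#' @export
frapIntensities <- function(x) x@intensities

#' @describeIn FrapTrace 1-based bleach (or fit-origin) frame index.
#' @export
bleachIndex <- function(x) x@bleachIndex

setMethod("show", "FrapTrace", function(object) {
  cat(sprintf("FrapTrace '%s' (%s)%s: %d frames, bleach at frame %d (t = %.3g s)\n",
              object@roiId, object@condition,
              if (object@normalized) " [normalized]" else "",
              length(object@times), object@bleachIndex,
              object@times[object@bleachIndex]))
})

#' FrapFit: a single-exponential FRAP recovery fit
#'
#' The result of fitting `y = A * (1 - exp(-koff * t))` to the post-bleach
#' part of a normalized recovery curve.
#'
#' @slot A Recovery amplitude (normalized units); values below 1 indicate
#'   incomplete recovery.
#' @slot kOff Unbinding rate constant (1/s).
#' @slot rSquared Coefficient of determination on the post-bleach points.
#' @slot converged Logical optimizer status; fits that pin a parameter at its
#'   bound are flagged not converged.
#' @slot nPoints Number of post-bleach points used.
#' @slot roiId,condition Labels carried over from the trace.
#'
#' @seealso [fitKoff()], [summarizeKoff()]
#' @export
setClass("FrapFit",
  representation(
    A = "numeric", kOff = "numeric", rSquared = "numeric",
    converged = "logical", nPoints = "integer",
    roiId = "character", condition = "character"
  ),
  prototype(roiId = "roi", condition = "unspecified")
)

setValidity("FrapFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged) && (!is.finite(object@kOff) || object@kOff <= 0))
    msg <- c(msg, "a converged fit must have kOff > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FrapFit", function(object) {
  cat(sprintf("FrapFit '%s' (%s): A = %.4g, koff = %.4g 1/s, R2 = %.4g%s\n",
              object@roiId, object@condition, object@A, object@kOff,
              object@rSquared,
              if (object@converged) "" else " [not converged]"))
})

#' @describeIn FrapFit Fitted unbinding rate (1/s).
#' @param object,x A `FrapFit`.
#' @export
kOff <- function(x) x@kOff

#' TestResult: a two-sample hypothesis test result
#'
#' @slot statistic Test statistic (Mann-Whitney U of the first sample, or the
#'   Welch t statistic).
#' @slot pValue Two-sided p-value.
#' @slot method One of `"mann_whitney_exact"`, `"mann_whitney_normal"`,
#'   `"welch_t"`.
#' @slot n1,n2 Sample sizes.
#' @slot df Degrees of freedom (Welch-Satterthwaite; `NA` for rank tests).
#'
#' @seealso [mannWhitneyU()], [welchT()]
#' @export
setClass("TestResult",
  representation(
    statistic = "numeric", pValue = "numeric", method = "character",
    n1 = "integer", n2 = "integer", df = "numeric"
  ),
  prototype(df = NA_real_)
)

setValidity("TestResult", function(object) {
  msg <- character()
  p <- object@pValue
  if (length(p) != 1 || (!is.na(p) && (p < 0 || p > 1)))
    msg <- c(msg, "'pValue' must lie in [0, 1]")
  if (!object@method %in%
      c("mann_whitney_exact", "mann_whitney_normal", "welch_t"))
    msg <- c(msg, "unknown test method")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.6g, two-sided p = %.6g (n1 = %d, n2 = %d%s)\n",
              object@method, object@statistic, object@pValue,
              object@n1, object@n2,
              if (is.na(object@df)) "" else sprintf(", df = %.4g", object@df)))
})

#' @describeIn TestResult Two-sided p-value.
#' @param object,x A `TestResult`.
#' @export
pValue <- function(x) x@pValue

#' @describeIn TestResult Test statistic.
#' @export
testStatistic <- function(x) x@statistic
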