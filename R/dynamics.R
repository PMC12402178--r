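## Dynamic-instability statistics from tip trajectories: phase segments from
## manually picked anchor points (the slope-coordinate convention) or from
## automatic piecewise-linear changepoint segmentation; time-weighted speeds
## with weighted standard errors; catastrophe/rescue frequencies with
## Poisson-counting errors.

#' Phase segments from slope anchor points
#'
#' Reproduces the kymograph point-picking workflow: anchors are (position,
#' time) coordinates clicked on the desired slopes; each consecutive pair
#' defines one phase whose speed is the slope between them, converted to
#' um/min. Segments whose absolute speed falls below `pauseBand` are
#' labelled pauses and later excluded from both speed statistics and
#' frequency exposure times.
#'
#' @param anchors data.frame (or matrix) with columns `position_um` and
#'   `t_s`; at least two rows, times strictly increasing.
#' @param pauseBand Absolute speed (um/min) below which a segment is a
#'   pause.
#' @return A phase-segment data.frame with columns `kind`
#'   (`"growth"`/`"shrink"`/`"pause"`), `t_start_s`, `t_end_s`,
#'   `duration_s`, `speed_um_per_min` (signed), `displacement_um`.
#' @examples
#' slopesFromAnchors(data.frame(position_um = c(0, 1, 0.2),
#'                              t_s = c(0, 30, 40)))
#' @export
slopesFromAnchors <- function(anchors, pauseBand = 0.1) {
  a <- as.data.frame(anchors)
  if (!all(c("position_um", "t_s") %in% names(a))) {
    if (ncol(a) >= 2) names(a)[1:2] <- c("position_um", "t_s")
    else stop("'anchors' needs columns 'position_um' and 't_s'")
  }
  if (nrow(a) < 2) stop("need at least two anchor points")
  dt <- diff(a$t_s)
  if (any(dt == 0)) stop("duplicate anchor times")
  if (any(dt < 0)) stop("anchor times must be strictly increasing")
  dx <- diff(a$position_um)
  speed <- dx / dt * 60
  kind <- ifelse(speed > pauseBand, "growth",
                 ifelse(speed < -pauseBand, "shrink", "pause"))
  data.frame(kind = kind, t_start_s = a$t_s[-nrow(a)], t_end_s = a$t_s[-1],
             duration_s = dt, speed_um_per_min = speed,
             displacement_um = dx, stringsAsFactors = FALSE)
}

## RSS of an OLS line over points i..j from cumulative sums; O(1)
segmentCostFactory <- function(t, x) {
  cs <- function(v) cumsum(c(0, v))
  St <- cs(t); Sx <- cs(x); Stt <- cs(t * t); Stx <- cs(t * x); Sxx <- cs(x * x)
  function(i, j) {
    n <- j - i + 1
    st <- St[j + 1] - St[i]; sx <- Sx[j + 1] - Sx[i]
    stt <- Stt[j + 1] - Stt[i]; stx <- Stx[j + 1] - Stx[i]
    sxx <- Sxx[j + 1] - Sxx[i]
    vt <- stt - st * st / n
    if (vt <= 0) return(sxx - sx * sx / n)
    b <- (stx - st * sx / n) / vt
    sxx - sx * sx / n - b * b * vt
  }
}

#' Automatic piecewise-linear segmentation of a tip trajectory
#'
#' Optimal-partitioning changepoint segmentation: the trajectory is split
#' into pieces, each fit by ordinary least squares, minimizing the total
#' residual sum of squares plus `penalty` per breakpoint (exact dynamic
#' programming, not a greedy heuristic). The default penalty is a BIC-like
#' `3 * sigma^2 * log(n)` with the noise variance estimated from second
#' differences. Fitted slopes are labelled growth/shrink/pause exactly as in
#' [slopesFromAnchors()].
#'
#' @param traj A [FilamentTrajectory-class] (>= 4 samples).
#' @param penalty Per-breakpoint penalty; `NULL` for the default.
#' @param pauseBand Pause labelling band (um/min), as in
#'   [slopesFromAnchors()].
#' @param minSize Minimum samples per segment.
#' @return A phase-segment data.frame (see [slopesFromAnchors()]).
#' @export
segmentAuto <- function(traj, penalty = NULL, pauseBand = 0.1, minSize = 3) {
  stopifnot(is(traj, "FilamentTrajectory"))
  t <- traj@times; x <- traj@tipPositions
  n <- length(t)
  if (n < 4) stop("need at least 4 samples for automatic segmentation")
  if (diff(range(x)) == 0) {
    return(data.frame(kind = "pause", t_start_s = t[1], t_end_s = t[n],
                      duration_s = t[n] - t[1], speed_um_per_min = 0,
                      displacement_um = 0, stringsAsFactors = FALSE))
  }
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x, differences = 2)) / sqrt(6)
    penalty <- 3 * sigma^2 * log(n)
    ## floor keeps the penalty above the floating-point noise of the
    ## cumulative-sum RSS on noiseless traces
    penalty <- max(penalty, 1e-9 * sum(x^2), .Machine$double.eps)
  }
  cost <- segmentCostFactory(t, x)

  ## F[j+1] = best cost of points 1..j; cp[j+1] = start of last segment
  F <- c(0, rep(Inf, n)); cp <- integer(n + 1)
  for (j in minSize:n) {
    starts <- 1:(j - minSize + 1)
    starts <- starts[starts == 1 | starts > minSize]  # no tiny first pieces
    for (i in starts) {
      v <- F[i] + cost(i, j) + penalty
      if (v < F[j + 1]) { F[j + 1] <- v; cp[j + 1] <- i }
    }
  }
  ## backtrack
  bounds <- integer(0); j <- n
  while (j > 0) { i <- cp[j + 1]; bounds <- c(i, bounds); j <- i - 1 }

  segs <- lapply(seq_along(bounds), function(k) {
    i <- bounds[k]
    j <- if (k < length(bounds)) bounds[k + 1] - 1 else n
    fit <- stats::lm.fit(cbind(1, t[i:j]), x[i:j])
    slope <- fit$coefficients[2] * 60
    data.frame(kind = if (slope > pauseBand) "growth"
                      else if (slope < -pauseBand) "shrink" else "pause",
               t_start_s = t[i], t_end_s = t[j], duration_s = t[j] - t[i],
               speed_um_per_min = unname(slope),
               displacement_um = unname(fit$coefficients[2]) * (t[j] - t[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

#' Time-weighted speed statistics
#'
#' Computes the time-weighted mean speed of one phase kind and its weighted
#' standard error. Each segment's weight is its duration divided by the
#' total duration of that kind, the weighted mean is the weight-weighted sum
#' of speeds, and the standard error is
#' `sqrt( sum(w * dx^2) / (((N-1)/N) * sum(w)) )` where `dx` is each speed's
#' deviation from the weighted mean and `N` the number of segments. The sum
#' of weights is carried through literally, keeping the formula valid for
#' unnormalized weights. For a single segment the SE is undefined (`NA`).
#'
#' @param segments A phase-segment data.frame.
#' @param kind `"growth"` or `"shrink"`.
#' @return A list with `weighted_mean`, `weighted_se` (um/min), `n_events`,
#'   `weights`, `deviations`.
#' @examples
#' segs <- data.frame(kind = "growth", t_start_s = c(0, 10),
#'                    t_end_s = c(10, 40), duration_s = c(10, 30),
#'                    speed_um_per_min = c(1, 3),
#'                    displacement_um = c(1 / 6, 1.5))
#' weightedSpeed(segs, "growth")  # mean 2.5, SE sqrt(1.5)
#' @export
weightedSpeed <- function(segments, kind = c("growth", "shrink")) {
  kind <- match.arg(kind)
  s <- segments[segments$kind == kind, , drop = FALSE]
  if (!nrow(s)) stop("no segments of kind '", kind, "'")
  w <- s$duration_s / sum(s$duration_s)
  v <- s$speed_um_per_min
  m <- sum(w * v)
  N <- nrow(s)
  dx <- v - m
  se <- if (N == 1) NA_real_
        else sqrt(sum(w * dx^2) / (((N - 1) / N) * sum(w)))
  list(weighted_mean = m, weighted_se = se, n_events = N,
       weights = w, deviations = dx)
}

## collapse pauses out of an ordered phase sequence and enumerate
## growth->shrink / shrink->growth transitions; seed-forced restarts
## (terminal_event == "seed") are not rescues
transitionsFromSegments <- function(segments, excludeSeed = TRUE) {
  nonPause <- segments[segments$kind != "pause", , drop = FALSE]
  nCat <- 0L; nRes <- 0L
  if (nrow(nonPause) >= 2) {
    for (k in 2:nrow(nonPause)) {
      a <- nonPause$kind[k - 1]; b <- nonPause$kind[k]
      seedEv <- excludeSeed && "terminal_event" %in% names(nonPause) &&
        identical(nonPause$terminal_event[k - 1], "seed")
      if (a == "growth" && b == "shrink") nCat <- nCat + 1L
      if (a == "shrink" && b == "growth" && !seedEv) nRes <- nRes + 1L
    }
  }
  c(catastrophes = nCat, rescues = nRes)
}

#' Catastrophe and rescue frequencies with counting errors
#'
#' The catastrophe frequency is the total number of catastrophes
#' (growth-to-shrinkage transitions) divided by the total time spent
#' growing; the rescue frequency is the total number of rescues divided by
#' the total time spent shrinking. Pauses are excluded from the exposure
#' times, and a growth-pause-shrinkage sequence counts as a single
#' catastrophe. The error on each frequency is `frequency / sqrt(n)` with
#' `n` the event count; for `n = 0` the frequency is 0 and the error
#' undefined (`NA`). With several trajectories the counts and exposures are
#' pooled (total events over total time), not averaged per filament.
#' Seed-forced regrowth events (phase logs carrying
#' `terminal_event == "seed"`) are excluded from rescue counts.
#'
#' @param segments A phase-segment data.frame, or a list of them (one per
#'   trajectory, each in time order).
#' @return data.frame with rows `catastrophe` and `rescue` and columns
#'   `kind`, `n_events`, `exposure_s`, `frequency_per_s`, `error_per_s`.
#' @examples
#' segs <- list(data.frame(
#'   kind = c("growth", "shrink"), t_start_s = c(0, 200),
#'   t_end_s = c(200, 210), duration_s = c(200, 10),
#'   speed_um_per_min = c(2, -20), displacement_um = c(6.7, -3.3)))
#' eventFrequencies(segs)
#' @export
eventFrequencies <- function(segments) {
  if (is.data.frame(segments)) segments <- list(segments)
  nCat <- 0L; nRes <- 0L; tGrow <- 0; tShrink <- 0
  for (s in segments) {
    tr <- transitionsFromSegments(s)
    nCat <- nCat + unname(tr["catastrophes"])
    nRes <- nRes + unname(tr["rescues"])
    tGrow <- tGrow + sum(s$duration_s[s$kind == "growth"])
    tShrink <- tShrink + sum(s$duration_s[s$kind == "shrink"])
  }
  one <- function(kind, n, expo) {
    if (expo <= 0) {
      warning("zero exposure time for ", kind, " frequency")
      freq <- NA_real_
    } else freq <- n / expo
    data.frame(kind = kind, n_events = as.integer(n), exposure_s = expo,
               frequency_per_s = if (expo > 0 && n == 0) 0 else freq,
               error_per_s = if (n >= 1 && expo > 0) freq / sqrt(n)
                             else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one("catastrophe", nCat, tGrow), one("rescue", nRes, tShrink))
}

#' Compare a dynamics metric across conditions
#'
#' Pairwise Welch two-sample t tests (unequal variances) across named groups
#' of per-filament values, the convention for comparing microtubule
#' dynamics between conditions.
#'
#' @param groups Named list of numeric vectors (>= 2 values each).
#' @param metric Label of the compared metric, carried into the report.
#' @return A list with `summary` (per-group n, mean, sd) and `tests`
#'   (data.frame of pairwise Welch results: t, df, two-sided p). Pairs with
#'   fewer than two values per group are flagged and get no p-value.
#' @export
compareDynamics <- function(groups, metric = "metric") {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  summ <- data.frame(
    condition = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(names(groups), 2)
  tests <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    x <- groups[[a]]; y <- groups[[b]]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(group1 = a, group2 = b, t = NA_real_, df = NA_real_,
                        p = NA_real_, note = "insufficient n",
                        stringsAsFactors = FALSE))
    }
    r <- welchT(x, y)
    data.frame(group1 = a, group2 = b, t = r@statistic, df = r@df,
               p = r@pValue, note = "", stringsAsFactors = FALSE)
  })
  list(metric = metric, summary = summ, tests = do.call(rbind, tests))
}
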