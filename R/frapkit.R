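## FRAP analysis: normalization of recovery traces, single-exponential
## off-rate fitting (reaction-limited recovery), and condition-level
## comparison of off-rate distributions by their medians.

#' Normalize a FRAP recovery trace
#'
#' Subtracts the post-bleach minimum from every intensity and divides by the
#' mean of the pre-bleach values, so the post-bleach minimum maps exactly to
#' 0 and a full recovery back to the pre-bleach level maps to
#' `(mean_pre - min_post) / mean_pre`. Time is re-zeroed at the post-bleach
#' minimum frame, which becomes the fit origin (`bleachIndex` of the
#' returned trace), consistent with a recovery model with no offset term.
#' The operation is idempotent on traces whose post-bleach minimum is 0 and
#' pre-bleach mean is 1.
#'
#' @param trace A [FrapTrace-class] with at least two pre- and post-bleach
#'   frames.
#' @return A normalized [FrapTrace-class]; times are shifted so the
#'   post-bleach minimum frame is at `t = 0`.
#' @examples
#' tr <- FrapTrace(times = 0:9, intensities = c(100, 100, 100, 20, 40,
#'                 55, 65, 72, 77, 80), bleachIndex = 4)
#' frapIntensities(normalizeFrap(tr))[4]  # the minimum maps to 0
#' @export
normalizeFrap <- function(trace) {
  stopifnot(is(trace, "FrapTrace"))
  validObject(trace)
  n <- length(trace@times)
  bi <- trace@bleachIndex
  pre <- trace@intensities[seq_len(bi - 1L)]
  post <- trace@intensities[bi:n]
  meanPre <- mean(pre)
  if (meanPre == 0) stop("zero pre-bleach mean: cannot normalize")
  minPost <- min(post)
  minIdx <- bi - 1L + which.min(post)
  y <- (trace@intensities - minPost) / meanPre
  FrapTrace(times = trace@times - trace@times[minIdx], intensities = y,
            bleachIndex = minIdx, roiId = trace@roiId,
            condition = trace@condition, normalized = TRUE)
}

#' Fit the single-exponential recovery model
#'
#' Least-squares fit of `y = A * (1 - exp(-t * koff))` to the post-bleach
#' part of a normalized recovery curve (points from the fit origin onward).
#' Starting values are `A0 =` mean of the last 10% of points and
#' `k0 = ln(2) /` (time to half of `A0`); parameters are bounded to
#' `A in (0, 2]` and `koff in [1e-4, 1e2]` 1/s. A fit that pins a parameter
#' at its bound, or whose optimizer fails, is returned with
#' `converged = FALSE` (and excluded from condition medians by
#' [summarizeKoff()]), so a pure-noise trace never silently reports a bound
#' as an estimate. The reported R-squared is computed on the post-bleach
#' points only.
#'
#' @param trace A normalized [FrapTrace-class] (see [normalizeFrap()]) with
#'   at least 5 post-bleach points.
#' @return A [FrapFit-class].
#' @examples
#' tr <- simulateFrapTrace(kOff = 0.5, plateau = 0.8, noiseSigma = 0)
#' fit <- fitKoff(normalizeFrap(tr))
#' kOff(fit)  # 0.5 to solver tolerance
#' @export
fitKoff <- function(trace) {
  stopifnot(is(trace, "FrapTrace"))
  if (!trace@normalized)
    stop("fitKoff() expects a normalized trace; run normalizeFrap() first")
  sel <- trace@times >= 0
  t <- trace@times[sel]
  y <- trace@intensities[sel]
  if (length(t) < 5) stop("need at least 5 post-bleach points")

  nTail <- max(1L, ceiling(0.1 * length(y)))
  A0 <- mean(utils::tail(y, nTail))
  A0 <- min(max(A0, 1e-3), 2)
  iHalf <- which(y >= A0 / 2)[1]
  tHalf <- if (!is.na(iHalf) && t[iHalf] > 0) t[iHalf] else
    max(t) / 4
  k0 <- min(max(log(2) / tHalf, 1e-4), 1e2)

  lower <- c(A = 1e-6, koff = 1e-4)
  upper <- c(A = 2, koff = 1e2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-t * koff)),
                      start = list(A = A0, koff = k0),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(new("FrapFit", A = NA_real_, kOff = NA_real_,
               rSquared = NA_real_, converged = FALSE,
               nPoints = length(t), roiId = trace@roiId,
               condition = trace@condition))
  }
  cf <- stats::coef(fit)
  res <- y - cf[["A"]] * (1 - exp(-t * cf[["koff"]]))
  ssRes <- sum(res^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else if (ssRes == 0) 1 else NA_real_

  atBound <- function(val, lo, hi) {
    tol <- 1e-6 * (hi - lo)
    val <= lo + tol || val >= hi - tol
  }
  converged <- isTRUE(fit$convInfo$isConv) &&
    !atBound(cf[["koff"]], lower[["koff"]], upper[["koff"]]) &&
    !atBound(cf[["A"]], lower[["A"]], upper[["A"]])
  if (!converged)
    warning("FRAP fit for '", trace@roiId,
            "' did not converge cleanly; parameters reported but flagged")

  new("FrapFit", A = unname(cf[["A"]]), kOff = unname(cf[["koff"]]),
      rSquared = r2, converged = converged, nPoints = length(t),
      roiId = trace@roiId, condition = trace@condition)
}

#' Tabulate a list of FRAP fits
#'
#' @param fits List of [FrapFit-class] objects.
#' @return data.frame with one row per fit: `roi_id`, `condition`, `A`,
#'   `koff_per_s`, `r_squared`, `converged`, `n_points`.
#' @export
frapFitTable <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    roi_id = f@roiId, condition = f@condition, A = f@A,
    koff_per_s = f@kOff, r_squared = f@rSquared, converged = f@converged,
    n_points = f@nPoints, stringsAsFactors = FALSE)))
}

#' Summarize and compare off-rate distributions across conditions
#'
#' Off-rate distributions are asymmetric, so conditions are summarized by
#' their median `koff` over usable fits (converged and with non-negative
#' R-squared); excluded fits are counted. Pairwise conditions are compared
#' with a two-sided Mann-Whitney U test.
#'
#' @param fits Either a named list of lists of [FrapFit-class] objects
#'   (condition -> fits) or a flat list of fits whose `condition` labels
#'   define the grouping.
#' @return A list with `summary` (condition, n_used, n_excluded,
#'   median_koff_per_s) and `tests` (pairwise Mann-Whitney results).
#' @export
summarizeKoff <- function(fits) {
  if (is.list(fits) && length(fits) && is(fits[[1]], "FrapFit")) {
    conds <- vapply(fits, function(f) f@condition, character(1))
    fits <- split(fits, conds)
  }
  stopifnot(is.list(fits), !is.null(names(fits)))
  usable <- lapply(fits, function(fl) {
    ok <- vapply(fl, function(f) isTRUE(f@converged) &&
                   is.finite(f@rSquared) && f@rSquared >= 0, logical(1))
    fl[ok]
  })
  nAll <- vapply(fits, length, integer(1))
  nUse <- vapply(usable, length, integer(1))
  if (any(nUse == 0))
    warning("condition(s) without a usable fit: ",
            paste(names(fits)[nUse == 0], collapse = ", "))
  med <- vapply(usable, function(fl)
    if (length(fl)) stats::median(vapply(fl, kOff, numeric(1)))
    else NA_real_, numeric(1))
  summ <- data.frame(condition = names(fits), n_used = nUse,
                     n_excluded = nAll - nUse, median_koff_per_s = med,
                     row.names = NULL, stringsAsFactors = FALSE)

  tests <- NULL
  if (length(fits) >= 2) {
    pairs <- utils::combn(names(fits), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ka <- vapply(usable[[a]], kOff, numeric(1))
      kb <- vapply(usable[[b]], kOff, numeric(1))
      if (!length(ka) || !length(kb))
        return(data.frame(group1 = a, group2 = b, U = NA_real_, p = NA_real_,
                          method = "none", stringsAsFactors = FALSE))
      r <- mannWhitneyU(ka, kb)
      data.frame(group1 = a, group2 = b, U = r@statistic, p = r@pValue,
                 method = r@method, stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, tests = tests)
}
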