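## Residence times, the diffusion filter, rule-based classification of
## actin-filament crosslinking events, and overlap-length / intensity time
## courses.

#' Residence times from particle tracks
#'
#' The residence (dwell) time of a particle or filament is the time between
#' its landing on and unbinding from the filament,
#' `dwell = t_unbind - t_land`. Tracks that carry exact continuous-time
#' `t_on_s` / `t_off_s` columns (as the simulator logs) use those; otherwise
#' the first and last sampled frame times are used. Tracks truncated by the
#' movie start or end are censored: excluded from the dwell table and
#' counted separately, so no reported dwell can exceed the movie duration.
#'
#' @param tracks Long-format track data.frame (`track_id`, `t_s`, ...),
#'   optionally with exact `t_on_s` / `t_off_s` columns, or a per-track
#'   dwell data.frame with `track_id`, `t_on_s`, `t_off_s`.
#' @param frameInterval Frame interval (s); used for the start-censoring
#'   margin on frame-resolved tracks.
#' @param movieDuration Movie duration (s); tracks still present at (or
#'   beyond) this time are censored.
#' @return A list with `dwells` (data.frame `track_id`, `t_on_s`, `t_off_s`,
#'   `dwell_s`), `n_censored`, and `summary` (n, median, min, max).
#' @export
residenceTimes <- function(tracks, frameInterval, movieDuration) {
  if (!nrow(tracks)) {
    return(list(dwells = data.frame(track_id = character(),
                                    t_on_s = numeric(), t_off_s = numeric(),
                                    dwell_s = numeric()),
                n_censored = 0L,
                summary = data.frame(n = 0L, median_s = NA_real_,
                                     min_s = NA_real_, max_s = NA_real_)))
  }
  exact <- all(c("t_on_s", "t_off_s") %in% names(tracks))
  if (exact) {
    per <- unique(tracks[, c("track_id", "t_on_s", "t_off_s")])
  } else {
    ids <- unique(tracks$track_id)
    per <- data.frame(
      track_id = ids,
      t_on_s = vapply(ids, function(i)
        min(tracks$t_s[tracks$track_id == i]), numeric(1)),
      t_off_s = vapply(ids, function(i)
        max(tracks$t_s[tracks$track_id == i]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  margin <- if (exact) 0 else frameInterval / 2
  censored <- per$t_on_s <= margin | per$t_off_s >= movieDuration - margin
  dw <- per[!censored, , drop = FALSE]
  dw$dwell_s <- dw$t_off_s - dw$t_on_s
  list(dwells = dw, n_censored = sum(censored),
       summary = data.frame(
         n = nrow(dw),
         median_s = if (nrow(dw)) stats::median(dw$dwell_s) else NA_real_,
         min_s = if (nrow(dw)) min(dw$dwell_s) else NA_real_,
         max_s = if (nrow(dw)) max(dw$dwell_s) else NA_real_))
}

#' Filter out static tracks
#'
#' Keeps only tracks whose positional standard deviation exceeds a
#' threshold: a particle genuinely bound to the lattice diffuses, whereas a
#' perfectly static signal is indistinguishable from background noise.
#'
#' @param tracks Long-format track data.frame (`track_id`, `position_um`).
#' @param minPositionalSdPx Threshold on the positional standard deviation,
#'   in pixels (default 0.5).
#' @param pixelSize Pixel size (um/px) used to express positions in pixels.
#' @return A list with `kept` and `discarded` track data.frames; `discarded`
#'   rows carry a `reason` attribute table in `reasons`.
#' @export
diffusionFilter <- function(tracks, minPositionalSdPx = 0.5,
                            pixelSize = 0.1) {
  if (!nrow(tracks))
    return(list(kept = tracks, discarded = tracks,
                reasons = data.frame(track_id = character(),
                                     sd_px = numeric(),
                                     reason = character())))
  ids <- unique(tracks$track_id)
  sds <- vapply(ids, function(i)
    stats::sd(tracks$position_um[tracks$track_id == i]) / pixelSize,
    numeric(1))
  sds[is.na(sds)] <- 0
  ## a non-positive threshold disables the filter entirely
  keep <- if (minPositionalSdPx <= 0) rep(TRUE, length(ids))
          else sds > minPositionalSdPx
  list(kept = tracks[tracks$track_id %in% ids[keep], , drop = FALSE],
       discarded = tracks[tracks$track_id %in% ids[!keep], , drop = FALSE],
       reasons = data.frame(
         track_id = ids[!keep], sd_px = sds[!keep],
         reason = sprintf("positional sd %.3g px below threshold %.3g px",
                          sds[!keep], minPositionalSdPx),
         stringsAsFactors = FALSE))
}

#' Default event-classification parameters
#'
#' @param pixelSize Pixel size (um/px).
#' @param minFrames Minimum frames for a binding event (4, i.e. 8 s at 2 s
#'   per frame).
#' @param slideMinPx Minimum net start-position displacement for sliding
#'   (px).
#' @param tipTolPx Distance tolerance to the microtubule tip for tip
#'   tracking (px).
#' @param stepFactor Minimum sustained actin-intensity fold change for
#'   bundling.
#' @param comovementMin Minimum displacement correlation with the
#'   crosslinker track ("moving along with" criterion).
#' @param monotoneMin Minimum |Spearman correlation| of position with time
#'   for the sliding trend.
#' @return Named list of parameters.
#' @export
eventParams <- function(pixelSize = 0.1, minFrames = 4L, slideMinPx = 3,
                        tipTolPx = 2, stepFactor = 1.8, comovementMin = 0.5,
                        monotoneMin = 0.8) {
  list(pixelSize = pixelSize, minFrames = as.integer(minFrames),
       slideMinPx = slideMinPx, tipTolPx = tipTolPx,
       stepFactor = stepFactor, comovementMin = comovementMin,
       monotoneMin = monotoneMin)
}

longestRun <- function(flag) {
  if (!length(flag)) return(0L)
  r <- rle(flag)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Classify one actin-filament track on a dynamic microtubule
#'
#' Applies the rule-based event taxonomy. A candidate binding event must be
#' present for at least `minFrames` frames (4 frames, 8 s at the 2-s frame
#' interval) and, when a crosslinker-channel track is supplied, move along
#' with it (displacement correlation at or above `comovementMin`). Exactly
#' one label is then assigned with precedence
#' tip_tracking > bundling > sliding > bind_unbind:
#' \describe{
#'   \item{tip_tracking}{the track stays within `tipTolPx` of the
#'     microtubule tip for at least `minFrames` consecutive frames.}
#'   \item{bundling}{a sustained (>= `minFrames`) step in the actin-channel
#'     intensity of at least `stepFactor` times the initial level.}
#'   \item{sliding}{net displacement of the filament start position above
#'     `slideMinPx` with a monotonic trend.}
#'   \item{bind_unbind}{anything else.}
#' }
#' The event location (seed / gdp_lattice / plus_tip) is assigned from the
#' landing-frame position against the seed extent and the tip position.
#'
#' @param track One track's data.frame (`t_s`, `position_um`, `intensity`).
#' @param mtTip A [FilamentTrajectory-class] for the microtubule tip.
#' @param anillinTrack Optional co-localized crosslinker track data.frame
#'   (`t_s`, `position_um`) for the co-movement check.
#' @param frameInterval Frame interval (s).
#' @param params Parameter list from [eventParams()].
#' @return A one-row event-record data.frame (see [emptyEventRecords()]), or
#'   a zero-row one with attribute `"reason"` when the track is rejected.
#' @export
classifyEvent <- function(track, mtTip, anillinTrack = NULL,
                          frameInterval = 2, params = eventParams()) {
  px <- params$pixelSize
  nF <- nrow(track)
  reject <- function(reason) {
    out <- emptyEventRecords()
    attr(out, "reason") <- reason
    out
  }
  if (nF < params$minFrames)
    return(reject(sprintf(
      "below %d frames (%g s): not a binding event",
      params$minFrames, params$minFrames * frameInterval)))

  if (!is.null(anillinTrack)) {
    shared <- intersect(round(track$t_s, 9), round(anillinTrack$t_s, 9))
    if (length(shared) >= 3) {
      pa <- track$position_um[match(shared, round(track$t_s, 9))]
      pb <- anillinTrack$position_um[match(shared,
                                           round(anillinTrack$t_s, 9))]
      da <- diff(pa); db <- diff(pb)
      cc <- if (stats::sd(da) == 0 || stats::sd(db) == 0) 1
            else stats::cor(da, db)
      if (is.finite(cc) && cc < params$comovementMin)
        return(reject(sprintf(
          "displacement correlation %.2f below %.2f: not co-moving",
          cc, params$comovementMin)))
    }
  }

  tip <- tipPositionAt(mtTip, track$t_s)
  nearTip <- abs(track$position_um - tip) <= params$tipTolPx * px
  isTip <- longestRun(nearTip) >= params$minFrames

  intensity <- track$intensity
  base <- mean(utils::head(intensity, max(2L, params$minFrames - 1L)))
  isBundle <- FALSE
  if (base > 0 && nF >= 2 * params$minFrames - 1L) {
    level <- stats::filter(intensity, rep(1 / params$minFrames,
                                          params$minFrames), sides = 1)
    isBundle <- any(level >= params$stepFactor * base, na.rm = TRUE)
  }

  netPx <- (track$position_um[nF] - track$position_um[1]) / px
  rho <- suppressWarnings(
    stats::cor(track$t_s, track$position_um, method = "spearman"))
  isSlide <- abs(netPx) > params$slideMinPx &&
    is.finite(rho) && abs(rho) >= params$monotoneMin

  label <- if (isTip) "tip_tracking"
           else if (isBundle) "bundling"
           else if (isSlide) "sliding"
           else "bind_unbind"

  x0 <- track$position_um[1]
  location <- if (x0 <= mtTip@seedReference) "seed"
    else if (abs(x0 - tip[1]) <= params$tipTolPx * px) "plus_tip"
    else "gdp_lattice"

  id <- if ("track_id" %in% names(track)) track$track_id[1] else "track"
  data.frame(event_id = id, track_id = id, label = label,
             t_on_s = track$t_s[1], t_off_s = track$t_s[nF],
             residence_time_s = track$t_s[nF] - track$t_s[1],
             n_filaments = if (label == "bundling") 2L else 1L,
             location = location, stringsAsFactors = FALSE)
}

#' Classify every actin track in a long-format table
#'
#' @param tracks Long-format track data.frame; actin tracks are classified,
#'   and a matching `<track_id>_anillin` track (channel `"anillin"`), when
#'   present, supplies the co-movement check.
#' @param mtTip A [FilamentTrajectory-class].
#' @param frameInterval Frame interval (s).
#' @param params Parameter list from [eventParams()].
#' @return A list with `events` (event records) and `rejected` (data.frame
#'   of track_id, reason).
#' @export
classifyEvents <- function(tracks, mtTip, frameInterval = 2,
                           params = eventParams()) {
  actin <- tracks[tracks$channel != "anillin", , drop = FALSE]
  rows <- list(); rej <- list()
  for (id in unique(actin$track_id)) {
    tr <- actin[actin$track_id == id, , drop = FALSE]
    an <- tracks[tracks$track_id == paste0(id, "_anillin"), , drop = FALSE]
    rec <- classifyEvent(tr, mtTip,
                         anillinTrack = if (nrow(an)) an else NULL,
                         frameInterval = frameInterval, params = params)
    if (nrow(rec)) rows[[length(rows) + 1L]] <- rec
    else rej[[length(rej) + 1L]] <- data.frame(
      track_id = id, reason = attr(rec, "reason"), stringsAsFactors = FALSE)
  }
  list(events = if (length(rows)) do.call(rbind, rows) else
         emptyEventRecords(),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(track_id = character(), reason = character()))
}

#' Compare residence times of bundled versus single filaments
#'
#' @param bundled Dwell times (s) of bundled filaments.
#' @param single Dwell times (s) of non-bundled filaments.
#' @return A list with per-group `mean`, `n`, the Mann-Whitney
#'   [TestResult-class] in `test`, and `reliable` (`FALSE` when either group
#'   has fewer than 3 values).
#' @export
compareResidence <- function(bundled, single) {
  if (!length(bundled) || !length(single))
    stop("both dwell samples must be non-empty")
  reliable <- length(bundled) >= 3 && length(single) >= 3
  if (!reliable)
    warning("fewer than 3 dwells in a group: p-value unreliable")
  list(mean_bundled_s = mean(bundled), n_bundled = length(bundled),
       mean_single_s = mean(single), n_single = length(single),
       test = mannWhitneyU(bundled, single), reliable = reliable)
}

#' Overlap length and normalized intensity time course
#'
#' From registered actin and crosslinker kymographs, measures per frame the
#' extent of the actin-microtubule overlap: the columns within the
#' microtubule extent where the background-subtracted actin signal exceeds
#' `k` background standard deviations. Channel intensities over the
#' microtubule extent are background-subtracted and divided by their
#' per-channel maxima, so each normalized channel peaks at exactly 1.
#'
#' @param actinKymo,anillinKymo Registered [Kymograph-class] objects (same
#'   shape and calibration).
#' @param mtExtent Integer range (1-based columns) occupied by the
#'   microtubule.
#' @param backgroundCols Integer columns of a background region.
#' @param k Threshold in background standard deviations (default 3).
#' @return data.frame with `t_s`, `overlap_length_um`,
#'   `actin_intensity_norm`, `anillin_intensity_norm`.
#' @export
overlapTimecourse <- function(actinKymo, anillinKymo, mtExtent,
                              backgroundCols, k = 3) {
  stopifnot(is(actinKymo, "Kymograph"), is(anillinKymo, "Kymograph"))
  if (!identical(dim(actinKymo@data), dim(anillinKymo@data)))
    stop("kymographs are not registered: shapes differ")
  a <- actinKymo@data; b <- anillinKymo@data
  cols <- seq(min(mtExtent), max(mtExtent))
  bgA <- rowMeans(a[, backgroundCols, drop = FALSE])
  sdA <- apply(a[, backgroundCols, drop = FALSE], 1, stats::sd)
  bgB <- rowMeans(b[, backgroundCols, drop = FALSE])

  above <- sweep(a[, cols, drop = FALSE], 1, bgA + k * sdA, ">")
  overlapLen <- rowSums(above) * actinKymo@pixelSize
  actInt <- rowMeans(a[, cols, drop = FALSE]) - bgA
  aniInt <- rowMeans(b[, cols, drop = FALSE]) - bgB
  normBy <- function(v) if (max(v) > 0) v / max(v) else v
  data.frame(
    t_s = (seq_len(nrow(a)) - 1) * actinKymo@frameInterval,
    overlap_length_um = overlapLen,
    actin_intensity_norm = normBy(actInt),
    anillin_intensity_norm = normBy(aniInt))
}

#' Crosslinker enrichment on overlaps relative to bare microtubules
#'
#' Divides background-subtracted crosslinker intensities measured on
#' actin-microtubule overlaps and on microtubule-only regions by the mean of
#' the microtubule-only sample, so the microtubule-only normalized mean is 1
#' by construction, and compares the two samples with a Mann-Whitney U test.
#'
#' @param overlapIntensities Background-subtracted intensities on overlaps.
#' @param mtOnlyIntensities Background-subtracted intensities on
#'   microtubule-only regions.
#' @return A list with normalized means, n, and the Mann-Whitney
#'   [TestResult-class].
#' @export
overlapEnrichment <- function(overlapIntensities, mtOnlyIntensities) {
  if (!length(overlapIntensities) || !length(mtOnlyIntensities))
    stop("both intensity samples must be non-empty")
  m <- mean(mtOnlyIntensities)
  if (m <= 0) stop("microtubule-only mean must be positive")
  ov <- overlapIntensities / m
  mt <- mtOnlyIntensities / m
  list(mean_overlap = mean(ov), n_overlap = length(ov),
       mean_mt_only = mean(mt), n_mt_only = length(mt),
       test = mannWhitneyU(ov, mt))
}
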