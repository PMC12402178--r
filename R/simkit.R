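## Synthetic-data generators: the forward models whose parameters the
## analysis modules are meant to recover. All simulators are event-driven
## (Gillespie-style) with exact exponential waiting times, so estimated
## frequencies are unbiased at any frame interval. Each simulator seeds one
## global RNG from its 'rngSeed' and draws from it in documented order.

rexpOrInf <- function(rate) {
  if (rate <= 0) Inf else stats::rexp(1L, rate)
}

#' Evaluate a trajectory's tip position at arbitrary times
#'
#' Linear interpolation between the trajectory's (event) time points;
#' constant extrapolation outside the recorded range.
#'
#' @param trajectory A [FilamentTrajectory-class].
#' @param t Numeric vector of times (s).
#' @return Tip positions (um) at `t`.
#' @export
tipPositionAt <- function(trajectory, t) {
  stats::approx(trajectory@times, trajectory@tipPositions, xout = t,
                rule = 2)$y
}

#' Sample a continuous-time trajectory onto an imaging frame grid
#'
#' The continuous-time truth is evaluated at frame midpoints
#' `(k - 1/2) * frameInterval`, which keeps phase durations unbiased when the
#' sampled trace is segmented again.
#'
#' @param trajectory A [FilamentTrajectory-class].
#' @param frameInterval Frame interval (s).
#' @param duration Total sampled time (s); defaults to the trajectory's last
#'   time point.
#' @return A [FilamentTrajectory-class] sampled at frame midpoints.
#' @export
sampleAtFrames <- function(trajectory, frameInterval, duration = NULL) {
  if (is.null(duration)) duration <- max(trajectory@times)
  nFrames <- max(1L, floor(duration / frameInterval))
  tMid <- (seq_len(nFrames) - 0.5) * frameInterval
  FilamentTrajectory(times = tMid,
                     tipPositions = tipPositionAt(trajectory, tMid),
                     seedReference = trajectory@seedReference)
}

#' Simulate two-state microtubule dynamic instability
#'
#' Event-driven simulation of a single microtubule tip switching between
#' growth and shrinkage. In the growth state, the waiting time to a
#' catastrophe is exponential with rate `fCat`; in the shrinkage state, the
#' waiting time to a rescue is exponential with rate `fRes`. When shrinkage
#' reaches the stabilized seed, regrowth is forced and the restart is logged
#' as a `"seed"` event, not a rescue (seeds are stabilized, so such restarts
#' must not inflate rescue statistics on the dynamic lattice).
#'
#' @param params A [DynamicsParams-class].
#' @return A list with components:
#'   \describe{
#'     \item{trajectory}{[FilamentTrajectory-class] holding the exact
#'       piecewise-linear tip path (one point per state switch).}
#'     \item{phaseLog}{data.frame with one row per growth/shrinkage phase:
#'       `kind`, `t_start_s`, `t_end_s`, `duration_s`, `speed_um_per_min`
#'       (signed), `displacement_um`, and `terminal_event` in
#'       `{"catastrophe", "rescue", "seed", "end"}`. The phases partition
#'       `[0, duration]`.}
#'   }
#' @examples
#' sim <- simulateDynamicInstability(
#'   DynamicsParams(vGrowth = 2, fCat = 0, duration = 300))
#' tail(tipPositions(sim$trajectory), 1)  # 10 um of uninterrupted growth
#' @export
simulateDynamicInstability <- function(params) {
  stopifnot(is(params, "DynamicsParams"))
  validObject(params)
  set.seed(params@rngSeed)
  vg <- params@vGrowth / 60   # um/s
  vs <- params@vShrink / 60
  seedLen <- params@seedLength
  dur <- params@duration

  t <- 0
  pos <- seedLen
  state <- "growth"
  times <- t
  positions <- pos
  kind <- character(); t0 <- numeric(); t1 <- numeric()
  speed <- numeric(); terminal <- character()

  while (t < dur) {
    if (state == "growth") {
      w <- rexpOrInf(params@fCat)
      tEnd <- min(t + w, dur)
      event <- if (t + w < dur) "catastrophe" else "end"
      newPos <- pos + vg * (tEnd - t)
      kind <- c(kind, "growth"); t0 <- c(t0, t); t1 <- c(t1, tEnd)
      speed <- c(speed, params@vGrowth); terminal <- c(terminal, event)
      t <- tEnd; pos <- newPos
      if (event == "catastrophe") state <- "shrink"
    } else {
      w <- rexpOrInf(params@fRes)
      tSeed <- (pos - seedLen) / vs      # time to reach the seed
      tEnd <- min(t + w, t + tSeed, dur)
      event <- if (tEnd == dur) "end"
               else if (tSeed <= w) "seed" else "rescue"
      newPos <- pos - vs * (tEnd - t)
      kind <- c(kind, "shrink"); t0 <- c(t0, t); t1 <- c(t1, tEnd)
      speed <- c(speed, -params@vShrink); terminal <- c(terminal, event)
      t <- tEnd; pos <- newPos
      if (event %in% c("rescue", "seed")) state <- "growth"
    }
    times <- c(times, t)
    positions <- c(positions, pos)
  }

  phaseLog <- data.frame(
    kind = kind, t_start_s = t0, t_end_s = t1, duration_s = t1 - t0,
    speed_um_per_min = speed,
    displacement_um = speed / 60 * (t1 - t0),
    terminal_event = terminal, stringsAsFactors = FALSE)

  list(trajectory = FilamentTrajectory(times, positions, seedLen),
       phaseLog = phaseLog)
}

#' Simulate diffusive binder tracks on a filament lattice
#'
#' Particles land on the lattice as a Poisson process with rate
#' `kOn * latticeLength`, diffuse along it in 1-D (reflecting boundaries),
#' and unbind with the off-rate of the lattice region they currently occupy:
#' `kOffSeed` on the seed segment `[0, seedLength]`, `kOffGdp` above it. The
#' unbinding time within each frame step is drawn exactly (exponential),
#' so dwell times on a homogeneous lattice are exactly exponential; with two
#' regions the occupied region is updated once per frame step. Each track
#' carries an intensity multiplicity drawn from `oligomerWeights`.
#'
#' @param params A [BinderParams-class].
#' @param lattice Either a single number (static lattice length, um) or a
#'   [FilamentTrajectory-class] whose tip position bounds the lattice at each
#'   time; particles overtaken by a shrinking tip are forced off.
#' @param duration Simulated time (s).
#' @param frameInterval Sampling (and region-update) interval (s).
#' @param seedLength Seed-segment length (um); used when `lattice` is a
#'   static length (a trajectory brings its own `seedReference`).
#' @return A list with components:
#'   \describe{
#'     \item{tracks}{long data.frame: `track_id`, `channel` ("binder"),
#'       `t_s`, `position_um`, `intensity` (multiplicity), one row per
#'       sampled frame.}
#'     \item{dwells}{per-track data.frame with exact continuous-time
#'       `t_on_s`, `t_off_s`, `dwell_s`, `multiplicity`, `censored` (track
#'       still bound at `duration`), and `landing_region` in
#'       `{"seed", "gdp_lattice"}`.}
#'   }
#' @export
simulateBinderTracks <- function(params, lattice, duration,
                                 frameInterval = 0.1, seedLength = 0) {
  stopifnot(is(params, "BinderParams"))
  validObject(params)
  set.seed(params@rngSeed)

  dynamic <- is(lattice, "FilamentTrajectory")
  if (dynamic) {
    seedLength <- lattice@seedReference
    latticeAt <- function(t) tipPositionAt(lattice, t)
    Lmax <- max(lattice@tipPositions)
  } else {
    L0 <- as.numeric(lattice)
    latticeAt <- function(t) L0
    Lmax <- L0
  }
  if (Lmax <= 0) {
    warning("zero-length lattice: no binder tracks generated")
    return(list(tracks = emptyTracks(),
                dwells = data.frame(track_id = character(),
                                    t_on_s = numeric(), t_off_s = numeric(),
                                    dwell_s = numeric(),
                                    multiplicity = numeric(),
                                    censored = logical(),
                                    landing_region = character())))
  }

  ## arrivals: Poisson with rate kOn * L(t); thinning against Lmax
  nCand <- stats::rpois(1L, params@kOn * Lmax * duration)
  tCand <- sort(stats::runif(nCand, 0, duration))
  keep <- stats::runif(nCand) < latticeAt(tCand) / Lmax
  tArr <- tCand[keep]

  mults <- as.numeric(names(params@oligomerWeights))
  rateOf <- function(x) {
    ifelse(x <= seedLength, params@kOffSeed, params@kOffGdp)
  }
  rexpVec <- function(rate) {
    w <- rep(Inf, length(rate))
    pos <- rate > 0
    if (any(pos)) w[pos] <- stats::rexp(sum(pos), rate[pos])
    w
  }

  nArr <- length(tArr)
  ids <- sprintf("P%05d", seq_len(nArr))
  tOffV <- numeric(nArr); censV <- logical(nArr)
  multV <- if (length(mults) == 1) rep(mults, nArr) else
    sample(mults, nArr, replace = TRUE, prob = params@oligomerWeights)
  x0V <- stats::runif(nArr, 0, latticeAt(tArr))
  landV <- ifelse(x0V <= seedLength, "seed", "gdp_lattice")

  ## frame-stepped, vectorized across currently bound particles; the
  ## detachment time inside each step is drawn exactly from the exponential
  ## with the particle's current rate (memoryless, so stepping preserves the
  ## exponential law on a homogeneous lattice)
  nSteps <- as.integer(ceiling(duration / frameInterval))
  sampId <- vector("list", nSteps + 1L)
  sampT <- vector("list", nSteps + 1L)
  sampX <- vector("list", nSteps + 1L)
  arrStep <- pmin(as.integer(floor(tArr / frameInterval)) + 1L, nSteps)

  aliveIdx <- integer(0); aliveX <- numeric(0); aliveT <- numeric(0)
  sdFull <- sqrt(2 * params@diffusionCoeff * frameInterval)

  for (k in seq_len(nSteps)) {
    tk1 <- min(k * frameInterval, duration)
    ## newcomers landing during this step
    newI <- which(arrStep == k)
    if (length(newI)) {
      aliveIdx <- c(aliveIdx, newI)
      aliveX <- c(aliveX, x0V[newI])
      aliveT <- c(aliveT, tArr[newI])
      sampId[[k]] <- newI
      sampT[[k]] <- tArr[newI]
      sampX[[k]] <- x0V[newI]
    }
    if (!length(aliveIdx)) next
    ## exact detachment within (aliveT, tk1]
    w <- rexpVec(rateOf(aliveX))
    det <- aliveT + w < tk1
    if (any(det)) {
      tOffV[aliveIdx[det]] <- aliveT[det] + w[det]
      aliveIdx <- aliveIdx[!det]; aliveX <- aliveX[!det]
      aliveT <- aliveT[!det]
    }
    if (!length(aliveIdx)) next
    if (tk1 >= duration) {
      tOffV[aliveIdx] <- duration
      censV[aliveIdx] <- TRUE
      aliveIdx <- integer(0)
      break
    }
    ## survivors diffuse to the frame boundary and are sampled there
    dt <- tk1 - aliveT
    aliveX <- aliveX + stats::rnorm(length(aliveX),
                                    0, sdFull * sqrt(dt / frameInterval))
    Lnow <- latticeAt(tk1)
    aliveX <- abs(aliveX)
    over <- aliveX > Lnow
    aliveX[over] <- 2 * Lnow - aliveX[over]
    bad <- aliveX < 0 | aliveX > Lnow
    if (any(bad)) aliveX[bad] <- stats::runif(sum(bad), 0, Lnow)
    if (dynamic && Lnow <= 0) {            # tip passed every binder
      tOffV[aliveIdx] <- tk1
      aliveIdx <- integer(0)
      next
    }
    aliveT <- rep(tk1, length(aliveIdx))
    sampId[[k]] <- c(sampId[[k]], aliveIdx)
    sampT[[k]] <- c(sampT[[k]], aliveT)
    sampX[[k]] <- c(sampX[[k]], aliveX)
  }

  idx <- unlist(sampId)
  ord <- order(idx, unlist(sampT))
  tracks <- if (length(idx)) data.frame(
    track_id = ids[idx][ord], channel = "binder",
    t_s = unlist(sampT)[ord], position_um = unlist(sampX)[ord],
    intensity = multV[idx][ord], stringsAsFactors = FALSE) else emptyTracks()
  dwells <- data.frame(
    track_id = ids, t_on_s = tArr, t_off_s = tOffV,
    dwell_s = tOffV - tArr, multiplicity = multV, censored = censV,
    landing_region = landV, stringsAsFactors = FALSE)

  list(tracks = tracks, dwells = dwells)
}

#' Simulate a FRAP bleach-and-recovery trace
#'
#' Forward model of a reaction-limited FRAP experiment in scaled units: the
#' pre-bleach intensity sits at 1.0, the bleach drops it instantaneously to
#' 0 at the bleach frame, and recovery follows
#' `plateau * (1 - exp(-kOff * t))` with `t = 0` at the bleach frame, plus
#' additive Gaussian noise of standard deviation `noiseSigma` on every
#' frame. A plateau below 1 models incomplete recovery.
#'
#' @param kOff True unbinding rate (1/s, >= 0).
#' @param plateau Recovery plateau as a fraction of the pre-bleach level
#'   (0 < plateau <= 1).
#' @param nPrebleach Number of pre-bleach frames (>= 2); the bleach occurs at
#'   frame `nPrebleach + 1`, i.e. at time `nPrebleach * frameInterval`.
#' @param frameInterval Frame interval (s).
#' @param noiseSigma Gaussian noise sd (fraction of the pre-bleach level).
#' @param nPostbleach Number of post-bleach frames (>= 2).
#' @param roiId,condition Labels stored on the trace.
#' @param rngSeed Optional integer seed.
#' @return A [FrapTrace-class] with `bleachIndex = nPrebleach + 1`.
#' @examples
#' tr <- simulateFrapTrace(kOff = 0.5, plateau = 0.8, nPrebleach = 55,
#'                         frameInterval = 0.2, noiseSigma = 0)
#' frapTimes(tr)[bleachIndex(tr)]  # 11 s
#' @export
simulateFrapTrace <- function(kOff, plateau = 0.8, nPrebleach = 55,
                              frameInterval = 0.2, noiseSigma = 0.05,
                              nPostbleach = 300, roiId = "roi",
                              condition = "unspecified", rngSeed = NULL) {
  if (!is.finite(kOff) || kOff < 0)
    stop("'kOff' must be a finite non-negative rate")
  if (plateau <= 0 || plateau > 1)
    stop("'plateau' must lie in (0, 1]")
  if (nPrebleach < 2 || nPostbleach < 2)
    stop("need at least 2 pre- and post-bleach frames")
  if (!is.null(rngSeed)) set.seed(rngSeed)

  n <- nPrebleach + nPostbleach
  times <- (seq_len(n) - 1) * frameInterval
  tBleach <- times[nPrebleach + 1L]
  y <- numeric(n)
  y[seq_len(nPrebleach)] <- 1
  post <- (nPrebleach + 1L):n
  y[post] <- plateau * (1 - exp(-kOff * (times[post] - tBleach)))
  if (noiseSigma > 0) y <- y + stats::rnorm(n, 0, noiseSigma)

  FrapTrace(times = times, intensities = y,
            bleachIndex = nPrebleach + 1L, roiId = roiId,
            condition = condition)
}

#' Simulate labelled actin-filament crosslinking events
#'
#' Constructs actin-channel particle tracks (with matched co-moving
#' crosslinker-channel tracks) that satisfy, by construction, the defining
#' criterion of each requested event class:
#' \describe{
#'   \item{bind_unbind}{the filament stays near its landing position with
#'     only sub-pixel jitter, then unbinds.}
#'   \item{sliding}{the filament start position moves monotonically along
#'     the lattice at `speed_um_per_s`.}
#'   \item{tip_tracking}{the filament position follows the microtubule tip
#'     within a fraction of a pixel for its whole duration.}
#'   \item{bundling}{a second filament joins partway through, producing a
#'     sustained step in the actin-channel intensity.}
#' }
#'
#' @param eventSpec data.frame with columns `label` (one of the four classes),
#'   `t_start_s`, `duration_s`, `start_position_um`, and optionally
#'   `speed_um_per_s` (sliding; default 0.1). See [defaultEventSpec()].
#' @param mt A [FilamentTrajectory-class] the events live on.
#' @param frameInterval Sampling interval (s).
#' @param pixelSize Pixel size (um/px), used to scale the sub-pixel jitter.
#' @param rngSeed Optional integer seed.
#' @return A list with `tracks` (long data.frame, channels "actin" and
#'   "anillin") and `events` (ground-truth event records as in
#'   [emptyEventRecords()], with `track_id` naming the actin track).
#' @export
simulateCrosslinkEvents <- function(eventSpec, mt, frameInterval = 2,
                                    pixelSize = 0.1, rngSeed = NULL) {
  known <- c("bind_unbind", "sliding", "tip_tracking", "bundling")
  bad <- setdiff(unique(eventSpec$label), known)
  if (length(bad))
    stop("unknown event label(s): ", paste(bad, collapse = ", "))
  if (!is.null(rngSeed)) set.seed(rngSeed)

  px <- pixelSize
  rowsT <- list(); rowsE <- list()
  for (i in seq_len(nrow(eventSpec))) {
    label <- eventSpec$label[i]
    tOn <- eventSpec$t_start_s[i]
    durE <- eventSpec$duration_s[i]
    x0 <- eventSpec$start_position_um[i]
    ts <- seq(tOn, tOn + durE, by = frameInterval)
    nF <- length(ts)
    if (nF < 5)
      stop("event ", i, " spans fewer than 5 frames; lengthen 'duration_s'")

    jitter <- stats::rnorm(nF - 1L, 0, 0.15 * px)
    if (label == "bind_unbind") {
      pos <- x0 + c(0, cumsum(jitter))
      intensity <- rep(1, nF)
      nFil <- 1L
    } else if (label == "sliding") {
      v <- if ("speed_um_per_s" %in% names(eventSpec) &&
               is.finite(eventSpec$speed_um_per_s[i]))
        eventSpec$speed_um_per_s[i] else 0.1
      pos <- x0 + c(0, cumsum(v * diff(ts) + jitter))
      intensity <- rep(1, nF)
      nFil <- 1L
    } else if (label == "tip_tracking") {
      tip <- tipPositionAt(mt, ts)
      dev <- pmin(pmax(stats::rnorm(nF, 0, 0.3 * px), -0.8 * px), 0.8 * px)
      pos <- tip + dev
      intensity <- rep(1, nF)
      nFil <- 1L
    } else {  # bundling
      pos <- x0 + c(0, cumsum(jitter))
      stepAt <- max(2L, floor(nF / 3))
      intensity <- c(rep(1, stepAt), rep(2.2, nF - stepAt))
      nFil <- 2L
    }

    id <- sprintf("E%04d", i)
    rowsT[[length(rowsT) + 1L]] <- data.frame(
      track_id = id, channel = "actin", t_s = ts, position_um = pos,
      intensity = intensity, stringsAsFactors = FALSE)
    ## co-moving crosslinker signal: same motion, small independent noise
    rowsT[[length(rowsT) + 1L]] <- data.frame(
      track_id = paste0(id, "_anillin"), channel = "anillin", t_s = ts,
      position_um = pos + stats::rnorm(nF, 0, 0.02 * px),
      intensity = rep(1, nF), stringsAsFactors = FALSE)

    tipOn <- tipPositionAt(mt, tOn)
    location <- if (pos[1] <= mt@seedReference) "seed"
      else if (abs(pos[1] - tipOn) <= 2 * px) "plus_tip"
      else "gdp_lattice"
    rowsE[[length(rowsE) + 1L]] <- data.frame(
      event_id = id, track_id = id, label = label, t_on_s = tOn,
      t_off_s = tOn + durE, residence_time_s = durE, n_filaments = nFil,
      location = location, stringsAsFactors = FALSE)
  }

  list(tracks = if (length(rowsT)) do.call(rbind, rowsT) else emptyTracks(),
       events = if (length(rowsE)) do.call(rbind, rowsE) else
         emptyEventRecords())
}

#' Build a balanced event specification on a microtubule
#'
#' Convenience constructor of an `eventSpec` for
#' [simulateCrosslinkEvents()]: `nPerClass` events of each class, spread
#' over the trajectory's duration, with start positions on the GDP lattice
#' well away from the tip (except tip-tracking events, which ride the tip).
#'
#' @param mt A [FilamentTrajectory-class].
#' @param nPerClass Events per class.
#' @param duration_s Duration of each event (s); at default sampling this is
#'   comfortably above the 4-frame (8 s) minimum.
#' @param frameInterval Sampling interval (s).
#' @return An event-spec data.frame.
#' @export
defaultEventSpec <- function(mt, nPerClass = 10, duration_s = 24,
                             frameInterval = 2) {
  labels <- rep(c("bind_unbind", "sliding", "tip_tracking", "bundling"),
                each = nPerClass)
  n <- length(labels)
  ## event durations spread around the base so residence times vary
  durs <- duration_s * rep_len(c(1, 0.75, 1.25, 1.5), n)
  durs <- pmax(durs, 5 * frameInterval)
  maxDur <- max(durs)
  seedRef <- mt@seedReference
  tEnd <- max(mt@times) - maxDur
  if (tEnd <= 0) stop("trajectory shorter than one event duration")
  ## lattice events need a lattice long enough that the tip never comes
  ## near them: only start once the tip stays >= 6 um above the seed for
  ## the whole event window
  grid <- seq(0, tEnd, by = 1)
  minTipOf <- function(t0) min(tipPositionAt(
    mt, seq(t0, t0 + maxDur, by = frameInterval)))
  spans <- vapply(grid, minTipOf, numeric(1)) - seedRef
  ok <- grid[spans >= 6]
  if (!length(ok))
    stop("lattice never reaches 6 um above the seed for a full event; ",
         "use a longer or faster-growing trajectory")
  tStart <- ok[unique(round(seq(1, length(ok), length.out = n)))]
  if (length(tStart) < n)   # few valid windows: reuse them round-robin
    tStart <- rep_len(ok, n)
  minTip <- vapply(tStart, minTipOf, numeric(1))
  ## lattice events sit in the lower quarter of the dynamic lattice,
  ## well below the tip's lowest excursion
  x0 <- seedRef + 0.25 * (minTip - seedRef)
  data.frame(label = labels, t_start_s = tStart, duration_s = durs,
             start_position_um = x0, speed_um_per_s = 0.1,
             stringsAsFactors = FALSE)
}

#' Render ground truth as TIRF-style kymographs
#'
#' Draws each channel of a [GroundTruth-class] as a kymograph (rows =
#' frames, columns = positions along the filament axis). Each emitter
#' contributes a Gaussian line-spread profile of width `psfSigma`,
#' integrated per pixel, scaled by `photonsPerFluor` times its intensity
#' multiplicity; a channel named `"mt"` (drawn when the truth carries a
#' trajectory) paints one unit emitter per pixel from the seed base to the
#' current tip. Background and noise follow `noiseModel`. The output is
#' deterministic given `rngSeed`.
#'
#' @param truth A [GroundTruth-class].
#' @param optics An [OpticsParams-class].
#' @param duration Rendered time (s); defaults to the span of the truth.
#' @param fieldLength Rendered axis length (um); defaults to the maximum
#'   extent plus a 1-um margin.
#' @param rngSeed Integer seed for the noise draws.
#' @return Named list of [Kymograph-class] objects, one per channel.
#' @export
renderKymograph <- function(truth, optics, duration = NULL,
                            fieldLength = NULL, rngSeed = 1L) {
  stopifnot(is(truth, "GroundTruth"), is(optics, "OpticsParams"))
  validObject(optics)
  set.seed(rngSeed)

  hasTraj <- length(truth@trajectory@times) > 0
  tAll <- c(if (hasTraj) max(truth@trajectory@times),
            if (nrow(truth@tracks)) max(truth@tracks$t_s))
  if (is.null(duration)) duration <- max(tAll, 0)
  if (duration <= 0) stop("nothing to render: zero duration")
  if (is.null(fieldLength)) {
    xAll <- c(if (hasTraj) max(truth@trajectory@tipPositions),
              if (nrow(truth@tracks)) max(truth@tracks$position_um), 0)
    fieldLength <- max(xAll) + 1
  }

  dt <- optics@frameInterval
  nFrames <- max(1L, floor(duration / dt))
  tMid <- (seq_len(nFrames) - 0.5) * dt
  nCols <- as.integer(ceiling(fieldLength / optics@pixelSize))
  sig <- optics@psfSigma

  depositRow <- function(row, xPx, amp) {
    if (sig <= 0) {
      j <- round(xPx) + 1L
      ok <- j >= 1L & j <= nCols
      if (any(ok)) {
        add <- tapply(amp[ok], j[ok], sum)
        idx <- as.integer(names(add))
        row[idx] <- row[idx] + as.numeric(add)
      }
      return(row)
    }
    win <- ceiling(6 * sig)
    cols <- seq_len(nCols) - 1L
    for (k in seq_along(xPx)) {
      jlo <- max(0L, floor(xPx[k] - win)); jhi <- min(nCols - 1L, ceiling(xPx[k] + win))
      if (jlo > jhi) next
      j <- jlo:jhi
      mass <- stats::pnorm((j + 0.5 - xPx[k]) / sig) -
              stats::pnorm((j - 0.5 - xPx[k]) / sig)
      row[j + 1L] <- row[j + 1L] + amp[k] * mass
    }
    row
  }

  channels <- unique(truth@tracks$channel)
  if (hasTraj) channels <- c("mt", channels)
  out <- list()
  trackIds <- unique(truth@tracks$track_id)

  for (ch in channels) {
    img <- matrix(optics@backgroundLevel, nrow = nFrames, ncol = nCols)
    for (f in seq_len(nFrames)) {
      xs <- numeric(); amps <- numeric()
      if (ch == "mt") {
        tip <- tipPositionAt(truth@trajectory, tMid[f]) / optics@pixelSize
        if (tip >= 0) {
          xs <- seq(0, tip, by = 1)
          amps <- rep(optics@photonsPerFluor, length(xs))
        }
      } else {
        sub <- truth@tracks[truth@tracks$channel == ch, , drop = FALSE]
        for (id in unique(sub$track_id)) {
          tr <- sub[sub$track_id == id, , drop = FALSE]
          if (tMid[f] < min(tr$t_s) || tMid[f] > max(tr$t_s)) next
          xs <- c(xs, stats::approx(tr$t_s, tr$position_um,
                                    xout = tMid[f])$y / optics@pixelSize)
          amps <- c(amps, optics@photonsPerFluor *
                      stats::approx(tr$t_s, tr$intensity, xout = tMid[f],
                                    method = "constant", rule = 2)$y)
        }
      }
      if (length(xs))
        img[f, ] <- depositRow(img[f, ], xs, amps)
    }
    if (optics@noiseModel %in% c("poisson", "poisson+gaussian"))
      img[] <- stats::rpois(length(img), pmax(img, 0))
    if (optics@noiseModel %in% c("gaussian", "poisson+gaussian"))
      img[] <- img + stats::rnorm(length(img), 0, optics@gaussianSigma)
    out[[ch]] <- Kymograph(img, optics@pixelSize, dt, channel = ch)
  }
  out
}
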