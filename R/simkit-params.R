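#' DynamicsParams: inputs to the dynamic-instability simulator
#'
#' Kinetic parameters of the two-state (growth/shrinkage) model of
#' microtubule dynamic instability. Defaults are plausible in vitro values
#' for tubulin-only assays at moderate tubulin concentration; they are
#' simulator inputs, not measured constants.
#'
#' @slot vGrowth Growth speed, um/min (> 0).
#' @slot vShrink Shrinkage speed, um/min, stored positive (> 0).
#' @slot fCat Catastrophe frequency, 1/s (>= 0): rate of growth-to-shrinkage
#'   switching per unit time spent growing.
#' @slot fRes Rescue frequency, 1/s (>= 0): rate of shrinkage-to-growth
#'   switching per unit time spent shrinking.
#' @slot seedLength Length of the stabilized seed, um (>= 0). Shrinkage
#'   stops at the seed and regrowth is forced; such restarts are logged as
#'   seed events, not rescues.
#' @slot duration Simulated observation time, s (> 0).
#' @slot rngSeed Integer seed for the simulation RNG.
#'
#' @seealso [simulateDynamicInstability()]
#' @export
setClass("DynamicsParams",
  representation(
    vGrowth = "numeric", vShrink = "numeric",
    fCat = "numeric", fRes = "numeric",
    seedLength = "numeric", duration = "numeric", rngSeed = "integer"
  )
)

setValidity("DynamicsParams", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1 && is.finite(x)
  if (!num1(object@vGrowth) || object@vGrowth <= 0)
    msg <- c(msg, "'vGrowth' must be a single finite positive number")
  if (!num1(object@vShrink) || object@vShrink <= 0)
    msg <- c(msg, "'vShrink' must be a single finite positive number")
  if (!num1(object@fCat) || object@fCat < 0)
    msg <- c(msg, "'fCat' must be a single finite non-negative number")
  if (!num1(object@fRes) || object@fRes < 0)
    msg <- c(msg, "'fRes' must be a single finite non-negative number")
  if (!num1(object@seedLength) || object@seedLength < 0)
    msg <- c(msg, "'seedLength' must be a single finite non-negative number")
  if (!num1(object@duration) || object@duration <= 0)
    msg <- c(msg, "'duration' must be a single finite positive number")
  if (length(msg)) msg else TRUE
})

#' Construct DynamicsParams
#'
#' @param vGrowth Growth speed (um/min).
#' @param vShrink Shrinkage speed (um/min, positive).
#' @param fCat Catastrophe frequency (1/s).
#' @param fRes Rescue frequency (1/s).
#' @param seedLength Stabilized seed length (um).
#' @param duration Observation time (s).
#' @param rngSeed Integer RNG seed.
#' @return A [DynamicsParams-class] object.
#' @examples
#' p <- DynamicsParams(vGrowth = 2, fCat = 0.005, duration = 600)
#' @export
DynamicsParams <- function(vGrowth = 2, vShrink = 30, fCat = 0.005,
                           fRes = 0.02, seedLength = 2, duration = 600,
                           rngSeed = 1L) {
  new("DynamicsParams", vGrowth = as.numeric(vGrowth),
      vShrink = as.numeric(vShrink), fCat = as.numeric(fCat),
      fRes = as.numeric(fRes), seedLength = as.numeric(seedLength),
      duration = as.numeric(duration), rngSeed = as.integer(rngSeed))
}

setMethod("show", "DynamicsParams", function(object) {
  cat("DynamicsParams:\n")
  cat(sprintf("  growth %.3g um/min, shrinkage %.3g um/min\n",
              object@vGrowth, object@vShrink))
  cat(sprintf("  f_cat %.3g 1/s, f_res %.3g 1/s\n", object@fCat, object@fRes))
  cat(sprintf("  seed %.3g um, duration %.3g s, seed %d\n",
              object@seedLength, object@duration, object@rngSeed))
})

#' BinderParams: inputs to the diffusive binder simulator
#'
#' Kinetics of a binder that lands on a filament lattice, diffuses along it
#' in 1-D, and unbinds with a lattice-dependent off-rate. The off-rate on the
#' stabilized (GMPCPP) seed can be set lower than on the dynamic GDP lattice,
#' reproducing the enrichment of the binder on seeds. Particle brightness
#' heterogeneity (oligomers) is modelled as an intensity multiplier only.
#'
#' @slot kOn Landing rate per micrometre of lattice per second.
#' @slot kOffGdp Off-rate on the GDP lattice, 1/s.
#' @slot kOffSeed Off-rate on the seed segment, 1/s.
#' @slot diffusionCoeff 1-D diffusion coefficient along the lattice, um^2/s.
#' @slot oligomerWeights Named numeric vector mapping intensity multiplicity
#'   (names, e.g. "1", "2") to probability; must sum to 1.
#' @slot rngSeed Integer RNG seed.
#'
#' @seealso [simulateBinderTracks()]
#' @export
setClass("BinderParams",
  representation(
    kOn = "numeric", kOffGdp = "numeric", kOffSeed = "numeric",
    diffusionCoeff = "numeric", oligomerWeights = "numeric",
    rngSeed = "integer"
  )
)

setValidity("BinderParams", function(object) {
  msg <- character()
  rates <- c(object@kOn, object@kOffGdp, object@kOffSeed,
             object@diffusionCoeff)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "all rates must be finite and non-negative")
  w <- object@oligomerWeights
  if (length(w) == 0 || is.null(names(w)) ||
      anyNA(suppressWarnings(as.numeric(names(w)))))
    msg <- c(msg, "'oligomerWeights' must be named by numeric multiplicity")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "'oligomerWeights' must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct BinderParams
#'
#' @param kOn Landing rate (per um per s).
#' @param kOffGdp Off-rate on the GDP lattice (1/s).
#' @param kOffSeed Off-rate on the seed (1/s).
#' @param diffusionCoeff 1-D diffusion coefficient (um^2/s).
#' @param oligomerWeights Named probabilities of intensity multiplicities.
#' @param rngSeed Integer RNG seed.
#' @return A [BinderParams-class] object.
#' @export
BinderParams <- function(kOn = 0.05, kOffGdp = 1.07, kOffSeed = 0.26,
                         diffusionCoeff = 0.05,
                         oligomerWeights = c("1" = 0.7, "2" = 0.2, "4" = 0.1),
                         rngSeed = 1L) {
  new("BinderParams", kOn = as.numeric(kOn), kOffGdp = as.numeric(kOffGdp),
      kOffSeed = as.numeric(kOffSeed),
      diffusionCoeff = as.numeric(diffusionCoeff),
      oligomerWeights = oligomerWeights, rngSeed = as.integer(rngSeed))
}

setMethod("show", "BinderParams", function(object) {
  cat("BinderParams:\n")
  cat(sprintf("  k_on %.3g /um/s, k_off GDP %.3g 1/s, k_off seed %.3g 1/s\n",
              object@kOn, object@kOffGdp, object@kOffSeed))
  cat(sprintf("  D %.3g um^2/s, multiplicities: %s\n", object@diffusionCoeff,
              paste0(names(object@oligomerWeights), " (",
                     object@oligomerWeights, ")", collapse = ", ")))
})

#' OpticsParams: TIRF-style rendering parameters
#'
#' Describes how ground-truth emitter positions are turned into a noisy
#' kymograph image: pixel calibration, point-spread blur, photon yield,
#' background and noise model.
#'
#' @slot pixelSize Pixel size, um/px (> 0).
#' @slot frameInterval Frame interval, s (> 0).
#' @slot psfSigma Gaussian point-spread sigma, px (>= 0).
#' @slot photonsPerFluor Expected counts contributed by a multiplicity-1
#'   emitter.
#' @slot backgroundLevel Constant background counts per pixel.
#' @slot noiseModel One of `"none"`, `"poisson"`, `"gaussian"`,
#'   `"poisson+gaussian"`.
#' @slot gaussianSigma Standard deviation of the additive Gaussian read
#'   noise (counts).
#'
#' @seealso [renderKymograph()]
#' @export
setClass("OpticsParams",
  representation(
    pixelSize = "numeric", frameInterval = "numeric", psfSigma = "numeric",
    photonsPerFluor = "numeric", backgroundLevel = "numeric",
    noiseModel = "character", gaussianSigma = "numeric"
  )
)

setValidity("OpticsParams", function(object) {
  msg <- character()
  if (object@pixelSize <= 0 || object@frameInterval <= 0)
    msg <- c(msg, "'pixelSize' and 'frameInterval' must be positive")
  if (object@psfSigma < 0)
    msg <- c(msg, "'psfSigma' must be non-negative")
  if (!object@noiseModel %in%
      c("none", "poisson", "gaussian", "poisson+gaussian"))
    msg <- c(msg, "unknown 'noiseModel'")
  if (length(msg)) msg else TRUE
})

#' Construct OpticsParams
#'
#' @param pixelSize Pixel size (um/px).
#' @param frameInterval Frame interval (s).
#' @param psfSigma PSF sigma (px).
#' @param photonsPerFluor Expected counts for one fluorophore unit.
#' @param backgroundLevel Background counts per pixel.
#' @param noiseModel `"none"`, `"poisson"`, `"gaussian"` or
#'   `"poisson+gaussian"`.
#' @param gaussianSigma Read-noise standard deviation (counts).
#' @return An [OpticsParams-class] object.
#' @export
OpticsParams <- function(pixelSize = 0.1, frameInterval = 2, psfSigma = 1.3,
                         photonsPerFluor = 200, backgroundLevel = 100,
                         noiseModel = "poisson", gaussianSigma = 10) {
  new("OpticsParams", pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      psfSigma = as.numeric(psfSigma),
      photonsPerFluor = as.numeric(photonsPerFluor),
      backgroundLevel = as.numeric(backgroundLevel),
      noiseModel = as.character(noiseModel),
      gaussianSigma = as.numeric(gaussianSigma))
}

setMethod("show", "OpticsParams", function(object) {
  cat("OpticsParams:\n")
  cat(sprintf("  %.3g um/px, %.3g s/frame, PSF sigma %.3g px\n",
              object@pixelSize, object@frameInterval, object@psfSigma))
  cat(sprintf("  %.4g counts/fluor, background %.4g, noise: %s\n",
              object@photonsPerFluor, object@backgroundLevel,
              object@noiseModel))
})

#' GroundTruth: simulated truth for one rendered field
#'
#' Bundles a filament trajectory, its phase log, the particle tracks on it
#' and the labelled crosslinking events, so that a renderer can draw them and
#' downstream estimators can be validated against known truth.
#'
#' @slot trajectory A [FilamentTrajectory-class] (or `NULL`-like empty one).
#' @slot phaseLog Phase-segment data.frame (see
#'   [simulateDynamicInstability()]).
#' @slot tracks Long-format particle-track data.frame (see
#'   [simulateBinderTracks()]).
#' @slot eventLabels Event-record data.frame (see
#'   [simulateCrosslinkEvents()]).
#'
#' @export
setClass("GroundTruth",
  representation(
    trajectory = "FilamentTrajectory",
    phaseLog = "data.frame",
    tracks = "data.frame",
    eventLabels = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@eventLabels) && nrow(object@tracks)) {
    if (!all(object@eventLabels$track_id %in% object@tracks$track_id))
      msg <- c(msg, "event labels must reference existing tracks")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GroundTruth bundle
#'
#' @param trajectory A [FilamentTrajectory-class].
#' @param phaseLog Phase-segment data.frame.
#' @param tracks Particle-track data.frame.
#' @param eventLabels Event-record data.frame.
#' @return A [GroundTruth-class] object.
#' @export
GroundTruth <- function(trajectory = FilamentTrajectory(numeric(), numeric()),
                        phaseLog = emptyPhaseLog(),
                        tracks = emptyTracks(),
                        eventLabels = emptyEventRecords()) {
  new("GroundTruth", trajectory = trajectory, phaseLog = phaseLog,
      tracks = tracks, eventLabels = eventLabels)
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:\n")
  cat(sprintf("  trajectory: %d points; phase log: %d segments\n",
              length(object@trajectory@times), nrow(object@phaseLog)))
  cat(sprintf("  tracks: %d (%d samples); labelled events: %d\n",
              length(unique(object@tracks$track_id)), nrow(object@tracks),
              nrow(object@eventLabels)))
})

## empty tabular prototypes (column contracts)

#' @rdname GroundTruth
#' @export
emptyPhaseLog <- function() {
  data.frame(kind = character(), t_start_s = numeric(), t_end_s = numeric(),
             duration_s = numeric(), speed_um_per_min = numeric(),
             displacement_um = numeric(), terminal_event = character(),
             stringsAsFactors = FALSE)
}

#' @rdname GroundTruth
#' @export
emptyTracks <- function() {
  data.frame(track_id = character(), channel = character(), t_s = numeric(),
             position_um = numeric(), intensity = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname GroundTruth
#' @export
emptyEventRecords <- function() {
  data.frame(event_id = character(), track_id = character(),
             label = character(), t_on_s = numeric(), t_off_s = numeric(),
             residence_time_s = numeric(), n_filaments = integer(),
             location = character(), stringsAsFactors = FALSE)
}
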