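test_that("a microtubule with no catastrophes grows deterministically", {
  sim <- simulateDynamicInstability(
    DynamicsParams(vGrowth = 2, fCat = 0, duration = 300, seedLength = 0))
  expect_equal(tail(tipPositions(sim$trajectory), 1), 10)
  expect_identical(sim$phaseLog$kind, "growth")
  expect_identical(sim$phaseLog$terminal_event, "end")
})

test_that("phase log partitions the observation window", {
  sim <- simulateDynamicInstability(
    DynamicsParams(fCat = 0.01, fRes = 0.05, duration = 900, rngSeed = 5))
  pl <- sim$phaseLog
  expect_equal(pl$t_start_s[1], 0)
  expect_equal(tail(pl$t_end_s, 1), 900)
  expect_equal(pl$t_start_s[-1], pl$t_end_s[-nrow(pl)])
  expect_true(all(pl$duration_s > 0))
  # length never below the seed
  expect_true(all(tipPositions(sim$trajectory) >= 2 - 1e-9))
})

test_that("growth-phase durations are exponential with rate fCat", {
  # closed-form mean of the exponential as the oracle
  durations <- unlist(lapply(1:40, function(s) {
    pl <- simulateDynamicInstability(
      DynamicsParams(fCat = 0.01, fRes = 0, vShrink = 60, seedLength = 0,
                     duration = 3000, rngSeed = s))$phaseLog
    g <- pl[pl$kind == "growth" & pl$terminal_event == "catastrophe", ]
    g$duration_s
  }))
  expect_gt(length(durations), 200)
  se <- sd(durations) / sqrt(length(durations))
  expect_lt(abs(mean(durations) - 100), 3 * se)
})

test_that("time in growth matches the two-state stationary fraction", {
  # stationary distribution f_res / (f_cat + f_res) as the oracle
  sim <- simulateDynamicInstability(
    DynamicsParams(vGrowth = 5, vShrink = 1, fCat = 0.005, fRes = 0.05,
                   seedLength = 0, duration = 10000, rngSeed = 7))
  fg <- sum(sim$phaseLog$duration_s[sim$phaseLog$kind == "growth"]) / 10000
  expect_lt(abs(fg - 0.05 / 0.055), 0.03)
})

test_that("seed-forced restarts are logged as seed events, not rescues", {
  sim <- simulateDynamicInstability(
    DynamicsParams(vGrowth = 2, vShrink = 60, fCat = 0.02, fRes = 0,
                   seedLength = 2, duration = 2000, rngSeed = 3))
  pl <- sim$phaseLog
  expect_true(any(pl$terminal_event == "seed"))
  expect_false(any(pl$terminal_event == "rescue"))  # fRes = 0
})

test_that("non-finite dynamics parameters are rejected", {
  expect_error(DynamicsParams(vGrowth = NaN), "finite")
  expect_error(DynamicsParams(fCat = -0.1), "non-negative")
  expect_error(DynamicsParams(duration = 0), "positive")
})

test_that("binder dwell times on a homogeneous lattice are exponential", {
  bp <- BinderParams(kOn = 2, kOffGdp = 0.1, kOffSeed = 0.1,
                     diffusionCoeff = 0.02, oligomerWeights = c("1" = 1),
                     rngSeed = 11)
  sim <- simulateBinderTracks(bp, lattice = 10, duration = 600,
                              frameInterval = 0.1)
  d <- sim$dwells$dwell_s[!sim$dwells$censored]
  expect_gt(length(d), 5000)
  # median of the exponential: ln 2 / rate
  expect_lt(abs(median(d) - log(2) / 0.1) / (log(2) / 0.1), 0.05)
  # Kolmogorov-Smirnov against the input rate
  ks <- suppressWarnings(ks.test(d, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero diffusion keeps every binder track in place", {
  bp <- BinderParams(kOn = 0.5, kOffGdp = 0.2, kOffSeed = 0.2,
                     diffusionCoeff = 0, oligomerWeights = c("1" = 1),
                     rngSeed = 4)
  sim <- simulateBinderTracks(bp, lattice = 8, duration = 100,
                              frameInterval = 0.2)
  spans <- tapply(sim$tracks$position_um, sim$tracks$track_id,
                  function(p) diff(range(p)))
  expect_true(all(spans == 0))
})

test_that("binders are enriched on the low-off-rate seed segment", {
  bp <- BinderParams(kOn = 1, kOffGdp = 1, kOffSeed = 0.2,
                     diffusionCoeff = 0.01, oligomerWeights = c("1" = 1),
                     rngSeed = 3)
  sim <- simulateBinderTracks(bp, lattice = 10, duration = 300,
                              frameInterval = 0.1, seedLength = 2)
  tr <- sim$tracks
  densSeed <- sum(tr$position_um <= 2) / 2
  densGdp <- sum(tr$position_um > 2) / 8
  expect_gt(densSeed / densGdp, 2)  # mean-dwell ratio is 5; mixing dilutes
})

test_that("a zero-length lattice yields an empty result with a warning", {
  bp <- BinderParams(rngSeed = 1)
  expect_warning(sim <- simulateBinderTracks(bp, lattice = 0, duration = 10),
                 "zero-length")
  expect_identical(nrow(sim$tracks), 0L)
})

test_that("noiseless FRAP traces equal the closed-form model", {
  tr <- simulateFrapTrace(kOff = 0.5, plateau = 0.8, nPrebleach = 55,
                          frameInterval = 0.2, noiseSigma = 0,
                          nPostbleach = 200)
  t <- frapTimes(tr); y <- frapIntensities(tr)
  expect_equal(frapTimes(tr)[bleachIndex(tr)], 11.0)
  expect_equal(y[1:55], rep(1, 55))
  post <- 56:length(y)
  expect_equal(y[post], 0.8 * (1 - exp(-0.5 * (t[post] - 11))))
  expect_error(simulateFrapTrace(kOff = -1), "non-negative")
})

test_that("constructed crosslinking events satisfy their defining criteria", {
  mt <- eventStageMt()
  spec <- data.frame(label = c("sliding", "tip_tracking"),
                     t_start_s = c(300, 340), duration_s = 24,
                     start_position_um = 4, speed_um_per_s = 0.1)
  lib <- simulateCrosslinkEvents(spec, mt, frameInterval = 2,
                                 pixelSize = 0.1, rngSeed = 8)
  slide <- lib$tracks[lib$tracks$track_id == "E0001", ]
  expect_true(all(diff(slide$position_um) > 0))
  expect_equal(tail(slide$position_um, 1) - slide$position_um[1],
               0.1 * 24, tolerance = 0.05)
  tipTr <- lib$tracks[lib$tracks$track_id == "E0002", ]
  expect_true(all(abs(tipTr$position_um -
                        tipPositionAt(mt, tipTr$t_s)) <= 0.1))  # 1 px
  expect_error(
    simulateCrosslinkEvents(data.frame(label = "teleport", t_start_s = 1,
                                       duration_s = 24,
                                       start_position_um = 3), mt),
    "unknown event label")
})

test_that("rendering is conservative and deterministic", {
  tracks <- data.frame(track_id = "T1", channel = "binder",
                       t_s = c(0, 60), position_um = c(3, 3), intensity = 2)
  gt <- GroundTruth(tracks = tracks)
  opt <- OpticsParams(pixelSize = 0.1, frameInterval = 2, psfSigma = 1.3,
                      photonsPerFluor = 200, backgroundLevel = 7,
                      noiseModel = "none")
  ky <- renderKymograph(gt, opt, duration = 60, fieldLength = 6,
                        rngSeed = 1)$binder
  d <- kymoData(ky)
  # Gaussian mass inside the field (emitter at 30 px, sigma 1.3, 60 cols)
  mass <- pnorm((59.5 - 30) / 1.3) - pnorm((-0.5 - 30) / 1.3)
  expect_equal(sum(d - 7) / nrow(d), 2 * 200 * mass, tolerance = 1e-6)

  # dark emitters: constant background everywhere
  dark <- tracks; dark$intensity <- 0
  blank <- renderKymograph(GroundTruth(tracks = dark), opt, duration = 60,
                           fieldLength = 6, rngSeed = 1)$binder
  expect_true(all(kymoData(blank) == 7))

  # identical seeds give bit-identical images, noisy or not
  opt2 <- OpticsParams(noiseModel = "poisson")
  k1 <- renderKymograph(gt, opt2, duration = 60, fieldLength = 6,
                        rngSeed = 42)$binder
  k2 <- renderKymograph(gt, opt2, duration = 60, fieldLength = 6,
                        rngSeed = 42)$binder
  expect_identical(kymoData(k1), kymoData(k2))
})

test_that("simulations replay bit-identically under a fixed seed", {
  p <- DynamicsParams(fCat = 0.01, fRes = 0.03, duration = 500, rngSeed = 99)
  expect_identical(simulateDynamicInstability(p),
                   simulateDynamicInstability(p))
  bp <- BinderParams(rngSeed = 21)
  expect_identical(simulateBinderTracks(bp, 10, 50),
                   simulateBinderTracks(bp, 10, 50))
})
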