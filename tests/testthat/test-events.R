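test_that("residence time is unbinding minus landing time", {
  d <- data.frame(track_id = "a", t_on_s = 10, t_off_s = 30)
  r <- residenceTimes(d, frameInterval = 2, movieDuration = 600)
  expect_equal(r$dwells$dwell_s, 20)
  expect_equal(r$n_censored, 0L)
  # empty input
  e <- residenceTimes(emptyTracks(), 2, 600)
  expect_equal(nrow(e$dwells), 0)
})

test_that("synthetic exponential dwells reproduce the closed-form median", {
  # movie much longer than the mean dwell, so end-censoring is negligible
  bp <- BinderParams(kOn = 0.6, kOffGdp = 0.1, kOffSeed = 0.1,
                     diffusionCoeff = 0.02, oligomerWeights = c("1" = 1),
                     rngSeed = 61)
  sim <- simulateBinderTracks(bp, lattice = 10, duration = 2000,
                              frameInterval = 0.1)
  r <- residenceTimes(sim$dwells, 0.1, 2000)
  expect_gt(nrow(r$dwells), 8000)
  expect_lt(abs(r$summary$median_s - log(2) / 0.1) / (log(2) / 0.1), 0.02)
  # censoring safety: no dwell can exceed the movie duration
  expect_true(all(r$dwells$dwell_s <= 2000))
  expect_gt(r$n_censored, 0)
})

test_that("the diffusion filter separates static from diffusing tracks", {
  set.seed(9)
  static <- data.frame(track_id = "s", channel = "binder",
                       t_s = 0:19 * 2, position_um = rep(3, 20),
                       intensity = 1)
  walk <- data.frame(track_id = "w", channel = "binder", t_s = 0:19 * 2,
                     position_um = 3 + cumsum(rnorm(20, 0, 0.1)),
                     intensity = 1)
  out <- diffusionFilter(rbind(static, walk), minPositionalSdPx = 0.5,
                         pixelSize = 0.1)
  expect_identical(unique(out$kept$track_id), "w")
  expect_identical(unique(out$discarded$track_id), "s")
  expect_match(out$reasons$reason, "below threshold")
  # zero threshold keeps everything that moves at all, and statics too
  all0 <- diffusionFilter(rbind(static, walk), minPositionalSdPx = 0,
                          pixelSize = 0.1)
  expect_identical(sort(unique(all0$kept$track_id)), c("s", "w"))
})

test_that("tracks below four frames are rejected as binding events", {
  mt <- eventStageMt()
  short <- data.frame(track_id = "s1", channel = "actin",
                      t_s = c(0, 2, 4), position_um = rep(5, 3),
                      intensity = 1)
  r <- classifyEvent(short, mt, frameInterval = 2)
  expect_equal(nrow(r), 0)
  expect_match(attr(r, "reason"), "below 4 frames \\(8 s\\)")
})

test_that("the classifier recovers a 40-event labelled library", {
  mt <- eventStageMt(seed = 2)
  lib <- simulateCrosslinkEvents(defaultEventSpec(mt, nPerClass = 10), mt,
                                 frameInterval = 2, pixelSize = 0.1,
                                 rngSeed = 902)
  cls <- classifyEvents(lib$tracks, mt, frameInterval = 2)
  pred <- cls$events$label[match(lib$events$track_id,
                                 cls$events$track_id)]
  expect_equal(nrow(lib$events), 40)
  expect_identical(pred, lib$events$label)     # diagonal confusion matrix
  expect_equal(nrow(cls$rejected), 0)
})

test_that("classifier accuracy degrades as positional noise grows", {
  mt <- eventStageMt(seed = 3)
  lib <- simulateCrosslinkEvents(defaultEventSpec(mt, nPerClass = 5), mt,
                                 frameInterval = 2, pixelSize = 0.1,
                                 rngSeed = 31)
  accAt <- function(sdUm, seed) {
    set.seed(seed)
    noisy <- lib$tracks
    noisy$position_um <- noisy$position_um + rnorm(nrow(noisy), 0, sdUm)
    cls <- classifyEvents(noisy, mt, frameInterval = 2)
    pred <- cls$events$label[match(lib$events$track_id,
                                   cls$events$track_id)]
    # a rejected track is a misclassification, not a missing value
    mean(!is.na(pred) & pred == lib$events$label)
  }
  clean <- accAt(0, 1)
  rough <- mean(vapply(1:3, function(s) accAt(0.5, s), numeric(1)))
  expect_gte(clean, rough)   # monotone trend, not a fixed bound
  expect_equal(clean, 1)
})

test_that("bundled and single residence times are compared by rank test", {
  set.seed(12)
  bundled <- rexp(28, 1 / 6.7)
  single <- rexp(32, 1 / 2)
  r <- compareResidence(bundled, single)
  expect_equal(r$n_bundled, 28)
  expect_equal(r$n_single, 32)
  expect_equal(r$mean_bundled_s, mean(bundled))
  expect_lt(pValue(r$test), 0.01)
  same <- compareResidence(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pValue(same$test), 1)
  expect_warning(compareResidence(c(1, 2), c(1, 2, 3)), "unreliable")
})

test_that("a rate contrast of 3x is detected in most repeats", {
  # power check for exponential samples with a 3-fold rate ratio; the
  # stochastic ordering P(X < Y) = 0.75 puts the attainable power at
  # alpha = 0.01, n = 30 near 0.8
  hits <- vapply(1:200, function(s) {
    set.seed(7000 + s)
    pValue(mannWhitneyU(rexp(30, 1), rexp(30, 3))) < 0.01
  }, logical(1))
  expect_gt(mean(hits), 0.7)
})

test_that("overlap length and normalized intensities behave as built", {
  nT <- 30; nX <- 60
  bgLevel <- 10
  actin <- matrix(bgLevel, nT, nX)
  anillin <- matrix(bgLevel, nT, nX)
  # actin filament sliding onto the microtubule: overlap grows 1 col/frame
  for (f in 1:nT) {
    cover <- min(10 + f, 40)
    actin[f, 11:cover] <- 100
    anillin[f, 11:cover] <- 60
  }
  ka <- Kymograph(actin, 0.1, 2); kb <- Kymograph(anillin, 0.1, 2)
  tc <- overlapTimecourse(ka, kb, mtExtent = c(11, 40),
                          backgroundCols = 50:60)
  expect_true(all(diff(tc$overlap_length_um) >= 0))
  plateau <- tc$overlap_length_um[tc$t_s >= 2 * 29]
  expect_equal(unique(plateau), 3.0)           # 30 columns x 0.1 um
  expect_equal(max(tc$actin_intensity_norm), 1)
  expect_equal(max(tc$anillin_intensity_norm), 1)
  expect_error(overlapTimecourse(ka, Kymograph(anillin[, 1:30], 0.1, 2),
                                 c(11, 40), 25:30), "registered")
})

test_that("overlap enrichment is self-normalized to the bare lattice", {
  set.seed(33)
  mtOnly <- rgamma(40, 4, 2)
  overlap <- mtOnly * 3
  r <- overlapEnrichment(overlap, mtOnly)
  expect_equal(r$mean_mt_only, 1)
  expect_equal(r$mean_overlap, 3)
  expect_lt(pValue(r$test), 0.01)
  expect_error(overlapEnrichment(overlap, -mtOnly), "positive")
})
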