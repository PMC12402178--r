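test_that("slopes from anchors reproduce hand-computed phases", {
  segs <- slopesFromAnchors(data.frame(position_um = c(0, 1, 0.2),
                                       t_s = c(0, 30, 40)))
  expect_equal(segs$kind, c("growth", "shrink"))
  expect_equal(segs$speed_um_per_min, c(2.0, -4.8))
  expect_equal(segs$duration_s, c(30, 10))
  # sub-band slope labelled pause
  p <- slopesFromAnchors(data.frame(position_um = c(0, 0.01),
                                    t_s = c(0, 60)))
  expect_equal(p$kind, "pause")
  expect_error(slopesFromAnchors(data.frame(position_um = c(0, 1),
                                            t_s = c(5, 5))), "duplicate")
})

test_that("weighted speed matches the hand-evaluated formulas", {
  segs <- data.frame(kind = "growth", t_start_s = c(0, 10),
                     t_end_s = c(10, 40), duration_s = c(10, 30),
                     speed_um_per_min = c(1, 3),
                     displacement_um = c(1 / 6, 1.5))
  ws <- weightedSpeed(segs, "growth")
  expect_equal(ws$weighted_mean, 2.5)
  expect_equal(ws$weighted_se, sqrt(1.5))
  # equal speeds: zero deviations, zero SE
  eq <- segs; eq$speed_um_per_min <- c(2, 2)
  expect_equal(weightedSpeed(eq, "growth")$weighted_se, 0)
  # single segment: SE undefined
  one <- weightedSpeed(segs[1, ], "growth")
  expect_equal(one$weighted_mean, 1)
  expect_true(is.na(one$weighted_se))
  expect_error(weightedSpeed(segs, "shrink"), "no segments")
})

test_that("weighted statistics agree with brute-force evaluation", {
  set.seed(1203)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    segs <- randomSegments(n)
    ws <- weightedSpeed(segs, "growth")
    ref <- refWeightedStats(segs$speed_um_per_min, segs$duration_s)
    expect_equal(ws$weighted_mean, ref$mean, tolerance = 1e-12)
    expect_equal(ws$weighted_se, ref$se, tolerance = 1e-10)
    # algebraic identity: weighted mean == total displacement / total time
    expect_equal(ws$weighted_mean,
                 sum(segs$displacement_um) / sum(segs$duration_s) * 60,
                 tolerance = 1e-12)
  }
})

test_that("speeds and SEs scale with positions; frequencies do not", {
  set.seed(88)
  segs <- randomSegments(8)
  a <- 3.7
  scaled <- segs
  scaled$speed_um_per_min <- a * segs$speed_um_per_min
  scaled$displacement_um <- a * segs$displacement_um
  w0 <- weightedSpeed(segs, "growth"); w1 <- weightedSpeed(scaled, "growth")
  expect_equal(w1$weighted_mean, a * w0$weighted_mean)
  expect_equal(w1$weighted_se, a * w0$weighted_se)
  # frequencies depend only on kinds and durations
  two <- rbind(segs, randomSegments(8, kind = "shrink", seedSign = -1))
  two2 <- two
  two2$speed_um_per_min <- a * two$speed_um_per_min
  expect_equal(eventFrequencies(two)$frequency_per_s,
               eventFrequencies(two2)$frequency_per_s)
})

test_that("event frequencies follow counts over exposure", {
  # 4 catastrophes over 200 s of growth: 0.02 +/- 0.01 per s
  segs <- do.call(rbind, lapply(1:4, function(i) data.frame(
    kind = c("growth", "shrink"),
    t_start_s = c(0, 50) + (i - 1) * 55, t_end_s = c(50, 55) + (i - 1) * 55,
    duration_s = c(50, 5), speed_um_per_min = c(2, -20),
    displacement_um = c(5 / 3, -5 / 3))))
  fq <- eventFrequencies(segs)
  cat <- fq[fq$kind == "catastrophe", ]
  expect_equal(cat$n_events, 4L)
  expect_equal(cat$frequency_per_s, 0.02)
  expect_equal(cat$error_per_s, 0.01)
  # zero events: frequency 0, error undefined
  g <- segs[segs$kind == "growth", ][1, ]
  fq0 <- eventFrequencies(rbind(g, segs[segs$kind == "shrink", ][1, ]))
  res <- fq0[fq0$kind == "rescue", ]
  expect_equal(res$frequency_per_s, 0)
  expect_true(is.na(res$error_per_s))
})

test_that("growth-pause-shrink counts as a single catastrophe", {
  segs <- data.frame(
    kind = c("growth", "pause", "shrink"),
    t_start_s = c(0, 100, 130), t_end_s = c(100, 130, 150),
    duration_s = c(100, 30, 20), speed_um_per_min = c(2, 0.05, -10),
    displacement_um = c(100 / 30, 0.025, -10 / 3))
  fq <- eventFrequencies(segs)
  expect_equal(fq$n_events[fq$kind == "catastrophe"], 1L)
  # pauses excluded from exposure
  expect_equal(fq$exposure_s[fq$kind == "catastrophe"], 100)
})

test_that("simulated frequencies are recovered within the counting error", {
  segLists <- lapply(1:100, function(s) simulateDynamicInstability(
    DynamicsParams(fCat = 0.005, fRes = 0.02, vShrink = 15,
                   duration = 900, rngSeed = 4000 + s))$phaseLog)
  fq <- eventFrequencies(segLists)
  cat <- fq[fq$kind == "catastrophe", ]
  res <- fq[fq$kind == "rescue", ]
  expect_lt(abs(cat$frequency_per_s - 0.005), 3 * cat$error_per_s)
  expect_lt(abs(res$frequency_per_s - 0.02), 3 * res$error_per_s)
  # relative bias stays small with hundreds of events
  expect_gt(cat$n_events, 200)
  expect_lt(abs(cat$frequency_per_s - 0.005) / 0.005, 0.05)
})

test_that("automatic segmentation finds noiseless transitions", {
  p <- DynamicsParams(vGrowth = 3, vShrink = 6, fCat = 0.01, fRes = 0,
                      seedLength = 1, duration = 400, rngSeed = 12)
  sim <- simulateDynamicInstability(p)
  tr <- sampleAtFrames(sim$trajectory, 1, 400)
  segs <- segmentAuto(tr)
  trueCat <- sim$phaseLog$t_end_s[sim$phaseLog$terminal_event ==
                                    "catastrophe"]
  expect_gte(sum(segs$kind == "shrink"), 1)
  for (tc in trueCat) {
    expect_lt(min(abs(segs$t_end_s - tc)), 1.5)  # within one 1-s frame
  }
  # recovered speeds match the simulator inputs
  expect_equal(unique(round(segs$speed_um_per_min[segs$kind == "growth"])),
               3)
})

test_that("pure growth yields one segment; white noise yields no phases", {
  pure <- FilamentTrajectory(times = 0:99, tipPositions = 0:99 * 0.05)
  expect_equal(nrow(segmentAuto(pure)), 1)
  expect_equal(segmentAuto(pure)$kind, "growth")
  set.seed(5)
  noise <- FilamentTrajectory(times = 0:199,
                              tipPositions = rnorm(200, 5, 0.05))
  segsN <- segmentAuto(noise)
  expect_true(all(segsN$kind == "pause"))
  # constant trace: single pause segment
  flat <- FilamentTrajectory(times = 0:10, tipPositions = rep(2, 11))
  expect_equal(segmentAuto(flat)$kind, "pause")
})

test_that("condition comparisons use the Welch test", {
  cmp <- compareDynamics(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(cmp$tests$t, -3.674, tolerance = 1e-3)
  expect_equal(cmp$tests$df, 4, tolerance = 1e-9)
  same <- compareDynamics(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$tests$p, 1)
  small <- compareDynamics(list(a = 1, b = c(1, 2)))
  expect_true(is.na(small$tests$p))
  expect_match(small$tests$note, "insufficient")
})
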