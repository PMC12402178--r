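test_that("normalization maps the post-bleach minimum to zero", {
  tr <- FrapTrace(times = 0:9,
                  intensities = c(100, 100, 100, 20, 40, 55, 60, 65, 70, 72),
                  bleachIndex = 4)
  nt <- normalizeFrap(tr)
  y <- frapIntensities(nt)
  expect_equal(y[4], 0)                       # minimum maps exactly to 0
  expect_equal(y[6], (55 - 20) / 100)         # value 55 -> 0.35
  expect_equal(y[1:3], rep((100 - 20) / 100, 3))
  expect_equal(frapTimes(nt)[4], 0)           # time re-zeroed at the minimum
  # a value of 60 with pre-mean 100 and min 20 maps to 0.40
  expect_equal((60 - 20) / 100, 0.4)
  expect_equal(y[7], 0.4)
})

test_that("normalization is idempotent on normalized traces", {
  tr <- simulateFrapTrace(kOff = 0.5, plateau = 0.8, nPrebleach = 10,
                          frameInterval = 0.2, noiseSigma = 0,
                          nPostbleach = 50)
  # construct a trace already in normalized form: min_post 0, pre mean 1
  n1 <- normalizeFrap(tr)
  scaled <- FrapTrace(times = frapTimes(n1) - min(frapTimes(n1)),
                      intensities = frapIntensities(n1) /
                        mean(frapIntensities(n1)[seq_len(bleachIndex(n1) -
                                                           1)]),
                      bleachIndex = bleachIndex(n1))
  n2 <- normalizeFrap(scaled)
  expect_equal(frapIntensities(n2), frapIntensities(scaled),
               tolerance = 1e-12)
  expect_error(normalizeFrap(FrapTrace(0:9, rep(0, 10), 5)), "zero")
})

test_that("noiseless simulated traces normalize to the exact closed form", {
  tr <- simulateFrapTrace(kOff = 0.5, plateau = 0.8, nPrebleach = 20,
                          frameInterval = 0.2, noiseSigma = 0,
                          nPostbleach = 120)
  nt <- normalizeFrap(tr)
  post <- frapTimes(nt) >= 0
  expect_equal(frapIntensities(nt)[post],
               0.8 * (1 - exp(-0.5 * frapTimes(nt)[post])),
               tolerance = 1e-12)
})

test_that("the exponential fit recovers noiseless parameters exactly", {
  tr <- simulateFrapTrace(kOff = 0.5, plateau = 0.8, nPrebleach = 55,
                          frameInterval = 0.2, noiseSigma = 0,
                          nPostbleach = 200)
  fit <- fitKoff(normalizeFrap(tr))
  expect_true(fit@converged)
  expect_equal(kOff(fit), 0.5, tolerance = 1e-6)
  expect_equal(fit@A, 0.8, tolerance = 1e-6)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
})

test_that("fitted off-rate is monotone in the true off-rate", {
  truths <- c(0.05, 0.1, 0.26, 0.5, 1.07, 2, 5)
  fitted <- vapply(truths, function(k) {
    tr <- simulateFrapTrace(kOff = k, plateau = 0.8, nPrebleach = 10,
                            frameInterval = 0.1, noiseSigma = 0,
                            nPostbleach = 400)
    kOff(fitKoff(normalizeFrap(tr)))
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
  expect_equal(fitted, truths, tolerance = 1e-4)
})

test_that("pure-noise traces are flagged rather than reported at bounds", {
  set.seed(41)
  tr <- FrapTrace(times = 0:99 * 0.2, intensities = rnorm(100, 0.5, 0.2),
                  bleachIndex = 20)
  nt <- normalizeFrap(tr)
  fit <- suppressWarnings(fitKoff(nt))
  expect_true(!fit@converged || fit@rSquared < 0.5)
})

test_that("off-rate medians and Mann-Whitney comparison are reported", {
  mkFits <- function(kvals, cond) lapply(kvals, function(k)
    new("FrapFit", A = 0.8, kOff = k, rSquared = 0.9, converged = TRUE,
        nPoints = 100L, roiId = "r", condition = cond))
  # medians engineered to the GDP / GMPCPP contrast
  gdp <- mkFits(1.07 * exp(seq(-0.4, 0.4, length.out = 11)), "gdp")
  gmp <- mkFits(0.26 * exp(seq(-0.4, 0.4, length.out = 11)), "gmpcpp")
  rep <- summarizeKoff(c(gdp, gmp))
  expect_equal(sort(rep$summary$median_koff_per_s), c(0.26, 1.07),
               tolerance = 1e-9)
  expect_lt(rep$tests$p, 0.001)
  # identical conditions: p = 1
  same <- summarizeKoff(list(a = gdp, b = gdp))
  expect_equal(same$tests$p, 1)
  # non-converged fits are excluded and counted
  bad <- mkFits(0.5, "gdp")[[1]]; bad@converged <- FALSE
  rep2 <- summarizeKoff(list(gdp = c(gdp, list(bad)), gmpcpp = gmp))
  expect_equal(rep2$summary$n_excluded[rep2$summary$condition == "gdp"], 1L)
})
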