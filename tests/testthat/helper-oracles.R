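# Independent reference implementations used as oracles. These deliberately
# use a different computational route than the package code they check.

# literal element-by-element evaluation of the weighted-speed formulas
refWeightedStats <- function(speeds, durations) {
  total <- 0
  for (d in durations) total <- total + d
  w <- numeric(length(speeds))
  for (i in seq_along(speeds)) w[i] <- durations[i] / total
  m <- 0
  for (i in seq_along(speeds)) m <- m + w[i] * speeds[i]
  num <- 0
  sw <- 0
  for (i in seq_along(speeds)) {
    num <- num + w[i] * (speeds[i] - m)^2
    sw <- sw + w[i]
  }
  N <- length(speeds)
  se <- if (N == 1) NA_real_ else sqrt(num / (((N - 1) / N) * sw))
  list(mean = m, se = se)
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
mwEnumerationP <- function(x, y) {
  n1 <- length(x)
  all <- c(x, y)
  r <- rank(all)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  sets <- utils::combn(length(all), n1)
  us <- apply(sets, 2, uOf)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# direct evaluation of the Welch statistic, df and p
welchOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# random phase-segment table with internally consistent displacements
randomSegments <- function(n, kind = "growth", seedSign = 1) {
  dur <- runif(n, 1, 120)
  speed <- seedSign * runif(n, 0.2, 5)
  data.frame(kind = kind, t_start_s = cumsum(c(0, dur[-n])),
             t_end_s = cumsum(dur), duration_s = dur,
             speed_um_per_min = speed,
             displacement_um = speed / 60 * dur,
             stringsAsFactors = FALSE)
}

# small constant-background stack with optional additive Gaussian noise
noiseStack <- function(h = 24, w = 80, nframes = 40, level = 100,
                       sigma = 10) {
  arr <- array(level, c(h, w, nframes))
  if (sigma > 0) arr <- arr + array(rnorm(length(arr), 0, sigma), dim(arr))
  new("ImageStack", frames = arr, pixelSize = 0.1, frameInterval = 2)
}

# a steadily growing microtubule used as a stage for event libraries
eventStageMt <- function(seed = 2) {
  p <- DynamicsParams(vGrowth = 2, vShrink = 30, fCat = 0.001, fRes = 0.05,
                      seedLength = 2, duration = 600, rngSeed = seed)
  simulateDynamicInstability(p)$trajectory
}
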