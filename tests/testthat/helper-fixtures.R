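# Shared fixtures and independent straight-loop oracles.

# small labeled session: three activities, short bouts
tiny_session <- function(seed = 101, duration_s = c(20, 20, 20),
                         acts = c("WALK", "HAM", "GUDVL"),
                         rof_interval_s = 20, ...) {
  p <- participant_profile("T01", age = 30, body_mass = 75, height = 175,
                           resting_hr = 65)
  simulate_session(p, activity_schedule(acts, duration_s),
                   activity_catalog(),
                   sim_config(seed = seed, rof_interval_s = rof_interval_s,
                              ...))
}

# fast sequence-model settings for structural tests
fast_model <- list(L = 10, stride = 5, eval_stride = 5, hidden = c(6, 4),
                   dense = 8, dropout = 0.2, epochs = 2, batch_size = 32,
                   learning_rate = 3e-3, validation_split = 0,
                   patience = 2)

# ---- independent oracles -------------------------------------------------

# straight-loop implementation of the 17 per-channel window statistics
oracle_channel_stats <- function(x, fs) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  zc <- 0
  for (i in 2:n) if (x[i - 1] * x[i] < 0) zc <- zc + 1
  ssc <- 0
  for (i in 2:(n - 1))
    if ((x[i] - x[i - 1]) * (x[i + 1] - x[i]) < 0) ssc <- ssc + 1
  pgram <- Mod(fft(x))^2
  half <- pgram[2:(floor(n / 2) + 1)]
  dom <- if (max(half) <= 0) 0 else which.max(half) * fs / n
  c(mean = mean(x), sd = sd(x), var = var(x), min = min(x), max = max(x),
    range = max(x) - min(x), median = median(x),
    rms = sqrt(mean(x^2)), mav = mean(abs(x)),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    skew = if (m2 > 0) m3 / m2^1.5 else 0,
    kurt = if (m2 > 0) m4 / m2^2 - 3 else 0,
    zc = zc, wl = sum(abs(diff(x))), ssc = ssc, energy = sum(x^2),
    domfreq = dom)
}

# brute-force one-way ANOVA F from sums of squares
oracle_anova_f <- function(x, g) {
  g <- as.factor(g)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  (ssb / (nlevels(g) - 1)) / (ssw / (length(x) - nlevels(g)))
}

# brute-force Pearson chi-squared on a contingency table
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}
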