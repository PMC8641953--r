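test_that("band edges partition 4-120 Hz without overlap or gap", {
  b <- lfp_bands()
  expect_length(b, 5)
  edges <- unlist(b, use.names = FALSE)
  expect_equal(edges[1], 4)
  expect_equal(edges[10], 120)
  for (i in 1:4) expect_equal(b[[i]][2], b[[i + 1]][1])
})

test_that("MUA envelope is linear-homogeneous and zero for zero input", {
  fs <- 20000
  expect_equal(mua_envelope(rep(0, fs), fs)$x, rep(0, 1000))
  set.seed(11)
  x <- rnorm(fs)
  e1 <- mua_envelope(x, fs)
  e2 <- mua_envelope(2 * x, fs)
  expect_equal(e2$x, 2 * e1$x, tolerance = 1e-10)
  expect_equal(e1$fs, 1000)
  expect_error(mua_envelope(x, 10000), "fs too low")
})

test_that("MUA envelope of a 3 kHz tone matches the staged reference pipeline", {
  fs <- 30000
  t <- seq(0, 0.5, by = 1 / fs)
  A <- 4
  x <- A * sin(2 * pi * 3000 * t)
  env <- mua_envelope(x, fs)
  # reference: apply the three stages independently with signal/filtfilt
  bp <- signal::filtfilt(signal::butter(4, c(500, 9000) / (fs / 2), "pass"), x)
  lp <- signal::filtfilt(signal::butter(4, 200 / (fs / 2), "low"), abs(bp))
  ref <- lp[seq(1, length(lp), by = 30)]
  expect_equal(env$x, ref, tolerance = 1e-12)
  # steady-state level ~ mean|sin| * A = 2A/pi times the band-pass gain at
  # 3 kHz (slightly below 1 for the 4th-order Butterworth stages)
  mid <- env$x[200:300]
  expect_equal(mean(mid), 2 * A / pi, tolerance = 0.05)
})

test_that("position responses are baselined means over the response window", {
  fs <- 1000
  ev <- data.frame(sweep = 1, position = 1:3, onset = c(2, 3, 4))
  # constant signal -> all zero after baselining
  expect_equal(position_response(rep(5, 6 * fs), fs, ev), rep(0, 3))
  # step of height h covering the window at position 2 only
  x <- rep(0, 6 * fs)
  x[(3.0 * fs):(3.6 * fs)] <- 2.5
  expect_equal(position_response(x, fs, ev), c(0, 2.5, 0), tolerance = 1e-6)
  # ramp signal: responses equal hand-integrated window means minus baseline
  x <- seq(0, 6, length.out = 6 * fs)
  r <- position_response(x, fs, ev)
  base <- mean(c(1, 2)) # ramp value averaged over [1, 2] s
  expected <- sapply(c(2, 3, 4), function(o) mean(c(o + 0.05, o + 0.5))) - base
  expect_equal(r, expected, tolerance = 1e-3)
  expect_error(position_response(x, fs, data.frame(sweep = 1, position = 1,
                                                   onset = 0.5)),
               "exceeds record bounds")
})

test_that("dpss tapers are orthonormal", {
  tap <- dpss_tapers(128, 5, 9)
  expect_equal(crossprod(tap), diag(9), tolerance = 1e-12)
})

test_that("a 40 Hz tone concentrates its multitaper power in the low-gamma band", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  sg <- multitaper_spectrogram(sin(2 * pi * 40 * t), fs)
  psd <- colMeans(sg$power)
  df <- sg$freq[2] - sg$freq[1]
  ip <- vapply(lfp_bands(), function(b)
    sum(psd[sg$freq > b[1] & sg$freq <= b[2]]) * df, numeric(1))
  expect_gt(ip[["gamma_low"]] / sum(ip), 0.9)
})

test_that("white-noise band power is proportional to bandwidth (flat PSD)", {
  set.seed(21)
  fs <- 500
  sg <- multitaper_spectrogram(rnorm(20000), fs)
  psd <- colMeans(sg$power)
  df <- sg$freq[2] - sg$freq[1]
  # Parseval: one-sided integral recovers the variance
  expect_equal(sum(psd) * df, 1, tolerance = 0.05)
  ip <- vapply(lfp_bands(), function(b)
    sum(psd[sg$freq > b[1] & sg$freq <= b[2]]) * df, numeric(1))
  bw <- vapply(lfp_bands(), diff, numeric(1))
  level <- ip / bw
  expect_lt(max(level) / min(level), 1.15)   # flat within Monte-Carlo tolerance
  expect_equal(mean(level), 2 / fs, tolerance = 0.1)
  expect_error(multitaper_spectrogram(rnorm(100), fs), "shorter than one")
})

test_that("silent epochs yield minus-baseline band power after correction", {
  set.seed(3)
  fs <- 500
  # active baseline (white noise), silent stimulus epochs
  x <- c(rnorm(3 * fs), rep(0, 2 * fs))
  ev <- data.frame(sweep = 1, position = 1:2, onset = c(3.2, 4.2))
  bp <- lfp_band_power(x, fs, ev, window = c(0.05, 0.5), baseline = 1)
  expect_true(all(bp < 0))
})

test_that("cRF size formula and diameter scaling are exact", {
  # 3-4-5 triangle through sqrt(w^2 + h^2)/2
  expect_equal(sqrt(3^2 + 4^2) / 2, 2.5)
  expect_equal(crf_diameter(1), 3.3)
  expect_equal(crf_diameter(0.5), 1.65)
  expect_equal(crf_diameter(2.5), 8.25)
})

test_that("the cRF estimator recovers a synthetic circular RF", {
  truth <- prf_params("P-LIN", 4, -3, 0.8)
  mb <- synth_moving_bar_mua(truth, aperture = 16, bar_speed = 8,
                             latency = 0, noise_sd = 1e-6, seed = 5)
  crf <- estimate_crf(mb$sweeps, mb$spont_sd)
  expect_lt(sqrt(sum((crf$center - c(4, -3))^2)), 0.1)
  expect_gt(crf$aspect_ratio, 1 / 1.05)
  expect_lt(crf$aspect_ratio, 1.05)
  expect_equal(crf$size, sqrt(crf$width^2 + crf$height^2) / 2)
  # onset/offset at mu +/- sd: width approximates 2 sigma
  expect_equal(crf$width / 2, 0.8, tolerance = 0.15)
  expect_equal(crf_diameter(crf), 3.3 * crf$size)
})

test_that("opposite-sweep averaging cancels response latency", {
  truth <- prf_params("P-LIN", 2, -1, 1)
  mb0 <- synth_moving_bar_mua(truth, aperture = 16, bar_speed = 8,
                              latency = 0, noise_sd = 1e-6, seed = 6)
  mb60 <- synth_moving_bar_mua(truth, aperture = 16, bar_speed = 8,
                               latency = 0.06, noise_sd = 1e-6, seed = 6)
  c0 <- estimate_crf(mb0$sweeps, mb0$spont_sd)$center
  c60 <- estimate_crf(mb60$sweeps, mb60$spont_sd)$center
  expect_equal(c60, c0, tolerance = 0.02)
})

test_that("low-SNR units and poor Gaussian fits are rejected", {
  truth <- prf_params("P-LIN", 0, 0, 1)
  mb <- synth_moving_bar_mua(truth, aperture = 16, bar_speed = 8,
                             amplitude = 0.1, noise_sd = 0.2, n_repeats = 2,
                             seed = 7)
  expect_error(estimate_crf(mb$sweeps, mb$spont_sd), "SNR")
  ok <- synth_moving_bar_mua(truth, aperture = 16, bar_speed = 8,
                             noise_sd = 0.01, seed = 8)
  expect_error(estimate_crf(ok$sweeps, ok$spont_sd, fit_r2_min = 99.999),
               "R2")
  # missing opposite pair
  expect_error(estimate_crf(ok$sweeps[1:3], ok$spont_sd), "opposite")
})
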