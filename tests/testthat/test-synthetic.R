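test_that("populations are reproducible and respect their invariants", {
  pop1 <- sample_population("V1", 50, seed = 101)
  pop2 <- sample_population("V1", 50, seed = 101)
  expect_identical(pop1, pop2)
  expect_true(all(pop1$ecc <= 8))
  pop4 <- sample_population("V4", 50, seed = 101)
  expect_true(all(pop4$ecc <= 14))
  # lower-right quadrant coverage
  expect_true(all(pop1$x0 >= 0 & pop1$y0 <= 0))
  expect_true(all(pop1$sigma > 0))
  expect_true(all(pop1$exponent > 0 & pop1$exponent <= 1))
  expect_true(all(pop1$gain > 0))
  one <- sample_population("V1", 1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$ecc, sqrt(one$x0^2 + one$y0^2))
})

test_that("a zero slope yields uncorrelated size and eccentricity", {
  pop <- sample_population("V1", 500, ecc_size_slope = 0, seed = 103)
  expect_lt(abs(cor(pop$sigma, pop$ecc)), 0.1)
  # and the default slope induces a positive correlation
  pop2 <- sample_population("V4", 500, seed = 103)
  expect_gt(cor(pop2$sigma, pop2$ecc), 0.5)
})

test_that("negative-gain fractions are honored", {
  pop <- sample_population("V1", 200, frac_negative = 0.3, seed = 104)
  expect_equal(mean(pop$gain < 0), 0.3, tolerance = 0.1)
})

test_that("synthetic BOLD noise has the requested per-TR SD", {
  p <- tiny_protocol(nstep = 4, ppd = 2, dirs = c(0, 90), step = 2.5,
                     pre = 5, post = 5, blank_after = "none")
  s <- render_effective_stimulus(p)
  hrf <- make_hrf("monkey", dt = 0.05)
  pop <- sample_population("V1", 2, ecc_max = 3, seed = 105)
  ds <- synth_bold(pop, s, hrf, tr = 2.5, noise_sd = 0.4, n_runs = 40,
                   model = "P-LIN", seed = 105)
  clean <- predict_bold(prf_params("P-LIN", pop$x0[1], pop$y0[1],
                                   pop$sigma[1], gain = pop$gain[1]),
                        s, hrf, 2.5)
  # each half averages 20 runs -> SD 0.4 / sqrt(20)
  resid <- ds$half_a[1, ] - clean
  expect_equal(sd(resid), 0.4 / sqrt(20), tolerance = 0.35)
  # doubling the gain doubles the noise-free response
  pop2 <- pop; pop2$gain <- 2 * pop$gain
  d1 <- synth_bold(pop, s, hrf, tr = 2.5, noise_sd = 0, n_runs = 2,
                   model = "P-LIN", seed = 1)
  d2 <- synth_bold(pop2, s, hrf, tr = 2.5, noise_sd = 0, n_runs = 2,
                   model = "P-LIN", seed = 1)
  expect_equal(d2$half_a, 2 * d1$half_a)
})

test_that("averaging repeats shrinks noise as 1/sqrt(n)", {
  p <- tiny_protocol(nstep = 6, ppd = 2, dirs = c(0, 90))
  s <- render_effective_stimulus(p)
  pop <- sample_population("V1", 1, ecc_max = 3, seed = 106)
  clean <- predict_response(prfmap:::pop_params(pop, 1, "CSS"), s)
  sds <- vapply(c(2, 32), function(nr) {
    ds <- synth_ephys(pop, s, noise_sd = 1, n_repeats = nr, seed = 106)
    sd(ds$half_a[1, ] - clean)
  }, numeric(1))
  expect_equal(sds[1] / sds[2], sqrt(32 / 2), tolerance = 0.35)
})

test_that("zero-gain units produce pure-noise responses with r2_cv near 0", {
  s <- recovery_stim()
  pop <- sample_population("V1", 6, ecc_max = 4, seed = 107)
  pop$gain <- 1e-12
  ds <- synth_ephys(pop, s, noise_sd = 1, n_repeats = 4, seed = 107)
  tab <- fit_prf_table("P-LIN", ds, prf_fit_control(grid_nxy = 5,
                                                    grid_nsigma = 4,
                                                    maxit = 20))
  expect_lt(mean(tab$r2_cv), 5)
})

test_that("generator outputs pass the consuming module's validation", {
  p <- tiny_protocol(nstep = 4, ppd = 2, dirs = c(0, 180), step = 0.5,
                     pre = 2.5, post = 2.5, blank_after = "none")
  s <- render_effective_stimulus(p)
  pop <- sample_population("V1", 2, ecc_max = 3, seed = 108)
  expect_s3_class(synth_ephys(pop, s, noise_sd = 0.1, n_repeats = 2,
                              seed = 1), "prf_dataset")
  raw <- synth_raw_lfp(prfmap:::pop_params(pop, 1, "P-LIN"), s,
                       band = "gamma_low", depth = 0.5, n_repeats = 1,
                       seed = 1)
  expect_equal(raw$fs, 500)
  expect_true(all(c("sweep", "position", "onset") %in% names(raw$events)))
  expect_error(synth_raw_lfp(prfmap:::pop_params(pop, 1, "P-LIN"), s,
                             band = "ripple"), "unknown band")
})

test_that("zero-depth LFP synthesis leaves no stimulus-locked band power", {
  p <- tiny_protocol(nstep = 6, ppd = 2, dirs = c(0, 180), step = 0.5,
                     pre = 2.5, inter = 2.5, post = 2.5, blank_after = "all")
  s <- render_effective_stimulus(p)
  unit <- prf_params("P-LIN", 1, -1, 1.5)
  raw <- synth_raw_lfp(unit, s, band = "gamma_low", depth = 0,
                       n_repeats = 4, seed = 109)
  bp <- lfp_band_power(raw$x, raw$fs, raw$events)
  # modulation depth (relative to carrier power ~ 2/band bandwidth spread)
  expect_lt(max(abs(bp[, "gamma_low"])), 0.05)
})

test_that("band-power pRFs recover the generating unit end to end", {
  # gamma carrier with positive modulation
  p <- tiny_protocol(nstep = 10, ppd = 2, aperture = 8,
                     dirs = c(0, 180, 90, 270), step = 0.5,
                     pre = 2.5, inter = 2.5, post = 2.5, blank_after = "all")
  s <- render_effective_stimulus(p)
  unit <- prf_params("P-LIN", 1.5, -1.5, 1)
  raw <- synth_raw_lfp(unit, s, band = "gamma_low", depth = 0.9,
                       n_repeats = 6, seed = 110)
  bp <- lfp_band_power(raw$x, raw$fs, raw$events)
  resp <- bp[, "gamma_low"]
  ds <- prf_dataset(rbind(resp), rbind(resp), s, "lfp_band")
  f <- fit_prf("P-LIN", ds, 1, prf_fit_control(maxit = 30))
  err <- sqrt((f$params$x0 - 1.5)^2 + (f$params$y0 + 1.5)^2)
  expect_lt(err, 0.5)
  # alpha carrier with negative modulation -> negative U-LIN gain
  raw_n <- synth_raw_lfp(prf_params("U-LIN", 1.5, -1.5, 1, gain = -1), s,
                         band = "alpha", depth = 0.9, n_repeats = 6,
                         seed = 111)
  bp_n <- lfp_band_power(raw_n$x, raw_n$fs, raw_n$events)
  ds_n <- prf_dataset(rbind(bp_n[, "alpha"]), rbind(bp_n[, "alpha"]), s,
                      "lfp_band")
  f_n <- fit_prf("U-LIN", ds_n, 1, prf_fit_control(maxit = 30))
  expect_lt(f_n$params$gain, 0)
  expect_equal(classify_negative(as.data.frame(f_n$params)), "negative")
})

test_that("sub-threshold moving-bar units are rejected by the SNR gate", {
  truth <- prf_params("P-LIN", 2, -2, 1)
  weak <- synth_moving_bar_mua(truth, aperture = 16, bar_speed = 8,
                               amplitude = 0.05, noise_sd = 0.5,
                               n_repeats = 2, seed = 112)
  expect_error(estimate_crf(weak$sweeps, weak$spont_sd), "SNR")
})
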