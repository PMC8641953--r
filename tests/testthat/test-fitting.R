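test_that("cross-validated R2 matches its defining formula", {
  set.seed(1)
  d <- rnorm(50)
  expect_equal(crossval_r2(d, d), 100)
  expect_equal(crossval_r2(rep(mean(d), 50), d), 0)
  pred <- d + rnorm(50, 0, 0.5)
  expect_equal(crossval_r2(pred, d),
               100 * (1 - sum((d - pred)^2) / sum((d - mean(d))^2)))
  expect_error(crossval_r2(1:3, 1:4), "equal lengths")
  expect_error(crossval_r2(1:3, rep(1, 3)), "zero-variance")
})

test_that("grid_init is self-consistent and validates degenerate data", {
  p <- tiny_protocol(nstep = 8, ppd = 3, aperture = 8,
                     dirs = c(0, 90, 180, 270))
  s <- render_effective_stimulus(p)
  # data generated exactly at a grid point -> that point is the top seed
  ctl <- prf_fit_control()
  ax <- seq(-1.5 * 4, 1.5 * 4, length.out = ctl$grid_nxy)
  sig <- exp(seq(log(0.1), log(8), length.out = ctl$grid_nsigma))
  truth <- prf_params("P-LIN", ax[3], ax[6], sig[4], gain = 1.7)
  d <- predict_response(truth, s)
  seeds <- grid_init(s, d, "P-LIN")
  expect_equal(seeds[[1]]$x0, truth$x0)
  expect_equal(seeds[[1]]$y0, truth$y0)
  expect_equal(seeds[[1]]$sigma1, truth$sigma1)
  expect_equal(seeds[[1]]$gain, 1.7, tolerance = 1e-10)
  expect_error(grid_init(s, rep(0, length(d)), "P-LIN"), "degenerate")
  # constant nonzero data: closed-form gain reproduces the OLS solution
  const <- rep(2, length(d))
  seeds_c <- grid_init(s, const, "U-LIN")
  shape <- predict_response(
    prf_params("U-LIN", seeds_c[[1]]$x0, seeds_c[[1]]$y0,
               seeds_c[[1]]$sigma1, gain = 1), s)
  expect_equal(seeds_c[[1]]$gain, sum(shape * const) / sum(shape^2),
               tolerance = 1e-10)
})

test_that("noise-free BOLD fits recover the generating P-LIN parameters", {
  p <- make_protocol(aperture_diameter = 16, bar_width = 2,
                     n_steps_per_sweep = 20, step_duration = 2.5,
                     sweep_directions = c(270, 180, 90, 0),
                     pre_blank = 5, inter_blank = 5, post_blank = 5,
                     blank_after = "all", pixels_per_dva = 2)
  s <- render_effective_stimulus(p)
  hrf <- make_hrf("monkey", dt = 0.05)
  # sigma = 1.5 at eccentricity 4
  pop <- data.frame(unit = 1, x0 = 4 * cos(-pi / 6), y0 = 4 * sin(-pi / 6),
                    ecc = 4, sigma = 1.5, exponent = 1, gain = 1)
  ds <- synth_bold(pop, s, hrf, tr = 2.5, noise_sd = 1e-9, n_runs = 2,
                   model = "P-LIN", seed = 3)
  f <- fit_prf("P-LIN", ds, 1, prf_fit_control(maxit = 60))
  expect_lt(abs(f$params$x0 - pop$x0), 0.1)
  expect_lt(abs(f$params$y0 - pop$y0), 0.1)
  expect_lt(abs(f$params$sigma1 - 1.5) / 1.5, 0.05)
  expect_gt(f$r2_cv, 99)
  expect_equal(f$r2_cv, mean(f$r2_fold))
})

test_that("noise-free CSS fits recover the exponent", {
  s <- recovery_stim()
  pop <- data.frame(unit = 1, x0 = 2.5, y0 = -2, ecc = sqrt(2.5^2 + 4),
                    sigma = 1.2, exponent = 0.4, gain = 1)
  ds <- synth_ephys(pop, s, noise_sd = 1e-9, n_repeats = 2, model = "CSS",
                    seed = 4)
  f <- fit_prf("CSS", ds, 1, prf_fit_control(maxit = 60))
  expect_lt(abs(f$params$exponent - 0.4), 0.05)
  expect_gt(f$r2_cv, 99)
})

test_that("pure-noise units score near-zero cross-validated R2", {
  p <- tiny_protocol(nstep = 8, ppd = 2, aperture = 8,
                     dirs = c(0, 90, 180, 270))
  s <- render_effective_stimulus(p)
  nf <- dim(s$frames)[3]
  set.seed(12)
  n <- 40
  r2 <- numeric(n)
  ds <- prf_dataset(matrix(rnorm(n * nf), n), matrix(rnorm(n * nf), n), s,
                    "mua")
  ctl <- prf_fit_control(grid_nxy = 5, grid_nsigma = 4, maxit = 20)
  ctx <- fit_context_for_test(ds, ctl)
  for (u in seq_len(n))
    r2[u] <- fit_prf("P-LIN", ds, u, ctl, ctx = ctx)$r2_cv
  expect_lte(mean(r2), 1)
})

test_that("cross-validated R2 does not exceed training R2 in expectation", {
  s <- recovery_stim()
  pop <- sample_population("V1", 12, ecc_max = 4, seed = 13)
  ds <- synth_ephys(pop, s, rel_noise = 1.3, n_repeats = 8, model = "P-LIN",
                    seed = 13)
  tab <- fit_prf_table("P-LIN", ds, prf_fit_control(maxit = 30))
  expect_lt(mean(tab$r2_cv), mean(tab$r2_train))
})

test_that("refitting with the same configuration is bit-reproducible", {
  s <- recovery_stim()
  pop <- sample_population("V1", 2, ecc_max = 4, seed = 14)
  ds <- synth_ephys(pop, s, rel_noise = 1, n_repeats = 4, model = "CSS",
                    seed = 14)
  f1 <- fit_prf("CSS", ds, 1)
  f2 <- fit_prf("CSS", ds, 1)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$r2_cv, f2$r2_cv)
})

test_that("model comparison flags a uniformly better model", {
  set.seed(15)
  n <- 30
  base <- rnorm(n, 40, 10)
  tabs <- rbind(
    data.frame(unit = 1:n, model = "P-LIN", r2 = base),
    data.frame(unit = 1:n, model = "U-LIN", r2 = base + rnorm(n, 0, 0.5)),
    data.frame(unit = 1:n, model = "CSS", r2 = base + 10),
    data.frame(unit = 1:n, model = "DoG", r2 = base + rnorm(n, 0, 0.5))
  )
  r <- compare_models(tabs, threshold_r2 = 5)
  expect_equal(r$ranking[1], "CSS")
  w <- r$wilcoxon
  expect_lt(w$p[w$model_a == "P-LIN" & w$model_b == "CSS"], 0.05)
  expect_equal(r$kruskal$df, 3)
  # identical columns: H ~ 0, no pair significant
  same <- rbind(data.frame(unit = 1:n, model = "A", r2 = base),
                data.frame(unit = 1:n, model = "B", r2 = base))
  r0 <- compare_models(same, threshold_r2 = 5)
  expect_lt(r0$kruskal$H, 1e-8)
  expect_true(all(r0$posthoc$p > 0.99))
  expect_true(all(r0$wilcoxon$p == 1))
})

test_that("signed-rank statistic agrees with a brute-force rank oracle", {
  set.seed(16)
  n <- 25
  a <- rnorm(n, 50, 8)
  b <- a + rnorm(n, 2, 3)
  tabs <- rbind(data.frame(unit = 1:n, model = "A", r2 = a),
                data.frame(unit = 1:n, model = "B", r2 = b))
  r <- compare_models(tabs, threshold_r2 = 0)
  # brute force: V = sum of ranks of |d| where d > 0
  d <- a - b
  V <- sum(rank(abs(d))[d > 0])
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
  expect_equal(unname(ref$statistic), V)
  expect_equal(r$wilcoxon$p, ref$p.value)
})

test_that("units below the comparison threshold are excluded", {
  tabs <- rbind(data.frame(unit = 1:10, model = "A", r2 = c(rep(1, 5), rep(60, 5))),
                data.frame(unit = 1:10, model = "B", r2 = c(rep(2, 5), rep(70, 5))))
  r <- compare_models(tabs, threshold_r2 = 25)
  expect_equal(r$n_units, 5)
  expect_error(compare_models(tabs, threshold_r2 = 99), "no units pass")
  expect_error(compare_models(tabs[1:10, ], 5), "at least two models")
})
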