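# small protocols/stimuli shared across tests (built once per test run)

# tiny 4-direction bar protocol on a coarse grid, no blanks
tiny_protocol <- function(nstep = 5, ppd = 4, aperture = 8, bar = 2,
                          dirs = c(0, 90, 180, 270), step = 1,
                          pre = 0, inter = 0, post = 0,
                          blank_after = "none") {
  make_protocol(aperture_diameter = aperture, bar_width = bar,
                n_steps_per_sweep = nstep, step_duration = step,
                sweep_directions = dirs, pre_blank = pre,
                inter_blank = inter, post_blank = post,
                blank_after = blank_after, pixels_per_dva = ppd)
}

# the reduced-scale recovery protocol: full 8-direction sweep set over a
# 16 dva aperture with fine 0.5 dva bar steps, rendered at 2 px/dva
recovery_protocol <- function(nstep = 32, ppd = 2) {
  make_protocol(aperture_diameter = 16, bar_width = 2,
                n_steps_per_sweep = nstep, step_duration = 0.5,
                sweep_directions = c(270, 315, 180, 225, 90, 135, 0, 45),
                pre_blank = 0, inter_blank = 0, post_blank = 0,
                blank_after = "none", pixels_per_dva = ppd)
}

recovery_stim <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- render_effective_stimulus(recovery_protocol())
    val
  }
})

# brute-force prediction oracle: explicit double loop over pixels
brute_force_response <- function(params, stim) {
  g <- stim$grid
  nf <- dim(stim$frames)[3]
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    f <- stim$frames[, , k]
    acc <- 0
    for (px in seq_along(g$x)) {
      if (f[px] == 0) next
      d2 <- (g$x[px] - params$x0)^2 + (g$y[px] - params$y0)^2
      w <- exp(-d2 / (2 * params$sigma1^2))
      if (params$model == "DoG")
        w <- w - params$amp_surround * exp(-d2 / (2 * params$sigma2^2))
      acc <- acc + w
    }
    drv <- acc / stim$protocol$pixels_per_dva^2
    out[k] <- params$gain * sign(drv) * abs(drv)^params$exponent
  }
  out
}

# access to internals used by a few tests
frame_drive_for_test <- function(params, stim) prfmap:::frame_drive(params, stim)
neural_ts_for_test <- function(params, stim, tr = 1) {
  prfmap:::neural_timeseries(predict_response(params, stim), stim, tr)
}

fit_context_for_test <- function(ds, ctl = prf_fit_control()) {
  prfmap:::fit_context(ds, ctl)
}
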