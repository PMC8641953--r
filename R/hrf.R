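#' Hemodynamic response function kernels
#'
#' Double-gamma HRF kernels whose timing matches the monkey and human HRFs
#' used for BOLD pRF fitting: the monkey HRF peaks at 4.2 s and falls back to
#' within 5% of baseline 6.2 s after the peak; the human HRF peaks at 4.8 s
#' with a 12.6 s peak-to-fall time. The monkey kernel is therefore narrower
#' than the human one.
#'
#' The positive lobe is a unit-peak gamma bump with mode fixed at
#' \code{time_to_peak}; its width (shape) parameter is solved by 1-D root
#' finding so that the kernel first returns to within 5% of baseline exactly
#' \code{peak_to_fall} seconds after the peak. A small undershoot (10% of
#' peak by default) peaking after the fall is subtracted, as is conventional.
#'
#' @param label \code{"monkey"} or \code{"human"}; or \code{"custom"} with
#'   explicit \code{time_to_peak} and \code{peak_to_fall}.
#' @param dt sampling interval in seconds (must be <= 0.25 s).
#' @param time_to_peak,peak_to_fall timing targets in seconds (defaulted by
#'   \code{label}).
#' @param undershoot undershoot amplitude as a fraction of the peak.
#' @param duration kernel length in seconds (>= 30).
#' @param fall_frac "fall" criterion: first post-peak sample within
#'   \code{fall_frac} of baseline (default 0.05).
#' @return An object of class \code{hrf_kernel}: \code{samples} (unit peak),
#'   \code{t}, \code{dt}, \code{time_to_peak}, \code{peak_to_fall},
#'   \code{label}.
#' @export
make_hrf <- function(label = c("monkey", "human", "custom"), dt = 0.05,
                     time_to_peak = NULL, peak_to_fall = NULL,
                     undershoot = 0.1, duration = 40, fall_frac = 0.05) {
  label <- match.arg(label)
  if (dt > 0.25) stop("dt too coarse to resolve the HRF peak (need dt <= 0.25 s)")
  if (duration < 30) stop("kernel length must be >= 30 s")
  timing <- switch(label,
                   monkey = c(4.2, 6.2),
                   human = c(4.8, 12.6),
                   custom = c(time_to_peak, peak_to_fall))
  if (is.null(time_to_peak)) time_to_peak <- timing[1]
  if (is.null(peak_to_fall)) peak_to_fall <- timing[2]
  if (is.null(time_to_peak) || is.null(peak_to_fall))
    stop("custom HRF needs time_to_peak and peak_to_fall")

  tt <- seq(0, duration, by = dt)
  kernel <- function(shape) hrf_shape(tt, time_to_peak, peak_to_fall, shape,
                                      undershoot)
  fall_err <- function(shape) {
    fall_time(kernel(shape), tt, time_to_peak, fall_frac) - peak_to_fall
  }
  # wider bump (small shape) -> later fall; fall_err is decreasing in shape
  sol <- stats::uniroot(fall_err, lower = 1.05, upper = 500, tol = 1e-8,
                        extendInt = "no")
  h <- kernel(sol$root)
  h <- h / max(h)
  structure(list(samples = h, t = tt, dt = dt,
                 time_to_peak = time_to_peak, peak_to_fall = peak_to_fall,
                 shape = sol$root, label = label),
            class = "hrf_kernel")
}

# unit-peak gamma bump with mode at p: (t/p)^a * exp(a (1 - t/p)),
# minus an undershoot bump peaking peak_to_fall after the positive peak
hrf_shape <- function(tt, p, fall, shape, undershoot) {
  bump <- function(t, mode, a) {
    z <- pmax(t, 0) / mode
    ifelse(t <= 0, 0, z^a * exp(a * (1 - z)))
  }
  pos <- bump(tt, p, shape)
  u_mode <- p + fall + 2
  neg <- bump(tt, u_mode, 8)
  pos - undershoot * neg
}

# time from peak to the first post-peak sample with |h| <= frac * peak
fall_time <- function(h, tt, ttp, frac) {
  ip <- which.max(h)
  peak <- h[ip]
  post <- which(abs(h) <= frac * peak & seq_along(h) > ip)
  if (!length(post)) return(Inf)
  tt[post[1]] - tt[ip]
}

#' Full width at half maximum of an HRF kernel
#' @param hrf an \code{hrf_kernel}.
#' @return seconds.
#' @export
hrf_fwhm <- function(hrf) {
  h <- hrf$samples / max(hrf$samples)
  above <- which(h >= 0.5)
  # linear interpolation at the crossings
  i1 <- above[1]; i2 <- above[length(above)]
  t_lo <- if (i1 == 1) hrf$t[1] else
    stats::approx(h[(i1 - 1):i1], hrf$t[(i1 - 1):i1], xout = 0.5)$y
  t_hi <- if (i2 == length(h)) hrf$t[i2] else
    stats::approx(h[i2:(i2 + 1)], hrf$t[i2:(i2 + 1)], xout = 0.5)$y
  t_hi - t_lo
}

#' Convolve a neural prediction to BOLD sampling
#'
#' The neural prediction is expected at half-TR resolution (the HRF kernel is
#' resampled to the same grid). A causal linear convolution is truncated to
#' the input length and decimated to TR resolution by averaging consecutive
#' pairs of samples. Predictions are implicitly zero-padded before run start.
#'
#' @param neural numeric vector sampled at \code{tr / 2}.
#' @param hrf an \code{hrf_kernel}.
#' @param tr repetition time, seconds.
#' @return numeric vector of length \code{length(neural) / 2} at TR
#'   resolution.
#' @export
convolve_to_bold <- function(neural, hrf, tr) {
  dt <- tr / 2
  if (length(neural) %% 2 != 0)
    stop("neural prediction length must be an even multiple of tr/2 samples")
  hk <- resample_hrf(hrf, dt)
  n <- length(neural)
  conv <- stats::convolve(neural, rev(hk), type = "open")[seq_len(n)]
  # average consecutive pairs -> TR resolution
  0.5 * (conv[seq(1, n, by = 2)] + conv[seq(2, n, by = 2)])
}

# kernel resampled to a coarser grid by linear interpolation, renormalized
# to unit peak so gain is comparable across sampling rates
resample_hrf <- function(hrf, dt) {
  if (abs(dt - hrf$dt) < 1e-12) return(hrf$samples)
  tt <- seq(0, max(hrf$t), by = dt)
  h <- stats::approx(hrf$t, hrf$samples, xout = tt)$y
  h / max(h)
}

#' Export an HRF kernel as two-column delimited text
#' @param hrf an \code{hrf_kernel}.
#' @param path output path.
#' @export
write_hrf_txt <- function(hrf, path) {
  utils::write.table(data.frame(time_s = hrf$t, amplitude = hrf$samples),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
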