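#' LFP frequency bands
#'
#' The five canonical bands partitioning 4-120 Hz: theta (4-8), alpha (8-16),
#' beta (16-30), low gamma (30-60), high gamma (60-120) Hz.
#' @return named list of c(lo, hi) edges in Hz.
#' @export
lfp_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 16), beta = c(16, 30),
       gamma_low = c(30, 60), gamma_high = c(60, 120))
}

# zero-phase 4th-order Butterworth filter (forward-backward)
butter_filtfilt <- function(x, fs, lo = NULL, hi = NULL, order = 4) {
  nyq <- fs / 2
  flt <- if (!is.null(lo) && !is.null(hi)) {
    signal::butter(order, c(lo, hi) / nyq, type = "pass")
  } else if (!is.null(hi)) {
    signal::butter(order, hi / nyq, type = "low")
  } else {
    signal::butter(order, lo / nyq, type = "high")
  }
  as.numeric(signal::filtfilt(flt, x))
}

#' MUA envelope from a raw broadband signal
#'
#' Band-pass 500 Hz - 9 kHz, full-wave rectification, 200 Hz low-pass,
#' resampled to 1 kHz. Filters are zero-phase 4th-order Butterworth.
#'
#' @param x raw signal, microvolts.
#' @param fs sampling rate, Hz (>= 20 kHz, and an integer multiple of 1 kHz).
#' @return list: \code{x} envelope samples, \code{fs} = 1000.
#' @export
mua_envelope <- function(x, fs) {
  if (fs < 20000) stop("fs too low for the 9 kHz band edge (need >= 20 kHz)")
  dec <- fs / 1000
  if (abs(dec - round(dec)) > 1e-9)
    stop("fs must be an integer multiple of 1 kHz")
  bp <- butter_filtfilt(x, fs, lo = 500, hi = 9000)
  env <- butter_filtfilt(abs(bp), fs, hi = 200)
  list(x = env[seq(1, length(env), by = round(dec))], fs = 1000)
}

#' Baseline-corrected per-position responses
#'
#' For each stimulus position, the mean signal in a response window after
#' position onset, after subtracting the baseline (mean over a pre-sweep
#' window), averaged across repeats.
#'
#' @param x signal samples (envelope or band power trace).
#' @param fs sampling rate, Hz.
#' @param events data frame with columns \code{sweep} (repeat/sweep id),
#'   \code{position} (1-based position index), \code{onset} (seconds).
#' @param window response window relative to position onset, seconds.
#' @param baseline seconds of pre-sweep baseline (before the sweep's first
#'   onset).
#' @return numeric vector, one mean response per position.
#' @export
position_response <- function(x, fs, events,
                              window = c(0.05, 0.5), baseline = 1.0) {
  stopifnot(all(c("sweep", "position", "onset") %in% names(events)))
  events <- events[order(events$sweep, events$onset), ]
  n <- length(x)
  idx <- function(t) pmax(1L, pmin(n, round(t * fs) + 1L))
  npos <- max(events$position)
  acc <- matrix(NA_real_, nrow = length(unique(events$sweep)), ncol = npos)
  for (si in seq_along(unique(events$sweep))) {
    s <- unique(events$sweep)[si]
    ev <- events[events$sweep == s, ]
    t0 <- min(ev$onset)
    if (t0 - baseline < 0 || max(ev$onset) + window[2] > n / fs)
      stop("baseline or response window exceeds record bounds")
    base <- mean(x[idx(t0 - baseline):idx(t0)])
    for (r in seq_len(nrow(ev))) {
      i1 <- idx(ev$onset[r] + window[1]); i2 <- idx(ev$onset[r] + window[2])
      acc[si, ev$position[r]] <- mean(x[i1:i2]) - base
    }
  }
  colMeans(acc, na.rm = TRUE)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem; tapers are
#' normalized to unit energy and sign-fixed (first taper positive mean).
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1] * (n - t[-1]))/2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (j %% 2 == 1 && sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    if (j %% 2 == 0 && tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper spectrogram
#'
#' Power spectra in a moving window, averaged across Slepian tapers
#' (default: 500 ms windows, 50 ms steps, time-bandwidth product 5, 9
#' tapers). Power is normalized so that summing \code{psd * df} over
#' frequencies approximates the signal variance in the window (one-sided).
#'
#' @param x signal samples.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param step_s step between window starts, seconds.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return list: \code{power} (windows x frequencies), \code{freq} (Hz),
#'   \code{t} (window centers, seconds).
#' @export
multitaper_spectrogram <- function(x, fs, window_s = 0.5, step_s = 0.05,
                                   nw = 5, k = 9) {
  nwin <- round(window_s * fs)
  nstep <- round(step_s * fs)
  if (length(x) < nwin) stop("record shorter than one spectral window")
  tapers <- dpss_tapers(nwin, nw, k)
  starts <- seq(1, length(x) - nwin + 1, by = nstep)
  nfft <- nwin
  freq <- (0:(nfft %/% 2)) * fs / nfft
  pow <- matrix(0, nrow = length(starts), ncol = length(freq))
  scale <- 2 / fs          # one-sided PSD scaling (tapers have unit energy)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nwin - 1)]
    sp <- stats::mvfft(tapers * seg)
    p <- rowMeans(Mod(sp)^2)[seq_along(freq)] * scale
    p[1] <- p[1] / 2
    if (nfft %% 2 == 0) p[length(freq)] <- p[length(freq)] / 2
    pow[i, ] <- p
  }
  list(power = pow, freq = freq, t = (starts - 1 + nwin / 2) / fs)
}

#' Band power per frequency band
#' @param psd vector of power values per frequency.
#' @param freq frequencies, Hz.
#' @param bands list of c(lo, hi) edges (default \code{lfp_bands()}); bands
#'   are half-open (lo, hi].
#' @return named vector of mean power per band.
#' @export
band_power <- function(psd, freq, bands = lfp_bands()) {
  vapply(bands, function(b) mean(psd[freq > b[1] & freq <= b[2]]), numeric(1))
}

#' LFP band-power responses per stimulus position
#'
#' The raw signal is low-pass filtered at 150 Hz and downsampled to 500 Hz if
#' needed, a multitaper spectrogram is computed (500 ms windows, 50 ms steps,
#' NW = 5, 9 tapers), power is averaged within the five canonical bands, the
#' pre-sweep baseline power (1000 ms) is subtracted, and responses are
#' averaged over a 50-500 ms window per position and across repeats.
#'
#' @param x raw or LFP signal samples.
#' @param fs sampling rate, Hz (downsampled to 500 Hz when higher).
#' @param events data frame (\code{sweep}, \code{position}, \code{onset}).
#' @param window,baseline as in \code{position_response}.
#' @return matrix, positions x 5 bands, baseline-corrected band power.
#' @export
lfp_band_power <- function(x, fs, events, window = c(0.05, 0.5),
                           baseline = 1.0) {
  if (fs > 500) {
    dec <- fs / 500
    if (abs(dec - round(dec)) > 1e-9)
      stop("fs must be an integer multiple of 500 Hz")
    x <- butter_filtfilt(x, fs, hi = 150)[seq(1, length(x), by = round(dec))]
    fs <- 500
  }
  sg <- multitaper_spectrogram(x, fs)
  bands <- lfp_bands()
  bp <- t(apply(sg$power, 1, band_power, freq = sg$freq, bands = bands))
  # one band-power time series per band, sampled at window centers
  resp <- sapply(seq_along(bands), function(bi) {
    position_response_windows(sg$t, bp[, bi], events, window, baseline)
  })
  colnames(resp) <- names(bands)
  resp
}

# position_response over an irregularly sampled series (window centers)
position_response_windows <- function(tc, v, events, window, baseline) {
  npos <- max(events$position)
  sweeps <- unique(events$sweep)
  acc <- matrix(NA_real_, nrow = length(sweeps), ncol = npos)
  for (si in seq_along(sweeps)) {
    ev <- events[events$sweep == sweeps[si], ]
    t0 <- min(ev$onset)
    bsel <- tc >= t0 - baseline & tc <= t0
    if (!any(bsel)) stop("baseline window contains no spectral estimates")
    base <- mean(v[bsel])
    for (r in seq_len(nrow(ev))) {
      sel <- tc >= ev$onset[r] + window[1] & tc <= ev$onset[r] + window[2]
      acc[si, ev$position[r]] <- mean(v[sel]) - base
    }
  }
  colMeans(acc, na.rm = TRUE)
}

#' Conventional moving-bar RF estimate from MUA sweep traces
#'
#' For each sweep direction, a Gaussian (with offset) is fitted to the
#' repeat-averaged response trace; response onset and offset are the Gaussian
#' mean plus or minus one SD, mapped through the bar trajectory to spatial
#' borders. Borders from opposite sweep directions are averaged so that the
#' response latency cancels. Units with SNR <= \code{snr_min} (peak response
#' over the SD of spontaneous activity) are rejected, as are Gaussian fits
#' with R-squared below \code{fit_r2_min}.
#'
#' @param sweeps list of sweeps; each a list with \code{direction} (degrees;
#'   must include both members of a horizontal and a vertical opposite pair),
#'   \code{t} (time, seconds), \code{response} (trace, averaged or one per
#'   repeat as a matrix with repeats in rows), and \code{bar_pos} (bar center
#'   position along the motion axis at each time, dva).
#' @param spont_sd SD of spontaneous activity (e.g. from inter-sweep blanks).
#' @param snr_min SNR rejection threshold (default 3).
#' @param fit_r2_min minimal Gaussian-fit R-squared in percent (default 25).
#' @return An object of class \code{crf_estimate}: borders (left, right,
#'   bottom, top), \code{center}, \code{width}, \code{height}, \code{size}
#'   (sqrt(width^2 + height^2) / 2), \code{aspect_ratio}
#'   (sigma_large / sigma_small), \code{snr}, \code{fit_r2} (worst fit).
#' @export
estimate_crf <- function(sweeps, spont_sd, snr_min = 3, fit_r2_min = 25) {
  dirs <- vapply(sweeps, `[[`, numeric(1), "direction") %% 360
  need <- c(0, 180, 90, 270)
  if (!all(need %in% dirs))
    stop("sweeps must include opposite horizontal (0/180) and vertical (90/270) pairs")
  avg_trace <- function(sw) {
    r <- sw$response
    if (is.matrix(r)) colMeans(r) else r
  }
  peak <- max(vapply(sweeps, function(sw) max(avg_trace(sw)), numeric(1)))
  snr <- peak / spont_sd
  if (snr <= snr_min)
    stop(sprintf("unit rejected: SNR %.2f <= %g", snr, snr_min))

  # fitted onset/offset positions per direction
  border_fit <- function(dir) {
    sw <- sweeps[[which(dirs == dir)[1]]]
    y <- avg_trace(sw)
    gf <- fit_gaussian_trace(sw$t, y)
    if (gf$r2 < fit_r2_min)
      stop(sprintf("unit rejected: Gaussian fit R2 %.1f%% < %g%% (direction %g)",
                   gf$r2, fit_r2_min, dir))
    pos_at <- function(tt) stats::approx(sw$t, sw$bar_pos, xout = tt,
                                         rule = 2)$y
    list(on = pos_at(gf$mu - gf$sd), off = pos_at(gf$mu + gf$sd), r2 = gf$r2)
  }
  # along-axis coordinates: direction 0 -> bar_pos = x of bar line;
  # direction 180 -> bar_pos = -x; similarly 90/270 for y
  h1 <- border_fit(0); h2 <- border_fit(180)
  v1 <- border_fit(90); v2 <- border_fit(270)
  left   <- (min(h1$on, h1$off) + min(-h2$on, -h2$off)) / 2
  right  <- (max(h1$on, h1$off) + max(-h2$on, -h2$off)) / 2
  bottom <- (min(v1$on, v1$off) + min(-v2$on, -v2$off)) / 2
  top    <- (max(v1$on, v1$off) + max(-v2$on, -v2$off)) / 2
  width <- right - left
  height <- top - bottom
  sig <- c(width, height) / 2    # onset/offset span mu +/- sd -> 2 SD
  structure(list(
    left = left, right = right, bottom = bottom, top = top,
    center = c(x = (left + right) / 2, y = (bottom + top) / 2),
    width = width, height = height,
    size = sqrt(width^2 + height^2) / 2,
    aspect_ratio = max(sig) / min(sig),
    snr = snr,
    fit_r2 = min(h1$r2, h2$r2, v1$r2, v2$r2)
  ), class = "crf_estimate")
}

# least-squares Gaussian + offset fit to a response trace
fit_gaussian_trace <- function(t, y) {
  i0 <- which.max(y)
  start <- list(A = max(y) - stats::median(y), mu = t[i0],
                sd = max(diff(range(t)) / 10, 1e-3), b = stats::median(y))
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(t - mu)^2 / (2 * sd^2)) + b,
    start = start,
    lower = c(A = 0, mu = min(t), sd = 1e-4, b = -Inf),
    upper = c(A = Inf, mu = max(t), sd = diff(range(t)), b = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(mu = t[i0], sd = diff(range(t)) / 10, r2 = -Inf))
  co <- stats::coef(fit)
  r2 <- 100 * (1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2))
  list(mu = unname(co["mu"]), sd = unname(co["sd"]), r2 = r2)
}

#' cRF diameter from an SD-equivalent size
#'
#' Conventional receptive-field diameter, defined as 3.3 times the
#' SD-equivalent radius.
#'
#' @param crf a \code{crf_estimate} (or a numeric size).
#' @return diameter, dva.
#' @export
crf_diameter <- function(crf) {
  s <- if (inherits(crf, "crf_estimate")) crf$size else crf
  3.3 * s
}
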