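#' Sample a ground-truth pRF population
#'
#' Draws a synthetic population of pRFs mimicking implant coverage of the
#' lower-right visual quadrant: centers uniform in the quadrant within the
#' area's eccentricity limit (8 dva for V1, 14 dva for V4), sizes following a
#' linear eccentricity-size trend with lognormal jitter, CSS exponents
#' truncated-normal in (0, 1], and positive gains (with an optional fraction
#' of negative-gain units for testing suppression).
#'
#' @param area \code{"V1"} or \code{"V4"} (sets eccentricity limit and the
#'   default slope).
#' @param n_units number of units.
#' @param ecc_size_slope dva size per dva eccentricity (defaults: 0.1 for V1,
#'   0.3 for V4).
#' @param ecc_size_intercept size at fixation, dva.
#' @param exponent_mean mean CSS exponent (default 0.35).
#' @param exponent_sd SD of the exponent before truncation.
#' @param sigma_jitter_sdlog SD of the lognormal size jitter.
#' @param gain_mean mean gain.
#' @param frac_negative fraction of units with negative gain.
#' @param ecc_max override the area's eccentricity limit.
#' @param seed RNG seed.
#' @return data frame with one row per unit: x0, y0, ecc, sigma, exponent,
#'   gain, area. Attribute \code{seed} records the seed.
#' @export
sample_population <- function(area = c("V1", "V4"), n_units = 100,
                              ecc_size_slope = NULL,
                              ecc_size_intercept = 0.5,
                              exponent_mean = 0.35, exponent_sd = 0.15,
                              sigma_jitter_sdlog = 0.15,
                              gain_mean = 1, frac_negative = 0,
                              ecc_max = NULL, seed = 1) {
  area <- match.arg(area)
  stopifnot(n_units >= 1)
  if (is.null(ecc_size_slope))
    ecc_size_slope <- switch(area, V1 = 0.1, V4 = 0.3)
  if (is.null(ecc_max)) ecc_max <- switch(area, V1 = 8, V4 = 14)
  set.seed(seed)
  # uniform over the lower-right quadrant disc sector (ecc in [0.25, ecc_max])
  ecc <- sqrt(stats::runif(n_units, 0.25^2 / ecc_max^2, 1)) * ecc_max
  ang <- stats::runif(n_units, -pi / 2, 0)
  x0 <- ecc * cos(ang)
  y0 <- ecc * sin(ang)
  sigma <- (ecc_size_intercept + ecc_size_slope * ecc) *
    stats::rlnorm(n_units, 0, sigma_jitter_sdlog)
  if (any(sigma <= 0)) stop("sampled non-positive sizes; check slope/intercept")
  exponent <- rtruncnorm(n_units, exponent_mean, exponent_sd, 0.05, 1)
  gain <- abs(stats::rnorm(n_units, gain_mean, 0.2 * abs(gain_mean)))
  neg <- stats::runif(n_units) < frac_negative
  gain[neg] <- -gain[neg]
  out <- data.frame(unit = seq_len(n_units), x0 = x0, y0 = y0, ecc = ecc,
                    sigma = sigma, exponent = exponent, gain = gain,
                    area = area)
  attr(out, "seed") <- seed
  out
}

# truncated normal via inverse-CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

pop_params <- function(pop, i, model = "CSS") {
  r <- pop[i, ]
  if (model %in% c("P-LIN", "U-LIN", "DoG")) {
    # DoG surround: 2.5x the center SD with amplitude 0.18, i.e. a normalized
    # suppressive amplitude of 0.18 * 2.5^2 = 1.125
    prf_params(model, r$x0, r$y0, r$sigma,
               sigma2 = if (model == "DoG") 2.5 * r$sigma else NA,
               amp_surround = if (model == "DoG") 0.18 else NA,
               exponent = 1, gain = r$gain)
  } else {
    prf_params("CSS", r$x0, r$y0, r$sigma, exponent = r$exponent,
               gain = if (r$gain <= 0) 1e-12 else r$gain)
  }
}

resolve_noise <- function(clean, noise_sd, rel_noise) {
  if (!is.null(noise_sd)) return(noise_sd)
  if (is.null(rel_noise)) stop("supply noise_sd or rel_noise")
  rel_noise * stats::sd(clean)
}

#' Synthesize BOLD runs from a ground-truth population
#'
#' Per run and unit, the forward model (pRF drive, optional compressive
#' exponent, HRF convolution, TR sampling) plus additive Gaussian noise.
#' Odd and even runs are averaged into the two cross-validation halves.
#'
#' @param pop population from \code{sample_population}.
#' @param stim an \code{effective_stimulus}.
#' @param hrf an \code{hrf_kernel}.
#' @param tr repetition time, seconds.
#' @param noise_sd per-TR noise SD (percent signal change); or \code{NULL}
#'   with \code{rel_noise} set.
#' @param rel_noise noise SD as a fraction of each unit's noise-free response
#'   SD.
#' @param n_runs number of runs (even).
#' @param model generating model (\code{"CSS"} uses the sampled exponent;
#'   linear models force n = 1).
#' @param seed RNG seed.
#' @return a \code{prf_dataset} with \code{truth} attached.
#' @export
synth_bold <- function(pop, stim, hrf, tr, noise_sd = NULL, rel_noise = NULL,
                       n_runs = 4, model = "CSS", seed = 1) {
  stopifnot(n_runs %% 2 == 0)
  set.seed(seed)
  n <- nrow(pop)
  clean <- lapply(seq_len(n), function(i)
    predict_bold(pop_params(pop, i, model), stim, hrf, tr))
  tlen <- length(clean[[1]])
  half_a <- half_b <- matrix(0, n, tlen)
  for (i in seq_len(n)) {
    sdn <- resolve_noise(clean[[i]], noise_sd, rel_noise)
    runs <- replicate(n_runs, clean[[i]] + stats::rnorm(tlen, 0, sdn))
    half_a[i, ] <- rowMeans(runs[, seq(1, n_runs, 2), drop = FALSE])
    half_b[i, ] <- rowMeans(runs[, seq(2, n_runs, 2), drop = FALSE])
  }
  prf_dataset(half_a, half_b, stim, "bold", hrf = hrf, tr = tr, truth = pop)
}

#' Synthesize per-position electrode responses
#'
#' As \code{synth_bold} but without hemodynamics: one response per stimulus
#' position per repeat, odd/even repeats averaged into the two halves.
#'
#' @inheritParams synth_bold
#' @param n_repeats number of repeats (even).
#' @param modality dataset tag (\code{"mua"} or \code{"lfp_band"}).
#' @return a \code{prf_dataset} with \code{truth} attached.
#' @export
synth_ephys <- function(pop, stim, noise_sd = NULL, rel_noise = NULL,
                        n_repeats = 8, model = "CSS", modality = "mua",
                        seed = 1) {
  stopifnot(n_repeats %% 2 == 0)
  set.seed(seed)
  n <- nrow(pop)
  nf <- dim(stim$frames)[3]
  half_a <- half_b <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    clean <- predict_response(pop_params(pop, i, model), stim)
    sdn <- resolve_noise(clean, noise_sd, rel_noise)
    reps <- replicate(n_repeats, clean + stats::rnorm(nf, 0, sdn))
    half_a[i, ] <- rowMeans(reps[, seq(1, n_repeats, 2), drop = FALSE])
    half_b[i, ] <- rowMeans(reps[, seq(2, n_repeats, 2), drop = FALSE])
  }
  prf_dataset(half_a, half_b, stim, modality, truth = pop)
}

#' Synthesize a raw LFP-like signal with stimulus-locked band power
#'
#' A band-limited Gaussian noise carrier whose instantaneous power is
#' modulated per stimulus position by the unit's (normalized) pRF drive:
#' power multiplier \code{1 + depth * drive / max|drive|} (sign of the gain
#' preserved, so negative-gain units suppress power). Sampled at 500 Hz with
#' per-position event times.
#'
#' @param unit_params a \code{prf_params} for the generating unit.
#' @param stim an \code{effective_stimulus} (its protocol supplies timing).
#' @param band band name from \code{names(lfp_bands())}.
#' @param depth modulation fraction (0 = no stimulus locking).
#' @param n_repeats how many times the movie repeats.
#' @param fs sampling rate (default 500 Hz).
#' @param seed RNG seed.
#' @return list: \code{x} signal, \code{fs}, \code{events} (sweep, position,
#'   onset), \code{band}, \code{truth}.
#' @export
synth_raw_lfp <- function(unit_params, stim, band = "gamma_low", depth = 0.5,
                          n_repeats = 2, fs = 500, seed = 1) {
  edges <- lfp_bands()[[band]]
  if (is.null(edges)) stop("unknown band: ", band)
  set.seed(seed)
  p <- stim$protocol
  dur1 <- protocol_duration(p)
  nsamp1 <- round(dur1 * fs)
  drive <- predict_response(unit_params, stim)
  mx <- max(abs(drive))
  drive_norm <- if (mx > 0) drive / mx else drive

  # per-sample power multiplier over one movie repeat
  bin_len <- round(p$step_duration * fs)
  mult_bins <- c(0, drive_norm)[stim$seq + 1L]
  mult <- rep(1 + depth * mult_bins, each = bin_len)
  length(mult) <- nsamp1
  mult[is.na(mult)] <- 1
  mult <- pmax(mult, 0.02)

  nsweep <- length(p$sweep_directions)
  nstep <- p$n_steps_per_sweep
  bar_bins <- which(stim$seq > 0)
  events1 <- data.frame(
    sweep = (stim$seq[bar_bins] - 1) %/% nstep + 1,
    position = stim$seq[bar_bins],
    onset = stim$onsets[bar_bins]
  )
  x <- numeric(0); events <- NULL
  for (r in seq_len(n_repeats)) {
    carrier <- butter_filtfilt(stats::rnorm(nsamp1), fs,
                               lo = edges[1], hi = edges[2])
    carrier <- carrier / stats::sd(carrier)
    x <- c(x, carrier * sqrt(mult))
    ev <- events1
    ev$onset <- ev$onset + (r - 1) * dur1
    ev$sweep <- ev$sweep + (r - 1) * nsweep
    events <- rbind(events, ev)
  }
  list(x = x, fs = fs, events = events, band = band,
       truth = unit_params, depth = depth)
}

#' Synthesize MUA traces for moving-bar cRF mapping
#'
#' A thin bar sweeps across the aperture in each requested direction; the
#' response is the Gaussian RF drive along the bar trajectory, shifted by a
#' response latency, plus Gaussian noise. A spontaneous (pre-sweep) epoch of
#' pure noise is included per sweep for SNR estimation.
#'
#' @param unit_params a \code{prf_params} (center and sigma1 are used).
#' @param aperture sweep extent (diameter), dva.
#' @param bar_speed dva per second.
#' @param directions motion directions, degrees; must contain opposite
#'   horizontal and vertical pairs for \code{estimate_crf}.
#' @param latency response latency, seconds.
#' @param noise_sd trace noise SD relative to a unit-amplitude response.
#' @param amplitude peak response amplitude.
#' @param n_repeats repeats per direction.
#' @param spont_dur spontaneous epoch per sweep, seconds.
#' @param fs trace sampling rate, Hz.
#' @param seed RNG seed.
#' @return list: \code{sweeps} (for \code{estimate_crf}), \code{spont_sd}
#'   (empirical SD of the spontaneous epochs), \code{truth}.
#' @export
synth_moving_bar_mua <- function(unit_params, aperture = 28, bar_speed = 14,
                                 directions = c(0, 180, 90, 270),
                                 latency = 0, noise_sd = 0.05,
                                 amplitude = 1, n_repeats = 4,
                                 spont_dur = 1, fs = 1000, seed = 1) {
  set.seed(seed)
  R <- aperture / 2
  dur <- aperture / bar_speed
  t <- seq(0, dur, by = 1 / fs)
  spont <- NULL
  sweeps <- lapply(directions, function(dg) {
    th <- dg * pi / 180
    c_along <- unit_params$x0 * cos(th) + unit_params$y0 * sin(th)
    bar_pos <- -R + bar_speed * t
    drive <- amplitude *
      exp(-(-R + bar_speed * (t - latency) - c_along)^2 /
            (2 * unit_params$sigma1^2))
    resp <- matrix(stats::rnorm(n_repeats * length(t), 0, noise_sd),
                   nrow = n_repeats, byrow = TRUE)
    resp <- sweep(resp, 2, drive, "+")
    spont_ep <- matrix(stats::rnorm(n_repeats * round(spont_dur * fs),
                                    0, noise_sd), nrow = n_repeats)
    spont <<- c(spont, as.vector(spont_ep))
    list(direction = dg, t = t, response = resp, bar_pos = bar_pos)
  })
  list(sweeps = sweeps, spont_sd = stats::sd(spont), truth = unit_params)
}
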