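#' pRF model parameters
#'
#' A population receptive field is an isotropic 2-D Gaussian in visual space,
#' described by its center (x0, y0), standard deviation sigma1, and a gain g.
#' Four model variants are supported:
#' \describe{
#'   \item{P-LIN}{linear spatial summation, gain constrained positive.}
#'   \item{U-LIN}{linear, gain may be negative (suppressed responses).}
#'   \item{DoG}{difference of Gaussians: an excitatory center minus a broader
#'     suppressive surround with SD sigma2 > sigma1 and relative amplitude
#'     \code{amp_surround}; linear summation.}
#'   \item{CSS}{compressive spatial summation: the pRF-weighted stimulus
#'     drive is raised to an exponent n (n < 1 means subadditive summation).}
#' }
#'
#' The Gaussian is unit-peak (unnormalized); all scaling is absorbed by the
#' gain.
#'
#' @param model one of \code{"P-LIN"}, \code{"U-LIN"}, \code{"DoG"},
#'   \code{"CSS"}.
#' @param x0,y0 pRF center, dva.
#' @param sigma1 center SD, dva (> 0).
#' @param sigma2 surround SD, dva (DoG only; > sigma1).
#' @param amp_surround surround amplitude a >= 0 (DoG only).
#' @param exponent spatial summation exponent n (CSS; fixed at 1 otherwise).
#' @param gain response gain g.
#' @return An object of class \code{prf_params}.
#' @export
prf_params <- function(model, x0, y0, sigma1, sigma2 = NA_real_,
                       amp_surround = NA_real_, exponent = 1, gain = 1) {
  model <- match.arg(model, c("P-LIN", "U-LIN", "DoG", "CSS"))
  if (!is.finite(sigma1) || sigma1 <= 0) stop("sigma1 must be > 0")
  if (model == "DoG") {
    if (!is.finite(sigma2) || sigma2 <= sigma1)
      stop("DoG requires sigma2 > sigma1")
    if (!is.finite(amp_surround) || amp_surround < 0)
      stop("DoG requires amp_surround >= 0")
  }
  if (model == "CSS") {
    if (!is.finite(exponent) || exponent <= 0)
      stop("CSS requires exponent > 0")
  } else if (model != "CSS" && !isTRUE(all.equal(exponent, 1))) {
    stop("exponent is fixed at 1 for ", model)
  }
  if (model %in% c("P-LIN", "CSS") && gain <= 0)
    stop(model, " requires gain > 0")
  structure(list(model = model, x0 = x0, y0 = y0, sigma1 = sigma1,
                 sigma2 = sigma2, amp_surround = amp_surround,
                 exponent = exponent, gain = gain),
            class = "prf_params")
}

#' Evaluate the pRF spatial profile on a pixel grid
#'
#' Unit-peak Gaussian \code{exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma1^2))};
#' for the DoG model the broader surround Gaussian (SD sigma2) scaled by
#' \code{amp_surround} is subtracted.
#'
#' @param params a \code{prf_params}.
#' @param grid a pixel grid from \code{stim_pixel_grid} (or any list with
#'   numeric \code{x}, \code{y}).
#' @return numeric vector of per-pixel weights (same order as grid pixels).
#' @export
prf_field <- function(params, grid) {
  d2 <- (grid$x - params$x0)^2 + (grid$y - params$y0)^2
  g1 <- exp(-d2 / (2 * params$sigma1^2))
  if (params$model == "DoG") {
    g2 <- exp(-d2 / (2 * params$sigma2^2))
    g1 - params$amp_surround * g2
  } else {
    g1
  }
}

#' Predicted response to an effective stimulus
#'
#' For each bar frame the response is
#' \code{g * (sum_xy S(x, y) G(x, y))^n}; the pixel sum is divided by
#' \code{pixels_per_dva^2} so predictions are independent of the rendering
#' resolution. The DoG drive may be negative (net surround suppression) and
#' passes through signed with n = 1; for negative U-LIN gains the linear
#' drive is scaled by the (negative) gain.
#'
#' @param params a \code{prf_params}.
#' @param stim an \code{effective_stimulus}.
#' @return numeric vector, one response per bar frame (sweep order).
#' @export
predict_response <- function(params, stim) {
  drv <- frame_drive(params, stim)
  apply_gain(drv, params)
}

# pre-gain, pre-exponent pRF-weighted drive per bar frame (dva^2 units)
frame_drive <- function(params, stim) {
  field <- prf_field(params, stim$grid)
  as.vector(frame_matrix(stim) %*% field) / stim$protocol$pixels_per_dva^2
}

apply_gain <- function(drive, params) {
  n <- params$exponent
  if (isTRUE(all.equal(n, 1))) return(params$gain * drive)
  params$gain * sign(drive) * abs(drive)^n
}

#' Predicted BOLD time series
#'
#' The per-frame neural prediction is expanded to half-TR resolution using
#' the stimulus time-bin sequence (blank bins contribute zero drive),
#' convolved with the HRF, and decimated to TR resolution.
#'
#' @param params a \code{prf_params}.
#' @param stim an \code{effective_stimulus}.
#' @param hrf an \code{hrf_kernel}.
#' @param tr repetition time, seconds. Must satisfy
#'   \code{step_duration \%\% (tr/2) == 0}.
#' @return numeric vector of BOLD samples at TR resolution.
#' @export
predict_bold <- function(params, stim, hrf, tr) {
  neural <- neural_timeseries(predict_response(params, stim), stim, tr)
  convolve_to_bold(neural, hrf, tr)
}

# expand per-frame responses to a tr/2-resolution time series using stim$seq
neural_timeseries <- function(frame_resp, stim, tr) {
  dt <- tr / 2
  rep_per_bin <- stim$protocol$step_duration / dt
  if (abs(rep_per_bin - round(rep_per_bin)) > 1e-9)
    stop("step_duration must be an integer multiple of tr/2")
  per_bin <- c(0, frame_resp)[stim$seq + 1L]
  rep(per_bin, each = round(rep_per_bin))
}

#' pRF size
#'
#' The pRF size is the standard deviation of the predicted Gaussian response
#' profile to a point stimulus: \code{sigma1 / sqrt(n)} (equal to sigma1 for
#' the linear models). For the DoG model the center size sigma1 is returned,
#' with the surround size sigma2 reported separately.
#'
#' @param params a \code{prf_params}.
#' @return For non-DoG models, a single value in dva. For DoG, a named vector
#'   \code{c(center = sigma1, surround = sigma2)}.
#' @export
prf_size <- function(params) {
  if (params$model == "DoG")
    return(c(center = params$sigma1, surround = params$sigma2))
  params$sigma1 / sqrt(params$exponent)
}

#' Normalized suppressive amplitude of a DoG pRF
#'
#' Surround-to-center volume ratio \code{a * (sigma2 / sigma1)^2}; values
#' above 1 indicate net suppression.
#'
#' @param params a DoG \code{prf_params}.
#' @return dimensionless ratio.
#' @export
suppressive_amplitude <- function(params) {
  if (params$model != "DoG") stop("suppressive amplitude is DoG-only")
  params$amp_surround * (params$sigma2 / params$sigma1)^2
}

#' Flatten pRF parameters to a one-row data frame
#' @param params a \code{prf_params}.
#' @return data frame with model tag, parameters, eccentricity, polar angle
#'   (degrees, atan2(y0, x0)), and size.
#' @export
as.data.frame.prf_params <- function(x, ...) {
  params <- x
  sz <- prf_size(params)
  data.frame(model = params$model, x0 = params$x0, y0 = params$y0,
             sigma1 = params$sigma1, sigma2 = params$sigma2,
             amp_surround = params$amp_surround,
             exponent = params$exponent, gain = params$gain,
             ecc = sqrt(params$x0^2 + params$y0^2),
             polar_angle = atan2(params$y0, params$x0) * 180 / pi,
             size = unname(sz[1]))
}
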