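#' Separation index between two receptive fields
#'
#' Euclidean distance between the two centers divided by the sum of the two
#' size estimates: \code{SI = D / (size_a + size_b)}. A value below 1
#' indicates overlapping receptive fields. The index is symmetric and
#' invariant to a common rescaling of positions and sizes.
#'
#' @param center_a,center_b numeric length-2 centers (x, y), dva.
#' @param size_a,size_b positive sizes (SD-equivalent), dva.
#' @return list: \code{si}, \code{overlapping} (\code{si < 1}).
#' @export
separation_index <- function(center_a, size_a, center_b, size_b) {
  if (size_a <= 0 || size_b <= 0) stop("sizes must be positive")
  d <- sqrt(sum((center_a - center_b)^2))
  si <- d / (size_a + size_b)
  list(si = si, overlapping = si < 1)
}

#' Classify pRFs as positive or negative from U-LIN gains
#'
#' The positive/negative split is based on the sign of the fitted gain of the
#' unconstrained linear model; a gain of exactly zero is labelled
#' indeterminate.
#'
#' @param fit_table data frame of U-LIN fits with a \code{gain} column (a
#'   \code{model} column, if present, must equal \code{"U-LIN"}).
#' @return character vector: \code{"positive"}, \code{"negative"}, or
#'   \code{"indeterminate"} per row.
#' @export
classify_negative <- function(fit_table) {
  if (!"gain" %in% names(fit_table)) stop("fit table lacks a gain column")
  if ("model" %in% names(fit_table) && !all(fit_table$model == "U-LIN"))
    stop("negative-pRF classification requires U-LIN fits")
  ifelse(fit_table$gain > 0, "positive",
         ifelse(fit_table$gain < 0, "negative", "indeterminate"))
}

#' Eccentricity-size relationship
#'
#' Per-unit linear regression of pRF size on eccentricity (unbinned) for the
#' slope, its confidence interval and p-value, plus binned means with SEM for
#' display (half-open eccentricity bins of \code{bin_width} dva).
#'
#' @param table data frame with columns \code{ecc}, \code{size}, and
#'   optionally \code{r2_cv} for thresholding.
#' @param r2_threshold inclusion threshold in percent applied to
#'   \code{r2_cv} when present (default \code{NULL}: no filtering).
#' @param bin_width eccentricity bin width, dva.
#' @param conf_level confidence level for the slope/intercept intervals.
#' @return list: \code{slope}, \code{intercept}, \code{ci} (2 x 2 matrix),
#'   \code{p_slope}, \code{n_units}, \code{bins} (data frame: bin_lo, bin_hi,
#'   mean_ecc, mean_size, sem_size, n), \code{model} (the lm fit).
#' @export
ecc_size_relation <- function(table, r2_threshold = NULL, bin_width = 2,
                              conf_level = 0.95) {
  if (!is.null(r2_threshold) && "r2_cv" %in% names(table))
    table <- table[table$r2_cv > r2_threshold, , drop = FALSE]
  if (nrow(table) < 3) stop("insufficient units for a slope fit (need >= 3)")
  m <- stats::lm(size ~ ecc, data = table)
  sm <- summary(m)
  ci <- stats::confint(m, level = conf_level)
  bin <- floor(table$ecc / bin_width)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    s <- table$size[bin == b]
    data.frame(bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width,
               mean_ecc = mean(table$ecc[bin == b]),
               mean_size = mean(s),
               sem_size = stats::sd(s) / sqrt(length(s)),
               n = length(s))
  }))
  list(slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]),
       ci = ci,
       p_slope = sm$coefficients[2, 4],
       n_units = nrow(table), bins = bins, model = m)
}

#' Compare eccentricity-size slopes between signal types
#'
#' Linear model \code{size ~ ecc * signal}: the F-test on the interaction
#' term asks whether the eccentricity-size slope differs between signal
#' types; pairwise contrasts compare a reference signal (default the first
#' level, conventionally BOLD) against each other signal.
#'
#' Comparisons of this kind are often run as linear mixed models; here
#' fixed-effects linear models are the default, with a \code{fitter} hook to
#' swap in a mixed-model backend (the hook receives the formula and data and
#' must return an object supported by \code{anova}).
#'
#' @param table data frame with columns \code{ecc}, \code{size},
#'   \code{signal}.
#' @param reference reference signal for pairwise contrasts (default: first
#'   factor level).
#' @param fitter optional replacement model-fitting function
#'   \code{function(formula, data)}.
#' @return list: \code{interaction} (F, df, p for the global
#'   signal x eccentricity interaction), \code{pairwise} (data frame of
#'   reference-vs-signal interaction tests), \code{model}.
#' @export
compare_slopes <- function(table, reference = NULL, fitter = NULL) {
  stopifnot(all(c("ecc", "size", "signal") %in% names(table)))
  table$signal <- factor(table$signal)
  if (nlevels(table$signal) < 2) stop("need >= 2 signal types")
  if (is.null(reference)) reference <- levels(table$signal)[1]
  table$signal <- stats::relevel(table$signal, ref = reference)
  fit2 <- if (is.null(fitter)) stats::lm else fitter

  itest <- function(dat) {
    m0 <- fit2(size ~ ecc + signal, data = dat)
    m1 <- fit2(size ~ ecc * signal, data = dat)
    a <- stats::anova(m0, m1)
    list(F = a$F[2], df = a$Df[2], p = a$`Pr(>F)`[2], model = m1)
  }
  global <- itest(table)
  others <- setdiff(levels(table$signal), reference)
  pairwise <- do.call(rbind, lapply(others, function(s) {
    sub <- droplevels(table[table$signal %in% c(reference, s), ])
    r <- itest(sub)
    data.frame(signal = s, F = r$F, df = r$df, p = r$p)
  }))
  list(interaction = list(F = global$F, df = global$df, p = global$p),
       pairwise = pairwise, model = global$model)
}
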