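#' Response dataset for pRF fitting
#'
#' Bundles the two non-overlapping data halves (averages of odd and even
#' runs/repeats) with the effective stimulus they are aligned to and, for
#' BOLD data, the HRF and TR.
#'
#' @param half_a,half_b numeric matrices, units x samples. For
#'   \code{modality = "bold"} samples are TRs; otherwise one response per bar
#'   frame (stimulus position, in sweep order).
#' @param stim an \code{effective_stimulus}.
#' @param modality \code{"bold"}, \code{"mua"}, or \code{"lfp_band"}.
#' @param hrf an \code{hrf_kernel} (BOLD only).
#' @param tr repetition time, seconds (BOLD only).
#' @param truth optional data frame of generating parameters (synthetic data).
#' @return An object of class \code{prf_dataset}.
#' @export
prf_dataset <- function(half_a, half_b, stim, modality = c("bold", "mua", "lfp_band"),
                        hrf = NULL, tr = NULL, truth = NULL) {
  modality <- match.arg(modality)
  half_a <- rbind(half_a); half_b <- rbind(half_b)
  if (!all(dim(half_a) == dim(half_b)))
    stop("data halves must have identical dimensions")
  if (modality == "bold" && (is.null(hrf) || is.null(tr)))
    stop("BOLD datasets need an HRF kernel and TR")
  nexp <- if (modality == "bold") {
    length(neural_timeseries(rep(0, dim(stim$frames)[3]), stim, tr)) / 2
  } else {
    dim(stim$frames)[3]
  }
  if (ncol(half_a) != nexp)
    stop("data length (", ncol(half_a), ") does not match stimulus (", nexp, ")")
  structure(list(half_a = half_a, half_b = half_b, stim = stim,
                 modality = modality, hrf = hrf, tr = tr, truth = truth,
                 n_units = nrow(half_a)),
            class = "prf_dataset")
}

#' Fitting control parameters
#'
#' @param grid_nxy grid points per axis for the coarse x0/y0 search.
#' @param grid_nsigma number of log-spaced sigma values (0.1 dva to the
#'   aperture diameter).
#' @param grid_exponent exponent values scanned for the CSS model.
#' @param top_k seeds retained for local refinement.
#' @param maxit iteration cap for the bounded quasi-Newton refinement.
#' @param sigma_bounds,exponent_bounds,amp_bounds parameter box constraints;
#'   centers are constrained to 1.5 x the aperture radius, the DoG surround
#'   to 4 x the aperture diameter.
#' @export
prf_fit_control <- function(grid_nxy = 8, grid_nsigma = 6,
                            grid_exponent = c(0.25, 0.5, 1),
                            top_k = 2, maxit = 40,
                            sigma_bounds = NULL,
                            exponent_bounds = c(0.05, 1.5),
                            amp_bounds = c(0, 3)) {
  list(grid_nxy = grid_nxy, grid_nsigma = grid_nsigma,
       grid_exponent = grid_exponent, top_k = top_k, maxit = maxit,
       sigma_bounds = sigma_bounds, exponent_bounds = exponent_bounds,
       amp_bounds = amp_bounds)
}

# precomputed machinery shared by grid search and refinement:
# frame matrix, pixel grid, and the map from per-frame drives to a
# prediction aligned with the data (identity for ephys, HRF pipeline for BOLD)
fit_context <- function(dataset, control = prf_fit_control()) {
  stim <- dataset$stim
  p <- stim$protocol
  ap <- p$aperture_diameter
  ctx <- list(
    M = frame_matrix(stim), grid = stim$grid, ppd2 = p$pixels_per_dva^2,
    aperture = ap, rmax = 1.5 * ap / 2,
    sigma_bounds = if (is.null(control$sigma_bounds)) c(0.05, 2 * ap)
                   else control$sigma_bounds,
    exponent_bounds = control$exponent_bounds,
    amp_bounds = control$amp_bounds,
    control = control
  )
  if (dataset$modality == "bold") {
    tr <- dataset$tr
    hk <- resample_hrf(dataset$hrf, tr / 2)
    rep_per_bin <- round(p$step_duration / (tr / 2))
    seq_idx <- rep(stim$seq, each = rep_per_bin)
    nsamp <- length(seq_idx)
    ctx$map <- function(frame_vals) {
      neural <- c(0, frame_vals)[seq_idx + 1L]
      conv <- stats::convolve(neural, rev(hk), type = "open")[seq_len(nsamp)]
      0.5 * (conv[seq(1, nsamp, by = 2)] + conv[seq(2, nsamp, by = 2)])
    }
  } else {
    ctx$map <- identity
  }
  ctx$cache <- new.env(parent = emptyenv())
  ctx
}

# grid candidates and their mapped prediction shapes, cached per model in the
# context (they depend on the stimulus only, so they are shared across data
# halves and units)
grid_predictions <- function(ctx, model) {
  key <- model
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  control <- ctx$control
  ax <- seq(-ctx$rmax, ctx$rmax, length.out = control$grid_nxy)
  sig <- exp(seq(log(0.1), log(ctx$aperture), length.out = control$grid_nsigma))
  spatial <- expand.grid(x0 = ax, y0 = ax, sigma1 = sig)
  fields <- exp(-(outer(ctx$grid$x, spatial$x0, "-")^2 +
                  outer(ctx$grid$y, spatial$y0, "-")^2) /
                 rep(2 * spatial$sigma1^2, each = length(ctx$grid$x)))
  drives <- (ctx$M %*% fields) / ctx$ppd2
  map_cols <- function(m) {
    if (identical(ctx$map, identity)) return(m)
    out <- vapply(seq_len(ncol(m)), function(j) ctx$map(m[, j]),
                  numeric(length(ctx$map(m[, 1]))))
    matrix(out, ncol = ncol(m))
  }
  entry <- if (model == "DoG") {
    sig2_mult <- 2.5
    fields2 <- exp(-(outer(ctx$grid$x, spatial$x0, "-")^2 +
                     outer(ctx$grid$y, spatial$y0, "-")^2) /
                    rep(2 * (sig2_mult * spatial$sigma1)^2,
                        each = length(ctx$grid$x)))
    drives2 <- (ctx$M %*% fields2) / ctx$ppd2
    list(cand = cbind(spatial, sigma2 = sig2_mult * spatial$sigma1,
                      exponent = 1),
         p1 = map_cols(drives), p2 = map_cols(drives2))
  } else {
    exps <- if (model == "CSS") control$grid_exponent else 1
    cand <- spatial[rep(seq_len(nrow(spatial)), times = length(exps)), ]
    cand$exponent <- rep(exps, each = nrow(spatial))
    preds <- do.call(cbind, lapply(exps, function(n) {
      map_cols(if (isTRUE(all.equal(n, 1))) drives else drives^n)
    }))
    list(cand = cand, preds = preds)
  }
  ctx$cache[[key]] <- entry
  entry
}

# drives for a Gaussian component (pre-gain, pre-exponent)
ctx_drive <- function(ctx, x0, y0, sigma) {
  d2 <- (ctx$grid$x - x0)^2 + (ctx$grid$y - y0)^2
  as.vector(ctx$M %*% exp(-d2 / (2 * sigma^2))) / ctx$ppd2
}

# profile the linear parameters for one candidate pRF; returns prediction,
# gain (and amp for DoG) and SSE against `data`
profile_linear <- function(ctx, model, data, x0, y0, sigma1,
                           sigma2 = NA, exponent = 1) {
  if (model == "DoG") {
    p1 <- ctx$map(ctx_drive(ctx, x0, y0, sigma1))
    p2 <- ctx$map(ctx_drive(ctx, x0, y0, sigma2))
    # data ~ g*p1 - (g a)*p2, g > 0, a in amp_bounds
    s11 <- sum(p1 * p1); s22 <- sum(p2 * p2); s12 <- sum(p1 * p2)
    c1 <- sum(p1 * data); c2 <- sum(p2 * data)
    det <- s11 * s22 - s12^2
    if (det > 1e-10 * max(s11 * s22, 1e-300)) {
      g <- (c1 * s22 - c2 * s12) / det
      b2 <- (c2 * s11 - c1 * s12) / det
      a <- if (g > 0) -b2 / g else 0
    } else {
      a <- 0
    }
    a <- min(max(a, ctx$amp_bounds[1]), ctx$amp_bounds[2])
    # (re-)profile g at the clamped surround amplitude
    g <- max((c1 - a * c2) /
               max(s11 - 2 * a * s12 + a^2 * s22, 1e-300), 0)
    pred <- g * (p1 - a * p2)
    return(list(pred = pred, gain = g, amp = a,
                sse = sum((data - pred)^2)))
  }
  drv <- ctx_drive(ctx, x0, y0, sigma1)
  shape <- ctx$map(if (isTRUE(all.equal(exponent, 1))) drv else drv^exponent)
  g <- sum(shape * data) / max(sum(shape * shape), 1e-300)
  if (model %in% c("P-LIN", "CSS")) g <- max(g, 0)
  pred <- g * shape
  list(pred = pred, gain = g, amp = NA_real_, sse = sum((data - pred)^2))
}

rcond_2x2 <- function(m) {
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  abs(d) / max(m[1, 1] * m[2, 2], 1e-300)
}

#' Coarse grid initialization
#'
#' Scans a coarse grid of center positions (within 1.5 x the aperture radius,
#' so centers may lie outside the stimulated field), log-spaced sigma values,
#' and (for CSS) a small set of exponents. The gain (and DoG surround
#' amplitude) is solved in closed form by least squares at each grid point;
#' the top-k seeds by training R-squared are returned.
#'
#' @param stim an \code{effective_stimulus}.
#' @param data_half numeric response vector for one data half.
#' @param model model tag.
#' @param dataset optional \code{prf_dataset} providing the BOLD context; if
#'   omitted, an ephys-style (per-position) alignment is assumed.
#' @param control a \code{prf_fit_control}.
#' @return list of \code{prf_params} seeds, best first.
#' @export
grid_init <- function(stim, data_half, model, dataset = NULL,
                      control = prf_fit_control()) {
  if (is.null(dataset))
    dataset <- prf_dataset(rbind(data_half), rbind(data_half), stim,
                           modality = "mua")
  ctx <- fit_context(dataset, control)
  grid_init_ctx(ctx, data_half, model)
}

grid_init_ctx <- function(ctx, data, model) {
  if (all(data == 0))
    stop("degenerate (all-zero) data half: unit is unfittable")
  gp <- grid_predictions(ctx, model)
  cand <- gp$cand
  ss_d <- sum(data^2)
  if (model == "DoG") {
    s11 <- colSums(gp$p1^2); s22 <- colSums(gp$p2^2)
    s12 <- colSums(gp$p1 * gp$p2)
    c1 <- as.vector(crossprod(gp$p1, data))
    c2 <- as.vector(crossprod(gp$p2, data))
    det <- s11 * s22 - s12^2
    ok <- det > 1e-12 * pmax(s11 * s22, 1e-300)
    g <- ifelse(ok, (c1 * s22 - c2 * s12) / det, c1 / pmax(s11, 1e-300))
    b2 <- ifelse(ok, (c2 * s11 - c1 * s12) / det, 0)
    a <- ifelse(g > 0, -b2 / pmax(g, 1e-300), 0)
    a <- pmin(pmax(a, ctx$amp_bounds[1]), ctx$amp_bounds[2])
    # re-profile g for the clamped a: shape = p1 - a p2
    g <- (c1 - a * c2) / pmax(s11 - 2 * a * s12 + a^2 * s22, 1e-300)
    g <- pmax(g, 0)
    sse <- ss_d - 2 * g * (c1 - a * c2) +
      g^2 * (s11 - 2 * a * s12 + a^2 * s22)
    ord <- order(sse)[seq_len(min(ctx$control$top_k, nrow(cand)))]
    return(lapply(ord, function(i) {
      prf_params(model, cand$x0[i], cand$y0[i], cand$sigma1[i],
                 sigma2 = cand$sigma2[i], amp_surround = a[i],
                 exponent = 1, gain = g[i])
    }))
  }
  sp <- colSums(gp$preds^2)
  cp <- as.vector(crossprod(gp$preds, data))
  g <- cp / pmax(sp, 1e-300)
  if (model %in% c("P-LIN", "CSS")) g <- pmax(g, 0)
  sse <- ss_d - 2 * g * cp + g^2 * sp
  ord <- order(sse)[seq_len(min(ctx$control$top_k, nrow(cand)))]
  lapply(ord, function(i) {
    prf_params(model, cand$x0[i], cand$y0[i], cand$sigma1[i],
               exponent = cand$exponent[i],
               gain = gain_floor(model, g[i]))
  })
}

gain_floor <- function(model, g) {
  if (model %in% c("P-LIN", "CSS")) max(g, 1e-12) else g
}

# encode/decode the nonlinear parameter vector for optim
par_encode <- function(model, x0, y0, sigma1, sigma2 = NA, exponent = 1) {
  switch(model,
         "P-LIN" = , "U-LIN" = c(x0, y0, log(sigma1)),
         "CSS" = c(x0, y0, log(sigma1), exponent),
         "DoG" = c(x0, y0, log(sigma1), log(max(sigma2 - sigma1, 1e-3))))
}

par_decode <- function(model, par, ctx) {
  out <- list(x0 = par[1], y0 = par[2], sigma1 = exp(par[3]),
              sigma2 = NA, exponent = 1)
  if (model == "CSS") out$exponent <- par[4]
  if (model == "DoG")
    out$sigma2 <- min(out$sigma1 + exp(par[4]), 4 * ctx$aperture)
  out
}

par_bounds <- function(model, ctx) {
  lo <- c(-ctx$rmax, -ctx$rmax, log(ctx$sigma_bounds[1]))
  hi <- c(ctx$rmax, ctx$rmax, log(ctx$sigma_bounds[2]))
  if (model == "CSS") {
    lo <- c(lo, ctx$exponent_bounds[1]); hi <- c(hi, ctx$exponent_bounds[2])
  }
  if (model == "DoG") {
    lo <- c(lo, log(1e-3)); hi <- c(hi, log(4 * ctx$aperture))
  }
  list(lower = lo, upper = hi)
}

refine_fit <- function(ctx, model, data, seed) {
  par0 <- par_encode(model, seed$x0, seed$y0, seed$sigma1, seed$sigma2,
                     seed$exponent)
  bounds <- par_bounds(model, ctx)
  par0 <- pmin(pmax(par0, bounds$lower), bounds$upper)
  obj <- function(par) {
    q <- par_decode(model, par, ctx)
    profile_linear(ctx, model, data, q$x0, q$y0, q$sigma1, q$sigma2,
                   q$exponent)$sse
  }
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = bounds$lower, upper = bounds$upper,
                      control = list(maxit = ctx$control$maxit, factr = 1e9))
  q <- par_decode(model, opt$par, ctx)
  pl <- profile_linear(ctx, model, data, q$x0, q$y0, q$sigma1, q$sigma2,
                       q$exponent)
  params <- prf_params(model, q$x0, q$y0, q$sigma1, sigma2 = q$sigma2,
                       amp_surround = if (model == "DoG") pl$amp else NA,
                       exponent = q$exponent,
                       gain = gain_floor(model, pl$gain))
  list(params = params, sse = pl$sse, pred = pl$pred,
       converged = opt$convergence == 0, n_evals = opt$counts[["function"]])
}

predict_from_params <- function(ctx, params) {
  pl_model <- params$model
  if (pl_model == "DoG") {
    p1 <- ctx$map(ctx_drive(ctx, params$x0, params$y0, params$sigma1))
    p2 <- ctx$map(ctx_drive(ctx, params$x0, params$y0, params$sigma2))
    params$gain * (p1 - params$amp_surround * p2)
  } else {
    drv <- ctx_drive(ctx, params$x0, params$y0, params$sigma1)
    n <- params$exponent
    shape <- if (isTRUE(all.equal(n, 1))) drv else drv^n
    params$gain * ctx$map(shape)
  }
}

#' Cross-validated percentage of variance explained
#'
#' \code{100 * (1 - SS_res / SS_tot)} with the total sum of squares taken
#' about the held-out mean; a flat prediction at the held-out mean scores 0
#' and values may be negative.
#'
#' @param prediction model prediction from the training fold.
#' @param held_out held-out data of equal length.
#' @return percent variance explained.
#' @export
crossval_r2 <- function(prediction, held_out) {
  if (length(prediction) != length(held_out))
    stop("prediction and held-out data must have equal lengths")
  sst <- sum((held_out - mean(held_out))^2)
  if (sst == 0) stop("zero-variance held-out data")
  100 * (1 - sum((held_out - prediction)^2) / sst)
}

#' Fit a pRF model to one unit with split-half cross-validation
#'
#' Two-stage fitting: a coarse grid with closed-form gain solves provides
#' seeds for bounded quasi-Newton refinement on each data half. Each fold's
#' best solution is scored on the complementary half; the two cross-validated
#' R-squared values are averaged. Final parameters come from a refinement on
#' the mean of the two halves, seeded from both fold solutions.
#'
#' @param model model tag (\code{"P-LIN"}, \code{"U-LIN"}, \code{"DoG"},
#'   \code{"CSS"}).
#' @param dataset a \code{prf_dataset}.
#' @param unit unit (row) index.
#' @param control a \code{prf_fit_control}.
#' @param ctx optional precomputed fitting context (grid caches are shared
#'   across units when fitting a whole dataset); built internally if omitted.
#' @return An object of class \code{prf_fit}: \code{params},
#'   \code{r2_cv} (mean of folds), \code{r2_fold}, \code{r2_train},
#'   \code{converged}, \code{n_evals}.
#' @export
fit_prf <- function(model, dataset, unit = 1, control = prf_fit_control(),
                    ctx = NULL) {
  if (is.null(ctx)) ctx <- fit_context(dataset, control)
  a <- dataset$half_a[unit, ]
  b <- dataset$half_b[unit, ]
  folds <- list(a, b)
  other <- list(b, a)
  fold_fits <- vector("list", 2)
  r2_fold <- numeric(2)
  n_evals <- 0
  for (f in 1:2) {
    seeds <- grid_init_ctx(ctx, folds[[f]], model)
    refined <- lapply(seeds, function(s) refine_fit(ctx, model, folds[[f]], s))
    best <- refined[[which.min(vapply(refined, `[[`, numeric(1), "sse"))]]
    n_evals <- n_evals + sum(vapply(refined, `[[`, numeric(1), "n_evals"))
    fold_fits[[f]] <- best
    r2_fold[f] <- crossval_r2(predict_from_params(ctx, best$params),
                              other[[f]])
  }
  # final parameters: refine on the mean of the halves, seeded from the fold
  # whose solution generalized better
  m <- (a + b) / 2
  best_fold <- fold_fits[[which.max(r2_fold)]]
  final <- refine_fit(ctx, model, m, best_fold$params)
  n_evals <- n_evals + final$n_evals
  sst <- sum((m - mean(m))^2)
  structure(list(
    params = final$params,
    r2_cv = mean(r2_fold), r2_fold = r2_fold,
    r2_train = 100 * (1 - final$sse / sst),
    converged = final$converged &&
      all(vapply(fold_fits, `[[`, logical(1), "converged")),
    n_evals = n_evals
  ), class = "prf_fit")
}

#' Fit one model to every unit of a dataset
#'
#' @param model model tag.
#' @param dataset a \code{prf_dataset}.
#' @param control a \code{prf_fit_control}.
#' @param units unit indices (default all).
#' @return data frame, one row per unit: parameters (via
#'   \code{as.data.frame.prf_params}) plus \code{unit}, \code{r2_cv},
#'   \code{r2_train}, \code{converged}.
#' @export
fit_prf_table <- function(model, dataset, control = prf_fit_control(),
                          units = seq_len(dataset$n_units)) {
  ctx <- fit_context(dataset, control)
  rows <- lapply(units, function(u) {
    ft <- fit_prf(model, dataset, u, control, ctx = ctx)
    cbind(unit = u, as.data.frame(ft$params),
          r2_cv = ft$r2_cv, r2_train = ft$r2_train, converged = ft$converged)
  })
  do.call(rbind, rows)
}

#' Compare cross-validated performance of several pRF models
#'
#' Filters the per-unit R-squared table at a threshold (a unit is kept when
#' its best model exceeds it), then runs a Kruskal-Wallis test across models,
#' Tukey-HSD-style post-hoc comparisons of mean rank, and per-pair Wilcoxon
#' signed-rank tests.
#'
#' @param fit_tables data frame with columns \code{unit}, \code{model},
#'   \code{r2} (stack the per-model fit tables).
#' @param threshold_r2 inclusion threshold in percent (default 5, the BOLD
#'   convention; 25 or 50 are typical for electrophysiology).
#' @return list with \code{kruskal} (H statistic, df, p), \code{posthoc}
#'   (mean-rank comparisons), \code{wilcoxon} (pairwise signed-rank),
#'   \code{ranking} (models by mean rank, best first), \code{n_units}.
#' @export
compare_models <- function(fit_tables, threshold_r2 = 5) {
  stopifnot(all(c("unit", "model", "r2") %in% names(fit_tables)))
  if (length(unique(fit_tables$model)) < 2)
    stop("need at least two models to compare")
  wide <- stats::reshape(fit_tables[c("unit", "model", "r2")],
                         idvar = "unit", timevar = "model",
                         direction = "wide")
  keep <- apply(wide[-1], 1, max) > threshold_r2
  if (!any(keep)) stop("no units pass the R2 threshold")
  wide <- wide[keep, , drop = FALSE]
  models <- sub("^r2\\.", "", names(wide)[-1])
  r2 <- as.matrix(wide[-1])
  colnames(r2) <- models

  kw <- stats::kruskal.test(as.vector(r2),
                            factor(rep(models, each = nrow(r2))))
  posthoc <- mean_rank_posthoc(r2)
  pairs <- utils::combn(models, 2)
  wilcox <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                       p = NA_real_, median_diff = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    da <- r2[, pairs[1, i]]; db <- r2[, pairs[2, i]]
    wilcox$median_diff[i] <- stats::median(da - db)
    wilcox$p[i] <- if (all(da == db)) 1 else
      stats::wilcox.test(da, db, paired = TRUE, exact = FALSE)$p.value
  }
  mean_ranks <- colMeans(apply(r2, 1, rank) |> t())
  list(kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                      p = kw$p.value),
       posthoc = posthoc, wilcoxon = wilcox,
       ranking = names(sort(mean_ranks, decreasing = TRUE)),
       n_units = nrow(r2))
}

# Tukey-HSD-style multiple comparisons of mean rank after Kruskal-Wallis:
# observations pooled and ranked; pairwise q statistics on mean-rank
# differences referred to the studentized range distribution
mean_rank_posthoc <- function(r2) {
  models <- colnames(r2)
  n <- nrow(r2)
  N <- length(r2)
  pooled_ranks <- matrix(rank(as.vector(r2)), nrow = n,
                         dimnames = list(NULL, models))
  mr <- colMeans(pooled_ranks)
  se <- sqrt(N * (N + 1) / 12 * (2 / n))
  pairs <- utils::combn(models, 2)
  out <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                    mean_rank_diff = NA_real_, p = NA_real_)
  k <- length(models)
  for (i in seq_len(ncol(pairs))) {
    d <- mr[pairs[1, i]] - mr[pairs[2, i]]
    out$mean_rank_diff[i] <- d
    q <- abs(d) / se * sqrt(2)
    out$p[i] <- stats::ptukey(q, k, 1e7, lower.tail = FALSE)
  }
  out
}
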