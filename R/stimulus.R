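#' Bar-sweep stimulus protocols
#'
#' Construct the stimulus protocol used for pRF mapping: a bar that traverses
#' a circular aperture in a fixed number of equal steps, repeated in several
#' motion directions, separated by uniform-background blanks.
#'
#' Two presets are provided. The \code{"fmri"} preset uses a 16 dva aperture
#' with a 2 dva bar moving in 20 steps of 2.5 s (one TR) per sweep, eight
#' directions in the order 270, 315, 180, 225, 90, 135, 0, 45 degrees,
#' 37.5 s of background before and after the sweep series, and a 25 s blank
#' after every horizontal or vertical sweep. The \code{"ephys"} preset uses a
#' 28 dva aperture, 30 steps of 0.5 s, the same direction order, and 2.5 s
#' blanks.
#'
#' @param preset \code{"fmri"}, \code{"ephys"}, or \code{NULL} to supply all
#'   fields explicitly.
#' @param aperture_diameter circular aperture diameter, dva.
#' @param bar_width bar width, dva.
#' @param n_steps_per_sweep number of bar positions per sweep.
#' @param step_duration seconds each bar position stays on screen.
#' @param sweep_directions motion directions in degrees (0 = rightward,
#'   90 = upward), each in [0, 360).
#' @param pre_blank,post_blank seconds of uniform background before the first
#'   and after the last sweep.
#' @param inter_blank seconds of background inserted after selected sweeps.
#' @param blank_after which sweeps are followed by an \code{inter_blank}:
#'   \code{"cardinal"} (after 0/90/180/270 degree sweeps), \code{"all"}, or
#'   \code{"none"}.
#' @param pixels_per_dva rendering resolution of the effective stimulus.
#' @return An object of class \code{prf_protocol}.
#' @export
make_protocol <- function(preset = NULL,
                          aperture_diameter = NULL, bar_width = NULL,
                          n_steps_per_sweep = NULL, step_duration = NULL,
                          sweep_directions = NULL,
                          pre_blank = NULL, inter_blank = NULL,
                          post_blank = NULL,
                          blank_after = NULL,
                          pixels_per_dva = NULL) {
  defaults <- NULL
  if (!is.null(preset)) {
    defaults <- switch(preset,
      fmri = list(aperture_diameter = 16, bar_width = 2,
                  n_steps_per_sweep = 20, step_duration = 2.5,
                  sweep_directions = c(270, 315, 180, 225, 90, 135, 0, 45),
                  pre_blank = 37.5, inter_blank = 25, post_blank = 37.5,
                  blank_after = "cardinal", pixels_per_dva = 10),
      ephys = list(aperture_diameter = 28, bar_width = 2,
                   n_steps_per_sweep = 30, step_duration = 0.5,
                   sweep_directions = c(270, 315, 180, 225, 90, 135, 0, 45),
                   pre_blank = 2.5, inter_blank = 2.5, post_blank = 2.5,
                   blank_after = "cardinal", pixels_per_dva = 10),
      stop("unknown preset: ", preset)
    )
  }
  pick <- function(x, name) if (!is.null(x)) x else defaults[[name]]
  p <- list(
    aperture_diameter = pick(aperture_diameter, "aperture_diameter"),
    bar_width         = pick(bar_width, "bar_width"),
    n_steps_per_sweep = pick(n_steps_per_sweep, "n_steps_per_sweep"),
    step_duration     = pick(step_duration, "step_duration"),
    sweep_directions  = pick(sweep_directions, "sweep_directions"),
    pre_blank         = pick(pre_blank, "pre_blank"),
    inter_blank       = pick(inter_blank, "inter_blank"),
    post_blank        = pick(post_blank, "post_blank"),
    blank_after       = pick(blank_after, "blank_after"),
    pixels_per_dva    = pick(pixels_per_dva, "pixels_per_dva")
  )
  if (is.null(p$blank_after)) p$blank_after <- "all"
  missing <- names(p)[vapply(p, is.null, logical(1))]
  if (length(missing))
    stop("protocol fields missing (no preset): ", paste(missing, collapse = ", "))
  validate_protocol(p)
  class(p) <- "prf_protocol"
  p
}

validate_protocol <- function(p) {
  stopifnot(p$aperture_diameter > 0, p$bar_width > 0,
            p$n_steps_per_sweep >= 1, p$step_duration > 0,
            p$pixels_per_dva >= 1,
            p$pre_blank >= 0, p$inter_blank >= 0, p$post_blank >= 0,
            length(p$sweep_directions) >= 1)
  if (any(p$sweep_directions < 0 | p$sweep_directions >= 360))
    stop("sweep directions must lie in [0, 360)")
  if (!p$blank_after %in% c("cardinal", "all", "none"))
    stop("blank_after must be 'cardinal', 'all' or 'none'")
  invisible(p)
}

#' Duration of one bar sweep
#' @param protocol a \code{prf_protocol}.
#' @return seconds.
#' @export
sweep_duration <- function(protocol) {
  protocol$n_steps_per_sweep * protocol$step_duration
}

#' Total stimulus movie duration
#' @param protocol a \code{prf_protocol}.
#' @return seconds, including all blanks.
#' @export
protocol_duration <- function(protocol) {
  protocol$pre_blank +
    length(protocol$sweep_directions) * sweep_duration(protocol) +
    sum(inter_blank_flags(protocol)) * protocol$inter_blank +
    protocol$post_blank
}

# logical vector: does a blank follow sweep i?
inter_blank_flags <- function(p) {
  switch(p$blank_after,
         cardinal = p$sweep_directions %% 90 == 0,
         all = rep(TRUE, length(p$sweep_directions)),
         none = rep(FALSE, length(p$sweep_directions)))
}

#' Pixel grid of the effective stimulus
#'
#' Pixel centers sit at half-integer offsets so the grid is symmetric about
#' fixation at (0, 0); x increases rightward and y upward.
#'
#' @param protocol a \code{prf_protocol}.
#' @return list with vectors \code{x}, \code{y} (one value per pixel,
#'   column-major over an n x n frame) and \code{n} (pixels per side).
#' @export
stim_pixel_grid <- function(protocol) {
  n <- round(protocol$aperture_diameter * protocol$pixels_per_dva)
  ax <- (seq_len(n) - 0.5 - n / 2) / protocol$pixels_per_dva
  # frame[i, j]: row i = y (top row = +y), col j = x
  x <- rep(ax, each = n)
  y <- rep(rev(ax), times = n)
  list(x = x, y = y, n = n, axis = ax)
}

#' Render a protocol as a binary effective stimulus
#'
#' Each bar frame marks the pixels lying within \code{bar_width / 2} of the
#' bar's midline (the line perpendicular to the motion direction) and inside
#' the circular aperture. Bar centers traverse the aperture diameter in
#' \code{n_steps_per_sweep} equal steps with the first and last centers flush
#' with the aperture rim (the bar is clipped by the aperture mask there).
#' Blank epochs are all-zero frames.
#'
#' Frames are stored compactly: \code{frames} holds the unique bar frames
#' (one per sweep step, H x W x F), and \code{seq} indexes them over time
#' bins of \code{step_duration} (0 = blank frame).
#'
#' @param protocol a \code{prf_protocol}.
#' @return An object of class \code{effective_stimulus} with fields
#'   \code{frames}, \code{seq}, \code{onsets} (seconds, one per time bin),
#'   \code{frame_info} (data frame: sweep, direction, step per bar frame),
#'   \code{grid}, \code{protocol}.
#' @export
render_effective_stimulus <- function(protocol) {
  validate_protocol(protocol)
  g <- stim_pixel_grid(protocol)
  R <- protocol$aperture_diameter / 2
  aperture <- (g$x^2 + g$y^2) <= R^2

  dirs <- protocol$sweep_directions
  nstep <- protocol$n_steps_per_sweep
  centers <- if (nstep == 1) 0 else seq(-R, R, length.out = nstep)

  nframe <- length(dirs) * nstep
  frames <- array(0L, dim = c(g$n, g$n, nframe))
  info <- data.frame(sweep = integer(nframe), direction = numeric(nframe),
                     step = integer(nframe))
  k <- 0
  for (s in seq_along(dirs)) {
    th <- dirs[s] * pi / 180
    proj <- g$x * cos(th) + g$y * sin(th)
    for (j in seq_len(nstep)) {
      k <- k + 1
      on <- aperture & (abs(proj - centers[j]) <= protocol$bar_width / 2)
      frames[, , k] <- as.integer(on)
      info$sweep[k] <- s
      info$direction[k] <- dirs[s]
      info$step[k] <- j
    }
  }

  # time-bin sequence at step_duration resolution; blanks must be integer
  # multiples of step_duration for an exact binning
  dt <- protocol$step_duration
  nbin <- function(sec) {
    b <- sec / dt
    if (abs(b - round(b)) > 1e-9)
      stop("blank durations must be integer multiples of step_duration")
    as.integer(round(b))
  }
  seq_ids <- rep(0L, nbin(protocol$pre_blank))
  flags <- inter_blank_flags(protocol)
  k <- 0
  for (s in seq_along(dirs)) {
    seq_ids <- c(seq_ids, k + seq_len(nstep))
    k <- k + nstep
    if (flags[s]) seq_ids <- c(seq_ids, rep(0L, nbin(protocol$inter_blank)))
  }
  seq_ids <- c(seq_ids, rep(0L, nbin(protocol$post_blank)))

  structure(list(
    frames = frames, seq = seq_ids,
    onsets = (seq_along(seq_ids) - 1) * dt,
    frame_info = info, grid = g, protocol = protocol
  ), class = "effective_stimulus")
}

#' Materialize one time bin of the effective stimulus
#' @param stim an \code{effective_stimulus}.
#' @param t_bin time-bin index (1-based into \code{stim$seq}).
#' @return an H x W binary matrix (all zero for blank bins).
#' @export
stim_frame <- function(stim, t_bin) {
  id <- stim$seq[t_bin]
  if (id == 0) matrix(0L, nrow = stim$grid$n, ncol = stim$grid$n)
  else stim$frames[, , id]
}

# F x P matrix of bar frames, pixels column-major; used by the fitter
frame_matrix <- function(stim) {
  f <- stim$frames
  dim(f) <- c(stim$grid$n * stim$grid$n, dim(stim$frames)[3])
  t(f)
}

#' Serialize a protocol to JSON
#' @param protocol a \code{prf_protocol}.
#' @param path output file; if \code{NULL}, the JSON string is returned.
#' @export
write_protocol_json <- function(protocol, path = NULL) {
  js <- jsonlite::toJSON(unclass(protocol), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a protocol from JSON
#' @param path JSON file written by \code{write_protocol_json}.
#' @export
read_protocol_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  do.call(make_protocol, p)
}

#' Write bar frames as PGM masks for inspection
#'
#' Plain-text (P2) portable graymap files, one per bar frame.
#'
#' @param stim an \code{effective_stimulus}.
#' @param dir output directory (created if needed).
#' @export
write_stimulus_pgm <- function(stim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nf <- dim(stim$frames)[3]
  for (k in seq_len(nf)) {
    f <- stim$frames[, , k]
    path <- file.path(dir, sprintf("frame_%03d.pgm", k))
    con <- file(path, "w")
    writeLines(c("P2", paste(ncol(f), nrow(f)), "1"), con)
    write(t(f), con, ncolumns = ncol(f))
    close(con)
  }
  invisible(dir)
}
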