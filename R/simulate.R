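# Synthetic single-particle movies with ground truth: Gaussian point-spread
# spots on a noisy background, particles moving by stationary / Brownian /
# directed / switching models, optional blinking (frames where a particle
# leaves the focal plane and is not rendered), and additive Gaussian camera
# noise calibrated to a target SNR. Everything is deterministic under a seed.

#' Motion model for a simulated particle
#'
#' @param kind `"stationary"`, `"brownian"`, `"directed"`, or `"switching"`.
#' @param D Diffusion coefficient in um^2/s (Brownian).
#' @param velocity `(vx, vy)` in um/s (directed).
#' @param schedule For `"switching"`: list of segments, each a list with
#'   `from`, `to` (0-based inclusive frame range) and `model` (a non-switching
#'   `motion_model`). Segments must be disjoint, ordered, and cover the movie.
#'
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(kind = c("stationary", "brownian", "directed", "switching"),
                         D = 0, velocity = c(0, 0), schedule = NULL) {
  kind <- match.arg(kind)
  stopifnot(D >= 0, length(velocity) == 2L)
  if (kind == "switching") {
    if (is.null(schedule) || length(schedule) == 0L) {
      stop("switching model needs a non-empty `schedule`", call. = FALSE)
    }
    prev_end <- -1L
    for (seg in schedule) {
      stopifnot(!is.null(seg$from), !is.null(seg$to), inherits(seg$model, "motion_model"))
      if (seg$model$kind == "switching") stop("schedule segments cannot nest", call. = FALSE)
      if (seg$from <= prev_end) stop("schedule ranges must be disjoint and ordered", call. = FALSE)
      if (seg$to < seg$from) stop("schedule range has to <= from", call. = FALSE)
      prev_end <- seg$to
    }
  }
  structure(list(kind = kind, D = D, velocity = as.numeric(velocity),
                 schedule = schedule), class = "motion_model")
}

#' Simulate one particle trajectory
#'
#' Positions are in pixels (0-based, x = column, y = row). Brownian steps are
#' drawn per axis with variance `2 D dt` (um^2), converted to pixels; directed
#' motion advances deterministically by `velocity * dt`; a switching model
#' concatenates its segments. Setting `seed` makes the draw reproducible.
#'
#' @param model A [motion_model()].
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame interval in seconds.
#' @param pixel_size Pixel size in micrometers.
#' @param start `(x, y)` start position in pixels.
#' @param seed Optional integer seed.
#'
#' @return Data frame with columns `frame` (0-based), `x`, `y` (pixels),
#'   `motion_kind`.
#' @export
simulate_trajectory <- function(model, n_frames, dt, pixel_size, start = c(0, 0),
                                seed = NULL) {
  stopifnot(n_frames >= 1, dt > 0, pixel_size > 0, length(start) == 2L)
  if (!is.null(seed)) set.seed(seed)
  steps_for <- function(m, k) {
    # k per-frame (dx, dy) displacements in pixels
    switch(m$kind,
      stationary = matrix(0, k, 2L),
      brownian = matrix(stats::rnorm(2L * k, sd = sqrt(2 * m$D * dt) / pixel_size), k, 2L),
      directed = matrix(rep(m$velocity * dt / pixel_size, each = k), k, 2L),
      stop("unexpected kind", call. = FALSE))
  }
  kinds <- rep(model$kind, n_frames)
  if (model$kind != "switching") {
    steps <- steps_for(model, n_frames - 1L)
  } else {
    kinds <- character(n_frames)
    steps <- matrix(0, max(n_frames - 1L, 0L), 2L)
    for (seg in model$schedule) {
      fr <- seg$from:min(seg$to, n_frames - 1L)
      fr <- fr[fr <= n_frames - 1L & fr >= 0L]
      if (length(fr) == 0L) next
      kinds[fr + 1L] <- seg$model$kind
      # step into frame f is governed by the segment active at frame f
      sf <- fr[fr >= 1L]
      if (length(sf) > 0L) steps[sf, ] <- steps_for(seg$model, length(sf))
    }
    if (any(kinds == "")) stop("schedule does not cover frames 0..n_frames-1", call. = FALSE)
  }
  if (n_frames == 1L) {
    return(data.frame(frame = 0L, x = start[1], y = start[2],
                      motion_kind = kinds[1L]))
  }
  x <- start[1] + c(0, cumsum(steps[, 1L]))
  y <- start[2] + c(0, cumsum(steps[, 2L]))
  data.frame(frame = 0:(n_frames - 1L), x = x, y = y, motion_kind = kinds)
}

#' Add a Gaussian spot to an image
#'
#' Adds `A * exp(-(x - x_c)^2 / (2 w_x^2) - (y - y_c)^2 / (2 w_y^2))` sampled
#' at pixel centers (integer coordinates, 0-based). Evaluation is restricted
#' to a +-6 sigma bounding box, where the truncated mass differs from the full
#' Gaussian integral `2*pi*A*w_x*w_y` by a negligible amount.
#'
#' @param image Numeric matrix to add the spot to.
#' @param A Peak amplitude.
#' @param x_c,y_c Spot center (0-based sub-pixel; x = column, y = row).
#' @param w_x,w_y Gaussian standard deviations in pixels (> 0).
#'
#' @return The image with the spot added.
#' @export
render_spot <- function(image, A, x_c, y_c, w_x, w_y) {
  stopifnot(all(is.finite(c(A, x_c, y_c, w_x, w_y))), w_x > 0, w_y > 0)
  nr <- nrow(image); nc <- ncol(image)
  r0 <- max(0L, floor(y_c - 6 * w_y)); r1 <- min(nr - 1L, ceiling(y_c + 6 * w_y))
  c0 <- max(0L, floor(x_c - 6 * w_x)); c1 <- min(nc - 1L, ceiling(x_c + 6 * w_x))
  if (r0 > r1 || c0 > c1) return(image)
  ry <- exp(-((r0:r1) - y_c)^2 / (2 * w_y^2))
  cx <- exp(-((c0:c1) - x_c)^2 / (2 * w_x^2))
  image[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <-
    image[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] + A * outer(ry, cx)
  image
}

#' Noise level that yields a target SNR
#'
#' Inverts the SNR definition `(mu_sig - mu_background) / sigma_background`:
#' for a spot of amplitude `A` centered in a `window_size` window, the expected
#' window-mean excess over background is the pixel-center average of the
#' Gaussian over the window; dividing it by `target_snr` gives the background
#' noise standard deviation at which the measured SNR equals the target in
#' expectation.
#'
#' @param A Spot peak amplitude.
#' @param w_x,w_y Gaussian widths in pixels.
#' @param window_size Odd integer signal-window side.
#' @param target_snr Desired SNR (> 0).
#'
#' @return Noise standard deviation `sigma`.
#' @export
calibrate_noise_for_snr <- function(A, w_x, w_y, window_size, target_snr) {
  stopifnot(target_snr > 0, window_size %% 2 == 1)
  half <- (window_size - 1L) %/% 2L
  off <- (-half):half
  excess <- A * mean(outer(exp(-off^2 / (2 * w_y^2)), exp(-off^2 / (2 * w_x^2))))
  excess / target_snr
}

#' Specification of a synthetic movie
#'
#' @param n_frames,height,width Movie dimensions (frames, rows, cols).
#' @param dt Frame interval in seconds (default 0.1, i.e. 10 fps).
#' @param pixel_size Pixel size in micrometers (default 0.107).
#' @param particles List of particles; each a list with `x0`, `y0` (start
#'   position, pixels), `model` (a [motion_model()]), `A` (amplitude), `w_x`,
#'   `w_y` (widths, default 1.5 px), and `blink` (integer vector of 0-based
#'   frames in which the spot is invisible, default none).
#' @param background_level Constant background offset (default 100).
#' @param noise_sigma Standard deviation of the additive Gaussian camera noise.
#' @param seed Integer seed; mandatory so every movie is reproducible.
#'
#' @return An object of class `synthetic_movie_spec`.
#' @export
synthetic_movie_spec <- function(n_frames, height, width, dt = 0.1,
                                 pixel_size = 0.107, particles = list(),
                                 background_level = 100, noise_sigma = 0,
                                 seed) {
  stopifnot(n_frames >= 1, height >= 1, width >= 1, dt > 0, pixel_size > 0,
            noise_sigma >= 0)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` is mandatory for reproducible movies", call. = FALSE)
  }
  particles <- lapply(seq_along(particles), function(i) {
    p <- particles[[i]]
    stopifnot(!is.null(p$x0), !is.null(p$y0), inherits(p$model, "motion_model"),
              !is.null(p$A))
    if (p$x0 < 0 || p$x0 > width - 1 || p$y0 < 0 || p$y0 > height - 1) {
      stop(sprintf("particle %d starts outside the image", i), call. = FALSE)
    }
    list(x0 = p$x0, y0 = p$y0, model = p$model, A = p$A,
         w_x = if (is.null(p$w_x)) 1.5 else p$w_x,
         w_y = if (is.null(p$w_y)) 1.5 else p$w_y,
         blink = if (is.null(p$blink)) integer(0) else as.integer(p$blink))
  })
  structure(list(n_frames = as.integer(n_frames), height = as.integer(height),
                 width = as.integer(width), dt = dt, pixel_size = pixel_size,
                 particles = particles, background_level = background_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_movie_spec")
}

#' Render a synthetic movie with ground truth
#'
#' Each frame is `background_level` plus the rendered non-blinked spots plus
#' i.i.d. Gaussian noise of standard deviation `noise_sigma`. Trajectories are
#' drawn first (particle by particle) and noise afterwards, all from a single
#' RNG stream seeded with `spec$seed`, so the whole movie is a deterministic
#' function of its spec.
#'
#' @param spec A [synthetic_movie_spec()].
#'
#' @return List with `stack` (array `n_frames` x `height` x `width`), `truth`
#'   (data frame: `particle_id`, `frame`, `x_true`, `y_true`, `visible`,
#'   `motion_kind`), and `spec`.
#' @export
simulate_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_movie_spec"))
  set.seed(spec$seed)
  trajs <- lapply(spec$particles, function(p) {
    simulate_trajectory(p$model, spec$n_frames, spec$dt, spec$pixel_size,
                        start = c(p$x0, p$y0))
  })
  truth <- do.call(rbind, c(list(
    data.frame(particle_id = integer(0), frame = integer(0), x_true = numeric(0),
               y_true = numeric(0), visible = logical(0), motion_kind = character(0))),
    lapply(seq_along(trajs), function(i) {
      tr <- trajs[[i]]
      data.frame(particle_id = i, frame = tr$frame, x_true = tr$x, y_true = tr$y,
                 visible = !(tr$frame %in% spec$particles[[i]]$blink),
                 motion_kind = tr$motion_kind)
    })))
  stack <- array(spec$background_level,
                 dim = c(spec$n_frames, spec$height, spec$width))
  for (t in seq_len(spec$n_frames)) {
    frame <- matrix(spec$background_level, spec$height, spec$width)
    for (i in seq_along(trajs)) {
      p <- spec$particles[[i]]
      if ((t - 1L) %in% p$blink) next
      tr <- trajs[[i]]
      frame <- render_spot(frame, p$A, tr$x[t], tr$y[t], p$w_x, p$w_y)
    }
    if (spec$noise_sigma > 0) {
      frame <- frame + matrix(stats::rnorm(length(frame), sd = spec$noise_sigma),
                              nrow(frame), ncol(frame))
    }
    stack[t, , ] <- frame
  }
  list(stack = stack, truth = truth, spec = spec)
}
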