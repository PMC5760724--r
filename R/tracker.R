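# The frame-by-frame hybrid tracking engine. A track is advanced one frame at
# a time: build the scan region around the last localized position, look for
# bright window-mean maxima, and either localize automatically (exactly one
# candidate) or ask the intervention policy (none, or two and more). Gap
# frames are stored as NaN; a stop decision terminates the track.

new_track <- function(track_id) {
  structure(list(
    track_id = as.integer(track_id),
    points = data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                        intensity = numeric(0), status = character(0),
                        snr = numeric(0))
  ), class = "track")
}

track_point <- function(frame, x, y, intensity, status, snr = NaN) {
  data.frame(frame = as.integer(frame), x = x, y = y, intensity = intensity,
             status = status, snr = snr)
}

gap_point <- function(frame) {
  track_point(frame, NaN, NaN, NaN, "gap", NaN)
}

append_point <- function(track, point) {
  track$points <- rbind(track$points, point)
  track
}

track_is_stopped <- function(track) {
  n <- nrow(track$points)
  n > 0L && track$points$status[n] == "stopped"
}

# last point with a localized position (status not gap/stopped)
last_localized_point <- function(track) {
  pts <- track$points
  ok <- is.finite(pts$x) & pts$status != "stopped"
  if (!any(ok)) stop("track has no localized point", call. = FALSE)
  pts[max(which(ok)), ]
}

#' @export
print.track <- function(x, ...) {
  st <- table(x$points$status)
  cat(sprintf("track %d: %d frames (%s)\n", x$track_id, nrow(x$points),
              paste(sprintf("%s %d", names(st), st), collapse = ", ")))
  invisible(x)
}

#' Predict a particle position by linear extrapolation
#'
#' Extrapolates the particle's previous velocity: the displacement between the
#' last two localized (non-gap) points divided by their frame difference,
#' applied from the last localized point to `current_frame`. Used to carry a
#' particle with constant-velocity directed motion through a two-particle
#' overlap.
#'
#' @param track A `track` with at least 2 localized points before
#'   `current_frame`.
#' @param current_frame Frame index to predict for.
#'
#' @return Numeric `(x, y)` predicted position in pixels.
#' @export
predict_linear_motion <- function(track, current_frame) {
  pts <- track$points
  ok <- which(is.finite(pts$x) & pts$status != "stopped" &
                pts$frame < current_frame)
  if (length(ok) < 2L) {
    stop("linear-motion prediction needs >= 2 localized points; fall back to manual or gap",
         call. = FALSE)
  }
  i2 <- ok[length(ok)]; i1 <- ok[length(ok) - 1L]
  df <- pts$frame[i2] - pts$frame[i1]
  v <- c(pts$x[i2] - pts$x[i1], pts$y[i2] - pts$y[i1]) / df
  c(pts$x[i2], pts$y[i2]) + v * (current_frame - pts$frame[i2])
}

# Localize a spot near `position` (sub-pixel x, y): window centered on the
# rounded position (clamped into the image), background from the scan-region
# surround, then Gaussian fit with centroid fallback, or plain centroid.
# If there is no signal above background the requested position itself is
# returned with zero intensity.
localize_at <- function(frame_image, region, position, config) {
  ctr <- clamp_window_center(round_half_up(position[2]), round_half_up(position[1]),
                             config$window_size, dim(frame_image))
  bg <- estimate_background(frame_image, region, ctr, config$window_size)
  res <- NULL
  if (config$localization_method == "gaussian") {
    fit <- tryCatch(
      fit_gaussian_2d(frame_image, ctr, config$window_size, bg),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      res <- list(x = fit$x_c, y = fit$y_c, intensity = fit$integrated_intensity)
    }
  }
  if (is.null(res)) {
    cen <- tryCatch(
      localize_centroid(frame_image, ctr, config$window_size, bg),
      error = function(e) NULL)
    res <- if (is.null(cen)) {
      list(x = position[1], y = position[2], intensity = 0)
    } else {
      list(x = cen$x_c, y = cen$y_c, intensity = cen$intensity)
    }
  }
  res$snr <- tryCatch(
    snr_in_region(frame_image, region, ctr, config$window_size)$snr,
    error = function(e) NaN)
  res
}

#' Advance one track by one frame
#'
#' Builds the scan region around the track's last localized position, detects
#' local maxima, and appends the resulting point: exactly one candidate is
#' localized automatically (`status = "detected"`); zero candidates raise a
#' `no_maximum` intervention (stop / manual / gap); two or more raise an
#' `overlap` intervention (manual / linear_motion / pick_candidate). The
#' decision comes from `policy`.
#'
#' @param track A non-stopped `track`.
#' @param frame_image The next unprocessed frame (numeric matrix).
#' @param config A [tracking_config()].
#' @param policy A `track_policy`.
#'
#' @return The appended `TrackPoint` as a one-row data frame, with attribute
#'   `"intervention"` (NULL, or a list describing the request and decision).
#' @export
step_frame <- function(track, frame_image, config, policy) {
  if (track_is_stopped(track)) stop("track is stopped", call. = FALSE)
  frame <- nrow(track$points)
  last <- last_localized_point(track)
  region <- define_scan_region(c(last$x, last$y), config, dim(frame_image))
  cands <- detect_local_maxima(frame_image, region, config)
  intervention <- NULL

  if (length(cands) == 1L) {
    loc <- localize_at(frame_image, region, c(cands[[1L]]$col, cands[[1L]]$row), config)
    pt <- track_point(frame, loc$x, loc$y, loc$intensity, "detected", loc$snr)
  } else {
    kind <- if (length(cands) == 0L) "no_maximum" else "overlap"
    request <- intervention_request(kind, track$track_id, frame, region, cands)
    decision <- check_decision(request, policy$decide(request, track, config))
    intervention <- list(kind = kind, action = decision$action,
                         track_id = track$track_id, frame = frame,
                         n_candidates = length(cands))
    pt <- switch(decision$action,
      stop = track_point(frame, last$x, last$y, NaN, "stopped"),
      gap = gap_point(frame),
      manual = {
        loc <- localize_at(frame_image, region, decision$manual_position, config)
        track_point(frame, loc$x, loc$y, loc$intensity, "manual", loc$snr)
      },
      pick_candidate = {
        idx <- decision$candidate_index
        if (idx < 1L || idx > length(cands)) {
          stop(sprintf("candidate_index %d out of range (1..%d)", idx, length(cands)),
               call. = FALSE)
        }
        loc <- localize_at(frame_image, region, c(cands[[idx]]$col, cands[[idx]]$row),
                           config)
        track_point(frame, loc$x, loc$y, loc$intensity, "detected", loc$snr)
      },
      linear_motion = {
        pred <- predict_linear_motion(track, frame)
        loc <- localize_at(frame_image, region, pred, config)
        # the prediction seeds sub-pixel refinement; a refinement that moves
        # more than 1 px has latched onto the overlapping particle, so keep
        # the prediction itself in that case
        if (sqrt((loc$x - pred[1])^2 + (loc$y - pred[2])^2) > 1) {
          loc$x <- pred[1]; loc$y <- pred[2]
        }
        track_point(frame, loc$x, loc$y, loc$intensity, "predicted", loc$snr)
      })
  }
  attr(pt, "intervention") <- intervention
  pt
}

#' Track annotated particles through a movie
#'
#' Each initial position seeds one track; the frame-0 point is localized
#' around the annotation (`status = "manual"`, mirroring the user's click) and
#' [step_frame()] is applied per particle and per subsequent frame, particles
#' in annotation order. Stopped tracks are skipped. Tracks are advanced
#' independently; if two tracks localize within `min_separation` of each other
#' in some frame, a warning is issued (no inter-track exclusion is applied).
#'
#' @param stack Image stack: array `frames` x `rows` x `cols` (an
#'   `image_stack` from [read_stack()] or [simulate_movie()]`$stack`).
#' @param initial_positions List (or n x 2 matrix) of `(x, y)` annotations in
#'   frame 0, 0-based pixels.
#' @param config A [tracking_config()].
#' @param policy A `track_policy` (default [policy_automatic()]).
#'
#' @return List of `track` objects, with attribute `"interventions"`: a data
#'   frame logging every request and the applied decision (`track_id`,
#'   `frame`, `kind`, `action`, `n_candidates`).
#' @export
track_movie <- function(stack, initial_positions, config,
                        policy = policy_automatic()) {
  if (is.matrix(initial_positions)) {
    initial_positions <- lapply(seq_len(nrow(initial_positions)),
                                function(i) initial_positions[i, ])
  }
  if (length(initial_positions) == 0L) stop("no initial positions given", call. = FALSE)
  dims <- dim(stack)
  stopifnot(length(dims) == 3L, dims[1] >= 1L)
  shape <- dims[2:3]
  for (i in seq_along(initial_positions)) {
    p <- initial_positions[[i]]
    if (length(p) != 2L || !all(is.finite(p)) ||
        p[1] < 0 || p[1] > shape[2] - 1 || p[2] < 0 || p[2] > shape[1] - 1) {
      stop(sprintf("annotation %d is outside frame 0", i), call. = FALSE)
    }
  }

  interventions <- list()
  tracks <- vector("list", length(initial_positions))
  frame0 <- matrix(stack[1L, , ], shape[1], shape[2])
  for (i in seq_along(initial_positions)) {
    tr <- new_track(i)
    p <- initial_positions[[i]]
    region <- define_scan_region(p, config, shape)
    loc <- localize_at(frame0, region, p, config)
    tracks[[i]] <- append_point(tr, track_point(0L, loc$x, loc$y, loc$intensity,
                                                "manual", loc$snr))
  }

  n_frames <- dims[1]
  if (n_frames > 1L) {
    for (t in 2:n_frames) {
      frame <- matrix(stack[t, , ], shape[1], shape[2])
      for (i in seq_along(tracks)) {
        if (track_is_stopped(tracks[[i]])) next
        pt <- step_frame(tracks[[i]], frame, config, policy)
        iv <- attr(pt, "intervention")
        if (!is.null(iv)) interventions[[length(interventions) + 1L]] <- iv
        attr(pt, "intervention") <- NULL
        tracks[[i]] <- append_point(tracks[[i]], pt)
      }
      warn_coincident_tracks(tracks, t - 1L, config)
    }
  }

  log_df <- if (length(interventions) == 0L) {
    data.frame(track_id = integer(0), frame = integer(0), kind = character(0),
               action = character(0), n_candidates = integer(0))
  } else {
    do.call(rbind, lapply(interventions, function(iv) {
      data.frame(track_id = iv$track_id, frame = iv$frame, kind = iv$kind,
                 action = iv$action, n_candidates = iv$n_candidates)
    }))
  }
  attr(tracks, "interventions") <- log_df
  tracks
}

# warn when two live tracks localized essentially the same spot in a frame
warn_coincident_tracks <- function(tracks, frame, config) {
  pos <- lapply(tracks, function(tr) {
    pts <- tr$points
    row <- pts[pts$frame == frame & is.finite(pts$x) & pts$status != "stopped", ]
    if (nrow(row) == 1L) c(row$x, row$y) else NULL
  })
  ids <- which(!vapply(pos, is.null, logical(1)))
  if (length(ids) < 2L) return(invisible())
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      d <- sqrt(sum((pos[[ids[a]]] - pos[[ids[b]]])^2))
      if (d < config$min_separation) {
        warning(sprintf("tracks %d and %d localized within %.1f px of each other at frame %d",
                        tracks[[ids[b]]]$track_id, tracks[[ids[a]]]$track_id, d, frame),
                call. = FALSE)
      }
    }
  }
  invisible()
}
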