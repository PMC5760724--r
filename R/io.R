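# File I/O: multi-page grayscale TIFF stacks in and out, CSV track and MSD
# tables (gap frames serialized as the literal token NaN), YAML configuration,
# scripted decision tables, and the x-t kymograph projection.

#' Read a multi-page TIFF stack
#'
#' Loads a grayscale 8/16-bit integer or 32-bit float multi-page TIFF as a
#' `frames x rows x cols` array. Integer samples are returned on their native
#' scale (0..255 / 0..65535); float samples are returned as stored. A
#' single-page file yields a one-frame stack; RGB data is rejected.
#'
#' @param path Path to a TIFF file.
#' @param frame_interval Optional frame interval in seconds, attached as an
#'   attribute.
#'
#' @return An `image_stack`: numeric array `frames x rows x cols`.
#' @export
read_stack <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      stop(sprintf("page %d has %d channels; only grayscale stacks are supported",
                   i, dim(pg)[3]), call. = FALSE)
    }
    info <- attributes(pg)
    fmt <- if (is.null(info$sample.format)) "uint" else info$sample.format
    bits <- if (is.null(info$bits.per.sample)) 8L else info$bits.per.sample
    if (fmt == "uint") {
      # readTIFF normalizes integers to [0, 1]; restore the native scale
      pages[[i]] <- round(unclass(pg) * (2^bits - 1))
    } else {
      pages[[i]] <- unclass(pg)
    }
  }
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop("all pages must have the same dimensions", call. = FALSE)
  }
  stack <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) stack[i, , ] <- pages[[i]]
  if (!is.null(frame_interval)) attr(stack, "frame_interval") <- frame_interval
  class(stack) <- c("image_stack", class(stack))
  stack
}

#' Write an image stack as a multi-page TIFF
#'
#' Writes 8- or 16-bit grayscale pages (the native formats of scientific
#' cameras). Values are rounded to integers; values outside `0..2^bits - 1`
#' are clamped with a warning.
#'
#' @param stack Array `frames x rows x cols`.
#' @param path Output path.
#' @param bits 8 or 16 bits per sample (default 16).
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(length(dim(stack)) == 3L, bits %in% c(8L, 16L))
  top <- 2^bits - 1
  vals <- round(unclass(stack))
  if (any(vals < 0 | vals > top)) {
    warning(sprintf("intensities clamped to 0..%d for %d-bit output", top, bits),
            call. = FALSE)
    vals <- pmin(pmax(vals, 0), top)
  }
  pages <- lapply(seq_len(dim(vals)[1]), function(t) {
    matrix(vals[t, , ], dim(vals)[2], dim(vals)[3]) / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "LZW", reduce = FALSE)
  invisible(path)
}

#' Flatten tracks to a table / rebuild tracks from a table
#'
#' The track table has one row per frame and track: `track_id`, `frame`, `x`,
#' `y`, `intensity`, `status`, `snr`. Gap frames carry `NaN` coordinates.
#'
#' @param tracks List of `track` objects.
#' @return A data frame.
#' @export
tracks_to_table <- function(tracks) {
  if (length(tracks) == 0L) {
    return(data.frame(track_id = integer(0), frame = integer(0), x = numeric(0),
                      y = numeric(0), intensity = numeric(0),
                      status = character(0), snr = numeric(0)))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    cbind(data.frame(track_id = tr$track_id), tr$points)
  }))
}

#' @describeIn tracks_to_table Rebuild the list of `track` objects from a
#'   track table, validating uniqueness of `(track_id, frame)` and per-track
#'   frame contiguity.
#' @param table Data frame as produced by [tracks_to_table()].
#' @export
table_to_tracks <- function(table) {
  required <- c("track_id", "frame", "x", "y", "intensity", "status")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop(sprintf("track table is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(table$snr)) table$snr <- NaN
  dup <- duplicated(table[, c("track_id", "frame")])
  if (any(dup)) {
    stop(sprintf("duplicate (track_id, frame) pair at line %d",
                 which(dup)[1L] + 1L), call. = FALSE)  # +1 for the header line
  }
  lapply(sort(unique(table$track_id)), function(id) {
    rows <- table[table$track_id == id, , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    if (!identical(as.integer(rows$frame), seq(0L, nrow(rows) - 1L))) {
      stop(sprintf("track %d frames are not contiguous from 0", id), call. = FALSE)
    }
    tr <- new_track(id)
    tr$points <- data.frame(frame = as.integer(rows$frame), x = rows$x, y = rows$y,
                            intensity = rows$intensity,
                            status = as.character(rows$status), snr = rows$snr)
    tr
  })
}

#' Write / read a track table as CSV
#'
#' Comma-separated text with a header, one row per track point; gap frames
#' serialize `x`, `y`, `intensity` as the literal token `NaN`. Reading inverts
#' writing exactly and enforces the table invariants (unique `(track_id,
#' frame)`, contiguous frames per track), reporting the offending line.
#'
#' @param tracks List of `track` objects.
#' @param path Output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks_to_table(tracks), path, row.names = FALSE, quote = FALSE,
                   na = "NaN")
  invisible(path)
}

#' @describeIn write_tracks Read a track table back into `track` objects.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  table_to_tracks(tab)
}

#' Kymograph (x-t projection) of a stack
#'
#' Projects each frame along the row (y) axis with a maximum-intensity
#' projection — the projection that keeps dim single-particle paths visible —
#' producing a `frames x cols` image in which a particle moving along x traces
#' a slanted line.
#'
#' @param stack Array `frames x rows x cols`.
#'
#' @return Numeric matrix `frames x cols`.
#' @export
make_kymograph <- function(stack) {
  dims <- dim(stack)
  stopifnot(length(dims) == 3L, dims[1] >= 1L)
  out <- matrix(0, dims[1], dims[3])
  for (t in seq_len(dims[1])) {
    out[t, ] <- apply(matrix(stack[t, , ], dims[2], dims[3]), 2L, max)
  }
  out
}

#' Write / read a tracking configuration as YAML
#'
#' Flat key/value file mirroring the [tracking_config()] fields.
#'
#' @param config A `tracking_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @describeIn write_config Read a configuration file; keys absent from the
#'   file keep their defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(tracking_config)))
  do.call(tracking_config, vals[keep])
}

#' Read a scripted decision table
#'
#' CSV with columns `frame`, `track_id`, `action` and optional `x`, `y`,
#' `candidate_index` (x/y blank unless `action = "manual"`), feeding
#' [policy_scripted()].
#'
#' @param path CSV path.
#' @return Data frame of decisions.
#' @export
read_decisions <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "track_id", "action")
  if (!all(required %in% names(d))) {
    stop("decision file needs columns frame, track_id, action", call. = FALSE)
  }
  d
}

#' MSD / diffusion summary tables for a set of tracks
#'
#' Convenience wrapper running [compute_ta_msd()] and
#' [fit_diffusion_coefficient()] per track.
#'
#' @param tracks List of `track` objects.
#' @param dt Frame interval (s).
#' @param pixel_size Pixel size (um).
#' @param fit_lags Lags for the diffusion fit (default `1:4`).
#'
#' @return List with `msd` (long data frame: `track_id`, `lag`, `tau_s`,
#'   `msd_um2`, `n_pairs`, `rel_error`) and `summary` (per-track `D_um2_s`,
#'   `intercept_um2`, `alpha`, `r_squared`).
#' @export
analyze_tracks <- function(tracks, dt, pixel_size, fit_lags = 1:4) {
  msd_rows <- list(); sum_rows <- list()
  for (tr in tracks) {
    curve <- tryCatch(compute_ta_msd(tr, dt, pixel_size), error = function(e) NULL)
    if (is.null(curve)) next
    msd_rows[[length(msd_rows) + 1L]] <-
      cbind(data.frame(track_id = tr$track_id), as.data.frame(curve))
    est <- tryCatch(fit_diffusion_coefficient(curve, fit_lags),
                    error = function(e) NULL)
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      track_id = tr$track_id,
      D_um2_s = if (is.null(est)) NA_real_ else est$D,
      intercept_um2 = if (is.null(est)) NA_real_ else est$intercept,
      alpha = if (is.null(est)) NA_real_ else est$alpha,
      r_squared = if (is.null(est)) NA_real_ else est$r_squared)
  }
  list(msd = do.call(rbind, msd_rows), summary = do.call(rbind, sum_rows))
}
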