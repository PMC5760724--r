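# Coordinate conventions used throughout the package:
#   * 0-based pixel indices; x = column index, y = row index.
#   * Pixel centers sit at integer coordinates; sub-pixel positions are reals.
#   * Rectangular regions are inclusive of both bounds.
# Internally R matrices are 1-based [row, col]; every public value is 0-based.

round_half_up <- function(x) floor(x + 0.5)

#' Define the scan region for the next frame
#'
#' Builds the `scan_rows` x `scan_cols` rectangle centered on the particle's
#' previous position (rounded to the nearest pixel), clipped to the image.
#' Clipping shrinks the region at the image border; it never shifts the
#' opposite edge.
#'
#' @param prev_position Numeric `(x, y)` pair, the particle's last known
#'   sub-pixel position (0-based; x = column, y = row).
#' @param config A [tracking_config()].
#' @param image_shape Integer `(rows, cols)` of the frame.
#'
#' @return A `scan_region` object: list with `row_min`, `row_max`, `col_min`,
#'   `col_max` (0-based inclusive) and `center = c(row, col)`.
#' @export
#' @examples
#' cfg <- tracking_config(scan_rows = 21, scan_cols = 21, window_size = 7)
#' define_scan_region(c(50, 50), cfg, c(512, 512))
define_scan_region <- function(prev_position, config, image_shape) {
  stopifnot(length(prev_position) == 2L, all(is.finite(prev_position)),
            length(image_shape) == 2L)
  rows <- as.integer(image_shape[1]); cols <- as.integer(image_shape[2])
  cr <- round_half_up(prev_position[2])  # y -> row
  cc <- round_half_up(prev_position[1])  # x -> col
  if (cr < 0 || cr > rows - 1 || cc < 0 || cc > cols - 1) {
    stop(sprintf(
      "particle lost: previous position (x=%.2f, y=%.2f) is outside the %dx%d image",
      prev_position[1], prev_position[2], rows, cols), call. = FALSE)
  }
  hr <- (config$scan_rows - 1L) %/% 2L
  hc <- (config$scan_cols - 1L) %/% 2L
  structure(list(
    row_min = max(0L, cr - hr), row_max = min(rows - 1L, cr + hr),
    col_min = max(0L, cc - hc), col_max = min(cols - 1L, cc + hc),
    center = c(row = cr, col = cc)
  ), class = "scan_region")
}

#' @export
print.scan_region <- function(x, ...) {
  cat(sprintf("scan region rows %d..%d, cols %d..%d (center row %d, col %d)\n",
              x$row_min, x$row_max, x$col_min, x$col_max,
              x$center["row"], x$center["col"]))
  invisible(x)
}

# Mean-intensity map of all window_size x window_size windows that fit inside
# the region, via a summed-area table. Returns the map plus the 0-based
# absolute (row, col) of each map cell's window center.
window_mean_map <- function(frame_image, region, window_size) {
  sub <- frame_image[(region$row_min + 1L):(region$row_max + 1L),
                     (region$col_min + 1L):(region$col_max + 1L), drop = FALSE]
  nr <- nrow(sub); nc <- ncol(sub)
  w <- window_size
  if (nr < w || nc < w) return(NULL)
  # summed-area table with a zero border row/col
  cs <- matrix(apply(sub, 2L, cumsum), nr, nc)
  cs <- t(matrix(apply(cs, 1L, cumsum), nc, nr))
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- cs
  i <- seq_len(nr - w + 1L); j <- seq_len(nc - w + 1L)
  sums <- sat[i + w, j + w, drop = FALSE] - sat[i, j + w, drop = FALSE] -
    sat[i + w, j, drop = FALSE] + sat[i, j, drop = FALSE]
  half <- (w - 1L) %/% 2L
  list(mean = sums / (w * w),
       center_rows = region$row_min + half + (i - 1L),
       center_cols = region$col_min + half + (j - 1L))
}

#' Detect local maxima inside a scan region
#'
#' Slides a `window_size` x `window_size` window over every position where it
#' fits inside the region and computes the mean intensity of each window.
#' Window centers that are local maxima of this mean map and whose mean exceeds
#' the local background by more than `brightness_k` background standard
#' deviations are returned as candidates, brightest first. The background is
#' estimated from the region pixels outside the brightest window, as median
#' (level) and scaled MAD (spread) so that a second particle in the surround
#' does not inflate the threshold. Candidates closer than `min_separation`
#' pixels
#' (Euclidean) to a brighter candidate are suppressed.
#'
#' An empty list is a valid result and means "nothing bright enough".
#'
#' @param frame_image Numeric matrix (rows x cols), one movie frame.
#' @param region A `scan_region` from [define_scan_region()].
#' @param config A [tracking_config()].
#'
#' @return List of candidates; each is a list with `row`, `col` (0-based
#'   absolute window-center pixel) and `window_mean`.
#' @export
detect_local_maxima <- function(frame_image, region, config) {
  wm <- window_mean_map(frame_image, region, config$window_size)
  if (is.null(wm)) return(list())
  m <- wm$mean
  nr <- nrow(m); nc <- ncol(m)

  # local maximum: >= all existing 8-neighbours in the window-mean map
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & (m >= pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())

  # background: region pixels outside the footprint of the brightest window
  best <- which(m == max(m), arr.ind = TRUE)[1L, , drop = TRUE]
  half <- (config$window_size - 1L) %/% 2L
  best_row <- wm$center_rows[best[1L]]; best_col <- wm$center_cols[best[2L]]
  rr <- (region$row_min):(region$row_max); cc <- (region$col_min):(region$col_max)
  grid_r <- matrix(rr, length(rr), length(cc))
  grid_c <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  outside <- abs(grid_r - best_row) > half | abs(grid_c - best_col) > half
  sub <- frame_image[rr + 1L, cc + 1L, drop = FALSE]
  bg_pixels <- sub[outside]
  if (length(bg_pixels) < 2L) bg_pixels <- as.vector(sub)
  bg_level <- stats::median(bg_pixels)
  # robust spread: a second particle in the surround must not inflate the
  # detection threshold, so use the scaled MAD rather than the raw sd
  bg_sd <- stats::mad(bg_pixels)
  threshold <- bg_level + config$brightness_k * bg_sd

  vals <- m[idx]
  keep <- vals > threshold
  idx <- idx[keep, , drop = FALSE]; vals <- vals[keep]
  if (nrow(idx) == 0L) return(list())

  cand_rows <- wm$center_rows[idx[, 1L]]
  cand_cols <- wm$center_cols[idx[, 2L]]
  # deterministic order: brightness desc, then nearest the previous position
  # (the region center), then row-major
  d2prev <- (cand_rows - region$center["row"])^2 + (cand_cols - region$center["col"])^2
  ord <- order(-vals, d2prev, cand_rows, cand_cols)
  cand_rows <- cand_rows[ord]; cand_cols <- cand_cols[ord]; vals <- vals[ord]

  # non-maximum suppression at min_separation
  kept <- integer(0)
  for (k in seq_along(vals)) {
    if (length(kept) == 0L) { kept <- k; next }
    d <- sqrt((cand_rows[kept] - cand_rows[k])^2 + (cand_cols[kept] - cand_cols[k])^2)
    if (all(d >= config$min_separation)) kept <- c(kept, k)
  }
  lapply(kept, function(k) list(row = cand_rows[k], col = cand_cols[k],
                                window_mean = vals[k]))
}
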