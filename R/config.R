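#' Tracking configuration
#'
#' Bundles the user-set parameters of the frame-by-frame tracker. The scan
#' region is the `scan_rows` x `scan_cols` rectangle centered on a particle's
#' last known position within which the next detection is sought; the
#' localization window is the smaller `window_size` x `window_size` rectangle
#' whose mean intensity defines the local-maxima map and whose pixels feed the
#' sub-pixel localizer. All pixel dimensions must be odd so every region has an
#' unambiguous center pixel.
#'
#' @param scan_rows,scan_cols Height and width of the particle scan region in
#'   pixels; positive odd integers, typically 5-50.
#' @param window_size Side of the localization window in pixels; positive odd
#'   integer, at most `min(scan_rows, scan_cols)`.
#' @param localization_method `"gaussian"` (2D Gaussian fit, centroid fallback)
#'   or `"centroid"`.
#' @param brightness_k Non-negative detection threshold multiplier: a candidate
#'   window mean must exceed the local background median by more than
#'   `brightness_k` background standard deviations to count as a detection.
#' @param min_separation Minimum distance in pixels between two detected
#'   candidates; closer candidates are suppressed in favor of the brighter one.
#'   Two or more surviving candidates trigger the overlap intervention.
#'   Defaults to `window_size`.
#' @param frame_interval Time between frames in seconds (default 0.1 s, i.e.
#'   10 frames per second).
#' @param pixel_size Physical pixel size in micrometers (default 0.107 um, a
#'   16-um EMCCD pixel behind a 150x objective).
#'
#' @return An object of class `tracking_config` (a named list).
#' @export
#' @examples
#' cfg <- tracking_config(scan_rows = 21, scan_cols = 21, window_size = 7)
#' cfg$min_separation  # defaults to the window size
tracking_config <- function(scan_rows = 21L,
                            scan_cols = 21L,
                            window_size = 7L,
                            localization_method = c("gaussian", "centroid"),
                            brightness_k = 2,
                            min_separation = window_size,
                            frame_interval = 0.1,
                            pixel_size = 0.107) {
  localization_method <- match.arg(localization_method)
  check_odd <- function(v, name) {
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v) || v %% 2 != 1) {
      stop(sprintf("`%s` must be a positive odd integer, got %s", name,
                   deparse(v)), call. = FALSE)
    }
    as.integer(v)
  }
  scan_rows <- check_odd(scan_rows, "scan_rows")
  scan_cols <- check_odd(scan_cols, "scan_cols")
  window_size <- check_odd(window_size, "window_size")
  if (window_size > min(scan_rows, scan_cols)) {
    stop("`window_size` must not exceed min(scan_rows, scan_cols)", call. = FALSE)
  }
  stopifnot(is.numeric(brightness_k), length(brightness_k) == 1L,
            is.finite(brightness_k), brightness_k >= 0)
  if (length(min_separation) != 1L || !is.finite(min_separation) ||
      min_separation < 1 || min_separation != round(min_separation)) {
    stop("`min_separation` must be a positive integer", call. = FALSE)
  }
  stopifnot(is.numeric(frame_interval), frame_interval > 0,
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(
    scan_rows = scan_rows,
    scan_cols = scan_cols,
    window_size = window_size,
    localization_method = localization_method,
    brightness_k = as.numeric(brightness_k),
    min_separation = as.integer(min_separation),
    frame_interval = as.numeric(frame_interval),
    pixel_size = as.numeric(pixel_size)
  ), class = "tracking_config")
}

#' @export
print.tracking_config <- function(x, ...) {
  cat("Tracking configuration\n")
  cat(sprintf("  scan region : %d x %d px\n", x$scan_rows, x$scan_cols))
  cat(sprintf("  window size : %d px\n", x$window_size))
  cat(sprintf("  localization: %s\n", x$localization_method))
  cat(sprintf("  brightness_k: %g, min_separation: %d px\n",
              x$brightness_k, x$min_separation))
  cat(sprintf("  frame interval: %g s, pixel size: %g um\n",
              x$frame_interval, x$pixel_size))
  invisible(x)
}
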