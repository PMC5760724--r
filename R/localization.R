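# Sub-pixel localization of a fluorescent spot within a small square window:
# intensity centroid, or a 2D Gaussian
#   I(x, y) = A exp(-(x - x_c)^2 / (2 w_x^2) - (y - y_c)^2 / (2 w_y^2))
# fitted to background-subtracted pixels by log-linearized weighted least
# squares. Plus background estimation and the signal-to-noise ratio
#   SNR = (mu_sig - mu_background) / sigma_background.

# 0-based inclusive window bounds around an integer center; errors if the
# window does not fit inside the image.
window_bounds <- function(center_row, center_col, window_size, image_shape) {
  half <- (window_size - 1L) %/% 2L
  b <- list(row_min = center_row - half, row_max = center_row + half,
            col_min = center_col - half, col_max = center_col + half)
  if (b$row_min < 0L || b$col_min < 0L ||
      b$row_max > image_shape[1] - 1L || b$col_max > image_shape[2] - 1L) {
    stop(sprintf("localization window (center row %d, col %d, size %d) falls outside the image",
                 center_row, center_col, window_size), call. = FALSE)
  }
  b
}

# clamp an integer window center so that the window fits inside the image
clamp_window_center <- function(center_row, center_col, window_size, image_shape) {
  half <- (window_size - 1L) %/% 2L
  c(row = min(max(center_row, half), image_shape[1] - 1L - half),
    col = min(max(center_col, half), image_shape[2] - 1L - half))
}

window_pixels <- function(frame_image, bounds) {
  frame_image[(bounds$row_min + 1L):(bounds$row_max + 1L),
              (bounds$col_min + 1L):(bounds$col_max + 1L), drop = FALSE]
}

#' Estimate the local background level
#'
#' Median of the scan-region pixels that lie outside the localization window;
#' if the window covers the whole region, the median of the region. The median
#' is robust to a second particle sitting in the surround.
#'
#' @param frame_image Numeric matrix, one movie frame.
#' @param region A `scan_region`.
#' @param window_center Integer `(row, col)`, 0-based window center.
#' @param window_size Odd integer window side.
#'
#' @return Background level (scalar).
#' @export
estimate_background <- function(frame_image, region, window_center, window_size) {
  rr <- (region$row_min):(region$row_max)
  cc <- (region$col_min):(region$col_max)
  if (length(rr) == 0L || length(cc) == 0L) stop("empty scan region", call. = FALSE)
  sub <- frame_image[rr + 1L, cc + 1L, drop = FALSE]
  half <- (window_size - 1L) %/% 2L
  grid_r <- matrix(rr, length(rr), length(cc))
  grid_c <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  outside <- abs(grid_r - window_center[1]) > half | abs(grid_c - window_center[2]) > half
  vals <- sub[outside]
  if (length(vals) == 0L) vals <- as.vector(sub)
  stats::median(vals)
}

#' Centroid localization
#'
#' Intensity-weighted centroid of the background-subtracted window:
#' `x_c = sum(I_ij * x_i) / sum(I_ij)` and likewise for `y_c`, where the sums
#' run over the window pixels with negative background-subtracted intensities
#' clipped to zero. The reported intensity is the raw window sum minus
#' `background` times the number of window pixels.
#'
#' @param frame_image Numeric matrix, one movie frame.
#' @param window_center Integer `(row, col)`, 0-based center of the window.
#' @param window_size Odd integer window side; window must fit in the image.
#' @param background Scalar background level to subtract.
#'
#' @return List with `x_c`, `y_c` (0-based sub-pixel coordinates) and
#'   `intensity`.
#' @export
#' @examples
#' img <- matrix(0, 9, 9)
#' img[5, 4] <- 2  # 0-based (row 4, col 3)
#' localize_centroid(img, c(4, 4), 5, background = 0)
localize_centroid <- function(frame_image, window_center, window_size, background) {
  b <- window_bounds(window_center[1], window_center[2], window_size, dim(frame_image))
  raw <- window_pixels(frame_image, b)
  I <- pmax(raw - background, 0)
  total <- sum(I)
  if (total <= 0) {
    stop("no signal: all background-subtracted window pixels are zero", call. = FALSE)
  }
  xs <- matrix((b$col_min):(b$col_max), nrow(raw), ncol(raw), byrow = TRUE)
  ys <- matrix((b$row_min):(b$row_max), nrow(raw), ncol(raw))
  list(x_c = sum(I * xs) / total,
       y_c = sum(I * ys) / total,
       intensity = sum(raw) - background * length(raw))
}

#' 2D Gaussian fit by log-linearized weighted least squares
#'
#' Fits `ln I` as a quadratic in x and y over the window pixels with positive
#' background-subtracted intensity, weighting each pixel by its squared
#' intensity (so bright pixels, whose log-transformed noise is smallest,
#' dominate). The Gaussian parameters are recovered from the quadratic
#' coefficients; for noiseless Gaussian data the fit is exact. The fit is
#' marked unconverged when either quadratic coefficient is non-negative (the
#' surface is not a peak) or the recovered center falls outside the window;
#' callers then fall back to the centroid.
#'
#' @inheritParams localize_centroid
#'
#' @return An object of class `gaussian_fit`: list with `A`, `x_c`, `y_c`,
#'   `w_x`, `w_y`, `integrated_intensity` (`2*pi*A*w_x*w_y`) and `converged`.
#' @export
fit_gaussian_2d <- function(frame_image, window_center, window_size, background) {
  b <- window_bounds(window_center[1], window_center[2], window_size, dim(frame_image))
  raw <- window_pixels(frame_image, b)
  v <- raw - background
  xs <- matrix((b$col_min):(b$col_max), nrow(raw), ncol(raw), byrow = TRUE)
  ys <- matrix((b$row_min):(b$row_max), nrow(raw), ncol(raw))
  use <- v > 0
  if (sum(use) < 6L) {
    stop(sprintf("2D Gaussian fit needs >= 6 pixels above background, got %d", sum(use)),
         call. = FALSE)
  }
  vi <- v[use]; xi <- xs[use]; yi <- ys[use]
  X <- cbind(1, xi, xi^2, yi, yi^2)
  fit <- stats::lm.wfit(X, log(vi), w = vi^2)
  cf <- fit$coefficients
  failed <- anyNA(cf) || cf[3] >= 0 || cf[5] >= 0
  if (!failed) {
    w_x <- sqrt(-1 / (2 * cf[3])); w_y <- sqrt(-1 / (2 * cf[5]))
    x_c <- -cf[2] / (2 * cf[3]);   y_c <- -cf[4] / (2 * cf[5])
    A <- exp(cf[1] - cf[3] * x_c^2 - cf[5] * y_c^2)
    failed <- x_c < b$col_min || x_c > b$col_max || y_c < b$row_min || y_c > b$row_max
  }
  if (failed) {
    return(structure(list(A = NA_real_, x_c = NA_real_, y_c = NA_real_,
                          w_x = NA_real_, w_y = NA_real_,
                          integrated_intensity = NA_real_, converged = FALSE),
                     class = "gaussian_fit"))
  }
  structure(list(A = unname(A), x_c = unname(x_c), y_c = unname(y_c),
                 w_x = unname(w_x), w_y = unname(w_y),
                 integrated_intensity = unname(2 * pi * A * w_x * w_y),
                 converged = TRUE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("2D Gaussian fit: not converged\n")
  } else {
    cat(sprintf("2D Gaussian fit: A=%.4g, center (x=%.4f, y=%.4f), w=(%.3f, %.3f) px, integrated=%.4g\n",
                x$A, x$x_c, x$y_c, x$w_x, x$w_y, x$integrated_intensity))
  }
  invisible(x)
}

#' Signal-to-noise ratio of a particle image
#'
#' `SNR = (mu_sig - mu_background) / sigma_background` where `mu_sig` and
#' `mu_background` are the mean intensities of the signal and background pixel
#' sets and `sigma_background` the standard deviation of the background set.
#' The conventional regions are the localization window (signal) and the scan
#' region minus the window (background); [snr_in_region()] applies that
#' convention.
#'
#' @param frame_image Numeric matrix, one movie frame.
#' @param signal_pixels,background_pixels Two-column matrices of 0-based
#'   `(row, col)` pixel indices; disjoint, background with >= 2 pixels.
#'
#' @return List with `mu_sig`, `mu_background`, `sigma_background`, `snr`.
#' @export
compute_snr <- function(frame_image, signal_pixels, background_pixels) {
  signal_pixels <- matrix(as.integer(signal_pixels), ncol = 2L)
  background_pixels <- matrix(as.integer(background_pixels), ncol = 2L)
  if (nrow(signal_pixels) < 1L || nrow(background_pixels) < 2L) {
    stop("signal region must be non-empty and background region have >= 2 pixels",
         call. = FALSE)
  }
  key <- function(m) paste(m[, 1], m[, 2])
  if (any(key(signal_pixels) %in% key(background_pixels))) {
    stop("signal and background regions must be disjoint", call. = FALSE)
  }
  sig <- frame_image[signal_pixels + 1L]
  bg <- frame_image[background_pixels + 1L]
  sigma <- stats::sd(bg)
  if (!is.finite(sigma) || sigma == 0) {
    stop("background standard deviation is zero: SNR undefined", call. = FALSE)
  }
  list(mu_sig = mean(sig), mu_background = mean(bg),
       sigma_background = sigma, snr = (mean(sig) - mean(bg)) / sigma)
}

#' @describeIn compute_snr SNR with signal = the localization window centered
#'   at `window_center` and background = the scan region minus that window.
#' @param region A `scan_region`.
#' @param window_center Integer `(row, col)` window center, 0-based.
#' @param window_size Odd integer window side.
#' @export
snr_in_region <- function(frame_image, region, window_center, window_size) {
  rr <- (region$row_min):(region$row_max)
  cc <- (region$col_min):(region$col_max)
  grid_r <- matrix(rr, length(rr), length(cc))
  grid_c <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  half <- (window_size - 1L) %/% 2L
  inside <- abs(grid_r - window_center[1]) <= half & abs(grid_c - window_center[2]) <= half
  compute_snr(frame_image,
              cbind(grid_r[inside], grid_c[inside]),
              cbind(grid_r[!inside], grid_c[!inside]))
}
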