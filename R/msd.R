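# Time-averaged mean squared displacement (TA-MSD) of a single trajectory,
#   rho_n = sum_{i=1}^{N-n} [(x_{i+n} - x_i)^2 + (y_{i+n} - y_i)^2] / (N - n),
# with pairs touching a gap frame dropped from both numerator and denominator,
# plus the closed-form relative standard deviation of rho_n for a Brownian
# trajectory of N frames (Qian et al.), and diffusion-coefficient /
# anomalous-exponent estimation from the curve.

#' Closed-form relative error of the TA-MSD
#'
#' Relative standard deviation of the time-averaged MSD estimator at lag `n`
#' for an `N`-frame Brownian trajectory (Qian et al.), evaluated piecewise:
#' \deqn{\sqrt{\frac{4n^2N - 5n^3 + 2N - n}{6n(N-n)^2}} \quad (n \le N/2)}
#' \deqn{\sqrt{1 + \frac{N^3 - 5n^3 - 7nN^2 + 11n^2N + 5n - N}{6n^2(N-n)}} \quad (n > N/2)}
#' At the single-pair limit `n = N - 1` the value is exactly 1.
#'
#' @param n Lag (frames), integer vector, `1 <= n <= N - 1`.
#' @param N Trajectory length in frames.
#'
#' @return Numeric vector of relative errors.
#' @export
#' @examples
#' qian_relative_error(1, 2)            # 1
#' qian_relative_error(1, 100)          # ~0.1005
#' qian_relative_error(99, 100)         # 1
qian_relative_error <- function(n, N) {
  stopifnot(length(N) == 1L, N >= 2, N == round(N))
  if (any(n < 1 | n >= N | n != round(n))) {
    stop(sprintf("lag n must satisfy 1 <= n <= N - 1 = %d", N - 1), call. = FALSE)
  }
  out <- numeric(length(n))
  lo <- n <= N / 2
  nl <- n[lo]; nh <- n[!lo]
  out[lo] <- sqrt((4 * nl^2 * N - 5 * nl^3 + 2 * N - nl) / (6 * nl * (N - nl)^2))
  out[!lo] <- sqrt(pmax(0, 1 + (N^3 - 5 * nh^3 - 7 * nh * N^2 + 11 * nh^2 * N +
                                  5 * nh - N) / (6 * nh^2 * (N - nh))))
  out
}

# accept a track object or a bare data frame of points
track_points <- function(track) {
  if (inherits(track, "track")) track$points else as.data.frame(track)
}

#' Time-averaged MSD of one trajectory
#'
#' Computes `rho_n` for every lag `n = 1 .. N-1`, averaging squared
#' displacements over all frame pairs `(i, i+n)` whose two endpoints are both
#' localized (gap frames, stored as `NaN`, are excluded from numerator and
#' denominator). Coordinates are converted from pixels to micrometers with
#' `pixel_size`; a terminal `stopped` point carries no measurement and is
#' dropped. Relative errors use the closed form of [qian_relative_error()]
#' with the full trajectory length `N`.
#'
#' @param track A `track` object, or a data frame with columns `x`, `y` (and
#'   optionally `status`).
#' @param dt Frame interval in seconds.
#' @param pixel_size Pixel size in micrometers.
#'
#' @return An object of class `msd_curve`: data frame with columns `lag`,
#'   `tau_s`, `msd_um2`, `n_pairs`, `rel_error`, and attributes `N` (frames),
#'   `dt`, `pixel_size`. `msd_um2` is `NA` at lags with no valid pair.
#' @export
compute_ta_msd <- function(track, dt, pixel_size) {
  stopifnot(dt > 0, pixel_size > 0)
  pts <- track_points(track)
  if (!is.null(pts$status)) pts <- pts[pts$status != "stopped", , drop = FALSE]
  x <- pts$x * pixel_size
  y <- pts$y * pixel_size
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) stop("trajectory has fewer than 2 localized points", call. = FALSE)
  N <- length(x)
  lags <- seq_len(N - 1L)
  rho <- rep(NA_real_, N - 1L)
  npairs <- integer(N - 1L)
  for (n in lags) {
    i <- seq_len(N - n)
    valid <- ok[i] & ok[i + n]
    npairs[n] <- sum(valid)
    if (npairs[n] > 0L) {
      dx <- x[i + n][valid] - x[i][valid]
      dy <- y[i + n][valid] - y[i][valid]
      rho[n] <- sum(dx^2 + dy^2) / npairs[n]
    }
  }
  structure(data.frame(lag = lags, tau_s = lags * dt, msd_um2 = rho,
                       n_pairs = npairs,
                       rel_error = qian_relative_error(lags, N)),
            N = N, dt = dt, pixel_size = pixel_size,
            class = c("msd_curve", "data.frame"))
}

#' Diffusion coefficient and anomalous exponent from an MSD curve
#'
#' Fits the 2-D Brownian relation `rho(tau) = 4 D tau + b` by ordinary least
#' squares over the chosen lags (free intercept `b` absorbing localization
#' noise) and, over the same lags, the anomalous exponent `alpha` as the slope
#' of `log(rho)` versus `log(tau)` (`alpha = 1` Brownian, `< 1` sub-diffusive,
#' `2` ballistic). Short lags (default 1-4) keep the correlated-error bias of
#' the TA-MSD small.
#'
#' @param curve An `msd_curve` from [compute_ta_msd()].
#' @param fit_lags Integer lags to fit (default `1:4`); lags missing from the
#'   curve or without valid pairs are dropped.
#'
#' @return An object of class `diffusion_estimate`: list with `D` (um^2/s;
#'   negative slopes are reported, flagged by `negative_slope`), `intercept`
#'   (um^2), `alpha`, `r_squared`, `fit_lags`.
#' @export
fit_diffusion_coefficient <- function(curve, fit_lags = 1:4) {
  sub <- curve[curve$lag %in% fit_lags & is.finite(curve$msd_um2), , drop = FALSE]
  if (nrow(sub) < 2L) {
    stop("need at least 2 defined MSD lags in `fit_lags` to fit", call. = FALSE)
  }
  fit <- stats::lm(msd_um2 ~ tau_s, data = sub)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((sub$msd_um2 - mean(sub$msd_um2))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  pos <- sub[sub$msd_um2 > 0, , drop = FALSE]
  alpha <- if (nrow(pos) >= 2L) {
    unname(stats::coef(stats::lm(log(msd_um2) ~ log(tau_s), data = pos))[2])
  } else {
    NA_real_
  }
  structure(list(D = slope / 4,
                 intercept = unname(stats::coef(fit)[1]),
                 alpha = alpha,
                 r_squared = r2,
                 fit_lags = sub$lag,
                 negative_slope = slope < 0),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g um^2/s (intercept %.4g um^2, lags %s, R^2 %.3f)%s\n",
              x$D, x$intercept, paste(range(x$fit_lags), collapse = "-"),
              x$r_squared, if (x$negative_slope) " [negative slope]" else ""))
  cat(sprintf("anomalous exponent alpha = %.3f\n", x$alpha))
  invisible(x)
}
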