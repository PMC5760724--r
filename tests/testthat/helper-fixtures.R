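# Shared fixtures, all generated in code. Amplitude 100 spots of width 1.5 px
# on a background of 100 counts, 10 fps sampling and 0.1 um pixels, with the
# camera noise set by calibrate_noise_for_snr() to hit a requested SNR.

fixture_config <- function(...) {
  tracking_config(scan_rows = 21, scan_cols = 21, window_size = 7,
                  pixel_size = 0.1, frame_interval = 0.1, ...)
}

# one particle with the given motion model
one_particle_movie <- function(model, snr, seed, n_frames = 50, x0 = 30, y0 = 30,
                               blink = integer(0), size = 64) {
  sigma <- if (is.finite(snr)) calibrate_noise_for_snr(100, 1.5, 1.5, 7, snr) else 0
  spec <- synthetic_movie_spec(
    n_frames = n_frames, height = size, width = size, dt = 0.1, pixel_size = 0.1,
    particles = list(list(x0 = x0, y0 = y0, model = model, A = 100, blink = blink)),
    background_level = 100, noise_sigma = sigma, seed = seed)
  simulate_movie(spec)
}

# two particles with directed motion crossing in x while passing 8 px apart in
# y (two spots sharing a scan region but never merging into one blob)
crossing_movie <- function(seed, snr = 8, n_frames = 40) {
  sigma <- calibrate_noise_for_snr(100, 1.5, 1.5, 7, snr)
  spec <- synthetic_movie_spec(
    n_frames = n_frames, height = 64, width = 96, dt = 0.1, pixel_size = 0.1,
    particles = list(
      list(x0 = 10, y0 = 26, model = motion_model("directed", velocity = c(1.3, 0)),
           A = 100),
      list(x0 = 62, y0 = 34, model = motion_model("directed", velocity = c(-1.3, 0)),
           A = 100)),
    background_level = 100, noise_sigma = sigma, seed = seed)
  simulate_movie(spec)
}

# per-frame distance of each track from its own particle's ground truth
track_errors <- function(tracks, truth) {
  lapply(seq_along(tracks), function(i) {
    p <- tracks[[i]]$points
    tr <- truth[truth$particle_id == i, ]
    sqrt((p$x - tr$x_true[match(p$frame, tr$frame)])^2 +
           (p$y - tr$y_true[match(p$frame, tr$frame)])^2)
  })
}
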