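# Scan-region maintenance, local-maxima detection, the intervention contract,
# and full-movie tracking.

test_that("scan region is centered, clipped, and rounded to the nearest pixel", {
  cfg <- fixture_config()
  r <- define_scan_region(c(50, 50), cfg, c(512, 512))
  expect_equal(c(r$row_min, r$row_max, r$col_min, r$col_max), c(40, 60, 40, 60))

  # clipping shrinks at the border without shifting the opposite edge
  r2 <- define_scan_region(c(50, 2), cfg, c(512, 512))
  expect_equal(c(r2$row_min, r2$row_max, r2$col_min, r2$col_max), c(0, 12, 40, 60))

  # sub-pixel center rounds to the nearest integer pixel
  r3 <- define_scan_region(c(50.4, 50.6), cfg, c(512, 512))
  r3b <- define_scan_region(c(50, 51), cfg, c(512, 512))
  expect_equal(r3[c("row_min", "row_max", "col_min", "col_max")],
               r3b[c("row_min", "row_max", "col_min", "col_max")])

  expect_error(define_scan_region(c(-40, 50), cfg, c(512, 512)), "lost")
})

test_that("local-maxima detection finds isolated and paired spots", {
  cfg <- fixture_config()

  # single bright pixel on a zero background -> one candidate at that pixel
  img <- matrix(0, 64, 64)
  img[31, 31] <- 100  # 0-based (30, 30)
  reg <- define_scan_region(c(30, 30), cfg, c(64, 64))
  cands <- detect_local_maxima(img, reg, cfg)
  expect_length(cands, 1)
  expect_equal(c(cands[[1]]$row, cands[[1]]$col), c(30, 30))

  # flat image -> nothing exceeds background
  expect_length(detect_local_maxima(matrix(5, 64, 64), reg, cfg), 0)

  # two rendered spots 10 px apart, min_separation 5 -> both found within 1 px
  cfg5 <- fixture_config(min_separation = 5)
  img2 <- render_spot(matrix(0, 64, 64), 100, 25, 30, 1.5, 1.5)
  img2 <- render_spot(img2, 80, 35, 30, 1.5, 1.5)
  reg2 <- define_scan_region(c(30, 30), cfg5, c(64, 64))
  cands2 <- detect_local_maxima(img2, reg2, cfg5)
  expect_length(cands2, 2)
  expect_lte(abs(cands2[[1]]$col - 25), 1)  # brighter spot first
  expect_lte(abs(cands2[[2]]$col - 35), 1)
  expect_gt(cands2[[1]]$window_mean, cands2[[2]]$window_mean)
})

test_that("raising brightness_k only removes detection candidates", {
  # the brightness test filters a fixed candidate list, so the candidate set
  # at a higher k is a subset of the set at any lower k, frame by frame
  mv <- one_particle_movie(motion_model("brownian", D = 0.05), snr = 2, seed = 21)
  ks <- c(0, 1, 2, 4, 8)
  truth <- mv$truth
  per_k <- lapply(ks, function(k) {
    cfg <- fixture_config(brightness_k = k)
    lapply(0:49, function(t) {
      fr <- matrix(mv$stack[t + 1, , ], 64, 64)
      reg <- define_scan_region(c(truth$x_true[t + 1], truth$y_true[t + 1]),
                                cfg, c(64, 64))
      cands <- detect_local_maxima(fr, reg, cfg)
      sort(vapply(cands, function(cd) cd$row * 64 + cd$col, numeric(1)))
    })
  })
  for (j in seq_along(ks)[-1]) {
    for (t in 1:50) {
      expect_true(all(per_k[[j]][[t]] %in% per_k[[j - 1]][[t]]),
                  label = sprintf("k=%g frame %d subset of k=%g", ks[j], t - 1,
                                  ks[j - 1]))
    }
  }
  n_any <- sapply(per_k, function(fr) sum(lengths(fr) > 0))
  expect_true(all(diff(n_any) <= 0))
})

test_that("linear-motion prediction extrapolates the last two localized points", {
  tr <- dimtrack:::new_track(1)
  tr <- dimtrack:::append_point(tr, dimtrack:::track_point(0, 1, 1, 10, "manual"))
  tr <- dimtrack:::append_point(tr, dimtrack:::track_point(1, 2, 3, 10, "detected"))
  expect_equal(predict_linear_motion(tr, 2), c(3, 5))

  # zero velocity
  tr0 <- dimtrack:::new_track(1)
  tr0 <- dimtrack:::append_point(tr0, dimtrack:::track_point(0, 4, 4, 10, "manual"))
  tr0 <- dimtrack:::append_point(tr0, dimtrack:::track_point(1, 4, 4, 10, "detected"))
  expect_equal(predict_linear_motion(tr0, 2), c(4, 4))

  # velocity measured across a gap: (0,0) .. gap .. (2,0) -> (3,0) at frame 3
  trg <- dimtrack:::new_track(1)
  trg <- dimtrack:::append_point(trg, dimtrack:::track_point(0, 0, 0, 10, "manual"))
  trg <- dimtrack:::append_point(trg, dimtrack:::gap_point(1))
  trg <- dimtrack:::append_point(trg, dimtrack:::track_point(2, 2, 0, 10, "detected"))
  expect_equal(predict_linear_motion(trg, 3), c(3, 0))

  # not enough history
  tr1 <- dimtrack:::new_track(1)
  tr1 <- dimtrack:::append_point(tr1, dimtrack:::track_point(0, 1, 1, 10, "manual"))
  expect_error(predict_linear_motion(tr1, 1), "fall back")
})

test_that("step_frame localizes an unambiguous spot without intervention", {
  mv <- one_particle_movie(motion_model("stationary"), snr = 10, seed = 5,
                           n_frames = 2)
  cfg <- fixture_config()
  tracks <- track_movie(mv$stack, list(c(30, 30)), cfg)
  pt <- tracks[[1]]$points[2, ]
  expect_equal(pt$status, "detected")
  expect_lt(sqrt((pt$x - 30)^2 + (pt$y - 30)^2), 0.2)
  expect_equal(nrow(attr(tracks, "interventions")), 0)
})

test_that("a blank region triggers no_maximum and the decision is applied", {
  stack <- array(100, dim = c(2, 64, 64))
  stack[1, , ] <- matrix(render_spot(matrix(100, 64, 64), 100, 30, 30, 1.5, 1.5),
                         64, 64)
  cfg <- fixture_config()

  gap_tracks <- track_movie(stack, list(c(30, 30)), cfg, policy_automatic())
  expect_equal(gap_tracks[[1]]$points$status[2], "gap")
  expect_true(is.nan(gap_tracks[[1]]$points$x[2]))

  stop_policy <- policy_scripted(data.frame(frame = 1, track_id = 1, action = "stop"))
  st <- track_movie(stack, list(c(30, 30)), cfg, stop_policy)
  expect_equal(st[[1]]$points$status[2], "stopped")

  log <- attr(gap_tracks, "interventions")
  expect_equal(log$kind, "no_maximum")
  expect_equal(log$action, "gap")
})

test_that("an illegal policy action is rejected by name", {
  stack <- array(100, dim = c(2, 64, 64))
  stack[1, , ] <- matrix(render_spot(matrix(100, 64, 64), 100, 30, 30, 1.5, 1.5),
                         64, 64)
  bad <- policy_scripted(data.frame(frame = 1, track_id = 1, action = "linear_motion"))
  expect_error(track_movie(stack, list(c(30, 30)), fixture_config(), bad),
               "illegal action 'linear_motion' for a no_maximum request")
})

test_that("stationary particles are tracked to sub-0.1-px RMSE at SNR 10", {
  mv <- one_particle_movie(motion_model("stationary"), snr = 10, seed = 42)
  tracks <- track_movie(mv$stack, list(c(30, 30)), fixture_config())
  pts <- tracks[[1]]$points
  expect_equal(nrow(pts), 50)
  expect_lt(sqrt(mean((pts$x - 30)^2 + (pts$y - 30)^2)), 0.1)
})

test_that("two well-separated particles produce two intervention-free tracks", {
  sigma <- calibrate_noise_for_snr(100, 1.5, 1.5, 7, 10)
  spec <- synthetic_movie_spec(30, 64, 96, dt = 0.1, pixel_size = 0.1,
    particles = list(
      list(x0 = 20, y0 = 30, model = motion_model("stationary"), A = 100),
      list(x0 = 70, y0 = 30, model = motion_model("stationary"), A = 100)),
    background_level = 100, noise_sigma = sigma, seed = 8)
  mv <- simulate_movie(spec)
  tracks <- track_movie(mv$stack, list(c(20, 30), c(70, 30)), fixture_config())
  expect_length(tracks, 2)
  expect_true(all(sapply(tracks, function(t) nrow(t$points) == 30)))
  expect_equal(nrow(attr(tracks, "interventions")), 0)
})

test_that("a 5-frame blink yields 5 gaps and tracking resumes on target", {
  mv <- one_particle_movie(motion_model("stationary"), snr = 5, seed = 7,
                           n_frames = 40, blink = 20:24)
  tracks <- track_movie(mv$stack, list(c(30, 30)), fixture_config())
  pts <- tracks[[1]]$points
  expect_equal(which(pts$status == "gap") - 1L, 20:24)
  resumed <- pts[pts$frame == 25, ]
  expect_lt(sqrt((resumed$x - 30)^2 + (resumed$y - 30)^2), 0.5)
})

test_that("every track has one point per frame and a valid status partition", {
  mv <- crossing_movie(seed = 4)
  tracks <- suppressWarnings(
    track_movie(mv$stack, list(c(10, 26), c(62, 34)),
                fixture_config(min_separation = 3)))
  for (tr in tracks) {
    expect_equal(tr$points$frame, 0:(nrow(tr$points) - 1L))
    expect_true(all(tr$points$status %in%
                      c("detected", "manual", "predicted", "gap", "stopped")))
    gaps <- tr$points$status == "gap"
    expect_true(all(is.nan(tr$points$x[gaps])))
    expect_true(all(is.finite(tr$points$x[!gaps & tr$points$status != "stopped"])))
  }
})

test_that("a constant-velocity crossing is carried through by linear motion", {
  mv <- crossing_movie(seed = 2)
  tracks <- suppressWarnings(
    track_movie(mv$stack, list(c(10, 26), c(62, 34)),
                fixture_config(min_separation = 3)))
  errs <- track_errors(tracks, mv$truth)
  # identities preserved to the end, predicted points stay on the line
  expect_lt(max(errs[[1]]), 0.5)
  expect_lt(max(errs[[2]]), 0.5)
  log <- attr(tracks, "interventions")
  expect_true(all(log$kind == "overlap"))
  expect_true(all(log$action == "linear_motion"))
  expect_gt(nrow(log), 0)
})

test_that("the oracle policy resolves low-SNR crossings almost perfectly", {
  correct <- 0L; total <- 0L
  for (s in 1:3) {
    mv <- crossing_movie(seed = 500 + s, snr = 2)
    tracks <- suppressWarnings(
      track_movie(mv$stack, list(c(10, 26), c(62, 34)),
                  fixture_config(min_separation = 3), policy_oracle(mv$truth)))
    errs <- track_errors(tracks, mv$truth)
    for (e in errs) {
      correct <- correct + sum(is.finite(e) & e < 2)
      total <- total + length(e)
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("tracking is deterministic: identical runs give identical tables", {
  mv <- crossing_movie(seed = 13)
  run <- function() suppressWarnings(
    track_movie(mv$stack, list(c(10, 26), c(62, 34)),
                fixture_config(min_separation = 3)))
  expect_identical(tracks_to_table(run()), tracks_to_table(run()))
})

test_that("invalid annotations are rejected with the particle index", {
  stack <- array(100, dim = c(2, 32, 32))
  expect_error(track_movie(stack, list(), fixture_config()), "no initial positions")
  expect_error(track_movie(stack, list(c(10, 10), c(200, 10)), fixture_config()),
               "annotation 2")
})
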