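test_that("peak detection: blank frames, suppression, sub-pixel accuracy", {
  expect_equal(nrow(detect_peaks(matrix(10, 32, 32) +
                                 matrix(rnorm(32 * 32, sd = 0.5), 32))), 0)
  # two spots closer than min_separation collapse to one detection
  img <- matrix(10, 48, 48)
  put <- function(img, r, c, a = 100) {
    for (dr in -2:2) for (dc in -2:2)
      img[r + dr, c + dc] <- img[r + dr, c + dc] +
        a * exp(-(dr^2 + dc^2) / 2)
    img
  }
  img2 <- put(put(img, 20, 20), 20, 22)
  expect_equal(nrow(detect_peaks(img2, min_separation = 3)), 1)
  # well-separated spots: both found, centroid within 0.5 px
  img3 <- put(put(img, 12, 12), 30, 34)
  d <- detect_peaks(img3, pixel_size = 0.16, min_separation = 3)
  expect_equal(nrow(d), 2)
  exp_xy <- rbind(c(11.5, 11.5), c(33.5, 29.5)) * 0.16  # (x, y) = (col, row)
  for (i in 1:2) {
    err <- min(sqrt((d$x_um - exp_xy[i, 1])^2 + (d$y_um - exp_xy[i, 2])^2))
    expect_lt(err, 0.5 * 0.16)
  }
})

test_that("linking: identities, length filter, duplicate handling", {
  # one particle drifting: a single full-length track
  locs <- data.frame(frame = 1:10, x_um = seq(1, 2.8, by = 0.2), y_um = 3)
  tr <- link_tracks(locs, max_jump = 0.8)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  # two particles always far apart: two tracks, no identity swap
  locs2 <- rbind(cbind(locs, id = 1),
                 cbind(data.frame(frame = 1:10,
                                  x_um = seq(15, 16.8, by = 0.2),
                                  y_um = 12), id = 2))
  tr2 <- link_tracks(locs2[c("frame", "x_um", "y_um")], max_jump = 0.8)
  expect_equal(length(unique(tr2$track_id)), 2)
  split_x <- split(tr2$x_um, tr2$track_id)
  expect_true(all(vapply(split_x, function(v) diff(range(v)) < 2, TRUE)))
  # retained tracks are strictly longer than five localizations
  locs3 <- data.frame(frame = 1:5, x_um = 1:5 * 0.1, y_um = 0.5)
  expect_equal(nrow(link_tracks(locs3)), 0)
  # duplicated (frame, position) rows are dropped with a warning
  expect_warning(link_tracks(rbind(locs, locs[3, ])), "duplicate")
  # no two detections in one frame share a track
  tr4 <- link_tracks(locs2[c("frame", "x_um", "y_um")])
  expect_false(any(duplicated(tr4[c("track_id", "frame")])))
})

test_that("linking recovers ground-truth steps on clean simulated data", {
  p <- sim_params(sigma_loc = 0, n_frames = 150,
                  particle_density_out = 0.02, survival_prob = 0.97,
                  seed = 31)
  s <- simulate_tracks(p, fx_mask)
  relinked <- link_tracks(s$tracks[c("frame", "x_um", "y_um", "intensity")],
                          max_jump = 4 * sqrt(2 * 0.6 * 0.03))
  # every true consecutive pair in retained tracks must be re-linked:
  # match by exact positions (no noise)
  key_true <- with(s$tracks, paste(frame, round(x_um, 9), round(y_um, 9)))
  true_id <- setNames(s$tracks$track_id, key_true)
  key_new <- with(relinked, paste(frame, round(x_um, 9), round(y_um, 9)))
  relinked$true_id <- true_id[key_new]
  same <- with(relinked, diff(track_id) == 0 & diff(frame) == 1)
  pairs_ok <- diff(relinked$true_id) == 0
  expect_gt(mean(pairs_ok[same]), 0.99)
})

test_that("track QC summarizes lengths and steps", {
  expect_equal(nrow(track_qc(data.frame(track_id = integer(0),
                                        frame = integer(0),
                                        x_um = numeric(0),
                                        y_um = numeric(0)))), 0)
  one <- make_track(1, xs = rep(1, 10), ys = rep(1, 10))
  qc1 <- track_qc(one)
  expect_equal(qc1$mean_length, 10)
  expect_equal(qc1$sd_length, 0)
  two <- rbind(make_track(1, rep(1, 6), rep(1, 6)),
               make_track(2, rep(2, 8), rep(2, 8)))
  qc2 <- track_qc(two)
  expect_equal(qc2$mean_length, 7)
  expect_equal(qc2$sd_length, sqrt(2), tolerance = 1e-12)
  # generator defaults: mean track length about 14 after the length filter
  # is *not* applied (raw geometric lengths)
  p <- sim_params(n_frames = 400, particle_density_out = 0.08, seed = 37)
  s <- simulate_tracks(p, fx_mask)
  qc <- track_qc(s$tracks)
  expect_gt(qc$n_tracks, 500)
  expect_equal(qc$mean_length, 14.3, tolerance = 0.08)
})
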