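test_that("parameter validation rejects invalid physics", {
  expect_error(sim_params(frame_interval = 0), "frame_interval")
  expect_error(sim_params(d_out = -1))
  expect_error(sim_params(eps_enter = -0.5))
  expect_error(sim_params(survival_prob = 0))
  expect_error(sim_params(field_size = c(16, 16)))
  expect_error(sim_params(d_out = NaN), "finite")
})

test_that("spacer image: geometry, heterogeneity and mask ground truth", {
  p <- sim_params(field_size = c(64, 64), seed = 1)
  # contact must fit in the field
  expect_error(generate_spacer_image(
    p, contact_shape = list(type = "disk", center_um = c(5.1, 5.1),
                            radius_um = 6)), "fit within")
  g <- generate_spacer_image(
    p, contact_shape = list(type = "disk", center_um = c(5.12, 5.12),
                            radius_um = 2),
    heterogeneity_amplitude = 0, noise_sd = 0)
  # zero heterogeneity: contact is spatially constant and above background
  vals <- g$image[g$mask$mask]
  expect_equal(diff(range(vals)), 0)
  expect_gt(vals[1], mean(g$image[!g$mask$mask]))
  # mask area equals the discrete disk pixel count
  px <- p$pixel_size
  xc <- (seq_len(64) - 0.5) * px
  disk <- outer((xc - 5.12)^2, (xc - 5.12)^2, "+") <= 4
  expect_equal(sum(g$mask$mask), sum(disk))
})

test_that("frozen tracks: D = 0 with no noise is static; same seed is identical", {
  p <- sim_params(field_size = c(64, 64), d_out = 0, d_in = 0, sigma_loc = 0,
                  n_frames = 20, survival_prob = 1,
                  particle_density_out = 0.05, seed = 11)
  g <- generate_spacer_image(p, contact_shape = list(
    type = "disk", center_um = c(5.12, 5.12), radius_um = 2))
  s1 <- simulate_tracks(p, g$mask)
  per <- tapply(s1$tracks$x_um, s1$tracks$track_id, function(v) diff(range(v)))
  expect_true(all(per == 0))
  s2 <- simulate_tracks(p, g$mask)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth$proposals, s2$truth$proposals)
})

test_that("barrier-free steps reproduce the 2D Brownian step-length law", {
  # mean jump of free 2D diffusion is sqrt(pi * D * dt); D = 0.6, dt = 30 ms
  p <- sim_params(eps_enter = 0, eps_exit = 0, sigma_loc = 0,
                  survival_prob = 1, n_frames = 700,
                  particle_density_out = 0.35, seed = 13)
  s <- simulate_tracks(p, fx_mask)
  jd <- jump_distances(s$tracks, frame_interval = p$frame_interval)
  expect_gt(jd$n, 1e5)
  expect_equal(mean(jd$r), sqrt(pi * 0.6 * 0.03), tolerance = 0.01)
  # and there are no boundary rejections without barriers
  expect_true(all(s$truth$proposals$accepted))
})

test_that("boundary acceptance converges to the Boltzmann factor", {
  p <- sim_params(eps_enter = 2, eps_exit = 0, sigma_loc = 0,
                  survival_prob = 1, n_frames = 1400,
                  particle_density_out = 0.3, seed = 17)
  s <- simulate_tracks(p, fx_mask)
  en <- s$truth$proposals[s$truth$proposals$direction == "enter", ]
  expect_gt(nrow(en), 1e3)
  ci <- stats::binom.test(sum(en$accepted), nrow(en))$conf.int
  expect_gt(exp(-2), ci[1])
  expect_lt(exp(-2), ci[2])
})

test_that("ground truth is self-consistent with the mask", {
  p <- sim_params(eps_enter = 1, eps_exit = 0.5, sigma_loc = 0.03,
                  n_frames = 120, particle_density_out = 0.1, seed = 19)
  s <- simulate_tracks(p, fx_mask)
  pos <- s$truth$positions
  lab <- ifelse(mask_contains(fx_mask, pos$x_um, pos$y_um),
                "inside", "outside")
  expect_identical(pos$region, lab)
  # rejected proposals leave the particle on its original side: a rejected
  # entry keeps an outside particle outside at that frame
  rej <- s$truth$proposals[!s$truth$proposals$accepted, ]
  key <- paste(pos$track_id, pos$frame)
  reg <- setNames(pos$region, key)
  side_now <- reg[paste(rej$track_id, rej$frame)]
  ok <- !is.na(side_now)
  expect_true(all((rej$direction == "enter")[ok] ==
                  (side_now == "outside")[ok]))
})

test_that("track lengths are geometric with mean 1/(1 - survival)", {
  p <- sim_params(survival_prob = 0.93, n_frames = 600, sigma_loc = 0,
                  particle_density_out = 0.1, seed = 23)
  s <- simulate_tracks(p, fx_mask)
  len <- as.numeric(table(s$tracks$track_id))
  # drop censored tracks (alive at the final frame)
  last <- tapply(s$tracks$frame, s$tracks$track_id, max)
  len <- len[last < 600]
  expect_equal(mean(len), 1 / 0.07, tolerance = 0.05)
})

test_that("movie rendering feeds detection end-to-end", {
  p <- sim_params(field_size = c(64, 64), n_frames = 2, seed = 3)
  expect_error(render_movie(data.frame(frame = 1, x_um = 1, y_um = 1),
                            p, psf_sigma = 0), "psf_sigma")
  # zero particles: pure Poisson background
  empty <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0))
  stack <- render_movie(empty, p, background = 10, noise_seed = 5)
  expect_equal(mean(stack), 10, tolerance = 0.05)
  # one bright spot recovered within 0.5 px; two spots 10 px apart resolved
  locs <- data.frame(frame = c(1, 2, 2),
                     x_um = c(5.0, 3.0, 3.0 + 10 * 0.16),
                     y_um = c(5.0, 5.0, 5.0))
  stack <- render_movie(locs, p, photon_count = 2000, noise_seed = 5)
  d1 <- detect_peaks(stack[, , 1], pixel_size = 0.16)
  expect_equal(nrow(d1), 1)
  expect_lt(sqrt((d1$x_um - 5)^2 + (d1$y_um - 5)^2), 0.5 * 0.16)
  d2 <- detect_peaks(stack[, , 2], pixel_size = 0.16)
  expect_equal(nrow(d2), 2)
})
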