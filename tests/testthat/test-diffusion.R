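test_that("jump distances: geometry, region labels, gap handling", {
  tr <- make_track(1, xs = c(0, 3), ys = c(0, 4))
  expect_equal(jump_distances(tr)$r, 5)
  tr2 <- make_track(2, xs = rep(1, 5), ys = rep(1, 5))
  expect_true(all(jump_distances(tr2)$r == 0))
  # frame gaps larger than 1 are excluded
  tr3 <- make_track(3, xs = c(0, 1, 2), ys = c(0, 0, 0),
                    frames = c(1, 2, 4))
  expect_equal(jump_distances(tr3)$n, 1)
  # inside/outside jump counts partition the total
  p <- sim_params(n_frames = 60, particle_density_out = 0.1, seed = 73)
  s <- simulate_tracks(p, fx_mask)
  jd_all <- jump_distances(s$tracks, fx_mask, "all")
  jd_in <- jump_distances(s$tracks, fx_mask, "inside")
  jd_out <- jump_distances(s$tracks, fx_mask, "outside")
  expect_equal(jd_in$n + jd_out$n, jd_all$n)
})

test_that("cumulative JD fit recovers Rayleigh scale and floors D at 0", {
  set.seed(79)
  # exact Rayleigh jumps with r0^2 = 4 D dt = 0.072 um^2 (D = 0.6, sigma = 0)
  r <- sqrt(stats::rexp(1e4, rate = 1 / 0.072))
  f <- fit_jd_cumulative(r, sigma = 0, frame_interval = 0.03,
                         n_bootstrap = 100)
  expect_equal(f$D, 0.6, tolerance = 0.05)
  expect_true(f$ci_D[1] < f$D && f$D < f$ci_D[2])
  # fitted CDF median: P(r^2 <= r0^2 ln 2) = 1/2 by construction
  expect_equal(1 - exp(-(f$r0_sq * log(2)) / f$r0_sq), 0.5)
  # static emitters with localization noise: r0^2 ~ 4 sigma^2, D ~ 0
  set.seed(83)
  n <- 4000
  x <- matrix(rnorm(2 * n, sd = 0.03), ncol = 2)
  y <- matrix(rnorm(2 * n, sd = 0.03), ncol = 2)
  r_static <- sqrt((x[, 1] - x[, 2])^2 + (y[, 1] - y[, 2])^2)
  fs <- fit_jd_cumulative(r_static, sigma = 0.03, frame_interval = 0.03,
                          n_bootstrap = 0)
  expect_equal(fs$r0_sq, 4 * 0.03^2, tolerance = 0.1)
  expect_lt(fs$D, 0.005)
  # jump-count floor enforced
  expect_error(fit_jd_cumulative(r[1:10]), "at least")
})

test_that("fit is scale-consistent and bootstrap width shrinks like 1/sqrt(n)", {
  set.seed(89)
  r <- sqrt(stats::rexp(1e4, rate = 1 / 0.072))
  f1 <- fit_jd_cumulative(r, sigma = 0, n_bootstrap = 0)
  f2 <- fit_jd_cumulative(3 * r, sigma = 0, n_bootstrap = 0)
  expect_equal(f2$r0_sq / f1$r0_sq, 9, tolerance = 0.01)
  set.seed(97)
  w <- vapply(c(1e3, 1e4), function(n) {
    f <- fit_jd_cumulative(sqrt(stats::rexp(n, 1 / 0.072)), sigma = 0,
                           n_bootstrap = 120)
    diff(f$ci_r0_sq)
  }, 1)
  expect_equal(w[1] / w[2], sqrt(10), tolerance = 0.35)
})

test_that("two-region diffusion separates with non-overlapping CIs", {
  p <- sim_params(d_in = 0.2, d_out = 0.6, n_frames = 250,
                  particle_density_out = 0.15, seed = 101)
  s <- simulate_tracks(p, fx_mask)
  f_in <- fit_jd_cumulative(jump_distances(s$tracks, fx_mask, "inside"),
                            sigma = 0.03, n_bootstrap = 150)
  f_out <- fit_jd_cumulative(jump_distances(s$tracks, fx_mask, "outside"),
                             sigma = 0.03, n_bootstrap = 150)
  expect_gt(f_in$n_jumps, 1e3); expect_gt(f_out$n_jumps, 1e3)
  expect_lt(f_in$D, f_out$D)
  expect_lt(f_in$ci_D[2], f_out$ci_D[1])
})

test_that("JD maps assign jumps to starting pixels with NA for unvisited", {
  tr <- make_track(1, xs = c(5 * 0.16 + 0.08, 5 * 0.16 + 0.28),
                   ys = c(5 * 0.16 + 0.08, 5 * 0.16 + 0.08))
  m <- jd_map(tr, dim = c(32, 32), pixel_size = 0.16)
  expect_equal(m$mean_jd[6, 6], 0.2)
  expect_equal(m$count[6, 6], 1)
  expect_equal(m$mean_speed[6, 6], 0.2 / 0.03)
  expect_true(is.na(m$mean_jd[1, 1]))
  expect_equal(m$count[1, 1], 0)
  # uniform free diffusion: spatial mean of the map ~ Rayleigh mean
  p <- sim_params(sigma_loc = 0, n_frames = 250,
                  particle_density_out = 0.15, seed = 103)
  s <- simulate_tracks(p, fx_mask)
  mm <- jd_map(s$tracks, dim = c(128, 128))
  expect_equal(mean(mm$mean_jd, na.rm = TRUE), sqrt(pi * 0.6 * 0.03),
               tolerance = 0.03)
})

test_that("intensity-zone diffusion: degenerate cases and rank recovery", {
  p <- sim_params(n_frames = 150, particle_density_out = 0.2, seed = 107)
  s <- simulate_tracks(p, fx_mask)
  # constant intensity: no distinct quantiles to bin by
  expect_error(zone_diffusion(s$tracks, matrix(7, 128, 128), fx_mask),
               "quantiles")
  # n_zones = 1 equals the plain inside-contact fit
  z1 <- zone_diffusion(s$tracks, fx_spacer$image, fx_mask, n_zones = 1,
                       n_bootstrap = 0)
  f_in <- fit_jd_cumulative(jump_distances(s$tracks, fx_mask, "inside"),
                            sigma = 0.03, n_bootstrap = 0)
  expect_equal(z1$zones$D[1], f_in$D, tolerance = 1e-10)
  # D decreasing with spacer intensity: fitted zone Ds in rank order
  rng <- range(fx_spacer$image[fx_mask$mask])
  dfun <- function(int)
    pmax(0.05, 0.6 - 0.5 * pmin(1, pmax(0, (int - rng[1]) / diff(rng))))
  p2 <- sim_params(d_in = dfun, n_frames = 300,
                   particle_density_out = 0.25, seed = 109)
  s2 <- simulate_tracks(p2, fx_mask, spacer_image = fx_spacer$image,
                        start_region = "inside")
  z4 <- zone_diffusion(s2$tracks, fx_spacer$image, fx_mask, n_zones = 4,
                       n_bootstrap = 0)
  expect_true(all(z4$zones$fitted))
  expect_true(all(diff(z4$zones$D) < 0))
})

test_that("retention matches a brute-force counting oracle exactly", {
  all_in <- rbind(make_track(1, rep(8, 7), rep(9, 7)),
                  make_track(2, rep(9, 7), rep(8, 7)))
  expect_equal(retention_fraction(all_in, fx_mask)$fraction, 1.0)
  one_exit <- rbind(make_track(1, rep(8, 7), rep(9, 7)),
                    make_track(2, seq(9, 18, length.out = 7), rep(9, 7)))
  expect_equal(retention_fraction(one_exit, fx_mask)$fraction, 0.5)
  # no inside-starting tracks: flagged undefined
  out_only <- make_track(1, rep(19, 7), rep(19, 7))
  expect_true(retention_fraction(out_only, fx_mask)$undefined)
  # oracle equivalence on simulated trajectories
  p <- sim_params(n_frames = 120, particle_density_out = 0.08, seed = 113)
  s <- simulate_tracks(p, fx_mask)
  got <- retention_fraction(s$tracks, fx_mask)
  want <- retention_oracle(s$tracks, fx_mask)
  expect_identical(got$fraction, want$fraction)
  expect_identical(got$n_inside_start, want$n_inside_start)
})
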