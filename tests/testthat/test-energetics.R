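test_that("track categories follow first/last side with a deflected refinement", {
  sq <- fx_square  # [2, 12] x [2, 12] um
  tracks <- rbind(
    make_track(1, xs = seq(0.5, 5, length.out = 8), ys = rep(5, 8)),   # enter
    make_track(2, xs = rep(18, 8), ys = rep(18, 8)),           # outside stay
    make_track(3, xs = c(0.5, 1.2, 1.9, 1.2, 0.8, 0.6, 0.5, 0.5),
               ys = rep(5, 8)),                                 # deflected
    make_track(4, xs = seq(5, 0.5, length.out = 8), ys = rep(5, 8)),   # exit
    make_track(5, xs = rep(6, 8), ys = rep(6, 8)))             # inside stay
  cat5 <- categorize_tracks(tracks, sq, touch_band = 0.16)
  expect_equal(cat5$category,
               c("enter", "outside_stay", "outside_stay", "exit",
                 "inside_stay"))
  expect_equal(cat5$deflected, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # categories partition retained tracks
  expect_equal(nrow(cat5), 5)
  # categories on simulated data partition and match a brute-force oracle
  p <- sim_params(n_frames = 80, particle_density_out = 0.1, seed = 47)
  s <- simulate_tracks(p, fx_mask)
  cats <- categorize_tracks(s$tracks, fx_mask)
  oracle <- vapply(split(s$tracks, s$tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    a <- mask_contains(fx_mask, tr$x_um[1], tr$y_um[1])
    b <- mask_contains(fx_mask, tr$x_um[nrow(tr)], tr$y_um[nrow(tr)])
    if (a && b) "inside_stay" else if (a) "exit"
    else if (b) "enter" else "outside_stay"
  }, "")
  expect_equal(cats$category, unname(oracle))
})

test_that("crossing tallies count one attempt per boundary approach", {
  sq <- fx_square
  # clean single crossing: 1 entry attempt, 1 success
  t1 <- make_track(1, xs = c(1.0, 1.9, 2.8, 3.4, 4.0, 4.6, 5.0, 5.2),
                   ys = rep(7, 8))
  tal <- tally_crossings(t1, sq, touch_band = 0.16)
  expect_equal(tal$n_attempts_enter, 1)
  expect_equal(tal$n_success_enter, 1)
  expect_equal(tal$n_attempts_exit, 0)
  # touches the band twice, retreats both times: 2 attempts, 0 successes
  t2 <- make_track(2, xs = c(1.0, 1.9, 1.0, 0.9, 1.9, 1.0, 0.8, 0.7, 0.6),
                   ys = rep(7, 9))
  tal2 <- tally_crossings(t2, sq, touch_band = 0.16)
  expect_equal(tal2$n_attempts_enter, 2)
  expect_equal(tal2$n_success_enter, 0)
  # hovering within the band across consecutive frames is one attempt
  t3 <- make_track(3, xs = c(1.0, 1.95, 1.93, 1.94, 1.92, 1.0, 0.8, 0.7),
                   ys = rep(7, 8))
  expect_equal(tally_crossings(t3, sq)$n_attempts_enter, 1)
  # fewer than five frames recorded after first touch: excluded entirely
  t4 <- make_track(4, xs = c(1.0, 1.9, 2.8, 3.4), ys = rep(7, 4))
  tal4 <- tally_crossings(t4, sq)
  expect_equal(tal4$n_attempts_enter + tal4$n_attempts_exit, 0)
  # successes never exceed attempts on simulated data
  p <- sim_params(n_frames = 100, particle_density_out = 0.1, seed = 53)
  s <- simulate_tracks(p, fx_mask)
  tal5 <- tally_crossings(s$tracks, fx_mask)
  expect_lte(tal5$n_success_enter, tal5$n_attempts_enter)
  expect_lte(tal5$n_success_exit, tal5$n_attempts_exit)
})

test_that("Boltzmann conversion and confidence intervals", {
  mk <- function(se, ae, sx, ax) {
    structure(list(n_attempts_enter = ae, n_success_enter = se,
                   n_attempts_exit = ax, n_success_exit = sx,
                   p_enter = se / ae, p_exit = sx / ax,
                   episodes = NULL, settings = list()),
              class = "crossing_tally")
  }
  e <- energy_penalty(mk(100, 100, 25, 100))
  expect_equal(e$enter$eps, 0)
  expect_equal(e$exit$eps, log(4))
  expect_lt(e$exit$ci[1], log(4)); expect_gt(e$exit$ci[2], log(4))
  # zero successes: censored at ln(n_attempts)
  e0 <- energy_penalty(mk(0, 50, 1, 10))
  expect_equal(e0$enter$eps, Inf)
  expect_equal(e0$enter$censored_at, log(50))
  # zero attempts: undefined and flagged
  eu <- energy_penalty(mk(0, 0, 1, 10))
  expect_false(eu$enter$defined)
})

test_that("null baseline is below a 1 kT barrier estimate; annulus control is clean", {
  run_tracks <- function(eps_enter, seed) {
    p <- sim_params(eps_enter = eps_enter, n_frames = 1100,
                    particle_density_out = 0.15, seed = seed)
    simulate_tracks(p, fx_mask)$tracks
  }
  tr0 <- run_tracks(0, 59)
  tr1 <- run_tracks(1, 61)
  t0 <- tally_crossings(tr0, fx_mask)
  t1 <- tally_crossings(tr1, fx_mask)
  e0 <- energy_penalty(t0); e1 <- energy_penalty(t1)
  # the eps = 0 estimate is a small positive episode-definition baseline,
  # strictly below the barrier-run estimate
  expect_gt(e0$enter$eps, 0)
  expect_gt(e1$enter$eps, e0$enter$eps)
  expect_gt(t0$n_attempts_enter, 300)
  # dilated-mask control on barrier-free data: annulus entry penalty is
  # statistically indistinguishable from the mask's own baseline
  ann <- dilate_mask(fx_mask, 8)
  ta <- tally_crossings(tr0, ann)
  ea <- energy_penalty(ta)
  expect_true(ea$enter$ci[1] < e0$enter$ci[2] &&
              e0$enter$ci[1] < ea$enter$ci[2])
})

test_that("breach zones anticorrelate entry success with spacer density", {
  # fewer than 3 segments is an error
  expect_error(breach_zones(make_track(1, 1:8, rep(7, 8)), fx_mask,
                            fx_spacer$image, segment_length = 50),
               "segments")
  # uniform barrier: no correlation signal
  p <- sim_params(n_frames = 500, particle_density_out = 0.15, seed = 67)
  s <- simulate_tracks(p, fx_mask)
  bz0 <- breach_zones(s$tracks, fx_mask, fx_spacer$image, segment_length = 3)
  expect_gt(bz0$p_value, 0.01)
  # entry barrier rising with local spacer intensity: negative rank
  # correlation between per-segment success rate and intensity
  rng <- range(fx_spacer$image[fx_mask$mask])
  efun <- function(int)
    3 * pmax(0, pmin(1, (int - rng[1]) / (rng[2] - rng[1])))
  p2 <- sim_params(eps_enter = efun, n_frames = 900,
                   particle_density_out = 0.2, seed = 71)
  s2 <- simulate_tracks(p2, fx_mask, spacer_image = fx_spacer$image)
  bz <- breach_zones(s2$tracks, fx_mask, fx_spacer$image, segment_length = 3)
  expect_lt(bz$spearman_rho, 0)
})
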