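#' Configuration for the barrier-free null simulation
#'
#' The null model is the control simulation: free Brownian diffusion over
#' a given contact mask with density and diffusion coefficient matched to
#' the data, repeated with independent seeds and pushed through the same
#' estimators as the experiment.
#'
#' @param mask a `contact_mask`.
#' @param D diffusion coefficient, um^2/s.
#' @param density particle density, particles/um^2 of field.
#' @param n_frames,frame_interval acquisition geometry.
#' @param start_region `"inside"`, `"outside"` or `"field"` initial
#'   placement.
#' @param n_repeats number of independent repeats (default 20).
#' @param seeds one seed per repeat (default `seed_base + 1:n_repeats`).
#' @param seed_base base seed used when `seeds` is not given.
#' @param sigma_loc localization noise, um.
#' @param survival_prob per-frame track survival probability.
#' @return list of class `null_config`.
#' @export
null_config <- function(mask, D = 0.6, density = 0.1, n_frames = 1000L,
                        frame_interval = 0.03,
                        start_region = c("inside", "outside", "field"),
                        n_repeats = 20L, seeds = NULL, seed_base = 1L,
                        sigma_loc = 0.03, survival_prob = 0.93) {
  stopifnot(inherits(mask, "contact_mask"), n_repeats >= 1)
  start_region <- match.arg(start_region)
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_repeats)
  if (length(seeds) != n_repeats) stop("one seed per repeat is required")
  structure(list(mask = mask, D = D, density = density,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 start_region = start_region,
                 n_repeats = as.integer(n_repeats), seeds = as.integer(seeds),
                 sigma_loc = sigma_loc, survival_prob = survival_prob),
            class = "null_config")
}

#' Run the barrier-free null simulation
#'
#' Delegates to [simulate_tracks()] with `eps_enter = eps_exit = 0` and
#' uniform `D`, once per repeat. Tracks are rebuilt from the reported
#' (noisy) localizations with the same linking and length filters applied
#' to real data, so estimator bias cancels in the comparison; then the
#' crossing tally, energy penalties and retention are computed per repeat.
#'
#' @param config a [null_config()].
#' @param touch_band,min_frames_after estimator settings (must match the
#'   experiment side of any later comparison).
#' @param max_jump linking radius, um.
#' @param relink rebuild tracks from pooled localizations with
#'   [link_tracks()] (default `TRUE`).
#' @return list of class `null_result`: `per_repeat` data.frame
#'   (`repeat_id, seed, eps_enter, eps_exit, retention, n_attempts_enter,
#'   n_attempts_exit, n_tracks`), `tracks` (list per repeat), `config`,
#'   `settings`.
#' @export
run_null <- function(config, touch_band = 0.16, min_frames_after = 5L,
                     max_jump = 0.8, relink = TRUE) {
  stopifnot(inherits(config, "null_config"))
  ps <- config$mask$pixel_size
  fs <- c(ncol(config$mask$mask), nrow(config$mask$mask))
  reps <- lapply(seq_len(config$n_repeats), function(i) {
    params <- sim_params(field_size = fs, pixel_size = ps,
                         frame_interval = config$frame_interval,
                         n_frames = config$n_frames,
                         d_out = config$D, d_in = config$D,
                         eps_enter = 0, eps_exit = 0,
                         sigma_loc = config$sigma_loc,
                         particle_density_out = config$density,
                         survival_prob = config$survival_prob,
                         seed = config$seeds[i])
    sim <- simulate_tracks(params, config$mask,
                           start_region = config$start_region)
    tracks <- if (relink) {
      locs <- sim$tracks[c("frame", "x_um", "y_um", "intensity")]
      link_tracks(locs, max_jump = max_jump)
    } else sim$tracks
    tal <- tally_crossings(tracks, config$mask, touch_band, min_frames_after)
    ep <- energy_penalty(tal)
    ret <- retention_fraction(tracks, config$mask)
    list(tracks = tracks, tally = tal, eps = ep, retention = ret)
  })
  per <- do.call(rbind, lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    data.frame(repeat_id = i, seed = config$seeds[i],
               eps_enter = r$eps$enter$eps, eps_exit = r$eps$exit$eps,
               retention = r$retention$fraction,
               n_attempts_enter = r$tally$n_attempts_enter,
               n_attempts_exit = r$tally$n_attempts_exit,
               n_tracks = length(unique(r$tracks$track_id)))
  }))
  structure(list(per_repeat = per,
                 tracks = lapply(reps, `[[`, "tracks"),
                 config = config,
                 settings = list(touch_band = touch_band,
                                 min_frames_after = as.integer(min_frames_after),
                                 max_jump = max_jump, relink = relink)),
            class = "null_result")
}

#' Compare experimental statistics with the null envelope
#'
#' Tabulates differences between an experiment's estimates (eps_enter,
#' eps_exit, retention) and the null repeats, flagging quantities that
#' fall outside the null's central 95% repeat envelope. Refuses to
#' compare results produced with different estimator settings.
#'
#' @param experiment_stats list with `eps_enter`, `eps_exit`, `retention`
#'   (scalars; `NA` allowed) and `settings` (as in `null_result$settings`).
#' @param null_result a `null_result`.
#' @param envelope central envelope coverage (default 0.95).
#' @return data.frame with one row per statistic: experiment value, null
#'   mean/sd, envelope bounds, difference and `flagged`.
#' @export
compare_to_null <- function(experiment_stats, null_result, envelope = 0.95) {
  stopifnot(inherits(null_result, "null_result"))
  es <- experiment_stats$settings
  ns <- null_result$settings
  key <- c("touch_band", "min_frames_after", "max_jump")
  if (is.null(es) || !isTRUE(all.equal(es[key], ns[key])))
    stop("estimator settings differ between experiment and null; ",
         "refusing apples-to-oranges comparison")
  a <- (1 - envelope) / 2
  per <- null_result$per_repeat
  one <- function(name, value) {
    nv <- per[[name]]
    nv <- nv[is.finite(nv)]
    qs <- if (length(nv) > 0) stats::quantile(nv, c(a, 1 - a)) else
      c(NA_real_, NA_real_)
    data.frame(statistic = name, experiment = value,
               null_mean = mean(nv), null_sd = stats::sd(nv),
               null_lo = unname(qs[1]), null_hi = unname(qs[2]),
               difference = value - mean(nv),
               flagged = is.finite(value) &&
                 (value < qs[1] || value > qs[2]))
  }
  out <- rbind(one("eps_enter", experiment_stats$eps_enter),
               one("eps_exit", experiment_stats$eps_exit),
               one("retention", experiment_stats$retention))
  rownames(out) <- NULL
  out
}
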