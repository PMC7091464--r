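#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Standard one-way analysis of variance across condition groups (for
#' example per-cell relative densities or energy penalties grouped by gap
#' size), followed by Tukey honest-significant-difference pairwise
#' comparisons; with unequal group sizes this is the Tukey-Kramer
#' procedure.
#'
#' @param groups either a named list of numeric vectors or a data.frame
#'   with columns `value` and `group`. At least two groups with at least
#'   two observations each.
#' @param alpha significance level (default 0.05).
#' @return list of class `anova_tukey`: `F`, `p_value`, `df`, `tukey`
#'   (pairwise table: diff, lwr, upr, p_adj), `degenerate` (`TRUE` with
#'   `F = NA` when the within-group variance is zero).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    df <- data.frame(value = groups$value, group = factor(groups$group))
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(names(groups),
                                        vapply(groups, length, 1L))))
  }
  cnt <- table(df$group)
  if (length(cnt) < 2 || any(cnt < 2))
    stop("need >= 2 groups with >= 2 observations each")
  if (!all(is.finite(df$value))) stop("non-finite values in groups")
  ss_within <- sum(tapply(df$value, df$group,
                          function(v) sum((v - mean(v))^2)))
  if (ss_within == 0)
    return(structure(list(F = NA_real_, p_value = NA_real_,
                          df = c(length(cnt) - 1L, nrow(df) - length(cnt)),
                          tukey = NULL, degenerate = TRUE, alpha = alpha),
                     class = "anova_tukey"))
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  structure(list(F = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
                 df = s[["Df"]],
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                    row.names = NULL),
                 degenerate = FALSE, alpha = alpha),
            class = "anova_tukey")
}

#' Pipeline configuration
#'
#' All module parameters with defaults, serializable to YAML. Unknown keys
#' are rejected so typos fail loudly.
#'
#' @param ... overrides of the default parameters; see
#'   `names(pipeline_config())`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    field_size = c(128L, 128L), pixel_size = 0.16,
    frame_interval = 0.03, n_frames = 1000L,
    d_out = 0.6, d_in = 0.6, eps_enter = 0, eps_exit = 0,
    sigma_loc = 0.03, particle_density_out = 0.1, survival_prob = 0.93,
    contact_radius_um = 6,
    background = 100, contrast = 100, heterogeneity_amplitude = 0.25,
    heterogeneity_sigma_px = 4, image_noise_sd = 2,
    gradient_threshold_fraction = 0.2, min_object_area = 0.5,
    smoothing_sigma = 1, dilation_width = 6L,
    max_jump = 0.8, max_gap = 0L, min_track_length = 6L,
    touch_band = 0.16, min_frames_after = 5L,
    fit_sigma = 0.03, n_bootstrap = 200L, min_jumps = 50L, n_zones = 4L,
    null_repeats = 20L,
    input_tracks_csv = NULL, output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulate-mode end-to-end run: generates a spacer image and probe
#' tracks from the configuration, derives the contact mask from the image,
#' rebuilds tracks from localizations, then computes exclusion,
#' energy penalties, diffusion fits, the JD map, intensity-zone diffusion,
#' retention and the barrier-free null comparison. Results and provenance
#' are written to `output_dir` when given; each stage failure is logged
#' and already-computed results are preserved.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress to stderr.
#' @return list of class `pipeline_result` with one element per stage plus
#'   `errors` (named list of stage failures) and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input_tracks_csv) && !file.exists(config$input_tracks_csv))
    stop("input tracks file not found: ", config$input_tracks_csv)
  res <- list(errors = list())
  say <- function(...) if (verbose) message("[nanogap] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      say(name, " FAILED: ", conditionMessage(e))
      NULL
    })
  }
  params <- sim_params(field_size = config$field_size,
                       pixel_size = config$pixel_size,
                       frame_interval = config$frame_interval,
                       n_frames = config$n_frames,
                       d_out = config$d_out, d_in = config$d_in,
                       eps_enter = config$eps_enter,
                       eps_exit = config$eps_exit,
                       sigma_loc = config$sigma_loc,
                       particle_density_out = config$particle_density_out,
                       survival_prob = config$survival_prob,
                       seed = config$seed)
  spacer <- stage("simulate_image", generate_spacer_image(
    params,
    contact_shape = list(type = "disk",
                         center_um = config$field_size * config$pixel_size / 2,
                         radius_um = config$contact_radius_um),
    background = config$background, contrast = config$contrast,
    heterogeneity_amplitude = config$heterogeneity_amplitude,
    heterogeneity_sigma_px = config$heterogeneity_sigma_px,
    noise_sd = config$image_noise_sd))
  if (is.null(spacer)) stop("cannot continue without a spacer image")
  res$spacer <- spacer
  mask <- stage("mask", contact_mask(
    spacer$image,
    mask_params(config$gradient_threshold_fraction, config$min_object_area,
                config$smoothing_sigma, config$dilation_width),
    pixel_size = config$pixel_size))
  if (is.null(mask) || !isTRUE(mask$provenance$found)) mask <- spacer$mask
  res$mask <- mask
  sim <- stage("simulate_tracks",
               simulate_tracks(params, spacer$mask, seed = config$seed + 1L))
  if (is.null(sim)) stop("cannot continue without tracks")
  res$sim <- sim
  res$tracks <- stage("link", link_tracks(
    sim$tracks[c("frame", "x_um", "y_um", "intensity")],
    max_jump = config$max_jump, max_gap = config$max_gap,
    min_length = config$min_track_length))
  res$qc <- stage("qc", track_qc(res$tracks))
  first <- sim$tracks[sim$tracks$frame == 1L, ]
  res$exclusion <- stage("exclusion", relative_density(first, mask))
  res$tally <- stage("energetics", tally_crossings(
    res$tracks, mask, config$touch_band, config$min_frames_after))
  if (!is.null(res$tally)) res$eps <- energy_penalty(res$tally)
  res$fit_outside <- stage("fit_outside", fit_jd_cumulative(
    jump_distances(res$tracks, mask, "outside", config$frame_interval),
    sigma = config$fit_sigma, n_bootstrap = config$n_bootstrap,
    min_jumps = config$min_jumps))
  res$fit_inside <- stage("fit_inside", fit_jd_cumulative(
    jump_distances(res$tracks, mask, "inside", config$frame_interval),
    sigma = config$fit_sigma, n_bootstrap = config$n_bootstrap,
    min_jumps = config$min_jumps))
  res$jd_map <- stage("jd_map", jd_map(
    res$tracks, dim(mask$mask), config$pixel_size, config$frame_interval))
  res$zones <- stage("zones", zone_diffusion(
    res$tracks, spacer$image, mask, config$n_zones, config$fit_sigma,
    config$frame_interval, config$n_bootstrap, config$min_jumps))
  res$retention <- stage("retention", retention_fraction(res$tracks, mask))
  res$null <- stage("null", run_null(
    null_config(mask, D = config$d_out, density = config$particle_density_out,
                n_frames = config$n_frames,
                frame_interval = config$frame_interval,
                start_region = "field", n_repeats = config$null_repeats,
                seed_base = config$seed + 1000L,
                sigma_loc = config$sigma_loc,
                survival_prob = config$survival_prob),
    touch_band = config$touch_band,
    min_frames_after = config$min_frames_after,
    max_jump = config$max_jump))
  if (!is.null(res$null) && !is.null(res$eps) && !is.null(res$retention)) {
    res$null_comparison <- stage("compare", compare_to_null(
      list(eps_enter = res$eps$enter$eps, eps_exit = res$eps$exit$eps,
           retention = res$retention$fraction,
           settings = res$null$settings),
      res$null))
  }
  res$provenance <- list(config = unclass(config),
                         package_version = as.character(
                           utils::packageVersion("nanogap")),
                         r_version = R.version.string,
                         timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(config$output_dir))
    stage("write", write_pipeline_result(res, config))
  structure(res, class = "pipeline_result")
}

write_pipeline_result <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  write_config(config, out("config.yaml"))
  res$provenance$config_md5 <- unname(tools::md5sum(out("config.yaml")))
  if (!is.null(res$tracks))
    utils::write.csv(res$tracks, out("tracks.csv"), row.names = FALSE)
  if (!is.null(res$mask)) write_mask(res$mask, out("mask.tif"))
  if (!is.null(res$jd_map)) write_jd_map(res$jd_map, out("jd_map"))
  if (!is.null(res$null))
    utils::write.csv(res$null$per_repeat, out("null_repeats.csv"),
                     row.names = FALSE)
  summary <- list(
    exclusion = if (!is.null(res$exclusion)) unclass(res$exclusion),
    eps_enter = if (!is.null(res$eps)) res$eps$enter[c("eps", "ci")],
    eps_exit = if (!is.null(res$eps)) res$eps$exit[c("eps", "ci")],
    D_outside = if (!is.null(res$fit_outside)) res$fit_outside$D,
    D_inside = if (!is.null(res$fit_inside)) res$fit_inside$D,
    retention = if (!is.null(res$retention)) res$retention$fraction,
    qc = if (!is.null(res$qc)) as.list(res$qc),
    errors = res$errors,
    provenance = res$provenance)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(config$output_dir)
}
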