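#' Extract jump distances from tracks
#'
#' Euclidean displacements between consecutive-frame localizations (frame
#' gap exactly 1; gap-spanning pairs are excluded). A jump's region is the
#' region of its starting localization.
#'
#' @param tracks data.frame `track_id, frame, x_um, y_um`.
#' @param mask optional `contact_mask` used to label jump regions.
#' @param region keep `"all"` jumps or only those starting `"inside"` /
#'   `"outside"` the mask.
#' @param frame_interval lag time between frames, s.
#' @return list of class `jd_set`: `r` (um), `dt` (s), `region` label per
#'   jump, `track_id`, `x_um, y_um` (jump start) and `n`.
#' @export
jump_distances <- function(tracks, mask = NULL,
                           region = c("all", "inside", "outside"),
                           frame_interval = 0.03) {
  region <- match.arg(region)
  tr <- tracks[order(tracks$track_id, tracks$frame), ]
  same <- diff(tr$track_id) == 0L & diff(tr$frame) == 1L
  i0 <- which(c(same, FALSE))
  r <- sqrt((tr$x_um[i0 + 1L] - tr$x_um[i0])^2 +
            (tr$y_um[i0 + 1L] - tr$y_um[i0])^2)
  reg <- if (!is.null(mask))
    ifelse(mask_contains(mask, tr$x_um[i0], tr$y_um[i0]), "inside", "outside")
  else rep(NA_character_, length(r))
  keep <- if (region == "all") rep(TRUE, length(r)) else reg == region
  structure(list(r = r[keep], dt = frame_interval, region = reg[keep],
                 track_id = tr$track_id[i0][keep],
                 x_um = tr$x_um[i0][keep], y_um = tr$y_um[i0][keep],
                 n = sum(keep)),
            class = "jd_set")
}

#' Fit a diffusion coefficient from the cumulative jump-distance
#' distribution
#'
#' Fits the empirical cumulative distribution of squared jump distances to
#' `P(r^2, dt) = 1 - exp(-r^2 / r0^2)` with `r0^2 = 4 D dt + 4 sigma^2` by
#' nonlinear least squares, where `sigma` is the localization precision.
#' `sigma` is supplied, not co-fitted: with a single lag, `D` and `sigma`
#' are not jointly identifiable. Errors come from bootstrap resampling of
#' the jumps with replacement.
#'
#' @param jd a `jd_set` or a numeric vector of jump distances (um).
#' @param sigma localization precision, um (default 0.03).
#' @param frame_interval lag, s (taken from the `jd_set` if given).
#' @param n_bootstrap bootstrap iterations (default 1000).
#' @param min_jumps minimum jump count required (default 50).
#' @param conf_level bootstrap CI level.
#' @return list of class `jd_fit`: `r0_sq` (um^2), `D` (um^2/s, floored at
#'   0), `sigma`, `dt`, `n_jumps`, `ci_r0_sq`, `ci_D` (percentile
#'   bootstrap), `converged`.
#' @export
fit_jd_cumulative <- function(jd, sigma = 0.03, frame_interval = 0.03,
                              n_bootstrap = 1000L, min_jumps = 50L,
                              conf_level = 0.95) {
  r <- if (inherits(jd, "jd_set")) jd$r else jd
  dt <- if (inherits(jd, "jd_set")) jd$dt else frame_interval
  if (length(r) < min_jumps)
    stop("need at least ", min_jumps, " jumps (got ", length(r), ")")
  r2 <- r^2
  fit1 <- function(r2) {
    s <- sort(r2)
    p <- (seq_along(s) - 0.5) / length(s)
    mu <- mean(s)
    obj <- function(r0sq) sum((p - (1 - exp(-s / r0sq)))^2)
    stats::optimize(obj, interval = c(mu / 50, mu * 50))$minimum
  }
  r0sq <- fit1(r2)
  a <- (1 - conf_level) / 2
  ci_r0 <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    bs <- vapply(seq_len(n_bootstrap), function(i)
      fit1(sample(r2, replace = TRUE)), numeric(1))
    ci_r0 <- unname(stats::quantile(bs, c(a, 1 - a)))
  }
  to_D <- function(x) pmax(0, (x - 4 * sigma^2) / (4 * dt))
  structure(list(r0_sq = r0sq, D = to_D(r0sq), sigma = sigma, dt = dt,
                 n_jumps = length(r2), ci_r0_sq = ci_r0, ci_D = to_D(ci_r0),
                 conf_level = conf_level, converged = TRUE),
            class = "jd_fit")
}

#' @export
print.jd_fit <- function(x, ...) {
  cat(sprintf("<jd_fit> D = %.4f um^2/s [%.4f, %.4f], r0^2 = %.5f um^2, n = %d\n",
              x$D, x$ci_D[1], x$ci_D[2], x$r0_sq, x$n_jumps))
  invisible(x)
}

#' Per-pixel jump-distance map
#'
#' Overlays the track ensemble with the acquisition pixel grid: each jump
#' is assigned to the pixel containing its starting localization and the
#' per-pixel mean jump distance and jump count are returned. Pixels with
#' no jumps carry `NA`, never 0.
#'
#' @param tracks data.frame of tracks.
#' @param dim field size `c(nrow, ncol)` in pixels.
#' @param pixel_size um/px.
#' @param frame_interval s; mean speed map = mean JD / frame_interval.
#' @return list of class `jd_map`: `mean_jd` (um), `count`, `mean_speed`
#'   (um/s), `pixel_size`.
#' @export
jd_map <- function(tracks, dim, pixel_size = 0.16, frame_interval = 0.03) {
  jd <- jump_distances(tracks, frame_interval = frame_interval)
  px <- point_to_pixel(jd$x_um, jd$y_um, dim, pixel_size)
  ok <- !is.na(px$row)
  lin <- (px$col[ok] - 1L) * dim[1] + px$row[ok]
  cnt <- matrix(tabulate(lin, nbins = dim[1] * dim[2]), dim[1], dim[2])
  tot <- matrix(0, dim[1], dim[2])
  if (length(lin) > 0) {
    agg <- rowsum(jd$r[ok], lin)
    tot[as.integer(rownames(agg))] <- agg[, 1]
  }
  mean_jd <- ifelse(cnt > 0, tot / cnt, NA_real_)
  structure(list(mean_jd = mean_jd, count = cnt,
                 mean_speed = mean_jd / frame_interval,
                 pixel_size = pixel_size),
            class = "jd_map")
}

#' Write a JD map as 32-bit float TIFFs
#'
#' @param map a `jd_map`.
#' @param path_prefix output prefix; writes `<prefix>_mean.tif` and
#'   `<prefix>_count.tif`.
#' @export
write_jd_map <- function(map, path_prefix) {
  m <- map$mean_jd; m[is.na(m)] <- 0
  tiff::writeTIFF(m / max(m, 1e-12), paste0(path_prefix, "_mean.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(map$count / max(map$count, 1L),
                  paste0(path_prefix, "_count.tif"), bits.per.sample = 32L)
  invisible(path_prefix)
}

#' Diffusion across spacer-intensity zones of the contact
#'
#' Bins contact pixels into `n_zones` equal-count (quantile) bins of
#' spacer intensity, assigns each jump starting inside the contact to the
#' zone of its starting pixel, and fits the cumulative jump-distance
#' distribution per zone. Higher intensity corresponds to higher local
#' spacer-protein density.
#'
#' @param tracks data.frame of tracks.
#' @param spacer_image spacer-channel matrix.
#' @param mask a `contact_mask`.
#' @param n_zones number of intensity zones (default 4).
#' @param sigma,frame_interval,n_bootstrap,min_jumps passed to
#'   [fit_jd_cumulative()].
#' @return list of class `zone_diffusion`: data.frame `zones`
#'   (`zone, mean_intensity, n_jumps, D, ci_lo, ci_hi, fitted`) and the
#'   per-zone `fits` list (`NULL` where a zone is below the jump floor).
#' @export
zone_diffusion <- function(tracks, spacer_image, mask, n_zones = 4L,
                           sigma = 0.03, frame_interval = 0.03,
                           n_bootstrap = 200L, min_jumps = 50L) {
  stopifnot(inherits(mask, "contact_mask"))
  ints <- spacer_image[mask$mask]
  qs <- stats::quantile(ints, probs = seq(0, 1, length.out = n_zones + 1L))
  if (length(unique(qs)) < n_zones + 1L)
    stop("contact does not contain ", n_zones, " distinct intensity quantiles")
  zone_img <- matrix(NA_integer_, nrow(spacer_image), ncol(spacer_image))
  zone_img[mask$mask] <- pmin(
    findInterval(ints, qs, rightmost.closed = TRUE), n_zones)
  jd <- jump_distances(tracks, mask, region = "inside",
                       frame_interval = frame_interval)
  px <- point_to_pixel(jd$x_um, jd$y_um, dim(mask$mask), mask$pixel_size)
  zone_of_jump <- zone_img[cbind(px$row, px$col)]
  fits <- vector("list", n_zones)
  rows <- lapply(seq_len(n_zones), function(z) {
    rz <- jd$r[which(zone_of_jump == z)]
    mi <- mean(ints[zone_img[mask$mask] == z])
    if (length(rz) >= min_jumps) {
      f <- fit_jd_cumulative(rz, sigma = sigma, frame_interval = frame_interval,
                             n_bootstrap = n_bootstrap, min_jumps = min_jumps)
      fits[[z]] <<- f
      data.frame(zone = z, mean_intensity = mi, n_jumps = length(rz),
                 D = f$D, ci_lo = f$ci_D[1], ci_hi = f$ci_D[2], fitted = TRUE)
    } else {
      data.frame(zone = z, mean_intensity = mi, n_jumps = length(rz),
                 D = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 fitted = FALSE)
    }
  })
  structure(list(zones = do.call(rbind, rows), fits = fits,
                 n_zones = n_zones),
            class = "zone_diffusion")
}

#' Fraction of inside-starting tracks retained in the contact
#'
#' The retention fraction is the share of tracks starting inside the
#' contact whose every localization stays inside for the whole observed
#' track.
#'
#' @param tracks data.frame of tracks.
#' @param mask a `contact_mask`.
#' @return list of class `retention`: `fraction`, `n_inside_start`,
#'   `n_retained`, `undefined` (no inside-starting tracks).
#' @export
retention_fraction <- function(tracks, mask) {
  stopifnot(inherits(mask, "contact_mask"))
  per <- vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    inside <- mask_contains(mask, tr$x_um, tr$y_um)
    if (!inside[1]) return(NA)      # not inside-starting
    all(inside)
  }, logical(1))
  starts_in <- !is.na(per)
  n0 <- sum(starts_in)
  structure(list(fraction = if (n0 > 0) sum(per[starts_in]) / n0 else NA_real_,
                 n_inside_start = n0,
                 n_retained = sum(per[starts_in]),
                 undefined = n0 == 0),
            class = "retention")
}
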