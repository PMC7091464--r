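#' Categorize tracks relative to the contact
#'
#' Each retained track is assigned one of four mutually exclusive
#' categories from the side (inside/outside the contact mask) of its first
#' and last localization: `outside_stay`, `enter` (starts outside, ends
#' inside), `inside_stay`, `exit` (starts inside, ends outside).
#' `deflected` refines `outside_stay`: the track starts outside, has at
#' least one localization within `touch_band` of the contact border, and
#' ends outside.
#'
#' @param tracks data.frame `track_id, frame, x_um, y_um`.
#' @param mask a `contact_mask`.
#' @param touch_band half-width of the border touch band, um (default one
#'   pixel, 0.16 um).
#' @return data.frame `track_id, category, deflected, ambiguous`
#'   (`ambiguous` flags tracks whose every localization sits in the touch
#'   band; they are assigned by their first-localization side).
#' @export
categorize_tracks <- function(tracks, mask, touch_band = 0.16) {
  stopifnot(inherits(mask, "contact_mask"))
  sdf <- mask_signed_distance(mask)
  per <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    inside <- mask_contains(mask, tr$x_um, tr$y_um)
    band <- abs(mask_edge_distance(mask, tr$x_um, tr$y_um, sdf)) <= touch_band
    first_in <- inside[1]; last_in <- inside[length(inside)]
    cat <- if (first_in && last_in) "inside_stay"
      else if (first_in && !last_in) "exit"
      else if (!first_in && last_in) "enter"
      else "outside_stay"
    data.frame(track_id = tr$track_id[1], category = cat,
               deflected = cat == "outside_stay" && any(band),
               ambiguous = all(band))
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Tally boundary-crossing attempts and successes
#'
#' An attempt is one boundary-approach episode: it opens when a track
#' arrives within `touch_band` of the contact border (one attempt per band
#' visit), and its outcome is read one frame later — success if the track
#' is then confidently on the opposite side, failure otherwise. A particle
#' hovering at the boundary over consecutive frames is one attempt, not
#' one per frame: a spent episode does not re-open until the track has
#' left the band and approached again. The single-frame outcome window
#' and the fresh-approach arming rule make the Boltzmann estimator
#' consistent: the probability that the opening step actually proposes a
#' boundary crossing is a geometric quantity independent of the barrier,
#' so it cancels against the barrier-free null baseline.
#'
#' Side assignment is robust to localization noise: the signed distance to
#' the boundary is interpolated continuously, a localization within
#' `side_margin` of the boundary is ambiguous and inherits the last
#' confident side, so single-frame apparent flips caused by noise are not
#' scored as crossings.
#'
#' An episode still unresolved at the track end is dropped, and, to avoid
#' bias toward unsuccessful crossings, tracks with fewer than
#' `min_frames_after` localizations recorded after first touching the
#' border are excluded entirely.
#'
#' @param tracks data.frame `track_id, frame, x_um, y_um` (length-filtered
#'   tracks).
#' @param mask a `contact_mask` (or annulus control mask).
#' @param touch_band touch-band half-width, um.
#' @param min_frames_after minimum recorded localizations after the first
#'   border touch (default 5).
#' @param side_margin half-width of the ambiguous zone around the boundary
#'   for side assignment, um (default 0.09, about three times the typical
#'   localization precision).
#' @return list of class `crossing_tally`: attempt/success counts and
#'   crossing probabilities per direction (`enter` = approach from
#'   outside, `exit` = approach from inside), the per-episode table
#'   (`track_id, direction, success, x_um, y_um`) and the settings used.
#' @export
tally_crossings <- function(tracks, mask, touch_band = 0.16,
                            min_frames_after = 5L, side_margin = 0.09) {
  stopifnot(inherits(mask, "contact_mask"), touch_band >= 0, side_margin >= 0)
  sdf <- mask_signed_distance(mask)
  episodes <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    d <- mask_edge_distance(mask, tr$x_um, tr$y_um, sdf)
    band <- abs(d) <= touch_band
    if (!any(band)) return(NULL)
    first_touch <- which(band)[1]
    if (n - first_touch < min_frames_after) return(NULL)  # excluded track
    # confident side: inside where d < -margin, outside where d > margin;
    # ambiguous localizations inherit the last confident side
    side <- rep(NA, n)
    conf <- abs(d) > side_margin
    side[conf] <- d[conf] < 0
    if (is.na(side[1])) side[1] <- d[1] < 0
    for (i in seq_len(n)[-1]) if (is.na(side[i])) side[i] <- side[i - 1L]
    dirs <- character(0); succ <- logical(0); ex <- numeric(0); ey <- numeric(0)
    # a track born in the band arms only if its first side is confident
    armed <- band[1] && conf[1]; arm_side <- side[1]; arm_idx <- 1L
    for (i in seq_len(n)[-1]) {
      if (armed) {
        ok <- side[i] != arm_side
        dirs <- c(dirs, if (arm_side) "exit" else "enter")
        succ <- c(succ, ok)
        ex <- c(ex, tr$x_um[arm_idx]); ey <- c(ey, tr$y_um[arm_idx])
        armed <- FALSE
      } else if (band[i] && !band[i - 1L]) {
        # fresh approach to the border: one attempt per band visit
        armed <- TRUE; arm_side <- side[i]; arm_idx <- i
      }
    }
    # an episode still armed at track end is unresolved and dropped
    if (length(dirs) == 0) return(NULL)
    data.frame(track_id = tr$track_id[1], direction = dirs, success = succ,
               x_um = ex, y_um = ey)
  })
  ep <- do.call(rbind, episodes)
  if (is.null(ep))
    ep <- data.frame(track_id = integer(0), direction = character(0),
                     success = logical(0), x_um = numeric(0),
                     y_um = numeric(0))
  rownames(ep) <- NULL
  n_att_en <- sum(ep$direction == "enter")
  n_suc_en <- sum(ep$direction == "enter" & ep$success)
  n_att_ex <- sum(ep$direction == "exit")
  n_suc_ex <- sum(ep$direction == "exit" & ep$success)
  structure(list(
    n_attempts_enter = n_att_en, n_success_enter = n_suc_en,
    n_attempts_exit = n_att_ex, n_success_exit = n_suc_ex,
    p_enter = if (n_att_en > 0) n_suc_en / n_att_en else NA_real_,
    p_exit = if (n_att_ex > 0) n_suc_ex / n_att_ex else NA_real_,
    episodes = ep,
    settings = list(touch_band = touch_band,
                    min_frames_after = as.integer(min_frames_after),
                    side_margin = side_margin)
  ), class = "crossing_tally")
}

#' Boltzmann energy penalties from a crossing tally
#'
#' Converts crossing probabilities to energy penalties via the Boltzmann
#' relation `p = exp(-eps / kT)`, i.e. `eps = -ln(n_success / n_attempts)`
#' in kT units (kT = 1 by convention). Confidence intervals are propagated
#' from Clopper-Pearson binomial intervals on `p`, treating attempts as
#' independent Bernoulli trials (a stated approximation: attempts by one
#' track are not strictly independent).
#'
#' @param tally a `crossing_tally`.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `energy_penalty` with, per direction, `eps`
#'   (kT), `ci` (lower, upper, in kT), counts, and for zero-success
#'   directions `eps = Inf` with `censored_at = ln(n_attempts)` (the
#'   resolvable lower bound). Directions with zero attempts are `NA` and
#'   flagged.
#' @export
energy_penalty <- function(tally, conf_level = 0.95) {
  stopifnot(inherits(tally, "crossing_tally"))
  one <- function(ns, na) {
    if (na < 1)
      return(list(eps = NA_real_, ci = c(NA_real_, NA_real_),
                  n_success = ns, n_attempts = na, defined = FALSE,
                  censored_at = NA_real_))
    ci_p <- stats::binom.test(ns, na, conf.level = conf_level)$conf.int
    if (ns == 0)
      return(list(eps = Inf, ci = c(-log(ci_p[2]), Inf),
                  n_success = 0L, n_attempts = na, defined = TRUE,
                  censored_at = log(na)))
    list(eps = -log(ns / na),
         ci = c(-log(ci_p[2]), -log(ci_p[1])),  # upper p -> lower eps
         n_success = ns, n_attempts = na, defined = TRUE,
         censored_at = NA_real_)
  }
  structure(list(enter = one(tally$n_success_enter, tally$n_attempts_enter),
                 exit = one(tally$n_success_exit, tally$n_attempts_exit),
                 conf_level = conf_level,
                 settings = tally$settings),
            class = "energy_penalty")
}

#' @export
print.energy_penalty <- function(x, ...) {
  fmt <- function(e, lab)
    cat(sprintf("eps_%s = %.3f kT [%.3f, %.3f] (%d/%d)\n", lab, e$eps,
                e$ci[1], e$ci[2], e$n_success, e$n_attempts))
  fmt(x$enter, "enter"); fmt(x$exit, "exit")
  invisible(x)
}

#' Breach-zone analysis along the contact boundary
#'
#' Splits the contact boundary into segments of roughly `segment_length`,
#' assigns every entry attempt to its nearest segment, and pairs each
#' segment's entry success rate with the local mean spacer intensity.
#' Breach zones are boundary segments where probes cross despite the
#' contact; a negative rank correlation between success rate and intensity
#' indicates that crossing happens preferentially where the spacer density
#' is low.
#'
#' @param tracks data.frame of tracks.
#' @param mask a `contact_mask`.
#' @param spacer_image spacer-channel matrix on the mask grid.
#' @param segment_length target boundary segment length, um (default 1).
#' @param touch_band,min_frames_after passed to [tally_crossings()].
#' @return list of class `breach_zones`: `segments` data.frame
#'   (`segment, n_attempts, n_success, success_rate, mean_intensity`),
#'   `spearman_rho`, `p_value` (over segments with at least one attempt).
#' @export
breach_zones <- function(tracks, mask, spacer_image, segment_length = 1,
                         touch_band = 0.16, min_frames_after = 5L) {
  stopifnot(inherits(mask, "contact_mask"))
  ps <- mask$pixel_size
  bnd <- which(mask$boundary, arr.ind = TRUE)
  if (nrow(bnd) < 3) stop("boundary too small to segment")
  # order boundary pixels by angle around the mask centroid (contacts are
  # approximately star-convex); arc length accumulated along that order
  ctr <- colMeans(which(mask$mask, arr.ind = TRUE))
  ang <- atan2(bnd[, 1] - ctr[1], bnd[, 2] - ctr[2])
  ord <- order(ang)
  bnd <- bnd[ord, , drop = FALSE]
  n_b <- nrow(bnd)
  step <- sqrt(rowSums((bnd - bnd[c(n_b, 1:(n_b - 1)), ])^2)) * ps
  arc <- cumsum(step)
  n_seg <- max(1L, round(max(arc) / segment_length))
  if (n_seg < 3) stop("insufficient segments: boundary shorter than 3 segments")
  seg_of_bpix <- pmin(floor(arc / max(arc) * n_seg) + 1L, n_seg)
  tal <- tally_crossings(tracks, mask, touch_band, min_frames_after)
  ep <- tal$episodes[tal$episodes$direction == "enter", , drop = FALSE]
  bx <- (bnd[, 2] - 0.5) * ps; by <- (bnd[, 1] - 0.5) * ps
  seg_of_ep <- if (nrow(ep) > 0) vapply(seq_len(nrow(ep)), function(i) {
    as.integer(seg_of_bpix[which.min((bx - ep$x_um[i])^2 + (by - ep$y_um[i])^2)])
  }, integer(1)) else integer(0)
  mean_int <- vapply(seq_len(n_seg), function(s)
    mean(spacer_image[bnd[seg_of_bpix == s, , drop = FALSE]]), numeric(1))
  n_att <- tabulate(seg_of_ep, nbins = n_seg)
  n_suc <- tabulate(seg_of_ep[ep$success], nbins = n_seg)
  segs <- data.frame(segment = seq_len(n_seg), n_attempts = n_att,
                     n_success = n_suc,
                     success_rate = ifelse(n_att > 0, n_suc / n_att, NA_real_),
                     mean_intensity = mean_int)
  use <- segs$n_attempts > 0
  ct <- if (sum(use) >= 3)
    suppressWarnings(stats::cor.test(segs$success_rate[use],
                                     segs$mean_intensity[use],
                                     method = "spearman"))
  else NULL
  structure(list(segments = segs,
                 spearman_rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
                 p_value = if (is.null(ct)) NA_real_ else ct$p.value,
                 n_segments_used = sum(use)),
            class = "breach_zones")
}
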