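#' Simulation parameters for the synthetic-data generator
#'
#' Collects the physical and acquisition parameters of the Brownian-dynamics
#' generator. Defaults mirror typical TIRF single-particle acquisitions of
#' quantum dots on a supported lipid bilayer: 1000 frames at 30 ms exposure,
#' free bilayer diffusion around 0.6 um^2/s, and a per-frame track survival
#' probability of 0.93 giving a mean track length of about 14 frames.
#'
#' @param field_size image size in pixels, `c(width, height)`; at least 32.
#' @param pixel_size pixel edge in micrometres (default 0.16 um/px, a typical
#'   100x EMCCD configuration).
#' @param frame_interval frame interval (Delta t) in seconds.
#' @param n_frames number of frames per acquisition.
#' @param d_out diffusion coefficient outside the contact, um^2/s.
#' @param d_in diffusion coefficient inside the contact, um^2/s (scalar), or
#'   a function mapping local spacer intensity to a local D when a spacer
#'   image is supplied to [simulate_tracks()].
#' @param eps_enter,eps_exit boundary energy barriers in kT; a step whose
#'   segment crosses the mask boundary inward is accepted with probability
#'   `exp(-eps_enter)`, outward with `exp(-eps_exit)`. `eps_enter` may also
#'   be a function of local spacer intensity.
#' @param sigma_loc localization noise standard deviation per axis, um.
#' @param particle_density_out particle density, particles/um^2 of field.
#' @param survival_prob per-frame probability that a track continues; track
#'   lengths are geometric with mean `1/(1 - survival_prob)`.
#' @param blink_rates optional `c(off_rate, on_rate)` per-frame two-state
#'   blinking switch; `NULL` (default) disables blinking.
#' @param seed integer seed for the generator's RNG.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(field_size = c(128L, 128L), pixel_size = 0.16,
                       frame_interval = 0.03, n_frames = 1000L,
                       d_out = 0.6, d_in = d_out,
                       eps_enter = 0, eps_exit = 0,
                       sigma_loc = 0.03, particle_density_out = 0.1,
                       survival_prob = 0.93, blink_rates = NULL, seed = 1L) {
  p <- list(field_size = as.integer(field_size), pixel_size = pixel_size,
            frame_interval = frame_interval, n_frames = as.integer(n_frames),
            d_out = d_out, d_in = d_in, eps_enter = eps_enter,
            eps_exit = eps_exit, sigma_loc = sigma_loc,
            particle_density_out = particle_density_out,
            survival_prob = survival_prob, blink_rates = blink_rates,
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  num_ok <- function(x) is.function(x) || (is.numeric(x) && all(is.finite(x)))
  if (!num_ok(p$d_in) || !num_ok(p$eps_enter) || !num_ok(p$eps_exit) ||
      !all(is.finite(c(p$pixel_size, p$frame_interval, p$d_out, p$sigma_loc,
                       p$particle_density_out, p$survival_prob))))
    stop("sim_params: all numeric parameters must be finite")
  stopifnot(
    p$frame_interval > 0, p$pixel_size > 0, p$n_frames >= 1,
    p$d_out >= 0, !is.numeric(p$d_in) || p$d_in >= 0,
    !is.numeric(p$eps_enter) || p$eps_enter >= 0,
    !is.numeric(p$eps_exit) || p$eps_exit >= 0,
    p$sigma_loc >= 0, p$particle_density_out > 0,
    p$survival_prob > 0, p$survival_prob <= 1,
    length(p$field_size) == 2, all(p$field_size >= 32)
  )
  invisible(p)
}

#' Generate a synthetic spacer-channel image with known contact mask
#'
#' Emulates the spacer-protein TIRF channel: a uniform bilayer background
#' plus a contact region of elevated mean intensity modulated by a smoothed
#' random heterogeneity field (spatial variation of spacer-protein density
#' within one contact). The exact binary mask used for generation is
#' returned as ground truth.
#'
#' @param params a [sim_params()] object.
#' @param contact_shape list describing the contact geometry. Currently
#'   `list(type = "disk", center_um = c(x, y), radius_um = r)`; the default
#'   centres a 6 um radius disk in the field.
#' @param background bilayer background intensity (arbitrary units).
#' @param contrast mean contact elevation above background.
#' @param heterogeneity_amplitude standard deviation of the smoothed
#'   intensity heterogeneity inside the contact, in units of `contrast`;
#'   `0` gives a spatially constant contact.
#' @param heterogeneity_sigma_px smoothing length of the heterogeneity
#'   field, pixels.
#' @param noise_sd per-pixel Gaussian camera noise standard deviation.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return list with `image` (matrix), `mask` (the true `contact_mask`) and
#'   `params` echo.
#' @export
generate_spacer_image <- function(params = sim_params(),
                                  contact_shape = NULL,
                                  background = 100, contrast = 100,
                                  heterogeneity_amplitude = 0.25,
                                  heterogeneity_sigma_px = 4,
                                  noise_sd = 2, seed = params$seed) {
  nr <- params$field_size[2L]; nc <- params$field_size[1L]
  ps <- params$pixel_size
  if (is.null(contact_shape))
    contact_shape <- list(type = "disk",
                          center_um = c(nc, nr) * ps / 2, radius_um = 6)
  m <- rasterize_shape(contact_shape, nr, nc, ps)
  if (!any(m)) stop("invalid geometry: contact region is empty")
  if (sum(m) == nr * nc || touches_edge(m))
    stop("invalid geometry: contact does not fit within the field")
  set.seed(seed)
  img <- matrix(background, nr, nc)
  het <- matrix(stats::rnorm(nr * nc), nr, nc)
  het <- as.matrix(EBImage::gblur(het, sigma = heterogeneity_sigma_px))
  s <- stats::sd(het)
  het <- if (s > 0) het / s else het * 0
  img[m] <- background + contrast * (1 + heterogeneity_amplitude * het[m])
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  img[img < 0] <- 0
  list(image = img,
       mask = contact_mask_from_matrix(m, ps,
         provenance = list(type = "ground_truth", shape = contact_shape)),
       params = params)
}

rasterize_shape <- function(shape, nr, nc, ps) {
  # pixel centers in um
  xc <- (seq_len(nc) - 0.5) * ps
  yc <- (seq_len(nr) - 0.5) * ps
  switch(shape$type,
    disk = {
      dx <- outer(rep(1, nr), xc - shape$center_um[1])
      dy <- outer(yc - shape$center_um[2], rep(1, nc))
      dx^2 + dy^2 <= shape$radius_um^2
    },
    rect = {
      inx <- xc >= shape$xlim_um[1] & xc < shape$xlim_um[2]
      iny <- yc >= shape$ylim_um[1] & yc < shape$ylim_um[2]
      outer(iny, inx)
    },
    stop("unknown contact shape type: ", shape$type)
  )
}

touches_edge <- function(m) {
  any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])
}

#' Simulate probe tracks with barrier-crossing Brownian dynamics
#'
#' Each particle takes isotropic Gaussian steps with per-axis standard
#' deviation `sqrt(2 * D_local * dt)`. When the continuous step segment
#' crosses the contact boundary, the crossing is accepted with Boltzmann
#' probability `exp(-eps)` for the corresponding direction; rejected steps
#' are specularly reflected at the boundary so the step-length distribution
#' is preserved. Reported positions carry independent Gaussian localization
#' noise; tracks terminate per frame with probability `1 - survival_prob`
#' and dead particles are replaced by fresh ones to keep the density
#' stationary. The field edges are reflecting.
#'
#' @param params a [sim_params()] object.
#' @param mask a `contact_mask` on the same pixel grid as the field.
#' @param seed RNG seed (defaults to `params$seed`); same seed, same
#'   arguments give bit-identical output tables.
#' @param start_region where particles (initial and replacement) are
#'   placed: uniformly over the whole `"field"` (default), only `"inside"`
#'   or only `"outside"` the mask.
#' @param spacer_image optional spacer-channel matrix used when `d_in` or
#'   `eps_enter` are functions of local spacer intensity.
#' @param n_particles override the particle count (default
#'   `particle_density_out * field area`).
#' @return list of class `sim_tracks`:
#'   \describe{
#'     \item{tracks}{data.frame `track_id, frame, x_um, y_um, intensity` of
#'       reported (noisy) localizations.}
#'     \item{truth}{list with `positions` (true coordinates and per-step
#'       region label), `proposals` (one row per boundary proposal:
#'       `track_id, frame, direction, accepted`), and a copy of the true
#'       parameters.}
#'   }
#' @export
simulate_tracks <- function(params, mask, seed = params$seed,
                            start_region = c("field", "inside", "outside"),
                            spacer_image = NULL, n_particles = NULL) {
  validate_sim_params(params)
  stopifnot(inherits(mask, "contact_mask"))
  if (!all(dim(mask$mask) == c(params$field_size[2L], params$field_size[1L])))
    stop("mask grid does not match field geometry")
  start_region <- match.arg(start_region)
  ps <- params$pixel_size
  w_um <- params$field_size[1L] * ps
  h_um <- params$field_size[2L] * ps
  dt <- params$frame_interval
  if (is.null(n_particles))
    n_particles <- max(1L, round(params$particle_density_out * w_um * h_um))

  # local-D and local-eps lookups
  d_in_fun <- if (is.function(params$d_in)) {
    stopifnot(!is.null(spacer_image))
    function(int) params$d_in(int)
  } else NULL
  eps_enter_fun <- if (is.function(params$eps_enter)) {
    stopifnot(!is.null(spacer_image))
    params$eps_enter
  } else NULL

  m <- mask$mask
  grad <- mask_indicator_gradient(m)   # for specular reflection normals
  sdf <- mask_signed_distance(mask)    # px units; screens boundary candidates
  inside_at <- function(x, y) {
    col <- floor(x / ps) + 1L; row <- floor(y / ps) + 1L
    ok <- col >= 1L & col <= ncol(m) & row >= 1L & row <= nrow(m)
    res <- rep(FALSE, length(x))
    res[ok] <- m[cbind(row[ok], col[ok])]
    res
  }
  intensity_at <- function(x, y) {
    col <- pmin(pmax(floor(x / ps) + 1L, 1L), ncol(m))
    row <- pmin(pmax(floor(y / ps) + 1L, 1L), nrow(m))
    spacer_image[cbind(row, col)]
  }
  local_d <- function(x, y, inside) {
    d <- rep(params$d_out, length(x))
    if (!is.null(d_in_fun)) d[inside] <- d_in_fun(intensity_at(x, y)[inside])
    else d[inside] <- params$d_in
    d
  }

  set.seed(seed)
  draw_positions <- function(n) {
    if (n == 0L) return(matrix(numeric(0), 0, 2))
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n) {
      cand <- cbind(stats::runif(2L * n, 0, w_um), stats::runif(2L * n, 0, h_um))
      keep <- switch(start_region,
                     field = rep(TRUE, nrow(cand)),
                     inside = inside_at(cand[, 1], cand[, 2]),
                     outside = !inside_at(cand[, 1], cand[, 2]))
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }

  pos <- draw_positions(n_particles)
  ids <- seq_len(n_particles)
  next_id <- n_particles + 1L
  nf <- params$n_frames
  max_rows <- n_particles * nf

  rec_id <- integer(max_rows); rec_fr <- integer(max_rows)
  rec_x <- numeric(max_rows); rec_y <- numeric(max_rows)
  rec_tx <- numeric(max_rows); rec_ty <- numeric(max_rows)
  rec_in <- logical(max_rows)
  nrec <- 0L
  prop_list <- vector("list", nf)

  blink_on <- rep(TRUE, n_particles)

  for (f in seq_len(nf)) {
    n <- length(ids)
    inside0 <- inside_at(pos[, 1], pos[, 2])
    if (f > 1L) {
      dvec <- local_d(pos[, 1], pos[, 2], inside0)
      sdv <- sqrt(2 * dvec * dt)
      prop <- pos + cbind(stats::rnorm(n, 0, sdv), stats::rnorm(n, 0, sdv))
      # reflecting field edges
      prop[, 1] <- reflect_into(prop[, 1], w_um)
      prop[, 2] <- reflect_into(prop[, 2], h_um)
      res <- advance_with_barriers(pos, prop, inside0, inside_at, grad, ps,
                                   params, eps_enter_fun, intensity_at, sdf)
      pos <- res$pos
      if (nrow(res$proposals) > 0) {
        res$proposals$track_id <- ids[res$proposals$particle]
        res$proposals$frame <- f
        prop_list[[f]] <- res$proposals[c("track_id", "frame", "direction",
                                          "accepted")]
      }
      inside0 <- inside_at(pos[, 1], pos[, 2])
    }
    # blinking (optional two-state switch)
    if (!is.null(params$blink_rates)) {
      off <- params$blink_rates[1]; on <- params$blink_rates[2]
      flip_off <- blink_on & stats::runif(n) < off
      flip_on <- !blink_on & stats::runif(n) < on
      blink_on <- (blink_on & !flip_off) | flip_on
    }
    vis <- blink_on
    nv <- sum(vis)
    if (nv > 0) {
      idx <- nrec + seq_len(nv)
      rec_id[idx] <- ids[vis]; rec_fr[idx] <- f
      rec_tx[idx] <- pos[vis, 1]; rec_ty[idx] <- pos[vis, 2]
      rec_x[idx] <- pos[vis, 1] + stats::rnorm(nv, 0, params$sigma_loc)
      rec_y[idx] <- pos[vis, 2] + stats::rnorm(nv, 0, params$sigma_loc)
      rec_in[idx] <- inside0[vis]
      nrec <- nrec + nv
    }
    # survival and replacement
    if (f < nf && params$survival_prob < 1) {
      die <- stats::runif(n) >= params$survival_prob
      nd <- sum(die)
      if (nd > 0) {
        pos[die, ] <- draw_positions(nd)
        ids[die] <- next_id + seq_len(nd) - 1L
        next_id <- next_id + nd
        blink_on[die] <- TRUE
      }
    }
  }

  keep <- seq_len(nrec)
  tracks <- data.frame(track_id = rec_id[keep], frame = rec_fr[keep],
                       x_um = rec_x[keep], y_um = rec_y[keep],
                       intensity = 1)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  positions <- data.frame(track_id = rec_id[keep], frame = rec_fr[keep],
                          x_um = rec_tx[keep], y_um = rec_ty[keep],
                          region = ifelse(rec_in[keep], "inside", "outside"))
  positions <- positions[order(positions$track_id, positions$frame), ]
  rownames(positions) <- NULL
  proposals <- do.call(rbind, prop_list[!vapply(prop_list, is.null, TRUE)])
  if (is.null(proposals))
    proposals <- data.frame(track_id = integer(0), frame = integer(0),
                            direction = character(0), accepted = logical(0))
  rownames(proposals) <- NULL
  structure(list(tracks = tracks,
                 truth = list(positions = positions, proposals = proposals,
                              params = params, mask = mask,
                              start_region = start_region, seed = seed)),
            class = "sim_tracks")
}

reflect_into <- function(x, L) {
  # fold coordinates into [0, L] (specular reflection at the field edges)
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

# gradient of the Gaussian-smoothed mask indicator, for boundary normals
mask_indicator_gradient <- function(m) {
  s <- as.matrix(EBImage::gblur(matrix(as.numeric(m), nrow(m)), sigma = 1.5))
  nr <- nrow(s); nc <- ncol(s)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (s[, 3:nc] - s[, 1:(nc - 2)]) / 2   # d/dcol = d/dx
  gy[2:(nr - 1), ] <- (s[3:nr, ] - s[1:(nr - 2), ]) / 2   # d/drow = d/dy
  list(gx = gx, gy = gy)
}

boundary_normal <- function(grad, x, y, ps) {
  nr <- nrow(grad$gx); nc <- ncol(grad$gx)
  col <- pmin(pmax(floor(x / ps) + 1L, 1L), nc)
  row <- pmin(pmax(floor(y / ps) + 1L, 1L), nr)
  v <- c(grad$gx[row, col], grad$gy[row, col])  # points toward increasing mask
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0) else v / n
}

# Advance all particles one frame, handling boundary crossings on the
# continuous step segment (dense sub-sampling + bisection refinement).
advance_with_barriers <- function(pos, prop, inside0, inside_at, grad, ps,
                                  params, eps_enter_fun, intensity_at, sdf) {
  n <- nrow(pos)
  seg_len <- sqrt(rowSums((prop - pos)^2))
  needs <- inside_at(prop[, 1], prop[, 2]) != inside0
  # particles closer to the boundary than their step length may tunnel
  # (cross and return within one step) even with unchanged endpoint side
  col <- pmin(pmax(floor(pos[, 1] / ps) + 1L, 1L), ncol(sdf))
  row <- pmin(pmax(floor(pos[, 2] / ps) + 1L, 1L), nrow(sdf))
  near <- abs(sdf[cbind(row, col)]) * ps < seg_len + ps
  long <- which(near & !needs & seg_len > 0)
  if (length(long) > 0) {
    kmax <- max(2L, ceiling(max(seg_len[long]) / (0.25 * ps)))
    fr <- seq_len(kmax) / kmax
    frm <- matrix(fr, nrow = length(long), ncol = kmax, byrow = TRUE)
    xs <- pos[long, 1] + frm * (prop[long, 1] - pos[long, 1])
    ys <- pos[long, 2] + frm * (prop[long, 2] - pos[long, 2])
    memb <- matrix(inside_at(as.vector(xs), as.vector(ys)), nrow = length(long))
    tun <- rowSums(memb != inside0[long]) > 0
    needs[long[tun]] <- TRUE
  }
  final <- prop
  events <- list()
  barrier_free <- !is.function(params$eps_enter) && !is.function(params$eps_exit) &&
    params$eps_enter == 0 && params$eps_exit == 0
  for (i in which(needs)) {
    r <- advance_one(pos[i, ], prop[i, ], inside0[i], inside_at, grad, ps,
                     params, eps_enter_fun, intensity_at, barrier_free)
    final[i, ] <- r$pos
    if (length(r$events) > 0)
      events[[length(events) + 1L]] <-
        data.frame(particle = i, direction = vapply(r$events, `[[`, "", "dir"),
                   accepted = vapply(r$events, `[[`, TRUE, "acc"))
  }
  proposals <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(particle = integer(0), direction = character(0),
               accepted = logical(0))
  list(pos = final, proposals = proposals)
}

# One particle's step with possibly multiple boundary crossings.
advance_one <- function(p0, p1, inside0, inside_at, grad, ps, params,
                        eps_enter_fun, intensity_at, barrier_free,
                        depth = 0L) {
  events <- list()
  cur <- p0; side <- inside0; target <- p1
  for (iter in 1:4) {
    cross <- find_crossing(cur, target, side, inside_at, ps)
    if (is.null(cross)) break
    dir <- if (side) "exit" else "enter"
    eps <- if (dir == "enter") {
      if (!is.null(eps_enter_fun))
        eps_enter_fun(intensity_at(cross$point[1], cross$point[2]))
      else params$eps_enter
    } else params$eps_exit
    acc <- barrier_free || stats::runif(1) < exp(-eps)
    events[[length(events) + 1L]] <- list(dir = dir, acc = acc)
    if (acc) {
      cur <- cross$beyond
      side <- !side
      # continue toward target; further crossings handled next iteration
    } else {
      # specular reflection of the remaining displacement about the normal
      nrm <- boundary_normal(grad, cross$point[1], cross$point[2], ps)
      v <- target - cross$point
      v_ref <- v - 2 * sum(v * nrm) * nrm
      cand <- cross$point + v_ref
      if (inside_at(cand[1], cand[2]) == side &&
          cand[1] >= 0 && cand[2] >= 0) {
        cur <- cand
      } else {
        # concave corner or reflection landed across: nudge back to the
        # original side along the normal
        sgn <- if (side) 1 else -1
        cand2 <- cross$point + sgn * nrm * 0.35 * ps
        cur <- if (inside_at(cand2[1], cand2[2]) == side) cand2 else cross$back
      }
      return(list(pos = cur, events = events))
    }
    if (inside_at(target[1], target[2]) == side) {
      cur <- target
      break
    }
  }
  if (inside_at(cur[1], cur[2]) != side) cur <- find_crossing_fallback(cur, side, inside_at, ps, p0)
  list(pos = cur, events = events)
}

find_crossing_fallback <- function(cur, side, inside_at, ps, p0) p0

# First membership change along the segment from `a` (on side `side`) to
# `b`; dense sampling then bisection. Returns the crossing point, a point
# just beyond it (opposite side) and just before it (original side).
find_crossing <- function(a, b, side, inside_at, ps) {
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(NULL)
  k <- max(2L, ceiling(len / (0.25 * ps)))
  fr <- seq_len(k) / k
  xs <- a[1] + fr * (b[1] - a[1]); ys <- a[2] + fr * (b[2] - a[2])
  memb <- inside_at(xs, ys)
  ch <- which(memb != side)
  if (length(ch) == 0) return(NULL)
  hi <- fr[ch[1]]; lo <- if (ch[1] == 1) 0 else fr[ch[1] - 1]
  for (j in 1:12) {
    mid <- (lo + hi) / 2
    pm <- a + mid * (b - a)
    if (inside_at(pm[1], pm[2]) == side) lo <- mid else hi <- mid
  }
  list(point = a + ((lo + hi) / 2) * (b - a),
       beyond = a + hi * (b - a),
       back = a + lo * (b - a))
}

#' Render simulated tracks into a synthetic image stack
#'
#' Draws each reported localization as a 2D Gaussian spot of integrated
#' intensity `photon_count` on a constant background and adds Poisson shot
#' noise, so the detection stage can be exercised end-to-end.
#'
#' @param sim a `sim_tracks` object (or a localization data.frame with
#'   `frame, x_um, y_um`).
#' @param params the [sim_params()] describing field geometry.
#' @param psf_sigma Gaussian PSF standard deviation, um (must be > 0).
#' @param photon_count photons per spot.
#' @param background mean background level, counts/pixel.
#' @param noise_seed seed for the Poisson noise.
#' @return 3D array `[row, col, frame]`.
#' @export
render_movie <- function(sim, params, psf_sigma = 0.12, photon_count = 400,
                         background = 10, noise_seed = 1L) {
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  locs <- if (inherits(sim, "sim_tracks")) sim$tracks else sim
  ps <- params$pixel_size
  nr <- params$field_size[2L]; nc <- params$field_size[1L]
  if (nrow(locs) > 0 &&
      (any(locs$x_um < 0 | locs$x_um > nc * ps) ||
       any(locs$y_um < 0 | locs$y_um > nr * ps)))
    stop("tracks must lie within the field")
  nf <- if (nrow(locs) > 0) max(locs$frame) else params$n_frames
  stack <- array(background, dim = c(nr, nc, nf))
  sig_px <- psf_sigma / ps
  half <- ceiling(4 * sig_px)
  for (r in seq_len(nrow(locs))) {
    cx <- locs$x_um[r] / ps + 0.5  # pixel-center coordinates
    cy <- locs$y_um[r] / ps + 0.5
    cols <- max(1L, floor(cx - half)):min(nc, ceiling(cx + half))
    rows <- max(1L, floor(cy - half)):min(nr, ceiling(cy + half))
    gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
    gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
    spot <- photon_count * outer(gy, gx) / (2 * pi * sig_px^2)
    stack[rows, cols, locs$frame[r]] <- stack[rows, cols, locs$frame[r]] + spot
  }
  set.seed(noise_seed)
  stack[] <- stats::rpois(length(stack), lambda = stack)
  stack
}

#' Write localization/track tables and ground truth to disk
#'
#' Tracks go to CSV (`track_id, frame, x_um, y_um, intensity`), ground-truth
#' positions to CSV and proposal tallies plus parameters to JSON.
#'
#' @param sim a `sim_tracks` object.
#' @param dir output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_tracks"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$positions, file.path(dir, "truth_positions.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$proposals, file.path(dir, "truth_proposals.csv"),
                   row.names = FALSE)
  pars <- sim$truth$params
  pars$d_in <- if (is.function(pars$d_in)) "function" else pars$d_in
  pars$eps_enter <- if (is.function(pars$eps_enter)) "function" else pars$eps_enter
  jsonlite::write_json(unclass(pars), file.path(dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
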