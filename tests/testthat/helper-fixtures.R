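# Shared fixtures, built once per test run. Kept small so the whole suite
# stays fast; heavier simulations are created inside the tests that need
# them.

fx_params <- sim_params(seed = 7)
fx_spacer <- generate_spacer_image(fx_params)
fx_mask <- fx_spacer$mask  # ground-truth disk mask, r = 6 um, 128x128 px

# square mask [2, 12] x [2, 12] um inside a 128 px field, for geometric
# category fixtures (interior so off-grid conventions do not interfere)
fx_square <- local({
  m <- matrix(FALSE, 128, 128)
  px <- 0.16
  idx <- which(((seq_len(128)) - 0.5) * px >= 2 & ((seq_len(128)) - 0.5) * px < 12)
  m[idx, idx] <- TRUE
  contact_mask_from_matrix(m, px)
})

make_track <- function(id, xs, ys, frames = seq_along(xs)) {
  data.frame(track_id = id, frame = frames, x_um = xs, y_um = ys,
             intensity = 1)
}

# brute-force retention oracle: per-track step-by-step counting
retention_oracle <- function(tracks, mask) {
  ids <- unique(tracks$track_id)
  n_in <- 0L; n_ret <- 0L
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    ins <- logical(nrow(tr))
    for (i in seq_len(nrow(tr)))
      ins[i] <- mask_contains(mask, tr$x_um[i], tr$y_um[i])
    if (ins[1]) {
      n_in <- n_in + 1L
      stays <- TRUE
      for (i in seq_len(nrow(tr))) if (!ins[i]) stays <- FALSE
      if (stays) n_ret <- n_ret + 1L
    }
  }
  list(fraction = n_ret / n_in, n_inside_start = n_in)
}

# brute-force one-way ANOVA F from explicit sums of squares
anova_F_oracle <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_b <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2, 1))
  ss_w <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}
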