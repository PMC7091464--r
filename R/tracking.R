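#' Detect probe localizations in one frame
#'
#' Local-maximum peak finding: pixels that are maxima within a
#' `min_separation` radius and exceed `median + threshold_k * MAD` of the
#' frame are kept and refined to sub-pixel position by the intensity
#' centroid of a background-subtracted 5x5 window. Peaks closer than
#' `min_separation` are suppressed in favour of the brighter one.
#'
#' @param frame_image 2D matrix.
#' @param pixel_size um/px.
#' @param min_separation minimum peak separation, px.
#' @param threshold_k robust threshold factor (median + k * MAD).
#' @return data.frame `x_um, y_um, intensity, score` (possibly empty).
#' @export
detect_peaks <- function(frame_image, pixel_size = 0.16,
                         min_separation = 3L, threshold_k = 5) {
  if (!is.matrix(frame_image)) stop("frame_image must be a 2D matrix")
  bg <- stats::median(frame_image)
  s <- stats::mad(frame_image)
  thr <- bg + threshold_k * max(s, 1e-12)
  brush <- EBImage::makeBrush(2L * as.integer(min_separation) + 1L,
                              shape = "disc")
  mx <- as.matrix(EBImage::dilate(frame_image, brush))  # grayscale max filter
  cand <- which(frame_image >= mx - 1e-9 & frame_image >= thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), score = numeric(0)))
  vals <- frame_image[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
      keep[later][d2 < min_separation^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]
  nr <- nrow(frame_image); nc <- ncol(frame_image)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rows <- max(1L, r0 - 2L):min(nr, r0 + 2L)
    cols <- max(1L, c0 - 2L):min(nc, c0 + 2L)
    w <- pmax(frame_image[rows, cols, drop = FALSE] - bg, 0)
    tw <- sum(w)
    if (tw <= 0) { cr <- r0; cc <- c0 } else {
      cr <- sum(rowSums(w) * rows) / tw
      cc <- sum(colSums(w) * cols) / tw
    }
    c(x = (cc - 0.5) * pixel_size, y = (cr - 0.5) * pixel_size,
      int = tw, score = (vals[i] - bg) / max(s, 1e-12))
  })
  out <- do.call(rbind, out)
  data.frame(x_um = out[, "x"], y_um = out[, "y"],
             intensity = out[, "int"], score = out[, "score"])
}

#' Detect localizations across an image stack
#'
#' @param stack 3D array `[row, col, frame]`.
#' @inheritParams detect_peaks
#' @return data.frame `frame, x_um, y_um, intensity, score`.
#' @export
detect_stack <- function(stack, pixel_size = 0.16, min_separation = 3L,
                         threshold_k = 5) {
  stopifnot(length(dim(stack)) == 3L)
  res <- lapply(seq_len(dim(stack)[3]), function(f) {
    d <- detect_peaks(stack[, , f], pixel_size, min_separation, threshold_k)
    if (nrow(d) > 0) cbind(frame = f, d) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), score = numeric(0))
  out
}

#' Link localizations into tracks
#'
#' Frame-to-frame mutual-nearest-neighbour linking within `max_jump`;
#' unmatched detections seed new tracks. Tracks shorter than six
#' localizations (i.e. not longer than five frames) are discarded, the
#' track-length filter applied throughout the analysis.
#'
#' @param localizations data.frame with `frame, x_um, y_um` (and optional
#'   `intensity`), sorted by frame (will be sorted if not).
#' @param max_jump maximum frame-to-frame displacement, um.
#' @param max_gap allowed frame gap when a detection is missed (default 0).
#' @param min_length minimum retained track length in localizations
#'   (default 6).
#' @return data.frame `track_id, frame, x_um, y_um, intensity`.
#' @export
link_tracks <- function(localizations, max_jump = 0.8, max_gap = 0L,
                        min_length = 6L) {
  locs <- localizations[order(localizations$frame), , drop = FALSE]
  if (!"intensity" %in% names(locs)) locs$intensity <- NA_real_
  dup <- duplicated(locs[c("frame", "x_um", "y_um")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (frame, position) localizations removed")
    locs <- locs[!dup, , drop = FALSE]
  }
  if (nrow(locs) == 0)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  frames <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), locs$frame)
  track_of <- integer(nrow(locs))
  # active track heads: row index of last localization, track id, last frame
  head_row <- integer(0); head_id <- integer(0); head_frame <- integer(0)
  next_id <- 1L
  for (f in frames) {
    rows <- by_frame[[as.character(f)]]
    live <- head_frame >= f - 1L - max_gap & head_frame < f
    cand_h <- which(live)
    assigned_det <- rep(FALSE, length(rows))
    if (length(cand_h) > 0 && length(rows) > 0) {
      hx <- locs$x_um[head_row[cand_h]]; hy <- locs$y_um[head_row[cand_h]]
      dx <- outer(hx, locs$x_um[rows], "-")
      dy <- outer(hy, locs$y_um[rows], "-")
      dist <- sqrt(dx^2 + dy^2)
      dist[dist > max_jump] <- Inf
      # mutual nearest neighbours
      nn_det <- apply(dist, 1, function(z) if (all(!is.finite(z))) NA_integer_ else which.min(z))
      nn_head <- apply(dist, 2, function(z) if (all(!is.finite(z))) NA_integer_ else which.min(z))
      for (h in seq_along(cand_h)) {
        j <- nn_det[h]
        if (!is.na(j) && !is.na(nn_head[j]) && nn_head[j] == h &&
            !assigned_det[j]) {
          track_of[rows[j]] <- head_id[cand_h[h]]
          head_row[cand_h[h]] <- rows[j]
          head_frame[cand_h[h]] <- f
          assigned_det[j] <- TRUE
        }
      }
    }
    new_rows <- rows[!assigned_det]
    if (length(new_rows) > 0) {
      ids <- next_id + seq_along(new_rows) - 1L
      next_id <- next_id + length(new_rows)
      track_of[new_rows] <- ids
      head_row <- c(head_row, new_rows)
      head_id <- c(head_id, ids)
      head_frame <- c(head_frame, rep(f, length(new_rows)))
    }
  }
  locs$track_id <- track_of
  len <- table(locs$track_id)
  keep_ids <- as.integer(names(len)[len >= min_length])
  out <- locs[locs$track_id %in% keep_ids,
              c("track_id", "frame", "x_um", "y_um", "intensity")]
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Track quality-control summary
#'
#' @param tracks data.frame `track_id, frame, x_um, y_um`.
#' @return one-row data.frame: `n_tracks`, `mean_length`, `sd_length`,
#'   `mean_step_um` (mean per-track mean jump distance). Empty input gives
#'   an empty summary.
#' @export
track_qc <- function(tracks) {
  if (nrow(tracks) == 0)
    return(data.frame(n_tracks = integer(0), mean_length = numeric(0),
                      sd_length = numeric(0), mean_step_um = numeric(0)))
  len <- as.numeric(table(tracks$track_id))
  steps <- vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    ok <- diff(tr$frame) == 1L
    if (!any(ok)) return(NA_real_)
    mean(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)[ok])
  }, numeric(1))
  data.frame(n_tracks = length(len), mean_length = mean(len),
             sd_length = if (length(len) > 1) stats::sd(len) else 0,
             mean_step_um = mean(steps, na.rm = TRUE))
}
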