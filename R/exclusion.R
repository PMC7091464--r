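#' Gap geometry: spacer + ligand versus probe diameter
#'
#' The spacer complex (spacer protein plus its cell-surface ligand) sets
#' the membrane-membrane gap `P = spacer_length + ligand_length`; a probe
#' of hydrodynamic diameter `Q` then experiences
#' `delta = P - Q`. Negative delta means the probe is larger than the gap
#' and size-dependent exclusion is expected.
#'
#' @param spacer_length,ligand_length,probe_diameter lengths in nm, all
#'   positive.
#' @return list of class `gap_geometry` with fields `spacer_length`,
#'   `ligand_length`, `gap_P`, `probe_Q`, `delta` (nm).
#' @export
#' @examples
#' gap_delta(3.5, 6.4, 21.2)$delta   # -11.3: large probe, small gap
#' gap_delta(22.5, 6.4, 14.0)$delta  #  14.9: small probe, large gap
gap_delta <- function(spacer_length, ligand_length, probe_diameter) {
  if (any(c(spacer_length, ligand_length, probe_diameter) <= 0))
    stop("all lengths must be positive")
  P <- spacer_length + ligand_length
  structure(list(spacer_length = spacer_length, ligand_length = ligand_length,
                 gap_P = P, probe_Q = probe_diameter,
                 delta = P - probe_diameter),
            class = "gap_geometry")
}

#' First-frame probe density inside versus outside the contact
#'
#' Counts first-frame localizations inside and outside the contact mask,
#' normalizes by the respective areas and returns the relative density
#' (inside density / outside density). Outside is the full field minus the
#' mask. Localizations on boundary pixels count as inside.
#'
#' @param first_frame_locs data.frame with `x_um, y_um` of first-frame
#'   detections.
#' @param mask a `contact_mask`.
#' @return list of class `density_result`: `n_in, n_out, area_in, area_out`
#'   (um^2), `relative_density`, `exclusion` (= 1 - relative density) and
#'   `undefined` flag (empty mask or zero outside density).
#' @export
relative_density <- function(first_frame_locs, mask) {
  stopifnot(inherits(mask, "contact_mask"))
  ps <- mask$pixel_size
  area_in <- sum(mask$mask) * ps^2
  area_out <- (length(mask$mask) - sum(mask$mask)) * ps^2
  inside <- mask_contains(mask, first_frame_locs$x_um, first_frame_locs$y_um)
  n_in <- sum(inside); n_out <- sum(!inside)
  undef <- area_in == 0 || area_out == 0 || n_out == 0
  rel <- if (undef) NA_real_ else (n_in / area_in) / (n_out / area_out)
  structure(list(n_in = n_in, n_out = n_out, area_in = area_in,
                 area_out = area_out, relative_density = rel,
                 exclusion = if (undef) NA_real_ else exclusion_fraction(rel),
                 undefined = undef),
            class = "density_result")
}

#' Exclusion fraction from a relative density
#'
#' `exclusion = 1 - relative_density`; negative values indicate enrichment
#' rather than exclusion.
#'
#' @param relative_density nonnegative relative density
#'   (inside/outside density ratio).
#' @return the exclusion fraction.
#' @export
#' @examples
#' exclusion_fraction(0.293)  # 0.707
#' exclusion_fraction(0.537)  # 0.463
exclusion_fraction <- function(relative_density) {
  stopifnot(all(relative_density >= 0))
  1 - relative_density
}
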