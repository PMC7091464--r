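#' Diffusive collision count onto a surface (Fick's law)
#'
#' Number of collisions of a dilute fluid of diffusing particles at
#' concentration `c0` with a perfectly absorbing surface of area `A`
#' during time `t`: the time integral of the absorbing-wall flux
#' `J(t) = 0.5 c0 sqrt(D / (pi t))` gives `N(t) = A c0 sqrt(D t / pi)`.
#' Used to bound nonspecific probe-cell binding rates from below.
#'
#' @param A surface area, um^2.
#' @param c0 concentration, particles/um^3.
#' @param D diffusion coefficient in solution, um^2/s.
#' @param t duration, s.
#' @return collision count, with an `interpretation` attribute recording
#'   the closed form used.
#' @export
collision_count <- function(A, c0, D, t) {
  if (any(c(A, c0, D, t) <= 0)) stop("all inputs must be positive")
  structure(A * c0 * sqrt(D * t / pi),
            interpretation = paste(
              "one-sided diffusive uptake N(t) = A*c0*sqrt(D*t/pi),",
              "time-integral of the absorbing-wall flux 0.5*c0*sqrt(D/(pi*t))"))
}

#' Bounds on the nonspecific binding rate
#'
#' Lower bound: observed temporary binding events divided by the
#' theoretical collision count. Upper bound: binding fraction among all
#' tracked particles (an overestimate, since faster particles blur and are
#' not tracked); the explored-volume to acquisition-volume ratio is
#' reported as context for the upper bound.
#'
#' @param n_tracked_binding number of observed temporary binding events.
#' @param n_collisions theoretical collision count (see
#'   [collision_count()]).
#' @param n_tracked_total number of tracked particles.
#' @param volume_ratio explored volume / acquisition volume (context only).
#' @return list: `lower_bound`, `upper_bound` (fractions; `NA` and
#'   `undefined = TRUE` on zero denominators), `volume_ratio`.
#' @export
nonspecific_rate_bounds <- function(n_tracked_binding, n_collisions,
                                    n_tracked_total, volume_ratio = NA_real_) {
  stopifnot(n_tracked_binding >= 0, n_tracked_total >= 0)
  if (n_collisions <= 0) stop("n_collisions must be > 0")
  upper <- if (n_tracked_total > 0) n_tracked_binding / n_tracked_total
           else NA_real_
  list(lower_bound = n_tracked_binding / n_collisions,
       upper_bound = upper,
       undefined = n_tracked_total == 0,
       volume_ratio = volume_ratio)
}
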