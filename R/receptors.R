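#' Polar angle of a spherical cap covering a fraction of the sphere
#'
#' A cap of polar half-angle `theta_c` covers the area fraction
#' `(1 - cos(theta_c)) / 2`; a cluster occupying `1/i` of the membrane has
#' `theta_c = arccos(1 - 2/i)`.
#'
#' @param i Inverse area fraction (>= 1); the cluster covers `1/i` of the
#'   sphere.
#' @return Cap angle in radians, in `(0, pi]`.
#' @examples
#' cluster_cap_angle(2) # pi/2, a hemisphere
#' @export
cluster_cap_angle <- function(i) {
  if (any(i < 1)) stop("`i` must be >= 1")
  acos(1 - 2 / i)
}

#' Axisymmetric receptor distribution with a polar cluster
#'
#' Describes the redistribution of membrane receptors when a fraction `F` of
#' them is aggregated into a cap around the north pole occupying `1/i` of the
#' cell surface. Inside the cap the density is `(1 - F + F i) p_bar`, outside
#' `(1 - F) p_bar`; the surface integral equals `4 pi p_bar` for every
#' `(F, i)`, i.e. aggregation conserves the total receptor number.
#'
#' @param F Aggregated receptor fraction, in `[0, 1]`.
#' @param i Inverse area fraction of the cluster (>= 1).
#' @param p_bar Mean receptor density.
#' @return An object of class `bcr_receptors` with fields `F`, `i`, `p_bar`
#'   and the derived cap angle `theta_c`.
#' @export
receptor_distribution <- function(F = 0, i = 1, p_bar = 1) {
  if (F < 0 || F > 1) stop("`F` must lie in [0, 1]")
  if (i < 1) stop("`i` must be >= 1")
  stopifnot(p_bar > 0)
  structure(
    list(F = F, i = i, p_bar = p_bar, theta_c = cluster_cap_angle(i)),
    class = "bcr_receptors"
  )
}

#' Receptor density at a polar angle
#'
#' @param theta Polar angle(s) in `[0, pi]`, measured from the cluster pole.
#' @param dist A `bcr_receptors` object.
#' @return Local total receptor density at each `theta`.
#' @examples
#' d <- receptor_distribution(F = 0.01, i = 100)
#' receptor_density(c(0, pi), d) # 1.99 inside the cap, 0.99 outside
#' @export
receptor_density <- function(theta, dist) {
  stopifnot(inherits(dist, "bcr_receptors"))
  if (any(theta < -1e-12) || any(theta > pi + 1e-12))
    stop("`theta` must lie in [0, pi]")
  ifelse(theta <= dist$theta_c,
         (1 - dist$F) * dist$p_bar + dist$F * dist$i * dist$p_bar,
         (1 - dist$F) * dist$p_bar)
}

#' @export
print.bcr_receptors <- function(x, ...) {
  cat(sprintf(
    "<bcr_receptors> F = %g aggregated on 1/i = %g of the surface (theta_c = %.4g rad)\n",
    x$F, 1 / x$i, x$theta_c))
  cat(sprintf("  density: %.4g inside cap, %.4g outside (p_bar = %g)\n",
              (1 - x$F) * x$p_bar + x$F * x$i * x$p_bar,
              (1 - x$F) * x$p_bar, x$p_bar))
  invisible(x)
}

#' Tabulate a receptor distribution on a theta grid
#'
#' @param dist A `bcr_receptors` object.
#' @param n Number of equally spaced angles in `[0, pi]`.
#' @return A tibble with columns `theta_rad` and `density`.
#' @export
receptor_profile <- function(dist, n = 721) {
  theta <- seq(0, pi, length.out = n)
  tibble::tibble(theta_rad = theta, density = receptor_density(theta, dist))
}
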