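#' Dimensional parameter set for the BCR-kinase model
#'
#' Bundles the dimensional quantities of the receptor-kinase system: cell
#' geometry, kinase diffusion, and the phosphatase rate constants. Time is
#' measured against the receptor dephosphorylation rate `gamma` (s^-1), which
#' sets the relative time scale of the whole system; with the default
#' `gamma = 1` s^-1 nondimensional time equals seconds.
#'
#' @param cell_radius Cell radius R* in micrometres.
#' @param nuclear_radius_ratio Nuclear-to-cell radius ratio, in `[0, 1)`.
#' @param kinase_diffusion Kinase diffusion coefficient d* in um^2/s.
#' @param receptor_dephos_rate Receptor dephosphorylation rate gamma* in s^-1.
#' @param kinase_dephos_rate Kinase dephosphorylation (phosphatase) rate b* in
#'   s^-1, a pseudo-first-order rate at low substrate.
#' @param michaelis Michaelis constant of kinase dephosphorylation, as a
#'   fraction of the total kinase density.
#' @param c0 Spontaneous receptor activation coefficient (dimensionless).
#' @param receptor_density Mean surface density of receptors (per um^2).
#' @param kinase_density Total kinase density (arbitrary units; fields are
#'   reported as fractions of it).
#' @return An object of class `bcr_dimensional` (a named list).
#' @seealso [nondimensionalize()], [alpha_from_dimensional()]
#' @export
dimensional_params <- function(cell_radius = 6,
                               nuclear_radius_ratio = 0.95,
                               kinase_diffusion = 0.36,
                               receptor_dephos_rate = 1,
                               kinase_dephos_rate = 10,
                               michaelis = 0.1,
                               c0 = 0.01,
                               receptor_density = 500,
                               kinase_density = 1) {
  stopifnot(
    cell_radius > 0, kinase_diffusion > 0, receptor_dephos_rate > 0,
    kinase_dephos_rate > 0, michaelis > 0,
    receptor_density > 0, kinase_density > 0
  )
  if (nuclear_radius_ratio < 0 || nuclear_radius_ratio >= 1)
    stop("`nuclear_radius_ratio` must lie in [0, 1)")
  if (c0 < 0 || c0 > 1) stop("`c0` must lie in [0, 1]")
  structure(
    list(
      cell_radius = cell_radius,
      nuclear_radius_ratio = nuclear_radius_ratio,
      kinase_diffusion = kinase_diffusion,
      receptor_dephos_rate = receptor_dephos_rate,
      kinase_dephos_rate = kinase_dephos_rate,
      michaelis = michaelis,
      c0 = c0,
      receptor_density = receptor_density,
      kinase_density = kinase_density
    ),
    class = "bcr_dimensional"
  )
}

#' Nondimensional diffusion parameter alpha
#'
#' `alpha = R* sqrt(gamma* / d*)` compares the cell radius with the length a
#' kinase diffuses during one receptor dephosphorylation time. Large `alpha`
#' means slow diffusion; the diffusion coefficient in model units is
#' `alpha^-2`. `alpha -> 0` is the perfectly mixed limit.
#'
#' @param cell_radius Cell radius in um.
#' @param receptor_dephos_rate Receptor dephosphorylation rate in s^-1.
#' @param kinase_diffusion Kinase diffusion coefficient in um^2/s.
#' @return Dimensionless alpha.
#' @examples
#' alpha_from_dimensional(6, 1, 0.36) # 10
#' @export
alpha_from_dimensional <- function(cell_radius, receptor_dephos_rate,
                                   kinase_diffusion) {
  if (any(cell_radius <= 0) || any(receptor_dephos_rate <= 0) ||
      any(kinase_diffusion <= 0))
    stop("all arguments to alpha_from_dimensional() must be positive")
  cell_radius * sqrt(receptor_dephos_rate / kinase_diffusion)
}

#' Surface-to-volume factor of a spherical shell
#'
#' For a cytosolic shell between the nuclear radius `r_n` and the unit cell
#' radius, the ratio of the outer membrane area to the cytosol volume is
#' `3 / (1 - r_n^3)`; it reduces to 3 for a full ball. This factor converts
#' the membrane kinase-activation flux into a volumetric rate in the
#' well-mixed limit, and is the kinase activation coefficient of the membrane
#' model (where the cytosol is collapsed onto the sphere surface).
#'
#' @param r_n Nuclear-to-cell radius ratio in `[0, 1)`.
#' @return Dimensionless surface-to-volume factor.
#' @export
surface_to_volume <- function(r_n) {
  if (any(r_n < 0) || any(r_n >= 1)) stop("`r_n` must lie in [0, 1)")
  3 / (1 - r_n^3)
}

#' Nondimensional model parameters
#'
#' The parameter bundle shared by all three model tiers. Receptor density and
#' the receptor phosphorylation coefficient are normalized to 1; the kinase
#' activation coefficient `a` is 1 in the cytosolic tier and
#' `3/(1 - r_n^3)` in the membrane tier (set `a = surface_to_volume(r_n)`
#' there, or use [membrane_params()]).
#'
#' @param alpha Dimensionless diffusion parameter (> 0); model diffusion
#'   coefficient is `alpha^-2`.
#' @param b Kinase dephosphorylation coefficient (> 0), or `NA` if it is to be
#'   calibrated later with [calibrate_b_q()].
#' @param H Michaelis saturation scale of kinase dephosphorylation.
#' @param c0 Spontaneous receptor activation coefficient, in `[0, 1]`.
#' @param a Kinase activation coefficient.
#' @param rho Receptor phosphorylation coefficient (1 by normalization).
#' @param p_bar Mean receptor density (1 by normalization).
#' @param q Receptor-level multiplier at which bistability is lost in the
#'   `b_q` calibration (> 1).
#' @param r_n Nuclear-to-cell radius ratio in `[0, 1)`.
#' @return An object of class `bcr_params`.
#' @examples
#' p <- model_params(alpha = 10, b = 15, r_n = 0.95)
#' @export
model_params <- function(alpha = 10, b = NA_real_, H = 0.1, c0 = 0.01,
                         a = 1, rho = 1, p_bar = 1, q = 1.5, r_n = 0.95) {
  stopifnot(alpha > 0, H > 0, a > 0, rho > 0, p_bar > 0)
  if (!is.na(b) && b <= 0) stop("`b` must be positive")
  if (c0 < 0 || c0 > 1) stop("`c0` must lie in [0, 1]")
  if (q <= 1) stop("`q` must exceed 1")
  if (r_n < 0 || r_n >= 1) stop("`r_n` must lie in [0, 1)")
  structure(
    list(alpha = alpha, b = b, H = H, c0 = c0, a = a, rho = rho,
         p_bar = p_bar, q = q, r_n = r_n),
    class = "bcr_params"
  )
}

#' Membrane-tier parameters
#'
#' Convenience wrapper around [model_params()] that sets the kinase activation
#' coefficient to the surface-to-volume factor `3/(1 - r_n^3)` of the
#' collapsed cytosolic shell.
#'
#' @inheritParams model_params
#' @return A `bcr_params` object with `a = surface_to_volume(r_n)`.
#' @export
membrane_params <- function(alpha = 10, b = NA_real_, H = 0.1, c0 = 0.01,
                            q = 1.5, r_n = 0.95) {
  model_params(alpha = alpha, b = b, H = H, c0 = c0,
               a = surface_to_volume(r_n), q = q, r_n = r_n)
}

#' Convert dimensional parameters to the nondimensional bundle
#'
#' Scales lengths by the cell radius, time by the receptor dephosphorylation
#' rate, kinase concentration by the total kinase density and receptor density
#' by its mean. The kinase dephosphorylation coefficient and Michaelis scale
#' carry over as `b = b*/gamma*` and `H` (already a kinase fraction).
#'
#' @param dp A `bcr_dimensional` object.
#' @param tier `"cytosol"` (kinase activation coefficient `a = 1`) or
#'   `"membrane"` (`a = 3/(1 - r_n^3)`).
#' @param q Bistability-loss receptor multiplier.
#' @return A `bcr_params` object.
#' @export
nondimensionalize <- function(dp, tier = c("cytosol", "membrane"), q = 1.5) {
  stopifnot(inherits(dp, "bcr_dimensional"))
  tier <- match.arg(tier)
  alpha <- alpha_from_dimensional(dp$cell_radius, dp$receptor_dephos_rate,
                                  dp$kinase_diffusion)
  a <- if (tier == "membrane") surface_to_volume(dp$nuclear_radius_ratio) else 1
  model_params(
    alpha = alpha,
    b = dp$kinase_dephos_rate / dp$receptor_dephos_rate,
    H = dp$michaelis,
    c0 = dp$c0,
    a = a,
    q = q,
    r_n = dp$nuclear_radius_ratio
  )
}

#' @export
print.bcr_params <- function(x, ...) {
  cat("<bcr_params>\n")
  cat(sprintf("  alpha = %g (diffusion coeff %g), b = %s, H = %g, c0 = %g\n",
              x$alpha, x$alpha^-2,
              if (is.na(x$b)) "<uncalibrated>" else format(x$b), x$H, x$c0))
  cat(sprintf("  a = %g, rho = %g, p_bar = %g, q = %g, r_n = %g\n",
              x$a, x$rho, x$p_bar, x$q, x$r_n))
  invisible(x)
}

#' @export
print.bcr_dimensional <- function(x, ...) {
  cat("<bcr_dimensional>\n")
  cat(sprintf("  R* = %g um, r_n/R = %g, d* = %g um^2/s, gamma* = %g /s\n",
              x$cell_radius, x$nuclear_radius_ratio, x$kinase_diffusion,
              x$receptor_dephos_rate))
  cat(sprintf("  b* = %g /s, H = %g, c0 = %g\n",
              x$kinase_dephos_rate, x$michaelis, x$c0))
  invisible(x)
}
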