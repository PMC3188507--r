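#' Effective kinase activity including basal activity
#'
#' Per-phosphorylation-event activity of the kinase pool: the active fraction
#' `K` at full activity plus the inactive fraction `1 - K` at the basal
#' activity `c0` (the unphosphorylated kinase is assumed 100-fold less active
#' when `c0 = 0.01`). Increases monotonically from `c0` at `K = 0` to 1 at
#' `K = 1`.
#'
#' @param K Active kinase fraction in `[0, 1]`.
#' @param c0 Basal (spontaneous) activity coefficient.
#' @return Effective activity in `[c0, 1]`.
#' @export
effective_kinase_activity <- function(K, c0) {
  K + c0 * (1 - K)
}

#' Receptor phosphorylation drive
#'
#' Receptors require double phosphorylation for full activation, giving a
#' drive quadratic in the active kinase level, plus the spontaneous activation
#' channel with coefficient `c0`: `drive = K^2 + c0`.
#'
#' @inheritParams effective_kinase_activity
#' @return Dimensionless activation drive.
#' @export
kinase_drive <- function(K, c0) {
  K^2 + c0
}

#' Kinase dephosphorylation rate
#'
#' Saturating (Michaelis-Menten, Hill coefficient 1) dephosphorylation of the
#' active kinase by a limited phosphatase pool: `b K / (1 + K/H)`. At low
#' substrate the reaction is pseudo-first-order with rate constant `b`; the
#' rate saturates at `b H` for `K >> H`.
#'
#' @param K Active kinase fraction.
#' @param b Pseudo-first-order dephosphorylation coefficient.
#' @param H Michaelis saturation scale.
#' @return Dephosphorylation rate (per unit time).
#' @export
kinase_sink <- function(K, b, H) {
  b * K / (1 + K / H)
}

#' Steady-state active receptor level at fixed kinase activity
#'
#' Solves `rho (K^2 + c0) (p - R) = R` for `R`:
#' `R_ss = p (K^2 + c0) / (1 + K^2 + c0)` with `rho = 1`.
#'
#' @param K Active kinase fraction.
#' @param p Local total receptor density.
#' @param c0 Spontaneous activation coefficient.
#' @param rho Receptor phosphorylation coefficient.
#' @return Steady-state active receptor density, in `[0, p)`.
#' @export
receptor_steady_state <- function(K, p, c0, rho = 1) {
  d <- rho * kinase_drive(K, c0)
  p * d / (1 + d)
}

#' Local reaction rates of the kinase-receptor system
#'
#' Returns the kinase sink term and the receptor net rate at a point with
#' local receptor density `p_local`. The kinase activation term
#' `a R (1 - K)` is geometry-dependent (volumetric in the membrane tier, a
#' boundary flux in the cytosolic tier) and is therefore applied by the
#' simulators, not here.
#'
#' @param K Active kinase fraction.
#' @param R Active receptor density.
#' @param p_local Local total receptor density.
#' @param params A `bcr_params` object.
#' @return A list with `kinase_sink` and `receptor_rate`.
#' @examples
#' p <- model_params(b = 15)
#' reaction_rates(K = 0, R = 0, p_local = 1, params = model_params(b = 15, c0 = 0))
#' @export
reaction_rates <- function(K, R, p_local, params) {
  list(
    kinase_sink = kinase_sink(K, params$b, params$H),
    receptor_rate = params$rho * kinase_drive(K, params$c0) * (p_local - R) - R
  )
}
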