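#' Critical-fraction sweep over cluster sizes
#'
#' Tabulates the critical aggregated fraction `F_crit(i)` for a set of
#' diffusion parameters, nuclear radii and cluster sizes, in the membrane
#' (2D) or cytosolic (3D) tier. Each `(alpha, r_n)` configuration is first
#' calibrated with the `q`-rule ([calibrate_b_q()] for the membrane tier,
#' [calibrate_b_q_cytosol()] for the cytosolic tier); calibration failures
#' are recorded per row, not fatally.
#'
#' @param tier `"membrane"` or `"cytosol"`.
#' @param alpha_list,r_n_list,i_list Parameter grids.
#' @param alpha,r_n,i Alternative spellings for single values.
#' @param H,c0,q Shared kinetic constants.
#' @param tol Relative bisection tolerance on `F_crit`.
#' @param ... Passed to the tier's critical-fraction routine.
#' @return A `sweep_table` tibble with columns `model_tier`, `alpha`, `r_n`,
#'   `i`, `F`, `b`, `outcome`, `T_A`, `F_crit`, `b_crit`.
#' @export
run_fcrit_sweep <- function(tier = c("membrane", "cytosol"),
                            alpha_list = 3, r_n_list = 0.95,
                            i_list = c(1e3, 1e4, 1e5), H = 0.1, c0 = 0.01,
                            q = 1.5, tol = 1e-2, ...) {
  tier <- match.arg(tier)
  rows <- list()
  for (alpha in alpha_list) for (r_n in r_n_list) {
    prm <- if (tier == "membrane") {
      membrane_params(alpha = alpha, H = H, c0 = c0, q = q, r_n = r_n)
    } else {
      model_params(alpha = alpha, H = H, c0 = c0, q = q, r_n = r_n)
    }
    b_q <- tryCatch(
      if (tier == "membrane") calibrate_b_q(prm, eta = 1)
      else calibrate_b_q_cytosol(prm),
      error = function(e) NA_real_)
    for (i in i_list) {
      Fc <- if (is.na(b_q)) NA_real_ else tryCatch({
        prm$b <- b_q
        if (tier == "membrane")
          critical_fraction_membrane(i, prm, tol = tol, ...)
        else critical_fraction_cytosol(i, prm, tol = tol, ...)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        model_tier = tier, alpha = alpha, r_n = r_n, i = i, F = NA_real_,
        b = b_q, outcome = NA_character_, T_A = NA_real_, F_crit = Fc,
        b_crit = NA_real_)
    }
  }
  new_sweep_table(dplyr::bind_rows(rows))
}

#' Local-only versus global activation demonstration
#'
#' Paired membrane simulations showing the two failure modes of wave
#' initiation: the same aggregated fraction `F` on a large cluster launches a
#' global wave but stays local on a small one (front curvature / wash-out),
#' and a very large `F` destroys global bistability by depleting the
#' background receptors so the wave cannot leave the cluster either.
#'
#' @param params Membrane-tier `bcr_params` with calibrated `b`.
#' @param F Aggregated fraction for the size pair.
#' @param i_pair Two cluster sizes `c(i_small_cluster, i_large_cluster)`
#'   (note larger `i` = smaller cluster).
#' @param F_large A large fraction destroying global bistability.
#' @param i_large Cluster size used with `F_large`.
#' @param t_end Horizon.
#' @return A `sweep_table` tibble with one row per run and the `outcome`
#'   column in `{"global", "local_only", "none"}`.
#' @export
run_local_vs_global_demo <- function(params, F = 0.1, i_pair = c(1e8, 1e3),
                                     F_large = 0.5, i_large = 100,
                                     t_end = 400) {
  cases <- tibble::tibble(F = c(F, F, F_large),
                          i = c(i_pair[1], i_pair[2], i_large))
  rows <- purrr::pmap(cases, function(F, i) {
    traj <- simulate_membrane(params,
                              receptor_distribution(F = F, i = i,
                                                    p_bar = params$p_bar),
                              t_end = t_end, save_by = 5)
    thr <- traj$threshold
    K_end <- traj$K[nrow(traj$K), ]
    outcome <- if (is_activated(traj)) "global"
      else if (max(K_end) > thr) "local_only" else "none"
    tibble::tibble(model_tier = "membrane", alpha = params$alpha,
                   r_n = params$r_n, i = i, F = F, b = traj$b,
                   outcome = outcome, T_A = activation_time(traj),
                   F_crit = NA_real_, b_crit = NA_real_)
  })
  new_sweep_table(dplyr::bind_rows(rows))
}

#' Activation time versus the diffusion parameter
#'
#' Runs the membrane model for a fixed activatory cluster across a list of
#' `alpha` values and reports the whole-cell activation time; since the front
#' speed scales as `u0/alpha`, `T_A` grows roughly linearly in `alpha` once
#' the transit dominates nucleation.
#'
#' @param alpha_list Diffusion parameters.
#' @param F,i Cluster configuration reused across `alpha`.
#' @param r_n,H,c0,q Model constants.
#' @param t_end_factor Horizon as a multiple of `alpha` (transit time scale).
#' @return A `sweep_table` tibble.
#' @export
run_activation_time_vs_alpha <- function(alpha_list = c(3, 10, 30),
                                         F = 0.05, i = 1e3, r_n = 0.95,
                                         H = 0.1, c0 = 0.01, q = 1.5,
                                         t_end_factor = 12) {
  rows <- purrr::map(alpha_list, function(alpha) {
    prm <- membrane_params(alpha = alpha, H = H, c0 = c0, q = q, r_n = r_n)
    prm$b <- calibrate_b_q(prm, eta = 1)
    traj <- simulate_membrane(prm,
                              receptor_distribution(F = F, i = i),
                              t_end = max(300, t_end_factor * alpha),
                              save_by = max(1, alpha / 10))
    tibble::tibble(model_tier = "membrane", alpha = alpha, r_n = r_n, i = i,
                   F = F, b = prm$b,
                   outcome = if (is_activated(traj)) "global" else "none",
                   T_A = activation_time(traj), F_crit = NA_real_,
                   b_crit = NA_real_)
  })
  new_sweep_table(dplyr::bind_rows(rows))
}

#' Critical-b sweep (wave-propagation failure threshold)
#'
#' Tabulates [critical_b()] across `alpha` for a fixed cluster, in the
#' straight (curvature-free) and/or spherical geometry.
#'
#' @param alpha_list Diffusion parameters.
#' @param i,F Cluster configuration.
#' @param geometry Geometries to include.
#' @param r_n,H,c0,q Model constants.
#' @param ... Passed to [critical_b()].
#' @return A `sweep_table` tibble.
#' @export
run_critical_b_sweep <- function(alpha_list = c(1, 3, 10), i = 1e4, F = 0.1,
                                 geometry = c("straight", "spherical"),
                                 r_n = 0.95, H = 0.1, c0 = 0.01, q = 1.5,
                                 ...) {
  rows <- list()
  for (geom in geometry) for (alpha in alpha_list) {
    prm <- membrane_params(alpha = alpha, H = H, c0 = c0, q = q, r_n = r_n)
    prm$b <- calibrate_b_q(prm, eta = 1)
    bc <- tryCatch(critical_b(prm, i = i, F = F, geometry = geom, ...),
                   error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- tibble::tibble(
      model_tier = paste0("membrane_", geom), alpha = alpha, r_n = r_n,
      i = i, F = F, b = prm$b, outcome = NA_character_, T_A = NA_real_,
      F_crit = NA_real_, b_crit = bc)
  }
  new_sweep_table(dplyr::bind_rows(rows))
}

new_sweep_table <- function(df) {
  stopifnot(all(c("model_tier", "alpha", "r_n", "i", "F", "b", "outcome",
                  "T_A", "F_crit", "b_crit") %in% names(df)))
  df <- df[, c("model_tier", "alpha", "r_n", "i", "F", "b", "outcome",
               "T_A", "F_crit", "b_crit")]
  class(df) <- c("sweep_table", class(df))
  df
}
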