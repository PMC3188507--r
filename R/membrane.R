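#' Nonuniform polar-angle grid for the membrane model
#'
#' Builds a 1D grid on `[0, pi]` (polar angle for the spherical geometry, arc
#' length for the planar variant) with geometric refinement into the receptor
#' cluster cap, so that even very small clusters (`1/i` down to ~1e-7 of the
#' surface) are resolved by at least `n_cap` nodes while the remainder of the
#' domain is gridded at `h_max`.
#'
#' @param theta_c Cluster cap angle (radians) to refine into, or `NULL` for a
#'   uniform grid.
#' @param h_max Maximum node spacing away from the cluster.
#' @param n_cap Minimum number of nodes inside the cap.
#' @param grow Geometric growth ratio of spacing outside the cap.
#' @return A list with `theta` (nodes, increasing, endpoints 0 and pi) and
#'   `n` (node count).
#' @export
theta_grid <- function(theta_c = NULL, h_max = pi / 400, n_cap = 25,
                       grow = 1.12) {
  if (is.null(theta_c) || theta_c >= pi / 4 ||
      theta_c / n_cap >= h_max) {
    theta <- seq(0, pi, length.out = ceiling(pi / h_max) + 1)
  } else {
    h_fine <- theta_c / n_cap
    theta <- seq(0, theta_c * 1.3, by = h_fine)
    h <- h_fine
    while (theta[length(theta)] < pi) {
      h <- min(h * grow, h_max)
      theta <- c(theta, theta[length(theta)] + h)
    }
    theta[length(theta)] <- pi
  }
  list(theta = theta, n = length(theta))
}

# finite-volume machinery shared by the spherical and planar 1D models.
# spherical: d/dt K = alpha^-2 (sin t)^-1 d/dt(sin t dK/dt) -> conservative
# flux form with face metric sin(theta); planar: metric 1. No-flux at both
# ends (pole regularity on the sphere).
membrane_rhs_factory <- function(theta, alpha, a, b, H, c0, rho, p_node,
                                 geometry) {
  N <- length(theta)
  h <- diff(theta)
  mid <- (theta[-1] + theta[-N]) / 2
  metric <- if (geometry == "spherical") sin(mid) else rep(1, N - 1)
  edges <- c(theta[1], mid, theta[N])
  w <- if (geometry == "spherical") {
    cos(edges[1:N]) - cos(edges[2:(N + 1)])
  } else {
    edges[2:(N + 1)] - edges[1:N]
  }
  w <- pmax(w, .Machine$double.eps)
  D <- alpha^-2
  iK <- seq(1, 2 * N, by = 2)
  iR <- seq(2, 2 * N, by = 2)
  function(t, y, parms) {
    K <- y[iK]; R <- y[iR]
    flux <- metric * (K[-1] - K[-N]) / h
    lap <- (c(flux, 0) - c(0, flux)) / w
    dK <- D * lap + a * R * (1 - K) - b * K / (1 + K / H)
    dR <- rho * (K^2 + c0) * (p_node - R) - R
    out <- numeric(2 * N)
    out[iK] <- dK; out[iR] <- dR
    list(out)
  }
}

#' Simulate the 1D membrane model
#'
#' Integrates the kinase-receptor system on the sphere surface (axisymmetric,
#' fields depending on the polar angle `theta` only) or on a planar
#' (curvature-free) segment of length pi, by the method of lines with a
#' conservative finite-volume Laplace-Beltrami discretization and a stiff
#' multistep integrator with banded Jacobian. The kinase lives on the
#' membrane: activation `a R (1 - K)` with `a = 3/(1 - r_n^3)` acts in the
#' same equation as diffusion and the Michaelis sink.
#'
#' @param params A `bcr_params` object (use [membrane_params()] so that `a`
#'   carries the surface-to-volume factor).
#' @param dist A `bcr_receptors` object describing the cluster.
#' @param init `"zero"` (K = R = 0), `"inactive"` or `"active"` (uniform
#'   well-mixed stable state), or a list with numeric vectors `K`, `R`.
#' @param t_end Final time; defaults to `max(300, 10 * alpha)`, roughly ten
#'   front transits plus nucleation margin.
#' @param grid Grid from [theta_grid()]; defaults to a cluster-refined grid.
#' @param geometry `"spherical"` or `"planar"`. On the planar segment the
#'   cluster occupies the length fraction `1/i` at the left end.
#' @param p_theta Optional explicit receptor density per node, overriding
#'   `dist` (used e.g. to suppress background depletion).
#' @param b Kinase dephosphorylation coefficient; defaults to `params$b`.
#' @param save_by Output interval.
#' @param box_tol Tolerance for the `0 <= K <= 1`, `0 <= R <= p` invariant
#'   check at output times; violation raises an error.
#' @return A `bcr_trajectory` object: `times`, `theta`, matrices `K`, `R`
#'   (time by node), the activation `threshold` (midpoint of the well-mixed
#'   stable kinase levels, `NA` if not bistable) and `activation_time`.
#' @export
simulate_membrane <- function(params, dist = receptor_distribution(),
                              init = "zero", t_end = NULL, grid = NULL,
                              geometry = c("spherical", "planar"),
                              p_theta = NULL, b = params$b, save_by = 1,
                              box_tol = 1e-5) {
  geometry <- match.arg(geometry)
  stopifnot(!is.na(b))
  if (is.null(t_end)) t_end <- max(300, 10 * params$alpha)
  if (is.null(grid)) {
    tc <- if (dist$F > 0 && dist$i > 1) {
      if (geometry == "planar") pi / dist$i else dist$theta_c
    } else NULL
    grid <- theta_grid(tc, h_max = min(pi / 400, 1 / (3 * params$alpha)))
  }
  theta <- grid$theta; N <- grid$n
  if (is.null(p_theta)) {
    p_theta <- if (geometry == "planar") {
      w_cl <- pi / dist$i
      ifelse(theta <= w_cl,
             (1 - dist$F) * dist$p_bar + dist$F * dist$i * dist$p_bar,
             (1 - dist$F) * dist$p_bar)
    } else {
      receptor_density(theta, dist)
    }
  }
  stopifnot(length(p_theta) == N)

  thr <- tryCatch(activation_threshold(params, eta = 1, p = params$p_bar,
                                       b = b),
                  error = function(e) NA_real_)
  state0 <- membrane_init(init, theta, p_theta, params, b)
  rhs <- membrane_rhs_factory(theta, params$alpha, params$a, b, params$H,
                              params$c0, params$rho, p_theta, geometry)
  y0 <- numeric(2 * N)
  y0[seq(1, 2 * N, 2)] <- state0$K
  y0[seq(2, 2 * N, 2)] <- state0$R
  times <- seq(0, t_end, by = save_by)
  sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-8,
                      jactype = "bandint", bandup = 2, banddown = 2)
  if (attr(sol, "istate")[1] < 0)
    stop("membrane solver failed to complete the requested interval")
  K <- sol[, 1 + seq(1, 2 * N, 2), drop = FALSE]
  R <- sol[, 1 + seq(2, 2 * N, 2), drop = FALSE]
  if (min(K) < -box_tol || max(K) > 1 + box_tol ||
      min(R) < -box_tol ||
      max(sweep(R, 2, p_theta)) > box_tol)
    stop("invariant box [0,1] x [0,p] violated beyond tolerance")
  traj <- structure(
    list(times = sol[, 1], theta = theta, K = K, R = R,
         geometry = geometry, params = params, b = b, dist = dist,
         p_theta = p_theta, threshold = thr),
    class = "bcr_trajectory")
  traj$activation_time <- activation_time(traj)
  traj
}

membrane_init <- function(init, theta, p_theta, params, b) {
  N <- length(theta)
  if (is.list(init)) {
    stopifnot(length(init$K) == N, length(init$R) == N)
    return(list(K = init$K, R = init$R))
  }
  init <- match.arg(init, c("zero", "inactive", "active"))
  if (init == "zero") return(list(K = rep(0, N), R = rep(0, N)))
  ss <- find_steady_states(params, eta = 1, p = params$p_bar, b = b)
  Kst <- if (init == "inactive") min(ss$K) else max(ss$K)
  list(K = rep(Kst, N),
       R = receptor_steady_state(Kst, p_theta, params$c0, params$rho))
}

#' Whole-cell activation time of a trajectory
#'
#' Time at which the spatial minimum of the kinase field first crosses the
#' activation threshold (by default the midpoint between the inactive and
#' active well-mixed kinase levels), with linear interpolation between saved
#' outputs. `NA` if the trajectory never activates everywhere.
#'
#' @param traj A `bcr_trajectory` (or `bcr_cytosol_trajectory`, whose spatial
#'   minimum is taken over the outer-membrane trace).
#' @param threshold Crossing level; defaults to the trajectory's stored
#'   threshold.
#' @return Activation time, or `NA_real_`.
#' @export
activation_time <- function(traj, threshold = NULL) {
  if (is.null(threshold)) threshold <- traj$threshold
  if (is.null(threshold) || is.na(threshold)) return(NA_real_)
  mn <- apply(traj$K, 1, min)
  above <- mn > threshold
  if (!any(above)) return(NA_real_)
  j <- which(above)[1]
  if (j == 1) return(traj$times[1])
  t0 <- traj$times[j - 1]; t1 <- traj$times[j]
  m0 <- mn[j - 1]; m1 <- mn[j]
  t0 + (threshold - m0) / (m1 - m0) * (t1 - t0)
}

#' Did a trajectory achieve whole-domain activation?
#'
#' @param traj A `bcr_trajectory`.
#' @return Logical.
#' @export
is_activated <- function(traj) {
  !is.na(activation_time(traj))
}

#' Critical aggregated fraction for membrane activation
#'
#' Smallest aggregated receptor fraction `F` whose cluster of inverse size `i`
#' triggers whole-cell activation from the zero initial state, located by
#' geometric bisection to relative tolerance `tol`.
#'
#' @param i Inverse area fraction of the cluster.
#' @param params `bcr_params` for the membrane tier (with calibrated `b`).
#' @param F_bounds Bisection bracket `c(lo, hi)`; `lo` must fail and `hi`
#'   activate, otherwise `NA` is returned (with a warning naming the side).
#'   Keep `hi` well below the global-bistability ceiling: a very large
#'   aggregated fraction depletes the background receptors and blocks
#'   propagation, so activation is not monotone in `F` there.
#' @param tol Relative tolerance on `F_crit`.
#' @param t_end Simulation horizon per trial.
#' @param geometry Passed to [simulate_membrane()].
#' @param ... Further arguments to [simulate_membrane()].
#' @return `F_crit`, or `NA_real_` when no `F` in the bracket activates.
#' @export
critical_fraction_membrane <- function(i, params, F_bounds = c(1e-5, 0.1),
                                       tol = 1e-2, t_end = NULL,
                                       geometry = "spherical", ...) {
  act <- function(F) {
    is_activated(simulate_membrane(
      params, receptor_distribution(F = F, i = i, p_bar = params$p_bar),
      t_end = t_end, geometry = geometry, ...))
  }
  lo <- F_bounds[1]; hi <- F_bounds[2]
  if (!act(hi)) {
    warning("upper bound of F_bounds does not activate; returning NA")
    return(NA_real_)
  }
  if (act(lo)) stop("lower bound of F_bounds already activates; not a bracket")
  while (hi / lo - 1 > tol) {
    m <- sqrt(lo * hi)
    if (act(m)) hi <- m else lo <- m
  }
  sqrt(lo * hi)
}

#' Minimal activatory fraction over cluster sizes
#'
#' Sweeps the cluster-size parameter `i` and minimizes the critical fraction:
#' the absolute minimal fraction of receptors that must be aggregated (at the
#' optimal cluster size) to activate the cell.
#'
#' @param params Membrane-tier `bcr_params` with calibrated `b`.
#' @param i_grid Cluster sizes to scan (should span past the minimum).
#' @param ... Passed to [critical_fraction_membrane()].
#' @return A list with `F_min`, `i_at_min`, and the scan `table` (tibble with
#'   columns `i`, `F_crit`).
#' @export
find_F_min <- function(params, i_grid, ...) {
  Fc <- purrr::map_dbl(i_grid, function(i)
    critical_fraction_membrane(i, params, ...))
  tab <- tibble::tibble(i = i_grid, F_crit = Fc)
  ok <- which(!is.na(Fc))
  if (!length(ok)) return(list(F_min = NA_real_, i_at_min = NA_real_,
                               table = tab))
  j <- ok[which.min(Fc[ok])]
  list(F_min = Fc[j], i_at_min = i_grid[j], table = tab)
}

#' Planar front speed of the activation wave
#'
#' Propagation speed of the front connecting the inactive and active states
#' in a uniform planar medium, measured by fitting the level-set position of
#' the threshold crossing against time in the linear regime. The
#' dimensionless speed scales as `c = u0 / alpha`; `u0 = c * alpha` is the
#' alpha-independent prefactor used to convert measured dimensional front
#' speeds into `alpha` (e.g. 18 nm/s on a 6 um cell gives
#' `alpha = u0 * R* gamma* / c* ~ 167` with `u0 ~ 0.5` at `b = b_q`).
#'
#' @param params Membrane-tier `bcr_params` with calibrated `b`.
#' @param b Dephosphorylation coefficient (defaults to `params$b`).
#' @param t_end Integration horizon.
#' @param n Number of grid nodes on the length-pi domain.
#' @return A list with `c` (nondimensional speed) and `u0 = c * alpha`.
#' @export
front_speed_planar <- function(params, b = params$b, t_end = NULL, n = 1500) {
  stopifnot(!is.na(b))
  thr <- activation_threshold(params, eta = 1, p = params$p_bar, b = b)
  ss <- find_steady_states(params, eta = 1, p = params$p_bar, b = b)
  theta <- seq(0, pi, length.out = n)
  K0 <- ifelse(theta < 0.4, max(ss$K), min(ss$K))
  R0 <- receptor_steady_state(K0, params$p_bar, params$c0, params$rho)
  if (is.null(t_end)) t_end <- 4 * params$alpha
  traj <- simulate_membrane(params, receptor_distribution(p_bar = params$p_bar),
                            init = list(K = K0, R = R0),
                            t_end = t_end, grid = list(theta = theta, n = n),
                            geometry = "planar", b = b,
                            save_by = max(t_end / 200, 0.25))
  pos <- apply(traj$K, 1, function(K) {
    up <- which(K > thr)
    if (!length(up)) 0 else theta[max(up)]
  })
  ok <- traj$times > 0.15 * t_end & pos > 0.7 & pos < 2.6
  if (sum(ok) < 4) stop("no propagating front (stalled or exited the domain)")
  cfit <- unname(stats::coef(stats::lm(pos[ok] ~ traj$times[ok]))[2])
  if (cfit <= 0) stop("no propagating front (non-positive fitted speed)")
  list(c = cfit, u0 = cfit * params$alpha)
}

#' Critical dephosphorylation coefficient for wave propagation
#'
#' Largest `b` at which the activation wave launched by a receptor cluster
#' still sweeps the whole domain, located by bisection. In the `"straight"`
#' geometry the cluster occupies the length fraction `1/i` at one end of a
#' flat domain of length pi and the background density stays at `p_bar` (the
#' domain is a local patch of a much larger membrane, so aggregation does not
#' deplete its surroundings); in the `"spherical"` geometry the cap cluster
#' obeys the conservative redistribution and the wave must in addition
#' overcome the front curvature near the pole.
#'
#' @param params Membrane-tier `bcr_params`.
#' @param i Inverse cluster size.
#' @param F Aggregated fraction.
#' @param geometry `"straight"` or `"spherical"`.
#' @param deplete Deplete the background to `(1-F) p_bar`? Default `FALSE`
#'   for `"straight"`, `TRUE` for `"spherical"`.
#' @param b_bounds Bisection bracket; lower must propagate, upper fail.
#' @param tol Absolute tolerance on `b_crit`.
#' @param t_end Horizon per trial (slow fronts near the threshold need a long
#'   horizon; the default is 800 time units).
#' @return `b_crit` (scalar).
#' @export
critical_b <- function(params, i, F, geometry = c("straight", "spherical"),
                       deplete = NULL, b_bounds = c(8, 26), tol = 0.1,
                       t_end = 800) {
  geometry <- match.arg(geometry)
  sim_geom <- if (geometry == "straight") "planar" else "spherical"
  if (is.null(deplete)) deplete <- geometry == "spherical"
  dist <- receptor_distribution(F = F, i = i, p_bar = params$p_bar)
  grid <- NULL
  act <- function(b) {
    p_theta <- NULL
    if (!deplete) {
      g <- theta_grid(if (sim_geom == "planar") pi / i else dist$theta_c,
                      h_max = min(pi / 400, 1 / (3 * params$alpha)))
      w_cl <- if (sim_geom == "planar") pi / i else dist$theta_c
      p_theta <- ifelse(g$theta <= w_cl,
                        (1 - F) * params$p_bar + F * i * params$p_bar,
                        params$p_bar)
      grid <<- g
    }
    is_activated(simulate_membrane(params, dist, t_end = t_end, grid = grid,
                                   geometry = sim_geom, p_theta = p_theta,
                                   b = b, save_by = 5))
  }
  lo <- b_bounds[1]; hi <- b_bounds[2]
  if (!act(lo)) stop("wave does not propagate at the lower b bound")
  if (act(hi)) stop("wave still propagates at the upper b bound")
  while (hi - lo > tol) {
    m <- (lo + hi) / 2
    if (act(m)) lo <- m else hi <- m
  }
  (lo + hi) / 2
}
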