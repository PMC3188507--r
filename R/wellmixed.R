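#' Right-hand side of the well-mixed (infinite diffusion) model
#'
#' In the perfectly mixed limit the kinase and receptor fields are spatially
#' uniform and obey
#' \deqn{dK/dt = \eta a R (1 - K) - b K / (1 + K/H)}
#' \deqn{dR/dt = \rho (K^2 + c_0)(p - R) - R}
#' where `eta` is the surface-to-volume factor converting the membrane
#' activation flux into a volumetric rate (`3/(1 - r_n^3)` for a shell,
#' 3 for a full ball, 1 when `a` already carries the factor as in the
#' membrane tier).
#'
#' @param state Numeric `c(K, R)`.
#' @param params A `bcr_params` object.
#' @param eta Surface-to-volume factor (> 0). Defaults to
#'   `surface_to_volume(params$r_n)`.
#' @param p Total receptor density (defaults to `params$p_bar`).
#' @param b Kinase dephosphorylation coefficient (defaults to `params$b`).
#' @return Numeric `c(dK, dR)`.
#' @export
wellmixed_rhs <- function(state, params, eta = surface_to_volume(params$r_n),
                          p = params$p_bar, b = params$b) {
  stopifnot(eta > 0)
  K <- state[[1]]; R <- state[[2]]
  c(eta * params$a * R * (1 - K) - kinase_sink(K, b, params$H),
    params$rho * kinase_drive(K, params$c0) * (p - R) - R)
}

# reduced scalar steady-state function: g(K) = 0 at steady states
wm_g <- function(K, b, kappa, p, c0, H, rho = 1) {
  kappa * receptor_steady_state(K, p, c0, rho) * (1 - K) -
    kinase_sink(K, b, H)
}

# all roots of wm_g on [0,1]: dense sign scan + bracketed polishing
wm_roots <- function(b, kappa, p, c0, H, rho = 1, n_scan = 10001) {
  K <- seq(0, 1, length.out = n_scan)
  g <- wm_g(K, b, kappa, p, c0, H, rho)
  roots <- numeric(0)
  sgn <- g[-1] * g[-n_scan]
  for (j in which(sgn < 0)) {
    roots <- c(roots, stats::uniroot(
      wm_g, c(K[j], K[j + 1]), b = b, kappa = kappa, p = p, c0 = c0, H = H,
      rho = rho, tol = 1e-13)$root)
  }
  if (any(g == 0)) roots <- sort(unique(c(roots, K[g == 0])))
  roots
}

#' Steady states of the well-mixed model
#'
#' Finds every root of the reduced steady-state equation
#' `eta a R_ss(K) (1 - K) = b K/(1 + K/H)` on `K` in `[0, 1]` by a dense sign
#' scan followed by bracketed root polishing, and classifies linear stability
#' from the eigenvalues of the 2x2 Jacobian. Generically the system has one
#' or three steady states; with three, the outer two (the *inactive* and
#' *active* states) are stable and bracket the unstable one.
#'
#' @inheritParams wellmixed_rhs
#' @return A tibble of class `steady_state_set` with columns `K`, `R`,
#'   `stable` (logical; `NA` flags a marginal eigenvalue, i.e. a fold).
#' @export
find_steady_states <- function(params, eta = surface_to_volume(params$r_n),
                               p = params$p_bar, b = params$b) {
  stopifnot(!is.na(b))
  kappa <- eta * params$a
  Ks <- wm_roots(b, kappa, p, params$c0, params$H, params$rho)
  rows <- lapply(Ks, function(K) {
    R <- receptor_steady_state(K, p, params$c0, params$rho)
    # Jacobian of (dK, dR) wrt (K, R)
    dsink <- b / (1 + K / params$H)^2
    j11 <- -kappa * R - dsink
    j12 <- kappa * (1 - K)
    j21 <- params$rho * 2 * K * (p - R)
    j22 <- -(params$rho * kinase_drive(K, params$c0) + 1)
    ev <- eigen(matrix(c(j11, j21, j12, j22), 2, 2),
                only.values = TRUE)$values
    re <- max(Re(ev))
    tibble::tibble(K = K, R = R,
                   stable = if (abs(re) < 1e-9) NA else re < 0)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("steady_state_set", class(out))
  out
}

#' Integrate the well-mixed model in time
#'
#' @inheritParams wellmixed_rhs
#' @param init Numeric `c(K, R)` initial state.
#' @param t_end Final time (units of `1/gamma*`, i.e. seconds for
#'   `gamma* = 1/s`).
#' @param save_by Output interval.
#' @return A tibble with columns `time`, `K`, `R`.
#' @export
simulate_wellmixed <- function(params, init = c(K = 0, R = 0), t_end = 50,
                               eta = surface_to_volume(params$r_n),
                               p = params$p_bar, b = params$b,
                               save_by = 0.1) {
  stopifnot(!is.na(b))
  sol <- deSolve::ode(
    y = c(K = unname(init[[1]]), R = unname(init[[2]])),
    times = seq(0, t_end, by = save_by),
    func = function(t, y, parms) list(wellmixed_rhs(y, params, eta, p, b)),
    parms = NULL, atol = 1e-11, rtol = 1e-9
  )
  tibble::tibble(time = sol[, 1], K = sol[, 2], R = sol[, 3])
}

# number of steady states at a given b
wm_count <- function(b, kappa, p, c0, H, rho = 1)
  length(wm_roots(b, kappa, p, c0, H, rho))

#' Bistability range in the kinase dephosphorylation coefficient
#'
#' Locates the interval `[b_min, b_max]` of `b` in which the well-mixed model
#' has three steady states (saddle-node fold on either side), by a coarse
#' logarithmic scan followed by bisection on the root-count transition.
#'
#' @inheritParams wellmixed_rhs
#' @param rel_tol Relative bisection tolerance on the fold positions.
#' @return A list of class `bistability_range` with `b_min`, `b_max`,
#'   `receptor_level`, and `empty` (TRUE when no `b` yields three states).
#' @export
bistability_range <- function(params, eta = surface_to_volume(params$r_n),
                              p = params$p_bar, rel_tol = 1e-4) {
  stopifnot(p > 0)
  kappa <- eta * params$a
  bs <- exp(seq(log(1e-4 * kappa), log(1e3 * kappa), length.out = 400))
  cnt <- vapply(bs, wm_count, integer(1), kappa = kappa, p = p,
                c0 = params$c0, H = params$H, rho = params$rho)
  i3 <- which(cnt >= 3)
  if (!length(i3) || min(i3) == 1 || max(i3) == length(bs)) {
    if (!length(i3))
      return(structure(list(b_min = NA_real_, b_max = NA_real_,
                            receptor_level = p, empty = TRUE),
                       class = "bistability_range"))
    stop("bistable window touches the scan boundary; widen the scan")
  }
  bisect <- function(lo, hi, want3_hi) {
    while ((hi - lo) / hi > rel_tol) {
      m <- sqrt(lo * hi)
      in3 <- wm_count(m, kappa, p, params$c0, params$H, params$rho) >= 3
      if (in3 == want3_hi) hi <- m else lo <- m
    }
    if (want3_hi) hi else lo
  }
  b_min <- bisect(bs[min(i3) - 1], bs[min(i3)], want3_hi = TRUE)
  b_max <- bisect(bs[max(i3)], bs[max(i3) + 1], want3_hi = FALSE)
  structure(list(b_min = b_min, b_max = b_max, receptor_level = p,
                 empty = FALSE),
            class = "bistability_range")
}

#' @export
print.bistability_range <- function(x, ...) {
  if (x$empty) cat("<bistability_range> empty (no b yields three states)\n")
  else cat(sprintf("<bistability_range> b in [%.4g, %.4g] at receptor level p = %g\n",
                   x$b_min, x$b_max, x$receptor_level))
  invisible(x)
}

#' Bistability region in the (B, H) plane
#'
#' The steady-state structure of the well-mixed model depends on `b`, `eta`
#' and `a` only through the combination `B = b / (eta a p_bar)` (the ratio of
#' kinase dephosphorylation to activation). This maps the bistable region over
#' a grid of `(B, H)` for a given spontaneous activation `c0`.
#'
#' @param c0 Spontaneous receptor activation coefficient.
#' @param B Numeric vector of `B` values.
#' @param H Numeric vector of Michaelis scales.
#' @return A tibble with columns `B`, `H`, `bistable`.
#' @export
bistability_map <- function(c0 = 0.01,
                            B = exp(seq(log(0.01), log(3), length.out = 40)),
                            H = exp(seq(log(0.01), log(3), length.out = 40))) {
  grid <- expand.grid(B = B, H = H)
  grid$bistable <- mapply(function(B, H)
    wm_count(B, kappa = 1, p = 1, c0 = c0, H = H) >= 3,
    grid$B, grid$H)
  tibble::as_tibble(grid)
}

#' Calibrate the kinase dephosphorylation coefficient by the q-rule
#'
#' Chooses `b = b_q` such that the well-mixed system is bistable at the
#' reference receptor level `p_bar` and loses bistability (becomes monostable
#' active) exactly when the receptor level is raised to `q p_bar`. This is the
#' lower fold `b_min` evaluated at receptor level `q p_bar`. The rule
#' guarantees the resting cell cannot be activated by a modest uniform
#' increase of the receptor level, while a local `q`-fold density increase
#' makes the cluster locus monostable active.
#'
#' @inheritParams wellmixed_rhs
#' @param q Receptor multiplier at marginal loss of bistability (defaults to
#'   `params$q`).
#' @return `b_q` (scalar). Errors if `b_q` falls outside the bistable window
#'   at `p = p_bar`.
#' @export
calibrate_b_q <- function(params, eta = surface_to_volume(params$r_n),
                          q = params$q) {
  stopifnot(q >= 1)
  rng_q <- bistability_range(params, eta, p = q * params$p_bar)
  if (rng_q$empty) stop("no bistability at receptor level q * p_bar")
  b_q <- rng_q$b_min
  rng_1 <- bistability_range(params, eta, p = params$p_bar)
  # b_q -> b_min as q -> 1 (definitional limit), so the lower comparison
  # tolerates the fold itself
  if (rng_1$empty || b_q < rng_1$b_min * (1 - 1e-6) || b_q >= rng_1$b_max)
    stop(sprintf(
      "calibration failure: b_q = %.4g outside the p = p_bar window [%.4g, %.4g] (window at p = q: [%.4g, %.4g])",
      b_q, rng_1$b_min, rng_1$b_max, rng_q$b_min, rng_q$b_max))
  b_q
}

#' Midpoint between the two stable well-mixed kinase levels
#'
#' Used as the activation threshold by the PDE tiers: a point is counted
#' active once its kinase level crosses the midpoint between the inactive and
#' active stable states of the corresponding well-mixed system.
#'
#' @inheritParams wellmixed_rhs
#' @return Scalar threshold; errors when the system is not bistable.
#' @export
activation_threshold <- function(params,
                                 eta = surface_to_volume(params$r_n),
                                 p = params$p_bar, b = params$b) {
  ss <- find_steady_states(params, eta, p, b)
  if (nrow(ss) < 3) stop("system is not bistable; no activation threshold")
  (min(ss$K) + max(ss$K)) / 2
}
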