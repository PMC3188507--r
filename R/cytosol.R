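#' Axisymmetric meridian mesh of the cytosolic shell
#'
#' Meshes the meridian cross-section of the cytoplasm - the region between
#' the unit outer membrane circle and a nuclear circle of radius `r_n` whose
#' center may be displaced by `shift` along the symmetry axis towards the
#' north pole. Nodes are laid out as a mapped tensor grid: for each polar
#' angle `theta` (from the cell center) the radial coordinate runs from the
#' nuclear surface `r_in(theta)` to 1 in `n_r` uniform steps, so the thin gap
#' of a displaced nucleus is always resolved by `n_r` cells.
#'
#' @param r_n Nuclear-to-cell radius ratio, in `(0, 1)`.
#' @param shift Axial displacement of the nucleus, `0 <= shift < 1 - r_n`.
#' @param n_theta Number of angular cells.
#' @param n_r Number of radial cells across the gap (>= 6 recommended).
#' @param theta Optional explicit angular nodes (overrides `n_theta`).
#' @return An object of class `bcr_mesh`: node coordinates `z`, `rho`
#'   (cylindrical, meridian plane), quad connectivity, outer-boundary node
#'   indices, the angular nodes, and `min_gap = 1 - r_n - shift`.
#' @examples
#' m <- build_meridian_mesh(0.9, shift = 0.08)
#' m$min_gap # 0.02
#' @export
build_meridian_mesh <- function(r_n, shift = 0, n_theta = 240, n_r = 8,
                                theta = NULL) {
  stopifnot(r_n > 0, r_n < 1, n_r >= 2, n_theta >= 8)
  if (shift < 0 || shift >= 1 - r_n)
    stop("nucleus touches the membrane: need 0 <= shift < 1 - r_n")
  if (is.null(theta)) theta <- seq(0, pi, length.out = n_theta + 1)
  sig <- seq(0, 1, length.out = n_r + 1)
  r_in <- shift * cos(theta) + sqrt(r_n^2 - (shift * sin(theta))^2)
  Nt <- length(theta); Ns <- length(sig)
  r <- outer(r_in, sig, function(ri, s) ri + s * (1 - ri))
  z <- r * cos(theta); rho <- r * sin(theta)
  id <- matrix(seq_len(Nt * Ns), Nt, Ns)
  quads <- cbind(c(id[-Nt, -Ns]), c(id[-Nt, -1]), c(id[-1, -1]),
                 c(id[-1, -Ns]))
  structure(
    list(z = c(z), rho = c(rho), quads = quads, theta = theta,
         outer_nodes = id[, Ns], inner_nodes = id[, 1],
         n_theta = Nt - 1, n_r = Ns - 1, r_n = r_n, shift = shift,
         min_gap = 1 - r_n - shift),
    class = "bcr_mesh")
}

#' @export
print.bcr_mesh <- function(x, ...) {
  cat(sprintf(
    "<bcr_mesh> %d nodes (%d x %d), r_n = %g, shift = %g, min_gap = %g\n",
    length(x$z), x$n_theta + 1, x$n_r + 1, x$r_n, x$shift, x$min_gap))
  invisible(x)
}

# Q1 (bilinear quad) axisymmetric FEM assembly in cylindrical (z, rho):
# stiffness S_ij = int grad(phi_i).grad(phi_j) rho dA, lumped volume mass ML,
# and lumped boundary mass MB on the outer membrane arc (weight rho dl).
# The 2*pi azimuthal factor cancels throughout and is omitted.
assemble_axisym_fem <- function(mesh) {
  gp <- 1 / sqrt(3)
  gauss <- cbind(xi = c(-gp, gp, gp, -gp), eta = c(-gp, -gp, gp, gp))
  nq <- nrow(mesh$quads)
  nn <- length(mesh$z)
  zq <- matrix(mesh$z[mesh$quads], nq, 4)
  rq <- matrix(mesh$rho[mesh$quads], nq, 4)
  II <- vector("list", 16L * 4L); JJ <- II; SS <- II
  ML <- numeric(nn)
  slot <- 1L
  for (g in 1:4) {
    xi <- gauss[g, 1]; eta <- gauss[g, 2]
    Nf <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
            (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
    dNx <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNe <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    J11 <- zq %*% dNx; J12 <- rq %*% dNx
    J21 <- zq %*% dNe; J22 <- rq %*% dNe
    detJ <- as.numeric(J11 * J22 - J12 * J21)
    rho_g <- as.numeric(rq %*% Nf)
    wdet <- detJ * rho_g
    gz <- matrix(0, nq, 4); gr <- matrix(0, nq, 4)
    for (k in 1:4) {
      gz[, k] <- (J22 * dNx[k] - J12 * dNe[k]) / detJ
      gr[, k] <- (-J21 * dNx[k] + J11 * dNe[k]) / detJ
    }
    for (ii in 1:4) {
      ML[mesh$quads[, ii]] <- ML[mesh$quads[, ii]] + Nf[ii] * wdet
      for (jj in 1:4) {
        II[[slot]] <- mesh$quads[, ii]
        JJ[[slot]] <- mesh$quads[, jj]
        SS[[slot]] <- (gz[, ii] * gz[, jj] + gr[, ii] * gr[, jj]) * wdet
        slot <- slot + 1L
      }
    }
  }
  S <- Matrix::sparseMatrix(i = unlist(II), j = unlist(JJ), x = unlist(SS),
                            dims = c(nn, nn))
  ob <- mesh$outer_nodes
  dl <- sqrt(diff(mesh$z[ob])^2 + diff(mesh$rho[ob])^2)
  rmid <- (mesh$rho[ob][-1] + mesh$rho[ob][-length(ob)]) / 2
  seg <- dl * rmid
  MB <- numeric(nn)
  MB[ob[-length(ob)]] <- MB[ob[-length(ob)]] + seg / 2
  MB[ob[-1]] <- MB[ob[-1]] + seg / 2
  list(S = S, ML = ML, MB = MB, outer = ob)
}

#' Simulate the axisymmetric cytosolic model
#'
#' Kinase diffuses through the cytosolic shell
#' (`dK/dt = alpha^-2 Lap K - b K/(1+K/H)`), receptors live on the outer
#' membrane and follow the local boundary-trace kinase; the coupling is the
#' nonlinear Robin condition `alpha^-2 dK/dn = a R (1 - K)` on the outer
#' membrane (flux proportional to active receptors and inactive kinase) with
#' zero flux through the nuclear membrane and the symmetry axis. The weak
#' form carries the axisymmetric `rho` weight; time stepping is IMEX
#' (diffusion and the linearized sink implicit via a sparse Cholesky
#' factorization updated each step, receptor kinetics integrated exactly for
#' frozen boundary kinase).
#'
#' @param params A `bcr_params` with `a = 1` (cytosolic convention).
#' @param mesh A `bcr_mesh` from [build_meridian_mesh()].
#' @param dist A `bcr_receptors` cluster specification.
#' @param init `"zero"` or a list with `K` (all nodes) and `R` (outer
#'   boundary nodes).
#' @param t_end Final time.
#' @param dt Time step.
#' @param save_by Output interval for the boundary trace.
#' @param b Dephosphorylation coefficient (defaults to `params$b`).
#' @return A `bcr_cytosol_trajectory`: `times`, `theta` (outer-boundary
#'   angles), boundary-trace matrices `K` and `R` (time by node), final full
#'   fields `K_final`, `R_final`, the mesh, threshold and `activation_time`
#'   (first time the minimum of K over the outer membrane crosses the
#'   threshold).
#' @export
simulate_cytosol <- function(params, mesh, dist = receptor_distribution(),
                             init = "zero", t_end = 250, dt = 0.05,
                             save_by = 1, b = params$b) {
  stopifnot(inherits(mesh, "bcr_mesh"), !is.na(b))
  fem <- assemble_axisym_fem(mesh)
  ob <- fem$outer
  nb <- length(ob)
  nn <- length(fem$ML)
  p_b <- receptor_density(mesh$theta, dist)
  if (identical(init, "zero")) {
    K <- numeric(nn); R <- numeric(nb)
  } else {
    stopifnot(is.list(init), length(init$K) == nn, length(init$R) == nb)
    K <- init$K; R <- init$R
  }
  thr <- tryCatch(
    activation_threshold(params, eta = surface_to_volume(params$r_n),
                         p = params$p_bar, b = b),
    error = function(e) NA_real_)
  D <- params$alpha^-2
  A0 <- Matrix::Diagonal(x = fem$ML) + (dt * D) * fem$S
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(A0), LDL = FALSE, perm = TRUE)
  n_steps <- round(t_end / dt)
  save_every <- max(1L, round(save_by / dt))
  n_save <- floor(n_steps / save_every) + 1L
  Kb_out <- matrix(NA_real_, n_save, nb)
  Rb_out <- matrix(NA_real_, n_save, nb)
  t_out <- numeric(n_save)
  Kb_out[1, ] <- K[ob]; Rb_out[1, ] <- R; t_out[1] <- 0
  si <- 1L
  aMB <- params$a * fem$MB[ob]
  for (st in seq_len(n_steps)) {
    fluxco <- aMB * R
    diagv <- fem$ML * (1 + dt * b / (1 + K / params$H))
    diagv[ob] <- diagv[ob] + dt * fluxco
    A <- Matrix::Diagonal(x = diagv) + (dt * D) * fem$S
    rhs <- fem$ML * K
    rhs[ob] <- rhs[ob] + dt * fluxco
    Ch <- Matrix::update(Ch, Matrix::forceSymmetric(A))
    K <- as.numeric(Matrix::solve(Ch, rhs))
    Kb <- K[ob]
    lam <- params$rho * kinase_drive(Kb, params$c0) + 1
    Rinf <- params$rho * kinase_drive(Kb, params$c0) * p_b / lam
    R <- Rinf + (R - Rinf) * exp(-lam * dt)
    if (st %% save_every == 0L) {
      si <- si + 1L
      Kb_out[si, ] <- Kb; Rb_out[si, ] <- R; t_out[si] <- st * dt
    }
  }
  traj <- structure(
    list(times = t_out[1:si], theta = mesh$theta,
         K = Kb_out[1:si, , drop = FALSE], R = Rb_out[1:si, , drop = FALSE],
         K_final = K, R_final = R, mesh = mesh, params = params, b = b,
         dist = dist, threshold = thr, dt = dt),
    class = c("bcr_cytosol_trajectory", "bcr_trajectory"))
  traj$activation_time <- activation_time(traj)
  traj
}

# ---- spherically symmetric radial steady states -------------------------

# Solve the radial Dirichlet problem alpha^-2 (r^2 K')' / r^2 = b K/(1+K/H)
# on (r_n, 1) with K'(r_n) = 0 and K(1) = s, by Newton iteration on a
# conservative finite-volume grid; return the boundary-condition residual
# alpha^-2 K'(1) - a p drive(s) (1 - s). Steady states of the spherically
# symmetric cytosolic model are the zeros of this residual in s.
radial_bc_residual <- function(s, b, alpha, r_n, p, a = 1, c0 = 0.01,
                               H = 0.1, n = 400) {
  r <- seq(r_n, 1, length.out = n + 1)
  h <- r[2] - r[1]
  rf <- ((r[-1] + r[-(n + 1)]) / 2)^2
  K <- rep(s, n + 1)
  D <- alpha^-2
  vol <- r^2 * h; vol[1] <- r[1]^2 * h / 2
  for (it in 1:80) {
    fl <- rf * (K[-1] - K[-(n + 1)]) / h
    Fv <- numeric(n + 1)
    Fv[2:n] <- D * (fl[-1] - fl[-n])[1:(n - 1)] / vol[2:n] -
      b * K[2:n] / (1 + K[2:n] / H)
    Fv[1] <- D * fl[1] / vol[1] - b * K[1] / (1 + K[1] / H)
    Fv[n + 1] <- 0
    dsink <- b / (1 + K / H)^2
    lo <- rf / h
    dl <- numeric(n); du <- numeric(n); dd <- numeric(n + 1)
    dd[2:n] <- -D * (lo[-1] + lo[-n])[1:(n - 1)] / vol[2:n] - dsink[2:n]
    du[2:n] <- D * lo[2:n] / vol[2:n]
    dl[1:(n - 1)] <- D * lo[1:(n - 1)] / vol[2:n]
    dd[1] <- -D * lo[1] / vol[1] - dsink[1]
    du[1] <- D * lo[1] / vol[1]
    dd[n + 1] <- 1; dl[n] <- 0
    aa <- dl; bb <- dd; cc <- du; dv <- -Fv
    for (k in 2:(n + 1)) {
      m <- aa[k - 1] / bb[k - 1]
      bb[k] <- bb[k] - m * cc[k - 1]
      dv[k] <- dv[k] - m * dv[k - 1]
    }
    dK <- numeric(n + 1)
    dK[n + 1] <- dv[n + 1] / bb[n + 1]
    for (k in n:1) dK[k] <- (dv[k] - cc[k] * dK[k + 1]) / bb[k]
    K <- pmin(pmax(K + dK, 0), 1)
    if (max(abs(dK)) < 1e-12) break
  }
  dK1 <- (3 * K[n + 1] - 4 * K[n] + K[n - 1]) / (2 * h)
  D * dK1 - a * p * (s^2 + c0) / (1 + s^2 + c0) * (1 - s)
}

#' Spherically symmetric steady states of the cytosolic model
#'
#' At finite diffusion the uniform steady states of the cytosolic model are
#' radial profiles, not constants: the kinase produced at the membrane decays
#' towards the nucleus over the boundary-layer length `alpha^-1 b^-1/2`, so
#' the bistability window in `b` shifts with `alpha`. Steady states are
#' located by continuation in the membrane kinase level `s = K(r=1)`: the
#' interior Dirichlet problem is solved by Newton iteration, and zeros of the
#' Robin-condition residual in `s` are counted/polished.
#'
#' @param params `bcr_params` with `a = 1`.
#' @param p Receptor density (defaults to `p_bar`).
#' @param b Dephosphorylation coefficient.
#' @param n_scan Number of `s` samples (log-spaced).
#' @return A tibble with the membrane kinase level `K_membrane` of each
#'   steady state.
#' @export
radial_steady_states <- function(params, p = params$p_bar, b = params$b,
                                 n_scan = 300) {
  ss <- exp(seq(log(1e-5), log(0.999), length.out = n_scan))
  res <- vapply(ss, radial_bc_residual, numeric(1), b = b,
                alpha = params$alpha, r_n = params$r_n, p = p, a = params$a,
                c0 = params$c0, H = params$H)
  roots <- numeric(0)
  for (j in which(res[-1] * res[-n_scan] < 0)) {
    roots <- c(roots, stats::uniroot(
      radial_bc_residual, c(ss[j], ss[j + 1]), b = b, alpha = params$alpha,
      r_n = params$r_n, p = p, a = params$a, c0 = params$c0, H = params$H,
      tol = 1e-10)$root)
  }
  tibble::tibble(K_membrane = roots)
}

#' Finite-alpha calibration of b_q for the cytosolic tier
#'
#' The `q`-rule applied to the spherically symmetric cytosolic steady states:
#' `b_q` is the fold value of `b` below which the inactive radial state
#' disappears at receptor level `q p_bar` (monostable active), found by
#' bisection on the radial steady-state count. Reduces to [calibrate_b_q()]
#' as `alpha -> 0`.
#'
#' @param params `bcr_params` with `a = 1`.
#' @param q Receptor multiplier (defaults to `params$q`).
#' @param b_bounds Bisection bracket for the fold.
#' @param tol Absolute tolerance on `b_q`.
#' @return `b_q` (scalar).
#' @export
calibrate_b_q_cytosol <- function(params, q = params$q, b_bounds = c(1, 80),
                                  tol = 0.02) {
  b_q <- radial_lower_fold(params, p = q * params$p_bar, b_bounds = b_bounds,
                           tol = tol)
  if (nrow(radial_steady_states(params, p = params$p_bar, b = b_q)) < 3)
    stop("calibration failure: system not bistable at p = p_bar for b_q")
  b_q
}

# locate the lower fold (inactive-state appearance) of the radial root count:
# scan for a bistable b first (the count is 1 below b_min and above b_max),
# then bisect the 1 -> 3 transition from below
radial_lower_fold <- function(params, p, b_bounds, tol) {
  cnt <- function(b) nrow(radial_steady_states(params, p = p, b = b))
  bs <- exp(seq(log(b_bounds[1]), log(b_bounds[2]), length.out = 30))
  cs <- vapply(bs, cnt, integer(1))
  i3 <- which(cs >= 3)
  if (!length(i3)) stop("no bistable b found in b_bounds for the radial scan")
  if (min(i3) == 1) stop("lower b bound already bistable")
  lo <- bs[min(i3) - 1]; hi <- bs[min(i3)]
  while (hi - lo > tol) {
    m <- (lo + hi) / 2
    if (cnt(m) >= 3) hi <- m else lo <- m
  }
  (lo + hi) / 2
}

#' Lower fold of the radial bistability window
#'
#' Smallest `b` at which the inactive spherically symmetric steady state of
#' the cytosolic model exists (at receptor level `p`). Below it the resting
#' cell activates spontaneously.
#'
#' @inheritParams calibrate_b_q_cytosol
#' @param p Receptor level.
#' @return Fold value of `b`.
#' @export
radial_b_min <- function(params, p = params$p_bar, b_bounds = c(1, 80),
                         tol = 0.02) {
  radial_lower_fold(params, p = p, b_bounds = b_bounds, tol = tol)
}

#' Critical aggregated fraction in the cytosolic model
#'
#' As [critical_fraction_membrane()], on the axisymmetric shell.
#'
#' @param i Inverse cluster size.
#' @param params `bcr_params` with `a = 1` and calibrated `b`.
#' @param mesh Optional `bcr_mesh`; defaults to a concentric mesh with the
#'   cluster cap resolved.
#' @param F_bounds Bisection bracket.
#' @param tol Relative tolerance on `F_crit`.
#' @param t_end Horizon per trial.
#' @param ... Passed to [simulate_cytosol()].
#' @return `F_crit` or `NA_real_`.
#' @export
critical_fraction_cytosol <- function(i, params, mesh = NULL,
                                      F_bounds = c(1e-4, 0.1), tol = 1e-2,
                                      t_end = 300, ...) {
  if (is.null(mesh)) {
    tc <- cluster_cap_angle(i)
    g <- theta_grid(if (tc < pi / 4) tc else NULL,
                    h_max = min(pi / 240, 1 / (2.5 * params$alpha)))
    mesh <- build_meridian_mesh(params$r_n, 0, theta = g$theta, n_r = 8)
  }
  act <- function(F) {
    is_activated(simulate_cytosol(
      params, mesh, receptor_distribution(F = F, i = i, p_bar = params$p_bar),
      t_end = t_end, ...))
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

#' Cell activation by displacement of the nucleus
#'
#' Simulates the cytosolic model with a uniform receptor distribution
#' (`F = 0`) on a mesh whose nucleus is displaced by `shift` along the axis,
#' thinning the cytoplasm to `1 - r_n - shift` at the near pole. The locally
#' increased membrane-to-cytoplasm volume ratio can activate the cell without
#' any receptor clustering; activation starts where the cytoplasm is
#' thinnest. By default `b` is set to 1.15 times the finite-alpha
#' inactive-existence fold [radial_b_min()], so that the concentric cell is
#' robustly inactive while the displacement-induced wave can cross the
#' thickest cytoplasm.
#'
#' @param params `bcr_params` with `a = 1`.
#' @param r_n Nuclear radius ratio (defaults to `params$r_n`).
#' @param shift Axial nuclear displacement.
#' @param b Dephosphorylation coefficient, or `NULL` for the default rule.
#' @param t_end Horizon.
#' @param n_theta,n_r Mesh resolution.
#' @return A list: `activated` (logical), `trajectory`, the `b` used, and
#'   `peak_theta` (angle at which the boundary kinase is maximal during the
#'   transient; near 0 means the thin-gap pole).
#' @export
nuclear_displacement_scenario <- function(params, r_n = params$r_n, shift,
                                          b = NULL, t_end = 400,
                                          n_theta = 200, n_r = 10) {
  prm <- model_params(alpha = params$alpha, b = NA_real_, H = params$H,
                      c0 = params$c0, a = params$a, rho = params$rho,
                      p_bar = params$p_bar, q = params$q, r_n = r_n)
  if (is.null(b)) b <- 1.15 * radial_b_min(prm)
  mesh <- build_meridian_mesh(r_n, shift, n_theta = n_theta, n_r = n_r)
  traj <- simulate_cytosol(prm, mesh, receptor_distribution(p_bar = prm$p_bar),
                           t_end = t_end, b = b)
  thr <- traj$threshold
  row <- if (!is.na(thr) && any(apply(traj$K, 1, max) > thr)) {
    which(apply(traj$K, 1, max) > thr)[1]  # onset of local activation
  } else ceiling(nrow(traj$K) / 2)
  list(activated = is_activated(traj), trajectory = traj, b = b,
       peak_theta = traj$theta[which.max(traj$K[row, ])])
}
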