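test_that("meridian mesh geometry and quadrature are exact", {
  m0 <- build_meridian_mesh(0.95, 0, n_theta = 60, n_r = 6)
  expect_equal(m0$min_gap, 0.05)
  fem <- bcrwave:::assemble_axisym_fem(m0)
  # lumped mass integrates the shell volume, boundary mass the sphere area
  expect_equal(2 * pi * sum(fem$ML), 4 * pi / 3 * (1 - 0.95^3),
               tolerance = 1e-3)
  expect_equal(2 * pi * sum(fem$MB), 4 * pi, tolerance = 1e-3)
  # displaced nucleus: Fig-5 geometry thins the cytoplasm to 0.02
  md <- build_meridian_mesh(0.9, shift = 0.08)
  expect_equal(md$min_gap, 0.02)
  expect_error(build_meridian_mesh(0.9, shift = 0.12), "touches")
  expect_error(build_meridian_mesh(0.9, shift = 0.1), "touches")
})

test_that("stiffness matrix annihilates constants (zero-flux consistency)", {
  m <- build_meridian_mesh(0.9, 0.05, n_theta = 40, n_r = 5)
  fem <- bcrwave:::assemble_axisym_fem(m)
  v <- rep(1, length(fem$ML))
  expect_lt(max(abs(fem$S %*% v)), 1e-10)
  expect_lt(max(abs(Matrix::t(fem$S) %*% v)), 1e-10)
})

test_that("cytosolic solution matches the well-mixed oracle at small alpha", {
  prm <- model_params(alpha = 0.1, r_n = 0.95)
  prm$b <- std_cytosol_params()$b
  mesh <- build_meridian_mesh(0.95, 0, n_theta = 60, n_r = 6)
  K0 <- 0.3
  traj <- simulate_cytosol(
    prm, mesh,
    init = list(K = rep(K0, length(mesh$z)),
                R = rep(receptor_steady_state(K0, 1, prm$c0),
                        length(mesh$theta))),
    t_end = 15, dt = 0.001, save_by = 0.5)
  wm <- simulate_wellmixed(prm, init = c(K0, receptor_steady_state(K0, 1, prm$c0)),
                           t_end = 15, save_by = 0.5)
  rel <- abs(traj$K[, 1] - wm$K) / pmax(wm$K, 1e-2)
  expect_lt(max(rel), 1e-3)
})

test_that("kinase is conserved up to boundary input and sink", {
  # with b = 0 and R frozen at 0 (zero init, c0 = 0 kills receptor activation)
  # the total kinase must stay exactly zero; with uniform init and no flux it
  # must decay only through the sink
  prm <- model_params(alpha = 1, b = 5, c0 = 0)
  mesh <- build_meridian_mesh(0.9, 0, n_theta = 40, n_r = 5)
  tr <- simulate_cytosol(prm, mesh, t_end = 5, dt = 0.01)
  expect_equal(max(abs(tr$K_final)), 0)
})

test_that("radial steady-state scan reproduces the well-mixed limit", {
  # alpha small: the radial fold positions collapse onto the ODE ones
  prm <- model_params(alpha = 0.05, r_n = 0.95)
  b_ode <- calibrate_b_q(prm)
  b_rad <- calibrate_b_q_cytosol(prm, b_bounds = c(2, 60))
  expect_equal(b_rad, b_ode, tolerance = 5e-3)
  # shooting oracle at thin shell: integrate the radial ODE outward from the
  # nucleus and compare the boundary residual root count at one b
  prm10 <- model_params(alpha = 10, r_n = 0.95)
  resid_shoot <- function(m, b) {
    o <- deSolve::ode(c(K = m, dK = 0), c(0.95, 1),
                      function(r, y, p) list(c(y[2], -2 / r * y[2] +
                        prm10$alpha^2 * b * y[1] / (1 + y[1] / prm10$H))),
                      NULL, atol = 1e-12, rtol = 1e-10)
    K1 <- o[2, 2]; dK1 <- o[2, 3]
    prm10$alpha^-2 * dK1 -
      (K1^2 + prm10$c0) / (1 + K1^2 + prm10$c0) * (1 - K1)
  }
  ms <- exp(seq(log(1e-5), log(0.999), length.out = 300))
  for (b in c(8, 18)) {
    rs <- vapply(ms, resid_shoot, numeric(1), b = b)
    expect_equal(nrow(radial_steady_states(prm10, b = b)),
                 sum(rs[-1] * rs[-length(rs)] < 0))
  }
})

test_that("cytosolic b_q shifts upward with alpha", {
  b0 <- calibrate_b_q(model_params(alpha = 10, r_n = 0.95))
  b10 <- calibrate_b_q_cytosol(model_params(alpha = 10, r_n = 0.95))
  expect_gt(b10, b0)
})

test_that("cluster-driven wave activates the shell; zero init alone does not", {
  prm <- std_cytosol_params(alpha = 10)
  mesh <- build_meridian_mesh(0.95, 0, n_theta = 160, n_r = 6)
  quiet <- simulate_cytosol(prm, mesh, t_end = 60, dt = 0.05)
  expect_false(is_activated(quiet))
  woke <- simulate_cytosol(prm, mesh, receptor_distribution(F = 0.01, i = 100),
                           t_end = 250, dt = 0.05)
  expect_true(is_activated(woke))
  # large aggregated fraction destroys global bistability: local only
  half <- simulate_cytosol(prm, mesh, receptor_distribution(F = 0.5, i = 100),
                           t_end = 250, dt = 0.05)
  expect_false(is_activated(half))
  expect_gt(max(half$K[nrow(half$K), ]), half$threshold) # active near cluster
})

test_that("thin-shell cytosol agrees with the membrane model", {
  # r_n = 0.98: boundary trace of the 3D solution vs the collapsed 2D model,
  # activation time within 5%
  prm3 <- model_params(alpha = 3, r_n = 0.98)
  prm2 <- membrane_params(alpha = 3, r_n = 0.98)
  prm2$b <- calibrate_b_q(prm2, eta = 1)
  prm3$b <- prm2$b
  dist <- receptor_distribution(F = 0.05, i = 1e3)
  g <- theta_grid(dist$theta_c, h_max = pi / 300)
  mesh <- build_meridian_mesh(0.98, 0, theta = g$theta, n_r = 6)
  t3 <- activation_time(simulate_cytosol(prm3, mesh, dist, t_end = 150,
                                         dt = 0.02))
  t2 <- activation_time(simulate_membrane(prm2, dist, t_end = 150, grid = g))
  expect_false(is.na(t3)); expect_false(is.na(t2))
  expect_lt(abs(t3 - t2) / t2, 0.05)
})

test_that("nucleus displacement activates the cell, concentric control stays off", {
  prm <- model_params(alpha = 10, r_n = 0.9)
  res <- nuclear_displacement_scenario(prm, shift = 0.08, t_end = 350,
                                       n_theta = 160, n_r = 8)
  expect_true(res$activated)
  # activation begins at the thin-gap pole
  expect_lt(res$peak_theta, pi / 4)
  ctrl <- nuclear_displacement_scenario(prm, shift = 0, b = res$b,
                                        t_end = 200, n_theta = 160, n_r = 8)
  expect_false(ctrl$activated)
})
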