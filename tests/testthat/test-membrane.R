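test_that("uniform membrane fields track the well-mixed oracle at small alpha", {
  prm <- membrane_params(alpha = 0.1, r_n = 0.95)
  prm$b <- std_membrane_params()$b # same q-rule value (alpha-independent)
  grid <- theta_grid(NULL, h_max = pi / 60)
  K0 <- rep(0.3, grid$n)
  R0 <- receptor_steady_state(K0, 1, prm$c0)
  traj <- simulate_membrane(prm, init = list(K = K0, R = R0), t_end = 20,
                            grid = grid, save_by = 0.5)
  wm <- simulate_wellmixed(prm, init = c(0.3, R0[1]), t_end = 20, eta = 1,
                           save_by = 0.5)
  # solution stays theta-uniform and matches the ODE to 1e-3 relative
  expect_lt(max(apply(traj$K, 1, function(x) diff(range(x)))), 1e-8)
  rel <- abs(traj$K[, 1] - wm$K) / pmax(wm$K, 1e-3)
  expect_lt(max(rel), 1e-3)
})

test_that("zero initial data stays inactive without a cluster at b = b_q", {
  prm <- std_membrane_params(alpha = 3)
  traj <- simulate_membrane(prm, t_end = 100, save_by = 5)
  ss <- find_steady_states(prm, eta = 1)
  expect_false(is_activated(traj))
  expect_equal(max(traj$K[nrow(traj$K), ]), min(ss$K), tolerance = 1e-4)
})

test_that("an activatory cluster launches a wave that sweeps the sphere", {
  prm <- std_membrane_params(alpha = 3)
  traj <- simulate_membrane(prm, receptor_distribution(F = 0.05, i = 1e3),
                            t_end = 150, save_by = 1)
  expect_true(is_activated(traj))
  TA <- activation_time(traj)
  expect_gt(TA, 1) # not instantaneous: a front must travel
  # raising the threshold never decreases the reported time
  TA_hi <- activation_time(traj, threshold = traj$threshold * 1.3)
  expect_gte(TA_hi, TA)
  # box invariance at saved times
  expect_true(all(traj$K >= -1e-6 & traj$K <= 1 + 1e-6))
  expect_true(all(traj$R >= -1e-6))
  expect_true(all(sweep(traj$R, 2, traj$p_theta) <= 1e-6))
})

test_that("activation time is grid-converged to about a percent", {
  prm <- std_membrane_params(alpha = 3)
  dist <- receptor_distribution(F = 0.05, i = 1e3)
  g1 <- theta_grid(dist$theta_c, h_max = pi / 300)
  g2 <- theta_grid(dist$theta_c, h_max = pi / 600, n_cap = 50)
  t1 <- activation_time(simulate_membrane(prm, dist, t_end = 150, grid = g1))
  t2 <- activation_time(simulate_membrane(prm, dist, t_end = 150, grid = g2))
  expect_lt(abs(t1 - t2) / t2, 0.01)
})

test_that("planar front speed gives u0 near 0.5 at b_q and scales as 1/alpha", {
  fs3 <- front_speed_planar(std_membrane_params(alpha = 3))
  expect_equal(fs3$u0, 0.5, tolerance = 0.1)
  fs10 <- front_speed_planar(std_membrane_params(alpha = 10))
  # c * alpha constant across alpha within 10%
  expect_equal(fs3$u0, fs10$u0, tolerance = 0.1)
  # near the propagation-failure point the front slows drastically
  prm <- std_membrane_params(alpha = 3)
  fs_slow <- front_speed_planar(prm, b = 19, t_end = 60)
  expect_lt(fs_slow$c, 0.25 * fs3$c)
})

test_that("backward wave: near b_max the active region shrinks", {
  prm <- std_membrane_params(alpha = 3)
  rng <- bistability_range(prm, eta = 1)
  b_back <- 0.95 * rng$b_max
  ss <- find_steady_states(prm, eta = 1, b = b_back)
  n <- 600
  theta <- seq(0, pi, length.out = n)
  K0 <- ifelse(theta < pi / 2, max(ss$K), min(ss$K))
  R0 <- receptor_steady_state(K0, 1, prm$c0)
  traj <- simulate_membrane(prm, init = list(K = K0, R = R0), b = b_back,
                            t_end = 60, grid = list(theta = theta, n = n),
                            geometry = "planar", save_by = 5)
  thr <- activation_threshold(prm, eta = 1, b = b_back)
  frac_active <- apply(traj$K > thr, 1, mean)
  expect_lt(frac_active[length(frac_active)], frac_active[1] - 0.05)
})

test_that("critical fraction bisection brackets and converges", {
  prm <- std_membrane_params(alpha = 3)
  Fc <- critical_fraction_membrane(1e3, prm, F_bounds = c(1e-3, 0.3),
                                   t_end = 200)
  # just below fails, just above activates
  above <- simulate_membrane(prm, receptor_distribution(F = Fc * 1.05, i = 1e3),
                             t_end = 200)
  below <- simulate_membrane(prm, receptor_distribution(F = Fc * 0.95, i = 1e3),
                             t_end = 200)
  expect_true(is_activated(above))
  expect_false(is_activated(below))
  # wash-out: far below the optimal cluster size nothing activates
  expect_warning(
    Fna <- critical_fraction_membrane(3e7, prm, F_bounds = c(1e-5, 5e-4),
                                      t_end = 150),
    "does not activate")
  expect_true(is.na(Fna))
})
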