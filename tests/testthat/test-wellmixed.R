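test_that("steady-state finder agrees with the brute-force sign-scan oracle", {
  prm <- membrane_params(alpha = 3, r_n = 0.95)
  kappa <- prm$a # eta = 1 in the membrane convention
  for (b in c(3, 9, 15, 24, 35)) {
    ss <- find_steady_states(prm, eta = 1, b = b)
    expect_equal(nrow(ss), oracle_root_count(b, kappa, p = 1))
    # each reported root really is a root
    for (K in ss$K) {
      R <- receptor_steady_state(K, 1, prm$c0)
      expect_equal(kappa * R * (1 - K), kinase_sink(K, b, prm$H),
                   tolerance = 1e-8)
    }
  }
})

test_that("fold structure: root count goes 1 -> 3 -> 1 as b sweeps upward", {
  prm <- membrane_params(alpha = 3, r_n = 0.95)
  rng <- bistability_range(prm, eta = 1)
  expect_false(rng$empty)
  expect_lt(rng$b_min, rng$b_max)
  counts <- vapply(c(rng$b_min * 0.8, sqrt(rng$b_min * rng$b_max),
                     rng$b_max * 1.2),
                   function(b) nrow(find_steady_states(prm, eta = 1, b = b)),
                   numeric(1))
  expect_equal(counts, c(1, 3, 1))
  # with three roots the outer two are stable and bracket the unstable one
  ss <- find_steady_states(prm, eta = 1, b = sqrt(rng$b_min * rng$b_max))
  ss <- ss[order(ss$K), ]
  expect_equal(ss$stable, c(TRUE, FALSE, TRUE))
})

test_that("bistable window shifts up with receptor level and shrinks with c0", {
  prm <- membrane_params(alpha = 3, r_n = 0.95)
  r1 <- bistability_range(prm, eta = 1, p = 1)
  rq <- bistability_range(prm, eta = 1, p = prm$q)
  expect_gt(rq$b_min, r1$b_min)
  prm_hi_c0 <- membrane_params(alpha = 3, r_n = 0.95)
  prm_hi_c0$c0 <- 0.05
  r_hi <- bistability_range(prm_hi_c0, eta = 1)
  width <- function(r) log(r$b_max / r$b_min)
  expect_lt(width(r_hi), width(r1))
})

test_that("q-rule calibration is marginal at p = q and bistable at p = 1", {
  prm <- membrane_params(alpha = 3, r_n = 0.95)
  b_q <- calibrate_b_q(prm, eta = 1)
  r1 <- bistability_range(prm, eta = 1, p = 1)
  expect_gt(b_q, r1$b_min)
  expect_lt(b_q, r1$b_max)
  # marginality: just below b_q the p = q system is monostable active,
  # just above it is bistable
  kappa <- prm$a
  expect_equal(oracle_root_count(b_q * 0.995, kappa, p = prm$q), 1)
  expect_equal(oracle_root_count(b_q * 1.005, kappa, p = prm$q), 3)
  # q = 1 limit: b_q collapses onto b_min at p = 1
  prm_q1 <- prm; prm_q1$q <- 1 + 1e-9
  expect_equal(calibrate_b_q(prm_q1, eta = 1), r1$b_min, tolerance = 1e-3)
})

test_that("resting cell is robust to a modest uniform receptor increase", {
  prm <- membrane_params(alpha = 3, r_n = 0.95)
  prm$b <- calibrate_b_q(prm, eta = 1)
  # raise the uniform receptor level to 1.4 p_bar (< q): still returns inactive
  tr <- simulate_wellmixed(prm, init = c(0, 0), t_end = 200, eta = 1, p = 1.4)
  ss <- find_steady_states(prm, eta = 1, p = 1.4)
  expect_equal(tail(tr$K, 1), min(ss$K), tolerance = 1e-5)
  expect_lt(tail(tr$K, 1), 0.1)
})

test_that("trajectories from the basins converge to their stable states", {
  prm <- membrane_params(alpha = 3, r_n = 0.95)
  prm$b <- calibrate_b_q(prm, eta = 1)
  ss <- find_steady_states(prm, eta = 1)
  lo <- simulate_wellmixed(prm, init = c(0, 0), t_end = 100, eta = 1)
  hi <- simulate_wellmixed(prm,
                           init = c(1, receptor_steady_state(1, 1, prm$c0)),
                           t_end = 100, eta = 1)
  expect_equal(tail(lo$K, 1), min(ss$K), tolerance = 1e-5)
  expect_equal(tail(hi$K, 1), max(ss$K), tolerance = 1e-5)
})

test_that("bistability map is consistent with the explicit range finder", {
  m <- bistability_map(c0 = 0.01, B = c(0.1, 0.5, 5), H = c(0.1, 0.5))
  expect_named(m, c("B", "H", "bistable"))
  # point checks against the range finder with unit coupling
  prm <- model_params(a = 1, r_n = 0)
  for (k in seq_len(nrow(m))) {
    prm$H <- m$H[k]
    rng <- bistability_range(prm, eta = 1)
    inside <- !rng$empty && m$B[k] > rng$b_min && m$B[k] < rng$b_max
    expect_identical(m$bistable[k], inside)
  }
  # H = 0.1, c0 = 0.01 admits a nonempty bistable interval in B
  expect_true(any(m$bistable[m$H == 0.1]))
})

test_that("the bistable region narrows with H and closes with larger c0", {
  # either nonlinearity (quadratic drive, saturating sink) alone sustains a
  # narrow window, so at c0 = 0.01 the range stays nonempty but shrinks as
  # the sink saturation weakens (H up); a larger basal activity removes it
  widths <- vapply(c(0.1, 1, 10), function(H) {
    prm <- model_params(a = 1, H = H, r_n = 0)
    rng <- bistability_range(prm, eta = 1)
    expect_false(rng$empty)
    log(rng$b_max / rng$b_min)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  prm <- model_params(a = 1, H = 1, c0 = 0.05, r_n = 0)
  expect_true(bistability_range(prm, eta = 1)$empty)
})
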