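test_that("fcrit sweep produces a well-formed, monotone table", {
  tab <- run_fcrit_sweep("membrane", alpha_list = 3, r_n_list = 0.95,
                         i_list = c(1e3, 1e4), t_end = 200,
                         F_bounds = c(1e-4, 0.1))
  expect_s3_class(tab, "sweep_table")
  expect_named(tab, c("model_tier", "alpha", "r_n", "i", "F", "b", "outcome",
                      "T_A", "F_crit", "b_crit"))
  expect_equal(nrow(tab), 2)
  expect_true(all(!is.na(tab$F_crit)))
  # F_crit decreases with the cluster size 1/i in the near-linear regime
  expect_gt(tab$F_crit[tab$i == 1e3], tab$F_crit[tab$i == 1e4])
  # calibrated b is shared within the configuration and inside the 6-25 band
  expect_equal(length(unique(tab$b)), 1)
  expect_gt(tab$b[1], 6); expect_lt(tab$b[1], 25)
})

test_that("local vs global demo separates the three regimes", {
  prm <- std_membrane_params(alpha = 10)
  tab <- run_local_vs_global_demo(prm, F = 0.1, i_pair = c(1e8, 1e3),
                                  F_large = 0.5, i_large = 100, t_end = 300)
  expect_equal(nrow(tab), 3)
  # same F: tiny cluster (i = 1e8) is washed out locally or stays pinned,
  # the larger one activates globally
  expect_false(tab$outcome[1] == "global")
  expect_equal(tab$outcome[2], "global")
  # F = 0.5 destroys global bistability: activation stays local
  expect_equal(tab$outcome[3], "local_only")
  # outcome consistency: finite T_A iff global
  expect_true(all(is.na(tab$T_A) != (tab$outcome == "global")))
})

test_that("activation time grows roughly linearly with alpha", {
  tab <- run_activation_time_vs_alpha(alpha_list = c(3, 10),
                                      F = 0.05, i = 1e3)
  expect_true(all(tab$outcome == "global"))
  ratio <- tab$T_A[tab$alpha == 10] / tab$T_A[tab$alpha == 3]
  # front transit dominates: T_A ~ alpha/u0, so the ratio tracks 10/3
  expect_gt(ratio, 2)
  expect_lt(ratio, 4.5)
})

test_that("experiment tables are deterministic", {
  t1 <- run_fcrit_sweep("membrane", alpha_list = 3, r_n_list = 0.95,
                        i_list = 1e3, t_end = 150, F_bounds = c(1e-3, 0.3))
  t2 <- run_fcrit_sweep("membrane", alpha_list = 3, r_n_list = 0.95,
                        i_list = 1e3, t_end = 150, F_bounds = c(1e-3, 0.3))
  expect_identical(t1$F_crit, t2$F_crit)
})
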