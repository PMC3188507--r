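# shared fixtures: calibrated parameter bundles, built once per test run
std_membrane_params <- local({
  cache <- NULL
  function(alpha = 3, r_n = 0.95) {
    key <- paste(alpha, r_n)
    if (is.null(cache[[key]])) {
      p <- membrane_params(alpha = alpha, r_n = r_n)
      p$b <- calibrate_b_q(p, eta = 1)
      cache[[key]] <<- p
    }
    cache[[key]]
  }
})

std_cytosol_params <- local({
  cache <- NULL
  function(alpha = 10, r_n = 0.95) {
    key <- paste(alpha, r_n)
    if (is.null(cache[[key]])) {
      p <- model_params(alpha = alpha, r_n = r_n)
      p$b <- calibrate_b_q(p)
      cache[[key]] <<- p
    }
    cache[[key]]
  }
})

# independent brute-force oracle for well-mixed steady states: dense scan of
# the sign of the scalar steady-state function, no root polishing shared with
# the implementation
oracle_root_count <- function(b, kappa, p, c0 = 0.01, H = 0.1, n = 200001) {
  K <- seq(0, 1, length.out = n)
  Rss <- p * (K^2 + c0) / (1 + K^2 + c0)
  g <- kappa * Rss * (1 - K) - b * K / (1 + K / H)
  sum(g[-1] * g[-n] < 0)
}
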