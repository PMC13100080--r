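# Shared fixtures.  Unit tests run on a micro benchmark (125 ms training,
# 500 ms prediction, 100 nodes) so the whole suite stays fast; the
# acceptance tests use the full reduced benchmark via acc_cache().

quick_cfg <- function(...) {
  benchmark_config("reduced", train_ms = 125, predict_ms = 500,
                   rmse_window_ms = 125, n_nodes = 100L, ...)
}

# memoised expensive fixtures
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

quick_data <- function(seed = 1) {
  memo(paste0("qdata", seed), make_benchmark_data(quick_cfg(), seed))
}

# classical fixed-step RK4 integrator, independent of the package's
# Cash-Karp path; used as the fine-step oracle
rk4_hh <- function(state0, params, I, dt, substeps = 10) {
  y <- c(state0$v, state0$m, state0$h, state0$n)
  deriv <- function(y, current) {
    s <- neuron_state(y[1], min(max(y[2], 0), 1), min(max(y[3], 0), 1),
                      min(max(y[4], 0), 1))
    unname(state_derivative(s, params, current))
  }
  n <- length(I)
  out <- matrix(NA_real_, n, 4)
  out[1, ] <- y
  h <- dt / substeps
  for (k in seq_len(n - 1)) {
    for (s in seq_len(substeps)) {
      k1 <- deriv(y, I[k])
      k2 <- deriv(y + h / 2 * k1, I[k])
      k3 <- deriv(y + h / 2 * k2, I[k])
      k4 <- deriv(y + h * k3, I[k])
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y[2:4] <- pmin(pmax(y[2:4], 0), 1)
    }
    out[k + 1, ] <- y
  }
  out
}
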