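test_that("gate steady state follows the sigmoid in both directions", {
  g <- gate_params(v_half = -40, dv = 15, tau0 = 0.1, eps_tau = 0.4, dvt = 15)
  expect_equal(gate_steady_state(-40, g), 0.5)
  # direct evaluation at one sigmoid width above half-activation
  expect_equal(gate_steady_state(-40 + 15, g), 0.5 * (1 + tanh(1)),
               tolerance = 1e-12)
  expect_equal(gate_steady_state(-40 + 15, g), 0.880797077977882,
               tolerance = 1e-12)
  # saturation far above threshold
  expect_lt(abs(gate_steady_state(-40 + 50 * 15, g) - 1), 1e-12)
  # inactivation gate: negative dv flips the curve
  h <- gate_params(-60, -15, 1, 7, 15)
  expect_lt(gate_steady_state(0, h), gate_steady_state(-80, h))
})

test_that("gate time constant is bell-shaped between tau0 and tau0+eps_tau", {
  g <- gate_params(-40, 15, tau0 = 0.3, eps_tau = 1.2, dvt = 20)
  expect_equal(gate_time_constant(-40, g), 0.3 + 1.2)
  expect_lt(abs(gate_time_constant(-40 + 50 * 20, g) - 0.3), 1e-10)
  # one bell width away: tau0 + eps * (1 - tanh^2(1))
  expect_equal(gate_time_constant(-40 + 20, g),
               0.3 + 1.2 * 0.419974341614026, tolerance = 1e-12)
  v <- seq(-120, 60, by = 1)
  taus <- gate_time_constant(v, g)
  expect_true(all(taus >= 0.3 & taus <= 1.5 + 1e-12))
})

test_that("state derivative vanishes at a constructed equilibrium", {
  p <- default_neuron_params()
  v <- -55
  s <- neuron_state(v,
                    gate_steady_state(v, p$gates$m),
                    gate_steady_state(v, p$gates$h),
                    gate_steady_state(v, p$gates$n))
  i_hold <- -(p$g_na * s$m^3 * s$h * (p$e_na - v) +
                p$g_k * s$n^4 * (p$e_k - v) + p$g_l * (p$e_l - v))
  expect_equal(unname(state_derivative(s, p, i_hold)), rep(0, 4),
               tolerance = 1e-12)
  # a single gate at its own steady state has zero rate even off-equilibrium
  s2 <- neuron_state(v, gate_steady_state(v, p$gates$m), 0.2, 0.9)
  expect_equal(unname(state_derivative(s2, p, 0)["m"]), 0, tolerance = 1e-12)
})

test_that("sodium-conductance detuning shifts dV/dt by the closed form", {
  p <- default_neuron_params()
  eps <- 0.37
  p2 <- detune(p, model_error(eps_g = eps))
  s <- neuron_state(-30, 0.4, 0.5, 0.35)
  d1 <- state_derivative(s, p, 3)["v"]
  d2 <- state_derivative(s, p2, 3)["v"]
  expect_equal(unname(d2 - d1),
               eps * p$g_na * s$m^3 * s$h * (p$e_na - s$v) / p$c_m,
               tolerance = 1e-10)
})

test_that("detune touches only the documented fields", {
  p <- default_neuron_params()
  expect_identical(detune(p, model_error(0, 0, 0)), p)
  d <- detune(p, model_error(eps_g = 1))
  expect_equal(d$g_na, 2 * p$g_na)
  d$g_na <- p$g_na
  expect_identical(d, p)
  # eps_v scales the m-gate half-activation voltage
  dv <- detune(p, model_error(eps_v = 0.1))
  expect_equal(dv$gates$m$v_half, p$gates$m$v_half * 1.1)
  dv$gates$m$v_half <- p$gates$m$v_half
  expect_identical(dv, p)
  # eps_tau scales the whole tau_m(V) curve pointwise
  dt2 <- detune(p, model_error(eps_tau = 1))
  v <- seq(-100, 40, by = 5)
  expect_equal(gate_time_constant(v, dt2$gates$m),
               2 * gate_time_constant(v, p$gates$m), tolerance = 1e-12)
  expect_error(detune(p, model_error(eps_v = 2)), NA)
  expect_error(model_error(eps_g = -1), "conductance")
})

test_that("a zero-length protocol returns only the initial state", {
  p <- default_neuron_params()
  s0 <- resting_state(p)
  tr <- integrate_window(s0, p, current_protocol(0, 0.25))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$V_mV, s0$v)
})

test_that("constant subthreshold current relaxes onto the root-finder fixed point", {
  p <- default_neuron_params()
  i0 <- 2
  tr <- integrate_window(resting_state(p), p,
                         current_protocol(rep(i0, 2001), 0.25))
  # independent oracle: root of the full derivative at gates' steady state
  f <- function(v) {
    m <- gate_steady_state(v, p$gates$m); h <- gate_steady_state(v, p$gates$h)
    n <- gate_steady_state(v, p$gates$n)
    p$g_na * m^3 * h * (p$e_na - v) + p$g_k * n^4 * (p$e_k - v) +
      p$g_l * (p$e_l - v) + i0
  }
  v_star <- uniroot(f, c(-90, -40), tol = 1e-12)$root
  expect_equal(tail(tr$V_mV, 1), v_star, tolerance = 1e-5)
  s_end <- neuron_state(tail(tr$V_mV, 1), tail(tr$m, 1), tail(tr$h, 1),
                        tail(tr$n, 1))
  expect_lt(abs(state_derivative(s_end, p, i0)["v"]), 1e-6)
})

test_that("adaptive integration matches a fine-step RK4 oracle on a spiking segment", {
  p <- default_neuron_params()
  s0 <- resting_state(p)
  I <- rep(c(0, 12), each = 100)     # 50 ms with a strong step: spikes
  prot <- current_protocol(I, 0.25)
  tr <- integrate_window(s0, p, prot, rtol = 1e-8, atol = 1e-10)
  expect_gt(count_spikes(tr$V_mV), 0)
  oracle <- rk4_hh(s0, p, I, 0.25, substeps = 25)
  expect_lt(max(abs(tr$V_mV - oracle[, 1])), 1e-3)
  expect_lt(max(abs(as.matrix(tr[, c("m", "h", "n")]) - oracle[, 2:4])), 1e-5)
})

test_that("adaptive integration agrees with deSolve on the same vector field", {
  p <- default_neuron_params()
  s0 <- resting_state(p)
  I <- rep(8, 201)                  # constant drive avoids ZOH differences
  tr <- integrate_window(s0, p, current_protocol(I, 0.25))
  f <- function(t, y, parms) {
    s <- neuron_state(y[1], min(max(y[2], 0), 1), min(max(y[3], 0), 1),
                      min(max(y[4], 0), 1))
    list(unname(state_derivative(s, p, 8)))
  }
  sol <- deSolve::ode(c(s0$v, s0$m, s0$h, s0$n), times = (0:200) * 0.25,
                      func = f, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$V_mV - sol[, 2])), 1e-3)
})

test_that("gates stay in [0,1] and trajectories are deterministic under strong drive", {
  p <- default_neuron_params()
  set.seed(42)
  prot <- current_protocol(runif(2000, -10, 40), 0.25)
  tr1 <- generate_reference(p, prot)
  tr2 <- generate_reference(p, prot)
  expect_identical(tr1, tr2)
  g <- as.matrix(tr1[, c("m", "h", "n")])
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(is.finite(tr1$V_mV)))
})

test_that("the resting fixed point persists for 100 ms at zero current", {
  p <- default_neuron_params()
  s0 <- resting_state(p)
  tr <- integrate_window(s0, p, current_protocol(rep(0, 401), 0.25))
  expect_lt(max(abs(tr$V_mV - s0$v)), 1e-6)
})

test_that("steady-state voltage increases with small subthreshold current", {
  p <- default_neuron_params()
  ends <- vapply(c(0.5, 1.5, 3), function(i0) {
    tr <- integrate_window(resting_state(p), p,
                           current_protocol(rep(i0, 1201), 0.25))
    tail(tr$V_mV, 1)
  }, numeric(1))
  expect_true(all(diff(ends) > 0))
})

test_that("the default mixed protocol elicits spikes and quiet stretches", {
  p <- default_neuron_params()
  prot <- mixed_protocol(protocol_plan(500, 0.25, seed = 11))
  tr <- generate_reference(p, prot)
  expect_gte(count_spikes(tr$V_mV), 1)
  expect_gt(mean(tr$V_mV < -50), 0.2)   # substantial subthreshold time
  quiet <- generate_reference(p, current_protocol(rep(0, 2001), 0.25))
  expect_lt(max(abs(quiet$V_mV - resting_state(p)$v)), 1e-6)
})
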