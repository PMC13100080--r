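test_that("node allocation follows the gamma split with floor-and-remainder", {
  v_asvh <- hybrid_variant("ASVH", "FH")
  expect_equal(unname(build_hybrid_layout(v_asvh, 0.5, 1000)),
               c(250L, 250L, 125L, 125L, 125L, 125L))
  # gamma = 0: all nodes on the data channels
  l0 <- build_hybrid_layout(v_asvh, 0, 1000)
  expect_equal(unname(l0), c(500L, 500L, 0L, 0L, 0L, 0L))
  # OH injection keeps the stand-alone split
  l_oh <- build_hybrid_layout(hybrid_variant("ASVH", "OH"), 0.5, 301)
  expect_equal(unname(l_oh), c(150L, 151L))
  for (g in c(0, 0.13, 0.5, 0.77, 1)) for (n in c(100L, 301L, 1000L)) {
    for (v in list(v_asvh, hybrid_variant("TVH", "IH")))
      expect_equal(sum(build_hybrid_layout(v, g, n)), n)
  }
})

test_that("surrogate teacher step holds at equilibrium and clamps gates", {
  p <- default_neuron_params()
  rest <- resting_state(p)
  s1 <- surrogate_teacher_step(rest, p, v_fb = rest$v, current = 0,
                               dt_ms = 0.25)
  expect_equal(c(s1$v, s1$m, s1$h, s1$n),
               c(rest$v, rest$m, rest$h, rest$n), tolerance = 1e-8)
  # gates stay in [0,1] even for absurd feedback voltages
  s <- rest
  for (vfb in c(-500, 500, -120, 80)) {
    s <- surrogate_teacher_step(s, p, vfb, 10, 0.25)
    expect_true(all(c(s$m, s$h, s$n) >= 0 & c(s$m, s$h, s$n) <= 1))
  }
})

test_that("an exact surrogate teacher-forced by the reference reproduces it", {
  p <- default_neuron_params()
  prot <- mixed_protocol(protocol_plan(100, 0.25, seed = 3))
  ref <- generate_reference(p, prot)
  teach <- reservoirHH:::cpp_surrogate_teacher(
    reservoirHH:::pack_neuron_params(p), ref$V_mV, prot$I, 0.25, 1e-8, 1e-10,
    reservoirHH:::pack_neuron_state(resting_state(p)))
  expect_lt(max(abs(teach$states[, 1] - ref$V_mV[-1])), 1e-4)
})

test_that("regressor widths follow the variant accounting", {
  cfg <- quick_cfg()
  data <- quick_data()
  widths <- c("tvh-ih" = 0L, "tvh-oh" = 1L, "tvh-fh" = 1L,
              "asvh-ih" = 0L, "asvh-oh" = 4L, "asvh-fh" = 4L)
  hc <- reservoir_config(cfg$n_nodes, cfg$hybrid$degree,
                         cfg$hybrid$spectral_radius, cfg$hybrid$sigma,
                         cfg$hybrid$beta, seed = data$seed_hyb)
  prot3 <- current_protocol(data$protocol_train$I[1:3], cfg$dt_ms)
  for (tag in names(widths)) {
    hyb <- new_hybrid(hc, reservoirHH:::variant_from_tag(tag),
                      cfg$neuron, 0.5)
    hyb$scaler_i <- fit_scaler(data$protocol_train$I, cfg$hybrid$sigma)
    hyb$scaler_v <- fit_scaler(data$v_train, cfg$hybrid$sigma)
    reg <- hybrid_collect_states(hyb, prot3, data$v_train[1:3])
    expect_equal(dim(reg), c(cfg$n_nodes + widths[[tag]], 2L),
                 info = tag)
  }
})

test_that("TVH-IH at gamma 0 is bit-identical to the stand-alone reservoir", {
  cfg <- quick_cfg()
  data <- quick_data()
  rc <- reservoir_config(cfg$n_nodes, cfg$hybrid$degree,
                         cfg$hybrid$spectral_radius, cfg$hybrid$sigma,
                         cfg$hybrid$beta, seed = data$seed_hyb)
  res <- reservoir_train(new_reservoir(rc), data$protocol_train, data$v_train)
  hyb <- hybrid_train(new_hybrid(rc, hybrid_variant("TVH", "IH"),
                                 cfg$neuron, gamma = 0),
                      data$protocol_train, data$v_train)
  expect_identical(res$readout$a, hyb$readout$a)
  expect_identical(res$training_rmse, hyb$training_rmse)
  pr <- predict_closed_loop(res, data$protocol_pred)
  ph <- predict_closed_loop(hyb, data$protocol_pred)
  expect_identical(pr$V, ph$V)
})

test_that("hybrid training mean-matches and a richer regressor never fits worse", {
  cfg <- quick_cfg()
  data <- quick_data()
  rc <- reservoir_config(cfg$n_nodes, cfg$hybrid$degree,
                         cfg$hybrid$spectral_radius, cfg$hybrid$sigma,
                         cfg$hybrid$beta, seed = data$seed_hyb)
  hyb <- hybrid_train(new_hybrid(rc, hybrid_variant("ASVH", "FH"),
                                 cfg$neuron, 0.5),
                      data$protocol_train, data$v_train)
  reg <- hybrid_collect_states(hyb, data$protocol_train, data$v_train)
  fitted <- apply_readout(hyb$readout, reg)
  expect_lt(abs(mean(fitted) - mean(data$v_train[-1])), 1e-9)
  # same pool and shared regularisation scale, exact embedded model:
  # the widened ASVH-FH regressor cannot fit worse than TVH-IH at gamma 0
  base <- hybrid_train(new_hybrid(rc, hybrid_variant("TVH", "IH"),
                                  cfg$neuron, gamma = 0),
                       data$protocol_train, data$v_train)
  expect_lte(hyb$training_rmse, base$training_rmse)
  # determinism of the full train + predict pipeline
  hyb2 <- hybrid_train(new_hybrid(rc, hybrid_variant("ASVH", "FH"),
                                  cfg$neuron, 0.5),
                       data$protocol_train, data$v_train)
  expect_identical(predict_closed_loop(hyb, data$protocol_pred)$V,
                   predict_closed_loop(hyb2, data$protocol_pred)$V)
})

test_that("an exact embedded model out-predicts the stand-alone reservoir", {
  cfg <- quick_cfg()
  data <- quick_data()
  rc0 <- reservoir_config(cfg$n_nodes, cfg$reservoir$degree,
                          cfg$reservoir$spectral_radius, cfg$reservoir$sigma,
                          cfg$reservoir$beta, seed = data$seed_res)
  res <- reservoir_train(new_reservoir(rc0), data$protocol_train,
                         data$v_train)
  hc <- reservoir_config(cfg$n_nodes, cfg$hybrid$degree,
                         cfg$hybrid$spectral_radius, cfg$hybrid$sigma,
                         cfg$hybrid$beta, seed = data$seed_hyb)
  hyb <- hybrid_train(new_hybrid(hc, hybrid_variant("ASVH", "FH"),
                                 cfg$neuron, 0.5),
                      data$protocol_train, data$v_train)
  wr <- rmse_windows(predict_closed_loop(res, data$protocol_pred)$V,
                     data$ref_pred_v, cfg$rmse_window_ms, cfg$dt_ms)
  wh <- rmse_windows(predict_closed_loop(hyb, data$protocol_pred)$V,
                     data$ref_pred_v, cfg$rmse_window_ms, cfg$dt_ms)
  expect_lt(wh$median, wr$median)
})

test_that("hybrid prediction returns gates, stays finite, and handles horizon 0", {
  cfg <- quick_cfg()
  data <- quick_data()
  hc <- reservoir_config(cfg$n_nodes, cfg$hybrid$degree,
                         cfg$hybrid$spectral_radius, cfg$hybrid$sigma,
                         cfg$hybrid$beta, seed = data$seed_hyb)
  surrogate <- detune(cfg$neuron, model_error(eps_g = 0.1))
  hyb <- hybrid_train(new_hybrid(hc, hybrid_variant("ASVH", "FH"),
                                 surrogate, 0.5),
                      data$protocol_train, data$v_train)
  p0 <- predict_closed_loop(hyb, data$protocol_pred, 0)
  expect_length(p0$V, 0)
  expect_equal(nrow(p0$gates), 0)
  ph <- predict_closed_loop(hyb, data$protocol_pred)
  expect_length(ph$V, data$horizon)
  expect_equal(dim(ph$gates), c(data$horizon, 3))
  expect_true(all(is.finite(ph$V)))
  expect_true(all(ph$gates >= 0 & ph$gates <= 1))
  expect_error(predict_closed_loop(new_hybrid(hc), data$protocol_pred),
               "untrained")
})

test_that("hidden gates corrected by the hybrid beat the raw surrogate's", {
  # default benchmark conditions (shared with the acceptance cache)
  gm <- memo("acc_gates1_1",
             run_gate_recovery(benchmark_config("reduced"),
                               model_error(eps_g = 1), 1))
  expect_true(all(gm$ratio < 1))
})
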