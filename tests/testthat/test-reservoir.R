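test_that("adjacency is symmetric, regular, and scaled to the target radius", {
  A <- build_adjacency(200, 6, 1.1, seed = 3)
  expect_true(all(A == Matrix::t(A)))
  expect_true(all(Matrix::diag(A) == 0))
  nnz <- Matrix::colSums(A != 0)
  expect_true(all(nnz == 6))                      # exactly D neighbours
  lam <- max(abs(eigen(as.matrix(A), symmetric = TRUE,
                       only.values = TRUE)$values))
  expect_lt(abs(lam - 1.1), 1e-6)
  expect_identical(A, build_adjacency(200, 6, 1.1, seed = 3))
  expect_warning(A2 <- build_adjacency(51, 3, 1, seed = 1), "degree")
  expect_true(all(Matrix::colSums(A2 != 0) %in% c(2, 3)))
})

test_that("input matrix is a one-hot block layout", {
  W <- build_input_matrix(10)
  expect_true(all(rowSums(W) == 1))
  expect_true(all(W %in% c(0, 1)))
  expect_equal(unname(colSums(W)), c(5, 5))
  W4 <- build_input_matrix(4)
  expect_equal(unname(W4), rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
})

test_that("reservoir step is a bounded tanh map", {
  A <- build_adjacency(20, 4, 1, seed = 2)
  W <- build_input_matrix(20)
  expect_equal(reservoir_step(rep(0, 20), A, W, c(0, 0)), rep(0, 20))
  # single unconnected node with unit input weight
  expect_equal(reservoir_step(0, Matrix::Matrix(0, 1, 1, sparse = TRUE),
                              matrix(1, 1, 1), 0.5),
               tanh(0.5), tolerance = 1e-12)
  r <- reservoir_step(runif(20, -1, 1), A, W, c(5, -7))
  expect_true(all(abs(r) < 1))
  expect_error(reservoir_step(c(NA, rep(0, 19)), A, W, c(0, 0)),
               "non-finite")
})

test_that("scalers honour their contracts and round trip", {
  set.seed(1); x <- rnorm(500, 3, 7)
  sr <- fit_scaler(x, 0.4)                        # range reading
  expect_lt(abs(mean(apply_scaler(sr, x))), 1e-12)
  expect_equal(max(abs(apply_scaler(sr, x))), 0.4, tolerance = 1e-12)
  sm <- fit_scaler(x, 0.4, method = "rms")        # rms reading
  expect_lt(abs(mean(apply_scaler(sm, x))), 1e-12)
  expect_equal(sqrt(mean(apply_scaler(sm, x)^2)), 0.4, tolerance = 1e-12)
  for (s in list(sr, sm))
    expect_equal(invert_scaler(s, apply_scaler(s, x)), x, tolerance = 1e-12)
  expect_error(fit_scaler(rep(2, 10), 0.4), "constant")
})

test_that("teacher-forced state collection counts and seeds states correctly", {
  cfg <- reservoir_config(n_nodes = 20, degree = 4, spectral_radius = 1,
                          sigma = 0.4, beta = 1e-4, seed = 7)
  sys <- new_reservoir(cfg)
  prot <- current_protocol(c(1, 2, 3), 0.25)
  v <- c(-60, -55, -50)
  st <- collect_states(sys, prot, v)
  expect_equal(dim(st), c(20, 2))
  # r(0) = 0, so the first state is tanh(W_in v_in(0))
  si <- fit_scaler(prot$I, 0.4); sv <- fit_scaler(v, 0.4)
  vin0 <- c(apply_scaler(si, 1), apply_scaler(sv, -60))
  expect_equal(st[, 1], tanh(vin0[sys$node_ch + 1]), tolerance = 1e-12)
  expect_identical(st, collect_states(sys, prot, v))
})

test_that("ridge readout recovers exact linear targets and matches means", {
  set.seed(5)
  states <- matrix(rnorm(30 * 400), 30, 400)
  w_true <- rnorm(30)
  targets <- as.numeric(crossprod(states, w_true)) + 2.5
  ro <- train_readout(states, targets, beta = 1e-12, sigma = 0.8)
  expect_lt(rmse(apply_readout(ro, states), targets), 1e-6)
  # mean-matching bias contract
  noisy <- targets + rnorm(400)
  ro2 <- train_readout(states, noisy, beta = 1e-2, sigma = 0.8)
  expect_lt(abs(mean(apply_readout(ro2, states)) - mean(noisy)), 1e-9)
})

test_that("ridge shrinkage is monotone in beta", {
  set.seed(6)
  states <- matrix(rnorm(25 * 300), 25, 300)
  targets <- rnorm(300)
  norms <- vapply(c(1e-6, 1e-4, 1e-2), function(b)
    sqrt(sum(train_readout(states, targets, b, 0.8)$w_scaled^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("the ridge solve matches an SVD-based normal-equations oracle", {
  set.seed(20)
  p <- 20; T <- 200; sigma <- 0.8; beta <- 1e-3
  states <- matrix(rnorm(p * T), p, T)
  targets <- rnorm(T)
  ro <- train_readout(states, targets, beta, sigma)
  # independent oracle on the same standardised problem
  centers <- rowMeans(states)
  spreads <- sqrt(rowMeans((states - centers)^2))
  H <- sigma * (states - centers) / spreads
  cy <- mean(targets); sy <- sqrt(mean((targets - cy)^2))
  ys <- sigma * (targets - cy) / sy
  sv <- svd(H)
  w_oracle <- sv$u %*% ((1 / (sv$d^2 + beta)) * crossprod(sv$u, H %*% ys))
  expect_lt(max(abs(ro$w_scaled - w_oracle)), 1e-8)
})

test_that("collinear regressors with beta = 0 fail with actionable advice", {
  states <- matrix(rnorm(100), 10, 10)
  states[2, ] <- states[1, ]
  states <- states[, c(1:10, 1:10)]
  expect_error(train_readout(states, rnorm(20), beta = 0, sigma = 0.8),
               "beta > 0")
})

test_that("node states remain inside (-1, 1) under prolonged bounded drive", {
  cfg <- reservoir_config(50, 6, 1.25, 0.4, 1e-4, seed = 9)
  sys <- new_reservoir(cfg)
  set.seed(9)
  vin <- rbind(runif(10000, -0.4, 0.4), runif(10000, -0.4, 0.4))
  st <- reservoirHH:::cpp_collect_states(sys$A@p, sys$A@i, sys$A@x,
                                         sys$node_ch, vin)
  expect_true(all(abs(st) < 1))
})

test_that("closed-loop reservoir prediction is deterministic and flags saturation honestly", {
  cfg <- quick_cfg()
  data <- quick_data()
  rc <- reservoir_config(cfg$n_nodes, cfg$reservoir$degree,
                         cfg$reservoir$spectral_radius, cfg$reservoir$sigma,
                         cfg$reservoir$beta, seed = data$seed_res)
  sys <- reservoir_train(new_reservoir(rc), data$protocol_train, data$v_train)
  expect_lt(sys$training_rmse, 20)
  p0 <- predict_closed_loop(sys, data$protocol_pred, 0)
  expect_length(p0$V, 0)
  p1 <- predict_closed_loop(sys, data$protocol_pred)
  p2 <- predict_closed_loop(sys, data$protocol_pred)
  expect_identical(p1, p2)
  expect_length(p1$V, data$horizon)
  expect_type(p1$saturated, "logical")
})

test_that("reservoir predicts quiet stretches better than spiking ones", {
  cfg <- quick_cfg()
  data <- quick_data()
  rc <- reservoir_config(cfg$n_nodes, cfg$reservoir$degree,
                         cfg$reservoir$spectral_radius, cfg$reservoir$sigma,
                         cfg$reservoir$beta, seed = data$seed_res)
  sys <- reservoir_train(new_reservoir(rc), data$protocol_train, data$v_train)
  # crafted continuation: a quiet subthreshold stretch, then a strong drive
  n_half <- 1000
  I_cont <- c(rep(1, n_half), rep(15, n_half))
  n_w <- data$n_w
  I_full <- c(data$protocol_train$I, I_cont)
  ref <- generate_reference(cfg$neuron, current_protocol(I_full, cfg$dt_ms))
  pred <- predict_closed_loop(
    sys, current_protocol(I_full[n_w:(n_w + 2 * n_half - 1)], cfg$dt_ms))
  ref_v <- ref$V_mV[(n_w + 1):(n_w + 2 * n_half)]
  expect_equal(count_spikes(ref_v[1:n_half]), 0)
  expect_gt(count_spikes(ref_v[(n_half + 1):(2 * n_half)]), 0)
  err_quiet <- rmse(pred$V[1:n_half], ref_v[1:n_half])
  err_spiking <- rmse(pred$V[(n_half + 1):(2 * n_half)],
                      ref_v[(n_half + 1):(2 * n_half)])
  expect_lt(err_quiet, err_spiking)
})
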