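#' Echo-state reservoir hyperparameters
#'
#' Defaults are the stand-alone reservoir settings: spectral radius 1.25,
#' degree 6, input scaling 0.4, Tikhonov constant 1e-4, 1000 nodes.  The
#' hybrid architectures use [hybrid_reservoir_config()] instead (spectral
#' radius 1, degree 8, input scaling 0.8, Tikhonov constant 1e-3), which
#' trades signal-transfer efficiency for the longer memory retention needed
#' to reconstruct hidden states from delayed voltage observations.
#'
#' @param n_nodes number of reservoir nodes, >= degree + 1.
#' @param degree recurrent connections per node.
#' @param spectral_radius largest-magnitude eigenvalue of the scaled
#'   adjacency matrix, > 0.
#' @param sigma input scaling, in (0, 1).
#' @param beta Tikhonov ridge constant, >= 0.
#' @param seed integer seed for adjacency construction.
#' @return an object of class `reservoir_config`.
#' @export
reservoir_config <- function(n_nodes = 1000, degree = 6,
                             spectral_radius = 1.25, sigma = 0.4,
                             beta = 1e-4, seed = 1L) {
  stopifnot(n_nodes >= degree + 1, spectral_radius > 0,
            sigma > 0, sigma < 1, beta >= 0)
  structure(list(n_nodes = as.integer(n_nodes), degree = as.integer(degree),
                 spectral_radius = spectral_radius, sigma = sigma,
                 beta = beta, seed = as.integer(seed)),
            class = "reservoir_config")
}

#' @rdname reservoir_config
#' @export
hybrid_reservoir_config <- function(n_nodes = 1000, degree = 8,
                                    spectral_radius = 1, sigma = 0.8,
                                    beta = 1e-3, seed = 1L) {
  reservoir_config(n_nodes, degree, spectral_radius, sigma, beta, seed)
}

spectral_radius_sym <- function(A) {
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (i in 1:500) {
    w <- as.numeric(A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v2 <- w / nw
    lam2 <- nw
    if (abs(lam2 - lam) < 1e-13 * max(1, lam2)) return(lam2)
    v <- v2; lam <- lam2
  }
  lam
}

#' Sparse symmetric reservoir adjacency
#'
#' Builds a random graph in which every node has exactly `degree`
#' neighbours (an undirected 0/1 matrix with no self-loops), then rescales
#' it globally so the largest-magnitude eigenvalue equals
#' `spectral_radius`.  The regular-graph reading of the degree makes the
#' per-node fraction of non-zero entries exactly `degree / n_nodes`.
#' When `n_nodes * degree` is odd no regular graph exists; one node is
#' assigned degree `degree - 1` with a warning.
#'
#' @inheritParams reservoir_config
#' @return a symmetric `dgCMatrix` with spectral radius `spectral_radius`.
#' @export
build_adjacency <- function(n_nodes, degree, spectral_radius, seed) {
  stopifnot(n_nodes >= degree + 1, spectral_radius > 0)
  degs <- rep(degree, n_nodes)
  if ((n_nodes * degree) %% 2 == 1) {
    warning("n_nodes * degree is odd; one node gets degree ", degree - 1)
    degs[n_nodes] <- degree - 1
  }
  g <- withr::with_seed(as.integer(seed),
                        igraph::sample_degseq(degs, method = "vl"))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  A@x <- rep(1, length(A@x))
  lam <- spectral_radius_sym(A)
  A * (spectral_radius / lam)
}

# node -> input-channel map (0-based channels) for the stand-alone
# reservoir: first half of nodes wired to I (channel 0), second half to
# V_mem (channel 1); an odd node count puts the extra node on V_mem.
standalone_layout <- function(n_nodes) {
  n_i <- floor(n_nodes / 2)
  c(rep(0L, n_i), rep(1L, n_nodes - n_i))
}

#' Two-channel input matrix
#'
#' One-hot block input layout: the first `floor(n_nodes / 2)` nodes receive
#' the current channel, the remainder the voltage channel, with unit
#' weights.  An odd node count assigns the extra node to the voltage block.
#'
#' @param n_nodes number of reservoir nodes.
#' @return an `n_nodes` x 2 matrix of 0/1 weights, columns `(I, V_mem)`.
#' @export
build_input_matrix <- function(n_nodes) {
  ch <- standalone_layout(n_nodes)
  if (n_nodes %% 2 == 1)
    message("odd node count: extra node assigned to the V_mem block")
  W <- matrix(0, n_nodes, 2, dimnames = list(NULL, c("I", "V_mem")))
  W[cbind(seq_len(n_nodes), ch + 1L)] <- 1
  W
}

#' Single reservoir update
#'
#' `r(t + dt) = tanh(A r(t) + W_in v_in(t))`; entries are strictly inside
#' (-1, 1).
#'
#' @param r node-state vector.
#' @param A (scaled) adjacency matrix.
#' @param w_in input matrix (nodes x channels).
#' @param v_in input vector (one value per channel).
#' @return updated node-state vector.
#' @export
reservoir_step <- function(r, A, w_in, v_in) {
  if (!all(is.finite(r)) || !all(is.finite(v_in)))
    stop("non-finite reservoir input")
  tanh(as.numeric(A %*% r) + as.numeric(w_in %*% v_in))
}

#' Construct an (untrained) stand-alone reservoir
#'
#' @param config a [reservoir_config()] object.
#' @return an object of class `hh_reservoir`.
#' @export
new_reservoir <- function(config) {
  stopifnot(inherits(config, "reservoir_config"))
  A <- build_adjacency(config$n_nodes, config$degree,
                       config$spectral_radius, config$seed)
  structure(list(config = config, A = A,
                 node_ch = standalone_layout(config$n_nodes),
                 scaler_i = NULL, scaler_v = NULL, readout = NULL,
                 r_final = NULL, vfb0 = NULL, dt_ms = NULL),
            class = "hh_reservoir")
}

#' @export
print.hh_reservoir <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("echo-state reservoir: %d nodes, degree %d, rho = %g, sigma = %g, beta = %g (%s)\n",
              cfg$n_nodes, cfg$degree, cfg$spectral_radius, cfg$sigma,
              cfg$beta, if (is.null(x$readout)) "untrained" else "trained"))
  invisible(x)
}

#' Teacher-forced reservoir states over a training window
#'
#' Runs the reservoir from `r(0) = 0` driven by the scaled current and
#' observed voltage, returning the `N_W - 1` node-state vectors aligned
#' with targets `V_mem(dt) ... V_mem((N_W - 1) dt)`.
#'
#' @param system an `hh_reservoir`; if its scalers are unset they are
#'   fitted on the supplied window at the configured input scaling.
#' @param protocol a [current_protocol()] of the training window.
#' @param v_mem observed voltage series aligned with `protocol`.
#' @return matrix with one column per step (`n_nodes` x `N_W - 1`).
#' @export
collect_states <- function(system, protocol, v_mem) {
  stopifnot(inherits(system, "hh_reservoir"))
  n <- length(protocol$I)
  if (length(v_mem) != n) stop("protocol and v_mem lengths differ")
  if (is.null(system$scaler_i))
    system$scaler_i <- fit_scaler(protocol$I, system$config$sigma)
  if (is.null(system$scaler_v))
    system$scaler_v <- fit_scaler(v_mem, system$config$sigma)
  vin <- rbind(apply_scaler(system$scaler_i, protocol$I[-n]),
               apply_scaler(system$scaler_v, v_mem[-n]))
  cpp_collect_states(system$A@p, system$A@i, system$A@x, system$node_ch, vin)
}

#' Ridge-regressed linear readout with mean-matching bias
#'
#' Standardises every regressor (per-regressor centre and RMS spread,
#' scaled to `sigma`) and the target, solves the Tikhonov-regularised
#' normal equations `W = Y H' (H H' + beta I)^-1`, and composes the result
#' into an affine readout in raw units.  Because the regression is run on
#' centred variables, the training-window mean of the predictions equals
#' the training-window mean of the targets by construction (mean-matching
#' bias).  Regressors with (near-)zero spread receive weight zero.
#'
#' @param states regressor matrix, one column per sample.
#' @param targets numeric target vector, one per column of `states`.
#' @param beta Tikhonov constant; with collinear regressors `beta = 0`
#'   fails with advice to use `beta > 0`.
#' @param sigma scaling amplitude used for the standardisation.
#' @return an object of class `rc_readout` with the composed raw-unit
#'   weights `a`, bias `b`, the standardised-space weights `w_scaled`, and
#'   the per-regressor statistics.
#' @export
train_readout <- function(states, targets, beta, sigma) {
  states <- as.matrix(states)
  p <- nrow(states); T <- ncol(states)
  if (length(targets) != T) stop("targets must match the state columns")
  if (T < 2) stop("need at least 2 samples")
  centers <- rowMeans(states)
  dev <- states - centers
  spreads <- sqrt(rowMeans(dev^2))
  dead <- spreads < 1e-12
  spreads[dead] <- 1
  H <- sigma * dev / spreads
  H[dead, ] <- 0
  cy <- mean(targets)
  sy <- sqrt(mean((targets - cy)^2))
  if (sy < 1e-300) stop("constant target series")
  ys <- sigma * (targets - cy) / sy
  G <- tcrossprod(H)
  diag(G) <- diag(G) + beta
  ch <- tryCatch(chol(G), error = function(e)
    stop("normal matrix is singular; use beta > 0 for a regularised solve"))
  w <- backsolve(ch, forwardsolve(t(ch), as.numeric(H %*% ys)))
  a <- w * sy / spreads
  a[dead] <- 0
  b <- cy - sum(a * centers)
  structure(list(a = a, b = b, w_scaled = w, centers = centers,
                 spreads = spreads, dead = dead, target_center = cy,
                 target_spread = sy, beta = beta, sigma = sigma),
            class = "rc_readout")
}

#' @rdname train_readout
#' @param readout an `rc_readout` object.
#' @param regressors matrix (one column per sample) or vector.
#' @export
apply_readout <- function(readout, regressors) {
  stopifnot(inherits(readout, "rc_readout"))
  regressors <- as.matrix(regressors)
  as.numeric(crossprod(regressors, readout$a)) + readout$b
}

#' Train the stand-alone reservoir on a voltage window
#'
#' Fits the input scalers on the training window, collects teacher-forced
#' states and ridge-regresses the readout onto the next-sample voltage.
#' The final reservoir state is retained so that closed-loop prediction
#' continues warm from the end of the window.
#'
#' @inheritParams collect_states
#' @return the trained `hh_reservoir` (with `readout`, `r_final`, `vfb0`
#'   and a `training_rmse` field).
#' @export
reservoir_train <- function(system, protocol, v_mem) {
  stopifnot(inherits(system, "hh_reservoir"))
  n <- length(protocol$I)
  if (length(v_mem) != n) stop("protocol and v_mem lengths differ")
  system$scaler_i <- fit_scaler(protocol$I, system$config$sigma)
  system$scaler_v <- fit_scaler(v_mem, system$config$sigma)
  states <- collect_states(system, protocol, v_mem)
  targets <- v_mem[-1]
  system$readout <- train_readout(states, targets, system$config$beta,
                                  system$config$sigma)
  system$r_final <- states[, ncol(states)]
  system$vfb0 <- apply_readout(system$readout, system$r_final)
  system$dt_ms <- protocol$dt_ms
  system$training_rmse <- rmse(apply_readout(system$readout, states), targets)
  system
}

#' Closed-loop voltage prediction
#'
#' Iterates the trained system with the readout voltage fed back on the
#' observed-voltage channel while the current channel follows the supplied
#' protocol.  Saturated or diverging outputs are returned and flagged,
#' never thrown.
#'
#' @param system a trained `hh_reservoir` or `hh_hybrid`.
#' @param protocol a [current_protocol()] covering the prediction window.
#' @param horizon number of samples to predict (default: the protocol
#'   length).
#' @return a list with `V` (predicted voltage), `saturated` flag and, for
#'   hybrids, the reconstructed `gates` matrix (columns m, h, n).
#' @export
predict_closed_loop <- function(system, protocol, horizon = NULL) {
  UseMethod("predict_closed_loop")
}

#' @export
predict_closed_loop.hh_reservoir <- function(system, protocol,
                                             horizon = NULL) {
  if (is.null(system$readout)) stop("system is untrained")
  if (is.null(horizon)) horizon <- length(protocol$I)
  if (horizon > length(protocol$I)) stop("horizon exceeds protocol length")
  if (horizon == 0)
    return(list(V = numeric(0), saturated = FALSE, nonfinite = FALSE))
  Iraw <- protocol$I[seq_len(horizon)]
  res <- cpp_predict(system$A@p, system$A@i, system$A@x, system$node_ch,
                     system$r_final, system$readout$a, system$readout$b,
                     Iraw, apply_scaler(system$scaler_i, Iraw),
                     0L, FALSE, FALSE, numeric(22), numeric(4),
                     system$vfb0, protocol$dt_ms, 1e-8, 1e-10,
                     system$scaler_v$center, system$scaler_v$spread,
                     system$config$sigma)
  list(V = res$V, saturated = res$saturated, nonfinite = res$nonfinite)
}
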