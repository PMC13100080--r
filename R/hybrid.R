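#' Hybrid reservoir-model architecture variant
#'
#' Six architectures arise from crossing the state scope passed from the
#' embedded surrogate model to the reservoir -- `TVH` (Target Variable
#' Hybrid, voltage only) or `ASVH` (All State Variables Hybrid, V, m, h, n)
#' -- with where the model state is injected: input layer (`IH`), output
#' (readout) layer (`OH`) or both (`FH`).
#'
#' @param scope `"TVH"` or `"ASVH"`.
#' @param injection `"IH"`, `"OH"` or `"FH"`.
#' @return an object of class `hybrid_variant`.
#' @export
hybrid_variant <- function(scope = c("ASVH", "TVH"),
                           injection = c("FH", "IH", "OH")) {
  scope <- match.arg(toupper(scope), c("ASVH", "TVH"))
  injection <- match.arg(toupper(injection), c("FH", "IH", "OH"))
  structure(list(scope = scope, injection = injection,
                 tag = paste0(tolower(scope), "-", tolower(injection))),
            class = "hybrid_variant")
}

variant_from_tag <- function(tag) {
  parts <- strsplit(tolower(tag), "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("variant tag must look like 'asvh-fh'")
  hybrid_variant(parts[1], parts[2])
}

#' Node allocation across input channels
#'
#' Splits the reservoir nodes between the data channels (I, V_mem) and the
#' model channels according to the fraction `gamma` of nodes updated by the
#' model: TVH assigns `(1 - gamma) N_R / 2` nodes to each data channel and
#' `gamma N_R` to the model voltage; ASVH assigns `(1 - gamma) N_R / 2` to
#' each data channel and `gamma N_R / 4` to each of V, m, h, n.  Fractional
#' allocations are floored with the remainder going to the last listed
#' channel.  For `OH` injection the model does not enter the input layer,
#' so the layout reduces to the stand-alone split.
#'
#' @param variant a [hybrid_variant()] object.
#' @param gamma fraction of nodes updated by the model, in `[0, 1]`.
#' @param n_nodes reservoir size.
#' @return named integer vector of per-channel node counts (summing to
#'   `n_nodes`).
#' @export
build_hybrid_layout <- function(variant, gamma, n_nodes) {
  stopifnot(inherits(variant, "hybrid_variant"), gamma >= 0, gamma <= 1)
  if (variant$injection == "OH") {
    n_i <- floor(n_nodes / 2)
    counts <- c(I = n_i, V_mem = n_nodes - n_i)
  } else if (variant$scope == "TVH") {
    n_i <- floor((1 - gamma) * n_nodes / 2)
    counts <- c(I = n_i, V_mem = n_i, V = n_nodes - 2 * n_i)
  } else {
    n_i <- floor((1 - gamma) * n_nodes / 2)
    n_g <- floor(gamma * n_nodes / 4)
    counts <- c(I = n_i, V_mem = n_i, V = n_g, m = n_g, h = n_g,
                n = n_nodes - 2 * n_i - 3 * n_g)
  }
  storage.mode(counts) <- "integer"
  counts
}

layout_to_node_ch <- function(counts) {
  rep(seq_along(counts) - 1L, times = counts)
}

#' Construct an (untrained) hybrid reservoir-model system
#'
#' Couples an echo-state reservoir to an embedded (typically detuned)
#' surrogate Hodgkin-Huxley model.  During teacher-forced training the
#' surrogate's voltage is overwritten each step by the observed voltage
#' while its gates persist; in closed-loop prediction the readout voltage
#' takes that role, which is what turns the surrogate's gate trajectories
#' into the corrected hidden-state reconstruction.
#'
#' @param config a [reservoir_config()]; defaults to
#'   [hybrid_reservoir_config()] values.
#' @param variant a [hybrid_variant()] object.
#' @param surrogate a [neuron_params()] object, usually [detune()]d.
#' @param gamma fraction of reservoir nodes updated by the model state.
#' @param rtol,atol integrator tolerances for the embedded model.
#' @return an object of class `hh_hybrid`.
#' @export
new_hybrid <- function(config = hybrid_reservoir_config(),
                       variant = hybrid_variant("ASVH", "FH"),
                       surrogate = default_neuron_params(), gamma = 0.5,
                       rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(config, "reservoir_config"),
            inherits(variant, "hybrid_variant"),
            inherits(surrogate, "neuron_params"))
  A <- build_adjacency(config$n_nodes, config$degree,
                       config$spectral_radius, config$seed)
  layout <- build_hybrid_layout(variant, gamma, config$n_nodes)
  structure(list(config = config, A = A, variant = variant, gamma = gamma,
                 layout = layout, node_ch = layout_to_node_ch(layout),
                 surrogate = surrogate, rtol = rtol, atol = atol,
                 scaler_i = NULL, scaler_v = NULL, readout = NULL,
                 r_final = NULL, surr_final = NULL, vfb0 = NULL,
                 dt_ms = NULL),
            class = "hh_hybrid")
}

#' @export
print.hh_hybrid <- function(x, ...) {
  cat(sprintf("hybrid reservoir-HH system: %s, gamma = %g, %d nodes (%s)\n",
              toupper(x$variant$tag), x$gamma, x$config$n_nodes,
              if (is.null(x$readout)) "untrained" else "trained"))
  cat("  input-layer nodes:",
      paste(names(x$layout), x$layout, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' One teacher-forced surrogate step
#'
#' Overwrites the model voltage with the feedback voltage (the observed
#' voltage in training, the readout voltage in prediction), keeps the
#' model's own gate values, and integrates one sampling interval with the
#' adaptive Cash-Karp scheme.
#'
#' @param state the surrogate's current [neuron_state()].
#' @param params surrogate [neuron_params()].
#' @param v_fb feedback voltage (mV).
#' @param current injected current held over the interval (uA/cm^2).
#' @param dt_ms sampling interval (ms).
#' @param rtol,atol integrator tolerances.
#' @return the surrogate [neuron_state()] at `t + dt`.
#' @export
surrogate_teacher_step <- function(state, params, v_fb, current, dt_ms,
                                   rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  res <- cpp_surrogate_teacher(pack_neuron_params(params), c(v_fb, NA),
                               c(current, current), dt_ms, rtol, atol,
                               pack_neuron_state(state))
  if (res$status == 2) stop("surrogate integration produced non-finite state")
  s <- res$states[1, ]
  neuron_state(s[1], s[2], s[3], s[4])
}

# input rows for the model channels wired to the input layer: the model
# state enters raw (V in mV, gates in [0, 1]).  The standardising scaler S
# is defined for the data channels (V_mem, I) only; passing the model
# voltage unscaled drives its nodes into tanh saturation, which turns them
# into near-binary spike indicators and, crucially, stops a badly detuned
# model from injecting large fluctuations into the recurrent pool.
model_input_rows <- function(system, X) {
  if (!(system$variant$injection %in% c("IH", "FH"))) return(NULL)
  if (system$variant$scope == "ASVH") t(X) else rbind(X[, 1])
}

# model outputs appended to the regressor vector (raw units)
model_output_rows <- function(system, X) {
  if (!(system$variant$injection %in% c("OH", "FH"))) return(NULL)
  if (system$variant$scope == "ASVH") t(X) else rbind(X[, 1])
}

#' Teacher-forced regressors for a hybrid system
#'
#' Runs the embedded surrogate teacher-forced along the observed voltage,
#' assembles the per-variant input vector (scaled current and voltage,
#' plus -- for IH/FH -- the model state: its voltage through the voltage
#' scaler, its gates through the fixed affine map `chi -> sigma (2 chi - 1)`
#' into `[-sigma, sigma]`), drives the reservoir, and returns the regressor
#' matrix: node states, concatenated -- for OH/FH -- with the model output
#' components.
#'
#' @param system an `hh_hybrid` (scalers fitted if unset).
#' @param protocol training-window [current_protocol()].
#' @param v_mem observed voltage aligned with `protocol`.
#' @return regressor matrix, one column per step, with attribute
#'   `"surrogate_states"` holding the teacher-forced model states.
#' @export
hybrid_collect_states <- function(system, protocol, v_mem) {
  stopifnot(inherits(system, "hh_hybrid"))
  n <- length(protocol$I)
  if (length(v_mem) != n) stop("protocol and v_mem lengths differ")
  if (is.null(system$scaler_i))
    system$scaler_i <- fit_scaler(protocol$I, system$config$sigma)
  if (is.null(system$scaler_v))
    system$scaler_v <- fit_scaler(v_mem, system$config$sigma)
  x0 <- resting_state(system$surrogate)
  teach <- cpp_surrogate_teacher(pack_neuron_params(system$surrogate),
                                 v_mem, protocol$I, protocol$dt_ms,
                                 system$rtol, system$atol,
                                 pack_neuron_state(x0))
  if (teach$status == 2)
    stop("surrogate integration produced non-finite state during training")
  X <- teach$states                      # (n-1) x 4: V, m, h, n at t + dt
  vin <- rbind(apply_scaler(system$scaler_i, protocol$I[-n]),
               apply_scaler(system$scaler_v, v_mem[-n]),
               model_input_rows(system, X))
  states <- cpp_collect_states(system$A@p, system$A@i, system$A@x,
                               system$node_ch, vin)
  reg <- rbind(states, model_output_rows(system, X))
  attr(reg, "surrogate_states") <- X
  attr(reg, "n_nodes") <- nrow(states)
  reg
}

#' Train a hybrid reservoir-model system
#'
#' Collects teacher-forced regressors and ridge-regresses the readout onto
#' the next-sample observed voltage; final reservoir and surrogate states
#' are stored for warm-start closed-loop prediction.
#'
#' @inheritParams hybrid_collect_states
#' @return the trained `hh_hybrid`.
#' @export
hybrid_train <- function(system, protocol, v_mem) {
  stopifnot(inherits(system, "hh_hybrid"))
  system$scaler_i <- fit_scaler(protocol$I, system$config$sigma)
  system$scaler_v <- fit_scaler(v_mem, system$config$sigma)
  reg <- hybrid_collect_states(system, protocol, v_mem)
  targets <- v_mem[-1]
  system$readout <- train_readout(reg, targets, system$config$beta,
                                  system$config$sigma)
  X <- attr(reg, "surrogate_states")
  system$r_final <- reg[seq_len(attr(reg, "n_nodes")), ncol(reg)]
  system$surr_final <- X[nrow(X), ]
  system$vfb0 <- apply_readout(system$readout, reg[, ncol(reg)])
  system$dt_ms <- protocol$dt_ms
  system$training_rmse <- rmse(apply_readout(system$readout, reg), targets)
  system
}

#' @export
predict_closed_loop.hh_hybrid <- function(system, protocol, horizon = NULL) {
  if (is.null(system$readout)) stop("system is untrained")
  if (is.null(horizon)) horizon <- length(protocol$I)
  if (horizon > length(protocol$I)) stop("horizon exceeds protocol length")
  if (horizon == 0)
    return(list(V = numeric(0),
                gates = matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("m", "h", "n"))),
                saturated = FALSE, nonfinite = FALSE))
  Iraw <- protocol$I[seq_len(horizon)]
  scope <- if (system$variant$scope == "ASVH") 4L else 1L
  res <- cpp_predict(system$A@p, system$A@i, system$A@x, system$node_ch,
                     system$r_final, system$readout$a, system$readout$b,
                     Iraw, apply_scaler(system$scaler_i, Iraw),
                     scope,
                     system$variant$injection %in% c("IH", "FH"),
                     system$variant$injection %in% c("OH", "FH"),
                     pack_neuron_params(system$surrogate),
                     system$surr_final, system$vfb0, protocol$dt_ms,
                     system$rtol, system$atol,
                     system$scaler_v$center, system$scaler_v$spread,
                     system$config$sigma)
  gates <- res$gates
  colnames(gates) <- c("m", "h", "n")
  list(V = res$V, gates = gates, saturated = res$saturated,
       nonfinite = res$nonfinite)
}
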