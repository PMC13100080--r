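#' Root-mean-square error
#'
#' @param pred,ref equal-length numeric vectors.
#' @return `sqrt(mean((pred - ref)^2))`; `NA` values propagate (flagged
#'   saturated runs are never silently dropped).
#' @export
rmse <- function(pred, ref) {
  if (length(pred) == 0) stop("empty input")
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  sqrt(mean((pred - ref)^2))
}

#' Windowed RMSE with interquartile dispersion
#'
#' Partitions the prediction into consecutive non-overlapping windows of
#' `window_ms`, computes the RMSE in each, and reports the per-window
#' values together with their median and interquartile range.  A trailing
#' partial window is dropped (with a message).
#'
#' @param pred,ref aligned voltage series.
#' @param window_ms window length (ms).
#' @param dt_ms sampling interval (ms).
#' @return an object of class `windowed_error`: list with `window_ms`,
#'   `rmse` (per-window vector), `median`, `iqr`, `n_windows`.
#' @export
rmse_windows <- function(pred, ref, window_ms, dt_ms) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  n_per <- round(window_ms / dt_ms)
  if (n_per < 1 || n_per > length(pred))
    stop("window longer than the series")
  k <- floor(length(pred) / n_per)
  dropped <- length(pred) - k * n_per
  if (dropped > 0)
    message(dropped, " trailing samples dropped from a partial window")
  vals <- vapply(seq_len(k), function(i) {
    idx <- ((i - 1) * n_per + 1):(i * n_per)
    rmse(pred[idx], ref[idx])
  }, numeric(1))
  structure(list(window_ms = window_ms, rmse = vals,
                 median = median(vals), iqr = IQR(vals), n_windows = k),
            class = "windowed_error")
}

#' @export
print.windowed_error <- function(x, ...) {
  cat(sprintf("windowed RMSE: %d windows of %g ms; median = %.4g, IQR = %.4g\n",
              x$n_windows, x$window_ms, x$median, x$iqr))
  invisible(x)
}

#' Benchmark configuration
#'
#' Bundles every setting of the reference-data / training / prediction
#' benchmark.  `"reduced"` is the default desk-scale study: 312.5 ms
#' training window (12501 samples at dt = 0.025 ms), 2500 ms prediction
#' window, 300-node reservoirs and 312.5 ms RMSE windows (8 windows).
#' `"paper"` restores the full-scale settings (1250 ms / 50001-sample
#' training, 5500 ms prediction, 1000 nodes, 1250 ms RMSE windows).
#'
#' @param scale `"reduced"` or `"paper"`.
#' @param ... named overrides of any top-level field.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(scale = c("reduced", "paper"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    scale = scale,
    neuron = default_neuron_params(),
    dt_ms = 0.25,
    train_ms = if (scale == "reduced") 312.5 else 1250,
    predict_ms = if (scale == "reduced") 2500 else 5500,
    rmse_window_ms = if (scale == "reduced") 312.5 else 1250,
    n_nodes = if (scale == "reduced") 300L else 1000L,
    reservoir = list(degree = 6L, spectral_radius = 1.25, sigma = 0.4,
                     beta = 1e-4),
    hybrid = list(degree = 8L, spectral_radius = 1, sigma = 0.8,
                  beta = 1e-3),
    gamma = 0.5,
    lorenz = lorenz_params(),
    steps = step_params(),
    target_range = c(-2, 22),
    mean_segment_ms = 50,
    rtol = 1e-8, atol = 1e-10
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown benchmark fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "benchmark_config")
}

#' Generate shared benchmark data for one seed
#'
#' Draws sub-seeds for the training protocol, the (distinct) prediction
#' protocol and the two adjacency matrices, generates the full-epoch mixed
#' protocol, and integrates the reference neuron from rest over the whole
#' epoch, so that training data and held-out prediction references (voltage
#' and hidden gates) share one trajectory.
#'
#' @param cfg a [benchmark_config()].
#' @param seed integer replicate seed.
#' @return a list with the protocols, reference series and sub-seeds.
#' @export
make_benchmark_data <- function(cfg, seed) {
  stopifnot(inherits(cfg, "benchmark_config"))
  ss <- derive_seeds(seed, 4L)
  dt <- cfg$dt_ms
  n_w <- round(cfg$train_ms / dt) + 1L
  horizon <- round(cfg$predict_ms / dt)
  pt <- mixed_protocol(protocol_plan(cfg$train_ms, dt, cfg$target_range,
                                     cfg$mean_segment_ms, seed = ss[1]),
                       cfg$lorenz, cfg$steps)
  pp <- mixed_protocol(protocol_plan(cfg$predict_ms, dt, cfg$target_range,
                                     cfg$mean_segment_ms, seed = ss[2]),
                       cfg$lorenz, cfg$steps)
  I_full <- c(pt$I, pp$I[-1])
  full <- current_protocol(I_full, dt)
  ref <- generate_reference(cfg$neuron, full, cfg$rtol, cfg$atol)
  pred_rows <- (n_w + 1):(n_w + horizon)
  list(seed = seed, n_w = n_w, horizon = horizon, dt_ms = dt,
       protocol_train = current_protocol(I_full[1:n_w], dt),
       protocol_pred = current_protocol(I_full[n_w:(n_w + horizon - 1)], dt),
       protocol_full = full,
       v_train = ref$V_mV[1:n_w],
       ref_pred_v = ref$V_mV[pred_rows],
       ref_pred_gates = as.matrix(ref[pred_rows, c("m", "h", "n")]),
       seed_res = ss[3], seed_hyb = ss[4])
}

build_benchmark_system <- function(cfg, data, tag, surrogate) {
  if (tag == "reservoir") {
    rc <- reservoir_config(cfg$n_nodes, cfg$reservoir$degree,
                           cfg$reservoir$spectral_radius,
                           cfg$reservoir$sigma, cfg$reservoir$beta,
                           seed = data$seed_res)
    new_reservoir(rc)
  } else {
    hc <- reservoir_config(cfg$n_nodes, cfg$hybrid$degree,
                           cfg$hybrid$spectral_radius, cfg$hybrid$sigma,
                           cfg$hybrid$beta, seed = data$seed_hyb)
    new_hybrid(hc, variant_from_tag(tag), surrogate, cfg$gamma,
               cfg$rtol, cfg$atol)
  }
}

#' Train and run one system on shared benchmark data
#'
#' `tag` selects the system: `"surrogate"` (the raw detuned model
#' integrated open loop from its own rest over the full epoch),
#' `"reservoir"` (stand-alone echo-state reservoir) or a hybrid tag such
#' as `"asvh-fh"`, `"tvh-ih"`, ...  Failed or saturated runs are returned
#' with a flag, never dropped.
#'
#' @param cfg a [benchmark_config()].
#' @param data output of [make_benchmark_data()].
#' @param tag system identifier.
#' @param surrogate detuned [neuron_params()] (ignored for
#'   `"reservoir"`).
#' @return list with predicted `V` over the prediction window, `gates`
#'   (matrix or NULL) and `saturated` flag.
#' @export
run_benchmark_system <- function(cfg, data, tag, surrogate = cfg$neuron) {
  if (tag == "surrogate") {
    out <- tryCatch({
      traj <- integrate_window(resting_state(surrogate), surrogate,
                               data$protocol_full, cfg$rtol, cfg$atol)
      rows <- (data$n_w + 1):(data$n_w + data$horizon)
      list(V = traj$V_mV[rows],
           gates = as.matrix(traj[rows, c("m", "h", "n")]),
           saturated = FALSE)
    }, error = function(e) list(V = rep(NA_real_, data$horizon),
                                gates = NULL, saturated = TRUE))
    return(out)
  }
  sys <- build_benchmark_system(cfg, data, tag, surrogate)
  sys <- if (tag == "reservoir")
    reservoir_train(sys, data$protocol_train, data$v_train)
  else
    hybrid_train(sys, data$protocol_train, data$v_train)
  pred <- predict_closed_loop(sys, data$protocol_pred, data$horizon)
  list(V = pred$V, gates = pred$gates, saturated = pred$saturated)
}

error_for <- function(error_type, eps) {
  switch(error_type,
         eps_g = model_error(eps_g = eps),
         eps_v = model_error(eps_v = eps),
         eps_tau = model_error(eps_tau = eps),
         combined = model_error(eps, eps, eps),
         stop("unknown error_type: ", error_type))
}

#' Model-error sweep across systems
#'
#' For each replicate seed and each detuning on the grid, trains the
#' requested systems on shared reference data and evaluates their windowed
#' prediction RMSE on the held-out protocol.  The stand-alone reservoir is
#' detuning-independent and is trained once per seed.  Fully reproducible
#' from the seeds.
#'
#' @param cfg a [benchmark_config()].
#' @param error_type one of `"eps_g"`, `"eps_v"`, `"eps_tau"`,
#'   `"combined"` (all three detuned at once).
#' @param grid numeric vector of fractional detunings.
#' @param systems character vector of system tags (see
#'   [run_benchmark_system()]).
#' @param seeds integer vector of replicate seeds.
#' @return a data frame of class `sweep_table` with columns
#'   `error_type, eps, system, seed, window, rmse, saturated`.
#' @export
sweep_model_error <- function(cfg, error_type, grid, systems, seeds) {
  stopifnot(inherits(cfg, "benchmark_config"), length(grid) >= 1)
  rows <- list()
  for (seed in seeds) {
    data <- make_benchmark_data(cfg, seed)
    res_cache <- NULL
    for (eps in grid) {
      surrogate <- detune(cfg$neuron, error_for(error_type, eps))
      for (tag in systems) {
        if (tag == "reservoir" && is.null(res_cache))
          res_cache <- run_benchmark_system(cfg, data, tag)
        run <- if (tag == "reservoir") res_cache
               else run_benchmark_system(cfg, data, tag, surrogate)
        we <- suppressMessages(
          rmse_windows(run$V, data$ref_pred_v, cfg$rmse_window_ms, data$dt_ms))
        rows[[length(rows) + 1L]] <- data.frame(
          error_type = error_type, eps = eps, system = tag, seed = seed,
          window = seq_len(we$n_windows), rmse = we$rmse,
          saturated = run$saturated)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Summarise a sweep table
#'
#' Median per-window RMSE per (eps, system, seed), plus the across-seed
#' median and interquartile range per (eps, system).  Medians (not means)
#' are used throughout, matching the interquartile reporting style of the
#' windowed-RMSE benchmark.
#'
#' @param table a `sweep_table` from [sweep_model_error()].
#' @return list with `per_seed` and `summary` data frames.
#' @export
sweep_summary <- function(table) {
  per_seed <- aggregate(rmse ~ error_type + eps + system + seed, table,
                        median)
  names(per_seed)[names(per_seed) == "rmse"] <- "median_rmse"
  med <- aggregate(median_rmse ~ error_type + eps + system, per_seed, median)
  iqr <- aggregate(median_rmse ~ error_type + eps + system, per_seed, IQR)
  names(med)[4] <- "median_rmse"
  names(iqr)[4] <- "iqr_rmse"
  list(per_seed = per_seed, summary = merge(med, iqr))
}

median_by_eps <- function(table, system) {
  ps <- sweep_summary(table)$per_seed
  ps <- ps[ps$system == system, ]
  agg <- aggregate(median_rmse ~ eps, ps, median)
  agg[order(agg$eps), ]
}

#' Crossover points between two systems on a sweep grid
#'
#' Locates the grid intervals bounding each sign change of
#' `median_rmse(system_a) - median_rmse(system_b)` across the detuning
#' grid (medians taken over windows, then over seeds).
#'
#' @param table a `sweep_table`.
#' @param system_a,system_b system tags present in the table.
#' @return data frame with columns `lower`, `upper` (one row per sign
#'   change; zero rows when one system dominates the whole grid).
#' @export
crossover_points <- function(table, system_a, system_b) {
  ma <- median_by_eps(table, system_a)
  mb <- median_by_eps(table, system_b)
  if (nrow(ma) == 0 || nrow(mb) == 0)
    stop("both systems must be present in the table")
  m <- merge(ma, mb, by = "eps", suffixes = c("_a", "_b"))
  m <- m[order(m$eps), ]
  d <- sign(m$median_rmse_a - m$median_rmse_b)
  idx <- which(d[-1] * d[-length(d)] < 0)
  data.frame(lower = m$eps[idx], upper = m$eps[idx + 1])
}

#' Largest grid detuning at which one system beats another
#'
#' Per replicate seed, finds the largest grid value at which the winner's
#' median windowed RMSE is strictly below the loser's (0 when it never
#' wins), then returns the median across seeds.  With
#' `winner = "surrogate"` this measures the reservoir-noise floor below
#' which hybrid correction cannot help; with the hybrid as winner it
#' measures the upper working range of model-error correction.
#'
#' @param table a `sweep_table`.
#' @param winner,loser system tags.
#' @return median (across seeds) of the per-seed largest winning
#'   detuning (fractional).
#' @export
largest_winning_eps <- function(table, winner, loser) {
  ps <- sweep_summary(table)$per_seed
  seeds <- unique(ps$seed)
  per_seed <- vapply(seeds, function(s) {
    a <- ps[ps$seed == s & ps$system == winner, c("eps", "median_rmse")]
    b <- ps[ps$seed == s & ps$system == loser, c("eps", "median_rmse")]
    m <- merge(a, b, by = "eps", suffixes = c("_w", "_l"))
    wins <- m$eps[m$median_rmse_w < m$median_rmse_l]
    if (length(wins)) max(wins) else 0
  }, numeric(1))
  median(per_seed)
}

#' Gate-recovery metrics
#'
#' Per gate (m, h, n): RMSE of the corrected (hybrid-reconstructed) gate
#' trajectory against the reference hidden trajectory, the same for the
#' raw detuned surrogate, and the improvement ratio corrected / raw (0
#' when both are exact, 1 when correction changed nothing).
#'
#' @param corrected,raw,reference matrices (or data frames) with columns
#'   `m`, `h`, `n`, row-aligned.
#' @return data frame with one row per gate: `gate, rmse_corrected,
#'   rmse_raw, ratio`.
#' @export
gate_recovery_metrics <- function(corrected, raw, reference) {
  corrected <- as.matrix(corrected); raw <- as.matrix(raw)
  reference <- as.matrix(reference)
  if (nrow(corrected) != nrow(reference) || nrow(raw) != nrow(reference))
    stop("gate trajectories must be aligned")
  out <- lapply(c("m", "h", "n"), function(g) {
    rc <- rmse(corrected[, g], reference[, g])
    rr <- rmse(raw[, g], reference[, g])
    ratio <- if (rr > 0) rc / rr else if (rc == 0) 0 else Inf
    data.frame(gate = g, rmse_corrected = rc, rmse_raw = rr, ratio = ratio)
  })
  do.call(rbind, out)
}

#' Hidden-gate recovery benchmark for one detuning and seed
#'
#' Trains the requested hybrid on shared benchmark data, predicts in
#' closed loop, and compares its reconstructed gate trajectories and the
#' raw detuned surrogate's gates against the reference hidden
#' trajectories.
#'
#' @param cfg a [benchmark_config()].
#' @param error a [model_error()].
#' @param seed replicate seed.
#' @param tag hybrid variant tag.
#' @return output of [gate_recovery_metrics()].
#' @export
run_gate_recovery <- function(cfg, error, seed, tag = "asvh-fh") {
  data <- make_benchmark_data(cfg, seed)
  surrogate <- detune(cfg$neuron, error)
  hyb <- run_benchmark_system(cfg, data, tag, surrogate)
  raw <- run_benchmark_system(cfg, data, "surrogate", surrogate)
  gate_recovery_metrics(hyb$gates, raw$gates, data$ref_pred_gates)
}

#' Reservoir-size and model-fraction study
#'
#' Median windowed prediction RMSE as a function of reservoir size (hybrid
#' and stand-alone reservoir) and of the fraction `gamma` of nodes updated
#' by the model, with a plateau flag marking the first size at which the
#' relative improvement per doubling drops below `plateau_threshold`.
#'
#' @param cfg a [benchmark_config()].
#' @param n_grid integer vector of reservoir sizes.
#' @param gamma_grid numeric vector of model fractions in `[0.1, 0.9]`.
#' @param seeds replicate seeds.
#' @param error a [model_error()] defining the surrogate used.
#' @param plateau_threshold relative improvement per doubling below which
#'   the size curve is declared flat.
#' @return list with `size` and `gamma` data frames and `plateau_n`.
#' @export
size_and_gamma_study <- function(cfg, n_grid, gamma_grid, seeds,
                                 error = model_error(eps_g = 0.1),
                                 plateau_threshold = 0.1) {
  stopifnot(length(n_grid) >= 1, length(gamma_grid) >= 1)
  surrogate <- detune(cfg$neuron, error)
  cell <- function(cfg2, tag) {
    vapply(seeds, function(s) {
      data <- make_benchmark_data(cfg2, s)
      run <- run_benchmark_system(cfg2, data, tag, surrogate)
      suppressMessages(rmse_windows(run$V, data$ref_pred_v,
                                    cfg2$rmse_window_ms, data$dt_ms))$median
    }, numeric(1))
  }
  size_rows <- do.call(rbind, lapply(n_grid, function(n) {
    cfg2 <- cfg; cfg2$n_nodes <- as.integer(n)
    data.frame(n_nodes = n,
               hybrid = median(cell(cfg2, "asvh-fh")),
               reservoir = median(cell(cfg2, "reservoir")))
  }))
  gamma_rows <- do.call(rbind, lapply(gamma_grid, function(g) {
    cfg2 <- cfg; cfg2$gamma <- g
    data.frame(gamma = g, hybrid = median(cell(cfg2, "asvh-fh")))
  }))
  plateau_n <- NA_integer_
  if (nrow(size_rows) >= 2) {
    for (i in 2:nrow(size_rows)) {
      rel <- (size_rows$hybrid[i - 1] - size_rows$hybrid[i]) /
        size_rows$hybrid[i - 1]
      per_doubling <- rel / log2(size_rows$n_nodes[i] /
                                   size_rows$n_nodes[i - 1])
      if (is.finite(per_doubling) && per_doubling < plateau_threshold) {
        plateau_n <- size_rows$n_nodes[i]
        break
      }
    }
  }
  list(size = size_rows, gamma = gamma_rows, plateau_n = plateau_n)
}
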