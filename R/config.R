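# Structured run configuration: YAML file mirroring the package defaults,
# with unknown keys rejected and invariants validated on load.

default_run_config <- function() {
  list(
    neuron = list(
      c_m = 1, g_na = 120, g_k = 36, g_l = 0.3,
      e_na = 50, e_k = -77, e_l = -54.4,
      gates = list(
        m = list(v_half = -40, dv = 15, tau0 = 0.1, eps_tau = 0.4, dvt = 15),
        h = list(v_half = -60, dv = -15, tau0 = 1, eps_tau = 7, dvt = 15),
        n = list(v_half = -55, dv = 30, tau0 = 1, eps_tau = 5, dvt = 30)
      )
    ),
    stimulus = list(
      lorenz = list(alpha = 10, rho = 28, beta = 8 / 3, ic = c(1, 1, 1),
                    time_scale = 25),
      steps = list(amp_min = -20, amp_max = 20, dur_min = 5, dur_max = 50),
      plan = list(mean_segment_ms = 50, target_min = -2, target_max = 22)
    ),
    windows = list(dt_ms = 0.25, train_ms = 312.5, predict_ms = 2500,
                   rmse_window_ms = 312.5),
    reservoir = list(n_nodes = 300, degree = 6, spectral_radius = 1.25,
                     sigma = 0.4, beta = 1e-4),
    hybrid = list(n_nodes = 300, degree = 8, spectral_radius = 1,
                  sigma = 0.8, beta = 1e-3, gamma = 0.5,
                  variant = list(scope = "ASVH", injection = "FH")),
    model_error = list(eps_g = 0, eps_v = 0, eps_tau = 0),
    sweep = list(error_type = "eps_g",
                 grid = 10^seq(-4, 2),
                 systems = c("surrogate", "asvh-fh"),
                 n_seeds = 5),
    seeds = list(master = 1),
    output_dir = "."
  )
}

merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config field '", paste(path, collapse = "."),
                           "' must be a mapping")
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key: ",
         paste(paste(c(path, bad[1]), collapse = "."), collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      val <- user[[nm]]
      if (is.list(val)) val <- unlist(val)
      if (is.numeric(defaults[[nm]]) && !is.numeric(val))
        stop("config field '", paste(c(path, nm), collapse = "."),
             "' must be numeric")
      defaults[[nm]] <- val
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  w <- cfg$windows
  if (w$dt_ms <= 0) stop("windows.dt_ms must be > 0")
  for (f in c("train_ms", "predict_ms", "rmse_window_ms")) {
    r <- w[[f]] / w$dt_ms
    if (abs(r - round(r)) > 1e-8)
      stop("windows.", f, " must be a multiple of windows.dt_ms")
  }
  for (tbl in c("reservoir", "hybrid")) {
    h <- cfg[[tbl]]
    if (h$sigma <= 0 || h$sigma >= 1) stop(tbl, ".sigma must be in (0, 1)")
    if (h$n_nodes < h$degree + 1) stop(tbl, ".n_nodes must be >= degree + 1")
  }
  if (cfg$hybrid$gamma < 0 || cfg$hybrid$gamma > 1)
    stop("hybrid.gamma must be in [0, 1]")
  if (cfg$model_error$eps_g <= -1) stop("model_error.eps_g must be > -1")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills every missing field with the package
#' defaults, rejects unknown keys (naming the offending field path) and
#' validates the invariants (positive sampling interval, window durations
#' that are multiples of it, admissible hyperparameters).  An empty file
#' yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return a validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  validate_run_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname load_config
#' @param cfg a configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

# converters from the flat config representation to package objects
config_neuron <- function(cfg) {
  n <- cfg$neuron
  gp <- function(g) gate_params(g$v_half, g$dv, g$tau0, g$eps_tau, g$dvt)
  neuron_params(n$c_m, n$g_na, n$g_k, n$g_l, n$e_na, n$e_k, n$e_l,
                lapply(n$gates, gp))
}

config_benchmark <- function(cfg) {
  benchmark_config(
    scale = "reduced",
    neuron = config_neuron(cfg),
    dt_ms = cfg$windows$dt_ms,
    train_ms = cfg$windows$train_ms,
    predict_ms = cfg$windows$predict_ms,
    rmse_window_ms = cfg$windows$rmse_window_ms,
    n_nodes = as.integer(cfg$hybrid$n_nodes),
    reservoir = cfg$reservoir[c("degree", "spectral_radius", "sigma", "beta")],
    hybrid = cfg$hybrid[c("degree", "spectral_radius", "sigma", "beta")],
    gamma = cfg$hybrid$gamma,
    lorenz = lorenz_params(cfg$stimulus$lorenz$alpha, cfg$stimulus$lorenz$rho,
                           cfg$stimulus$lorenz$beta, cfg$stimulus$lorenz$ic,
                           cfg$stimulus$lorenz$time_scale),
    steps = step_params(c(cfg$stimulus$steps$amp_min, cfg$stimulus$steps$amp_max),
                        c(cfg$stimulus$steps$dur_min, cfg$stimulus$steps$dur_max)),
    target_range = c(cfg$stimulus$plan$target_min, cfg$stimulus$plan$target_max),
    mean_segment_ms = cfg$stimulus$plan$mean_segment_ms
  )
}
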