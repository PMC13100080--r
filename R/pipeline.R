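#' End-to-end pipeline subcommands
#'
#' Runs one stage of the generate / train / predict / sweep / report
#' pipeline against a run configuration, writing all artifacts (and the
#' fully resolved configuration) into `out_dir`.  Identical configuration
#' and master seed yield byte-identical binary artifacts.
#'
#' Stages and their artifacts:
#' \describe{
#'   \item{generate}{paired training/prediction protocols from disjoint
#'     sub-seeds (`protocol_train.tsv/.rds`, `protocol_predict.tsv/.rds`)
#'     and the reference trajectory from the reference neuron
#'     (`reference.tsv/.rds`).}
#'   \item{train}{trains the system selected by `mode` (`"reservoir"` or
#'     `"hybrid"`, the latter detuned per `model_error`) on the generated
#'     artifacts; writes `system_<mode>.rds`.}
#'   \item{predict}{closed-loop prediction over the prediction window;
#'     writes `prediction.tsv` and `prediction_rmse.tsv`.}
#'   \item{sweep}{model-error sweep per the `sweep` config table; writes
#'     `sweep_table.tsv` and `sweep_summary.tsv`.}
#'   \item{report}{summarises an existing sweep table, adding crossover
#'     intervals (`sweep_report.tsv`).}
#' }
#'
#' @param command one of `"generate"`, `"train"`, `"predict"`, `"sweep"`,
#'   `"report"`.
#' @param config a `run_config` (from [load_config()]) or a path to one.
#' @param out_dir output directory (default: the config's `output_dir`).
#' @param mode training mode for `train`/`predict`: `"reservoir"` or
#'   `"hybrid"`.
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(command = c("generate", "train", "predict",
                                     "sweep", "report"),
                         config, out_dir = NULL,
                         mode = c("hybrid", "reservoir")) {
  command <- match.arg(command)
  mode <- match.arg(mode)
  if (is.character(config)) config <- load_config(config)
  validate_run_config(config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  write_config(config, pth("resolved_config.yml"))
  bench <- config_benchmark(config)
  master <- as.integer(config$seeds$master)
  written <- list(config = pth("resolved_config.yml"))

  if (command == "generate") {
    data <- make_benchmark_data(bench, master)
    ref <- generate_reference(bench$neuron, data$protocol_full)
    meta <- list(master_seed = master, rtol = bench$rtol, atol = bench$atol)
    for (nm in c("protocol_train", "protocol_full")) {
      tag <- if (nm == "protocol_train") "protocol_train" else "protocol_predict"
      df <- protocol_to_df(data[[nm]])
      write_timeseries(df, pth(paste0(tag, ".tsv")), "protocol")
      write_timeseries(df, pth(paste0(tag, ".rds")), "protocol", meta)
      written[[tag]] <- pth(paste0(tag, ".tsv"))
    }
    write_timeseries(ref, pth("reference.tsv"), "trajectory")
    write_timeseries(ref, pth("reference.rds"), "trajectory", meta)
    written$reference <- pth("reference.tsv")
    message("generate: ", length(data$protocol_full$I), " samples at dt = ",
            bench$dt_ms, " ms (master seed ", master, ")")
  } else if (command == "train") {
    need <- pth(c("protocol_train.tsv", "reference.tsv"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("missing upstream artifacts (run `generate` first): ",
           paste(missing, collapse = ", "))
    data <- make_benchmark_data(bench, master)
    sys <- if (mode == "reservoir") {
      build_benchmark_system(bench, data, "reservoir", bench$neuron)
    } else {
      me <- config$model_error
      surrogate <- detune(bench$neuron,
                          model_error(me$eps_g, me$eps_v, me$eps_tau))
      v <- config$hybrid$variant
      build_benchmark_system(bench, data,
                             hybrid_variant(v$scope, v$injection)$tag,
                             surrogate)
    }
    sys <- if (mode == "reservoir")
      reservoir_train(sys, data$protocol_train, data$v_train)
    else hybrid_train(sys, data$protocol_train, data$v_train)
    save_system(sys, pth(paste0("system_", mode, ".rds")),
                meta = list(master_seed = master))
    written$system <- pth(paste0("system_", mode, ".rds"))
    message("train (", mode, "): training RMSE = ",
            signif(sys$training_rmse, 4), " mV over ",
            length(data$v_train) - 1, " samples")
  } else if (command == "predict") {
    sys_path <- pth(paste0("system_", mode, ".rds"))
    if (!file.exists(sys_path))
      stop("missing upstream artifact (run `train` first): ", sys_path)
    sys <- load_system(sys_path)
    data <- make_benchmark_data(bench, master)
    pred <- predict_closed_loop(sys, data$protocol_pred, data$horizon)
    t0 <- (data$n_w) * data$dt_ms
    df <- data.frame(time_ms = t0 + (seq_along(pred$V) - 1) * data$dt_ms,
                     V_mV = pred$V)
    write_timeseries(df, pth("prediction.tsv"), "voltage")
    we <- suppressMessages(rmse_windows(pred$V, data$ref_pred_v,
                                        bench$rmse_window_ms, data$dt_ms))
    write.table(data.frame(window = seq_along(we$rmse), rmse = we$rmse,
                           saturated = pred$saturated),
                pth("prediction_rmse.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    written$prediction <- pth("prediction.tsv")
    written$rmse <- pth("prediction_rmse.tsv")
    message("predict (", mode, "): median windowed RMSE = ",
            signif(we$median, 4), " mV",
            if (pred$saturated) " [saturated]" else "")
  } else if (command == "sweep") {
    sw <- config$sweep
    seeds <- derive_seeds(master, as.integer(sw$n_seeds))
    tbl <- sweep_model_error(bench, sw$error_type, sw$grid, sw$systems,
                             seeds)
    write.table(tbl, pth("sweep_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sm <- sweep_summary(tbl)$summary
    write.table(sm, pth("sweep_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    written$table <- pth("sweep_table.tsv")
    written$summary <- pth("sweep_summary.tsv")
    message("sweep (", sw$error_type, "): ", nrow(tbl), " rows over ",
            length(sw$grid), " detunings x ", length(seeds), " seeds")
  } else if (command == "report") {
    tbl_path <- pth("sweep_table.tsv")
    if (!file.exists(tbl_path))
      stop("missing upstream artifact (run `sweep` first): ", tbl_path)
    tbl <- read.table(tbl_path, header = TRUE, sep = "\t")
    class(tbl) <- c("sweep_table", "data.frame")
    sm <- sweep_summary(tbl)$summary
    systems <- unique(tbl$system)
    cross <- if (length(systems) >= 2)
      crossover_points(tbl, systems[1], systems[2]) else
        data.frame(lower = numeric(0), upper = numeric(0))
    write.table(sm, pth("sweep_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    written$report <- pth("sweep_report.tsv")
    message("report: ", nrow(sm), " summary cells; ", nrow(cross),
            " crossover interval(s)",
            if (nrow(cross)) paste0(" near eps = ",
                                    paste(signif(cross$upper, 3),
                                          collapse = ", ")) else "")
  }
  invisible(written)
}
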