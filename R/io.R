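# Trace I/O: columnar text (portable, 1e-12 round trip) and an RDS binary
# container that is lossless and carries provenance metadata.

schema_columns <- list(
  protocol = c("time_ms", "I"),
  voltage = c("time_ms", "V_mV"),
  trajectory = c("time_ms", "V_mV", "m", "h", "n")
)

is_rds_path <- function(path) grepl("\\.rds$", path, ignore.case = TRUE)

#' Write / read sampled time series
#'
#' Three schemas are supported: `"protocol"` (`time_ms, I`), `"voltage"`
#' (`time_ms, V_mV`) and `"trajectory"` (`time_ms, V_mV, m, h, n`).  Paths
#' ending in `.rds` use a lossless binary container that also stores the
#' schema and a metadata block (seed, tolerance, package version --
#' whatever is passed in `meta`); any other path writes tab-separated text
#' with a header, round-tripping within 1e-12.
#'
#' @param df data frame whose columns match the schema.
#' @param path output path.
#' @param schema one of `"protocol"`, `"voltage"`, `"trajectory"`.
#' @param meta named list of provenance metadata (binary container only).
#' @return the path (write) or the data frame (read).
#' @export
write_timeseries <- function(df, path, schema, meta = list()) {
  cols <- schema_columns[[schema]]
  if (is.null(cols)) stop("unknown schema: ", schema)
  if (!all(cols %in% names(df)))
    stop("data does not match schema '", schema, "': need columns ",
         paste(cols, collapse = ", "))
  df <- as.data.frame(df)[cols]
  if (is_rds_path(path)) {
    saveRDS(list(schema = schema, data = df,
                 meta = c(meta, list(package_version =
                                       as.character(utils::packageVersion("reservoirHH"))))),
            path)
  } else {
    txt <- vapply(df, function(col) sprintf("%.15g", col), character(nrow(df)))
    write.table(matrix(txt, nrow = nrow(df), dimnames = list(NULL, cols)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, schema) {
  cols <- schema_columns[[schema]]
  if (is.null(cols)) stop("unknown schema: ", schema)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_rds_path(path)) {
    obj <- readRDS(path)
    if (!identical(obj$schema, schema))
      stop("schema mismatch: file holds '", obj$schema, "', requested '",
           schema, "'")
    return(obj$data)
  }
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!identical(names(df), cols))
    stop("schema mismatch: file has columns (",
         paste(names(df), collapse = ", "), "), schema '", schema,
         "' expects (", paste(cols, collapse = ", "), ")")
  df
}

protocol_to_df <- function(protocol) {
  data.frame(time_ms = protocol$start_ms +
               (seq_along(protocol$I) - 1) * protocol$dt_ms,
             I = protocol$I)
}

df_to_protocol <- function(df) {
  dt <- if (nrow(df) > 1) df$time_ms[2] - df$time_ms[1] else 0.025
  current_protocol(df$I, dt, start_ms = df$time_ms[1])
}

#' Save / load a trained system container
#'
#' Binary container holding the full system (configuration, sparse
#' adjacency, layout, scalers, readout, final states) plus provenance
#' metadata, so prediction can resume warm in a later session.
#'
#' @param system an `hh_reservoir` or `hh_hybrid`.
#' @param path `.rds` path.
#' @param meta named list of provenance metadata.
#' @return the path (save) or the system (load).
#' @export
save_system <- function(system, path, meta = list()) {
  stopifnot(inherits(system, c("hh_reservoir", "hh_hybrid")))
  saveRDS(list(system = system,
               meta = c(meta, list(package_version =
                                     as.character(utils::packageVersion("reservoirHH"))))),
          path)
  invisible(path)
}

#' @rdname save_system
#' @export
load_system <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj$system, c("hh_reservoir", "hh_hybrid")))
    stop("file does not contain a trained system container")
  obj$system
}
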