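# File formats: the sample-log CSV (one dialect), its JSON-lines mirror,
# ground-truth event CSV, estimate-record CSV, and the structured model
# file. All readers and writers round-trip exactly.

#' Write / read a raw sample log
#'
#' CSV dialect: header `tick,raw_weight_g,stable,nest_id,rfid`; `stable` is
#' 0/1; missing RFID is an empty field; UTF-8.
#'
#' @param samples Data frame with those columns.
#' @param path File path.
#' @return `write_sample_log()` returns `path` invisibly;
#'   `read_sample_log()` returns the data frame (logical `stable`,
#'   `NA` rfid for empty fields).
#' @export
write_sample_log <- function(samples, path) {
  out <- samples[, c("tick", "raw_weight_g", "stable", "nest_id", "rfid")]
  out$stable <- as.integer(out$stable)
  out$rfid[is.na(out$rfid)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sample_log
#' @export
read_sample_log <- function(path) {
  x <- utils::read.csv(path, colClasses = c(tick = "integer",
                                            raw_weight_g = "numeric",
                                            stable = "integer",
                                            nest_id = "character",
                                            rfid = "character"),
                       fileEncoding = "UTF-8")
  x$stable <- x$stable == 1L
  x$rfid[!nzchar(x$rfid) | is.na(x$rfid)] <- NA_character_
  x
}

#' Write / read a sample log as JSON lines
#'
#' One JSON object per line with the same keys as the CSV dialect.
#'
#' @inheritParams write_sample_log
#' @export
write_sample_log_json <- function(samples, path) {
  out <- samples[, c("tick", "raw_weight_g", "stable", "nest_id", "rfid")]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(out, con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_sample_log_json
#' @export
read_sample_log_json <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  x <- jsonlite::stream_in(con, verbose = FALSE)
  x$tick <- as.integer(x$tick)
  if (!"rfid" %in% names(x)) x$rfid <- NA_character_
  x
}

#' Write / read ground-truth visit events
#'
#' CSV with header `rfid,true_weight_g,arrival_tick,departure_tick,had_stable_run`.
#'
#' @param events Data frame of events (extra columns are kept).
#' @param path File path.
#' @export
write_events <- function(events, path) {
  out <- events
  out$had_stable_run <- as.integer(out$had_stable_run)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8",
                       colClasses = c(rfid = "character"))
  x$had_stable_run <- x$had_stable_run == 1L
  x
}

#' Write / read estimate records
#'
#' CSV with header
#' `nest_id,rfid,start_tick,end_tick,weight_g,method,stable_tag` — the
#' per-visit message a nest box sends instead of the raw pattern.
#'
#' @param estimates A list of [weight_estimate()] objects or a data frame
#'   with the columns above.
#' @param path File path.
#' @export
write_estimates <- function(estimates, path) {
  out <- if (is.data.frame(estimates)) estimates else estimates_to_df(estimates)
  out$stable_tag <- as.integer(out$stable_tag)
  out$rfid[is.na(out$rfid)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8",
                       colClasses = c(nest_id = "character",
                                      rfid = "character"))
  x$stable_tag <- x$stable_tag == 1L
  x$rfid[!nzchar(x$rfid) | is.na(x$rfid)] <- NA_character_
  x
}

#' Collect weight estimates into a data frame
#'
#' @param estimates List of [weight_estimate()] objects.
#' @return Data frame in the estimate-record column order.
#' @export
estimates_to_df <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(nest_id = e$nest_id, rfid = e$rfid,
               start_tick = e$tick_range[1], end_tick = e$tick_range[2],
               weight_g = e$grams, method = e$method,
               stable_tag = e$stable_tag)))
}

#' Write / read network parameters
#'
#' Structured JSON holding layer sizes, row-major connection weights,
#' biases, the resample factor and the input-scaling constants; numbers are
#' written at full precision so the parameter file round-trips exactly.
#'
#' @param params An [mlp_parameters()] object.
#' @param path File path.
#' @export
write_mlp <- function(params, path) {
  obj <- list(layer_sizes = params$layer_sizes,
              hidden_weights = as.numeric(t(params$hidden_weights)),
              hidden_bias = params$hidden_bias,
              output_weights = params$output_weights,
              output_bias = params$output_bias,
              resample_factor = params$resample_factor,
              n_max = params$n_max,
              sigmoid = params$sigmoid)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$layer_sizes[1]; H <- obj$layer_sizes[2]
  hw <- matrix(as.numeric(obj$hidden_weights), nrow = d, ncol = H,
               byrow = TRUE)
  rownames(hw) <- feature_names[seq_len(d)]
  mlp_parameters(hidden_weights = hw,
                 hidden_bias = as.numeric(obj$hidden_bias),
                 output_weights = as.numeric(obj$output_weights),
                 output_bias = as.numeric(obj$output_bias),
                 resample_factor = as.numeric(obj$resample_factor),
                 n_max = as.numeric(obj$n_max), sigmoid = obj$sigmoid)
}

#' Read a run configuration file
#'
#' A single YAML file whose top-level keys are the module names
#' (`acquisition`, `simulator`, `training`, `link`) with field names as in
#' the corresponding constructors; missing keys take the defaults.
#'
#' @param path YAML file path; `NULL` gives all defaults.
#' @return A list with `acquisition`, `simulator`, `training`, `link`
#'   config objects and any `seed` set in the file.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  list(acquisition = build(acquisition_config, raw$acquisition),
       simulator = build(simulator_config, raw$simulator),
       training = build(train_config, raw$training),
       link = build(link_config, raw$link),
       seed = raw$seed)
}
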