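## Run configuration and pipeline entry points. Each run_*() function takes a
## plain named list (typically loaded from YAML with load_run_config() and/or
## overridden by CLI flags), validates it, executes one pipeline step, writes
## its artifacts and emits a structured log line so every run is reproducible
## from its logged configuration and seed.

KNOWN_CONFIG_KEYS <- c(
  "key", "flow_order", "method", "filter_stage", "min_distance",
  "length_range", "sigma0", "sigma1", "p_dropout", "seed",
  "templates", "barcodes", "reads", "expected", "out", "fasta",
  "n_per_barcode", "insert_length", "correct_errors", "adapter_core",
  "counts", "concentrations", "target_molecules", "min_volume",
  "max_volume", "fold")

#' Load and validate a run configuration
#'
#' Reads a YAML file of run parameters, rejects unknown keys, and merges the
#' result over `defaults`.
#'
#' @param path YAML file path, or `NULL` for an empty configuration.
#' @param defaults Named list of default values.
#' @param overrides Named list applied over the file's values (e.g. from
#'   command-line flags).
#' @return A named list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, defaults = list(), overrides = list()) {
  config <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(config)) {
    stop_flowcode("configuration file must contain a YAML mapping",
                  "flowcode_invalid_config")
  }
  unknown <- setdiff(c(names(config), names(overrides)), KNOWN_CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop_flowcode(sprintf("unknown configuration key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "flowcode_invalid_config")
  }
  merged <- utils::modifyList(utils::modifyList(defaults, config), overrides)
  structure(merged, class = c("run_config", "list"))
}

config_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config[[key]]
  if (is.null(val)) {
    if (required) {
      stop_flowcode(sprintf("configuration key '%s' is required", key),
                    "flowcode_invalid_config")
    }
    return(default)
  }
  val
}

log_run <- function(step, ...) {
  kv <- list(...)
  message(sprintf("[flowcode] %s %s", step,
                  paste(sprintf("%s=%s", names(kv),
                                vapply(kv, function(v) paste(v, collapse = ","),
                                       character(1L))),
                        collapse = " ")))
}

config_key_order <- function(config) {
  order <- flow_order(config_get(config, "flow_order", c("T", "A", "C", "G")))
  key <- sequencing_key(config_get(config, "key", "TCAG"), order)
  list(order = order, key = key)
}

#' Pipeline entry points
#'
#' Thin, artifact-producing wrappers around the package's functions, designed
#' for the command line (see the `flowcode` script in `inst/cli/`). Each
#' takes a configuration list (see [load_run_config()]), writes its outputs
#' and logs its parameters; on any error the outputs are not partially
#' committed (files are written to a temporary path, then renamed).
#'
#' @param config Named list / `run_config`.
#' @return The main result object of the step, invisibly.
#' @name run_steps
NULL

## Write via a temporary file in the same directory so a failed run leaves no
## partial artifact.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop_flowcode(sprintf("cannot write %s", path), "flowcode_io_error")
  }
  invisible(path)
}

#' @rdname run_steps
#' @export
run_design <- function(config = list()) {
  ko <- config_key_order(config)
  out <- config_get(config, "out", required = TRUE)
  set <- design_barcode_set(
    method = config_get(config, "method", "lexicode"),
    filter_stage = config_get(config, "filter_stage", "before"),
    min_distance = config_get(config, "min_distance", 3L),
    length_range = config_get(config, "length_range", c(5L, 8L)),
    key = ko$key, order = ko$order,
    seed = config_get(config, "seed", 1L))
  atomic_write(out, function(p) write_barcode_table(set, p))
  fasta <- config_get(config, "fasta")
  if (!is.null(fasta)) atomic_write(fasta, function(p) write_barcode_fasta(set, p))
  log_run("design", method = set$metadata$method, n_barcodes = nrow(set$table),
          min_distance = set$metadata$min_distance,
          seed = set$metadata$seed, out = out)
  invisible(set)
}

#' @rdname run_steps
#' @export
run_validate <- function(config = list()) {
  set <- read_barcode_table(config_get(config, "barcodes", required = TRUE))
  report <- validate_set(set)
  print(report)
  out <- config_get(config, "out")
  if (!is.null(out)) {
    atomic_write(out, function(p) {
      write.table(report$per_word, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }
  log_run("validate", n_words = report$n_words,
          min_distance = report$min_distance,
          pass = isTRUE(report$pass))
  if (!isTRUE(report$pass)) {
    stop_flowcode("barcode set failed validation", "flowcode_validation_failed")
  }
  invisible(report)
}

#' @rdname run_steps
#' @export
run_simulate <- function(config = list()) {
  ko <- config_key_order(config)
  set <- read_barcode_table(config_get(config, "barcodes", required = TRUE))
  out <- config_get(config, "out", required = TRUE)
  sim <- simulate_reads(
    templates = config_get(config, "templates", required = TRUE),
    set = set,
    n_per_barcode = config_get(config, "n_per_barcode", 100L),
    noise = noise_model(config_get(config, "sigma0", 0),
                        config_get(config, "sigma1", 0),
                        config_get(config, "p_dropout", 0)),
    key = ko$key, order = ko$order,
    insert_length = config_get(config, "insert_length", c(40L, 80L)),
    seed = config_get(config, "seed", 1L))
  paths <- write_simulation(sim, out)
  log_run("simulate", n_reads = length(sim$reads), seed = sim$params$seed,
          out = paths[["reads"]])
  invisible(sim)
}

#' @rdname run_steps
#' @export
run_demux <- function(config = list()) {
  ko <- config_key_order(config)
  set <- read_barcode_table(config_get(config, "barcodes", required = TRUE))
  expected <- config_get(config, "expected")
  if (!is.null(expected) && length(expected) == 1L && file.exists(expected)) {
    expected <- readLines(expected)
    expected <- expected[nzchar(expected)]
  }
  out <- config_get(config, "out", required = TRUE)
  report <- demultiplex(
    reads = config_get(config, "reads", required = TRUE),
    set = set, expected_ids = expected,
    key = ko$key, order = ko$order,
    correct_errors = isTRUE(config_get(config, "correct_errors", FALSE)),
    out_prefix = out)
  write_demux_report(report, out)
  print(report)
  log_run("demux", n_reads = report$n_reads,
          assigned = sum(report$counts$total),
          unassigned = sum(report$unassigned), out = out)
  invisible(report)
}

#' @rdname run_steps
#' @export
run_poolstats <- function(config = list()) {
  counts_path <- config_get(config, "counts", required = TRUE)
  tab <- read.delim(counts_path, sep = "\t", stringsAsFactors = FALSE)
  count_col <- intersect(c("count", "total"), names(tab))
  if (length(count_col) == 0L) {
    stop_flowcode("counts table needs a 'count' or 'total' column",
                  "flowcode_parse_error")
  }
  counts <- tab[[count_col[1L]]]
  names(counts) <- tab[[1L]]
  stats <- evenness_stats(counts, fold = config_get(config, "fold", 2))
  print(stats)
  out <- config_get(config, "out")
  if (!is.null(out)) {
    atomic_write(out, function(p) {
      write.table(as.data.frame(unclass(stats)), p, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
  }
  log_run("poolstats", n_barcodes = stats$n_barcodes,
          fraction_within = stats$fraction_within)
  invisible(stats)
}

#' @rdname run_steps
#' @export
run_poolplan <- function(config = list()) {
  conc_path <- config_get(config, "concentrations", required = TRUE)
  tab <- read.delim(conc_path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop_flowcode("concentrations table needs sample and concentration columns",
                  "flowcode_parse_error")
  }
  conc <- setNames(as.numeric(tab[[2L]]), tab[[1L]])
  plan <- equimolar_plan(conc,
                         config_get(config, "target_molecules", required = TRUE),
                         min_volume = config_get(config, "min_volume"),
                         max_volume = config_get(config, "max_volume"))
  print(plan)
  out <- config_get(config, "out")
  if (!is.null(out)) {
    atomic_write(out, function(p) {
      write.table(as.data.frame(plan), p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }
  log_run("poolplan", n_samples = nrow(plan))
  invisible(plan)
}
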