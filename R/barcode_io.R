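#' Read and write barcode tables
#'
#' The barcode table is a TSV with columns `id`, `digits` (10 comma-separated
#' ternary digits), `bases` (separator included), `base_length` and
#' `flow_span`, preceded by `#key=value` metadata lines recording the design
#' parameters. Writing is deterministic: identical sets and metadata produce
#' byte-identical files.
#'
#' @param set A `barcode_set` (see [design_barcode_set()]).
#' @param path File path.
#' @return `write_barcode_table()` returns `path` invisibly;
#'   `read_barcode_table()` returns a `barcode_set`.
#' @export
write_barcode_table <- function(set, path) {
  stopifnot(inherits(set, "barcode_set"))
  md <- set$metadata
  md_lines <- character(0L)
  if (length(md)) {
    keys <- sort(names(md))
    md_lines <- sprintf("#%s=%s", keys,
                        vapply(md[keys], function(v) paste(v, collapse = ","),
                               character(1L)))
  }
  tab <- set$table
  body <- c(paste(names(tab), collapse = "\t"),
            do.call(paste, c(unname(tab), list(sep = "\t"))))
  writeLines(c(md_lines, body), path)
  invisible(path)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  lines <- readLines(path)
  md_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ln in md_lines) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0L) {
      key <- substr(kv, 1L, eq - 1L)
      val <- substr(kv, eq + 1L, nchar(kv))
      metadata[[key]] <- val
    }
  }
  for (k in c("min_distance", "seed")) {
    if (!is.null(metadata[[k]])) metadata[[k]] <- as.integer(metadata[[k]])
  }
  if (!is.null(metadata$length_range)) {
    metadata$length_range <- as.integer(strsplit(metadata$length_range, ",")[[1L]])
  }
  tab <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                    stringsAsFactors = FALSE)
  required <- c("id", "digits", "bases", "base_length", "flow_span")
  if (!all(required %in% names(tab))) {
    stop_flowcode(sprintf("barcode table %s lacks required columns (%s)", path,
                          paste(setdiff(required, names(tab)), collapse = ", ")),
                  "flowcode_parse_error")
  }
  if (anyDuplicated(tab$id)) {
    stop_flowcode("barcode table contains duplicate ids", "flowcode_parse_error")
  }
  digit_list <- strsplit(tab$digits, ",", fixed = TRUE)
  if (any(lengths(digit_list) != BARCODE_DIGITS)) {
    stop_flowcode("barcode table digits must have 10 comma-separated entries",
                  "flowcode_parse_error")
  }
  words <- do.call(rbind, lapply(digit_list, validate_digits))
  order <- if (!is.null(metadata$flow_order)) {
    flow_order(metadata$flow_order)
  } else flow_order()
  key <- if (!is.null(metadata$key)) sequencing_key(metadata$key, order) else {
    sequencing_key(order = order)
  }
  set <- new_barcode_set(words, metadata, key, order, ids = tab$id)
  if (!identical(set$table$bases, tab$bases)) {
    stop_flowcode("stored bases disagree with re-rendered digits",
                  "flowcode_parse_error")
  }
  set
}

#' Export barcode base strings as FASTA
#'
#' @param set A `barcode_set`.
#' @param path FASTA file path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(set, path) {
  stopifnot(inherits(set, "barcode_set"))
  seqs <- Biostrings::DNAStringSet(setNames(set$table$bases, set$table$id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
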