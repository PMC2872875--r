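## Read demultiplexing in flow space. The observed 10-digit barcode window is
## compared to the panel by Hamming distance over digits (a digit differing by
## any magnitude counts as one error). With a minimum pairwise distance of 3,
## exact matching identifies error-free barcodes, a unique match at distance 1
## corrects a single flow miscall, and two miscalls can never cross over to a
## different valid barcode.

## Match observed window digits against a barcode set.
match_barcode <- function(digits, set, correct_errors = FALSE) {
  d <- hamming_to_words(digits, set$digits)
  exact <- which(d == 0L)
  if (length(exact) == 1L) {
    return(list(barcode_id = set$table$id[exact], n_flow_errors = 0L,
                status = "perfect"))
  }
  if (!correct_errors) {
    return(list(barcode_id = NA_character_, n_flow_errors = NA_integer_,
                status = "unassigned-distant"))
  }
  near <- which(d == 1L)
  if (length(near) == 1L) {
    return(list(barcode_id = set$table$id[near], n_flow_errors = 1L,
                status = "corrected"))
  }
  if (length(near) > 1L) {
    ## impossible for a distance-3 set; reported defensively
    return(list(barcode_id = NA_character_, n_flow_errors = NA_integer_,
                status = "unassigned-ambiguous"))
  }
  list(barcode_id = NA_character_, n_flow_errors = NA_integer_,
       status = "unassigned-distant")
}

#' Assign a read to a barcode
#'
#' Extracts the 11-flow barcode window after the sequencing key
#' ([extract_barcode_window()]) and matches the 10 digit flows against the
#' panel. An exact digit match is `perfect`; otherwise, when
#' `correct_errors = TRUE`, a unique barcode at Hamming distance 1 is
#' `corrected` (guaranteed unambiguous for a distance-3 set). The separator
#' flow takes no part in the distance. Reads failing the key check or too
#' short for the window receive status `key-mismatch` / `truncated`.
#'
#' @param read Read sequence (a single string).
#' @param set A `barcode_set`.
#' @param key,order Sequencing key and flow order.
#' @param correct_errors Attempt single-flow-error correction? Default
#'   `FALSE` (exact matching only).
#' @return An object of class `demux_assignment`: `barcode_id` (or `NA`),
#'   `n_flow_errors`, `trim_start` (1-based position of the first insert
#'   base; key + barcode bases + exactly one separator base are removed) and
#'   `status`.
#' @export
assign_read <- function(read, set, key = sequencing_key(),
                        correct_errors = FALSE, order = flow_order()) {
  stopifnot(inherits(set, "barcode_set"))
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  win <- tryCatch(extract_barcode_window(read, key, order), error = function(e) e)
  if (inherits(win, "flowcode_key_mismatch")) {
    return(new_assignment(NA_character_, NA_integer_, NA_integer_, "key-mismatch"))
  }
  if (inherits(win, "flowcode_truncated_read")) {
    return(new_assignment(NA_character_, NA_integer_, NA_integer_, "truncated"))
  }
  if (inherits(win, "error")) stop(win)
  m <- match_barcode(win$digits, set, correct_errors)
  trim_start <- if (!is.na(m$barcode_id)) {
    ## observed digit bases + exactly one separator base are trimmed; extra
    ## separator-flow bases (an insert starting with C) stay with the insert
    nchar(key$bases) + sum(win$digits) + 1L + 1L
  } else NA_integer_
  new_assignment(m$barcode_id, m$n_flow_errors, trim_start, m$status)
}

new_assignment <- function(barcode_id, n_flow_errors, trim_start, status) {
  structure(list(barcode_id = barcode_id, n_flow_errors = n_flow_errors,
                 trim_start = trim_start, status = status),
            class = "demux_assignment")
}

#' @export
print.demux_assignment <- function(x, ...) {
  cat("<demux_assignment> ", x$status,
      if (!is.na(x$barcode_id)) paste0(" -> ", x$barcode_id,
                                       " (", x$n_flow_errors, " flow error",
                                       if (x$n_flow_errors != 1L) "s", ")"),
      "\n", sep = "")
  invisible(x)
}

#' Assign a raw flowgram to a barcode
#'
#' The flow-space path: the key portion of the flowgram must equal the key's
#' canonical flowgram exactly; the following 10 flow values are the barcode
#' digits. Under the package's conventions this path and the base-space path
#' ([assign_read()]) give identical assignments on base-called reads.
#'
#' @param fg A [flowgram()] starting at flow 1 and covering at least the key
#'   plus the 11-flow window.
#' @inheritParams assign_read
#' @return A `demux_assignment` (the `trim_start` refers to the base-called
#'   sequence).
#' @export
assign_flowgram <- function(fg, set, key = sequencing_key(),
                            correct_errors = FALSE, order = flow_order()) {
  stopifnot(inherits(set, "barcode_set"), inherits(fg, "flowgram"))
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  if (fg$start_flow != 1L) {
    stop_flowcode("flowgram must start at flow 1", "flowcode_invalid_flowgram")
  }
  span <- key$flow_span
  if (length(fg$values) < span + 11L) {
    return(new_assignment(NA_character_, NA_integer_, NA_integer_, "truncated"))
  }
  if (!identical(fg$values[seq_len(span)], key$flowgram$values)) {
    return(new_assignment(NA_character_, NA_integer_, NA_integer_, "key-mismatch"))
  }
  digits <- fg$values[span + 1:10]
  m <- match_barcode(digits, set, correct_errors)
  trim_start <- if (!is.na(m$barcode_id)) {
    nchar(key$bases) + sum(digits) + 1L + 1L
  } else NA_integer_
  new_assignment(m$barcode_id, m$n_flow_errors, trim_start, m$status)
}

UNASSIGNED_REASONS <- c("unassigned-ambiguous", "unassigned-distant",
                        "key-mismatch", "truncated")

#' Demultiplex a pooled read set
#'
#' Assigns every read to a barcode ([assign_read()]), trims key + barcode +
#' separator, optionally writes per-sample files, and reports per-barcode
#' tallies, unassigned counts by reason, cross-contamination (reads carrying
#' a valid barcode that is not in `expected_ids`) and pooling evenness over
#' the expected barcodes.
#'
#' @param reads A named character vector of read sequences, a list of
#'   [flowgram()]s, or the path to a FASTA/FASTQ file.
#' @param set A `barcode_set`.
#' @param expected_ids Barcode ids expected in this pool (default: all ids in
#'   `set`). Must be a subset of the set's ids.
#' @param key,order Sequencing key and flow order.
#' @param correct_errors Attempt single-flow-error correction?
#' @param out_prefix If non-`NULL`, trimmed reads are written to
#'   `<prefix>.<barcode_id>.<ext>` and unassigned reads (untrimmed, with the
#'   reason in the description) to `<prefix>.unassigned.<ext>`.
#' @param format Output format, `"fastq"` or `"fasta"`; defaults to the
#'   input's format (fasta for in-memory reads).
#' @return An object of class `demux_report`; its `assignments` element holds
#'   the per-read table.
#' @export
demultiplex <- function(reads, set, expected_ids = NULL,
                        key = sequencing_key(), correct_errors = FALSE,
                        out_prefix = NULL, format = NULL,
                        order = flow_order()) {
  stopifnot(inherits(set, "barcode_set"))
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  if (is.null(expected_ids)) expected_ids <- set$table$id
  if (!all(expected_ids %in% set$table$id)) {
    stop_flowcode("expected_ids must be a subset of the barcode set's ids",
                  "flowcode_invalid_input")
  }

  input <- load_reads(reads)
  if (is.null(format)) format <- input$format
  n <- length(input$seqs)

  assignments <- data.frame(read_id = names(input$seqs),
                            barcode_id = rep(NA_character_, n),
                            status = rep(NA_character_, n),
                            n_flow_errors = rep(NA_integer_, n),
                            trim_start = rep(NA_integer_, n),
                            stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- assign_read(input$seqs[[i]], set, key, correct_errors, order)
    assignments$barcode_id[i] <- a$barcode_id
    assignments$status[i] <- a$status
    assignments$n_flow_errors[i] <- a$n_flow_errors
    assignments$trim_start[i] <- a$trim_start
  }

  assigned <- !is.na(assignments$barcode_id)
  counts <- data.frame(barcode_id = set$table$id,
                       perfect = 0L, corrected = 0L, total = 0L,
                       expected = set$table$id %in% expected_ids,
                       stringsAsFactors = FALSE)
  if (any(assigned)) {
    tab_p <- table(assignments$barcode_id[assigned & assignments$status == "perfect"])
    tab_c <- table(assignments$barcode_id[assigned & assignments$status == "corrected"])
    counts$perfect <- as.integer(tab_p[counts$barcode_id])
    counts$corrected <- as.integer(tab_c[counts$barcode_id])
    counts$perfect[is.na(counts$perfect)] <- 0L
    counts$corrected[is.na(counts$corrected)] <- 0L
    counts$total <- counts$perfect + counts$corrected
  }
  unassigned <- setNames(integer(length(UNASSIGNED_REASONS)), UNASSIGNED_REASONS)
  ua_tab <- table(assignments$status[!assigned])
  unassigned[names(ua_tab)] <- as.integer(ua_tab)
  stopifnot(sum(counts$total) + sum(unassigned) == n)  # conservation

  contam <- counts[!counts$expected & counts$total > 0L,
                   c("barcode_id", "total")]
  names(contam) <- c("barcode_id", "count")
  contam$fraction <- if (n > 0L) contam$count / n else numeric(0L)
  rownames(contam) <- NULL

  evenness <- NULL
  exp_counts <- counts$total[counts$expected]
  if (length(exp_counts) > 0L) {
    evenness <- evenness_stats(setNames(exp_counts,
                                        counts$barcode_id[counts$expected]))
  }

  files <- NULL
  if (!is.null(out_prefix) && n > 0L) {
    files <- write_demux_outputs(input, assignments, out_prefix, format)
  }

  structure(list(n_reads = n,
                 counts = counts,
                 unassigned = unassigned,
                 expected_ids = expected_ids,
                 contamination = contam,
                 evenness = evenness,
                 correct_errors = correct_errors,
                 assignments = assignments,
                 files = files),
            class = "demux_report")
}

#' @export
print.demux_report <- function(x, ...) {
  cat("<demux_report> ", x$n_reads, " reads, correction ",
      if (x$correct_errors) "on" else "off", "\n", sep = "")
  n_assigned <- sum(x$counts$total)
  cat(sprintf("  assigned:   %d (%d perfect, %d corrected)\n",
              n_assigned, sum(x$counts$perfect), sum(x$counts$corrected)))
  cat(sprintf("  unassigned: %d (%s)\n", sum(x$unassigned),
              paste(sprintf("%s=%d", names(x$unassigned), x$unassigned),
                    collapse = ", ")))
  if (nrow(x$contamination) > 0L) {
    cat("  contamination (unexpected barcodes):\n")
    print(x$contamination)
  } else {
    cat("  contamination: none\n")
  }
  if (!is.null(x$evenness)) {
    cat(sprintf("  evenness: %.1f%% of expected barcodes within two-fold of the mean\n",
                100 * x$evenness$fraction_within))
  }
  invisible(x)
}

#' Write a demultiplexing report as TSV
#'
#' Writes the per-barcode count table (`<prefix>.counts.tsv`), the
#' unassigned tallies (`<prefix>.unassigned.tsv`) and the per-read
#' assignments (`<prefix>.assignments.tsv`).
#'
#' @param report A `demux_report`.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_demux_report <- function(report, prefix) {
  stopifnot(inherits(report, "demux_report"))
  paths <- c(counts = paste0(prefix, ".counts.tsv"),
             unassigned = paste0(prefix, ".unassigned.tsv"),
             assignments = paste0(prefix, ".assignments.tsv"))
  write.table(report$counts, paths[["counts"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(reason = names(report$unassigned),
                         count = as.integer(report$unassigned)),
              paths[["unassigned"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$assignments, paths[["assignments"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

## ---- read I/O ---------------------------------------------------------------

load_reads <- function(reads) {
  if (is.list(reads) && length(reads) > 0L && inherits(reads[[1L]], "flowgram")) {
    seqs <- vapply(reads, flowgram_to_bases, character(1L))
    if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d", seq_along(seqs))
    return(list(seqs = seqs, quals = NULL, format = "fasta"))
  }
  if (is.character(reads) && length(reads) == 1L && !is.na(reads) &&
      file.exists(reads) && !grepl("^[ACGTacgt]+$", reads)) {
    return(read_seq_file(reads))
  }
  if (!is.character(reads)) {
    stop_flowcode("reads must be a named character vector, a list of flowgrams, or a file path",
                  "flowcode_invalid_input")
  }
  seqs <- reads
  if (is.null(names(seqs)) && length(seqs) > 0L) {
    names(seqs) <- sprintf("read%06d", seq_along(seqs))
  }
  list(seqs = seqs, quals = NULL, format = "fasta")
}

guess_seq_format <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) return("fastq")
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) return("fasta")
  first <- tryCatch(readLines(path, n = 1L), error = function(e) {
    stop_flowcode(sprintf("cannot read %s: %s", path, conditionMessage(e)),
                  "flowcode_io_error")
  })
  if (length(first) == 0L || startsWith(first, ">")) "fasta"
  else if (startsWith(first, "@")) "fastq"
  else stop_flowcode(sprintf("cannot determine format of %s", path),
                     "flowcode_io_error")
}

read_seq_file <- function(path) {
  fmt <- guess_seq_format(path)
  if (fmt == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    seqs <- setNames(as.character(x), names(x))
    quals <- setNames(as.character(S4Vectors::mcols(x)$qualities), names(x))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    seqs <- setNames(as.character(x), names(x))
    quals <- NULL
  }
  ## keep only the id token for naming; full header kept as description
  ids <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- ids
  if (!is.null(quals)) names(quals) <- ids
  list(seqs = seqs, quals = quals, format = fmt)
}

write_read_group <- function(path, seqs, quals, format, descriptions = NULL) {
  nm <- names(seqs)
  if (!is.null(descriptions)) nm <- paste(nm, descriptions)
  if (format == "fastq") {
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(unname(seqs), nm)),
      Biostrings::PhredQuality(unname(quals)))
    Biostrings::writeQualityScaledXStringSet(x, path)
  } else {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(unname(seqs), nm)), path)
  }
  path
}

write_demux_outputs <- function(input, assignments, out_prefix, format) {
  ext <- if (format == "fastq") "fastq" else "fasta"
  files <- character(0L)
  assigned <- !is.na(assignments$barcode_id)
  for (bc in unique(assignments$barcode_id[assigned])) {
    sel <- which(assigned & assignments$barcode_id == bc)
    trimmed <- substring(input$seqs[sel], assignments$trim_start[sel])
    names(trimmed) <- assignments$read_id[sel]
    quals <- if (!is.null(input$quals)) {
      substring(input$quals[sel], assignments$trim_start[sel])
    }
    path <- paste0(out_prefix, ".", bc, ".", ext)
    files <- c(files, write_read_group(path, trimmed, quals, format))
  }
  sel <- which(!assigned)
  if (length(sel) > 0L) {
    ua <- input$seqs[sel]
    names(ua) <- assignments$read_id[sel]
    quals <- if (!is.null(input$quals)) input$quals[sel]
    path <- paste0(out_prefix, ".unassigned.", ext)
    files <- c(files, write_read_group(path, ua, quals, format,
                                       descriptions = assignments$status[sel]))
  }
  files
}

## ---- flowgram TSV dialect ---------------------------------------------------

#' Read and write per-read flowgrams as TSV
#'
#' A simple plain-text flowgram dialect (standing in for binary SFF):
#' tab-separated columns `read_id`, `start_flow`, `values`, where `values`
#' is a comma-separated list of non-negative integer flow values.
#'
#' @param path File path.
#' @param flowgrams Named list of [flowgram()] objects.
#' @return `read_flowgram_tsv()` returns a named list of `flowgram`s;
#'   `write_flowgram_tsv()` returns `path` invisibly.
#' @export
read_flowgram_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(list())
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("read_id", "start_flow", "values"))) {
    stop_flowcode(sprintf("%s line 1: expected header 'read_id\tstart_flow\tvalues'",
                          path), "flowcode_parse_error")
  }
  out <- list()
  for (i in seq_along(lines)[-1L]) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 3L) {
      stop_flowcode(sprintf("%s line %d: expected 3 tab-separated fields", path, i),
                    "flowcode_parse_error")
    }
    start_flow <- suppressWarnings(as.integer(fields[2L]))
    values <- suppressWarnings(as.integer(strsplit(fields[3L], ",", fixed = TRUE)[[1L]]))
    if (is.na(start_flow) || anyNA(values) || any(values < 0L) || start_flow < 1L) {
      stop_flowcode(sprintf("%s line %d: malformed flowgram (start_flow and values must be non-negative integers, start_flow >= 1)",
                            path, i), "flowcode_parse_error")
    }
    out[[fields[1L]]] <- flowgram(values, start_flow)
  }
  out
}

#' @rdname read_flowgram_tsv
#' @export
write_flowgram_tsv <- function(flowgrams, path) {
  if (length(flowgrams) > 0L && is.null(names(flowgrams))) {
    names(flowgrams) <- sprintf("read%06d", seq_along(flowgrams))
  }
  lines <- c("read_id\tstart_flow\tvalues",
             vapply(seq_along(flowgrams), function(i) {
               fg <- flowgrams[[i]]
               paste(names(flowgrams)[i], fg$start_flow,
                     paste(fg$values, collapse = ","), sep = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
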