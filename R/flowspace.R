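#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

## Condition helper: all package errors carry class c(<specific>, "flowcode_error").
stop_flowcode <- function(message, class, call = sys.call(-1L)) {
  stop(errorCondition(message, class = c(class, "flowcode_error"), call = call))
}

#' Pyrosequencing flow order
#'
#' A flow order is the fixed cyclic order in which the four nucleotides are
#' presented to the sequencing reaction. On the 454 platform the order is
#' T, A, C, G, repeated indefinitely; the nucleotide presented on (1-based)
#' flow \eqn{i} is `nucleotides[((i - 1) mod 4) + 1]`.
#'
#' @param nucleotides The four bases in flow order, either as a character
#'   vector of length 4 or a single 4-character string. Default `"TACG"`.
#' @return An object of class `flow_order`.
#' @examples
#' fo <- flow_order()
#' flow_nucleotide(fo, 1:8)
#' @export
flow_order <- function(nucleotides = c("T", "A", "C", "G")) {
  if (is.character(nucleotides) && length(nucleotides) == 1L) {
    nucleotides <- strsplit(nucleotides, "", fixed = TRUE)[[1L]]
  }
  nucleotides <- toupper(nucleotides)
  if (length(nucleotides) != 4L || anyDuplicated(nucleotides) > 0L ||
      !all(nucleotides %in% c("A", "C", "G", "T"))) {
    stop_flowcode("a flow order must list each of A, C, G, T exactly once",
                  "flowcode_invalid_flow_order")
  }
  structure(list(nucleotides = nucleotides), class = "flow_order")
}

#' @export
print.flow_order <- function(x, ...) {
  cat("<flow_order> ", paste(x$nucleotides, collapse = ""), " (cyclic)\n", sep = "")
  invisible(x)
}

#' @rdname flow_order
#' @param order A `flow_order`.
#' @param flows Integer vector of 1-based flow indices.
#' @export
flow_nucleotide <- function(order, flows) {
  order$nucleotides[(as.integer(flows) - 1L) %% 4L + 1L]
}

as_flow_order <- function(order) {
  if (inherits(order, "flow_order")) order else flow_order(order)
}

#' Flowgram: per-flow incorporation counts
#'
#' A flowgram records, for each successive nucleotide flow starting at
#' `start_flow`, how many bases of that flow's nucleotide were incorporated.
#' It is the native representation of a 454 read ("flow space").
#'
#' @param values Non-negative integer vector of incorporation counts, one per
#'   flow.
#' @param start_flow 1-based index of the first flow covered by `values`.
#' @return An object of class `flowgram` with fields `start_flow` and
#'   `values`.
#' @export
flowgram <- function(values, start_flow = 1L) {
  values <- as.integer(values)
  start_flow <- as.integer(start_flow)
  if (length(start_flow) != 1L || is.na(start_flow) || start_flow < 1L) {
    stop_flowcode("start_flow must be a single integer >= 1",
                  "flowcode_invalid_flowgram")
  }
  if (anyNA(values) || any(values < 0L)) {
    stop_flowcode("flowgram values must be non-negative integers",
                  "flowcode_invalid_flowgram")
  }
  structure(list(start_flow = start_flow, values = values), class = "flowgram")
}

#' @export
print.flowgram <- function(x, ...) {
  cat("<flowgram> start_flow=", x$start_flow, " n_flows=", length(x$values),
      "\n  [", paste(x$values, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' @export
length.flowgram <- function(x) length(x$values)

split_bases <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop_flowcode(sprintf("%s must be a single character string", what),
                  "flowcode_invalid_sequence")
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop_flowcode(sprintf("%s contains non-ACGT character(s): %s", what,
                          paste(unique(chars[bad]), collapse = ", ")),
                  "flowcode_invalid_sequence")
  }
  chars
}

#' Convert bases to a flowgram (greedy encoding)
#'
#' Encodes a nucleotide string in flow space: at each successive flow the
#' emitted value is the length of the maximal run of that flow's nucleotide
#' at the current position of the sequence (0 if the next base differs). The
#' whole sequence is consumed and trailing zero flows are not emitted, so a
#' non-empty canonical flowgram always ends in a positive value.
#'
#' @param seq Nucleotide string (A/C/G/T only).
#' @param order A [flow_order()].
#' @param start_flow 1-based flow index at which encoding starts.
#' @return A [flowgram()].
#' @examples
#' bases_to_flowgram("TCAG")$values  # 1,0,1,0,0,1,0,1 — the 454 key spans 8 flows
#' @export
bases_to_flowgram <- function(seq, order = flow_order(), start_flow = 1L) {
  order <- as_flow_order(order)
  chars <- split_bases(seq)
  start_flow <- as.integer(start_flow)
  if (length(chars) == 0L) {
    return(flowgram(integer(0L), start_flow))
  }
  runs <- rle(chars)
  ord_idx <- match(runs$values, order$nucleotides)
  flows <- integer(length(ord_idx))
  cur <- start_flow - 1L
  for (i in seq_along(ord_idx)) {
    ## first flow > cur presenting this run's nucleotide
    cur <- cur + ((ord_idx[i] - 1L - cur) %% 4L) + 1L
    flows[i] <- cur
  }
  values <- integer(cur - start_flow + 1L)
  values[flows - start_flow + 1L] <- runs$lengths
  flowgram(values, start_flow)
}

#' Convert a flowgram back to bases
#'
#' Concatenates, over flows, the flow's nucleotide repeated `value` times.
#' Inverse of [bases_to_flowgram()] on canonical flowgrams; on arbitrary
#' flowgrams runs split across same-nucleotide flows merge into one run.
#'
#' @param fg A [flowgram()].
#' @param order A [flow_order()].
#' @return A nucleotide string.
#' @export
flowgram_to_bases <- function(fg, order = flow_order()) {
  order <- as_flow_order(order)
  if (!inherits(fg, "flowgram")) {
    fg <- flowgram(fg)
  }
  if (length(fg$values) == 0L) {
    return("")
  }
  nucs <- flow_nucleotide(order, fg$start_flow + seq_along(fg$values) - 1L)
  paste(strrep(nucs, fg$values), collapse = "")
}

#' Sequencing key
#'
#' The key is the short known sequence (TCAG on the 454 platform) read at the
#' start of every well; the barcode window is anchored immediately after the
#' flow on which the key's last base is incorporated. Under the default flow
#' order the TCAG key occupies 8 flows and ends on a G flow, so the barcode
#' window starts on a T flow and its 11th flow is a C flow (the separator).
#'
#' @param bases Key sequence, default `"TCAG"`.
#' @param order A [flow_order()].
#' @return An object of class `sequencing_key` with fields `bases`,
#'   `flow_span` (flows occupied by the key's greedy flowgram) and `flowgram`.
#' @export
sequencing_key <- function(bases = "TCAG", order = flow_order()) {
  order <- as_flow_order(order)
  chars <- split_bases(bases, "sequencing key")
  if (length(chars) == 0L) {
    stop_flowcode("sequencing key must be non-empty", "flowcode_invalid_sequence")
  }
  fg <- bases_to_flowgram(bases, order, 1L)
  structure(list(bases = toupper(bases), flow_span = length(fg$values),
                 flowgram = fg),
            class = "sequencing_key")
}

as_sequencing_key <- function(key, order = flow_order()) {
  if (inherits(key, "sequencing_key")) key else sequencing_key(key, order)
}

#' @export
print.sequencing_key <- function(x, ...) {
  cat("<sequencing_key> ", x$bases, " (", x$flow_span, " flows)\n", sep = "")
  invisible(x)
}

#' Extract the 11-flow barcode window from a read
#'
#' Greedily encodes the post-key portion of a read starting at the flow after
#' the key's last flow, and returns the first 10 flow values (the barcode
#' digits), the 11th flow value (the separator flow, a C flow under the
#' defaults) and the number of bases those 11 flows consumed. Digits greater
#' than 2 are retained as observed; the caller decides how to treat them.
#'
#' @param read_bases Read sequence beginning with the key.
#' @param key A [sequencing_key()] or key string.
#' @param order A [flow_order()].
#' @return A list with `digits` (length-10 integer vector),
#'   `separator_value` and `consumed_bases`.
#' @export
extract_barcode_window <- function(read_bases, key = sequencing_key(),
                                   order = flow_order()) {
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  if (!is.character(read_bases) || length(read_bases) != 1L || is.na(read_bases)) {
    stop_flowcode("read_bases must be a single character string",
                  "flowcode_invalid_sequence")
  }
  read_bases <- toupper(read_bases)
  if (!startsWith(read_bases, key$bases)) {
    stop_flowcode("read does not start with the sequencing key",
                  "flowcode_key_mismatch")
  }
  remainder <- substring(read_bases, nchar(key$bases) + 1L)
  fg <- bases_to_flowgram(remainder, order, start_flow = key$flow_span + 1L)
  if (length(fg$values) < 11L) {
    stop_flowcode("read too short to fill the 11-flow barcode window",
                  "flowcode_truncated_read")
  }
  list(digits = fg$values[1:10],
       separator_value = fg$values[11L],
       consumed_bases = sum(fg$values[1:11]))
}

## Nucleotides presented over the 11 barcode-window flows (window flow 1 is
## the flow after the key's last flow).
window_nucleotides <- function(key = sequencing_key(), order = flow_order()) {
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  flow_nucleotide(order, key$flow_span + 1:11)
}
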