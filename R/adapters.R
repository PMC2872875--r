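## Barcoded A-adapter assembly: the barcode (codeword + separator) is appended
## to the 3' end of the A-adapter top strand, so that every read carries
## key + barcode immediately before the insert. The true vendor adapter
## sequence is not public; `core` is therefore a required, configurable value
## with a documented placeholder. Chemistry annotations (phosphorothioate
## protection, the B adapter's 5' BioTEG) are carried as inert metadata only.

#' Default (placeholder) A-adapter core
#'
#' A documented stand-in for the proprietary A-adapter sequence; replace it
#' with the real adapter core when assembling production oligos.
#' @export
DEFAULT_ADAPTER_CORE <- "GCCTCCCTCGCGCCATCAG"

default_modifications <- function() {
  c(a_adapter = "4x phosphorothioate 5' and 3'",
    b_adapter = "5' BioTEG; 4x phosphorothioate 5' and 3'")
}

#' Build a barcoded A-adapter design
#'
#' Concatenates the A-adapter core with a barcode's rendered bases (separator
#' included) to give the synthesis top strand.
#'
#' @param barcode A single-row subset of a `barcode_set` table, or a list
#'   with `id` and `bases`.
#' @param core A-adapter core sequence (ACGT, non-empty). Default
#'   [DEFAULT_ADAPTER_CORE] (a placeholder).
#' @param modifications Named character vector of chemistry annotations,
#'   carried as metadata.
#' @return An object of class `adapter_design` with fields `id`, `core`,
#'   `barcode_id`, `barcode_bases`, `top_strand`, `modifications`.
#' @export
build_adapter <- function(barcode, core = DEFAULT_ADAPTER_CORE,
                          modifications = default_modifications()) {
  split_bases(core, "adapter core")
  if (nchar(core) == 0L) {
    stop_flowcode("adapter core must be non-empty", "flowcode_invalid_sequence")
  }
  if (is.data.frame(barcode)) barcode <- as.list(barcode[1L, ])
  if (is.null(barcode$bases) || is.null(barcode$id)) {
    stop_flowcode("barcode must provide 'id' and 'bases'",
                  "flowcode_invalid_word")
  }
  structure(list(id = paste0("A_", barcode$id),
                 core = toupper(core),
                 barcode_id = barcode$id,
                 barcode_bases = toupper(barcode$bases),
                 top_strand = paste0(toupper(core), toupper(barcode$bases)),
                 modifications = modifications),
            class = "adapter_design")
}

#' @export
print.adapter_design <- function(x, ...) {
  cat("<adapter_design> ", x$id, "\n  ", x$core, "|", x$barcode_bases,
      "\n  modifications: ", paste(x$modifications, collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

#' Build adapters for every barcode in a set
#'
#' @param set A `barcode_set`.
#' @inheritParams build_adapter
#' @return List of `adapter_design` objects.
#' @export
build_adapters <- function(set, core = DEFAULT_ADAPTER_CORE,
                           modifications = default_modifications()) {
  stopifnot(inherits(set, "barcode_set"))
  lapply(seq_len(nrow(set$table)), function(i) {
    build_adapter(set$table[i, ], core, modifications)
  })
}

#' Check that no barcode is a suffix of another
#'
#' Base-space barcode identification by suffix match on the adapter requires
#' that no barcode's rendered string be a suffix of another's. Flow-space
#' matching disambiguates even when this fails, so violations are reported,
#' not fatal.
#'
#' @param set A `barcode_set`.
#' @return A data frame of violating pairs (zero rows when the set is
#'   suffix-unique), with attribute `ok`.
#' @export
check_suffix_unique <- function(set) {
  stopifnot(inherits(set, "barcode_set"))
  bases <- set$table$bases
  ids <- set$table$id
  pairs <- list()
  for (i in seq_along(bases)) {
    hits <- endsWith(bases, bases[i])
    hits[i] <- FALSE
    if (any(hits)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        suffix_id = ids[i], of_id = ids[hits], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(suffix_id = character(0L), of_id = character(0L))
  }
  attr(out, "ok") <- nrow(out) == 0L
  out
}

#' Write / read an oligo synthesis sheet
#'
#' TSV with columns `id`, `sequence`, `modifications`; the round trip
#' `read_oligo_sheet(write_oligo_sheet(x))` is the identity on those fields.
#'
#' @param designs List of `adapter_design` objects.
#' @param path File path.
#' @return `write_oligo_sheet()` returns `path` invisibly;
#'   `read_oligo_sheet()` returns a data frame.
#' @export
write_oligo_sheet <- function(designs, path) {
  if (inherits(designs, "adapter_design")) designs <- list(designs)
  ids <- vapply(designs, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop_flowcode("duplicate oligo ids in synthesis sheet",
                  "flowcode_duplicate_id")
  }
  tab <- data.frame(
    id = ids,
    sequence = vapply(designs, `[[`, character(1L), "top_strand"),
    modifications = vapply(designs, function(d) {
      paste(d$modifications, collapse = "; ")
    }, character(1L)),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oligo_sheet
#' @export
read_oligo_sheet <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Export full adapter top strands as FASTA
#'
#' @param designs List of `adapter_design` objects.
#' @param path FASTA file path.
#' @return `path`, invisibly.
#' @export
write_adapter_fasta <- function(designs, path) {
  if (inherits(designs, "adapter_design")) designs <- list(designs)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(designs, `[[`, character(1L), "top_strand"),
    vapply(designs, `[[`, character(1L), "id")))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
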