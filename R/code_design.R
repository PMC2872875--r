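## Barcode words are length-10 ternary digit vectors; digit d on window flow f
## means d bases of that flow's nucleotide. A constant separator base (the
## window flow-11 nucleotide, C under the defaults) terminates every barcode so
## that it occupies exactly 11 flows and can be trimmed precisely.

BARCODE_DIGITS <- 10L

validate_digits <- function(digits) {
  digits <- as.integer(digits)
  if (length(digits) != BARCODE_DIGITS || anyNA(digits) ||
      any(digits < 0L | digits > 2L)) {
    stop_flowcode("a barcode word must be 10 digits, each in {0, 1, 2}",
                  "flowcode_invalid_word")
  }
  digits
}

## Enumerate all 3^n ternary words in lexicographic order (row 1 = 0...0).
all_ternary_words <- function(n_digits = BARCODE_DIGITS) {
  idx <- 0:(3L^n_digits - 1L)
  m <- matrix(0L, length(idx), n_digits)
  for (j in seq_len(n_digits)) {
    m[, j] <- as.integer((idx %/% 3L^(n_digits - j)) %% 3L)
  }
  m
}

## Vectorised rendering of digit matrices to base strings (separator included).
render_barcode_bases <- function(m, nucs) {
  if (nrow(m) == 0L) return(character(0L))
  parts <- lapply(seq_len(BARCODE_DIGITS), function(j) strrep(nucs[j], m[, j]))
  do.call(paste0, c(parts, list(nucs[11L])))
}

## Vectorised failure flags for the composition filters, one row per word.
## flow_span flags words whose digit vector is not the canonical greedy
## encoding of its own rendered bases (first run after window flow 4, or a
## gap of >= 3 zero flows after a run, shifts/merges runs on re-encoding and
## breaks the 11-flow span).
composition_filter_flags <- function(m, length_range = c(5L, 8L),
                                     key = sequencing_key(),
                                     order = flow_order()) {
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  nucs <- window_nucleotides(key, order)
  n_bases <- rowSums(m) + 1L
  fail_length <- n_bases < length_range[1L] | n_bases > length_range[2L]

  fnz <- max.col(cbind(m > 0L, TRUE), ties.method = "first") # 11 if all zero
  last_key_base <- substring(key$bases, nchar(key$bases), nchar(key$bases))
  key_base_flows <- which(nucs[1:10] == last_key_base)
  fail_leading <- fnz %in% key_base_flows

  bad_gap <- rep(FALSE, nrow(m))
  for (t in 1:7) {
    bad_gap <- bad_gap |
      (m[, t] > 0L & m[, t + 1L] == 0L & m[, t + 2L] == 0L & m[, t + 3L] == 0L)
  }
  fail_span <- rowSums(m) == 0L | fnz > 4L | bad_gap

  rendered <- render_barcode_bases(m, nucs)
  fail_homo <- grepl("AAA|CCC|GGG|TTT", rendered)

  data.frame(length = fail_length, leading_g = fail_leading,
             homopolymer = fail_homo, flow_span = fail_span)
}

#' Composition filters for candidate barcode words
#'
#' A candidate 10-digit ternary word is acceptable when (a) its rendered base
#' string, separator included, is 5-8 bases long; (b) its first rendered base
#' is not the key's last base (G for the TCAG key -- a leading G would merge
#' into the key's final flow); (c) the rendered barcode + separator string
#' contains no homopolymer run longer than two bases, including runs merged
#' across zero flows; and (d) the word spans exactly 11 flows, i.e. its digit
#' vector is the canonical greedy flowgram of its own rendered bases.
#'
#' @param digits Integer vector of 10 digits in {0, 1, 2}.
#' @param length_range Allowed rendered length (separator included),
#'   default `c(5, 8)`.
#' @param key,order Sequencing key and flow order anchoring the window.
#' @return A list with `pass` (logical) and `reasons` (character vector drawn
#'   from `"base-length"`, `"leading-G"`, `"homopolymer"`, `"flow-span"`).
#' @examples
#' passes_composition_filters(c(2, 0, 1, 0, 0, 2, 0, 1, 0, 0))  # TTCAAG + C
#' @export
passes_composition_filters <- function(digits, length_range = c(5L, 8L),
                                       key = sequencing_key(),
                                       order = flow_order()) {
  digits <- validate_digits(digits)
  flags <- composition_filter_flags(matrix(digits, 1L), length_range, key, order)
  labels <- c(length = "base-length", leading_g = "leading-G",
              homopolymer = "homopolymer", flow_span = "flow-span")
  reasons <- unname(labels[names(flags)[as.logical(flags[1L, ])]])
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Shortened ternary Hamming code [10, 7, 3]
#'
#' Constructs the linear ternary code of length 10 with 3^7 = 2187 codewords
#' and minimum Hamming distance 3, as the null space over GF(3) of a 3 x 10
#' parity-check matrix whose columns are distinct non-zero ternary 3-vectors,
#' no two of which are scalar multiples. The column order is fixed:
#' (0,1,1), (0,1,2), (1,0,1), (1,0,2), (1,1,0), (1,1,1), (1,1,2),
#' then the identity columns (1,0,0), (0,1,0), (0,0,1).
#'
#' @param length Code length; only 10 is implemented.
#' @param min_distance Minimum distance; only 3 is implemented.
#' @return Integer matrix with 2187 rows (codewords) and 10 columns, in the
#'   lexicographic order of the 7-digit message words.
#' @export
linear_ternary_code <- function(length = 10L, min_distance = 3L) {
  if (length != 10L || min_distance != 3L) {
    stop_flowcode("only the [10, 7, 3] ternary construction is implemented",
                  "flowcode_not_implemented")
  }
  h <- cbind(c(0L, 1L, 1L), c(0L, 1L, 2L), c(1L, 0L, 1L), c(1L, 0L, 2L),
             c(1L, 1L, 0L), c(1L, 1L, 1L), c(1L, 1L, 2L),
             c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  a <- h[, 1:7]                                  # H = [A | I3]
  g <- cbind(diag(7L), t((3L - a) %% 3L))        # G = [I7 | -A'] so H G' = 0
  messages <- all_ternary_words(7L)
  code <- (messages %*% g) %% 3L
  storage.mode(code) <- "integer"
  code
}

#' Greedy lexicode selection
#'
#' Scans candidate digit vectors in their given order and keeps a word iff
#' its Hamming distance to every previously kept word is at least
#' `min_distance`. Deterministic for a fixed candidate order; duplicates are
#' dropped (the first occurrence is considered).
#'
#' @param candidates Integer matrix, one candidate word per row.
#' @param min_distance Minimum pairwise Hamming distance, default 3.
#' @return Integer matrix of kept words, in scan order.
#' @export
greedy_lexicode <- function(candidates, min_distance = 3L) {
  candidates <- as.matrix(candidates)
  storage.mode(candidates) <- "integer"
  candidates <- candidates[!duplicated(candidates), , drop = FALSE]
  n <- nrow(candidates)
  kept <- matrix(0L, n, ncol(candidates))
  nk <- 0L
  for (i in seq_len(n)) {
    w <- candidates[i, ]
    if (nk > 0L) {
      d <- rowSums(kept[seq_len(nk), , drop = FALSE] != rep(w, each = nk))
      if (any(d < min_distance)) next
    }
    nk <- nk + 1L
    kept[nk, ] <- w
  }
  kept[seq_len(nk), , drop = FALSE]
}

#' Minimum pairwise Hamming distance
#'
#' Exhaustive minimum, over all unordered pairs of words, of the number of
#' digit positions at which the two words differ.
#'
#' @param words Integer matrix of digit vectors (one per row) or a
#'   [design_barcode_set()] result.
#' @return Integer scalar.
#' @export
min_pairwise_distance <- function(words) {
  if (inherits(words, "barcode_set")) words <- words$digits
  words <- as.matrix(words)
  n <- nrow(words)
  if (n < 2L) {
    stop_flowcode("need at least 2 words to compute a pairwise distance",
                  "flowcode_insufficient_input")
  }
  matches <- matrix(0, n, n)
  for (s in unique(as.vector(words))) {
    matches <- matches + tcrossprod((words == s) * 1)
  }
  d <- ncol(words) - matches
  as.integer(min(d[upper.tri(d)]))
}

## Hamming distances from one observed digit vector to every row of a matrix.
hamming_to_words <- function(digits, words) {
  rowSums(words != rep(as.integer(digits), each = nrow(words)))
}

#' Design a validated flow-space barcode set
#'
#' Builds the package's barcode panel: 10-digit ternary codewords rendered
#' over the 11-flow window after the sequencing key, filtered for
#' composition ([passes_composition_filters()]) and guaranteed a minimum
#' pairwise Hamming distance of 3, so any single flow miscall is correctable
#' and two miscalls are detectable.
#'
#' The default pipeline (`method = "lexicode"`, `filter_stage = "before"`)
#' enumerates all 3^10 digit vectors in lexicographic order, applies the
#' composition filters, then greedily selects a distance-3 subset. The
#' alternative (`method = "linear"`) generates the [10, 7, 3] ternary
#' Hamming code ([linear_ternary_code()]) and filters it.
#'
#' @param method `"lexicode"` (default) or `"linear"`.
#' @param filter_stage Apply the composition filters `"before"` (default) or
#'   `"after"` the distance selection. A filtered subset of a distance-3 set
#'   keeps its distance, so both orders yield valid sets.
#' @param min_distance Minimum pairwise Hamming distance, default 3.
#' @param length_range Allowed rendered base length including the separator,
#'   default `c(5, 8)`.
#' @param key,order Sequencing key and flow order.
#' @param seed Integer recorded in the design metadata (the default
#'   constructions are deterministic; the seed documents the run).
#' @return An object of class `barcode_set`: a list with `table` (data frame
#'   with columns `id`, `digits`, `bases`, `base_length`, `flow_span`),
#'   `digits` (integer matrix) and `metadata`.
#' @examples
#' set <- design_barcode_set()
#' nrow(set$table)
#' min_pairwise_distance(set)
#' @export
design_barcode_set <- function(method = c("lexicode", "linear"),
                               filter_stage = c("before", "after"),
                               min_distance = 3L,
                               length_range = c(5L, 8L),
                               key = sequencing_key(),
                               order = flow_order(),
                               seed = 1L) {
  method <- match.arg(method)
  filter_stage <- match.arg(filter_stage)
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)

  filter_words <- function(m) {
    flags <- composition_filter_flags(m, length_range, key, order)
    m[!Reduce(`|`, flags), , drop = FALSE]
  }

  if (method == "lexicode") {
    universe <- all_ternary_words()
    if (filter_stage == "before") {
      words <- greedy_lexicode(filter_words(universe), min_distance)
    } else {
      words <- filter_words(greedy_lexicode(universe, min_distance))
    }
  } else {
    words <- filter_words(linear_ternary_code(10L, min_distance))
  }

  metadata <- list(method = method, filter_stage = filter_stage,
                   min_distance = as.integer(min_distance),
                   length_range = as.integer(length_range),
                   key = key$bases,
                   flow_order = paste(order$nucleotides, collapse = ""),
                   seed = as.integer(seed))
  new_barcode_set(words, metadata, key, order)
}

new_barcode_set <- function(words, metadata, key = sequencing_key(),
                            order = flow_order(), ids = NULL) {
  storage.mode(words) <- "integer"
  rownames(words) <- NULL
  nucs <- window_nucleotides(key, order)
  bases <- render_barcode_bases(words, nucs)
  if (is.null(ids)) {
    ids <- sprintf("BC%04d", seq_len(nrow(words)))
  }
  window_start <- as_sequencing_key(key, order)$flow_span + 1L
  flow_span <- vapply(bases, function(b) {
    length(bases_to_flowgram(b, order, window_start)$values)
  }, integer(1L), USE.NAMES = FALSE)
  digit_strings <- if (nrow(words) > 0L) {
    unname(apply(words, 1L, paste, collapse = ","))
  } else character(0L)
  table <- data.frame(id = ids,
                      digits = digit_strings,
                      bases = bases,
                      base_length = nchar(bases),
                      flow_span = flow_span,
                      stringsAsFactors = FALSE)
  rownames(words) <- ids
  structure(list(table = table, digits = words, metadata = metadata),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  md <- x$metadata
  cat("<barcode_set> ", nrow(x$table), " barcodes",
      if (!is.null(md$method)) paste0(" (method=", md$method,
                                      ", min_distance=", md$min_distance, ")"),
      "\n", sep = "")
  cat("  base lengths: ", paste(range(x$table$base_length), collapse = "-"),
      "; flow spans: ", paste(unique(x$table$flow_span), collapse = ","),
      "\n", sep = "")
  print(utils::head(x$table, 5L))
  if (nrow(x$table) > 5L) cat("  ... ", nrow(x$table) - 5L, " more rows\n")
  invisible(x)
}

#' @export
summary.barcode_set <- function(object, ...) {
  validate_set(object)
}

#' Validate a barcode set
#'
#' Exhaustive in-silico validation of a barcode panel: word count, minimum
#' pairwise Hamming distance (brute force over all pairs), base-length
#' histogram, per-word composition-filter results, the 11-flow span check,
#' and single-error correctability (for every word and every single-digit
#' substitution, the perturbed vector is within distance 1 of no other word).
#'
#' @param set A `barcode_set`.
#' @param key,order Sequencing key and flow order (defaults from the set's
#'   metadata when present).
#' @return An object of class `barcode_validation`.
#' @export
validate_set <- function(set, key = NULL, order = NULL) {
  stopifnot(inherits(set, "barcode_set"))
  if (is.null(order)) {
    order <- if (!is.null(set$metadata$flow_order)) {
      flow_order(set$metadata$flow_order)
    } else flow_order()
  }
  if (is.null(key)) {
    key <- if (!is.null(set$metadata$key)) {
      sequencing_key(set$metadata$key, order)
    } else sequencing_key(order = order)
  }
  n <- nrow(set$digits)
  length_range <- set$metadata$length_range
  if (is.null(length_range)) length_range <- c(5L, 8L)

  if (n == 0L) {
    rep0 <- list(n_words = 0L, min_distance = NA_integer_,
                 length_histogram = table(integer(0L)),
                 per_word = data.frame(id = character(0L), pass = logical(0L),
                                       reasons = character(0L)),
                 flow_span_ok = TRUE,
                 single_error_correctable = TRUE, pass = TRUE)
    return(structure(rep0, class = "barcode_validation"))
  }

  flags <- composition_filter_flags(set$digits, length_range, key, order)
  labels <- c(length = "base-length", leading_g = "leading-G",
              homopolymer = "homopolymer", flow_span = "flow-span")
  reasons <- apply(as.matrix(flags), 1L, function(f) {
    paste(labels[names(flags)[f]], collapse = ";")
  })
  per_word <- data.frame(id = set$table$id, pass = !Reduce(`|`, flags),
                         reasons = reasons, stringsAsFactors = FALSE)

  min_d <- if (n >= 2L) min_pairwise_distance(set$digits) else NA_integer_

  ## every single-digit substitution of every word must be nearer (distance
  ## <= 1) to its source word than to any other word
  correctable <- TRUE
  if (n >= 2L) {
    perturbed <- matrix(0L, n * BARCODE_DIGITS * 2L, BARCODE_DIGITS)
    source_idx <- integer(nrow(perturbed))
    r <- 0L
    for (i in seq_len(n)) {
      w <- set$digits[i, ]
      for (j in seq_len(BARCODE_DIGITS)) {
        for (v in setdiff(0:2, w[j])) {
          r <- r + 1L
          p <- w
          p[j] <- v
          perturbed[r, ] <- p
          source_idx[r] <- i
        }
      }
    }
    matches <- matrix(0, nrow(perturbed), n)
    for (s in 0:2) {
      matches <- matches + tcrossprod((perturbed == s) * 1, (set$digits == s) * 1)
    }
    d <- BARCODE_DIGITS - matches
    d[cbind(seq_len(nrow(d)), source_idx)] <- Inf  # ignore the source word
    correctable <- all(apply(d, 1L, min) >= 2)
  }

  res <- list(n_words = n,
              min_distance = min_d,
              length_histogram = table(set$table$base_length),
              per_word = per_word,
              flow_span_ok = all(set$table$flow_span == 11L),
              single_error_correctable = correctable,
              pass = all(per_word$pass) && all(set$table$flow_span == 11L) &&
                correctable && (is.na(min_d) || min_d >= 3L))
  structure(res, class = "barcode_validation")
}

#' @export
print.barcode_validation <- function(x, ...) {
  cat("<barcode_validation>\n")
  cat("  words:                    ", x$n_words, "\n")
  cat("  min pairwise distance:    ", x$min_distance, "\n")
  cat("  base-length histogram:    ",
      paste(sprintf("%s:%d", names(x$length_histogram), x$length_histogram),
            collapse = "  "), "\n")
  cat("  all spans = 11 flows:     ", x$flow_span_ok, "\n")
  cat("  composition filters pass: ", all(x$per_word$pass), "\n")
  cat("  single-error correctable: ", x$single_error_correctable, "\n")
  cat("  overall:                  ", if (isTRUE(x$pass)) "PASS" else "FAIL", "\n")
  invisible(x)
}
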