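## Pyrosequencing-style read simulator. Noise acts in flow space -- each flow
## value v is replaced by max(0, round(Normal(v, sigma0 + sigma1 * v))), with
## an optional dropout of single-base flows -- matching the homopolymer error
## mechanism that motivates flow-space barcodes. Carry-forward and incomplete
## extension are deliberately omitted so the per-flow perturbation probability
## has a closed form.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Flow-level noise model
#'
#' @param sigma0 Baseline standard deviation of the Gaussian flow-value
#'   noise (flow-value units).
#' @param sigma1 Additional standard deviation per unit of homopolymer
#'   length, so a flow of value v is drawn with sd `sigma0 + sigma1 * v`.
#' @param p_dropout Probability that a flow whose true value is 1 reads as 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma0 = 0, sigma1 = 0, p_dropout = 0) {
  if (sigma0 < 0 || sigma1 < 0 || p_dropout < 0 || p_dropout > 1) {
    stop_flowcode("need sigma0, sigma1 >= 0 and p_dropout in [0, 1]",
                  "flowcode_invalid_noise")
  }
  structure(list(sigma0 = sigma0, sigma1 = sigma1, p_dropout = p_dropout),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> sigma0=%g sigma1=%g p_dropout=%g\n",
              x$sigma0, x$sigma1, x$p_dropout))
  invisible(x)
}

apply_flow_noise <- function(values, noise) {
  if (noise$sigma0 == 0 && noise$sigma1 == 0 && noise$p_dropout == 0) {
    return(values)
  }
  sd <- noise$sigma0 + noise$sigma1 * values
  w <- pmax(0L, as.integer(round(rnorm(length(values), values, sd))))
  drop <- values == 1L & runif(length(values)) < noise$p_dropout
  w[drop] <- 0L
  w
}

#' Closed-form per-flow perturbation probability
#'
#' Probability that a flow of true value `v` is emitted with a different
#' value under a [noise_model()]: the Gaussian term is one-sided for `v = 0`
#' (negative draws are floored back to 0) and two-sided otherwise, and the
#' dropout term applies to `v = 1` flows. Used as the independent oracle for
#' the simulator's empirical flow-error rate.
#'
#' @param v Integer vector of true flow values.
#' @param noise A [noise_model()].
#' @return Numeric vector of perturbation probabilities.
#' @export
flow_perturb_prob <- function(v, noise) {
  s <- noise$sigma0 + noise$sigma1 * v
  p_gauss <- ifelse(s <= 0, 0,
                    ifelse(v == 0,
                           stats::pnorm(0.5, 0, s, lower.tail = FALSE),
                           2 * stats::pnorm(-0.5, 0, s)))
  ifelse(v == 1L, noise$p_dropout + (1 - noise$p_dropout) * p_gauss, p_gauss)
}

load_templates <- function(templates) {
  if (is.character(templates) && length(templates) == 1L &&
      file.exists(templates) && !grepl("^[ACGTacgt]+$", templates)) {
    x <- Biostrings::readDNAStringSet(templates)
    templates <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  if (!is.character(templates) || length(templates) == 0L) {
    stop_flowcode("need at least one template sequence",
                  "flowcode_invalid_input")
  }
  if (is.null(names(templates))) {
    names(templates) <- sprintf("template%03d", seq_along(templates))
  }
  templates
}

#' Simulate a multiplexed pyrosequencing read set
#'
#' Each read is built as key + barcode bases + a random template substring,
#' encoded as a flowgram, perturbed flow by flow under the noise model, and
#' decoded back to bases. A truth table records every read's barcode,
#' template, insert and the number of perturbed flows inside the 11-flow
#' barcode window. Output is deterministic for a fixed seed.
#'
#' @param templates Named character vector of template sequences, or a FASTA
#'   path. Every template must be at least `max(insert_length)` long.
#' @param set A `barcode_set`.
#' @param n_per_barcode Reads per barcode (scalar, or one value per
#'   `barcode_ids`). Mutually exclusive with `proportions`.
#' @param proportions Per-barcode pool proportions (must sum to 1); reads are
#'   drawn multinomially with total `n_reads`.
#' @param n_reads Total reads when `proportions` is given.
#' @param noise A [noise_model()].
#' @param key,order Sequencing key and flow order.
#' @param insert_length Inclusive range of insert lengths, sampled uniformly.
#' @param barcode_ids Barcodes to include (default: all in `set`).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `sim_reads`: `reads` (named character),
#'   `truth` (data frame: `read_id`, `barcode_id`, `template_id`, `insert`,
#'   `n_window_flows_perturbed`) and `params`.
#' @export
simulate_reads <- function(templates, set, n_per_barcode = NULL,
                           proportions = NULL, n_reads = NULL,
                           noise = noise_model(), key = sequencing_key(),
                           insert_length = c(40L, 80L), barcode_ids = NULL,
                           seed = 1L, order = flow_order()) {
  stopifnot(inherits(set, "barcode_set"), inherits(noise, "noise_model"))
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  templates <- load_templates(templates)
  insert_length <- as.integer(insert_length)
  if (length(insert_length) == 1L) insert_length <- rep(insert_length, 2L)
  if (any(nchar(templates) < max(insert_length))) {
    stop_flowcode("every template must be at least max(insert_length) long",
                  "flowcode_invalid_input")
  }
  if (is.null(barcode_ids)) barcode_ids <- set$table$id
  if (!all(barcode_ids %in% set$table$id)) {
    stop_flowcode("barcode_ids must belong to the barcode set",
                  "flowcode_invalid_input")
  }
  bc_rows <- match(barcode_ids, set$table$id)

  with_seed(seed, {
    if (!is.null(proportions)) {
      if (is.null(n_reads)) {
        stop_flowcode("n_reads is required with proportions",
                      "flowcode_invalid_input")
      }
      if (length(proportions) != length(barcode_ids) ||
          abs(sum(proportions) - 1) > 1e-8) {
        stop_flowcode("proportions must match barcode_ids and sum to 1",
                      "flowcode_invalid_input")
      }
      counts <- as.integer(stats::rmultinom(1L, n_reads, proportions))
    } else {
      if (is.null(n_per_barcode)) {
        stop_flowcode("give either n_per_barcode or proportions",
                      "flowcode_invalid_input")
      }
      counts <- rep_len(as.integer(n_per_barcode), length(barcode_ids))
    }
    total <- sum(counts)
    span <- key$flow_span
    win_idx <- span + 1:11

    bc_of <- rep(seq_along(barcode_ids), counts)
    reads <- character(total)
    template_id <- character(total)
    insert <- character(total)
    n_pert <- integer(total)
    for (r in seq_len(total)) {
      ti <- sample.int(length(templates), 1L)
      len <- sample(insert_length[1L]:insert_length[2L], 1L)
      start <- sample.int(nchar(templates[ti]) - len + 1L, 1L)
      ins <- substr(templates[[ti]], start, start + len - 1L)
      bases <- paste0(key$bases, set$table$bases[bc_rows[bc_of[r]]], ins)
      fg <- bases_to_flowgram(bases, order, 1L)
      noisy <- apply_flow_noise(fg$values, noise)
      n_pert[r] <- sum(noisy[win_idx] != fg$values[win_idx])
      reads[r] <- flowgram_to_bases(flowgram(noisy, 1L), order)
      template_id[r] <- names(templates)[ti]
      insert[r] <- ins
    }
    ord <- sample.int(total)
    ids <- sprintf("read%06d", seq_len(total))
    truth <- data.frame(read_id = ids,
                        barcode_id = barcode_ids[bc_of[ord]],
                        template_id = template_id[ord],
                        insert = insert[ord],
                        n_window_flows_perturbed = n_pert[ord],
                        stringsAsFactors = FALSE)
    structure(list(reads = setNames(reads[ord], ids),
                   truth = truth,
                   params = list(noise = unclass(noise), key = key$bases,
                                 flow_order = paste(order$nucleotides,
                                                    collapse = ""),
                                 insert_length = insert_length,
                                 barcode_ids = barcode_ids,
                                 counts = counts, seed = as.integer(seed))),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("<sim_reads> ", length(x$reads), " reads over ",
      length(x$params$barcode_ids), " barcodes (seed ", x$params$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a simulated read set to disk
#'
#' Emits `<prefix>.fastq` (constant placeholder qualities),
#' `<prefix>.truth.tsv` and `<prefix>.params.yaml`.
#'
#' @param sim A `sim_reads` object.
#' @param prefix Output path prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_reads"))
  paths <- c(reads = paste0(prefix, ".fastq"),
             truth = paste0(prefix, ".truth.tsv"),
             params = paste0(prefix, ".params.yaml"))
  write_read_group(paths[["reads"]], sim$reads, quals = NULL, format = "fastq")
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(sim$params, paths[["params"]])
  invisible(paths)
}

## Canonical window digits: the greedy re-encoding of the rendered remainder
## reproduces them iff the first run sits on window flows 1-4 and no run is
## followed by three or more empty flows before the next run (separator at
## flow 11 included).
canonical_window_digits <- function(digits) {
  nz <- which(digits > 0L)
  if (length(nz) == 0L) return(FALSE)
  if (nz[1L] > 4L) return(FALSE)
  gaps <- diff(c(nz, 11L))
  all(gaps <= 3L)
}

#' Substitute barcode-window digits of a read
#'
#' Adversarial test harness: changes exactly `k` distinct digit flows of the
#' read's barcode window to different values in {0, 1, 2}, then rebuilds the
#' read. Substitutions are resampled until the perturbed window is still a
#' canonical flow-space encoding, so the demultiplexer observes exactly the
#' intended digit vector.
#'
#' @param read Read sequence (key + barcode + insert).
#' @param k Number of digit substitutions, 1 to 3.
#' @param key,order Sequencing key and flow order.
#' @param seed Optional seed for reproducible substitutions.
#' @return The perturbed read, with the perturbed digit vector in attribute
#'   `"digits"`.
#' @export
perturb_barcode_flows <- function(read, k, key = sequencing_key(),
                                  order = flow_order(), seed = NULL) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 3L) {
    stop_flowcode("k must be 1, 2 or 3", "flowcode_invalid_input")
  }
  order <- as_flow_order(order)
  key <- as_sequencing_key(key, order)
  run <- function() {
    remainder <- substring(read, nchar(key$bases) + 1L)
    fg <- bases_to_flowgram(remainder, order, key$flow_span + 1L)
    if (length(fg$values) < 11L) {
      stop_flowcode("read too short to fill the 11-flow barcode window",
                    "flowcode_truncated_read")
    }
    digits <- fg$values[1:10]
    for (attempt in 1:10000) {
      pos <- sample.int(BARCODE_DIGITS, k)
      cand <- digits
      for (p in pos) {
        cand[p] <- sample(setdiff(0:2, digits[p]), 1L)
      }
      if (canonical_window_digits(cand)) {
        fg$values[1:10] <- cand
        out <- paste0(key$bases, flowgram_to_bases(fg, order))
        attr(out, "digits") <- cand
        return(out)
      }
    }
    stop_flowcode("no canonical perturbation found", "flowcode_internal")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Mis-assignment experiment across noise settings
#'
#' Simulates a pool, demultiplexes it with the truth table in hand, and
#' tabulates the perfect / corrected / wrong / unassigned read fractions for
#' each noise setting. Settings may specify Gaussian flow noise (`sigma0`,
#' `sigma1`, `p_dropout`) or an exact number `k` of barcode-digit
#' substitutions per read (the adversarial harness); the four fractions sum
#' to 1 on every row.
#'
#' @param set A `barcode_set`.
#' @param templates Templates for [simulate_reads()].
#' @param settings Data frame with any of the columns `sigma0`, `sigma1`,
#'   `p_dropout`, `k` (missing columns default to 0); one experiment per row.
#' @param n_per_barcode Reads per barcode per experiment.
#' @param barcode_ids Barcodes to pool (default: all in `set`).
#' @param correct_errors Correction mode for the demultiplexer.
#' @param key,order Sequencing key and flow order.
#' @param insert_length Insert length range.
#' @param seed Base seed; row i uses `seed + i`.
#' @return Data frame: the settings plus `n_reads`, `perfect`, `corrected`,
#'   `wrong`, `unassigned` and `seed_used`.
#' @export
mis_assignment_experiment <- function(set, templates,
                                      settings = data.frame(sigma0 = c(0, 0.2)),
                                      n_per_barcode = 50L,
                                      barcode_ids = NULL,
                                      correct_errors = TRUE,
                                      key = sequencing_key(),
                                      insert_length = c(40L, 80L),
                                      seed = 1L, order = flow_order()) {
  for (col in c("sigma0", "sigma1", "p_dropout", "k")) {
    if (is.null(settings[[col]])) settings[[col]] <- 0
  }
  out <- settings
  out$n_reads <- NA_integer_
  out$perfect <- out$corrected <- out$wrong <- out$unassigned <- NA_real_
  out$seed_used <- seed + seq_len(nrow(settings))
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    nm <- if (s$k > 0) noise_model() else {
      noise_model(s$sigma0, s$sigma1, s$p_dropout)
    }
    sim <- simulate_reads(templates, set, n_per_barcode = n_per_barcode,
                          noise = nm, key = key,
                          insert_length = insert_length,
                          barcode_ids = barcode_ids,
                          seed = out$seed_used[i], order = order)
    reads <- sim$reads
    if (s$k > 0) {
      reads <- with_seed(out$seed_used[i] + 10000L, {
        setNames(vapply(reads, function(r) {
          as.character(perturb_barcode_flows(r, s$k, key, order))
        }, character(1L)), names(reads))
      })
    }
    rep <- demultiplex(reads, set, expected_ids = sim$params$barcode_ids,
                       key = key, correct_errors = correct_errors,
                       order = order)
    a <- rep$assignments
    stopifnot(identical(a$read_id, sim$truth$read_id))
    assigned <- !is.na(a$barcode_id)
    right <- assigned & a$barcode_id == sim$truth$barcode_id
    n <- nrow(a)
    out$n_reads[i] <- n
    out$perfect[i] <- sum(right & a$status == "perfect") / n
    out$corrected[i] <- sum(right & a$status == "corrected") / n
    out$wrong[i] <- sum(assigned & !right) / n
    out$unassigned[i] <- sum(!assigned) / n
  }
  out
}
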