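## Pooling arithmetic for multiplexed libraries. Libraries are quantified
## (molecules per microlitre, e.g. by qPCR) and pooled so that each sample
## contributes the same number of molecules; after sequencing, the evenness
## of read representation across barcodes is summarised against the
## conventional "within two-fold of the mean" band.

#' Equimolar pooling plan
#'
#' Computes, for each library, the volume contributing `target_molecules`
#' molecules to the pool: `volume = target / concentration`. Volumes outside
#' the pipettable range are flagged with a suggested dilution factor that
#' brings the sample to `min_volume` (factor > 1) or notes that the sample
#' is too dilute to reach the target within `max_volume` (factor < 1).
#'
#' @param concentrations Named positive numeric vector, molecules per
#'   microlitre per sample.
#' @param target_molecules Molecules each sample should contribute.
#' @param min_volume,max_volume Pipettable volume range in microlitres
#'   (optional).
#' @return An object of class `pool_plan`: a data frame with columns
#'   `sample`, `concentration`, `volume`, `in_range`, `dilution_factor`.
#' @examples
#' equimolar_plan(c(a = 2e9, b = 1e9), target_molecules = 1e9)
#' @export
equimolar_plan <- function(concentrations, target_molecules,
                           min_volume = NULL, max_volume = NULL) {
  if (!is.numeric(concentrations) || length(concentrations) == 0L) {
    stop_flowcode("concentrations must be a non-empty numeric vector",
                  "flowcode_invalid_input")
  }
  samples <- names(concentrations)
  if (is.null(samples)) {
    samples <- sprintf("sample%03d", seq_along(concentrations))
  }
  bad <- which(!is.finite(concentrations) | concentrations <= 0)
  if (length(bad) > 0L) {
    stop_flowcode(sprintf("non-positive concentration for sample(s): %s",
                          paste(samples[bad], collapse = ", ")),
                  "flowcode_invalid_input")
  }
  if (!is.numeric(target_molecules) || length(target_molecules) != 1L ||
      target_molecules <= 0) {
    stop_flowcode("target_molecules must be a single positive number",
                  "flowcode_invalid_input")
  }
  volume <- target_molecules / concentrations
  in_range <- rep(TRUE, length(volume))
  dilution <- rep(NA_real_, length(volume))
  if (!is.null(min_volume)) {
    low <- volume < min_volume
    in_range[low] <- FALSE
    dilution[low] <- min_volume / volume[low]  # dilute by this factor
  }
  if (!is.null(max_volume)) {
    high <- volume > max_volume
    in_range[high] <- FALSE
    dilution[high] <- max_volume / volume[high]  # < 1: needs concentrating
  }
  plan <- data.frame(sample = samples,
                     concentration = unname(concentrations),
                     volume = unname(volume),
                     in_range = in_range,
                     dilution_factor = dilution,
                     stringsAsFactors = FALSE)
  structure(plan, class = c("pool_plan", "data.frame"),
            target_molecules = target_molecules)
}

#' @export
print.pool_plan <- function(x, ...) {
  cat("<pool_plan> target ", format(attr(x, "target_molecules")),
      " molecules per sample\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Pooling evenness statistics
#'
#' Summarises per-barcode read counts: a barcode is "within two-fold of the
#' mean" iff `mean/fold <= count <= fold * mean` (closed interval,
#' `fold = 2` by default). Also reports the min/mean and max/mean ratios and
#' the coefficient of variation. The fraction is scale invariant.
#'
#' @param counts Numeric vector of per-barcode read counts (optionally
#'   named).
#' @param fold Width of the evenness band, default 2.
#' @return An object of class `evenness_summary` with fields `n_barcodes`,
#'   `mean_count`, `fraction_within`, `min_ratio`, `max_ratio`, `cv`,
#'   `fold`.
#' @examples
#' evenness_stats(c(4, 10, 10, 40))  # mean 16, band [8, 32] -> 0.5
#' @export
evenness_stats <- function(counts, fold = 2) {
  if (length(counts) == 0L || !is.numeric(counts) || anyNA(counts) ||
      any(counts < 0)) {
    stop_flowcode("counts must be a non-empty vector of non-negative numbers",
                  "flowcode_invalid_input")
  }
  if (fold < 1) {
    stop_flowcode("fold must be >= 1", "flowcode_invalid_input")
  }
  m <- mean(counts)
  within <- counts >= m / fold & counts <= fold * m
  res <- list(n_barcodes = length(counts),
              mean_count = m,
              fraction_within = mean(within),
              min_ratio = if (m > 0) min(counts) / m else NA_real_,
              max_ratio = if (m > 0) max(counts) / m else NA_real_,
              cv = if (m > 0) stats::sd(counts) / m else NA_real_,
              fold = fold)
  structure(res, class = "evenness_summary")
}

#' @export
print.evenness_summary <- function(x, ...) {
  cat("<evenness_summary> ", x$n_barcodes, " barcodes, mean count ",
      format(x$mean_count), "\n", sep = "")
  cat(sprintf("  within %g-fold of mean: %.1f%%\n", x$fold,
              100 * x$fraction_within))
  cat(sprintf("  min/mean = %s, max/mean = %s, CV = %s\n",
              format(x$min_ratio), format(x$max_ratio), format(x$cv)))
  invisible(x)
}
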