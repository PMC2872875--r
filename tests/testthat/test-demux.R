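templates <- make_templates()

test_that("noise-free pools demultiplex perfectly and trim byte-exactly", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 25L,
                        barcode_ids = small_pool_ids, seed = 7L)
  rep <- demultiplex(sim$reads, default_set, expected_ids = small_pool_ids)
  expect_identical(rep$n_reads, 100L)
  expect_identical(sum(rep$counts$perfect), 100L)
  expect_identical(sum(rep$unassigned), 0L)
  expect_identical(nrow(rep$contamination), 0L)
  a <- rep$assignments
  expect_identical(a$barcode_id, sim$truth$barcode_id)
  expect_identical(unname(substring(sim$reads, a$trim_start)), sim$truth$insert)
  # trim_start = key + barcode bases + one separator
  bc_len <- default_set$table$base_length[match(a$barcode_id, default_set$table$id)]
  expect_identical(a$trim_start, 4L + bc_len + 1L)
})

test_that("every single-digit substitution is corrected to the true barcode", {
  set <- default_set
  n <- nrow(set$digits)
  ok_corrected <- ok_exact <- logical(0L)
  for (i in seq_len(n)) {
    w <- set$digits[i, ]
    for (j in 1:10) {
      for (v in setdiff(0:2, w[j])) {
        p <- w
        p[j] <- v
        m <- flowcode:::match_barcode(p, set, correct_errors = TRUE)
        ok_corrected <- c(ok_corrected, identical(m$status, "corrected") &&
                            identical(m$barcode_id, set$table$id[i]))
        # exact-only mode leaves the read unassigned
        m0 <- flowcode:::match_barcode(p, set, correct_errors = FALSE)
        ok_exact <- c(ok_exact, identical(m0$status, "unassigned-distant"))
      }
    }
  }
  expect_identical(length(ok_corrected), n * 20L)
  expect_true(all(ok_corrected))
  expect_true(all(ok_exact))
})

test_that("perturbed reads are recovered (k=1) or safely rejected (k=2, exact mode)", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 10L,
                        barcode_ids = small_pool_ids, seed = 11L)
  r1 <- withr::with_seed(12, vapply(sim$reads, function(r) {
    as.character(perturb_barcode_flows(r, 1L))
  }, character(1L)))
  rep1 <- demultiplex(r1, default_set, expected_ids = small_pool_ids,
                      correct_errors = TRUE)
  expect_identical(rep1$assignments$barcode_id, sim$truth$barcode_id)
  expect_true(all(rep1$assignments$status == "corrected"))
  expect_true(all(rep1$assignments$n_flow_errors == 1L))

  r2 <- withr::with_seed(13, vapply(sim$reads, function(r) {
    as.character(perturb_barcode_flows(r, 2L))
  }, character(1L)))
  rep2 <- demultiplex(r2, default_set, expected_ids = small_pool_ids,
                      correct_errors = FALSE)
  # two flow errors are always detected, never silently cross-assigned
  expect_true(all(is.na(rep2$assignments$barcode_id)))
  expect_true(all(rep2$assignments$status == "unassigned-distant"))
})

test_that("reads from unexpected barcodes are reported as contamination", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 20L,
                        barcode_ids = small_pool_ids, seed = 21L)
  stray_id <- default_set$table$id[10L]
  stray <- simulate_reads(templates, default_set, n_per_barcode = 50L,
                          barcode_ids = stray_id, seed = 22L)
  reads <- c(sim$reads, setNames(stray$reads,
                                 paste0("stray_", names(stray$reads))))
  rep <- demultiplex(reads, default_set, expected_ids = small_pool_ids)
  expect_identical(rep$n_reads, 130L)
  expect_identical(sum(rep$counts$total) + sum(rep$unassigned), 130L)
  expect_identical(nrow(rep$contamination), 1L)
  expect_identical(rep$contamination$barcode_id, stray_id)
  expect_identical(rep$contamination$count, 50L)
  expect_equal(rep$contamination$fraction, 50 / 130)
})

test_that("empty input yields an empty, conserving report", {
  rep <- demultiplex(character(0L), default_set, expected_ids = small_pool_ids)
  expect_identical(rep$n_reads, 0L)
  expect_identical(sum(rep$counts$total) + sum(rep$unassigned), 0L)
})

test_that("demultiplexing writes trimmed per-sample files and an unassigned file", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 5L,
                        barcode_ids = small_pool_ids[1:2], seed = 31L)
  reads <- c(sim$reads, bad001 = "ACGTACGTACGTACGT")  # fails the key check
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "pool")
  rep <- demultiplex(reads, default_set, expected_ids = small_pool_ids[1:2],
                     out_prefix = prefix, format = "fastq")
  for (bc in small_pool_ids[1:2]) {
    path <- paste0(prefix, ".", bc, ".fastq")
    expect_true(file.exists(path))
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    expect_identical(length(x), 5L)
    ids <- sub("\\s.*$", "", names(x))
    expect_identical(sort(unname(as.character(x))),
                     sort(sim$truth$insert[sim$truth$barcode_id == bc]))
    expect_identical(sort(ids), sort(sim$truth$read_id[sim$truth$barcode_id == bc]))
  }
  ua <- Biostrings::readDNAStringSet(paste0(prefix, ".unassigned.fastq"),
                                     format = "fastq")
  expect_identical(length(ua), 1L)
  expect_match(names(ua), "key-mismatch")

  report_paths <- write_demux_report(rep, prefix)
  expect_true(all(file.exists(report_paths)))
  counts <- read.delim(report_paths[["counts"]])
  expect_identical(sum(counts$total), 10L)
})

test_that("FASTQ input round trips through demultiplexing", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 4L,
                        barcode_ids = small_pool_ids, seed = 41L)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, file.path(dir, "sim"))
  rep <- demultiplex(paths[["reads"]], default_set,
                     expected_ids = small_pool_ids)
  expect_identical(rep$n_reads, 16L)
  expect_identical(sum(rep$counts$perfect), 16L)
})

test_that("the flowgram TSV dialect round trips and rejects malformed lines", {
  fgs <- list(r1 = flowgram(c(1, 0, 2, 1), 1L), r2 = flowgram(c(0, 3, 1), 5L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_flowgram_tsv(fgs, f)
  back <- read_flowgram_tsv(f)
  expect_identical(length(back), 2L)
  expect_identical(back$r1$values, fgs$r1$values)
  expect_identical(back$r2$start_flow, 5L)

  writeLines(c("read_id\tstart_flow\tvalues", "r1\t1\t1,0,-2"), f)
  expect_error(read_flowgram_tsv(f), "line 2", class = "flowcode_parse_error")
  writeLines(c("read_id\tstart_flow\tvalues", "r1\t1"), f)
  expect_error(read_flowgram_tsv(f), class = "flowcode_parse_error")
})

test_that("raw flowgrams are assigned identically to their base-called reads", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 3L,
                        barcode_ids = small_pool_ids, seed = 51L)
  for (r in sim$reads[1:6]) {
    fg <- bases_to_flowgram(r)
    a_flow <- assign_flowgram(fg, default_set)
    a_base <- assign_read(r, default_set)
    expect_identical(a_flow$barcode_id, a_base$barcode_id)
    expect_identical(a_flow$status, a_base$status)
    expect_identical(a_flow$trim_start, a_base$trim_start)
  }
  short <- assign_flowgram(flowgram(c(1, 0, 1), 1L), default_set)
  expect_identical(short$status, "truncated")
  bad <- assign_flowgram(flowgram(rep(1L, 30L), 1L), default_set)
  expect_identical(bad$status, "key-mismatch")
})
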