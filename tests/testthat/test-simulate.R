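templates <- make_templates()

test_that("noise-free reads equal their construction and runs are reproducible", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 10L,
                        barcode_ids = small_pool_ids, seed = 5L)
  expected <- paste0("TCAG",
                     default_set$table$bases[match(sim$truth$barcode_id,
                                                   default_set$table$id)],
                     sim$truth$insert)
  expect_identical(unname(sim$reads), expected)
  expect_true(all(sim$truth$n_window_flows_perturbed == 0L))
  expect_identical(nrow(sim$truth), length(sim$reads))  # one truth row per read
  expect_true(all(sim$truth$barcode_id %in% default_set$table$id))

  again <- simulate_reads(templates, default_set, n_per_barcode = 10L,
                          barcode_ids = small_pool_ids, seed = 5L)
  expect_identical(again$reads, sim$reads)
  expect_identical(again$truth, sim$truth)

  other <- simulate_reads(templates, default_set, n_per_barcode = 10L,
                          barcode_ids = small_pool_ids, seed = 6L)
  expect_false(identical(other$reads, sim$reads))
})

test_that("simulation files round trip: FASTQ, truth table, params", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 3L,
                        barcode_ids = small_pool_ids, seed = 9L)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, file.path(dir, "sim"))
  expect_true(all(file.exists(paths)))
  reads <- Biostrings::readDNAStringSet(paths[["reads"]], format = "fastq")
  expect_identical(setNames(as.character(reads), names(reads)), sim$reads)
  truth <- read.delim(paths[["truth"]], stringsAsFactors = FALSE)
  expect_identical(truth$barcode_id, sim$truth$barcode_id)
  params <- yaml::read_yaml(paths[["params"]])
  expect_identical(params$seed, 9L)
  expect_identical(params$key, "TCAG")
})

test_that("proportions draw a multinomial pool of the requested size", {
  sim <- simulate_reads(templates, default_set,
                        proportions = c(0.5, 0.25, 0.125, 0.125),
                        n_reads = 400L, barcode_ids = small_pool_ids,
                        seed = 4L)
  expect_identical(length(sim$reads), 400L)
  counts <- table(sim$truth$barcode_id)
  expect_gt(counts[[small_pool_ids[1L]]], counts[[small_pool_ids[4L]]])
  expect_error(simulate_reads(templates, default_set,
                              proportions = c(0.5, 0.25), n_reads = 10L,
                              barcode_ids = small_pool_ids, seed = 1L),
               class = "flowcode_invalid_input")
  expect_error(simulate_reads(character(0L), default_set, n_per_barcode = 1L),
               class = "flowcode_invalid_input")
})

test_that("the noise model validates its parameters and perturbs flows", {
  expect_error(noise_model(sigma0 = -1), class = "flowcode_invalid_noise")
  expect_error(noise_model(p_dropout = 1.5), class = "flowcode_invalid_noise")
  sim <- simulate_reads(templates, default_set, n_per_barcode = 200L,
                        noise = noise_model(sigma0 = 0.3),
                        barcode_ids = small_pool_ids[1L], seed = 8L)
  expect_gt(sum(sim$truth$n_window_flows_perturbed), 0L)
  # dropout alone turns single-base flows into zeros
  simd <- simulate_reads(templates, default_set, n_per_barcode = 50L,
                         noise = noise_model(p_dropout = 1),
                         barcode_ids = small_pool_ids[1L], seed = 8L)
  expect_true(all(simd$truth$n_window_flows_perturbed > 0L))
})

test_that("closed-form per-flow perturbation probabilities match simulation", {
  nm <- noise_model(sigma0 = 0.25)
  # empirically estimate P(perturbed) for flow values 0..2
  withr::with_seed(77, {
    for (v in 0:2) {
      draws <- flowcode:::apply_flow_noise(rep(v, 40000L), nm)
      p_hat <- mean(draws != v)
      p <- flow_perturb_prob(v, nm)
      se <- sqrt(p * (1 - p) / 40000)
      expect_lt(abs(p_hat - p), 3 * se + 1e-12)
    }
  })
  # dropout contributes only at v = 1
  nm2 <- noise_model(p_dropout = 0.3)
  expect_equal(flow_perturb_prob(0:2, nm2), c(0, 0.3, 0))
})

test_that("digit substitutions change exactly k digits and stay canonical", {
  sim <- simulate_reads(templates, default_set, n_per_barcode = 5L,
                        barcode_ids = small_pool_ids, seed = 14L)
  withr::with_seed(15, {
    for (k in 1:3) {
      for (r in seq_along(sim$reads)) {
        true_digits <- default_set$digits[
          match(sim$truth$barcode_id[r], default_set$table$id), ]
        pr <- perturb_barcode_flows(sim$reads[[r]], k)
        w <- extract_barcode_window(as.character(pr))
        expect_identical(w$digits, attr(pr, "digits"))  # canonical: observed = intended
        expect_identical(sum(w$digits != true_digits), k)
      }
    }
  })
  expect_error(perturb_barcode_flows(sim$reads[[1L]], 4L),
               class = "flowcode_invalid_input")
})

test_that("three errors can cross over to another valid barcode", {
  set <- default_set
  # find a pair of set members at distance exactly 3
  found <- NULL
  for (i in 1:50) {
    d <- rowSums(set$digits != rep(set$digits[i, ], each = nrow(set$digits)))
    j <- which(d == 3L)
    if (length(j) > 0L) { found <- c(i, j[1L]); break }
  }
  expect_false(is.null(found))
  read_a <- paste0("TCAG", set$table$bases[found[1L]], "TAAGG")
  # rewrite the three differing digits to the other barcode's values
  remainder <- substring(read_a, 5L)
  fg <- bases_to_flowgram(remainder, start_flow = 9L)
  fg$values[1:10] <- set$digits[found[2L], ]
  crossed <- paste0("TCAG", flowgram_to_bases(fg))
  a <- assign_read(crossed, set, correct_errors = FALSE)
  expect_identical(a$status, "perfect")
  expect_identical(a$barcode_id, set$table$id[found[2L]])  # mis-assigned
})

test_that("mis-assignment experiments tabulate conserving fractions", {
  ex <- mis_assignment_experiment(
    set = default_set, templates = templates,
    settings = data.frame(sigma0 = c(0, 0.2, 0), k = c(0, 0, 1)),
    n_per_barcode = 15L, barcode_ids = small_pool_ids, seed = 30L)
  expect_equal(ex$perfect + ex$corrected + ex$wrong + ex$unassigned,
               rep(1, 3L))
  expect_identical(ex$perfect[1L], 1)           # noise off
  expect_identical(ex$wrong[3L], 0)             # k = 1 with correction on
  expect_identical(ex$corrected[3L], 1)
  expect_true(all(ex$n_reads == 60L))
})
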