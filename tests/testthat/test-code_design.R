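test_that("composition filters accept and reject the right words", {
  ok <- passes_composition_filters(c(2, 0, 1, 0, 0, 2, 0, 1, 0, 0))  # TTCAAG+C
  expect_true(ok$pass)
  expect_length(ok$reasons, 0L)

  g <- passes_composition_filters(c(0, 0, 0, 1, 1, 0, 0, 0, 1, 1))  # starts on G flow
  expect_false(g$pass)
  expect_true("leading-G" %in% g$reasons)

  # T runs merge across zero flows: renders TTTTAC
  hp <- passes_composition_filters(c(2, 0, 0, 0, 2, 1, 0, 0, 0, 0))
  expect_false(hp$pass)
  expect_true("homopolymer" %in% hp$reasons)

  # too short / too long rendered strings
  expect_true("base-length" %in%
                passes_composition_filters(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))$reasons)
  expect_true("base-length" %in%
                passes_composition_filters(c(2, 2, 2, 0, 2, 0, 0, 0, 0, 2))$reasons)

  # a C on window flow 7 followed by zeros merges with the separator C and
  # collapses the 11-flow span
  span <- passes_composition_filters(c(1, 1, 1, 0, 0, 1, 1, 0, 0, 0))
  expect_false(span$pass)
  expect_true("flow-span" %in% span$reasons)

  expect_error(passes_composition_filters(c(3, rep(0, 9))),
               class = "flowcode_invalid_word")
  expect_error(passes_composition_filters(1:5), class = "flowcode_invalid_word")
})

test_that("the [10,7,3] ternary construction has 2187 words at distance exactly 3", {
  code <- linear_ternary_code(10, 3)
  expect_identical(dim(code), c(2187L, 10L))
  expect_false(anyDuplicated(code) > 0L)
  expect_true(any(rowSums(code) == 0L))  # contains the zero word
  expect_identical(min_pairwise_distance(code), 3L)
  # linearity: sums of random codeword pairs are codewords
  withr::with_seed(5, {
    keys <- apply(code, 1L, paste, collapse = "")
    for (i in 1:50) {
      pair <- sample(nrow(code), 2L)
      s <- (code[pair[1L], ] + code[pair[2L], ]) %% 3L
      expect_true(paste(s, collapse = "") %in% keys)
    }
  })
  expect_error(linear_ternary_code(8, 3), class = "flowcode_not_implemented")
})

test_that("greedy lexicode keeps only words far from all kept words", {
  one <- matrix(c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L), 1L)
  expect_identical(greedy_lexicode(one), one)

  two <- rbind(rep(0L, 10L), c(1L, 1L, rep(0L, 8L)))  # distance 2
  expect_identical(greedy_lexicode(two), two[1L, , drop = FALSE])

  withr::with_seed(11, {
    cand <- matrix(sample(0:2, 200L * 10L, replace = TRUE), ncol = 10L)
    sel <- greedy_lexicode(cand, 3L)
    expect_true(min_pairwise_distance(sel) >= 3L)
    # greedy maximality: every rejected candidate is within distance 2 of a kept word
    for (i in seq_len(nrow(cand))) {
      d <- rowSums(sel != rep(cand[i, ], each = nrow(sel)))
      expect_true(min(d) < 3L || any(d == 0L))
    }
  })
})

test_that("min_pairwise_distance is the exhaustive Hamming minimum", {
  w <- rep(0L, 10L)
  expect_identical(min_pairwise_distance(rbind(w, w)), 0L)
  w3 <- w; w3[c(2, 5, 9)] <- 1L
  expect_identical(min_pairwise_distance(rbind(w, w3)), 3L)
  expect_error(min_pairwise_distance(matrix(w, 1L)),
               class = "flowcode_insufficient_input")
  # agrees with a naive double loop on a random small set
  withr::with_seed(21, {
    m <- matrix(sample(0:2, 30L * 10L, replace = TRUE), ncol = 10L)
    naive <- min(utils::combn(nrow(m), 2L, function(p) sum(m[p[1L], ] != m[p[2L], ])))
    expect_identical(min_pairwise_distance(m), as.integer(naive))
  })
})

test_that("the default design yields a large validated distance-3 panel", {
  set <- default_set
  expect_gte(nrow(set$table), 144L)
  expect_identical(min_pairwise_distance(set), 3L)
  expect_true(all(set$table$flow_span == 11L))
  expect_true(all(set$table$base_length >= 5L & set$table$base_length <= 8L))
  for (i in seq_len(nrow(set$digits))) {
    expect_true(passes_composition_filters(set$digits[i, ])$pass)
  }
  expect_identical(set$table$id[1L], "BC0001")

  # cross-module oracle: re-encoding each rendered barcode reproduces
  # digits + separator over exactly 11 window flows
  win_start <- sequencing_key()$flow_span + 1L
  for (i in seq_len(nrow(set$digits))) {
    fg <- bases_to_flowgram(set$table$bases[i], start_flow = win_start)
    expect_identical(fg$values, c(set$digits[i, ], 1L))
  }
})

test_that("design is deterministic and the linear variant also validates", {
  expect_identical(design_barcode_set()$table, default_set$table)

  lin <- design_barcode_set(method = "linear")
  expect_gte(nrow(lin$table), 2L)
  expect_gte(min_pairwise_distance(lin), 3L)
  expect_true(all(lin$table$flow_span == 11L))
  expect_true(validate_set(lin)$pass)
})

test_that("validate_set reports distance failures and handles the empty set", {
  v <- validate_set(default_set)
  expect_true(v$pass)
  expect_true(v$single_error_correctable)
  expect_identical(v$min_distance, 3L)
  expect_identical(sum(v$length_histogram), nrow(default_set$table))

  # two words at distance 2 must be flagged
  w1 <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 0L)
  w2 <- w1; w2[c(1L, 2L)] <- 2L
  bad <- flowcode:::new_barcode_set(rbind(w1, w2), list())
  vb <- validate_set(bad)
  expect_identical(vb$min_distance, 2L)
  expect_false(vb$pass)
  expect_false(vb$single_error_correctable)

  v0 <- validate_set(flowcode:::new_barcode_set(matrix(integer(0L), 0L, 10L), list()))
  expect_identical(v0$n_words, 0L)
  expect_true(v0$pass)
})

test_that("barcode tables round trip byte-identically", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_table(default_set, f1)
  back <- read_barcode_table(f1)
  expect_identical(back$table, default_set$table)
  expect_identical(back$digits, default_set$digits)
  write_barcode_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(default_set, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(seqs), setNames(default_set$table$bases,
                                                default_set$table$id))
})
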