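# Shared fixtures, built in code. The default barcode panel is deterministic,
# so it is computed once per test run.

default_set <- design_barcode_set()

# random templates long enough for any insert the tests request
make_templates <- function(n = 2L, len = 300L, seed = 42L) {
  withr::with_seed(seed, {
    setNames(
      vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      }, character(1L)),
      sprintf("template%02d", seq_len(n)))
  })
}

# random ACGT string
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a small 4-barcode pool used by the demux tests
small_pool_ids <- default_set$table$id[1:4]
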