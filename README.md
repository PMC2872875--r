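# flowcode

Error-correcting molecular barcodes designed directly in 454 pyrosequencing
"flow space", for labs multiplexing many samples (small genomes, amplicons,
viral isolates) into a single sequencing run and sorting the reads back out
afterwards — with per-read contamination tracking and pooling-evenness QC.

## The idea

A pyrosequencer presents nucleotides in a fixed cyclic flow order (TACG); at
each flow the signal reports how many bases of that nucleotide were
incorporated. The dominant error mode is not a substitution but a
homopolymer length miscall — a single *flow value* off by one. flowcode
therefore treats a barcode not as a base string but as a ternary codeword
**d** = (d₁, …, d₁₀), dᵢ ∈ {0, 1, 2}, where dᵢ is the homopolymer length on
the i-th flow of a fixed window that starts right after the TCAG sequencing
key. A constant separator cytosine terminates the word on the window's 11th
flow (a C flow), so every barcode:

* occupies **exactly 11 flows**,
* renders to **5–8 bases** (separator included),
* contains **no homopolymer longer than two bases**,
* never starts with G (the key's final base, which would merge flows), and
* sits at **Hamming distance ≥ 3** (over digits) from every other barcode —
  one flow miscall is correctable, two are always detectable.

Two constructions are provided: a greedy lexicode over the filtered 3¹⁰
universe (default, maximises yield: 191 barcodes) and the linear [10, 7, 3]
ternary Hamming code (3⁷ = 2187 codewords, minimum distance exactly 3).
Around the design sit adapter-oligo assembly, a flow-space demultiplexer
with optional single-error correction, equimolar pooling arithmetic,
evenness/contamination reporting, and a flow-level read simulator that makes
every claim testable without instrument data.

## Worked example

```r
library(flowcode)

set <- design_barcode_set()   # enumerate 3^10, filter, greedy distance-3 select
set
#> <barcode_set> 191 barcodes (method=lexicode, min_distance=3)
#>   base lengths: 5-8; flow spans: 11
#>       id              digits    bases base_length flow_span
#> 1 BC0001 0,0,1,0,0,1,0,0,1,1    CATAC           5        11
#> 2 BC0002 0,0,1,0,0,1,0,1,0,2   CAGAAC           6        11
#> 3 BC0003 0,0,1,0,0,1,0,2,2,0  CAGGTTC           7        11
#> ...

summary(set)                  # exhaustive validation
#> <barcode_validation>
#>   words:                     191
#>   min pairwise distance:     3
#>   base-length histogram:     5:8  6:20  7:38  8:125
#>   all spans = 11 flows:      TRUE
#>   composition filters pass:  TRUE
#>   single-error correctable:  TRUE
#>   overall:                   PASS
```

Simulate a noisy 4-plex pool and demultiplex it with error correction:

```r
set.seed(42)
templates <- c(hiv1 = paste(sample(c("A","C","G","T"), 300, TRUE), collapse = ""))
sim <- simulate_reads(templates, set, n_per_barcode = 250,
                      noise = noise_model(sigma0 = 0.2),
                      barcode_ids = set$table$id[1:4], seed = 7)
demultiplex(sim$reads, set, expected_ids = set$table$id[1:4],
            correct_errors = TRUE)
#> <demux_report> 1000 reads, correction on
#>   assigned:   926 (865 perfect, 61 corrected)
#>   unassigned: 74 (unassigned-ambiguous=0, unassigned-distant=9, key-mismatch=65, truncated=0)
#>   contamination (unexpected barcodes):
#>   barcode_id count fraction
#> 1     BC0008     1    0.001
#> ...
#>   evenness: 100.0% of expected barcodes within two-fold of the mean
```

Reading the report: `perfect` reads matched a barcode's digit vector
exactly; `corrected` reads were one flow value off and uniquely recovered
(possible because the minimum distance is 3); `key-mismatch` reads lost
their TCAG key to noise and are never barcode-matched; the contamination
table lists reads carrying a *valid* panel barcode that was not pooled —
exactly how a real cross-contamination event surfaces. With noise off the
report is 100% perfect and trimming returns each insert byte-for-byte.

Pooling arithmetic:

```r
equimolar_plan(c(s1 = 2e9, s2 = 1e9), target_molecules = 1e9)  # volumes 0.5, 1.0 µl
evenness_stats(c(4, 10, 10, 40))   # mean 16, band [8, 32] -> 50% within two-fold
```

A thin command-line interface covering design / validate / simulate / demux
/ poolstats / poolplan lives in `inst/cli/flowcode`; see the methods
vignette (`vignettes/flowspace-barcoding.Rmd`) for the full model
description, parameter choices and limitations.

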