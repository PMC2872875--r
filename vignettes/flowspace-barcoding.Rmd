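---
title: "Designing and using flow-space barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and using flow-space barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowcode)
```

## Flow space and why barcodes should live there

A pyrosequencer reads DNA one reagent *flow* at a time: nucleotides are
presented in a fixed cyclic order (T, A, C, G on the 454 platform) and the
light signal at each flow encodes how many bases of that nucleotide were
incorporated. A read is therefore natively a *flowgram* — a vector of
non-negative integers, one per flow — and base calls are derived from it.
Crucially, the dominant sequencing error is a homopolymer length miscall:
one flow value off by one. In base space that single event inserts or
deletes a base and shifts every downstream coordinate, which is why
substitution-distance barcodes behave poorly on this chemistry. In flow
space the same event changes exactly one coordinate of the flowgram.

flowcode therefore defines barcodes directly in flow space. The greedy
encoding implemented by `bases_to_flowgram()` places each maximal run of a
nucleotide on the first subsequent flow presenting it; `flowgram_to_bases()`
inverts it. The pair is mutually inverse — an invariant the test suite
exercises on 10,000 generated sequences — and the sum of flow values always
equals the sequence length.

## The barcode model

Every read starts with the sequencing key (TCAG by default), whose greedy
flowgram spans 8 flows and ends on a G flow. The **barcode window** is
defined as the 11 flows immediately after that, so it always begins on a T
flow and its 11th flow is a C flow. A barcode is a ternary digit vector
$d = (d_1, \dots, d_{10})$, $d_i \in \{0,1,2\}$, giving the homopolymer
length on each of the window's first 10 flows, followed by a constant
separator C on flow 11. The separator guarantees a non-zero final flow (a
fixed 11-flow span) and contributes exactly one base, so trimming removes
key + barcode bases + one C; if the insert itself begins with C, the extra
Cs merge into flow 11 on the instrument but remain with the insert after
trimming — no insert base is ever lost.

Distance between barcodes is the Hamming distance over the 10 digits: a
digit differing by any magnitude counts once, and the separator flow takes
no part. At minimum pairwise distance 3, one flow miscall is uniquely
correctable and two are always detectable.

### Composition filters

`passes_composition_filters()` applies four checks to a candidate word:

* **base-length** — the rendered string, separator included, must be 5–8
  bases, i.e. $\sum_i d_i \in [4, 7]$. We read the conventional 5–8 base
  range as *including* the separator C, since the validated barcode that is
  synthesised and sequenced carries it; the band is a configurable argument
  (`length_range`) for users who prefer the other reading.
* **leading-G** — the first rendered base must not equal the key's last
  base (G): a barcode starting with G would merge into the key's final G
  flow and shift the whole window.
* **homopolymer** — the rendered barcode + separator string may contain no
  run longer than two bases. Runs can merge across zero flows (two T digits
  four flows apart with nothing in between render adjacently), and a C on
  window flow 7 can merge with the separator; the filter checks the
  rendered string, so both cases are caught.
* **flow-span** — the digit vector must be the *canonical* greedy encoding
  of its own rendered bases: the first non-zero digit within window flows
  1–4 and never three or more empty flows between successive runs
  (separator included). Without this, re-encoding the rendered bases would
  place runs on earlier flows, the word would span fewer than 11 flows, and
  a noise-free read would demultiplex to the wrong digits. This check is
  what makes "exactly 11 flows" operational; the first three filters alone
  do not imply it.

### Constructions and tie-breaking

Two constructions are provided:

* **Greedy lexicode** (default): enumerate all $3^{10} = 59049$ words in
  lexicographic order (smallest first — fixed for reproducibility), keep
  those passing the filters, then scan in order keeping each word at
  Hamming distance ≥ 3 from everything kept so far. Filtering before
  selection maximises yield; `filter_stage = "after"` is available and also
  yields a valid (smaller) set, since any subset of a distance-3 set keeps
  its distance.
* **Linear [10, 7, 3] ternary Hamming code**: the null space over GF(3) of
  a parity-check matrix whose 10 columns are distinct non-zero ternary
  3-vectors, no two proportional (column order documented in
  `?linear_ternary_code`). It has $3^7 = 2187$ codewords at minimum
  distance exactly 3 — verified in the tests by exhaustive pairwise
  comparison — and is then composition-filtered.

The lexicode is the default because the filters interact badly with
linearity (a linear code cannot adapt to them), so greedy selection over
the filtered universe yields a larger panel; the acceptance script computes
191 barcodes under the defaults, comfortably above the 144 a large
plate-based production run requires. Ids are assigned `BC0001…` in
selection order, and identical parameters always produce byte-identical
barcode tables (`write_barcode_table()` emits sorted metadata and no
timestamps).

`validate_set()` re-derives everything exhaustively: per-word filters, the
11-flow span, minimum pairwise distance by brute force, and single-error
correctability (all 20 single-digit perturbations of every word, each
required to be within distance 1 of no other word).

## Demultiplexing

`assign_read()` anchors the window on the key (reads failing the key check
are never barcode-matched), extracts the 10 observed digits — values above
2 are retained as observed, not clamped — and matches:

* exact digit match → `perfect`;
* otherwise, with `correct_errors = TRUE`, a unique barcode at distance 1 →
  `corrected`; none within 1 → `unassigned-distant`; a tie at distance 1 is
  impossible for a distance-3 panel but handled defensively as
  `unassigned-ambiguous`.

A deliberate asymmetry follows from coding theory: a distance-3 code
*corrects* one error but only *detects* two. With correction enabled, a
read carrying two flow errors can land at distance 1 of a codeword three
away from the truth and be mis-corrected; in exact-match mode two errors
can never cross over (a cross-assignment would imply two codewords at
distance 2). The package tests the two-error safety property in exact mode,
which is also the recommended production mode when per-read error rates are
low. Both modes are exposed because the observed perfect-barcode rate in
practice is high enough that correction buys little.

`demultiplex()` wraps this per read, writes trimmed per-sample FASTA/FASTQ
(via Biostrings; qualities are preserved through trimming), and reports:
per-barcode perfect/corrected totals, unassigned counts by reason,
**contamination** (reads carrying a valid panel barcode absent from
`expected_ids` — the signature of a sample swap or carry-over, trackable to
the individual read), and pooling evenness. Counts always conserve:
assigned + unassigned = input reads. A flow-space path
(`assign_flowgram()`, plus a plain-text flowgram TSV dialect standing in
for binary SFF) gives identical assignments on base-called reads; both are
provided because detection could equally be run on raw flowgrams or after
base calling.

## The simulator and what passing its tests shows

`simulate_reads()` builds each read as key + barcode bases + a uniformly
sampled template substring, encodes it as a flowgram, perturbs every flow
value $v$ to $\max(0, \mathrm{round}(\mathcal{N}(v, \sigma_0 + \sigma_1
v)))$, optionally drops single-base flows to zero with probability
`p_dropout`, and decodes back to bases. Noise acts in flow space because
that is the physical error mechanism the barcodes are designed against.
Defaults are noise-free (`sigma0 = 0`): the baseline condition for the
exactness properties. For noisy scenarios the tests use
$\sigma_0 = 0.2$–$0.3$, which puts the per-flow miscall probability near
1%, the right order for a well-running instrument; real per-flow error
rates vary between runs, so noise is exposed as free parameters rather than
asserted as a calibration.

The per-flow perturbation probability has a closed form
(`flow_perturb_prob()`): two-sided normal tail for $v \ge 1$, one-sided for
$v = 0$ (the flooring at zero means a zero flow can only be perturbed
upward), plus the dropout term at $v = 1$. The acceptance suite simulates
10,000 reads and requires the empirical fraction of reads with at least one
perturbed window flow to match the per-read closed form within 3 binomial
standard errors.

What the simulator deliberately omits: carry-forward and incomplete
extension (which make real flow noise weakly correlated across flows),
quality-value modelling (output qualities are constant placeholders), and
paired/jumping constructs. Passing tests therefore demonstrate the coding
properties and the pipeline's bookkeeping under the stated noise model, not
instrument-calibrated error rates.

`perturb_barcode_flows()` is the adversarial harness: it substitutes
exactly *k* window digits, resampling until the perturbed window is still a
canonical encoding so the demultiplexer observes exactly the intended digit
vector. The guarantees — k = 1 always recovered with correction on, k = 2
never cross-assigned in exact mode, k = 3 able to cross (demonstrated on a
pair at distance exactly 3) — are tested exhaustively at the digit level
and on simulated reads.

## Pooling

`equimolar_plan()` implements molarity normalisation: volume = target
molecules / concentration (molecules per µl, e.g. from qPCR — the assay
itself is out of scope; concentrations are inputs). Volumes outside the
pipettable band get a dilution-factor suggestion. `evenness_stats()`
summarises per-barcode read counts against the closed band
$[\bar{c}/2,\ 2\bar{c}]$ — the most common reading of "within two-fold of
the mean", exposed via `fold` for other conventions. The fraction is scale
invariant, and the all-equal case (including the degenerate all-zero input)
is defined as 1.

## Numerical and interface choices

* Flow indices are 1-based (flows are conventionally counted from 1);
  sequence positions in reports are 1-based; internals use 0-based offsets
  where convenient.
* Degenerate inputs are defined, not errored, where a sensible value
  exists: empty read sets give empty conserving reports; the empty barcode
  set validates trivially; `evenness_stats(0)` is 1.
* All randomness (simulation, perturbation, experiments) flows from a
  single integer seed; runs restore the caller's RNG state.
* Test and example problem sizes — a 4-plex pool, 250–2500 reads per
  barcode, 10,000-case property sweeps — were chosen so the whole suite
  validates the exhaustive claims (every word × every perturbation) in well
  under a minute on one core.

## Known limitations

* The vendor A/B adapter cores are proprietary; `build_adapter()` ships a
  documented placeholder and chemistry annotations (phosphorothioate
  protection, BioTEG) are inert metadata.
* Native binary SFF is not parsed; the flowgram TSV dialect covers the
  flow-space path.
* Quality-aware matching, Levenshtein-distance designs and quaternary codes
  are out of scope.
* The exact membership of any historically synthesised panel is not
  reproduced here; the constructions are parameterised and deterministic,
  which is what matters for a new deployment.
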