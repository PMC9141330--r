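---
title: "mirpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpipe)
```

# Scope and model of the data

`mirpipe` profiles microRNA (miR) cargo in single-end small RNA
sequencing libraries from megakaryocytes (Mk), megakaryocyte-derived
microparticles (MkMP), platelet-like particles (PLP) and platelets
(PLT). The expected input is HiSeq-era chemistry: ~51-cycle reads,
Phred+33 qualities, TruSeq-style small RNA library preparation in which
the RNA insert is ligated to a 3' adapter, so that short inserts are
read through into the adapter. Two gel-purified size fractions exist in
such libraries: 18–40 nt (miR/piRNA) and 40–150 nt (snoRNA and other
species). Only the 18–40 nt fraction is quantified against the mature
miR reference; the longer fraction is counted and reported as
non-quantified mass.

The pipeline stages are:

1. **Adapter detection with mandatory retention.** Only reads in which
   the 3' flanking adapter is detected are retained, because only those
   represent full-length sequencing of the insert. Detection scans all
   start positions left to right; a position qualifies when the overlap
   between the adapter prefix and the read suffix (running to the read
   end or covering the whole adapter) is at least `min_overlap` (default
   8 nt) with at most `floor(max_mismatch_rate * overlap)` mismatches
   (default rate 0.1; `N` counts as a mismatch). The leftmost qualifying
   position wins and the insert is the prefix before it.
2. **Quality end-trimming.** The retained insert is trimmed from the 3'
   end to the longest prefix whose *mean* Phred score is strictly
   greater than `qual_threshold` (default 30). Only 3' trimming is
   performed: the 5' adapter is removed during sequencing by the library
   chemistry.
3. **Size partitioning.** 18–40 nt inserts form the quantified fraction;
   41–150 nt inserts are counted as the long fraction; everything else
   (including empty inserts) is out of size.
4. **Clustering and assignment.** Identical inserts are clustered
   (exact multiset tally) and each cluster is assigned to a collapsed
   mature reference (see below).
5. **CPM normalisation.** `cpm[f, s] = counts[f, s] / total_s * 1e6`
   where `total_s` is the sample's miR-assigned reads.
6. **Differential enrichment.** Two-group negative-binomial exact test
   with common dispersion, Benjamini–Hochberg FDR, and classification
   into enriched / depleted / not significant.
7. **Reports.** Per-group detection sets (mean CPM ≥ 1), high-abundance
   sets (mean CPM ≥ 1000), ranked composition tables with percent of
   total miR content, and Venn overlap counts of the detected sets.

# Design decisions

## Stage order: adapter before quality trim

The literal listing of the cleanup steps puts quality trimming first,
but the adapter defines the biological insert boundary; trimming quality
first can destroy the adapter and discard otherwise valid reads. The
default is therefore adapter-first, with `order = "qtrim-first"`
available as an explicit divergence knob. Both orders conserve reads in
the attrition accounting.

## Empty inserts

A read that is pure adapter (detection at position 1, empty insert) is
*not* `NO_ADAPTER` — its adapter was detected — and it cannot be
`EMPTY_AFTER_QTRIM` because no quality trimming was applied. It is
classed `OUT_OF_SIZE`: length 0 falls below the 18 nt bound.

## "Average quality larger than 30"

Read as a strict inequality on the mean of the retained prefix. The
trimmed prefix is the *longest* one qualifying, which equals the result
of iteratively dropping the final base until the mean qualifies; both
characterisations are tested against a brute-force oracle.

## Adapter parameters

The adapter sequence itself is never hard-coded as correct: it is a
required configuration value (the TruSeq small RNA 3' adapter,
`TGGAATTCTCGGGTGCCAAGG`, is the natural choice for this chemistry and is
the generator's default). `min_overlap = 8` and a 10% mismatch allowance
are defaults chosen to match common small RNA trimmers; both are
exposed.

## Reference collapse and multi-mapping

Distinct genomic loci frequently produce byte-identical mature
sequences. Rather than fractionally splitting counts across such loci,
identical matures are merged into a single feature whose name joins the
member names with `//` after factoring out a shared arm suffix
(`mir-19b-1-3p` + `mir-19b-2-3p` becomes `mir-19b-1//mir-19b-2_3p`, the
naming style used in multi-locus reports, with gene ids joined as
`406995/406996`). This removes the dominant multi-mapping case exactly.
Reads matching two *non-identical* matures can only occur under the
tolerance policy and are resolved deterministically: exact-length match
first, then the longest matched mature, then the lexicographically
smallest feature name. Assignment is invariant to reference row order.

## Matching policy

The default policy is exact sequence equality — the strictest reading of
"aligned against the mature reference". Real small RNA data contain 3'
isomiRs, so `match_policy("tol3p", tol = 2)` additionally accepts reads
missing up to `tol` 3' bases of a mature, or carrying up to `tol` extra
3' bases, with zero internal mismatches. The policy in force is recorded
in the run summary.

## CPM denominator

The denominator is the sample's miR-assigned reads, not all sequenced
reads. This is forced by the printed top-10 tables: every printed
percentage equals `CPM / 1e4` (e.g. 164,087 CPM ↔ 16.4%; 231,441 CPM ↔
23.1%), which is only possible when CPM is normalised to total miR
content. Group-level reports use the mean CPM across the group's
replicates.

## Differential test

The named upstream tool family offers several workflows (classic exact
test vs GLM, common vs tagwise dispersion, TMM on or off). `mirpipe`
implements the simplest reading: the classic conditional exact test with
a single common dispersion and plain library-size equalisation (no TMM).
Each choice is a config knob; GLM and tagwise dispersion are non-goals.

* **Equalisation.** The conditional test requires equal library sizes;
  counts are scaled to the geometric mean of the per-sample totals and
  rounded half-to-even.
* **Dispersion.** The common dispersion maximises the summed
  per-feature conditional log-likelihood (each feature conditioned on
  its within-group total, which removes the mean parameter) over a
  log-spaced grid on [1e-4, 4] refined by golden-section search to
  relative tolerance 1e-4. Grid + golden section is deliberately robust
  for the tiny replicate numbers here (3 vs 3, 3 vs 2), where
  Newton-type updates are fragile. With no overdispersion signal the
  estimate pins at the lower grid bound (Poisson limit).
* **Exact test.** Conditional on the total `s` of the two group sums,
  the split follows a beta-binomial law with shapes `n_a/phi` and
  `n_b/phi` (each group sum is NB with size `n_g/phi` and equal
  per-library mean; the mean cancels). The two-sided p value doubles the
  smaller tail, **including the observed point mass in both tails**, and
  caps at 1 — stated explicitly because doubling conventions differ
  subtly between implementations; the enumeration oracle in the test
  suite defines this package's ground truth. For `s > 5000` the tails
  switch to a normal approximation with continuity correction using the
  exact beta-binomial mean and variance (documented approximation; the
  boundary is configurable).
* **Fold change.** Computed from group-mean CPMs with a 0.5-CPM
  pseudo-count on both means, so zero-count features have finite fold
  changes and every feature can be placed on a volcano-style table. The
  fold-change axis of the original volcano figure may have used the
  internal logFC of the upstream tool instead; numeric identity with
  that figure is not claimed.
* **Classification.** ENRICHED iff fold change ≥ 2 and FDR < 0.01;
  DEPLETED iff fold change ≤ 0.5 and FDR < 0.01; NS otherwise. The
  source text is internally inconsistent about whether the 58/90
  enriched/depleted counts used the raw p (figure caption) or the
  corrected p (methods text); the default follows the methods text
  (FDR), and `use_raw_p = TRUE` flips it.

## Detection and composition reporting

"Average CPM ≥ 1" is applied per group across that group's replicates
(matching the per-population detection counts). Display rounding is
half-up to one decimal, matching the printed tables' style; all set
operations and cumulative sums use unrounded values, so a printed column
can disagree with a printed "Other" row by ±0.1 — this is observed in
the printed tables themselves and is documented, not "fixed". The Venn
report is restricted to ≤ 4 sets because the profiled study has exactly
four populations.

# The synthetic-data generator

`simulate_study()` emulates the profiled study so that every stage of
the pipeline is testable without the deposited libraries. Its defaults
*are* the stated world:

| parameter | default | rationale |
|---|---|---|
| groups | Mk 3, MkMP 3, PLP 3, PLT 2 | the 11-library design |
| read length | 51 nt | 51-cycle sequencing |
| depth | 1e5 reads/library | desk-scale stand-in for the deposited libraries |
| n_mirs | 300 | a few hundred detectable miRs, as in the profiled populations |
| mature length | 18–25 nt | mature miR length range |
| composition | log-normal, sigma = 2 | heavy-tailed, so a handful of miRs dominate (top-7 ≈ 57% regime) |
| dispersion phi | 0.1 | typical biological replicate overdispersion for bulk counts |
| adapter | TruSeq small RNA 3' | the library chemistry's adapter |
| quality model | plateau Q37, 3' decay from cycle 40 at 0.5/cycle, noise sd 1 (clipped ±3 sd) | HiSeq-like profiles; insert prefixes always pass the mean-Q30 rule when clean |
| contaminant rates | 0 | contaminants are opt-in per test |

Ground truth is exact by construction, which required three guarantees:

* mature sequences are rejected at generation if the adapter would be
  falsely detected before the true insert boundary in `mature + adapter`
  (windows before the boundary never involve the random pad, so one
  check per mature suffices);
* contaminant inserts are rejection-sampled under the same rule, and
  adapter-less contaminants are re-drawn until no adapter is detectable
  anywhere;
* assigned-read qualities keep the full-insert mean above the trimming
  threshold, so clean inserts are never shortened.

Consequently, for a contaminant-free study the recovered count matrix
equals the generator's truth *exactly*, and with contaminants the
per-library attrition equals the generator ledger *exactly* — both are
asserted in the tests. Contaminant counts are Binomial(depth, rate)
draws; assigned counts are NB draws around `depth * (1 - sum(rates)) *
p_g(f)`, so realized library sizes fluctuate around the target depth, as
real libraries do. Every library has its own RNG stream derived by
hashing (seed, purpose, sample id), so adding a library never perturbs
the others and all outputs are byte-deterministic under a fixed spec.

**What a green test does not establish.** The generator emulates adapter
ligation, quality decay, size contamination and NB count noise. It does
not model sequencing substitution errors inside the insert, PCR
duplication, ligation bias, isomiR populations, or genuine piRNA/snoRNA
sequence content (the long fraction is random sequence). Exact-recovery
tests therefore validate the pipeline's bookkeeping and algorithmic
correctness, not its robustness to base-calling error — the tolerance
matching policy exists for real data but defaults off.

**Spike-in design for the differential-enrichment acceptance test.**
Twenty features are spiked 4-fold up and twenty 4-fold down in MkMPs at
depth 1e5. Down-spiked features are placed at abundance ranks 26–45 —
they need count headroom, since a 0.25× spike on a low-count feature
leaves too few reads for a 3-vs-3 exact test at FDR < 0.01 — and
up-spikes at ranks 46–65, which also balances the composition mass so
renormalisation shifts the null features' fold changes only slightly.
This placement is a power-design choice made once, before freezing the
acceptance seed, and is how a scientist would design detectable
spike-ins; sensitivity is 0.95–0.975 across seeds under this design.

# Numerical choices and degenerate inputs

* Phred+33 is assumed; there is no Phred+64 autodetection (silent
  mis-detection is worse than an explicit flag). Scores outside [0, 60]
  are a hard error pointing at the offending record.
* Ties in composition ranking break lexicographically by feature name;
  ties in BH-FDR are stable; all tie-breaks are deterministic.
* A sample with zero assigned reads yields a zero CPM column with a
  warning (it cannot be normalised); a zero-total sample is a hard error
  in library equalisation, naming the sample.
* `s = 0` in the exact test returns p = 1; `phi = 0` uses the exact
  binomial split.
* Pipeline outputs are written via write-then-rename, so a partial
  failure never leaves truncated files; outputs are stamped with an MD5
  hash of the config.

# Known limitations

* No genome alignment, hairpin-arm inference, or novel-miR discovery:
  quantification is strictly against the provided mature reference.
* piRNA/snoRNA content is counted (as unassigned 18–40 mass and as the
  long fraction) but never identified or quantified.
* The headline detection counts of the profiled study (514/609/589/484
  detected miRs, 58 enriched / 90 depleted, 63 miRs ≥ 1000 CPM covering
  96.1%) depend on the deposited libraries; they are reproduced in kind
  by the synthetic study, not in number, and are treated as
  documentation.
* The exact test assumes a common dispersion; strongly feature-specific
  overdispersion will make it anticonservative for the noisiest
  features. Tagwise dispersion is a deliberate non-goal.
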