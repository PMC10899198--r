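---
title: "Methods: MPRA quantification and allele-specific enhancer calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MPRA quantification and allele-specific enhancer calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpracall)
```

This vignette is the package's account of its models and the design
choices behind them: what each stage assumes, which parameters matter
and why their defaults are what they are, what the simulator does and
does not emulate, and where the genuinely open decisions were made.

## The assay and its data

A massively parallel reporter assay couples each candidate regulatory
sequence to many random 20 bp barcodes in a reporter plasmid. After
transfection, the plasmid DNA pool and the transcribed RNA pool are
sequenced; a barcode's RNA/DNA count ratio measures the activity of its
linked element. Three kinds of sequencing feed the pipeline:

1. **Association reads** (paired-end, from the inert library): read 1
   carries a fixed 21-mer adapter followed by the element sequence;
   read 2 carries the barcode between two fixed guide sequences. These
   establish which barcode belongs to which element.
2. **DNA count reads** per replicate: barcodes from the delivered
   plasmid pool, locating each barcode between assay-specific guides.
3. **RNA (cDNA) count reads** per replicate: barcodes from the
   transcribed pool.

## Library design

Each variant contributes two 230 bp elements: a fixed 15 bp adapter,
a 200 bp genomic insert, and a second fixed adapter. The insert places
the variant base at 0-based offset 99 (99 bases upstream, the allele,
100 downstream). Centring an even-length window is ambiguous by one
base; offset 99 was fixed once so that element sequences — and all
tests — are exact. Only single-nucleotide substitutions are supported
(indels are rejected with a typed error), elements are taken from the
forward strand of the supplied genome, and soft-masked lowercase bases
are uppercased rather than rejected.

## Exact matching everywhere

All read parsing is exact: the association adapter must match as a
prefix; a trimmed read maps to an element only if it is an exact,
unambiguous prefix of that element's post-adapter sequence (zero
mismatches, zero indels — a read too short to span the variant offset
is shared by the allele pair and dropped as ambiguous); barcodes must
sit exactly between their guides and contain no N. Exact matching
trades recall for precision: corrupted reads are rejected, not
misassigned, which the simulation tests verify directly. No quality
scores are used, and no indel-tolerant or error-correcting matching is
attempted (a Hamming-cluster barcode corrector would be a natural
extension).

A barcode observed with more than one element is resolved by majority:
it is kept only if the top element holds at least a `dominance`
fraction (default 0.9) of its read support, otherwise dropped. The
default is deliberately strict — at typical association depths a
barcode's reads overwhelmingly support one element, and raising the
threshold can only shrink the map (a property the tests assert).

## Aggregation filters

Barcode-level counts are aggregated to elements under two rules:

* **Presence across replicates.** A barcode contributes only if its
  DNA count is at least 1 in *every* replicate. The DNA pool witnesses
  that the plasmid was delivered; a zero RNA count is then a meaningful
  "delivered but silent" observation, so RNA presence is *not*
  required by default (`require_rna_presence = FALSE` — configurable,
  and worth flagging because either reading of "present across all
  replicates" is defensible).
* **Minimum complexity.** Elements represented by fewer than
  `min_barcodes = 5` contributing barcodes are dropped. The two allele
  elements of a variant are filtered independently, so a variant can
  lose one allele here; such variants are skipped (and logged) by the
  allelic model rather than modelled with unbalanced data.

## Activity and general enhancers

Activity is `log2` of depth-normalised RNA over DNA with a pseudocount
of 1 on both assays. The pseudocount keeps activities finite for
RNA-silent elements and biases ratios by less than 0.01 once counts
reach ~1000; it is the only smoothing applied. Pooled activity `A_e`
uses counts summed over replicates, and general enhancers are called at
`z >= 3` on the standardised pooled activities (sample SD, all retained
elements — including controls — forming the background). Calling is
one-sided by default because the target class is *enhancers*; a
`two_sided` option flags the silencer-like negative tail, which is
otherwise reported but not called. If all activities are equal the SD
is zero, z is defined as 0 everywhere, and nothing is called.

## The moderated allelic model

For the balanced design — both alleles retained, same replicates — a
mixed model with replicate as a correlated block is exactly equivalent
to the paired formulation on per-replicate differences
`d_r = a_alt,r − a_ref,r`. That equivalence is why the implementation
uses paired differences: it is exact here, transparent, and easy to
verify against an ordinary paired t-test (setting the prior df to 0
reduces to it, a property tested at 1e-8). The limit of the
equivalence is unbalanced data, which is skipped, not modelled.

Per variant: `beta = mean(d_r)`, `s² = var(d_r)` with `d_g = R − 1`
degrees of freedom, unscaled variance `v = 1/R`. The empirical-Bayes
prior `(d0, s0²)` is estimated from all variants by method of moments
on `e_g = log s²_g − digamma(d_g/2) + log(d_g/2)`: the prior df solves
`trigamma(d0/2) = max(0, var(e)·n/(n−1) − mean(trigamma(d_g/2)))` by
monotone bisection on `[1e-4, 1e6]` at tolerance 1e-8, with `d0 = Inf`
when the excess dispersion is non-positive (then `s0² = exp(mean(e))`).
Posterior variances `s̃² = (d0·s0² + d_g·s²)/(d0 + d_g)` give moderated
`t = beta/(s̃·sqrt(v))` on `d0 + d_g` df. With only `R − 1 = 2` residual
df per variant, this shrinkage is what makes the test usable at all —
the library-wide ensemble stabilises every variant's variance.

P-values are adjusted by an in-package Benjamini–Hochberg step-up
(cross-checked against `p.adjust` and a direct double-loop
implementation) and tiered at adjusted p < 0.05 (*active*) and
[0.05, 0.1) (*suggestive*). The optional B statistic is the posterior
log-odds of differential activity under a two-component mixture with
prior proportion 0.01; its effect-variance component is moment-matched
on the strongest `prior_prop` fraction of effects, making B a ranking
diagnostic rather than a calibrated posterior — it is off by default.

Zero-variance corner cases are defined explicitly: an all-zero
difference vector gives `t = 0, p = 1`; the degenerate all-variances-
zero ensemble is an error.

## Annotation arithmetic

* **Depletion rank**: each variant's score is the mean over all 500 bp
  windows covering it; on the 50 bp grid that is ~10 windows. Windows
  are validated to be exactly 500 bp with scores in [0, 1]; coordinates
  are 0-based half-open.
* **TFBS delta scores** in [−1, 1] are thresholded at |score| ≥ 0.8,
  *inclusive* (the cutoff is stated as ±0.8 without strictness, so the
  boundary is documented rather than guessed both ways); negative =
  predicted disruption, positive = creation.
* **Interval overlap** uses the variant position ±100 bp against
  0-based half-open (BED) intervals.
* **Proportion tests** are Pearson chi-square on the k×2 table, with
  Yates continuity correction for k = 2 only — the default behaviour
  of the standard proportion test, and the combination that reproduces
  both published p-value families (three-group uncorrected, two-group
  corrected) from the same counts. Percentages are rounded half-up to
  2 decimals for report parity.

## The simulator

`simulate_library()` → `simulate_assoc_reads()` / `simulate_counts()`
generate data with exactly the structure the analysis assumes, plus the
planted truth needed for recovery tests:

* Barcode complements per element are log-normal (sdlog 1) around
  `barcode_mean = 449`, truncated to [1, 9333] — the scale observed in
  real libraries of this design. Barcode abundances within the pool are
  log-normal (sdlog 0.8), normalised to weights.
* A fraction `frac_enhancer = 0.03` of variants get baseline activity
  `alpha ~ N(2, 0.5)` shared by both alleles; `frac_allelic = 0.005`
  get an allelic effect `|beta| ~ N(1.5, 0.3)` with random sign
  (roughly the proportions seen in a library of ~5000 disease-linked
  variants with ~27 allele-specific calls).
* DNA counts are multinomial over the weights at the configured depth.
  RNA expectations multiply each weight by
  `2^(alpha + beta·[alt] + u_r)`, with a replicate effect
  `u_r ~ N(0, replicate_sd = 0.05)` shared across all barcodes and
  both alleles of a replicate — so the paired model's invariance to
  replicate shifts is exercised by construction. RNA counts are
  negative binomial (`nb_dispersion = 0.05`) or multinomial at
  dispersion 0, the setting used for exact round-trip tests.
* One global seed drives a fixed per-stage offset stream, so any stage
  can be regenerated independently and byte-identically.

What the simulator does **not** emulate: PCR chimeras and duplicates,
index hopping, GC and length bias, quality-score structure, and
unequal replicate depths. Passing round-trip and calibration tests
therefore certify the *computation* — parsing, counting, filtering and
inference — not robustness to every artefact of real sequencing runs.

## Problem sizes used in tests

The shipped tests and the acceptance script run the simulator at desk
scale, chosen to exercise every code path with comfortable margins:
round trips use 30-variant libraries (~8 barcodes/element, depth
3×10⁴); null calibration uses 120 variants × 20 seeds at depth 4×10⁵;
power checks plant ±2 logFC effects at depth 10⁶; hyperparameter
recovery uses 2000 variances from a scaled-χ² prior with d0 = 4,
s0² = 1. The statistical guarantees asserted (false-positive fraction
at adjusted p < 0.05 of at most 7% under the null, sensitivity of at
least 80% with |logFC| = 2, mean logFC bias within ±0.1, d0 recovered
in [3, 5]) hold with slack at these sizes.

## Known limitations

* Barcode-level modelling with precision weights is out of scope; the
  model works on aggregated element counts only, and only total-count
  normalisation is offered.
* Unbalanced allele pairs are skipped, not modelled.
* Exact matching discards all reads carrying errors in anchored
  regions; with long association reads this costs recall (documented
  and simulated) and would need error-tolerant matching for
  low-quality data.
* The B statistic's effect-variance estimator is a simple moment
  match; rank interpretation only.
* The ±0.8 TFBS threshold and the z ≥ 3 enhancer cutoff are
  conventions, not optimised quantities; both are parameters.
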