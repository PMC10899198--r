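# mpracall

Enhancer and allele-specific variant calling for massively parallel
reporter assays (MPRA).

## The problem

MPRAs test thousands of candidate regulatory sequences at once: each
~200 bp genomic element is synthesised in both its reference- and
alternate-allele form, tagged with many random 20 bp barcodes, cloned
upstream of a minimal promoter, and transfected into cells. Sequencing
the barcodes in the plasmid DNA pool and in the transcribed RNA pool
gives, per barcode, a pair of counts whose ratio measures the linked
element's regulatory activity. The questions the assay answers are
(i) *which elements act as enhancers at all* and (ii) *for which
variants the two alleles drive significantly different activity* — the
allele-specific regulatory variants that fine-map GWAS signals to
functional bases.

`mpracall` implements the full computation for this design, from raw
reads to calls, for users analysing their own barcode-level MPRA data or
validating an analysis on simulated data with planted ground truth.

## The statistics at the core

Per element *e* and replicate *r*, with DNA/RNA counts aggregated over
that element's barcodes and a pseudocount of 1:

    a_er = log2( ((rna_er + 1) / N_rna,r) / ((dna_er + 1) / N_dna,r) )

where the `N` are per-replicate assay totals. **General enhancers** are
elements whose pooled (across-replicate) activity `A_e` is at least 3
sample standard deviations above the library mean (`z_e >= 3`).

**Allele-specific enhancers** come from a moderated paired linear model.
With replicate as the block, the balanced two-allele design reduces
exactly to per-replicate differences `d_r = a_alt,r − a_ref,r`, giving
per variant *g*: effect `beta_g = mean(d_r)` (the reported logFC),
residual variance `s²_g = var(d_r)` on `d_g = R − 1` degrees of freedom,
and unscaled variance `v = 1/R`. Variances are shrunk toward an
empirical-Bayes prior estimated from the whole library by
method-of-moments on log variances (`e_g = log s²_g − ψ(d_g/2) +
log(d_g/2)`, solving `ψ′(d₀/2) = var(e) · n/(n−1) − mean(ψ′(d_g/2))`):

    s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g)
    t_g  = beta_g / (s̃_g · sqrt(v)),   df = d₀ + d_g

Two-sided p-values are Benjamini–Hochberg adjusted and tiered:
**active** below adjusted p 0.05, **suggestive** in [0.05, 0.1).

Around that core sit exact-match read parsers (adapter-anchored element
alignment with zero mismatches/indels; guide-flanked barcode
extraction), the aggregation filters (barcode present in every
replicate's DNA; at least 5 barcodes per element), and downstream
annotation arithmetic (depletion-rank window means, TFBS delta-score
thresholding at |score| ≥ 0.8, ±100 bp interval overlap, and k-group
proportion tests).

## Worked example

Simulate a small library with planted allelic effects, run the count →
call path, and compare against the planted truth:

```r
library(mpracall)

cfg <- sim_config_tiny(seed = 42, frac_allelic = 0.05)  # 200 variants
sim <- simulate_library(cfg)
smc <- simulate_counts(sim$truth, cfg)
map <- build_barcode_map(sim$truth$barcodes$barcode,
                         sim$truth$barcodes$element_id)
elements <- aggregate_elements(smc$counts, map, min_barcodes = 5)
activity <- compute_activity(elements)

enh <- call_general_enhancers(activity, z_threshold = 3)
sum(enh$is_enhancer)
#> [1] 13

fit <- fit_allelic(activity)
fit
#> Moderated allelic activity fit
#>   variants tested: 148 | replicates: 3 | skipped (one allele): 42
#>   prior df d0 = 9.033, prior variance s0^2 = 0.04296, df = 11.03
#>   tiers: 10 active (adj.p < 0.05), 1 suggestive (< 0.1), 137 ns

subset(as.data.frame(fit), tier == "active")[1:4, ]
#>  variant_id  logFC      t        p    adj_p  B   tier
#>      sv0002  1.465  12.94 5.18e-08 5.62e-06 NA active
#>      sv0003 -1.456  -6.39 5.06e-05 8.32e-04 NA active
#>      sv0013 -1.457 -11.25 2.19e-07 6.49e-06 NA active
#>      sv0022 -1.295 -10.54 4.25e-07 8.98e-06 NA active
```

The printed `logFC` is the alt-minus-ref activity difference on the
log2 scale; `t` is the moderated statistic; the `tier` encodes the BH
cutoffs. In this run 9 of the 10 planted allelic variants (|logFC|
drawn near 1.5) are recovered as active; 42 variants lost one allele to
the 5-barcode filter, mirroring what happens in real libraries.

The same analysis runs from FASTQ files on disk through the staged
pipeline (`run_pipeline()` with a YAML manifest; stages `design`,
`map`, `count`, `aggregate`, `call`, `annotate`), writing deterministic
TSV artifacts and a run log.

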