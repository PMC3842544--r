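# cpgdrift

Hematopoietic stem and progenitor cells (HPCs, the CD34+ fraction of cord
blood) acquire reproducible DNA **hypermethylation** within days of in
vitro culture — concentrated in upstream promoter regions (TSS1500) and in
CpG-island shores, co-located with hematopoietic transcription-factor
binding sites, and reflected in down-regulated expression of the affected
genes. `cpgdrift` is an R package for the complete desk analysis behind
such a study, aimed at epigenomics analysts working with methylation-array
beta values and paired (donor-matched) designs.

The statistical core:

* **Paired moderated t** per CpG: with pair differences
  `d_k = beta_b(k) − beta_a(k)` over donors `k = 1..n`, the statistic is
  `t = delta / sqrt(s²_post / n)` with posterior variance
  `s²_post = (d0·s0² + (n−1)·s²) / (d0 + n−1)` on `d0 + n − 1` degrees of
  freedom; `(d0, s0²)` are moment-matched across sites, and `d0 = 0`
  recovers the classical paired t-test exactly. Sites are first confined
  to the most variable 50% across all samples; p-values are
  Benjamini–Hochberg adjusted and directions called at adjusted p < 0.05.
* **Context enrichment**: exact upper-tail hypergeometric `P(X ≥ k)` of
  hyper/hypo calls per gene-region label (TSS1500, TSS200, 5'UTR, first
  exon, body, 3'UTR, intergenic) and CGI relation (island; shore = first
  2 kb outside an island; shelf = next 2 kb; open sea), against the whole
  array as background; one-sided Fisher gene-set tests on GMT input.
* **Motif & peak co-location**: log2-odds PWM scanning of 124 bp windows
  centered on hypermethylated CpGs (hit ⇔ score ≥ 0.8 × max score, both
  strands), hypergeometric window enrichment, and one-sided Fisher peak
  co-location at window widths 124/200/500/1000 bp.
* **Expression integration**: paired moderated differential expression,
  extreme-expression deciles, context-resolved methylation means, and the
  quadrant Fisher test of promoter (TSS200) hypermethylation × expression
  down-regulation.
* **Synthetic data with ground truth**: a seeded generator producing
  manifests, CGI intervals, genome sequences, donor-paired logit-normal
  beta values with planted hypermethylation, motif- and peak-bearing
  windows, and coupled expression — the basis of all recovery tests.

## Worked example

```r
library(cpgdrift)

cfg <- sim_config(n_cpg = 5000, n_genes = 200, seed = 7)  # plants +0.15 beta
sim <- simulate_manifest(cfg)                             # in 10% of TSS1500/Shore CpGs
sb  <- simulate_beta(cfg, sim)

design <- paired_design(sb$beta, "CD34pos_d0", "CD34pos_woMSC")
dm <- differential_methylation(sb$beta, design, keep_fraction = 0.5, alpha = 0.05)
attr(dm, "summary")
#> n_hyper  n_hypo    n_ns
#>     111       4    2385

prof <- category_enrichment_profile(dm, sim$manifest)
hyper <- prof[prof$direction == "hyper", ]
head(hyper[order(hyper$p), c("category","k","n","K","N","fold","p")], 3)
#>    category   k   n    K    N      fold            p
#>       Shore 111 111 1110 5000 4.5045045 3.216063e-75
#>     TSS1500  63 111  591 5000 4.8017561 6.067913e-31
#>  Intergenic  20 111 1257 5000 0.7167072 9.720690e-01
```

All 111 hypermethylated calls sit in shores (fold 4.5) and 63 of them in
TSS1500 (fold 4.8) — the planted categories — while intergenic sites are
depleted (fold 0.72, p ≈ 1). Motif and peak recovery on the same run:

```r
sp <- simulate_sequences_and_peaks(cfg, sim, sb$truth)
hyper_ids <- dm$cpg_id[dm$direction == "hyper"]
motif_enrichment(sp$windows[intersect(hyper_ids, names(sp$windows))],
                 sp$windows, pwm_from_consensus(cfg$motif_consensus))
#>     category  k   n  K    N     fold            p           test
#>  AAGAGGAAGTG 34 111 85 5000 18.01802 6.598722e-36 hypergeometric

peak_colocation(hyper_ids, sim$manifest, sp$peaks)[, c(1, 4:6)]
#>  width prop_hyper prop_background            p
#>    124  0.2252252          0.0206 3.920908e-20
#>    200  0.2252252          0.0218 1.764008e-19
#>    500  0.2252252          0.0272 5.305096e-17
#>   1000  0.2432432          0.0376 1.710875e-15
```

The planted consensus is 18-fold enriched in hypermethylated windows, and
peak-positive proportions rise with window width (nested windows) while
staying far above background at every width. The whole analysis — from
generator to report — also runs as one YAML-configured pipeline:

```r
run_pipeline(list(seed = 11, simulate = list(n_cpg = 3000, n_genes = 120)),
             "run1")   # writes inputs/, per-stage TSVs, run_manifest.json,
                       # report.txt; byte-identical on re-run
```

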