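---
title: "Detecting culture-associated CpG hypermethylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting culture-associated CpG hypermethylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Hematopoietic stem and progenitor cells (the CD34+ fraction of cord blood)
lose stemness within days of in vitro culture, and this loss is accompanied
by reproducible DNA hypermethylation at specific CpG sites — concentrated
in upstream promoter regions (TSS1500) and in the 2 kb shores flanking CpG
islands, co-located with binding sites of hematopoietic transcription
factors, and mirrored by down-regulation of the affected genes. `cpgdrift`
implements the complete desk analysis behind such a study: donor-paired
differential methylation on array beta values, genomic-context and gene-set
enrichment against the array background, motif and ChIP-seq-peak
co-location around hypermethylated CpGs, and methylation–expression
integration — together with a fully seeded synthetic-data generator that
plants known effects so every stage can be validated by recovery tests.

# Differential methylation model

Methylation at site $i$ in sample $j$ is a beta value
$\beta_{ij} \in [0,1]$. For a contrast between conditions $a$ and $b$
measured in the same donors, the per-site statistic is built from the
donor-paired differences $d_{ik} = \beta_{i,b(k)} - \beta_{i,a(k)}$ over
pairs $k = 1..n$:

$$\hat\delta_i = \bar d_i, \qquad s_i^2 = \mathrm{var}(d_{ik}), \qquad
\tilde s_i^2 = \frac{d_0 s_0^2 + (n-1)\, s_i^2}{d_0 + (n-1)}, \qquad
\tilde t_i = \frac{\hat\delta_i}{\sqrt{\tilde s_i^2 / n}}$$

with $\tilde t_i$ referred to a t distribution on $d_0 + n - 1$ degrees of
freedom. This is the standard empirical-Bayes moderated paired t: the
per-site variance is shrunk toward a prior $s_0^2$ worth $d_0$
pseudo-observations, which stabilizes inference when only three donor
pairs are available. The hyperparameters are fitted by moment matching on
$\log s_i^2$ across sites (the scaled-F model): with
$e_i = \log s_i^2 - \psi(df/2) + \log(df/2)$, the excess of
$\mathrm{var}(e)$ over $\psi'(df/2)$ identifies $d_0$ through the inverse
trigamma function, and $\mathrm{mean}(e)$ identifies $s_0^2$. Setting
$d_0 = 0$ recovers the ordinary paired t-test exactly (verified to
relative error $10^{-10}$ against `t.test` in the test suite), and the
moment fit is cross-checked against limma's `squeezeVar` in a dedicated
test; the implementation itself is self-contained.

Before testing, sites are confined to the `keep_fraction = 0.5` most
variable half by unbiased sample variance of beta across **all** samples
of all conditions (the analysis' variance filter); ties at the cutoff are
broken by site order. P-values are adjusted by Benjamini–Hochberg, and a
site is called *hyper* (*hypo*) iff its adjusted p is below
`alpha = 0.05` and its mean paired difference is positive (negative).

Numerical edge cases: donor pairs missing either beta are dropped
pairwise; sites with fewer than two complete pairs are excluded with a
message. A site whose pair differences are all equal has zero sample
variance; with a prior ($d_0 > 0$) the posterior variance is positive and
nothing special happens, while without a prior the package applies an
explicit zero-variance policy — $t = 0, p = 1$ for an all-zero difference,
$p = 0$ for a nonzero one. Because of this policy (and because extreme
moderated t statistics underflow double precision), the BH adjuster
accepts $p = 0$ and keeps it at 0.

# Genomic context

Region labels follow the Illumina vocabulary: TSS200 (0–200 bp upstream of
the transcription start, strand-aware), TSS1500 (200–1500 bp upstream),
5'UTR, first exon, gene body, 3'UTR, and Intergenic for probes touching no
gene; a probe affiliated with several genes accumulates all labels. The
CpG-island relation is a distance rule on merged islands: *Island* inside;
*Shore* within 2000 bp outside an island edge (the first base outside has
distance 1); *Shelf* within the next 2000 bp; *OpenSea* beyond. North and
south flanks are collapsed into symmetric shore/shelf classes since the
analysis reports them symmetrically.

Enrichment of the hyper (or hypo) set in each category is the exact
upper-tail hypergeometric probability $P(X \ge k)$ with the whole manifest
as background — no normal approximation; the test suite checks every
instance with background size $N \le 12$ against exhaustive subset
enumeration to $10^{-12}$. Gene-set enrichment (GMT input) uses the
one-sided Fisher exact test at gene level: a gene is selected if at least
one of its CpGs is called, and each gene counts once regardless of probe
multiplicity. The gene universe is the genes on the array; testing against
CpG-level background would double-weight probe-dense genes.

# Motifs and peak co-location

Windows are total-width intervals centered on the CpG: a 124 bp window
spans ±62 bp and keeps the C at offset `width/2`. (The 124 bp default is
the field's standard scan radius around differential CpGs; treated as an
opaque constant.) PWM occurrences are scored by log2 odds
$\sum_j \log_2(p_{j,b_j} / q_{b_j})$ against the background base
composition, and an offset is a hit iff its score reaches
`threshold_fraction = 0.8` of the maximum attainable score, on either
strand; an uninformative PWM (maximum score 0) never produces hits, and
offsets covering non-ACGT bases are skipped. This fractional-score
threshold replaces a p-value machinery deliberately: it is transparent,
fast, and exposed as a parameter. Motif enrichment counts windows with at
least one hit and applies the same exact hypergeometric test against all
array windows.

Peak co-location asks, for each width in 124/200/500/1000 bp, whether a
merged peak interval intersects the window around each CpG, and tests the
2×2 table (hyper vs non-hyper sites × peak-positive vs not) with the
one-sided Fisher exact test. Because the windows are nested, positivity is
monotone in width — the reported proportions can only grow — and the test
suite asserts this invariant.

# Expression integration

Paired differential expression reuses the same moderated machinery on
log2 intensities. Gene deciles are ranked by mean signal intensity across
all samples (ties broken by gene id), and `mean_dnam_by_context()`
averages beta over all (site, sample) observations of a gene set per
(region × CGI class) cell — cell means recombine exactly to the overall
mean, which is tested.

The methylation–expression claim is reduced to a quadrant association:
over the genes present in both data sets, a one-sided Fisher test of
(has a hyper CpG in the chosen region, default TSS200) × (down-regulated).
The down-regulation side uses the raw p-value (`p < 0.05` with negative
fold change) rather than the BH-called direction, matching the
figure-style `p < 0.05` threshold such scatter analyses use; under a BH
rule a null expression data set produces zero down calls and the quadrant
test degenerates to a constant $p = 1$, which would make its own null
calibration untestable. The BH rule remains available via
`down_rule = "adjusted"`.

## Calibration checks for exact tests

Both the quadrant Fisher test and motif enrichment are *exact* tests on
sparse discrete tables: under the null their p-values are super-uniform by
construction (a zero-count table yields exactly $p = 1$), so their
empirical distribution lies on or above the uniform CDF. A two-sided
Kolmogorov–Smirnov comparison against the continuous uniform therefore
rejects a perfectly valid exact test once enough replicates accumulate,
purely because of discreteness. The package's calibration tests check the
direction that would actually falsify validity — an excess of *small*
p-values — with the one-sided KS statistic, plus a cap on the fraction of
nominal-level calls.

# The synthetic-data generator

The generator is the package's test bed and defines its study conditions;
it is deterministic given `seed` (each operation draws from its own
derived stream, so skipping one stage never shifts another).

**Layout.** Each of `n_genes` genes occupies an isolated 30 kb tile on one
of two chromosomes, alternating strands. The promoter carries a CpG island
spanning TSS200/5'UTR/first exon, so TSS1500 probes fall on island shores
*by construction* — the geometry that makes "hypermethylation planted in
TSS1500 and shores" coherent. The 11.6 kb gene body crosses shore, shelf
and open sea; an intergenic band hosts open-sea probes, with an intergenic
island (own shore/shelf neighborhood) in every third tile. Probe labels
are drawn from a configurable mixture (defaults approximate a 450K-style
design: 41% body, 25% intergenic, 12% TSS1500, 7% TSS200, 5% each for
5'UTR/first exon/3'UTR) and placed uniformly at even offsets within a
matching zone, so no two probes overlap and every position carries a CG
dinucleotide in the emitted genome.

**Beta values.** $\beta = \mathrm{logit}^{-1}(\mu_i + u_{ij} +
\varepsilon_{ijc})$ with island-class-dependent baselines (islands
hypomethylated, open sea methylated: $\mu$ centered at −2.2 / −1.0 / 0 /
0.8 logits for Island/Shore/Shelf/OpenSea), a donor random effect
$u_{ij} \sim N(0, 0.10^2)$ shared across conditions (this is what makes
donor pairing informative) and measurement noise
$\varepsilon \sim N(0, 0.15^2)$, both on the logit scale. The logit-normal
construction keeps additive donor/condition effects well defined where a
Beta-distribution model would not. The planted effect is then added on the
**beta scale**: a fraction `effect_fraction = 0.10` of the probes in
`effect_categories = {TSS1500, Shore}` is shifted by
`effect_delta = +0.15` in every cultured condition (clamped to $[0,1]$),
so the expected paired difference equals the configured delta exactly and
recovery tests can use data-derived standard errors. Four conditions
(fresh CD34+ baseline and three cultured fractions) × three donors mirror
the study design; expression is profiled for the first three conditions
(nine arrays).

**Sequences, peaks, expression.** The planted consensus (a PU.1-like
`AAGAGGAAGTG` by default) is written into 30% of planted-probe windows vs
1% of background windows, at offsets avoiding the central CG; peaks of
width 150 bp are centered within ±62 bp of 30% of planted probes (vs 1%
background), so a planted peak intersects the window at every tested
width. Genes with a planted TSS200/first-exon probe get
`expression_coupling × effect_delta` (default $-4 × 0.15 = -0.6$ log2
units) added in cultured conditions, on top of gene baselines
$N(7, 1.5^2)$, donor effects $N(0, 0.10^2)$ and noise $N(0, 0.15^2)$.

**What the generator does not emulate.** Probe cross-reactivity and
SNP-affected probes, batch and chip effects, spatially correlated
methylation along the genome, realistic donor-variance heterogeneity (the
real data's variance decomposition is unpublished; defaults were chosen
once for testability), genome-scale gene counts, and raw-intensity
preprocessing (the pipeline consumes normalized matrices by design).
Passing recovery tests therefore demonstrate correctness of the
statistical machinery under a clean generative model, not robustness to
array artifacts.

# Problem sizes and runtime choices

The packaged tests exercise the generator at 800–6000 probes for unit
properties and at the study-scale configuration — 10,000 probes, 300
genes, 3 donors, 20 replicate seeds — for the error-control and recovery
checks (null false-call fraction, empirical FDR of planted calls,
context-category recovery, motif/peak recovery, integration coupling).
These sizes give Monte-Carlo standard errors well inside the asserted
margins while keeping a full run in tens of seconds. `scripts/acceptance.R`
re-runs all of them from scratch at the same sizes.

# Known limitations

* Gene-region assignment relies on the simplified single-transcript gene
  models the generator emits; real annotations with overlapping
  transcripts are reduced to multi-label sets, without priority ordering.
* Depletion is reported as fold < 1 without a second tail test, matching
  the one-sided usage throughout.
* FIMO-style p-value scoring for motif hits is out of scope; the
  fractional-score threshold behaves differently near low-information
  PWMs.
* The variance filter is computed once on the full matrix, not per
  contrast; with very unbalanced designs a per-contrast filter could rank
  sites differently.
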