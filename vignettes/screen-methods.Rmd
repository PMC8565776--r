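---
title: "Models and methods behind lncscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscreen)
library(dplyr)
```

# What the package models

`lncscreen` analyses pooled CRISPRi screens in which a guide library targeting
lncRNA transcription start sites (TSSs) is transduced into dCas9-KRAB hESCs,
the cells are differentiated, and FACS separates differentiated
(marker double-positive) from undifferentiated (double-negative) cells. A
guide whose target locus is required for differentiation enriches in the
undifferentiated pool. The package covers the four computational stages
around that experiment: annotation-driven library design, expression
profiling, screen enrichment statistics with hierarchical-mixture hit
calling, and genomic-feature clustering for mechanism inference — plus a
synthetic generator that produces every input with known ground truth.

# Annotation and library design

## Genomic-context classification

`categorize_lncrna()` assigns each lncRNA gene one of four categories using
1000-bp distance rules: promoter-overlapping (gene start within 1000 bp of a
protein-coding gene start), transcript-overlapping (any transcript overlap
with a protein-coding transcript), gene-nearby (no overlap, but a
protein-coding gene start or end within 1000 bp of the lncRNA gene start or
end), and intergenic otherwise. Two aspects of the rules are genuinely open
and we fixed them explicitly:

* **Precedence.** A gene can satisfy several rules; we impose the strict
  order promoter > transcript-overlap > nearby > intergenic, so
  classification is a total function and category counts always sum to the
  number of lncRNAs.
* **"Gene start".** For the promoter rule a start is a transcription start
  and is compared strand-aware by default (`promoter_rule = "tss"`); the
  strand-agnostic genomic minimum is available as
  `promoter_rule = "gene_start"` because the two readings differ for
  minus-strand genes. For the nearby/intergenic rules, gene start and end
  are the strand-agnostic genomic min/max of the gene span.

All interval arithmetic is done directly on the 1-based inclusive
coordinates that GTF uses — the native convention of R's genomics stack —
so no coordinate shifting happens anywhere between input and output.
Distances are counted between closest interval edges
(`nearest_feature_distance()`), with 0 for any overlap; a TSS at 10,000 and
an enhancer at 7,000 are 3,000 bp apart. This edge convention is checked
against a brute-force all-pairs scan in the tests.

## TSS assignment

CRISPRi only works when the guide sits at the true TSS, and annotated 5'
ends of lowly expressed transcripts are unreliable. `assign_tss()` uses a
three-rule fallback: a curated (CAGE-transcriptome) TSS when provided; else
the closest same-strand CAGE cluster within 400 bp of the annotated 5' end;
else the annotated 5' end itself. Equidistant CAGE peaks are broken toward
the 5'-most position on the transcript's strand, which keeps assignment
deterministic. `consolidate_tss()` then merges TSSs by exact (chrom, strand,
position) identity only — positional fuzziness is the CAGE step's job, and
exact merging makes the consolidation idempotent and auditable.

## Guides and scrambled controls

Guide scoring and ranking is consumed from an external designer as a
pre-ranked candidate list; `select_guides()` keeps the 10 best-ranked per
TSS. Negative controls are built by `make_scrambled_controls()`: 500 seeds
sampled without replacement, each scrambled 10 times by uniform letter
permutation, rejecting any scramble that occurs exactly (either strand) in
the supplied genome. Exact substring matching is the deterministic
stand-in for a permissive alignment screen; at toy-genome scale it is the
only well-defined criterion, and rejected scrambles are replaced so the
5,000-control quota is always met. Duplicated sequences across TSSs are
consolidated by `dedup_library()` with target-set union semantics.

# Expression profiling

Tissue specificity uses the tau statistic,
$\tau = \sum_i (1 - x_i/\max_j x_j)/(n-1)$, computed across the three
lineages (hESC, endoderm, mesoderm) on replicate-mean tpm. Replicates are
averaged within lineage before tau and before the 0.1-tpm expression
threshold; the thresholding rule is "replicate-mean tpm at or above 0.1 in
at least one lineage" by default, with an any-sample mode available because
both readings occur in practice. Gene-level tpm is always the exact sum of
the gene's transcript tpms.

Splicing efficiency treats the unspliced pre-RNA as one extra "transcript":
$\mathrm{SE} = \sum \mathrm{spliced} / (\sum \mathrm{spliced} +
\mathrm{unspliced})$, 0 for a gene whose signal is entirely unspliced, 1
for fully spliced, NA when both are zero.

`simple_de_test()` is deliberately labeled plumbing: a Welch t-test on
`log2(tpm + 0.01)` with BH correction, provided only so synthetic pipelines
run end to end. Differential expression of real screens should come from a
bootstrap-aware engine and enter as input q-values.

# Screen statistics

## Filtering

Three consecutive filters remove noisy guides before modelling
(`filter_cascade()`): cpm >= 5 in *every* day-0 replicate, then cpm >= 1 in
*every* undifferentiated replicate (the undifferentiated pool is gated
conservatively and therefore small and noisy), then removal of guides whose
TSS retains fewer than 3 guides. Thresholds are inclusive (`>=`, a guide at
exactly 5.0 cpm survives), cpm is computed on raw library sizes because the
filter precedes normalisation, and scrambled controls — having no TSS — are
exempt from the third stage. The cascade is monotone by construction and the
per-stage report mirrors that order.

## Enrichment estimation

Per-guide enrichment is the log2 ratio of undifferentiated over
differentiated abundance. Counts of the sorted samples are normalised with
median-of-ratios size factors; each replicate contributes
$\log_2((u_r + 0.5)/(d_r + 0.5))$ and replicates are averaged, with the
standard error from the between-replicate spread. The replicate pairing
plays the role of a batch term: each replicate is compared only with
itself, so multiplicative batch offsets on the sorted populations cancel
exactly. We chose this estimator over a negative-binomial GLM with a batch
covariate because it is deterministic, closed-form and transparent at desk
scale while preserving the batch-blocking intent; its agreement with the
generator's true composition log-ratios is measured in the acceptance suite
(mean bias about 0.02–0.03 log2 units at 500 reads/guide) rather than
assumed. The pseudo-count of 0.5 keeps the estimator finite for sampling
zeros at the cost of a small shrinkage toward zero for very low counts.

## Hierarchical mixture hit calling

Only a subset of a functional TSS's guides work, so TSS-level testing must
not average effective guides away. `fit_guide_mixture()` models guide
log2 fold-changes hierarchically:

* empirical null $f_0 = N(\mu_0, \sigma_0)$ fit to scrambled guides only
  (moments by default, median/MAD optionally; a degraded mode fits all
  guides robustly when fewer than 100 controls survive filtering, with a
  warning);
* each TSS functional with prior $p$; conditional on functional, each guide
  independently effective with probability $\pi$, effective guides drawn
  from one shifted normal $f_1 = N(\mu_1, \sigma_1)$ with $\mu_1 \ge \mu_0$
  (the enrichment direction), ineffective guides from $f_0$.

$p$, $\pi$, $\mu_1$, $\sigma_1$ are fit by EM on the per-TSS marginal
likelihood, with relative log-likelihood tolerance 1e-6, at most 500
iterations, $\sigma_1$ floored at $\sigma_0/20$, and 5 restarts from
jittered initialisations under a fixed seed (best likelihood kept;
non-convergence is flagged, never silent). The TSS score is its posterior
null probability; the reported global FDR is the running mean of posterior
null probabilities in score order (the q-value convention), with ties
sharing the most conservative value of their group. Hits are TSSs with
FDR < 0.1; "stringent non-hits" — the well-powered negatives used in
feature comparisons — require FDR > 0.9 *and* at least 9 filtered guides.

Because the published hit landscape of a real screen embeds fits that
cannot be re-derived from printed numbers, the model's correctness is
established by properties: on pure-null simulations the empirical false
discovery proportion stays below nominal + 0.05, and on planted simulations
(50 functional of 1,000 TSSs, $\pi = 0.5$, +2 SD shift) it recovers at
least 70% of functional TSSs at FDR < 0.1 with FDP <= 0.15. Effect sizes
are reported separately as the mean of each TSS's top-3 guide
log2 fold-changes, defined only for TSSs with at least 3 filtered guides
and invariant to ties at the cut rank.

The validation enrichment score for individually tested guides,
$\log_2[(u/d) / (u_s/d_s)]$ against a same-batch scrambled control with a
0.1% floor on zero percentages, is isolated in `validation_score()` so the
definition can be swapped by configuration if a different convention is
preferred.

# Feature clustering for mechanism inference

CRISPRi silences DNA regulatory activity along with transcription, so the
screen alone cannot distinguish enhancer-like loci from functional RNAs.
The package aggregates 11 genomic features per gene (transcript length,
exon count, GC, locus length, CAGE TSS density, enhancer counts and
distance, TSS and exon conservation, maximal panel expression, splicing
efficiency), standardizes each to mean 1 and unit *population* standard
deviation (the choice of population vs sample sd is arbitrary and fixed
here once; k-means is invariant to the shared translation), mean-imputes
missing values after standardization (imputed value 1, flagged per gene),
drops constant features with a warning, and clusters with k-means, k = 2,
10 restarts under a fixed seed. Labels are canonicalized so cluster 2 is
the mRNA-majority cluster; lncRNA screen hits landing there are the
candidate RNA-mechanism hits, and known RNA-acting lncRNAs can be passed as
gold standards for a placement diagnostic. On tiny instances (n <= 12) the
k-means objective is verified against exhaustive 2-partition enumeration.

The t-SNE embedding (`embed_tsne()`, an exact O(n^2) implementation) is
quarantined as visualization: nothing numerical depends on it and its tests
assert only finiteness and seed-determinism.

# The synthetic generator

`sim_annotation()`, `sim_expression()`, `sim_screen_truth()` and
`sim_screen_counts()` produce every input the pipeline consumes, with the
ground truth serialized next to the data. They emulate:

* a toy chromosome whose lncRNA placement realizes any requested category
  mix exactly (verified by a construction-vs-classification round trip);
* 3 lineages x 2 replicates of tpm with lineage-specific structure
  (specific genes reach expected tau about 0.95; lncRNAs are specific with
  probability 0.8 versus 0.2 for mRNAs), mean-preserving log-normal
  replicate noise at CV 0.2, and a per-gene splicing-efficiency truth
  realized through spliced/unspliced abundance pairs;
* a guide library of 10 guides per TSS plus scrambled controls;
* sorted screen counts with log-normal library representation
  (sd(log) = 0.3; 3% of guides crippled to ~1% representation to exercise
  the filter), two-point guide efficiency (a guide of a functional TSS
  works with probability 0.5, a Beta option exists), a baseline 10%
  differentiation-failure rate multiplied by $2^{\mathrm{effect}}$ (capped
  at 0.95) for working guides, a half-depth undifferentiated sample
  (conservative gating), multiplicative log-normal batch offsets (sd 0.15)
  per replicate on sorted sample sizes, and multinomial sampling.

The generator records each guide's implied true composition log-ratio,
$\log_2\frac{\phi(1-s_0)}{(1-\phi)s_0}$, so estimator bias is measured
against the generator exactly rather than against the nominal effect (the
two differ by a depletion term of order $s_0$ in the differentiated pool).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: guide-specific off-target effects, chromatin-dependent
efficacy correlated within a locus, overdispersion beyond multinomial
sampling, growth/fitness effects that deplete guides from all populations,
PCR jackpotting, and any correlation structure between neighbouring loci.
Calibration results on this generator bound the statistics' behaviour under
their own assumptions, not under every failure mode of a real screen.

# Problem sizes and runtime choices

The test and acceptance suites run at the following scales, chosen as the
smallest sizes at which the distributional claims are meaningful: FDR
calibration and planted-recovery suites use 1,000 TSSs x 10 guides with
1,000 scrambled controls over 50 seeds; estimator-bias suites use 200
replicate count simulations of a 120-guide library at 500 reads/guide; the
end-to-end count-level recovery uses 10 full screens of 11,000 guides. The
demonstration pipeline (`run_screen_pipeline()`) uses a 12-mRNA / 20-lncRNA
toy genome with 4 planted functional TSSs.

# Known limitations

* The alternative component is a single shifted normal; strongly bimodal
  effect-size distributions would be summarised by one mode.
* The FDR is a q-value-style running mean of posterior null probabilities;
  it inherits the empirical null's accuracy, so a contaminated scrambled
  set (controls with real effects) would inflate $\sigma_0$ and cost power.
* Exact-match genome screening of scrambled controls is weaker than a
  permissive aligner on a real genome; with real data, supply the
  pre-screened control list instead.
* The conservation and expression features are consumed as summary tracks
  and panels; the package never computes alignments or pseudo-alignments.
* Mean imputation of missing features shrinks incomplete genes toward the
  feature centre, which biases them toward the larger cluster.
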