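---
title: "Methods: deciding whether paired sputum samples agree"
author: "mbpairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deciding whether paired sputum samples agree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Airway-microbiome studies of COPD use sputum obtained either by induction
with hypertonic saline or by spontaneous expectoration. If the two
collection methods recover the same community, they can be used
interchangeably; if not, mixing them inside one study confounds the
biology with the sampling method. `mbpairs` implements the statistical
machinery for answering that question from paired 16S rRNA amplicon data:
for each subject a pair of samples, one per method, taken at the same
consultation, with each pair labelled by disease state (stable or
exacerbation).

The design hinges on a contrast: *group-level* summaries (mean profiles,
mean beta diversity) can look nearly identical while *pair-level*
comparisons reveal strong disagreement in a third of subjects. Every
analysis therefore runs both ways.

## Data model

All stages operate on four objects:

* a **count table** — integer matrix of sequence counts, OTUs × samples;
* a **taxonomy map** — OTU id → GreenGenes-style lineage string
  (`k_…;p_…;c_…;o_…;f_…;g_…`), used to collapse OTUs to genus level
  (level 6). Unnamed genera (`f_Gemellaceae;g_`) are legitimate labels and
  are kept distinct by their family prefix;
* a **rooted phylogenetic tree** with branch lengths, whose leaves index
  the OTUs;
* a **pairing table** — `(pair_id, induced_id, spontaneous_id, state)`.

Input formats are tab-separated matrices (a `#OTU ID` header is
tolerated) or BIOM 1.0 JSON, sparse or dense, via `biomformat`; trees are
newick via `ape`. BIOM 2.x HDF5 is deliberately unsupported — it would
pull in a binary dependency for a format the genus-level workflow never
needs. Missing branch lengths read as zero with a warning rather than an
error: the diversity arithmetic stays defined, and silently invented
lengths would be worse.

## Pre-processing

* `filter_rare()` removes OTUs holding less than 0.005 % of all sequences
  (`min_fraction = 5e-5`), the conventional floor for amplicon OTU tables.
* `filter_dominant()` keeps OTUs holding ≥ 1 % of all sequences — the
  "dominating" community view.
* Both filters retain an OTU **exactly at** the threshold (the `≥`
  convention), and both are computed on the grand total of the table as
  given. Filtering precedes every pairing-specific analysis; the rare
  filter precedes rarefaction.
* `rarefy()` subsamples each sample without replacement (multivariate
  hypergeometric, backed by `vegan::rrarefy`) to a common depth, dropping
  and listing samples that are too shallow. The depths used throughout are
  the study's: 18 250 sequences/sample for all-samples and exacerbation
  analyses, 19 743 for stable-state. A single seeded draw is used, not
  repeated-rarefaction averaging.

## Pair-level concordance statistics

**Yue–Clayton dissimilarity.** For two composition vectors $a, b$,

$$\theta_{YC} = \frac{\sum_i a_i b_i}{\sum_i a_i^2 + \sum_i b_i^2 - \sum_i a_i b_i},$$

and $1-\theta_{YC} \in [0,1]$ is 0 for identical and 1 for disjoint
compositions. It weighs both shared and unshared components, which is why
it is preferred here over purely overlap-based indices. Per pair it is
computed twice: on the genus-collapsed profile of all OTUs and on the
profile of dominant OTUs only (a flag switches the "all" computation to
OTU-level granularity; the genus level is the default because that is the
granularity at which the communities are reported). A pair whose
dominant-set profile is empty on one side is maximally dissimilar (1) by
definition; empty on both sides yields `NA`.

**Bland–Altman limits of agreement.** Per pair, the per-taxon differences
$d_i = a_i - b_i$ of the percent abundances give
$\mathrm{LOA} = \bar d \pm 1.96\, s_d$ (sample SD, $n-1$; the classical
1.96 multiplier, not a t-quantile), and the range statistic
$(\mathrm{LOA}_{upper} - \mathrm{LOA}_{lower})/100 \in [0,1]$, 0 meaning
perfect agreement.

**Classification.** A pair is discordant when $1-\theta_{YC} > 0.2$ or
LOA range $> 0.1$ — strict inequalities, so a pair exactly at a cut-off
counts as concordant. Both cut-offs are the study's (and are admittedly
arbitrary; they are parameters, not constants).

**Group comparison.** `group_mean_dissimilarity()` averages the relative
abundance profiles of all induced and all spontaneous samples in a
disease-state subset, renormalises, and applies $1-\theta_{YC}$ to the two
mean profiles. Crossed perturbations cancel in the means, which is
exactly how pooling hides pair-level discordance.

## Per-taxon tests

`taxon_g_test()` compares, per genus-level taxon, the total rarefied
sequence count in induced vs spontaneous samples with a log-likelihood
ratio statistic

$$G = 2 \sum_g O_g \ln(O_g/E_g),$$

where $E_g$ is proportional to the number of samples per group
(zero-count groups contribute 0), referred to $\chi^2_{k-1}$, Bonferroni-
corrected by the number of taxa tested. No Williams or continuity
correction is applied by default — the correction is exposed as a flag —
because the homogeneity layout with totals in the thousands leaves the
uncorrected statistic essentially unbiased.

## Diversity

Alpha diversity per rarefied sample: observed OTUs; Chao1 in the classic
form $S_{obs} + F_1^2/(2F_2)$ with the bias-corrected fallback
$S_{obs} + F_1(F_1-1)/2$ when no doubletons exist; Faith's phylogenetic
diversity as the branch length of the union of root-to-leaf paths of
observed OTUs, including a root edge when the tree carries one (a
deterministic convention; trees without a root edge are unaffected).
Groups are compared with a non-parametric two-sample t-test: the t
statistic on the observed labels against random relabelings,
$p = (1 + \#\{|t_\pi| \ge |t_{obs}|\})/(1 + n_\pi)$.

Beta diversity uses UniFrac in both forms. With $p_{X,i}$ the fraction of
sample $X$'s sequences descending through branch $i$ of length $b_i$:

* unweighted: branch length found under exactly one sample's observed
  leaves divided by branch length under either;
* weighted (raw, the default): $\sum_i b_i\,|p_{A,i} - p_{B,i}|$;
  the normalised form divides by $\sum_i b_i (p_{A,i} + p_{B,i})$, the
  abundance-weighted average root-to-leaf depth, and is available by flag.
  Raw is the default because it is what the era's QIIME pipeline reported.

Pair significance is the Monte-Carlo UniFrac test: each sequence is
randomly reassigned to one of the two samples with both depths fixed (a
multivariate hypergeometric split of the pooled counts — the exact
conditional null when both samples come from one multinomial), and
$p = (1 + \#\{d_\pi \ge d_{obs}\})/(1 + n_\pi)$. The add-one estimator
never returns 0, and drawing the smaller depth (the complement carries
the larger) makes the p-value exactly invariant to the order of the two
samples. The matrix driver runs either all unordered pairs (2 556 for 72
samples) or only the matched within-pair comparisons, and Bonferroni-
corrects by the number of comparisons actually run.

**A validity constraint on permutation counts.** With $m$ comparisons and
$n_\pi$ permutations the smallest attainable corrected p-value is
$m/(n_\pi+1)$. At the study's pairwise threshold of 0.01 and 36 matched
comparisons, $n_\pi$ must exceed 3 599; the analysis scripts use 3 999.
A run with fewer permutations cannot reject anything and is silently
meaningless — the scripts choose the count from this inequality, not from
runtime convenience.

## Ordination

`pcoa()` is classical metric scaling: double-centre $-\tfrac12 D^2$,
eigendecompose, scale eigenvectors by $\sqrt{\lambda}$. Negative
eigenvalues are reported but excluded from coordinates, and no
Lingoes/Cailliez correction is applied — corrections would change the
Procrustes $M^2$ downstream while the method chain specifies none.

`procrustes_m2()` centres both configurations, scales each to unit sum of
squares, and minimises the residual over rotation, reflection and
dilation; with unit-norm inputs $M^2 = 1 - (\sum_k \sigma_k)^2$ from the
SVD of the cross-covariance, 0 for identical shapes, 1 for completely
dissimilar ones (0.3 is used as an indicative level for influential
differences). `procrustes_monte_carlo()` ordinates the induced-sample and
spontaneous-sample distance matrices (rows matched by pair), takes $M^2$
on axes 1–3, and permutes the pair correspondence of one configuration
for the null; $p = (1 + \#\{M^2_\pi \le M^2_{obs}\})/(1+n_\pi)$. The
correspondence-shuffling null is a documented choice — the alternative of
permuting raw distances destroys the metric structure.

`anosim()` ranks all $n(n-1)/2$ distances (average ranks on ties) and
computes $R = (\bar r_{between} - \bar r_{within})/(M/2)$ with
$M = n(n-1)/2$, group-label permutation for $p$.

## The synthetic generator

`simulate_paired_tables()` exists so every stage, and the pipeline end to
end, can be exercised and validated without external data. It emulates
the study design: 36 pairs (11 stable listed first, then 25
exacerbation), 1000 OTUs mapped onto 106 genus-level lineages (a few with
unnamed genus labels), and sequencing depths drawn uniformly from
$[0.8, 1.2] \times 25\,000$ so that every sample clears both rarefaction
depths by construction.

The community model: a global mean profile $m \sim$ Dirichlet$(100\,w)$
with rank-skewed weights $w_i \propto 1/i$ — the skew matters, because a
flat Dirichlet over 1000 OTUs produces *no* OTU above 1 % of all
sequences and hence an empty "dominant" set, whereas the $1/i$ profile
yields the realistic handful (~10–12) of dominant OTUs over a long rare
tail. Per pair, a base composition $\pi_j \sim$
Dirichlet$(50\,m)$; the induced member draws
Multinomial$(N_j, \pi_j)$. The spontaneous member's composition is the
base perturbed on the log scale,
$\pi'_j = \mathrm{softmax}(\log \pi_j + \varepsilon_j)$,
$\varepsilon_j \sim N(0, \sigma_j^2)$ per OTU — multiplicative
log-abundance noise lets low-abundance taxa diverge realistically; a
Dirichlet-resampling alternative sits behind a flag. Optional genus-level
fold-change effects apply to the spontaneous side before renormalisation.
The default per-pair divergence sweeps $\sigma_j$ from 0 to 2 across
pairs, spanning near-identical to strongly discordant compositions. The
truth record keeps $\pi_j$, $\pi'_j$, their $L_1$ distance, states and
effects for parameter-recovery checks.

What the generator does **not** emulate: contamination (including the
saline-control question), copy-number variation, overdispersion beyond
the Dirichlet layer, phylogenetic signal in abundances (the random tree
is independent of the compositions), or any association between
divergence and disease state beyond the ordering of the default sweep —
in the defaults the stable pairs occupy the low-divergence end, so
state-by-state discordance contrasts in simulated output reflect that
ordering, not biology. Passing tests therefore demonstrate correctness of
the statistical machinery under a known model, not robustness to every
failure mode of real sputum data.

## Seeds and determinism

Every stochastic stage takes a seed; `run_pipeline()` derives named child
seeds from one master seed (`child_seed(master, stage)`), so adding or
reordering stages never silently changes another stage's draws, and the
same configuration and seed reproduce every output byte for byte. RNG
state is restored after each seeded call (`withr::with_seed`).

## Problem sizes used in validation

The test suite and the acceptance script run entirely on simulated data,
at sizes chosen to keep the full validation comfortably re-runnable on a
laptop: oracle comparisons on 100 random 8-leaf trees; null calibration
with 200 replicate datasets (G tests: 30 taxa, 10 + 10 samples at depth
2000; UniFrac: 16-leaf tree, two samples of 500 sequences, 100
permutations) and 1000 rarefaction replicates; parameter recovery at 50
pairs and depth 20 000 across the divergence grid (0, 0.5, 1, 2); and
effect-detection power over 100 replicates of the full 36-pair design.
The acceptance run reproduces the whole pipeline at study scale (36
pairs, 1000 OTUs, depths ≥ 20 000) with 3 999 permutations for the 36
pairwise UniFrac tests and 1000 for Procrustes.

## Known limitations

* The Yue–Clayton and LOA cut-offs (0.2, 0.1) and the Procrustes 0.3
  level are field conventions without distributional justification; treat
  the classifications as descriptive.
* The G test compares pooled group totals, not per-sample variability; a
  taxon driven by one extreme sample can reach significance. The paired
  structure is used by the pair-level statistics, not by the G test.
* Unnormalised weighted UniFrac depends on tree depth; compare values
  only within one tree.
* `NA` dissimilarities (both dominant profiles empty) are counted as
  not-discordant in summaries; they are visible in the per-pair table.
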