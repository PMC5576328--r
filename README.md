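# mbpairs — concordance analysis of paired microbiota samples

`mbpairs` answers a practical question in airway-microbiome research: if
the same patient gives two sputum samples by different methods (induced
with hypertonic saline vs spontaneously expectorated), does 16S rRNA
profiling recover the same community from both? The package implements
the full paired-concordance workflow for OTU count data — per-pair
composition comparison, per-taxon tests, alpha/beta diversity with
permutation significance, and ordination — together with a seeded
generator of synthetic paired datasets used to validate every stage.

It is aimed at microbiome researchers comparing sampling (or extraction,
or storage) methods on paired designs, where the central trap is that
group-level summaries can agree almost perfectly while a third of the
individual pairs disagree badly.

## Statistics implemented

* **Yue–Clayton dissimilarity** per pair and per group:
  `1 − θ`, with `θ = Σaᵢbᵢ / (Σaᵢ² + Σbᵢ² − Σaᵢbᵢ)`; 0 = identical,
  1 = disjoint compositions. Computed on genus-level profiles for all
  OTUs and for dominant OTUs (≥ 1 % of all sequences).
* **Bland–Altman limits of agreement** on percent abundances per pair:
  `mean(d) ± 1.96·sd(d)` and the range statistic `(upper − lower)/100`.
* **Pair classification**: discordant when `1 − θ > 0.2` or LOA range
  `> 0.1` (strict comparisons; both cut-offs configurable).
* **Per-taxon G tests** (log-likelihood ratio, `G = 2 Σ O·ln(O/E)`),
  Bonferroni-corrected, on rarefied genus tables.
* **Alpha diversity** (observed OTUs, Chao1, Faith's PD) with
  non-parametric permutation t-tests.
* **UniFrac**, unweighted and weighted (raw or normalised), with the
  Monte-Carlo sequence-reassignment significance test and Bonferroni
  correction over the comparisons run.
* **PCoA**, **Procrustes M²** on principal coordinates 1–3 with a
  Monte-Carlo correspondence-shuffling test, and **ANOSIM**.
* **Synthetic paired communities**: Dirichlet-multinomial pairs with a
  logistic-normal per-pair divergence parameter, genus fold-change
  effects, and a truth record for parameter recovery.

I/O covers tab-separated OTU tables (`#OTU ID` headers tolerated), BIOM
1.0 JSON (sparse or dense), newick trees, pairing tables, and tsv
reports that re-read at full precision.

## Worked example

The `analysis/` scripts run the whole study on a simulated 36-pair
dataset and narrate what they find:

```sh
Rscript analysis/01_simulate.R     # writes results/simulated/{otu_table.tsv,biom,taxonomy,tree,pairing}
Rscript analysis/02_concordance.R  # per-pair and group-level composition comparison
Rscript analysis/03_diversity.R    # G tests, alpha diversity, pairwise weighted UniFrac
Rscript analysis/04_ordination.R   # PCoA, Procrustes, ANOSIM
```

Step 2 prints (numbers from the run with the seeds committed in the
scripts):

```
Per-pair concordance (1-theta cut 0.2, LOA range cut 0.1):
        state n_pairs theta_discordant_all theta_discordant_dom loa_discordant
          all      36                   25                   25             13
 exacerbation      25                   24                   24             13
       stable      11                    1                    1              0

1-theta (dominant) range: 0.000 - 0.829
LOA range span: 0.003 - 0.215

Group-level 1-theta (mean induced vs mean spontaneous profiles):
       subset    dominant   all_otus
          all 0.058124768 0.05428503
 exacerbation 0.113186295 0.10610047
       stable 0.005012174 0.00427463
```

Reading this: the simulated pairs sweep a divergence parameter from 0 to
2, so per-pair dissimilarity spans near-zero to 0.83 and most
high-divergence pairs are flagged — yet the *pooled* method-versus-method
dissimilarity stays at 0.004–0.11, the masking effect the paired design
exists to expose. Step 4 then reports:

```
Procrustes M^2 (PC1-3) = 0.794, Monte-Carlo p = 0.0020
ANOSIM by sampling method (induced vs spontaneous):
 metric           R     p
    wuf  0.08088012 0.001
   uwuf -0.01444616 0.783
```

i.e. the paired configurations are far from superimposable (M² well
above the indicative 0.3) even though grouping samples merely by method
barely separates them.

The same machinery is available programmatically:

```r
library(mbpairs)
sim <- simulate_paired_tables(synthetic_config(seed = 1))
res <- run_pipeline(sim$counts, sim$taxonomy, sim$tree, sim$pairing,
                    pipeline_config(unifrac_scope = "paired", seed = 1))
attr(res$pairs, "summary")
write_report(res, "results/run1")
```

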