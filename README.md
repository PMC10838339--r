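# itgact

T cell activation scoring and ITGB7/ITGB1 integrin subset analysis for
RNA-seq in Crohn's disease.

Anti-integrin therapy in inflammatory bowel disease blocks gut homing of
T cells, yet cytotoxic T cell activity can persist in treated patients.
`itgact` provides the computational side of studying that question from
transcriptomes: it stratifies a paired week-0/week-14 bulk RNA-seq cohort by
a composite T cell activation score and asks whether cytotoxic mediator
genes (granulysin, granzymes, perforin, Fas ligand) fall only when
activation is low; and it classifies single memory T cells by their ITGB7
and ITGB1 transcripts, locates the triple-integrin (ITGB1/7
double-positive) subset in cluster space, and extracts its cytotoxic marker
signature.

## The score

For activation genes $g \in$ {CD40LG, TNFRSF4, IL2RA, CD69, TNFRSF9} and
timepoints $t \in \{0, 14\}$ weeks, with $x_{g,i,t}$ the
size-factor-normalized expression of patient $i$ and $\tilde{x}_g$ the
gene's median over all samples of the cohort:

$$ S_i = \sum_{t} \sum_{g} \mathbb{1}\!\left[ x_{g,i,t} > \tilde{x}_g \right] \in \{0, \dots, 10\} $$

Patients are **high** if $S_i \ge 6$ with both per-timepoint subscores
$\ge 2$, **low** if $S_i \le 4$ with both subscores $\le 3$, otherwise
intermediate. Stratified contrasts then use 1% ROUT outlier removal and a
normality-dispatched test (D'Agostino–Pearson for $n \ge 10$, Shapiro–Wilk
below; t test if normal, Mann–Whitney/Wilcoxon otherwise).

The single-cell arm follows the standard path — mitochondrial QC (> 20%
removed), median-of-ratios size factors, log1p, 40 PCs, UMAP, Leiden at
resolution 0.5 — then classifies subsets (`ITGB7neg`, `ITGB7sp`,
`ITGB1/7dp` by transcript positivity, ITGB7 keyed first), tests subset
enrichment per cluster hypergeometrically, and ranks cluster-vs-rest
markers by Wilcoxon rank-sum. Negative-binomial bulk and UMI-level
single-cell simulators with ground truth make the whole pipeline testable
offline; see `vignettes/itgact-methods.Rmd` for the models and every fixed
numerical choice.

## Worked example

The `analysis/` scripts run the two arms end to end on simulated cohorts
(tables land under `results/`):

```sh
Rscript analysis/01_simulate_bulk.R
Rscript analysis/02_bulk_activation.R
Rscript analysis/03_simulate_scrna.R
Rscript analysis/04_scrna_subsets.R
```

`02_bulk_activation.R` prints, for the default 42-patient cohort (34
etrolizumab / 8 placebo, seed 1):

```
Recovery of latent truth: sensitivity 1.000, specificity 1.000

Week-14 high vs low (cytotoxic genes):
  gene         arm         test            p    mean_a    mean_b
  GNLY etrolizumab   unpaired t 1.308194e-13  70.03665 11.840795
  GZMB etrolizumab   unpaired t 1.001343e-11  15.27094  2.466665
  ...
Paired week-0 to week-14 change, etrolizumab/low stratum:
  gene     test            p mean_change
  GNLY paired t 2.438072e-04  -11.890369
```

i.e. the score recovers the planted latent activation perfectly, week-14
cytotoxic expression is far lower in low- than high-activation etrolizumab
patients (`mean_a` = high-group mean, `mean_b` = low-group mean, normalized
counts), and the planted week-14 reduction shows up as a significant
negative paired change. `04_scrna_subsets.R` prints:

```
QC: removed 86 of 3000 cells (planted high-mito: 86 )
Subset classification accuracy vs truth: 0.980
Clusters: 6
Most dp-enriched cluster: 1
Cytotoxic program genes among them: 6 of 7
```

— the QC step removes exactly the planted high-mitochondrial cells, six
Leiden communities emerge, the double-positive subset concentrates in one
cluster (fold-enrichment ≈ 18, hypergeometric p below machine precision),
and six of the seven planted cytotoxic program genes sit in that cluster's
top-15 upregulated markers.

Programmatic use mirrors the scripts:

```r
library(itgact)
sim <- simulate_bulk_cohort(bulk_sim_params(seed = 1))
res <- run_bulk_pipeline(sim$counts, sim$design, "results/bulk/pipeline")
head(res$scores)

sc <- simulate_scrna(sc_sim_params(seed = 1))
out <- run_sc_pipeline(sc$counts, sc$cells$donor, "results/scrna/pipeline")
```

Real data drop in through `read_counts()` (dense TSV or 10x-style MTX
directory), `read_design()` (CSV sample sheet) and `read_panels()`
(YAML/JSON gene sets).

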