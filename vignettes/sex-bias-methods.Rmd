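---
title: "Quantifying sex bias in cell composition, expression and cell size"
author: "scSexBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sex bias in cell composition, expression and cell size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(scSexBias))
```

## The problem

Sexual size dimorphism — females of *Drosophila melanogaster* are markedly
larger than males — must ultimately be carried by cells: the sexes can
differ in how many cells of each type they have, in how large those cells
are, or both. Sexed single-nucleus atlases (such as the Fly Cell Atlas
head and headless-body datasets, sequenced in replicated male and female
samples) let both questions be asked tissue-wide: per-cluster cell
*proportions* address cell numbers, and per-cluster *ribosomal-protein
(RP) expression* serves as a proxy for cell size, because ribosome content
scales with cytoplasmic volume. `scSexBias` implements this analysis as a
reusable, tested pipeline, together with a synthetic atlas generator with
known ground truth and the closed-form morphometry calculators used to
validate atlas-derived predictions experimentally (flight-muscle volumes
and nuclei counts, cardiac fractional shortening and stroke volume,
nucleolar ratios, qPCR fold changes).

## The statistics

### Sex bias in cell numbers

Cells are first filtered: nuclei annotated as a sex-specific cell type,
annotated `"artefact"`, or with sex recorded as `"mix"` are removed
(`filterCells()`). Cells are grouped into clusters (Leiden community
detection on an SNN graph, `clusterCells()`, or any precomputed
assignment), clusters are annotated by their predominant cell label, and
clusters with fewer than 100 male nuclei are dropped
(`filterClusters()`) because their sex contrasts are unreliable.

For cluster $c$, replicate $r$ and sex $s$, the normalized cell count is

$$Z_{c,r,s} = \frac{n_{c,r,s}}{N_{r,s}},$$

where $N_{r,s}$ is the replicate's total cell count for that sex; this
removes differences in sequencing depth of cells between replicates and
sexes. The sex-biased cell count is the pseudocounted log ratio

$$B_c = \log_2\frac{\text{pseudocount} + \bar Z_{c,\cdot,\mathrm{female}}}
                   {\text{pseudocount} + \bar Z_{c,\cdot,\mathrm{male}}},$$

with pseudocount $10^{-256}$, small enough never to disturb any real
proportion (the smallest observable nonzero $Z$ is vastly larger) while
keeping $B$ finite when one sex contributes no cells at all. Such
single-sex values are astronomic (about $10^2$–$10^3$) and are reported
as-is; figures clip them to the plotting frame, tables never do.

Significance comes from a Wilcoxon test comparing the per-replicate
$Z_{c,r,\mathrm{female}}$ and $Z_{c,r,\mathrm{male}}$ across replicates,
followed by Benjamini–Hochberg correction across the clusters of a
sample. Two details were genuinely open and were decided as follows:

* **Paired vs unpaired.** The default is the *unpaired* Mann–Whitney
  rank-sum test (`mode = "paired"` is available). With six replicates per
  sex the paired signed-rank test's smallest attainable two-sided p-value
  is $2/2^6 = 0.03125$; after BH correction across the dozens of clusters
  of a real sample *no* cluster could ever reach $q < 0.05$, so a paired
  default would make the replicate design incapable of producing
  significant calls. The unpaired test's floor, $2/\binom{12}{6} \approx
  0.0022$, keeps detection possible while remaining exact.
* **Exactness.** With up to 12 replicates per group the two-sided p-value
  is computed by exact null enumeration using midranks (a subset-sum
  dynamic programme), so ties — common in small proportions — are handled
  exactly rather than by refusing exactness; beyond that the normal
  approximation with tie and continuity corrections is used. The test
  suite checks both modes against independent brute-force enumeration
  oracles for all group sizes up to 8.

### Sex bias in expression

Counts are normalized per cell to a fixed total (`target_sum` 10,000)
and log-transformed (`log1p`); zeros stay zeros. For each cluster and
gene the bias is

$$B_{\mathrm{expr}} = \log_2\frac{\overline{x}_{\mathrm{male}} + 10^{-9}}
                                 {\overline{x}_{\mathrm{female}} + 10^{-9}},$$

where the means are taken over *de-logged* normalized expression, and a
rank-sum z score measures how consistently the gene ranks higher in one
sex: $z = (R_f - \mu)/\sigma$ with midranks, $\mu = n_f(N+1)/2$ and the
tie-corrected variance $\sigma^2 = \frac{n_f n_m}{12}\bigl((N+1) -
\sum_t (t^3-t)/(N(N-1))\bigr)$. Rank statistics are invariant to the
monotone log, so logged and de-logged values give identical scores (a
property the tests assert). Zero-variance genes score 0 with $p = 1$.
P-values use the normal approximation of the rank statistic; BH runs
within each cluster.

The printed ratio is male-over-female while the rank score is
female-positive; `orientBias()` (default orientation `"female"`) flips
reports to a consistent female-positive display, which is what
`runPipeline()` writes.

### The cell-size proxy and stoichiometry

The per-cluster size proxy is the arithmetic mean of the rank scores of
the 94-gene RP panel (`panelScore()`); genes absent from a dataset are
listed as missing, never imputed. Because ribosomal proteins are needed
in stoichiometric amounts, their bias scores should co-vary across cell
types; `stoichiometryMatrix()` reports the gene-by-gene Pearson
correlation of score vectors across clusters (Spearman by flag — the
coefficient for the cross-cluster check was not prescribed, Pearson on
scores is the default; the growth-regulator-vs-panel check,
`geneVsPanelCorrelation()`, uses Spearman as printed in the reference
figures). Constant score vectors have undefined correlation and are
recorded as missing, not zero.

Three gene panels ship as plain-text fixtures: the RP panel (94 genes:
54 large- plus 40 small-subunit), 61 further translation-associated
genes, and 9 growth regulators (DENR, InR, MCTS1, Myc, Nelf-A, NELF-B,
Nelf-E, pix, tor). The two larger panels are reconstructed from standard
FlyBase nomenclature at the documented sizes (their files are marked
`synthetic`); nothing is fetched at runtime, avoiding version drift.

## The synthetic atlas generator

`generateAtlas()` emulates the structure of a sexed, replicated
single-nucleus atlas so every downstream stage can be tested against
known truth:

* **Counts**: gene-wise negative binomial (Gamma–Poisson), the standard
  overdispersed model for UMI counts; dispersion (NB size) defaults to 2.
* **Baseline means**: log-normal across genes (meanlog $-0.5$, sdlog 1,
  i.e. about one UMI per gene per cell on average, snRNA-seq-like).
  Panel genes get an 8-fold baseline multiplier because RP transcripts
  are among the most abundant in real cells.
* **Cluster identity**: per-cluster log-normal gene multipliers
  (`clusterDeSd`, default 0.5; tests that need clearly separable "blobs"
  raise it).
* **Library size**: per-cell log-normal factor with CV 0.3, exercising
  the target-sum normalization.
* **Composition**: baseline cluster proportions are unequal
  ($\propto 1/\sqrt{\text{cluster index}}$); female proportions are the
  baseline times the configured fold, renormalized. The ground-truth
  `true_B` is the log2 of the configured fold; renormalization makes the
  *realized* ratio slightly smaller (by $\log_2(1 + (f-1)p_c)$ for a
  cluster of share $p_c$), which is why recovered values sit just below
  the nominal truth, within the documented tolerance.
* **Labels**: six replicates per sex by default (the replicated-sample
  design the composition test is built for; configurable), a 2% artefact
  fraction, a 2% `"mix"`-sex fraction, and optionally clusters generated
  with cells of one sex only, to exercise every filter.

What the generator does *not* emulate: doublets, ambient RNA, batch
effects beyond library size, or realistic gene–gene correlation within a
cluster. Passing recovery tests therefore demonstrates that the
statistics recover the biases they define under a clean overdispersed
count model — not that every property of real atlas data is handled.

## Numerical choices and degenerate inputs

* Annotation ties break lexicographically and set an `ambiguous` flag.
* Cluster ids from `clusterCells()` are consecutive integers ordered by
  decreasing size; the kNN graph (k = 15) is built on 50 principal
  components of log-normalized expression and SNN/Jaccard-weighted, with
  Leiden run under the modularity objective so the resolution parameter
  behaves as in the common toolkits; both PCA and refinement are seeded.
* Cells with zero total count cannot be normalized and are excluded with
  a warning; all-zero genes are retained (their biases are defined, 0,
  through the offsets).
* Completely tied composition inputs give $p = 1$; fewer than two
  replicates per sex is an error, never `NaN`.
* The qPCR rule $2^{|\Delta C_q|}$ is reproduced as printed even though
  it folds down-regulation onto up-regulation; a signed variant
  ($2^{-\Delta C_q}$) is available behind `signed = TRUE` and clearly
  marked as not the printed rule.
* Stroke volume uses a cylindrical-annulus model,
  $SV = \frac{\pi}{4}(EDD^2 - ESD^2) \cdot L$; the source analysis'
  geometry is not printed, so the model name is stamped on every result.
  Between-sex SV *ratios* at fixed chamber length are robust to this
  choice.

## Problem sizes used by the tests

The simulation-based checks run at the sizes the statistics were designed
for: composition recovery uses 20 clusters, 6 replicates/sex and 5,000
cells/replicate over 20 seeds (the 1.5-fold cluster is recovered with
mean $B$ within 0.1 of $\log_2 1.5$ and called at $q<0.05$); null
calibration uses 400 cluster-tests at fold 1; panel recovery uses a
20-gene panel shifted 1.3-fold in one of five clusters over 20 seeds.
Note the exact rank-sum test is discrete: at six replicates per sex the
largest attainable rejection region below $\alpha = 0.05$ has
probability $2 \cdot 19/924 \approx 0.041$, and occasional tied
proportions push the realized type-I error slightly lower still — the
test is conservative by construction, never anticonservative.
These sizes give each check high power while keeping the default test
run fast.

## A worked example

```{r example, eval = FALSE}
library(scSexBias)

cfg <- synthConfig(nClusters = 5, nGenes = 80, cellsPerReplicate = 800,
                   replicatesPerSex = 6,
                   compositionBias = c(c3 = 1.5),
                   panelGenes = paste0("rp", 1:10),
                   panelFold = c(c2 = 1.3), seed = 71)
atl <- generateAtlas(cfg)

panelFile <- tempfile(); writeLines(paste0("rp", 1:10), panelFile)
bundle <- runPipeline(atl,
    pipelineConfig(clusterBy = "true_cluster", panels = panelFile),
    outdir = tempfile())

bundle$composition[, c("cluster_id", "B", "p", "q")]
bundle$panel_scores[[1]]
makeFigures(bundle)
```

The composition table shows cluster `c3` with the largest positive $B$
(near $\log_2 1.5 \approx 0.585$, slightly shrunk by renormalization) and
the smallest q-value, and the panel-score table shows `c2` with the
extreme positive mean score — both planted by the generator.

## Limitations

* The expression test compares cells, not replicates, so its p-values
  inherit the usual pseudoreplication caveat of single-cell differential
  expression; the composition test is the replicate-aware statistic.
* The RP panel is a *proxy* for cell size; direct volume measurements are
  outside the package's scope (they are the role of the morphometry
  calculators applied to imaging data).
* The packaged RP and translation panel memberships are nomenclature
  reconstructions at the documented sizes, not a versioned database
  export.
* Leiden clustering at a fixed resolution inherits the usual
  arbitrariness of resolution choice; the reference analysis selected
  resolutions by manual inspection, so resolution remains a configuration
  input here.
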