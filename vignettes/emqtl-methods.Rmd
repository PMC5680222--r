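---
title: "Expression-methylation QTL analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-methylation QTL analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emqtl)
```

## The analysis in one paragraph

An expression-methylation quantitative trait locus (emQTL) is a CpG whose
methylation level correlates with the expression of a gene across tumors, in
cis or in trans. `emqtl` screens every CpG-gene combination with a Pearson
test of zero correlation, controls the family-wise error by Bonferroni
correction over the full test count, re-tests discovered pairs in an
independent cohort, and then looks for structure in the survivors: the
CpG-by-gene matrix of corrected p-values is hierarchically co-clustered, and
dense biclusters ("cliques") of mutually associated CpGs and genes are
extracted and split into directional sub-clusters. CpG sets are then
characterized against chromatin-state segmentations, transcription-factor
ChIP-seq peaks, super-enhancers and chromatin-interaction loops; gene sets
against curated collections and experimentally derived TF-target lists.
Finally, a lymphocyte expression signature scores each tumor for immune
infiltration, and methylation of the immune clique is examined across
infiltration quartiles. Because the cohorts that motivated this design are
controlled-access, the package ships a synthetic cohort generator that
plants exactly this structure with known truth labels; the whole pipeline is
validated against those labels.

## The correlation screen

For CpG $i$ and gene $j$ with $n$ paired observations, the screen computes
the sample Pearson correlation $r_{ij}$ and tests $H_0: \rho = 0$ with

$$ t = r\,\sqrt{\frac{n-2}{1-r^2}} \sim t_{n-2}, $$

two-sided. With $m = n_\text{CpG} \times n_\text{gene}$ tests, a pair is
significant when $p \cdot m < \alpha$ with $\alpha = 0.05$; equivalently the
nominal threshold is $\alpha/m$ (`bonferroni_threshold()`). At the scale of
a 450k methylation array this is billions of tests, so `all_pair_emqtl()`
evaluates correlations in CpG-row chunks from masked cross-products:
missing-value indicator matrices give, for every pair in a chunk, the
pairwise-complete $n$, sums, and cross-moments in a handful of matrix
products. Rows are centred by their own mean first (which leaves every
pairwise-complete correlation unchanged) so the raw-moment formula stays
well-conditioned. The retained pair set, $r$, and $p$ are identical for any
`chunk_size`; the test suite holds the engine to a per-pair
`stats::cor.test` loop at $10^{-10}$.

Numerical conventions worth stating:

* CpGs enter the screen only if their beta-value interquartile range exceeds
  0.1 (strictly). Quartiles use linear interpolation between order
  statistics (`stats::quantile` type 7); the quantile rule is not dictated
  by the method, so it is fixed here and stated.
* $|r| = 1$ underflows the $t$ transform; the p-value is stored as 0, which
  passes every positive threshold. Only threshold crossings matter in the
  screen, not the exact magnitude of astronomically small p-values.
* Zero-variance rows and pairs with fewer than 3 complete observations are
  *untestable*, recorded with a reason, never an exception.
* Samples are aligned by the sorted intersection of column names; the
  result is invariant to joint sample permutation.

Validation (`validate_pairs()`) re-tests each discovered pair in a second
cohort. Pairs whose CpG or gene is absent there, or degenerate, are counted
untestable; the Bonferroni correction then uses the *testable* pair count,
and `validation_rate = n_validated / n_testable`. By default a validated
pair must also keep its discovery correlation sign — re-testing a discovered
association is directional in spirit — but `require_sign = FALSE` gives the
strict any-non-zero-correlation replication, since either reading of
"re-analysis" is defensible. `rediscovery_rate()` compares two result sets
by their (CpG, gene) keys for ab-initio rediscovery experiments.

## Biclustering the significance matrix

`significance_matrix()` arranges $-\log_{10}(p_\text{Bonf})$ for every
significant pair into a CpG-by-gene matrix (zero where not significant),
capping values at 300 because p-values below double underflow would
otherwise be infinite; a signed variant carries
$\mathrm{sign}(r)\cdot(-\log_{10} p)$. Rows and columns are clustered
independently (`cocluster()`) with distance $1 - \text{Pearson}$ over the
full profile, zeros included, and average linkage — the distance/linkage
pair is the specification, the dendrogram drawing is not. A constant profile
has no defined correlation; such rows get distance 1 to everything rather
than being dropped.

`extract_biclusters()` cuts the trees into `k_rows` and `k_cols` groups and
pairs each row group with the column group maximizing its mean significance.
The original analysis identified its two cliques visually; an objective rule
is needed here, so with `k = "auto"` the cut is chosen by scanning
$k \in 2..10$ and maximizing the **cell-weighted** mean inside the candidate
cliques minus the mean outside. The weighting matters: an unweighted mean of
per-clique densities is maximized by shaving the weakest members off a
clique into singleton groups, which inflates the average while destroying
recall. Two further guards reflect the same concern. Candidates whose
density does not exceed the overall matrix mean are discarded, and
candidates smaller than 2 CpGs × 2 genes are discarded by default
(`min_rows`, `min_cols`): over millions of tests the family-wise error
budget still admits an occasional stray background pair, and a single cell
is not a bicluster. Cliques are labelled `Cluster1`, `Cluster2`, ... by
decreasing cell count.

`split_by_direction()` labels a clique CpG `A` when its mean signed value
across the clique's genes is negative — methylation anti-correlated with
clique expression, the enhancer-like direction — and `B` otherwise, with
zero means tied to `A` deterministically. Genes are labelled `A` when their
mean signed value across the `A` CpGs is negative. The labelling is
antisymmetric under a global sign flip, which the tests assert.

## Enrichment analyses

All categorical enrichment is the upper-tail hypergeometric test
(`stats::phyper`) with explicit background universes:

$$ p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n), \qquad
   \text{ratio} = \frac{k/n}{K/N}. $$

Backgrounds are always arguments, never implicit — the array CpG universe
for CpG sets, the analysis gene universe for gene sets, the validated pair
set for loop support — because the choice changes results materially.
Conventions: a CpG belongs to the single chromatin state containing its
base (segmentations tile the genome; a CpG outside all segments falls into
a sentinel `unannotated` state); for TF peaks a CpG is a hit when the
window of `half_width` bp around it overlaps any peak, with
`half_width = 200` for the peak analyses that look at regions around CpGs
and 0 where the CpG base itself is meant; whether chromatin-state overlap
should use the base or a window is genuinely open, and the base is the
choice made here. Enhancer and promoter state families can be collapsed
(`Enhancer`+`Enhancer+CTCF`; `Promoter`+`Promoter+CTCF`+`Poised Promoter`).
No correction across enrichment categories is applied by default, matching
the per-category reporting the analysis mirrors; callers can correct the
returned table.

`permutation_enrichment()` draws `n_perm` (default 1000) same-size CpG sets
from the background and counts hits in the union of the supplied tracks. The
p-value uses the add-one rule $p = (1 + \#\{\text{perm} \ge
\text{obs}\})/(n_\text{perm}+1)$, so finite resampling never reports zero
and an observation above every permutation gives $p = 1/1001 < 0.001$ at
the default. The tests check that at `n_perm = 20000` the permutation p
agrees with the hypergeometric p within two binomial standard errors.

A CpG-gene pair is loop-supported when some loop holds the CpG base in one
anchor and the gene's TSS in the other, in either orientation; a pair inside
a single anchor is not a contact. A pair is *local* (cis) when CpG and TSS
are on one chromosome at most 10 kb apart, and the reported fraction is the
share of clique genes with at least one local clique CpG.
`differential_median_cpgs()` implements the two-condition screen — absolute
median beta difference at least 0.1 *and* nominal p below 0.05 — using the
two-sided Mann-Whitney rank-sum test, chosen as the nonparametric test
consistent with the Kruskal-Wallis usage elsewhere; the test behind that
screen is otherwise unspecified.

## Infiltration scoring

`infiltration_score()` averages the expression of a lymphocyte-specific
"standard gene" list per sample; the list is a plain input (deriving it
from an expression compendium is out of scope, and the synthetic generator
emits its own truth list). Scores are computed on the expression values as
given, without per-gene standardization — a config-level choice, since
either convention is seen in practice. `quartile_groups()` splits samples
at the 25/50/75% rank cut points into `Q1`-`Q4` with ties broken by stable
input order, so group sizes differ by at most one even for degenerate
scores. Group comparisons use the tie-corrected Kruskal-Wallis statistic
with the $\chi^2_{g-1}$ upper tail (`stats::kruskal.test` underneath).
`infiltration_methylation_trend()` reports the mean clique methylation per
quartile and whether the Q1..Q4 sequence is strictly monotone. Tumor purity
enters only through the generator's known `purity = 1 - infiltration`; no
purity estimator is re-implemented.

## What the synthetic cohort emulates

`generate_cohort()` plants the two structures the analysis is designed to
find, with truth labels:

* **Cluster 2 (lineage clique).** A binary ER-status variable (ER+
  probability 0.6) switches CpG methylation between `beta_low = 0.1` and
  `beta_high = 0.8`: 2A CpGs are hypomethylated in ER+ tumors, 2B CpGs the
  reverse. 2A genes gain `expr_effect = 1` expression unit in ER+ samples,
  2B genes in ER− samples, so 2A CpG / 2A gene pairs anti-correlate. The
  default counts are 100+100 CpGs and 50+30 genes in a 2,000 CpG × 1,000
  gene, 200-sample cohort.
* **Cluster 1 (infiltration clique).** Each sample's lymphocyte fraction
  $f \sim \mathrm{Beta}(1.5, 3.5)$ (mean 0.3, broad — a realistic spread of
  infiltration) mixes two tissue methylomes: 1A CpGs follow
  $(1-f)\,0.8 + f\,0.1$, 1B CpGs the reverse, and the 60 immune genes rise
  linearly in $f$ with slope 3. With zero noise these are exactly affine in
  $f$, so planted within-clique correlations are exactly $\pm 1$ — a limit
  the tests exploit.

Methylation noise is gaussian on the logit scale (SD 0.3) and transformed
back, so beta values stay in $[0,1]$ without truncation artifacts;
expression noise is additive gaussian (SD 0.5). Background CpGs are
logit-normal around fixed uniform means, background genes gaussian. The two
cliques use disjoint feature sets, as the analysis treats them.

Two defaults deserve their rationale. First, the ER+ fraction is 0.6 rather
than the 0.75 typical of unselected breast-cancer cohorts: a bimodal CpG
whose minority mode holds a fraction $q$ of samples has its quartile
boundary collide with the mode boundary when $q \approx 0.25$, making the
IQR of a perfectly informative CpG degenerate to the within-mode spread and
dropping it from the screen whenever the realized cohort fraction drifts
past the boundary. 0.6 keeps both quartiles inside the majority mode with a
wide margin while remaining within the ER+ prevalence range reported across
cohorts. Second, effect sizes are calibration choices, not published
values — the source analyses report figure-level contrasts, not simulation
parameters — chosen so planted pairs carry $|r| \approx 0.6$-$0.7$,
comfortably detectable at $n = 100$ per cohort half yet far from
deterministic.

`generate_annotations()` builds a matched annotation bundle: a
chromatin-state segmentation tiling each chromosome in 1 kb tiles with the
nine-state vocabulary (tiles holding planted clique CpGs forced to
`Enhancer`/`Enhancer+CTCF`), ERα/FOXA1/GATA3-like peak tracks covering each
2A CpG with probability 0.8 plus sparse decoys (about one background peak
per 67 kb, keeping the background CpG hit rate near 2%), an immune-TF track
over Cluster-1 CpGs, a super-enhancer track, and loops connecting 25% of
(2A CpG, 2A gene) truth pairs with randomized anchor orientation plus decoy
loops. For cis pairing, 32% of Cluster-2 genes receive one same-direction
clique CpG placed inside their 10 kb TSS window, and every other clique CpG
is kept out of all Cluster-2 TSS windows, so the locally-paired gene
fraction is exact by construction; genes whose window is fully shadowed by
a neighbour's are skipped in favour of another draw rather than rejected
forever.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: co-methylation blocks and LD-like correlation
among background CpGs, copy-number and purity artifacts in expression,
probe-chemistry effects, cell-type deconvolution structure beyond a single
infiltration axis, and any genome sequence context. Recovery statistics on
synthetic cohorts certify the machinery, not biological discovery.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
default 200 × 2,000 × 1,000 cohort (seconds on one core; the screen itself
is ~600 retained CpGs × 1,000 genes per half after IQR filtering), the
engine-oracle comparison on 50 × 40 × 30 fixtures, the family-wise error
simulation on 200 null cohorts of 100 × 100 × 50, and the permutation-
hypergeometric agreement at 20,000 permutations. All randomness flows
through explicit seeds: the pipeline expands one global seed into fixed
per-stage seeds, `with_seed()` restores global RNG state afterwards, and
re-running any stage with the same config reproduces byte-identical
outputs (`manifest.tsv` records a semantic config hash that ignores path
relocation).

## Known limitations

* The biclique extractor assumes the significance matrix is dominated by a
  small number of dense blocks; overlapping or nested cliques are out of
  scope, as are spectral/plaid biclustering alternatives.
* Bonferroni is the only multiplicity rule, by design; no FDR variants.
* The screen is marginal: no covariate adjustment, no purity correction.
* Hypergeometric backgrounds assume exchangeability of CpGs; GC- or
  density-matched backgrounds are not provided.
* `impute_knn()` is quadratic in rows with missing data and meant for
  array-scale preprocessing of moderate matrices, not single-cell scale.
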