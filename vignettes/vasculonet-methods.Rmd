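---
title: "Methods: batch correction, network discovery and enrichment for the brain vascular proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch correction, network discovery and enrichment for the brain vascular proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculonet)
```

## The analysis problem

Isolating brain microvessels from postmortem cortex and profiling them by
multiplexed tandem-mass-tag (TMT) mass spectrometry yields a log2 protein
abundance matrix with several entangled sources of variation: TMT batch,
fractionation quality (how much parenchyma contaminates a vessel
preparation), nuisance covariates (age, sex, postmortem interval, neuronal
content), and the biology of interest — diagnosis-dependent changes across
control, Alzheimer's disease (AD) and progressive supranuclear palsy (PSP)
groups, organised into co-expressed protein communities. `vasculonet`
implements the full chain from raw log2 matrices to annotated co-expression
modules: batch correction anchored on pooled standards, sample quality
control, covariate regression that protects diagnosis effects, signed
weighted co-expression network construction, permutation module
preservation against the paired bulk proteome, per-protein and per-module
differential statistics, and cell-type / genetic-risk / biofluid
overrepresentation.

Because the matched human data are access-restricted, the package ships a
synthetic cohort generator that plants every signal the pipeline is
designed to recover. All statistical guarantees quoted below are
*planted-truth* properties measured on that generator, at stated problem
sizes.

## The synthetic cohort and what it does (and does not) emulate

`generate_cohort()` simulates a paired vascular/bulk TMT study under a
module factor model. For protein $i$ in module $m$ and sample $s$:

$$x_{is} = \mu_i + \sigma\left(\lambda_i f_{m(i),s} +
\sqrt{1-\lambda_i^2}\,\varepsilon_{is}\right) + b_{B(s)} +
\textstyle\sum_c \beta_{ic}(z_{cs}-\bar z_c) + \delta_{m(i),g(s)} + e_i,$$

where $f_{m,s}$ is a per-module latent factor **shared between the paired
vascular and bulk fractions** (the biology), $\lambda_i =
\sqrt{r}\,u_i$ with $u_i \sim U(0.75, 1.25)$ a per-protein loading giving
each module hub structure, $r$ the mean planted within-module correlation,
$b$ the per-batch log2 offset, $\beta_{ic}$ nuisance covariate slopes
carried by a recorded 30% subset of proteins, $\delta$ the diagnosis
effects, and $e_i$ the per-protein vascular-over-bulk enrichment (vascular
fraction only). GIS (global internal standard) channels are each batch's
mean biological channel plus 0.05 log2 noise, mirroring a pooled-aliquot
standard; they are always quantified, while biological entries go missing
completely at random (an intensity-dependent mode exists but is off by
default, since the underlying study does not model missingness).

Key default conditions, fixed once for testability at desk scale while
preserving the shape of a four-batch, 62-sample study: 1,000 proteins x
60 samples (20 per group) x 3 batches with one GIS each; 8 modules of
120 down to 40 proteins at $r = 0.6$; batch offsets $(+1, -1, 0)$ log2;
residual scale $\sigma = 0.4$ log2; covariate slopes 0.02 log2/year (age),
0.10 (sex), 0.01 log2/h (PMI); diagnosis effects *balanced in mass*
(AD $+0.5$ log2 on two modules and $-0.5$ on two others; PSP $\pm 0.4$ on
one module each). The balance is deliberate: any median-polish style
normalization treats a net shift of a large protein fraction within a
sample as a loading artifact and removes part of it, so a grossly
one-sided disease signature would be attenuated by design — in real
cohorts with ~10,000 proteins the affected fraction is small and the
effect negligible, but at 1,000 proteins it matters. Known limitations of
the generator: it produces Gaussian noise (no heavy-tailed peptide-level
artifacts), missingness is unrelated to abundance by default, covariate
values are independent of diagnosis (no age-by-diagnosis confounding),
and one latent factor per module (no nested or overlapping communities).
Passing planted-truth tests therefore demonstrates correctness of the
estimators under the model's assumptions, not robustness to every
pathology of real TMT data.

## Batch correction (TAMPOR)

`tampor_correct()` removes batch effects by an iterative two-way median
polish on the log2 matrix, equivalent to the sample-over-GIS ratio
formulation on the raw scale. Each pass subtracts, per protein and batch,
the median over that batch's *denominator* samples — the GIS channels by
default (`use_all_non_gis = FALSE`, the published choice), or all non-GIS
samples — and then each sample's median over proteins. Iteration stops
when the largest adjustment in a pass falls below `tolerance` (default
1e-8 log2; the source analysis reports convergence in 2 iterations but no
tolerance, so the default is chosen so an already-centered matrix
terminates immediately). The grand per-protein median **over the
denominator samples** is added back at the end; anchoring the add-back on
the pooled standard makes the whole correction an exact fixed point, so
running it twice changes nothing (idempotence to machine precision), while
leaving fold changes untouched. Medians are updated iteratively across
passes (true median polish) rather than frozen at their raw values — the
reference description does not say which; we record this choice here.

Two practical caveats the tests quantify. First, with a single GIS per
batch the corrected data retain batch-to-batch variance equal to the GIS
measurement noise itself (about $n_b(B-1)\sigma^2_{GIS}$ of sum-of-squares
per protein, ~1% of total variance at the default settings) — a floor no
GIS-anchored correction can go below. Second, a constant protein passes
through exactly only when samples have no global median shifts; otherwise
it absorbs the per-sample loading correction, which is the method working
as intended.

## Cell-type scores, outlier flagging, regression

`score_cell_types()` replaces the multi-algorithm deconvolution ensemble
of the source analysis with a transparent marker surrogate: per-protein
z-scores across samples, averaged over each cell type's markers, then
standardized across samples by median/MAD. The robust scale is essential:
the very fractionation outliers the scores must expose would otherwise
inflate the SD and mask themselves. `flag_outliers()` flags samples with
depleted endothelial (`z < -2`) *and* elevated neuronal (`z > +2`)
signal — the signature of a failed vessel enrichment — with both
thresholds configurable.

`bootstrap_regress()` fits, per protein, a linear model on neuronal
score, age, sex, PMI and TMT batch (one-hot, first batch as reference)
plus diagnosis; resamples *cases* with replacement `n_boot` times
(1000 by default, matching the published setting; "nonparametric
bootstrap" is read as case resampling), takes the per-term median
coefficient, and subtracts only the nuisance terms. Diagnosis
contributions are modeled but never subtracted, protecting group
differences. The published phrase "median estimated coefficient of
variation" is read as the median estimated coefficient over bootstrap
variation — subtracting a coefficient of variation would be dimensionally
incoherent. With `n_boot = 1` the result equals ordinary single-fit
residualization exactly, which the tests use as an oracle.

`variance_partition()` attributes per-protein variance fractions by exact
Shapley values over the covariate subset lattice (all term orderings
averaged), so the attribution is order-independent and fractions plus
residual sum to one by construction.

## Network construction

`build_network()` runs, in a single block over all proteins: biweight
midcorrelation (`bicor`) between all protein pairs
(pairwise-complete; a pair with fewer than 4 shared samples gets the
neutral correlation 0, a near-zero adjacency under the signed power);
signed adjacency $a_{ij} = ((1+\rho_{ij})/2)^\beta$ with $\beta = 9$;
mean-denominator topological overlap; average-linkage clustering of
$1-\mathrm{TOM}$; adaptive branch cutting; eigenprotein merging at
dissimilarity 0.07; and iterative kME reassignment. Defaults are the
published network settings (power 9, deep split 4, minimum module size
20, merge height 0.07, PAM staging respecting the dendrogram, kME rules
0.30/0.10 with at most 30 iterations).

Zero-MAD vectors fall back to Pearson weighting inside `bicor`, and
eigenproteins are sign-aligned so the mean member correlation is positive
(a convention is mandatory for downstream trait-correlation signs; the
source is silent, so we fix this one).

The branch cutter is this package's own adaptive variant of the
dynamic-hybrid idea, since the reference cutter's internals are not part
of the published description: the tree is cut at
$h_{min} + q\,(h_{max}-h_{min})$ with $q$ indexed by `deep_split`
(presets 0.99, 0.97, 0.95, 0.93, 0.91 from coarse to fine — these
constants are the auditable interpretation of the deep-split levels),
branches below the minimum size are unassigned, and a PAM stage assigns
leftover proteins to the nearest module by average dissimilarity,
restricted (when `pam_respects_dendro`) to modules found in the smallest
enclosing dendrogram branch. Module recovery is validated against planted
truth (adjusted Rand index), not against numeric equality with any
particular reference cutter.

The kME reassignment applies, each iteration after recomputing
eigenproteins (recomputation per iteration is our reading of the
iterative description): proteins with all kME < 0.30 become unassigned;
unassigned proteins with a kME > 0.30 join their best module; assigned
proteins whose current kME trails the best by more than 0.10 move. The
separate p-value-based reassignment threshold of the initial build is
subsumed by these explicit rules and not separately implemented. On the
default cohort the rules converge in 2-4 iterations, comfortably inside
the 30-iteration cap (the published build converged within 5).

## Module preservation

`module_preservation()` quantifies, per module, how much of its density
and connectivity structure recurs in a second (target) data set, via the
permutation Z approach: three density statistics (mean within-module
correlation, mean signed adjacency, eigenprotein variance explained) and
three connectivity statistics (reference-vs-test correlation of
intramodular connectivity, of kME, and of the within-module correlation
entries), each standardized against `n_permutations` random same-size
protein draws (500 by default, the published count; draws come from all
test-network proteins — the source does not say whether grey proteins are
excluded, so they are not). Zdensity and Zconnectivity are the medians of
their statistic groups, Zsummary their mean, and the one-sided p the
upper normal tail computed at full double precision (`pnorm(z, lower.tail
= FALSE)`, no 1-CDF cancellation; Z = 10 maps below 1e-23). The full
published preservation suite has many more statistics; this fixed 3+3
subset is a documented simplification, validated by planted-truth
behavior. Classification follows the published bands: Zsummary < 1.96 not
preserved, 1.96-10 moderate, > 10 high.

## Differential statistics

`anova_tukey()` computes per-protein one-way ANOVA and Tukey HSD
(Tukey-Kramer under unequal group sizes) from the closed-form
distributions (`pf`, `ptukey`); whenever a Tukey p falls below
$10^{-8.5}$ — where the studentized-range tail is numerically
unreliable — it is replaced by $\min(1, 3\,p_{Welch})$, the
Bonferroni-corrected two-tailed unequal-variance t-test over the three
pairwise comparisons (the multiplier 3 is the number of comparisons in a
three-group design). The substituted p is used everywhere downstream and
flagged. Zero-variance or under-observed proteins are skipped, never
reported as p = 0.

`module_trait_correlation()` uses bicor with the Student-t transform
$t = r\sqrt{(n-2)/(1-r^2)}$; ordinal neuropathology scores (CERAD, Braak,
CAA, gliosis) enter as numeric scores. `log2_enrichment()` gives
per-protein and per-module mean log2 vascular/bulk ratios over paired
samples, with fraction-unique proteins flagged after each fraction's own
missingness filter. `select_classifier_proteins()` applies the supervised
clustering input rule: unique to vasculature or at least 3-fold enriched,
and pairwise p < 0.05 in all three comparisons.
`normalize_reporter_channels()` and `abeta_ratios()` implement the
peptide-level amyloid workflow: channel-sum equalization to the maximum
summed channel, GIS-anchored batch correction reused verbatim at the
peptide level, and per-sample log2 ratios of the C-terminal tryptic
peptides of Abeta40 (`GAIIGLMVGGVV`) and Abeta42 (`GAIIGLMVGGVVIA`).

## Enrichment analyses

`fisher_set_enrichment()` is the shared overrepresentation engine:
one-tailed hypergeometric p on an explicit background, Haldane-corrected
odds ratios, Benjamini-Hochberg FDR across the call's rows. The cell-type
background is all network proteins (the source does not state its
background; ours is configurable). `biofluid_overlap()` builds the three
category sets per fluid (all detected, significantly increased,
significantly decreased at p < 0.05) and delegates to the same engine
with the full network as background.

`gwas_permutation_enrichment()` combines gene-level association p-values
from multiple studies into an ensemble (per gene, the mean of $-\log_{10}
p$ across studies containing it — the source says only "considered as an
ensemble", so the rule is fixed here and recorded in the output), scores
each module by its net nominal risk burden — the sum of $-\log_{10}$
ensemble p over member genes below the nominal 0.05 cut, divided by
module size — and standardizes against random same-size gene draws from
the network background (NES). A per-hit mean without the size denominator
would be blind to how many genes carry risk, which is the quantity of
interest in overrepresentation. Permutation FDR compares each NES against
the pooled standardized null, BH-adjusted across modules, with flags at
5% and 10%.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains filter, TAMPOR, QC/flagging, regression, network,
preservation against the paired bulk fraction, differential statistics
and the three enrichment analyses, writing every intermediate table, a
JSON manifest (parameters, per-stage seeds, input checksums) and a log.
One global seed deterministically derives per-stage seeds by stage-name
hashing, so any stage can be rerun in isolation and two runs with the
same configuration are bitwise identical.

Routine tests and the shipped acceptance analysis run at desk scale:
the default 1,000 x 60 cohort for recovery and regression (200 bootstrap
fits, scaled down from the published 1,000), a 500-protein network with
500 permutations for preservation, 10,000 null proteins for ANOVA
calibration, and 2,000 permutations for GWAS enrichment (scaled down
from the published 10,000). These sizes were chosen once as the smallest
at which the planted effects are comfortably identifiable; the published
full-scale settings remain the package defaults.
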