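---
title: "Cell-type enrichment analysis for bulk brain DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type enrichment analysis for bulk brain DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellenrich)
```

## The problem

Most epigenome-wide association studies (EWAS) of brain disorders profile
DNA methylation in bulk tissue, where every CpG's beta value is a mixture
over the constituent cell types. Two consequences follow. First, shifts in
cell composition between cases and controls (neuronal loss, gliosis) can
masquerade as differential methylation. Second, even genuine differentially
methylated positions (DMPs) carry no label saying *which* cell type drives
them. `cellenrich` addresses the second problem - attributing bulk EWAS
hits to cell types - by over-representation analysis (ORA) of a DMP list
against reference panels of cell-type-specific CpGs, and provides a
simulation framework to characterise how the first problem (composition
confounding) affects the answer.

The four cell classes are those resolved by fluorescence-activated nuclei
sorting of cortical tissue: NeuN+ neurons (NEU), IRF8+ microglia (MG),
SOX10+ oligodendrocytes (OLIG), and the triple-negative fraction, treated
as astrocyte-enriched (AST). The astrocyte fraction is defined by
exclusion, so it inevitably contains other minority glial populations; the
panels inherit that impurity.

## Panel construction

Panels are built from purified-nuclei beta matrices of **two independent
cohorts**; every criterion is evaluated within each cohort separately and
only CpGs passing in both are retained. The classification statistic is
the per-cell-type **median** beta, which is insensitive to single outlier
donors. Three nested specificity levels trade stringency against coverage:

* **High**: the median is strictly intermediate (0.1 < beta < 0.9) in
  exactly one cell type, all other medians are non-intermediate, and the
  target median differs from every other by at least 0.1. High sets are
  exclusive (disjoint across cell types) by construction.
* **Medium**: every cell type with an intermediate median is annotated,
  provided between one and three cell types are intermediate (at least one
  extreme cell type remains). Multi-annotation is allowed. The 0.1 median
  gap is *not* required here - the defining condition is the presence of an
  extreme cell type - but `classify_medium(require_gap = TRUE)` adds it
  for users who want the stricter reading.
* **Low**: a cell type is annotated when its median is intermediate and
  all three pairwise mixed-model contrasts against the other cell types
  are Bonferroni-significant (p\_Bonf < 0.05) in both cohorts. CpGs from
  the high and medium levels are carried over regardless, which enforces
  the nesting high ⊆ medium ⊆ low.

Intermediate means the *open* interval: a median at exactly 0.1 or 0.9 is
neither intermediate nor counted as extreme, a deterministic tie-break.
CpGs hypo- (< 0.1) or hypermethylated (> 0.9) in all four cell types can
never be annotated - they have no intermediate type - and they remain in
the background universe, since a background should contain every CpG the
assay could have reported.

### The mixed model

Low-specificity contrasts are fitted per CpG on M-values
(M = log2(beta/(1-beta)), clamped at epsilon = 1e-6), the
variance-stabilised scale for linear modelling of methylation:

M ~ cell_type + age + sex + (1 | donor)

fitted by REML through `nlme::lme` with convergence tolerance 1e-8. The
donor random intercept absorbs the repeated-measures structure (each donor
contributes all four cell types). The six pairwise cell-type contrasts are
Wald t-tests on fixed-effect differences, with the per-CpG Bonferroni
family of size 6 - the family the procedure actually performs per CpG; a
genome-wide factor can be supplied via `bonferroni_factor`. When the mixed
model cannot be estimated (too few donors, singular fit), the engine falls
back to ordinary least squares with donor as a fixed covariate and flags
the CpG in the `engine` column; CpGs where both engines fail are excluded
from low-specificity candidacy and listed in the `failed` attribute.

Only CpGs that are intermediate in at least one cell type in both cohorts
and not already medium-annotated for that type are sent to the mixed
model; the outcome for every other CpG is already decided, so the restriction
changes nothing and saves most of the fitting time.

## Enrichment statistics

For each cell-type set the 2x2 table counts input DMPs in/out of the set
against non-input background CpGs in/out of it. The set is intersected
with the background first, so unmeasured panel CpGs cannot inflate the set
margin. Three conventions matter:

* **p-value**: the one-sided exact hypergeometric tail P(X >= a) with all
  margins fixed (the enrichment direction; a two-sided Fisher test is
  available by flag). The test suite verifies the implementation against
  brute-force enumeration of the hypergeometric mass for every table with
  a total up to 30.
* **Odds ratio**: the plain cross-product ratio (ad)/(bc) when all four
  cells are positive; when any cell is zero, 0.5 is added to *all* cells
  (the Haldane-Anscombe correction, applied conditionally). When the
  overlap itself is zero the reported OR is 0 with a `zero_overlap` flag -
  a display convention for "nothing of this set was in the input" - while
  the corrected OR is retained in a diagnostic column. The flagged 0 never
  enters any p-value computation.
* **FDR**: Benjamini-Hochberg across the four cell types within one
  specificity level, the family in which results are reported. Pooling
  across levels is possible by adjusting the returned p-values directly.

Because the hypergeometric test is discrete and the per-level family is
small, the realised false-positive rate under random inputs sits below the
nominal level; the acceptance suite checks <= 5% (plus Monte-Carlo slack)
over 500 random-input runs.

### Matched permutation null

Large, permissive sets can look enriched for purely compositional reasons
(probe chemistry, CpG-island context, genic context are not uniform across
sets). `matched_permutation_null()` draws permuted input sets from the
background with the *joint* stratum counts of the observed input over
probe design x island context x gene context, recomputes the OR per draw,
and reports the add-one empirical p-value
(1 + #{permuted OR >= observed}) / (n_perm + 1), which can never be zero.
Draws are without replacement within a permutation. Since the input is a
subset of the background, each joint stratum always contains at least as
many background probes as the input demands; the coarsening fallback
(drop gene context, then island context) exists for the residual case
where sequential draws deplete a shared pool, and every engagement is
logged. A stratum whose pool exactly equals its demand is drawn
deterministically - with 1000 permutations this is visible as zero
variance contributed by that stratum.

## The pseudo-bulk simulation model

Validation rests on synthetic bulk data in which the truth is known.

**CpG model.** Each simulated CpG has per-cell-type means: set CpGs have
an intermediate mean (uniform 0.15-0.85) in their target cell type and
extreme means (uniform on 0.01-0.09 or 0.91-0.99, side chosen by fair
coin) elsewhere; background CpGs are intermediate in all four cell types.
A base SD is drawn uniformly on (0, 0.1) and shrunk towards the extremes
by the heteroskedasticity rule

SD\* = SD x (1 - |0.5 - mu| / 0.5),

so fully (un)methylated CpGs are noiseless - the familiar mean-variance
relationship of beta values. Observations are normal(mu, SD\*) truncated
to [0, 1], drawn by inverse-CDF so SD = 0 degenerates exactly to mu.

**Mixing.** Per-sample cell-type weights are Dirichlet draws; bulk beta is
the convex combination of the four per-sample cell profiles. Controls use
alpha = (1,1,1,1). The disease group of the composition-shift experiment
uses alpha = (1,2,2,2): the three glial parameters are increased equally,
producing a relative neuron reduction - the direction typical of
neurodegeneration. Methylation-generating distributions are identical in
both groups, so any disease/control difference is purely compositional.

**Set fractions.** The set sizes mirror the relative sizes of real
high-specificity panels - neuron and microglia sets several-fold larger
than oligodendrocyte and astrocyte sets - with defaults NEU 2.5%, MG 2.5%,
OLIG 0.6%, AST 0.6% of CpGs (about 6% in total). These are documented
approximations, configurable in `simulation_config()`.

**DMP calling.** Per CpG, ordinary least squares of bulk beta on the
disease indicator, optionally with three of the four mixing weights as
covariates (the fourth is collinear on the simplex), BH adjustment, call
at FDR < 0.05. Betas, not M-values, are regressed here: pseudo-bulk values
concentrate in mid-range where the scales are equivalent, and the simple
linear model is the one the validation is meant to characterise. The fit
is one vectorised least-squares solve over a shared design matrix,
verified in the tests to match per-CpG `lm()` to 1e-10.

**Weight noise.** Imperfect deconvolution is emulated by perturbing the
weights used for correction. The default convention is noise *scaled by
the weight*, w' = w(1 + e) with e ~ N(0, SD), floored at zero and
renormalised to the simplex (an all-zero row becomes uniform). This
convention was chosen because it reproduces the calibration anchor of the
study conditions - mean RMSE ≈ 0.12 between true and perturbed
proportions at SD 0.6 - whereas purely additive noise of that SD yields
RMSE ≈ 0.25, already close to the distance between two independent
simplex points. Additive mode remains available (`noise_mode =
"additive"`). Under the scaled convention, even SD = 1.5 leaves the
perturbed weights positively associated with the truth, so the corrected
analysis approaches - but does not exactly reach - the uncorrected one;
the acceptance suite asserts the approach as a shrinking distance between
corrected and uncorrected median ORs.

**DMP injection.** The input-size experiment uses equal alphas in both
groups and injects n DMPs allocated 50% to the neuron set, 20% to
microglia, 0.1% each to oligodendrocytes and astrocytes, and 29.8% to
background, with largest-remainder rounding so counts conserve exactly
(1000 DMPs give 500/200/1/1/298). Designated CpGs get a bulk shift
(default 0.2; the input-size acceptance runs use 0.3) in the disease
group, clamped to [0, 1]; `effect_delta = 0` designates without any
methylation effect, isolating ORA sensitivity from DMP-calling power.
Within an iteration one base dataset is generated and re-injected at each
count - iterations, not re-generation, provide the replication.

## Problem sizes and reproducibility

Full-scale simulated datasets hold 200,000 CpGs x 500 samples. The test
and acceptance suites run the same experiments at 20,000 CpGs (with
100+100 samples and 5 iterations for the composition-shift check, 250+250
and 10 iterations for the input-size check), sizes at which every
qualitative conclusion is stable while a full run completes in minutes on
one core; `simulation_config()` restores full scale. Every stochastic
component takes an explicit seed, experiments are bit-reproducible given a
config, and each CLI run writes a manifest (command, resolved parameters,
input digests, seed, version) sufficient to reproduce its outputs.

## What passing tests do and do not show

The generators emulate the *structure* the method relies on - four sorted
populations, two cohorts, donor random effects, intermediate-vs-extreme
methylation classes, Dirichlet composition, heteroskedastic truncated-
normal betas. They deliberately do not emulate array artifacts: probe-type
chemistry bias, batch effects, cross-hybridisation, SNP-affected probes,
or the empirical (bimodal, beta-like) distribution of real beta values.
Passing recovery and calibration tests therefore show the *procedures*
implement their definitions correctly and behave as designed under the
stated generative model; they do not certify performance on any real
array, where preprocessing quality and the accuracy of upstream
composition estimates dominate.

Other known limitations: the astrocyte fraction impurity noted above;
threshold-based set membership cannot represent graded cell-type
association; enrichment against panels from aged cortical tissue may not
transfer to other tissues, ages, or disease states; and low-specificity
panels annotate a CpG to several cell types, so `overlap_decomposition()`
should accompany any multi-annotated enrichment claim.

## Numerical choices

* M-value clamp epsilon 1e-6; beta_to_m is monotone and antisymmetric.
* Mixed-model convergence tolerance 1e-8; REML; deterministic fallback.
* Medians at exactly 0.1/0.9 excluded from intermediate (open intervals).
* A CpG column with numerically zero variance gets p = 1 (no information).
* Largest-remainder rounding for DMP allocation; ties broken by the order
  NEU, MG, OLIG, AST, background.
* Hypergeometric tails via `stats::phyper`; BH via `stats::p.adjust`;
  Dirichlet draws as normalised gamma variates; truncated normals by
  inverse CDF.
* Empirical permutation p uses the add-one estimator, bounded below by
  1/(n_perm + 1).
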