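---
title: "Differential lipidomics with lipidlens: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential lipidomics with lipidlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidlens)
```

## The analysis problem

Quantitative shotgun lipidomics delivers, per biological sample, absolute
amounts (pmol) for a few hundred lipid species identified by shorthand
names such as `PE 16:0-18:2` or `SM 34:1`. `lipidlens` implements the
full downstream analysis for two study designs:

* a **2×2 factorial animal study** — genotype (wild type vs a conditional
  knockout, here adipose-specific ATGL deletion) crossed with an
  intervention (sham surgery vs transverse aortic constriction, a
  pressure-overload model of heart failure), read out in left-ventricular
  tissue; and
* a **case/control human cohort** — heart-failure patients (HFrEF) vs
  controls, read out in plasma, where age and body-mass index differ
  between groups and must be adjusted for.

The package's core outputs are class-level abundance comparisons,
species-level differential statistics with false-discovery-rate control,
regulation-group clustering, dual-threshold fold-change classification,
and intervention tests on acyl-chain-matched PC/PE ratios.

## Nomenclature model

Species names follow the shorthand grammar `CLASS [O-] C:D[;H]`, chains
separated by `-`, en-dash or `/`. The parser distinguishes
*chain-resolved* names (each radyl chain listed, e.g. `PE 16:0-18:2`)
from *sum compositions* (`SM 34:1`, `CL 76:12`), because real tables mix
both: a single composition token on a multi-chain class is read as a sum
composition. Chain counts are structural: cardiolipin has 4 radyl
chains, triacylglycerol 3, diacyl phospholipids/ceramides/sphingomyelins
2, lyso-species and sterol esters 1, free sterols 0. Ether classes
(`PC O-`, `PE O-`, ...) mark the sn-1 chain as alkyl/alkenyl-linked.

Matching "the same fatty acids" across classes — the basis of the PC/PE
ratio statistic — is implemented as equality of the *multiset* of chain
compositions: sn-position is ignored (published names are inconsistent
about it), hydroxylation counts participate, and ether species are
excluded by default (matched among themselves on request), because a
diacyl/ether pair is chemically not the same-FA comparison.

## From pmol to log2 mole percent

1. **Zeros are missingness.** Shotgun pipelines only report
   identifications above a signal threshold, so a zero in the raw table
   is a below-detection event, not a true absence. Zeros and blanks both
   become explicit missing values at ingest; downstream log-transforms
   therefore never need pseudocounts.
2. **Missingness filter.** A species is kept iff in at least one
   experimental group it is observed in at least half the samples
   (`max_missing_fraction = 0.5`, a knob). Evaluating the rule within
   groups keeps group-confined species — exactly the interesting ones in
   an intervention study.
3. **Mole percent.** Each sample's observed values are renormalized to
   sum to 100, the denominator being the retained species. This makes
   samples comparable when total recovered lipid differs, at the price of
   *compositional closure*: raising one species necessarily lowers the
   relative share of all others. The package treats closure as a fact of
   the data rather than correcting it; the simulator (below) quantifies
   its footprint.
4. **log2.** All models operate on log2 mole percent, so coefficients
   are log2 fold changes and `2^coef` is a linear fold change.
5. **Imputation is class-level only.** Group-median (default) or
   group-mean regression imputation is applied *only* before class-total
   aggregation, where a missing low-abundance species would otherwise
   bias a class sum downward. Species-level models use casewise deletion
   instead — imputed values would fabricate degrees of freedom.

## Class-level comparisons

Class totals (per-sample sums of mole percent over the class's species)
are compared between intervention groups with a two-sided Mann-Whitney U
test — totals are bounded, skewed quantities for which rank tests are the
field's default. Exact enumeration of the U null distribution is used
for tie-free data up to a combined n of 20; ties or larger samples fall
back to the normal approximation with tie and continuity correction
(enumeration assumes continuity). In the mouse design, sham vs TAC is
tested separately within each genotype, and Benjamini-Hochberg (BH)
adjustment is applied across classes *within* each such family — the
families answer distinct questions and pooling them would couple their
error budgets. Display tiers (\*, \*\*, \*\*\*) use adjusted p < 0.05 /
0.01 / 0.001; the pipeline-wide discovery rule is adjusted p < 0.1, and
both are reported.

## Species-level factorial models

For every species the package fits, by ordinary least squares on the
log2 scale with casewise deletion,

$$y = \beta_0 + \beta_1\,G + \beta_2\,I + \beta_3\,G{\cdot}I + \varepsilon$$

with treatment coding (reference wild type, sham). Three hypotheses are
read off the single fit: the genotype t-test ($\beta_1$), the
intervention t-test ($\beta_2$), and the joint F-test of all three terms
against the intercept-only model ("genotype, intervention, and the sum of
both plus their interaction"). BH runs separately within each of the
three families across species; a species is *retained* when any family's
adjusted p falls below 0.1. A species needs at least 5 observations
spanning at least 3 cells; rank-deficient or zero-residual-variance fits
are flagged inestimable and excluded from the BH families rather than
given fake p-values of 0 or 1.

The intervention effect *within the knockout* is the linear contrast
$\beta_2 + \beta_3$, whose standard error comes from the coefficient
covariance; this backs the knockout half of the fold-change
classification below.

**Regulation groups.** Retained species are clustered by Ward linkage on
Euclidean distance over the standardized vector (genotype t,
intervention t, signed $\sqrt F$), the sign taken from the coefficient
with the largest absolute t so that the F component carries the
direction of the dominant effect. The tree is cut at k = 4 — the four
regulation patterns the factorial design can produce (up/down with
intervention, up/down with genotype). Species are processed in
canonical-name order, making labels invariant to input order; linkage,
metric and k are knobs. The display matrix holds row z-scores of the
four cell means (population SD over the 4 values), so each row shows a
species' *pattern*, not its magnitude.

**Fold-change classification.** Per genotype, the log2 fold change is
the difference of mean log2 values (TAC minus sham) and a species is
*significant* under the dual threshold: BH-adjusted p < 0.1 **and**
|log2FC| ≥ 0.5. The p backing this rule is a genuinely open design
point: a per-genotype two-sample test uses only that genotype's 14
samples (12 residual df), while the factorial model's intervention test
(wild type: $\beta_2$; knockout: $\beta_2+\beta_3$) estimates the
residual variance from all four cells (24 df) under the standard
homoscedasticity assumption of the factorial fit. The package defaults
to the factorial backing — the better-calibrated estimator under the
model already being fitted — and exposes `p_backing = "ttest"`,
`"welch"` and `"mw"` for the two-group alternatives. The choice was
fixed from a design-stage power analysis (see *Simulator* below), not
tuned on data.

## Matched PC/PE ratios

For every acyl-chain-matched PC/PE pair the per-sample ratio of mole
percents is computed (missing whenever either member is missing — no
imputation), which is algebraically `2^(log2 PC − log2 PE)` and invariant
to the per-sample normalization. Ratios are compared sham vs TAC by
Mann-Whitney within each genotype, BH across that genotype's testable
pairs. Pairs with fewer than half their ratios observed in a family, or
fewer than 2 observations in either group, are excluded from that
family's BH family rather than tested on near-empty groups. A fall in
the PC/PE ratio — PE induction outpacing PC — is the membrane-integrity
signal this statistic is designed to expose.

## The human arm

Class totals are corrected for age and BMI by pooled (both groups
together) least-squares residualization plus the grand mean. Pooling is
deliberate: residualizing within groups would leave group differences
untouched by construction and answer a different question. Corrected
values are exactly uncorrelated with both covariates and are then
compared control vs HFrEF by Mann-Whitney, BH across classes.

Species-level inference uses Huber M-estimation of
`log2 value ~ group + age + bmi` (tuning constant 1.345, 95% efficiency
at the normal; iterated to coefficient change < 1e-8 or 50 iterations).
Plasma lipidomes of small clinical cohorts carry occasional gross
outliers — hemolysis, lipemia, sampling artifacts — which is why a
robust fit is the default (`engine = "ls"` gives the plain fit). With no
outliers every Huber weight is 1 and the M-estimate coincides with
least squares. The group coefficient is the estimated log2 fold change
at fixed age and BMI; its standard error comes from the robust
asymptotic covariance of the M-estimator (the standard MASS form) with
a t reference on n − 4 df. The estimated control-group mean mole
percent — the x-axis of the classification plot — is the
back-transformed model prediction for a control subject at cohort-mean
age and BMI. BH runs across all species (not within class: the
discovery claim is cohort-wide), and the same dual threshold applies.

## Simulator: the study conditions in silico

`simulation_config()` + `simulate_study()` generate seeded synthetic
studies with known ground truth, used by the test suite and the
acceptance script in place of the clinical raw tables.

* **Catalog.** Deterministic: heart mode has 225 species in 18 classes
  with PC (35 mole%), PE (28%) and CL (12%) dominant; plasma mode 147
  species in 13 classes dominated by PC (32%), TAG (22%), SE (18%) and
  ST (8%). These dimensions and rankings mirror the emulated study;
  within-class species shares decay geometrically (ratio 0.9), the
  right-skewed profile typical of shotgun data. Other catalog sizes
  rescale class counts by largest remainder.
* **Signal model.** Per sample, species log2 mole fractions are baseline
  + planted effects + covariate terms + Gaussian noise (SD 0.5 log2 —
  mid-range for biological replicates in tissue lipidomics), then
  renormalized to a composition (closure applied exactly as in real
  data) and scaled to a pmol total. Planted `interaction` effects act
  only in the wild-type TAC cell: the headline biological pattern,
  induction present in wild type and absent in knockout, which in
  treatment coding is $\beta_2 = \delta$, $\beta_3 = -\delta$.
* **Missingness** is abundance-dependent, not completely at random:
  detection failure follows a logistic in log2 mole percent (intercept
  −7, slope −1), so low-abundance species drop out preferentially —
  exercising the filter and imputation paths the way real below-detection
  censoring does.
* **Covariates (plasma).** Ages are drawn at the cohort's group means
  (43.3 vs 59.2 years, SD 12) and BMI at 25.5 ± 2.7 vs 27.3 ± 3.6, so
  group and age are genuinely confounded; 20% of species get random
  age/BMI slopes (SD 0.01 and 0.02 log2 per unit), creating
  covariate-driven signal the adjustment must remove.
* **Default effect ledgers.** Heart: +1 log2 wt-confined induction on
  the 10 lowest-abundance diacyl PE species — low-mass placement keeps
  the planted total near 2% of the composition, so closure shrinks the
  realized contrast only by about 0.03 log2 (1 − log2(1 + 0.02)) and
  barely perturbs unplanted species; a documented property, not
  corrected. Plasma: 10 group effects echoing the cohort pattern (PE,
  DAG, PC, Cer up — the strongest at +2.5 log2, i.e. 5.7-fold — and two
  ether PCs down).

What the simulator does *not* emulate: instrument drift and batch
structure, isotope interference, correlated noise between co-regulated
species, non-Gaussian heavy-tailed biological variation in tissue, and
real chain-composition frequencies. Passing recovery tests therefore
demonstrates that the *statistical pipeline* recovers planted signal
under realistic dimensions, noise, closure and censoring — not that any
particular biological dataset would yield the same counts.

## Power at the design point, and pinned expectations

At the default recovery scenario (200 species, 10 planted wt-confined
inductions of +1 log2, 7 samples per cell, residual SD 0.5), a
design-stage power analysis with a closed-form oracle — accounting for
closure shrinkage of the realized effect (≈ 0.97 log2) and the ~2%
detection dropout on planted species — gives the factorial-backed dual
threshold a mean sensitivity of 0.62 (SE of a 50-replicate mean: 0.027)
at an observed false-discovery proportion near 0.09. The test suite
asserts mean sensitivity ≥ 0.51 (oracle mean minus four SEs), FDP ≤
0.15, mean wild-type log2FC within 0.1 of the planted 1.0, and mean
knockout log2FC within 0.1 of 0. The per-genotype two-sample t backing
would sit near 0.58 sensitivity at these conditions — the pooled
residual variance of the factorial fit buys its extra power.

Under the global null, BH at q = 0.1 bounds the probability of any
false rejection by about 0.1; the suite checks the observed fraction of
replicates with at least one dual-threshold discovery against that level
(plus binomial slack at 60 replicates).

## Numerical and degenerate-input policy

* Exact agreement of the factorial fit with the normal equations is
  asserted to 1e-10; the log2/mole-percent round-trip to 1e-12.
* Zero residual variance (all cell values equal) yields inestimable
  p-values, never 0; rank deficiency after missingness flags the species
  inestimable and removes it from BH families.
* All-equal z-score rows map to zeros rather than 0/0.
* Mann-Whitney p-values are clipped into (0, 1]; ties always force the
  corrected normal approximation.
* Every random draw flows from the configuration seed; identical
  configurations are bit-identical, and pipeline outputs are written
  with 10 significant digits so reruns compare byte for byte.
* Problem sizes in the shipped tests (catalog sizes 20–225, 50 recovery
  and 60 null replicates) were chosen to exercise every code path while
  keeping the default suite fast enough to run habitually.

## Known limitations

* Closure is reported, not corrected: no log-ratio (CLR/ALR)
  transformation is offered, matching the mole-percent convention of the
  emulated workflow.
* No empirical-Bayes variance moderation; plain least squares mirrors
  the original analysis and is honest at n = 7 per cell, but limma-style
  shrinkage would likely improve ranking at these sample sizes.
* The human arm adjusts for age and BMI only (the emulated cohort is
  all male); no other clinical covariates, no outcome modelling.
* Sum-composition species (e.g. `Cer 36:1`) cannot participate in
  chain-matched ratios — a data limitation, not a software one.
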