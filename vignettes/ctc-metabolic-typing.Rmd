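---
title: "Metabolic typing of single circulating tumor cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic typing of single circulating tumor cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcmet)
```

## The problem

Circulating tumor cells (CTCs) are shed from a primary tumor into the
bloodstream; counting them per blood draw is an established, but blunt,
indicator of metastatic risk, because CTC populations are heterogeneous and
only a subpopulation appears to carry metastatic potential. `ctcmet`
implements a molecular-typing workflow that (i) screens bulk cell-line
metabolomes for metastasis-associated metabolites, (ii) quantifies a small
metabolite panel in single CTCs with internal-standard calibration, (iii)
discovers metabolic subgroups of CTCs by consensus non-negative matrix
factorization (NMF) and summarizes them with a four-metabolite logistic
risk score that splits cells into a low-risk (C1) and a high-risk (C2)
subgroup, and (iv) predicts patient metastasis from per-patient subgroup
counts with Youden-optimal count cutoffs.

## Screening model

Bulk screens compare a primary and a metastatic colorectal cell line
(two such pairs). Processing order is fixed:

1. **Filter**: a feature is dropped when its detection fraction is below
   80% in *every* group, or when its maximum intensity is below 3 times its
   blank noise level. The 80% rule is applied group-wise — a feature well
   detected in one group is biology, not noise, even if absent in the
   other.
2. **Impute**: missing peaks become one tenth of the feature's minimum
   observed intensity, the conventional "left-censored" stand-in.
3. **Normalize**: per sample by protein amount and by the spiked
   internal-standard (acetaminophen) intensity, then per batch by each
   feature's median across the batch's pooled-QC samples. The QC step
   cancels any per-feature, per-batch multiplicative drift exactly.
4. **Test and select**: log2 fold change of linear-scale group means
   (metastatic over primary), an equal-variance two-tailed t-test on log10
   intensities, and the variable importance in projection (VIP) from an
   OPLS-DA model. A feature is selected iff |log2FC| > 1, p < 0.05 and
   VIP > 1 — all inequalities strict, so values exactly at a threshold are
   never selected. No multiple-testing correction is applied; the rule is
   deliberately the raw three-way filter.
5. **Intersect** the selections of the two cell-line pairs.

The OPLS-DA is a NIPALS orthogonal projection to latent structures with
one predictive component. Orthogonal components are added while the 7-fold
cross-validated Q2 improves by more than 0.01, capped at 5 (the commercial
implementation's heuristic is proprietary; a CV-gain rule is the standard
open-source surrogate). VIP is computed from the predictive weights, so
the mean squared VIP is exactly 1 — a structural identity the tests
verify on every fit. The t-test uses the equal-variance form on
log-transformed intensities; the source analysis does not state its exact
choice, and this one is recorded as the package's convention.

## Single-cell quantification

Cell content is withdrawn electro-osmotically through a conical
nanocapillary tip. The filled volume for tip radius $a$, cone half-angle
$\alpha$ and meniscus height $h$ (with $L = h/a$) is

$$V = \frac{\pi a^3}{3\tan\alpha}\left[(1 + L\tan\alpha)^3 - 1\right],$$

the closed form of $\int_0^h \pi (a + x\tan\alpha)^2\,dx$; with lengths in
micrometers, $V$ is in femtoliters. The implementation is checked against
numerical quadrature to below 1e-8 relative error and against the cylinder
limit $\pi a^2 h$ as $\alpha \to 0$. Representative narrow-tip settings
(a = 0.05 um, tan angle 0.1) reproduce the ~120 fL scale of a typical
single-cell extraction at a ~22 um fill height.

Quantification normalizes each analyte's peak area to its stable-isotope
internal standard and inverts an ordinary-least-squares calibration line.
Detection limits follow the ICH-style blank convention, LOD = 3.3
sigma_blank/slope and LLOQ = 10 sigma_blank/slope (the blank-based choice
is the package's; a signal-to-noise definition would differ only in the
sigma estimate). Negative back-calculated concentrations are clamped to
zero and flagged below-LLOQ: concentrations are physical quantities and the
downstream factorization requires non-negative input. A missing internal
standard refuses quantification rather than returning zero.

Batch effects are removed with ComBat (parametric empirical-Bayes
location/scale adjustment on log values, via `sva`). Two consequences of
the empirical-Bayes shrinkage are worth knowing: pure per-feature batch
shifts are removed *exactly* only when the standardized shift is the same
for every feature; otherwise a small residual of order
$\delta^2/(n\tau^2)$ remains, and repeated application moves values by at
most a couple of percent (the scale step's pooled-versus-within variance
bookkeeping). The tests assert exactness in the homogeneous regime and a
>= 90% reduction of the batch-mean gap plus ~2% near-idempotence in
general. Features with no within-batch variance get a location-only
adjustment, since a scale factor is undefined for them.

Precision QC reports intra-day and inter-day relative standard deviations
(100·sd/mean, sample sd; inter-day on the pooled values) with a pass flag
at the customary 20% bioanalytical criterion.

## Subgroup discovery and the risk score

NMF factorizes the non-negative cells-by-metabolites matrix as
$V \approx WH$ by Lee–Seung multiplicative updates on the squared
Frobenius objective (monotonically non-increasing; stopping at 1e-5
relative improvement or 2000 iterations). Consensus clustering runs 30
random restarts per candidate rank k in 2..6, converts each run's
argmax-of-W labels into a connectivity matrix, and averages these into a
consensus matrix. Rank selection maximizes the cophenetic correlation
between the consensus dissimilarity (1 − consensus) and the cophenetic
distances of its average-linkage dendrogram; ties prefer the smaller rank,
and final cell labels come from cutting that dendrogram — not from any
single run. When the cophenetic criterion prefers a finer rank than 2,
`consensus_labels(result, 2)` provides the two-group cut: the C1/C2
subgrouping is binary by definition, and the pipeline models risk on that
cut while still reporting the selected rank.

The metabolite fingerprint is chosen by backward elimination on a logistic
regression of the cluster label against all standardized panel
metabolites, dropping the largest Wald p while any p >= 0.05. A property
worth stating precisely: each uninformative metabolite survives this
procedure with probability roughly alpha, so with 7 null panel members the
fingerprint equals the informative set exactly in about $0.95^7 \approx
70\%$ of replicates and contains it in essentially all; the tests encode
those rates rather than an idealized 90% exact-recovery rate.

The risk model is a maximum-likelihood logistic regression of the cluster
label on the raw (mM) fingerprint abundances. Coefficients are divided by
$\ln 10$ so the stored model is on the base-10 logit scale of the
published classifier:

$$\log_{10}\frac{s}{1-s} = -0.932\,x_{\mathrm{Glu}} + 3.967\,x_{\mathrm{Mal}}
  - 0.166\,x_{\mathrm{Asp}} - 1.822\,x_{\mathrm{Lac}} - 3.694,$$

with C2 assigned iff $s \ge 0.420$ (the boundary is closed). The published
constants are available verbatim via `published_risk_model()`; abundances
are matched by metabolite name, never by position. Whether the original
regression was fit against cluster labels or patient outcomes is ambiguous
in the source; this package fits against cluster labels and uses outcomes,
when supplied, only to orient which cluster is called high-risk (otherwise
the positive-coded cluster of the provisional fit is C2). Thresholds come
from the Youden index over the observed scores under the rule "positive
iff score >= cutoff"; the J statistic is compared through its exact
integer numerator so tied cutoffs resolve deterministically to the
smallest.

## Patient-level classification

Cell labels aggregate to per-patient total, C1 and C2 counts; patients on
the roster with no detected CTCs are flagged CTC-negative and excluded
from classifier evaluation. Count classifiers use a strict boundary:
positive iff count > cutoff for total and C2 counts, and count < cutoff
for C1 (a *low* C1 count is unfavorable). The strict reading is anchored
in the prospective-cohort behavior where a C2 count equal to the cutoff of
1 was favorable. Default cutoffs are 3 (total), 1 (C1), 1 (C2). AUC is
the tie-aware Mann–Whitney probability (ties credited 0.5), which
coincides with trapezoidal ROC integration in the absence of ties;
sensitivity, specificity and accuracy are reported as one-decimal
percentages. Logistic association fits univariate and joint multivariate
models with Wald 95% intervals; (quasi-)separation falls back to a flagged
ridge-penalized fit.

## The synthetic cohort generator

No patient-level single-CTC data are public, so the generator reproduces
the *structure* the analysis assumes rather than any patient's data:

- Per-patient CTC counts are drawn from the reported clinical distribution
  (1: 3.3%, 2: 6.7%, 3: 30.0%, >=4: 60.0%; the >=4 mass is split 35/15/10%
  over 4/5/6 as a package choice).
- Each cell belongs to one of two latent subgroups (C2 prevalence 0.4, a
  free parameter). C2 centroids are shifted 4-fold on the four fingerprint
  metabolites; the source reports no per-metabolite effect sizes, so the
  shift is a free parameter fixed once.
- Biological noise is multiplicative log-normal with CV equal to the
  configured RSD (default 60%, the reported single-cell scale), so
  concentrations stay positive and the within-subgroup RSD converges to
  its target. Batch effects are additive in log space (matching ComBat's
  model), small by default (sd 0.1 over 3 batches).
- Metastasis outcomes are Bernoulli with logit $-2.2 + 1.1 \times$ (C2
  count): outcome depends on the C2 count only, so the C2-count classifier
  should dominate the total-count classifier — the qualitative counterpart
  of the published AUC gap (0.927 vs 0.681), whose exact values are not
  reproducible without the cohort data.
- `simulate_from_risk_model()` draws fingerprint concentrations from
  independent log-normals and labels cells by the model's own Bernoulli
  probabilities. Dispersions were fixed by a design power analysis so that
  every coefficient is identifiable from a few thousand cells: the
  smallest coefficient (aspartic acid, −0.166) gets the widest spread
  (RSD 125%, the upper range of reported intrapatient variability), and
  the means center the linear predictor near zero.

What the generator does *not* emulate: measurement censoring below the
LLOQ, correlated metabolite covariance within a cell, patient-level random
effects beyond the count distribution, cohort-level covariates that
correlate with outcome, or CTC-enrichment false negatives. Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical structure, not clinical performance on real cohorts.

## Problem sizes and numerical choices

The test-suite and acceptance workloads use cohorts of 60–75 patients
(~230–300 cells), 20 seeds for rate-style checks (8 for the end-to-end
chain), 30 NMF restarts per rank over ranks 2–6, and n = 5000 cells for
coefficient recovery — sizes chosen to put Monte-Carlo error comfortably
below the asserted margins. NMF uses a machine-epsilon guard in the
multiplicative denominators; OPLS-DA drops constant features with a
warning and guards the degenerate zero-covariance direction; Youden and
count-cutoff searches use exact integer arithmetic for tie resolution;
volume units are micrometers/femtoliters internally.

## Known limitations

- Consensus NMF on raw concentrations loses accuracy as biological noise
  grows: at the default 60% RSD the end-to-end subgroup recovery averages
  ~91% against planted truth (Bayes-optimal would be ~99%); at 30% RSD it
  is essentially perfect. Log-scale or robust factorizations are out of
  scope.
- The backward-elimination fingerprint keeps a spurious metabolite in
  roughly 1 − 0.95^(panel − informative) of runs by construction of the
  alpha = 0.05 retention rule.
- Printed cohort quantities that depend on the non-public patient data
  (exact AUCs, feature counts) are checked only for internal integer
  consistency or qualitatively, as described above.
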