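---
title: "Methods: vertex-wise hemispheric asymmetry and its behavioral correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertex-wise hemispheric asymmetry and its behavioral correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Task-fMRI contrast maps sampled on matched left/right cortical surface
vertices admit a threshold-independent, vertex-wise laterality index. For
left and right contrast estimates $L$ and $R$ at corresponding vertices,

$$\Delta = \frac{L - R}{|L| + |R|}, \qquad A = \frac{|L| + |R|}{2}.$$

$\Delta$ is dimensionless and bounded in $[-1, 1]$; positive values indicate
leftward lateralization. $A$ is the bilateral amplitude in the contrast's
units. Because $A$ uses absolute values, bilateral *deactivation*
contributes positive amplitude; the package implements the printed formula
as-is and leaves the interpretation of negative-contrast regions to the
analyst. Where $|L| + |R| = 0$ the index carries no information and the
cell is masked (propagating missingness) rather than set to zero, and no
epsilon is added to near-zero denominators: the index is meant to be
threshold-independent, and unstable vertices are tamed downstream by
network averaging, not by regularization.

Left/right correspondence is established geometrically: both hemispheres'
coordinates are re-centered on their bounding-box centers, the right
x-coordinates are mirrored, and each left vertex takes its nearest right
vertex by Euclidean distance. The Pearson correlation of the matched
coordinate vectors is a single quality figure; a correspondence whose
fit does not exceed 0.995 is rejected outright, and a non-bijective
assignment is an error carrying the collision count. No surface
registration or resampling is attempted — inputs are assumed
vertex-matched up to mirroring and permutation.

## Aggregation, ranking, and group inference

Network summaries are unweighted means of $\Delta$ (and $A$) over each
network's unmasked vertices — vertex-first, never recomputed from averaged
hemispheres, so the bounded index is averaged rather than re-derived from
sums. Networks are ranked by the RMS of cohort-mean asymmetry across
epochs; epochs by their mean across networks, with ties broken by the
canonical network/epoch order. Because unilateral-movement epochs share a
large task-level asymmetry, rankings can optionally center each task's
epochs on the task mean (`centering = "task_mean"`); the default is raw
epochs, and both code paths are first-class since reasonable displays
differ on this point.

Group inference on vertex maps follows the order: age is regressed out by
OLS (slope removed, mean restored), then grand-mean scaling normalizes
across the sex-by-race cells. Sex and race are scaled, not regressed —
deliberately mirroring the stated adjustment order rather than a full
linear model. For vector inputs the scaling factor is the classic
per-cell mean ratio; for vertex maps one factor per cell is computed from
the cell's mean over all vertices jointly, because per-vertex cell means of
a signed, noisy index pass arbitrarily close to zero and a column-wise
multiplicative factor would explode. Vertex-wise one-sample t-tests are
two-sided (the sign of asymmetry is the finding), with Benjamini–Hochberg
FDR over all vertices with a defined statistic; zero-variance vertices are
flagged and excluded from the family. The step-up rule is the standard
non-strict one (a vertex exactly at the boundary is rejected). Effect
sizes are Cohen's $d$ with the Hedges small-sample factor
$J = 1 - 3/(4\nu - 1)$, $\nu = n - 1$; the uncorrected $d$ is available by
flag since "corrected" is not uniquely defined in the literature.

## Coupling and accuracy analyses

Amplitude–asymmetry coupling is quantified two ways. Vertex-wise:
per-epoch Pearson correlations across subjects, averaged over the 17
epochs (epochs with zero variance at a vertex are dropped from that
vertex's mean). Group-binned: within each (network, epoch) cell subjects
are ranked by network-mean amplitude and cut into consecutive groups of 10
(remainder subjects beyond the last full group are dropped, the most
conservative reading when the cohort is not a multiple of the group size);
the correlation of group-mean amplitude with group-mean asymmetry then
characterizes the association at the group level.

Accuracy associations are subject-level Pearson correlations between a
network measure and percent-correct accuracy per scored epoch, Bonferroni
controlled over all tested cells in a call (9 networks x 12 scored epochs
= 108 by default; the family is all cells of one call since no other
family is well-defined). A binned display mode exists but the default is
subject-level. Linear-versus-polynomial structure is assessed with
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$, $k = \text{degree} + 2$. The
reported `selected` degree is the AIC minimizer, exactly as defined;
`selected_parsimonious` additionally reports the smallest degree within 2
AIC units of the minimum. Note a statistical fact about the minimizer: a
spurious extra term is selected whenever it improves the log-likelihood
term by more than its penalty, which under a true lower-degree model
happens with probability $P(\chi^2_1 > 2) \approx 0.16$ per degree —
roughly a fifth of linear-truth datasets select a higher degree no matter
the sample size or noise level. Consumers who want a stable selection
should use the parsimonious variant; the AIC differences themselves (raw
and as a percentage of the linear model's AIC) are always reported.

## PLS prediction

Network-mean measures for the 9 model networks across 17 epochs form a
153-column predictor matrix (epoch-major, canonical network order within
epoch). The ORA, VMM and PMM networks are excluded from prediction models
by default: they are small partitions with diffuse activation whose means
are the noisiest, and their inclusion degrades and destabilizes the fits.
Responses are either the corresponding 153 asymmetry columns or the 12
scored-epoch accuracies (missing accuracy imputed to the training column
mean, with the mask retained so imputed cells never enter evaluation).

Both $X$ and $Y$ are centered and scaled to unit variance with *training*
statistics — predictors span networks with very different scales, and
without scaling the components are dominated by high-variance networks.
Components are extracted by NIPALS with X-deflation, giving mutually
orthogonal X-scores; extraction stops early if the residual is exhausted.
The component count is fixed (12 by default) rather than auto-selected;
k-fold cross-validation (random, seeded fold assignment, no
stratification) reports out-of-fold explained variance per component count
as a diagnostic. Cumulative explained variance is reported for the
response *and* the predictors, since "variance explained" is ambiguous
between the two. Two-cohort validation fits on one cohort, evaluates
correlations between predicted and observed responses on the other, and
repeats with roles reversed; per-component scores can be tested against
age (correlation) and sex (two-sample t) with Bonferroni control across
components.

Internally the amplitude predictor matrix, the asymmetry matrix and the
accuracy matrix are distinct objects (built by `build_predictor_matrix()`
and `build_accuracy_matrix()`), avoiding the symbol collision that arises
when one letter names both an amplitude formula and a predictor block.

## The synthetic cohort generator

Restricted-access cohort data cannot ship with a package, so validation
rests on a generator that plants every statistical feature the analyses
consume, with the planted values retained as ground truth:

* **Geometry.** A quasi-regular jittered lattice filling a
  hemisphere-sized ellipsoidal volume (semi-axes 55 x 75 x 62 mm), with
  the right hemisphere an exactly mirrored, randomly permuted copy. A
  folded cortical sheet is effectively space-filling at low vertex counts,
  and the near-constant lattice spacing keeps mirror-matching well
  conditioned. The generator does *not* emulate surface topology, folding,
  or spatially smooth noise.
* **Signal.** A per-subject latent factor
  $f_i \sim N(\beta_{age} z(\text{age}) + \beta_{sex}\,\text{sex}_c,\, 1)$
  modulates amplitude multiplicatively and couples into asymmetry:
  $A_{ike} = \bar A_{ke}(1 + s f_i + s\varepsilon)$,
  $\Delta_{ike} = \bar\Delta_{ke} + c_{ke} f_i + s\zeta$, clipped to
  $\pm 0.99$ (the index must stay inside $(-1,1)$ for the construction
  $L = A(1+\Delta)$, $R = A(1-\Delta)$ to be sign-valid and exactly
  invertible at zero vertex noise). Defaults: $s = 0.1$, vertex noise SD
  0.5 contrast units, planted network-by-epoch means within $\pm 0.3$
  with contralateral motor, leftward language-story, and rightward
  emotion/attention patterns — magnitudes typical of network-mean
  laterality indices. Coupling coefficients default to 0.02–0.15 with the
  language network strongest; a coupling of order 1 on a unit-variance
  latent factor would push $|\Delta|$ past 1 and saturate the bounded
  index, so "more coupling" is expressed by scaling this pattern.
* **Behavior.** Accuracy is generated at the network-summary level (where
  the associations are measured): a per-epoch baseline plus weights (in
  percent per SD) on standardized noiseless network measures plus noise
  (SD 10%), clipped to [0, 100]. Default weights put the strongest
  asymmetry association in the language network during story epochs.
* **Covariates.** Age uniform 22–36 y, sex Bernoulli(0.5), BMI
  $N(26.5, 4.5^2)$, a right-shifted handedness score, and RMS motion
  $|N(0.3, 0.2^2)|$ mm. Age is standardized before entering the latent
  mean so that $\beta_{age}$ is per-SD.

The single-latent-factor correlation structure across epochs is an
assumption, not an observation: real within-subject dependence across task
epochs is richer. Passing tests therefore demonstrate that the pipeline
recovers what it assumes — planted lateralization, coupling, accuracy
structure, covariate effects — not that those structures describe any real
cohort.

## Cohort splitting

Discovery/replication splits stratify by sex and by quartile bins of age
and BMI, randomize within strata, and distribute rounding remainders by
largest fractional part so the global split matches `round(fraction * n)`
exactly. A stratified-random scheme was chosen over a named convenience
routine because it is reproducible from a seed and verifiably balanced;
accuracy is checked in the balance report but never used to form strata
(no selection on the outcome). Balance is reported descriptively (Welch
t / chi-square, standardized mean differences, no multiplicity
adjustment).

## Numerical and interface choices

* Native container: a version-tagged serialized R object; bit-for-bit
  lossless round trips. CIFTI-2 input is declared but not available in
  this build; vertex indices in all text sidecars are 0-based.
* Unassigned vertices carry background code -1 and never enter network
  means.
* NIPALS convergence: relative squared change of the score vector below
  1e-20, max 1000 iterations; component extraction truncates when the
  residual is numerically exhausted.
* All randomness flows from explicit seeds; the CLI threads one `--seed`
  through every subcommand.
* Test and validation problem sizes (up to 1,000 subjects and 2,000
  vertices; 500 subjects x 1,000 vertices in the acceptance script) were
  chosen as the smallest scales at which every planted effect is detected
  with comfortable power; all operations scale to full-surface inputs.

## Known limitations

Subcortical structures are out of scope: only cortical vertices are
analyzed. The generator's block-constant network signal has no spatial
autocorrelation, so FDR behavior under smooth noise is not exercised. The
amplitude formula folds deactivation into positive amplitude. The
combined amplitude-plus-asymmetry PLS model is available but no claim is
made about its relative performance, which is data-dependent.
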