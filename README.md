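# lateralize

Vertex-wise hemispheric asymmetry analysis for surface-based task fMRI.

Interhemispheric asymmetry — the unequal engagement of the two cortical
hemispheres during cognition — is usually quantified with
threshold-dependent laterality counts in volume space. `lateralize`
implements a threshold-independent alternative computed directly on the
cortical sheet and carries it through a complete group-analysis pipeline.
It is written for imaging researchers who have per-subject bilateral
contrast maps (e.g., surface-sampled task contrasts for many subjects and
task epochs) and want reproducible asymmetry maps, network-level
summaries, and brain–behavior models.

## The measures

For corresponding left/right vertices with contrast estimates *L* and *R*:

- **Laterality index** Δ = (L − R) / (|L| + |R|), dimensionless in
  [−1, 1]; positive = leftward lateralization. Cells with |L| + |R| = 0
  are masked.
- **Bilateral amplitude** A = (|L| + |R|) / 2, in contrast units.

Left–right vertex correspondence is established by mirror matching on
bounding-box-centered coordinates and accepted only if the matched
coordinate correlation exceeds R = 0.995.

On top of the maps the package provides: network aggregation over a
12-network partition with RMS/mean rankings; covariate-adjusted vertex-wise
one-sample t-maps with Benjamini–Hochberg FDR and Hedges-corrected Cohen's
d; vertex-wise and rank-binned amplitude–asymmetry coupling; accuracy
correlations with Bonferroni control and a linear-vs-polynomial AIC
comparison; partial least squares (NIPALS) prediction of asymmetry or task
accuracy from 153 network-by-epoch predictors with k-fold and two-cohort
(discovery/replication) cross-validation; covariate-matched cohort
splitting with balance reporting; and a synthetic cohort generator with
planted ground truth that makes every step testable end to end.

## Worked example

```r
library(lateralize)

cfg    <- sim_config(n_subjects = 120, n_vertices = 600, seed = 7)
cohort <- generate_cohort(cfg)

corr <- match_vertices(cohort$dataset$left_coords, cohort$dataset$right_coords)
#> Vertex correspondence: 600 vertices, coordinate fit R = 1

res  <- compute_asymmetry(cohort$dataset, corr)
summ <- aggregate_by_network(res, cohort$partition)
head(rank_networks(summ), 4)
#>   network  rms_delta
#> 1     SMM 0.13984965
#> 2     LAN 0.08655146
#> 3     AUD 0.08155911
#> 4     FPN 0.07305705

mean(summ$delta_mean[, "story", "LAN"])
#> [1] 0.251
```

The somatomotor network shows the strongest overall asymmetry (its planted
contralateral motor pattern dominates the RMS), and story epochs are
strongly left-lateralized in the language network (Δ ≈ 0.25, i.e., L
exceeds R by about 50% of the bilateral magnitude).

```r
X   <- build_predictor_matrix(summ, "amplitude")   # 153 = 9 networks x 17 epochs
Y   <- build_predictor_matrix(summ, "delta")
fit <- pls_fit(X, Y, n_components = 12, cv_folds = 10, seed = 7)
fit
#> PLS regression fit: 153 predictors -> 153 responses, 12 components, n = 120
#>   cumulative explained response variance: 0.164 0.179 ... 0.305
#>   out-of-fold explained variance at 12 components: 0.133

ac <- accuracy_correlations(summ, cohort$subjects, measure = "delta")
ac$r["LAN", "story"]          # 0.57, significant at the Bonferroni level
```

Amplitude predicts asymmetry well above chance out of fold, and language
asymmetry correlates with story-comprehension accuracy — the planted
brain–behavior coupling the generator encodes.

## Command line

A thin Rscript wrapper chains the whole pipeline
(`simulate → asymmetry → summarize → vertex-stats → couple →
accuracy-corr → pls → split → report`), sharing one `--seed` and one
`--out-dir`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lateralize.R", package = "lateralize"))')
Rscript "$CLI" simulate  --subjects 200 --vertices 2000 --seed 7 --out-dir run/
Rscript "$CLI" asymmetry --seed 7 --out-dir run/
Rscript "$CLI" summarize --seed 7 --out-dir run/
# ... vertex-stats, couple, accuracy-corr, pls, split, report
```

Outputs are TSV tables and JSON summaries with documented schemas.

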