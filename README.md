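# deltarad

Delta-radiomics response phenotyping for paired CT lesion scans.

## The problem

Targeted therapies such as EGFR tyrosine-kinase inhibitors only help the
patients whose tumors carry a sensitising mutation, and the imaging
phenotype of responders diverges from non-responders within weeks of
treatment. *Radiomics* quantifies that phenotype by extracting large
panels of intensity, texture, shape and margin descriptors from the
segmented lesion; *delta radiomics* takes the per-feature difference
between a baseline and a follow-up scan as a response signal. deltarad is
an R implementation of that screen for analysts working with paired
(pre/post) 3D CT volumes and binary lesion masks: it extracts a
183-feature catalogue per scan, forms delta features, selects a compact
panel of variant, mutually independent features, and scores each one as a
biomarker of mutation status, together with a test-retest stability
analysis on same-day repeat scans.

## The method

For subject *i* with feature vector *x*ᵢ at baseline (pre) and follow-up
(post), the delta dataset is

    Δxᵢ = xᵢ(pre) − xᵢ(post).

Features are screened in two stages on the delta table: the 15 most
variant features by coefficient of variation, CV = s/|x̄|, then iterative
removal of features from any pair with Spearman |ρ| > 0.95 until the
panel is mutually independent at that threshold; tumor volume and maximum
3D diameter are always appended for comparison. Each selected feature is
evaluated at all three time points with the rank-based AUC

    AUC = U / (n₊ n₋),   U = Mann–Whitney statistic (label 1 positive),

with a two-sided Mann–Whitney p-value (exact on small tie-free samples,
tie-corrected normal approximation otherwise). Test-retest stability of a
feature across same-day scan pairs is the one-way intraclass correlation

    ICC(1,1) = (MS_B − MS_W) / (MS_B + MS_W).

The 183-feature catalogue covers tumor volume, maximum diameter,
boundary-radius standard deviation, 9 surface shape-index fractions
(principal-curvature classes from cup to cap), sigmoid lesion-margin
offset/slope/amplitude, 14 Laws texture energies, 16 Gabor energies, and
135 grey-level co-occurrence statistics (15 statistics including IMC1 and
the maximum correlation coefficient, at 3 distances, aggregated over the
13 unique 3D directions by mean/std/range). The methods vignette
(`vignettes/delta-radiomics-methods.Rmd`) documents every class, its
parameters and the numerical conventions.

Because clinical cohorts of this kind are not publicly deposited, the
package ships a synthetic lesion-phantom generator (perturbed ellipsoids
with sigmoid margins, correlated intralesional texture and scan noise, a
mutation-dependent shrinkage/margin-blurring response model, and same-day
re-scan pairs) that reproduces the statistical structure the analysis
assumes, so the whole pipeline is testable end to end.

## Worked example

```r
library(deltarad)

# a synthetic lesion on a 64^3, 1 mm grid
lesion <- render_lesion(lesion_params(radii = c(9, 7, 8), margin_width = 1.5),
                        seed = 101)
fv <- extract_features(lesion$image, lesion$mask)   # 183 named values
round(fv[c("Volume", "Max_Diameter", "Boundary_Radius_Std",
           "Shape_SI9", "Sigmoid-Slope-Mean-d5", "GLCM_IMC1-mean-d1")], 3)
#>               Volume          Max_Diameter   Boundary_Radius_Std
#>             2132.000                18.166                 0.699
#>            Shape_SI9 Sigmoid-Slope-Mean-d5     GLCM_IMC1-mean-d1
#>                0.919               478.939                -0.122

# a small end-to-end study: 10 mutant + 10 wild-type subjects
res <- run_study(study_config(
  cohort = list(type = "synthetic", n_mutant = 10, n_wt = 10, seed = 7,
                grid_dim = 48, radius_range = c(5, 10))))
subset(res$auc, feature == "Volume")
#>    feature timepoint  auc        p direction n_pos n_neg p_adj_bh
#> 15  Volume       pre 0.64 3.15e-01         1    10    10 0.698752
#> 31  Volume      post 0.22 3.55e-02        -1    10    10 0.238242
#> 47  Volume     delta 0.98 4.33e-05         1    10    10 0.000693
```

The lesion's 2132 mm³ volume and 18.2 mm diameter are read straight off
the mask; `Shape_SI9 = 0.92` says 92 % of the surface is locally
cap-like (the lesion is nearly ellipsoidal); the sigmoid slope is the
mean maximum density-change rate across the margin in HU/mm. In the
study, baseline volume barely separates the groups (AUC 0.64, p = 0.32)
while delta volume is strongly predictive (AUC 0.98, p < 10⁻⁴) —
mutant lesions shrink under therapy, wild-type ones do not.

## Analysis workflow

The `analysis/` scripts run the full simulated study and leave their
tables under `results/` (volumes land in `scratch/`, which is
regenerable):

```sh
Rscript analysis/01_simulate_cohort.R    # cohort + retest NIfTI phantoms
Rscript analysis/02_extract_features.R   # 183 features x 2 time points
Rscript analysis/03_select_and_score.R   # delta, selection, AUC, correlations
Rscript analysis/04_stability.R          # per-feature test-retest ICC
```

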