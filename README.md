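# cpcquant

Whole-slide quantification of chromogenic immunohistochemistry (IHC) for
cardiac progenitor-cell markers, with the cohort statistics to compare
disease groups.

## The problem

Putative cardiac progenitor cells are identified in myocardial biopsies by
surface markers such as CD117 (c-Kit) and CD90 (Thy-1), stained with an
AEC chromogen over a hematoxylin counterstain. Comparing marker expression
across patients requires (a) turning a scanned brightfield slide into
per-section numbers that do not depend on section size, and (b) comparing
those numbers across small, unbalanced diagnosis groups (healthy,
myocarditis, ischemic and dilatative cardiomyopathy). `cpcquant`
implements both layers, plus the serial-section co-expression count used
to argue that CD117+ and CD90+ signals mark the same cells, and a
synthetic-slide generator so every stage is testable against exact ground
truth without any raw slide data.

## What it computes

**Image layer.** A slide is separated into stain concentrations by
optical-density colour deconvolution: with Beer–Lambert absorbances
`OD = -log10((I+1)/(I0+1))` per RGB channel and unit stain vectors as the
columns of `M`, each pixel solves `OD = M c` for the concentration triple
`c` (hematoxylin, AEC, residual). Tissue is the Otsu foreground of the
summed concentration image (holes filled, debris removed), eroded by an
edge margin (default 20 µm) to drop cutting artifacts. Signals are
8-connected components of `{AEC ≥ 0.15 OD}` inside the tissue mask,
classified *single* vs *concatenated* (area > 300 µm², or ≥ 2 intensity
peaks ≥ 5 µm apart). Per-section metrics:

- relative number = signal count / tissue area (px)
- relative area = signal pixels / tissue pixels
- signals per mm² = count / tissue area (mm²)

**Co-expression layer.** Serial sections carry one marker each. Masks are
registered rigidly (rotation grid × phase correlation), a 4 mm² field of
maximal tissue coverage is selected, and cells are matched across sections
by greedy mutual nearest neighbours within 15 µm; the matched count is
reported per mm².

**Statistics layer.** Ratio metrics are transformed with
`logit(p) = log(p/(1-p))`, then compared by one-way ANOVA and Tukey–Kramer
post-hoc tests, `SE = sqrt(MSW/2 (1/n_i + 1/n_j))`, with adjusted p-values
from a studentized-range distribution evaluated by direct numerical
integration. The 23-patient reference cohort (four metrics per patient)
ships as a packaged CSV fixture (`table2_cohort()`).

## Worked example

```r
library(cpcquant)

# a seeded synthetic slide with known ground truth (35 signals painted)
g <- generate_slide(phantom_spec(seed = 7))
m <- quantify_slide(g$slide, pipeline_config())
as.data.frame(m)[, c(1, 3:5, 7:9)]
#>        slide_id total_signals n_single n_concatenated relative_area
#> 1 phantom_seed7            35       30              5    0.04944489
#>   signals_per_mm2 tissue_area_mm2
#> 1        278.3499        0.125741
g$truth$n_signals
#> [1] 35
```

All 35 painted signals are recovered, with the 30/5 single/concatenated
split matching the generator's labels. The cohort analysis of the packaged
fixture:

```r
run_cohort_analysis("table2", "cd117_relative_area")
#> == Cohort analysis: cd117_relative_area (scale: logit ) ==
#>
#> Group summaries (analysis scale):
#>        group  n        mean        sd scale
#>      Healthy  3 -4.07556832 2.4871098 logit
#>  Myocarditis  3  0.04096917 0.8350909 logit
#>          ICM 10 -1.02099689 1.4153078 logit
#>          DCM  7 -0.97666554 0.5932967 logit
#>
#> One-way ANOVA: F(3, 19) = 5.6022, p = 0.006324
#>
#> Tukey-Kramer pairwise comparisons (alpha = 0.05):
#>      group_a     group_b mean_diff standard_error q_statistic adjusted_p
#>      Healthy Myocarditis   -4.1165         0.7713      5.3374   0.006442
#>      Healthy         ICM   -3.0546         0.6218      4.9124   0.012430
#>      Healthy         DCM   -3.0989         0.6518      4.7541   0.015830
#>  Myocarditis         ICM    1.0620         0.6218      1.7079   0.629700
#>  Myocarditis         DCM    1.0176         0.6518      1.5612   0.691500
#>          ICM         DCM   -0.0443         0.4655      0.0952   0.999900
#>  significant
#>         TRUE
#>         TRUE
#>         TRUE
#>        FALSE
#>        FALSE
#>        FALSE
```

CD117 relative area is significantly higher in every disease group than in
healthy sections (all three adjusted p < 0.05); the same pipeline on CD90
relative area finds no group effect (ANOVA p = 0.15).

## Command line

```sh
Rscript inst/cli/cpcquant.R simulate slide --seed 1 --out out/
Rscript inst/cli/cpcquant.R quantify --in slide.png --mpp 0.5 --out out/
Rscript inst/cli/cpcquant.R coexpress --cells cells.csv --out out/
Rscript inst/cli/cpcquant.R stats --fixture table2 \
    --metric cd117_relative_area --out out/
```

Exit codes: 0 success, 2 input error, 3 degenerate data (e.g. no tissue).

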