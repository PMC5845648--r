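---
title: "Methods: whole-slide IHC quantification and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-slide IHC quantification and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcquant)
```

`cpcquant` quantifies chromogenic IHC (AEC chromogen over hematoxylin
counterstain) on whole-slide brightfield images of myocardial biopsies and
compares the resulting per-section metrics across diagnosis groups. This
vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not establish.

## 1. Stain model

Brightfield absorbance is additive in optical density (Beer–Lambert). Per
channel, with white reference `I0`,

    OD = -log10((I + 1) / (I0 + 1)),

the +1 offsets keeping OD finite at intensity 0 on 8-bit data (the price
is a bounded, sub-0.002 bias at typical backgrounds, far below the 0.15 OD
positivity cut). A pixel's OD 3-vector is modelled as `M c`, where the
columns of `M` are unit stain vectors: hematoxylin `(0.650, 0.704, 0.286)`
and AEC `(0.274, 0.679, 0.680)` — the standard published brightfield
values for this pair, renormalised — plus their unit cross product as a
residual channel. `deconvolve()` inverts the 3×3 system per pixel;
negative concentrations are physically meaningless and are clipped to
zero, but the unclipped solution is kept in an attribute so the exact
round trip `M c = OD` remains testable to 1e-9. Blind stain-vector
estimation is deliberately out of scope; the basis is a config parameter.

**White reference.** The background of a slide scan is bright glass. We
take, per channel, a quantile of the pixels whose Rec.601 luminance
exceeds 200/255. The luminance floor is what rejects tissue; given that,
an extreme quantile is *not* desirable, because for constant illumination
plus camera noise of sd σ the 99th percentile is biased +2.33σ (≈ +7
units at σ = 3). The default is therefore the median of the floored
pixels, which recovers a known illumination within fractions of a unit at
realistic noise; the quantile remains a parameter for unusually dirty
backgrounds.

## 2. Tissue mask and edge exclusion

Tissue is the Otsu foreground of the summed hematoxylin + chromogen
concentration image, floored at 0.05 OD so an empty slide yields an empty
mask instead of a noise split. Holes (vessel lumina) are filled before
anything else so they cannot generate internal "edges"; connected
components below 500 µm² are discarded as debris (biopsy fragments are
orders of magnitude larger). Sections carry cutting and staining artifacts
along their rim, so the mask is eroded by a disc of radius 20 µm (the
margin is configurable; the erosion is computed exactly via a squared
Euclidean distance transform, so the disc is the true discrete disc). A
separable square-element mode exists only because the erosion of a
rectangle has a closed form, which the tests exploit. Every downstream
metric uses the post-exclusion area as its denominator — this composition
contract is what makes "relative area" comparable across sections.

## 3. Signal detection and classification

Signals are 8-connected components of `{chromogen OD ≥ 0.15}` inside the
(post-exclusion) tissue mask, dropping components under 20 µm². The fixed
0.15 OD default favours reproducibility; an adaptive per-slide mode (Otsu
restricted to tissue pixels with chromogen > 0.02) is available because
staining intensity judgements in rule-set software are typically relative,
but it is off by default. A component is *concatenated* rather than
*single* when its area exceeds 300 µm² (≈ two nominal 150 µm² cells) or
when its chromogen map holds ≥ 2 regional maxima at least 5 µm apart;
peak counting smooths with a 3×3 box filter (twice) and ignores secondary
maxima below 50% of the component peak, a guard against noise-born
maxima on one cell's staining dome. Concatenated signals count once
toward the total — the alternative (counting constituents) is not
computable without a cell model, which is deliberately out of scope (no
nucleus segmentation, no watershed splitting, no mast-cell exclusion).

Large diffuse chromogen areas (e.g. cardiomyocyte-wide CD117 staining)
are *not* excluded by any cell-type classifier; they simply enter the
relative area, which is why area rather than count is the robust CD117
readout.

## 4. Serial-section co-expression

Each marker lives on its own serial section, so co-expression is a
spatial match across sections. Registration is deliberately simple:
serial sections are near-aligned, so an exhaustive rotation grid
(±10° in 0.5° steps) with phase-correlation translation at each angle,
scored by mask overlap, is robust and deterministic; elastic registration
is out of scope. The analysis field is the axis-aligned square window (4
mm² by default) with maximal tissue coverage — a computable proxy for the
human "high histological quality" judgement, with ties broken toward the
smallest (row, col) origin for determinism. Matching links one centroid
per section by greedy mutual nearest neighbours, candidates ordered by
total pairwise distance, each centroid used once, all pairwise distances
within 15 µm (≈ one cell diameter); an exhaustive assignment oracle in
the test suite confirms the greedy count is near-optimal at realistic
densities. Group summaries use the sample (n−1) standard deviation; a
singleton group reports sd 0.

## 5. Cohort statistics

Per-section ratio metrics live in (0, 1) and are variance-stabilised with
`logit(p) = log(p/(1-p))` before comparison; counts are analysed raw (the
logit domain excludes values ≥ 1). The natural logarithm is a pure
convention: a base change is a positive rescaling, and the test suite
verifies that F, q and every significance call are invariant under
`y → a y + b, a > 0`, so no reported conclusion can depend on it.

Groups are compared by classical one-way ANOVA and Tukey–Kramer all-pairs
post-hoc tests with `SE = sqrt(MSW/2 (1/n_i + 1/n_j))` (valid for the
unbalanced 3/3/10/7 design). Adjusted p-values come from the package's
own studentized-range distribution, computed from the classical double
integral by high-order Gauss–Legendre quadrature (384 nodes below 20
degrees of freedom, 128 above). Against adaptive quadrature at 1e-12
tolerance the integrator is accurate to ~1e-12 — closer than R's own
`ptukey` at small df — and it reproduces the published critical values
q(k=4, df=19) = 3.98 and q(k=4, df=20) = 3.96 to two decimals. No
multiple-testing correction is applied beyond Tukey–Kramer itself.

The packaged 23-patient cohort CSV carries the per-patient values
verbatim at printed precision; published group averages of counts are
printed rounded, so count means are compared after nearest-integer
rounding.

## 6. The synthetic world

The generator exists so that every stage has exact ground truth:

- **Slides** (`generate_slide`): a tissue disc of counterstain on bright
  glass (default 1024² px at 0.5 µm/px, the scale of a 20× scan), with
  isolated and clustered chromogen signals and chromogen-like artifact
  blobs hugging the tissue rim (which the edge margin must remove).
  Signals are 7 µm-radius discs (≈ 150 µm², one cell) with a dome
  intensity profile — 60% plateau plus a Gaussian cap — so the positive
  area is exactly the painted disc union while touching cells keep
  distinct intensity peaks for the concatenation rule. Rendering inverts
  Beer–Lambert exactly; camera noise is additive Gaussian in intensity
  space (sd 3/255), not OD space, so the noise-free round trip is exact
  to 1e-6. Signal anchors are snapped to pixel centres to keep that round
  trip exact at the peak. Placements keep ≥ 32 µm apart and ≥ 40 µm from
  the rim, so detected counts should be *exact*, not approximate — and
  the acceptance suite asserts exactly that.
- **Serial stacks** (`generate_serial_stack`): an asymmetric multi-lobed
  tissue blob (a plain disc is rotationally symmetric and cannot
  constrain the registration angle — a real biopsy fragment is
  irregular), sectioned under recorded small rigid transforms, with a
  configurable fraction of cells shared across sections. All cell
  positions come from one pool separated by ≥ 35 µm (> 2× the match
  radius), so the true co-expression count is unambiguous up to
  registration error.
- **Cohorts** (`generate_cohort`): logit-normal draws with per-group
  shifts, sizes (3, 3, 10, 7), baseline −4 logits and within-group sd 1.3
  — the spread actually observed in the reference cohort — so effect
  sizes are directly on the tested scale.

What a green synthetic test establishes: the algorithms recover known
geometry, counts and effects under the stated noise model. What it does
not: robustness to real histology — texture, folds, pen marks,
out-of-focus regions, stain batch variation — which geometric phantoms by
design do not emulate. The per-patient image metrics of the reference
cohort are not recomputable at all (the raw slides were never deposited);
the image layer is therefore validated by these property-based criteria,
while the statistics layer is validated against the published per-patient
table directly.

## 7. Numerical and degenerate-input policy

- All component labelling is 8-connected and deterministic; ties in field
  selection and peak ordering are broken lexicographically.
- An all-background slide yields an empty mask, which downstream stages
  reject with a `no tissue` error (CLI exit code 3); all-identical values
  raise a degenerate-variance error rather than returning F = 0/0.
- Every generator is a pure function of its spec, seed included; the
  pipeline writes a provenance block (config hash, seed, version) so
  identical inputs give identical reports.
- Erosion by margin 0 is the identity; `logit` rejects its boundary;
  background estimation fails loudly when no pixel clears the luminance
  floor rather than returning a dark "white" reference.

## 8. Known limitations

- PNG is the only on-disk image format (the environment provides no R
  TIFF reader); the proprietary scanner container was always out of
  scope. All APIs accept in-memory arrays.
- The relative-number denominator is pixel area, matching the reference
  per-patient table; densities in physical units are provided alongside
  (`signals_per_mm2`) and tests pin the `1/mpp²` consistency between
  them.
- Greedy matching is near-optimal, not provably optimal, for k ≥ 3
  markers; the k = 2 case is validated against an exhaustive oracle.
- Registration is rigid and global; warped or torn sections are out of
  scope.
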