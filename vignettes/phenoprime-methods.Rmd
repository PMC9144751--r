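---
title: "Methods: plate phenotyping, the PBCI, and the simulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate phenotyping, the PBCI, and the simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprime)
library(dplyr)
```

`phenoprime` analyses in-vitro screens in which *Arabidopsis thaliana*
seedlings from primed and unprimed seeds grow one-per-well in multi-well
plates — under optimal conditions, 100 mM mannitol (osmotic stress) or
100 mM NaCl (salt stress) — and are imaged from above twice a day for seven
days. This vignette documents the models and the numerical and design
choices behind each stage.

## The growth model behind the simulator

No public dataset accompanies this kind of screen, so the package ships a
first-class generator whose defaults are the screen's design: 48 plants per
treatment × condition, 14 timepoints at 0.00, 0.25, 1.00, 1.25, …, 6.25
days (two acquisitions per day, six hours apart), three conditions, and
seven treatments (an unprimed control plus DAP, ornithine and putrescine at
0.1 and 1 mM).

Rosette area follows a logistic curve,

$$A(t) = \frac{K'}{1 + \frac{K' - A_0}{A_0}\, e^{-r' t}},$$

with initial area $A_0 = 60$ px, control carrying capacity $K = 6000$ px
and intrinsic rate $r = 1.5$/day, chosen so an unstressed rosette saturates
near the end of the 7-day window while staying well inside a 10.4 mm well
(≈ 8500 px at the default 0.1 mm/px scale). Growth curves in such assays
are sigmoidal but no functional form is canonical; the logistic was chosen
because rosettes saturate in wells, and because letting $K \to \infty$
reduces it to pure exponential growth — which makes relative-growth-rate
recovery exactly testable (`rgr` equals the simulated $r$ on noiseless
exponential data).

Stress multiplies the carrying capacity: `stress_K_multiplier` defaults to
0.30 (osmotic) and 0.22 (salt), so the simulated unprimed final size drops
by 70% and 78% relative to optimal — the magnitudes this kind of stress
produces at 100 mM. Treatments multiply $r$, $K$ and greenness per
condition, so the PBCI's slope-like components (GC-slope, RGR) and
size-like components (AUC, FG) can be perturbed independently. The default
treatment-effect table emulates a screen qualitatively: most agents are
mild salt alleviators, low doses are near-neutral under optimal conditions,
and high-dose ornithine is inhibitory everywhere. These are illustrative
defaults, not estimates.

Measurement noise is multiplicative lognormal with mean 1 and coefficient
of variation `noise_cv`; areas therefore stay positive and the noise is
scale-free. Within-group variability is not reported for screens of this
type, so the default `noise_cv = 0.15` is a deliberate, config-exposed
choice of a realistic imaging + biology spread; nothing downstream depends
on its exact value. Per-plant greenness is drawn once per plant
(`gli_sd = 0.02` around the treatment level, baseline GLI 0.40) and held
constant over time.

What the generator does *not* emulate: leaf-level morphology, overlap
between neighbouring rosettes, lighting gradients, specular highlights on
the sealing film, or temporal autocorrelation of measurement errors.
Passing tests on synthetic scenes therefore demonstrate the pipeline's
internal consistency and statistical calibration, not robustness to every
artefact of real plate imaging.

## Rendering and segmentation

`render_plate()` draws each plant as a connected blob whose boundary is a
level set of a radially lobed profile (4–8 lobes, random amplitude and
phase per plant). Pixels are ranked by lobe-scaled radius and the requested
number of innermost pixels is taken, so the rendered area matches the
request exactly and the ground-truth mask is exact by construction. Leaf
color fixes red and blue at leaf-like values and solves the green channel
per pixel so each pixel's GLI equals the requested greenness up to integer
quantization; greenness requests are clamped to [0, 0.55], the range the
color model can represent within 8-bit channels. The agar background is a
neutral tone (GLI ≈ 0) with mild channel noise, keeping excess-green
segmentation well posed.

`segment_plants()` thresholds excess green (2G − R − B) at a fixed default
of 40 — comfortably above background fluctuations and below leaf pixels at
any plausible greenness — then applies a morphological opening with a 3 × 3
diamond element to remove speckle, labels connected components, and assigns
to each well the largest component whose centroid falls inside the well's
disc. Centroid-based assignment avoids double counting when a blob touches
a well wall; a component reaching beyond its disc is still assigned (with a
warning) to the disc containing its centroid. Components smaller than
`min_object_px = 25` px are treated as debris. An Otsu threshold on the
excess-green histogram is available (`otsu_threshold()`) for images where
a fixed cutoff is unsuitable. Channel means are computed per pixel over the
final mask — not from pre-averaged channels — so the per-plant GLI is the
mean of per-pixel GLI values, which is what a ratio index requires.

## The five traits

- **AUC.** The printed convention for this trait in the screening
  literature, $\sum (s_i - s_{i-1})/2$, telescopes to $(s_n - s_0)/2$ and
  cannot distinguish trajectories with equal endpoints, which would defeat
  the trait's purpose of summarising the whole curve. The package therefore
  defaults to the trapezoidal rule over time in days (px·day) and preserves
  the telescoping form as `mode = "literal"` for comparability.
- **RGR.** First/last observations, time in days. With noiseless
  exponential data the estimate equals the simulated rate; at the design
  noise level (CV 0.15, n = 48) the group mean is within two standard
  errors of it (both are asserted in the test suite).
- **GC-slope.** Ordinary least squares of area on time; the trait is
  defined only as "the slope of the growth curve", and OLS is the neutral
  reading.
- **FG.** The last observed area.
- **GLI.** Computed at the final timepoint's mask, pixel-averaged. Black
  pixels (zero denominator) are excluded from the mean and counted; the
  pooling choice (final timepoint, per-pixel) is stated here because the
  trait's definition does not fix it.

A degenerate plant (nonpositive endpoint area) gets `rgr = NA` and a flag;
it is never silently dropped.

## The PBCI

Ratios are taken between group means, not averaged per-plant ratios —
plants are unpaired across groups, so per-plant ratios do not exist. A
nonpositive group mean (possible for GC-slope under severe stress) makes
that trait's log2 ratio undefined; the ratio is recorded as missing,
excluded from the sum, and the record carries the missing count, rather
than clamping to an arbitrary value. A PBCI of exactly zero is labelled
`neutral`; the sign rule otherwise maps positive values to
promoter/alleviator (by condition) and negative values to inductor. The
control scored against itself is exactly zero.

The bootstrap layer (percentile CI and sign stability from resampling
plants within groups) is an addition of this package — the index itself is
a point score — and is marked as such in its documentation.

## Statistical surface

- **AUC testing**: two-group Kruskal–Wallis rank tests of each treatment
  against its condition's control, flagged at p < 0.05 with no multiplicity
  correction by default (a `p_adjust_method` argument is available). This
  mirrors the per-treatment asterisks convention of growth bar charts.
- **Metabolites**: one-way ANOVA on ln-transformed concentrations across
  the seven treatment groups within each condition, then post hoc
  comparisons against control. Sources conflict on the post hoc test for
  this design (Duncan vs Tukey); Tukey HSD is the default because it
  controls the family-wise error rate, with Duncan's multiple range test
  available behind `posthoc = "duncan"` (implemented with the studentized
  range and protection level $\alpha_p = 1 - (1-\alpha)^{p-1}$). A two-way
  treatment × condition variant is provided separately. Zero-variance
  metabolites are flagged undefined, never reported significant.
- **PCA**: SVD of the centered, unit-variance-scaled matrix; variance
  fractions are $\sigma_k^2 / \sum \sigma^2$. Default input is the ln of
  group means (matching biplots of group symbols); a per-sample mode and an
  `extra` argument for appending growth variables are provided. Constant
  columns are dropped with a warning.
- **Correlations**: Pearson with two-sided t-distribution p-values;
  zero-variance variables give NA, not 0.
- **Heatmap**: ln of group means (n = 4 replicates by default), metabolite
  class blocks in rows, treatment × condition in columns, significance
  dots wired to the ANOVA output.

## Determinism and problem sizes

One global seed fans out into per-stage child seeds, so two runs of
`run_pipeline()` with the same configuration are byte-identical and any
stage can be reproduced in isolation; the run manifest records the
configuration and the derived seeds. The test suite exercises the
design-scale cases directly: 100-well segmentation recovery, 200 simulated
two-group experiments for PBCI sign behaviour (48 plants/group), and 2000
null simulations for the type-I error of each test; smaller fixtures are
used where a property is size-independent.

## Known limitations

- Segmentation is validated against the package's own renderer; equivalence
  with any specific laboratory's segmentation software cannot be claimed.
- The excess-green threshold assumes a non-green background; soil, algae or
  strong color casts would require the Otsu option or preprocessing.
- The PBCI weights all five traits equally and mixes slope-like and
  size-like components; no cross-condition composite is attempted.
- Metabolite simulation uses independent lognormal noise per metabolite;
  real metabolomic covariance structure (pathway correlation) is not
  emulated, so PCA on default synthetic tables shows no interesting
  low-dimensional structure unless effects are injected.
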