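---
title: "Eggshell pigments, colorimetry, and phylogenetic signal: methods and design"
author: "ovotrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eggshell pigments, colorimetry, and phylogenetic signal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovotrait)
```

## The scientific problem

Avian eggshells owe most of their visible colour to two tetrapyrrole
pigments: protoporphyrin IX (red-brown hues and spotting) and biliverdin
IXα (blue-green hues). Across a set of related species, pigment
concentrations are not independent observations — close relatives tend to
resemble each other — so any comparative question ("do cavity nesters lay
less pigmented eggs?", "do thicker shells carry more biliverdin?") must
model the phylogenetic covariance of the data. `ovotrait` implements the
full analysis chain for such a study:

1. **Colorimetry**: extract background colour (CIELAB) and maculation
   (percent dark pixels) from standardized egg photographs;
2. **Phylogenetic signal**: estimate Pagel's λ for each pigment by
   maximum likelihood, plus the repeatability (ICC) of replicate
   measurements and the Spearman correlation between per-mass and
   per-area concentration standardizations;
3. **Comparative regression**: phylogenetic generalized least squares
   (PGLS) of log10 pigment concentration on life-history/nesting
   covariates, with all-subsets AIC ranking, a 95% cumulative-weight
   confidence set of models, and model-averaged estimates.

Because real museum-egg measurements of this kind are not publicly
deposited, the package ships a first-class synthetic-data generator that
emulates the study conditions — 71 passerine species, 3 replicate eggs
each — with *known* ground truth, so every stage can be validated by
parameter recovery rather than by eye.

## Models

### Trait evolution and Pagel's λ

For a rooted ultrametric tree, the Brownian-motion (BM) covariance of a
trait across tips is `σ² V`, where `V[i, j]` is the shared root-to-MRCA
path length of tips *i* and *j*. Pagel's λ multiplies the off-diagonal of
`V`: λ = 1 is pure BM, λ = 0 is phylogenetic independence. The
log-likelihood is profiled analytically over the ancestral mean μ (GLS
mean) and the rate σ² (ML estimator, divisor *n*), leaving a 1-D profile
in λ that is maximized numerically over [0, 1].

`simulate_bm_traits()` draws from this model exactly, without matrix
factorization, via

```
x = μ + sqrt(λ) · b + sqrt(1 − λ) · e,
```

where `b` is a Brownian walk accumulated edge by edge and `e` is
tip-independent noise with variance `σ² · depth_i`. The identity
`Cov(x) = σ²(λ V_off + diag(V))` holds for every λ, including both
boundaries, and is verified entrywise against 6000 Monte-Carlo
replicates in the test suite.

### The pure-birth tree generator

`simulate_yule_tree()` simulates the constant-rate pure-birth process
forward in time: while `k` lineages exist, the waiting time to the next
speciation is exponential with rate `k·b`, and a uniformly chosen lineage
splits. The returned tree is observed through the epoch during which `n`
lineages exist — that is, including the final `Exp(n·b)` wait, which by
memorylessness is the residual lifetime of the *n*-lineage epoch. This
choice is deliberate: stopping exactly *at* the n-th speciation event
would give the final cherry two zero-length pendant edges almost surely,
making `V` at λ = 1 exactly singular and PGLS with λ = 1 undefined on
every simulated tree. With the epoch convention all pendant edges are
strictly positive, and the expected origin-to-tip height (stem included)
is `Σ_{k=1..n} 1/(k·b)`, which the tests verify against 1000 simulated
trees. The single-lineage stem is kept as `root.edge` and excluded from
`V`, as is conventional.

### The generating model of a study

`simulate_species_dataset()` composes the data-generating process the
analysis assumes:

- binary covariates (nest type, nest location, brood-parasitized) are BM
  liabilities thresholded at their median, so they carry phylogenetic
  signal and are always balanced;
- continuous covariates are scaled BM draws: log10 body mass
  (mean 1.25, SD 0.35 — about 3–300 g, a realistic passerine range),
  clutch size (4.5 ± 1.2 eggs, clipped to [1.5, 12]), shell thickness
  (0.09 ± 0.02 mm, clipped to [0.04, 0.2] mm);
- log10 pigment concentrations are a linear predictor in these covariates
  plus BM-structured error. Default coefficients are anchored to the
  model-averaged estimates the package is designed to emulate, e.g.
  +6.47 per **mm** of shell thickness on log10 biliverdin, +0.19 for
  open (vs cavity) nesting on log10 protoporphyrin, and cross-pigment
  terms of 0.36 / 0.43. Thickness is stored in µm in the trait table but
  modelled in mm: on the µm scale a coefficient of 6.47 would span
  hundreds of log10 units across the observed range, so mm is the only
  physically coherent reading of that value. Body mass is
  log10-transformed before fitting because it spans two orders of
  magnitude across passerines.

Two design points deserve emphasis because they determine what
"parameter recovery" can even mean:

- **Directed pigment equations.** The two reported cross-pigment
  estimates (protoporphyrin on biliverdin 0.36, and vice versa 0.43)
  cannot both be structural coefficients of one joint model — the system
  would be circular. The generator therefore builds one pigment from
  covariates only and adds `cross ×` that pigment to the other
  (`pigment_order` chooses the direction), so each generating coefficient
  is exactly the estimand of the corresponding PGLS fit.
- **Independent pigment residuals.** The default residual correlation
  between the two pigments' BM errors is 0. If the residuals were
  correlated, the co-pigment regressor would be endogenous and *no*
  regression would recover the generating cross term (we measured the
  bias: fitted 0.81 against a generating 0.36). The strong positive
  correlation between the pigments across species (typically ρ ≈ 0.5
  under the defaults) instead emerges from the cross-pigment effect and
  the shared covariates. `pigment_correlation` remains available for
  sensitivity analyses.

Replicate (within-species) measurements add i.i.d. Gaussian noise on the
log10 scale, with SD set from a target one-way ICC (default 0.7, between
the two repeatabilities the package emulates); the within-species
distribution of pigment concentrations is an assumption — nothing in the
emulated study constrains it. Per-area concentrations are per-mass values
times shell mass per area (thickness × a nominal density) with
multiplicative log-normal noise, which reproduces the near-unity Spearman
correlation between the two standardizations.

### Egg images

`render_egg_image()` draws an ovoid egg (an ellipse with a 12% taper,
broad end at lower x) in a requested CIELAB background colour on a
near-black ground, places small dark disks (radius 2–4 px) uniformly
within the egg until the ground-truth spot coverage reaches the target
(always within ±0.02, in practice within one spot's area), and adds
Gaussian pixel noise in linear RGB. The ground-truth masks describe the
pre-noise image exactly. The mild taper is load-bearing: a perfectly
symmetric ellipse has no detectable broad end, so "rotate by 180° and
re-orient" would be ill-defined and the rotation-invariance property of
the colorimetry pipeline untestable. Images are 16-bit TIFF (linear
RGB; masks as PNG); the reader accepts 8- or 16-bit PNG and TIFF and can
optionally decode sRGB gamma.

What the renderer deliberately does **not** emulate: shell texture,
gloss and iridescence, UV reflectance (birds are tetrachromats; this
package works in human-visible CIELAB only), camera optics, or
illumination gradients (an optional vignetting flag exists, default
off). Passing tests therefore demonstrate correctness of the *measurement
operators*, not robustness to real-world photographic nuisance.

### Colorimetry pipeline

Per image: (1) grayscale = Rec. 709 luminance of linear RGB; (2) Otsu's
threshold on a 256-bin histogram (ties toward the lowest threshold), the
brighter class is the egg; (3) the largest connected component is kept
and its interior holes filled — hole filling matters because heavily
maculated eggs have spots darker than the Otsu cut, and without it the
egg region would exclude exactly the pixels the maculation statistic
needs; (4) the pose is canonicalized: transpose if the mask's principal
axis is closer to vertical, mirror if the broader half lies at higher x,
and crop to the mask bounding box (+2 px) so that all later coordinates
are egg-relative — this is what makes the pipeline invariant to where
the egg sat on the canvas; (5) a circular subsample of one third of the
egg area (radius `sqrt(A/(3π))`) is centred at the mask centroid with
`midX → 0.88 · midX`, shifting it toward the broad end and away from the
rim where curvature distorts spots; overhang is clipped to the mask and
the achieved fraction recorded; (6) member pixels are converted to
CIELAB (Rec. 709 primaries, D65 reference white taken as the XYZ of
linear RGB (1,1,1) so white maps to L\* = 100 exactly); (7) k-means with
k = 2 on (L\*, a\*, b\*) separates maculated from background pixels:
initialization is deterministic (the min-L\* and max-L\* pixels),
Lloyd iterations run to a relative tolerance of 1e-8, and the
lower-L\* cluster is maculated — *unless* the converged centroids are
closer than 5 Lab units, in which case the shell is declared immaculate.
Without that separation rule, k = 2 on a homogeneous shell splits its own
pixel noise 50/50 and reports ~50% maculation on a spotless egg; 5 units
is far above the noise-induced centroid gap (~1 unit at the default
noise SD) and far below any real spot contrast (≥ 15 units).
(8) maculation % = maculated / members; background L\*a\*b\* mean and SD
over the non-maculated members; egg area = mask pixels × `pixel_scale²`
(a configured scale, not a detected scale bar).

### PGLS and multimodel inference

`fit_pgls()` is GLS with covariance `σ² V(λ)`: coefficients
`(XᵀV(λ)⁻¹X)⁻¹XᵀV(λ)⁻¹y` via a Cholesky whitening, σ² profiled (ML
divisor *n* for the likelihood; the bias-corrected divisor *n − p* for
coefficient standard errors), and λ either fixed or jointly ML-estimated
per model (each candidate gets its own λ̂; a flag fixes it instead).
`AIC = −2·logLik + 2k` with `k = p + 1` for fixed λ and `k = p + 2` when
λ is estimated — the convention matters for comparability and is
therefore explicit. AICc is available behind a flag; plain AIC is the
default to match the emulated analysis.

`pgls_model_average()` enumerates all subsets of the free predictors
(optionally with always-included terms; the life-history tables force
the co-pigment term into all 64 candidates from 6 free covariates),
ranks by AIC, forms Akaike weights, takes the smallest prefix of models
whose cumulative weight exceeds 0.95 (ties: fewer parameters first, then
enumeration order), renormalizes weights within that confidence set, and
averages **conditionally**: a predictor is averaged only over models
that contain it, which is the convention under which "N containing
models" and "relative variable importance" (the sum of set-renormalized
weights of containing models) are natural outputs. The unconditional
standard error uses the Burnham–Anderson form
`SE = Σ w̃ᵢ · sqrt(SEᵢ² + (βᵢ − β̄)²)`; intervals are normal
(±1.96·SE and ±1.645·SE), and an estimate is flagged significant when
the corresponding interval excludes zero — interval-based importance is
the only inferential rule; no multiple-testing adjustment is applied.
The intercept row is reported without an importance (it is in every
model by construction).

### λ estimation details

The profile is evaluated on a 21-point grid over [0, 1] including both
boundaries, then refined with `stats::optimize` (golden-section with
parabolic interpolation) to 1e-6 in the bracketing interval; the
reported λ̂ is the better of the grid and refined points, so it can never
fall below the grid maximum. The CI is the profile-likelihood set at the
χ²₁ cutoff (3.841/2 at 95%), found by root-bisection on each side and
truncated to [0, 1]. If `V(λ)` is numerically singular at an evaluation
point (possible at λ = 1 on trees with effectively duplicated tips), the
likelihood there is treated as −∞ and estimation proceeds on the rest of
the interval; a star tree (no shared history at all) is detected up
front and reported as unidentifiable with λ̂ = 0. The dense Cholesky
likelihood is exact and entirely adequate at the problem sizes this
package targets (tens to a few hundred tips); no pruning algorithm is
used.

ICC repeatability uses the one-way ANOVA estimator with the
harmonic-mean-adjusted replicate count, clips negative estimates to 0,
and reports 5th/95th percentile bootstrap intervals over species
(default 2000 resamples). Spearman's ρ is the Pearson correlation of
average ranks.

## Problem sizes and reproducibility

Everything is seeded: one master seed per simulated dataset, split
deterministically across the tree / covariate / pigment / replicate /
image sub-generators, so changing image settings never perturbs trait
draws, and identical configurations are bit-identical. The test suite
chooses sizes that keep the full run under a minute while leaving
comfortable Monte-Carlo margins: 1000 trees for the height expectation,
5–6000 replicates for the covariance law, 100 traits on a 71-tip tree
for λ recovery (median λ̂ at the BM boundary; median ≤ 0.05 for i.i.d.
traits), a 4 × 4 background-colour × spot-coverage grid at the default
400 × 300 px canvas for colorimetry recovery (maculation within ±3
percentage points of the rendered ground truth inside the subsample,
background L\*a\*b\* within ±2 units), and 2 × 100 simulated studies for
coverage of the generating regression coefficients (≥ 90% at nominal
95%). Pipeline tests run 12–16 species with 2 replicates at reduced
canvas sizes.

## Known limitations

- The generator's Gaussian-on-log10 within-species noise and
  median-threshold liabilities are modelling conveniences, not
  biological claims.
- Colorimetry assumes one egg per image on a dark ground, linear-RGB
  input, and a configured pixel scale; arbitrary-angle deskewing is not
  performed (canonicalization handles axis swaps and mirror flips
  exactly, which covers 90°/180° rotations).
- Conditional model averaging is reported; zero-substitution (full-model)
  averaging is not implemented.
- Binary covariates simulated at small `n_species` can occasionally
  produce identical partitions; the resulting rank-deficient design is a
  named error rather than a silent drop.
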