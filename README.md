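# ovotrait

Eggshell colorimetry and phylogenetic comparative analysis of eggshell
pigments, for comparative biologists studying why egg colour varies
across bird species.

Avian eggshell colour is driven by two pigments — protoporphyrin IX
(red-brown hues and spotting) and biliverdin IXα (blue-green hues) — and
across related species neither the pigments nor the ecological traits
that might explain them are independent observations: close relatives
resemble each other. `ovotrait` implements the complete analysis chain
for a multispecies eggshell-pigment study:

- **Image colorimetry.** Each egg photograph (linear RGB, PNG/TIFF) is
  segmented by Otsu's threshold (the cut maximizing between-class
  variance of the gray histogram), a circular subsample of one third of
  the egg area is placed at the mask centroid with the centre shifted
  toward the broad end (`midX → 0.88·midX`, avoiding rim pixels distorted
  by shell curvature), pixels are converted to CIELAB (L\*, a\*, b\*),
  and k-means (k = 2) separates maculated (dark) from background pixels.
  Outputs per image: background L\*a\*b\* mean and SD, maculation %, and
  egg area in mm².
- **Phylogenetic signal.** For a trait `x` on a tree with
  Brownian-motion covariance `V` (shared root-to-ancestor path lengths),
  Pagel's λ scales the off-diagonal of `V`; `estimate_lambda()` maximizes
  the profile likelihood of `σ²·V(λ)` over λ ∈ [0, 1] and reports a
  profile-likelihood CI. Repeatability of replicate measurements
  (one-way ICC with species bootstrap) and Spearman's ρ between per-mass
  and per-area concentrations round out the signal stage.
- **PGLS with multimodel inference.** `fit_pgls()` fits
  `β̂ = (XᵀV(λ)⁻¹X)⁻¹ XᵀV(λ)⁻¹ y` with λ jointly ML-estimated per model;
  `pgls_model_average()` enumerates all predictor subsets, ranks by AIC,
  keeps the smallest set of models whose cumulative Akaike weight
  exceeds 0.95, and reports conditionally model-averaged estimates with
  Burnham–Anderson unconditional SEs, 95%/90% CIs, relative variable
  importance, and N containing models.
- **Synthetic data with ground truth.** Because studies of this kind are
  built on museum material that is not publicly deposited, the package
  ships a generator (`sim_config()`, `simulate_species_dataset()`,
  `render_egg_image()`) that emulates the study design — 71 species,
  3 replicate eggs each, pigments evolving with strong phylogenetic
  signal, covariate effects anchored to published model-averaged
  estimates — including rendered egg images with exact ground-truth
  masks. Every stage is validated by recovering what the generator put
  in.

## Worked example

Estimate phylogenetic signal in a simulated 71-species study, measure a
rendered egg, and build a life-history model-averaged table:

```r
library(ovotrait)

cfg <- sim_config(seed = 11)                  # 71 species x 3 replicates
ds  <- simulate_species_dataset(cfg)

x <- setNames(ds$species$proto_log10_ugg, ds$species$species)
estimate_lambda(x, ds$tree)
#> Pagel's lambda = 0.988 [95% CI 0.941, 1.000], sigma2 = 0.03751, logLik = 11.430 (n = 71)
```

The traits were simulated at λ = 1; the estimate sits at the Brownian
boundary with a CI that covers it. Measuring one rendered egg
(background L\*a\*b\* = (70, 5, 18), 20% spot coverage):

```r
b <- render_egg_image(c(70, 5, 18), maculation_fraction = 0.2, seed = 1)
process_egg_image(b)
#>   image_id   L_mean      L_sd   a_mean      a_sd   b_mean     b_sd
#> 1     <NA> 69.99649 0.2624905 5.001447 0.6413505 17.99312 0.747139
#>   maculation_pct egg_area_mm2 subsample_fraction
#> 1        22.6966       408.82          0.3334475
```

Background colour is recovered to within a few hundredths of a CIELAB
unit; the maculation percentage matches the ground-truth spot fraction
inside the subsample (spots are placed uniformly over the egg, so the
interior subsample runs slightly above the egg-wide 20% target — the
ground-truth masks confirm it). Finally, the life-history analysis —
log10 protoporphyrin on six life-history covariates with the biliverdin
term always included (64 candidate models):

```r
d  <- dataset_to_analysis_frame(ds)   # see vignette; thickness in mm
ms <- pgls_model_average(
  "proto_log10_ugg",
  c("nest_location", "parasitized", "nest_type", "log10_body_mass",
    "clutch_size", "thickness_mm"),
  d, ds$tree, always_include = "bili_log10_ugg")
ms
#> All-subsets PGLS for 'proto_log10_ugg': 64 candidate models,
#>   13 in the 95% confidence set (AIC)
#>            term estimate    se ci95_low ci95_high importance n_containing_models
#>  bili_log10_ugg    0.450 0.110    0.234     0.666      1.000                  13
#>   nest_typeopen    0.141 0.030    0.082     0.200      1.000                  13
#>     clutch_size   -0.114 0.027   -0.166    -0.062      1.000                  13
#>             ...
```

The generating coefficients (cross-pigment 0.36, open nesting +0.19,
clutch −0.09) fall inside their 95% intervals. `run_pipeline()` chains
all stages (simulate → colorimetry → signal → pgls → report) from a YAML
config and writes CSV tables, a markdown report with the 95%/90%
significance conventions, and a checksummed JSON manifest; a thin CLI
wrapper lives at `inst/cli/ovotrait.R`.

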