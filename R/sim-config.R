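#' Simulation configuration for a synthetic eggshell-pigment study
#'
#' Bundles every parameter of the synthetic-data generator: tree size and
#' speciation rate, strength of phylogenetic signal, Brownian rate and
#' correlation of the two pigment concentrations (log10 micrograms per gram
#' of eggshell), the generating regression coefficients that link pigments
#' to life-history/nesting covariates, the target repeatability of
#' replicate measurements, and the egg-image rendering parameters.
#'
#' Defaults mirror the study conditions the package emulates: 71 species
#' with 3 replicate eggs each, both pigments evolving with full
#' phylogenetic signal (`lambda_true = 1`), and covariate coefficients
#' anchored to the model-averaged estimates of the reference analysis
#' (e.g. eggshell thickness 6.47 per mm on log10 biliverdin, nest type
#' 0.19 on log10 protoporphyrin, cross-pigment terms 0.36 / 0.43).
#'
#' @param seed Master integer seed; sub-generators (tree, covariates,
#'   pigments, replicates, images) draw from independently derived streams.
#' @param n_species Number of species (>= 3; default 71).
#' @param n_replicates Replicate eggs per species (default 3).
#' @param birth_rate Speciation rate of the simulated pure-birth tree.
#' @param lambda_true Pagel's lambda of simulated traits, in `[0, 1]`.
#' @param sigma2 Brownian rate of the pigment residuals
#'   (log10 units squared per unit branch length).
#' @param pigment_correlation Innovation correlation of the two pigments'
#'   Brownian *residuals*, in `(-1, 1)`. Default 0: the pigments'
#'   positive correlation then comes from the cross-pigment effect and the
#'   shared covariates, and every generating coefficient remains the
#'   estimand of the matching PGLS fit (a nonzero residual correlation
#'   makes the co-pigment regressor endogenous).
#' @param pigment_order Which pigment is generated first (the second
#'   receives `cross` times the first): `"biliverdin_first"` or
#'   `"protoporphyrin_first"`.
#' @param proto_effects,bili_effects Named lists of generating
#'   coefficients (`intercept`, `cross`, `nest_type` (open vs cavity),
#'   `nest_location` (off ground vs ground), `parasitized` (yes vs no),
#'   `log10_body_mass`, `clutch_size`, `thickness_mm`). Partial lists
#'   override the defaults.
#' @param icc_target Target intraclass correlation of replicate
#'   measurements within species, in `(0, 1)`; sets the within-species
#'   noise SD on the log10 scale.
#' @param area_noise_sd SD of the multiplicative (log10) noise linking
#'   per-mass to per-area concentrations.
#' @param canvas Image canvas as `c(width, height)` in pixels.
#' @param pixel_scale Physical size of a pixel (mm per pixel).
#' @param maculation_fraction Dataset-level baseline spot coverage in
#'   `[0, 1]`; a species' realized fraction scales with its
#'   protoporphyrin level.
#' @param noise_sd SD of Gaussian pixel noise added to rendered images
#'   (linear RGB units).
#' @return An object of class `ovo_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_species = 10, n_replicates = 2)
#' @export
sim_config <- function(seed = 1L,
                       n_species = 71L,
                       n_replicates = 3L,
                       birth_rate = 1,
                       lambda_true = 1,
                       sigma2 = 0.03,
                       pigment_correlation = 0,
                       pigment_order = c("biliverdin_first",
                                         "protoporphyrin_first"),
                       proto_effects = list(),
                       bili_effects = list(),
                       icc_target = 0.7,
                       area_noise_sd = 0.05,
                       canvas = c(400L, 300L),
                       pixel_scale = 0.1,
                       maculation_fraction = 0.15,
                       noise_sd = 0.005) {
  pigment_order <- match.arg(pigment_order)
  proto_default <- list(intercept = 1.65, cross = 0.36,
                        nest_location = 0.002, parasitized = 0.11,
                        nest_type = 0.19, log10_body_mass = -0.28,
                        clutch_size = -0.09, thickness_mm = 2.29)
  bili_default <- list(intercept = -0.71, cross = 0.43,
                       nest_location = -0.15, parasitized = -0.11,
                       nest_type = 0.03, log10_body_mass = 0.28,
                       clutch_size = 0.06, thickness_mm = 6.47)
  bad_p <- setdiff(names(proto_effects), names(proto_default))
  bad_b <- setdiff(names(bili_effects), names(bili_default))
  if (length(bad_p) || length(bad_b)) {
    stop("unknown effect name(s): ",
         paste(c(bad_p, bad_b), collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_species = as.integer(n_species),
    n_replicates = as.integer(n_replicates),
    birth_rate = birth_rate,
    lambda_true = lambda_true,
    sigma2 = sigma2,
    pigment_correlation = pigment_correlation,
    pigment_order = pigment_order,
    proto_effects = modifyList(proto_default, proto_effects),
    bili_effects = modifyList(bili_default, bili_effects),
    icc_target = icc_target,
    area_noise_sd = area_noise_sd,
    canvas = as.integer(canvas),
    pixel_scale = pixel_scale,
    maculation_fraction = maculation_fraction,
    noise_sd = noise_sd)
  validate_config(cfg)
  class(cfg) <- "ovo_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    "n_species must be >= 3" = cfg$n_species >= 3,
    "n_replicates must be >= 1" = cfg$n_replicates >= 1,
    "birth_rate must be > 0" = cfg$birth_rate > 0,
    "lambda_true must lie in [0, 1]" =
      cfg$lambda_true >= 0 && cfg$lambda_true <= 1,
    "sigma2 must be >= 0" = cfg$sigma2 >= 0,
    "pigment_correlation must lie in (-1, 1)" =
      abs(cfg$pigment_correlation) < 1,
    "icc_target must lie in (0, 1)" =
      cfg$icc_target > 0 && cfg$icc_target < 1,
    "canvas must be two positive integers" =
      length(cfg$canvas) == 2 && all(cfg$canvas >= 32),
    "pixel_scale must be > 0" = cfg$pixel_scale > 0,
    "maculation_fraction must lie in [0, 1]" =
      cfg$maculation_fraction >= 0 && cfg$maculation_fraction <= 1,
    "noise_sd must be >= 0" = cfg$noise_sd >= 0)
  invisible(cfg)
}

#' @export
print.ovo_config <- function(x, ...) {
  cat("Synthetic eggshell-study configuration\n")
  cat(sprintf("  %d species x %d replicates, birth rate %g, seed %d\n",
              x$n_species, x$n_replicates, x$birth_rate, x$seed))
  cat(sprintf("  lambda = %g, sigma2 = %g, pigment correlation = %g (%s)\n",
              x$lambda_true, x$sigma2, x$pigment_correlation,
              x$pigment_order))
  cat(sprintf("  images: %dx%d px, %g mm/px, baseline maculation %g\n",
              x$canvas[1], x$canvas[2], x$pixel_scale,
              x$maculation_fraction))
  invisible(x)
}
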