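#' Simulate a complete synthetic eggshell-pigment study
#'
#' Composes the generating model the downstream analysis assumes:
#' a pure-birth phylogeny; binary nesting covariates obtained by
#' thresholding Brownian liabilities at their median (so covariates carry
#' phylogenetic signal and both levels are always present); continuous
#' covariates (log10 body mass, clutch size, shell thickness) from scaled
#' Brownian draws; log10 pigment concentrations equal to a linear
#' predictor in the covariates plus Brownian-structured error (the two
#' pigments' errors correlated at `pigment_correlation`); replicate
#' (within-species) Gaussian noise on the log10 scale calibrated to the
#' target repeatability `icc_target`; and per-area concentrations derived
#' from per-mass values through shell thickness with multiplicative noise.
#'
#' One pigment is generated first from covariates only and the other adds
#' `cross` times the first (`pigment_order`), so every generating
#' coefficient is a well-defined estimand of the corresponding PGLS fit.
#'
#' Egg images are *parameterized* here (one row per species x replicate,
#' with the background CIELAB colour and target spot coverage driven by
#' the species' pigment levels via [pigment_to_lab()]) and rendered lazily
#' by [render_dataset_images()] or [render_egg_image()], so large datasets
#' need not hold hundreds of images in memory.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `ovo_dataset` with elements `tree` (phylo),
#'   `traits` (one row per species x replicate), `species` (ground-truth
#'   species-level values), `image_params` (one row per image), and
#'   `config`.
#' @examples
#' d <- simulate_species_dataset(sim_config(seed = 1, n_species = 10,
#'                                          n_replicates = 2))
#' head(d$traits)
#' @export
simulate_species_dataset <- function(config) {
  stopifnot(inherits(config, "ovo_config"))
  validate_config(config)
  cfg <- config
  n <- cfg$n_species
  tree <- simulate_yule_tree(n, cfg$birth_rate, derive_seed(cfg$seed, 1L))
  sp <- tree$tip.label

  # --- covariates --------------------------------------------------------
  cov_bm <- simulate_bm_traits(tree, sigma2 = 1, lambda = cfg$lambda_true,
                               n_traits = 6L, seed = derive_seed(cfg$seed, 2L))
  z <- apply(cov_bm, 2L, function(v) (v - mean(v)) / max(sd(v), 1e-12))
  nest_type <- factor(ifelse(z[, 1] > median(z[, 1]), "open", "cavity"),
                      levels = c("cavity", "open"))
  nest_location <- factor(ifelse(z[, 2] > median(z[, 2]), "off_ground",
                                 "ground"),
                          levels = c("ground", "off_ground"))
  parasitized <- factor(ifelse(z[, 3] > median(z[, 3]), "yes", "no"),
                        levels = c("no", "yes"))
  for (v in list(nest_type, nest_location, parasitized)) {
    if (nlevels(droplevels(v)) < 2L) {
      warning("a binary covariate came out single-level; ",
              "median thresholding should prevent this")
    }
  }
  log10_body_mass <- 1.25 + 0.35 * z[, 4]
  body_mass_g <- 10^log10_body_mass
  clutch_size <- round(pmin(pmax(4.5 + 1.2 * z[, 5], 1.5), 12), 1)
  thickness_mm <- pmin(pmax(0.09 + 0.02 * z[, 6], 0.04), 0.2)

  # --- species-level pigments -------------------------------------------
  err <- simulate_bm_traits(tree, sigma2 = cfg$sigma2,
                            lambda = cfg$lambda_true, n_traits = 2L,
                            correlation = cfg$pigment_correlation,
                            seed = derive_seed(cfg$seed, 3L))
  lp <- function(e) {
    e$intercept +
      e$nest_type * (nest_type == "open") +
      e$nest_location * (nest_location == "off_ground") +
      e$parasitized * (parasitized == "yes") +
      e$log10_body_mass * log10_body_mass +
      e$clutch_size * clutch_size +
      e$thickness_mm * thickness_mm
  }
  if (cfg$pigment_order == "biliverdin_first") {
    bili <- lp(cfg$bili_effects) + err[, 1]
    proto <- lp(cfg$proto_effects) + cfg$proto_effects$cross * bili + err[, 2]
  } else {
    proto <- lp(cfg$proto_effects) + err[, 1]
    bili <- lp(cfg$bili_effects) + cfg$bili_effects$cross * proto + err[, 2]
  }
  names(proto) <- names(bili) <- sp

  species <- data.frame(
    species = sp, proto_log10_ugg = as.numeric(proto),
    bili_log10_ugg = as.numeric(bili),
    eggshell_thickness_um = thickness_mm * 1000,
    clutch_size = clutch_size, body_mass_g = body_mass_g,
    nest_type = nest_type, nest_location = nest_location,
    parasitized = parasitized, row.names = NULL)

  # --- replicate eggs ----------------------------------------------------
  k <- cfg$n_replicates
  sw_p <- sd(proto) * sqrt((1 - cfg$icc_target) / cfg$icc_target)
  sw_b <- sd(bili) * sqrt((1 - cfg$icc_target) / cfg$icc_target)
  traits <- with_seed(derive_seed(cfg$seed, 4L), {
    idx <- rep(seq_len(n), each = k)
    rep_p <- proto[idx] + rnorm(n * k, 0, sw_p)
    rep_b <- bili[idx] + rnorm(n * k, 0, sw_b)
    # per-area concentration: per-mass value times shell mass per area
    # (thickness x nominal density), with multiplicative noise
    la_p <- rep_p + log10(0.002 * thickness_mm[idx] * 1000) +
      rnorm(n * k, 0, cfg$area_noise_sd)
    la_b <- rep_b + log10(0.002 * thickness_mm[idx] * 1000) +
      rnorm(n * k, 0, cfg$area_noise_sd)
    data.frame(
      species = sp[idx], replicate = rep(seq_len(k), times = n),
      proto_log10_ugg = rep_p, bili_log10_ugg = rep_b,
      proto_area_ugmm2 = 10^la_p, bili_area_ugmm2 = 10^la_b,
      eggshell_thickness_um = thickness_mm[idx] * 1000,
      clutch_size = clutch_size[idx], body_mass_g = body_mass_g[idx],
      nest_type = nest_type[idx], nest_location = nest_location[idx],
      parasitized = parasitized[idx], row.names = NULL)
  })

  # --- image parameters --------------------------------------------------
  zp <- (proto - mean(proto)) / max(sd(proto), 1e-12)
  zb <- (bili - mean(bili)) / max(sd(bili), 1e-12)
  lab <- pigment_to_lab(zp, zb)
  frac <- maculation_from_pigment(zp, cfg$maculation_fraction)
  image_params <- data.frame(
    image_id = sprintf("%s_r%02d", traits$species, traits$replicate),
    species = traits$species, replicate = traits$replicate,
    background_L = lab[traits$species, "L"],
    background_a = lab[traits$species, "a"],
    background_b = lab[traits$species, "b"],
    maculation_fraction = frac[traits$species],
    seed = vapply(seq_len(nrow(traits)),
                  function(i) derive_seed(cfg$seed, 100L + i), integer(1)),
    row.names = NULL)

  structure(list(tree = tree, traits = traits, species = species,
                 image_params = image_params, config = cfg),
            class = "ovo_dataset")
}

#' Map standardized pigment levels to an egg background colour
#'
#' The default colour model of the synthetic generator: higher
#' protoporphyrin darkens the background (lower L*) and pushes it toward
#' red-brown (higher a*); higher biliverdin darkens it and pushes it
#' toward green (lower a*). The mapping is monotone in each argument, with
#' clipping to a comfortably in-gamut CIELAB box.
#'
#' @param z_proto,z_bili Standardized (z-score) log10 pigment
#'   concentrations.
#' @return Matrix with columns `L`, `a`, `b` and one row per species.
#' @export
pigment_to_lab <- function(z_proto, z_bili) {
  out <- cbind(L = pmin(pmax(72 - 7 * z_proto - 5 * z_bili, 40), 88),
               a = pmin(pmax(4 + 5 * z_proto - 6 * z_bili, -12), 20),
               b = pmin(pmax(16 + 3 * z_proto, 2), 30))
  rownames(out) <- names(z_proto)
  out
}

# Species maculation target: logistic in the protoporphyrin z-score,
# equal to the configured baseline at z = 0, capped at the renderer's
# packable limit.
maculation_from_pigment <- function(z_proto, baseline) {
  f <- 2 * baseline * stats::plogis(1.3 * z_proto)
  out <- pmin(pmax(f, 0), 0.6)
  names(out) <- names(z_proto)
  out
}

#' Render and write every egg image of a dataset
#'
#' Streams one [render_egg_image()] bundle at a time to `dir` via
#' [write_egg_bundle()], so memory use is one image regardless of dataset
#' size.
#'
#' @param dataset An `ovo_dataset`.
#' @param dir Output directory.
#' @return (Invisibly) a character vector of all files written.
#' @export
render_dataset_images <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ovo_dataset"))
  cfg <- dataset$config
  files <- character(0)
  for (i in seq_len(nrow(dataset$image_params))) {
    p <- dataset$image_params[i, ]
    b <- render_egg_image(c(p$background_L, p$background_a, p$background_b),
                          maculation_fraction = p$maculation_fraction,
                          pixel_scale = cfg$pixel_scale,
                          canvas = cfg$canvas, seed = p$seed,
                          noise_sd = cfg$noise_sd)
    files <- c(files, write_egg_bundle(b, dir, p$image_id))
  }
  invisible(files)
}

#' @export
print.ovo_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic eggshell dataset: %d species x %d replicates (seed %d)\n",
    x$config$n_species, x$config$n_replicates, x$config$seed))
  cat(sprintf("  tree height %.3f; pigment order: %s\n",
              tree_height(x$tree), x$config$pigment_order))
  cat(sprintf("  log10 protoporphyrin range [%.2f, %.2f]; ",
              min(x$species$proto_log10_ugg), max(x$species$proto_log10_ugg)))
  cat(sprintf("log10 biliverdin range [%.2f, %.2f]\n",
              min(x$species$bili_log10_ugg), max(x$species$bili_log10_ugg)))
  invisible(x)
}

#' Write a dataset to disk in portable formats
#'
#' Writes the tree as newick, the replicate-level and species-level trait
#' tables as CSV, the configuration as flat key-value YAML, and (optionally)
#' all egg images with their ground-truth masks.
#'
#' @param dataset An `ovo_dataset`.
#' @param dir Output directory (created if needed).
#' @param label File-name stem for the dataset files.
#' @param images Render and write the egg images too.
#' @return (Invisibly) a character vector of files written.
#' @export
write_dataset <- function(dataset, dir, label = "dataset", images = TRUE) {
  stopifnot(inherits(dataset, "ovo_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_tree <- file.path(dir, paste0(label, "_tree.nwk"))
  f_traits <- file.path(dir, paste0(label, "_traits.csv"))
  f_species <- file.path(dir, paste0(label, "_species.csv"))
  f_imgpar <- file.path(dir, paste0(label, "_image_params.csv"))
  f_cfg <- file.path(dir, paste0(label, "_config.yaml"))
  ape::write.tree(dataset$tree, f_tree)
  write.csv(dataset$traits, f_traits, row.names = FALSE)
  write.csv(dataset$species, f_species, row.names = FALSE)
  write.csv(dataset$image_params, f_imgpar, row.names = FALSE)
  yaml::write_yaml(flatten_config(dataset$config), f_cfg)
  files <- c(f_tree, f_traits, f_species, f_imgpar, f_cfg)
  if (images) {
    files <- c(files,
               render_dataset_images(dataset, file.path(dir, "images")))
  }
  invisible(files)
}

# flat key-value view of a config (dotted keys for the effect lists)
flatten_config <- function(cfg) {
  out <- list()
  for (nm in names(unclass(cfg))) {
    v <- cfg[[nm]]
    if (is.list(v)) {
      for (k in names(v)) out[[paste(nm, k, sep = ".")]] <- v[[k]]
    } else if (length(v) > 1L) {
      for (i in seq_along(v)) out[[paste(nm, i, sep = ".")]] <- v[[i]]
    } else out[[nm]] <- v
  }
  out
}

#' Species-mean analysis frame from a simulated dataset
#'
#' Builds the species-level `data.frame` the PGLS stage operates on:
#' ground-truth log10 pigment concentrations, shell thickness converted
#' to mm, log10 body mass, clutch size, and the three binary covariates,
#' with species as rownames (matching the tree's tip labels).
#'
#' @param dataset An `ovo_dataset`.
#' @return A `data.frame` with one row per species.
#' @export
dataset_to_analysis_frame <- function(dataset) {
  stopifnot(inherits(dataset, "ovo_dataset"))
  sp <- dataset$species
  data.frame(
    proto_log10_ugg = sp$proto_log10_ugg,
    bili_log10_ugg = sp$bili_log10_ugg,
    thickness_mm = sp$eggshell_thickness_um / 1000,
    clutch_size = sp$clutch_size,
    log10_body_mass = log10(sp$body_mass_g),
    nest_type = sp$nest_type,
    nest_location = sp$nest_location,
    parasitized = sp$parasitized,
    row.names = sp$species)
}
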