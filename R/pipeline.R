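# Pipeline orchestration: simulate -> colorimetry -> signal -> pgls ->
# report, with a YAML run configuration, per-stage outputs, and a JSON
# manifest carrying content checksums for reproducibility.

run_option_defaults <- function() {
  list(label = "synthetic", render_images = TRUE, icc_boot = 2000L,
       threshold = 0.95, srgb_gamma = FALSE)
}

#' Read and validate a pipeline run configuration
#'
#' The file is flat key-value YAML. Keys are either [sim_config()]
#' arguments (effect lists as dotted keys, e.g. `proto_effects.cross`;
#' `canvas.1` / `canvas.2` for the canvas) or run options: `label`
#' (file-name stem), `render_images`, `icc_boot` (bootstrap resamples for
#' the repeatability ICC), `threshold` (cumulative Akaike weight of the
#' model confidence set), `srgb_gamma` (decode sRGB gamma when reading
#' images). Unknown keys are an error, not a warning.
#'
#' @param path YAML file path.
#' @return List with elements `config` (an `ovo_config`) and `options`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  opts <- run_option_defaults()
  sim_args <- list()
  known_sim <- names(formals(sim_config))
  for (key in names(raw)) {
    base <- strsplit(key, ".", fixed = TRUE)[[1]][1]
    if (base %in% names(opts)) {
      opts[[base]] <- raw[[key]]
    } else if (base %in% known_sim) {
      if (grepl(".", key, fixed = TRUE)) {
        sub <- strsplit(key, ".", fixed = TRUE)[[1]][2]
        if (base %in% c("proto_effects", "bili_effects")) {
          sim_args[[base]][[sub]] <- raw[[key]]
        } else {   # positional vector component, e.g. canvas.1
          idx <- suppressWarnings(as.integer(sub))
          if (is.na(idx)) stop("bad config key: ", key, call. = FALSE)
          v <- sim_args[[base]] %||% numeric(0)
          v[idx] <- raw[[key]]
          sim_args[[base]] <- v
        }
      } else {
        sim_args[[key]] <- raw[[key]]
      }
    } else {
      stop("unknown config key: ", key, call. = FALSE)
    }
  }
  list(config = do.call(sim_config, sim_args), options = opts)
}

stage_error <- function(stage, out_dir, label, e) {
  marker <- file.path(out_dir, sprintf("%s_FAILED_%s", label, stage))
  writeLines(conditionMessage(e), marker)
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

pipeline_paths <- function(out_dir, label) {
  p <- function(suffix) file.path(out_dir, paste0(label, "_", suffix))
  list(tree = p("tree.nwk"), traits = p("traits.csv"),
       species = p("species.csv"), image_params = p("image_params.csv"),
       config = p("config.yaml"), images = file.path(out_dir, "images"),
       colorimetry = p("colorimetry.csv"), signal = p("signal.csv"),
       table1_proto = p("table1_protoporphyrin.csv"),
       table1_bili = p("table1_biliverdin.csv"),
       table2_proto = p("table2_protoporphyrin.csv"),
       table2_bili = p("table2_biliverdin.csv"),
       report = p("report.md"), manifest = p("manifest.json"))
}

#' Run the full synthetic-study pipeline
#'
#' Stages: `simulate` (write tree, trait tables, optionally all egg
#' images), `colorimetry` (per-image background CIELAB / maculation /
#' area), `signal` (Pagel's lambda, repeatability ICC and the per-mass vs
#' per-area Spearman correlation for both pigments), `pgls` (the
#' colorimetrics and life-history model-averaged PGLS tables), `report`
#' (human-readable summary), and a JSON manifest with an md5 checksum of
#' every output file. Stages can be re-run individually against an
#' existing output directory; any stage failure leaves a
#' `<label>_FAILED_<stage>` marker and raises an error naming the stage.
#'
#' @param config Path to a YAML run config, or the list returned by
#'   [read_run_config()], or an `ovo_config` (default run options then
#'   apply).
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run, in pipeline order.
#' @return (Invisibly) the manifest as a list.
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 1, n_species = 10, n_replicates = 2,
#'                   canvas = c(160, 120))
#' run_pipeline(cfg, file.path(tempdir(), "ovorun"))
#' }
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "colorimetry", "signal",
                                    "pgls", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config)) config <- read_run_config(config)
  if (inherits(config, "ovo_config")) {
    config <- list(config = config, options = run_option_defaults())
  }
  cfg <- config$config
  opts <- utils::modifyList(run_option_defaults(), config$options)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(out_dir, opts$label)
  for (st in stages) {      # clear stale failure markers for re-run stages
    marker <- file.path(out_dir, sprintf("%s_FAILED_%s", opts$label, st))
    if (file.exists(marker)) file.remove(marker)
  }

  if ("simulate" %in% stages) {
    tryCatch({
      dataset <- simulate_species_dataset(cfg)
      write_dataset(dataset, out_dir, label = opts$label,
                    images = isTRUE(opts$render_images))
    }, error = function(e) stage_error("simulate", out_dir, opts$label, e))
  }
  if ("colorimetry" %in% stages && isTRUE(opts$render_images)) {
    tryCatch(stage_colorimetry(paths, cfg, opts),
             error = function(e) stage_error("colorimetry", out_dir,
                                             opts$label, e))
  }
  if ("signal" %in% stages) {
    tryCatch(stage_signal(paths, cfg, opts),
             error = function(e) stage_error("signal", out_dir, opts$label, e))
  }
  if ("pgls" %in% stages) {
    tryCatch(stage_pgls(paths, cfg, opts),
             error = function(e) stage_error("pgls", out_dir, opts$label, e))
  }
  if ("report" %in% stages) {
    tryCatch(write_report(out_dir, label = opts$label),
             error = function(e) stage_error("report", out_dir, opts$label, e))
  }
  manifest <- build_manifest(out_dir, cfg, opts, paths)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_colorimetry <- function(paths, cfg, opts) {
  imgs <- list.files(paths$images, pattern = "\\.tif$", full.names = TRUE)
  if (!length(imgs)) stop("no rendered images found in ", paths$images)
  rows <- lapply(imgs, process_egg_image, pixel_scale = cfg$pixel_scale,
                 srgb_gamma = isTRUE(opts$srgb_gamma))
  out <- do.call(rbind, rows)
  params <- read.csv(paths$image_params)
  out <- merge(params[, c("image_id", "species", "replicate")], out,
               by = "image_id", sort = TRUE)
  write.csv(out, paths$colorimetry, row.names = FALSE)
  invisible(out)
}

stage_signal <- function(paths, cfg, opts) {
  tree <- suppressWarnings(ape::read.tree(paths$tree))
  if (is.null(tree)) stop("could not parse newick tree: ", paths$tree)
  traits <- read.csv(paths$traits)
  sp_mean <- function(col) {
    tapply(traits[[col]], traits$species, mean)[tree$tip.label]
  }
  rows <- lapply(list(
    list(trait = "protoporphyrin", mass = "proto_log10_ugg",
         area = "proto_area_ugmm2"),
    list(trait = "biliverdin", mass = "bili_log10_ugg",
         area = "bili_area_ugmm2")), function(tr) {
      x <- sp_mean(tr$mass)
      lam <- estimate_lambda(x, tree)
      icc <- repeatability_icc(traits[[tr$mass]], traits$species,
                               n_boot = opts$icc_boot,
                               seed = derive_seed(cfg$seed, 7L))
      rho <- spearman_rho(x, sp_mean(tr$area))
      data.frame(trait = tr$trait, lambda_hat = lam$lambda,
                 ci_low = lam$ci[1], ci_high = lam$ci[2],
                 sigma2_hat = lam$sigma2, mu_hat = lam$mu,
                 loglik = lam$loglik, icc = icc$icc, icc_p5 = icc$p5,
                 icc_p95 = icc$p95, spearman_mass_area = rho)
    })
  out <- do.call(rbind, rows)
  write.csv(out, paths$signal, row.names = FALSE)
  invisible(out)
}

# Species-mean analysis table: pigments + life-history covariates
# (thickness in mm, body mass log10-transformed), plus measured
# colorimetrics when the colorimetry stage has run.
species_table <- function(paths, tree) {
  traits <- read.csv(paths$traits, stringsAsFactors = TRUE)
  agg <- function(col) tapply(traits[[col]], traits$species, mean)
  first <- function(col) {
    tapply(as.character(traits[[col]]), traits$species, `[`, 1L)
  }
  d <- data.frame(
    proto_log10_ugg = agg("proto_log10_ugg"),
    bili_log10_ugg = agg("bili_log10_ugg"),
    thickness_mm = agg("eggshell_thickness_um") / 1000,
    clutch_size = agg("clutch_size"),
    log10_body_mass = log10(agg("body_mass_g")),
    nest_type = factor(first("nest_type"), levels = c("cavity", "open")),
    nest_location = factor(first("nest_location"),
                           levels = c("ground", "off_ground")),
    parasitized = factor(first("parasitized"), levels = c("no", "yes")))
  if (file.exists(paths$colorimetry)) {
    cm <- read.csv(paths$colorimetry)
    for (col in c("L_mean", "a_mean", "b_mean", "maculation_pct")) {
      d[[col]] <- tapply(cm[[col]], cm$species, mean)[rownames(d)]
    }
  }
  d[tree$tip.label, , drop = FALSE]
}

write_modavg_csv <- function(ms, path) {
  df <- as.data.frame(ms$averaged)
  names(df)[names(df) == "term"] <- "predictor"
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

stage_pgls <- function(paths, cfg, opts) {
  tree <- suppressWarnings(ape::read.tree(paths$tree))
  if (is.null(tree)) stop("could not parse newick tree: ", paths$tree)
  d <- species_table(paths, tree)
  life <- c("nest_location", "parasitized", "nest_type", "log10_body_mass",
            "clutch_size", "thickness_mm")
  t2p <- pgls_model_average("proto_log10_ugg", life, d, tree,
                            always_include = "bili_log10_ugg",
                            threshold = opts$threshold)
  t2b <- pgls_model_average("bili_log10_ugg", life, d, tree,
                            always_include = "proto_log10_ugg",
                            threshold = opts$threshold)
  write_modavg_csv(t2p, paths$table2_proto)
  write_modavg_csv(t2b, paths$table2_bili)
  if (all(c("L_mean", "a_mean", "b_mean", "maculation_pct") %in% names(d))) {
    colm <- c("L_mean", "a_mean", "b_mean", "maculation_pct")
    t1p <- pgls_model_average("proto_log10_ugg", colm, d, tree,
                              threshold = opts$threshold)
    t1b <- pgls_model_average("bili_log10_ugg", colm, d, tree,
                              threshold = opts$threshold)
    write_modavg_csv(t1p, paths$table1_proto)
    write_modavg_csv(t1b, paths$table1_bili)
  }
  invisible(NULL)
}

#' Write the human-readable pipeline report
#'
#' Summarizes the signal stage (lambda with profile CIs, repeatability
#' ICCs with bootstrap percentiles, per-mass vs per-area Spearman rho) and
#' the model-averaged tables, bolding estimates whose 95% CI excludes zero
#' and marking with `*` those significant at 90% only.
#'
#' @param out_dir Pipeline output directory.
#' @param label Run label (file-name stem).
#' @return (Invisibly) the report path.
#' @export
write_report <- function(out_dir, label = "synthetic") {
  paths <- pipeline_paths(out_dir, label)
  if (!file.exists(paths$signal)) {
    stop("missing signal stage output: ", paths$signal, call. = FALSE)
  }
  sig <- read.csv(paths$signal)
  lines <- c(sprintf("# Eggshell pigment analysis report (%s)", label), "",
             "## Phylogenetic signal and repeatability", "")
  for (i in seq_len(nrow(sig))) {
    r <- sig[i, ]
    lines <- c(lines, sprintf(
      "- %s: lambda = %.2f [%.3f, %.3f]; ICC = %.2f [5th, 95th: %.2f, %.2f]; Spearman rho (per-mass vs per-area) = %.3f",
      r$trait, r$lambda_hat, r$ci_low, r$ci_high, r$icc, r$icc_p5, r$icc_p95,
      r$spearman_mass_area))
  }
  fmt_table <- function(path, title) {
    if (!file.exists(path)) return(character(0))
    tb <- read.csv(path)
    hdr <- c("", sprintf("## %s", title), "",
             "| Predictor | Estimate (95% CI) | Importance | N models |",
             "|---|---|---|---|")
    body <- vapply(seq_len(nrow(tb)), function(i) {
      r <- tb[i, ]
      est <- sprintf("%.3f (%.3f, %.3f)", r$estimate, r$ci95_low, r$ci95_high)
      if (isTRUE(r$significant_95)) est <- paste0("**", est, "**")
      else if (isTRUE(r$significant_90)) est <- paste0(est, " \\*")
      sprintf("| %s | %s | %s | %s |", r$predictor, est,
              ifelse(is.na(r$importance), "", sprintf("%.2f", r$importance)),
              ifelse(is.na(r$n_containing_models), "",
                     r$n_containing_models))
    }, character(1))
    c(hdr, body)
  }
  lines <- c(lines,
             fmt_table(paths$table1_proto,
                       "Colorimetrics on protoporphyrin"),
             fmt_table(paths$table1_bili,
                       "Colorimetrics on biliverdin"),
             fmt_table(paths$table2_proto,
                       "Life history and nesting ecology on protoporphyrin"),
             fmt_table(paths$table2_bili,
                       "Life history and nesting ecology on biliverdin"),
             "", "Bold: 95% CI excludes zero. \\*: 90% CI excludes zero.")
  writeLines(lines, paths$report)
  invisible(paths$report)
}

build_manifest <- function(out_dir, cfg, opts, paths) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("_manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  names(sums) <- sub("^/", "", sub(normalizePath(out_dir), "",
                                   normalizePath(files), fixed = TRUE))
  list(package = "ovotrait",
       version = as.character(packageVersion("ovotrait")),
       seed = cfg$seed,
       config = flatten_config(cfg),
       options = opts,
       checksums = as.list(sums))
}
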