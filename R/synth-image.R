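#' Render a synthetic egg image with ground-truth masks
#'
#' Draws an ovoid egg (a mildly tapered ellipse, long axis horizontal,
#' blunt end at lower x so the broad end is detectable by the
#' colorimetry pose canonicalization) in a requested uniform background
#' colour on a near-black ground, then adds randomly placed
#' dark circular spots until the ground-truth spot coverage (spot pixels /
#' egg pixels) reaches the requested maculation fraction, and finally adds
#' Gaussian pixel noise in linear RGB. The returned ground-truth masks
#' describe the image *before* noise injection exactly.
#'
#' Spots are small (radius 2-4 px) so coverage can be controlled finely;
#' the achieved fraction always lies within +-0.02 of the target (in
#' practice within +0.002, the area of one spot).
#'
#' @param background_lab Egg background colour as a CIELAB triple (must be
#'   inside the linear-RGB gamut).
#' @param maculation_fraction Target spot coverage of the egg, in
#'   `[0, 0.65]`; larger values exceed the packable limit and error.
#' @param pixel_scale Physical pixel size (mm per pixel), recorded for
#'   area computations.
#' @param canvas `c(width, height)` in pixels.
#' @param seed Optional integer seed (bit-reproducible rendering).
#' @param noise_sd SD of Gaussian pixel noise (linear RGB units).
#' @param spot_lab Spot colour (CIELAB); default is the background darkened
#'   by 28 L* units and shifted toward red-brown.
#' @param vignette If `TRUE`, darken the egg toward its rim (off by
#'   default; the circular subsample excludes rim pixels anyway).
#' @return An object of class `ovo_egg_bundle`: `image` (h x w x 3 linear
#'   RGB in `[0, 1]`), `egg_mask` and `spot_mask` (logical h x w,
#'   `spot_mask` a subset of `egg_mask`), and `params` (generating
#'   parameters including the achieved spot fraction).
#' @examples
#' b <- render_egg_image(c(70, 5, 18), maculation_fraction = 0.2,
#'                       canvas = c(120, 90), seed = 1)
#' b$params$achieved_fraction
#' @export
render_egg_image <- function(background_lab, maculation_fraction = 0,
                             pixel_scale = 0.1, canvas = c(400L, 300L),
                             seed = NULL, noise_sd = 0.005,
                             spot_lab = NULL, vignette = FALSE) {
  stopifnot(length(background_lab) == 3L, length(canvas) == 2L)
  if (!is.numeric(maculation_fraction) || maculation_fraction < 0 ||
      maculation_fraction > 1) {
    stop("`maculation_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (maculation_fraction > 0.65) {
    stop("maculation_fraction ", maculation_fraction,
         " exceeds the packable spot coverage (0.65)", call. = FALSE)
  }
  w <- as.integer(canvas[1]); h <- as.integer(canvas[2])
  shell_rgb <- as.vector(lab_to_rgb(background_lab))
  if (is.null(spot_lab)) {
    spot_lab <- c(max(background_lab[1] - 28, 8),
                  background_lab[2] + 8, background_lab[3] + 6)
  }
  spot_rgb <- as.vector(lab_to_rgb(spot_lab, clip = TRUE))
  dark_rgb <- as.vector(lab_to_rgb(c(2, 0, 0)))

  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  ax <- 0.37 * w; by <- 0.30 * h
  taper <- 0.12                       # mild ovoid taper; blunt end at low x
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  u <- (xs - cx) / ax
  egg_mask <- u^2 + ((ys - cy) / (by * (1 - taper * u)))^2 <= 1
  n_egg <- sum(egg_mask)

  with_seed(seed, {
    spot_mask <- matrix(FALSE, h, w)
    if (maculation_fraction > 0) {
      egg_idx <- which(egg_mask)
      count <- 0L
      iter <- 0L
      while (count / n_egg < maculation_fraction) {
        iter <- iter + 1L
        if (iter > 50000L) {
          stop("spot coverage ", maculation_fraction,
               " unreachable within the egg region", call. = FALSE)
        }
        ctr <- egg_idx[sample.int(n_egg, 1L)]
        x0 <- ((ctr - 1L) %/% h) + 1L
        y0 <- ((ctr - 1L) %% h) + 1L
        r <- runif(1, 2, 4)
        xr <- max(1L, x0 - 4L):min(w, x0 + 4L)
        yr <- max(1L, y0 - 4L):min(h, y0 + 4L)
        disk <- outer(yr - y0, xr - x0, function(dy, dx) dy^2 + dx^2) <= r^2
        new <- disk & egg_mask[yr, xr, drop = FALSE] &
          !spot_mask[yr, xr, drop = FALSE]
        spot_mask[yr, xr] <- spot_mask[yr, xr, drop = FALSE] | new
        count <- count + sum(new)
      }
    }
    img <- array(rep(dark_rgb, each = h * w), c(h, w, 3L))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[egg_mask] <- shell_rgb[ch]
      plane[spot_mask] <- spot_rgb[ch]
      img[, , ch] <- plane
    }
    if (vignette) {
      d2 <- ((xs - cx) / ax)^2 + ((ys - cy) / by)^2
      fac <- 1 - 0.25 * pmax(d2 - 0.6, 0) / 0.4
      for (ch in 1:3) img[, , ch] <- img[, , ch] * ifelse(egg_mask, fac, 1)
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- pmin(pmax(img, 0), 1)
    structure(list(
      image = img, egg_mask = egg_mask, spot_mask = spot_mask,
      params = list(background_lab = as.numeric(background_lab),
                    spot_lab = as.numeric(spot_lab),
                    maculation_target = maculation_fraction,
                    achieved_fraction = sum(spot_mask) / n_egg,
                    pixel_scale = pixel_scale, canvas = c(w, h),
                    noise_sd = noise_sd, vignette = vignette,
                    seed = seed)),
      class = "ovo_egg_bundle")
  })
}

#' @export
print.ovo_egg_bundle <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic egg image %dx%d px (%g mm/px): background L*a*b* = (%.1f, %.1f, %.1f), spot coverage %.3f (target %.3f)\n",
    p$canvas[1], p$canvas[2], p$pixel_scale, p$background_lab[1],
    p$background_lab[2], p$background_lab[3], p$achieved_fraction,
    p$maculation_target))
  invisible(x)
}

#' Write an egg-image bundle to disk
#'
#' The rendered image is written as 16-bit TIFF (linear RGB), the
#' ground-truth masks as PNG, and the generating parameters as a flat
#' key-value YAML file.
#'
#' @param bundle An `ovo_egg_bundle`.
#' @param dir Output directory (created if needed).
#' @param id File-name stem.
#' @return (Invisibly) the named character vector of files written.
#' @export
write_egg_bundle <- function(bundle, dir, id) {
  stopifnot(inherits(bundle, "ovo_egg_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(image = file.path(dir, paste0(id, ".tif")),
             egg_mask = file.path(dir, paste0(id, "_egg_mask.png")),
             spot_mask = file.path(dir, paste0(id, "_spot_mask.png")),
             params = file.path(dir, paste0(id, "_params.yaml")))
  tiff::writeTIFF(bundle$image, files[["image"]], bits.per.sample = 16L)
  png::writePNG(bundle$egg_mask * 1, files[["egg_mask"]])
  png::writePNG(bundle$spot_mask * 1, files[["spot_mask"]])
  p <- bundle$params
  flat <- list(background_L = p$background_lab[1],
               background_a = p$background_lab[2],
               background_b = p$background_lab[3],
               spot_L = p$spot_lab[1], spot_a = p$spot_lab[2],
               spot_b = p$spot_lab[3],
               maculation_target = p$maculation_target,
               achieved_fraction = p$achieved_fraction,
               pixel_scale = p$pixel_scale,
               canvas_width = p$canvas[1], canvas_height = p$canvas[2],
               noise_sd = p$noise_sd, seed = p$seed %||% NA)
  yaml::write_yaml(flat, files[["params"]])
  invisible(files)
}

#' Read an egg image from PNG or TIFF
#'
#' Returns an `h x w x 3` linear-RGB array in `[0, 1]`. Grayscale input is
#' replicated across channels; an alpha channel is dropped. Set
#' `srgb_gamma = TRUE` for images stored with the sRGB transfer curve
#' (they are decoded to linear RGB).
#'
#' @param path Image file (`.png`, `.tif` or `.tiff`).
#' @param srgb_gamma Decode the sRGB gamma curve to linear RGB.
#' @return Numeric array `h x w x 3`.
#' @export
read_egg_image <- function(path, srgb_gamma = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (srgb_gamma) {
    img <- ifelse(img <= 0.04045, img / 12.92, ((img + 0.055) / 1.055)^2.4)
  }
  img
}
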