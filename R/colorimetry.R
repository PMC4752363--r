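# Image colorimetry pipeline: partition the image into egg and background
# by Otsu's threshold on a grayscale version, select a circular subsample
# of one third of the egg area shifted toward the broad end
# (midX -> 0.88 * midX), convert to CIELAB, split maculated from
# background pixels with k = 2 clustering, and summarize background
# colour, maculation percentage and egg area.

#' Histogram of gray values
#'
#' Equal-width bin counts over `[0, 1]`, the input expected by
#' [compute_otsu_threshold()].
#'
#' @param gray Numeric vector or matrix of gray values in `[0, 1]`.
#' @param n_bins Number of bins (default 256).
#' @return Object of class `ovo_histogram`: list with `counts` (length
#'   `n_bins`) and `breaks` (length `n_bins + 1`).
#' @export
gray_histogram <- function(gray, n_bins = 256L) {
  g <- as.numeric(gray)
  stopifnot(all(is.finite(g)))
  g <- pmin(pmax(g, 0), 1)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(floor(g * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = counts, breaks = breaks), class = "ovo_histogram")
}

#' Otsu's threshold from a gray-value histogram
#'
#' Returns the bin boundary that maximizes the between-class variance
#' (equivalently minimizes the intraclass variance) of the two-class
#' partition; ties are broken toward the lowest such threshold. A
#' histogram whose mass falls in a single bin has no two-class partition
#' and is an error.
#'
#' @param histogram An `ovo_histogram` from [gray_histogram()], or a plain
#'   vector of per-bin counts (breaks then assumed equally spaced on
#'   `[0, 1]`).
#' @return The threshold (a bin boundary in `[0, 1]`); pixels strictly
#'   above it form the brighter class.
#' @examples
#' h <- gray_histogram(c(rep(0.2, 50), rep(0.8, 50)))
#' compute_otsu_threshold(h)
#' @export
compute_otsu_threshold <- function(histogram) {
  if (inherits(histogram, "ovo_histogram")) {
    counts <- as.numeric(histogram$counts)
    breaks <- histogram$breaks
  } else {
    counts <- as.numeric(histogram)
    breaks <- seq(0, 1, length.out = length(counts) + 1L)
  }
  nb <- length(counts)
  if (sum(counts > 0) < 2L) {
    stop("degenerate histogram: fewer than two occupied bins", call. = FALSE)
  }
  mids <- (breaks[-1] + breaks[-(nb + 1L)]) / 2
  total <- sum(counts)
  w1 <- cumsum(counts)[-nb]                 # class sizes for cut after bin t
  s1 <- cumsum(counts * mids)[-nb]
  w2 <- total - w1
  mu_all <- sum(counts * mids) / total
  ok <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, nb - 1L)
  bcv[ok] <- (mu_all * w1[ok] - s1[ok])^2 / (w1[ok] * w2[ok])
  best <- which.max(bcv)                    # which.max takes the first max
  breaks[best + 1L]
}

#' Segment the egg from the image background
#'
#' Computes the Rec. 709 luminance of the linear-RGB image, thresholds it
#' with [compute_otsu_threshold()] (the brighter class is the egg), keeps
#' the largest connected foreground component and fills its interior
#' holes, so that dark maculation spots remain part of the egg region.
#'
#' @param image `h x w x 3` linear-RGB array (values in `[0, 1]`).
#' @param pixel_scale Physical pixel size (mm per pixel), stored in the
#'   mask for area computations.
#' @param n_bins Histogram resolution for the threshold.
#' @return Object of class `ovo_egg_mask`: logical matrix `mask`, the
#'   `threshold` used, `pixel_scale`, and `area_mm2` (foreground pixels
#'   times `pixel_scale^2`).
#' @export
segment_egg <- function(image, pixel_scale = 0.1, n_bins = 256L) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  gray <- rgb_luminance(image)
  thr <- compute_otsu_threshold(gray_histogram(gray, n_bins))
  fg <- gray > thr
  if (!any(fg)) stop("empty foreground after thresholding", call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask) > 0
  structure(list(mask = mask, threshold = thr, pixel_scale = pixel_scale,
                 area_mm2 = sum(mask) * pixel_scale^2),
            class = "ovo_egg_mask")
}

#' Rotate and crop an egg image to the canonical pose
#'
#' The colorimetry pipeline assumes eggs lie long-axis horizontal with the
#' broad end at lower x (so the 0.88 centroid shift moves toward the broad
#' end). This helper transposes the image when the mask's principal axis
#' is closer to vertical, mirrors it when the broader half (larger mask
#' area about the centroid) sits at higher x, and crops to the mask
#' bounding box plus a small margin so that coordinates are egg-relative
#' (making the pipeline invariant to where the egg sat on the canvas).
#' All operations are exact pixel permutations; no resampling occurs.
#'
#' @param image `h x w x 3` linear-RGB array.
#' @param mask An `ovo_egg_mask` from [segment_egg()].
#' @param margin Crop margin in pixels.
#' @return List with the transformed `image`, `mask` (an `ovo_egg_mask`)
#'   and `ops`, the character vector of operations applied.
#' @export
canonicalize_egg <- function(image, mask, margin = 2L) {
  stopifnot(inherits(mask, "ovo_egg_mask"))
  m <- mask$mask
  ops <- character(0)
  pix <- which(m, arr.ind = TRUE)
  cy <- mean(pix[, 1]); cx <- mean(pix[, 2])
  dy <- pix[, 1] - cy; dx <- pix[, 2] - cx
  # principal axis from second moments of the foreground
  cov <- matrix(c(mean(dx^2), mean(dx * dy), mean(dx * dy), mean(dy^2)), 2)
  v <- eigen(cov, symmetric = TRUE)$vectors[, 1]
  if (abs(v[2]) > abs(v[1])) {
    image <- aperm(image, c(2, 1, 3))
    m <- t(m)
    ops <- c(ops, "transpose")
    pix <- which(m, arr.ind = TRUE)
    cx <- mean(pix[, 2])
  }
  # broad end to lower x: mirror if the half right of the centroid is larger
  if (sum(pix[, 2] > cx) > sum(pix[, 2] < cx)) {
    image <- image[, rev(seq_len(ncol(m))), , drop = FALSE]
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    ops <- c(ops, "mirror_x")
    pix <- which(m, arr.ind = TRUE)
  }
  rr <- range(pix[, 1]); cc <- range(pix[, 2])
  rows <- max(1L, rr[1] - margin):min(nrow(m), rr[2] + margin)
  cols <- max(1L, cc[1] - margin):min(ncol(m), cc[2] + margin)
  image <- image[rows, cols, , drop = FALSE]
  m <- m[rows, cols, drop = FALSE]
  ops <- c(ops, sprintf("crop[%d:%d,%d:%d]", min(rows), max(rows),
                        min(cols), max(cols)))
  new_mask <- structure(list(mask = m, threshold = mask$threshold,
                             pixel_scale = mask$pixel_scale,
                             area_mm2 = sum(m) * mask$pixel_scale^2),
                        class = "ovo_egg_mask")
  list(image = image, mask = new_mask, ops = ops)
}

#' Select the circular one-third-area subsample
#'
#' Places a circle of area equal to one third of the egg area at the mask
#' centroid, with the centre x-coordinate replaced by 0.88 times the
#' centroid x (shifting the circle toward the broad end and away from the
#' shell rim, where curvature distorts spot shapes and brightness). Member
#' pixels are the circle clipped to the egg mask; the achieved fraction of
#' egg area is recorded and a warning is given if clipping pushed it more
#' than 0.02 from one third.
#'
#' @param mask An `ovo_egg_mask`.
#' @return Object of class `ovo_subsample`: `center` (x, y in pixel
#'   coordinates, x rightward, origin top-left), `radius` (px), `members`
#'   (logical matrix of member pixels), `fraction` (members / egg pixels).
#' @export
select_subsample <- function(mask) {
  stopifnot(inherits(mask, "ovo_egg_mask"))
  m <- mask$mask
  if (!any(m)) stop("empty egg mask", call. = FALSE)
  pix <- which(m, arr.ind = TRUE)
  mid_x <- mean(pix[, 2]); mid_y <- mean(pix[, 1])
  cx <- 0.88 * mid_x
  r <- sqrt(sum(m) / (3 * pi))
  xs <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  ys <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  circle <- (xs - cx)^2 + (ys - mid_y)^2 <= r^2
  members <- circle & m
  fraction <- sum(members) / sum(m)
  if (abs(fraction - 1 / 3) > 0.02) {
    warning(sprintf(
      "subsample clipped by the egg mask: %.3f of egg area instead of 1/3",
      fraction))
  }
  structure(list(center = c(x = cx, y = mid_y), radius = r,
                 members = members, fraction = fraction,
                 centroid = c(x = mid_x, y = mid_y)),
            class = "ovo_subsample")
}

#' Classify subsample pixels as maculated or background
#'
#' k-means (k = 2) on the CIELAB coordinates with deterministic
#' initialization (the minimum- and maximum-L* pixels) and Lloyd
#' iterations to a relative tolerance of 1e-8. The cluster with the lower
#' centroid L* is labelled maculated. If the two converged centroids are
#' closer than `min_separation` (Euclidean distance in Lab), the egg is
#' declared immaculate and all pixels are background — without this rule
#' any homogeneous shell would be split in half by its own pixel noise.
#'
#' @param lab_pixels `n x 3` matrix of CIELAB pixels.
#' @param k Number of clusters (fixed at 2).
#' @param min_separation Minimum centroid distance for a genuine
#'   maculated/background split (Lab units).
#' @return List: `maculated` (logical per pixel), `centroids` (`k x 3`),
#'   `separation` (centroid distance), `iterations`.
#' @export
classify_maculation <- function(lab_pixels, k = 2L, min_separation = 5) {
  stopifnot(is.matrix(lab_pixels), ncol(lab_pixels) == 3L)
  if (k != 2L) stop("only k = 2 is supported", call. = FALSE)
  n <- nrow(lab_pixels)
  if (nrow(unique(lab_pixels)) < k) {
    warning("fewer than 2 distinct pixels; all labelled background")
    return(list(maculated = rep(FALSE, n),
                centroids = rbind(colMeans(lab_pixels), colMeans(lab_pixels)),
                separation = 0, iterations = 0L))
  }
  ctr <- rbind(lab_pixels[which.min(lab_pixels[, 1]), ],
               lab_pixels[which.max(lab_pixels[, 1]), ])
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- (lab_pixels[, 1] - ctr[1, 1])^2 + (lab_pixels[, 2] - ctr[1, 2])^2 +
      (lab_pixels[, 3] - ctr[1, 3])^2
    d2 <- (lab_pixels[, 1] - ctr[2, 1])^2 + (lab_pixels[, 2] - ctr[2, 2])^2 +
      (lab_pixels[, 3] - ctr[2, 3])^2
    grp <- d2 < d1
    new_ctr <- ctr
    if (any(!grp)) new_ctr[1, ] <- colMeans(lab_pixels[!grp, , drop = FALSE])
    if (any(grp)) new_ctr[2, ] <- colMeans(lab_pixels[grp, , drop = FALSE])
    shift <- max(abs(new_ctr - ctr)) / max(1, max(abs(ctr)))
    ctr <- new_ctr
    if (shift < 1e-8 || it >= 200L) break
  }
  sep <- sqrt(sum((ctr[1, ] - ctr[2, ])^2))
  low <- which.min(ctr[, 1])                # darker cluster = maculated
  maculated <- if (low == 1L) !grp else grp
  if (sep < min_separation) maculated <- rep(FALSE, n)
  list(maculated = maculated, centroids = unname(ctr), separation = sep,
       iterations = it)
}

#' Summarize the colorimetrics of one egg image
#'
#' Maculation percentage (dark pixels among subsample members), mean and
#' standard deviation of the background (non-maculated) pixels' L*, a*,
#' b*, and the egg area from the full mask.
#'
#' @param region An `ovo_subsample`.
#' @param maculated Logical vector over region members (from
#'   [classify_maculation()]).
#' @param lab_pixels CIELAB matrix of region members, same order.
#' @param mask The full `ovo_egg_mask`.
#' @return One-row `data.frame`: `L_mean`, `L_sd`, `a_mean`, `a_sd`,
#'   `b_mean`, `b_sd`, `maculation_pct`, `egg_area_mm2`,
#'   `subsample_fraction`.
#' @export
summarize_colorimetrics <- function(region, maculated, lab_pixels, mask) {
  stopifnot(inherits(region, "ovo_subsample"), inherits(mask, "ovo_egg_mask"))
  n <- sum(region$members)
  if (length(maculated) != n || nrow(lab_pixels) != n) {
    stop("labels/pixels do not cover the subsample members", call. = FALSE)
  }
  if (all(maculated)) {
    stop("no background pixels in the subsample; cannot summarize",
         call. = FALSE)
  }
  bg <- lab_pixels[!maculated, , drop = FALSE]
  data.frame(
    L_mean = mean(bg[, 1]), L_sd = sd(bg[, 1]),
    a_mean = mean(bg[, 2]), a_sd = sd(bg[, 2]),
    b_mean = mean(bg[, 3]), b_sd = sd(bg[, 3]),
    maculation_pct = 100 * sum(maculated) / n,
    egg_area_mm2 = mask$area_mm2,
    subsample_fraction = region$fraction)
}

#' Run the full colorimetry pipeline on one image
#'
#' Segment, canonicalize, subsample, convert to CIELAB, classify
#' maculation, summarize. Accepts a file path (PNG/TIFF), a rendered
#' [render_egg_image()] bundle, or a raw image array.
#'
#' @param image File path, `ovo_egg_bundle`, or `h x w x 3` array.
#' @param pixel_scale mm per pixel.
#' @param srgb_gamma Decode sRGB gamma when reading from file.
#' @param min_separation Passed to [classify_maculation()].
#' @param white Reference white for the CIELAB conversion.
#' @return One-row `data.frame` as [summarize_colorimetrics()], plus an
#'   `image_id` column when reading from file.
#' @examples
#' b <- render_egg_image(c(70, 5, 18), 0.2, canvas = c(120, 90), seed = 1)
#' process_egg_image(b)
#' @export
process_egg_image <- function(image, pixel_scale = 0.1, srgb_gamma = FALSE,
                              min_separation = 5, white = d65_white()) {
  id <- NA_character_
  if (is.character(image)) {
    id <- tools::file_path_sans_ext(basename(image))
    image <- read_egg_image(image, srgb_gamma = srgb_gamma)
  } else if (inherits(image, "ovo_egg_bundle")) {
    pixel_scale <- image$params$pixel_scale
    image <- image$image
  }
  mask <- segment_egg(image, pixel_scale = pixel_scale)
  can <- canonicalize_egg(image, mask)
  region <- select_subsample(can$mask)
  lab <- rgb_to_lab(pixel_rows(can$image, region$members), white = white)
  cls <- classify_maculation(lab, min_separation = min_separation)
  out <- summarize_colorimetrics(region, cls$maculated, lab, can$mask)
  cbind(data.frame(image_id = id), out)
}

# Extract the member pixels of a logical matrix from an image array as an
# n x 3 matrix (row order = column-major order of `which(members)`).
pixel_rows <- function(image, members) {
  idx <- which(members)
  cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
}
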