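test_that("Otsu threshold separates two well-separated classes", {
  h <- gray_histogram(c(rep(0.2, 50), rep(0.8, 50)))
  thr <- compute_otsu_threshold(h)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
})

test_that("Otsu operator equals brute-force between-class maximization", {
  set.seed(42)
  for (i in 1:100) {
    nb <- sample(c(8, 16, 32, 64), 1)
    counts <- rpois(nb, lambda = sample(1:50, 1))
    if (sum(counts > 0) < 2) counts[c(1, nb)] <- c(5, 7)
    breaks <- seq(0, 1, length.out = nb + 1)
    expect_equal(compute_otsu_threshold(counts),
                 brute_otsu(counts, breaks), tolerance = 1e-12)
  }
})

test_that("degenerate histograms are rejected", {
  expect_error(compute_otsu_threshold(gray_histogram(rep(0.5, 100))),
               "degenerate")
  img <- array(0.5, c(20, 30, 3))
  expect_error(segment_egg(img), "degenerate")
})

test_that("segmentation recovers a bright ellipse on a dark ground", {
  b <- render_egg_image(c(75, 3, 14), maculation_fraction = 0,
                        canvas = c(200, 150), seed = 5)
  m <- segment_egg(b$image, pixel_scale = 0.1)
  iou <- sum(m$mask & b$egg_mask) / sum(m$mask | b$egg_mask)
  expect_gte(iou, 0.99)
  expect_equal(m$area_mm2, sum(m$mask) * 0.1^2)
})

test_that("the subsample centre follows the 0.88 centroid shift", {
  # rectangular mask with a known centroid, far from edges so the circle
  # is unclipped
  mk <- matrix(FALSE, 200, 260)
  mk[60:140, 60:200] <- TRUE                   # centroid x = 130, y = 100
  mask <- structure(list(mask = mk, threshold = 0.5, pixel_scale = 0.1,
                         area_mm2 = sum(mk) * 0.01),
                    class = "ovo_egg_mask")
  reg <- select_subsample(mask)
  expect_equal(unname(reg$center["x"]), 0.88 * 130, tolerance = 1e-9)
  expect_equal(unname(reg$center["y"]), 100, tolerance = 1e-9)
  expect_equal(unname(reg$radius), sqrt(sum(mk) / (3 * pi)), tolerance = 1e-12)
})

test_that("the subsample covers one third of a large centred egg", {
  b <- render_egg_image(c(70, 2, 10), 0, canvas = c(400, 300), seed = 6)
  m <- segment_egg(b$image)
  reg <- select_subsample(m)
  expect_lt(abs(reg$fraction - 1 / 3), 0.02)
  expect_true(all(reg$members <= m$mask))
})

test_that("an overhanging circle is clipped to the mask with a warning", {
  mk <- matrix(FALSE, 60, 300)
  mk[5:55, 3:290] <- TRUE        # thin strip: the circle cannot fit
  mask <- structure(list(mask = mk, threshold = 0.5, pixel_scale = 0.1,
                         area_mm2 = sum(mk) * 0.01),
                    class = "ovo_egg_mask")
  expect_warning(reg <- select_subsample(mask), "clipped")
  expect_true(all(reg$members <= mk))
  expect_lt(reg$fraction, 1 / 3)
})

test_that("CIELAB conversion matches the CIE formulas and convertColor", {
  expect_equal(as.vector(rgb_to_lab(matrix(c(1, 1, 1), 1))),
               c(100, 0, 0), tolerance = 1e-6)
  expect_equal(rgb_to_lab(matrix(c(0, 0, 0), 1))[1, "L"], c(L = 0),
               tolerance = 1e-9)
  gray <- rgb_to_lab(matrix(0.18, 1, 3))
  expect_equal(unname(gray[1, "L"]), 116 * 0.18^(1 / 3) - 16,
               tolerance = 1e-6)
  expect_equal(unname(gray[1, c("a", "b")]), c(0, 0), tolerance = 1e-6)
  # independent route: grDevices converts XYZ -> Lab with a D65 white
  set.seed(1)
  px <- matrix(runif(30, 0.05, 0.95), ncol = 3)
  ours <- rgb_to_lab(px)
  xyz <- px %*% t(ovotrait:::RGB_TO_XYZ)
  ref <- grDevices::convertColor(xyz, from = "XYZ", to = "Lab",
                                 to.ref.white = "D65")
  expect_equal(unname(ours), unname(ref), tolerance = 0.05)
  expect_warning(rgb_to_lab(matrix(c(1.2, 0.5, 0.5), 1)), "clipped")
})

test_that("CIELAB round-trips through its inverse", {
  set.seed(2)
  lab <- cbind(runif(20, 45, 85), runif(20, -8, 12), runif(20, 4, 22))
  back <- rgb_to_lab(lab_to_rgb(lab))
  expect_equal(unname(back), unname(lab), tolerance = 1e-6)
})

test_that("k-means recovers constructed clusters exactly", {
  set.seed(3)
  a <- cbind(rnorm(300, 30, 0.5), rnorm(300, 10, 0.5), rnorm(300, 5, 0.5))
  b <- cbind(rnorm(200, 70, 0.5), rnorm(200, 2, 0.5), rnorm(200, 15, 0.5))
  px <- rbind(a, b)
  cls <- classify_maculation(px)
  expect_equal(cls$maculated, rep(c(TRUE, FALSE), c(300, 200)))
  # converged centroids are the cluster means
  expect_equal(cls$centroids[order(cls$centroids[, 1]), ],
               rbind(colMeans(a), colMeans(b)), tolerance = 1e-9)
  # independent route: stats::kmeans from the same deterministic start
  init <- rbind(px[which.min(px[, 1]), ], px[which.max(px[, 1]), ])
  km <- stats::kmeans(px, centers = init, algorithm = "Lloyd",
                      iter.max = 200)
  expect_equal(unname(cls$centroids), unname(km$centers), tolerance = 1e-6)
})

test_that("pixel order does not change the k-means labels", {
  set.seed(4)
  px <- rbind(cbind(rnorm(150, 25), rnorm(150, 8), rnorm(150, 4)),
              cbind(rnorm(150, 65), rnorm(150, 1), rnorm(150, 12)))
  cls <- classify_maculation(px)
  perm <- sample(nrow(px))
  cls_p <- classify_maculation(px[perm, ])
  expect_equal(cls_p$maculated, cls$maculated[perm])
})

test_that("homogeneous pixels are never split into spurious maculation", {
  set.seed(5)
  px <- cbind(rnorm(500, 70, 0.5), rnorm(500, 4, 0.5), rnorm(500, 15, 0.5))
  cls <- classify_maculation(px)
  expect_false(any(cls$maculated))
  expect_lt(cls$separation, 5)
  expect_warning(cls2 <- classify_maculation(matrix(1, 10, 3)), "distinct")
  expect_false(any(cls2$maculated))
})

test_that("summaries require a background and report the egg area", {
  b <- render_egg_image(c(68, 6, 12), 0.2, canvas = c(200, 150), seed = 7)
  m <- segment_egg(b$image)
  reg <- select_subsample(m)
  lab <- rgb_to_lab(ovotrait:::pixel_rows(b$image, reg$members))
  cls <- classify_maculation(lab)
  s <- summarize_colorimetrics(reg, cls$maculated, lab, m)
  expect_equal(s$egg_area_mm2, m$area_mm2)
  expect_true(s$maculation_pct >= 0 && s$maculation_pct <= 100)
  expect_error(summarize_colorimetrics(reg, rep(TRUE, sum(reg$members)),
                                       lab, m), "background")
  expect_error(summarize_colorimetrics(reg, cls$maculated[-1], lab[-1, ], m),
               "cover")
})

test_that("colour and maculation are recovered from rendered eggs", {
  cases <- expand.grid(L = c(55, 75), f = c(0, 0.2))
  for (i in seq_len(nrow(cases))) {
    lab0 <- c(cases$L[i], 6, 14)
    b <- render_egg_image(lab0, cases$f[i], canvas = c(200, 150),
                          seed = 100 + i)
    m <- segment_egg(b$image)
    reg <- select_subsample(m)
    lab <- rgb_to_lab(ovotrait:::pixel_rows(b$image, reg$members))
    cls <- classify_maculation(lab)
    s <- summarize_colorimetrics(reg, cls$maculated, lab, m)
    truth <- 100 * sum(b$spot_mask & reg$members) / sum(reg$members)
    expect_lt(abs(s$maculation_pct - truth), 3)
    expect_lt(abs(s$L_mean - lab0[1]), 2)
    expect_lt(abs(s$a_mean - lab0[2]), 2)
    expect_lt(abs(s$b_mean - lab0[3]), 2)
  }
})

test_that("the pipeline is invariant to translation and 180-degree rotation", {
  b <- render_egg_image(c(66, 7, 13), 0.25, canvas = c(180, 140), seed = 8)
  base <- process_egg_image(b$image, pixel_scale = 0.1)
  # translation: embed in a larger dark canvas at an offset
  big <- array(0, c(220, 260, 3))
  dark <- as.vector(lab_to_rgb(c(2, 0, 0)))
  for (ch in 1:3) big[, , ch] <- dark[ch]
  big[41:180, 61:240, ] <- b$image
  shifted <- process_egg_image(big, pixel_scale = 0.1)
  expect_equal(shifted, base, tolerance = 1e-10)
  # 180-degree rotation (reverse both axes)
  rot <- b$image[dim(b$image)[1]:1, dim(b$image)[2]:1, , drop = FALSE]
  rotated <- process_egg_image(rot, pixel_scale = 0.1)
  expect_equal(rotated, base, tolerance = 1e-10)
})
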