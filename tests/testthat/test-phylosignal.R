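test_that("the trait covariance matches hand-computed shared path lengths", {
  V <- tree_to_covariance(tree_abc())
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["C", "C"], 2)
  V2 <- tree_to_covariance(tree_ab())
  expect_equal(unname(diag(V2)), c(1, 3))
  expect_equal(V2["A", "B"], 0)
  # ultrametric trees have a constant diagonal
  tr <- simulate_yule_tree(15, seed = 2)
  expect_lt(diff(range(diag(tree_to_covariance(tr)))), 1e-9)
  expect_error(tree_to_covariance(ape::read.tree(text = "(A,B);")),
               "branch lengths")
})

test_that("the lambda transform rescales only the off-diagonal", {
  V <- tree_to_covariance(tree_abc())
  expect_equal(apply_lambda(V, 1), V)
  expect_equal(apply_lambda(V, 0), diag(diag(V)), ignore_attr = TRUE)
  expect_equal(apply_lambda(V, 0.5)["A", "B"], 0.5)
  expect_equal(diag(apply_lambda(V, 0.5)), diag(V))
  expect_error(apply_lambda(V, 1.5), "lambda")
})

test_that("the profile likelihood reduces to i.i.d. ML for identity V", {
  set.seed(10)
  x <- rnorm(20, 3, 2)
  fit <- bm_profile_loglik(x, diag(20))
  expect_equal(fit$mu, mean(x))
  expect_equal(fit$sigma2, mean((x - mean(x))^2))
})

test_that("the profile log-likelihood equals a dense-density oracle", {
  tr <- simulate_yule_tree(8, seed = 3)
  x <- simulate_bm_traits(tr, seed = 4)[, 1]
  for (l in c(0, 0.4, 1)) {
    V <- apply_lambda(tree_to_covariance(tr), l)
    fit <- bm_profile_loglik(x, V)
    oracle <- dense_mvn_loglik(x, fit$mu, fit$sigma2 * V)
    expect_equal(fit$loglik, as.numeric(oracle), tolerance = 1e-8)
  }
  expect_error(bm_profile_loglik(x, matrix(1, 8, 8)), "singular")
})

test_that("rescaling the trait rescales the rate but not lambda", {
  tr <- simulate_yule_tree(30, seed = 5)
  x <- simulate_bm_traits(tr, lambda = 0.7, seed = 6)[, 1]
  f1 <- estimate_lambda(x, tr)
  f3 <- estimate_lambda(3 * x, tr)
  expect_equal(f3$lambda, f1$lambda, tolerance = 1e-4)
  expect_equal(f3$sigma2, 9 * f1$sigma2, tolerance = 1e-6)
})

test_that("the lambda optimizer matches a 1001-point grid argmax", {
  tr <- simulate_yule_tree(40, seed = 7)
  V <- tree_to_covariance(tr)
  for (s in 1:3) {
    x <- simulate_bm_traits(tr, lambda = c(0.3, 0.8, 1)[s], seed = 20 + s)[, 1]
    fit <- estimate_lambda(x, tr)
    grid <- seq(0, 1, length.out = 1001)
    ll <- vapply(grid, function(l) {
      tryCatch(bm_profile_loglik(x, apply_lambda(V, l))$loglik,
               error = function(e) -Inf)
    }, numeric(1))
    expect_lte(abs(fit$lambda - grid[which.max(ll)]), 0.001)
    expect_gte(fit$loglik, max(ll) - 1e-6)
    expect_true(fit$lambda >= 0 && fit$lambda <= 1)
    expect_true(fit$ci[1] <= fit$lambda && fit$lambda <= fit$ci[2])
  }
})

test_that("lambda estimates agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(50, seed = 31)
  x <- simulate_bm_traits(tr, lambda = 0.6, seed = 32)[, 1]
  ours <- estimate_lambda(x, tr)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(ours$loglik, ref$logL, tolerance = 0.01)
})

test_that("a star tree flags lambda as unidentifiable", {
  tr <- star_tree(8)
  x <- rnorm(8)
  names(x) <- tr$tip.label
  fit <- estimate_lambda(x, tr)
  expect_equal(fit$lambda, 0)
  expect_false(fit$identifiable)
})

test_that("profile CIs under Brownian motion usually cover lambda = 1", {
  tr <- simulate_yule_tree(71, seed = 8)
  x <- simulate_bm_traits(tr, lambda = 1, n_traits = 60, seed = 9)
  hits <- vapply(seq_len(ncol(x)), function(j) {
    ci <- estimate_lambda(x[, j], tr)$ci
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ICC handles the degenerate variance structures", {
  sp <- rep(letters[1:6], each = 3)
  x <- rep(1:6, each = 3)                       # zero within-species variance
  expect_equal(repeatability_icc(x, sp, n_boot = 20, seed = 1)$icc, 1)
  set.seed(11)
  y <- rnorm(18)                                # identical species means
  sp2 <- rep("a", 18)
  expect_error(repeatability_icc(y, sp2, n_boot = 10), "2 species")
  y3 <- rep(0, 18) + rnorm(18)
  icc3 <- repeatability_icc(y3, sp, n_boot = 20, seed = 2)
  expect_lt(icc3$icc, 0.35)
  expect_error(repeatability_icc(1:6, letters[1:6], n_boot = 10),
               "single replicate")
})

test_that("ICC is invariant to affine transformation", {
  set.seed(12)
  sp <- rep(sprintf("s%02d", 1:20), each = 3)
  x <- rnorm(20)[rep(1:20, each = 3)] + rnorm(60, 0, 0.5)
  a <- repeatability_icc(x, sp, n_boot = 200, seed = 5)
  b <- repeatability_icc(3.2 * x - 7, sp, n_boot = 200, seed = 5)
  expect_equal(a$icc, b$icc, tolerance = 1e-12)
  expect_equal(c(a$p5, a$p95), c(b$p5, b$p95), tolerance = 1e-10)
})

test_that("ICC recovers a known between/within variance ratio", {
  # 71 species x 3 replicates, between-variance 1, within-variance 0.5:
  # true one-way ICC = 1 / 1.5
  set.seed(13)
  est <- replicate(200, {
    mu <- rnorm(71, 0, 1)
    v <- rep(mu, each = 3) + rnorm(213, 0, sqrt(0.5))
    repeatability_icc(v, rep(sprintf("s%02d", 1:71), each = 3),
                      n_boot = 2, seed = NULL)$icc
  })
  expect_lt(abs(mean(est) - 1 / 1.5), 0.05)
})

test_that("Spearman correlation matches the rank-then-Pearson definition", {
  expect_equal(spearman_rho(1:10, exp(1:10)), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman_rho(x, y),
               cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("Spearman correlation is invariant to monotone transforms", {
  set.seed(14)
  x <- runif(30, 1, 5); y <- x + rnorm(30, 0, 0.5)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base, tolerance = 1e-12)
  expect_equal(spearman_rho(x, y^3), base, tolerance = 1e-12)
  expect_equal(spearman_rho(log(x), sqrt(y - min(y) + 1)), base,
               tolerance = 1e-12)
})
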