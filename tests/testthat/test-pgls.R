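test_that("GLS reduces to OLS when the covariance is the identity", {
  tr <- star_tree(25)                    # unit star tree: V = I
  set.seed(20)
  d <- data.frame(x1 = rnorm(25), x2 = runif(25))
  d$y <- 1 + 2 * d$x1 - 0.5 * d$x2 + rnorm(25, 0, 0.3)
  rownames(d) <- tr$tip.label
  fit <- fit_pgls(y ~ x1 + x2, d, tr, lambda = 0)
  ols <- lm(y ~ x1 + x2, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[, "se"]),
               unname(summary(ols)$coefficients[, "Std. Error"]),
               tolerance = 1e-8)
})

test_that("the PGLS log-likelihood equals a dense-density oracle", {
  tr <- simulate_yule_tree(9, seed = 21)
  set.seed(22)
  d <- data.frame(x = rnorm(9))
  d$y <- 0.5 + 1.5 * d$x + simulate_bm_traits(tr, sigma2 = 0.5, seed = 23)[, 1]
  rownames(d) <- tr$tip.label
  fit <- fit_pgls(y ~ x, d, tr, lambda = 0.6)
  V <- apply_lambda(tree_to_covariance(tr), 0.6)
  X <- cbind(1, d[tr$tip.label, "x"])
  mu <- X %*% coef(fit)
  oracle <- dense_mvn_loglik(d[tr$tip.label, "y"], as.vector(mu),
                             fit$sigma2 * V)
  expect_equal(fit$loglik, as.numeric(oracle), tolerance = 1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
  expect_equal(fit$k, 2 + 1)            # two coefficients + rate, fixed lambda
})

test_that("PGLS agrees with nlme::gls under a Pagel correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(40, seed = 24)
  d <- data.frame(x = simulate_bm_traits(tr, seed = 25)[, 1])
  d$y <- 1 + 0.8 * d$x + simulate_bm_traits(tr, sigma2 = 0.3, seed = 26)[, 1]
  rownames(d) <- tr$tip.label
  ours <- fit_pgls(y ~ x, d, tr, lambda = 0.7)
  d$sp <- rownames(d)
  ref <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(0.7, tr, fixed = TRUE,
                                               form = ~ sp))
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("species mismatches and collinear designs are named in errors", {
  tr <- simulate_yule_tree(10, seed = 27)
  d <- data.frame(x = rnorm(10), y = rnorm(10))
  rownames(d) <- c(tr$tip.label[-1], "intruder")
  expect_error(fit_pgls(y ~ x, d, tr), "intruder")
  d2 <- data.frame(x = rnorm(10))
  d2$y <- rnorm(10)
  d2$x_copy <- 2 * d2$x
  rownames(d2) <- tr$tip.label
  expect_error(fit_pgls(y ~ x + x_copy, d2, tr), "x_copy")
})

test_that("model enumeration is complete and deterministically ordered", {
  m3 <- enumerate_models(c("a", "b", "c"))
  expect_length(m3, 8)
  expect_equal(m3[[1]], character(0))
  expect_equal(lengths(m3), c(0, 1, 1, 1, 2, 2, 2, 3))
  expect_equal(m3[[5]], c("a", "b"))          # size then lexicographic
  expect_length(enumerate_models(character(0)), 1)
  m6 <- enumerate_models(sprintf("p%d", 1:6), always_include = "co")
  expect_length(m6, 64)
  expect_true(all(vapply(m6, function(s) "co" %in% s, logical(1))))
  expect_error(enumerate_models(sprintf("p%d", 1:13)), "12")
})

test_that("Akaike weights match the closed form and its invariances", {
  expect_equal(akaike_weights(rep(5, 4)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(akaike_weights(c(3, 7, 4)), akaike_weights(c(103, 107, 104)),
               tolerance = 1e-12)
  expect_equal(sum(akaike_weights(rnorm(10, 100, 5))), 1, tolerance = 1e-12)
  expect_warning(w2 <- akaike_weights(c(10, Inf, 12)), "non-finite")
  expect_equal(w2[2], 0)
})

test_that("the confidence set is the smallest prefix over the threshold", {
  w <- c(0.6, 0.3, 0.08, 0.02)
  expect_equal(confidence_set(w), 1:3)
  expect_equal(confidence_set(1), 1L)
  expect_equal(confidence_set(w, threshold = 0), 1L)
  # ties broken toward fewer parameters
  expect_equal(confidence_set(c(0.5, 0.5), k = c(3L, 2L), threshold = 0.4),
               2L)
})

test_that("model averaging matches the hand-evaluated Burnham-Anderson form", {
  mk_fit <- function(terms, est, se) {
    cf <- cbind(estimate = est, se = se, t = est / se)
    rownames(cf) <- terms
    structure(list(coefficients = cf), class = "ovo_pgls")
  }
  f1 <- mk_fit(c("(Intercept)", "x"), c(0.2, 1.0), c(0.1, 0.3))
  f2 <- mk_fit(c("(Intercept)", "x"), c(0.4, 2.0), c(0.1, 0.5))
  avg <- model_average(list(f1, f2), weights = c(0.75, 0.25))
  row <- avg[avg$term == "x", ]
  expect_equal(row$estimate, 0.75 * 1 + 0.25 * 2)
  se_hand <- 0.75 * sqrt(0.3^2 + (1 - 1.25)^2) +
    0.25 * sqrt(0.5^2 + (2 - 1.25)^2)
  expect_equal(row$se, se_hand, tolerance = 1e-12)
  expect_equal(row$ci95_low, row$estimate - qnorm(0.975) * row$se)
  expect_equal(row$importance, 1)
  expect_equal(row$n_containing_models, 2L)
  # a predictor absent from one model is averaged conditionally
  f3 <- mk_fit("(Intercept)", 0.1, 0.05)
  avg2 <- model_average(list(f1, f3), weights = c(0.6, 0.4))
  row2 <- avg2[avg2$term == "x", ]
  expect_equal(row2$estimate, 1.0)
  expect_equal(row2$importance, 0.6)
  expect_equal(row2$n_containing_models, 1L)
  # degenerate: identical estimates and SEs average to themselves
  avg3 <- model_average(list(f1, f1), weights = c(0.5, 0.5))
  expect_equal(avg3[avg3$term == "x", "estimate"], 1.0)
  expect_equal(avg3[avg3$term == "x", "se"], 0.3)
})

test_that("raw weights normalize over candidates and renormalize in the set", {
  tr <- simulate_yule_tree(30, seed = 28)
  d <- as.data.frame(simulate_bm_traits(tr, n_traits = 4, seed = 29))
  names(d) <- c("y", "x1", "x2", "x3")
  ms <- pgls_model_average("y", c("x1", "x2", "x3"), d, tr)
  expect_equal(ms$n_candidates, 8)
  expect_equal(sum(ms$weights), 1, tolerance = 1e-12)
  expect_equal(sum(attr(ms$averaged, "weights")), 1, tolerance = 1e-12)
  expect_true(all(ms$averaged$importance <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(ms$averaged$n_containing_models <= length(ms$set),
                  na.rm = TRUE))
})

test_that("AIC ranking is invariant to rescaling a predictor", {
  tr <- simulate_yule_tree(35, seed = 30)
  d <- as.data.frame(simulate_bm_traits(tr, n_traits = 3, seed = 31))
  names(d) <- c("y", "x1", "x2")
  f_a <- fit_pgls(y ~ x1 + x2, d, tr, lambda = 1)
  d$x1 <- d$x1 * 1000
  f_b <- fit_pgls(y ~ x1 + x2, d, tr, lambda = 1)
  expect_equal(f_b$loglik, f_a$loglik, tolerance = 1e-8)
  expect_equal(f_b$aic, f_a$aic, tolerance = 1e-8)
  expect_equal(coef(f_b)[["x1"]], coef(f_a)[["x1"]] / 1000, tolerance = 1e-10)
})

test_that("fixed-lambda PGLS intervals cover Brownian generating coefficients", {
  tr <- simulate_yule_tree(71, seed = 32)
  set.seed(33)
  d <- data.frame(x1 = simulate_bm_traits(tr, seed = 34)[, 1],
                  x2 = runif(71), g = rep(c(0, 1), length.out = 71))
  rownames(d) <- tr$tip.label
  beta <- c(2, 0.5, -0.3, 0.2)
  X <- cbind(1, d$x1, d$x2, d$g)
  errs <- simulate_bm_traits(tr, sigma2 = 0.1, n_traits = 200, seed = 35)
  hits <- matrix(FALSE, 200, 4)
  for (s in 1:200) {
    d$y <- as.vector(X %*% beta) + errs[, s]
    ci <- confint(fit_pgls(y ~ x1 + x2 + g, d, tr, lambda = 1))
    hits[s, ] <- ci[, 1] <= beta & beta <= ci[, 2]
  }
  expect_true(all(colMeans(hits) >= 0.90))
})
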