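# Shared fixtures, all built in code.

# small fixed trees for hand-checkable covariance examples
tree_abc <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree_ab <- function() ape::read.tree(text = "(A:1,B:3);")
star_tree <- function(n = 6) {
  ape::read.tree(text = paste0(
    "(", paste0("t", seq_len(n), ":1", collapse = ","), ");"))
}

# dense multivariate-normal log-density, written independently of the
# package's Cholesky-based likelihood (oracle for logLik checks)
dense_mvn_loglik <- function(x, mean, Sigma) {
  n <- length(x)
  d <- x - mean
  -0.5 * (n * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus +
            drop(t(d) %*% solve(Sigma) %*% d))
}

# brute-force Otsu: evaluate the between-class variance at every cut and
# return the lowest maximizing boundary
brute_otsu <- function(counts, breaks) {
  counts <- as.numeric(counts)
  nb <- length(counts)
  mids <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  best_v <- -Inf
  best_t <- NA_real_
  for (t in seq_len(nb - 1)) {
    w1 <- sum(counts[1:t]); w2 <- sum(counts[(t + 1):nb])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[1:t] * mids[1:t]) / w1
    m2 <- sum(counts[(t + 1):nb] * mids[(t + 1):nb]) / w2
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- breaks[t + 1]
    }
  }
  best_t
}

# species-mean analysis table from a simulated dataset
dataset_to_pgls_data <- function(ds) dataset_to_analysis_frame(ds)

life_predictors <- c("nest_location", "parasitized", "nest_type",
                     "log10_body_mass", "clutch_size", "thickness_mm")
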