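# Phylogenetic signal: Pagel's lambda by profile maximum likelihood on the
# Brownian-motion covariance, plus the auxiliary statistics (one-way ICC
# repeatability with species bootstrap, Spearman correlation).

#' Brownian-motion trait covariance of a tree
#'
#' `V[i, j]` is the root-to-MRCA path length of tips i and j (their shared
#' evolutionary history); the diagonal holds root-to-tip depths. Under
#' Brownian motion a trait's tip covariance is `sigma2 * V`.
#'
#' @param tree Rooted `phylo` object with branch lengths.
#' @return Symmetric positive semi-definite matrix with tip labels as
#'   dimnames, in `tree$tip.label` order.
#' @export
tree_to_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label]
}

#' Scale the off-diagonal of a trait covariance by Pagel's lambda
#'
#' `lambda = 1` leaves the Brownian covariance unchanged; `lambda = 0`
#' removes all shared history (phylogenetic independence); intermediate
#' values interpolate.
#'
#' @param V Trait covariance matrix (from [tree_to_covariance()]).
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
apply_lambda <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must lie in [0, 1]", call. = FALSE)
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Profile log-likelihood of a trait under a fixed covariance structure
#'
#' Maximizes the Gaussian likelihood analytically over the ancestral mean
#' and the Brownian rate for a given `V`: the GLS mean
#' `mu = (1' V^-1 x) / (1' V^-1 1)`, the ML rate
#' `sigma2 = (x - mu)' V^-1 (x - mu) / n`, and the log-likelihood at the
#' optimum. Used pointwise by [estimate_lambda()].
#'
#' @param x Numeric trait vector (one value per tip, in `V` order).
#' @param V Positive-definite covariance structure.
#' @return List: `mu`, `sigma2`, `loglik`.
#' @export
bm_profile_loglik <- function(x, V) {
  n <- length(x)
  stopifnot(is.matrix(V), nrow(V) == n, ncol(V) == n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps) * max(diag(R))) {
    stop(sprintf(
      "covariance matrix is singular or near-singular (condition number %.3g)",
      kappa(V)), call. = FALSE)
  }
  z <- backsolve(R, x, transpose = TRUE)
  o <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(o * z) / sum(o * o)
  r <- z - mu * o
  sigma2 <- sum(r^2) / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + n)
  list(mu = mu, sigma2 = sigma2, loglik = loglik)
}

#' Estimate Pagel's lambda by maximum likelihood
#'
#' Profiles the log-likelihood over `lambda` in `[0, 1]` (ancestral mean
#' and Brownian rate maximized analytically at each point): a 21-point
#' coarse grid with both boundaries evaluated explicitly, then
#' derivative-free 1-D refinement to tolerance 1e-6 in the bracketing
#' interval. The confidence interval is the profile-likelihood set
#' `{lambda : logLik(lambda) >= logLik(lambda_hat) - chisq_1(ci_level)/2}`
#' truncated to `[0, 1]`.
#'
#' On a star tree (no shared history) lambda is unidentifiable; the fit is
#' returned with `lambda = 0` and `identifiable = FALSE`.
#'
#' @param x Named trait vector (names = tip labels), or unnamed in tip
#'   order.
#' @param tree `phylo` object.
#' @param ci_level Confidence level for the profile interval.
#' @return Object of class `ovo_lambda`: `lambda`, `ci` (lower, upper),
#'   `mu`, `sigma2`, `loglik`, `identifiable`, `n`.
#' @examples
#' tr <- simulate_yule_tree(40, seed = 1)
#' x <- simulate_bm_traits(tr, seed = 2)[, 1]
#' estimate_lambda(x, tr)
#' @export
estimate_lambda <- function(x, tree, ci_level = 0.95) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (length(x) != ntip) stop("length(x) must equal the number of tips",
                              call. = FALSE)
  if (!is.null(names(x))) {
    missing <- setdiff(tree$tip.label, names(x))
    if (length(missing)) {
      stop("trait values missing for tips: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    x <- x[tree$tip.label]
  }
  if (ntip < 4L) stop("need at least 4 tips to estimate lambda", call. = FALSE)
  if (var(x) <= 0) stop("trait has no variance", call. = FALSE)
  V <- tree_to_covariance(tree)

  if (max(abs(V[upper.tri(V)])) < 1e-12 * max(diag(V))) {
    fit0 <- bm_profile_loglik(x, apply_lambda(V, 0))
    out <- list(lambda = 0, ci = c(0, 1), mu = fit0$mu, sigma2 = fit0$sigma2,
                loglik = fit0$loglik, identifiable = FALSE, n = ntip,
                ci_level = ci_level)
    class(out) <- "ovo_lambda"
    return(out)
  }

  prof <- function(l) {
    tryCatch(bm_profile_loglik(x, apply_lambda(V, l))$loglik,
             error = function(e) -Inf)
  }
  grid <- seq(0, 1, length.out = 21L)
  ll <- vapply(grid, prof, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(prof, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  cand_l <- c(grid[i], opt$maximum)
  cand_ll <- c(ll[i], opt$objective)
  best <- which.max(cand_ll)
  lambda_hat <- cand_l[best]
  ll_max <- cand_ll[best]

  fit <- bm_profile_loglik(x, apply_lambda(V, lambda_hat))
  thr <- ll_max - qchisq(ci_level, df = 1) / 2
  ci_lo <- if (prof(0) >= thr) 0 else {
    uniroot(function(l) prof(l) - thr, lower = 0, upper = lambda_hat,
            tol = 1e-6)$root
  }
  ci_hi <- if (prof(1) >= thr) 1 else {
    upper <- if (is.finite(prof(1))) 1 else 1 - 1e-9
    if (prof(upper) >= thr) upper else {
      uniroot(function(l) prof(l) - thr, lower = lambda_hat, upper = upper,
              tol = 1e-6)$root
    }
  }
  out <- list(lambda = lambda_hat, ci = c(ci_lo, ci_hi), mu = fit$mu,
              sigma2 = fit$sigma2, loglik = ll_max, identifiable = TRUE,
              n = ntip, ci_level = ci_level)
  class(out) <- "ovo_lambda"
  out
}

#' @export
print.ovo_lambda <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda = %.3f [%g%% CI %.3f, %.3f], sigma2 = %.4g, logLik = %.3f (n = %d)\n",
    x$lambda, 100 * x$ci_level, x$ci[1], x$ci[2], x$sigma2, x$loglik, x$n))
  if (!x$identifiable) cat("  (star tree: lambda unidentifiable, fixed at 0)\n")
  invisible(x)
}

#' Repeatability (intraclass correlation) of replicated measurements
#'
#' One-way random-effects ICC from ANOVA mean squares:
#' `(MS_between - MS_within) / (MS_between + (k0 - 1) MS_within)` with
#' `k0` the harmonic-mean-adjusted replicate count
#' `(N - sum(n_i^2)/N) / (a - 1)`. Negative estimates are clipped to 0.
#' Uncertainty comes from a percentile bootstrap over species (resampling
#' species with replacement, keeping their replicates together): the 5th
#' and 95th percentiles are reported.
#'
#' @param values Numeric measurements (e.g. log10 pigment concentration).
#' @param species Grouping factor/character, same length as `values`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `ovo_icc`: `icc`, `p5`, `p95`, `n_species`,
#'   `n_obs`.
#' @export
repeatability_icc <- function(values, species, n_boot = 2000L, seed = NULL) {
  stopifnot(length(values) == length(species))
  ok <- complete.cases(values, species)
  values <- values[ok]
  species <- as.character(species)[ok]
  counts <- table(species)
  if (length(counts) < 2L) stop("need at least 2 species", call. = FALSE)
  if (all(counts < 2L)) {
    stop("all species have a single replicate; within-species variance is undefined",
         call. = FALSE)
  }
  icc_point <- function(v, s) {
    s <- factor(s)
    ni <- tapply(v, s, length)
    a <- length(ni); N <- sum(ni)
    gm <- mean(v)
    mi <- tapply(v, s, mean)
    ssb <- sum(ni * (mi - gm)^2)
    ssw <- sum((v - mi[as.integer(s)])^2)
    msb <- ssb / (a - 1)
    dfw <- N - a
    msw <- if (dfw > 0) ssw / dfw else 0
    k0 <- (N - sum(ni^2) / N) / (a - 1)
    val <- (msb - msw) / (msb + (k0 - 1) * msw)
    min(max(val, 0), 1)
  }
  point <- icc_point(values, species)
  sp <- names(counts)
  idx_by_sp <- split(seq_along(values), species)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(sp, length(sp), replace = TRUE)
      idx <- unlist(idx_by_sp[pick], use.names = FALSE)
      grp <- rep(seq_along(pick), lengths(idx_by_sp[pick]))
      icc_point(values[idx], grp)
    }, numeric(1))
  })
  out <- list(icc = point,
              p5 = unname(quantile(boot, 0.05)),
              p95 = unname(quantile(boot, 0.95)),
              n_species = length(sp), n_obs = length(values),
              n_boot = n_boot)
  class(out) <- "ovo_icc"
  out
}

#' @export
print.ovo_icc <- function(x, ...) {
  cat(sprintf("ICC repeatability = %.3f [5th, 95th percentiles: %.3f, %.3f] (%d species, %d measurements)\n",
              x$icc, x$p5, x$p95, x$n_species, x$n_obs))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their
#' average rank). Returns `NA` with a warning when either vector is
#' constant (ranks have no variance).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @examples
#' spearman_rho(1:10, log(1:10))  # 1: rank correlation is monotone-invariant
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (var(rx) == 0 || var(ry) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
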