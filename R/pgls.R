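# Phylogenetic generalized least squares with Pagel's lambda, all-subsets
# AIC ranking, 95% cumulative-weight confidence sets, and model-averaged
# estimates with relative variable importance.

#' Fit a phylogenetic generalized least squares model
#'
#' GLS with error covariance `sigma2 * V(lambda)` from the tree:
#' `beta = (X' W X)^-1 X' W y` with `W = V(lambda)^-1`, the Brownian rate
#' profiled out analytically, and `lambda` either fixed or jointly
#' ML-estimated (21-point grid plus 1-D refinement, boundaries included).
#' Coefficient standard errors use the bias-corrected rate
#' (RSS / (n - p)); `AIC = -2 logLik + 2 k` with
#' `k = p + 1` (coefficients + rate) for fixed `lambda` and `k = p + 2`
#' when `lambda` is estimated.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data `data.frame` whose rownames (or a `species` column) match
#'   the tree's tip labels, one row per species.
#' @param tree `phylo` object.
#' @param lambda `"ML"` for joint maximum likelihood, or a fixed value in
#'   `[0, 1]`.
#' @return Object of class `ovo_pgls` with elements `coefficients`
#'   (matrix: estimate, se, t), `lambda`, `lambda_ml` (logical), `sigma2`,
#'   `loglik`, `aic`, `k`, `n`, `terms`, `call`.
#' @examples
#' tr <- simulate_yule_tree(30, seed = 1)
#' d <- data.frame(x = simulate_bm_traits(tr, seed = 2)[, 1])
#' d$y <- 2 * d$x + simulate_bm_traits(tr, seed = 3)[, 1]
#' rownames(d) <- tr$tip.label
#' fit_pgls(y ~ x, d, tr)
#' @export
fit_pgls <- function(formula, data, tree, lambda = "ML") {
  stopifnot(inherits(formula, "formula"), is.data.frame(data),
            inherits(tree, "phylo"))
  if (!is.null(data$species) && is.null(attr(data, "ovo_aligned"))) {
    rownames(data) <- data$species
  }
  sp_data <- rownames(data)
  extra <- setdiff(sp_data, tree$tip.label)
  missing <- setdiff(tree$tip.label, sp_data)
  if (length(extra) || length(missing)) {
    stop("species mismatch between data and tree; ",
         if (length(extra)) paste0("not in tree: ",
                                   paste(head(extra, 5), collapse = ", "), "; "),
         if (length(missing)) paste0("not in data: ",
                                     paste(head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  V <- tree_to_covariance(tree)

  gls_at <- function(l) {
    W <- apply_lambda(V, l)
    R <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    yt <- backsolve(R, y, transpose = TRUE)
    Xt <- backsolve(R, X, transpose = TRUE)
    fit <- stats::lm.fit(Xt, yt)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    loglik <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + n)
    list(beta = fit$coefficients, Xt = Xt, rss = rss, sigma2 = sigma2,
         loglik = loglik, lambda = l)
  }

  if (identical(lambda, "ML")) {
    prof <- function(l) {
      g <- gls_at(l)
      if (is.null(g)) -Inf else g$loglik
    }
    grid <- seq(0, 1, length.out = 21L)
    ll <- vapply(grid, prof, numeric(1))
    i <- which.max(ll)
    opt <- optimize(prof, interval = c(grid[max(1L, i - 1L)],
                                       grid[min(21L, i + 1L)]),
                    maximum = TRUE, tol = 1e-6)
    lam <- if (opt$objective > ll[i]) opt$maximum else grid[i]
    lambda_ml <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("`lambda` must be \"ML\" or a value in [0, 1]", call. = FALSE)
    }
    lam <- lambda
    lambda_ml <- FALSE
  }
  g <- gls_at(lam)
  if (is.null(g)) {
    stop("phylogenetic covariance is singular at lambda = ", lam, call. = FALSE)
  }
  XtX_inv <- chol2inv(qr.R(qr(g$Xt)))
  se <- sqrt(diag(XtX_inv) * g$rss / (n - p))
  coefs <- cbind(estimate = g$beta, se = se, t = g$beta / se)
  rownames(coefs) <- colnames(X)
  k <- p + 1L + as.integer(lambda_ml)
  out <- list(coefficients = coefs, lambda = lam, lambda_ml = lambda_ml,
              sigma2 = g$sigma2, loglik = g$loglik,
              aic = -2 * g$loglik + 2 * k, k = k, n = n,
              df_residual = n - p, terms = attr(mf, "terms"),
              formula = formula, call = match.call())
  class(out) <- "ovo_pgls"
  out
}

#' @export
print.ovo_pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n")
  cat(sprintf("  lambda = %.4f%s, sigma2 = %.4g, logLik = %.3f, AIC = %.2f (n = %d, k = %d)\n",
              x$lambda, if (x$lambda_ml) " (ML)" else " (fixed)",
              x$sigma2, x$loglik, x$aic, x$n, x$k))
  printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' @export
coef.ovo_pgls <- function(object, ...) object$coefficients[, "estimate"]

#' @export
logLik.ovo_pgls <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @importFrom stats confint
#' @export
confint.ovo_pgls <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  q <- qt(1 - (1 - level) / 2, df = object$df_residual)
  out <- cbind(cf[, "estimate"] - q * cf[, "se"],
               cf[, "estimate"] + q * cf[, "se"])
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Enumerate all predictor subsets of a full model
#'
#' All `2^p` subsets of the free predictors (including the intercept-only
#' model), each combined with the always-included terms, in deterministic
#' order: by subset size, then lexicographically by predictor position in
#' `predictors`.
#'
#' @param predictors Character vector of free predictor names (at most 12;
#'   beyond that the candidate set explodes combinatorially and the call
#'   is refused).
#' @param always_include Character vector of terms present in every model
#'   (e.g. the co-pigment concentration).
#' @return List of character vectors, each the predictor set of one model
#'   (possibly empty = intercept-only).
#' @examples
#' length(enumerate_models(c("a", "b", "c")))  # 8
#' @export
enumerate_models <- function(predictors, always_include = character(0)) {
  stopifnot(is.character(predictors))
  if (anyDuplicated(c(predictors, always_include))) {
    stop("duplicated predictor names", call. = FALSE)
  }
  p <- length(predictors)
  if (p > 12L) {
    stop("refusing to enumerate subsets of more than 12 predictors (2^",
         p, " models)", call. = FALSE)
  }
  subsets <- list(integer(0))
  if (p > 0L) {
    for (size in seq_len(p)) {
      subsets <- c(subsets,
                   utils::combn(p, size, simplify = FALSE))
    }
  }
  lapply(subsets, function(ix) c(always_include, predictors[ix]))
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`. Non-finite AIC values are excluded (their
#' weight is 0) with a warning.
#'
#' @param aic Numeric vector of AIC scores.
#' @return Numeric vector of weights summing to 1 over the finite entries.
#' @export
akaike_weights <- function(aic) {
  stopifnot(length(aic) >= 1L)
  w <- rep(0, length(aic))
  ok <- is.finite(aic)
  if (!all(ok)) warning(sum(!ok), " model(s) with non-finite AIC excluded")
  if (!any(ok)) stop("no model with finite AIC", call. = FALSE)
  d <- aic[ok] - min(aic[ok])
  ew <- exp(-d / 2)
  w[ok] <- ew / sum(ew)
  w
}

#' Cumulative-weight confidence set of models
#'
#' Models are sorted by descending Akaike weight (ties: fewer parameters
#' first, then enumeration order) and the smallest prefix whose cumulative
#' weight exceeds `threshold` is returned.
#'
#' @param weights Akaike weights (normalized over the candidate set).
#' @param k Parameter counts, used only to break ties.
#' @param threshold Cumulative weight to exceed (default 0.95).
#' @return Integer indices of the selected models, in ranking order.
#' @export
confidence_set <- function(weights, k = rep(0L, length(weights)),
                           threshold = 0.95) {
  stopifnot(length(weights) == length(k), threshold >= 0, threshold < 1)
  ord <- order(-weights, k, seq_along(weights))
  cum <- cumsum(weights[ord])
  ord[seq_len(which(cum > threshold)[1])]
}

#' Model-averaged estimates over a confidence set
#'
#' Conditional (natural) averaging: each predictor is averaged over the
#' models that contain it, with weights renormalized over those models:
#' `beta_bar = sum(w_i beta_i) / sum(w_i)`. The unconditional standard
#' error uses the Burnham-Anderson form
#' `SE = sum(w_i * sqrt(se_i^2 + (beta_i - beta_bar)^2))` (weights again
#' renormalized over containing models). Confidence intervals are normal:
#' `beta_bar +/- 1.96 SE` (95%) and `+/- 1.645 SE` (90%). Relative
#' variable importance is the sum of the confidence-set-renormalized
#' weights of the containing models; the intercept row (present in every
#' model) reports no importance, matching standard presentation.
#'
#' @param fits List of `ovo_pgls` fits (the confidence set).
#' @param weights Their Akaike weights (any positive scale; renormalized
#'   internally).
#' @return Object of class `ovo_modavg`: a `data.frame` with one row per
#'   term (`term`, `estimate`, `se`, `ci95_low`, `ci95_high`, `ci90_low`,
#'   `ci90_high`, `importance`, `n_containing_models`, `significant_95`,
#'   `significant_90`), plus attributes `n_models` and `weights`.
#' @export
model_average <- function(fits, weights) {
  stopifnot(length(fits) == length(weights), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "ovo_pgls")))
  w <- weights / sum(weights)
  terms_by_fit <- lapply(fits, function(f) rownames(f$coefficients))
  all_terms <- unique(unlist(terms_by_fit))
  all_terms <- c(intersect("(Intercept)", all_terms),
                 setdiff(all_terms, "(Intercept)"))
  rows <- lapply(all_terms, function(tm) {
    has <- vapply(terms_by_fit, function(tt) tm %in% tt, logical(1))
    wc <- w[has] / sum(w[has])
    est <- vapply(fits[has], function(f) f$coefficients[tm, "estimate"],
                  numeric(1))
    se_i <- vapply(fits[has], function(f) f$coefficients[tm, "se"],
                   numeric(1))
    b <- sum(wc * est)
    se <- sum(wc * sqrt(se_i^2 + (est - b)^2))
    is_int <- tm == "(Intercept)"
    data.frame(
      term = tm, estimate = b, se = se,
      ci95_low = b - qnorm(0.975) * se, ci95_high = b + qnorm(0.975) * se,
      ci90_low = b - qnorm(0.95) * se, ci90_high = b + qnorm(0.95) * se,
      importance = if (is_int) NA_real_ else sum(w[has]),
      n_containing_models = if (is_int) NA_integer_ else sum(has),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant_95 <- out$ci95_low > 0 | out$ci95_high < 0
  out$significant_90 <- out$ci90_low > 0 | out$ci90_high < 0
  structure(out, n_models = length(fits), weights = w,
            class = c("ovo_modavg", "data.frame"))
}

#' @export
print.ovo_modavg <- function(x, digits = 3, ...) {
  cat(sprintf("Model-averaged estimates over %d models (conditional averaging)\n",
              attr(x, "n_models")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' All-subsets PGLS with AIC ranking and model averaging
#'
#' The complete multimodel-inference workflow behind the package's output
#' tables: enumerate every subset of the free predictors (plus any
#' always-included terms), fit each by PGLS, rank by AIC (or AICc), take
#' the smallest set of top-ranked models whose cumulative Akaike weight
#' exceeds `threshold`, and average estimates over that set.
#'
#' @param response Response variable name.
#' @param predictors Free predictor names.
#' @param data Species-level `data.frame` (rownames = tip labels).
#' @param tree `phylo` object.
#' @param always_include Terms forced into every candidate model.
#' @param lambda Per-model lambda treatment (see [fit_pgls()]); each
#'   candidate gets its own ML lambda by default.
#' @param threshold Cumulative-weight threshold of the confidence set.
#' @param ic `"AIC"` (default) or `"AICc"` (small-sample correction).
#' @return Object of class `ovo_modsel`: the `ovo_modavg` table
#'   (`$averaged`), plus `$fits`, `$weights`, `$aic`, `$set` (confidence
#'   set indices), `$n_candidates`.
#' @examples
#' tr <- simulate_yule_tree(30, seed = 1)
#' d <- as.data.frame(simulate_bm_traits(tr, n_traits = 3, seed = 2))
#' names(d) <- c("y", "x1", "x2")
#' pgls_model_average("y", c("x1", "x2"), d, tr)$averaged
#' @export
pgls_model_average <- function(response, predictors, data, tree,
                               always_include = character(0),
                               lambda = "ML", threshold = 0.95,
                               ic = c("AIC", "AICc")) {
  ic <- match.arg(ic)
  models <- enumerate_models(predictors, always_include)
  fits <- lapply(models, function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fit_pgls(as.formula(paste(response, "~", rhs)), data, tree,
             lambda = lambda)
  })
  aic <- vapply(fits, function(f) {
    if (ic == "AICc") f$aic + 2 * f$k * (f$k + 1) / (f$n - f$k - 1) else f$aic
  }, numeric(1))
  w <- akaike_weights(aic)
  kp <- vapply(fits, function(f) f$k, integer(1))
  set <- confidence_set(w, kp, threshold)
  avg <- model_average(fits[set], w[set])
  structure(list(averaged = avg, fits = fits, weights = w, aic = aic,
                 set = set, n_candidates = length(fits),
                 response = response, ic = ic, threshold = threshold),
            class = "ovo_modsel")
}

#' @export
print.ovo_modsel <- function(x, ...) {
  cat(sprintf(
    "All-subsets PGLS for '%s': %d candidate models, %d in the %.0f%% confidence set (%s)\n",
    x$response, x$n_candidates, length(x$set), 100 * x$threshold, x$ic))
  print(x$averaged, ...)
  invisible(x)
}
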