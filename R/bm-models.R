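# Brownian-motion trait models: likelihoods, Pagel's lambda, directional
# random walk, likelihood-ratio machinery.

# Order a trait vector to the tree's tip order. Named vectors are matched by
# name; unnamed vectors are assumed already aligned.
.order_trait <- function(y, tree) {
  if (!is.null(names(y))) {
    if (!all(tree$tip.label %in% names(y)))
      .stop2("invalid_input", "trait vector is missing tips: %s",
             paste(setdiff(tree$tip.label, names(y)), collapse = ", "))
    y <- y[tree$tip.label]
  } else if (length(y) != length(tree$tip.label)) {
    .stop2("invalid_input", "trait vector length %d != %d tips",
           length(y), length(tree$tip.label))
  }
  as.numeric(y)
}

# Whitened GLS core: returns coefficients, whitened residual sum of squares,
# log|V| and the whitened design, via the Cholesky factor of V.
.gls_core <- function(y, X, V) {
  U <- tryCatch(chol(V), error = function(e)
    .stop2("numerical_error",
           "covariance matrix is not positive definite (%s); check for %s",
           conditionMessage(e), "duplicated tips or zero terminal branches"))
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(X))
    .stop2("collinearity_error", "design matrix is rank deficient")
  beta <- qr.coef(qx, yw)
  res <- yw - Xw %*% beta
  list(beta = drop(beta), rss = sum(res^2), logdet = 2 * sum(log(diag(U))),
       yw = yw, Xw = Xw, resw = drop(res))
}

# Profile (over beta, sigma2) Gaussian log-likelihood at a given V.
.profile_loglik <- function(y, X, V) {
  g <- .gls_core(y, X, V)
  n <- length(y)
  s2 <- g$rss / n
  ll <- if (s2 <= 0) Inf else
    -n / 2 * (log(2 * pi) + log(s2) + 1) - g$logdet / 2
  c(g, list(sigma2 = s2, loglik = ll))
}

#' Brownian-motion log-likelihood of tip data
#'
#' Multivariate-normal log density of a tip trait vector with mean
#' `alpha * 1` and covariance `sigma2 * V`, where V is the (possibly
#' lambda-transformed) Brownian variance-covariance matrix of the tree.
#'
#' @param y numeric tip trait vector, ordered as the rows of `V`.
#' @param V a [vcv_from_tree()] / [lambda_transform()] matrix.
#' @param alpha root state / phylogenetic mean (trait units).
#' @param sigma2 Brownian rate (trait units squared per unit branch length),
#'   > 0.
#' @return the log-likelihood (a single number).
#' @export
bm_loglik <- function(y, V, alpha, sigma2) {
  .check_number(sigma2, "sigma2", positive = TRUE)
  .check_number(alpha, "alpha")
  V <- unclass(V)
  n <- length(y)
  if (nrow(V) != n)
    .stop2("invalid_input", "y and V dimensions disagree")
  U <- tryCatch(chol(V), error = function(e)
    .stop2("numerical_error", "V is singular; check the tree for %s",
           "duplicated tips or zero-length terminal branches"))
  z <- backsolve(U, y - alpha, transpose = TRUE)
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - sum(log(diag(U))) -
    sum(z^2) / (2 * sigma2)
}

#' Fit a Brownian-motion model with Pagel's lambda
#'
#' Maximum-likelihood fit of the constant-variance Brownian model with
#' optional lambda scaling of the shared-history covariances. The root state
#' is the phylogenetically weighted mean `alpha = (1' V^-1 y)/(1' V^-1 1)`,
#' the rate is the ML estimator `sigma2 = (y - alpha)' V^-1 (y - alpha) / n`,
#' and lambda is profiled over [0, 1] by bounded scalar optimisation of the
#' profile log-likelihood (interior optimum compared against both
#' boundaries). On trees where the profile is flat (e.g. a star tree, where
#' lambda is unidentifiable) the fit is flagged and `lambda` set to `NA`.
#'
#' @param y tip trait vector (named, or ordered as `tree$tip.label`).
#' @param tree a `phylo` phylogram with >= 3 tips.
#' @param lam_mode `"ML"` to estimate lambda, or a fixed numeric value in
#'   [0, 1].
#' @param vcv optional precomputed [vcv_from_tree()] matrix (at lambda 1).
#' @return an object of class `brownian_fit` with fields `alpha`, `sigma2`,
#'   `lambda`, `beta` (NULL for pure BM), `loglik`, `n_params`, `model`,
#'   `flat_profile`, `n`.
#' @export
fit_brownian <- function(y, tree, lam_mode = "ML", vcv = NULL) {
  V0 <- unclass(vcv %||% vcv_from_tree(tree))
  y <- .order_trait(y, tree)
  n <- length(y)
  if (n < 3L) .stop2("invalid_input", "need at least 3 tips")
  X <- matrix(1, n, 1L)
  f <- function(lam) .profile_loglik(y, X, .lam_V(V0, lam))$loglik

  if (identical(lam_mode, "ML")) {
    grid <- f_grid <- NULL
    grid <- c(0, 0.25, 0.5, 0.75, 1)
    f_grid <- vapply(grid, f, 0)
    flat <- diff(range(f_grid)) < 1e-8
    if (flat) {
      lam_hat <- NA_real_
      fit <- .profile_loglik(y, X, V0)
    } else {
      opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
      cand <- c(0, opt$maximum, 1)
      ll_cand <- c(f_grid[1L], opt$objective, f_grid[5L])
      lam_hat <- cand[which.max(ll_cand)]
      fit <- .profile_loglik(y, X, .lam_V(V0, lam_hat))
    }
    k <- 3L
  } else {
    .check_number(lam_mode, "lam_mode", lower = 0, upper = 1)
    lam_hat <- lam_mode
    flat <- FALSE
    fit <- .profile_loglik(y, X, .lam_V(V0, lam_hat))
    k <- 2L
  }
  structure(list(alpha = fit$beta[[1L]], sigma2 = fit$sigma2,
                 lambda = lam_hat, beta = NULL, loglik = fit$loglik,
                 n_params = k, model = "BM", flat_profile = flat, n = n),
            class = "brownian_fit")
}

# lambda transform on a plain matrix (fast path used inside optimisers)
.lam_V <- function(V, lam) {
  d <- diag(V)
  W <- V * lam
  diag(W) <- d
  W
}

#' @export
print.brownian_fit <- function(x, ...) {
  cat(sprintf("<%s fit: alpha = %.4g, sigma2 = %.4g, lambda = %s%s, logLik = %.4f>\n",
              x$model, x$alpha, x$sigma2,
              if (is.na(x$lambda)) "NA (flat profile)" else
                sprintf("%.3f", x$lambda),
              if (!is.null(x$beta)) sprintf(", beta = %.4g", x$beta) else "",
              x$loglik))
  invisible(x)
}

#' Fit a directional random-walk model
#'
#' Brownian motion with a directional drift: generalized least squares of
#' the tip values on an intercept and the root-to-tip path length h, with
#' residual covariance `sigma2 * V`. The drift coefficient `beta` (trait
#' units per unit path length) is identifiable only on non-ultrametric trees
#' (phylograms), where root-to-tip path lengths vary; ultrametric trees are
#' rejected.
#'
#' @inheritParams fit_brownian
#' @param lam fixed lambda for the residual covariance (default 1).
#' @return a `brownian_fit` with a non-NULL `beta`.
#' @export
fit_directional <- function(y, tree, lam = 1, vcv = NULL) {
  V0 <- unclass(vcv %||% vcv_from_tree(tree))
  y <- .order_trait(y, tree)
  h <- diag(V0)
  if (sd(h) < 1e-8 * mean(h))
    .stop2("identifiability_error",
           "tree is ultrametric (equal root-to-tip paths); %s",
           "directional drift is unidentifiable")
  X <- cbind(1, h)
  fit <- .profile_loglik(y, X, .lam_V(V0, lam))
  structure(list(alpha = fit$beta[[1L]], sigma2 = fit$sigma2, lambda = lam,
                 beta = fit$beta[[2L]], loglik = fit$loglik, n_params = 3L,
                 model = "directional", flat_profile = FALSE, n = length(y)),
            class = "brownian_fit")
}

#' Likelihood-ratio test between nested models
#'
#' Statistic `2 * (loglik_alt - loglik_null)` (clipped at zero), referred to
#' the upper tail of a chi-squared distribution with `df` degrees of freedom
#' (the difference in estimated parameter counts between the nested models).
#'
#' @param loglik_alt log-likelihood of the richer model.
#' @param loglik_null log-likelihood of the nested null model.
#' @param df degrees of freedom, >= 1.
#' @return a list with `statistic` and `p`.
#' @export
lr_test <- function(loglik_alt, loglik_null, df) {
  if (!is.numeric(df) || length(df) != 1L || df < 1)
    .stop2("invalid_parameter", "df must be >= 1")
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  list(statistic = stat, p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Pagel's lambda phylogenetic-signal test
#'
#' The four-step procedure for a continuous trait on a phylogram:
#' (i) estimate lambda by maximum likelihood; (ii) refit with lambda fixed
#' at 1 and (iii) compare by likelihood-ratio test (chi-squared, df = 1) -
#' is the signal weaker than the Brownian expectation?; (iv) refit with
#' lambda fixed at 0 and compare - is there any signal at all? A trait that
#' is constant across tips is degenerate: `sigma2 = 0` is reported and the
#' tests are skipped.
#'
#' @inheritParams fit_brownian
#' @return an object of class `signal_test`: `lambda_ml`, `loglik_ml`,
#'   `loglik_lambda0`, `loglik_lambda1`, `p_vs_0`, `p_vs_1`, `degenerate`,
#'   plus the three underlying fits.
#' @export
lambda_signal_test <- function(y, tree, vcv = NULL) {
  y_ord <- .order_trait(y, tree)
  if (length(y_ord) < 4L) .stop2("invalid_input", "need at least 4 tips")
  if (var(y_ord) == 0) {
    return(structure(list(lambda_ml = NA_real_, loglik_ml = NA_real_,
                          loglik_lambda0 = NA_real_,
                          loglik_lambda1 = NA_real_,
                          p_vs_0 = NA_real_, p_vs_1 = NA_real_,
                          degenerate = TRUE, sigma2 = 0),
                     class = "signal_test"))
  }
  V0 <- vcv %||% vcv_from_tree(tree)
  fit_ml <- fit_brownian(y, tree, lam_mode = "ML", vcv = V0)
  fit0 <- fit_brownian(y, tree, lam_mode = 0, vcv = V0)
  fit1 <- fit_brownian(y, tree, lam_mode = 1, vcv = V0)
  structure(list(lambda_ml = fit_ml$lambda, loglik_ml = fit_ml$loglik,
                 loglik_lambda0 = fit0$loglik, loglik_lambda1 = fit1$loglik,
                 p_vs_0 = lr_test(fit_ml$loglik, fit0$loglik, 1L)$p,
                 p_vs_1 = lr_test(fit_ml$loglik, fit1$loglik, 1L)$p,
                 degenerate = FALSE, sigma2 = fit_ml$sigma2,
                 fit_ml = fit_ml, fit_lambda0 = fit0, fit_lambda1 = fit1),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<signal_test: degenerate (constant trait), sigma2 = 0>\n")
    return(invisible(x))
  }
  cat(sprintf("<signal_test: lambda_ML = %s, p(lambda=0) = %.4g, p(lambda=1) = %.4g>\n",
              if (is.na(x$lambda_ml)) "NA (flat profile)" else
                sprintf("%.3f", x$lambda_ml), x$p_vs_0, x$p_vs_1))
  invisible(x)
}

#' Brownian vs directional random-walk comparison
#'
#' Fits the one-parameter constant-variance Brownian model (null) and the
#' two-parameter directional random-walk model (alternative) at lambda = 1
#' and compares them by likelihood-ratio test with df = 1.
#'
#' @inheritParams fit_brownian
#' @return list with both fits, `statistic` and `p`.
#' @export
directional_test <- function(y, tree, vcv = NULL) {
  V0 <- vcv %||% vcv_from_tree(tree)
  bm <- fit_brownian(y, tree, lam_mode = 1, vcv = V0)
  dir <- fit_directional(y, tree, lam = 1, vcv = V0)
  lrt <- lr_test(dir$loglik, bm$loglik, 1L)
  list(fit_bm = bm, fit_directional = dir,
       statistic = lrt$statistic, p = lrt$p)
}
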