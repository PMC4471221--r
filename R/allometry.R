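# Allometric regression: OLS, RMA, PGLS with simultaneous lambda, AIC
# ranking, residual diagnostics, fossil expected values.

.new_regression_fit <- function(method, coefficients, lambda, loglik, k,
                                r_squared, residuals, fitted, response,
                                predictors, species = NULL, log_base = NA,
                                extra = list()) {
  out <- c(list(method = method, coefficients = coefficients,
                lambda = lambda, loglik = loglik, k = k,
                aic = if (is.na(loglik)) NA_real_ else 2 * k - 2 * loglik,
                r_squared = r_squared, residuals = residuals,
                fitted = fitted, response = response,
                predictors = predictors, species = species,
                log_base = log_base), extra)
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<%s fit of %s ~ %s>\n", x$method, x$response,
              paste(x$predictors, collapse = " + ")))
  print(round(x$coefficients, 6))
  cat(sprintf("  R2 = %.4f%s%s\n", x$r_squared,
              if (!is.na(x$aic)) sprintf(", AIC = %.3f", x$aic) else "",
              if (!is.na(x$lambda)) sprintf(", lambda = %.3f", x$lambda)
              else ""))
  invisible(x)
}

.design_matrix <- function(X, n) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) .stop2("invalid_input", "X and y lengths disagree")
  X
}

#' Ordinary least squares with Gaussian log-likelihood and AIC
#'
#' OLS regression with intercept. The log-likelihood is the maximised iid
#' Gaussian likelihood (ML variance estimate, denominator n), and the AIC
#' parameter count includes the intercept, the slopes and the error
#' variance: `AIC = 2k - 2 logLik` with `k = ncol(X) + 2`.
#'
#' @param y response vector.
#' @param X predictor vector or matrix (intercept added internally).
#' @param response,species optional labels carried into the fit.
#' @param log_base base of the log transform already applied to the inputs
#'   (recorded so [predict_expected()] can back-transform; `NA` if none).
#' @return a `regression_fit` (method `"OLS"`).
#' @export
ols_fit <- function(y, X, response = "y", species = NULL, log_base = NA) {
  y <- as.numeric(y)
  X <- .design_matrix(X, length(y))
  if (length(y) <= ncol(X) + 1L)
    .stop2("invalid_input", "need n > number of coefficients")
  Xd <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd))
    .stop2("collinearity_error", "predictors are collinear")
  beta <- qr.coef(qx, y)
  fitted <- drop(Xd %*% beta)
  res <- y - fitted
  n <- length(y)
  s2 <- sum(res^2) / n
  ll <- -n / 2 * (log(2 * pi) + log(s2) + 1)
  tss <- sum((y - mean(y))^2)
  .new_regression_fit("OLS", beta, NA_real_, ll, ncol(Xd) + 1L,
                      if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
                      res, fitted, response, colnames(X), species, log_base)
}

#' Reduced major axis regression
#'
#' Symmetric bivariate line fit appropriate when the x variable also carries
#' error: slope `sign(r) * sd(y)/sd(x)`, intercept through the bivariate
#' mean. The algebraic identity `|slope_RMA| = |slope_OLS| / |r|` holds
#' exactly. RMA has no associated likelihood, so `loglik` and `aic` are `NA`.
#'
#' @param y,x numeric vectors with non-zero variance.
#' @inheritParams ols_fit
#' @return a `regression_fit` (method `"RMA"`).
#' @export
rma_fit <- function(y, x, response = "y", species = NULL, log_base = NA) {
  y <- as.numeric(y); x <- as.numeric(x)
  if (length(y) != length(x) || length(y) < 3L)
    .stop2("invalid_input", "x and y must be equal-length vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    .stop2("invalid_input", "RMA requires non-zero variance in x and y")
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (r == 0) slope <- sd(y) / sd(x)  # sign undefined at r = 0
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  res <- y - fitted
  .new_regression_fit("RMA", c(`(Intercept)` = intercept, x = slope),
                      NA_real_, NA_real_, NA_integer_, r^2, res, fitted,
                      response, "x", species, log_base)
}

#' Phylogenetic generalized least squares with simultaneous lambda
#'
#' GLS regression `beta = (X' V^-1 X)^-1 X' V^-1 y` with residual covariance
#' `sigma2 * V(lambda)`; lambda is either fixed or profiled by ML over
#' [0, 1] simultaneously with the coefficients. R-squared is defined against
#' the intercept-only PGLS fit evaluated at the same lambda. The AIC
#' parameter count is the coefficients + the residual variance + 1 when
#' lambda is estimated. At `lambda = 0` on an ultrametric tree PGLS reduces
#' exactly to OLS.
#'
#' @param y response vector, named or ordered as `tree$tip.label`.
#' @param X predictor vector/matrix in the same order.
#' @param tree a `phylo` phylogram aligned with the data.
#' @param lam_mode `"ML"` or a fixed lambda in [0, 1].
#' @param response optional response label carried into the fit.
#' @inheritParams ols_fit
#' @param vcv optional precomputed [vcv_from_tree()] matrix.
#' @return a `regression_fit` (method `"PGLS"`) with `lambda` filled.
#' @export
pgls_fit <- function(y, X, tree, lam_mode = "ML", response = "y",
                     log_base = NA, vcv = NULL) {
  V0 <- unclass(vcv %||% vcv_from_tree(tree))
  y <- .order_trait(y, tree)
  n <- length(y)
  X <- .design_matrix(X, n)
  if (n <= ncol(X) + 1L) .stop2("invalid_input", "need n > k")
  Xd <- cbind(`(Intercept)` = 1, X)
  f <- function(lam) .profile_loglik(y, Xd, .lam_V(V0, lam))$loglik
  if (identical(lam_mode, "ML")) {
    opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1)
    ll <- c(f(0), opt$objective, f(1))
    lam <- cand[which.max(ll)]
    k_lam <- 1L
  } else {
    .check_number(lam_mode, "lam_mode", lower = 0, upper = 1)
    lam <- lam_mode
    k_lam <- 0L
  }
  Vl <- .lam_V(V0, lam)
  fit <- .profile_loglik(y, Xd, Vl)
  null_fit <- .profile_loglik(y, matrix(1, n, 1L), Vl)
  r2 <- if (null_fit$rss > 0) 1 - fit$rss / null_fit$rss else NA_real_
  fitted <- drop(Xd %*% fit$beta)
  res <- y - fitted
  out <- .new_regression_fit("PGLS", setNames(fit$beta, colnames(Xd)),
                             lam, fit$loglik, ncol(Xd) + 1L + k_lam, r2,
                             res, fitted, response, colnames(X),
                             tree$tip.label, log_base,
                             extra = list(whitened_residuals = fit$resw,
                                          sigma2 = fit$sigma2))
  out
}

#' Rank regression fits by AIC
#'
#' Orders fits of the same response by ascending AIC (best first). Fits
#' without a likelihood (RMA) cannot be ranked and are rejected; mixing
#' responses is an error because AIC comparisons are only meaningful on the
#' same data.
#'
#' @param fits a list of `regression_fit` objects.
#' @return the list reordered, with a `ranking` attribute data frame
#'   (method, predictors, k, loglik, aic, delta_aic).
#' @export
model_select_aic <- function(fits) {
  if (inherits(fits, "regression_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "regression_fit")))
    .stop2("invalid_input", "expected a list of regression_fit objects")
  resp <- vapply(fits, `[[`, "", "response")
  if (length(unique(resp)) > 1L)
    .stop2("invalid_comparison", "fits have different responses: %s",
           paste(unique(resp), collapse = ", "))
  aics <- vapply(fits, `[[`, 0, "aic")
  if (anyNA(aics))
    .stop2("invalid_comparison",
           "fit without a likelihood (e.g. RMA) cannot be AIC-ranked")
  ord <- order(aics)
  fits <- fits[ord]
  attr(fits, "ranking") <- data.frame(
    method = vapply(fits, `[[`, "", "method"),
    predictors = vapply(fits, function(f)
      paste(f$predictors, collapse = "+"), ""),
    k = vapply(fits, `[[`, 0L, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = aics[ord],
    delta_aic = aics[ord] - min(aics))
  fits
}

#' Standardized residuals and outlier flags
#'
#' OLS/RMA: raw residual divided by the sample standard deviation of the
#' residuals (so the standardized values have sd 1). PGLS: the
#' V(lambda)-whitened residual divided by its sample sd, so phylogenetic
#' correlation is removed before standardisation. Species at least two
#' standard deviations from the line are flagged.
#'
#' @param fit a `regression_fit`.
#' @param threshold flag threshold in sd units (default 2).
#' @return data frame with `species`, `residual`, `std_residual`, `flagged`.
#' @export
standardized_residuals <- function(fit, threshold = 2) {
  if (!inherits(fit, "regression_fit"))
    .stop2("invalid_input", "expected a regression_fit")
  res <- if (fit$method == "PGLS") fit$whitened_residuals else fit$residuals
  s <- sd(res)
  # an (effectively) perfect fit standardises to zero, not to noise/noise
  tol <- 1e-10 * (1 + sd(fit$fitted))
  z <- if (s > tol) res / s else rep(0, length(res))
  data.frame(species = fit$species %||% paste0("obs", seq_along(res)),
             residual = fit$residuals, std_residual = z,
             flagged = abs(z) >= threshold)
}

#' Expected trait value for a body mass
#'
#' Evaluates an allometric fit (on log-log scale) at a given body mass and
#' back-transforms to original trait units. Used to ask what trait value a
#' fossil of known estimated mass "should" have under the interspecific
#' allometry.
#'
#' @param fit a `regression_fit` from log-transformed data (single
#'   predictor; `log_base` recorded at fit time).
#' @param body_mass body mass in kg, > 0 (vectorised).
#' @return expected trait value(s) in original units.
#' @export
predict_expected <- function(fit, body_mass) {
  if (!inherits(fit, "regression_fit"))
    .stop2("invalid_input", "expected a regression_fit")
  if (any(!is.finite(body_mass)) || any(body_mass <= 0))
    .stop2("invalid_input", "body mass must be strictly positive")
  if (length(fit$coefficients) != 2L)
    .stop2("invalid_input",
           "predict_expected needs a bivariate (mass-only) fit")
  b <- fit$log_base
  if (is.na(b))
    .stop2("invalid_input",
           "fit does not record a log base; refit with log_base set")
  lp <- fit$coefficients[[1L]] + fit$coefficients[[2L]] *
    log(body_mass, base = b)
  b^lp
}

#' Diagnostic tables for a regression fit
#'
#' Emits the data behind standard residual diagnostics as plain tables:
#' residual vs fitted pairs, residual histogram counts, and
#' probability-probability (P-P) quantile pairs against the standard normal,
#' so diagnostic plots can be regenerated without refitting.
#'
#' @param fit a `regression_fit`.
#' @param bins number of histogram bins.
#' @return list of data frames `residual_vs_fitted`, `histogram`, `pp`.
#' @export
regression_diagnostics <- function(fit, bins = 10L) {
  sr <- standardized_residuals(fit)
  z <- sort(sr$std_residual)
  n <- length(z)
  br <- seq(min(z), max(z), length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(z, br, rightmost.closed = TRUE),
                          bins), nbins = bins)
  list(residual_vs_fitted = data.frame(fitted = fit$fitted,
                                       std_residual = sr$std_residual),
       histogram = data.frame(bin_low = br[-length(br)], bin_high = br[-1L],
                              count = counts),
       pp = data.frame(theoretical = pnorm(z),
                       empirical = (seq_len(n) - 0.5) / n))
}
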