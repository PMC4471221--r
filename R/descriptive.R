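# Descriptive statistics: Monte Carlo permutation t-tests, coefficients of
# variation, PCA with factor-map correlations.

.pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Monte Carlo permutation two-sample t-test
#'
#' Two-sided permutation test of identical distributions using the
#' pooled-variance two-sample t statistic (pooled, not Welch, because the
#' null asserts identical cumulative distribution functions). Group labels
#' are permuted; the p-value uses the add-one estimator
#' `(1 + #permuted |t| >= |t_obs|) / (n_perm + 1)`, which can never reach
#' zero. When the number of distinct label arrangements is at most `n_perm`
#' the test switches automatically to exhaustive enumeration and the
#' p-value is exact (`#{|t*| >= |t_obs|} / #arrangements`, which includes
#' the observed arrangement and so is also positive).
#'
#' @param a,b numeric samples, each with n >= 2.
#' @param n_perm number of random permutations (default 10,000).
#' @param seed RNG seed (mandatory: pipeline runs must be reproducible).
#' @param method `"auto"` (exhaustive when feasible), or force
#'   `"exhaustive"` / `"monte-carlo"` (the latter is mainly for validating
#'   the sampler against the exact enumeration).
#' @return object of class `permutation_result`: `statistic`, `p`,
#'   `n_permutations`, `exhaustive`, `seed`.
#' @export
permutation_ttest <- function(a, b, n_perm = 10000L, seed = 1L,
                              method = c("auto", "exhaustive",
                                         "monte-carlo")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    .stop2("invalid_input", "each sample needs at least 2 observations")
  t_obs <- .pooled_t(a, b)
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  tol <- 1e-12 * max(1, abs(t_obs))
  n_arr <- choose(n, na)
  if (method == "exhaustive" ||
      (method == "auto" && n_arr <= n_perm)) {
    idx <- combn(n, na)
    ts <- apply(idx, 2L, function(i) .pooled_t(pool[i], pool[-i]))
    p <- mean(abs(ts) >= abs(t_obs) - tol)
    out <- list(statistic = t_obs, p = p, n_permutations = n_arr,
                exhaustive = TRUE, seed = seed)
  } else {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pi <- sample.int(n, na)
      if (abs(.pooled_t(pool[pi], pool[-pi])) >= abs(t_obs) - tol)
        hits <- hits + 1L
    }
    out <- list(statistic = t_obs, p = (1 + hits) / (n_perm + 1),
                n_permutations = n_perm, exhaustive = FALSE, seed = seed)
  }
  class(out) <- "permutation_result"
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation t-test: t = %.4f, p = %.5f (%s, %d arrangements)>\n",
              x$statistic, x$p,
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$n_permutations))
  invisible(x)
}

#' Pairwise permutation-test matrix for two traits
#'
#' Runs [permutation_ttest()] on every pair of groups for two traits and
#' lays the p-values out as a single square matrix: the first trait on the
#' upper triangle, the second on the lower (the conventional two-trait
#' pairwise table). Pairs where either group has fewer than 2 observations
#' are left `NA`.
#'
#' @param data data frame of specimen-level values.
#' @param group name of the grouping (species) column.
#' @param trait_upper,trait_lower trait column names.
#' @inheritParams permutation_ttest
#' @return list: `p_matrix` (square, groups x groups), `significant`
#'   (logical matrix at 5%).
#' @export
pairwise_permutation_matrix <- function(data, group, trait_upper,
                                        trait_lower, n_perm = 10000L,
                                        seed = 1L) {
  g <- as.character(data[[group]])
  levs <- unique(g)
  k <- length(levs)
  P <- matrix(NA_real_, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    for (tr in c(trait_upper, trait_lower)) {
      x <- data[[tr]][g == levs[i]]; y <- data[[tr]][g == levs[j]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) >= 2L && length(y) >= 2L) {
        p <- permutation_ttest(x, y, n_perm = n_perm,
                               seed = seed + i * 1000L + j)$p
        if (tr == trait_upper) P[i, j] <- p else P[j, i] <- p
      }
    }
  }
  list(p_matrix = P, significant = P <= 0.05)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the sample
#' mean. Dimensionless and scale-invariant; conventionally reported to two
#' decimals (use [.round_half_up] semantics at the reporting layer only).
#'
#' @param x numeric sample, n >= 2, non-zero mean.
#' @return the CV.
#' @export
coefficient_of_variation <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L)
    .stop2("invalid_input", "CV needs at least 2 observations")
  m <- mean(x)
  if (m == 0) .stop2("undefined_cv", "CV is undefined for zero-mean data")
  sd(x) / m
}

#' Principal component analysis with a factor map
#'
#' Eigen-decomposition of the correlation (default, because cochlear
#' variables mix units: mm, turns, mm^2) or covariance matrix of a complete
#' specimen-by-variable matrix. Returns the percent variance per component,
#' specimen scores, orthonormal loadings, and the factor map: the Pearson
#' correlation of each input variable with each component's scores. Signs
#' are fixed so each component's largest-magnitude loading is positive.
#'
#' @param traits numeric matrix/data frame, rows = specimens, columns =
#'   variables; must be complete (no NA) with more rows than variables.
#' @param scale_mode `"correlation"` or `"covariance"`.
#' @return a `pca_result`: `percent_variance`, `scores`, `loadings`,
#'   `factor_map`, `scale_mode`.
#' @export
pca <- function(traits, scale_mode = c("correlation", "covariance")) {
  scale_mode <- match.arg(scale_mode)
  M <- as.matrix(traits)
  if (anyNA(M))
    .stop2("missing_values",
           "trait matrix contains NA; filter to complete cases first")
  if (nrow(M) <= ncol(M))
    .stop2("invalid_input", "need more specimens than variables")
  pc <- prcomp(M, center = TRUE, scale. = scale_mode == "correlation")
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  fm <- suppressWarnings(cor(M, scores))
  fm[!is.finite(fm)] <- 0  # zero-variance component scores
  structure(list(percent_variance = pv, scores = scores, loadings = rot,
                 factor_map = fm, scale_mode = scale_mode),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result (%s): PC variance %% = %s>\n", x$scale_mode,
              paste(sprintf("%.1f", head(x$percent_variance, 5L)),
                    collapse = ", ")))
  invisible(x)
}
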