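# Ancestral-state reconstruction under (lambda-scaled) Brownian motion:
# exact Gaussian conditionals, a Metropolis-within-Gibbs MCMC sampler, and
# fossil Z-score placement.

# Joint shared-path matrix over tips and internal nodes, under Pagel's
# lambda: entry (a, b) is lambda * depth(MRCA(a, b)) except the tip diagonal,
# which keeps the full root-to-tip depth. Internal nodes sit on fully
# internal paths, so their variances and covariances all scale with lambda.
.joint_path_matrix <- function(tree, lam = 1) {
  M <- ape::mrca(tree, full = TRUE)
  depths <- ape::node.depth.edgelength(tree)
  S <- matrix(depths[M], nrow(M), ncol(M))
  n <- length(tree$tip.label)
  C <- S * lam
  diag(C)[seq_len(n)] <- depths[seq_len(n)]
  C
}

# Resolve a node specification to an ape node id: integer id, "root", or a
# character vector of tip labels (their MRCA).
.resolve_node <- function(tree, node) {
  n <- length(tree$tip.label)
  if (identical(node, "root")) return(n + 1L)
  if (is.character(node)) {
    miss <- setdiff(node, tree$tip.label)
    if (length(miss))
      .stop2("invalid_input", "unknown tips in node spec: %s",
             paste(miss, collapse = ", "))
    if (length(node) == 1L) return(match(node, tree$tip.label))
    return(ape::getMRCA(tree, node))
  }
  node <- as.integer(node)
  if (node < 1L || node > n + tree$Nnode)
    .stop2("invalid_input", "node id %d out of range", node)
  node
}

# Short human-readable label for an internal node: its descendant tip set.
.node_label <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  tips <- ape::extract.clade(tree, node)$tip.label
  if (length(tips) <= 3L) paste(tips, collapse = "|")
  else sprintf("%s|...|%s(%d tips)", tips[1L], tips[length(tips)],
               length(tips))
}

#' Exact Gaussian ancestral-state conditional (analytic oracle)
#'
#' Under Brownian motion with fixed parameters, the joint distribution of
#' the tip values and any internal-node state is multivariate normal with
#' covariances given by shared root-to-MRCA path lengths. The conditional
#' distribution of the node state given the tips is therefore Gaussian with
#' closed-form mean and standard deviation; at the root the conditional mean
#' is the phylogenetically weighted mean `(1' V^-1 y)/(1' V^-1 1)`. This is
#' the independent oracle against which [mcmc_ancestral()] is validated.
#'
#' @param y tip trait vector (named or in `tree$tip.label` order).
#' @param tree a `phylo` phylogram.
#' @param sigma2 Brownian rate, > 0.
#' @param alpha root state; `NULL` (default) marginalises the root state
#'   over a flat prior, in which case the root's conditional mean is exactly
#'   the phylogenetically weighted mean and its variance
#'   `sigma2 / (1' V^-1 1)`.
#' @param lam Pagel's lambda in [0, 1].
#' @param node node spec: ape node id, `"root"`, or character vector of tip
#'   labels whose MRCA is used.
#' @return list with `mean`, `sd`, `node` (ape id).
#' @export
analytic_ancestral <- function(y, tree, sigma2, alpha = NULL, lam = 1,
                               node = "root") {
  .check_number(sigma2, "sigma2", positive = TRUE)
  .check_number(lam, "lam", lower = 0, upper = 1)
  y <- .order_trait(y, tree)
  n <- length(y)
  node_id <- .resolve_node(tree, node)
  C <- .joint_path_matrix(tree, lam)
  Ctt <- C[seq_len(n), seq_len(n), drop = FALSE]
  cnt <- C[node_id, seq_len(n)]
  one <- rep(1, n)
  sol <- tryCatch(solve(Ctt, cbind(cnt, y, one)),
                  error = function(e)
                    .stop2("numerical_error",
                           "singular joint covariance: %s",
                           conditionMessage(e)))
  if (is.null(alpha)) {
    # flat prior on the root state: alpha-hat = GLS mean, and the node
    # variance gains the alpha uncertainty through the shrinkage weight
    alpha_hat <- sum(one * sol[, 2L]) / sum(one * sol[, 3L])
    m <- alpha_hat + sum(cnt * (sol[, 2L] - alpha_hat * sol[, 3L]))
    w <- 1 - sum(cnt * sol[, 3L])
    v <- sigma2 * (C[node_id, node_id] - sum(cnt * sol[, 1L]) +
                     w^2 / sum(one * sol[, 3L]))
  } else {
    .check_number(alpha, "alpha")
    m <- alpha + sum(cnt * (sol[, 2L] - alpha * sol[, 3L]))
    v <- sigma2 * (C[node_id, node_id] - sum(cnt * sol[, 1L]))
  }
  list(mean = m, sd = sqrt(max(v, 0)), node = node_id)
}

#' MCMC chain settings for ancestral reconstruction
#'
#' Defaults follow long-chain practice for small comparative data sets:
#' 110,000 iterations with 10,000 discarded as burn-in and thinning every
#' 20, giving 5,000 retained posterior draws.
#'
#' @param iterations total MCMC iterations.
#' @param burnin iterations discarded from the front.
#' @param thin keep every `thin`-th iteration after burn-in.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param proposal_sd random-walk sd for the lambda update.
#' @param fixed named list; any of `alpha`, `sigma2`, `lambda` held fixed
#'   instead of sampled (used for oracle comparisons).
#' @param min_ess effective-sample-size threshold below which a convergence
#'   warning is emitted.
#' @return a list of chain settings.
#' @export
mcmc_config <- function(iterations = 110000L, burnin = 10000L, thin = 20L,
                        seed = 1L, proposal_sd = 0.08,
                        fixed = list(), min_ess = 100) {
  stopifnot(iterations > burnin, thin >= 1L)
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       thin = as.integer(thin), seed = as.integer(seed),
       proposal_sd = proposal_sd, fixed = fixed, min_ess = min_ess)
}

# crude initial-sequence effective sample size
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf[-1L]
  pos <- which(rho < 0.05)
  cut <- if (length(pos)) pos[1L] else length(rho)
  n / (1 + 2 * sum(rho[seq_len(cut)]))
}

#' Bayesian MCMC ancestral-state reconstruction
#'
#' Samples the posterior of the lambda-scaled Brownian model parameters -
#' root state alpha (flat prior), rate sigma2 (Jeffreys 1/sigma2 prior) and
#' lambda (uniform on [0, 1]) - by Metropolis-within-Gibbs: alpha and sigma2
#' have conjugate Gaussian / inverse-gamma full conditionals and are sampled
#' exactly, lambda by random-walk Metropolis. At every retained iteration
#' the internal-node states are drawn jointly from their exact Gaussian full
#' conditional given the current parameters, so node posteriors integrate
#' over parameter uncertainty. Fossils never enter the reconstruction; they
#' are compared post hoc with [zscore_fossil()].
#'
#' @param y tip trait vector (named or in tip order).
#' @param tree a `phylo` phylogram with >= 4 tips.
#' @param config chain settings from [mcmc_config()].
#' @param nodes internal nodes to reconstruct (ape ids); default all.
#' @return an `ancestral_posterior` object: `params` (retained draws of
#'   alpha, sigma2, lambda), `nodes` (matrix of node-state draws), `summary`
#'   (per node: label, mean, sd, 2.5/97.5 percentiles), `ess`, `config`.
#' @export
mcmc_ancestral <- function(y, tree, config = mcmc_config(), nodes = NULL) {
  y <- .order_trait(y, tree)
  n <- length(y)
  if (n < 4L) .stop2("invalid_input", "need at least 4 tips")
  set.seed(config$seed)
  n_all <- n + tree$Nnode
  node_ids <- if (is.null(nodes)) seq.int(n + 1L, n_all) else
    vapply(nodes, function(nd) .resolve_node(tree, nd), 1L)
  S <- .joint_path_matrix(tree, lam = 1)     # lambda applied on the fly
  depths <- ape::node.depth.edgelength(tree)
  tipd <- depths[seq_len(n)]

  fx <- config$fixed
  lam <- fx$lambda %||% 0.5
  sig2 <- fx$sigma2 %||% var(y)
  if (sig2 <= 0) sig2 <- 1e-6
  alpha <- fx$alpha %||% mean(y)

  tip_cov <- function(l) {
    Ct <- S[seq_len(n), seq_len(n)] * l
    diag(Ct) <- tipd
    Ct
  }
  # cached tip-covariance Cholesky for the current lambda
  Ut <- chol(tip_cov(lam))
  loglik_state <- function(U, a, s2) {
    z <- backsolve(U, y - a, transpose = TRUE)
    -n / 2 * log(2 * pi * s2) - sum(log(diag(U))) - sum(z^2) / (2 * s2)
  }

  keep <- seq.int(config$burnin + config$thin, config$iterations,
                  by = config$thin)
  n_keep <- length(keep)
  params <- matrix(NA_real_, n_keep, 3L,
                   dimnames = list(NULL, c("alpha", "sigma2", "lambda")))
  node_draws <- matrix(NA_real_, n_keep, length(node_ids),
                       dimnames = list(NULL, paste0("node_", node_ids)))
  acc <- 0L; k <- 0L
  for (it in seq_len(config$iterations)) {
    if (is.null(fx$lambda)) {
      lam_prop <- lam + rnorm(1L, 0, config$proposal_sd)
      if (lam_prop >= 0 && lam_prop <= 1) {
        U_prop <- chol(tip_cov(lam_prop))
        if (log(runif(1L)) < loglik_state(U_prop, alpha, sig2) -
              loglik_state(Ut, alpha, sig2)) {
          lam <- lam_prop; Ut <- U_prop; acc <- acc + 1L
        }
      }
    }
    one_w <- backsolve(Ut, rep(1, n), transpose = TRUE)
    y_w <- backsolve(Ut, y, transpose = TRUE)
    if (is.null(fx$sigma2)) {
      r_w <- y_w - alpha * one_w
      sig2 <- sum(r_w^2) / (2 * rgamma(1L, shape = n / 2, rate = 1))
    }
    if (is.null(fx$alpha)) {
      prec <- sum(one_w^2)
      alpha <- rnorm(1L, sum(one_w * y_w) / prec, sqrt(sig2 / prec))
    }
    if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
      k <- k + 1L
      params[k, ] <- c(alpha, sig2, lam)
      Cl <- S * lam
      diag(Cl)[seq_len(n)] <- tipd
      cnt <- Cl[node_ids, seq_len(n), drop = FALSE]
      W <- backsolve(Ut, t(cnt), transpose = TRUE)      # Lt^-1 Ctn
      mu <- alpha + drop(crossprod(W, y_w - alpha * one_w))
      Sig <- sig2 * (Cl[node_ids, node_ids, drop = FALSE] - crossprod(W))
      Us <- tryCatch(chol(Sig + diag(1e-12, nrow(Sig))),
                     error = function(e) NULL)
      node_draws[k, ] <- if (is.null(Us))
        mu + sqrt(pmax(diag(Sig), 0)) * rnorm(length(mu))
      else mu + drop(crossprod(Us, rnorm(length(mu))))
    }
  }

  ess <- c(alpha = .ess(params[, 1L]), sigma2 = .ess(params[, 2L]),
           lambda = if (is.null(fx$lambda)) .ess(params[, 3L]) else NA)
  if (any(ess[!is.na(ess)] < config$min_ess))
    warning(sprintf(
      "low effective sample size (min %.0f < %g); lengthen the chain",
      min(ess, na.rm = TRUE), config$min_ess))

  summ <- data.frame(
    node = node_ids,
    label = vapply(node_ids, function(nd) .node_label(tree, nd), ""),
    mean = colMeans(node_draws),
    sd = apply(node_draws, 2L, sd),
    q2.5 = apply(node_draws, 2L, quantile, 0.025),
    q97.5 = apply(node_draws, 2L, quantile, 0.975),
    row.names = NULL)
  structure(list(params = as.data.frame(params), nodes = node_draws,
                 summary = summ, ess = ess,
                 accept_lambda = if (is.null(fx$lambda))
                   acc / config$iterations else NA,
                 config = config, tree = tree),
            class = "ancestral_posterior")
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat(sprintf("<ancestral_posterior: %d retained draws, %d nodes>\n",
              nrow(x$params), ncol(x$nodes)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Z-score placement of a fossil value against a node posterior
#'
#' Standardises a fossil trait value against the posterior distribution of
#' an ancestral node: `z = (fossil - posterior mean) / posterior sd`, with a
#' one-tailed standard-normal p-value on the side the fossil lies
#' (right tail for values above the posterior mean, left below), and a
#' significance flag at the 5% level.
#'
#' @param fossil_value the fossil trait value (original units).
#' @param posterior an `ancestral_posterior` (with `node` naming which
#'   reconstruction to use) or any list with `mean` and `sd` fields, e.g.
#'   the output of [analytic_ancestral()].
#' @param node node id (ape numbering) when `posterior` covers several.
#' @param tail `"auto"` (side of the fossil), `"left"` or `"right"`.
#' @param fossil,trait optional labels carried into the result.
#' @return one-row data frame: fossil, trait, node, z, p, tail, significant.
#' @export
zscore_fossil <- function(fossil_value, posterior, node = NULL,
                          tail = c("auto", "left", "right"),
                          fossil = "fossil", trait = "trait") {
  tail <- match.arg(tail)
  if (inherits(posterior, "ancestral_posterior")) {
    summ <- posterior$summary
    row <- if (is.null(node)) {
      if (nrow(summ) > 1L)
        .stop2("invalid_input", "posterior covers several nodes; give `node`")
      summ[1L, ]
    } else summ[match(node, summ$node), ]
    if (anyNA(row$mean)) .stop2("invalid_input", "unknown node %s", node)
    m <- row$mean; s <- row$sd; node_lab <- row$label
  } else {
    m <- posterior$mean; s <- posterior$sd
    node_lab <- as.character(node %||% posterior$node %||% NA)
  }
  if (!is.finite(s) || s <= 0)
    .stop2("degenerate_posterior", "posterior sd must be > 0")
  z <- (fossil_value - m) / s
  if (tail == "auto") tail <- if (z >= 0) "right" else "left"
  p <- if (tail == "right") pnorm(z, lower.tail = FALSE) else pnorm(z)
  data.frame(fossil = fossil, trait = trait, node = node_lab, z = z, p = p,
             tail = tail, significant = p <= 0.05)
}
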