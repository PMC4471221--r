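# Synthetic-data generators with recorded ground truth: trees, Brownian
# traits, allometric species tables, parametric spirals and window outlines.

.new_truth <- function(generator, params, seed) {
  structure(list(generator = generator, params = params, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: %s, seed = %s>\n", x$generator,
              x$seed %||% "none"))
  str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Serialize ground truth next to a generated dataset
#'
#' @param truth a `synthetic_truth`.
#' @param file output JSON path.
#' @export
write_truth <- function(truth, file) {
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' Simulate a rooted tree
#'
#' Pure-birth (Yule) trees via \pkg{ape}, caterpillar (fully pectinate,
#' unit branch lengths, non-ultrametric by construction) and star trees.
#' An optional multiplicative lognormal branch-length jitter turns
#' ultrametric trees into phylograms, as needed by directional-model tests.
#'
#' @param n_tips number of tips, >= 2.
#' @param kind `"pure-birth"`, `"caterpillar"` or `"star"`.
#' @param seed RNG seed.
#' @param jitter_sd sd of the lognormal branch-length jitter (0 = none).
#' @return a `phylo` tree with tips `t1..tn` and positive branch lengths.
#' @export
simulate_tree <- function(n_tips, kind = c("pure-birth", "caterpillar",
                                           "star"),
                          seed = 1L, jitter_sd = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(n_tips) || n_tips < 2L)
    .stop2("invalid_input", "n_tips must be >= 2")
  n_tips <- as.integer(n_tips)
  set.seed(seed)
  tree <- switch(kind,
    "pure-birth" = ape::rphylo(n_tips, birth = 1, death = 0),
    "caterpillar" = {
      nk <- paste0("(t1:1,t2:1)")
      if (n_tips > 2L)
        for (i in 3:n_tips) nk <- sprintf("(%s:1,t%d:1)", nk, i)
      ape::read.tree(text = paste0(nk, ";"))
    },
    "star" = {
      s <- ape::stree(n_tips, type = "star")
      s$tip.label <- paste0("t", seq_len(n_tips))
      s$edge.length <- rep(1, nrow(s$edge))
      s
    })
  if (kind == "pure-birth") tree$tip.label <- paste0("t", seq_len(n_tips))
  if (jitter_sd > 0)
    tree$edge.length <- tree$edge.length *
      exp(rnorm(length(tree$edge.length), 0, jitter_sd))
  tree
}

#' Simulate Brownian tip values with known lambda
#'
#' Draws tip values from MVN(alpha * 1, sigma2 * V(lambda)) by recursive
#' simulation of independent Gaussian increments down the lambda-stretched
#' tree (all branches scaled by lambda, terminal branches extended by
#' (1 - lambda) times the tip depth, which reproduces the lambda transform
#' of the covariance matrix exactly). Internal-node states can be recorded
#' for ancestral-recovery tests.
#'
#' @param tree a `phylo` tree.
#' @param alpha root state.
#' @param sigma2 Brownian rate, >= 0.
#' @param lam Pagel's lambda in [0, 1].
#' @param seed RNG seed.
#' @param keep_internal record true internal-node states (attribute
#'   `node_states`).
#' @return named numeric tip vector with attributes `truth` and (optionally)
#'   `node_states`.
#' @export
simulate_bm_tips <- function(tree, alpha = 0, sigma2 = 1, lam = 1,
                             seed = 1L, keep_internal = FALSE) {
  if (sigma2 < 0) .stop2("invalid_input", "sigma2 must be >= 0")
  .check_number(lam, "lam", lower = 0, upper = 1)
  set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")  # preorder: parents first
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  states <- numeric(n + tree$Nnode)
  states[n + 1L] <- alpha
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    v <- if (child <= n) lam * len + (1 - lam) * depths[child]
         else lam * len
    states[child] <- states[par] + rnorm(1L, 0, sqrt(sigma2 * v))
  }
  y <- setNames(states[seq_len(n)], tree$tip.label)
  attr(y, "truth") <- .new_truth("simulate_bm_tips",
                                 list(alpha = alpha, sigma2 = sigma2,
                                      lambda = lam), seed)
  if (keep_internal)
    attr(y, "node_states") <- setNames(states[seq.int(n + 1L, n + tree$Nnode)],
                                       paste0("node_", seq.int(n + 1L,
                                                               n + tree$Nnode)))
  y
}

#' Simulate an allometrically structured species table
#'
#' Log10 body mass evolves by Brownian motion on the tree; the log10 trait
#' is `intercept + slope * log10(mass)` plus a phylogenetically structured
#' residual with Pagel's lambda `resid_lam` and average per-species standard
#' deviation `resid_sd` (the residual covariance is `resid_sd^2 *
#' V(lambda) / mean(diag V)` so the stated sd applies at the average tip
#' depth). The emitted table is back-transformed to original units and
#' carries clade tags from the root bipartition, mimicking a
#' hominoid/cercopithecoid split. An optional outlier species gets an
#' injected residual shift for flagging tests.
#'
#' @param tree a `phylo` tree.
#' @param slope,intercept allometric line on the log10-log10 scale.
#' @param resid_sd residual sd around the line (log10 units).
#' @param resid_lam lambda of the residual covariance.
#' @param seed RNG seed.
#' @param mass_alpha,mass_sigma2 Brownian parameters of log10 body mass
#'   (defaults: root at 10 kg, rate 0.2 per unit branch length).
#' @param trait_name column name for the trait.
#' @param outlier_species,outlier_shift optional species name and residual
#'   shift (in units of `resid_sd`) injected into its trait value.
#' @return data frame (species, body_mass_kg, trait, clade) with attribute
#'   `truth`.
#' @export
simulate_allometric_table <- function(tree, slope = 0.2, intercept = 1,
                                      resid_sd = 0.05, resid_lam = 1,
                                      seed = 1L, mass_alpha = 1,
                                      mass_sigma2 = 0.2,
                                      trait_name = "trait",
                                      outlier_species = NULL,
                                      outlier_shift = 0) {
  V <- unclass(vcv_from_tree(tree))
  scale_depth <- mean(diag(V))
  logmass <- simulate_bm_tips(tree, mass_alpha, mass_sigma2, 1, seed = seed)
  eps <- if (resid_sd > 0)
    simulate_bm_tips(tree, 0, resid_sd^2 / scale_depth, resid_lam,
                     seed = seed + 1L)
  else setNames(numeric(length(logmass)), names(logmass))
  logtrait <- intercept + slope * as.numeric(logmass) + as.numeric(eps)
  names(logtrait) <- names(logmass)
  if (!is.null(outlier_species)) {
    i <- match(outlier_species, names(logtrait))
    if (is.na(i)) .stop2("invalid_input", "unknown outlier species")
    logtrait[i] <- logtrait[i] + outlier_shift * resid_sd
  }
  n <- length(tree$tip.label)
  root_children <- tree$edge[tree$edge[, 1L] == n + 1L, 2L]
  first_clade <- if (root_children[1L] <= n) tree$tip.label[root_children[1L]]
    else ape::extract.clade(tree, root_children[1L])$tip.label
  clade <- ifelse(tree$tip.label %in% first_clade, "hominoid",
                  "cercopithecoid")
  df <- data.frame(species = tree$tip.label,
                   body_mass_kg = 10^as.numeric(logmass[tree$tip.label]),
                   trait = 10^as.numeric(logtrait[tree$tip.label]),
                   clade = clade)
  names(df)[3L] <- trait_name
  attr(df, "truth") <- .new_truth("simulate_allometric_table",
                                  list(slope = slope, intercept = intercept,
                                       resid_sd = resid_sd,
                                       resid_lam = resid_lam,
                                       mass_alpha = mass_alpha,
                                       mass_sigma2 = mass_sigma2,
                                       log_base = 10,
                                       outlier_species = outlier_species,
                                       outlier_shift = outlier_shift), seed)
  df
}

# random proper rotation matrix (Haar-ish via QR)
.random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Generate Archimedean spiral landmarks with known truth
#'
#' Archimedean spiral (radius linear in the winding angle) sampled at
#' equal angular steps, starting at the basal (larger-radius) end, with an
#' optional conical axial rise, isotropic Gaussian landmark noise, and a
#' random rigid rotation + translation (applied whenever a seed is given).
#' The recorded truth holds the generating parameters, the quadrature arc
#' length, the extreme-radius ratio, and the analytically expected measured
#' curvature ratio given full-turn circle fits (the mean radius over the
#' basal and apical turn windows used by [fit_turn_circles()]).
#'
#' @param turns number of turns, > 0.
#' @param r_start basal starting radius (mm), >= `r_end`.
#' @param r_end apical ending radius (mm), > 0.
#' @param points_per_turn landmark density (default 240).
#' @param axial_rise rise per turn along the spiral axis (mm).
#' @param noise_sd isotropic landmark noise sd (mm).
#' @param seed RNG seed; `NULL` leaves the spiral in canonical pose with no
#'   noise applied.
#' @return list with `path` (a spiral [landmark_path], base first) and
#'   `truth` (a `synthetic_truth`).
#' @export
generate_spiral_landmarks <- function(turns, r_start, r_end,
                                      points_per_turn = 240L,
                                      axial_rise = 0, noise_sd = 0,
                                      seed = NULL) {
  .check_number(turns, "turns", positive = TRUE)
  .check_number(r_end, "r_end", positive = TRUE)
  if (r_start < r_end)
    .stop2("invalid_input", "r_start must be >= r_end (base is wider)")
  th_max <- 2 * pi * turns
  n <- max(8L, round(points_per_turn * turns) + 1L)
  th <- seq(0, th_max, length.out = n)
  slope_r <- (r_end - r_start) / th_max
  r <- r_start + slope_r * th
  zp <- axial_rise / (2 * pi)
  pts <- cbind(r * cos(th), r * sin(th), zp * th)
  center <- c(0, 0, 0)
  if (!is.null(seed)) {
    set.seed(seed)
    R <- .random_rotation()
    shift <- runif(3L, -5, 5)
    pts <- sweep(pts %*% t(R), 2L, shift, `+`)
    center <- shift
    if (noise_sd > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, noise_sd), ncol = 3L)
  }
  ecl_true <- integrate(function(t)
    sqrt((r_start + slope_r * t)^2 + slope_r^2 + zp^2),
    0, th_max, rel.tol = 1e-10)$value
  w <- min(2 * pi, th_max / 2)
  r_at <- function(t) r_start + slope_r * t
  expected_cur <- ((r_at(0) + r_at(w)) / 2) /
    ((r_at(th_max - w) + r_at(th_max)) / 2)
  truth <- .new_truth("generate_spiral_landmarks",
                      list(turns = turns, r_start = r_start, r_end = r_end,
                           axial_rise = axial_rise, noise_sd = noise_sd,
                           ecl = ecl_true, cur_extremes = r_start / r_end,
                           cur_expected_measured = expected_cur,
                           center = center), seed)
  list(path = landmark_path(pts, role = "spiral", start = "base"),
       truth = truth)
}

#' Generate an elliptical oval-window outline with known area
#'
#' Ellipse outline sampled at equal parameter steps, tilted out of the xy
#' plane by `plane_tilt` degrees about the x axis, with optional landmark
#' noise and (when a seed is supplied) a random rigid rotation +
#' translation. The true area is `pi * a * b`, invariant to all rigid
#' motions.
#'
#' @param semi_major,semi_minor ellipse semi-axes (mm), `a >= b > 0`.
#' @param n_points number of outline points (default 360).
#' @param plane_tilt tilt angle in degrees.
#' @param noise_sd isotropic landmark noise sd (mm).
#' @param seed RNG seed; `NULL` = canonical pose, no noise.
#' @return list with `path` (window [landmark_path]) and `truth`.
#' @export
generate_window_outline <- function(semi_major, semi_minor,
                                    n_points = 360L, plane_tilt = 0,
                                    noise_sd = 0, seed = NULL) {
  .check_number(semi_minor, "semi_minor", positive = TRUE)
  if (semi_major < semi_minor)
    .stop2("invalid_input", "semi_major must be >= semi_minor")
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  pts <- cbind(semi_major * cos(t), semi_minor * sin(t), 0)
  tilt <- plane_tilt * pi / 180
  R_tilt <- rbind(c(1, 0, 0),
                  c(0, cos(tilt), -sin(tilt)),
                  c(0, sin(tilt), cos(tilt)))
  pts <- pts %*% t(R_tilt)
  if (!is.null(seed)) {
    set.seed(seed)
    pts <- pts %*% t(.random_rotation())
    pts <- sweep(pts, 2L, runif(3L, -5, 5), `+`)
    if (noise_sd > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, noise_sd), ncol = 3L)
  }
  truth <- .new_truth("generate_window_outline",
                      list(semi_major = semi_major, semi_minor = semi_minor,
                           plane_tilt = plane_tilt, noise_sd = noise_sd,
                           area = pi * semi_major * semi_minor), seed)
  list(path = landmark_path(pts, role = "window"), truth = truth)
}
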