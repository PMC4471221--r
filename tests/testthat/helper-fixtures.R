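# Shared fixtures and independent oracles used across the test files.

# rotation matrix from Euler angles (independent of the package's internals)
rot_xyz <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# circular arc / multi-turn circle path in the z = z0 plane
circle_path <- function(r = 1, turns = 1, n = 100, z0 = 0, center = c(0, 0),
                        closed_tol = FALSE) {
  th <- seq(0, 2 * pi * turns, length.out = n)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th), z0)
}

# Kasa algebraic least-squares circle fit (oracle for spiral_center)
kasa_circle_center <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  coefs <- qr.coef(qr(A), b)
  coefs[1:2]
}

# brute-force shared-path-length matrix by walking root-to-tip paths
vcv_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- n + 1L
  anc_path <- function(i) {       # ancestors from node up to root
    out <- integer(0)
    while (i != root) { out <- c(out, i); i <- parent[i] }
    c(out, root)
  }
  depth <- function(i) sum(elen[setdiff(anc_path(i), root)])
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), anc_path)
  for (i in seq_len(n)) for (j in i:n) {
    common <- intersect(paths[[i]], paths[[j]])
    mrca <- common[1]   # paths are ordered tipward -> rootward
    V[i, j] <- V[j, i] <- depth(mrca)
  }
  diag(V) <- vapply(seq_len(n), depth, 0)
  V
}

# direct multivariate-normal log density via explicit determinant/inverse
mvn_loglik_bruteforce <- function(y, mu, Sigma) {
  n <- length(y)
  -n / 2 * log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
    0.5 * drop(t(y - mu) %*% solve(Sigma) %*% (y - mu))
}

# fixed small trees used in several files
tree3 <- function() read_newick("((A:1,B:1):1,C:2);")
tree_cat4 <- function() read_newick("(((t1:1,t2:1):1,t3:1):1,t4:1);")
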