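#' Read a rooted phylogram from Newick text or file
#'
#' Parses a Newick tree (via \pkg{ape}) and validates it for comparative
#' analysis: every edge must carry a non-negative branch length and tip
#' labels must be unique. Branch lengths are taken as supplied ('molecular
#' calibrated' phylograms are used as-is, never ultrametricised). Trees with
#' a basal polytomy (e.g. majority-rule consensus trees, star trees) are
#' treated as rooted at that polytomy.
#'
#' @param source a Newick string or the path of a file containing one.
#' @return an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(source) {
  txt <- if (length(source) == 1L && !grepl("(", source, fixed = TRUE) &&
             file.exists(source)) readLines(source, warn = FALSE) else source
  tree <- tryCatch(ape::read.tree(text = paste(txt, collapse = "")),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    .stop2("parse_error", "malformed Newick input")
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param tree a `phylo` object to validate.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo"))
    .stop2("invalid_input", "expected a 'phylo' tree")
  if (is.null(tree$edge.length))
    .stop2("parse_error", "tree has no branch lengths; they are required")
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    lab <- .edge_child_label(tree, bad[1L])
    .stop2("parse_error",
           "missing branch length on the edge leading to '%s'", lab)
  }
  neg <- which(tree$edge.length < 0)
  if (length(neg))
    .stop2("invalid_input", "negative branch length on the edge leading to '%s'",
           .edge_child_label(tree, neg[1L]))
  if (anyDuplicated(tree$tip.label))
    .stop2("invalid_input", "tip labels must be unique")
  tree
}

.edge_child_label <- function(tree, edge_idx) {
  child <- tree$edge[edge_idx, 2L]
  if (child <= length(tree$tip.label)) tree$tip.label[child]
  else sprintf("internal node #%d", child)
}

#' @rdname read_newick
#' @param file optional output path; when `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Brownian variance-covariance matrix of a tree
#'
#' Converts a rooted phylogram into the Brownian-motion variance-covariance
#' matrix: diagonal entries are root-to-tip path lengths (the expected trait
#' variance at each tip, per unit Brownian rate) and off-diagonal entries
#' are root-to-MRCA shared path lengths (the expected covariance of each
#' species pair). The returned object carries the lambda already applied
#' (1 for the untransformed tree).
#'
#' @param tree a validated `phylo` phylogram.
#' @return a `phylo_vcv` object: the n x n matrix with tip order in its
#'   dimnames and attribute `lambda`.
#' @export
vcv_from_tree <- function(tree) {
  tree <- validate_phylogeny(tree)
  V <- ape::vcv(tree)
  structure(V, class = c("phylo_vcv", "matrix"), lambda = 1)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies every off-diagonal element of the Brownian variance-covariance
#' matrix by `lam`, leaving the diagonal untouched. `lam = 0` produces a
#' diagonal ("star"-like) matrix with no shared history; `lam = 1` returns
#' the matrix unchanged. Values outside [0, 1] are rejected: the statistic
#' is defined on that interval.
#'
#' @param V a `phylo_vcv` (or plain covariance matrix).
#' @param lam lambda in [0, 1].
#' @return the transformed matrix, with attribute `lambda` updated.
#' @export
lambda_transform <- function(V, lam) {
  .check_number(lam, "lam", lower = 0, upper = 1)
  W <- unclass(V)
  d <- diag(W)
  W <- W * lam
  diag(W) <- d
  structure(W, class = c("phylo_vcv", "matrix"),
            lambda = lam * (attr(V, "lambda") %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align a species-level trait table with a tree
#'
#' Matches the `species` column of a trait table against the tip labels of a
#' tree (exact, case-sensitive string match). Tips without a trait row are
#' pruned with a warning; trait rows naming species absent from the tree are
#' a hard error (they would silently drop data otherwise). The returned
#' table rows are reordered to the pruned tree's tip order, so that trait
#' vectors and covariance matrices line up from then on.
#'
#' @param table a data frame with a `species` column.
#' @param tree a `phylo` phylogram.
#' @return a list with elements `tree` (pruned), `table` (reordered) and
#'   `pruned` (character vector of dropped tips).
#' @export
align_table_to_tree <- function(table, tree) {
  if (!is.data.frame(table) || !"species" %in% names(table))
    .stop2("invalid_input", "trait table must have a 'species' column")
  tree <- validate_phylogeny(tree)
  sp <- as.character(table$species)
  if (anyDuplicated(sp))
    .stop2("invalid_input", "duplicated species in trait table: %s",
           paste(unique(sp[duplicated(sp)]), collapse = ", "))
  missing_tips <- setdiff(sp, tree$tip.label)
  if (length(missing_tips))
    .stop2("species_not_in_tree",
           "trait species absent from the tree: %s",
           paste(missing_tips, collapse = ", "))
  if (!length(intersect(sp, tree$tip.label)))
    .stop2("empty_intersection", "no species shared between table and tree")
  drop <- setdiff(tree$tip.label, sp)
  if (length(drop)) {
    warning(sprintf("pruning %d tip(s) without trait data: %s",
                    length(drop), paste(drop, collapse = ", ")))
    tree <- ape::drop.tip(tree, drop)
  }
  table <- table[match(tree$tip.label, sp), , drop = FALSE]
  rownames(table) <- NULL
  list(tree = tree, table = table, pruned = drop)
}
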