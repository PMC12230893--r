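#' Group-weighted Gower distance for mixed traits
#'
#' Pairwise dissimilarity between species over one service's traits. Each of
#' the functional trait groups contributes equally: a binary group's score is
#' the mean absolute mismatch over its member categories, a continuous trait
#' is its own group with score `|x_i - x_j| / range` (ranges are 1 after
#' min-max scaling). The distance is the mean of the group scores, so it lies
#' in `[0, 1]`. Set `group_weighting = FALSE` to weight every column equally
#' instead (plain Gower).
#'
#' @param table a prepared [trait_table()].
#' @param service `"cultural"` or `"regulating"`.
#' @param group_weighting average binary mismatches within groups first
#'   (default `TRUE`).
#' @return A symmetric species-by-species distance matrix with zero diagonal.
#' @export
gower_distance <- function(table, service = c("cultural", "regulating"),
                           group_weighting = TRUE) {
  stopifnot(inherits(table, "trait_table"))
  service <- match.arg(service)
  meta <- trait_meta(table)
  meta <- meta[meta$service == service, , drop = FALSE]
  if (nrow(meta) == 0) stopf("no traits for service '%s'", service)
  x <- as.matrix(as.data.frame(table)[meta$trait])
  rownames(x) <- table$species
  if (!group_weighting) meta$group <- meta$trait
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(table$species, table$species))
  groups <- unique(meta$group)
  for (g in groups) {
    cols <- meta$trait[meta$group == g]
    score <- matrix(0, n, n)
    for (cl in cols) {
      v <- x[, cl]
      rng <- diff(range(v))
      m <- abs(outer(v, v, "-"))
      if (rng > 0) m <- m / rng else m[] <- 0
      score <- score + m
    }
    d <- d + score / length(cols)
  }
  d / length(groups)
}

#' Neighbour-joining functional tree
#'
#' Builds an unrooted tree from a distance matrix by classical Saitou-Nei
#' neighbour joining. On an additive input the patristic distances of the
#' result reproduce the input exactly. Labels are canonicalized (sorted)
#' before joining so the tree is invariant to input label order. Negative
#' branch lengths, which NJ can produce on non-additive input, are clamped to
#' zero with the deficit moved to the adjacent edge, preserving tip-to-tip
#' path lengths as closely as possible. Two or three taxa are handled by the
#' unique unrooted topology with closed-form branch lengths.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal and
#'   labelled dimnames.
#' @return A `phylo` tree whose tip set equals the input labels.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stopf("distance matrix needs labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stopf("distance matrix must be symmetric")
  if (any(d < 0)) stopf("distances must be nonnegative")
  if (any(diag(d) != 0)) stopf("diagonal must be zero")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  lab <- rownames(d)
  n <- nrow(d)
  if (n < 2) stopf("need at least 2 taxa")
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", lab[1], d[1, 2] / 2, lab[2], d[1, 2] / 2)))
  }
  if (n == 3) {
    # star tree: solve the three pairwise path equations
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    return(ape::read.tree(text = sprintf(
      "(%s:%g,%s:%g,%s:%g);", lab[1], max(a, 0), lab[2], max(b, 0), lab[3], max(c3, 0)
    )))
  }
  tr <- ape::nj(d)
  fix_negative_edges(tr)
}

# Clamp negative branch lengths to 0, adding the deficit to the edge on the
# parent side so tip-to-tip sums through the parent are preserved.
fix_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    adj <- which(tr$edge[, 2] == parent)
    if (!length(adj)) adj <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(adj)) tr$edge.length[adj[1]] <- tr$edge.length[adj[1]] + deficit
  }
  tr
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of tips.
#'
#' @param tree a `phylo` object.
#' @return A symmetric tip-by-tip matrix with zero diagonal.
#' @export
patristic <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  stats::cophenetic(tree)
}

#' Functional (or phylogenetic) dispersion of one community
#'
#' The mean patristic distance between all unordered pairs of community
#' members on the tree: the average trait (or phylogenetic) dissimilarity
#' between any two species randomly chosen from the community. Communities
#' with fewer than three species are rejected, as such tiny communities give
#' biased dispersion estimates and are filtered out of the analysis.
#'
#' @param tree a `phylo` tree, or a precomputed patristic matrix.
#' @param community character vector of species (>= 3, all on the tree).
#' @return A single nonnegative number.
#' @export
dispersion <- function(tree, community) {
  d <- if (inherits(tree, "phylo")) patristic(tree) else as.matrix(tree)
  community <- unique(as.character(community))
  if (length(community) < 3) stopf("dispersion needs >= 3 species")
  missing <- setdiff(community, rownames(d))
  if (length(missing)) stopf("species not on tree: %s", paste(missing, collapse = ", "))
  sub <- d[community, community]
  mean(sub[upper.tri(sub)])
}

# Vectorized dispersion for all rows of a 0/1 matrix M (cells x species),
# given a patristic matrix D over M's columns. perm optionally permutes the
# positions species occupy on the tree (tip-label randomization).
dispersion_profile <- function(M, D, perm = NULL) {
  stopifnot(identical(colnames(M), rownames(D)))
  if (!is.null(perm)) D <- D[perm, perm]
  k <- rowSums(M)
  e <- M %*% D
  tot <- rowSums(e * M)
  out <- tot / (k * (k - 1))
  out[k < 3] <- NA_real_
  names(out) <- rownames(M)
  out
}
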