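## Distance matrices, neighbor joining, bootstrap supports, outgroup rooting
## and subfamily cluster assignment.

#' Pairwise distances from an MSA
#'
#' p-distance = mismatches / both-non-gap columns per pair; the Poisson
#' correction (default) is -ln(1 - p).  A saturated pair (p = 1) has no
#' finite Poisson distance and raises an error, as does a pair with no
#' overlapping columns.
#'
#' @param msa named character vector of gapped rows (>= 2)
#' @param model `"poisson_corrected"` (default) or `"p_distance"`
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
msaDistances <- function(msa, model = c("poisson_corrected", "p_distance")) {
  model <- match.arg(model)
  msa <- .msa_check(msa)
  if (length(msa) < 2L) stop("need at least two rows")
  mat <- .msa_matrix(msa)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(both)) stop("no overlapping columns for pair ",
                         names(msa)[i], " / ", names(msa)[j])
    p <- sum(mat[i, both] != mat[j, both]) / sum(both)
    d <- if (model == "p_distance") p else {
      if (p >= 1) stop("saturated pair (p = 1) under the Poisson correction: ",
                       names(msa)[i], " / ", names(msa)[j])
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei NJ with the standard Q criterion.  Ties on Q are broken by the
#' smallest (row, column) index pair in the current matrix order, so the
#' result is deterministic.  Negative branch lengths are clamped to zero with
#' the deficit moved onto the sibling edge (preserving the joined pair's
#' distance sum).
#'
#' @param D symmetric distance matrix with taxa dimnames (>= 3 taxa)
#' @return A [SupportedTree-class] (unrooted, supports empty).
#' @export
njTree <- function(D) {
  if (is.null(dimnames(D)[[1L]])) stop("distance matrix needs taxon dimnames")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(D)
  nodes <- labs                      # growing newick substrings
  fmt <- function(x) sprintf("%.10g", max(x, 0))

  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest index pair among minima (column-major scan of upper triangle)
    best <- c(NA_integer_, NA_integer_); qbest <- Inf
    for (jj in 2:m) for (ii in 1:(jj - 1)) {
      if (Q[ii, jj] < qbest - 1e-12) { qbest <- Q[ii, jj]; best <- c(ii, jj) }
    }
    i <- best[1L]; j <- best[2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(vi), nodes[j], fmt(vj))
    others <- setdiff(seq_len(m), c(i, j))
    d_new <- (D[i, others] + D[j, others] - D[i, j]) / 2
    d_new <- pmax(d_new, 0)
    D <- rbind(cbind(D[others, others, drop = FALSE], d_new),
               c(d_new, 0))
    nodes <- c(nodes[others], merged)
    dimnames(D) <- list(seq_along(nodes), seq_along(nodes))
  }
  # closed-form star join of the last three
  v1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  v2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  v3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(v1), nodes[2], fmt(v2),
                 nodes[3], fmt(v3))
  phy <- ape::read.tree(text = nwk)
  new("SupportedTree", tree = phy, supports = rep(NA_real_, phy$Nnode),
      rooted = FALSE)
}

#' Nonparametric bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' fraction of replicates containing the same bipartition.  Deterministic
#' given the seed.  (This stands in for approximate-ML local support values;
#' the two are not numerically comparable.)
#'
#' @param msa named character vector of gapped rows
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed RNG seed
#' @param model distance model, see [msaDistances()]
#' @return A [SupportedTree-class] whose supports are proportions in [0, 1];
#'   node labels carry the supports at 2 decimals.
#' @export
bootstrapSupport <- function(msa, n_reps = 100L, seed = 1L,
                             model = c("poisson_corrected", "p_distance")) {
  model <- match.arg(model)
  msa <- .msa_check(msa)
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ref <- njTree(msaDistances(msa, model))
  phy <- ref@tree

  mat <- .msa_matrix(msa)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    boot <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste, collapse = ""),
                     names(msa))
    reps[[k]] <- njTree(msaDistances(boot, model))@tree
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(phy, reps, rooted = FALSE)
  support <- counts / n_reps
  support[is.na(support)] <- 0
  # the basal trifurcation node corresponds to the trivial full-taxon split
  support[1L] <- NA_real_
  phy$node.label <- ifelse(is.na(support), "", sprintf("%.2f", support))
  new("SupportedTree", tree = phy, supports = support, rooted = FALSE)
}

#' Root a tree on its outgroup
#'
#' Places the root on the edge separating a monophyletic outgroup from the
#' ingroup.  A non-monophyletic outgroup is an error naming the offending
#' taxa.  Rooting never changes the set of bipartitions.
#'
#' @param tree a [SupportedTree-class] or ape `phylo`
#' @param outgroup_taxa character vector of outgroup tip labels
#' @return A rooted [SupportedTree-class].
#' @export
rootByOutgroup <- function(tree, outgroup_taxa) {
  phy <- if (is(tree, "SupportedTree")) tree@tree else tree
  tips <- phy$tip.label
  if (!all(outgroup_taxa %in% tips))
    stop("outgroup taxa absent from tree: ",
         paste(setdiff(outgroup_taxa, tips), collapse = ", "))
  if (length(outgroup_taxa) < length(tips) - 1L && length(outgroup_taxa) > 1L) {
    # monophyly on the unrooted tree: judge from a rooting at an ingroup tip
    anchor <- setdiff(tips, outgroup_taxa)[1L]
    probe <- ape::root(phy, outgroup = anchor, resolve.root = TRUE)
    if (!ape::is.monophyletic(probe, outgroup_taxa))
      stop("outgroup is not monophyletic; offending split: {",
           paste(outgroup_taxa, collapse = ", "), "} vs ingroup")
  }
  rooted <- ape::root(phy, outgroup = outgroup_taxa, resolve.root = TRUE)
  sup <- rep(NA_real_, rooted$Nnode)
  if (!is.null(rooted$node.label)) {
    parsed <- suppressWarnings(as.numeric(rooted$node.label))
    sup <- parsed
  }
  new("SupportedTree", tree = rooted, supports = sup, rooted = TRUE)
}

#' Assign the query to a subfamily cluster
#'
#' Finds the smallest clade of a rooted tree containing the query tip and at
#' least one labelled non-query tip, labels the query by the majority label
#' inside that clade (alphabetical tie-break), and reports the sister taxa
#' plus whether the clade is single-label (the query nested within a
#' monophyletic subfamily).
#'
#' @param tree a rooted [SupportedTree-class] or `phylo`
#' @param labels named character vector tip -> subfamily label; the query tip
#'   must carry the label `"query"`
#' @return list: `query_cluster_label`, `sister_taxa`, `is_nested`.
#' @export
clusterAssignment <- function(tree, labels) {
  phy <- if (is(tree, "SupportedTree")) tree@tree else tree
  if (!ape::is.rooted(phy)) stop("cluster assignment needs a rooted tree")
  query <- names(labels)[labels == "query"]
  if (length(query) != 1L) stop("labels must mark exactly one query tip")
  if (!query %in% phy$tip.label) stop("query tip absent from tree")
  unlabelled <- setdiff(phy$tip.label, names(labels))
  if (length(unlabelled)) stop("unlabelled tips: ", paste(unlabelled, collapse = ", "))

  tip_idx <- match(query, phy$tip.label)
  parent_of <- function(node) phy$edge[phy$edge[, 2L] == node, 1L]
  node <- parent_of(tip_idx)
  repeat {
    clade_tips <- ape::extract.clade(phy, node)$tip.label
    others <- setdiff(clade_tips, query)
    if (length(others)) break
    nxt <- parent_of(node)
    if (!length(nxt)) break
    node <- nxt
  }
  labs <- labels[others]
  tab <- sort(table(labs), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  list(query_cluster_label = sort(top)[1L],
       sister_taxa = others,
       is_nested = length(unique(labs)) == 1L)
}

#' Write a SupportedTree as Newick
#'
#' Branch lengths plus internal-node support labels (proportions, two
#' decimals); labels containing spaces are single-quoted by ape.
#'
#' @param tree a [SupportedTree-class]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeSupportedTree <- function(tree, path) {
  stopifnot(is(tree, "SupportedTree"))
  ape::write.tree(tree@tree, file = path)
  invisible(path)
}

#' Read a Newick tree with optional support labels
#'
#' @param path Newick file
#' @return A [SupportedTree-class]; numeric node labels become supports.
#' @export
readSupportedTree <- function(path) {
  phy <- ape::read.tree(path)
  sup <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label))
    sup <- suppressWarnings(as.numeric(phy$node.label))
  new("SupportedTree", tree = phy, supports = sup, rooted = ape::is.rooted(phy))
}
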