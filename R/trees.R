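#' Neighbor-joining tree from a K2P distance matrix
#'
#' Builds an unrooted tree over all labels with the BioNJ
#' (variance-weighted) or classic Saitou-Nei neighbor-joining
#' agglomeration. Undefined (saturated) distances abort with the offending
#' pairs listed. Negative branch lengths, which NJ can produce on
#' non-additive data, are clamped to zero with the deficit shifted to the
#' sibling edge so that downstream path lengths stay non-negative.
#'
#' @param dm a [K2PMatrix-class] or a symmetric numeric distance matrix
#'   with dimnames.
#' @param variant \code{"bionj"} (default) or \code{"classic_nj"}.
#' @return an unrooted \code{ape::phylo} tree with branch lengths in
#'   substitutions/site.
#' @export
buildNJTree <- function(dm, variant = c("bionj", "classic_nj")) {
  variant <- match.arg(variant)
  d <- if (is(dm, "K2PMatrix")) distMatrix(dm) else as.matrix(dm)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (anyNA(d)) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(sprintf("(%s, %s)", rownames(d)[idx[, 1]],
                       colnames(d)[idx[, 2]]), collapse = ", "))
  }
  tr <- switch(variant,
    bionj = ape::bionj(stats::as.dist(d)),
    classic_nj = ape::nj(stats::as.dist(d)))
  clampNegativeBranches(tr)
}

#' Clamp negative branch lengths to zero
#'
#' Sets each negative edge length to zero and adds the (negative) deficit
#' to a sibling edge of the same parent node, iterating until no negative
#' edges remain (any residual negativity after a bounded number of passes
#' is clamped outright).
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return the tree with all edge lengths \code{>= 0}; total tree length is
#'   preserved whenever a sibling can absorb the deficit.
#' @export
clampNegativeBranches <- function(tree) {
  el <- tree$edge.length
  parent <- tree$edge[, 1]
  for (pass in seq_len(10L)) {
    neg <- which(el < 0)
    if (length(neg) == 0L) break
    for (e in neg) {
      if (el[e] >= 0) next
      sib <- setdiff(which(parent == parent[e]), e)
      deficit <- el[e]
      el[e] <- 0
      if (length(sib)) el[sib[1L]] <- el[sib[1L]] + deficit
    }
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Root a tree according to a rooting policy
#'
#' @param tree an \code{ape::phylo}.
#' @param rootPolicy \code{"midpoint"} (default), the label of an outgroup
#'   leaf, or \code{NULL} to keep the tree as supplied.
#' @return a rooted \code{ape::phylo}.
#' @export
rootTree <- function(tree, rootPolicy = "midpoint") {
  if (is.null(rootPolicy)) {
    tree
  } else if (identical(rootPolicy, "midpoint")) {
    phangorn::midpoint(tree)
  } else {
    if (!rootPolicy %in% tree$tip.label) stop("unknown outgroup: ", rootPolicy)
    ape::root(tree, outgroup = rootPolicy, resolve.root = TRUE)
  }
}

#' Most recent common ancestor of a set of leaves
#'
#' MRCA is root-dependent, so the tree is rooted first (midpoint by
#' default, matching how unrooted NJ trees are read for OTU internal
#' distances).
#'
#' @param tree an \code{ape::phylo} (rooted or unrooted).
#' @param labels two or more leaf labels.
#' @param rootPolicy passed to [rootTree()]; use \code{NULL} if
#'   \code{tree} is already rooted as desired.
#' @return list with \code{node} (node id in the rooted tree) and
#'   \code{tree} (the rooted tree, for reuse).
#' @export
mrcaNode <- function(tree, labels, rootPolicy = "midpoint") {
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  if (length(labels) < 2L) stop("need at least 2 labels")
  rooted <- if (is.null(rootPolicy)) tree else rootTree(tree, rootPolicy)
  node <- ape::getMRCA(rooted, as.character(labels))
  list(node = node, tree = rooted)
}

#' Internal distance of an OTU on a tree
#'
#' The internal distance of an OTU is the maximum path length from the
#' OTU's last common ancestor node (treated as part of the OTU) to any of
#' its member leaves. It is 0 for quasi-singletons (identical sequences)
#' and undefined for singletons, which is signalled as an error rather
#' than returned as 0. A distance-matrix fallback (half the maximum
#' within-OTU pairwise distance) is available for sensitivity checks.
#'
#' @param tree an \code{ape::phylo} over the member labels (only needed for
#'   \code{method = "mrca"}).
#' @param members character vector of at least 2 member leaf labels.
#' @param method \code{"mrca"} (default) or \code{"pairwise"}.
#' @param dm [K2PMatrix-class] or distance matrix, required for
#'   \code{"pairwise"}.
#' @param rootPolicy passed to [mrcaNode()].
#' @return internal distance (substitutions/site).
#' @export
otuInternalDistance <- function(tree, members, method = c("mrca", "pairwise"),
                                dm = NULL, rootPolicy = "midpoint") {
  method <- match.arg(method)
  if (length(members) < 2L) {
    stop("internal distance is undefined for singleton OTUs")
  }
  if (method == "pairwise") {
    d <- if (is(dm, "K2PMatrix")) distMatrix(dm) else as.matrix(dm)
    sub <- d[members, members, drop = FALSE]
    return(max(sub, na.rm = TRUE) / 2)
  }
  res <- mrcaNode(tree, members, rootPolicy)
  rooted <- res$tree
  dn <- ape::dist.nodes(rooted)
  tips <- match(members, rooted$tip.label)
  max(dn[res$node, tips])
}

#' Bootstrap clade supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; each pseudoreplicate
#' alignment yields a K2P distance matrix and an NJ tree, and the
#' bipartitions of the original tree are scored against the replicate
#' trees (strict bipartition matching). Replicates whose distance matrix
#' contains undefined entries are skipped and counted.
#'
#' @param aln a [SeqAlignment-class].
#' @param replicates number of pseudoreplicates (default 100).
#' @param seed RNG seed; runs with the same seed are identical.
#' @param variant NJ variant, see [buildNJTree()].
#' @param sitePolicy site policy for [k2pMatrix()].
#' @return list with \code{tree} (the original NJ tree), \code{supports}
#'   (percent per internal node, in node order), \code{replicates},
#'   \code{failedReplicates}.
#' @export
bootstrapSupports <- function(aln, replicates = 100L, seed = NULL,
                              variant = "bionj",
                              sitePolicy = "complete_deletion") {
  stopifnot(is(aln, "SeqAlignment"), replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tree <- buildNJTree(k2pMatrix(aln, sitePolicy = sitePolicy), variant)
  m <- alignmentMatrix(aln)
  nc <- ncol(m)
  bootTrees <- list()
  failed <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    baln <- new("SeqAlignment", seqs = m[, cols, drop = FALSE],
                treatment = treatment(aln))
    bt <- tryCatch(
      buildNJTree(k2pMatrix(baln, sitePolicy = sitePolicy), variant),
      error = function(e) NULL)
    if (is.null(bt)) failed <- failed + 1L else bootTrees[[length(bootTrees) + 1L]] <- bt
  }
  counts <- if (length(bootTrees)) {
    ape::prop.clades(tree, bootTrees, rooted = FALSE)
  } else {
    rep(0L, tree$Nnode)
  }
  counts[is.na(counts)] <- 0L
  list(tree = tree, supports = 100 * counts / replicates,
       replicates = replicates, failedReplicates = failed)
}

#' Monophyly report for labelled groups
#'
#' For each group of leaves: whether the group forms a complete clade under
#' the rooting policy, and the mean bootstrap support over the clade's
#' internal nodes. Also reports the tree-wide mean bootstrap and the number
#' of supports above 49 percent.
#'
#' @param tree an \code{ape::phylo} (unrooted NJ tree).
#' @param supports percent supports per internal node as from
#'   [bootstrapSupports()] (in the node order of \code{tree}).
#' @param grouping named character vector mapping leaf label to group.
#' @param rootPolicy passed to [rootTree()].
#' @return list with \code{groups} (data.frame \code{group, nLeaves,
#'   monophyletic, meanSupport}), \code{treeMeanSupport},
#'   \code{nSupportsOver49}.
#' @export
monophylyReport <- function(tree, supports, grouping,
                            rootPolicy = "midpoint") {
  stopifnot(!is.null(names(grouping)))
  rooted <- rootTree(tree, rootPolicy)
  # carry supports over to the rooted tree by matching bipartitions
  rootedSupports <- .transferSupports(tree, supports, rooted)
  groups <- sort(unique(grouping))
  ntip <- length(rooted$tip.label)
  rows <- lapply(groups, function(g) {
    leaves <- names(grouping)[grouping == g]
    leaves <- intersect(leaves, rooted$tip.label)
    if (length(leaves) == 0L) stop("group with zero leaves: ", g)
    mono <- if (length(leaves) == 1L) TRUE else {
      ape::is.monophyletic(rooted, leaves)
    }
    meanSup <- NA_real_
    if (length(leaves) >= 2L) {
      node <- ape::getMRCA(rooted, leaves)
      desc <- phangorn::Descendants(rooted, node, type = "all")
      inner <- c(node, desc[desc > ntip])
      meanSup <- mean(rootedSupports[inner - ntip], na.rm = TRUE)
    }
    data.frame(group = g, nLeaves = length(leaves), monophyletic = mono,
               meanSupport = meanSup)
  })
  list(groups = do.call(rbind, rows),
       treeMeanSupport = mean(supports, na.rm = TRUE),
       nSupportsOver49 = sum(supports > 49, na.rm = TRUE))
}

# Map per-node supports of `tree` onto the internal nodes of `rooted` by
# strict bipartition matching on tip-label sets.
.transferSupports <- function(tree, supports, rooted) {
  key <- function(phy, node) {
    tips <- phy$tip.label[phangorn::Descendants(phy, node, "tips")[[1]]]
    comp <- setdiff(phy$tip.label, tips)
    a <- paste(sort(tips), collapse = "|")
    b <- paste(sort(comp), collapse = "|")
    if (a < b) paste(a, b, sep = "//") else paste(b, a, sep = "//")
  }
  ntipO <- length(tree$tip.label)
  keysO <- vapply(seq_len(tree$Nnode) + ntipO, function(nd) key(tree, nd), "")
  ntipR <- length(rooted$tip.label)
  vapply(seq_len(rooted$Nnode) + ntipR, function(nd) {
    i <- match(key(rooted, nd), keysO)
    if (is.na(i)) NA_real_ else supports[i]
  }, numeric(1))
}
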