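# Shared fixtures and independent oracles for the test suite.

makeAln <- function(strings, ids = NULL, treatment = "T1") {
  if (is.null(ids)) ids <- paste0("s", seq_along(strings))
  SeqAlignment(strings, ids = ids, treatment = treatment)
}

# Random valid alignment over the full alphabet (for fuzz tests).
randomAln <- function(n, L, gapProb = 0.1, ambProb = 0.05) {
  syms <- c("A", "C", "G", "T")
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  m <- matrix(sample(syms, n * L, replace = TRUE), nrow = n)
  pick <- matrix(stats::runif(n * L), nrow = n)
  m[pick < gapProb] <- "-"
  hit <- pick >= gapProb & pick < gapProb + ambProb
  m[hit] <- sample(amb, sum(hit), replace = TRUE)
  rownames(m) <- paste0("r", seq_len(n))
  new("SeqAlignment", seqs = m, treatment = "T1")
}

# Independent brute-force column entropy: enumerates each cell's
# contribution symbol by symbol, without sharing code with the package.
bruteColumnEntropy <- function(column) {
  share <- function(sym) {
    out <- c(A = 0, C = 0, G = 0, T = 0, E = 0)
    if (sym %in% c("N", "-")) {
      out[] <- 1 / 5
    } else {
      cons <- switch(sym,
        A = "A", C = "C", G = "G", T = "T",
        R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
        K = c("G", "T"), M = c("A", "C"),
        B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
        V = c("A", "C", "G"),
        stop("bad symbol ", sym))
      for (b in cons) out[b] <- out[b] + 1 / length(cons)
    }
    out
  }
  total <- c(A = 0, C = 0, G = 0, T = 0, E = 0)
  for (sym in column) total <- total + share(sym)
  p <- total / length(column)
  H <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) H <- H - p[k] * log(p[k])
  }
  unname(H)
}

# Unconstrained least-squares fit of branch lengths for a fixed topology
# against a distance matrix; returns the residual sum of squares and the
# fitted edge lengths. Independent oracle for NJ correctness.
lsTopologyFit <- function(topo, D) {
  tips <- topo$tip.label
  D <- D[tips, tips]
  nt <- length(tips)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  desc <- phangorn::Descendants(topo, topo$edge[, 2], type = "tips")
  A <- matrix(0, nrow(pairs), nrow(topo$edge))
  for (e in seq_len(nrow(topo$edge))) {
    inSet <- logical(nt)
    inSet[desc[[e]]] <- TRUE
    A[, e] <- xor(inSet[pairs[, 1]], inSet[pairs[, 2]])
  }
  dvec <- D[pairs]
  fit <- stats::lm.fit(A, dvec)
  list(rss = sum(fit$residuals^2), edgeLengths = unname(fit$coefficients))
}

# Exhaustive least-squares search over all unrooted topologies.
bruteForceBestTree <- function(D) {
  labels <- rownames(D)
  topos <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  best <- NULL
  bestRss <- Inf
  for (i in seq_along(topos)) {
    tp <- topos[[i]]   # [[ reattaches tip labels on compressed multiPhylo
    f <- lsTopologyFit(tp, D)
    if (f$rss < bestRss) {
      bestRss <- f$rss
      tp$edge.length <- f$edgeLengths
      best <- tp
    }
  }
  list(tree = best, rss = bestRss)
}

# A controlled fixture: four planted clusters, then edited so the OTU table
# contains a multiton, a two-member OTU, a quasi-singleton and a singleton.
buildAreaFixture <- function(seed = 13) {
  sim <- simulateAlignment(nSequences = 12, nClusters = 4,
                           withinDivergence = 0.02, betweenDivergence = 0.30,
                           blocks = data.frame(length = c(300L, 150L),
                                               class = c("conserved", "variable"),
                                               gapProb = c(0, 0)),
                           overhangMax = 0, ambiguityRate = 0, seed = seed)
  m <- alignmentMatrix(sim$alignment)
  # cluster 2 (rows 4:6) becomes a quasi-singleton: identical copies
  m[5, ] <- m[4, ]
  m[6, ] <- m[4, ]
  # cluster 3 keeps rows 7:8 (a doubleton), cluster 4 keeps row 10 (singleton)
  m <- m[c(1:8, 10), , drop = FALSE]
  aln <- new("SeqAlignment", seqs = m, treatment = "T1")
  tab <- classifyOTUs(clusterOTUs(aln, 0.9), aln)
  tree <- buildNJTree(k2pMatrix(aln))
  list(aln = aln, tab = tab, tree = tree, N = nrow(m))
}
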