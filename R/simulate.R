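# Seeded simulator of aligned amplicon sets with planted OTU structure.

# K2P substitution probabilities for one branch of length d (expected
# substitutions/site) at transition/transversion ratio R = alpha/(2 beta).
.k2pProbs <- function(d, tsTv = 2) {
  b <- d / (2 * (tsTv + 1))
  a <- d * tsTv / (tsTv + 1)
  pTs <- 1 / 4 + exp(-4 * b) / 4 - exp(-2 * (a + b)) / 2
  pTv <- 1 / 2 - exp(-4 * b) / 2
  c(same = 1 - pTs - pTv, ts = pTs, tv = pTv)
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

# Evolve a base vector along a branch of length d under K2P; `sites`
# restricts mutation to a column subset.
.mutateK2P <- function(seq, d, tsTv = 2, sites = seq_along(seq)) {
  if (d <= 0 || length(sites) == 0L) return(seq)
  pr <- .k2pProbs(d, tsTv)
  fate <- sample(c("same", "ts", "tv"), length(sites), replace = TRUE,
                 prob = pr)
  tsIdx <- sites[fate == "ts"]
  seq[tsIdx] <- .TS_PARTNER[seq[tsIdx]]
  tvIdx <- sites[fate == "tv"]
  if (length(tvIdx)) {
    pick <- stats::runif(length(tvIdx)) < 0.5
    seq[tvIdx] <- vapply(seq_along(tvIdx), function(k) {
      .TV_PARTNERS[[seq[tvIdx[k]]]][if (pick[k]) 1L else 2L]
    }, "")
  }
  seq
}

#' Simulate an aligned amplicon set with planted OTU clusters
#'
#' Generates an alignment that emulates environmental amplicon data: a
#' conserved core, hypervariable blocks, gap-rich stretches, IUPAC
#' ambiguities and leading/trailing overhangs, with a known (planted)
#' cluster membership for every sequence.
#'
#' The mutation model is K2P with a configurable transition/transversion
#' ratio. Each cluster member evolves from its cluster ancestor along a
#' branch of length \code{withinDivergence / 2}, so \code{withinDivergence}
#' is the expected pairwise K2P distance between two members of the same
#' cluster. Cluster ancestors evolve from a common root so that the
#' expected ancestor-to-ancestor distance is \code{betweenDivergence};
#' these deep mutations are confined to the non-conserved (variable and
#' gap-rich) blocks, mirroring amplicons whose deep divergence concentrates
#' in hypervariable regions while the core stays alignable.
#'
#' Defaults emulate the clone-library setting the package targets: 120
#' sequences (40 per sample, three samples pooled per primer set), an
#' alignment of around 1000 columns with a hypervariable third, within-OTU
#' divergence 1 percent and deep between-OTU divergence 20 percent
#' (the distance scale at which ITS-like alignments saturate).
#'
#' @param nSequences total number of sequences (default 120).
#' @param nClusters number of planted clusters (default 20; sizes as equal
#'   as possible).
#' @param withinDivergence expected within-cluster pairwise K2P distance
#'   (substitutions/site, default 0.01).
#' @param betweenDivergence expected between-ancestor K2P distance (default
#'   0.20); must exceed \code{withinDivergence}.
#' @param blocks data.frame with columns \code{length}, \code{class}
#'   (\code{"conserved"}, \code{"variable"}, \code{"gap_rich"}) and
#'   \code{gapProb}; default 600 conserved + 300 variable + 100 gap-rich
#'   (gap probability 0.3).
#' @param overhangMax maximum leading/trailing overhang length per
#'   sequence (uniform on 0..max; default 25).
#' @param ambiguityRate per-cell probability of replacing a base with an
#'   IUPAC ambiguity code (default 0.001).
#' @param tsTv transition/transversion ratio of the mutation model
#'   (default 2, matching the downstream distance model).
#' @param seed RNG seed; identical seeds give byte-identical alignments.
#' @return list with \code{alignment} (a [SeqAlignment-class]) and
#'   \code{truth} (list: \code{clusters} named id-to-cluster vector,
#'   \code{blockClass} per-column class, \code{ancestors} cluster ancestor
#'   strings).
#' @export
simulateAlignment <- function(nSequences = 120L, nClusters = 20L,
                              withinDivergence = 0.01,
                              betweenDivergence = 0.20,
                              blocks = data.frame(
                                length = c(600L, 300L, 100L),
                                class = c("conserved", "variable", "gap_rich"),
                                gapProb = c(0, 0, 0.3)),
                              overhangMax = 25L, ambiguityRate = 0.001,
                              tsTv = 2, seed = NULL) {
  if (withinDivergence >= betweenDivergence) {
    stop("withinDivergence must be smaller than betweenDivergence")
  }
  stopifnot(nSequences >= nClusters, nClusters >= 1L,
            all(blocks$length >= 1L), all(blocks$gapProb >= 0 & blocks$gapProb <= 1),
            all(blocks$class %in% c("conserved", "variable", "gap_rich")))
  if (!is.null(seed)) set.seed(seed)
  L <- sum(blocks$length)
  blockClass <- rep(as.character(blocks$class), blocks$length)
  gapProbCol <- rep(blocks$gapProb, blocks$length)
  root <- sample(.BASES, L, replace = TRUE)
  mutable <- which(blockClass != "conserved")
  # scale the per-site ancestor branch so that the whole-sequence expected
  # between-ancestor distance equals betweenDivergence
  ancBranch <- if (length(mutable)) {
    (betweenDivergence / 2) * L / length(mutable)
  } else 0
  sizes <- rep(nSequences %/% nClusters, nClusters)
  extra <- nSequences %% nClusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ancestors <- lapply(seq_len(nClusters), function(k) {
    .mutateK2P(root, ancBranch, tsTv, sites = mutable)
  })
  m <- matrix("", nrow = nSequences, ncol = L)
  ids <- character(nSequences)
  clusterOf <- character(nSequences)
  row <- 0L
  for (k in seq_len(nClusters)) {
    for (s in seq_len(sizes[k])) {
      row <- row + 1L
      m[row, ] <- .mutateK2P(ancestors[[k]], withinDivergence / 2, tsTv)
      ids[row] <- sprintf("c%02d_s%03d", k, row)
      clusterOf[row] <- sprintf("c%02d", k)
    }
  }
  # ambiguities on bases, then block gaps, then overhangs (gaps win)
  if (ambiguityRate > 0) {
    hit <- which(stats::runif(length(m)) < ambiguityRate)
    if (length(hit)) {
      m[hit] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), length(hit),
                       replace = TRUE)
    }
  }
  gapRich <- which(gapProbCol > 0)
  for (j in gapRich) {
    hit <- stats::runif(nSequences) < gapProbCol[j]
    m[hit, j] <- "-"
  }
  if (overhangMax > 0) {
    for (i in seq_len(nSequences)) {
      lead <- sample.int(overhangMax + 1L, 1L) - 1L
      trail <- sample.int(overhangMax + 1L, 1L) - 1L
      if (lead > 0) m[i, seq_len(lead)] <- "-"
      if (trail > 0) m[i, (L - trail + 1L):L] <- "-"
    }
  }
  rownames(m) <- ids
  names(clusterOf) <- ids
  list(
    alignment = new("SeqAlignment", seqs = m, treatment = "T1"),
    truth = list(
      clusters = clusterOf,
      blockClass = blockClass,
      ancestors = vapply(ancestors, paste0, "", collapse = "")))
}

#' Resampling profile of a finite pool
#'
#' Draws \code{sampleSize} items without replacement from a pool of
#' \code{poolSize} items partitioned into classes, over many replicates,
#' and reports the per-class mean percentage and its standard deviation
#' across replicates. Used to judge how faithfully a small clone library
#' (e.g. 120 of 120,000 amplicons) represents the pool composition.
#'
#' @param poolProportions numeric vector of class proportions summing to 1
#'   (names are class labels; unnamed vectors get A, B, C, ...).
#' @param poolSize total pool size (default 120000).
#' @param sampleSize items drawn per replicate (default 120); must not
#'   exceed \code{poolSize}.
#' @param replicates number of replicate draws (default 100).
#' @param seed RNG seed.
#' @return data.frame with columns \code{class}, \code{meanPercent},
#'   \code{sdPercent}.
#' @export
resamplingProfile <- function(poolProportions, poolSize = 120000L,
                              sampleSize = 120L, replicates = 100L,
                              seed = NULL) {
  if (abs(sum(poolProportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (sampleSize > poolSize) stop("sampleSize exceeds poolSize")
  stopifnot(replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  k <- length(poolProportions)
  labels <- names(poolProportions)
  if (is.null(labels)) labels <- LETTERS[seq_len(k)]
  counts <- floor(poolProportions * poolSize)
  rem <- poolSize - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  pool <- rep.int(seq_len(k), counts)
  pct <- matrix(0, nrow = replicates, ncol = k)
  for (r in seq_len(replicates)) {
    drawn <- pool[sample.int(poolSize, sampleSize)]
    pct[r, ] <- 100 * tabulate(drawn, nbins = k) / sampleSize
  }
  data.frame(class = labels,
             meanPercent = colMeans(pct),
             sdPercent = apply(pct, 2L, stats::sd))
}
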