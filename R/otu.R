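#' Columns usable for percentage sequence identity
#'
#' The default PSI denominator ignores gap-containing alignment columns
#' globally: a column is usable when no sequence of the alignment has a
#' \code{-} there.
#'
#' @param aln a [SeqAlignment-class].
#' @return integer vector of usable column indices (1-based).
#' @export
usableColumns <- function(aln) {
  stopifnot(is(aln, "SeqAlignment"))
  which(colSums(alignmentMatrix(aln) == "-") == 0L)
}

#' Percentage sequence identity between two aligned records
#'
#' Matches divided by the number of compared columns. By default the
#' comparison is restricted to the alignment-wide gap-free column set
#' (see [usableColumns()]); a pairwise mode drops only columns where either
#' of the two sequences has a gap.
#'
#' @param a,b single symbols vectors (rows of the alignment matrix) or
#'   equal-length strings.
#' @param usable integer vector of column indices to compare over; required
#'   (obtain from [usableColumns()] or compute per pair).
#' @return identity fraction in [0, 1]; symmetric in \code{a}, \code{b}.
#' @export
pairwisePSI <- function(a, b, usable) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  stopifnot(length(a) == length(b))
  if (length(usable) == 0L) stop("no usable columns: identity undefined")
  mean(a[usable] == b[usable])
}

#' OTUTable: clusters of sequences at an identity cutoff
#'
#' @slot members named list; each element is the character vector of member
#'   sequence ids of one OTU, in joining order.
#' @slot seeds character; the founding sequence id of each OTU.
#' @slot classes character; \code{"singleton"}, \code{"quasi_singleton"},
#'   \code{"multiton"} or \code{NA} before [classifyOTUs()].
#' @slot cutoff identity fraction used for clustering.
#' @slot linkage \code{"seed"} or \code{"single"}.
#' @slot treatment treatment tag of the source alignment.
#' @export
setClass("OTUTable",
  representation(members = "list", seeds = "character", classes = "character",
                 cutoff = "numeric", linkage = "character",
                 treatment = "character"))

setValidity("OTUTable", function(object) {
  k <- length(object@members)
  if (length(object@seeds) != k || length(object@classes) != k) {
    return("members, seeds and classes must have one entry per OTU")
  }
  allIds <- unlist(object@members)
  if (anyDuplicated(allIds)) return("a sequence id appears in two OTUs")
  if (!all(mapply(function(s, m) s %in% m, object@seeds, object@members))) {
    return("every seed must be a member of its OTU")
  }
  TRUE
})

setMethod("show", "OTUTable", function(object) {
  sz <- otuSizes(object)
  cat(sprintf("OTUTable: %d OTUs from %d sequences (cutoff %.2f, %s linkage, %s)\n",
              length(sz), sum(sz), object@cutoff, object@linkage,
              object@treatment))
  if (!all(is.na(object@classes))) {
    cat("  classes:", paste(sprintf("%s=%d", names(table(object@classes)),
                                    table(object@classes)), collapse = ", "), "\n")
  }
})

#' @rdname OTUTable-class
#' @param x an \code{OTUTable}.
#' @aliases otuSizes otuMembers otuSeeds otuClasses nOtus otuCutoff
#' @export
otuSizes <- function(x) lengths(x@members)

#' @rdname OTUTable-class
#' @export
otuMembers <- function(x) x@members

#' @rdname OTUTable-class
#' @export
otuSeeds <- function(x) x@seeds

#' @rdname OTUTable-class
#' @export
otuClasses <- function(x) x@classes

#' @rdname OTUTable-class
#' @export
nOtus <- function(x) length(x@members)

#' @rdname OTUTable-class
#' @export
otuCutoff <- function(x) x@cutoff

#' Cluster sequences into OTUs by percentage sequence identity
#'
#' Two linkage rules are provided. The default \code{"seed"} rule emulates
#' the greedy dereplication of FastGroupII: sequences are processed in input
#' order; each is compared to the seeds of the existing OTUs (in founding
#' order) and joins the first OTU whose seed identity is \code{>= cutoff},
#' otherwise it founds a new OTU. \code{"single"} performs single-linkage
#' clustering: two sequences share an OTU when a chain of pairwise
#' identities \code{>= cutoff} connects them.
#'
#' @param aln a [SeqAlignment-class].
#' @param cutoff identity fraction in (0, 1); the usual amplicon levels are
#'   0.95, 0.97, 0.98, 0.99. (At cutoff 1 every OTU degenerates to a
#'   (quasi-)singleton, so 1 is excluded.)
#' @param linkage \code{"seed"} (default) or \code{"single"}.
#' @param psiMode \code{"global"} (default; compare over the alignment-wide
#'   gap-free column set) or \code{"pairwise"} (drop gap columns per pair).
#' @param sortByAbundance reserved switch: process sequences in input order
#'   (\code{FALSE}, default, FastGroupII behaviour) or after sorting ids
#'   lexicographically for order-robustness studies.
#' @return an [OTUTable-class]; classes are unset until [classifyOTUs()].
#' @export
clusterOTUs <- function(aln, cutoff, linkage = c("seed", "single"),
                        psiMode = c("global", "pairwise"),
                        sortByAbundance = FALSE) {
  stopifnot(is(aln, "SeqAlignment"))
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)")
  linkage <- match.arg(linkage)
  psiMode <- match.arg(psiMode)
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  if (n == 0L) stop("empty alignment")
  ids <- rownames(m)
  order_ <- if (sortByAbundance) order(ids) else seq_len(n)
  globalUsable <- usableColumns(aln)
  psi <- function(i, j) {
    if (psiMode == "global") {
      if (length(globalUsable) == 0L) stop("no gap-free columns: PSI undefined")
      mean(m[i, globalUsable] == m[j, globalUsable])
    } else {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("no usable columns for pair (", ids[i], ", ", ids[j], ")")
      mean(m[i, ok] == m[j, ok])
    }
  }
  if (linkage == "seed") {
    seedIdx <- integer(0)
    members <- list()
    for (i in order_) {
      placed <- FALSE
      for (k in seq_along(seedIdx)) {
        if (psi(i, seedIdx[k]) >= cutoff) {
          members[[k]] <- c(members[[k]], ids[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        seedIdx <- c(seedIdx, i)
        members[[length(seedIdx)]] <- ids[i]
      }
    }
    seeds <- ids[seedIdx]
  } else {
    # single linkage: components at identity >= cutoff, via hclust on 1-PSI
    if (n == 1L) {
      members <- list(ids)
      seeds <- ids
    } else {
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- 1 - psi(i, j)
      }
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      grp <- stats::cutree(hc, h = 1 - cutoff)
      members <- split(ids[order_], grp[order_])
      # order OTUs by first appearance, seed = first member
      firstPos <- vapply(members, function(mm) match(mm[1], ids[order_]), 0L)
      members <- members[order(firstPos)]
      seeds <- vapply(members, `[`, "", 1L)
    }
  }
  names(members) <- paste0("OTU", seq_along(members))
  names(seeds) <- names(members)
  new("OTUTable", members = members, seeds = unname(seeds),
      classes = rep(NA_character_, length(members)),
      cutoff = cutoff, linkage = linkage, treatment = treatment(aln))
}

#' Classify OTUs as singleton, quasi-singleton or multiton
#'
#' A singleton contains exactly one sequence. A quasi-singleton contains
#' two or more sequences that are all identical over the usable (gap-free)
#' columns; such OTUs have no measurable internal distance and act like
#' singletons in distance-area analyses. All other OTUs are multitons.
#'
#' @param table an [OTUTable-class].
#' @param aln the source [SeqAlignment-class].
#' @return the table with the \code{classes} slot filled.
#' @export
classifyOTUs <- function(table, aln) {
  stopifnot(is(table, "OTUTable"), is(aln, "SeqAlignment"))
  m <- alignmentMatrix(aln)
  missing_ <- setdiff(unlist(table@members), rownames(m))
  if (length(missing_)) {
    stop("member id(s) missing from alignment: ", paste(missing_, collapse = ", "))
  }
  usable <- usableColumns(aln)
  cls <- vapply(table@members, function(mm) {
    if (length(mm) == 1L) return("singleton")
    sub <- m[mm, usable, drop = FALSE]
    allIdentical <- all(vapply(seq_len(ncol(sub)), function(j) {
      length(unique(sub[, j])) == 1L
    }, logical(1)))
    if (allIdentical) "quasi_singleton" else "multiton"
  }, "")
  table@classes <- unname(cls)
  table
}

#' Diversity indices from an OTU abundance vector
#'
#' Observed richness, Shannon-Wiener diversity (nats), species evenness,
#' and the Chao1 richness estimate. Chao1 uses the classic form
#' \code{S + F1^2 / (2 F2)} where \code{F1} and \code{F2} are the numbers
#' of singleton and doubleton OTUs; when \code{F2 = 0} the fallback
#' \code{S + F1 (F1 - 1) / 2} is used. Evenness is \code{H' / ln S} (0 when
#' \code{S = 1}).
#'
#' @param abundances integer vector of OTU sizes (all \code{>= 1}).
#' @return list with \code{S_obs}, \code{chao1}, \code{shannon_H},
#'   \code{evenness_E}, \code{F1}, \code{F2}.
#' @examples
#' # 35 OTUs of which 24 singletons and 1 doubleton: chao1 = 35 + 24^2/2
#' div <- diversityIndices(c(rep(1, 24), 2, rep(3, 10)))
#' div$chao1
#' @export
diversityIndices <- function(abundances) {
  if (length(abundances) == 0L) stop("empty abundance vector")
  if (any(abundances < 1)) stop("abundances must be >= 1")
  S <- length(abundances)
  N <- sum(abundances)
  p <- abundances / N
  H <- -sum(p * log(p))
  F1 <- sum(abundances == 1)
  F2 <- sum(abundances == 2)
  chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
  E <- if (S > 1) H / log(S) else 0
  list(S_obs = S, chao1 = chao1, shannon_H = H, evenness_E = E,
       F1 = F1, F2 = F2)
}

#' Rarefaction curve of an OTU abundance vector
#'
#' Expected OTU count as a function of subsample size. The analytic mode
#' evaluates the hypergeometric expectation
#' \code{E[S_n] = sum_i (1 - choose(N - n_i, n) / choose(N, n))}; the
#' Monte-Carlo mode averages observed OTU counts over seeded random
#' subsamples without replacement.
#'
#' @param abundances integer vector of OTU sizes.
#' @param method \code{"analytic"} (default) or \code{"montecarlo"}.
#' @param replicates Monte-Carlo replicates per sample size.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @param stride evaluate at sample sizes \code{seq(1, N, by = stride)}
#'   (N itself is always included).
#' @return data.frame with columns \code{n}, \code{expectedOtus} and, for
#'   Monte-Carlo, \code{sd} and \code{se} across replicates.
#' @export
rarefactionCurve <- function(abundances, method = c("analytic", "montecarlo"),
                             replicates = 100L, seed = NULL, stride = 1L) {
  method <- match.arg(method)
  if (length(abundances) == 0L || sum(abundances) < 1) {
    stop("empty abundance vector")
  }
  N <- sum(abundances)
  ns <- unique(c(seq.int(1L, N, by = stride), N))
  if (method == "analytic") {
    exp_ <- vapply(ns, function(n) {
      # log-scale hypergeometric expectation for numerical stability
      sum(1 - exp(lchoose(N - abundances, n) - lchoose(N, n)))
    }, numeric(1))
    data.frame(n = ns, expectedOtus = exp_)
  } else {
    if (replicates < 1L) stop("replicates must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    pool <- rep(seq_along(abundances), abundances)
    # one permutation per replicate: the OTU count at sample size n is the
    # number of distinct OTUs among the first n items of the permutation
    counts <- matrix(0, nrow = replicates, ncol = length(ns))
    for (r in seq_len(replicates)) {
      perm <- pool[sample.int(N, N)]
      cum <- cumsum(!duplicated(perm))
      counts[r, ] <- cum[ns]
    }
    sds <- apply(counts, 2L, stats::sd)
    data.frame(n = ns, expectedOtus = colMeans(counts), sd = sds,
               se = sds / sqrt(replicates))
  }
}
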