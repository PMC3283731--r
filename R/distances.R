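#' Transition/transversion counts for a pair of aligned sequences
#'
#' Sites where either sequence has a gap, an \code{N} or any other IUPAC
#' ambiguity code are excluded from the comparison. Differences between two
#' purines (A/G) or two pyrimidines (C/T) count as transitions (s); all
#' other differences count as transversions (v).
#'
#' @param a,b single-symbol character vectors or equal-length strings.
#' @param usable optional integer vector of column indices to restrict to
#'   before the per-pair exclusion of non-ACGT sites (used by the
#'   complete-deletion policy).
#' @return list with \code{s}, \code{v}, \code{sites}, \code{P = s/sites},
#'   \code{Q = v/sites}.
#' @export
substitutionSummary <- function(a, b, usable = NULL) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  stopifnot(length(a) == length(b))
  if (!is.null(usable)) {
    a <- a[usable]
    b <- b[usable]
  }
  ok <- a %in% .BASES & b %in% .BASES
  if (!any(ok)) stop("zero comparable sites")
  a <- a[ok]
  b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  s <- sum(ts)
  v <- sum(diff) - s
  sites <- sum(ok)
  list(s = s, v = v, sites = sites, P = s / sites, Q = v / sites)
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' \code{d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)}, correcting separately
#' for multiple transitions (proportion \code{P}) and transversions
#' (\code{Q}). When a logarithm argument is non-positive the distance is
#' undefined (substitution saturation); \code{NA} is returned and callers
#' record the pair rather than silently dropping it.
#'
#' @param P,Q observed proportions of transition and transversion sites.
#' @return distance in substitutions/site, or \code{NA} if undefined.
#' @examples
#' k2pDistance(0.1, 0.05)  # 0.17018
#' @export
k2pDistance <- function(P, Q) {
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2PMatrix: pairwise K2P distances with substitution accounting
#'
#' @slot d symmetric numeric matrix of K2P distances (NA where undefined).
#' @slot transitions,transversions,sites symmetric integer-valued matrices
#'   of per-pair counts.
#' @slot sitePolicy \code{"complete_deletion"} or \code{"pairwise_deletion"}.
#' @export
setClass("K2PMatrix",
  representation(d = "matrix", transitions = "matrix",
                 transversions = "matrix", sites = "matrix",
                 sitePolicy = "character"))

setValidity("K2PMatrix", function(object) {
  if (!isSymmetric(unname(object@d))) return("distance matrix must be symmetric")
  if (any(diag(object@d) != 0)) return("self-distances must be 0")
  if (any(object@d < 0, na.rm = TRUE)) return("distances must be >= 0")
  TRUE
})

setMethod("show", "K2PMatrix", function(object) {
  nundef <- sum(is.na(object@d[upper.tri(object@d)]))
  cat(sprintf("K2PMatrix: %d taxa (%s); %d undefined pair(s)\n",
              nrow(object@d), object@sitePolicy, nundef))
})

#' @rdname K2PMatrix-class
#' @param x a \code{K2PMatrix}.
#' @aliases distMatrix undefinedPairs
#' @export
distMatrix <- function(x) x@d

#' @rdname K2PMatrix-class
#' @export
undefinedPairs <- function(x) {
  idx <- which(is.na(x@d) & upper.tri(x@d), arr.ind = TRUE)
  data.frame(a = rownames(x@d)[idx[, 1]], b = colnames(x@d)[idx[, 2]])
}

#' Pairwise K2P distance matrix of an alignment
#'
#' Site policies: \code{"complete_deletion"} (default; drop every column
#' that contains a gap in any sequence, then exclude remaining non-ACGT
#' sites per pair — the convention of distance-based tree building on
#' gap-stripped alignments) or \code{"pairwise_deletion"} (exclude gap,
#' \code{N} and ambiguity sites per pair only — the convention of
#' saturation plotting).
#'
#' @param aln a [SeqAlignment-class] with at least 2 sequences.
#' @param sitePolicy see Details.
#' @return a [K2PMatrix-class].
#' @export
k2pMatrix <- function(aln, sitePolicy = c("complete_deletion",
                                          "pairwise_deletion")) {
  stopifnot(is(aln, "SeqAlignment"))
  sitePolicy <- match.arg(sitePolicy)
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  usable <- if (sitePolicy == "complete_deletion") usableColumns(aln) else NULL
  ids <- rownames(m)
  d <- s <- v <- sites <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ss <- substitutionSummary(m[i, ], m[j, ], usable = usable)
      dij <- k2pDistance(ss$P, ss$Q)
      d[i, j] <- d[j, i] <- dij
      s[i, j] <- s[j, i] <- ss$s
      v[i, j] <- v[j, i] <- ss$v
      sites[i, j] <- sites[j, i] <- ss$sites
    }
  }
  new("K2PMatrix", d = d, transitions = s, transversions = v, sites = sites,
      sitePolicy = sitePolicy)
}

#' Write a distance matrix to disk
#'
#' \code{"phylip"} writes the square PHYLIP matrix format (taxon count on
#' the first line); \code{"tsv"} writes one row per pair in long format
#' with the substitution counts.
#'
#' @param x a [K2PMatrix-class].
#' @param path output file path.
#' @param format \code{"phylip"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(x, path, format = c("phylip", "tsv")) {
  stopifnot(is(x, "K2PMatrix"))
  format <- match.arg(format)
  d <- x@d
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(c(formatC(rownames(d)[i], width = -10),
                         formatC(d[i, ], format = "f", digits = 6)),
                       collapse = "  "), con)
    }
  } else {
    ut <- which(upper.tri(d), arr.ind = TRUE)
    df <- data.frame(a = rownames(d)[ut[, 1]], b = colnames(d)[ut[, 2]],
                     d = d[ut], s = x@transitions[ut],
                     v = x@transversions[ut], sites = x@sites[ut])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Substitution saturation profile of an alignment
#'
#' One (d, s, v) record per defined sequence pair, where d is the K2P
#' distance and s, v the transition and transversion counts, plus
#' equal-width bins over the observed distances with means and standard
#' deviations of s and v per bin. Substitution saturation is diagnosed when
#' the frequency of transversions overtakes the frequency of transitions:
#' the crossover distance is the smallest bin midpoint where the mean
#' transversion count is at least the mean transition count (\code{NA} when
#' no bin crosses).
#'
#' @param aln a [SeqAlignment-class] with at least 2 sequences.
#' @param bins number of equal-width distance bins (default 20).
#' @param sitePolicy site policy passed to [k2pMatrix()]; the default for
#'   saturation plotting is pairwise deletion.
#' @return list with \code{pairs} (data.frame \code{a, b, d, s, v, P, Q},
#'   defined pairs only), \code{undefinedPairs}, \code{bins} (data.frame
#'   \code{mid, meanS, meanV, sdS, sdV, nPairs}) and
#'   \code{crossoverDistance}.
#' @export
saturationProfile <- function(aln, bins = 20L,
                              sitePolicy = c("pairwise_deletion",
                                             "complete_deletion")) {
  sitePolicy <- match.arg(sitePolicy)
  km <- k2pMatrix(aln, sitePolicy = sitePolicy)
  ids <- rownames(km@d)
  ut <- which(upper.tri(km@d), arr.ind = TRUE)
  pairs <- data.frame(
    a = ids[ut[, 1]], b = ids[ut[, 2]],
    d = km@d[ut], s = km@transitions[ut], v = km@transversions[ut],
    P = km@transitions[ut] / km@sites[ut],
    Q = km@transversions[ut] / km@sites[ut])
  undef <- pairs[is.na(pairs$d), c("a", "b")]
  pairs <- pairs[!is.na(pairs$d), , drop = FALSE]
  if (nrow(pairs) == 0L) stop("all pairwise distances are undefined")
  rng <- range(pairs$d)
  if (diff(rng) == 0) {
    binDf <- data.frame(mid = rng[1], meanS = mean(pairs$s),
                        meanV = mean(pairs$v), sdS = stats::sd(pairs$s),
                        sdV = stats::sd(pairs$v), nPairs = nrow(pairs))
  } else {
    brk <- seq(rng[1], rng[2], length.out = bins + 1L)
    bin <- cut(pairs$d, brk, include.lowest = TRUE)
    agg <- function(x, f) as.numeric(tapply(x, bin, f))
    binDf <- data.frame(
      mid = (brk[-1] + brk[-length(brk)]) / 2,
      meanS = agg(pairs$s, mean), meanV = agg(pairs$v, mean),
      sdS = agg(pairs$s, stats::sd), sdV = agg(pairs$v, stats::sd),
      nPairs = as.numeric(tapply(pairs$d, bin, length)))
    binDf$nPairs[is.na(binDf$nPairs)] <- 0
  }
  crossed <- !is.na(binDf$meanS) & !is.na(binDf$meanV) &
    binDf$meanV >= binDf$meanS & binDf$nPairs > 0 & binDf$mid > 0
  crossover <- if (any(crossed)) min(binDf$mid[crossed]) else NA_real_
  list(pairs = pairs, undefinedPairs = undef, bins = binDf,
       crossoverDistance = crossover)
}
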