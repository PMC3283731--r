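#' Column masks for the T3 treatment
#'
#' A column mask is a set of 1-based inclusive column intervals to excise
#' from an alignment. Intervals are normalised (sorted, merged) on
#' construction; they are represented as an [IRanges::IRanges] object.
#'
#' @param start,end integer vectors of interval bounds (1-based inclusive).
#' @return an \code{IRanges} of non-overlapping intervals.
#' @examples
#' columnMask(c(5, 7), c(8, 12))  # merges to 5-12
#' @export
columnMask <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start), all(start >= 1))
  IRanges::reduce(IRanges::IRanges(start = as.integer(start),
                                   end = as.integer(end)))
}

#' Read a column mask from a TSV file
#'
#' Expected format: two tab-separated integer columns, \code{start} and
#' \code{end}, 1-based inclusive; lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return an \code{IRanges} mask as from [columnMask()].
#' @export
readColumnMask <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#",
                          col.names = c("start", "end"))
  columnMask(df$start, df$end)
}

#' T2 treatment: recode terminal gaps as N
#'
#' Every maximal run of \code{-} at the 5' and 3' end of each sequence
#' becomes \code{N} (a terminal gap denotes a missing, unsequenced stretch
#' rather than an indel event). Internal gaps are untouched and the column
#' count is unchanged. The operation is idempotent and conserves the number
#' of nucleotide characters. A record that is entirely gaps becomes entirely
#' \code{N}.
#'
#' @param aln a [SeqAlignment-class] (any treatment; typically T1).
#' @return the T2-tagged alignment.
#' @examples
#' sequenceStrings(applyT2(SeqAlignment(c(s = "--ACGT-A--"))))
#' @export
applyT2 <- function(aln) {
  stopifnot(is(aln, "SeqAlignment"))
  m <- alignmentMatrix(aln)
  nc <- ncol(m)
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    nong <- which(row != "-")
    if (length(nong) == 0L) {
      m[i, ] <- "N"
      next
    }
    first <- nong[1L]
    last <- nong[length(nong)]
    if (first > 1L) m[i, seq_len(first - 1L)] <- "N"
    if (last < nc) m[i, (last + 1L):nc] <- "N"
  }
  new("SeqAlignment", seqs = m, treatment = "T2")
}

#' T3 treatment: excise ambiguously alignable columns
#'
#' Applies the T2 terminal-gap recoding first (unless the alignment is
#' already T2), then deletes the masked columns. The resulting width equals
#' the input width minus the number of masked columns, matching the reduced
#' alignment-length bookkeeping of the treatment protocol.
#'
#' @param aln a [SeqAlignment-class] with treatment T1 or T2.
#' @param mask an \code{IRanges} mask from [columnMask()],
#'   [readColumnMask()] or [detectAmbiguousColumns()]; an empty mask yields
#'   the T2 result with a T3 tag.
#' @return the T3-tagged alignment.
#' @export
applyT3 <- function(aln, mask) {
  stopifnot(is(aln, "SeqAlignment"))
  if (treatment(aln) == "T1") aln <- applyT2(aln)
  nc <- alignmentWidth(aln)
  if (length(mask) > 0) {
    if (min(IRanges::start(mask)) < 1L || max(IRanges::end(mask)) > nc) {
      stop("mask interval outside alignment columns [1, ", nc, "]")
    }
    drop <- unlist(lapply(seq_along(mask), function(k) {
      seq.int(IRanges::start(mask)[k], IRanges::end(mask)[k])
    }))
    keep <- setdiff(seq_len(nc), drop)
    if (length(keep) == 0L) stop("mask removes every column")
    m <- alignmentMatrix(aln)[, keep, drop = FALSE]
  } else {
    m <- alignmentMatrix(aln)
  }
  new("SeqAlignment", seqs = m, treatment = "T3")
}

#' Automatic detection of ambiguously alignable column ranges
#'
#' A surrogate for the manual curation step of the treatment protocol:
#' columns whose windowed mean gap fraction reaches \code{gapThreshold} OR
#' whose windowed mean entropy reaches \code{entropyThreshold} are flagged,
#' and maximal runs of flagged columns are returned as a mask. Defaults:
#' gap fraction 0.5, entropy 1.5 nats (the high-entropy run threshold),
#' window 5 columns.
#'
#' @param aln a [SeqAlignment-class].
#' @param gapThreshold flagged when windowed mean gap fraction exceeds this.
#' @param entropyThreshold nats; flagged when windowed mean entropy exceeds
#'   this.
#' @param window rolling window width (columns), \code{>= 1}.
#' @return an \code{IRanges} mask suitable for [applyT3()].
#' @export
detectAmbiguousColumns <- function(aln, gapThreshold = 0.5,
                                   entropyThreshold = 1.5, window = 5L) {
  stopifnot(is(aln, "SeqAlignment"), window >= 1L,
            gapThreshold >= 0, entropyThreshold >= 0)
  nc <- alignmentWidth(aln)
  if (window > nc) stop("window (", window, ") exceeds column count (", nc, ")")
  prof <- entropyProfile(aln)
  gapFrac <- gapFraction(prof)
  ent <- entropies(prof)
  flag <- .rollMean(gapFrac, window) >= gapThreshold |
    .rollMean(ent, window) >= entropyThreshold
  runs <- .flaggedRuns(flag)
  columnMask(runs$start, runs$end)
}
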