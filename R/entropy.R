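#' Gap- and ambiguity-aware column state frequencies
#'
#' Each cell of an alignment column contributes total weight 1, distributed
#' over the five entropy states \code{A, C, G, T, E} (where \code{E} is the
#' real-indel state):
#' \itemize{
#'   \item an unambiguous base contributes 1 to that base;
#'   \item \code{-} and \code{N} contribute 1/5 to each of the five states
#'     (a gap may be missing information realisable as any base, or a real
#'     indel; all five possibilities are weighted equally);
#'   \item any other IUPAC code contributes equal shares to its constituent
#'     bases (e.g. \code{Y} = 1/2 C + 1/2 T, \code{B} = 1/3 C + 1/3 G +
#'     1/3 T).
#' }
#' Frequencies are contribution sums divided by the column depth.
#'
#' With \code{nStates = 4}, \code{N} instead contributes 1/4 to each base
#' and nothing to \code{E} (sensitivity analysis switch); \code{-} always
#' uses the five-state rule.
#'
#' @param column character vector of symbols (one column of an alignment).
#' @param nStates 5 (default) or 4; see Details.
#' @return named numeric vector over \code{c("A","C","G","T","E")}, summing
#'   to 1.
#' @examples
#' columnStateFrequencies(c("A", "A", "C", "-"))
#' @export
columnStateFrequencies <- function(column, nStates = 5L) {
  if (length(column) == 0L) stop("empty column")
  unknown <- setdiff(unique(column), .ALPHABET)
  if (length(unknown)) stop("unknown symbol(s): ", paste(unknown, collapse = ", "))
  W <- .stateWeights(nStates)
  freq <- colSums(W[column, , drop = FALSE]) / length(column)
  freq
}

# Weight lookup: rows = alphabet symbols, cols = the five entropy states.
.stateWeights <- function(nStates = 5L) {
  key <- if (nStates == 5L) "w5" else "w4"
  cached <- .weightCache[[key]]
  if (!is.null(cached)) return(cached)
  W <- matrix(0, nrow = length(.ALPHABET), ncol = 5L,
              dimnames = list(.ALPHABET, .ENTROPY_STATES))
  for (sym in names(.IUPAC_CONSTITUENTS)) {
    if (sym == "N") next
    cons <- .IUPAC_CONSTITUENTS[[sym]]
    W[sym, cons] <- 1 / length(cons)
  }
  W["-", ] <- 1 / 5
  if (nStates == 5L) {
    W["N", ] <- 1 / 5
  } else {
    W["N", .BASES] <- 1 / 4
  }
  assign(key, W, envir = .weightCache)
  W
}
.weightCache <- new.env(parent = emptyenv())

#' Shannon entropy of a column's state frequencies
#'
#' The entropy at an alignment position is the negative sum over occurring
#' states of the frequency times its natural logarithm, in nats. Partial
#' entropies for non-occurring states are not added, so different columns
#' have different maximum possible entropies.
#'
#' @param freqs named numeric vector as from [columnStateFrequencies()].
#' @return entropy in nats (\code{>= 0}; 0 for single-state columns).
#' @examples
#' columnEntropy(columnStateFrequencies(c("A", "A", "C", "C")))  # ln 2
#' @export
columnEntropy <- function(freqs) {
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' EntropyProfile: per-column entropy of an alignment
#'
#' @slot entropies numeric, per-column entropy in nats.
#' @slot gapFlag logical, TRUE where the column contains at least one
#'   \code{-}.
#' @slot gapFraction numeric, fraction of \code{-} cells per column.
#' @slot occurringStates integer, number of entropy states with nonzero
#'   frequency per column.
#' @export
setClass("EntropyProfile",
  representation(entropies = "numeric", gapFlag = "logical",
                 gapFraction = "numeric", occurringStates = "integer"))

setValidity("EntropyProfile", function(object) {
  n <- length(object@entropies)
  if (length(object@gapFlag) != n || length(object@gapFraction) != n ||
      length(object@occurringStates) != n) {
    return("all per-column slots must have equal length")
  }
  if (any(object@entropies < -1e-12)) return("entropies must be non-negative")
  TRUE
})

setMethod("show", "EntropyProfile", function(object) {
  cat(sprintf(
    "EntropyProfile: %d columns; H_total = %.2f nats; %d gap-containing\n",
    length(object@entropies), sum(object@entropies), sum(object@gapFlag)))
})

#' @rdname EntropyProfile-class
#' @param x an \code{EntropyProfile}.
#' @aliases entropies gapFlag gapFraction occurringStates
#' @export
entropies <- function(x) x@entropies

#' @rdname EntropyProfile-class
#' @export
gapFlag <- function(x) x@gapFlag

#' @rdname EntropyProfile-class
#' @export
gapFraction <- function(x) x@gapFraction

#' @rdname EntropyProfile-class
#' @export
occurringStates <- function(x) x@occurringStates

#' Entropy profile of an alignment
#'
#' Computes the per-column gap-aware Shannon entropy for every alignment
#' position, flagging columns that contain at least one gap.
#'
#' @param aln a [SeqAlignment-class].
#' @param nStates feeder rule for \code{N}; see
#'   [columnStateFrequencies()].
#' @return an [EntropyProfile-class].
#' @export
entropyProfile <- function(aln, nStates = 5L) {
  stopifnot(is(aln, "SeqAlignment"))
  m <- alignmentMatrix(aln)
  depth <- nrow(m)
  W <- .stateWeights(nStates)
  idx <- match(m, .ALPHABET)
  # per-state contribution sums per column, fully vectorised
  freqs <- vapply(seq_len(5L), function(s) {
    colSums(matrix(W[, s][idx], nrow = depth)) / depth
  }, numeric(ncol(m)))
  if (ncol(m) == 1L) freqs <- matrix(freqs, nrow = 1L)
  H <- apply(freqs, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  k <- as.integer(rowSums(freqs > 0))
  gaps <- colSums(m == "-")
  new("EntropyProfile",
      entropies = pmax(H, 0),
      gapFlag = gaps > 0,
      gapFraction = gaps / depth,
      occurringStates = k)
}

#' Cumulative entropy and relative heterogeneity of an alignment
#'
#' Summarises an [EntropyProfile-class] into the cumulative entropy
#' \code{H_total} (partitioned exactly into \code{H_f} over gap-free and
#' \code{H_g} over gap-containing columns) and the relative heterogeneities
#' \code{h = H_total / H_max}, with \code{h_f} and \code{h_g} computed
#' analogously on the column subsets. \code{h} is 0 for a fully conserved
#' alignment (every column one state: the easiest alignment to make, but
#' carrying no phylogenetic information) and 1 when every column's
#' occurring states are equally frequent.
#'
#' Two conventions for the per-column maximum entropy are available:
#' \describe{
#'   \item{occurring_states (default)}{\code{H_max = sum(ln k_i)} where
#'     \code{k_i} is the number of states with nonzero frequency in column
#'     i; single-state columns contribute 0 to numerator and denominator.}
#'   \item{uniform5}{\code{H_max = ncol * ln 5}, a fixed per-column
#'     ceiling.}
#' }
#'
#' @param profile an [EntropyProfile-class].
#' @param hMaxMode \code{"occurring_states"} or \code{"uniform5"}.
#' @return a list: \code{H_total}, \code{H_f}, \code{H_g} (nats); \code{h},
#'   \code{h_f}, \code{h_g} (ratios in [0,1]); \code{meanEntropy},
#'   \code{medianEntropy}; \code{positionsHPosGapfree},
#'   \code{positionsHZeroGapfree}.
#' @export
heterogeneitySummary <- function(profile,
                                 hMaxMode = c("occurring_states", "uniform5")) {
  stopifnot(is(profile, "EntropyProfile"))
  hMaxMode <- match.arg(hMaxMode)
  H <- entropies(profile)
  if (length(H) == 0L) stop("empty profile")
  g <- gapFlag(profile)
  hmaxCol <- switch(hMaxMode,
    occurring_states = log(pmax(occurringStates(profile), 1L)),
    uniform5 = rep(log(5), length(H))
  )
  ratio <- function(num, den) {
    if (den == 0) {
      if (num > 0) warning("positive entropy with zero maximum entropy")
      return(0)
    }
    num / den
  }
  Hf <- sum(H[!g])
  Hg <- sum(H[g])
  if (sum(hmaxCol) == 0) {
    warning("fully conserved alignment: maximum entropy is 0, h set to 0")
  }
  list(
    H_total = Hf + Hg,
    H_f = Hf,
    H_g = Hg,
    h = ratio(Hf + Hg, sum(hmaxCol)),
    h_f = ratio(Hf, sum(hmaxCol[!g])),
    h_g = ratio(Hg, sum(hmaxCol[g])),
    meanEntropy = mean(H),
    medianEntropy = stats::median(H),
    positionsHPosGapfree = sum(!g & H > 0),
    positionsHZeroGapfree = sum(!g & H == 0)
  )
}

#' High-entropy runs in an entropy profile
#'
#' Maximal runs of consecutive columns whose entropy strictly exceeds
#' \code{threshold}, filtered to runs of at least \code{minLength} columns,
#' each annotated with the mean gap frequency over its columns. The default
#' threshold of 1.5 nats with a minimum length of 2 targets the
#' gap-dominated hypervariable blocks of spacer alignments.
#'
#' @param profile an [EntropyProfile-class].
#' @param threshold nats; a column belongs to a run when \code{H >
#'   threshold}.
#' @param minLength minimum run length, \code{>= 1}.
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive), \code{length}, \code{meanGapFrequency} (percent).
#' @export
highEntropyRuns <- function(profile, threshold = 1.5, minLength = 2L) {
  stopifnot(is(profile, "EntropyProfile"), threshold >= 0, minLength >= 1L)
  runs <- .flaggedRuns(entropies(profile) > threshold)
  runs$length <- runs$end - runs$start + 1L
  runs <- runs[runs$length >= minLength, , drop = FALSE]
  gf <- gapFraction(profile)
  runs$meanGapFrequency <- vapply(seq_len(nrow(runs)), function(i) {
    100 * mean(gf[runs$start[i]:runs$end[i]])
  }, numeric(1))
  rownames(runs) <- NULL
  runs
}
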