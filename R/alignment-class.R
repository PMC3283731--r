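#' SeqAlignment: a treated multiple sequence alignment
#'
#' The central data container of the package: an aligned set of DNA
#' sequences over the IUPAC alphabet extended with the indel symbol
#' \code{"-"}, stored as a character matrix (one row per sequence, one
#' column per alignment position) together with a treatment tag.
#'
#' Treatments follow the three-step protocol for amplicon alignments:
#' \describe{
#'   \item{T1}{the raw alignment as produced by the aligner;}
#'   \item{T2}{leading and trailing indel symbols of every sequence recoded
#'     as the ambiguity code \code{N} (a terminal gap denotes missing data,
#'     not an indel event);}
#'   \item{T3}{T2 with ambiguously alignable column ranges removed.}
#' }
#'
#' @slot seqs character matrix of single uppercase symbols; rownames are the
#'   unique sequence identifiers.
#' @slot treatment one of \code{"T1"}, \code{"T2"}, \code{"T3"}.
#'
#' @seealso [readAlignment()], [applyT2()], [applyT3()], [entropyProfile()]
#' @export
setClass("SeqAlignment",
  representation(seqs = "matrix", treatment = "character"),
  prototype(treatment = "T1")
)

setValidity("SeqAlignment", function(object) {
  m <- object@seqs
  msg <- character(0)
  if (!is.character(m)) msg <- c(msg, "sequence matrix must be character")
  if (nrow(m) < 1L || ncol(m) < 1L) {
    msg <- c(msg, "alignment must contain at least one sequence and one column")
  }
  ids <- rownames(m)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    msg <- c(msg, "sequence ids must be present, non-empty and unique")
  }
  bad <- array(!(m %in% .ALPHABET), dim = dim(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "non-alphabet symbol '%s' in sequence '%s' at column %d",
      m[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
  }
  if (!(length(object@treatment) == 1L &&
        object@treatment %in% c("T1", "T2", "T3"))) {
    msg <- c(msg, "treatment must be one of 'T1', 'T2', 'T3'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SeqAlignment from character strings
#'
#' Input residues are canonicalised: case-insensitive ingestion with
#' uppercase storage, RNA \code{U} mapped to \code{T}, NEXUS-style \code{?}
#' mapped to \code{N} and \code{.} to \code{-}.
#'
#' @param x named character vector of equal-length sequence strings, or a
#'   character matrix of single symbols with rownames.
#' @param ids sequence identifiers (defaults to \code{names(x)}).
#' @param treatment treatment tag, default \code{"T1"}.
#' @return a [SeqAlignment-class] object.
#' @examples
#' aln <- SeqAlignment(c(s1 = "AC-G", s2 = "ACTG"))
#' alignmentWidth(aln)
#' @export
SeqAlignment <- function(x, ids = NULL, treatment = "T1") {
  if (is.matrix(x)) {
    m <- x
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    if (is.null(ids)) ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    if (length(x) == 0L) stop("empty alignment: no sequences supplied")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      short <- ids[lens != max(lens)]
      stop("unequal sequence lengths; offending ids: ",
           paste(short, collapse = ", "))
    }
    m <- do.call(rbind, strsplit(as.character(x), "", fixed = TRUE))
    rownames(m) <- ids
  }
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  m[m == "?"] <- "N"
  m[m == "."] <- "-"
  bad <- array(!(m %in% .ALPHABET), dim = dim(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-alphabet symbol '%s' in sequence '%s' at column %d",
                 m[idx[1L], idx[2L]], rownames(m)[idx[1L]], idx[2L]))
  }
  new("SeqAlignment", seqs = m, treatment = treatment)
}

#' @describeIn SeqAlignment-class number of sequences and alignment width
#' @param x a \code{SeqAlignment}.
#' @export
setMethod("dim", "SeqAlignment", function(x) dim(x@seqs))

#' Accessors for SeqAlignment objects
#'
#' @param x a [SeqAlignment-class].
#' @return \code{sequenceIds}: character vector of identifiers;
#'   \code{alignmentWidth}: number of columns (bp); \code{alignmentMatrix}:
#'   the underlying character matrix; \code{treatment}: the treatment tag;
#'   \code{sequenceStrings}: named character vector of full-length strings.
#' @aliases sequenceIds alignmentWidth alignmentMatrix treatment
#'   sequenceStrings
#' @name SeqAlignment-accessors
#' @export
sequenceIds <- function(x) rownames(x@seqs)

#' @rdname SeqAlignment-accessors
#' @export
alignmentWidth <- function(x) ncol(x@seqs)

#' @rdname SeqAlignment-accessors
#' @export
alignmentMatrix <- function(x) x@seqs

#' @rdname SeqAlignment-accessors
#' @export
treatment <- function(x) x@treatment

#' @rdname SeqAlignment-accessors
#' @export
sequenceStrings <- function(x) {
  out <- apply(x@seqs, 1L, paste0, collapse = "")
  names(out) <- rownames(x@seqs)
  out
}

setMethod("show", "SeqAlignment", function(object) {
  cat(sprintf("SeqAlignment: %d sequences x %d columns [%s]\n",
              nrow(object@seqs), ncol(object@seqs), object@treatment))
  n <- min(nrow(object@seqs), 5L)
  w <- min(ncol(object@seqs), 60L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-12s %s%s\n", rownames(object@seqs)[i],
                paste0(object@seqs[i, seq_len(w)], collapse = ""),
                if (ncol(object@seqs) > w) "..." else ""))
  }
  if (nrow(object@seqs) > n) cat(sprintf("  ... %d more\n", nrow(object@seqs) - n))
})

#' Subset an alignment by sequence and/or column
#'
#' @param x a [SeqAlignment-class].
#' @param i sequence selector (ids or indices).
#' @param j column selector (1-based indices).
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{SeqAlignment}.
#' @export
setMethod("[", "SeqAlignment", function(x, i, j, ..., drop = FALSE) {
  m <- x@seqs
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  new("SeqAlignment", seqs = m, treatment = x@treatment)
})
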