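#' Read a multiple sequence alignment
#'
#' FASTA files are parsed with Biostrings; NEXUS DATA/CHARACTERS blocks
#' (simple dialect: \code{DIMENSIONS}, \code{FORMAT datatype=dna gap=-
#' missing=?}, \code{MATRIX}) with ape. Residues are canonicalised to
#' uppercase; \code{U} becomes \code{T}, NEXUS \code{?} becomes \code{N} and
#' \code{.} becomes \code{-}.
#'
#' @param path file path.
#' @param format \code{"fasta"} or \code{"nexus"}; \code{"auto"} guesses from
#'   the file extension (\code{.nex}/\code{.nxs} are NEXUS).
#' @param treatment treatment tag to attach, default \code{"T1"}.
#' @return a [SeqAlignment-class].
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "nexus"),
                          treatment = "T1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nxs|nexus)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("no sequences in ", path)
    strs <- as.character(ss)
    names(strs) <- sub("\\s.*$", "", names(ss))
    lens <- nchar(strs)
    if (length(unique(lens)) != 1L) {
      short <- names(strs)[lens != max(lens)]
      stop("records are not aligned (unequal lengths); offending ids: ",
           paste(short, collapse = ", "))
    }
    SeqAlignment(strs, treatment = treatment)
  } else {
    recs <- ape::read.nexus.data(path)
    m <- do.call(rbind, recs)
    rownames(m) <- names(recs)
    SeqAlignment(m, treatment = treatment)
  }
}

#' Write a multiple sequence alignment
#'
#' Round-trip fidelity: \code{readAlignment(writeAlignment(aln))} reproduces
#' ids, order and residues exactly, for both formats.
#'
#' @param aln a [SeqAlignment-class].
#' @param path output file path.
#' @param format \code{"fasta"} or \code{"nexus"}.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  stopifnot(is(aln, "SeqAlignment"))
  strs <- sequenceStrings(aln)
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(strs)
    Biostrings::writeXStringSet(ss, path)
  } else {
    recs <- strsplit(strs, "", fixed = TRUE)
    names(recs) <- names(strs)
    ape::write.nexus.data(recs, file = path, format = "dna",
                          interleaved = FALSE)
  }
  invisible(path)
}

#' Composition summary of an alignment
#'
#' Frequencies are computed over all cells of the alignment matrix: the four
#' standard bases, the total ambiguity frequency (with contributing codes
#' listed), and the gap frequency, all as percentages summing to 100. The
#' fraction of columns containing at least one gap is reported over columns.
#'
#' @param aln a [SeqAlignment-class].
#' @return a list with elements \code{baseFrequencies} (named percent vector
#'   A,C,G,T), \code{ambiguityFrequencyTotal} (percent),
#'   \code{ambiguityCodes} (codes observed), \code{gapFrequency} (percent),
#'   \code{gapContainingColumnFraction} (percent) and \code{columnCount}.
#' @examples
#' compositionSummary(SeqAlignment(c(a = "AC-G", b = "ACTG")))
#' @export
compositionSummary <- function(aln) {
  stopifnot(is(aln, "SeqAlignment"))
  m <- alignmentMatrix(aln)
  ncell <- length(m)
  tab <- table(factor(m, levels = .ALPHABET))
  basePct <- 100 * as.numeric(tab[.BASES]) / ncell
  names(basePct) <- .BASES
  ambTab <- tab[.AMBIG_CODES]
  ambCodes <- names(ambTab)[ambTab > 0]
  ambPct <- 100 * sum(ambTab) / ncell
  gapPct <- 100 * as.numeric(tab["-"]) / ncell
  gapCols <- colSums(m == "-") > 0
  list(
    baseFrequencies = basePct,
    ambiguityFrequencyTotal = ambPct,
    ambiguityCodes = sort(ambCodes),
    gapFrequency = gapPct,
    gapContainingColumnFraction = 100 * mean(gapCols),
    columnCount = ncol(m)
  )
}
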