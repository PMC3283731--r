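# Internal constants and helpers shared across modules.

# Constituent standard bases of every accepted symbol. 'N' and '-' are
# handled specially by the entropy feeder rule (1/5 over {A,C,G,T,E}).
.IUPAC_CONSTITUENTS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.ALPHABET <- c(names(.IUPAC_CONSTITUENTS), "-")
.BASES <- c("A", "C", "G", "T")
.AMBIG_CODES <- setdiff(names(.IUPAC_CONSTITUENTS), .BASES)  # includes N
.ENTROPY_STATES <- c("A", "C", "G", "T", "E")

#' Derive a stream-specific seed from a master seed
#'
#' All stochastic operations (bootstrap, Monte-Carlo rarefaction, the
#' simulator) draw their seeds from one master seed through this splitter,
#' so a single integer reproduces a whole analysis.
#'
#' @param seed master seed (single integer).
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer seed in [0, 2^31).
#' @keywords internal
deriveSeed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %% 2147483647)
}

# Merge a sorted logical vector of flagged columns into 1-based inclusive runs.
.flaggedRuns <- function(flag) {
  if (!any(flag)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Centred rolling mean with truncated windows at the edges.
.rollMean <- function(x, window) {
  n <- length(x)
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (window - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
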