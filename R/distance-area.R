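#' OTU distance-area table (IODA and RODA)
#'
#' The distance area of an OTU is the product of its internal distance
#' \code{d_int} (see [otuInternalDistance()]) and its member count
#' \code{n}. The Internal OTU Distance Area (IODA) expresses this as a
#' percentage of the tree's maximum possible distance area, which equals
#' the number of sequences in the alignment \code{N}:
#' \code{IODA = 100 * d_int * n / N}. The Realized OTU Distance Area
#' (RODA) replaces the maximum by a correction for the genetic distance
#' actually covered by all OTUs together; in the default
#' \code{"sum_internal"} mode the normaliser is the sum of internal
#' distances over all included OTUs,
#' \code{RODA = 100 * d_int * n / (N * sum_j d_int_j)}; the alternative
#' \code{"max_internal"} mode normalises by the largest internal distance
#' instead.
#'
#' Singletons have no internal distance and quasi-singletons (identical
#' sequences) have none measurable, so both are listed with
#' \code{excluded = TRUE} and carry no area. OTUs with exactly two
#' sequences sit on the minimum possible distance-area line (\code{n = 2});
#' the maximum line corresponds to \code{n = N}.
#'
#' @param otus a classified [OTUTable-class] (run [classifyOTUs()] first;
#'   unclassified tables are classified against \code{aln} when given).
#' @param tree \code{ape::phylo} over the sequences (for the MRCA internal
#'   distance).
#' @param N total number of sequences in the alignment.
#' @param rodaMode \code{"sum_internal"} (default) or \code{"max_internal"}.
#' @param distanceMethod passed to [otuInternalDistance()].
#' @param dm distance matrix, required when \code{distanceMethod =
#'   "pairwise"}.
#' @param aln optional [SeqAlignment-class] used to classify an
#'   unclassified table.
#' @return data.frame with columns \code{otuId, n, dInt, ioda, roda,
#'   class, onMinLine, excluded}; RODA is \code{NA} with a warning when
#'   all included internal distances are zero.
#' @export
distanceAreaTable <- function(otus, tree, N, rodaMode = c("sum_internal",
                                                          "max_internal"),
                              distanceMethod = "mrca", dm = NULL,
                              aln = NULL) {
  stopifnot(is(otus, "OTUTable"), N >= 2)
  rodaMode <- match.arg(rodaMode)
  if (all(is.na(otuClasses(otus)))) {
    if (is.null(aln)) stop("OTU table is unclassified; supply `aln`")
    otus <- classifyOTUs(otus, aln)
  }
  members <- otuMembers(otus)
  classes <- otuClasses(otus)
  sizes <- otuSizes(otus)
  dInt <- rep(NA_real_, length(members))
  for (k in seq_along(members)) {
    if (classes[k] %in% c("singleton", "quasi_singleton")) next
    dInt[k] <- otuInternalDistance(tree, members[[k]],
                                   method = distanceMethod, dm = dm)
  }
  excluded <- classes %in% c("singleton", "quasi_singleton") |
    (!is.na(dInt) & dInt == 0)
  ioda <- ifelse(excluded, NA_real_, 100 * dInt * sizes / N)
  inc <- !excluded
  denom <- switch(rodaMode,
    sum_internal = sum(dInt[inc]),
    max_internal = if (any(inc)) max(dInt[inc]) else 0)
  roda <- rep(NA_real_, length(members))
  if (any(inc)) {
    if (denom == 0) {
      warning("all included internal distances are zero: RODA undefined")
    } else {
      roda[inc] <- 100 * dInt[inc] * sizes[inc] / (N * denom)
    }
  }
  data.frame(
    otuId = names(members), n = as.integer(sizes), dInt = dInt,
    ioda = ioda, roda = roda, class = classes,
    onMinLine = !excluded & sizes == 2L, excluded = excluded,
    row.names = NULL)
}

#' Coordinates for an OTU distance-area plot
#'
#' Emits the point set (x = internal distance, y = RODA or IODA) for the
#' included OTUs, the minimum (\code{n = 2}) and maximum (\code{n = N})
#' boundary lines as slopes through the origin, and vertical guide lines
#' at requested K2P cutoffs. All points lie between the two boundary lines
#' inclusive; OTUs with two sequences lie exactly on the minimum line. The
#' result is plain data suitable for serialisation to TSV/JSON and
#' external plotting.
#'
#' @param table output of [distanceAreaTable()].
#' @param N total number of sequences.
#' @param yAxis \code{"roda"} (default) or \code{"ioda"}.
#' @param cutoffGuides numeric K2P distances for vertical guide lines.
#' @return list with \code{points} (data.frame \code{otuId, x, y, n}),
#'   \code{minLineSlope}, \code{maxLineSlope} (y per unit distance) and
#'   \code{cutoffGuides}.
#' @export
plotCoordinates <- function(table, N, yAxis = c("roda", "ioda"),
                            cutoffGuides = numeric(0)) {
  yAxis <- match.arg(yAxis)
  inc <- !table$excluded
  pts <- data.frame(otuId = table$otuId[inc], x = table$dInt[inc],
                    y = table[[if (yAxis == "roda") "roda" else "ioda"]][inc],
                    n = table$n[inc], row.names = NULL)
  # area = d * n scaled by the mode's denominator: the slope in d is
  # proportional to n, so the n = 2 and n = N loci bound all points.
  denomScale <- if (nrow(pts) && any(table$dInt[inc] > 0)) {
    i <- which(inc)[which(table$dInt[inc] > 0)[1]]
    table[[if (yAxis == "roda") "roda" else "ioda"]][i] /
      (table$dInt[i] * table$n[i])
  } else {
    if (yAxis == "ioda") 100 / N else NA_real_
  }
  list(points = pts,
       minLineSlope = 2 * denomScale,
       maxLineSlope = N * denomScale,
       cutoffGuides = as.numeric(cutoffGuides))
}

#' Sweep OTU cutoffs and link parent/child OTUs
#'
#' Clusters the alignment at a strictly increasing series of identity
#' cutoffs and links each OTU obtained at a stricter cutoff (the "child")
#' to the OTU at the previous, looser cutoff that contains its seed
#' sequence (the "parent"). The lineage table makes it easy to see how
#' OTUs split as the cutoff tightens and which OTUs are robust to the
#' cutoff choice.
#'
#' @param aln a [SeqAlignment-class].
#' @param cutoffs strictly increasing identity fractions in (0, 1);
#'   default \code{c(0.95, 0.97, 0.98, 0.99)}.
#' @param linkage,psiMode passed to [clusterOTUs()].
#' @return list with \code{tables} (one classified [OTUTable-class] per
#'   cutoff, named by cutoff) and \code{lineage} (data.frame
#'   \code{parentCutoff, parentOtu, childCutoff, childOtu}).
#' @export
cutoffSweep <- function(aln, cutoffs = c(0.95, 0.97, 0.98, 0.99),
                        linkage = "seed", psiMode = "global") {
  stopifnot(all(diff(cutoffs) > 0), all(cutoffs > 0 & cutoffs < 1))
  tables <- lapply(cutoffs, function(co) {
    classifyOTUs(clusterOTUs(aln, co, linkage = linkage, psiMode = psiMode),
                 aln)
  })
  names(tables) <- as.character(cutoffs)
  lineage <- NULL
  for (k in seq_along(cutoffs)[-1]) {
    par <- tables[[k - 1]]
    chl <- tables[[k]]
    parentOf <- function(id) {
      hit <- vapply(otuMembers(par), function(mm) id %in% mm, logical(1))
      names(otuMembers(par))[which(hit)[1]]
    }
    rows <- data.frame(
      parentCutoff = cutoffs[k - 1],
      parentOtu = vapply(otuSeeds(chl), parentOf, ""),
      childCutoff = cutoffs[k],
      childOtu = names(otuMembers(chl)), row.names = NULL)
    lineage <- rbind(lineage, rows)
  }
  list(tables = tables, lineage = lineage)
}
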