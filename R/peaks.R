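#' @importFrom stats dist hclust
NULL

POST_TIMES <- c(1, 2, 5, 20)

#' Call recruitment peaks from bin counts
#'
#' The fold-enrichment detector with a kinetic filter: an intergenic region
#' yields (at most one) peak when some bin's normalized count reaches
#' \code{threshold}-fold the per-time-point genome average at one or more
#' post-stress time points \emph{and} the threshold is met at 2 and/or 5 min
#' (the kinetic filter matching the rapid nuclear entry of Crz1). The summit
#' is the bin with the maximum normalized count over all post-stress time
#' points, the reported span is the widest contiguous run of
#' super-threshold bins containing the summit, and the time of maximum is
#' the post-stress time with the highest per-time maximum count (ties go to
#' the earliest time). Per-time fold-changes versus time 0 use a pseudocount
#' in numerator and denominator to guard zero baselines.
#'
#' @param counts a [BinCounts-class] from [countBins()].
#' @param threshold minimum fold enrichment over the genome average
#'   (default 2).
#' @param kineticTimes post-stress minutes at which the threshold must be
#'   met (default \code{c(2, 5)}).
#' @param strengthBounds fold boundaries between weak/moderate and
#'   moderate/strong (default \code{c(5, 10)}).
#' @param pseudocount normalized-count pseudocount for fold-changes
#'   (default 1).
#' @return peak \code{GRanges} (one per qualifying region) with metadata
#'   columns \code{region_id}, \code{summit_start}, \code{summit_end},
#'   \code{max_t0}, \code{enrich_1/2/5/20}, \code{fc_*}, \code{log2fc_*}
#'   (including \code{log2fc_0 = 0}), \code{time_of_max}, \code{max_enrich}
#'   and \code{strength}.
#' @seealso [assignGenes()], [classifyStrength()], [kineticFilterPass()]
#' @export
callPeaks <- function(counts, threshold = 2, kineticTimes = c(2, 5),
                      strengthBounds = c(5, 10), pseudocount = 1) {
  stopIfNot(threshold > 0, "threshold must be positive")
  stopIfNot(all(kineticTimes %in% POST_TIMES), "invalid kinetic times")
  stopIfNot(length(strengthBounds) == 2 && diff(strengthBounds) > 0 &&
              all(strengthBounds > 0), "strength bounds must be ascending")
  rr <- rowRanges(counts)
  N <- normCounts(counts)
  avg <- genomeAverage(counts)
  enr <- sweep(N, 2, avg, "/")
  postCols <- tpName(POST_TIMES)
  kinCols <- tpName(kineticTimes)

  out <- list()
  for (ridx in split(seq_along(rr), factor(rr$region_id,
                                           levels = unique(rr$region_id)))) {
    e <- enr[ridx, , drop = FALSE]
    n <- N[ridx, , drop = FALSE]
    perTimeMax <- apply(n, 2, max)
    perTimeMaxEnr <- perTimeMax / avg
    if (!any(perTimeMaxEnr[kinCols] >= threshold)) next
    if (!any(perTimeMaxEnr[postCols] >= threshold)) next

    post <- n[, postCols, drop = FALSE]
    summitLocal <- ((which.max(post) - 1L) %% nrow(post)) + 1L
    tMax <- POST_TIMES[which.max(perTimeMax[postCols])]
    maxEnrich <- max(perTimeMaxEnr[postCols])

    superBin <- apply(e[, postCols, drop = FALSE], 1, max) >= threshold
    runs <- rle(superBin)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & starts <= summitLocal & ends >= summitLocal)
    span <- c(starts[hit], ends[hit])

    bins <- rr[ridx]
    summitBin <- bins[summitLocal]
    fc <- (perTimeMax + pseudocount) / (perTimeMax["t0"] + pseudocount)
    pk <- GRanges(seqnames(summitBin),
                  IRanges(start(bins)[span[1]], end(bins)[span[2]]))
    pk$region_id <- bins$region_id[1]
    pk$summit_start <- start(summitBin)
    pk$summit_end <- end(summitBin)
    pk$max_t0 <- unname(perTimeMax["t0"])
    for (t in POST_TIMES)
      mcols(pk)[[paste0("enrich_", t)]] <- unname(perTimeMaxEnr[tpName(t)])
    for (t in TIMEPOINTS) {
      mcols(pk)[[paste0("fc_", t)]] <- unname(fc[tpName(t)])
      mcols(pk)[[paste0("log2fc_", t)]] <- unname(log2(fc[tpName(t)]))
    }
    pk$time_of_max <- tMax
    pk$max_enrich <- unname(maxEnrich)
    out[[length(out) + 1L]] <- pk
  }
  if (!length(out)) {
    pk <- GRanges()
    pk$region_id <- character(0)
    return(pk)
  }
  peaks <- unname(unlist(GRangesList(out)))
  peaks$strength <- classifyStrength(peaks$max_enrich, strengthBounds,
                                     minimum = threshold)
  sort(peaks, ignore.strand = TRUE)
}

#' Classify peak strength from maximum enrichment
#'
#' Weak for folds in \[2, 5), moderate in \[5, 10\] (the boundary folds 5 and
#' 10 both count as moderate), strong above 10, with configurable bounds.
#'
#' @param e numeric vector of maximum fold enrichments (each >= the calling
#'   threshold; lower values are a contract violation and raise an error).
#' @param bounds length-2 ascending fold boundaries (default \code{c(5, 10)}).
#' @param minimum the peak-calling threshold (default 2).
#' @return character vector of \code{"weak"}, \code{"moderate"},
#'   \code{"strong"}.
#' @examples
#' classifyStrength(c(2.5, 5, 10, 12))
#' @export
classifyStrength <- function(e, bounds = c(5, 10), minimum = 2) {
  stopIfNot(all(e >= minimum),
            "enrichment below the calling threshold cannot be classified")
  ifelse(e > bounds[2], "strong",
         ifelse(e >= bounds[1], "moderate", "weak"))
}

#' Re-check the kinetic filter on called peaks
#'
#' TRUE for peaks whose enrichment reaches the threshold at 2 and/or 5 min;
#' every peak emitted by [callPeaks()] satisfies this by construction.
#'
#' @param peaks peak \code{GRanges} from [callPeaks()].
#' @param threshold fold threshold (default 2).
#' @param kineticTimes minutes checked (default \code{c(2, 5)}).
#' @return logical vector.
#' @export
kineticFilterPass <- function(peaks, threshold = 2, kineticTimes = c(2, 5)) {
  if (length(peaks) == 0L) return(logical(0))
  m <- vapply(kineticTimes, function(t) mcols(peaks)[[paste0("enrich_", t)]],
              numeric(length(peaks)))
  if (length(peaks) == 1L) m <- matrix(m, nrow = 1L)
  apply(m >= threshold, 1, any)
}

#' Assign peaks to flanking genes
#'
#' A region whose two flanking genes both transcribe away from it is a
#' divergent promoter serving both genes; when exactly one flank's promoter
#' faces the region the peak is attributed to that single gene; convergent
#' flanks leave the peak unassigned. The left flank's promoter faces the
#' region when the left gene is on the minus strand, the right flank's when
#' the right gene is on the plus strand.
#'
#' @param peaks peak \code{GRanges} from [callPeaks()].
#' @param regions intergenic \code{GRanges} with flanking-gene columns (as
#'   from [readIntergenicRegions()] or [buildGenome()]).
#' @return \code{peaks} with added columns \code{assignment}
#'   (\code{"single"}, \code{"divergent"}, \code{"unassigned"}),
#'   \code{gene1} and \code{gene2} (NA unless divergent).
#' @export
assignGenes <- function(peaks, regions) {
  if (length(peaks) == 0L) {
    peaks$assignment <- character(0)
    peaks$gene1 <- character(0)
    peaks$gene2 <- character(0)
    return(peaks)
  }
  i <- match(peaks$region_id, regions$region_id)
  stopIfNot(!anyNA(i), "peak region_id missing from regions")
  ls <- regions$left_strand[i]
  rs <- regions$right_strand[i]
  unknown <- !(ls %in% c("+", "-")) | !(rs %in% c("+", "-"))
  if (any(unknown))
    warning(sum(unknown), " region(s) with unknown flank strand left unassigned")
  leftFaces <- ls == "-"
  rightFaces <- rs == "+"
  assignment <- ifelse(unknown, "unassigned",
                ifelse(leftFaces & rightFaces, "divergent",
                ifelse(leftFaces | rightFaces, "single", "unassigned")))
  gene1 <- rep(NA_character_, length(peaks))
  gene2 <- rep(NA_character_, length(peaks))
  div <- which(assignment == "divergent")
  gene1[div] <- regions$left_gene[i][div]
  gene2[div] <- regions$right_gene[i][div]
  sing <- which(assignment == "single")
  gene1[sing] <- ifelse(leftFaces[sing], regions$left_gene[i][sing],
                        regions$right_gene[i][sing])
  peaks$assignment <- assignment
  peaks$gene1 <- gene1
  peaks$gene2 <- gene2
  peaks
}

#' Percentage of peaks confirmed by an external peak list
#'
#' The fraction (as a percentage, one decimal) of peaks overlapping, by at
#' least 1 bp, any interval of an externally produced peak list such as a
#' MACS or GEM BED export.
#'
#' @param peaks peak \code{GRanges} (denominator).
#' @param external \code{GRanges} of external peaks.
#' @return percentage rounded to one decimal.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:10 * 100, width = 50))
#' b <- a[1:9]
#' peakSetOverlap(a, b)  # 90.0
#' @export
peakSetOverlap <- function(peaks, external) {
  stopIfNot(length(peaks) > 0L, "empty peak set")
  round(100 * sum(overlapsAny(peaks, external, ignore.strand = TRUE)) /
          length(peaks), 1)
}

#' Hierarchically cluster peak fold-change kinetics
#'
#' Complete-linkage agglomerative clustering (Euclidean distance) of the
#' per-peak log2 fold-change vectors at 0, 1, 2, 5 and 20 min, the procedure
#' used to group recruitment kinetics.
#'
#' @param peaks peak \code{GRanges} from [callPeaks()] (>= 2 peaks).
#' @return an \code{\link[stats]{hclust}} object; leaf labels are region ids.
#' @export
clusterFoldChanges <- function(peaks) {
  stopIfNot(length(peaks) >= 2L, "need at least two peaks to cluster")
  m <- foldChangeMatrix(peaks)
  hclust(dist(m), method = "complete")
}

# peaks -> log2 FC matrix (rows = peaks, cols = the five time points)
foldChangeMatrix <- function(peaks) {
  m <- vapply(TIMEPOINTS, function(t) mcols(peaks)[[paste0("log2fc_", t)]],
              numeric(length(peaks)))
  if (length(peaks) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- peaks$region_id
  colnames(m) <- tpName(TIMEPOINTS)
  m
}
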