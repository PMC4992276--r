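#' @importFrom IRanges slidingWindows
NULL

#' Tile intergenic regions into contiguous bins
#'
#' Each region is partitioned into contiguous, non-overlapping bins of
#' \code{binSize} nt (default 50); the last bin of a region may be shorter.
#' The number of bins per region is \code{ceiling(length / binSize)}.
#'
#' @param regions non-overlapping intergenic \code{GRanges} with a
#'   \code{region_id} column.
#' @param binSize bin width in bp (default 50).
#' @return \code{GRanges} bin grid with \code{region_id} and 1-based
#'   \code{bin_index} metadata columns, in region order.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 220),
#'                             region_id = "ig1")
#' tileRegions(r)  # 3 bins of widths 50, 50, 20
#' @export
tileRegions <- function(regions, binSize = 50) {
  stopIfNot(binSize >= 1, "binSize must be >= 1")
  stopIfNot(!is.null(regions$region_id), "regions need a region_id column")
  if (length(regions) > 1L) {
    red <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
    stopIfNot(length(red) == length(regions), "regions must not overlap")
  }
  wins <- slidingWindows(regions, width = binSize, step = binSize)
  bins <- unlist(wins)
  nb <- lengths(wins)
  bins$region_id <- rep(regions$region_id, nb)
  bins$bin_index <- unlist(lapply(nb, seq_len))
  names(bins) <- NULL
  bins
}

#' Remove identical reads
#'
#' Collapses reads with identical (chromosome, start, end, strand) to a
#' single read, emulating duplicate removal before quantitation.
#'
#' @param reads read \code{GRanges}.
#' @return deduplicated \code{GRanges}.
#' @export
dedupReads <- function(reads) {
  unique(reads)
}

#' Quantitate bins across the time course
#'
#' Counts, for every bin and time point, the deduplicated reads overlapping
#' the bin by at least 1 bp (so a read spanning several bins increments each
#' of them). Counts are depth-normalized to the largest dataset: the scale
#' factor of time point t is \code{max(totals) / totals[t]}, so the deepest
#' time point keeps factor 1 and all factors are >= 1. The per-time-point
#' genome average -- the enrichment denominator downstream -- is the mean
#' normalized count over all bins of the intergenic probe universe.
#'
#' @param grid bin \code{GRanges} from [tileRegions()].
#' @param readsets named list (\code{t0, t1, t2, t5, t20}) of deduplicated
#'   read \code{GRanges}; reads are deduplicated again defensively.
#' @param midpoint if TRUE, assign each read to the single bin containing its
#'   midpoint instead of every overlapped bin.
#' @return a [BinCounts-class] object.
#' @export
countBins <- function(grid, readsets, midpoint = FALSE) {
  stopIfNot(length(grid) > 0L, "empty bin grid")
  stopIfNot(all(tpName(TIMEPOINTS) %in% names(readsets)),
            "readsets must be named t0, t1, t2, t5, t20")
  readsets <- lapply(readsets[tpName(TIMEPOINTS)], dedupReads)
  totals <- vapply(readsets, length, integer(1))
  if (any(totals == 0L))
    stop("time point with zero reads: scale factor undefined", call. = FALSE)
  raw <- vapply(readsets, function(r) {
    if (midpoint) r <- resize(r, width = 1L, fix = "center")
    countOverlaps(grid, r, ignore.strand = TRUE)
  }, numeric(length(grid)))
  sf <- max(totals) / totals
  norm <- sweep(raw, 2, sf, "*")
  se <- SummarizedExperiment(
    assays = list(raw = raw, norm = norm),
    rowRanges = grid,
    colData = DataFrame(timepoint = TIMEPOINTS,
                        row.names = tpName(TIMEPOINTS)))
  metadata(se) <- list(totals = totals, scale_factors = sf,
                       genome_average = colMeans(norm))
  new("BinCounts", se)
}

#' Export bin counts as TSV
#'
#' Bin coordinates plus one normalized-count column per time point.
#'
#' @param counts a [BinCounts-class].
#' @param path output path.
#' @param header optional \code{#} provenance lines.
#' @return the path, invisibly.
#' @export
writeBinCounts <- function(counts, path, header = NULL) {
  rr <- rowRanges(counts)
  d <- data.frame(region_id = rr$region_id, bin_index = rr$bin_index,
                  chrom = as.character(seqnames(rr)),
                  start = start(rr), end = end(rr))
  d <- cbind(d, as.data.frame(normCounts(counts)))
  writeTsv(d, path, header)
  invisible(path)
}
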