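#' TSS-aligned percent-of-fold-change binding profiles
#'
#' For every gene assigned to a peak and having a reported TSS, computes the
#' fold-change (versus time 0, with pseudocount) of each 50-bp bin in the
#' 1 kb spanning upstream from the TSS, evaluated at the peak's time of
#' maximum, and normalizes the bins to percentages of the row total so that
#' profiles of different magnitudes are comparable. Bins are ordered from
#' -1000 bp to the TSS along the gene's 5'-to-TSS direction (minus-strand
#' genes are flipped). Bins extending beyond the peak's intergenic region
#' are truncated: they contribute 0 and the remaining bins are normalized to
#' 100.
#'
#' @param peaks assigned peak \code{GRanges} (after [assignGenes()]).
#' @param readsets named list of deduplicated read \code{GRanges}
#'   (\code{t0..t20}); counts are normalized with \code{counts}' scale
#'   factors.
#' @param counts the [BinCounts-class] the peaks were called from (source of
#'   scale factors).
#' @param tss TSS \code{GRanges} with \code{gene_id} (genes without a TSS are
#'   skipped with a message).
#' @param regions intergenic \code{GRanges} with \code{region_id}.
#' @param span bp upstream of the TSS (default 1000).
#' @param binSize profile bin width (default 50; \code{span} must be a
#'   multiple).
#' @param pseudocount fold-change pseudocount (default 1).
#' @param time fixed time point (minutes) at which to evaluate fold-changes,
#'   or NULL (default) to use each peak's own time of maximum.
#' @return list with \code{profile} (matrix, rows = gene/peak pairs, 20
#'   columns summing to 100), \code{group} (strength class per row),
#'   \code{gene}, \code{region_id}.
#' @seealso [groupAverageProfile()]
#' @export
geneProfiles <- function(peaks, readsets, counts, tss, regions,
                         span = 1000, binSize = 50, pseudocount = 1,
                         time = NULL) {
  stopIfNot(span %% binSize == 0, "span must be a multiple of binSize")
  nbin <- span %/% binSize
  sf <- scaleFactors(counts)
  readsets <- lapply(readsets[tpName(TIMEPOINTS)], dedupReads)
  tssOf <- setNames(start(tss), tss$gene_id)
  tssStrand <- setNames(as.character(strand(tss)), tss$gene_id)
  regionOf <- match(peaks$region_id, regions$region_id)

  rows <- list()
  meta <- list()
  skipped <- 0L
  for (k in seq_along(peaks)) {
    genes <- stats::na.omit(c(peaks$gene1[k], peaks$gene2[k]))
    for (g in genes) {
      if (is.na(tssOf[g])) { skipped <- skipped + 1L; next }
      tPoint <- if (is.null(time)) peaks$time_of_max[k] else time
      prof <- oneProfile(g, tssOf[g], tssStrand[g],
                         as.character(seqnames(peaks))[k],
                         regions[regionOf[k]], readsets, sf,
                         tPoint, nbin, binSize, pseudocount)
      if (is.null(prof)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- prof
      meta[[length(meta) + 1L]] <-
        data.frame(gene = g, region_id = peaks$region_id[k],
                   group = peaks$strength[k], stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    message(skipped, " gene(s) without usable TSS/profile excluded")
  if (!length(rows))
    return(list(profile = matrix(numeric(0), ncol = nbin),
                group = character(0), gene = character(0),
                region_id = character(0)))
  md <- do.call(rbind, meta)
  profile <- do.call(rbind, rows)
  colnames(profile) <- paste0("bp_", seq(-span, -binSize, by = binSize))
  rownames(profile) <- md$gene
  list(profile = profile, group = md$group, gene = md$gene,
       region_id = md$region_id)
}

oneProfile <- function(gene, tssPos, gstrand, chrom, region, readsets, sf,
                       tPoint, nbin, binSize, pseudocount) {
  if (gstrand == "+") {
    starts <- seq(tssPos - nbin * binSize, tssPos - binSize, by = binSize)
    bins <- GRanges(chrom, IRanges(starts, width = binSize))
  } else {
    starts <- seq(tssPos + nbin * binSize - binSize + 1L, tssPos + 1L,
                  by = -binSize)
    bins <- GRanges(chrom, IRanges(starts, width = binSize))
  }
  # truncate bins falling outside the intergenic region
  inside <- start(bins) >= start(region) & end(bins) <= end(region)
  if (!any(inside)) return(NULL)
  c0 <- countOverlaps(bins, readsets$t0, ignore.strand = TRUE) * sf["t0"]
  ct <- countOverlaps(bins, readsets[[tpName(tPoint)]],
                      ignore.strand = TRUE) * sf[tpName(tPoint)]
  fc <- (ct + pseudocount) / (c0 + pseudocount)
  fc[!inside] <- 0
  100 * fc / sum(fc)
}

#' Average profile per strength group
#'
#' Arithmetic mean of the percent profiles within each strength group; since
#' every row sums to 100, each group average also sums to 100.
#'
#' @param profiles result of [geneProfiles()].
#' @return matrix with one row per non-empty group (weak/moderate/strong) and
#'   the profile's bin columns.
#' @export
groupAverageProfile <- function(profiles) {
  stopIfNot(nrow(profiles$profile) > 0L, "no profile rows")
  groups <- intersect(c("strong", "moderate", "weak"),
                      unique(profiles$group))
  out <- t(vapply(groups, function(g)
    colMeans(profiles$profile[profiles$group == g, , drop = FALSE]),
    numeric(ncol(profiles$profile))))
  rownames(out) <- groups
  out
}
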