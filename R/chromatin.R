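#' @importFrom stats dhyper
NULL

#' Stratify peaks into early and late responders
#'
#' Early response: time of maximum at 1 or 2 min after stress; late
#' response: 5 or 20 min. The partition is exhaustive and exclusive.
#'
#' @param peaks peak \code{GRanges} with a \code{time_of_max} column.
#' @return factor with levels \code{early}, \code{late}.
#' @export
stratifyEarlyLate <- function(peaks) {
  factor(ifelse(peaks$time_of_max %in% c(1, 2), "early", "late"),
         levels = c("early", "late"))
}

#' Fraction of features overlapping a chromatin track
#'
#' Two modes matching the two association questions: \code{"point"} counts a
#' feature when its midpoint lies inside a track interval (CDRE centers in
#' nucleosome-free regions), \code{"interval"} when the feature span
#' overlaps the track by at least 1 bp (peak spans against histone-mark
#' domains).
#'
#' @param x feature \code{GRanges} (CDRE hits or peak spans).
#' @param track \code{GRanges} of the chromatin track.
#' @param mode \code{"point"} or \code{"interval"}.
#' @return list with \code{fraction}, \code{hits} and \code{total}.
#' @export
featureOverlapFraction <- function(x, track, mode = c("point", "interval")) {
  mode <- match.arg(mode)
  stopIfNot(length(x) > 0L, "empty feature set")
  if (mode == "point")
    x <- resize(x, width = 1L, fix = "center")
  hits <- sum(overlapsAny(x, track, ignore.strand = TRUE))
  list(fraction = hits / length(x), hits = hits, total = length(x))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration over all tables
#' with the observed margins, summing the probabilities of tables no more
#' probable than the observed one (with a 1e-7 relative tolerance on the
#' comparison, the conventional definition). Used for the early/late versus
#' chromatin-feature association tables.
#'
#' @param table 2x2 matrix of non-negative counts (rows = early/late,
#'   columns = in/out of feature), or the count \code{a} with \code{b, c, d}.
#' @param b,c,d remaining counts when \code{table} is given as a scalar.
#' @return the two-sided p-value in (0, 1\]; if any margin is zero the test
#'   is degenerate and p = 1 is returned with a warning.
#' @examples
#' fisherExactTest(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
fisherExactTest <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopIfNot(all(dim(table) == 2L), "table must be 2x2")
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
  }
  stopIfNot(all(c(a, b, c, d) >= 0), "counts must be non-negative")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    warning("a zero margin makes the test degenerate; p = 1")
    return(1)
  }
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  pObs <- dhyper(a, m, nn, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Early/late chromatin association summary
#'
#' For each track, computes the early and late overlap fractions (CDRE
#' centers for NFR, peak spans for the histone marks) and the exact
#' association p-value from the resulting 2x2 table.
#'
#' @param peaks assigned peak \code{GRanges} with \code{time_of_max}.
#' @param cdre \code{GRanges} of central CDREs with a \code{region_id}
#'   column (from [centralCdre()]); peaks without one are dropped from the
#'   NFR row.
#' @param nfr,h3k4me3,h3k4ac chromatin track \code{GRanges}.
#' @return data.frame with one row per (feature, group): hits, totals,
#'   fraction, and the feature's two-sided Fisher p-value.
#' @export
chromatinAssociation <- function(peaks, cdre, nfr, h3k4me3, h3k4ac) {
  grp <- stratifyEarlyLate(peaks)
  res <- list()
  addFeature <- function(name, x, byGroup, track, mode) {
    tab <- matrix(0, 2, 2)
    for (gi in 1:2) {
      g <- levels(grp)[gi]
      sel <- byGroup == g
      if (!any(sel)) next
      ov <- featureOverlapFraction(x[sel], track, mode)
      tab[gi, ] <- c(ov$hits, ov$total - ov$hits)
      res[[length(res) + 1L]] <<- data.frame(
        feature = name, group = g, hits = ov$hits, total = ov$total,
        fraction = ov$fraction, stringsAsFactors = FALSE)
    }
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      fisherExactTest(tab) else NA_real_
    for (j in seq_len(length(res)))
      if (res[[j]]$feature == name) res[[j]]$pvalue <<- p
  }
  if (length(cdre)) {
    cg <- grp[match(cdre$region_id, peaks$region_id)]
    addFeature("nfr", cdre, cg, nfr, "point")
  }
  addFeature("h3k4me3", peaks, grp, h3k4me3, "interval")
  addFeature("h3k4ac", peaks, grp, h3k4ac, "interval")
  do.call(rbind, res)
}
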