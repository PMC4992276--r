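# Craft a BinCounts whose numbers are known exactly: 20 one-bin regions on
# chrT. Every bin carries one baseline read at every time point; `extras`
# adds reads (distinct width-1 spans, so nothing collapses in dedup) per bin
# at a time point. Totals are equalized with filler reads outside the grid,
# so every scale factor is exactly 1 and normalized counts equal raw counts.
craftCounts <- function(extras, nbins = 20) {
  regions <- GRanges("chrT", IRanges(1 + (seq_len(nbins) - 1) * 1000,
                                     width = 50),
                     region_id = sprintf("r%02d", seq_len(nbins)))
  grid <- tileRegions(regions)
  binReads <- function(b, n)
    GRanges("chrT", IRanges(start(grid)[b] + seq_len(n) - 1, width = 1))
  perTp <- lapply(c(t0 = 0, t1 = 1, t2 = 2, t5 = 5, t20 = 20), function(t) {
    add <- extras[[paste0("t", t)]]
    if (is.null(add)) add <- rep(0, nbins)
    do.call("c", lapply(seq_len(nbins), function(b)
      binReads(b, 1 + add[b])))
  })
  top <- max(vapply(perTp, length, integer(1))) + 10L
  readsets <- lapply(perTp, function(r) c(r, fillerReads(top - length(r))))
  list(counts = countBins(grid, readsets), regions = regions)
}

test_that("a bin enriched over twofold at 5 min qualifies as a peak", {
  # bin 1 holds 5 reads at t5, the 19 others 1: genome average 1.2
  cc <- craftCounts(list(t5 = c(4, rep(0, 19))))
  avg5 <- genomeAverage(cc$counts)[["t5"]]
  expect_equal(avg5, (5 + 19) / 20)
  peaks <- callPeaks(cc$counts)
  expect_equal(length(peaks), 1L)
  expect_equal(peaks$region_id, "r01")
  expect_equal(peaks$enrich_5, 5 / avg5)
  expect_equal(peaks$time_of_max, 5)
})

test_that("enrichment only at 20 min is rejected by the kinetic filter", {
  cc <- craftCounts(list(t20 = c(5, rep(0, 19))))
  expect_equal(length(callPeaks(cc$counts)), 0L)
  # and sub-threshold everywhere yields no peak
  cc2 <- craftCounts(list(t2 = rep(0, 20)))
  expect_equal(length(callPeaks(cc2$counts)), 0L)
})

test_that("summit, span and per-time maxima are taken over post-stress times", {
  # one region of several bins: summit must be the max bin, span the
  # contiguous super-threshold run containing it
  regions <- GRanges("chrT", IRanges(1, 500), region_id = "big")
  grid <- tileRegions(regions)  # 10 bins
  mk <- function(perBin) {
    parts <- fillerReads(200)
    for (b in seq_along(perBin))
      if (perBin[b] > 0)
        parts <- c(parts, GRanges("chrT", IRanges(start(grid)[b] +
                                                    seq_len(perBin[b]) - 1,
                                                  width = 1)))
    parts
  }
  readsets <- list(t0 = mk(rep(1, 10)),
                   t1 = mk(c(1, 1, 8, 12, 8, 1, 1, 4, 1, 1)),
                   t2 = mk(c(1, 1, 4, 8, 4, 1, 1, 1, 1, 1)),
                   t5 = mk(rep(1, 10)),
                   t20 = mk(rep(1, 10)))
  counts <- countBins(grid, readsets)
  peaks <- callPeaks(counts)
  expect_equal(length(peaks), 1L)
  expect_equal(peaks$summit_start, start(grid)[4])
  expect_equal(peaks$time_of_max, 1)  # t1 carries the overall max bin
  # span covers bins 3-5 (the contiguous run over threshold), not bin 8
  expect_equal(start(peaks), start(grid)[3])
  expect_equal(end(peaks), end(grid)[5])
  expect_true(kineticFilterPass(peaks))
})

test_that("ties in time of max break toward the earliest time", {
  cc <- craftCounts(list(t1 = c(5, rep(0, 19)), t2 = c(5, rep(0, 19))))
  peaks <- callPeaks(cc$counts)
  expect_equal(peaks$time_of_max, 1)
})

test_that("fold-changes use the pseudocount and log2fc_0 is zero", {
  cc <- craftCounts(list(t2 = c(8, rep(0, 19))))
  peaks <- callPeaks(cc$counts, pseudocount = 1)
  expect_equal(peaks$log2fc_0, 0)
  # max at t2 is 9, baseline max at t0 is 1: fc_2 = (9+1)/(1+1) = 5
  expect_equal(peaks$fc_2, 5)
  expect_equal(peaks$log2fc_2, log2(5))
})

test_that("strength classification is total on [2, Inf) with closed moderate bounds", {
  expect_equal(classifyStrength(c(12, 7, 5, 10, 4.99, 2)),
               c("strong", "moderate", "moderate", "moderate", "weak", "weak"))
  expect_error(classifyStrength(1.5), "below")
  e <- seq(2, 20, by = 0.01)
  lab <- classifyStrength(e)
  expect_true(all(lab %in% c("weak", "moderate", "strong")))
  expect_true(all(lab[e < 5] == "weak"))
  expect_true(all(lab[e >= 5 & e <= 10] == "moderate"))
  expect_true(all(lab[e > 10] == "strong"))
})

test_that("raising the threshold never increases the number of called peaks", {
  run <- defaultRun()
  n <- vapply(c(2, 3, 5, 8), function(thr)
    length(callPeaks(run$counts, threshold = thr)), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("gene assignment follows flanking-gene orientation", {
  regions <- GRanges(rep("chrT", 4), IRanges(c(1, 1001, 2001, 3001), width = 500),
                     region_id = paste0("r", 1:4),
                     left_gene = paste0("L", 1:4),
                     left_strand = c("-", "+", "-", "+"),
                     right_gene = paste0("R", 1:4),
                     right_strand = c("+", "+", "-", "-"))
  peaks <- do.call("c", lapply(1:4, function(i)
    manualPeak("chrT", paste0("r", i), start(regions)[i] + 100)))
  peaks <- assignGenes(peaks, regions)
  expect_equal(peaks$assignment,
               c("divergent", "single", "single", "unassigned"))
  expect_equal(peaks$gene1, c("L1", "R2", "L3", NA))
  expect_equal(peaks$gene2, c("R1", NA, NA, NA))

  regions$left_strand[1] <- "?"
  expect_warning(pk <- assignGenes(peaks, regions), "unknown")
  expect_equal(pk$assignment[1], "unassigned")
})

test_that("peak-set overlap percentages reproduce printed confirmation rates", {
  peaks <- GRanges("chr1", IRanges((1:152) * 1000, width = 200))
  expect_equal(peakSetOverlap(peaks, peaks[1:143] ), 94.1)
  expect_equal(peakSetOverlap(peaks, peaks[1:145]), 95.4)
  expect_equal(peakSetOverlap(peaks, peaks), 100.0)
  expect_error(peakSetOverlap(peaks[0], peaks), "empty")
})

test_that("complete-linkage clustering matches simple reference cases", {
  pk <- function(id, fc) {
    p <- manualPeak("chrT", id, 1)
    for (i in seq_along(fc))
      mcols(p)[[paste0("log2fc_", c(0, 1, 2, 5, 20)[i])]] <- fc[i]
    p
  }
  peaks <- c(pk("a", c(0, 0, 0, 0, 0)), pk("b", c(0, 0, 0, 0, 10)),
             pk("c", c(0, 0, 0, 0, 11)), pk("d", c(0, 0, 0, 0, 0)))
  hc <- clusterFoldChanges(peaks)
  expect_equal(min(hc$height), 0)  # identical rows a, d merge at distance 0
  first <- sort(hc$merge[1, ])
  expect_equal(first, c(-4, -1))   # the identical pair merges first
  expect_equal(sort(hc$merge[2, ]), c(-3, -2))  # then the 10/11 pair
  expect_error(clusterFoldChanges(peaks[1]), "two peaks")
})

test_that("clustering agrees with a brute-force complete-linkage oracle", {
  for (s in 1:10) {
    set.seed(400 + s)
    m <- matrix(rnorm(40), nrow = 8)
    peaks <- do.call("c", lapply(1:8, function(i) {
      p <- manualPeak("chrT", paste0("r", i), 1)
      for (j in 1:5)
        mcols(p)[[paste0("log2fc_", c(0, 1, 2, 5, 20)[j])]] <- m[i, j]
      p
    }))
    hc <- clusterFoldChanges(peaks)
    ref <- naiveCompleteLinkage(m)
    expect_equal(unname(hc$height), ref$heights, tolerance = 1e-9)
    expect_equal(hclustPartitions(hc), ref$partitions)
  }
})
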