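# A 1200-bp intergenic region on chrP whose right gene starts at 1301 (+
# strand TSS), so the 1 kb upstream window 301..1300 lies inside the region.
profileFixture <- function(tReads = NULL, t0Reads = NULL) {
  regions <- GRanges("chrP", IRanges(101, 1300), region_id = "rP",
                     left_gene = "gL", left_strand = "+",
                     right_gene = "gR", right_strand = "+")
  tss <- GRanges("chrP", IRanges(1301, width = 1), strand = "+",
                 gene_id = "gR")
  mk <- function(extra) {
    base <- fillerReads(50, chrom = "chrP")
    if (!is.null(extra)) c(base, extra) else base
  }
  readsets <- list(t0 = mk(t0Reads), t1 = mk(NULL), t2 = mk(tReads),
                   t5 = mk(NULL), t20 = mk(NULL))
  counts <- countBins(tileRegions(regions), readsets)
  peaks <- manualPeak("chrP", "rP", 701, gene1 = "gR", timeOfMax = 2)
  list(regions = regions, tss = tss, readsets = readsets, counts = counts,
       peaks = peaks)
}

test_that("uniform fold-change gives a flat 5 percent profile", {
  fx <- profileFixture()
  prof <- geneProfiles(fx$peaks, fx$readsets, fx$counts, fx$tss, fx$regions)
  expect_equal(nrow(prof$profile), 1L)
  expect_equal(unname(prof$profile[1, ]), rep(5, 20))
  expect_equal(sum(prof$profile[1, ]), 100)
  expect_equal(prof$group, "strong")
})

test_that("concentrated signal peaks in its bin and rows still sum to 100", {
  # 60 distinct reads piled on the bin 451..500 = 850 bp upstream of the TSS
  pile <- GRanges("chrP", IRanges(451 + 0:59, width = 1), strand = "+")
  fx <- profileFixture(tReads = pile)
  prof <- geneProfiles(fx$peaks, fx$readsets, fx$counts, fx$tss, fx$regions)
  row <- prof$profile[1, ]
  expect_equal(sum(row), 100, tolerance = 1e-9)
  expect_equal(unname(which.max(row)), 4L)  # bins run -1000.., -850 is no. 4
  expect_identical(names(which.max(row)), "bp_-850")
  expect_gt(max(row), 50)
})

test_that("minus-strand genes give the mirrored profile", {
  # mirror fixture: gene on -, TSS at 100, upstream window 101..1100
  regions <- GRanges("chrP", IRanges(101, 1300), region_id = "rM",
                     left_gene = "gL", left_strand = "-",
                     right_gene = "gR", right_strand = "-")
  tss <- GRanges("chrP", IRanges(100, width = 1), strand = "-",
                 gene_id = "gL")
  pile <- GRanges("chrP", IRanges(901 + 0:59, width = 1), strand = "+")
  mk <- function(extra = NULL) {
    base <- fillerReads(50, chrom = "chrP")
    if (!is.null(extra)) c(base, extra) else base
  }
  readsets <- list(t0 = mk(), t1 = mk(), t2 = mk(pile), t5 = mk(), t20 = mk())
  counts <- countBins(tileRegions(regions), readsets)
  peaks <- manualPeak("chrP", "rM", 701, gene1 = "gL", timeOfMax = 2)
  prof <- geneProfiles(peaks, readsets, counts, tss, regions)
  row <- prof$profile[1, ]
  # pile at 901..960 is 801-860 bp upstream of the minus-strand TSS at 100
  expect_identical(names(which.max(row)), "bp_-850")
  expect_equal(sum(row), 100, tolerance = 1e-9)
})

test_that("windows reaching outside the region truncate and renormalize", {
  # region is only 600 bp: bins beyond it contribute 0
  regions <- GRanges("chrP", IRanges(701, 1300), region_id = "rS",
                     left_gene = "gL", left_strand = "+",
                     right_gene = "gR", right_strand = "+")
  tss <- GRanges("chrP", IRanges(1301, width = 1), strand = "+",
                 gene_id = "gR")
  mk <- function() fillerReads(50, chrom = "chrP")
  readsets <- list(t0 = mk(), t1 = mk(), t2 = mk(), t5 = mk(), t20 = mk())
  counts <- countBins(tileRegions(regions), readsets)
  peaks <- manualPeak("chrP", "rS", 1001, gene1 = "gR", timeOfMax = 2)
  prof <- geneProfiles(peaks, readsets, counts, tss, regions)
  row <- prof$profile[1, ]
  expect_equal(sum(row), 100, tolerance = 1e-9)
  expect_equal(unname(row[1:8]), rep(0, 8))     # outside the region
  expect_equal(unname(row[9:20]), rep(100 / 12, 12))
})

test_that("genes without a TSS are excluded with a notice", {
  fx <- profileFixture()
  tssWrong <- GRanges("chrP", IRanges(1301, width = 1), strand = "+",
                      gene_id = "someOtherGene")
  expect_message(
    prof <- geneProfiles(fx$peaks, fx$readsets, fx$counts, tssWrong,
                         fx$regions),
    "excluded")
  expect_equal(nrow(prof$profile), 0L)
})

test_that("group averages preserve the percent normalization", {
  profiles <- list(
    profile = rbind(c(100, rep(0, 19)), c(0, 100, rep(0, 18)),
                    c(100, rep(0, 19))),
    group = c("strong", "strong", "weak"))
  avg <- groupAverageProfile(profiles)
  expect_equal(unname(avg["strong", 1:3]), c(50, 50, 0))
  expect_equal(unname(avg["weak", 1]), 100)
  expect_equal(unname(rowSums(avg)), c(100, 100), tolerance = 1e-9)
  # two identical rows average to themselves
  same <- list(profile = rbind(rep(5, 20), rep(5, 20)),
               group = c("moderate", "moderate"))
  expect_equal(unname(groupAverageProfile(same)["moderate", ]), rep(5, 20))
  expect_error(groupAverageProfile(list(profile = matrix(numeric(0), 0, 20),
                                        group = character(0))), "no profile")
})

test_that("shifting planted summits by 50 bp shifts the group argmax one bin", {
  argmaxAt <- function(offset) {
    cfg <- simConfig(seed = 50, nIntergenic = 40L,
                     nPlanted = c(strong = 6L, moderate = 0L, weak = 0L),
                     summitTssOffset = offset)
    res <- runPipeline(cfg, verbose = FALSE)
    unname(which.max(res$groupProfiles["strong", ]))
  }
  a400 <- argmaxAt(400)
  a350 <- argmaxAt(350)
  expect_equal(a400 - a350, -1L)
})
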