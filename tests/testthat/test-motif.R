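certaintyPwm <- function(bases = rep("C", 9)) {
  p <- t(vapply(bases, function(b) as.numeric(DNA_BASES_T() == b), numeric(4)))
  motifPWM(p)
}
DNA_BASES_T <- function() c("A", "C", "G", "T")

test_that("window scores are log2-odds sums with floored zero probabilities", {
  uni <- motifPWM(matrix(0.25, 9, 4))
  expect_equal(scoreWindow(uni, "ACGTACGTA"), 0)
  expect_equal(scoreWindow(uni, "CCCCCCCCC", strand = "-"), 0)

  # one certain position contributes log2(1/0.25) = 2 bits
  p <- matrix(0.25, 9, 4)
  p[5, ] <- c(0, 1, 0, 0)
  pwm <- motifPWM(p)
  expect_equal(scoreWindow(pwm, "AAAACAAAA"), 2)
  # a mismatching certain position is floored at 1e-4, not -Inf
  expect_equal(scoreWindow(pwm, "AAAAGAAAA"), log2(1e-4 / 0.25))
  # minus strand scores the reverse complement
  expect_equal(scoreWindow(pwm, "TTTTGTTTT", strand = "-"), 2)
  expect_error(scoreWindow(pwm, "ACGT"), "width")
  expect_message(na <- scoreWindow(pwm, "AAAANAAAA"), "ambiguous")
  expect_true(is.na(na))
})

test_that("the best-scoring window is the per-position argmax string", {
  set.seed(31)
  p <- matrix(rgamma(20, 1), 5, 4)
  p <- p / rowSums(p)
  pwm <- motifPWM(p)
  idx <- as.matrix(expand.grid(rep(list(1:4), 5)))
  seqs <- apply(idx, 1, function(i) paste(DNA_BASES_T()[i], collapse = ""))
  scores <- vapply(seqs, function(s) scoreWindow(pwm, s), numeric(1))
  argmax <- paste(DNA_BASES_T()[apply(p, 1, which.max)], collapse = "")
  expect_equal(seqs[which.max(scores)], argmax)
  expect_equal(max(scores), scoreWindow(pwm, argmax))
})

test_that("the exact score distribution sums to 1 and matches brute force", {
  d <- scoreDistribution(defaultCrz1PWM())
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(d$tail[nrow(d)], 1, tolerance = 1e-12)
  brute <- sort(unique(round(bruteForceScores(defaultCrz1PWM()), 9)),
                decreasing = TRUE)
  expect_equal(d$score, brute)
})

test_that("p-value thresholds are minimal and achieve the exact tail", {
  pwm <- defaultCrz1PWM()
  thr <- thresholdFromPvalue(pwm, 1e-3)
  d <- scoreDistribution(pwm)
  expect_lte(max(d$tail[d$score >= thr]), 1e-3)
  below <- max(d$score[d$score < thr])
  expect_gt(d$tail[match(below, d$score)], 1e-3)

  # degenerate uniform matrix: every window scores 0, nothing can pass
  expect_warning(thrU <- thresholdFromPvalue(motifPWM(matrix(0.25, 9, 4)),
                                             1e-3), "Inf")
  expect_equal(thrU, Inf)

  # all-certainty matrix: exactly one 9-mer attains the maximum 18 bits,
  # with tail 4^-9 <= 1e-3; with the 1e-4 probability floor the minimal
  # passing level is one floored mismatch (tail 28/4^9, still <= 1e-3)
  cert <- certaintyPwm()
  dC <- scoreDistribution(cert)
  expect_equal(max(dC$score), 18)
  expect_equal(dC$tail[1], 4^-9, tolerance = 1e-9)
  thrC <- thresholdFromPvalue(cert, 1e-3)
  expect_equal(thrC, 16 + log2(4e-4), tolerance = 1e-6)
  expect_lte(max(dC$tail[dC$score >= thrC]), 1e-3)
  expect_error(thresholdFromPvalue(cert, 2), "in \\(0, 1\\)")
})

test_that("region scans recover planted CDREs and respect strand symmetry", {
  sim <- buildGenome(simConfig(seed = 9, nIntergenic = 60L,
                               nPlanted = c(strong = 3L, moderate = 4L,
                                            weak = 5L)))
  hits <- scanRegions(sim$genome, sim$regions, defaultCrz1PWM())
  expect_true(all(hits$pvalue <= 1e-3))
  truth <- sim$truth
  found <- vapply(seq_len(nrow(truth)), function(k) {
    h <- hits[hits$region_id == truth$region_id[k]]
    any(start(h) == truth$cdre_start[k] &
          as.character(strand(h)) == truth$cdre_strand[k])
  }, logical(1))
  expect_true(all(found))  # planted sites beat the scan threshold by design

  # scanning the reverse-complemented genome mirrors the hit set
  rcGenome <- reverseComplement(sim$genome)
  L <- setNames(width(sim$genome), names(sim$genome))
  rcRegions <- GRanges(seqnames(sim$regions),
                       IRanges(L[as.character(seqnames(sim$regions))] -
                                 end(sim$regions) + 1,
                               width = width(sim$regions)),
                       region_id = sim$regions$region_id)
  rcHits <- scanRegions(rcGenome, rcRegions, defaultCrz1PWM())
  expect_equal(length(rcHits), length(hits))
  # a hit at [s, e] maps to [L - e + 1, L - s + 1] with flipped strand
  mapped <- paste(rcHits$region_id,
                  L[as.character(seqnames(rcHits))] - end(rcHits) + 1,
                  ifelse(as.character(strand(rcHits)) == "+", "-", "+"))
  expect_setequal(mapped,
                  paste(hits$region_id, start(hits),
                        as.character(strand(hits))))
  expect_equal(sort(round(rcHits$score, 6)), sort(round(hits$score, 6)))
})

test_that("hit counts on random sequence match the binomial expectation", {
  pwm <- defaultCrz1PWM()
  counts <- vapply(1:30, function(s) {
    set.seed(700 + s)
    g <- DNAStringSet(paste(sample(c("A", "C", "G", "T"), 3000,
                                   replace = TRUE), collapse = ""))
    names(g) <- "chrR"
    r <- GRanges("chrR", IRanges(1, 3000), region_id = "r1")
    length(scanRegions(g, r, pwm))
  }, numeric(1))
  expected <- 2 * (3000 - 8) * 1e-3  # both strands, achieved tail <= 1e-3
  se <- sqrt(expected / 30)
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.3)
})

test_that("degenerate core patterns match on both strands", {
  g <- DNAStringSet(c(chr1 = "AAGCCAAAAA", chr2 = "ACGCCAAGCCAAAAAGGCAA"))
  r <- GRanges(c("chr1", "chr2"), IRanges(1, c(10, 20)),
               region_id = c("r1", "r2"))
  hits <- patternSearch(g, r, "GCC")
  h1 <- hits[hits$region_id == "r1"]
  expect_true(any(start(h1) == 3 & as.character(strand(h1)) == "+"))
  # GGC at chr2:16 is GCC on the minus strand
  h2m <- hits[hits$region_id == "r2" & as.character(strand(hits)) == "-"]
  expect_true(any(start(h2m) == 16))

  alt <- patternSearch(g, r, "(C/A)GCC")
  plus <- alt[as.character(strand(alt)) == "+"]
  expect_setequal(start(plus[plus$region_id == "r2"]), c(2, 7))  # CGCC, AGCC
  expect_error(patternSearch(g, r, "G%C"), "malformed")
})

test_that("the central CDRE is the best-scoring hit near the summit", {
  pk <- manualPeak("chr1", "r1", 1000)
  mkHit <- function(pos, score, strand = "+") {
    h <- GRanges("chr1", IRanges(pos, pos + 8), strand = strand,
                 region_id = "r1")
    h$score <- score
    h
  }
  # summit midpoint is 1024.5; score wins over distance
  hits <- c(mkHit(1054, 8), mkHit(1014, 6))
  best <- centralCdre(pk, hits, window = 100)
  expect_equal(best$score, 8)
  # equal scores: smaller distance wins, then + strand
  hits <- c(mkHit(1100, 5), mkHit(1030, 5, "-"))
  expect_equal(start(centralCdre(pk, hits)), 1030)
  hits <- c(mkHit(1016, 5, "-"), mkHit(1025, 5, "+"))
  expect_equal(as.character(strand(centralCdre(pk, hits))), "+")
  # nothing within the window
  expect_null(centralCdre(pk, mkHit(2000, 9)))
  expect_null(centralCdre(pk, mkHit(1000, 9)[0]))
})

test_that("PWMs built from sites use the pseudocount closed form", {
  pwm <- buildPwm(rep("CAGCCTCAC", 10), pseudocount = 1)
  p <- pwmProbs(pwm)
  expect_equal(unname(p[1, "C"]), 11 / 14)
  expect_equal(unname(p[2, "A"]), 11 / 14)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))

  pwm0 <- buildPwm(c("AAAAAAAAA", "CCCCCCCCC"), pseudocount = 0)
  expect_equal(unname(pwmProbs(pwm0)[4, ]), c(0.5, 0.5, 0, 0))
  expect_error(buildPwm(c("AAAA", "AAAAA")), "same width")
  expect_error(buildPwm(character(0)), "at least one")
})

test_that("site sampling and rebuilding recovers the generator PWM", {
  withr::with_seed(77, {
    sites <- samplePwmSites(defaultCrz1PWM(), 1000)
  })
  rebuilt <- buildPwm(sites, pseudocount = 1)
  tv <- rowSums(abs(pwmProbs(rebuilt) - pwmProbs(defaultCrz1PWM()))) / 2
  expect_lt(max(tv), 0.1)
})

test_that("consensus strings follow the single/pair/N rules", {
  expect_equal(pwmConsensus(certaintyPwm(strsplit("CAGCCTCAC", "")[[1]])),
               "CAGCCTCAC")
  p <- matrix(0.25, 9, 4)
  p[4, ] <- c(0.45, 0.45, 0.05, 0.05)
  expect_equal(substr(pwmConsensus(motifPWM(p)), 4, 8), "(A/C)")
  expect_equal(pwmConsensus(defaultCrz1PWM()), "NNN(A/C)GCCNC")
})

test_that("a strict terminal-C site set refines to a PWM with P(G) < 0.05", {
  # strong-recruiter sites: final position always C
  withr::with_seed(5, {
    core <- samplePwmSites(defaultCrz1PWM(), 150)
  })
  sites <- paste0(substr(core, 1, 8), "C")
  refined <- buildPwm(sites, pseudocount = 1)
  expect_lt(pwmProbs(refined)[9, "G"], 0.05)
  expect_gt(pwmProbs(refined)[9, "C"], 0.9)
})

test_that("information content spans 0 (uniform) to 2 (certain) bits", {
  expect_equal(informationContent(motifPWM(matrix(0.25, 9, 4))), rep(0, 9))
  expect_equal(informationContent(certaintyPwm()), rep(2, 9))
  ic <- informationContent(defaultCrz1PWM())
  expect_true(all(ic >= 0 & ic <= 2))
  expect_gt(ic[5], ic[1])  # the core G is far more informative than flanks
})
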