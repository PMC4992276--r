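# Independent reference implementations used to cross-check the package.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(Biostrings)
})

# Brute-force complete-linkage agglomeration in O(n^3): at each step merge
# the pair of clusters with the smallest maximum inter-point Euclidean
# distance (ties: lowest-index pair first). Returns merge heights and the
# partition (list of member index sets) after each merge.
naiveCompleteLinkage <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestH <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < bestH - 1e-12) {
          bestH <- h
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bestH)
    partitions[[length(partitions) + 1L]] <-
      canonicalPartition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

canonicalPartition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, numeric(1), 1))]
}

# Partition sequence of an hclust object: the canonical partition after each
# of the n-1 merges, derived from cutree.
hclustPartitions <- function(hc) {
  n <- length(hc$order)
  lapply((n - 1L):1L, function(k) {
    grp <- cutree(hc, k = k)
    canonicalPartition(unname(split(seq_len(n), grp)))
  })
}

# Exhaustive two-sided Fisher p-value from first principles (log-binomial
# coefficients, no dhyper): enumerate every table with the observed margins.
fisherOracle <- function(a, b, c, d) {
  k <- a + b; m <- a + c; nn <- b + d; N <- a + b + c + d
  support <- max(0, k - nn):min(k, m)
  logp <- lchoose(m, support) + lchoose(nn, k - support) - lchoose(N, k)
  p <- exp(logp)
  pObs <- exp(lchoose(m, a) + lchoose(nn, k - a) - lchoose(N, k))
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# All 9-mers scored one sequence at a time against a PWM (floored log-odds),
# independent of the package's outer-sum accumulation.
bruteForceScores <- function(pwm) {
  lo <- log2(pmax(pwmProbs(pwm), 1e-4)) -
    matrix(log2(pmax(pwmBackground(pwm), 1e-4)),
           nrow(pwmProbs(pwm)), 4, byrow = TRUE)
  w <- nrow(lo)
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(idx))
  for (j in seq_len(w)) sc <- sc + lo[j, idx[, j]]
  sc
}

randomIntervals <- function(n, seed) {
  set.seed(seed)
  st <- sample(1e6, n)
  GRanges(sample(paste0("chr", 1:3), n, replace = TRUE),
          IRanges(st, width = sample(50:500, n, replace = TRUE)),
          strand = sample(c("+", "-"), n, replace = TRUE))
}
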