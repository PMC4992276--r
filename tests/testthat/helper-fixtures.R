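# Small in-code fixtures shared across test files.

# One cached default-condition simulation + analysis for the recovery tests;
# built lazily so fast test files do not pay for it.
defaultRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simConfig(seed = 101L)
      sim <- buildGenome(cfg)
      reads <- simulateReads(cfg, sim)
      counts <- countBins(tileRegions(sim$regions), reads)
      peaks <- assignGenes(callPeaks(counts), sim$regions)
      cache <<- list(cfg = cfg, sim = sim, reads = reads,
                     counts = counts, peaks = peaks)
    }
    cache
  }
})

# A tiny two-region annotation on a short chromosome, with hand-placed reads
# so expected bin counts are known exactly.
toyRegions <- function() {
  GRanges(c("chrT", "chrT"), IRanges(c(101, 501), c(250, 650)),
          region_id = c("rA", "rB"),
          left_gene = c("gA1", "gB1"), left_strand = c("-", "+"),
          right_gene = c("gA2", "gB2"), right_strand = c("+", "+"))
}

# Build readsets giving each time point an exact list of read spans.
# spans: named list t0..t20 of data.frames (start, end) on chrT.
toyReadsets <- function(spans) {
  lapply(spans, function(d) {
    if (is.null(d) || nrow(d) == 0) return(GRanges())
    GRanges("chrT", IRanges(d$start, d$end), strand = "+")
  })
}

# n distinct width-1 filler reads far outside any bin grid, to pin totals.
fillerReads <- function(n, at = 1000000, chrom = "chrT") {
  GRanges(chrom, IRanges(at + seq_len(n), width = 1), strand = "+")
}

# Construct a minimal assigned peak GRanges row for profile tests.
manualPeak <- function(chrom, region_id, summitStart, gene1 = NA_character_,
                       strength = "strong", timeOfMax = 2,
                       gene2 = NA_character_) {
  pk <- GRanges(chrom, IRanges(summitStart, summitStart + 49L))
  pk$region_id <- region_id
  pk$summit_start <- summitStart
  pk$summit_end <- summitStart + 49L
  pk$time_of_max <- timeOfMax
  pk$strength <- strength
  pk$assignment <- if (is.na(gene2)) "single" else "divergent"
  pk$gene1 <- gene1
  pk$gene2 <- gene2
  pk
}
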