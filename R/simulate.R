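#' @importFrom stats rpois rnorm runif pnorm setNames
NULL

KINETIC_CLASSES <- c("1", "2", "5", "20")

siteScore <- function(lodds, site) {
  codes <- match(strsplit(site, "")[[1]], DNA_BASES)
  sum(lodds[cbind(seq_len(nrow(lodds)), codes)])
}

# Expected-count geometry of the read model, used to calibrate enriched
# fragment numbers against *deduplicated* counts. Reads live on a discrete
# combo space (start, width, strand); duplicate removal keeps one read per
# occupied combo, so the expected distinct count is a Poisson-thinning sum
# 1 - exp(-lambda) over combos. bgDistinct = expected deduplicated
# background reads overlapping one 50-nt bin; binsPerRead = expected bins a
# read overlaps; summitDistinct(n) = expected deduplicated enriched reads
# overlapping the summit bin when n fragments are emitted (enriched read
# starts are a normal/fragment-length mixture, so stacking saturates);
# cap = the saturation limit of summitDistinct.
readGeometry <- function(config) {
  fl <- seq(config@fragmentLenRange[1], config@fragmentLenRange[2])
  rl <- config@readLen
  sd <- config@enrichmentSd
  pfl <- 1 / length(fl)
  b <- config@backgroundRate / 2          # intensity per (position, strand)
  eb <- exp(-b)
  xrel <- seq(-(rl - 1L) - 25L, 24L)      # starts overlapping the summit bin

  # full-length reads (fragment >= read length) share one width class -- and
  # the background's combos; each shorter fragment length is its own class
  long <- fl[fl >= rl]
  short <- fl[fl < rl]
  dens <- function(set, shift) {
    if (!length(set)) return(matrix(0, length(xrel), 0))
    vapply(set, function(l) pfl * dnorm(xrel + shift(l), 0, sd),
           numeric(length(xrel)))
  }
  lamLong <- cbind(rowSums(dens(long, function(l) l / 2)),
                   rowSums(dens(long, function(l) rl - l / 2)))
  # a short fragment's two reads span the whole fragment: same start, the
  # two strands are distinct combos with identical intensity
  lamShort <- cbind(dens(short, function(l) l / 2),
                    dens(short, function(l) l / 2))
  # a width-l read only overlaps the bin from start offset -(l-1)-25 on
  if (length(short)) {
    maskS <- outer(xrel, rep(short, 2), function(x, l) x >= -(l - 1) - 25)
    lamShort <- lamShort * maskS
  }
  capShort <- if (length(short)) 2 * sum(short + 49) else 0

  list(
    bgDistinct = 2 * length(xrel) * (1 - eb),
    binsPerRead = mean((pmin(rl, fl) + 49) / 50),
    summitDistinct = function(n)
      eb * sum(1 - exp(-n * lamLong)) + sum(1 - exp(-n * lamShort)),
    cap = 2 * length(xrel) * eb + capShort
  )
}

# Number of enriched fragments whose expected deduplicated summit-bin count
# equals `target`, by bisection on the saturating yield curve.
solveFragments <- function(geom, target) {
  if (target <= 0) return(0)
  stopIfNot(target < 0.9 * geom$cap,
            "target fold unattainable after deduplication at this depth")
  hi <- 10
  while (geom$summitDistinct(hi) < target) hi <- hi * 2
  stats::uniroot(function(n) geom$summitDistinct(n) - target,
                 c(0, hi), tol = 1e-3)$root
}

#' Build a synthetic genome, annotation and ground truth
#'
#' Lays out gene/intergenic blocks over the configured chromosomes, assigns
#' promoter orientations (divergent / single-gene / convergent), selects the
#' planted peaks with their strength class, target fold and kinetic class,
#' plants a CDRE sampled from the reference PWM within 25 bp of each summit,
#' and constructs NFR and histone-mark tracks with the configured
#' early/late association probabilities. Deterministic given
#' \code{config@seed}.
#'
#' @param config a [SimConfig-class].
#' @return a list with elements \code{genome} (\code{DNAStringSet}),
#'   \code{regions} (intergenic \code{GRanges} with flanking-gene columns),
#'   \code{genes}, \code{tss}, \code{nfr}, \code{h3k4me3}, \code{h3k4ac}
#'   (\code{GRanges}) and \code{truth} (data.frame manifest of planted
#'   peaks: summit, strength, target fold, kinetic class, CDRE sequence /
#'   position / strand, NFR and mark flags, anchor gene).
#' @seealso [simulateReads()], [writeSimulation()]
#' @export
buildGenome <- function(config) {
  withSeed(config@seed, buildGenomeImpl(config))
}

buildGenomeImpl <- function(config) {
  n <- config@nIntergenic
  sp <- config@spacerLen

  regionLens <- sample(seq(config@regionLenRange[1], config@regionLenRange[2],
                           by = 50), n, replace = TRUE)
  geneLens <- matrix(round(runif(2 * n, config@geneLenRange[1],
                                 config@geneLenRange[2])), ncol = 2)

  nDiv <- round(config@divergentFraction * n)
  nConv <- round(config@convergentFraction * n)
  nSingle <- n - nDiv - nConv
  type <- sample(c(rep("divergent", nDiv), rep("convergent", nConv),
                   rep("single_right", ceiling(nSingle / 2)),
                   rep("single_left", floor(nSingle / 2))))

  leftStrand <- c(divergent = "-", convergent = "+",
                  single_right = "+", single_left = "-")[type]
  rightStrand <- c(divergent = "+", convergent = "-",
                   single_right = "+", single_left = "-")[type]

  # contiguous blocks: spacer | left gene | region | right gene | spacer
  chromOf <- sort(rep_len(seq_len(config@nChrom), n))
  regionId <- sprintf("ig%04d", seq_len(n))
  geneL <- sprintf("gene%04dL", seq_len(n))
  geneR <- sprintf("gene%04dR", seq_len(n))

  rStart <- integer(n); glStart <- integer(n); grStart <- integer(n)
  chromLen <- setNames(integer(config@nChrom),
                       paste0("chr", seq_len(config@nChrom)))
  for (ch in seq_len(config@nChrom)) {
    pos <- 1L
    for (i in which(chromOf == ch)) {
      glStart[i] <- pos + sp
      rStart[i] <- glStart[i] + geneLens[i, 1]
      grStart[i] <- rStart[i] + regionLens[i]
      pos <- grStart[i] + geneLens[i, 2] + sp
    }
    chromLen[ch] <- pos - 1L + sp
  }
  chrom <- paste0("chr", chromOf)

  regions <- GRanges(chrom, IRanges(rStart, width = regionLens),
                     region_id = regionId,
                     left_gene = geneL, left_strand = unname(leftStrand),
                     right_gene = geneR, right_strand = unname(rightStrand))
  genes <- GRanges(rep(chrom, 2),
                   IRanges(c(glStart, grStart),
                           width = c(geneLens[, 1], geneLens[, 2])),
                   strand = c(unname(leftStrand), unname(rightStrand)),
                   gene_id = c(geneL, geneR))
  tssPos <- ifelse(as.character(strand(genes)) == "+",
                   start(genes), end(genes))
  tss <- GRanges(seqnames(genes), IRanges(tssPos, width = 1),
                 strand = strand(genes), gene_id = genes$gene_id)

  truth <- planPeaks(config, regions, type)

  # plant CDRE sequences into the random genome
  genome <- DNAStringSet(vapply(seq_len(config@nChrom), function(ch)
    paste(sample(DNA_BASES, chromLen[ch], replace = TRUE), collapse = ""),
    character(1)))
  names(genome) <- names(chromLen)
  if (nrow(truth)) {
    for (ch in names(genome)) {
      sel <- truth$chrom == ch
      if (!any(sel)) next
      site <- truth$cdre_seq[sel]
      neg <- truth$cdre_strand[sel] == "-"
      site[neg] <- vapply(site[neg], function(s)
        as.character(reverseComplement(DNAString(s))), character(1))
      genome[[ch]] <- replaceAt(genome[[ch]],
                                IRanges(truth$cdre_start[sel], width = 9L),
                                site)
    }
  }

  chromatin <- planChromatin(config, regions, truth)

  list(genome = genome, regions = regions, genes = genes, tss = tss,
       nfr = chromatin$nfr, h3k4me3 = chromatin$h3k4me3,
       h3k4ac = chromatin$h3k4ac, truth = truth, config = config)
}

planPeaks <- function(config, regions, type) {
  nPl <- config@nPlanted
  nTotal <- sum(nPl)
  eligible <- which(type != "convergent")
  stopIfNot(length(eligible) >= nTotal,
            "not enough non-convergent regions for the planted peaks")
  idx <- sort(sample(eligible, nTotal))

  strength <- sample(rep(names(nPl), nPl))
  kin <- sample(rep(KINETIC_CLASSES, apportion(nTotal, config@kineticMix)))
  fold <- vapply(strength, function(s)
    runif(1, config@foldRanges[[s]][1], config@foldRanges[[s]][2]), numeric(1))

  rStart <- start(regions)[idx]
  rEnd <- end(regions)[idx]
  nbins <- width(regions)[idx] / 50L

  anchorRight <- regions$right_strand[idx] == "+"
  anchorGene <- ifelse(anchorRight, regions$right_gene[idx],
                       regions$left_gene[idx])
  if (!is.na(config@summitTssOffset)) {
    off <- config@summitTssOffset
    # TSS of the anchor gene sits just beyond the region edge; the summit
    # lands in the bin whose start is `off` bp upstream of it
    p <- ifelse(anchorRight, (rEnd + 1) - off, (rStart - 1) + off)
    binIdx <- pmax(0L, pmin(nbins - 1L, floor((p - rStart) / 50)))
  } else {
    binIdx <- vapply(nbins, function(nb) sample(4:(nb - 5L), 1L), numeric(1))
  }
  summit <- rStart + binIdx * 50L + 25L

  lodds <- logOdds(config@pwm)
  thr <- thresholdFromPvalue(config@pwm, config@cdrePvalue)
  cdreSeq <- vapply(seq_len(nTotal), function(i) {
    best <- ""; bestScore <- -Inf
    for (try in seq_len(200L)) {
      s <- samplePwmSites(config@pwm, 1L)
      sc <- siteScore(lodds, s)
      if (sc >= thr) return(s)
      if (sc > bestScore) { best <- s; bestScore <- sc }
    }
    best
  }, character(1))
  cdreStart <- summit - 4L + sample(-20:20, nTotal, replace = TRUE)
  cdreStrand <- sample(c("+", "-"), nTotal, replace = TRUE)

  early <- kin %in% c("1", "2")
  inNfr <- runif(nTotal) < ifelse(early, config@nfrEarlyProb,
                                  config@nfrLateProb)
  me3 <- runif(nTotal) < ifelse(early, config@markProbs["h3k4me3_early"],
                                config@markProbs["h3k4me3_late"])
  ac <- runif(nTotal) < ifelse(early, config@markProbs["h3k4ac_early"],
                               config@markProbs["h3k4ac_late"])

  data.frame(region_id = regions$region_id[idx],
             chrom = as.character(seqnames(regions))[idx],
             summit = summit,
             summit_bin_start = rStart + binIdx * 50L,
             strength = strength, target_fold = fold,
             kinetic_class = as.numeric(kin),
             cdre_seq = cdreSeq, cdre_start = cdreStart,
             cdre_strand = cdreStrand,
             in_nfr = inNfr, h3k4me3 = me3, h3k4ac = ac,
             anchor_gene = anchorGene,
             row.names = NULL, stringsAsFactors = FALSE)
}

planChromatin <- function(config, regions, truth) {
  planted <- match(truth$region_id, regions$region_id)
  cdreCenter <- truth$cdre_start + 4L

  # planted regions: NFR covering the CDRE center when flagged, otherwise a
  # decoy NFR near the region start (summits sit > 200 bp into the region)
  nfrCenter <- ifelse(truth$in_nfr, cdreCenter,
                      start(regions)[planted] + 100L)
  nfrHalf <- ifelse(truth$in_nfr, 80L, 80L)
  nfrCh <- truth$chrom
  me3Ch <- truth$chrom[truth$h3k4me3]
  me3Center <- truth$summit[truth$h3k4me3]
  acCh <- truth$chrom[truth$h3k4ac]
  acCenter <- truth$summit[truth$h3k4ac]

  unplanted <- setdiff(seq_along(regions), planted)
  if (length(unplanted)) {
    ch <- as.character(seqnames(regions))[unplanted]
    mid <- start(regions)[unplanted] +
      round(runif(length(unplanted), 0.2, 0.8) * width(regions)[unplanted])
    hasNfr <- runif(length(unplanted)) < config@backgroundNfrProb
    hasMe3 <- runif(length(unplanted)) < config@backgroundMarkProbs["h3k4me3"]
    hasAc <- runif(length(unplanted)) < config@backgroundMarkProbs["h3k4ac"]
    nfrCh <- c(nfrCh, ch[hasNfr]); nfrCenter <- c(nfrCenter, mid[hasNfr])
    nfrHalf <- c(nfrHalf, rep(80L, sum(hasNfr)))
    me3Ch <- c(me3Ch, ch[hasMe3]); me3Center <- c(me3Center, mid[hasMe3])
    acCh <- c(acCh, ch[hasAc]); acCenter <- c(acCenter, mid[hasAc])
  }

  track <- function(ch, center, half) {
    if (!length(ch)) return(GRanges())
    sort(GRanges(ch, IRanges(center - half, center + half)))
  }
  list(nfr = track(nfrCh, nfrCenter, nfrHalf),
       h3k4me3 = track(me3Ch, me3Center, 150L),
       h3k4ac = track(acCh, acCenter, 150L))
}

#' Simulate the five time-point read sets
#'
#' Background reads are independent: a Poisson number (rate x genome length)
#' of read-length spans placed uniformly on every chromosome with random
#' strand. Each planted peak adds enriched fragments whose centers are
#' normal around the summit and whose number is calibrated so that the
#' expected summit-bin enrichment over the (planting-inflated) intergenic
#' genome average equals \code{1 + mult * (fold - 1)}, where \code{mult} is
#' the kinetic-class multiplier at that time point -- i.e. exactly the target
#' fold at the class's peak time. Each fragment is emitted as its two
#' read-length ends (+ and - strand), mirroring paired-end sequencing of the
#' immunoprecipitated fragments. The 0-min read set contains no enrichment
#' component.
#'
#' @param config the [SimConfig-class] used for [buildGenome()].
#' @param sim the list returned by [buildGenome()].
#' @param seed RNG seed for the read stage (defaults to
#'   \code{config@seed + 1000} so genome and reads are independently
#'   reproducible).
#' @return named list \code{t0, t1, t2, t5, t20} of read \code{GRanges}.
#' @export
simulateReads <- function(config, sim, seed = config@seed + 1000L) {
  withSeed(seed, simulateReadsImpl(config, sim))
}

simulateReadsImpl <- function(config, sim) {
  geom <- readGeometry(config)
  chromLen <- setNames(width(sim$genome), names(sim$genome))
  genomeLen <- sum(chromLen)
  truth <- sim$truth
  nbins <- sum(width(sim$regions) %/% 50L)
  mRaw <- geom$summitDistinct(1e-6) / 1e-6  # small-n summit yield/fragment
  cconst <- 2 * geom$binsPerRead / (mRaw * nbins)
  nP <- nrow(truth)

  fragRange <- config@fragmentLenRange
  rl <- config@readLen

  fragReads <- function(chrom, fs, flen) {
    rlp <- pmin(rl, flen)
    fe <- fs + flen - 1L
    GRanges(rep(chrom, 2L),
            IRanges(c(fs, fe - rlp + 1L), width = rep(rlp, 2L)),
            strand = rep(c("+", "-"), each = length(fs)))
  }

  readsets <- list()
  for (t in TIMEPOINTS) {
    # background: independent reads, Poisson count, uniform positions
    nBg <- rpois(1, config@backgroundRate * genomeLen)
    ch <- sample(names(chromLen), nBg, replace = TRUE,
                 prob = chromLen / genomeLen)
    bs <- floor(runif(nBg) * (chromLen[ch] - rl)) + 1L
    parts <- list(GRanges(ch, IRanges(bs, width = rl),
                          strand = sample(c("+", "-"), nBg, replace = TRUE)))

    if (t > 0 && nP > 0) {
      mult <- config@kineticProfiles[, as.character(t)][
        as.character(truth$kinetic_class)]
      St <- sum(mult * (truth$target_fold - 1))
      denom <- 1 - cconst * (St + nP)
      stopIfNot(denom > 0.1,
                "planted enrichment mass too high for this genome size")
      # the planted mass inflates the intergenic genome average; solve the
      # fixed point so the summit enrichment over the *final* average is
      # 1 + mult * (fold - 1): exactly the target fold at the class time
      avg <- geom$bgDistinct * (1 - cconst * nP) / denom
      nExp <- numeric(nP)
      for (iter in 1:3) {
        ept <- mult * (truth$target_fold - 1) * avg + (avg - geom$bgDistinct)
        nExp <- vapply(ept, function(e) solveFragments(geom, e), numeric(1))
        rho <- ifelse(nExp > 0, pmax(ept, 0) / pmax(nExp * mRaw, 1e-9), 1)
        avg <- geom$bgDistinct +
          sum(2 * nExp * pmin(rho, 1)) * geom$binsPerRead / nbins
      }
      nFrag <- rpois(nP, nExp)
      centers <- round(rnorm(sum(nFrag), rep(truth$summit, nFrag),
                             config@enrichmentSd))
      echrom <- rep(truth$chrom, nFrag)
      eflen <- sample(seq(fragRange[1], fragRange[2]), sum(nFrag),
                      replace = TRUE)
      efs <- pmax(1L, pmin(centers - eflen %/% 2L,
                           chromLen[echrom] - eflen + 1L))
      parts[[2]] <- fragReads(echrom, efs, eflen)
    }
    rs <- unname(unlist(GRangesList(parts)))
    readsets[[tpName(t)]] <- sort(rs, ignore.strand = TRUE)
  }
  readsets
}

#' Write a simulated experiment to disk
#'
#' Writes the genome FASTA, intergenic-region and TSS tables, chromatin BED
#' tracks, one BED of reads per time point, and the ground-truth manifest
#' TSV, each with a provenance header where the format allows comments.
#'
#' @param sim list from [buildGenome()].
#' @param reads list from [simulateReads()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, reads, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("crzKinetics simulation, seed %d", sim$config@seed)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             regions = file.path(outdir, "intergenic.tsv"),
             tss = file.path(outdir, "tss.tsv"),
             nfr = file.path(outdir, "nfr.bed"),
             h3k4me3 = file.path(outdir, "h3k4me3.bed"),
             h3k4ac = file.path(outdir, "h3k4ac.bed"),
             truth = file.path(outdir, "truth.tsv"))
  writeXStringSet(sim$genome, paths["genome"])
  writeIntergenicRegions(sim$regions, paths["regions"], header = prov)
  writeTssTable(sim$tss, paths["tss"], header = prov)
  writeBed(sim$nfr, paths["nfr"])
  writeBed(sim$h3k4me3, paths["h3k4me3"])
  writeBed(sim$h3k4ac, paths["h3k4ac"])
  writeTsv(sim$truth, paths["truth"], header = prov)
  for (nm in names(reads)) {
    p <- file.path(outdir, paste0("reads_", nm, ".bed"))
    writeBed(reads[[nm]], p)
    paths[paste0("reads_", nm)] <- p
  }
  invisible(paths)
}
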