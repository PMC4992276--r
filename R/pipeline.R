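#' Run the full synthetic time-course analysis end to end
#'
#' Chains the pipeline stages -- simulate, quantify, call peaks, assign
#' genes, scan for CDREs, refine per-strength PWMs, derive consensus
#' strings, build TSS profiles, and test chromatin associations -- on data
#' generated from \code{config}, writing every artifact with a provenance
#' header and returning a summary report. The run is deterministic given
#' \code{config@seed}: the genome stage uses the seed itself and the read
#' stage \code{seed + 1000}.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory, or NULL to skip writing artifacts.
#' @param sim optionally, an already-built simulation (from [buildGenome()])
#'   to analyse instead of regenerating one; its TSS table may be absent, in
#'   which case the profile stage is skipped with a notice.
#' @param threshold,kineticTimes,pseudocount peak-calling parameters (see
#'   [callPeaks()]).
#' @param pvalue CDRE scan p-value cutoff (default 1e-3).
#' @param cdreWindow central-CDRE window around the summit (bp, default 100).
#' @param verbose emit per-stage progress messages.
#' @return (invisibly when writing) a list with elements \code{sim},
#'   \code{reads}, \code{counts}, \code{peaks}, \code{hits}, \code{cdre},
#'   \code{pwms} (refined per group + overall), \code{consensus},
#'   \code{profiles}, \code{groupProfiles}, \code{chromatin}, and
#'   \code{summary} (peak counts by strength and time of maximum, CDRE
#'   central-recovery rate, consensus strings, profile argmax per group,
#'   association table).
#' @export
runPipeline <- function(config, outdir = NULL, sim = NULL, threshold = 2,
                        kineticTimes = c(2, 5), pseudocount = 1,
                        pvalue = 1e-3, cdreWindow = 100, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("simulate: genome + reads (seed ", config@seed, ")")
  if (is.null(sim)) sim <- stage("simulate", buildGenome(config))
  reads <- stage("simulate", simulateReads(config, sim))

  say("quantify: 50-nt bins, dedup + depth normalization")
  grid <- stage("quantify", tileRegions(sim$regions))
  counts <- stage("quantify", countBins(grid, reads))

  say("callpeaks: ", threshold, "-fold over genome average, kinetic filter")
  peaks <- stage("callpeaks",
                 callPeaks(counts, threshold = threshold,
                           kineticTimes = kineticTimes,
                           pseudocount = pseudocount))
  peaks <- stage("callpeaks", assignGenes(peaks, sim$regions))

  say("scan: PWM p<", pvalue, " + central CDRE selection")
  hits <- stage("scan", scanRegions(sim$genome, sim$regions, config@pwm,
                                    pvalue = pvalue))
  cdreList <- lapply(seq_along(peaks), function(k)
    centralCdre(peaks[k], hits, window = cdreWindow))
  hasCdre <- !vapply(cdreList, is.null, logical(1))
  cdre <- if (any(hasCdre)) unname(unlist(GRangesList(cdreList[hasCdre])))
          else GRanges()

  say("refine-pwm: per strength group")
  siteSeq <- function(h) {
    s <- regionSequences(sim$genome, h)[[1]]
    if (as.character(strand(h)) == "-") s <- reverseComplement(s)
    as.character(s)
  }
  cdreSites <- if (length(cdre))
    vapply(seq_along(cdre), function(i) siteSeq(cdre[i]), character(1))
  else character(0)
  cdreGroup <- peaks$strength[hasCdre]
  pwms <- list()
  for (g in c("strong", "moderate", "weak")) {
    sites <- cdreSites[cdreGroup == g]
    if (length(sites)) pwms[[g]] <- buildPwm(sites)
  }
  if (length(cdreSites)) pwms$overall <- buildPwm(cdreSites)
  consensus <- vapply(pwms, pwmConsensus, character(1))

  profiles <- NULL; groupProfiles <- NULL
  if (is.null(sim$tss) || length(sim$tss) == 0L) {
    say("profiles: skipped (no TSS table)")
  } else {
    say("profiles: 1 kb upstream, 50-bp bins, percent of fold-change")
    profiles <- stage("profiles",
                      geneProfiles(peaks, reads, counts, sim$tss,
                                   sim$regions))
    if (nrow(profiles$profile))
      groupProfiles <- groupAverageProfile(profiles)
  }

  say("chromatin: NFR / H3K4me3 / H3K4ac association")
  chromatin <- stage("chromatin",
                     chromatinAssociation(peaks, cdre, sim$nfr,
                                          sim$h3k4me3, sim$h3k4ac))

  summary <- list(
    n_peaks = length(peaks),
    by_strength = table(factor(peaks$strength,
                               levels = c("weak", "moderate", "strong"))),
    by_time_of_max = table(factor(peaks$time_of_max,
                                  levels = POST_TIMES)),
    cdre_central_rate = if (length(peaks)) mean(hasCdre) else NA_real_,
    consensus = consensus,
    profile_argmax_bp = if (!is.null(groupProfiles))
      vapply(rownames(groupProfiles), function(g) {
        j <- which.max(groupProfiles[g, ])
        -ncol(groupProfiles) * 50 + (j - 1) * 50
      }, numeric(1)) else NULL,
    chromatin = chromatin)

  result <- list(sim = sim, reads = reads, counts = counts, peaks = peaks,
                 hits = hits, cdre = cdre, pwms = pwms,
                 consensus = consensus, profiles = profiles,
                 groupProfiles = groupProfiles, chromatin = chromatin,
                 summary = summary)

  if (!is.null(outdir)) {
    writePipeline(result, config, outdir)
    return(invisible(result))
  }
  result
}

writePipeline <- function(result, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("crzKinetics run, seed %d", config@seed)
  writeSimulation(result$sim, result$reads, outdir)
  writeBinCounts(result$counts, file.path(outdir, "bincounts.tsv"),
                 header = prov)
  writePeakTable(result$peaks, file.path(outdir, "peaks.tsv"), header = prov)
  if (length(result$cdre))
    writeBed(result$cdre, file.path(outdir, "central_cdre.bed"))
  for (nm in names(result$pwms))
    writePwmFile(result$pwms[[nm]],
                 file.path(outdir, paste0("pwm_", nm, ".txt")))
  if (!is.null(result$groupProfiles))
    writeTsv(cbind(group = rownames(result$groupProfiles),
                   as.data.frame(result$groupProfiles)),
             file.path(outdir, "group_profiles.tsv"), header = prov)
  if (!is.null(result$profiles) && nrow(result$profiles$profile))
    writeTsv(cbind(gene = result$profiles$gene,
                   region_id = result$profiles$region_id,
                   group = result$profiles$group,
                   as.data.frame(result$profiles$profile)),
             file.path(outdir, "gene_profiles.tsv"), header = prov)
  writeTsv(result$chromatin, file.path(outdir, "chromatin.tsv"),
           header = prov)

  s <- result$summary
  lines <- c(paste0("# ", prov),
             sprintf("peaks\t%d", s$n_peaks),
             sprintf("strength\t%s",
                     paste(names(s$by_strength), s$by_strength,
                           sep = "=", collapse = " ")),
             sprintf("time_of_max\t%s",
                     paste(names(s$by_time_of_max), s$by_time_of_max,
                           sep = "=", collapse = " ")),
             sprintf("cdre_central_rate\t%.4f", s$cdre_central_rate),
             sprintf("consensus_%s\t%s", names(s$consensus), s$consensus))
  if (!is.null(s$profile_argmax_bp))
    lines <- c(lines, sprintf("profile_argmax_%s\t%d",
                              names(s$profile_argmax_bp),
                              as.integer(s$profile_argmax_bp)))
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(outdir)
}
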