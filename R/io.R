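#' @importFrom rtracklayer import export
#' @importFrom utils read.table write.table
NULL

#' Read a BED file of intervals or mapped reads
#'
#' Thin wrapper around \code{rtracklayer::import} that converts the BED
#' 0-based half-open convention to 1-based closed \code{GRanges}. Strand is
#' taken from column 6 when present, otherwise left as \code{*}.
#'
#' @param path BED file path.
#' @return \code{GRanges} (with \code{name}/\code{score} columns when the BED
#'   carries them).
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  gr <- tryCatch(import(path, format = "BED"),
                 error = function(e) stop("malformed BED '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (any(width(gr) < 1L))
    stop("empty interval (start >= end) in ", path, call. = FALSE)
  gr
}

#' Write intervals to BED
#'
#' @param gr \code{GRanges} to write (converted to 0-based half-open on disk).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBed <- function(gr, path) {
  export(gr, path, format = "BED")
  invisible(path)
}

#' Read mapped reads from a text SAM file
#'
#' Minimal single-end SAM text reader for workflows whose mapper emitted SAM:
#' extracts reference name, 1-based position, aligned span (from the CIGAR
#' reference-consuming operations) and strand (FLAG bit 0x10). Unmapped
#' records are dropped. BAM/CRAM are out of scope.
#'
#' @param path SAM text file.
#' @return \code{GRanges} of aligned read spans with strand.
#' @export
readSamReads <- function(path) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(GRanges())
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) < 11L)
  if (length(bad))
    stop("malformed SAM record at line ", bad[1], call. = FALSE)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  refw <- vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  GRanges(rname[keep],
          IRanges(pos[keep], width = pmax(refw[keep], 1L)),
          strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"))
}

#' Read a plain-text PWM file
#'
#' Whitespace-separated numbers, one row per motif position, four columns in
#' A, C, G, T order; \code{#} comment lines allowed. Rows of probabilities
#' (summing to 1) are taken as-is; rows of counts are converted to
#' probabilities with the given pseudocount.
#'
#' @param path file path.
#' @param pseudocount pseudocount per base applied when converting counts.
#' @param background background probabilities to attach.
#' @param width if non-NULL, the matrix must have exactly this many rows.
#' @return a [MotifPWM-class].
#' @seealso [writePwmFile()]
#' @export
readPwmFile <- function(path, pseudocount = 1, background = rep(0.25, 4),
                        width = NULL) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  m <- as.matrix(read.table(path, comment.char = "#"))
  if (ncol(m) != 4L)
    stop("PWM file must have 4 columns (A,C,G,T)", call. = FALSE)
  if (any(m < 0))
    stop("negative PWM entry in ", path, call. = FALSE)
  if (!is.null(width) && nrow(m) != width)
    stop(sprintf("PWM width %d differs from the expected %d", nrow(m), width),
         call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6)) {
    # treat as counts
    m <- sweep(m + pseudocount, 1, rs + 4 * pseudocount, "/")
    if (any(abs(rowSums(m) - 1) > 1e-6))
      stop("PWM rows do not normalize to 1", call. = FALSE)
  } else {
    pseudocount <- 0
  }
  motifPWM(m, background = background, pseudocount = pseudocount)
}

#' Write a PWM as plain text
#'
#' @param pwm a [MotifPWM-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePwmFile <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# PWM probabilities; columns A C G T", con)
  write.table(format(pwmProbs(pwm), digits = 10), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the intergenic-region annotation table
#'
#' Tab-separated with a header: \code{region_id, chrom, start, end,
#' left_gene, left_strand, right_gene, right_strand}; coordinates 1-based
#' closed. \code{#} comment lines are skipped.
#'
#' @param path TSV path.
#' @return \code{GRanges} with the flanking-gene metadata columns.
#' @seealso [writeIntergenicRegions()]
#' @export
readIntergenicRegions <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("region_id", "chrom", "start", "end",
            "left_gene", "left_strand", "right_gene", "right_strand")
  stopIfNot(all(need %in% names(d)),
            "intergenic table lacks required columns")
  stopIfNot(!anyDuplicated(d$region_id), "region_id values must be unique")
  GRanges(d$chrom, IRanges(d$start, d$end),
          region_id = d$region_id,
          left_gene = d$left_gene, left_strand = d$left_strand,
          right_gene = d$right_gene, right_strand = d$right_strand)
}

#' @rdname readIntergenicRegions
#' @param regions \code{GRanges} as returned by [readIntergenicRegions()].
#' @param path output path.
#' @param header optional character vector of \code{#}-prefixed provenance
#'   lines written before the table.
#' @export
writeIntergenicRegions <- function(regions, path, header = NULL) {
  d <- data.frame(region_id = regions$region_id,
                  chrom = as.character(seqnames(regions)),
                  start = start(regions), end = end(regions),
                  left_gene = regions$left_gene,
                  left_strand = regions$left_strand,
                  right_gene = regions$right_gene,
                  right_strand = regions$right_strand)
  writeTsv(d, path, header)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated with header \code{gene_id, chrom, position, strand};
#' position is the 1-based transcription start site. One record per gene.
#'
#' @param path TSV path.
#' @return \code{GRanges} of width-1 TSS positions with \code{gene_id}.
#' @export
readTssTable <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "position", "strand")
  stopIfNot(all(need %in% names(d)), "TSS table lacks required columns")
  stopIfNot(!anyDuplicated(d$gene_id), "one TSS record per gene_id")
  GRanges(d$chrom, IRanges(d$position, width = 1), strand = d$strand,
          gene_id = d$gene_id)
}

#' @rdname readTssTable
#' @param tss \code{GRanges} of TSS positions with \code{gene_id}.
#' @param path output path.
#' @param header optional \code{#} provenance lines.
#' @export
writeTssTable <- function(tss, path, header = NULL) {
  d <- data.frame(gene_id = tss$gene_id,
                  chrom = as.character(seqnames(tss)),
                  position = start(tss),
                  strand = as.character(strand(tss)))
  writeTsv(d, path, header)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return \code{DNAStringSet} named by chromosome.
#' @export
readGenomeFasta <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

peakTableColumns <- function() {
  c("region_id", "chrom", "start", "end", "summit_start", "summit_end",
    paste0("enrich_", TIMEPOINTS[-1]),
    paste0("log2fc_", TIMEPOINTS),
    "time_of_max", "strength", "assignment", "gene1", "gene2")
}

#' Write called peaks as a TSV
#'
#' One row per peak, ordered by (chrom, start); fixed columns: region and
#' summit coordinates (1-based closed), per-time enrichment over the genome
#' average, per-time log2 fold-change versus time 0, time of maximum,
#' strength class and gene assignment. A header-only file is written for an
#' empty peak set.
#'
#' @param peaks peak \code{GRanges} from [callPeaks()] (optionally after
#'   [assignGenes()]).
#' @param path output path.
#' @param header optional \code{#} provenance lines.
#' @return the path, invisibly.
#' @seealso [readPeakTable()]
#' @export
writePeakTable <- function(peaks, path, header = NULL) {
  cols <- peakTableColumns()
  if (length(peaks) == 0L) {
    d <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                              dimnames = list(NULL, cols)))
  } else {
    o <- order(as.character(seqnames(peaks)), start(peaks))
    p <- peaks[o]
    d <- data.frame(region_id = p$region_id,
                    chrom = as.character(seqnames(p)),
                    start = start(p), end = end(p),
                    summit_start = p$summit_start, summit_end = p$summit_end)
    for (t in TIMEPOINTS[-1]) d[[paste0("enrich_", t)]] <-
      mcols(p)[[paste0("enrich_", t)]]
    for (t in TIMEPOINTS) d[[paste0("log2fc_", t)]] <-
      mcols(p)[[paste0("log2fc_", t)]]
    d$time_of_max <- p$time_of_max
    d$strength <- p$strength
    d$assignment <- if (!is.null(p$assignment)) p$assignment else NA
    d$gene1 <- if (!is.null(p$gene1)) p$gene1 else NA
    d$gene2 <- if (!is.null(p$gene2)) p$gene2 else NA
  }
  writeTsv(d, path, header)
  invisible(path)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(GRanges())
  gr <- GRanges(d$chrom, IRanges(d$start, d$end))
  for (nm in setdiff(names(d), c("chrom", "start", "end")))
    mcols(gr)[[nm]] <- d[[nm]]
  gr
}

writeTsv <- function(d, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
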