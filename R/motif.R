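#' @importFrom Biostrings DNAString DNAStringSet reverseComplement vmatchPattern
#'   subseq readDNAStringSet writeXStringSet replaceAt mergeIUPACLetters
NULL

# Floor applied to zero/near-zero probabilities before taking log-odds, so a
# disallowed base scores harshly negative instead of -Inf.
PWM_PROB_FLOOR <- 1e-4

#' Default reference PWM for the Crz1 CDRE
#'
#' A synthetic, consensus-derived 9-position matrix for the calcineurin
#' dependent response element: three quasi-uniform flanking positions (with a
#' slight prevalence of C at the first), an A/C position, the invariant GCC
#' core, a quasi-uniform position, and a strongly preferred terminal C with
#' very little tolerance for G. Its consensus under [pwmConsensus()] is
#' \code{NNN(A/C)GCCNC}. It stands in for an experimentally derived Crz1
#' matrix wherever the user does not supply one via [readPwmFile()].
#'
#' The same matrix ships as a plain-text file at
#' \code{system.file("extdata", "cdre_reference_pwm_synthetic.txt",
#' package = "crzKinetics")} as a template for the PWM file dialect.
#'
#' @return a [MotifPWM-class] of width 9 with uniform background.
#' @examples
#' pwmConsensus(defaultCrz1PWM())
#' @export
defaultCrz1PWM <- function() {
  p <- rbind(
    c(0.20, 0.40, 0.17, 0.23),  # slight C prevalence
    c(0.27, 0.26, 0.22, 0.25),
    c(0.24, 0.28, 0.21, 0.27),
    c(0.46, 0.44, 0.04, 0.06),  # (A/C)
    c(0.02, 0.02, 0.94, 0.02),  # G
    c(0.02, 0.94, 0.02, 0.02),  # C
    c(0.03, 0.92, 0.02, 0.03),  # C
    c(0.28, 0.30, 0.20, 0.22),
    c(0.04, 0.90, 0.02, 0.04)   # C, G disfavoured
  )
  motifPWM(p)
}

logOdds <- function(pwm) {
  p <- pmax(pwmProbs(pwm), PWM_PROB_FLOOR)
  b <- pmax(pwmBackground(pwm), PWM_PROB_FLOOR)
  sweep(log2(p), 2, log2(b), "-")
}

revcompMatrix <- function(m) {
  # scoring the minus strand of a window equals scoring the plus strand with
  # the position-reversed, base-complemented matrix
  m[rev(seq_len(nrow(m))), c("T", "G", "C", "A"), drop = FALSE]
}

baseCodes <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]], DNA_BASES)
}

#' Score one window against a PWM
#'
#' Log2-odds score of a single sequence window of the motif's width:
#' \code{sum_i log2(probs[i, base_i] / background[base_i])}, with
#' zero-probability entries floored at 1e-4. On the minus strand the reverse
#' complement of the window is scored.
#'
#' @param pwm a [MotifPWM-class].
#' @param seq character or \code{DNAString} of length \code{pwmWidth(pwm)}.
#' @param strand "+" (default) or "-".
#' @return numeric score in bits; \code{NA} (with a message) if the window
#'   contains an ambiguous base.
#' @examples
#' scoreWindow(defaultCrz1PWM(), "CACAGCCTC")
#' @export
scoreWindow <- function(pwm, seq, strand = "+") {
  codes <- baseCodes(seq)
  stopIfNot(length(codes) == pwmWidth(pwm),
            "window length must equal the PWM width")
  if (anyNA(codes)) {
    message("window contains an ambiguous base; skipped")
    return(NA_real_)
  }
  m <- logOdds(pwm)
  if (strand == "-") m <- revcompMatrix(m)
  sum(m[cbind(seq_len(nrow(m)), codes)])
}

#' Exact background score distribution of a PWM
#'
#' Enumerates the log2-odds scores of all \code{4^width} sequences, weighted
#' by the background base composition, by accumulating per-position score
#' vectors with an outer sum. Scores are grouped after rounding to 9 decimals
#' so that floating-point ulp differences do not split identical score levels.
#'
#' @param pwm a [MotifPWM-class] (width <= 10; larger widths would need a
#'   dynamic-programming approximation, which this package does not provide).
#' @param background optional override of the PWM's background.
#' @return data.frame with columns \code{score} (descending), \code{prob}
#'   (background probability of exactly that score) and \code{tail}
#'   (probability of scoring >= that score).
#' @export
scoreDistribution <- function(pwm, background = NULL) {
  stopIfNot(pwmWidth(pwm) <= 10,
            "exact enumeration supports widths up to 10 only")
  if (!is.null(background)) pwm@background <- as.numeric(background)
  m <- logOdds(pwm)
  bg <- pwmBackground(pwm)
  sc <- 0
  pr <- 1
  for (i in seq_len(nrow(m))) {
    sc <- as.vector(outer(sc, m[i, ], "+"))
    pr <- as.vector(outer(pr, bg, "*"))
  }
  sc <- round(sc, 9)
  agg <- rowsum(pr, sc)
  score <- as.numeric(rownames(agg))
  o <- order(score, decreasing = TRUE)
  score <- score[o]
  prob <- agg[o, 1]
  data.frame(score = score, prob = prob, tail = cumsum(prob),
             row.names = NULL)
}

#' Score threshold achieving a background p-value
#'
#' The smallest attainable score s such that the exact background probability
#' of scoring >= s is at most \code{p}, computed from the full enumeration in
#' [scoreDistribution()].
#'
#' @param pwm a [MotifPWM-class].
#' @param p tail probability cutoff in (0, 1); default 1e-3 as used for the
#'   CDRE scan.
#' @param background optional background override.
#' @return the threshold score (bits); \code{Inf} with a warning when even the
#'   maximal score is attained with probability above \code{p} (no window can
#'   pass, as for a degenerate uniform matrix).
#' @examples
#' thresholdFromPvalue(defaultCrz1PWM(), 1e-3)
#' @export
thresholdFromPvalue <- function(pwm, p = 1e-3, background = NULL) {
  stopIfNot(is.numeric(p) && p > 0 && p < 1, "p must be in (0, 1)")
  d <- scoreDistribution(pwm, background)
  ok <- d$tail <= p
  if (!any(ok)) {
    warning("no attainable score has background tail <= p; threshold is Inf")
    return(Inf)
  }
  min(d$score[ok])
}

# P(background score >= s) from a scoreDistribution() table.
tailPvalue <- function(dist, s) {
  asc <- rev(dist$score)
  tailAsc <- rev(dist$tail)
  idx <- findInterval(s - 1e-9, asc) + 1L
  ifelse(idx > length(asc), 0, tailAsc[pmin(idx, length(asc))])
}

regionSequences <- function(genome, regions) {
  chr <- as.character(seqnames(regions))
  stopIfNot(all(chr %in% names(genome)), "region chromosome missing from genome")
  glen <- setNames(width(genome), names(genome))
  stopIfNot(all(end(regions) <= glen[chr] & start(regions) >= 1),
            "region outside genome bounds")
  DNAStringSet(lapply(seq_along(regions), function(i)
    subseq(genome[[chr[i]]], start(regions)[i], end(regions)[i])))
}

scanOneStrand <- function(codes, m) {
  w <- nrow(m)
  L <- length(codes) - w + 1L
  if (L < 1L) return(numeric(0))
  s <- numeric(L)
  for (j in seq_len(w)) s <- s + unname(m[j, ])[codes[j:(j + L - 1L)]]
  s
}

#' Scan intergenic regions with a PWM
#'
#' Scores every window of both strands of each region and reports hits whose
#' log2-odds score meets the exact-p-value threshold.
#'
#' @param genome \code{DNAStringSet} of chromosome sequences.
#' @param regions \code{GRanges} of intergenic regions with a
#'   \code{region_id} metadata column.
#' @param pwm a [MotifPWM-class].
#' @param pvalue background tail cutoff (default 1e-3).
#' @param background optional background override for threshold and p-values.
#' @return \code{GRanges} of hits (genome coordinates, strand), with metadata
#'   columns \code{region_id}, \code{score} (bits) and \code{pvalue}
#'   (exact background tail of the score), ordered by position then strand.
#' @seealso [patternSearch()] for score-free degenerate-core matching.
#' @export
scanRegions <- function(genome, regions, pwm, pvalue = 1e-3, background = NULL) {
  dist <- scoreDistribution(pwm, background)
  ok <- dist$tail <= pvalue
  if (!any(ok)) {
    warning("no score passes the p-value cutoff; returning no hits")
    return(GRanges(score = numeric(0)))
  }
  thr <- min(dist$score[ok])
  m <- logOdds(pwm)
  mrc <- revcompMatrix(m)
  w <- pwmWidth(pwm)
  seqs <- regionSequences(genome, regions)
  out <- list()
  for (i in seq_along(regions)) {
    codes <- match(strsplit(as.character(seqs[[i]]), "")[[1]], DNA_BASES)
    plus <- scanOneStrand(codes, m)
    minus <- scanOneStrand(codes, mrc)
    for (str in c("+", "-")) {
      s <- if (str == "+") plus else minus
      hit <- which(!is.na(s) & round(s, 9) >= thr)
      if (length(hit)) {
        out[[length(out) + 1L]] <- GRanges(
          seqnames(regions)[i],
          IRanges(start(regions)[i] + hit - 1L, width = w),
          strand = str,
          region_id = regions$region_id[i],
          score = s[hit],
          pvalue = tailPvalue(dist, s[hit]))
      }
    }
  }
  if (!length(out)) return(GRanges(score = numeric(0)))
  res <- unlist(GRangesList(out))
  sort(res, ignore.strand = TRUE)
}

# "(C/A)GCC" -> "MGCC": degenerate alternations become IUPAC letters
parseDegeneratePattern <- function(pattern) {
  toks <- regmatches(pattern,
                     gregexpr("\\([ACGT]/[ACGT]\\)|[ACGTN]", pattern))[[1]]
  if (length(toks) == 0L ||
      nchar(paste(toks, collapse = "")) != nchar(pattern))
    stop("malformed pattern: ", pattern, call. = FALSE)
  paste(vapply(toks, function(tk) {
    if (nchar(tk) == 1L) tk
    else as.character(mergeIUPACLetters(paste0(substr(tk, 2, 2),
                                               substr(tk, 4, 4))))
  }, character(1)), collapse = "")
}

#' Degenerate core-pattern search over intergenic regions
#'
#' Exact matching of degenerate patterns such as \code{"GCC"} or
#' \code{"(C/A)GCC"} (alternations in \code{(X/Y)} form) on both strands,
#' used for regions where the matrix scan finds no site.
#'
#' @param genome \code{DNAStringSet} of chromosomes.
#' @param regions \code{GRanges} with \code{region_id}.
#' @param patterns character vector of degenerate patterns.
#' @return \code{GRanges} of score-free hits with \code{region_id} and
#'   \code{pattern} metadata columns.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAAGCCAAAA"))
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), region_id = "ig1")
#' patternSearch(g, r, "GCC")
#' @export
patternSearch <- function(genome, regions, patterns = c("GCC", "(C/A)GCC")) {
  seqs <- regionSequences(genome, regions)
  names(seqs) <- regions$region_id
  out <- list()
  for (pat in patterns) {
    iupac <- parseDegeneratePattern(pat)
    for (str in c("+", "-")) {
      query <- if (str == "+") DNAString(iupac)
               else reverseComplement(DNAString(iupac))
      mt <- vmatchPattern(query, seqs, fixed = FALSE)
      for (i in seq_along(mt)) {
        ir <- mt[[i]]
        if (length(ir)) {
          out[[length(out) + 1L]] <- GRanges(
            seqnames(regions)[i],
            IRanges(start(regions)[i] + start(ir) - 1L, width = width(ir)),
            strand = str,
            region_id = regions$region_id[i],
            pattern = pat)
        }
      }
    }
  }
  if (!length(out)) return(GRanges(pattern = character(0)))
  sort(unlist(GRangesList(out)), ignore.strand = TRUE)
}

#' Select the central CDRE of a peak
#'
#' Among motif hits of the peak's region lying within a window of the summit
#' midpoint, returns the best-scoring hit; ties go to the smallest absolute
#' distance, then to the + strand. Mirrors the selection of CDREs mapping at
#' the center of each recruitment peak before per-group PWM refinement.
#'
#' @param peak a single-row peak \code{GRanges} (from [callPeaks()]) carrying
#'   \code{summit_start}/\code{summit_end}.
#' @param hits motif-hit \code{GRanges} (from [scanRegions()]); score-free
#'   hits from [patternSearch()] are accepted and treated as score 0.
#' @param window maximum distance (bp) from the summit midpoint; default 100.
#' @return the selected hit with an added \code{distance_to_summit} column, or
#'   \code{NULL} when no hit lies within the window.
#' @export
centralCdre <- function(peak, hits, window = 100) {
  stopIfNot(length(peak) == 1L, "centralCdre expects a single peak")
  h <- hits[hits$region_id == peak$region_id]
  if (!length(h)) return(NULL)
  mid <- (peak$summit_start + peak$summit_end) / 2
  d <- (start(h) + end(h)) / 2 - mid
  keep <- abs(d) <= window
  if (!any(keep)) return(NULL)
  h <- h[keep]
  d <- d[keep]
  sc <- if (!is.null(h$score)) h$score else rep(0, length(h))
  o <- order(-sc, abs(d), as.character(strand(h)) != "+")
  best <- h[o[1]]
  best$distance_to_summit <- d[o[1]]
  best
}

#' Build a PWM from aligned binding sites
#'
#' Per-position base probabilities with a pseudocount:
#' \code{(count + pseudocount) / (n + 4 * pseudocount)}.
#'
#' @param sites character vector (or \code{DNAStringSet}) of equal-width
#'   site sequences.
#' @param pseudocount count added per base (default 1).
#' @param background background probabilities for the resulting matrix.
#' @return a [MotifPWM-class].
#' @examples
#' buildPwm(c("CAGCCTCAC", "CAGCCTCAC", "AAGCCTCCC"))
#' @export
buildPwm <- function(sites, pseudocount = 1, background = rep(0.25, 4)) {
  sites <- toupper(as.character(sites))
  stopIfNot(length(sites) >= 1L, "at least one site is required")
  w <- unique(nchar(sites))
  stopIfNot(length(w) == 1L, "sites must all have the same width")
  mat <- do.call(rbind, strsplit(sites, ""))
  n <- length(sites)
  probs <- t(vapply(seq_len(w), function(i) {
    cnt <- table(factor(mat[, i], levels = DNA_BASES))
    (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4)))
  colnames(probs) <- DNA_BASES
  motifPWM(probs, background = background, pseudocount = pseudocount)
}

#' Sample site sequences from a PWM
#'
#' Draws each position independently from the matrix probabilities. Used both
#' by the synthetic generator (where planted sites are additionally required
#' to beat the scan threshold) and by the refinement-recovery checks.
#'
#' @param pwm a [MotifPWM-class].
#' @param n number of sites.
#' @return character vector of \code{n} sequences of width
#'   \code{pwmWidth(pwm)}.
#' @export
samplePwmSites <- function(pwm, n) {
  p <- pwmProbs(pwm)
  cols <- vapply(seq_len(nrow(p)), function(i)
    sample(DNA_BASES, n, replace = TRUE, prob = p[i, ]), character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1, paste, collapse = "")
}

#' Information content per PWM position
#'
#' \code{2 - entropy} bits per position (uniform background), the quantity a
#' sequence-logo plot displays.
#'
#' @param pwm a [MotifPWM-class].
#' @return numeric vector, one value in \[0, 2\] per position.
#' @export
informationContent <- function(pwm) {
  p <- pwmProbs(pwm)
  ent <- apply(p, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log2(r))
  })
  2 - ent
}

#' Degenerate consensus string of a PWM
#'
#' Per position: the single base when its probability is at least 0.80; a
#' two-base alternation \code{(X/Y)} when the top two bases each reach 0.25
#' and jointly 0.80; otherwise \code{N}. On the default reference matrix this
#' yields the refined CDRE consensus \code{NNN(A/C)GCCNC}.
#'
#' @param pwm a [MotifPWM-class].
#' @param single probability needed for a single-base call (default 0.80).
#' @param pair per-base (default 0.25) threshold for an alternation call;
#'   the pair must jointly reach \code{single}.
#' @return a character consensus string.
#' @export
pwmConsensus <- function(pwm, single = 0.80, pair = 0.25) {
  p <- pwmProbs(pwm)
  paste(apply(p, 1, function(r) {
    o <- order(r, decreasing = TRUE)
    if (r[o[1]] >= single) return(DNA_BASES[o[1]])
    if (r[o[1]] >= pair && r[o[2]] >= pair && r[o[1]] + r[o[2]] >= single)
      return(sprintf("(%s/%s)", DNA_BASES[o[1]], DNA_BASES[o[2]]))
    "N"
  }), collapse = "")
}
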