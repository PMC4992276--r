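# crzKinetics

Time-resolved ChIP-Seq analysis of transcription-factor recruitment to
yeast intergenic regions, built around the alkaline-pH–stress response of
the calcineurin/Crz1 pathway.

## The problem

When *Saccharomyces cerevisiae* meets an alkaline environment, a burst of
cytosolic calcium activates calcineurin, which dephosphorylates the
transcription factor Crz1. Crz1 then enters the nucleus within 1–2 minutes
and binds calcineurin dependent response elements (CDREs, core
`(A/C)GCCNC`) in its target promoters. A five–time-point ChIP-Seq series
(0, 1, 2, 5, 20 min after the pH shift) captures this recruitment wave.
`crzKinetics` is for analysts of such time courses: it turns mapped reads
plus an intergenic annotation into called recruitment peaks with kinetic
and strength classes, refined binding-site models, TSS-aligned binding
profiles, and chromatin-accessibility association statistics — and ships a
synthetic-data generator with planted ground truth so the whole pipeline is
testable end to end.

## The method

* **Quantitation** — intergenic regions are tiled into 50-nt bins; reads are
  deduplicated and counted per bin (a read increments every bin it
  overlaps); counts are depth-corrected to the largest dataset
  (`scale_factor_t = max(totals)/totals_t`). The *genome average* `Ā_t`
  (mean normalized count per intergenic bin at time *t*) is the enrichment
  denominator.
* **Peak calling** — a region yields a peak when some bin has
  `count / Ā_t ≥ 2` at a post-stress time point *and* at 2 and/or 5 min
  (the kinetic filter matching Crz1's rapid nuclear entry). The summit is
  the maximal bin; `time_of_max` is the argmax over {1, 2, 5, 20} min
  (ties → earliest); strength is weak `[2,5)`, moderate `[5,10]`, strong
  `(10,∞)` in maximum fold enrichment; fold-changes vs time 0 use a
  pseudocount, `FC_t = (max_t + 1)/(max_0 + 1)`.
* **Motifs** — PWM scanning with log2-odds scores and an *exact* score
  threshold: all `4^9` window scores are enumerated and the smallest score
  with background tail ≤ 10⁻³ is used. Central CDREs (±100 bp of the
  summit) feed per-strength-group PWM refinement
  (`(count + ψ)/(n + 4ψ)`) and consensus derivation, which yields
  `NNN(A/C)GCCNC` on the shipped (synthetic, consensus-derived) reference
  matrix. A degenerate-core pattern search (`GCC`, `(C/A)GCC`) covers
  scan-negative regions.
* **Profiles** — per assigned gene with a known TSS, the fold-change of each
  50-bp bin in the 1 kb upstream of the TSS, expressed as a percentage of
  the row total (rows sum to 100), averaged per strength group.
* **Chromatin** — early (1–2 min) vs late (5–20 min) peaks are tested for
  CDRE-in-NFR containment and H3K4me3/H3K4ac overlap with a two-sided
  Fisher's exact test (hypergeometric enumeration).

## Worked example

```r
library(crzKinetics)

cfg <- simConfig(seed = 1, nIntergenic = 80L,
                 nPlanted = c(strong = 4L, moderate = 5L, weak = 6L))
res <- runPipeline(cfg, verbose = FALSE)

res$counts
#> BinCounts: 2073 bins x 5 time points (0, 1, 2, 5, 20 min)
#>   regions: 80, totals: 12162, 12681, 13208, 12907, 12392
#>   genome average per bin: 11.08, 11.84, 12.20, 11.96, 11.32

res$summary$by_strength
#>     weak moderate   strong
#>        5        5        4

res$summary$by_time_of_max
#>  1  2  5 20
#>  3  6  4  1

unname(res$consensus["overall"])
#> [1] "NNN(A/C)GCCNC"

res$chromatin[res$chromatin$feature == "nfr", ]
#>   feature group hits total fraction pvalue
#> 1     nfr early    4     9    0.444 0.3007
#> 2     nfr  late    4     5    0.800 0.3007
```

Reading the output: of the 15 planted peaks, 14 pass the 2-fold + kinetic
filter (one weak peak stays under threshold at this depth); the five
normalized totals differ by < 10 %, so scale factors are mild; most peaks
max out at 1–5 min, as the planted kinetic mix dictates; and the refined
motif consensus round-trips the generator's CDRE model. With only 14 peaks
the NFR association is far from significant (p ≈ 0.30) — the power analysis
in `scripts/acceptance.R` uses 150 peaks per run, where the planted
0.70 vs 0.40 early/late NFR rates are detected in ~98 % of replicates.

Individual stages are exported too: `buildGenome()` / `simulateReads()`,
`tileRegions()` / `countBins()`, `callPeaks()` / `assignGenes()`,
`scanRegions()` / `buildPwm()` / `pwmConsensus()`, `geneProfiles()`,
`chromatinAssociation()`, plus readers/writers for BED, FASTA, plain-text
PWMs and the package's TSV tables (`readBed()`, `readPwmFile()`,
`writePeakTable()`, …).

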