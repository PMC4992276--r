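---
title: "Methods: time-resolved analysis of Crz1 promoter recruitment"
author: "crzKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved analysis of Crz1 promoter recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crzKinetics)
```

# The biological problem

When budding yeast is shifted to an alkaline medium, a near-instantaneous
burst of cytosolic calcium activates the phosphatase calcineurin, which
dephosphorylates the zinc-finger transcription factor Crz1. Dephosphorylated
Crz1 enters the nucleus within a minute or two and binds calcineurin
dependent response elements (CDREs, core `(A/C)GCCNC`) in the promoters of
its target genes. A ChIP-Seq time course sampled at 0, 1, 2, 5 and 20 min
after the pH shift captures this recruitment wave: most bound promoters peak
at 1--2 min and decay by 20 min.

`crzKinetics` implements the full downstream analysis of such a time course
-- bin-level quantitation over intergenic regions, kinetically filtered
fold-enrichment peak calling, strength classification, CDRE discovery and
PWM refinement, TSS-aligned binding profiles, and chromatin-accessibility
association tests -- together with a synthetic-data generator that plants
ground-truth peaks so every stage can be validated end to end.

# Quantitation model

Intergenic regions (the probe universe; genic DNA is ignored) are tiled into
contiguous 50-nt bins, the last bin of a region possibly shorter
(`tileRegions()`). Reads identical in chromosome, start, end and strand are
collapsed to one before counting (`dedupReads()`). A bin's raw count is the
number of deduplicated reads overlapping it by at least one base, so a
~150-nt read typically increments four consecutive bins; a midpoint
assignment mode is available as a flag. Depth normalization is multiplicative
to the largest dataset: time point *t* is scaled by
`max(totals) / totals[t]`, so the deepest library keeps factor 1 and every
factor is at least 1. The **genome average** of a time point -- the
denominator of all enrichment values -- is the mean normalized count over
all intergenic bins at that time point. Two consequences worth noting:

* enrichment ratios are invariant to the scale factors (numerator and
  denominator scale together), and
* because the average is taken over the probe universe only, planted (or
  real) binding mass inflates it; the synthetic generator accounts for this
  (below).

A time point with zero reads is an error (its scale factor is undefined)
rather than being silently dropped.

# Peak calling

A region yields at most one peak. It qualifies when some bin reaches
`threshold`-fold (default 2) the genome average at one or more post-stress
time points **and** the threshold is met at 2 and/or 5 min. The second
condition is the kinetic filter: recruitment that appears only at 20 min is
not compatible with the fast nuclear entry of Crz1 and is discarded. The
summit is the bin with the maximum normalized count over the post-stress
time points; the reported span is the widest contiguous run of
super-threshold bins containing the summit; the time of maximum is the
post-stress time point with the highest per-time maximum count, ties
breaking toward the earliest time (consistent with the emphasis on fast
recruitment). Fold-changes versus time 0 add a pseudocount (default 1
normalized count) to numerator and denominator so that unbound baselines do
not divide by zero; `log2fc_0` is identically 0.

Strength classes partition maximum enrichment *e* with no gaps: weak for
2 &le; *e* &lt; 5, moderate for 5 &le; *e* &le; 10 (both boundary folds count as
moderate -- the verbal definitions "5 to 10-fold" and "more than 10-fold"
leave 5 and 10 ambiguous, and a closed moderate interval is the documented
choice), strong for *e* &gt; 10.

Gene assignment is purely orientational: a region whose two flanking genes
both transcribe away from it is a divergent promoter serving both genes;
exactly one promoter-facing flank gives a single-gene assignment; convergent
flanks leave the peak unassigned. Kinetic clustering
(`clusterFoldChanges()`) is agglomerative with Euclidean distance and
complete linkage on the five log2 fold-change values per peak, delegated to
`stats::hclust` and cross-checked in the test suite against a brute-force
O(n^3) reference.

# Motif analysis

Windows are scored as log2-odds sums against a background base composition
(uniform by default; a genome-composition background can be supplied).
Zero-probability matrix entries are floored at 1e-4 before the logarithm, so
a disallowed base scores about -11 bits rather than -Inf; this floor also
determines the score levels attainable by near-degenerate matrices. The
score threshold for a p-value cutoff (default 1e-3) is computed **exactly**:
all `4^width` sequences are enumerated (widths up to 10), their background
probabilities accumulated per distinct score, and the smallest score whose
tail probability is at most the cutoff is used. Scores are grouped after
rounding to 9 decimals so floating-point ulp noise cannot split a level.

The reference matrix shipped as `defaultCrz1PWM()` is **synthetic and
consensus-derived**: the experimentally derived Crz1 matrix is not
redistributable here, so the default encodes the refined CDRE consensus --
three quasi-uniform flanks with a slight C prevalence at the first position,
an A/C position, the invariant GCC core, a quasi-uniform position, and a
strongly preferred terminal C with almost no tolerance for G. Its consensus
string is `NNN(A/C)GCCNC` and any user matrix can be substituted via
`readPwmFile()`.

Refinement (`buildPwm()`) uses the closed form
`(count + pseudocount) / (n + 4 pseudocount)` per position, and consensus
derivation calls a single base at probability &ge; 0.80, a two-base
alternation when the top two bases each reach 0.25 and jointly 0.80, and `N`
otherwise; the 0.80/0.25 thresholds are configurable and were chosen once so
that the default matrix's own consensus round-trips. The score-free
degenerate-pattern search (`patternSearch()`, patterns like `GCC` and
`(C/A)GCC`) covers regions where the matrix scan finds nothing, mirroring
the two-pronged site search of the original analysis. For each peak the
central CDRE is the best-scoring hit within ±100 bp of the summit midpoint
("near the center" is not quantified anywhere; ±100 bp is the documented
default), ties resolved by distance and then by the + strand.

# TSS profiles

For every assigned gene with a reported TSS, the fold-change versus time 0
of each 50-bp bin in the 1 kb upstream of the TSS is evaluated at the
peak's own time of maximum (a `time` argument overrides this; the exact
time point feeding the published profile figure is not stated, so the
region's time of maximum is the package's default) and converted to
percentages of the row total, which removes the magnitude differences
between strong and weak recruiters. Minus-strand genes are flipped so bins
always run 5'&rarr;TSS. Windows that extend beyond the peak's intergenic
region contribute zero for the out-of-region bins and the remainder is
normalized to 100, so every row -- and hence every group average -- sums to
exactly 100.

# Chromatin association

Peaks are stratified into early (time of maximum 1 or 2 min) and late (5 or
20 min) responders. NFR membership is **point** containment of the central
CDRE's midpoint in a nucleosome-free-region interval; histone-mark
enrichment is &ge; 1 bp **interval** overlap between the peak span and the
mark track -- matching the "located in" versus "enriched in" distinction.
Each feature's 2×2 early/late table is tested with a two-sided Fisher's
exact test implemented by hypergeometric enumeration (probabilities no more
probable than the observed table, with a 1e-7 relative tolerance on the
comparison); a zero margin returns p = 1 with a warning. The published
p-values for the real data are treated as descriptive context, not
reproduction targets, because the underlying counts are unpublished.

# The synthetic-data generator

`simConfig()` bundles the study conditions. The defaults are fixed once and
are what the acceptance checks run under:

* **Genome layout** -- 300 intergenic regions of 1000--1600 bp (multiples of
  50 so bin grids partition regions exactly) on 2 chromosomes, each flanked
  by its own pair of genes (400--900 bp) and 200-bp spacers; 30% divergent
  promoters, 5% convergent (never planted), the rest single-gene with the
  promoter-facing flank split evenly between sides. TSSs sit at the
  gene edge abutting the region.
* **Planted peaks** -- 12 strong (target fold 12--20), 18 moderate (6--9),
  30 weak (3--4.5); kinetic mix 30/30/25/15% peaking at 1/2/5/20 min,
  apportioned by largest remainder so realized counts are exact. Kinetic
  shape is a piecewise multiplier profile per class (e.g. class "2 min" is
  0.6/1.0/0.7/0.3 across 1/2/5/20 min); only the location of the maximum is
  constrained by the biology, and every class keeps a &ge; 0.6 multiplier at
  2 or 5 min so planted profiles are compatible with the kinetic filter.
* **Reads** -- background reads are independent: a Poisson number (rate x
  genome length; default rate 0.05/bp/time point, giving a mean bin count
  near 10) of 150-nt spans placed uniformly with random strand. Enriched
  fragments (100--300 bp, the sonication range capped at 500) have normal
  centers around the summit (sd 60 bp) and are emitted as their two 150-nt
  ends on opposite strands, mirroring paired-end sequencing. Time 0 has no
  enrichment component.
* **Fold calibration** -- the number of enriched fragments is chosen so that
  the **expected deduplicated** summit-bin count, over the
  **planting-inflated** genome average, equals `1 + mult (fold - 1)` --
  exactly the target fold at the class's peak time. Two effects make this
  non-trivial: (i) with 60 planted peaks over ~7800 bins the planted mass
  itself raises the genome average by 10--20% (the real data were ~40x
  sparser), so a per-time fixed point is solved; (ii) duplicate removal
  clips densely stacked enriched reads (~20% at the summit at default
  depth), so fragments are solved from a Poisson-thinning yield curve over
  the discrete (start, width, strand) read space rather than a linear
  yield. The residual calibration error is ~3%.
* **CDREs** -- each planted peak carries one site sampled from the reference
  PWM, written into the genome within 25 bp of the summit on a random
  strand. Sites are rejection-sampled to score above the scan threshold at
  the configured cutoff: a bound site is by definition one the factor
  recognizes, and an unconditional draw from this moderately informative
  matrix would fall below the 1e-3 threshold almost half the time. The
  unconditional sampler (`samplePwmSites()`) remains the path used for
  refinement-recovery checks.
* **Chromatin** -- planted CDREs fall inside an NFR with probability 0.70
  (early classes) or 0.40 (late), the published association the generator
  emulates; mark probabilities by class (H3K4me3 0.84/0.78, H3K4ac
  0.82/0.64) and background rates for unplanted regions (NFR 0.5, H3K4me3
  0.87, H3K4ac 0.72) follow the corresponding published percentages.

Everything is deterministic given the seed; the read stage derives its
stream as `seed + 1000` so genome and reads are independently reproducible,
and `runPipeline()` writes every artifact with a provenance header.

## What the generator does and does not emulate

It reproduces the *quantitative contract* of the analysis: planted folds,
kinetic classes, motif positions and chromatin flags are recovered by the
pipeline within sampling error. It does **not** model mappability or GC
bias, PCR duplication beyond chance collisions, base-call qualities, or
non-uniform fragmentation; background is homogeneous. Passing tests
therefore demonstrate the correctness of the algorithms under the stated
model, not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* Probability floor 1e-4 in log-odds scoring (documented constant).
* Score levels grouped at 9 decimals in the exact enumeration.
* Fold-change pseudocount 1.0 normalized count.
* Zero-read time points, empty bin grids, empty peak sets for overlap
  percentages, and sub-2-fold strength queries raise errors; degenerate
  Fisher margins return p = 1 with a warning; uniform PWMs yield an
  infinite scan threshold with a warning (no window can pass).
* Tie-breaks: earliest time for the time of maximum; score, then distance,
  then + strand for the central CDRE; `stats::hclust` ordering for
  clustering (continuous inputs make ties measure-zero).

# Problem sizes

The shipped checks run the default 300-region genome (~840 kb, ~250k reads
per run) once, a 60-region profile run, 50 replicates of a 170-region
genome build for the association-power check, full enumeration of all
262,144 9-mers for the threshold oracle, and all ~136k 2×2 tables with
N &le; 40 for the Fisher oracle. These sizes were chosen so the entire
validation completes in a few minutes on one CPU while every statistical
bound retains a comfortable margin.

# Known limitations

* One peak per intergenic region; sub-peaks within a region are merged.
* The kinetic filter is the simplest reading of the published "functional
  filter" (a threshold at 2 and/or 5 min); shape constraints beyond that
  are not modelled.
* The genome average is computed over intergenic bins only; whether the
  original quantitation included genic bins is unknowable from the text.
* Exact p-value thresholds are limited to motif widths &le; 10 (full
  enumeration); longer motifs would need a dynamic-programming
  approximation that is out of scope.
* The default reference PWM is synthetic; analyses of real data should
  supply the experimentally derived matrix.
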