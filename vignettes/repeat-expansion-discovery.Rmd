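---
title: "Somatic repeat expansion discovery: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic repeat expansion discovery: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropicr)
```

## 1. Signal model

A tandem repeat tract longer than the read length produces read pairs in
which one mate maps confidently to unique flanking sequence while the other
lies entirely within the repeat and cannot be placed. We call the pair an
*anchored in-repeat read* (anchored IRR). The expected number of anchored
pairs at a locus grows roughly linearly with tract length beyond the read
length, because every fragment whose unique-side mate falls within one
fragment length of the tract boundary contributes, and the boundary "catch
zone" widens as the tract grows. Anchored IRR counts are therefore a
monotone proxy for repeat length that requires no assembly and no
realignment.

### Read classification

`repeat_purity(read, motif)` is the fraction of read bases matched by the
best tiling of the motif, maximized over both strands and all phases of the
unit; `N` bases count as mismatches. A read is an in-repeat read when some
motif achieves purity ≥ 0.9 *and* the read's mapping quality is ≤ 40 — a
pure repeat read that nevertheless maps uniquely (high MAPQ) is part of a
reference-length tract and carries no expansion evidence. The anchor mate
must have MAPQ ≥ 50. Both thresholds are inclusive at their boundary and
configurable in `tropic_config()`. Pairs whose two mates are both in-repeat
reads are discarded: with neither mate anchored there is no reliable
position, and keeping them would double-count long tracts.

### Motif canonicalization

Counting must not fragment one tract across the 6 rotations × 2 strands of
its unit. `canonical_motif()` first reduces the unit to its primitive
period (so `CAGCAG` → `CAG`), then takes the lexicographic minimum over all
rotations of the unit and of its reverse complement (`CAG`, `AGC`, `GCA`,
`CTG`, `TGC`, `GCT` → `AGC`). Homopolymers and primitive units outside 2–20
bases are rejected as invalid motifs. The C++ implementation
(`src/repeats.cpp`) does classification with an exact self-correlation
screen so that scanning is linear in read length times the number of
candidate periods.

## 2. Normalization

**Global.** Raw per-locus counts scale with sequencing depth. Each sample's
counts are rescaled by `40 / global_depth`, where global depth is total
aligned autosomal bases divided by total autosomal reference length (sex
chromosomes excluded so ploidy differences between donors do not bias the
scale). 40× is the conventional cancer-WGS depth and is only a choice of
units.

**Local.** Chromosomal amplification inflates anchored IRR counts at any
locus inside the amplified segment. Local depth — mean per-base coverage in
the locus ± 250 bp window, counting *all* primary non-duplicate reads
regardless of MAPQ so in-repeat reads are included — scales with the same
copy number. The ratio `raw / local_depth` is therefore invariant under
amplification but still grows with true expansion (events rise, local
coverage stays put). A window with zero coverage yields `NA` and the locus
is flagged rather than silently kept or dropped.

## 3. The prioritization cascade

Given the loci × samples matrix of globally normalized values:

1. **Chromosome filter** — only 1–22, X, Y (with or without a `chr`
   prefix); unplaced contigs are too unstable to test.
2. **Cap filter** — a locus is removed when strictly more than 10 % of
   samples exceed a normalized value of 40. Such saturated loci are
   dominated by reference polymorphism or mapping pathology; the strict
   inequality means exactly 10 % is kept.
3. **Rank-sum test** — one-sided (tumour > normal). With many tied zeros,
   the usual normal approximation is poor for small cohorts, so when both
   groups have ≤ 12 samples the p-value is computed exactly over the tied
   permutation distribution by dynamic programming on doubled midranks
   (doubling makes midranks integral). Larger groups use the tie-corrected
   variance with a 0.5 continuity correction; a degenerate all-tied locus
   gets p = 1.
4. **FDR** — Benjamini–Hochberg across loci surviving steps 1–2.
5. **AIQ calling** — per pair, AIQ = (tumour − normal) / (normal + 1); a
   pair is called expanded when AIQ > 2.5 (strict). The +1 regularizes
   zero-count normals; 2.5 demands roughly a 3.5-fold excess at typical
   backgrounds. A locus is `somatic_rre` when q < 0.05 and the called
   fraction exceeds 0.05, `candidate` at q < 0.10, `not_significant`
   otherwise. All inequalities are strict, which has a practical corollary:
   the exact rank-sum floor for *n* pairs versus *n* all-zero normals is
   1/choose(2n, n), so a cohort needs at least 4 complete pairs before any
   locus can clear q < 0.05.
6. **Local-depth refilter** — candidates are re-tested on local-depth
   rescaled values (multiplied by the cohort median positive local depth so
   the two value scales are comparable), with a fresh rank-sum + BH + AIQ
   round. Loci that stay significant are final `rre` calls; loci that
   collapse are `removed_local_depth` (amplification artefacts); loci whose
   window had no coverage are `flagged_local_depth` for manual review.

## 4. Population frequency and catalogue matching

To ask "is this locus commonly expanded in normal genomes?",
`population_frequency()` takes normalized anchored IRR values across a
panel, sets the threshold at the interpolated (type 7) 99th percentile and
reports the fraction *strictly* exceeding it. Panels sequenced at 150 bp
reads sit on a different scale than 100 bp panels — longer reads make
in-repeat classification of boundary reads more demanding — and are mapped
onto the 100 bp scale by the fixed affine conversion `0.5 + 1.5 × value`
before thresholding. `match_loci()` aligns two locus catalogues by overlap
after symmetric 1000 bp padding (clusters of the same tract can shift
between runs by up to a fragment length) *and* identical canonical motif.

## 5. The simulator

`make_repeat_genome()` embeds exact tandem tracts in otherwise random
sequence; `simulate_cohort()` builds, per tumour–normal pair, two diploid
genomes — carrier tumours get the expansion on haplotype 1 only, matching
the typically heterozygous somatic event — and draws read pairs in the
standard shotgun way: `round(coverage × G / (2 × read_length))` pairs per
haplotype, fragment lengths Normal(500, 50) truncated at the read length,
uniform start positions, per-base error 0.02 applied via R's RNG so every
read is reproducible from the seed. Alignment is by construction (an
"oracle aligner"): reads whose best motif purity reaches 0.9 get MAPQ 0,
others MAPQ 60, and positions are lifted from haplotype to reference
coordinates through the known expansion. `simulate_amplification()` adds
self-contained extra read pairs from a ±1000 bp region at a chosen copy
number, reproducing the confound the refilter exists to remove.
`downsample()` thins pairs (keeping mates together) for depth-sensitivity
studies.

**Realism and limits.** The simulator reproduces the *counting* physics —
boundary geometry, depth scaling, heterozygosity, amplification — which is
what the statistics consume. It does not model mappability structure,
indels, GC bias, chimeras, or realistic aligner MAPQ distributions; its
MAPQ is binary by design so that classification thresholds are exercised at
their boundaries by construction rather than by chance. Empirically, a
heterozygous 70-copy CAG expansion (210 bp) at 30× yields on the order of
10–20 anchored events per sample against an essentially zero background
from 20-copy (60 bp) reference tracts, because a 60 bp tract cannot produce
a 100 bp read of ≥ 90 % purity.

All stochastic entry points require an explicit seed;
`child_seed(seed, i)` derives per-stage seeds (always < 2³¹) so a single
seed determines every read, alignment and downstream number, and identical
configurations are byte-reproducible.

## 6. Numerical and design decisions

* **Coordinates** are 0-based half-open everywhere inside the package and
  in TSV output; conversion to 1-based closed happens only at the SAM
  boundary (`read_alignments()` / `write_sam()`).
* **Exact-vs-approximate switch** at group size 12: the DP over doubled
  midranks is O(n₁ · S) per locus, which is milliseconds at n = 12 and
  pointless beyond, where the tie-corrected normal approximation is
  accurate to well under 0.01.
* **BH is delegated** to `stats::p.adjust`; canonicalization, purity
  scanning, simulation and error injection are implemented in C++ because
  they are character-level hot loops (the purity scan is the pipeline's
  dominant cost; the C++ reverse complement is ~50× faster than generic
  S4-dispatched alternatives and is cross-checked against Biostrings in
  the test suite).
* **Strict inequalities** at every threshold (purity, MAPQ, cap, AIQ,
  q-value, population exceedance) are deliberate and tested at their exact
  boundaries.
* **Problem sizes.** The package's own benchmarks run cohorts of 4–20
  pairs on chromosomes of 40 kb–1 Mb at 10–30×, which covers the regime
  where exact small-sample statistics matter; per-sample simulate + scan on
  a 1 Mb chromosome at 30× takes a few seconds. Real-cohort use scales
  linearly in total aligned reads and in loci.
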