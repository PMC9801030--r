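---
title: "Artifact-aware markers for meiotic analyses: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact-aware markers for meiotic analyses: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(meiomapr)
```

## The problem

Short reads from repetitive genomes mis-map. When an element present in one
genome is deleted (or transposed) in another, reads from the non-allelic
copy land inside the deleted reference interval and their few divergent
bases are called as SNPs. When a duplicated element collapses onto a
single-copy reference locus, depth doubles and every divergent site between
the two copies looks like a clean 50/50 heterozygous SNP. When a read
terminates inside a tandem repeat it aligns gaplessly whatever the unit
count, so a true homozygous unit loss acquires fake reference support and is
genotyped heterozygous. None of these artifacts is rescued by base or
mapping quality alone — the mis-mapped reads are high-quality.

Most downstream analyses tolerate a small false-marker rate. Gene-conversion
detection does not: a GC event *is* one or a few markers contradicting
their surrounding genotype block, which is exactly what an artificial
heterozygous marker looks like in a homozygous block. Unfiltered marker sets
inflate GC counts by orders of magnitude. Bulked-segregant mapping is also
degraded, because artificial hets drag window allelic ratios toward 0.5
inside the causal region.

## Models

### Candidate calling

Genotypes are called per pileup column under a diallelic diploid model.
An observation of base $b$ with error probability $e$ (from its quality)
has likelihood $1-e$ under a matching allele and $e/3$ otherwise; the
heterozygous likelihood is the average of the two allele likelihoods.
Priors are $P(\mathrm{het}) = h$, $P(\mathrm{hom\text{-}alt}) = h/2$,
$P(\mathrm{hom\text{-}ref}) = 1 - 1.5h$ with $h = 10^{-3}$ by default.
A call is emitted when the maximal-posterior genotype is non-reference and
its phred quality $-10\log_{10}(1 - P_{best})$ reaches 20 (symmetric with
the mapping-quality threshold). Observations under base quality 13 are
ignored; mapping quality is a hard pre-filter (reads < 20 dropped), not a
likelihood term. Indel (gap) observations are modelled the same way with a
fixed per-observation error of 0.01 — gap placement is noisier than base
calls, and a smaller value makes genuinely homozygous repeat indels
unresolvable against a handful of stray gapless reads (neither genotype
reaches the quality floor and the site is silently lost).

Reads that do not span a tandem repeat are excluded from indel genotype
evidence inside it (`repeat_aware = TRUE`), which is the published read
filter; `repeat_aware = FALSE` emulates a naive caller so that the
refinement route for third-party call sets stays testable end to end.

### Refinement

Filters attach reason codes; codes are unioned and never overwritten, so
the cascade is order-insensitive and idempotent on the annotated set.

* `SV_OVERLAP` / `SV_ADJACENT` — inside an SV interval, or within the
  adjacency margin (default 500 bp ≈ one library insert: mis-mapping
  artifacts extend about a fragment length past a breakpoint).
* `TANDEM_NONSPAN` — heterozygous indel whose second allele is supported
  only by repeat-terminating reads. If the spanning reads are unanimous the
  genotype is instead rewritten homozygous and the non-spanning evidence
  dropped from the supports. Indels whose length is a whole number of
  repeat units are annotated as gain/loss of `units_changed` units.
* `DEPTH_EXTREME` — the depth rule is *conjunctive*: depth at least
  `depth_fold` (4) times the genome mean **and** in a 1% percentile tail of
  the candidate depth distribution (linear-interpolated quantiles). Since
  four-fold excess and bottom-tail membership exclude each other, the rule
  in practice removes collapsed-CNV-like candidates while preserving
  genuine low-coverage markers; an alternative composite reading
  ((fold AND top tail) OR bottom tail) is selectable via
  `depth_rule = "composite"` but unconditionally sacrifices ~1% of true
  markers to the bottom tail, which is measurably incompatible with
  retaining ≥ 99% of true markers away from SVs.
* `ALLELE_RATIO` — the heterozygous allelic ratio, primary over
  primary-plus-alternative support, must lie inside the central 99% of the
  empirical ratio distribution over all heterozygous candidates (0.5%–99.5%
  bounds). The band is two-sided because mis-mapping artifacts produce
  ratios near both 0 and 1. Homozygous candidates are exempt.
* `LOW_SUPPORT` — variant-allele support below 3 reads.

Multi-sample merging takes the union of PASS loci and re-evaluates every
sample's genotype there, re-piling that sample's reads under the same read
filters as calling (this resolves, in one direction, whether re-evaluation
uses raw or filtered reads: filtered, for consistency). Samples without
coverage become missing (`./.`).

### SV detection

Deliberately signature-level — refinement needs reliable intervals, not
breakpoint-precise genotyped calls. Pairs are classified LONG / SHORT /
INVERTED / DISTANT / NORMAL from template length (±3 sd around the insert
mean, k configurable), strand, and mate distance (> 10× mean or another
sequence). Same-signature pairs cluster by overlap of their implied
intervals; the reported interval is the intersection over the *consensus
core* (pairs covering the component's most-covered position) — intersecting
every member naively lets one stray pair empty the intersection. INVERTED
and DISTANT clusters report the union of their inner intervals instead,
since those pairs bracket the event from both sides; DISTANT pairs
contribute only their local read span as evidence, the remote mate anchor
being kept for the transposition rule (a deletion cluster whose interior
reads carry DISTANT mates anchored at one remote locus is a transposed
element). Co-located clusters of different classes merge into `complex`.
Depth CNVs use 500 bp windows against the genome *median* (the mean is
inflated by the very CNVs being detected, which would push a clean 2×
collapse below the threshold): ≥ 2× is a duplication, ≤ 0.25× a
depth-supported deletion. Split reads (≥ 20 clipped bases near a cluster
edge) only corroborate.

### Recombination

Marker observations follow the published ratio conventions exactly:
$\mathrm{Ratio}_s = M/(P+M)$ per marker and
$\mathrm{Ratio}_w = \sum_i P_i / \sum_i (P_i+M_i)$ per window, so a window
is paternal-homozygous at $\mathrm{Ratio}_w \ge 0.8$ and
maternal-homozygous at $\le 0.2$ (both inclusive). Windows are anchored at
position 1 on a fixed grid (default 20 kb size, 10 kb step, trailing
partial window kept; the window size heuristic is
$2\times10^3/\mathrm{depth} \times \mathrm{genome\ size}/\mathrm{SNP\
number}$, rounded to the nearest kb, floored at 1 kb); windows with fewer
than 5 informative markers are uncalled. Runs of equal genotype become
blocks; each junction yields a crossover whose boundary is refined to
(last marker consistent with the left genotype, first marker consistent
with the right genotype), requiring a run of two consistent markers on the
right so a single noisy marker cannot spoof the boundary; junctions without
informative markers within 50 kb fall back to the inter-window gap with a
`low_resolution` flag. Gene conversions are markers (≥ 5 reads)
contradicting a homozygous block — fully converted at ≥ 0.8 toward the
other parent, het-converted in the central band (the same 0.8/0.2
vocabulary as windows, one threshold set across the module) — grouped into
events when < 1 kb apart, with ± one window around block edges excluded.
Scanning heterozygous blocks for homozygous conversions is implemented but
off by default, since a hom-looking marker in a het block is
indistinguishable from allele-specific coverage noise at typical depths.

### Causal mapping

The pooled ratio track re-uses the window machinery (200 kb / 100 kb), and
a longer grid (2 Mb / 500 kb) carries the smoothing plus central-difference
first and second derivatives. Candidate regions are runs of smoothed
windows at ≥ 0.75 toward the mutant parent carrying an extremum's
derivative signature: the first derivative changes sign across the run
(assessed at the run edges — a fully selected locus is a plateau near 1.0
whose interior derivatives vanish, so testing the argmax window alone finds
nothing on long chromosomes) and the curvature reaches $|d_2| \ge 0.02$
somewhere in or adjacent to the run. A 0.5→1.0 rise over 5 Mb, the stated
qualifying shape, flattens to $|d_2| \approx 0.04$ on the smoothed grid
(the 2 Mb window spreads the peak), so 0.02 accepts it with a two-fold
margin while binomial noise on windows holding thousands of reads
(≈ 0.005) stays an order of magnitude below. Regions extend until the smoothed ratio recedes by 0.1
from the extremum — a deterministic stand-in for interactive boundary
refinement — and must reach 0.75 toward the mutant parent (recessive
screen). The peak/valley direction is declared by the caller
(`mutant = "M"` or `"P"`), not inferred from cross design. EMS filtering
applies, in order: allelic ratio ≥ 0.75, absence from both parental sets,
and the G→A / C→T transition constraint, recording the first failed rule
per candidate. T-DNA scanning reruns pair-signature SV detection restricted
to the regions (depth statistics are meaningless on a region-restricted
read subset and are not used) and keeps SVs absent from the parental SV
set. Annotation precedence is splice site (first/last 2 intronic bases) >
CDS > UTR > exon > intron > intergenic; CDS SNPs are translated on the
feature strand, with non-multiple-of-3 CDS degraded to `exon` with a
warning.

## What the simulator emulates — and what it does not

Generators are pure functions of (spec, seed). The reference string is the
paternal parent; the alternate parent diverges by SNPs (default one per
200 bp, the observed inter-ecotype density), 1–3 bp deletions, tandem
repeat unit losses, and large SVs. Alignments are synthesized directly
rather than via an external aligner, so artifact geometry is exact:

* deletions produce LONG pairs at the junction (counts follow the fragment
  density, Poisson over the junction window) and, optionally, mis-mapped
  paralog reads inside the deleted interval at ~0.6× depth with 30–55
  mapping quality — high enough to pass the filter, which is the point —
  a third of them with DISTANT mates at the remote paralog locus;
* collapsed duplications add the diverged copy's reads on top of the
  allelic ones (2× depth, divergent sites ~50/50);
* repeat unit losses give spanning reads a gapped CIGAR and leave
  repeat-terminating reads gapless (they genuinely match the reference
  phase of the repeat);
* insert sizes are Normal(500, 50) truncated at ±3 sd (size selection), so
  a concordant background pair is never discordant by chance; sequencing
  error is 0.1% per base at constant Q30.

Progenies are two chromatid mosaics switching at given crossover positions;
conversion tracts flip one chromatid locally (so a tract in a homozygous
block appears het-converted, the common single-chromatid case). Pools draw
each progeny's gametes with Poisson crossovers and keep only
causal-homozygous progenies (recessive selection), reads sampled uniformly
over the pooled chromatids.

Not emulated: empirical error/quality profiles, GC-content coverage bias,
chimeric fragments, alignment-score-dependent mapq, multi-chromosome
genomes in one call (loop over chromosomes instead), and insertions longer
than the insert size. Progeny and pool generators require SNP-only parents
(indels and SVs are realized at read level in the parental artifact
simulator). A green test therefore establishes correctness of the
*algorithms* on data whose artifact geometry matches the mechanism being
filtered — not robustness to every idiosyncrasy of a real sequencer or
aligner.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based closed throughout (the IRanges
  convention); BED is converted at the boundary. One convention internally
  eliminates off-by-one drift, and in R that convention is 1-based.
* Percentiles are type-7 (linear interpolation) everywhere.
* Genotype posteriors are computed in log space with max-subtraction;
  ties break toward the more conservative genotype (ref-hom first).
* Quality caps at phred 1000 when the posterior saturates.
* Zero-depth columns are no-calls, not errors; empty repeat/SV tables are
  valid inputs; chromosomes shorter than one smoothing window skip
  smoothing with a warning; fewer than 100 candidates disable percentile
  tails with a warning (the fold rule still applies).
* `call_variants` processes the genome in 1 Mb chunks (50 bp overlap,
  candidates assigned to their home chunk) to bound pileup memory.

## Known limitations

* The SV module is signature-level; breakpoints are accurate to roughly an
  insert size and SVs are not genotyped.
* Genotyping of indel markers in progeny reads relies on gapped alignments
  being present in the input; an aligner that soft-clips instead will
  undercount the indel allele.
* The merged VCF re-evaluation uses stored allele depths when alignments
  are not supplied, which cannot distinguish "no coverage" from "not
  called"; supply alignments for faithful `./.` semantics.
* Acceptance scenarios run at desk scale (1–20 Mb, 30–100 progenies);
  real-genome-scale behaviour (hundreds of Mb, ~80× coverage) is
  extrapolated, not tested.
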