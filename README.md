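# meiomapr

Accurate genetic markers from short-read resequencing, and the meiotic
analyses they unlock.

Repetitive genomes break naive variant calling: reads from a transposed or
duplicated element mis-map onto non-allelic positions, and reads that
terminate inside a tandem repeat cannot tell `(AG)10` from `(AG)9`. Both
failure modes produce *artificial* SNPs and indels that look like perfectly
good heterozygous calls. For most genotyping work a percent of false markers
is noise; for detecting meiotic gene conversions — single markers that
disagree with their surrounding genotype block — artificial variants inflate
the event count by orders of magnitude, and for bulked-segregant mapping
they blur the causal peak.

meiomapr is a scriptable R toolkit for this problem, in three stages:

1. **Call** candidate SNPs and small indels (1–10 bp) from coordinate-sorted
   alignments with a standard diallelic genotype-likelihood model
   (per-observation error from base quality, heterozygous prior 1e-3), or
   import them from any VCF. Reads with mapping quality < 20 are ignored;
   reads whose alignment ends inside a tandem repeat (Tandem Repeats Finder
   output, score ≥ 10, unit ≤ 20 bp) are excluded from indel evidence
   there. Structural variants are detected from discordant read-pair
   distance/orientation signatures, window read depth, and split reads.
2. **Refine**: flag candidates inside or within ~500 bp of an SV
   (`SV_OVERLAP`, `SV_ADJACENT`), heterozygous indels whose second allele is
   supported only by repeat-terminating reads (`TANDEM_NONSPAN`, with
   genotype rewrite when spanning reads are unanimous), depth extremes
   (≥ 4× mean coverage and a 1% percentile tail, `DEPTH_EXTREME`),
   low support (`LOW_SUPPORT`), and heterozygous allelic ratios outside the
   central 99% of the empirical distribution (`ALLELE_RATIO`). Multi-sample
   runs are merged into one VCF with per-sample genotypes re-evaluated at
   every union locus.
3. **Apply** the refined markers:
   - *Recombination*: genotype a progeny's reads at each marker
     (`Ratio_s = M/(P+M)`), smooth over sliding windows
     (`Ratio_w = ΣP/Σ(P+M)`, 20 kb / 10 kb), call windows paternal-hom
     (`Ratio_w ≥ 0.8`), heterozygous, or maternal-hom (`≤ 0.2`), merge
     blocks, refine crossover boundaries to the flanking markers, and call
     gene conversions (converted markers < 1 kb apart grouped into events).
     The window size follows `2e3/depth × genome_size/snp_number`.
   - *Causal mapping (BSA)*: window allelic ratios of a phenotype-selected
     pooled F2 population (200 kb / 100 kb), smoothing on a 2 Mb / 500 kb
     grid with first/second discrete derivatives to find peaks/valleys,
     EMS candidate filtering (allelic ratio ≥ 0.75, absent from parents,
     G→A / C→T transitions), T-DNA novel-SV scanning, and gene-model
     annotation (splice site > CDS > UTR > exon > intron > intergenic,
     synonymous/non-synonymous by codon translation).

A **simulator** builds parental haplotypes, artifact-bearing alignments
(mis-mapped paralog reads inside deletions, collapsed duplication copies,
repeat-terminating reads), recombinant progenies with known crossovers and
conversion tracts, and selected F2 pools — all with complete ground truth,
so the whole pipeline is testable without external data.

## Worked example

```r
library(meiomapr)

## two parents: 1 Mb, one SNP per 200 bp, a deletion whose paralog
## mis-maps into it, a collapsed duplication, and an (AG)10 repeat that
## lost one unit in the second parent
par <- make_parents(
  length = 1e6, snp_rate = 1/200, indel_rate = 1/5000,
  sv_spec = list(
    list(class = "deletion",    pos = 3e5, len = 1500, divergence = 4,
         paralog = TRUE),
    list(class = "duplication", pos = 6e5, len = 2500, divergence = 3,
         true_snp = TRUE)),
  repeat_spec = list(list(pos = 8e5, unit = "AG", copies = 10,
                          alt_copy_delta = -1)),
  seed = 7)
sim  <- write_alignments(par, depth = 20, seed = 11)
reps <- meiomapr:::sim_repeats(par)   # (read_trf_dat() for real TRF output)
svs  <- detect_svs(sim$aln, par$gi, insert_mean = 500, insert_sd = 50)
svs
#>     chrom  start    end         class pair_support depth_ratio
#> 1:   chr1 299989 301516 transposition           27         NaN
#> 2:   chr1 600501 602500   duplication            0        2.16

cand    <- call_variants(sim$aln, par$gi, reps)
refined <- refine_variants(cand, svs, reps, mean_depth = 20)
nrow(cand); nrow(pass_variants(refined))
#> 5203 candidates; 5191 PASS markers
```

The mis-mapped paralog reads produce heterozygous-looking SNPs *inside* the
deleted interval; the detected SV flags them `SV_OVERLAP`, the collapsed
duplication's divergent sites are flagged through the 2× depth signal, and
the repeat indel is genotyped homozygous from spanning reads only — which is
the whole point of the refinement stage.

`window_size(20, 1e8, 5e5)` returns `20000`: 20 kb windows for 20× coverage
of a 100 Mb genome with one marker per 200 bp.

## Command line

A thin wrapper lives in `exec/meiomapr`:

```sh
meiomapr call   --bam sample.bam --ref ref.fa --repeats trf.dat --out cand.vcf
meiomapr sv     --bam sample.bam --ref ref.fa --out sv.bed
meiomapr refine --vcf cand.vcf --sv sv.bed --repeats trf.dat --out refined.vcf
meiomapr recomb --bam f2.bam --markers merged.vcf --ref ref.fa --out outdir/
meiomapr bsa    --bam pool.bam --markers merged.vcf --ref ref.fa \
                --mutant-parent M --out outdir/
meiomapr pipeline --config run.json
```

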