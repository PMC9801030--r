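## Bulked-segregant localization of causal mutations: window allelic
## ratios over the pooled F2 alignments, long-window smoothing with
## discrete derivatives, extremum detection, EMS/T-DNA candidate
## filters, and gene-model annotation.

#' Build the pooled allelic-ratio track
#'
#' Short windows (200 kb / 100 kb by default) estimate `Ratio_w` as in
#' progeny genotyping; a longer grid (2 Mb / 500 kb) re-averages the
#' supports for smoothing, and first/second discrete derivatives
#' (central differences) are attached to the smoothed grid.
#'
#' @param obs Marker observations from [genotype_markers()] on the
#'   pooled alignments.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window,step Short grid (defaults 2e5 / 1e5 bp).
#' @param smooth_window,smooth_step Long grid (defaults 2e6 / 5e5 bp).
#' @param min_markers Minimum informative markers per window (default 5).
#' @return Object of class `bsa_track`: `windows`, `smoothed` (with
#'   `d1`, `d2`), and the grid parameters.
#' @export
build_ratio_track <- function(obs, chrom_lengths, window = 2e5,
                              step = 1e5, smooth_window = 2e6,
                              smooth_step = 5e5, min_markers = 5L) {
  if (nrow(obs[p_supp + m_supp > 0L]) == 0L)
    stop("no informative marker observations")
  win <- call_windows(obs, chrom_lengths, window = window, step = step,
                      min_markers = min_markers)
  sm <- list()
  for (ch in names(chrom_lengths)) {
    if (chrom_lengths[[ch]] < smooth_window) {
      warning("chromosome ", ch, " shorter than one smoothing window; ",
              "smoothing skipped")
      next
    }
    s1 <- call_windows(obs[chrom == ch], chrom_lengths[ch],
                       window = smooth_window, step = smooth_step,
                       min_markers = min_markers)
    n <- nrow(s1)
    d1 <- d2 <- rep(NA_real_, n)
    if (n >= 3L) {
      r <- s1$ratio_w
      d1[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / 2
      d2[2:(n - 1)] <- r[3:n] - 2 * r[2:(n - 1)] + r[1:(n - 2)]
    }
    s1[, `:=`(d1 = d1, d2 = d2)]
    sm[[ch]] <- s1
  }
  structure(list(windows = win,
                 smoothed = if (length(sm)) rbindlist(sm) else NULL,
                 window = window, step = step,
                 smooth_window = smooth_window,
                 smooth_step = smooth_step),
            class = "bsa_track")
}

#' @export
print.bsa_track <- function(x, ...) {
  cat("bsa_track:", nrow(x$windows), "windows;",
      if (is.null(x$smoothed)) 0L else nrow(x$smoothed),
      "smoothed windows\n")
  invisible(x)
}

#' Find candidate regions from the smoothed ratio track
#'
#' Candidate stretches are runs of smoothed windows whose mutant-parent
#' allele fraction reaches `min_ratio` (0.75 for a recessive screen).
#' Each run must carry the derivative signature of an extremum: the
#' first derivative non-negative entering the run and non-positive
#' leaving it (a sign change across the run; a fully selected locus is
#' a plateau near 1.0 whose interior derivatives vanish), and a
#' curvature of at least `min_curvature` somewhere in or adjacent to
#' the run. The extremum is the run's argmax and the region extends to
#' where the smoothed ratio recedes by `drop` on each side.
#'
#' @param track A `bsa_track`.
#' @param mutant Which parent carries the mutation (`"M"` or `"P"`).
#' @param min_curvature Curvature floor on the smoothed grid (default
#'   0.02). A 0.5 to 1.0 rise over 5 Mb gives |d2| of about 0.04 after
#'   the 2 Mb window flattens the peak, so it qualifies with margin,
#'   while binomial noise on windows holding thousands of reads stays
#'   an order of magnitude below the floor.
#' @param drop Ratio recession defining the region edge (default 0.1).
#' @param min_ratio Expected-ratio floor at the extremum (default 0.75).
#' @return [data.table] of regions: chrom, start, end, kind
#'   (peak/valley on the raw `Ratio_w` scale), extreme_ratio (raw
#'   `Ratio_w` at the extremum).
#' @export
find_candidate_regions <- function(track, mutant = c("M", "P"),
                                   min_curvature = 0.02, drop = 0.1,
                                   min_ratio = 0.75) {
  mutant <- match.arg(mutant)
  if (is.null(track$smoothed)) stop("track has no smoothed component")
  out <- list()
  for (ch in unique(track$smoothed$chrom)) {
    s <- track$smoothed[chrom == ch][order(start)]
    mr <- if (mutant == "P") s$ratio_w else 1 - s$ratio_w
    n <- length(mr)
    if (n < 3L) next
    d1 <- c(NA, (mr[3:n] - mr[1:(n - 2)]) / 2, NA)
    d2 <- c(NA, mr[3:n] - 2 * mr[2:(n - 1)] + mr[1:(n - 2)], NA)
    ## candidate stretches: runs where the mutant fraction meets the
    ## expected ratio; a selected locus produces a plateau near 1.0, so
    ## the extremum is the run's argmax, the first-derivative sign
    ## change is assessed across the run, and the curvature test uses
    ## the strongest bend in or next to the run (plateau interiors are
    ## flat by construction)
    above <- !is.na(mr) & mr >= min_ratio
    if (!any(above)) next
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- c(1L, head(ends_i, -1L) + 1L)
    for (k in which(r$values)) {
      a <- starts_i[k]; b <- ends_i[k]
      i <- (a:b)[which.max(mr[a:b])]
      rising <- if (a == 1L) TRUE else {
        dl <- d1[max(2L, a - 1L)]; is.na(dl) || dl >= 0
      }
      falling <- if (b == n) TRUE else {
        dr <- d1[min(n - 1L, b + 1L)]; is.na(dr) || dr <= 0
      }
      if (!(rising && falling)) next
      d2win <- d2[max(2L, a - 1L):min(n - 1L, b + 1L)]
      if (!any(!is.na(d2win) & abs(d2win) >= min_curvature)) next
      lo <- i; hi <- i
      while (lo > 1L && !is.na(mr[lo - 1]) && mr[lo - 1] > mr[i] - drop)
        lo <- lo - 1L
      while (hi < n && !is.na(mr[hi + 1]) && mr[hi + 1] > mr[i] - drop)
        hi <- hi + 1L
      out[[paste(ch, i)]] <- data.table(
        chrom = ch, start = s$start[lo], end = s$end[hi],
        kind = if (mutant == "P") "peak" else "valley",
        extreme_ratio = s$ratio_w[i])
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      extreme_ratio = numeric()))
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

#' EMS candidate filter
#'
#' Applies, in order: 1) drop heterozygous-pool variants whose
#' variant-allele fraction is below `min_ratio` (0.75); 2) drop variants
#' whose alternate allele matches a parental genome; 3) keep only the
#' canonical EMS transitions G>A and C>T. The first failing rule is
#' recorded per variant in `ems_reason` (`""` = survivor).
#'
#' @param variants Variant table called on the pool inside candidate
#'   regions.
#' @param parental List of parental variant tables (alt alleles present
#'   in either parent are "consistent with parental genomes").
#' @param min_ratio Allelic-ratio floor (default 0.75).
#' @return The annotated table; survivors have `ems_reason == ""`.
#' @export
ems_candidate_filter <- function(variants, parental = list(),
                                 min_ratio = 0.75) {
  v <- copy(variants)
  v[, ems_reason := ""]
  if (nrow(v) == 0L) return(v[])
  af <- v$a_supp / pmax(v$p_supp + v$a_supp, 1L)
  v[af < min_ratio, ems_reason := "RATIO_BELOW_0.75"]
  if (length(parental)) {
    par <- unique(rbindlist(lapply(parental, function(p)
      p[, .(chrom, pos, alt)])))
    hit <- v[par, on = .(chrom, pos, alt), which = TRUE, nomatch = NULL]
    in_parent <- rep(FALSE, nrow(v)); in_parent[hit] <- TRUE
    v[in_parent & ems_reason == "", ems_reason := "PARENTAL_ALLELE"]
  }
  not_transition <- !((v$ref == "G" & v$alt == "A") |
                        (v$ref == "C" & v$alt == "T"))
  v[not_transition & ems_reason == "", ems_reason := "NOT_EMS_TRANSITION"]
  v[]
}

#' Scan candidate regions for novel structural variants (T-DNA mode)
#'
#' Runs pair-signature SV detection restricted to the candidate regions
#' and reports SVs absent from the parental SV set, ranked by support.
#'
#' @param aln Pooled alignment table.
#' @param regions Candidate regions from [find_candidate_regions()].
#' @param gi `genome_index`.
#' @param parental_svs SV table of the parents (novelty reference).
#' @param insert_mean,insert_sd Optional insert statistics.
#' @param min_support,min_mapq As in [detect_svs()]. Only pair and
#'   split-read signatures are used: window-depth statistics are not
#'   meaningful on a region-restricted read subset.
#' @return [sv_table()] of novel SVs, ordered by decreasing support.
#' @export
tdna_candidate_scan <- function(aln, regions, gi,
                                parental_svs = sv_table(),
                                insert_mean = NULL, insert_sd = NULL,
                                min_support = 3L, min_mapq = 20L) {
  if (nrow(regions) == 0L) return(sv_table())
  keep <- rep(FALSE, nrow(aln))
  for (i in seq_len(nrow(regions)))
    keep <- keep | (aln$chrom == regions$chrom[i] &
                      aln$pos <= regions$end[i] &
                      aln$end >= regions$start[i])
  sub <- aln[keep & !is.na(aln$mapq) & aln$mapq >= min_mapq]
  if (nrow(sub) == 0L) return(sv_table())
  pairs <- classify_pairs(sub, insert_mean, insert_sd)
  svs <- cluster_signatures(pairs, min_support = min_support)
  if (nrow(svs) == 0L) return(svs)
  svs <- add_split_support(svs, sub)
  ## novelty: no overlap with any parental SV of the same class
  if (nrow(parental_svs)) {
    ov <- findOverlaps(as_granges(svs), as_granges(parental_svs))
    drop <- unique(queryHits(ov)[
      svs$class[queryHits(ov)] == parental_svs$class[subjectHits(ov)]])
    if (length(drop)) svs <- svs[-drop]
  }
  ## keep SVs inside the regions only
  ov2 <- findOverlaps(as_granges(svs), as_granges(regions))
  svs <- svs[unique(queryHits(ov2))]
  svs[order(-pair_support - split_support)]
}

#' Annotate a mutation against gene models
#'
#' Feature class by interval containment with precedence splice-site >
#' CDS > UTR > exon > intron > intergenic; splice sites are the first
#' and last two intronic bases. CDS SNPs are translated on the feature
#' strand with the standard code and classified synonymous or
#' non-synonymous. A CDS whose length is not a multiple of 3 degrades
#' the annotation to `exon` with a warning.
#'
#' @param variants Variant table (SNPs annotated for coding effect;
#'   other classes get effect `not-applicable`).
#' @param gff Path to a GFF3 file or an imported `GRanges`.
#' @param gi `genome_index` (for codon lookup).
#' @return data.table: chrom, pos, ref, alt, feature, effect, gene_id.
#' @export
annotate_mutation <- function(variants, gff, gi) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  md <- mcols(gr)
  typ <- as.character(md$type)
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  utr5 <- gr[typ %in% c("five_prime_UTR", "5UTR")]
  utr3 <- gr[typ %in% c("three_prime_UTR", "3UTR")]
  genes <- gr[typ == "gene"]
  ## introns: gaps between exons of the same parent transcript
  exp_par <- as.character(unlist(mcols(exons)$Parent))
  introns <- GRanges()
  splice <- GRanges()
  if (length(exons) && length(exp_par) == length(exons)) {
    for (p in unique(exp_par)) {
      ex <- sort(exons[exp_par == p])
      if (length(ex) < 2L) next
      gaps <- GRanges(seqnames(ex)[1],
                      IRanges(head(end(ex), -1L) + 1L,
                              tail(start(ex), -1L) - 1L))
      gaps <- gaps[IRanges::width(gaps) > 0L]
      introns <- c(introns, gaps)
      if (length(gaps)) {
        sp <- c(GRanges(seqnames(gaps), IRanges(start(gaps),
                                                start(gaps) + 1L)),
                GRanges(seqnames(gaps), IRanges(end(gaps) - 1L,
                                                end(gaps))))
        splice <- c(splice, sp)
      }
    }
  }
  out <- list()
  for (i in seq_len(nrow(variants))) {
    vg <- GRanges(variants$chrom[i], IRanges(variants$pos[i],
                                             variants$pos[i]))
    gene_hit <- findOverlaps(vg, genes)
    gene_id <- if (length(gene_hit)) {
      id <- mcols(genes)$ID[subjectHits(gene_hit)[1]]
      if (is.null(id) || is.na(id)) NA_character_ else as.character(id)
    } else NA_character_
    feature <- "intergenic"; effect <- "not-applicable"
    if (length(findOverlaps(vg, splice))) {
      feature <- "splice site"
    } else if (length(findOverlaps(vg, cds))) {
      feature <- "exon"
      if (variants$class[i] == "SNP") {
        hit <- subjectHits(findOverlaps(vg, cds))[1]
        tx <- as.character(unlist(mcols(cds)$Parent))[hit]
        seg <- cds[as.character(unlist(mcols(cds)$Parent)) == tx]
        seg <- sort(seg)
        total <- sum(IRanges::width(seg))
        if (total %% 3L != 0L) {
          warning("CDS length of ", tx, " not divisible by 3; ",
                  "annotation degraded to exon")
        } else {
          strand_c <- as.character(BiocGenerics::strand(seg))[1]
          cds_seq <- paste(vapply(seq_along(seg), function(k)
            genome_seq(gi, as.character(seqnames(seg))[k],
                       start(seg)[k], end(seg)[k]), character(1)),
            collapse = "")
          offs <- cumsum(c(0L, head(IRanges::width(seg), -1L)))
          k <- which(start(seg) <= variants$pos[i] &
                       end(seg) >= variants$pos[i])[1]
          cpos <- offs[k] + variants$pos[i] - start(seg)[k] + 1L
          alt_seq <- cds_seq
          substr(alt_seq, cpos, cpos) <- variants$alt[i]
          if (strand_c == "-") {
            cds_seq <- as.character(reverseComplement(DNAString(cds_seq)))
            alt_seq <- as.character(reverseComplement(DNAString(alt_seq)))
          }
          p_ref <- as.character(translate(DNAString(cds_seq)))
          p_alt <- as.character(translate(DNAString(alt_seq)))
          effect <- if (p_ref == p_alt) "synonymous" else "non-synonymous"
        }
      }
    } else if (length(findOverlaps(vg, utr5))) {
      feature <- "5'-UTR"
    } else if (length(findOverlaps(vg, utr3))) {
      feature <- "3'-UTR"
    } else if (length(findOverlaps(vg, exons))) {
      feature <- "exon"
    } else if (length(findOverlaps(vg, introns))) {
      feature <- "intron"
    } else if (length(gene_hit)) {
      feature <- "intron"
    }
    out[[i]] <- data.table(chrom = variants$chrom[i],
                           pos = variants$pos[i], ref = variants$ref[i],
                           alt = variants$alt[i], feature = feature,
                           effect = effect, gene_id = gene_id)
  }
  rbindlist(out)
}
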