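## Candidate SNP/indel calling from pileups. The genotype model is a
## standard diallelic genotype likelihood: per-observation error from the
## base quality, error mass spread uniformly over the three alternative
## bases, diploid genotypes {ref-hom, het, alt-hom} with a configurable
## heterozygous prior. Mapping quality acts as a hard pre-filter only.

#' Filter reads by mapping quality and flag tandem-repeat spanning
#'
#' Reads with mapping quality below `min_mapq` are dropped. Remaining
#' reads are annotated against the filter-active repeat regions: a read
#' whose alignment start or end lies inside an active repeat (without
#' covering the whole region with both ends outside) is flagged
#' non-spanning; a read enclosing a repeat with both ends outside gets
#' the spans-repeat flag.
#'
#' @param aln Alignment table.
#' @param repeats [repeat_table()] (may be `NULL`).
#' @param min_mapq Minimum mapping quality (default 20).
#' @return The filtered table with logical columns `spans_rep` and
#'   `nonspan`.
#' @export
filter_reads <- function(aln, repeats = NULL, min_mapq = 20L) {
  aln <- aln[!is.na(mapq) & mapq >= min_mapq]
  aln[, `:=`(spans_rep = FALSE, nonspan = FALSE)]
  if (!is.null(repeats) && nrow(repeats)) {
    act <- repeats[active == TRUE]
    if (nrow(act)) {
      hits <- findOverlaps(as_granges(aln, "pos", "end"), as_granges(act))
      if (length(hits)) {
        q <- queryHits(hits); s <- subjectHits(hits)
        spans <- aln$pos[q] < act$start[s] & aln$end[q] > act$end[s]
        aln[unique(q[spans]), spans_rep := TRUE]
        aln[unique(q[!spans]), nonspan := TRUE]
      }
    }
  }
  aln[]
}

#' Extract pileup observations from an alignment table
#'
#' Walks CIGARs (vectorized through GenomicAlignments) and returns
#' per-column base observations plus gapped (indel) observations.
#'
#' @param aln Alignment table (ideally from [filter_reads()], so repeat
#'   span flags are present).
#' @param gi `genome_index` of the reference.
#' @param region Optional `list(chrom =, start =, end =)` restriction.
#' @return List with `bases` (chrom, pos, read, base, bq, mapq, nonspan,
#'   spans_rep) and `indels` (chrom, pos = anchor, type, len, alt_seq,
#'   read, nonspan, spans_rep).
#' @export
pileup_observations <- function(aln, gi, region = NULL) {
  if (!is.null(region))
    aln <- aln[chrom == region$chrom & pos <= region$end &
                 end >= region$start]
  if (!"spans_rep" %in% names(aln)) aln[, `:=`(spans_rep = FALSE,
                                               nonspan = FALSE)]
  if (nrow(aln) == 0L)
    return(list(bases = data.table(chrom = character(), pos = integer(),
                                   read = integer(), base = character(),
                                   bq = integer(), mapq = integer(),
                                   nonspan = logical(),
                                   spans_rep = logical()),
                indels = data.table(chrom = character(), pos = integer(),
                                    type = character(), len = integer(),
                                    alt_seq = character(), read = integer(),
                                    nonspan = logical(),
                                    spans_rep = logical())))
  rid <- seq_len(nrow(aln))
  rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = "M")
  rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(
    aln$cigar, ops = "M")
  nblk <- S4Vectors::elementNROWS(rref)
  bread <- rep(rid, nblk)
  uref <- unlist(rref, use.names = FALSE)
  uqry <- unlist(rqry, use.names = FALSE)
  bseq <- substr(aln$seq[bread], IRanges::start(uqry), IRanges::end(uqry))
  bqual <- substr(aln$qual[bread], IRanges::start(uqry), IRanges::end(uqry))
  w <- IRanges::width(uref)
  obs_read <- rep(bread, w)
  obs_pos <- sequence(w, from = IRanges::start(uref))
  obs_base <- CHAR_LOOKUP[utf8ToInt(paste(bseq, collapse = ""))]
  obs_bq <- utf8ToInt(paste(bqual, collapse = "")) - 33L
  bases <- data.table(chrom = aln$chrom[obs_read], pos = obs_pos,
                      read = obs_read, base = obs_base, bq = obs_bq,
                      mapq = aln$mapq[obs_read],
                      nonspan = aln$nonspan[obs_read],
                      spans_rep = aln$spans_rep[obs_read])
  if (!is.null(region))
    bases <- bases[pos >= region$start & pos <= region$end]

  ## deletions
  has_id <- grepl("[DI]", aln$cigar)
  idx <- which(has_id)
  ind_list <- list()
  if (length(idx)) {
    dref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      aln$cigar[idx], pos = aln$pos[idx], ops = "D")
    nd <- S4Vectors::elementNROWS(dref)
    if (sum(nd)) {
      dr <- unlist(dref, use.names = FALSE)
      dread <- idx[rep(seq_along(idx), nd)]
      anchor <- IRanges::start(dr) - 1L
      dl <- IRanges::width(dr)
      ind_list$del <- data.table(chrom = aln$chrom[dread], pos = anchor,
                                 type = "deletion", len = dl,
                                 alt_seq = "", read = dread,
                                 nonspan = aln$nonspan[dread],
                                 spans_rep = aln$spans_rep[dread])
    }
    iref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      aln$cigar[idx], pos = aln$pos[idx], ops = "I")
    iqry <- GenomicAlignments::cigarRangesAlongQuerySpace(
      aln$cigar[idx], ops = "I")
    ni <- S4Vectors::elementNROWS(iref)
    if (sum(ni)) {
      ir <- unlist(iref, use.names = FALSE)
      iq <- unlist(iqry, use.names = FALSE)
      iread <- idx[rep(seq_along(idx), ni)]
      ins_seq <- substr(aln$seq[iread], IRanges::start(iq),
                        IRanges::end(iq))
      ind_list$ins <- data.table(chrom = aln$chrom[iread],
                                 pos = IRanges::start(ir) - 1L,
                                 type = "insertion",
                                 len = IRanges::width(iq),
                                 alt_seq = ins_seq, read = iread,
                                 nonspan = aln$nonspan[iread],
                                 spans_rep = aln$spans_rep[iread])
    }
  }
  indels <- if (length(ind_list)) rbindlist(ind_list) else
    data.table(chrom = character(), pos = integer(), type = character(),
               len = integer(), alt_seq = character(), read = integer(),
               nonspan = logical(), spans_rep = logical())
  if (!is.null(region) && nrow(indels))
    indels <- indels[pos >= region$start & pos <= region$end]
  list(bases = bases, indels = indels)
}

## diallelic genotype posterior from per-observation log-likelihood terms
## returns list(genotype index 1=RR 2=RA 3=AA, posterior of the best)
genotype_posterior <- function(ll_rr, ll_ra, ll_aa, het_prior) {
  lp <- cbind(ll_rr + log(max(1 - 1.5 * het_prior, 1e-12)),
              ll_ra + log(het_prior),
              ll_aa + log(het_prior / 2))
  m <- pmax(lp[, 1], lp[, 2], lp[, 3])
  w <- exp(lp - m)
  post <- w / rowSums(w)
  best <- max.col(post, ties.method = "first")
  list(best = best, post = post[cbind(seq_len(nrow(post)), best)])
}

#' Call candidate SNPs and small indels from pileup observations
#'
#' Per column, the maximal-posterior diploid genotype is computed under
#' the diallelic likelihood; a call is emitted when it is non-reference
#' and its phred-scaled quality reaches `min_qual`. Indels are called
#' from gapped observations (length capped at 10 bp). Observations below
#' the base-quality floor are ignored.
#'
#' @param pile Result of [pileup_observations()].
#' @param gi `genome_index`.
#' @param het_prior Prior probability of a heterozygous genotype
#'   (default 1e-3).
#' @param min_qual Phred quality floor for emitting a call (default 20).
#' @param min_bq Base-quality floor for counting an observation
#'   (default 13).
#' @param min_obs Minimum non-reference observations to evaluate a
#'   column (default 2).
#' @param max_indel Small-indel length cap (default 10).
#' @param indel_err Per-observation error assumed for gap evidence
#'   (default 0.01; gap placement is noisier than base calls).
#' @param repeat_aware Drop reads that do not span a tandem repeat from
#'   the indel genotype evidence there (default `TRUE`, the published
#'   read filter). `FALSE` emulates a naive caller: repeat-terminating
#'   reads count as reference support and fake heterozygous indels,
#'   which the refinement stage must then catch.
#' @return Variant table; indel rows carry `span_ref`/`span_alt`/
#'   `nonspan_ref`/`nonspan_alt` support columns used by the tandem
#'   filter.
#' @export
call_candidates <- function(pile, gi, het_prior = 1e-3, min_qual = 20,
                            min_bq = 13L, min_obs = 2L, max_indel = 10L,
                            indel_err = 0.01, repeat_aware = TRUE) {
  bases <- pile$bases[bq >= min_bq]
  out <- list()

  if (nrow(bases)) {
    bases[, ref := ref_base_at(gi, chrom, pos)]
    cand <- bases[base != ref & base %in% c("A", "C", "G", "T"),
                  .N, by = .(chrom, pos, base)]
    cand <- cand[N >= min_obs]
    if (nrow(cand)) {
      ## alt allele = most supported non-reference base per column
      setorder(cand, chrom, pos, -N, base)
      cand <- cand[, .SD[1], by = .(chrom, pos)]
      cols <- bases[cand[, .(chrom, pos, alt = base)],
                    on = .(chrom, pos), nomatch = NULL]
      cols[, e := 10^(-bq / 10)]
      cols[, `:=`(p_ref = fifelse(base == ref, 1 - e, e / 3),
                  p_alt = fifelse(base == alt, 1 - e, e / 3))]
      gl <- cols[, .(ll_rr = sum(log(p_ref)),
                     ll_ra = sum(log((p_ref + p_alt) / 2)),
                     ll_aa = sum(log(p_alt)),
                     depth = .N, p_supp = sum(base == ref),
                     a_supp = sum(base == alt),
                     ref = ref[1], alt = alt[1]),
                 by = .(chrom, pos)]
      gp <- genotype_posterior(gl$ll_rr, gl$ll_ra, gl$ll_aa, het_prior)
      gl[, `:=`(gt = c("ref-hom", "het", "alt-hom")[gp$best],
                qual = phred(1 - gp$post))]
      snps <- gl[gt != "ref-hom" & qual >= min_qual]
      if (nrow(snps))
        out$snps <- snps[, .(chrom, pos, ref, alt, class = "SNP", depth,
                             p_supp, a_supp, genotype = gt,
                             qual = pmin(qual, 1000))]
    }
  }

  ind <- pile$indels[len <= max_indel & len >= 1L]
  if (nrow(ind)) {
    ind[, key := paste0(type, ":", len, ":", alt_seq)]
    ## dominant indel op per anchor
    tab <- ind[, .N, by = .(chrom, pos, key, type, len, alt_seq)]
    setorder(tab, chrom, pos, -N)
    tab <- tab[, .SD[1], by = .(chrom, pos)]
    tab <- tab[N >= min_obs]
    setkey(ind, chrom, pos)
    bidx <- pile$bases
    setkey(bidx, chrom, pos)
    for (i in seq_len(nrow(tab))) {
      ch <- tab$chrom[i]; p <- tab$pos[i]
      supp <- ind[.(ch, p)][key == tab$key[i]]
      ## reference support: reads aligned through the first affected base
      thru <- bidx[.(ch, p + 1L)][!is.na(read) & !(read %in% supp$read)]
      supp_gl <- if (repeat_aware) supp[nonspan == FALSE] else supp
      thru_gl <- if (repeat_aware) thru[nonspan == FALSE] else thru
      na <- nrow(supp_gl); nr <- nrow(thru_gl)
      if (na == 0L) next
      e <- indel_err
      gp <- genotype_posterior(na * log(e) + nr * log(1 - e),
                               (na + nr) * log(0.5),
                               na * log(1 - e) + nr * log(e),
                               het_prior)
      gt <- c("ref-hom", "het", "alt-hom")[gp$best]
      q <- phred(1 - gp$post)
      if (gt == "ref-hom" || q < min_qual) next
      anchor <- ref_base_at(gi, ch, p)
      if (tab$type[i] == "deletion") {
        refseq <- paste0(anchor, genome_seq(gi, ch, p + 1L, p + tab$len[i]))
        altseq <- anchor
      } else {
        refseq <- anchor
        altseq <- paste0(anchor, tab$alt_seq[i])
      }
      out[[paste0("ind", i)]] <- data.table(
        chrom = ch, pos = p, ref = refseq, alt = altseq,
        class = tab$type[i], depth = na + nr, p_supp = nr, a_supp = na,
        genotype = gt, qual = min(q, 1000),
        span_ref = sum(!thru$nonspan), span_alt = sum(!supp$nonspan),
        nonspan_ref = sum(thru$nonspan), nonspan_alt = sum(supp$nonspan))
    }
  }
  if (!length(out)) {
    res <- variant_table()
    res[, `:=`(span_ref = integer(), span_alt = integer(),
               nonspan_ref = integer(), nonspan_alt = integer())]
    return(res[])
  }
  res <- rbindlist(out, fill = TRUE)
  for (cc in c("span_ref", "span_alt", "nonspan_ref", "nonspan_alt"))
    if (!cc %in% names(res)) res[, (cc) := NA_integer_]
  res[, filter := ""]
  validate_variants(res)
  setkey(res, chrom, pos)
  res[]
}

## single-character lookup table: UTF-8 code point -> character
CHAR_LOOKUP <- vapply(1:127, function(i) intToUtf8(i), character(1))

## reference base lookup, vectorized over (chrom, pos): slices the
## covered stretch of each chromosome once and indexes into it
ref_base_at <- function(gi, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    lo <- min(pos[i]); hi <- max(pos[i])
    v <- CHAR_LOOKUP[utf8ToInt(genome_seq(gi, ch, lo, hi))]
    out[i] <- v[pos[i] - lo + 1L]
  }
  out
}

#' Call candidate variants from alignments
#'
#' Convenience wrapper: [filter_reads()] then [pileup_observations()]
#' then [call_candidates()].
#'
#' @param aln Alignment table (or path to SAM/BAM).
#' @param gi `genome_index`.
#' @param repeats Optional [repeat_table()].
#' @param min_mapq Mapping-quality floor (default 20).
#' @param region Optional `list(chrom, start, end)` restriction.
#' @param chunk_bp Genome is processed in chunks of this size to bound
#'   the pileup memory (default 5e5 bp).
#' @param ... Passed to [call_candidates()].
#' @return Variant table of candidates.
#' @export
call_variants <- function(aln, gi, repeats = NULL, min_mapq = 20L,
                          region = NULL, chunk_bp = 5e5, ...) {
  if (is.character(aln)) aln <- read_alignments(aln)
  aln <- filter_reads(copy(aln), repeats, min_mapq)
  spans <- if (!is.null(region))
    data.table(chrom = region$chrom, start = as.integer(region$start),
               end = as.integer(region$end))
  else data.table(chrom = names(gi$lengths), start = 1L,
                  end = as.integer(gi$lengths))
  out <- list()
  for (i in seq_len(nrow(spans))) {
    ch <- spans$chrom[i]
    cs_all <- seq.int(spans$start[i], spans$end[i], by = as.integer(chunk_bp))
    for (cs in cs_all) {
      ce <- min(cs + as.integer(chunk_bp) - 1L, spans$end[i])
      pile <- pileup_observations(
        aln, gi, region = list(chrom = ch, start = cs,
                               end = min(ce + 50L, spans$end[i])))
      cand <- call_candidates(pile, gi, ...)
      out[[paste(ch, cs)]] <- cand[pos >= cs & pos <= ce]
      rm(pile, cand)
      gc(FALSE)    # keep the per-chunk pileup from piling up
    }
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) return(out[[1]])
  setkey(res, chrom, pos)
  res[]
}
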