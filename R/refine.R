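## Artifact refinement: the filters that turn raw candidates into
## high-confidence markers. Reasons are unioned, never overwritten, so
## the cascade is order-insensitive and idempotent on the annotated set.

#' Flag candidates inside or adjacent to structural variants
#'
#' A candidate inside an SV interval gets `SV_OVERLAP`; one within
#' `margin` bp of an SV boundary gets `SV_ADJACENT`. The class of the
#' implicated SV is recorded in the `sv_class` column.
#'
#' @param candidates Variant table (coordinate-sorted).
#' @param svs [sv_table()].
#' @param margin Adjacency margin in bp (default 500).
#' @return The annotated table.
#' @export
filter_by_sv <- function(candidates, svs, margin = 500L) {
  if (!"sv_class" %in% names(candidates))
    candidates[, sv_class := NA_character_]
  if (nrow(svs) == 0L || nrow(candidates) == 0L) return(candidates[])
  vgr <- variants_granges(candidates)
  ov <- findOverlaps(vgr, as_granges(svs))
  inside <- unique(queryHits(ov))
  add_filter_reason(candidates, inside, "SV_OVERLAP")
  near <- findOverlaps(vgr, GRanges(svs$chrom,
                                    IRanges(pmax(1L, svs$start - margin),
                                            svs$end + margin)))
  adj <- setdiff(unique(queryHits(near)), inside)
  add_filter_reason(candidates, adj, "SV_ADJACENT")
  hits <- rbind(data.table(v = queryHits(ov), s = subjectHits(ov)),
                data.table(v = queryHits(near), s = subjectHits(near)))
  if (nrow(hits)) {
    lab <- hits[, .(cls = paste(sort(unique(svs$class[s])),
                                collapse = ",")), by = v]
    data.table::set(candidates, lab$v, "sv_class", lab$cls)
  }
  candidates[]
}

#' Examine small indels against tandem repeats
#'
#' Indels overlapping a filter-active repeat whose length is an integer
#' multiple of the repeat unit are re-typed as gain/loss of
#' `units_changed` units. A heterozygous indel whose second-allele
#' evidence comes only from reads that do not span the repeat gets
#' `TANDEM_NONSPAN`; when the spanning reads unanimously support one
#' allele the genotype is rewritten homozygous for that allele and the
#' non-spanning evidence is discarded from the supports.
#'
#' @param candidates Variant table carrying the per-candidate
#'   spanning-read support columns (`span_ref`, `span_alt`,
#'   `nonspan_ref`, `nonspan_alt`) produced by [call_candidates()].
#' @param repeats [repeat_table()].
#' @return The annotated table.
#' @export
filter_tandem_indels <- function(candidates, repeats) {
  if (!"units_changed" %in% names(candidates))
    candidates[, units_changed := NA_integer_]
  if (nrow(candidates) == 0L || is.null(repeats) || nrow(repeats) == 0L)
    return(candidates[])
  act <- repeats[active == TRUE]
  idx <- which(candidates$class %in% c("insertion", "deletion"))
  if (!length(idx) || nrow(act) == 0L) return(candidates[])
  ilen <- abs(nchar(candidates$ref[idx]) - nchar(candidates$alt[idx]))
  ## indel body: the bases gained/lost, anchored right of pos
  igr <- GRanges(candidates$chrom[idx],
                 IRanges(candidates$pos[idx] + 1L,
                         candidates$pos[idx] + pmax(ilen, 1L)))
  ov <- findOverlaps(igr, as_granges(act))
  if (!length(ov)) return(candidates[])
  for (h in seq_along(ov)) {
    i <- idx[queryHits(ov)[h]]
    r <- subjectHits(ov)[h]
    unit <- act$unit_len[r]
    len <- abs(nchar(candidates$ref[i]) - nchar(candidates$alt[i]))
    if (len %% unit == 0L)
      data.table::set(candidates, i, "units_changed",
                      as.integer(len %/% unit))
    sa <- candidates$span_alt[i]; sr <- candidates$span_ref[i]
    if (is.na(sa) || is.na(sr)) next
    if (candidates$genotype[i] == "het") {
      if (sa == 0L) {
        ## variant allele seen only in non-spanning reads: artificial
        add_filter_reason(candidates, i, "TANDEM_NONSPAN")
      } else if (sr == 0L && sa > 0L) {
        ## spanning reads unanimous for the variant: rewrite homozygous
        data.table::set(candidates, i, "genotype", "alt-hom")
        data.table::set(candidates, i, "p_supp", sr)
        data.table::set(candidates, i, "a_supp", sa)
        data.table::set(candidates, i, "depth", sr + sa)
      }
    }
  }
  candidates[]
}

#' Flag depth-extreme and under-supported candidates
#'
#' The published rule is conjunctive: a candidate is `DEPTH_EXTREME`
#' when its depth is at least `depth_fold` times the genome mean AND
#' falls in the top or bottom percentile tail of the depth distribution
#' over all candidates in the run (linear-interpolated quantiles). Since
#' fold-excess and bottom-tail membership exclude each other, only
#' high-coverage (collapsed-CNV-like) candidates are removed, which is
#' what preserves genuine low-coverage markers. `depth_rule =
#' "composite"` instead applies (fold AND top-tail) OR bottom-tail,
#' an alternative reading that also prunes the low-coverage tail. With
#' fewer than 100 candidates the percentile tails are disabled with a
#' warning and the fold rule applies alone. `LOW_SUPPORT` flags
#' candidates whose variant-allele support is below the floor.
#'
#' @param candidates Variant table.
#' @param mean_depth Genome mean sequencing depth (> 0).
#' @param config [refine_config()].
#' @param depth_rule `"conjunctive"` (default) or `"composite"`.
#' @return The annotated table.
#' @export
filter_by_depth <- function(candidates, mean_depth,
                            config = refine_config(),
                            depth_rule = c("conjunctive", "composite")) {
  depth_rule <- match.arg(depth_rule)
  if (nrow(candidates) == 0L) return(candidates[])
  if (is.na(mean_depth) || mean_depth <= 0)
    stop("mean depth must be positive")
  dp <- candidates$depth
  if (nrow(candidates) < 100L) {
    warning("fewer than 100 candidates; percentile tails disabled")
    extreme <- dp >= config$depth_fold * mean_depth
  } else {
    lo <- quantile(dp, config$depth_tail, names = FALSE, type = 7)
    hi <- quantile(dp, 1 - config$depth_tail, names = FALSE, type = 7)
    extreme <- if (depth_rule == "conjunctive")
      dp >= config$depth_fold * mean_depth & (dp >= hi | dp <= lo)
    else
      (dp >= config$depth_fold * mean_depth & dp >= hi) | dp <= lo
  }
  add_filter_reason(candidates, which(extreme), "DEPTH_EXTREME")
  add_filter_reason(candidates,
                    which(candidates$a_supp < config$min_support),
                    "LOW_SUPPORT")
  candidates[]
}

#' Flag heterozygous candidates with aberrant allelic ratios
#'
#' The allelic ratio of a candidate is primary/(primary + alternative)
#' support. The empirical ratio distribution over all heterozygous
#' candidates defines central acceptance bounds holding
#' `ratio_percentile` of the mass (0.5%-99.5% at the default 0.99);
#' het candidates outside the bounds get `ALLELE_RATIO`. Homozygous
#' candidates are exempt.
#'
#' @param candidates Variant table.
#' @param config [refine_config()].
#' @return The annotated table.
#' @export
filter_by_allele_ratio <- function(candidates,
                                   config = refine_config()) {
  het <- which(candidates$genotype == "het" &
                 candidates$p_supp + candidates$a_supp > 0L)
  if (length(het) < 2L) return(candidates[])
  ratio <- candidates$p_supp[het] /
    (candidates$p_supp[het] + candidates$a_supp[het])
  tail <- (1 - config$ratio_percentile) / 2
  b <- quantile(ratio, c(tail, 1 - tail), names = FALSE, type = 7)
  out <- het[ratio < b[1] | ratio > b[2]]
  add_filter_reason(candidates, out, "ALLELE_RATIO")
  candidates[]
}

#' Run the full refinement cascade
#'
#' Applies the SV, tandem-repeat, depth, and allelic-ratio filters in
#' sequence. Because reasons are unioned, the outcome is independent of
#' the order and refining an already-annotated table is a no-op.
#'
#' @param candidates Variant table of candidates.
#' @param svs [sv_table()] (may be empty).
#' @param repeats [repeat_table()] (may be `NULL`).
#' @param mean_depth Genome mean sequencing depth.
#' @param config [refine_config()].
#' @param depth_rule Passed to [filter_by_depth()].
#' @return The annotated table; take [pass_variants()] for the marker
#'   set.
#' @export
refine_variants <- function(candidates, svs = sv_table(), repeats = NULL,
                            mean_depth = mean(candidates$depth),
                            config = refine_config(),
                            depth_rule = "conjunctive") {
  candidates <- copy(candidates)
  filter_by_sv(candidates, svs, config$sv_margin)
  filter_tandem_indels(candidates, repeats)
  filter_by_depth(candidates, mean_depth, config, depth_rule)
  filter_by_allele_ratio(candidates, config)
  candidates[]
}

#' Merge refined calls from multiple samples
#'
#' Takes the union of PASS loci over the samples and re-evaluates every
#' sample's genotype at every union locus: from a fresh pileup of that
#' sample's alignments when given (same read filters as calling), else
#' from the stored allele depths. A sample with no coverage at a locus
#' is set missing.
#'
#' @param calls_list Named list of per-sample refined variant tables.
#' @param aln_list Optional named list of alignment tables (same names).
#' @param gi `genome_index` (required with `aln_list`).
#' @param repeats Optional repeats for the read filter.
#' @param het_prior Heterozygous prior for re-genotyping.
#' @param min_mapq Mapping-quality floor for re-pileup.
#' @return Long-format multi-sample variant table (one row per locus per
#'   sample) with a `sample_id` column.
#' @export
merge_samples <- function(calls_list, aln_list = NULL, gi = NULL,
                          repeats = NULL, het_prior = 1e-3,
                          min_mapq = 20L) {
  if (length(calls_list) < 2L) stop("need >= 2 samples to merge")
  if (is.null(names(calls_list)))
    names(calls_list) <- paste0("sample", seq_along(calls_list))
  loci <- unique(rbindlist(lapply(calls_list, function(x)
    pass_variants(x)[, .(chrom, pos, ref, alt, class)])))
  ## same position with different alleles is fine (kept as two records),
  ## but a conflicting REF at one position is a contract error
  refs <- unique(loci[, .(chrom, pos, ref1 = substr(ref, 1L, 1L))])
  dupref <- refs[, .N, by = .(chrom, pos)][N > 1L]
  if (nrow(dupref))
    stop("conflicting reference alleles at ", dupref$chrom[1], ":",
         dupref$pos[1])
  setkey(loci, chrom, pos)
  out <- list()
  for (s in names(calls_list)) {
    own <- calls_list[[s]][, .(chrom, pos, ref, alt, depth, p_supp,
                               a_supp, genotype, qual)]
    m <- merge(loci, own, by = c("chrom", "pos", "ref", "alt"),
               all.x = TRUE)
    need <- which(is.na(m$genotype))
    if (length(need) && !is.null(aln_list) && !is.null(aln_list[[s]])) {
      stopifnot(!is.null(gi))
      aln <- filter_reads(copy(aln_list[[s]]), repeats, min_mapq)
      pile <- pileup_observations(aln, gi)
      counts <- pile$bases[, .(chrom, pos, base)][
        m[need, .(chrom, pos, ref, alt, i = need)],
        on = .(chrom, pos), nomatch = NULL]
      if (nrow(counts)) {
        gcount <- counts[, .(depth = .N,
                             p_supp = sum(base == substr(ref, 1L, 1L)),
                             a_supp = sum(base == substr(alt, 1L, 1L))),
                         by = .(i)]
        e <- 1e-3
        gp <- genotype_posterior(
          gcount$p_supp * log(1 - e) + gcount$a_supp * log(e / 3),
          (gcount$p_supp + gcount$a_supp) * log(0.5),
          gcount$p_supp * log(e / 3) + gcount$a_supp * log(1 - e),
          het_prior)
        gt <- c("ref-hom", "het", "alt-hom")[gp$best]
        for (k in seq_len(nrow(gcount))) {
          i <- gcount$i[k]
          data.table::set(m, i, "genotype", gt[k])
          data.table::set(m, i, "depth", gcount$depth[k])
          data.table::set(m, i, "p_supp", gcount$p_supp[k])
          data.table::set(m, i, "a_supp", gcount$a_supp[k])
          data.table::set(m, i, "qual", phred(1 - gp$post[k]))
        }
      }
    } else if (length(need)) {
      ## no alignments: re-evaluate from any stored (non-PASS) candidate
      full <- calls_list[[s]][, .(chrom, pos, ref, alt, depth, p_supp,
                                  a_supp, genotype, qual)]
      m2 <- merge(m[need, .(chrom, pos, ref, alt, i = need)], full,
                  by = c("chrom", "pos", "ref", "alt"))
      for (k in seq_len(nrow(m2))) {
        i <- m2$i[k]
        for (cc in c("depth", "p_supp", "a_supp", "genotype", "qual"))
          data.table::set(m, i, cc, m2[[cc]][k])
      }
    }
    m[is.na(genotype), `:=`(genotype = "missing", depth = 0L,
                            p_supp = 0L, a_supp = 0L, qual = 0)]
    m[, `:=`(sample_id = s, filter = "")]
    out[[s]] <- m[, .(chrom, pos, ref, alt, class, depth, p_supp, a_supp,
                      genotype, qual, filter, sample_id)]
  }
  res <- rbindlist(out)
  setkey(res, chrom, pos, sample_id)
  res[]
}
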