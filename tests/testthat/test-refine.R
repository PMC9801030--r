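## refinement filter unit + property tests

test_that("filter_by_sv flags inside and adjacent candidates", {
  ## the published transposed-element deletion interval
  svs <- sv_table("chr1", 3728969L, 3730413L, "deletion", 12L)
  v <- vt(c(3729500, 3730913 + 1, 3726000), genotype = "alt-hom")
  filter_by_sv(v, svs, margin = 500L)
  expect_equal(v[pos == 3729500]$filter, "SV_OVERLAP")
  expect_equal(v[pos == 3729500]$sv_class, "deletion")
  ## exactly margin+1 bp past the SV end -> PASS
  expect_equal(v[pos == 3730914]$filter, "")
  ## margin boundary itself is flagged adjacent
  v2 <- vt(3730413 + 500)
  filter_by_sv(v2, svs, margin = 500L)
  expect_equal(v2$filter, "SV_ADJACENT")
  ## empty SV list leaves candidates unchanged
  v3 <- vt(c(10, 20))
  filter_by_sv(v3, sv_table(), margin = 500L)
  expect_equal(v3$filter, c("", ""))
})

test_that("filter_tandem_indels applies the unit/spanning rules", {
  reps <- repeat_table("chr1", 100L, 119L, 2L, 10, 40L)
  mk_ind <- function(genotype, span_ref, span_alt, nonspan_ref,
                     nonspan_alt, ref = "AAG", alt = "A", pos = 99L) {
    v <- vt(pos, ref = ref, alt = alt, class = "deletion",
            depth = span_ref + span_alt + nonspan_ref + nonspan_alt,
            p_supp = span_ref + nonspan_ref,
            a_supp = span_alt + nonspan_alt, genotype = genotype)
    v[, `:=`(span_ref = span_ref, span_alt = span_alt,
             nonspan_ref = nonspan_ref, nonspan_alt = nonspan_alt)]
    v
  }
  ## spanning reads unanimous for the deletion: rewritten homozygous
  v <- mk_ind("het", span_ref = 0L, span_alt = 9L, nonspan_ref = 5L,
              nonspan_alt = 0L)
  filter_tandem_indels(v, reps)
  expect_equal(v$genotype, "alt-hom")
  expect_equal(v$filter, "")
  expect_equal(v$a_supp, 9L)                    # nonspan evidence dropped
  expect_equal(v$units_changed, 1L)             # 2 bp = one AG unit
  ## variant allele only in non-spanning reads: artificial het
  v <- mk_ind("het", span_ref = 7L, span_alt = 0L, nonspan_ref = 0L,
              nonspan_alt = 4L)
  filter_tandem_indels(v, reps)
  expect_equal(v$filter, "TANDEM_NONSPAN")
  ## genuinely mixed spanning evidence: kept heterozygous
  v <- mk_ind("het", span_ref = 6L, span_alt = 6L, nonspan_ref = 2L,
              nonspan_alt = 0L)
  filter_tandem_indels(v, reps)
  expect_equal(v$genotype, "het")
  expect_equal(v$filter, "")
  ## 3-bp indel in a 2-bp-unit repeat: retained, not re-typed
  v <- mk_ind("het", 5L, 5L, 0L, 0L, ref = "AAGA", alt = "A")
  filter_tandem_indels(v, reps)
  expect_true(is.na(v$units_changed))
  ## indel outside all repeats: untouched
  v <- mk_ind("het", 0L, 9L, 5L, 0L, pos = 5000L)
  filter_tandem_indels(v, reps)
  expect_equal(v$genotype, "het")
  expect_equal(v$filter, "")
})

test_that("filter_by_depth: conjunctive (default) and composite rules", {
  withr::with_seed(17, {
    dp <- c(rpois(197, 20), 85L, 2L, 21L)
    v <- vt(seq_along(dp) * 100L, depth = dp, a_supp = pmin(dp, 10L))
  })
  cfg <- refine_config()
  filter_by_depth(v, mean_depth = 20, cfg)
  ## 85 = 4.25x mean and top-tail member -> flagged either way
  expect_match(v[depth == 85]$filter, "DEPTH_EXTREME")
  ## mid-distribution candidate passes
  expect_equal(v[depth == 21][1]$filter, "")
  ## bottom-tail depth 2: kept under the conjunctive rule...
  expect_false(grepl("DEPTH_EXTREME", v[depth == 2]$filter))
  ## ...flagged under the composite reading
  v2 <- vt(v$pos, depth = v$depth, a_supp = v$a_supp)
  filter_by_depth(v2, mean_depth = 20, cfg, depth_rule = "composite")
  expect_match(v2[depth == 2]$filter, "DEPTH_EXTREME")
  ## LOW_SUPPORT floor
  v3 <- vt(c(100, 200), depth = c(20L, 20L), a_supp = c(2L, 10L),
           p_supp = c(18L, 10L))
  expect_warning(filter_by_depth(v3, 20, cfg), "percentile tails")
  expect_equal(v3$filter, c("LOW_SUPPORT", ""))
  expect_error(filter_by_depth(v3, 0, cfg), "positive")
})

test_that("filter_by_allele_ratio bounds act on het candidates only", {
  withr::with_seed(23, {
    p <- rbinom(300, 40, 0.5)
    v <- vt(seq_len(300) * 10L, depth = 40L, p_supp = p, a_supp = 40L - p,
            genotype = "het")
  })
  ## plant two extreme het ratios and one hom
  outlier <- vt(c(9991, 9992), depth = 40L, p_supp = c(38L, 1L),
                a_supp = c(2L, 39L), genotype = "het")
  hom <- vt(9993, depth = 40L, p_supp = 1L, a_supp = 39L,
            genotype = "alt-hom")
  all <- rbind(v, outlier, hom, fill = TRUE)
  filter_by_allele_ratio(all, refine_config())
  expect_equal(all[pos == 9991]$filter, "ALLELE_RATIO")
  expect_equal(all[pos == 9992]$filter, "ALLELE_RATIO")
  expect_equal(all[pos == 9993]$filter, "")      # hom exempt
  ## 50/50 candidate sits inside the central band
  expect_equal(all[p_supp == 20 & genotype == "het"][1]$filter, "")
  ## oracle: bounds equal manual quantiles of the het ratio vector
  r <- all[genotype == "het", p_supp / (p_supp + a_supp)]
  b <- quantile(r, c(0.005, 0.995), names = FALSE)
  flagged <- all[genotype == "het" & filter != ""]
  fr <- flagged[, p_supp / (p_supp + a_supp)]
  expect_true(all(fr < b[1] | fr > b[2]))
})

test_that("refinement is order-insensitive and idempotent", {
  par <- artifact_parents()
  sim <- artifact_sim()
  reps <- meiomapr:::sim_repeats(par)
  cand <- call_variants(sim$aln, par$gi, reps)
  svs <- detect_svs(sim$aln, par$gi, insert_mean = 500, insert_sd = 50)
  cfg <- refine_config()
  r1 <- refine_variants(cand, svs, reps, mean_depth = 20, config = cfg)
  ## refined set is a subset of candidates; removals always carry reasons
  expect_lte(nrow(pass_variants(r1)), nrow(cand))
  expect_equal(nrow(r1), nrow(cand))
  expect_true(all(r1[filter != ""]$filter %in% r1$filter))
  ## idempotence
  r2 <- refine_variants(r1, svs, reps, mean_depth = 20, config = cfg)
  expect_equal(r2$filter, r1$filter)
  expect_equal(r2$genotype, r1$genotype)
  ## order-insensitivity of the PASS set: apply filters in reverse order
  alt_order <- copy(cand)
  filter_by_allele_ratio(alt_order, cfg)
  filter_by_depth(alt_order, 20, cfg)
  filter_tandem_indels(alt_order, reps)
  filter_by_sv(alt_order, svs, cfg$sv_margin)
  expect_equal(alt_order[filter == "", pos], r1[filter == "", pos])
})

test_that("merge_samples re-evaluates genotypes at union loci", {
  par <- tiny_parents()
  simA <- write_alignments(par, depth = 18, seed = 51L, sample = "A")
  simB <- write_alignments(par, depth = 18, seed = 52L, sample = "B")
  ca <- call_variants(simA$aln, par$gi)
  cb <- call_variants(simB$aln, par$gi)
  ## drop some loci from B's candidate list to force re-pileup
  cb_cut <- cb[-(1:5)]
  mg <- merge_samples(list(A = ca, B = cb_cut),
                      list(A = simA$aln, B = simB$aln), par$gi)
  expect_setequal(unique(mg$sample_id), c("A", "B"))
  ## every union locus appears once per sample
  expect_equal(nrow(mg), 2L * length(unique(paste(mg$chrom, mg$pos,
                                                  mg$alt))))
  ## the loci dropped from B were re-genotyped from B's alignments:
  ## both samples carry the alternate haplotype, so B is alt-hom there
  dropped <- cb[1:5, .(chrom, pos)]
  bgeno <- mg[sample_id == "B"][dropped, on = .(chrom, pos)]
  expect_true(all(bgeno$genotype == "alt-hom"))
  expect_true(all(bgeno$depth > 0))
  ## conflicting REF alleles are a contract error
  bad <- copy(ca)[1, ref := ifelse(ref == "A", "C", "A")]
  expect_error(merge_samples(list(A = bad, B = ca)), "conflicting")
  expect_error(merge_samples(list(A = ca)), ">= 2 samples")
})

test_that("merge without alignments uses stored depths; no coverage -> missing", {
  a <- vt(c(100, 200), depth = 20L, a_supp = 20L)
  b <- vt(100, depth = 15L, a_supp = 15L)
  mg <- merge_samples(list(A = a, B = b))
  expect_equal(mg[sample_id == "B" & pos == 200]$genotype, "missing")
  expect_equal(mg[sample_id == "B" & pos == 100]$genotype, "alt-hom")
  expect_equal(mg[sample_id == "A" & pos == 200]$genotype, "alt-hom")
})
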