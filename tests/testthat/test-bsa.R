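## BSA ratio track, candidate regions, EMS filter, annotation

## construct a bsa_track directly from a smoothed ratio curve
mk_track <- function(ratio, step = 5e5, chrom = "chr1") {
  n <- length(ratio)
  s <- data.table::data.table(
    chrom = chrom, start = seq(1L, by = as.integer(step),
                               length.out = n),
    end = seq(as.integer(step), by = as.integer(step), length.out = n),
    p_sum = 1000L, m_sum = 1000L, n_markers = 100L, ratio_w = ratio,
    genotype = "het")
  d1 <- d2 <- rep(NA_real_, n)
  d1[2:(n - 1)] <- (ratio[3:n] - ratio[1:(n - 2)]) / 2
  d2[2:(n - 1)] <- ratio[3:n] - 2 * ratio[2:(n - 1)] + ratio[1:(n - 2)]
  s[, `:=`(d1 = d1, d2 = d2)]
  structure(list(windows = s, smoothed = s, window = 2e5, step = 1e5,
                 smooth_window = 2e6, smooth_step = step),
            class = "bsa_track")
}

test_that("build_ratio_track: flat het pool gives a flat 0.5 track", {
  withr::with_seed(71, {
    pos <- sort(sample(6e6, 3000))
    obs <- data.table::data.table(chrom = "chr1", pos = pos,
                                  p_supp = rbinom(3000, 24, 0.5))
    obs[, m_supp := 24L - p_supp]
    obs[, ratio_s := m_supp / 24]
  })
  data.table::setkey(obs, chrom, pos)
  trk <- build_ratio_track(obs, c(chr1 = 6e6))
  expect_s3_class(trk, "bsa_track")
  expect_true(all(abs(trk$smoothed$ratio_w - 0.5) < 0.05))
  expect_true(all(abs(na.omit(trk$smoothed$d1)) < 0.02))
  expect_equal(nrow(find_candidate_regions(trk, "M")), 0L)
  ## empty marker set errors
  empty <- obs[0]
  expect_error(build_ratio_track(empty, c(chr1 = 6e6)), "no informative")
  ## short chromosome: smoothing skipped with warning
  expect_warning(
    t2 <- build_ratio_track(obs[pos < 1e6], c(chr1 = 1e6)),
    "shorter than one smoothing window")
  expect_null(t2$smoothed)
})

test_that("find_candidate_regions detects constructed extrema", {
  ## single valley in Ratio_w (= peak toward the maternal mutant)
  x <- seq(0, 1, length.out = 41)
  valley <- 0.5 - 0.48 * exp(-((x - 0.5) / 0.15)^2)
  tr <- mk_track(valley)
  reg <- find_candidate_regions(tr, mutant = "M")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$kind, "valley")
  vpos <- tr$smoothed$start[which.min(valley)]
  expect_lte(reg$start, vpos)
  expect_gte(reg$end, vpos)
  expect_equal(reg$extreme_ratio, min(valley), tolerance = 1e-9)
  ## flat track -> empty
  expect_equal(nrow(find_candidate_regions(mk_track(rep(0.5, 41)),
                                           "M")), 0L)
  ## two separated minima -> two regions
  two <- 0.5 - 0.45 * exp(-((x - 0.25) / 0.08)^2) -
    0.45 * exp(-((x - 0.75) / 0.08)^2)
  expect_equal(nrow(find_candidate_regions(mk_track(two), "M")), 2L)
  ## extremum short of the expected ratio is discarded
  shallow <- 0.5 - 0.15 * exp(-((x - 0.5) / 0.15)^2)
  expect_equal(nrow(find_candidate_regions(mk_track(shallow), "M")), 0L)
})

test_that("mirror-imaged tracks give mirrored regions (symmetry)", {
  x <- seq(0, 1, length.out = 41)
  curve <- 0.5 - 0.48 * exp(-((x - 0.4) / 0.12)^2)
  a <- find_candidate_regions(mk_track(curve), mutant = "M")
  b <- find_candidate_regions(mk_track(1 - curve), mutant = "P")
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$extreme_ratio, 1 - b$extreme_ratio, tolerance = 1e-12)
  expect_equal(a$kind, "valley")
  expect_equal(b$kind, "peak")
})

test_that("ems_candidate_filter applies rules 1-3 in order", {
  v <- rbind(
    vt(100, ref = "G", alt = "A", depth = 25L, p_supp = 2L,
       a_supp = 23L, genotype = "alt-hom"),       # survivor
    vt(200, ref = "G", alt = "A", depth = 20L, p_supp = 8L,
       a_supp = 12L, genotype = "het"),           # ratio 0.6 -> rule 1
    vt(300, ref = "A", alt = "C", depth = 20L, p_supp = 1L,
       a_supp = 19L, genotype = "alt-hom"),       # not G>A/C>T -> rule 3
    vt(400, ref = "C", alt = "T", depth = 20L, p_supp = 0L,
       a_supp = 20L, genotype = "alt-hom"))       # parental -> rule 2
  parental <- list(vt(400, ref = "C", alt = "T"))
  out <- ems_candidate_filter(v, parental)
  expect_equal(out[pos == 100]$ems_reason, "")
  expect_equal(out[pos == 200]$ems_reason, "RATIO_BELOW_0.75")
  expect_equal(out[pos == 300]$ems_reason, "NOT_EMS_TRANSITION")
  expect_equal(out[pos == 400]$ems_reason, "PARENTAL_ALLELE")
  ## a parental variant failing rule 1 keeps the rule-1 reason (order)
  v2 <- vt(400, ref = "C", alt = "T", depth = 20L, p_supp = 10L,
           a_supp = 10L, genotype = "het")
  expect_equal(ems_candidate_filter(v2, parental)$ems_reason,
               "RATIO_BELOW_0.75")
})

test_that("tdna_candidate_scan reports only novel in-region SVs", {
  par <- make_parents(
    length = 4e5L, snp_rate = 1 / 500,
    sv_spec = list(list(class = "insertion", pos = 150000, len = 250),
                   list(class = "deletion", pos = 300000, len = 1200)),
    seed = 81L)
  sim <- write_alignments(par, depth = 25, seed = 82L)
  regions <- data.table::data.table(chrom = "chr1", start = 100000L,
                                    end = 350000L, kind = "peak",
                                    extreme_ratio = 0.9)
  ## parental SV set contains the deletion: only the insertion is novel
  parental <- sv_table("chr1", 300000L, 301199L, "deletion", 10L)
  novel <- tdna_candidate_scan(sim$aln, regions, par$gi,
                               parental_svs = parental,
                               insert_mean = 500, insert_sd = 50)
  expect_true(nrow(novel) >= 1L)
  expect_true(any(novel$class == "insertion" &
                    abs(novel$start - 150000) < 1000))
  expect_false(any(novel$class == "deletion" &
                     novel$start > 299000 & novel$start < 302000))
  ## no discordant clusters in region -> empty
  calm <- data.table::data.table(chrom = "chr1", start = 10000L,
                                 end = 60000L, kind = "peak",
                                 extreme_ratio = 0.9)
  expect_equal(nrow(tdna_candidate_scan(sim$aln, calm, par$gi,
                                        parental_svs = parental,
                                        insert_mean = 500,
                                        insert_sd = 50)), 0L)
})

test_that("annotate_mutation classifies features and coding effects", {
  ## gene on +: exons 101-160 and 201-280; CDS 121-160 + 201-260
  ## (total 100 bases, 33 codons + 1 -> pad to 120: use 121-160,201-280)
  cds1 <- c(121L, 160L); cds2 <- c(201L, 280L)   # 40 + 80 = 120 bases
  seqs <- rand_seq(1000, seed = 91)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "test", "gene", 101, 300, ".", "+", ".",
          "ID=gene1", sep = "\t"),
    paste("chr1", "test", "mRNA", 101, 300, ".", "+", ".",
          "ID=tx1;Parent=gene1", sep = "\t"),
    paste("chr1", "test", "exon", 101, 160, ".", "+", ".",
          "ID=ex1;Parent=tx1", sep = "\t"),
    paste("chr1", "test", "exon", 201, 300, ".", "+", ".",
          "ID=ex2;Parent=tx1", sep = "\t"),
    paste("chr1", "test", "five_prime_UTR", 101, 120, ".", "+", ".",
          "ID=u5;Parent=tx1", sep = "\t"),
    paste("chr1", "test", "CDS", cds1[1], cds1[2], ".", "+", "0",
          "ID=c1;Parent=tx1", sep = "\t"),
    paste("chr1", "test", "CDS", cds2[1], cds2[2], ".", "+", "0",
          "ID=c2;Parent=tx1", sep = "\t"),
    paste("chr1", "test", "three_prime_UTR", 281, 300, ".", "+", ".",
          "ID=u3;Parent=tx1", sep = "\t")), gff)
  gi <- genome_index(c(chr1 = seqs))
  ## pick a codon third position inside CDS1 whose substitution is
  ## synonymous: codon 1 = bases 121-123; use a G>A at a wobble spot of
  ## a codon where both translate identically. Find one composedly:
  cds_seq <- genome_seq(gi, "chr1", 121, 160)
  syn_pos <- NA
  for (k in seq(3, 40, by = 3)) {
    codon <- substr(cds_seq, k - 2, k)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      mut <- codon; substr(mut, 3, 3) <- b
      aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
      aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
      if (aa1 == aa2) { syn_pos <- c(120L + k, b); break }
    }
    if (!is.na(syn_pos[1])) break
  }
  v_syn <- vt(as.integer(syn_pos[1]),
              ref = substr(cds_seq, as.integer(syn_pos[1]) - 120L,
                           as.integer(syn_pos[1]) - 120L),
              alt = syn_pos[2])
  ann <- annotate_mutation(v_syn, gff, gi)
  expect_equal(ann$feature, "exon")
  expect_equal(ann$effect, "synonymous")
  expect_equal(ann$gene_id, "gene1")
  ## 1 bp inside the intron after an exon boundary -> splice site
  ann2 <- annotate_mutation(vt(161), gff, gi)
  expect_equal(ann2$feature, "splice site")
  ## mid-intron
  ann3 <- annotate_mutation(vt(180), gff, gi)
  expect_equal(ann3$feature, "intron")
  ## UTRs
  expect_equal(annotate_mutation(vt(110), gff, gi)$feature, "5'-UTR")
  expect_equal(annotate_mutation(vt(290), gff, gi)$feature, "3'-UTR")
  ## far away -> intergenic
  ann4 <- annotate_mutation(vt(900), gff, gi)
  expect_equal(ann4$feature, "intergenic")
  expect_equal(ann4$effect, "not-applicable")
})
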