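## window-size formula, marker genotyping, window calls, blocks/COs, GCs

test_that("window_size reproduces the published example and floors", {
  expect_equal(window_size(20, 1e8, 5e5), 20000)
  expect_equal(window_size(10, 1e8, 5e5), 40000)
  expect_equal(window_size(2000, 1e6, 1e6), 1000)   # floor case
  expect_error(window_size(0, 1e8, 5e5), "positive")
  ## monotonicity: strictly decreasing in depth and in snp number
  withr::with_seed(3, {
    for (i in 1:50) {
      d <- runif(1, 1, 100); g <- runif(1, 1e7, 1e9)
      s <- runif(1, 1e4, 1e6)
      expect_gte(window_size(d, g, s), window_size(d * 2, g, s))
      expect_gte(window_size(d, g, s), window_size(d, g, s * 2))
    }
  })
})

mk_obs <- function(pos, p, m, chrom = "chr1") {
  o <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                              p_supp = as.integer(p),
                              m_supp = as.integer(m))
  o[, ratio_s := ifelse(p_supp + m_supp > 0, m_supp / (p_supp + m_supp),
                        NA_real_)]
  data.table::setkey(o, chrom, pos)
  o[]
}

test_that("genotype_markers partitions reads by allele", {
  gi <- genome_index(c(chr1 = rand_seq(2000, seed = 8)))
  pos <- 1000L
  ref <- genome_seq(gi, "chr1", pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  other <- setdiff(c("A", "C", "G", "T"), c(ref, alt))[1]
  mk <- marker_set(vt(pos, ref = ref, alt = alt), paternal = "ref")
  ## 7 paternal(ref), 3 maternal(alt), 2 other-base reads
  mkread <- function(b, n, off) {
    s <- substring(genome_seq(gi, "chr1", 951, 1050), 1, 100)
    substr(s, pos - 951 + 1, pos - 951 + 1) <- b
    data.table::data.table(qname = paste0(b, seq_len(n), "_", off),
                           flag = 0L, chrom = "chr1", pos = 951L,
                           mapq = 60L, cigar = "100M", rnext = "*",
                           pnext = 0L, tlen = 0L, seq = s,
                           qual = strrep("?", 100))
  }
  aln <- alignment_table(rbind(mkread(ref, 7, 1), mkread(alt, 3, 2),
                               mkread(other, 2, 3)))
  obs <- genotype_markers(aln, mk)
  expect_equal(obs$p_supp, 7L)
  expect_equal(obs$m_supp, 3L)
  expect_equal(obs$ratio_s, 0.3)
  ## boundary ratios
  aln2 <- alignment_table(mkread(alt, 12, 9))
  expect_equal(genotype_markers(aln2, mk)$ratio_s, 1.0)
  ## zero coverage markers masked
  far <- marker_set(vt(5L, ref = "A", alt = "C"), paternal = "ref")
  expect_true(is.na(genotype_markers(aln, far)$ratio_s))
})

test_that("call_windows applies the printed thresholds inclusively", {
  lens <- c(chr1 = 50000L)
  ## one marker per kb, all inside the first window
  obs <- mk_obs(seq(1000, 19000, by = 1000),
                p = rep(9, 19), m = rep(1, 19))
  w <- call_windows(obs, lens, window = 20000L, step = 20000L)
  expect_equal(w[1]$ratio_w, 0.9)
  expect_equal(w[1]$genotype, "paternal-hom")
  ## threshold boundaries: 0.8 inclusive paternal, 0.2 inclusive maternal
  for (case in list(list(p = 8, m = 2, g = "paternal-hom"),
                    list(p = 79, m = 21, g = "het"),
                    list(p = 21, m = 79, g = "het"),
                    list(p = 2, m = 8, g = "maternal-hom"))) {
    obs <- mk_obs(seq(1000, 5000, by = 1000), rep(case$p, 5),
                  rep(case$m, 5))
    w <- call_windows(obs, lens, window = 20000L, step = 20000L)
    expect_equal(w[1]$genotype, case$g)
  }
  ## windows short of informative markers are uncalled
  obs <- mk_obs(c(1000, 2000), c(10, 10), c(0, 0))
  w <- call_windows(obs, lens, window = 20000L, step = 20000L)
  expect_equal(w[1]$genotype, "uncalled")
  ## trailing partial window exists
  expect_equal(tail(w$end, 1), 50000L)
})

test_that("window sums conserve read-marker overlaps (property)", {
  withr::with_seed(41, {
    obs <- mk_obs(sort(sample(1e6, 400)), rpois(400, 10), rpois(400, 10))
  })
  w <- call_windows(obs, c(chr1 = 1e6L), window = 20000L, step = 20000L)
  expect_equal(sum(w$p_sum) + sum(w$m_sum),
               sum(obs$p_supp) + sum(obs$m_supp))
  expect_equal(sum(w$n_markers), nrow(obs[p_supp + m_supp > 0]))
})

test_that("merge_blocks groups windows and refines CO boundaries", {
  ## genotype sequence [M-hom x100, het x50, P-hom x30] -> 2 COs
  wins <- data.table::data.table(
    chrom = "chr1",
    start = seq(1L, by = 10000L, length.out = 180),
    end = seq(10000L, by = 10000L, length.out = 180),
    p_sum = 0L, m_sum = 0L, n_markers = 10L, ratio_w = 0.5,
    genotype = rep(c("maternal-hom", "het", "paternal-hom"),
                   c(100, 50, 30)))
  mb <- merge_blocks(wins)
  expect_equal(nrow(mb$blocks), 3L)
  expect_equal(nrow(mb$crossovers), 2L)
  expect_equal(mb$crossovers$left_genotype, c("maternal-hom", "het"))
  expect_true(all(mb$crossovers$right > mb$crossovers$left))
  ## uniform chromosome -> zero COs
  uni <- data.table::copy(wins)[, genotype := "het"]
  expect_equal(nrow(merge_blocks(uni)$crossovers), 0L)
  ## uncalled windows flanked by equal genotypes are absorbed
  absorbed <- data.table::copy(wins)[, genotype := "het"]
  absorbed[90:95, genotype := "uncalled"]
  mbu <- merge_blocks(absorbed)
  expect_equal(nrow(mbu$blocks), 1L)
  ## boundary refinement with markers every 200 bp
  obs <- mk_obs(seq(990000, 1010000, by = 200),
                p = ifelse(seq(990000, 1010000, by = 200) < 1000100,
                           0, 10),
                m = ifelse(seq(990000, 1010000, by = 200) < 1000100,
                           10, 0))
  wins2 <- data.table::data.table(
    chrom = "chr1",
    start = seq(1L, by = 10000L, length.out = 200),
    end = seq(10000L, by = 10000L, length.out = 200),
    p_sum = 0L, m_sum = 0L, n_markers = 10L, ratio_w = 0.5,
    genotype = rep(c("maternal-hom", "paternal-hom"), c(100, 100)))
  mb2 <- merge_blocks(wins2, obs)
  expect_false(mb2$crossovers$low_resolution)
  expect_lte(mb2$crossovers$right - mb2$crossovers$left, 2000L)
  expect_gte(1000100, mb2$crossovers$left)
  expect_lte(1000000, mb2$crossovers$right)
  ## junction without informative markers: inter-window gap + flag
  mb3 <- merge_blocks(wins2, mk_obs(integer(), integer(), integer()))
  expect_true(mb3$crossovers$low_resolution)
})

test_that("detect_gc groups converted markers below 1 kb spacing", {
  blocks <- data.table::data.table(chrom = "chr1", start = 1L,
                                   end = 100000L,
                                   genotype = "paternal-hom")
  ## converted markers at 30000/30600/32200: gaps 600 (merge) and 1600
  obs <- mk_obs(c(25000, 30000, 30600, 32200, 40000),
                p = c(10, 0, 1, 2, 10), m = c(0, 10, 9, 8, 0))
  ev <- detect_gc(obs, blocks, min_reads = 5L, window = 10000L)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_markers, c(2L, 1L))
  expect_equal(ev$start, c(30000L, 32200L))
  expect_equal(ev$background, rep("paternal-hom", 2))
  ## support floor: 3 opposite reads with min 5 -> not converted
  weak <- mk_obs(30000, p = 0, m = 3)
  expect_equal(nrow(detect_gc(weak, blocks, min_reads = 5L,
                              window = 1000L)), 0L)
  ## no converted markers -> empty
  expect_equal(nrow(detect_gc(mk_obs(30000, 10, 0), blocks)), 0L)
  ## het-conversion in hom background counts as converted
  hc <- detect_gc(mk_obs(30000, 5, 5), blocks, min_reads = 5L,
                  window = 1000L)
  expect_equal(hc$converted_to, "het")
})

test_that("simulated progeny COs are recovered with covering intervals", {
  par <- fixture("recomb_parents",
                 make_parents(length = 2e6L, snp_rate = 1 / 200,
                              seed = 61L))
  prog <- make_progeny(par, cos = list(c(600000, 1400000), numeric()),
                       start_origin = c("M", "M"),
                       depth = 20, seed = 62L)
  mk <- marker_set(vt(par$truth$snps$pos, ref = par$truth$snps$ref,
                      alt = par$truth$snps$alt), paternal = "ref")
  obs <- genotype_markers(prog$aln, mk)
  wins <- call_windows(obs, par$gi$lengths, 20000L, 10000L)
  mb <- merge_blocks(wins, obs)
  expect_equal(nrow(mb$crossovers), 2L)
  expect_true(all(!mb$crossovers$low_resolution))
  for (i in 1:2) {
    expect_lte(mb$crossovers$left[i], prog$truth$cos$pos[i])
    expect_gte(mb$crossovers$right[i], prog$truth$cos$pos[i])
    expect_lt(mb$crossovers$right[i] - mb$crossovers$left[i], 2000L)
  }
  ## recombination-free simulation: zero spurious COs
  flat <- make_progeny(par, cos = list(numeric(), numeric()),
                       start_origin = c("M", "M"), depth = 20,
                       seed = 63L)
  fobs <- genotype_markers(flat$aln, mk)
  fmb <- merge_blocks(call_windows(fobs, par$gi$lengths, 20000L, 10000L),
                      fobs)
  expect_equal(nrow(fmb$crossovers), 0L)
  expect_equal(nrow(detect_gc(fobs, fmb$blocks)), 0L)
})
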