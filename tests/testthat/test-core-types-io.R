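test_that("genome_index clips interval queries and rejects bad input", {
  gi <- genome_index(c(chr1 = "ACGTACGTAC"))
  expect_equal(genome_seq(gi, "chr1", 3, 6), "GTAC")
  expect_equal(genome_seq(gi, "chr1", -5, 100), "ACGTACGTAC")
  expect_equal(genome_seq(gi, "chr1", 9, 3), "")
  expect_equal(genome_length(gi, "chr1"), 10)
  expect_error(genome_length(gi, "chrX"), "unknown sequence")
  expect_error(genome_index(DNAStringSet("ACGT")), "named")
})

test_that("variant_table enforces its invariants", {
  expect_error(vt(10, depth = 5L, p_supp = 4L, a_supp = 4L),
               "exceeds depth")
  expect_error(vt(10, filter = "BOGUS"), "unknown filter reason")
  expect_error(vt(10, ref = paste(rep("A", 13), collapse = ""), alt = "A",
                  class = "deletion"), "1-10 bp")
  v <- vt(c(10, 20))
  expect_equal(v$filter, c("", ""))
})

test_that("add_filter_reason unions codes without duplication", {
  v <- vt(c(10, 20, 30))
  add_filter_reason(v, 1:2, "SV_OVERLAP")
  add_filter_reason(v, 2:3, "DEPTH_EXTREME")
  add_filter_reason(v, 2L, "SV_OVERLAP")        # already there: no-op
  expect_equal(v$filter,
               c("SV_OVERLAP", "SV_OVERLAP;DEPTH_EXTREME",
                 "DEPTH_EXTREME"))
  expect_equal(nrow(pass_variants(v)), 0L)
  expect_error(add_filter_reason(v, 1L, "NOT_A_CODE"))
})

test_that("read_alignments honours regions and rejects unknown sequences", {
  gi <- genome_index(c(chr1 = rand_seq(400)))
  aln <- alignment_table(data.table::data.table(
    qname = c("r1", "r2", "r3"), flag = 0L, chrom = "chr1",
    pos = c(120L, 150L, 250L), mapq = 60L, cigar = "50M", rnext = "*",
    pnext = 0L, tlen = 0L, seq = substring(genome_seq(gi, "chr1"),
                                           c(120, 150, 250),
                                           c(169, 199, 299)),
    qual = strrep("?", 50)))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, gi, sam)
  back <- read_alignments(sam)
  expect_equal(nrow(back), 3L)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$seq, aln$seq)
  ## region query: two of three reads overlap chr1:150-160
  sub <- read_alignments(sam, GenomicRanges::GRanges("chr1:150-160"))
  expect_equal(sort(sub$qname), c("r1", "r2"))
  ## empty region
  none <- read_alignments(sam, GenomicRanges::GRanges("chr1:350-360"))
  expect_equal(nrow(none), 0L)
  expect_error(read_alignments(sam, GenomicRanges::GRanges("chrZ:1-10")),
               "unknown sequence")
  expect_error(alignment_table(data.table::data.table(
    qname = "x", flag = 0L, chrom = "chr1", pos = 1L, mapq = 99L,
    cigar = "10M", rnext = "*", pnext = 0L, tlen = 0L,
    seq = "ACGTACGTAC", qual = "??????????")), "quality")
})

test_that("read_trf_dat parses the .dat dialect with activity thresholds", {
  f <- tempfile(fileext = ".dat")
  writeLines(c(
    "Tandem Repeats Finder Program",
    "",
    "Sequence: chr1 some description",
    "",
    "Parameters: 2 7 7 80 10 50 500",
    "",
    "101 140 2 10.0 2 95 0 28 25 25 25 25 1.9 AG AGAGAG",
    "201 500 24 12.0 24 90 5 80 25 25 25 25 2.0 AAC AACAAC",
    "301 320 2 10.0 2 95 0 6 25 25 25 25 1.9 AG AGAG"), f)
  reps <- read_trf_dat(f)
  expect_equal(nrow(reps), 3L)
  ## period 2, score 28 -> active; period 24 -> retained, inactive;
  ## score 6 < 10 -> inactive
  expect_equal(reps[start == 101]$active, TRUE)
  expect_equal(reps[start == 201]$active, FALSE)
  expect_equal(reps[start == 301]$active, FALSE)
  ## empty file
  f2 <- tempfile(); writeLines(character(), f2)
  expect_equal(nrow(read_trf_dat(f2)), 0L)
  ## BED dialect (0-based start converted)
  f3 <- tempfile(fileext = ".bed")
  writeLines("chr2\t99\t140\t2\t10.5\t30", f3)
  b <- read_trf_dat(f3)
  expect_equal(b$start, 100L)
  expect_equal(b$end, 140L)
  expect_true(b$active)
  f4 <- tempfile(fileext = ".bed")
  writeLines("chr2\t99\t140", f4)
  expect_error(read_trf_dat(f4), "4 columns")
})

test_that("VCF round trip is lossless for every field (property)", {
  withr::with_seed(99, {
    n <- 100
    pos <- sort(sample(1e6, n))
    cls <- sample(c("SNP", "deletion", "insertion"), n, TRUE,
                  prob = c(.7, .15, .15))
    ref <- alt <- character(n)
    for (i in seq_len(n)) {
      if (cls[i] == "SNP") {
        ref[i] <- sample(c("A", "C", "G", "T"), 1)
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
      } else {
        tail_seq <- paste(sample(c("A", "C", "G", "T"),
                                 sample(1:10, 1), TRUE), collapse = "")
        if (cls[i] == "deletion") {
          ref[i] <- paste0("A", tail_seq); alt[i] <- "A"
        } else {
          ref[i] <- "A"; alt[i] <- paste0("A", tail_seq)
        }
      }
    }
    dp <- sample(5:60, n, TRUE)
    a <- pmin(dp, sample(0:40, n, TRUE)); p <- dp - a
    v <- variant_table(rep("chr1", n), pos, ref, alt, cls, dp, p, a,
                       sample(c("ref-hom", "het", "alt-hom", "missing"),
                              n, TRUE),
                       round(runif(n, 0, 99), 2),
                       sample(c("", "SV_OVERLAP", "TANDEM_NONSPAN",
                                "DEPTH_EXTREME;ALLELE_RATIO"), n, TRUE))
  })
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  v2 <- import_vcf(f)
  for (cc in c("chrom", "pos", "ref", "alt", "class", "depth", "p_supp",
               "a_supp", "genotype", "filter"))
    expect_identical(v2[[cc]], v[[cc]])
  expect_equal(v2$qual, v$qual, tolerance = 1e-9)
})

test_that("write_vcf handles edge cases per contract", {
  f <- tempfile(fileext = ".vcf")
  write_vcf(variant_table(), f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))      # header-only
  v <- vt(c(100, 50))                            # variant_table sorts
  expect_equal(v$pos, c(50L, 100L))
  unsorted <- data.table::copy(v)[, pos := c(100L, 50L)]
  expect_error(write_vcf(unsorted, f), "sorted")
  ## FILTER column carries PASS and reason codes
  v2 <- vt(c(10, 20), filter = c("", "SV_OVERLAP"))
  write_vcf(v2, f)
  body <- grep("^[^#]", readLines(f), value = TRUE)
  expect_match(body[1], "\tPASS\t")
  expect_match(body[2], "\tSV_OVERLAP\t")
})

test_that("SV BED round trip preserves intervals and classes", {
  svs <- sv_table(c("chr1", "chr1"), c(100L, 5000L), c(900L, 6200L),
                  c("deletion", "duplication"), c(7L, 0L), c(NA, 2.4),
                  c(1L, 0L))
  f <- tempfile(fileext = ".bed")
  write_sv_bed(svs, f)
  back <- read_sv_bed(f)
  expect_equal(back$start, svs$start)
  expect_equal(back$end, svs$end)
  expect_equal(back$class, svs$class)
  expect_equal(back$pair_support, svs$pair_support)
})

test_that("import_vcf splits multi-allelic records and skips symbolic alts", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##contig=<ID=chr1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tT,G\t50\tPASS\t.\tGT:AD:DP\t1/2:2,9,8:20",
    "chr1\t200\t.\tC\t<DEL>\t50\tPASS\t.\tGT:AD:DP\t0/1:5,5:10",
    "chr1\t300\t.\tG\tA\t70\tPASS\t.\tGT:AD:DP\t1/1:0,22:22"), f)
  expect_warning(v <- import_vcf(f), "symbolic")
  expect_equal(nrow(v), 3L)                     # 2 from split + 1
  expect_equal(v[pos == 100]$alt, c("T", "G"))
  expect_equal(v[pos == 100]$a_supp, c(9L, 8L))
  expect_equal(v[pos == 300]$genotype, "alt-hom")
  expect_identical(attr(v, "provenance"), "imported")
})
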