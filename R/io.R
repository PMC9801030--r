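## Readers/writers for the standard formats the pipeline touches.
## Alignments are held as a data.table mirroring the SAM columns
## (qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, seq, qual)
## plus a derived reference `end`; this is the one in-memory currency all
## read-level operations consume.

ALN_COLS <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Read alignments from a SAM or BAM file
#'
#' SAM input is converted to a temporary coordinate-sorted BAM with
#' Rsamtools; a missing BAM index is created next to the file. Reads
#' overlapping `region` are returned in coordinate order.
#'
#' @param path SAM or BAM file.
#' @param region Optional `GRanges` (or `"chr:start-end"` string)
#'   restricting the query.
#' @return Alignment `data.table` (one row per record) with columns
#'   qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, seq, qual,
#'   end.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- asBam(path, tempfile(), overwrite = TRUE,
                 indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      indexBam(bam)
  }
  param_what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                  "mrnm", "mpos", "isize", "seq", "qual")
  if (!is.null(region)) {
    if (is.character(region)) region <- GRanges(region)
    hdr <- scanBamHeader(bam)[[1]]$targets
    missing_seq <- setdiff(as.character(seqnames(region)), names(hdr))
    if (length(missing_seq))
      stop("unknown sequence name(s): ", paste(missing_seq, collapse = ", "))
    param <- ScanBamParam(what = param_what, which = region)
  } else {
    param <- ScanBamParam(what = param_what)
  }
  res <- scanBam(bam, param = param)
  dt <- rbindlist(lapply(res, function(x)
    data.table(qname = x$qname, flag = x$flag,
               chrom = as.character(x$rname), pos = x$pos, mapq = x$mapq,
               cigar = x$cigar, rnext = as.character(x$mrnm),
               pnext = x$mpos, tlen = x$isize,
               seq = as.character(x$seq), qual = as.character(x$qual))))
  if (nrow(dt) == 0L)
    return(alignment_table(dt))
  dt <- unique(dt)               # overlapping region chunks may duplicate
  alignment_table(dt)
}

#' Build/complete an alignment table
#'
#' Fills derived columns (reference `end` from CIGAR, strand flags) and
#' sorts by coordinate.
#' @param dt data.table with the SAM-like columns.
#' @return The completed table keyed by (chrom, pos).
#' @export
alignment_table <- function(dt) {
  if (nrow(dt) == 0L) {
    dt <- data.table(qname = character(), flag = integer(),
                     chrom = character(), pos = integer(), mapq = integer(),
                     cigar = character(), rnext = character(),
                     pnext = integer(), tlen = integer(), seq = character(),
                     qual = character(), end = integer())
    setkey(dt, chrom, pos)
    return(dt[])
  }
  stopifnot(all(ALN_COLS %in% names(dt)))
  dt[, mapq := as.integer(mapq)]
  if (any(!is.na(dt$mapq) & (dt$mapq < 0L | dt$mapq > 60L)))
    stop("mapping quality outside [0, 60]")
  dt[, end := pos + cigarWidthAlongReferenceSpace(cigar) - 1L]
  setkey(dt, chrom, pos)
  dt[]
}

aln_strand <- function(flag) ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
aln_mate_strand <- function(flag) ifelse(bitwAnd(flag, 32L) > 0L, "-", "+")
aln_is_paired <- function(flag) bitwAnd(flag, 1L) > 0L

#' Write an alignment table as SAM
#'
#' @param aln Alignment table.
#' @param gi `genome_index` supplying the `@SQ` header lines.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, gi, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(gi$lengths),
                   as.integer(gi$lengths)))
  aln <- aln[order(chrom, pos)]
  body <- aln[, paste(qname, flag, chrom, pos, mapq, cigar,
                      ifelse(rnext == chrom & rnext != "*", "=", rnext),
                      pnext, tlen, seq, qual, sep = "\t")]
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse Tandem Repeats Finder output (.dat) or a repeat BED file
#'
#' The `.dat` dialect carries `Sequence:` headers followed by data rows
#' `start end period copies ... score ...`. BED input (0-based half-open)
#' needs at least 4 columns: chrom, start, end, unit length, and
#' optionally copies and score (score defaults high enough to be active).
#' Regions with score >= 10 and unit length <= 20 become filter-active;
#' others are retained inactive (units up to 24 bp are accepted).
#'
#' @param path `.dat` or `.bed` file.
#' @return A [repeat_table()].
#' @export
read_trf_dat <- function(path) {
  lines <- readLines(path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (length(lines) == 0L) return(repeat_table())
    f <- strsplit(lines, "\t| +")
    ncol <- lengths(f)
    if (any(ncol < 4L))
      stop("BED repeat line ", which(ncol < 4L)[1], ": need >= 4 columns")
    get <- function(i, default = NA) vapply(f, function(r)
      if (length(r) >= i) r[i] else as.character(default), character(1))
    start0 <- suppressWarnings(as.integer(get(2)))
    end <- suppressWarnings(as.integer(get(3)))
    unit <- suppressWarnings(as.integer(get(4)))
    if (anyNA(start0) || anyNA(end) || anyNA(unit))
      stop("unparseable BED repeat line ",
           which(is.na(start0) | is.na(end) | is.na(unit))[1])
    copies <- suppressWarnings(as.numeric(get(5)))
    score <- suppressWarnings(as.integer(get(6)))
    copies[is.na(copies)] <- (end - start0) / unit[is.na(copies)]
    score[is.na(score)] <- 1000L
    return(repeat_table(get(1), start0 + 1L, end, unit, copies, score))
  }
  ## TRF .dat
  cur <- NA_character_
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "Sequence:")) {
      cur <- strsplit(trimws(sub("^Sequence:", "", ln)), "\\s+")[[1]][1]
      next
    }
    if (grepl("^[0-9]+ [0-9]+ [0-9]+ ", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 8L) stop("unparseable TRF line ", i)
      if (is.na(cur)) stop("TRF data line ", i, " before any Sequence header")
      v <- suppressWarnings(as.numeric(f[1:8]))
      if (anyNA(v)) stop("unparseable TRF line ", i)
      rows[[i]] <- data.table(chrom = cur, start = as.integer(v[1]),
                              end = as.integer(v[2]),
                              unit_len = as.integer(v[3]), copies = v[4],
                              score = as.integer(v[8]))
    }
  }
  dt <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(dt) == 0L) return(repeat_table())
  repeat_table(dt$chrom, dt$start, dt$end, dt$unit_len, dt$copies, dt$score)
}

GT_CODE <- c("ref-hom" = "0/0", "het" = "0/1", "alt-hom" = "1/1",
             "missing" = "./.")

#' Write variant calls as VCF 4.2
#'
#' FILTER carries the refinement reason codes (`PASS` when empty); the
#' per-sample FORMAT is `GT:AD:DP` with AD = (primary, alternative)
#' allele read counts. A single-sample table (no `sample_id` column) is
#' written under `sample`; a long multi-sample table (from
#' [merge_samples()]) is pivoted into one column per sample. Reading the
#' file back with [import_vcf()] reproduces every field.
#'
#' @param calls Variant table, sorted by (chrom, pos).
#' @param path Output path.
#' @param sample Sample name for single-sample tables.
#' @param gi Optional `genome_index` for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "sample1", gi = NULL) {
  multi <- "sample_id" %in% names(calls)
  loci_cols <- c("chrom", "pos", "ref", "alt")
  key_dt <- unique(calls[, c(loci_cols, "class", "qual", "filter"),
                         with = FALSE])
  if (is.unsorted(order(key_dt$chrom, key_dt$pos)) ||
      !identical(order(key_dt$chrom, key_dt$pos), seq_len(nrow(key_dt))))
    stop("calls must be sorted by (chrom, pos)")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=meiomapr",
           sprintf("##FILTER=<ID=%s,Description=\"%s\">", FILTER_REASONS,
                   FILTER_REASONS),
           "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=2,Type=Integer,Description=",
                  "\"Primary,alternative allele read depth\">"),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  if (!is.null(gi))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(gi$lengths),
                          as.integer(gi$lengths)))
  samples <- if (multi) sort(unique(calls$sample_id)) else sample
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  fmt_one <- function(gt, p, a, dp)
    sprintf("%s:%d,%d:%d", GT_CODE[gt], p, a, dp)
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  if (multi) {
    wide <- dcast(calls, chrom + pos + ref + alt + class + qual + filter ~
                    sample_id,
                  value.var = list("genotype", "p_supp", "a_supp", "depth"))
    setorder(wide, chrom, pos)
    gcols <- lapply(samples, function(s)
      fmt_one(wide[[paste0("genotype_", s)]],
              nafill_int(wide[[paste0("p_supp_", s)]]),
              nafill_int(wide[[paste0("a_supp_", s)]]),
              nafill_int(wide[[paste0("depth_", s)]])))
    base <- wide
  } else {
    gcols <- list(fmt_one(calls$genotype, calls$p_supp, calls$a_supp,
                          calls$depth))
    base <- calls
  }
  body <- paste(base$chrom, base$pos, ".", base$ref, base$alt,
                formatC(base$qual, format = "f", digits = 2),
                ifelse(base$filter == "", "PASS", base$filter),
                paste0("VC=", base$class), "GT:AD:DP", sep = "\t")
  for (g in gcols) body <- paste(body, g, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

nafill_int <- function(x) {
  x <- as.integer(x)
  x[is.na(x)] <- 0L
  x
}

#' Import variants from a VCF file
#'
#' Reads VCF (own output or third-party) into the internal variant table.
#' Multi-allelic records are split into one candidate per alternate
#' allele; symbolic alternates (e.g. `<DEL>`) are skipped with a warning,
#' as are indels longer than the 10-bp small-indel cap. Allele depths are
#' recovered from `AD` (records lacking AD get zero support, flagged by a
#' warning, and are marked unrefinable via the `refinable` attribute
#' column).
#'
#' @param path VCF file.
#' @param sample Sample column to read (index or name; default first).
#' @return Variant table; multi-sample files additionally return the long
#'   form with `sample_id` when `sample = NULL`.
#' @export
import_vcf <- function(path, sample = 1L) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0L) return(variant_table())
  rr <- SummarizedExperiment::rowRanges(vcf)
  altl <- VariantAnnotation::alt(vcf)
  gtm <- VariantAnnotation::geno(vcf)
  all_samples <- colnames(vcf)
  want <- if (is.null(sample)) all_samples else all_samples[sample]
  per_alt <- rep(seq_len(n), S4Vectors::elementNROWS(altl))
  alt_chr <- as.character(unlist(altl))
  rec <- data.table(
    row = per_alt,
    alt_i = unlist(lapply(S4Vectors::elementNROWS(altl), seq_len)),
    chrom = as.character(seqnames(rr))[per_alt],
    pos = start(rr)[per_alt],
    ref = as.character(rr$REF)[per_alt],
    alt = alt_chr,
    qual = as.numeric(rr$QUAL)[per_alt],
    filter = as.character(rr$FILTER)[per_alt])
  sym <- grepl("[][<>]", rec$alt) | rec$alt == "*" | rec$alt == ""
  if (any(sym)) {
    warning(sum(sym), " symbolic/breakend alternate allele(s) skipped")
    rec <- rec[!sym]
  }
  rec[, class := fifelse(nchar(ref) == nchar(alt), "SNP",
                  fifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))]
  toolong <- abs(nchar(rec$ref) - nchar(rec$alt)) > 10L |
    (rec$class == "SNP" & nchar(rec$ref) != 1L)
  if (any(toolong)) {
    warning(sum(toolong), " record(s) outside the SNP/small-indel classes",
            " skipped")
    rec <- rec[!toolong]
  }
  if (nrow(rec) == 0L) return(variant_table())
  rec[, filter := fifelse(filter %in% c("PASS", "."), "", filter)]
  out_list <- lapply(want, function(s) {
    r <- copy(rec)
    if (!is.null(gtm$DP) && s %in% colnames(gtm$DP)) {
      dp <- as.integer(gtm$DP[, s])
      r[, depth := pmax(nafill_int(dp[row]), 0L)]
    } else r[, depth := 0L]
    refinable <- TRUE
    if (!is.null(gtm$AD) && s %in% colnames(gtm$AD)) {
      adm <- gtm$AD
      if (is.array(adm) && length(dim(adm)) == 3L) {
        ## fixed Number=2: records x samples x alleles
        r[, p_supp := nafill_int(adm[row, s, 1L])]
        r[, a_supp := mapply(function(i, k) nafill_int(adm[i, s, k + 1L]),
                             row, alt_i)]
      } else {
        adl <- adm[, s]
        r[, p_supp := vapply(row, function(i) nafill_int(adl[[i]][1]),
                             integer(1))]
        r[, a_supp := mapply(function(i, k) nafill_int(adl[[i]][k + 1L]),
                             row, alt_i)]
      }
    } else {
      warning("no AD field for sample ", s,
              "; allele depths set to 0 (records unrefinable)")
      r[, `:=`(p_supp = 0L, a_supp = 0L)]
      refinable <- FALSE
    }
    r[, depth := pmax(depth, p_supp + a_supp)]
    gts <- if (!is.null(gtm$GT)) gtm$GT[, s] else rep(".", n)
    code <- gts[r$row]
    alt_ix <- as.character(r$alt_i)
    gclass <- rep("missing", nrow(r))
    gclass[code %in% c("0/0", "0|0")] <- "ref-hom"
    split_gt <- strsplit(code, "[/|]")
    hasalt <- mapply(function(g, k) sum(g == k), split_gt, alt_ix)
    gclass[hasalt == 1] <- "het"
    gclass[hasalt == 2] <- "alt-hom"
    r[, genotype := gclass]
    out <- variant_table(r$chrom, r$pos, r$ref, r$alt, r$class, r$depth,
                         r$p_supp, r$a_supp, r$genotype,
                         fifelse(is.na(r$qual), 0, r$qual), r$filter)
    out[, `:=`(sample_id = s)]
    setattr(out, "refinable", refinable)
    out
  })
  if (length(out_list) == 1L) {
    res <- out_list[[1]]
    res[, sample_id := NULL]
  } else res <- rbindlist(out_list)
  setattr(res, "provenance", "imported")
  setkey(res, chrom, pos)
  res[]
}

#' Write structural variants as BED
#'
#' Columns: chrom, start (0-based), end, class, pair support, strand
#' placeholder, depth ratio, split support.
#' @param svs SV table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_bed <- function(svs, path) {
  lines <- svs[, paste(chrom, start - 1L, end, class, pair_support, ".",
                       round(depth_ratio, 4), split_support, sep = "\t")]
  writeLines(lines, path)
  invisible(path)
}

#' Read structural variants from a BED written by [write_sv_bed()]
#' @param path BED file.
#' @return SV table.
#' @export
read_sv_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track)", lines)]
  if (length(lines) == 0L) return(sv_table())
  f <- fread(text = lines, header = FALSE)
  sv_table(as.character(f$V1), f$V2 + 1L, f$V3, as.character(f$V4),
           if (ncol(f) >= 5) f$V5 else 0L,
           if (ncol(f) >= 7) as.numeric(f$V7) else NA_real_,
           if (ncol(f) >= 8) f$V8 else 0L)
}
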