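## Domain containers. All tables are data.tables with a fixed column
## contract; coordinates are 1-based closed (the IRanges convention) for
## every internal structure. VCF/GFF3/TRF are already 1-based, so format
## boundaries need no shifting; BED is converted on read/write.

#' Filter reason codes
#'
#' Enumerated reason codes attached to candidate variants during
#' refinement. An empty reason set means the candidate passes all filters
#' and is written to the VCF FILTER column as `PASS`.
#'
#' \describe{
#'   \item{MQ_LOW}{supporting evidence dominated by low mapping quality}
#'   \item{SV_OVERLAP}{lies inside a structural-variant interval}
#'   \item{SV_ADJACENT}{within the adjacency margin of an SV boundary}
#'   \item{TANDEM_NONSPAN}{heterozygous indel evidence only from reads
#'     that do not span the tandem repeat}
#'   \item{DEPTH_EXTREME}{read depth in a percentile tail and/or above the
#'     fold-coverage threshold}
#'   \item{ALLELE_RATIO}{heterozygous allelic ratio outside the empirical
#'     acceptance bounds}
#'   \item{LOW_SUPPORT}{fewer supporting reads than the configured floor}
#' }
#' @export
FILTER_REASONS <- c("MQ_LOW", "SV_OVERLAP", "SV_ADJACENT", "TANDEM_NONSPAN",
                    "DEPTH_EXTREME", "ALLELE_RATIO", "LOW_SUPPORT")

#' Genome index backed by a DNA string set
#'
#' Light wrapper over a [Biostrings::DNAStringSet] providing sequence
#' names, lengths, and a clipped interval accessor.
#'
#' @param x A `DNAStringSet`, a named character vector of sequences, or a
#'   path to a FASTA file.
#' @return An object of class `genome_index`.
#' @examples
#' gi <- genome_index(c(chr1 = "ACGTACGTAC"))
#' genome_seq(gi, "chr1", 3, 6)
#' @export
genome_index <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x)))
    x <- readDNAStringSet(x)
  if (is.character(x)) x <- DNAStringSet(x)
  stopifnot(is(x, "DNAStringSet"))
  nm <- names(x)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("genome sequences must be named")
  ## FASTA headers may carry descriptions after the first token
  names(x) <- sub("\\s.*$", "", nm)
  if (any(Biostrings::width(x) <= 0L)) stop("sequence lengths must be positive")
  structure(list(seq = x, lengths = setNames(Biostrings::width(x), names(x))),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$lengths), "sequence(s),",
      sum(as.numeric(x$lengths)), "bp total\n")
  invisible(x)
}

#' @rdname genome_index
#' @param gi A `genome_index`.
#' @param chrom Sequence name.
#' @param start,end 1-based closed interval, clipped to the sequence.
#' @export
genome_seq <- function(gi, chrom, start = 1L, end = NULL) {
  len <- genome_length(gi, chrom)
  if (is.null(end)) end <- len
  start <- max(1L, as.integer(start))
  end <- min(len, as.integer(end))
  if (end < start) return("")
  as.character(subseq(gi$seq[[chrom]], start, end))
}

#' @rdname genome_index
#' @export
genome_length <- function(gi, chrom) {
  len <- gi$lengths[chrom]
  if (anyNA(len)) stop("unknown sequence name: ", chrom)
  unname(len)
}

#' Construct a candidate/refined variant table
#'
#' The central table of the pipeline: one row per candidate SNP or small
#' indel. `p_supp`/`a_supp` are the primary- and alternative-allele read
#' supports (the allelic-ratio numerator and denominator components);
#' `filter` is a semicolon-joined set of [FILTER_REASONS] codes, `""`
#' meaning PASS.
#'
#' @param chrom,pos,ref,alt Locus and alleles (`pos` 1-based, anchored
#'   VCF-style for indels).
#' @param class One of `"SNP"`, `"insertion"`, `"deletion"`.
#' @param depth Total read depth at the locus.
#' @param p_supp,a_supp Primary/alternative allele read support.
#' @param genotype One of `"ref-hom"`, `"het"`, `"alt-hom"`, `"missing"`.
#' @param qual Phred-scaled call quality.
#' @param filter Semicolon-joined reason codes (`""` = PASS).
#' @return A `data.table` keyed by (chrom, pos).
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          class = character(), depth = integer(),
                          p_supp = integer(), a_supp = integer(),
                          genotype = character(), qual = numeric(),
                          filter = character()) {
  n <- length(pos)
  if (length(filter) == 0L && n > 0L) filter <- rep("", n)
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   class = as.character(class), depth = as.integer(depth),
                   p_supp = as.integer(p_supp), a_supp = as.integer(a_supp),
                   genotype = as.character(genotype), qual = as.numeric(qual),
                   filter = as.character(filter))
  validate_variants(dt)
  setkey(dt, chrom, pos)
  dt[]
}

validate_variants <- function(dt) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "class", "depth", "p_supp",
                  "a_supp", "genotype", "qual", "filter") %in% names(dt)))
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(dt$p_supp + dt$a_supp > dt$depth))
    stop("primary + alternative support exceeds depth")
  bad <- setdiff(unlist(strsplit(dt$filter[dt$filter != ""], ";")),
                 FILTER_REASONS)
  if (length(bad)) stop("unknown filter reason code(s): ",
                        paste(bad, collapse = ", "))
  ilen <- nchar(dt$ref) + nchar(dt$alt) - 2L
  if (any(dt$class %in% c("insertion", "deletion") & (ilen < 1L | ilen > 10L)))
    stop("small-indel length must be 1-10 bp")
  invisible(dt)
}

#' Add a filter reason code to selected variants
#'
#' Reasons are unioned, never overwritten, so the filter cascade is
#' order-insensitive.
#'
#' @param calls Variant table.
#' @param idx Row indices (integer or logical) to annotate.
#' @param reason A code from [FILTER_REASONS].
#' @return The modified table (by reference).
#' @export
add_filter_reason <- function(calls, idx, reason) {
  reason <- match.arg(reason, FILTER_REASONS)
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0L) return(invisible(calls))
  cur <- calls$filter[idx]
  has <- vapply(strsplit(cur, ";"), function(r) reason %in% r, logical(1))
  new <- ifelse(has, cur, ifelse(cur == "", reason,
                                 paste(cur, reason, sep = ";")))
  data.table::set(calls, idx, "filter", new)
  invisible(calls)
}

#' Passing (PASS) subset of a variant table
#' @param calls Variant table.
#' @return Rows with an empty filter-reason set.
#' @export
pass_variants <- function(calls) calls[filter == ""]

#' Construct a structural-variant table
#'
#' @param chrom,start,end SV interval (1-based closed).
#' @param class One of deletion, duplication, transposition, inversion,
#'   complex.
#' @param pair_support Number of discordant read pairs supporting the SV.
#' @param depth_ratio Mean window depth over genome mean depth.
#' @param split_support Split-read (clipped alignment) support.
#' @return A `data.table` keyed by (chrom, start, end).
#' @export
sv_table <- function(chrom = character(), start = integer(), end = integer(),
                     class = character(), pair_support = integer(),
                     depth_ratio = numeric(), split_support = integer()) {
  if (length(split_support) == 0L && length(start) > 0L)
    split_support <- rep(0L, length(start))
  if (length(depth_ratio) == 0L && length(start) > 0L)
    depth_ratio <- rep(NA_real_, length(start))
  dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), class = as.character(class),
                   pair_support = as.integer(pair_support),
                   depth_ratio = as.numeric(depth_ratio),
                   split_support = as.integer(split_support))
  if (nrow(dt) && any(dt$start > dt$end)) stop("SV start must be <= end")
  if (nrow(dt) && any(dt$pair_support < 0L | dt$split_support < 0L))
    stop("support counts must be >= 0")
  setkey(dt, chrom, start, end)
  dt[]
}

#' Construct a tandem-repeat region table
#'
#' Regions with alignment score >= 10 and unit length <= 20 are marked
#' `active` (used by the read and indel filters); others are retained but
#' inactive. Units up to 24 bp are accepted from input.
#'
#' @param chrom,start,end Repeat interval (1-based closed).
#' @param unit_len Repeat unit length in bp.
#' @param copies Copy number (real).
#' @param score Alignment score from the repeat finder.
#' @param min_score,max_unit Activity thresholds.
#' @return A `data.table` keyed by (chrom, start, end) with an `active`
#'   flag column.
#' @export
repeat_table <- function(chrom = character(), start = integer(),
                         end = integer(), unit_len = integer(),
                         copies = numeric(), score = integer(),
                         min_score = 10L, max_unit = 20L) {
  dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), unit_len = as.integer(unit_len),
                   copies = as.numeric(copies), score = as.integer(score))
  if (nrow(dt)) {
    if (any(dt$unit_len < 1L)) stop("repeat unit length must be >= 1")
    if (any(dt$end - dt$start + 1L < dt$unit_len))
      stop("repeat region shorter than its unit")
  }
  dt[, active := score >= min_score & unit_len <= max_unit]
  setkey(dt, chrom, start, end)
  dt[]
}

#' Refinement configuration
#'
#' Bundles every tunable of the artifact filters. Defaults follow the
#' published procedure: four-fold depth threshold, 1% depth percentile
#' tails, central 99% allelic-ratio acceptance.
#'
#' @param sv_margin SV adjacency margin in bp (default 500, about one
#'   sequencing-library insert size).
#' @param depth_fold Fold-coverage threshold over the mean (default 4).
#' @param depth_tail Percentile tail fraction on each side (default 0.01).
#' @param ratio_percentile Central acceptance mass for heterozygous
#'   allelic ratios (default 0.99).
#' @param min_support Minimum alternative-allele supporting reads
#'   (default 3).
#' @return A list of class `refine_config`.
#' @export
refine_config <- function(sv_margin = 500L, depth_fold = 4,
                          depth_tail = 0.01, ratio_percentile = 0.99,
                          min_support = 3L) {
  stopifnot(depth_tail > 0, depth_tail < 0.5, depth_fold > 1,
            ratio_percentile > 0, ratio_percentile < 1, sv_margin >= 0)
  structure(list(sv_margin = as.integer(sv_margin),
                 depth_fold = as.numeric(depth_fold),
                 depth_tail = as.numeric(depth_tail),
                 ratio_percentile = as.numeric(ratio_percentile),
                 min_support = as.integer(min_support)),
            class = "refine_config")
}

## GRanges view of any (chrom, start, end) table
as_granges <- function(dt, start_col = "start", end_col = "end") {
  GRanges(dt$chrom, IRanges(dt[[start_col]], dt[[end_col]]))
}

## GRanges of variant positions (anchor base only)
variants_granges <- function(calls) GRanges(calls$chrom,
                                            IRanges(calls$pos, calls$pos))

phred <- function(p) -10 * log10(pmax(p, 1e-300))
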