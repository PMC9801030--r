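## Structural-variant signatures from paired-end distance/orientation,
## window depth, and split reads. Deliberately simple: refinement only
## needs reliable SV intervals, not breakpoint-precise genotyped calls.

#' Estimate the insert-size distribution from proper pairs
#'
#' @param aln Alignment table.
#' @param min_pairs Minimum proper pairs required (default 1000).
#' @return `list(mean, sd)`.
#' @export
estimate_insert <- function(aln, min_pairs = 1000L) {
  tl <- aln[aln_is_paired(flag) & tlen > 0L & rnext == chrom, tlen]
  ## trim the tails so discordant pairs do not poison the estimate
  qs <- quantile(tl, c(0.01, 0.99), names = FALSE)
  tl <- tl[tl >= qs[1] & tl <= qs[2]]
  if (length(tl) < min_pairs)
    stop("fewer than ", min_pairs,
         " proper pairs; supply insert_mean/insert_sd explicitly")
  list(mean = mean(tl), sd = stats::sd(tl))
}

#' Classify read pairs by distance and orientation signatures
#'
#' One row per pair (taken from the leftmost mate). Signatures:
#' `LONG` (template longer than mean + k.sd: deletion evidence), `SHORT`
#' (shorter than mean - k.sd: insertion evidence), `INVERTED` (same
#' strand mates), `DISTANT` (mates on different sequences or more than
#' 10x mean apart: transposition/translocation evidence), else `NORMAL`.
#' Unpaired reads are skipped.
#'
#' @param aln Alignment table.
#' @param insert_mean,insert_sd Library insert statistics; estimated with
#'   [estimate_insert()] when `NULL`.
#' @param k Discordance threshold in standard deviations (default 3).
#' @return data.table: chrom, pos, end (leftmost read), mate_pos,
#'   inner_start, inner_end (pair-implied interval), tlen, sig.
#' @export
classify_pairs <- function(aln, insert_mean = NULL, insert_sd = NULL,
                           k = 3) {
  pr <- aln[aln_is_paired(flag)]
  if (nrow(pr) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      end = integer(), mate_pos = integer(),
                      inner_start = integer(), inner_end = integer(),
                      tlen = integer(), sig = character()))
  if (is.null(insert_mean) || is.null(insert_sd)) {
    est <- estimate_insert(pr)
    insert_mean <- est$mean; insert_sd <- est$sd
  }
  ## leftmost mate of each pair carries the record
  left <- pr[pnext >= pos | rnext != chrom]
  left <- left[!duplicated(qname)]
  rl <- nchar(left$seq)
  rl[rl == 0L | is.na(rl)] <- left[rl == 0L | is.na(rl),
                                   end - pos + 1L]
  left[, `:=`(mate_pos = pnext,
              inner_start = end + 1L,
              inner_end = pnext - 1L)]
  dist <- abs(left$pnext - left$pos)
  same_strand <- aln_strand(left$flag) == aln_mate_strand(left$flag)
  sig <- rep("NORMAL", nrow(left))
  atl <- abs(left$tlen)
  sig[atl > insert_mean + k * insert_sd] <- "LONG"
  sig[atl < insert_mean - k * insert_sd & atl > 0L] <- "SHORT"
  sig[same_strand] <- "INVERTED"
  sig[left$rnext != left$chrom | dist > 10 * insert_mean] <- "DISTANT"
  left[, sig := sig]
  left[, .(chrom, pos, end, mate_pos, inner_start, inner_end, tlen, sig,
           qname)]
}

## connected components of overlapping intervals (single chrom)
overlap_components <- function(start, end) {
  o <- order(start, end)
  comp <- integer(length(start))
  cur <- 0L; reach <- -Inf
  for (i in o) {
    if (start[i] > reach) cur <- cur + 1L
    comp[i] <- cur
    reach <- max(reach, end[i])
  }
  comp
}

#' Cluster discordant-pair signatures into structural variants
#'
#' Same-signature pairs with overlapping implied intervals merge into one
#' SV; the breakpoint interval is the intersection of the pair-implied
#' intervals (union for INVERTED/DISTANT, whose implied intervals bracket
#' the event from both sides). Clusters below `min_support` are dropped.
#' Deletion clusters whose interior reads have DISTANT mates anchored at
#' one remote locus are re-labelled transpositions; loci supported by
#' two or more distinct signature classes are labelled complex.
#'
#' @param pairs Output of [classify_pairs()].
#' @param min_support Minimum supporting pairs (default 3).
#' @param max_sv_len Discard implied intervals longer than this
#'   (default 1e6; guards against stray inter-chromosomal noise).
#' @return [sv_table()].
#' @export
cluster_signatures <- function(pairs, min_support = 3L, max_sv_len = 1e6) {
  disc <- pairs[sig != "NORMAL"]
  if (nrow(disc) == 0L) return(sv_table())
  class_of <- c(LONG = "deletion", SHORT = "insertion",
                INVERTED = "inversion", DISTANT = "transposition")
  out <- list()
  for (sg in unique(disc$sig)) {
    dd <- disc[sig == sg]
    if (sg == "INVERTED") {
      ## cluster by full pair span; event interval = union of inner
      dd[, `:=`(cs = pos, ce = pmax(mate_pos + (end - pos), end))]
      dd <- dd[ce - cs <= max_sv_len]
    } else if (sg == "DISTANT") {
      ## only the local read cluster is evidence; the remote anchor is
      ## kept on the pair record for the transposition rule
      dd[, `:=`(cs = pos, ce = end, inner_start = pos, inner_end = end)]
    } else {
      dd[, `:=`(cs = inner_start, ce = inner_end)]
      dd <- dd[ce - cs >= 0L & ce - cs <= max_sv_len]
    }
    if (nrow(dd) == 0L) next
    for (ch in unique(dd$chrom)) {
      d1 <- dd[chrom == ch]
      comp <- overlap_components(d1$cs, d1$ce)
      if (sg %in% c("INVERTED", "DISTANT")) {
        cl <- d1[, .(n = .N, istart = min(inner_start),
                     iend = max(inner_end)), by = .(comp = comp)]
      } else {
        ## consensus core: stray same-signature pairs can share a
        ## component without sharing a breakpoint; intersect only the
        ## pairs covering the component's most-covered position
        cl <- d1[, {
          ev <- data.table(x = c(inner_start, inner_end + 1L),
                           d = rep(c(1L, -1L), each = .N))
          setorder(ev, x, -d)
          peak_x <- ev$x[which.max(cumsum(ev$d))]
          keep <- inner_start <= peak_x & inner_end >= peak_x
          .(n = sum(keep), istart = max(inner_start[keep]),
            iend = min(inner_end[keep]))
        }, by = .(comp = comp)]
      }
      cl <- cl[n >= min_support & iend >= istart]
      if (nrow(cl) == 0L) next
      out[[paste(sg, ch)]] <- data.table(chrom = ch, start = cl$istart,
                                         end = cl$iend,
                                         class = class_of[[sg]],
                                         pair_support = cl$n)
    }
  }
  if (!length(out)) return(sv_table())
  svs <- rbindlist(out)

  ## transposition refinement: a deletion whose interior reads carry
  ## DISTANT mates anchored at one remote locus is a transposed element;
  ## the DISTANT cluster is the same event, not a separate SV
  del <- which(svs$class == "deletion")
  dist_pairs <- pairs[sig == "DISTANT"]
  drop_distant <- integer()
  for (i in del) {
    inside <- dist_pairs[chrom == svs$chrom[i] & pos >= svs$start[i] -
                           200L & pos <= svs$end[i] + 200L]
    if (nrow(inside) >= 2L &&
        diff(range(inside$mate_pos)) <= 2000L) {
      svs[i, class := "transposition"]
      dcl <- which(svs$class == "transposition" &
                     svs$chrom == svs$chrom[i] & seq_len(nrow(svs)) != i &
                     svs$start >= svs$start[i] - 200L &
                     svs$end <= svs$end[i] + 200L)
      drop_distant <- c(drop_distant, dcl)
    }
  }
  if (length(drop_distant)) svs <- svs[-unique(drop_distant)]

  ## >= 2 distinct signature classes at one locus -> complex
  gr <- as_granges(svs)
  ov <- findOverlaps(gr, gr)
  ov <- ov[queryHits(ov) < subjectHits(ov)]
  if (length(ov)) {
    qh <- queryHits(ov); sh <- subjectHits(ov)
    mixed <- which(svs$class[qh] != svs$class[sh] &
                     !(svs$class[qh] == "transposition" &
                         svs$class[sh] == "transposition"))
    if (length(mixed)) {
      grp_ids <- unique(c(qh[mixed], sh[mixed]))
      comp <- overlap_components(svs$start[grp_ids], svs$end[grp_ids])
      merged <- data.table(start = svs$start[grp_ids],
                           end = svs$end[grp_ids],
                           chrom = svs$chrom[grp_ids],
                           n = svs$pair_support[grp_ids],
                           comp = comp)[, .(
                             start = min(start), end = max(end),
                             pair_support = sum(n), chrom = chrom[1]),
                             by = comp]
      svs <- svs[-grp_ids]
      svs <- rbind(svs, merged[, .(chrom, start, end, class = "complex",
                                   pair_support)], fill = TRUE)
    }
  }
  sv_table(svs$chrom, svs$start, svs$end, svs$class, svs$pair_support)
}

#' Per-window read depth track
#'
#' @param aln Alignment table (apply [filter_reads()] first so only
#'   mapq-passing reads count).
#' @param gi `genome_index`.
#' @param window Window size in bp (default 500).
#' @return data.table: chrom, start, end, depth (mean per-bp coverage).
#' @export
depth_track <- function(aln, gi, window = 500L) {
  out <- list()
  for (ch in names(gi$lengths)) {
    len <- genome_length(gi, ch)
    a <- aln[chrom == ch]
    cov <- coverage(IRanges(a$pos, pmin(a$end, len)), width = len)
    starts <- seq(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    v <- Views(cov, starts, ends)
    out[[ch]] <- data.table(chrom = ch, start = starts, end = ends,
                            depth = viewMeans(v))
  }
  rbindlist(out)
}

#' Detect copy-number variants from the depth track
#'
#' Runs of windows at >= `dup_fold` times the genome mean become
#' duplications; runs at <= `del_fold` times the mean become
#' depth-supported deletions. Runs are seeded at those thresholds and
#' extended through adjacent windows passing a weaker one
#' (`dup_extend`/`del_extend`): event edges only partially cover a
#' window, so without hysteresis the reported interval is truncated by
#' up to a window on each side.
#'
#' @param track Output of [depth_track()].
#' @param mean_depth Genome mean depth (must be > 0).
#' @param dup_fold,del_fold Seed thresholds (defaults 2 and 0.25).
#' @param dup_extend,del_extend Extension thresholds (defaults 1.5 and
#'   0.5).
#' @return [sv_table()] with `depth_ratio` filled in.
#' @export
detect_cnv_by_depth <- function(track, mean_depth, dup_fold = 2,
                                del_fold = 0.25, dup_extend = 1.5,
                                del_extend = 0.5) {
  if (is.na(mean_depth) || mean_depth <= 0)
    stop("mean depth must be positive")
  out <- list()
  for (cls in c("duplication", "deletion")) {
    if (cls == "duplication") {
      core <- track$depth >= dup_fold * mean_depth
      weak <- track$depth >= dup_extend * mean_depth
    } else {
      core <- track$depth <= del_fold * mean_depth
      weak <- track$depth <= del_extend * mean_depth
    }
    if (!any(core)) next
    tt <- track[weak][, core := core[weak]]
    for (ch in unique(tt$chrom)) {
      t1 <- tt[chrom == ch]
      comp <- overlap_components(t1$start, t1$end + 1L)  # adjacency
      cl <- t1[, .(start = min(start), end = max(end),
                   depth = mean(depth), has_core = any(core)),
               by = .(comp = comp)][has_core == TRUE]
      if (nrow(cl) == 0L) next
      out[[paste(cls, ch)]] <- data.table(
        chrom = ch, start = cl$start, end = cl$end, class = cls,
        pair_support = 0L, depth_ratio = cl$depth / mean_depth)
    }
  }
  if (!length(out)) return(sv_table())
  res <- rbindlist(out)
  sv_table(res$chrom, res$start, res$end, res$class, res$pair_support,
           res$depth_ratio)
}

#' Count split-read (soft-clip) support near SV edges
#'
#' Clipped alignments with >= `min_clip` clipped bases whose clip point
#' falls within `margin` of an SV boundary sharpen the breakpoint
#' support count; they are corroborating evidence only, never required.
#'
#' @param svs SV table.
#' @param aln Alignment table.
#' @param min_clip Minimum clipped bases (default 20).
#' @param margin Distance from the SV edge (default 50 bp).
#' @return The SV table with `split_support` filled.
#' @export
add_split_support <- function(svs, aln, min_clip = 20L, margin = 50L) {
  if (nrow(svs) == 0L) return(svs)
  cl <- aln[grepl("S", cigar)]
  if (nrow(cl) == 0L) return(svs)
  ops <- explodeCigarOps(cl$cigar)
  lens <- explodeCigarOpLengths(cl$cigar)
  nclip <- mapply(function(o, l) max(c(0L, l[o == "S"])), ops, lens)
  ## clip point: end of aligned part (right clip) or pos (left clip)
  right_clip <- vapply(ops, function(o) o[length(o)] == "S", logical(1))
  cp <- ifelse(right_clip, cl$end, cl$pos)
  cl <- cl[nclip >= min_clip]
  cp <- cp[nclip >= min_clip]
  if (nrow(cl) == 0L) return(svs)
  for (i in seq_len(nrow(svs))) {
    n <- sum(cl$chrom == svs$chrom[i] &
               (abs(cp - svs$start[i]) <= margin |
                  abs(cp - svs$end[i]) <= margin))
    svs[i, split_support := n]
  }
  svs[]
}

#' Full SV detection from alignments
#'
#' Pair-signature clustering plus depth CNVs, with split-read support
#' annotation; intervals are clipped to the sequence bounds and
#' same-class overlapping calls merged.
#'
#' @param aln Alignment table (mapq-filtered internally).
#' @param gi `genome_index`.
#' @param insert_mean,insert_sd Optional insert statistics.
#' @param min_support Minimum pair support (default 3).
#' @param min_mapq Mapping-quality floor (default 20).
#' @param window CNV window in bp (default 500).
#' @return [sv_table()].
#' @export
detect_svs <- function(aln, gi, insert_mean = NULL, insert_sd = NULL,
                       min_support = 3L, min_mapq = 20L, window = 500L) {
  aln <- aln[!is.na(mapq) & mapq >= min_mapq]
  pairs <- classify_pairs(aln, insert_mean, insert_sd)
  svs <- cluster_signatures(pairs, min_support = min_support)
  trk <- depth_track(aln, gi, window = window)
  ## median baseline: the genome mean is inflated by the very CNVs being
  ## detected, which would push a clean 2x collapse under the threshold
  md <- stats::median(trk$depth)
  cnv <- detect_cnv_by_depth(trk, md)
  all <- rbind(svs, cnv)
  if (nrow(all) == 0L) return(all)
  ## clip to bounds, merge same-class overlaps
  all[, `:=`(start = pmax(start, 1L)) ]
  for (ch in unique(all$chrom))
    all[chrom == ch, end := pmin(end, genome_length(gi, ch))]
  merged <- list()
  for (cls in unique(all$class)) for (ch in unique(all$chrom)) {
    a1 <- all[class == cls & chrom == ch]
    if (nrow(a1) == 0L) next
    comp <- overlap_components(a1$start, a1$end)
    merged[[paste(cls, ch)]] <- a1[, .(
      chrom = ch, start = min(start), end = max(end), class = cls,
      pair_support = sum(pair_support),
      depth_ratio = mean(depth_ratio, na.rm = TRUE),
      split_support = sum(split_support)), by = .(comp = comp)][, -1]
  }
  res <- rbindlist(merged)
  res <- sv_table(res$chrom, res$start, res$end, res$class,
                  res$pair_support, res$depth_ratio, res$split_support)
  add_split_support(res, aln)
}
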