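## Sliding-window genotyping of a meiotic progeny against refined
## parental markers, crossover detection at block junctions, and
## gene-conversion detection from markers contradicting their block.
##
## Ratio conventions follow the published definitions exactly:
##   per-SNP    Ratio_s = Msupp / (Psupp + Msupp)
##   per-window Ratio_w = sum(P_i) / sum(P_i + M_i)
## so G_w >= 0.8 is paternal-homozygous and <= 0.2 maternal-homozygous.

#' Empirical window size for progeny genotyping
#'
#' `(2e3 / depth) * (genome_size / snp_number)`, rounded to the nearest
#' kb and floored at 1 kb. For 20x coverage of a 100 Mb genome with one
#' SNP per 200 bp this gives 20 kb.
#'
#' @param depth Sequencing depth (fold coverage).
#' @param genome_size Genome size in bp.
#' @param snp_number Number of markers.
#' @return Window size in bp.
#' @examples
#' window_size(20, 1e8, 5e5)   # 20000
#' @export
window_size <- function(depth, genome_size, snp_number) {
  if (any(c(depth, genome_size, snp_number) <= 0))
    stop("all arguments must be positive")
  ws <- (2e3 / depth) * (genome_size / snp_number)
  max(1000, round(ws / 1000) * 1000)
}

#' Designate parental alleles on a refined marker set
#'
#' The reference genome need not be a parent; this constructor simply
#' declares which allele of each marker belongs to which parent. With
#' `paternal = "ref"` (the usual case when the paternal line is the
#' reference ecotype) the reference allele is paternal.
#'
#' @param calls Refined variant table (PASS rows are kept).
#' @param paternal `"ref"` or `"alt"`.
#' @return Marker table: chrom, pos, ref, alt, class, p_allele,
#'   m_allele.
#' @export
marker_set <- function(calls, paternal = c("ref", "alt")) {
  paternal <- match.arg(paternal)
  mk <- pass_variants(calls)[, .(chrom, pos, ref, alt, class)]
  if (paternal == "ref") mk[, `:=`(p_allele = ref, m_allele = alt)]
  else mk[, `:=`(p_allele = alt, m_allele = ref)]
  setkey(mk, chrom, pos)
  mk[]
}

#' Genotype progeny reads at marker loci
#'
#' Each mapq-passing read overlapping a marker contributes to the
#' paternal or maternal support according to the base it carries there;
#' other bases are ignored. SNP markers use the aligned base; indel
#' markers use gapped-alignment evidence (reads spanning the site
#' without the gap support the reference-like allele).
#'
#' @param aln Progeny alignment table.
#' @param markers [marker_set()].
#' @param min_mapq Mapping-quality floor (default 20).
#' @param repeats Optional repeats; reads not spanning a repeat are
#'   excluded from indel-marker evidence.
#' @return Observations: chrom, pos, p_supp, m_supp, ratio_s
#'   (= M/(P+M), `NA` when uncovered).
#' @export
genotype_markers <- function(aln, markers, min_mapq = 20L,
                             repeats = NULL) {
  ## slim projection: full alignment tables can be huge (pooled runs)
  aln <- filter_reads(aln[, .(chrom, pos, end, mapq, cigar, seq, qual)],
                      repeats, min_mapq)
  obs <- list()
  snp <- markers[class == "SNP"]
  is_simple <- grepl("^\\d+M$", aln$cigar)
  pile_cx <- if (any(!is_simple))
    pileup_observations(aln[!is_simple], gi = NULL) else NULL
  if (nrow(snp)) {
    ## fast path: gapless reads, base by string offset
    sidx <- which(is_simple)
    bt <- list()
    if (length(sidx)) {
      q <- snp[, .(chrom, start = pos, end = pos, mid = seq_len(nrow(snp)))]
      r <- data.table(chrom = aln$chrom[sidx], start = aln$pos[sidx],
                      end = aln$end[sidx], rid = sidx)
      setkey(r, chrom, start, end)
      hits <- foverlaps(q, r, by.x = c("chrom", "start", "end"),
                        type = "within", nomatch = NULL)
      if (nrow(hits)) {
        off <- hits$i.start - hits$start + 1L
        bt$simple <- data.table(mid = hits$mid,
                                base = substr(aln$seq[hits$rid],
                                              off, off))
      }
      rm(r, hits)
    }
    if (!is.null(pile_cx) && nrow(pile_cx$bases)) {
      mb <- pile_cx$bases[snp[, .(chrom, pos,
                                  mid = seq_len(nrow(snp)))],
                          on = .(chrom, pos), nomatch = NULL]
      if (nrow(mb)) bt$cx <- mb[, .(mid, base)]
    }
    if (length(bt)) {
      allb <- rbindlist(bt)
      cnt <- allb[, .(p_supp = sum(base == snp$p_allele[mid[1]]),
                      m_supp = sum(base == snp$m_allele[mid[1]])),
                  by = .(mid)]
      obs$snp <- data.table(chrom = snp$chrom[cnt$mid],
                            pos = snp$pos[cnt$mid],
                            p_supp = cnt$p_supp, m_supp = cnt$m_supp)
    }
  }
  ## indel markers: gapped observations vs gapless spanning reads
  ind <- markers[class %in% c("insertion", "deletion")]
  if (nrow(ind)) {
    pile <- pileup_observations(aln, gi = NULL)
    for (i in seq_len(nrow(ind))) {
      k <- abs(nchar(ind$ref[i]) - nchar(ind$alt[i]))
      supp <- pile$indels[chrom == ind$chrom[i] & pos == ind$pos[i] &
                            type == ind$class[i] & len == k & !nonspan]
      thru <- pile$bases[chrom == ind$chrom[i] & pos == ind$pos[i] + 1L &
                           !nonspan & !(read %in% supp$read)]
      ## the indel allele (alt) belongs to whichever parent was assigned
      ## the alt allele in marker_set()
      alt_is_m <- ind$m_allele[i] == ind$alt[i]
      obs[[paste0("ind", i)]] <- data.table(
        chrom = ind$chrom[i], pos = ind$pos[i],
        p_supp = if (alt_is_m) nrow(thru) else nrow(supp),
        m_supp = if (alt_is_m) nrow(supp) else nrow(thru))
    }
  }
  res <- if (length(obs)) rbindlist(obs) else
    data.table(chrom = character(), pos = integer(), p_supp = integer(),
               m_supp = integer())
  full <- merge(markers[, .(chrom, pos)], res, by = c("chrom", "pos"),
                all.x = TRUE)
  full[is.na(p_supp), `:=`(p_supp = 0L, m_supp = 0L)]
  full[, ratio_s := fifelse(p_supp + m_supp > 0L,
                            m_supp / (p_supp + m_supp), NA_real_)]
  setkey(full, chrom, pos)
  full[]
}

#' Window genotype calls from marker observations
#'
#' Windows are anchored at position 1 on a fixed grid per chromosome
#' (trailing partial window included). `Ratio_w = sum(P)/sum(P+M)`;
#' genotype thresholds: >= 0.8 paternal-hom, <= 0.2 maternal-hom, else
#' het; windows with fewer informative markers than `min_markers` are
#' uncalled.
#'
#' @param obs Output of [genotype_markers()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window,step Window size and step in bp (window >= step).
#' @param min_markers Minimum informative markers per window (default 5).
#' @return Window table: chrom, start, end, p_sum, m_sum, n_markers,
#'   ratio_w, genotype (`"uncalled"` allowed).
#' @export
call_windows <- function(obs, chrom_lengths, window = 20000L,
                         step = 10000L, min_markers = 5L) {
  stopifnot(window >= step)
  window <- as.integer(window); step <- as.integer(step)
  out <- list()
  inf <- obs[p_supp + m_supp > 0L]
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(1L, max(1L, len), by = step)
    ## drop grid starts beyond the sequence; keep the trailing partial
    starts <- starts[starts <= len]
    ends <- pmin(starts + window - 1L, len)
    grid <- data.table(chrom = ch, start = starts, end = ends)
    o <- inf[chrom == ch]
    if (nrow(o)) {
      setkey(grid, chrom, start, end)
      oo <- o[, .(chrom, start = pos, end = pos, p_supp, m_supp)]
      hits <- foverlaps(oo, grid, by.x = c("chrom", "start", "end"),
                        type = "within", nomatch = NULL)
      agg <- hits[, .(p_sum = sum(p_supp), m_sum = sum(m_supp),
                      n_markers = .N), by = .(start, end)]
      grid <- merge(grid, agg, by = c("start", "end"), all.x = TRUE)
    } else {
      grid[, `:=`(p_sum = NA_integer_, m_sum = NA_integer_,
                  n_markers = NA_integer_)]
    }
    out[[ch]] <- grid
  }
  win <- rbindlist(out, use.names = TRUE)
  win[is.na(n_markers), `:=`(p_sum = 0L, m_sum = 0L, n_markers = 0L)]
  win[, ratio_w := fifelse(p_sum + m_sum > 0L,
                           p_sum / (p_sum + m_sum), NA_real_)]
  win[, genotype := fifelse(
    n_markers < min_markers | is.na(ratio_w), "uncalled",
    fifelse(ratio_w >= 0.8, "paternal-hom",
            fifelse(ratio_w <= 0.2, "maternal-hom", "het")))]
  setkey(win, chrom, start)
  win[, .(chrom, start, end, p_sum, m_sum, n_markers, ratio_w, genotype)]
}

## marker consistency with a block genotype, by Ratio_s
marker_consistent <- function(ratio_s, genotype) {
  switch(genotype,
         "paternal-hom" = ratio_s <= 0.2,
         "maternal-hom" = ratio_s >= 0.8,
         "het" = ratio_s > 0.2 & ratio_s < 0.8,
         rep(FALSE, length(ratio_s)))
}

#' Merge same-genotype windows into blocks and call crossovers
#'
#' Maximal runs of equal window genotype become blocks; uncalled windows
#' are absorbed into the surrounding run. Each block junction yields a
#' crossover whose boundary interval is refined by scanning the flanking
#' markers: (position of the last marker consistent with the left
#' genotype, position of the first marker consistent with the right
#' genotype). Junctions without informative markers within
#' `max_scan` bp are reported as the inter-window gap with a
#' low-resolution flag.
#'
#' @param windows Output of [call_windows()].
#' @param obs Marker observations (for boundary refinement); optional.
#' @param min_reads Minimum reads for a marker to inform the scan
#'   (default 3).
#' @param max_scan Scan radius around the junction (default 50000 bp).
#' @return `list(blocks = , crossovers = )`.
#' @export
merge_blocks <- function(windows, obs = NULL, min_reads = 3L,
                         max_scan = 50000L) {
  blocks <- list(); cos <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[chrom == ch][order(start)]
    called <- w[genotype != "uncalled"]
    if (nrow(called) == 0L) next
    r <- rle(called$genotype)
    nb <- length(r$values)
    ends_i <- cumsum(r$lengths)
    starts_i <- c(1L, head(ends_i, -1L) + 1L)
    bl <- data.table(chrom = ch,
                     start = called$start[starts_i],
                     end = called$end[ends_i],
                     genotype = r$values)
    ## absorb leading/trailing uncalled grid space
    bl$start[1] <- min(w$start)
    bl$end[nrow(bl)] <- max(w$end)
    blocks[[ch]] <- bl
    if (nb < 2L) next
    for (j in seq_len(nb - 1L)) {
      lg <- r$values[j]; rg <- r$values[j + 1L]
      ## junction gap between the last left window and first right one
      gap_lo <- called$start[ends_i[j]]
      gap_hi <- called$end[starts_i[j + 1L]]
      left_bound <- NA_integer_; right_bound <- NA_integer_
      lowres <- TRUE
      if (!is.null(obs)) {
        sc <- obs[chrom == ch & pos >= gap_lo - max_scan &
                    pos <= gap_hi + max_scan &
                    p_supp + m_supp >= min_reads][order(pos)]
        if (nrow(sc)) {
          lcon <- marker_consistent(sc$ratio_s, lg)
          rcon <- marker_consistent(sc$ratio_s, rg)
          ## first right-consistent run of two markers
          rstart <- which(rcon & c(rcon[-1], FALSE))
          rstart <- rstart[rstart > which.max(lcon)]
          if (length(rstart)) {
            fi <- rstart[1]
            lprev <- which(lcon & seq_along(lcon) < fi)
            if (length(lprev)) {
              left_bound <- sc$pos[max(lprev)]
              right_bound <- sc$pos[fi]
              lowres <- FALSE
            }
          }
        }
      }
      if (lowres) { left_bound <- gap_lo; right_bound <- gap_hi }
      if (right_bound <= left_bound) right_bound <- left_bound + 1L
      cos[[paste(ch, j)]] <- data.table(
        chrom = ch, left = as.integer(left_bound),
        right = as.integer(right_bound), left_genotype = lg,
        right_genotype = rg, low_resolution = lowres)
    }
  }
  list(blocks = if (length(blocks)) rbindlist(blocks) else
         data.table(chrom = character(), start = integer(),
                    end = integer(), genotype = character()),
       crossovers = if (length(cos)) rbindlist(cos) else
         data.table(chrom = character(), left = integer(),
                    right = integer(), left_genotype = character(),
                    right_genotype = character(),
                    low_resolution = logical()))
}

#' Detect gene-conversion events
#'
#' Inside homozygous blocks (crossover-junction neighbourhoods of +- one
#' window excluded), a marker with at least `min_reads` informative
#' reads whose `Ratio_s` contradicts the block is a converted marker:
#' fully converted when on the far side (>= 0.8 toward the other
#' parent), het-converted when in the central band. Converted markers
#' closer than `max_gap` bp group into one event.
#'
#' @param obs Marker observations.
#' @param blocks Blocks from [merge_blocks()].
#' @param min_reads Support floor (default 5).
#' @param max_gap Grouping distance (default 1000 bp).
#' @param window Junction exclusion radius (default 20000 bp).
#' @param het_background Also scan heterozygous blocks for
#'   homozygous-converted markers (default `FALSE`).
#' @return Event table: chrom, start, end, span, n_markers, positions
#'   (list), background, converted_to.
#' @export
detect_gc <- function(obs, blocks, min_reads = 5L, max_gap = 1000L,
                      window = 20000L, het_background = FALSE) {
  ev <- list()
  scan_blocks <- blocks[genotype %in%
                          c("paternal-hom", "maternal-hom",
                            if (het_background) "het")]
  for (i in seq_len(nrow(scan_blocks))) {
    b <- scan_blocks[i]
    ## stay clear of block edges (CO junction neighbourhoods)
    lo <- b$start + window; hi <- b$end - window
    if (hi <= lo) next
    o <- obs[chrom == b$chrom & pos >= lo & pos <= hi &
               p_supp + m_supp >= min_reads][order(pos)]
    if (nrow(o) == 0L) next
    if (b$genotype == "paternal-hom") {
      conv_full <- o$ratio_s >= 0.8
      conv_het <- o$ratio_s > 0.2 & o$ratio_s < 0.8
      full_lab <- "maternal-hom"
    } else if (b$genotype == "maternal-hom") {
      conv_full <- o$ratio_s <= 0.2
      conv_het <- o$ratio_s > 0.2 & o$ratio_s < 0.8
      full_lab <- "paternal-hom"
    } else {
      conv_full <- o$ratio_s >= 0.8 | o$ratio_s <= 0.2
      conv_het <- rep(FALSE, nrow(o))
      full_lab <- "hom"
    }
    conv <- conv_full | conv_het
    if (!any(conv)) next
    cm <- o[conv]
    cm[, kind := fifelse(conv_full[conv], full_lab, "het")]
    grp <- cumsum(c(1L, diff(cm$pos) >= max_gap))
    g <- cm[, .(start = min(pos), end = max(pos), n_markers = .N,
                positions = list(pos),
                converted_to = names(sort(table(kind),
                                          decreasing = TRUE))[1]),
            by = .(grp = grp)]
    g[, `:=`(chrom = b$chrom, background = b$genotype,
             span = end - start + 1L)]
    ev[[length(ev) + 1L]] <- g[, .(chrom, start, end, span, n_markers,
                                   positions, background, converted_to)]
  }
  if (!length(ev))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), span = integer(),
                      n_markers = integer(), positions = list(),
                      background = character(),
                      converted_to = character()))
  rbindlist(ev)
}
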