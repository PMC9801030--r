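## Ground-truth simulator. Builds two parental haplotypes (the reference
## plus a diverged alternate), synthesizes alignments directly -- no
## external aligner -- so artifact geometry is exactly controlled:
##   * deletions in the alternate genome yield LONG read pairs at the
##     junction plus (optionally) mis-mapped paralogous reads inside the
##     deleted reference interval carrying divergent bases;
##   * collapsed duplications stack reads of both alternate copies onto
##     the single reference locus (2x depth, divergent sites look het);
##   * tandem-repeat unit losses produce spanning reads with a gapped
##     CIGAR and repeat-terminating reads that align gaplessly, faking a
##     heterozygous indel.
## All generators are pure functions of (spec, seed).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1))
}

#' Simulate a pair of parental haplotypes with ground truth
#'
#' The reference sequence plays the first (paternal) parent; the
#' alternate haplotype diverges by SNPs, small deletions, tandem-repeat
#' unit changes, and large-scale SVs. Divergent sites of non-allelic SV
#' copies (the future artificial variants) are chosen here so that read
#' synthesis is deterministic.
#'
#' @param length Chromosome length in bp.
#' @param chrom Sequence name.
#' @param snp_rate Per-bp probability of a parental SNP.
#' @param indel_rate Per-bp probability of a small (1-3 bp) deletion.
#' @param sv_spec List of SV descriptors:
#'   `list(class = "deletion"|"duplication"|"inversion"|"insertion",
#'   pos =, len =, divergence = n, paralog = TRUE/FALSE,
#'   true_snp = TRUE/FALSE)`. `divergence` sets the number of divergent
#'   sites carried by the non-allelic copy (deletion paralog or second
#'   duplication copy).
#' @param repeat_spec List of tandem-repeat descriptors:
#'   `list(pos =, unit = "AG", copies = 10, alt_copy_delta = -1)`;
#'   a negative `alt_copy_delta` deletes units from the alternate
#'   haplotype.
#' @param seed Integer seed; identical inputs give identical output.
#' @return An object of class `sim_parents`: `gi` (reference
#'   [genome_index()]), `ref`/`alt` haplotype strings (`alt` carries SNPs
#'   only; indels and SVs are realized at read level), and `truth`
#'   (tables `snps`, `indels`, `svs`, `repeats`, `artificial`).
#' @export
make_parents <- function(length = 1e6L, chrom = "chr1", snp_rate = 1 / 200,
                         indel_rate = 0, sv_spec = list(),
                         repeat_spec = list(), seed = 1L) {
  stopifnot(length > 0, snp_rate >= 0, snp_rate < 1, indel_rate >= 0,
            indel_rate < 1)
  with_seed(seed, {
    L <- as.integer(length)
    refv <- rand_dna(L)

    ## tandem repeats are written into the reference itself
    reps <- rbindlist(lapply(repeat_spec, function(r) {
      unit <- toupper(r$unit)
      n <- nchar(unit) * r$copies
      s <- as.integer(r$pos); e <- s + as.integer(n) - 1L
      stopifnot(s >= 1, e <= L)
      refv[s:e] <<- strsplit(strrep(unit, r$copies), "")[[1]]
      data.table(chrom = chrom, start = s, end = e,
                 unit_len = nchar(unit), copies = as.numeric(r$copies),
                 score = 2L * as.integer(n),
                 alt_copy_delta = as.integer(r$alt_copy_delta %||% 0L),
                 unit = unit)
    }))
    if (nrow(reps) == 0L)
      reps <- data.table(chrom = character(), start = integer(),
                         end = integer(), unit_len = integer(),
                         copies = numeric(), score = integer(),
                         alt_copy_delta = integer(), unit = character())

    ## large-scale SVs; overlapping placements are a contract error
    svs <- rbindlist(lapply(sv_spec, function(s)
      data.table(chrom = chrom, start = as.integer(s$pos),
                 end = as.integer(s$pos + (s$len %||% 0L) - 1L),
                 class = s$class, len = as.integer(s$len %||% 0L),
                 divergence = as.integer(s$divergence %||% 0L),
                 paralog = isTRUE(s$paralog),
                 true_snp = isTRUE(s$true_snp))))
    if (nrow(svs)) {
      if (any(svs$start < 1L | svs$end > L)) stop("SV outside the sequence")
      o <- order(svs$start)
      if (nrow(svs) > 1L &&
          any(svs$start[o][-1] <= svs$end[o][-nrow(svs)] + 1000L))
        stop("overlapping (or nearly overlapping) SV placements")
    } else {
      svs <- data.table(chrom = character(), start = integer(),
                        end = integer(), class = character(),
                        len = integer(), divergence = integer(),
                        paralog = logical(), true_snp = logical())
    }

    ## exclusion mask for random small variants: SV bodies, repeats
    excl <- rep(FALSE, L)
    mask <- function(s, e) {
      s <- pmax(1L, s); e <- pmin(L, e)
      for (i in seq_along(s)) excl[s[i]:e[i]] <<- TRUE
    }
    if (nrow(svs)) mask(svs$start - 20L, svs$end + 20L)
    if (nrow(reps)) mask(reps$start - 20L, reps$end + 20L)
    mask(1L, 210L); mask(L - 210L, L)   # keep chromosome ends quiet

    snp_pos <- which(runif(L) < snp_rate & !excl)
    snp_alt <- other_base(refv[snp_pos])
    snps <- data.table(chrom = chrom, pos = snp_pos, ref = refv[snp_pos],
                       alt = snp_alt)

    ## duplications may carry one designated true SNP inside the interval
    for (i in seq_len(nrow(svs))) {
      if (svs$class[i] == "duplication" && svs$true_snp[i]) {
        p <- as.integer((svs$start[i] + svs$end[i]) / 2)
        snps <- rbind(snps, data.table(chrom = chrom, pos = p,
                                       ref = refv[p],
                                       alt = other_base(refv[p])))
      }
    }
    setorder(snps, pos)

    ## small deletions (1-3 bp), kept clear of SNPs and each other
    ind_pos <- which(runif(L) < indel_rate & !excl)
    ind_pos <- ind_pos[!ind_pos %in% outer(snp_pos, -12:12, "+")]
    if (length(ind_pos) > 1L)
      ind_pos <- ind_pos[c(TRUE, diff(ind_pos) > 50L)]
    ind_len <- if (length(ind_pos)) sample(1:3, length(ind_pos), TRUE)
               else integer()
    indels <- data.table(chrom = rep(chrom, length(ind_pos)),
                         pos = ind_pos, len = ind_len,
                         in_repeat = rep(FALSE, length(ind_pos)),
                         unit_len = rep(NA_integer_, length(ind_pos)))
    ## repeat unit losses are indels anchored just before the lost units
    for (i in seq_len(nrow(reps))) {
      d <- reps$alt_copy_delta[i]
      if (d < 0L) {
        k <- -d * reps$unit_len[i]
        indels <- rbind(indels,
          data.table(chrom = chrom, pos = reps$start[i] - 1L, len = k,
                     in_repeat = TRUE, unit_len = reps$unit_len[i]))
      }
    }
    setorder(indels, pos)
    ## VCF-style truth for indels: anchor base + deleted sequence
    indels[, ref := vapply(seq_len(.N), function(i)
      paste(refv[indels$pos[i]:(indels$pos[i] + indels$len[i])],
            collapse = ""), character(1))]
    indels[, alt := substr(ref, 1L, 1L)]

    ## divergent sites of non-allelic copies = future artificial variants
    art <- list()
    for (i in seq_len(nrow(svs))) {
      nd <- svs$divergence[i]
      if (nd > 0L && svs$class[i] %in% c("deletion", "duplication")) {
        lo <- svs$start[i] + 30L; hi <- svs$end[i] - 30L
        p <- sort(sample(seq(lo, hi), nd))
        ## keep clear of the duplication's true allelic SNP
        p <- p[!p %in% snps$pos]
        art[[length(art) + 1L]] <-
          data.table(chrom = chrom, pos = p, ref = refv[p],
                     alt = other_base(refv[p]),
                     source = if (svs$class[i] == "deletion") "paralog_del"
                              else "dup_collapse",
                     sv_start = svs$start[i], sv_end = svs$end[i])
      }
    }
    art <- if (length(art)) rbindlist(art) else
      data.table(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), source = character(),
                 sv_start = integer(), sv_end = integer())

    altv <- refv
    altv[snps$pos] <- snps$alt
    ref <- paste(refv, collapse = "")
    alt <- paste(altv, collapse = "")
    gi <- genome_index(setNames(DNAStringSet(ref), chrom))
    structure(list(gi = gi, ref = ref, alt = alt, chrom = chrom, L = L,
                   truth = list(snps = snps, indels = indels, svs = svs,
                                repeats = reps, artificial = art),
                   seed = seed),
              class = "sim_parents")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_parents <- function(x, ...) {
  cat("sim_parents:", x$L, "bp;", nrow(x$truth$snps), "SNPs;",
      nrow(x$truth$indels), "indels;", nrow(x$truth$svs), "SVs;",
      nrow(x$truth$repeats), "repeats\n")
  invisible(x)
}

## repeat regions as a repeat_table (what read_trf_dat would return)
sim_repeats <- function(parents) {
  r <- parents$truth$repeats
  repeat_table(r$chrom, r$start, r$end, r$unit_len, r$copies, r$score)
}

## ---- paired-end read synthesis from the alternate parent ---------------

q_string <- function(n, q = 30L) strrep(rawToChar(as.raw(q + 33L)), n)

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  nb <- nchar(seqs)
  nerr <- rbinom(1L, sum(nb), error_rate)
  if (nerr == 0L) return(seqs)
  ridx <- sample.int(length(seqs), nerr, replace = TRUE, prob = nb)
  off <- floor(runif(nerr) * nb[ridx]) + 1L
  newb <- sample(c("A", "C", "G", "T"), nerr, replace = TRUE)
  ## a read drawn twice keeps only its last error; negligible at 0.1%
  str <- seqs[ridx]
  substr(str, off, off) <- newb
  seqs[ridx] <- str
  seqs
}

#' Synthesize paired-end alignments of the alternate parent
#'
#' Emits coordinate-level alignments of reads drawn from the alternate
#' haplotype against the reference, directly encoding the artifact
#' patterns selected at [make_parents()] time (see the file header).
#'
#' @param parents A `sim_parents` object.
#' @param depth Fold coverage.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Library insert size distribution.
#' @param error_rate Per-base sequencing error probability.
#' @param artifacts Emit artifact reads (mis-mapped paralogs, collapsed
#'   duplication copies)? Junction signatures (LONG/INVERTED/SHORT pairs)
#'   are always emitted because they are physical, not artifactual.
#' @param mq_low_frac Fraction of background reads given mapping quality
#'   below 20 (exercised by the read filter).
#' @param seed Integer seed.
#' @param sample Read-name prefix.
#' @return List with `aln` (alignment table; artifact reads have qnames
#'   prefixed `dupB_`/`par_`) and `truth_reads` (qname, artifact label).
#' @export
write_alignments <- function(parents, depth = 20, read_len = 100L,
                             insert_mean = 500, insert_sd = 50,
                             error_rate = 0.001, artifacts = TRUE,
                             mq_low_frac = 0.02, seed = 1L,
                             sample = "alt") {
  stopifnot(inherits(parents, "sim_parents"))
  if (depth <= 0) stop("depth must be positive")
  with_seed(seed, {
    L <- parents$L; chrom <- parents$chrom; rl <- as.integer(read_len)
    svs <- parents$truth$svs
    dels <- svs[class == "deletion"]
    dups <- svs[class == "duplication"]
    invs <- svs[class == "inversion"]
    inss <- svs[class == "insertion"]

    nfrag <- round(L * depth / (2 * rl))
    ## size selection truncates the insert distribution at +-3 sd, so a
    ## concordant background pair is never LONG/SHORT by chance
    isize <- pmin(as.integer(round(insert_mean + 3 * insert_sd)) - 1L,
                  pmax(2L * rl + 10L,
                       as.integer(round(rnorm(nfrag, insert_mean,
                                              insert_sd)))))
    fs <- floor(runif(nfrag) * (L - isize - 1L)) + 1L
    r1s <- fs; r1e <- fs + rl - 1L
    r2s <- fs + isize - rl; r2e <- fs + isize - 1L

    ## drop fragments touching a deleted interval (no alternate material
    ## there; junction pairs are added explicitly below)
    keep <- rep(TRUE, nfrag)
    for (i in seq_len(nrow(dels))) {
      s <- dels$start[i]; e <- dels$end[i]
      keep <- keep & !(r1e >= s & r1s <= e) & !(r2e >= s & r2s <= e) &
        !(r1s < s & r2s > e)    # straddling pairs re-emitted as LONG
    }
    frag <- data.table(fs = fs[keep], isize = isize[keep])

    reads <- frag[, .(
      qname = paste0(sample, "_f", .I),
      r1s = fs, r2s = fs + isize - rl, isize = isize)]

    mk_pair <- function(qn, s1, s2, tl, f1 = 99L, f2 = 147L, mapq = 60L) {
      n <- length(s1)
      if (n == 0L) return(NULL)
      data.table(
        qname = rep(qn, 2L),
        flag = c(rep(f1, n), rep(f2, n)),
        chrom = chrom,
        pos = c(s1, s2), mapq = rep(mapq, 2L * n),
        cigar = paste0(rl, "M"),
        rnext = chrom, pnext = c(s2, s1),
        tlen = c(tl, -tl),
        seq = "", qual = q_string(rl))
    }

    aln <- mk_pair(reads$qname, reads$r1s, reads$r2s, reads$isize)

    truth_reads <- list()

    ## LONG junction pairs for each deletion
    for (i in seq_len(nrow(dels))) {
      s <- dels$start[i]; e <- dels$end[i]; k <- dels$len[i]
      wlo <- s - insert_mean + rl; whi <- s - rl
      if (whi <= wlo) next
      npair <- rpois(1L, (whi - wlo) * nfrag / L)
      if (npair == 0L) npair <- 1L
      f <- sort(floor(runif(npair) * (whi - wlo)) + wlo)
      iz <- pmin(as.integer(round(insert_mean + 3 * insert_sd)) - 1L,
                 pmax(2L * rl + 10L,
                      as.integer(round(rnorm(npair, insert_mean,
                                             insert_sd)))))
      ## read2 sits after the deleted interval on the reference
      s2 <- f + iz - rl + k
      ok <- s2 > e & s2 + rl - 1L <= L & f >= 1L
      f <- f[ok]; s2 <- s2[ok]; iz <- iz[ok]
      if (!length(f)) next
      aln <- rbind(aln, mk_pair(paste0(sample, "_delj", i, "_", seq_along(f)),
                                f, s2, s2 + rl - f, f1 = 97L, f2 = 145L))
    }

    ## SHORT junction pairs + clipped reads at insertions
    for (i in seq_len(nrow(inss))) {
      p <- inss$start[i]; k <- inss$len[i]
      wlo <- p - insert_mean + rl; whi <- p - rl
      if (whi > wlo) {
        npair <- max(1L, rpois(1L, (whi - wlo) * nfrag / L))
        f <- sort(floor(runif(npair) * (whi - wlo)) + wlo)
        iz <- as.integer(round(rnorm(npair, insert_mean, insert_sd)))
        s2 <- f + iz - rl - k
        ok <- s2 > p & f >= 1L
        f <- f[ok]; s2 <- s2[ok]
        if (length(f))
          aln <- rbind(aln, mk_pair(paste0(sample, "_insj", i, "_",
                                           seq_along(f)),
                                    f, s2, s2 + rl - f, f1 = 97L,
                                    f2 = 145L))
      }
      ## clip alignments crossing the insertion point
      cross <- aln$pos < p & aln$pos + rl - 1L > p & aln$cigar ==
        paste0(rl, "M")
      if (any(cross)) {
        a <- p - aln$pos[cross] + 1L
        data.table::set(aln, which(cross), "cigar",
                        paste0(a, "M", rl - a, "S"))
      }
    }

    ## INVERTED (same-strand) pairs at both inversion breakpoints
    for (i in seq_len(nrow(invs))) {
      b1 <- invs$start[i]; b2 <- invs$end[i]
      ## left breakpoint: read1 forward before b1, mate maps inside the
      ## inversion at the mirrored position, also forward
      wlo <- b1 - insert_mean + rl; whi <- b1 - rl
      if (whi > wlo) {
        npair <- max(1L, rpois(1L, (whi - wlo) * nfrag / L))
        f <- sort(floor(runif(npair) * (whi - wlo)) + wlo)
        iz <- as.integer(round(rnorm(npair, insert_mean, insert_sd)))
        o <- f + iz - rl - b1                 # reach into the inversion
        s2 <- b2 - o - rl + 1L
        ok <- o > 0L & s2 > b1 & s2 + rl - 1L <= b2 & f >= 1L
        f <- f[ok]; s2 <- s2[ok]
        if (length(f))
          aln <- rbind(aln, mk_pair(paste0(sample, "_invjL", i, "_",
                                           seq_along(f)),
                                    f, s2, abs(s2 + rl - f),
                                    f1 = 65L, f2 = 129L))
      }
      ## right breakpoint: read1 reverse after b2, mate mirrored near b1,
      ## both reverse
      wlo <- b2 + rl; whi <- b2 + insert_mean - rl
      if (whi > wlo) {
        npair <- max(1L, rpois(1L, (whi - wlo) * nfrag / L))
        fr <- sort(floor(runif(npair) * (whi - wlo)) + wlo)
        iz <- as.integer(round(rnorm(npair, insert_mean, insert_sd)))
        o <- iz - rl - (fr - b2)              # reach into the inversion
        s2 <- b1 + o - rl + 1L
        ok <- o > rl & s2 >= max(1L, b1) & s2 + rl - 1L < b2 &
          fr + rl - 1L <= L
        fr <- fr[ok]; s2 <- s2[ok]
        if (length(fr))
          aln <- rbind(aln, mk_pair(paste0(sample, "_invjR", i, "_",
                                           seq_along(fr)),
                                    s2, fr, abs(fr + rl - s2),
                                    f1 = 113L, f2 = 177L))
      }
    }

    ## collapsed duplication: reads of the second (diverged) copy pile
    ## onto the single reference locus
    if (artifacts) for (i in seq_len(nrow(dups))) {
      s <- dups$start[i]; e <- dups$end[i]; len <- e - s + 1L
      nb <- round(len * depth / (2 * rl))
      if (nb == 0L) next
      iz <- pmin(as.integer(round(insert_mean + 3 * insert_sd)) - 1L,
                 pmax(2L * rl + 10L,
                      as.integer(round(rnorm(nb, insert_mean,
                                             insert_sd)))))
      f <- floor(runif(nb) * pmax(1L, len - iz)) + s
      ok <- f + iz - 1L <= e + insert_mean    # allow slight overhang
      f <- f[ok]; iz <- iz[ok]
      if (!length(f)) next
      qn <- paste0("dupB_", sample, "_", i, "_", seq_along(f))
      pr <- mk_pair(qn, f, f + iz - rl, iz,
                    mapq = as.integer(sample(40:60, 1L)))
      aln <- rbind(aln, pr)
      truth_reads[[length(truth_reads) + 1L]] <-
        data.table(qname = qn, artifact = "dup_collapse")
    }

    ## mis-mapped paralogous reads inside deleted intervals
    if (artifacts) for (i in seq_len(nrow(dels))) {
      if (!dels$paralog[i]) next
      s <- dels$start[i]; e <- dels$end[i]; len <- e - s + 1L
      nb <- round(len * depth * 0.6 / (2 * rl))
      if (nb == 0L) next
      iz <- pmin(as.integer(round(insert_mean + 3 * insert_sd)) - 1L,
                 pmax(2L * rl + 10L,
                      as.integer(round(rnorm(nb, insert_mean,
                                             insert_sd)))))
      f <- floor(runif(nb) * pmax(1L, len - iz)) + s
      ok <- f + iz - 1L <= e
      f <- f[ok]; iz <- iz[ok]
      if (!length(f)) next
      qn <- paste0("par_", sample, "_", i, "_", seq_along(f))
      pr <- mk_pair(qn, f, f + iz - rl, iz, mapq = 50L)
      ## a third of the pairs anchor their mate at the remote paralog
      ## locus (the transposed element), giving DISTANT signatures
      nfar <- length(f) %/% 3L
      if (nfar > 0L) {
        far_pos <- as.integer(min(L - rl, s + L %/% 3L))
        idx <- seq_len(nfar)
        data.table::set(pr, idx, "pnext", rep(far_pos, nfar))
        data.table::set(pr, idx, "tlen", far_pos - pr$pos[idx])
      }
      aln <- rbind(aln, pr)
      truth_reads[[length(truth_reads) + 1L]] <-
        data.table(qname = qn, artifact = "paralog_del")
    }

    ## ---- sequences --------------------------------------------------
    aln[, end := pos + rl - 1L]
    ## default: read content from the SNP-bearing alternate haplotype
    aln[, seq := substring(parents$alt, pos, end)]

    ## non-allelic reads carry the diverged copy content
    artsnp <- parents$truth$artificial
    if (nrow(artsnp)) {
      hit <- artsnp[, {
        idx <- which((startsWith(aln$qname, "dupB_") |
                        startsWith(aln$qname, "par_")) &
                       aln$pos <= pos & aln$end >= pos)
        if (length(idx)) data.table(idx = idx, p = pos, b = alt) else NULL
      }, by = seq_len(nrow(artsnp))]
      if (nrow(hit)) {
        off <- hit$p - aln$pos[hit$idx] + 1L
        str <- aln$seq[hit$idx]
        substr(str, off, off) <- hit$b
        data.table::set(aln, hit$idx, "seq", str)
      }
      ## the duplication's diverged copy lacks the true allelic SNP
      tsnp <- parents$truth$snps[
        parents$truth$svs[class == "duplication"],
        on = .(pos >= start, pos <= end), nomatch = NULL,
        .(pos = x.pos, ref = x.ref)]
      if (nrow(tsnp)) {
        hit2 <- tsnp[, {
          idx <- which(startsWith(aln$qname, "dupB_") &
                         aln$pos <= pos & aln$end >= pos)
          if (length(idx)) data.table(idx = idx, p = pos, b = ref) else NULL
        }, by = seq_len(nrow(tsnp))]
        if (nrow(hit2)) {
          off <- hit2$p - aln$pos[hit2$idx] + 1L
          str <- aln$seq[hit2$idx]
          substr(str, off, off) <- hit2$b
          data.table::set(aln, hit2$idx, "seq", str)
        }
      }
    }

    ## ---- small indels: spanning reads get gapped CIGARs -------------
    indels <- parents$truth$indels
    reps <- parents$truth$repeats
    for (i in seq_len(nrow(indels))) {
      d <- indels$pos[i]; k <- indels$len[i]
      cover <- which(aln$pos <= d & aln$end > d &
                       grepl("^\\d+M$", aln$cigar) &
                       !startsWith(aln$qname, "par_"))
      if (!length(cover)) next
      s <- aln$pos[cover]
      if (indels$in_repeat[i]) {
        rr <- reps[start == d + 1L | (d >= start & d <= end)]
        rs <- rr$start[1]; re <- rr$end[1]
        spans <- s < rs & (s + rl + k - 1L) > re
      } else {
        spans <- (d - s + 1L) >= 10L & (s + rl + k - 1L - (d + k)) >= 10L
      }
      a <- d - s + 1L
      ## spanning: aM kD bM, consuming ref span rl + k
      sp <- cover[spans]
      if (length(sp)) {
        asp <- a[spans]
        data.table::set(aln, sp, "cigar",
                        paste0(asp, "M", k, "D", rl - asp, "M"))
        data.table::set(aln, sp, "end", aln$pos[sp] + rl + k - 1L)
        data.table::set(aln, sp, "seq",
                        paste0(substring(parents$alt, aln$pos[sp], d),
                               substring(parents$alt, d + k + 1L,
                                         aln$pos[sp] + rl + k - 1L)))
      }
      ## non-spanning: inside a tandem repeat the read aligns gaplessly
      ## and supports the reference; elsewhere it is soft-clipped
      ns <- cover[!spans]
      if (length(ns) && !indels$in_repeat[i]) {
        ans <- pmax(a[!spans], 1L)
        data.table::set(aln, ns, "cigar",
                        paste0(ans, "M", rl - ans, "S"))
        data.table::set(aln, ns, "end", aln$pos[ns] + ans - 1L)
      }
      ## (in-repeat non-spanning reads keep their full-M alignment; their
      ## sequence already matches the reference phase of the repeat)
    }

    ## low-mapq background fraction
    if (mq_low_frac > 0) {
      bg <- which(!startsWith(aln$qname, "dupB_") &
                    !startsWith(aln$qname, "par_"))
      nlow <- round(length(bg) * mq_low_frac)
      if (nlow > 0L) {
        idx <- sample(bg, nlow)
        data.table::set(aln, idx, "mapq",
                        as.integer(floor(runif(nlow) * 20)))
      }
    }

    aln[, seq := inject_errors(seq, error_rate)]
    aln[, qual := q_string(rl)]
    aln <- alignment_table(aln)
    truth_reads <- if (length(truth_reads)) rbindlist(truth_reads) else
      data.table(qname = character(), artifact = character())
    list(aln = aln, truth_reads = truth_reads)
  })
}

## ---- recombinant progeny ----------------------------------------------

## phase lookup: origin ("P"/"M") of each position given CO breakpoints
phase_at <- function(pos, breaks, start_origin) {
  nflip <- findInterval(pos, sort(breaks))
  ifelse((nflip %% 2L == 0L) == (start_origin == "P"), "P", "M")
}

#' Simulate a recombinant meiotic progeny and its alignments
#'
#' The diploid progeny carries two chromatids, each a mosaic of the two
#' parental haplotypes switching at the given crossover positions. Gene
#' conversion tracts overwrite the origin of one chromatid locally.
#' Parents must be SNP-only (no indels/SVs) for coordinate stability;
#' duplication-collapse artifact reads can be injected to emulate an
#' unrefined marker set's effect on downstream analyses.
#'
#' @param parents `sim_parents` (SNP-only).
#' @param cos List of two numeric vectors: crossover positions of
#'   chromatid 1 and 2 (strictly increasing).
#' @param start_origin Character vector of length 2: origin ("P"/"M") of
#'   each chromatid at position 1.
#' @param gc_tracts `data.frame(pos, len, hap)`: conversion tracts; `hap`
#'   (1 or 2) selects the chromatid whose origin flips over
#'   `[pos, pos+len-1]`. A tract overlapping a crossover is an error.
#' @param depth,read_len,error_rate Sequencing parameters (single-end).
#' @param artifact_dups Optional SV table-like of duplication intervals
#'   at which collapsed-copy reads are injected (defaults to the parents'
#'   duplication SVs when `artifacts = TRUE`).
#' @param artifacts Inject duplication-collapse reads?
#' @param seed Integer seed.
#' @return List: `aln` (single-end alignment table), `truth` (tables
#'   `blocks`, `cos`, `gcs`).
#' @export
make_progeny <- function(parents, cos = list(numeric(), numeric()),
                         start_origin = c("M", "M"), gc_tracts = NULL,
                         depth = 20, read_len = 100L, error_rate = 0.001,
                         artifacts = FALSE, artifact_dups = NULL,
                         seed = 1L) {
  stopifnot(inherits(parents, "sim_parents"), length(cos) == 2L)
  for (h in 1:2) if (is.unsorted(cos[[h]], strictly = TRUE) &&
                     length(cos[[h]]) > 1L)
    stop("crossover positions must be strictly increasing")
  if (!is.null(gc_tracts)) {
    gc_tracts <- as.data.table(gc_tracts)
    for (i in seq_len(nrow(gc_tracts))) {
      h <- gc_tracts$hap[i]
      if (any(cos[[h]] >= gc_tracts$pos[i] &
              cos[[h]] <= gc_tracts$pos[i] + gc_tracts$len[i] - 1L))
        stop("gene-conversion tract overlaps a crossover boundary")
    }
  }
  with_seed(seed, {
    L <- parents$L; chrom <- parents$chrom; rl <- as.integer(read_len)
    if (depth <= 0) stop("depth must be positive")
    nread <- round(L * depth / rl)
    pos <- floor(runif(nread) * (L - rl)) + 1L
    hap <- sample(1:2, nread, replace = TRUE)
    origin <- character(nread)
    for (h in 1:2) {
      idx <- which(hap == h)
      origin[idx] <- phase_at(pos[idx], cos[[h]], start_origin[h])
    }
    ## gene-conversion overlay (origin decided at read start)
    if (!is.null(gc_tracts)) for (i in seq_len(nrow(gc_tracts))) {
      s <- gc_tracts$pos[i]; e <- s + gc_tracts$len[i] - 1L
      idx <- which(hap == gc_tracts$hap[i] & pos >= s - rl + 1L & pos <= e)
      origin[idx] <- ifelse(origin[idx] == "P", "M", "P")
    }
    sq <- character(nread)
    isP <- origin == "P"
    if (any(isP))
      sq[isP] <- substring(parents$ref, pos[isP], pos[isP] + rl - 1L)
    if (any(!isP))
      sq[!isP] <- substring(parents$alt, pos[!isP], pos[!isP] + rl - 1L)
    ## reads physically spanning a crossover are chimeric: the molecule
    ## switches parent mid-read, so splice the sequence at the breakpoint
    for (h in 1:2) for (co in cos[[h]]) {
      idx <- which(hap == h & pos <= co & pos + rl - 1L > co)
      if (!length(idx)) next
      left_o <- origin[idx]   # origin at the read start (pre-breakpoint)
      for (j in seq_along(idx)) {
        i <- idx[j]
        lsrc <- if (left_o[j] == "P") parents$ref else parents$alt
        rsrc <- if (left_o[j] == "P") parents$alt else parents$ref
        sq[i] <- paste0(substring(lsrc, pos[i], co),
                        substring(rsrc, co + 1L, pos[i] + rl - 1L))
      }
    }
    aln <- data.table(qname = paste0("f2_", seq_len(nread)),
                      flag = 0L, chrom = chrom, pos = pos, mapq = 60L,
                      cigar = paste0(rl, "M"), rnext = "*", pnext = 0L,
                      tlen = 0L, seq = sq, qual = q_string(rl))
    ## collapsed-duplication artifact reads: diverged copy present on
    ## every M chromatid the progeny carries at the locus
    if (artifacts) {
      dups <- if (!is.null(artifact_dups)) as.data.table(artifact_dups)
              else parents$truth$svs[class == "duplication"]
      artsnp <- parents$truth$artificial[source == "dup_collapse"]
      extra <- list()
      for (i in seq_len(nrow(dups))) {
        s <- dups$start[i]; e <- dups$end[i]; len <- e - s + 1L
        mid <- (s + e) / 2
        mdos <- sum(vapply(1:2, function(h) {
          o <- phase_at(mid, cos[[h]], start_origin[h]); o == "M"
        }, logical(1)))
        if (mdos == 0L) next
        nb <- round(len * depth * mdos / 2 / rl)
        if (nb == 0L) next
        p <- floor(runif(nb) * pmax(1L, len - rl)) + s
        sqb <- substring(parents$ref, p, p + rl - 1L)
        dv <- artsnp[sv_start == s]
        for (j in seq_len(nrow(dv))) {
          idx <- which(p <= dv$pos[j] & p + rl - 1L >= dv$pos[j])
          if (length(idx)) {
            off <- dv$pos[j] - p[idx] + 1L
            str <- sqb[idx]
            substr(str, off, off) <- dv$alt[j]
            sqb[idx] <- str
          }
        }
        extra[[length(extra) + 1L]] <- data.table(
          qname = paste0("dupB_f2_", i, "_", seq_len(nb)),
          flag = 0L, chrom = chrom, pos = p, mapq = 55L,
          cigar = paste0(rl, "M"), rnext = "*", pnext = 0L, tlen = 0L,
          seq = sqb, qual = q_string(rl))
      }
      if (length(extra)) aln <- rbind(aln, rbindlist(extra))
    }
    aln[, seq := inject_errors(seq, error_rate)]
    aln <- alignment_table(aln)

    ## genotype-block truth from the two chromatid mosaics
    junctions <- sort(unique(c(cos[[1]], cos[[2]])))
    bounds <- c(1, junctions, L + 1)
    blocks <- data.table(
      chrom = chrom, start = as.integer(head(bounds, -1L)),
      end = as.integer(tail(bounds, -1L) - 1L))
    blocks[, genotype := {
      mids <- (start + end) / 2
      o1 <- phase_at(mids, cos[[1]], start_origin[1])
      o2 <- phase_at(mids, cos[[2]], start_origin[2])
      fifelse(o1 == "P" & o2 == "P", "paternal-hom",
              fifelse(o1 == "M" & o2 == "M", "maternal-hom", "het"))
    }]
    gcs <- if (!is.null(gc_tracts))
      data.table(chrom = chrom, start = gc_tracts$pos,
                 end = gc_tracts$pos + gc_tracts$len - 1L,
                 hap = gc_tracts$hap)
    else data.table(chrom = character(), start = integer(),
                    end = integer(), hap = integer())
    list(aln = aln,
         truth = list(blocks = blocks,
                      cos = data.table(chrom = chrom,
                                       pos = junctions),
                      gcs = gcs))
  })
}

#' Simulate a phenotype-selected pooled F2 population
#'
#' Each progeny is an independent meiosis product (two gametes with
#' Poisson-distributed crossovers); only progenies homozygous for the
#' causal allele (recessive selection) enter the pool. Reads are drawn
#' uniformly over the pooled chromatids.
#'
#' @param parents `sim_parents` (SNP-only).
#' @param n_progeny Number of selected progenies in the pool.
#' @param causal_pos Approximate causal position; the nearest reference
#'   `G` (or `C`) is mutated on the mutant-parent haplotype to `A` (`T`),
#'   the canonical EMS transition.
#' @param mutant Which parent carries the mutation: `"M"` (the alternate
#'   haplotype; default) or `"P"`.
#' @param co_mean Mean crossovers per gamete per chromosome.
#' @param depth Pooled fold coverage.
#' @param read_len,error_rate Sequencing parameters (single-end).
#' @param seed Integer seed.
#' @param region Optional `list(start =, end =)`: materialize only reads
#'   starting inside the interval. Gametes and genome-wide read
#'   positions are drawn identically for a given seed whatever the
#'   region, so slicing the genome streams the same pool in bounded
#'   memory (sequencing errors are drawn after slicing and so differ
#'   between sliced and whole-genome materializations).
#' @return List: `aln`, `truth` (`causal` one-row table; `gametes`
#'   segment table with per-gamete parental origin).
#' @export
make_f2_pool <- function(parents, n_progeny = 100L, causal_pos,
                         mutant = "M", co_mean = 2, depth = 25,
                         read_len = 100L, error_rate = 0.001, seed = 1L,
                         region = NULL) {
  stopifnot(inherits(parents, "sim_parents"), mutant %in% c("P", "M"))
  with_seed(seed, {
    L <- parents$L; chrom <- parents$chrom; rl <- as.integer(read_len)
    ## nearest G/C on the reference becomes the EMS site
    win <- substring(parents$ref, max(1L, causal_pos - 500L),
                     min(L, causal_pos + 500L))
    offs <- gregexpr("[GC]", win)[[1]]
    if (offs[1] == -1L) stop("no G/C near causal_pos")
    cand <- offs + max(1L, causal_pos - 500L) - 1L
    cpos <- cand[which.min(abs(cand - causal_pos))]
    cref <- substring(parents$ref, cpos, cpos)
    calt <- if (cref == "G") "A" else "T"
    mut_str <- if (mutant == "M") parents$alt else parents$ref
    substr(mut_str, cpos, cpos) <- calt
    wt_str <- if (mutant == "M") parents$ref else parents$alt
    mut_origin <- mutant

    ## gametes: rejection-sample until the progeny is causal-homozygous
    gam_segments <- vector("list", 2L * n_progeny)
    g <- 0L
    while (g < 2L * n_progeny) {
      nco <- rpois(1L, co_mean)
      brk <- sort(floor(runif(nco) * (L - 2L)) + 1L)
      so <- sample(c("P", "M"), 1L)
      if (phase_at(cpos, brk, so) != mut_origin) next
      g <- g + 1L
      bounds <- c(1L, brk, L + 1L)
      seg <- data.table(gamete = g,
                        start = as.integer(head(bounds, -1L)),
                        end = as.integer(tail(bounds, -1L) - 1L))
      seg[, origin := phase_at((start + end) / 2, brk, so)]
      gam_segments[[g]] <- seg
    }
    gam <- rbindlist(gam_segments)
    setkey(gam, gamete, start, end)

    nread <- round(L * depth / rl)
    pos <- floor(runif(nread) * (L - rl)) + 1L
    gid <- sample.int(2L * n_progeny, nread, replace = TRUE)
    q <- data.table(gamete = gid, start = pos, end = pos, rid = seq_len(nread))
    hit <- foverlaps(q, gam, by.x = c("gamete", "start", "end"),
                     type = "within", nomatch = NULL)
    origin <- character(nread)
    origin[hit$rid] <- hit$origin
    origin[origin == ""] <- "P"
    if (!is.null(region)) {
      keep <- pos >= region$start & pos <= region$end
      pos <- pos[keep]; origin <- origin[keep]
      rid_keep <- which(keep)
      nread <- length(pos)
    } else rid_keep <- seq_len(nread)
    sq <- character(nread)
    isMut <- origin == mut_origin
    if (any(isMut))
      sq[isMut] <- substring(mut_str, pos[isMut], pos[isMut] + rl - 1L)
    if (any(!isMut))
      sq[!isMut] <- substring(wt_str, pos[!isMut], pos[!isMut] + rl - 1L)
    aln <- data.table(qname = paste0("pool_", rid_keep),
                      flag = 0L, chrom = chrom, pos = pos, mapq = 60L,
                      cigar = paste0(rl, "M"), rnext = "*", pnext = 0L,
                      tlen = 0L, seq = sq, qual = q_string(rl))
    aln[, seq := inject_errors(seq, error_rate)]
    aln <- alignment_table(aln)
    gc(FALSE)    # pooled runs are large; consolidate before returning
    list(aln = aln,
         truth = list(causal = data.table(chrom = chrom, pos = cpos,
                                          ref = cref, alt = calt,
                                          mutant = mutant),
                      gametes = gam))
  })
}
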