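## Single entry point wiring the stages:
##   call -> sv -> refine -> merge -> recomb | bsa
## Configuration is one declarative list (or JSON file); every published
## default (mapq 20, 4x depth fold, 1% depth tails, 99% ratio band,
## 0.8/0.2 genotype thresholds, 20 kb/10 kb progeny windows,
## 200 kb/100 kb + 2 Mb/500 kb pool windows, 1 kb GC grouping, 0.75 EMS
## ratio) is a named constant surfaced here.

#' Published default parameters
#' @export
PIPELINE_DEFAULTS <- list(
  min_mapq = 20L, het_prior = 1e-3, min_qual = 20,
  depth_fold = 4, depth_tail = 0.01, ratio_percentile = 0.99,
  sv_margin = 500L, min_support = 3L,
  window = 20000L, step = 10000L, min_markers = 5L,
  bsa_window = 2e5, bsa_step = 1e5, bsa_smooth_window = 2e6,
  bsa_smooth_step = 5e5, gc_max_gap = 1000L, gc_min_reads = 5L,
  ems_min_ratio = 0.75)

#' Run the pipeline
#'
#' Executes the requested stages in dependency order over one or more
#' samples. Outputs (VCF/BED/TSV) are written into `outdir` with a
#' provenance header (tool version, config hash, seed) and a
#' machine-readable `summary.json` whose per-reason filter counts
#' partition the removed candidates exactly (each removed candidate is
#' counted under its first reason in the [FILTER_REASONS] order).
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `reference` (FASTA path), `samples` (named list of SAM/BAM paths or
#'   alignment tables), `repeats` (TRF .dat/BED path or table,
#'   optional), `stages` (subset of call, sv, refine, merge, recomb,
#'   bsa), `outdir`, `seed`, and optional parameter overrides named as
#'   in [PIPELINE_DEFAULTS]. `recomb` needs `progeny` (sample name) and
#'   a merged/refined marker source; `bsa` needs `pool` and
#'   `mutant_parent`.
#' @return Invisibly, a list with the per-stage results and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  p <- utils::modifyList(PIPELINE_DEFAULTS, config[
    intersect(names(config), names(PIPELINE_DEFAULTS))])
  stages <- config$stages %||% c("call", "sv", "refine")
  outdir <- config$outdir %||% tempfile("run")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  known <- c("call", "sv", "refine", "merge", "recomb", "bsa")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known),
                                     collapse = ", "))
  stages <- known[known %in% stages]

  gi <- if (!is.null(config$reference)) {
    if (is.character(config$reference)) genome_index(config$reference)
    else config$reference
  } else NULL
  repeats <- if (!is.null(config$repeats)) {
    if (is.character(config$repeats)) read_trf_dat(config$repeats)
    else config$repeats
  } else NULL
  samples <- config$samples %||% list()
  aln <- lapply(samples, function(s)
    if (is.character(s)) read_alignments(s) else s)

  need <- function(stage, what, ok) if (!ok)
    stop("stage '", stage, "' missing its input: ", what)

  res <- list()
  prov <- c(sprintf("## meiomapr %s", as.character(packageVersion("meiomapr"))),
            sprintf("## seed %s", config$seed %||% "NA"),
            sprintf("## config-hash %s", config_hash(config)))

  if ("call" %in% stages) {
    need("call", "reference + samples", !is.null(gi) && length(aln) > 0)
    res$candidates <- lapply(aln, function(a)
      call_variants(a, gi, repeats, min_mapq = p$min_mapq,
                    het_prior = p$het_prior, min_qual = p$min_qual))
    for (s in names(res$candidates))
      write_vcf(res$candidates[[s]],
                file.path(outdir, paste0(s, ".candidates.vcf")),
                sample = s, gi = gi)
  }
  if ("sv" %in% stages) {
    need("sv", "reference + samples", !is.null(gi) && length(aln) > 0)
    res$svs <- lapply(aln, function(a)
      detect_svs(a[!is.na(mapq)], gi, min_support = p$min_support,
                 min_mapq = p$min_mapq))
    for (s in names(res$svs))
      write_sv_bed(res$svs[[s]], file.path(outdir, paste0(s, ".sv.bed")))
  }
  if ("refine" %in% stages) {
    cand <- res$candidates %||% config$candidates
    need("refine", "candidates (run 'call' or supply them)",
         !is.null(cand))
    svs <- res$svs %||% config$svs %||%
      lapply(cand, function(x) sv_table())
    cfg <- refine_config(sv_margin = p$sv_margin,
                         depth_fold = p$depth_fold,
                         depth_tail = p$depth_tail,
                         ratio_percentile = p$ratio_percentile,
                         min_support = p$min_support)
    res$refined <- lapply(names(cand), function(s) {
      md <- if (!is.null(aln[[s]]) && !is.null(gi))
        sum(as.numeric(nchar(aln[[s]]$seq))) / sum(as.numeric(gi$lengths))
      else mean(cand[[s]]$depth)
      refine_variants(cand[[s]], svs[[s]] %||% sv_table(), repeats,
                      mean_depth = md, config = cfg)
    })
    names(res$refined) <- names(cand)
    for (s in names(res$refined))
      write_vcf(res$refined[[s]],
                file.path(outdir, paste0(s, ".refined.vcf")),
                sample = s, gi = gi)
  }
  if ("merge" %in% stages) {
    need("merge", ">= 2 refined sample sets",
         !is.null(res$refined) && length(res$refined) >= 2L)
    res$merged <- merge_samples(res$refined, aln, gi, repeats,
                                het_prior = p$het_prior,
                                min_mapq = p$min_mapq)
    write_vcf(res$merged, file.path(outdir, "merged.vcf"), gi = gi)
  }
  markers <- NULL
  if (any(c("recomb", "bsa") %in% stages)) {
    msrc <- res$refined[[1]] %||% config$markers
    need("recomb/bsa", "markers (refined calls or config$markers)",
         !is.null(msrc))
    markers <- if (all(c("p_allele", "m_allele") %in% names(msrc))) msrc
               else marker_set(msrc, paternal = config$paternal %||% "ref")
  }
  if ("recomb" %in% stages) {
    need("recomb", "config$progeny naming a sample",
         !is.null(config$progeny) && config$progeny %in% names(aln))
    pobs <- genotype_markers(aln[[config$progeny]], markers,
                             min_mapq = p$min_mapq, repeats = repeats)
    wins <- call_windows(pobs, gi$lengths, window = p$window,
                         step = p$step, min_markers = p$min_markers)
    mb <- merge_blocks(wins, pobs)
    gcs <- detect_gc(pobs, mb$blocks, min_reads = p$gc_min_reads,
                     max_gap = p$gc_max_gap, window = p$window)
    res$recomb <- list(observations = pobs, windows = wins,
                       blocks = mb$blocks, crossovers = mb$crossovers,
                       gene_conversions = gcs)
    write_tsv_prov(mb$blocks, file.path(outdir, "blocks.tsv"), prov)
    write_tsv_prov(mb$crossovers, file.path(outdir, "crossovers.tsv"),
                   prov)
    write_tsv_prov(gcs[, .(chrom, start, end, span, n_markers,
                           background, converted_to)],
                   file.path(outdir, "gene_conversions.tsv"), prov)
  }
  if ("bsa" %in% stages) {
    need("bsa", "config$pool naming a sample",
         !is.null(config$pool) && config$pool %in% names(aln))
    pobs <- genotype_markers(aln[[config$pool]], markers,
                             min_mapq = p$min_mapq, repeats = repeats)
    track <- build_ratio_track(pobs, gi$lengths, window = p$bsa_window,
                               step = p$bsa_step,
                               smooth_window = p$bsa_smooth_window,
                               smooth_step = p$bsa_smooth_step)
    regions <- find_candidate_regions(track,
                                      mutant = config$mutant_parent %||%
                                        "M")
    res$bsa <- list(track = track, regions = regions)
    write_tsv_prov(regions, file.path(outdir, "candidate_regions.tsv"),
                   prov)
    write_tsv_prov(track$windows[, .(chrom, start, end, ratio_w)],
                   file.path(outdir, "ratio_track.tsv"), prov)
  }

  ## run summary: per-reason counts partition the removed candidates
  summary <- list(stages = stages, seed = config$seed,
                  config_hash = config_hash(config))
  if (!is.null(res$refined)) {
    summary$samples <- lapply(res$refined, function(rf) {
      removed <- rf[filter != ""]
      first_reason <- vapply(strsplit(removed$filter, ";"), function(r)
        FILTER_REASONS[min(match(r, FILTER_REASONS))], character(1))
      counts <- as.list(table(factor(first_reason,
                                     levels = FILTER_REASONS)))
      list(candidates = nrow(rf), pass = nrow(pass_variants(rf)),
           removed = nrow(removed), by_reason = counts)
    })
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  res$summary <- summary
  res$outdir <- outdir
  invisible(res)
}

config_hash <- function(config) {
  config$outdir <- NULL
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        force = TRUE)
  ## cheap stable hash (no digest dependency): sum of char codes mixed
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

write_tsv_prov <- function(dt, path, prov) {
  writeLines(prov, path)
  suppressWarnings(fwrite(dt, path, sep = "\t", append = TRUE,
                          col.names = TRUE))
  invisible(path)
}
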