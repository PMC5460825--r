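#' Run the full GR ChIP-seq analysis chain on simulated or supplied data
#'
#' Stage order: tag preprocessing (dedup, 3' extension to 150 bp, depth
#' normalisation) -> hotspot calling per replicate against matched input ->
#' replicate concordance per condition -> top-20\% selection -> cross-group
#' pooling of non-duplicated positions -> tag counting and NB differential
#' test -> nearest-TSS annotation -> motif architecture (frequency window
#' +/-100 bp; histogram window +/-1000 bp) -> nGRE centrality. Every output
#' is a TSV with header, plus BED exports of the peak sets and a JSON run
#' metadata file carrying the seed and a config hash.
#'
#' @param genome named character vector of sequences (or FASTA path).
#' @param tags named list of tag data.tables (\code{chip_c<i>_r<j>},
#'   \code{input_c<i>_r<j>}), e.g. from [simulate_tags()].
#' @param genes gene-model table (or TSV path).
#' @param outdir output directory (created if needed).
#' @param mask optional repeat-mask interval table; if NULL, simple tandem
#'   repeats detected in the genome are masked.
#' @param params a \code{hotspot_params}.
#' @param top_fraction fraction of concordant peaks carried forward (0.2).
#' @param motif_library motif library for scanning.
#' @param seed integer seed recorded in the metadata (the pipeline itself is
#'   deterministic given its inputs).
#' @return invisible list of in-memory results (peaks, pooled peaks, counts,
#'   diff table, annotations, architectures, nGRE report, concordance).
#' @export
run_pipeline <- function(genome, tags, genes, outdir,
                         mask = NULL,
                         params = hotspot_params(),
                         top_fraction = 0.2,
                         motif_library = default_motif_library(),
                         seed = 1L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(genes) && length(genes) == 1 && file.exists(genes))
    genes <- read_gene_models(genes)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chrom_lengths <- vapply(genome, nchar, integer(1))
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (is.null(mask)) {
    mask <- stage("mask", find_simple_repeats(genome))
    say("mask: %d simple-repeat interval(s) detected", nrow(mask))
  }

  chip_names <- grep("^chip_", names(tags), value = TRUE)
  conds <- sort(unique(sub("^chip_(c\\d+)_r\\d+$", "\\1", chip_names)))

  # --- tag preprocessing ---
  prep <- stage("tags", {
    lapply(tags, function(tt) {
      dd <- deduplicate_tags(tt)
      extend_tags(dd, 150L, chrom_lengths)
    })
  })
  for (nm in names(prep))
    say("tags: %s %d -> %d after dedup+extension", nm,
        nrow(tags[[nm]]), nrow(prep[[nm]]))

  tracks <- lapply(prep, density_track, bin = params$step,
                   chrom_lengths = chrom_lengths)

  # --- per-replicate hotspots, per-condition concordance, top fraction ---
  group_peaks <- list()
  for (cond in conds) {
    reps <- sort(grep(sprintf("^chip_%s_r", cond), names(tags), value = TRUE))
    pk <- lapply(reps, function(nm) {
      inp <- sub("^chip", "input", nm)
      stage(paste0("callpeaks:", nm),
            call_hotspots(tracks[[nm]], tracks[[inp]], params, mask = mask))
    })
    say("peaks: %s replicate counts %s", cond,
        paste(vapply(pk, nrow, integer(1)), collapse = "/"))
    conc <- stage(paste0("concordance:", cond),
                  concordant_peaks(pk[[1]], pk[[2]]))
    top <- stage(paste0("top:", cond), rank_top_fraction(conc, top_fraction))
    say("peaks: %s concordant %d, top %.0f%% kept %d", cond, nrow(conc),
        100 * top_fraction, nrow(top))
    write_tsv(top, file.path(outdir, sprintf("peaks_%s.tsv", cond)))
    write_bed(top, file.path(outdir, sprintf("peaks_%s.bed", cond)))
    group_peaks[[cond]] <- top
  }

  # --- pooling ---
  pooled <- stage("pool", pool_nonduplicated(group_peaks[[1]],
                                             group_peaks[[2]]))
  say("pool: %d non-duplicated position(s)", nrow(pooled))
  write_tsv(pooled, file.path(outdir, "peaks_pooled.tsv"))
  write_bed(pooled, file.path(outdir, "peaks_pooled.bed"))

  # --- counting + differential binding ---
  chip_prep <- prep[chip_names]
  counts <- stage("count", count_tags(pooled, chip_prep))
  groups <- sub("^chip_(c\\d+)_r\\d+$", "\\1", colnames(counts))
  diff <- stage("diff", {
    sf <- size_factors(counts)
    disp <- estimate_dispersion(counts, sf, groups)
    nb_test(counts, sf, disp$dispersion, groups)
  })
  say("diff: %d peak(s) tested, %d at BH-adjusted p < 0.05",
      nrow(diff), sum(diff$padj < 0.05))
  write_tsv(data.table(peak_id = rownames(counts), counts),
            file.path(outdir, "counts.tsv"))
  write_tsv(diff, file.path(outdir, "diff_results.tsv"))

  # --- group densities and concordance ---
  dens <- lapply(conds, function(cond) {
    reps <- grep(sprintf("^chip_%s_r", cond), chip_names, value = TRUE)
    cnt <- counts[, reps, drop = FALSE]
    rowMeans(sweep(cnt, 2, vapply(chip_prep[reps], nrow, numeric(1)) / 1e7, "/"))
  })
  conc <- stage("concordance_plot",
                intensity_concordance(dens[[1]], dens[[2]], pooled$peak_id))
  say("concordance: Pearson r = %.4f", conc$pearson_r)
  write_tsv(conc$table, file.path(outdir, "intensity_ma.tsv"))

  # --- annotation ---
  ann <- stage("annotate", classify_genomic_region(pooled, genes))
  say("annotate: %s", paste(sprintf("%s=%d", names(table(ann$category)),
                                    table(ann$category)), collapse = " "))
  write_tsv(ann, file.path(outdir, "annotations.tsv"))

  # --- motif architecture ---
  masked_genome <- mask_genome(genome, mask)
  hits_freq <- stage("scan", scan_peaks(masked_genome, pooled, motif_library,
                                        halfwidth = 100L))
  hits_hist <- stage("scan_hist", scan_peaks(masked_genome, pooled,
                                             motif_library, halfwidth = 1000L))
  arch <- stage("architecture",
                classify_architecture(hits_freq, pooled$peak_id))
  hist <- positional_histogram(hits_hist)
  part <- partition_by_full_gre(arch)
  strat <- stratify_by_strength(pooled, arch)
  comp <- composite_by_strength(arch, strat$strata)
  ngre <- ngre_analysis(hits_hist)
  say("motifs: %d hit(s) in counting windows; %d peak(s) with full GRE",
      nrow(hits_freq), sum(arch$has_full_gre))
  write_tsv(hits_freq, file.path(outdir, "motif_hits.tsv"))
  write_tsv(arch, file.path(outdir, "architectures.tsv"))
  write_tsv(hist$histogram, file.path(outdir, "motif_histograms.tsv"))
  write_tsv(part$frequencies, file.path(outdir, "motif_frequencies.tsv"))
  write_tsv(strat$frequencies, file.path(outdir, "strength_frequencies.tsv"))
  write_tsv(comp, file.path(outdir, "composite_by_strength.tsv"))
  write_tsv(ngre$per_peak, file.path(outdir, "ngre_report.tsv"))

  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  write_run_metadata(outdir, list(params = unclass(params),
                                  top_fraction = top_fraction),
                     seed, extra = list(n_pooled_peaks = nrow(pooled)))
  invisible(list(group_peaks = group_peaks, pooled = pooled, counts = counts,
                 diff = diff, annotations = ann, architectures = arch,
                 histograms = hist, partition = part, strata = strat,
                 composite = comp, ngre = ngre, concordance = conc))
}
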