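#!/usr/bin/env Rscript
# Stage 3 -- between-condition differential binding at pooled peaks.
#
# Raw tag counts (midpoint rule) per pooled peak and ChIP sample; DESeq-style
# median-of-ratios size factors; trend-shared method-of-moments NB
# dispersions; per-peak conditional NB exact test with BH adjustment; and the
# group-intensity scatter/MA concordance. The simulation is a
# between-condition null, so the expectation is no significant peaks and a
# high Pearson correlation.

suppressMessages({library(grchip); library(data.table)})

indir <- "results/analysis"
pooled <- fread(file.path(indir, "peaks_pooled.tsv"))
lens <- vapply(read_fasta(file.path(indir, "genome.fa")), nchar, integer(1))

chip_names <- sub("\\.bed$", "", list.files(indir, pattern = "^chip.*\\.bed$"))
prep <- lapply(chip_names, function(nm)
  extend_tags(deduplicate_tags(
    read_bed(file.path(indir, paste0(nm, ".bed")), require_strand = TRUE)),
    150L, lens))
names(prep) <- chip_names

counts <- count_tags(pooled, prep)
groups <- sub("^chip_(c[12])_r[12]$", "\\1", colnames(counts))
sf <- size_factors(counts)
disp <- estimate_dispersion(counts, sf, groups)
res <- nb_test(counts, sf, disp$dispersion, groups)

message(sprintf("size factors: %s", paste(round(sf, 3), collapse = " ")))
message(sprintf("%d peaks tested; %d at BH-adjusted p < 0.05 (null design)",
                nrow(res), sum(res$padj < 0.05)))

dens <- lapply(c("c1", "c2"), function(cond) {
  reps <- grep(cond, colnames(counts), value = TRUE)
  rowMeans(sweep(counts[, reps, drop = FALSE], 2,
                 vapply(prep[reps], nrow, numeric(1)) / 1e7, "/"))
})
conc <- intensity_concordance(dens[[1]], dens[[2]], pooled$peak_id)
message(sprintf("between-group intensity concordance: Pearson r = %.4f",
                conc$pearson_r))

write_tsv(data.table(peak_id = rownames(counts), counts),
          file.path(indir, "counts.tsv"))
write_tsv(res, file.path(indir, "diff_results.tsv"))
write_tsv(conc$table, file.path(indir, "intensity_ma.tsv"))
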