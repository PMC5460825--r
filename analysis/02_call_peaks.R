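#!/usr/bin/env Rscript
# Stage 2 -- tag preprocessing and replicate-concordant hotspot calling.
#
# Per sample: deduplicate on (chrom, 5' position, strand), extend to 150 bp
# in the 3' direction, bin at 50 bp. Per replicate: windowed binomial
# enrichment vs the depth-ratio-scaled local input expectation, BH q < 0.01,
# merged windows. Per condition: regions supported by both replicates, then
# the top 20% by tag density. Finally the two conditions' non-duplicated
# positions are pooled.

suppressMessages({library(grchip); library(data.table)})

indir <- "results/analysis"
genome <- read_fasta(file.path(indir, "genome.fa"))
lens <- vapply(genome, nchar, integer(1))
truth <- fread(file.path(indir, "truth_sites.tsv"))

samples <- sub("\\.bed$", "", list.files(indir, pattern = "^(chip|input).*\\.bed$"))
tags <- lapply(samples, function(nm)
  read_bed(file.path(indir, paste0(nm, ".bed")), require_strand = TRUE))
names(tags) <- samples

mask <- find_simple_repeats(genome)
message(nrow(mask), " simple-repeat interval(s) masked")

prep <- lapply(tags, function(x) extend_tags(deduplicate_tags(x), 150L, lens))
tracks <- lapply(prep, density_track, bin = 50L, chrom_lengths = lens)

group_peaks <- list()
for (cond in c("c1", "c2")) {
  pk <- lapply(1:2, function(r) {
    call_hotspots(tracks[[sprintf("chip_%s_r%d", cond, r)]],
                  tracks[[sprintf("input_%s_r%d", cond, r)]], mask = mask)
  })
  conc <- concordant_peaks(pk[[1]], pk[[2]])
  top <- rank_top_fraction(conc, 0.2)
  covered <- mean(vapply(truth$center, function(ct)
    any(conc$start <= ct & ct < conc$end), logical(1)))
  message(sprintf("%s: %d/%d replicate peaks, %d concordant (%.0f%% of planted sites recovered), top 20%% = %d",
                  cond, nrow(pk[[1]]), nrow(pk[[2]]), nrow(conc),
                  100 * covered, nrow(top)))
  write_tsv(conc, file.path(indir, sprintf("peaks_concordant_%s.tsv", cond)))
  write_tsv(top, file.path(indir, sprintf("peaks_top20_%s.tsv", cond)))
  group_peaks[[cond]] <- conc
}

pooled <- pool_nonduplicated(group_peaks$c1, group_peaks$c2)
message(sprintf("pooled non-duplicated positions: %d (%d in both groups)",
                nrow(pooled), sum(pooled$source == "both")))
write_tsv(pooled, file.path(indir, "peaks_pooled.tsv"))
write_bed(pooled, file.path(indir, "peaks_pooled.bed"))

# density matrix around summits for heat-map style displays
m <- density_heat_matrix(pooled, rbindlist(prep[grep("^chip", names(prep))]))
write_tsv(data.table(peak_id = rownames(m), m), file.path(indir, "heat_matrix.tsv"))
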