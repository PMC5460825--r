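#!/usr/bin/env Rscript
# Stage 5 -- consensus-motif architecture of the pooled binding sites.
#
# Scans +/-100 bp around every pooled summit with the standard library (full
# GRE ACANNNTGTYCT, half-site TGTYCT, NF-1 half-site TTGGCA, bHLH CANATGG,
# nGRE CTCC(N)0-2GGAGA), sets per-class flags (a full GRE implies the
# half-site), partitions peaks by full-GRE presence, builds +/-1 kb
# positional histograms, stratifies motif frequencies by peak strength
# (top vs bottom third by tag density) and tabulates composite classes.
# A k-mer enrichment pass over the peak windows stands in for de novo
# discovery.

suppressMessages({library(grchip); library(data.table)})

indir <- "results/analysis"
genome <- read_fasta(file.path(indir, "genome.fa"))
pooled <- fread(file.path(indir, "peaks_pooled.tsv"))
mask <- find_simple_repeats(genome)
masked <- mask_genome(genome, mask)

hits <- scan_peaks(masked, pooled, halfwidth = 100L)
hits_wide <- scan_peaks(masked, pooled, halfwidth = 1000L)
arch <- classify_architecture(hits, pooled$peak_id)

message(sprintf("motif frequencies over %d peaks:", nrow(arch)))
for (f in c("has_full_gre", "has_gre_half", "has_nf1_half", "has_bhlh",
            "has_ngre"))
  message(sprintf("  %-12s %.1f%%", sub("has_", "", f),
                  100 * mean(arch[[f]])))
message(sprintf("  neither GRE form: %d peaks",
                sum(!arch$has_full_gre & !arch$has_gre_half)))

part <- partition_by_full_gre(arch)
hist <- positional_histogram(hits_wide)
message("median |offset| from summit (bp):")
for (i in seq_len(nrow(hist$median_abs_offset)))
  message(sprintf("  %-10s %.0f", hist$median_abs_offset$motif[i],
                  hist$median_abs_offset$median_abs_offset[i]))

strat <- stratify_by_strength(pooled, arch)
comp <- composite_by_strength(arch, strat$strata)
message("top vs bottom third motif frequencies:")
for (i in seq_len(nrow(strat$frequencies)))
  message(sprintf("  %-10s top %.2f  bottom %.2f", strat$frequencies$class[i],
                  strat$frequencies$top[i], strat$frequencies$bottom[i]))

# simplified de novo stand-in on the strongest peaks
setorder(pooled, -density)
fg <- vapply(head(seq_len(nrow(pooled)), 100), function(i) {
  s0 <- pooled$summit[i]
  substring(genome[[pooled$chrom[i]]], s0 - 99L, s0 + 100L)
}, character(1))
kmers <- kmer_enrichment(fg, widths = c(6L, 12L), seed = 42L)
message(sprintf("top enriched 12-mer: %s (q = %.2g)",
                kmers[width == 12][1, kmer], kmers[width == 12][1, q]))

write_tsv(hits, file.path(indir, "motif_hits.tsv"))
write_tsv(arch, file.path(indir, "architectures.tsv"))
write_tsv(part$frequencies, file.path(indir, "motif_frequencies.tsv"))
write_tsv(hist$histogram, file.path(indir, "motif_histograms.tsv"))
write_tsv(strat$frequencies, file.path(indir, "strength_frequencies.tsv"))
write_tsv(comp, file.path(indir, "composite_by_strength.tsv"))
write_tsv(kmers, file.path(indir, "kmer_enrichment.tsv"))
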