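#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic study data.
#
# A 3 Mb motif-free background genome; 200 GR binding sites planted with the
# default composition's class proportions (palindromic GRE, GRE half-site,
# NF-1 half-site, bHLH, nGRE); ChIP and matched input tags for two conditions
# x two replicates under the between-condition null; and a set of synthetic
# gene models for annotation. Everything lands in results/analysis/ as
# FASTA / BED6 / TSV so the later stages (and any genome browser) can read it.

suppressMessages(library(grchip))

outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 1000L

cfg <- composition_config(
  n_sites = 200,
  full_gre = 3301 / 7298, gre_half = 3262 / 7298,
  nf1_half = 3985 / 7298, bhlh = 1248 / 7298, ngre = 126 / 7298,
  ngre_without_gre = 1, min_spacing = 2000L)

message("generating 3 Mb motif-free background genome ...")
genome <- generate_background_genome(3e6, gc = 0.42, seed = seed)

message("planting ", cfg$n_sites, " binding sites ...")
ps <- plant_sites(genome, cfg, seed = seed + 1L)
lens <- vapply(ps$genome, nchar, integer(1))

message("simulating tags (2 conditions x 2 replicates, ChIP + input) ...")
tags <- simulate_tags(lens, ps$truth, read_sim_params(), seed = seed + 2L)

genes <- simulate_gene_models(lens, 60L, seed = seed + 3L)

write_fasta(ps$genome, file.path(outdir, "genome.fa"))
write_tsv(ps$truth, file.path(outdir, "truth_sites.tsv"))
write_tsv(ps$instances, file.path(outdir, "truth_instances.tsv"))
write_gene_models(genes, file.path(outdir, "genes.tsv"))
for (nm in names(tags))
  write_bed(tags[[nm]], file.path(outdir, paste0(nm, ".bed")))

message(sprintf("wrote %d samples; ChIP c1_r1 has %d tags; %d/%d/%d/%d/%d sites carry full-GRE/half/NF-1/bHLH/nGRE",
                length(tags), nrow(tags$chip_c1_r1),
                sum(ps$truth$has_full_gre),
                sum(ps$truth$has_gre_half & !ps$truth$has_full_gre),
                sum(ps$truth$has_nf1_half), sum(ps$truth$has_bhlh),
                sum(ps$truth$has_ngre)))
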