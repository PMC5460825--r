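#!/usr/bin/env Rscript
# Stage 4 -- nearest-TSS annotation and genomic distribution.
#
# Each pooled peak is annotated to its nearest transcription start site with
# an orientation-signed distance (negative = upstream), classified into one
# exclusive category at its summit (promoter -5 kb/+100 bp > 5'UTR > exon >
# intron > 3'UTR > intergenic), and the gene-proximal subset (gene body or
# extended promoter) is written out for downstream gene-list use.

suppressMessages({library(grchip); library(data.table)})

indir <- "results/analysis"
pooled <- fread(file.path(indir, "peaks_pooled.tsv"))
genes <- read_gene_models(file.path(indir, "genes.tsv"))

ann <- classify_genomic_region(pooled, genes)
tab <- table(ann$category)
message("genomic distribution of GR binding sites:")
for (nm in names(tab))
  message(sprintf("  %-10s %4d (%.1f%%)", nm, tab[[nm]],
                  100 * tab[[nm]] / nrow(ann)))

proximal <- select_gene_proximal(pooled, ann)
message(sprintf("gene-proximal subset: %d of %d peaks; %d distinct genes",
                nrow(proximal), nrow(pooled),
                length(unique(ann[ann$peak_id %in% proximal$peak_id, gene]))))

write_tsv(ann, file.path(indir, "annotations.tsv"))
write_tsv(proximal, file.path(indir, "peaks_gene_proximal.tsv"))
write_tsv(unique(ann[ann$peak_id %in% proximal$peak_id, .(gene)]),
          file.path(indir, "proximal_gene_list.tsv"))
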