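gene_tss <- function(genes) {
  genes <- as.data.table(genes)
  genes[, tss := ifelse(strand == "+", txStart, txEnd)]
  genes[]
}

parse_exons <- function(gene_row) {
  data.table(start = as.integer(strsplit(gene_row$exonStarts, ",")[[1]]),
             end = as.integer(strsplit(gene_row$exonEnds, ",")[[1]]))
}

#' Annotate peaks to their nearest transcription start site
#'
#' Distance is signed relative to the gene's orientation: negative means the
#' summit lies upstream (5') of the TSS, positive downstream. Ties between
#' equidistant genes go to the lexicographically smaller gene id.
#'
#' @param peaks peak table with \code{peak_id}, \code{chrom}, \code{summit}.
#' @param genes gene-model table (\code{gene}, \code{chrom}, \code{strand},
#'   \code{txStart}, \code{txEnd}, \code{exonStarts}, \code{exonEnds}).
#' @return data.table: \code{peak_id}, \code{gene}, \code{distance}.
#' @export
nearest_tss <- function(peaks, genes) {
  peaks <- as.data.table(peaks)
  genes <- gene_tss(genes)
  if (!nrow(genes)) stopf("need at least one gene model")
  setorder(genes, gene)
  out <- rbindlist(lapply(seq_len(nrow(peaks)), function(i) {
    gg <- genes[chrom == peaks$chrom[i]]
    if (!nrow(gg)) gg <- genes   # fall back to any chromosome (distance Inf-ish)
    d_abs <- abs(gg$tss - peaks$summit[i]) +
      ifelse(gg$chrom == peaks$chrom[i], 0, Inf)
    j <- which(d_abs == min(d_abs))[1]     # genes sorted by id -> tie-break
    signed <- if (gg$strand[j] == "+") peaks$summit[i] - gg$tss[j]
              else gg$tss[j] - peaks$summit[i]
    data.table(peak_id = peaks$peak_id[i], gene = gg$gene[j],
               distance = as.numeric(signed))
  }))
  out[]
}

#' Classify the genomic region of each peak summit
#'
#' One exclusive category per peak, tested at the summit with precedence
#' promoter > 5'UTR > exon > intron > 3'UTR > intergenic. The promoter is
#' defined as -5 kb to +100 bp around the nearest TSS. First/last exons
#' (strand-aware) are treated as 5'/3' UTR-containing segments in synthetic
#' gene models.
#'
#' @param peaks peak table with \code{peak_id}, \code{chrom}, \code{summit}.
#' @param genes gene-model table.
#' @param annotations optional precomputed [nearest_tss()] output.
#' @param promoter_upstream,promoter_downstream promoter bounds in bp
#'   (defaults 5000 and 100).
#' @return data.table: \code{peak_id}, \code{gene}, \code{distance},
#'   \code{category}.
#' @export
classify_genomic_region <- function(peaks, genes, annotations = NULL,
                                    promoter_upstream = 5000L,
                                    promoter_downstream = 100L) {
  peaks <- as.data.table(peaks)
  genes <- gene_tss(genes)
  if (is.null(annotations)) annotations <- nearest_tss(peaks, genes)
  ann <- merge(peaks[, .(peak_id, chrom, summit)],
               as.data.table(annotations), by = "peak_id", sort = FALSE)
  cats <- vapply(seq_len(nrow(ann)), function(i) {
    if (ann$distance[i] >= -promoter_upstream &&
        ann$distance[i] <= promoter_downstream) return("promoter")
    s <- ann$summit[i]
    gg <- genes[chrom == ann$chrom[i] & txStart <= s & s < txEnd]
    if (!nrow(gg)) return("intergenic")
    # prefer the nearest-TSS gene if it contains the summit
    g <- if (ann$gene[i] %in% gg$gene) gg[gene == ann$gene[i]] else gg[1]
    ex <- parse_exons(g)
    setorder(ex, start)
    in_ex <- which(ex$start <= s & s < ex$end)
    if (!length(in_ex)) return("intron")
    first_ex <- if (g$strand == "+") 1L else nrow(ex)
    last_ex <- if (g$strand == "+") nrow(ex) else 1L
    if (in_ex == first_ex) "5'UTR"
    else if (in_ex == last_ex) "3'UTR"
    else "exon"
  }, character(1))
  ann[, category := cats]
  ann[, .(peak_id, gene, distance, category)]
}

#' Select the gene-proximal peak subset
#'
#' Keeps peaks whose summit lies inside a gene body (intron, exon or UTR) or
#' within the extended promoter (up to 5 kb upstream of a TSS) -- i.e. every
#' non-intergenic category.
#'
#' @param peaks peak table.
#' @param annotations output of [classify_genomic_region()].
#' @return subset of \code{peaks}.
#' @export
select_gene_proximal <- function(peaks, annotations) {
  peaks <- as.data.table(peaks)
  ann <- as.data.table(annotations)
  keep <- ann[category != "intergenic", peak_id]
  peaks[peak_id %in% keep]
}
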