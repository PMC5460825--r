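#' Read a FASTA file (case-preserving)
#'
#' Lowercase (soft-masked) bases are preserved as-is, which the motif scanner
#' relies on; duplicate headers are an error.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty FASTA file: %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stopf("FASTA file does not start with a header: %s", path)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  if (anyDuplicated(names_))
    stopf("duplicate sequence name '%s' in %s",
          names_[duplicated(names_)][1], path)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- names_
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED file (BED3/BED6, 0-based half-open)
#'
#' @param path BED path (tab-separated, no header).
#' @param require_strand if TRUE (tag files), a valid strand column is
#'   required.
#' @return data.table with \code{chrom}, \code{start}, \code{end} and, when
#'   present, \code{name}, \code{score}, \code{strand}; sorted by coordinate.
#' @export
read_bed <- function(path, require_strand = FALSE) {
  d <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (!nrow(d)) stopf("empty BED file: %s", path)
  if (ncol(d) < 3) stopf("BED file needs >= 3 columns: %s", path)
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(d, cn[seq_len(min(ncol(d), 6L))])
  for (col in c("start", "end")) {
    v <- d[[col]]
    if (!is.numeric(v) || any(v != floor(v)))
      stopf("non-integer %s coordinate at line %d of %s", col,
            which(!grepl("^[0-9]+$", as.character(v)))[1], path)
  }
  bad <- which(d$start >= d$end)
  if (length(bad))
    stopf("start >= end at line %d of %s", bad[1], path)
  if (require_strand) {
    if (!"strand" %in% names(d) || any(!d$strand %in% c("+", "-")))
      stopf("tag BED requires a +/- strand column: %s", path)
  }
  d[, `:=`(start = as.integer(start), end = as.integer(end))]
  setorder(d, chrom, start, end)
  d[]
}

#' Write intervals/tags as BED
#'
#' @param x data.table with at least \code{chrom}, \code{start}, \code{end};
#'   \code{name}, \code{score}, \code{strand} written when present.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as.data.table(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  out <- x[, ..cols]
  setorder(out, chrom, start, end)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a refFlat-style gene-model table
#'
#' @param path TSV with header: gene, chrom, strand, txStart, txEnd,
#'   exonStarts, exonEnds.
#' @return data.table of gene models.
#' @export
read_gene_models <- function(path) {
  d <- fread(path, sep = "\t", header = TRUE,
             colClasses = list(character = c("exonStarts", "exonEnds")))
  need <- c("gene", "chrom", "strand", "txStart", "txEnd",
            "exonStarts", "exonEnds")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("gene-model table missing column(s): %s",
                          paste(miss, collapse = ", "))
  d[]
}

#' Write a gene-model table
#'
#' @param genes data.table from [simulate_gene_models()] or
#'   [read_gene_models()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  fwrite(as.data.table(genes), path, sep = "\t")
  invisible(path)
}

#' Write a table as TSV with header
#' @param x data.frame/data.table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

write_run_metadata <- function(outdir, config, seed, extra = list()) {
  meta <- c(list(
    package = "grchip",
    version = as.character(utils::packageVersion("grchip")),
    seed = seed,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), extra)
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta)
}
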