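#' Extend reads to fixed-length tags in their 3' direction
#'
#' Plus-strand reads become \code{[start, start+length)}, minus-strand reads
#' \code{[end-length, end)}, clipped to \code{[0, chromosome length)}.
#' Records without a usable strand are dropped with a warning.
#'
#' @param reads data.table/data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}.
#' @param length target tag length in bp (default 150).
#' @param chrom_lengths optional named vector for right-boundary clipping.
#' @return data.table of extended tags (same columns, plus any extras carried
#'   through).
#' @export
extend_tags <- function(reads, length = 150L, chrom_lengths = NULL) {
  tags <- as.data.table(reads)
  ok <- tags$strand %in% c("+", "-")
  if (any(!ok)) {
    warning(sprintf("dropping %d record(s) without strand", sum(!ok)))
    tags <- tags[ok]
  }
  tags <- copy(tags)
  tags[, `:=`(
    start = ifelse(strand == "+", start, pmax(0L, end - as.integer(length))),
    end = ifelse(strand == "+", start + as.integer(length), end)
  )]
  if (!is.null(chrom_lengths)) {
    Lv <- as.integer(chrom_lengths[tags$chrom])
    tags[, end := pmin(end, Lv)]
  }
  tags[, start := pmax(start, 0L)]
  tags[]
}

#' Remove duplicate tags (PCR-bias control)
#'
#' Keeps the first tag per (chromosome, 5' position, strand). The 5' position
#' is \code{start} for plus-strand tags and \code{end} for minus-strand tags,
#' so this is applied before extension in the standard pipeline.
#'
#' @param tags data.table with \code{chrom}, \code{start}, \code{end},
#'   \code{strand}.
#' @return deduplicated data.table; the number removed is reported via
#'   \code{attr(, "removed")}.
#' @export
deduplicate_tags <- function(tags) {
  tags <- as.data.table(tags)
  p5 <- ifelse(tags$strand == "+", tags$start, tags$end)
  keep <- !duplicated(data.table(tags$chrom, p5, tags$strand))
  out <- tags[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Sequencing-depth normalization factor
#'
#' Tags-per-10-million scaling: \code{1e7 / total}.
#'
#' @param total total tag count (> 0).
#' @return numeric factor.
#' @export
depth_normalization_factor <- function(total) {
  if (length(total) != 1 || is.na(total) || total <= 0)
    stopf("total tag count must be a single positive number")
  1e7 / total
}

#' Binned tag-density track
#'
#' Counts each tag once, at the bin containing its midpoint (the default
#' assignment; sufficient for window statistics over 200-bp windows).
#'
#' @param tags data.table with \code{chrom}, \code{start}, \code{end}.
#' @param bin bin size in bp (>= 1), default 50.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return a \code{density_track}: list with \code{bin}, \code{counts} (named
#'   list of per-chromosome integer vectors), \code{total} and
#'   \code{norm_factor} (tags per 10 million).
#' @export
density_track <- function(tags, bin = 50L, chrom_lengths) {
  stopifnot(bin >= 1)
  tags <- as.data.table(tags)
  counts <- lapply(names(chrom_lengths), function(ch) {
    nb <- as.integer(ceiling(chrom_lengths[[ch]] / bin))
    tt <- tags[chrom == ch]
    if (!nrow(tt)) return(integer(nb))
    mid <- (tt$start + tt$end) %/% 2L
    mid <- pmin(pmax(mid, 0L), chrom_lengths[[ch]] - 1L)  # clip strays
    tabulate(mid %/% bin + 1L, nbins = nb)
  })
  names(counts) <- names(chrom_lengths)
  total <- sum(vapply(counts, sum, numeric(1)))
  structure(list(bin = as.integer(bin), counts = counts, total = total,
                 norm_factor = if (total > 0) 1e7 / total else NA_real_,
                 chrom_lengths = chrom_lengths),
            class = "density_track")
}

#' Remove intervals overlapping a repeat mask
#'
#' Drops every record whose interval overlaps a mask interval by >= 1 bp
#' (half-open convention: abutting intervals do not overlap).
#'
#' @param x data.table with \code{chrom}, \code{start}, \code{end}.
#' @param mask data.table of masked intervals (same columns), or NULL/empty
#'   for identity.
#' @return filtered data.table.
#' @export
apply_repeat_mask <- function(x, mask) {
  x <- as.data.table(x)
  if (is.null(mask) || !nrow(as.data.table(mask))) return(x)
  mask <- as.data.table(mask)
  gx <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end))
  gm <- GenomicRanges::GRanges(mask$chrom,
                               IRanges::IRanges(mask$start + 1L, mask$end))
  hit <- GenomicRanges::countOverlaps(gx, gm) > 0
  x[!hit]
}

#' Detect simple tandem repeats in a genome
#'
#' Finds runs of a repeated unit (unit length <= \code{unit_max}) covering at
#' least \code{min_len} bp; used to build a simple-repeat mask for synthetic
#' genomes when no mask BED is supplied.
#'
#' @param genome named character vector of chromosome sequences.
#' @param unit_max maximum repeat-unit length (default 6).
#' @param min_len minimum total repeat length in bp (default 24).
#' @return data.table of masked intervals (\code{chrom}, \code{start},
#'   \code{end}; 0-based half-open), merged.
#' @export
find_simple_repeats <- function(genome, unit_max = 6L, min_len = 24L) {
  res <- lapply(names(genome), function(ch) {
    s <- toupper(genome[[ch]])
    ivs <- list()
    for (u in seq_len(unit_max)) {
      reps <- max(ceiling(min_len / u) - 1L, 1L)
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, reps)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      keep <- len >= min_len
      if (!any(keep)) next
      ivs[[u]] <- data.table(start = as.integer(m[keep]) - 1L,
                             end = as.integer(m[keep]) - 1L + len[keep])
    }
    iv <- rbindlist(ivs)
    if (!nrow(iv)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    data.table(chrom = ch, start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
  })
  out <- rbindlist(res)
  if (!nrow(out))
    out <- data.table(chrom = character(), start = integer(), end = integer())
  out[]
}

#' Soft-mask genome regions (lowercase)
#'
#' Lowercases masked intervals so the motif scanner treats them as
#' non-matching.
#'
#' @param genome named character vector of sequences.
#' @param mask data.table of intervals (\code{chrom}, \code{start},
#'   \code{end}; 0-based half-open).
#' @return genome with masked regions lowercased.
#' @export
mask_genome <- function(genome, mask) {
  mask <- as.data.table(mask)
  if (!nrow(mask)) return(genome)
  for (ch in unique(mask$chrom)) {
    if (!ch %in% names(genome)) next
    gv <- strsplit(genome[[ch]], "")[[1]]
    for (i in which(mask$chrom == ch)) {
      idx <- (mask$start[i] + 1L):mask$end[i]
      idx <- idx[idx >= 1 & idx <= length(gv)]
      gv[idx] <- tolower(gv[idx])
    }
    genome[[ch]] <- paste(gv, collapse = "")
  }
  genome
}
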