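#' Hotspot caller parameters
#'
#' @param window enrichment test window (bp), default 200.
#' @param step window step (bp), default 50; must be a multiple of the track
#'   bin size.
#' @param local_window local background window (bp), default 25000.
#' @param q_threshold BH q-value cutoff for significant windows, default 0.01.
#' @param merge_gap merge significant windows closer than this (bp).
#' @param pseudocount floor on the expected window count.
#' @return a \code{hotspot_params} list.
#' @export
hotspot_params <- function(window = 200L, step = 50L, local_window = 25000L,
                           q_threshold = 0.01, merge_gap = 150L,
                           pseudocount = 1) {
  stopifnot(window >= step, local_window > window, q_threshold > 0,
            q_threshold < 1, merge_gap >= 0, pseudocount > 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 local_window = as.integer(local_window),
                 q_threshold = q_threshold, merge_gap = as.integer(merge_gap),
                 pseudocount = pseudocount),
            class = "hotspot_params")
}

#' Call enriched regions (hotspots) against an input control
#'
#' Slides a window along binned ChIP density; the expected window count is
#' the maximum of (a) the depth-ratio-scaled input count in a local window,
#' (b) the genome-average expectation and (c) a pseudocount. Window
#' significance is the upper-tail binomial probability of the observed count
#' given total ChIP depth; windows at BH q below threshold are merged into
#' peaks. The summit is the centre of the maximum-density bin (leftmost on
#' ties).
#'
#' @param chip_track,input_track \code{density_track}s on the same binning.
#' @param params a \code{hotspot_params}.
#' @param mask optional data.table of masked intervals; overlapping windows
#'   are excluded before testing.
#' @return data.table of peaks: \code{peak_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{summit}, \code{density} (max
#'   window count scaled to tags per 10 million), \code{p}, \code{q}.
#' @export
call_hotspots <- function(chip_track, input_track, params = hotspot_params(),
                          mask = NULL) {
  stopifnot(inherits(chip_track, "density_track"))
  if (chip_track$total == 0) stopf("empty ChIP track")
  bin <- chip_track$bin
  if (!is.null(input_track) && input_track$bin != bin)
    stopf("ChIP and input tracks must share a binning")
  if (params$step %% bin != 0 || params$window %% bin != 0)
    stopf("window and step must be multiples of the bin size (%d)", bin)
  use_input <- !is.null(input_track) && input_track$total > 0
  if (!use_input)
    warning("input track empty; using genome-average background only")
  wpb <- params$window %/% bin
  spb <- params$step %/% bin
  lpb <- params$local_window %/% bin
  genome_len <- sum(as.numeric(chip_track$chrom_lengths))
  ratio <- if (use_input) chip_track$total / input_track$total else NA_real_
  global_exp <- chip_track$total * params$window / genome_len

  win <- rbindlist(lapply(names(chip_track$counts), function(ch) {
    cc <- chip_track$counts[[ch]]
    nb <- length(cc)
    if (nb < wpb) return(NULL)
    obs_all <- frollsum(cc, wpb, align = "left")
    idx <- seq(1L, nb - wpb + 1L, by = spb)
    obs <- obs_all[idx]
    if (use_input) {
      ic <- input_track$counts[[ch]]
      loc_all <- frollsum(ic, min(lpb, nb), align = "center", fill = NA)
      loc <- loc_all[pmin(pmax(idx + wpb %/% 2L, lpb %/% 2L + 1L),
                          nb - lpb %/% 2L)]
      loc[is.na(loc)] <- sum(ic) * min(lpb, nb) / nb
      exp_local <- loc * (wpb / min(lpb, nb)) * ratio
    } else exp_local <- 0
    data.table(chrom = ch, start = (idx - 1L) * bin,
               end = (idx - 1L) * bin + params$window,
               obs = obs, expected = pmax(exp_local, global_exp,
                                          params$pseudocount))
  }))
  if (!is.null(mask)) win <- apply_repeat_mask(win, mask)
  if (!nrow(win)) return(empty_peaks())
  win[, p := pbinom(obs - 1, size = chip_track$total,
                    prob = pmin(expected / chip_track$total, 1),
                    lower.tail = FALSE)]
  win[, q := p.adjust(p, method = "BH")]
  sig <- win[q < params$q_threshold & obs > expected]
  if (!nrow(sig)) return(empty_peaks())
  setorder(sig, chrom, start)
  sig[, grp := cumsum(c(1L, (chrom[-1] != chrom[-.N]) |
                          (start[-1] - end[-.N] > params$merge_gap)))]
  nf <- chip_track$norm_factor
  peaks <- sig[, {
    s <- min(start); e <- max(end)
    cc <- chip_track$counts[[chrom[1]]]
    b1 <- s %/% bin + 1L; b2 <- min((e - 1L) %/% bin + 1L, length(cc))
    summit_bin <- b1 + which.max(cc[b1:b2]) - 1L
    .(start = s, end = e,
      summit = as.integer((summit_bin - 1L) * bin + bin %/% 2L),
      density = max(obs) * nf, p = min(p), q = min(q))
  }, by = .(chrom, grp)][, grp := NULL]
  setorder(peaks, chrom, start)
  peaks[, peak_id := sprintf("peak_%05d", seq_len(.N))]
  peaks[, .(peak_id, chrom, start, end, summit, density, p, q)]
}

empty_peaks <- function() {
  data.table(peak_id = character(), chrom = character(), start = integer(),
             end = integer(), summit = integer(), density = numeric(),
             p = numeric(), q = numeric())
}

peaks_to_granges <- function(p) {
  GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
}

#' Replicate-concordant peaks
#'
#' Keeps genomic regions where a replicate-1 peak and a replicate-2 peak
#' overlap by >= 1 bp; the output interval is the union of the overlapping
#' peaks (chained overlaps merged), the density is the mean of the two
#' replicates' best-window densities in the region, and the summit is taken
#' from the denser constituent peak.
#'
#' @param peaks1,peaks2 peak tables from [call_hotspots()].
#' @return concordant peak data.table (same columns plus \code{density_rep1},
#'   \code{density_rep2}).
#' @export
concordant_peaks <- function(peaks1, peaks2) {
  peaks1 <- as.data.table(peaks1); peaks2 <- as.data.table(peaks2)
  if (!nrow(peaks1) || !nrow(peaks2)) return(empty_peaks())
  g1 <- peaks_to_granges(peaks1); g2 <- peaks_to_granges(peaks2)
  ov <- GenomicRanges::findOverlaps(g1, g2)
  if (!length(ov)) return(empty_peaks())
  pieces <- c(g1[unique(S4Vectors::queryHits(ov))],
              g2[unique(S4Vectors::subjectHits(ov))])
  merged <- GenomicRanges::reduce(pieces)
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged))
  both <- rbind(peaks1[, .(chrom, start, end, summit, density, p, q, rep = 1L)],
                peaks2[, .(chrom, start, end, summit, density, p, q, rep = 2L)])
  gb <- GenomicRanges::GRanges(both$chrom,
                               IRanges::IRanges(both$start + 1L, both$end))
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start + 1L, out$end)),
    gb)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  stats <- rbindlist(lapply(seq_len(nrow(out)), function(i) {
    b <- both[sh[qh == i]]
    d1 <- max(b[rep == 1L, density], -Inf); d2 <- max(b[rep == 2L, density], -Inf)
    if (!is.finite(d1) || !is.finite(d2))
      return(NULL)  # region supported by one replicate only
    best <- b[which.max(b$density)]
    data.table(row = i, summit = best$summit,
               density_rep1 = d1, density_rep2 = d2,
               density = (d1 + d2) / 2, p = min(b$p), q = min(b$q))
  }))
  out <- cbind(out[stats$row], stats[, -"row"])
  setorder(out, chrom, start)
  out[, peak_id := sprintf("peak_%05d", seq_len(.N))]
  out[, .(peak_id, chrom, start, end, summit, density,
          density_rep1, density_rep2, p, q)]
}

#' Keep the top fraction of peaks by tag density
#'
#' Sorts descending by density (ties broken by ascending p then coordinate)
#' and keeps the top \code{ceiling(fraction * n)}, assigning ranks.
#'
#' @param peaks peak data.table with \code{density} and \code{p}.
#' @param fraction fraction in (0, 1]; the analysis default is 0.2.
#' @return ranked subset with a \code{rank} column.
#' @export
rank_top_fraction <- function(peaks, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  peaks <- as.data.table(peaks)
  if (!nrow(peaks)) return(peaks)
  setorder(peaks, -density, p, chrom, start)
  k <- ceiling(fraction * nrow(peaks))
  out <- peaks[seq_len(k)]
  out[, rank := seq_len(.N)]
  out[]
}

#' Pool non-duplicated peaks across groups
#'
#' Merges overlapping intervals across two groups into single records (union
#' coordinates, maximum density, provenance flag A/B/both); non-overlapping
#' records pass through.
#'
#' @param peaks_a,peaks_b group peak tables.
#' @return pooled peak data.table with a \code{source} column.
#' @export
pool_nonduplicated <- function(peaks_a, peaks_b) {
  peaks_a <- as.data.table(peaks_a); peaks_b <- as.data.table(peaks_b)
  both <- rbind(peaks_a[, .(chrom, start, end, summit, density, p, q, src = "A")],
                peaks_b[, .(chrom, start, end, summit, density, p, q, src = "B")])
  if (!nrow(both)) {
    out <- empty_peaks(); out[, source := character(0)]; return(out[])
  }
  gb <- GenomicRanges::GRanges(both$chrom,
                               IRanges::IRanges(both$start + 1L, both$end))
  merged <- GenomicRanges::reduce(gb)
  hit <- GenomicRanges::findOverlaps(merged, gb)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  out <- rbindlist(lapply(seq_along(merged), function(i) {
    b <- both[sh[qh == i]]
    best <- b[which.max(b$density)]
    srcs <- unique(b$src)
    data.table(chrom = as.character(GenomicRanges::seqnames(merged))[i],
               start = GenomicRanges::start(merged)[i] - 1L,
               end = GenomicRanges::end(merged)[i],
               summit = best$summit, density = max(b$density),
               p = min(b$p), q = min(b$q),
               source = if (length(srcs) == 2) "both" else srcs)
  }))
  setorder(out, chrom, start)
  out[, peak_id := sprintf("pool_%05d", seq_len(.N))]
  out[, .(peak_id, chrom, start, end, summit, density, p, q, source)]
}

#' Tag-density matrix around peak summits
#'
#' Rows are peaks sorted by descending density (the heat-map row order);
#' columns are bins across \code{[summit - flank, summit + flank)}; values
#' are depth-normalised tag-midpoint counts. Bins beyond a chromosome end are
#' zero.
#'
#' @param peaks peak table with \code{summit} and \code{density}.
#' @param tags tag data.table (one sample, or several rbind-ed).
#' @param flank half-width in bp (default 3000).
#' @param bin column bin width in bp (default 100).
#' @return numeric matrix, rownames = peak ids in row order.
#' @export
density_heat_matrix <- function(peaks, tags, flank = 3000L, bin = 100L) {
  peaks <- as.data.table(peaks)
  stopifnot(nrow(peaks) > 0, "summit" %in% names(peaks))
  tags <- as.data.table(tags)
  nf <- if (nrow(tags)) 1e7 / nrow(tags) else 1
  setorder(peaks, -density, p, chrom, start)
  nbin <- as.integer(2L * flank / bin)
  mat <- matrix(0, nrow(peaks), nbin,
                dimnames = list(peaks$peak_id,
                                as.character(seq(-flank, flank - bin, by = bin))))
  mids <- tags[, .(chrom, mid = (start + end) %/% 2L)]
  setkey(mids, chrom)
  for (i in seq_len(nrow(peaks))) {
    mm <- mids[.(peaks$chrom[i]), mid]
    mm <- mm[!is.na(mm)]
    rel <- mm - peaks$summit[i]
    rel <- rel[rel >= -flank & rel < flank]
    if (length(rel))
      mat[i, ] <- tabulate((rel + flank) %/% bin + 1L, nbins = nbin) * nf
  }
  mat
}
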