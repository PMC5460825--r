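#' Positional histogram of motif hits around peak summits
#'
#' Counts hit offsets per motif in fixed-width bins over \code{[-range,
#' range)} and reports each motif's median absolute offset (a compact measure
#' of how tightly a motif hugs the binding-site centre).
#'
#' @param hits hit table from [scan_peaks()] (needs \code{motif},
#'   \code{offset}).
#' @param bin bin width in bp (default 10).
#' @param range half-range in bp (default 1000).
#' @return list with \code{histogram} (data.table: motif, bin_start, count)
#'   and \code{median_abs_offset} (data.table: motif, median_abs_offset).
#' @export
positional_histogram <- function(hits, bin = 10L, range = 1000L) {
  hits <- as.data.table(hits)
  breaks <- seq(-range, range, by = bin)
  motifs <- unique(hits$motif)
  hist_tab <- rbindlist(c(list(
    data.table(motif = character(), bin_start = numeric(), count = integer())),
    lapply(motifs, function(m) {
      off <- hits[motif == m & offset >= -range & offset < range, offset]
      data.table(motif = m, bin_start = breaks[-length(breaks)],
                 count = tabulate(findInterval(off, breaks),
                                  nbins = length(breaks) - 1L))
    })))
  med_tab <- if (nrow(hits))
    hits[, .(median_abs_offset = median(abs(offset))), by = motif] else
    data.table(motif = character(), median_abs_offset = numeric())
  list(histogram = hist_tab, median_abs_offset = med_tab)
}

ARCH_FLAGS <- c("has_full_gre", "has_gre_half", "has_nf1_half",
                "has_bhlh", "has_ngre")

composite_label <- function(full, half, nf1, bhlh, ngre) {
  gre <- full | half
  if (gre) {
    if (nf1 && bhlh) "GRE/H+NF1+bHLH"
    else if (nf1) "GRE/H+NF1"
    else if (bhlh) "GRE/H+bHLH"
    else "GRE/H alone"
  } else if (nf1 || bhlh || ngre) "non-GRE motifs only"
  else "none"
}

#' Classify the motif architecture of each peak
#'
#' Sets one boolean flag per motif class (>= 1 hit in the counting window)
#' and a composite-class label. A full-GRE hit implies the half-site flag:
#' the palindrome's 3' arm is itself a half-site.
#'
#' @param hits hit table from [scan_peaks()] over the frequency-counting
#'   window.
#' @param peak_ids character vector of all peak ids (peaks without hits get
#'   all-FALSE flags and label "none").
#' @return data.table: \code{peak_id}, the five \code{has_*} flags,
#'   \code{label}.
#' @export
classify_architecture <- function(hits, peak_ids) {
  hits <- as.data.table(hits)
  arch <- data.table(peak_id = peak_ids)
  for (cl in c("full_gre", "gre_half", "nf1_half", "bhlh", "ngre")) {
    with_hit <- unique(hits[class == cl, peak_id])
    arch[, paste0("has_", cl) := peak_id %in% with_hit]
  }
  arch[has_full_gre == TRUE, has_gre_half := TRUE]
  arch[, label := mapply(composite_label, has_full_gre, has_gre_half,
                         has_nf1_half, has_bhlh, has_ngre)]
  arch[]
}

#' Partition peaks by presence of a full palindromic GRE
#'
#' Splits architectures into peaks with and without a full GRE and reports
#' per-class motif frequencies (fraction of peaks with the flag) in each
#' partition.
#'
#' @param arch output of [classify_architecture()].
#' @return list with \code{with_full_gre}, \code{without_full_gre}
#'   (data.tables) and \code{frequencies} (data.table: partition, class,
#'   fraction).
#' @export
partition_by_full_gre <- function(arch) {
  arch <- as.data.table(arch)
  w <- arch[has_full_gre == TRUE]
  wo <- arch[has_full_gre == FALSE]
  freq_of <- function(d, name) {
    if (!nrow(d)) return(NULL)
    data.table(partition = name,
               class = sub("^has_", "", ARCH_FLAGS),
               fraction = vapply(ARCH_FLAGS, function(f) mean(d[[f]]),
                                 numeric(1)))
  }
  list(with_full_gre = w, without_full_gre = wo,
       frequencies = rbindlist(list(freq_of(w, "with_full_gre"),
                                    freq_of(wo, "without_full_gre"))))
}

#' Motif frequencies in the strongest vs weakest third of peaks
#'
#' Orders peaks by descending tag density, takes the top and bottom
#' \code{floor(n/3)}, and reports per class the fraction of peaks in each
#' stratum carrying the motif.
#'
#' @param peaks peak table with \code{peak_id} and \code{density}.
#' @param arch output of [classify_architecture()].
#' @return list with \code{strata} (data.table: peak_id, stratum) and
#'   \code{frequencies} (data.table: class, top, bottom).
#' @export
stratify_by_strength <- function(peaks, arch) {
  peaks <- as.data.table(peaks)
  if (nrow(peaks) < 3) stopf("need >= 3 peaks to form thirds")
  setorder(peaks, -density)
  k <- nrow(peaks) %/% 3L
  strata <- rbind(
    data.table(peak_id = peaks$peak_id[seq_len(k)], stratum = "top"),
    data.table(peak_id = peaks$peak_id[seq(nrow(peaks) - k + 1L, nrow(peaks))],
               stratum = "bottom"))
  a <- merge(strata, as.data.table(arch), by = "peak_id", sort = FALSE)
  freq <- rbindlist(lapply(ARCH_FLAGS, function(f) {
    data.table(class = sub("^has_", "", f),
               top = mean(a[stratum == "top"][[f]]),
               bottom = mean(a[stratum == "bottom"][[f]]))
  }))
  list(strata = strata, frequencies = freq)
}

#' Composite-class frequencies per strength stratum
#'
#' Fraction of peaks per composite architecture label within each stratum;
#' fractions sum to 1 per stratum.
#'
#' @param arch output of [classify_architecture()].
#' @param strata \code{strata} table from [stratify_by_strength()].
#' @return data.table: \code{stratum}, \code{label}, \code{fraction}.
#' @export
composite_by_strength <- function(arch, strata) {
  a <- merge(as.data.table(strata), as.data.table(arch),
             by = "peak_id", sort = FALSE)
  labs <- sort(unique(a$label))
  out <- a[, {
    n <- .N
    .(label = labs, fraction = vapply(labs, function(l) sum(label == l) / n,
                                      numeric(1)))
  }, by = stratum]
  out[]
}

#' Negative-GRE centrality analysis
#'
#' Restricted to peaks with >= 1 nGRE hit: compares the most central nGRE
#' (minimum absolute offset) with the most central GRE-class hit (full GRE or
#' half-site) per peak, and summarises how many nGRE-containing peaks lack
#' any GRE form and in how many the nGRE is not the most central motif.
#'
#' @param hits hit table from [scan_peaks()] over the histogram window.
#' @return list with \code{per_peak} (peak_id, min_abs_ngre, min_abs_gre,
#'   gre_closer) and \code{summary} (n_with_ngre, n_without_gre,
#'   n_gre_closer, mean_abs_offset per class).
#' @export
ngre_analysis <- function(hits) {
  hits <- as.data.table(hits)
  ngre_peaks <- unique(hits[class == "ngre", peak_id])
  per_peak <- rbindlist(c(list(
    data.table(peak_id = character(), min_abs_ngre = numeric(),
               min_abs_gre = numeric(), gre_closer = logical())),
    lapply(ngre_peaks, function(p) {
      h <- hits[peak_id == p]
      mn <- min(abs(h[class == "ngre", offset]))
      gre_off <- h[class %in% c("full_gre", "gre_half"), offset]
      mg <- if (length(gre_off)) min(abs(gre_off)) else NA_real_
      data.table(peak_id = p, min_abs_ngre = mn, min_abs_gre = mg,
                 gre_closer = !is.na(mg) && mg < mn)
    })))
  class_means <- if (nrow(hits))
    hits[, .(mean_abs_offset = mean(abs(offset))), by = class] else
    data.table(class = character(), mean_abs_offset = numeric())
  list(per_peak = per_peak,
       summary = list(
         n_with_ngre = length(ngre_peaks),
         n_without_gre = sum(is.na(per_peak$min_abs_gre)),
         n_gre_closer = sum(per_peak$gre_closer, na.rm = TRUE),
         mean_abs_offset = class_means))
}

canonical_kmer <- function(k) pmin(k, revcomp(k))

# First-order Markov resample of a sequence (preserves dinucleotide
# frequencies in expectation) -- background model for k-mer enrichment.
markov_shuffle <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  s <- s[s %in% c("A", "C", "G", "T")]
  n <- length(s)
  if (n < 3) return(paste(s, collapse = ""))
  trans <- table(factor(s[-n], levels = c("A", "C", "G", "T")),
                 factor(s[-1], levels = c("A", "C", "G", "T")))
  out <- character(n)
  out[1] <- s[1]
  for (i in 2:n) {
    p <- trans[out[i - 1], ]
    if (sum(p) == 0) p <- rep(1, 4)
    out[i] <- sample(c("A", "C", "G", "T"), 1, prob = p)
  }
  paste(out, collapse = "")
}

#' Simple k-mer enrichment (de novo discovery stand-in)
#'
#' For each width, counts how many foreground vs background sequences contain
#' each k-mer (collapsed with its reverse complement) and ranks k-mers by the
#' hypergeometric upper-tail p-value, BH-adjusted per width. The background
#' defaults to a per-sequence first-order Markov (dinucleotide-frequency)
#' resample of the foreground.
#'
#' @param fg character vector of foreground sequences (peak windows).
#' @param bg optional background sequences; default shuffled foreground.
#' @param widths k-mer widths to score (default 6, 8, 10, 12, 14, 16).
#' @param seed seed for background shuffling.
#' @param max_kmers keep at most this many top k-mers per width (by
#'   foreground count) before testing.
#' @return data.table: \code{width}, \code{kmer} (canonical), \code{fg_with},
#'   \code{bg_with}, \code{p}, \code{q}, ranked by p within width.
#' @export
kmer_enrichment <- function(fg, bg = NULL, widths = c(6L, 8L, 10L, 12L, 14L, 16L),
                            seed = 1L, max_kmers = 2000L) {
  if (is.null(bg)) bg <- with_seed(seed, vapply(fg, markov_shuffle,
                                                character(1), USE.NAMES = FALSE))
  if (any(widths > min(nchar(c(fg, bg)))))
    stopf("k-mer width exceeds the shortest sequence")
  seq_kmer_sets <- function(seqs, k) {
    lapply(seqs, function(s) {
      s <- toupper(s)
      n <- nchar(s)
      if (n < k) return(character(0))
      km <- substring(s, 1:(n - k + 1), k:n)
      km <- km[!grepl("[^ACGT]", km)]
      unique(canonical_kmer(km))
    })
  }
  res <- rbindlist(lapply(widths, function(k) {
    fs <- seq_kmer_sets(fg, k); bs <- seq_kmer_sets(bg, k)
    fg_tab <- sort(table(unlist(fs)), decreasing = TRUE)
    if (!length(fg_tab)) return(NULL)
    fg_tab <- head(fg_tab, max_kmers)
    kms <- names(fg_tab)
    bg_tab <- table(unlist(bs))
    bg_with <- as.integer(bg_tab[kms]); bg_with[is.na(bg_with)] <- 0L
    fg_with <- as.integer(fg_tab)
    nf <- length(fg); nb <- length(bg)
    p <- phyper(fg_with - 1L, fg_with + bg_with,
                nf + nb - fg_with - bg_with, nf, lower.tail = FALSE)
    data.table(width = k, kmer = kms, fg_with = fg_with, bg_with = bg_with,
               p = p, q = bh_adjust(p))
  }))
  if (is.null(res) || !nrow(res))
    return(data.table(width = integer(), kmer = character(),
                      fg_with = integer(), bg_with = integer(),
                      p = numeric(), q = numeric()))
  setorder(res, width, p, -fg_with)
  res[]
}
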