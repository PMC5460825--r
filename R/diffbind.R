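#' Count tags at peaks
#'
#' A tag counts toward a peak iff its midpoint lies in \code{[start, end)}
#' (half-open). Counts are raw integers; normalisation happens downstream via
#' size factors.
#'
#' @param peaks peak table with \code{peak_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @param tag_list named list of tag data.tables (extended, deduplicated),
#'   one per sample.
#' @return integer matrix, peaks x samples.
#' @export
count_tags <- function(peaks, tag_list) {
  peaks <- as.data.table(peaks)
  m <- matrix(0L, nrow(peaks), length(tag_list),
              dimnames = list(peaks$peak_id, names(tag_list)))
  gp <- peaks_to_granges(peaks)
  for (s in seq_along(tag_list)) {
    tt <- as.data.table(tag_list[[s]])
    if (!nrow(tt)) next
    mid <- (tt$start + tt$end) %/% 2L
    gm <- GenomicRanges::GRanges(tt$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
    m[, s] <- GenomicRanges::countOverlaps(gp, gm)
  }
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive peaks of the ratio of that
#' sample's count to the peak's geometric mean across samples.
#'
#' @param counts integer matrix, peaks x samples.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stopf("no peak has positive counts in every sample; add a pseudocount or filter peaks")
  lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2, function(k) median(exp(log(k) - lgm)))
}

#' Per-peak negative-binomial dispersion
#'
#' Method-of-moments dispersion from the within-group variance of
#' size-factor-normalised counts, pooled across groups, with the sampling
#' (shot-noise) component removed, plus a mean-dispersion trend
#' (\code{a0 + a1 / mean}) fitted across all peaks. With
#' \code{sharing = "trend"} (default) the trend value at each peak's base
#' mean is used -- at two replicates per group the per-peak moment estimate
#' is so noisy that taking a per-peak maximum systematically inflates the
#' variance and destroys null calibration. \code{sharing = "max"} gives the
#' conservative per-peak maximum instead. Both are floored at 1e-8. Requires
#' >= 2 replicates per group.
#'
#' @param counts integer matrix, peaks x samples.
#' @param sf size factors from [size_factors()].
#' @param groups factor/character of group labels per sample (two groups).
#' @param sharing \code{"trend"} (default) or \code{"max"}.
#' @return list with \code{dispersion} (final per-peak values),
#'   \code{raw} (per-peak method-of-moments values), \code{trend} (fitted
#'   trend at each peak's base mean) and \code{base_mean}.
#' @export
estimate_dispersion <- function(counts, sf, groups,
                                sharing = c("trend", "max")) {
  sharing <- match.arg(sharing)
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (any(table(groups) < 2))
    stopf("each group needs >= 2 replicates for dispersion estimation")
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  glev <- unique(groups)
  # pooled within-group variance of normalised counts
  ssq <- 0; df <- 0
  for (g in glev) {
    j <- which(groups == g)
    mu_g <- rowMeans(norm[, j, drop = FALSE])
    ssq <- ssq + rowSums((norm[, j, drop = FALSE] - mu_g)^2)
    df <- df + (length(j) - 1)
  }
  w <- ssq / df
  z <- base_mean * mean(1 / sf)      # expected shot noise on the common scale
  raw <- (w - z) / base_mean^2
  raw[!is.finite(raw)] <- 0
  # fit on ALL estimates (negatives included): restricting to positive
  # per-peak values selects upward noise and biases the trend high
  ok <- base_mean > 0
  trend_fun <- NULL
  if (sum(ok) >= 10) {
    fit <- try(suppressWarnings(
      nls(raw ~ a0 + a1 / base_mean,
          data = data.frame(raw = raw[ok], base_mean = base_mean[ok]),
          start = list(a0 = max(median(raw[ok]), 1e-4), a1 = 1),
          control = list(warnOnly = TRUE))), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- coef(fit)
      trend_fun <- function(m) pmax(cf[["a0"]] + cf[["a1"]] / m, 0)
    }
  }
  if (is.null(trend_fun)) {
    med <- max(if (any(ok)) median(raw[ok]) else 0, 0)
    trend_fun <- function(m) rep(med, length(m))
  }
  trend <- trend_fun(pmax(base_mean, 1e-8))
  disp <- if (sharing == "max") pmax(raw, trend, 1e-8) else pmax(trend, 1e-8)
  list(dispersion = disp, raw = raw, trend = trend, base_mean = base_mean)
}

# Exact conditional NB test for one peak: probability, under the null, of
# group-A/group-B splits of the pooled count that are as or less likely than
# the observed split. Group sums are treated as NB with moment-matched size.
nb_exact_p <- function(kA, kB, sA, sB, ssqA, ssqB, alpha, max_enum = 2e6) {
  K <- kA + kB
  if (K == 0) return(1)
  q0 <- K / (sA + sB)
  muA <- q0 * sA; muB <- q0 * sB
  varA <- muA + alpha * q0^2 * ssqA
  varB <- muB + alpha * q0^2 * ssqB
  size_of <- function(mu, v) if (v > mu) mu^2 / (v - mu) else 1e8
  szA <- size_of(muA, varA); szB <- size_of(muB, varB)
  if (K > max_enum) stopf("pooled count %d too large for exact enumeration", K)
  a <- 0:K
  lp <- dnbinom(a, mu = muA, size = szA, log = TRUE) +
    dnbinom(K - a, mu = muB, size = szB, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pobs <- pr[kA + 1]
  sum(pr[pr <= pobs * (1 + 1e-7)]) / sum(pr)
}

#' Negative-binomial exact test for differential binding
#'
#' Per peak, a two-sided conditional test on the split of the pooled count
#' between the two groups: outcome probabilities as or less likely than the
#' observed split are summed under the null (group means proportional to
#' summed size factors, variance from the estimated dispersion). The log2
#' fold change uses normalised group means with a 0.5 pseudocount.
#'
#' @param counts integer matrix, peaks x samples.
#' @param sf size factors.
#' @param dispersions per-peak dispersions (from [estimate_dispersion()]).
#' @param groups two-level group labels per sample; fold change is group 2
#'   vs group 1 (levels in order of first appearance).
#' @return data.table: \code{peak_id}, \code{base_mean}, \code{log2fc},
#'   \code{dispersion}, \code{p}, \code{padj} (BH).
#' @export
nb_test <- function(counts, sf, dispersions, groups) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  glev <- unique(groups)
  if (length(glev) != 2) stopf("exactly two groups required")
  jA <- which(groups == glev[1]); jB <- which(groups == glev[2])
  sA <- sum(sf[jA]); sB <- sum(sf[jB])
  ssqA <- sum(sf[jA]^2); ssqB <- sum(sf[jB]^2)
  kA <- rowSums(counts[, jA, drop = FALSE])
  kB <- rowSums(counts[, jB, drop = FALSE])
  norm <- sweep(counts, 2, sf, "/")
  mA <- rowMeans(norm[, jA, drop = FALSE])
  mB <- rowMeans(norm[, jB, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_p(kA[i], kB[i], sA, sB, ssqA, ssqB, dispersions[i])
  }, numeric(1))
  res <- data.table(
    peak_id = rownames(counts) %||% sprintf("peak_%05d", seq_len(nrow(counts))),
    base_mean = rowMeans(norm),
    log2fc = ifelse(kA + kB == 0, 0, log2((mB + 0.5) / (mA + 0.5))),
    dispersion = dispersions,
    p = ifelse(kA + kB == 0, 1, pmin(p, 1))
  )
  res[, padj := bh_adjust(p)]
  res[]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Between-group intensity concordance (scatter and MA tables)
#'
#' Per peak: \code{x = log2(density_A + 0.5)}, \code{y = log2(density_B +
#' 0.5)}, \code{M = y - x}, \code{A = (x + y)/2}; Pearson r over all peaks.
#'
#' @param dens_a,dens_b per-peak group densities (same length >= 2).
#' @param peak_ids optional ids.
#' @return list with \code{table} (data.table: peak_id, x, y, M, A) and
#'   \code{pearson_r}.
#' @export
intensity_concordance <- function(dens_a, dens_b, peak_ids = NULL) {
  if (length(dens_a) != length(dens_b) || length(dens_a) < 2)
    stopf("need densities for both groups at >= 2 peaks")
  x <- log2(dens_a + 0.5); y <- log2(dens_b + 0.5)
  tab <- data.table(
    peak_id = peak_ids %||% sprintf("peak_%05d", seq_along(x)),
    x = x, y = y, M = y - x, A = (x + y) / 2)
  list(table = tab, pearson_r = cor(x, y))
}
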