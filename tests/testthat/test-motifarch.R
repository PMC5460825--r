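library(data.table)

hit_row <- function(peak, class, offset, motif = class) {
  data.table(peak_id = peak, motif = motif, class = class, offset = offset,
             strand = "+", text = "X")
}

test_that("positional histograms bin offsets and report central tendency", {
  hits <- rbind(hit_row("p1", "full_gre", 0), hit_row("p2", "full_gre", 0),
                hit_row("p3", "full_gre", 0))
  h <- positional_histogram(hits, bin = 10L, range = 1000L)
  tab <- h$histogram[motif == "full_gre"]
  expect_equal(sum(tab$count), 3L)
  expect_equal(tab[count > 0, bin_start], 0)      # single central bin
  expect_equal(h$median_abs_offset$median_abs_offset, 0)
  # empty hit list -> all-zero histogram
  h0 <- positional_histogram(hits[0])
  expect_equal(nrow(h0$histogram), 0L)
})

test_that("tightly planted GREs sit closer to summits than NF-1 sites", {
  sim <- small_sim()
  hits <- scan_peaks(sim$genome, sim$peaks, halfwidth = 1000L)
  h <- positional_histogram(hits)
  med <- h$median_abs_offset
  expect_lt(med[motif == "full_GRE", median_abs_offset],
            med[motif == "NF1_half", median_abs_offset])
})

test_that("architecture flags and composite labels follow the stated rules", {
  hits <- rbind(
    hit_row("p1", "full_gre", 0), hit_row("p1", "gre_half", 3),
    hit_row("p2", "gre_half", 0), hit_row("p2", "nf1_half", 20),
    hit_row("p3", "nf1_half", 10),
    hit_row("p4", "gre_half", 0), hit_row("p4", "nf1_half", 5),
    hit_row("p4", "bhlh", -30))
  arch <- classify_architecture(hits, c("p1", "p2", "p3", "p4", "p5"))
  expect_equal(arch$label,
               c("GRE/H alone", "GRE/H+NF1", "non-GRE motifs only",
                 "GRE/H+NF1+bHLH", "none"))
  # full GRE implies the half-site flag even without a separate half hit
  only_full <- classify_architecture(hit_row("q1", "full_gre", 0), "q1")
  expect_true(only_full$has_gre_half)
  expect_equal(only_full$label, "GRE/H alone")
})

test_that("full-GRE partition is disjoint with valid frequencies", {
  sim <- small_sim()
  hits <- scan_peaks(sim$genome, sim$peaks, halfwidth = 100L)
  arch <- classify_architecture(hits, sim$peaks$peak_id)
  part <- partition_by_full_gre(arch)
  expect_equal(nrow(part$with_full_gre) + nrow(part$without_full_gre),
               nrow(arch))
  expect_equal(intersect(part$with_full_gre$peak_id,
                         part$without_full_gre$peak_id), character(0))
  expect_true(all(part$frequencies$fraction >= 0 &
                    part$frequencies$fraction <= 1))
  # half-site frequency among no-full-GRE peaks matches the planted ratio
  cc <- sim$config$counts
  expect_equal(part$frequencies[partition == "without_full_gre" &
                                  class == "gre_half", fraction],
               unname(cc["gre_half"]) /
                 (nrow(arch) - unname(cc["full_gre"])))
})

test_that("strength strata have floor(n/3) peaks and symmetric behaviour", {
  arch <- classify_architecture(
    rbind(hit_row("p1", "gre_half", 0), hit_row("p2", "gre_half", 0)),
    sprintf("p%d", 1:9))
  peaks <- data.table(peak_id = sprintf("p%d", 1:9), density = 9:1)
  st <- stratify_by_strength(peaks, arch)
  expect_equal(sum(st$strata$stratum == "top"), 3L)
  expect_equal(sum(st$strata$stratum == "bottom"), 3L)
  # all peaks identical -> equal frequencies in both strata
  arch_same <- classify_architecture(
    rbindlist(lapply(sprintf("p%d", 1:9), hit_row, class = "gre_half",
                     offset = 0)), sprintf("p%d", 1:9))
  st2 <- stratify_by_strength(peaks, arch_same)
  expect_equal(st2$frequencies[class == "gre_half", top],
               st2$frequencies[class == "gre_half", bottom])
  expect_error(stratify_by_strength(peaks[1:2], arch), ">= 3")
})

test_that("composite-class fractions are a distribution per stratum", {
  sim <- small_sim()
  hits <- scan_peaks(sim$genome, sim$peaks, halfwidth = 100L)
  arch <- classify_architecture(hits, sim$peaks$peak_id)
  peaks <- as.data.table(sim$peaks)
  st <- stratify_by_strength(peaks, arch)
  comp <- composite_by_strength(arch, st$strata)
  sums <- comp[, sum(fraction), by = stratum]$V1
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  # single label present -> fraction 1
  one <- composite_by_strength(
    classify_architecture(hit_row("p1", "full_gre", 0), "p1"),
    data.table(peak_id = "p1", stratum = "top"))
  expect_equal(one$fraction, 1)
})

test_that("nGRE centrality report matches the planted truth", {
  # constructed cases
  hits <- rbind(hit_row("p1", "ngre", 300), hit_row("p1", "gre_half", 10),
                hit_row("p2", "ngre", 40),
                hit_row("p3", "gre_half", 5))
  out <- ngre_analysis(hits)
  expect_equal(out$summary$n_with_ngre, 2L)
  expect_equal(out$summary$n_without_gre, 1L)      # p2 has only an nGRE
  expect_true(out$per_peak[peak_id == "p1", gre_closer])
  # synthetic set: counts equal the truth table's co-occurrence structure
  sim <- small_sim()
  hits2 <- scan_peaks(sim$genome, sim$peaks, halfwidth = 1000L)
  out2 <- ngre_analysis(hits2)
  tr <- sim$truth
  expect_equal(out2$summary$n_with_ngre, sum(tr$has_ngre))
  expect_equal(out2$summary$n_without_gre,
               sum(tr$has_ngre & !tr$has_gre_half & !tr$has_full_gre))
})

test_that("k-mer enrichment recovers a planted 12-mer and canonicalizes", {
  withr::with_seed(11, {
    core <- "ACATGCTGTTCT"
    fg <- vapply(1:60, function(i) {
      s <- rand_seq(80, seed = 1000 + i)
      paste0(substr(s, 1, 30), core, substr(s, 43, 80))
    }, character(1))
    bg <- vapply(1:60, function(i) rand_seq(80, seed = 2000 + i), character(1))
    res <- kmer_enrichment(fg, bg, widths = 12L, seed = 3)
    top <- res[order(p)][1]
    expect_equal(top$kmer, min(core, revcomp(core)))
    expect_lt(top$p, 1e-10)
  })
  # fg == bg -> no significant k-mer
  same <- rand_seq(200, seed = 5)
  res0 <- kmer_enrichment(rep(same, 10), rep(same, 10), widths = 6L)
  expect_true(all(res0$q >= 0.99))
  # reverse-complement pair counted under one canonical key
  res_rc <- kmer_enrichment(c("AAAAAATTTTTT"), c("GGGGGGGGGGGG"), widths = 6L)
  expect_false(any(duplicated(res_rc$kmer)))
  expect_true("AAAAAA" %in% res_rc$kmer)
  expect_error(kmer_enrichment("ACGT", widths = 6L), "width")
})
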