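library(data.table)

uniform_tags <- function(n, L, seed, chrom = "chr1") {
  withr::with_seed(seed, {
    st <- sort(sample.int(L - 150L, n, replace = TRUE))
    data.table(chrom = chrom, start = st, end = st + 150L,
               strand = sample(c("+", "-"), n, TRUE))
  })
}

sim_tracks <- function(truth, L = 1e6L, depth = 80, bg = 0.05, seed = 50) {
  params <- read_sim_params(depth = depth, background_rate = bg)
  tt <- simulate_tags(c(chr1 = L), truth, params, n_replicates = 1L,
                      n_conditions = 1L, seed = seed)
  prep <- lapply(tt, function(x)
    extend_tags(deduplicate_tags(x), 150L, c(chr1 = L)))
  lapply(prep, density_track, bin = 50L, chrom_lengths = c(chr1 = L))
}

test_that("uniform ChIP equal to input yields zero peaks", {
  L <- 5e5L
  chip <- density_track(uniform_tags(20000, L, 1), 50L, c(chr1 = L))
  input <- density_track(uniform_tags(20000, L, 2), 50L, c(chr1 = L))
  pk <- call_hotspots(chip, input)
  expect_equal(nrow(pk), 0L)
})

test_that("input-only samples yield zero calls at default thresholds", {
  truth <- data.table(site_id = "s1", chrom = "chr1", center = 5e5L,
                      enrichment_weight = 4)
  trk <- sim_tracks(truth, seed = 51)
  pk <- call_hotspots(trk$input_c1_r1, trk$chip_c1_r1)  # roles swapped on purpose
  expect_equal(nrow(pk), 0L)
})

test_that("a strongly enriched planted site is called as one containing peak", {
  truth <- data.table(site_id = "s1", chrom = "chr1", center = 5e5L,
                      enrichment_weight = 5)
  trk <- sim_tracks(truth, seed = 52)
  pk <- call_hotspots(trk$chip_c1_r1, trk$input_c1_r1)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$start <= 5e5 & 5e5 < pk$end)
  expect_lt(abs(pk$summit - 5e5), 200)
})

test_that("peak calls are stable under doubling of sequencing depth", {
  truth <- data.table(site_id = sprintf("s%d", 1:5), chrom = "chr1",
                      center = as.integer(seq(1e5, 9e5, length.out = 5)),
                      enrichment_weight = c(2, 3, 4, 3, 2))
  params <- read_sim_params(depth = 80, background_rate = 0.05)
  t1 <- simulate_tags(c(chr1 = 1e6L), truth, params, 1L, 1L, seed = 60)
  t2 <- simulate_tags(c(chr1 = 1e6L), truth, params, 1L, 1L, seed = 61)
  prep <- function(x) extend_tags(deduplicate_tags(x), 150L, c(chr1 = 1e6L))
  chip1 <- density_track(prep(t1$chip_c1_r1), 50L, c(chr1 = 1e6L))
  inp1 <- density_track(prep(t1$input_c1_r1), 50L, c(chr1 = 1e6L))
  chip2 <- density_track(rbind(prep(t1$chip_c1_r1), prep(t2$chip_c1_r1)),
                         50L, c(chr1 = 1e6L))
  inp2 <- density_track(rbind(prep(t1$input_c1_r1), prep(t2$input_c1_r1)),
                        50L, c(chr1 = 1e6L))
  pk1 <- call_hotspots(chip1, inp1)
  pk2 <- call_hotspots(chip2, inp2)
  # same sites recovered at both depths
  hit <- function(pk) vapply(truth$center, function(ct)
    any(pk$start <= ct & ct < pk$end), logical(1))
  expect_equal(hit(pk1), hit(pk2))
  expect_true(all(hit(pk1)))
})

test_that("replicate concordance keeps overlaps and unions the pair", {
  p1 <- data.table(peak_id = "a", chrom = "chr1", start = 100L, end = 300L,
                   summit = 200L, density = 10, p = 1e-6, q = 1e-5)
  p2 <- data.table(peak_id = "b", chrom = "chr1", start = 250L, end = 500L,
                   summit = 350L, density = 8, p = 1e-5, q = 1e-4)
  out <- concordant_peaks(p1, p2)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 500L)
  expect_equal(out$density, 9)           # mean of replicate densities
  # idempotence on identical lists
  same <- concordant_peaks(p1, p1)
  expect_equal(nrow(same), 1L)
  expect_equal(same$start, 100L); expect_equal(same$end, 300L)
  # disjoint lists -> empty
  p3 <- copy(p2)[, `:=`(start = 1000L, end = 1200L, summit = 1100L)]
  expect_equal(nrow(concordant_peaks(p1, p3)), 0L)
})

test_that("top-fraction ranking sorts by density with stated tie-breaks", {
  pk <- data.table(peak_id = sprintf("p%02d", 1:10), chrom = "chr1",
                   start = seq(0L, 9000L, by = 1000L),
                   end = seq(200L, 9200L, by = 1000L),
                   summit = seq(100L, 9100L, by = 1000L),
                   density = c(5, 9, 9, 1, 2, 3, 4, 6, 7, 8),
                   p = c(0.5, 1e-4, 1e-6, rep(0.01, 7)),
                   q = rep(0.005, 10))
  top <- rank_top_fraction(pk, 0.2)
  expect_equal(nrow(top), 2L)
  # equal densities at the cut: lower p wins rank 1
  expect_equal(top$peak_id, c("p03", "p02"))
  expect_equal(top$rank, 1:2)
  all_ranked <- rank_top_fraction(pk, 1.0)
  expect_equal(nrow(all_ranked), 10L)
  expect_equal(all_ranked$density, sort(pk$density, decreasing = TRUE))
})

test_that("pooling merges overlaps across groups and flags provenance", {
  a <- data.table(peak_id = "a", chrom = "chr1", start = 0L, end = 200L,
                  summit = 100L, density = 5, p = 1e-4, q = 1e-3)
  b <- data.table(peak_id = "b", chrom = "chr1", start = 100L, end = 400L,
                  summit = 250L, density = 7, p = 1e-5, q = 1e-4)
  out <- pool_nonduplicated(a, b)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 0L); expect_equal(out$end, 400L)
  expect_equal(out$source, "both")
  expect_equal(out$density, 7)           # max across groups
  # identical lists -> one copy; disjoint lists -> a + b records
  expect_equal(nrow(pool_nonduplicated(a, a)), 1L)
  far <- copy(b)[, `:=`(start = 5000L, end = 5400L, summit = 5200L)]
  out2 <- pool_nonduplicated(a, far)
  expect_equal(nrow(out2), 2L)
  expect_setequal(out2$source, c("A", "B"))
})

test_that("heat-map matrix rows follow density order with central maxima", {
  truth <- data.table(site_id = c("s1", "s2"), chrom = "chr1",
                      center = c(3e5L, 7e5L), enrichment_weight = c(5, 3))
  params <- read_sim_params(depth = 100, background_rate = 0.01)
  tt <- simulate_tags(c(chr1 = 1e6L), truth, params, 1L, 1L, seed = 71)
  tags <- extend_tags(deduplicate_tags(tt$chip_c1_r1), 150L, c(chr1 = 1e6L))
  peaks <- data.table(peak_id = c("pk_weak", "pk_strong"), chrom = "chr1",
                      start = c(699800L, 299800L), end = c(700200L, 300200L),
                      summit = c(7e5L, 3e5L), density = c(3, 5), p = 1, q = 1)
  m <- density_heat_matrix(peaks, tags, flank = 3000L, bin = 100L)
  expect_equal(rownames(m), c("pk_strong", "pk_weak"))  # density order
  centre_bins <- 28:33
  for (i in 1:2)
    expect_true(which.max(m[i, ]) %in% centre_bins)
  # no tags -> zero row
  m0 <- density_heat_matrix(peaks, tags[0], flank = 3000L, bin = 100L)
  expect_true(all(m0 == 0))
})
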