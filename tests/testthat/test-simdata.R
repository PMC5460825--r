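library(data.table)

test_that("background genome is motif-free and deterministic", {
  lib <- default_motif_library()
  g1 <- generate_background_genome(5e4, 0.42, lib, seed = 9)
  g2 <- generate_background_genome(5e4, 0.42, lib, seed = 9)
  expect_identical(g1, g2)                       # same seed -> same genome
  g3 <- generate_background_genome(5e4, 0.42, lib, seed = 10)
  expect_false(identical(g1, g3))
  # independent exhaustive scan: zero hits for every library motif
  for (m in lib) for (p in m$patterns) {
    expect_equal(nrow(oracle_scan(g1[[1]], p)), 0L, info = p)
  }
})

test_that("a 6-mer half-site library yields a clean megabase by regex scan", {
  lib <- list(half = compile_motif("half", "TGTYCT", class = "gre_half"))
  g <- generate_background_genome(1e6, 0.42, lib, seed = 21)
  expect_equal(nrow(oracle_scan(g[[1]], "TGTYCT")), 0L)
})

test_that("exact-count planting recovers the configured composition", {
  sim <- small_sim()
  tr <- sim$truth
  cc <- sim$config$counts
  expect_equal(sum(tr$has_full_gre), unname(cc["full_gre"]))
  expect_equal(sum(tr$has_gre_half & !tr$has_full_gre), unname(cc["gre_half"]))
  expect_equal(sum(tr$has_nf1_half), unname(cc["nf1_half"]))
  expect_equal(sum(tr$has_bhlh), unname(cc["bhlh"]))
  expect_equal(sum(tr$has_ngre), unname(cc["ngre"]))
  # nGRE co-occurrence structure
  expect_equal(sum(tr$has_ngre & !tr$has_gre_half), 2L)
  # scanning the planted genome recovers the flags exactly
  hits <- scan_peaks(sim$genome, sim$peaks, halfwidth = 100)
  arch <- classify_architecture(hits, sim$peaks$peak_id)
  m <- merge(arch, tr, by.x = "peak_id", by.y = "site_id")
  for (f in c("has_full_gre", "has_gre_half", "has_nf1_half", "has_bhlh",
              "has_ngre"))
    expect_equal(m[[paste0(f, ".x")]], m[[paste0(f, ".y")]], info = f)
})

test_that("a planted full GRE always carries a half-site hit", {
  sim <- small_sim()
  hits <- scan_peaks(sim$genome, sim$peaks, halfwidth = 100)
  full_peaks <- sim$truth[sim$truth$has_full_gre == TRUE, site_id]
  half_hit_peaks <- unique(hits[class == "gre_half", peak_id])
  expect_true(all(full_peaks %in% half_hit_peaks))
})

test_that("enrichment weight is 1 plus the sum of planted class weights", {
  sim <- small_sim()
  w <- sim$config$weights
  inst <- as.data.table(sim$instances)
  expected <- inst[, .(wsum = sum(w[class])), by = site_id]
  m <- merge(sim$truth, expected, by = "site_id", all.x = TRUE)
  m$wsum[is.na(m$wsum)] <- 0
  expect_equal(m$enrichment_weight, 1 + m$wsum)
})

test_that("planting nothing leaves the genome unchanged", {
  g <- generate_background_genome(5e4, 0.42, seed = 31)
  cfg <- composition_config(n_sites = 10)
  ps <- plant_sites(g, cfg, seed = 32)
  expect_identical(ps$genome, g)
  expect_equal(nrow(ps$truth), 10L)
  expect_equal(nrow(ps$instances), 0L)
  expect_true(all(ps$truth$enrichment_weight == 1))
})

test_that("planting errors when the genome cannot hold the sites", {
  g <- generate_background_genome(2e4, 0.42, seed = 33)
  cfg <- composition_config(n_sites = 500)
  expect_error(plant_sites(g, cfg, seed = 1), "too small")
})

test_that("simulated ChIP counts scale with enrichment weight", {
  # two sites, weights w and 2w: mean tag counts ratio ~ 2 over replicates
  truth <- data.table(site_id = c("s1", "s2"), chrom = "chr1",
                      center = c(30000L, 70000L),
                      enrichment_weight = c(2, 4),
                      has_full_gre = TRUE, has_gre_half = TRUE,
                      has_nf1_half = FALSE, has_bhlh = FALSE, has_ngre = FALSE)
  params <- read_sim_params(depth = 100, background_rate = 0.001)
  counts <- matrix(0, 20, 2)
  for (i in 1:20) {
    tt <- simulate_tags(c(chr1 = 1e5L), truth, params, n_replicates = 1L,
                        n_conditions = 1L, seed = 1000 + i)$chip_c1_r1
    for (j in 1:2)
      counts[i, j] <- sum(tt$chrom == "chr1" &
                            abs((tt$start + tt$end) / 2 - truth$center[j]) < 500)
  }
  ratio <- mean(counts[, 2]) / mean(counts[, 1])
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)
  # Poisson expectation check for site 1: depth * weight = 200
  expect_gt(mean(counts[, 1]), 200 * 0.85)
  expect_lt(mean(counts[, 1]), 200 * 1.15)
})

test_that("null condition effect gives equal expected counts across conditions", {
  sim <- small_sim()
  params <- read_sim_params(depth = 60, background_rate = 0.01)
  tt <- simulate_tags(vapply(sim$genome, nchar, integer(1)), sim$truth,
                      params, seed = 77)
  expect_named(tt, c("chip_c1_r1", "input_c1_r1", "chip_c1_r2", "input_c1_r2",
                     "chip_c2_r1", "input_c2_r1", "chip_c2_r2", "input_c2_r2"),
               ignore.order = TRUE)
  n1 <- nrow(tt$chip_c1_r1) + nrow(tt$chip_c1_r2)
  n2 <- nrow(tt$chip_c2_r1) + nrow(tt$chip_c2_r2)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.05)   # same expectation, Poisson noise
  # determinism: identical seeds give byte-identical tag tables
  tt2 <- simulate_tags(vapply(sim$genome, nchar, integer(1)), sim$truth,
                       params, seed = 77)
  expect_identical(tt, tt2)
  # input is background only: fewer tags than ChIP, no site structure
  expect_lt(nrow(tt$input_c1_r1), nrow(tt$chip_c1_r1))
})

test_that("gene models are non-overlapping, strand-aware and round-trip", {
  gm <- simulate_gene_models(c(chr1 = 1e6L), 3L, seed = 5)
  expect_equal(nrow(gm), 3L)
  setorder(gm, txStart)
  expect_true(all(gm$txStart[-1] >= gm$txEnd[-nrow(gm)]))  # non-overlapping
  # exons within the gene body
  for (i in seq_len(nrow(gm))) {
    es <- as.integer(strsplit(gm$exonStarts[i], ",")[[1]])
    ee <- as.integer(strsplit(gm$exonEnds[i], ",")[[1]])
    expect_true(all(es < ee))
    expect_equal(es[1], gm$txStart[i])
    expect_equal(ee[length(ee)], gm$txEnd[i])
  }
  f <- tempfile(fileext = ".tsv")
  write_gene_models(gm, f)
  back <- read_gene_models(f)
  expect_equal(as.data.frame(back), as.data.frame(gm))
})
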