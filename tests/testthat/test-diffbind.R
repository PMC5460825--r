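library(data.table)

test_that("tag counting uses midpoints and half-open peak intervals", {
  peaks <- data.table(peak_id = "p1", chrom = "chr1", start = 100L, end = 200L)
  mk <- function(starts) data.table(chrom = "chr1", start = starts,
                                    end = starts + 10L, strand = "+")
  # midpoint = start + 5
  inside <- mk(c(95L, 100L, 180L, 189L))       # midpoints 100,105,185,194
  at_end <- mk(195L)                           # midpoint 200 -> excluded
  cnt <- count_tags(peaks, list(s1 = rbind(inside, at_end)))
  expect_equal(unname(cnt[1, 1]), 4L)
  expect_equal(unname(count_tags(peaks, list(s1 = inside[0]))[1, 1]), 0L)
})

test_that("size factors follow the median-of-ratios definition", {
  k <- matrix(c(10, 20, 40, 80, 10, 20, 40, 80), ncol = 2)
  expect_equal(unname(size_factors(k)), c(1, 1))
  k2 <- cbind(k[, 1], 2 * k[, 1])
  expect_equal(unname(size_factors(k2)), c(1 / sqrt(2), sqrt(2)))
  # scaling all counts leaves normalized counts invariant
  sf1 <- size_factors(k2); sf3 <- size_factors(3 * k2)
  n1 <- sweep(k2, 2, sf1, "/"); n3 <- sweep(3 * k2, 2, sf3, "/")
  expect_equal(n3 / n1, matrix(3, nrow(k2), 2))  # common scale only
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("dispersion estimates shrink toward zero for Poisson counts", {
  spread <- function(nrep, seed) {
    withr::with_seed(seed, {
      mu <- rep(200, 300)
      k <- matrix(rpois(300 * 2 * nrep, mu), nrow = 300)
      groups <- rep(c("A", "B"), each = nrep)
      est <- estimate_dispersion(k, rep(1, 2 * nrep), groups)
      c(raw = median(abs(est$raw)), final = median(est$dispersion))
    })
  }
  s2 <- spread(2, 1); s10 <- spread(10, 2); s40 <- spread(40, 3)
  # per-peak moment estimates concentrate on the true value 0 ...
  expect_gt(s2["raw"], s10["raw"])
  expect_gt(s10["raw"], s40["raw"])
  expect_lt(s40["raw"], 0.005)
  # ... and the shared dispersion used for testing is already near zero
  expect_lt(s2["final"], 0.01)
  expect_lt(s40["final"], 0.01)
})

test_that("dispersion never goes negative when variance < mean", {
  k <- matrix(c(100, 100, 100, 100), nrow = 1)  # zero variance
  est <- estimate_dispersion(rbind(k, k + c(0, 5, -5, 0)), rep(1, 4),
                             c("A", "A", "B", "B"))
  expect_true(all(est$dispersion >= 1e-8))
})

test_that("known NB dispersion is recovered within 2x at 50 peaks", {
  withr::with_seed(99, {
    alpha <- 0.1
    mu <- runif(50, 100, 500)
    k <- sapply(1:8, function(j) rnbinom(50, mu = mu, size = 1 / alpha))
    est <- estimate_dispersion(k, rep(1, 8), rep(c("A", "B"), each = 4))
    expect_gt(median(est$dispersion), alpha / 2)
    expect_lt(median(est$dispersion), alpha * 2)
  })
})

test_that("single-replicate groups are rejected", {
  k <- matrix(rpois(30, 100), ncol = 3)
  expect_error(estimate_dispersion(k, rep(1, 3), c("A", "A", "B")),
               "replicates")
})

test_that("NB exact test matches brute-force enumeration to 1e-10", {
  withr::with_seed(7, {
    sf <- c(0.9, 1.1, 1.05, 0.95)
    sA <- sum(sf[1:2]); sB <- sum(sf[3:4])
    ssqA <- sum(sf[1:2]^2); ssqB <- sum(sf[3:4]^2)
    cases <- data.table(kA = c(0L, 3L, 50L, 100L, 77L, 100L),
                        kB = c(0L, 7L, 50L, 0L, 123L, 100L),
                        alpha = c(0.1, 0.05, 0.01, 0.05, 0.2, 1e-8))
    for (i in seq_len(nrow(cases))) {
      counts <- matrix(c(cases$kA[i], 0L, cases$kB[i], 0L), nrow = 1)
      counts[1, 2] <- 0L  # put full group sums in one replicate each
      res <- nb_test(matrix(c(cases$kA[i], 0, cases$kB[i], 0), 1), sf,
                     cases$alpha[i], c("A", "A", "B", "B"))
      want <- oracle_exact_p(cases$kA[i], cases$kB[i], sA, sB, ssqA, ssqB,
                             cases$alpha[i])
      expect_lt(abs(res$p - want), 1e-10)
    }
  })
})

test_that("balanced splits give p = 1 and extreme splits tiny p", {
  sf <- rep(1, 4); groups <- c("A", "A", "B", "B")
  bal <- nb_test(matrix(c(50, 50, 50, 50), 1), sf, 0.01, groups)
  expect_equal(bal$p, 1)
  expect_equal(bal$log2fc, 0)
  ext <- nb_test(matrix(c(100, 100, 0, 0), 1), sf, 0.01, groups)
  expect_lt(ext$p, 0.01)
  expect_lt(ext$log2fc, -2)
  zero <- nb_test(matrix(0, 1, 4), sf, 0.01, groups)
  expect_equal(zero$p, 1); expect_equal(zero$log2fc, 0)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  # monotone in rank
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))
})

test_that("4-fold differential sites at dispersion 0.05 are detected", {
  withr::with_seed(1234, {
    n <- 200
    muA <- runif(n, 100, 400)
    fc <- rep(1, n); fc[1:50] <- 4
    k <- cbind(rnbinom(n, mu = muA, size = 20), rnbinom(n, mu = muA, size = 20),
               rnbinom(n, mu = muA * fc, size = 20),
               rnbinom(n, mu = muA * fc, size = 20))
    groups <- c("A", "A", "B", "B")
    sf <- size_factors(k)
    disp <- estimate_dispersion(k, sf, groups)
    res <- nb_test(k, sf, disp$dispersion, groups)
    expect_gte(mean(res$padj[1:50] < 0.05), 0.9)
    expect_lte(mean(res$padj[51:n] < 0.05), 0.05)
  })
})

test_that("intensity concordance reproduces exact scatter/MA identities", {
  d <- c(1, 3, 7, 15)
  same <- intensity_concordance(d, d)
  expect_equal(same$pearson_r, 1)
  expect_true(all(same$table$M == 0))
  doubled <- intensity_concordance(d, 2 * d + 0.5)  # y = x + 1 in log2
  expect_equal(doubled$pearson_r, 1, tolerance = 1e-3)
  expect_equal(mean(doubled$table$M), 1, tolerance = 0.2)
  expect_error(intensity_concordance(1, 2), "2 peaks")
})
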