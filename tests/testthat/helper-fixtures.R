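# Shared fixtures: small synthetic datasets built in code at test time.

# Random ACGT string (uniform base composition unless gc given).
rand_seq <- function(n, seed = 1, gc = 0.5) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

# Independent brute-force IUPAC scanner used as the oracle for scan_interval:
# regex with lookahead on both strands, palindrome dedup by interval.
oracle_scan <- function(seq, pattern) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
             D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  to_re <- function(p) paste(iupac[strsplit(toupper(p), "")[[1]]], collapse = "")
  w <- nchar(pattern)
  find <- function(s, p) {
    m <- gregexpr(paste0("(?=", to_re(p), ")"), gsub("[a-z]", "X", s),
                  perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  fwd <- find(seq, pattern)
  rc <- grchip::revcomp(seq)
  n <- nchar(seq)
  rev_ <- rev(n - (find(rc, pattern) + w - 1L) + 1L)
  hits <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+") else NULL,
    if (length(rev_)) data.frame(start = sort(rev_), strand = "-") else NULL)
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  hits$end <- hits$start + w - 1L
  # palindrome dedup: identical interval on both strands -> keep '+'
  dup <- hits$strand == "-" &
    paste(hits$start, hits$end) %in%
    paste(hits$start[hits$strand == "+"], hits$end[hits$strand == "+"])
  hits <- hits[!dup, c("start", "end", "strand")]
  hits[order(hits$start, hits$strand), ]
}

# Small planted dataset reused across module tests (cheap: ~40 sites, 200 kb).
small_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- generate_background_genome(2e5, 0.42, seed = 404)
    cfg <- composition_config(n_sites = 40, full_gre = 18, gre_half = 14,
                              nf1_half = 20, bhlh = 8, ngre = 5,
                              ngre_without_gre = 2)
    ps <- plant_sites(g, cfg, seed = 405)
    cache <<- list(genome = ps$genome, truth = ps$truth,
                   instances = ps$instances, config = cfg,
                   peaks = data.frame(peak_id = ps$truth$site_id,
                                      chrom = ps$truth$chrom,
                                      summit = ps$truth$center,
                                      density = ps$truth$enrichment_weight))
    cache
  }
})

# Independent brute-force oracle for the NB exact test: enumerate every split
# a + (K - a) = K and sum the probabilities of outcomes as or less likely
# than the observed one.
oracle_exact_p <- function(kA, kB, sA, sB, ssqA, ssqB, alpha) {
  K <- kA + kB
  if (K == 0) return(1)
  q0 <- K / (sA + sB)
  muA <- q0 * sA; muB <- q0 * sB
  vA <- muA + alpha * q0^2 * ssqA; vB <- muB + alpha * q0^2 * ssqB
  szA <- if (vA > muA) muA^2 / (vA - muA) else 1e8
  szB <- if (vB > muB) muB^2 / (vB - muB) else 1e8
  pr <- numeric(K + 1)
  for (a in 0:K)
    pr[a + 1] <- dnbinom(a, mu = muA, size = szA) *
      dnbinom(K - a, mu = muB, size = szB)
  sum(pr[pr <= pr[kA + 1] * (1 + 1e-7)]) / sum(pr)
}
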