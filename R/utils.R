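#' @importFrom data.table data.table as.data.table setDT setorder := rbindlist
#'   fread fwrite setnames copy frollsum .N .SD .I setkey
#' @importFrom stats rnorm rpois runif median p.adjust pbinom dnbinom cor
#'   complete.cases rbinom sd var nls coef phyper setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for sub-stream `i` of a parent seed; kept below
# 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Reverse complement of a DNA string
#'
#' IUPAC degeneracy codes are complemented correctly; case is preserved so
#' soft-masked (lowercase) bases stay masked.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  from <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
  to   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"
  vapply(x, function(s) {
    chartr(from, to, paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Stable short hash of an R object (config fingerprinting in run metadata).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
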