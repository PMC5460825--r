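IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Compile a consensus motif
#'
#' A motif is either a single IUPAC consensus string or a gapped pair of
#' half-patterns with a variable spacer; gapped motifs expand to one concrete
#' IUPAC pattern per spacer length (e.g. the negative GRE
#' \code{CTCC(N)0-2GGAGA} expands to \code{CTCCGGAGA}, \code{CTCCNGGAGA},
#' \code{CTCCNNGGAGA}).
#'
#' @param name motif name.
#' @param pattern IUPAC consensus string (ungapped motifs).
#' @param left,right half-patterns of a gapped motif.
#' @param spacer integer vector \code{c(min, max)} of spacer lengths in bp.
#' @param class motif class, one of \code{"full_gre"}, \code{"gre_half"},
#'   \code{"nf1_half"}, \code{"bhlh"}, \code{"ngre"}, \code{"custom"}.
#' @return an object of class \code{motif_model} with fields \code{name},
#'   \code{class} and \code{patterns} (character vector of expanded IUPAC
#'   patterns).
#' @examples
#' compile_motif("GRE", "ACANNNTGTYCT", class = "full_gre")
#' compile_motif("nGRE", left = "CTCC", right = "GGAGA", spacer = c(0, 2),
#'               class = "ngre")
#' @export
compile_motif <- function(name, pattern = NULL, left = NULL, right = NULL,
                          spacer = c(0L, 0L),
                          class = c("custom", "full_gre", "gre_half",
                                    "nf1_half", "bhlh", "ngre")) {
  class <- match.arg(class)
  check_iupac <- function(p, what) {
    bad <- setdiff(strsplit(toupper(p), "")[[1]], names(IUPAC_MAP))
    if (length(bad))
      stopf("non-IUPAC character '%s' in %s of motif '%s'", bad[1], what, name)
  }
  if (!is.null(pattern)) {
    check_iupac(pattern, "pattern")
    patterns <- toupper(pattern)
  } else {
    if (is.null(left) || is.null(right))
      stopf("motif '%s': give either `pattern` or both `left` and `right`", name)
    check_iupac(left, "left half"); check_iupac(right, "right half")
    if (any(spacer < 0) || spacer[1] > spacer[2])
      stopf("motif '%s': spacer bounds must satisfy 0 <= min <= max", name)
    patterns <- vapply(spacer[1]:spacer[2], function(k) {
      paste0(toupper(left), strrep("N", k), toupper(right))
    }, character(1))
  }
  structure(list(name = name, class = class, patterns = patterns),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s [%s]: %s\n", x$name, x$class,
              paste(x$patterns, collapse = " | ")))
  invisible(x)
}

#' Default consensus motif library
#'
#' Full GRE \code{ACANNNTGTYCT}; GRE half-site \code{TGTYCT} (the 3' half of
#' the palindrome); NF-1 half-site \code{TTGGCA} (the TTGGC-containing half of
#' the canonical NF-1 site TTGGC(N5)GCCAA); bHLH/E-box \code{CANATGG}
#' (NeuroD1/Olig2-like; \code{CAGCTG} selectable via \code{bhlh}); negative
#' GRE \code{CTCC(N)0-2GGAGA} scanned as exact matches to its three spacer
#' variants.
#'
#' @param bhlh bHLH consensus to use (default \code{"CANATGG"}).
#' @param nf1 NF-1 half-site consensus (default \code{"TTGGCA"}).
#' @return named list of \code{motif_model} objects.
#' @export
default_motif_library <- function(bhlh = "CANATGG", nf1 = "TTGGCA") {
  list(
    full_gre = compile_motif("full_GRE", "ACANNNTGTYCT", class = "full_gre"),
    gre_half = compile_motif("GRE_half", "TGTYCT", class = "gre_half"),
    nf1_half = compile_motif("NF1_half", nf1, class = "nf1_half"),
    bhlh     = compile_motif("bHLH", bhlh, class = "bhlh"),
    ngre     = compile_motif("nGRE", left = "CTCC", right = "GGAGA",
                             spacer = c(0L, 2L), class = "ngre")
  )
}

# IUPAC pattern -> perl regex character classes. Masked bases are represented
# as "X" before matching, which no class contains, so lowercase regions never
# match.
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

# All (overlapping) match start positions of an IUPAC pattern in `seq`
# (1-based). Lowercase bases are treated as masked and never match.
iupac_match_starts <- function(seq, pattern) {
  subj <- gsub("[a-z]", "X", seq)
  m <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), subj, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan a sequence window for motif hits on both strands
#'
#' Every position x strand whose bases satisfy the IUPAC pattern yields a hit.
#' A hit whose reverse complement matches the same interval on the other
#' strand (a palindromic match) is reported once, on the plus strand.
#' Lowercase (soft-masked) bases never match.
#'
#' @param window character scalar, the sequence window (typically centred on a
#'   peak summit).
#' @param motif a \code{motif_model}.
#' @param center 1-based position within \code{window} taken as offset 0
#'   (default the window midpoint); hit offsets are midpoints relative to it.
#' @return data.table with columns \code{motif}, \code{class}, \code{start}
#'   (1-based within window), \code{end}, \code{offset} (hit midpoint minus
#'   \code{center}), \code{strand}, \code{text} (matched bases, strand of the
#'   hit).
#' @export
scan_interval <- function(window, motif, center = (nchar(window) + 1) / 2) {
  stopifnot(inherits(motif, "motif_model"))
  n <- nchar(window)
  rc <- revcomp(window)
  out <- lapply(motif$patterns, function(pat) {
    w <- nchar(pat)
    fwd <- iupac_match_starts(window, pat)
    rev_on_rc <- iupac_match_starts(rc, pat)
    # map a match on the reverse-complement strand back to forward coordinates
    rev <- if (length(rev_on_rc)) (n - (rev_on_rc + w - 1L) + 1L) else integer(0)
    hits <- data.table(
      start = c(fwd, rev),
      end = c(fwd, rev) + w - 1L,
      strand = rep(c("+", "-"), c(length(fwd), length(rev)))
    )
    if (!nrow(hits)) return(hits)
    # palindrome dedup: same interval matched on both strands -> keep '+'
    hits[, dup := strand == "-" & paste(start, end) %in%
           hits[strand == "+", paste(start, end)]]
    hits[dup == FALSE][, dup := NULL]
  })
  out <- rbindlist(out)
  if (!nrow(out)) {
    return(data.table(motif = character(), class = character(),
                      start = integer(), end = integer(), offset = numeric(),
                      strand = character(), text = character()))
  }
  out[, `:=`(
    motif = motif$name, class = motif$class,
    offset = (start + end) / 2 - center,
    text = {
      fwdtxt <- toupper(substring(window, start, end))
      ifelse(strand == "+", fwdtxt, revcomp(fwdtxt))
    }
  )]
  setorder(out, start, strand)
  out[, .(motif, class, start, end, offset, strand, text)]
}

#' Scan peak windows for a motif library
#'
#' Extracts a window of \code{2*halfwidth} centred on each peak summit and
#' scans it with every motif in the library on both strands.
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks data.frame with columns \code{peak_id}, \code{chrom},
#'   \code{summit} (0-based).
#' @param library list of \code{motif_model} objects (default
#'   \code{default_motif_library()}).
#' @param halfwidth half-width in bp of the scan window (100 for frequency
#'   counting; 1000 for positional histograms).
#' @return data.table of hits with \code{peak_id}, \code{motif}, \code{class},
#'   \code{offset} (bp from summit), \code{strand}, \code{text}.
#' @export
scan_peaks <- function(genome, peaks, library = default_motif_library(),
                       halfwidth = 100L) {
  peaks <- as.data.table(peaks)
  stopifnot(all(c("peak_id", "chrom", "summit") %in% names(peaks)))
  res <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    L <- nchar(genome[[chrom]])
    s0 <- peaks$summit[i]                    # 0-based summit
    lo <- max(0L, s0 - halfwidth)            # 0-based window start
    hi <- min(L, s0 + halfwidth)             # 0-based half-open end
    win <- substring(genome[[chrom]], lo + 1L, hi)
    h <- rbindlist(lapply(library, scan_interval, window = win,
                          center = s0 - lo + 1L))
    if (nrow(h)) h[, peak_id := peaks$peak_id[i]]
    res[[i]] <- h
  }
  out <- rbindlist(res, fill = TRUE)
  if (!nrow(out)) {
    return(data.table(peak_id = character(), motif = character(),
                      class = character(), offset = numeric(),
                      strand = character(), text = character()))
  }
  out[, .(peak_id, motif, class, offset, strand, text)]
}
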