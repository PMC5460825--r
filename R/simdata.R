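#' Composition configuration for planted binding sites
#'
#' Describes how many synthetic GR binding sites to plant and which motif
#' classes they carry. Per-class values may be exact counts (>= 1) or
#' fractions of \code{n_sites} (in [0, 1)). The GRE classes partition the
#' sites: \code{full_gre} sites carry a palindromic GRE (which contains a
#' half-site, so the half-site flag is implied), \code{gre_half} sites carry a
#' half-site only, and the remainder carry neither GRE form. NF-1 and bHLH
#' instances are assigned to sites independently of GRE status; nGRE
#' instances are split between GRE-free sites (\code{ngre_without_gre}) and
#' GRE-carrying sites (the rest).
#'
#' @param n_sites number of binding sites.
#' @param full_gre,gre_half,nf1_half,bhlh,ngre per-class planting rate or
#'   exact count. \code{gre_half} counts sites carrying a half-site only
#'   (no palindrome).
#' @param ngre_without_gre how many nGRE sites must carry no GRE form.
#' @param offset_sd named numeric, per-class SD (bp) of the planted instance
#'   offset from the site centre.
#' @param weights named numeric, per-class enrichment weight; a site's
#'   enrichment weight is 1 + the sum over its planted instances.
#' @param peak_halfwidth bp; planted instances lie within centre +/- this.
#' @param min_spacing minimum distance between site centres (bp).
#' @return a \code{composition_config} list.
#' @export
composition_config <- function(n_sites,
                               full_gre = 0, gre_half = 0, nf1_half = 0,
                               bhlh = 0, ngre = 0, ngre_without_gre = 0,
                               offset_sd = c(full_gre = 15, gre_half = 15,
                                             nf1_half = 60, bhlh = 60,
                                             ngre = 60),
                               weights = c(full_gre = 1.5, gre_half = 0.75,
                                           nf1_half = 0.75, bhlh = 0.75,
                                           ngre = 0.25),
                               peak_halfwidth = 100L,
                               min_spacing = max(2L * peak_halfwidth, 1000L)) {
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1)
  to_count <- function(x, what) {
    if (x < 0) stopf("%s must be non-negative", what)
    n <- if (x > 0 && x < 1) round(x * n_sites) else as.integer(round(x))
    if (n > n_sites) stopf("%s count (%d) exceeds n_sites (%d)", what, n, n_sites)
    as.integer(n)
  }
  counts <- c(full_gre = to_count(full_gre, "full_gre"),
              gre_half = to_count(gre_half, "gre_half"),
              nf1_half = to_count(nf1_half, "nf1_half"),
              bhlh = to_count(bhlh, "bhlh"),
              ngre = to_count(ngre, "ngre"))
  if (counts["full_gre"] + counts["gre_half"] > n_sites)
    stopf("full_gre + gre_half counts exceed n_sites")
  ngre_without_gre <- as.integer(ngre_without_gre)
  if (ngre_without_gre > counts["ngre"])
    stopf("ngre_without_gre exceeds the nGRE count")
  if (ngre_without_gre > n_sites - counts["full_gre"] - counts["gre_half"])
    stopf("not enough GRE-free sites for ngre_without_gre")
  if (any(offset_sd <= 0)) stopf("offset_sd must be > 0")
  if (any(weights < 0)) stopf("weights must be >= 0")
  structure(list(n_sites = n_sites, counts = counts,
                 ngre_without_gre = ngre_without_gre,
                 offset_sd = offset_sd, weights = weights,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 min_spacing = as.integer(min_spacing)),
            class = "composition_config")
}

#' Default composition mirroring the reported hippocampal GR motif accounting
#'
#' Reads \code{inst/extdata/default_composition.yaml}: 7298 sites of which
#' 3301 carry a full palindromic GRE, 3262 a GRE half-site only and 735
#' neither GRE form (so 89.9\% carry some GRE form); 3985 (54.6\%) carry an
#' NF-1 half-site, 1248 (17.1\%) a bHLH motif, and 126 an nGRE of which 6
#' lack any GRE form.
#'
#' @param path optional path to a YAML composition file.
#' @return a \code{composition_config}.
#' @export
default_composition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_composition.yaml",
                        package = "grchip", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  composition_config(
    n_sites = y$n_sites,
    full_gre = y$counts$full_gre, gre_half = y$counts$gre_half,
    nf1_half = y$counts$nf1_half, bhlh = y$counts$bhlh, ngre = y$counts$ngre,
    ngre_without_gre = y$ngre_without_gre,
    offset_sd = unlist(y$offset_sd), weights = unlist(y$weights),
    peak_halfwidth = y$peak_halfwidth,
    min_spacing = y$min_spacing %||% max(2L * y$peak_halfwidth, 1000L)
  )
}

# ---- internal: global scanning and local resampling --------------------------

# Both-strand patterns for a motif library: each IUPAC pattern plus its
# reverse complement (a minus-strand hit equals a forward match of the RC).
library_patterns <- function(library) {
  rbindlist(lapply(library, function(m) {
    pats <- unique(c(m$patterns, revcomp(m$patterns)))
    data.table(class = m$class, name = m$name, pattern = pats)
  }))
}

# All hit intervals (1-based, forward coordinates, both strands collapsed) of
# the library in one chromosome string.
scan_chrom_global <- function(seq, pats) {
  rbindlist(lapply(seq_len(nrow(pats)), function(i) {
    st <- iupac_match_starts(seq, pats$pattern[i])
    if (!length(st)) return(NULL)
    data.table(class = pats$class[i], start = st,
               end = st + nchar(pats$pattern[i]) - 1L)
  }))
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Sample a concrete realisation of an IUPAC consensus.
realize_consensus <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(IUPAC_MAP[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Generate a motif-free background genome
#'
#' Samples a random genome at the requested GC content, then iteratively
#' resamples any window matching a library motif (either strand) until an
#' exhaustive scan finds zero hits. The guarantee is the final verified scan,
#' so planted motif composition is exactly recoverable downstream.
#'
#' @param length genome length in bp (>= 10 kb).
#' @param gc GC fraction in (0, 1).
#' @param motif_library list of \code{motif_model}s to exclude (default the
#'   standard library).
#' @param seed integer seed; identical seeds give identical genomes.
#' @param chrom_name chromosome name for the single returned sequence.
#' @param max_passes resampling passes before giving up.
#' @return named character vector of length 1 (the genome).
#' @export
generate_background_genome <- function(length, gc = 0.42,
                                       motif_library = default_motif_library(),
                                       seed = 1L, chrom_name = "chr1",
                                       max_passes = 50L) {
  stopifnot(length >= 10000, gc > 0, gc < 1)
  pats <- library_patterns(motif_library)
  with_seed(seed, {
    gv <- random_bases(length, gc)
    g <- paste(gv, collapse = "")
    for (pass in seq_len(max_passes)) {
      hits <- scan_chrom_global(g, pats)
      if (!nrow(hits)) {
        out <- g
        names(out) <- chrom_name
        return(out)
      }
      for (i in seq_len(nrow(hits)))
        gv[hits$start[i]:hits$end[i]] <-
          random_bases(hits$end[i] - hits$start[i] + 1L, gc)
      g <- paste(gv, collapse = "")
    }
    worst <- hits[, .N, by = class][order(-N)]$class[1]
    stopf("could not build a motif-free genome in %d passes (motif class '%s' keeps re-occurring)",
          max_passes, worst)
  })
}

#' Plant binding sites with configured motif architectures
#'
#' Places \code{n_sites} site centres (spaced at least \code{min_spacing}
#' apart, away from chromosome ends), writes concrete motif realisations into
#' the genome at normally distributed offsets from each centre (truncated so
#' instances fit within \code{peak_halfwidth}), and repairs any accidental
#' motif matches created by the insertions so that scanning recovers exactly
#' the planted composition. A full-GRE site also scans positive for the
#' half-site contained in the palindrome's 3' arm; that implication is part of
#' the planted truth.
#'
#' @param genome named character vector of chromosome sequences (motif-free
#'   background from [generate_background_genome()]).
#' @param config a \code{composition_config}.
#' @param seed integer seed.
#' @param motif_library motif library (default standard).
#' @param gc GC fraction used when resampling repair windows.
#' @param max_passes repair passes before giving up.
#' @return list with \code{genome} (modified sequences), \code{truth}
#'   (data.table: site_id, chrom, center, enrichment_weight and per-class
#'   flags) and \code{instances} (data.table of planted motif instances:
#'   site_id, class, offset, strand, seq).
#' @export
plant_sites <- function(genome, config, seed = 1L,
                        motif_library = default_motif_library(),
                        gc = 0.42, max_passes = 100L) {
  stopifnot(inherits(config, "composition_config"))
  pats <- library_patterns(motif_library)
  maxlen <- max(nchar(pats$pattern))
  hw <- config$peak_halfwidth
  margin <- hw + maxlen + 50L

  with_seed(seed, {
    # --- site centres, proportionally across chromosomes ---
    lens <- vapply(genome, nchar, integer(1))
    cap <- pmax(0, floor((lens - 2 * margin) / config$min_spacing))
    if (sum(cap) < config$n_sites)
      stopf("genome too small: capacity %d sites at spacing %d, requested %d",
            sum(cap), config$min_spacing, config$n_sites)
    alloc <- floor(config$n_sites * cap / sum(cap))
    while (sum(alloc) < config$n_sites) {
      i <- which.max(cap - alloc); alloc[i] <- alloc[i] + 1L
    }
    centers <- rbindlist(lapply(seq_along(genome), function(ci) {
      n <- alloc[ci]
      if (n == 0) return(NULL)
      extra <- lens[ci] - 2 * margin - n * config$min_spacing
      u <- sort(runif(n, 0, max(extra, 0)))
      data.table(chrom = names(genome)[ci],
                 center = as.integer(margin + round(u) +
                                       (seq_len(n) - 1L) * config$min_spacing +
                                       config$min_spacing %/% 2L))
    }))
    n <- nrow(centers)
    centers[, site_id := sprintf("site_%05d", seq_len(n))]

    # --- class assignment ---
    cc <- config$counts
    perm <- sample(n)
    full_idx <- perm[seq_len(cc["full_gre"])]
    half_idx <- perm[seq_len(cc["gre_half"]) + cc["full_gre"]]
    none_idx <- setdiff(seq_len(n), c(full_idx, half_idx))
    pick <- function(pool, k) if (k == 0) integer(0) else
      pool[sample.int(length(pool), k)]
    nf1_idx  <- pick(seq_len(n), cc["nf1_half"])
    bhlh_idx <- pick(seq_len(n), cc["bhlh"])
    ngre_idx <- c(pick(none_idx, config$ngre_without_gre),
                  pick(c(full_idx, half_idx),
                       cc["ngre"] - config$ngre_without_gre))

    site_classes <- vector("list", n)
    for (i in full_idx) site_classes[[i]] <- c(site_classes[[i]], "full_gre")
    for (i in half_idx) site_classes[[i]] <- c(site_classes[[i]], "gre_half")
    for (i in nf1_idx)  site_classes[[i]] <- c(site_classes[[i]], "nf1_half")
    for (i in bhlh_idx) site_classes[[i]] <- c(site_classes[[i]], "bhlh")
    for (i in ngre_idx) site_classes[[i]] <- c(site_classes[[i]], "ngre")

    # --- realise and place instances ---
    consensus_of <- function(cls) {
      m <- motif_library[[cls]]
      m$patterns[sample.int(length(m$patterns), 1)]
    }
    inst <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- site_classes[[i]]
      if (is.null(cls)) next
      placed <- data.table(lo = integer(), hi = integer())
      rows <- lapply(cls, function(cl) {
        pat <- consensus_of(cl)
        txt <- realize_consensus(pat)
        w <- nchar(txt)
        sdv <- config$offset_sd[[cl]]
        for (try in 1:200) {
          off <- round(rnorm(1, 0, sdv))
          lo <- off - (w - 1L) %/% 2L            # offsets rel. centre
          hi <- lo + w - 1L
          ok <- lo >= -hw + 1L && hi <= hw - 1L &&
            !any(placed$lo <= hi + 2L & placed$hi >= lo - 2L)
          if (ok) break
          if (try == 200) stopf("cannot place a '%s' instance at site %d", cl, i)
        }
        placed <<- rbind(placed, data.table(lo = lo, hi = hi))
        strand <- sample(c("+", "-"), 1)
        data.table(class = cl, offset = (lo + hi) / 2, lo = lo, hi = hi,
                   strand = strand, seq = txt)
      })
      inst[[i]] <- rbindlist(rows)[, site_id := centers$site_id[i]]
    }
    instances <- rbindlist(inst)
    if (nrow(instances)) {
      instances <- merge(instances, centers, by = "site_id", sort = FALSE)
      instances[, `:=`(gstart = center + lo + 1L,      # 1-based
                       gend = center + hi + 1L)]
    }

    # write instances into per-chrom character vectors
    gvs <- lapply(genome, function(s) strsplit(s, "")[[1]])
    if (nrow(instances)) {
      for (i in seq_len(nrow(instances))) {
        txt <- if (instances$strand[i] == "+") instances$seq[i]
               else revcomp(instances$seq[i])
        gvs[[instances$chrom[i]]][instances$gstart[i]:instances$gend[i]] <-
          strsplit(txt, "")[[1]]
      }
    }

    # --- truth flags and enrichment weights ---
    truth <- copy(centers)
    flag <- function(idx) seq_len(n) %in% idx
    truth[, `:=`(
      has_full_gre = flag(full_idx),
      has_gre_half = flag(full_idx) | flag(half_idx),  # palindrome implies half
      has_nf1_half = flag(nf1_idx),
      has_bhlh = flag(bhlh_idx),
      has_ngre = flag(ngre_idx)
    )]
    wsum <- vapply(site_classes, function(cls)
      if (is.null(cls)) 0 else sum(config$weights[cls]), numeric(1))
    truth[, enrichment_weight := 1 + wsum]

    # --- repair accidental matches created by insertion boundaries ---
    expected <- lapply(seq_len(n), function(i) {
      cls <- site_classes[[i]]
      if ("full_gre" %in% cls) cls <- union(cls, "gre_half")
      cls
    })
    inst_iv <- if (nrow(instances))
      instances[, .(chrom, gstart, gend, class, idx = .I)] else NULL

    for (pass in seq_len(max_passes)) {
      gstr <- lapply(gvs, paste, collapse = "")
      viol <- rbindlist(lapply(names(gstr), function(ch) {
        h <- scan_chrom_global(gstr[[ch]], pats)
        if (!nrow(h)) return(NULL)
        h[, chrom := ch]
        ctr <- centers[chrom == ch]
        pos <- findInterval((h$start + h$end) / 2,
                            c(-Inf, ctr$center + 1 +
                                c(diff(ctr$center) / 2, Inf)[seq_len(nrow(ctr))]))
        # map each hit to the nearest site on this chromosome (or none)
        mid <- (h$start + h$end) / 2
        near <- vapply(mid, function(m) {
          j <- which.min(abs(ctr$center + 1 - m))
          if (abs(ctr$center[j] + 1 - m) <= hw + maxlen) j else NA_integer_
        }, integer(1))
        h[, site := ifelse(is.na(near), NA_integer_,
                           match(ctr$site_id[near], centers$site_id))]
        h
      }))
      if (!nrow(viol)) break
      viol[, bad := TRUE]
      for (i in seq_len(nrow(viol))) {
        s <- viol$site[i]
        if (!is.na(s)) {
          exp_cls <- expected[[s]]
          # intended hit: class expected and fully inside the scan region
          if (viol$class[i] %in% exp_cls) { viol$bad[i] <- FALSE; next }
        }
      }
      viol <- viol[bad == TRUE]
      if (!nrow(viol)) break
      if (pass == max_passes)
        stopf("planting repair did not converge (class '%s' persists)",
              viol$class[1])
      for (i in seq_len(nrow(viol))) {
        ch <- viol$chrom[i]
        span <- viol$start[i]:viol$end[i]
        inside <- if (!is.null(inst_iv)) {
          ii <- inst_iv[chrom == ch & gstart <= viol$end[i] & gend >= viol$start[i]]
          if (nrow(ii)) unlist(lapply(seq_len(nrow(ii)), function(k)
            ii$gstart[k]:ii$gend[k])) else integer(0)
        } else integer(0)
        fix <- setdiff(span, inside)
        if (length(fix)) {
          gvs[[ch]][fix] <- random_bases(length(fix), gc)
        } else {
          # violation entirely within planted instances: re-realise the
          # degenerate positions of the overlapping instance
          ii <- inst_iv[chrom == ch & gstart <= viol$end[i] & gend >= viol$start[i]]
          k <- ii$idx[1]
          pat_cls <- instances$class[k]
          newtxt <- realize_consensus(consensus_of(pat_cls))
          while (nchar(newtxt) != nchar(instances$seq[k]))
            newtxt <- realize_consensus(consensus_of(pat_cls))
          instances[k, seq := newtxt]
          txt <- if (instances$strand[k] == "+") newtxt else revcomp(newtxt)
          gvs[[ch]][instances$gstart[k]:instances$gend[k]] <- strsplit(txt, "")[[1]]
        }
      }
    }

    out_genome <- vapply(gvs, paste, character(1), collapse = "")
    names(out_genome) <- names(genome)
    inst_out <- if (nrow(instances))
      instances[, .(site_id, class, offset, strand, seq)] else
      data.table(site_id = character(), class = character(),
                 offset = numeric(), strand = character(), seq = character())
    list(genome = out_genome,
         truth = truth[, .(site_id, chrom, center, enrichment_weight,
                           has_full_gre, has_gre_half, has_nf1_half,
                           has_bhlh, has_ngre)],
         instances = inst_out)
  })
}

#' Read-simulation parameters
#'
#' @param depth mean ChIP fragment count per unit enrichment weight per site.
#' @param dispersion SD (bp) of fragment centres around the site centre.
#' @param shift strand shift: 5' tag positions sit \code{-shift} (plus reads)
#'   or \code{+shift} (minus reads) from the fragment centre.
#' @param read_length sequenced read length (bp).
#' @param background_rate uniform background tag rate (tags/bp).
#' @param condition_effect per-site ChIP count multiplier applied to the
#'   second condition; 1.0 is the between-condition null.
#' @return a \code{read_sim_params} list.
#' @export
read_sim_params <- function(depth = 100, dispersion = 50, shift = 75,
                            read_length = 36L, background_rate = 0.08,
                            condition_effect = 1.0) {
  stopifnot(depth > 0, dispersion > 0, shift >= 0, read_length > 0,
            background_rate > 0, all(condition_effect > 0))
  structure(list(depth = depth, dispersion = dispersion, shift = shift,
                 read_length = as.integer(read_length),
                 background_rate = background_rate,
                 condition_effect = condition_effect),
            class = "read_sim_params")
}

#' Simulate ChIP and input tags for a two-condition, replicated design
#'
#' Per ChIP sample and site, the fragment count is Poisson with mean
#' \code{depth * enrichment_weight * condition multiplier}; fragment centres
#' are normal around the site centre and each yields one stranded read whose
#' 5' end is offset by \code{-shift}/\code{+shift}. Background reads are
#' uniform. Input samples contain background only.
#'
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param truth truth table from [plant_sites()] (may have zero rows).
#' @param params a \code{read_sim_params}.
#' @param n_replicates,n_conditions design dimensions (default 2 x 2).
#' @param seed integer seed; per-sample streams are split deterministically.
#' @return named list of BED6-style data.tables
#'   (\code{chip_c<i>_r<j>}, \code{input_c<i>_r<j>}), each sorted by
#'   coordinate, with a \code{"clipped"} attribute counting boundary-clipped
#'   reads.
#' @export
simulate_tags <- function(genome_lengths, truth, params = read_sim_params(),
                          n_replicates = 2L, n_conditions = 2L, seed = 1L) {
  stopifnot(inherits(params, "read_sim_params"))
  truth <- as.data.table(truth)
  rl <- params$read_length
  clipped_total <- 0L
  mult_for <- function(cond) {
    if (cond == 1) rep(1, nrow(truth))
    else rep(params$condition_effect, length.out = max(nrow(truth), 1))
  }
  one_sample <- function(kind, cond, rep_i, sseed) {
    with_seed(sseed, {
      parts <- list()
      if (kind == "chip" && nrow(truth)) {
        lam <- params$depth * truth$enrichment_weight * mult_for(cond)
        nsite <- rpois(nrow(truth), lam)
        tot <- sum(nsite)
        if (tot > 0) {
          centers <- rnorm(tot, rep(truth$center, nsite), params$dispersion)
          chroms <- rep(truth$chrom, nsite)
          strand <- sample(c("+", "-"), tot, replace = TRUE)
          p5 <- ifelse(strand == "+", round(centers) - params$shift,
                       round(centers) + params$shift)
          start <- ifelse(strand == "+", p5, p5 - rl + 1)
          parts$site <- data.table(chrom = chroms, start = as.integer(start),
                                   strand = strand)
        }
      }
      bgl <- lapply(names(genome_lengths), function(ch) {
        L <- genome_lengths[[ch]]
        nb <- rpois(1, params$background_rate * L)
        if (nb == 0) return(NULL)
        data.table(chrom = ch,
                   start = as.integer(floor(runif(nb, 0, L - rl))),
                   strand = sample(c("+", "-"), nb, replace = TRUE))
      })
      tags <- rbindlist(c(parts, bgl))
      # clip at chromosome boundaries
      tags[, end := start + rl]
      Lv <- genome_lengths[tags$chrom]
      nclip <- sum(tags$start < 0 | tags$end > Lv)
      clipped_total <<- clipped_total + nclip
      tags[, `:=`(start = pmax(start, 0L),
                  end = pmin(end, as.integer(Lv)))]
      tags <- tags[end > start]
      setorder(tags, chrom, start, end, strand)
      tags[, `:=`(name = sprintf("t%07d", seq_len(.N)), score = 0L)]
      tags[, .(chrom, start, end, name, score, strand)]
    })
  }
  out <- list()
  k <- 0L
  for (cond in seq_len(n_conditions)) for (r in seq_len(n_replicates)) {
    for (kind in c("chip", "input")) {
      k <- k + 1L
      out[[sprintf("%s_c%d_r%d", kind, cond, r)]] <-
        one_sample(kind, cond, r, child_seed(seed, k))
    }
  }
  attr(out, "clipped") <- clipped_total
  out
}

#' Simulate non-overlapping gene models
#'
#' Places \code{n_genes} genes in disjoint slots along the genome, each with
#' 2-5 exons; the TSS is \code{txStart} for plus-strand genes and
#' \code{txEnd} for minus-strand genes.
#'
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed.
#' @return data.table with columns \code{gene}, \code{chrom}, \code{strand},
#'   \code{txStart}, \code{txEnd}, \code{exonStarts}, \code{exonEnds}
#'   (comma-separated, 0-based half-open).
#' @export
simulate_gene_models <- function(genome_lengths, n_genes, seed = 1L) {
  stopifnot(n_genes >= 1)
  with_seed(seed, {
    lens <- as.numeric(genome_lengths)
    alloc <- pmax(0, floor(n_genes * lens / sum(lens)))
    while (sum(alloc) < n_genes) {
      i <- which.max(lens / (alloc + 1)); alloc[i] <- alloc[i] + 1L
    }
    rows <- list()
    gi <- 0L
    for (ci in seq_along(genome_lengths)) {
      ng <- alloc[ci]
      if (ng == 0) next
      L <- lens[ci]
      slot <- floor((L - 2000) / ng)
      if (slot < 3000) stopf("genome too small for %d genes", n_genes)
      for (j in seq_len(ng)) {
        gi <- gi + 1L
        s0 <- 1000 + (j - 1) * slot
        glen <- floor(runif(1, 0.3, 0.7) * slot)
        tx_start <- as.integer(s0 + floor(runif(1, 0, slot - glen - 10)))
        tx_end <- as.integer(tx_start + glen)
        k <- sample(2:5, 1)
        cuts <- sort(sample(seq(tx_start + 50, tx_end - 50, by = 10),
                            2 * (k - 1)))
        es <- as.integer(c(tx_start, cuts[seq(2, length(cuts), by = 2)]))
        ee <- as.integer(c(cuts[seq(1, length(cuts), by = 2)], tx_end))
        rows[[gi]] <- data.table(
          gene = sprintf("g%04d", gi), chrom = names(genome_lengths)[ci],
          strand = sample(c("+", "-"), 1),
          txStart = tx_start, txEnd = tx_end,
          exonStarts = paste(es, collapse = ","),
          exonEnds = paste(ee, collapse = ","))
      }
    }
    rbindlist(rows)
  })
}

#' Simulate per-site ChIP tag counts directly (count-level model)
#'
#' Draws the read simulator's site-count model without generating reads:
#' per site, replicate and condition, count ~ Poisson(depth x
#' enrichment_weight x condition multiplier). Useful for count-level
#' calibration studies of the differential-binding test where read-level
#' artefacts (coincidental 5' collisions removed by deduplication) are out
#' of scope.
#'
#' @param truth truth table with \code{site_id} and \code{enrichment_weight}.
#' @param params a \code{read_sim_params} (uses \code{depth} and
#'   \code{condition_effect}).
#' @param n_replicates,n_conditions design dimensions.
#' @param seed integer seed.
#' @return integer matrix sites x samples (\code{chip_c<i>_r<j>}).
#' @export
simulate_site_counts <- function(truth, params = read_sim_params(),
                                 n_replicates = 2L, n_conditions = 2L,
                                 seed = 1L) {
  stopifnot(inherits(params, "read_sim_params"))
  truth <- as.data.table(truth)
  with_seed(seed, {
    cols <- list()
    for (cond in seq_len(n_conditions)) for (r in seq_len(n_replicates)) {
      mult <- if (cond == 1) 1 else params$condition_effect
      cols[[sprintf("chip_c%d_r%d", cond, r)]] <-
        rpois(nrow(truth), params$depth * truth$enrichment_weight * mult)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- truth$site_id
    m
  })
}
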