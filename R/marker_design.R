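# Screening homozygous InDels into agarose-genotypable PCR markers:
# length filter, flank cleanliness, PIC across an accession panel, and
# primer design under a fixed constraint envelope (product 200-350 bp,
# primer 18-29 nt, Tm 55-64 C by nearest-neighbor thermodynamics, GC
# 35-65%).

#' Select InDel marker candidates
#'
#' Keeps homozygous insertions/deletions with `min_len <= indel_len <=
#' max_len` whose flanks are assay-clean: no other InDel of >=
#' `flank_indel_min` bp within `flank` bp of the site (so the amplicon is
#' the same in both parents apart from the target InDel). Marker ids are
#' assigned per chromosome in position order, `In{chrom}-{rank}`.
#'
#' @param variants variant table (needs zygosity, vclass, indel_len).
#' @param min_len,max_len InDel length bounds in bp (defaults 20 and 200).
#' @param flank cleanliness radius in bp around the site.
#' @param flank_indel_min smallest interfering InDel length in bp.
#' @return data.frame of candidates with a `marker_id` column; attribute
#'   `filter_log` records counts in/out of each filter.
#' @export
select_candidates <- function(variants, min_len = 20L, max_len = 200L,
                              flank = 350L, flank_indel_min = 5L) {
  n_in <- nrow(variants)
  is_indel <- variants$vclass %in% c("INS", "DEL")
  keep_class <- is_indel & variants$indel_len >= min_len &
    variants$indel_len <= max_len
  keep_zyg <- variants$zygosity == "hom"
  cand <- variants[keep_class & keep_zyg, , drop = FALSE]
  # flank cleanliness against every InDel >= flank_indel_min (any zygosity)
  noise <- variants[is_indel & variants$indel_len >= flank_indel_min, ,
                    drop = FALSE]
  clean <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    near <- noise$chrom == cand$chrom[i] &
      abs(noise$pos - cand$pos[i]) <= flank &
      !(noise$pos == cand$pos[i] & noise$ref == cand$ref[i] &
          noise$alt == cand$alt[i])
    clean[i] <- !any(near)
  }
  out <- cand[clean, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(chrom_number(out$chrom), out$pos), , drop = FALSE]
    rank <- stats::ave(out$pos, out$chrom, FUN = seq_along)
    out$marker_id <- sprintf("In%d-%d", chrom_number(out$chrom), rank)
  } else {
    out$marker_id <- character(0)
  }
  rownames(out) <- NULL
  attr(out, "filter_log") <- data.frame(
    filter = c("class_and_length", "zygosity", "flank_clean"),
    rejected = c(sum(!keep_class), sum(keep_class & !keep_zyg),
                 sum(!clean)),
    stringsAsFactors = FALSE)
  attr(attr(out, "filter_log"), "n_in") <- n_in
  out
}

#' Polymorphism information content of a marker locus
#'
#' Heterozygosity-corrected PIC (Botstein-style):
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}
#' A simpler expected-heterozygosity variant `1 - sum(p^2)` is available
#' via `method = "expected_het"`.
#'
#' @param freqs allele frequencies, summing to 1 (tolerance 1e-9).
#' @param method `"botstein"` (default) or `"expected_het"`.
#' @return PIC in `[0, 1)`; 0 iff the locus is monomorphic.
#' @examples
#' compute_pic(c(0.5, 0.5))          # 0.375
#' compute_pic(1)                    # 0 (monomorphic)
#' @export
compute_pic <- function(freqs, method = c("botstein", "expected_het")) {
  method <- match.arg(method)
  if (any(freqs < 0)) imr_stop("allele frequencies must be >= 0")
  if (abs(sum(freqs) - 1) > 1e-9)
    imr_stop("allele frequencies must sum to 1")
  s2 <- sum(freqs^2)
  if (method == "expected_het") return(1 - s2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(freqs^4))
}

#' Per-locus allele frequencies from an accession panel
#'
#' @param panel `accession_panel` data.frame (0 = reference allele,
#'   1 = alternate; inbred accessions, one allele each).
#' @return data.frame locus, p_ref, p_alt, n (non-missing accessions).
#' @export
panel_allele_freqs <- function(panel) {
  loci <- setdiff(colnames(panel), "accession")
  res <- lapply(loci, function(lc) {
    g <- panel[[lc]]
    g <- g[!is.na(g)]
    data.frame(locus = lc, p_ref = mean(g == 0), p_alt = mean(g == 1),
               n = length(g), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Screen marker candidates by PIC across a panel
#'
#' Computes each candidate's PIC from the panel allele frequencies and
#' retains candidates with PIC strictly greater than the threshold.
#' Candidates whose locus is missing from the panel are dropped with a
#' warning.
#'
#' @param candidates output of [select_candidates()].
#' @param panel `accession_panel`.
#' @param threshold retain PIC > threshold (default 0.5, strict).
#' @param method PIC formula, see [compute_pic()].
#' @return retained candidates with a `pic` column; attribute
#'   `per_chrom` summarises counts and mean PIC per chromosome.
#' @export
screen_by_pic <- function(candidates, panel, threshold = 0.5,
                          method = "botstein") {
  if (!nrow(candidates)) return(cbind(candidates, pic = numeric(0)))
  key <- sprintf("%s_%d", candidates$chrom, candidates$pos)
  af <- panel_allele_freqs(panel)
  hit <- match(key, af$locus)
  if (any(is.na(hit))) {
    warning(sprintf("%d candidate locus/loci absent from panel; dropped",
                    sum(is.na(hit))))
  }
  keep <- !is.na(hit)
  cand <- candidates[keep, , drop = FALSE]
  hit <- hit[keep]
  cand$pic <- vapply(hit, function(i)
    compute_pic(c(af$p_ref[i], af$p_alt[i]), method = method), numeric(1))
  out <- cand[cand$pic > threshold, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    per <- stats::aggregate(pic ~ chrom, out, function(x)
      c(n = length(x), mean_pic = mean(x)))
    attr(out, "per_chrom") <- data.frame(
      chrom = per$chrom, n = per$pic[, "n"],
      mean_pic = per$pic[, "mean_pic"], stringsAsFactors = FALSE)
  }
  out
}

# ---- melting temperature ----------------------------------------------------

# Unified nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K) for
# DNA/DNA duplexes, plus terminal initiation terms.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
           TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
           GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbor melting temperature of a primer
#'
#' Unified nearest-neighbor thermodynamics with the entropic salt
#' correction `dS + 0.368 * (n-1) * ln([Na+])` and
#' `Tm = 1000*dH / (dS + R*ln(Ct/4)) - 273.15` for non-self-complementary
#' oligos. Defaults (50 mM monovalent cation, 50 nM total oligo) follow
#' common primer-design practice.
#'
#' @param seq primer sequence(s), 5'->3'.
#' @param oligo_nM total oligo concentration in nM.
#' @param na_mM monovalent cation concentration in mM.
#' @return Tm in degrees Celsius (vectorised).
#' @export
primer_tm <- function(seq, oligo_nM = 50, na_mM = 50) {
  R <- 1.987  # cal/mol/K
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "")[[1]]
    if (length(b) < 2 || !all(b %in% c("A", "C", "G", "T")))
      imr_stop("primer must be >= 2 ACGT bases")
    nn <- paste0(b[-length(b)], b[-1])
    dh <- sum(NN_DH[nn])
    ds <- sum(NN_DS[nn])
    for (term in c(b[1], b[length(b)])) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (length(b) - 1) * log(na_mM / 1000)
    1000 * dh / (ds + R * log(oligo_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer-design constraint envelope
#'
#' @param product_range PCR product size bounds on the reference allele.
#' @param primer_len primer length bounds (nt).
#' @param tm_range allowed melting temperatures (C).
#' @param gc_range allowed GC fraction.
#' @param max_homopolymer longest tolerated single-base run.
#' @param max_gc_clamp 3' end must not end in a G/C run longer than this.
#' @param opt_tm scoring optimum (C); pairs minimise summed |Tm - opt_tm|.
#' @param flank search space either side of the InDel (bp).
#' @return list of class `primer_constraints`.
#' @export
primer_constraints <- function(product_range = c(200L, 350L),
                               primer_len = c(18L, 29L),
                               tm_range = c(55, 64),
                               gc_range = c(0.35, 0.65),
                               max_homopolymer = 4L,
                               max_gc_clamp = 3L,
                               opt_tm = 59.5,
                               flank = 400L) {
  out <- list(product_range = product_range, primer_len = primer_len,
              tm_range = tm_range, gc_range = gc_range,
              max_homopolymer = max_homopolymer,
              max_gc_clamp = max_gc_clamp, opt_tm = opt_tm, flank = flank)
  class(out) <- "primer_constraints"
  out
}

#' Enumerate valid primers within a template window
#' @noRd
enumerate_primers <- function(template, from, to, constraints,
                              reverse = FALSE) {
  lens <- seq(constraints$primer_len[1], constraints$primer_len[2])
  cand <- list()
  for (l in lens) {
    starts <- seq.int(from, to - l + 1L)
    if (!length(starts) || starts[1] > to - l + 1L) next
    seqs <- substring(template, starts, starts + l - 1L)
    if (reverse) seqs <- revcomp(seqs)
    gc <- gc_fraction(seqs)
    ok <- gc >= constraints$gc_range[1] & gc <= constraints$gc_range[2]
    hp <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                  constraints$max_homopolymer + 1L,
                  constraints$max_homopolymer + 1L,
                  constraints$max_homopolymer + 1L,
                  constraints$max_homopolymer + 1L)
    ok <- ok & !grepl(hp, seqs)
    clamp <- sprintf("[GC]{%d}$", constraints$max_gc_clamp + 1L)
    ok <- ok & !grepl(clamp, seqs)
    if (!any(ok)) next
    tm <- rep(NA_real_, length(seqs))
    tm[ok] <- primer_tm(seqs[ok])
    ok <- ok & !is.na(tm) & tm >= constraints$tm_range[1] &
      tm <= constraints$tm_range[2]
    if (!any(ok)) next
    cand[[length(cand) + 1L]] <- data.frame(
      start = starts[ok], end = starts[ok] + l - 1L, seq = seqs[ok],
      tm = tm[ok], gc = gc[ok], stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(NULL)
  do.call(rbind, cand)
}

#' Design a PCR primer pair for an InDel marker
#'
#' Enumerates all primer windows in the flanks of the InDel, applies the
#' full constraint envelope (length, Tm by nearest-neighbor
#' thermodynamics, GC fraction, homopolymer and 3' G/C-clamp limits,
#' reference product size), and returns the best-scoring satisfying pair
#' (minimal summed |Tm - opt|, ties broken by leftmost forward primer,
#' then leftmost reverse). The predicted product sizes on both parental
#' alleles differ by exactly the InDel length.
#'
#' @param candidate one-row candidate data.frame (chrom, pos, ref, alt,
#'   vclass, indel_len, optionally marker_id).
#' @param genome named `DNAStringSet` reference.
#' @param constraints a [primer_constraints()] envelope.
#' @return list of class `primer_pair` (fwd/rev sequence, Tm, GC,
#'   genomic coordinates, product_size_ref, product_size_alt), or class
#'   `primer_design_failure` with a reason.
#' @export
design_primers <- function(candidate, genome,
                           constraints = primer_constraints()) {
  fail <- function(reason) {
    out <- list(marker_id = candidate$marker_id %||% NA_character_,
                chrom = candidate$chrom, pos = candidate$pos,
                reason = reason)
    class(out) <- "primer_design_failure"
    out
  }
  chrom_seq <- genome[[candidate$chrom]]
  L <- length(chrom_seq)
  p <- candidate$pos
  ref_len <- nchar(candidate$ref)
  ws <- max(1L, p - constraints$flank)
  we <- min(L, p + ref_len - 1L + constraints$flank)
  if (p - ws < constraints$product_range[1] / 2)
    return(fail("insufficient left flank"))
  template <- as.character(Biostrings::subseq(chrom_seq, ws, we))
  # window-relative coordinates
  p_rel <- p - ws + 1L
  fwd <- enumerate_primers(template, 1L, p_rel, constraints,
                           reverse = FALSE)
  rev <- enumerate_primers(template, p_rel + ref_len - 1L + 1L,
                           nchar(template), constraints, reverse = TRUE)
  if (is.null(fwd) || is.null(rev))
    return(fail("no primer satisfies the single-primer constraints"))
  # pair on reference product size
  best <- NULL
  rev <- rev[order(rev$end), ]
  for (i in order(fwd$start)) {
    size <- rev$end - fwd$start[i] + 1L
    ok <- which(size >= constraints$product_range[1] &
                  size <= constraints$product_range[2])
    if (!length(ok)) next
    sc <- abs(fwd$tm[i] - constraints$opt_tm) +
      abs(rev$tm[ok] - constraints$opt_tm)
    j <- ok[order(sc, rev$start[ok])[1]]
    cand_score <- abs(fwd$tm[i] - constraints$opt_tm) +
      abs(rev$tm[j] - constraints$opt_tm)
    if (is.null(best) || cand_score < best$score - 1e-12) {
      best <- list(i = i, j = j, score = cand_score,
                   size = rev$end[j] - fwd$start[i] + 1L)
    }
  }
  if (is.null(best)) return(fail("no pair yields a product in range"))
  i <- best$i; j <- best$j
  delta <- nchar(candidate$alt) - nchar(candidate$ref)
  out <- list(
    marker_id = candidate$marker_id %||% NA_character_,
    chrom = candidate$chrom, pos = p,
    fwd_seq = fwd$seq[i], rev_seq = rev$seq[j],
    fwd_tm = fwd$tm[i], rev_tm = rev$tm[j],
    fwd_gc = fwd$gc[i], rev_gc = rev$gc[j],
    fwd_start = ws + fwd$start[i] - 1L, rev_end = ws + rev$end[j] - 1L,
    product_size_ref = best$size,
    product_size_alt = best$size + delta)
  class(out) <- "primer_pair"
  out
}

#' Re-validate a designed primer pair against a constraint envelope
#'
#' Idempotence check: every accepted pair must satisfy its own constraint
#' set when re-tested.
#'
#' @param pair a `primer_pair`.
#' @param candidate the candidate it was designed for.
#' @param constraints a [primer_constraints()].
#' @return logical; attribute `violations` lists any failed constraints.
#' @export
validate_primer_pair <- function(pair, candidate,
                                 constraints = primer_constraints()) {
  viol <- character(0)
  chk <- function(cond, what) if (!cond) viol <<- c(viol, what)
  for (side in c("fwd", "rev")) {
    s <- pair[[paste0(side, "_seq")]]
    chk(nchar(s) >= constraints$primer_len[1] &&
          nchar(s) <= constraints$primer_len[2],
        paste(side, "length"))
    tm <- primer_tm(s)
    chk(tm >= constraints$tm_range[1] && tm <= constraints$tm_range[2],
        paste(side, "Tm"))
    gc <- gc_fraction(s)
    chk(gc >= constraints$gc_range[1] && gc <= constraints$gc_range[2],
        paste(side, "GC"))
    chk(!grepl(sprintf("A{%1$d,}|C{%1$d,}|G{%1$d,}|T{%1$d,}",
                       constraints$max_homopolymer + 1L), s),
        paste(side, "homopolymer"))
    chk(!grepl(sprintf("[GC]{%d}$", constraints$max_gc_clamp + 1L), s),
        paste(side, "3' clamp"))
  }
  chk(pair$product_size_ref >= constraints$product_range[1] &&
        pair$product_size_ref <= constraints$product_range[2],
      "product size")
  chk(abs(pair$product_size_ref - pair$product_size_alt) ==
        candidate$indel_len, "product size difference")
  ok <- length(viol) == 0
  attr(ok, "violations") <- viol
  ok
}

#' Design primers for a whole candidate table
#'
#' @param candidates candidate table (with `marker_id`).
#' @param genome named `DNAStringSet`.
#' @param constraints a [primer_constraints()].
#' @return data.frame marker table (one row per successful design) with
#'   primer sequences, Tm, GC and both product sizes; attribute
#'   `failures` holds the `primer_design_failure` records.
#' @export
design_markers <- function(candidates, genome,
                           constraints = primer_constraints()) {
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(candidates))) {
    res <- design_primers(candidates[i, ], genome, constraints)
    if (inherits(res, "primer_design_failure")) {
      fails[[length(fails) + 1L]] <- res
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = res$marker_id, chrom = res$chrom, pos = res$pos,
        indel_len = candidates$indel_len[i],
        pic = candidates$pic[i] %||% NA_real_,
        fwd_seq = res$fwd_seq, rev_seq = res$rev_seq,
        fwd_tm = res$fwd_tm, rev_tm = res$rev_tm,
        fwd_gc = res$fwd_gc, rev_gc = res$rev_gc,
        product_size_ref = res$product_size_ref,
        product_size_alt = res$product_size_alt,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    marker_id = character(0), chrom = character(0), pos = integer(0),
    indel_len = integer(0), pic = numeric(0), fwd_seq = character(0),
    rev_seq = character(0), fwd_tm = numeric(0), rev_tm = numeric(0),
    fwd_gc = numeric(0), rev_gc = numeric(0),
    product_size_ref = integer(0), product_size_alt = integer(0),
    stringsAsFactors = FALSE)
  attr(out, "failures") <- fails
  out
}

#' In-silico PCR
#'
#' Finds matches of the forward primer and of the reverse complement of
#' the reverse primer on each chromosome (allowing up to `max_mismatch`
#' substitutions per primer, as annealing tolerates a few internal
#' mismatches) and reports every orientation-consistent product up to
#' `max_product` bp.
#'
#' @param genome named `DNAStringSet` template.
#' @param fwd_seq,rev_seq primer sequences (5'->3').
#' @param max_product largest reported product (bp).
#' @param max_mismatch substitutions tolerated per primer site.
#' @return data.frame chrom, start, end, size (possibly empty).
#' @export
insilico_pcr <- function(genome, fwd_seq, rev_seq, max_product = 5000L,
                         max_mismatch = 0L) {
  out <- list()
  rc <- revcomp(rev_seq)
  for (ch in names(genome)) {
    fhit <- Biostrings::matchPattern(fwd_seq, genome[[ch]],
                                     max.mismatch = max_mismatch)
    rhit <- Biostrings::matchPattern(rc, genome[[ch]],
                                     max.mismatch = max_mismatch)
    if (!length(fhit) || !length(rhit)) next
    fs <- Biostrings::start(fhit); re <- Biostrings::end(rhit)
    for (a in fs) for (b in re) {
      size <- b - a + 1L
      if (size >= nchar(fwd_seq) + nchar(rev_seq) && size <= max_product)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = a, end = b, size = size,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      size = integer(0)))
  do.call(rbind, out)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("Primer pair %s (%s:%d)\n", x$marker_id, x$chrom, x$pos))
  cat(sprintf("  F 5'-%s-3'  Tm %.1fC  GC %.0f%%\n", x$fwd_seq, x$fwd_tm,
              100 * x$fwd_gc))
  cat(sprintf("  R 5'-%s-3'  Tm %.1fC  GC %.0f%%\n", x$rev_seq, x$rev_tm,
              100 * x$rev_gc))
  cat(sprintf("  products: ref %d bp / alt %d bp\n", x$product_size_ref,
              x$product_size_alt))
  invisible(x)
}

#' @export
print.primer_design_failure <- function(x, ...) {
  cat(sprintf("Primer design failed for %s (%s:%d): %s\n", x$marker_id,
              x$chrom, x$pos, x$reason))
  invisible(x)
}
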