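# Positional cloning of a recessive locus: recessive-bulk BSA over
# genome-wide markers, recombinant-count fine mapping, 3:1 segregation
# testing, and BSA-seq style causal-SNP nomination.

#' Genotype a pooled recessive bulk at markers
#'
#' Samples `n_pool` phenotypically recessive F2 individuals once (a single
#' DNA pool) and computes, per marker, the mutant-parent allele fraction
#' `(2*#A + #H) / (2*n_pool)` from their individual genotypes. The pool
#' call is `A-like` at fraction >= 0.9, `B-like` at <= 0.1, otherwise
#' `H-like`.
#'
#' @param pop an `f2_population`.
#' @param n_pool bulk size (default 30 recessives).
#' @param markers marker ids to genotype (default: all of `pop`).
#' @param seed sampling seed for pool membership.
#' @return data.frame of class `pool_result`: marker_id, chrom, pos,
#'   n_pool, a_allele_fraction, pool_call.
#' @export
pool_recessives <- function(pop, n_pool = 30L, markers = NULL, seed = 1L) {
  if (n_pool < 1L) imr_stop("n_pool must be >= 1")
  rec <- which(pop$individuals$phenotype == "mutant")
  if (length(rec) < n_pool)
    imr_stop(sprintf("only %d recessive individuals; need %d",
                     length(rec), n_pool))
  set.seed(seed)
  pool <- sample(rec, n_pool)
  ids <- markers %||% pop$markers$marker_id
  miss <- setdiff(ids, colnames(pop$geno))
  if (length(miss))
    imr_stop(sprintf("unknown marker(s): %s", paste(miss, collapse = ", ")))
  g <- pop$geno[pool, ids, drop = FALSE]
  if (all(is.na(g))) imr_stop("all genotypes missing in pool")
  frac <- vapply(ids, function(mk) {
    gg <- g[, mk]
    gg <- gg[!is.na(gg)]
    if (!length(gg)) return(NA_real_)
    (2 * sum(gg == "A") + sum(gg == "H")) / (2 * length(gg))
  }, numeric(1))
  m <- pop$markers[match(ids, pop$markers$marker_id), ]
  out <- data.frame(
    marker_id = ids, chrom = m$chrom, pos = m$pos, n_pool = n_pool,
    a_allele_fraction = frac,
    pool_call = ifelse(frac >= 0.9, "A-like",
                       ifelse(frac <= 0.1, "B-like", "H-like")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pool_result", "data.frame")
  out
}

#' Coarse BSA mapping from pooled-bulk allele fractions
#'
#' In a bulk of recessives, markers unlinked to the causal locus have
#' mutant-parent allele fraction ~0.5; the causal region is skewed toward
#' 1. Each marker is tested with a one-sided binomial test of the allele
#' count against 0.5 (Bonferroni-corrected over markers); the marker with
#' the maximal allele fraction is returned provided it is significant.
#'
#' @param pool_results a `pool_result` table over genome-wide markers.
#' @param alpha familywise significance level.
#' @return list of class `coarse_map`: chrom, marker_id, pos,
#'   a_allele_fraction, p_adj, significant, and the per-marker table.
#'   `chrom`/`marker_id` are `NA` when no marker is significant.
#' @export
coarse_map <- function(pool_results, alpha = 0.05) {
  pr <- pool_results[!is.na(pool_results$a_allele_fraction), , drop = FALSE]
  if (!nrow(pr)) imr_stop("no usable marker data")
  m <- nrow(pr)
  pvals <- vapply(seq_len(m), function(i) {
    n_allele <- 2L * pr$n_pool[i]
    x <- round(pr$a_allele_fraction[i] * n_allele)
    stats::binom.test(x, n_allele, 0.5, alternative = "greater")$p.value
  }, numeric(1))
  p_adj <- pmin(1, pvals * m)
  ord <- order(-pr$a_allele_fraction, p_adj, pr$chrom, pr$pos)
  best <- ord[1]
  sig <- p_adj[best] < alpha
  tab <- cbind(pr, p_value = pvals, p_adj = p_adj)
  tab <- tab[order(match(tab$chrom, unique(pool_results$chrom)), tab$pos), ]
  rownames(tab) <- NULL
  out <- list(
    chrom = if (sig) pr$chrom[best] else NA_character_,
    marker_id = if (sig) pr$marker_id[best] else NA_character_,
    pos = if (sig) pr$pos[best] else NA_real_,
    a_allele_fraction = pr$a_allele_fraction[best],
    p_adj = p_adj[best], significant = sig, table = tab)
  class(out) <- "coarse_map"
  out
}

#' @export
print.coarse_map <- function(x, ...) {
  if (x$significant)
    cat(sprintf(
      "Coarse BSA peak: %s on %s (pos %.0f), allele fraction %.2f, adj. p %.3g\n",
      x$marker_id, x$chrom, x$pos, x$a_allele_fraction, x$p_adj))
  else cat("Coarse BSA: no significant marker\n")
  invisible(x)
}

#' Fine mapping by recombinant counts in recessive individuals
#'
#' Every phenotypically recessive individual is homozygous mutant at the
#' causal locus, so any non-`A` genotype at a marker marks a recombinant.
#' The interval is delimited by the nearest markers on each side of the
#' zero-recombinant core that still show at least one recombinant. When no
#' marker is recombinant-free the markers with the minimal recombinant
#' count are bracketed instead (with a warning).
#'
#' @param pop an `f2_population` (only its recessive individuals are used).
#' @param region_marker_ids markers in the candidate region, any order;
#'   they are sorted by position.
#' @param genes optional gene models; genes overlapping the interval are
#'   reported as candidates.
#' @return list of class `mapping_interval`: chrom, left_marker,
#'   right_marker, left_pos, right_pos, length, candidate_gene_ids, and
#'   the per-marker recombinant table.
#' @export
fine_map <- function(pop, region_marker_ids = NULL, genes = NULL) {
  ids <- region_marker_ids %||% pop$markers$marker_id
  m <- pop$markers[match(ids, pop$markers$marker_id), ]
  if (any(is.na(m$pos))) imr_stop("unknown region marker id(s)")
  if (length(unique(m$chrom)) != 1L)
    imr_stop("region markers must lie on one chromosome")
  ord <- order(m$pos)
  m <- m[ord, ]; ids <- ids[ord]
  rec <- pop$individuals$phenotype == "mutant"
  if (!any(rec)) imr_stop("no recessive individuals")
  g <- pop$geno[rec, ids, drop = FALSE]
  recomb <- colSums(g != "A", na.rm = TRUE)
  k <- length(ids)
  core <- which(recomb == 0)
  if (!length(core)) {
    warning("no zero-recombinant marker; bracketing the minimal-recombinant markers")
    core <- which(recomb == min(recomb))
    core <- seq(min(core), max(core))
  }
  li <- max(c(0L, which(seq_len(k) < min(core) & recomb >= 1)))
  ri <- min(c(k + 1L, which(seq_len(k) > max(core) & recomb >= 1)))
  if (li == 0L) {
    warning("no recombinant marker left of the core; using leftmost marker")
    li <- 1L
  }
  if (ri == k + 1L) {
    warning("no recombinant marker right of the core; using rightmost marker")
    ri <- k
  }
  left_pos <- m$pos[li]; right_pos <- m$pos[ri]
  cand_genes <- character(0)
  if (!is.null(genes)) {
    cand_genes <- vapply(
      Filter(function(gg) gg$chrom == m$chrom[1] &&
               gg$tx_end >= left_pos && gg$tx_start <= right_pos, genes),
      `[[`, character(1), "gene_id")
    names(cand_genes) <- NULL
  }
  out <- list(
    chrom = m$chrom[1],
    left_marker = ids[li], right_marker = ids[ri],
    left_pos = left_pos, right_pos = right_pos,
    length = right_pos - left_pos,
    n_recessives = sum(rec),
    candidate_gene_ids = cand_genes,
    recombinants = data.frame(marker_id = ids, chrom = m$chrom,
                              pos = m$pos, n_recombinant = as.integer(recomb),
                              stringsAsFactors = FALSE))
  class(out) <- "mapping_interval"
  out
}

#' @export
print.mapping_interval <- function(x, ...) {
  cat(sprintf(
    "Mapping interval: %s:%.0f-%.0f (%.2f kb) between %s and %s (%d recessives)\n",
    x$chrom, x$left_pos, x$right_pos, x$length / 1000, x$left_marker,
    x$right_marker, x$n_recessives))
  if (length(x$candidate_gene_ids))
    cat(sprintf("  %d candidate gene(s): %s\n",
                length(x$candidate_gene_ids),
                paste(head(x$candidate_gene_ids, 10), collapse = ", ")))
  invisible(x)
}

#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Tests observed dominant:recessive counts against an expected Mendelian
#' ratio (default 3:1) with Pearson's chi-square statistic on 1 df (no
#' continuity correction).
#'
#' @param n_dom,n_rec observed dominant and recessive counts.
#' @param ratio expected ratio as a length-2 vector (default `c(3, 1)`).
#' @return list of class `segregation_test`: n_dominant, n_recessive,
#'   expected, chi2, df, p_value, fits (TRUE when p >= 0.05).
#' @examples
#' segregation_chisq(745, 237)  # chi2 ~ 0.392, consistent with 3:1
#' @export
segregation_chisq <- function(n_dom, n_rec, ratio = c(3, 1)) {
  if (n_dom < 0 || n_rec < 0 || (n_dom + n_rec) == 0)
    imr_stop("counts must be non-negative and not both zero")
  ht <- stats::chisq.test(c(n_dom, n_rec), p = ratio / sum(ratio),
                          correct = FALSE)
  out <- list(n_dominant = n_dom, n_recessive = n_rec,
              expected = as.numeric(ht$expected),
              chi2 = unname(ht$statistic),
              df = as.integer(unname(ht$parameter)),
              p_value = ht$p.value, fits = ht$p.value >= 0.05)
  class(out) <- "segregation_test"
  out
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(
    "Segregation %d:%d vs expected %.1f:%.1f -> chi2 = %.3f (df %d), p = %.3f%s\n",
    x$n_dominant, x$n_recessive, x$expected[1], x$expected[2], x$chi2,
    x$df, x$p_value,
    if (x$fits) " (consistent)" else " (deviates)"))
  invisible(x)
}

#' BSA-seq candidate SNP nomination within a mapping interval
#'
#' Nominates SNPs that look like an EMS-induced recessive causal mutation:
#' inside the interval, alternate-allele frequency >= `mut_min` in the
#' mutant pool and within `wild_range` in the wild pool (the expected 1/3
#' for a recessive allele among phenotypically wild F2 plants), EMS-type
#' substitution (G->A or C->T) when `require_ems`, and an annotated
#' protein-altering effect. Results are sorted by mutant-pool frequency.
#'
#' @param pool_freqs data.frame chrom, pos, ref, alt, af_mutant_pool,
#'   af_wild_pool (e.g. from [pool_allele_freqs()]).
#' @param interval a `mapping_interval`.
#' @param annotations annotation table from [annotate_variants()]; used to
#'   attach effects. SNPs without a protein-altering annotation
#'   (missense or any large-effect class) are filtered out.
#' @param mut_min mutant-pool alternate-frequency threshold.
#' @param wild_range allowed wild-pool alternate-frequency window.
#' @param require_ems restrict to G->A / C->T substitutions.
#' @return data.frame of class `bsa_seq_candidates`: chrom, pos, ref, alt,
#'   af_mutant_pool, af_wild_pool, is_ems_type, effect.
#' @export
bsa_seq_scan <- function(pool_freqs, interval, annotations,
                         mut_min = 0.9, wild_range = c(0.2, 0.45),
                         require_ems = TRUE) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      af_mutant_pool = numeric(0),
                      af_wild_pool = numeric(0),
                      is_ems_type = logical(0), effect = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(interval$left_pos) || interval$length <= 0) {
    warning("empty or degenerate mapping interval; no candidates")
    return(empty)
  }
  v <- pool_freqs[pool_freqs$chrom == interval$chrom &
                    pool_freqs$pos >= interval$left_pos &
                    pool_freqs$pos <= interval$right_pos &
                    nchar(pool_freqs$ref) == 1 &
                    nchar(pool_freqs$alt) == 1, , drop = FALSE]
  if (!nrow(v)) {
    warning("no SNPs inside the mapping interval")
    return(empty)
  }
  v$is_ems_type <- (v$ref == "G" & v$alt == "A") |
    (v$ref == "C" & v$alt == "T")
  key <- paste(v$chrom, v$pos)
  akey <- paste(annotations$chrom, annotations$pos)
  v$effect <- annotations$effect[match(key, akey)]
  protein_altering <- !is.na(v$effect) &
    (v$effect == "missense" | v$effect %in% LARGE_EFFECTS)
  keep <- v$af_mutant_pool >= mut_min &
    v$af_wild_pool >= wild_range[1] & v$af_wild_pool <= wild_range[2] &
    (!require_ems | v$is_ems_type) & protein_altering
  out <- v[keep, , drop = FALSE]
  out <- out[order(-out$af_mutant_pool, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("bsa_seq_candidates", "data.frame")
  out
}
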