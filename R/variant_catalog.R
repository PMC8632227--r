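# Catalogue statistics for variants between two inbred accessions:
# zygosity, Ts/Tv, InDel length classes, SV classes, windowed densities
# and mean spacing.

#' Read a VCF into a variant record table
#'
#' Parses a VCF v4.2 (first sample's GT is used for zygosity), splits
#' multi-allelic records into one row per alternate allele, and classifies
#' each record as SNP, INS, DEL or INV (symbolic `<INV>` alleles). Records
#' without a GT call are dropped with a warning; unsorted files raise a
#' parse error naming the offending record.
#'
#' @param path VCF file (plain or gzipped).
#' @return data.frame with columns chrom, pos (1-based), ref, alt,
#'   zygosity (`hom`/`het`), vclass (`SNP`/`INS`/`DEL`/`INV`), indel_len,
#'   sv_len, causal (INFO flag).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) imr_stop(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) imr_stop("empty VCF")
  info <- vcfR::getINFO(v)
  gt_raw <- tryCatch(vcfR::extract.gt(v, "GT"),
                     error = function(e) NULL)
  if (is.null(gt_raw))
    imr_stop("VCF has no GT field; genotypes are required")
  gt <- gt_raw[, 1]
  pos <- as.integer(fix$POS)
  # sortedness check per chromosome
  for (ch in unique(fix$CHROM)) {
    p <- pos[fix$CHROM == ch]
    if (is.unsorted(p)) {
      bad <- which(diff(p) < 0)[1] + 1L
      imr_stop(sprintf("VCF unsorted on %s (record %d at pos %d)",
                       ch, bad, p[bad]))
    }
  }
  drop <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(drop)) {
    warning(sprintf("dropping %d record(s) lacking GT", sum(drop)))
  }
  rows <- list()
  info_field <- function(s, key) {
    m <- regmatches(s, regexpr(sprintf("(?<=%s=)[-0-9]+", key), s,
                               perl = TRUE))
    if (length(m)) as.integer(m) else NA_integer_
  }
  for (i in which(!drop)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[i], "[/|]")[[1]]
    for (ai in seq_along(alts)) {
      nhit <- sum(alleles == as.character(ai))
      if (nhit == 0) next
      alt <- alts[ai]
      ref <- fix$REF[i]
      if (alt == "<INV>") {
        vclass <- "INV"
        svlen <- info_field(info[i], "SVLEN")
        if (is.na(svlen)) {
          e <- info_field(info[i], "END")
          svlen <- if (!is.na(e)) e - pos[i] + 1L else NA_integer_
        }
        ilen <- 0L
      } else if (grepl("^<", alt)) {
        next  # other symbolic alleles unsupported
      } else if (nchar(ref) == 1L && nchar(alt) == 1L) {
        if (ref == alt)
          imr_stop(sprintf("malformed record %s:%d (REF == ALT)",
                           fix$CHROM[i], pos[i]))
        vclass <- "SNP"; ilen <- 0L; svlen <- 0L
      } else if (nchar(ref) != nchar(alt)) {
        vclass <- if (nchar(alt) > nchar(ref)) "INS" else "DEL"
        ilen <- abs(nchar(alt) - nchar(ref))
        svlen <- if (ilen >= 100L) ilen else 0L
      } else {
        next  # balanced multi-nucleotide substitutions not catalogued
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos[i], ref = ref, alt = alt,
        zygosity = if (nhit == length(alleles)) "hom" else "het",
        vclass = vclass, indel_len = ilen,
        sv_len = if (is.na(svlen)) 0L else svlen,
        causal = grepl("CAUSAL", info[i], fixed = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) imr_stop("no usable variant records in VCF")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a single-base substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' A<->G and C<->T; the remaining eight ordered pairs are transversions.
#'
#' @param ref,alt single bases in `{A, C, G, T}` (vectorised).
#' @return character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G") # transition
#' classify_substitution("C", "A") # transversion
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) imr_stop("ref and alt must be single A/C/G/T bases")
  if (any(ref == alt)) imr_stop("ref and alt must differ")
  ifelse((ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
           (ref == "C" & alt == "T") | (ref == "T" & alt == "C"),
         "transition", "transversion")
}

#' Summarise a variant catalogue
#'
#' Computes the headline statistics of an inter-accession comparison:
#' class and zygosity counts, heterozygosity ratio, Ts/Tv, InDel length
#' classes (1 bp, 2-20 bp, >20 bp), SV count and median length, and (when
#' chromosome lengths are supplied) per-Mb densities and mean spacing
#' (covered length / count, equivalently 1e6 / per-Mb density).
#'
#' InDels with length >= `sv_min_len` and symbolic inversions are counted
#' as SVs, not InDels. When there are no transversions the Ts/Tv ratio is
#' reported as `NA` (undefined), never infinity.
#'
#' @param variants data.frame from [read_vcf()] or the simulator.
#' @param chrom_lengths optional named chromosome lengths; densities use
#'   the full declared length (no gap exclusion).
#' @param sv_min_len SV length threshold (bp).
#' @return list of class `catalog_summary`.
#' @export
summarize_variants <- function(variants, chrom_lengths = NULL,
                               sv_min_len = 100L) {
  if (!nrow(variants)) imr_stop("empty variant table")
  is_sv <- variants$vclass == "INV" |
    (variants$vclass %in% c("INS", "DEL") & variants$indel_len >= sv_min_len)
  snp <- variants$vclass == "SNP"
  ind <- variants$vclass %in% c("INS", "DEL") & !is_sv
  n_het <- sum(variants$zygosity == "het")
  ts <- classify_substitution(variants$ref[snp], variants$alt[snp])
  n_ts <- sum(ts == "transition"); n_tv <- sum(ts == "transversion")
  len <- variants$indel_len[ind]
  sv_lens <- ifelse(variants$vclass[is_sv] == "INV",
                    variants$sv_len[is_sv], variants$indel_len[is_sv])
  covered <- if (!is.null(chrom_lengths)) sum(chrom_lengths) else NA_real_
  out <- list(
    n_snp = sum(snp), n_indel = sum(ind), n_sv = sum(is_sv),
    n_hom = nrow(variants) - n_het, n_het = n_het,
    het_ratio = n_het / nrow(variants),
    n_ts = n_ts, n_tv = n_tv,
    tstv = if (n_tv > 0) n_ts / n_tv else NA_real_,
    indel_len_classes = c(`1` = sum(len == 1L),
                          `2-20` = sum(len >= 2L & len <= 20L),
                          `>20` = sum(len > 20L)),
    snp_density_per_mb = if (!is.na(covered)) sum(snp) / covered * 1e6
    else NA_real_,
    indel_density_per_mb = if (!is.na(covered)) sum(ind) / covered * 1e6
    else NA_real_,
    mean_snp_spacing = if (!is.na(covered) && sum(snp) > 0)
      covered / sum(snp) else NA_real_,
    mean_indel_spacing = if (!is.na(covered) && sum(ind) > 0)
      covered / sum(ind) else NA_real_,
    sv_len_median = if (length(sv_lens)) median(sv_lens) else NA_real_)
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Variant catalogue summary\n")
  cat(sprintf("  SNPs: %d  InDels: %d  SVs: %d\n", x$n_snp, x$n_indel,
              x$n_sv))
  cat(sprintf("  hom: %d  het: %d  (heterozygosity %.2f%%)\n", x$n_hom,
              x$n_het, 100 * x$het_ratio))
  cat(sprintf("  Ts: %d  Tv: %d  Ts/Tv: %s\n", x$n_ts, x$n_tv,
              ifelse(is.na(x$tstv), "undefined", sprintf("%.2f", x$tstv))))
  cat("  InDel length classes:",
      paste(names(x$indel_len_classes), x$indel_len_classes, sep = "=",
            collapse = "  "), "\n")
  if (!is.na(x$mean_snp_spacing))
    cat(sprintf("  one SNP every %.0f bp, one InDel every %.0f bp\n",
                x$mean_snp_spacing, x$mean_indel_spacing))
  invisible(x)
}

#' Heterozygosity ratio from total and homozygous counts
#' @param n_total total variant count.
#' @param n_hom homozygous count.
#' @return fraction heterozygous.
#' @examples heterozygosity_ratio(1102064, 865781) # ~0.2144
#' @export
heterozygosity_ratio <- function(n_total, n_hom) {
  stopifnot(n_total > 0, n_hom >= 0, n_hom <= n_total)
  (n_total - n_hom) / n_total
}

#' Transition/transversion ratio
#' @param n_ts,n_tv transition and transversion counts.
#' @return ratio, `NA` if `n_tv == 0`.
#' @examples ts_tv_ratio(1400101, 513280) # ~2.73
#' @export
ts_tv_ratio <- function(n_ts, n_tv) {
  if (n_tv == 0) return(NA_real_)
  n_ts / n_tv
}

#' Mean variant spacing implied by a per-Mb density
#' @param density_per_mb variants per Mb.
#' @return mean spacing in bp (`1e6 / density`).
#' @examples mean_spacing(2719.65) # ~368 bp
#' @export
mean_spacing <- function(density_per_mb) {
  stopifnot(density_per_mb > 0)
  1e6 / density_per_mb
}

#' Windowed SNP/InDel densities along chromosomes
#'
#' Counts SNPs and InDels in half-open windows `[k*w, (k+1)*w)` (0-based,
#' BED-like; the last window is truncated at the declared chromosome end)
#' and scales counts to per-Mb densities using each window's true width.
#'
#' @param variants variant table.
#' @param chrom_lengths named chromosome lengths.
#' @param window_size window width in bp (default 1 Mb).
#' @return data.frame: chrom, window_start (0-based), window_end, n_snp,
#'   n_indel, snp_density_per_mb, indel_density_per_mb.
#' @export
window_densities <- function(variants, chrom_lengths, window_size = 1e6) {
  if (window_size <= 0) imr_stop("window_size must be > 0")
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    vv <- variants[variants$chrom == ch, , drop = FALSE]
    if (nrow(vv) && any(vv$pos > L))
      imr_stop(sprintf("variant at %s:%d beyond declared length %d",
                       ch, max(vv$pos), L))
    starts <- seq(0, L - 1, by = window_size)
    ends <- pmin(starts + window_size, L)
    widx <- if (nrow(vv)) floor((vv$pos - 1) / window_size) + 1L
    else integer(0)
    n_snp <- tabulate(widx[vv$vclass == "SNP"], nbins = length(starts))
    n_ind <- tabulate(widx[vv$vclass %in% c("INS", "DEL")],
                      nbins = length(starts))
    w <- (ends - starts) / 1e6
    out[[ch]] <- data.frame(
      chrom = ch, window_start = starts, window_end = ends,
      n_snp = n_snp, n_indel = n_ind,
      snp_density_per_mb = n_snp / w, indel_density_per_mb = n_ind / w,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Windowed GC content of a genome
#' @param genome named `DNAStringSet`.
#' @param window_size window width in bp.
#' @return data.frame chrom, window_start (0-based), window_end, gc.
#' @export
window_gc <- function(genome, window_size = 1e6) {
  out <- list()
  for (ch in names(genome)) {
    L <- length(genome[[ch]])
    starts <- seq(0, L - 1, by = window_size)
    ends <- pmin(starts + window_size, L)
    v <- Biostrings::Views(genome[[ch]], start = starts + 1, end = ends)
    f <- Biostrings::letterFrequency(v, c("GC"), as.prob = TRUE)
    out[[ch]] <- data.frame(chrom = ch, window_start = starts,
                            window_end = ends, gc = as.numeric(f),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
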