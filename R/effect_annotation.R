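# Genomic-region assignment and CDS effect classification for homozygous
# variants: synonymous/missense/stop/start changes for SNPs, frameshift or
# in-frame for InDels, splice-region changes, and the large-effect flag.

LARGE_EFFECTS <- c("frameshift", "splice_change", "start_loss",
                   "stop_gain", "stop_loss")

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features
#' (1-based inclusive). One transcript per gene is assumed; additional
#' transcripts are ignored with a warning.
#'
#' @param path GFF3 file.
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    ID = as.character(S4Vectors::mcols(gr)$ID),
    Parent = vapply(S4Vectors::mcols(gr)$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)),
    stringsAsFactors = FALSE)
  genes <- list()
  for (gid in d$ID[d$type == "gene"]) {
    grow <- d[d$type == "gene" & d$ID == gid, ]
    tx <- d[d$type == "mRNA" & d$Parent == gid, ]
    if (nrow(tx) > 1) {
      warning(sprintf("gene %s has %d transcripts; using the first",
                      gid, nrow(tx)))
      tx <- tx[1, ]
    }
    feats <- d[!is.na(d$Parent) & d$Parent == tx$ID, ]
    iv <- function(type) {
      f <- feats[feats$type == type, , drop = FALSE]
      f <- f[order(f$start), , drop = FALSE]
      m <- cbind(start = f$start, end = f$end)
      storage.mode(m) <- "integer"
      m
    }
    g <- list(gene_id = gid, chrom = grow$chrom, strand = grow$strand,
              tx_start = grow$start, tx_end = grow$end,
              exons = iv("exon"), cds = iv("CDS"),
              utr5 = iv("five_prime_UTR"), utr3 = iv("three_prime_UTR"))
    class(g) <- "gene_model"
    validate_gene_model(g)
    genes[[gid]] <- g
  }
  genes
}

#' @noRd
validate_gene_model <- function(g) {
  ex <- g$exons
  if (nrow(ex) && is.unsorted(ex[, 1]))
    imr_stop(sprintf("gene %s: exons not sorted", g$gene_id))
  if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
    imr_stop(sprintf("gene %s: overlapping exons", g$gene_id))
  cds_len <- sum(g$cds[, 2] - g$cds[, 1] + 1L)
  if (cds_len %% 3L != 0L)
    imr_stop(sprintf("gene %s: CDS length %d not divisible by 3",
                     g$gene_id, cds_len))
  invisible(g)
}

#' Category GRanges for a gene list, used by the region assigner
#' @noRd
region_ranges <- function(genes, flank = 5000L, splice_width = 2L) {
  mk <- function(chrom, m, gene_idx) {
    if (!length(chrom)) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]))
    S4Vectors::mcols(gr)$gene_idx <- gene_idx
    gr
  }
  acc <- list(cds = list(), splice = list(), utr5 = list(), utr3 = list(),
              intron = list(), up = list(), down = list())
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    push <- function(slot, m) {
      if (is.null(m) || !nrow(m)) return()
      acc[[slot]][[length(acc[[slot]]) + 1L]] <<-
        list(chrom = rep(g$chrom, nrow(m)), m = m,
             idx = rep(i, nrow(m)))
    }
    push("cds", g$cds); push("utr5", g$utr5); push("utr3", g$utr3)
    ex <- g$exons
    if (nrow(ex) > 1) {
      ints <- cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L)
      push("intron", ints)
      push("splice", rbind(
        cbind(ints[, 1], pmin(ints[, 1] + splice_width - 1L, ints[, 2])),
        cbind(pmax(ints[, 2] - splice_width + 1L, ints[, 1]), ints[, 2])))
    }
    if (g$strand == "+") {
      push("up", cbind(max(1L, g$tx_start - flank), g$tx_start - 1L))
      push("down", cbind(g$tx_end + 1L, g$tx_end + flank))
    } else {
      push("up", cbind(g$tx_end + 1L, g$tx_end + flank))
      push("down", cbind(max(1L, g$tx_start - flank), g$tx_start - 1L))
    }
  }
  lapply(acc, function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    mk(unlist(lapply(lst, `[[`, "chrom")),
       do.call(rbind, lapply(lst, `[[`, "m")),
       unlist(lapply(lst, `[[`, "idx")))
  })
}

#' Assign each variant a genomic region
#'
#' Categories follow a fixed precedence so every variant gets exactly one
#' label: cds > splice_region > utr5/utr3 > intron > upstream5kb >
#' downstream5kb > intergenic. The splice region is the first/last
#' `splice_width` bp of each intron; upstream/downstream extend `flank` bp
#' from the transcript boundaries, strand-aware. When a variant falls in
#' the flanking zone of several genes the nearer gene wins; at equal
#' distance upstream beats downstream. InDels are located by their first
#' changed base (anchor + 1).
#'
#' @param variants variant table (chrom, pos, ref, vclass).
#' @param genes list of `gene_model` objects.
#' @param flank upstream/downstream reach in bp.
#' @param splice_width splice-region width in bp.
#' @return data.frame with columns `region` and `gene_id` (NA for
#'   intergenic).
#' @export
assign_region <- function(variants, genes, flank = 5000L,
                          splice_width = 2L) {
  n <- nrow(variants)
  pos1 <- ifelse(variants$vclass == "SNP", variants$pos, variants$pos + 1L)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(pos1, pos1))
  rr <- region_ranges(genes, flank, splice_width)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  take <- function(cat_gr, label) {
    if (!length(cat_gr)) return()
    ov <- GenomicRanges::findOverlaps(vgr, cat_gr)
    hit <- S4Vectors::queryHits(ov)
    first <- !duplicated(hit)
    q <- hit[first]; s <- S4Vectors::subjectHits(ov)[first]
    free <- region[q] == "intergenic"
    region[q[free]] <<- label
    gene_id[q[free]] <<- gene_ids[S4Vectors::mcols(cat_gr)$gene_idx[s[free]]]
  }
  take(rr$cds, "cds")
  take(rr$splice, "splice_region")
  take(rr$utr5, "utr5")
  take(rr$utr3, "utr3")
  take(rr$intron, "intron")
  # flanking zones: nearest gene wins, tie -> upstream
  fl_gr <- c(rr$up, rr$down)
  fl_lab <- c(rep("upstream5kb", length(rr$up)),
              rep("downstream5kb", length(rr$down)))
  if (length(fl_gr)) {
    ov <- GenomicRanges::findOverlaps(vgr, fl_gr)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    keep <- region[q] == "intergenic"
    q <- q[keep]; s <- s[keep]
    if (length(q)) {
      gidx <- S4Vectors::mcols(fl_gr)$gene_idx[s]
      tx_s <- vapply(genes, `[[`, numeric(1), "tx_start")[gidx]
      tx_e <- vapply(genes, `[[`, numeric(1), "tx_end")[gidx]
      d <- pmax(tx_s - pos1[q], pos1[q] - tx_e)
      is_up <- fl_lab[s] == "upstream5kb"
      ord <- order(q, d, !is_up)   # per variant: distance, then upstream
      first <- !duplicated(q[ord])
      qf <- q[ord][first]; sf <- s[ord][first]
      region[qf] <- fl_lab[sf]
      gene_id[qf] <- gene_ids[S4Vectors::mcols(fl_gr)$gene_idx[sf]]
    }
  }
  data.frame(region = region, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Coding-order genomic map and reference CDS bases for a gene (cached)
#' @noRd
gene_coding_cache <- function(gene, genome, cache = NULL) {
  key <- gene$gene_id
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  map <- cds_position_map(gene)
  bases <- strsplit(cds_coding_seq(gene, genome), "")[[1]]
  val <- list(map = map, bases = bases)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Classify the coding effect of a variant inside a CDS
#'
#' SNPs: the affected codon is rebuilt on the coding strand and both
#' alleles are translated with the standard nuclear genetic code; the call
#' is synonymous, missense (with the amino-acid change), stop_gain,
#' stop_loss, or start_loss (initiator ATG disrupted). InDels: frameshift
#' when the length is not a multiple of 3, otherwise inframe_indel.
#'
#' @param variant one-row variant data.frame (chrom, pos, ref, alt,
#'   vclass, indel_len).
#' @param gene the `gene_model` whose CDS contains the variant.
#' @param genome named `DNAStringSet` reference.
#' @param cache optional environment for per-gene coding maps.
#' @return list: effect, aa_change (e.g. `"G245E"`, NA unless an
#'   amino-acid substitution), large_effect.
#' @export
classify_cds_effect <- function(variant, gene, genome, cache = NULL) {
  ref_at <- as.character(Biostrings::extractAt(
    genome[[variant$chrom]],
    IRanges::IRanges(variant$pos,
                     variant$pos + nchar(variant$ref) - 1L)))
  if (!identical(ref_at[[1]], variant$ref))
    imr_stop(sprintf(
      "reference mismatch at %s:%d (VCF %s, genome %s)", variant$chrom,
      variant$pos, variant$ref, ref_at[[1]]), class = "imr_internal_error")
  if (variant$vclass %in% c("INS", "DEL")) {
    eff <- if (variant$indel_len %% 3L != 0L) "frameshift"
    else "inframe_indel"
    return(list(effect = eff, aa_change = NA_character_,
                large_effect = eff %in% LARGE_EFFECTS))
  }
  if (variant$vclass != "SNP")
    return(list(effect = "none", aa_change = NA_character_,
                large_effect = FALSE))
  cc <- gene_coding_cache(gene, genome, cache)
  ci <- match(variant$pos, cc$map)
  if (is.na(ci))
    imr_stop(sprintf("position %s:%d not in CDS of %s", variant$chrom,
                     variant$pos, gene$gene_id),
             class = "imr_internal_error")
  codon_idx <- ceiling(ci / 3)
  off <- ci - (codon_idx - 1L) * 3L
  cod <- cc$bases[(codon_idx - 1L) * 3L + 1:3]
  alt_coding <- if (gene$strand == "+") variant$alt
  else comp_base(variant$alt)
  alt_cod <- cod; alt_cod[off] <- alt_coding
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[paste(cod, collapse = "")]]
  aa_alt <- code[[paste(alt_cod, collapse = "")]]
  effect <-
    if (codon_idx == 1L && paste(cod, collapse = "") == "ATG" &&
        paste(alt_cod, collapse = "") != "ATG") "start_loss"
    else if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gain"
    else if (aa_ref == "*") "stop_loss"
    else "missense"
  aa_change <- if (effect %in% c("missense", "stop_gain", "stop_loss"))
    sprintf("%s%d%s", aa_ref, codon_idx, aa_alt) else NA_character_
  list(effect = effect, aa_change = aa_change,
       large_effect = effect %in% LARGE_EFFECTS)
}

#' Annotate homozygous variants with region and effect
#'
#' Heterozygous calls are excluded (only homozygous differences between
#' two inbred accessions are meaningful for annotation). Variants in a CDS
#' get a coding-effect call; variants in a splice region are flagged
#' `splice_change` (large effect); all other regions carry effect `none`.
#'
#' @inheritParams assign_region
#' @param genome named `DNAStringSet` reference.
#' @param include_het keep heterozygous calls too (default FALSE).
#' @return the variant table with added columns region, gene_id, effect,
#'   aa_change, large_effect.
#' @export
annotate_variants <- function(variants, genes, genome, flank = 5000L,
                              splice_width = 2L, include_het = FALSE) {
  v <- if (include_het) variants
  else variants[variants$zygosity == "hom", , drop = FALSE]
  if (!nrow(v)) imr_stop("no variants to annotate")
  reg <- assign_region(v, genes, flank, splice_width)
  v$region <- reg$region
  v$gene_id <- reg$gene_id
  v$effect <- "none"
  v$aa_change <- NA_character_
  v$large_effect <- FALSE
  v$effect[v$region == "splice_region"] <- "splice_change"
  v$large_effect[v$region == "splice_region"] <- TRUE
  cache <- new.env(parent = emptyenv())
  cds_idx <- which(v$region == "cds")
  for (i in cds_idx) {
    res <- classify_cds_effect(v[i, ], genes[[v$gene_id[i]]], genome,
                               cache)
    v$effect[i] <- res$effect
    v$aa_change[i] <- res$aa_change
    v$large_effect[i] <- res$large_effect
  }
  rownames(v) <- NULL
  v
}

#' Summarise an annotation table
#'
#' Counts and percentages per region and per effect, the genic share
#' (UTRs + introns + splice regions + CDS), the share of intronic variants
#' in splice regions, and the non-synonymous/synonymous ratio
#' (missense + stop_gain + stop_loss + start_loss over synonymous;
#' `NA` when there are no synonymous calls).
#'
#' @param ann annotation table from [annotate_variants()].
#' @return list of class `annotation_summary`: `regions` and `effects`
#'   data.frames plus scalar shares.
#' @export
annotation_summary <- function(ann) {
  if (!nrow(ann)) imr_stop("empty annotation table")
  n <- nrow(ann)
  reg_levels <- c("intergenic", "upstream5kb", "downstream5kb", "utr5",
                  "utr3", "intron", "splice_region", "cds")
  reg <- table(factor(ann$region, levels = reg_levels))
  genic_cats <- c("utr5", "utr3", "intron", "splice_region", "cds")
  n_genic <- sum(reg[genic_cats])
  n_intronic <- sum(reg[c("intron", "splice_region")])
  eff <- table(factor(ann$effect,
                      levels = c("none", "synonymous", "missense",
                                 "stop_gain", "stop_loss", "start_loss",
                                 "frameshift", "inframe_indel",
                                 "splice_change")))
  n_ns <- sum(eff[c("missense", "stop_gain", "stop_loss", "start_loss")])
  out <- list(
    regions = data.frame(region = names(reg), n = as.integer(reg),
                         pct = 100 * as.integer(reg) / n,
                         stringsAsFactors = FALSE),
    effects = data.frame(effect = names(eff), n = as.integer(eff),
                         stringsAsFactors = FALSE),
    n = n, n_genic = n_genic, genic_pct = 100 * n_genic / n,
    intronic_of_genic_pct = if (n_genic > 0) 100 * n_intronic / n_genic
    else NA_real_,
    splice_of_intronic_pct = if (n_intronic > 0)
      100 * as.integer(reg["splice_region"]) / n_intronic else NA_real_,
    ns_s_ratio = ns_s_ratio(n_ns, as.integer(eff["synonymous"])))
  class(out) <- "annotation_summary"
  out
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("Annotation summary over %d variants\n", x$n))
  print(x$regions, row.names = FALSE)
  cat(sprintf("genic: %.2f%%  intronic of genic: %.2f%%  splice of intronic: %.2f%%\n",
              x$genic_pct, x$intronic_of_genic_pct,
              x$splice_of_intronic_pct))
  cat(sprintf("NS/S ratio: %s\n",
              ifelse(is.na(x$ns_s_ratio), "undefined",
                     sprintf("%.2f", x$ns_s_ratio))))
  invisible(x)
}

#' Non-synonymous / synonymous ratio
#' @param n_ns non-synonymous count (missense + stop/start changes).
#' @param n_syn synonymous count.
#' @return ratio, `NA` when `n_syn == 0`.
#' @examples ns_s_ratio(15224, 12894) # ~1.18
#' @export
ns_s_ratio <- function(n_ns, n_syn) {
  if (n_syn == 0) return(NA_real_)
  n_ns / n_syn
}
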