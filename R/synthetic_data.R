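# Seeded simulator for the whole pipeline: a reference genome with gene
# models, a divergent inbred accession (SNPs, InDels, a few SVs), a
# multi-accession genotype panel, and an F2 population segregating one
# recessive EMS-type (G->A) causal mutation at 3:1.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' polymorphism landscape reported for a cross of two divergent foxtail
#' millet accessions: SNP/InDel densities of 2719.65 and 485.61 per Mb, a
#' transition bias matching a Ts/Tv ratio of 2.73, an InDel length mixture
#' with about half single-base events, 21.44% heterozygous calls, and an F2
#' of 982 individuals.
#'
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param n_chromosomes,chrom_length number and length (bp) of chromosomes.
#' @param n_genes total number of genes, distributed round-robin over
#'   chromosomes.
#' @param snp_rate,indel_rate,sv_rate per-bp polymorphism rates (defaults:
#'   printed per-Mb densities / 1e6; SVs are rare optional events).
#' @param ts_bias probability a simulated SNP is a transition (A<->G, C<->T).
#' @param indel_len_mix probabilities of the three InDel length classes
#'   (1 bp, 2-20 bp, 21-200 bp); normalised to sum to 1.
#' @param het_fraction probability a variant is emitted as heterozygous.
#'   Heterozygous calls exercise downstream zygosity filters; they are not
#'   applied to the (inbred) alternate genome.
#' @param panel_size number of inbred accessions in the genotype panel.
#' @param panel_af fixed per-locus reference-allele frequency for the panel,
#'   or `NULL` to draw one per locus from `Beta(panel_af_beta)`.
#' @param panel_af_beta shape parameters of the per-locus allele-frequency
#'   prior.
#' @param f2_size number of F2 individuals.
#' @param causal_spec `NULL`, or `list(chrom =, pos =)`: plant one recessive
#'   G->A (coding strand) causal substitution in a CDS near `pos`.
#' @param gc_content genomic GC fraction (must lie in \[0.3, 0.6\]).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1e6,
                       n_genes = 100L,
                       snp_rate = 2719.65e-6,
                       indel_rate = 485.61e-6,
                       sv_rate = 2e-6,
                       ts_bias = 2.73 / 3.73,
                       indel_len_mix = c(len1 = 0.4807, len2_20 = 0.4434,
                                         len21_200 = 0.0670),
                       het_fraction = 0.2144,
                       panel_size = 200L,
                       panel_af = NULL,
                       panel_af_beta = c(1.2, 1.2),
                       f2_size = 982L,
                       causal_spec = NULL,
                       gc_content = 0.46) {
  if (any(c(snp_rate, indel_rate, sv_rate) < 0))
    imr_stop("variant rates must be >= 0")
  if (ts_bias < 0 || ts_bias > 1 || het_fraction < 0 || het_fraction > 1)
    imr_stop("ts_bias and het_fraction must lie in [0, 1]")
  if (length(indel_len_mix) != 3 || any(indel_len_mix < 0) ||
      sum(indel_len_mix) <= 0)
    imr_stop("indel_len_mix must be three non-negative class probabilities")
  if (gc_content < 0.3 || gc_content > 0.6)
    imr_stop("gc_content must lie in [0.3, 0.6]")
  if (!is.null(causal_spec) &&
      !all(c("chrom", "pos") %in% names(causal_spec)))
    imr_stop("causal_spec needs fields 'chrom' and 'pos'")
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    snp_rate = snp_rate, indel_rate = indel_rate, sv_rate = sv_rate,
    ts_bias = ts_bias,
    indel_len_mix = indel_len_mix / sum(indel_len_mix),
    het_fraction = het_fraction,
    panel_size = as.integer(panel_size), panel_af = panel_af,
    panel_af_beta = panel_af_beta,
    f2_size = as.integer(f2_size), causal_spec = causal_spec,
    gc_content = gc_content)
  class(cfg) <- "sim_config"
  cfg
}

# ---- gene structure ---------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

#' Draw one gene's exon/intron/UTR layout in transcript-forward coordinates
#' @noRd
draw_gene_structure <- function() {
  n_exons <- sample(2:5, 1)
  n_codons <- sample(80:300, 1)              # internal codons
  cds_len <- 3L * (n_codons + 2L)            # + start and stop codons
  repeat {                                   # split CDS; every piece >= 12 bp
    cuts <- sort(sample(seq_len(cds_len - 1L), n_exons - 1L))
    parts <- diff(c(0L, cuts, cds_len))
    if (all(parts >= 12L)) break
  }
  introns <- sample(120:500, n_exons - 1L, replace = TRUE)
  utr5 <- sample(100:300, 1)
  utr3 <- sample(100:300, 1)
  list(n_exons = n_exons, cds_parts = as.integer(parts),
       introns = as.integer(introns), utr5 = utr5, utr3 = utr3,
       n_codons = n_codons)
}

#' Lay a drawn structure out at a genomic offset on a strand
#'
#' Returns a `gene_model`: exon/CDS/UTR intervals as two-column matrices in
#' genomic (left-to-right) order, 1-based inclusive.
#' @noRd
layout_gene <- function(struct, chrom, start, strand, gene_id) {
  k <- struct$n_exons
  # transcript-forward relative coordinates (1-based)
  exon_len <- struct$cds_parts
  exon_len[1] <- exon_len[1] + struct$utr5
  exon_len[k] <- exon_len[k] + struct$utr3
  ex_start <- integer(k); ex_end <- integer(k)
  pos <- 1L
  for (i in seq_len(k)) {
    ex_start[i] <- pos
    ex_end[i] <- pos + exon_len[i] - 1L
    pos <- ex_end[i] + 1L
    if (i < k) pos <- pos + struct$introns[i]
  }
  glen <- ex_end[k]
  cds_start1 <- struct$utr5 + 1L                       # within exon 1
  cds <- cbind(ex_start, ex_end)
  cds[1, 1] <- ex_start[1] + struct$utr5
  cds[k, 2] <- ex_end[k] - struct$utr3
  utr5 <- cbind(ex_start[1], ex_start[1] + struct$utr5 - 1L)
  utr3 <- cbind(ex_end[k] - struct$utr3 + 1L, ex_end[k])
  exons <- cbind(ex_start, ex_end)
  mirror <- function(m) {
    m2 <- cbind(glen - m[, 2] + 1L, glen - m[, 1] + 1L)
    m2[rev(seq_len(nrow(m2))), , drop = FALSE]
  }
  if (strand == "-") {
    exons <- mirror(exons); cds <- mirror(cds)
    utr5 <- mirror(utr5); utr3 <- mirror(utr3)
  }
  shift <- function(m) {
    m <- m + start - 1L
    storage.mode(m) <- "integer"
    colnames(m) <- c("start", "end")
    m
  }
  g <- list(gene_id = gene_id, chrom = chrom, strand = strand,
            tx_start = start, tx_end = start + glen - 1L,
            exons = shift(exons), cds = shift(cds),
            utr5 = shift(utr5), utr3 = shift(utr3),
            n_codons = struct$n_codons + 2L)
  class(g) <- "gene_model"
  g
}

#' Genomic positions of CDS bases in coding (5'->3' transcript) order
#' @noRd
cds_position_map <- function(gene) {
  p <- unlist(lapply(seq_len(nrow(gene$cds)), function(i)
    seq.int(gene$cds[i, 1], gene$cds[i, 2])))
  if (gene$strand == "-") p <- rev(p)
  p
}

#' Coding-strand CDS sequence of a gene, read off a genome
#' @noRd
cds_coding_seq <- function(gene, genome) {
  s <- as.character(Biostrings::extractAt(
    genome[[gene$chrom]],
    IRanges::IRanges(gene$cds[, 1], gene$cds[, 2])))
  s <- paste(s, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

# ---- reference genome -------------------------------------------------------

#' Generate a reference genome with gene models
#'
#' Builds random chromosomes at the configured GC content and places
#' non-overlapping genes on them. Each gene has 2-5 exons, 5' and 3' UTRs,
#' a CDS whose length is divisible by 3, an ATG start and a stop codon on
#' the coding strand, no internal stop codons, and canonical GT..AG splice
#' dinucleotides.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_reference` with elements `genome`
#'   (named `DNAStringSet`), `genes` (list of `gene_model`), and
#'   `chrom_lengths` (named integer vector).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("Chr%d", seq_len(config$n_chromosomes))
  L <- config$chrom_length
  seqs <- vapply(chroms, function(ch) random_dna(L, config$gc_content),
                 character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  n_per_chrom <- tabulate(rep_len(seq_along(chroms), config$n_genes),
                          nbins = length(chroms))
  sense <- setdiff(all_codons(), STOP_CODONS)
  genes <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    k <- n_per_chrom[ci]
    if (k == 0L) next
    structs <- replicate(k, draw_gene_structure(), simplify = FALSE)
    glens <- vapply(structs, function(s) {
      len <- sum(s$cds_parts) + sum(s$introns) + s$utr5 + s$utr3
      as.integer(len)
    }, integer(1))
    margin <- 6000L; min_gap <- 2000L
    slack <- L - 2L * margin - sum(glens) - (k - 1L) * min_gap
    if (slack < 0L)
      imr_stop(sprintf(
        "cannot place %d genes (%d bp) on a %d bp chromosome", k,
        sum(glens), L))
    extra <- floor(diff(c(0, sort(runif(k)), 1)) * slack)
    starts <- margin + cumsum(extra[seq_len(k)]) +
      (seq_len(k) - 1L) * min_gap + c(0L, cumsum(glens)[-k]) + 1L
    strands <- sample(c("+", "-"), k, replace = TRUE)
    at <- IRanges::IRanges(); val <- character(0)
    for (j in seq_len(k)) {
      gi <- gi + 1L
      g <- layout_gene(structs[[j]], chroms[ci], as.integer(starts[j]),
                       strands[j], sprintf("gene%04d", gi))
      genes[[g$gene_id]] <- g
      # coding sequence: ATG + sense codons + stop
      cds_seq <- paste0(
        "ATG",
        paste(sample(sense, structs[[j]]$n_codons, replace = TRUE),
              collapse = ""),
        sample(STOP_CODONS, 1))
      gseq <- if (g$strand == "-") revcomp(cds_seq) else cds_seq
      w <- g$cds[, 2] - g$cds[, 1] + 1L
      off <- cumsum(c(0L, w[-length(w)]))
      pieces <- substring(gseq, off + 1L, off + w)
      at <- c(at, IRanges::IRanges(g$cds[, 1], g$cds[, 2]))
      val <- c(val, pieces)
      # canonical splice dinucleotides on introns
      ex <- g$exons
      if (nrow(ex) > 1) {
        int_s <- ex[-nrow(ex), 2] + 1L
        int_e <- ex[-1, 1] - 1L
        don <- if (g$strand == "+") "GT" else "CT"
        acc <- if (g$strand == "+") "AG" else "AC"
        at <- c(at, IRanges::IRanges(int_s, int_s + 1L),
                IRanges::IRanges(int_e - 1L, int_e))
        val <- c(val, rep(don, length(int_s)), rep(acc, length(int_e)))
      }
    }
    if (length(val))
      genome[[ci]] <- Biostrings::replaceAt(
        genome[[ci]], at, Biostrings::DNAStringSet(val))
  }
  ref <- list(genome = genome, genes = genes,
              chrom_lengths = setNames(rep(L, length(chroms)), chroms),
              config = config)
  class(ref) <- "sim_reference"
  ref
}

# ---- divergent accession ----------------------------------------------------

transition_of <- function(b) chartr("ACGT", "GTAC", b)

#' Simulate the divergent accession and its truth variant set
#'
#' Draws SNPs (transition-biased), InDels (three-class length mixture) and
#' rare SVs (INS/DEL/INV, 100-600 bp) along each chromosome, assigns
#' zygosity, optionally plants one recessive G->A causal substitution in a
#' CDS (EMS-type, guaranteed missense), and applies all homozygous
#' accession variants to produce the alternate genome. Positions are
#' 1-based with the usual anchored-base InDel convention.
#'
#' @param ref a `sim_reference` from [generate_reference()].
#' @param config a [sim_config()]; the causal variant is placed per
#'   `config$causal_spec`.
#' @return list of class `sim_mutation`: `alt_genome` (DNAStringSet),
#'   `variants` (data.frame of truth records with region labels),
#'   `truth` (list: `variants`, `causal_variant`, `causal_gene_id`,
#'   `chrom_lengths`).
#' @export
mutate_accession <- function(ref, config = ref$config) {
  stopifnot(inherits(ref, "sim_reference"))
  set.seed(config$seed + 1000L)
  out <- list()
  for (ch in names(ref$genome)) {
    seq_ch <- as.character(ref$genome[[ch]])
    L <- nchar(seq_ch)
    occupied <- logical(L)

    acc <- new.env(parent = emptyenv())
    acc$pos <- integer(0); acc$ref <- character(0)
    acc$alt <- character(0); acc$vclass <- character(0)
    acc$sv_len <- integer(0)
    add_row <- function(pos, refa, alta, vclass, sv_len = 0L) {
      i <- length(acc$pos) + 1L
      acc$pos[i] <- as.integer(pos); acc$ref[i] <- refa
      acc$alt[i] <- alta; acc$vclass[i] <- vclass
      acc$sv_len[i] <- as.integer(sv_len)
    }

    # SVs first (largest footprints), then InDels, then SNPs
    n_sv <- rbinom(1, L, config$sv_rate)
    if (n_sv > 0) {
      for (i in seq_len(n_sv)) {
        len <- sample(100:600, 1)
        p <- sample.int(L - len - 10L, 1) + 5L
        if (any(occupied[p:(p + len)])) next
        type <- sample(c("INS", "DEL", "INV"), 1)
        if (type == "DEL") {
          add_row(p, substr(seq_ch, p, p + len), substr(seq_ch, p, p),
                  "DEL", len)
          occupied[p:(p + len)] <- TRUE
        } else if (type == "INS") {
          add_row(p, substr(seq_ch, p, p),
                  paste0(substr(seq_ch, p, p), random_dna(len)), "INS", len)
          occupied[p] <- TRUE
        } else {
          add_row(p, substr(seq_ch, p, p), "<INV>", "INV", len)
          occupied[p:(p + len - 1L)] <- TRUE
        }
      }
    }

    n_ind <- rbinom(1, L, config$indel_rate)
    if (n_ind > 0) {
      cls <- sample.int(3L, n_ind, replace = TRUE,
                        prob = config$indel_len_mix)
      lens <- ifelse(cls == 1L, 1L,
                     ifelse(cls == 2L, sample(2:20, n_ind, replace = TRUE),
                            sample(21:200, n_ind, replace = TRUE)))
      for (i in seq_len(n_ind)) {
        len <- lens[i]
        p <- sample.int(L - len - 10L, 1) + 5L
        if (any(occupied[p:(p + len)])) next
        if (runif(1) < 0.5) {
          add_row(p, substr(seq_ch, p, p + len), substr(seq_ch, p, p),
                  "DEL", if (len >= 100L) len else 0L)
        } else {
          add_row(p, substr(seq_ch, p, p),
                  paste0(substr(seq_ch, p, p), random_dna(len)), "INS",
                  if (len >= 100L) len else 0L)
        }
        occupied[p:(p + len)] <- TRUE
      }
    }

    n_snp <- rbinom(1, L, config$snp_rate)
    if (n_snp > 0) {
      free <- which(!occupied)
      pos <- sort(sample(free, min(n_snp, length(free))))
      refb <- strsplit(substring(seq_ch, 1, L), "")[[1]][pos]
      is_ts <- runif(length(pos)) < config$ts_bias
      altb <- character(length(pos))
      altb[is_ts] <- transition_of(refb[is_ts])
      if (any(!is_ts)) {
        tv_map <- list(A = c("C", "T"), C = c("A", "G"),
                       G = c("C", "T"), T = c("A", "G"))
        altb[!is_ts] <- vapply(refb[!is_ts],
                               function(b) sample(tv_map[[b]], 1),
                               character(1))
      }
      for (i in seq_along(pos)) add_row(pos[i], refb[i], altb[i], "SNP")
    }
    out[[ch]] <- data.frame(
      chrom = rep(ch, length(acc$pos)), pos = acc$pos, ref = acc$ref,
      alt = acc$alt, vclass = acc$vclass,
      indel_len = ifelse(acc$vclass %in% c("INS", "DEL"),
                         abs(nchar(acc$ref) - nchar(acc$alt)), 0L),
      sv_len = acc$sv_len, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, out)
  variants <- variants[order(match(variants$chrom, names(ref$genome)),
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  variants$zygosity <- ifelse(runif(nrow(variants)) < config$het_fraction,
                              "het", "hom")
  variants$carrier <- rep("accession", nrow(variants))
  variants$causal <- rep(FALSE, nrow(variants))

  causal_row <- NULL
  causal_gene <- NA_character_
  if (!is.null(config$causal_spec)) {
    pl <- place_causal(ref, config$causal_spec)
    causal_gene <- pl$gene_id
    # drop accession variants whose footprint touches the causal site
    foot <- variants$pos <= pl$pos &
      (variants$pos + nchar(variants$ref) - 1L) >= pl$pos &
      variants$chrom == pl$chrom
    variants <- variants[!foot, , drop = FALSE]
    causal_row <- data.frame(
      chrom = pl$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
      vclass = "SNP", indel_len = 0L, sv_len = 0L, zygosity = "hom",
      carrier = "mutant_parent", causal = TRUE, stringsAsFactors = FALSE)
    variants <- rbind(variants, causal_row)
    variants <- variants[order(match(variants$chrom, names(ref$genome)),
                               variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
  }
  variants$region_truth <- label_regions_truth(variants, ref$genes)

  # alternate (mapping-parent) genome: homozygous accession variants only
  alt_genome <- ref$genome
  for (ch in names(ref$genome)) {
    vv <- variants[variants$chrom == ch & variants$zygosity == "hom" &
                     variants$carrier == "accession", , drop = FALSE]
    if (!nrow(vv)) next
    is_inv <- vv$vclass == "INV"
    at <- IRanges::IRanges(
      vv$pos,
      ifelse(is_inv, vv$pos + vv$sv_len - 1L, vv$pos + nchar(vv$ref) - 1L))
    val <- vv$alt
    if (any(is_inv))
      val[is_inv] <- revcomp(as.character(
        Biostrings::extractAt(ref$genome[[ch]], at[is_inv])))
    alt_genome[[ch]] <- Biostrings::replaceAt(
      ref$genome[[ch]], at, Biostrings::DNAStringSet(val))
  }

  res <- list(
    alt_genome = alt_genome,
    variants = variants,
    truth = list(variants = variants,
                 causal_variant = causal_row,
                 causal_gene_id = causal_gene,
                 chrom_lengths = ref$chrom_lengths),
    config = config)
  class(res) <- "sim_mutation"
  res
}

#' Find a CDS G (coding strand) near the requested position whose G->A
#' change is missense
#' @noRd
place_causal <- function(ref, causal_spec) {
  ch <- causal_spec$chrom; target <- causal_spec$pos
  genes <- Filter(function(g) g$chrom == ch, ref$genes)
  if (!length(genes)) imr_stop("causal_spec chromosome has no genes")
  mid <- vapply(genes, function(g) (g$tx_start + g$tx_end) / 2, numeric(1))
  code <- Biostrings::GENETIC_CODE
  for (g in genes[order(abs(mid - target))]) {
    map <- cds_position_map(g)
    cds <- cds_coding_seq(g, ref$genome)
    bases <- strsplit(cds, "")[[1]]
    n_cod <- length(bases) / 3
    cand <- which(bases == "G")
    cand <- cand[ceiling(cand / 3) > 1 & ceiling(cand / 3) < n_cod]
    if (!length(cand)) next
    ok <- vapply(cand, function(i) {
      ci <- ceiling(i / 3); off <- i - (ci - 1L) * 3L
      cod <- bases[(ci - 1L) * 3L + 1:3]
      alt <- cod; alt[off] <- "A"
      aa_r <- code[[paste(cod, collapse = "")]]
      aa_a <- code[[paste(alt, collapse = "")]]
      aa_r != aa_a && aa_r != "*" && aa_a != "*"
    }, logical(1))
    cand <- cand[ok]
    if (!length(cand)) next
    i <- cand[which.min(abs(map[cand] - target))]
    gpos <- map[i]
    if (g$strand == "+") {
      return(list(chrom = ch, pos = gpos, ref = "G", alt = "A",
                  gene_id = g$gene_id))
    } else {
      return(list(chrom = ch, pos = gpos, ref = "C", alt = "T",
                  gene_id = g$gene_id))
    }
  }
  imr_stop("no suitable G (coding strand, missense on G->A) near causal_spec")
}

#' Region labels derived directly from the generator's gene layout
#'
#' Independent, loop-based labelling used as the truth against which the
#' annotation module is checked. Precedence: cds > splice_region > UTRs >
#' intron > upstream5kb > downstream5kb > intergenic; ties between two
#' genes' flanking zones go to the nearer gene, then upstream.
#' @noRd
label_regions_truth <- function(variants, genes, flank = 5000L,
                                splice_width = 2L) {
  pos1 <- ifelse(variants$vclass == "SNP", variants$pos, variants$pos + 1L)
  # upstream and downstream share a rank: between two genes' flanking
  # zones the nearer gene wins, and only a distance tie prefers upstream
  rank <- c(cds = 1, splice_region = 2, utr5 = 3, utr3 = 3, intron = 4,
            upstream5kb = 5, downstream5kb = 5, intergenic = 7)
  lab <- rep("intergenic", nrow(variants))
  best_rank <- rep(7, nrow(variants))
  best_dist <- rep(Inf, nrow(variants))
  in_iv <- function(p, m) {
    if (is.null(m) || nrow(m) == 0) return(rep(FALSE, length(p)))
    res <- rep(FALSE, length(p))
    for (i in seq_len(nrow(m))) res <- res | (p >= m[i, 1] & p <= m[i, 2])
    res
  }
  for (g in genes) {
    sel <- which(variants$chrom == g$chrom &
                   pos1 >= g$tx_start - flank & pos1 <= g$tx_end + flank)
    if (!length(sel)) next
    p <- pos1[sel]
    inside <- p >= g$tx_start & p <= g$tx_end
    this_lab <- rep(NA_character_, length(p))
    if (any(inside)) {
      ex <- g$exons
      ints <- if (nrow(ex) > 1)
        cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L) else NULL
      spl <- NULL
      if (!is.null(ints))
        spl <- rbind(cbind(ints[, 1], ints[, 1] + splice_width - 1L),
                     cbind(ints[, 2] - splice_width + 1L, ints[, 2]))
      this_lab[inside & in_iv(p, g$cds)] <- "cds"
      idx <- inside & is.na(this_lab) & in_iv(p, spl)
      this_lab[idx] <- "splice_region"
      idx <- inside & is.na(this_lab) & in_iv(p, g$utr5)
      this_lab[idx] <- "utr5"
      idx <- inside & is.na(this_lab) & in_iv(p, g$utr3)
      this_lab[idx] <- "utr3"
      this_lab[inside & is.na(this_lab)] <- "intron"
    }
    up <- if (g$strand == "+") p < g$tx_start else p > g$tx_end
    this_lab[!inside & up] <- "upstream5kb"
    this_lab[!inside & !up] <- "downstream5kb"
    d <- pmax(g$tx_start - p, p - g$tx_end, 0L)
    r <- rank[this_lab]
    upd <- r < best_rank[sel] |
      (r == best_rank[sel] & r == 5 &
         (d < best_dist[sel] |
            (d == best_dist[sel] & this_lab == "upstream5kb" &
               lab[sel] == "downstream5kb")))
    w <- sel[upd]
    lab[w] <- this_lab[upd]
    best_rank[w] <- r[upd]
    best_dist[w] <- d[upd]
  }
  lab
}

# ---- accession panel --------------------------------------------------------

#' Simulate a genotype panel of inbred accessions
#'
#' For each locus a reference-allele frequency is drawn from the configured
#' prior (or fixed at `config$panel_af`) and each inbred accession draws a
#' homozygous allele at that frequency (0 = reference, 1 = alternate).
#'
#' @param variants truth variant data.frame (typically from
#'   [mutate_accession()]); loci are keyed `chrom_pos`.
#' @param config a [sim_config()].
#' @return data.frame of class `accession_panel`: `accession` column plus
#'   one 0/1 column per locus; attribute `loci` holds the locus table.
#' @export
generate_panel <- function(variants, config) {
  if (config$panel_size < 2L) imr_stop("panel_size must be >= 2")
  set.seed(config$seed + 2000L)
  loci <- sprintf("%s_%d", variants$chrom, variants$pos)
  n <- config$panel_size
  p_ref <- if (!is.null(config$panel_af)) rep(config$panel_af, length(loci))
  else stats::rbeta(length(loci), config$panel_af_beta[1],
                    config$panel_af_beta[2])
  geno <- vapply(p_ref, function(p) rbinom(n, 1L, 1 - p), integer(n))
  colnames(geno) <- loci
  panel <- data.frame(accession = sprintf("acc%04d", seq_len(n)),
                      geno, check.names = FALSE, stringsAsFactors = FALSE)
  attr(panel, "loci") <- data.frame(locus = loci, chrom = variants$chrom,
                                    pos = variants$pos,
                                    stringsAsFactors = FALSE)
  class(panel) <- c("accession_panel", "data.frame")
  panel
}

# ---- F2 population ----------------------------------------------------------

#' Simulate an F2 population segregating the planted recessive mutation
#'
#' Each individual receives two recombinant gametes per chromosome (one
#' obligate crossover plus Poisson(1) extras, uniform breakpoints).
#' Haplotype "A" is the mutant parent (reference background carrying the
#' causal allele); "B" is the mapping accession. Marker genotypes are coded
#' A/B/H; phenotype is `mutant` iff the individual is homozygous A at the
#' causal position.
#'
#' @param truth `truth` element of a [mutate_accession()] result (needs a
#'   planted causal variant).
#' @param markers data.frame with `marker_id`, `chrom`, `pos`.
#' @param config a [sim_config()].
#' @return object of class `f2_population`: `individuals` (id, phenotype),
#'   `geno` (individuals x markers character matrix), `markers`, `gametes`
#'   (per individual/chromosome crossover lists), `causal`,
#'   `chrom_lengths`.
#' @export
generate_f2 <- function(truth, markers, config) {
  if (is.null(truth$causal_variant))
    imr_stop("truth carries no causal variant; set causal_spec")
  causal <- truth$causal_variant
  if (!any(markers$chrom == causal$chrom))
    imr_stop("no markers on the causal chromosome")
  set.seed(config$seed + 3000L)
  chroms <- names(truth$chrom_lengths)
  n <- config$f2_size
  m <- markers[order(match(markers$chrom, chroms), markers$pos), ,
               drop = FALSE]
  geno <- matrix(NA_character_, n, nrow(m),
                 dimnames = list(NULL, m$marker_id))
  phen <- character(n)
  gametes <- vector("list", n)
  for (ind in seq_len(n)) {
    gam_i <- list()
    anc2 <- matrix(NA_character_, 2L, nrow(m))
    caus_anc <- c(NA_character_, NA_character_)
    for (ch in chroms) {
      L <- truth$chrom_lengths[[ch]]
      midx <- which(m$chrom == ch)
      pair <- vector("list", 2L)
      for (h in 1:2) {
        xo <- sort(runif(1L + rpois(1, 1), 1, L))
        start <- sample(c("A", "B"), 1)
        pair[[h]] <- list(start = start, xo = xo)
        if (length(midx)) {
          flips <- findInterval(m$pos[midx], xo)
          anc2[h, midx] <- ifelse(flips %% 2 == 0, start,
                                  setdiff(c("A", "B"), start))
        }
        if (ch == causal$chrom) {
          fl <- findInterval(causal$pos, xo)
          caus_anc[h] <- if (fl %% 2 == 0) start else
            setdiff(c("A", "B"), start)
        }
      }
      gam_i[[ch]] <- pair
    }
    geno[ind, ] <- ifelse(anc2[1, ] == anc2[2, ], anc2[1, ], "H")
    phen[ind] <- if (all(caus_anc == "A")) "mutant" else "wild"
    gametes[[ind]] <- gam_i
  }
  pop <- list(
    individuals = data.frame(id = sprintf("F2_%04d", seq_len(n)),
                             phenotype = phen, stringsAsFactors = FALSE),
    geno = geno, markers = m, gametes = gametes,
    causal = list(chrom = causal$chrom, pos = causal$pos),
    chrom_lengths = truth$chrom_lengths)
  class(pop) <- "f2_population"
  pop
}

#' Ancestry genotype of F2 individuals at an arbitrary position
#'
#' @param pop an `f2_population`.
#' @param chrom,pos genomic position.
#' @param individuals indices (default all).
#' @return character vector of codes in `{A, B, H}`.
#' @export
genotype_at <- function(pop, chrom, pos, individuals = NULL) {
  idx <- individuals %||% seq_len(nrow(pop$individuals))
  vapply(idx, function(ind) {
    anc <- vapply(pop$gametes[[ind]][[chrom]], function(g) {
      fl <- findInterval(pos, g$xo)
      if (fl %% 2 == 0) g$start else setdiff(c("A", "B"), g$start)
    }, character(1))
    if (anc[1] == anc[2]) anc[1] else "H"
  }, character(1))
}

#' Pool allele frequencies for BSA-seq style scans
#'
#' Samples a mutant (recessive) pool and a wild pool from an F2 population
#' and computes, for each truth variant, the alternate-allele frequency in
#' each pool by counting carrier haplotypes (accession variants ride on
#' haplotype B; the causal mutation on haplotype A). Heterozygous truth
#' calls are skipped: they are not parental differences in an inbred cross.
#'
#' @param pop an `f2_population`.
#' @param variants truth variants data.frame (with `carrier`, `zygosity`).
#' @param n_mutant,n_wild pool sizes.
#' @param seed sampling seed.
#' @return data.frame: chrom, pos, ref, alt, af_mutant_pool, af_wild_pool.
#' @export
pool_allele_freqs <- function(pop, variants, n_mutant = 30L, n_wild = 30L,
                              seed = 1L) {
  set.seed(seed)
  rec <- which(pop$individuals$phenotype == "mutant")
  wld <- which(pop$individuals$phenotype == "wild")
  if (length(rec) < n_mutant || length(wld) < n_wild)
    imr_stop("not enough individuals for the requested pool sizes")
  mut_pool <- sample(rec, n_mutant)
  wld_pool <- sample(wld, n_wild)
  vv <- variants[variants$zygosity == "hom" & variants$vclass != "INV", ,
                 drop = FALSE]
  af_for <- function(pool) {
    af <- numeric(nrow(vv))
    for (ch in unique(vv$chrom)) {
      vi <- which(vv$chrom == ch)
      cnt <- numeric(length(vi))
      for (ind in pool) {
        for (g in pop$gametes[[ind]][[ch]]) {
          fl <- findInterval(vv$pos[vi], g$xo)
          anc <- ifelse(fl %% 2 == 0, g$start,
                        setdiff(c("A", "B"), g$start))
          carrier <- ifelse(vv$carrier[vi] == "accession", "B", "A")
          cnt <- cnt + (anc == carrier)
        }
      }
      af[vi] <- cnt / (2 * length(pool))
    }
    af
  }
  data.frame(chrom = vv$chrom, pos = vv$pos, ref = vv$ref, alt = vv$alt,
             af_mutant_pool = af_for(mut_pool),
             af_wild_pool = af_for(wld_pool),
             stringsAsFactors = FALSE)
}

#' Pick genome-wide marker loci from the truth variant set
#'
#' Selects homozygous InDels of marker-suitable length (20-200 bp) spaced
#' as evenly as possible: `n_per_chrom` per chromosome at quantile
#' positions. Used to emulate a genome-wide agarose marker set for BSA.
#'
#' @param variants truth variants data.frame.
#' @param chrom_lengths named lengths.
#' @param n_per_chrom markers per chromosome.
#' @return data.frame `marker_id`, `chrom`, `pos`.
#' @export
pick_genomewide_markers <- function(variants, chrom_lengths,
                                    n_per_chrom = 6L) {
  cand <- variants[variants$zygosity == "hom" &
                     variants$vclass %in% c("INS", "DEL") &
                     variants$indel_len >= 20 & variants$indel_len <= 200 &
                     !variants$causal, , drop = FALSE]
  out <- list()
  for (ch in names(chrom_lengths)) {
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    if (!nrow(cc)) next
    targets <- chrom_lengths[[ch]] * (seq_len(n_per_chrom) - 0.5) /
      n_per_chrom
    sel <- unique(vapply(targets, function(t)
      cc$pos[which.min(abs(cc$pos - t))], numeric(1)))
    cc <- cc[match(sel, cc$pos), , drop = FALSE]
    cc <- cc[order(cc$pos), ]
    out[[ch]] <- data.frame(
      marker_id = sprintf("In%d-%d", chrom_number(ch), seq_len(nrow(cc))),
      chrom = ch, pos = cc$pos, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# ---- writers ----------------------------------------------------------------

#' Write a genome to FASTA
#' @param genome named `DNAStringSet`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Convert gene models to a GFF3-style GRanges
#' @noRd
gene_models_granges <- function(genes) {
  rows <- list()
  for (g in genes) {
    add <- function(type, m, id, parent, phase = NA_integer_) {
      if (is.null(m) || nrow(m) == 0) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = g$chrom, start = m[, 1], end = m[, 2], strand = g$strand,
        type = type, ID = id, Parent = parent, phase = phase,
        stringsAsFactors = FALSE)
    }
    tx <- paste0(g$gene_id, ".1")
    # GFF3 phase: bases to skip in each CDS piece to reach a codon start
    w <- g$cds[, 2] - g$cds[, 1] + 1L
    cum <- cumsum(c(0L, if (g$strand == "+") w[-length(w)] else
      rev(w)[-length(w)]))
    phase <- (3L - cum %% 3L) %% 3L
    if (g$strand == "-") phase <- rev(phase)
    add("gene", cbind(g$tx_start, g$tx_end), g$gene_id, NA)
    add("mRNA", cbind(g$tx_start, g$tx_end), tx, g$gene_id)
    add("exon", g$exons, paste0(tx, ".exon", seq_len(nrow(g$exons))), tx)
    add("CDS", g$cds, paste0(tx, ".cds", seq_len(nrow(g$cds))), tx,
        phase = phase)
    add("five_prime_UTR", g$utr5, paste0(tx, ".utr5"), tx)
    add("three_prime_UTR", g$utr3, paste0(tx, ".utr3"), tx)
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start, d$end), strand = d$strand)
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$ID <- d$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(d$Parent), "", d$Parent)
  S4Vectors::mcols(gr)$phase <- d$phase
  gr
}

#' Write gene models to GFF3
#' @param genes list of `gene_model` objects.
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- gene_models_granges(genes)
  p <- S4Vectors::mcols(gr)$Parent
  S4Vectors::mcols(gr)$Parent <- ifelse(p == "", NA_character_, p)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write truth variants to a VCF v4.2 file
#'
#' Minimal single-sample VCF: GT encodes zygosity (1/1 or 0/1); INFO
#' carries SVTYPE/SVLEN/END for symbolic inversions and CAUSAL=1 for the
#' planted mutation. The generator seed is recorded in the header.
#'
#' @param variants truth variants data.frame.
#' @param chrom_lengths named chromosome lengths (for contig headers).
#' @param path output file.
#' @param seed seed recorded in the header.
#' @export
write_truth_vcf <- function(variants, chrom_lengths, path, seed = NA) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=indelmapr_simulator",
    sprintf("##indelmapr_seed=%s", seed),
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
    '##INFO=<ID=CAUSAL,Number=0,Type=Flag,Description="Planted causal">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sample1", sep = "\t"))
  info <- ifelse(
    variants$vclass == "INV",
    sprintf("SVTYPE=INV;SVLEN=%d;END=%d", variants$sv_len,
            variants$pos + variants$sv_len - 1L),
    ifelse(variants$sv_len >= 100L,
           sprintf("SVTYPE=%s;SVLEN=%d", variants$vclass, variants$sv_len),
           "."))
  info <- ifelse(variants$causal,
                 ifelse(info == ".", "CAUSAL", paste0(info, ";CAUSAL")),
                 info)
  gt <- ifelse(variants$zygosity == "hom", "1/1", "0/1")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                  variants$chrom, variants$pos,
                  sprintf("var%06d", seq_len(nrow(variants))),
                  variants$ref, variants$alt, info, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an accession panel to TSV
#' @param panel an `accession_panel`.
#' @param path output file.
#' @export
write_panel_tsv <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an accession panel TSV
#' @param path panel file written by [write_panel_tsv()].
#' @return `accession_panel` data.frame.
#' @export
read_panel_tsv <- function(path) {
  panel <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
  loci <- setdiff(colnames(panel), "accession")
  attr(panel, "loci") <- data.frame(
    locus = loci,
    chrom = sub("_[0-9]+$", "", loci),
    pos = as.integer(sub("^.*_", "", loci)), stringsAsFactors = FALSE)
  class(panel) <- c("accession_panel", "data.frame")
  panel
}

#' Write an F2 genotype/phenotype table to TSV
#' @param pop an `f2_population`.
#' @param path output file.
#' @export
write_f2_tsv <- function(pop, path) {
  d <- cbind(pop$individuals, as.data.frame(pop$geno,
                                            stringsAsFactors = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an F2 genotype/phenotype table
#'
#' Reconstructs a marker-level `f2_population` (without gamete breakpoints,
#' which only the simulator knows).
#' @param path TSV written by [write_f2_tsv()].
#' @param markers marker table (`marker_id`, `chrom`, `pos`) for the
#'   genotype columns.
#' @return `f2_population` (fields `individuals`, `geno`, `markers`).
#' @export
read_f2_tsv <- function(path, markers) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  geno <- as.matrix(d[, setdiff(colnames(d), c("id", "phenotype")),
                      drop = FALSE])
  pop <- list(individuals = d[, c("id", "phenotype")], geno = geno,
              markers = markers[match(colnames(geno), markers$marker_id), ])
  class(pop) <- "f2_population"
  pop
}
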