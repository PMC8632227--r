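# Shared fixtures: one medium simulated dataset reused across test files
# (built lazily, once per test run), hand-built gene models with known
# coordinates, and coordinate-mirroring helpers for strand-symmetry checks.

shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, n_chromosomes = 2L,
                        chrom_length = 300000L, n_genes = 30L,
                        causal_spec = list(chrom = "Chr2", pos = 150000L))
      ref <- generate_reference(cfg)
      mut <- mutate_accession(ref, cfg)
      cache <<- list(cfg = cfg, ref = ref, mut = mut)
    }
    cache
  }
})

shared_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- shared_sim()
      causal <- s$mut$truth$causal_variant
      gw <- pick_genomewide_markers(s$mut$variants, s$ref$chrom_lengths,
                                    6L)
      extra <- data.frame(
        marker_id = c("CM", sprintf("FM%d", 1:8)),
        chrom = causal$chrom,
        pos = causal$pos + c(0L, -30000L, -10000L, -3000L, -500L, 500L,
                             3000L, 10000L, 30000L),
        stringsAsFactors = FALSE)
      markers <- rbind(gw, extra)
      pop <- generate_f2(s$mut$truth, markers, s$cfg)
      cache <<- list(pop = pop, markers = markers, causal = causal,
                     sim = s)
    }
    cache
  }
})

# Hand-built minus-strand gene with known coordinates:
# tx 10001..12000, exons 10001..10600 and 10801..12000, intron
# 10601..10800, utr5 (coding 5', genomic right) 11901..12000,
# CDS 10201..10600 + 10801..11900 (1500 bp), utr3 10001..10200.
minus_gene <- function() {
  iv <- function(...) {
    m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  }
  g <- list(gene_id = "gM", chrom = "Chr1", strand = "-",
            tx_start = 10001L, tx_end = 12000L,
            exons = iv(10001, 10600, 10801, 12000),
            cds = iv(10201, 10600, 10801, 11900),
            utr5 = iv(11901, 12000), utr3 = iv(10001, 10200))
  class(g) <- "gene_model"
  g
}

# Plus-strand gene embedded in a concrete genome, with codon 5 forced to
# GGA: utr5 1001..1100, CDS 1101..1250 + 1451..1600 (300 bp = 100
# codons), intron 1251..1450, utr3 1601..1700.
plus_gene_with_genome <- function(seed = 7) {
  set.seed(seed)
  n <- 3000L
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  iv <- function(...) {
    m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  }
  g <- list(gene_id = "gP", chrom = "Chr1", strand = "+",
            tx_start = 1001L, tx_end = 1700L,
            exons = iv(1001, 1250, 1451, 1700),
            cds = iv(1101, 1250, 1451, 1600),
            utr5 = iv(1001, 1100), utr3 = iv(1601, 1700))
  class(g) <- "gene_model"
  sense <- setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                      c("A","C","G","T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  cds_seq <- paste0("ATG", paste(sample(sense, 98, replace = TRUE),
                                 collapse = ""), "TAA")
  substr(cds_seq, 13, 15) <- "GGA"      # codon 5
  pieces <- c(substr(cds_seq, 1, 150), substr(cds_seq, 151, 300))
  b <- bases
  b[1101:1250] <- strsplit(pieces[1], "")[[1]]
  b[1451:1600] <- strsplit(pieces[2], "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(b, collapse = ""))
  names(genome) <- "Chr1"
  list(gene = g, genome = genome)
}

# Coordinate mirror: reverse-complement the genome and flip every gene.
mirror_gene <- function(g, L) {
  flip <- function(m) {
    m2 <- cbind(L - m[, 2] + 1L, L - m[, 1] + 1L)
    m2 <- m2[rev(seq_len(nrow(m2))), , drop = FALSE]
    storage.mode(m2) <- "integer"
    colnames(m2) <- c("start", "end")
    m2
  }
  g2 <- g
  g2$strand <- if (g$strand == "+") "-" else "+"
  g2$tx_start <- L - g$tx_end + 1L
  g2$tx_end <- L - g$tx_start + 1L
  for (f in c("exons", "cds", "utr5", "utr3")) g2[[f]] <- flip(g[[f]])
  g2
}

mirror_genome <- function(genome) {
  g <- Biostrings::reverseComplement(genome)
  names(g) <- names(genome)
  g
}

mirror_snps <- function(variants, L) {
  v <- variants
  v$pos <- L - variants$pos + 1L
  v$ref <- chartr("ACGT", "TGCA", variants$ref)
  v$alt <- chartr("ACGT", "TGCA", variants$alt)
  v
}

# Minimal variant-row constructor
vrow <- function(chrom = "Chr1", pos, ref, alt, zygosity = "hom",
                 sv_len = 0L) {
  vclass <- if (alt == "<INV>") "INV"
  else if (nchar(ref) == 1 && nchar(alt) == 1) "SNP"
  else if (nchar(alt) > nchar(ref)) "INS" else "DEL"
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = vclass,
             indel_len = if (vclass %in% c("INS", "DEL"))
               abs(nchar(ref) - nchar(alt)) else 0L,
             sv_len = as.integer(sv_len), zygosity = zygosity,
             carrier = "accession", causal = FALSE,
             stringsAsFactors = FALSE)
}

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=Chr1,length=100000>",
           "##contig=<ID=Chr2,length=100000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", sep = "\t"))
  writeLines(c(hdr, lines), path)
  path
}
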