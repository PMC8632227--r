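test_that("region assignment resolves hand-worked minus-strand boundaries", {
  g <- minus_gene()
  at <- function(pos, ref = "A", alt = "G")
    vrow(pos = pos, ref = ref, alt = alt)
  reg <- function(pos) assign_region(at(pos), list(g))$region
  expect_identical(reg(10500), "cds")
  expect_identical(reg(10601), "splice_region")   # intron edge, 1st bp
  expect_identical(reg(10602), "splice_region")
  expect_identical(reg(10603), "intron")
  expect_identical(reg(10700), "intron")
  expect_identical(reg(10800), "splice_region")   # intron edge, last bp
  expect_identical(reg(11950), "utr5")            # genomic right = coding 5'
  expect_identical(reg(10100), "utr3")
  # minus strand: upstream is beyond tx_end
  expect_identical(reg(12001), "upstream5kb")
  expect_identical(reg(12000 + 4999), "upstream5kb")
  expect_identical(reg(12000 + 5001), "intergenic")
  expect_identical(reg(10000), "downstream5kb")
  expect_identical(reg(10001 - 5000), "downstream5kb")
  expect_identical(reg(10001 - 5001), "intergenic")
})

test_that("flanking-zone ties go to the nearer gene, then upstream", {
  gL <- minus_gene()                          # tx 10001..12000, minus
  iv <- function(...) {
    m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end"); m
  }
  gR <- list(gene_id = "gR", chrom = "Chr1", strand = "+",
             tx_start = 15001L, tx_end = 16000L,
             exons = iv(15001, 16000), cds = iv(15101, 15700),
             utr5 = iv(15001, 15100), utr3 = iv(15701, 16000))
  class(gR) <- "gene_model"
  genes <- list(gL, gR)
  # pos 12500: 500 bp from gL (upstream of minus gene), 2501 bp from gR
  r1 <- assign_region(vrow(pos = 12500, ref = "A", alt = "G"), genes)
  expect_identical(r1$region, "upstream5kb")
  expect_identical(r1$gene_id, "gM")
  # pos 14800: 201 bp from gR (upstream), 2800 bp from gL
  r2 <- assign_region(vrow(pos = 14800, ref = "A", alt = "G"), genes)
  expect_identical(r2$gene_id, "gR")
  expect_identical(r2$region, "upstream5kb")
})

test_that("coding effects include the canonical GGA Gly->Glu missense case", {
  fx <- plus_gene_with_genome()
  # codon 5 is GGA at coding positions 13-15 -> genomic 1113-1115
  v <- vrow(pos = 1114, ref = "G", alt = "A")
  res <- classify_cds_effect(v, fx$gene, fx$genome)
  expect_identical(res$effect, "missense")
  expect_identical(res$aa_change, "G5E")
  expect_false(res$large_effect)
  # 1-bp deletion in CDS: frameshift, large effect
  b <- substr(as.character(fx$genome[[1]]), 1120, 1121)
  del <- vrow(pos = 1120, ref = b, alt = substr(b, 1, 1))
  resd <- classify_cds_effect(del, fx$gene, fx$genome)
  expect_identical(resd$effect, "frameshift")
  expect_true(resd$large_effect)
  # 3-bp deletion: in-frame
  b3 <- substr(as.character(fx$genome[[1]]), 1120, 1123)
  del3 <- vrow(pos = 1120, ref = b3, alt = substr(b3, 1, 1))
  expect_identical(classify_cds_effect(del3, fx$gene, fx$genome)$effect,
                   "inframe_indel")
  # disrupting the initiator ATG
  start_v <- vrow(pos = 1101, ref = "A", alt = "C")
  expect_identical(classify_cds_effect(start_v, fx$gene, fx$genome)$effect,
                   "start_loss")
  # reference mismatch is refused
  bad <- vrow(pos = 1114, ref = "C", alt = "A")
  expect_error(classify_cds_effect(bad, fx$gene, fx$genome),
               "mismatch", class = "imr_internal_error")
})

test_that("SNP effect calls agree with a brute-force translation oracle", {
  s <- shared_sim()
  code <- Biostrings::GENETIC_CODE
  set.seed(101)
  genes <- s$ref$genes
  checked <- 0L
  cache <- new.env()
  while (checked < 200L) {
    g <- genes[[sample(length(genes), 1)]]
    # test-side coding map, built independently
    pieces <- lapply(seq_len(nrow(g$cds)), function(i)
      seq.int(g$cds[i, 1], g$cds[i, 2]))
    map <- unlist(pieces)
    cds_chars <- strsplit(paste(as.character(Biostrings::extractAt(
      s$ref$genome[[g$chrom]],
      IRanges::IRanges(g$cds[, 1], g$cds[, 2]))), collapse = ""),
      "")[[1]]
    if (g$strand == "-") {
      map <- rev(map)
      cds_chars <- rev(chartr("ACGT", "TGCA", cds_chars))
    }
    n_cod <- length(map) / 3
    ci <- sample(2:(n_cod - 1), 1)            # skip start and stop codons
    cod <- cds_chars[(ci - 1) * 3 + 1:3]
    for (off in 1:3) {
      for (alt_c in setdiff(c("A", "C", "G", "T"), cod[off])) {
        gpos <- map[(ci - 1) * 3 + off]
        gref <- if (g$strand == "+") cod[off] else
          chartr("ACGT", "TGCA", cod[off])
        galt <- if (g$strand == "+") alt_c else
          chartr("ACGT", "TGCA", alt_c)
        res <- classify_cds_effect(vrow(chrom = g$chrom, pos = gpos,
                                        ref = gref, alt = galt),
                                   g, s$ref$genome, cache)
        alt_cod <- cod; alt_cod[off] <- alt_c
        aa_r <- code[[paste(cod, collapse = "")]]
        aa_a <- code[[paste(alt_cod, collapse = "")]]
        expected <- if (aa_r == aa_a) "synonymous"
        else if (aa_a == "*") "stop_gain"
        else if (aa_r == "*") "stop_loss"
        else "missense"
        expect_identical(res$effect, expected)
        if (expected == "missense")
          expect_identical(res$aa_change, sprintf("%s%d%s", aa_r, ci,
                                                  aa_a))
      }
    }
    checked <- checked + 1L
  }
})

test_that("effect calls are invariant under genome reverse-complement", {
  s <- shared_sim()
  L <- s$cfg$chrom_length
  genome_m <- mirror_genome(s$ref$genome)
  genes_m <- lapply(s$ref$genes, mirror_gene, L = L)
  v <- s$mut$variants
  snps <- v[v$vclass == "SNP" & v$zygosity == "hom", ]
  snps <- snps[seq(1, nrow(snps), by = 7), ]   # subsample for speed
  ann <- annotate_variants(snps, s$ref$genes, s$ref$genome)
  ann_m <- annotate_variants(mirror_snps(snps, L), genes_m, genome_m)
  expect_identical(ann_m$region, ann$region)
  expect_identical(ann_m$effect, ann$effect)
  expect_identical(ann_m$aa_change, ann$aa_change)
})

test_that("assigned regions match the generator's independent truth labels", {
  s <- shared_sim()
  hom <- s$mut$variants[s$mut$variants$zygosity == "hom", ]
  ann <- annotate_variants(hom, s$ref$genes, s$ref$genome)
  agree <- mean(ann$region == hom$region_truth)
  expect_gte(agree, 0.999)
  # region categories partition the variants
  expect_identical(nrow(ann), nrow(hom))
  asum <- annotation_summary(ann)
  expect_equal(sum(asum$regions$pct), 100)
})

test_that("annotation summary reproduces printed proportions from counts", {
  expect_equal(round(ns_s_ratio(15224, 12894), 2), 1.18)
  expect_equal(round(count_percent(97833, 865781), 2), 11.30)
  expect_equal(round(count_percent(51514, 97833), 2), 52.66)
  expect_equal(round(count_percent(3418, 51514), 2), 6.64)
  expect_equal(round(count_percent(12894, 28138), 2), 45.82)
  expect_true(is.na(ns_s_ratio(5, 0)))
})

test_that("gene models survive a GFF3 round trip", {
  s <- shared_sim()
  path <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(s$ref$genes, path)
  back <- read_gene_models(path)
  expect_identical(length(back), length(s$ref$genes))
  for (gid in names(s$ref$genes)[1:5]) {
    a <- s$ref$genes[[gid]]; b <- back[[gid]]
    expect_identical(b$strand, a$strand)
    expect_identical(b$tx_start, a$tx_start)
    expect_identical(b$tx_end, a$tx_end)
    expect_equal(unname(b$exons), unname(a$exons))
    expect_equal(unname(b$cds), unname(a$cds))
  }
})
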