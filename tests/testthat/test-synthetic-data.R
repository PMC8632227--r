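test_that("reference generation is deterministic and respects the request", {
  cfg <- sim_config(seed = 5L, n_chromosomes = 2L, chrom_length = 100000L,
                    n_genes = 8L)
  ref1 <- generate_reference(cfg)
  ref2 <- generate_reference(cfg)
  expect_identical(names(ref1$genome), c("Chr1", "Chr2"))
  expect_equal(unname(Biostrings::width(ref1$genome)), c(100000L, 100000L))
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(ref1$genes, f1)
  write_gene_models_gff3(ref2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  gc <- gc_fraction(as.character(ref1$genome))
  expect_true(all(gc >= 0.3 & gc <= 0.6))
})

test_that("every emitted CDS translates to Met...stop with length 3k", {
  ref <- shared_sim()$ref
  for (g in ref$genes) {
    pieces <- Biostrings::extractAt(
      ref$genome[[g$chrom]], IRanges::IRanges(g$cds[, 1], g$cds[, 2]))
    cds <- paste(as.character(pieces), collapse = "")
    if (g$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    expect_identical(nchar(cds) %% 3L, 0L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_true(nrow(g$exons) >= 2)
  }
})

test_that("gene placement fails loudly when infeasible", {
  cfg <- sim_config(seed = 1L, n_chromosomes = 1L, chrom_length = 30000L,
                    n_genes = 40L)
  expect_error(generate_reference(cfg), "cannot place",
               class = "imr_user_error")
})

test_that("zero rates give a no-op accession; forced bias is obeyed", {
  cfg0 <- sim_config(seed = 3L, n_chromosomes = 1L, chrom_length = 60000L,
                     n_genes = 4L, snp_rate = 0, indel_rate = 0,
                     sv_rate = 0)
  ref <- generate_reference(cfg0)
  mut <- mutate_accession(ref, cfg0)
  expect_identical(nrow(mut$variants), 0L)
  expect_identical(as.character(mut$alt_genome), as.character(ref$genome))

  cfg1 <- sim_config(seed = 3L, n_chromosomes = 1L, chrom_length = 60000L,
                     n_genes = 4L, ts_bias = 1, indel_rate = 0,
                     sv_rate = 0)
  mut1 <- mutate_accession(generate_reference(cfg1), cfg1)
  snp <- mut1$variants[mut1$variants$vclass == "SNP", ]
  expect_gt(nrow(snp), 50)
  expect_true(all(classify_substitution(snp$ref, snp$alt) == "transition"))
})

test_that("realized SNP counts follow the binomial expectation", {
  cfg <- sim_config(seed = 7L, n_chromosomes = 1L, chrom_length = 1000000L,
                    n_genes = 20L, snp_rate = 1e-3, indel_rate = 0,
                    sv_rate = 0)
  mut <- mutate_accession(generate_reference(cfg), cfg)
  n <- sum(mut$variants$vclass == "SNP")
  expect_true(abs(n - 1000) <= 3 * sqrt(1000))
})

test_that("realized transition fraction and InDel length mix track the config", {
  s <- shared_sim()
  v <- s$mut$variants
  snp <- v[v$vclass == "SNP" & !v$causal, ]
  ts <- mean(classify_substitution(snp$ref, snp$alt) == "transition")
  p <- s$cfg$ts_bias
  expect_lt(abs(ts - p), 3 * sqrt(p * (1 - p) / nrow(snp)))
  ind <- v[v$vclass %in% c("INS", "DEL") & v$indel_len <= 200, ]
  obs <- c(mean(ind$indel_len == 1), mean(ind$indel_len %in% 2:20),
           mean(ind$indel_len >= 21))
  for (k in 1:3) {
    pk <- s$cfg$indel_len_mix[k]
    expect_lt(abs(obs[k] - pk), 3 * sqrt(pk * (1 - pk) / nrow(ind)))
  }
  expect_true(abs(mean(v$zygosity == "het") - s$cfg$het_fraction) <
                3 * sqrt(0.2144 * 0.7856 / nrow(v)))
})

test_that("the causal variant is planted in a CDS and is a coding-strand G>A missense", {
  s <- shared_sim()
  causal <- s$mut$truth$causal_variant
  g <- s$ref$genes[[s$mut$truth$causal_gene_id]]
  expect_identical(causal$chrom, g$chrom)
  in_cds <- any(causal$pos >= g$cds[, 1] & causal$pos <= g$cds[, 2])
  expect_true(in_cds)
  coding_ref <- if (g$strand == "+") causal$ref else
    chartr("ACGT", "TGCA", causal$ref)
  coding_alt <- if (g$strand == "+") causal$alt else
    chartr("ACGT", "TGCA", causal$alt)
  expect_identical(coding_ref, "G")
  expect_identical(coding_alt, "A")
  ann <- annotate_variants(s$mut$variants[s$mut$variants$causal, ],
                           s$ref$genes, s$ref$genome)
  expect_identical(ann$region, "cds")
  expect_identical(ann$effect, "missense")
  expect_true(grepl("^[A-Z][0-9]+[A-Z]$", ann$aa_change))
})

test_that("panel generation is seed-stable with recoverable frequencies", {
  loci <- data.frame(chrom = "Chr1", pos = seq_len(500) * 100L,
                     stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 9L, panel_size = 200L, panel_af = 1)
  mono <- generate_panel(loci, cfg)
  af <- panel_allele_freqs(mono)
  expect_true(all(af$p_alt == 0))
  expect_true(all(vapply(seq_len(nrow(af)), function(i)
    compute_pic(c(af$p_ref[i], af$p_alt[i])), numeric(1)) == 0))

  cfg5 <- sim_config(seed = 9L, panel_size = 200L, panel_af = 0.5)
  pan <- generate_panel(loci, cfg5)
  af5 <- panel_allele_freqs(pan)
  maf <- pmin(af5$p_ref, af5$p_alt)
  expect_lt(abs(mean(maf) - 0.5), 0.05)
  pan2 <- generate_panel(loci, cfg5)
  expect_identical(as.data.frame(pan), as.data.frame(pan2))
})

test_that("F2 segregation, linkage and determinism behave Mendelianly", {
  sp <- shared_pop()
  pop <- sp$pop
  n <- nrow(pop$individuals)
  n_mut <- sum(pop$individuals$phenotype == "mutant")
  bounds <- qbinom(c(0.005, 0.995), n, 0.25)
  expect_true(n_mut >= bounds[1] && n_mut <= bounds[2])
  # marker CM sits exactly at the causal position: perfect linkage
  rec <- pop$individuals$phenotype == "mutant"
  expect_true(all(pop$geno[rec, "CM"] == "A"))
  pop2 <- generate_f2(sp$sim$mut$truth, sp$markers, sp$sim$cfg)
  expect_identical(pop$geno, pop2$geno)
  expect_identical(pop$individuals, pop2$individuals)
})

test_that("markers on other chromosomes segregate independently of phenotype", {
  s <- shared_sim()
  markers <- data.frame(
    marker_id = c("CM", "U1"),
    chrom = c(s$mut$truth$causal_variant$chrom, "Chr1"),
    pos = c(s$mut$truth$causal_variant$pos, 150000L),
    stringsAsFactors = FALSE)
  indep <- 0L
  n_runs <- 100L
  for (k in seq_len(n_runs)) {
    cfg <- sim_config(seed = 500L + k, n_chromosomes = 2L,
                      chrom_length = 300000L, n_genes = 30L,
                      f2_size = 200L,
                      causal_spec = list(chrom = "Chr2", pos = 150000L))
    pop <- generate_f2(s$mut$truth, markers, cfg)
    tab <- table(pop$geno[, "U1"], pop$individuals$phenotype)
    p <- suppressWarnings(chisq.test(tab)$p.value)
    if (p > 0.05) indep <- indep + 1L
  }
  expect_gte(indep, 90L)
})

test_that("errors are raised for impossible F2 or panel configurations", {
  sp <- shared_pop()
  expect_error(
    generate_f2(sp$sim$mut$truth,
                data.frame(marker_id = "x", chrom = "Chr1", pos = 1000L),
                sp$sim$cfg),
    "causal chromosome", class = "imr_user_error")
  no_causal <- sp$sim$mut$truth
  no_causal$causal_variant <- NULL
  expect_error(generate_f2(no_causal, sp$markers, sp$sim$cfg),
               "causal", class = "imr_user_error")
  expect_error(generate_panel(data.frame(chrom = "Chr1", pos = 1L),
                              sim_config(panel_size = 1L)),
               "panel_size", class = "imr_user_error")
})
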