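test_that("a recessive pool is fixed for the mutant allele at the causal marker", {
  sp <- shared_pop()
  pr <- pool_recessives(sp$pop, n_pool = 30, markers = "CM", seed = 1)
  expect_equal(pr$a_allele_fraction, 1)
  expect_identical(pr$pool_call, "A-like")
  expect_error(pool_recessives(sp$pop, n_pool = 0), ">= 1",
               class = "imr_user_error")
  expect_error(pool_recessives(sp$pop, n_pool = 1e6), "recessive",
               class = "imr_user_error")
  expect_error(pool_recessives(sp$pop, markers = "nope"), "unknown",
               class = "imr_user_error")
})

test_that("unlinked markers hover around 0.5 in the recessive pool", {
  sp <- shared_pop()
  unlinked <- sp$markers$marker_id[sp$markers$chrom == "Chr1"][1]
  inside <- 0L
  for (k in 1:200) {
    pr <- pool_recessives(sp$pop, n_pool = 30, markers = unlinked,
                          seed = k)
    if (pr$a_allele_fraction >= 0.32 && pr$a_allele_fraction <= 0.68)
      inside <- inside + 1L
  }
  expect_gte(inside, 185L)   # ~95% of binomial(60, 0.5) draws
})

test_that("coarse mapping finds the linked marker and is order-invariant", {
  sp <- shared_pop()
  coarse_ids <- sp$markers$marker_id[grepl("^In", sp$markers$marker_id)]
  pr <- pool_recessives(sp$pop, 30, coarse_ids, seed = 2)
  cm <- coarse_map(pr)
  expect_true(cm$significant)
  expect_identical(cm$chrom, sp$causal$chrom)
  # nearest coarse marker to the causal position wins
  on_chr <- sp$markers[sp$markers$marker_id %in% coarse_ids &
                         sp$markers$chrom == sp$causal$chrom, ]
  nearest <- on_chr$marker_id[which.min(abs(on_chr$pos - sp$causal$pos))]
  expect_identical(cm$marker_id, nearest)
  # marker input order does not matter
  cm2 <- coarse_map(pr[sample(nrow(pr)), ])
  expect_identical(cm2$marker_id, cm$marker_id)
  # a single fully linked marker among unlinked ones is returned
  toy <- data.frame(marker_id = c("a", "b", "c"),
                    chrom = c("Chr1", "Chr1", "Chr2"),
                    pos = c(1e4, 2e4, 3e4), n_pool = 30L,
                    a_allele_fraction = c(0.5, 1.0, 0.48),
                    stringsAsFactors = FALSE)
  expect_identical(coarse_map(toy)$marker_id, "b")
})

test_that("permuted phenotypes rarely produce a significant coarse call", {
  sp <- shared_pop()
  coarse_ids <- sp$markers$marker_id[grepl("^In", sp$markers$marker_id)]
  n_sig <- 0L
  for (k in 1:50) {
    perm <- sp$pop
    set.seed(7000 + k)
    perm$individuals$phenotype <- sample(perm$individuals$phenotype)
    pr <- pool_recessives(perm, 30, coarse_ids, seed = k)
    if (coarse_map(pr)$significant) n_sig <- n_sig + 1L
  }
  expect_gte(50L - n_sig, 44L)
})

test_that("fine mapping brackets the causal locus with monotone recombinants", {
  sp <- shared_pop()
  fine_ids <- c("CM", sprintf("FM%d", 1:8))
  fm <- suppressWarnings(fine_map(sp$pop, fine_ids,
                                  genes = sp$sim$ref$genes))
  rec <- fm$recombinants
  # the marker at the causal position has zero recombinants
  expect_identical(rec$n_recombinant[rec$marker_id == "CM"], 0L)
  # interval contains the causal position and the causal gene
  expect_lte(fm$left_pos, sp$causal$pos)
  expect_gte(fm$right_pos, sp$causal$pos)
  expect_true(sp$sim$mut$truth$causal_gene_id %in% fm$candidate_gene_ids)
  # recombinant counts grow with distance from the causal locus
  d <- abs(rec$pos - sp$causal$pos)
  expect_gt(suppressWarnings(cor(d, rec$n_recombinant,
                                 method = "spearman")), 0)
  # adding an informative marker inside the interval never widens it
  fm2 <- suppressWarnings(fine_map(sp$pop, setdiff(fine_ids, "CM"),
                                   genes = sp$sim$ref$genes))
  expect_lte(fm$length, fm2$length)
  expect_error(fine_map(sp$pop, c("CM", "In1-1")), "one chromosome",
               class = "imr_user_error")
})

test_that("segregation chi-square matches hand-computed values", {
  exact <- segregation_chisq(750, 250)
  expect_equal(exact$chi2, 0)
  expect_true(exact$fits)
  pub <- segregation_chisq(745, 237)
  expect_equal(pub$chi2, 72.25 / 736.5 + 72.25 / 245.5, tolerance = 1e-9)
  expect_equal(pub$chi2, 0.3924, tolerance = 1e-4)
  expect_identical(pub$df, 1L)
  expect_true(pub$fits)
  extreme <- segregation_chisq(982, 0)
  expect_gt(extreme$chi2, 100)
  expect_false(extreme$fits)
  expect_error(segregation_chisq(0, 0), class = "imr_user_error")
})

test_that("BSA-seq scan nominates EMS-type protein-altering SNPs only", {
  iv <- structure(list(chrom = "Chr2", left_pos = 100000,
                       right_pos = 120000, length = 20000),
                  class = "mapping_interval")
  pf <- data.frame(
    chrom = "Chr2",
    pos = c(105000L, 106000L, 107000L, 108000L, 109000L),
    ref = c("G", "A", "G", "C", "G"),
    alt = c("A", "C", "A", "T", "A"),
    af_mutant_pool = c(1.0, 1.0, 1.0, 0.5, 1.0),
    af_wild_pool = c(0.33, 0.33, 0.33, 0.33, 0.6),
    stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "Chr2", pos = pf$pos,
                    effect = c("missense", "missense", "synonymous",
                               "missense", "missense"),
                    stringsAsFactors = FALSE)
  out <- bsa_seq_scan(pf, iv, ann)
  expect_identical(out$pos, 105000L)           # only the G>A missense
  expect_true(all(out$is_ems_type))
  # A>C with identical frequencies is rejected as non-EMS
  out2 <- bsa_seq_scan(pf, iv, ann, require_ems = FALSE)
  expect_setequal(out2$pos, c(105000L, 106000L))
  # degenerate interval warns and returns nothing
  iv0 <- structure(list(chrom = "Chr2", left_pos = NA_real_,
                        right_pos = NA_real_, length = 0),
                   class = "mapping_interval")
  expect_warning(empty <- bsa_seq_scan(pf, iv0, ann), "interval")
  expect_identical(nrow(empty), 0L)
})

test_that("the causal SNP survives the scan against sampled background noise", {
  iv <- structure(list(chrom = "Chr2", left_pos = 100000,
                       right_pos = 120000, length = 20000),
                  class = "mapping_interval")
  hits <- 0L
  for (k in 1:10) {
    set.seed(800 + k)
    # 50 background accession SNPs: mutant pool is nearly fixed for the
    # mutant-parent haplotype here, so their alt frequency is low
    bg_pos <- sort(sample(100001:119999, 50))
    bg <- data.frame(
      chrom = "Chr2", pos = bg_pos,
      ref = sample(c("G", "C", "A", "T"), 50, replace = TRUE),
      alt = NA_character_,
      af_mutant_pool = rbinom(50, 60, 0.05) / 60,
      af_wild_pool = rbinom(50, 60, 0.5) / 60,
      stringsAsFactors = FALSE)
    bg$alt <- vapply(bg$ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    causal <- data.frame(chrom = "Chr2", pos = 110500L, ref = "G",
                         alt = "A",
                         af_mutant_pool = 1,
                         af_wild_pool = rbinom(1, 60, 1 / 3) / 60,
                         stringsAsFactors = FALSE)
    pf <- rbind(bg, causal)
    ann <- data.frame(chrom = "Chr2", pos = pf$pos,
                      effect = c(sample(c("synonymous", "missense",
                                          "none"), 50, replace = TRUE),
                                 "missense"),
                      stringsAsFactors = FALSE)
    out <- bsa_seq_scan(pf, iv, ann)
    if (nrow(out) >= 1 && out$pos[1] == 110500L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
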