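test_that("candidate selection applies length, zygosity and flank rules", {
  v <- rbind(
    vrow(pos = 1000, ref = paste0("A", strrep("T", 19)), alt = "A"),  # 19 bp
    vrow(pos = 5000, ref = paste0("A", strrep("T", 20)), alt = "A"),  # 20 bp
    vrow(pos = 9000, ref = "A", alt = paste0("A", strrep("G", 200))),
    vrow(pos = 13000, ref = "A", alt = paste0("A", strrep("G", 201))),
    vrow(pos = 17000, ref = paste0("A", strrep("T", 50)), alt = "A",
         zygosity = "het"),
    vrow(pos = 21000, ref = "A", alt = paste0("A", strrep("C", 30))),
    vrow(pos = 21200, ref = paste0("G", strrep("A", 6)), alt = "G"))   # dirty flank
  cand <- select_candidates(v)
  expect_identical(sort(cand$pos), c(5000L, 9000L))
  expect_identical(cand$marker_id[cand$pos == 5000], "In1-1")
  fl <- attr(cand, "filter_log")
  expect_identical(attr(fl, "n_in") - sum(fl$rejected), nrow(cand))
})

test_that("candidate selection agrees with an independent brute-force filter", {
  s <- shared_sim()
  v <- s$mut$variants
  cand <- select_candidates(v)
  # brute force, written independently of the implementation
  expected <- character(0)
  for (i in seq_len(nrow(v))) {
    if (!(v$vclass[i] %in% c("INS", "DEL"))) next
    if (v$zygosity[i] != "hom") next
    if (v$indel_len[i] < 20 || v$indel_len[i] > 200) next
    clean <- TRUE
    for (j in seq_len(nrow(v))) {
      if (j == i) next
      if (!(v$vclass[j] %in% c("INS", "DEL"))) next
      if (v$indel_len[j] < 5) next
      if (v$chrom[j] == v$chrom[i] && abs(v$pos[j] - v$pos[i]) <= 350)
        clean <- FALSE
    }
    if (clean) expected <- c(expected, paste(v$chrom[i], v$pos[i]))
  }
  expect_setequal(paste(cand$chrom, cand$pos), expected)
})

test_that("PIC closed forms, brute force and maximum location hold", {
  expect_equal(compute_pic(1), 0)
  expect_equal(compute_pic(c(0.5, 0.5)), 0.375)
  expect_equal(compute_pic(rep(1 / 3, 3)), 48 / 81, tolerance = 1e-12)
  # brute-force double sum for random frequency vectors
  set.seed(20)
  for (k in 1:30) {
    n <- sample(2:6, 1)
    p <- runif(n); p <- p / sum(p)
    brute <- 1 - sum(p^2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      brute <- brute - 2 * p[i]^2 * p[j]^2
    expect_equal(compute_pic(p), brute, tolerance = 1e-12)
  }
  # biallelic PIC is maximised at p = 0.5
  grid <- seq(0, 1, by = 0.01)
  pic <- vapply(grid, function(p) compute_pic(c(p, 1 - p)), numeric(1))
  expect_equal(grid[which.max(pic)], 0.5)
  expect_error(compute_pic(c(0.5, 0.4)), "sum to 1")
  expect_equal(compute_pic(c(0.5, 0.5), method = "expected_het"), 0.5)
})

test_that("PIC screening is strict and drops unknown loci loudly", {
  cand <- rbind(vrow(pos = 1000, ref = paste0("A", strrep("T", 25)),
                     alt = "A"),
                vrow(pos = 5000, ref = paste0("A", strrep("T", 30)),
                     alt = "A"),
                vrow(pos = 9000, ref = paste0("A", strrep("T", 40)),
                     alt = "A"))
  cand$marker_id <- c("In1-1", "In1-2", "In1-3")
  panel <- data.frame(accession = sprintf("a%02d", 1:20),
                      Chr1_1000 = rep(c(0L, 1L), 10),       # p = 0.5
                      Chr1_5000 = rep(0L, 20),              # monomorphic
                      check.names = FALSE)
  class(panel) <- c("accession_panel", "data.frame")
  expect_warning(kept <- screen_by_pic(cand, panel, threshold = 0.3),
                 "absent")
  expect_identical(kept$pos, 1000L)
  expect_equal(kept$pic, 0.375)
  # strictly greater than: a threshold equal to the PIC rejects the locus
  expect_warning(none <- screen_by_pic(cand, panel, threshold = 0.375))
  expect_identical(nrow(none), 0L)
  # all-monomorphic panel leaves nothing
  panel2 <- panel; panel2$Chr1_1000 <- 0L
  expect_warning(m <- screen_by_pic(cand, panel2, threshold = 0.5))
  expect_identical(nrow(m), 0L)
})

test_that("nearest-neighbor Tm matches an independent implementation", {
  # reference values computed with an independent nearest-neighbor
  # implementation (unified NN table, 50 mM Na+, 50 nM total oligo)
  frozen <- c(ACGTTGCAATGCCGTAATGC = 54.806,
              AAAAAAAAAAAAAAAAAA = 32.674,
              GCGCGCGCGCGCGCGCGC = 74.047,
              ATGCATGCATGCATGCATGCATGC = 60.521,
              TTGACCTAGATCGGATCCAAT = 49.998)
  got <- primer_tm(names(frozen))
  expect_equal(unname(got), unname(frozen), tolerance = 0.01)
  # monotonicity: AT-rich melts below GC-rich at equal length
  expect_lt(primer_tm("AAAAAAAAAAAAAAAAAA"),
            primer_tm("GCGCGCGCGCGCGCGCGC"))
  expect_error(primer_tm("ANA"), "ACGT")
})

test_that("primer design fails explicitly on infeasible templates", {
  at_only <- paste(rep("AT", 1500), collapse = "")
  genome <- Biostrings::DNAStringSet(at_only)
  names(genome) <- "Chr1"
  cand <- vrow(pos = 1500, ref = substr(at_only, 1500, 1530),
               alt = substr(at_only, 1500, 1500))
  cand$marker_id <- "In1-1"
  res <- design_primers(cand, genome)
  expect_s3_class(res, "primer_design_failure")
})

test_that("designed pairs satisfy their envelope and amplify both parents once", {
  s <- shared_sim()
  # fully InDel-clean amplicons so predicted alt product sizes are exact
  cand <- select_candidates(s$mut$variants, flank_indel_min = 1L)
  expect_gt(nrow(cand), 0)
  n_done <- 0L
  for (i in seq_len(nrow(cand))) {
    if (n_done >= 4L) break
    pair <- design_primers(cand[i, ], s$ref$genome)
    if (inherits(pair, "primer_design_failure")) next
    n_done <- n_done + 1L
    ok <- validate_primer_pair(pair, cand[i, ])
    expect_true(ok, info = paste(attr(ok, "violations"), collapse = "; "))
    expect_identical(abs(pair$product_size_ref - pair$product_size_alt),
                     cand$indel_len[i])
    ref_prod <- insilico_pcr(s$ref$genome, pair$fwd_seq, pair$rev_seq)
    alt_prod <- insilico_pcr(s$mut$alt_genome, pair$fwd_seq, pair$rev_seq,
                             max_mismatch = 2L)
    expect_identical(nrow(ref_prod), 1L)
    expect_identical(nrow(alt_prod), 1L)
    expect_identical(ref_prod$size, pair$product_size_ref)
    expect_identical(alt_prod$size, pair$product_size_alt)
  }
  expect_gte(n_done, 2L)
})
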