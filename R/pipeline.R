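# Configuration, logging and the staged pipeline front end
# (simulate / catalog / annotate / markers / bsa / all).

#' One seeded end-to-end positional-cloning simulation
#'
#' Runs the full recovery experiment at study-like sizes: simulate a
#' reference and divergent accession with a planted recessive G->A causal
#' mutation, genotype an F2 population at genome-wide InDel markers plus a
#' ladder of fine markers around the coarse peak region, pool recessives
#' for coarse BSA, fine-map with all recessive individuals, and nominate
#' candidate SNPs from pool allele frequencies (BSA-seq style).
#'
#' @param seed simulation seed.
#' @param n_chromosomes,chrom_length,n_genes genome sizing.
#' @param causal_chrom,causal_pos requested causal location.
#' @param f2_size F2 population size (default 982).
#' @param n_pool recessive bulk size for coarse BSA (default 30).
#' @param n_coarse_per_chrom genome-wide markers per chromosome.
#' @param fine_offsets fine-marker offsets (bp) from the causal site.
#' @return list: `truth` (causal chrom/pos/gene), `coarse` (`coarse_map`),
#'   `interval` (`mapping_interval`), `candidates`
#'   (`bsa_seq_candidates`), `n_recessives`, `contains_causal`,
#'   `causal_top_ranked`.
#' @export
run_recovery_sim <- function(seed, n_chromosomes = 3L,
                             chrom_length = 400000L, n_genes = 45L,
                             causal_chrom = "Chr2", causal_pos = 260000L,
                             f2_size = 982L, n_pool = 30L,
                             n_coarse_per_chrom = 6L,
                             fine_offsets = c(-30000L, -10000L, -3000L,
                                              -500L, 500L, 3000L, 10000L,
                                              30000L)) {
  cfg <- sim_config(seed = seed, n_chromosomes = n_chromosomes,
                    chrom_length = chrom_length, n_genes = n_genes,
                    f2_size = f2_size,
                    causal_spec = list(chrom = causal_chrom,
                                       pos = causal_pos))
  ref <- generate_reference(cfg)
  mut <- mutate_accession(ref, cfg)
  causal <- mut$truth$causal_variant
  gw <- pick_genomewide_markers(mut$variants, ref$chrom_lengths,
                                n_coarse_per_chrom)
  fine_pos <- causal$pos + fine_offsets
  fine_pos <- fine_pos[fine_pos >= 1 &
                         fine_pos <= ref$chrom_lengths[[causal$chrom]]]
  fine <- data.frame(marker_id = sprintf("FM%d", seq_along(fine_pos)),
                     chrom = causal$chrom, pos = fine_pos,
                     stringsAsFactors = FALSE)
  pop <- generate_f2(mut$truth, rbind(gw, fine), cfg)
  pr <- pool_recessives(pop, n_pool, gw$marker_id, seed = seed + 10000L)
  cm <- coarse_map(pr)
  fm <- suppressWarnings(fine_map(pop, fine$marker_id, ref$genes))
  pf <- pool_allele_freqs(pop, mut$variants, n_pool, n_pool,
                          seed = seed + 20000L)
  in_iv <- mut$variants$chrom == fm$chrom &
    mut$variants$pos >= fm$left_pos & mut$variants$pos <= fm$right_pos &
    mut$variants$zygosity == "hom"
  sc <- if (any(in_iv)) {
    ann <- annotate_variants(mut$variants[in_iv, ], ref$genes, ref$genome)
    suppressWarnings(bsa_seq_scan(pf, fm, ann))
  } else data.frame(pos = integer(0))
  list(truth = list(chrom = causal$chrom, pos = causal$pos,
                    gene_id = mut$truth$causal_gene_id),
       coarse = cm, interval = fm, candidates = sc,
       n_recessives = sum(pop$individuals$phenotype == "mutant"),
       contains_causal = causal$pos >= fm$left_pos &&
         causal$pos <= fm$right_pos && fm$chrom == causal$chrom,
       causal_top_ranked = nrow(sc) > 0 && sc$chrom[1] == causal$chrom &&
         sc$pos[1] == causal$pos)
}

#' Default pipeline configuration
#' @noRd
default_config <- function() {
  list(
    outdir = "indelmapr_out",
    seed = 1L,
    sim = list(
      n_chromosomes = 3L, chrom_length = 400000L, n_genes = 45L,
      snp_rate = 2719.65e-6, indel_rate = 485.61e-6, sv_rate = 2e-6,
      ts_bias = 2.73 / 3.73,
      indel_len_mix = c(0.4807, 0.4434, 0.0670),
      het_fraction = 0.2144, panel_size = 200L, f2_size = 982L,
      causal_chrom = "Chr2", causal_pos = 260000L,
      n_coarse_per_chrom = 6L,
      fine_offsets = c(-30000L, -10000L, -3000L, -500L, 500L, 3000L,
                       10000L, 30000L),
      pool_size_mutant = 30L, pool_size_wild = 30L),
    paths = list(fasta = NULL, gff3 = NULL, vcf = NULL, panel = NULL,
                 f2 = NULL, markers = NULL, pool_freqs = NULL,
                 annotations = NULL),
    catalog = list(window_size = 1e6, sv_min_len = 100L),
    annotate = list(flank = 5000L, splice_width = 2L),
    markers = list(min_len = 20L, max_len = 200L, flank = 350L,
                   flank_indel_min = 5L, pic_threshold = 0.5,
                   pic_method = "botstein", design_primers = TRUE,
                   max_designs = 30L),
    bsa = list(n_pool = 30L, alpha = 0.05, mut_min = 0.9,
               wild_range = c(0.2, 0.45), require_ems = TRUE,
               ratio = c(3, 1)))
}

#' Build a pipeline configuration
#'
#' Defaults are overridden first by a YAML file, then by an override list
#' (mirroring command-line flags). The effective configuration of every
#' run is written next to its outputs as `effective_config.yaml`.
#'
#' @param path optional YAML configuration file.
#' @param overrides named list merged last (nested lists merge by name).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  merge_lists <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) imr_stop(sprintf("config file not found: %s",
                                             path))
    cfg <- merge_lists(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_lists(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
sim_config_from <- function(cfg) {
  s <- cfg$sim
  sim_config(
    seed = cfg$seed, n_chromosomes = s$n_chromosomes,
    chrom_length = s$chrom_length, n_genes = s$n_genes,
    snp_rate = s$snp_rate, indel_rate = s$indel_rate, sv_rate = s$sv_rate,
    ts_bias = s$ts_bias, indel_len_mix = s$indel_len_mix,
    het_fraction = s$het_fraction, panel_size = s$panel_size,
    f2_size = s$f2_size,
    causal_spec = list(chrom = s$causal_chrom, pos = s$causal_pos))
}

#' @noRd
pipeline_log <- function(state, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...))
  cat(line, "\n", sep = "", file = state$logfile, append = TRUE)
  if (isTRUE(state$verbose)) message(line)
  invisible(NULL)
}

#' @noRd
log_filter <- function(state, stage, filter_log) {
  n_in <- attr(filter_log, "n_in")
  n_out <- n_in - sum(filter_log$rejected)
  for (i in seq_len(nrow(filter_log)))
    pipeline_log(state, "%s: filter %-18s rejected %d", stage,
                 filter_log$filter[i], filter_log$rejected[i])
  pipeline_log(state, "%s: n_in=%d n_out=%d", stage, n_in, n_out)
  invisible(n_out)
}

#' @noRd
write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic reference, divergent accession, truth
#' VCF, panel, F2 population and pool frequencies), `catalog` (variant
#' summary and window densities), `annotate` (region/effect table and
#' summary), `markers` (InDel screening, PIC, primer design), `bsa`
#' (segregation test, coarse and fine mapping, BSA-seq scan), `all` (each
#' in turn, feeding the files forward). Outputs are TSV tables plus a
#' plain-text `summary.txt`; a run log and the effective configuration are
#' written beside them. All randomness flows from `config$seed`, so reruns
#' are byte-identical.
#'
#' @param name one of simulate, catalog, annotate, markers, bsa, all.
#' @param config a [pipeline_config()].
#' @param verbose echo log lines as messages.
#' @return invisible named list of artifact paths.
#' @export
run_subcommand <- function(name = c("all", "simulate", "catalog",
                                    "annotate", "markers", "bsa"),
                           config = pipeline_config(), verbose = FALSE) {
  name <- match.arg(name)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- list(logfile = file.path(config$outdir, "pipeline.log"),
                verbose = verbose)
  cat("", file = state$logfile)  # truncate
  cfg_out <- config; class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, file.path(config$outdir,
                                      "effective_config.yaml"))
  artifacts <- list()
  p <- function(f) file.path(config$outdir, f)
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path))
      imr_stop(sprintf("%s input missing: %s", what,
                       path %||% "(not set)"))
    path
  }
  paths <- config$paths
  stages <- if (name == "all")
    c("simulate", "catalog", "annotate", "markers", "bsa") else name

  for (stage in stages) {
    pipeline_log(state, "stage %s (seed %d)", stage, config$seed)
    if (stage == "simulate") {
      sc <- sim_config_from(config)
      ref <- generate_reference(sc)
      mut <- mutate_accession(ref, sc)
      artifacts$fasta <- write_genome_fasta(ref$genome, p("reference.fasta"))
      artifacts$alt_fasta <- write_genome_fasta(mut$alt_genome,
                                                p("accession.fasta"))
      artifacts$gff3 <- write_gene_models_gff3(ref$genes, p("genes.gff3"))
      artifacts$vcf <- write_truth_vcf(mut$variants, ref$chrom_lengths,
                                       p("truth.vcf"), seed = sc$seed)
      panel <- generate_panel(mut$variants, sc)
      artifacts$panel <- write_panel_tsv(panel, p("panel.tsv"))
      gw <- pick_genomewide_markers(mut$variants, ref$chrom_lengths,
                                    config$sim$n_coarse_per_chrom)
      causal <- mut$truth$causal_variant
      fine_pos <- causal$pos + config$sim$fine_offsets
      fine_pos <- fine_pos[fine_pos >= 1 &
                             fine_pos <= ref$chrom_lengths[[causal$chrom]]]
      fine <- data.frame(marker_id = sprintf("FM%d", seq_along(fine_pos)),
                         chrom = causal$chrom, pos = fine_pos,
                         stringsAsFactors = FALSE)
      mk <- rbind(gw, fine)
      artifacts$markers <- write_tsv(mk, p("f2_markers.tsv"))
      pop <- generate_f2(mut$truth, mk, sc)
      artifacts$f2 <- write_f2_tsv(pop, p("f2.tsv"))
      pf <- pool_allele_freqs(pop, mut$variants,
                              config$sim$pool_size_mutant,
                              config$sim$pool_size_wild,
                              seed = sc$seed + 4000L)
      artifacts$pool_freqs <- write_tsv(pf, p("pool_freqs.tsv"))
      pipeline_log(state, "simulate: %d variants, %d markers, F2 n=%d",
                   nrow(mut$variants), nrow(mk), sc$f2_size)
      paths$fasta <- artifacts$fasta; paths$gff3 <- artifacts$gff3
      paths$vcf <- artifacts$vcf; paths$panel <- artifacts$panel
      paths$f2 <- artifacts$f2; paths$markers <- artifacts$markers
      paths$pool_freqs <- artifacts$pool_freqs
    } else if (stage == "catalog") {
      v <- read_vcf(need(paths$vcf, "VCF"))
      genome <- Biostrings::readDNAStringSet(need(paths$fasta, "FASTA"))
      names(genome) <- sub("\\s.*", "", names(genome))
      chl <- setNames(Biostrings::width(genome), names(genome))
      s <- summarize_variants(v, chl, config$catalog$sv_min_len)
      sd <- data.frame(statistic = c(
        "n_snp", "n_indel", "n_sv", "n_hom", "n_het", "het_ratio",
        "n_ts", "n_tv", "tstv", "indel_1bp", "indel_2_20", "indel_gt20",
        "snp_density_per_mb", "indel_density_per_mb", "mean_snp_spacing",
        "mean_indel_spacing", "sv_len_median"),
        value = c(s$n_snp, s$n_indel, s$n_sv, s$n_hom, s$n_het,
                  s$het_ratio, s$n_ts, s$n_tv, s$tstv,
                  s$indel_len_classes, s$snp_density_per_mb,
                  s$indel_density_per_mb, s$mean_snp_spacing,
                  s$mean_indel_spacing, s$sv_len_median))
      artifacts$catalog <- write_tsv(sd, p("catalog_summary.tsv"))
      wd <- window_densities(v, chl, config$catalog$window_size)
      artifacts$windows <- write_tsv(wd, p("window_densities.tsv"))
      pipeline_log(state, "catalog: %d SNP, %d InDel, %d SV", s$n_snp,
                   s$n_indel, s$n_sv)
    } else if (stage == "annotate") {
      v <- read_vcf(need(paths$vcf, "VCF"))
      genes <- read_gene_models(need(paths$gff3, "GFF3"))
      genome <- Biostrings::readDNAStringSet(need(paths$fasta, "FASTA"))
      names(genome) <- sub("\\s.*", "", names(genome))
      ann <- annotate_variants(v, genes, genome,
                               config$annotate$flank,
                               config$annotate$splice_width)
      artifacts$annotations <- write_tsv(ann, p("annotations.tsv"))
      paths$annotations <- artifacts$annotations
      asum <- annotation_summary(ann)
      artifacts$annotation_summary <-
        write_tsv(asum$regions, p("annotation_summary.tsv"))
      pipeline_log(state,
                   "annotate: %d hom variants, genic %.2f%%, NS/S %s",
                   asum$n, asum$genic_pct,
                   ifelse(is.na(asum$ns_s_ratio), "NA",
                          sprintf("%.2f", asum$ns_s_ratio)))
    } else if (stage == "markers") {
      v <- read_vcf(need(paths$vcf, "VCF"))
      mc <- config$markers
      cand <- select_candidates(v, mc$min_len, mc$max_len, mc$flank,
                                mc$flank_indel_min)
      log_filter(state, "markers", attr(cand, "filter_log"))
      panel <- read_panel_tsv(need(paths$panel, "panel"))
      kept <- screen_by_pic(cand, panel, mc$pic_threshold, mc$pic_method)
      pipeline_log(state, "markers: PIC > %.2f keeps %d of %d",
                   mc$pic_threshold, nrow(kept), nrow(cand))
      if (isTRUE(mc$design_primers) && nrow(kept)) {
        genome <- Biostrings::readDNAStringSet(need(paths$fasta, "FASTA"))
        names(genome) <- sub("\\s.*", "", names(genome))
        take <- head(seq_len(nrow(kept)), mc$max_designs)
        tab <- design_markers(kept[take, ], genome)
        pipeline_log(state, "markers: primers designed for %d/%d (%d failures)",
                     nrow(tab), length(take),
                     length(attr(tab, "failures")))
      } else {
        tab <- kept
      }
      artifacts$marker_table <- write_tsv(tab, p("marker_table.tsv"))
      if (!nrow(tab))
        pipeline_log(state, "markers: empty marker table (no candidate passed)")
    } else if (stage == "bsa") {
      mk <- read.table(need(paths$markers, "marker table"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
      pop <- read_f2_tsv(need(paths$f2, "F2 table"), mk)
      bc <- config$bsa
      phen <- table(factor(pop$individuals$phenotype,
                           levels = c("wild", "mutant")))
      seg <- segregation_chisq(phen[["wild"]], phen[["mutant"]],
                               bc$ratio)
      pipeline_log(state, "bsa: segregation %d:%d chi2=%.3f p=%.3f",
                   seg$n_dominant, seg$n_recessive, seg$chi2, seg$p_value)
      coarse_ids <- mk$marker_id[grepl("^In", mk$marker_id)]
      pr <- pool_recessives(pop, bc$n_pool, coarse_ids,
                            seed = config$seed + 5000L)
      cm <- coarse_map(pr, bc$alpha)
      artifacts$pool_results <- write_tsv(cm$table, p("pool_results.tsv"))
      fine_ids <- mk$marker_id[grepl("^FM", mk$marker_id)]
      if (!length(fine_ids))
        fine_ids <- mk$marker_id[mk$chrom == cm$chrom]
      fm <- suppressWarnings(fine_map(pop, fine_ids,
                                      genes = if (!is.null(paths$gff3) &&
                                                  file.exists(paths$gff3))
                                        read_gene_models(paths$gff3)))
      artifacts$interval <- write_tsv(fm$recombinants,
                                      p("fine_map_recombinants.tsv"))
      scan <- data.frame()
      if (!is.null(paths$pool_freqs) && file.exists(paths$pool_freqs) &&
          !is.null(paths$annotations) && file.exists(paths$annotations)) {
        pf <- read.table(paths$pool_freqs, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
        ann <- read.table(paths$annotations, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
        scan <- suppressWarnings(
          bsa_seq_scan(pf, fm, ann, bc$mut_min, bc$wild_range,
                       bc$require_ems))
        artifacts$bsa_candidates <- write_tsv(scan,
                                              p("bsa_candidates.tsv"))
      }
      summary_lines <- c(
        sprintf("Segregation: %d dominant : %d recessive, chi2 = %.3f (df %d), p = %.3f",
                seg$n_dominant, seg$n_recessive, seg$chi2, seg$df,
                seg$p_value),
        if (cm$significant)
          sprintf("Coarse BSA peak: %s on %s at %.0f (allele fraction %.2f, adj p %.3g)",
                  cm$marker_id, cm$chrom, cm$pos, cm$a_allele_fraction,
                  cm$p_adj)
        else "Coarse BSA: no significant marker",
        sprintf("Fine interval: %s:%.0f-%.0f (%.2f kb) between %s and %s",
                fm$chrom, fm$left_pos, fm$right_pos, fm$length / 1000,
                fm$left_marker, fm$right_marker),
        sprintf("Candidate genes in interval: %s",
                if (length(fm$candidate_gene_ids))
                  paste(fm$candidate_gene_ids, collapse = ", ")
                else "(none)"),
        if (nrow(scan))
          sprintf("BSA-seq nominated SNP(s): %s",
                  paste(sprintf("%s:%d %s>%s (%s)", scan$chrom, scan$pos,
                                scan$ref, scan$alt, scan$effect),
                        collapse = "; "))
        else "BSA-seq: no SNP met the nomination criteria")
      artifacts$summary <- p("summary.txt")
      writeLines(summary_lines, artifacts$summary)
      pipeline_log(state, "bsa: interval %s:%.0f-%.0f, %d candidate SNP(s)",
                   fm$chrom, fm$left_pos, fm$right_pos, nrow(scan))
    }
  }
  invisible(artifacts)
}
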