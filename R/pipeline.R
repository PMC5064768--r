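# End-to-end pipeline driver. Stages write plain TSV (header line prefixed
# with '#') so downstream stages and tests never parse binary output; a
# JSON manifest records inputs, parameters and the seed. Given the same
# config and seed, reruns produce byte-identical outputs.

default_run_config <- function() {
  list(
    probes = list(width = 20000L, min_cpg = 10L, kmeans_width = 2000L,
                  n_cpg = 50L),
    alpha = 0.05, k = 7L, n_restarts = 25L,
    background = list(n_bins = 20L, min_bin_n = 50L),
    sim = list()
  )
}

load_run_config <- function(config) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(base, config)
}

require_input <- function(path, stage) {
  if (!file.exists(path)) {
    abort(paste0(stage, ": required input not found: ", path))
  }
  path
}

#' Run the analysis pipeline
#'
#' Wires the synthetic-data generator and the analysis stages into a
#' single entry point writing TSV outputs and a JSON manifest.
#' Subcommands: `simulate` (generate and write synthetic data),
#' `quantify` (probe matrices, feature summary, metagene, DMR panel,
#' repeat methylation), `dynamics` (background model outliers, trajectory
#' k-means, enrichment, ChIP overlay), `repeats` (repeat-class RPKM),
#' `smrna` (read classification, length spectra, 5' composition,
#' ping-pong), `all` (everything in order). Later stages read the files
#' written by earlier ones, so `quantify` requires a prior `simulate`
#' (or externally supplied files of the same layout).
#'
#' @param subcommand one of simulate/quantify/dynamics/repeats/smrna/all
#' @param config `NULL` for defaults, a YAML path, or a nested list
#'   overriding the defaults (`sim` entries are passed to
#'   [simulation_config()]; `probes`, `background`, `alpha`, `k`,
#'   `n_restarts` steer the analysis)
#' @param outdir output directory (created if needed)
#' @param seed overrides the config seed
#' @param plots also write PNG figures (default FALSE)
#' @return invisibly, the manifest list
#' @export
run_germreprog <- function(subcommand = c("all", "simulate", "quantify",
                                          "dynamics", "repeats", "smrna"),
                           config = NULL, outdir = "germreprog_out",
                           seed = NULL, plots = FALSE) {
  subcommand <- match.arg(subcommand)
  cfg <- load_run_config(config)
  if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  simcfg <- do.call(simulation_config, cfg$sim)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(subcommand = subcommand, seed = simcfg$seed,
                   parameters = cfg[setdiff(names(cfg), "sim")],
                   outputs = character(0))
  log_msg <- function(...) message("[germreprog] ", ...)

  stages <- if (subcommand == "all") {
    c("simulate", "quantify", "dynamics", "repeats", "smrna")
  } else subcommand

  add_out <- function(path) {
    # record paths relative to outdir so the manifest is location-agnostic
    manifest$outputs <<- c(manifest$outputs, basename(path))
    path
  }
  p <- function(...) file.path(outdir, ...)

  if ("simulate" %in% stages) {
    log_msg("simulate: genome, methylomes, reads, chip (seed ",
            simcfg$seed, ")")
    sim <- simulate_genome_and_annotation(simcfg)
    meth <- simulate_methylomes(simcfg, sim)
    smr <- simulate_smrna(simcfg, sim)
    chip <- simulate_chip(simcfg, sim)
    rna <- simulate_rnaseq(simcfg, sim)

    writeLines(paste(sim$genome$chrom, sim$genome$length, sep = "\t"),
               add_out(p("genome.chrom.sizes")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$sequence), add_out(p("genome.fa")))
    write_bed(sim$cgis, add_out(p("cgis.bed")))
    write_gene_models(sim$genes, add_out(p("genes.bed12")))
    write_repeats(sim$repeats, add_out(p("repeats.tsv")))
    write_dmrs(sim$dmrs, add_out(p("dmrs.tsv")))
    if (!is.null(sim$rrna)) write_bed(sim$rrna, add_out(p("rrna.bed")))
    if (!is.null(sim$mirna)) write_bed(sim$mirna, add_out(p("mirna.bed")))
    write_tsv_hash(sim$regions %>%
                     mutate(dmr_parent = ifelse(is.na(dmr_parent), ".",
                                                dmr_parent)),
                   add_out(p("truth_regions.tsv")))
    for (st in simcfg$stages) {
      write_cpg_calls(meth$calls %>% filter(sample == st),
                      add_out(p(paste0("calls_", st, ".cov"))),
                      dialect = "bismark_cov")
    }
    write_tsv_hash(meth$truth, add_out(p("truth_methylation.tsv")))
    write_smrna(smr$reads, add_out(p("smrna.fa")), add_out(p("smrna.bed")))
    write_tsv_hash(smr$truth %>%
                     mutate(partner = ifelse(is.na(partner), ".", partner)),
                   add_out(p("truth_smrna.tsv")))
    write_tsv_hash(chip, add_out(p("chip_scores.tsv")))
    write_bed(rna, add_out(p("rna_reads.bed")))
  }

  if (any(c("quantify", "dynamics", "repeats", "smrna") %in% stages)) {
    genome <- read_genome(require_input(p("genome.chrom.sizes"), stages[1]))
    stage_files <- Sys.glob(p("calls_*.cov"))
  }

  if ("quantify" %in% stages) {
    log_msg("quantify: probe matrices and feature summaries")
    genes <- read_gene_models(require_input(p("genes.bed12"), "quantify"),
                              genome)
    cgis <- read_intervals(require_input(p("cgis.bed"), "quantify"), "bed",
                           genome, feature_class = "CGI")
    repeats <- read_intervals(require_input(p("repeats.tsv"), "quantify"),
                              "repeat_tsv", genome)
    dmrs <- read_intervals(require_input(p("dmrs.tsv"), "quantify"),
                           "dmr_tsv", genome)
    calls <- map_dfr(stage_files, function(f) {
      read_cpg_calls(f, "bismark_cov",
                     sub("^calls_(.*)\\.cov$", "\\1", basename(f)), genome)
    })
    stage_order <- simcfg$stages[simcfg$stages %in% unique(calls$sample)]
    calls$sample <- factor(calls$sample, levels = stage_order)
    calls <- calls %>% arrange(sample, chrom, pos) %>%
      mutate(sample = as.character(sample))

    probes20 <- make_probes(genome, mode = "tiling",
                            width = cfg$probes$width)
    mm20 <- quantify_probes(probes20, calls, min_cpg = cfg$probes$min_cpg)
    write_probe_matrix(probes20, mm20, add_out(p("probe20kb_matrix.tsv")))

    probes2 <- make_probes(genome, mode = "tiling",
                           width = cfg$probes$kmeans_width,
                           exclude = repeats)
    mm2 <- quantify_probes(probes2, calls, min_cpg = 1)
    write_probe_matrix(probes2, mm2, add_out(p("probe2kb_matrix.tsv")))

    probes50 <- make_probes(genome, calls = calls, mode = "cpg_count",
                            n_cpg = cfg$probes$n_cpg)
    mm50 <- quantify_probes(probes50, calls, min_cpg = 1)
    write_probe_matrix(probes50, mm50, add_out(p("probe50cpg_matrix.tsv")))

    panel <- feature_panel(genome, genes, cgis, dmrs)
    write_tsv_hash(feature_methylation(panel, calls) %>%
                     arrange(sample, feature_class),
                   add_out(p("feature_summary.tsv")))
    write_tsv_hash(dmr_methylation(dmrs, calls),
                   add_out(p("dmr_panel.tsv")))
    write_tsv_hash(repeat_class_methylation(repeats, calls) %>%
                     arrange(sample, feature_class),
                   add_out(p("repeat_methylation.tsv")))
    mg <- metagene_profile(genes, calls)
    write_tsv_hash(mg, add_out(p("metagene.tsv")))
    if (plots) {
      ggsave(add_out(p("metagene.png")), plot_metagene(mg),
             width = 7, height = 4, dpi = 120)
    }
  }

  if ("dynamics" %in% stages) {
    log_msg("dynamics: background model, outliers, trajectory clusters")
    mm50 <- read_probe_matrix(require_input(p("probe50cpg_matrix.tsv"),
                                            "dynamics"))
    mm2 <- read_probe_matrix(require_input(p("probe2kb_matrix.tsv"),
                                           "dynamics"))
    stage_order <- simcfg$stages
    model <- fit_background(mm50$mm, start_sample = "epilc",
                            end_sample = stage_order[length(stage_order)],
                            n_bins = cfg$background$n_bins,
                            min_bin_n = cfg$background$min_bin_n)
    out <- call_outliers(model, alpha = cfg$alpha)
    write_tsv_hash(as_tibble(out) %>%
                     select(probe_id, start_fraction, end_fraction, p,
                            p_adj, class),
                   add_out(p("outliers.tsv")))

    km <- kmeans_trajectories(mm2$mm, k = cfg$k, seed = simcfg$seed,
                              n_restarts = cfg$n_restarts,
                              samples = stage_order)
    write_tsv_hash(km$assignments, add_out(p("clusters.tsv")))
    write_tsv_hash(tidy(km), add_out(p("centroids.tsv")))

    genome2 <- read_genome(p("genome.chrom.sizes"))
    genes <- read_gene_models(p("genes.bed12"), genome2)
    cgis <- read_intervals(p("cgis.bed"), "bed", genome2,
                           feature_class = "CGI")
    repeats <- read_intervals(p("repeats.tsv"), "repeat_tsv", genome2)
    feats <- bind_rows(
      cgis,
      genes %>% transmute(chrom, start = tx_start, end = tx_end,
                          strand, name = gene_id,
                          feature_class = "gene_body"),
      repeats %>% select(-family)
    )
    enr <- map_dfr(sort(unique(km$assignments$cluster)), function(cl) {
      enrich_features(km$assignments$probe_id[km$assignments$cluster == cl],
                      mm2$probes %>%
                        filter(probe_id %in% km$assignments$probe_id),
                      feats) %>%
        mutate(group = paste0("cluster", cl), .before = 1)
    })
    write_tsv_hash(enr, add_out(p("cluster_enrichment.tsv")))

    chip <- read_tsv_hash(require_input(p("chip_scores.tsv"), "dynamics"))
    ov <- overlay_chip(mm50$probes,
                       chip %>% filter(feature_class == "H3K9me3"))
    write_tsv_hash(ov, add_out(p("chip_overlay.tsv")))
    if (plots) {
      ggsave(add_out(p("background_scatter.png")),
             autoplot(model, calls = out), width = 5, height = 5, dpi = 120)
      ggsave(add_out(p("centroids.png")), autoplot(km),
             width = 6, height = 4, dpi = 120)
    }
  }

  if ("repeats" %in% stages) {
    log_msg("repeats: gene-proximity exclusion and RPKM")
    genes <- read_gene_models(require_input(p("genes.bed12"), "repeats"),
                              genome)
    repeats <- read_intervals(require_input(p("repeats.tsv"), "repeats"),
                              "repeat_tsv", genome)
    rna_raw <- read_token_table(require_input(p("rna_reads.bed"), "repeats"),
                                n_min = 6)
    rna <- tibble(chrom = rna_raw[[1]],
                  start = parse_count(rna_raw[[2]], "rna_reads.bed", "start"),
                  end = parse_count(rna_raw[[3]], "rna_reads.bed", "end"))
    kept <- exclude_near_genes(repeats, genes)
    expr <- repeat_rpkm(rna, kept, library_size = nrow(rna))
    write_tsv_hash(expr, add_out(p("repeat_rpkm.tsv")))
  }

  if ("smrna" %in% stages) {
    log_msg("smrna: classification, length spectra, ping-pong")
    reads <- read_smrna(require_input(p("smrna.fa"), "smrna"),
                        require_input(p("smrna.bed"), "smrna"), genome)
    genes <- read_gene_models(require_input(p("genes.bed12"), "smrna"),
                              genome)
    repeats <- read_intervals(require_input(p("repeats.tsv"), "smrna"),
                              "repeat_tsv", genome)
    ann <- list(
      rRNA = if (file.exists(p("rrna.bed"))) {
        read_intervals(p("rrna.bed"), "bed", genome, "rRNA")
      },
      miRNA = if (file.exists(p("mirna.bed"))) {
        read_intervals(p("mirna.bed"), "bed", genome, "miRNA")
      },
      "repeat" = repeats,
      gene = genes %>% transmute(chrom, start = tx_start, end = tx_end,
                                 strand, name = gene_id,
                                 feature_class = "gene")
    )
    cls <- classify_reads(reads, ann)
    write_tsv_hash(cls %>% count(class_label, name = "n_reads"),
                   add_out(p("smrna_classes.tsv")))
    write_tsv_hash(length_distribution(cls),
                   add_out(p("smrna_lengths.tsv")))
    write_tsv_hash(length_distribution(cls, by_repeat_strand = TRUE),
                   add_out(p("smrna_lengths_by_strand.tsv")))
    comp <- five_prime_composition(cls, require_input(p("genome.fa"),
                                                      "smrna"))
    write_tsv_hash(as_tibble(comp), add_out(p("smrna_5prime.tsv")))
    pp <- pingpong_profile(cls)
    ppt <- as_tibble(pp)
    ppt$z10 <- c(pingpong_z(pp) %||% NA_real_, rep(NA_real_, nrow(ppt) - 1))
    write_tsv_hash(ppt, add_out(p("smrna_pingpong.tsv")))
    if (plots) {
      ggsave(add_out(p("pingpong.png")), autoplot(pp),
             width = 5, height = 4, dpi = 120)
      ggsave(add_out(p("lengths.png")),
             plot_length_distribution(length_distribution(cls)),
             width = 5, height = 4, dpi = 120)
    }
  }

  manifest$package_version <- as.character(utils::packageVersion("germreprog"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

write_probe_matrix <- function(probes, mm, path) {
  wide <- meth_matrix_wide(mm)
  cov <- mm %>% select(probe_id, sample, covered_cpgs) %>%
    pivot_wider(names_from = sample, values_from = covered_cpgs,
                names_prefix = "cpgs_")
  out <- probes %>% select(probe_id, chrom, start, end) %>%
    left_join(wide, by = "probe_id") %>%
    left_join(cov, by = "probe_id")
  write_tsv_hash(out, path)
}

read_probe_matrix <- function(path) {
  d <- read_tsv_hash(path)
  sample_cols <- setdiff(names(d),
                         c("probe_id", "chrom", "start", "end",
                           grep("^cpgs_", names(d), value = TRUE)))
  mm <- d %>%
    select(probe_id, all_of(sample_cols)) %>%
    pivot_longer(-probe_id, names_to = "sample",
                 values_to = "meth_fraction")
  list(probes = d %>% select(probe_id, chrom, start, end), mm = mm)
}
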