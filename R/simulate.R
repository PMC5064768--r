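# Deterministic synthetic-data generator. Emulates the structure of a
# staged germ-cell specification methylome experiment: a genome tiled with
# region classes of distinct demethylation kinetics (CGIs hypomethylated
# throughout, young-TE-like regions resistant, imprinted DMRs at
# intermediate levels then erased, the rest following the global wave of
# priming hypermethylation and PGCLC demethylation), binomial per-CpG
# calls under a negative-binomial coverage model, small RNA reads with
# piRNA characteristics (24-31 nt, 5'U bias, slicer-paired ping-pong
# partners), and chromatin-mark score tracks. Everything is reproducible
# bit-for-bit under the config seed.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: four stages from naive
#' pluripotency through primed EpiLC to early and late PGCLC; global
#' methylation around 0.30 in naive cells, rising to about 0.65 on
#' priming, then declining stepwise in PGCLCs; CGIs at 0.05 throughout;
#' young-TE-like regions resistant to demethylation; imprinted DMRs at
#' 0.5 until late erasure.
#'
#' @param seed master RNG seed (all outputs deterministic given it)
#' @param chrom_sizes named integer vector of chromosome lengths
#' @param cpg_per_kb CpG density outside CGIs (CGIs are `cgi_factor`-fold
#'   denser)
#' @param cgi_factor CpG density enrichment inside CGIs (default 10)
#' @param proportions named numeric, genome share per region class; must
#'   sum to 1
#' @param stage_means matrix/data.frame of per-stage per-class mean
#'   methylation (stages x classes); `NULL` uses the defaults above
#' @param beta_precision precision of the per-region beta distribution of
#'   latent methylation (larger = tighter around the class mean)
#' @param coverage_mean,coverage_size negative-binomial per-CpG coverage
#'   parameters
#' @param smrna list: `n_reads`, fractions (`frac_rrna`, `frac_mirna`,
#'   `frac_pirna`; remainder is gene-derived), `p_u` (5'U probability),
#'   `pingpong_fraction` (share of piRNA reads that are slicer-paired
#'   secondaries), `pirna_len`, `mirna_len` ranges, `p_unique`
#' @param chip list: `k9_effect` (multiplicative H3K9me3 elevation on
#'   resistant regions), `k4_effect` (H3K4me3 elevation on CGIs),
#'   `noise_sd` (lognormal sd)
#' @param rnaseq list: `n_reads`, `read_len`, `frac_gene`, per-class TE
#'   expression weights `te_weights`
#' @return a `germ_simconfig` list
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
    cpg_per_kb = 4,
    cgi_factor = 10,
    proportions = c(cgi = 0.02, young_te = 0.05, old_te = 0.13,
                    gene_body = 0.30, imprinted_dmr = 0.01,
                    intergenic = 0.49),
    stage_means = NULL,
    beta_precision = 50,
    coverage_mean = 10, coverage_size = 5,
    smrna = list(),
    chip = list(),
    rnaseq = list()) {
  stages <- c("naive", "epilc", "pgclc_early", "pgclc_late")
  if (is.null(stage_means)) {
    stage_means <- rbind(
      cgi          = c(0.05, 0.05, 0.05, 0.05),
      young_te     = c(0.35, 0.80, 0.75, 0.70),
      old_te       = c(0.30, 0.70, 0.45, 0.25),
      gene_body    = c(0.32, 0.68, 0.45, 0.22),
      imprinted_dmr = c(0.50, 0.50, 0.35, 0.05),
      intergenic   = c(0.30, 0.65, 0.40, 0.18)
    )
    colnames(stage_means) <- stages
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    abort("region-class proportions must sum to 1")
  }
  if (any(stage_means < 0 | stage_means > 1)) {
    abort("stage means must lie in [0, 1]")
  }
  smrna <- utils::modifyList(list(
    n_reads = 5000L, frac_rrna = 0.10, frac_mirna = 0.25, frac_pirna = 0.60,
    p_u = 0.8, pingpong_fraction = 0.3,
    pirna_len = c(24L, 31L), mirna_len = c(22L, 23L), p_unique = 0.95
  ), smrna)
  chip <- utils::modifyList(list(
    k9_effect = 4, k4_effect = 4, noise_sd = 0.5
  ), chip)
  rnaseq <- utils::modifyList(list(
    n_reads = 20000L, read_len = 100L, frac_gene = 0.7,
    te_weights = c(young_te = 3, old_te = 1)
  ), rnaseq)
  structure(
    list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
         cpg_per_kb = cpg_per_kb, cgi_factor = cgi_factor,
         proportions = proportions, stages = colnames(stage_means),
         stage_means = stage_means, beta_precision = beta_precision,
         coverage_mean = coverage_mean, coverage_size = coverage_size,
         smrna = smrna, chip = chip, rnaseq = rnaseq),
    class = "germ_simconfig"
  )
}

# mean segment length per region class (bp); drawn uniform within +/- 50%
SEG_MEAN_LEN <- c(cgi = 1000, young_te = 4000, old_te = 4000,
                  gene_body = 15000, imprinted_dmr = 3000,
                  intergenic = 10000)

#' Simulate a genome with annotation and planted kinetic classes
#'
#' Tiles each chromosome with non-overlapping region-class segments whose
#' expected bp share matches the configured proportions, plants CpG
#' positions (density boosted inside CGIs), derives gene models (with
#' CGI-associated promoters for about half the genes), repeat instances
#' for TE segments, imprinted DMRs with alternating parent of origin, an
#' rRNA locus and miRNA loci for small RNA classification, and optionally
#' the genome sequence itself (random bases with CG planted at every CpG).
#'
#' @param config a `germ_simconfig` object
#' @param emit_sequence generate chromosome sequences (needed for small
#'   RNA simulation; default TRUE)
#' @return list: `genome` (index tibble), `regions` (truth tibble with
#'   `region_id`, class, `resistant`, `dmr_parent`), `cpgs`
#'   (`chrom`, `pos`), `genes`, `cgis`, `repeats`, `dmrs`,
#'   `rrna`, `mirna` annotation tibbles, `sequence` (named character or
#'   NULL), and `config`
#' @export
simulate_genome_and_annotation <- function(config, emit_sequence = TRUE) {
  stopifnot(inherits(config, "germ_simconfig"))
  with_seed(config$seed, {
    classes <- names(config$proportions)
    # probability of drawing a class per segment, adjusted for mean length
    # so that the expected bp share matches the configured proportions
    w <- config$proportions / SEG_MEAN_LEN[classes]
    w <- w / sum(w)
    regions <- map_dfr(names(config$chrom_sizes), function(chr) {
      len <- config$chrom_sizes[[chr]]
      pos <- 0
      out <- list()
      i <- 0
      while (pos < len) {
        cl <- sample(classes, 1, prob = w)
        sl <- round(runif(1, 0.5, 1.5) * SEG_MEAN_LEN[[cl]])
        sl <- min(sl, len - pos)
        i <- i + 1
        out[[i]] <- tibble(chrom = chr, start = pos, end = pos + sl,
                           class = cl)
        pos <- pos + sl
      }
      bind_rows(out)
    })
    # pair roughly half the gene bodies with a CGI promoter: relocate a
    # CGI segment to sit immediately upstream where the neighbour allows
    # CGI segments drawn immediately before a plus-strand gene body (or
    # after a minus-strand one) become that gene's promoter CGI, so a
    # share of genes carries CGI promoters without further placement
    regions <- regions %>%
      mutate(region_id = paste0("region", sprintf("%05d", row_number())))

    # CpG positions: density per class
    rate <- config$cpg_per_kb / 1000
    cpgs <- map_dfr(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      lambda <- rate * ifelse(r$class == "cgi", config$cgi_factor, 1)
      n <- rbinom(1, r$end - r$start, min(1, lambda))
      if (n == 0) return(NULL)
      pos <- sort(sample.int(r$end - r$start, n)) + r$start - 1L
      tibble(chrom = r$chrom, pos = as.integer(pos))
    }) %>%
      distinct(chrom, pos) %>%
      arrange(chrom, pos) %>%
      group_by(chrom) %>%
      # CG dinucleotides cannot overlap; enforce >= 2 bp spacing
      filter(is.na(lag(pos)) | pos - lag(pos) >= 2) %>%
      ungroup()
    genome <- tibble(chrom = names(config$chrom_sizes),
                     length = as.integer(config$chrom_sizes))
    cpgs <- cpgs %>%
      left_join(genome, by = "chrom") %>%
      filter(pos + 1 < length) %>%
      select(chrom, pos)

    # gene models from gene_body segments
    gene_regions <- regions %>% filter(class == "gene_body")
    genes <- map_dfr(seq_len(nrow(gene_regions)), function(i) {
      r <- gene_regions[i, ]
      n_ex <- sample(1:4, 1)
      glen <- r$end - r$start
      cuts <- sort(sample.int(glen - 1, 2 * n_ex - 2))
      bounds <- c(r$start, r$start + cuts, r$end)
      ex <- tibble(start = bounds[seq(1, length(bounds) - 1, by = 2)],
                   end = bounds[seq(2, length(bounds), by = 2)])
      tibble(gene_id = paste0("gene", sprintf("%04d", i)),
             chrom = r$chrom, strand = sample(c("+", "-"), 1),
             tx_start = r$start, tx_end = r$end, exons = list(ex))
    })

    # CGIs: the cgi segments; mark truth
    cgis <- regions %>% filter(class == "cgi") %>%
      transmute(chrom, start, end, strand = ".", name = region_id,
                feature_class = "CGI")

    # repeats from TE segments
    young_classes <- c("LTR/ERVK", "SVA")
    old_classes <- c("LINE/L1", "SINE/Alu")
    te <- regions %>% filter(class %in% c("young_te", "old_te"))
    repeats <- if (nrow(te) > 0) {
      te %>% mutate(
        feature_class = ifelse(class == "young_te",
                               sample(young_classes, n(), replace = TRUE),
                               sample(old_classes, n(), replace = TRUE)),
        strand = sample(c("+", "-"), n(), replace = TRUE),
        name = region_id, family = feature_class
      ) %>%
        select(chrom, start, end, strand, name, feature_class, family)
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), name = character(),
             feature_class = character(), family = character())
    }

    # imprinted DMRs with alternating parent of origin
    dmr_regions <- regions %>% filter(class == "imprinted_dmr")
    dmrs <- if (nrow(dmr_regions) > 0) {
      dmr_regions %>%
        mutate(parent = rep(c("maternal", "paternal"),
                            length.out = n())) %>%
        transmute(chrom, start, end, strand = ".", name = region_id,
                  feature_class = parent)
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), name = character(),
             feature_class = character())
    }
    regions <- regions %>%
      left_join(dmrs %>% select(name, dmr_parent = feature_class),
                by = c("region_id" = "name")) %>%
      mutate(resistant = class == "young_te")

    # rRNA locus: carve from the largest intergenic segment
    ig <- regions %>% filter(class == "intergenic") %>%
      arrange(desc(end - start))
    rrna <- if (nrow(ig) > 0) {
      r <- ig[1, ]
      w <- min(10000L, r$end - r$start)
      tibble(chrom = r$chrom, start = r$start, end = r$start + w,
             strand = "+", name = "rRNA_locus", feature_class = "rRNA")
    } else NULL
    # miRNA loci: 30 short hairpin loci inside other intergenic segments
    ig2 <- ig[-1, ] %>% filter(end - start > 500)
    n_mir <- min(30L, nrow(ig2))
    mirna <- if (n_mir > 0) {
      picks <- ig2[seq_len(n_mir), ]
      picks %>% transmute(
        chrom, start = start + 100L, end = start + 180L,
        strand = sample(c("+", "-"), n(), replace = TRUE),
        name = paste0("mir", seq_len(n_mir)), feature_class = "miRNA")
    } else NULL

    sequence <- if (emit_sequence) {
      seqs <- lapply(names(config$chrom_sizes), function(chr) {
        len <- config$chrom_sizes[[chr]]
        # avoid spontaneous CG dinucleotides so CpG truth is exact: draw
        # from a CG-free backbone, then plant CG at every CpG position
        v <- sample(c("A", "C", "T"), len, replace = TRUE)
        p <- cpgs$pos[cpgs$chrom == chr]
        v[p + 1L] <- "C"
        v[p + 2L] <- "G"
        paste(v, collapse = "")
      })
      setNames(unlist(seqs), names(config$chrom_sizes))
    } else NULL

    list(genome = genome, regions = regions, cpgs = cpgs, genes = genes,
         cgis = cgis, repeats = repeats, dmrs = dmrs, rrna = rrna,
         mirna = mirna, sequence = sequence, config = config)
  })
}

#' Simulate stage-wise methylomes
#'
#' For every region and stage a latent methylation level is drawn from a
#' beta distribution centred on the class mean (precision
#' `beta_precision`); per CpG, coverage is negative-binomial and
#' methylated calls are binomial at the latent level. CpGs with zero
#' coverage are absent from that sample.
#'
#' @param config a `germ_simconfig` object
#' @param sim result of [simulate_genome_and_annotation()]
#' @return list: `calls` (long tibble `sample`, `chrom`, `pos`, `meth`,
#'   `unmeth`; samples ordered as `config$stages`) and `truth`
#'   (per region x stage latent methylation)
#' @export
simulate_methylomes <- function(config, sim) {
  with_seed(config$seed + 1L, {
    regions <- sim$regions
    cpgs <- sim$cpgs
    # assign each CpG to its region (regions tile the genome)
    hits <- overlap_pairs(cpgs %>% transmute(chrom, start = pos, end = pos + 1L),
                          regions)
    cpg_region <- integer(nrow(cpgs))
    cpg_region[hits$q] <- hits$s
    truth <- list()
    calls <- list()
    for (stage in config$stages) {
      mu <- config$stage_means[regions$class, stage]
      prec <- config$beta_precision
      a <- pmax(mu * prec, 1e-6)
      b <- pmax((1 - mu) * prec, 1e-6)
      latent <- ifelse(mu == 0, 0, ifelse(mu == 1, 1, rbeta(nrow(regions), a, b)))
      truth[[stage]] <- tibble(region_id = regions$region_id, stage = stage,
                               class = regions$class, latent = latent)
      cov <- rnbinom(nrow(cpgs), mu = config$coverage_mean,
                     size = config$coverage_size)
      keep <- cov > 0
      m <- rbinom(sum(keep), cov[keep], latent[cpg_region[keep]])
      calls[[stage]] <- tibble(
        sample = stage,
        chrom = cpgs$chrom[keep], pos = cpgs$pos[keep],
        meth = as.integer(m), unmeth = as.integer(cov[keep] - m)
      )
    }
    list(calls = bind_rows(calls), truth = bind_rows(truth))
  })
}

#' Simulate a small RNA read set
#'
#' Primary piRNA-like reads (24-31 nt) are sampled from TE instances on
#' the instance strand with a configurable 5'U probability (the 5' base is
#' chosen from the genome, not overwritten, so the bias is genuine
#' sequence bias). A configured fraction of piRNA reads are slicer-paired
#' secondaries: their 5' end sits on the opposite strand across from
#' nucleotide 10 of a primary, so 10-nt 5'-5' overlaps emerge from the
#' cleavage rule rather than being hard-coded in the statistic. miRNA-like
#' reads (22-23 nt) come from miRNA loci and rRNA background from the rRNA
#' locus.
#'
#' @param config a `germ_simconfig` object
#' @param sim result of [simulate_genome_and_annotation()] with sequence
#' @return list: `reads` (small RNA read tibble) and `truth` (read origin
#'   classes and ping-pong partner ids)
#' @export
simulate_smrna <- function(config, sim) {
  if (is.null(sim$sequence)) {
    abort("simulate_smrna needs sim$sequence (emit_sequence = TRUE)")
  }
  pars <- config$smrna
  with_seed(config$seed + 2L, {
    n <- pars$n_reads
    n_rrna <- round(pars$frac_rrna * n)
    n_mirna <- round(pars$frac_mirna * n)
    n_pirna <- round(pars$frac_pirna * n)
    n_gene <- max(0L, n - n_rrna - n_mirna - n_pirna)
    if (n_pirna > 0 && nrow(sim$repeats) == 0) {
      abort("piRNA fraction > 0 but no repeat instances in the simulation")
    }

    base_at <- function(chrom, pos0, strand) {
      b <- substring(sim$sequence[chrom], pos0 + 1L, pos0 + 1L)
      ifelse(strand == "+", b, chartr("ACGT", "TGCA", b))
    }

    # --- primary piRNAs -----------------------------------------------
    n_sec <- round(pars$pingpong_fraction * n_pirna)
    n_pri <- n_pirna - n_sec
    reps <- sim$repeats
    pri <- NULL
    if (n_pri > 0) {
      ri <- sample.int(nrow(reps), n_pri, replace = TRUE,
                       prob = reps$end - reps$start)
      len <- sample(seq(pars$pirna_len[1], pars$pirna_len[2]), n_pri,
                    replace = TRUE)
      strand <- reps$strand[ri]
      want_u <- runif(n_pri) < pars$p_u
      five0 <- integer(n_pri)
      for (i in seq_len(n_pri)) {
        lo <- reps$start[ri[i]]
        hi <- reps$end[ri[i]] - len[i]
        if (hi <= lo) { ri[i] <- ri[i]; hi <- lo + 1 }
        # rejection-sample a 5' position whose strand-aware base matches
        # the wanted identity (T for 5'U reads, non-T otherwise)
        cand <- NA_integer_
        for (try in 1:50) {
          p0 <- sample.int(hi - lo, 1) + lo - 1L
          f0 <- if (strand[i] == "+") p0 else p0 + len[i] - 1L
          b <- base_at(reps$chrom[ri[i]], f0, strand[i])
          if ((b == "T") == want_u[i]) { cand <- p0; break }
        }
        if (is.na(cand)) cand <- sample.int(hi - lo, 1) + lo - 1L
        five0[i] <- cand
      }
      pri <- tibble(
        chrom = reps$chrom[ri], start = five0, end = five0 + len,
        strand = strand, origin = "piRNA_primary", partner = NA_character_
      )
    }

    # --- secondary (slicer-paired) piRNAs -----------------------------
    sec <- NULL
    if (n_sec > 0) {
      if (is.null(pri) || nrow(pri) == 0) {
        abort("pingpong_fraction > 0 requires primary piRNAs")
      }
      src <- sample.int(nrow(pri), n_sec, replace = n_sec > nrow(pri))
      len <- sample(seq(pars$pirna_len[1], pars$pirna_len[2]), n_sec,
                    replace = TRUE)
      p_chrom <- pri$chrom[src]
      p_strand <- pri$strand[src]
      p_five <- ifelse(p_strand == "+", pri$start[src], pri$end[src] - 1L)
      # cleavage across from nucleotide 10 of the guide: the secondary 5'
      # end lies 9 nt into the guide, on the opposite strand
      s_strand <- ifelse(p_strand == "+", "-", "+")
      s_five <- ifelse(p_strand == "+", p_five + 9L, p_five - 9L)
      s_start <- ifelse(s_strand == "+", s_five, s_five - len + 1L)
      s_end <- s_start + len
      chrlen <- setNames(as.integer(config$chrom_sizes),
                         names(config$chrom_sizes))
      ok <- s_start >= 0 & s_end <= chrlen[p_chrom]
      sec <- tibble(
        chrom = p_chrom, start = as.integer(s_start),
        end = as.integer(s_end), strand = s_strand,
        origin = "piRNA_secondary", partner_src = src
      )[ok, ]
    }

    # --- miRNA / rRNA / gene background -------------------------------
    sample_from <- function(iv, n_r, len_range, origin, stranded = TRUE) {
      if (n_r == 0 || is.null(iv) || nrow(iv) == 0) return(NULL)
      ii <- sample.int(nrow(iv), n_r, replace = TRUE,
                       prob = iv$end - iv$start)
      len <- sample(seq(len_range[1], len_range[2]), n_r, replace = TRUE)
      room <- pmax(1L, iv$end[ii] - iv$start[ii] - len)
      off <- vapply(room, function(r) sample.int(r, 1) - 1L, integer(1))
      start <- iv$start[ii] + off
      tibble(
        chrom = iv$chrom[ii], start = start, end = start + len,
        strand = if (stranded) iv$strand[ii]
                 else sample(c("+", "-"), n_r, replace = TRUE),
        origin = origin, partner = NA_character_
      )
    }
    rr <- sample_from(sim$rrna, n_rrna, c(18L, 35L), "rRNA",
                      stranded = FALSE)
    mi <- sample_from(sim$mirna, n_mirna,
                      c(pars$mirna_len[1], pars$mirna_len[2]), "miRNA")
    gn <- sample_from(
      sim$genes %>% transmute(chrom, start = tx_start, end = tx_end, strand),
      n_gene, c(18L, 35L), "gene")

    reads <- bind_rows(rr, mi, pri, sec, gn)
    reads <- reads %>%
      mutate(
        read_id = paste0("read_", sprintf("%06d", row_number())),
        unique_flag = runif(n()) < pars$p_unique
      )
    # resolve slicer partners: partner_src indexes the primary read table
    if (!"partner" %in% names(reads)) reads$partner <- NA_character_
    if ("partner_src" %in% names(reads)) {
      idx_pri <- which(reads$origin == "piRNA_primary")
      is_sec <- !is.na(reads$partner_src)
      reads$partner[is_sec] <-
        reads$read_id[idx_pri[reads$partner_src[is_sec]]]
    }
    # sequences copied from the genome, reverse-complemented on minus
    seqs <- character(nrow(reads))
    for (chr in unique(reads$chrom)) {
      sel <- reads$chrom == chr
      s <- substring(sim$sequence[[chr]], reads$start[sel] + 1L,
                     reads$end[sel])
      minus <- reads$strand[sel] == "-"
      s[minus] <- revcomp_chr(s[minus])
      seqs[sel] <- s
    }
    reads$sequence <- seqs
    truth <- reads %>% select(read_id, origin, partner)
    reads <- reads %>%
      select(read_id, chrom, start, end, strand, sequence, unique_flag) %>%
      mutate(class_label = NA_character_)
    list(reads = reads, truth = truth)
  })
}

#' Simulate chromatin-mark score tracks
#'
#' Per-region lognormal scores: an H3K9me3-like track elevated on
#' demethylation-resistant (young-TE) regions and an H3K4me3-like track
#' elevated on CGIs.
#'
#' @param config a `germ_simconfig` object
#' @param sim result of [simulate_genome_and_annotation()]
#' @return interval tibble (`chrom`, `start`, `end`, `name`,
#'   `feature_class` in H3K9me3/H3K4me3, `score`)
#' @export
simulate_chip <- function(config, sim) {
  with_seed(config$seed + 3L, {
    r <- sim$regions
    k9 <- r %>% transmute(
      chrom, start, end, name = region_id, feature_class = "H3K9me3",
      score = rlnorm(n(), 0, config$chip$noise_sd) *
        ifelse(resistant, config$chip$k9_effect, 1))
    k4 <- r %>% transmute(
      chrom, start, end, name = region_id, feature_class = "H3K4me3",
      score = rlnorm(n(), 0, config$chip$noise_sd) *
        ifelse(class == "cgi", config$chip$k4_effect, 1))
    bind_rows(k9, k4)
  })
}

#' Simulate bulk RNA-seq read intervals
#'
#' A simple read placer for repeat-expression quantitation: a configured
#' share of reads from gene bodies, the rest from TE instances with
#' class-weighted expression.
#'
#' @param config a `germ_simconfig` object
#' @param sim result of [simulate_genome_and_annotation()]
#' @return interval tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`)
#' @export
simulate_rnaseq <- function(config, sim) {
  with_seed(config$seed + 4L, {
    pars <- config$rnaseq
    n_gene <- round(pars$frac_gene * pars$n_reads)
    n_te <- pars$n_reads - n_gene
    place <- function(iv, n_r, w) {
      if (n_r == 0 || nrow(iv) == 0) return(NULL)
      ii <- sample.int(nrow(iv), n_r, replace = TRUE, prob = w)
      room <- pmax(1L, iv$end[ii] - iv$start[ii] - pars$read_len)
      off <- vapply(room, function(r) sample.int(r, 1) - 1L, integer(1))
      tibble(chrom = iv$chrom[ii], start = iv$start[ii] + off,
             end = iv$start[ii] + off + pars$read_len,
             strand = sample(c("+", "-"), n_r, replace = TRUE))
    }
    gene_iv <- sim$genes %>%
      transmute(chrom, start = tx_start, end = tx_end)
    te_iv <- sim$repeats
    te_class <- ifelse(te_iv$feature_class %in% c("LTR/ERVK", "SVA"),
                       "young_te", "old_te")
    te_w <- pars$te_weights[te_class] * (te_iv$end - te_iv$start)
    reads <- bind_rows(
      place(gene_iv, n_gene, gene_iv$end - gene_iv$start),
      place(te_iv, n_te, te_w)
    )
    reads %>% mutate(name = paste0("rna_", row_number()), score = 0L) %>%
      select(chrom, start, end, name, score, strand)
  })
}
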