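#' Simulation configuration
#'
#' Defines the synthetic study: two target species with multi-strain
#' pangenomes carrying strain-level SNPs, a small off-target species
#' database, a host transcriptome, log-normal per-gene expression with
#' planted differential expression, and probe-captured reads with
#' method-specific mismatch sensitivity and host background. All
#' randomness derives from `seed` (sub-stages use fixed small offsets of
#' it); no unseeded draw exists anywhere in the simulator.
#'
#' @param seed Integer seed (mandatory).
#' @param n_species Number of target species.
#' @param n_genomes Strains per target species.
#' @param n_core,n_accessory Core and accessory gene counts per species.
#' @param gene_len Length-2 range of gene lengths (bases).
#' @param intergenic_len Spacer length between genes (bases).
#' @param snp_rate Per-base substitution rate of non-reference strains.
#' @param accessory_presence Probability an accessory gene is present in a
#'   given strain.
#' @param off_n_species,off_n_genomes Off-target species and strains each.
#' @param off_homology_frac Fraction of off-target genes copied (with
#'   divergence `off_divergence`) from a target species, so the exclusion
#'   screen has realistic near-matches to reject.
#' @param off_divergence Per-base divergence of those homologous genes.
#' @param host_n_tx,host_tx_len Host transcript count and length.
#' @param expr_meanlog,expr_sdlog Log-normal baseline abundance parameters.
#' @param de_fraction Fraction of genes per species with planted DE.
#' @param de_log2fc Planted |log2 fold change|.
#' @param n_reads Reads per sample (on-target + background).
#' @param read_len Raw read length (bases).
#' @param error_rate Per-base substitution sequencing-error rate.
#' @param background_fraction Fraction of reads drawn from the host.
#' @param method `"spe"` or `"mip"` capture chemistry.
#' @param spe_tm_slope Logistic slope of SPE efficiency in (Tm - median Tm).
#' @param spe_mm_penalty Multiplicative SPE efficiency penalty per probe
#'   mismatch to the captured strain.
#' @param mip_max_mm MIP tolerates up to this many arm mismatches with
#'   unchanged efficiency; more abolish capture.
#' @param bcv Biological coefficient of variation for replicate-level
#'   count overdispersion in [simulate_probe_counts()].
#' @return List of class `tealseq_sim_config`.
#' @export
sim_config <- function(seed,
                       n_species = 2L, n_genomes = 6L,
                       n_core = 100L, n_accessory = 20L,
                       gene_len = c(300L, 900L), intergenic_len = 100L,
                       snp_rate = 0.01, accessory_presence = 0.5,
                       off_n_species = 2L, off_n_genomes = 2L,
                       off_homology_frac = 0.05, off_divergence = 0.1,
                       host_n_tx = 100L, host_tx_len = 500L,
                       expr_meanlog = 3, expr_sdlog = 1.2,
                       de_fraction = 0.1, de_log2fc = 3,
                       n_reads = 1e5L, read_len = 100L,
                       error_rate = 0.002, background_fraction = 0.5,
                       method = c("mip", "spe"),
                       spe_tm_slope = 0.3, spe_mm_penalty = 0.5,
                       mip_max_mm = 3L, bcv = 0.1) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  method <- match.arg(method)
  stopifnot(seed == floor(seed), snp_rate >= 0, snp_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            background_fraction >= 0, background_fraction <= 1,
            de_fraction >= 0, de_fraction <= 1,
            accessory_presence >= 0, accessory_presence <= 1,
            length(gene_len) == 2, gene_len[1] <= gene_len[2],
            gene_len[1] >= 40)
  structure(as.list(environment()), class = "tealseq_sim_config")
}

.rand_dna <- function(n, len) {
  if (n == 0) return(character(0))
  len <- rep_len(as.integer(len), n)
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  vapply(seq_len(n), function(i) {
    if (len[i] == 0L) "" else paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

# substitute bases at rate `rate`; each hit becomes a different base
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  vapply(seq, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n_mut <- rbinom(1, length(b), rate)
    if (n_mut == 0) return(s)
    pos <- sample.int(length(b), n_mut)
    for (i in pos) {
      b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.hamming_pair <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    sum(charToRaw(a[i]) != charToRaw(b[i]))
  }, integer(1))
}

#' Simulate a multi-species pangenome with ground truth
#'
#' Builds, per target species, a set of strain genomes: core genes present
#' in every strain, accessory genes in a random subset, strain-level SNPs
#' at `snp_rate` relative to the ancestral (reference, strain 1) sequence,
#' genes separated by random intergenic spacers. Off-target species are
#' generated independently except for a configurable fraction of diverged
#' homologs of target genes. A host transcriptome is generated alongside.
#'
#' @param config A [sim_config()].
#' @return A `tealseq_sim` object: per-species `genomes`, reference `cds`,
#'   `genes` (ancestral sequences), `strain_genes` (per-strain gene copies
#'   with contig offsets), long presence/absence `pa`; plus `off_genomes`
#'   and `host` tibbles.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "tealseq_sim_config"))
  set.seed(config$seed)
  species_ids <- sprintf("sp%d", seq_len(config$n_species))
  species <- setNames(vector("list", length(species_ids)), species_ids)
  for (sp in species_ids) {
    n_genes <- config$n_core + config$n_accessory
    lens <- sample(config$gene_len[1]:config$gene_len[2], n_genes,
                   replace = TRUE)
    gene_ids <- sprintf("%s_g%03d", sp, seq_len(n_genes))
    type <- rep(c("core", "accessory"),
                c(config$n_core, config$n_accessory))
    genes <- tibble::tibble(species_id = sp, gene_id = gene_ids,
                            type = type, length = lens,
                            ref_seq = .rand_dna(n_genes, lens))
    strains <- sprintf("%s_strain%02d", sp, seq_len(config$n_genomes))
    presence <- matrix(1L, n_genes, config$n_genomes,
                       dimnames = list(gene_ids, strains))
    acc <- which(type == "accessory")
    if (length(acc) > 0) {
      presence[acc, ] <- matrix(
        rbinom(length(acc) * config$n_genomes, 1,
               config$accessory_presence),
        nrow = length(acc))
      presence[acc, 1] <- 1L  # reference strain carries all genes
    }
    strain_genes <- list()
    genomes <- list()
    for (gi in seq_along(strains)) {
      here <- which(presence[, gi] == 1L)
      seqs <- genes$ref_seq[here]
      if (gi > 1) seqs <- .mutate_seq(seqs, config$snp_rate)
      spacers <- .rand_dna(length(here) + 1L, config$intergenic_len)
      starts <- config$intergenic_len +
        cumsum(c(0L, head(genes$length[here], -1) + config$intergenic_len))
      contig <- paste0(paste0(spacers[seq_along(here)], seqs,
                              collapse = ""),
                       spacers[length(here) + 1L])
      contig_id <- paste0(strains[gi], "_c1")
      strain_genes[[gi]] <- tibble::tibble(
        species_id = sp, genome_id = strains[gi], contig_id = contig_id,
        gene_id = genes$gene_id[here], start = starts, seq = seqs)
      genomes[[gi]] <- tibble::tibble(
        genome_id = strains[gi], contig_id = contig_id, seq = contig,
        length = nchar(contig))
    }
    strain_genes <- dplyr::bind_rows(strain_genes)
    genomes <- dplyr::bind_rows(genomes)
    ref <- strain_genes[strain_genes$genome_id == strains[1], ]
    cds <- tibble::tibble(
      contig_id = ref$contig_id, start = ref$start,
      end = ref$start + nchar(ref$seq), strand = "+",
      gene_id = ref$gene_id, product = "simulated CDS")
    pa <- tibble::as_tibble(as.data.frame.table(
      presence, stringsAsFactors = FALSE)) |>
      setNames(c("cluster_id", "genome_id", "present"))
    species[[sp]] <- list(species_id = sp, genes = genes,
                          strain_genes = strain_genes, genomes = genomes,
                          cds = cds, pa = pa)
  }
  # off-target species: independent, with a sprinkle of diverged homologs
  off <- list()
  for (oi in seq_len(config$off_n_species)) {
    osp <- sprintf("off%d", oi)
    n_genes <- config$n_core
    lens <- sample(config$gene_len[1]:config$gene_len[2], n_genes,
                   replace = TRUE)
    seqs <- .rand_dna(n_genes, lens)
    n_hom <- round(config$off_homology_frac * n_genes)
    if (n_hom > 0 && length(species) > 0) {
      src_sp <- species[[1 + (oi - 1) %% length(species)]]
      src <- sample.int(nrow(src_sp$genes), n_hom)
      seqs[seq_len(n_hom)] <- .mutate_seq(src_sp$genes$ref_seq[src],
                                          config$off_divergence)
    }
    for (gi in seq_len(config$off_n_genomes)) {
      gid <- sprintf("%s_strain%02d", osp, gi)
      gseqs <- if (gi > 1) .mutate_seq(seqs, config$snp_rate) else seqs
      spacers <- .rand_dna(n_genes + 1L, config$intergenic_len)
      contig <- paste0(paste0(spacers[seq_len(n_genes)], gseqs,
                              collapse = ""),
                       spacers[n_genes + 1L])
      off[[length(off) + 1L]] <- tibble::tibble(
        species_id = osp, genome_id = gid,
        contig_id = paste0(gid, "_c1"), seq = contig,
        length = nchar(contig))
    }
  }
  host <- tibble::tibble(
    contig_id = sprintf("host_tx%04d", seq_len(config$host_n_tx)),
    seq = .rand_dna(config$host_n_tx, config$host_tx_len),
    length = config$host_tx_len)
  structure(list(config = config, species = species,
                 off_genomes = dplyr::bind_rows(off), host = host),
            class = "tealseq_sim")
}

#' @export
print.tealseq_sim <- function(x, ...) {
  cat(sprintf("<tealseq simulation> %d target species x %d strains, %d off-target genomes, %d host transcripts\n",
              length(x$species), x$config$n_genomes,
              if (nrow(x$off_genomes)) dplyr::n_distinct(x$off_genomes$genome_id) else 0L,
              nrow(x$host)))
  invisible(x)
}

#' Simulate per-condition expression states with planted DE
#'
#' Baseline abundances are i.i.d. log-normal; a fraction of genes per
#' species is planted as differentially expressed, multiplied by
#' `2^(+-de_log2fc)` in condition B (signs alternate so both directions are
#' represented); all other genes are identical across conditions.
#'
#' @param sim A `tealseq_sim` from [simulate_pangenome()].
#' @param config Overrides `sim$config` when given.
#' @return The `sim` with `$expression` added: tibble `species_id`,
#'   `gene_id`, `abundance_A`, `abundance_B`, `is_de`, `true_log2fc`.
#' @export
simulate_expression <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "tealseq_sim"))
  set.seed(config$seed + 1L)
  out <- purrr::map(sim$species, function(spd) {
    n <- nrow(spd$genes)
    base <- rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    lfc <- numeric(n)
    if (n_de > 0) {
      lfc[de_idx] <- rep_len(c(1, -1), n_de) * config$de_log2fc
    }
    tibble::tibble(species_id = spd$species_id,
                   gene_id = spd$genes$gene_id,
                   abundance_A = base,
                   abundance_B = base * 2^lfc,
                   is_de = lfc != 0,
                   true_log2fc = lfc)
  })
  sim$expression <- dplyr::bind_rows(out)
  sim
}

# Per-probe, per-strain capture efficiency.
# SPE: logistic in (Tm - panel median Tm) times a per-mismatch penalty.
# MIP: flat, tolerating up to `mip_max_mm` total arm mismatches, zero above.
# Returns tibble(probe_id, gene_id, species_id, genome_id, mm, efficiency, tm)
probe_strain_efficiency <- function(sim, panel, config = sim$config) {
  p <- panel$probes
  if (nrow(p) == 0) return(tibble::tibble())
  sp <- panel$species_id
  spd <- sim$species[[sp]]
  cds <- spd$cds[, c("gene_id", "start")]
  names(cds)[2] <- "gene_start"
  is_mip <- panel$architecture == "mip"
  pp <- dplyr::left_join(p, cds, by = "gene_id")
  strains <- unique(spd$strain_genes$genome_id)
  res <- purrr::map(strains, function(st) {
    sg <- spd$strain_genes[spd$strain_genes$genome_id == st, ]
    gs <- setNames(sg$seq, sg$gene_id)
    ref <- setNames(spd$genes$ref_seq, spd$genes$gene_id)
    if (is_mip) {
      lo <- pp$left_start - pp$gene_start
      ro <- pp$right_start - pp$gene_start
      llen <- pp$left_end - pp$left_start
      rlen <- pp$right_end - pp$right_start
      mm <- .hamming_pair(
        paste0(substring(ref[pp$gene_id], lo + 1, lo + llen),
               substring(ref[pp$gene_id], ro + 1, ro + rlen)),
        paste0(substring(gs[pp$gene_id], lo + 1, lo + llen),
               substring(gs[pp$gene_id], ro + 1, ro + rlen)))
      tm <- (pp$left_tm + pp$right_tm) / 2
    } else {
      off <- pp$start - pp$gene_start
      plen <- pp$end - pp$start
      mm <- .hamming_pair(substring(ref[pp$gene_id], off + 1, off + plen),
                          substring(gs[pp$gene_id], off + 1, off + plen))
      tm <- pp$tm
    }
    tibble::tibble(probe_id = pp$probe_id, gene_id = pp$gene_id,
                   species_id = sp, genome_id = st, mm = mm, tm = tm)
  }) |> dplyr::bind_rows()
  med_tm <- median(res$tm[res$genome_id == strains[1]])
  if (is_mip) {
    res$efficiency <- ifelse(res$mm <= config$mip_max_mm, 1, 0)
  } else {
    res$efficiency <- stats::plogis(config$spe_tm_slope * (res$tm - med_tm)) *
      config$spe_mm_penalty^res$mm
  }
  res
}

#' Simulate probe-captured reads with full ground truth
#'
#' Draws on-target reads per (probe, strain) with probability proportional
#' to gene abundance times capture efficiency (see the efficiency model in
#' the package vignette), plus host background reads at
#' `background_fraction`. Raw reads carry the method's adapter structure —
#' SPE/bulk reads end in the bait adapter, MIP reads begin with five
#' to-be-trimmed bases — so the trimming rules are exercised end to end.
#' Substitution sequencing errors are applied at `error_rate`. The truth
#' alignment table places every cleaned on-target read on the species'
#' reference genome with its exact NM (strain SNPs + sequencing errors);
#' background reads are recorded unmapped.
#'
#' @param sim A `tealseq_sim` with `$expression` (see
#'   [simulate_expression()]).
#' @param panels A `tealseq_panel` or list of panels (one per species).
#' @param condition `"A"` or `"B"`: which abundance column drives capture.
#' @param seed Seed for this sample's draws (derive one per sample, e.g.
#'   `config$seed + 100 + sample_index`).
#' @param config Overrides `sim$config` when given.
#' @return List with `reads` (tibble `read_id`, `seq` — raw FASTQ-ready),
#'   `truth` (tibble `read_id`, `origin` probe or `"background"`,
#'   `genome_id`), and `alignments` (cleaned-read truth placements, ready
#'   for [write_sam()]), plus `ref_contigs` for the SAM header.
#' @export
simulate_captured_reads <- function(sim, panels, condition = "A",
                                    seed = sim$config$seed + 100L,
                                    config = sim$config) {
  stopifnot(inherits(sim, "tealseq_sim"), !is.null(sim$expression))
  if (inherits(panels, "tealseq_panel")) panels <- list(panels)
  for (pan in panels) {
    if (pan$architecture != config$method) {
      stop("panel architecture ", pan$architecture,
           " does not match config method ", config$method)
    }
  }
  set.seed(seed)
  is_mip <- config$method == "mip"
  ab_col <- paste0("abundance_", condition)
  eff <- purrr::map(panels, probe_strain_efficiency, sim = sim,
                    config = config) |>
    dplyr::bind_rows()
  eff <- dplyr::left_join(
    eff, sim$expression[, c("species_id", "gene_id", ab_col)],
    by = c("species_id", "gene_id"))
  eff$weight <- eff$efficiency * eff[[ab_col]]
  if (sum(eff$weight) <= 0) stop("no probe has positive capture weight")
  n_bg <- round(config$background_fraction * config$n_reads)
  n_on <- config$n_reads - n_bg
  draw <- as.integer(rmultinom(1, n_on, eff$weight))
  # genomic part length of the cleaned read
  bait <- "AGATCGGAAGAG"
  glen <- if (is_mip) config$read_len - 5L else config$read_len - nchar(bait)
  probe_pos <- .probe_read_anchor(panels, sim)
  idx <- rep.int(seq_len(nrow(eff)), draw)
  on_reads <- NULL
  if (length(idx) > 0) {
    e <- eff[idx, c("probe_id", "species_id", "gene_id", "genome_id")]
    anchor <- probe_pos[match(e$probe_id, probe_pos$probe_id), ]
    spd_strain <- dplyr::bind_rows(
      purrr::map(sim$species, "strain_genes"))
    key_strain <- paste(spd_strain$genome_id, spd_strain$gene_id)
    gseq <- spd_strain$seq[match(paste(e$genome_id, e$gene_id), key_strain)]
    offs <- anchor$gene_offset
    gl <- pmin(glen, nchar(gseq) - offs)
    raw_core <- substring(gseq, offs + 1L, offs + gl)
    raw_core <- .apply_errors(raw_core, config$error_rate)
    seq_raw <- if (is_mip) {
      paste0(.rand_dna(length(raw_core), 5L), raw_core)
    } else {
      paste0(raw_core, bait,
             .rand_dna(length(raw_core),
                       pmax(0L, config$read_len - gl - nchar(bait))))
    }
    # reference placement + exact NM of the cleaned read
    ref_gene <- dplyr::bind_rows(purrr::map(sim$species, "genes"))
    rseq <- ref_gene$ref_seq[match(e$gene_id, ref_gene$gene_id)]
    nm <- .hamming_pair(raw_core, substring(rseq, offs + 1L, offs + gl))
    on_reads <- tibble::tibble(
      origin = e$probe_id, species_id = e$species_id,
      genome_id = e$genome_id,
      contig_id = anchor$ref_contig,
      start = anchor$ref_start,
      seq_raw = seq_raw, seq_clean = raw_core, nm = nm)
  }
  bg_reads <- NULL
  if (n_bg > 0) {
    tx <- sim$host[sample.int(nrow(sim$host), n_bg, replace = TRUE), ]
    bstart <- floor(runif(n_bg, 0, pmax(1, tx$length - glen)))
    core <- .apply_errors(substring(tx$seq, bstart + 1L, bstart + glen),
                          config$error_rate)
    seq_raw <- if (is_mip) {
      paste0(.rand_dna(n_bg, 5L), core)
    } else {
      paste0(core, bait,
             .rand_dna(n_bg, max(0L, config$read_len - glen - nchar(bait))))
    }
    bg_reads <- tibble::tibble(
      origin = "background", species_id = NA_character_,
      genome_id = NA_character_, contig_id = NA_character_,
      start = NA_integer_, seq_raw = seq_raw, seq_clean = core,
      nm = NA_integer_)
  }
  all_reads <- dplyr::bind_rows(on_reads, bg_reads)
  if (nrow(all_reads) > 0) {
    all_reads <- all_reads[sample.int(nrow(all_reads)), ]
    all_reads$read_id <- sprintf("read_%07d", seq_len(nrow(all_reads)))
  } else {
    all_reads$read_id <- character(0)
  }
  ref_contigs <- dplyr::bind_rows(purrr::map(sim$species, function(s) {
    s$genomes[s$genomes$genome_id == s$genomes$genome_id[1],
              c("contig_id", "length")]
  }))
  list(
    reads = tibble::tibble(read_id = all_reads$read_id,
                           seq = all_reads$seq_raw),
    truth = tibble::tibble(read_id = all_reads$read_id,
                           origin = all_reads$origin,
                           species_id = all_reads$species_id,
                           genome_id = all_reads$genome_id),
    alignments = tibble::tibble(
      read_id = all_reads$read_id,
      contig_id = all_reads$contig_id,
      start = all_reads$start,
      strand = "+",
      mapq = ifelse(is.na(all_reads$contig_id), 0L, 60L),
      nm = all_reads$nm,
      seq = all_reads$seq_clean),
    ref_contigs = ref_contigs,
    seed = seed
  )
}

# where on the reference genome a cleaned read anchors for each probe:
# SPE reads start at the probe start; MIP reads start at the left arm start
.probe_read_anchor <- function(panels, sim) {
  purrr::map(panels, function(pan) {
    p <- pan$probes
    if (nrow(p) == 0) return(NULL)
    cds <- sim$species[[pan$species_id]]$cds
    gene_start <- cds$start[match(p$gene_id, cds$gene_id)]
    anchor_start <- if (pan$architecture == "mip") p$left_start else p$start
    tibble::tibble(probe_id = p$probe_id, ref_contig = p$contig_id,
                   ref_start = anchor_start,
                   gene_offset = anchor_start - gene_start)
  }) |>
    dplyr::bind_rows()
}

.apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(b), n_err[i])
    for (j in pos) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
    seqs[i] <- paste(b, collapse = "")
  }
  seqs
}

#' Simulate replicate probe-count tables directly
#'
#' Count-level shortcut past read generation for differential-expression
#' studies: per sample, probe counts are multinomial draws over probes with
#' weights abundance x efficiency, jittered by a per-(probe, sample) gamma
#' multiplier with coefficient of variation `bcv` to induce
#' negative-binomial-like replicate overdispersion.
#'
#' @inheritParams simulate_captured_reads
#' @param samples Sample sheet tibble `sample_id`, `condition` (`"A"`/
#'   `"B"`).
#' @return Long tibble `probe_id`, `gene_id`, `species_id`, `sample_id`,
#'   `count`.
#' @export
simulate_probe_counts <- function(sim, panels, samples,
                                  config = sim$config) {
  stopifnot(inherits(sim, "tealseq_sim"), !is.null(sim$expression),
            all(c("sample_id", "condition") %in% names(samples)))
  if (inherits(panels, "tealseq_panel")) panels <- list(panels)
  set.seed(config$seed + 2L)
  eff <- purrr::map(panels, probe_strain_efficiency, sim = sim,
                    config = config) |>
    dplyr::bind_rows() |>
    dplyr::summarise(efficiency = mean(.data$efficiency),
                     .by = c("probe_id", "gene_id", "species_id"))
  eff <- dplyr::left_join(
    eff,
    sim$expression[, c("species_id", "gene_id", "abundance_A",
                       "abundance_B")],
    by = c("species_id", "gene_id"))
  out <- purrr::pmap(samples, function(sample_id, condition, ...) {
    ab <- if (condition == "A") eff$abundance_A else eff$abundance_B
    w <- eff$efficiency * ab
    if (config$bcv > 0) {
      shape <- 1 / config$bcv^2
      w <- w * rgamma(length(w), shape = shape, rate = shape)
    }
    tibble::tibble(probe_id = eff$probe_id, gene_id = eff$gene_id,
                   species_id = eff$species_id, sample_id = sample_id,
                   count = as.integer(rmultinom(1, config$n_reads, w)))
  })
  dplyr::bind_rows(out)
}

#' Default sample sheet for a two-condition study
#'
#' @param n_per_condition Biological replicates per condition.
#' @return Tibble `sample_id`, `condition`.
#' @export
sim_sample_sheet <- function(n_per_condition = 3L) {
  tibble::tibble(
    sample_id = c(sprintf("A%d", seq_len(n_per_condition)),
                  sprintf("B%d", seq_len(n_per_condition))),
    condition = rep(c("A", "B"), each = n_per_condition))
}

#' Write a simulation to disk in standard formats
#'
#' Emits one FASTA per strain genome, a GFF3 of reference CDS and an Rtab
#' presence/absence matrix per species, one FASTA each for the off-target
#' genomes and the host transcriptome, and the expression truth table.
#'
#' @param sim A `tealseq_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (spd in sim$species) {
    for (g in unique(spd$genomes$genome_id)) {
      write_genome_fasta(spd$genomes[spd$genomes$genome_id == g, ],
                         file.path(dir, paste0(g, ".fasta")))
    }
    write_cds_gff3(spd$cds,
                   file.path(dir, paste0(spd$species_id, "_reference.gff3")))
    write_presence_absence(spd$pa,
                           file.path(dir, paste0(spd$species_id, ".Rtab")))
  }
  if (nrow(sim$off_genomes) > 0) {
    write_genome_fasta(sim$off_genomes, file.path(dir, "off_target.fasta"))
  }
  write_genome_fasta(sim$host, file.path(dir, "host_transcripts.fasta"))
  if (!is.null(sim$expression)) {
    readr::write_tsv(sim$expression, file.path(dir, "expression_truth.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}
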