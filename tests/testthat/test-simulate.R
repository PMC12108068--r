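test_that("zero SNP rate makes all strains identical over core genes", {
  cfg <- sim_config(seed = 5, n_core = 8L, n_accessory = 0L,
                    n_genomes = 4L, snp_rate = 0)
  sim <- simulate_pangenome(cfg)
  sg <- sim$species$sp1$strain_genes
  per_gene <- split(sg$seq, sg$gene_id)
  expect_true(all(vapply(per_gene, function(s) length(unique(s)) == 1,
                         logical(1))))
})

test_that("core genes are present in every genome; accessory vary", {
  sim <- small_sim()
  for (spd in sim$species) {
    pa <- spd$pa
    core_ids <- spd$genes$gene_id[spd$genes$type == "core"]
    sums <- tapply(pa$present, pa$cluster_id, sum)
    expect_true(all(sums[core_ids] == sim$config$n_genomes))
    expect_true(all(pa$present %in% c(0L, 1L)))
  }
})

test_that("reference CDS coordinates cut the reference genome correctly", {
  sim <- small_sim()
  spd <- sim$species$sp1
  ref <- spd$genomes$seq[spd$genomes$genome_id == "sp1_strain01"]
  genes <- setNames(spd$genes$ref_seq, spd$genes$gene_id)
  for (i in seq_len(nrow(spd$cds))) {
    expect_equal(substr(ref, spd$cds$start[i] + 1, spd$cds$end[i]),
                 unname(genes[spd$cds$gene_id[i]]))
  }
})

test_that("realised SNP fraction is within 3 sigma of the binomial", {
  cfg <- sim_config(seed = 6, n_core = 30L, n_accessory = 0L,
                    n_genomes = 2L, snp_rate = 0.02)
  sim <- simulate_pangenome(cfg)
  spd <- sim$species$sp1
  sg <- spd$strain_genes
  ref <- setNames(spd$genes$ref_seq, spd$genes$gene_id)
  mut <- sg[sg$genome_id == "sp1_strain02", ]
  mm <- sum(mapply(function(a, b) {
    sum(charToRaw(a) != charToRaw(b))
  }, mut$seq, ref[mut$gene_id]))
  n_bases <- sum(nchar(mut$seq))
  expect_lt(abs(mm - n_bases * 0.02), 3 * sqrt(n_bases * 0.02 * 0.98))
})

test_that("expression truth plants exact fold changes", {
  cfg0 <- sim_config(seed = 7, n_core = 50L, n_accessory = 0L,
                     de_fraction = 0)
  sim0 <- simulate_expression(simulate_pangenome(cfg0))
  expect_equal(sim0$expression$abundance_A, sim0$expression$abundance_B)

  sim <- small_sim()
  de <- sim$expression[sim$expression$is_de, ]
  expect_true(all(abs(de$abundance_B / de$abundance_A -
                        2^de$true_log2fc) < 1e-12))
  nde <- sim$expression[!sim$expression$is_de, ]
  expect_equal(nde$abundance_A, nde$abundance_B)
})

test_that("baseline abundances follow the configured log-normal", {
  cfg <- sim_config(seed = 8, n_core = 5000L, n_accessory = 0L,
                    n_species = 1L, de_fraction = 0)
  sim <- simulate_expression(simulate_pangenome(cfg))
  m <- mean(log(sim$expression$abundance_A))
  expect_lt(abs(m - cfg$expr_meanlog), 3 * cfg$expr_sdlog / sqrt(5000))
})

test_that("with zero error and background every read overlaps its probe", {
  sim <- small_sim()
  cfg <- sim$config
  cfg$error_rate <- 0
  cfg$background_fraction <- 0
  cfg$n_reads <- 4000L
  panels <- lapply(sim$species, function(spd) {
    ref <- spd$genomes[spd$genomes$genome_id ==
                         paste0(spd$species_id, "_strain01"), ]
    cand <- composition_filter(
      tile_candidates(spd$cds, ref, panel_config(), spd$species_id),
      panel_config())
    design_mip(cand, panel_config(), spd$species_id)
  })
  rr <- simulate_captured_reads(sim, panels, condition = "A", seed = 9,
                                config = cfg)
  expect_equal(nrow(rr$reads), 4000L)
  expect_true(all(rr$truth$origin != "background"))
  bed <- dplyr::bind_rows(lapply(panels, panel_bed))
  bed$probe_id <- sub("/[LR]$", "", bed$name)
  aln <- rr$alignments
  src <- merge(aln, rr$truth, by = "read_id")
  arm <- bed[match(src$origin, bed$probe_id), ]  # left arm rows come first
  overlap <- pmin(src$start + nchar(src$seq), arm$end) -
    pmax(src$start, arm$start)
  expect_true(all(overlap >= 1))
  # cleaned read sequences equal the reference at their placement
  ref_seq <- dplyr::bind_rows(lapply(sim$species, function(s) s$genomes))
  ref_map <- setNames(ref_seq$seq, ref_seq$contig_id)
  ref_reads <- src[src$genome_id %in% c("sp1_strain01", "sp2_strain01"), ]
  expect_true(all(ref_reads$nm == 0))
  idx <- which(ref_reads$nm == 0)[1:50]
  expect_true(all(substr(ref_map[ref_reads$contig_id[idx]],
                         ref_reads$start[idx] + 1,
                         ref_reads$start[idx] + nchar(ref_reads$seq[idx]))
                  == ref_reads$seq[idx]))
})

test_that("read simulation conserves counts and partitions origins", {
  sim <- small_sim()
  panels <- lapply(sim$species, function(spd) {
    ref <- spd$genomes[spd$genomes$genome_id ==
                         paste0(spd$species_id, "_strain01"), ]
    cand <- composition_filter(
      tile_candidates(spd$cds, ref, panel_config(), spd$species_id),
      panel_config())
    design_mip(cand, panel_config(), spd$species_id)
  })
  rr <- simulate_captured_reads(sim, panels, condition = "A", seed = 10)
  expect_equal(nrow(rr$reads), sim$config$n_reads)
  expect_equal(nrow(rr$truth), sim$config$n_reads)
  expect_equal(anyDuplicated(rr$truth$read_id), 0L)
  expect_equal(sum(rr$truth$origin == "background"),
               round(sim$config$background_fraction * sim$config$n_reads))
  # raw MIP reads trim back to the cleaned sequence recorded in the truth
  pp <- preprocess_reads(rr$reads, filter_policy("mip"), min_len = 1)
  m <- match(rr$alignments$read_id, pp$read_id)
  expect_equal(pp$seq[m], rr$alignments$seq)
})

test_that("SPE capture efficiency drops by the per-mismatch penalty", {
  # two probes over one gene; strain 2 carries 2 mismatches under probe 2
  cfg <- sim_config(seed = 11, n_species = 1L, n_core = 1L,
                    n_accessory = 0L, n_genomes = 2L, snp_rate = 0,
                    gene_len = c(400L, 400L), method = "spe",
                    background_fraction = 0, error_rate = 0,
                    n_reads = 50000L, de_fraction = 0)
  sim <- simulate_pangenome(cfg)
  spd <- sim$species$sp1
  # plant 2 mismatches inside [200, 240) of the gene on strain 2
  sg <- spd$strain_genes
  i2 <- which(sg$genome_id == "sp1_strain02")
  b <- strsplit(sg$seq[i2], "")[[1]]
  for (p in c(210, 225)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  sim$species$sp1$strain_genes$seq[i2] <- paste(b, collapse = "")
  sim <- simulate_expression(sim)
  probes <- tibble::tibble(
    probe_id = c("pA", "pB"), species_id = "sp1", gene_id = sg$gene_id[1],
    contig_id = spd$cds$contig_id[1],
    start = spd$cds$start[1] + c(0L, 200L),
    end = spd$cds$start[1] + c(40L, 240L), strand = "+",
    seq = substring(spd$genes$ref_seq[1], c(1, 201), c(40, 240)),
    tm = 60, gc_frac = 0.5, max_run = 2L)
  pan <- tealseq:::new_tealseq_panel(
    "sp1", "spe", probes, tibble::tibble(gene_id = character(),
                                         reason = character()),
    2, tibble::tibble(), panel_config())
  eff <- tealseq:::probe_strain_efficiency(sim, pan, cfg)
  expect_equal(eff$mm[eff$probe_id == "pB" &
                        eff$genome_id == "sp1_strain02"], 2L)
  e_pb <- eff$efficiency[eff$probe_id == "pB" &
                           eff$genome_id == "sp1_strain02"]
  e_pb0 <- eff$efficiency[eff$probe_id == "pB" &
                            eff$genome_id == "sp1_strain01"]
  expect_equal(e_pb / e_pb0, 0.5^2)       # stated penalty model
  # realised counts: strain-2 reads from pB suppressed by ~0.25
  rr <- simulate_captured_reads(sim, pan, condition = "A", seed = 12,
                                config = cfg)
  tab <- table(rr$truth$origin, rr$truth$genome_id)
  ratio_b <- tab["pB", "sp1_strain02"] / tab["pB", "sp1_strain01"]
  n <- tab["pB", "sp1_strain01"]
  expect_lt(abs(ratio_b - 0.25), 3 * sqrt(0.25 / n) * 2)
  # pA unaffected: strains drawn evenly
  ratio_a <- tab["pA", "sp1_strain02"] / tab["pA", "sp1_strain01"]
  expect_lt(abs(ratio_a - 1), 0.2)
})

test_that("MIP efficiency tolerates up to three arm mismatches", {
  cfg <- sim_config(seed = 13, n_species = 1L, n_core = 2L,
                    n_accessory = 0L, n_genomes = 2L, snp_rate = 0,
                    gene_len = c(500L, 500L), method = "mip")
  sim <- simulate_pangenome(cfg)
  spd <- sim$species$sp1
  sg <- spd$strain_genes
  g1 <- spd$genes$gene_id[1]
  i2 <- which(sg$genome_id == "sp1_strain02" & sg$gene_id == g1)
  b <- strsplit(sg$seq[i2], "")[[1]]
  for (p in c(5, 15, 25)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  sim$species$sp1$strain_genes$seq[i2] <- paste(b, collapse = "")
  cand <- composition_filter(
    tile_candidates(spd$cds, spd$genomes[spd$genomes$genome_id ==
                                           "sp1_strain01", ],
                    panel_config(tm_window = c(0, 100)), "sp1"),
    panel_config(tm_window = c(0, 100)))
  pan <- design_mip(cand, panel_config(tm_window = c(0, 100)), "sp1")
  eff <- tealseq:::probe_strain_efficiency(sim, pan, cfg)
  first <- eff[eff$genome_id == "sp1_strain02" & eff$gene_id == g1, ]
  affected <- first[first$mm > 0 & first$mm <= 3, ]
  if (nrow(affected) > 0) {
    expect_true(all(affected$efficiency == 1))   # mm <= 3: no penalty
  }
  expect_true(all(eff$efficiency[eff$mm > 3] == 0))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 14, n_core = 6L, n_accessory = 2L,
                    n_genomes = 2L, host_n_tx = 5L, n_reads = 500L)
  run <- function(dir) {
    sim <- simulate_expression(simulate_pangenome(cfg))
    write_sim(sim, dir)
    spd <- sim$species$sp1
    cand <- composition_filter(
      tile_candidates(spd$cds, spd$genomes[spd$genomes$genome_id ==
                                             "sp1_strain01", ],
                      panel_config(), "sp1"),
      panel_config())
    pan <- design_mip(cand, panel_config(), "sp1")
    rr <- simulate_captured_reads(sim, pan, condition = "A", seed = 15)
    write_fastq(rr$reads, file.path(dir, "reads.fastq"))
    write_sam(rr$alignments, rr$ref_contigs, file.path(dir, "truth.sam"))
    dir
  }
  d1 <- run(withr::local_tempdir())
  d2 <- run(withr::local_tempdir())
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
})

test_that("probe CPM tracks true abundance", {
  # zero SNP rate isolates the proportionality of the capture model:
  # every probe then has unit efficiency and CPM ~ abundance exactly in
  # expectation (strain variants modulate efficiency by design and are
  # exercised in the mismatch-sensitivity tests above)
  cfg <- sim_config(seed = 17, n_core = 40L, n_accessory = 0L,
                    n_genomes = 2L, snp_rate = 0, host_n_tx = 10L,
                    n_reads = 30000L, background_fraction = 0.3)
  sim <- simulate_expression(simulate_pangenome(cfg))
  panels <- lapply(sim$species, function(spd) {
    ref <- spd$genomes[spd$genomes$genome_id ==
                         paste0(spd$species_id, "_strain01"), ]
    cand <- composition_filter(
      tile_candidates(spd$cds, ref, panel_config(), spd$species_id),
      panel_config())
    design_mip(cand, panel_config(), spd$species_id)
  })
  rr <- simulate_captured_reads(sim, panels, condition = "A", seed = 16,
                                config = cfg)
  on <- rr$truth[rr$truth$origin != "background", ]
  probe_map <- dplyr::bind_rows(lapply(panels, function(p) {
    tibble::tibble(probe_id = p$probes$probe_id,
                   gene_id = p$probes$gene_id,
                   species_id = p$species_id)
  }))
  counts <- dplyr::count(on, origin, name = "count") |>
    dplyr::rename(probe_id = "origin") |>
    dplyr::right_join(probe_map, by = "probe_id") |>
    dplyr::mutate(count = dplyr::coalesce(count, 0L),
                  sample_id = "s1")
  counts <- cpm_normalize(counts)
  ab <- sim$expression$abundance_A[match(counts$gene_id,
                                         sim$expression$gene_id)]
  for (sp in unique(counts$species_id)) {
    keep <- counts$species_id == sp & counts$count > 0
    expect_gt(cor(counts$cpm[keep], ab[keep]), 0.95)
  }
})
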