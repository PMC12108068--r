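# a single-contig genome wrapping the given CDS sequences with spacers
design_fixture <- function(gene_seqs, spacer = 50L) {
  ids <- sprintf("g%02d", seq_along(gene_seqs))
  sp <- strrep("T", spacer)
  contig <- paste0(sp, paste0(gene_seqs, sp, collapse = ""))
  starts <- spacer + cumsum(c(0L, head(nchar(gene_seqs), -1) + spacer))
  list(
    genome = tibble::tibble(genome_id = "ref", contig_id = "c1",
                            seq = contig, length = nchar(contig)),
    cds = tibble::tibble(contig_id = "c1", start = starts,
                         end = starts + nchar(gene_seqs), strand = "+",
                         gene_id = ids, product = NA_character_))
}

test_that("tiling yields one candidate per start per strand, excluding N", {
  withr::with_seed(21, gene <- o_random_dna(1, 40))
  fx <- design_fixture(gene)
  cand <- tile_candidates(fx$cds, fx$genome, panel_config())
  expect_equal(nrow(cand), 2)           # length-40 CDS: one start, 2 strands
  expect_setequal(cand$strand, c("+", "-"))
  expect_equal(unique(cand$end - cand$start), 40L)

  withr::with_seed(22, gene <- o_random_dna(1, 45))
  fx <- design_fixture(gene)
  cand <- tile_candidates(fx$cds, fx$genome, panel_config())
  expect_equal(nrow(cand), 12)          # 6 starts x 2 strands

  gene_n <- paste0(substr(gene, 1, 20), "N", substr(gene, 22, 45))
  fx <- design_fixture(gene_n)
  cand_n <- tile_candidates(fx$cds, fx$genome, panel_config())
  expect_equal(nrow(cand_n), 0)         # every window covers the N

  expect_warning(
    tile_candidates(
      tibble::tibble(contig_id = "c1", start = 0L, end = 30L, strand = "+",
                     gene_id = "short", product = NA),
      fx$genome, panel_config()),
    "shorter than probe length")
})

test_that("candidate sequences match the reference on their strand", {
  withr::with_seed(23, gene <- o_random_dna(1, 60))
  fx <- design_fixture(gene)
  cand <- tile_candidates(fx$cds, fx$genome, panel_config())
  for (i in seq_len(nrow(cand))) {
    window <- substr(fx$genome$seq, cand$start[i] + 1, cand$end[i])
    expected <- if (cand$strand[i] == "+") window else o_revcomp(window)
    expect_equal(cand$seq[i], expected)
  }
})

test_that("composition filter enforces the homopolymer boundary", {
  base <- "ACGTACGTACGTACGTACGTACGTACGTACGTAC"  # 34 bases, no long runs
  run6 <- paste0("AAAAAA", base)   # run of exactly 6: allowed
  run7 <- paste0("AAAAAAA", substr(base, 1, 33))  # run of 7: rejected
  cand <- tibble::tibble(
    probe_id = c("p6", "p7"), species_id = "sp", gene_id = "g",
    contig_id = "c1", start = c(0L, 0L), end = c(40L, 40L), strand = "+",
    seq = c(run6, run7),
    tm = c(60, 60), gc_frac = 0.5,
    max_run = c(6L, 7L))
  out <- composition_filter(cand, panel_config(tm_window = c(0, 100)))
  expect_true(out$pass[out$probe_id == "p6"])
  expect_false(out$pass[out$probe_id == "p7"])
  expect_match(out$filter_flags[out$probe_id == "p7"], "homopolymer")
})

test_that("composition filter trims melting-temperature extremes", {
  cand <- tibble::tibble(
    probe_id = paste0("p", 1:3), species_id = "sp", gene_id = "g",
    contig_id = "c1", start = 0L, end = 40L, strand = "+",
    seq = strrep("ACGT", 10), tm = c(40, 60, 90), gc_frac = 0.5,
    max_run = 1L)
  out <- composition_filter(cand, panel_config(tm_window = c(50, 80)))
  expect_equal(out$filter_flags, c("tm_low", "", "tm_high"))
  # percentile mode trims the stated tails of the candidate distribution
  withr::with_seed(24, tms <- rnorm(100, 65, 5))
  cand100 <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:100), species_id = "sp", gene_id = "g",
    contig_id = "c1", start = 0L, end = 40L, strand = "+",
    seq = strrep("ACGT", 10), tm = tms, gc_frac = 0.5, max_run = 1L)
  out <- composition_filter(cand100,
                            panel_config(tm_percentile = c(0.05, 0.95)))
  lo <- quantile(tms, 0.05); hi <- quantile(tms, 0.95)
  expect_equal(out$pass, tms >= lo & tms <= hi)
})

test_that("spacing selection reproduces known optima and is greedy-optimal", {
  mk <- function(starts) tibble::tibble(
    probe_id = sprintf("p%03d", seq_along(starts)), species_id = "sp",
    gene_id = "g", contig_id = "c1", start = as.integer(starts),
    end = as.integer(starts) + 40L, strand = "+",
    seq = strrep("ACGT", 10), tm = 60, gc_frac = 0.5, max_run = 1L,
    pass = TRUE, filter_flags = "")
  cfg <- panel_config(max_probes_per_cds = 100L)
  p <- assemble_panel(mk(c(0, 50, 120, 260)), cfg)
  expect_equal(nrow(p$probes), 3)       # brute force confirms max = 3
  expect_equal(o_best_spaced_size(c(0, 50, 120, 260), 100), 3)
  p <- assemble_panel(mk(42), cfg)
  expect_equal(nrow(p$probes), 1)
  p <- assemble_panel(mk(c(0, 30, 60, 99)), cfg)
  expect_equal(nrow(p$probes), 1)       # all within 99 bases

  withr::with_seed(25, {
    for (rep in 1:20) {
      starts <- sort(sample.int(600, sample(3:12, 1)))
      got <- nrow(assemble_panel(mk(starts), cfg)$probes)
      expect_equal(got, o_best_spaced_size(starts, 100),
                   info = paste(starts, collapse = ","))
    }
  })
})

test_that("the per-gene budget keeps the most Tm-central probes", {
  starts <- c(0L, 150L, 300L, 450L, 600L, 750L)
  tms <- c(55, 80, 60, 61, 62, 40)
  cand <- tibble::tibble(
    probe_id = sprintf("p%d", 1:6), species_id = "sp", gene_id = "g",
    contig_id = "c1", start = starts, end = starts + 40L, strand = "+",
    seq = strrep("ACGT", 10), tm = tms, gc_frac = 0.5, max_run = 1L,
    pass = TRUE, filter_flags = "")
  p <- assemble_panel(cand, panel_config(max_probes_per_cds = 3L))
  expect_equal(nrow(p$probes), 3)
  med <- median(tms)
  kept_dev <- abs(p$probes$tm - med)
  dropped <- setdiff(cand$probe_id, p$probes$probe_id)
  expect_true(max(kept_dev) <=
                min(abs(cand$tm[cand$probe_id %in% dropped] - med)))
})

test_that("genes without passing candidates are reported uncovered", {
  cand <- tibble::tibble(
    probe_id = "p1", species_id = "sp", gene_id = "gA",
    contig_id = "c1", start = 0L, end = 40L, strand = "+",
    seq = strrep("ACGT", 10), tm = 60, gc_frac = 0.5, max_run = 1L,
    pass = FALSE, filter_flags = "homopolymer")
  p <- assemble_panel(cand, panel_config(), target_genes = c("gA", "gB"))
  expect_equal(nrow(p$probes), 0)
  expect_setequal(p$uncovered$gene_id, c("gA", "gB"))
})

test_that("MIP pairing honours the configured gap and spacing", {
  mk_arm <- function(starts) tibble::tibble(
    probe_id = sprintf("a%03d", seq_along(starts)), species_id = "sp",
    gene_id = "g", contig_id = "c1", start = as.integer(starts),
    end = as.integer(starts) + 40L, strand = "+",
    seq = strrep("ACGT", 10), tm = 60, gc_frac = 0.5, max_run = 1L,
    pass = TRUE, filter_flags = "")
  cfg <- panel_config(mip_gap_len = 120L, mip_gap_tol = 10L)
  p <- design_mip(mk_arm(c(0, 160)), cfg)
  expect_equal(nrow(p$probes), 1)
  expect_equal(p$probes$gap_start, 40L)
  expect_equal(p$probes$gap_end, 160L)
  expect_equal(p$probes$gap_end - p$probes$gap_start, 120L)

  p <- design_mip(mk_arm(c(0, 60)), cfg,
                  target_genes = "g")   # no pair within tolerance
  expect_equal(nrow(p$probes), 0)
  expect_equal(p$uncovered$gene_id, "g")
})

test_that("greedy MIP pairing matches the exhaustive matching oracle", {
  cfg <- panel_config(mip_gap_len = 120L, mip_gap_tol = 10L,
                      max_probes_per_cds = 100L)
  withr::with_seed(26, {
    for (rep in 1:25) {
      starts <- sort(sample.int(900, sample(4:10, 1)))
      arms <- tibble::tibble(
        probe_id = sprintf("a%03d", seq_along(starts)), species_id = "sp",
        gene_id = "g", contig_id = "c1", start = as.integer(starts),
        end = as.integer(starts) + 40L, strand = "+",
        seq = strrep("ACGT", 10), tm = 60, gc_frac = 0.5, max_run = 1L,
        pass = TRUE, filter_flags = "")
      got <- nrow(design_mip(arms, cfg)$probes)
      want <- o_max_mip_pairs(starts, starts + 40L, 110, 130, 100)
      expect_equal(got, want, info = paste(starts, collapse = ","))
    }
  })
})

test_that("panel summaries count probes per gene and coverage", {
  probes <- tibble::tibble(
    probe_id = paste0("p", 1:5), species_id = "sp",
    gene_id = c("g1", "g2", "g2", "g3", "g3"),
    contig_id = "c1", start = c(0L, 0L, 150L, 0L, 150L),
    end = c(40L, 40L, 190L, 40L, 190L), strand = "+",
    seq = strrep("ACGT", 10), tm = 60, gc_frac = 0.5, max_run = 1L)
  pan <- tealseq:::new_tealseq_panel(
    "sp", "spe", probes, tibble::tibble(gene_id = character(),
                                        reason = character()),
    5, tibble::tibble(), panel_config())
  s <- panel_summary(pan)
  expect_equal(s$histogram,
               tibble::tibble(n_probes = c(1L, 2L), n_genes = c(1L, 2L)))
  expect_equal(s$coverage, 1)
  expect_equal(panel_summary(pan, target_genes = paste0("g", 1:6))$coverage,
               0.5)
  empty <- tealseq:::new_tealseq_panel(
    "sp", "spe", probes[0, ], tibble::tibble(gene_id = "g1",
                                             reason = "none"),
    0, tibble::tibble(), panel_config())
  expect_equal(panel_summary(empty)$coverage, 0)
})

test_that("panel design is a pure function of inputs and config", {
  sim <- small_sim()
  spd <- sim$species$sp1
  ref <- spd$genomes[spd$genomes$genome_id == "sp1_strain01", ]
  run <- function() {
    design_panel(ref, spd$cds, panel_config(), architecture = "mip",
                 include_genomes = spd$genomes,
                 host = sim$host, species_id = "sp1")
  }
  p1 <- run(); p2 <- run()
  expect_identical(p1$probes, p2$probes)
  expect_identical(p1$uncovered, p2$uncovered)
})
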