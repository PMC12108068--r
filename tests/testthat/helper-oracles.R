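# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (Biostrings scans, seeded search, phyper, ...):
# plain-R enumeration and vector arithmetic only.

# reverse complement without Biostrings
o_revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# all ungapped full-length placements of `seq` with Hamming distance
# <= max_mm over both strands of every contig: sliding-window scan done
# with k-shift vector comparisons
o_scan_hits <- function(seq, genomes, max_mm) {
  plen <- nchar(seq)
  out <- list()
  for (r in seq_len(nrow(genomes))) {
    sb <- strsplit(genomes$seq[r], "", fixed = TRUE)[[1]]
    L <- length(sb)
    if (L < plen) next
    n_win <- L - plen + 1L
    for (strand in c("+", "-")) {
      p <- if (strand == "+") seq else o_revcomp(seq)
      pb <- strsplit(p, "", fixed = TRUE)[[1]]
      mm <- integer(n_win)
      for (k in seq_len(plen)) {
        mm <- mm + (sb[k:(n_win + k - 1L)] != pb[k])
      }
      hit <- which(mm <= max_mm)
      if (length(hit) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          genome_id = genomes$genome_id[r],
          contig_id = genomes$contig_id[r],
          start = hit - 1L, strand = strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(genome_id = character(), contig_id = character(),
                      start = integer(), strand = character(),
                      mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$genome_id, res$contig_id, res$start, res$strand), ,
      drop = FALSE]
}

# maximum matched bases of `seq` over all ungapped local alignments
# against any transcript, either strand, including partial end overlaps
o_host_max_match <- function(seq, host) {
  plen <- nchar(seq)
  best <- 0L
  for (t in seq_len(nrow(host))) {
    padded <- c(rep(".", plen - 1L),
                strsplit(host$seq[t], "", fixed = TRUE)[[1]],
                rep(".", plen - 1L))
    L <- length(padded)
    n_win <- L - plen + 1L
    for (p in c(seq, o_revcomp(seq))) {
      pb <- strsplit(p, "", fixed = TRUE)[[1]]
      match_count <- integer(n_win)
      for (k in seq_len(plen)) {
        match_count <- match_count + (padded[k:(n_win + k - 1L)] == pb[k])
      }
      best <- max(best, max(match_count))
    }
  }
  best
}

# maximum-cardinality subset of starts with pairwise distance >= spacing,
# by exhaustive bitmask enumeration (n <= 20)
o_best_spaced_size <- function(starts, spacing) {
  n <- length(starts)
  stopifnot(n <= 20)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- sort(starts[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L])
    if (length(sel) < 2 || all(diff(sel) >= spacing)) {
      best <- max(best, length(sel))
    }
  }
  best
}

# maximum number of MIPs formable from arms (start/end sorted ascending):
# disjoint arm pairs with gap in [gap_lo, gap_hi] and left-arm starts of
# chosen pairs >= spacing apart; exhaustive recursion (n <= 10)
o_max_mip_pairs <- function(starts, ends, gap_lo, gap_hi, spacing) {
  n <- length(starts)
  recurse <- function(used, lefts) {
    best <- 0L
    for (i in seq_len(n)) {
      if (used[i]) next
      if (any(abs(starts[i] - lefts) < spacing)) next
      for (j in seq_len(n)) {
        if (used[j] || j == i) next
        gap <- starts[j] - ends[i]
        if (gap < gap_lo || gap > gap_hi) next
        u2 <- used; u2[c(i, j)] <- TRUE
        best <- max(best, 1L + recurse(u2, c(lefts, starts[i])))
      }
    }
    best
  }
  recurse(rep(FALSE, n), numeric(0))
}

# upper-tail hypergeometric P(X >= k) by direct enumeration
o_hyper_p <- function(N, K, n, k) {
  i <- k:min(K, n)
  i <- i[i >= max(0, n - (N - K))]
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
# (distinct values assumed)
o_wilcox_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  stat <- function(idx) sum(rank(pooled)[idx]) - nx * (nx + 1) / 2
  obs <- stat(seq_len(nx))
  combos <- utils::combn(length(pooled), nx)
  ws <- apply(combos, 2, stat)
  p_le <- mean(ws <= obs)
  p_ge <- mean(ws >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up closed form
o_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  adj[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(adj, 1)
}

# random DNA helper for fixtures
o_random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# one small shared simulation, built once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_core = 15L, n_accessory = 5L,
                        n_genomes = 3L, host_n_tx = 20L, n_reads = 20000L,
                        off_n_species = 1L, off_n_genomes = 2L)
      s <- simulate_pangenome(cfg)
      cache <<- simulate_expression(s)
    }
    cache
  }
})
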