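#' Mismatch-tolerant probe placement search
#'
#' Finds every ungapped full-length placement of each probe on either strand
#' of a genome set with Hamming distance at most `max_mismatches`. The scan
#' evaluates the mismatch count at every offset (C-level, via
#' `Biostrings::neditStartingAt`), so completeness holds by construction; an
#' independent sliding-window oracle re-derives the same hit set in the test
#' suite. `N` bases in the subject never match, so masked sequence cannot
#' create spurious hits.
#'
#' @param probes Character vector of probe sequences (optionally named), or
#'   a tibble with `probe_id` and `seq` columns.
#' @param genomes Genome tibble ([read_genome_fasta()]; may hold several
#'   `genome_id`s).
#' @param max_mismatches Maximum Hamming distance reported.
#' @param max_hits_per_genome Reporting cap per probe per genome, bounding
#'   pathological low-complexity cases; capped (probe, genome) pairs are
#'   listed in the `capped` attribute of the result.
#' @return Tibble with columns `probe_id`, `genome_id`, `contig_id`,
#'   `start` (0-based), `strand`, `mismatches`.
#' @export
find_hits <- function(probes, genomes, max_mismatches = 4L,
                      max_hits_per_genome = 1000L) {
  probes <- .as_probe_tbl(probes)
  out <- list()
  capped <- list()
  for (g in unique(genomes$genome_id)) {
    contigs <- genomes[genomes$genome_id == g, , drop = FALSE]
    subjects <- lapply(contigs$seq, Biostrings::DNAString)
    names(subjects) <- contigs$contig_id
    for (p in seq_len(nrow(probes))) {
      hits <- .scan_probe(probes$seq[p], subjects, max_mismatches)
      if (nrow(hits) > max_hits_per_genome) {
        hits <- hits[seq_len(max_hits_per_genome), , drop = FALSE]
        capped[[length(capped) + 1L]] <-
          tibble::tibble(probe_id = probes$probe_id[p], genome_id = g)
      }
      if (nrow(hits) > 0) {
        hits$probe_id <- probes$probe_id[p]
        hits$genome_id <- g
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  res <- if (length(out) > 0) {
    dplyr::bind_rows(out) |>
      dplyr::select("probe_id", "genome_id", "contig_id", "start",
                    "strand", "mismatches") |>
      dplyr::arrange(.data$probe_id, .data$genome_id, .data$contig_id,
                     .data$start, .data$strand)
  } else {
    tibble::tibble(probe_id = character(), genome_id = character(),
                   contig_id = character(), start = integer(),
                   strand = character(), mismatches = integer())
  }
  attr(res, "capped") <- dplyr::bind_rows(capped)
  res
}

# mismatch count of `pattern` at every full-length offset of each subject,
# both strands; returns tibble(contig_id, start, strand, mismatches)
.scan_probe <- function(seq, subjects, max_mismatches) {
  pat_f <- Biostrings::DNAString(seq)
  pat_r <- Biostrings::reverseComplement(pat_f)
  plen <- length(pat_f)
  res <- list()
  for (cid in names(subjects)) {
    subj <- subjects[[cid]]
    L <- length(subj)
    if (L < plen) next
    starts <- seq_len(L - plen + 1L)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      nm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                        with.indels = FALSE, fixed = TRUE)
      hit <- which(nm <= max_mismatches)
      if (length(hit) > 0) {
        res[[length(res) + 1L]] <- tibble::tibble(
          contig_id = cid, start = hit - 1L, strand = strand,
          mismatches = as.integer(nm[hit]))
      }
    }
  }
  if (length(res) == 0) {
    tibble::tibble(contig_id = character(), start = integer(),
                   strand = character(), mismatches = integer())
  } else {
    dplyr::bind_rows(res)
  }
}

.as_probe_tbl <- function(probes) {
  if (is.character(probes)) {
    ids <- names(probes) %||% sprintf("probe_%04d", seq_along(probes))
    ids[!nzchar(ids)] <- sprintf("probe_%04d", which(!nzchar(ids)))
    return(tibble::tibble(probe_id = ids, seq = unname(probes)))
  }
  stopifnot(all(c("probe_id", "seq") %in% names(probes)))
  tibble::as_tibble(probes[, c("probe_id", "seq")])
}

#' Inclusion screen: perfect match in enough target genomes
#'
#' A probe passes when at least `min_genomes` distinct genomes contain at
#' least one perfect (zero-mismatch) full-length placement on either
#' strand — the within-species prevalence requirement on the probe itself.
#' Several perfect hits in one genome count once.
#'
#' @inheritParams find_hits
#' @param min_genomes Minimum number of genomes with a perfect hit.
#' @return Tibble `probe_id`, `seq`, `n_genomes_perfect`, `pass`.
#' @export
inclusion_screen <- function(probes, genomes, min_genomes) {
  probes <- .as_probe_tbl(probes)
  gids <- unique(genomes$genome_id)
  n_perfect <- integer(nrow(probes))
  for (g in gids) {
    contigs <- genomes[genomes$genome_id == g, , drop = FALSE]
    subjects <- lapply(contigs$seq, Biostrings::DNAString)
    names(subjects) <- contigs$contig_id
    for (p in seq_len(nrow(probes))) {
      if (.has_hit(probes$seq[p], subjects, 0L)) {
        n_perfect[p] <- n_perfect[p] + 1L
      }
    }
  }
  tibble::tibble(probe_id = probes$probe_id, seq = probes$seq,
                 n_genomes_perfect = n_perfect,
                 pass = n_perfect >= min_genomes)
}

# early-exit existence test for a hit with <= max_mismatches
.has_hit <- function(seq, subjects, max_mismatches) {
  pat_f <- Biostrings::DNAString(seq)
  pat_r <- Biostrings::reverseComplement(pat_f)
  plen <- length(pat_f)
  for (subj in subjects) {
    L <- length(subj)
    if (L < plen) next
    starts <- seq_len(L - plen + 1L)
    for (pat in list(pat_f, pat_r)) {
      nm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                        with.indels = FALSE, fixed = TRUE)
      if (any(nm <= max_mismatches)) return(TRUE)
    }
  }
  FALSE
}

# Bulk perfect-match inclusion verdict for many probes at once via an exact
# PDict lookup against each genome (either strand). Equivalent to
# inclusion_screen() probe by probe, asserted in the test suite.
.inclusion_pass_bulk <- function(seqs, genomes, min_genomes) {
  if (length(seqs) == 0) return(logical(0))
  widths <- unique(nchar(seqs))
  stopifnot(length(widths) == 1)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
  n_genomes <- integer(length(seqs))
  for (g in unique(genomes$genome_id)) {
    contigs <- genomes[genomes$genome_id == g, , drop = FALSE]
    present <- logical(length(seqs))
    for (cs in contigs$seq) {
      subj <- Biostrings::DNAString(cs)
      present <- present |
        (Biostrings::countPDict(pd, subj) > 0) |
        (Biostrings::countPDict(pd, Biostrings::reverseComplement(subj)) > 0)
      if (all(present)) break
    }
    n_genomes <- n_genomes + present
  }
  n_genomes >= min_genomes
}

# Concatenate many sequences into one search subject with N separators of
# the probe length, so no window can span two sequences; segment bounds are
# kept so seeded window starts can be restricted to real placements.
.make_search_subject <- function(seqs, plen) {
  sep <- strrep("N", plen)
  lens <- nchar(seqs)
  starts <- cumsum(c(0L, head(lens + plen, -1L)))  # 0-based segment starts
  list(seq = paste(seqs, collapse = sep), seg_start = starts,
       seg_end = starts + lens, plen = plen, n = length(seqs))
}

# Pigeonhole seed-and-verify existence test for a hit with <= max_mm
# mismatches: split the probe into max_mm + 1 disjoint exact seeds (at
# least one must match exactly in any qualifying window), locate seeds with
# fixed-string search over the concatenated subject, verify the implied
# in-segment windows by Hamming distance. Completeness vs the full scan is
# asserted in the test suite.
.has_hit_seeded <- function(seq, subject, max_mm) {
  if (!is.list(subject)) {
    subject <- .make_search_subject(subject, nchar(seq))
  }
  plen <- nchar(seq)
  n_seeds <- max_mm + 1L
  k <- plen %/% n_seeds
  offs <- (seq_len(n_seeds) - 1L) * k  # 0-based seed offsets within probe
  subj <- subject$seq
  for (probe in c(seq, revcomp(seq))) {
    seeds <- substring(probe, offs + 1L, offs + k)
    praw <- charToRaw(probe)
    for (si in seq_len(n_seeds)) {
      m <- gregexpr(seeds[si], subj, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      wstart <- (as.integer(m) - 1L) - offs[si]  # 0-based window starts
      wstart <- wstart[wstart >= 0L]
      if (length(wstart) == 0) next
      seg <- findInterval(wstart, subject$seg_start)
      ok <- wstart + plen <= subject$seg_end[seg]
      for (w in unique(wstart[ok])) {
        if (sum(charToRaw(substr(subj, w + 1L, w + plen)) != praw)
            <= max_mm) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Exclusion screen: no near-match in off-target genomes
#'
#' A probe fails when any off-target placement with at most
#' `max_mismatches` mismatches exists (default 4: placements with fewer
#' than five mismatches to an alternative species disqualify a probe). The
#' offending hit is reported. Off-target matching is ungapped full-length
#' Hamming; a 40-mer hit with four or fewer mismatches is effectively
#' ungapped, and gapped off-target alignments are out of scope.
#'
#' @inheritParams find_hits
#' @return Tibble `probe_id`, `seq`, `pass`, and `hit_*` columns describing
#'   the first offending placement (`NA` when passing).
#' @export
exclusion_screen <- function(probes, genomes, max_mismatches = 4L) {
  probes <- .as_probe_tbl(probes)
  # fast seeded existence test first; the full scan then documents the
  # offending hit only for the (typically few) failing probes
  subject <- if (nrow(probes) > 0) {
    .make_search_subject(genomes$seq, nchar(probes$seq[1]))
  }
  fails <- vapply(probes$seq, .has_hit_seeded, logical(1),
                  subject = subject, max_mm = max_mismatches,
                  USE.NAMES = FALSE)
  hits <- find_hits(probes[fails, , drop = FALSE], genomes,
                    max_mismatches = max_mismatches,
                    max_hits_per_genome = 1L)
  first_hit <- hits |>
    dplyr::slice_head(n = 1, by = "probe_id") |>
    dplyr::rename(hit_genome_id = "genome_id", hit_contig_id = "contig_id",
                  hit_start = "start", hit_strand = "strand",
                  hit_mismatches = "mismatches")
  probes |>
    dplyr::left_join(first_hit, by = "probe_id") |>
    dplyr::mutate(pass = is.na(.data$hit_mismatches)) |>
    dplyr::select("probe_id", "seq", "pass", dplyr::starts_with("hit_"))
}

#' Host-transcriptome cross-reactivity screen
#'
#' Computes, for each probe, the maximum number of matched bases over all
#' ungapped local alignments against any host transcript on either strand
#' (mismatches inside the alignment are allowed but not counted as matches;
#' partial overlaps at transcript ends are considered). A probe fails when
#' that maximum reaches `max_match_bases + 1` — with the defaults, probes
#' must have fewer than 25 of their 40 bases matching the host
#' transcriptome.
#'
#' @inheritParams find_hits
#' @param host Host transcript tibble with `contig_id` (transcript ID) and
#'   `seq` columns (e.g. from [read_genome_fasta()]).
#' @param max_match_bases Largest tolerated matched-base count.
#' @return Tibble `probe_id`, `seq`, `max_match_bases`, `transcript_id`
#'   (a transcript attaining the maximum; `NA` when the host set is empty),
#'   `pass`.
#' @export
host_screen <- function(probes, host, max_match_bases = 24L) {
  probes <- .as_probe_tbl(probes)
  if (is.null(host) || nrow(host) == 0) {
    return(tibble::tibble(probe_id = probes$probe_id, seq = probes$seq,
                          max_match_bases = 0L,
                          transcript_id = NA_character_, pass = TRUE))
  }
  plens <- nchar(probes$seq)
  plen <- unique(plens)
  stopifnot(length(plen) == 1)
  # One concatenated subject with N separators of the probe length: N never
  # matches, so every partial end overlap scores exactly its overlapping
  # identical bases, and no window can combine two transcripts.
  pad <- strrep("N", plen)
  subject <- .make_search_subject(host$seq, plen)
  subj <- Biostrings::DNAString(paste0(pad, subject$seq, pad))
  starts <- seq_len(length(subj) - plen + 1L)
  best <- integer(nrow(probes))
  best_tx <- rep(NA_character_, nrow(probes))
  for (p in seq_len(nrow(probes))) {
    pat_f <- Biostrings::DNAString(probes$seq[p])
    pat_r <- Biostrings::reverseComplement(pat_f)
    for (pat in list(pat_f, pat_r)) {
      nm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                        with.indels = FALSE, fixed = TRUE)
      i <- which.min(nm)
      m <- plen - nm[i]
      if (m > best[p]) {
        best[p] <- m
        # locate the transcript owning the best window (window start in the
        # unpadded concatenation, clamped into its segment)
        w0 <- (i - 1L) - plen  # 0-based start in unpadded subject
        seg <- max(1L, findInterval(w0 + plen - 1L, subject$seg_start))
        best_tx[p] <- host$contig_id[seg]
      }
    }
  }
  thr <- max_match_bases
  tibble::tibble(probe_id = probes$probe_id, seq = probes$seq,
                 max_match_bases = best, transcript_id = best_tx,
                 pass = best <= thr)
}

#' Run all specificity screens and write a report
#'
#' @inheritParams find_hits
#' @param include_genomes,exclude_genomes,host Genome/transcript tibbles
#'   for the three screens; any may be `NULL` to skip.
#' @param min_genomes Inclusion threshold (default: all inclusion genomes).
#' @param max_mismatches Exclusion threshold.
#' @param max_match_bases Host threshold.
#' @return Long tibble `probe_id`, `screen`, `pass`, `evidence`.
#' @export
screen_report <- function(probes, include_genomes = NULL,
                          exclude_genomes = NULL, host = NULL,
                          min_genomes = NULL, max_mismatches = 4L,
                          max_match_bases = 24L) {
  probes <- .as_probe_tbl(probes)
  rows <- list()
  if (!is.null(include_genomes)) {
    min_g <- min_genomes %||% dplyr::n_distinct(include_genomes$genome_id)
    inc <- inclusion_screen(probes, include_genomes, min_g)
    rows$inclusion <- tibble::tibble(
      probe_id = inc$probe_id, screen = "inclusion", pass = inc$pass,
      evidence = sprintf("perfect in %d genome(s), need %d",
                         inc$n_genomes_perfect, min_g))
  }
  if (!is.null(exclude_genomes)) {
    exc <- exclusion_screen(probes, exclude_genomes, max_mismatches)
    rows$exclusion <- tibble::tibble(
      probe_id = exc$probe_id, screen = "exclusion", pass = exc$pass,
      evidence = ifelse(exc$pass, "no off-target hit",
                        sprintf("hit %s:%s@%d (%s) with %d mismatch(es)",
                                exc$hit_genome_id, exc$hit_contig_id,
                                exc$hit_start, exc$hit_strand,
                                exc$hit_mismatches)))
  }
  if (!is.null(host)) {
    hs <- host_screen(probes, host, max_match_bases)
    rows$host <- tibble::tibble(
      probe_id = hs$probe_id, screen = "host", pass = hs$pass,
      evidence = sprintf("max %d matched base(s)%s", hs$max_match_bases,
                         ifelse(is.na(hs$transcript_id), "",
                                paste0(" vs ", hs$transcript_id))))
  }
  dplyr::bind_rows(rows)
}
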