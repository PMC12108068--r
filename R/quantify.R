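#' Alignment filter policy per targeting method
#'
#' Encodes the method-specific quality filters: alignments are kept only
#' with MAPQ strictly above `min_mapq` and NM strictly below `max_nm`.
#' SPE probe alignments demand a perfect match (NM < 1), MIP probe
#' alignments tolerate up to two mismatches (NM < 3), and genome (bulk)
#' alignments up to three (NM < 4). Both bounds are exclusive.
#'
#' @param method `"spe"`, `"mip"` or `"genome"`.
#' @param min_mapq Exclusive MAPQ lower bound.
#' @param max_nm Exclusive NM upper bound; defaults to the method rule.
#' @return List of class `tealseq_filter_policy`.
#' @export
filter_policy <- function(method = c("spe", "mip", "genome"),
                          min_mapq = 30L, max_nm = NULL) {
  method <- match.arg(method)
  max_nm <- max_nm %||% switch(method, spe = 1L, mip = 3L, genome = 4L)
  structure(list(method = method, min_mapq = as.integer(min_mapq),
                 max_nm = as.integer(max_nm),
                 trim_rule = if (method == "mip") "fixed5" else "bait"),
            class = "tealseq_filter_policy")
}

#' Trim raw reads according to the method's rule
#'
#' SPE and bulk reads are truncated at the first occurrence of the bait
#' adapter sequence (`AGATCGGAAGAG`) through the 3' end; MIP reads lose a
#' fixed five bases from their 5' end. Reads shorter than `min_len` after
#' trimming are discarded and tallied.
#'
#' @param reads Tibble with `read_id` and `seq` columns, or a character
#'   vector of sequences.
#' @param policy A [filter_policy()] (its `trim_rule` selects the rule).
#' @param bait Bait adapter sequence for SPE/bulk trimming.
#' @param mip_trim Number of 5' bases removed for MIP.
#' @param min_len Minimum post-trim read length.
#' @return Tibble `read_id`, `seq` of retained trimmed reads; the number of
#'   discarded reads is in the `n_discarded` attribute.
#' @export
preprocess_reads <- function(reads, policy = filter_policy("mip"),
                             bait = "AGATCGGAAGAG", mip_trim = 5L,
                             min_len = 30L) {
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = sprintf("read_%06d", seq_along(reads)), seq = reads)
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)),
            inherits(policy, "tealseq_filter_policy"))
  trimmed <- if (policy$trim_rule == "fixed5") {
    substring(reads$seq, mip_trim + 1L)
  } else {
    pos <- regexpr(bait, reads$seq, fixed = TRUE)
    ifelse(pos > 0, substring(reads$seq, 1L, pos - 1L), reads$seq)
  }
  keep <- nchar(trimmed) >= min_len
  out <- tibble::tibble(read_id = reads$read_id[keep], seq = trimmed[keep])
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Filter alignments on mapping quality and edit distance
#'
#' Keeps records with `mapq > min_mapq` and `nm < max_nm` (both strict, so
#' MAPQ exactly 30 and, for SPE, NM of 1 are rejected). Rejections are
#' tallied by reason in the `rejections` attribute.
#'
#' @param alignments Tibble from [read_alignments()].
#' @param policy A [filter_policy()].
#' @return The kept alignment rows; attribute `rejections` is a tibble
#'   `reason`, `n` (a record failing both filters counts under both).
#' @export
filter_alignments <- function(alignments, policy) {
  stopifnot(inherits(policy, "tealseq_filter_policy"),
            all(c("mapq", "nm") %in% names(alignments)))
  low_mapq <- !(alignments$mapq > policy$min_mapq)
  high_nm <- !(alignments$nm < policy$max_nm)
  out <- alignments[!low_mapq & !high_nm, , drop = FALSE]
  attr(out, "rejections") <- tibble::tibble(
    reason = c("mapq", "nm"), n = c(sum(low_mapq), sum(high_nm)))
  out
}

#' Count filtered reads over probe intervals
#'
#' Coverage-style counting: a read increments a probe when its aligned span
#' overlaps the probe interval by at least one base (half-open intervals; a
#' read ending exactly where a probe starts does not overlap). A read
#' overlapping two probes increments both. For MIP panels the BED carries
#' one row per binding arm (`/L`, `/R`); arm counts are summed into a
#' single per-probe count.
#'
#' @param alignments Kept alignment tibble ([filter_alignments()]).
#' @param bed Probe BED6 tibble ([panel_bed()] or [read_probe_bed()]).
#' @return Tibble `probe_id`, `count`, one row per probe in the BED (arm
#'   rows collapsed), including zero counts.
#' @export
count_probe_coverage <- function(alignments, bed) {
  stopifnot(all(c("contig_id", "start", "end", "name") %in% names(bed)))
  probe_gr <- GenomicRanges::GRanges(
    seqnames = bed$contig_id,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end))
  if (nrow(alignments) > 0) {
    aln_gr <- GenomicRanges::GRanges(
      seqnames = alignments$contig_id,
      ranges = IRanges::IRanges(start = alignments$start + 1L,
                                end = alignments$end))
    n <- GenomicRanges::countOverlaps(probe_gr, aln_gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  } else {
    n <- rep(0L, nrow(bed))
  }
  tibble::tibble(probe_id = sub("/[LR]$", "", bed$name), count = n) |>
    dplyr::summarise(count = sum(.data$count), .by = "probe_id")
}

#' CPM-normalise a probe count table
#'
#' Scales raw probe counts to counts per million within each
#' (sample, species) stratum: `cpm = 1e6 * r / R`, where `R` is the total
#' count of the sample restricted to that species' probes. The two species
#' of a mixed panel are normalised independently. Strata with zero total
#' yield all-zero CPM and are flagged.
#'
#' @param counts Long tibble with columns `probe_id`, `sample_id`,
#'   `species_id`, `count`.
#' @return The input with `cpm` added; zero-total strata are listed in the
#'   `zero_total` attribute (and a warning is raised).
#' @export
cpm_normalize <- function(counts) {
  stopifnot(all(c("probe_id", "sample_id", "species_id", "count")
                %in% names(counts)))
  out <- counts |>
    dplyr::mutate(total = sum(.data$count),
                  .by = c("sample_id", "species_id")) |>
    dplyr::mutate(cpm = ifelse(.data$total > 0,
                               1e6 * .data$count / .data$total, 0)) |>
    dplyr::select(-"total")
  zero <- counts |>
    dplyr::summarise(total = sum(.data$count),
                     .by = c("sample_id", "species_id")) |>
    dplyr::filter(.data$total == 0)
  if (nrow(zero) > 0) {
    warning(nrow(zero), " (sample, species) stratum/strata with zero mapped",
            " reads: CPM set to 0")
  }
  attr(out, "zero_total") <- zero
  out
}

#' RPKM for CDS-level counts
#'
#' `rpkm = count / (total_mapped / 1e6) / (cds_length / 1000)` — reads per
#' kilobase of CDS per million mapped reads, the bulk RNA-seq summary used
#' alongside probe CPM.
#'
#' @param counts Tibble with `gene_id`, `sample_id`, `count`.
#' @param cds_lengths Tibble with `gene_id`, `length` (bases).
#' @param totals Optional tibble `sample_id`, `total` of mapped reads per
#'   sample; defaults to the per-sample sum of `count`.
#' @return The input with `length` and `rpkm` columns added.
#' @export
rpkm <- function(counts, cds_lengths, totals = NULL) {
  stopifnot(all(c("gene_id", "sample_id", "count") %in% names(counts)),
            all(c("gene_id", "length") %in% names(cds_lengths)),
            all(cds_lengths$length > 0))
  if (is.null(totals)) {
    totals <- dplyr::summarise(counts, total = sum(.data$count),
                               .by = "sample_id")
  }
  if (any(totals$total <= 0)) {
    stop("zero total mapped reads for sample(s): ",
         paste(totals$sample_id[totals$total <= 0], collapse = ", "))
  }
  counts |>
    dplyr::left_join(dplyr::select(cds_lengths, "gene_id", "length"),
                     by = "gene_id") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(rpkm = .data$count / (.data$total / 1e6) /
                    (.data$length / 1000)) |>
    dplyr::select(-"total")
}

#' Quantify one sample's SAM against a probe panel
#'
#' Convenience composition of the per-sample pipeline: read the SAM, apply
#' the method's MAPQ/NM filters, and count coverage over the panel BED.
#'
#' @param sam_path Path to the sample's alignments (SAM).
#' @param panel A `tealseq_panel` or BED6 tibble.
#' @param policy A [filter_policy()].
#' @return Tibble `probe_id`, `count`; attributes `n_mapped` (records read)
#'   and `n_kept` (records surviving the filters).
#' @export
quantify_sample <- function(sam_path, panel, policy = filter_policy("mip")) {
  bed <- if (inherits(panel, "tealseq_panel")) panel_bed(panel) else panel
  aln <- read_alignments(sam_path)
  kept <- filter_alignments(aln, policy)
  out <- count_probe_coverage(kept, bed)
  attr(out, "n_mapped") <- nrow(aln)
  attr(out, "n_kept") <- nrow(kept)
  out
}
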