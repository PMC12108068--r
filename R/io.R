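#' Read genome sequences from FASTA
#'
#' Sequences are uppercased and any character outside `A`, `C`, `G`, `T` is
#' collapsed to `N`. Probes are synthesised oligos and must be fully
#' specified, so downstream candidate windows containing `N` are rejected
#' rather than interpreted.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Identifier recorded for every contig in the file;
#'   defaults to the file name without extension.
#' @return A tibble with columns `genome_id`, `contig_id`, `seq`, `length`.
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  .validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate contig IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tibble::tibble(
    genome_id = genome_id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path)),
    contig_id = ids,
    seq = unname(seqs),
    length = unname(nchar(seqs))
  )
}

.validate_fasta_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("FASTA parse error in ", path, ": file is empty (line 1)")
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop("FASTA parse error in ", path, ": line ", first,
         " does not start a '>' header")
  }
  hdr <- which(startsWith(lines, ">"))
  empty_hdr <- hdr[!nzchar(trimws(substring(lines[hdr], 2)))]
  if (length(empty_hdr) > 0) {
    stop("FASTA parse error in ", path, ": empty header at line ", empty_hdr[1])
  }
  # a header immediately followed by another header (or EOF) has no sequence
  nxt <- c(hdr[-1] - 1, length(lines))
  for (i in seq_along(hdr)) {
    body <- lines[setdiff(seq(hdr[i] + 1, max(hdr[i], nxt[i])), hdr)]
    if (hdr[i] >= length(lines) || !any(nzchar(trimws(body)))) {
      stop("FASTA parse error in ", path, ": contig at line ", hdr[i],
           " has no sequence")
    }
  }
  invisible(TRUE)
}

#' Write genome sequences to FASTA
#'
#' @param genomes A tibble with `contig_id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  stopifnot(all(c("contig_id", "seq") %in% names(genomes)))
  set <- Biostrings::DNAStringSet(setNames(genomes$seq, genomes$contig_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read CDS features from GFF3
#'
#' Keeps only rows of type `CDS` and converts the 1-based inclusive GFF3
#' interval to the package's internal 0-based half-open convention. Strand is
#' mandatory: an unstranded CDS cannot be tiled with strand-specific probes.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `product`.
#' @export
read_cds_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in ", path, ": ",
                             conditionMessage(e))
  )
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(gr) == 0) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          gene_id = character(), product = character()))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop("GFF3 parse error in ", path, ": CDS rows without strand")
  }
  mc <- S4Vectors::mcols(gr)
  pick <- function(...) {
    for (nm in c(...)) {
      if (nm %in% names(mc) && !all(is.na(mc[[nm]]))) return(as.character(mc[[nm]]))
    }
    rep(NA_character_, length(gr))
  }
  gene_id <- pick("ID", "locus_tag", "gene", "Name")
  gene_id[is.na(gene_id)] <- paste0("cds_", which(is.na(gene_id)))
  tibble::tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    gene_id = gene_id,
    product = pick("product")
  )
}

#' Write CDS features to GFF3
#'
#' @param cds A tibble as returned by [read_cds_gff3()] (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_gff3 <- function(cds, path) {
  stopifnot(all(c("contig_id", "start", "end", "strand", "gene_id") %in% names(cds)))
  gr <- GenomicRanges::GRanges(
    seqnames = cds$contig_id,
    ranges = IRanges::IRanges(start = cds$start + 1L, end = cds$end),
    strand = cds$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- cds$gene_id
  if ("product" %in% names(cds)) S4Vectors::mcols(gr)$product <- cds$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Minimal alignment reader for the quantification pipeline: unmapped records
#' are skipped, secondary and supplementary records are dropped (multi-mapped
#' reads are resolved by the upstream aligner's primary alignment), and the
#' aligner-reported `NM` edit-distance tag is required on every mapped record
#' because all downstream filters are defined on `NM`, never on a recomputed
#' edit distance.
#'
#' @param path Path to a SAM file (text, with `@SQ` header lines).
#' @return A tibble with columns `read_id`, `contig_id`, `start`, `end`
#'   (0-based half-open reference span), `strand`, `mapq`, `nm`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("qname", "mapq"), tag = "NM",
                                   flag = flags)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  mc <- S4Vectors::mcols(aln)
  nm <- mc$NM
  if (length(aln) > 0 && anyNA(nm)) {
    stop("SAM record(s) without NM tag in ", path,
         " (e.g. read ", mc$qname[which(is.na(nm))[1]],
         "); aligner output incompatible with NM-based filtering")
  }
  tibble::tibble(
    read_id = as.character(mc$qname),
    contig_id = as.character(GenomicAlignments::seqnames(aln)),
    start = BiocGenerics::start(aln) - 1L,
    end = BiocGenerics::end(aln),
    strand = as.character(BiocGenerics::strand(aln)),
    mapq = as.integer(mc$mapq),
    nm = as.integer(nm)
  )
}

#' Write alignments to a SAM file
#'
#' Companion writer used by the read simulator: emits a minimal valid SAM
#' with `@SQ` lines, one `<n>M` CIGAR per mapped read and `NM:i:` tags.
#' Records with `NA` contig are written as unmapped (FLAG 4).
#'
#' @param alignments Tibble with columns `read_id`, `contig_id`, `start`
#'   (0-based), `strand`, `mapq`, `nm`, `seq`.
#' @param contigs Tibble with `contig_id` and `length` for the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contigs, path) {
  stopifnot(all(c("read_id", "contig_id", "start", "strand", "mapq",
                  "nm", "seq") %in% names(alignments)))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id,
                   as.integer(contigs$length)))
  mapped <- !is.na(alignments$contig_id)
  qual <- strrep("I", nchar(alignments$seq))
  rec <- character(nrow(alignments))
  rec[mapped] <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
    alignments$read_id[mapped],
    ifelse(alignments$strand[mapped] == "-", 16L, 0L),
    alignments$contig_id[mapped],
    alignments$start[mapped] + 1L,
    as.integer(alignments$mapq[mapped]),
    nchar(alignments$seq[mapped]),
    alignments$seq[mapped],
    qual[mapped],
    as.integer(alignments$nm[mapped])
  )
  rec[!mapped] <- sprintf(
    "%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
    alignments$read_id[!mapped], alignments$seq[!mapped], qual[!mapped]
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a probe panel as BED6
#'
#' Emits one row per SPE probe. A MIP probe contributes two rows — its
#' binding arms — sharing the probe ID with `/L` and `/R` suffixes. The
#' score column carries no meaning and is written as 0. Coordinates are
#' native BED (0-based half-open), identical to the internal convention.
#'
#' @param panel A `tealseq_panel` (see [assemble_panel()], [design_mip()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(panel, path) {
  bed <- panel_bed(panel)
  if (nrow(bed) == 0) stop("refusing to write an empty probe panel to ", path)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' BED6 representation of a panel
#'
#' @inheritParams write_probe_bed
#' @return Tibble with BED6 columns `contig_id`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
panel_bed <- function(panel) {
  probes <- if (inherits(panel, "tealseq_panel")) panel$probes else panel
  if (is.null(probes) || nrow(probes) == 0) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), name = character(),
                          score = integer(), strand = character()))
  }
  if (all(c("left_start", "right_start") %in% names(probes))) {
    dplyr::bind_rows(
      tibble::tibble(contig_id = probes$contig_id, start = probes$left_start,
                     end = probes$left_end,
                     name = paste0(probes$probe_id, "/L"),
                     score = 0L, strand = probes$strand),
      tibble::tibble(contig_id = probes$contig_id, start = probes$right_start,
                     end = probes$right_end,
                     name = paste0(probes$probe_id, "/R"),
                     score = 0L, strand = probes$strand)
    ) |> dplyr::arrange(.data$contig_id, .data$start)
  } else {
    tibble::tibble(contig_id = probes$contig_id, start = probes$start,
                   end = probes$end, name = probes$probe_id,
                   score = 0L, strand = probes$strand) |>
      dplyr::arrange(.data$contig_id, .data$start)
  }
}

#' Read a BED6 probe file
#'
#' @param path Path to a BED6 file written by [write_probe_bed()].
#' @return Tibble with columns `contig_id`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_probe_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("contig_id", "start", "end", "name",
                                "score", "strand"),
                  col_types = "ciicic", progress = FALSE)
}

#' Read or write FASTQ reads
#'
#' @param path Path to a FASTQ file.
#' @return `read_fastq()` returns a tibble with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub("\\s.*$", "", names(set)),
                 seq = unname(as.character(set)))
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id` and `seq` columns (all-`I` qualities
#'   are written; quality simulation is out of scope).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$seq,
                           "+",
                           strrep("I", nchar(reads$seq))))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a file against its expected format
#'
#' Light-weight validation used by the command-line `io validate`
#' subcommand: attempts to parse the file with the matching reader.
#'
#' @param path File path.
#' @param format One of `"fasta"`, `"gff3"`, `"sam"`, `"bed"`, `"fastq"`,
#'   `"yaml"`; guessed from the extension when omitted.
#' @return `TRUE` invisibly on success; otherwise the reader's error.
#' @export
io_validate <- function(path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
    fa = , fna = , fasta = "fasta",
    gff = , gff3 = "gff3",
    sam = "sam",
    bed = "bed",
    fq = , fastq = "fastq",
    yml = , yaml = "yaml",
    stop("cannot guess format of ", path)
  )
  switch(format,
    fasta = read_genome_fasta(path),
    gff3 = read_cds_gff3(path),
    sam = read_alignments(path),
    bed = read_probe_bed(path),
    fastq = read_fastq(path),
    yaml = read_panel_config(path)
  )
  invisible(TRUE)
}
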