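#' Read a pangenome presence/absence matrix (Rtab dialect)
#'
#' Consumes the tab-separated gene_presence_absence Rtab produced by
#' pangenome pipelines: first column the gene-cluster ID, one 0/1 column per
#' genome. Paralogs (several members of one cluster in one genome) are
#' collapsed to presence = 1; the prevalence filter is per genome.
#'
#' @param path Path to an Rtab file.
#' @return A long tibble with columns `cluster_id`, `genome_id`, `present`
#'   (integer 0/1).
#' @export
read_presence_absence <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(wide) < 2) stop("Rtab parse error in ", path, ": need >=2 columns")
  names(wide)[1] <- "cluster_id"
  if (anyDuplicated(wide$cluster_id)) {
    stop("duplicate cluster IDs in ", path)
  }
  long <- tidyr::pivot_longer(wide, -"cluster_id",
                              names_to = "genome_id", values_to = "present")
  long$present <- as.integer(long$present > 0)
  long
}

#' Write a presence/absence tibble as Rtab
#'
#' @param pa Long tibble from [read_presence_absence()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_absence <- function(pa, path) {
  wide <- tidyr::pivot_wider(pa, names_from = "genome_id",
                             values_from = "present", values_fill = 0L)
  names(wide)[1] <- "Gene"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Select core target gene clusters by pangenome prevalence
#'
#' Retains exactly the clusters present in at least `min_genomes` genomes —
#' the prevalence rule used to nominate targets (e.g. present in at least
#' 50 of 86 *S. epidermidis* or 30 of 51 *S. aureus* genomes). Output order
#' is deterministic (by `cluster_id`).
#'
#' @param pa Long presence/absence tibble (`cluster_id`, `genome_id`,
#'   `present`).
#' @param min_genomes Minimum number of genomes a cluster must appear in.
#' @return A tibble with columns `cluster_id`, `n_genomes` (prevalence),
#'   `n_total` (genomes in the matrix), sorted by `cluster_id`.
#' @export
select_core_targets <- function(pa, min_genomes) {
  stopifnot(all(c("cluster_id", "genome_id", "present") %in% names(pa)))
  n_total <- dplyr::n_distinct(pa$genome_id)
  if (min_genomes < 1 || min_genomes > n_total) {
    stop("min_genomes must be in [1, ", n_total, "], got ", min_genomes)
  }
  pa |>
    dplyr::summarise(n_genomes = sum(.data$present > 0),
                     .by = "cluster_id") |>
    dplyr::filter(.data$n_genomes >= min_genomes) |>
    dplyr::mutate(n_total = n_total) |>
    dplyr::arrange(.data$cluster_id)
}

#' Map selected clusters to reference-genome CDS intervals
#'
#' The pangenome names clusters; probes are designed on intervals of a
#' chosen reference strain. The bridge is an explicit cluster-to-gene table
#' because cluster naming conventions vary between pipelines. Clusters with
#' no reference gene are reported, never silently dropped; a cluster mapping
#' to several reference genes keeps all intervals.
#'
#' @param targets Tibble from [select_core_targets()].
#' @param cds Reference CDS tibble from [read_cds_gff3()].
#' @param cluster_map Tibble with columns `cluster_id`, `gene_id` linking
#'   clusters to reference gene IDs. When `NULL`, `cluster_id` is assumed to
#'   equal `gene_id`.
#' @return A tibble with one row per (cluster, reference CDS) pair:
#'   `cluster_id`, `n_genomes`, `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, plus a `mapped` logical; unmapped clusters have `NA`
#'   coordinates and are counted in a warning.
#' @export
map_targets_to_reference <- function(targets, cds, cluster_map = NULL) {
  if (nrow(targets) == 0) {
    warning("empty target set: nothing to map")
    return(tibble::tibble(cluster_id = character(), n_genomes = integer(),
                          gene_id = character(), contig_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), mapped = logical()))
  }
  if (is.null(cluster_map)) {
    cluster_map <- tibble::tibble(cluster_id = targets$cluster_id,
                                  gene_id = targets$cluster_id)
  }
  stopifnot(all(c("cluster_id", "gene_id") %in% names(cluster_map)))
  out <- targets |>
    dplyr::select("cluster_id", "n_genomes") |>
    dplyr::left_join(cluster_map, by = "cluster_id",
                     relationship = "many-to-many") |>
    dplyr::left_join(
      dplyr::select(cds, "gene_id", "contig_id", "start", "end", "strand"),
      by = "gene_id", relationship = "many-to-many") |>
    dplyr::mutate(mapped = !is.na(.data$start))
  n_unmapped <- dplyr::n_distinct(out$cluster_id[!out$mapped])
  if (n_unmapped > 0) {
    warning(n_unmapped, " target cluster(s) have no reference CDS mapping; ",
            "kept with NA coordinates (filter on `mapped`)")
  }
  multi <- out |>
    dplyr::filter(.data$mapped) |>
    dplyr::count(.data$cluster_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    message(nrow(multi), " cluster(s) map to multiple reference CDS; ",
            "all intervals kept")
  }
  out
}
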