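#' Panel design configuration
#'
#' Collects every tunable of the probe-design and screening stages in one
#' validated object. Defaults encode the panel rules used throughout:
#' 40-base probes, at least 100 bases between probe starts within a gene,
#' homopolymer runs of more than 6 bases rejected, off-target hits with 4 or
#' fewer mismatches rejected, and host matches of 25 or more of 40 bases
#' rejected.
#'
#' @param probe_len Probe (or MIP arm) length in bases.
#' @param min_spacing Minimum distance between starts of accepted probes
#'   within one gene, in bases.
#' @param max_homopolymer Longest tolerated single-base run; longer runs fail
#'   the composition filter.
#' @param tm_percentile Length-2 numeric in `[0,1]`: candidates whose melting
#'   temperature falls below/above these per-species quantiles fail. Ignored
#'   when `tm_window` is given.
#' @param tm_window Optional absolute melting-temperature window `c(low, high)`
#'   in degrees Celsius overriding the percentile rule.
#' @param inclusion_min_genomes Minimum number of target genomes that must
#'   contain a perfect probe match (`NULL` = 60% of the genomes supplied,
#'   rounded up, mirroring the majority-prevalence rule used for target
#'   gene selection).
#' @param exclusion_max_mismatches Off-target placements with at most this
#'   many mismatches disqualify a probe.
#' @param host_max_match_bases Probes matching at least
#'   `host_max_match_bases + 1` of their bases to a host transcript fail; the
#'   default 24 keeps probes with fewer than 25 of 40 bases matching.
#' @param max_probes_per_cds Per-gene probe budget applied after spacing
#'   optimisation.
#' @param mip_gap_len,mip_gap_tol Target gap between MIP arms and the
#'   tolerated deviation, in bases.
#' @param na_mM Monovalent cation concentration for the melting-temperature
#'   model, in mM.
#' @param oligo_conc_M Total oligo concentration for the melting-temperature
#'   model, in mol/L.
#'
#' @return A list of class `tealseq_config`.
#' @seealso [design_panel()], [melting_temperature()]
#' @export
panel_config <- function(probe_len = 40L,
                         min_spacing = 100L,
                         max_homopolymer = 6L,
                         tm_percentile = c(0.05, 0.95),
                         tm_window = NULL,
                         inclusion_min_genomes = NULL,
                         exclusion_max_mismatches = 4L,
                         host_max_match_bases = 24L,
                         max_probes_per_cds = 4L,
                         mip_gap_len = 120L,
                         mip_gap_tol = 10L,
                         na_mM = 50,
                         oligo_conc_M = 250e-12) {
  stopifnot(probe_len > 0, min_spacing >= 0, max_homopolymer >= 1,
            exclusion_max_mismatches < probe_len,
            host_max_match_bases >= 0, host_max_match_bases <= probe_len,
            max_probes_per_cds >= 1, mip_gap_len >= 0, mip_gap_tol >= 0)
  if (!is.null(tm_window)) {
    stopifnot(length(tm_window) == 2, tm_window[1] <= tm_window[2])
  } else {
    stopifnot(length(tm_percentile) == 2,
              tm_percentile[1] >= 0, tm_percentile[2] <= 1,
              tm_percentile[1] <= tm_percentile[2])
  }
  structure(list(
    probe_len = as.integer(probe_len),
    min_spacing = as.integer(min_spacing),
    max_homopolymer = as.integer(max_homopolymer),
    tm_percentile = tm_percentile,
    tm_window = tm_window,
    inclusion_min_genomes = inclusion_min_genomes,
    exclusion_max_mismatches = as.integer(exclusion_max_mismatches),
    host_max_match_bases = as.integer(host_max_match_bases),
    max_probes_per_cds = as.integer(max_probes_per_cds),
    mip_gap_len = as.integer(mip_gap_len),
    mip_gap_tol = as.integer(mip_gap_tol),
    na_mM = na_mM,
    oligo_conc_M = oligo_conc_M
  ), class = "tealseq_config")
}

#' Read or write a panel configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_panel_config()` returns a `tealseq_config`;
#'   `write_panel_config()` returns `path` invisibly.
#' @export
read_panel_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(panel_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown panel_config fields in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  do.call(panel_config, vals)
}

#' @rdname read_panel_config
#' @param config A `tealseq_config` object.
#' @export
write_panel_config <- function(config, path) {
  stopifnot(inherits(config, "tealseq_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' @export
print.tealseq_config <- function(x, ...) {
  cat("<tealseq panel config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
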