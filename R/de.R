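#' Probe-level differential expression (negative-binomial Wald test)
#'
#' Fits, per probe, a negative-binomial GLM of raw counts on the condition
#' factor (optionally with a covariate and its interaction, e.g. an
#' amplification-protocol indicator), using log library-size offsets, a
#' method-of-moments dispersion estimate with a small-sample floor, and a
#' Wald test on the condition main effect. P-values are
#' Benjamini-Hochberg adjusted across all tested probes. The reported
#' `log2fc` is computed from library-size-normalised counts with a
#' pseudocount of 0.5, robust to zero groups.
#'
#' This engine is deliberately simpler than shrinkage-based DE frameworks:
#' no dispersion shrinkage, no fold-change moderation. Its acceptance
#' surface is recovery of planted effects in simulation, not coefficient
#' parity with any particular framework.
#'
#' @param counts Long tibble `probe_id`, `gene_id`, `sample_id`, `count`
#'   (integer raw counts, one species at a time — per-species
#'   normalisation happens upstream).
#' @param samples Sample sheet tibble `sample_id`, `condition` (2 levels;
#'   the second level is tested against the first), optional `covariate`.
#' @param min_disp Dispersion floor (the method-of-moments estimate is
#'   noisy at n = 3; the floor keeps Wald SEs honest).
#' @param max_disp Dispersion ceiling.
#' @return A `tealseq_de` object; `tidy()` returns the probe table
#'   (`probe_id`, `gene_id`, `base_mean`, `log2fc`, `se`, `stat`, `p`,
#'   `adj_p`), `glance()` a one-row summary. Probes with all-zero counts
#'   are excluded and listed in `$excluded`.
#' @export
probe_de <- function(counts, samples, min_disp = 0.01, max_disp = 10) {
  stopifnot(all(c("probe_id", "gene_id", "sample_id", "count")
                %in% names(counts)),
            all(c("sample_id", "condition") %in% names(samples)))
  samples <- dplyr::mutate(
    samples, condition = factor(.data$condition))
  if (nlevels(samples$condition) != 2) {
    stop("condition must have exactly 2 levels")
  }
  if (min(table(samples$condition)) < 2) {
    stop("need at least 2 samples per condition")
  }
  has_cov <- "covariate" %in% names(samples) &&
    dplyr::n_distinct(samples$covariate) > 1
  wide <- counts |>
    dplyr::select("probe_id", "gene_id", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  mat <- as.matrix(wide[, samples$sample_id, drop = FALSE])
  rownames(mat) <- wide$probe_id
  lib <- colSums(mat)
  if (any(lib == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(samples$sample_id[lib == 0], collapse = ", "))
  }
  all_zero <- rowSums(mat) == 0
  excluded <- tibble::tibble(probe_id = wide$probe_id[all_zero],
                             gene_id = wide$gene_id[all_zero],
                             reason = "all-zero counts")
  keep <- which(!all_zero)
  norm <- sweep(mat, 2, mean(lib) / lib, `*`)
  cond <- samples$condition
  is_b <- cond == levels(cond)[2]
  df_fit <- data.frame(condition = cond, off = log(lib))
  form <- count ~ condition
  if (has_cov) {
    df_fit$covariate <- factor(samples$covariate)
    form <- count ~ condition * covariate
  }
  res <- purrr::map(keep, function(i) {
    y <- mat[i, ]
    disp <- .mom_dispersion(norm[i, ], cond, min_disp, max_disp)
    df_fit$count <- y
    fit <- tryCatch(
      suppressWarnings(glm(form, data = df_fit,
                           family = MASS::negative.binomial(theta = 1 / disp),
                           offset = df_fit$off)),
      error = function(e) NULL)
    coef_name <- paste0("condition", levels(cond)[2])
    if (is.null(fit) || !coef_name %in% names(coef(fit)) ||
        is.na(coef(fit)[coef_name])) {
      beta <- NA_real_; se <- NA_real_
    } else {
      beta <- unname(coef(fit)[coef_name])
      # dispersion = 1: overdispersion is carried by theta, not by a
      # Pearson scale factor on top of it
      sm <- summary(fit, dispersion = 1)
      se <- sm$coefficients[coef_name, "Std. Error"]
    }
    stat <- beta / se
    tibble::tibble(
      probe_id = wide$probe_id[i], gene_id = wide$gene_id[i],
      base_mean = mean(norm[i, ]),
      log2fc = log2((mean(norm[i, is_b]) + 0.5) /
                      (mean(norm[i, !is_b]) + 0.5)),
      disp = disp, se = unname(se), stat = unname(stat),
      p = 2 * pnorm(-abs(stat)))
  })
  probes <- dplyr::bind_rows(res)
  probes$adj_p <- p.adjust(probes$p, method = "BH")
  structure(list(probes = probes, excluded = excluded,
                 condition_levels = levels(cond), has_covariate = has_cov,
                 n_samples = nrow(samples)),
            class = "tealseq_de")
}

# method-of-moments NB dispersion pooled across condition groups:
# var = mu + disp * mu^2  =>  disp = (var - mu) / mu^2
.mom_dispersion <- function(z, cond, min_disp, max_disp) {
  ests <- vapply(split(z, cond), function(v) {
    m <- mean(v)
    if (m <= 0 || length(v) < 2) return(NA_real_)
    (var(v) - m) / m^2
  }, numeric(1))
  d <- mean(ests, na.rm = TRUE)
  if (!is.finite(d)) d <- min_disp
  min(max(d, min_disp), max_disp)
}

#' @export
tidy.tealseq_de <- function(x, ...) x$probes

#' @export
glance.tealseq_de <- function(x, ...) {
  tibble::tibble(n_probes = nrow(x$probes),
                 n_excluded = nrow(x$excluded),
                 n_samples = x$n_samples,
                 comparison = paste(rev(x$condition_levels), collapse = " vs "),
                 median_dispersion = median(x$probes$disp))
}

#' @export
print.tealseq_de <- function(x, ...) {
  cat(sprintf("<tealseq probe-level DE> %d probes, %s%s\n",
              nrow(x$probes),
              paste(rev(x$condition_levels), collapse = " vs "),
              if (x$has_covariate) " (with covariate interaction)" else ""))
  invisible(x)
}

#' Median-of-probes gene aggregation and DEG calling
#'
#' Collapses probe-level results to genes using the median (interpolated
#' for even probe counts) of the probe log2 fold changes and of the
#' adjusted p-values — robust against outlier values from probes with poor
#' performance. A gene is called `up` iff its median log2FC strictly
#' exceeds `lfc_thresh` and its median adjusted p is strictly below
#' `p_thresh` (`down` symmetric; otherwise `ns`). Defaults implement the
#' |median probe log2FC| > 2, median adjusted p < 0.05 rule (a fold-change
#' magnitude of 4 is the same threshold on the log2 scale).
#'
#' @param de A `tealseq_de` object or its `tidy()` probe tibble.
#' @param lfc_thresh Log2 fold-change threshold (strict).
#' @param p_thresh Adjusted-p threshold (strict).
#' @return Tibble `gene_id`, `n_probes`, `median_log2fc`, `median_adj_p`,
#'   `call` (`"up"`, `"down"`, `"ns"`).
#' @export
aggregate_genes <- function(de, lfc_thresh = 2, p_thresh = 0.05) {
  probes <- if (inherits(de, "tealseq_de")) de$probes else de
  stopifnot(all(c("gene_id", "log2fc", "adj_p") %in% names(probes)))
  probes |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      median_log2fc = median(.data$log2fc),
      median_adj_p = median(.data$adj_p),
      .by = "gene_id") |>
    dplyr::mutate(call = dplyr::case_when(
      .data$median_log2fc > lfc_thresh & .data$median_adj_p < p_thresh ~ "up",
      .data$median_log2fc < -lfc_thresh & .data$median_adj_p < p_thresh ~ "down",
      .default = "ns")) |>
    dplyr::arrange(.data$gene_id)
}

#' Hypergeometric over-representation test for gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realised overlap between a query set (e.g. genes called up by the
#' targeted assay) and a reference set (e.g. genes up in a published bulk
#' study) drawn from a common universe, with a Bonferroni multiplier for
#' the number of set comparisons in the batch.
#'
#' @param query,reference Character vectors, both subsets of `universe`.
#' @param universe Character vector of all testable genes.
#' @param n_comparisons Bonferroni family size (number of directional set
#'   comparisons performed together).
#' @return One-row tibble `N`, `K`, `n`, `k`, `p_hyper`, `p_bonferroni`.
#' @export
overrep_test <- function(query, reference, universe, n_comparisons = 1L) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query); reference <- unique(reference)
  if (!all(query %in% universe) || !all(reference %in% universe)) {
    stop("query and reference must be subsets of the universe")
  }
  N <- length(universe); K <- length(reference); n <- length(query)
  k <- length(intersect(query, reference))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(N = N, K = K, n = n, k = k, p_hyper = p,
                 p_bonferroni = min(1, p * n_comparisons))
}

#' Batch of directional over-representation tests
#'
#' @param comparisons Named list; each element a list with `query` and
#'   `reference` character vectors.
#' @param universe Common gene universe.
#' @return Tibble with one row per comparison; the Bonferroni family size
#'   is the number of comparisons in the batch.
#' @export
overrep_batch <- function(comparisons, universe) {
  m <- length(comparisons)
  purrr::imap(comparisons, function(cmp, nm) {
    dplyr::mutate(
      overrep_test(cmp$query, cmp$reference, universe, n_comparisons = m),
      comparison = nm, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Compare protocol-induced distortion by sum of squared errors
#'
#' For each comparison, computes per-CDS squared differences of
#' `log2(value + 1)` between paired samples, and tests whether one
#' comparison's squared-error distribution is stochastically smaller than
#' the other's with a two-sided Wilcoxon rank-sum test (exact for group
#' sizes up to 25 without ties; normal approximation with tie correction
#' otherwise).
#'
#' @param expr Long tibble `gene_id`, `sample_id`, `value` (CPM or RPKM).
#' @param pairs_a,pairs_b Tibbles with columns `x`, `y` naming paired
#'   sample IDs for the two comparisons.
#' @param labels Length-2 character labels for the comparisons.
#' @param log2p1 Transform values as `log2(value + 1)` before differencing
#'   (set `FALSE` when the table already holds log-scale profiles).
#' @return A `tealseq_sse` object: `errors` (per-CDS squared errors, long),
#'   `sse` (total per comparison), `wilcoxon_p`.
#' @export
sse_compare <- function(expr, pairs_a, pairs_b,
                        labels = c("A", "B"), log2p1 = TRUE) {
  stopifnot(all(c("gene_id", "sample_id", "value") %in% names(expr)),
            all(c("x", "y") %in% names(pairs_a)),
            all(c("x", "y") %in% names(pairs_b)))
  err <- function(pairs, label) {
    purrr::pmap(pairs, function(x, y, ...) {
      a <- expr[expr$sample_id == x, c("gene_id", "value")]
      b <- expr[expr$sample_id == y, c("gene_id", "value")]
      shared <- dplyr::inner_join(a, b, by = "gene_id",
                                  suffix = c("_x", "_y"))
      if (nrow(shared) == 0) {
        stop("samples ", x, " and ", y, " share no CDS")
      }
      vx <- if (log2p1) log2(shared$value_x + 1) else shared$value_x
      vy <- if (log2p1) log2(shared$value_y + 1) else shared$value_y
      tibble::tibble(
        comparison = label, pair = paste(x, y, sep = "|"),
        gene_id = shared$gene_id,
        sq_err = (vx - vy)^2)
    }) |> dplyr::bind_rows()
  }
  errors <- dplyr::bind_rows(err(pairs_a, labels[1]), err(pairs_b, labels[2]))
  sse <- dplyr::summarise(errors, sse = sum(.data$sq_err),
                          .by = "comparison")
  ea <- errors$sq_err[errors$comparison == labels[1]]
  eb <- errors$sq_err[errors$comparison == labels[2]]
  exact <- length(ea) <= 25 && length(eb) <= 25
  wt <- suppressWarnings(
    wilcox.test(ea, eb, alternative = "two.sided", exact = exact,
                correct = TRUE))
  structure(list(errors = errors, sse = sse, wilcoxon_p = wt$p.value,
                 labels = labels),
            class = "tealseq_sse")
}

#' @export
print.tealseq_sse <- function(x, ...) {
  cat("<tealseq SSE comparison>\n")
  print(x$sse)
  cat(sprintf("two-sided Wilcoxon p = %.4g\n", x$wilcoxon_p))
  invisible(x)
}

#' @export
tidy.tealseq_sse <- function(x, ...) x$errors

#' @export
glance.tealseq_sse <- function(x, ...) {
  tidyr::pivot_wider(x$sse, names_from = "comparison", values_from = "sse",
                     names_prefix = "sse_") |>
    dplyr::mutate(wilcoxon_p = x$wilcoxon_p)
}

#' Pairwise Pearson correlation and correlation-space distances
#'
#' Computes pairwise Pearson correlation coefficients between samples on
#' `log2(value + 1)` profiles, the corresponding test p-values, and the
#' Euclidean distance between rows of the correlation matrix (samples that
#' correlate similarly with everything cluster together).
#'
#' @param expr Long tibble `gene_id`, `sample_id`, `value`.
#' @param log2p1 Transform values as `log2(value + 1)` first?
#' @return A `tealseq_cor` object with `r`, `p` and `dist` matrices;
#'   zero-variance samples yield `NA` correlations and are listed in
#'   `degenerate`.
#' @export
cor_matrix <- function(expr, log2p1 = TRUE) {
  stopifnot(all(c("gene_id", "sample_id", "value") %in% names(expr)))
  wide <- tidyr::pivot_wider(expr[, c("gene_id", "sample_id", "value")],
                             names_from = "sample_id",
                             values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (log2p1) m <- log2(m + 1)
  ok <- complete.cases(m)
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 shared observations per pair")
  s <- colnames(m)
  degenerate <- s[apply(m, 2, function(v) var(v) == 0)]
  r <- matrix(NA_real_, length(s), length(s), dimnames = list(s, s))
  p <- r
  for (i in seq_along(s)) {
    for (j in seq_len(i)) {
      if (s[i] %in% degenerate || s[j] %in% degenerate) next
      ct <- cor.test(m[, i], m[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (length(degenerate) > 0) {
    warning("zero-variance sample(s): ",
            paste(degenerate, collapse = ", "),
            "; correlations reported as NA")
  }
  d <- as.matrix(dist(r))
  structure(list(r = r, p = p, dist = d, degenerate = degenerate,
                 n_genes = nrow(m)),
            class = "tealseq_cor")
}

#' @export
print.tealseq_cor <- function(x, ...) {
  cat(sprintf("<tealseq correlation matrix> %d samples on %d genes\n",
              ncol(x$r), x$n_genes))
  print(round(x$r, 3))
  invisible(x)
}

#' @export
tidy.tealseq_cor <- function(x, ...) {
  s <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(sample_x = s[idx[, 1]], sample_y = s[idx[, 2]],
                 r = x$r[idx], p = x$p[idx], dist = x$dist[idx])
}
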