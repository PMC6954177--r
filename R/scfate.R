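#' Quality-control filter for single cells
#'
#' Keeps cells with at least `min_genes` detected genes, a
#' mitochondrial fraction at or below `max_mito`, and at most
#' `max_umis` UMIs. The filter is idempotent.
#'
#' @param cells Tibble with columns `n_genes`, `mito_fraction`,
#'   `n_umis`.
#' @param min_genes Minimum unique gene count (default 200; cells below
#'   it are removed).
#' @param max_mito Maximum mitochondrial fraction (default 0.20; cells
#'   above it are removed).
#' @param max_umis Maximum UMI count (default 40000; cells above it are
#'   removed).
#' @return The kept cells; the number of removed cells is attached as
#'   attribute `"n_removed"`.
#' @export
qc_filter <- function(cells, min_genes = 200, max_mito = 0.20,
                      max_umis = 40000) {
  keep <- cells$n_genes >= min_genes &
    cells$mito_fraction <= max_mito &
    cells$n_umis <= max_umis
  out <- tibble::as_tibble(cells[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Identify clonotypes with increased or decreased relative frequency
#'
#' For each clonotype observed in the infusion product (IP), a
#' two-by-two table of clonotype versus all-other cell counts at the IP
#' and the early post-infusion timepoint is tested with a two-sided
#' Fisher exact test. P-values are adjusted with Benjamini-Hochberg
#' across the tested clonotypes (within the patient); clonotypes
#' significant at the chosen FDR are labeled `IRF` (increased relative
#' frequency) when the early proportion exceeds the IP proportion and
#' `DRF` (decreased) when it is lower; all others are `unchanged`.
#'
#' @param cells Cell table with columns `timepoint` and `clonotype_id`
#'   (cells lacking a clonotype are ignored).
#' @param ip,early Timepoint labels of the infusion product and the
#'   early post-infusion sample (defaults `"IP"`, `"early"`).
#' @param fdr False discovery rate for calling IRF/DRF (default 0.05).
#' @return An object of class `clonekin_fate` with a per-clonotype
#'   results table; use [tidy()] / [glance()] to extract tibbles.
#' @export
clonotype_fate_test <- function(cells, ip = "IP", early = "early", fdr = 0.05) {
  cells <- cells[!is.na(cells$clonotype_id), , drop = FALSE]
  ip_cells <- cells[cells$timepoint == ip, , drop = FALSE]
  early_cells <- cells[cells$timepoint == early, , drop = FALSE]
  if (!nrow(ip_cells) || !nrow(early_cells)) {
    abort("both the IP and the early timepoint must contain clonotype-bearing cells.")
  }
  ip_total <- nrow(ip_cells)
  early_total <- nrow(early_cells)
  ip_counts <- table(ip_cells$clonotype_id)
  early_counts <- table(early_cells$clonotype_id)
  ids <- sort(names(ip_counts)) # tested clonotypes: present in the IP
  a <- as.integer(ip_counts[ids])
  b <- as.integer(early_counts[ids]); b[is.na(b)] <- 0L

  p <- vapply(seq_along(ids), function(i) {
    fisher.test(matrix(c(a[i], ip_total - a[i], b[i], early_total - b[i]),
                       nrow = 2))$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  direction <- ifelse(b / early_total > a / ip_total, "up", "down")
  label <- dplyr::case_when(
    q <= fdr & direction == "up" ~ "IRF",
    q <= fdr & direction == "down" ~ "DRF",
    TRUE ~ "unchanged")
  res <- tibble::tibble(
    clonotype_id = ids,
    ip_count = a, early_count = b,
    ip_total = ip_total, early_total = early_total,
    direction = direction, p_value = p, q_value = q, label = label)
  structure(list(results = res, fdr = fdr,
                 ip = ip, early = early,
                 n_tested = length(ids),
                 n_irf = sum(label == "IRF"),
                 n_drf = sum(label == "DRF")),
            class = "clonekin_fate")
}

#' @export
print.clonekin_fate <- function(x, ...) {
  cat(sprintf(
    "Clonotype fate test (%s vs %s): %d clonotypes tested, %d IRF, %d DRF (FDR %.2g)\n",
    x$ip, x$early, x$n_tested, x$n_irf, x$n_drf, x$fdr))
  invisible(x)
}

#' @describeIn clonotype_fate_test Per-clonotype results as a tibble.
#' @param x A `clonekin_fate` object.
#' @param ... Unused.
#' @export
tidy.clonekin_fate <- function(x, ...) x$results

#' @describeIn clonotype_fate_test One-row summary (clonotypes tested,
#'   IRF/DRF counts, FDR).
#' @export
glance.clonekin_fate <- function(x, ...) {
  tibble::tibble(n_tested = x$n_tested, n_irf = x$n_irf, n_drf = x$n_drf,
                 fdr = x$fdr)
}

detected_sets <- function(cells, timepoints) {
  cells <- cells[!is.na(cells$clonotype_id), , drop = FALSE]
  setNames(lapply(timepoints, function(tp) {
    unique(cells$clonotype_id[cells$timepoint == tp])
  }), timepoints)
}

#' Persistence of IRF/DRF clonotypes at later timepoints
#'
#' For each fate label and each later timepoint, reports how many of
#' the labeled clonotypes are detected (at least one cell) and the
#' rounded percentage. Label classes with no clonotypes report `NA`
#' rather than 0.
#'
#' @param fate A [clonotype_fate_test()] result, or a data frame with
#'   `clonotype_id` and `label` columns.
#' @param detected Either a named list of detected clonotype-id vectors
#'   (one per later timepoint) or a cell table from which detection is
#'   derived (a clonotype is detected when it has at least one cell at
#'   the timepoint).
#' @param timepoints Later timepoints to report when `detected` is a
#'   cell table (default `c("late", "very_late")`).
#' @param labels Label classes to report (default IRF and DRF).
#' @return A tibble `label`, `timepoint`, `n_detected`, `n_total`,
#'   `percent`.
#' @export
persistence_proportions <- function(fate, detected,
                                    timepoints = c("late", "very_late"),
                                    labels = c("IRF", "DRF")) {
  lab <- if (inherits(fate, "clonekin_fate")) fate$results else fate
  if (is.data.frame(detected)) detected <- detected_sets(detected, timepoints)
  purrr::map_dfr(names(detected), function(tp) {
    purrr::map_dfr(labels, function(lb) {
      ids <- lab$clonotype_id[lab$label == lb]
      n_total <- length(ids)
      n_det <- sum(ids %in% detected[[tp]])
      tibble::tibble(
        label = lb, timepoint = tp,
        n_detected = if (n_total) n_det else NA_integer_,
        n_total = n_total,
        percent = if (n_total) round(100 * n_det / n_total) else NA_real_)
    })
  })
}

#' Cluster attribution of IRF/DRF clonotypes in the infusion product
#'
#' Among infusion-product cells belonging to clonotypes of each fate
#' label, reports the fraction of cells in each transcriptional
#' cluster (fractions sum to 1 per label).
#'
#' @inheritParams persistence_proportions
#' @param ip_cells Infusion-product cells with `clonotype_id` and
#'   `cluster` columns.
#' @return A tibble `label`, `cluster`, `n_cells`, `fraction`.
#' @export
cluster_attribution <- function(fate, ip_cells, labels = c("IRF", "DRF")) {
  lab <- if (inherits(fate, "clonekin_fate")) fate$results else fate
  ip_cells <- ip_cells[!is.na(ip_cells$clonotype_id) &
                         !is.na(ip_cells$cluster), , drop = FALSE]
  clusters <- sort(unique(ip_cells$cluster))
  out <- purrr::map_dfr(labels, function(lb) {
    ids <- lab$clonotype_id[lab$label == lb]
    sub <- ip_cells[ip_cells$clonotype_id %in% ids, , drop = FALSE]
    n <- vapply(clusters, function(cl) sum(sub$cluster == cl), integer(1))
    tibble::tibble(label = lb, cluster = clusters, n_cells = n,
                   fraction = if (sum(n)) n / sum(n) else rep(NA_real_, length(n)))
  })
  if (all(is.na(out$fraction))) abort("no labeled cells with cluster assignments.")
  out
}

#' Cluster composition of infusion-product cells by later detection
#'
#' Partitions infusion-product cells by whether their clonotype is
#' detected at a given later timepoint and reports per-cluster cell
#' fractions within each partition (fractions sum to 1 per partition).
#'
#' @param ip_cells Infusion-product cells with `clonotype_id` and
#'   `cluster` columns.
#' @param cells Full cell table (or a named list of detected clonotype
#'   sets) used to determine detection at the later timepoints.
#' @param timepoints Later timepoints to evaluate.
#' @return A tibble `timepoint`, `detected` (`"yes"`/`"no"`),
#'   `cluster`, `n_cells`, `fraction`.
#' @export
detected_cluster_composition <- function(ip_cells, cells,
                                         timepoints = c("early", "late", "very_late")) {
  det <- if (is.data.frame(cells)) detected_sets(cells, timepoints) else cells
  ip_cells <- ip_cells[!is.na(ip_cells$clonotype_id) &
                         !is.na(ip_cells$cluster), , drop = FALSE]
  clusters <- sort(unique(ip_cells$cluster))
  purrr::map_dfr(names(det), function(tp) {
    is_det <- ip_cells$clonotype_id %in% det[[tp]]
    purrr::map_dfr(c(yes = TRUE, no = FALSE), function(flag) {
      sub <- ip_cells[is_det == flag, , drop = FALSE]
      n <- vapply(clusters, function(cl) sum(sub$cluster == cl), integer(1))
      tibble::tibble(timepoint = tp, detected = if (flag) "yes" else "no",
                     cluster = clusters, n_cells = n,
                     fraction = if (sum(n)) n / sum(n) else rep(NA_real_, length(n)))
    })
  })
}
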