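#' Simulate a single-cell table linked to a repertoire timeline
#'
#' Generates one row per cell (barcode, timepoint, clonotype, infusion
#' product cluster label, and the three QC scalars used for cell
#' filtering) from the true clonotype frequencies of a simulated
#' repertoire timeline. Cells of planted expanding clonotypes in the
#' infusion product (IP) are preferentially placed in designated
#' transcriptional clusters, emulating expansion-fated clones
#' originating from cytotoxic/proliferative clusters.
#'
#' QC scalars are drawn from in-range distributions (detected genes
#' around 2,500, mitochondrial fraction around 5%, UMIs around 8,000); a
#' `qc_outlier_rate` fraction of cells instead violate exactly one QC
#' gate (genes < 200, mitochondrial fraction > 20%, or UMIs > 40,000).
#'
#' @param timeline A `clonekin_sim_repertoire` object from
#'   [sim_repertoire_timeline()], whose truth table supplies clonotype
#'   identities, planted patterns and per-timepoint true frequencies.
#' @param n_cells_per_timepoint Cells sampled at each timepoint.
#' @param n_clusters Number of IP transcriptional clusters.
#' @param cluster_mixture Baseline per-cluster cell fractions (sums to 1).
#' @param designated_clusters Cluster indices that attract expanding
#'   clones.
#' @param irf_cluster_bias Probability that an IP cell of a planted
#'   increasing clonotype sits in a designated cluster.
#' @param qc_outlier_rate Fraction of cells planted as QC violations.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `cell_barcode`, `patient_id`,
#'   `timepoint`, `clonotype_id`, `cluster` (integer, `NA` outside the
#'   IP), `n_genes`, `mito_fraction`, `n_umis`.
#' @export
sim_cell_table <- function(timeline,
                           n_cells_per_timepoint = 2000,
                           n_clusters = 4,
                           cluster_mixture = NULL,
                           designated_clusters = c(2, 4),
                           irf_cluster_bias = 0.85,
                           qc_outlier_rate = 0,
                           seed = NULL) {
  if (!inherits(timeline, "clonekin_sim_repertoire")) {
    abort("`timeline` must come from sim_repertoire_timeline().")
  }
  if (is.null(cluster_mixture)) cluster_mixture <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_mixture) != n_clusters ||
      abs(sum(cluster_mixture) - 1) > 1e-8) {
    abort("`cluster_mixture` must have `n_clusters` fractions summing to 1.")
  }
  if (irf_cluster_bias < 0 || irf_cluster_bias > 1) {
    abort("`irf_cluster_bias` must be in [0, 1].")
  }
  if (qc_outlier_rate < 0 || qc_outlier_rate > 1) {
    abort("`qc_outlier_rate` must be in [0, 1].")
  }
  if (!all(designated_clusters %in% seq_len(n_clusters))) {
    abort("`designated_clusters` must index into 1..n_clusters.")
  }

  truth <- timeline$truth
  patient <- timeline$samples$patient_id[1]
  tps <- levels(truth$timepoint)
  expanding_ids <- unique(truth$clonotype_id[truth$pattern == "increasing"])

  with_seed(derive_seed(seed, 3L), {
    cells <- purrr::map_dfr(tps, function(tp) {
      tr <- truth[truth$timepoint == tp, ]
      idx <- sample.int(nrow(tr), n_cells_per_timepoint,
                        replace = TRUE, prob = tr$true_freq)
      tibble::tibble(
        patient_id = patient,
        timepoint = tp,
        clonotype_id = tr$clonotype_id[idx]
      )
    })
    n <- nrow(cells)
    cells$cell_barcode <- sprintf("cell%06d", seq_len(n))
    cells$timepoint <- factor(cells$timepoint, levels = tps)

    # IP cluster labels: expanding clones biased into designated clusters
    cells$cluster <- NA_integer_
    ip <- which(cells$timepoint == tps[1])
    base_draw <- sample.int(n_clusters, length(ip), replace = TRUE,
                            prob = cluster_mixture)
    cl <- base_draw
    is_exp <- cells$clonotype_id[ip] %in% expanding_ids
    go_designated <- is_exp & (runif(length(ip)) < irf_cluster_bias)
    if (any(go_designated)) {
      cl[go_designated] <- sample(rep(designated_clusters, 2),
                                  sum(go_designated), replace = TRUE)
    }
    # biased cells not sent to a designated cluster land in the others
    off <- is_exp & !go_designated
    other <- setdiff(seq_len(n_clusters), designated_clusters)
    if (any(off) && length(other)) {
      cl[off] <- sample(rep(other, 2), sum(off), replace = TRUE)
    }
    cells$cluster[ip] <- cl

    cells$n_genes <- pmax(300L, as.integer(round(rnorm(n, 2500, 500))))
    cells$mito_fraction <- pmin(0.19, rbeta(n, 2, 38))
    cells$n_umis <- pmin(39000L, as.integer(round(rlnorm(n, log(8000), 0.4))))

    n_out <- rbinom(1, n, qc_outlier_rate)
    if (n_out > 0) {
      out_idx <- sample.int(n, n_out)
      kind <- sample.int(3, n_out, replace = TRUE)
      cells$n_genes[out_idx[kind == 1]] <-
        sample(50:199, sum(kind == 1), replace = TRUE)
      cells$mito_fraction[out_idx[kind == 2]] <-
        runif(sum(kind == 2), 0.201, 0.6)
      cells$n_umis[out_idx[kind == 3]] <-
        sample(40001:80000, sum(kind == 3), replace = TRUE)
    }

    cells[, c("cell_barcode", "patient_id", "timepoint", "clonotype_id",
              "cluster", "n_genes", "mito_fraction", "n_umis")]
  })
}
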