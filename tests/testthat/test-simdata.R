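test_that("repertoire simulation is deterministic and conserves depth", {
  s1 <- sim_repertoire_timeline(100, depth = 5000, n_timepoints = 3, seed = 42)
  s2 <- sim_repertoire_timeline(100, depth = 5000, n_timepoints = 3, seed = 42)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth, s2$truth)

  totals <- tapply(s1$samples$count, s1$samples$timepoint, sum)
  expect_true(all(totals == 5000))

  # truth and emitted samples are mutually consistent
  expect_true(all(s1$samples$clonotype_id %in% s1$truth$clonotype_id))
  tf <- tapply(s1$truth$true_freq, s1$truth$timepoint, sum)
  expect_equal(as.numeric(tf), rep(1, 3), tolerance = 1e-12)
})

test_that("degenerate single-clonotype repertoire has frequency 1 everywhere", {
  s <- sim_repertoire_timeline(1, depth = 100, n_timepoints = 2, seed = 1)
  expect_equal(nrow(s$samples), 2L)
  expect_true(all(s$samples$count == 100))
  expect_true(all(s$truth$true_freq == 1))
})

test_that("invalid repertoire configs are rejected", {
  expect_error(sim_repertoire_timeline(0, depth = 100), "positive")
  expect_error(sim_repertoire_timeline(10, depth = 0), "positive")
  expect_error(sim_repertoire_timeline(
    10, depth = 100,
    planted = data.frame(clone_index = c(2, 2), pattern = "increasing",
                         fold_per_step = 4)), "unique")
  expect_error(sim_repertoire_timeline(
    10, depth = 100,
    planted = data.frame(clone_index = 1, pattern = "increasing",
                         fold_per_step = 1)), "exceed")
})

test_that("a planted increasing clone rises in sampled frequency in >=95/100 seeds", {
  planted <- data.frame(clone_index = 134, pattern = "increasing",
                        fold_per_step = 4)
  rises <- vapply(1:100, function(s) {
    sim <- sim_repertoire_timeline(1000, depth = 1e5, n_timepoints = 4,
                                   planted = planted, seed = s)
    id <- sim$truth$clonotype_id[sim$truth$clone_index == 134][1]
    sub <- sim$samples[sim$samples$clonotype_id == id, ]
    totals <- tapply(sim$samples$count, sim$samples$timepoint, sum)
    freq <- sub$count / totals[as.character(sub$timepoint)]
    length(freq) == 4 && all(diff(freq) > 0)
  }, logical(1))
  expect_gte(sum(rises), 95)
})

test_that("planted pattern multipliers follow the three kinetic regimes", {
  planted <- data.frame(clone_index = 1:3,
                        pattern = c("increasing", "transient", "decreasing"),
                        fold_per_step = 4)
  sim <- sim_repertoire_timeline(50, depth = 1000, n_timepoints = 4,
                                 planted = planted, seed = 9)
  tf <- tidyr::pivot_wider(sim$truth[sim$truth$clone_index %in% 1:3, ],
                           id_cols = "clone_index", names_from = "timepoint",
                           values_from = "true_freq")
  inc <- unlist(tf[tf$clone_index == 1, -1])
  tra <- unlist(tf[tf$clone_index == 2, -1])
  dec <- unlist(tf[tf$clone_index == 3, -1])
  expect_true(all(diff(inc) > 0))
  expect_true(tra[2] > tra[1] && tra[3] < tra[2] && tra[4] < tra[3])
  expect_true(all(diff(dec) < 0))
})

test_that("zero-noise ISA reads are identical and contain the fragment verbatim", {
  sim <- sim_isa_reads(genome_length = 5000, n_sites = 1,
                       mean_reads_per_site = 10, min_reads_per_site = 10,
                       fragment_length_range = c(60, 60),
                       substitution_rate = 0, seed = 7)
  expect_equal(nrow(sim$reads), sim$truth$n_reads[1])
  expect_length(unique(sim$reads$sequence), 1L)
  pos <- sim$truth$position[1]
  frag <- if (sim$truth$strand[1] == "+") {
    substr(sim$genome[["chr1"]], pos, pos + 59)
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(sim$genome[["chr1"]], pos - 59, pos))))
  }
  expect_true(grepl(frag, sim$reads$sequence[1], fixed = TRUE))
  expect_identical(sim$reads$sequence[1],
                   paste0(sim$ltr_seq, frag, sim$linker_seq))
})

test_that("ISA substitution and contamination rates match binomial expectations", {
  sim <- sim_isa_reads(genome_length = 5000, n_sites = 1,
                       mean_reads_per_site = 1000, min_reads_per_site = 1000,
                       fragment_length_range = c(100, 100),
                       substitution_rate = 0.01, seed = 11)
  pos <- sim$truth$position[1]
  frag <- if (sim$truth$strand[1] == "+") {
    substr(sim$genome[["chr1"]], pos, pos + 99)
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(sim$genome[["chr1"]], pos - 99, pos))))
  }
  truth_read <- paste0(sim$ltr_seq, frag, sim$linker_seq)
  L <- nchar(truth_read)
  mism <- vapply(sim$reads$sequence, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(truth_read, "")[[1]])
  }, numeric(1), USE.NAMES = FALSE)
  # mean mismatches ~ Binomial(L, 0.01); 4-sigma band on the mean
  expect_equal(mean(mism), L * 0.01,
               tolerance = 4 * sqrt(L * 0.01 * 0.99 / nrow(sim$reads)) / (L * 0.01))

  simc <- sim_isa_reads(genome_length = 5000, n_sites = 5,
                        mean_reads_per_site = 200, min_reads_per_site = 150,
                        fragment_length_range = c(60, 120),
                        substitution_rate = 0, contaminant_fraction = 0.2,
                        seed = 12)
  n <- nrow(simc$reads)
  n_cont <- sum(is.na(simc$reads$true_site))
  expect_lt(abs(n_cont - 0.2 * n), 4 * sqrt(n * 0.2 * 0.8))
  # contaminant inserts really do come from the vector
  one <- simc$reads$sequence[is.na(simc$reads$true_site)][1]
  insert <- substr(one, nchar(simc$ltr_seq) + 1,
                   nchar(one) - nchar(simc$linker_seq))
  expect_true(grepl(insert, simc$vector_seq, fixed = TRUE))
})

test_that("ISA config errors fire", {
  expect_error(sim_isa_reads(genome_length = 100, n_sites = 2,
                             fragment_length_range = c(40, 200), seed = 1),
               "exceeds")
  expect_error(sim_isa_reads(fragment_length_range = c(10, 50), seed = 1),
               ">= 30")
})

test_that("cell-table generation honors bias, outlier rate and determinism", {
  planted <- data.frame(clone_index = 5:14, pattern = "increasing",
                        fold_per_step = 8)
  sim <- sim_repertoire_timeline(200, depth = 2e4, n_timepoints = 2,
                                 planted = planted, seed = 21)
  exp_ids <- unique(sim$truth$clonotype_id[sim$truth$pattern == "increasing"])

  all_in <- sim_cell_table(sim, n_cells_per_timepoint = 800,
                           irf_cluster_bias = 1, qc_outlier_rate = 0, seed = 3)
  ip <- all_in[all_in$timepoint == "IP" & all_in$clonotype_id %in% exp_ids, ]
  expect_true(all(ip$cluster %in% c(2, 4)))
  expect_identical(attr(qc_filter(all_in), "n_removed"), 0L)

  c1 <- sim_cell_table(sim, n_cells_per_timepoint = 500, seed = 8)
  c2 <- sim_cell_table(sim, n_cells_per_timepoint = 500, seed = 8)
  expect_identical(c1, c2)

  biased <- sim_cell_table(sim, n_cells_per_timepoint = 3000,
                           irf_cluster_bias = 0.85, seed = 5)
  ipb <- biased[biased$timepoint == "IP" & biased$clonotype_id %in% exp_ids, ]
  frac <- mean(ipb$cluster %in% c(2, 4))
  expect_gt(nrow(ipb), 300)
  expect_lt(abs(frac - 0.85), 4 * sqrt(0.85 * 0.15 / nrow(ipb)))

  expect_error(sim_cell_table(sim, irf_cluster_bias = 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(sim_cell_table(sim, qc_outlier_rate = -0.1, seed = 1), "\\[0, 1\\]")
})
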