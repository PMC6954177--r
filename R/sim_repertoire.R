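#' Simulate a clonotype repertoire timeline with planted clonal dynamics
#'
#' Draws one clonotype count table per timepoint from an evolving
#' true-frequency vector. Baseline clone frequencies follow a power law
#' in rank (frequency proportional to rank^-abundance_exponent), the
#' heavy-tailed shape typical of T-cell receptor beta (TCRB) repertoires.
#' Selected clones can be planted with one of three kinetic patterns:
#'
#' * `"increasing"`: true frequency multiplied by `fold_per_step` at each
#'   successive timepoint;
#' * `"transient"`: multiplied by `fold_per_step` through the second
#'   timepoint, then symmetrically decayed;
#' * `"decreasing"`: divided by `fold_per_step` at each step.
#'
#' Frequencies are renormalized per timepoint and counts drawn
#' multinomially at the requested sequencing depth, so observed counts
#' carry realistic sampling noise and per-timepoint totals equal the
#' depth exactly.
#'
#' @param n_clonotypes Number of distinct clonotypes in the true repertoire.
#' @param depth Sequencing depth per timepoint (total template count).
#'   Either a single value or one value per timepoint.
#' @param n_timepoints Number of timepoints (>= 2). The first four are
#'   labeled `IP`, `early`, `late`, `very_late` to mirror an infusion
#'   product followed by post-infusion blood draws.
#' @param abundance_exponent Positive power-law slope of baseline clone
#'   frequencies.
#' @param planted Optional data frame with columns `clone_index`
#'   (1-based, unique, <= `n_clonotypes`), `pattern` (one of
#'   `"increasing"`, `"transient"`, `"decreasing"`) and `fold_per_step`
#'   (> 1).
#' @param cdr3_length Length of the random CDR3 nucleotide sequence
#'   attached to each clonotype identifier.
#' @param patient_id Identifier stamped on the output samples.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#'
#' @return A list of class `clonekin_sim_repertoire` with elements
#'   `samples` (tibble: `patient_id`, `timepoint`, `clonotype_id`,
#'   `cdr3_nt`, `count`, `productive`) containing only clonotypes with
#'   non-zero observed count, and `truth` (tibble: `clonotype_id`,
#'   `clone_index`, `pattern`, `timepoint`, `true_freq`).
#' @export
#' @examples
#' sim <- sim_repertoire_timeline(50, depth = 1000, seed = 1)
#' head(sim$samples)
sim_repertoire_timeline <- function(n_clonotypes,
                                    depth,
                                    n_timepoints = 4,
                                    abundance_exponent = 1,
                                    planted = NULL,
                                    cdr3_length = 36,
                                    patient_id = "P1",
                                    seed = NULL) {
  if (n_clonotypes < 1) abort("`n_clonotypes` must be a positive integer.")
  if (any(depth < 1)) abort("`depth` must be positive.")
  if (n_timepoints < 2) abort("`n_timepoints` must be at least 2.")
  if (abundance_exponent <= 0) abort("`abundance_exponent` must be positive.")
  depth <- rep_len(as.numeric(depth), n_timepoints)
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("clone_index", "pattern", "fold_per_step") %in% names(planted)))
    if (anyDuplicated(planted$clone_index) ||
        any(planted$clone_index < 1) || any(planted$clone_index > n_clonotypes)) {
      abort("planted `clone_index` values must be unique and within 1..n_clonotypes.")
    }
    if (!all(planted$pattern %in% c("increasing", "transient", "decreasing"))) {
      abort("planted `pattern` must be increasing, transient or decreasing.")
    }
    if (any(planted$fold_per_step <= 1)) abort("`fold_per_step` must exceed 1.")
  }

  with_seed(derive_seed(seed, 1L), {
    ids <- sprintf("CT%04d", seq_len(n_clonotypes))
    cdr3 <- random_dna(n_clonotypes, cdr3_length)
    base <- seq_len(n_clonotypes)^(-abundance_exponent)
    base <- base / sum(base)

    tp_labels <- timepoint_labels(n_timepoints)
    pattern <- rep("none", n_clonotypes)
    fold <- rep(1, n_clonotypes)
    if (!is.null(planted)) {
      pattern[planted$clone_index] <- planted$pattern
      fold[planted$clone_index] <- planted$fold_per_step
    }

    freq_mat <- matrix(0, n_clonotypes, n_timepoints)
    for (t in seq_len(n_timepoints)) {
      mult <- pattern_multiplier(pattern, fold, t)
      f <- base * mult
      freq_mat[, t] <- f / sum(f)
    }

    samples <- purrr::map_dfr(seq_len(n_timepoints), function(t) {
      counts <- as.vector(rmultinom(1, size = depth[t], prob = freq_mat[, t]))
      keep <- counts > 0
      tibble::tibble(
        patient_id = patient_id,
        timepoint = tp_labels[t],
        clonotype_id = ids[keep],
        cdr3_nt = cdr3[keep],
        count = counts[keep],
        productive = TRUE
      )
    })
    samples$timepoint <- factor(samples$timepoint, levels = tp_labels)

    truth <- tidyr::expand_grid(
      clone_index = seq_len(n_clonotypes),
      timepoint = factor(tp_labels, levels = tp_labels)
    )
    truth$clonotype_id <- ids[truth$clone_index]
    truth$pattern <- pattern[truth$clone_index]
    truth$true_freq <- freq_mat[cbind(truth$clone_index,
                                      as.integer(truth$timepoint))]
    truth <- truth[, c("clonotype_id", "clone_index", "pattern",
                       "timepoint", "true_freq")]

    structure(list(samples = samples, truth = tibble::as_tibble(truth)),
              class = "clonekin_sim_repertoire")
  })
}

timepoint_labels <- function(n) {
  base <- c("IP", "early", "late", "very_late")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("t%d", seq.int(length(base) + 1L, n)))
}

# Per-clone true-frequency multiplier at timepoint t (1-based).
pattern_multiplier <- function(pattern, fold, t) {
  step <- t - 1L
  out <- rep(1, length(pattern))
  inc <- pattern == "increasing"
  dec <- pattern == "decreasing"
  tra <- pattern == "transient"
  out[inc] <- fold[inc]^step
  out[dec] <- fold[dec]^(-step)
  # transient: rise through the second timepoint, then symmetric decay
  tra_exp <- if (t <= 2) step else 2 - t + 1  # t=3 -> 0, t=4 -> -1, ...
  out[tra] <- fold[tra]^tra_exp
  out
}

#' Demo repertoire simulation with planted oligoclonal expansion
#'
#' A fixed study design used throughout the examples and tests: 1000
#' clonotypes with power-law slope 1, four timepoints with decreasing
#' sequencing depth (25,000 / 18,000 / 12,000 / 8,000 templates, deepest
#' in the infusion product), and twenty planted clones — ten increasing,
#' five transient, five decreasing, all at 4-fold per step — seeded at
#' mid-rank baseline abundances. The expanding clones progressively take
#' over the repertoire, reproducing the oligoclonal-expansion regime in
#' which diversity falls after infusion.
#'
#' @param seed Integer seed.
#' @inheritParams sim_repertoire_timeline
#' @return See [sim_repertoire_timeline()].
#' @export
sim_demo_repertoire <- function(seed = NULL, patient_id = "P1") {
  planted <- tibble::tibble(
    clone_index = c(30:39, 60:64, 80:84),
    pattern = c(rep("increasing", 10), rep("transient", 5), rep("decreasing", 5)),
    fold_per_step = 4
  )
  sim_repertoire_timeline(
    n_clonotypes = 1000,
    depth = c(25000, 18000, 12000, 8000),
    n_timepoints = 4,
    abundance_exponent = 1,
    planted = planted,
    patient_id = patient_id,
    seed = seed
  )
}
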