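#' Shannon entropy of a clonotype repertoire
#'
#' Computes H = -sum(p_i * log(p_i)) over clonotypes with non-zero
#' frequency, where p_i is the clonotype's share of total templates.
#' Entropy is 0 for a monoclonal sample and log(richness) for a uniform
#' one.
#'
#' @param sample A data frame with a `count` column (one row per
#'   clonotype) or a numeric count vector.
#' @param base Logarithm base; natural log by default (`base = 2` for
#'   bits).
#' @return A non-negative number.
#' @export
#' @examples
#' shannon_entropy(c(8, 2))
shannon_entropy <- function(sample, base = exp(1)) {
  counts <- as_count_vector(sample)
  check_nonempty_sample(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Median Shannon entropy after repeated downsampling
#'
#' Repertoire samples of different sequencing depths are made comparable
#' by repeatedly subsampling each to a common depth without replacement
#' and taking the median entropy across replicates.
#'
#' @inheritParams shannon_entropy
#' @param depth Downsampling depth; must not exceed the sample total.
#' @param n_reps Number of downsampling replicates (1000 by default).
#' @param seed Integer seed; fixed seed gives a deterministic result.
#' @return The median entropy across replicates.
#' @export
median_downsampled_entropy <- function(sample, depth, n_reps = 1000,
                                       base = exp(1), seed = NULL) {
  counts <- as_count_vector(sample)
  check_nonempty_sample(counts)
  total <- sum(counts)
  if (depth < 1) abort("`depth` must be positive.")
  if (depth > total) {
    abort(sprintf("`depth` (%s) exceeds the sample total (%s).", depth, total))
  }
  ids <- rep.int(seq_along(counts), counts)
  with_seed(derive_seed(seed, 11L), {
    h <- vapply(seq_len(n_reps), function(i) {
      sub <- tabulate(ids[sample.int(total, depth)], nbins = length(counts))
      p <- sub[sub > 0] / depth
      -sum(p * log(p, base = base))
    }, numeric(1))
    median(h)
  })
}

#' Morisita-Horn overlap between two repertoires
#'
#' Abundance-weighted overlap C = 2 * sum(p_i * q_i) /
#' (sum(p_i^2) + sum(q_i^2)) on relative clonotype frequencies. The
#' index is 0 when no clonotypes are shared and 1 when the repertoires
#' contain the same clonotypes in the same proportions; it is symmetric
#' and invariant to rescaling the counts of either sample.
#'
#' @param a,b Data frames with `clonotype_id` and `count` columns, or
#'   named count vectors.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' ip <- data.frame(clonotype_id = c("A", "B"), count = c(3, 1))
#' early <- data.frame(clonotype_id = c("A", "B"), count = c(1, 3))
#' morisita_index(ip, early)
morisita_index <- function(a, b) {
  ca <- check_nonempty_sample(as_count_vector(a, "a"), "a")
  cb <- check_nonempty_sample(as_count_vector(b, "b"), "b")
  ids <- union(names(ca), names(cb))
  p <- setNames(numeric(length(ids)), ids)
  q <- p
  p[names(ca)] <- ca / sum(ca)
  q[names(cb)] <- cb / sum(cb)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' Combined frequency of the top-ranked clonotypes
#'
#' Sum of relative frequencies of the `n` most abundant clonotypes
#' (ties at the boundary broken lexicographically by clonotype
#' identifier for a deterministic result). Returns 1 when the sample
#' holds `n` or fewer clonotypes.
#'
#' @inheritParams shannon_entropy
#' @param n Number of top clonotypes (default 10).
#' @return A number in `[0, 1]`.
#' @export
top_n_fraction <- function(sample, n = 10) {
  if (n < 1) abort("`n` must be at least 1.")
  counts <- as_count_vector(sample)
  check_nonempty_sample(counts)
  ord <- order(-counts, names(counts))
  sum(counts[ord[seq_len(min(n, length(counts)))]]) / sum(counts)
}

#' Competition ranks and relative frequencies of clonotypes
#'
#' Ranks clonotypes by descending count with competition ranking (ties
#' share the minimum rank of the tied block). Ranks above `cap` are
#' reported as `cap + 1`, the convention used when plotting rank
#' trajectories; clonotypes requested via `clonotypes` but absent from
#' the sample are reported at rank `cap + 1` with frequency 0.
#'
#' @inheritParams shannon_entropy
#' @param cap Rank cap (default 100).
#' @param clonotypes Optional character vector of clonotypes to report
#'   (useful when tracking a fixed clone set across samples); defaults
#'   to all clonotypes in the sample.
#' @return A tibble with `clonotype_id`, `rank`, `rel_freq`.
#' @export
rank_clonotypes <- function(sample, cap = 100, clonotypes = NULL) {
  counts <- as_count_vector(sample)
  check_nonempty_sample(counts)
  rk <- rank(-counts, ties.method = "min")
  freq <- counts / sum(counts)
  out <- tibble::tibble(
    clonotype_id = names(counts),
    rank = as.integer(pmin(rk, cap + 1L)),
    rel_freq = as.numeric(freq)
  )
  if (!is.null(clonotypes)) {
    out <- dplyr::left_join(tibble::tibble(clonotype_id = clonotypes), out,
                            by = "clonotype_id")
    out$rank[is.na(out$rank)] <- cap + 1L
    out$rel_freq[is.na(out$rel_freq)] <- 0
  }
  out
}

#' Track clonotype rank and frequency across timepoints
#'
#' Selects the top `top_n` clonotypes of one reference timepoint and
#' reports their competition rank and relative frequency at every
#' timepoint, with absent clonotypes at rank `cap + 1` and frequency 0.
#'
#' @param samples Long-format tibble of samples with columns
#'   `timepoint`, `clonotype_id`, `count` (and optionally `patient_id`).
#' @param from_timepoint Reference timepoint whose top clonotypes are
#'   tracked (default the first level/value present).
#' @param top_n Number of reference clonotypes to follow.
#' @param cap Rank cap.
#' @return A tibble `clonotype_id`, `timepoint`, `rank`, `rel_freq`.
#' @export
track_clonotype_ranks <- function(samples, from_timepoint = NULL,
                                  top_n = 10, cap = 100) {
  tps <- sample_timepoints(samples)
  if (is.null(from_timepoint)) from_timepoint <- tps[1]
  ref <- samples[samples$timepoint == from_timepoint, ]
  counts <- as_count_vector(ref)
  ord <- order(-counts, names(counts))
  track_ids <- names(counts)[ord[seq_len(min(top_n, length(counts)))]]
  purrr::map_dfr(tps, function(tp) {
    res <- rank_clonotypes(samples[samples$timepoint == tp, ],
                           cap = cap, clonotypes = track_ids)
    res$timepoint <- tp
    res[, c("clonotype_id", "timepoint", "rank", "rel_freq")]
  })
}

sample_timepoints <- function(samples) {
  if (!"timepoint" %in% names(samples)) abort("`samples` needs a `timepoint` column.")
  if (is.factor(samples$timepoint)) {
    levels(droplevels(samples$timepoint))
  } else {
    unique(samples$timepoint)
  }
}

#' Per-sample repertoire diversity metrics
#'
#' Computes richness, Shannon entropy, median downsampled entropy (at
#' the minimum total across the grouped samples unless `depth` is
#' given), and the combined top-10 clonotype frequency for every
#' patient/timepoint sample in a long-format table.
#'
#' @inheritParams track_clonotype_ranks
#' @param depth Common downsampling depth; defaults to the smallest
#'   per-sample total within each patient.
#' @param n_reps Downsampling replicates.
#' @param seed Integer seed for the downsampling streams.
#' @return A tibble with one row per patient/timepoint.
#' @export
repertoire_metrics <- function(samples, depth = NULL, n_reps = 1000,
                               seed = NULL) {
  if (!"patient_id" %in% names(samples)) samples$patient_id <- "P1"
  samples <- honor_productive(samples)
  patients <- unique(samples$patient_id)
  purrr::map_dfr(seq_along(patients), function(pi) {
    df <- samples[samples$patient_id == patients[pi], ]
    tps <- sample_timepoints(df)
    totals <- vapply(tps, function(tp) sum(df$count[df$timepoint == tp]), numeric(1))
    d <- if (is.null(depth)) min(totals) else depth
    purrr::map_dfr(seq_along(tps), function(ti) {
      s <- df[df$timepoint == tps[ti], ]
      tibble::tibble(
        patient_id = patients[pi],
        timepoint = tps[ti],
        total = sum(s$count),
        richness = sum(s$count > 0),
        entropy = shannon_entropy(s),
        median_downsampled_entropy = median_downsampled_entropy(
          s, depth = d, n_reps = n_reps,
          seed = derive_seed(seed, 100L * pi + ti)),
        top10_fraction = top_n_fraction(s, 10)
      )
    })
  })
}

#' Pairwise Morisita-Horn overlap matrix across timepoints
#'
#' @inheritParams track_clonotype_ranks
#' @return A tibble `timepoint_a`, `timepoint_b`, `morisita` covering all
#'   ordered pairs (symmetric; diagonal 1).
#' @export
morisita_matrix <- function(samples) {
  samples <- honor_productive(samples)
  tps <- sample_timepoints(samples)
  grid <- tidyr::expand_grid(timepoint_a = tps, timepoint_b = tps)
  grid$morisita <- purrr::map2_dbl(grid$timepoint_a, grid$timepoint_b, function(a, b) {
    morisita_index(samples[samples$timepoint == a, ],
                   samples[samples$timepoint == b, ])
  })
  grid
}

# Drop non-productive rearrangements when the table carries the flag.
honor_productive <- function(samples) {
  if ("productive" %in% names(samples)) {
    samples <- samples[as.logical(samples$productive) %in% TRUE, ]
  }
  samples
}

#' Read a clonotype count table
#'
#' Reads a tab-separated clonotype table with columns `clonotype_id`,
#' `cdr3_nt`, `count` and optional `productive`. AIRR rearrangement
#' column aliases are accepted: `junction` for `cdr3_nt`,
#' `duplicate_count` for `count`, `sequence_id`/`clone_id` for
#' `clonotype_id`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with standardized column names.
#' @export
read_clonotype_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  aliases <- c(junction = "cdr3_nt", duplicate_count = "count",
               sequence_id = "clonotype_id", clone_id = "clonotype_id")
  for (from in names(aliases)) {
    to <- aliases[[from]]
    if (from %in% names(df) && !(to %in% names(df))) {
      names(df)[names(df) == from] <- to
    }
  }
  if (!"clonotype_id" %in% names(df) && "cdr3_nt" %in% names(df)) {
    df$clonotype_id <- df$cdr3_nt
  }
  if (!all(c("clonotype_id", "count") %in% names(df))) {
    abort(sprintf("`%s` lacks clonotype_id/count columns (or AIRR aliases).", path))
  }
  if ("productive" %in% names(df)) {
    df$productive <- df$productive %in% c(TRUE, "TRUE", "T", "true", "productive")
  }
  tibble::as_tibble(df)
}
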