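#' Estimated total blood volume from body weight and sex
#'
#' Blood volume is modeled as weight times an average per-kilogram
#' volume: 65 ml/kg for women and 75 ml/kg for men.
#'
#' @param weight_kg Body weight in kilograms (> 0); vectorized.
#' @param sex `"female"` or `"male"`; recycled against `weight_kg`.
#' @return Blood volume in milliliters.
#' @export
#' @examples
#' blood_volume(70, "male") # 5250 ml
blood_volume <- function(weight_kg, sex) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    abort("`weight_kg` must be positive.")
  }
  sex <- match.arg(tolower(as.character(sex)), c("female", "male"),
                   several.ok = TRUE)
  per_kg <- ifelse(rep_len(sex, length(weight_kg)) == "female", 65, 75)
  weight_kg * per_kg
}

#' Modeled day-0 absolute count of a clone after infusion
#'
#' The absolute concentration of CAR-T cells in blood immediately after
#' infusion is the infused cell number divided by the estimated blood
#' volume; an individual clone's day-0 count scales this by the clone's
#' relative frequency in the infusion product.
#'
#' @param rel_freq Clone relative frequency in the infusion product,
#'   in `[0, 1]`.
#' @param dose Number of infused CD8+ CAR-T cells.
#' @param blood_volume_ml Estimated total blood volume in ml (> 0).
#' @return Cells per microliter of blood.
#' @export
day0_clone_count <- function(rel_freq, dose, blood_volume_ml) {
  check_freq(rel_freq)
  if (any(blood_volume_ml <= 0)) abort("`blood_volume_ml` must be positive.")
  if (any(dose < 0)) abort("`dose` must be non-negative.")
  (dose * rel_freq) / (blood_volume_ml * 1000)
}

#' Absolute clone count from relative frequency and total CAR-T count
#'
#' @param rel_freq Clone relative frequency in the sample, in `[0, 1]`.
#' @param car_count Absolute CD8+ CAR-T cell count (cells per microliter).
#' @return Cells per microliter.
#' @export
clone_abs_count <- function(rel_freq, car_count) {
  check_freq(rel_freq)
  if (any(car_count < 0)) abort("`car_count` must be non-negative.")
  rel_freq * car_count
}

check_freq <- function(rel_freq) {
  if (any(!is.finite(rel_freq)) || any(rel_freq < 0) || any(rel_freq > 1)) {
    abort("`rel_freq` must lie in [0, 1].")
  }
  invisible(rel_freq)
}

#' Classify per-clone kinetic pattern from three absolute counts
#'
#' Applies a fold-threshold rule on the day-0 (modeled post-infusion),
#' early, and late absolute counts of each clone:
#'
#' * `increasing`: early > fold * day0 and late >= early;
#' * `transient`: early > fold * day0 and late < early / fold;
#' * `decreasing`: early <= day0 / fold;
#' * `indeterminate` otherwise.
#'
#' The rule is invariant to multiplying all three counts by a positive
#' constant.
#'
#' @param day0,early,late Absolute clone counts (vectorized).
#' @param fold_threshold Fold change separating the patterns (default 2).
#' @return A character vector of pattern labels.
#' @export
#' @examples
#' classify_kinetics(c(1, 1, 10), c(10, 50, 1), c(100, 2, 0.1))
classify_kinetics <- function(day0, early, late, fold_threshold = 2) {
  n <- max(length(day0), length(early), length(late))
  if (any(is.na(day0)) || any(is.na(early)) || any(is.na(late))) {
    abort("classify_kinetics() needs counts at all three timepoints (day 0, early, late).")
  }
  day0 <- rep_len(day0, n); early <- rep_len(early, n); late <- rep_len(late, n)
  if (any(c(day0, early, late) < 0)) abort("counts must be non-negative.")
  f <- fold_threshold
  out <- rep("indeterminate", n)
  rose <- early > day0 * f
  out[rose & late >= early] <- "increasing"
  out[rose & late < early / f] <- "transient"
  out[early <= day0 / f] <- "decreasing"
  out
}

#' Build absolute-count clone tracks and classify their kinetics
#'
#' Converts per-timepoint clonotype frequencies to absolute blood counts
#' and labels each tracked clone's kinetic pattern. Day-0 counts are
#' modeled from the infusion-product frequency and the infused dose
#' distributed over the estimated blood volume; later counts multiply
#' the clonotype's relative frequency by the measured absolute CD8+
#' CAR-T cell count on that day. Clones are the union of the top
#' `top_n` clonotypes of the infusion product, early, and late samples.
#'
#' @param samples Long-format samples tibble (`timepoint`,
#'   `clonotype_id`, `count`) with an infusion-product timepoint named
#'   `"IP"` and at least `"early"` and `"late"` timepoints.
#' @param weight_kg,sex,dose Patient metadata: body weight, sex and
#'   infused CD8+ CAR-T cell number.
#' @param car_counts Named numeric vector of absolute CD8+ CAR-T cell
#'   counts (cells/ul) for the post-infusion timepoints, e.g.
#'   `c(early = 80, late = 15)`.
#' @param top_n Clones tracked per sample (default 30).
#' @param fold_threshold Passed to [classify_kinetics()].
#' @return A list of class `clonekin_tracks`: `tracks` (tibble
#'   `clonotype_id`, `timepoint`, `rel_freq`, `abs_count`) and
#'   `patterns` (tibble `clonotype_id`, `pattern`).
#' @export
clone_kinetics <- function(samples, weight_kg, sex, dose, car_counts,
                           top_n = 30, fold_threshold = 2) {
  tps <- sample_timepoints(samples)
  needed <- c("IP", "early", "late")
  if (!all(needed %in% as.character(tps))) {
    abort("`samples` must contain IP, early and late timepoints.")
  }
  if (!all(c("early", "late") %in% names(car_counts))) {
    abort("`car_counts` must be named with the post-infusion timepoints.")
  }
  vol <- blood_volume(weight_kg, sex)
  day0_total <- dose / (vol * 1000)

  top_ids <- unique(unlist(lapply(needed, function(tp) {
    counts <- as_count_vector(samples[samples$timepoint == tp, ])
    ord <- order(-counts, names(counts))
    names(counts)[ord[seq_len(min(top_n, length(counts)))]]
  })))

  freq_at <- function(tp) {
    counts <- as_count_vector(samples[samples$timepoint == tp, ])
    freq <- counts / sum(counts)
    out <- setNames(numeric(length(top_ids)), top_ids)
    shared <- intersect(top_ids, names(freq))
    out[shared] <- freq[shared]
    out
  }

  use_tps <- intersect(c(needed, setdiff(names(car_counts), needed)),
                       c(as.character(tps)))
  tracks <- purrr::map_dfr(use_tps, function(tp) {
    freq <- freq_at(tp)
    abs_count <- if (tp == "IP") {
      day0_clone_count(freq, dose, vol)
    } else {
      clone_abs_count(freq, car_counts[[tp]])
    }
    tibble::tibble(clonotype_id = top_ids,
                   timepoint = if (tp == "IP") "day0" else tp,
                   rel_freq = as.numeric(freq),
                   abs_count = as.numeric(abs_count))
  })

  wide <- tidyr::pivot_wider(tracks, id_cols = "clonotype_id",
                             names_from = "timepoint",
                             values_from = "abs_count")
  patterns <- tibble::tibble(
    clonotype_id = wide$clonotype_id,
    pattern = classify_kinetics(wide$day0, wide$early, wide$late,
                                fold_threshold = fold_threshold)
  )
  structure(list(tracks = tracks, patterns = patterns,
                 day0_total = day0_total),
            class = "clonekin_tracks")
}
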