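# Internal helpers shared across modules.

# Derive a reproducible child seed from a user seed. Offsets keep the
# generator streams of the three simulators independent; results stay
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483629L)
}

# Run `expr` under a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Accept a repertoire sample as a data frame with a `count` column (and
# optional clonotype_id), or a bare (possibly named) numeric vector.
# Returns a named integer-ish vector of counts.
as_count_vector <- function(sample, arg = "sample") {
  if (is.data.frame(sample)) {
    if (!"count" %in% names(sample)) {
      abort(sprintf("`%s` must have a `count` column.", arg))
    }
    counts <- sample$count
    ids <- if ("clonotype_id" %in% names(sample)) as.character(sample$clonotype_id)
           else as.character(seq_along(counts))
    names(counts) <- ids
  } else if (is.numeric(sample)) {
    counts <- sample
    if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  } else {
    abort(sprintf("`%s` must be a data frame or numeric vector.", arg))
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort(sprintf("`%s` counts must be non-negative and non-missing.", arg))
  }
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  counts
}

check_nonempty_sample <- function(counts, arg = "sample") {
  if (length(counts) == 0L || sum(counts) < 1) {
    abort(sprintf("`%s` is an empty repertoire (total count < 1).", arg))
  }
  invisible(counts)
}

# uniform integer draw on [lo, hi], safe when lo == hi
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep.int(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_dna <- function(seq, substitution_rate, indel_rate = 0) {
  if (substitution_rate <= 0 && indel_rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  sub_at <- which(runif(n) < substitution_rate)
  for (i in sub_at) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  if (indel_rate > 0) {
    keep <- runif(length(bases)) >= indel_rate / 2
    bases <- bases[keep]
    ins_at <- which(runif(length(bases)) < indel_rate / 2)
    if (length(ins_at)) {
      out <- character(0)
      last <- 0L
      for (i in ins_at) {
        out <- c(out, bases[(last + 1L):i], sample(c("A", "C", "G", "T"), 1L))
        last <- i
      }
      if (last < length(bases)) out <- c(out, bases[(last + 1L):length(bases)])
      bases <- out
    }
  }
  paste(bases, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Alignment identity = matches / aligned columns (gaps count as mismatch).
# type follows Biostrings::pairwiseAlignment: "global" for end-to-end
# similarity, "global-local" for a query matched in full against the best
# region of a longer reference.
alignment_identity <- function(query, reference, type = "global") {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = type,
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}
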