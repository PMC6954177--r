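# k-mer seeded local alignment of integration-site inserts to a toy
# genome: a desk-scale replacement for an external genome aligner with
# the same contracts (top-scoring alignment plus all alignments within a
# score fraction of the top; chromosome, locus and strand reported per
# alignment).

isa_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Build a k-mer seed index over a genome
#'
#' Tiles each chromosome with k-mers at a fixed step and records their
#' positions. k-mers occurring more often than `max_kmer_hits` are
#' masked (a frequency cap standing in for over-represented-k-mer
#' masking on real genomes).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param k Seed length (default 11).
#' @param step Tiling step on the genome (default 5).
#' @param max_kmer_hits Mask k-mers with more genome positions than this.
#' @return An object of class `clonekin_genome_index`.
#' @export
genome_index <- function(genome, k = 11, step = 5, max_kmer_hits = 24) {
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  kmers <- character(0); chroms <- character(0); positions <- integer(0)
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    if (L < k) next
    pos <- seq.int(1L, L - k + 1L, by = step)
    kmers <- c(kmers, substring(seq, pos, pos + k - 1L))
    chroms <- c(chroms, rep(chrom, length(pos)))
    positions <- c(positions, pos)
  }
  keys <- split(seq_along(kmers), kmers)
  keys <- keys[lengths(keys) <= max_kmer_hits]
  structure(list(genome = genome, k = k, step = step,
                 hash = keys, chrom = chroms, pos = positions),
            class = "clonekin_genome_index")
}

# Seed hits of a query against the index: tibble(chrom, diag_start)
# where diag_start is the implied 1-based genomic start of query base 1.
seed_hits <- function(query, index) {
  k <- index$k
  L <- nchar(query)
  if (L < k) return(NULL)
  qpos <- seq_len(L - k + 1L)
  qk <- substring(query, qpos, qpos + k - 1L)
  hit <- index$hash[qk]
  found <- which(!vapply(hit, is.null, logical(1)))
  if (!length(found)) return(NULL)
  idx <- unlist(hit[found], use.names = FALSE)
  nrep <- lengths(hit[found])
  data.frame(chrom = index$chrom[idx],
             start = index$pos[idx] - rep(qpos[found], nrep) + 1L)
}

# One local alignment of `query` against a genomic window; returns the
# alignment geometry in genome coordinates or NULL when below `min_score`.
align_window <- function(query, index, chrom, win_start, win_end, min_score = 15) {
  seq <- index$genome[[chrom]]
  win_start <- max(1L, win_start)
  win_end <- min(nchar(seq), win_end)
  window <- substr(seq, win_start, win_end)
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = window, type = "local",
    substitutionMatrix = isa_submat(), gapOpening = 2, gapExtension = 1)
  sc <- Biostrings::score(aln)
  if (sc < min_score) return(NULL)
  list(score = sc,
       p_start = IRanges::start(Biostrings::pattern(aln)),
       p_end = IRanges::end(Biostrings::pattern(aln)),
       g_start = win_start + IRanges::start(Biostrings::subject(aln)) - 1L,
       g_end = win_start + IRanges::end(Biostrings::subject(aln)) - 1L,
       align_length = nchar(as.character(Biostrings::pattern(aln))))
}

#' Align trimmed inserts to the genome
#'
#' For each insert, candidate loci are found by exact k-mer seed hits on
#' both strands, clustered by alignment diagonal, and refined with a
#' local alignment. The top-scoring alignment and all alignments within
#' `top_score_frac` of the top score are reported. The `locus` of an
#' alignment is the 1-based genomic position corresponding to the first
#' base of the insert (the LTR junction), extrapolated across any
#' soft-trimmed leading bases; `align_start` is the 0-based offset of
#' the aligned region within the insert.
#'
#' @param reads Tibble with `read_id` and `insert` columns (e.g. from
#'   [filter_vector()]).
#' @param index A [genome_index()] (or a named genome character vector,
#'   indexed on the fly).
#' @param top_score_frac Keep alignments scoring at least this fraction
#'   of the read's best score (default 0.95).
#' @param min_score Discard candidate alignments below this raw score.
#' @return A tibble `read_id`, `chrom`, `locus`, `strand`, `score`,
#'   `align_length`, `align_start`. Reads without any alignment are
#'   absent (they form the unaligned pool).
#' @export
align_inserts <- function(reads, index, top_score_frac = 0.95, min_score = 15) {
  if (!inherits(index, "clonekin_genome_index")) index <- genome_index(index)
  res <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    alns <- align_one_insert(reads$insert[i], index, min_score)
    if (is.null(alns) || !nrow(alns)) return(NULL)
    best <- max(alns$score)
    alns <- alns[alns$score >= top_score_frac * best, , drop = FALSE]
    alns$read_id <- reads$read_id[i]
    alns
  })
  if (!nrow(res)) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          locus = integer(), strand = character(),
                          score = numeric(), align_length = integer(),
                          align_start = integer()))
  }
  tibble::as_tibble(res[, c("read_id", "chrom", "locus", "strand", "score",
                            "align_length", "align_start")])
}

align_one_insert <- function(insert, index, min_score = 15) {
  L <- nchar(insert)
  out <- list()
  for (strand in c("+", "-")) {
    query <- if (strand == "+") insert else revcomp(insert)
    hits <- seed_hits(query, index)
    if (is.null(hits)) next
    # cluster seed hits on the same approximate diagonal
    hits$bucket <- paste0(hits$chrom, ":", floor(hits$start / 30))
    for (b in unique(hits$bucket)) {
      hb <- hits[hits$bucket == b, ]
      g0 <- min(hb$start)
      a <- align_window(query, index, hb$chrom[1],
                        g0 - 15L, g0 + L + 15L, min_score)
      if (is.null(a)) next
      if (strand == "+") {
        locus <- a$g_start - (a$p_start - 1L)
        align_start <- a$p_start - 1L
      } else {
        # query is the reverse complement: insert base 1 maps to the
        # genomic end of the alignment, extrapolated over trimmed bases
        locus <- a$g_end + (L - a$p_end)
        align_start <- L - a$p_end
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = hb$chrom[1], locus = as.integer(locus), strand = strand,
        score = a$score, align_length = as.integer(a$align_length),
        align_start = as.integer(align_start))
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  # overlapping windows can rediscover the same locus; keep the best
  key <- paste(res$chrom, res$locus, res$strand)
  res <- res[order(key, -res$score), , drop = FALSE]
  res[!duplicated(paste(res$chrom, res$locus, res$strand)), , drop = FALSE]
}

#' Drop reads whose best alignment is short or starts late in the insert
#'
#' A read is discarded when its best-scoring alignment has
#' `align_length < min_align_length` or `align_start > max_align_start`;
#' otherwise all of the read's retained alignments pass through.
#'
#' @param alignments Output of [align_inserts()].
#' @param min_align_length Minimum aligned length (default 30).
#' @param max_align_start Maximum 0-based offset of the alignment start
#'   within the insert (default 10).
#' @return The filtered alignment tibble.
#' @export
filter_alignments <- function(alignments, min_align_length = 30,
                              max_align_start = 10) {
  if (!nrow(alignments)) return(alignments)
  best <- alignments |>
    dplyr::group_by(.data$read_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  bad <- best$read_id[best$align_length < min_align_length |
                        best$align_start > max_align_start]
  alignments[!alignments$read_id %in% bad, , drop = FALSE]
}

#' Mapping-ambiguity ratio of a read's alignments
#'
#' Ratio of the second-best to the best alignment score; 0 when a single
#' alignment exists (unique mapping), 1 when two loci score equally.
#'
#' @param scores Numeric vector of alignment scores for one read (>= 1).
#' @return A number in `[0, 1]`.
#' @export
multi_align_ratio <- function(scores) {
  if (!length(scores)) abort("`scores` must contain at least one alignment score.")
  if (length(scores) == 1L) return(0)
  s <- sort(scores, decreasing = TRUE)
  s[2] / s[1]
}
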