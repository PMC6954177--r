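# Read-level filters applied before alignment: every read must carry a
# recognizable LTR junction, and reads matching internal vector
# sequence are contamination, not genomic junctions.
#
# "% match" is matches / aligned columns (gaps count as mismatch) of a
# semi-global alignment in which the shorter, biologically constrained
# side is aligned in full: the LTR against the read, and the insert
# against the vector.

#' Filter reads on LTR identity and trim the LTR off
#'
#' The provirus LTR is aligned semi-globally against each read (LTR in
#' full, read locally). Reads whose LTR identity falls below
#' `min_identity` are discarded; for passing reads the matched LTR span
#' is trimmed off, leaving the genomic insert.
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param ltr_seq The LTR reference sequence (non-empty DNA string).
#' @param min_identity Minimum LTR identity to keep a read (default
#'   0.90; identity exactly at the threshold is retained).
#' @return The passing reads with added columns `ltr_identity` and
#'   `insert` (read sequence after LTR removal).
#' @export
filter_ltr <- function(reads, ltr_seq, min_identity = 0.90) {
  if (is.null(ltr_seq) || !nzchar(ltr_seq)) abort("`ltr_seq` must be non-empty.")
  ok_len <- nzchar(reads$sequence)
  reads <- reads[ok_len, , drop = FALSE]
  if (!nrow(reads)) {
    reads$ltr_identity <- numeric(0); reads$insert <- character(0)
    return(tibble::as_tibble(reads))
  }
  res <- purrr::map(reads$sequence, function(s) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = ltr_seq, subject = s, type = "global-local",
      substitutionMatrix = isa_submat(), gapOpening = 2, gapExtension = 1)
    ident <- Biostrings::pid(aln, type = "PID1") / 100
    trim_to <- IRanges::end(Biostrings::subject(aln))
    list(ident = ident, insert = substr(s, trim_to + 1L, nchar(s)))
  })
  reads$ltr_identity <- vapply(res, `[[`, numeric(1), "ident")
  reads$insert <- vapply(res, `[[`, character(1), "insert")
  out <- reads[reads$ltr_identity >= min_identity & nzchar(reads$insert), ,
               drop = FALSE]
  tibble::as_tibble(out)
}

#' Trim the ligated linker off the 3' end of trimmed inserts
#'
#' The linker cassette is a known adapter ligated to the sheared genomic
#' DNA; reads run from the LTR junction into the linker. When the linker
#' aligns within an insert at or above `min_identity` (linker aligned in
#' full, insert locally), the insert is cut at the alignment start so
#' downstream vector comparison and genome alignment see genomic
#' sequence only. Inserts that are pure linker are dropped.
#'
#' @param reads Tibble with an `insert` column (from [filter_ltr()]).
#' @param linker_seq The linker reference sequence.
#' @param min_identity Minimum linker identity required to trim
#'   (default 0.80).
#' @return The reads with trimmed `insert`s (non-empty only).
#' @export
trim_linker <- function(reads, linker_seq, min_identity = 0.80) {
  if (is.null(linker_seq) || !nzchar(linker_seq)) {
    abort("`linker_seq` must be non-empty.")
  }
  if (!nrow(reads)) return(tibble::as_tibble(reads))
  reads$insert <- vapply(reads$insert, function(ins) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = linker_seq, subject = ins, type = "global-local",
      substitutionMatrix = isa_submat(), gapOpening = 2, gapExtension = 1)
    if (Biostrings::pid(aln, type = "PID1") / 100 >= min_identity) {
      substr(ins, 1L, IRanges::start(Biostrings::subject(aln)) - 1L)
    } else ins
  }, character(1), USE.NAMES = FALSE)
  tibble::as_tibble(reads[nzchar(reads$insert), , drop = FALSE])
}

#' Discard reads matching internal vector sequence
#'
#' Each trimmed insert is aligned semi-globally against the vector
#' (insert in full, vector locally); inserts with identity at or above
#' `max_identity` are vector carry-over rather than genomic junctions
#' and are discarded.
#'
#' @param reads Tibble with an `insert` column (from [filter_ltr()]).
#' @param vector_seq Internal vector reference sequence.
#' @param max_identity Reject inserts with vector identity `>=` this
#'   value (default 0.80).
#' @return The passing reads with an added `vector_identity` column.
#' @export
filter_vector <- function(reads, vector_seq, max_identity = 0.80) {
  if (is.null(vector_seq) || !nzchar(vector_seq)) {
    abort("`vector_seq` must be non-empty.")
  }
  if (!nrow(reads)) {
    reads$vector_identity <- numeric(0)
    return(tibble::as_tibble(reads))
  }
  reads$vector_identity <- vapply(reads$insert, function(ins) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = ins, subject = vector_seq, type = "global-local",
      substitutionMatrix = isa_submat(), gapOpening = 2, gapExtension = 1)
    Biostrings::pid(aln, type = "PID1") / 100
  }, numeric(1), USE.NAMES = FALSE)
  tibble::as_tibble(reads[reads$vector_identity < max_identity, , drop = FALSE])
}
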