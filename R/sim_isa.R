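#' Simulate lentiviral integration-site sequencing reads
#'
#' Emulates stitched reads from an LTR-anchored integration-site assay:
#' each read is the provirus long terminal repeat (LTR) suffix, followed
#' by a genomic fragment that starts at the integration locus in the
#' orientation of the provirus, followed by the ligated linker, with
#' i.i.d. base substitutions (and optional indels). A configurable
#' fraction of contaminant reads carry internal vector sequence instead
#' of a genomic fragment.
#'
#' The reported locus of a site is the 1-based position of the first
#' genomic base after the LTR junction; for a minus-strand site the
#' fragment is the reverse complement of the genome ending at that
#' position.
#'
#' @param genome_length Length of the random toy genome (bp); ignored
#'   when `genome` is supplied.
#' @param n_sites Number of integration sites to plant.
#' @param mean_reads_per_site,min_reads_per_site Per-site read counts are
#'   drawn as `min_reads_per_site + rpois(mean - min)`, giving clone-size
#'   variation with a guaranteed floor.
#' @param fragment_length_range Length-2 integer range of genomic
#'   fragment lengths (>= 30 so reads can pass alignment-length filters).
#' @param substitution_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability (default 0; substitutions
#'   only).
#' @param contaminant_fraction Fraction of reads whose insert is copied
#'   from the internal vector sequence rather than the genome.
#' @param ltr_seq,linker_seq,vector_seq DNA strings; random defaults are
#'   generated when `NULL`.
#' @param genome Optional genome as a single DNA string; random when `NULL`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#'
#' @return A list of class `clonekin_sim_isa`: `reads` (tibble `read_id`,
#'   `sequence`), `truth` (tibble `site_id`, `chrom`, `position`,
#'   `strand`, `n_reads`), `genome` (named character, one chromosome
#'   `chr1`), and the `ltr_seq`, `linker_seq`, `vector_seq` used.
#' @export
sim_isa_reads <- function(genome_length = 1e5,
                          n_sites = 50,
                          mean_reads_per_site = 10,
                          min_reads_per_site = 5,
                          fragment_length_range = c(40, 150),
                          substitution_rate = 0.01,
                          indel_rate = 0,
                          contaminant_fraction = 0,
                          ltr_seq = NULL,
                          linker_seq = NULL,
                          vector_seq = NULL,
                          genome = NULL,
                          seed = NULL) {
  if (n_sites < 1) abort("`n_sites` must be positive.")
  if (min_reads_per_site < 1) abort("`min_reads_per_site` must be positive.")
  if (fragment_length_range[1] < 30) {
    abort("`fragment_length_range` minimum must be >= 30.")
  }
  if (contaminant_fraction < 0 || contaminant_fraction > 1) {
    abort("`contaminant_fraction` must be in [0, 1].")
  }

  with_seed(derive_seed(seed, 2L), {
    if (is.null(genome)) genome <- random_dna(1, genome_length)
    genome_length <- nchar(genome)
    if (fragment_length_range[2] > genome_length) {
      abort("`fragment_length_range` exceeds the genome length.")
    }
    if (is.null(ltr_seq)) ltr_seq <- random_dna(1, 60)
    if (is.null(linker_seq)) linker_seq <- random_dna(1, 30)
    if (is.null(vector_seq)) vector_seq <- random_dna(1, 600)
    if (!nzchar(ltr_seq) || !nzchar(linker_seq) || !nzchar(vector_seq)) {
      abort("LTR, linker and vector sequences must be non-empty.")
    }

    max_frag <- fragment_length_range[2]
    # keep full fragment range available on either strand
    position <- sample(seq.int(max_frag + 1L, genome_length - max_frag), n_sites)
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    n_reads <- min_reads_per_site +
      rpois(n_sites, max(mean_reads_per_site - min_reads_per_site, 0))

    truth <- tibble::tibble(
      site_id = sprintf("site%03d", seq_len(n_sites)),
      chrom = "chr1",
      position = position,
      strand = strand,
      n_reads = as.integer(n_reads)
    )

    reads <- purrr::map_dfr(seq_len(n_sites), function(i) {
      lens <- sample_range(fragment_length_range[1], fragment_length_range[2],
                           n_reads[i])
      frags <- vapply(lens, function(L) {
        site_fragment(genome, position[i], strand[i], L)
      }, character(1))
      tibble::tibble(
        site_id = truth$site_id[i],
        fragment = frags
      )
    })
    # contaminants replace the genomic fragment with vector internal sequence
    n_total <- nrow(reads)
    is_contaminant <- runif(n_total) < contaminant_fraction
    vec_len <- nchar(vector_seq)
    reads$fragment[is_contaminant] <- vapply(which(is_contaminant), function(j) {
      L <- sample_range(fragment_length_range[1],
                        min(fragment_length_range[2], vec_len), 1L)
      s <- sample.int(vec_len - L + 1L, 1L)
      substr(vector_seq, s, s + L - 1L)
    }, character(1))
    reads$site_id[is_contaminant] <- NA_character_

    sequence <- vapply(reads$fragment, function(f) {
      mutate_dna(paste0(ltr_seq, f, linker_seq), substitution_rate, indel_rate)
    }, character(1), USE.NAMES = FALSE)

    truth$n_reads <- as.integer(table(factor(reads$site_id, truth$site_id)))
    truth <- truth[truth$n_reads > 0, ]

    out <- list(
      reads = tibble::tibble(
        read_id = sprintf("read%05d", seq_len(n_total)),
        sequence = sequence,
        true_site = reads$site_id
      ),
      truth = truth,
      genome = c(chr1 = genome),
      ltr_seq = ltr_seq,
      linker_seq = linker_seq,
      vector_seq = vector_seq
    )
    class(out) <- "clonekin_sim_isa"
    out
  })
}

# Genomic fragment of length L read off from an integration locus.
site_fragment <- function(genome, position, strand, L) {
  if (strand == "+") {
    substr(genome, position, position + L - 1L)
  } else {
    revcomp(substr(genome, position - L + 1L, position))
  }
}
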