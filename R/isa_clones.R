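# Integration-site clone calling: reads sharing an alignment set are
# grouped, a consensus is built per group by center-star multiple
# alignment with per-column majority vote, unaligned reads are rescued
# by consensus identity, and groups are merged within and across
# samples by locus and sequence-similarity rules.

# Center-star consensus: members aligned globally to the most frequent
# member sequence (ties broken lexicographically); per-column majority
# vote weighted by sequence multiplicity, ties resolved to the center
# base; majority-deletion columns are dropped.
consensus_sequence <- function(inserts) {
  tab <- table(inserts)
  ord <- order(-as.integer(tab), names(tab))
  center <- names(tab)[ord[1]]
  members <- names(tab)
  weights <- as.integer(tab)
  letters5 <- c("A", "C", "G", "T", "N", "-")
  clen <- nchar(center)
  votes <- matrix(0, nrow = clen, ncol = length(letters5),
                  dimnames = list(NULL, letters5))
  cbases <- strsplit(center, "", fixed = TRUE)[[1]]
  for (m in seq_along(members)) {
    if (members[m] == center) {
      idx <- match(cbases, letters5, nomatch = 5L)
      votes[cbind(seq_len(clen), idx)] <-
        votes[cbind(seq_len(clen), idx)] + weights[m]
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = members[m], subject = center, type = "global",
      substitutionMatrix = isa_submat(), gapOpening = 2, gapExtension = 1)
    pc <- strsplit(as.character(Biostrings::pattern(aln)), "", fixed = TRUE)[[1]]
    sc <- strsplit(as.character(Biostrings::subject(aln)), "", fixed = TRUE)[[1]]
    keep <- sc != "-"
    cpos <- cumsum(keep)[keep]
    pch <- pc[keep]
    idx <- match(pch, letters5, nomatch = 5L)
    for (j in seq_along(cpos)) {
      votes[cpos[j], idx[j]] <- votes[cpos[j], idx[j]] + weights[m]
    }
  }
  win <- vapply(seq_len(clen), function(i) {
    v <- votes[i, ]
    best <- max(v)
    cand <- letters5[v == best]
    if (cbases[i] %in% cand) cbases[i] else cand[1]
  }, character(1))
  paste(win[win != "-"], collapse = "")
}

#' Group aligned reads and build per-group consensus sequences
#'
#' Reads sharing an identical alignment set (all retained loci) are
#' combined into a group, processed in descending read-count order. Each
#' group gets a consensus insert via center-star multiple alignment with
#' per-column majority vote. Reads that produced no genome alignment are
#' then rescued: any unaligned insert with global identity at or above
#' `rescue_identity` to a group consensus joins that group (the best
#' matching group; ties go to the larger group).
#'
#' @param reads Tibble with `read_id` and `insert` (the post-filter
#'   reads, aligned or not).
#' @param alignments Retained alignments from [filter_alignments()].
#' @param rescue_identity Minimum consensus identity to rescue an
#'   unaligned read (default 0.90).
#' @return A tibble of clones: `clone_id`, `chrom`, `locus`, `strand`,
#'   `multi_align_ratio`, `consensus`, `n_reads`, `align_key`,
#'   `read_ids` (list column).
#' @export
group_and_consensus <- function(reads, alignments, rescue_identity = 0.90) {
  aligned_ids <- unique(alignments$read_id)
  key_of <- alignments |>
    dplyr::mutate(entry = paste(.data$chrom, .data$locus, .data$strand, sep = "_")) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(align_key = paste(sort(.data$entry), collapse = ";"),
                     .groups = "drop")
  reads_aligned <- dplyr::inner_join(reads, key_of, by = "read_id")
  groups <- split(reads_aligned, reads_aligned$align_key)
  ord <- order(-vapply(groups, nrow, integer(1)), names(groups))
  groups <- groups[ord]

  clones <- purrr::map_dfr(seq_along(groups), function(g) {
    grp <- groups[[g]]
    cons <- consensus_sequence(grp$insert)
    # representative alignment & ambiguity from the center read
    tab <- table(grp$insert)
    center <- names(tab)[order(-as.integer(tab), names(tab))[1]]
    center_read <- grp$read_id[match(center, grp$insert)]
    ca <- alignments[alignments$read_id == center_read, , drop = FALSE]
    best <- ca[which.max(ca$score), , drop = FALSE]
    tibble::tibble(
      align_key = grp$align_key[1],
      chrom = best$chrom, locus = best$locus, strand = best$strand,
      multi_align_ratio = multi_align_ratio(ca$score),
      consensus = cons,
      n_reads = nrow(grp),
      read_ids = list(sort(grp$read_id))
    )
  })

  unaligned <- reads[!reads$read_id %in% aligned_ids, , drop = FALSE]
  if (nrow(unaligned) && nrow(clones)) {
    unaligned <- unaligned[order(unaligned$insert, unaligned$read_id), ]
    for (i in seq_len(nrow(unaligned))) {
      ins <- unaligned$insert[i]
      lens <- nchar(clones$consensus)
      plausible <- which(pmin(lens, nchar(ins)) / pmax(lens, nchar(ins)) >=
                           rescue_identity)
      if (!length(plausible)) next
      ident <- vapply(clones$consensus[plausible], function(cons) {
        alignment_identity(ins, cons, type = "global")
      }, numeric(1), USE.NAMES = FALSE)
      if (max(ident) >= rescue_identity) {
        j <- plausible[which.max(ident)]
        clones$n_reads[j] <- clones$n_reads[j] + 1L
        clones$read_ids[[j]] <- sort(c(clones$read_ids[[j]], unaligned$read_id[i]))
      }
    }
  }
  if (!nrow(clones)) return(clones)
  clones <- clones[order(-clones$n_reads, clones$align_key), ]
  clones$clone_id <- sprintf("clone%03d", seq_len(nrow(clones)))
  clones[, c("clone_id", "chrom", "locus", "strand", "multi_align_ratio",
             "consensus", "n_reads", "align_key", "read_ids")]
}

#' Merge clones within and across samples of one subject
#'
#' Applies the clone-identity merge rules as a transitive closure over
#' per-sample groups:
#'
#' 1. within a sample, groups whose consensus sequences are at least
#'    `merge_identity` identical (global alignment) are merged;
#' 2. groups with exactly matching alignment sets share one clone ID;
#' 3. groups with exactly matching consensus sequences share one clone ID;
#' 4. non-uniquely aligned groups (multi-align-ratio at or above
#'    `multi_align_min`) with consensus identity at or above
#'    `merge_identity` share one clone ID.
#'
#' Per-sample read counts are preserved (rows merged within one sample
#' sum their counts); each merged clone's representative locus,
#' consensus and ambiguity come from its highest-count member.
#'
#' @param clones Tibble from [group_and_consensus()], optionally with a
#'   `sample` column when several samples are combined.
#' @param merge_identity Consensus similarity threshold (default 0.90).
#' @param multi_align_min Multi-align-ratio at or above which a group
#'   counts as non-uniquely aligned (default 0.9).
#' @return A tibble with one row per clone and sample: `clone_id`,
#'   `sample`, `chrom`, `locus`, `strand`, `multi_align_ratio`,
#'   `consensus`, `n_reads`, `read_ids`.
#' @export
merge_clones <- function(clones, merge_identity = 0.90, multi_align_min = 0.9) {
  if (!nrow(clones)) return(clones)
  if (!"sample" %in% names(clones)) clones$sample <- "S1"
  n <- nrow(clones)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  sim_cache <- new.env(parent = emptyenv())
  sim <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
    a <- clones$consensus[i]; b <- clones$consensus[j]
    la <- nchar(a); lb <- nchar(b)
    val <- if (min(la, lb) / max(la, lb) < merge_identity) 0
           else alignment_identity(a, b, type = "global")
    sim_cache[[key]] <- val
    val
  }

  ord <- order(-clones$n_reads, clones$align_key)
  for (ii in seq_len(n - 1)) {
    for (jj in seq.int(n, ii + 1)) {
      i <- ord[ii]; j <- ord[jj]
      same_sample <- clones$sample[i] == clones$sample[j]
      if (clones$align_key[i] == clones$align_key[j] ||
          clones$consensus[i] == clones$consensus[j]) {
        union_(i, j)
      } else if ((same_sample ||
                  (clones$multi_align_ratio[i] >= multi_align_min &&
                   clones$multi_align_ratio[j] >= multi_align_min)) &&
                 sim(i, j) >= merge_identity) {
        union_(i, j)
      }
    }
  }

  clones$group <- vapply(seq_len(n), find, integer(1))
  merged <- clones |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      rep_row <- df[order(-df$n_reads, df$align_key)[1], ]
      df |>
        dplyr::group_by(.data$sample) |>
        dplyr::summarise(n_reads = sum(.data$n_reads),
                         read_ids = list(sort(unlist(.data$read_ids))),
                         .groups = "drop") |>
        dplyr::mutate(chrom = rep_row$chrom, locus = rep_row$locus,
                      strand = rep_row$strand,
                      multi_align_ratio = rep_row$multi_align_ratio,
                      consensus = rep_row$consensus,
                      align_key = rep_row$align_key)
    }) |>
    dplyr::ungroup()
  totals <- merged |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(total = sum(.data$n_reads), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total))
  totals$clone_id <- sprintf("clone%03d", seq_len(nrow(totals)))
  merged <- dplyr::left_join(merged, totals[, c("group", "clone_id")], by = "group")
  merged <- merged[order(match(merged$clone_id, totals$clone_id), merged$sample), ]
  merged[, c("clone_id", "sample", "chrom", "locus", "strand",
             "multi_align_ratio", "consensus", "n_reads", "align_key",
             "read_ids")]
}

#' Per-sample clone frequencies with ribbon flags
#'
#' Divides each clone's read count by the total reads attributed to any
#' clone in the sample. Clones at or above `ribbon_min` frequency are
#' flagged for individual (colored-ribbon) display; the rest are pooled
#' into a grouped remainder when plotting.
#'
#' @param clones Merged clone tibble from [merge_clones()] (columns
#'   `clone_id`, `sample`, `n_reads`).
#' @param ribbon_min Minimum frequency for an individual ribbon
#'   (default 0.01).
#' @return A tibble `clone_id`, `sample`, `n_reads`, `frequency`,
#'   `ribbon` (logical).
#' @export
clone_frequencies <- function(clones, ribbon_min = 0.01) {
  if (!"sample" %in% names(clones)) clones$sample <- "S1"
  if (!nrow(clones) || sum(clones$n_reads) < 1) {
    abort("no clone-associated reads in the sample.")
  }
  clones |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(frequency = .data$n_reads / sum(.data$n_reads),
                  ribbon = .data$frequency >= ribbon_min) |>
    dplyr::ungroup() |>
    dplyr::select("clone_id", "sample", "n_reads", "frequency", "ribbon")
}

#' Construct a gene model from gene and exon interval tables
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive gene spans).
#' @param exons Optional data frame with the same columns giving exon
#'   intervals (within their gene spans). When omitted, genes are
#'   treated as single-exon.
#' @return A list of class `clonekin_gene_model` with `genes` and
#'   `exons` as `GRanges`.
#' @export
gene_model <- function(genes, exons = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    gene_id = genes$gene_id)
  if (is.null(exons)) exons <- genes
  er <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    gene_id = exons$gene_id)
  structure(list(genes = gr, exons = er), class = "clonekin_gene_model")
}

#' Read a gene model from a BED or GFF3 file
#'
#' BED12 exon blocks are used as exons when present; otherwise each
#' record is a single-exon gene. For GFF3, `gene` and `exon` features
#' are used.
#'
#' @param path Path to a BED/BED12 or GFF3 file.
#' @return A `clonekin_gene_model` (see [gene_model()]).
#' @export
read_gene_model <- function(path) {
  fmt <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    genes <- gr[tolower(as.character(gr$type)) == "gene"]
    exons <- gr[tolower(as.character(gr$type)) == "exon"]
    gid <- if (!is.null(genes$ID)) genes$ID else genes$Name
    eid <- if (!is.null(exons$Parent)) as.character(unlist(exons$Parent)) else exons$Name
    genes$gene_id <- gid
    exons$gene_id <- eid
  } else {
    genes <- gr
    genes$gene_id <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    if (!is.null(gr$blocks)) {
      exons <- rtracklayer::blocks(gr)
      ids <- rep(genes$gene_id, lengths(exons))
      exons <- unlist(exons, use.names = FALSE)
      exons$gene_id <- ids
    } else {
      exons <- genes
    }
  }
  structure(list(genes = genes, exons = exons), class = "clonekin_gene_model")
}

#' Classify integration sites as exonic, intronic or intergenic
#'
#' A site falls in an `exon` when its locus overlaps any exon interval,
#' in an `intron` when it lies within a gene span but outside all exons,
#' and is `intergenic` otherwise. The strand of the site does not affect
#' the classification.
#'
#' @param sites Tibble with `chrom` and `locus` (1-based) columns.
#' @param model A [gene_model()] or [read_gene_model()] result.
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   supplied, loci outside their chromosome raise an error.
#' @return `sites` with added columns `category` and `gene_id` (`NA`
#'   for intergenic sites).
#' @export
annotate_sites <- function(sites, model, chrom_sizes = NULL) {
  if (!inherits(model, "clonekin_gene_model")) {
    abort("`model` must be a clonekin_gene_model.")
  }
  if (!is.null(chrom_sizes)) {
    bad <- sites$locus < 1 |
      sites$locus > chrom_sizes[as.character(sites$chrom)]
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      abort("site locus outside chromosome bounds.")
    }
  }
  pts <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$locus, width = 1))
  in_exon <- GenomicRanges::findOverlaps(pts, model$exons, select = "first",
                                         ignore.strand = TRUE)
  in_gene <- GenomicRanges::findOverlaps(pts, model$genes, select = "first",
                                         ignore.strand = TRUE)
  category <- dplyr::case_when(
    !is.na(in_exon) ~ "exon",
    !is.na(in_gene) ~ "intron",
    TRUE ~ "intergenic")
  gene_id <- ifelse(!is.na(in_exon), model$exons$gene_id[in_exon],
                    ifelse(!is.na(in_gene), model$genes$gene_id[in_gene],
                           NA_character_))
  sites$category <- category
  sites$gene_id <- gene_id
  tibble::as_tibble(sites)
}

#' Integration sites expanded or contracted between two samples
#'
#' Compares per-clone frequencies between an infusion-product sample and
#' a post-infusion sample and lists clones whose relative abundance
#' changed at least `fold`-fold in either direction. A clone undetected
#' on one side is given a pseudo-frequency of half the reciprocal of
#' that sample's clone-read total so the fold rule stays defined.
#'
#' @param freqs Output of [clone_frequencies()].
#' @param ip_sample,post_sample Sample identifiers to compare.
#' @param fold Fold-change threshold (default 5).
#' @return A tibble `clone_id`, `ip_freq`, `post_freq`, `ratio`,
#'   `class` (`expanded` / `contracted` / `neither`).
#' @export
fold_change_sites <- function(freqs, ip_sample = "IP", post_sample, fold = 5) {
  totals <- freqs |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total = sum(.data$n_reads), .groups = "drop")
  get_total <- function(s) {
    t <- totals$total[totals$sample == s]
    if (!length(t)) abort(sprintf("sample `%s` not present in `freqs`.", s))
    t
  }
  pseudo_ip <- 0.5 / get_total(ip_sample)
  pseudo_post <- 0.5 / get_total(post_sample)
  wide <- freqs |>
    dplyr::filter(.data$sample %in% c(ip_sample, post_sample)) |>
    dplyr::select("clone_id", "sample", "frequency") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "frequency",
                       values_fill = 0)
  ip_freq <- wide[[ip_sample]] %||% rep(0, nrow(wide))
  post_freq <- wide[[post_sample]] %||% rep(0, nrow(wide))
  ratio <- ifelse(post_freq > 0, post_freq, pseudo_post) /
    ifelse(ip_freq > 0, ip_freq, pseudo_ip)
  out <- tibble::tibble(
    clone_id = wide$clone_id,
    ip_freq = ip_freq, post_freq = post_freq, ratio = ratio,
    class = dplyr::case_when(
      post_freq > 0 & ratio >= fold ~ "expanded",
      ip_freq > 0 & ratio <= 1 / fold ~ "contracted",
      TRUE ~ "neither"))
  out[out$ip_freq > 0 | out$post_freq > 0, , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the integration-site clone-calling pipeline end to end
#'
#' Applies, in order: LTR identity filtering and trimming, vector
#' contamination filtering, k-mer seeded genome alignment, alignment
#' length/start filtering, grouping with consensus building and
#' unaligned-read rescue, clone merging within and across samples, and
#' per-sample frequency calculation.
#'
#' @param reads Tibble with `read_id`, `sequence`, and optionally
#'   `sample` (defaults to one sample `"S1"`).
#' @param genome Named character vector of chromosome sequences, or a
#'   prebuilt [genome_index()].
#' @param ltr_seq,vector_seq Reference LTR and internal vector sequences.
#' @param linker_seq Optional linker (ligated adapter) sequence; when
#'   supplied it is trimmed off the 3' end of each insert before the
#'   vector comparison and genome alignment.
#' @param model Optional [gene_model()] for site annotation.
#' @param min_ltr_identity,max_vector_identity,min_align_length,max_align_start,top_score_frac,rescue_identity,merge_identity,multi_align_min,ribbon_min
#'   Pipeline thresholds (defaults 0.90, 0.80, 30, 10, 0.95, 0.90, 0.90,
#'   0.9, 0.01).
#' @return A list of class `clonekin_isa`: `clones` (merged per-sample
#'   clone table), `frequencies`, `sites` (unique clone loci, annotated
#'   when `model` is given), and `stats` (read counts surviving each
#'   stage).
#' @export
call_integration_sites <- function(reads, genome, ltr_seq, vector_seq,
                                   linker_seq = NULL,
                                   model = NULL,
                                   min_ltr_identity = 0.90,
                                   max_vector_identity = 0.80,
                                   min_align_length = 30,
                                   max_align_start = 10,
                                   top_score_frac = 0.95,
                                   rescue_identity = 0.90,
                                   merge_identity = 0.90,
                                   multi_align_min = 0.9,
                                   ribbon_min = 0.01) {
  if (!"sample" %in% names(reads)) reads$sample <- "S1"
  index <- if (inherits(genome, "clonekin_genome_index")) genome
           else genome_index(genome)
  per_sample <- purrr::map_dfr(sort(unique(reads$sample)), function(s) {
    rs <- reads[reads$sample == s, c("read_id", "sequence")]
    ltr_pass <- filter_ltr(rs, ltr_seq, min_identity = min_ltr_identity)
    if (!is.null(linker_seq)) ltr_pass <- trim_linker(ltr_pass, linker_seq)
    vec_pass <- filter_vector(ltr_pass, vector_seq,
                              max_identity = max_vector_identity)
    alns <- align_inserts(vec_pass, index, top_score_frac = top_score_frac)
    alns <- filter_alignments(alns, min_align_length = min_align_length,
                              max_align_start = max_align_start)
    cl <- group_and_consensus(vec_pass, alns, rescue_identity = rescue_identity)
    if (nrow(cl)) cl$sample <- s
    attr(cl, "stats") <- tibble::tibble(
      sample = s, n_input = nrow(rs), n_ltr_pass = nrow(ltr_pass),
      n_vector_pass = nrow(vec_pass),
      n_aligned = length(unique(alns$read_id)),
      n_in_clones = sum(cl$n_reads))
    cl
  })
  merged <- merge_clones(per_sample, merge_identity = merge_identity,
                         multi_align_min = multi_align_min)
  freqs <- clone_frequencies(merged, ribbon_min = ribbon_min)
  sites <- merged |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(chrom = .data$chrom[1], locus = .data$locus[1],
                     strand = .data$strand[1],
                     multi_align_ratio = .data$multi_align_ratio[1],
                     n_reads = sum(.data$n_reads), .groups = "drop")
  if (!is.null(model)) sites <- annotate_sites(sites, model)
  structure(list(clones = merged, frequencies = freqs, sites = sites,
                 stats = tibble::tibble(
                   n_input = nrow(reads),
                   n_clones = nrow(sites),
                   n_reads_in_clones = sum(merged$n_reads))),
            class = "clonekin_isa")
}
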