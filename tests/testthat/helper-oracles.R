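# Independent brute-force oracles. These deliberately avoid the package
# code paths they check: plain loops over definitions.

oracle_entropy <- function(counts, base = exp(1)) {
  total <- sum(counts)
  h <- 0
  for (x in counts) {
    if (x > 0) h <- h - (x / total) * log(x / total, base = base)
  }
  h
}

oracle_morisita <- function(a, b) {
  ids <- union(names(a), names(b))
  num <- 0; pa2 <- 0; qb2 <- 0
  for (id in ids) {
    p <- if (id %in% names(a)) a[[id]] / sum(a) else 0
    q <- if (id %in% names(b)) b[[id]] / sum(b) else 0
    num <- num + p * q
    pa2 <- pa2 + p^2
    qb2 <- qb2 + q^2
  }
  2 * num / (pa2 + qb2)
}

# competition rank: 1 + number of strictly larger counts
oracle_rank <- function(counts) {
  vapply(counts, function(x) 1L + sum(counts > x), integer(1))
}

# two-sided Fisher exact p for a 2x2 table via hypergeometric enumeration:
# sum of all table probabilities not exceeding the observed one
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact distribution of the downsampled-entropy statistic for a
# two-clonotype sample: enumerate hypergeometric outcomes
oracle_two_clone_downsampled_median <- function(n1, n2, depth) {
  ks <- max(0, depth - n2):min(depth, n1)
  w <- dhyper(ks, n1, n2, depth)
  h <- vapply(ks, function(k) oracle_entropy(c(k, depth - k)), numeric(1))
  ord <- order(h)
  h <- h[ord]; w <- w[ord]
  h[which(cumsum(w) >= 0.5)[1]]
}

# expand per-clonotype cell counts into a cell table
make_cells <- function(counts, timepoint, cluster = NA_integer_) {
  tibble::tibble(
    cell_barcode = paste0(timepoint, "_", seq_len(sum(counts))),
    timepoint = timepoint,
    clonotype_id = rep(names(counts), counts),
    cluster = cluster,
    n_genes = 2500L, mito_fraction = 0.05, n_umis = 8000L
  )
}

# random small repertoire as a named count vector
random_repertoire <- function(n_clones = 8, max_count = 50) {
  counts <- sample.int(max_count, n_clones, replace = TRUE)
  names(counts) <- paste0("C", sample.int(10000, n_clones))
  counts
}

# mutate exactly k positions of a DNA string (deterministic given RNG)
mutate_k <- function(seq, k) {
  bases <- strsplit(seq, "")[[1]]
  at <- sample(seq_along(bases), k)
  for (i in at) bases[i] <- setdiff(c("A", "C", "G", "T"), bases[i])[1]
  paste(bases, collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# minimal clone-row builder for merge_clones() inputs
clone_row <- function(consensus, locus, n_reads, sample = "S1", strand = "+",
                      chrom = "chr1", ratio = 0,
                      align_key = paste(chrom, locus, strand, sep = "_")) {
  tibble::tibble(clone_id = NA_character_, chrom = chrom, locus = locus,
                 strand = strand, multi_align_ratio = ratio,
                 consensus = consensus, n_reads = n_reads,
                 align_key = align_key,
                 read_ids = list(character(0)), sample = sample)
}
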