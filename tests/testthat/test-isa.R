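# Shared toy fixture: a deterministic genome with one duplicated segment
# for multi-mapping tests.
local_isa_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) {
      set.seed(99)
      genome <- rand_dna(8000)
      dup <- substr(genome, 1001, 1150)
      genome <- paste0(genome, rand_dna(200), dup, rand_dna(200))
      fx <<- list(genome = c(chr1 = genome), # segment 1001-1150 repeats at 8201
                  ltr = rand_dna(50), vector = rand_dna(400),
                  index = genome_index(c(chr1 = genome)))
    }
    fx
  }
})

test_that("LTR filter trims exact prefixes and applies the 90% boundary", {
  fx <- local_isa_fixture()
  set.seed(10)
  insert <- rand_dna(80)
  reads <- tibble::tibble(read_id = "r1", sequence = paste0(fx$ltr, insert))
  out <- filter_ltr(reads, fx$ltr)
  expect_equal(out$ltr_identity, 1)
  expect_identical(out$insert, insert)

  # 85% LTR identity is rejected, 90% exactly is retained
  ltr40 <- rand_dna(40)
  r85 <- tibble::tibble(read_id = "r", sequence = paste0(mutate_k(ltr40, 6), insert))
  r90 <- tibble::tibble(read_id = "r", sequence = paste0(mutate_k(ltr40, 4), insert))
  expect_equal(nrow(filter_ltr(r85, ltr40)), 0L)
  kept <- filter_ltr(r90, ltr40)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$ltr_identity, 0.9)
  expect_error(filter_ltr(reads, ""), "non-empty")
})

test_that("vector filter rejects vector inserts including the 80% boundary", {
  fx <- local_isa_fixture()
  set.seed(11)
  vec_insert <- substr(fx$vector, 51, 150)
  genomic <- rand_dna(100)
  reads <- tibble::tibble(read_id = c("v", "g"),
                          insert = c(vec_insert, genomic))
  kept <- filter_vector(reads, fx$vector)
  expect_identical(kept$read_id, "g")
  expect_lt(kept$vector_identity, 0.8)

  r80 <- tibble::tibble(read_id = "b", insert = mutate_k(vec_insert, 20))
  expect_equal(nrow(filter_vector(r80, fx$vector)), 0L)
})

test_that("alignment finds planted loci, strands, and duplicated segments", {
  fx <- local_isa_fixture()
  g <- fx$genome[["chr1"]]
  insert <- substr(g, 3001, 3100)
  aln <- align_inserts(tibble::tibble(read_id = "r1", insert = insert), fx$index)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$locus, 3001L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$align_start, 0L)
  expect_gte(aln$align_length, 100L)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(insert)))
  aln_rc <- align_inserts(tibble::tibble(read_id = "r2", insert = rc), fx$index)
  expect_equal(aln_rc$strand, "-")
  expect_equal(aln_rc$locus, 3100L)

  # duplicated segment: two equal-score alignments survive the 95% rule
  dup_insert <- substr(g, 1001, 1100)
  aln_dup <- align_inserts(tibble::tibble(read_id = "r3", insert = dup_insert),
                           fx$index)
  expect_equal(nrow(aln_dup), 2L)
  expect_equal(aln_dup$score[1], aln_dup$score[2])
  expect_equal(multi_align_ratio(aln_dup$score), 1.0)
})

test_that("alignment length/start filters apply at their printed boundaries", {
  mk <- function(len, start) tibble::tibble(
    read_id = "r", chrom = "chr1", locus = 1L, strand = "+",
    score = len, align_length = len, align_start = start)
  expect_equal(nrow(filter_alignments(mk(29, 0))), 0L)
  expect_equal(nrow(filter_alignments(mk(30, 11))), 0L)
  expect_equal(nrow(filter_alignments(mk(30, 10))), 1L)
})

test_that("multi-align ratio is 0 for unique hits and second/best otherwise", {
  expect_equal(multi_align_ratio(57), 0)
  expect_equal(multi_align_ratio(c(80, 80)), 1)
  expect_equal(multi_align_ratio(c(95, 100)), 0.95)
  expect_error(multi_align_ratio(numeric(0)), "at least one")
})

test_that("grouping builds consensus and rescues near-identical unaligned reads", {
  fx <- local_isa_fixture()
  g <- fx$genome[["chr1"]]
  insert <- substr(g, 4001, 4100)
  reads <- tibble::tibble(read_id = sprintf("r%02d", 1:10),
                          insert = rep(insert, 10))
  alns <- align_inserts(reads, fx$index)
  clones <- group_and_consensus(reads, alns)
  expect_equal(nrow(clones), 1L)
  expect_equal(clones$n_reads, 10L)
  expect_identical(clones$consensus, insert)
  expect_equal(clones$locus, 4001L)

  # a 2%-substituted read with simulated alignment dropout is rescued
  set.seed(12)
  noisy <- mutate_k(insert, 2)
  reads2 <- dplyr::bind_rows(reads[1:9, ],
                             tibble::tibble(read_id = "r99", insert = noisy))
  alns9 <- align_inserts(reads2[1:9, ], fx$index) # r99 left unaligned
  clones2 <- group_and_consensus(reads2, alns9)
  expect_equal(clones2$n_reads, 10L)
  expect_true("r99" %in% clones2$read_ids[[1]])

  # an unrelated unaligned read stays unassigned
  set.seed(13)
  reads3 <- dplyr::bind_rows(reads[1:9, ],
                             tibble::tibble(read_id = "far", insert = rand_dna(100)))
  clones3 <- group_and_consensus(reads3, alns9)
  expect_equal(clones3$n_reads, 9L)
  expect_false("far" %in% clones3$read_ids[[1]])
})

test_that("consensus majority vote fixes scattered substitutions", {
  set.seed(14)
  base <- rand_dna(120)
  members <- c(rep(base, 4),
               vapply(1:3, function(i) mutate_k(base, 3), character(1)))
  expect_identical(clonekin:::consensus_sequence(members), base)
})

test_that("clone merging applies locus, consensus and multi-align rules", {
  set.seed(15)
  cons <- rand_dna(100)
  # same locus in two samples: one clone id, per-sample counts kept
  m1 <- merge_clones(dplyr::bind_rows(
    clone_row(cons, 500, 30, sample = "IP"),
    clone_row(mutate_k(cons, 1), 500, 10, sample = "d28")))
  expect_equal(length(unique(m1$clone_id)), 1L)
  expect_equal(sort(m1$n_reads), c(10L, 30L))

  # 89% consensus similarity between uniquely mapped clones at
  # different loci in different samples: not merged
  m2 <- merge_clones(dplyr::bind_rows(
    clone_row(cons, 500, 30, sample = "IP"),
    clone_row(mutate_k(cons, 11), 900, 10, sample = "d28")))
  expect_equal(length(unique(m2$clone_id)), 2L)

  # but within one sample, >=90% similarity merges (counts sum)
  m3 <- merge_clones(dplyr::bind_rows(
    clone_row(cons, 500, 30, sample = "IP"),
    clone_row(mutate_k(cons, 8), 900, 10, sample = "IP")))
  expect_equal(length(unique(m3$clone_id)), 1L)
  expect_equal(m3$n_reads, 40L)

  # multi-aligned groups with 92%-similar consensus merge across samples
  m4 <- merge_clones(dplyr::bind_rows(
    clone_row(cons, 500, 30, sample = "IP", ratio = 0.95),
    clone_row(mutate_k(cons, 8), 900, 10, sample = "d28", ratio = 0.95)))
  expect_equal(length(unique(m4$clone_id)), 1L)
  # representative locus comes from the higher-count member
  expect_equal(unique(m4$locus), 500)
})

test_that("clone frequencies sum to one per sample and flag ribbon clones", {
  clones <- dplyr::bind_rows(
    clone_row("A", 1, 60), clone_row("C", 2, 30), clone_row("G", 3, 10))
  fr <- clone_frequencies(clones)
  expect_equal(sort(fr$frequency), c(0.1, 0.3, 0.6))
  expect_true(all(fr$ribbon))

  many <- dplyr::bind_rows(clone_row("A", 1, 995), clone_row("C", 2, 5))
  fr2 <- clone_frequencies(many)
  expect_equal(fr2$frequency[2], 0.005)
  expect_false(fr2$ribbon[2]) # 0.5% clone pooled into the gray remainder
  expect_equal(sum(fr2$frequency), 1)
  expect_error(clone_frequencies(clones[0, ]), "no clone")
})

test_that("site annotation distinguishes exon, intron and intergenic loci", {
  model <- gene_model(
    genes = tibble::tibble(gene_id = "GENE1", chrom = "chr1",
                           start = 1000, end = 2000),
    exons = tibble::tibble(gene_id = "GENE1", chrom = "chr1",
                           start = c(1000, 1500), end = c(1200, 1600)))
  sites <- tibble::tibble(chrom = "chr1", locus = c(1100, 1300, 500))
  ann <- annotate_sites(sites, model)
  expect_equal(ann$category, c("exon", "intron", "intergenic"))
  expect_equal(ann$gene_id, c("GENE1", "GENE1", NA))
  expect_error(annotate_sites(tibble::tibble(chrom = "chr1", locus = 99999),
                              model, chrom_sizes = c(chr1 = 5000)),
               "bounds")
})

test_that("gene models round-trip through BED12", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 999, 2000, "GENE1", 0, "+", 999, 2000, "0",
                     2, "201,100", "0,500"), collapse = "\t"), path)
  model <- read_gene_model(path)
  ann <- annotate_sites(tibble::tibble(chrom = "chr1",
                                       locus = c(1100, 1300, 2500)), model)
  expect_equal(ann$category, c("exon", "intron", "intergenic"))
})

test_that("fold-change lists apply the 5-fold rule in both directions", {
  freqs <- dplyr::bind_rows(
    tibble::tibble(clone_id = c("a", "b", "c"), sample = "IP",
                   n_reads = c(2, 10, 20), frequency = c(0.002, 0.010, 0.020)),
    tibble::tibble(clone_id = c("a", "b", "c"), sample = "d28",
                   n_reads = c(15, 5, 2), frequency = c(0.015, 0.005, 0.002)))
  freqs$ribbon <- TRUE
  fc <- fold_change_sites(freqs, ip_sample = "IP", post_sample = "d28")
  expect_equal(fc$class[fc$clone_id == "a"], "expanded")   # 7.5-fold up
  expect_equal(fc$class[fc$clone_id == "b"], "neither")    # 2-fold down
  expect_equal(fc$class[fc$clone_id == "c"], "contracted") # 10-fold down
})

test_that("the pipeline output is invariant to input read order", {
  sim <- sim_isa_reads(genome_length = 1.5e4, n_sites = 8,
                       mean_reads_per_site = 6, substitution_rate = 0.005,
                       seed = 17)
  res1 <- call_integration_sites(sim$reads, sim$genome, sim$ltr_seq,
                                 sim$vector_seq)
  shuffled <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  res2 <- call_integration_sites(shuffled, sim$genome, sim$ltr_seq,
                                 sim$vector_seq)
  expect_identical(res1$sites, res2$sites)
  expect_identical(res1$frequencies, res2$frequencies)
})

test_that("exact vector contaminants never survive the read filters", {
  sim <- sim_isa_reads(genome_length = 1.5e4, n_sites = 6,
                       mean_reads_per_site = 6, substitution_rate = 0,
                       contaminant_fraction = 0.3, seed = 18)
  kept <- filter_ltr(sim$reads, sim$ltr_seq) |>
    trim_linker(sim$linker_seq) |>
    filter_vector(sim$vector_seq)
  expect_gt(sum(is.na(sim$reads$true_site)), 0)
  expect_false(any(is.na(kept$true_site)))
})
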