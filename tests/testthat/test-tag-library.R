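test_that("quality trimming truncates at the first passing 3' block", {
  # all high quality: unchanged
  r_hi <- make_reads(strrep("ACGT", 25))
  expect_identical(trim_reads(r_hi)$bases, r_hi$bases)

  # all low quality: dropped entirely
  r_lo <- make_reads(strrep("ACGT", 25),
                     quals = qual_string(rep(5L, 100)))
  expect_equal(nrow(trim_reads(r_lo, min_len = 1)), 0)

  # 60 bases at Q40 then 40 at Q2: trimmed to exactly 60
  r_mix <- make_reads(strrep("A", 100),
                      quals = qual_string(c(rep(40L, 60), rep(2L, 40))))
  out <- trim_reads(r_mix, window = 10, min_mean_q = 20, min_len = 50)
  expect_equal(nchar(out$bases), 60)
  expect_equal(nchar(out$quals), 60)

  # empty input passes through; order is preserved
  expect_equal(nrow(trim_reads(make_reads(character(0)))), 0)
  r_many <- make_reads(vapply(1:20, function(i) rand_dna(80, i), character(1)))
  expect_identical(trim_reads(r_many, min_len = 10)$read_id, r_many$read_id)
})

test_that("greedy clustering separates divergent sequences and counts tissues", {
  s1 <- rand_dna(200, 31)
  s2 <- mutate_many(s1, 0.30)
  reads <- make_reads(c(rep(s1, 3), rep(s2, 2)))
  cl <- cluster_tags(reads, min_identity = 0.95)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$total, c(3, 2))
  expect_equal(cl$cluster_id, c("000001", "000002"))

  one <- cluster_tags(make_reads(rand_dna(150, 32), tissue = "ME"))
  expect_equal(unname(unlist(one[1, c("ME", "P", "PS")])), c(1, 0, 0))
})

test_that("zero-error clustering recovers the simulated genes and counts", {
  tr <- simulate_transcriptome(20, 4, 4, seed = 41,
                               seq_len_range = c(300, 500))
  cts <- sample_read_counts(tr, c(700, 700, 700), seed = 42)
  rd <- emit_tag_reads(tr, cts, read_len = 150,
                       error_mod = error_model(substitution_rate = 0,
                                               low_quality_tail_len = 0),
                       seed = 43)
  cl <- cluster_tags(rd)
  expressed <- rowSums(cts) > 0
  expect_equal(nrow(cl), sum(expressed))
  expect_equal(sum(cl$total), nrow(rd))

  # map each cluster back to its source gene via the exact 3' tag
  tails <- substr(tr$genes$sequence, nchar(tr$genes$sequence) - 149,
                  nchar(tr$genes$sequence))
  src <- tr$genes$gene_id[match(cl$representative, tails)]
  expect_false(anyNA(src))
  expect_equal(unname(as.matrix(cl[, c("ME", "P", "PS")])),
               unname(cts[src, ]), ignore_attr = TRUE)
})

test_that("clustering is invariant to read order for well-separated genes", {
  tr <- simulate_transcriptome(10, 0, 0, seed = 51,
                               seq_len_range = c(250, 300))
  cts <- sample_read_counts(tr, c(150, 150, 150), seed = 52)
  rd <- emit_tag_reads(tr, cts, read_len = 120,
                       error_mod = error_model(substitution_rate = 0,
                                               low_quality_tail_len = 0),
                       seed = 53)
  cl1 <- cluster_tags(rd)
  set.seed(99)
  cl2 <- cluster_tags(rd[sample(nrow(rd)), ])
  expect_equal(nrow(cl1), nrow(cl2))
  ord1 <- order(cl1$representative)
  ord2 <- order(cl2$representative)
  expect_equal(cl1[ord1, c("representative", "ME", "P", "PS", "total")],
               cl2[ord2, c("representative", "ME", "P", "PS", "total")],
               ignore_attr = TRUE)
})

test_that("library summary reports read and contig statistics", {
  cl <- structure(data.frame(
    cluster_id = c("000001", "000002"),
    representative = c(strrep("A", 120), strrep("C", 80)),
    ME = c(2L, 1L), P = c(2L, 2L), PS = c(1L, 0L),
    total = c(5L, 3L), length_bp = c(120L, 80L),
    stringsAsFactors = FALSE), class = c("gene_clusters", "data.frame"))
  rd <- make_reads(c(strrep("A", 100), strrep("C", 60)))
  s <- library_summary(cl, rd)
  expect_equal(s$n_reads_total, 8)
  expect_equal(s$mean_reads_per_contig, 4.0)
  expect_equal(unname(s$n_reads_per_tissue), c(3, 4, 1))
  expect_equal(unname(s$n_clusters_per_tissue), c(2, 2, 1))
  expect_equal(s$mean_read_len, 80)
  expect_equal(s$max_contig_len, 120)
  expect_error(library_summary(cl[0, ], rd), "empty")
})

test_that("reads survive a FASTQ round-trip with tissue labels intact", {
  tr <- simulate_transcriptome(5, 1, 1, seed = 61,
                               seq_len_range = c(250, 300))
  cts <- sample_read_counts(tr, c(40, 40, 40), seed = 62)
  rd <- emit_tag_reads(tr, cts, read_len = 100, seed = 63)
  dir <- withr::local_tempdir()
  paths <- write_tag_fastq(rd, dir)
  back <- read_tag_reads(unname(paths))
  expect_equal(nrow(back), nrow(rd))
  m <- match(rd$read_id, back$read_id)
  expect_false(anyNA(m))
  expect_equal(back$bases[m], rd$bases)
  expect_equal(back$quals[m], rd$quals)
  expect_equal(back$tissue[m], rd$tissue)
})
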