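test_that("local alignment reproduces its documented examples", {
  self <- smith_waterman("ACGT", "ACGT", match = 2)
  expect_equal(self$score, 8)
  expect_equal(self$identity, 1.0)
  expect_equal(c(self$a_start, self$a_end), c(0, 4))

  none <- smith_waterman("AAAA", "TTTT", match = 2, mismatch = -3)
  expect_equal(none$score, 0)
  expect_equal(none$aln_len, 0)

  # single-gap example under linear gap costs (open == extend)
  gap <- smith_waterman("ACGTT", "ACTT", match = 2, mismatch = -1,
                        gap_open = 2, gap_extend = 2)
  expect_equal(gap$score, 6)
  expect_equal(gap$score, sw_brute("ACGTT", "ACTT", 2, -1, 2, 2))

  expect_error(smith_waterman("ACGT", "MKLV"), "alphabet")
  expect_error(smith_waterman("", "ACGT"), "non-empty")
})

test_that("aligner is symmetric and maximal for self-alignment", {
  set.seed(5)
  for (i in 1:15) {
    a <- rand_dna(sample(10:60, 1))
    b <- rand_dna(sample(10:60, 1))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
    expect_equal(smith_waterman(a, a)$score, 2 * nchar(a))
  }
})

test_that("aligner equals the exhaustive path oracle on short strings", {
  strings <- all_strings(c("A", "C"), 3)
  for (a in strings) for (b in strings) {
    expect_equal(smith_waterman(a, b)$score, sw_brute(a, b),
                 info = paste(a, b))
  }
  # sampled longer pairs, both oracles
  set.seed(42)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C"), sample(4:6, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C"), sample(4:6, 1), TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score, sw_brute(a, b),
                 info = paste(a, b))
    expect_equal(smith_waterman(a, b)$score, sw_biostrings(a, b),
                 info = paste(a, b))
  }
})

test_that("aligner matches Biostrings on random nucleotide pairs", {
  set.seed(11)
  for (i in 1:10) {
    a <- rand_dna(80)
    b <- if (i %% 2) mutate_many(a, 0.2, seed = i) else rand_dna(70)
    expect_equal(smith_waterman(a, b)$score, sw_biostrings(a, b))
  }
})

test_that("six-frame translation follows the standard genetic code", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr[["+1"]], "MK")
  expect_equal(fr[["-1"]], "FH")   # revcomp is TTTCAT
  # frame +2 of a 7-base sequence: floor((7 - 1) / 3) = 2 residues
  expect_equal(nchar(six_frame_translate("ATGAAAG")[["+2"]]), 2)
  expect_equal(six_frame_translate("ATGTAA")[["+1"]], "M*")
  expect_equal(six_frame_translate("ATGNAA")[["+1"]], "MX")
})

test_that("marker search finds exact, mutated and translated targets", {
  set.seed(61)
  genes <- c(rand_dna(300), rand_dna(300), rand_dna(300))
  marker_nt <- genes[1]
  iso <- mutate_many(genes[2], 0.10, seed = 62)      # 90% identity isoform
  clusters <- data.frame(cluster_id = sprintf("%06d", 1:3),
                         representative = genes, stringsAsFactors = FALSE)
  panel <- marker_panel(c("mkA", "mkB"), c("nacreous", "prismatic"),
                        c("nucleotide", "nucleotide"),
                        c(marker_nt, iso))
  hits <- marker_search(clusters, panel, min_identity = 0.8)
  exact <- hits[hits$marker_id == "mkA" & hits$gene_id == "000001", ]
  expect_equal(exact$identity, 1.0)
  expect_equal(exact$frame, 0L)
  isohit <- hits[hits$marker_id == "mkB" & hits$gene_id == "000002", ]
  expect_equal(nrow(isohit), 1)
  expect_equal(isohit$identity, 0.90, tolerance = 0.03)
  # unrelated random sequences yield no hit at the default thresholds
  expect_false(any(hits$marker_id == "mkA" & hits$gene_id == "000003"))

  # reverse-complemented target is still found, on the minus strand
  rc_clusters <- data.frame(cluster_id = "000009",
                            representative = pearlscreen:::revcomp(marker_nt),
                            stringsAsFactors = FALSE)
  rc_hit <- marker_search(rc_clusters, panel[1, ])
  expect_equal(rc_hit$identity, 1.0)
  expect_equal(rc_hit$strand, "-")
})

test_that("protein markers are found through translated frames", {
  set.seed(71)
  prot <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  # back-translate with one codon per residue (unambiguous choice)
  codons <- c(M = "ATG", K = "AAA", T = "ACC", A = "GCC", Y = "TAC",
              I = "ATC", Q = "CAA", R = "CGC", S = "TCC", F = "TTC",
              V = "GTC", H = "CAC", L = "CTG", E = "GAA", G = "GGC")
  nt <- paste(codons[strsplit(prot, "")[[1]]], collapse = "")
  gene <- paste0(rand_dna(50), nt, rand_dna(40))
  clusters <- data.frame(cluster_id = c("000001", "000002"),
                         representative = c(gene,
                                            pearlscreen:::revcomp(gene)),
                         stringsAsFactors = FALSE)
  panel <- marker_panel("protM", "nacreous", "protein", prot)
  hits <- marker_search(clusters, panel, min_score = 30, min_identity = 0.9)
  expect_equal(nrow(hits), 2)
  fwd <- hits[hits$gene_id == "000001", ]
  rev <- hits[hits$gene_id == "000002", ]
  expect_true(fwd$frame > 0)
  expect_true(rev$frame < 0)
  expect_equal(fwd$identity, 1.0)
  # translated spans map back to the embedded ORF in forward coordinates
  expect_equal(fwd$gene_start, 50)
  expect_equal(fwd$gene_end, 50 + nchar(nt))
})

test_that("isoform grouping separates known, novel and diverged members", {
  set.seed(81)
  canonical <- rand_dna(240)
  novel <- mutate_many(canonical, 0.02, seed = 82)   # ~98% identity variant
  far <- mutate_many(canonical, 0.10, seed = 83)     # ~90%: too diverged
  clusters <- data.frame(cluster_id = sprintf("%06d", 1:3),
                         representative = c(canonical, novel, far),
                         stringsAsFactors = FALSE)
  panel <- marker_panel("mk", "nacreous", "nucleotide", canonical)
  hits <- marker_search(clusters, panel, min_score = 40, min_identity = 0.4)
  fams <- group_isoforms(hits, clusters, list(mk = canonical),
                         novel_min_identity = 0.95)
  known <- fams[fams$gene_id == "000001", ]
  expect_false(known$novel)
  expect_equal(known$variant_identity, 1.0)
  nv <- fams[fams$gene_id == "000002", ]
  expect_equal(nrow(nv), 1)
  expect_true(nv$novel)
  # below the membership floor: excluded from the family report
  expect_false("000003" %in% fams$gene_id)
  # identity-sorted within marker
  expect_equal(fams$gene_id, fams$gene_id[order(-fams$identity)])
})
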