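tab1_totals <- c(ME = 68690, P = 83692, PS = 108095)

fixture_em <- function(extra = NULL) {
  fx <- published_candidates()
  tpm <- as.matrix(fx[, c("tpm_me", "tpm_p", "tpm_ps")])
  rownames(tpm) <- fx$gene_id
  if (!is.null(extra)) tpm <- rbind(tpm, extra)
  counts <- invert_tpm(tpm, tab1_totals)
  compute_tpm(counts, tab1_totals)
}

test_that("the dominance rule reproduces the published candidate set", {
  v <- verify_candidate_table()
  expect_equal(v$n_pass, 29)
  expect_equal(v$n_rows, 29)
  expect_true(all(v$rows$screen_pass))
  # derived counts sum to the printed totals wherever the mantle-edge TPM
  # is recoverable
  expect_true(all(v$rows$sum_ok, na.rm = TRUE))
  rows <- v$rows
  expect_equal(rows$pass_reason[rows$gene_id == "000096"], "both")
  expect_equal(rows$pass_reason[rows$gene_id == "000464"], "pearl_sac")
  expect_equal(rows$pass_reason[rows$gene_id == "000858"], "pallium")
  expect_equal(rows$pass_reason[rows$gene_id == "000569"], "zero_ME")

  # a perturbed row is flagged, an empty fixture errors
  fx <- published_candidates()
  fx$tpm_me[fx$gene_id == "000280"] <- fx$tpm_me[fx$gene_id == "000280"] * 10
  v_bad <- verify_candidate_table(fx)
  expect_false(v_bad$rows$screen_pass[v_bad$rows$gene_id == "000280"])
  expect_error(verify_candidate_table(fx[0, ]), "empty")
})

test_that("nacre_screen applies strict fold dominance with read filtering", {
  em <- fixture_em(extra = matrix(c(1000, 1000, 1000), 1,
                                  dimnames = list("flat01", NULL)))
  res <- nacre_screen(em)
  expect_setequal(res$gene_id, published_candidates()$gene_id)
  expect_false("flat01" %in% res$gene_id)

  # boundary: 2x exactly is not "over 2 times higher"
  tpm_b <- matrix(c(100, 200, 150), 1,
                  dimnames = list("edge", c("ME", "P", "PS")))
  em_b <- compute_tpm(invert_tpm(tpm_b, rep(1e6, 3)), rep(1e6, 3))
  expect_equal(nrow(nacre_screen(em_b, min_total = 0)), 0)

  # low-count genes are ignored even with dominant profiles
  em_low <- compute_tpm(matrix(c(0L, 30L, 5L), 1,
                               dimnames = list("low", c("ME", "P", "PS"))),
                        c(ME = 1000, P = 1000, PS = 1000))
  expect_equal(nrow(nacre_screen(em_low, min_total = 40)), 0)
  expect_equal(nacre_screen(em_low, min_total = 10)$pass_reason, "zero_ME")
})

test_that("euclidean distance matches direct arithmetic", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  x <- c(437, 1446, 2701)
  expect_equal(euclidean_distance(x, x), 0)
  y <- c(218, 753, 500)
  expect_equal(euclidean_distance(x, y),
               sqrt(219^2 + 693^2 + 2201^2))
  expect_error(euclidean_distance(1:3, 1:4), "length")
})

test_that("average-linkage dendrogram has the documented small-case behaviour", {
  two <- matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  t2 <- hcluster(two)
  expect_equal(t2$height, 5)
  expect_equal(sort(t2$labels), c("a", "b"))

  three <- matrix(c(0, 0, 0,
                    0, 0, 1,
                    100, 100, 100), 3, 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  t3 <- hcluster(three)
  expect_equal(dendro_merged_sets(t3)[[1]], c("a", "b"))
  expect_equal(t3$height[1], 1)

  dup <- matrix(c(1, 2, 3, 1, 2, 3, 9, 9, 9), 3, 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(hcluster(dup)$height[1], 0)
  expect_error(hcluster(two[1, , drop = FALSE]), "at least 2")
})

test_that("dendrogram agrees with brute-force agglomeration and hclust", {
  set.seed(77)
  for (case in 1:25) {
    n <- sample(2:7, 1)
    m <- matrix(runif(n * 3, 0, 100), n, 3,
                dimnames = list(sprintf("g%02d", sample(99, n)), NULL))
    tree <- hcluster(m)
    oracle <- upgma_brute(m)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    expect_equal(dendro_merged_sets(tree), oracle$merged_sets)
    # heights are monotone non-decreasing toward the root
    expect_true(all(diff(tree$height) >= -1e-12))
    # independent implementation: same heights from stats::hclust
    hc <- stats::hclust(stats::dist(m), method = "average")
    expect_equal(sort(tree$height), sort(hc$height), tolerance = 1e-12)
  }
})

test_that("marker co-clustering retrieves the marker's neighbourhood", {
  prof <- matrix(c(100, 900, 700,   # M (marker, nacreous-like)
                   110, 880, 720,   # g1
                   105, 910, 690,   # g3
                   800, 100, 90,    # g2
                   820, 120, 80),   # K (marker, prismatic-like)
                 5, 3, byrow = TRUE,
                 dimnames = list(c("M", "g1", "g3", "g2", "K"), NULL))
  tree <- hcluster(prof)
  rep_mk <- marker_cocluster(tree, c("M", "K"))
  expect_equal(nrow(rep_mk$groups), 2)
  got_m <- rep_mk$hits$gene_id[rep_mk$hits$marker_ids == "M"]
  got_k <- rep_mk$hits$gene_id[rep_mk$hits$marker_ids == "K"]
  expect_setequal(got_m, c("g1", "g3"))
  expect_setequal(got_k, "g2")

  # identical-profile gene retrieved at height 0
  dup <- matrix(c(5, 5, 5, 5, 5, 5, 50, 1, 1, 80, 80, 1), 4, 3,
                byrow = TRUE, dimnames = list(c("M", "g1", "x", "y"), NULL))
  r0 <- marker_cocluster(hcluster(dup), "M", max_cluster_size = 2)
  expect_equal(r0$hits$gene_id, "g1")
  expect_equal(r0$hits$height, 0)

  # max_cluster_size = 1: the subtree is the leaf itself, empty retrieval
  r1 <- marker_cocluster(hcluster(prof), "M", max_cluster_size = 1)
  expect_equal(nrow(r1$hits), 0)
  expect_error(marker_cocluster(tree, "absent"), "not found")
})

test_that("tiered co-clustering recovers planted co-regulated partners", {
  # 6-gene nacreous module with equal base abundance (marker + 5 partners),
  # highly expressed; moderate tier gets its own marker + 2 partners.
  set.seed(123)
  n_other <- 12
  base <- c(rep(0.06, 6),                  # high-tier module
            rep(0.0035, 3),                # moderate-tier module
            runif(n_other, 0.001, 0.05))
  arch <- c(rep("nacreous", 6), rep("nacreous", 3),
            rep("housekeeping", n_other))
  A <- matrix(base, length(base), 3)
  A[arch == "nacreous", 2:3] <- A[arch == "nacreous", 2:3] * 4
  A <- A * exp(matrix(rnorm(length(A), 0, 0.05), nrow(A), 3))
  seqs <- vapply(seq_len(nrow(A)), function(i) rand_dna(300, 1000 + i),
                 character(1))
  tr <- make_truth(seqs, A, archetype = arch)
  cts <- sample_read_counts(tr, c(6000, 6000, 6000), seed = 9)
  em <- compute_tpm(cts)

  marker_high <- "g0001"; marker_mod <- "g0007"
  expect_gte(sum(cts[marker_high, ]), 200)
  expect_true(sum(cts[marker_mod, ]) >= 40 && sum(cts[marker_mod, ]) < 200)

  rep_t <- run_tiered_coclustering(em, c(marker_high, marker_mod))
  got_high <- rep_t$high$hits$gene_id
  expect_gte(length(intersect(got_high, sprintf("g%04d", 2:6))), 4)
  got_mod <- rep_t$moderate$hits$gene_id
  expect_gte(length(intersect(got_mod, c("g0008", "g0009"))), 1)

  # a marker below the moderate threshold is excluded with a warning
  low_truth <- make_truth(seqs[1:5], matrix(c(0.9, rep(0.025, 4)), 5, 3))
  low_cts <- sample_read_counts(low_truth, c(500, 500, 500), seed = 10)
  low_cts["g0002", ] <- c(5L, 5L, 5L)
  em_low <- compute_tpm(low_cts, c(ME = 500, P = 500, PS = 500))
  expect_warning(
    out <- run_tiered_coclustering(em_low, c("g0001", "g0002")),
    "excluded")
  expect_equal(out$excluded_markers, "g0002")
})
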