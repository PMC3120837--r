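# Independent oracles and fixture builders used across the suite.

# Brute-force local alignment by path enumeration: every start cell, every
# monotone move sequence, affine gap cost open + (L-1)*extend. The running
# score is recorded at every node; branches whose running score drops below
# zero are pruned (any such prefix is dominated by the alignment starting
# after it, and all starts are enumerated).
sw_brute <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                     gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0
  explore <- function(i, j, score, last) {
    # last: 0 diag, 1 gap consuming a, 2 gap consuming b
    if (score > best) best <<- score
    if (score < 0) return(invisible())
    if (i <= la && j <= lb) {
      s <- if (av[i] == bv[j]) match else mismatch
      explore(i + 1, j + 1, score + s, 0)
    }
    if (i <= la)
      explore(i + 1, j, score - if (last == 1) gap_extend else gap_open, 1)
    if (j <= lb)
      explore(i, j + 1, score - if (last == 2) gap_extend else gap_open, 2)
    invisible()
  }
  for (i in seq_len(la)) for (j in seq_len(lb)) explore(i, j, 0, 0)
  best
}

# Biostrings local alignment with the package's gap convention
# (gap of length L costs open + (L-1)*extend).
sw_biostrings <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  s <- Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = sm,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend))
  max(s, 0)
}

all_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(g, 1, paste, collapse = ""))
  }
  out
}

# From-scratch average-linkage agglomeration: group average distances are
# recomputed from the original distance matrix at every step (no Lance-
# Williams update), same lexicographic tie-break as the implementation.
# Returns merge heights and the leaf-label set merged at each step.
upgma_brute <- function(m) {
  D0 <- as.matrix(stats::dist(m))
  labs <- rownames(m)
  groups <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  merged_sets <- list()
  while (length(groups) > 1) {
    best <- NULL
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      d <- mean(D0[groups[[i]], groups[[j]], drop = FALSE])
      key <- paste(sort(c(min(labs[groups[[i]]]), min(labs[groups[[j]]]))),
                   collapse = "\r")
      if (is.null(best) || d < best$d ||
          (d == best$d && key < best$key))
        best <- list(i = i, j = j, d = d, key = key)
    }
    heights <- c(heights, best$d)
    merged_sets[[length(merged_sets) + 1]] <-
      sort(labs[c(groups[[best$i]], groups[[best$j]])])
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    groups[[best$j]] <- NULL
  }
  list(heights = heights, merged_sets = merged_sets)
}

# leaf-label sets merged at each step of a gene_dendrogram
dendro_merged_sets <- function(tree) {
  sets <- pearlscreen:::node_leafsets(tree$merge)
  lapply(sets, function(s) sort(tree$labels[s]))
}

# Hand-built simulation truth with explicit abundance profiles.
make_truth <- function(sequences, abundance, archetype = NULL,
                       family_id = NULL) {
  n <- length(sequences)
  ids <- sprintf("g%04d", seq_len(n))
  A <- abundance
  dimnames(A) <- list(ids, c("ME", "P", "PS"))
  A <- sweep(A, 2, colSums(A), "/")
  structure(list(
    genes = data.frame(gene_id = ids,
                       archetype = archetype %||% rep("housekeeping", n),
                       family_id = family_id %||% rep(NA_character_, n),
                       sequence = sequences, stringsAsFactors = FALSE),
    abundance = A, tissue_names = c("ME", "P", "PS"), seed = 0L),
    class = "sim_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fraction of equal characters between equal-length strings
str_identity <- function(a, b) {
  mean(utf8ToInt(a) == utf8ToInt(b))
}

qual_string <- function(q) {
  intToUtf8(q + 33L)
}

make_reads <- function(bases, tissue = "ME", quals = NULL) {
  n <- length(bases)
  quals <- quals %||% vapply(nchar(bases),
                             function(w) qual_string(rep(38L, w)),
                             character(1))
  structure(data.frame(
    read_id = sprintf("r%04d_%s", seq_len(n), tissue),
    tissue = rep_len(tissue, n), bases = bases, quals = quals,
    origin = rep(NA_character_, n), stringsAsFactors = FALSE),
    class = c("tag_reads", "data.frame"))
}

# mutate a fixed fraction of positions (always to a different base)
mutate_many <- function(seq, frac, seed = 1) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), round(frac * length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
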