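dominance_reason <- function(me, p, ps, fold) {
  # Strict dominance of either nacre-forming tissue over the mantle edge.
  # A zero mantle-edge TPM passes whenever either nacre tissue is expressed
  # (the ratio is formally infinite).
  if (me == 0) {
    if (p > 0 || ps > 0) return("zero_ME") else return(NA_character_)
  }
  pass_p <- p > fold * me
  pass_ps <- ps > fold * me
  if (pass_p && pass_ps) "both"
  else if (pass_p) "pallium"
  else if (pass_ps) "pearl_sac"
  else NA_character_
}

nacre_screen_tpm <- function(tpm, total_reads, fold = 2, min_total = 40L) {
  reason <- vapply(seq_len(nrow(tpm)), function(i) {
    if (total_reads[i] < min_total) return(NA_character_)
    dominance_reason(tpm[i, 1], tpm[i, 2], tpm[i, 3], fold)
  }, character(1))
  keep <- !is.na(reason)
  res <- data.frame(gene_id = rownames(tpm)[keep],
                    tpm_me = tpm[keep, 1], tpm_p = tpm[keep, 2],
                    tpm_ps = tpm[keep, 3],
                    total_reads = as.integer(total_reads[keep]),
                    pass_reason = reason[keep],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(-res$total_reads, res$gene_id), , drop = FALSE]
}

#' Nacre-dominance fold-change screen
#'
#' Retrieves genes dominantly expressed in the nacre-forming tissues: a
#' gene passes iff its total reads are at least `min_total` and its TPM in
#' the pallium *or* the pearl sac strictly exceeds `fold` times its TPM in
#' the mantle edge. A gene with zero mantle-edge TPM passes whenever
#' either nacre tissue is expressed (reason `zero_ME`). Inequalities are
#' strict throughout: a gene exactly at the fold boundary fails.
#'
#' @param em an [`expression_matrix`][compute_tpm()] with tissues in
#'   ME, P, PS order.
#' @param fold dominance fold threshold (> 0; default 2).
#' @param min_total minimum total reads (default 40).
#' @return A data frame of candidates: `gene_id`, TPM per tissue,
#'   `total_reads` and `pass_reason` in `pallium`, `pearl_sac`, `both` or
#'   `zero_ME`; ordered by descending total reads.
#' @export
nacre_screen <- function(em, fold = 2, min_total = 40L) {
  stopifnot(inherits(em, "expression_matrix"))
  if (fold <= 0) stop("`fold` must be positive")
  nacre_screen_tpm(em$tpm, rowSums(em$counts), fold, min_total)
}

#' Euclidean distance between expression profiles
#'
#' @param x,y numeric vectors of equal length.
#' @return The Euclidean distance `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal lengths")
  sqrt(sum((x - y)^2))
}

#' Agglomerative clustering of expression profiles
#'
#' Average-linkage (UPGMA) hierarchical clustering of gene TPM vectors
#' under Euclidean distance. The agglomeration is deterministic: when
#' several cluster pairs are tied at the minimum distance, the pair whose
#' sorted pair of smallest member gene ids is lexicographically least is
#' merged first. Clustering operates on raw TPM by default;
#' `log_transform = TRUE` uses `log10(TPM + 1)` instead.
#'
#' @param x an [`expression_matrix`][compute_tpm()] or a numeric matrix of
#'   profiles with gene ids as row names (>= 2 rows).
#' @param linkage agglomeration rule; only `"average"` is implemented.
#' @param log_transform cluster `log10(TPM + 1)` instead of raw TPM.
#' @return An object of class `gene_dendrogram` with `merge`, `height`,
#'   `labels` and `order` in [stats::hclust()] layout; coerce with
#'   `as.hclust()` or export with [write_newick()].
#' @export
hcluster <- function(x, linkage = c("average"), log_transform = FALSE) {
  linkage <- match.arg(linkage)
  m <- if (inherits(x, "expression_matrix")) x$tpm else as.matrix(x)
  if (nrow(m) < 2) stop("clustering needs at least 2 genes")
  if (is.null(rownames(m))) rownames(m) <- sprintf("row%04d", seq_len(nrow(m)))
  if (log_transform) m <- log10(m + 1)
  n <- nrow(m)
  labels <- rownames(m)

  D <- as.matrix(stats::dist(m, method = "euclidean"))
  diag(D) <- Inf
  # active cluster bookkeeping
  size <- rep(1L, n)
  node <- -seq_len(n)             # hclust code: negative leaf, positive merge
  minlab <- labels                # lexicographic tie-break key per cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    dmin <- min(D[active, active])
    idx <- which(D == dmin & outer(active, active, "&"), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (nrow(idx) > 1L) {
      keys <- apply(idx, 1, function(p) {
        lab <- sort(c(minlab[p[1]], minlab[p[2]]))
        paste(lab, collapse = "\r")
      })
      idx <- idx[order(keys)[1], , drop = FALSE]
    }
    i <- idx[1, 1]; j <- idx[1, 2]
    merge[s, ] <- as.integer(c(node[i], node[j]))
    height[s] <- dmin
    # UPGMA update: average of original pairwise distances, weighted by size
    others <- which(active); others <- setdiff(others, c(i, j))
    if (length(others)) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- newd; D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    node[i] <- s
    minlab[i] <- min(minlab[i], minlab[j])
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }

  res <- structure(list(merge = merge, height = height, labels = labels,
                        method = linkage, dist.method = "euclidean"),
                   class = "gene_dendrogram")
  res$order <- dendrogram_leaf_order(merge, n)
  res
}

# leaf order for plotting: left-to-right depth-first over the merge matrix
dendrogram_leaf_order <- function(merge, n) {
  walk <- function(v) {
    if (v < 0) return(-v)
    c(walk(merge[v, 1]), walk(merge[v, 2]))
  }
  as.integer(walk(nrow(merge)))
}

#' @export
as.hclust.gene_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 dist.method = x$dist.method, call = match.call()),
            class = "hclust")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("gene_dendrogram: %d leaves, %s linkage, root height %.3f\n",
              length(x$labels), x$method, max(x$height)))
  invisible(x)
}

#' Export a dendrogram as a Newick tree
#'
#' @param tree a [`gene_dendrogram`][hcluster()].
#' @param path output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# leaf index sets for every internal node of an hclust-style merge matrix
node_leafsets <- function(merge) {
  n_nodes <- nrow(merge)
  sets <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) {
    lv <- merge[v, 1]; rv <- merge[v, 2]
    sets[[v]] <- c(if (lv < 0) -lv else sets[[lv]],
                   if (rv < 0) -rv else sets[[rv]])
  }
  sets
}

#' Retrieve genes co-clustering with marker genes
#'
#' For each marker leaf, finds the largest subtree of the dendrogram that
#' contains the marker and has at most `max_cluster_size` leaves; markers
#' landing in the same subtree are merged into one marker group. The
#' retrieved genes are the non-marker leaves of each group's subtree.
#'
#' @param tree a [`gene_dendrogram`][hcluster()].
#' @param markers character vector of marker gene ids; all must be leaves
#'   of the tree.
#' @param max_cluster_size maximum number of leaves in a reported subtree
#'   (default 8, matching the small marker neighbourhoods expression
#'   heatmaps typically display).
#' @return An object of class `marker_cocluster`: list with `groups` (one
#'   row per marker group: `group`, comma-joined `marker_ids`, subtree
#'   `height` and `n_leaves`) and `hits` (one row per retrieved gene:
#'   `group`, `marker_ids`, `gene_id`, `height`).
#' @export
marker_cocluster <- function(tree, markers, max_cluster_size = 8L) {
  stopifnot(inherits(tree, "gene_dendrogram"))
  missing <- setdiff(markers, tree$labels)
  if (length(missing))
    stop("marker(s) not found among dendrogram leaves: ",
         paste(missing, collapse = ", "))
  sets <- node_leafsets(tree$merge)
  sizes <- lengths(sets)
  marker_idx <- match(markers, tree$labels)

  # For each marker: the largest containing node with <= max size.
  # The root (the trivial cluster of every gene) only qualifies when it is
  # the sole candidate; node 0 encodes "the leaf itself".
  root <- nrow(tree$merge)
  best_node <- vapply(marker_idx, function(li) {
    containing <- which(vapply(sets, function(s) li %in% s, logical(1)))
    ok <- containing[sizes[containing] <= max_cluster_size]
    if (length(ok) > 1L) ok <- setdiff(ok, root)
    if (!length(ok)) 0L else ok[which.max(sizes[ok])]
  }, integer(1))

  grp_nodes <- unique(best_node)
  groups <- data.frame(group = seq_along(grp_nodes),
                       marker_ids = vapply(grp_nodes, function(v)
                         paste(sort(markers[best_node == v]), collapse = ","),
                         character(1)),
                       height = vapply(grp_nodes, function(v)
                         if (v == 0) 0 else tree$height[v], numeric(1)),
                       n_leaves = vapply(grp_nodes, function(v)
                         if (v == 0) 1L else as.integer(sizes[v]), integer(1)),
                       stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(seq_along(grp_nodes), function(gi) {
    v <- grp_nodes[gi]
    leaves <- if (v == 0) character(0) else tree$labels[sets[[v]]]
    got <- setdiff(leaves, markers)
    if (!length(got)) return(NULL)
    data.frame(group = gi, marker_ids = groups$marker_ids[gi],
               gene_id = got, height = groups$height[gi],
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    hits <- data.frame(group = integer(), marker_ids = character(),
                       gene_id = character(), height = numeric(),
                       stringsAsFactors = FALSE)
  structure(list(groups = groups, hits = hits), class = "marker_cocluster")
}

#' @export
print.marker_cocluster <- function(x, ...) {
  cat(sprintf("marker co-clustering: %d group(s), %d retrieved gene(s)\n",
              nrow(x$groups), nrow(x$hits)))
  invisible(x)
}

#' Tiered marker co-clustering screen
#'
#' Splits the genes into highly and moderately expressed tiers (see
#' [tier_split()]) and runs [hcluster()] plus [marker_cocluster()]
#' independently within each tier. Markers whose total reads fall below
#' `mod_min` are excluded from the analysis with a warning, since tag
#' counts that low make expression profiles unreliable.
#'
#' @param em an [`expression_matrix`][compute_tpm()].
#' @param markers character vector of marker gene ids present in `em`.
#' @param high_min,mod_min tier thresholds (defaults 200 and 40).
#' @param max_cluster_size passed to [marker_cocluster()].
#' @param log_transform passed to [hcluster()].
#' @return A list with `high` and `moderate` [marker_cocluster()] reports
#'   (`NULL` where a tier has no markers or fewer than two genes) and
#'   `excluded_markers`.
#' @export
run_tiered_coclustering <- function(em, markers, high_min = 200L,
                                    mod_min = 40L, max_cluster_size = 8L,
                                    log_transform = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  missing <- setdiff(markers, rownames(em$counts))
  if (length(missing))
    stop("marker(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  totals <- rowSums(em$counts)
  low <- markers[totals[markers] < mod_min]
  if (length(low))
    warning("marker(s) excluded for low expression (<", mod_min, " reads): ",
            paste(low, collapse = ", "))
  markers <- setdiff(markers, low)
  tiers <- tier_split(em, high_min = high_min, mod_min = mod_min)

  run_tier <- function(ids) {
    mk <- intersect(markers, ids)
    if (length(ids) < 2 || !length(mk)) return(NULL)
    tpm <- em$tpm[ids, , drop = FALSE]
    tree <- hcluster(tpm, log_transform = log_transform)
    marker_cocluster(tree, mk, max_cluster_size = max_cluster_size)
  }
  list(high = run_tier(tiers$high), moderate = run_tier(tiers$moderate),
       excluded_markers = low)
}
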