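#' Quality-trim 3'-tag reads
#'
#' Reads are trimmed from the 3' end in blocks of `window` bases: trailing
#' blocks whose mean Phred quality is below `min_mean_q` are dropped, and
#' trimming stops at the first (3'-most) block that passes. Reads shorter
#' than `min_len` after trimming are removed. Input order is preserved.
#'
#' This is the conventional windowed 3' trim used ahead of EST assembly;
#' because 3'-tag reads degrade toward their end, block-wise trailing
#' removal is both fast and conservative.
#'
#' @param reads a `tag_reads` data frame.
#' @param window block width in bases (>= 1).
#' @param min_mean_q minimum mean Phred quality for a block to survive.
#' @param min_len minimum read length after trimming.
#' @return The trimmed `tag_reads` data frame.
#' @export
#' @examples
#' r <- data.frame(read_id = "x_ME", tissue = "ME",
#'                 bases = strrep("A", 30),
#'                 quals = paste0(strrep("I", 20), strrep("#", 10)),
#'                 origin = NA)
#' nchar(trim_reads(r, min_len = 10)$bases)  # low-quality tail removed
trim_reads <- function(reads, window = 10L, min_mean_q = 20L, min_len = 50L) {
  if (window < 1) stop("`window` must be >= 1")
  window <- as.integer(window)
  if (nrow(reads) == 0) return(reads)
  quals <- phred_decode(reads$quals)
  keep_len <- vapply(quals, function(q) {
    n <- length(q)
    n_blocks <- ceiling(n / window)
    for (j in seq_len(n_blocks)) {
      hi <- n - (j - 1L) * window
      lo <- max(1L, hi - window + 1L)
      if (mean(q[lo:hi]) >= min_mean_q) return(hi)
    }
    0L
  }, integer(1))
  out <- reads
  out$bases <- substr(out$bases, 1L, keep_len)
  out$quals <- substr(out$quals, 1L, keep_len)
  out <- out[keep_len >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tag_reads", "data.frame")
  out
}

# Ungapped identity between `s` and `r` on diagonal `d` (offset of s within
# r, may be negative). Returns c(identity, overlap_len).
diag_identity <- function(s_int, r_int, d) {
  ls <- length(s_int); lr <- length(r_int)
  i1 <- max(1L, 1L - d); i2 <- min(ls, lr - d)
  if (i2 < i1) return(c(0, 0))
  seg_s <- s_int[i1:i2]
  seg_r <- r_int[(i1 + d):(i2 + d)]
  c(mean(seg_s == seg_r), i2 - i1 + 1L)
}

#' Greedily cluster 3'-tag reads into gene clusters
#'
#' Single-pass greedy identity clustering in the CD-HIT style: reads are
#' sorted by descending length (long reads found clusters and become
#' representatives), then each read joins the first existing cluster, in
#' creation order, whose representative it matches with ungapped identity
#' `>= min_identity` over at least `min_overlap_frac` of the shorter
#' sequence on a k-mer-seeded diagonal. Otherwise it founds a new cluster.
#' Gaps are ignored: 3'-tags from one gene are near-collinear. Per-tissue
#' counts are tallied from the reads' tissue labels, and clusters are
#' numbered `000001`, `000002`, ... by descending total reads (ties by
#' creation order).
#'
#' @param reads a `tag_reads` data frame (typically after [trim_reads()]).
#' @param k exact k-mer seed length (>= 4).
#' @param min_identity minimum ungapped identity to join a cluster, in
#'   (0, 1\].
#' @param min_overlap_frac minimum aligned fraction of the shorter
#'   sequence.
#' @return A `gene_clusters` data frame with columns `cluster_id`,
#'   `representative`, `ME`, `P`, `PS`, `total`, `length_bp`.
#' @export
cluster_tags <- function(reads, k = 12L, min_identity = 0.95,
                         min_overlap_frac = 0.8) {
  if (k < 4) stop("`k` must be >= 4")
  if (min_identity <= 0 || min_identity > 1)
    stop("`min_identity` must be in (0, 1]")
  if (nrow(reads) == 0)
    return(structure(data.frame(cluster_id = character(),
                                representative = character(),
                                ME = integer(), P = integer(),
                                PS = integer(), total = integer(),
                                length_bp = integer()),
                     class = c("gene_clusters", "data.frame")))

  ord <- order(-nchar(reads$bases))         # stable: ties keep input order
  seqs <- reads$bases[ord]
  tissue <- factor(reads$tissue[ord], levels = TISSUES)

  # Collapse identical sequences: they always co-cluster, and 3'-tags are
  # highly redundant.
  first <- !duplicated(seqs)
  useq <- seqs[first]
  grp <- match(seqs, useq)
  tab <- table(factor(grp, levels = seq_along(useq)), tissue)
  ucounts <- matrix(as.integer(tab), ncol = 3,
                    dimnames = list(NULL, TISSUES))

  kmer_index <- new.env(parent = emptyenv())   # kmer -> cluster indices
  reps <- character(0)
  reps_int <- list()
  assign_cluster <- integer(length(useq))

  for (i in seq_along(useq)) {
    s <- useq[i]
    ls <- nchar(s)
    s_int <- utf8ToInt(s)
    hit <- 0L
    if (ls >= k) {
      starts <- 1:(ls - k + 1L)
      kmers <- substring(s, starts, starts + k - 1L)
      cand <- unlist(mget(unique(kmers), envir = kmer_index,
                          ifnotfound = list(NULL)), use.names = FALSE)
      for (ci in sort(unique(cand))) {
        r <- reps[ci]
        r_int <- reps_int[[ci]]
        min_len <- min(ls, length(r_int))
        # candidate diagonals from shared k-mer seeds (first few suffice)
        shared <- which(kmers %in% substring(r, 1:(nchar(r) - k + 1L),
                                             k:nchar(r)))
        diags <- integer(0)
        for (p in head(shared, 10L)) {
          hits_in_r <- gregexpr(kmers[p], r, fixed = TRUE)[[1]]
          if (hits_in_r[1] > 0) diags <- c(diags, hits_in_r - starts[p])
        }
        ok <- FALSE
        for (d in unique(diags)) {
          di <- diag_identity(s_int, r_int, d)
          if (di[2] >= min_overlap_frac * min_len && di[1] >= min_identity) {
            ok <- TRUE; break
          }
        }
        if (ok) { hit <- ci; break }
      }
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      reps_int[[length(reps)]] <- s_int
      hit <- length(reps)
      if (ls >= k) {
        for (km in unique(kmers)) {
          assign(km, c(kmer_index[[km]], hit), envir = kmer_index)
        }
      }
    }
    assign_cluster[i] <- hit
  }

  n_cl <- length(reps)
  counts <- matrix(0L, n_cl, 3, dimnames = list(NULL, TISSUES))
  for (t in 1:3) {
    agg <- tapply(ucounts[, t], assign_cluster, sum)
    counts[as.integer(names(agg)), t] <- as.integer(agg)
  }
  total <- rowSums(counts)
  ord_cl <- order(-total, seq_len(n_cl))
  res <- data.frame(cluster_id = sprintf("%06d", seq_len(n_cl)),
                    representative = reps[ord_cl],
                    ME = counts[ord_cl, "ME"], P = counts[ord_cl, "P"],
                    PS = counts[ord_cl, "PS"],
                    total = as.integer(total[ord_cl]),
                    length_bp = nchar(reps[ord_cl]),
                    stringsAsFactors = FALSE)
  class(res) <- c("gene_clusters", "data.frame")
  res
}

#' Library summary statistics
#'
#' Computes the standard summary of a clustered 3'-tag library: per-tissue
#' and total read numbers, cluster counts, mean read length, contig length
#' range and reads-per-contig range. Means are reported at full precision;
#' `print()` shows them rounded to one decimal.
#'
#' @param clusters a non-empty `gene_clusters` data frame.
#' @param reads the `tag_reads` that were clustered.
#' @return An object of class `library_summary` (a named list).
#' @export
library_summary <- function(clusters, reads) {
  if (nrow(clusters) == 0) stop("empty cluster set")
  n_per_tissue <- vapply(TISSUES, function(t) sum(clusters[[t]]), numeric(1))
  n_total <- sum(n_per_tissue)
  structure(list(
    n_reads_per_tissue = n_per_tissue,
    n_reads_total = n_total,
    n_clusters = nrow(clusters),
    n_clusters_per_tissue = vapply(TISSUES,
                                   function(t) sum(clusters[[t]] > 0),
                                   numeric(1)),
    mean_read_len = mean(nchar(reads$bases)),
    mean_contig_len = mean(clusters$length_bp),
    max_contig_len = max(clusters$length_bp),
    min_contig_len = min(clusters$length_bp),
    mean_reads_per_contig = n_total / nrow(clusters),
    max_reads_per_contig = max(clusters$total),
    min_reads_per_contig = min(clusters$total)),
    class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat("3'-tag library summary\n")
  cat(sprintf("  reads: %d (ME %d, P %d, PS %d)\n", x$n_reads_total,
              x$n_reads_per_tissue[1], x$n_reads_per_tissue[2],
              x$n_reads_per_tissue[3]))
  cat(sprintf("  clusters: %d (mean length %.1f bp, range %d-%d)\n",
              x$n_clusters, x$mean_contig_len, x$min_contig_len,
              x$max_contig_len))
  cat(sprintf("  reads per contig: mean %.1f, range %d-%d\n",
              x$mean_reads_per_contig, x$min_reads_per_contig,
              x$max_reads_per_contig))
  cat(sprintf("  mean read length: %.1f bp\n", x$mean_read_len))
  invisible(x)
}
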