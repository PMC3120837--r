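#' Gene-by-tissue expression matrix with TPM normalization
#'
#' Computes transcripts per million for a gene x tissue count table:
#' `TPM[g, t] = counts[g, t] / tissue_totals[t] * 1e6`, i.e. (reads of the
#' gene in the tissue / total reads in the tissue) x 10^6. The tissue
#' totals are the *library-wide* assembled-read totals and are carried
#' unchanged through any downstream filtering, so the TPM of a gene never
#' depends on which other genes are kept. TPM values are stored at full
#' precision; rounding to integers is presentation-only.
#'
#' @param counts integer gene x tissue matrix (columns ME, P, PS) with
#'   gene ids as row names, or a `gene_clusters` data frame from
#'   [cluster_tags()].
#' @param tissue_totals per-tissue library read totals (positive). When
#'   `counts` is a full unfiltered library this defaults to its column
#'   sums.
#' @return An object of class `expression_matrix`: a list with `counts`,
#'   `tissue_totals` and `tpm`.
#' @export
#' @examples
#' counts <- matrix(c(30L, 121L, 292L), 1,
#'                  dimnames = list("000096", c("ME", "P", "PS")))
#' em <- compute_tpm(counts, c(ME = 68690, P = 83692, PS = 108095))
#' round(em$tpm)   # 437 1446 2701
compute_tpm <- function(counts, tissue_totals = NULL) {
  if (inherits(counts, "gene_clusters")) {
    m <- as.matrix(counts[, TISSUES])
    rownames(m) <- counts$cluster_id
    counts <- m
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(tissue_totals)) tissue_totals <- colSums(counts)
  if (length(tissue_totals) != ncol(counts))
    stop("`tissue_totals` must have one entry per tissue")
  if (any(tissue_totals <= 0)) stop("tissue totals must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(names(tissue_totals))) names(tissue_totals) <- colnames(counts)
  tpm <- sweep(counts, 2, as.numeric(tissue_totals), "/") * 1e6
  structure(list(counts = counts,
                 tissue_totals = tissue_totals,
                 tpm = tpm),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d tissues (totals %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(x$tissue_totals),
                            as.integer(x$tissue_totals)), collapse = " ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Invert TPM values back to read counts
#'
#' The inverse of the TPM statistic:
#' `count[t] = round(tpm[t] * tissue_totals[t] / 1e6)`. Used as a
#' verification oracle for published TPM tables whose raw counts are not
#' printed.
#'
#' @param tpm numeric per-tissue TPM values (vector or gene x tissue
#'   matrix).
#' @param tissue_totals per-tissue library read totals.
#' @return Integer counts with the shape of `tpm`.
#' @export
#' @examples
#' invert_tpm(c(218, 753, 500), c(68690, 83692, 108095))  # 15 63 54
invert_tpm <- function(tpm, tissue_totals) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be >= 0")
  if (is.matrix(tpm)) {
    out <- round(sweep(tpm, 2, as.numeric(tissue_totals), "*") / 1e6)
  } else {
    out <- round(tpm * as.numeric(tissue_totals) / 1e6)
  }
  storage.mode(out) <- "integer"
  out
}

#' Filter genes by total read count
#'
#' Retains genes whose total reads across tissues are at least `min_total`
#' (inclusive). Tissue totals are *not* recomputed: survivors keep exactly
#' the TPM they had in the full library.
#'
#' @param em an [`expression_matrix`][compute_tpm()].
#' @param min_total minimum total reads (default 40, the conventional
#'   reliability cut for tag counts).
#' @return A filtered `expression_matrix`.
#' @export
filter_by_total <- function(em, min_total = 40L) {
  stopifnot(inherits(em, "expression_matrix"))
  if (min_total < 0) stop("`min_total` must be >= 0")
  keep <- rowSums(em$counts) >= min_total
  structure(list(counts = em$counts[keep, , drop = FALSE],
                 tissue_totals = em$tissue_totals,
                 tpm = em$tpm[keep, , drop = FALSE]),
            class = "expression_matrix")
}

#' Split genes into expression tiers
#'
#' Partitions genes into highly expressed (total reads `>= high_min`),
#' moderately expressed (`[mod_min, high_min)`) and excluded
#' (`< mod_min`) tiers, the split used ahead of tiered co-clustering.
#'
#' @param em an [`expression_matrix`][compute_tpm()].
#' @param high_min,mod_min tier thresholds (`mod_min < high_min`).
#' @return An object of class `tier_partition`: list of gene-id vectors
#'   `high`, `moderate`, `excluded`.
#' @export
tier_split <- function(em, high_min = 200L, mod_min = 40L) {
  stopifnot(inherits(em, "expression_matrix"))
  if (mod_min >= high_min) stop("`mod_min` must be below `high_min`")
  totals <- rowSums(em$counts)
  ids <- rownames(em$counts)
  structure(list(high = ids[totals >= high_min],
                 moderate = ids[totals >= mod_min & totals < high_min],
                 excluded = ids[totals < mod_min]),
            class = "tier_partition")
}

#' @export
print.tier_partition <- function(x, ...) {
  cat(sprintf("tiers: %d high, %d moderate, %d excluded\n",
              length(x$high), length(x$moderate), length(x$excluded)))
  invisible(x)
}
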