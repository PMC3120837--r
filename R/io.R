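#' Write 3'-tag reads to per-tissue FASTQ files
#'
#' @param reads a `tag_reads` data frame (see [emit_tag_reads()]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix>_<tissue>.fastq`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_tag_fastq <- function(reads, dir, prefix = "tags") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (t in TISSUES) {
    sub <- reads[reads$tissue == t, , drop = FALSE]
    path <- file.path(dir, sprintf("%s_%s.fastq", prefix, t))
    x <- Biostrings::DNAStringSet(sub$bases)
    names(x) <- sub$read_id
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(sub$quals))
    paths[t] <- path
  }
  invisible(paths)
}

#' Read 3'-tag reads from FASTQ or FASTA
#'
#' The tissue of origin is parsed from the identifier suffix (`_ME`, `_P`
#' or `_PS` after the last underscore). FASTA input gets uniform maximal
#' qualities, so downstream trimming is a no-op.
#'
#' @param paths character vector of FASTQ/FASTA files.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return A `tag_reads` data frame (`origin` is `NA`: unknown truth).
#' @export
read_tag_reads <- function(paths, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  parts <- lapply(paths, function(p) {
    if (format == "fastq") {
      x <- Biostrings::readDNAStringSet(p, format = "fastq",
                                        with.qualities = TRUE)
      quals <- as.character(S4Vectors::mcols(x)$qualities)
    } else {
      x <- Biostrings::readDNAStringSet(p, format = "fasta")
      quals <- vapply(Biostrings::width(x),
                      function(w) strrep(intToUtf8(41L + 33L), w),
                      character(1))
    }
    ids <- sub("\\s.*$", "", names(x))
    data.frame(read_id = ids,
               tissue = sub("^.*_", "", ids),
               bases = as.character(x),
               quals = quals,
               origin = NA_character_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  bad <- !res$tissue %in% TISSUES
  if (any(bad))
    stop("cannot parse tissue from read identifier(s): ",
         paste(head(res$read_id[bad], 3), collapse = ", "))
  class(res) <- c("tag_reads", "data.frame")
  res
}

#' Write gene-cluster representatives as FASTA and counts as TSV
#'
#' @param clusters a `gene_clusters` data frame from [cluster_tags()].
#' @param fasta,tsv output paths (either may be `NULL` to skip).
#' @return Invisibly, the cluster table.
#' @export
write_clusters <- function(clusters, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(clusters$representative)
    names(x) <- clusters$cluster_id
    Biostrings::writeXStringSet(x, fasta)
  }
  if (!is.null(tsv)) {
    write.table(
      clusters[, c("cluster_id", "ME", "P", "PS", "total")],
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(clusters)
}

#' Write / read a gene-by-tissue count matrix as TSV
#'
#' Layout: a `#totals:` header comment carrying the library-wide per-tissue
#' read totals, then a header line `gene_id<TAB>ME<TAB>P<TAB>PS`.
#'
#' @param counts integer gene x tissue matrix.
#' @param tissue_totals per-tissue library totals (defaults to column
#'   sums).
#' @param path file path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` a list with `counts` and `tissue_totals`.
#' @export
write_count_matrix <- function(counts, path, tissue_totals = colSums(counts)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#totals: %s",
                     paste(sprintf("%s=%d", colnames(counts),
                                   as.integer(tissue_totals)),
                           collapse = " ")), con)
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  write.table(data.frame(gene_id = rownames(counts), counts),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  first <- readLines(path, n = 1)
  totals <- NULL
  if (startsWith(first, "#totals:")) {
    kv <- strsplit(trimws(sub("^#totals:", "", first)), "[ =]")[[1]]
    totals <- as.integer(kv[c(FALSE, TRUE)])
    names(totals) <- kv[c(TRUE, FALSE)]
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(gene_id = "character"))
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  list(counts = counts, tissue_totals = totals %||% colSums(counts))
}
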