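#' Published library-summary fixture
#'
#' The sequencing summary of the reference pearl-oyster 3'-tag study,
#' packaged as a worked example: raw and assembled read numbers, mean read
#' lengths and contig counts per tissue, plus contig-level statistics.
#'
#' @return A list with `reads_raw`, `reads_assembled`, `mean_read_length`
#'   and `n_contigs` (each a named ME/P/PS vector plus a `total`
#'   attribute-free 4th element named `total`), and `contig_stats` (data
#'   frame).
#' @export
published_library_summary <- function() {
  path <- system.file("extdata", "published_library_summary.tsv",
                      package = "pearlscreen", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, c("ME", "P", "PS", "total")])
    names(v) <- c("ME", "P", "PS", "total")
    v
  })
  names(rows) <- df$feature
  stats_path <- system.file("extdata", "published_contig_stats.tsv",
                            package = "pearlscreen", mustWork = TRUE)
  rows$contig_stats <- read.delim(stats_path, stringsAsFactors = FALSE)
  rows
}

#' Published nacre-candidate fixture
#'
#' The 29 candidate genes retrieved by the nacre-dominance screen in the
#' reference study, with their printed per-tissue TPM values and total
#' reads. A blank mantle-edge TPM cell parses as 0.
#'
#' @return A data frame with columns `category`, `gene_id`, `label`,
#'   `tpm_me`, `tpm_p`, `tpm_ps`, `total_reads`.
#' @export
published_candidates <- function() {
  path <- system.file("extdata", "published_candidates.tsv",
                      package = "pearlscreen", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(gene_id = "character"))
  for (col in c("tpm_me", "tpm_p", "tpm_ps"))
    df[[col]][is.na(df[[col]])] <- 0
  df
}

#' Verify the published candidate table against the pipeline's statistics
#'
#' Re-derives each candidate's per-tissue read counts from its printed TPM
#' values via [invert_tpm()] (using the library-wide assembled-read
#' totals), checks that the derived counts sum to the printed total reads,
#' and re-applies the nacre-dominance rule to the printed TPM triple. Rows
#' with a blank (zero) mantle-edge TPM cannot have their mantle-edge count
#' recovered, so their sum check is reported as `NA`.
#'
#' @param fixture candidate table as from [published_candidates()].
#' @param tissue_totals per-tissue assembled-read totals (default: the
#'   packaged library summary).
#' @param fold,min_total screen parameters (defaults 2 and 40).
#' @return A list of class `candidate_verification`: `rows` (per-row derived
#'   counts, `sum_ok`, `screen_pass`, `pass_reason`), `n_pass`, `n_rows`
#'   and `all_ok`.
#' @export
verify_candidate_table <- function(fixture = published_candidates(),
                          tissue_totals = published_library_summary()$reads_assembled[TISSUES],
                          fold = 2, min_total = 40L) {
  if (is.null(fixture) || nrow(fixture) == 0)
    stop("empty candidate fixture")
  tpm <- as.matrix(fixture[, c("tpm_me", "tpm_p", "tpm_ps")])
  counts <- invert_tpm(tpm, tissue_totals)
  derived_sum <- rowSums(counts)
  zero_me <- tpm[, 1] == 0
  sum_ok <- derived_sum == fixture$total_reads
  sum_ok[zero_me] <- NA
  reason <- vapply(seq_len(nrow(tpm)), function(i)
    dominance_reason(tpm[i, 1], tpm[i, 2], tpm[i, 3], fold), character(1))
  screen_pass <- !is.na(reason) & fixture$total_reads >= min_total
  rows <- data.frame(gene_id = fixture$gene_id, label = fixture$label,
                     count_me = counts[, 1], count_p = counts[, 2],
                     count_ps = counts[, 3], derived_sum = derived_sum,
                     printed_total = fixture$total_reads, sum_ok = sum_ok,
                     screen_pass = screen_pass, pass_reason = reason,
                     stringsAsFactors = FALSE)
  structure(list(rows = rows,
                 n_pass = sum(screen_pass),
                 n_rows = nrow(rows),
                 all_ok = all(screen_pass) && all(sum_ok, na.rm = TRUE)),
            class = "candidate_verification")
}

#' @export
print.candidate_verification <- function(x, ...) {
  cat(sprintf("candidate-table verification: %d/%d rows pass the screen; %s\n",
              x$n_pass, x$n_rows,
              if (x$all_ok) "all count sums consistent"
              else "inconsistencies flagged"))
  invisible(x)
}
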