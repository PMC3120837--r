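#' Per-base error model for simulated 3'-tag reads
#'
#' Describes the noise applied when reads are emitted: a uniform per-base
#' substitution probability plus a two-level quality profile (a high-quality
#' body and a fixed-length low-quality 3' tail, mimicking the quality decay
#' of pyrosequencing reads).
#'
#' @param substitution_rate probability of a substitution per base, in
#'   \[0, 1\].
#' @param quality_high Phred score assigned to the read body (0-41).
#' @param quality_low Phred score assigned to the low-quality tail (0-41).
#' @param low_quality_tail_len number of 3'-terminal bases receiving
#'   `quality_low`.
#' @return An object of class `error_model`.
#' @export
#' @examples
#' error_model(substitution_rate = 0.01, low_quality_tail_len = 20)
error_model <- function(substitution_rate = 0.005, quality_high = 38L,
                        quality_low = 8L, low_quality_tail_len = 10L) {
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("`substitution_rate` must be in [0, 1]")
  for (q in c(quality_high, quality_low))
    if (q < 0 || q > 41) stop("Phred qualities must be in [0, 41]")
  if (low_quality_tail_len < 0) stop("`low_quality_tail_len` must be >= 0")
  structure(list(substitution_rate = substitution_rate,
                 quality_high = as.integer(quality_high),
                 quality_low = as.integer(quality_low),
                 low_quality_tail_len = as.integer(low_quality_tail_len)),
            class = "error_model")
}

random_dna <- function(n_len) {
  paste(sample(c("A", "C", "G", "T"), n_len, replace = TRUE), collapse = "")
}

# Mutate `seq` with point substitutions so pairwise identity to the original
# is ~`identity` (positions drawn without replacement, always to a different
# base).
mutate_to_identity <- function(seq, identity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- round(length(chars) * (1 - identity))
  if (n_mut > 0) {
    pos <- sample(seq_along(chars), n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a ground-truth transcriptome with tissue archetypes
#'
#' Generates `n_genes` gene sequences and a per-tissue relative-abundance
#' profile over the three shell-forming tissues (mantle edge, pallium,
#' pearl sac). Genes carry one of three archetypes: *nacreous* genes are
#' `fold_effect`-times more abundant in the pallium and pearl sac than in
#' the mantle edge, *prismatic* genes are `fold_effect`-times more abundant
#' in the mantle edge, and *housekeeping* genes are flat. Optionally,
#' isoform families are planted as groups of genes sharing high sequence
#' identity to a common family seed.
#'
#' Base abundances are log-normal. When both archetype groups are
#' non-empty, the prismatic group's base mass is rescaled so that the three
#' tissue columns carry equal total abundance; tissue-wise normalization
#' then preserves the nacreous pallium:mantle-edge ratio at exactly
#' `fold_effect` when `dispersion = 0`. Multiplicative log-normal noise
#' with sdlog `dispersion` is applied per gene and tissue before the final
#' per-tissue normalization to sum 1.
#'
#' @param n_genes total number of genes.
#' @param n_nacreous,n_prismatic number of genes with each archetype
#'   (`n_nacreous + n_prismatic <= n_genes`).
#' @param n_families number of planted isoform families.
#' @param fold_effect abundance fold difference of archetype genes between
#'   their dominant and depleted tissues (>= 1).
#' @param dispersion sdlog of multiplicative log-normal abundance noise
#'   (>= 0; 0 gives exact archetype ratios).
#' @param seed integer seed; the result is fully deterministic given it.
#' @param seq_len_range integer range from which gene lengths are drawn
#'   uniformly (all >= 200).
#' @param family_size genes per isoform family.
#' @param family_identity target sequence identity of family members to the
#'   family seed (>= 0.85).
#' @param abund_sdlog sdlog of the log-normal base abundances.
#' @return An object of class `sim_truth`: a list with `genes` (data frame
#'   of `gene_id`, `archetype`, `family_id`, `sequence`), `abundance`
#'   (gene x tissue matrix, each column summing to 1), `tissue_names` and
#'   `seed`.
#' @export
#' @examples
#' truth <- simulate_transcriptome(20, n_nacreous = 4, n_prismatic = 4,
#'                                 fold_effect = 4, seed = 7)
#' table(truth$genes$archetype)
simulate_transcriptome <- function(n_genes, n_nacreous = 0L, n_prismatic = 0L,
                                   n_families = 0L, fold_effect = 4,
                                   dispersion = 0, seed = 1L,
                                   seq_len_range = c(400L, 900L),
                                   family_size = 2L, family_identity = 0.9,
                                   abund_sdlog = 1) {
  if (n_genes < 1) stop("`n_genes` must be positive")
  if (n_nacreous < 0 || n_prismatic < 0 || n_nacreous + n_prismatic > n_genes)
    stop("archetype counts must be non-negative and sum to at most `n_genes`")
  if (fold_effect < 1) stop("`fold_effect` must be >= 1")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (min(seq_len_range) < 200) stop("gene lengths must be >= 200")
  if (n_families * family_size > n_genes)
    stop("too many isoform families for `n_genes`")
  if (family_identity < 0.85)
    stop("`family_identity` must be >= 0.85")

  with_seed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    archetype <- rep("housekeeping", n_genes)
    if (n_nacreous > 0) archetype[seq_len(n_nacreous)] <- "nacreous"
    if (n_prismatic > 0)
      archetype[n_nacreous + seq_len(n_prismatic)] <- "prismatic"

    lens <- sample(seq(min(seq_len_range), max(seq_len_range)), n_genes,
                   replace = TRUE)
    sequence <- vapply(lens, random_dna, character(1))

    # Isoform families occupy the trailing genes (housekeeping first when
    # available) so archetype counts stay exact.
    family_id <- rep(NA_character_, n_genes)
    if (n_families > 0) {
      slots <- rev(seq_len(n_genes))[seq_len(n_families * family_size)]
      for (f in seq_len(n_families)) {
        members <- slots[(f - 1) * family_size + seq_len(family_size)]
        family_id[members] <- sprintf("fam%02d", f)
        seed_seq <- sequence[members[1]]
        for (m in members[-1])
          sequence[m] <- mutate_to_identity(seed_seq, family_identity)
      }
    }

    base <- rlnorm(n_genes, meanlog = 0, sdlog = abund_sdlog)
    nac <- archetype == "nacreous"
    pri <- archetype == "prismatic"
    # Equalize the archetype groups' base mass so all three tissue columns
    # have the same total and normalization preserves fold ratios exactly.
    if (any(nac) && any(pri))
      base[pri] <- base[pri] * sum(base[nac]) / sum(base[pri])
    A <- matrix(base, nrow = n_genes, ncol = 3,
                dimnames = list(gene_id, TISSUES))
    A[nac, c("P", "PS")] <- A[nac, c("P", "PS")] * fold_effect
    A[pri, "ME"] <- A[pri, "ME"] * fold_effect
    if (dispersion > 0)
      A <- A * exp(matrix(rnorm(n_genes * 3, 0, dispersion), n_genes, 3))
    A <- sweep(A, 2, colSums(A), "/")

    structure(list(
      genes = data.frame(gene_id = gene_id, archetype = archetype,
                         family_id = family_id, sequence = sequence,
                         stringsAsFactors = FALSE),
      abundance = A,
      tissue_names = TISSUES,
      seed = as.integer(seed)), class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes (%d nacreous, %d prismatic), %d families, seed %d\n",
              nrow(x$genes), sum(x$genes$archetype == "nacreous"),
              sum(x$genes$archetype == "prismatic"),
              length(unique(stats::na.omit(x$genes$family_id))), x$seed))
  invisible(x)
}

#' Draw per-tissue read counts from a simulated transcriptome
#'
#' Counts for each tissue are multinomial draws of the requested depth from
#' that tissue's relative-abundance vector, so column sums equal the depths
#' exactly (read-conservation).
#'
#' @param truth a [`sim_truth`][simulate_transcriptome()] object.
#' @param depths positive integer vector of length 3 (reads per tissue, in
#'   ME, P, PS order; names are optional).
#' @param seed integer seed.
#' @return Integer gene x tissue count matrix with gene ids as row names.
#' @export
sample_read_counts <- function(truth, depths, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(depths) != 3 || any(depths <= 0))
    stop("`depths` must be three positive integers")
  if (any(colSums(truth$abundance) <= 0))
    stop("a tissue has zero total abundance")
  with_seed(seed, {
    counts <- matrix(vapply(1:3, function(t)
      rmultinom(1, size = depths[t], prob = truth$abundance[, t])[, 1],
      integer(nrow(truth$abundance))),
      nrow = nrow(truth$abundance), ncol = 3)
    dimnames(counts) <- dimnames(truth$abundance)
    counts
  })
}

#' Emit 3'-tag reads for a simulated count table
#'
#' Each read is the 3'-terminal `read_len` bases of its source gene (sense
#' strand, matching an oligo(dT)-primed tag protocol), with substitutions
#' at the error model's rate and a two-level quality string. Read
#' identifiers end in `_<tissue>` so the tissue of origin survives a
#' round-trip through FASTQ.
#'
#' @param truth a [`sim_truth`][simulate_transcriptome()] object.
#' @param counts integer gene x tissue matrix (as from
#'   [sample_read_counts()]); row names must match the truth's gene ids.
#' @param read_len tag length in bases; must not exceed the shortest gene.
#' @param error_mod an [error_model()].
#' @param seed integer seed.
#' @param random_strand if `TRUE`, each read is reverse-complemented with
#'   probability 1/2 (stress-tests strand-aware downstream steps).
#' @return A `tag_reads` data frame with columns `read_id`, `tissue`,
#'   `bases`, `quals` (Phred+33 string) and `origin` (true source gene).
#' @export
emit_tag_reads <- function(truth, counts, read_len = 250L,
                           error_mod = error_model(), seed = 1L,
                           random_strand = FALSE) {
  stopifnot(inherits(truth, "sim_truth"), inherits(error_mod, "error_model"))
  lens <- nchar(truth$genes$sequence)
  if (read_len > min(lens))
    stop("`read_len` exceeds the shortest gene length")
  if (!identical(rownames(counts), truth$genes$gene_id))
    counts <- counts[truth$genes$gene_id, , drop = FALSE]

  with_seed(seed, {
    qual <- rep(error_mod$quality_high, read_len)
    tail_n <- min(error_mod$low_quality_tail_len, read_len)
    if (tail_n > 0)
      qual[(read_len - tail_n + 1):read_len] <- error_mod$quality_low
    qual_str <- phred_encode(list(qual))

    out <- vector("list", nrow(counts) * 3L)
    serial <- 0L
    idx <- 0L
    for (g in seq_len(nrow(counts))) {
      tail_seq <- substr(truth$genes$sequence[g], lens[g] - read_len + 1,
                         lens[g])
      tmpl <- strsplit(tail_seq, "", fixed = TRUE)[[1]]
      for (t in 1:3) {
        n <- counts[g, t]
        if (n == 0) next
        mat <- matrix(tmpl, nrow = n, ncol = read_len, byrow = TRUE)
        if (error_mod$substitution_rate > 0) {
          err <- which(matrix(runif(n * read_len) <
                                error_mod$substitution_rate, n, read_len))
          if (length(err)) {
            alt <- c("A", "C", "G", "T")
            repl <- alt[(match(mat[err], alt) - 1L +
                           sample.int(3L, length(err), replace = TRUE)) %% 4L + 1L]
            mat[err] <- repl
          }
        }
        bases <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
        if (random_strand) {
          flip <- runif(n) < 0.5
          if (any(flip)) bases[flip] <- revcomp(bases[flip])
        }
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          read_id = sprintf("tag%07d_%s", serial + seq_len(n), TISSUES[t]),
          tissue = TISSUES[t], bases = bases, quals = qual_str,
          origin = truth$genes$gene_id[g], stringsAsFactors = FALSE)
        serial <- serial + n
      }
    }
    res <- if (idx == 0)
      data.frame(read_id = character(), tissue = character(),
                 bases = character(), quals = character(),
                 origin = character(), stringsAsFactors = FALSE)
    else do.call(rbind, out[seq_len(idx)])
    class(res) <- c("tag_reads", "data.frame")
    res
  })
}
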