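seq_alphabet <- function(x) {
  chars <- unique(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  if (all(chars %in% c("A", "C", "G", "T", "N"))) "nucleotide" else "protein"
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Exact local alignment dynamic programming (Gotoh's algorithm): the
#' maximal-scoring local alignment of `a` and `b` under match/mismatch
#' scoring and affine gap penalties, where a gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (penalties are subtracted; set
#' `gap_open == gap_extend` for linear gaps). With no positive-scoring
#' alignment the score is 0 and the spans are empty. Traceback ties are
#' broken by preferring a diagonal step, then a gap in `b`, then a gap in
#' `a`. `N`/`X` characters never match.
#'
#' @param a,b non-empty sequences over a common alphabet (both nucleotide
#'   or both protein).
#' @param match,mismatch per-position scores (defaults +2 / -3).
#' @param gap_open,gap_extend non-negative gap penalties (defaults 5 / 2).
#' @return A list: `score`, `identity` (matches / alignment columns),
#'   `a_start`, `a_end`, `b_start`, `b_end` (0-based half-open spans),
#'   `n_match`, `aln_len`.
#' @export
#' @examples
#' smith_waterman("ACGT", "ACGT")$score            # 8
#' smith_waterman("AAAA", "TTTT")$score            # 0: no positive alignment
smith_waterman <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be >= 0 (they are subtracted)")
  if (seq_alphabet(a) != seq_alphabet(b))
    stop("alphabet mismatch: one sequence is nucleotide, the other protein")
  sw_align_cpp(toupper(a), toupper(b), match, mismatch, gap_open, gap_extend)
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 start at positions 1..3 of the given strand; frames
#' -1..-3 start at positions 1..3 of the reverse complement. Trailing
#' partial codons are dropped, codons containing `N` translate to `X`,
#' and stops are `*` (standard genetic code).
#'
#' @param seq a nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return A named character vector of the six protein sequences
#'   (`"+1"` ... `"-3"`).
#' @export
#' @examples
#' six_frame_translate("ATGAAA")[["+1"]]   # "MK"
six_frame_translate <- function(seq) {
  if (!grepl("^[ACGTNacgtn]*$", seq))
    stop("`seq` must use the A/C/G/T/N alphabet")
  fwd <- Biostrings::DNAString(toupper(seq))
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    L <- length(s) - off
    n_codon <- L %/% 3
    if (n_codon == 0) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, off + 1L, off + n_codon * 3L),
      if.fuzzy.codon = "X"))
  }
  out <- c(vapply(0:2, function(o) one(fwd, o), character(1)),
           vapply(0:2, function(o) one(rev, o), character(1)))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Construct or read a marker-gene panel
#'
#' A panel of known nacreous/prismatic shell-matrix genes (e.g. MSI60,
#' nacrein, N16s, aspein, prismalin-14, KRMPs, shematrins) used as queries
#' for the homology screen. FASTA headers use `id|class|moltype` tokens.
#'
#' @param marker_id,class,moltype,sequence parallel vectors: unique ids,
#'   class in `nacreous`/`prismatic`, moltype in `nucleotide`/`protein`,
#'   and sequences.
#' @return A `marker_panel` data frame.
#' @export
marker_panel <- function(marker_id, class, moltype, sequence) {
  if (anyDuplicated(marker_id)) stop("marker ids must be unique")
  if (!all(class %in% c("nacreous", "prismatic")))
    stop("`class` must be 'nacreous' or 'prismatic'")
  if (!all(moltype %in% c("nucleotide", "protein")))
    stop("`moltype` must be 'nucleotide' or 'protein'")
  bad <- moltype == "nucleotide" & !grepl("^[ACGTNacgtn]+$", sequence)
  if (any(bad))
    stop("non-nucleotide characters in nucleotide marker(s): ",
         paste(marker_id[bad], collapse = ", "))
  structure(data.frame(marker_id = marker_id, class = class,
                       moltype = moltype, sequence = toupper(sequence),
                       stringsAsFactors = FALSE),
            class = c("marker_panel", "data.frame"))
}

#' @rdname marker_panel
#' @param path FASTA file with `id|class|moltype` headers.
#' @export
read_marker_panel <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tok <- strsplit(sub("\\s.*$", "", names(x)), "|", fixed = TRUE)
  if (any(lengths(tok) != 3))
    stop("panel FASTA headers must be 'id|class|moltype'")
  marker_panel(vapply(tok, `[`, character(1), 1),
               vapply(tok, `[`, character(1), 2),
               vapply(tok, `[`, character(1), 3),
               as.character(x))
}

#' @rdname marker_panel
#' @param panel a `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  x <- Biostrings::BStringSet(panel$sequence)
  names(x) <- sprintf("%s|%s|%s", panel$marker_id, panel$class,
                      panel$moltype)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

empty_hits <- function() {
  data.frame(marker_id = character(), gene_id = character(),
             score = numeric(), identity = numeric(),
             marker_start = integer(), marker_end = integer(),
             gene_start = integer(), gene_end = integer(),
             frame = integer(), stringsAsFactors = FALSE)
}

# convert a span on a translated frame back to forward nucleotide coords
frame_to_nt <- function(frame, aa_start, aa_end, gene_len) {
  off <- abs(frame) - 1L
  s <- off + 3L * aa_start
  e <- off + 3L * aa_end
  if (frame > 0) c(s, e) else c(gene_len - e, gene_len - s)
}

#' Search gene clusters for known marker genes
#'
#' Local-alignment homology search of a marker panel against cluster
#' representatives. Nucleotide markers are aligned against each
#' representative and its reverse complement; protein markers against all
#' six translated frames (a translated, tblastn-style search). The best
#' alignment per (marker, gene) pair is kept and reported when both the
#' score and identity thresholds are met. Spans are 0-based half-open in
#' forward nucleotide coordinates of the representative; `frame` is 0 for
#' nucleotide hits (strand in `strand`) and +-1..3 for translated hits,
#' the sign carrying the strand.
#'
#' @param clusters a `gene_clusters` data frame (or any data frame with
#'   `cluster_id` and `representative` columns).
#' @param panel a [marker_panel()].
#' @param min_score,min_identity reporting thresholds (defaults 40 and
#'   0.7; raw score and identity stand in for database-dependent E-value
#'   statistics).
#' @param match,mismatch,gap_open,gap_extend alignment scoring, passed to
#'   [smith_waterman()].
#' @return A data frame of alignment hits sorted by marker then descending
#'   score.
#' @export
marker_search <- function(clusters, panel, min_score = 40,
                          min_identity = 0.7, match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2) {
  if (min_score < 0 || min_identity < 0) stop("thresholds must be >= 0")
  if (nrow(panel) == 0 || nrow(clusters) == 0) return(empty_hits())
  sw <- function(a, b) sw_align_cpp(a, b, match, mismatch, gap_open,
                                    gap_extend)
  rows <- list()
  for (mi in seq_len(nrow(panel))) {
    mk <- panel[mi, ]
    for (gi in seq_len(nrow(clusters))) {
      rep_seq <- toupper(clusters$representative[gi])
      gene_len <- nchar(rep_seq)
      best <- NULL
      if (mk$moltype == "nucleotide") {
        for (strand in c("+", "-")) {
          target <- if (strand == "+") rep_seq else revcomp(rep_seq)
          h <- sw(mk$sequence, target)
          if (is.null(best) || h$score > best$h$score)
            best <- list(h = h, frame = 0L, strand = strand)
        }
      } else {
        frames <- six_frame_translate(rep_seq)
        for (f in seq_along(frames)) {
          if (!nzchar(frames[f])) next
          h <- sw(mk$sequence, frames[f])
          fr <- c(1L, 2L, 3L, -1L, -2L, -3L)[f]
          if (is.null(best) || h$score > best$h$score)
            best <- list(h = h, frame = fr,
                         strand = if (fr > 0) "+" else "-")
        }
      }
      if (is.null(best)) next
      h <- best$h
      if (h$score < min_score || h$identity < min_identity) next
      if (best$frame == 0L) {
        span <- c(h$b_start, h$b_end)
        if (best$strand == "-")
          span <- c(gene_len - h$b_end, gene_len - h$b_start)
      } else {
        span <- frame_to_nt(best$frame, h$b_start, h$b_end, gene_len)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = mk$marker_id, gene_id = clusters$cluster_id[gi],
        score = h$score, identity = h$identity,
        marker_start = h$a_start, marker_end = h$a_end,
        gene_start = as.integer(span[1]), gene_end = as.integer(span[2]),
        frame = best$frame, strand = best$strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  res <- do.call(rbind, rows)
  res[order(res$marker_id, -res$score), , drop = FALSE]
}

#' Group marker hits into isoform families
#'
#' All genes hitting a marker form that marker's family. Each member's
#' identity to every known sequence variant of the marker is measured by
#' local alignment; a member identical to some known variant is an
#' existing isoform, a member below `novel_min_identity` to all variants
#' is dropped as too diverged, and anything in between is flagged as a
#' candidate novel isoform (the way tissue-specific variants such as new
#' members of the N16 family surface in EST libraries).
#'
#' @param hits output of [marker_search()], best hit per (marker, gene).
#' @param clusters the `gene_clusters` the hits refer to.
#' @param known_variants named list: `marker_id` -> character vector of
#'   known nucleotide sequence variants (include the canonical sequence).
#' @param novel_min_identity identity floor for family membership
#'   (default 0.5).
#' @return An `isoform_families` data frame: `marker_id`, `gene_id`,
#'   `identity` (to the marker, from the hit), `variant_identity` (max
#'   identity to any known variant) and `novel`; members sorted by
#'   descending identity within marker.
#' @export
group_isoforms <- function(hits, clusters, known_variants,
                           novel_min_identity = 0.5) {
  if (anyDuplicated(hits[, c("marker_id", "gene_id")]))
    stop("`hits` must contain one row per (marker, gene) pair")
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    mk <- hits$marker_id[i]
    vars <- known_variants[[mk]]
    if (is.null(vars))
      stop("no known variants supplied for marker ", mk)
    rep_seq <- clusters$representative[match(hits$gene_id[i],
                                             clusters$cluster_id)]
    vid <- max(vapply(vars, function(v)
      smith_waterman(rep_seq, v)$identity, numeric(1)))
    if (vid < novel_min_identity) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker_id = mk, gene_id = hits$gene_id[i],
      identity = hits$identity[i], variant_identity = vid,
      novel = vid < 1, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows)
  else data.frame(marker_id = character(), gene_id = character(),
                  identity = numeric(), variant_identity = numeric(),
                  novel = logical(), stringsAsFactors = FALSE)
  res <- res[order(res$marker_id, -res$identity), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("isoform_families", "data.frame")
  res
}
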