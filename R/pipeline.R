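#' Pipeline configuration
#'
#' Collects every tunable of the simulate-trim-cluster-normalize-screen
#' pipeline in one serializable list. Defaults follow the package-wide
#' conventions: a 40-read reliability cut, a 200-read high-expression
#' tier, a 2-fold dominance rule, 95% clustering identity with 12-mer
#' seeds, Q20/10-base window trimming, and +2/-3 with 5/2 affine-gap
#' alignment scoring.
#'
#' @param ... named overrides of any default (nested lists are replaced
#'   whole-sale per leaf, e.g. `sim = list(n_genes = 80)` keeps the other
#'   `sim` entries).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    tissue_names = TISSUES,
    sim = list(n_genes = 60L, n_nacreous = 12L, n_prismatic = 12L,
               n_families = 3L, fold_effect = 4, dispersion = 0.05,
               depths = c(ME = 8000L, P = 8000L, PS = 8000L),
               read_len = 250L, seq_len_range = c(400L, 900L),
               substitution_rate = 0.005, quality_high = 38L,
               quality_low = 8L, low_quality_tail_len = 10L),
    trim = list(window = 10L, min_mean_q = 20L, min_len = 50L),
    cluster = list(k = 12L, min_identity = 0.95),
    screen = list(fold = 2, min_total = 40L, high_min = 200L,
                  mod_min = 40L, max_cluster_size = 8L,
                  log_transform = FALSE),
    homology = list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2,
                    min_score = 40, min_identity = 0.7,
                    markers_per_class = 3L, novel_min_identity = 0.5))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (sub in names(over[[nm]])) cfg[[nm]][[sub]] <- over[[nm]][[sub]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(sim$n_genes >= 1, sim$fold_effect >= 1, sim$dispersion >= 0,
              all(sim$depths > 0), screen$fold > 0, screen$min_total >= 0,
              screen$mod_min < screen$high_min,
              cluster$min_identity > 0, cluster$min_identity <= 1,
              cluster$k >= 4, trim$window >= 1)
  })
  invisible(cfg)
}

#' Save / load a pipeline configuration as YAML
#'
#' `load_config(save_config(cfg))` round-trips the configuration.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` a
#'   `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$sim$depths <- as.list(out$sim$depths)  # keep tissue names in YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$sim$depths <- unlist(raw$sim$depths)
  raw$sim$seq_len_range <- unlist(raw$sim$seq_len_range)
  raw$tissue_names <- unlist(raw$tissue_names)
  do.call(pipeline_config, raw)
}

# Match cluster representatives back to simulated source genes: ungapped
# identity of the representative against each gene's 3' tail at offset 0
# (representatives are prefixes of the tail by construction of the tag
# protocol). Returns the truth gene_id per cluster, NA when nothing
# reaches `min_identity`.
map_clusters_to_truth <- function(clusters, truth, read_len,
                                  min_identity = 0.9) {
  tails <- substr(truth$genes$sequence,
                  nchar(truth$genes$sequence) - read_len + 1,
                  nchar(truth$genes$sequence))
  tails_int <- lapply(tails, utf8ToInt)
  vapply(clusters$representative, function(rep_seq) {
    r <- utf8ToInt(rep_seq)
    ids <- vapply(tails_int, function(tl) {
      L <- min(length(r), length(tl))
      mean(r[seq_len(L)] == tl[seq_len(L)])
    }, numeric(1))
    if (max(ids) >= min_identity) truth$genes$gene_id[which.max(ids)]
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full screening pipeline on simulated libraries
#'
#' Executes simulate -> emit reads -> trim -> cluster -> TPM ->
#' fold-change screen -> tiered co-clustering -> homology search, writing
#' every intermediate and report to `out_dir` along with a JSON manifest
#' (configuration, seed, file checksums). Marker genes for the
#' co-clustering and homology stages are taken from the simulation truth:
#' the most abundant nacreous and prismatic genes, mapped to their
#' clusters.
#'
#' The run is deterministic for a fixed configuration: running it twice
#' into different directories produces byte-identical tables.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @return Invisibly, a list with the main in-memory results: `truth`,
#'   `counts`, `clusters`, `summary`, `em`, `screen`, `cocluster`,
#'   `hits`, `isoforms`, `marker_map` and `files`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  files <- character(0)

  truth <- stage("simulate", {
    tr <- simulate_transcriptome(
      n_genes = cfg$sim$n_genes, n_nacreous = cfg$sim$n_nacreous,
      n_prismatic = cfg$sim$n_prismatic, n_families = cfg$sim$n_families,
      fold_effect = cfg$sim$fold_effect, dispersion = cfg$sim$dispersion,
      seed = cfg$seed, seq_len_range = cfg$sim$seq_len_range)
    jsonlite::write_json(tr$genes[, c("gene_id", "archetype", "family_id")],
                         fp("truth_genes.json"), na = "null")
    files <- c(files, "truth_genes.json")
    tr
  })

  counts <- stage("sample_counts", {
    cts <- sample_read_counts(truth, cfg$sim$depths, seed = cfg$seed + 1L)
    write_count_matrix(cts, fp("true_counts.tsv"))
    cts
  })

  reads <- stage("emit_reads", {
    em_model <- error_model(cfg$sim$substitution_rate, cfg$sim$quality_high,
                            cfg$sim$quality_low, cfg$sim$low_quality_tail_len)
    rd <- emit_tag_reads(truth, counts, read_len = cfg$sim$read_len,
                         error_mod = em_model, seed = cfg$seed + 2L)
    write_tag_fastq(rd, out_dir)
    rd
  })

  reads_in <- stage("read_fastq", {
    read_tag_reads(fp(sprintf("tags_%s.fastq", TISSUES)))
  })

  trimmed <- stage("trim", {
    trim_reads(reads_in, window = cfg$trim$window,
               min_mean_q = cfg$trim$min_mean_q, min_len = cfg$trim$min_len)
  })

  clusters <- stage("cluster", {
    cl <- cluster_tags(trimmed, k = cfg$cluster$k,
                       min_identity = cfg$cluster$min_identity)
    write_clusters(cl, fasta = fp("clusters.fasta"),
                   tsv = fp("cluster_counts.tsv"))
    cl
  })

  summ <- stage("summary", {
    s <- library_summary(clusters, trimmed)
    jsonlite::write_json(unclass(s), fp("library_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    s
  })

  em <- stage("tpm", {
    e <- compute_tpm(clusters)
    write.table(data.frame(gene_id = rownames(e$tpm), round(e$tpm, 2)),
                fp("tpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    e
  })

  screen <- stage("nacre_screen", {
    sc <- nacre_screen(filter_by_total(em, cfg$screen$min_total),
                       fold = cfg$screen$fold,
                       min_total = cfg$screen$min_total)
    write.table(sc, fp("nacre_screen.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sc
  })

  marker_map <- stage("pick_markers", {
    pick <- function(arch) {
      cand <- truth$genes$gene_id[truth$genes$archetype == arch]
      if (!length(cand)) return(character(0))
      tot <- rowSums(counts)[cand]
      head(cand[order(-tot)], cfg$homology$markers_per_class)
    }
    truth_markers <- c(pick("nacreous"), pick("prismatic"))
    cl_gene <- map_clusters_to_truth(clusters, truth, cfg$sim$read_len)
    mm <- data.frame(truth_gene = truth_markers,
                     cluster_id = clusters$cluster_id[
                       match(truth_markers, cl_gene)],
                     stringsAsFactors = FALSE)
    mm[!is.na(mm$cluster_id), , drop = FALSE]
  })

  cocl <- stage("cocluster", {
    cc <- run_tiered_coclustering(
      em, marker_map$cluster_id, high_min = cfg$screen$high_min,
      mod_min = cfg$screen$mod_min,
      max_cluster_size = cfg$screen$max_cluster_size,
      log_transform = cfg$screen$log_transform)
    for (tier in c("high", "moderate")) {
      rep_t <- cc[[tier]]
      if (!is.null(rep_t))
        write.table(rep_t$hits, fp(sprintf("cocluster_%s.tsv", tier)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ids_high <- tier_split(em, cfg$screen$high_min, cfg$screen$mod_min)$high
    if (length(ids_high) >= 2)
      write_newick(hcluster(em$tpm[ids_high, , drop = FALSE],
                            log_transform = cfg$screen$log_transform),
                   fp("dendrogram_high.nwk"))
    cc
  })

  hits <- stage("homology", {
    panel <- marker_panel(
      marker_id = marker_map$truth_gene,
      class = truth$genes$archetype[match(marker_map$truth_gene,
                                          truth$genes$gene_id)],
      moltype = rep("nucleotide", nrow(marker_map)),
      sequence = truth$genes$sequence[match(marker_map$truth_gene,
                                            truth$genes$gene_id)])
    h <- marker_search(clusters, panel,
                       min_score = cfg$homology$min_score,
                       min_identity = cfg$homology$min_identity,
                       match = cfg$homology$match,
                       mismatch = cfg$homology$mismatch,
                       gap_open = cfg$homology$gap_open,
                       gap_extend = cfg$homology$gap_extend)
    write.table(h, fp("homology_hits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    h
  })

  isoforms <- stage("isoforms", {
    if (nrow(hits)) {
      variants <- as.list(truth$genes$sequence[match(marker_map$truth_gene,
                                                     truth$genes$gene_id)])
      names(variants) <- marker_map$truth_gene
      iso <- group_isoforms(hits, clusters, variants,
                            cfg$homology$novel_min_identity)
    } else iso <- NULL
    if (!is.null(iso))
      write.table(iso, fp("isoform_families.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    iso
  })

  stage("manifest", {
    save_config(cfg, fp("config.yaml"))
    outs <- list.files(out_dir)
    outs <- setdiff(outs, "manifest.json")
    manifest <- list(seed = cfg$seed,
                     config = "config.yaml",
                     config_md5 = unname(tools::md5sum(fp("config.yaml"))),
                     files = as.list(tools::md5sum(file.path(out_dir, outs))))
    names(manifest$files) <- outs
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  })

  invisible(list(truth = truth, counts = counts, clusters = clusters,
                 summary = summ, em = em, screen = screen, cocluster = cocl,
                 hits = hits, isoforms = isoforms, marker_map = marker_map,
                 files = list.files(out_dir, full.names = TRUE)))
}
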