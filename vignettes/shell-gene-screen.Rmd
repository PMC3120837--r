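---
title: "Screening shell-formation genes from 3'-tag EST libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening shell-formation genes from 3'-tag EST libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearlscreen)
```

## The biological problem

The pearl-oyster shell has two calcium-carbonate layers assembled by
different regions of the mantle epithelium: the mantle edge (ME) secretes
the matrix of the outer calcite prisms, while the pallium (P) — and, in
cultured pearls, the pearl sac (PS) — secretes the matrix of the inner
aragonite nacre. A gene whose transcripts are concentrated in the two
nacre-forming tissues is therefore a candidate regulator of nacre
deposition, and a gene tracking the expression profile of a known
shell-matrix gene (nacrein, MSI60, the N16 family, aspein, prismalin-14,
KRMPs, shematrins, ...) is a candidate member of the same functional
program.

`pearlscreen` implements this screening logic for three-tissue 3'-tag EST
libraries: single-pass cDNA reads anchored at the poly(A) end of
transcripts, so that the number of reads per gene in a tissue is a direct
proxy of that gene's expression there.

## The expression statistic

Counts are normalized as transcripts per million:

$$\mathrm{TPM}_{g,t} = \frac{c_{g,t}}{N_t} \times 10^6,$$

where $c_{g,t}$ is the number of reads of gene $g$ in tissue $t$ and
$N_t$ is the total number of assembled reads in tissue $t$. Two
conventions matter and are enforced throughout:

* $N_t$ is always the **library-wide** total. Filtering genes never
  rescales the TPM of the survivors (`filter_by_total()` keeps
  `tissue_totals` fixed), so a full, unfiltered matrix — and only that —
  has TPM columns summing to $10^6$.
* TPM is stored at full precision; integer values appear only in
  printed reports. `invert_tpm()` is the exact inverse at the integer
  level, `round(tpm * N_t / 10^6)`, and is used to verify published TPM
  tables whose raw counts were never printed.

## The two screens

**Fold-change screen** (`nacre_screen()`). A gene is a nacre candidate iff
its total reads reach `min_total` (default 40, below which tag counts are
too noisy to ratio) *and* its TPM in the pallium **or** the pearl sac
strictly exceeds `fold` (default 2) times its mantle-edge TPM. Two edge
rules are deliberate:

* *OR, not AND.* Published candidate sets contain genes dominant in only
  one of the two nacre tissues; requiring both would drop them.
* *Strict inequality,* so a gene exactly at the fold boundary fails; and
  a zero mantle-edge TPM (a blank cell in printed tables) passes whenever
  either nacre tissue is expressed, avoiding a division by zero while
  keeping the intent of "infinitely enriched".

**Co-clustering screen** (`hcluster()`, `marker_cocluster()`,
`run_tiered_coclustering()`). Genes are clustered by their raw TPM
vectors under Euclidean distance with average linkage (UPGMA), the common
default of expression-clustering tools; a `log_transform` flag offers
`log10(TPM + 1)` for exploration but is off by default because the screen
is defined on TPM itself. Genes are first split into highly
(`>= 200` reads) and moderately (40–199) expressed tiers and clustered
within tiers, so that the moderate tier's structure is not dominated by a
few very abundant genes. For each marker the report returns the largest
subtree containing it with at most `max_cluster_size` leaves (default 8,
the size of marker neighbourhoods that expression heatmaps typically
resolve); markers falling in one subtree are merged into a single marker
group. The dendrogram root — the trivial cluster of every gene — is
excluded unless it is the only qualifying subtree, otherwise small inputs
would return the whole gene set as one "cluster". Markers below the
40-read cut are dropped with a warning rather than clustered on
unreliable profiles.

Determinism: when several cluster pairs tie at the minimal distance, the
pair whose sorted pair of smallest member gene ids is lexicographically
least merges first. Average-linkage heights are monotone non-decreasing
toward the root, which the tests assert.

## The homology and isoform search

`smith_waterman()` is an exact local-alignment dynamic program (Gotoh's
affine-gap formulation) with a gap of length $L$ costing
`gap_open + (L - 1) * gap_extend`; setting the two penalties equal gives
linear gaps. Defaults (+2 match, −3 mismatch, 5/2 gaps, minimum score 40,
minimum identity 0.7) are conventional BLASTN-like values. Raw score and
identity thresholds replace E-values on purpose: E-values depend on
database size and Karlin–Altschul parameters that a desk-scale search
need not model. Traceback ties prefer diagonal, then a gap in the
subject, then a gap in the query, making reported spans deterministic.

Nucleotide markers are searched against each cluster representative and
its reverse complement; protein markers against all six translated frames
(`six_frame_translate()`, standard code, partial codons dropped, `N`
codons to `X`), with translated spans mapped back to forward nucleotide
coordinates and the frame sign carrying the strand.

`group_isoforms()` turns hits into families: every gene hitting a marker
belongs to its family; a member identical to a known sequence variant is
an existing isoform, a member below `novel_min_identity` (default 0.5) to
all variants is dropped, and anything between is flagged as a candidate
novel isoform — the pattern by which tissue-specific variants of known
shell-matrix genes surface in EST data. Because identities come from
*local* alignments, a short perfect segment can inflate the identity of a
diverged sequence; the flag is a triage aid, not a curation decision.

## Tag clustering in place of assembly

Real EST pipelines assemble reads and then cluster contigs. The object of
study here is the downstream screen, so `cluster_tags()` uses single-pass
greedy identity clustering in the CD-HIT style: reads sorted by
descending length found clusters (the founder is the representative), and
a read joins the first cluster, in creation order, that it matches with
ungapped identity `>= min_identity` (default 0.95) over at least 80% of
the shorter sequence on a k-mer-seeded diagonal (default k = 12). Gaps
are ignored because 3'-tags of one gene are near-collinear; identical
reads are collapsed before the pass, which cannot change any assignment.
Clusters are numbered by descending total reads as zero-padded six-digit
ids, the naming convention of clustered EST sets.

Quality trimming (`trim_reads()`) removes trailing blocks of `window`
bases (default 10) whose mean Phred quality is below `min_mean_q`
(default 20), stopping at the first passing block, and drops reads
shorter than `min_len` (default 50). Block-wise trailing removal is the
behaviour consistent with the package's worked trimming example (a
60-base Q40 head followed by a Q2 tail is cut to exactly 60 bases) and is
conservative for 3'-tags, which degrade toward their end.

## What the simulator emulates — and what it does not

`simulate_transcriptome()` builds the ground truth the screens assume:

* **Archetypes.** Nacreous genes have pallium and pearl-sac abundance
  `fold_effect` times their mantle-edge abundance; prismatic genes the
  reverse; housekeeping genes are flat. Base abundances are log-normal
  (sdlog 1), giving the heavy-tailed count distributions real tag
  libraries show.
* **Exactness.** Per-tissue abundances must sum to 1 (they are
  multinomial sampling weights) *and* archetype ratios should be exact at
  zero dispersion. Both hold simultaneously because the prismatic group's
  base mass is rescaled so all three tissue columns carry equal totals
  before normalization. When only one archetype group is present this
  balancing is impossible and ratios are exact only up to a common
  per-tissue factor — the library-composition effect real TPM data also
  has.
* **Noise.** Multiplicative log-normal abundance noise (sdlog
  `dispersion`) keeps abundances strictly positive; counts are
  multinomial per tissue, so column sums equal the requested depths
  exactly; reads are the 3'-terminal `read_len` bases (sense strand,
  matching an oligo(dT)-primed protocol) with uniform per-base
  substitutions and a two-level quality string whose low tail exercises
  the trimmer. Isoform families are planted by mutating a family seed to
  a target identity (default 0.90 — close enough to be found by the
  homology search, far enough apart that the 0.95 clustering threshold
  keeps the isoforms as separate clusters, as distinct tissue-specific
  isoforms should be).

Not modelled: pyrosequencing homopolymer/flowgram errors, adapter
sequence, fragmentation-position variability, gapped assembly, chimeras.
Passing tests therefore demonstrate correctness of the screening logic
under clean multinomial sampling, not robustness to every artefact of
real 454 data.

Defaults for scale are desk-sized on purpose: read length 250 bp against
gene lengths of 400–900 bp (3'-tag reads of a few hundred bases), demo
libraries of 60 genes at 8,000 reads per tissue, and recovery experiments
at 20,000 reads per tissue — large enough that a 40-read cut leaves most
genes in play, small enough that the whole pipeline runs in seconds.

## Worked verification against a published candidate table

The package ships the printed summary of a real three-tissue pearl-oyster
tag study (per-tissue assembled-read totals 68,690 / 83,692 / 108,095)
and its 29-row nacre-candidate table as plain-text fixtures.
`verify_candidate_table()` re-derives each candidate's per-tissue counts from its
printed TPM triple, checks the sums against the printed total-read
column, and re-applies the dominance rule:

```{r verify}
v <- verify_candidate_table()
v
head(v$rows[, c("gene_id", "count_me", "count_p", "count_ps",
                "derived_sum", "printed_total", "pass_reason")])
```

All 29 rows pass, including the two one-tissue-only candidates and the
blank-mantle-edge row (whose count sum is unrecoverable and reported as
`NA`). One textual inconsistency is worth noting: the source's prose
gives a pallium read total of 83,629 while its summary table prints
83,692; only the latter is consistent with the printed grand total of
260,477, so the table value is used.

## End-to-end example

```{r pipeline}
cfg <- pipeline_config(
  seed = 11L,
  sim = list(n_genes = 30L, n_nacreous = 6L, n_prismatic = 6L,
             depths = c(ME = 2000L, P = 2000L, PS = 2000L),
             read_len = 120L, seq_len_range = c(250L, 400L)))
run <- run_pipeline(cfg, file.path(tempdir(), "demo_run"))
run$summary
head(run$screen)
```

## Known limitations

* Greedy clustering is order-dependent by construction; with noisy reads
  near the identity threshold, cluster counts can differ from the true
  gene count (the tests pin exact recovery only for error-free input).
* The co-clustering retrieval criterion (largest marker subtree under a
  size cap) is a transparent stand-in for the visual cluster-picking of
  heatmap figures; no significance is attached to retrieved genes.
* Published genome-scale figures (29,682 clusters; 796 genes above the
  cut; tier sizes 195/601) depend on archived raw data and are used only
  as arithmetic fixtures, never recomputed.
* The aligner is exact but quadratic; it is meant for representatives of
  a few kilobases against marker panels of tens of sequences, not for
  genome-scale search.
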