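#' Presence status of NAGs cross-mapped onto one genome
#'
#' For each consolidated NAG, evaluates its status in a genome from the
#' cross-mapped ORF locus: an intact reconstruction is `intact` (1 in the
#' presence matrix); a loss-of-function reconstruction whose mutation is
#' fully read-supported is `pseudogene` (-1); an unsupported apparent
#' mutation keeps the gene present (`intact`, the partially-supported
#' reading); a NAG with no mapped locus is `absent` (0).
#'
#' @param genome A `genome_assembly`.
#' @param genome_id Genome label for the output rows.
#' @param nag_map data.frame of cross-mapped ORF loci in this genome:
#'   `nag_id`, `seqid`, `orf_start`, `orf_end`, `strand`.
#' @param coverage A `coverage_track` for this genome.
#' @param nag_ids All consolidated NAG ids (rows of the matrix).
#' @param config A [nag_config()].
#' @return data.frame `nag_id`, `genome_id`, `status` for
#'   [build_presence_matrix()].
#' @export
nag_presence_calls <- function(genome, genome_id, nag_map, coverage, nag_ids,
                               config = nag_config()) {
  status <- vapply(nag_ids, function(id) {
    row <- nag_map[nag_map$nag_id == id, , drop = FALSE]
    if (nrow(row) == 0L) return("absent")
    locus <- data.frame(seqid = row$seqid[1L], start = row$orf_start[1L],
                        end = row$orf_end[1L], strand = row$strand[1L])
    cds <- reconstruct_cds(genome, locus)
    diag <- classify_cds(cds)
    if (diag$status == "intact") return("intact")
    supp <- verify_support(locus, coverage, config$min_coverage)
    if (supp == "read_supported") "pseudogene" else "intact"
  }, character(1))
  data.frame(nag_id = nag_ids, genome_id = genome_id, status = unname(status))
}

#' Run the full discovery pipeline on a cohort
#'
#' Chains the stages end to end over a cohort of genomes: homology-based
#' gene calling, RNA-seq transcript classification, NAG consolidation and
#' triage, and the presence/absence/pseudogenization matrix. The input
#' list mirrors what [simulate_cohort()] emits; real data are supplied in
#' the same shapes (see the individual stage functions).
#'
#' @param inputs List with `genomes`, `templates`, `mappings`, `coverage`,
#'   `annotations`, `transcripts`, `hit_table` and optionally `nag_loci`
#'   (per-genome cross-mapped NAG ORF loci, for the presence matrix).
#' @param config A [nag_config()].
#' @param reference_tags Assembly tags of the template references whose
#'   hits do not count as chicken-breed support (default the three
#'   reference assemblies).
#' @param nag_id_of Function mapping a NAG candidate/representative id to
#'   its cross-map id; defaults to stripping an `@genome` suffix (the
#'   simulator's naming).
#' @return List with `gene_calls` (per genome), `tx_calls` (per genome),
#'   `nag_table`, `presence` (matrix), `clustering` (when the matrix
#'   admits it, else `NULL`).
#' @export
run_cohort_pipeline <- function(inputs, config = nag_config(),
                                reference_tags = c("GRCg6a", "GRCg7b", "GRCg7w"),
                                nag_id_of = function(id) sub("@.*$", "", id)) {
  gids <- names(inputs$genomes)
  gene_calls <- lapply(gids, function(g)
    annotate_homology(inputs$genomes[[g]], inputs$templates,
                      inputs$mappings[[g]], inputs$coverage[[g]], config))
  names(gene_calls) <- gids

  tx_calls <- lapply(gids, function(g)
    annotate_rnaseq(inputs$genomes[[g]], inputs$transcripts[[g]],
                    inputs$annotations[[g]], config))
  names(tx_calls) <- gids

  # pool coding-NAG candidate sequences across genomes
  seqs <- character(0)
  for (g in gids) {
    tc <- tx_calls[[g]]
    cand <- tc[tc$verdict == "coding_NAG", , drop = FALSE]
    tx <- inputs$transcripts[[g]]
    for (i in seq_len(nrow(cand))) {
      ex <- tx[tx$transcript_id == cand$transcript_id[i], , drop = FALSE]
      seqs[[cand$transcript_id[i]]] <-
        reconstruct_cds(inputs$genomes[[g]], ex)
    }
  }

  nag_table <- consolidate_nags(seqs, inputs$hit_table, reference_tags, config)

  presence <- NULL; clustering <- NULL
  if (!is.null(inputs$nag_loci)) {
    rep_ids <- nag_table$nag_id
    cross_ids <- vapply(rep_ids, nag_id_of, character(1))
    calls <- do.call(rbind, lapply(gids, function(g) {
      pc <- nag_presence_calls(inputs$genomes[[g]], g,
                               inputs$nag_loci[[g]], inputs$coverage[[g]],
                               cross_ids, config)
      pc$nag_id <- rep_ids[match(pc$nag_id, cross_ids)]
      pc
    }))
    presence <- build_presence_matrix(calls)
    presence <- presence[rep_ids, gids, drop = FALSE]
    if (nrow(presence) >= 2L && ncol(presence) >= 2L &&
        length(unique(as.vector(presence))) > 1L)
      clustering <- bicluster(presence)
  }

  list(gene_calls = gene_calls, tx_calls = tx_calls,
       nag_table = nag_table, presence = presence, clustering = clustering)
}
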