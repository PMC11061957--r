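#' Remove redundancy among NAG sequences
#'
#' NAG candidates discovered independently in several genomes are often
#' near-identical copies of the same gene. Greedy clustering: sequences are
#' sorted by length descending (ties by id), and each joins the first
#' existing representative to which its global [pairwise_identity()]
#' strictly exceeds `threshold`; otherwise it founds a new cluster. The
#' representative of a cluster is its founding (longest) member, so
#' sequences at exactly the threshold identity (e.g. 0.985) stay separate.
#'
#' @param seqs Named character vector of NAG sequences.
#' @param threshold Identity above which two sequences are redundant
#'   (default 0.985; strict inequality).
#' @return List with `representatives` (ids), `clusters` (named list:
#'   representative -> member ids, representative first) and `membership`
#'   (named character vector id -> representative).
#' @export
deduplicate_nags <- function(seqs, threshold = 0.985) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)),
            threshold > 0, threshold <= 1)
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)
  clusters <- list()
  membership <- character(0)
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      # identity <= min(len)/max(len): columns >= max(len), matches <= min(len)
      la <- nchar(seqs[[id]]); lb <- nchar(seqs[[r]])
      if (min(la, lb) / max(la, lb) <= threshold) next
      if (pairwise_identity(seqs[[id]], seqs[[r]]) > threshold) {
        clusters[[r]] <- c(clusters[[r]], id)
        membership[[id]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      clusters[[id]] <- id
      membership[[id]] <- id
    }
  }
  list(representatives = reps, clusters = clusters, membership = membership)
}

#' Triage a NAG by the taxonomy of its database hits
#'
#' A NAG with at least one hit to *Gallus gallus* outside the template
#' reference assemblies is chicken-supported (`gNAG`); otherwise a hit to
#' any other species makes it other-species-supported (`oNAG`); with no
#' hits at all it is `novel`.
#'
#' @param hits data.frame of hits for one query: columns `taxon` (species
#'   label) and `tag` (assembly/breed tag, may be `NA`); extra columns
#'   ignored. Zero rows allowed.
#' @param reference_tags Character vector of template assembly tags whose
#'   hits are ignored (the reference genomes the NAG was, by construction,
#'   absent from).
#' @return `"gNAG"`, `"oNAG"` or `"novel"`.
#' @export
classify_nag <- function(hits, reference_tags = character(0)) {
  if (is.null(hits) || nrow(hits) == 0L) return("novel")
  tag <- if ("tag" %in% names(hits)) as.character(hits$tag) else rep(NA_character_, nrow(hits))
  gg <- hits$taxon == "Gallus gallus" & !(tag %in% reference_tags)
  if (any(gg)) return("gNAG")
  if (any(hits$taxon != "Gallus gallus")) return("oNAG")
  "novel"
}

#' Family size of a NAG
#'
#' Estimated as the number of hits the NAG has in the nucleotide database.
#'
#' @param hits Hit data.frame for one query (zero rows allowed).
#' @return Integer hit count.
#' @export
family_size <- function(hits) {
  if (is.null(hits)) 0L else nrow(hits)
}

#' Consolidate per-genome NAG candidates
#'
#' Removes redundancy across genomes, triages each representative by its
#' database hits, and attaches family sizes.
#'
#' @param seqs Named character vector of NAG candidate sequences (all
#'   genomes pooled).
#' @param hit_table data.frame with columns `query`, `taxon`, `tag`,
#'   `identity` (one row per database hit).
#' @param reference_tags Tags of the template reference assemblies.
#' @param config A [nag_config()] (uses `identity_dedup`).
#' @return data.frame with one row per non-redundant NAG: `nag_id`,
#'   `n_members`, `class`, `family_size`, `length`.
#' @export
consolidate_nags <- function(seqs, hit_table, reference_tags = character(0),
                             config = nag_config()) {
  dd <- deduplicate_nags(seqs, threshold = config$identity_dedup)
  hits_by_query <- if (nrow(hit_table)) split(hit_table, hit_table$query) else list()
  rows <- lapply(dd$representatives, function(r) {
    h <- hits_by_query[[r]]
    if (is.null(h)) h <- hit_table[0, , drop = FALSE]
    data.frame(nag_id = r, n_members = length(dd$clusters[[r]]),
               class = classify_nag(h, reference_tags),
               family_size = family_size(h),
               length = nchar(seqs[[r]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  log_stage("consolidate",
            c(input = length(seqs), nonredundant = nrow(out),
              gNAG = sum(out$class == "gNAG"), oNAG = sum(out$class == "oNAG"),
              novel = sum(out$class == "novel")))
  out
}

#' Build the NAG presence/absence/pseudogenization matrix
#'
#' Each NAG is cross-mapped onto every genome of the cohort; the matrix
#' encodes an intact copy as 1, no mapping as 0 and a read-supported
#' pseudogenized copy as -1.
#'
#' @param calls data.frame with columns `nag_id`, `genome_id`, `status`;
#'   `status` is one of `"intact"` (or `"intact_gene"`/`"present"`),
#'   `"absent"` (or `"unmapped"`), `"pseudogene"` (or `"pseudogenized"`).
#'   A (nag, genome) pair may also simply be missing from the table (absent).
#' @return Integer matrix over \{1, 0, -1\} with NAG rows and genome columns.
#' @export
build_presence_matrix <- function(calls) {
  if (anyDuplicated(calls[, c("nag_id", "genome_id")]))
    stop("duplicate (NAG, genome) entries in presence calls")
  code <- c(intact = 1L, intact_gene = 1L, present = 1L,
            absent = 0L, unmapped = 0L,
            pseudogene = -1L, pseudogenized = -1L)
  val <- code[as.character(calls$status)]
  if (any(is.na(val)))
    stop("unknown status value(s): ",
         paste(unique(calls$status[is.na(val)]), collapse = ", "))
  nags <- unique(calls$nag_id)
  genomes <- unique(calls$genome_id)
  m <- matrix(0L, nrow = length(nags), ncol = length(genomes),
              dimnames = list(nags, genomes))
  m[cbind(match(calls$nag_id, nags), match(calls$genome_id, genomes))] <- val
  m
}

#' Two-way hierarchical clustering of a presence matrix
#'
#' Agglomerative clustering of rows (NAGs) and columns (genomes) of the
#' \{1, 0, -1\} matrix, Euclidean distance with Ward linkage (`ward.D2`).
#' Deterministic for a given input.
#'
#' @param mat Presence matrix from [build_presence_matrix()], >= 2 rows and
#'   >= 2 columns with some variation.
#' @param method Linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @return List with `row_order`, `col_order` (labels in dendrogram order)
#'   and `row_hclust`, `col_hclust` (the merge trees).
#' @export
bicluster <- function(mat, method = "ward.D2") {
  stopifnot(nrow(mat) >= 2L, ncol(mat) >= 2L)
  if (length(unique(as.vector(mat))) == 1L)
    stop("no variation to cluster")
  hr <- stats::hclust(stats::dist(mat), method = method)
  hc <- stats::hclust(stats::dist(t(mat)), method = method)
  list(row_order = rownames(mat)[hr$order],
       col_order = colnames(mat)[hc$order],
       row_hclust = hr, col_hclust = hc)
}
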