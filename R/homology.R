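#' Mapped-locus tables
#'
#' Mapped loci come from a spliced aligner run upstream (or from the
#' simulator) and are consumed as a flat table: one row per exon with
#' columns `template_id`, `isoform_id`, `locus_id`, `seqid`, `start`, `end`
#' (0-based half-open), `strand`, `identity` (constant within a locus) and
#' `exon_rank` (transcription order). Helper constructors/validators below.
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame, exons ordered by locus and rank.
#' @export
as_mapped_loci <- function(df) {
  need <- c("template_id", "isoform_id", "locus_id", "seqid", "start", "end",
            "strand", "identity", "exon_rank")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mapped-locus table missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(df$end > df$start), all(df$strand %in% c("+", "-")),
            all(df$identity >= 0 & df$identity <= 1))
  df[order(df$locus_id, df$exon_rank), , drop = FALSE]
}

#' Select the best mapped locus for a template
#'
#' When a template's CDS maps to multiple loci in a target genome, the
#' locus with the highest mapping identity is kept; ties are broken by the
#' lexicographically smallest chromosome name, then smallest start.
#'
#' @param mappings Mapped-locus exon table (see [as_mapped_loci()]) holding
#'   one or more loci for a single template isoform.
#' @return The exon rows of the winning locus, or `NULL` with a
#'   `"template unmapped"` condition message if the table is empty.
#' @export
select_best_locus <- function(mappings) {
  if (is.null(mappings) || nrow(mappings) == 0L) {
    cnd <- structure(class = c("nagpipe_unmapped", "condition"),
                     list(message = "template unmapped", call = NULL))
    signalCondition(cnd)
    return(NULL)
  }
  per <- unique(mappings[, c("locus_id", "identity")])
  first_exon <- mappings[!duplicated(mappings$locus_id), c("locus_id", "seqid", "start")]
  per <- merge(per, first_exon, by = "locus_id")
  locstart <- vapply(split(mappings$start, mappings$locus_id), min, numeric(1))
  per$minstart <- locstart[per$locus_id]
  per <- per[order(-per$identity, per$seqid, per$minstart, per$locus_id), , drop = FALSE]
  best <- per$locus_id[1L]
  mappings[mappings$locus_id == best, , drop = FALSE]
}

#' Reconstruct a projected full-length CDS
#'
#' Concatenates the mapped exon substrings in transcription order to form
#' the putative full-length CDS. Exons are stored in ascending genomic
#' order; on the minus strand the concatenation is reverse-complemented as
#' a unit.
#'
#' @param genome A `genome_assembly` (see [read_genome()]).
#' @param locus Exon rows of one locus (`seqid`, `start`, `end`, `strand`).
#' @return CDS character string.
#' @export
reconstruct_cds <- function(genome, locus) {
  stopifnot(nrow(locus) >= 1L, length(unique(locus$seqid)) == 1L,
            length(unique(locus$strand)) == 1L)
  chrom <- locus$seqid[1L]
  if (!chrom %in% names(genome)) stop("locus chromosome not in genome: ", chrom)
  L <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(locus$start < 0L) || any(locus$end > L))
    stop("exon out of chromosome bounds on ", chrom)
  locus <- locus[order(locus$start), , drop = FALSE]
  pieces <- as.character(Biostrings::extractAt(
    genome[[chrom]], IRanges::IRanges(start = locus$start + 1L, end = locus$end)))
  cds <- paste(pieces, collapse = "")
  if (locus$strand[1L] == "-") cds <- reverse_complement(cds)
  cds
}

#' Diagnose a reconstructed CDS
#'
#' A CDS is `intact` iff its length is a multiple of 3, the last three
#' nucleotides form a stop codon, and no stop codon appears in the middle
#' (after selenoprotein recoding of annotated TGA codons). A premature stop
#' is a `nonsense` mutation (detail = first internal stop's codon ordinal);
#' a length not divisible by 3 is an `orf_shift` mutation (detail = length
#' mod 3). Stop-codon loss (in-frame, clean, but not stop-terminated) is
#' grouped with `orf_shift` (reading runs through the annotated end);
#' its detail is `NA`.
#'
#' @param cds Non-empty CDS string.
#' @param sec_codon_indices 1-based codon ordinals annotated as
#'   selenocysteine in the template.
#' @return List with `status` (`"intact"`, `"nonsense"` or `"orf_shift"`)
#'   and `detail` (codon ordinal, mod-3 residue, or `NA`).
#' @export
classify_cds <- function(cds, sec_codon_indices = integer(0)) {
  stopifnot(nchar(cds) > 0L)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    return(list(status = "orf_shift", detail = n %% 3L))
  res <- tryCatch(translate_cds(cds, sec_codon_indices),
                  nagpipe_internal_stop = function(e) e)
  if (inherits(res, "nagpipe_internal_stop"))
    return(list(status = "nonsense", detail = res$codon))
  last <- toupper(substring(cds, n - 2L, n))
  if (!last %in% c("TAA", "TAG", "TGA"))
    return(list(status = "orf_shift", detail = NA_integer_))
  list(status = "intact", detail = NA_integer_)
}

#' Verify a candidate mutation against short-read coverage
#'
#' A candidate loss-of-function mutation counts as read-supported only if
#' the locus is completely covered by at least `min_cov` perfectly matching
#' short reads at every nucleotide position of every exon. A chromosome
#' missing from the coverage track yields `unsupported` (absence of
#' evidence).
#'
#' @param locus Exon rows of one locus (`seqid`, `start`, `end`).
#' @param coverage A `coverage_track` (see [read_coverage()]).
#' @param min_cov Minimum depth, >= 1 (default 10).
#' @return `"read_supported"` or `"unsupported"`.
#' @export
verify_support <- function(locus, coverage, min_cov = 10L) {
  stopifnot(min_cov >= 1L)
  chrom <- locus$seqid[1L]
  v <- coverage[[chrom]]
  if (is.null(v)) return("unsupported")
  for (i in seq_len(nrow(locus))) {
    s <- locus$start[i]; e <- locus$end[i]
    if (e > length(v)) return("unsupported")
    if (any(v[(s + 1L):e] < min_cov)) return("unsupported")
  }
  "read_supported"
}

#' Final gene call from diagnosis, support and template kind
#'
#' Decision table of the annotation procedure:
#' \itemize{
#'   \item intact CDS from a gene template: `intact_gene`.
#'   \item intact CDS from a pseudogene template, intact ORF fully
#'     read-supported: `gene_from_pseudogene`; without full support the
#'     call stays `pseudogene`.
#'   \item nonsense/ORF-shift with full read support: `pseudogene`.
#'   \item nonsense/ORF-shift without full support, gene template:
#'     `partially_supported_gene` (the apparent mutation may be an
#'     uncorrected long-read error).
#'   \item nonsense/ORF-shift from a pseudogene template: `pseudogene`
#'     regardless of support.
#' }
#'
#' @param status CDS diagnosis status (`"intact"`, `"nonsense"`, `"orf_shift"`).
#' @param support `"read_supported"`, `"unsupported"` or `"not_applicable"`.
#'   For gene templates, `not_applicable` is required iff the diagnosis is
#'   intact; for pseudogene templates support is always evaluated (it gates
#'   the promotion to `gene_from_pseudogene`).
#' @param source_kind `"gene"` or `"pseudogene"` (kind of the template).
#' @return One of `"intact_gene"`, `"partially_supported_gene"`,
#'   `"pseudogene"`, `"gene_from_pseudogene"`.
#' @export
call_gene <- function(status, support, source_kind) {
  stopifnot(status %in% c("intact", "nonsense", "orf_shift"),
            support %in% c("read_supported", "unsupported", "not_applicable"),
            source_kind %in% c("gene", "pseudogene"))
  if (source_kind == "gene") {
    if (status == "intact") {
      if (support != "not_applicable")
        stop("support must be not_applicable for an intact gene-template CDS")
      return("intact_gene")
    }
    if (support == "not_applicable")
      stop("support required for a candidate loss-of-function mutation")
    return(if (support == "read_supported") "pseudogene" else "partially_supported_gene")
  }
  # pseudogene template
  if (support == "not_applicable")
    stop("support is always evaluated for pseudogene templates")
  if (status == "intact" && support == "read_supported") return("gene_from_pseudogene")
  "pseudogene"
}

#' Codons affected by a frameshifting deletion
#'
#' For a CDS of `cds_len` nt (a multiple of 3) carrying a deletion at
#' 1-based CDS positions `del_start..del_end`, every codon from the codon
#' containing the first deleted base through the final codon of the
#' original CDS is affected: `cds_len/3 - ceiling(del_start/3) + 1`.
#' For the mitochondrial ND5 example (1,818-bp CDS, 5-bp deletion at
#' 1,552-1,556) this is 89 codons at the carboxyl terminus.
#'
#' @param cds_len CDS length in nt, divisible by 3.
#' @param del_start,del_end 1-based first and last deleted CDS positions.
#' @return Integer codon count.
#' @export
frameshift_impact <- function(cds_len, del_start, del_end) {
  stopifnot(cds_len %% 3L == 0L, del_start >= 1L, del_end >= del_start,
            del_end <= cds_len)
  as.integer(cds_len %/% 3L - ceiling(del_start / 3) + 1L)
}

#' Homology-based annotation of one genome
#'
#' Projects every template onto the target genome and emits one gene call
#' per template: per isoform, the best-identity locus is selected, the CDS
#' reconstructed and diagnosed; a template is intact if any isoform
#' reconstructs an intact CDS, otherwise the diagnosis of the
#' highest-identity isoform locus is used. Candidate mutations (and intact
#' ORFs from pseudogene templates) are verified against the coverage track
#' before the final call.
#'
#' @param genome A `genome_assembly`.
#' @param templates data.frame with one row per template: `template_id`,
#'   `source_kind` (`"gene"`/`"pseudogene"`) and optionally `sec_codons`
#'   (comma-separated 1-based selenocysteine codon ordinals, `""`/`NA` if none).
#' @param mappings Mapped-locus exon table (see [as_mapped_loci()]).
#' @param coverage A `coverage_track`.
#' @param config A [nag_config()] (uses `min_coverage`, `min_map_identity`).
#' @return data.frame of gene calls: `template_id`, `seqid`, `start`, `end`,
#'   `strand`, `identity`, `diagnosis`, `support`, `status`; templates with
#'   no (qualifying) mapping are reported with status `"absent"`.
#' @export
annotate_homology <- function(genome, templates, mappings, coverage,
                              config = nag_config()) {
  mappings <- as_mapped_loci(mappings)
  mappings <- mappings[mappings$identity >= config$min_map_identity, , drop = FALSE]
  calls <- vector("list", nrow(templates))
  for (i in seq_len(nrow(templates))) {
    tid <- templates$template_id[i]
    kind <- templates$source_kind[i]
    sec <- parse_sec(templates$sec_codons[i])
    tm <- mappings[mappings$template_id == tid, , drop = FALSE]
    if (nrow(tm) == 0L) {
      calls[[i]] <- data.frame(template_id = tid, seqid = NA_character_,
                               start = NA_integer_, end = NA_integer_,
                               strand = NA_character_, identity = NA_real_,
                               diagnosis = NA_character_, support = NA_character_,
                               status = "absent")
      next
    }
    iso_res <- lapply(split(tm, tm$isoform_id), function(im) {
      locus <- select_best_locus(im)
      diag <- classify_cds(reconstruct_cds(genome, locus), sec)
      list(locus = locus, diag = diag, identity = locus$identity[1L])
    })
    intact <- vapply(iso_res, function(r) r$diag$status == "intact", logical(1))
    pick <- if (any(intact)) {
      w <- which(intact)
      w[which.max(vapply(iso_res[w], `[[`, numeric(1), "identity"))]
    } else {
      which.max(vapply(iso_res, `[[`, numeric(1), "identity"))
    }
    r <- iso_res[[pick]]
    needs_support <- r$diag$status != "intact" || kind == "pseudogene"
    supp <- if (needs_support) verify_support(r$locus, coverage, config$min_coverage)
            else "not_applicable"
    status <- call_gene(r$diag$status, supp, kind)
    calls[[i]] <- data.frame(template_id = tid, seqid = r$locus$seqid[1L],
                             start = min(r$locus$start), end = max(r$locus$end),
                             strand = r$locus$strand[1L], identity = r$identity,
                             diagnosis = r$diag$status, support = supp,
                             status = status)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  log_stage("annotate-homology",
            c(templates = nrow(templates),
              intact = sum(out$status == "intact_gene"),
              partially_supported = sum(out$status == "partially_supported_gene"),
              pseudogene = sum(out$status == "pseudogene"),
              gene_from_pseudogene = sum(out$status == "gene_from_pseudogene"),
              absent = sum(out$status == "absent")))
  out
}

parse_sec <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(as.character(x), ",", fixed = TRUE)[[1L]])
}

#' Per-genome annotation summary
#'
#' Tabulates gene calls into the per-genome summary rows (counts of intact,
#' partially supported, pseudogene, gene-from-pseudogene and absent
#' templates).
#'
#' @param calls Gene-call data.frame from [annotate_homology()].
#' @return Named integer vector of counts.
#' @export
summarize_calls <- function(calls) {
  lv <- c("intact_gene", "partially_supported_gene", "pseudogene",
          "gene_from_pseudogene", "absent")
  table(factor(calls$status, levels = lv))
}
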