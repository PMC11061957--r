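#' Does a mapped transcript overlap existing annotation?
#'
#' A transcript is discarded from new-gene calling if at least 1 bp of any
#' of its exons overlaps any annotated gene, pseudogene or non-coding RNA
#' span. The test is strand-blind by default; `overlap_level = "span"`
#' compares the transcript's genomic span instead of individual exons.
#'
#' @param exons data.frame of the transcript's exons: `seqid`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @param annotations Feature data.frame (`seqid`, `start`, `end`, `strand`)
#'   of existing genes/pseudogenes/ncRNAs.
#' @param stranded Require matching strand? (default FALSE)
#' @param level `"exon"` (default) or `"span"`.
#' @return Logical scalar.
#' @export
overlaps_existing <- function(exons, annotations, stranded = FALSE,
                              level = c("exon", "span")) {
  level <- match.arg(level)
  if (nrow(annotations) == 0L || nrow(exons) == 0L) return(FALSE)
  q <- exons
  if (level == "span")
    q <- data.frame(seqid = exons$seqid[1L], start = min(exons$start),
                    end = max(exons$end), strand = exons$strand[1L])
  for (i in seq_len(nrow(q))) {
    a <- annotations[annotations$seqid == q$seqid[i], , drop = FALSE]
    if (stranded) a <- a[a$strand == q$strand[i], , drop = FALSE]
    if (nrow(a) == 0L) next
    # half-open intervals overlap iff start < other end on both sides
    if (any(q$start[i] < a$end & a$start < q$end[i])) return(TRUE)
  }
  FALSE
}

#' Classify a mapped assembled transcript
#'
#' A transcript not overlapping existing annotation is called a new
#' protein-coding gene (`coding_NAG`) if it contains at least one ORF and
#' the longest is at least `min_orf` nt; an ORF-free transcript (no ORF
#' reaching `min_orf`) longer than `lnc_min` nt is a `lncRNA`; anything
#' else is `unclassified`.
#'
#' @param seq Spliced transcript sequence.
#' @param min_orf Coding threshold in nt including the stop codon (default 300).
#' @param lnc_min lncRNA length threshold, exclusive (default 1000).
#' @return List with `verdict` and `longest_orf` (nt; 0 when none >= 6 nt).
#' @export
classify_transcript <- function(seq, min_orf = 300L, lnc_min = 1000L) {
  lo <- longest_orf(seq, min_len = 6L)
  if (lo >= min_orf)
    return(list(verdict = "coding_NAG", longest_orf = lo))
  if (nchar(seq) > lnc_min)
    return(list(verdict = "lncRNA", longest_orf = lo))
  list(verdict = "unclassified", longest_orf = lo)
}

#' RNA-seq-based annotation of one genome
#'
#' Partitions every mapped assembled transcript into exactly one of four
#' verdicts: `overlaps_existing` (already covered by homology-based or
#' ncRNA annotation), `coding_NAG`, `lncRNA` or `unclassified`.
#'
#' @param genome A `genome_assembly` (used to reconstruct spliced sequences
#'   when `transcripts$seq` is absent).
#' @param transcripts data.frame with one row per transcript exon:
#'   `transcript_id`, `seqid`, `start`, `end`, `strand`, `exon_rank`;
#'   optionally a per-transcript `seq` (spliced sequence) column.
#' @param annotations Existing-annotation feature data.frame.
#' @param config A [nag_config()] (uses `min_orf`, `lncrna_min_len`,
#'   `overlap_stranded`, `overlap_level`).
#' @return data.frame with `transcript_id`, `seqid`, `start`, `end`,
#'   `strand`, `length`, `longest_orf`, `verdict`.
#' @export
annotate_rnaseq <- function(genome, transcripts, annotations,
                            config = nag_config()) {
  by_tx <- split(transcripts, transcripts$transcript_id)
  rows <- lapply(names(by_tx), function(tid) {
    ex <- by_tx[[tid]]
    ex <- ex[order(ex$start), , drop = FALSE]
    seq <- if ("seq" %in% names(ex) && !is.na(ex$seq[1L]) && nzchar(ex$seq[1L]))
      ex$seq[1L] else reconstruct_cds(genome, ex)
    if (overlaps_existing(ex, annotations, stranded = config$overlap_stranded,
                          level = config$overlap_level)) {
      verdict <- "overlaps_existing"; lo <- NA_integer_
    } else {
      cl <- classify_transcript(seq, config$min_orf, config$lncrna_min_len)
      verdict <- cl$verdict; lo <- cl$longest_orf
    }
    data.frame(transcript_id = tid, seqid = ex$seqid[1L],
               start = min(ex$start), end = max(ex$end),
               strand = ex$strand[1L], length = nchar(seq),
               longest_orf = lo, verdict = verdict)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  log_stage("annotate-rnaseq",
            c(transcripts = nrow(out),
              overlaps = sum(out$verdict == "overlaps_existing"),
              coding_NAG = sum(out$verdict == "coding_NAG"),
              lncRNA = sum(out$verdict == "lncRNA"),
              unclassified = sum(out$verdict == "unclassified")))
  out
}
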