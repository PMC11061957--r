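#' G/C content of a nucleotide sequence
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T). Unknown bases (N) are excluded
#' from both numerator and denominator, so a run of Ns does not dilute the
#' estimate. An empty or all-N sequence has undefined G/C content and
#' returns `NA_real_` rather than 0.
#'
#' @param seq A character scalar, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet]/`XStringViews` (vectorised over elements).
#' @return Numeric fraction(s) in `[0, 1]`, or `NA_real_` where undefined.
#' @export
gc_content <- function(seq) {
  if (is.character(seq)) {
    if (length(seq) == 1L) seq <- Biostrings::DNAString(seq)
    else seq <- Biostrings::DNAStringSet(seq)
  }
  af <- Biostrings::letterFrequency(seq, letters = c("A", "C", "G", "T"))
  if (is.null(dim(af))) af <- matrix(af, nrow = 1L, dimnames = list(NULL, names(af)))
  denom <- rowSums(af)
  out <- ifelse(denom == 0, NA_real_, (af[, "C"] + af[, "G"]) / denom)
  unname(out)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over A/C/G/T/N.
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find open reading frames on the sense strand of a transcript
#'
#' An ORF starts at ATG, ends at the first in-frame stop (TAA/TAG/TGA)
#' downstream with no internal in-frame stop, and its length (nt, counted
#' including the stop codon) must reach `min_len`. All three frames of the
#' given strand are scanned; genome-guided transcripts are already oriented,
#' so the reverse strand is not searched.
#'
#' @param seq Transcript sequence (character scalar).
#' @param min_len Minimum ORF length in nt including the stop codon;
#'   must be >= 6 and a multiple of 3 (default 300, the protein-coding
#'   gene threshold).
#' @return data.frame with columns `start`, `end` (0-based half-open on the
#'   transcript), `frame` (0-2) and `length`, sorted by length descending,
#'   ties by leftmost start. Zero rows when no ORF qualifies.
#' @export
find_orfs <- function(seq, min_len = 300L) {
  stopifnot(min_len >= 6L, min_len %% 3L == 0L)
  n <- nchar(seq)
  seq <- toupper(seq)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    cod_start <- frame + 3L * (seq_len(ncod) - 1L)        # 0-based
    codons <- substring(seq, cod_start + 1L, cod_start + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% stops
    if (!any(is_atg) || !any(is_stop)) next
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      s <- stop_idx[stop_idx > a]
      if (length(s) == 0L) next
      s <- s[1L]
      len <- (s - a + 1L) * 3L
      if (len >= min_len)
        out[[length(out) + 1L]] <- c(start = cod_start[a],
                                     end = cod_start[s] + 3L,
                                     frame = frame, length = len)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(-df$length, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Longest ORF length of a transcript
#'
#' @inheritParams find_orfs
#' @return Length in nt of the longest ORF of at least `min_len` nt
#'   (including the stop codon), or 0 when none exists.
#' @export
longest_orf <- function(seq, min_len = 6L) {
  orfs <- find_orfs(seq, min_len = min_len)
  if (nrow(orfs) == 0L) 0L else orfs$length[1L]
}

#' Translate a CDS with selenoprotein recoding
#'
#' Standard genetic code. A TGA codon whose 1-based codon ordinal is listed
#' in `sec_codon_indices` is translated as selenocysteine (`U`) instead of
#' terminating; the terminal stop codon is dropped. Any other internal stop
#' raises an error of class `nagpipe_internal_stop` carrying the codon
#' ordinal (used by [classify_cds()] to locate nonsense mutations).
#'
#' @param cds CDS sequence, length a multiple of 3.
#' @param sec_codon_indices Integer vector of 1-based codon ordinals
#'   annotated as selenocysteine (possibly empty).
#' @return Protein string; codons containing N translate to `X`.
#' @export
translate_cds <- function(cds, sec_codon_indices = integer(0)) {
  cds <- toupper(cds)
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L, n >= 3L)
  ncod <- n %/% 3L
  codons <- substring(cds, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- gc_tab[codons]
  aa[is.na(aa)] <- "X"
  is_stop <- aa == "*"
  sec <- intersect(which(is_stop & codons == "TGA"), sec_codon_indices)
  aa[sec] <- "U"
  is_stop[sec] <- FALSE
  internal <- unname(which(is_stop & seq_len(ncod) < ncod))
  if (length(internal) > 0L) {
    cnd <- structure(class = c("nagpipe_internal_stop", "error", "condition"),
                     list(message = sprintf("internal stop codon at codon %d", internal[1L]),
                          call = sys.call(-1L), codon = internal[1L]))
    stop(cnd)
  }
  if (is_stop[ncod]) aa <- aa[-ncod]
  paste(aa, collapse = "")
}

#' Scan for canonical G-quadruplex motifs
#'
#' Matches the minimal literature-standard quadruplex pattern
#' `G{3,}(N{1,7}G{3,}){3}` — four runs of at least three guanines separated
#' by loops of 1-7 nt — non-overlapping and leftmost-greedy, on both
#' strands (the minus strand is scanned on the reverse complement and
#' coordinates mapped back). N never participates in a G run.
#'
#' @param seq Character scalar.
#' @return data.frame with columns `start`, `end` (0-based half-open on the
#'   forward sequence) and `strand`.
#' @export
scan_g4 <- function(seq) {
  seq <- toupper(seq)
  pat <- "G{3,}([ACGTN]{1,7}G{3,}){3}"
  one_strand <- function(s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(data.frame(start = integer(0), end = integer(0)))
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"))
  }
  fwd <- one_strand(seq)
  fwd$strand <- rep("+", nrow(fwd))
  L <- nchar(seq)
  rc <- one_strand(reverse_complement(seq))
  rev <- data.frame(start = L - rc$end, end = L - rc$start,
                    strand = rep("-", nrow(rc)))
  out <- rbind(fwd, rev)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' G-quadruplex frequency (motifs per kbp)
#'
#' @inheritParams scan_g4
#' @return Motif count per kbp of scanned sequence (both strands pooled).
#' @export
g4_frequency <- function(seq) {
  L <- nchar(seq)
  if (L == 0L) return(NA_real_)
  nrow(scan_g4(seq)) / (L / 1000)
}

.nagpipe_cache <- new.env(parent = emptyenv())

.submat_unit <- function() {
  if (is.null(.nagpipe_cache$submat))
    .nagpipe_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = FALSE)
  .nagpipe_cache$submat
}

#' Global pairwise identity of two sequences
#'
#' Needleman-Wunsch global alignment scored with match +1, mismatch 0 and
#' unit gap cost; identity is the number of matched columns divided by the
#' total number of alignment columns (gaps included). This whole-sequence
#' identity drives the redundancy-removal threshold (> 98.5%) when
#' consolidating NAGs across genomes.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Fraction in `[0, 1]`, with attributes `matches` and `columns`
#'   giving the alignment bookkeeping.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (a == b) return(structure(1, matches = nchar(a), columns = nchar(a)))
  # canonical argument order: co-optimal alignments can differ in their
  # match/column split, so fix the orientation to keep identity symmetric
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  mat <- .submat_unit()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(p)
  matches <- sum(strsplit(p, "")[[1L]] == strsplit(s, "")[[1L]] &
                   strsplit(p, "")[[1L]] != "-")
  structure(matches / cols, matches = matches, columns = cols)
}
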