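#' Read a genome assembly from FASTA
#'
#' Loads chromosome sequences, upper-cases them, validates the alphabet
#' (A, C, G, T, N only) and attaches a size-class label per chromosome
#' (see [chromosome_class()]).
#'
#' @param path Path to a FASTA file.
#' @return A `genome_assembly`: a [Biostrings::DNAStringSet] with unique
#'   names and a `chrom_class` metadata column holding the size class.
#' @seealso [write_genome()], [chromosome_class()]
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  af <- Biostrings::alphabetFrequency(seqs)
  bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE]) > 0
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  as_genome_assembly(seqs)
}

#' @rdname read_genome
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @export
as_genome_assembly <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  S4Vectors::mcols(seqs)$chrom_class <- chromosome_class(names(seqs))
  seqs
}

#' @rdname read_genome
#' @param genome A `genome_assembly`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read genomic features from GFF3
#'
#' Parses a GFF3 file into a flat feature table. Coordinates are converted
#' to the package-internal 0-based half-open convention; [write_features()]
#' converts back, so printed GFF3 is always 1-based inclusive. The pair of
#' functions is the single place the coordinate shift happens.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `seqid`, `type`, `start`, `end`
#'   (0-based half-open), `strand`, `id`, `parent`, `status`, `class`.
#'   CDS rows sharing a parent keep their file order.
#' @export
read_features <- function(path) {
  stopifnot(file.exists(path))
  ln <- readLines(path, warn = FALSE)
  feat <- !startsWith(ln, "#") & nzchar(ln)
  if (any(feat)) {
    parts <- strsplit(ln[feat], "\t", fixed = TRUE)
    st <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 4L)))
    en <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 5L)))
    bad <- which(!is.na(st) & !is.na(en) & en < st)
    if (length(bad))
      stop("end < start at line ", which(feat)[bad[1L]], " of ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (!nm %in% colnames(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[nm]]
    if (methods::is(v, "List")) v <- vapply(v, function(x)
      if (length(x)) as.character(x[[1]]) else NA_character_, character(1))
    as.character(v)
  }
  data.frame(
    seqid  = as.character(GenomicRanges::seqnames(gr)),
    type   = as.character(mc$type),
    start  = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id     = getcol("ID"),
    parent = getcol("Parent"),
    status = getcol("status"),
    class  = getcol("class"),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_features
#' @param features A feature data.frame as returned by [read_features()].
#' @export
write_features <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges   = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand   = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
  gr$type <- features$type
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  gr$ID <- features$id
  if (!is.null(features$parent) && any(!is.na(features$parent)))
    gr$Parent <- features$parent
  if (!is.null(features$status) && any(!is.na(features$status)))
    gr$status <- features$status
  if (!is.null(features$class) && any(!is.na(features$class)))
    gr$class <- features$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a per-base coverage track from bedGraph
#'
#' Expands a 4-column bedGraph (0-based half-open intervals) into per-base
#' integer depths. Positions absent from the file have depth 0. Used by
#' [verify_support()] to test the >=10x read-support rule for candidate
#' loss-of-function mutations.
#'
#' @param path Path to a bedGraph file.
#' @param seq_lengths Optional named integer vector of chromosome lengths;
#'   when given, each track is padded with zeros to full length.
#' @return A `coverage_track`: named list of non-negative integer vectors.
#' @export
read_coverage <- function(path, seq_lengths = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  depth <- as.numeric(gr$score)
  if (any(depth < 0)) stop("negative depth in bedGraph: ", path)
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), depth = depth)
  tracks <- lapply(split(df, df$seqid), function(d) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping bedGraph intervals on ", d$seqid[1L])
    len <- max(d$end)
    v <- integer(len)
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- as.integer(d$depth[i])
    v
  })
  if (!is.null(seq_lengths)) {
    for (nm in names(seq_lengths)) {
      v <- if (nm %in% names(tracks)) tracks[[nm]] else integer(0)
      if (length(v) < seq_lengths[[nm]]) v <- c(v, integer(seq_lengths[[nm]] - length(v)))
      tracks[[nm]] <- v
    }
  }
  structure(tracks, class = "coverage_track")
}

#' @rdname read_coverage
#' @param track A `coverage_track` (named list of per-base depth vectors).
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(track)) {
    v <- as.integer(track[[nm]])
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths   # 0-based
    keep <- r$values != 0L
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", nm, starts[keep], ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Flat key-value configuration holding the thresholds of the discovery
#' procedure. Every value can be overridden per call; these are the
#' pipeline-wide defaults.
#'
#' @param min_coverage Minimum per-base perfect-read depth for a
#'   loss-of-function mutation to count as read-supported (default 10).
#' @param min_orf Minimum ORF length, nt including the stop codon, for a
#'   transcript to be called protein-coding (default 300).
#' @param lncrna_min_len Minimum transcript length, exclusive, for an
#'   ORF-free transcript to be called a lncRNA (default 1000).
#' @param identity_dedup Pairwise identity above which two NAG sequences are
#'   redundant (strict inequality; default 0.985).
#' @param window G/C-vs-density window size in bp (default 1e6).
#' @param bins Number of equal portions per chromosome for positional
#'   profiles (default 100).
#' @param min_map_identity Mapping identity below which a template is
#'   declared absent (default 0 = any mapping counts).
#' @param overlap_stranded Should the transcript-vs-annotation overlap test
#'   respect strand? (default FALSE)
#' @param overlap_level `"exon"` or `"span"` overlap test (default exon).
#' @param flank Flanking-region size in bp for gene-context statistics
#'   (default 1e6).
#' @return A named list of class `nag_config`.
#' @export
nag_config <- function(min_coverage = 10L, min_orf = 300L, lncrna_min_len = 1000L,
                       identity_dedup = 0.985, window = 1000000L, bins = 100L,
                       min_map_identity = 0, overlap_stranded = FALSE,
                       overlap_level = c("exon", "span"), flank = 1000000L) {
  overlap_level <- match.arg(overlap_level)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_orf = as.integer(min_orf),
                 lncrna_min_len = as.integer(lncrna_min_len),
                 identity_dedup = identity_dedup,
                 window = as.integer(window), bins = as.integer(bins),
                 min_map_identity = min_map_identity,
                 overlap_stranded = overlap_stranded,
                 overlap_level = overlap_level,
                 flank = as.integer(flank)),
            class = "nag_config")
}

#' @rdname nag_config
#' @param path Path to a flat `key=value` text file; `#` starts a comment.
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", ln[bad][1L])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  cfg <- nag_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    v <- vals[i]
    cfg[[k]] <- if (is.logical(cfg[[k]])) as.logical(v)
      else if (is.character(cfg[[k]])) v
      else if (is.integer(cfg[[k]])) as.integer(v)
      else as.numeric(v)
  }
  cfg
}

#' Stage logging
#'
#' Records record counts in and out of each pipeline stage so per-genome
#' summary tables can be regenerated from logs.
#'
#' @param stage Stage name.
#' @param counts Named integer vector of counts to report.
#' @param verbose Emit a message? (default `getOption("nagpipe.verbose", FALSE)`)
#' @return The counts, invisibly.
#' @export
log_stage <- function(stage, counts, verbose = getOption("nagpipe.verbose", FALSE)) {
  if (isTRUE(verbose))
    message(sprintf("[%s] %s", stage,
                    paste(sprintf("%s=%d", names(counts), counts), collapse = " ")))
  invisible(counts)
}

#' Format a percentage the way the summary tables print it
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places as printed (default 1).
#' @return Numeric percentage rounded to `digits` places (e.g. 89.9).
#' @export
format_percent <- function(count, total, digits = 1L) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}
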