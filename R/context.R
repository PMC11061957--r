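#' Chicken chromosome size class
#'
#' chr1-chr5 and chrZ are macro-chromosomes, chr6-chr13 and chrW middle
#' chromosomes, chr14-chr39 micro-chromosomes; anything else (unplaced
#' contigs, scaffolds, MT) is `unplaced`. Parsing tolerates case and a
#' missing `chr` prefix.
#'
#' @param name Character vector of chromosome names.
#' @return Factor with levels `macro`, `middle`, `micro`, `unplaced`.
#' @export
chromosome_class <- function(name) {
  core <- sub("^chr", "", tolower(name))
  out <- rep("unplaced", length(name))
  out[core == "z"] <- "macro"
  out[core == "w"] <- "middle"
  num <- suppressWarnings(as.integer(core))
  isnum <- !is.na(num) & grepl("^[0-9]+$", core)
  out[isnum & num >= 1 & num <= 5] <- "macro"
  out[isnum & num >= 6 & num <= 13] <- "middle"
  out[isnum & num >= 14 & num <= 39] <- "micro"
  factor(out, levels = c("macro", "middle", "micro", "unplaced"))
}

#' Windowed G/C content and feature counts
#'
#' Tiles each chromosome into half-open windows of `window` bp from
#' position 0 (the last window is shorter) and computes the N-aware G/C
#' content of each window together with the number of NAGs (and optionally
#' existing genes) whose start falls in it. A feature belongs to exactly
#' one window: the one containing its start.
#'
#' @param genome A `genome_assembly`.
#' @param nags data.frame of NAG loci (`seqid`, `start`); may have 0 rows.
#' @param annotations Optional data.frame of existing gene loci
#'   (`seqid`, `start`).
#' @param window Window size in bp (default 1e6).
#' @return data.frame: `seqid`, `start`, `end`, `gc`, `nag_count`,
#'   `gene_count`.
#' @export
window_stats <- function(genome, nags, annotations = NULL, window = 1000000L) {
  stopifnot(window >= 1L)
  rows <- lapply(names(genome), function(chrom) {
    L <- Biostrings::width(genome)[match(chrom, names(genome))]
    starts <- seq.int(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    v <- Biostrings::Views(genome[[chrom]], start = starts + 1L, end = ends)
    af <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(af)
    gc <- ifelse(denom == 0, NA_real_, (af[, "C"] + af[, "G"]) / denom)
    count_in <- function(feat) {
      if (is.null(feat) || nrow(feat) == 0L) return(integer(length(starts)))
      f <- feat[feat$seqid == chrom, , drop = FALSE]
      tabulate(f$start %/% window + 1L, nbins = length(starts))
    }
    data.frame(seqid = chrom, start = starts, end = ends, gc = gc,
               nag_count = count_in(nags), gene_count = count_in(annotations))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between window G/C and NAG density
#'
#' @param windows Window table from [window_stats()].
#' @return List with `r` (Pearson coefficient) and `n` (windows used).
#' @export
density_gc_correlation <- function(windows) {
  w <- windows[!is.na(windows$gc), , drop = FALSE]
  if (nrow(w) < 3L) stop("need at least 3 windows with defined G/C")
  if (stats::var(w$gc) == 0 || stats::var(w$nag_count) == 0)
    stop("degenerate correlation: zero variance")
  list(r = stats::cor(w$gc, w$nag_count), n = nrow(w))
}

#' Positional G/C and NAG-density profile along chromosomes of a group
#'
#' Splits every chromosome of a size class into `bins` equal-length
#' portions (the last absorbs the remainder), computes per-bin G/C and NAG
#' density (features per Mbp), and averages bin-wise across all
#' chromosomes of the group over one or more genomes. This is the
#' subtelomere-resolving profile: G/C and NAG density rise in the outer
#' bins of macro- and middle chromosomes.
#'
#' @param genomes A `genome_assembly` or list of them.
#' @param nags NAG locus data.frame (`seqid`, `start`), or a list parallel
#'   to `genomes`.
#' @param group `"macro"`, `"middle"` or `"micro"`.
#' @param bins Number of portions (default 100).
#' @return data.frame: `bin` (1..bins), `gc`, `nag_density` (per Mbp),
#'   `n_chromosomes` averaged over.
#' @export
percent_bin_profile <- function(genomes, nags, group, bins = 100L) {
  if (!is.list(genomes) || methods::is(genomes, "DNAStringSet")) {
    genomes <- list(genomes)
    nags <- list(nags)
  }
  gc_acc <- matrix(0, nrow = 0L, ncol = bins)
  dens_acc <- matrix(0, nrow = 0L, ncol = bins)
  for (g in seq_along(genomes)) {
    genome <- genomes[[g]]
    nag <- nags[[g]]
    cls <- chromosome_class(names(genome))
    chroms <- names(genome)[cls == group]
    if (length(chroms) == 0L) next
    for (chrom in chroms) {
      L <- Biostrings::width(genome)[match(chrom, names(genome))]
      if (L < bins) stop("chromosome ", chrom, " shorter than bin count")
      w <- L %/% bins
      starts <- (seq_len(bins) - 1L) * w
      ends <- c(starts[-1L], L)
      v <- Biostrings::Views(genome[[chrom]], start = starts + 1L, end = ends)
      af <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
      denom <- rowSums(af)
      gc <- ifelse(denom == 0, NA_real_, (af[, "C"] + af[, "G"]) / denom)
      f <- nag[nag$seqid == chrom, , drop = FALSE]
      cnt <- tabulate(pmin(f$start %/% w + 1L, bins), nbins = bins)
      dens <- cnt / ((ends - starts) / 1e6)
      gc_acc <- rbind(gc_acc, gc)
      dens_acc <- rbind(dens_acc, dens)
    }
  }
  if (nrow(gc_acc) == 0L) stop("no chromosomes in group ", group)
  data.frame(bin = seq_len(bins),
             gc = colMeans(gc_acc, na.rm = TRUE),
             nag_density = colMeans(dens_acc),
             n_chromosomes = nrow(gc_acc))
}

#' Flanking intervals of a gene
#'
#' The two `flank`-bp regions immediately upstream and downstream of a
#' gene, clipped to the chromosome; empty intervals are dropped.
#'
#' @param start,end Gene interval, 0-based half-open.
#' @param flank Flank size in bp (default 1e6).
#' @param chrom_len Chromosome length.
#' @return data.frame of 0-2 rows with `start`, `end`, `side`
#'   (`"left"`/`"right"`).
#' @export
flank_intervals <- function(start, end, flank = 1000000L, chrom_len) {
  stopifnot(start >= 0L, end > start, end <= chrom_len)
  out <- data.frame(start = c(max(0L, start - flank), end),
                    end = c(start, min(chrom_len, end + flank)),
                    side = c("left", "right"))
  out[out$end > out$start, , drop = FALSE]
}

#' Two-sample comparison of context statistics
#'
#' Wilcoxon rank-sum (exact where [stats::wilcox.test()] uses the exact
#' distribution, normal approximation otherwise) or Welch two-sided t-test.
#' When both groups are constant and equal the comparison is degenerate;
#' p is set to 1 by convention and flagged.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param test `"ranksum"` (default) or `"t"`.
#' @return List with `statistic`, `p`, `test`, `degenerate`.
#' @export
compare_groups <- function(a, b, test = c("ranksum", "t")) {
  test <- match.arg(test)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (length(unique(c(a, b))) == 1L)
    return(list(statistic = NA_real_, p = 1, test = test, degenerate = TRUE))
  res <- if (test == "ranksum")
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  else
    stats::t.test(a, b, alternative = "two.sided")
  list(statistic = unname(res$statistic), p = res$p.value, test = test,
       degenerate = FALSE)
}

#' Body and flank G/C and G4 statistics for a set of genes
#'
#' For each gene: G/C content and G4 frequency (motifs/kbp) of the gene
#' body and of its two flanking regions pooled. These are the inputs to
#' the NAG-vs-existing-gene comparisons.
#'
#' @param genome A `genome_assembly`.
#' @param genes data.frame of gene loci (`seqid`, `start`, `end`).
#' @param flank Flank size in bp (default 1e6).
#' @return data.frame: `gc_body`, `gc_flank`, `g4_body`, `g4_flank`
#'   per gene.
#' @export
gene_context_stats <- function(genome, genes, flank = 1000000L) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    chrom <- genes$seqid[i]
    L <- Biostrings::width(genome)[match(chrom, names(genome))]
    body <- as.character(Biostrings::subseq(genome[[chrom]],
                                            start = genes$start[i] + 1L,
                                            end = genes$end[i]))
    fl <- flank_intervals(genes$start[i], genes$end[i], flank, L)
    flseq <- paste(vapply(seq_len(nrow(fl)), function(j)
      as.character(Biostrings::subseq(genome[[chrom]], start = fl$start[j] + 1L,
                                      end = fl$end[j])), character(1)),
      collapse = "")
    data.frame(gc_body = gc_content(body),
               gc_flank = if (nzchar(flseq)) gc_content(flseq) else NA_real_,
               g4_body = g4_frequency(body),
               g4_flank = if (nzchar(flseq)) g4_frequency(flseq) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
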