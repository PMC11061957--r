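# Independent brute-force oracles used by the unit and acceptance tests.
# Each deliberately re-derives the quantity by enumeration rather than
# reusing the package's code path.

# G/C by per-character tally
gc_oracle <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  denom <- sum(ch %in% c("A", "C", "G", "T"))
  if (denom == 0) return(NA_real_)
  sum(ch %in% c("G", "C")) / denom
}

# ORFs by exhaustive (frame, ATG, stop) triples with explicit
# no-internal-stop check; 1-based input scan, 0-based half-open output
orf_oracle <- function(seq, min_len) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  codon_at <- function(i) substr(seq, i, i + 2)
  res <- list()
  for (a in seq_len(max(0, n - 2))) {
    if (codon_at(a) != "ATG") next
    s <- a + 3
    while (s + 2 <= n) {
      if (codon_at(s) %in% stops) {
        mids <- if (s - 3 >= a + 3) seq(a + 3, s - 3, by = 3) else integer(0)
        clean <- !any(vapply(mids, function(m) codon_at(m) %in% stops,
                             logical(1)))
        len <- s + 3 - a
        if (clean && len >= min_len)
          res[[length(res) + 1]] <- data.frame(start = a - 1L, end = s + 2L,
                                               frame = (a - 1L) %% 3L,
                                               length = len)
        break  # only the nearest stop terminates the ORF
      }
      s <- s + 3
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length = integer(0)))
  df <- do.call(rbind, res)
  df <- df[order(-df$length, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# full-match test of the canonical quadruplex pattern
g4_full_match <- function(s) {
  grepl("^G{3,}([ACGTN]{1,7}G{3,}){3}$", s, perl = TRUE)
}

# leftmost-greedy G4 selection by per-position anchored scan (one strand)
g4_starts_oracle <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  starts <- integer(0)
  i <- 1L
  while (i <= n - 14L) {
    m <- regexpr("^G{3,}([ACGTN]{1,7}G{3,}){3}", substring(seq, i), perl = TRUE)
    if (m[1] == 1L) {
      starts <- c(starts, i - 1L)  # 0-based
      i <- i + attr(m, "match.length")
    } else i <- i + 1L
  }
  starts
}

# optimal global alignment score (match +1, mismatch 0, gap -1) by full DP
nw_score_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  S <- matrix(0, la + 1, lb + 1)
  S[, 1] <- -(0:la); S[1, ] <- -(0:lb)
  for (i in seq_len(la)) for (j in seq_len(lb))
    S[i + 1, j + 1] <- max(S[i, j] + (a[i] == b[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  S[la + 1, lb + 1]
}

# exact two-sided rank-sum p by enumeration of all group assignments
ranksum_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  u_stat <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  obs <- u_stat(seq_len(na))
  idxs <- utils::combn(n, na)
  us <- apply(idxs, 2, u_stat)
  p <- 2 * min(mean(us <= obs), mean(us >= obs))
  min(1, p)
}

# random DNA helpers
rand_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# small shared cohort simulation reused across test files (kept small so
# the default suite stays fast)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 301, n_templates = 30, n_nags = 12,
                        chromosomes = data.frame(
                          name = c("chr1", "chr6", "chr20"),
                          length = c(320000L, 260000L, 240000L)))
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
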