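test_that("chromosome size classes follow the chicken karyotype", {
  expect_equal(as.character(chromosome_class(
    c("chr3", "chrZ", "chr10", "chrW", "chr20", "contig_517", "chr40", "chrMT"))),
    c("macro", "macro", "middle", "middle", "micro", "unplaced", "unplaced",
      "unplaced"))
  expect_equal(as.character(chromosome_class(c("Chr1", "14", "z"))),
               c("macro", "micro", "macro"))
})

test_that("window tiling and per-window G/C match direct slicing", {
  set.seed(10)
  s <- rand_dna(2500)
  g <- as_genome_assembly(c(chr1 = s))
  nags <- data.frame(seqid = "chr1", start = c(999L, 1000L, 2400L))
  w <- window_stats(g, nags, window = 1000L)
  expect_equal(nrow(w), 3L)
  expect_equal(w$end - w$start, c(1000L, 1000L, 500L))
  expect_equal(w$nag_count, c(1L, 1L, 1L))
  for (i in 1:3)
    expect_equal(w$gc[i], gc_oracle(substr(s, w$start[i] + 1, w$end[i])))
  # a feature is counted once, in the window containing its start
  spanner <- data.frame(seqid = "chr1", start = 999999L)
  g2 <- as_genome_assembly(c(chr1 = rand_dna(2000) ))
  w2 <- window_stats(g2, data.frame(seqid = "chr1", start = 1999L),
                     window = 1000L)
  expect_equal(w2$nag_count, c(0L, 1L))
  expect_equal(sum(w$nag_count), nrow(nags))
})

test_that("length-weighted window G/C equals whole-genome G/C", {
  set.seed(20)
  g <- as_genome_assembly(c(chr1 = rand_dna(5234), chr2 = rand_dna(1777)))
  w <- window_stats(g, data.frame(seqid = character(0), start = integer(0)),
                    window = 1000L)
  lens <- w$end - w$start
  whole <- sum(vapply(names(g), function(ch)
    sum(Biostrings::letterFrequency(g[[ch]], c("G", "C"))), numeric(1))) /
    sum(lens)
  expect_equal(sum(w$gc * lens) / sum(lens), whole, tolerance = 1e-12)
})

test_that("density/GC correlation behaves on linear, null and degenerate input", {
  gc <- seq(0.3, 0.6, length.out = 50)
  w <- data.frame(gc = gc, nag_count = round(100 * gc))
  expect_equal(density_gc_correlation(w)$r, 1, tolerance = 0.01)
  set.seed(30)
  w$nag_count <- sample(w$nag_count)
  expect_lt(abs(density_gc_correlation(w)$r), 0.5)
  w$nag_count <- 3L
  expect_error(density_gc_correlation(w), "degenerate")
  expect_error(density_gc_correlation(w[1:2, ]), "at least 3")
})

test_that("bin profiles place features and recover a planted G/C gradient", {
  set.seed(40)
  # flat genome: profile flat within noise
  flat <- as_genome_assembly(c(chr1 = rand_dna(100000)))
  nags <- data.frame(seqid = "chr1", start = c(5L, 50500L))
  p <- percent_bin_profile(flat, nags, "macro", bins = 100L)
  expect_equal(nrow(p), 100L)
  expect_equal(which(p$nag_density > 0), c(1L, 51L))
  expect_lt(diff(range(p$gc)), 0.12)
  # feature at position 5 of a 1000-bp chromosome falls in bin 1
  tiny <- as_genome_assembly(c(chr1 = rand_dna(1000)))
  pt <- percent_bin_profile(tiny, data.frame(seqid = "chr1", start = 5L),
                            "macro", bins = 100L)
  expect_equal(which(pt$nag_density > 0), 1L)
  expect_error(percent_bin_profile(
    as_genome_assembly(c(chr1 = rand_dna(50))), nags, "macro", bins = 100L),
    "shorter")
})

test_that("flank intervals clip at chromosome ends", {
  f <- flank_intervals(0L, 500L, flank = 1000L, chrom_len = 10000L)
  expect_equal(nrow(f), 1L)
  expect_equal(f$side, "right")
  expect_equal(c(f$start, f$end), c(500L, 1500L))
  m <- flank_intervals(5000L, 5100L, flank = 1000L, chrom_len = 10000L)
  expect_equal(nrow(m), 2L)
  expect_equal(m$end - m$start, c(1000L, 1000L))
  set.seed(50)
  for (i in 1:25) {
    L <- sample(2000:10000, 1)
    st <- sample(0:(L - 10), 1); en <- st + sample(1:9, 1)
    fl <- sample(100:3000, 1)
    f <- flank_intervals(st, en, fl, L)
    expect_equal(sum(f$end - f$start),
                 min(fl, st) + min(fl, L - en))
  }
})

test_that("two-sample comparisons give exact small-n and degenerate results", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), "ranksum")
  expect_equal(r$p, 0.1)  # 2/20 of all rank assignments
  expect_equal(r$p, ranksum_p_oracle(c(1, 2, 3), c(4, 5, 6)))
  eq <- compare_groups(c(2, 2), c(2, 2))
  expect_true(eq$degenerate)
  expect_equal(eq$p, 1)
  set.seed(60)
  big <- compare_groups(rnorm(200), rnorm(200, 3), "ranksum")
  expect_lt(big$p, 1e-10)
  tt <- compare_groups(rnorm(50), rnorm(50, 2), "t")
  expect_lt(tt$p, 1e-6)
})

test_that("gene context stats expose planted body-G4 and flank-GC enrichment", {
  set.seed(70)
  bg <- rand_dna(40000, probs = c(0.3, 0.2, 0.2, 0.3))
  g4 <- "GGGTTGGGTTGGGTTGGG"
  # plant one gene with three body G4s and GC-rich flanks
  body <- rand_dna(600, probs = c(0.3, 0.2, 0.2, 0.3))
  for (k in 0:2) substr(body, 1 + k * 40, k * 40 + nchar(g4)) <- g4
  fl <- rand_dna(800, probs = c(0.1, 0.4, 0.4, 0.1))
  s <- bg
  substr(s, 9201, 10000) <- fl
  substr(s, 10001, 10600) <- body
  substr(s, 10601, 11400) <- fl
  g <- as_genome_assembly(c(chr1 = s))
  genes <- data.frame(seqid = "chr1",
                      start = c(10000L, 30000L), end = c(10600L, 30600L))
  st <- gene_context_stats(g, genes, flank = 800L)
  expect_gt(st$g4_body[1], st$g4_body[2])
  expect_gt(st$gc_flank[1], st$gc_flank[2])
  expect_equal(st$gc_body[2],
               gc_oracle(substr(s, 30001, 30600)))
})
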