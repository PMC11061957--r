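mk_locus <- function(locus_id, seqid, starts, ends, strand = "+",
                     identity = 1, template_id = "t1", isoform_id = "t1.1") {
  data.frame(template_id = template_id, isoform_id = isoform_id,
             locus_id = locus_id, seqid = seqid, start = starts, end = ends,
             strand = strand, identity = identity,
             exon_rank = seq_along(starts))
}

test_that("the highest-identity locus wins, ties by position", {
  m <- rbind(mk_locus("L1", "chr2", 0L, 9L, identity = 0.91),
             mk_locus("L2", "chr1", 100L, 109L, identity = 0.99))
  expect_equal(unique(select_best_locus(m)$locus_id), "L2")
  one <- mk_locus("L1", "chr1", 0L, 9L)
  expect_equal(select_best_locus(one)$locus_id, "L1")
  tie <- rbind(mk_locus("La", "chr2", 0L, 9L, identity = 0.99),
               mk_locus("Lb", "chr1", 50L, 59L, identity = 0.99))
  expect_equal(unique(select_best_locus(tie)$locus_id), "Lb")
  expect_null(suppressWarnings(select_best_locus(NULL)))
})

test_that("CDS reconstruction concatenates exons and honours strand", {
  g <- as_genome_assembly(c(chr1 = "ATGGGTTTTAAATAA"))
  one <- data.frame(seqid = "chr1", start = 0L, end = 9L, strand = "+")
  expect_equal(reconstruct_cds(g, one), "ATGGGTTTT")
  spliced <- data.frame(seqid = "chr1", start = c(0L, 9L), end = c(3L, 15L),
                        strand = "+")
  expect_equal(reconstruct_cds(g, spliced), "ATGAAATAA")
  # minus strand equals reverse complement of the + reconstruction on the
  # mirrored genome
  set.seed(55)
  s <- rand_dna(60)
  gm <- as_genome_assembly(c(chr1 = s, chr1m = reverse_complement(s)))
  ex <- data.frame(seqid = "chr1", start = c(5L, 30L), end = c(14L, 42L),
                   strand = "-")
  mirrored <- data.frame(seqid = "chr1m", start = 60L - c(42L, 14L),
                         end = 60L - c(30L, 5L), strand = "+")
  expect_equal(reconstruct_cds(gm, ex),
               reconstruct_cds(gm, mirrored))
  oob <- data.frame(seqid = "chr1", start = 50L, end = 70L, strand = "+")
  expect_error(reconstruct_cds(gm, oob), "bounds")
})

test_that("CDS diagnosis separates intact, nonsense and ORF-shift", {
  expect_equal(classify_cds("ATGAAATAA")$status, "intact")
  d <- classify_cds("ATGTAAAAATAA")
  expect_equal(d$status, "nonsense")
  expect_equal(d$detail, 2L)
  d2 <- classify_cds("ATGAAAAAAT")  # 10 nt
  expect_equal(d2$status, "orf_shift")
  expect_equal(d2$detail, 1L)
  expect_equal(classify_cds("ATGTGAAAATAA", sec_codon_indices = 2L)$status,
               "intact")
  expect_equal(classify_cds("ATGTGAAAATAA")$status, "nonsense")
  # stop-loss: in frame, clean, but not stop-terminated
  expect_equal(classify_cds("ATGAAAAAA")$status, "orf_shift")
})

test_that("read support requires min coverage at every exon base", {
  locus <- data.frame(seqid = "chr1", start = c(2L, 10L), end = c(6L, 14L))
  cov <- structure(list(chr1 = rep(12L, 20)), class = "coverage_track")
  expect_equal(verify_support(locus, cov), "read_supported")
  cov$chr1[12] <- 9L  # one base inside the second exon
  expect_equal(verify_support(locus, cov), "unsupported")
  expect_equal(verify_support(locus, cov, min_cov = 1L), "read_supported")
  expect_equal(verify_support(locus, structure(list(), class = "coverage_track")),
               "unsupported")
})

test_that("the gene-call decision table matches the annotation rules", {
  expect_equal(call_gene("intact", "not_applicable", "gene"), "intact_gene")
  expect_equal(call_gene("orf_shift", "read_supported", "gene"), "pseudogene")
  expect_equal(call_gene("nonsense", "unsupported", "gene"),
               "partially_supported_gene")
  expect_equal(call_gene("intact", "read_supported", "pseudogene"),
               "gene_from_pseudogene")
  expect_equal(call_gene("intact", "unsupported", "pseudogene"), "pseudogene")
  expect_equal(call_gene("nonsense", "read_supported", "pseudogene"),
               "pseudogene")
  expect_error(call_gene("intact", "read_supported", "gene"))
  expect_error(call_gene("nonsense", "not_applicable", "gene"))
})

test_that("frameshift codon arithmetic matches codon-index counting", {
  expect_equal(frameshift_impact(1818, 1552, 1556), 89L)
  expect_equal(frameshift_impact(1818, 1816, 1816), 1L)
  set.seed(66)
  for (i in 1:50) {
    n <- 3L * sample(4:20, 1)
    ds <- sample.int(n - 1L, 1)
    de <- min(n, ds + sample(0:4, 1))
    first_codon <- ceiling(ds / 3)
    affected <- length(first_codon:(n / 3))
    expect_equal(frameshift_impact(n, ds, de), affected)
  }
  expect_error(frameshift_impact(10, 1, 1))      # length not multiple of 3
  expect_error(frameshift_impact(9, 5, 12))      # deletion past the end
})

test_that("diagnosis is invariant to splitting an exon in two", {
  set.seed(77)
  g <- as_genome_assembly(c(chr1 = rand_dna(200)))
  whole <- data.frame(seqid = "chr1", start = 20L, end = 80L, strand = "+")
  for (cut in c(25L, 40L, 79L)) {
    split2 <- data.frame(seqid = "chr1", start = c(20L, cut),
                         end = c(cut, 80L), strand = "+")
    expect_equal(classify_cds(reconstruct_cds(g, split2)),
                 classify_cds(reconstruct_cds(g, whole)))
  }
})

test_that("coverage support is monotone in depth and threshold", {
  locus <- data.frame(seqid = "chr1", start = 0L, end = 30L)
  set.seed(88)
  base <- sample(5:20, 30, replace = TRUE)
  for (i in 1:10) {
    cov1 <- structure(list(chr1 = base), class = "coverage_track")
    raised <- base + sample(0:5, 30, replace = TRUE)
    cov2 <- structure(list(chr1 = raised), class = "coverage_track")
    # raising coverage can only move unsupported -> supported
    s1 <- verify_support(locus, cov1, 10L)
    s2 <- verify_support(locus, cov2, 10L)
    expect_false(s1 == "read_supported" && s2 == "unsupported")
    # lowering the threshold never loses support
    s_lo <- verify_support(locus, cov1, 5L)
    expect_false(s1 == "read_supported" && s_lo == "unsupported")
  }
})
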