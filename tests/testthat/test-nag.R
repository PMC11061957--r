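test_that("redundancy removal applies the strict > threshold rule", {
  s <- rand_dna(200)
  two_same <- c(a = s, b = s)
  dd <- deduplicate_nags(two_same)
  expect_equal(length(dd$representatives), 1L)
  expect_equal(sort(dd$clusters[[1]]), c("a", "b"))

  # 3 substitutions in 200: identity exactly 0.985, NOT above the threshold
  s3 <- s
  for (p in c(40L, 100L, 160L))
    substr(s3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
  expect_equal(as.numeric(pairwise_identity(s, s3)), 0.985)
  expect_equal(length(deduplicate_nags(c(a = s, b = s3))$representatives), 2L)

  # 1 substitution in 200: identity 0.995 > threshold, merged
  s1 <- s
  substr(s1, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(s, 100, 100))[1]
  expect_equal(length(deduplicate_nags(c(a = s, b = s1))$representatives), 1L)
})

test_that("greedy clustering equals an independent greedy re-run", {
  # naive O(n^2) reimplementation with the same ordering rule
  greedy_oracle <- function(seqs, thr) {
    ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
    reps <- character(0); memb <- character(0)
    for (id in ids) {
      hit <- NA_character_
      for (r in reps)
        if (as.numeric(pairwise_identity(seqs[[id]], seqs[[r]])) > thr) {
          hit <- r; break
        }
      if (is.na(hit)) { reps <- c(reps, id); memb[[id]] <- id }
      else memb[[id]] <- hit
    }
    list(reps = reps, memb = memb)
  }
  set.seed(99)
  base <- replicate(3, rand_dna(120))
  seqs <- character(0)
  k <- 0
  for (b in base) for (j in 1:2) {
    k <- k + 1
    v <- b
    nmut <- sample(0:2, 1)
    for (p in sample(120, nmut))
      substr(v, p, p) <- sample(c("A", "C", "G", "T"), 1)
    seqs[[sprintf("q%02d", k)]] <- v
  }
  dd <- deduplicate_nags(seqs, 0.985)
  or <- greedy_oracle(seqs, 0.985)
  expect_equal(dd$representatives, or$reps)
  expect_equal(dd$membership[names(or$memb)], or$memb)
  # members exceed threshold identity to their representative
  for (id in names(dd$membership)) {
    r <- dd$membership[[id]]
    if (id != r)
      expect_gt(as.numeric(pairwise_identity(seqs[[id]], seqs[[r]])), 0.985)
  }
  # representatives are pairwise at or below threshold
  rp <- dd$representatives
  if (length(rp) > 1)
    for (i in 1:(length(rp) - 1)) for (j in (i + 1):length(rp))
      expect_lte(as.numeric(pairwise_identity(seqs[[rp[i]]], seqs[[rp[j]]])),
                 0.985)
})

test_that("NAG triage follows hit taxonomy and ignores reference tags", {
  refs <- c("GRCg6a", "GRCg7b", "GRCg7w")
  gg <- data.frame(taxon = "Gallus gallus", tag = "breed-X")
  expect_equal(classify_nag(gg, refs), "gNAG")
  turkey <- data.frame(taxon = "Meleagris gallopavo", tag = NA)
  expect_equal(classify_nag(turkey, refs), "oNAG")
  expect_equal(classify_nag(data.frame(taxon = character(0), tag = character(0)),
                            refs), "novel")
  # chicken hits carried only by reference assemblies do not count
  ggref <- data.frame(taxon = "Gallus gallus", tag = "GRCg6a")
  expect_equal(classify_nag(ggref, refs), "novel")
  mixed <- data.frame(taxon = c("Gallus gallus", "Meleagris gallopavo"),
                      tag = c("GRCg6a", NA))
  expect_equal(classify_nag(mixed, refs), "oNAG")
  # invariant to hit order
  sh <- mixed[2:1, ]
  expect_equal(classify_nag(sh, refs), classify_nag(mixed, refs))
})

test_that("family size is the hit count", {
  h5 <- data.frame(taxon = rep("Gallus gallus", 5), tag = NA)
  expect_equal(family_size(h5), 5L)
  expect_equal(family_size(h5[0, ]), 0L)
  set.seed(101)
  tab <- data.frame(query = sample(sprintf("q%d", 1:6), 40, replace = TRUE),
                    taxon = "x", tag = NA)
  for (q in unique(tab$query))
    expect_equal(family_size(tab[tab$query == q, ]), sum(tab$query == q))
})

test_that("presence matrix encodes 1/0/-1 and rejects duplicates", {
  calls <- data.frame(nag_id = c("n1", "n1", "n1", "n2", "n2", "n2"),
                      genome_id = rep(c("A", "B", "C"), 2),
                      status = c("intact", "absent", "pseudogene",
                                 "intact", "intact", "intact"))
  m <- build_presence_matrix(calls)
  expect_equal(unname(m["n1", ]), c(1L, 0L, -1L))
  expect_equal(unname(m["n2", ]), c(1L, 1L, 1L))
  dup <- rbind(calls, calls[1, ])
  expect_error(build_presence_matrix(dup), "duplicate")
  bad <- calls; bad$status[1] <- "weird"
  expect_error(build_presence_matrix(bad), "unknown status")
})

test_that("biclustering recovers planted blocks and ignores row order", {
  m <- rbind(matrix(rep(c(1L, 1L, 0L, 0L), each = 6), 6, 4),
             matrix(rep(c(-1L, -1L, 1L, 1L), each = 6), 6, 4))
  rownames(m) <- sprintf("r%02d", 1:12)
  colnames(m) <- sprintf("c%d", 1:4)
  bc <- bicluster(m)
  top_rows <- stats::cutree(bc$row_hclust, 2)
  expect_equal(length(unique(top_rows[1:6])), 1L)
  expect_equal(length(unique(top_rows[7:12])), 1L)
  expect_true(top_rows[1] != top_rows[7])
  top_cols <- stats::cutree(bc$col_hclust, 2)
  expect_true(top_cols["c1"] == top_cols["c2"] &&
                top_cols["c3"] == top_cols["c4"] &&
                top_cols["c1"] != top_cols["c3"])

  perm <- sample(nrow(m))
  bc2 <- bicluster(m[perm, ])
  reord <- stats::cutree(bc2$row_hclust, 2)[rownames(m)]
  # same partition up to cluster relabelling
  expect_equal(unname(reord == reord[1]), unname(top_rows == top_rows[1]))

  expect_error(bicluster(matrix(1L, 3, 3)), "no variation")
})

test_that("agglomeration equals a step-by-step single-linkage trace", {
  # independent naive agglomerative trace (single linkage, Euclidean)
  naive_single <- function(x) {
    n <- nrow(x)
    d <- as.matrix(stats::dist(x))
    active <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(NA, NA); bd <- Inf
      for (i in 1:(length(active) - 1)) for (j in (i + 1):length(active)) {
        dd <- min(d[active[[i]], active[[j]]])
        if (dd < bd) { bd <- dd; best <- c(i, j) }
      }
      heights <- c(heights, bd)
      active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
      active[[best[2]]] <- NULL
    }
    heights
  }
  set.seed(202)
  x <- matrix(sample(c(-1L, 0L, 1L), 24, replace = TRUE), 6, 4)
  x[1, ] <- c(1L, 1L, 0L, -1L)  # ensure variation
  dimnames(x) <- list(sprintf("r%d", 1:6), sprintf("c%d", 1:4))
  bc <- bicluster(x, method = "single")
  expect_equal(bc$row_hclust$height, naive_single(x), tolerance = 1e-12)
  expect_equal(bc$col_hclust$height, naive_single(t(x)), tolerance = 1e-12)
})
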