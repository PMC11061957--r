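#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic cohort: a small
#' multi-chromosome karyotype with class-dependent base G/C (macro 0.40,
#' middle 0.42, micro 0.53) and a linear subtelomeric G/C ramp, planted
#' multi-exon template genes, orthologs carrying nonsense/frameshift
#' mutations with or without short-read support, G/C-biased NAG placement
#' with G4-enriched bodies and G/C+G4-enriched flanks, taxon-labelled hit
#' tables mixing chicken-breed, other-species and no-hit NAGs, and a
#' tissue-specific expression model. All randomness flows from `seed`.
#'
#' @param seed Integer seed (mandatory).
#' @param genome_ids Names of the cohort genomes (default 4 breeds).
#' @param chromosomes data.frame `name`,`length`: per-genome karyotype
#'   (default chr1 1.2 Mbp macro, chr6 0.7 Mbp middle, chr20 0.6 Mbp micro).
#' @param gc_base Named base G/C per size class.
#' @param ramp_amplitude,ramp_fraction Subtelomeric G/C elevation: linear
#'   ramp of this amplitude over the outer fraction of each chromosome.
#' @param n_templates Number of template genes shared by the cohort.
#' @param pseudo_template_frac Fraction of templates that are pseudogene
#'   templates (exercising the gene-from-pseudogene path).
#' @param sec_frac Fraction of gene templates that are selenoproteins (one
#'   internal UGA recoded as Sec).
#' @param exon_range,codon_range Exons per template and codons per CDS.
#' @param p_absent Probability a template has no mapping in a genome.
#' @param p_mutation Probability a mapped gene-template ortholog carries a
#'   loss-of-function mutation (split evenly nonsense/frameshift).
#' @param p_supported Probability a planted mutation is fully covered
#'   >= `base_depth` (otherwise one base is dropped to `hole_depth`).
#' @param decoy_frac Fraction of templates that also get a lower-identity
#'   decoy locus (exercising best-locus selection).
#' @param base_depth,hole_depth Coverage depths (default 30 and 5).
#' @param n_nags Number of distinct NAGs in the cohort.
#' @param nag_class_probs Mixture over gNAG/oNAG/novel (default
#'   0.56/0.34/0.10).
#' @param presence_probs Probabilities of 1/0/-1 per (NAG, genome) entry.
#' @param group_specific_frac Fraction of NAGs present only in the first
#'   half of the genomes (the indigenous-vs-reference style column split).
#' @param gc_enrichment NAG placement weight: slot probability proportional
#'   to `exp(gc_enrichment * gc)`; 0 disables the G/C bias.
#' @param n_g4_body,n_g4_flank G4 motifs inserted per NAG body / flank pair.
#' @param flank_width,flank_gc_boost Enriched-flank width (bp) and G/C
#'   elevation around each planted NAG.
#' @param n_overlap_tx,n_lnc_tx,n_unclassified_tx Extra transcripts per
#'   genome planted to overlap existing genes / be ORF-free lncRNAs /
#'   be short unclassifiable.
#' @param n_tissues,p_expressed Expression model: tissue count and the
#'   probability a NAG is expressed in at least one tissue.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_ids = c("breedA", "breedB", "breedC", "breedD"),
                       chromosomes = data.frame(
                         name = c("chr1", "chr6", "chr20"),
                         length = c(1200000L, 700000L, 600000L)),
                       gc_base = c(macro = 0.40, middle = 0.42,
                                   micro = 0.53, unplaced = 0.45),
                       ramp_amplitude = 0.10, ramp_fraction = 0.10,
                       n_templates = 300L, pseudo_template_frac = 0.05,
                       sec_frac = 0.02,
                       exon_range = c(1L, 4L), codon_range = c(100L, 250L),
                       p_absent = 0.05, p_mutation = 0.2, p_supported = 0.5,
                       decoy_frac = 0.05,
                       base_depth = 30L, hole_depth = 5L,
                       n_nags = 100L,
                       nag_class_probs = c(gNAG = 0.56, oNAG = 0.34, novel = 0.10),
                       presence_probs = c(p1 = 0.70, p0 = 0.15, pm1 = 0.15),
                       group_specific_frac = 0.3,
                       gc_enrichment = 12,
                       n_g4_body = 3L, n_g4_flank = 4L,
                       flank_width = 1500L, flank_gc_boost = 0.08,
                       n_overlap_tx = 10L, n_lnc_tx = 5L, n_unclassified_tx = 5L,
                       n_tissues = 8L, p_expressed = 0.95) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1L)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# genome slot layout used to plant loci without overlap
.SLOT_W <- 5500L
.GENE_AT <- 1600L  # gene offset within its slot (leaves room for flanks)

rand_bases <- function(n, p_gc) {
  if (length(p_gc) == 1L) p_gc <- rep(p_gc, n)
  gc <- stats::runif(n) < p_gc
  pick <- stats::runif(n) < 0.5
  # codepoints G=71 C=67 A=65 T=84; intToUtf8 builds the string in C
  intToUtf8(ifelse(gc, ifelse(pick, 71L, 67L), ifelse(pick, 65L, 84L)))
}

# sequence over C/G/T only: guaranteed free of ATG and stop codons
rand_noncoding <- function(n) {
  paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
}

.NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

random_cds <- function(n_codons) {
  stopifnot(n_codons >= 4L)
  body <- sample(.NONSTOP_CODONS, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Simulate one genome assembly
#'
#' Per-base independent draws with position-dependent G/C probability:
#' class base level plus a linear subtelomeric ramp rising to
#' `ramp_amplitude` at the chromosome ends over the outer `ramp_fraction`
#' of the length. Byte-identical for a given seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a `genome_assembly`) and `truth`
#'   (per-chromosome class and G/C parameters).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  g <- simulate_genome_impl(config)
  list(genome = as_genome_assembly(g),
       truth = data.frame(seqid = config$chromosomes$name,
                          class = chromosome_class(config$chromosomes$name),
                          base_gc = config$gc_base[
                            as.character(chromosome_class(config$chromosomes$name))],
                          ramp_amplitude = config$ramp_amplitude,
                          ramp_fraction = config$ramp_fraction))
}

simulate_genome_impl <- function(config) {
  chroms <- config$chromosomes
  cls <- as.character(chromosome_class(chroms$name))
  seqs <- vapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length[i]
    base <- config$gc_base[[cls[i]]]
    pos <- seq_len(L)
    d <- pmin(pos - 1L, L - pos)
    ramp <- pmax(0, 1 - d / (L * config$ramp_fraction))
    rand_bases(L, pmin(0.98, base + config$ramp_amplitude * ramp))
  }, character(1))
  names(seqs) <- chroms$name
  seqs
}

#' Derive a mutated ortholog of a template CDS
#'
#' Applies the planted mutation to an intact template CDS: `nonsense`
#' replaces one internal codon (never the start, stop or an annotated Sec
#' codon) with TAA; `frameshift` deletes 1-5 bp (never a multiple of 3) at
#' a random internal CDS position. Uses the current RNG state.
#'
#' @param cds Intact template CDS.
#' @param mutation `"none"`, `"nonsense"` or `"frameshift"`.
#' @param sec_codons Codon ordinals to protect from the nonsense mutation.
#' @return List with `cds` (mutated sequence), `mutation` and `detail`
#'   (codon ordinal or deleted width).
#' @export
derive_ortholog <- function(cds, mutation = c("none", "nonsense", "frameshift"),
                            sec_codons = integer(0)) {
  mutation <- match.arg(mutation)
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L, n >= 12L)
  if (mutation == "none") return(list(cds = cds, mutation = "none", detail = NA_integer_))
  if (mutation == "nonsense") {
    ncod <- n %/% 3L
    cand <- setdiff(2:(ncod - 1L), sec_codons)
    k <- cand[sample.int(length(cand), 1L)]
    out <- paste0(substring(cds, 1L, 3L * (k - 1L)), "TAA",
                  substring(cds, 3L * k + 1L, n))
    return(list(cds = out, mutation = "nonsense", detail = k))
  }
  d <- sample(c(1L, 2L, 4L, 5L), 1L)
  pos <- sample.int(n - d - 6L, 1L) + 3L  # keep start codon intact
  out <- paste0(substring(cds, 1L, pos - 1L), substring(cds, pos + d, n))
  list(cds = out, mutation = "frameshift", detail = d)
}

#' G/C-biased placement of NAGs into windows
#'
#' Samples `n` window indices with probability proportional to
#' `exp(enrichment * gc)`; with `enrichment = 0` placement is uniform.
#' This is the placement kernel behind the NAG-density-follows-G/C
#' behaviour of the simulator.
#'
#' @param gc Numeric vector of window G/C contents.
#' @param n Number of placements.
#' @param enrichment Exponential tilt strength (0 = uniform).
#' @param replace Sample windows with replacement? (default TRUE)
#' @return Integer vector of window indices.
#' @export
place_nags_by_gc <- function(gc, n, enrichment, replace = TRUE) {
  stopifnot(length(gc) >= 1L, n >= 0L)
  w <- exp(enrichment * (gc - mean(gc, na.rm = TRUE)))
  w[is.na(w)] <- 0
  sample.int(length(gc), n, replace = replace, prob = w)
}

# split a CDS into n_exons pieces and plant at slot; returns exon table rows
split_exons <- function(cds_len, n_exons) {
  if (n_exons == 1L) return(cds_len)
  cuts <- sort(sample.int(cds_len - 1L, n_exons - 1L))
  diff(c(0L, cuts, cds_len))
}

#' Simulate a full annotation cohort with planted truth
#'
#' Generates the complete input set of the discovery pipeline for a small
#' cohort of genomes: assemblies, template models, mapped loci (with
#' decoys), coverage tracks, NAG loci and transcripts, extra transcripts
#' exercising each verdict, taxon-labelled hit tables and an expression
#' matrix — together with the true status/class of every planted object.
#'
#' @param config A [sim_config()].
#' @return List with elements `config`, `genomes`, `templates`,
#'   `template_cds`, `mappings`, `coverage`, `annotations`, `transcripts`,
#'   `nag_loci`, `hit_table`, `expression`, `truth` (list: `gene_status`,
#'   `nag_class`, `nag_family_size`, `presence`, `transcript_verdict`,
#'   `expressed`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_t <- config$n_templates
  n_nag <- config$n_nags
  n_g <- length(config$genome_ids)

  ## --- templates (shared across the cohort) ---
  kind <- ifelse(stats::runif(n_t) < config$pseudo_template_frac,
                 "pseudogene", "gene")
  sec_list <- vector("list", n_t)
  tmpl_cds <- character(n_t)
  tmpl_nexon <- sample(config$exon_range[1]:config$exon_range[2], n_t, replace = TRUE)
  for (i in seq_len(n_t)) {
    ncod <- sample(config$codon_range[1]:config$codon_range[2], 1L)
    cds <- random_cds(ncod)
    sec <- integer(0)
    if (kind[i] == "gene" && stats::runif(1) < config$sec_frac) {
      k <- sample(3:(ncod - 2L), 1L)
      cds <- paste0(substring(cds, 1L, 3L * (k - 1L)), "TGA",
                    substring(cds, 3L * k + 1L, nchar(cds)))
      sec <- k
    }
    tmpl_cds[i] <- cds
    sec_list[[i]] <- sec
  }
  template_ids <- sprintf("tmpl%03d", seq_len(n_t))
  templates <- data.frame(
    template_id = template_ids, source_kind = kind,
    sec_codons = vapply(sec_list, function(s) paste(s, collapse = ","), character(1)))

  ## --- NAG genes (shared sequences; discovered per genome) ---
  nag_ids <- sprintf("nag%03d", seq_len(n_nag))
  nag_orf <- vapply(seq_len(n_nag), function(i)
    random_cds(sample(114:200, 1L)), character(1))  # ORFs 342-600 nt
  nag_utr5 <- vapply(seq_len(n_nag), function(i) rand_noncoding(150L), character(1))
  nag_utr3 <- vapply(seq_len(n_nag), function(i) rand_noncoding(150L), character(1))
  g4 <- "GGGTTGGGTTGGGTTGGG"
  if (config$n_g4_body > 0L) {
    # seed G4 motifs into the UTRs of every NAG body
    for (i in seq_len(n_nag)) {
      u <- nag_utr5[i]
      for (k in seq_len(config$n_g4_body)) {
        at <- 1L + (k - 1L) * (nchar(g4) + 10L)
        substring(u, at, at + nchar(g4) - 1L) <- g4
      }
      nag_utr5[i] <- u
    }
  }

  ## NAG truth: class, hits, presence plan
  cls_draw <- sample(names(config$nag_class_probs), n_nag, replace = TRUE,
                     prob = config$nag_class_probs)
  other_taxa <- c("Meleagris gallopavo", "Coturnix japonica",
                  "Numida meleagris", "Anas platyrhynchos")
  breeds <- c("Silkie", "Leghorn", "Cochin", "Tibetan")
  pres <- matrix(sample(c(1L, 0L, -1L), n_nag * n_g, replace = TRUE,
                        prob = config$presence_probs),
                 nrow = n_nag, dimnames = list(nag_ids, config$genome_ids))
  n_spec <- round(config$group_specific_frac * n_nag)
  if (n_spec > 0L && n_g >= 4L) {
    grpA <- seq_len(n_g %/% 2L)
    pres[seq_len(n_spec), grpA] <- 1L
    pres[seq_len(n_spec), -grpA] <- 0L
  }
  # every NAG must be discoverable: present (1) in at least one genome
  for (i in seq_len(n_nag))
    if (!any(pres[i, ] == 1L)) pres[i, sample.int(n_g, 1L)] <- 1L

  ## --- per-genome construction ---
  genomes <- list(); mappings <- list(); coverage <- list()
  annotations <- list(); transcripts <- list(); nag_loci <- list()
  gene_status <- matrix(NA_character_, nrow = n_t, ncol = n_g,
                        dimnames = list(template_ids, config$genome_ids))
  tx_truth <- list()

  for (g in seq_len(n_g)) {
    gid <- config$genome_ids[g]
    seqs <- simulate_genome_impl(config)
    chrom_len <- vapply(seqs, nchar, integer(1))

    # slot pool across chromosomes (skip the outermost slot at each end)
    slots <- do.call(rbind, lapply(names(seqs), function(ch) {
      ns <- chrom_len[[ch]] %/% .SLOT_W
      data.frame(seqid = ch, slot_start = .SLOT_W * (seq_len(ns - 2L)))
    }))
    stopifnot(nrow(slots) >= n_t + n_nag)
    slot_gc <- vapply(seq_len(nrow(slots)), function(s)
      gc_content(substring(seqs[[slots$seqid[s]]], slots$slot_start[s] + 1L,
                           slots$slot_start[s] + .SLOT_W)), numeric(1))

    # NAG slots first (G/C-biased), then template slots uniformly from the rest
    nag_slot <- place_nags_by_gc(slot_gc, n_nag, config$gc_enrichment,
                                 replace = FALSE)
    rest <- setdiff(seq_len(nrow(slots)), nag_slot)
    n_decoy <- round(config$decoy_frac * n_t)
    tmpl_slot <- sample(rest, n_t)
    decoy_pool <- setdiff(rest, tmpl_slot)
    decoy_tmpl <- sample.int(n_t, n_decoy)
    decoy_slot <- sample(decoy_pool, n_decoy)

    map_rows <- list(); ann_rows <- list(); depth_edit <- list()

    plant_cds <- function(slot_i, cds, n_exons, strand) {
      ch <- slots$seqid[slot_i]
      at <- slots$slot_start[slot_i] + .GENE_AT
      lens <- split_exons(nchar(cds), n_exons)
      pieces <- substring(cds, cumsum(c(1L, lens[-length(lens)])),
                          cumsum(lens))
      if (strand == "-") {
        pieces <- rev(vapply(pieces, reverse_complement, character(1)))
      }
      starts <- integer(length(lens)); pos <- at
      s <- seqs[[ch]]
      plens <- nchar(pieces)
      for (e in seq_along(pieces)) {
        starts[e] <- pos
        substring(s, pos + 1L, pos + plens[e]) <- pieces[e]
        pos <- pos + plens[e] + if (e < length(pieces)) sample(100:300, 1L) else 0L
      }
      seqs[[ch]] <<- s
      rank <- if (strand == "-") rev(seq_along(pieces)) else seq_along(pieces)
      data.frame(seqid = ch, start = starts, end = starts + plens,
                 strand = strand, exon_rank = rank)
    }

    ## templates
    for (i in seq_len(n_t)) {
      tid <- template_ids[i]
      if (stats::runif(1) < config$p_absent) {
        gene_status[i, g] <- "absent"
        next
      }
      if (kind[i] == "gene") {
        mut <- if (stats::runif(1) < config$p_mutation)
          sample(c("nonsense", "frameshift"), 1L) else "none"
        supported <- stats::runif(1) < config$p_supported
        truth <- if (mut == "none") "intact_gene"
                 else if (supported) "pseudogene" else "partially_supported_gene"
      } else {
        # pseudogene template: half resurrect to an intact supported ORF
        if (stats::runif(1) < 0.5) {
          mut <- "none"; supported <- TRUE; truth <- "gene_from_pseudogene"
        } else {
          mut <- sample(c("nonsense", "frameshift"), 1L)
          supported <- TRUE; truth <- "pseudogene"
        }
      }
      ort <- derive_ortholog(tmpl_cds[i], mut, sec_list[[i]])
      strand <- if (stats::runif(1) < 0.3) "-" else "+"
      ex <- plant_cds(tmpl_slot[i], ort$cds, tmpl_nexon[i], strand)
      ex$template_id <- tid; ex$isoform_id <- paste0(tid, ".1")
      ex$locus_id <- paste0(tid, ".1.L1")
      ex$identity <- round(stats::runif(1, 0.97, 1.0), 4)
      map_rows[[length(map_rows) + 1L]] <- ex
      ann_rows[[length(ann_rows) + 1L]] <-
        data.frame(seqid = ex$seqid[1L], type = if (truth == "pseudogene")
                     "pseudogene" else "gene",
                   start = min(ex$start), end = max(ex$end),
                   strand = strand, id = tid, parent = NA_character_,
                   status = truth, class = NA_character_)
      if (mut != "none" && !supported) {
        hole <- ex$start[1L] + sample.int(ex$end[1L] - ex$start[1L], 1L) - 1L
        depth_edit[[length(depth_edit) + 1L]] <- c(match(ex$seqid[1L], names(seqs)), hole)
      }
      if (i %in% decoy_tmpl) {
        dec <- derive_ortholog(tmpl_cds[i], "nonsense", sec_list[[i]])
        dx <- plant_cds(decoy_slot[match(i, decoy_tmpl)], dec$cds, 1L, "+")
        dx$template_id <- tid; dx$isoform_id <- paste0(tid, ".1")
        dx$locus_id <- paste0(tid, ".1.L2")
        dx$identity <- round(stats::runif(1, 0.80, 0.93), 4)
        map_rows[[length(map_rows) + 1L]] <- dx
      }
      gene_status[i, g] <- truth
    }

    ## NAGs
    nag_rows <- list(); tx_rows <- list()
    for (i in seq_len(n_nag)) {
      entry <- pres[i, g]
      if (entry == 0L) next
      orf <- nag_orf[i]
      if (entry == -1L) orf <- derive_ortholog(orf, "nonsense")$cds
      body <- paste0(nag_utr5[i], orf, nag_utr3[i])
      slot_i <- nag_slot[i]
      ch <- slots$seqid[slot_i]
      at <- slots$slot_start[slot_i] + .GENE_AT
      s <- seqs[[ch]]
      substring(s, at + 1L, at + nchar(body)) <- body
      # enriched flanks: elevated G/C plus planted G4 motifs
      fw <- config$flank_width
      lf <- rand_bases(fw, config$gc_base[["macro"]] + config$flank_gc_boost)
      rf <- rand_bases(fw, config$gc_base[["macro"]] + config$flank_gc_boost)
      for (k in seq_len(config$n_g4_flank)) {
        atg4 <- 1L + (k - 1L) * (nchar(g4) + 25L)
        substring(lf, atg4, atg4 + nchar(g4) - 1L) <- g4
        substring(rf, atg4, atg4 + nchar(g4) - 1L) <- g4
      }
      substring(s, at - fw + 1L, at) <- lf
      substring(s, at + nchar(body) + 1L, at + nchar(body) + fw) <- rf
      seqs[[ch]] <- s
      orf_start <- at + nchar(nag_utr5[i])
      nag_rows[[length(nag_rows) + 1L]] <-
        data.frame(nag_id = nag_ids[i], seqid = ch,
                   start = at, end = at + nchar(body),
                   orf_start = orf_start, orf_end = orf_start + nchar(orf),
                   strand = "+", planted_entry = entry)
      if (entry == 1L) {
        txid <- paste0(nag_ids[i], "@", gid)
        tx_rows[[length(tx_rows) + 1L]] <-
          data.frame(transcript_id = txid, seqid = ch, start = at,
                     end = at + nchar(body), strand = "+", exon_rank = 1L)
        tx_truth[[txid]] <- "coding_NAG"
      }
    }

    ## extra transcripts exercising the other verdicts
    extra_pool <- setdiff(decoy_pool, decoy_slot)
    extra_i <- 0L
    add_tx <- function(id, ch, start, end, verdict) {
      tx_rows[[length(tx_rows) + 1L]] <<-
        data.frame(transcript_id = id, seqid = ch, start = start, end = end,
                   strand = "+", exon_rank = 1L)
      tx_truth[[id]] <<- verdict
    }
    for (k in seq_len(config$n_overlap_tx)) {
      i <- sample.int(n_t, 1L)
      if (gene_status[i, g] == "absent") next
      sl <- tmpl_slot[i]
      st <- slots$slot_start[sl] + .GENE_AT - 50L
      add_tx(sprintf("ovl%02d@%s", k, gid), slots$seqid[sl], st, st + 400L,
             "overlaps_existing")
    }
    for (k in seq_len(config$n_lnc_tx)) {
      extra_i <- extra_i + 1L; sl <- extra_pool[extra_i]
      ch <- slots$seqid[sl]; at <- slots$slot_start[sl] + .GENE_AT
      lnc <- rand_noncoding(1200L)
      s <- seqs[[ch]]; substring(s, at + 1L, at + 1200L) <- lnc; seqs[[ch]] <- s
      add_tx(sprintf("lnc%02d@%s", k, gid), ch, at, at + 1200L, "lncRNA")
    }
    for (k in seq_len(config$n_unclassified_tx)) {
      extra_i <- extra_i + 1L; sl <- extra_pool[extra_i]
      ch <- slots$seqid[sl]; at <- slots$slot_start[sl] + .GENE_AT
      sh <- rand_noncoding(600L)
      s <- seqs[[ch]]; substring(s, at + 1L, at + 600L) <- sh; seqs[[ch]] <- s
      add_tx(sprintf("sht%02d@%s", k, gid), ch, at, at + 600L, "unclassified")
    }

    ## coverage: uniform base depth with the planted holes
    cov <- lapply(chrom_len, function(L) rep(config$base_depth, L))
    for (h in depth_edit) cov[[h[1L]]][h[2L] + 1L] <- config$hole_depth
    coverage[[gid]] <- structure(cov, class = "coverage_track")
    genomes[[gid]] <- as_genome_assembly(seqs)
    mappings[[gid]] <- do.call(rbind, map_rows)
    annotations[[gid]] <- do.call(rbind, ann_rows)
    transcripts[[gid]] <- do.call(rbind, tx_rows)
    nag_loci[[gid]] <- if (length(nag_rows)) do.call(rbind, nag_rows) else
      data.frame(nag_id = character(0), seqid = character(0), start = integer(0),
                 end = integer(0), orf_start = integer(0), orf_end = integer(0),
                 strand = character(0), planted_entry = integer(0))
  }

  ## --- hit table over NAG candidate transcript ids ---
  fam <- integer(n_nag)
  hit_rows <- list()
  for (i in seq_len(n_nag)) {
    cl <- cls_draw[i]
    nh <- if (cl == "novel") 0L else sample(1:8, 1L)
    fam[i] <- nh
    if (nh == 0L) next
    taxa <- if (cl == "gNAG")
      c("Gallus gallus", sample(c("Gallus gallus", other_taxa), nh - 1L, replace = TRUE))
    else sample(other_taxa, nh, replace = TRUE)
    tags <- ifelse(taxa == "Gallus gallus", sample(breeds, nh, replace = TRUE),
                   NA_character_)
    for (g in seq_len(n_g)) {
      if (pres[i, g] != 1L) next
      txid <- paste0(nag_ids[i], "@", config$genome_ids[g])
      hit_rows[[length(hit_rows) + 1L]] <-
        data.frame(query = txid, taxon = taxa, tag = tags,
                   identity = round(stats::runif(nh, 0.85, 0.999), 4))
    }
  }
  hit_table <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(query = character(0), taxon = character(0),
               tag = character(0), identity = numeric(0))

  ## --- expression matrix over NAGs ---
  expr <- matrix(0, nrow = n_nag, ncol = config$n_tissues,
                 dimnames = list(nag_ids, sprintf("tissue%02d", seq_len(config$n_tissues))))
  expressed <- stats::runif(n_nag) < config$p_expressed
  for (i in which(expressed)) {
    k <- sample(1:3, 1L)
    expr[i, sample.int(config$n_tissues, k)] <- pmax(0.001, round(stats::rlnorm(k, 2, 1), 3))
  }

  list(config = config, genomes = genomes, templates = templates,
       template_cds = stats::setNames(tmpl_cds, template_ids),
       mappings = mappings, coverage = coverage, annotations = annotations,
       transcripts = transcripts, nag_loci = nag_loci, hit_table = hit_table,
       expression = expr,
       truth = list(gene_status = gene_status,
                    nag_class = stats::setNames(cls_draw, nag_ids),
                    nag_family_size = stats::setNames(fam, nag_ids),
                    presence = pres,
                    transcript_verdict = unlist(tx_truth),
                    expressed = stats::setNames(expressed, nag_ids)))
}
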