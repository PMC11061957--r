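---
title: "Methods: homology-projected annotation and NAG discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-projected annotation and NAG discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nagpipe)
```

## The problem

High-quality long-read assemblies of non-reference chicken breeds routinely
contain protein-coding genes that reference annotations miss, and conversely
carry apparent loss-of-function alleles that are nothing more than
uncorrected long-read errors. `nagpipe` implements the annotation and
discovery procedure for this situation as a reusable, testable pipeline.
Its two entry routes are:

1. **Homology projection.** Template CDS models (protein-coding genes and
   pseudogenes from reference annotations) are projected onto a target
   assembly by an external spliced aligner; the package consumes the mapped
   exon chains, reconstructs each putative full-length CDS by concatenating
   the mapped exons, and diagnoses it.
2. **RNA-seq classification.** Genome-mapped assembled transcripts that do
   not overlap any existing annotation are classified into newly annotated
   protein-coding genes (NAGs) and lncRNAs by an ORF rule.

Around these sit consolidation (redundancy removal, taxonomic triage,
family sizes), a presence/absence/pseudogenization matrix with two-way
clustering, genomic-context statistics (G/C windows, subtelomeric
profiles, G-quadruplex frequencies), and expression/RT-qPCR summaries.

## The decision model

A reconstructed CDS is **intact** iff its length is a multiple of 3, its
last codon is a stop, and no internal stop appears — after recoding
annotated selenoprotein UGA codons as selenocysteine. A premature stop is a
*nonsense* mutation; a length not divisible by 3 is an *ORF-shift*
(frameshift) mutation. Because an apparent mutation can be an assembly
artefact, it must be validated against perfectly matching short reads: only
if **every base** of the locus is covered at depth ≥ `min_coverage`
(default 10) is the mutation considered supported, and the locus called a
**pseudogene**; otherwise the locus is a **partially supported gene**. A
pseudogene template that reconstructs an intact, fully read-supported ORF
is resurrected as a **gene from a pseudogene**; without full support it
stays a pseudogene (promotion requires positive evidence).

Two genuinely open corners were decided as follows:

* A CDS that is in frame and internally clean but lacks a terminal stop
  (stop-loss) falls outside the nonsense/ORF-shift dichotomy;
  the reading frame runs through the annotated end, so it is grouped with
  `orf_shift` (detail `NA`).
* When a template maps to several loci, the highest mapping identity wins;
  exact ties go to the lexicographically smallest chromosome, then the
  smallest start — an arbitrary but deterministic rule.
* A template with several CDS isoforms is intact if **any** isoform
  reconstructs an intact CDS (the permissive reading of per-isoform
  projection); otherwise the best-identity isoform's diagnosis is used.

Transcripts are classified by: **coding NAG** if the longest ORF
(ATG-initiated, stop-terminated, length counted including the stop codon)
is ≥ `min_orf` = 300 nt; otherwise **lncRNA** if the transcript is longer
than `lncrna_min_len` = 1000 nt; otherwise unclassified. "Lacking an ORF"
is read as "no ORF reaching 300 nt" — a literal zero-ORF reading would
discard transcripts with tiny incidental ORFs. The 300-nt rule is also what
excludes the mini-ORF class (CDS 100–300 bp) that inflates other catalogs.
The overlap filter against existing annotation is exon-level and
strand-blind by default (`overlap_level`, `overlap_stranded` expose the
alternatives).

Consolidation removes redundancy by greedy clustering at global pairwise
identity **strictly above** 0.985 (match +1, mismatch 0, unit gap cost;
identity = matched columns / alignment columns — a whole-gene measure;
local identity would over-merge). Sequences join the first existing
representative they exceed the threshold with; the representative is the
founding, longest member (ties by id). Triage is by hit taxonomy: a
*Gallus gallus* hit outside the template reference assemblies makes a
gNAG; any other-species hit an oNAG; no hits, a novel gene. Family size is
the raw database hit count (the query itself is not added).

The presence matrix codes an intact cross-mapped copy as 1, no mapping as
0, and a read-supported pseudogenized copy as −1; an unsupported apparent
mutation keeps the gene present, mirroring the partially-supported logic.
Two-way clustering is agglomerative with Euclidean distance and Ward
(`ward.D2`) linkage — unstated in the source material, chosen because it is
standard, deterministic, and recovers planted blocks; both are arguments.

## Genomic context statistics

Chromosome size classes follow the chicken karyotype: chr1–chr5 + chrZ
(macro), chr6–chr13 + chrW (middle), chr14–chr39 (micro), everything else
unplaced. Windows are half-open 1-Mbp tiles from position 0; a feature is
counted in the window containing its **start** (avoids double counting; the
alternative conventions differ negligibly at these densities). Positional
profiles split each chromosome into 100 equal portions (the last absorbs
the remainder) and average per-bin G/C and NAG density (per Mbp) across the
chromosomes of a group. Flanks are the two 1-Mbp regions abutting a gene,
clipped at chromosome ends and not masked for neighbouring genes (no
masking rule is defined upstream). Group comparisons default to the
Wilcoxon rank-sum test (Welch's t selectable); degenerate all-equal input
yields p = 1 with a flag.

G/C content is N-aware: N counts in neither numerator nor denominator, and
an all-N window is undefined (`NA`) rather than 0. G-quadruplexes are the
canonical minimal motif `G{3,}(N{1,7}G{3,}){3}`, matched non-overlapping
and leftmost-greedy on both strands; frequency is motifs per kbp. Both
per-gene counts and densities are available; density is what the
flank/body comparisons use. Thermodynamic G4 scores are out of scope.

## The simulator

`simulate_cohort()` generates everything the pipeline consumes, with truth:

* **Genomes** — per-base independent draws with G/C probability = class
  base (macro 0.40, middle 0.42, micro 0.53) plus a linear subtelomeric
  ramp (default amplitude 0.10 over the outer 10%). A dinucleotide model is
  deliberately omitted: no statistic the pipeline computes depends on
  dinucleotide structure.
* **Templates and orthologs** — intact multi-exon CDSs (1–4 exons, 100–250
  codons); per genome, 5% of templates are unmapped, 20% of mapped
  gene-template orthologs carry a planted mutation (nonsense/frameshift in
  equal parts), of which half are fully covered (depth 30) and half get a
  single-base coverage hole (depth 5) under the 10× threshold. A small
  fraction of templates are pseudogene templates and selenoproteins,
  exercising the resurrection and UGA-recoding paths. Decoy loci at lower
  identity exercise best-locus selection.
* **NAGs** — placed into genome slots sampled with probability
  ∝ exp(12 · G/C), giving the density-follows-G/C behaviour; bodies carry
  G4 motifs in their UTRs and flanks are rewritten G/C-elevated (+0.08)
  with planted G4s. The class mixture defaults to 0.56/0.34/0.10
  (gNAG/oNAG/novel), matching the observed triage proportions, and each
  presence-matrix entry is 1/0/−1 with probability 0.70/0.15/0.15; a
  configurable fraction of NAGs is private to half the genomes so the
  column dendrogram has a planted split.
* **Coverage** — emitted directly as depths (the support rule consumes
  depths; read-level simulation would add nothing).

All randomness flows from the single config seed; two runs with equal
configs are identical. Because planting is noise-free, the pipeline must
recover truth *exactly*, which is what the acceptance suite asserts: a
4-genome, ~10-Mbp cohort with 300 templates and 100 NAGs (sizes chosen so
the whole suite stays comfortable on a laptop) is recovered at 100% for
gene statuses, transcript verdicts, NAG classes, family sizes and the
presence matrix. The context-statistics checks use a single-genome, 200 +
200 gene configuration with mutations disabled — clean gene sets are the
right substrate for distributional comparisons — and reduced flank widths
(1.5 kbp), since only the direction and significance of the planted
enrichment is being tested, not its magnitude at 1 Mbp.

What passing these tests does **not** show: robustness to alignment error,
paralog confusion, fragmented assemblies, or expression noise — real-data
concerns that live upstream of this package's contracts (the spliced
aligner, the transcript assembler) or are explicitly out of scope.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based inclusive in all
  printed/GFF3 output; the conversion happens only in the I/O layer.
* `gc_content` of an empty/all-N sequence, and tau of an all-zero row, are
  `NA` with a signal, never 0.
* `density_gc_correlation` refuses fewer than 3 usable windows or
  zero-variance input rather than returning a meaningless coefficient.
* `bicluster` refuses a constant matrix ("no variation to cluster").
* The identity threshold is strict (`> 0.985`): two 200-mers differing at
  exactly 3 positions (identity 0.985) stay separate.
* Expression "presence" defaults to *any value > 0*; the threshold is
  exposed because presence counts are sensitive to it. RT-qPCR summaries
  average technical replicates within biological replicates, then report
  mean ± SD over biological replicates of 2^−ΔCt against the reference
  gene.
* `min_map_identity` (default 0) governs when a low-identity mapping
  counts as "absent"; no defensible nonzero default exists without
  benchmark data, so any mapping counts unless the user raises it.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_templates = 40, n_nags = 15,
                  chromosomes = data.frame(name = c("chr1", "chr6", "chr20"),
                                           length = c(4e5, 3e5, 2.5e5)))
sim <- simulate_cohort(cfg)
res <- run_cohort_pipeline(sim)
summarize_calls(res$gene_calls$breedA)
table(res$nag_table$class)
res$presence[1:5, ]
```

A mitochondrial curiosity reproduced by the arithmetic helpers: a 1,818-bp
ND5 CDS with a 5-bp deletion at positions 1,552–1,556 frameshifts
`frameshift_impact(1818, 1552, 1556)` = `r frameshift_impact(1818, 1552, 1556)`
codons at the carboxyl terminus.

## Limitations

The pipeline consumes spliced alignments, assembled transcripts and
coverage tracks; it does not produce them. Non-coding RNA families beyond
the length-based lncRNA rule, GO enrichment, isoform detection and
population statistics are out of scope. The simulator's independence
assumptions (per-base composition, noise-free planting) make it a contract
test, not a benchmark of real-data performance.
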