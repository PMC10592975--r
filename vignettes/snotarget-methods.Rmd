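---
title: "Consensus dysregulation and snoRNA target enrichment: methods"
author: "snotarget package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus dysregulation and snoRNA target enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snotarget)
```

## The scientific problem

Prader-Willi syndrome (PWS) is caused by loss of paternal expression of the
imprinted chr15q11-q13 locus. The smallest deletions associated with the
disorder remove little more than the tandem array of 30 SNORD116 C/D-box
snoRNAs, which makes SNORD116 a prime candidate driver — yet these snoRNAs
are "orphans": they have no known RNA targets and no complementarity to
ribosomal RNA. Two experimental design ideas make the downstream inference
tractable:

1. **Isogenic deletion models.** Engineered deletions (a small deletion of
   the SNORD116 cluster alone, `smDEL`, and a larger one from the SNRPN
   promoter region through the cluster, `lgDEL`) in two distinct genetic
   backgrounds (H9, CT2) let differential expression be read against a
   matched wild-type control, and intersecting results across backgrounds
   and deletion models strips away background-specific false positives.
2. **Computational target prediction.** A sliding-window snoRNA-target
   interaction predictor scores short duplexes; after a stringent
   consecutive-window filter, the predicted binding events can be tested
   for enrichment on the consensus dysregulated genes against
   covariate-matched control gene lists.

`snotarget` implements the full downstream statistical pipeline — consensus
calling, resampling nulls, event filtering, matched-control enrichment,
genomic feature coverage, and box-relative binding positions — together with
a seeded synthetic-data module that generates every input with planted
structure, so each stage can be validated by planted-truth recovery.

## Consensus differential expression

Per-gene statistics arrive as DESeq2-style tables (`gene_id`, `baseMean`,
`log2FoldChange`, `pvalue`, BH-adjusted `padj`), one per contrast. The
pipeline never refits the count model; three analysis designs are consumed
per deletion model: a per-background contrast (`background_condition`), a
pooled condition contrast and a background-by-condition interaction.

* `filter_low_counts()` retains genes whose mean raw count across all
  samples reaches `min_mean`. The conventional prefilter is a mean of 1 —
  one count per sample, i.e. a total of 39 counts in a 39-sample design.
* `call_shared_degs()` intersects per-background results at `padj < alpha`
  (default 0.05): shared up-regulated genes must be significant with
  positive log2 fold change in *every* background, and symmetrically for
  down. Direction-discordant significant genes are ambiguous and excluded
  from both sets, which guarantees `up` and `down` are disjoint. The upset
  bars in this kind of analysis are direction-stratified, which is why
  direction consistency is part of the definition here.
* `triple_design_consensus()` keeps genes significant in all three designs;
  applied per background and intersected across backgrounds it yields the
  per-model consensus, and `cross_model_shared()` intersects the two
  deletion models into the final shared gene network (the 42-gene analog
  under the default simulation conditions).
* `locus_log2fc()` reports `log2((mean_A + c) / (mean_B + c))` on
  CPM-normalized counts with pseudocount `c > 0`, the robust display
  statistic for locus genes whose counts drop to zero inside a deletion.
  CPM is used rather than median-of-ratios scaling because model refitting
  is out of scope and CPM preserves the qualitative contract.

The reference analysis reports both a triple-design stage (691 and 232
genes for the two models) and a further-filtered stage (649 and 190); the
additional filter is not fully specified, so the pipeline exposes both
stages explicitly and labels outputs by stage rather than guessing.

## Resampling nulls and empirical p-values

`overlap_permutation_test()` measures a k-way gene-list overlap against a
joint permutation null: every permutation redraws all k lists (original
sizes, uniform, without replacement) from the universe and records the
intersection size. Fold enrichment is `observed / mean(null)`; for k = 2
the null mean converges to the hypergeometric expectation
`|A||B|/N`. All empirical p-values in the package use the add-one rule

$$p = \frac{1 + \#\{T_{null} \ge T_{obs}\}}{n_{perm} + 1},$$

which can never return 0 from finite resampling and attains 1. The joint
(rather than pairwise) scheme is the default because a single enrichment is
reported per intersection; a pairwise mode exists behind a flag. The
default `n_perm` is 10,000.

On a *discrete* statistic such as an intersection count, the add-one p is
conservative: ties between the observed and null values inflate the count in
the numerator. For small universes this is noticeable (the exact type-I rate
at nominal 0.05 is about 0.042 for two lists of 250 in a universe of 1000,
computable in closed form from the hypergeometric mass); the package's
calibration tests therefore use overlap configurations large enough that the
statistic is effectively continuous.

## Over-representation statistic

`hypergeom_ora()` implements the minimal ORA used downstream of consensus
calling: upper-tail hypergeometric p per term, BH adjustment across tested
terms, `GeneRatio = |q ∩ t|/|q|`, `BgRatio = |t ∩ U|/|U|` and
`foldEnrichment = GeneRatio / BgRatio`, with results ordered by adjusted p
then fold enrichment. Zero-overlap terms report p = 1 and fold 0 (one-sided
enrichment convention); terms with fewer than two universe genes are skipped
as degenerate. Ontology *databases* are out of scope — term-to-gene maps are
supplied by the user (two-column TSV or GMT).

## Consecutive-window filter

Sliding-window predictions (score in [0, 1], window length L read from the
input, 13 nt by convention) are consolidated by `merge_consecutive()`: within
each (snoRNA copy, target gene, strand) group, a *run* is a maximal chain of
windows whose target starts increase by exactly 1 nt while the snoRNA-side
starts step 1 nt in the duplex-consistent direction — decreasing on + strand
targets, increasing on −, reflecting the antiparallel duplex. Runs of at
least `w` windows, all scoring at least `t`, become binding events spanning
first window start to last start + L on both molecules. The conventional
parameters are `t = 0.98`, `w = 3`. The upstream tool does not document the
precise semantics of "consecutive" or of its merge flag, so the duplex
requirement is this package's documented default (a target-only mode exists
behind `consecutive = "target"`), and `merge_overlaps = TRUE` unions events
of the same copy/gene/strand that overlap on the target. Event scores are
summarized as both min and mean, since neither is canonical upstream.

The implementation groups windows on anti-diagonals (target + sno start is
invariant along a duplex-consistent run on + strand targets, target − sno on
−), which reduces run finding to detecting unit steps in sorted target
starts; tests cross-check it against an independent O(n²) successor-chasing
oracle over randomized inputs and (t, w) grids.

## Covariate-matched targeting enrichment

Whether predicted binding events pile up on the consensus genes is tested
against *matched* control lists, not against arbitrary random genes:

* `compute_covariates()` computes per gene: merged-exonic length (nt), GC
  fraction of the merged exonic sequence, and mean neuron expression (CPM).
  These operationalizations are the package's documented choices; the
  covariate trio itself (length, GC, expression) is standard.
* `sample_matched_lists()` rejection-samples lists of the target's size from
  `universe \ target`, accepting a candidate only if two-sided Wilcoxon
  rank-sum tests against the target give p > `alpha_match` (default 0.05,
  since "not significantly different" is not otherwise quantified) for all
  three covariates. The conventional configuration is 100 accepted lists.
  Target genes are excluded from candidates to avoid trivial acceptance;
  accepted lists are re-verifiable post hoc and are kept with their
  acceptance p-values for audit.
* `targeting_enrichment()` compares the mean, median and sum of per-gene
  event counts on the target list against the same statistics over the
  matched lists (fold = observed / null mean; add-one empirical p). Under
  the default simulation conditions a planted 2.5-fold enrichment is
  recovered by all three statistics.
* `family_contrast()` contrasts per-copy event counts between SNORD116 and
  SNORD115 (the natural same-locus control family, whose isolated deletion
  has no phenotype), plus the restricted group-III versus SNORD115 contrast.
  Note the family-wide rank-sum test is underpowered when only group III is
  planted (24 of 30 SNORD116 copies then sit at zero alongside SNORD115);
  the restricted contrast is the appropriate detector in that regime.

## Genomic feature coverage

`select_transcripts()` restricts the annotation to transcripts with support
level 1-3 and the "basic" tag before any coverage computation.
`background_composition()` classifies every nucleotide of a gene set's
transcript union with fixed priority

> junction > 5'UTR > 3'UTR > CDS > other exon > intron,

where junctions are ±J nt around each internal exon/intron boundary
(J defaults to 2 nt; the operational junction definition is not documented
upstream, so J is an explicit parameter). Fractions are normalized at the
top level among {exon, intron, junction} and, within exon, among the UTR /
CDS split — mirroring the two-ring donut display this analysis feeds.

`event_composition()` assigns one category per event. Two modes exist
deliberately:

* `assign = "overlap"` (default): an event takes the highest-priority
  category it overlaps, so anything spanning an exon/intron boundary is
  junctional — the convention for displaying event composition.
* `assign = "center"`: an event takes the category of its midpoint
  nucleotide. This is the statistically consistent estimator — for
  uniformly placed events the composition converges to the per-bp null
  expectation, which the overlap mode cannot do (it inflates the junction
  share by event width). The package's chi-square calibration test runs in
  center mode for exactly this reason; enrichment ratios
  (event fraction / background fraction) are reported in both modes.

## Box-relative binding positions

`relative_centers()` maps each event's snoRNA-side span to the continuous
midpoint `(start + end) / 2` of its 0-based half-open interval and scales by
copy length; box tracks (C, D', C', D, ASE2) are scaled the same way. The
continuous midpoint makes the even-length tie-break moot and keeps a window
at [40, 60) of a 98-nt copy at exactly 50. `region_fractions()` reports the
fraction of event centers per named region (sums to 1 exactly).
`scan_boxes()` is a utility motif scanner (RUGAUGA for C-type boxes with one
mismatch allowed for C', CUGA for D-type, ranked by positional
plausibility); curated fixture boxes always take precedence over scan
results.

The ASE2 element is modeled as 15 nt immediately 5' of the D' box — C/D-box
biology places antisense elements directly upstream of the D/D' boxes, but
no width is specified upstream, so it is an explicit, configurable default.

## The synthetic-data module

`build_locus_fixture()` is deterministic: 30 SNORD116 copies (groups I =
copies 1-9, II = 10-24, III = 25-30; 98 nt each) and 48 SNORD115 copies
(82 nt), flanking imprinted genes, and smDEL/lgDEL intervals satisfying the
locus invariants (smDEL covers the SNORD116 cluster and no coding flanking
gene; lgDEL additionally covers SNURF and the SNRPN promoter region).
Coordinates are synthetic, on a pseudo-chromosome — no genome download is
required and nothing here should be mistaken for hg38. Copy sequences are
deterministic A/C backgrounds (which cannot spawn spurious box motifs) with
the real box motifs planted at the curated coordinates.

`gen_annotation()`, `gen_counts()`, `gen_de_tables()` and `gen_windows()`
generate the remaining inputs under a single master seed (every stage
derives its own child seed, so outputs are byte-identical across runs):

* Genes on a pseudo-chromosome with 1-6 exons, both strands, ~70% coding,
  GENCODE-style TSL and basic tags, and per-gene GC content drawn uniformly
  in [0.35, 0.65] so covariate matching has real variation to match on.
* Counts are negative binomial with gene-wise log-normal dispersions around
  `nb_dispersion` (default 0.05) and per-sample library factors in
  [0.7, 1.3], over the full 2-background × 3-condition × 2-lineage design
  (default 3 replicates per cell). Only moments matter for the tests.
* DE tables are synthesized in *oracle mode* directly from the planted
  truth (model fitting is explicitly out of scope): planted genes receive
  p-values guaranteed below the BH threshold with the planted sign, null
  genes uniform p-values. Because null p-values are genuinely uniform, BH
  can admit occasional false positives into a single table — the exactness
  of planted-truth recovery holds for the intersected consensus, which is
  what the tests assert.
* Windows: isolated noise windows (uniform scores — isolated windows cannot
  form runs) plus planted events: runs of ≥3 consecutive duplex-consistent
  windows scoring ≥0.98, at per-gene rate `event_rate` on background genes
  and `event_rate × targeting_enrichment_fold` on the target set. Event
  placement is biased into 5'UTRs with probability `w/(1+w)` of the
  `utr5_bias_weight` odds, and group-III snoRNA-side centers into ASE2 with
  the analogous `ase2_bias_weight` odds (`Inf` forces the bias). Copies are
  drawn with per-group weights defaulting to I:II:III:SNORD115 = 2:3:6:1,
  echoing the observed regime in which group III carries the highest
  per-copy rate and SNORD116 exceeds SNORD115.

Default study conditions: 2000 genes, 22 + 20 planted shared genes (the
42-gene analog), 150 background-specific false leads, |log2FC| = 2,
targeting fold 2.5, `utr5_bias_weight = 3`, `ase2_bias_weight = 9`, window
length 13, event rate 3 per gene, 100 matched control lists.

What the generator does *not* emulate: read-level noise and alignment
artifacts, DESeq2's shrinkage and dispersion estimation (oracle-mode tables
bypass fitting entirely), correlated gene-gene expression, realistic
transcript-isoform complexity, hg38 coordinates and real snoRNA sequences.
Passing the planted-recovery tests therefore demonstrates the correctness of
the downstream statistics, not the end-to-end behavior of an aligner +
DESeq2 stack on real reads.

## Numerical and interface choices

* **Coordinates.** Genomic intervals are held in `GRanges`/`IRanges`
  (1-based closed), the native R/Bioconductor convention, and converted at
  the file boundaries: GTF is 1-based closed on disk, window TSVs, event
  tables and BED are 0-based half-open. snoRNA-side window coordinates stay
  0-based half-open throughout, matching the predictor's TSV. Every output
  file declares its convention in a header comment.
* **Strand.** Feature assignment uses same-strand overlap only; events on a
  gene carry that gene's strand.
* **Determinism.** Every stochastic stage takes an explicit seed; `run_all()`
  derives per-stage seeds from the config seed and writes a manifest with
  md5 hashes of every output, and two runs under one seed are byte-identical.
* **Degenerate inputs.** Empty matrices, empty event sets, unknown copy ids,
  score ranges outside [0, 1], overlapping sample groups and
  out-of-universe gene lists all raise immediate, named errors rather than
  returning silent zeros.
* **Problem sizes in the test suite.** The suite validates oracle
  equivalences on exhaustively enumerable sizes (universes ≤ 20 for the
  overlap expectation, ≤ 15 for ORA, ≤ 50-window tables for the filter),
  calibration on 500 overlap / 200 targeting null replicates, planted-fold
  recovery at the default 2000-gene conditions, and end-to-end determinism
  at 400 genes. These sizes were chosen to make the Monte-Carlo error of
  each check small relative to its tolerance.

## Known limitations

* The extra filter separating the triple-design stage from the final
  per-model gene sets in the reference analysis is not reproducible from its
  description; both stages are exposed instead.
* Matched-list sampling uses three marginal Wilcoxon screens, not joint
  (propensity/caliper) matching; heavily skewed universes can fail to match
  (the failure carries a diagnostic naming the covariate that rejects most).
* The overlap permutation test permutes lists jointly across the whole
  universe; whether permutation should be stratified within background is
  an open modeling question and a stratified scheme is not implemented.
* Real snoGloBe scores, hg38 annotation and the study's sequencing data are
  out of scope; dataset-dependent headline values (e.g. the specific 42-gene
  list) are emulated, not reproduced.
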