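# snotarget

Consensus differential expression and orphan C/D-box snoRNA target
enrichment — the downstream statistical pipeline for isogenic deletion
models of the Prader-Willi (chr15q11-q13) locus.

## The problem

Prader-Willi syndrome is caused by loss of paternal expression at
chr15q11-q13, and the smallest disease-associated deletions remove little
beyond the 30-copy *SNORD116* C/D-box snoRNA cluster. *SNORD116* snoRNAs are
orphans — no verified targets, no rRNA complementarity — so the analytical
route to their function runs through two statistical questions:

1. Which genes are *consistently* dysregulated when the cluster is deleted —
   significant with consistent direction across isogenic genetic backgrounds
   (H9, CT2), across deletion models (`smDEL`: the cluster alone; `lgDEL`:
   SNRPN promoters through the cluster), and across statistical designs?
2. Is that consensus gene set *enriched for predicted SNORD116 targeting* —
   binding events from a sliding-window interaction predictor, filtered to
   runs of at least `w = 3` consecutive windows scoring at least
   `t = 0.98` — relative to control gene lists matched on length, GC content
   and expression, and relative to the SNORD115 control family? Where on the
   targets (5'UTR/CDS/intron/junction) and where on the snoRNA (relative to
   the C/D'/C'/D boxes and the ASE2 antisense element) do events fall?

`snotarget` implements every stage: consensus DEG calling with low-count
filtering and pseudocount locus fold changes; k-way overlap permutation
tests with add-one empirical p-values,
`p = (1 + #{null >= obs}) / (n_perm + 1)`, and fold enrichment
`observed / mean(null)`; a minimal hypergeometric ORA with
`foldEnrichment = GeneRatio / BgRatio`; the consecutive-window filter;
covariate-matched (Wilcoxon-screened) control-list sampling and
mean/median/sum targeting-enrichment statistics; per-bp and per-event
genomic feature composition under TSL 1-3 + basic transcript filtering; and
box-relative binding-position profiles. A fully seeded synthetic-data module
(including a deterministic 30 + 48-copy locus fixture with group boundaries
I = 1-9, II = 10-24, III = 25-30) generates every input with planted
structure, so all statistics are validated by planted-truth recovery.

## Worked example

```r
library(snotarget)

locus <- build_locus_fixture()
locus
#> Synthetic PWS locus model (chr15s)
#>   30 SNORD116 copies (groups: 9/15/6)
#>   48 SNORD115 copies
#>   deletions: smDEL [79000, 139098), lgDEL [49500, 139098)

cfg <- sim_config(n_genes = 1000, seed = 7)
res <- run_all(cfg, outdir = "demo", n_perm = 1000, n_lists = 50)

res$consensus$per_model$lgDEL$shared
#> consensus_set: 23 up, 20 down (alpha = 0.05)
length(res$consensus$shared42)
#> [1] 42

res$overlap          # smDEL x lgDEL consensus overlap vs permutation null
#> Enrichment result (2-way overlap)
#>   observed: 42   null mean: 1.827   null median: 2
#>   fold enrichment: 22.99   empirical p: 0.000999 (n = 1000)

res$enrich$enrichment$sum   # targeting on the shared set vs matched lists
#> Enrichment result (targeting sum)
#>   observed: 82   null mean: 30.02   null median: 30.5
#>   fold enrichment: 2.732   empirical p: 0.01961 (n = 50)

round(res$coverage$enrichment_ratio$exon[["utr5"]], 2)
#> [1] 7.12
round(res$position$fractions$by_group[["SNORD116-III"]], 3)
#>    ase2   c_box  cp_box d_boxes   other
#>   0.924   0.008   0.008   0.005   0.056

res$scoring
#>   n_called n_planted sensitivity precision
#> 1       42        42           1         1
```

Reading the numbers: the consensus caller recovers exactly the 42 planted
shared genes (23 up + 20 down in the lgDEL model at `padj < 0.05`, then
intersected across backgrounds, designs and deletion models; sensitivity and
precision 1.0 against the planted truth). Their cross-model overlap is ~23×
what random same-sized lists produce (empirical p ≈ 0.001, the add-one
floor at 1000 permutations). Predicted targeting events on the shared set
are ~2.7× the matched-control expectation — the generator planted a 2.5-fold
enrichment — with event placement heavily biased into 5'UTRs (ratio 7.1 vs
the per-bp background) and group-III snoRNA-side binding centers
concentrated in the ASE2 element (92% of centers), upstream of the D' box.

Every stage is also callable on user data: `read_gtf()` +
`read_de_table()` + `read_windows()` feed `call_shared_degs()`,
`merge_consecutive()`, `sample_matched_lists()`, `targeting_enrichment()`,
`event_composition()` and `relative_centers()` directly; `run_all()` writes
TSV/BED/JSON outputs plus a manifest with per-file md5 hashes and is
byte-identical under a fixed seed.

See `vignettes/snotarget-methods.Rmd` for the statistical model,
parameter-by-parameter defaults, and known limitations.

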