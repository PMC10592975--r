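test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(targeting_enrichment_fold = -1), "fold")
  expect_error(sim_config(n_genes = 10, planted_shared_up = 20,
                          planted_shared_down = 0,
                          planted_background_specific = 0),
               "exceed")
})

test_that("generated annotation is structurally sound", {
  cfg <- tiny_config(n_genes = 200L)
  ann <- gen_annotation(cfg)
  mc <- S4Vectors::mcols(ann$features)
  expect_equal(length(ann_gene_ids(ann)), 200L)
  expect_setequal(unique(mc$type),
                  c("gene", "transcript", "exon", "CDS", "UTR"))
  expect_true(all(c("+", "-") %in%
                    as.character(GenomicRanges::strand(ann$features))))

  # every transcript's exons lie within its gene's bounds
  genes <- ann$features[mc$type == "gene"]
  gene_rng <- data.frame(
    id = S4Vectors::mcols(genes)$gene_id,
    start = GenomicRanges::start(genes), end = GenomicRanges::end(genes)
  )
  exons <- ann$features[mc$type == "exon"]
  gi <- match(S4Vectors::mcols(exons)$gene_id, gene_rng$id)
  expect_true(all(GenomicRanges::start(exons) >= gene_rng$start[gi]))
  expect_true(all(GenomicRanges::end(exons) <= gene_rng$end[gi]))
  # every transcript has at least one exon
  tx_with_exons <- unique(S4Vectors::mcols(exons)$transcript_id)
  all_tx <- mc$transcript_id[mc$type == "transcript"]
  expect_true(all(all_tx %in% tx_with_exons))
  # genome long enough to cover every feature
  expect_gte(sum(Biostrings::width(ann$genome)),
             max(GenomicRanges::end(ann$features)))
})

test_that("fully noncoding configuration yields no CDS/UTR features", {
  cfg <- tiny_config(n_genes = 30L, frac_coding = 0,
                     planted_shared_up = 0L, planted_shared_down = 0L,
                     planted_background_specific = 0L)
  ann <- gen_annotation(cfg)
  expect_false(any(S4Vectors::mcols(ann$features)$type %in% c("CDS", "UTR")))
})

test_that("annotation generation is byte-identical under a fixed seed", {
  cfg <- tiny_config(n_genes = 40L)
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(gen_annotation(cfg), f1)
  write_gtf(gen_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("counts carry planted shifts at the configured magnitude", {
  # many replicates so group means are tight around the NB means
  cfg <- tiny_config(n_genes = 60L, n_replicates = 50L,
                     planted_shared_up = 6L, planted_shared_down = 6L,
                     planted_background_specific = 0L, lfc_magnitude = 2)
  ann <- gen_annotation(cfg)
  cnt <- gen_counts(ann, cfg)
  expect_equal(nrow(cnt$samples), 2 * 3 * 2 * 50)
  up <- unique(cnt$truth$gene_id[cnt$truth$direction == "up"])
  wt <- cnt$samples$sample[cnt$samples$condition == "WT" &
                             cnt$samples$lineage == "neuron"]
  del <- cnt$samples$sample[cnt$samples$condition == "lgDEL" &
                              cnt$samples$lineage == "neuron"]
  ratio <- rowMeans(cnt$counts[up, del]) / rowMeans(cnt$counts[up, wt])
  expect_true(all(abs(log2(ratio) - 2) < 0.5))
  # ESC samples are never shifted
  esc_wt <- cnt$samples$sample[cnt$samples$condition == "WT" &
                                 cnt$samples$lineage == "ESC"]
  esc_del <- cnt$samples$sample[cnt$samples$condition == "lgDEL" &
                                  cnt$samples$lineage == "ESC"]
  esc_ratio <- rowMeans(cnt$counts[up, esc_del]) /
    rowMeans(cnt$counts[up, esc_wt])
  expect_true(all(abs(log2(esc_ratio)) < 0.5))
})

test_that("zero effect size produces an empty truth table", {
  cfg <- tiny_config(n_genes = 30L, lfc_magnitude = 0)
  ann <- gen_annotation(cfg)
  cnt <- gen_counts(ann, cfg)
  expect_equal(nrow(cnt$truth), 0L)
})

test_that("planted shared set sizes are honored by construction", {
  cfg <- tiny_config(n_genes = 200L, planted_shared_up = 50L,
                     planted_shared_down = 10L,
                     planted_background_specific = 0L)
  ann <- gen_annotation(cfg)
  cnt <- gen_counts(ann, cfg)
  shared_up <- unique(cnt$truth$gene_id[cnt$truth$shared &
                                          cnt$truth$direction == "up"])
  expect_length(shared_up, 50L)
  # planted in both deletion models
  per_gene <- table(cnt$truth$gene_id[cnt$truth$shared],
                    cnt$truth$contrast[cnt$truth$shared])
  expect_true(all(per_gene == 1L))
})

test_that("oracle DE tables guarantee planted significance with correct sign", {
  cfg <- tiny_config(n_genes = 150L)
  ann <- gen_annotation(cfg)
  cnt <- gen_counts(ann, cfg)
  de <- gen_de_tables(cnt$truth, ann_gene_ids(ann), cfg)
  expect_length(de, 8L)
  for (ct in c("smDEL", "lgDEL")) {
    pl <- cnt$truth[cnt$truth$contrast == ct & cnt$truth$shared, ]
    for (nm in grep(paste0("^", ct), names(de), value = TRUE)) {
      tab <- de[[nm]]
      idx <- match(pl$gene_id, tab$gene_id)
      expect_true(all(tab$padj[idx] < 0.05))
      expect_true(all(sign(tab$log2FoldChange[idx]) ==
                        ifelse(pl$direction == "up", 1, -1)))
    }
  }
})

test_that("null-only DE tables have near-zero BH discovery fraction", {
  cfg <- tiny_config(n_genes = 400L, lfc_magnitude = 0)
  ann <- gen_annotation(cfg)
  cnt <- gen_counts(ann, cfg)
  de <- gen_de_tables(cnt$truth, ann_gene_ids(ann), cfg)
  fracs <- vapply(de, function(tab) mean(tab$padj < 0.05), numeric(1))
  expect_true(all(fracs < 0.02))
})

test_that("gen_windows validates targets and plants ASE2 bias in the limit", {
  locus <- build_locus_fixture()
  cfg <- tiny_config(n_genes = 40L, ase2_bias_weight = Inf,
                     noise_windows_per_gene = 0)
  ann <- gen_annotation(cfg)
  expect_error(gen_windows(locus, ann, "NOT_A_GENE", cfg), "absent")

  win <- gen_windows(locus, ann, ann_gene_ids(ann)[1:5], cfg)
  planted <- attr(win, "planted")
  g3 <- grepl("^SNORD116-(2[5-9]|30)$", planted$sno_id)
  expect_true(all(planted$in_ase2[g3]))
  ev <- merge_consecutive(win, t = 0.98, w = 3)
  prof <- relative_centers(ev, locus)
  g3ev <- prof$events$group == "SNORD116-III"
  cp <- locus$copies[match(prof$events$sno_id[g3ev], locus$copies$copy_id), ]
  ctr <- prof$events$center[g3ev]
  # merged spans can extend past a clamped or unioned run; allow slack at
  # the edges and a small fraction of unions straddling the boundary
  expect_true(mean(ctr >= cp$ase2_start - 2 & ctr <= cp$ase2_end + 2) > 0.9)
})

test_that("window scores are valid and planted runs survive the filter", {
  locus <- build_locus_fixture()
  cfg <- tiny_config(n_genes = 30L)
  ann <- gen_annotation(cfg)
  win <- gen_windows(locus, ann, character(0), cfg)
  expect_true(all(win$score >= 0 & win$score <= 1))
  expect_true(all(win$sno_window_start >= 0))
  len <- build_locus_fixture()$copies$length
  names(len) <- build_locus_fixture()$copies$copy_id
  expect_true(all(win$sno_window_end <= len[win$sno_id]))
  ev <- merge_consecutive(win, t = 0.98, w = 3)
  expect_gte(nrow(ev), 1L)
  expect_true(all(ev$n_windows >= 3L))
})
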