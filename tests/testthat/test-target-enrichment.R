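test_that("covariates reproduce interval arithmetic and GC by hand", {
  # GPLUS merged exons: [101,150] + [201,250] -> 100 nt
  ann <- manual_annotation(seq_letters = strrep("G", 400))
  cnts <- rbind(GPLUS = c(10, 20), GMINUS = c(0, 0))
  colnames(cnts) <- c("s1", "s2")
  smp <- data.frame(sample = c("s1", "s2"),
                    lineage = c("neuron", "neuron"))
  cov <- compute_covariates(ann, cnts, smp)
  expect_equal(cov$length[cov$gene_id == "GPLUS"], 100)
  expect_equal(cov$gc[cov$gene_id == "GPLUS"], 1)  # all-G genome
  expect_equal(cov$expression[cov$gene_id == "GMINUS"], 0)
  # expression is mean CPM over neuron samples; GPLUS carries each library
  expect_equal(cov$expression[cov$gene_id == "GPLUS"], 1e6)
})

test_that("matched lists all pass the three Wilcoxon screens post hoc", {
  set.seed(4)
  n <- 400
  covs <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    length = rlnorm(n, 7, 0.6),
    gc = runif(n, 0.3, 0.7),
    expression = rlnorm(n, 4, 1)
  )
  target <- sample(covs$gene_id, 30)
  mn <- sample_matched_lists(target, covs$gene_id, covs, n_lists = 20,
                             alpha_match = 0.05, seed = 10)
  expect_length(mn$lists, 20L)
  rownames(covs) <- covs$gene_id
  for (lst in mn$lists) {
    expect_length(lst, 30L)
    expect_length(intersect(lst, target), 0L)  # controls exclude the target
    for (v in c("length", "gc", "expression")) {
      p <- suppressWarnings(
        wilcox.test(covs[target, v], covs[lst, v], exact = FALSE)$p.value
      )
      expect_gt(p, 0.05)
    }
  }
  expect_true(all(mn$acceptance_pvalues > 0.05))
})

test_that("an unmatchable universe fails with a covariate diagnostic", {
  covs <- data.frame(
    gene_id = sprintf("g%03d", 1:120),
    length = c(rep(100, 20), rep(1000, 100)),  # universe 10x target lengths
    gc = 0.5, expression = 10
  )
  target <- covs$gene_id[1:20]
  expect_error(
    sample_matched_lists(target, covs$gene_id, covs, n_lists = 5,
                         max_tries = 50, seed = 1),
    "length"
  )
  expect_error(
    sample_matched_lists(covs$gene_id, covs$gene_id, covs, n_lists = 2),
    "smaller than the target"
  )
})

test_that("targeting enrichment recovers planted and null folds", {
  locus <- build_locus_fixture()
  cfg <- tiny_config(n_genes = 400L, event_rate = 4,
                     targeting_enrichment_fold = 2.5,
                     utr5_bias_weight = 0, ase2_bias_weight = 0)
  ann <- gen_annotation(cfg)
  cnt <- gen_counts(ann, cfg)
  genes <- ann_gene_ids(ann)
  covs <- compute_covariates(ann, cnt$counts, cnt$samples)
  target <- sample(genes, 42)

  win <- gen_windows(locus, ann, target, cfg)
  ev <- merge_consecutive(win, t = 0.98, w = 3)
  mn <- sample_matched_lists(target, genes, covs, n_lists = 60, seed = 3)
  enr <- targeting_enrichment(ev, target, mn)
  expect_named(enr, c("mean", "median", "sum"))
  expect_equal(enr$sum$fold, 2.5, tolerance = 0.2)
  expect_equal(enr$mean$fold, 2.5, tolerance = 0.2)
  expect_lt(enr$sum$p_empirical, 0.05)

  # null configuration: fold ~ 1 and p not extreme
  cfg0 <- tiny_config(n_genes = 400L, event_rate = 4,
                      targeting_enrichment_fold = 1,
                      utr5_bias_weight = 0, ase2_bias_weight = 0, seed = 77)
  win0 <- gen_windows(locus, gen_annotation(cfg), target, cfg0)
  ev0 <- merge_consecutive(win0, t = 0.98, w = 3)
  enr0 <- targeting_enrichment(ev0, target, mn)
  expect_equal(enr0$sum$fold, 1, tolerance = 0.2)
})

test_that("zero events give the fold-0, p = 1 convention", {
  mn <- structure(list(lists = list(letters[1:3], letters[4:6]),
                       acceptance_pvalues = NULL, n_tries = 2,
                       alpha_match = 0.05, seed = 1),
                  class = "matched_null")
  ev <- data.frame(target_gene = character(0))
  enr <- targeting_enrichment(ev, letters[7:9], mn)
  expect_equal(enr$sum$observed, 0)
  expect_equal(enr$sum$fold, 0)
  expect_equal(enr$sum$p_empirical, 1)
  expect_error(targeting_enrichment(ev, letters[1:2],
                                    structure(list(lists = list()),
                                              class = "matched_null")),
               "non-empty")
})

test_that("fold estimates are invariant to gene relabeling", {
  ev <- data.frame(target_gene = c("a", "a", "b", "c"))
  mn <- structure(list(lists = list(c("b", "c"), c("d", "e")),
                       acceptance_pvalues = NULL, n_tries = 2,
                       alpha_match = 0.05, seed = 1),
                  class = "matched_null")
  e1 <- targeting_enrichment(ev, c("a", "d"), mn)
  relab <- c(a = "x1", b = "x2", c = "x3", d = "x4", e = "x5")
  ev2 <- data.frame(target_gene = unname(relab[ev$target_gene]))
  mn2 <- mn; mn2$lists <- lapply(mn$lists, function(g) unname(relab[g]))
  e2 <- targeting_enrichment(ev2, unname(relab[c("a", "d")]), mn2)
  expect_equal(e1$sum$fold, e2$sum$fold)
  expect_equal(e1$mean$observed, e2$mean$observed)
})

test_that("family contrast detects planted family bias and stays flat under equal rates", {
  locus <- build_locus_fixture()
  # family-wide planting: every SNORD116 copy elevated over SNORD115
  cfg <- tiny_config(n_genes = 200L,
                     copy_weights = c(I = 1, II = 1, III = 1, SNORD115 = 0.05),
                     utr5_bias_weight = 0, ase2_bias_weight = 0)
  ann <- gen_annotation(cfg)
  win <- gen_windows(locus, ann, character(0), cfg)
  ev <- merge_consecutive(win, t = 0.98, w = 3)
  fc <- family_contrast(ev, locus)
  expect_gt(fc$family_test$mean_snord116, fc$family_test$mean_snord115)
  expect_lt(fc$family_test$p_value, 0.01)

  # group-III-only planting: the restricted contrast detects it
  cfg3 <- tiny_config(n_genes = 200L,
                      copy_weights = c(I = 0, II = 0, III = 1, SNORD115 = 0.01),
                      utr5_bias_weight = 0, ase2_bias_weight = 0)
  win3 <- gen_windows(locus, ann, character(0), cfg3)
  ev3 <- merge_consecutive(win3, t = 0.98, w = 3)
  fc3 <- family_contrast(ev3, locus)
  expect_gt(fc3$group3_test$mean_group3, fc3$group3_test$mean_snord115)
  expect_lt(fc3$group3_test$p_value, 0.01)

  # equal per-copy rates: type-I behavior over repeated simulation
  pvals <- vapply(1:8, function(s) {
    cfge <- tiny_config(n_genes = 60L, seed = 100 + s,
                        copy_weights = c(I = 1, II = 1, III = 1, SNORD115 = 1),
                        utr5_bias_weight = 0, ase2_bias_weight = 0)
    wine <- gen_windows(locus, ann, character(0), cfge)
    eve <- merge_consecutive(wine, t = 0.98, w = 3)
    family_contrast(eve, locus)$family_test$p_value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.5) # far from systematic rejection
})
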