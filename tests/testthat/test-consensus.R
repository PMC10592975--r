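make_de <- function(genes, padj, lfc, contrast = "lgDEL",
                    background = "H9", design = "background_condition") {
  de_result_table(
    data.frame(gene_id = genes, baseMean = 100, log2FoldChange = lfc,
               pvalue = padj, padj = padj, stringsAsFactors = FALSE),
    contrast = contrast, background = background, design = design
  )
}

test_that("filter_low_counts applies the mean threshold exactly", {
  m <- rbind(g1 = c(0, 1), g2 = c(1, 1), g3 = c(0, 0), g4 = c(100, 20))
  expect_setequal(filter_low_counts(m, min_mean = 1), c("g2", "g4"))
  expect_setequal(filter_low_counts(m, min_mean = 0.5), c("g1", "g2", "g4"))
  # a mean threshold of 1 is one count per sample — a total of 39 counts
  # in a 39-sample design
  m39 <- matrix(1, nrow = 2, ncol = 39, dimnames = list(c("a", "b"), NULL))
  m39["b", 1] <- 0
  expect_equal(filter_low_counts(m39, min_mean = 1), "a")
  expect_equal(sum(m39["a", ]), 39)
  expect_error(filter_low_counts(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(filter_low_counts(m - 50), "non-negative")
})

test_that("shared-DEG calling enumerates significance/sign patterns correctly", {
  # all combinations of (sig/nonsig) x (sign) across two backgrounds
  genes <- sprintf("g%02d", 1:9)
  padj_a <- c(.01, .01, .01, .01, .20, .01, .20, .20, NA)
  lfc_a <- c(2, -2, 2, -2, 2, 2, -1, 1, 1)
  padj_b <- c(.01, .01, .01, .01, .01, .20, .01, .20, .01)
  lfc_b <- c(1, -1, -2, 2, 1, 1, -1, 1, 1)
  cs <- call_shared_degs(list(H9 = make_de(genes, padj_a, lfc_a),
                              CT2 = make_de(genes, padj_b, lfc_b,
                                            background = "CT2")))
  expect_setequal(cs$up, "g01")     # concordant up, both significant
  expect_setequal(cs$down, "g02")   # concordant down, both significant
  # discordant significant (g03, g04), single-background (g05..g07),
  # never significant (g08) and NA padj (g09) are all excluded
  expect_length(intersect(c(cs$up, cs$down),
                          c("g03", "g04", "g05", "g06", "g07", "g08", "g09")),
                0L)
  expect_length(intersect(cs$up, cs$down), 0L)
})

test_that("consensus sets shrink monotonically in alpha", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:300)
  tables <- list(
    H9 = make_de(genes, runif(300)^2, rnorm(300)),
    CT2 = make_de(genes, runif(300)^2, rnorm(300), background = "CT2")
  )
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  sets <- lapply(alphas, function(a) call_shared_degs(tables, alpha = a))
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(sets[[i + 1]]$up %in% sets[[i]]$up))
    expect_true(all(sets[[i + 1]]$down %in% sets[[i]]$down))
  }
})

test_that("triple-design consensus requires significance in all three designs", {
  genes <- c("a", "b", "c", "d")
  t1 <- make_de(genes, c(.01, .01, .01, .2), 1, design = "background_condition")
  t2 <- make_de(genes, c(.01, .01, .2, .01), 1, design = "condition")
  t3 <- make_de(genes, c(.01, .2, .01, .01), 1, design = "interaction")
  expect_equal(triple_design_consensus(list(t1, t2, t3)), "a")
  expect_error(triple_design_consensus(list(t1, t2)), "three")
  expect_error(triple_design_consensus(list(t1, t2, t2)), "design")
})

test_that("cross-model intersection behaves as a set intersection", {
  expect_setequal(cross_model_shared(c("a", "b"), c("a", "b")), c("a", "b"))
  expect_length(cross_model_shared(c("a", "b"), c("c", "d")), 0L)
  expect_equal(cross_model_shared(c("a", "b", "c"), c("b", "c", "d")),
               c("b", "c"))
})

test_that("consensus calling recovers the planted truth exactly on oracle tables", {
  cfg <- tiny_config(n_genes = 500L, planted_shared_up = 15L,
                     planted_shared_down = 12L,
                     planted_background_specific = 40L)
  ann <- gen_annotation(cfg)
  cnt <- gen_counts(ann, cfg)
  genes <- ann_gene_ids(ann)
  de <- gen_de_tables(cnt$truth, genes, cfg)

  truth_shared_up <- unique(cnt$truth$gene_id[cnt$truth$shared &
                                                cnt$truth$direction == "up"])
  truth_shared_dn <- unique(cnt$truth$gene_id[cnt$truth$shared &
                                                cnt$truth$direction == "down"])
  per_model <- lapply(c("smDEL", "lgDEL"), function(ct) {
    shared <- call_shared_degs(
      list(H9 = de[[sprintf("%s.H9.background_condition", ct)]],
           CT2 = de[[sprintf("%s.CT2.background_condition", ct)]])
    )
    triple <- lapply(c("H9", "CT2"), function(bg) {
      triple_design_consensus(list(
        de[[sprintf("%s.%s.background_condition", ct, bg)]],
        de[[sprintf("%s.condition", ct)]],
        de[[sprintf("%s.interaction", ct)]]
      ))
    })
    list(shared = shared, triple_shared = intersect(triple[[1]], triple[[2]]))
  })
  final <- cross_model_shared(per_model[[1]]$triple_shared,
                              per_model[[2]]$triple_shared)
  expect_setequal(final, c(truth_shared_up, truth_shared_dn))
  # per-model shared calls recover the direction-stratified truth
  for (pm in per_model) {
    expect_setequal(pm$shared$up, truth_shared_up)
    expect_setequal(pm$shared$down, truth_shared_dn)
  }
})

test_that("locus_log2fc computes pseudocount ratios and rejects bad input", {
  cnts <- rbind(flat = c(0, 0, 0, 0), up = c(3, 3, 1, 1),
                del = c(0, 0, 63, 63))
  colnames(cnts) <- c("a1", "a2", "b1", "b2")
  lfc <- locus_log2fc(cnts, c("a1", "a2"), c("b1", "b2"), pseudocount = 1,
                      normalize = FALSE)
  expect_equal(unname(lfc["flat"]), 0)
  expect_equal(unname(lfc["up"]), 1)
  expect_equal(unname(lfc["del"]), -6)
  expect_error(locus_log2fc(cnts, c("a1", "b1"), c("b1", "b2")), "overlap")
  expect_error(locus_log2fc(cnts, "a1", "b1", pseudocount = 0), "pseudocount")
  expect_error(locus_log2fc(cnts, "zz", "b1"), "unknown sample")
})
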