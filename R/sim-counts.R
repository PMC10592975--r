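#' Simulate a negative-binomial count matrix with planted DEGs
#'
#' Generates RNA-seq-like counts for the six-line design of the study system:
#' two genetic backgrounds (H9, CT2) x three conditions (WT, smDEL, lgDEL)
#' x two lineages (ESC, neuron), `n_replicates` each. Counts are negative
#' binomial with gene-wise log-normal dispersions around
#' `config$nb_dispersion` and per-sample library-size factors. Planted shared
#' DEGs are shifted by `lfc_magnitude` in neurons of both backgrounds and
#' both deletion conditions; background-specific DEGs are shifted in one
#' background and one deletion condition only (alternating), emulating the
#' spurious single-background hits that consensus calling removes.
#'
#' @param annotation An `annotation` from [gen_annotation()] (supplies the
#'   gene universe).
#' @param config A [sim_config()].
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (data.frame: sample, background, condition, lineage) and `truth`
#'   (data.frame: gene_id, contrast in smDEL/lgDEL, background in
#'   H9/CT2/both, direction in up/down, shared logical).
#' @export
gen_counts <- function(annotation, config) {
  validate_sim_config(config)
  genes <- ann_gene_ids(annotation)
  n <- length(genes)

  with_seed(derive_seed(config$seed, "counts"), {
    samples <- expand.grid(
      replicate = seq_len(config$n_replicates),
      lineage = c("ESC", "neuron"),
      condition = c("WT", "smDEL", "lgDEL"),
      background = c("H9", "CT2"),
      stringsAsFactors = FALSE
    )
    samples$sample <- sprintf("%s_%s_%s_r%d", samples$background,
                              samples$condition, samples$lineage,
                              samples$replicate)
    samples <- samples[, c("sample", "background", "condition", "lineage")]

    truth <- plant_truth(genes, config)

    base_mu <- 2^runif(n, 3, 12)
    disp <- rlnorm(n, meanlog = log(config$nb_dispersion), sdlog = 0.5)
    size_factors <- runif(nrow(samples), 0.7, 1.3)

    lfc <- matrix(0, nrow = n, ncol = nrow(samples),
                  dimnames = list(genes, samples$sample))
    if (nrow(truth)) {
      for (k in seq_len(nrow(truth))) {
        tr <- truth[k, ]
        bgs <- if (tr$background == "both") c("H9", "CT2") else tr$background
        hit <- samples$lineage == "neuron" & samples$condition == tr$contrast &
          samples$background %in% bgs
        sgn <- if (tr$direction == "up") 1 else -1
        lfc[tr$gene_id, hit] <- sgn * config$lfc_magnitude
      }
    }

    mu <- outer(base_mu, size_factors) * 2^lfc
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = rep(1 / disp, ncol(mu))),
      nrow = n, dimnames = dimnames(lfc)
    )
    list(counts = counts, samples = samples, truth = truth)
  })
}

# Assign planted genes to truth rows. Shared genes are dysregulated in both
# backgrounds and both deletion models; background-specific genes in exactly
# one background and one deletion model.
plant_truth <- function(genes, config) {
  n_up <- config$planted_shared_up
  n_dn <- config$planted_shared_down
  n_bs <- config$planted_background_specific
  if (config$lfc_magnitude == 0 || (n_up + n_dn + n_bs) == 0L) {
    return(data.frame(gene_id = character(0), contrast = character(0),
                      background = character(0), direction = character(0),
                      shared = logical(0), stringsAsFactors = FALSE))
  }
  picked <- sample(genes, n_up + n_dn + n_bs)
  up <- picked[seq_len(n_up)]
  dn <- picked[n_up + seq_len(n_dn)]
  bs <- picked[n_up + n_dn + seq_len(n_bs)]

  shared <- expand.grid(gene_id = c(up, dn), contrast = c("smDEL", "lgDEL"),
                        stringsAsFactors = FALSE)
  shared$background <- "both"
  shared$direction <- ifelse(shared$gene_id %in% up, "up", "down")
  shared$shared <- TRUE

  if (length(bs)) {
    i <- seq_along(bs)
    spec <- data.frame(
      gene_id = bs,
      contrast = c("smDEL", "lgDEL")[(i %% 2L) + 1L],
      background = c("H9", "CT2")[((i %/% 2L) %% 2L) + 1L],
      direction = c("up", "down")[((i %/% 4L) %% 2L) + 1L],
      shared = FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    spec <- shared[0, ]
  }
  rbind(shared, spec)
}

#' Synthesize DESeq2-style result tables from a planted truth table
#'
#' "Oracle mode" generator: differential-expression model fitting is out of
#' scope, so per-contrast result tables are synthesized directly from the
#' truth table. For each deletion contrast it emits the three analysis
#' designs used on real data — a per-background contrast
#' (`background_condition`, one table per background), a pooled `condition`
#' contrast and a background-by-condition `interaction` contrast. Planted
#' genes receive p-values guaranteed below the Benjamini-Hochberg threshold
#' at `alpha` with a log2 fold change of the planted sign; null genes receive
#' uniform p-values and near-zero fold changes. `padj` is BH-adjusted within
#' each table.
#'
#' @param truth Truth table from [gen_counts()].
#' @param genes Character vector: the gene universe.
#' @param config A [sim_config()].
#' @param alpha Significance threshold the guarantee is built against.
#' @return Named list of `de_result_table` data.frames (columns `gene_id`,
#'   `baseMean`, `log2FoldChange`, `pvalue`, `padj`), named
#'   `<contrast>.<background>.background_condition`, `<contrast>.condition`
#'   and `<contrast>.interaction`; each carries attributes `contrast`,
#'   `background` and `design`.
#' @export
gen_de_tables <- function(truth, genes, config, alpha = 0.05) {
  validate_sim_config(config)
  m <- length(genes)
  if (!m) stop_input("empty gene universe")

  with_seed(derive_seed(config$seed, "de"), {
    planted_in <- function(contrast, background) {
      hit <- truth$contrast == contrast &
        (truth$background == "both" | truth$background == background |
           background == "pooled")
      truth[hit, c("gene_id", "direction")]
    }

    make_table <- function(contrast, background, design) {
      pl <- planted_in(contrast, background)
      p <- runif(m)
      lfc <- rnorm(m, 0, 0.2)
      idx <- match(pl$gene_id, genes)
      # below alpha/m: survives BH at any rank
      p[idx] <- runif(length(idx), 0, alpha / (10 * m))
      lfc[idx] <- ifelse(pl$direction == "up", 1, -1) * config$lfc_magnitude +
        rnorm(length(idx), 0, 0.15)
      tab <- data.frame(
        gene_id = genes,
        baseMean = 2^runif(m, 3, 12),
        log2FoldChange = lfc,
        pvalue = p,
        padj = p.adjust(p, method = "BH"),
        stringsAsFactors = FALSE
      )
      de_result_table(tab, contrast = contrast, background = background,
                      design = design)
    }

    out <- list()
    for (ct in c("smDEL", "lgDEL")) {
      for (bg in c("H9", "CT2")) {
        out[[sprintf("%s.%s.background_condition", ct, bg)]] <-
          make_table(ct, bg, "background_condition")
      }
      out[[sprintf("%s.condition", ct)]] <- make_table(ct, "pooled", "condition")
      out[[sprintf("%s.interaction", ct)]] <- make_table(ct, "pooled", "interaction")
    }
    out
  })
}

#' Construct a differential-expression result table
#'
#' Validates and labels a per-gene statistics table (one row per gene) in the
#' schema the pipeline consumes: `gene_id`, `baseMean`, `log2FoldChange`,
#' `pvalue`, `padj`.
#'
#' @param tab data.frame with the columns above.
#' @param contrast Contrast label (e.g. "lgDEL").
#' @param background Genetic background label ("H9", "CT2" or "pooled").
#' @param design One of "background_condition", "condition", "interaction".
#' @return The table with class `de_result_table` and label attributes.
#' @export
de_result_table <- function(tab, contrast, background = "pooled",
                            design = "background_condition") {
  need <- c("gene_id", "log2FoldChange", "pvalue", "padj")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop_input("DE table missing column(s): %s",
                               paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) stop_input("DE table has duplicated gene ids")
  ok <- is.na(tab$padj) | (tab$padj >= 0 & tab$padj <= 1)
  if (!all(ok)) stop_input("padj outside [0, 1]")
  design <- match.arg(design,
                      c("background_condition", "condition", "interaction"))
  attr(tab, "contrast") <- contrast
  attr(tab, "background") <- background
  attr(tab, "design") <- design
  class(tab) <- c("de_result_table", "data.frame")
  tab
}
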