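#' Filter genes on mean raw count
#'
#' Removes genes whose mean count across all samples falls below a threshold.
#' The conventional prefilter keeps genes averaging at least one count per
#' sample (`min_mean = 1`), i.e. a total of 39 counts in a 39-sample design;
#' the neuron-only deletion contrasts use the same mean-of-1 rule.
#'
#' @param counts Non-negative genes x samples matrix with gene rownames.
#' @param min_mean Retain genes with `rowMeans(counts) >= min_mean`.
#' @return Character vector of retained gene ids.
#' @export
filter_low_counts <- function(counts, min_mean = 1) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop_input("counts must be a non-empty matrix")
  }
  if (any(counts < 0)) stop_input("counts must be non-negative")
  rownames(counts)[rowMeans(counts) >= min_mean]
}

#' Call DEGs shared across isogenic backgrounds
#'
#' Intersects per-background differential-expression results: a gene is a
#' shared upregulated DEG if `padj < alpha` and `log2FoldChange > 0` in every
#' background, and shared downregulated likewise with negative fold change.
#' Genes significant everywhere but with discordant signs are excluded from
#' both sets, so `up` and `down` are disjoint by construction.
#'
#' @param tables Named list of `de_result_table`s (or data.frames with
#'   `gene_id`, `log2FoldChange`, `padj`), one per background.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return A `consensus_set`: list with `up`, `down` (character vectors) and
#'   `provenance` (tables intersected, alpha, gene universe size).
#' @export
call_shared_degs <- function(tables, alpha = 0.05) {
  if (length(tables) < 2L) stop_input("need at least two background tables")
  for (tb in tables) {
    if (!all(c("gene_id", "log2FoldChange", "padj") %in% colnames(tb))) {
      stop_input("DE table lacks gene_id/log2FoldChange/padj columns")
    }
  }
  universe <- Reduce(intersect, lapply(tables, function(tb) tb$gene_id))
  status <- vapply(tables, function(tb) {
    tb <- tb[match(universe, tb$gene_id), ]
    sig <- !is.na(tb$padj) & tb$padj < alpha
    ifelse(!sig, 0L, ifelse(tb$log2FoldChange > 0, 1L, -1L))
  }, integer(length(universe)))
  status <- matrix(status, nrow = length(universe))
  up <- universe[rowSums(status == 1L) == ncol(status)]
  down <- universe[rowSums(status == -1L) == ncol(status)]
  new_consensus_set(up, down, provenance = list(
    tables = names(tables), alpha = alpha, universe_size = length(universe)
  ))
}

new_consensus_set <- function(up, down, provenance = list()) {
  stopifnot(length(intersect(up, down)) == 0L)
  structure(list(up = up, down = down, provenance = provenance),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d up, %d down (alpha = %s)\n",
              length(x$up), length(x$down),
              format(x$provenance$alpha %||% NA)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genes significant in all three analysis designs
#'
#' Intersects the significant gene sets of the three statistical designs run
#' per deletion contrast (per-background contrast, pooled condition contrast
#' and background-by-condition interaction): a gene is retained only if
#' `padj < alpha` in all three tables.
#'
#' @param tables List of exactly three `de_result_table`s whose `design`
#'   attributes are `background_condition`, `condition` and `interaction`
#'   (one each).
#' @param alpha Adjusted-p cutoff.
#' @return Character vector of genes significant in all three designs.
#' @export
triple_design_consensus <- function(tables, alpha = 0.05) {
  if (length(tables) != 3L) stop_input("exactly three design tables required")
  designs <- vapply(tables, function(tb) attr(tb, "design") %||% NA_character_,
                    character(1))
  if (!setequal(designs, c("background_condition", "condition", "interaction"))) {
    stop_input("tables must carry designs background_condition, condition, interaction (got: %s)",
               paste(designs, collapse = ", "))
  }
  sig <- lapply(tables, function(tb) {
    tb$gene_id[!is.na(tb$padj) & tb$padj < alpha]
  })
  Reduce(intersect, sig)
}

#' Genes shared between deletion models
#'
#' Intersection of the consensus gene sets of the large-deletion and
#' small-deletion models — the cross-model gene network analog.
#'
#' @param lgdel_set,smdel_set Character vectors of gene ids.
#' @return Character vector: `intersect(lgdel_set, smdel_set)`.
#' @export
cross_model_shared <- function(lgdel_set, smdel_set) {
  intersect(lgdel_set, smdel_set)
}

#' Counts-per-million normalization
#'
#' @param counts Non-negative genes x samples matrix.
#' @return Matrix of the same shape scaled to counts per million per sample.
#' @export
cpm <- function(counts) {
  if (!is.matrix(counts)) stop_input("counts must be a matrix")
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  sweep(counts, 2, lib, "/") * 1e6
}

#' Pseudocount log2 fold change between sample groups
#'
#' Per-gene `log2((mean_A + pseudocount) / (mean_B + pseudocount))` on
#' library-size-normalized counts (counts per million), the robust fold
#' change used to display locus genes that drop to zero counts inside a
#' deletion.
#'
#' @param counts Genes x samples matrix (raw counts; CPM-normalized
#'   internally unless `normalize = FALSE`).
#' @param group_a,group_b Disjoint character vectors of column names.
#' @param pseudocount Positive offset added to both group means.
#' @param normalize Scale to CPM first (default TRUE).
#' @return Named numeric vector of per-gene log2 ratios (A vs B).
#' @export
locus_log2fc <- function(counts, group_a, group_b, pseudocount = 1,
                         normalize = TRUE) {
  if (pseudocount <= 0) stop_input("pseudocount must be > 0")
  if (length(intersect(group_a, group_b))) {
    stop_input("sample groups overlap: %s",
               paste(intersect(group_a, group_b), collapse = ", "))
  }
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss)) stop_input("unknown sample(s): %s", paste(miss, collapse = ", "))
  x <- if (normalize) cpm(counts) else counts
  ma <- rowMeans(x[, group_a, drop = FALSE])
  mb <- rowMeans(x[, group_b, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}
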