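#' Per-gene covariates for matched-list sampling
#'
#' Computes, per gene, the three covariates used to accept matched control
#' lists: merged-exonic length (nt), GC fraction of the merged exonic
#' sequence, and mean expression (counts per million) across neuron samples.
#'
#' @param annotation An `annotation` with a genome sequence.
#' @param counts Genes x samples count matrix.
#' @param samples Sample sheet with columns `sample` and `lineage` (only
#'   `lineage == "neuron"` columns enter the expression covariate; if no
#'   sample sheet is given all columns are used).
#' @return data.frame: `gene_id`, `length`, `gc`, `expression`. Genes
#'   without exon sequence are dropped with a warning.
#' @export
compute_covariates <- function(annotation, counts, samples = NULL) {
  if (is.null(annotation$genome)) stop_input("annotation carries no genome sequence")
  exons <- ann_subset(annotation, "exon")
  chrom_seq <- annotation$genome[[1]]
  chrom_len <- length(chrom_seq)

  red_by_gene <- IRanges::reduce(
    S4Vectors::split(IRanges::ranges(exons),
                     S4Vectors::mcols(exons)$gene_id)
  )
  genes <- names(red_by_gene)
  flat <- unlist(red_by_gene, use.names = FALSE)
  flat_gene <- rep(genes, lengths(red_by_gene))
  flat <- IRanges::restrict(flat, start = 1L, end = chrom_len)

  fr <- Biostrings::letterFrequency(Biostrings::extractAt(chrom_seq, flat),
                                    c("A", "C", "G", "T"))
  acgt <- rowsum(fr, flat_gene)[genes, , drop = FALSE]
  length_nt <- as.numeric(rowsum(IRanges::width(flat), flat_gene)[genes, 1])
  gc <- (acgt[, "C"] + acgt[, "G"]) / pmax(1, rowSums(acgt))
  ok <- length_nt > 0
  if (!all(ok)) {
    warning(sprintf("%d gene(s) without exonic sequence were excluded",
                    sum(!ok)))
  }

  neuron_cols <- if (!is.null(samples)) {
    samples$sample[samples$lineage == "neuron"]
  } else colnames(counts)
  neuron_cols <- intersect(neuron_cols, colnames(counts))
  if (!length(neuron_cols)) stop_input("no neuron expression columns found")
  expr_cpm <- cpm(counts[, neuron_cols, drop = FALSE])
  expr <- rowMeans(expr_cpm)[genes]
  expr[is.na(expr)] <- 0

  out <- data.frame(gene_id = genes, length = length_nt, gc = gc,
                    expression = as.numeric(expr),
                    stringsAsFactors = FALSE)[ok, ]
  rownames(out) <- NULL
  out
}

#' Sample covariate-matched control gene lists
#'
#' Rejection sampling of control lists statistically indistinguishable from a
#' target list: each candidate draws `|target|` genes uniformly without
#' replacement from `universe \\ target` and is accepted only if a two-sided
#' Wilcoxon rank-sum test against the target list gives p > `alpha_match`
#' for each of the three covariates (length, GC content, expression). The
#' conventional configuration is 100 accepted lists.
#'
#' @param target Character vector: the target gene list.
#' @param universe Character vector: the sampling universe (target genes are
#'   excluded from candidates).
#' @param covariates data.frame from [compute_covariates()] covering target
#'   and universe.
#' @param n_lists Number of accepted lists required (default 100).
#' @param alpha_match Per-covariate Wilcoxon acceptance threshold
#'   (default 0.05).
#' @param max_tries Candidate draws allowed before failing (default
#'   `200 * n_lists`).
#' @param seed RNG seed.
#' @return A `matched_null`: list with `lists` (list of character vectors),
#'   `acceptance_pvalues` (n_lists x 3 matrix), `n_tries`, `alpha_match`,
#'   `seed`.
#' @export
sample_matched_lists <- function(target, universe, covariates,
                                 n_lists = 100L, alpha_match = 0.05,
                                 max_tries = NULL, seed = 1L) {
  if (is.null(max_tries)) max_tries <- 200L * n_lists
  pool <- setdiff(unique(universe), target)
  if (length(pool) < length(target)) {
    stop_input("universe minus target is smaller than the target list")
  }
  rownames(covariates) <- covariates$gene_id
  miss <- setdiff(c(target, pool), covariates$gene_id)
  if (length(miss)) stop_input("covariates missing for %d gene(s) (e.g. %s)",
                               length(miss), miss[1])
  covs <- c("length", "gc", "expression")
  tgt <- as.matrix(covariates[target, covs])

  with_seed(seed, {
    lists <- vector("list", n_lists)
    pvals <- matrix(NA_real_, n_lists, 3L, dimnames = list(NULL, covs))
    reject_by <- c(length = 0L, gc = 0L, expression = 0L)
    accepted <- 0L
    tries <- 0L
    while (accepted < n_lists && tries < max_tries) {
      tries <- tries + 1L
      cand <- sample(pool, length(target))
      cnd <- as.matrix(covariates[cand, covs])
      p <- vapply(covs, function(v) {
        suppressWarnings(wilcox.test(tgt[, v], cnd[, v], exact = FALSE)$p.value)
      }, numeric(1))
      if (all(p > alpha_match)) {
        accepted <- accepted + 1L
        lists[[accepted]] <- cand
        pvals[accepted, ] <- p
      } else {
        worst <- covs[which.min(p)]
        reject_by[worst] <- reject_by[worst] + 1L
      }
    }
    if (accepted < n_lists) {
      stop_input(paste0(
        "matched-list sampling failed: %d/%d lists accepted after %d tries; ",
        "most rejections driven by covariate '%s'"),
        accepted, n_lists, tries, names(which.max(reject_by)))
    }
    structure(list(lists = lists, acceptance_pvalues = pvals,
                   n_tries = tries, alpha_match = alpha_match, seed = seed),
              class = "matched_null")
  })
}

#' @export
print.matched_null <- function(x, ...) {
  cat(sprintf("matched_null: %d lists of %d genes (alpha_match = %g, %d draws)\n",
              length(x$lists), length(x$lists[[1]]), x$alpha_match, x$n_tries))
  invisible(x)
}

#' Per-gene counts of merged binding events
#'
#' @param events Merged events from [merge_consecutive()].
#' @param universe Character vector of genes over which to zero-fill.
#' @return Named integer vector of event counts per gene.
#' @export
events_per_gene <- function(events, universe) {
  cnt <- table(factor(events$target_gene, levels = unique(universe)))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Targeting enrichment of a gene list against matched null lists
#'
#' Compares the mean, median and sum of per-gene predicted binding-event
#' counts on the target list against the same statistics on each
#' covariate-matched control list. Fold enrichment is the observed statistic
#' over the null mean; empirical p-values use the add-one rule.
#'
#' @param events Merged events (optionally pre-filtered with
#'   [filter_events()], e.g. to group-III copies).
#' @param target Character vector: target gene list.
#' @param null A `matched_null` from [sample_matched_lists()].
#' @param statistics Which statistics to report (default mean, median, sum).
#' @return Named list of `enrichment_result`, one per statistic.
#' @export
targeting_enrichment <- function(events, target, null,
                                 statistics = c("mean", "median", "sum")) {
  if (!inherits(null, "matched_null") || !length(null$lists)) {
    stop_input("null must be a non-empty matched_null")
  }
  universe <- unique(c(target, unlist(null$lists), events$target_gene))
  counts <- events_per_gene(events, universe)
  out <- lapply(statistics, function(st) {
    f <- switch(st, mean = mean, median = stats::median, sum = sum,
                stop_input("unknown statistic '%s'", st))
    obs <- f(counts[target])
    nul <- vapply(null$lists, function(g) f(counts[g]), numeric(1))
    new_enrichment_result(obs, nul, n_perm = length(nul), seed = null$seed,
                          statistic = sprintf("targeting %s", st))
  })
  stats::setNames(out, statistics)
}

#' Per-copy targeting contrast between snoRNA families
#'
#' Compares per-copy merged-event counts between SNORD116 and SNORD115
#' copies with a two-sided Wilcoxon rank-sum test, plus the restricted
#' contrast of SNORD116 group III versus SNORD115.
#'
#' @param events Merged events from [merge_consecutive()].
#' @param locus A `locus_model`.
#' @return List with `per_copy` counts, `family_test` and `group3_test`
#'   (each: means per side and the Wilcoxon p-value).
#' @export
family_contrast <- function(events, locus) {
  pc <- events_per_copy(events, locus)$per_copy
  x116 <- pc$n_events[pc$family == "SNORD116"]
  x115 <- pc$n_events[pc$family == "SNORD115"]
  xg3 <- pc$n_events[pc$family == "SNORD116" & pc$group == "III"]
  wt <- function(a, b) {
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  list(
    per_copy = pc,
    family_test = list(mean_snord116 = mean(x116), mean_snord115 = mean(x115),
                       p_value = wt(x116, x115)),
    group3_test = list(mean_group3 = mean(xg3), mean_snord115 = mean(x115),
                       p_value = wt(xg3, x115))
  )
}
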