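#' Hypergeometric over-representation analysis
#'
#' Minimal ORA over user-supplied term-to-gene maps: for each term, the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of term genes in a query of the given size from the universe.
#' `GeneRatio = |query inter term| / |query|`,
#' `BgRatio = |term inter universe| / |universe|`, and
#' `foldEnrichment = GeneRatio / BgRatio`. p-values are Benjamini-Hochberg
#' adjusted across tested terms and results are ordered first by adjusted
#' p-value, then by decreasing fold enrichment. Terms with zero query overlap
#' report p = 1 and fold enrichment 0 (one-sided enrichment convention).
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param universe Character vector, the gene universe.
#' @param terms Named list of character vectors (term id -> gene set), e.g.
#'   from [read_term_map()] or [read_gmt()].
#' @param min_term_size Terms with fewer universe genes are skipped
#'   (default 2; degenerate hypergeometric cells).
#' @param q_cutoff Optional padj cutoff applied to the returned table
#'   (default `NULL`, return all tested terms).
#' @return data.frame: `term`, `overlap`, `term_size`, `GeneRatio`,
#'   `BgRatio`, `foldEnrichment`, `pvalue`, `padj`.
#' @export
hypergeom_ora <- function(query, universe, terms, min_term_size = 2L,
                          q_cutoff = NULL) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(query) || !length(universe)) stop_input("empty query or universe")
  bad <- setdiff(query, universe)
  if (length(bad)) stop_input("query contains genes outside universe (e.g. %s)",
                              bad[1])
  N <- length(universe)
  q <- length(query)

  term_genes <- lapply(terms, function(g) intersect(unique(g), universe))
  keep <- lengths(term_genes) >= min_term_size
  term_genes <- term_genes[keep]
  if (!length(term_genes)) {
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), GeneRatio = numeric(0),
                      BgRatio = numeric(0), foldEnrichment = numeric(0),
                      pvalue = numeric(0), padj = numeric(0)))
  }

  K <- lengths(term_genes)
  k <- vapply(term_genes, function(g) length(intersect(g, query)), integer(1))
  p <- phyper(k - 1L, K, N - K, q, lower.tail = FALSE)
  gene_ratio <- k / q
  bg_ratio <- K / N
  fe <- ifelse(k == 0L, 0, gene_ratio / bg_ratio)

  res <- data.frame(
    term = names(term_genes),
    overlap = k,
    term_size = K,
    GeneRatio = gene_ratio,
    BgRatio = bg_ratio,
    foldEnrichment = fe,
    pvalue = p,
    padj = p.adjust(p, method = "BH"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$padj, -res$foldEnrichment, res$term), ]
  rownames(res) <- NULL
  if (!is.null(q_cutoff)) res <- res[res$padj < q_cutoff, ]
  res
}

#' Read a two-column term-to-gene map
#'
#' @param path TSV with columns `term` and `gene` (header optional; detected).
#' @return Named list of character vectors.
#' @export
read_term_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- identical(strsplit(first, "\t")[[1]][1:2], c("term", "gene"))
  tab <- if (has_header) {
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("term", "gene"))
  }
  split(tab$gene, tab$term)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors; descriptions kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop_input("malformed GMT line %d (need name, description, >=1 gene)",
                              bad[1])
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}
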