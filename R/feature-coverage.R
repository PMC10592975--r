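#' Select high-confidence basic transcripts
#'
#' Restricts an annotation to transcripts with a transcript support level of
#' 1-3 and the GENCODE "basic" tag — the transcript set used for genomic
#' feature coverage.
#'
#' @param annotation An `annotation`.
#' @param warn Warn about genes losing all transcripts (default TRUE).
#' @return Character vector of retained transcript ids.
#' @export
select_transcripts <- function(annotation, warn = TRUE) {
  tx <- ann_subset(annotation, "transcript")
  mc <- S4Vectors::mcols(tx)
  keep <- !is.na(mc$tsl) & mc$tsl %in% 1:3 & !is.na(mc$basic) & mc$basic
  kept_genes <- unique(mc$gene_id[keep])
  lost <- setdiff(unique(mc$gene_id), kept_genes)
  if (warn && length(lost)) {
    warning(sprintf("%d gene(s) have no TSL 1-3 basic transcript and are dropped",
                    length(lost)))
  }
  mc$transcript_id[keep]
}

# Disjoint per-bp category ranges for one gene set, priority
# junction > utr5 > utr3 > cds > other_exon > intron.
category_ranges <- function(annotation, gene_set, transcripts,
                            junction_width = 2L) {
  get <- function(type, utr_kind = NULL) {
    gr <- ann_subset(annotation, type, tx_ids = transcripts,
                     gene_ids = gene_set)
    if (!is.null(utr_kind)) {
      gr <- gr[S4Vectors::mcols(gr)$utr_kind == utr_kind]
    }
    gr
  }
  exons <- get("exon")
  if (!length(exons)) stop_input("no exons for the gene set after filtering")

  by_gene <- S4Vectors::split(exons, S4Vectors::mcols(exons)$gene_id)
  red_exons <- unlist(GenomicRanges::reduce(by_gene))
  spans <- unlist(range(by_gene))
  introns <- GenomicRanges::setdiff(spans, red_exons, ignore.strand = FALSE)

  # internal exon/intron boundaries: +/- J nt around each splice site
  ex_by_gene <- GenomicRanges::reduce(by_gene)
  junc <- lapply(seq_along(ex_by_gene), function(i) {
    ex <- ex_by_gene[[i]]
    if (length(ex) < 2L) return(GenomicRanges::GRanges())
    s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
    # boundary after exon end (donor side) and before exon start (acceptor)
    bpos <- sort(c(e[-length(e)], s[-1] - 1L))  # base 5' of each boundary
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(ex)[1],
      ranges = IRanges::IRanges(start = bpos - junction_width + 1L,
                                end = bpos + junction_width),
      strand = GenomicRanges::strand(ex)[1]
    )
  })
  junc <- GenomicRanges::reduce(do.call(c, junc))

  utr5 <- GenomicRanges::reduce(get("UTR", "five_prime"))
  utr3 <- GenomicRanges::reduce(get("UTR", "three_prime"))
  cds <- GenomicRanges::reduce(get("CDS"))

  sub <- function(a, b) GenomicRanges::setdiff(a, b, ignore.strand = FALSE)
  taken <- junc
  utr5_d <- sub(utr5, taken); taken <- GenomicRanges::union(taken, utr5)
  utr3_d <- sub(utr3, taken); taken <- GenomicRanges::union(taken, utr3)
  cds_d <- sub(cds, taken); taken <- GenomicRanges::union(taken, cds)
  other_d <- sub(red_exons, taken)
  intron_d <- sub(introns, junc)

  list(junction = junc, utr5 = utr5_d, utr3 = utr3_d, cds = cds_d,
       other_exon = other_d, intron = intron_d)
}

compose <- function(counts) {
  counts <- as.numeric(counts)
  names(counts) <- c("utr5", "utr3", "cds", "other_exon", "intron", "junction")
  exon_total <- sum(counts[c("utr5", "utr3", "cds", "other_exon")])
  top <- c(exon = exon_total, intron = counts[["intron"]],
           junction = counts[["junction"]])
  top_frac <- if (sum(top) > 0) top / sum(top) else top
  exon_parts <- counts[c("utr5", "utr3", "cds", "other_exon")]
  exon_frac <- if (exon_total > 0) exon_parts / exon_total else exon_parts
  structure(
    list(counts = counts, top_fractions = top_frac,
         exon_fractions = exon_frac),
    class = "feature_composition"
  )
}

#' @export
print.feature_composition <- function(x, ...) {
  cat("feature composition\n  top level: ",
      paste(sprintf("%s %.3f", names(x$top_fractions), x$top_fractions),
            collapse = ", "), "\n  exon split: ",
      paste(sprintf("%s %.3f", names(x$exon_fractions), x$exon_fractions),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-nucleotide feature composition of a gene set
#'
#' Counts, over the union of the selected transcripts of a gene set, the
#' nucleotides falling in each feature category with fixed priority
#' junction > 5'UTR > 3'UTR > CDS > other exon > intron. Junctions are
#' `junction_width` nt on each side of every internal exon/intron boundary.
#' Fractions are normalized at the top level among {exon, intron, junction}
#' and, within exon, among {5'UTR, 3'UTR, CDS, other exon}.
#'
#' @param gene_set Character vector of gene ids.
#' @param annotation An `annotation`.
#' @param transcripts Transcript ids to use (default
#'   [select_transcripts()]).
#' @param junction_width Half-width J of the junction zone in nt (default 2).
#' @return A `feature_composition` (bp counts + fractions).
#' @export
background_composition <- function(gene_set, annotation,
                                   transcripts = select_transcripts(annotation,
                                                                    warn = FALSE),
                                   junction_width = 2L) {
  if (!length(gene_set)) stop_input("empty gene set")
  cat_gr <- category_ranges(annotation, gene_set, transcripts, junction_width)
  bp <- vapply(cat_gr[c("utr5", "utr3", "cds", "other_exon", "intron",
                        "junction")],
               function(gr) sum(GenomicRanges::width(gr)), numeric(1))
  compose(bp)
}

#' Feature composition of merged binding events
#'
#' Assigns one feature category to each merged binding event. With
#' `assign = "overlap"` (the tool convention) an event takes the
#' highest-priority category it overlaps (junction > 5'UTR > 3'UTR > CDS >
#' other exon > intron), so any event spanning an exon/intron boundary is
#' junctional. With `assign = "center"` the event takes the category of the
#' nucleotide at its midpoint, which makes the composition converge to the
#' per-bp background composition for uniformly placed events. Events
#' overlapping no selected transcript are reported as `intergenic`.
#'
#' @param events Merged events from [merge_consecutive()].
#' @param gene_set Gene set defining the background feature space.
#' @param annotation An `annotation`.
#' @param transcripts Transcript ids (default [select_transcripts()]).
#' @param junction_width Junction half-width J in nt (default 2).
#' @param assign `"overlap"` (default) or `"center"`.
#' @return List with `composition` (a `feature_composition` over events),
#'   `n_intergenic`, `assignments` (per-event category) and
#'   `enrichment_ratio` (event fraction / background fraction per category,
#'   top level and exon split).
#' @export
event_composition <- function(events, gene_set, annotation,
                              transcripts = select_transcripts(annotation,
                                                               warn = FALSE),
                              junction_width = 2L,
                              assign = c("overlap", "center")) {
  assign <- match.arg(assign)
  cat_gr <- category_ranges(annotation, gene_set, transcripts, junction_width)
  priority <- c("junction", "utr5", "utr3", "cds", "other_exon", "intron")

  if (!nrow(events)) stop_input("empty event set")
  ev_gr <- GenomicRanges::GRanges(
    seqnames = events$target_chrom,
    ranges = IRanges::IRanges(start = events$target_start + 1L,
                              end = events$target_end),
    strand = events$strand
  )
  if (assign == "center") {
    mid <- floor((events$target_start + events$target_end - 1L) / 2) + 1L
    ev_gr <- GenomicRanges::GRanges(
      seqnames = events$target_chrom,
      ranges = IRanges::IRanges(start = mid, width = 1L),
      strand = events$strand
    )
  }

  cat_assign <- rep("intergenic", length(ev_gr))
  for (cat in rev(priority)) {
    hit <- IRanges::overlapsAny(ev_gr, cat_gr[[cat]], ignore.strand = FALSE)
    cat_assign[hit] <- cat
  }

  tab <- table(factor(cat_assign, levels = c("utr5", "utr3", "cds",
                                             "other_exon", "intron",
                                             "junction", "intergenic")))
  comp <- compose(tab[1:6])
  bg <- background_composition(gene_set, annotation, transcripts,
                               junction_width)
  ratio_top <- ifelse(bg$top_fractions > 0,
                      comp$top_fractions / bg$top_fractions, NA_real_)
  ratio_exon <- ifelse(bg$exon_fractions > 0,
                       comp$exon_fractions / bg$exon_fractions, NA_real_)
  list(
    composition = comp,
    n_intergenic = as.integer(tab[["intergenic"]]),
    assignments = cat_assign,
    enrichment_ratio = list(top = ratio_top, exon = ratio_exon),
    background = bg
  )
}
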