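#' Generate a synthetic GENCODE-style gene annotation
#'
#' Builds a multi-gene annotation on a pseudo-chromosome (`chrS`) with the
#' feature types the pipeline consumes: `gene`, `transcript`, `exon`, `CDS`
#' and `UTR` records, GENCODE-style `transcript_support_level` (1-5 or NA)
#' and `tag "basic"` flags, genes on both strands, and a genome sequence with
#' gene-specific GC content so that per-gene GC and merged-exonic length are
#' computable. A fraction of genes carry a second, noncoding transcript.
#'
#' @param config A [sim_config()].
#' @return An `annotation` object: list with `features`
#'   (a [GenomicRanges::GRanges] with metadata columns `type`, `gene_id`,
#'   `transcript_id`, `tsl`, `basic`, `utr_kind`) and `genome`
#'   (a [Biostrings::DNAStringSet] holding `chrS`).
#' @export
gen_annotation <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "annotation"), {
    n <- config$n_genes
    rows <- vector("list", n)
    seqs <- character(n)
    gaps <- character(n)
    cursor <- 1L

    for (i in seq_len(n)) {
      gid <- sprintf("GSYN%04d", i)
      strand <- sample(c("+", "-"), 1L)
      n_exons <- sample(1:6, 1L, prob = c(0.15, 0.25, 0.25, 0.15, 0.12, 0.08))
      exon_w <- sample(80:400, n_exons, replace = TRUE)
      intron_w <- if (n_exons > 1L) sample(200:1500, n_exons - 1L, replace = TRUE) else integer(0)

      starts <- cursor + cumsum(c(0L, head(exon_w, -1L) + intron_w))
      ends <- starts + exon_w - 1L
      gene_start <- starts[1L]; gene_end <- ends[n_exons]

      coding <- runif(1) < config$frac_coding && sum(exon_w) >= 300L
      tx1 <- sprintf("%s.t1", gid)
      tsl1 <- sample(c(1:5, NA_integer_), 1L,
                     prob = c(0.35, 0.2, 0.15, 0.1, 0.1, 0.1))
      basic1 <- runif(1) < 0.85

      fs <- c(gene_start, gene_start, starts)
      fe <- c(gene_end, gene_end, ends)
      ft <- c("gene", "transcript", rep("exon", n_exons))
      ftx <- c(NA_character_, rep(tx1, n_exons + 1L))
      ftsl <- c(NA_integer_, rep(tsl1, n_exons + 1L))
      fbasic <- c(NA, rep(basic1, n_exons + 1L))
      futr <- rep(NA_character_, n_exons + 2L)

      if (coding) {
        mrna_len <- sum(exon_w)
        u5 <- sample(20:min(150L, max(20L, (mrna_len - 60L) %/% 3L)), 1L)
        u3 <- sample(50:min(300L, max(50L, (mrna_len - 60L) %/% 3L)), 1L)
        if (u5 + u3 + 60L > mrna_len) { u5 <- 20L; u3 <- 50L }
        cds_iv <- mrna_to_genomic(starts, ends, strand, u5 + 1L, mrna_len - u3)
        u5_iv <- mrna_to_genomic(starts, ends, strand, 1L, u5)
        u3_iv <- mrna_to_genomic(starts, ends, strand, mrna_len - u3 + 1L, mrna_len)
        nn <- lengths(list(cds_iv$start, u5_iv$start, u3_iv$start))
        fs <- c(fs, cds_iv$start, u5_iv$start, u3_iv$start)
        fe <- c(fe, cds_iv$end, u5_iv$end, u3_iv$end)
        ft <- c(ft, rep(c("CDS", "UTR", "UTR"), nn))
        ftx <- c(ftx, rep(tx1, sum(nn)))
        ftsl <- c(ftsl, rep(tsl1, sum(nn)))
        fbasic <- c(fbasic, rep(basic1, sum(nn)))
        futr <- c(futr, rep(c(NA_character_, "five_prime", "three_prime"), nn))
      }

      # occasional second (noncoding) isoform dropping one terminal exon
      if (n_exons >= 3L && runif(1) < 0.2) {
        tx2 <- sprintf("%s.t2", gid)
        tsl2 <- sample(c(1:5, NA_integer_), 1L,
                       prob = c(0.2, 0.2, 0.2, 0.15, 0.15, 0.1))
        basic2 <- runif(1) < 0.6
        keep <- if (runif(1) < 0.5) 2:n_exons else 1:(n_exons - 1L)
        nk <- length(keep)
        fs <- c(fs, starts[keep][1L], starts[keep])
        fe <- c(fe, ends[keep][nk], ends[keep])
        ft <- c(ft, "transcript", rep("exon", nk))
        ftx <- c(ftx, rep(tx2, nk + 1L))
        ftsl <- c(ftsl, rep(tsl2, nk + 1L))
        fbasic <- c(fbasic, rep(basic2, nk + 1L))
        futr <- c(futr, rep(NA_character_, nk + 1L))
      }

      rows[[i]] <- list(start = fs, end = fe, type = ft, tx = ftx,
                        tsl = ftsl, basic = fbasic, utr_kind = futr,
                        gene_id = rep(gid, length(fs)),
                        strand = rep(strand, length(fs)))

      gc <- runif(1, 0.35, 0.65)
      span <- gene_end - gene_start + 1L
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), span, replace = TRUE,
                              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                       collapse = "")
      gap <- sample(500:2000, 1L)
      gaps[i] <- strrep("A", gap)
      cursor <- gene_end + gap + 1L
    }

    tab <- lapply(stats::setNames(nm = names(rows[[1]])), function(col) {
      unlist(lapply(rows, `[[`, col), use.names = FALSE)
    })
    gr <- GenomicRanges::GRanges(
      seqnames = "chrS",
      ranges = IRanges::IRanges(start = tab$start, end = tab$end),
      strand = tab$strand
    )
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = tab$type, gene_id = tab$gene_id, transcript_id = tab$tx,
      tsl = tab$tsl, basic = tab$basic, utr_kind = tab$utr_kind
    )
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(paste0(seqs, gaps), collapse = ""), "chrS")
    )
    new_annotation(gr, genome)
  })
}

# Map an mRNA interval [a, b] (1-based, 5'->3') onto genomic exon intervals.
mrna_to_genomic <- function(starts, ends, strand, a, b) {
  w <- ends - starts + 1L
  ord <- if (strand == "+") seq_along(starts) else rev(seq_along(starts))
  cum <- cumsum(w[ord])
  off <- c(0L, head(cum, -1L))
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(ord)) {
    lo <- max(a, off[k] + 1L); hi <- min(b, cum[k])
    if (lo > hi) next
    i <- ord[k]
    if (strand == "+") {
      gs <- starts[i] + (lo - off[k] - 1L); ge <- starts[i] + (hi - off[k] - 1L)
    } else {
      ge <- ends[i] - (lo - off[k] - 1L); gs <- ends[i] - (hi - off[k] - 1L)
    }
    out_s <- c(out_s, gs); out_e <- c(out_e, ge)
  }
  o <- order(out_s)
  list(start = out_s[o], end = out_e[o])
}

new_annotation <- function(features, genome = NULL) {
  stopifnot(methods::is(features, "GRanges"))
  need <- c("type", "gene_id", "transcript_id", "tsl", "basic", "utr_kind")
  miss <- setdiff(need, colnames(S4Vectors::mcols(features)))
  if (length(miss)) stop_input("annotation missing columns: %s",
                               paste(miss, collapse = ", "))
  structure(list(features = features, genome = genome), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  tt <- table(S4Vectors::mcols(x$features)$type)
  cat("annotation:", sum(tt[names(tt) == "gene"]), "genes,",
      sum(tt[names(tt) == "transcript"]), "transcripts,",
      sum(tt[names(tt) == "exon"]), "exons",
      if (!is.null(x$genome)) sprintf("(+ genome, %d bp)",
                                      sum(Biostrings::width(x$genome))) else "",
      "\n")
  invisible(x)
}

# Convenience accessors -------------------------------------------------

ann_subset <- function(ann, type, tx_ids = NULL, gene_ids = NULL) {
  mc <- S4Vectors::mcols(ann$features)
  keep <- mc$type == type
  if (!is.null(tx_ids)) keep <- keep & mc$transcript_id %in% tx_ids
  if (!is.null(gene_ids)) keep <- keep & mc$gene_id %in% gene_ids
  ann$features[keep]
}

#' Gene identifiers of an annotation
#' @param ann An `annotation` object.
#' @return Character vector of gene ids.
#' @export
ann_gene_ids <- function(ann) {
  mc <- S4Vectors::mcols(ann$features)
  unique(mc$gene_id[mc$type == "gene"])
}
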