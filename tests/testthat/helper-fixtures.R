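# Small shared fixtures built in code.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 120L, n_replicates = 3L,
                   planted_shared_up = 5L, planted_shared_down = 4L,
                   planted_background_specific = 12L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Hand-built two-gene annotation with known structure, for interval
# arithmetic tests. Gene GPLUS (+): exons [101,150] and [201,250] 1-based
# (0-based [100,150) + [200,250)), CDS/UTRs set; gene GMINUS (-):
# single exon, noncoding.
manual_annotation <- function(genome_len = 400L, seq_letters = NULL) {
  df <- data.frame(
    start = c(101L, 101L, 101L, 201L, 121L, 201L, 101L, 231L,
              301L, 301L, 301L),
    end = c(250L, 250L, 150L, 250L, 150L, 230L, 120L, 250L,
            360L, 360L, 360L),
    type = c("gene", "transcript", "exon", "exon", "CDS", "CDS", "UTR", "UTR",
             "gene", "transcript", "exon"),
    gene_id = c(rep("GPLUS", 8), rep("GMINUS", 3)),
    tx = c(NA, rep("GPLUS.t1", 7), NA, rep("GMINUS.t1", 2)),
    strand = c(rep("+", 8), rep("-", 3)),
    tsl = c(NA, rep(1L, 7), NA, rep(2L, 2)),
    basic = c(NA, rep(TRUE, 7), NA, rep(TRUE, 2)),
    utr_kind = c(rep(NA, 6), "five_prime", "three_prime", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  gr <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, gene_id = df$gene_id, transcript_id = df$tx,
    tsl = df$tsl, basic = df$basic, utr_kind = df$utr_kind
  )
  if (is.null(seq_letters)) {
    seq_letters <- paste(rep("ACGT", ceiling(genome_len / 4)), collapse = "")
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(substr(seq_letters, 1, genome_len), "chrS")
  )
  ann <- list(features = gr, genome = genome)
  class(ann) <- "annotation"
  ann
}
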