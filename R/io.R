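# Readers and writers for the pipeline's file formats. Genomic coordinates
# are GTF 1-based closed on disk for GTF, 0-based half-open for windows /
# events / BED; in memory genomic intervals live in GRanges (1-based closed).

#' Read a GENCODE-dialect GTF annotation
#'
#' Parses a GTF file via rtracklayer and assembles the internal annotation
#' object. `transcript_support_level` and the `basic` tag are parsed; UTR
#' records are classified as five_prime/three_prime by their position
#' relative to the transcript's CDS (strand-aware).
#'
#' @param path GTF file path.
#' @param genome Optional [Biostrings::DNAStringSet] to attach.
#' @return An `annotation` object.
#' @export
read_gtf <- function(path, genome = NULL) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1]]
    stop_input("malformed GTF line %d in %s (expected 9 tab-separated fields)",
               bad, path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  tsl_raw <- if ("transcript_support_level" %in% colnames(mc)) {
    as.character(mc$transcript_support_level)
  } else rep(NA_character_, length(gr))
  tsl <- suppressWarnings(as.integer(tsl_raw))
  basic <- if ("tag" %in% colnames(mc)) {
    !is.na(mc$tag) & mc$tag == "basic"
  } else rep(FALSE, length(gr))
  basic[mc$type %in% c("gene")] <- NA

  utr_kind <- rep(NA_character_, length(gr))
  is_utr <- as.character(mc$type) == "UTR"
  if (any(is_utr)) {
    cds_idx <- which(as.character(mc$type) == "CDS")
    cds_by_tx <- split(cds_idx, mc$transcript_id[cds_idx])
    for (i in which(is_utr)) {
      tx <- mc$transcript_id[i]
      ci <- cds_by_tx[[tx]]
      if (is.null(ci)) next
      cds_min <- min(GenomicRanges::start(gr)[ci])
      cds_max <- max(GenomicRanges::end(gr)[ci])
      before <- GenomicRanges::end(gr)[i] < cds_min
      plus <- as.character(GenomicRanges::strand(gr))[i] != "-"
      utr_kind[i] <- if (xor(before, plus)) "three_prime" else "five_prime"
    }
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr)
  )
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = as.character(mc$type),
    gene_id = mc$gene_id,
    transcript_id = if ("transcript_id" %in% colnames(mc)) mc$transcript_id
      else NA_character_,
    tsl = tsl,
    basic = basic,
    utr_kind = utr_kind
  )
  new_annotation(out, genome)
}

#' Write an annotation as GENCODE-dialect GTF
#'
#' Emits 1-based closed GTF with `gene_id`, `transcript_id`,
#' `transcript_support_level` and `tag "basic"` attributes. Output is
#' deterministic (byte-identical for identical annotations).
#'
#' @param annotation An `annotation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(annotation, path) {
  gr <- annotation$features
  mc <- S4Vectors::mcols(gr)
  attrs <- vapply(seq_along(gr), function(i) {
    a <- sprintf('gene_id "%s";', mc$gene_id[i])
    if (!is.na(mc$transcript_id[i])) {
      a <- paste(a, sprintf('transcript_id "%s";', mc$transcript_id[i]))
      tslv <- if (is.na(mc$tsl[i])) "NA" else as.character(mc$tsl[i])
      a <- paste(a, sprintf('transcript_support_level "%s";', tslv))
      if (!is.na(mc$basic[i]) && mc$basic[i]) a <- paste(a, 'tag "basic";')
    }
    a
  }, character(1))
  lines <- sprintf(
    "%s\tsnotarget\t%s\t%d\t%d\t.\t%s\t%s\t%s",
    as.character(GenomicRanges::seqnames(gr)),
    as.character(mc$type),
    GenomicRanges::start(gr),
    GenomicRanges::end(gr),
    as.character(GenomicRanges::strand(gr)),
    ifelse(as.character(mc$type) == "CDS", "0", "."),
    attrs
  )
  writeLines(c("## coordinates: 1-based, closed (GTF)", lines), path)
  invisible(path)
}

write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}

#' Read / write sliding-window interaction tables
#'
#' snoGloBe-style TSV with 0-based half-open window coordinates on both the
#' snoRNA copy and the target genome.
#'
#' @param path File path.
#' @return data.frame in the [gen_windows()] schema.
#' @export
read_windows <- function(path) {
  tab <- read_tsv(path)
  need <- c("sno_id", "sno_window_start", "sno_window_end", "target_gene",
            "target_chrom", "target_window_start", "target_window_end",
            "strand", "score")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop_input("windows file missing column(s): %s",
                               paste(miss, collapse = ", "))
  if (nrow(tab) && (any(tab$score < 0) || any(tab$score > 1))) {
    stop_input("window scores outside [0, 1]")
  }
  tab
}

#' @rdname read_windows
#' @param windows data.frame in the [gen_windows()] schema.
#' @export
write_windows <- function(windows, path) {
  write_tsv(windows, path,
            comment = "window coordinates: 0-based, half-open")
}

#' Write merged binding events as BED6
#'
#' Target spans as 0-based half-open BED intervals, `name` = snoRNA copy id,
#' `score` = `round(1000 * min_score)`.
#'
#' @param events Merged events from [merge_consecutive()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events_bed <- function(events, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   events$target_chrom, events$target_start,
                   events$target_end, events$sno_id,
                   as.integer(round(1000 * events$min_score)),
                   events$strand)
  writeLines(c("# BED6; coordinates: 0-based, half-open", lines), path)
  invisible(path)
}

#' Read / write count matrices and sample sheets
#'
#' @param path File path.
#' @return `read_counts`: genes x samples integer matrix.
#' @export
read_counts <- function(path) {
  tab <- read_tsv(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' @rdname read_counts
#' @param counts Genes x samples matrix with rownames.
#' @export
write_counts <- function(counts, path) {
  write_tsv(data.frame(gene_id = rownames(counts), counts,
                       check.names = FALSE),
            path, comment = "raw counts, genes x samples")
}

#' Read / write differential-expression result tables
#'
#' @param path File path.
#' @param contrast,background,design Labels attached on read (see
#'   [de_result_table()]).
#' @return `read_de_table`: a `de_result_table`.
#' @export
read_de_table <- function(path, contrast, background = "pooled",
                          design = "background_condition") {
  de_result_table(read_tsv(path), contrast = contrast,
                  background = background, design = design)
}

#' @rdname read_de_table
#' @param tab A `de_result_table`.
#' @export
write_de_table <- function(tab, path) {
  write_tsv(as.data.frame(tab), path,
            comment = sprintf("contrast=%s background=%s design=%s",
                              attr(tab, "contrast"), attr(tab, "background"),
                              attr(tab, "design")))
}
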