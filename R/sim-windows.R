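#' Simulate sliding-window interaction predictions
#'
#' Emulates the output of a sliding-window snoRNA-target interaction
#' predictor. Two strata are generated: (i) isolated background noise windows
#' placed uniformly over gene bodies with scores uniform on [0, 1] — these do
#' not form consecutive runs; and (ii) planted binding events: runs of >= 3
#' consecutive windows (1-nt steps on both molecules, antiparallel) with
#' scores >= 0.98, whose per-gene rate is `event_rate` on background genes
#' and `event_rate * targeting_enrichment_fold` on `target_set` genes. Event
#' placement on the target is biased into annotated 5'UTRs with probability
#' `w5 / (1 + w5)`; the snoRNA-side window center of events attributed to
#' group-III copies is biased into the ASE2 element with probability
#' `wa / (1 + wa)`. Copies are drawn with the per-group weights in
#' `config$copy_weights`.
#'
#' @param locus A `locus_model` from [build_locus_fixture()].
#' @param annotation An `annotation` from [gen_annotation()].
#' @param target_set Character vector of target genes (subset of annotation).
#' @param config A [sim_config()].
#' @return data.frame in snoGloBe-style schema: `sno_id`,
#'   `sno_window_start`, `sno_window_end` (0-based half-open on the copy),
#'   `target_gene`, `target_chrom`, `target_window_start`,
#'   `target_window_end` (0-based half-open genomic), `strand`, `score`.
#'   The planted event table is attached as attribute `"planted"` (columns
#'   `gene_id`, `sno_id`, `in_utr5`, `in_ase2`).
#' @export
gen_windows <- function(locus, annotation, target_set, config) {
  validate_sim_config(config)
  genes <- ann_gene_ids(annotation)
  bad <- setdiff(target_set, genes)
  if (length(bad)) stop_input("target gene(s) absent from annotation: %s",
                              paste(head(bad, 3), collapse = ", "))
  L <- config$window_length

  gene_gr <- ann_subset(annotation, "gene")
  gidx <- match(genes, S4Vectors::mcols(gene_gr)$gene_id)
  gene_start <- GenomicRanges::start(gene_gr)[gidx]
  gene_end <- GenomicRanges::end(gene_gr)[gidx]
  gene_chrom <- as.character(GenomicRanges::seqnames(gene_gr))[gidx]
  gene_strand <- as.character(GenomicRanges::strand(gene_gr))[gidx]

  utr5 <- ann_subset(annotation, "UTR")
  utr5 <- utr5[S4Vectors::mcols(utr5)$utr_kind == "five_prime"]
  utr5_start <- GenomicRanges::start(utr5)
  utr5_width <- GenomicRanges::width(utr5)
  utr5_by_gene <- split(seq_along(utr5), S4Vectors::mcols(utr5)$gene_id)

  cp <- locus$copies
  grp <- ifelse(cp$family == "SNORD115", "SNORD115", cp$group)
  copy_w <- config$copy_weights[grp]

  with_seed(derive_seed(config$seed, "windows"), {
    p5 <- if (is.infinite(config$utr5_bias_weight)) 1 else
      config$utr5_bias_weight / (1 + config$utr5_bias_weight)
    pa <- if (is.infinite(config$ase2_bias_weight)) 1 else
      config$ase2_bias_weight / (1 + config$ase2_bias_weight)

    # --- background noise windows (isolated, any score) ---
    n_noise <- rpois(1L, config$noise_windows_per_gene * length(genes))
    noise <- NULL
    if (n_noise > 0L) {
      gi <- sample.int(length(genes), n_noise, replace = TRUE)
      span <- pmax(gene_end[gi] - gene_start[gi] - L, 1L)
      t0 <- as.integer(gene_start[gi] - 1L + floor(runif(n_noise) * span))  # 0-based
      ci <- sample.int(nrow(cp), n_noise, replace = TRUE, prob = copy_w)
      s0 <- as.integer(floor(runif(n_noise) * (cp$length[ci] - L + 1L)))
      noise <- data.frame(
        sno_id = cp$copy_id[ci],
        sno_window_start = s0, sno_window_end = s0 + L,
        target_gene = genes[gi], target_chrom = gene_chrom[gi],
        target_window_start = t0, target_window_end = t0 + L,
        strand = gene_strand[gi],
        score = runif(n_noise),
        stringsAsFactors = FALSE
      )
    }

    # --- planted events ---
    rate <- rep(config$event_rate, length(genes))
    rate[genes %in% target_set] <- rate[genes %in% target_set] *
      config$targeting_enrichment_fold
    n_ev <- rpois(length(genes), rate)
    ev_gene <- rep.int(seq_along(genes), n_ev)
    total <- length(ev_gene)

    ev_tab <- NULL
    planted <- data.frame(gene_id = character(0), sno_id = character(0),
                          in_utr5 = logical(0), in_ase2 = logical(0))
    if (total) {
      gi <- ev_gene
      nw <- 3L + rpois(total, 1)
      run_len <- nw + L - 1L

      # target placement: 5'UTR-biased or uniform over the gene body
      has_u5 <- genes[gi] %in% names(utr5_by_gene)
      use_u5 <- has_u5 & runif(total) < p5
      span <- pmax(gene_end[gi] - gene_start[gi] - run_len, 1L)
      t0 <- as.integer(gene_start[gi] - 1L + floor(runif(total) * span))
      if (any(use_u5)) {
        for (e in which(use_u5)) {
          u5 <- utr5_by_gene[[genes[gi[e]]]]
          j <- if (length(u5) > 1L) sample(u5, 1L) else u5
          ctr <- utr5_start[j] + floor(runif(1) * utr5_width[j]) - 1L  # 0-based
          t0[e] <- as.integer(ctr - run_len[e] %/% 2L)
        }
      }
      t0 <- pmax(t0, 0L)

      # copy choice and snoRNA-side placement
      ci <- sample.int(nrow(cp), total, replace = TRUE, prob = copy_w)
      len <- cp$length[ci]
      is_g3 <- !is.na(cp$group[ci]) & cp$group[ci] == "III"
      use_a2 <- is_g3 & runif(total) < pa
      # default: uniform window start on the copy
      s_hi <- as.integer(floor(runif(total) * (len - L + 1L)))
      # ASE2-biased: place the run so the merged sno span (width nw + L - 1)
      # centers on a point in ASE2: span center = s_hi + (L + 1 - nw) / 2
      ctr_s <- as.integer(cp$ase2_start[ci] +
        floor(runif(total) * (cp$ase2_end[ci] - cp$ase2_start[ci])))
      s_hi[use_a2] <- (ctr_s - (L + 1L - nw) %/% 2L)[use_a2]
      # antiparallel duplex: sno start decreases as target start increases
      # (on + strand targets); clamp so the whole run stays on the copy
      s_hi <- pmin(pmax(s_hi, nw - 1L), len - L)

      fwd <- gene_strand[gi] == "+"
      # expand each event to its nw windows
      ei <- rep.int(seq_len(total), nw)
      off <- sequence(nw)  # 1..nw within each event
      sno_starts <- as.integer(ifelse(fwd[ei], s_hi[ei] - off + 1L,
                                      s_hi[ei] - nw[ei] + off))
      ev_tab <- data.frame(
        sno_id = cp$copy_id[ci][ei],
        sno_window_start = sno_starts,
        sno_window_end = sno_starts + L,
        target_gene = genes[gi][ei], target_chrom = gene_chrom[gi][ei],
        target_window_start = t0[ei] + off - 1L,
        target_window_end = t0[ei] + off - 1L + L,
        strand = gene_strand[gi][ei],
        score = runif(length(ei), 0.98, 1),
        stringsAsFactors = FALSE
      )
      planted <- data.frame(
        gene_id = genes[gi], sno_id = cp$copy_id[ci],
        in_utr5 = use_u5, in_ase2 = use_a2, stringsAsFactors = FALSE
      )
    }

    out <- rbind(noise, ev_tab)
    if (is.null(out)) out <- data.frame(
      sno_id = character(0), sno_window_start = integer(0),
      sno_window_end = integer(0), target_gene = character(0),
      target_chrom = character(0), target_window_start = integer(0),
      target_window_end = integer(0), strand = character(0),
      score = numeric(0), stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "planted") <- planted
    out
  })
}
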