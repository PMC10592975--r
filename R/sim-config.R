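#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. The defaults describe the
#' study conditions the pipeline is validated under: a final consensus list of
#' 42 planted genes shared across both genetic backgrounds and both deletion
#' models (22 up, 20 down), additional background-specific false leads, a
#' 2.5-fold planted targeting enrichment on the shared list, a strong 5'UTR
#' placement bias of binding events and a strong ASE2 bias of group-III
#' snoRNA-side binding centers.
#'
#' @param n_genes Number of simulated genes.
#' @param n_replicates Replicates per (background, condition, lineage) cell.
#' @param nb_dispersion Median negative-binomial dispersion; gene-wise
#'   dispersions are drawn log-normally around it.
#' @param planted_shared_up,planted_shared_down Numbers of genes up/down
#'   regulated in both backgrounds and both deletion models (the consensus
#'   truth set).
#' @param planted_background_specific Number of genes dysregulated in only one
#'   background (and one deletion model) — the spurious DEGs that consensus
#'   calling must remove.
#' @param lfc_magnitude Planted |log2 fold change|.
#' @param targeting_enrichment_fold Ratio of binding-event rate on the planted
#'   consensus genes to the background rate.
#' @param utr5_bias_weight Odds weight `w` for placing a planted event inside
#'   a 5'UTR: probability `w / (1 + w)`; `Inf` forces all events into 5'UTRs.
#' @param ase2_bias_weight Odds weight for centering the snoRNA-side window of
#'   group-III copy events inside ASE2; same `w / (1 + w)` convention.
#' @param window_length Sliding-window length L in nt (snoGloBe convention
#'   default 13).
#' @param event_rate Mean number of planted binding events per background gene.
#' @param noise_windows_per_gene Mean number of isolated noise windows per gene.
#' @param copy_weights Named numeric: relative per-copy event rates for
#'   SNORD116 groups I/II/III and SNORD115.
#' @param frac_coding Fraction of simulated genes that are protein coding.
#' @param seed Master seed; fully determines all generator output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_replicates = 3L,
                       nb_dispersion = 0.05,
                       planted_shared_up = 22L,
                       planted_shared_down = 20L,
                       planted_background_specific = 150L,
                       lfc_magnitude = 2,
                       targeting_enrichment_fold = 2.5,
                       utr5_bias_weight = 3,
                       ase2_bias_weight = 9,
                       window_length = 13L,
                       event_rate = 3,
                       noise_windows_per_gene = 2,
                       copy_weights = c(I = 2, II = 3, III = 6, SNORD115 = 1),
                       frac_coding = 0.7,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates),
    nb_dispersion = nb_dispersion,
    planted_shared_up = as.integer(planted_shared_up),
    planted_shared_down = as.integer(planted_shared_down),
    planted_background_specific = as.integer(planted_background_specific),
    lfc_magnitude = lfc_magnitude,
    targeting_enrichment_fold = targeting_enrichment_fold,
    utr5_bias_weight = utr5_bias_weight,
    ase2_bias_weight = ase2_bias_weight,
    window_length = as.integer(window_length),
    event_rate = event_rate,
    noise_windows_per_gene = noise_windows_per_gene,
    copy_weights = copy_weights,
    frac_coding = frac_coding,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_input("invalid sim_config: %s", msg)
  chk(cfg$n_genes >= 1L, "n_genes must be >= 1")
  chk(cfg$n_replicates >= 2L, "n_replicates must be >= 2")
  chk(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  sizes <- c(cfg$planted_shared_up, cfg$planted_shared_down,
             cfg$planted_background_specific)
  chk(all(sizes >= 0L), "planted set sizes must be >= 0")
  chk(sum(sizes) <= cfg$n_genes, "planted sets exceed n_genes")
  chk(cfg$targeting_enrichment_fold >= 0, "targeting_enrichment_fold must be >= 0")
  chk(cfg$utr5_bias_weight >= 0, "utr5_bias_weight must be >= 0")
  chk(cfg$ase2_bias_weight >= 0, "ase2_bias_weight must be >= 0")
  chk(cfg$window_length >= 1L, "window_length must be >= 1")
  chk(cfg$event_rate >= 0, "event_rate must be >= 0")
  chk(cfg$noise_windows_per_gene >= 0, "noise_windows_per_gene must be >= 0")
  chk(all(cfg$copy_weights >= 0) &&
        all(c("I", "II", "III", "SNORD115") %in% names(cfg$copy_weights)),
      "copy_weights must name I, II, III and SNORD115 with values >= 0")
  chk(cfg$frac_coding >= 0 && cfg$frac_coding <= 1, "frac_coding in [0,1]")
  chk(is.finite(cfg$seed), "seed must be a finite integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_replicates, "replicates/cell,",
      "seed", x$seed, "\n")
  cat(sprintf("  planted: %d up + %d down shared, %d background-specific, |lfc| = %g\n",
              x$planted_shared_up, x$planted_shared_down,
              x$planted_background_specific, x$lfc_magnitude))
  cat(sprintf("  windows: L = %d, event rate %g/gene, fold %g, utr5 w %g, ase2 w %g\n",
              x$window_length, x$event_rate, x$targeting_enrichment_fold,
              x$utr5_bias_weight, x$ase2_bias_weight))
  invisible(x)
}
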