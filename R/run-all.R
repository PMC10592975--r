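#' Run the full synthetic-data pipeline end to end
#'
#' Orchestrates every stage on synthetic data: locus fixture, annotation,
#' counts, DE tables, consensus calling (per-background shared DEGs, the
#' three-design consensus per deletion model, and the cross-model shared
#' set), the overlap permutation test, window simulation targeted at the
#' recovered shared set's planted truth, the consecutive-window filter,
#' covariate-matched targeting enrichment, the SNORD116/SNORD115 family
#' contrast, feature coverage and box-relative position profiles, and an ORA
#' run against truth-derived term sets. All outputs are written under
#' `outdir` together with a manifest (parameters, seeds, md5 hash of every
#' file); given the same config the run is byte-identical.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param outdir Output directory (created if missing).
#' @param alpha Consensus padj cutoff (default 0.05).
#' @param n_perm Permutations for the overlap test (default 2000 here; the
#'   standalone test defaults to 10000).
#' @param n_lists Matched control lists (default 100).
#' @param t,w Consecutive-window filter parameters (defaults 0.98, 3).
#' @param junction_width Junction half-width J in nt (default 2).
#' @return Invisibly, a result bundle (list) with every stage's in-memory
#'   output plus `manifest`.
#' @export
run_all <- function(config = sim_config(), outdir, alpha = 0.05,
                    n_perm = 2000L, n_lists = 100L, t = 0.98, w = 3L,
                    junction_width = 2L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  locus <- stage("locus", build_locus_fixture())
  ann <- stage("annotation", gen_annotation(config))
  write_gtf(ann, pth("annotation.gtf"))

  cnt <- stage("counts", gen_counts(ann, config))
  write_counts(cnt$counts, pth("counts.tsv"))
  write_tsv(cnt$samples, pth("samples.tsv"))
  write_tsv(cnt$truth, pth("truth.tsv"))

  genes <- ann_gene_ids(ann)
  de <- stage("de_tables", gen_de_tables(cnt$truth, genes, config, alpha))
  for (nm in names(de)) {
    write_de_table(de[[nm]], pth(sprintf("de_%s.tsv", gsub("\\.", "_", nm))))
  }

  consensus <- stage("consensus", {
    per_model <- lapply(c(smDEL = "smDEL", lgDEL = "lgDEL"), function(ct) {
      shared <- call_shared_degs(
        list(H9 = de[[sprintf("%s.H9.background_condition", ct)]],
             CT2 = de[[sprintf("%s.CT2.background_condition", ct)]]),
        alpha = alpha
      )
      triple <- lapply(c(H9 = "H9", CT2 = "CT2"), function(bg) {
        triple_design_consensus(
          list(de[[sprintf("%s.%s.background_condition", ct, bg)]],
               de[[sprintf("%s.condition", ct)]],
               de[[sprintf("%s.interaction", ct)]]),
          alpha = alpha
        )
      })
      list(shared = shared, triple = triple,
           triple_shared = intersect(triple$H9, triple$CT2))
    })
    shared42 <- cross_model_shared(per_model$lgDEL$triple_shared,
                                   per_model$smDEL$triple_shared)
    list(per_model = per_model, shared42 = shared42)
  })
  writeLines(consensus$shared42, pth("shared_genes.txt"))
  jsonlite::write_json(
    list(alpha = alpha,
         smDEL = list(up = consensus$per_model$smDEL$shared$up,
                      down = consensus$per_model$smDEL$shared$down,
                      triple_shared = consensus$per_model$smDEL$triple_shared),
         lgDEL = list(up = consensus$per_model$lgDEL$shared$up,
                      down = consensus$per_model$lgDEL$shared$down,
                      triple_shared = consensus$per_model$lgDEL$triple_shared),
         shared = consensus$shared42),
    pth("consensus.json"), auto_unbox = TRUE, pretty = TRUE
  )

  overlap <- stage("overlap_test", overlap_permutation_test(
    list(lgDEL = consensus$per_model$lgDEL$triple_shared,
         smDEL = consensus$per_model$smDEL$triple_shared),
    universe = genes, n_perm = n_perm,
    seed = derive_seed(config$seed, "overlap")
  ))
  jsonlite::write_json(unclass(overlap), pth("overlap_test.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  windows <- stage("windows", gen_windows(locus, ann, consensus$shared42,
                                          config))
  write_windows(windows, pth("windows.tsv"))

  events <- stage("filter_windows",
                  merge_consecutive(windows, t = t, w = w,
                                    merge_overlaps = TRUE))
  write_tsv(events, pth("events.tsv"),
            comment = "merged binding events; coordinates 0-based half-open")
  write_events_bed(events, pth("events.bed"))
  per_copy <- events_per_copy(events, locus)
  write_tsv(per_copy$per_copy, pth("events_per_copy.tsv"))
  write_tsv(per_copy$per_group, pth("events_per_group.tsv"))

  enrich <- stage("enrich", {
    covs <- compute_covariates(ann, cnt$counts, cnt$samples)
    matched <- sample_matched_lists(
      consensus$shared42, genes, covs, n_lists = n_lists,
      seed = derive_seed(config$seed, "matched")
    )
    ev3 <- filter_events(events, locus, group = "III")
    list(covariates = covs, matched = matched,
         enrichment = targeting_enrichment(ev3, consensus$shared42, matched),
         family = family_contrast(events, locus))
  })
  jsonlite::write_json(
    list(enrichment = lapply(enrich$enrichment, unclass),
         family_test = enrich$family$family_test,
         group3_test = enrich$family$group3_test),
    pth("enrichment.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  coverage <- stage("coverage", {
    ev3 <- filter_events(events, locus, group = "III")
    event_composition(ev3, consensus$shared42, ann,
                      junction_width = junction_width)
  })
  write_tsv(
    data.frame(category = names(coverage$background$counts),
               background_bp = as.numeric(coverage$background$counts),
               event_count = as.numeric(coverage$composition$counts)),
    pth("feature_coverage.tsv")
  )

  position <- stage("position", {
    prof <- relative_centers(events, locus)
    list(profile = prof, fractions = region_fractions(prof, locus))
  })
  write_tsv(position$profile$events, pth("positions.tsv"),
            comment = "snoRNA copy coordinates 0-based; centers are continuous midpoints")

  ora <- stage("ora", {
    truth_sets <- split(cnt$truth$gene_id,
                        paste0("planted_", cnt$truth$direction))
    terms <- c(truth_sets,
               list(random_term = with_seed(
                 derive_seed(config$seed, "terms"),
                 sample(genes, min(100L, length(genes)))
               )))
    hypergeom_ora(consensus$shared42, genes, terms)
  })
  write_tsv(ora, pth("ora.tsv"))

  scoring <- stage("truth_scoring", {
    truth_shared <- unique(cnt$truth$gene_id[cnt$truth$shared])
    tp <- length(intersect(consensus$shared42, truth_shared))
    data.frame(
      n_called = length(consensus$shared42),
      n_planted = length(truth_shared),
      sensitivity = if (length(truth_shared)) tp / length(truth_shared) else NA,
      precision = if (length(consensus$shared42))
        tp / length(consensus$shared42) else NA
    )
  })
  write_tsv(scoring, pth("truth_scoring.tsv"))

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "snotarget",
    version = as.character(utils::packageVersion("snotarget")),
    seed = config$seed,
    parameters = c(unclass(config)[setdiff(names(config), "copy_weights")],
                   list(copy_weights = as.list(config$copy_weights),
                        alpha = alpha, n_perm = n_perm, n_lists = n_lists,
                        t = t, w = w, junction_width = junction_width)),
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(pth(f)))
    })
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(locus = locus, annotation = ann, counts = cnt, de = de,
                 consensus = consensus, overlap = overlap, windows = windows,
                 events = events, per_copy = per_copy, enrich = enrich,
                 coverage = coverage, position = position, ora = ora,
                 scoring = scoring, manifest = manifest))
}
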