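#' Merge consecutive high-scoring interaction windows into binding events
#'
#' Implements the consecutive-window filter applied to sliding-window
#' interaction predictions: within each (snoRNA copy, target gene, strand)
#' group, a run is a maximal chain of windows whose target starts increase by
#' exactly 1 nt while the snoRNA-side starts step by 1 nt in the
#' duplex-consistent direction (antiparallel: decreasing on + strand targets,
#' increasing on - strand), all with `score >= t`. Runs of at least `w`
#' windows are consolidated into binding events spanning the first to last
#' window. The conventional parameters are `t = 0.98`, `w = 3`.
#'
#' @param windows data.frame in the schema of [gen_windows()] /
#'   [read_windows()]: 0-based half-open `sno_window_*` and
#'   `target_window_*` columns, `sno_id`, `target_gene`, `target_chrom`,
#'   `strand`, `score`.
#' @param t Score threshold in [0, 1] (default 0.98).
#' @param w Minimum run length (default 3).
#' @param merge_overlaps Union events of the same copy/gene/strand that
#'   overlap on the target (the tool's merge behavior; default TRUE).
#' @param consecutive `"duplex"` (default) requires 1-nt steps on both
#'   molecules; `"target"` only requires consecutive target starts.
#' @return data.frame of merged events: `sno_id`, `target_gene`,
#'   `target_chrom`, `strand`, `target_start`, `target_end`, `sno_start`,
#'   `sno_end` (all 0-based half-open), `n_windows`, `min_score`,
#'   `mean_score`.
#' @export
merge_consecutive <- function(windows, t = 0.98, w = 3L,
                              merge_overlaps = TRUE,
                              consecutive = c("duplex", "target")) {
  consecutive <- match.arg(consecutive)
  if (t < 0 || t > 1) stop_input("t must be in [0, 1]")
  if (w < 1L) stop_input("w must be >= 1")
  need <- c("sno_id", "sno_window_start", "sno_window_end", "target_gene",
            "target_chrom", "target_window_start", "target_window_end",
            "strand", "score")
  miss <- setdiff(need, colnames(windows))
  if (length(miss)) stop_input("windows table missing column(s): %s",
                               paste(miss, collapse = ", "))
  widths <- unique(c(windows$sno_window_end - windows$sno_window_start,
                     windows$target_window_end - windows$target_window_start))
  if (nrow(windows) && length(widths) != 1L) {
    stop_input("inconsistent window widths: %s", paste(widths, collapse = ", "))
  }
  empty <- data.frame(
    sno_id = character(0), target_gene = character(0),
    target_chrom = character(0), strand = character(0),
    target_start = integer(0), target_end = integer(0),
    sno_start = integer(0), sno_end = integer(0),
    n_windows = integer(0), min_score = numeric(0), mean_score = numeric(0),
    stringsAsFactors = FALSE
  )
  if (!nrow(windows)) return(empty)
  L <- widths

  win <- windows[windows$score >= t, , drop = FALSE]
  if (!nrow(win)) return(empty)

  # chains live on anti-diagonals: target + sno is invariant along a
  # duplex-consistent run on + strand targets, target - sno on - strand
  diag_key <- if (consecutive == "duplex") {
    ifelse(win$strand == "-",
           win$target_window_start - win$sno_window_start,
           win$target_window_start + win$sno_window_start)
  } else {
    0L
  }
  grp <- paste(win$sno_id, win$target_gene, win$target_chrom, win$strand,
               diag_key, sep = "\r")

  if (consecutive == "target") {
    # one window per target start is enough; keep the best-scoring one
    o <- order(grp, win$target_window_start, -win$score)
    win <- win[o, , drop = FALSE]; grp <- grp[o]
    dup <- duplicated(paste(grp, win$target_window_start, sep = "\r"))
    win <- win[!dup, , drop = FALSE]; grp <- grp[!dup]
  } else {
    o <- order(grp, win$target_window_start, win$sno_window_start)
    win <- win[o, , drop = FALSE]; grp <- grp[o]
    dup <- duplicated(paste(grp, win$target_window_start,
                            win$sno_window_start, sep = "\r"))
    win <- win[!dup, , drop = FALSE]; grp <- grp[!dup]
  }
  n <- nrow(win)
  new_run <- c(TRUE, grp[-1] != grp[-n] |
                 diff(win$target_window_start) != 1L)
  run_id <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, n)
  len <- last - first + 1L
  keep <- len >= w
  if (!any(keep)) return(empty)

  min_score <- vapply(seq_along(first),
                      function(r) min(win$score[first[r]:last[r]]),
                      numeric(1))
  sum_score <- vapply(seq_along(first),
                      function(r) sum(win$score[first[r]:last[r]]),
                      numeric(1))
  sno_min <- vapply(seq_along(first),
                    function(r) min(win$sno_window_start[first[r]:last[r]]),
                    integer(1))
  sno_max <- vapply(seq_along(first),
                    function(r) max(win$sno_window_start[first[r]:last[r]]),
                    integer(1))
  events <- data.frame(
    sno_id = win$sno_id[first], target_gene = win$target_gene[first],
    target_chrom = win$target_chrom[first], strand = win$strand[first],
    target_start = win$target_window_start[first],
    target_end = win$target_window_start[last] + L,
    sno_start = sno_min, sno_end = sno_max + L,
    n_windows = len, min_score = min_score, mean_score = sum_score / len,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(events) <- NULL

  if (merge_overlaps && nrow(events) > 1L) {
    key <- paste(events$sno_id, events$target_gene, events$target_chrom,
                 events$strand, sep = "\r")
    gr <- GenomicRanges::GRanges(
      seqnames = factor(key),
      ranges = IRanges::IRanges(start = events$target_start + 1L,
                                end = events$target_end)
    )
    red <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, red)
    grp2 <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    o <- order(grp2)
    ev <- events[o, , drop = FALSE]; g <- grp2[o]
    newg <- c(TRUE, g[-1] != g[-length(g)])
    f <- which(newg)
    agg <- function(x, fun, mode = numeric(1)) {
      vapply(seq_along(f), function(r) {
        idx <- f[r]:(if (r < length(f)) f[r + 1L] - 1L else length(g))
        fun(x[idx])
      }, mode)
    }
    nw_sum <- agg(ev$n_windows, sum, integer(1))
    events <- data.frame(
      sno_id = ev$sno_id[f], target_gene = ev$target_gene[f],
      target_chrom = ev$target_chrom[f], strand = ev$strand[f],
      target_start = agg(ev$target_start, min, integer(1)),
      target_end = agg(ev$target_end, max, integer(1)),
      sno_start = agg(ev$sno_start, min, integer(1)),
      sno_end = agg(ev$sno_end, max, integer(1)),
      n_windows = nw_sum,
      min_score = agg(ev$min_score, min),
      mean_score = agg(ev$mean_score * ev$n_windows, sum) / nw_sum,
      stringsAsFactors = FALSE
    )
  }
  events[order(events$target_chrom, events$target_start, events$sno_id), ,
         drop = FALSE] -> events
  rownames(events) <- NULL
  events
}

#' Predicted targeting events per snoRNA copy
#'
#' Counts merged binding events per snoRNA copy (zero-filled over all copies
#' in the locus) and summarizes per-copy means by family and SNORD116 group.
#'
#' @param events Merged events from [merge_consecutive()].
#' @param locus A `locus_model`.
#' @return List with `per_copy` (data.frame: copy_id, family, group,
#'   n_events) and `per_group` (data.frame: family, group, n_copies,
#'   mean_events).
#' @export
events_per_copy <- function(events, locus) {
  cp <- locus$copies
  unknown <- setdiff(events$sno_id, cp$copy_id)
  if (length(unknown)) stop_input("unknown snoRNA copy id(s): %s",
                                  paste(head(unknown, 3), collapse = ", "))
  cnt <- table(factor(events$sno_id, levels = cp$copy_id))
  per_copy <- data.frame(
    copy_id = cp$copy_id, family = cp$family, group = cp$group,
    n_events = as.integer(cnt),
    stringsAsFactors = FALSE
  )
  key <- ifelse(per_copy$family == "SNORD115", "SNORD115",
                paste0("SNORD116-", per_copy$group))
  agg <- split(per_copy$n_events, key)
  per_group <- data.frame(
    family = ifelse(grepl("^SNORD116", names(agg)), "SNORD116", "SNORD115"),
    group = ifelse(grepl("^SNORD116", names(agg)),
                   sub("^SNORD116-", "", names(agg)), NA_character_),
    n_copies = lengths(agg),
    mean_events = vapply(agg, mean, numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  list(per_copy = per_copy, per_group = per_group)
}

#' Restrict merged events to a snoRNA family or group
#'
#' @param events Merged events from [merge_consecutive()].
#' @param locus A `locus_model`.
#' @param family Optional family filter ("SNORD116" or "SNORD115").
#' @param group Optional SNORD116 group filter ("I", "II" or "III").
#' @return The filtered events data.frame.
#' @export
filter_events <- function(events, locus, family = NULL, group = NULL) {
  ann <- copy_groups(events$sno_id, locus)
  keep <- rep(TRUE, nrow(events))
  if (!is.null(family)) keep <- keep & ann$family == family
  if (!is.null(group)) keep <- keep & !is.na(ann$group) & ann$group == group
  events[keep, , drop = FALSE]
}
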