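#' Relative binding positions along snoRNA copies
#'
#' Computes, for each merged binding event, the center of its snoRNA-side
#' span (continuous midpoint of the 0-based half-open interval) and the
#' relative position `center / copy_length` in [0, 1]. Box and ASE2 tracks
#' are scaled per copy the same way and aggregated per SNORD116 group /
#' SNORD115 family.
#'
#' @param events Merged events from [merge_consecutive()].
#' @param locus A `locus_model`.
#' @return A `position_profile`: list with `events` (data.frame: sno_id,
#'   family, group, center, rel_center), `box_track` (per-copy relative box
#'   and ASE2 intervals) and `groups` (split of rel_center by group label).
#' @export
relative_centers <- function(events, locus) {
  if (!nrow(events)) stop_input("empty event set")
  cp <- locus$copies
  idx <- match(events$sno_id, cp$copy_id)
  if (anyNA(idx)) stop_input("unknown snoRNA copy id(s): %s",
                             paste(unique(events$sno_id[is.na(idx)]),
                                   collapse = ", "))
  len <- cp$length[idx]
  if (any(events$sno_start < 0L) || any(events$sno_end > len)) {
    stop_input("event snoRNA span exceeds copy length")
  }
  center <- (events$sno_start + events$sno_end) / 2
  grp_label <- ifelse(cp$family[idx] == "SNORD115", "SNORD115",
                      paste0("SNORD116-", cp$group[idx]))
  ev <- data.frame(
    sno_id = events$sno_id,
    family = cp$family[idx],
    group = grp_label,
    center = center,
    rel_center = center / len,
    stringsAsFactors = FALSE
  )
  box_track <- data.frame(
    copy_id = cp$copy_id,
    c_lo = cp$c_start / cp$length, c_hi = cp$c_end / cp$length,
    dp_lo = cp$dp_start / cp$length, dp_hi = cp$dp_end / cp$length,
    cp_lo = cp$cp_start / cp$length, cp_hi = cp$cp_end / cp$length,
    d_lo = cp$d_start / cp$length, d_hi = cp$d_end / cp$length,
    ase2_lo = cp$ase2_start / cp$length, ase2_hi = cp$ase2_end / cp$length,
    stringsAsFactors = FALSE
  )
  structure(list(events = ev, box_track = box_track,
                 groups = split(ev$rel_center, ev$group)),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat("position_profile:", nrow(x$events), "events across",
      length(x$groups), "group(s)\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %s: n = %d, median rel. position %.3f\n",
                g, length(x$groups[[g]]), stats::median(x$groups[[g]])))
  }
  invisible(x)
}

#' Fractions of binding-event centers per snoRNA region
#'
#' Classifies each event center (copy coordinates) into the named regions of
#' its copy — ASE2, C box, C' box, D/D' boxes — or "other", and returns the
#' fraction of centers per region (sums to 1), optionally per group.
#'
#' @param profile A `position_profile` from [relative_centers()].
#' @param locus A `locus_model`.
#' @param by_group Also return per-group fraction tables (default TRUE).
#' @return List with `overall` (named fractions) and, if requested,
#'   `by_group`.
#' @export
region_fractions <- function(profile, locus, by_group = TRUE) {
  ev <- profile$events
  if (!nrow(ev)) stop_input("empty position profile")
  cp <- locus$copies
  idx <- match(ev$sno_id, cp$copy_id)
  ctr <- ev$center
  inside <- function(lo, hi) ctr >= lo[idx] & ctr < hi[idx]
  region <- rep("other", nrow(ev))
  region[inside(cp$d_start, cp$d_end) | inside(cp$dp_start, cp$dp_end)] <- "d_boxes"
  region[inside(cp$cp_start, cp$cp_end)] <- "cp_box"
  region[inside(cp$c_start, cp$c_end)] <- "c_box"
  region[inside(cp$ase2_start, cp$ase2_end)] <- "ase2"
  lv <- c("ase2", "c_box", "cp_box", "d_boxes", "other")
  frac <- function(r) {
    tab <- table(factor(r, levels = lv))
    as.numeric(tab) / length(r) -> f
    stats::setNames(f, lv)
  }
  out <- list(overall = frac(region))
  if (by_group) {
    out$by_group <- lapply(split(region, ev$group), frac)
  }
  out
}

#' Scan a snoRNA sequence for candidate C/D box motifs
#'
#' Searches a single snoRNA sequence (RNA or DNA alphabet) for box motifs:
#' C-type boxes match RUGAUGA (IUPAC R = A/G; the C' copy is allowed one
#' mismatch), D-type boxes match CUGA. Candidates are ranked by positional
#' plausibility — the C box nearest the 5' end, the D box nearest the 3'
#' end, the D' box the most 5' remaining D-type match, and the C' box a
#' (possibly degenerate) match between D' and D. Curated fixture boxes
#' always take precedence over scan results.
#'
#' @param sequence Character scalar, one snoRNA sequence.
#' @return List with `C`, `Dp`, `Cp`, `D` (each `c(start, end)` 0-based
#'   half-open, or NULL if not found) and `candidates` (data.frame of all
#'   motif hits).
#' @export
scan_boxes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  rna <- Biostrings::RNAString(chartr("Tt", "Uu", toupper(sequence)))

  hits <- function(pattern, max.mismatch = 0L) {
    m <- Biostrings::matchPattern(Biostrings::RNAString(pattern), rna,
                                  max.mismatch = max.mismatch, fixed = FALSE)
    if (!length(m)) return(NULL)
    data.frame(start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m))  # 0-based half-open
  }

  c_exact <- hits("RUGAUGA")
  d_hits <- hits("CUGA")
  cand <- rbind(
    if (!is.null(c_exact)) cbind(c_exact, box_type = "C_like"),
    if (!is.null(d_hits)) cbind(d_hits, box_type = "D_like")
  )

  out <- list(C = NULL, Dp = NULL, Cp = NULL, D = NULL,
              candidates = if (is.null(cand)) {
                data.frame(start = integer(0), end = integer(0),
                           box_type = character(0))
              } else cand[order(cand$start), ])

  if (!is.null(c_exact)) {
    out$C <- c(c_exact$start[1], c_exact$end[1])
  }
  if (!is.null(d_hits)) {
    last <- nrow(d_hits)
    out$D <- c(d_hits$start[last], d_hits$end[last])
    interior <- d_hits[d_hits$start > (out$C[2] %||% 0) &
                         d_hits$end < out$D[1], , drop = FALSE]
    if (nrow(interior)) out$Dp <- c(interior$start[1], interior$end[1])
  }
  # C' candidate: exact or one-mismatch RUGAUGA between D' and D
  c_deg <- hits("RUGAUGA", max.mismatch = 1L)
  if (!is.null(c_deg) && !is.null(out$Dp) && !is.null(out$D)) {
    mid <- c_deg[c_deg$start >= out$Dp[2] & c_deg$end <= out$D[1], ,
                 drop = FALSE]
    if (nrow(mid)) out$Cp <- c(mid$start[1], mid$end[1])
  }
  out
}
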