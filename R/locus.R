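#' Deterministic Prader-Willi locus model
#'
#' Builds a synthetic model of the imprinted chr15q11-q13 snoRNA locus:
#' 30 SNORD116 copies partitioned into the sequence-similarity groups
#' I (copies 1-9), II (copies 10-24) and III (copies 25-30), 48 SNORD115
#' copies, the flanking imprinted genes (MKRN3, MAGEL2, NDN, SNURF, SNRPN,
#' IPW, UBE3A analogs) and the two engineered deletion intervals: `smDEL`
#' removes only the SNORD116 cluster while `lgDEL` extends from the SNRPN
#' promoter region through the SNORD116 cluster.
#'
#' Coordinates live on a pseudo-chromosome (`chr15s`), not on hg38; each
#' snoRNA copy carries curated C, D', C' and D box intervals (0-based
#' half-open on the copy), the 15-nt second antisense element (ASE2)
#' immediately 5' of the D' box, and a deterministic sequence with the box
#' motifs planted (RUGAUGA for C/C', CUGA for D/D').
#'
#' @param ase2_width Width in nt of the ASE2 element placed immediately
#'   upstream (5') of the D' box. Default 15.
#' @return A `locus_model` list with elements `copies` (data.frame: copy_id,
#'   family, group, length, chrom, start, end, strand, box coordinates, ase2),
#'   `flanking_genes` (data.frame), `deletions` (named list of `c(start, end)`
#'   0-based half-open genomic intervals) and `sequences` (named character,
#'   RNA alphabet).
#' @examples
#' locus <- build_locus_fixture()
#' table(locus$copies$family)
#' @export
build_locus_fixture <- function(ase2_width = 15L) {
  stopifnot(ase2_width >= 1L)

  copy_row <- function(copy_id, family, group, len, start) {
    # box layout scales with copy length; D' placed so that ASE2 fits 5' of it
    if (family == "SNORD116") {
      c_box <- c(4L, 11L); dp_box <- c(40L, 44L)
      cp_box <- c(55L, 62L); d_box <- c(len - 8L, len - 4L)
    } else {
      c_box <- c(4L, 11L); dp_box <- c(38L, 42L)
      cp_box <- c(50L, 57L); d_box <- c(len - 8L, len - 4L)
    }
    ase2 <- c(dp_box[1] - ase2_width, dp_box[1])
    data.frame(
      copy_id = copy_id, family = family, group = group, length = len,
      chrom = "chr15s", start = start, end = start + len, strand = "+",
      c_start = c_box[1], c_end = c_box[2],
      dp_start = dp_box[1], dp_end = dp_box[2],
      cp_start = cp_box[1], cp_end = cp_box[2],
      d_start = d_box[1], d_end = d_box[2],
      ase2_start = ase2[1], ase2_end = ase2[2],
      stringsAsFactors = FALSE
    )
  }

  s116 <- do.call(rbind, lapply(seq_len(30L), function(i) {
    grp <- if (i <= 9L) "I" else if (i <= 24L) "II" else "III"
    copy_row(sprintf("SNORD116-%d", i), "SNORD116", grp, 98L,
             80000L + (i - 1L) * 2000L)
  }))
  s115 <- do.call(rbind, lapply(seq_len(48L), function(j) {
    copy_row(sprintf("SNORD115-%d", j), "SNORD115", NA_character_, 82L,
             160000L + (j - 1L) * 2000L)
  }))
  copies <- rbind(s116, s115)

  flanking <- data.frame(
    gene_id = c("MKRN3", "MAGEL2", "NDN", "SNURF", "SNRPN", "IPW", "UBE3A"),
    chrom = "chr15s",
    start = c(10000L, 20000L, 30000L, 50000L, 54000L, 150000L, 260000L),
    end = c(15000L, 26000L, 33000L, 54000L, 70000L, 156000L, 280000L),
    strand = c("+", "+", "-", "+", "+", "+", "-"),
    coding = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )

  sno116_end <- max(s116$end)
  deletions <- list(
    smDEL = c(79000L, sno116_end + 1000L),
    # covers SNORD116, SNURF and the SNRPN promoter region
    lgDEL = c(49500L, sno116_end + 1000L)
  )

  sequences <- vapply(seq_len(nrow(copies)), function(i) {
    r <- copies[i, ]
    # A/C background cannot spawn spurious RUGAUGA/CUGA motifs
    bg <- c("A", "C", "A", "A", "C")
    s <- bg[(seq_len(r$length) - 1L) %% 5L + 1L]
    plant <- function(s, iv, motif) {
      m <- strsplit(motif, "")[[1]]
      s[(iv[1] + 1L):(iv[1] + length(m))] <- m
      s
    }
    s <- plant(s, c(r$c_start, r$c_end), "AUGAUGA")
    s <- plant(s, c(r$dp_start, r$dp_end), "CUGA")
    s <- plant(s, c(r$cp_start, r$cp_end), "AUGAUGA")
    s <- plant(s, c(r$d_start, r$d_end), "CUGA")
    paste(s, collapse = "")
  }, character(1))
  names(sequences) <- copies$copy_id

  model <- structure(
    list(copies = copies, flanking_genes = flanking,
         deletions = deletions, sequences = sequences),
    class = "locus_model"
  )
  validate_locus(model)
  model
}

validate_locus <- function(model) {
  cp <- model$copies
  stopifnot(
    sum(cp$family == "SNORD116") == 30L,
    sum(cp$family == "SNORD115") == 48L,
    all(cp$c_start < cp$c_end, cp$c_end <= cp$dp_start,
        cp$dp_start < cp$dp_end, cp$dp_end <= cp$cp_start,
        cp$cp_start < cp$cp_end, cp$cp_end <= cp$d_start,
        cp$d_start < cp$d_end, cp$d_end <= cp$length),
    all(cp$ase2_end == cp$dp_start),
    all(cp$ase2_start >= 0L)
  )
  del <- model$deletions
  s116 <- cp[cp$family == "SNORD116", ]
  stopifnot(
    all(s116$start >= del$smDEL[1] & s116$end <= del$smDEL[2]),
    all(s116$start >= del$lgDEL[1] & s116$end <= del$lgDEL[2])
  )
  fl <- model$flanking_genes
  coding <- fl[fl$coding, ]
  overlaps <- coding$start < del$smDEL[2] & coding$end > del$smDEL[1]
  stopifnot(!any(overlaps))
  invisible(model)
}

#' @export
print.locus_model <- function(x, ...) {
  cat("Synthetic PWS locus model (chr15s)\n")
  cat(sprintf("  %d SNORD116 copies (groups: %s)\n",
              sum(x$copies$family == "SNORD116"),
              paste(table(x$copies$group[x$copies$family == "SNORD116"]),
                    collapse = "/")))
  cat(sprintf("  %d SNORD115 copies\n", sum(x$copies$family == "SNORD115")))
  cat(sprintf("  deletions: smDEL [%d, %d), lgDEL [%d, %d)\n",
              x$deletions$smDEL[1], x$deletions$smDEL[2],
              x$deletions$lgDEL[1], x$deletions$lgDEL[2]))
  invisible(x)
}

#' Map snoRNA copy ids to family and group labels
#'
#' @param sno_ids Character vector of copy ids present in `locus`.
#' @param locus A `locus_model`.
#' @return data.frame with columns `copy_id`, `family`, `group`.
#' @export
copy_groups <- function(sno_ids, locus) {
  idx <- match(sno_ids, locus$copies$copy_id)
  if (anyNA(idx)) {
    stop_input("unknown snoRNA copy id(s): %s",
               paste(unique(sno_ids[is.na(idx)]), collapse = ", "))
  }
  data.frame(copy_id = sno_ids,
             family = locus$copies$family[idx],
             group = locus$copies$group[idx],
             stringsAsFactors = FALSE)
}
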