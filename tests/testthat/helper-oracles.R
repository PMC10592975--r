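# Brute-force oracles, independent of the package implementations they check.

# O(n^2) run finder: follows successor links window-by-window instead of
# grouping on diagonals. Returns events like merge_consecutive(..., merge
# disabled), unordered.
brute_force_runs <- function(windows, t, w, mode = c("duplex", "target")) {
  mode <- match.arg(mode)
  L <- unique(windows$sno_window_end - windows$sno_window_start)
  stopifnot(length(L) == 1L)
  win <- windows[windows$score >= t, , drop = FALSE]
  if (mode == "target") {
    win <- win[order(win$sno_id, win$target_gene, win$strand,
                     win$target_window_start, -win$score), , drop = FALSE]
    win <- win[!duplicated(win[, c("sno_id", "target_gene", "strand",
                                   "target_window_start")]), , drop = FALSE]
  } else {
    win <- win[!duplicated(win[, c("sno_id", "target_gene", "strand",
                                   "target_window_start",
                                   "sno_window_start")]), , drop = FALSE]
  }
  n <- nrow(win)
  if (!n) return(NULL)
  succ <- rep(NA_integer_, n)
  has_pred <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same <- win$sno_id[i] == win$sno_id[j] &&
        win$target_gene[i] == win$target_gene[j] &&
        win$strand[i] == win$strand[j]
      if (!same) next
      step_t <- win$target_window_start[j] == win$target_window_start[i] + 1L
      step_s <- if (mode == "target") TRUE else if (win$strand[i] == "-") {
        win$sno_window_start[j] == win$sno_window_start[i] + 1L
      } else {
        win$sno_window_start[j] == win$sno_window_start[i] - 1L
      }
      if (step_t && step_s) {
        succ[i] <- j
        has_pred[j] <- TRUE
      }
    }
  }
  out <- NULL
  for (start in which(!has_pred)) {
    chain <- start
    while (!is.na(succ[chain[length(chain)]])) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    if (length(chain) < w) next
    r <- win[chain, , drop = FALSE]
    out <- rbind(out, data.frame(
      sno_id = r$sno_id[1], target_gene = r$target_gene[1],
      target_chrom = r$target_chrom[1], strand = r$strand[1],
      target_start = min(r$target_window_start),
      target_end = max(r$target_window_start) + L,
      sno_start = min(r$sno_window_start),
      sno_end = max(r$sno_window_start) + L,
      n_windows = length(chain),
      min_score = min(r$score), mean_score = mean(r$score),
      stringsAsFactors = FALSE
    ))
  }
  out
}

# Exact ORA upper-tail p by exhaustive enumeration of all query draws.
brute_force_ora_p <- function(k_obs, term_size, universe_size, query_size) {
  draws <- utils::combn(universe_size, query_size)
  in_term <- draws <= term_size  # wlog: term = first term_size elements
  mean(colSums(in_term) >= k_obs)
}

# Exact mean k=2 overlap by enumeration of all second lists (first fixed).
brute_force_overlap_mean <- function(universe_size, s1, s2) {
  draws <- utils::combn(universe_size, s2)
  mean(colSums(draws <= s1))  # wlog: first list = 1..s1
}

# Window-table builder for filter tests.
make_windows <- function(target_starts, sno_starts, scores,
                         sno_id = "SNORD116-27", gene = "G1",
                         chrom = "chrS", strand = "+", L = 13L) {
  data.frame(
    sno_id = sno_id,
    sno_window_start = as.integer(sno_starts),
    sno_window_end = as.integer(sno_starts) + L,
    target_gene = gene, target_chrom = chrom,
    target_window_start = as.integer(target_starts),
    target_window_end = as.integer(target_starts) + L,
    strand = strand, score = scores,
    stringsAsFactors = FALSE
  )
}

# Random window tables for oracle cross-checks: mixture of planted runs and
# scattered windows over a few (copy, gene) groups.
random_window_table <- function(n_max = 50L, L = 7L) {
  n_runs <- sample(0:3, 1)
  tabs <- list()
  for (r in seq_len(n_runs)) {
    len <- sample(2:6, 1)
    t0 <- sample(0:40, 1)
    s0 <- sample(len:30, 1)
    strand <- sample(c("+", "-"), 1)
    s_seq <- if (strand == "+") s0 - seq_len(len) + 1L else s0 + seq_len(len)
    tabs[[length(tabs) + 1L]] <- make_windows(
      t0 + seq_len(len) - 1L, s_seq, runif(len, 0.9, 1),
      sno_id = sample(c("A", "B"), 1), gene = sample(c("G1", "G2"), 1),
      strand = strand, L = L
    )
  }
  n_scatter <- sample(0:20, 1)
  if (n_scatter > 0) {
    tabs[[length(tabs) + 1L]] <- make_windows(
      sample(0:60, n_scatter, replace = TRUE),
      sample(0:30, n_scatter, replace = TRUE),
      runif(n_scatter),
      sno_id = sample(c("A", "B"), n_scatter, replace = TRUE),
      gene = sample(c("G1", "G2"), n_scatter, replace = TRUE),
      strand = sample(c("+", "-"), n_scatter, replace = TRUE), L = L
    )
  }
  out <- do.call(rbind, tabs)
  if (is.null(out)) out <- make_windows(integer(0), integer(0), numeric(0), L = L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical event key for set comparison between implementations.
event_key <- function(ev) {
  if (is.null(ev) || !nrow(ev)) return(character(0))
  sort(sprintf("%s|%s|%s|%d|%d|%d|%d|%d|%.6f",
               ev$sno_id, ev$target_gene, ev$strand,
               ev$target_start, ev$target_end, ev$sno_start, ev$sno_end,
               ev$n_windows, ev$min_score))
}
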