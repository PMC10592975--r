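#' Permutation test for a k-way gene-list overlap
#'
#' Tests whether the intersection of k gene lists is larger than expected for
#' random lists of the same sizes. Each permutation redraws all k lists
#' uniformly without replacement from the universe (joint scheme) and records
#' the intersection size. Fold enrichment is the observed intersection over
#' the null mean; the empirical p-value uses the add-one rule
#' `(1 + #{null >= obs}) / (n_perm + 1)`. For two lists the null mean
#' converges to the hypergeometric expectation `|A| * |B| / N`.
#'
#' @param lists List of k >= 2 character vectors, each a subset of `universe`.
#' @param universe Character vector of the gene universe.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param mode `"joint"` (default) tests the single k-way intersection;
#'   `"pairwise"` returns a joint test per unordered pair of lists.
#' @return An `enrichment_result` (or a named list of them for
#'   `mode = "pairwise"`).
#' @export
overlap_permutation_test <- function(lists, universe, n_perm = 10000L,
                                     seed = 1L, mode = c("joint", "pairwise")) {
  mode <- match.arg(mode)
  if (!is.list(lists) || length(lists) < 2L) stop_input("need k >= 2 lists")
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  universe <- unique(universe)
  for (i in seq_along(lists)) {
    lists[[i]] <- unique(lists[[i]])
    bad <- setdiff(lists[[i]], universe)
    if (length(bad)) stop_input("list %d contains genes outside the universe (e.g. %s)",
                                i, bad[1])
  }

  if (mode == "pairwise") {
    idx <- utils::combn(length(lists), 2L)
    out <- lapply(seq_len(ncol(idx)), function(j) {
      overlap_permutation_test(lists[idx[, j]], universe, n_perm,
                               seed = seed + j, mode = "joint")
    })
    names(out) <- apply(idx, 2, paste, collapse = "_vs_")
    return(out)
  }

  k <- length(lists)
  N <- length(universe)
  sizes <- lengths(lists)
  observed <- length(Reduce(intersect, lists))

  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cnt <- integer(N)
      for (s in sizes) {
        idx <- sample.int(N, s)
        cnt[idx] <- cnt[idx] + 1L
      }
      sum(cnt == k)
    }, integer(1))
  })
  new_enrichment_result(observed, null, n_perm = n_perm, seed = seed,
                        statistic = sprintf("%d-way overlap", k))
}
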