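#' @keywords internal
"_PACKAGE"

#' @importFrom stats median p.adjust phyper rnbinom rnorm rpois runif
#'   wilcox.test rlnorm setNames
#' @importFrom utils read.delim write.table head
NULL

# Derive a stream-specific child seed from a master seed. Keeps all derived
# seeds inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    annotation = 11L, counts = 23L, de = 37L, windows = 53L,
    overlap = 71L, matched = 89L, enrichment = 101L, terms = 113L
  )
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 1000003 + off * 7919) %% 2147483647)
}

# Run `expr` under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Add-one empirical p-value
#'
#' Upper-tail empirical p-value of an observed statistic against a resampled
#' null, with the add-one correction `(1 + #{null >= obs}) / (n + 1)` so that
#' finite resampling can never report p = 0.
#'
#' @param observed Observed statistic (length 1).
#' @param null Numeric vector of null statistics.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(length(observed) == 1L, length(null) >= 1L)
  (1 + sum(null >= observed)) / (length(null) + 1)
}

# Shared container for resampling-based enrichment statistics.
new_enrichment_result <- function(observed, null, n_perm, seed,
                                  statistic = "intersection") {
  null_mean <- mean(null)
  fold <- if (null_mean > 0) observed / null_mean else if (observed == 0) 0 else Inf
  structure(
    list(
      statistic = statistic,
      observed = observed,
      null_mean = null_mean,
      null_median = stats::median(null),
      fold = fold,
      p_empirical = empirical_pvalue(observed, null),
      n_perm = n_perm,
      seed = seed
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment result (", x$statistic, ")\n", sep = "")
  cat(sprintf("  observed: %.4g   null mean: %.4g   null median: %.4g\n",
              x$observed, x$null_mean, x$null_median))
  cat(sprintf("  fold enrichment: %.4g   empirical p: %.4g (n = %d)\n",
              x$fold, x$p_empirical, x$n_perm))
  invisible(x)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
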