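# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Rank of the shuffle-pool value used as threshold
#'
#' For a pool of simulated per-offset relative entropies, the threshold
#' at significance level `alpha` is the k-th highest pool value with
#' k = max(1, round(alpha * pool_size)) -- e.g. the 10th-highest of
#' 10,000 (20 offsets x 500 repeats) at alpha = 0.001, or the
#' 3rd-highest of 3,000 (6 x 500).
#'
#' @param alpha Significance level in (0, 1).
#' @param pool_size Number of simulated values.
#' @return Integer rank k.
#' @export
threshold_rank <- function(alpha, pool_size) {
  stopifnot(alpha > 0, alpha < 1, pool_size >= 1)
  max(1L, as.integer(round(alpha * pool_size)))
}

#' Shuffle-based null distribution for one side of a context table
#'
#' Builds the positional null: in each of `repeats` rounds, the stored
#' flanking strings of the chosen side have their W positions permuted
#' (by default each string independently, preserving every string's
#' residue composition), the per-offset relative entropies are
#' recomputed against the same background, and all W values join the
#' pool.  The significance threshold is the k-th highest pool value
#' (see [threshold_rank()]).
#'
#' @param table A [context_count_table].
#' @param side `"N"` or `"C"`.
#' @param background A `background_distribution`.
#' @param repeats Number of shuffle rounds (default 500).
#' @param alpha Significance level (default 0.001).
#' @param mode `"per_string"` (each flank permuted independently, the
#'   default) or `"global"` (one shared permutation of the W positions
#'   per round).
#' @param seed Optional RNG seed; the caller's RNG state is restored.
#' @return An object of class `shuffle_null` with the pool, the rank
#'   `k` and the `threshold`.
#' @export
shuffle_null <- function(table, side, background, repeats = 500L,
                         alpha = 0.001, mode = c("per_string", "global"),
                         seed = NULL) {
  stopifnot(inherits(table, "context_count_table"), side %in% c("N", "C"))
  mode <- match.arg(mode)
  store <- table$context_store[[side]]
  if (length(store) == 0L)
    stop("context store is empty on the ", side, " side")
  W <- table$window
  m <- store_matrix(store, W)
  Q <- background_side_matrix(background, W, side)
  pool <- with_rng_seed(seed,
    cpp_shuffle_pool(m, Q, as.integer(repeats), mode == "per_string"))
  k <- threshold_rank(alpha, length(pool))
  threshold <- sort(pool, decreasing = TRUE)[k]
  structure(
    list(side = side, window = W, repeats = as.integer(repeats),
         alpha = alpha, k = k, pool = pool, threshold = threshold,
         mode = mode),
    class = "shuffle_null"
  )
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat("<shuffle_null> side=", x$side, " pool=", length(x$pool),
      " (", x$repeats, " x ", x$window, "), alpha=", x$alpha,
      ", k=", x$k, ", threshold=", signif(x$threshold, 6), "\n", sep = "")
  invisible(x)
}

#' Bootstrap standard deviations of per-offset relative entropies
#'
#' Resamples the stored flanking strings of each side with replacement
#' at the original side count, `n_boot` times, recomputes the per-offset
#' totals against the background, and returns the standard deviation
#' (denominator n_boot - 1) per offset.  Sides with fewer than two
#' contexts yield `NA`.
#'
#' @param table A [context_count_table].
#' @param background A `background_distribution`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Optional RNG seed; the caller's RNG state is restored.
#' @return Named numeric vector of SDs over all 2W offset labels.
#' @export
bootstrap_sd <- function(table, background, n_boot = 100L, seed = NULL) {
  stopifnot(inherits(table, "context_count_table"))
  W <- table$window
  labs <- offset_labels(W)
  sds <- stats::setNames(rep(NA_real_, 2L * W), labs)
  with_rng_seed(seed, {
    for (side in c("N", "C")) {
      if (table$n_side[[side]] < 2L) next
      m <- store_matrix(table$context_store[[side]], W)
      Q <- background_side_matrix(background, W, side)
      totals <- cpp_bootstrap_totals(m, Q, as.integer(n_boot))
      offs <- if (side == "N") as.character(-W:-1) else as.character(1:W)
      sds[offs] <- apply(totals, 2L, stats::sd)
    }
  })
  sds
}

#' Attach thresholds and significance flags to a profile
#'
#' Each populated side carries its own shuffle threshold (the N- and
#' C-side context sets generally differ in size, so their thresholds
#' differ); an offset is significant iff its total relative entropy
#' exceeds its side's threshold.
#'
#' @param profile An [entropy_profile()].
#' @param nulls Named list with a [shuffle_null()] per populated side
#'   (`N` and/or `C`).
#' @param sds Optional per-offset bootstrap SDs from [bootstrap_sd()].
#' @return The profile with `threshold`, `significant` (and optionally
#'   `bootstrap_sd`) filled in.
#' @export
annotate_significance <- function(profile, nulls, sds = NULL) {
  stopifnot(inherits(profile, "entropy_profile"))
  for (side in unique(profile$side)) {
    nl <- nulls[[side]]
    if (is.null(nl))
      stop("no shuffle null supplied for populated side ", side)
    stopifnot(inherits(nl, "shuffle_null"), nl$side == side)
    rows <- profile$side == side
    profile$threshold[rows] <- nl$threshold
    profile$significant[rows] <-
      profile$total_relative_entropy[rows] > nl$threshold
  }
  if (!is.null(sds))
    profile$bootstrap_sd <- unname(sds[as.character(profile$offset)])
  profile
}
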