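#' Background residue distribution from a dataset
#'
#' The expected frequency Q(a) used for neighbor-preference profiles:
#' the observed frequencies of the 20 canonical residues over the scoped
#' part of the dataset -- all residues, the residues lying in one
#' secondary-structure class, or the residues of records carrying one
#' group label.  Unknown symbols are excluded from numerator and
#' denominator.
#'
#' @param records List of [protein_record].
#' @param structure Optional structure class (`"H"`, `"E"` or `"C"`):
#'   restrict to residues whose track letter matches.
#' @param group Optional group label: restrict to records with that
#'   label.
#' @param pseudocount If `TRUE`, add 0.5 to every residue count before
#'   normalizing, so no background frequency is exactly zero.
#' @return A `background_distribution` with `mode = "global"`.
#' @export
background_from_records <- function(records, structure = NULL, group = NULL,
                                    pseudocount = FALSE) {
  check_records(records)
  if (!is.null(group)) {
    keep <- vapply(records, function(r)
      !is.null(r$group_label) && r$group_label == group, logical(1))
    records <- records[keep]
    if (length(records) == 0L) stop("no record has group label '", group, "'")
  }
  counts <- aa_zero_counts()
  for (rec in records) {
    ch <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
    if (!is.null(structure)) {
      stopifnot(structure %in% STRUCTURE_CLASSES)
      if (is.null(rec$structure_track))
        stop("record '", rec$id, "' has no structure track")
      tr <- strsplit(rec$structure_track, "", fixed = TRUE)[[1]]
      ch <- ch[tr == structure]
    }
    tb <- table(factor(ch, levels = AA_ALPHABET))
    counts <- counts + as.integer(tb)
  }
  if (sum(counts) == 0L)
    stop("no canonical residue in the requested scope")
  if (pseudocount) counts <- counts + 0.5
  structure(
    list(mode = "global", q = counts / sum(counts)),
    class = "background_distribution"
  )
}

#' Per-offset background from the flanks of one residue type
#'
#' The substitution-specific background correction: for a substitution
#' X->Y the expected distribution at each flanking offset is the observed
#' distribution at the corresponding flanking offset of all occurrences
#' of the pre-substituted residue X in the reference dataset.  This
#' removes X's own neighbor preferences from the substitution profile.
#'
#' @param records Reference dataset (list of [protein_record]).
#' @param focal_aa The residue whose flanks define the background.
#' @param window Flanking sites per side.
#' @param structure Optional structure class: build the background from
#'   structure-stratified contexts ([extract_contexts_in_structure()]).
#' @param pseudocount If `TRUE`, add 0.5 to every count before
#'   normalizing.
#' @return A `background_distribution` with `mode = "per_offset"`; `q` is
#'   a 20 x 2W matrix with offset column names.
#' @export
per_offset_background <- function(records, focal_aa, window = 20L,
                                  structure = NULL, pseudocount = FALSE) {
  tab <- if (is.null(structure))
    extract_contexts(records, focal_aa, window)
  else
    extract_contexts_in_structure(records, focal_aa, structure, window)
  counts <- tab$counts
  if (pseudocount) counts <- counts + 0.5
  sums <- colSums(counts)
  if (any(sums == 0))
    stop("no counts at offset(s) ",
         paste(colnames(counts)[sums == 0], collapse = ", "),
         " of focal '", focal_aa, "': insufficient data for a per-offset ",
         "background")
  structure(
    list(mode = "per_offset", q = sweep(counts, 2L, sums, "/"),
         focal = focal_aa),
    class = "background_distribution"
  )
}

#' @export
print.background_distribution <- function(x, ...) {
  cat("<background_distribution> mode=", x$mode,
      if (x$mode == "per_offset") paste0(" focal=", x$focal,
                                         " offsets=", ncol(x$q)),
      "\n", sep = "")
  invisible(x)
}

# Background vectors for one side of a table, as a 20 x W matrix whose
# columns run left-to-right along the stored flanking strings
# (N side: offsets -W..-1; C side: offsets +1..+W).
background_side_matrix <- function(background, window, side) {
  stopifnot(inherits(background, "background_distribution"),
            side %in% c("N", "C"))
  if (background$mode == "global") {
    return(matrix(background$q, nrow = length(AA_ALPHABET), ncol = window,
                  dimnames = list(AA_ALPHABET, NULL)))
  }
  want <- if (side == "N") as.character(-window:-1) else as.character(1:window)
  missing <- setdiff(want, colnames(background$q))
  if (length(missing))
    stop("per-offset background lacks offset(s) ",
         paste(missing, collapse = ", "))
  background$q[, want, drop = FALSE]
}

#' One term of the per-residue relative entropy
#'
#' The contribution of a single residue to the relative entropy of a
#' flanking site: p * log2(p / q), with the limit convention that the
#' term is 0 when p = 0.  Negative values indicate under-representation
#' relative to the background.
#'
#' @param p_a Observed frequency of the residue at the site.
#' @param q_a Background frequency of the residue.
#' @return p_a * log2(p_a / q_a) (vectorized).
#' @export
component_entropy <- function(p_a, q_a) {
  stopifnot(all(p_a >= 0 & p_a <= 1), all(q_a >= 0 & q_a <= 1))
  bad <- p_a > 0 & q_a == 0
  if (any(bad))
    stop("observed frequency positive where background is zero",
         if (!is.null(names(p_a))) paste0(" (residue ",
           paste(names(p_a)[bad], collapse = ", "), ")"),
         "; use a pseudocount background")
  out <- numeric(length(p_a))
  pos <- p_a > 0
  out[pos] <- p_a[pos] * log2(p_a[pos] / q_a[pos])
  names(out) <- names(p_a)
  out
}

#' Relative entropy of one flanking site
#'
#' Converts a 20-vector of residue counts at one offset into observed
#' frequencies P(a) (normalized over the canonical counts only; unknown
#' symbols never enter the normalizer) and returns the per-residue
#' components p * log2(p/q) and their sum, the site's total relative
#' entropy.  The total is nonnegative and zero iff P equals Q.
#'
#' @param counts Named 20-vector of counts (AA_ALPHABET order).
#' @param background Named 20-vector of background frequencies.
#' @param n Optional side count for validation (`sum(counts) <= n`).
#' @return List with elements `total` and `components`.
#' @export
site_entropy <- function(counts, background, n = NULL) {
  stopifnot(length(counts) == length(AA_ALPHABET),
            length(background) == length(AA_ALPHABET),
            all(counts >= 0))
  tot <- sum(counts)
  if (tot == 0) stop("all residue counts are zero at this site")
  if (!is.null(n) && tot > n)
    stop("counts sum (", tot, ") exceeds the side count n (", n, ")")
  p <- counts / tot
  comp <- component_entropy(p, background)
  names(comp) <- AA_ALPHABET
  list(total = sum(comp), components = comp)
}

#' Flag outlier components with the Tukey 1.5 IQR rule
#'
#' Given the 20 per-residue relative-entropy components at one offset,
#' flags the residues lying above Q3 + 1.5 IQR (`"high"`: preferred
#' neighbors) or below Q1 - 1.5 IQR (`"low"`: avoided neighbors), the
#' boxplot-whisker convention.
#'
#' @param components Numeric vector of exactly 20 values (named by
#'   residue; if unnamed, AA_ALPHABET order is assumed).
#' @param quartile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return Data frame with columns `residue` and `direction`.
#' @export
component_outliers <- function(components, quartile_type = 7) {
  stopifnot(length(components) == length(AA_ALPHABET))
  if (is.null(names(components))) names(components) <- AA_ALPHABET
  qs <- stats::quantile(components, c(0.25, 0.75), type = quartile_type,
                        names = FALSE)
  iqr <- qs[2] - qs[1]
  hi <- components > qs[2] + 1.5 * iqr
  lo <- components < qs[1] - 1.5 * iqr
  out <- data.frame(
    residue = c(names(components)[hi], names(components)[lo]),
    direction = c(rep("high", sum(hi)), rep("low", sum(lo))),
    stringsAsFactors = FALSE
  )
  out[order(match(out$residue, AA_ALPHABET)), , drop = FALSE]
}

format_outliers <- function(out_df) {
  if (nrow(out_df) == 0L) return("")
  paste0(out_df$residue, ifelse(out_df$direction == "high", "+", "-"),
         collapse = ",")
}

parse_outliers <- function(s) {
  if (is.na(s) || s == "") return(data.frame(residue = character(0),
                                             direction = character(0)))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  data.frame(residue = substr(parts, 1L, 1L),
             direction = ifelse(substr(parts, 2L, 2L) == "+", "high", "low"),
             stringsAsFactors = FALSE)
}

new_entropy_profile <- function(df, focal, window) {
  structure(df, focal = focal, window = window,
            class = c("entropy_profile", "data.frame"))
}

#' Per-offset relative-entropy profile of a context table
#'
#' Computes, for every populated offset of a [context_count_table], the
#' total relative entropy of the observed flanking-site distribution
#' against the background, its 20 per-residue components, and the Tukey
#' outlier flags.  Offsets whose side has no contributing contexts are
#' absent from the profile (not reported as zero).  Thresholds and
#' bootstrap standard deviations are filled in later by
#' [annotate_significance()] and [bootstrap_sd()].
#'
#' @param table A [context_count_table].
#' @param background A `background_distribution` (global or per-offset).
#' @param quartile_type Quantile algorithm for the outlier rule.
#' @return An `entropy_profile`: a data frame with one row per populated
#'   offset (columns `offset`, `side`, `n_contexts`,
#'   `total_relative_entropy`, `threshold`, `bootstrap_sd`,
#'   `significant`, `outlier_residues`, and `comp_A` .. `comp_Y`),
#'   with attributes `focal` and `window`.
#' @export
entropy_profile <- function(table, background, quartile_type = 7) {
  stopifnot(inherits(table, "context_count_table"),
            inherits(background, "background_distribution"))
  W <- table$window
  if (sum(table$n_side) == 0L)
    stop("context table is empty on both sides")
  sides <- list(N = -W:-1, C = 1:W)
  rows <- list()
  for (side in c("N", "C")) {
    n <- table$n_side[[side]]
    if (n == 0L) next
    bg <- background_side_matrix(background, W, side)
    offs <- sides[[side]]
    for (j in seq_len(W)) {
      off <- offs[j]
      cnt <- table$counts[, as.character(off)]
      se <- site_entropy(cnt, bg[, j], n = n)
      out <- component_outliers(se$components, quartile_type)
      row <- data.frame(offset = off, side = side, n_contexts = n,
                        total_relative_entropy = se$total,
                        threshold = NA_real_, bootstrap_sd = NA_real_,
                        significant = NA, outlier_residues = format_outliers(out),
                        stringsAsFactors = FALSE)
      comp <- as.data.frame(as.list(se$components))
      names(comp) <- paste0("comp_", AA_ALPHABET)
      rows[[length(rows) + 1L]] <- cbind(row, comp)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$offset), , drop = FALSE]
  rownames(df) <- NULL
  new_entropy_profile(df, focal = table$focal, window = W)
}

#' @export
print.entropy_profile <- function(x, ...) {
  foc <- attr(x, "focal")
  cat("<entropy_profile> focal=", paste(foc, collapse = "->"),
      " window=", attr(x, "window"), ", ", nrow(x), " offsets\n", sep = "")
  want <- c("offset", "side", "n_contexts", "total_relative_entropy",
            "threshold", "significant", "outlier_residues")
  show <- as.data.frame(x)[, intersect(want, names(x)), drop = FALSE]
  print(show, row.names = FALSE)
  invisible(x)
}
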