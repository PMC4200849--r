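#' Infer substitution events from an aligned ancestor/descendant pair
#'
#' Walks the alignment columns and emits one event per column where both
#' rows hold canonical residues that differ.  Columns containing a gap
#' or an unknown residue in either row yield no event.  Positions are
#' 1-based in the ungapped ancestral sequence, and the flanking contexts
#' (up to `window` residues per side) are read from the ungapped
#' ancestral sequence -- the same sequence the substitution-specific
#' background correction is keyed to.
#'
#' @param pairs An [aligned_pair] or a list of them.
#' @param window Maximum context length retained per side (default 20).
#' @param drop_overlapping If `TRUE`, drop events whose window contains
#'   the position of another substitution in the same pair (strict
#'   mode; default `FALSE`, i.e. neighboring substituted columns stay in
#'   the context).
#' @return Data frame with columns `pair_id`, `branch_label`,
#'   `position`, `from_aa`, `to_aa`, `context_N`, `context_C`.
#' @export
infer_events <- function(pairs, window = 20L, drop_overlapping = FALSE) {
  if (inherits(pairs, "aligned_pair")) pairs <- list(pairs)
  window <- as.integer(window)
  out <- lapply(pairs, infer_events_one, window = window,
                drop_overlapping = drop_overlapping)
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- empty_events()
  rownames(df) <- NULL
  df
}

empty_events <- function() {
  data.frame(pair_id = character(0), branch_label = character(0),
             position = integer(0), from_aa = character(0),
             to_aa = character(0), context_N = character(0),
             context_C = character(0), stringsAsFactors = FALSE)
}

infer_events_one <- function(pair, window, drop_overlapping) {
  stopifnot(inherits(pair, "aligned_pair"))
  a <- strsplit(pair$ancestor, "", fixed = TRUE)[[1]]
  d <- strsplit(pair$descendant, "", fixed = TRUE)[[1]]
  anc_res <- a != "-"
  anc_pos <- cumsum(anc_res)           # ungapped ancestral coordinate
  ungapped <- paste0(a[anc_res], collapse = "")
  len <- nchar(ungapped)
  is_event <- anc_res & d != "-" & a != d &
    a %in% AA_ALPHABET & d %in% AA_ALPHABET
  idx <- which(is_event)
  if (length(idx) == 0L) return(NULL)
  pos <- anc_pos[idx]
  if (drop_overlapping && length(pos) > 1L) {
    keep <- vapply(seq_along(pos), function(i)
      all(abs(pos[-i] - pos[i]) > window), logical(1))
    idx <- idx[keep]
    pos <- pos[keep]
    if (length(idx) == 0L) return(NULL)
  }
  data.frame(
    pair_id = pair$pair_id,
    branch_label = if (is.null(pair$branch_label)) "" else pair$branch_label,
    position = pos,
    from_aa = a[idx],
    to_aa = d[idx],
    context_N = substring(ungapped, pmax(1L, pos - window), pos - 1L),
    context_C = substring(ungapped, pos + 1L, pmin(len, pos + window)),
    stringsAsFactors = FALSE
  )
}

#' Enumerate the 380 ordered substitution types
#'
#' All ordered pairs (X, Y) of distinct canonical residues, in stable
#' lexicographic order.
#'
#' @return Data frame with columns `from_aa` and `to_aa` (380 rows).
#' @export
enumerate_types <- function() {
  grid <- expand.grid(to_aa = AA_ALPHABET, from_aa = AA_ALPHABET,
                      stringsAsFactors = FALSE)[, c("from_aa", "to_aa")]
  grid <- grid[grid$from_aa != grid$to_aa, , drop = FALSE]
  grid <- grid[order(grid$from_aa, grid$to_aa), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Build a context count table from the events of one substitution type
#'
#' Applies the same per-side completeness rule as [extract_contexts()]:
#' an event contributes its N-side flank iff its ancestral context holds
#' at least `window` residues on that side, and symmetrically for the C
#' side.
#'
#' @param events Data frame of events, all of one type X->Y.
#' @param window Flanking sites per side (must not exceed the window the
#'   events were inferred with).
#' @return A [context_count_table] with `focal = c(X, Y)`.
#' @export
events_to_table <- function(events, window = 20L) {
  window <- as.integer(window)
  type <- unique(events[, c("from_aa", "to_aa")])
  if (nrow(type) > 1L)
    stop("events contain ", nrow(type), " substitution types; expected one")
  focal <- if (nrow(type) == 1L) c(type$from_aa, type$to_aa)
           else c(NA_character_, NA_character_)
  nN <- nchar(events$context_N)
  nC <- nchar(events$context_C)
  store_N <- substring(events$context_N[nN >= window],
                       nN[nN >= window] - window + 1L, nN[nN >= window])
  store_C <- substring(events$context_C[nC >= window], 1L, window)
  new_context_table(focal, window, store_N, store_C)
}

#' Context-dependence profile of one substitution type
#'
#' Computes the per-offset relative entropies of the flanking contexts
#' of X->Y events against the bias-correcting background: the per-offset
#' flanking distribution of all occurrences of the pre-substituted
#' residue X in the reference dataset.  A flat (non-significant) profile
#' therefore means the substitution is no more context-dependent than X
#' itself is neighbor-preferring.
#'
#' @param table [context_count_table] built by [events_to_table()].
#' @param reference_records Reference dataset defining the background
#'   (typically the ancestral proteome the events were called on).
#' @param structure Optional structure class for stratified analyses
#'   (background then uses structure-scoped contexts of X).
#' @param pseudocount Passed to [per_offset_background()].
#' @param quartile_type Quantile algorithm for the outlier rule.
#' @return An [entropy_profile()].
#' @export
substitution_profile <- function(table, reference_records, structure = NULL,
                                 pseudocount = FALSE, quartile_type = 7) {
  stopifnot(inherits(table, "context_count_table"))
  if (sum(table$n_side) == 0L)
    stop("substitution table is empty on both sides")
  from_aa <- table$focal[1]
  bg <- per_offset_background(reference_records, from_aa,
                              window = table$window, structure = structure,
                              pseudocount = pseudocount)
  entropy_profile(table, bg, quartile_type = quartile_type)
}

#' Filter substitution types by data size
#'
#' A type is retained iff the larger of its two side counts reaches
#' `min_events_per_side`.
#'
#' @param tables Named list of [context_count_table]s (one per type).
#' @param min_events_per_side Minimum side count (default 100).
#' @return Character vector of retained names.
#' @export
filter_types <- function(tables, min_events_per_side = 100L) {
  keep <- vapply(tables, function(t)
    max(t$n_side) >= min_events_per_side, logical(1))
  names(tables)[keep]
}

# Canonical label for a substitution type.
type_label <- function(from_aa, to_aa) paste0(from_aa, ">", to_aa)
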