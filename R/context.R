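#' @title Flanking-context count tables
#' @description
#' A `context_count_table` holds, for one focal residue type (or one
#' substitution type), the residue counts at every flanking offset
#' -W..-1 (N-terminal side) and +1..+W (C-terminal side), together with
#' the flanking strings themselves (`context_store`), which are retained
#' so that shuffle nulls and bootstrap resampling can operate on the raw
#' contexts.
#'
#' A focal occurrence contributes its N-side flank iff at least W
#' residues precede it, and its C-side flank iff at least W residues
#' follow it; the two sides are independent, so the two sides generally
#' have different numbers of contributing occurrences (`n_side`).
#' Unknown-residue symbols occupy window slots but are counted towards
#' no residue.
#' @name context_count_table
NULL

offset_labels <- function(window) {
  as.character(c(-window:-1, 1:window))
}

# Convert a vector of equal-length flanking strings into an integer
# matrix (rows = contexts, cols = positions left to right; 0 = unknown).
store_matrix <- function(store, window) {
  if (length(store) == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = window))
  ch <- unlist(strsplit(store, "", fixed = TRUE), use.names = FALSE)
  v <- match(ch, AA_ALPHABET)
  v[is.na(v)] <- 0L
  matrix(v, nrow = length(store), ncol = window, byrow = TRUE)
}

# Column-wise residue counts of a store matrix: 20 x window.
store_counts <- function(m) {
  apply(m, 2L, function(col) tabulate(col, nbins = length(AA_ALPHABET)))
}

new_context_table <- function(focal, window, store_N, store_C) {
  m_N <- store_matrix(store_N, window)
  m_C <- store_matrix(store_C, window)
  counts <- matrix(0L, nrow = length(AA_ALPHABET), ncol = 2L * window,
                   dimnames = list(AA_ALPHABET, offset_labels(window)))
  if (nrow(m_N)) counts[, seq_len(window)] <- store_counts(m_N)
  if (nrow(m_C)) counts[, window + seq_len(window)] <- store_counts(m_C)
  structure(
    list(focal = focal, window = as.integer(window), counts = counts,
         n_side = c(N = nrow(m_N), C = nrow(m_C)),
         context_store = list(N = store_N, C = store_C)),
    class = "context_count_table"
  )
}

#' @export
print.context_count_table <- function(x, ...) {
  cat("<context_count_table> focal=", paste(x$focal, collapse = "->"),
      " window=", x$window,
      " n_N=", x$n_side[["N"]], " n_C=", x$n_side[["C"]], "\n", sep = "")
  invisible(x)
}

#' Combine two context count tables
#'
#' Tables over the same focal type and window combine by concatenating
#' their context stores; counts add cell-wise.
#'
#' @param e1,e2 `context_count_table` objects.
#' @return A combined `context_count_table`.
#' @export
"+.context_count_table" <- function(e1, e2) {
  stopifnot(identical(e1$focal, e2$focal), e1$window == e2$window)
  new_context_table(e1$focal, e1$window,
                    c(e1$context_store$N, e2$context_store$N),
                    c(e1$context_store$C, e2$context_store$C))
}

# Core per-sequence extraction: flanking strings of the focal residue
# under the per-side completeness rule.
extract_from_sequence <- function(sequence, focal_idx, window) {
  x <- aa_ints(sequence)
  len <- length(x)
  pos <- which(x == focal_idx)
  pos_N <- pos[pos > window]
  pos_C <- pos[pos + window <= len]
  list(
    N = if (length(pos_N)) substring(sequence, pos_N - window, pos_N - 1L)
        else character(0),
    C = if (length(pos_C)) substring(sequence, pos_C + 1L, pos_C + window)
        else character(0)
  )
}

#' Extract flanking contexts of a focal residue
#'
#' Scans every record for occurrences of `focal_aa` and collects the W
#' residues on each side.  An occurrence contributes its N-side flank iff
#' at least W residues precede it and its C-side flank iff at least W
#' residues follow it (the sides are evaluated independently, so a single
#' occurrence may contribute one side only).  Unknown-residue symbols
#' occupy their window slot but are excluded from all counts.
#'
#' @param records List of [protein_record].
#' @param focal_aa One canonical residue letter.
#' @param window Number of flanking sites per side (default 20).
#' @param drop_unknown_contexts If `TRUE`, a flank containing the unknown
#'   symbol is discarded entirely instead of contributing its canonical
#'   residues (strict mode; default `FALSE`).
#' @return A [context_count_table].
#' @export
extract_contexts <- function(records, focal_aa, window = 20L,
                             drop_unknown_contexts = FALSE) {
  check_records(records)
  if (!is_canonical_aa(focal_aa))
    stop("focal_aa must be one of the 20 canonical residues, got '",
         focal_aa, "'")
  window <- as.integer(window)
  stopifnot(window >= 1L)
  f <- match(focal_aa, AA_ALPHABET)
  store_N <- vector("list", length(records))
  store_C <- vector("list", length(records))
  for (i in seq_along(records)) {
    fl <- extract_from_sequence(records[[i]]$sequence, f, window)
    store_N[[i]] <- fl$N
    store_C[[i]] <- fl$C
  }
  store_N <- unlist(store_N, use.names = FALSE)
  store_C <- unlist(store_C, use.names = FALSE)
  if (is.null(store_N)) store_N <- character(0)
  if (is.null(store_C)) store_C <- character(0)
  if (drop_unknown_contexts) {
    store_N <- store_N[!grepl(AA_UNKNOWN, store_N, fixed = TRUE)]
    store_C <- store_C[!grepl(AA_UNKNOWN, store_C, fixed = TRUE)]
  }
  new_context_table(focal_aa, window, store_N, store_C)
}

#' Segment a secondary-structure track into maximal runs
#'
#' @param track Character scalar over \{H, E, C\}.
#' @return Data frame with columns `class`, `start`, `end`: maximal
#'   single-class runs as 0-based half-open intervals that tile the
#'   track exactly.
#' @export
segmentize <- function(track) {
  stopifnot(is.character(track), length(track) == 1L, nchar(track) >= 1L)
  ch <- strsplit(track, "", fixed = TRUE)[[1]]
  if (!all(ch %in% STRUCTURE_CLASSES))
    stop("track contains letters outside H/E/C")
  r <- rle(ch)
  end <- cumsum(r$lengths)
  data.frame(class = r$values, start = end - r$lengths, end = end,
             stringsAsFactors = FALSE)
}

#' Extract contexts restricted to one secondary-structure class
#'
#' Like [extract_contexts()], but a focal occurrence and its flank must
#' lie entirely inside a single maximal segment of `structure_class`:
#' per-side completeness is evaluated within the segment, and flanks
#' never cross segment boundaries.
#'
#' @param records List of [protein_record]; every record needs a
#'   structure track.
#' @param focal_aa One canonical residue letter.
#' @param structure_class One of `"H"`, `"E"`, `"C"`.
#' @param window Flanking sites per side (default 6 for structure-
#'   stratified runs, reflecting typical segment lengths).
#' @param drop_unknown_contexts Strict unknown handling as in
#'   [extract_contexts()].
#' @return A [context_count_table].
#' @export
extract_contexts_in_structure <- function(records, focal_aa, structure_class,
                                          window = 6L,
                                          drop_unknown_contexts = FALSE) {
  check_records(records)
  if (!is_canonical_aa(focal_aa))
    stop("focal_aa must be one of the 20 canonical residues")
  stopifnot(structure_class %in% STRUCTURE_CLASSES)
  window <- as.integer(window)
  stopifnot(window >= 1L)
  f <- match(focal_aa, AA_ALPHABET)
  store_N <- list()
  store_C <- list()
  for (rec in records) {
    if (is.null(rec$structure_track))
      stop("record '", rec$id, "' has no structure track")
    segs <- segmentize(rec$structure_track)
    segs <- segs[segs$class == structure_class, , drop = FALSE]
    for (k in seq_len(nrow(segs))) {
      seg_seq <- substr(rec$sequence, segs$start[k] + 1L, segs$end[k])
      fl <- extract_from_sequence(seg_seq, f, window)
      store_N[[length(store_N) + 1L]] <- fl$N
      store_C[[length(store_C) + 1L]] <- fl$C
    }
  }
  store_N <- unlist(store_N, use.names = FALSE)
  store_C <- unlist(store_C, use.names = FALSE)
  if (is.null(store_N)) store_N <- character(0)
  if (is.null(store_C)) store_C <- character(0)
  if (drop_unknown_contexts) {
    store_N <- store_N[!grepl(AA_UNKNOWN, store_N, fixed = TRUE)]
    store_C <- store_C[!grepl(AA_UNKNOWN, store_C, fixed = TRUE)]
  }
  new_context_table(focal_aa, window, store_N, store_C)
}
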