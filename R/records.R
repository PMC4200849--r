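#' Construct a protein record
#'
#' The basic unit the analysis iterates over: an identifier, an amino-acid
#' sequence (already normalized to the canonical alphabet plus
#' [AA_UNKNOWN]), an optional per-residue secondary-structure track over
#' \{H, E, C\} and an optional group label (e.g. a cellular-location class).
#'
#' @param id Character scalar, unique within a dataset.
#' @param sequence Character scalar over the canonical alphabet plus the
#'   unknown symbol; non-canonical characters are normalized away.
#' @param structure_track Optional character scalar over \{H, E, C\},
#'   same length as `sequence`.
#' @param group_label Optional character scalar.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, structure_track = NULL,
                           group_label = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- as.character(normalize_sequence(sequence))
  if (nchar(sequence) < 1L)
    stop("record '", id, "': empty sequence")
  if (!is.null(structure_track)) {
    structure_track <- toupper(structure_track)
    if (nchar(structure_track) != nchar(sequence))
      stop("record '", id, "': structure track length ",
           nchar(structure_track), " != sequence length ", nchar(sequence))
    ch <- strsplit(structure_track, "", fixed = TRUE)[[1]]
    if (!all(ch %in% STRUCTURE_CLASSES))
      stop("record '", id, "': structure track contains letters outside H/E/C")
  }
  structure(
    list(id = id, sequence = sequence, structure_track = structure_track,
         group_label = group_label),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa",
      if (!is.null(x$structure_track)) ", with structure track",
      if (!is.null(x$group_label)) paste0(", group=", x$group_label),
      ")\n", sep = "")
  invisible(x)
}

# Validate that a list of records has unique ids; returns the list.
check_records <- function(records) {
  stopifnot(is.list(records), length(records) >= 1L)
  ids <- vapply(records, function(r) r$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record identifier(s): ", paste(unique(dup), collapse = ", "))
  records
}

#' Construct an aligned ancestor/descendant pair
#'
#' One branch of a pairwise comparison: the (gapped) ancestral and
#' descendant sequences of an alignment.  Both rows must have equal
#' length and no column may be a gap in both rows.
#'
#' @param pair_id Character scalar.
#' @param ancestor,descendant Gapped sequence strings (gap = `-`).
#' @param branch_label Optional character scalar.
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(pair_id, ancestor, descendant, branch_label = NULL) {
  stopifnot(is.character(pair_id), length(pair_id) == 1L)
  anc <- normalize_gapped(ancestor)
  des <- normalize_gapped(descendant)
  if (nchar(anc) != nchar(des))
    stop("pair '", pair_id, "': aligned lengths differ (",
         nchar(anc), " vs ", nchar(des), ")")
  a <- strsplit(anc, "", fixed = TRUE)[[1]]
  d <- strsplit(des, "", fixed = TRUE)[[1]]
  if (any(a == "-" & d == "-"))
    stop("pair '", pair_id, "': alignment column gapped in both rows")
  structure(
    list(pair_id = pair_id, ancestor = anc, descendant = des,
         branch_label = branch_label),
    class = "aligned_pair"
  )
}

# Normalize a gapped alignment row: keep '-', normalize residues.
normalize_gapped <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  res <- ch != "-"
  ch[res & !(ch %in% AA_ALPHABET)] <- AA_UNKNOWN
  paste0(ch, collapse = "")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair> ", x$pair_id, " (", nchar(x$ancestor), " columns)\n",
      sep = "")
  invisible(x)
}
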