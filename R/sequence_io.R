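#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a list of [protein_record]s.  Sequences are
#' upper-cased and characters outside the 20 canonical one-letter codes
#' are mapped to the unknown symbol [AA_UNKNOWN]; the number of replaced
#' characters is reported via a message and attached as the
#' `"n_replaced"` attribute of the result.
#'
#' The record identifier is the first whitespace-delimited token of the
#' description line and must be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @param quiet Suppress the replacement-count message.
#' @return List of `protein_record`, with attribute `n_replaced`.
#' @export
read_fasta <- function(path, quiet = FALSE) {
  seqs <- read_fasta_raw(path)
  ids <- names(seqs)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  n_replaced <- 0L
  records <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- normalize_sequence(seqs[[i]])
    n_replaced <- n_replaced + attr(s, "n_replaced")
    records[[i]] <- protein_record(ids[[i]], as.character(s))
  }
  if (n_replaced > 0L && !quiet)
    message(n_replaced, " non-canonical residue(s) replaced by '",
            AA_UNKNOWN, "'")
  attr(records, "n_replaced") <- n_replaced
  records
}

# Low-level FASTA reader: named character vector, names = first token of
# the description line.  Uses Biostrings for the parsing itself.
read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  out <- as.character(set)
  names(out) <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  out
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  check_records(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Attach secondary-structure tracks to records
#'
#' Reads a FASTA-like file whose entries carry per-residue secondary
#' structure letters (H = helix, E = strand, C = coil) under the same
#' identifiers as `records`, and attaches each track to its record.
#'
#' @param path Path to the FASTA-like track file.
#' @param records List of [protein_record].
#' @return The records, with `structure_track` filled in for each matched
#'   identifier.
#' @export
read_structure_tracks <- function(path, records) {
  check_records(records)
  tracks <- read_fasta_raw(path)
  ids <- vapply(records, function(r) r$id, character(1))
  unmatched <- setdiff(names(tracks), ids)
  if (length(unmatched))
    stop("track identifier(s) not present in records: ",
         paste(unmatched, collapse = ", "))
  for (i in seq_along(records)) {
    tr <- tracks[records[[i]]$id]
    if (is.na(tr)) next
    records[[i]] <- protein_record(records[[i]]$id, records[[i]]$sequence,
                                   structure_track = unname(tr),
                                   group_label = records[[i]]$group_label)
  }
  records
}

#' Write structure tracks to a FASTA-like file
#'
#' @param records List of [protein_record] with tracks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_tracks <- function(records, path) {
  has <- vapply(records, function(r) !is.null(r$structure_track), logical(1))
  recs <- records[has]
  if (length(recs) == 0L) stop("no record carries a structure track")
  set <- Biostrings::BStringSet(
    vapply(recs, function(r) r$structure_track, character(1)))
  names(set) <- vapply(recs, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read aligned ancestor/descendant pairs from paired FASTA
#'
#' Entries must come in consecutive couples: the ancestral row first,
#' then the descendant row, sharing a pair identifier.  Identifiers of
#' the form `pairid|role` (e.g. `">g1|anc"`, `">g1|desc"`) use the part
#' before the `|` as the pair id; otherwise the full identifier of the
#' first row of the couple is used.
#'
#' @param path Path to the paired FASTA file.
#' @return List of [aligned_pair].
#' @export
read_aligned_pairs <- function(path) {
  seqs <- read_fasta_raw(path)
  if (length(seqs) %% 2L != 0L)
    stop("paired FASTA has an odd number of entries (", length(seqs), ")")
  n <- length(seqs) %/% 2L
  pairs <- vector("list", n)
  for (k in seq_len(n)) {
    i <- 2L * k - 1L
    id_a <- names(seqs)[i]
    pid <- sub("\\|.*$", "", id_a)
    pairs[[k]] <- aligned_pair(pid, seqs[[i]], seqs[[i + 1L]])
  }
  pids <- vapply(pairs, function(p) p$pair_id, character(1))
  dup <- unique(pids[duplicated(pids)])
  if (length(dup))
    stop("duplicate pair identifier(s): ", paste(dup, collapse = ", "))
  pairs
}

#' Write aligned pairs to paired FASTA
#'
#' @param pairs List of [aligned_pair].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_pairs <- function(pairs, path) {
  seqs <- character(2L * length(pairs))
  nms <- character(2L * length(pairs))
  for (k in seq_along(pairs)) {
    seqs[2L * k - 1L] <- pairs[[k]]$ancestor
    seqs[2L * k] <- pairs[[k]]$descendant
    nms[2L * k - 1L] <- paste0(pairs[[k]]$pair_id, "|anc")
    nms[2L * k] <- paste0(pairs[[k]]$pair_id, "|desc")
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- nms
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

profile_tsv_columns <- function() {
  c("offset", "side", "n_contexts", "total_relative_entropy", "threshold",
    "bootstrap_sd", "significant", "outlier_residues",
    paste0("comp_", AA_ALPHABET))
}

#' Write an entropy profile to TSV
#'
#' One row per populated offset with the per-offset total relative
#' entropy, its significance threshold and flag, the bootstrap standard
#' deviation, the flagged outlier residues (comma-joined, suffixed
#' `+`/`-` for high/low) and the 20 per-residue components.  Numeric
#' fields are written with full precision so the file round-trips.
#'
#' @param profile An [entropy_profile] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "entropy_profile"))
  df <- as.data.frame(profile)
  cols <- profile_tsv_columns()
  df <- df[, cols, drop = FALSE]
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.15g", df[[nm]])
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write profile TSV to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read an entropy profile TSV back
#'
#' Inverse of [write_profile_tsv()]; restores the per-offset table
#' (metadata such as the focal residue is not stored in the TSV and is
#' taken from arguments).
#'
#' @param path Path to the TSV.
#' @param focal Focal residue or substitution label to attach.
#' @return An [entropy_profile].
#' @export
read_profile_tsv <- function(path, focal = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  cols <- profile_tsv_columns()
  if (!identical(names(df), cols))
    stop("unexpected profile TSV columns in ", path)
  num <- setdiff(cols, c("side", "significant", "outlier_residues"))
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df$offset <- as.integer(df$offset)
  df$n_contexts <- as.integer(df$n_contexts)
  df$significant <- df$significant == "TRUE"
  new_entropy_profile(df, focal = focal,
                      window = if (nrow(df)) max(abs(df$offset)) else NA_integer_)
}

#' Write a substitution-event table to TSV
#'
#' @param events Data frame of substitution events (see [infer_events()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("pair_id", "branch_label", "position", "from_aa", "to_aa",
            "context_N", "context_C")
  stopifnot(all(cols %in% names(events)))
  utils::write.table(events[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a substitution-event table from TSV
#'
#' @param path Path to a TSV written by [write_events_tsv()].
#' @return Data frame of substitution events.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  df$position <- as.integer(df$position)
  df$context_N[is.na(df$context_N)] <- ""
  df$context_C[is.na(df$context_C)] <- ""
  df
}
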