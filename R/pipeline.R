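#' Analysis run configuration
#'
#' Collects every tunable of the pipeline in one serializable object.
#'
#' @param window Flanking sites per side (20 for whole-sequence runs,
#'   6 for structure-stratified runs).
#' @param alpha Significance level of the shuffle threshold.
#' @param repeats Shuffle rounds per null.
#' @param n_boot Bootstrap replicates (0 disables bootstrap SDs).
#' @param min_events_per_side Data-size filter for substitution types.
#' @param pseudocount Add 0.5 to background counts before normalizing.
#' @param quartile_type Quantile algorithm for the outlier rule.
#' @param shuffle_mode `"per_string"` or `"global"` (see
#'   [shuffle_null()]).
#' @param drop_unknown_contexts Strict unknown-residue handling.
#' @param drop_overlapping Drop substitution events with another
#'   substitution inside their window.
#' @param seed Master RNG seed; per-task sub-seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(window = 20L, alpha = 0.001, repeats = 500L,
                       n_boot = 100L, min_events_per_side = 100L,
                       pseudocount = FALSE, quartile_type = 7L,
                       shuffle_mode = "per_string",
                       drop_unknown_contexts = FALSE,
                       drop_overlapping = FALSE, seed = NULL) {
  cfg <- list(window = as.integer(window), alpha = alpha,
              repeats = as.integer(repeats), n_boot = as.integer(n_boot),
              min_events_per_side = as.integer(min_events_per_side),
              pseudocount = pseudocount,
              quartile_type = as.integer(quartile_type),
              shuffle_mode = shuffle_mode,
              drop_unknown_contexts = drop_unknown_contexts,
              drop_overlapping = drop_overlapping, seed = seed)
  stopifnot(cfg$window >= 1L, cfg$alpha > 0, cfg$alpha < 1,
            cfg$repeats >= 1L, cfg$n_boot >= 0L,
            cfg$shuffle_mode %in% c("per_string", "global"))
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [run_config()].
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

# Deterministic sub-seed derived from the master seed and a string key,
# kept below 2^31.
derive_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 31) %% 2147483629)
}

write_manifest <- function(output_dir, command, params, config = NULL) {
  manifest <- list(
    package = "aacontext",
    version = as.character(utils::packageVersion("aacontext")),
    command = command,
    parameters = params,
    config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

# Shared per-focal significance machinery: profile + nulls + SDs.
profile_with_significance <- function(table, background, config, seed_key) {
  prof <- entropy_profile(table, background,
                          quartile_type = config$quartile_type)
  nulls <- list()
  for (side in c("N", "C")) {
    if (table$n_side[[side]] == 0L) next
    nulls[[side]] <- shuffle_null(
      table, side, background, repeats = config$repeats,
      alpha = config$alpha, mode = config$shuffle_mode,
      seed = derive_seed(config$seed, paste0("shuffle/", seed_key, "/", side)))
  }
  sds <- NULL
  if (config$n_boot > 0L)
    sds <- bootstrap_sd(table, background, n_boot = config$n_boot,
                        seed = derive_seed(config$seed,
                                           paste0("boot/", seed_key)))
  list(profile = annotate_significance(prof, nulls, sds), nulls = nulls)
}

summarize_profile <- function(prof) {
  tot <- prof$total_relative_entropy
  i <- which.max(tot)
  data.frame(
    n_N = if (any(prof$side == "N")) prof$n_contexts[prof$side == "N"][1] else 0L,
    n_C = if (any(prof$side == "C")) prof$n_contexts[prof$side == "C"][1] else 0L,
    max_offset = prof$offset[i],
    max_total = tot[i],
    n_significant = sum(prof$significant, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Neighbor-preference analysis over a dataset
#'
#' For each focal residue: extract flanking contexts (whole-sequence or
#' within one secondary-structure class), compute the relative-entropy
#' profile against the dataset-wide background, attach shuffle
#' thresholds and bootstrap SDs, and flag outlier residues.  The
#' summary lists, per focal residue, the offset of maximal total
#' relative entropy and the number of significant offsets.
#'
#' @param records List of [protein_record].
#' @param config A [run_config()].
#' @param focal Focal residues to analyze (default all 20).
#' @param structure Optional structure class; uses structure-stratified
#'   extraction and a structure-scoped background.
#' @param group Optional group label restricting the dataset (records
#'   and background).
#' @param output_dir Optional directory: per-focal profile TSVs, the
#'   summary TSV and a manifest are written there.
#' @return List with `profiles` (named list of annotated
#'   [entropy_profile()]s), `summary` (data frame) and `background`.
#' @export
run_neighbors <- function(records, config = run_config(),
                          focal = AA_ALPHABET, structure = NULL,
                          group = NULL, output_dir = NULL) {
  check_records(records)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(group)) {
    keep <- vapply(records, function(r)
      !is.null(r$group_label) && r$group_label == group, logical(1))
    records <- records[keep]
    if (!length(records)) stop("no record has group label '", group, "'")
  }
  bg <- background_from_records(records, structure = structure,
                                pseudocount = config$pseudocount)
  profiles <- list()
  rows <- list()
  for (aa in focal) {
    tab <- if (is.null(structure))
      extract_contexts(records, aa, config$window,
                       drop_unknown_contexts = config$drop_unknown_contexts)
    else
      extract_contexts_in_structure(records, aa, structure, config$window,
                                    drop_unknown_contexts =
                                      config$drop_unknown_contexts)
    if (sum(tab$n_side) == 0L) {
      warning("no complete context for focal '", aa, "'; skipped")
      next
    }
    res <- profile_with_significance(tab, bg, config, seed_key = aa)
    profiles[[aa]] <- res$profile
    rows[[aa]] <- cbind(data.frame(focal = aa, stringsAsFactors = FALSE),
                        summarize_profile(res$profile))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (aa in names(profiles))
      write_profile_tsv(profiles[[aa]],
                        file.path(output_dir,
                                  paste0("neighbors_", aa, ".tsv")))
    utils::write.table(summary, file.path(output_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(output_dir, "neighbors",
                   list(n_records = length(records),
                        focal = focal, structure = structure, group = group),
                   config)
  }
  list(profiles = profiles, summary = summary, background = bg)
}

# Keep only events whose ancestral focal residue lies in a segment of
# the requested structure class (tracks come from the reference records,
# matched by pair_id).
filter_events_by_structure <- function(events, records, structure) {
  tracks <- stats::setNames(
    lapply(records, function(r) r$structure_track),
    vapply(records, function(r) r$id, character(1)))
  keep <- vapply(seq_len(nrow(events)), function(i) {
    tr <- tracks[[events$pair_id[i]]]
    !is.null(tr) && substr(tr, events$position[i], events$position[i]) ==
      structure
  }, logical(1))
  events[keep, , drop = FALSE]
}

#' Context-dependence analysis of amino-acid substitutions
#'
#' Infers substitution events from aligned pairs (or consumes a
#' precomputed event table), builds per-type context tables, filters
#' types by data size, and computes each retained type's relative-
#' entropy profile against the bias-correcting per-offset background of
#' its pre-substituted residue, with shuffle thresholds.  A type is
#' called context dependent iff at least one offset is significant; the
#' per-type number of significant offsets is also reported for stricter
#' user-defined calls.
#'
#' @param reference_records Reference dataset for the backgrounds
#'   (typically the ancestral proteome).
#' @param pairs List of [aligned_pair] (ignored if `events` given).
#' @param events Precomputed event data frame (see [infer_events()]).
#' @param config A [run_config()].
#' @param structure Optional structure class (reference records need
#'   tracks; events are restricted to focal residues in that class).
#' @param types Optional data frame (`from_aa`, `to_aa`) restricting the
#'   analyzed types.
#' @param output_dir Optional output directory for per-type TSVs,
#'   summary and manifest.
#' @return List with `profiles` (named by type label, e.g. `"S>P"`),
#'   `summary` (data frame with `context_dependent` flag) and `events`.
#' @export
run_substitutions <- function(reference_records, pairs = NULL, events = NULL,
                              config = run_config(), structure = NULL,
                              types = NULL, output_dir = NULL) {
  check_records(reference_records)
  stopifnot(inherits(config, "run_config"))
  if (is.null(events)) {
    if (is.null(pairs)) stop("supply either pairs or events")
    events <- infer_events(pairs, window = max(20L, config$window),
                           drop_overlapping = config$drop_overlapping)
  }
  if (!is.null(structure) && nrow(events))
    events <- filter_events_by_structure(events, reference_records, structure)
  if (nrow(events) == 0L) {
    warning("empty event set; nothing to analyze")
    return(list(profiles = list(), summary = empty_subst_summary(),
                events = events))
  }
  if (is.null(types)) {
    types <- unique(events[, c("from_aa", "to_aa")])
  }
  tables <- list()
  for (k in seq_len(nrow(types))) {
    sel <- events$from_aa == types$from_aa[k] &
           events$to_aa == types$to_aa[k]
    if (!any(sel)) next
    tables[[type_label(types$from_aa[k], types$to_aa[k])]] <-
      events_to_table(events[sel, , drop = FALSE], config$window)
  }
  retained <- filter_types(tables, config$min_events_per_side)
  profiles <- list()
  rows <- list()
  bg_cache <- list()
  for (lab in retained) {
    tab <- tables[[lab]]
    from_aa <- tab$focal[1]
    if (is.null(bg_cache[[from_aa]]))
      bg_cache[[from_aa]] <- per_offset_background(
        reference_records, from_aa, window = config$window,
        structure = structure, pseudocount = config$pseudocount)
    res <- profile_with_significance(tab, bg_cache[[from_aa]], config,
                                     seed_key = lab)
    profiles[[lab]] <- res$profile
    s <- summarize_profile(res$profile)
    rows[[lab]] <- cbind(
      data.frame(type = lab, from_aa = from_aa, to_aa = tab$focal[2],
                 stringsAsFactors = FALSE),
      s,
      data.frame(context_dependent = s$n_significant >= 1L))
  }
  summary <- do.call(rbind, rows)
  if (is.null(summary)) summary <- empty_subst_summary()
  rownames(summary) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(profiles))
      write_profile_tsv(profiles[[lab]],
                        file.path(output_dir,
                                  paste0("substitution_",
                                         gsub(">", "_to_", lab), ".tsv")))
    utils::write.table(summary, file.path(output_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_events_tsv(events, file.path(output_dir, "events.tsv"))
    write_manifest(output_dir, "substitutions",
                   list(n_events = nrow(events), structure = structure),
                   config)
  }
  list(profiles = profiles, summary = summary, events = events)
}

empty_subst_summary <- function() {
  data.frame(type = character(0), from_aa = character(0),
             to_aa = character(0), n_N = integer(0), n_C = integer(0),
             max_offset = integer(0), max_total = numeric(0),
             n_significant = integer(0), context_dependent = logical(0))
}

#' Generate a synthetic dataset and write it to disk
#'
#' Thin driver over the generators: writes FASTA (plus tracks / paired
#' FASTA / truth TSV as applicable) and a manifest recording the seed
#' and parameters, so runs are reproducible byte for byte.
#'
#' @param generator One of `"iid"`, `"collagen"`, `"self-clustering"`,
#'   `"helix-pairing"`, `"context-subs"`.
#' @param output_dir Output directory (created if needed).
#' @param config A [generator_config()].
#' @param ... Generator-specific parameters (e.g. `collagen_fraction`,
#'   `pair`, `rule`, `base_rate`).
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(generator, output_dir, config, ...) {
  generators <- c("iid", "collagen", "self-clustering", "helix-pairing",
                  "context-subs")
  if (!generator %in% generators)
    stop("unknown generator '", generator, "'; valid names: ",
         paste(generators, collapse = ", "))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  args <- list(...)
  files <- c(sequences = file.path(output_dir, "sequences.fasta"))
  if (generator == "iid") {
    records <- gen_iid(config)
    write_fasta(records, files[["sequences"]])
  } else if (generator == "collagen") {
    res <- do.call(gen_collagen_mix, c(list(config), args))
    write_fasta(res$records, files[["sequences"]])
    files[["truth"]] <- file.path(output_dir, "truth.tsv")
    utils::write.table(res$truth, files[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (generator == "self-clustering") {
    res <- do.call(gen_self_clustering, c(list(config), args))
    write_fasta(res$records, files[["sequences"]])
    files[["truth"]] <- file.path(output_dir, "truth.tsv")
    utils::write.table(res$truth, files[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (generator == "helix-pairing") {
    res <- do.call(gen_helix_pairing, c(list(config), args))
    write_fasta(res$records, files[["sequences"]])
    files[["tracks"]] <- file.path(output_dir, "tracks.fasta")
    write_structure_tracks(res$records, files[["tracks"]])
  } else if (generator == "context-subs") {
    anc_args <- args[names(args) %in% c("base_rate", "rule", "window", "seed")]
    ancestors <- gen_iid(config)
    res <- do.call(gen_context_substitutions, c(list(ancestors), anc_args))
    write_fasta(ancestors, files[["sequences"]])
    files[["pairs"]] <- file.path(output_dir, "pairs.fasta")
    write_aligned_pairs(res$pairs, files[["pairs"]])
    files[["truth"]] <- file.path(output_dir, "truth_events.tsv")
    write_events_tsv(res$events, files[["truth"]])
  }
  write_manifest(output_dir, paste0("simulate/", generator),
                 c(list(n_sequences = config$n_sequences,
                        min_length = config$min_length,
                        max_length = config$max_length,
                        seed = config$seed),
                   args[!vapply(args, is.list, logical(1))]))
  invisible(files)
}
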