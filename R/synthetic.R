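#' Configuration for the synthetic-sequence generators
#'
#' @param n_sequences Number of records to generate.
#' @param min_length,max_length Sequence lengths are drawn
#'   uniform-integer in `[min_length, max_length]` (defaults 150-400, so
#'   full 20-site windows exist in every sequence).
#' @param composition Named 20-vector of residue frequencies
#'   (AA_ALPHABET order; default uniform).  Must sum to 1.
#' @param seed Optional RNG seed; generators restore the caller's RNG
#'   state.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sequences, min_length = 150L,
                             max_length = 400L,
                             composition = NULL, seed = NULL) {
  if (is.null(composition))
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(length(composition) == 20L, all(composition >= 0),
            abs(sum(composition) - 1) < 1e-9,
            n_sequences >= 1L, min_length >= 1L, max_length >= min_length)
  if (is.null(names(composition))) names(composition) <- AA_ALPHABET
  structure(
    list(n_sequences = as.integer(n_sequences),
         min_length = as.integer(min_length),
         max_length = as.integer(max_length),
         composition = composition, seed = seed),
    class = "generator_config"
  )
}

sample_lengths <- function(config) {
  sample(config$min_length:config$max_length, config$n_sequences,
         replace = TRUE)
}

sample_chars <- function(n, composition) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = composition)
}

make_records <- function(seqs, prefix = "seq", tracks = NULL) {
  lapply(seq_along(seqs), function(i)
    protein_record(sprintf("%s_%05d", prefix, i), seqs[[i]],
                   structure_track = tracks[[i]]))
}

#' Generate i.i.d. sequences (the positional null)
#'
#' Residues drawn independently from the configured composition; no
#' positional structure whatsoever, so every flanking-site relative
#' entropy is pure sampling noise.  Used to calibrate the shuffle
#' thresholds.
#'
#' @param config A [generator_config()].
#' @return List of [protein_record].
#' @export
gen_iid <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_rng_seed(config$seed, {
    lens <- sample_lengths(config)
    seqs <- vapply(lens, function(L)
      paste0(sample_chars(L, config$composition), collapse = ""),
      character(1))
    make_records(seqs)
  })
}

#' Generate a mixture with collagen-like (G-X-Y)n repeats
#'
#' A designated fraction of records carries one (G-X-Y)n block -- G at
#' every third position, X and Y drawn from the composition excluding G
#' -- embedded at a random position inside otherwise i.i.d. sequence.
#' This reproduces the hallmark of collagen triple-helix domains: a 3n-
#' periodic glycine signal in the flanks of G.
#'
#' @param config A [generator_config()].
#' @param collagen_fraction Fraction of records containing a repeat
#'   block.
#' @param n_repeats Number of G-X-Y triplets per block (default 30, a
#'   modest triple-helical domain).
#' @return List with `records` and `truth` (data frame: `id`,
#'   `is_collagen`, `block_start`, `block_end`, 1-based inclusive).
#' @export
gen_collagen_mix <- function(config, collagen_fraction, n_repeats = 30L) {
  stopifnot(inherits(config, "generator_config"),
            collagen_fraction >= 0, collagen_fraction <= 1, n_repeats >= 1L)
  block_len <- 3L * as.integer(n_repeats)
  comp_noG <- config$composition
  comp_noG["G"] <- 0
  comp_noG <- comp_noG / sum(comp_noG)
  with_rng_seed(config$seed, {
    n <- config$n_sequences
    n_col <- round(collagen_fraction * n)
    is_col <- seq_len(n) <= n_col       # ids are arbitrary; no need to shuffle
    lens <- pmax(sample_lengths(config), block_len + 2L)
    seqs <- character(n)
    start <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (!is_col[i]) {
        seqs[i] <- paste0(sample_chars(lens[i], config$composition),
                          collapse = "")
        next
      }
      xy <- matrix(sample(AA_ALPHABET, 2L * n_repeats, replace = TRUE,
                          prob = comp_noG), ncol = 2L)
      block <- paste0("G", xy[, 1L], xy[, 2L], collapse = "")
      flank_total <- lens[i] - block_len
      s <- sample.int(flank_total + 1L, 1L)   # residues before the block + 1
      left <- paste0(sample_chars(s - 1L, config$composition), collapse = "")
      right <- paste0(sample_chars(flank_total - (s - 1L),
                                   config$composition), collapse = "")
      seqs[i] <- paste0(left, block, right)
      start[i] <- s
    }
    records <- make_records(seqs)
    truth <- data.frame(
      id = vapply(records, function(r) r$id, character(1)),
      is_collagen = is_col,
      block_start = start,
      block_end = ifelse(is_col, start + block_len - 1L, NA_integer_),
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

#' Generate sequences with planted homopolymer runs
#'
#' Inserts Poisson-placed runs of one residue into i.i.d. background --
#' the self-clustering pattern that replication slippage produces in
#' real proteomes and that makes a residue its own preferred neighbor.
#'
#' @param config A [generator_config()].
#' @param run_aa The residue forming the runs.
#' @param run_rate Expected number of runs per residue of sequence
#'   (per-position Poisson intensity).
#' @param run_length Length of each run (default 4).
#' @return List with `records` and `truth` (data frame: `id`, `start`,
#'   `end` per planted run, 1-based inclusive).
#' @export
gen_self_clustering <- function(config, run_aa, run_rate, run_length = 4L) {
  stopifnot(inherits(config, "generator_config"), is_canonical_aa(run_aa),
            run_rate >= 0, run_length >= 1L)
  run_length <- as.integer(run_length)
  with_rng_seed(config$seed, {
    lens <- sample_lengths(config)
    seqs <- character(config$n_sequences)
    truth <- list()
    for (i in seq_len(config$n_sequences)) {
      ch <- sample_chars(lens[i], config$composition)
      n_runs <- stats::rpois(1L, run_rate * lens[i])
      if (n_runs > 0L && lens[i] >= run_length) {
        starts <- sample.int(lens[i] - run_length + 1L, n_runs,
                             replace = TRUE)
        for (s in starts) ch[s:(s + run_length - 1L)] <- run_aa
        truth[[length(truth) + 1L]] <- data.frame(
          id = sprintf("seq_%05d", i), start = starts,
          end = starts + run_length - 1L, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste0(ch, collapse = "")
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(id = character(0), start = integer(0),
                             end = integer(0))
    list(records = make_records(seqs), truth = truth)
  })
}

#' Generate helical sequences with a planted i,i+d pairing
#'
#' Sequences are built left to right from the configured composition,
#' except that whenever the residue d positions upstream is X, the
#' probability of Y at the current position is multiplied by
#' `enrichment` (renormalized).  All records carry an all-H structure
#' track, so structure-stratified extraction sees each sequence as one
#' helix segment.  This emulates the i,i+3 / i,i+4 side-chain pairings
#' of alpha-helices.
#'
#' @param config A [generator_config()].
#' @param pair Character vector `c(X, Y)`.
#' @param offset_d Spacing d (3 or 4 for helical pairings).
#' @param enrichment Multiplier (>= 1) on Y's probability after an X.
#' @return List with `records` (all-H tracks) and `truth` (the planted
#'   parameters).
#' @export
gen_helix_pairing <- function(config, pair, offset_d = 4L, enrichment = 5) {
  stopifnot(inherits(config, "generator_config"), length(pair) == 2L,
            is_canonical_aa(pair[1]), is_canonical_aa(pair[2]),
            offset_d >= 1L, enrichment >= 1)
  d <- as.integer(offset_d)
  comp_mod <- config$composition
  comp_mod[pair[2]] <- comp_mod[pair[2]] * enrichment
  comp_mod <- comp_mod / sum(comp_mod)
  with_rng_seed(config$seed, {
    lens <- sample_lengths(config)
    seqs <- character(config$n_sequences)
    for (i in seq_len(config$n_sequences)) {
      L <- lens[i]
      zbase <- sample_chars(L, config$composition)
      zmod <- sample_chars(L, comp_mod)
      z <- zbase
      if (L > d) {
        for (j in (d + 1L):L)
          if (z[j - d] == pair[1]) z[j] <- zmod[j]
      }
      seqs[i] <- paste0(z, collapse = "")
    }
    tracks <- lapply(lens, function(L) strrep("H", L))
    list(records = make_records(seqs, tracks = tracks),
         truth = list(pair = pair, offset_d = d, enrichment = enrichment))
  })
}

#' Simulate neighbor-conditioned substitutions on ancestral sequences
#'
#' Every ancestral residue substitutes independently: residues equal to
#' `rule$from_aa` substitute to `rule$to_aa` with probability
#' `base_rate * rule$multiplier` when the residue at signed offset
#' `rule$neighbor_offset` equals `rule$neighbor_aa`, and with
#' `base_rate` otherwise; every other canonical residue substitutes to
#' a uniformly chosen different residue with probability `base_rate`.
#' Alignments are gapless, so [infer_events()] recovers the true event
#' list exactly.
#'
#' @param ancestors List of [protein_record] (the ancestral sequences).
#' @param base_rate Per-site substitution probability in (0, 1).
#' @param rule List with `from_aa`, `to_aa`, `neighbor_offset` (signed,
#'   nonzero), `neighbor_aa`, `multiplier` (>= 0).  `multiplier = 1`
#'   makes the rule residue context-independent (negative control).
#' @param window Context length stored in the truth table (default 20).
#' @param seed Optional RNG seed.
#' @return List with `pairs` (list of [aligned_pair]) and `events` (the
#'   true event table, same columns as [infer_events()]).
#' @export
gen_context_substitutions <- function(ancestors, base_rate, rule,
                                      window = 20L, seed = NULL) {
  check_records(ancestors)
  stopifnot(base_rate > 0, base_rate < 1,
            is_canonical_aa(rule$from_aa), is_canonical_aa(rule$to_aa),
            rule$from_aa != rule$to_aa,
            rule$neighbor_offset != 0, is_canonical_aa(rule$neighbor_aa),
            rule$multiplier >= 0)
  if (base_rate * rule$multiplier > 1)
    stop("base_rate * multiplier exceeds 1 (",
         base_rate * rule$multiplier, ")")
  d <- as.integer(rule$neighbor_offset)
  with_rng_seed(seed, {
    pairs <- vector("list", length(ancestors))
    events <- vector("list", length(ancestors))
    for (i in seq_along(ancestors)) {
      rec <- ancestors[[i]]
      ch <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
      L <- length(ch)
      canonical <- ch %in% AA_ALPHABET
      is_from <- ch == rule$from_aa
      neigh <- rep(FALSE, L)
      src <- seq_len(L) + d
      ok <- src >= 1L & src <= L
      neigh[ok] <- ch[src[ok]] == rule$neighbor_aa
      p <- ifelse(canonical, base_rate, 0)
      p[is_from & neigh] <- base_rate * rule$multiplier
      hit <- stats::runif(L) < p
      dch <- ch
      idx <- which(hit)
      for (j in idx) {
        dch[j] <- if (is_from[j]) rule$to_aa
                  else sample(setdiff(AA_ALPHABET, ch[j]), 1L)
      }
      pairs[[i]] <- aligned_pair(rec$id, rec$sequence,
                                 paste0(dch, collapse = ""))
      if (length(idx)) {
        events[[i]] <- data.frame(
          pair_id = rec$id, branch_label = "",
          position = idx, from_aa = ch[idx], to_aa = dch[idx],
          context_N = substring(rec$sequence, pmax(1L, idx - window),
                                idx - 1L),
          context_C = substring(rec$sequence, idx + 1L,
                                pmin(L, idx + window)),
          stringsAsFactors = FALSE)
      }
    }
    ev <- do.call(rbind, events)
    if (is.null(ev)) ev <- empty_events()
    rownames(ev) <- NULL
    list(pairs = pairs, events = ev)
  })
}
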