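# Shared fixtures for the test suite.  Everything is built in code; no
# data files.

records_from <- function(...) {
  seqs <- c(...)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("p%d", seq_along(seqs))
  lapply(seq_along(seqs), function(i) protein_record(ids[i], seqs[[i]]))
}

uniform_background <- function() {
  structure(list(mode = "global",
                 q = stats::setNames(rep(0.05, 20), AA_ALPHABET)),
            class = "background_distribution")
}

# Independent term-by-term evaluation of the per-site relative entropy,
# written deliberately as a plain loop over the 20 residues with
# natural-log arithmetic, as an oracle for the vectorized path.
oracle_site_entropy <- function(counts, q) {
  n <- 0
  for (a in seq_len(20)) n <- n + counts[a]
  total <- 0
  comps <- numeric(20)
  for (a in seq_len(20)) {
    p <- counts[a] / n
    if (p > 0) {
      comps[a] <- p * (log(p) - log(q[a])) / log(2)
      total <- total + comps[a]
    }
  }
  list(total = total, components = comps)
}

# Random small count table + strictly positive background.
random_site <- function() {
  counts <- stats::rpois(20, lambda = stats::runif(1, 0.5, 5))
  if (sum(counts) == 0) counts[sample.int(20, 1)] <- 1L
  q <- stats::rgamma(20, shape = 1) + 1e-3
  q <- q / sum(q)
  list(counts = stats::setNames(counts, AA_ALPHABET), q = q)
}
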