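test_that("infer_events finds mismatching canonical columns", {
  ev <- infer_events(aligned_pair("g1", "ACDEFG", "ACNEFG"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$position, 3L)
  expect_equal(ev$from_aa, "D")
  expect_equal(ev$to_aa, "N")
  expect_equal(ev$context_N, "AC")
  expect_equal(ev$context_C, "EFG")

  # insertion column yields no event
  expect_equal(nrow(infer_events(aligned_pair("g1", "AC-EF", "ACDEF"))), 0L)
  # deletion column yields no event
  expect_equal(nrow(infer_events(aligned_pair("g1", "ACDEF", "AC-EF"))), 0L)
  # identical rows
  expect_equal(nrow(infer_events(aligned_pair("g1", "ACDEF", "ACDEF"))), 0L)
  # unknown residues in either row yield no event
  expect_equal(nrow(infer_events(aligned_pair("g1", "AXDEF", "ACDEF"))), 0L)
  expect_equal(nrow(infer_events(aligned_pair("g1", "ACDEF", "AXDEF"))), 0L)
})

test_that("event positions and contexts use ungapped ancestral coordinates", {
  # alignment: ancestor A-CDEF, descendant AGCDEW; ungapped ancestor ACDEF
  ev <- infer_events(aligned_pair("g1", "A-CDEF", "AGCDEW"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$position, 5L)
  expect_equal(ev$from_aa, "F")
  expect_equal(ev$context_N, "ACDE")
  expect_equal(ev$context_C, "")
})

test_that("strict mode drops events with another substitution in window", {
  pair <- aligned_pair("g1", "ACDEFGHIKL", "ACNEFGHTKL")
  expect_equal(nrow(infer_events(pair, window = 20)), 2L)
  expect_equal(nrow(infer_events(pair, window = 20,
                                 drop_overlapping = TRUE)), 0L)
  # the two events are 5 positions apart
  expect_equal(nrow(infer_events(pair, window = 5,
                                 drop_overlapping = TRUE)), 0L)
  expect_equal(nrow(infer_events(pair, window = 4,
                                 drop_overlapping = TRUE)), 2L)
})

test_that("the 380 ordered substitution types enumerate correctly", {
  types <- enumerate_types()
  expect_equal(nrow(types), 20L * 19L)
  expect_true(any(types$from_aa == "A" & types$to_aa == "D"))
  expect_true(any(types$from_aa == "D" & types$to_aa == "A"))
  expect_false(any(types$from_aa == types$to_aa))
  expect_false(is.unsorted(types$from_aa))
})

test_that("events_to_table applies the per-side completeness rule", {
  L <- 45
  anc <- paste0(strrep("A", 20), "S", strrep("G", 24))
  des <- paste0(strrep("A", 20), "P", strrep("G", 24))
  ev <- infer_events(aligned_pair("g1", anc, des))
  tab <- events_to_table(ev, window = 20)
  expect_equal(unname(tab$n_side), c(1L, 1L))
  expect_equal(tab$focal, c("S", "P"))

  # event at ancestral position 5: C side only at W = 20
  anc2 <- paste0("AAAAS", strrep("G", 24))
  des2 <- paste0("AAAAP", strrep("G", 24))
  ev2 <- infer_events(aligned_pair("g2", anc2, des2))
  tab2 <- events_to_table(ev2, window = 20)
  expect_equal(tab2$n_side[["N"]], 0L)
  expect_equal(tab2$n_side[["C"]], 1L)

  empty <- events_to_table(ev[0, ], window = 20)
  expect_equal(unname(empty$n_side), c(0L, 0L))

  mixed <- rbind(ev, transform(ev2, from_aa = "A"))
  expect_error(events_to_table(mixed, 20), "types")
})

test_that("event counts equal mismatching canonical columns over pairs", {
  anc <- gen_iid(generator_config(30, 60, 90, seed = 31))
  sim <- gen_context_substitutions(
    anc, base_rate = 0.05,
    rule = list(from_aa = "S", to_aa = "P", neighbor_offset = 1L,
                neighbor_aa = "P", multiplier = 1), seed = 32)
  ev <- infer_events(sim$pairs)
  n_mismatch <- sum(vapply(sim$pairs, function(p) {
    a <- strsplit(p$ancestor, "")[[1]]
    d <- strsplit(p$descendant, "")[[1]]
    sum(a != d & a != "-" & d != "-" & a != "?" & d != "?")
  }, numeric(1)))
  expect_equal(nrow(ev), n_mismatch)
})

test_that("filter_types retains types by their larger side count", {
  anc <- gen_iid(generator_config(20, 60, 90, seed = 41))
  sim <- gen_context_substitutions(
    anc, base_rate = 0.1,
    rule = list(from_aa = "S", to_aa = "P", neighbor_offset = 1L,
                neighbor_aa = "P", multiplier = 1), seed = 42)
  ev <- infer_events(sim$pairs)
  split_ev <- split(ev, paste0(ev$from_aa, ">", ev$to_aa))
  tables <- lapply(split_ev, events_to_table, window = 10)
  expect_setequal(filter_types(tables, 1L),
                  names(tables)[vapply(tables, function(t) max(t$n_side) >= 1,
                                       logical(1))])
  expect_length(filter_types(tables, 10000L), 0L)
  expect_equal(sort(filter_types(tables, 0L)), sort(names(tables)))

  fake <- tables[[1]]
  fake$n_side <- c(N = 49L, C = 10L)
  expect_false(names(tables)[1] %in%
                 filter_types(stats::setNames(list(fake), names(tables)[1]),
                              50L))
})

test_that("substitution profiles use the pre-substituted residue's background", {
  # events sampled uniformly from S occurrences: totals near zero
  anc <- gen_iid(generator_config(150, 150, 250, seed = 51))
  sim <- gen_context_substitutions(
    anc, base_rate = 0.2,
    rule = list(from_aa = "S", to_aa = "P", neighbor_offset = 1L,
                neighbor_aa = "P", multiplier = 1), seed = 52)
  ev <- infer_events(sim$pairs)
  sp <- ev[ev$from_aa == "S" & ev$to_aa == "P", ]
  tab <- events_to_table(sp, window = 6)
  expect_gt(min(tab$n_side), 200)
  prof <- substitution_profile(tab, anc)
  expect_true(all(prof$total_relative_entropy >= 0))
  expect_lt(mean(prof$total_relative_entropy), 0.05)
  expect_error(substitution_profile(events_to_table(sp[0, ], 6), anc),
               "empty")
})
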