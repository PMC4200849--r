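test_that("generators are deterministic under a fixed seed", {
  cfg <- generator_config(10, 50, 80, seed = 101)
  r1 <- gen_iid(cfg)
  r2 <- gen_iid(cfg)
  expect_identical(vapply(r1, `[[`, character(1), "sequence"),
                   vapply(r2, `[[`, character(1), "sequence"))

  c1 <- gen_collagen_mix(cfg, 0.5, n_repeats = 10)
  c2 <- gen_collagen_mix(cfg, 0.5, n_repeats = 10)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$records[[1]]$sequence, c2$records[[1]]$sequence)

  s1 <- gen_context_substitutions(
    r1, 0.05, list(from_aa = "A", to_aa = "G", neighbor_offset = -2L,
                   neighbor_aa = "W", multiplier = 2), seed = 7)
  s2 <- gen_context_substitutions(
    r1, 0.05, list(from_aa = "A", to_aa = "G", neighbor_offset = -2L,
                   neighbor_aa = "W", multiplier = 2), seed = 7)
  expect_identical(s1$events, s2$events)
})

test_that("iid sequences reflect the configured composition", {
  cfg <- generator_config(200, 150, 250, seed = 103)
  recs <- gen_iid(cfg)
  bg <- background_from_records(recs)
  n <- sum(vapply(recs, function(r) nchar(r$sequence), numeric(1)))
  se3 <- 3 * sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(bg$q - 0.05) < se3 + 1e-3))

  lens <- vapply(recs, function(r) nchar(r$sequence), numeric(1))
  expect_true(all(lens >= 150 & lens <= 250))

  deg <- generator_config(3, 30, 40,
                          composition = stats::setNames(c(1, rep(0, 19)),
                                                        AA_ALPHABET),
                          seed = 1)
  expect_true(all(grepl("^A+$",
                        vapply(gen_iid(deg), `[[`, character(1),
                               "sequence"))))
})

test_that("collagen blocks carry G at every third position", {
  cfg <- generator_config(40, 92, 92, seed = 107)
  res <- gen_collagen_mix(cfg, 1, n_repeats = 30)
  expect_true(all(res$truth$is_collagen))
  for (i in 1:5) {
    s <- res$records[[i]]$sequence
    b <- res$truth$block_start[i]
    block <- substr(s, b, b + 89)
    ch <- strsplit(block, "")[[1]]
    expect_true(all(ch[seq(1, 88, by = 3)] == "G"))
    expect_true(all(ch[-seq(1, 88, by = 3)] != "G"))
  }
  # G contexts concentrate G at 3n offsets, deplete it elsewhere
  tab <- extract_contexts(res$records, "G", 6)
  pg <- tab$counts["G", ] / tab$n_side[["C"]]
  expect_gt(pg[["3"]], 0.8)
  expect_gt(pg[["6"]], 0.7)
  expect_lt(pg[["1"]], 0.1)
  expect_lt(pg[["2"]], 0.1)

  none <- gen_collagen_mix(cfg, 0, n_repeats = 30)
  expect_false(any(none$truth$is_collagen))
  expect_true(all(is.na(none$truth$block_start)))
})

test_that("self-clustering runs enrich the run residue next to itself", {
  cfg <- generator_config(80, 150, 250, seed = 109)
  res <- gen_self_clustering(cfg, "A", run_rate = 0.01, run_length = 4)
  expect_gt(nrow(res$truth), 0L)
  tab <- extract_contexts(res$records, "A", 3)
  bg <- background_from_records(res$records)
  prof <- entropy_profile(tab, bg)
  comps <- prof$comp_A[prof$offset %in% c(-1L, 1L)]
  out1 <- prof$outlier_residues[prof$offset == 1L]
  expect_true(grepl("A\\+", out1))
  expect_true(all(comps > 0))

  quiet <- gen_self_clustering(cfg, "A", run_rate = 0, run_length = 4)
  expect_equal(nrow(quiet$truth), 0L)
})

test_that("helix pairing enriches Y at +d of X only", {
  cfg <- generator_config(150, 150, 250, seed = 113)
  res <- gen_helix_pairing(cfg, c("E", "K"), offset_d = 4, enrichment = 5)
  expect_true(all(vapply(res$records, function(r)
    grepl("^H+$", r$structure_track), logical(1))))
  tab <- extract_contexts(res$records, "E", 6)
  pK_p4 <- tab$counts["K", "4"] / tab$n_side[["C"]]
  pK_m4 <- tab$counts["K", "-4"] / tab$n_side[["N"]]
  pK_p3 <- tab$counts["K", "3"] / tab$n_side[["C"]]
  expect_gt(pK_p4, 0.15)                 # ~0.21 planted
  expect_lt(pK_m4, 0.08)                 # no signal planted at -4
  expect_lt(pK_p3, 0.08)

  flat <- gen_helix_pairing(generator_config(30, 100, 150, seed = 5),
                            c("E", "K"), offset_d = 4, enrichment = 1)
  tabf <- extract_contexts(flat$records, "E", 6)
  expect_lt(tabf$counts["K", "4"] / tabf$n_side[["C"]], 0.09)
})

test_that("context substitutions follow the planted rule", {
  anc <- gen_iid(generator_config(150, 150, 250, seed = 127))
  rule <- list(from_aa = "S", to_aa = "P", neighbor_offset = 1L,
               neighbor_aa = "P", multiplier = 5)
  sim <- gen_context_substitutions(anc, 0.02, rule, seed = 128)
  ev <- sim$events
  sp <- ev[ev$from_aa == "S", ]
  expect_true(all(sp$to_aa == "P"))
  # S sites followed by P substitute ~5x more often
  n_SP_ctx <- sum(substr(sp$context_C, 1, 1) == "P")
  expect_gt(n_SP_ctx / nrow(sp), 0.12)   # vs 0.05 under no rule

  # non-rule residues never substitute into themselves
  other <- ev[ev$from_aa != "S", ]
  expect_true(all(other$from_aa != other$to_aa))

  expect_error(gen_context_substitutions(
    anc, 0.5, list(from_aa = "S", to_aa = "P", neighbor_offset = 1L,
                   neighbor_aa = "P", multiplier = 3), seed = 1),
    "exceeds 1")
})
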