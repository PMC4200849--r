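test_that("component_entropy evaluates single terms with the limit rule", {
  expect_equal(component_entropy(0.5, 0.05), 0.5 * log2(10),
               tolerance = 1e-12)
  expect_identical(component_entropy(0, 0.3), 0)
  expect_equal(component_entropy(0.2, 0.2), 0)
  expect_error(component_entropy(0.1, 0), "background is zero")
})

test_that("site_entropy matches hand-evaluated cases", {
  counts <- aacontext::AA_ALPHABET == "A" | aacontext::AA_ALPHABET == "L"
  counts <- stats::setNames(as.integer(counts) * 5L, AA_ALPHABET)
  se <- site_entropy(counts, rep(0.05, 20))
  expect_equal(se$total, log2(10), tolerance = 1e-12)
  expect_equal(unname(se$components[c("A", "L")]),
               rep(0.5 * log2(10), 2), tolerance = 1e-12)
  expect_true(all(se$components[setdiff(AA_ALPHABET, c("A", "L"))] == 0))

  # counts proportional to the background give exactly zero
  q <- (1:20) / sum(1:20)
  se <- site_entropy(stats::setNames(3L * (1:20), AA_ALPHABET), q)
  expect_equal(se$total, 0, tolerance = 1e-12)

  one <- stats::setNames(c(7L, rep(0L, 19)), AA_ALPHABET)
  qa <- c(1, rep(0, 19))
  expect_equal(site_entropy(one, qa)$total, 0)

  expect_error(site_entropy(stats::setNames(rep(0L, 20), AA_ALPHABET),
                            rep(0.05, 20)), "zero")
  expect_error(site_entropy(one, rep(0.05, 20), n = 5), "exceeds")
})

test_that("global backgrounds are scoped observed frequencies", {
  bg <- background_from_records(records_from("AAAA"))
  expect_equal(unname(bg$q["A"]), 1)
  expect_equal(sum(bg$q), 1)

  bg <- background_from_records(records_from("AC", "CA"))
  expect_equal(unname(bg$q[c("A", "C")]), c(0.5, 0.5))

  # unknown symbols excluded from numerator and denominator
  bg <- background_from_records(records_from("AXA?C"))
  expect_equal(unname(bg$q["A"]), 2 / 3)

  recs <- list(protein_record("p1", "AAA", structure_track = "CCC"))
  expect_error(background_from_records(recs, structure = "H"),
               "no canonical residue")
  expect_error(background_from_records(recs, group = "nucleus"), "group")
})

test_that("per-offset backgrounds mirror the focal residue's flanks", {
  bg <- per_offset_background(records_from("CAD", "CAD"), "A", window = 1)
  expect_equal(bg$mode, "per_offset")
  expect_equal(unname(bg$q["C", "-1"]), 1)
  expect_equal(unname(bg$q["D", "1"]), 1)
  expect_equal(unname(colSums(bg$q)), c(1, 1))
  expect_error(per_offset_background(records_from("CCD"), "A", 1),
               "insufficient|no counts|offset")
})

test_that("profiles report per-offset totals against the background", {
  tab <- extract_contexts(records_from("ACDEF"), "D", 2)
  prof <- entropy_profile(tab, uniform_background())
  expect_s3_class(prof, "entropy_profile")
  expect_equal(nrow(prof), 4L)
  expect_equal(prof$total_relative_entropy, rep(log2(20), 4),
               tolerance = 1e-12)

  # totals equal the component sums
  comp_sums <- rowSums(as.matrix(prof[, paste0("comp_", AA_ALPHABET)]))
  expect_equal(unname(comp_sums), prof$total_relative_entropy,
               tolerance = 1e-9)

  # observed == background at every offset gives all-zero totals
  recs <- gen_iid(generator_config(10, 50, 70, seed = 3))
  tab <- extract_contexts(recs, "A", 3)
  bg <- per_offset_background(recs, "A", 3)
  prof0 <- entropy_profile(tab, bg)
  expect_equal(prof0$total_relative_entropy, rep(0, 6), tolerance = 1e-12)

  # an empty side is absent, not zero
  tab <- extract_contexts(records_from("DAC"), "D", 2)
  prof <- entropy_profile(tab, uniform_background())
  expect_equal(prof$side, c("C", "C"))
  expect_equal(prof$offset, c(1L, 2L))
})

test_that("profile totals are invariant under record relabeling", {
  recs <- gen_iid(generator_config(15, 40, 60, seed = 9))
  relabeled <- lapply(seq_along(recs), function(i)
    protein_record(sprintf("z%02d", i), recs[[i]]$sequence))
  bg <- background_from_records(recs)
  p1 <- entropy_profile(extract_contexts(recs, "K", 3), bg)
  p2 <- entropy_profile(extract_contexts(relabeled, "K", 3), bg)
  expect_equal(p1$total_relative_entropy, p2$total_relative_entropy)
})

test_that("the 1.5 IQR rule flags outlier components", {
  x <- c(rep(0.1, 19), 5.0)
  names(x) <- AA_ALPHABET
  out <- component_outliers(x)
  expect_equal(out$residue, "Y")
  expect_equal(out$direction, "high")

  expect_equal(nrow(component_outliers(rep(0.3, 20))), 0L)

  # flags invariant under permutation of input order
  set.seed(42)
  y <- stats::setNames(c(rnorm(18), 9, -9), AA_ALPHABET)
  o1 <- component_outliers(y)
  perm <- sample(20)
  o2 <- component_outliers(y[perm])
  expect_equal(o1, o2)
  expect_setequal(o1$residue[o1$direction == "high"], "W")
  expect_setequal(o1$residue[o1$direction == "low"], "Y")
})

test_that("zero-background residues error unless a pseudocount is used", {
  recs <- records_from("GAGAGAGAGA", "GAGAGAGAGA")
  tab <- extract_contexts(records_from("WDCDW"), "C", 2)
  bg <- background_from_records(recs)        # only G and A present
  expect_error(entropy_profile(tab, bg), "pseudocount")
  bgp <- background_from_records(recs, pseudocount = TRUE)
  expect_true(all(bgp$q > 0))
  expect_silent(entropy_profile(tab, bgp))
})
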