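scheme2 <- residue_scheme(list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
  charged = c("D", "E", "K", "R", "H"),
  turn = c("G", "P", "S", "N"),
  hydrophilic = c("T", "Q", "Y")))

test_that("class proportions partition to 1 and flag empty regions", {
  expect_equal(unname(class_proportions("AAAA", scheme2)["hydrophobic"]), 1)
  p <- class_proportions("AD", scheme2)
  expect_equal(unname(p["hydrophobic"]), 0.5)
  expect_equal(unname(p["charged"]), 0.5)

  # empty region: flagged NA, never a silent zero
  p0 <- class_proportions("", scheme2)
  expect_true(all(is.na(p0)))
  expect_true(attr(p0, "missing"))
  p1 <- class_proportions("---", scheme2)
  expect_true(attr(p1, "missing"))

  # property: proportions sum to 1 for random strings
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(AA20, sample(3:60, 1), replace = TRUE), collapse = "")
    expect_equal(sum(class_proportions(s, scheme2)), 1, tolerance = 1e-12)
  }
})

test_that("scheme validation enforces disjoint full coverage", {
  expect_error(residue_scheme(list(a = c("A", "V"), b = c("V", "L"))),
               "disjoint")
  expect_error(residue_scheme(list(a = AA20[1:10])), "missing")
  expect_s3_class(default_residue_scheme(), "residue_scheme")
})

test_that("mean pairwise identity matches hand counting", {
  m <- toy_model()
  p <- carrier_pool(c(strrep("A", 76), strrep("A", 76)))
  expect_equal(as.numeric(mean_pairwise_identity(p)), 100)

  p2 <- carrier_pool(c(strrep("A", 76), strrep("L", 76)))
  expect_equal(as.numeric(mean_pairwise_identity(p2)), 0)

  # 3 gapped sequences, counted by hand over 4 columns:
  # (1,2): matches at cols 1,3 of 4 compared -> 0.5
  # (1,3): matches at 1,2,3; col 4 is gap/C mismatch -> 0.75
  # (2,3): matches at 1,3,4; col 2 gap/A mismatch  -> 0.75
  p3 <- carrier_pool(c("AAC-", "A-CC", "AACC"))
  expect_equal(as.numeric(mean_pairwise_identity(p3)),
               100 * (0.5 + 0.75 + 0.75) / 3)

  expect_error(mean_pairwise_identity(carrier_pool("AAAA")), "at least 2")
})

test_that("resampling is seed-deterministic and degenerate pools collapse", {
  m <- toy_model()
  # every sequence has hydrophobic proportion exactly 0.5 in TR1_DOWN
  # (columns 9-12): two hydrophobic, two not
  s <- toy_seq("G", overrides = list(list(at = 9, str = "ALGG")))
  pool <- carrier_pool(rep(s, 20))
  r <- resample_ecdf(pool, m, "TR1_DOWN", "hydrophobic",
                     sample_size = 10, replicates = 25, seed = 3,
                     scheme = scheme2)
  expect_true(all(r$replicate_means == 0.5))
  expect_equal(r$ecdf(0.5), 1)
  expect_equal(r$ecdf(0.4999), 0)

  sim <- generate_mcf_pools(sim_params(seed = 5))
  a <- resample_ecdf(sim$pools[[1]], sim$model, "TR_DOWN135", "hydrophobic",
                     sample_size = 50, replicates = 40, seed = 9)
  b <- resample_ecdf(sim$pools[[1]], sim$model, "TR_DOWN135", "hydrophobic",
                     sample_size = 50, replicates = 40, seed = 9)
  expect_identical(a$replicate_means, b$replicate_means)

  expect_error(resample_ecdf(pool, m, "TR1_DOWN", "hydrophobic",
                             sample_size = 21, replicates = 5, seed = 1,
                             scheme = scheme2), "exceeds")
})

test_that("gap-only sequences are skipped with a warning during resampling", {
  m <- toy_model()
  good <- toy_seq("A")
  bad <- toy_seq("A", overrides = list(list(at = 9, str = "----")))
  pool <- carrier_pool(c(rep(good, 10), bad))
  expect_warning(
    r <- resample_ecdf(pool, m, "TR1_DOWN", "hydrophobic",
                       sample_size = 5, replicates = 10, seed = 1,
                       scheme = scheme2),
    "skipped")
  expect_equal(r$n_skipped, 1)
})

test_that("ECDF KS distance is exact on hand-checkable samples", {
  expect_equal(ecdf_ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ecdf_ks_distance(c(0, 0), c(1, 1)), 1)
  # F1 jumps to 2/3 at 2; F2 still 1/3 -> D = 1/3
  expect_equal(ecdf_ks_distance(c(1, 2, 4), c(1, 3, 5)), 1 / 3)
})

test_that("one-way ANOVA matches the definitional formula", {
  # {1,2} vs {3,4}: SSB = 4, SSW = 1, df = (1, 2) -> F = 4 / (1/2) = 8
  res <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(res$F, 8)
  expect_equal(res$p.value, 1 - pf(8, 1, 2))
  expect_equal(res$df, c(1L, 2L))

  # identical group means -> F = 0
  eq <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(eq$F, 0)

  # fully degenerate: flagged, F = 0, p = 1
  dg <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_true(dg$degenerate)
  expect_equal(dg$F, 0)
  expect_equal(dg$p.value, 1)

  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 values")
})

test_that("Holm-Sidak step-down follows the hand-applied formula", {
  # all p = 1: nothing rejected
  expect_false(any(holm_sidak(c(1, 1, 1))$reject))
  # single comparison reduces to the plain test
  expect_true(holm_sidak(0.001, alpha = 0.05)$reject)
  expect_false(holm_sidak(0.06, alpha = 0.05)$reject)

  # {0.01, 0.02, 0.04} at alpha = 0.05, thresholds
  # 1-(0.95)^(1/3)=0.01695, 1-(0.95)^(1/2)=0.02532, 0.05: all rejected
  r <- holm_sidak(c(0.04, 0.01, 0.02), alpha = 0.05)
  expect_true(all(r$reject))

  # step-down stops at the first failure: 0.03 > 0.01695 blocks everything
  r2 <- holm_sidak(c(0.03, 0.035, 0.04), alpha = 0.05)
  expect_false(any(r2$reject))

  expect_error(holm_sidak(c(0.5, 1.2)), "0, 1")
})

test_that("Holm-Sidak never rejects more than unadjusted testing", {
  set.seed(21)
  for (i in 1:30) {
    p <- runif(sample(2:8, 1))^2
    r <- holm_sidak(p, alpha = 0.05)
    expect_true(all(!r$reject | p <= 0.05))
    # monotone: every p smaller than a rejected p is rejected
    if (any(r$reject))
      expect_true(all(r$reject[p <= max(p[r$reject])]))
  }
})

test_that("the pool-level KS test is calibrated on per-sequence values", {
  set.seed(7)
  a <- rbinom(150, 30, 0.4) / 30
  b <- rbinom(150, 30, 0.4) / 30
  t0 <- ks_pool_test(a, b, n_perm = 199, seed = 2)
  expect_gte(t0$p.value, 0.05 * 0)   # a valid p-value
  expect_lte(t0$p.value, 1)
  # a large shift is detected
  t1 <- ks_pool_test(a, a + 0.2, n_perm = 199, seed = 2)
  expect_lt(t1$p.value, 0.01)
  expect_gt(t1$statistic, 0.5)
})
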