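test_that("planted motifs give the complete 18-residue mark sequence", {
  m <- toy_model()
  s <- toy_seq("G", overrides = list(list(at = 7, str = "PIDQLK"),
                                     list(at = 31, str = "PIDQLK"),
                                     list(at = 55, str = "PIDQLK")))
  ms <- extract_mark_sequence(s, m)
  expect_true(ms$complete)
  expect_equal(ms$mark, "PIDQLKPIDQLKPIDQLK")
  expect_equal(nchar(ms$mark), 18)
  expect_equal(ms$starts, c(7L, 31L, 55L))
})

test_that("a non-matching 6-mer leaves the motif flagged missing", {
  m <- toy_model()
  # PADTTQ: position 6 is Q, neither K nor R -> no match
  s <- toy_seq("G", overrides = list(list(at = 7, str = "PADTTQ"),
                                     list(at = 31, str = "PIDQLK"),
                                     list(at = 55, str = "PIDQLK")))
  ms <- extract_mark_sequence(s, m)
  expect_false(ms$complete)
  expect_false(ms$found[1])
  expect_true(all(ms$found[2:3]))
  expect_equal(ms$motifs[1], "------")
})

test_that("the nearest match to the anchor wins", {
  m <- toy_model()
  # two matches: a decoy 6 residues before the anchor and one exactly at
  # the anchor (31); the nearer one wins
  s <- toy_seq("G", overrides = list(list(at = 7, str = "PIDQLK"),
                                     list(at = 25, str = "PMDALR"),
                                     list(at = 31, str = "PIDQLK"),
                                     list(at = 55, str = "PIDQLK")))
  ms <- extract_mark_sequence(s, m)
  expect_equal(ms$starts[2], 31L)
  expect_equal(ms$motifs[2], "PIDQLK")
})

test_that("mark extraction is idempotent and gap-insertion invariant", {
  base <- toy_seq("G", overrides = list(list(at = 7, str = "PIDQLK"),
                                        list(at = 31, str = "PIDQLK"),
                                        list(at = 55, str = "PIDQLK")))
  m0 <- toy_model()
  r0 <- extract_mark_sequence(base, m0)
  expect_identical(extract_mark_sequence(base, m0)$mark, r0$mark)
  # insert two all-gap columns before column 30 (inside TR3, ahead of the
  # anchor) with the correspondingly shifted model
  chars <- strsplit(base, "")[[1]]
  gapped <- paste(c(chars[1:29], "-", "-", chars[30:76]), collapse = "")
  m1 <- toy_model(insert_at = 30, n_insert = 2L)
  r1 <- extract_mark_sequence(gapped, m1)
  expect_identical(r1$mark, r0$mark)
  expect_identical(r1$starts, r0$starts)   # ungapped coordinates
})

test_that("generator families yield complete marks at full conservation", {
  sim <- generate_mcf_pools(sim_params(motif_conservation = 1, seed = 2))
  for (ph in names(sim$pools)) {
    marks <- pool_mark_sequences(sim$pools[[ph]], sim$model)
    expect_true(all(marks$complete))
    expect_true(all(nchar(marks$mark) == 18))
  }
})

test_that("position frequency matrices are column-stochastic", {
  f <- pfm(c("ADKL", "ADKV", "AEKL"))
  expect_equal(unname(colSums(f)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(f["A", 1]), 1)
  expect_equal(unname(f["D", 2]), 2 / 3)
  expect_error(pfm(c("AD", "ADK")), "equal length")
  expect_error(pfm(character(0)), "at least one")
})

test_that("JS divergence spans 0 (identical) to 1 (disjoint)", {
  a <- c("ADKL", "ADKV")
  expect_equal(pfm_divergence(a, a), 0)
  # disjoint residue usage at every column: maximal JS in bits
  expect_equal(pfm_divergence(c("ADKL"), c("VERM")), 1)
  expect_error(pfm_divergence(pfm("ADK"), pfm("ADKL")), "column counts")
  # divergence between phases of generated marks stays small when the
  # motifs are conserved
  sim <- generate_mcf_pools(sim_params(delta = 0.05, seed = 6))
  mk <- function(ph) {
    d <- pool_mark_sequences(sim$pools[[ph]], sim$model)
    d$mark[d$complete]
  }
  ver <- c(mk("Ver-eco"), mk("Ver-endo"))
  expect_lt(pfm_divergence(mk("Non-ver"), ver), 0.05)
})

test_that("cluster age averages log10 of the k smallest E-values", {
  ev <- list(carA = rep(1e-40, 10))
  r <- cluster_age(ev, c(carA = "X"), k = 10)
  expect_equal(r$carriers$mean_exponent, -40)

  # arithmetic mean of exponents: five -10s and five -20s -> -15
  ev2 <- list(carB = c(rep(1e-10, 5), rep(1e-20, 5)))
  r2 <- cluster_age(ev2, c(carB = "X"), k = 10)
  expect_equal(r2$carriers$mean_exponent, -15)

  # fewer than k: all used, with a warning
  ev3 <- list(carC = rep(1e-5, 6))
  expect_warning(r3 <- cluster_age(ev3, c(carC = "X"), k = 10), "only 6")
  expect_equal(r3$carriers$n_used, 6)

  # E = 0 clipped to the floor exponent, flagged by warning
  expect_warning(r4 <- cluster_age(list(carD = c(0, 1e-10)),
                                   c(carD = "X"), k = 2), "clipped")
  expect_equal(r4$carriers$mean_exponent, (-180 + -10) / 2)
  expect_error(cluster_age(list(carE = c(-1, 1e-5)), c(carE = "X")),
               "negative")
})

test_that("cluster age is monotone under uniform E-value scaling", {
  set.seed(9)
  ev <- lapply(1:4, function(i) 10^runif(15, -60, -5))
  names(ev) <- paste0("c", 1:4)
  cl <- setNames(c("g1", "g1", "g2", "g2"), names(ev))
  r1 <- cluster_age(ev, cl, k = 10)
  r2 <- cluster_age(lapply(ev, function(x) x / 10), cl, k = 10)
  expect_equal(r2$carriers$mean_exponent, r1$carriers$mean_exponent - 1,
               tolerance = 1e-10)
  expect_equal(r2$clusters$mean_exponent, r1$clusters$mean_exponent - 1,
               tolerance = 1e-10)
})

test_that("clusters are ordered oldest first and recover generator targets", {
  gen <- generate_evalue_lists(c(old = -50, mid = -43, young = -38),
                               carriers_per_cluster = 6, seed = 12)
  ages <- cluster_age(gen$evalues, gen$clusters, k = 10)
  expect_equal(ages$clusters$cluster, c("old", "mid", "young"))
  expect_true(all(diff(ages$clusters$mean_exponent) > 0))
})
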