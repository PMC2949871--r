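test_that("topology models validate their structural invariants", {
  m <- toy_model()
  expect_s3_class(m, "topology_model")
  expect_length(m$helices, 6)
  # default split is the midpoint of each helix
  expect_equal(m$splits, c(9L, 21L, 33L, 45L, 57L, 69L))

  iv <- toy_intervals()
  # overlapping helices
  bad <- iv$helices; bad[[2]] <- c(10, 24)
  expect_error(topology_model(bad, iv$loops, iv$width, iv$anchors),
               "disjoint")
  # wrong helix count
  expect_error(topology_model(iv$helices[1:5], iv$loops, iv$width,
                              iv$anchors), "6 helix")
  # split outside its helix
  expect_error(topology_model(iv$helices, iv$loops, iv$width, iv$anchors,
                              splits = c(4, 21, 33, 45, 57, 69)),
               "split column")
  # wrong anchor count
  expect_error(topology_model(iv$helices, iv$loops, iv$width,
                              c(7, 31)), "3 motif anchors")
  # incomplete tiling
  short_loops <- iv$loops; short_loops$c <- c(73, 75)
  expect_error(topology_model(iv$helices, short_loops, iv$width,
                              iv$anchors), "tile")
})

test_that("custom split columns are carried verbatim", {
  custom <- c(6L, 18L, 30L, 42L, 54L, 66L)
  m <- toy_model(splits = custom)
  expect_identical(m$splits, custom)
  # non-midpoint split changes the half sizes accordingly
  p <- partition_sequence(strrep("A", 76), m)
  expect_equal(nchar(p$regions$TR1_UP$residues), 1)   # col 5 only
  expect_equal(nchar(p$regions$TR1_DOWN$residues), 7) # cols 6-12
})

test_that("a YAML topology config round-trips through load_topology", {
  iv <- toy_intervals()
  cfg <- list(
    alignment_width = iv$width,
    helices = lapply(iv$helices, function(h) list(start = h[1], end = h[2])),
    loops = lapply(iv$loops, function(h) list(start = h[1], end = h[2])),
    motif_anchors = as.list(iv$anchors))
  path <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(cfg, path)
  m <- load_topology(path)
  expect_equal(m$alignment_width, 76L)
  expect_equal(m$motif_anchors, c(7L, 31L, 55L))
  # the shipped default is itself valid
  expect_s3_class(default_topology(), "topology_model")
})

test_that("partition tiles every column and reassembles the input exactly", {
  m <- toy_model()
  set.seed(42)
  for (i in 1:20) {
    s <- random_aligned_seq(76, gap_prob = 0.15)
    p <- partition_sequence(s, m)
    cols <- sort(unlist(lapply(p$regions, `[[`, "columns"),
                        use.names = FALSE))
    expect_identical(as.integer(cols), 1:76)
    expect_identical(reassemble(p), gsub("\\.", "-", s))
  }
})

test_that("per-region residue lengths match manual column slicing", {
  # fixture: gaps at columns 5-8 (TR1 first half) and 37-40 (all of loop3)
  s <- toy_seq("L", overrides = list(list(at = 5, str = "----"),
                                     list(at = 37, str = "----")))
  m <- toy_model()
  p <- partition_sequence(s, m)
  # sliced by hand: TR1 is 5-12, split 9, UP half 5-8 (gap-only)
  expect_equal(nchar(p$regions$TR1_UP$residues), 0)
  expect_true(p$regions$TR1_UP$empty)
  expect_equal(nchar(p$regions$TR1_DOWN$residues), 4)
  expect_true(p$regions$loop3$empty)
  expect_equal(nchar(p$regions$n$residues), 4)
  expect_equal(nchar(p$regions$loop1$residues), 4)
  # all other helix halves are 4 residues
  expect_equal(nchar(p$regions$TR6_UP$residues), 4)
})

test_that("sequence validation rejects bad input", {
  m <- toy_model()
  expect_error(partition_sequence(strrep("A", 75), m), "length")
  expect_error(partition_sequence(paste0(strrep("A", 75), "Z"), m),
               "non-amino-acid")
})

test_that("composite regions are exact unions of atomic regions", {
  m <- toy_model()
  s <- random_aligned_seq(76, gap_prob = 0)
  p <- partition_sequence(s, m)
  tr <- composite_region(p, "TR")
  halves <- paste0("TR", rep(1:6, each = 2), "_",
                   rep(c("UP", "DOWN"), 6))
  manual <- sort(unlist(lapply(halves, function(h)
    p$regions[[h]]$columns), use.names = FALSE))
  expect_identical(tr$columns, as.integer(manual))
  expect_equal(nchar(tr$residues), 48)

  d135 <- composite_region(p, "TR_DOWN135")
  manual135 <- sort(c(p$regions$TR1_DOWN$columns,
                      p$regions$TR3_DOWN$columns,
                      p$regions$TR5_DOWN$columns))
  expect_identical(d135$columns, as.integer(manual135))

  # the four quadrants are pairwise disjoint and union to TR
  quads <- lapply(c("TR_UP135", "TR_UP246", "TR_DOWN135", "TR_DOWN246"),
                  function(nm) composite_region(p, nm)$columns)
  expect_equal(sum(lengths(quads)), length(tr$columns))
  expect_identical(sort(unlist(quads)), tr$columns)
  expect_identical(sort(c(composite_region(p, "TR_UP")$columns,
                          composite_region(p, "TR_DOWN")$columns)),
                   tr$columns)

  expect_error(composite_region(p, "TR_XYZ"), "unknown region")
})

test_that("partition is invariant to gap-only column insertion", {
  base <- toy_seq("K", overrides = list(list(at = 30, str = "PIDQLK")))
  m0 <- toy_model()
  p0 <- partition_sequence(base, m0)
  # insert three all-gap columns before column 33 (inside TR3) and shift
  # the model accordingly
  chars <- strsplit(base, "")[[1]]
  gapped <- paste(c(chars[1:32], "-", "-", "-", chars[33:76]),
                  collapse = "")
  m1 <- toy_model(insert_at = 33, n_insert = 3L)
  p1 <- partition_sequence(gapped, m1)
  for (rn in names(p0$regions))
    expect_identical(p1$regions[[rn]]$residues, p0$regions[[rn]]$residues)
})
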