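test_that("Poisson distance follows the closed form", {
  p <- carrier_pool(c(strrep("A", 40), strrep("A", 40)))
  d <- poisson_distance(p)
  expect_equal(d[1, 2], 0)

  # half the compared columns differ: d = -ln(0.5)
  s1 <- paste0(strrep("A", 20), strrep("L", 20))
  s2 <- paste0(strrep("A", 20), strrep("V", 20))
  d2 <- poisson_distance(carrier_pool(c(s1, s2)))
  expect_equal(d2[1, 2], -log(0.5), tolerance = 1e-12)

  # saturated pair flagged infinite
  d3 <- poisson_distance(carrier_pool(c(strrep("A", 10), strrep("L", 10))))
  expect_true(is.infinite(d3[1, 2]))
  expect_length(attr(d3, "saturated"), 1)
})

test_that("NJ solves the 3-taxon closed form exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  # v1 = (5+9-10)/2 = 2, v2 = (5+10-9)/2 = 3, v3 = (9+10-5)/2 = 7
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(2, 3, 7))
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  # true unrooted tree: (A:2,B:3) -- 1 -- (C:4,D:5)
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 7
  D["A", "D"] <- D["D", "A"] <- 8
  D["B", "C"] <- D["C", "B"] <- 8
  D["B", "D"] <- D["D", "B"] <- 9
  D["C", "D"] <- D["D", "C"] <- 9
  tree <- neighbor_joining(D)
  # patristic distances reproduce the additive matrix to 1e-9
  coph <- ape::cophenetic.phylo(tree)[labs, labs]
  expect_equal(unname(coph), unname(D), tolerance = 1e-9)
  # topology identical to the generating tree
  truth <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):0);")
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(truth)), 0)
})

test_that("NJ validates its input and documents the tie rule", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), "3 taxa")
  asym <- matrix(c(0, 1, 2, 3, 0, 1, 2, 4, 0), 3, 3)
  expect_error(neighbor_joining(asym), "symmetric")
  nam <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3)
  expect_error(neighbor_joining(nam), "NA")

  # all-equal distances tie every Q entry: the lowest-index pair joins
  labs <- paste0("t", 1:4)
  eq <- matrix(2, 4, 4, dimnames = list(labs, labs)); diag(eq) <- 0
  tree <- neighbor_joining(eq)
  # t1 and t2 form a cherry: same parent node
  parent_of <- function(lab) {
    tip <- match(lab, tree$tip.label)
    tree$edge[tree$edge[, 2] == tip, 1]
  }
  expect_equal(parent_of("t1"), parent_of("t2"))
})

test_that("NJ matches the reference implementation on random matrices", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    pts <- matrix(runif(n * 3), n)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  }
})

test_that("species overlap flags textbook duplication cases", {
  t1 <- ape::read.tree(text = "((human|A:1,mouse|A:1):1,(human|B:1,mouse|B:1):1);")
  d1 <- detect_duplications(t1)
  expect_equal(sum(d1$duplication), 1)
  expect_true(d1$accepted[d1$duplication])
  # the duplication sits at the root: both child clades span 2 species
  expect_equal(d1$n_species_left[d1$duplication], 2)

  t2 <- ape::read.tree(text = "((human|A:1,mouse|A:1):1,frog|B:1);")
  d2 <- detect_duplications(t2)
  expect_equal(sum(d2$duplication), 0)

  # overlap without the two-species criterion: flagged but not accepted
  t3 <- ape::read.tree(text = "((human|A:1,human|B:1):1,mouse|A:1);")
  d3 <- detect_duplications(t3)
  expect_equal(sum(d3$duplication), 1)
  expect_false(any(d3$accepted))
})

test_that("duplication detection requires a rooting decision", {
  unrooted <- ape::unroot(ape::read.tree(
    text = "((a|x:1,b|x:1):1,(a|y:1,c|y:1):1);"))
  expect_error(detect_duplications(unrooted), "unrooted")
  # midpoint rooting resolves it
  d <- detect_duplications(unrooted, root = "midpoint")
  expect_s3_class(d, "data.frame")
})

test_that("duplication counts ignore tip order and within-species labels", {
  a <- ape::read.tree(text = "((h|A:1,m|A:1):1,(h|B:1,m|B:1):1);")
  b <- ape::read.tree(text = "((m|B:1,h|B:1):1,(m|A:1,h|A:1):1);")
  expect_equal(sum(detect_duplications(a)$duplication),
               sum(detect_duplications(b)$duplication))
})

test_that("planted duplications are recovered perfectly", {
  set.seed(3)
  tp <- fp <- fn <- 0
  for (i in 1:40) {
    n_sp <- sample(4:9, 1)
    sim <- NULL
    for (nd in 3:1) {
      sim <- tryCatch(generate_duplication_tree(n_sp, nd, seed = i),
                      error = function(e) NULL)
      if (!is.null(sim)) break
    }
    det <- detect_duplications(sim$tree)
    found <- attr(det, "events")
    found_keys <- vapply(found, function(e)
      paste(sort(e$tips), collapse = ";"), character(1))
    true_keys <- vapply(sim$events, function(e)
      paste(sort(e$tips), collapse = ";"), character(1))
    tp <- tp + length(intersect(found_keys, true_keys))
    fp <- fp + length(setdiff(found_keys, true_keys))
    fn <- fn + length(setdiff(true_keys, found_keys))
  }
  expect_gt(tp, 0)
  expect_equal(fp, 0)
  expect_equal(fn, 0)
})

test_that("bootstrap support is reproducible and bounded", {
  sim <- generate_mcf_pools(sim_params(pool_sizes = c(
    "Non-ver" = 8, "Ver-eco" = 8, "Ver-endo" = 8), n_carriers = 8,
    seed = 10))
  pool <- sim$pools[[1]]
  t1 <- nj_bootstrap(pool, n_boot = 10, seed = 4, region = "TR",
                     model = sim$model)
  t2 <- nj_bootstrap(pool, n_boot = 10, seed = 4, region = "TR",
                     model = sim$model)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 1))
})
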