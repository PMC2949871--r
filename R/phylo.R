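# Distance-based gene-family trees and species-overlap duplication
# detection. Trees are ape "phylo" objects throughout; Newick I/O goes
# through ape.

#' Poisson-corrected pairwise distances of an aligned pool
#'
#' For each unordered pair, `p` is the proportion of differing compared
#' columns (both-gap columns excluded; a single-gap column counts as a
#' difference) and the distance is `d = -log(1 - p)`. Saturated pairs
#' (`p >= 1`) get `Inf` and are flagged via the `saturated` attribute.
#'
#' @param pool a [carrier_pool()] with >= 2 sequences.
#' @param region optional region label to restrict columns.
#' @param model a [topology_model()], required with `region`.
#' @return symmetric numeric matrix with zero diagonal, labelled by id.
#' @export
poisson_distance <- function(pool, region = NULL, model = NULL) {
  if (length(pool$seqs) < 2L) stop("need at least 2 sequences")
  cols <- if (is.null(region)) seq_len(pool$width) else {
    if (is.null(model)) stop("model is required when region is given")
    region_columns(model, region)
  }
  m <- pool_matrix(pool, cols)
  nongap <- !(m %in% GAP_CHARS)
  dim(nongap) <- dim(m)
  matches <- matrix(0, nrow(m), nrow(m))
  for (r in unique(as.vector(m[nongap]))) {
    b <- (m == r) & nongap
    matches <- matches + tcrossprod(b * 1)
  }
  compared <- ncol(m) - tcrossprod((!nongap) * 1)
  p <- 1 - matches / compared
  p[compared == 0] <- NA_real_
  diag(p) <- 0
  d <- ifelse(p >= 1, Inf, -log(1 - p))
  dimnames(d) <- list(pool$meta$id, pool$meta$id)
  structure(d, saturated = which(is.infinite(d) & upper.tri(d)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' The classic agglomeration of Saitou & Nei (1987): at each step the pair
#' minimising `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined. Determinism on
#' ties: the pair with the lowest row index, then lowest column index, is
#' joined. Negative branch lengths are clamped to zero and counted in the
#' `negative_branches` attribute. The result is unrooted; `rooted =
#' "midpoint"` midpoint-roots it.
#'
#' @param d symmetric non-negative distance matrix with >= 3 labelled taxa.
#' @param rooted `"none"` (default) or `"midpoint"`.
#' @return an [ape::read.tree()]-style `phylo` object.
#' @export
neighbor_joining <- function(d, rooted = c("none", "midpoint")) {
  rooted <- match.arg(rooted)
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(is.na(d)) || any(!is.finite(d)))
    stop("distance matrix has NA/NaN/Inf entries")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  n_neg <- 0L
  bl <- function(x) {            # clamp, count negatives
    if (x < 0) { n_neg <<- n_neg + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.17g", x)
  sub <- labs                     # newick fragments per active node
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    # lowest (row, col) among minima: column-major which() ordered by j then
    # i, so re-rank explicitly by (i, j)
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2])[1], ]
    i <- hit[1]; j <- hit[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new <- paste0("(", sub[i], ":", fmt(bl(li)), ",",
                  sub[j], ":", fmt(bl(lj)), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    sub <- c(sub[keep], new)
    rownames(d2) <- colnames(d2) <- seq_len(nrow(d2))
    d <- d2
  }
  # closed-form star for the final three nodes
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", fmt(bl(v1)), ",", sub[2], ":", fmt(bl(v2)),
                ",", sub[3], ":", fmt(bl(v3)), ");")
  tree <- ape::read.tree(text = nwk)
  if (rooted == "midpoint") tree <- phangorn::midpoint(tree)
  attr(tree, "negative_branches") <- n_neg
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' Poisson-corrected distances each time, and annotates the reference tree's
#' internal nodes with the proportion of replicates containing each clade.
#'
#' @param pool aligned [carrier_pool()].
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param region,model optional region restriction.
#' @return the reference NJ tree with `node.label` support proportions.
#' @export
nj_bootstrap <- function(pool, n_boot = 100, seed = 1L,
                         region = NULL, model = NULL) {
  cols <- if (is.null(region)) seq_len(pool$width) else
    region_columns(model, region)
  ref <- neighbor_joining(poisson_distance(pool, region, model))
  set.seed(as.integer(seed))
  boots <- vector("list", n_boot)
  m <- pool_matrix(pool, cols)
  for (b in seq_len(n_boot)) {
    bm <- m[, sample.int(ncol(m), replace = TRUE), drop = FALSE]
    bp <- carrier_pool(apply(bm, 1, paste, collapse = ""),
                       id = pool$meta$id)
    boots[[b]] <- neighbor_joining(poisson_distance(bp))
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_boot
  ref
}

#' Species labels of a tree's tips
#'
#' Tip labels follow the `species|gene` convention by default.
#'
#' @param tree a `phylo` object.
#' @param delim delimiter between species and gene fields.
#' @return character vector of species, one per tip.
#' @export
tip_species <- function(tree, delim = "|") {
  vapply(strsplit(tree$tip.label, delim, fixed = TRUE), `[`, character(1), 1L)
}

#' Detect gene duplications by species overlap
#'
#' An internal node of a rooted gene-family tree is flagged as a duplication
#' if the species sets of its two descendant clades intersect. A flagged
#' event is *accepted* when both emerging orthologous subfamilies span at
#' least two species. Polytomies are resolved arbitrarily (and flagged)
#' before scanning; unrooted trees require `root = "midpoint"`.
#'
#' @param tree a `phylo` object with species-labelled tips.
#' @param species optional character vector of per-tip species; parsed from
#'   tip labels via `delim` when absent.
#' @param root `"asis"` (tree must already be rooted) or `"midpoint"`.
#' @param delim tip-label delimiter for [tip_species()].
#' @return data.frame, one row per internal node: `node`, `duplication`,
#'   `accepted`, species counts, and list-columns with the two clades' tip
#'   labels. Attribute `events` holds the accepted/flagged events as a list.
#' @export
detect_duplications <- function(tree, species = NULL,
                                root = c("asis", "midpoint"), delim = "|") {
  root <- match.arg(root)
  if (!ape::is.rooted(tree)) {
    if (root == "asis")
      stop("tree is unrooted; supply a rooted tree or root = \"midpoint\"")
    tree <- phangorn::midpoint(tree)
  }
  polytomies <- !ape::is.binary(tree)
  if (polytomies) tree <- ape::multi2di(tree)
  if (is.null(species)) species <- tip_species(tree, delim)
  if (any(!nzchar(species)) || any(is.na(species)))
    stop("empty species labels")
  ntip <- length(tree$tip.label)
  # tip sets per node by postorder accumulation
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- i
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  rows <- lapply(internal, function(nd) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    spl <- lapply(ch, function(x) unique(species[tips_below[[x]]]))
    dup <- length(intersect(spl[[1]], spl[[2]])) > 0
    acc <- dup && all(lengths(spl) >= 2L)
    data.frame(node = nd, duplication = dup, accepted = acc,
               n_species_left = length(spl[[1]]),
               n_species_right = length(spl[[2]]))
  })
  out <- do.call(rbind, rows)
  out$tips <- lapply(internal, function(nd) tree$tip.label[tips_below[[nd]]])
  events <- lapply(which(out$duplication), function(k) {
    nd <- out$node[k]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    list(node = nd,
         left_species = unique(species[tips_below[[ch[1]]]]),
         right_species = unique(species[tips_below[[ch[2]]]]),
         tips = sort(tree$tip.label[tips_below[[nd]]]),
         accepted = out$accepted[k])
  })
  attr(out, "events") <- events
  attr(out, "polytomies_resolved") <- polytomies
  out
}
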