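#' Residue class schemes
#'
#' A residue class scheme assigns each of the 20 amino acids to physico-
#' chemical classes (hydrophobic, charged, turn, hydrophilic, ...). The
#' classes used for a given composition statistic must be pairwise disjoint
#' and every residue must belong to at least one declared class. Schemes are
#' data, not code: the default ships as an editable TSV and any alternative
#' hydropathy table can be supplied instead.
#'
#' @param classes named list mapping class name to a character vector of
#'   one-letter residue codes.
#' @return an object of class `residue_scheme`.
#' @export
residue_scheme <- function(classes) {
  classes <- lapply(classes, function(x) toupper(as.character(x)))
  all_res <- unlist(classes, use.names = FALSE)
  bad <- setdiff(all_res, AA1)
  if (length(bad))
    stop("unknown residues in scheme: ", paste(bad, collapse = ", "))
  if (anyDuplicated(all_res))
    stop("scheme classes must be disjoint; duplicated: ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  uncovered <- setdiff(AA1, all_res)
  if (length(uncovered))
    stop("every residue must map to a class; missing: ",
         paste(uncovered, collapse = ", "))
  structure(classes, class = "residue_scheme")
}

#' @rdname residue_scheme
#' @param path 2-column TSV (`residue`, `class`), one row per assignment.
#' @export
read_residue_scheme <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "class") %in% names(tab)))
    stop("scheme file needs columns 'residue' and 'class'")
  residue_scheme(split(tab$residue, tab$class))
}

#' @rdname residue_scheme
#' @details `default_residue_scheme()` returns the shipped default:
#'   hydrophobic \{A,V,L,I,M,F,W,C\}, charged \{D,E,K,R,H\},
#'   turn \{G,P,S,N\}, hydrophilic \{T,Q,Y\}.
#' @export
default_residue_scheme <- function() {
  read_residue_scheme(system.file("extdata", "residue_classes_default.tsv",
                                  package = "mcfevo", mustWork = TRUE))
}

#' Amino-acid class proportions of a residue string
#'
#' Computes the proportion of residues in each class of the scheme, after
#' gap removal. Proportions over the scheme's partition sum to 1. An empty
#' region (no residues after gap removal) yields `NA` proportions with
#' attribute `missing = TRUE` — never a silent zero.
#'
#' @param residues a residue string (or character vector of single residues);
#'   gaps are dropped.
#' @param scheme a [residue_scheme()].
#' @return named numeric vector of per-class proportions.
#' @export
class_proportions <- function(residues, scheme = default_residue_scheme()) {
  if (length(residues) == 1L && (is.na(residues) || nchar(residues) != 1L))
    residues <- strsplit(as.character(residues), "")[[1]]
  residues <- toupper(residues)
  residues <- residues[!(residues %in% GAP_CHARS) & !is.na(residues)]
  out <- stats::setNames(rep(NA_real_, length(scheme)), names(scheme))
  if (length(residues) == 0L) {
    attr(out, "missing") <- TRUE
    return(out)
  }
  bad <- setdiff(unique(residues), AA1)
  if (length(bad))
    stop("unknown residues: ", paste(bad, collapse = ", "))
  for (cl in names(scheme))
    out[cl] <- sum(residues %in% scheme[[cl]])
  out <- out / length(residues)
  attr(out, "missing") <- FALSE
  out
}

#' Per-sequence class proportion of a region across a pool
#'
#' The workhorse behind the resampling analysis: for every sequence in the
#' pool, the proportion of region residues (gaps excluded) that belong to
#' `class`. Sequences whose region is gap-only get `NA`.
#'
#' @param pool a [carrier_pool()].
#' @param model a [topology_model()].
#' @param region region label (see [region_columns()]).
#' @param class a class name of `scheme`.
#' @param scheme a [residue_scheme()].
#' @return numeric vector, one value per sequence, named by id.
#' @export
pool_class_proportions <- function(pool, model, region, class,
                                   scheme = default_residue_scheme()) {
  if (!class %in% names(scheme)) stop("unknown class: ", class)
  cols <- region_columns(model, region)
  m <- pool_matrix(pool, cols)
  is_gap <- m %in% GAP_CHARS
  dim(is_gap) <- dim(m)
  in_class <- m %in% scheme[[class]]
  dim(in_class) <- dim(m)
  n_res <- rowSums(!is_gap)
  out <- ifelse(n_res > 0, rowSums(in_class) / n_res, NA_real_)
  stats::setNames(out, pool$meta$id)
}

#' Mean pairwise sequence identity of a region
#'
#' Mean over all unordered sequence pairs of the percentage of matching
#' columns. Columns where both sequences are gaps are excluded from the
#' comparison; a column where exactly one sequence is gapped counts as a
#' mismatch (this convention is recorded on the result).
#'
#' @param pool a [carrier_pool()] with at least two sequences.
#' @param region optional region label; default uses all columns.
#' @param model required when `region` is given.
#' @return mean pairwise identity in percent, with attribute
#'   `gap_convention`.
#' @export
mean_pairwise_identity <- function(pool, region = NULL, model = NULL) {
  if (length(pool$seqs) < 2L) stop("need at least 2 sequences")
  cols <- if (is.null(region)) seq_len(pool$width) else {
    if (is.null(model)) stop("model is required when region is given")
    region_columns(model, region)
  }
  m <- pool_matrix(pool, cols)
  nongap <- !(m %in% GAP_CHARS)
  dim(nongap) <- dim(m)
  # matches(i,j) = sum over columns of [same residue, both non-gap]
  matches <- matrix(0, nrow(m), nrow(m))
  for (r in unique(as.vector(m[nongap]))) {
    b <- (m == r) & nongap
    matches <- matches + tcrossprod(b * 1)
  }
  # compared(i,j) = columns with at least one non-gap
  both_gap <- tcrossprod((!nongap) * 1)
  compared <- ncol(m) - both_gap
  idx <- which(upper.tri(matches))
  comp <- compared[idx]
  if (all(comp == 0)) stop("no comparable columns in region")
  ident <- matches[idx][comp > 0] / comp[comp > 0]
  structure(100 * mean(ident),
            gap_convention = "both-gap columns excluded; single-gap = mismatch")
}

#' Resampling distribution of a mean class proportion
#'
#' Emulates the pooled-resampling design of the analysis: draw `sample_size`
#' sequences from the pool by simple random sampling (without replacement
#' within a replicate, by default), average their per-sequence class
#' proportions in `region`, and repeat `replicates` times. The defaults
#' (132 sequences, 132 replicates) are the study design: 44 carriers times 3
#' species per phase. The empirical cumulative distribution of the replicate
#' means is the phase-comparison device.
#'
#' Sequences whose region is gap-only are excluded up front with a warning
#' and sampling proceeds over the remaining sequences.
#'
#' @param pool a [carrier_pool()].
#' @param model a [topology_model()].
#' @param region region label.
#' @param class residue class name.
#' @param sample_size sequences per replicate (default 132).
#' @param replicates number of replicates (default 132).
#' @param seed integer RNG seed; recorded on the result.
#' @param scheme a [residue_scheme()].
#' @param replace sample with replacement within a replicate? Default
#'   `FALSE`; pool sizes of ~160-210 against a sample of 132 make the two
#'   modes materially different, and without-replacement is the conservative
#'   reading of "sampled randomly from the pool".
#' @return an object of class `resampling_result`: `replicate_means`,
#'   `ecdf`, the per-sequence `proportions`, and all parameters.
#' @export
resample_ecdf <- function(pool, model, region, class,
                          sample_size = 132, replicates = 132, seed,
                          scheme = default_residue_scheme(),
                          replace = FALSE) {
  props <- pool_class_proportions(pool, model, region, class, scheme)
  n_skipped <- sum(is.na(props))
  if (n_skipped > 0) {
    warning(n_skipped, " sequence(s) with a gap-only ", region,
            " region skipped")
    props <- props[!is.na(props)]
  }
  if (!replace && sample_size > length(props))
    stop("sample_size (", sample_size, ") exceeds usable pool size (",
         length(props), ")")
  set.seed(as.integer(seed))
  means <- vapply(seq_len(replicates), function(i)
    mean(sample(props, sample_size, replace = replace)), numeric(1))
  structure(
    list(replicate_means = means, ecdf = stats::ecdf(means),
         proportions = props, sample_size = as.integer(sample_size),
         replicates = as.integer(replicates), seed = as.integer(seed),
         region = region, class = class, replace = replace,
         n_skipped = n_skipped),
    class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "Resampling: %s %s in %s | %d replicates of %d (%s replacement, seed %d)\n",
    x$class, "proportion", x$region, x$replicates, x$sample_size,
    if (x$replace) "with" else "without", x$seed))
  cat(sprintf("  replicate means: %.4f (sd %.4f)\n",
              mean(x$replicate_means), stats::sd(x$replicate_means)))
  invisible(x)
}

#' Write a resampling result as TSV plus JSON metadata
#'
#' @param x a [resample_ecdf()] result.
#' @param path output TSV (replicate index, mean); metadata is written next
#'   to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_resampling_tsv <- function(x, path) {
  utils::write.table(
    data.frame(replicate = seq_along(x$replicate_means),
               mean = x$replicate_means),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- x[c("sample_size", "replicates", "seed", "region", "class",
              "replace", "n_skipped")]
  meta$gap_convention <- "gap-only regions skipped; gaps excluded from counts"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Exact Kolmogorov-Smirnov distance between two ECDFs
#'
#' The sup-norm distance between the step functions, evaluated at all jump
#' points of either sample. Used as the separation measure between the
#' replicate-mean ECDFs of two phases.
#'
#' @param a,b numeric samples or [resample_ecdf()] results.
#' @return the KS distance in `[0, 1]`.
#' @export
ecdf_ks_distance <- function(a, b) {
  if (inherits(a, "resampling_result")) a <- a$replicate_means
  if (inherits(b, "resampling_result")) b <- b$replicate_means
  x <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(x)
  Fb <- stats::ecdf(b)(x)
  max(abs(Fa - Fb))
}

#' Two-sample KS test between the pools behind two resampling runs
#'
#' Tests whether the *per-sequence* region proportions of two pools come from
#' the same distribution, using the two-sample Kolmogorov-Smirnov statistic.
#' Replicate means from subsampling a pool are not independent draws (they
#' concentrate around the pool's own mean), so a KS test on replicate-mean
#' ECDFs is badly anticonservative; the valid pool-level comparison operates
#' on the per-sequence values. Because region proportions are heavily tied
#' (few residues per region), the default p-value is calibrated by label
#' permutation rather than the continuous asymptotic formula.
#'
#' When sequences are clustered — orthologous members of the same carrier
#' subfamily appear in both pools — plain permutation over-states the null
#' spread of D. Passing the subfamily labels as `strata_a`/`strata_b`
#' permutes pool membership *within* each subfamily, which matches how the
#' phase pools are actually assembled (the same carriers, different
#' species) and keeps the test exact under that design.
#'
#' @param a,b numeric vectors of per-sequence proportions, or
#'   [resample_ecdf()] results (their `proportions` are used).
#' @param method `"permutation"` (default) or `"asymptotic"`
#'   ([stats::ks.test]).
#' @param n_perm permutations for the calibrated p-value.
#' @param seed RNG seed for the permutation draw.
#' @param strata_a,strata_b optional per-sequence stratum labels (e.g.
#'   carrier subfamily); permutations then shuffle labels within strata.
#' @return list with `statistic` (D), `p.value` and `method`.
#' @export
ks_pool_test <- function(a, b, method = c("permutation", "asymptotic"),
                         n_perm = 999, seed = 1L,
                         strata_a = NULL, strata_b = NULL) {
  method <- match.arg(method)
  if (inherits(a, "resampling_result")) a <- a$proportions
  if (inherits(b, "resampling_result")) b <- b$proportions
  keep_a <- !is.na(a); keep_b <- !is.na(b)
  a <- a[keep_a]; b <- b[keep_b]
  if (!is.null(strata_a)) strata_a <- strata_a[keep_a]
  if (!is.null(strata_b)) strata_b <- strata_b[keep_b]
  D <- ecdf_ks_distance(a, b)
  if (method == "asymptotic") {
    p <- suppressWarnings(stats::ks.test(a, b)$p.value)
  } else {
    set.seed(as.integer(seed))
    v <- c(a, b)
    in_a <- rep(c(TRUE, FALSE), c(length(a), length(b)))
    strata <- if (is.null(strata_a) || is.null(strata_b))
      rep(1L, length(v)) else c(strata_a, strata_b)
    idx_by_stratum <- split(seq_along(v), strata)
    exceed <- vapply(seq_len(n_perm), function(i) {
      g <- in_a
      for (idx in idx_by_stratum)
        g[idx] <- g[idx][sample.int(length(idx))]
      ecdf_ks_distance(v[g], v[!g]) >= D
    }, logical(1))
    p <- (1 + sum(exceed)) / (n_perm + 1)
  }
  list(statistic = D, p.value = p, method = method,
       stratified = !(is.null(strata_a) || is.null(strata_b)))
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test) across two or
#' more groups of values, as used for the nine-species phase comparison of
#' class proportions. The fully degenerate case — every value identical in
#' every group — returns `F = 0`, `p = 1` with `degenerate = TRUE` rather
#' than `NaN`.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with `F`, `p.value`, `df` (numerator, denominator) and
#'   `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df <- c(nlevels(g) - 1L, length(values) - nlevels(g))
  if (stats::var(values) == 0)
    return(list(F = 0, p.value = 1, df = df, degenerate = TRUE))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p.value = fit$p.value, df = df,
       degenerate = FALSE)
}

#' Holm-Sidak step-down multiple-comparison decisions
#'
#' Orders the p-values, compares the k-th smallest against
#' `1 - (1 - alpha)^(1/(m - k + 1))` and stops at the first failure; all
#' earlier hypotheses are rejected, all later ones retained. Decisions are
#' monotone in the p-values and never exceed unadjusted per-comparison
#' testing. Sidak-adjusted p-values (step-down, cumulative-maximum) are
#' reported alongside.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return data.frame with `p`, `p.adjusted` and `reject`, in input order.
#' @export
holm_sidak <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- length(p)
  o <- order(p)
  k <- seq_len(m)
  thresh <- 1 - (1 - alpha)^(1 / (m - k + 1))
  ok <- p[o] <= thresh
  first_fail <- which(!ok)[1]
  reject_sorted <- if (is.na(first_fail)) rep(TRUE, m) else k < first_fail
  adj_sorted <- cummax(1 - (1 - p[o])^(m - k + 1))
  out <- data.frame(p = p, p.adjusted = NA_real_, reject = NA)
  out$p.adjusted[o] <- pmin(adj_sorted, 1)
  out$reject[o] <- reject_sorted
  out
}
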