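# Nei-Gojobori (1986) pathway counting with Jukes-Cantor correction, and the
# branch-site likelihood-ratio decision rule.

.ng86 <- new.env(parent = emptyenv())

# Codon index 1..64, amino acids from the standard genetic code, and
# memoised site/difference tables. Site fractions exclude mutations that
# create stop codons and renormalise over the remaining alternatives,
# matching the pathway rule below (paths through stops are dropped and the
# weights renormalised).
ng86_tables <- function() {
  if (!is.null(.ng86$codons)) return(.ng86)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  idx <- stats::setNames(seq_along(codons), codons)
  syn_sites <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { syn_sites[i] <- NA_real_; next }
    cs <- strsplit(codons[i], "")[[1]]
    s <- 0
    for (pos in 1:3) {
      alt <- BASES[BASES != cs[pos]]
      tgt <- vapply(alt, function(b) {
        x <- cs; x[pos] <- b; paste(x, collapse = "")
      }, character(1))
      taa <- aa[idx[tgt]]
      valid <- taa != "*"
      if (any(valid)) s <- s + sum(taa[valid] == aa[i]) / sum(valid)
    }
    syn_sites[i] <- s
  }
  perms <- list(matrix(1L, 1, 1),
                rbind(c(1L, 2L), c(2L, 1L)),
                rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  .ng86$codons <- codons; .ng86$aa <- aa; .ng86$idx <- idx
  .ng86$syn_sites <- syn_sites; .ng86$perms <- perms
  .ng86$sd <- matrix(NA_real_, 64, 64)
  .ng86$nd <- matrix(NA_real_, 64, 64)
  .ng86
}

# Pathway-averaged (synonymous, nonsynonymous) difference counts for one
# codon pair; paths through stop codons are excluded and the average taken
# over the remaining paths.
codon_diff_counts <- function(c1, c2) {
  tb <- ng86_tables()
  i <- tb$idx[[c1]]; j <- tb$idx[[c2]]
  if (!is.na(tb$sd[i, j])) return(c(tb$sd[i, j], tb$nd[i, j]))
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  k <- length(diffs)
  if (k == 0L) { res <- c(0, 0) } else {
    paths <- tb$perms[[k]]
    tot_s <- tot_n <- 0; n_valid <- 0L
    all_s <- all_n <- 0   # fallback accumulators, stops allowed
    for (r in seq_len(nrow(paths))) {
      cur <- a; s <- n <- 0; valid <- TRUE
      for (pos in diffs[paths[r, ]]) {
        nxt <- cur; nxt[pos] <- b[pos]
        aa1 <- tb$aa[tb$idx[[paste(cur, collapse = "")]]]
        aa2 <- tb$aa[tb$idx[[paste(nxt, collapse = "")]]]
        if (aa2 == "*") valid <- FALSE
        if (identical(aa1, aa2)) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      all_s <- all_s + s; all_n <- all_n + n
      if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n
                   n_valid <- n_valid + 1L }
    }
    res <- if (n_valid > 0L) c(tot_s, tot_n) / n_valid
           else c(all_s, all_n) / nrow(paths)
  }
  .ng86$sd[i, j] <- res[1]; .ng86$nd[i, j] <- res[2]
  res
}

split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) %% 3L != 0L)
    stop("sequence length must be a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) pathway method
#'
#' Counts synonymous and nonsynonymous sites per codon (per-position
#' fractions of single-nucleotide changes, averaged over the two sequences;
#' changes creating stop codons are excluded and the fractions
#' renormalised), counts observed differences by averaging over all
#' mutational pathways between differing codons (pathways through stop
#' codons excluded), and applies the Jukes-Cantor multiple-hit correction
#' `d = -3/4 log(1 - 4p/3)` to both proportions.
#'
#' Codon columns where either sequence carries a gap are dropped pairwise
#' before counting. The estimator is symmetric in its two arguments.
#'
#' @param seq1,seq2 in-frame nucleotide strings of equal length (multiple of
#'   3; `ACGT`/`U`, gaps `-`/`.` allowed in aligned input, no ambiguity
#'   codes, no internal stop codons).
#' @return an object of class `omega_estimate`: `dN`, `dS`, `omega` (`NA`
#'   and flagged `undefined` when `dS = 0`), `N_sites`, `S_sites`, raw
#'   difference counts `Nd`/`Sd`, `codons_used`, and `flags`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
ng86_dnds <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2))
    stop("sequences must have equal length")
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  gap_re <- "[-.]"
  keep <- !grepl(gap_re, c1) & !grepl(gap_re, c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  if (length(c1) == 0L) stop("no ungapped codon columns")
  bad <- grepl("[^TCAG]", c(c1, c2))
  if (any(bad))
    stop("ambiguity codes or invalid bases in codons: ",
         paste(unique(c(c1, c2)[bad]), collapse = ", "))
  tb <- ng86_tables()
  if (any(tb$aa[tb$idx[c1]] == "*") || any(tb$aa[tb$idx[c2]] == "*"))
    stop("internal stop codon")
  S1 <- sum(tb$syn_sites[tb$idx[c1]])
  S2 <- sum(tb$syn_sites[tb$idx[c2]])
  S <- (S1 + S2) / 2
  N <- 3 * length(c1) - S
  cnt <- vapply(seq_along(c1),
                function(i) codon_diff_counts(c1[i], c2[i]), numeric(2))
  Sd <- sum(cnt[1, ]); Nd <- sum(cnt[2, ])
  flags <- character(0)
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jc(pS); dN <- jc(pN)
  if (is.na(dS)) flags <- c(flags, "dS_saturated")
  if (is.na(dN)) flags <- c(flags, "dN_saturated")
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) {
    flags <- c(flags, "omega_undefined"); NA_real_
  } else dN / dS
  structure(list(dN = dN, dS = dS, omega = omega, N_sites = N, S_sites = S,
                 Nd = Nd, Sd = Sd, codons_used = length(c1), flags = flags),
            class = "omega_estimate")
}

#' @export
print.omega_estimate <- function(x, ...) {
  cat(sprintf("NG86: dN = %.4f, dS = %.4f, omega = %s (%d codons)\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega),
              x$codons_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Summary and ECDF of a set of omega estimates
#'
#' @param estimates list of [ng86_dnds()] results (or a numeric vector of
#'   omega values).
#' @return list with `mean_omega`, `omegas`, `ecdf` and `n_undefined`.
#' @export
omega_distribution <- function(estimates) {
  om <- if (is.numeric(estimates)) estimates else
    vapply(estimates, function(e) e$omega, numeric(1))
  n_undef <- sum(is.na(om))
  om <- om[!is.na(om)]
  if (length(om) == 0L) stop("all omega estimates are undefined")
  list(mean_omega = mean(om), omegas = om, ecdf = stats::ecdf(om),
       n_undefined = n_undef)
}

#' Critical value of the branch-site test's mixture null
#'
#' The null distribution of `2*lambda` for the branch-site test of positive
#' selection is a 50:50 mixture of a point mass at 0 and chi-square with 1
#' degree of freedom; the critical value c solves
#' `0.5 * P(chisq_1 > c) = alpha` for `alpha < 0.5` (c = 0 otherwise).
#' At the 5% and 1% levels this gives 2.71 and 5.41.
#'
#' @param alpha significance level in (0, 1).
#' @return the critical value of `2*lambda`.
#' @export
lrt_critical_value <- function(alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (alpha >= 0.5) return(0)
  stats::qchisq(2 * alpha, df = 1, lower.tail = FALSE)
}

#' Branch-site likelihood-ratio decision
#'
#' Consumes the log-likelihoods of the null model (foreground omega fixed at
#' 1) and the alternative model (foreground omega free >= 1) and applies the
#' decision rule: `2*lambda = 2 (lnL_alt - lnL_null)` exceeds the mixture
#' critical value strictly. Numerically negative `2*lambda` is clipped to 0
#' and flagged.
#'
#' @param lnl_null,lnl_alt log-likelihoods of the null and alternative
#'   models.
#' @param alpha significance level.
#' @return an object of class `lrt_result`: `two_lambda`, `alpha`,
#'   `critical_value`, `significant`, `clipped`.
#' @export
branch_site_lrt <- function(lnl_null, lnl_alt, alpha = 0.05) {
  crit <- lrt_critical_value(alpha)
  tl <- 2 * (lnl_alt - lnl_null)
  clipped <- tl < 0
  tl <- pmax(tl, 0)
  structure(list(two_lambda = tl, alpha = alpha, critical_value = crit,
                 significant = tl > crit, clipped = clipped),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("2*lambda = %.4f vs critical %.2f (alpha = %g): %s\n",
              x$two_lambda, x$critical_value, x$alpha,
              if (x$significant) "positive selection" else "not significant"))
  invisible(x)
}

#' Apply the branch-site decision rule to a table of likelihoods
#'
#' @param path 3-column TSV with `family`, `lnl_null`, `lnl_alt`.
#' @param alpha significance level.
#' @return the table with `two_lambda`, `critical_value`, `significant` and
#'   `clipped` columns appended.
#' @export
lrt_table <- function(path, alpha = 0.05) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "lnl_null", "lnl_alt")
  if (!all(need %in% names(tab)))
    stop("LRT input needs columns ", paste(need, collapse = ", "))
  res <- branch_site_lrt(tab$lnl_null, tab$lnl_alt, alpha)
  tab$two_lambda <- res$two_lambda
  tab$critical_value <- res$critical_value
  tab$significant <- res$significant
  tab$clipped <- res$clipped
  tab
}
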