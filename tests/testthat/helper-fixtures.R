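# Shared fixtures: a small hand-checkable topology, pool builders, and an
# independent brute-force NG86 oracle.

# 76-column toy layout: 8-column helices, 4-column loops and termini.
# Splits default to the midpoint (e.g. TR1 5-12 splits at 9), motif anchors
# on the last six columns of the odd helices.
toy_intervals <- function() {
  list(helices = list(c(5, 12), c(17, 24), c(29, 36),
                      c(41, 48), c(53, 60), c(65, 72)),
       loops = list(n = c(1, 4), loop1 = c(13, 16), loop2 = c(25, 28),
                    loop3 = c(37, 40), loop4 = c(49, 52), loop5 = c(61, 64),
                    c = c(73, 76)),
       width = 76, anchors = c(7, 31, 55))
}

toy_model <- function(insert_at = NULL, n_insert = 0L, splits = NULL) {
  iv <- toy_intervals()
  shift <- function(x) {
    if (is.null(insert_at) || n_insert == 0L) return(x)
    x + n_insert * (x >= insert_at)
  }
  topology_model(
    helices = lapply(iv$helices, shift),
    loops = lapply(iv$loops, shift),
    alignment_width = iv$width + n_insert,
    motif_anchors = shift(iv$anchors),
    splits = if (!is.null(splits)) splits else NULL)
}

# a toy sequence with given default residue and column overrides
toy_seq <- function(fill = "G", overrides = list(), width = 76) {
  chars <- rep(fill, width)
  for (ov in overrides) {
    cols <- ov$at:(ov$at + nchar(ov$str) - 1L)
    chars[cols] <- strsplit(ov$str, "")[[1]]
  }
  paste(chars, collapse = "")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_aligned_seq <- function(width, gap_prob = 0.1) {
  chars <- sample(AA20, width, replace = TRUE)
  gaps <- runif(width) < gap_prob
  chars[gaps] <- "-"
  paste(chars, collapse = "")
}

# reassemble a partition into the aligned input string
reassemble <- function(part) {
  chars <- rep("-", part$model$alignment_width)
  for (r in part$regions) {
    if (!r$empty)
      chars[r$residue_columns] <- strsplit(r$residues, "")[[1]]
  }
  paste(chars, collapse = "")
}

# ---- independent NG86 oracle -------------------------------------------
# Brute force: translation via seqinr, explicit enumeration of all
# mutational pathways per codon pair (paths through stop codons dropped,
# falling back to all paths if none survives), per-position synonymous site
# fractions over non-stop single-nucleotide changes, Jukes-Cantor
# correction of both proportions.

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(c(1L, 2L), c(2L, 1L)))
  out <- list()
  for (i in 1:3) for (rest in oracle_perms(2))
    out[[length(out) + 1L]] <- c(i, setdiff(1:3, i)[rest])
  out
}

oracle_codon_sites <- function(codon) {
  cs <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(c("T", "C", "A", "G"), cs[pos])) {
      x <- cs; x[pos] <- b
      taa <- oracle_translate(paste(x, collapse = ""))
      if (taa == "*") next
      valid <- valid + 1
      if (taa == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_codon_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  if (length(diffs) == 0) return(c(0, 0))
  acc <- list(valid = c(0, 0, 0), all = c(0, 0, 0))  # syn, nonsyn, count
  for (perm in oracle_perms(length(diffs))) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (pos in diffs[perm]) {
      nxt <- cur; nxt[pos] <- b[pos]
      a1 <- oracle_translate(paste(cur, collapse = ""))
      a2 <- oracle_translate(paste(nxt, collapse = ""))
      if (a2 == "*") ok <- FALSE
      if (a1 == a2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    acc$all <- acc$all + c(s, n, 1)
    if (ok) acc$valid <- acc$valid + c(s, n, 1)
  }
  use <- if (acc$valid[3] > 0) acc$valid else acc$all
  use[1:2] / use[3]
}

ng86_oracle <- function(seq1, seq2) {
  sp <- function(s) substring(toupper(s), seq(1, nchar(s), 3),
                              seq(3, nchar(s), 3))
  c1 <- sp(seq1); c2 <- sp(seq2)
  keep <- !grepl("[-.]", c1) & !grepl("[-.]", c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  S <- (sum(vapply(c1, oracle_codon_sites, numeric(1))) +
        sum(vapply(c2, oracle_codon_sites, numeric(1)))) / 2
  N <- 3 * length(c1) - S
  d <- vapply(seq_along(c1),
              function(i) oracle_codon_diffs(c1[i], c2[i]), numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dN = jc(Nd / N), dS = jc(Sd / S), N_sites = N, S_sites = S,
       Nd = Nd, Sd = Sd)
}
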