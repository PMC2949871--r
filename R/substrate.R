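# Conical-pit mark sequences, position frequency matrices and the
# E-value-based carrier-age metric.

#' Extract the conical-pit mark sequence of a carrier
#'
#' The conical pit of the carrier fold is lined by three Px(D/E)xx(K/R)
#' signature motifs at the C-terminal (matrix) ends of the odd helices TR1,
#' TR3 and TR5. For each odd helix the motif is located by pattern search
#' in a window of `window` ungapped residues around the configured anchor
#' position; the match whose start is nearest to the anchor wins (ties go to
#' the left). The three 6-mers are concatenated in helix order into the
#' 18-residue mark sequence used as a substrate-selectivity proxy.
#'
#' A helix with no match contributes a `"------"` placeholder and the motif
#' is flagged missing; `complete` is `TRUE` only when all three motifs
#' matched.
#'
#' @param seq aligned amino-acid string (or length-1 [carrier_pool()]
#'   subset).
#' @param model a [topology_model()] carrying the motif anchors.
#' @param window search half-width in ungapped residues around the anchor.
#' @return an object of class `mark_sequence`: `mark` (18 characters when
#'   complete), `motifs` (3 strings), `starts` (ungapped 1-based start
#'   positions), `found` (logical per motif), `complete`.
#' @export
extract_mark_sequence <- function(seq, model, window = 10L) {
  if (inherits(seq, "carrier_pool")) seq <- seq$seqs[[1]]
  window <- as.integer(window)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) != model$alignment_width)
    stop("sequence length does not match the model's alignment width")
  nongap <- !(chars %in% GAP_CHARS)
  ungapped <- paste(chars[nongap], collapse = "")
  # ungapped position of each alignment column (position of last residue at
  # or before the column)
  cum <- cumsum(nongap)
  motifs <- character(3); starts <- rep(NA_integer_, 3); found <- logical(3)
  for (k in 1:3) {
    anchor_col <- model$motif_anchors[k]
    anchor_pos <- max(cum[anchor_col], 1L)
    lo <- max(1L, anchor_pos - window)
    hi <- min(nchar(ungapped), anchor_pos + window + 5L)
    win <- substr(ungapped, lo, hi)
    m <- gregexpr(MOTIF_REGEX, win, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      motifs[k] <- "------"
      next
    }
    cand <- as.integer(m) + as.integer(lo) - 1L
    best <- cand[order(abs(cand - anchor_pos), cand)][1]
    motifs[k] <- substr(ungapped, best, best + 5L)
    starts[k] <- as.integer(best)
    found[k] <- TRUE
  }
  structure(list(mark = paste(motifs, collapse = ""), motifs = motifs,
                 starts = starts, found = found, complete = all(found)),
            class = "mark_sequence")
}

#' @export
print.mark_sequence <- function(x, ...) {
  cat("Mark sequence:", x$mark,
      if (x$complete) "(complete)" else "(incomplete)", "\n")
  invisible(x)
}

#' Mark sequences for a whole pool
#'
#' @param pool a [carrier_pool()].
#' @param model a [topology_model()].
#' @param window see [extract_mark_sequence()].
#' @return data.frame with `id`, `mark`, `complete` and per-motif start
#'   columns.
#' @export
pool_mark_sequences <- function(pool, model, window = 10L) {
  ms <- lapply(pool$seqs, extract_mark_sequence, model = model,
               window = window)
  data.frame(id = pool$meta$id,
             mark = vapply(ms, `[[`, character(1), "mark"),
             complete = vapply(ms, `[[`, logical(1), "complete"),
             start1 = vapply(ms, function(m) m$starts[1], integer(1)),
             start2 = vapply(ms, function(m) m$starts[2], integer(1)),
             start3 = vapply(ms, function(m) m$starts[3], integer(1)),
             stringsAsFactors = FALSE)
}

#' Position frequency matrix of equal-length sequences
#'
#' The per-column residue frequencies underlying a sequence logo. Columns
#' sum to 1.
#'
#' @param seqs character vector of equal-length residue strings.
#' @return an object of class `pfm`: a 20 x L matrix of frequencies with
#'   attributes `n_seqs`.
#' @export
pfm <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) == 0L) stop("need at least one sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  m <- do.call(rbind, strsplit(seqs, ""))
  freq <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    col <- col[!(col %in% GAP_CHARS)]
    tab <- table(factor(col, levels = AA1))
    as.numeric(tab) / max(length(col), 1L)
  }, numeric(length(AA1)))
  rownames(freq) <- AA1
  structure(freq, n_seqs = length(seqs), class = "pfm")
}

#' Mean per-column Jensen-Shannon divergence between two PFMs
#'
#' Quantifies how similar two sequence logos are: 0 iff every column
#' distribution is identical, 1 (in bits, log base 2) when every column uses
#' disjoint residue sets. This is the numeric counterpart of comparing logo
#' charts by eye.
#'
#' @param a,b [pfm()] objects (or sequence vectors, converted on the fly)
#'   with equal column counts.
#' @return mean per-column JS divergence in `[0, 1]` bits.
#' @export
pfm_divergence <- function(a, b) {
  if (!inherits(a, "pfm")) a <- pfm(a)
  if (!inherits(b, "pfm")) b <- pfm(b)
  if (ncol(a) != ncol(b)) stop("PFMs have different column counts")
  js_col <- function(p, q) {
    m <- (p + q) / 2
    kl <- function(x, y) {
      i <- x > 0
      sum(x[i] * log2(x[i] / y[i]))
    }
    kl(p, m) / 2 + kl(q, m) / 2
  }
  mean(vapply(seq_len(ncol(a)), function(j) js_col(a[, j], b[, j]),
              numeric(1)))
}

#' Carrier-cluster age from E-value exponents
#'
#' For each carrier, the mean of `log10` of its `k` smallest E-values
#' against a reference proteome set; the cluster value is the mean over its
#' carriers. More negative exponents mean stronger ancient similarity, hence
#' an older carrier lineage. Averaging in log10 space is the geometric-mean
#' reading of "average E-value" implied by exponent notation.
#'
#' Carriers with fewer than `k` E-values use all of them, with a warning.
#' E-values of exactly 0 are clipped to `10^floor_exponent` and flagged;
#' other non-positive values are errors.
#'
#' @param evalues named list: carrier id -> numeric vector of E-values, or a
#'   data.frame with columns `carrier` and `evalue` (as read by
#'   [read_evalues()]).
#' @param clusters named character vector: carrier id -> cluster label.
#' @param k number of smallest E-values to average (default 10).
#' @param floor_exponent exponent used for E = 0.
#' @return list with `carriers` (data.frame: carrier, cluster,
#'   mean_exponent, n_used) and `clusters` (data.frame: cluster,
#'   mean_exponent, n_carriers), clusters ordered oldest (most negative)
#'   first.
#' @export
cluster_age <- function(evalues, clusters, k = 10L, floor_exponent = -180) {
  if (is.data.frame(evalues))
    evalues <- split(evalues$evalue, evalues$carrier)
  missing <- setdiff(names(evalues), names(clusters))
  if (length(missing))
    stop("carriers without cluster assignment: ",
         paste(missing, collapse = ", "))
  per <- lapply(names(evalues), function(id) {
    ev <- evalues[[id]]
    if (any(ev < 0)) stop("negative E-value for ", id)
    zero <- ev == 0
    if (any(zero)) {
      warning("E-value of 0 for ", id, " clipped to 1e", floor_exponent)
      ev[zero] <- 10^floor_exponent
    }
    if (length(ev) < k)
      warning("carrier ", id, " has only ", length(ev),
              " E-values; using all of them")
    used <- sort(ev)[seq_len(min(k, length(ev)))]
    data.frame(carrier = id, cluster = unname(clusters[id]),
               mean_exponent = mean(log10(used)), n_used = length(used),
               stringsAsFactors = FALSE)
  })
  carriers <- do.call(rbind, per)
  cl <- stats::aggregate(mean_exponent ~ cluster, carriers, mean)
  cl$n_carriers <- as.vector(table(carriers$cluster)[cl$cluster])
  cl <- cl[order(cl$mean_exponent), ]
  rownames(cl) <- NULL
  list(carriers = carriers, clusters = cl)
}

#' Read a tabular E-value list
#'
#' Three tab-separated columns, `carrier`, `subject`, `evalue` — the shape
#' of tabular output from common local-alignment search tools.
#'
#' @param path TSV file.
#' @return data.frame with those columns.
#' @export
read_evalues <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("carrier", "subject", "evalue")
  if (!all(need %in% names(tab)))
    stop("E-value list needs columns ", paste(need, collapse = ", "))
  tab
}
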