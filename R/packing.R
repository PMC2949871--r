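#' Per-residue helix packing values
#'
#' Packing values are dimensionless per-residue measures of how densely a
#' residue packs against neighbouring helices in membrane proteins; region
#' averages proxy the compactness ("tightness") of the transmembrane bundle.
#' The table must cover all 20 residues with finite positive values. The
#' package ships a *synthetic* example table
#' (`extdata/packing_values_synthetic.tsv`) with plausible magnitudes; users
#' supply their preferred published table as a 2-column TSV
#' (`residue`, `value`).
#'
#' @param values named numeric vector (names = one-letter residue codes).
#' @param source free-text provenance label carried on the object.
#' @return an object of class `packing_table` (a named numeric vector).
#' @export
packing_table <- function(values, source = "user") {
  values <- unlist(values)
  names(values) <- toupper(names(values))
  missing <- setdiff(AA1, names(values))
  if (length(missing))
    stop("packing table must cover all 20 residues; missing: ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("packing values must be finite and positive")
  structure(values[AA1], source = source, class = "packing_table")
}

#' @rdname packing_table
#' @param path 2-column TSV (`residue`, `value`).
#' @export
read_packing_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab)))
    stop("packing table file needs columns 'residue' and 'value'")
  packing_table(stats::setNames(tab$value, tab$residue), source = path)
}

#' @rdname packing_table
#' @export
synthetic_packing_table <- function() {
  read_packing_table(system.file("extdata", "packing_values_synthetic.tsv",
                                 package = "mcfevo", mustWork = TRUE))
}

#' Mean packing value of a region across a pool
#'
#' Averages per-residue packing values over the non-gap residues of `region`.
#' Three aggregations are reported because "the mean packing value of a pool"
#' is ambiguous: `residues` is the grand mean over all residues (default),
#' `sequences` first averages within each sequence, `carriers` first averages
#' within each subfamily. With complete gap-free pools of equal-length
#' regions all three coincide.
#'
#' @param pool a [carrier_pool()].
#' @param model a [topology_model()].
#' @param region region label.
#' @param table a [packing_table()].
#' @param aggregate one of `"residues"`, `"sequences"`, `"carriers"`.
#' @return the mean packing value (numeric scalar).
#' @export
mean_packing <- function(pool, model, region,
                         table = synthetic_packing_table(),
                         aggregate = c("residues", "sequences", "carriers")) {
  aggregate <- match.arg(aggregate)
  cols <- region_columns(model, region)
  m <- pool_matrix(pool, cols)
  is_gap <- m %in% GAP_CHARS
  dim(is_gap) <- dim(m)
  res <- m[!is_gap]
  if (length(res) == 0L)
    stop("region ", region, " is empty (gap-only) in the whole pool")
  bad <- setdiff(unique(res), names(table))
  if (length(bad))
    stop("residues absent from packing table: ", paste(bad, collapse = ", "))
  v <- matrix(NA_real_, nrow(m), ncol(m))
  v[!is_gap] <- unname(table[m[!is_gap]])
  per_seq <- rowMeans(v, na.rm = TRUE)
  switch(aggregate,
    residues = mean(v[!is_gap]),
    sequences = mean(per_seq[!is.nan(per_seq)]),
    carriers = {
      sf <- pool$meta$subfamily
      if (all(is.na(sf))) stop("pool has no subfamily annotations")
      mean(tapply(per_seq[!is.nan(per_seq)], sf[!is.nan(per_seq)], mean))
    })
}

#' Per-phase packing summary of a pool set
#'
#' Convenience wrapper producing the (phase, region) table written by the
#' analysis scripts, with all three aggregations.
#'
#' @param pools named list of [carrier_pool()] objects (names = phases).
#' @param model a [topology_model()].
#' @param regions character vector of region labels.
#' @param table a [packing_table()].
#' @return data.frame with columns phase, region and the three means.
#' @export
packing_summary <- function(pools, model, regions,
                            table = synthetic_packing_table()) {
  rows <- expand.grid(phase = names(pools), region = regions,
                      stringsAsFactors = FALSE)
  for (agg in c("residues", "sequences", "carriers")) {
    rows[[paste0("mean_", agg)]] <- mapply(function(ph, rg) {
      tryCatch(mean_packing(pools[[ph]], model, rg, table, agg),
               error = function(e) NA_real_)
    }, rows$phase, rows$region)
  }
  rows
}
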