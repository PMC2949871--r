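#' Structural-region model of the six-helix carrier fold
#'
#' A `topology_model` maps alignment columns onto the canonical mitochondrial
#' carrier architecture: six transmembrane alpha-helices (TR1..TR6), each cut
#' by a split column into a cytosol-facing (UP) and a matrix-facing (DOWN)
#' half, tiled with the hydrophilic segments (the N-terminus `n`, loops
#' `loop1..loop5`, the C-terminus `c`). Three motif anchors mark where the
#' Px(D/E)xx(K/R) signature motif is expected to start, at the C-terminal
#' (matrix) end of the odd helices TR1, TR3 and TR5.
#'
#' Coordinates are 1-based inclusive alignment columns. Helix boundaries are
#' data, not code: they come from a topology configuration (see
#' [load_topology()]) so that alternative helix definitions can be swapped in
#' without touching the partitioning logic.
#'
#' @param helices list of six integer vectors `c(start, end)`, ordered and
#'   pairwise disjoint.
#' @param loops named list of intervals for `n`, `loop1`..`loop5`, `c`.
#'   Together with the helices these must tile `1:alignment_width` exactly.
#' @param alignment_width total number of alignment columns.
#' @param motif_anchors integer vector of length 3: the expected first column
#'   of the signature motif in TR1, TR3, TR5.
#' @param splits optional integer vector of length 6; `splits[k]` is the first
#'   column of the *second* half of helix k. Defaults to `ceiling((a+b)/2)`,
#'   the vertical midpoint of the helix.
#' @param up_first optional logical vector of length 6: is the first half of
#'   helix k the cytosol-facing (UP) half? Defaults to the alternating
#'   membrane orientation of the carrier fold: odd helices run cytosol to
#'   matrix (UP first), even helices matrix to cytosol (DOWN first).
#' @return an object of class `topology_model`.
#' @seealso [load_topology()], [partition_sequence()], [composite_region()]
#' @export
topology_model <- function(helices, loops, alignment_width, motif_anchors,
                           splits = NULL, up_first = NULL) {
  if (length(helices) != 6L)
    stop("exactly 6 helix intervals are required, got ", length(helices))
  helices <- lapply(helices, function(h) {
    h <- as.integer(h)
    if (length(h) != 2L || anyNA(h) || h[1] > h[2])
      stop("helix intervals must be c(start, end) with start <= end")
    h
  })
  starts <- vapply(helices, `[`, integer(1), 1L)
  ends <- vapply(helices, `[`, integer(1), 2L)
  if (any(diff(starts) <= 0) || any(starts[-1] <= ends[-6]))
    stop("helix intervals must be strictly increasing and pairwise disjoint")

  loop_names <- c("n", paste0("loop", 1:5), "c")
  if (!setequal(names(loops), loop_names))
    stop("loops must be named ", paste(loop_names, collapse = ", "))
  loops <- lapply(loops[loop_names], function(h) {
    h <- as.integer(h)
    if (length(h) != 2L || anyNA(h) || h[1] > h[2])
      stop("loop intervals must be c(start, end) with start <= end")
    h
  })

  covered <- integer(0)
  for (h in c(helices, loops)) covered <- c(covered, h[1]:h[2])
  if (anyDuplicated(covered))
    stop("helix and loop intervals overlap")
  if (!setequal(covered, seq_len(alignment_width)))
    stop("helix + loop intervals must tile columns 1..", alignment_width,
         " exactly")

  if (is.null(splits))
    splits <- ceiling((starts + ends) / 2)
  splits <- as.integer(splits)
  if (length(splits) != 6L)
    stop("need one split column per helix")
  # split column = first column of the second half; both halves non-empty
  if (any(splits <= starts) || any(splits > ends))
    stop("each split column must lie inside its helix interval")

  if (is.null(up_first))
    up_first <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  if (length(up_first) != 6L || !is.logical(up_first))
    stop("up_first must be a logical vector of length 6")

  motif_anchors <- as.integer(motif_anchors)
  if (length(motif_anchors) != 3L)
    stop("exactly 3 motif anchors are required (TR1, TR3, TR5)")
  odd <- c(1L, 3L, 5L)
  for (i in seq_along(odd)) {
    k <- odd[i]
    if (motif_anchors[i] < starts[k] || motif_anchors[i] + 5L > ends[k])
      stop("motif anchor ", i, " must leave room for a 6-mer inside helix ", k)
  }

  structure(
    list(helices = helices, splits = splits, up_first = up_first,
         loops = loops, motif_anchors = motif_anchors,
         alignment_width = as.integer(alignment_width)),
    class = "topology_model")
}

#' @export
print.topology_model <- function(x, ...) {
  cat("Topology model:", x$alignment_width, "alignment columns\n")
  for (k in 1:6) {
    h <- x$helices[[k]]
    cat(sprintf("  TR%d %d-%d (split at %d, %s half first)\n", k, h[1], h[2],
                x$splits[k], if (x$up_first[k]) "UP" else "DOWN"))
  }
  cat("  motif anchors:", paste(x$motif_anchors, collapse = ", "), "\n")
  invisible(x)
}

#' Read a topology model from a YAML configuration
#'
#' The configuration lists the six helix intervals, the loop intervals, the
#' alignment width and the three motif anchors; split columns and helix
#' orientation are optional (see [topology_model()] for defaults). The
#' package ships an editable default under
#' `system.file("extdata", "topology_default.yml", package = "mcfevo")`.
#'
#' @param path path to a YAML topology configuration.
#' @return a validated [topology_model()].
#' @export
load_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("alignment_width", "helices", "loops", "motif_anchors")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("topology config is missing: ", paste(missing, collapse = ", "))
  # YAML 1.1 parses a bare `n` key as FALSE; map it back
  names(cfg$loops)[names(cfg$loops) == "FALSE"] <- "n"
  iv <- function(x) c(x$start, x$end)
  topology_model(
    helices = lapply(cfg$helices, iv),
    loops = lapply(cfg$loops, iv),
    alignment_width = cfg$alignment_width,
    motif_anchors = unlist(cfg$motif_anchors),
    splits = if (!is.null(cfg$splits)) unlist(cfg$splits),
    up_first = if (!is.null(cfg$up_first)) unlist(cfg$up_first))
}

#' The default topology model shipped with the package
#'
#' A 200-column six-helix layout (20-column helices, 12-column loops,
#' 10-column termini) with midpoint splits and signature-motif anchors on the
#' last six columns of the odd helices. It is the layout the synthetic-data
#' generator emits; it is a faithful *shape* of the carrier fold, not the
#' boundary columns of any particular curated alignment.
#'
#' @return a [topology_model()].
#' @export
default_topology <- function() {
  load_topology(system.file("extdata", "topology_default.yml",
                            package = "mcfevo", mustWork = TRUE))
}

# Atomic region name -> integer columns, in column order.
atomic_regions <- function(model) {
  out <- list()
  out[["n"]] <- model$loops$n[1]:model$loops$n[2]
  for (k in 1:6) {
    h <- model$helices[[k]]
    s <- model$splits[k]
    first <- h[1]:(s - 1L)
    second <- s:h[2]
    if (model$up_first[k]) {
      out[[paste0("TR", k, "_UP")]] <- first
      out[[paste0("TR", k, "_DOWN")]] <- second
    } else {
      out[[paste0("TR", k, "_DOWN")]] <- first
      out[[paste0("TR", k, "_UP")]] <- second
    }
    if (k < 6) {
      l <- model$loops[[paste0("loop", k)]]
      out[[paste0("loop", k)]] <- l[1]:l[2]
    }
  }
  out[["c"]] <- model$loops$c[1]:model$loops$c[2]
  # order regions by first column so concatenation is column-ordered
  out[order(vapply(out, min, integer(1)))]
}

composite_table <- function() {
  odd <- c(1, 3, 5); even <- c(2, 4, 6)
  half <- function(ks, side) paste0("TR", ks, "_", side)
  list(
    TR         = c(half(1:6, "UP"), half(1:6, "DOWN")),
    TR_UP      = half(1:6, "UP"),
    TR_DOWN    = half(1:6, "DOWN"),
    TR135      = c(half(odd, "UP"), half(odd, "DOWN")),
    TR246      = c(half(even, "UP"), half(even, "DOWN")),
    TR_UP135   = half(odd, "UP"),
    TR_UP246   = half(even, "UP"),
    TR_DOWN135 = half(odd, "DOWN"),
    TR_DOWN246 = half(even, "DOWN"),
    LOOP135    = paste0("loop", odd),
    NCLOOP24   = c("n", "c", "loop2", "loop4"))
}

#' Alignment columns of a named region
#'
#' Resolves an atomic region (`n`, `c`, `loop1..5`, `TR1_UP`, ... `TR6_DOWN`),
#' a composite region (`TR`, `TR_UP`, `TR_DOWN`, `TR135`, `TR246`,
#' `TR_UP135`, `TR_UP246`, `TR_DOWN135`, `TR_DOWN246`, `LOOP135`,
#' `NCLOOP24`) or the conical-pit region `CPR` (the three 6-column motif
#' windows) to its sorted alignment columns.
#'
#' @param model a [topology_model()].
#' @param name region label.
#' @return sorted integer vector of alignment columns.
#' @export
region_columns <- function(model, name) {
  atoms <- atomic_regions(model)
  if (name %in% names(atoms)) return(atoms[[name]])
  comp <- composite_table()
  if (name %in% names(comp))
    return(sort(unlist(atoms[comp[[name]]], use.names = FALSE)))
  if (name == "CPR")
    return(sort(unlist(lapply(model$motif_anchors, function(a) a:(a + 5L)))))
  stop("unknown region name: ", name)
}

#' Region names understood by [region_columns()]
#' @param model a [topology_model()].
#' @return character vector of atomic and composite region labels.
#' @export
region_names <- function(model) {
  c(names(atomic_regions(model)), names(composite_table()), "CPR")
}

#' Partition an aligned carrier sequence into structural regions
#'
#' Cuts one aligned sequence into the atomic regions of the model. Gap
#' characters (`-`, `.`) are excluded from the per-region residue strings but
#' the column provenance of every retained residue is kept, so the partition
#' can be reassembled into the input exactly.
#'
#' @param seq an aligned amino-acid string (gaps allowed), or a length-1
#'   subset of a [carrier_pool()].
#' @param model a [topology_model()]; the sequence length must equal the
#'   model's alignment width.
#' @return an object of class `region_partition`: a list with `regions` (per
#'   atomic region: `residues`, gap-free; `columns`, all columns of the
#'   region; `residue_columns`, the columns of the retained residues;
#'   `empty`, flag for gap-only regions), the input `sequence` and the
#'   `model`.
#' @export
partition_sequence <- function(seq, model) {
  if (inherits(seq, "carrier_pool")) {
    if (length(seq$seqs) != 1L)
      stop("pass a single sequence (subset the pool first)")
    seq <- seq$seqs[[1]]
  }
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) != model$alignment_width)
    stop("sequence length ", length(chars), " does not match alignment width ",
         model$alignment_width)
  bad <- setdiff(unique(chars), c(AA1, GAP_CHARS))
  if (length(bad))
    stop("non-amino-acid characters in sequence: ",
         paste(bad, collapse = ", "))
  atoms <- atomic_regions(model)
  regions <- lapply(atoms, function(cols) {
    cc <- chars[cols]
    keep <- !(cc %in% GAP_CHARS)
    list(residues = paste(cc[keep], collapse = ""),
         columns = cols,
         residue_columns = cols[keep],
         empty = !any(keep))
  })
  structure(list(regions = regions, sequence = seq, model = model),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  lens <- vapply(x$regions, function(r) nchar(r$residues), integer(1))
  cat("Region partition of a", x$model$alignment_width, "column sequence\n")
  print(lens)
  invisible(x)
}

#' Extract a composite region from a partition
#'
#' Composite regions are exact unions of atomic regions, concatenated in
#' column order (`CPR` is the union of the three motif windows). See
#' [region_columns()] for the defined labels.
#'
#' @param partition a [partition_sequence()] result.
#' @param name composite (or atomic) region label.
#' @return list with `residues` (gap-free string), `columns` (all columns of
#'   the region) and `residue_columns`.
#' @export
composite_region <- function(partition, name) {
  model <- partition$model
  cols <- region_columns(model, name)  # errors on unknown names
  chars <- strsplit(partition$sequence, "")[[1]]
  cc <- chars[cols]
  keep <- !(cc %in% GAP_CHARS)
  list(residues = paste(cc[keep], collapse = ""),
       columns = cols, residue_columns = cols[keep])
}

#' Write per-region partitions of a pool as TSV
#'
#' One row per (sequence, atomic region): id, region, gap-free residues and
#' comma-separated source columns.
#'
#' @param pool a [carrier_pool()].
#' @param model a [topology_model()].
#' @param path output file.
#' @return the output path, invisibly.
#' @export
write_partition_tsv <- function(pool, model, path) {
  rows <- list()
  for (i in seq_along(pool$seqs)) {
    part <- partition_sequence(pool$seqs[[i]], model)
    for (rn in names(part$regions)) {
      r <- part$regions[[rn]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = pool$meta$id[i], region = rn, residues = r$residues,
        columns = paste(r$columns, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
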