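#' Build a pool of aligned, annotated carrier sequences
#'
#' A `carrier_pool` groups aligned amino-acid sequences with their species,
#' evolutionary phase and subfamily annotations. Phases follow the three
#' metazoan strata used throughout the analysis: `Non-ver` (invertebrates),
#' `Ver-eco` (vertebrate ectotherms) and `Ver-endo` (vertebrate endotherms).
#'
#' @param seqs character vector of aligned sequences (equal lengths; gaps
#'   `-`/`.` allowed), optionally named by id.
#' @param id,species,phase,subfamily per-sequence annotations, recycled if
#'   length 1. `phase` must be one of `"Non-ver"`, `"Ver-eco"`, `"Ver-endo"`
#'   or `NA`.
#' @return an object of class `carrier_pool` with elements `seqs` (named
#'   character vector), `meta` (data.frame) and `width`.
#' @export
carrier_pool <- function(seqs, id = names(seqs), species = NA_character_,
                         phase = NA_character_, subfamily = NA_character_) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n == 0L) stop("empty pool")
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("sequences are not aligned: lengths ", paste(w, collapse = ", "))
  if (is.null(id)) id <- paste0("seq", seq_len(n))
  phase <- as.character(phase)
  known <- c("Non-ver", "Ver-eco", "Ver-endo")
  if (!all(is.na(phase) | phase %in% known))
    stop("phase must be one of ", paste(known, collapse = ", "))
  meta <- data.frame(id = rep_len(as.character(id), n),
                     species = rep_len(as.character(species), n),
                     phase = rep_len(phase, n),
                     subfamily = rep_len(as.character(subfamily), n),
                     stringsAsFactors = FALSE)
  names(seqs) <- meta$id
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), c(AA1, GAP_CHARS))
  if (length(bad))
    stop("non-amino-acid characters in pool: ", paste(bad, collapse = ", "))
  structure(list(seqs = seqs, meta = meta, width = w), class = "carrier_pool")
}

#' @export
print.carrier_pool <- function(x, ...) {
  cat("Carrier pool:", length(x$seqs), "aligned sequences,",
      x$width, "columns\n")
  ph <- table(x$meta$phase, useNA = "ifany")
  if (length(ph)) print(ph)
  invisible(x)
}

#' @export
`[.carrier_pool` <- function(x, i) {
  carrier_pool(x$seqs[i], id = x$meta$id[i], species = x$meta$species[i],
               phase = x$meta$phase[i], subfamily = x$meta$subfamily[i])
}

#' @export
length.carrier_pool <- function(x) length(x$seqs)

#' Read an alignment into a carrier pool
#'
#' Reads FASTA or Clustal-format alignments (Clustal conservation lines are
#' ignored by the reader). Annotations can be parsed from sequence names
#' with `parse_names = TRUE`, which expects the four-field convention
#' written by [write_pool()]: `species|gene|phase|subfamily`, where
#' `species|gene` together form the sequence id.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param parse_names parse annotations out of sequence names?
#' @param delim field delimiter inside names (default `"|"`).
#' @return a [carrier_pool()].
#' @export
read_pool <- function(path, format = c("fasta", "clustal"),
                      parse_names = FALSE, delim = "|") {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  seqs <- toupper(unlist(aln$seq))
  nm <- aln$nam
  species <- phase <- subfam <- NA_character_
  if (parse_names) {
    parts <- strsplit(nm, delim, fixed = TRUE)
    pick <- function(k) vapply(parts, function(p)
      if (length(p) >= k) p[k] else NA_character_, character(1))
    species <- pick(1); phase <- pick(3); subfam <- pick(4)
    nm <- vapply(parts, function(p)
      paste(p[seq_len(min(2L, length(p)))], collapse = delim),
      character(1))
  }
  carrier_pool(seqs, id = nm, species = species, phase = phase,
               subfamily = subfam)
}

#' Write a carrier pool as FASTA
#'
#' Names encode the annotations as `species|gene|phase|subfamily` (the gene
#' field is the id with any leading `species|` prefix removed) so that
#' [read_pool()] with `parse_names = TRUE` round-trips them.
#'
#' @param pool a [carrier_pool()].
#' @param path output file.
#' @param annotate encode annotations into the FASTA names?
#' @return the output path, invisibly.
#' @export
write_pool <- function(pool, path, annotate = TRUE) {
  nm <- if (annotate) {
    gene <- mapply(function(id, sp) sub(paste0("^", sp, "\\|"), "", id),
                   pool$meta$id, pool$meta$species)
    paste(pool$meta$species, gene, pool$meta$phase,
          pool$meta$subfamily, sep = "|")
  } else pool$meta$id
  seqinr::write.fasta(as.list(pool$seqs), names = nm, file.out = path,
                      nbchar = 80)
  invisible(path)
}

# Pool as a characters-by-columns matrix (sequences in rows).
pool_matrix <- function(pool, cols = NULL) {
  m <- do.call(rbind, strsplit(unname(pool$seqs), ""))
  rownames(m) <- pool$meta$id
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  m
}
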