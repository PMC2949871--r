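# End-to-end orchestration over the module functions, with a manifest.
# The numbered scripts under analysis/ are the narrative interface; this
# runner exists so a whole configuration can be reproduced in one call.

#' Default pipeline configuration
#'
#' All stages over the bundled synthetic scenario. Supply `input_fasta` and
#' `topology` paths to run on real alignments instead of the generator.
#'
#' @param seed integer seed used by every stochastic stage.
#' @param out_dir output directory.
#' @return a configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("mcfevo_run_")) {
  list(seed = as.integer(seed), out_dir = out_dir,
       stages = c("simulate", "partition", "composition", "packing",
                  "selection", "trees", "duplications", "mark", "age"),
       input_fasta = NULL, topology = NULL,
       delta = 0.05, sample_size = 132, replicates = 132,
       alpha = 0.05, k_evalues = 10, window = 10,
       omega_sim = c(neutral = 1, purifying = 0.1), t_sim = 0.3,
       n_codons = 300, n_codon_pairs = 20,
       tree_region = "TR", n_boot = 0)
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  need <- c("seed", "out_dir", "stages")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing: ", paste(missing, collapse = ", "))
  if (!is.null(config$alpha) &&
      (config$alpha <= 0 || config$alpha >= 1))
    stop("alpha must be in (0, 1)")
  if (!is.null(config$sample_size) && config$sample_size < 1)
    stop("sample_size must be positive")
  if (!is.null(config$input_fasta) && !file.exists(config$input_fasta))
    stop("input_fasta does not exist: ", config$input_fasta)
  if (!is.null(config$topology) && !file.exists(config$topology))
    stop("topology config does not exist: ", config$topology)
  known <- c("simulate", "partition", "composition", "packing", "selection",
             "trees", "duplications", "mark", "age")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  invisible(config)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (simulate/load ->
#' partition -> composition/packing/mark -> trees -> duplications ->
#' selection -> ages), writing each stage's tables under
#' `config$out_dir` and a JSON manifest (`manifest.json`) with the full
#' configuration, the seed, the package version and the md5 of every
#' output. Deterministic stages are byte-identical across reruns of the
#' same configuration.
#'
#' @param config a configuration list; see [default_config()]. Validated
#'   before any stage runs.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stages <- config$stages

  model <- if (!is.null(config$topology)) load_topology(config$topology)
           else default_topology()
  if (!is.null(config$input_fasta)) {
    pool <- read_pool(config$input_fasta, parse_names = TRUE)
    pools <- split_pool_by_phase(pool)
    truth <- NULL
  } else {
    if (!"simulate" %in% stages)
      stop("no input_fasta given and the simulate stage is disabled")
    sim <- generate_mcf_pools(sim_params(delta = config$delta,
                                         seed = config$seed), model)
    pools <- sim$pools
    truth <- sim$truth
    for (ph in names(pools))
      write_pool(pools[[ph]],
                 file.path(config$out_dir,
                           paste0("pool_", gsub("-", "", ph), ".fasta")))
    emit(truth, "simulation_truth.tsv")
  }
  all_pool <- do.call(c_pools, unname(pools))

  if ("partition" %in% stages) {
    write_partition_tsv(pools[[1]][1], model,
                        file.path(config$out_dir, "partition_example.tsv"))
    outputs <- c(outputs,
                 file.path(config$out_dir, "partition_example.tsv"))
  }

  if ("composition" %in% stages) {
    regions <- c("TR", "LOOP135", "NCLOOP24")
    ident <- data.frame(region = regions,
                        identity_pct = vapply(regions, function(rg)
                          as.numeric(mean_pairwise_identity(
                            all_pool, rg, model)), numeric(1)))
    emit(ident, "region_identity.tsv")
    res <- lapply(names(pools), function(ph)
      resample_ecdf(pools[[ph]], model, "TR_DOWN135", "hydrophobic",
                    sample_size = config$sample_size,
                    replicates = config$replicates, seed = config$seed))
    names(res) <- names(pools)
    ecdf_tab <- do.call(rbind, lapply(names(res), function(ph)
      data.frame(phase = ph, replicate = seq_len(config$replicates),
                 mean = res[[ph]]$replicate_means)))
    emit(ecdf_tab, "resampling_TR_DOWN135_hydrophobic.tsv")
    ks <- data.frame(
      comparison = c("Non-ver_vs_Ver-eco", "Non-ver_vs_Ver-endo"),
      ks_distance = c(ecdf_ks_distance(res[["Non-ver"]], res[["Ver-eco"]]),
                      ecdf_ks_distance(res[["Non-ver"]], res[["Ver-endo"]])))
    emit(ks, "resampling_ks.tsv")
  }

  if ("packing" %in% stages) {
    emit(packing_summary(pools, model,
                         c("TR", "TR_DOWN135", "TR_DOWN246")),
         "packing_summary.tsv")
  }

  if ("selection" %in% stages) {
    rows <- list()
    for (nm in names(config$omega_sim)) {
      for (i in seq_len(config$n_codon_pairs)) {
        pr <- generate_codon_pair(config$omega_sim[[nm]], config$t_sim,
                                  config$n_codons,
                                  seed = config$seed + 1000L * i)
        est <- ng86_dnds(pr$seq1, pr$seq2)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = nm, pair = i, dN = est$dN, dS = est$dS,
          omega = est$omega, N_sites = est$N_sites, S_sites = est$S_sites)
      }
    }
    emit(do.call(rbind, rows), "dnds_estimates.tsv")
  }

  tree <- NULL
  if ("trees" %in% stages) {
    # one-per-subfamily representative tree keeps the NJ problem small
    first <- !duplicated(paste(all_pool$meta$subfamily,
                               all_pool$meta$phase))
    rep_pool <- all_pool[which(first & all_pool$meta$phase == "Non-ver")]
    d <- poisson_distance(rep_pool, config$tree_region, model)
    tree <- neighbor_joining(d)
    path <- file.path(config$out_dir, "nj_tree.nwk")
    ape::write.tree(tree, path)
    outputs <- c(outputs, path)
  }

  if ("duplications" %in% stages) {
    dup_sim <- generate_duplication_tree(6, 2, seed = config$seed)
    det <- detect_duplications(dup_sim$tree)
    emit(det[, c("node", "duplication", "accepted",
                 "n_species_left", "n_species_right")],
         "duplications.tsv")
  }

  if ("mark" %in% stages) {
    marks <- do.call(rbind, lapply(names(pools), function(ph)
      cbind(phase = ph,
            pool_mark_sequences(pools[[ph]], model, config$window))))
    emit(marks, "mark_sequences.tsv")
  }

  if ("age" %in% stages) {
    ev <- generate_evalue_lists(
      c(adp_atp = -50, amino_cofactor = -43, proton = -38),
      seed = config$seed)
    ages <- cluster_age(ev$evalues, ev$clusters, k = config$k_evalues)
    emit(ages$clusters, "cluster_ages.tsv")
  }

  manifest <- list(
    package = "mcfevo",
    version = as.character(utils::packageVersion("mcfevo")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Split a pool into per-phase pools
#' @param pool a [carrier_pool()] with phase annotations.
#' @return named list of pools.
#' @export
split_pool_by_phase <- function(pool) {
  ph <- pool$meta$phase
  if (all(is.na(ph))) stop("pool has no phase annotations")
  lapply(split(seq_along(ph), ph), function(i) pool[i])
}

#' Concatenate carrier pools
#' @param ... [carrier_pool()] objects of equal alignment width.
#' @return a single [carrier_pool()].
#' @export
c_pools <- function(...) {
  ps <- list(...)
  carrier_pool(unlist(lapply(ps, `[[`, "seqs")),
               id = unlist(lapply(ps, function(p) p$meta$id)),
               species = unlist(lapply(ps, function(p) p$meta$species)),
               phase = unlist(lapply(ps, function(p) p$meta$phase)),
               subfamily = unlist(lapply(ps, function(p) p$meta$subfamily)))
}
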