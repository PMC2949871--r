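# Synthetic-data generators: carrier sequence pools with known per-region
# composition, codon pairs with known omega, gene-family trees with planted
# duplications, and E-value lists with known cluster exponents. Every
# generator is seed-deterministic and returns its ground truth.

#' Parameters for the carrier-pool generator
#'
#' Defaults emulate the study conditions: three phase pools of 192 (Non-ver),
#' 164 (Ver-eco) and 208 (Ver-endo) sequences drawn from 44 carrier
#' subfamilies, hydrophobic enrichment `delta` applied to the matrix-facing
#' odd-helix halves and cytosol-facing even-helix halves (`TR_DOWN135`,
#' `TR_UP246`) of the vertebrate phases, three Px(D/E)xx(K/R) motifs at the
#' odd-helix C-termini, conserved P/G hinges at the even-helix midpoints,
#' and orthologs diverging by i.i.d. per-site substitution.
#'
#' `delta` is the region-wide increase in expected hydrophobic proportion:
#' constrained motif/hinge columns cannot carry hydrophobic residues, so the
#' boost applied to the free columns of an enriched region is inflated by
#' the region's free-column fraction to make the realized region-level
#' difference equal `delta`.
#'
#' @param n_carriers number of carrier subfamilies.
#' @param pool_sizes named integer vector of phase pool sizes.
#' @param delta added hydrophobic proportion in enriched regions of enriched
#'   phases.
#' @param enriched_regions composite region labels receiving the enrichment.
#' @param enriched_phases phases receiving the enrichment.
#' @param p_hydro_tr,p_hydro_loop background hydrophobic proportion at free
#'   transmembrane / loop columns.
#' @param sub_rate per-site substitution probability between a phase
#'   ancestor and each ortholog.
#' @param motif_conservation probability that a substitution at a
#'   motif-constrained position stays within the motif pattern.
#' @param seed integer RNG seed (recorded in all outputs).
#' @return a list of validated parameters (class `sim_params`).
#' @export
sim_params <- function(n_carriers = 44,
                       pool_sizes = c("Non-ver" = 192, "Ver-eco" = 164,
                                      "Ver-endo" = 208),
                       delta = 0,
                       enriched_regions = c("TR_DOWN135", "TR_UP246"),
                       enriched_phases = c("Ver-eco", "Ver-endo"),
                       p_hydro_tr = 0.40, p_hydro_loop = 0.25,
                       sub_rate = 0.10, motif_conservation = 1.0,
                       seed = 1L) {
  phases <- c("Non-ver", "Ver-eco", "Ver-endo")
  if (!setequal(names(pool_sizes), phases))
    stop("pool_sizes must be named by the three phases")
  stopifnot(n_carriers >= 1, all(pool_sizes >= 1),
            delta >= 0, delta <= 1,
            p_hydro_tr > 0, p_hydro_tr < 1,
            p_hydro_loop > 0, p_hydro_loop < 1,
            sub_rate >= 0, sub_rate <= 1,
            motif_conservation >= 0, motif_conservation <= 1)
  if (!all(enriched_phases %in% phases))
    stop("enriched_phases must be a subset of the three phases")
  structure(list(n_carriers = as.integer(n_carriers),
                 pool_sizes = pool_sizes[phases], delta = delta,
                 enriched_regions = enriched_regions,
                 enriched_phases = enriched_phases,
                 p_hydro_tr = p_hydro_tr, p_hydro_loop = p_hydro_loop,
                 sub_rate = sub_rate,
                 motif_conservation = motif_conservation,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Per-column site categories of a model: "hinge_P"/"hinge_G" at even-helix
# split columns, "motif_P"/"motif_DE"/"motif_KR"/"motif_x" at the motif
# windows, "tr" elsewhere in helices, "loop" elsewhere.
site_categories <- function(model) {
  cat <- rep("loop", model$alignment_width)
  for (k in 1:6) {
    h <- model$helices[[k]]
    cat[h[1]:h[2]] <- "tr"
  }
  for (k in c(2, 4, 6)) {
    s <- model$splits[k]
    cat[s - 1L] <- "hinge_P"
    cat[s] <- "hinge_G"
  }
  for (a in model$motif_anchors) {
    cat[a] <- "motif_P"
    cat[a + 1L] <- "motif_x"
    cat[a + 2L] <- "motif_DE"
    cat[a + 3L] <- "motif_x"
    cat[a + 4L] <- "motif_x"
    cat[a + 5L] <- "motif_KR"
  }
  cat
}

# free = columns whose residue is drawn from the background distribution
free_categories <- c("tr", "loop", "motif_x")

#' Generate the three phase pools of synthetic carrier sequences
#'
#' See [sim_params()] for the generating model. The returned ground truth
#' records, per phase and region, the expected and the realized hydrophobic
#' proportion, which is sufficient to verify the downstream composition
#' statistics without re-running the generator.
#'
#' @param params a [sim_params()] object.
#' @param model a [topology_model()]; the default shipped layout.
#' @return list with `pools` (named by phase), `model`, `truth`
#'   (data.frame) and `params`.
#' @export
generate_mcf_pools <- function(params, model = default_topology()) {
  stopifnot(inherits(params, "sim_params"))
  W <- model$alignment_width
  cat <- site_categories(model)
  free <- cat %in% free_categories
  is_tr <- rep(FALSE, W)
  for (k in 1:6) { h <- model$helices[[k]]; is_tr[h[1]:h[2]] <- TRUE }

  # per-column hydrophobic probability at free columns, before enrichment
  p_base <- ifelse(is_tr, params$p_hydro_tr, params$p_hydro_loop)

  # Region-wide delta -> per-column boost. Only the unconstrained helix
  # columns outside the conical-pit motif windows receive the boost (the
  # interface positions); the motif x-positions keep the background
  # composition so mark sequences stay comparable across phases. The boost
  # is inflated by the region's boosted-column fraction so the realized
  # region-level difference equals delta.
  boost <- rep(0, W)
  for (rg in params$enriched_regions) {
    cols <- region_columns(model, rg)
    n_boostable <- sum(cat[cols] == "tr")
    if (n_boostable == 0)
      stop("enriched region ", rg, " has no unconstrained helix columns")
    b <- params$delta * length(cols) / n_boostable
    if (any(p_base[cols][cat[cols] == "tr"] + b >= 1))
      stop("infeasible delta: hydrophobic probability would reach 1 in ", rg)
    boost[cols][cat[cols] == "tr"] <- boost[cols][cat[cols] == "tr"] + b
  }

  draw_free <- function(n, p_col) {
    # matrix n x W of background draws with per-column hydrophobic prob
    hyd <- matrix(stats::runif(n * W), n, W) <
      matrix(p_col, n, W, byrow = TRUE)
    out <- matrix(sample(NONHYDRO_SET, n * W, replace = TRUE), n, W)
    out[hyd] <- sample(HYDRO_SET, sum(hyd), replace = TRUE)
    out
  }
  constrained_draw <- function(type, n) {
    switch(type,
           hinge_P = rep("P", n),
           hinge_G = rep("G", n),
           motif_P = rep("P", n),
           motif_DE = sample(c("D", "E"), n, replace = TRUE),
           motif_KR = sample(c("K", "R"), n, replace = TRUE))
  }

  set.seed(params$seed)
  pools <- list()
  truth_rows <- list()
  report_regions <- unique(c("TR", "TR_UP135", "TR_UP246", "TR_DOWN135",
                             "TR_DOWN246", params$enriched_regions))

  # One root ancestor per carrier subfamily, shared by all phases: the
  # phase pools hold orthologs of the same carriers, so with delta = 0 all
  # sequences of a family are exchangeable across phases.
  anc_base <- draw_free(params$n_carriers, p_base)
  for (ct in c("hinge_P", "hinge_G", "motif_P", "motif_DE", "motif_KR")) {
    for (j in which(cat == ct))
      anc_base[, j] <- constrained_draw(ct, params$n_carriers)
  }

  for (phase in names(params$pool_sizes)) {
    size <- params$pool_sizes[[phase]]
    enriched <- phase %in% params$enriched_phases
    p_col <- p_base + if (enriched) boost else 0
    n_sp <- ceiling(size / params$n_carriers)
    sp_names <- sprintf("%s_sp%d", gsub("-", "", tolower(phase)), 1:n_sp)
    grid <- expand.grid(carrier = seq_len(params$n_carriers),
                        species = sp_names, stringsAsFactors = FALSE)
    grid <- grid[seq_len(size), ]   # last species may miss some carriers

    # phase ancestor: lift the hydrophobic marginal of boosted columns from
    # p to p + boost by flipping non-hydrophobic residues with probability
    # boost / (1 - p)
    anc <- anc_base
    if (enriched) {
      for (j in which(boost > 0)) {
        flip <- !(anc[, j] %in% HYDRO_SET) &
          stats::runif(params$n_carriers) < boost[j] / (1 - p_base[j])
        if (any(flip))
          anc[flip, j] <- sample(HYDRO_SET, sum(flip), replace = TRUE)
      }
    }

    S <- anc[grid$carrier, , drop = FALSE]
    mut <- matrix(stats::runif(size * W), size, W) < params$sub_rate
    mut[, cat %in% c("hinge_P", "hinge_G")] <- FALSE  # hinges conserved
    # free sites: redraw from the background (marginal preserved)
    redraw <- draw_free(size, p_col)
    sel <- mut & matrix(free, size, W, byrow = TRUE)
    S[sel] <- redraw[sel]
    # constrained motif sites: redraw within the pattern with probability
    # motif_conservation, otherwise from the background
    for (ct in c("motif_P", "motif_DE", "motif_KR")) {
      for (j in which(cat == ct)) {
        hit <- which(mut[, j])
        if (!length(hit)) next
        keep <- stats::runif(length(hit)) < params$motif_conservation
        if (any(keep))
          S[hit[keep], j] <- constrained_draw(ct, sum(keep))
        if (any(!keep))
          S[hit[!keep], j] <- redraw[hit[!keep], j]
      }
    }

    seqs <- apply(S, 1, paste, collapse = "")
    subfam <- sprintf("A%d", grid$carrier)
    ids <- paste0(grid$species, "|", subfam)
    pools[[phase]] <- carrier_pool(seqs, id = ids, species = grid$species,
                                   phase = phase, subfamily = subfam)

    hydro <- matrix(S %in% HYDRO_SET, size, W)
    for (rg in report_regions) {
      cols <- region_columns(model, rg)
      expected <- mean(p_col[cols] * free[cols])  # constrained cols: 0
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        phase = phase, region = rg, class = "hydrophobic",
        expected = expected, realized = mean(hydro[, cols]),
        n_residues = size * length(cols), stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  list(pools = pools, model = model, truth = truth, params = params)
}

#' Simulate a pair of codon sequences at a known omega
#'
#' A random gap- and stop-free ancestor is evolved for time `t` (expected
#' attempted mutations per nucleotide site) under uniform single-nucleotide
#' mutation with selection thinning: synonymous changes are always accepted,
#' nonsynonymous changes with probability `omega`, changes creating stop
#' codons never. The returned pair is (ancestor, descendant).
#'
#' @param omega nonsynonymous acceptance probability (>= 0).
#' @param t expected attempted mutations per nucleotide site (>= 0).
#' @param n_codons codons per sequence.
#' @param seed RNG seed.
#' @return list with `seq1`, `seq2`, realized `n_syn`/`n_nonsyn` accepted
#'   changes, and the parameters.
#' @export
generate_codon_pair <- function(omega, t, n_codons, seed = 1L) {
  stopifnot(omega >= 0, t >= 0, n_codons >= 1)
  tb <- ng86_tables()
  sense <- which(tb$aa != "*")
  set.seed(as.integer(seed))
  anc_idx <- sample(sense, n_codons, replace = TRUE)
  chars <- unlist(strsplit(tb$codons[anc_idx], ""))
  cur <- chars
  n_events <- stats::rpois(1, 3 * n_codons * t)
  n_syn <- n_nonsyn <- 0L
  if (n_events > 0) {
    sites <- sample.int(3L * n_codons, n_events, replace = TRUE)
    accept_u <- stats::runif(n_events)
    for (e in seq_len(n_events)) {
      s <- sites[e]
      newb <- sample(BASES[BASES != cur[s]], 1)
      cd <- ((s - 1L) %/% 3L) * 3L
      old_cod <- paste(cur[(cd + 1):(cd + 3)], collapse = "")
      tmp <- cur[(cd + 1):(cd + 3)]
      tmp[s - cd] <- newb
      new_cod <- paste(tmp, collapse = "")
      old_aa <- tb$aa[tb$idx[[old_cod]]]
      new_aa <- tb$aa[tb$idx[[new_cod]]]
      if (new_aa == "*") next
      if (old_aa == new_aa) {
        cur[s] <- newb; n_syn <- n_syn + 1L
      } else if (accept_u[e] < omega) {
        cur[s] <- newb; n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  list(seq1 = paste(chars, collapse = ""), seq2 = paste(cur, collapse = ""),
       n_syn = n_syn, n_nonsyn = n_nonsyn,
       omega = omega, t = t, n_codons = n_codons, seed = as.integer(seed))
}

# Random rooted binary topology over labels, as a nested list.
random_topology <- function(labels) {
  if (length(labels) == 1L) return(labels)
  k <- sample(seq_len(length(labels) - 1L), 1)
  picks <- sample(labels)
  list(random_topology(picks[seq_len(k)]),
       random_topology(picks[-seq_len(k)]))
}

node_tipsets <- function(node) {
  # list of tip sets of all internal nodes, preorder, with node paths
  if (!is.list(node)) return(list())
  tips <- function(x) if (is.list(x)) unlist(lapply(x, tips)) else x
  out <- list(list(path = integer(0), tips = tips(node)))
  for (i in 1:2) {
    sub <- node_tipsets(node[[i]])
    for (s in sub)
      out[[length(out) + 1L]] <- list(path = c(i, s$path), tips = s$tips)
  }
  out
}

#' Generate a gene-family tree with planted duplications
#'
#' Builds a random rooted binary species tree, then plants `n_duplications`
#' duplication events at pairwise non-nested internal nodes: the subtree
#' below each chosen node is replaced by two paralogous copies with distinct
#' gene ids (no losses). Tip labels follow the `species|gene` convention.
#' Events nested one below another are not modelled (under no-loss they
#' would be copied into both paralog subtrees, making the event count
#' ambiguous), so placement errors out when no non-nested node remains.
#'
#' @param n_species number of species (>= 2).
#' @param n_duplications events to plant.
#' @param seed RNG seed.
#' @return list with `tree` (ape `phylo`, rooted, branch lengths 1),
#'   `events` (per event: `species`, sorted `tips` of the duplicated clade)
#'   and the parameters.
#' @export
generate_duplication_tree <- function(n_species, n_duplications = 0,
                                      seed = 1L) {
  stopifnot(n_species >= 2, n_duplications >= 0)
  set.seed(as.integer(seed))
  sp <- sprintf("s%02d", seq_len(n_species))
  topo <- random_topology(sp)
  nodes <- node_tipsets(topo)
  if (n_duplications > length(nodes))
    stop("n_duplications exceeds the number of internal nodes")
  comparable <- function(a, b)
    all(a %in% b) || all(b %in% a)
  chosen <- list()
  for (cand in sample(nodes)) {
    if (length(chosen) == n_duplications) break
    if (!any(vapply(chosen, function(c) comparable(c$tips, cand$tips),
                    logical(1))))
      chosen[[length(chosen) + 1L]] <- cand
  }
  if (length(chosen) < n_duplications)
    stop("cannot place ", n_duplications,
         " pairwise non-nested duplications on this species tree")
  paths <- lapply(chosen, `[[`, "path")
  events_env <- new.env()
  events_env$events <- list()
  render <- function(node, path, gtag) {
    planted <- any(vapply(paths, function(p) identical(p, path), logical(1)))
    plain <- function(gt) {
      if (!is.list(node)) return(paste0(node, "|", gt))
      paste0("(", render(node[[1]], c(path, 1L), gt), ":1,",
             render(node[[2]], c(path, 2L), gt), ":1)")
    }
    if (!planted) return(plain(gtag))
    a <- plain(paste0(gtag, "a"))
    b <- plain(paste0(gtag, "b"))
    tip_re <- "[^(),:]+\\|[^(),:]+"
    tips <- c(regmatches(a, gregexpr(tip_re, a))[[1]],
              regmatches(b, gregexpr(tip_re, b))[[1]])
    spset <- unique(sub("\\|.*$", "", tips))
    events_env$events[[length(events_env$events) + 1L]] <-
      list(species = sort(spset), tips = sort(tips))
    paste0("(", a, ":1,", b, ":1)")
  }
  nwk <- paste0(render(topo, integer(0), "g1"), ";")
  tree <- ape::read.tree(text = nwk)
  list(tree = tree, events = events_env$events,
       n_species = n_species, n_duplications = n_duplications,
       seed = as.integer(seed))
}

#' Generate E-value lists with known cluster age exponents
#'
#' Emulates tabular homology-search output for carriers grouped into
#' substrate clusters: each carrier draws its E-value exponents around its
#' cluster's mean exponent, so the recovered cluster age (mean log10 of the
#' k smallest E-values) has a known target.
#'
#' @param cluster_means named numeric vector: cluster label -> mean log10
#'   E-value exponent (negative).
#' @param carriers_per_cluster carriers per cluster.
#' @param n_evalues E-values per carrier.
#' @param sd_exponent spread of the exponents around the cluster mean.
#' @param seed RNG seed.
#' @return list with `evalues` (data.frame: carrier, subject, evalue),
#'   `clusters` (named vector carrier -> cluster) and the parameters.
#' @export
generate_evalue_lists <- function(cluster_means, carriers_per_cluster = 5,
                                  n_evalues = 20, sd_exponent = 1,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list(); assign_cl <- character(0)
  for (cl in names(cluster_means)) {
    for (i in seq_len(carriers_per_cluster)) {
      id <- sprintf("%s_c%02d", cl, i)
      expo <- stats::rnorm(n_evalues, cluster_means[[cl]], sd_exponent)
      rows[[length(rows) + 1L]] <- data.frame(
        carrier = id, subject = sprintf("ref_%03d", seq_len(n_evalues)),
        evalue = 10^expo, stringsAsFactors = FALSE)
      assign_cl[id] <- cl
    }
  }
  list(evalues = do.call(rbind, rows), clusters = assign_cl,
       cluster_means = cluster_means, seed = as.integer(seed))
}
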