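#!/usr/bin/env Rscript
# Gene-family trees: Poisson-corrected NJ tree over one representative
# sequence per carrier subfamily (with bootstrap support), and species-
# overlap duplication detection benchmarked on planted-event trees.

suppressMessages(library(mcfevo))
out <- "results/trees"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260924L

pool <- do.call(c_pools, lapply(
  list.files("results/sim", pattern = "^pool_.*fasta$", full.names = TRUE),
  read_pool, parse_names = TRUE))
model <- default_topology()

first <- !duplicated(pool$meta$subfamily)
rep_pool <- pool[which(first)]
tree <- nj_bootstrap(rep_pool, n_boot = 100, seed = seed,
                     region = "TR", model = model)
ape::write.tree(tree, file.path(out, "nj_subfamily_tree.nwk"))
cat(sprintf("NJ tree over %d subfamily representatives (TR region), %d%% of nodes with bootstrap >= 0.5\n",
            length(rep_pool), round(100 * mean(tree$node.label >= 0.5))))

dup_tree <- ape::read.tree("results/sim/gene_family_tree.nwk")
det <- detect_duplications(dup_tree)
write.table(det[, c("node", "duplication", "accepted",
                    "n_species_left", "n_species_right")],
            file.path(out, "duplications.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("simulated gene-family tree: %d duplication nodes, %d accepted\n",
            sum(det$duplication), sum(det$accepted)))

set.seed(seed)
tp <- fp <- fn <- 0L
for (i in 1:100) {
  sim <- NULL
  for (nd in 3:1) {
    sim <- tryCatch(generate_duplication_tree(sample(4:10, 1), nd,
                                              seed = seed + i),
                    error = function(e) NULL)
    if (!is.null(sim)) break
  }
  d <- detect_duplications(sim$tree)
  found <- vapply(attr(d, "events"),
                  function(e) paste(e$tips, collapse = ";"), character(1))
  truth <- vapply(sim$events,
                  function(e) paste(e$tips, collapse = ";"), character(1))
  tp <- tp + length(intersect(found, truth))
  fp <- fp + length(setdiff(found, truth))
  fn <- fn + length(setdiff(truth, found))
}
cat(sprintf("planted-duplication benchmark (100 trees): precision %.3f, recall %.3f\n",
            tp / (tp + fp), tp / (tp + fn)))
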