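#!/usr/bin/env Rscript
# Substrate-selectivity proxies: conical-pit mark sequences per phase,
# position-frequency-matrix similarity between vertebrate and invertebrate
# marks, and the E-value-based carrier-cluster age metric.

suppressMessages(library(mcfevo))
out <- "results/substrate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pool <- do.call(c_pools, lapply(
  list.files("results/sim", pattern = "^pool_.*fasta$", full.names = TRUE),
  read_pool, parse_names = TRUE))
pools <- split_pool_by_phase(pool)
model <- default_topology()

marks <- lapply(names(pools), function(ph)
  cbind(phase = ph, pool_mark_sequences(pools[[ph]], model)))
marks <- do.call(rbind, marks)
write.table(marks, file.path(out, "mark_sequences.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mark sequences: %d/%d complete 18-mers\n",
            sum(marks$complete), nrow(marks)))

ok <- marks[marks$complete, ]
ver <- ok$mark[ok$phase != "Non-ver"]
nonver <- ok$mark[ok$phase == "Non-ver"]
f <- pfm(ver)
write.table(round(unclass(f), 4), file.path(out, "pfm_ver_marks.tsv"),
            sep = "\t", quote = FALSE)
cat(sprintf("mark PFM divergence, vertebrate vs invertebrate: %.4f (JS, bits)\n",
            pfm_divergence(nonver, ver)))

ev <- read_evalues("results/sim/evalues.tsv")
cl_tab <- read.delim("results/sim/clusters.tsv")
clusters <- setNames(cl_tab$cluster, cl_tab$carrier)
ages <- cluster_age(ev, clusters, k = 10)
write.table(ages$clusters, file.path(out, "cluster_ages.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("cluster ages (mean log10 E-value of the 10 smallest; most negative = oldest):\n")
print(ages$clusters, row.names = FALSE)
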