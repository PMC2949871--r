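#!/usr/bin/env Rscript
# Helix packing ("tightness") contrast between phases, using the shipped
# synthetic residue packing table. All three aggregations (residues,
# sequences, carriers) are reported because the pool-level mean is
# ambiguous for ragged pools.

suppressMessages(library(mcfevo))
out <- "results/packing"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pool <- do.call(c_pools, lapply(
  list.files("results/sim", pattern = "^pool_.*fasta$", full.names = TRUE),
  read_pool, parse_names = TRUE))
pools <- split_pool_by_phase(pool)
model <- default_topology()
tab <- synthetic_packing_table()

summ <- packing_summary(pools, model,
                        c("TR", "TR_UP", "TR_DOWN",
                          "TR_DOWN135", "TR_DOWN246", "TR_UP246"), tab)
write.table(summ, file.path(out, "packing_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ, row.names = FALSE)

d135 <- subset(summ, region == "TR_DOWN135")
cat(sprintf("\nTR_DOWN135 packing, vertebrates minus invertebrates: %+.4f\n",
            mean(d135$mean_residues[d135$phase != "Non-ver"]) -
            d135$mean_residues[d135$phase == "Non-ver"]))
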