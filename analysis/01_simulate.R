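#!/usr/bin/env Rscript
# Stage 1: simulate the five-library experiment (two A-genome parents,
# the shared C parent, their two hybrids) and write the on-disk fixtures
# every later stage consumes.

suppressPackageStartupMessages(library(alloexpr))

out_dir <- "results/sim"
cfg <- sim_config(n_genes = 20000, seed = 42)
ds <- generate_dataset(cfg)
paths <- write_fixture(ds, out_dir)

expressed <- colSums(pool_counts(ds$counts) > 0)
cat("Simulated", nrow(ds$genes), "genes (", nrow(ds$pairs),
    "homoeolog pairs ) for samples:",
    paste(cfg$samples, collapse = ", "), "\n")
cat("Expressed genes per sample (count > 0):\n")
print(expressed)
cat(sprintf("Mean expressed fraction: %.1f%% of %d genes\n",
            mean(expressed) / nrow(ds$genes) * 100, nrow(ds$genes)))
cat("Planted truth classes:\n")
print(table(ds$truth$true_class))
cat("Fixtures written under", out_dir, ":",
    paste(basename(unlist(paths)), collapse = ", "), "\n")
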