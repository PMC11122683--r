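#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study dataset.
#
# Plants 300 double-ended DSBs (100 per kinetic class), 50 single-ended
# DSBs, 10 unenriched solitary peaks, 280 R-loop peaks (40 per kinetic
# category) and ~28 RNase-H-insensitive decoys on a 3 x 5 Mbp genome,
# then writes strand-specific peak BEDs per replicate and condition,
# coverage tracks, spike-aware count matrices, library metadata, gene
# models and the truth table under results/synthetic/.

suppressMessages(library(dsbrloop))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1
out <- "results/synthetic"

cfg <- simulation_config(seed = seed)
ds <- simulate_dataset(cfg, out_dir = out)

cat("dataset written to", out, "with seed", seed, "\n\n")
cat("planted features:\n")
print(table(kind = ds$truth$kind, class = ds$truth$class))
cat("\nlibraries:\n")
print(ds$libraries[, c("library_id", "condition", "role", "total_reads")])
cat("\nfiles:", length(ds$files), "(see", file.path(out, "manifest.yaml"), ")\n")
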