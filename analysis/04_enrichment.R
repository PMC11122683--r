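#!/usr/bin/env Rscript

# Stage 4: overlap enrichment, annotation and profiles.
#
# Asks where the DSB kinetic classes fall relative to the R-loop kinetic
# categories: observed overlaps versus the mean of 100 within-chromosome
# randomizations, binomial p-values, and log2 fold changes. Also
# annotates persistent DSB clusters by gene feature (promoter /
# gene body / terminator / intergenic windows of +-10 kbp) and computes
# a reference-point metaprofile of END-seq coverage around persistent
# clusters. Requires stages 01-03.

suppressMessages({
  library(dsbrloop)
  library(GenomicRanges)
})

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1
ds <- read_dataset("results/synthetic")
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

classes <- list()
for (cl in c("persistent", "transient", "late"))
  classes[[cl]] <- read_intervals(file.path("results/dsb", paste0(cl, ".bed")),
                                  genome = ds$genome)
rl_files <- setdiff(list.files("results/rloop", pattern = "\\.bed$"), NULL)
rl_sets <- lapply(rl_files, function(f)
  read_intervals(file.path("results/rloop", f), genome = ds$genome))
names(rl_sets) <- sub("\\.bed$", "", rl_files)
rl_sets <- rl_sets[vapply(rl_sets, length, 0L) > 0]

panel <- run_enrichment_panel(classes, rl_sets, ds$genome,
                              n_shuffles = 100, seed = seed + 1000)
write.table(panel, "results/enrichment/dsb_vs_rloop.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("enrichment of DSB classes over R-loop categories:\n")
print(panel[, c("query", "features", "observed", "expected", "log2fc", "p",
                "direction")], digits = 3)

ann <- annotate_gene_feature(classes$persistent, gene_models(ds$genes))
write.table(cbind(peak = seq_along(classes$persistent), ann),
            "results/enrichment/persistent_gene_features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\npersistent DSB clusters by gene feature:\n")
print(table(ann$category))

trk <- read_signal_track("results/synthetic/tracks/endseq_T10_rep1_fwd.bedgraph",
                         ds$genome)
prof <- metaprofile(trk, classes$persistent)
write.table(data.frame(bin = seq_along(prof$profile), mean = prof$profile),
            "results/enrichment/persistent_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nmetaprofile around %d persistent clusters: centre bin %.2f, edge bin %.2f\n",
            length(classes$persistent), prof$profile[51], prof$profile[1]))
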