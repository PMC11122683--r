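#!/usr/bin/env Rscript

# Stage 2: END-seq branch.
#
# Reads the dataset written by 01_simulate.R from disk, pairs reverse and
# forward strand peaks into DSB clusters per replicate (gap < 150 bp),
# takes the replicate consensus per timepoint, normalizes counts by
# on-target spike-in and library size, tests each timepoint against the
# untreated control (|log2FC| > 1, p < 0.05, positive direction), assigns
# kinetic classes, and detects single-ended DSB candidates from solitary
# peaks. Writes class BEDs and the stage log under results/dsb/, and
# reports recovery against the planted truth.

suppressMessages({
  library(dsbrloop)
  library(GenomicRanges)
})

ds <- read_dataset("results/synthetic")
dir.create("results/dsb", recursive = TRUE, showWarnings = FALSE)

libs <- ds$libraries[ds$libraries$assay == "ENDseq", ]
res <- run_dsb_analysis(ds$peaks$endseq, ds$counts$endseq$regions,
                        ds$counts$endseq$counts, libs)

for (cl in names(res$classes)) {
  gr <- res$classes[[cl]]
  if (length(gr)) gr$name <- rep(cl, length(gr))
  write_intervals(gr, file.path("results/dsb", paste0(cl, ".bed")),
                  genome = ds$genome)
}
write_intervals(res$unclassified, "results/dsb/unclassified.bed",
                genome = ds$genome)
write_intervals(res$sedsb[res$sedsb$iq_retained], "results/dsb/sedsb.bed",
                genome = ds$genome)
write.table(res$log, "results/dsb/stage_log.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("cluster classes:\n")
print(vapply(res$classes, length, 0L))
cat("\nstage attrition:\n")
print(res$log)

truth <- ds$truth[ds$truth$kind == "deDSB", ]
tgr <- make_intervals(truth$chrom, truth$start, truth$end)
all_cl <- c(res$classes$persistent, res$classes$transient, res$classes$late)
cat(sprintf("\nplanted deDSB recovered: %.3f (n = %d)\n",
            mean(countOverlaps(tgr, all_cl) > 0), nrow(truth)))
correct <- vapply(c("persistent", "transient", "late"), function(cl)
  sum(countOverlaps(tgr[truth$class == cl], res$classes[[cl]]) > 0), 0)
cat(sprintf("kinetic class accuracy:  %.3f\n", sum(correct) / nrow(truth)))
cat(sprintf("seDSB candidates kept:   %d (persistent among kept: %d)\n",
            sum(res$sedsb$iq_retained),
            sum(res$sedsb$persistent & res$sedsb$iq_retained)))
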