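# a light configuration used wherever the full default study is overkill
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 30,
         n_dedsb_per_class = c(persistent = 8, transient = 8, late = 8),
         n_sedsb = 5, n_solo_noise = 2, n_rloop_per_category = 4,
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}

test_that("planted kinetic classes produce the stated mean vectors", {
  expect_equal(unname(plant_kinetics("no_change", 100)), c(100, 100, 100))
  expect_equal(unname(plant_kinetics("transient_gain", 100, delta = 2)),
               c(100, 400, 100))
  expect_equal(unname(plant_kinetics("stable_loss", 100, delta = 2)),
               c(100, 25, 25))
  expect_equal(unname(plant_kinetics("late_gain", 100, delta = 1)),
               c(100, 100, 200))
  expect_equal(names(plant_kinetics("stable_gain", 10)), c("NT", "T5", "T60"))
  # DSB classes run over the 10/20-minute timepoints
  expect_equal(unname(plant_kinetics("persistent", 100)), c(100, 400, 400))
  expect_equal(unname(plant_kinetics("transient", 100)), c(100, 400, 100))
  expect_equal(names(plant_kinetics("late", 100)), c("NT", "T10", "T20"))
  expect_error(plant_kinetics("sideways_gain", 100), "unknown kinetic class")
})

test_that("identical config and seed give byte-identical datasets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- simulate_dataset(small_config(seed = 42), out_dir = d1)
  ds2 <- simulate_dataset(small_config(seed = 42), out_dir = d2)
  expect_identical(ds1$files, ds2$files)
  sums1 <- tools::md5sum(file.path(d1, ds1$files))
  sums2 <- tools::md5sum(file.path(d2, ds2$files))
  expect_identical(unname(sums1), unname(sums2))
  # a different seed moves the features
  ds3 <- simulate_dataset(small_config(seed = 43))
  expect_false(identical(ds1$truth$center, ds3$truth$center))
})

test_that("feature bookkeeping follows the configuration", {
  ds <- simulate_dataset(small_config(seed = 2))
  expect_equal(sum(ds$truth$kind == "deDSB"), 24)
  expect_equal(sum(ds$truth$kind == "seDSB"), 5)
  expect_equal(sum(ds$truth$kind == "rloop"), 28)
  expect_false(anyDuplicated(ds$truth$feature_id) > 0)
  # no single-ended breaks requested: none planted
  none <- simulate_dataset(small_config(seed = 2, n_sedsb = 0))
  expect_equal(sum(none$truth$kind == "seDSB"), 0)
  # every planted deDSB pairs within the gate in every active replicate
  for (cond in names(ds$peaks$endseq)) for (r in 1:2) {
    pk <- ds$peaks$endseq[[cond]][[r]]
    cl <- pair_strand_peaks(pk$rev, pk$fwd, 150)
    active <- ds$truth[ds$truth$kind == "deDSB" &
                         ds$truth$class %in% c("persistent",
                                               if (cond == "T10") "transient"
                                               else "late"), ]
    expect_equal(length(cl), nrow(active))
    expect_true(all(cl$gap >= 0 & cl$gap < 150))
  }
})

test_that("treated counts follow the planted negative-binomial means", {
  ds <- simulate_dataset(simulation_config(seed = 8))
  libs <- ds$libraries[ds$libraries$assay == "ENDseq", ]
  norm <- normalize_counts(ds$counts$endseq$counts,
                           endseq_scale_factors(libs))
  t10 <- libs$library_id[libs$condition == "T10"]
  up_at_t10 <- ds$truth$feature_id[ds$truth$kind == "deDSB" &
                                     ds$truth$class %in% c("persistent",
                                                           "transient")]
  m <- mean(norm[up_at_t10, t10])
  expect_lt(abs(m - 400) / 400, 0.05)
  # RNase H libraries sit at background for true peaks, IP level for decoys
  drip <- ds$libraries[ds$libraries$assay == "DRIP", ]
  rh <- drip$library_id[drip$role == "RNaseH"]
  dnorm <- normalize_counts(ds$counts$drip$counts, drip_scale_factors(drip))
  true_ids <- ds$truth$feature_id[ds$truth$kind == "rloop"]
  decoy_ids <- ds$truth$feature_id[ds$truth$kind == "decoy"]
  expect_lt(mean(dnorm[true_ids, rh]), 15)
  expect_gt(mean(dnorm[decoy_ids, rh]), 80)
})

test_that("a written dataset reads back equivalent to the in-memory one", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_config(seed = 12), out_dir = d)
  rd <- read_dataset(d)
  expect_identical(rd$counts$endseq$counts, ds$counts$endseq$counts)
  expect_identical(rd$counts$drip$counts, ds$counts$drip$counts)
  expect_equal(GenomeInfoDb::seqlengths(rd$genome),
               GenomeInfoDb::seqlengths(ds$genome))
  expect_setequal(rd$genes$gene_id, ds$genes$gene_id)
  # peak sets survive the BED round trip (order may differ within a file)
  for (cond in names(ds$peaks$endseq)) for (r in 1:2) {
    a <- ds$peaks$endseq[[cond]][[r]]$fwd
    b <- rd$peaks$endseq[[cond]][[r]]$fwd
    expect_setequal(paste(GenomicRanges::start(a), a$name),
                    paste(GenomicRanges::start(b), b$name))
  }
  # and the pipeline gives identical cluster calls from either source
  libs <- ds$libraries[ds$libraries$assay == "ENDseq", ]
  r1 <- suppressWarnings(run_dsb_analysis(ds$peaks$endseq,
                                          ds$counts$endseq$regions,
                                          ds$counts$endseq$counts, libs))
  r2 <- suppressWarnings(run_dsb_analysis(rd$peaks$endseq,
                                          rd$counts$endseq$regions,
                                          rd$counts$endseq$counts,
                                          rd$libraries[rd$libraries$assay == "ENDseq", ]))
  expect_equal(GenomicRanges::start(r1$classes$persistent),
               GenomicRanges::start(r2$classes$persistent))
})

test_that("infeasible packing is reported rather than looping forever", {
  g <- genome_spec("chr1", 2e5)
  expect_error(simulate_dataset(simulation_config(genome = g, seed = 1)),
               "infeasible packing")
})
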