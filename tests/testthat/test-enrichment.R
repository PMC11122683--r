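test_that("shuffling preserves lengths and chromosomes and is seeded", {
  g <- tiny_genome(c(chr1 = 1e5, chr2 = 2e5))
  q <- make_intervals(c("chr1", "chr1", "chr2"), c(0, 5000, 100),
                      c(1000, 5100, 4100), genome = g)
  s1 <- shuffle_intervals(q, g, seed = 9)
  s2 <- shuffle_intervals(q, g, seed = 9)
  expect_equal(bed_start(s1), bed_start(s2))
  expect_equal(GenomicRanges::width(s1), GenomicRanges::width(q))
  expect_equal(as.character(GenomicRanges::seqnames(s1)),
               as.character(GenomicRanges::seqnames(q)))
  # an interval as long as its chromosome can only start at 0
  full <- make_intervals("chr1", 0, 1e5, genome = g)
  expect_equal(bed_start(shuffle_intervals(full, g, seed = 1)), 0)
  expect_error(shuffle_intervals(make_intervals("chr2", 0, 2.5e5), g),
               "longer than its chromosome")
})

test_that("shuffled placement is uniform over the chromosome", {
  g <- tiny_genome(c(chr1 = 1e5))
  q <- rep(make_intervals("chr1", 0, 100, genome = g), 10000)
  s <- shuffle_intervals(q, g, seed = 4)
  mids <- (bed_start(s) + bed_end(s)) / 2
  expect_lt(abs(mean(mids) - 5e4) / 5e4, 0.02)
})

test_that("overlap enrichment handles the degenerate extremes", {
  g <- tiny_genome(c(chr1 = 1e5))
  q <- make_intervals("chr1", seq(0, 49000, by = 1000), seq(200, 49200, by = 1000),
                      genome = g)
  # features tiling the genome: everything overlaps, no enrichment signal
  tile <- make_intervals("chr1", 0, 1e5, genome = g)
  res <- overlap_enrichment(q, tile, g, n_shuffles = 20, seed = 2)
  expect_equal(res$observed, res$n_query)
  expect_equal(res$log2fc, 0)
  expect_equal(res$direction, "enriched")
  expect_gt(res$p, 0.9)
  # no features at all: nothing observed, nothing expected, no claim
  none <- overlap_enrichment(q, GenomicRanges::GRanges(), g,
                             n_shuffles = 20, seed = 2)
  expect_equal(none$observed, 0)
  expect_equal(none$expected, 0)
  expect_equal(none$log2fc, 0)
})

test_that("planted enrichment is recovered with the expected fold change", {
  g <- genome_spec(paste0("chr", 1:3), rep(5e6, 3))
  fx <- simulate_enrichment_fixture(g, seed = 12)
  res <- overlap_enrichment(fx$query, fx$features, g, n_shuffles = 100,
                            seed = 13)
  expect_lt(abs(res$log2fc - 3.0), 0.3)
  expect_lt(res$p, 1e-6)
  expect_equal(res$direction, "enriched")
})

test_that("gene-feature annotation is strand-aware and total", {
  g <- tiny_genome(c(chr1 = 1e6, chr2 = 1e6))
  genes <- make_intervals("chr1", c(100000, 500000), c(140000, 540000),
                          strand = c("+", "-"), genome = g,
                          gene_id = c("gA", "gB"))
  models <- gene_models(genes)
  peaks <- make_intervals(
    c("chr1", "chr1", "chr1", "chr1", "chr2"),
    c(94900, 119900, 494900, 545000, 1000),
    c(95100, 120100, 495100, 545200, 1200))
  ann <- suppressWarnings(annotate_gene_feature(peaks, models))
  # 5 kb upstream of the + gene TSS; mid-gene; 5 kb left of the - gene's
  # leftmost coordinate (downstream of its TES); 5 kb right of the - gene
  # (upstream of its TSS); and a chromosome without genes
  expect_equal(as.character(ann$category),
               c("promoter", "gene_body", "terminator", "promoter",
                 "intergenic"))
  expect_equal(ann$gene_id, c("gA", "gA", "gB", "gB", NA))
  expect_false(anyNA(ann$category))
})

test_that("nearest-feature distances use half-open gap arithmetic", {
  peaks <- make_intervals(c("chr1", "chr1", "chr2"), c(100, 100, 0),
                          c(200, 200, 50))
  feats <- make_intervals(c("chr1", "chr1"), c(150, 500), c(300, 600))
  d <- nearest_feature_distance(peaks, feats)
  expect_equal(d[1], 0)      # overlap
  expect_equal(d[2], 0)      # same peak; nearest of {0, 300}
  expect_true(is.na(d[3]))   # chromosome without features
  d2 <- nearest_feature_distance(make_intervals("chr1", 100, 200),
                                 make_intervals("chr1", c(500, 900), c(600, 950)))
  expect_equal(d2, 300)      # 500 - 200 in half-open coordinates
})

test_that("metaprofiles match closed forms and commute with scaling", {
  g <- tiny_genome(c(chr1 = 1e5))
  regions <- make_intervals("chr1", c(20000, 40000), c(20400, 40400))
  const <- signal_track(make_intervals("chr1", 0, 1e5, score = 2), g)
  prof <- metaprofile(const, regions, half_window = 3000, n_bins = 100)
  expect_equal(prof$profile, rep(2, 100))
  # 1-bp spike at a region centre lights only the central bin
  centre <- floor((20000 + 20400) / 2)
  spike <- signal_track(make_intervals("chr1", centre, centre + 1, score = 60), g)
  prof <- metaprofile(spike, regions[1], half_window = 3000, n_bins = 100)
  expect_equal(which(prof$profile != 0), 51)
  expect_equal(prof$profile[51], 1)  # 60 over a 60-bp bin
  # per-region averaging: tracks of 1 and 3 average to 2 everywhere
  two <- signal_track(make_intervals("chr1", c(0, 30000), c(30000, 1e5),
                                     score = c(1, 3)), g)
  prof <- metaprofile(two, regions, half_window = 1000, n_bins = 20)
  expect_equal(prof$profile, rep(2, 20))
  # scaling the track scales every bin mean by the same constant
  scaled <- signal_track(make_intervals("chr1", c(0, 30000), c(30000, 1e5),
                                        score = c(5, 15)), g)
  expect_equal(metaprofile(scaled, regions, 1000, 20)$profile,
               5 * prof$profile)
  # window clipped at the chromosome start masks the missing bins; the
  # unclipped region still carries the profile there
  edge <- metaprofile(const, make_intervals("chr1", c(0, 40000), c(200, 40400)),
                      half_window = 3000, n_bins = 100)
  expect_equal(edge$profile, rep(2, 100))
  expect_true(anyNA(edge$matrix))
})
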