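test_that("reverse-forward pairing applies the signed distance gate", {
  pair1 <- function(rev, fwd)
    pair_strand_peaks(make_intervals("chr1", rev[1], rev[2]),
                      make_intervals("chr1", fwd[1], fwd[2]))
  # forward 50 bp downstream: kept, cluster spans reverse start to forward end
  cl <- pair1(c(800, 950), c(1000, 1200))
  expect_equal(bed_start(cl), 800)
  expect_equal(bed_end(cl), 1200)
  expect_equal(cl$gap, 50)
  # distance exactly at the gate is discarded
  expect_length(pair1(c(800, 950), c(1100, 1300)), 0)
  # overlapping flank peaks count as distance 0 and form a valid pair
  cl <- pair1(c(800, 1000), c(950, 1200))
  expect_equal(cl$gap, 0)
  expect_equal(c(bed_start(cl), bed_end(cl)), c(800, 1200))
  # a forward peak on the wrong side gives a negative distance: discarded
  expect_length(pair1(c(800, 950), c(100, 300)), 0)
})

test_that("each forward peak anchors at most one cluster", {
  # two reverse peaks compete for one forward peak; the closer one wins
  rev <- make_intervals("chr1", c(700, 900), c(780, 960))
  fwd <- make_intervals("chr1", 1000, 1100)
  cl <- pair_strand_peaks(rev, fwd)
  expect_length(cl, 1)
  expect_equal(cl$rev_idx, 2)  # gap 40 beats gap 220 (which also fails gate)
  expect_error(
    pair_strand_peaks(make_intervals("chr1", c(0, 50), c(100, 150)), fwd),
    "overlap within a strand")
})

test_that("pairing agrees with the brute-force all-pairs oracle", {
  set.seed(202)
  for (i in 1:60) {
    rev <- random_strand_peaks(sample(2:50, 1))
    fwd <- random_strand_peaks(sample(2:50, 1), offset = sample(0:300, 1))
    got <- pair_strand_peaks(rev, fwd)
    want <- oracle_pair(rev, fwd)
    expect_setequal(pair_key(data.frame(rev = got$rev_idx, fwd = got$fwd_idx)),
                    pair_key(want))
    expect_true(all(got$gap >= 0 & got$gap < 150))
    expect_false(any(duplicated(got$fwd_idx)))
  }
})

test_that("replicate consensus keeps only cross-replicate overlaps, merged", {
  r1 <- make_intervals("chr1", c(100, 420), c(400, 700))
  r2 <- make_intervals("chr1", 350, 600)
  cons <- consensus_clusters(r1[1], r2)
  expect_equal(c(bed_start(cons), bed_end(cons)), c(100, 600))
  expect_length(consensus_clusters(r1[1], make_intervals("chr1", 500, 600)), 0)
  # transitive merge: both rep1 clusters overlap the same rep2 cluster
  cons <- consensus_clusters(r1, make_intervals("chr1", 300, 500))
  expect_equal(c(bed_start(cons), bed_end(cons)), c(100, 700))
})

test_that("DSB kinetic classes partition enriched clusters with promotion", {
  t10 <- make_intervals("chr1", c(100, 1000, 5000), c(300, 1200, 5200))
  t20 <- make_intervals("chr1", c(250, 3000), c(500, 3200))
  cl <- classify_dsb_kinetics(t10, t20)
  # the transient cluster overlapping a late cluster is promoted and merged
  expect_equal(c(bed_start(cl$persistent), bed_end(cl$persistent)), c(100, 500))
  expect_equal(bed_start(cl$transient), c(1000, 5000))
  expect_equal(bed_start(cl$late), 3000)
  # classes are disjoint after promotion and merging
  all_cl <- c(cl$persistent, cl$transient, cl$late)
  expect_length(GenomicRanges::findOverlaps(all_cl, drop.self = TRUE), 0)
})

test_that("solitary peaks are gated by opposite-strand distance", {
  fwd <- make_intervals("chr1", c(1000, 9000), c(1300, 9300), strand = "+")
  rev <- make_intervals("chr1", 1400, 1700, strand = "-")
  res <- suppressWarnings(detect_sedsb(fwd, rev,
                                       counts = list(forward = c(10, 20),
                                                     reverse = 5)))
  # forward peak 100 bp from a reverse peak is not solitary; 7.3 kb is
  expect_equal(sum(GenomicRanges::strand(res) == "+"), 1)
  expect_equal(bed_start(res[GenomicRanges::strand(res) == "+"]), 9000)
  # the lone reverse peak has no opposite peak beyond 150 bp? it is 100 bp
  expect_false(1400 %in% bed_start(res))
})

test_that("the inter-quartile count filter retains the central half", {
  # eight solitary forward peaks, counts 10..80
  fwd <- make_intervals("chr1", seq(1000, 71000, by = 10000),
                        seq(1300, 71300, by = 10000), strand = "+")
  res <- detect_sedsb(fwd, GenomicRanges::GRanges(),
                      counts = list(forward = seq(10, 80, by = 10),
                                    reverse = numeric(0)))
  expect_length(res, 8)
  expect_true(all(is.infinite(res$nearest_opposite_distance)))
  # linear-interpolation quartiles: Q1 = 27.5, Q3 = 62.5
  expect_equal(sort(res$count[res$iq_retained]), c(30, 40, 50, 60))
  # fewer than 4 peaks on a strand: filter skipped with a warning
  expect_warning(
    small <- detect_sedsb(fwd[1:2], GenomicRanges::GRanges(),
                          counts = list(forward = c(1, 1000),
                                        reverse = numeric(0))),
    "fewer than 4")
  expect_true(all(small$iq_retained))
})

test_that("threshold peak calling recovers rectangular blocks", {
  g <- tiny_genome(c(chr1 = 50000))
  bg <- signal_track(make_intervals("chr1", 0, 50000, score = 1), g)
  # flat signal equal to background: nothing called
  expect_length(call_strand_peaks(bg, bg, min_fold = 2, min_width = 150), 0)
  # one 400-bp block at 10x background
  sig <- signal_track(make_intervals("chr1", c(0, 2000, 2400), c(2000, 2400, 50000),
                                     score = c(1, 10, 1)), g)
  pk <- call_strand_peaks(sig, bg, min_fold = 5, min_width = 150)
  expect_equal(c(bed_start(pk), bed_end(pk)), c(2000, 2400))
  # two blocks separated by 1 kb of background stay separate
  sig2 <- signal_track(make_intervals("chr1", c(2000, 3700), c(2300, 4000),
                                      score = c(10, 10)), g)
  expect_length(call_strand_peaks(sig2, bg, min_fold = 5, min_width = 150), 2)
  expect_error(call_strand_peaks(sig, bg, min_fold = 1, min_width = 150),
               "min_fold")
})
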