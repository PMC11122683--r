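test_that("fragment counting is per-overlap with >= 1 bp", {
  regions <- make_intervals("chr1", c(200, 400), c(400, 600))
  frags <- make_intervals("chr1", c(100, 100, 390), c(250, 150, 410))
  # [100,250) overlaps region 1; [100,150) overlaps none; [390,410) both
  expect_equal(count_reads(regions, frags), c(2, 1))
  expect_equal(count_reads(GenomicRanges::GRanges(), frags), integer(0))
})

test_that("the moderated t-statistic matches the closed form", {
  # target region: y_A = (8,8), y_B = (6,6) so s2 = 0; two filler regions
  # with within-group deviations +-0.5 pin the median variance at 0.5
  pc <- 0.5
  y2c <- function(y) 2^y - pc
  a <- rbind(y2c(c(8, 8)), y2c(c(7.5, 8.5)), y2c(c(7.5, 8.5)))
  b <- rbind(y2c(c(6, 6)), y2c(c(5.5, 6.5)), y2c(c(5.5, 6.5)))
  res <- moderated_test(a, b, d0 = 4, pseudocount = pc)
  # s0^2 = median(0, 0.5, 0.5) = 0.5; s~2 = (4 * 0.5 + 2 * 0) / 6 = 1/3
  # t = 2 / sqrt((1/3) * (1/2 + 1/2)) = 2 * sqrt(3) = 3.464
  expect_equal(res$log2fc[1], 2)
  expect_equal(res$t[1], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$p[1], 2 * stats::pt(-2 * sqrt(3), df = 6), tolerance = 1e-12)
  # identical groups: no change, p = 1
  same <- moderated_test(a, a)
  expect_equal(same$log2fc, rep(0, 3))
  expect_equal(same$p, rep(1, 3))
})

test_that("d0 = 0 recovers the classical equal-variance t-test", {
  set.seed(17)
  a <- matrix(rnbinom(200 * 3, mu = 100, size = 20), ncol = 3)
  b <- matrix(rnbinom(200 * 3, mu = 100, size = 20), ncol = 3)
  res <- moderated_test(a, b, d0 = 0, pseudocount = 0.5)
  for (i in c(1, 57, 200)) {
    tt <- stats::t.test(log2(a[i, ] + 0.5), log2(b[i, ] + 0.5),
                        var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
  # d0 = Inf pins every region's variance at the median variance
  rinf <- moderated_test(a, b, d0 = Inf)
  se <- sqrt(stats::median((apply(log2(a + 0.5), 1, stats::var) * 2 +
                              apply(log2(b + 0.5), 1, stats::var) * 2) / 4))
  expect_equal(rinf$t, rinf$log2fc / (se * sqrt(2 / 3)), tolerance = 1e-10)
})

test_that("log2 fold changes agree with a limma linear fit", {
  skip_if_not_installed("limma")
  set.seed(23)
  a <- matrix(rnbinom(50 * 2, mu = 300, size = 20), ncol = 2)
  b <- matrix(rnbinom(50 * 2, mu = 100, size = 20), ncol = 2)
  res <- moderated_test(a, b)
  y <- log2(cbind(a, b) + 0.5)
  design <- cbind(1, c(1, 1, 0, 0))
  fit <- limma::lmFit(y, design)
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("the RNase H filter keeps IP-enriched regions only", {
  set.seed(5)
  ip_true <- matrix(rnbinom(100 * 2, mu = 100, size = 50), ncol = 2)
  rh_true <- matrix(rnbinom(100 * 2, mu = 10, size = 50), ncol = 2)
  ip_decoy <- matrix(rnbinom(100 * 2, mu = 100, size = 50), ncol = 2)
  rh_decoy <- matrix(rnbinom(100 * 2, mu = 100, size = 50), ncol = 2)
  pass <- rnaseh_filter(rbind(ip_true, ip_decoy), rbind(rh_true, rh_decoy))
  expect_gt(mean(pass[1:100]), 0.9)     # sensitive regions retained
  expect_lt(mean(pass[101:200]), 0.1)   # insensitive regions removed
  expect_warning(all_pass <- rnaseh_filter(ip_true, NULL), "skipped")
  expect_true(all(all_pass))
})

test_that("consensus universe requires cross-replicate support in one condition", {
  nt <- list(make_intervals("chr1", c(0, 5000), c(300, 5400)),
             make_intervals("chr1", c(200, 9000), c(500, 9300)))
  t5 <- list(make_intervals("chr1", 5000, 5400),
             make_intervals("chr1", 12000, 12300))
  universe <- consensus_regions(list(NT = nt, T5 = t5))
  # [0,300)+[200,500) overlap in NT: union-merged to [0,500)
  expect_true(any(bed_start(universe) == 0 & bed_end(universe) == 500))
  # 5 kb peak present in NT rep1 and T5 rep1 but never both reps: excluded
  expect_false(any(bed_start(universe) == 5000))
  expect_false(any(bed_start(universe) == 9000))
  expect_error(consensus_regions(list(NT = nt[1])), "fewer than 2")
})

test_that("seven-category classification maps contrast states", {
  d5 <- data.frame(log2fc = c(1.2, 1.2, 0.1, 1.2, -1.1, 0.0, -0.8, 0.3),
                   p = c(0.001, 0.001, 0.5, 0.001, 0.002, 0.9, 0.3, 0.004))
  d60 <- data.frame(log2fc = c(1.1, 0.3, 0.2, -1.2, -1.0, 0.1, -0.9, 0.2),
                    p = c(0.002, 0.4, 0.5, 0.001, 0.003, 0.8, 0.002, 0.6))
  got <- classify_rloop_kinetics(d5, d60, rloop_p = 0.01)
  expect_equal(as.character(got),
               c("stable_gain", "transient_gain", "no_change", "discordant",
                 "stable_loss", "no_change", "late_loss", "transient_gain"))
  expect_error(classify_rloop_kinetics(d5, NULL), "required")
})

test_that("differential states honour both fold-change and p gates", {
  test <- data.frame(log2fc = c(2, 0.5, -2, 2), p = c(0.01, 0.01, 0.01, 0.5))
  expect_equal(as.character(differential_state(test, 1, 0.05)),
               c("up", "ns", "down", "ns"))
  expect_equal(as.character(differential_state(test, 0, 0.05)),
               c("up", "up", "down", "ns"))
})
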