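#' Count fragments overlapping regions
#'
#' A fragment is counted in every region it overlaps by at least 1 bp, so
#' a fragment spanning two regions contributes to both.
#'
#' @param regions GRanges of count regions.
#' @param fragments GRanges of sequenced fragments.
#' @return integer vector, one count per region.
#' @export
count_reads <- function(regions, fragments) {
  GenomicRanges::countOverlaps(regions, fragments, ignore.strand = TRUE)
}

#' Moderated two-sample t-test on log2 normalized counts
#'
#' Counts are shifted by a pseudocount and log2-transformed; per region a
#' two-sample t statistic is formed with a moderated variance that shrinks
#' the pooled within-group variance toward the median variance across
#' regions: `s~2 = (d0 * s0^2 + d * s^2) / (d0 + d)` with `s0^2 =
#' median(s^2)` and `d` the residual degrees of freedom. The statistic is
#' referred to a t distribution with `d0 + d` degrees of freedom. `d0 = 0`
#' recovers the classical equal-variance t-test; `d0 = Inf` fixes the
#' variance at `s0^2`.
#'
#' @param group_a,group_b numeric matrices of normalized counts with one
#'   row per region and at least two columns (replicates) each.
#' @param d0 prior degrees of freedom (default 4).
#' @param pseudocount added before log2 (default 0.5).
#' @return data.frame with columns `log2fc` (A minus B), `t`, `p`
#'   (two-sided).
#' @export
moderated_test <- function(group_a, group_b, d0 = 4, pseudocount = 0.5) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) != nrow(group_b))
    stop("group matrices must cover the same regions")
  na <- ncol(group_a); nb <- ncol(group_b)
  if (na < 2 || nb < 2) stop("need at least 2 replicates per group")
  ya <- log2(group_a + pseudocount)
  yb <- log2(group_b + pseudocount)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  lfc <- ma - mb
  d <- na + nb - 2
  ss <- rowSums((ya - ma)^2) + rowSums((yb - mb)^2)
  s2 <- ss / d
  s02 <- stats::median(s2)
  if (s02 < 1e-8) {
    warning("near-zero variance across all regions; flooring s0^2 at 1e-8")
    s02 <- 1e-8
  }
  s2mod <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  tt <- lfc / sqrt(s2mod * (1 / na + 1 / nb))
  df <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df)
  data.frame(log2fc = lfc, t = tt, p = p,
             row.names = rownames(group_a))
}

#' Flag differentially enriched regions
#'
#' Two gates are used in the pipeline: the DSB gate requires
#' `|log2FC| > log2fc_min` and `p < p_max`; the R-loop gate is p-only
#' (`log2fc_min = 0`). The returned state records the direction.
#'
#' @param test data.frame from [moderated_test()].
#' @param log2fc_min absolute log2 fold-change gate (0 disables it).
#' @param p_max p-value gate.
#' @return factor with levels `up`, `down`, `ns`.
#' @export
differential_state <- function(test, log2fc_min, p_max) {
  sig <- test$p < p_max & abs(test$log2fc) > log2fc_min
  state <- ifelse(!sig, "ns", ifelse(test$log2fc > 0, "up", "down"))
  factor(state, levels = c("up", "down", "ns"))
}

#' RNase H true-positive filter
#'
#' Retains only regions whose immunoprecipitated signal exceeds the
#' matched RNase H1-treated control: the region passes when the moderated
#' test of IP versus RNase H counts gives `log2FC > log2fc_min` and
#' `p < p_max`.
#'
#' @param ip_counts,rnaseh_counts numeric matrices of normalized counts
#'   over a matched region universe (>= 2 replicates each). When
#'   `rnaseh_counts` is NULL the filter is skipped with a warning and all
#'   regions pass.
#' @param d0,pseudocount see [moderated_test()].
#' @param log2fc_min,p_max gate (defaults 1 and 0.05).
#' @return logical vector, TRUE where the region passes.
#' @export
rnaseh_filter <- function(ip_counts, rnaseh_counts, d0 = 4, pseudocount = 0.5,
                          log2fc_min = 1, p_max = 0.05) {
  if (is.null(rnaseh_counts)) {
    warning("no RNase H libraries: true-positive filter skipped, ",
            "all regions retained")
    return(rep(TRUE, nrow(as.matrix(ip_counts))))
  }
  res <- moderated_test(ip_counts, rnaseh_counts, d0 = d0,
                        pseudocount = pseudocount)
  res$log2fc > log2fc_min & res$p < p_max
}

#' Consensus region universe across replicates and conditions
#'
#' A region enters the universe when, in at least one condition, a peak of
#' one replicate overlaps a peak of another replicate by >= 1 bp. Entered
#' regions are the union-merge of their overlapping group across all
#' inputs.
#'
#' @param peaks_by_condition named list; each element is a list of
#'   per-replicate GRanges (>= 2 replicates) for one condition.
#' @return GRanges of merged universe regions.
#' @export
consensus_regions <- function(peaks_by_condition) {
  all_peaks <- list()
  seeds <- list()
  for (cond in names(peaks_by_condition)) {
    reps <- peaks_by_condition[[cond]]
    if (length(reps) < 2)
      stop("condition ", cond, " has fewer than 2 replicates")
    all_peaks <- c(all_peaks, lapply(reps, GenomicRanges::granges))
    for (i in seq_len(length(reps) - 1)) for (j in seq(i + 1, length(reps))) {
      ov <- GenomicRanges::findOverlaps(reps[[i]], reps[[j]], ignore.strand = TRUE)
      if (length(ov))
        seeds[[length(seeds) + 1L]] <- GenomicRanges::granges(
          reps[[i]][unique(S4Vectors::queryHits(ov))])
    }
  }
  all_gr <- unlist(methods::as(all_peaks, "GRangesList"), use.names = FALSE)
  blocks <- GenomicRanges::reduce(all_gr, ignore.strand = TRUE)
  if (!length(seeds)) return(blocks[0])
  seed_gr <- unlist(methods::as(seeds, "GRangesList"), use.names = FALSE)
  keep <- unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(seed_gr, blocks, ignore.strand = TRUE)))
  sort_intervals(blocks[sort(keep)])
}

#' Seven-category R-loop kinetic classification
#'
#' Per region the early (5 min) and late (60 min) contrasts against the
#' untreated control are each reduced to a state (up / down / ns at
#' `p < rloop_p`, direction from the log2 fold-change sign) and the pair
#' of states maps onto the kinetic category: changes at 5 min that
#' persist at 60 min are stable gains/losses, changes at 5 min only are
#' transient, changes at 60 min only are late, and regions never
#' significant are no-change. Opposite-direction changes (up then down or
#' the reverse) are reported as `discordant` and are not counted among
#' the seven categories.
#'
#' @param diff_early,diff_late data.frames from [moderated_test()] over
#'   the same regions (early and late contrast vs control).
#' @param rloop_p p-value gate (default 0.01).
#' @return factor with levels `stable_gain`, `stable_loss`,
#'   `transient_gain`, `transient_loss`, `late_gain`, `late_loss`,
#'   `no_change`, `discordant`.
#' @export
classify_rloop_kinetics <- function(diff_early, diff_late, rloop_p = 0.01) {
  if (is.null(diff_early) || is.null(diff_late))
    stop("both contrasts are required")
  if (nrow(diff_early) != nrow(diff_late))
    stop("contrasts must cover the same regions")
  s1 <- differential_state(diff_early, log2fc_min = 0, p_max = rloop_p)
  s2 <- differential_state(diff_late, log2fc_min = 0, p_max = rloop_p)
  key <- paste(s1, s2, sep = ".")
  map <- c(up.up = "stable_gain", down.down = "stable_loss",
           up.ns = "transient_gain", down.ns = "transient_loss",
           ns.up = "late_gain", ns.down = "late_loss",
           ns.ns = "no_change", up.down = "discordant",
           down.up = "discordant")
  factor(unname(map[key]), levels = rloop_categories())
}

#' @rdname classify_rloop_kinetics
#' @export
rloop_categories <- function() {
  c("stable_gain", "stable_loss", "transient_gain", "transient_loss",
    "late_gain", "late_loss", "no_change", "discordant")
}
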