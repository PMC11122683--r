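#' Call peaks on a strand-specific signal track
#'
#' A deliberately simple threshold caller used when only coverage tracks
#' are available: maximal runs where the signal reaches `min_fold` times
#' the local background (floored at the genome-wide background mean) are
#' kept, nearby runs are merged, and short runs are dropped. It is not a
#' model-based caller; externally called peaks can be supplied to the rest
#' of the pipeline instead.
#'
#' @param track `signal_track` with the strand's coverage.
#' @param background `signal_track` with matched control coverage.
#' @param min_fold required fold over background, must be > 1.
#' @param min_width minimum peak width in bp; runs separated by less than
#'   `min_width / 2` bp of sub-threshold signal are merged first.
#' @param strand strand label stamped on the returned peaks.
#' @return GRanges of peaks.
#' @export
call_strand_peaks <- function(track, background, min_fold, min_width,
                              strand = "*") {
  if (min_fold <= 1) stop("min_fold must be > 1")
  lens <- GenomeInfoDb::seqlengths(track$genome)
  bg_mean <- sum(vapply(background$cov, function(r) sum(as.numeric(r)), 0)) /
    sum(as.numeric(lens))
  if (!is.finite(bg_mean) || bg_mean <= 0)
    stop("background track has non-positive genome-wide mean")
  out <- list()
  for (chr in names(track$cov)) {
    sig <- track$cov[[chr]]
    thr <- min_fold * S4Vectors::Rle(pmax(as.numeric(background$cov[[chr]]), bg_mean))
    ir <- IRanges::slice(sig - thr, lower = 0, rangesOnly = TRUE)
    ir <- IRanges::reduce(ir, min.gapwidth = ceiling(min_width / 2))
    ir <- ir[IRanges::width(ir) >= min_width]
    if (length(ir))
      out[[chr]] <- GenomicRanges::GRanges(chr, ir, strand = strand)
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqinfo(gr) <- track$genome
    return(gr)
  }
  gr <- unlist(methods::as(out, "GRangesList"), use.names = FALSE)
  bind_genome(gr, track$genome)
}

# Signed reverse->forward distance in BED coordinates: positive when the
# forward peak starts at or beyond the reverse peak end, 0 on overlap,
# negative when the forward peak lies entirely left of the reverse peak.
pair_distance <- function(rs, re, fs, fe) {
  if (fs >= re) fs - re else if (fe <= rs) -(rs - fe) else 0
}

#' Pair reverse and forward strand peaks into DSB clusters
#'
#' END-seq reads flank a double-strand break strand-specifically: minus
#' strand on the left, plus strand on the right. For each reverse peak the
#' closest forward peak is found; the pair is kept when the signed
#' distance `d` (forward start minus reverse end, 0 on overlap, negative
#' when the forward peak is on the wrong side) satisfies
#' `0 <= d < max_pair_gap`, and the cluster spans reverse start to forward
#' end. A forward peak on the wrong (left) side never forms a pair, even
#' when abutting the reverse peak, but can still be the closest candidate
#' and leave the reverse peak unpaired. Each forward peak anchors at most
#' one cluster; competing claims are resolved by smaller distance, then
#' leftmost forward peak, then leftmost reverse peak.
#'
#' @param reverse_peaks,forward_peaks GRanges of one replicate/condition;
#'   peaks must be non-overlapping within each strand.
#' @param max_pair_gap exclusive upper bound on the gap in bp (default
#'   150).
#' @return GRanges of clusters with metadata columns `rev_idx`, `fwd_idx`
#'   (indices into the inputs) and `gap`.
#' @export
pair_strand_peaks <- function(reverse_peaks, forward_peaks, max_pair_gap = 150) {
  for (p in list(reverse_peaks, forward_peaks)) {
    o <- order(as.integer(GenomicRanges::seqnames(p)), GenomicRanges::start(p))
    same <- as.integer(GenomicRanges::seqnames(p))[o]
    st <- GenomicRanges::start(p)[o]; en <- GenomicRanges::end(p)[o]
    n <- length(st)
    if (n > 1 && any(st[-1] <= en[-n] & same[-1] == same[-n]))
      stop("peaks overlap within a strand; merge them first")
  }
  rev_chr <- as.character(GenomicRanges::seqnames(reverse_peaks))
  fwd_chr <- as.character(GenomicRanges::seqnames(forward_peaks))
  all_rs <- start0(reverse_peaks); all_re <- end0(reverse_peaks)
  all_fs <- start0(forward_peaks); all_fe <- end0(forward_peaks)
  nr <- length(reverse_peaks)
  c_chr <- character(nr); c_rev <- integer(nr); c_fwd <- integer(nr)
  c_rs <- numeric(nr); c_fe <- numeric(nr); c_fstart <- numeric(nr)
  c_gap <- numeric(nr); n_claim <- 0L
  ri_by_chr <- split(seq_along(rev_chr), rev_chr)
  fi_by_chr <- split(seq_along(fwd_chr), fwd_chr)
  for (chr in unique(rev_chr)) {
    ri <- ri_by_chr[[chr]]
    fi <- fi_by_chr[[chr]]
    if (is.null(fi)) next
    fo <- fi[order(all_fs[fi])]
    fs <- all_fs[fo]; fe <- all_fe[fo]
    nf <- length(fo)
    for (i in ri) {
      rs <- all_rs[i]; re <- all_re[i]
      n_left <- findInterval(rs, fe)            # forward peaks entirely left
      n_before <- findInterval(re - 0.5, fs)    # forward peaks starting < re
      # a left-adjacent forward peak sits at distance -0: it is the
      # closest candidate (leftmost at |d| = 0) but on the wrong side,
      # so the reverse peak stays unpaired
      if (n_left >= 1L && fe[n_left] == rs) next
      if (n_before > n_left) {                  # at least one overlapping peak
        j <- n_left + 1L                        # leftmost overlapping forward
        d <- 0
      } else {
        d_left <- if (n_left >= 1L) rs - fe[n_left] else Inf
        d_right <- if (n_before < nf) fs[n_before + 1L] - re else Inf
        # closest by |d|; a tie goes to the smaller signed d, i.e. the
        # wrong-side candidate, which discards the reverse peak
        if (d_left <= d_right || d_right >= max_pair_gap) next
        j <- n_before + 1L; d <- d_right
      }
      if (d < max_pair_gap) {
        n_claim <- n_claim + 1L
        c_chr[n_claim] <- chr; c_rev[n_claim] <- i; c_fwd[n_claim] <- fo[j]
        c_rs[n_claim] <- rs; c_fe[n_claim] <- fe[j]
        c_fstart[n_claim] <- fs[j]; c_gap[n_claim] <- d
      }
    }
  }
  k <- seq_len(n_claim)
  claims <- data.frame(chrom = c_chr[k], rev_idx = c_rev[k], fwd_idx = c_fwd[k],
                       rs = c_rs[k], fe = c_fe[k], f_start = c_fstart[k],
                       gap = c_gap[k])
  if (!nrow(claims)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(rev_idx = integer(0),
                                                 fwd_idx = integer(0),
                                                 gap = numeric(0))
    if (length(GenomeInfoDb::seqlengths(reverse_peaks)))
      GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::seqinfo(reverse_peaks)
    return(gr)
  }
  cl <- claims[order(claims$gap, claims$f_start, claims$rs), , drop = FALSE]
  cl <- cl[!duplicated(cl$fwd_idx), , drop = FALSE]
  cl <- cl[order(match(cl$chrom, unique(cl$chrom)), cl$rs), , drop = FALSE]
  gr <- make_intervals(cl$chrom, cl$rs, cl$fe,
                       rev_idx = cl$rev_idx, fwd_idx = cl$fwd_idx, gap = cl$gap)
  if (length(GenomeInfoDb::seqlengths(reverse_peaks)))
    gr <- bind_genome(gr, GenomeInfoDb::seqinfo(reverse_peaks))
  gr
}

#' Replicate consensus of DSB clusters
#'
#' Keeps cluster regions supported by both replicates: wherever a
#' replicate-1 cluster overlaps a replicate-2 cluster by at least 1 bp,
#' the whole overlapping group is union-merged into one consensus cluster.
#'
#' @param clusters_rep1,clusters_rep2 GRanges of per-replicate clusters
#'   from one condition.
#' @return GRanges of merged consensus clusters.
#' @export
consensus_clusters <- function(clusters_rep1, clusters_rep2) {
  ov <- GenomicRanges::findOverlaps(clusters_rep1, clusters_rep2,
                                    ignore.strand = TRUE)
  keep <- c(clusters_rep1[unique(S4Vectors::queryHits(ov))],
            clusters_rep2[unique(S4Vectors::subjectHits(ov))])
  GenomicRanges::reduce(GenomicRanges::granges(keep), ignore.strand = TRUE)
}

#' Kinetic classification of DSB clusters
#'
#' Clusters enriched at both treatment timepoints are persistent; clusters
#' enriched only at the early timepoint are transient; only at the late
#' timepoint, late. Because cluster identity across timepoints is defined
#' by overlap, a transient cluster overlapping a late cluster means both
#' timepoints are enriched at that locus, so both members are promoted to
#' one merged persistent cluster. Within each final class overlapping
#' clusters are merged.
#'
#' @param enriched_t1 GRanges of consensus clusters enriched (over
#'   control) at the early timepoint.
#' @param enriched_t2 same for the late timepoint.
#' @return list with GRanges elements `persistent`, `transient`, `late`.
#' @export
classify_dsb_kinetics <- function(enriched_t1, enriched_t2) {
  ov <- GenomicRanges::findOverlaps(enriched_t1, enriched_t2, ignore.strand = TRUE)
  in_both1 <- unique(S4Vectors::queryHits(ov))
  in_both2 <- unique(S4Vectors::subjectHits(ov))
  persistent <- GenomicRanges::reduce(GenomicRanges::granges(
    c(enriched_t1[in_both1], enriched_t2[in_both2])), ignore.strand = TRUE)
  transient <- GenomicRanges::reduce(GenomicRanges::granges(
    enriched_t1[setdiff(seq_along(enriched_t1), in_both1)]), ignore.strand = TRUE)
  late <- GenomicRanges::reduce(GenomicRanges::granges(
    enriched_t2[setdiff(seq_along(enriched_t2), in_both2)]), ignore.strand = TRUE)
  list(persistent = persistent, transient = transient, late = late)
}

#' Detect single-ended DSB candidates from solitary strand peaks
#'
#' A peak whose nearest opposite-strand peak is farther than
#' `max_pair_gap` bp (overlap counts as 0) is a solitary peak ascribable
#' to a single-ended break. To remove count outliers, only peaks whose
#' count lies within the first and third quartile of their strand's count
#' distribution (linear-interpolation quantiles, boundaries inclusive)
#' are retained for differential testing.
#'
#' @param forward_peaks,reverse_peaks per-strand consensus peaks
#'   (GRanges).
#' @param counts list with numeric vectors `forward` and `reverse`, the
#'   (normalized) count per peak.
#' @param max_pair_gap bp (default 150).
#' @return GRanges of solitary peaks with strand set and metadata columns
#'   `nearest_opposite_distance`, `count`, `iq_retained`.
#' @export
detect_sedsb <- function(forward_peaks, reverse_peaks, counts,
                         max_pair_gap = 150) {
  empty_solo <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      nearest_opposite_distance = numeric(0), count = numeric(0),
      iq_retained = logical(0))
    gr
  }
  solo_one <- function(peaks, opposite, count, strand) {
    if (!length(peaks)) return(empty_solo())
    dist <- rep(Inf, length(peaks))
    if (length(opposite)) {
      hit <- GenomicRanges::distanceToNearest(peaks, opposite, ignore.strand = TRUE)
      dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    }
    keep <- dist > max_pair_gap
    peaks <- GenomicRanges::granges(peaks)[keep]
    GenomicRanges::strand(peaks) <- strand
    peaks$nearest_opposite_distance <- dist[keep]
    peaks$count <- count[keep]
    if (length(peaks) < 4) {
      if (length(peaks))
        warning("fewer than 4 solitary peaks on strand ", strand,
                "; inter-quartile filter skipped")
      peaks$iq_retained <- rep(TRUE, length(peaks))
    } else {
      q <- stats::quantile(peaks$count, c(0.25, 0.75), type = 7)
      peaks$iq_retained <- peaks$count >= q[1] & peaks$count <= q[2]
    }
    peaks
  }
  fwd <- solo_one(forward_peaks, reverse_peaks, counts$forward, "+")
  rev <- solo_one(reverse_peaks, forward_peaks, counts$reverse, "-")
  sort_intervals(c(fwd, rev))
}
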