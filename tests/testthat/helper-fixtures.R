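# Shared fixtures: a small genome, random non-overlapping strand peaks,
# and a brute-force all-pairs pairing oracle kept deliberately independent
# of the package's sorted-search implementation.

tiny_genome <- function(lens = c(chr1 = 1e6, chr2 = 1e6)) {
  genome_spec(names(lens), lens)
}

# Non-overlapping peaks on one chromosome: widths and inter-peak gaps
# drawn from ranges that produce plenty of near-150-bp cross-strand
# distances. Uses the caller's RNG state.
random_strand_peaks <- function(n, chrom = "chr1", width_range = c(50, 400),
                                gap_range = c(0, 500), offset = 0) {
  w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  g <- sample(seq(gap_range[1], gap_range[2]), n, replace = TRUE)
  start <- offset + cumsum(g) + c(0, cumsum(w[-n]))
  make_intervals(rep(chrom, n), start, start + w)
}

# Brute-force oracle: enumerate every (reverse, forward) pair on the
# chromosome, apply the signed-distance rule, take per reverse peak the
# candidate minimizing |d| (ties: smaller signed d, then leftmost forward
# start), gate 0 <= d < max_gap, then resolve forward-peak conflicts by
# (d, forward start, reverse start). Returns the kept (rev, fwd) index
# pairs.
oracle_pair <- function(rev, fwd, max_gap = 150) {
  rs <- GenomicRanges::start(rev) - 1L; re <- GenomicRanges::end(rev)
  fs <- GenomicRanges::start(fwd) - 1L; fe <- GenomicRanges::end(fwd)
  rchr <- as.character(GenomicRanges::seqnames(rev))
  fchr <- as.character(GenomicRanges::seqnames(fwd))
  fwd_by_chr <- split(seq_along(fchr), fchr)
  rows <- vector("list", length(rev))
  for (i in seq_along(rev)) {
    on <- fwd_by_chr[[rchr[i]]]
    if (is.null(on)) next
    d <- ifelse(fs[on] >= re[i], fs[on] - re[i],
                ifelse(fe[on] <= rs[i], -(rs[i] - fe[on]), 0))
    j <- on[order(abs(d), d, fs[on])][1]
    dj <- d[match(j, on)]
    # wrong-side candidates (including a left-adjacent forward peak, whose
    # signed distance is -0) never form a cluster
    if (dj >= 0 && dj < max_gap && fe[j] > rs[i])
      rows[[i]] <- c(rev = i, fwd = j, d = dj, fstart = fs[j], rstart = rs[i])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(data.frame(rev = integer(0), fwd = integer(0)))
  claims <- as.data.frame(do.call(rbind, rows))
  claims <- claims[order(claims$d, claims$fstart, claims$rstart), ]
  claims <- claims[!duplicated(claims$fwd), ]
  claims[order(claims$rev), c("rev", "fwd")]
}

pair_key <- function(df) paste(df$rev, df$fwd, sep = ":")

# Batch of independent pairing instances, one per virtual chromosome, so
# a single pair_strand_peaks() call processes them all. Returns the two
# strand GRanges; indices stay comparable with the oracle because both
# work on global record indices.
random_pairing_instances <- function(n_inst, max_n = 50) {
  rl <- list(); fl <- list()
  for (i in seq_len(n_inst)) {
    chr <- sprintf("inst%03d", i)
    nr <- sample(2:max_n, 1); nf <- sample(2:max_n, 1)
    wr <- sample(50:400, nr, replace = TRUE)
    gr <- sample(0:500, nr, replace = TRUE)
    sr <- cumsum(gr) + c(0, cumsum(wr[-nr]))
    wf <- sample(50:400, nf, replace = TRUE)
    gf <- sample(0:500, nf, replace = TRUE)
    sf <- sample(0:300, 1) + cumsum(gf) + c(0, cumsum(wf[-nf]))
    rl[[i]] <- data.frame(chr = chr, s = sr, e = sr + wr)
    fl[[i]] <- data.frame(chr = chr, s = sf, e = sf + wf)
  }
  rdf <- do.call(rbind, rl); fdf <- do.call(rbind, fl)
  list(rev = make_intervals(rdf$chr, rdf$s, rdf$e),
       fwd = make_intervals(fdf$chr, fdf$s, fdf$e))
}

# compact accessors used throughout the tests
bed_start <- function(gr) GenomicRanges::start(gr) - 1L
bed_end <- function(gr) GenomicRanges::end(gr)
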