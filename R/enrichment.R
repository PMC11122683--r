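#' Randomize intervals within their chromosomes
#'
#' Each interval keeps its length and chromosome; a new start is drawn
#' uniformly from the admissible range. Shuffled intervals may overlap
#' one another.
#'
#' @param query GRanges.
#' @param genome \link[GenomeInfoDb]{Seqinfo}.
#' @param seed optional integer; when given, placement is reproducible
#'   and the caller's RNG state is left untouched.
#' @return GRanges of randomized intervals.
#' @export
shuffle_intervals <- function(query, genome, seed = NULL) {
  with_seed(seed, {
    lens <- GenomeInfoDb::seqlengths(genome)[as.character(GenomicRanges::seqnames(query))]
    w <- GenomicRanges::width(query)
    if (any(w > lens))
      stop("interval longer than its chromosome at record ", which(w > lens)[1])
    # integer start0 uniform on 0 .. (len - width), inclusive
    new_start0 <- floor(stats::runif(length(query)) * (lens - w + 1))
    new_start0 <- pmin(new_start0, lens - w)
    make_intervals(as.character(GenomicRanges::seqnames(query)),
                   new_start0, new_start0 + w, genome = genome)
  })
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomization-based overlap enrichment with a binomial test
#'
#' The observed statistic is the number of query intervals overlapping at
#' least one feature by >= 1 bp. The expectation is the mean of the same
#' count over `n_shuffles` within-chromosome randomizations of the query.
#' The expectation divided by the number of query intervals, clamped away
#' from 0 and 1, serves as the binomial success probability; the p-value
#' is the upper tail when the observed count is at or above expectation
#' and the lower tail otherwise. The fold change is
#' `log2((observed + 0.5) / (expected + 0.5))`.
#'
#' @param query GRanges of query intervals (e.g. one kinetic class).
#' @param features GRanges of the annotation set.
#' @param genome \link[GenomeInfoDb]{Seqinfo}.
#' @param n_shuffles number of randomizations (default 100).
#' @param seed optional integer for reproducible randomization.
#' @return one-row data.frame: `n_query`, `observed`, `expected`,
#'   `log2fc`, `p`, `direction` ("enriched" when observed >= expected,
#'   else "depleted").
#' @export
overlap_enrichment <- function(query, features, genome, n_shuffles = 100,
                               seed = NULL) {
  n <- length(query)
  if (n < 1) stop("empty query set")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  observed <- sum(GenomicRanges::countOverlaps(query, features,
                                               ignore.strand = TRUE) > 0)
  rep_query <- rep(query, n_shuffles)
  shuffled <- shuffle_intervals(rep_query, genome, seed = seed)
  hit <- GenomicRanges::countOverlaps(shuffled, features,
                                      ignore.strand = TRUE) > 0
  per_shuffle <- rowsum(as.numeric(hit),
                        group = rep(seq_len(n_shuffles), each = n))
  expected <- mean(per_shuffle)
  floor_p <- 1 / (2 * n * n_shuffles)
  p_hat <- min(max(expected / n, floor_p), 1 - floor_p)
  p <- if (observed >= expected)
    stats::pbinom(observed - 1, n, p_hat, lower.tail = FALSE)
  else
    stats::pbinom(observed, n, p_hat)
  data.frame(n_query = n, observed = observed, expected = expected,
             log2fc = log2((observed + 0.5) / (expected + 0.5)),
             p = p,
             direction = if (observed >= expected) "enriched" else "depleted")
}

#' Gene models for feature annotation
#'
#' @param genes GRanges of gene spans with strand and a `gene_id` column;
#'   TSS/TES are derived from the strand.
#' @param utr5,utr3 optional GRanges of UTR spans with a `gene_id` column.
#' @return list of class `gene_models`.
#' @export
gene_models <- function(genes, utr5 = NULL, utr3 = NULL) {
  if (is.null(genes$gene_id)) stop("genes need a gene_id column")
  if (any(GenomicRanges::strand(genes) == "*"))
    stop("genes must be stranded")
  structure(list(genes = genes, utr5 = utr5, utr3 = utr3),
            class = "gene_models")
}

#' Annotate peaks by gene feature
#'
#' Strand-aware windows: promoter = 10 kbp upstream of the TSS (plus the
#' 5' UTR), terminator = 3' UTR plus 10 kbp downstream of the TES,
#' gene body = the gene span. Each peak is assigned by its midpoint with
#' priority promoter > terminator > gene body > intergenic.
#'
#' @param peaks GRanges.
#' @param models a [gene_models()] object.
#' @param promoter_upstream,downstream window sizes in bp (default 10000).
#' @return data.frame with `category` (factor: promoter, terminator,
#'   gene_body, intergenic) and `gene_id` (NA for intergenic).
#' @export
annotate_gene_feature <- function(peaks, models, promoter_upstream = 10000,
                                  downstream = 10000) {
  genes <- models$genes
  prom <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genes, upstream = promoter_upstream, downstream = 1)))
  prom$gene_id <- genes$gene_id
  if (!is.null(models$utr5)) prom <- c(prom, models$utr5)
  term <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(genes, width = downstream, start = FALSE)))
  term$gene_id <- genes$gene_id
  if (!is.null(models$utr3)) term <- c(term, models$utr3)
  mid0 <- floor((start0(peaks) + end0(peaks)) / 2)
  mid <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(mid0 + 1L, width = 1L))
  known <- as.character(GenomicRanges::seqnames(mid)) %in%
    unique(as.character(GenomicRanges::seqnames(genes)))
  if (!all(known))
    warning(sum(!known), " peak(s) on chromosomes absent from the gene ",
            "models; annotated intergenic")
  category <- rep("intergenic", length(peaks))
  gene_id <- rep(NA_character_, length(peaks))
  assign_hits <- function(windows, label) {
    ov <- GenomicRanges::findOverlaps(mid, windows, ignore.strand = TRUE)
    first <- !duplicated(S4Vectors::queryHits(ov))
    qh <- S4Vectors::queryHits(ov)[first]
    free <- category[qh] == "intergenic"
    category[qh[free]] <<- label
    gene_id[qh[free]] <<- windows$gene_id[S4Vectors::subjectHits(ov)[first]][free]
  }
  assign_hits(prom, "promoter")
  assign_hits(term, "terminator")
  body <- genes; body$gene_id <- genes$gene_id
  assign_hits(body, "gene_body")
  data.frame(
    category = factor(category,
                      levels = c("promoter", "terminator", "gene_body", "intergenic")),
    gene_id = gene_id)
}

#' Distance to the nearest feature
#'
#' @param peaks,features GRanges.
#' @return numeric vector of unsigned gaps in bp (0 on overlap); NA for
#'   peaks on chromosomes without any feature.
#' @export
nearest_feature_distance <- function(peaks, features) {
  if (!length(features)) stop("empty feature set")
  out <- rep(NA_real_, length(peaks))
  hit <- GenomicRanges::distanceToNearest(peaks, features, ignore.strand = TRUE)
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  out
}

#' Reference-point metaprofile
#'
#' For each region the window of `2 * half_window` bp centred on the
#' region midpoint is cut into `n_bins` equal bins and the mean track
#' value per bin is computed; positions clipped at chromosome edges are
#' masked. The profile is the column mean over regions.
#'
#' @param track a `signal_track`.
#' @param regions GRanges (non-empty).
#' @param half_window bp on each side of the centre (default 3000).
#' @param n_bins number of bins (default 100).
#' @return list with `profile` (numeric, length `n_bins`) and `matrix`
#'   (regions x bins).
#' @export
metaprofile <- function(track, regions, half_window = 3000, n_bins = 100) {
  if (!length(regions)) stop("no regions supplied")
  lens <- GenomeInfoDb::seqlengths(track$genome)
  # bin index of each offset in the window
  bounds <- round(seq(0, 2 * half_window, length.out = n_bins + 1))
  bin_of <- findInterval(seq_len(2 * half_window) - 1, bounds,
                         rightmost.closed = FALSE)
  bin_of[bin_of > n_bins] <- n_bins
  mat <- matrix(NA_real_, length(regions), n_bins)
  any_on <- FALSE
  for (i in seq_along(regions)) {
    chr <- as.character(GenomicRanges::seqnames(regions))[i]
    if (!chr %in% names(track$cov)) next
    any_on <- TRUE
    centre0 <- floor((start0(regions)[i] + end0(regions)[i]) / 2)
    lo0 <- centre0 - half_window
    hi0 <- centre0 + half_window            # window is [lo0, hi0), 0-based
    v <- rep(NA_real_, 2 * half_window)
    take_lo <- max(lo0, 0)
    take_hi <- min(hi0, lens[[chr]])
    if (take_hi > take_lo)
      v[(take_lo - lo0 + 1):(take_hi - lo0)] <-
        as.numeric(S4Vectors::window(track$cov[[chr]], take_lo + 1, take_hi))
    row <- vapply(seq_len(n_bins),
                  function(b) mean(v[bin_of == b], na.rm = TRUE), numeric(1))
    row[is.nan(row)] <- NA_real_
    mat[i, ] <- row
  }
  if (!any_on) stop("all regions lie on chromosomes absent from the track")
  list(profile = colMeans(mat, na.rm = TRUE), matrix = mat)
}
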