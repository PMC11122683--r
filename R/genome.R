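#' Construct a genome specification
#'
#' A genome specification is the chromosome dictionary every stage of the
#' pipeline validates against. It is represented as a
#' \link[GenomeInfoDb]{Seqinfo} object so that all interval containers
#' (\link[GenomicRanges]{GRanges}) carry it natively.
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in base pairs,
#'   strictly positive, one per chromosome.
#' @return A \link[GenomeInfoDb]{Seqinfo} object.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_spec <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have the same length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be strictly positive")
  GenomeInfoDb::Seqinfo(seqnames = chromosomes, seqlengths = as.integer(lengths))
}

#' Build genomic intervals from 0-based half-open coordinates
#'
#' Convenience constructor mapping BED-convention coordinates (0-based
#' start, exclusive end) onto the 1-based closed coordinates GRanges uses
#' internally. All public functions of this package accept and return
#' GRanges; files on disk use the BED convention.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open.
#' @param strand optional strand vector ("+", "-"); default "*".
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}; when supplied the
#'   intervals are validated against it and carry it along.
#' @param ... further metadata columns (e.g. \code{name}, \code{score}).
#' @return A \link[GenomicRanges]{GRanges}.
#' @examples
#' make_intervals("chr1", 100, 200)  # BED chr1:100-200
#' @export
make_intervals <- function(chrom, start, end, strand = "*", genome = NULL, ...) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval coordinates must be finite")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval (start >= end) at record ", bad[1])
  if (any(start < 0))
    stop("interval start must be >= 0")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  mcols <- list(...)
  if (length(mcols)) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mcols)
  if (!is.null(genome)) gr <- bind_genome(gr, genome)
  gr
}

#' Validate intervals against a genome specification
#'
#' Attaches the genome's Seqinfo to the intervals and errors if any
#' interval names an unknown chromosome or extends beyond a chromosome
#' end.
#'
#' @param gr a GRanges.
#' @param genome a \link[GenomeInfoDb]{Seqinfo} from [genome_spec()].
#' @return `gr` with `seqinfo` set.
#' @export
bind_genome <- function(gr, genome) {
  unknown <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), GenomeInfoDb::seqnames(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unique(unknown), collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
  GenomeInfoDb::seqinfo(gr) <- genome
  lens <- GenomeInfoDb::seqlengths(genome)[as.character(GenomicRanges::seqnames(gr))]
  over <- which(GenomicRanges::end(gr) > lens)
  if (length(over))
    stop("interval extends beyond chromosome end at record ", over[1])
  gr
}

#' Sort intervals deterministically
#'
#' Ordering is by genome chromosome order, then start, then end. Used by
#' all writers so outputs diff cleanly between runs.
#'
#' @param gr a GRanges with seqinfo set (or with seqlevels in the desired
#'   order).
#' @return the sorted GRanges.
#' @export
sort_intervals <- function(gr) {
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# 0-based start / exclusive end accessors (BED view of a GRanges)
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)
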