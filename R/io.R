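#' Read a BED3/BED6 interval file
#'
#' Coordinates are parsed as 0-based half-open and returned as a GRanges
#' (1-based internally, converted back on write). Column 4 becomes
#' \code{name}, column 5 \code{score}, column 6 the strand.
#'
#' @param path path to a tab-separated BED file without header.
#' @param expect_strand if TRUE, require a valid strand in field 6.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo} to validate against.
#' @return GRanges in file order.
#' @export
read_intervals <- function(path, expect_strand = FALSE, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  if (expect_strand && any(nf < 6))
    stop("malformed BED line ", which(nf < 6)[1],
         ": strand expected but fewer than 6 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval (start >= end) at line ", bad[1])
  strand <- rep("*", length(lines))
  if (expect_strand) {
    strand <- vapply(fields, `[[`, "", 6L)
    badstr <- which(!strand %in% c("+", "-"))
    if (length(badstr))
      stop("malformed BED line ", badstr[1], ": strand must be + or -")
  }
  gr <- make_intervals(chrom, start, end, strand = strand, genome = genome)
  if (any(nf >= 4)) {
    nm <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
    if (!all(is.na(nm))) gr$name <- nm
  }
  if (any(nf >= 5)) {
    sc <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")))
    if (!all(is.na(sc))) gr$score <- sc
  }
  gr
}

#' Write intervals as BED
#'
#' Records are written 0-based half-open, sorted by genome chromosome
#' order, then start, then end, so output is deterministic. Round-trips
#' through [read_intervals()].
#'
#' @param gr GRanges to write; metadata columns \code{name} and
#'   \code{score} populate BED columns 4-5, strand column 6 when any
#'   record is stranded.
#' @param path output path.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}; records are
#'   validated and sorted in its chromosome order.
#' @param extra_columns optional character vector of metadata column names
#'   appended after the standard BED columns.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path, genome = NULL, extra_columns = NULL) {
  if (!is.null(genome)) gr <- bind_genome(gr, genome)
  gr <- sort_intervals(gr)
  if (!length(gr)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stranded <- any(GenomicRanges::strand(gr) != "*")
  has_name <- !is.null(gr$name)
  has_score <- !is.null(gr$score)
  cols <- list(
    as.character(GenomicRanges::seqnames(gr)),
    format(start0(gr), scientific = FALSE, trim = TRUE),
    format(end0(gr), scientific = FALSE, trim = TRUE)
  )
  if (has_name || has_score || stranded)
    cols <- c(cols, list(if (has_name) gr$name else "."))
  if (has_score || stranded)
    cols <- c(cols, list(if (has_score) format(gr$score, trim = TRUE) else "0"))
  if (stranded)
    cols <- c(cols, list(as.character(GenomicRanges::strand(gr))))
  for (ec in extra_columns) cols <- c(cols, list(as.character(S4Vectors::mcols(gr)[[ec]])))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Returns a piecewise-constant signal queryable at any base pair (0 where
#' uncovered), stored as a run-length encoded coverage vector per
#' chromosome.
#'
#' @param path 4-column bedGraph (chrom, start, end, value), 0-based
#'   half-open, no header. Blocks on one chromosome must not overlap.
#' @param genome \link[GenomeInfoDb]{Seqinfo} giving chromosome lengths.
#' @return A `signal_track`: list with elements `cov` (an RleList) and
#'   `genome`.
#' @export
read_signal_track <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("invalid bedGraph block (start >= end) at line ", bad[1])
  gr <- make_intervals(df$chrom, df$start, df$end, genome = genome, score = df$value)
  signal_track(gr, genome)
}

#' Build a signal track from scored intervals
#'
#' @param gr GRanges with a numeric `score` column; blocks on a chromosome
#'   must not overlap.
#' @param genome \link[GenomeInfoDb]{Seqinfo}.
#' @return A `signal_track` object.
#' @export
signal_track <- function(gr, genome) {
  gr <- bind_genome(gr, genome)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE,
                                    ignore.strand = TRUE)
  if (length(ov))
    stop("overlapping signal blocks (records ",
         S4Vectors::queryHits(ov)[1], " and ", S4Vectors::subjectHits(ov)[1], ")")
  if (is.null(gr$score)) stop("signal intervals need a 'score' column")
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  structure(list(cov = cov, genome = genome), class = "signal_track")
}

#' Signal value at single positions
#'
#' @param track a `signal_track`.
#' @param chrom chromosome name.
#' @param pos 0-based positions.
#' @return numeric vector of values (0 where uncovered).
#' @export
track_value <- function(track, chrom, pos) {
  as.numeric(track$cov[[chrom]][pos + 1L])
}

#' Mean signal over intervals
#'
#' @param track a `signal_track`.
#' @param gr GRanges of query intervals.
#' @return numeric vector, mean track value per interval.
#' @export
track_mean <- function(track, gr) {
  vapply(seq_along(gr), function(i) {
    chr <- as.character(GenomicRanges::seqnames(gr))[i]
    mean(S4Vectors::window(track$cov[[chr]],
                           GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
  }, numeric(1))
}

#' Write a signal track as bedGraph
#'
#' Emits one line per constant-value run with value != 0, 0-based
#' half-open, in chromosome order.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  out <- character(0)
  for (chr in names(track$cov)) {
    r <- track$cov[[chr]]
    v <- S4Vectors::runValue(r)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    keep <- v != 0
    if (any(keep))
      out <- c(out, paste(chr,
                          format(starts[keep], scientific = FALSE, trim = TRUE),
                          format(ends[keep], scientific = FALSE, trim = TRUE),
                          format(v[keep], trim = TRUE), sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read library metadata
#'
#' @param path TSV with header; columns `library_id`, `assay`, `condition`,
#'   `replicate`, `role`, `total_reads` and, depending on assay,
#'   `spike_on_target_reads` (END-seq) or `spike_fraction` (DRIP).
#' @return data.frame, validated.
#' @export
read_library_info <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_library_info(df)
}

validate_library_info <- function(df) {
  need <- c("library_id", "assay", "condition", "replicate", "role", "total_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("library metadata missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$total_reads <= 0)) stop("total_reads must be > 0")
  if (!is.null(df$spike_on_target_reads) &&
      any(df$spike_on_target_reads < 0, na.rm = TRUE))
    stop("spike_on_target_reads must be >= 0")
  if (!is.null(df$spike_fraction)) {
    sf <- df$spike_fraction[!is.na(df$spike_fraction)]
    if (any(sf <= 0 | sf >= 1)) stop("spike_fraction must lie in (0, 1)")
  }
  df
}

#' Read / write a count matrix
#'
#' The on-disk form is a TSV with header: columns `chrom`, `start`, `end`,
#' `region_id`, then one integer column per library.
#'
#' @param path file path.
#' @param genome optional \link[GenomeInfoDb]{Seqinfo}.
#' @return list with `regions` (GRanges, `region_id` in `name`) and
#'   `counts` (integer matrix, rownames = region ids, colnames = library
#'   ids).
#' @export
read_count_matrix <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  regions <- make_intervals(df$chrom, df$start, df$end, genome = genome,
                            name = df$region_id)
  counts <- as.matrix(df[, setdiff(names(df), c("chrom", "start", "end", "region_id")),
                         drop = FALSE])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$region_id
  list(regions = regions, counts = counts)
}

#' @rdname read_count_matrix
#' @param regions GRanges with a `name` column of region ids.
#' @param counts integer matrix (regions x libraries).
#' @export
write_count_matrix <- function(regions, counts, path) {
  stopifnot(length(regions) == nrow(counts))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = start0(regions), end = end0(regions),
                   region_id = regions$name, check.names = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
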