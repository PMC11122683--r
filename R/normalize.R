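#' Spike-in and library-size scale factors
#'
#' For END-seq each library's raw factor is its on-target spike-in reads
#' (RiP) divided by its total quality-filtered reads (RQC); for DRIP-seq
#' it is the library's spike-in read fraction. Raw factors are rescaled
#' by the minimum within the experiment (so the smallest becomes exactly
#' 1), a library-size factor median(total)/total is computed, and the
#' final factor is their product. Normalized counts are raw counts
#' divided by the final factor, so a library with higher spike recovery
#' is deflated.
#'
#' @param libraries data.frame of library metadata (see
#'   [read_library_info()]).
#' @return data.frame with one row per library: `library_id`, `raw` (f),
#'   `spike` (s = f / min f), `libsize` (l = median(total)/total) and
#'   `final` (s * l).
#' @export
endseq_scale_factors <- function(libraries) {
  libraries <- validate_library_info(libraries)
  if (is.null(libraries$spike_on_target_reads) ||
      anyNA(libraries$spike_on_target_reads))
    stop("END-seq scaling needs spike_on_target_reads for every library")
  if (all(libraries$spike_on_target_reads == 0))
    stop("spike-in absent: all on-target spike-in read counts are zero")
  f <- libraries$spike_on_target_reads / libraries$total_reads
  scale_factor_set(libraries$library_id, f, libraries$total_reads)
}

#' @rdname endseq_scale_factors
#' @export
drip_scale_factors <- function(libraries) {
  libraries <- validate_library_info(libraries)
  if (is.null(libraries$spike_fraction) || anyNA(libraries$spike_fraction))
    stop("DRIP scaling needs spike_fraction for every library")
  scale_factor_set(libraries$library_id, libraries$spike_fraction,
                   libraries$total_reads)
}

scale_factor_set <- function(library_id, f, total_reads) {
  if (any(f <= 0))
    stop("raw spike factor must be > 0 for every library")
  s <- f / min(f)
  l <- stats::median(total_reads) / total_reads
  data.frame(library_id = library_id, raw = f, spike = s, libsize = l,
             final = s * l, row.names = NULL)
}

#' Apply scale factors to a count matrix
#'
#' @param counts matrix, regions x libraries (colnames = library ids).
#' @param factors data.frame from [endseq_scale_factors()] or
#'   [drip_scale_factors()].
#' @return numeric matrix of normalized counts (raw / final factor).
#' @export
normalize_counts <- function(counts, factors) {
  idx <- match(colnames(counts), factors$library_id)
  if (anyNA(idx))
    stop("no scale factor for library: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  sweep(counts, 2, factors$final[idx], "/")
}
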