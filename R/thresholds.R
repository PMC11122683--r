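#' Pipeline thresholds
#'
#' Bundles every statistical and geometric gate the pipeline uses.
#'
#' @param max_pair_gap maximum allowed gap (bp, exclusive) between a
#'   reverse peak end and its paired forward peak start; pairs at or above
#'   this distance are discarded. Default 150.
#' @param dsb_log2fc absolute log2 fold-change gate for END-seq
#'   differential enrichment. Default 1.
#' @param dsb_p p-value gate for END-seq differential enrichment and the
#'   RNase H filter. Default 0.05.
#' @param rloop_p p-value gate for DRIP-seq differential calls. Default
#'   0.01.
#' @param n_shuffles number of genome randomizations in overlap
#'   enrichment. Default 100.
#' @param pseudocount added to normalized counts before log2. Default 0.5.
#' @param d0 prior degrees of freedom of the moderated variance. Default 4.
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(max_pair_gap = 150, dsb_log2fc = 1, dsb_p = 0.05,
                             rloop_p = 0.01, n_shuffles = 100,
                             pseudocount = 0.5, d0 = 4) {
  cfg <- list(max_pair_gap = max_pair_gap, dsb_log2fc = dsb_log2fc,
              dsb_p = dsb_p, rloop_p = rloop_p, n_shuffles = n_shuffles,
              pseudocount = pseudocount, d0 = d0)
  num <- unlist(cfg)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all thresholds must be finite and strictly positive")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  class(cfg) <- "threshold_config"
  cfg
}
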