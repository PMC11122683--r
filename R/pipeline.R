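#' Match derived regions to count-matrix regions
#'
#' Each query region is assigned the count-matrix region it overlaps the
#' most (NA when it overlaps none). Used to connect consensus regions
#' derived from peak files to an externally provided count matrix.
#'
#' @param query GRanges.
#' @param regions GRanges of count-matrix rows.
#' @return integer vector of indices into `regions`, NA where unmatched.
#' @export
match_to_regions <- function(query, regions) {
  ov <- GenomicRanges::findOverlaps(query, regions, ignore.strand = TRUE)
  if (!length(ov)) return(rep(NA_integer_, length(query)))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(query)[qh], GenomicRanges::ranges(regions)[sh]))
  ord <- order(qh, -w)
  first <- !duplicated(qh[ord])
  out <- rep(NA_integer_, length(query))
  out[qh[ord][first]] <- sh[ord][first]
  out
}

#' END-seq analysis: pairing, consensus, differential, kinetics, seDSB
#'
#' Runs the full double-strand-break branch on strand-specific peaks plus
#' a count matrix: per-replicate reverse/forward pairing into clusters,
#' replicate consensus per condition, spike-in and library-size
#' normalization, moderated differential tests of each treatment
#' timepoint against the untreated control (enrichment gate
#' `log2FC > dsb_log2fc`, `p < dsb_p`, positive direction only), kinetic
#' classification (persistent / transient / late), and solitary-peak
#' single-ended DSB detection.
#'
#' @param peaks nested list `peaks[[condition]][[replicate]]` with
#'   elements `fwd` and `rev` (GRanges); conditions are the two treatment
#'   timepoints, earliest first.
#' @param count_regions GRanges of count-matrix regions (`name` column of
#'   region ids).
#' @param counts integer matrix regions x libraries.
#' @param libraries END-seq library metadata including the untreated
#'   (`NT`) libraries.
#' @param thresholds a [threshold_config()].
#' @return list with `classes` (GRanges per kinetic class),
#'   `unclassified`, `consensus` (per condition), `differential` (per
#'   condition, data.frame over count regions), `sedsb` (solitary peaks
#'   with per-contrast enrichment flags), `factors` and `log`.
#' @export
run_dsb_analysis <- function(peaks, count_regions, counts, libraries,
                             thresholds = threshold_config()) {
  conds <- names(peaks)
  if (length(conds) != 2)
    stop("expected exactly two treatment timepoints, got: ",
         paste(conds, collapse = ", "))
  log <- list()
  note <- function(stage, n_in, n_out)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)
  consensus <- list(); strand_cons <- list()
  for (cond in conds) {
    reps <- peaks[[cond]]
    if (length(reps) < 2)
      stop("condition ", cond, " has fewer than 2 replicates; ",
           "consensus requires 2")
    paired <- lapply(reps, function(p)
      pair_strand_peaks(p$rev, p$fwd, thresholds$max_pair_gap))
    note(paste0("pairing_", cond),
         sum(vapply(reps, function(p) length(p$rev), 0L)),
         sum(vapply(paired, length, 0L)))
    consensus[[cond]] <- consensus_clusters(paired[[1]], paired[[2]])
    note(paste0("consensus_", cond), sum(vapply(paired, length, 0L)),
         length(consensus[[cond]]))
    strand_cons[[cond]] <- list(
      fwd = consensus_clusters(reps[[1]]$fwd, reps[[2]]$fwd),
      rev = consensus_clusters(reps[[1]]$rev, reps[[2]]$rev))
  }
  factors <- endseq_scale_factors(libraries)
  norm <- normalize_counts(counts, factors)
  lib_of <- function(cond)
    libraries$library_id[libraries$condition == cond & libraries$role == "IP"]
  if (!length(lib_of("NT"))) stop("no untreated (NT) libraries in metadata")
  differential <- list(); enriched <- list()
  for (cond in conds) {
    res <- moderated_test(norm[, lib_of(cond), drop = FALSE],
                          norm[, lib_of("NT"), drop = FALSE],
                          d0 = thresholds$d0,
                          pseudocount = thresholds$pseudocount)
    state <- differential_state(res, thresholds$dsb_log2fc, thresholds$dsb_p)
    res$enriched <- state == "up"
    differential[[cond]] <- res
    idx <- match_to_regions(consensus[[cond]], count_regions)
    keep <- !is.na(idx) & res$enriched[idx]
    enriched[[cond]] <- consensus[[cond]][which(keep)]
    note(paste0("enriched_", cond), length(consensus[[cond]]),
         length(enriched[[cond]]))
  }
  classes <- classify_dsb_kinetics(enriched[[conds[1]]], enriched[[conds[2]]])
  note("kinetic_classes", sum(lengths(enriched)),
       sum(vapply(classes, length, 0L)))
  un_idx <- lapply(conds, function(cond) {
    hit <- GenomicRanges::countOverlaps(consensus[[cond]],
                                        c(enriched[[conds[1]]],
                                          enriched[[conds[2]]]),
                                        ignore.strand = TRUE)
    consensus[[cond]][hit == 0]
  })
  unclassified <- GenomicRanges::reduce(do.call(c, unname(un_idx)), ignore.strand = TRUE)

  # single-ended branch: per-strand consensus merged across timepoints
  fwd_cons <- GenomicRanges::reduce(
    do.call(c, unname(lapply(strand_cons, `[[`, "fwd"))), ignore.strand = TRUE)
  rev_cons <- GenomicRanges::reduce(
    do.call(c, unname(lapply(strand_cons, `[[`, "rev"))), ignore.strand = TRUE)
  mean_norm <- function(gr) {
    idx <- match_to_regions(gr, count_regions)
    out <- rep(NA_real_, length(gr))
    ok <- !is.na(idx)
    out[ok] <- rowMeans(norm[idx[ok], , drop = FALSE])
    out
  }
  sedsb <- detect_sedsb(fwd_cons, rev_cons,
                        counts = list(forward = mean_norm(fwd_cons),
                                      reverse = mean_norm(rev_cons)),
                        max_pair_gap = thresholds$max_pair_gap)
  note("sedsb_candidates", length(fwd_cons) + length(rev_cons), length(sedsb))
  if (length(sedsb)) {
    idx <- match_to_regions(sedsb, count_regions)
    for (cond in conds) {
      flag <- rep(FALSE, length(sedsb))
      flag[!is.na(idx)] <- differential[[cond]]$enriched[idx[!is.na(idx)]]
      S4Vectors::mcols(sedsb)[[paste0("enriched_", cond)]] <- flag
    }
    sedsb$persistent <- S4Vectors::mcols(sedsb)[[paste0("enriched_", conds[1])]] &
      S4Vectors::mcols(sedsb)[[paste0("enriched_", conds[2])]]
  }
  list(classes = classes, unclassified = unclassified, consensus = consensus,
       differential = differential, sedsb = sedsb, factors = factors,
       log = do.call(rbind, log))
}

#' DRIP-seq analysis: consensus, RNase H filter, seven-category kinetics
#'
#' Builds the consensus region universe from per-replicate peak sets,
#' normalizes counts by spike-in fraction and library size, removes
#' regions failing the RNase H true-positive filter, tests each treatment
#' timepoint against the untreated control, and assigns each surviving
#' region one of the seven kinetic categories (discordant regions are
#' reported separately).
#'
#' @param peaks nested list `peaks[[condition]][[replicate]]` of GRanges,
#'   conditions NT plus the two treatment timepoints (earliest first).
#' @param count_regions,counts count matrix as in [run_dsb_analysis()].
#' @param libraries DRIP library metadata; RNase H libraries carry role
#'   `RNaseH`.
#' @param thresholds a [threshold_config()].
#' @return list with `universe` (GRanges, with `rnaseh_pass` and
#'   `category`), `diff_early`, `diff_late`, `factors`, `table`
#'   (data.frame summary) and `log`.
#' @export
run_rloop_analysis <- function(peaks, count_regions, counts, libraries,
                               thresholds = threshold_config()) {
  if (!"NT" %in% names(peaks)) stop("untreated (NT) condition is required")
  treat <- setdiff(names(peaks), "NT")
  if (length(treat) != 2)
    stop("expected exactly two treatment timepoints, got: ",
         paste(treat, collapse = ", "))
  log <- list()
  note <- function(stage, n_in, n_out)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)
  universe <- consensus_regions(peaks)
  note("consensus_universe", sum(lengths(unlist(peaks, recursive = FALSE))),
       length(universe))
  factors <- drip_scale_factors(libraries)
  norm <- normalize_counts(counts, factors)
  idx <- match_to_regions(universe, count_regions)
  universe <- universe[!is.na(idx)]; idx <- idx[!is.na(idx)]
  lib_of <- function(cond, role = "IP")
    libraries$library_id[libraries$condition == cond & libraries$role == role]
  rh_libs <- libraries$library_id[libraries$role == "RNaseH"]
  if (length(rh_libs)) {
    pass <- rnaseh_filter(norm[idx, lib_of("NT"), drop = FALSE],
                          norm[idx, rh_libs, drop = FALSE],
                          d0 = thresholds$d0,
                          pseudocount = thresholds$pseudocount,
                          log2fc_min = thresholds$dsb_log2fc,
                          p_max = thresholds$dsb_p)
  } else {
    pass <- rnaseh_filter(norm[idx, lib_of("NT"), drop = FALSE], NULL)
  }
  universe$rnaseh_pass <- pass
  note("rnaseh_filter", length(pass), sum(pass))
  kept <- idx[pass]
  diff_early <- moderated_test(norm[kept, lib_of(treat[1]), drop = FALSE],
                               norm[kept, lib_of("NT"), drop = FALSE],
                               d0 = thresholds$d0,
                               pseudocount = thresholds$pseudocount)
  diff_late <- moderated_test(norm[kept, lib_of(treat[2]), drop = FALSE],
                              norm[kept, lib_of("NT"), drop = FALSE],
                              d0 = thresholds$d0,
                              pseudocount = thresholds$pseudocount)
  category <- classify_rloop_kinetics(diff_early, diff_late,
                                      rloop_p = thresholds$rloop_p)
  universe$category <- factor(NA, levels = rloop_categories())
  universe$category[pass] <- category
  note("classified", sum(pass), sum(!is.na(universe$category)))
  tab <- data.frame(region_id = rownames(counts)[kept],
                    chrom = as.character(GenomicRanges::seqnames(universe))[pass],
                    start = start0(universe)[pass], end = end0(universe)[pass],
                    log2fc_early = diff_early$log2fc, p_early = diff_early$p,
                    log2fc_late = diff_late$log2fc, p_late = diff_late$p,
                    category = as.character(category))
  list(universe = universe, diff_early = diff_early, diff_late = diff_late,
       factors = factors, table = tab, log = do.call(rbind, log))
}

#' Overlap-enrichment panel
#'
#' One [overlap_enrichment()] row per (query class, feature set) pair.
#'
#' @param query_sets,feature_sets named lists of GRanges.
#' @param genome \link[GenomeInfoDb]{Seqinfo}.
#' @param n_shuffles randomizations per cell (default 100).
#' @param seed optional integer; each cell uses a distinct derived seed.
#' @return data.frame with `query`, `features` and the enrichment columns.
#' @export
run_enrichment_panel <- function(query_sets, feature_sets, genome,
                                 n_shuffles = 100, seed = NULL) {
  rows <- list()
  cell <- 0L
  for (qn in names(query_sets)) for (fn in names(feature_sets)) {
    cell <- cell + 1L
    q <- query_sets[[qn]]
    if (!length(q)) next
    res <- overlap_enrichment(q, feature_sets[[fn]], genome,
                              n_shuffles = n_shuffles,
                              seed = if (is.null(seed)) NULL else seed + cell)
    rows[[length(rows) + 1L]] <- cbind(query = qn, features = fn, res)
  }
  do.call(rbind, rows)
}

#' Run the whole synthetic study end to end
#'
#' Simulates the dataset, runs the END-seq and DRIP-seq branches, the
#' enrichment panel of DSB kinetic classes over R-loop categories, and a
#' reference-point metaprofile, writing all result tables and BEDs under
#' `out_dir`. Fully deterministic for a fixed config seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param thresholds a [threshold_config()].
#' @return invisible list with `dataset`, `dsb`, `rloop`, `enrichment`.
#' @export
run_full_study <- function(config = simulation_config(), out_dir,
                           thresholds = threshold_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- simulate_dataset(config, out_dir = file.path(out_dir, "dataset"))
  genome <- dataset$genome
  end_libs <- dataset$libraries[dataset$libraries$assay == "ENDseq", ]
  dsb <- run_dsb_analysis(dataset$peaks$endseq,
                          dataset$counts$endseq$regions,
                          dataset$counts$endseq$counts,
                          end_libs, thresholds)
  drip_libs <- dataset$libraries[dataset$libraries$assay == "DRIP", ]
  rloop <- run_rloop_analysis(dataset$peaks$drip,
                              dataset$counts$drip$regions,
                              dataset$counts$drip$counts,
                              drip_libs, thresholds)
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, showWarnings = FALSE)
  for (cl in names(dsb$classes)) {
    gr <- dsb$classes[[cl]]
    if (length(gr)) gr$name <- rep(cl, length(gr))
    write_intervals(gr, file.path(res_dir, paste0("dsb_", cl, ".bed")),
                    genome = genome)
  }
  write_intervals(dsb$unclassified, file.path(res_dir, "dsb_unclassified.bed"),
                  genome = genome)
  if (length(dsb$sedsb))
    write_intervals(dsb$sedsb[dsb$sedsb$iq_retained],
                    file.path(res_dir, "sedsb.bed"), genome = genome)
  utils::write.table(rloop$table, file.path(res_dir, "rloop_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rl_sets <- split(GenomicRanges::granges(rloop$universe),
                   rloop$universe$category)
  rl_sets <- rl_sets[vapply(rl_sets, length, 0L) > 0]
  enrichment <- run_enrichment_panel(dsb$classes, rl_sets, genome,
                                     n_shuffles = thresholds$n_shuffles,
                                     seed = config$seed + 1000L)
  utils::write.table(enrichment, file.path(res_dir, "dsb_rloop_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  track_file <- file.path(out_dir, "dataset", "tracks",
                          sprintf("endseq_%s_rep1_fwd.bedgraph",
                                  names(dataset$peaks$endseq)[1]))
  profile <- NULL
  if (file.exists(track_file) && length(dsb$classes$persistent)) {
    trk <- read_signal_track(track_file, genome)
    profile <- metaprofile(trk, dsb$classes$persistent)
    utils::write.table(
      data.frame(bin = seq_along(profile$profile), mean = profile$profile),
      file.path(res_dir, "persistent_dsb_profile.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  logs <- rbind(cbind(branch = "dsb", dsb$log), cbind(branch = "rloop", rloop$log))
  utils::write.table(logs, file.path(res_dir, "stage_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(dataset = dataset, dsb = dsb, rloop = rloop,
                 enrichment = enrichment, profile = profile))
}
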