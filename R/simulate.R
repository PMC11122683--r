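#' Simulation configuration
#'
#' Defines the synthetic study: a small genome carrying planted
#' double-ended DSBs in three kinetic classes, single-ended DSBs as
#' solitary strand peaks, R-loop peaks in seven kinetic categories plus
#' RNase-H-insensitive decoys, and library metadata with spike-in and
#' depth perturbations that force normalization to matter.
#'
#' @param genome chromosome dictionary; default 3 chromosomes of 5 Mbp.
#' @param n_genes number of non-overlapping gene models.
#' @param n_dedsb_per_class planted double-ended DSBs per kinetic class
#'   (persistent, transient, late).
#' @param n_sedsb planted single-ended DSBs (solitary peaks enriched at
#'   both treatment timepoints).
#' @param n_solo_noise solitary peaks with flat counts (never enriched).
#' @param n_rloop_per_category planted R-loop peaks per kinetic category
#'   (applied to all seven).
#' @param decoy_fraction decoy (RNase-H-insensitive) R-loop peaks as a
#'   fraction of the true peaks.
#' @param planted_lfc planted |log2 fold change| of every enriched state.
#' @param nb_dispersion negative-binomial dispersion shared by all counts.
#' @param baseline_mean expected count of an unenriched region in an
#'   unperturbed library.
#' @param rloop_width_range R-loop peak width range in bp.
#' @param dsb_flank_peak_width width of each strand flank peak at a
#'   double-ended break.
#' @param dsb_gap_range range the break gap is drawn from; its upper end
#'   must stay below the pairing gate (150 bp) even after replicate
#'   jitter.
#' @param dsb_at_rloop_frac fraction of persistent double-ended DSBs
#'   planted at the position of a stable-gain R-loop peak (one break per
#'   peak), so that break/hybrid colocalization is present in the truth
#'   and the enrichment stage has signal to find.
#' @param spike_ratio spike-in genome proportion (1:1000 by default).
#' @param replicates biological replicates per condition.
#' @param nominal_depth nominal quality-filtered reads per library.
#' @param depth_jitter,efficiency_jitter half-width of the uniform
#'   perturbation of library depth and IP efficiency.
#' @param rnaseh_background expected RNase H library count at a true
#'   R-loop peak; decoys keep IP-level counts in the RNase H libraries.
#' @param gene_length_range gene span range in bp.
#' @param seed integer seed; identical config and seed give byte-identical
#'   output.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(genome = genome_spec(paste0("chr", 1:3), rep(5e6, 3)),
                              n_genes = 300,
                              n_dedsb_per_class = c(persistent = 100,
                                                    transient = 100, late = 100),
                              n_sedsb = 50,
                              n_solo_noise = 10,
                              n_rloop_per_category = 40,
                              decoy_fraction = 0.1,
                              dsb_at_rloop_frac = 0.3,
                              planted_lfc = 2,
                              nb_dispersion = 0.05,
                              baseline_mean = 100,
                              rloop_width_range = c(300, 800),
                              dsb_flank_peak_width = 300,
                              dsb_gap_range = c(0, 140),
                              spike_ratio = 0.001,
                              replicates = 2,
                              nominal_depth = 1e6,
                              depth_jitter = 0.3,
                              efficiency_jitter = 0.3,
                              rnaseh_background = baseline_mean / 10,
                              gene_length_range = c(5000, 20000),
                              seed = 1) {
  stopifnot(all(n_dedsb_per_class >= 0), n_sedsb >= 0, n_solo_noise >= 0,
            n_rloop_per_category >= 0, nb_dispersion > 0, baseline_mean > 0,
            replicates >= 1, spike_ratio > 0, spike_ratio < 1)
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (dsb_gap_range[2] >= 150 - 8)
    stop("dsb_gap_range upper bound must stay below the pairing gate ",
         "after replicate jitter")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Per-condition expected counts of a planted kinetic class
#'
#' Implements the class semantics: a stable gain changes at the early
#' treatment timepoint and persists at the late one, a transient gain
#' does not persist, a late gain appears only at the late timepoint;
#' losses mirror the gains with the inverse fold change. DSB classes are
#' the gain-only analogues over the 10 and 20 minute timepoints.
#'
#' @param class_label one of the seven R-loop categories (conditions NT,
#'   T5, T60) or a DSB class persistent / transient / late (conditions
#'   NT, T10, T20).
#' @param baseline untreated expected count m.
#' @param delta planted |log2 fold change| (default 2).
#' @return named numeric vector of expected counts per condition.
#' @examples
#' plant_kinetics("transient_gain", 100)  # c(NT = 100, T5 = 400, T60 = 100)
#' @export
plant_kinetics <- function(class_label, baseline, delta = 2) {
  up <- baseline * 2^delta
  dn <- baseline * 2^-delta
  m <- baseline
  rl <- list(
    stable_gain = c(m, up, up), stable_loss = c(m, dn, dn),
    transient_gain = c(m, up, m), transient_loss = c(m, dn, m),
    late_gain = c(m, m, up), late_loss = c(m, m, dn),
    no_change = c(m, m, m))
  dsb <- list(persistent = c(m, up, up), transient = c(m, up, m),
              late = c(m, m, up))
  if (class_label %in% names(rl))
    return(stats::setNames(rl[[class_label]], c("NT", "T5", "T60")))
  if (class_label %in% names(dsb))
    return(stats::setNames(dsb[[class_label]], c("NT", "T10", "T20")))
  stop("unknown kinetic class: ", class_label)
}

# Non-overlapping random feature centres, >= spacing apart, away from
# chromosome edges. Deterministic given the RNG state.
sample_positions <- function(genome, n, spacing = 3000, edge = 20000,
                             max_tries = 200) {
  if (n == 0)
    return(data.frame(chrom = character(0), center = numeric(0)))
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  if (sum(pmax(lens - 2 * edge, 0)) < n * spacing * 1.5)
    stop("infeasible packing: too many features for the genome length")
  placed <- stats::setNames(vector("list", length(chroms)), chroms)
  out_chrom <- character(n); out_center <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(length(chroms), 1, prob = lens)
      pos <- floor(stats::runif(1, edge, lens[ci] - edge))
      if (!length(placed[[ci]]) || min(abs(placed[[ci]] - pos)) >= spacing) {
        placed[[ci]] <- c(placed[[ci]], pos)
        out_chrom[i] <- chroms[ci]; out_center[i] <- pos
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible packing: could not place feature ", i)
  }
  data.frame(chrom = out_chrom, center = out_center)
}

sim_conditions <- function(assay) {
  if (assay == "ENDseq") c("NT", "T10", "T20") else c("NT", "T5", "T60")
}

# Conditions in which a planted feature produces a called peak. Untreated
# cells carry no breaks, so END-seq features only yield peaks in the
# treated condition(s) where they are active; R-loop peaks exist in all
# conditions.
dsb_peak_conditions <- function(class_label) {
  switch(class_label,
         persistent = , sedsb = , solo_noise = c("T10", "T20"),
         transient = "T10", late = "T20",
         stop("unknown DSB class: ", class_label))
}

#' Generate the full synthetic dataset
#'
#' Plants every feature of the study design, derives per-replicate
#' per-condition strand-specific peak intervals (with small replicate
#' jitter), coverage tracks consistent with the peaks, negative-binomial
#' count matrices whose expected values embed both the planted kinetics
#' and the library-specific scale factor (so normalization must undo
#' exactly what was planted), library metadata, gene models, and a truth
#' table. With `out_dir` set, everything is written to disk together with
#' a manifest; identical config and seed reproduce byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory.
#' @return list with elements `genome`, `truth`, `peaks`, `counts`,
#'   `libraries`, `genes`, `config` and (when written) `files`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  with_seed(config$seed, simulate_dataset_impl(config, out_dir))
}

simulate_dataset_impl <- function(config, out_dir) {
  genome <- config$genome
  reps <- seq_len(config$replicates)

  ## ---- feature table -------------------------------------------------
  dsb_classes <- rep(names(config$n_dedsb_per_class), config$n_dedsb_per_class)
  n_true_rloop <- 7 * config$n_rloop_per_category
  n_decoy <- round(config$decoy_fraction * n_true_rloop)
  rloop_classes <- c(rep(setdiff(rloop_categories(), "discordant"),
                         each = config$n_rloop_per_category),
                     rep("decoy", n_decoy))
  kinds <- c(rep("deDSB", length(dsb_classes)),
             rep("seDSB", config$n_sedsb),
             rep("solo_noise", config$n_solo_noise),
             rep("rloop", n_true_rloop), rep("decoy", n_decoy))
  classes <- c(dsb_classes,
               rep("sedsb", config$n_sedsb),
               rep("solo_noise", config$n_solo_noise),
               rloop_classes)
  n_feat <- length(kinds)
  pos <- sample_positions(genome, n_feat)
  w <- config$dsb_flank_peak_width
  truth <- data.frame(feature_id = sprintf("%s_%04d", kinds, seq_len(n_feat)),
                      kind = kinds, class = classes,
                      chrom = pos$chrom, center = pos$center,
                      strand = "*", start = NA_real_, end = NA_real_,
                      gap = NA_real_, stringsAsFactors = FALSE)
  is_dedsb <- kinds == "deDSB"
  truth$gap[is_dedsb] <- sample(seq(config$dsb_gap_range[1],
                                    config$dsb_gap_range[2]),
                                sum(is_dedsb), replace = TRUE)
  solo <- kinds %in% c("seDSB", "solo_noise")
  truth$strand[solo] <- sample(c("+", "-"), sum(solo), replace = TRUE)
  # colocalize a fraction of persistent breaks with stable-gain hybrids
  # (one break per hybrid peak; spacing to all other features is kept
  # because every feature centre is mutually separated)
  pers <- which(truth$kind == "deDSB" & truth$class == "persistent")
  sg <- which(truth$class == "stable_gain")
  k <- min(round(config$dsb_at_rloop_frac * length(pers)), length(sg))
  if (k > 0) {
    pick_d <- sample(pers, k)
    pick_r <- sample(sg, k)
    truth$center[pick_d] <- truth$center[pick_r]
    truth$chrom[pick_d] <- truth$chrom[pick_r]
  }
  is_rl <- kinds %in% c("rloop", "decoy")
  rl_w <- sample(seq(config$rloop_width_range[1], config$rloop_width_range[2]),
                 sum(is_rl), replace = TRUE)
  # planted spans: deDSB = reverse-peak start to forward-peak end
  truth$start[is_dedsb] <- truth$center[is_dedsb] -
    floor(truth$gap[is_dedsb] / 2) - w
  truth$end[is_dedsb] <- truth$center[is_dedsb] +
    ceiling(truth$gap[is_dedsb] / 2) + w
  truth$start[solo] <- truth$center[solo] - floor(w / 2)
  truth$end[solo] <- truth$start[solo] + w
  truth$start[is_rl] <- truth$center[is_rl] - floor(rl_w / 2)
  truth$end[is_rl] <- truth$start[is_rl] + rl_w
  lfc_of <- function(cls, cond_idx) {
    mu <- vapply(cls, function(cl)
      plant_kinetics(cl_or_flat(cl), 1, config$planted_lfc)[cond_idx], 0)
    log2(mu)
  }
  truth$lfc_t1 <- lfc_of(truth$class, 2L)
  truth$lfc_t2 <- lfc_of(truth$class, 3L)

  ## ---- library metadata with planted scale factors -------------------
  make_libs <- function(assay) {
    conds <- sim_conditions(assay)
    grid <- expand.grid(condition = conds, replicate = reps,
                        stringsAsFactors = FALSE)
    grid$role <- "IP"
    if (assay == "DRIP")
      grid <- rbind(grid, data.frame(condition = "NT", replicate = reps,
                                     role = "RNaseH"))
    n <- nrow(grid)
    depth <- round(config$nominal_depth *
                     stats::runif(n, 1 - config$depth_jitter,
                                  1 + config$depth_jitter))
    eff <- stats::runif(n, 1 - config$efficiency_jitter,
                        1 + config$efficiency_jitter)
    df <- data.frame(
      library_id = sprintf("%s_%s_rep%d", tolower(assay),
                           ifelse(grid$role == "RNaseH", "RH", grid$condition),
                           grid$replicate),
      assay = assay, condition = grid$condition, replicate = grid$replicate,
      role = grid$role, total_reads = depth,
      spike_on_target_reads = NA_real_, spike_fraction = NA_real_,
      stringsAsFactors = FALSE)
    if (assay == "ENDseq") {
      df$spike_on_target_reads <- pmax(1, round(depth * config$spike_ratio * eff))
    } else {
      df$spike_fraction <- config$spike_ratio * eff
    }
    df
  }
  end_libs <- make_libs("ENDseq")
  drip_libs <- make_libs("DRIP")
  end_factors <- endseq_scale_factors(end_libs)
  drip_factors <- drip_scale_factors(drip_libs)

  ## ---- count matrices ------------------------------------------------
  nb_counts <- function(region_idx, libs, factors) {
    mu_mat <- vapply(seq_len(nrow(libs)), function(i) {
      ci <- cond_index(libs$condition[i])
      f <- factors$final[match(libs$library_id[i], factors$library_id)]
      vapply(region_idx, function(r) {
        cl <- truth$class[r]
        if (libs$role[i] == "RNaseH") {
          base <- if (truth$kind[r] == "decoy") config$baseline_mean
                  else config$rnaseh_background
          return(base * f)
        }
        plant_kinetics(cl_or_flat(cl), config$baseline_mean,
                       config$planted_lfc)[ci] * f
      }, 0)
    }, numeric(length(region_idx)))
    cnt <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                 size = 1 / config$nb_dispersion),
                  nrow = length(region_idx))
    storage.mode(cnt) <- "integer"
    dimnames(cnt) <- list(truth$feature_id[region_idx], libs$library_id)
    cnt
  }
  end_idx <- which(truth$kind %in% c("deDSB", "seDSB", "solo_noise"))
  rl_idx <- which(truth$kind %in% c("rloop", "decoy"))
  end_regions <- make_intervals(truth$chrom[end_idx], truth$start[end_idx],
                                truth$end[end_idx],
                                strand = truth$strand[end_idx],
                                genome = genome,
                                name = truth$feature_id[end_idx])
  rl_regions <- make_intervals(truth$chrom[rl_idx], truth$start[rl_idx],
                               truth$end[rl_idx], genome = genome,
                               name = truth$feature_id[rl_idx])
  counts <- list(
    endseq = list(regions = end_regions,
                  counts = nb_counts(end_idx, end_libs, end_factors)),
    drip = list(regions = rl_regions,
                counts = nb_counts(rl_idx, drip_libs, drip_factors)))

  ## ---- per-replicate peak intervals and tracks -----------------------
  jit <- function(n, amp) sample(seq(-amp, amp), n, replace = TRUE)
  end_peaks <- list(); drip_peaks <- list()
  for (cond in c("T10", "T20")) {
    end_peaks[[cond]] <- list()
    idx_end_feat <- which(truth$kind %in% c("deDSB", "seDSB", "solo_noise"))
    for (r in reps) {
      act <- idx_end_feat[vapply(truth$class[idx_end_feat], function(cl)
        cond %in% dsb_peak_conditions(cl), TRUE)]
      ded <- act[truth$kind[act] == "deDSB"]
      sol <- act[truth$kind[act] != "deDSB"]
      s_r <- jit(length(ded), 4); s_f <- jit(length(ded), 4)
      rev_end <- truth$center[ded] - floor(truth$gap[ded] / 2) + s_r
      fwd_start <- truth$center[ded] + ceiling(truth$gap[ded] / 2) + s_f
      rev_gr <- make_intervals(truth$chrom[ded], rev_end - w, rev_end,
                               strand = "-", genome = genome,
                               name = truth$feature_id[ded])
      fwd_gr <- make_intervals(truth$chrom[ded], fwd_start, fwd_start + w,
                               strand = "+", genome = genome,
                               name = truth$feature_id[ded])
      s_s <- jit(length(sol), 4)
      sol_gr <- make_intervals(truth$chrom[sol], truth$start[sol] + s_s,
                               truth$end[sol] + s_s,
                               strand = truth$strand[sol], genome = genome,
                               name = truth$feature_id[sol])
      fwd_all <- c(fwd_gr, sol_gr[GenomicRanges::strand(sol_gr) == "+"])
      rev_all <- c(rev_gr, sol_gr[GenomicRanges::strand(sol_gr) == "-"])
      end_peaks[[cond]][[r]] <- list(fwd = sort_intervals(fwd_all),
                                     rev = sort_intervals(rev_all))
    }
  }
  for (cond in c("NT", "T5", "T60")) {
    drip_peaks[[cond]] <- list()
    for (r in reps) {
      s <- jit(length(rl_idx), 10)
      drip_peaks[[cond]][[r]] <- sort_intervals(
        make_intervals(truth$chrom[rl_idx], truth$start[rl_idx] + s,
                       truth$end[rl_idx] + s, genome = genome,
                       name = truth$feature_id[rl_idx]))
    }
  }

  ## ---- gene models ---------------------------------------------------
  gpos <- sample_positions(genome, config$n_genes,
                           spacing = config$gene_length_range[2] + 2000)
  glen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 config$n_genes, replace = TRUE)
  genes <- make_intervals(gpos$chrom, gpos$center,
                          pmin(gpos$center + glen,
                               GenomeInfoDb::seqlengths(genome)[gpos$chrom] - 1),
                          strand = sample(c("+", "-"), config$n_genes,
                                          replace = TRUE),
                          genome = genome,
                          gene_id = sprintf("gene_%04d", seq_len(config$n_genes)))
  genes <- sort_intervals(genes)

  truth$lfc_t1[truth$kind %in% c("decoy", "solo_noise")] <- 0
  truth$lfc_t2[truth$kind %in% c("decoy", "solo_noise")] <- 0
  dataset <- list(genome = genome, truth = truth,
                  peaks = list(endseq = end_peaks, drip = drip_peaks),
                  counts = counts,
                  libraries = rbind(end_libs, drip_libs),
                  scale_factors = list(endseq = end_factors, drip = drip_factors),
                  genes = genes, config = config)
  if (!is.null(out_dir)) dataset$files <- write_dataset(dataset, out_dir)
  dataset
}

# condition -> position in a plant_kinetics vector (NT, early, late)
cond_index <- function(cond) {
  switch(cond, NT = 1L, T10 = , T5 = 2L, T20 = , T60 = 3L,
         stop("unknown condition: ", cond))
}

# enriched classes drive the mean; flat features reuse the no-change vector
cl_or_flat <- function(cl) {
  if (cl %in% c("decoy", "solo_noise")) "no_change"
  else if (cl == "sedsb") "persistent"
  else cl
}

write_dataset <- function(dataset, out_dir) {
  dir.create(file.path(out_dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "counts"), showWarnings = FALSE)
  genome <- dataset$genome
  files <- character(0)
  put <- function(rel) { files <<- c(files, rel); file.path(out_dir, rel) }
  for (cond in names(dataset$peaks$endseq)) {
    for (r in seq_along(dataset$peaks$endseq[[cond]])) {
      pk <- dataset$peaks$endseq[[cond]][[r]]
      write_intervals(pk$fwd, put(sprintf("peaks/endseq_%s_rep%d_fwd.bed", cond, r)),
                      genome = genome)
      write_intervals(pk$rev, put(sprintf("peaks/endseq_%s_rep%d_rev.bed", cond, r)),
                      genome = genome)
      for (strand_name in c("fwd", "rev")) {
        gr <- pk[[strand_name]]
        mu1 <- plant_kinetics_lookup(dataset, gr$name, cond)
        trk <- GenomicRanges::granges(gr)
        GenomicRanges::strand(trk) <- "*"
        trk$score <- mu1 / 10
        write_signal_track(signal_track(trk, genome),
                           put(sprintf("tracks/endseq_%s_rep%d_%s.bedgraph",
                                       cond, r, strand_name)))
      }
    }
  }
  for (cond in names(dataset$peaks$drip)) {
    for (r in seq_along(dataset$peaks$drip[[cond]])) {
      write_intervals(dataset$peaks$drip[[cond]][[r]],
                      put(sprintf("peaks/drip_%s_rep%d.bed", cond, r)),
                      genome = genome)
    }
  }
  bg <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genome),
                               IRanges::IRanges(1, GenomeInfoDb::seqlengths(genome)),
                               score = 1)
  write_signal_track(signal_track(bg, genome), put("tracks/background.bedgraph"))
  write_count_matrix(dataset$counts$endseq$regions, dataset$counts$endseq$counts,
                     put("counts/endseq_counts.tsv"))
  write_count_matrix(dataset$counts$drip$regions, dataset$counts$drip$counts,
                     put("counts/drip_counts.tsv"))
  utils::write.table(dataset$libraries, put("libraries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, put("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  genes_out <- dataset$genes
  genes_out$name <- genes_out$gene_id
  write_intervals(genes_out, put("genes.bed"), genome = genome)
  paths <- file.path(out_dir, files)
  manifest <- list(
    tool = paste0("dsbrloop ", as.character(utils::packageVersion("dsbrloop"))),
    seed = dataset$config$seed,
    genome = as.list(stats::setNames(
      as.numeric(GenomeInfoDb::seqlengths(genome)),
      GenomeInfoDb::seqnames(genome))),
    files = as.list(stats::setNames(unname(tools::md5sum(paths)), files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  c(files, "manifest.yaml")
}

plant_kinetics_lookup <- function(dataset, feature_ids, cond) {
  idx <- match(feature_ids, dataset$truth$feature_id)
  ci <- cond_index(cond)
  vapply(idx, function(i)
    plant_kinetics(cl_or_flat(dataset$truth$class[i]),
                   dataset$config$baseline_mean,
                   dataset$config$planted_lfc)[ci], 0)
}

#' Load a simulated dataset from disk
#'
#' Reads back everything [simulate_dataset()] wrote: the genome is
#' reconstructed from the manifest, peak BEDs are reassembled into the
#' nested condition/replicate lists the pipeline functions expect, and
#' count matrices, library metadata, gene models and the truth table are
#' parsed from their TSV/BED forms.
#'
#' @param dir dataset directory containing `manifest.yaml`.
#' @return list with the same shape as the return of [simulate_dataset()]
#'   (minus `config` and `scale_factors`).
#' @export
read_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  genome <- genome_spec(names(man$genome), unlist(man$genome))
  libraries <- read_library_info(file.path(dir, "libraries.tsv"))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  counts <- list(
    endseq = read_count_matrix(file.path(dir, "counts", "endseq_counts.tsv"),
                               genome = genome),
    drip = read_count_matrix(file.path(dir, "counts", "drip_counts.tsv"),
                             genome = genome))
  peaks <- list(endseq = list(), drip = list())
  for (f in list.files(file.path(dir, "peaks"), pattern = "\\.bed$")) {
    parts <- strsplit(sub("\\.bed$", "", f), "_")[[1]]
    cond <- parts[2]; rep <- as.integer(sub("rep", "", parts[3]))
    stranded <- parts[1] == "endseq"
    gr <- read_intervals(file.path(dir, "peaks", f), expect_strand = stranded,
                         genome = genome)
    if (stranded) {
      if (is.null(peaks$endseq[[cond]])) peaks$endseq[[cond]] <- list()
      if (rep > length(peaks$endseq[[cond]]) ||
          is.null(peaks$endseq[[cond]][[rep]]))
        peaks$endseq[[cond]][[rep]] <- list()
      peaks$endseq[[cond]][[rep]][[parts[4]]] <- gr
    } else {
      if (is.null(peaks$drip[[cond]])) peaks$drip[[cond]] <- list()
      peaks$drip[[cond]][[rep]] <- gr
    }
  }
  genes <- read_intervals(file.path(dir, "genes.bed"), expect_strand = TRUE,
                          genome = genome)
  genes$gene_id <- genes$name
  list(genome = genome, truth = truth, peaks = peaks, counts = counts,
       libraries = libraries, genes = genes)
}

#' Planted-enrichment fixture for the overlap statistic
#'
#' Places non-overlapping features covering roughly `coverage` of the
#' genome and query intervals that fall inside a random feature with
#' probability `p_in` (uniform anywhere otherwise), so the expected
#' enrichment is known in closed form.
#'
#' @param genome \link[GenomeInfoDb]{Seqinfo}.
#' @param n_features,feature_width feature count and width; defaults give
#'   10 percent coverage of the default simulation genome.
#' @param n_query,query_width query count and width.
#' @param p_in probability a query is planted inside a feature.
#' @param seed optional integer seed.
#' @return list with GRanges `query` and `features`.
#' @export
simulate_enrichment_fixture <- function(genome, n_features = 150,
                                        feature_width = 10000, n_query = 200,
                                        query_width = 200, p_in = 0.8,
                                        seed = NULL) {
  with_seed(seed, {
    pos <- sample_positions(genome, n_features, spacing = feature_width + 2000)
    features <- make_intervals(pos$chrom, pos$center, pos$center + feature_width,
                               genome = genome)
    inside <- stats::runif(n_query) < p_in
    lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
    chroms <- GenomeInfoDb::seqnames(genome)
    q_chrom <- character(n_query); q_start <- numeric(n_query)
    host <- sample.int(n_features, n_query, replace = TRUE)
    for (i in seq_len(n_query)) {
      if (inside[i]) {
        f <- features[host[i]]
        q_chrom[i] <- as.character(GenomicRanges::seqnames(f))
        q_start[i] <- floor(stats::runif(1, start0(f),
                                         end0(f) - query_width))
      } else {
        ci <- sample.int(length(chroms), 1, prob = lens)
        q_chrom[i] <- chroms[ci]
        q_start[i] <- floor(stats::runif(1, 0, lens[ci] - query_width))
      }
    }
    list(query = make_intervals(q_chrom, q_start, q_start + query_width,
                                genome = genome),
         features = features)
  })
}
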