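#' Build a PWM from a consensus sequence
#'
#' Each motif position puts `match_prob` on the consensus base and spreads
#' the remainder uniformly over the other three bases.
#'
#' @param consensus DNA string (ACGT).
#' @param match_prob Probability of the consensus base per position.
#' @param name Motif name.
#' @param floor Pseudo-probability floor.
#' @return A `pwm`.
#' @export
consensus_pwm <- function(consensus, match_prob = 0.85, name = "sim_motif",
                          floor = 1e-4) {
  codes <- seq_codes(consensus)
  if (any(codes > 4L)) abort("consensus must contain only ACGT")
  m <- matrix((1 - match_prob) / 3, nrow = length(codes), ncol = 4)
  m[cbind(seq_along(codes), codes)] <- match_prob
  pwm(m, name = name, floor = floor)
}

#' Configuration of the synthetic fixture generator
#'
#' Defaults describe the package's reference toy dataset: a desk-scale
#' genome small enough for the full pipeline to run in minutes, with the
#' structural features of the real task — motif-carrying bound sites whose
#' chromatin is open in the bound cell type, open-but-unbound decoy
#' regions without a motif, partial sharing of sites between cell types,
#' and nested conservative/relaxed peak flavours.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_celltypes Number of simulated cell types.
#' @param n_sites Bound sites per cell type.
#' @param shared_fraction Fraction of each cell type's sites shared by all
#'   cell types.
#' @param n_decoys Open-but-unbound decoy regions (motif-free, open in
#'   every cell type).
#' @param motif_consensus Consensus of the planted motif.
#' @param motif_match_prob Per-position consensus probability used both to
#'   build the scanning PWM and to sample planted instances.
#' @param signal_height Mean accessibility fold-enrichment of an open
#'   region over background.
#' @param smooth_bp Moving-average smoothing window of the coverage track.
#' @param weak_site_fraction Fraction of bound sites with strongly reduced
#'   accessibility (hard positives).
#' @param background_gc Background G+C fraction of the genome.
#' @param chip_halfwidth_cons,chip_halfwidth_rel Half-widths of the
#'   conservative and relaxed ChIP peaks around a site summit.
#' @param dnase_halfwidth_cons,dnase_halfwidth_rel Same for accessibility
#'   peaks around open regions.
#' @param seed Default RNG seed of the generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 3, chrom_length = 200000, n_celltypes = 2,
                       n_sites = 80, shared_fraction = 0.5, n_decoys = 160,
                       motif_consensus = "TGACGTCATAGC",
                       motif_match_prob = 0.85, signal_height = 8,
                       smooth_bp = 150, weak_site_fraction = 0.1,
                       background_gc = 0.41,
                       chip_halfwidth_cons = 150, chip_halfwidth_rel = 200,
                       dnase_halfwidth_cons = 150, dnase_halfwidth_rel = 200,
                       seed = 20260925) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_celltypes = n_celltypes, n_sites = n_sites,
              shared_fraction = shared_fraction, n_decoys = n_decoys,
              motif_consensus = motif_consensus,
              motif_match_prob = motif_match_prob,
              signal_height = signal_height, smooth_bp = smooth_bp,
              weak_site_fraction = weak_site_fraction,
              background_gc = background_gc,
              chip_halfwidth_cons = chip_halfwidth_cons,
              chip_halfwidth_rel = chip_halfwidth_rel,
              dnase_halfwidth_cons = dnase_halfwidth_cons,
              dnase_halfwidth_rel = dnase_halfwidth_rel, seed = seed)
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length >= 5000,
            cfg$n_celltypes >= 1, cfg$n_sites >= 0, cfg$n_decoys >= 0,
            cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
            cfg$weak_site_fraction >= 0, cfg$weak_site_fraction <= 1,
            cfg$background_gc > 0, cfg$background_gc < 1)
  structure(cfg, class = "sim_config")
}

# clipped moving-average smoothing of a per-base vector
smooth_vector <- function(v, width) {
  if (width <= 1) return(v)
  cs <- cumsum(c(0, v))
  n <- length(v)
  h <- floor(width / 2)
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

peaks_around <- function(sites, halfwidth, prefix, size_lookup) {
  if (nrow(sites) == 0L) return(empty_peaks())
  start <- pmax(sites$pos - halfwidth, 0)
  end <- pmin(sites$pos + halfwidth, size_lookup[sites$chrom])
  out <- tibble(chrom = sites$chrom, start = start, end = end,
                name = sprintf("%s_%d", prefix, seq_len(nrow(sites))),
                score = 0L, strand = ".", signal_value = 1,
                p_value = -1, q_value = -1,
                summit = as.integer(sites$pos - start))
  arrange(out, .data$chrom, .data$start)
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Produces, deterministically for a given seed: a random genome with
#' planted motif instances at bound sites; per cell type a smoothed
#' accessibility fold-enrichment track with bumps at that cell type's
#' bound sites and at shared motif-free decoy regions; ChIP-seq peak lists
#' in nested conservative/relaxed flavours around bound sites; matching
#' accessibility peak lists around open regions; and the ground-truth site
#' table.  Sites not bound in a given cell type stay closed there, so
#' cross-cell-type hard negatives (motif present, chromatin closed) and
#' decoy hard negatives (chromatin open, motif absent) both exist.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed overriding `config$seed`.
#' @return A `sim_dataset`: list with `genome`, `sizes`, `pwm`,
#'   `celltypes` (per cell type: `chip_conservative`, `chip_relaxed`,
#'   `coverage`, `dnase_conservative`, `dnase_relaxed`), `truth` (tibble
#'   `chrom`, `pos`, `celltype`), `decoys` (tibble `chrom`, `pos`) and the
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  seed <- seed %||% config$seed
  with_local_seed(seed, function() {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    sizes <- chrom_sizes(setNames(rep(config$chrom_length, config$n_chroms),
                                  chroms))
    lu <- sizes_lookup(sizes)
    gc <- config$background_gc
    base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    genome <- setNames(vapply(chroms, function(ch) {
      paste(sample(BASES, config$chrom_length, replace = TRUE,
                   prob = base_probs), collapse = "")
    }, character(1)), chroms)

    # element slots: spaced positions so peaks never merge
    margin <- 600
    slot_step <- 800
    slots <- purrr::map_dfr(chroms, function(ch) {
      pos <- seq(margin, config$chrom_length - margin, by = slot_step)
      tibble(chrom = ch, pos = pos + sample(-150:150, length(pos),
                                            replace = TRUE))
    })
    n_shared <- round(config$shared_fraction * config$n_sites)
    n_specific <- config$n_sites - n_shared
    need <- n_shared + config$n_celltypes * n_specific + config$n_decoys
    if (need > nrow(slots)) {
      abort(sprintf("%d elements requested but only %d positions fit", need,
                    nrow(slots)))
    }
    pick <- slots[sample(nrow(slots), need), , drop = FALSE]
    shared <- pick[seq_len(n_shared), , drop = FALSE]
    rest <- if (n_shared > 0) pick[-seq_len(n_shared), , drop = FALSE] else pick
    celltype_names <- paste0("ct", seq_len(config$n_celltypes))
    specific <- list()
    for (k in seq_len(config$n_celltypes)) {
      take <- seq_len(n_specific) + (k - 1L) * n_specific
      specific[[celltype_names[k]]] <- rest[take, , drop = FALSE]
    }
    decoys <- rest[config$n_celltypes * n_specific + seq_len(config$n_decoys), ,
                   drop = FALSE]

    motif <- consensus_pwm(config$motif_consensus, config$motif_match_prob)
    all_sites <- bind_rows(c(list(shared = shared), specific), .id = "origin")
    # plant a sampled motif instance centred at every bound site
    m <- motif$length
    for (i in seq_len(nrow(all_sites))) {
      inst <- paste(vapply(seq_len(m), function(j) {
        sample(BASES, 1, prob = motif$prob[j, ])
      }, character(1)), collapse = "")
      at <- all_sites$pos[i] - floor(m / 2)
      ch <- all_sites$chrom[i]
      substr(genome[[ch]], at + 1L, at + m) <- inst
    }

    truth <- purrr::map_dfr(celltype_names, function(ctn) {
      bind_rows(shared, specific[[ctn]]) |>
        mutate(celltype = ctn)
    })
    celltypes <- list()
    for (ctn in celltype_names) {
      ct_sites <- truth[truth$celltype == ctn, c("chrom", "pos"), drop = FALSE]
      open <- bind_rows(ct_sites, decoys[, c("chrom", "pos")])
      n_open <- nrow(open)
      heights <- config$signal_height * exp(rnorm(n_open, 0, 0.35))
      weak <- c(runif(nrow(ct_sites)) < config$weak_site_fraction,
                rep(FALSE, nrow(decoys)))
      heights[weak] <- heights[weak] * 0.25
      cov <- lapply(lu, function(n) {
        # low non-negative background noise
        rgamma(n, shape = 1.5, scale = 0.2)
      })
      for (i in seq_len(n_open)) {
        ch <- open$chrom[i]
        lo <- max(open$pos[i] - 175, 0) + 1L
        hi <- min(open$pos[i] + 175, lu[[ch]])
        cov[[ch]][lo:hi] <- cov[[ch]][lo:hi] + heights[i]
      }
      cov <- lapply(cov, smooth_vector, width = config$smooth_bp)
      celltypes[[ctn]] <- list(
        chip_conservative = peaks_around(ct_sites, config$chip_halfwidth_cons,
                                         paste0(ctn, "_cons"), lu),
        chip_relaxed = peaks_around(ct_sites, config$chip_halfwidth_rel,
                                    paste0(ctn, "_rel"), lu),
        coverage = coverage_track(cov),
        dnase_conservative = peaks_around(open, config$dnase_halfwidth_cons,
                                          paste0(ctn, "_dnase_cons"), lu),
        dnase_relaxed = peaks_around(open, config$dnase_halfwidth_rel,
                                     paste0(ctn, "_dnase_rel"), lu)
      )
    }
    structure(list(genome = genome, sizes = sizes, pwm = motif,
                   celltypes = celltypes, truth = truth,
                   decoys = decoys[, c("chrom", "pos")], config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d chromosome(s) x %d bp, %d cell type(s), %d truth sites, %d decoys\n",
    length(x$genome), x$config$chrom_length, length(x$celltypes),
    nrow(x$truth), nrow(x$decoys)))
  invisible(x)
}

#' Write a simulated dataset to a directory of standard-format files
#'
#' Emits `genome.fa`, `chrom.sizes`, `motif.txt` and, per cell type,
#' `<ct>_chip_{conservative,relaxed}.narrowPeak`,
#' `<ct>_dnase.bedGraph`, `<ct>_dnase_{conservative,relaxed}.narrowPeak`,
#' plus `truth_sites.tsv`.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta_genome(sim$genome, file.path(dir, "genome.fa"))
  readr::write_lines(paste(sim$sizes$chrom, as.integer(sim$sizes$size),
                           sep = "\t"),
                     file.path(dir, "chrom.sizes"))
  write_pwm_matrix(sim$pwm, file.path(dir, "motif.txt"))
  for (ctn in names(sim$celltypes)) {
    ct <- sim$celltypes[[ctn]]
    write_narrowpeak(ct$chip_conservative,
                     file.path(dir, sprintf("%s_chip_conservative.narrowPeak", ctn)))
    write_narrowpeak(ct$chip_relaxed,
                     file.path(dir, sprintf("%s_chip_relaxed.narrowPeak", ctn)))
    write_coverage(ct$coverage, file.path(dir, sprintf("%s_dnase.bedGraph", ctn)))
    write_narrowpeak(ct$dnase_conservative,
                     file.path(dir, sprintf("%s_dnase_conservative.narrowPeak", ctn)))
    write_narrowpeak(ct$dnase_relaxed,
                     file.path(dir, sprintf("%s_dnase_relaxed.narrowPeak", ctn)))
  }
  readr::write_lines(
    c("chrom\tpos\tcelltype",
      paste(sim$truth$chrom, sim$truth$pos, sim$truth$celltype, sep = "\t")),
    file.path(dir, "truth_sites.tsv"))
  invisible(dir)
}

#' Per-bin feature table for one simulated cell type
#'
#' Accessibility, motif and simple sequence features combined, the feature
#' set the pipeline trains on.
#'
#' @param sim A `sim_dataset`.
#' @param celltype Cell type name.
#' @param bins A `bin_index`.
#' @param groups Feature-group toggles, see [accessibility_features()];
#'   `"motif"` and `"sequence"` additionally control those blocks.
#' @return Wide feature tibble keyed by `chrom`, `bin`.
#' @export
sim_features <- function(sim, celltype, bins,
                         groups = c("fold_enrichment", "long_range",
                                    "peak_based", "variation", "motif",
                                    "sequence")) {
  ct <- sim$celltypes[[celltype]]
  if (is.null(ct)) abort(sprintf("unknown cell type '%s'", celltype))
  others <- sim$celltypes[setdiff(names(sim$celltypes), celltype)]
  out <- accessibility_features(
    ct$coverage, bins,
    dnase_conservative = ct$dnase_conservative,
    dnase_relaxed = ct$dnase_relaxed,
    other_tracks = purrr::map(others, "coverage"),
    groups = intersect(groups, c("fold_enrichment", "long_range",
                                 "peak_based", "variation")))
  if ("motif" %in% groups) {
    out <- left_join(out, motif_features(sim$genome, list(sim$pwm), bins),
                     by = c("chrom", "bin"))
  }
  if ("sequence" %in% groups) {
    out <- left_join(out, sequence_features(sim$genome, bins),
                     by = c("chrom", "bin"))
  }
  out
}

#' Full pipeline on synthetic data with held-out evaluation
#'
#' Simulates a dataset, computes features, builds the initial training set
#' and runs iterative training for every cell type on the training
#' chromosomes, applies the resulting classifier ensemble to the target
#' cell type on the held-out chromosome, and evaluates against the known
#' labels.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed for the whole run.
#' @param holdout_chrom Held-out chromosome; default the last one.
#' @param target_celltype Cell type evaluated on the holdout; default the
#'   first.
#' @param n_rounds Iterative-training rounds per cell type.
#' @param feature_groups Feature-group toggles, see [sim_features()].
#' @return List with `eval` (a `binding_eval`), `track`, `peaks_relaxed`,
#'   `peaks_conservative`, `fits` (per cell type), `round1_eval`
#'   (ensemble of the initial classifiers only), `width_bins`, `sim`.
#' @export
end_to_end_check <- function(config = sim_config(), seed = 1,
                             holdout_chrom = NULL, target_celltype = NULL,
                             n_rounds = 5,
                             feature_groups = c("fold_enrichment",
                                                "long_range", "peak_based",
                                                "variation", "motif",
                                                "sequence")) {
  sim <- simulate_dataset(config, seed = seed)
  bins <- bin_genome(sim$sizes, 50)
  chroms <- sim$sizes$chrom
  holdout_chrom <- holdout_chrom %||% tail(chroms, 1)
  train_chroms <- setdiff(chroms, holdout_chrom)
  if (length(train_chroms) == 0L) abort("no training chromosomes left")
  target_celltype <- target_celltype %||% names(sim$celltypes)[1L]

  width_bins <- peak_width_bins(
    purrr::map(sim$celltypes, "chip_conservative"), bins$bin_width)
  windows <- enumerate_windows(bins)
  features <- purrr::imap(sim$celltypes, function(ct, ctn) {
    sim_features(sim, ctn, bins, groups = feature_groups)
  })

  fits <- purrr::imap(sim$celltypes, function(ct, ctn) {
    labels <- derive_labels(windows[windows$chrom %in% train_chroms, ],
                            ct$chip_conservative, ct$chip_relaxed)
    med <- bin_stats(ct$coverage, bins)[, c("chrom", "bin", "acc_median")]
    others <- purrr::map(sim$celltypes[setdiff(names(sim$celltypes), ctn)],
                         "chip_conservative")
    init <- initial_training_set(
      bins, filter_chroms(ct$chip_conservative, train_chroms),
      filter_chroms(ct$chip_relaxed, train_chroms),
      med, width_bins, other_conservative = purrr::map(others, filter_chroms,
                                                       train_chroms),
      seed = seed + 1000)
    iterative_train(features[[ctn]], bins, labels, init, width_bins,
                    n_rounds = n_rounds)
  })

  target_feat <- features[[target_celltype]]
  track <- predict_track(fits, target_feat, bins, width_bins,
                         chroms = holdout_chrom)
  round1 <- purrr::map(fits, function(f) f$models[[1L]])
  track1 <- predict_track(round1, target_feat, bins, width_bins,
                          chroms = holdout_chrom)
  ct <- sim$celltypes[[target_celltype]]
  holdout_labels <- derive_labels(windows[windows$chrom == holdout_chrom, ],
                                  ct$chip_conservative, ct$chip_relaxed)
  list(
    eval = evaluate_predictions(track, holdout_labels),
    round1_eval = evaluate_predictions(track1, holdout_labels),
    track = track,
    peaks_relaxed = call_peaks(track, 0.6, "relaxed"),
    peaks_conservative = call_peaks(track, 0.8, "conservative"),
    fits = fits, width_bins = width_bins, sim = sim,
    holdout_chrom = holdout_chrom, target_celltype = target_celltype
  )
}

filter_chroms <- function(peaks, chroms) {
  peaks[peaks$chrom %in% chroms, , drop = FALSE]
}
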