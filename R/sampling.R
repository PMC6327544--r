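# run fn with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# 0-based bin indices intersecting any of the peaks on one chromosome
bins_covered_by <- function(peaks_ch, nb, bin_width) {
  if (nrow(peaks_ch) == 0L || nb == 0L) return(integer())
  covered <- logical(nb)
  lo <- pmax(floor(peaks_ch$start / bin_width), 0)
  hi <- pmin(ceiling(peaks_ch$end / bin_width) - 1, nb - 1)
  for (i in seq_along(lo)) {
    if (hi[i] >= lo[i]) covered[(lo[i]:hi[i]) + 1L] <- TRUE
  }
  which(covered) - 1L
}

valid_center_range <- function(nb, width_bins) {
  h <- (width_bins - 1L) %/% 2L
  if (nb - 1L - h < h) integer() else h:(nb - 1L - h)
}

#' Positive training regions from conservative ChIP-seq peak summits
#'
#' One positive region per conservative peak, centred at the bin containing
#' the peak summit (the peak midpoint when no summit is annotated), with
#' weight 1.  Summit bins too close to a chromosome end to host a full
#' window are dropped.
#'
#' @param conservative Conservative ChIP-seq peak tibble.
#' @param bins A `bin_index`.
#' @param width_bins Odd window width in bins.
#' @return Training-region tibble with `chrom`, `bin`, `label`, `weight`,
#'   `provenance`.
#' @export
training_positives <- function(conservative, bins, width_bins) {
  if (nrow(conservative) == 0L) {
    return(tibble(chrom = character(), bin = integer(), label = character(),
                  weight = numeric(), provenance = character()))
  }
  summit_bp <- ifelse(conservative$summit >= 0,
                      conservative$start + conservative$summit,
                      floor((conservative$start + conservative$end) / 2))
  out <- tibble(chrom = conservative$chrom,
                bin = as.integer(floor(summit_bp / bins$bin_width)),
                label = "B", weight = 1, provenance = "positive")
  keep <- vapply(seq_len(nrow(out)), function(i) {
    nb <- bins$n_bins[[out$chrom[i]]]
    !is.null(nb) && out$bin[i] %in% valid_center_range(nb, width_bins)
  }, logical(1))
  out[keep, , drop = FALSE]
}

#' Uniformly sampled negative regions
#'
#' On each chromosome, samples `multiplier` times as many negative centre
#' bins as there are positives on that chromosome, uniformly without
#' replacement over all bins not covered by a relaxed peak of the target
#' cell type (sampling is stratified by chromosome).  Weight 1 each.
#'
#' @param bins A `bin_index`.
#' @param relaxed Relaxed ChIP-seq peak tibble of the target cell type/TF.
#' @param positives Positive-region tibble ([training_positives()]).
#' @param width_bins Odd window width in bins.
#' @param multiplier Negatives per positive (default 10).
#' @param seed Optional RNG seed for reproducibility.
#' @return Training-region tibble with provenance `"uniform"`.
#' @export
sample_uniform_negatives <- function(bins, relaxed, positives, width_bins,
                                     multiplier = 10, seed = NULL) {
  with_local_seed(seed, function() {
    purrr::map_dfr(names(bins$n_bins), function(ch) {
      n_pos <- sum(positives$chrom == ch)
      if (n_pos == 0L) return(NULL)
      nb <- bins$n_bins[[ch]]
      blocked <- bins_covered_by(relaxed[relaxed$chrom == ch, , drop = FALSE],
                                 nb, bins$bin_width)
      eligible <- setdiff(valid_center_range(nb, width_bins), blocked)
      want <- multiplier * n_pos
      if (length(eligible) < want) {
        warn(sprintf(
          "chromosome %s: only %d eligible bins for %d requested uniform negatives",
          ch, length(eligible), want))
      }
      take <- min(want, length(eligible))
      if (take == 0L) return(NULL)
      drawn <- sort(sample(eligible, take, replace = FALSE))
      tibble(chrom = ch, bin = as.integer(drawn), label = "U", weight = 1,
             provenance = "uniform")
    })
  })
}

# largest-remainder allocation of n draws proportional to target
allocate_draws <- function(target, n) {
  if (sum(target) == 0) target <- rep(1, length(target))
  raw <- n * target / sum(target)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Accessibility-matched, importance-weighted negative regions
#'
#' Over-samples negatives whose per-bin DNase median resembles the
#' positives' — the hard negatives that uniform sampling under-represents —
#' and down-weights them so that the weighted sample still represents the
#' eligible-negative population.  Eligible bins are split into
#' `n_strata` equal-population strata of the DNase bin median; draws are
#' allocated to strata following the positives' stratum distribution, and
#' each draw from stratum `g` gets the importance weight
#' `(N_g / N_neg) / (n_g / n_total)`.  Draws targeted at an empty stratum
#' are redistributed to the nearest non-empty strata with a warning.
#' Stratified by chromosome throughout.
#'
#' @param bins A `bin_index`.
#' @param relaxed Relaxed ChIP-seq peak tibble of the target cell type/TF.
#' @param positives Positive-region tibble.
#' @param bin_medians Tibble with `chrom`, `bin`, `acc_median` (from
#'   [bin_stats()]).
#' @param width_bins Odd window width in bins.
#' @param multiplier Negatives per positive (default 10).
#' @param n_strata Number of accessibility strata (default 10: deciles).
#' @param seed Optional RNG seed.
#' @return Training-region tibble with provenance `"dnase-matched"`.
#' @export
sample_dnase_matched_negatives <- function(bins, relaxed, positives,
                                           bin_medians, width_bins,
                                           multiplier = 10, n_strata = 10,
                                           seed = NULL) {
  with_local_seed(seed, function() {
    purrr::map_dfr(names(bins$n_bins), function(ch) {
      n_pos <- sum(positives$chrom == ch)
      if (n_pos == 0L) return(NULL)
      nb <- bins$n_bins[[ch]]
      med_ch <- bin_medians[bin_medians$chrom == ch, , drop = FALSE]
      med <- setNames(med_ch$acc_median, med_ch$bin)
      blocked <- bins_covered_by(relaxed[relaxed$chrom == ch, , drop = FALSE],
                                 nb, bins$bin_width)
      eligible <- setdiff(valid_center_range(nb, width_bins), blocked)
      if (length(eligible) == 0L) {
        warn(sprintf("chromosome %s: no eligible bins for matched negatives", ch))
        return(NULL)
      }
      ev <- med[as.character(eligible)]
      breaks <- unique(quantile(ev, probs = seq(0, 1, length.out = n_strata + 1)))
      if (length(breaks) < 2L) breaks <- c(-Inf, Inf)
      stratum_of <- function(v) {
        pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
             length(breaks) - 1L)
      }
      g_elig <- stratum_of(ev)
      n_groups <- length(breaks) - 1L
      N_g <- tabulate(g_elig, nbins = n_groups)
      pos_med <- med[as.character(positives$bin[positives$chrom == ch])]
      target <- tabulate(stratum_of(pos_med), nbins = n_groups)
      n_draw <- allocate_draws(target, multiplier * n_pos)
      # redistribute draws aimed at empty/underfull strata
      for (g in seq_len(n_groups)) {
        excess <- n_draw[g] - N_g[g]
        if (excess > 0) {
          if (N_g[g] == 0L) {
            warn(sprintf(
              "chromosome %s: accessibility stratum %d is empty; redistributing draws",
              ch, g))
          }
          n_draw[g] <- N_g[g]
          others <- order(abs(seq_len(n_groups) - g))
          for (o in others) {
            if (excess == 0) break
            room <- N_g[o] - n_draw[o]
            give <- min(room, excess)
            if (give > 0) {
              n_draw[o] <- n_draw[o] + give
              excess <- excess - give
            }
          }
        }
      }
      n_total <- sum(n_draw)
      if (n_total == 0L) return(NULL)
      drawn <- integer(); wts <- numeric()
      for (g in which(n_draw > 0)) {
        pick <- sample(eligible[g_elig == g], n_draw[g], replace = FALSE)
        w_g <- (N_g[g] / length(eligible)) / (n_draw[g] / n_total)
        drawn <- c(drawn, pick)
        wts <- c(wts, rep(w_g, n_draw[g]))
      }
      o <- order(drawn)
      tibble(chrom = ch, bin = as.integer(drawn[o]), label = "U",
             weight = wts[o], provenance = "dnase-matched")
    })
  })
}

#' Cross-cell-type negative regions
#'
#' Samples negatives from regions that are ChIP-seq positive in another
#' training cell type but do not overlap a relaxed peak of the current cell
#' type — regions that teach the classifier cell type-specific binding.
#' Four times as many regions as positives are drawn per chromosome,
#' uniformly weighted such that their weight sum equals the rate of such
#' regions among all putative negatives times the weight of the negatives
#' from the first two schemas.  Skipped (empty result) when no other cell
#' type exists; the single-cell-type pipeline mode always skips it.
#'
#' @param bins A `bin_index`.
#' @param other_conservative List of conservative ChIP-seq peak tibbles of
#'   the other training cell types (may be empty).
#' @param relaxed Relaxed peak tibble of the current cell type.
#' @param positives Positive-region tibble.
#' @param base_negatives Combined schema-1/2 negative tibble (weight
#'   anchor).
#' @param width_bins Odd window width in bins.
#' @param multiplier Negatives per positive (default 4).
#' @param seed Optional RNG seed.
#' @return Training-region tibble with provenance `"cross-celltype"`.
#' @export
sample_cross_celltype_negatives <- function(bins, other_conservative, relaxed,
                                            positives, base_negatives,
                                            width_bins, multiplier = 4,
                                            seed = NULL) {
  empty <- tibble(chrom = character(), bin = integer(), label = character(),
                  weight = numeric(), provenance = character())
  if (length(other_conservative) == 0L) return(empty)
  with_local_seed(seed, function() {
    out <- purrr::map_dfr(names(bins$n_bins), function(ch) {
      n_pos <- sum(positives$chrom == ch)
      if (n_pos == 0L) return(NULL)
      nb <- bins$n_bins[[ch]]
      other_bins <- sort(unique(unlist(lapply(other_conservative, function(pk) {
        bins_covered_by(pk[pk$chrom == ch, , drop = FALSE], nb, bins$bin_width)
      }))))
      blocked <- bins_covered_by(relaxed[relaxed$chrom == ch, , drop = FALSE],
                                 nb, bins$bin_width)
      valid <- valid_center_range(nb, width_bins)
      eligible <- setdiff(intersect(other_bins, valid), blocked)
      putative <- setdiff(valid, blocked)
      if (length(eligible) == 0L) {
        warn(sprintf("chromosome %s: no eligible cross-cell-type regions", ch))
        return(NULL)
      }
      want <- multiplier * n_pos
      take <- min(want, length(eligible))
      if (take < want) {
        warn(sprintf(
          "chromosome %s: only %d eligible bins for %d requested cross-cell-type negatives",
          ch, length(eligible), want))
      }
      drawn <- sort(sample(eligible, take, replace = FALSE))
      anchor <- sum(base_negatives$weight[base_negatives$chrom == ch])
      target_sum <- length(eligible) / max(length(putative), 1L) * anchor
      tibble(chrom = ch, bin = as.integer(drawn), label = "U",
             weight = target_sum / take, provenance = "cross-celltype")
    })
    if (nrow(out) == 0L) empty else out
  })
}

#' Assemble the initial weighted training set
#'
#' Positives at conservative-peak summits plus the negative-sampling
#' schemas: chromosome-stratified uniform sampling, accessibility-matched
#' importance sampling and (when other training cell types are available)
#' cross-cell-type sampling.
#'
#' @param bins A `bin_index`.
#' @param conservative,relaxed ChIP-seq peak tibbles of the target cell
#'   type/TF.  When `conservative` is empty, `relaxed` also defines the
#'   positives.
#' @param bin_medians Tibble with `chrom`, `bin`, `acc_median`.
#' @param width_bins Odd window width in bins.
#' @param other_conservative Optional list of other cell types'
#'   conservative peak tibbles.
#' @param seed Optional RNG seed.
#' @return Training-region tibble (`chrom`, `bin`, `label`, `weight`,
#'   `provenance`).
#' @export
initial_training_set <- function(bins, conservative, relaxed, bin_medians,
                                 width_bins, other_conservative = list(),
                                 seed = NULL) {
  pos_source <- if (nrow(conservative) > 0L) conservative else relaxed
  pos <- training_positives(pos_source, bins, width_bins)
  if (nrow(pos) == 0L) abort("no positive regions: cannot build a training set")
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  u <- sample_uniform_negatives(bins, relaxed, pos, width_bins,
                                seed = seeds[[1]])
  m <- sample_dnase_matched_negatives(bins, relaxed, pos, bin_medians,
                                      width_bins, seed = seeds[[2]])
  x <- sample_cross_celltype_negatives(bins, other_conservative, relaxed, pos,
                                       bind_rows(u, m), width_bins,
                                       seed = seeds[[3]])
  bind_rows(pos, u, m, x)
}
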