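#' Per-bin summary statistics of a coverage track
#'
#' Summarises the per-base fold-enrichment values of each bin as minimum,
#' maximum, mean and median — the base-pair-resolution signal reduced to the
#' classifier's 50-bp resolution.
#'
#' @param track A `coverage_track`.
#' @param bins A `bin_index` whose chromosomes are covered by `track`.
#' @return Tibble with `chrom`, `bin`, `acc_min`, `acc_max`, `acc_mean`,
#'   `acc_median`.
#' @export
bin_stats <- function(track, bins) {
  w <- bins$bin_width
  purrr::map_dfr(names(bins$n_bins), function(ch) {
    nb <- bins$n_bins[[ch]]
    if (nb == 0L) {
      return(tibble(chrom = character(), bin = integer(), acc_min = numeric(),
                    acc_max = numeric(), acc_mean = numeric(),
                    acc_median = numeric()))
    }
    v <- track[[ch]]
    if (is.null(v) || length(v) < nb * w) {
      abort(sprintf("coverage track does not span chromosome '%s'", ch))
    }
    m <- matrix(v[seq_len(nb * w)], nrow = w)
    tibble(
      chrom = ch, bin = 0:(nb - 1L),
      acc_min = apply(m, 2, min), acc_max = apply(m, 2, max),
      acc_mean = colMeans(m), acc_median = apply(m, 2, median)
    )
  })
}

#' Long-range accessibility features
#'
#' Mean fold-enrichment over broader windows of +/- `r` bins around each
#' bin, one feature per radius.  Windows are clipped at chromosome ends, so
#' the value is always the mean over the bins that exist.
#'
#' @param track A `coverage_track`.
#' @param bins A `bin_index`.
#' @param radii Integer bin radii (>= 1).
#' @return Tibble with `chrom`, `bin` and one `acc_lr_r<r>` column per
#'   radius.
#' @export
long_range_stats <- function(track, bins, radii = c(2, 10, 50)) {
  if (any(radii < 1)) abort("radii must be >= 1")
  w <- bins$bin_width
  purrr::map_dfr(names(bins$n_bins), function(ch) {
    nb <- bins$n_bins[[ch]]
    if (nb == 0L) return(tibble(chrom = character(), bin = integer()))
    mu <- colMeans(matrix(track[[ch]][seq_len(nb * w)], nrow = w))
    cs <- cumsum(c(0, mu))
    out <- tibble(chrom = ch, bin = 0:(nb - 1L))
    for (r in radii) {
      i <- seq_len(nb)
      lo <- pmax(i - r, 1L)
      hi <- pmin(i + r, nb)
      out[[sprintf("acc_lr_r%d", r)]] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    out
  })
}

#' Accessibility-peak overlap features
#'
#' For each bin and each accessibility peak flavour: a 0/1 overlap
#' indicator, the fraction of the bin covered by (merged) peaks, and the
#' distance in bp to the nearest peak (0 inside a peak, capped at
#' `distance_cap`; the cap is also used on peak-free chromosomes).
#'
#' @param bins A `bin_index`.
#' @param conservative,relaxed Accessibility peak tibbles.
#' @param distance_cap Distance cap in bp.
#' @return Tibble with `chrom`, `bin` and, per flavour `cons`/`rel`,
#'   `dnase_<flavour>_ind`, `_frac`, `_dist` columns.
#' @export
peak_features <- function(bins, conservative, relaxed, distance_cap = 10000) {
  flavours <- list(cons = conservative, rel = relaxed)
  w <- bins$bin_width
  purrr::map_dfr(names(bins$n_bins), function(ch) {
    nb <- bins$n_bins[[ch]]
    if (nb == 0L) return(tibble(chrom = character(), bin = integer()))
    out <- tibble(chrom = ch, bin = 0:(nb - 1L))
    br <- IRanges::IRanges(start = out$bin * w + 1L, width = w)
    for (fl in names(flavours)) {
      pk <- flavours[[fl]]
      pk <- pk[pk$chrom == ch, , drop = FALSE]
      frac <- numeric(nb); dist <- rep(distance_cap, nb)
      if (nrow(pk) > 0L) {
        pr <- IRanges::reduce(IRanges::IRanges(start = pk$start + 1L, end = pk$end))
        hit <- IRanges::findOverlaps(br, pr)
        if (length(hit) > 0L) {
          ov <- IRanges::width(IRanges::pintersect(
            br[S4Vectors::queryHits(hit)], pr[S4Vectors::subjectHits(hit)]))
          agg <- rowsum(ov, S4Vectors::queryHits(hit))
          frac[as.integer(rownames(agg))] <- agg[, 1] / w
        }
        ntn <- IRanges::distanceToNearest(br, pr)
        dist[S4Vectors::queryHits(ntn)] <-
          pmin(S4Vectors::mcols(ntn)$distance, distance_cap)
      }
      out[[sprintf("dnase_%s_ind", fl)]] <- as.numeric(frac > 0)
      out[[sprintf("dnase_%s_frac", fl)]] <- frac
      out[[sprintf("dnase_%s_dist", fl)]] <- dist
    }
    out
  })
}

#' Cross-cell-type variation of accessibility
#'
#' Population standard deviation and coefficient of variation of the
#' per-bin mean fold-enrichment across cell types.  Requires at least two
#' tracks; with fewer the features are absent (the single-cell-type mode of
#' the streamlined pipeline skips every step that evaluates several cell
#' types jointly).
#'
#' @param tracks Named list of `coverage_track`s, one per cell type.
#' @param bins A `bin_index`.
#' @param eps Stabiliser in the denominator of the CV.
#' @return Tibble with `chrom`, `bin`, `acc_sd`, `acc_cv`, or with no
#'   feature columns when fewer than two tracks are given.
#' @export
variation_features <- function(tracks, bins, eps = 1e-6) {
  base <- bin_tibble(bins)[, c("chrom", "bin")]
  if (length(tracks) < 2L) return(base)
  means <- purrr::map(tracks, function(tr) bin_stats(tr, bins)$acc_mean)
  m <- do.call(cbind, means)
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  base$acc_sd <- sdev
  base$acc_cv <- sdev / (mu + eps)
  base
}

#' All chromatin-accessibility features for one cell type
#'
#' Convenience wrapper joining [bin_stats()], [long_range_stats()],
#' [peak_features()] (when peak lists are supplied) and
#' [variation_features()] (when tracks for other cell types are supplied)
#' into one wide per-bin feature table.  Feature groups can be toggled to
#' reproduce ablations.
#'
#' @param track `coverage_track` of the target cell type.
#' @param bins A `bin_index`.
#' @param dnase_conservative,dnase_relaxed Optional accessibility peak
#'   tibbles.
#' @param other_tracks Optional named list of `coverage_track`s for other
#'   cell types (enables the variation group).
#' @param radii Bin radii for the long-range group.
#' @param distance_cap Distance cap in bp for the peak group.
#' @param groups Character subset of
#'   `c("fold_enrichment", "long_range", "peak_based", "variation")`.
#' @return Wide tibble keyed by `chrom`, `bin`.
#' @export
accessibility_features <- function(track, bins, dnase_conservative = NULL,
                                   dnase_relaxed = NULL, other_tracks = NULL,
                                   radii = c(2, 10, 50), distance_cap = 10000,
                                   groups = c("fold_enrichment", "long_range",
                                              "peak_based", "variation")) {
  out <- bin_tibble(bins)[, c("chrom", "bin")]
  if ("fold_enrichment" %in% groups) {
    out <- left_join(out, bin_stats(track, bins), by = c("chrom", "bin"))
  }
  if ("long_range" %in% groups) {
    out <- left_join(out, long_range_stats(track, bins, radii),
                     by = c("chrom", "bin"))
  }
  if ("peak_based" %in% groups && !is.null(dnase_conservative) &&
      !is.null(dnase_relaxed)) {
    out <- left_join(out,
                     peak_features(bins, dnase_conservative, dnase_relaxed,
                                   distance_cap),
                     by = c("chrom", "bin"))
  }
  if ("variation" %in% groups && !is.null(other_tracks) &&
      length(other_tracks) >= 1L) {
    out <- left_join(out,
                     variation_features(c(list(target = track), other_tracks),
                                        bins),
                     by = c("chrom", "bin"))
  }
  out
}

#' Write a per-bin feature table in sparse long TSV
#'
#' Zero feature values are omitted; `.gz` paths are compressed.
#'
#' @param features Wide feature tibble keyed by `chrom`, `bin`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  long <- tidyr::pivot_longer(features, cols = -c("chrom", "bin"),
                              names_to = "feature", values_to = "value")
  long <- filter(long, .data$value != 0)
  readr::write_lines(paste(long$chrom, long$bin, long$feature,
                           fmt_num(long$value), sep = "\t"), path)
  invisible(path)
}

#' Read a sparse feature table written by [write_features()]
#'
#' @param path Sparse TSV path.
#' @param bins Optional `bin_index`; when given, bins whose features were
#'   all zero are restored as explicit zero rows.
#' @return Wide feature tibble keyed by `chrom`, `bin`.
#' @export
read_features <- function(path, bins = NULL) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "bin", "feature", "value"),
                         col_types = "cicd", progress = FALSE)
  wide <- tidyr::pivot_wider(tab, names_from = "feature",
                             values_from = "value", values_fill = 0)
  if (!is.null(bins)) {
    full <- bin_tibble(bins)[, c("chrom", "bin")]
    wide <- left_join(full, wide, by = c("chrom", "bin"))
    wide <- mutate(wide, across(-c("chrom", "bin"), ~ tidyr::replace_na(.x, 0)))
  }
  arrange(wide, .data$chrom, .data$bin)
}
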