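#' Per-bin summit posteriors for one classifier
#'
#' Applies a trained classifier to every representable centre bin and
#' returns `P_i`, the posterior that bin `i` contains a peak summit.  Edge
#' bins whose window does not fit inside the chromosome get `P = 0` (they
#' cannot be scored and contribute nothing to window probabilities).
#'
#' @param model An `mcl_model`.
#' @param features Wide per-bin feature tibble.
#' @param bins A `bin_index`.
#' @param width_bins Odd window width in bins.
#' @param chroms Optional chromosome subset.
#' @return Tibble with `chrom`, `bin`, `p`, complete over all bins of the
#'   selected chromosomes.
#' @export
bin_posteriors <- function(model, features, bins, width_bins, chroms = NULL) {
  fw <- feature_window_matrix(features, bins, width_bins, chroms = chroms)
  use_chroms <- chroms %||% names(bins$n_bins)
  full <- purrr::map_dfr(use_chroms, function(ch) {
    nb <- bins$n_bins[[ch]]
    if (nb == 0L) return(tibble(chrom = character(), bin = integer()))
    tibble(chrom = ch, bin = 0:(nb - 1L))
  })
  full$p <- 0
  if (nrow(fw$centers) > 0L) {
    pv <- posterior(model, fw$x)
    key_full <- paste(full$chrom, full$bin)
    key_ctr <- paste(fw$centers$chrom, fw$centers$bin)
    full$p[match(key_ctr, key_full)] <- pv
  }
  full
}

#' Window overlap probability from per-bin posteriors
#'
#' The probability `S_i` that the window starting at bin `i` overlaps a
#' predicted peak by at least `overlap_bins` bins is the complement of the
#' product of `1 - P_l` over all centre bins `l` whose putative peak
#' (`width_bins` bins centred at `l`) overlaps the window sufficiently.
#' For `width_bins = 5` and a 4-bin window that set is `i-1 ... i+4`.
#' Out-of-range bins contribute `P = 0`.
#'
#' @param p Numeric vector of per-bin posteriors for one chromosome
#'   (bin 0 first).
#' @param width_bins Odd peak width in bins (`W`).
#' @param window_bins Window width in bins (default 4, i.e. 200 bp).
#' @param overlap_bins Minimum peak/window overlap in bins (default 2,
#'   i.e. 100 bp).
#' @return Numeric vector of `S_i` for window start bins
#'   `0 ... length(p) - window_bins`.
#' @export
window_probability <- function(p, width_bins, window_bins = 4L,
                               overlap_bins = 2L) {
  if (width_bins %% 2 != 1) abort("width_bins must be odd")
  nb <- length(p)
  if (nb < window_bins) return(numeric())
  h <- (width_bins - 1L) %/% 2L
  starts <- 0:(nb - window_bins)
  # a peak of width_bins bins can never overlap by more bins than it spans
  if (overlap_bins > min(width_bins, window_bins)) {
    return(rep(0, length(starts)))
  }
  # centre bins l with overlap(l-h..l+h, i..i+wb-1) >= overlap_bins
  offsets <- (overlap_bins - h - 1L):(window_bins - overlap_bins + h)
  q <- rep(1, length(starts))
  for (off in offsets) {
    l <- starts + off
    pl <- ifelse(l >= 0L & l < nb, p[pmax(l, 0L) + 1L], 0)
    q <- q * (1 - pl)
  }
  1 - q
}

#' Genome-wide window score track for a classifier ensemble
#'
#' Computes `P_i` for each classifier, converts them to window
#' probabilities `S_i` on the 200-bp/50-bp prediction grid, and averages
#' the `S` values per window across classifiers.
#'
#' @param models An `mcl_model`, a list of them, or an `iterative_fit`.
#' @param features Wide per-bin feature tibble.
#' @param bins A `bin_index`.
#' @param width_bins Odd peak width in bins.
#' @param chroms Optional chromosome subset.
#' @return A `prob_track` tibble with `chrom`, `start`, `end`, `s`.
#' @export
predict_track <- function(models, features, bins, width_bins, chroms = NULL) {
  models <- as_model_list(models)
  tracks <- purrr::map(models, function(m) {
    pb <- bin_posteriors(m, features, bins, width_bins, chroms)
    track_from_posteriors(pb, bins, width_bins)
  })
  ensemble_average(tracks)
}

as_model_list <- function(models) {
  if (inherits(models, "mcl_model")) return(list(models))
  if (inherits(models, "iterative_fit")) return(models$models)
  if (is.list(models)) {
    flat <- unlist(lapply(models, function(m) {
      if (inherits(m, "iterative_fit")) m$models else list(m)
    }), recursive = FALSE)
    if (!all(vapply(flat, inherits, logical(1), "mcl_model"))) {
      abort("models must be mcl_model or iterative_fit objects")
    }
    return(flat)
  }
  abort("models must be mcl_model or iterative_fit objects")
}

# bin posterior tibble -> window score track
track_from_posteriors <- function(pb, bins, width_bins, window = 200) {
  w <- bins$bin_width
  wb <- as.integer(window / w)
  out <- purrr::map_dfr(unique(pb$chrom), function(ch) {
    p <- pb$p[pb$chrom == ch]
    s <- window_probability(p, width_bins, window_bins = wb)
    if (length(s) == 0L) {
      return(tibble(chrom = character(), start = numeric(),
                    end = numeric(), s = numeric()))
    }
    starts <- (seq_along(s) - 1) * w
    tibble(chrom = ch, start = starts, end = starts + window, s = s)
  })
  class(out) <- c("prob_track", class(out))
  out
}

#' Average window score tracks of several classifiers
#'
#' @param tracks List of `prob_track` tibbles on identical window grids.
#' @return A `prob_track` with the per-window arithmetic mean of `s`.
#' @export
ensemble_average <- function(tracks) {
  if (length(tracks) == 0L) abort("no tracks to average")
  ref <- tracks[[1L]]
  for (tr in tracks[-1L]) {
    if (!identical(tr$chrom, ref$chrom) || !identical(tr$start, ref$start)) {
      abort("window grids of the tracks differ")
    }
  }
  s <- rowMeans(do.call(cbind, purrr::map(tracks, "s")))
  out <- ref
  out$s <- s
  out
}

#' Call peaks from a window score track
#'
#' Joins contiguous runs of windows with score above threshold `t`,
#' records the maximum probability `p` of the run, trims bordering windows
#' with score below `0.8 * p` from both ends (never removing the maximal
#' window), and emits narrowPeak records with the summit at the centre of
#' the maximal window (leftmost on ties), score `-100 * log10(1 - p)`
#' (probability capped at `1 - 1e-8`, score clamped to 0..1000) and signal
#' value `p`.  `t = 0.6` gives relaxed and `t = 0.8` conservative calls.
#'
#' @param track A `prob_track`.
#' @param t Probability threshold in (0, 1).
#' @param name_prefix Stem for peak names.
#' @return Peak tibble in narrowPeak column layout.
#' @export
call_peaks <- function(track, t, name_prefix = "peak") {
  if (t <= 0 || t >= 1) abort("t must be in (0, 1)")
  step <- if (nrow(track) >= 2L) {
    d <- diff(track$start[track$chrom == track$chrom[1L]])
    if (length(d) > 0L) min(d) else 50
  } else 50
  window <- if (nrow(track) > 0L) track$end[1L] - track$start[1L] else 200
  recs <- list()
  for (ch in unique(track$chrom)) {
    tc <- track[track$chrom == ch, , drop = FALSE]
    tc <- arrange(tc, .data$start)
    above <- tc$s > t
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      lo <- starts[k]; hi <- ends[k]
      # runs must be contiguous on the window grid
      seg <- lo:hi
      brk <- which(diff(tc$start[seg]) != step)
      segs <- if (length(brk) == 0L) list(seg) else {
        split(seg, cumsum(c(0, as.integer(diff(tc$start[seg]) != step))))
      }
      for (sg in segs) {
        s_run <- tc$s[sg]
        pmaxv <- max(s_run)
        cutoff <- 0.8 * pmaxv
        a <- 1L; b <- length(sg)
        while (a < b && s_run[a] < cutoff) a <- a + 1L
        while (b > a && s_run[b] < cutoff) b <- b - 1L
        kept <- sg[a:b]
        imax <- kept[which.max(tc$s[kept])]
        pstart <- tc$start[kept[1L]]
        pend <- tc$start[kept[length(kept)]] + window
        pcap <- min(pmaxv, 1 - 1e-8)
        score <- max(0L, min(1000L, as.integer(round(-100 * log10(1 - pcap)))))
        recs[[length(recs) + 1L]] <- tibble(
          chrom = ch, start = pstart, end = pend,
          name = NA_character_, score = score, strand = ".",
          signal_value = pmaxv, p_value = -1, q_value = -1,
          summit = as.integer(tc$start[imax] + window / 2 - pstart)
        )
      }
    }
  }
  if (length(recs) == 0L) return(empty_peaks())
  out <- bind_rows(recs)
  out <- arrange(out, .data$chrom, .data$start)
  out$name <- sprintf("%s_%d", name_prefix, seq_len(nrow(out)))
  out
}

#' Write a window score track as bedGraph at bin resolution
#'
#' Each 200-bp window's score is written on its leading 50-bp step
#' interval, the challenge's track convention.
#'
#' @param track A `prob_track`.
#' @param path Output path (`.gz` for gzip).
#' @param step Step of the window grid in bp.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, step = 50) {
  readr::write_lines(paste(track$chrom, as.integer(track$start),
                           as.integer(track$start + step),
                           fmt_num(track$s), sep = "\t"), path)
  invisible(path)
}

#' Read a window score track written by [write_track()]
#' @param path bedGraph path.
#' @param window Window width in bp.
#' @return A `prob_track` tibble.
#' @export
read_track <- function(path, window = 200) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "start", "step_end", "s"),
                         col_types = "cddd", progress = FALSE)
  out <- tibble(chrom = tab$chrom, start = tab$start,
                end = tab$start + window, s = tab$s)
  class(out) <- c("prob_track", class(out))
  out
}

#' @export
autoplot.prob_track <- function(object, t = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$s)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "window start (bp)", y = "binding probability S") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(t)) {
    p <- p + ggplot2::geom_hline(yintercept = t, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
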