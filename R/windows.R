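#' Assemble classifier input windows from a per-bin feature table
#'
#' A training/prediction region is the concatenation of all per-bin
#' features over `width_bins` (odd) adjacent bins centred on a candidate
#' summit bin.  Feature columns are suffixed `@<offset>` with offsets
#' `-h ... h`, `h = (width_bins - 1) / 2`.  Only centre bins whose full
#' window lies inside the chromosome are representable; others are dropped.
#'
#' @param features Wide per-bin feature tibble keyed by `chrom`, `bin`
#'   (complete and 0-based contiguous per chromosome).
#' @param bins A `bin_index`.
#' @param width_bins Odd window width in bins (`W`).
#' @param centers Optional tibble with `chrom`, `bin` of requested centre
#'   bins; default all valid bins.
#' @param chroms Optional chromosome subset.
#' @return List with `centers` (tibble `chrom`, `bin`, in output row order)
#'   and `x` (numeric matrix, one row per centre).
#' @export
feature_window_matrix <- function(features, bins, width_bins, centers = NULL,
                                  chroms = NULL) {
  if (width_bins %% 2 != 1 || width_bins < 1) {
    abort("width_bins must be an odd positive integer")
  }
  h <- (width_bins - 1L) %/% 2L
  feat_cols <- setdiff(colnames(features), c("chrom", "bin"))
  features <- arrange(features, .data$chrom, .data$bin)
  use_chroms <- chroms %||% names(bins$n_bins)
  out_centers <- list(); out_x <- list()
  for (ch in use_chroms) {
    nb <- bins$n_bins[[ch]]
    fch <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(fch) != nb || (nb > 0L && !identical(fch$bin, 0:(nb - 1L)))) {
      abort(sprintf("feature table is not complete/contiguous on '%s'", ch))
    }
    lo <- h; hi <- nb - 1L - h
    if (hi < lo) next
    ctr <- if (is.null(centers)) lo:hi else {
      cc <- sort(unique(centers$bin[centers$chrom == ch]))
      cc[cc >= lo & cc <= hi]
    }
    if (length(ctr) == 0L) next
    M <- as.matrix(fch[, feat_cols, drop = FALSE])
    blocks <- lapply(-h:h, function(off) {
      B <- M[ctr + off + 1L, , drop = FALSE]
      colnames(B) <- sprintf("%s@%d", feat_cols, off)
      B
    })
    out_centers[[ch]] <- tibble(chrom = ch, bin = as.integer(ctr))
    out_x[[ch]] <- do.call(cbind, blocks)
  }
  if (length(out_x) == 0L) {
    return(list(centers = tibble(chrom = character(), bin = integer()),
                x = matrix(numeric(), nrow = 0, ncol = 0)))
  }
  list(centers = bind_rows(out_centers), x = do.call(rbind, out_x))
}

#' Default family assignment for window feature columns
#'
#' Peak-overlap indicator features (`*_ind@*`) are Bernoulli; everything
#' else is Gaussian.
#'
#' @param colnames Column names of a window feature matrix.
#' @return Named character vector usable as `families` in [train_mcl()].
#' @export
window_families <- function(colnames) {
  fam <- ifelse(grepl("_ind@", colnames, fixed = TRUE), "bernoulli", "gaussian")
  setNames(fam, colnames)
}
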