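#' Partition a genome into fixed-width bins
#'
#' Tiles every chromosome with non-overlapping, contiguous bins of
#' `bin_width` bp (default 50, the native resolution of the classifier).
#' A trailing partial bin is dropped, so each chromosome contributes
#' `floor(size / bin_width)` bins.  Bin `i` (0-based) covers
#' `[i * bin_width, (i + 1) * bin_width)`.
#'
#' @param sizes Chromosome-length tibble ([chrom_sizes()]).
#' @param bin_width Bin width in bp (>= 1).
#' @return A `bin_index` object.
#' @examples
#' bins <- bin_genome(chrom_sizes(c(chrA = 230)), bin_width = 50)
#' n_bins(bins, "chrA")  # 4: trailing 30 bp dropped
#' @export
bin_genome <- function(sizes, bin_width = 50) {
  if (length(bin_width) != 1L || bin_width < 1 || bin_width != round(bin_width)) {
    abort("bin_width must be a positive integer")
  }
  nb <- setNames(floor(sizes$size / bin_width), sizes$chrom)
  structure(list(bin_width = as.integer(bin_width), n_bins = nb),
            class = "bin_index")
}

#' @export
print.bin_index <- function(x, ...) {
  cat(sprintf("<bin_index> %d-bp bins over %d chromosome(s), %d bins total\n",
              x$bin_width, length(x$n_bins), sum(x$n_bins)))
  invisible(x)
}

#' Number of bins on a chromosome
#' @param bins A `bin_index`.
#' @param chrom Chromosome name(s); all chromosomes when `NULL`.
#' @return Named integer vector of bin counts.
#' @export
n_bins <- function(bins, chrom = NULL) {
  if (is.null(chrom)) bins$n_bins else bins$n_bins[chrom]
}

#' Bins as a tibble of intervals
#' @param bins A `bin_index`.
#' @return Tibble with `chrom`, `bin` (0-based), `start`, `end`.
#' @export
bin_tibble <- function(bins) {
  w <- bins$bin_width
  purrr::map_dfr(names(bins$n_bins), function(ch) {
    nb <- bins$n_bins[[ch]]
    if (nb == 0L) return(tibble(chrom = character(), bin = integer(),
                                start = numeric(), end = numeric()))
    b <- 0:(nb - 1L)
    tibble(chrom = ch, bin = b, start = b * w, end = (b + 1) * w)
  })
}

#' Enumerate scoring windows
#'
#' The prediction grid of the method: `window` bp regions every `step` bp
#' (defaults 200 and 50).  Windows are emitted while they fit inside the
#' binned part of the chromosome.
#'
#' @param bins A `bin_index`.
#' @param window Window width in bp.
#' @param step Offset between consecutive windows in bp.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
enumerate_windows <- function(bins, window = 200, step = 50) {
  purrr::map_dfr(names(bins$n_bins), function(ch) {
    len <- bins$n_bins[[ch]] * bins$bin_width
    if (len < window) return(tibble(chrom = character(), start = numeric(),
                                    end = numeric()))
    starts <- seq(0, len - window, by = step)
    tibble(chrom = ch, start = starts, end = starts + window)
  })
}

#' Label windows from ChIP-seq peak lists
#'
#' Implements the challenge labelling rule: a window overlapping a
#' conservative peak by at least 100 bp is `B` ("bound"); of the rest, a
#' window overlapping a relaxed peak by at least 1 bp is `A` ("ambiguous");
#' all other windows are `U` ("unbound").  When the conservative list is
#' empty (e.g., no replicates for IDR), the relaxed peaks also drive the
#' bound rule.
#'
#' @param windows Window tibble from [enumerate_windows()].
#' @param conservative,relaxed Peak tibbles ([read_narrowpeak()]).
#' @param min_bound_overlap Minimum overlap in bp for the bound rule.
#' @return `windows` with an added `label` column (character, `B`/`A`/`U`).
#' @export
derive_labels <- function(windows, conservative, relaxed,
                          min_bound_overlap = 100) {
  bound_source <- if (nrow(conservative) > 0L) conservative else relaxed
  lab <- rep("U", nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    wr <- IRanges::IRanges(start = windows$start[wi] + 1L, end = windows$end[wi])
    bp <- bound_source[bound_source$chrom == ch, , drop = FALSE]
    if (nrow(bp) > 0L) {
      br <- IRanges::IRanges(start = bp$start + 1L, end = bp$end)
      hit <- IRanges::findOverlaps(wr, br, minoverlap = min_bound_overlap)
      lab[wi[unique(S4Vectors::queryHits(hit))]] <- "B"
    }
    rp <- relaxed[relaxed$chrom == ch, , drop = FALSE]
    if (nrow(rp) > 0L) {
      rr <- IRanges::IRanges(start = rp$start + 1L, end = rp$end)
      hit <- IRanges::findOverlaps(wr, rr, minoverlap = 1L)
      amb <- wi[unique(S4Vectors::queryHits(hit))]
      lab[setdiff(amb, wi[lab[wi] == "B"])] <- "A"
    }
  }
  windows$label <- lab
  windows
}

#' Classifier input width in bins from peak widths
#'
#' The number of adjacent bins the classifier looks at is derived from peak
#' geometry: the median across cell types of the per-cell-type median peak
#' width, divided by the bin width, rounded, and forced odd by adding one
#' when even.
#'
#' @param peak_lists List of peak tibbles, one per training cell type.
#' @param bin_width Bin width in bp.
#' @return Odd integer `W >= 1`.
#' @examples
#' pk <- tibble::tibble(chrom = "c", start = 0, end = 250)
#' peak_width_bins(list(pk))  # 5
#' @export
peak_width_bins <- function(peak_lists, bin_width = 50) {
  meds <- purrr::compact(purrr::map(peak_lists, function(p) {
    if (nrow(p) == 0L) NULL else median(p$end - p$start)
  }))
  if (length(meds) == 0L) abort("no non-empty peak lists: cannot derive width")
  w <- round(median(unlist(meds)) / bin_width)
  if (w %% 2 == 0) w <- w + 1
  max(as.integer(w), 1L)
}

#' Write window labels as gzip-friendly TSV
#' @param labels Labelled window tibble from [derive_labels()].
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_lines(paste(labels$chrom, as.integer(labels$start),
                           labels$label, sep = "\t"), path)
  invisible(path)
}

#' Read window labels written by [write_labels()]
#' @param path Label TSV path.
#' @param window Window width used to reconstruct `end`.
#' @return Tibble with `chrom`, `start`, `end`, `label`.
#' @export
read_labels <- function(path, window = 200) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "start", "label"),
                         col_types = "cdc", progress = FALSE)
  mutate(tab, end = .data$start + window, .after = "start")
}
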