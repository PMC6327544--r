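BASES <- c("A", "C", "G", "T")

# integer codes 1..4 for ACGT, 5 for N/anything else
seq_codes <- function(seq) {
  lut <- rep(5L, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(seq)]
}

#' Position weight matrix
#'
#' Builds a PWM from a position-by-base matrix of counts or probabilities.
#' Rows are motif positions, columns the bases A, C, G, T.  Each row is
#' normalised and mixed with the uniform distribution so that every entry is
#' at least `floor` — this pseudo-probability floor keeps all log scores
#' finite.
#'
#' @param mat Numeric matrix, `m x 4`, rows summing to anything positive.
#' @param name Motif name.
#' @param floor Pseudo-probability floor (0 disables flooring).
#' @return A `pwm` object.
#' @export
pwm <- function(mat, name = "motif", floor = 1e-4) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) abort("a PWM needs exactly 4 base columns (A,C,G,T)")
  if (any(mat < 0) || any(rowSums(mat) <= 0)) {
    abort("PWM rows must be non-negative with positive sums")
  }
  p <- mat / rowSums(mat)
  p <- (1 - 4 * floor) * p + floor
  colnames(p) <- BASES
  structure(list(name = name, prob = p, floor = floor, length = nrow(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> '%s', length %d, floor %g\n", x$name, x$length, x$floor))
  invisible(x)
}

#' Read a JASPAR-style plain-text PWM
#'
#' Accepts the common 4-row layout (one row per base A, C, G, T, values
#' optionally wrapped in `A [ ... ]` brackets, optional `>name` header) with
#' counts or probabilities.
#'
#' @param path Path to the matrix file.
#' @param floor Pseudo-probability floor passed to [pwm()].
#' @return A `pwm` object.
#' @export
read_pwm_matrix <- function(path, floor = 1e-4) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- tools::file_path_sans_ext(basename(path))
  if (startsWith(lines[1], ">")) {
    name <- trimws(sub("^>", "", lines[1]))
    name <- sub("\\s.*$", "", name)
    lines <- lines[-1]
  }
  if (length(lines) != 4L) {
    abort(sprintf("PWM file '%s': expected 4 base rows, found %d",
                  path, length(lines)))
  }
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*|\\[|\\]", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1L) {
    abort(sprintf("PWM file '%s': base rows have unequal lengths", path))
  }
  pwm(t(do.call(rbind, rows)), name = name, floor = floor)
}

#' Write a PWM in the 4-row plain-text layout
#' @param x A `pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_matrix <- function(x, path) {
  lines <- c(paste0(">", x$name),
             vapply(1:4, function(b) {
               paste(BASES[b], paste(fmt_num(x$prob[, b]), collapse = " "))
             }, character(1)))
  readr::write_lines(lines, path)
  invisible(path)
}

# per-strand log-prob score matrices including the N column
pwm_score_rows <- function(x) {
  lp <- log(x$prob)
  lp <- cbind(lp, N = log(apply(x$prob, 1, min)))
  m <- x$length
  # reverse strand: complement bases, reversed positions
  lp_rc <- lp[m:1, c(4L, 3L, 2L, 1L, 5L), drop = FALSE]
  colnames(lp_rc) <- colnames(lp)
  list(fwd = lp, rev = lp_rc)
}

#' Scan a sequence with a PWM
#'
#' Slides the motif along the sequence and records, for every start
#' position, the natural-log probability of the m-mer under the PWM, on the
#' forward strand and on the reverse complement.  An `N` base contributes
#' the minimum probability of the corresponding motif position.
#'
#' @param seq DNA string.
#' @param x A `pwm`.
#' @return A `score_profile`: list with numeric vectors `forward` and
#'   `reverse` of length `nchar(seq) - m + 1` (empty when the sequence is
#'   shorter than the motif) and the motif length `m`.
#' @export
scan_pwm <- function(seq, x) {
  m <- x$length
  L <- nchar(seq)
  if (L < m) {
    return(structure(list(forward = numeric(), reverse = numeric(), m = m),
                     class = "score_profile"))
  }
  codes <- seq_codes(seq)
  n <- L - m + 1L
  rows <- pwm_score_rows(x)
  fwd <- numeric(n); rev <- numeric(n)
  for (j in seq_len(m)) {
    idx <- codes[j:(j + n - 1L)]
    fwd <- fwd + unname(rows$fwd[j, ])[idx]
    rev <- rev + unname(rows$rev[j, ])[idx]
  }
  structure(list(forward = fwd, reverse = rev, m = m), class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile> motif length %d, %d positions\n",
              x$m, length(x$forward)))
  invisible(x)
}

#' Strand-combined per-position scores
#'
#' Per-position maximum of the forward and reverse-strand log
#' probabilities; the aggregation input.
#'
#' @param profile A `score_profile`.
#' @return Numeric vector.
#' @export
combined_scores <- function(profile) pmax(profile$forward, profile$reverse)

#' Aggregate a score profile into per-bin motif features
#'
#' For each bin, over the scan positions whose start lies in the bin: the
#' maximum log probability (affinity of the strongest site) and the log of
#' the average probability (general affinity of the region), computed with
#' a log-sum-exp.  Tail bins without any scan position are imputed with the
#' chromosome-wide minimum of each feature.
#'
#' @param profile A `score_profile` for one chromosome's sequence.
#' @param bins A `bin_index`.
#' @param chrom Chromosome the profile belongs to.
#' @param name Feature-name stem (usually the motif name).
#' @return Tibble with `chrom`, `bin`, `motif_<name>_max`,
#'   `motif_<name>_logmean`.
#' @export
aggregate_profile <- function(profile, bins, chrom, name = "pwm") {
  nb <- bins$n_bins[[chrom]]
  if (is.null(nb)) abort(sprintf("chromosome '%s' not in bin index", chrom))
  w <- bins$bin_width
  s <- combined_scores(profile)
  if (length(s) == 0L) abort("empty score profile")
  pos_bin <- (seq_along(s) - 1L) %/% w
  keep <- pos_bin < nb
  s <- s[keep]; pos_bin <- pos_bin[keep]
  f <- factor(pos_bin, levels = 0:(nb - 1L))
  mx <- suppressWarnings(vapply(split(s, f), function(v) {
    if (length(v) == 0L) NA_real_ else max(v)
  }, numeric(1)))
  # stable log-mean-exp per bin
  cnt <- as.integer(table(f))
  shifted <- exp(s - mx[pos_bin + 1L])
  sums <- rep(NA_real_, nb)
  agg <- rowsum(shifted, pos_bin)
  sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  lm <- mx + log(sums / cnt)
  mx[is.na(mx)] <- min(mx, na.rm = TRUE)
  lm[is.na(lm)] <- min(lm, na.rm = TRUE)
  out <- tibble(chrom = chrom, bin = 0:(nb - 1L))
  out[[sprintf("motif_%s_max", name)]] <- unname(mx)
  out[[sprintf("motif_%s_logmean", name)]] <- unname(lm)
  out
}

#' Per-bin motif features for a set of PWMs
#'
#' Scans every chromosome with every PWM and aggregates scores per bin.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param pwms List of `pwm` objects.
#' @param bins A `bin_index`.
#' @return Wide tibble keyed by `chrom`, `bin` with two features per motif.
#' @export
motif_features <- function(genome, pwms, bins) {
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  }
  purrr::map_dfr(names(bins$n_bins), function(ch) {
    out <- NULL
    for (nm in names(pwms)) {
      prof <- scan_pwm(genome[[ch]], pwms[[nm]])
      agg <- aggregate_profile(prof, bins, ch, name = nm)
      out <- if (is.null(out)) agg else left_join(out, agg, by = c("chrom", "bin"))
    }
    out
  })
}

#' Simple per-bin sequence statistics
#'
#' G/C fraction, CpG dinucleotide frequency (count over the `w - 1`
#' dinucleotide starts inside the bin) and the longest homopolymer run,
#' computed within each bin.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param bins A `bin_index`.
#' @return Tibble with `chrom`, `bin`, `seq_gc`, `seq_cpg`, `seq_run`.
#' @export
sequence_features <- function(genome, bins) {
  w <- bins$bin_width
  purrr::map_dfr(names(bins$n_bins), function(ch) {
    nb <- bins$n_bins[[ch]]
    if (nb == 0L) return(tibble(chrom = character(), bin = integer()))
    codes <- seq_codes(genome[[ch]])[seq_len(nb * w)]
    binvec <- rep(0:(nb - 1L), each = w)
    gc <- rowsum(as.numeric(codes == 2L | codes == 3L), binvec)[, 1] / w
    cg <- codes[-length(codes)] == 2L & codes[-1L] == 3L
    within_bin <- (seq_len(nb * w - 1L) %% w) != 0L
    cpg <- numeric(nb)
    agg <- rowsum(as.numeric(cg & within_bin), binvec[-length(binvec)])
    cpg[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    cpg <- cpg / (w - 1L)
    run <- vapply(split(codes, binvec), function(cc) max(rle(cc)$lengths),
                  numeric(1))
    tibble(chrom = ch, bin = 0:(nb - 1L), seq_gc = unname(gc),
           seq_cpg = cpg, seq_run = unname(run))
  })
}
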