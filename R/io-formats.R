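#' Read an ENCODE narrowPeak file
#'
#' Parses a 10-column narrowPeak (BED6+4) file into a tibble of peaks.
#' Coordinates are kept in the file's 0-based half-open convention, the
#' internal convention of the whole package.  Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to a narrowPeak file (optionally `.gz`).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal_value`, `p_value`, `q_value`, `summit` (offset from
#'   `start`, or -1 when absent).  One row per file line, in file order.
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t400\tp1\t0\t.\t5.0\t-1\t-1\t150", tf)
#' read_narrowpeak(tf)
#' @export
read_narrowpeak <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    bad <- which(nf < 10L)[1L]
    abort(sprintf(
      "narrowPeak parse error at line %d of '%s': expected >= 10 tab-separated columns, found %d",
      bad, path, nf[bad]
    ))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1L]
      abort(sprintf(
        "narrowPeak parse error at line %d of '%s': non-numeric %s field",
        bad, path, what
      ))
    }
    x
  }
  peaks <- tibble(
    chrom = col(1), start = num(2, "start"), end = num(3, "end"),
    name = col(4), score = as.integer(num(5, "score")), strand = col(6),
    signal_value = num(7, "signalValue"), p_value = num(8, "pValue"),
    q_value = num(9, "qValue"), summit = num(10, "summit")
  )
  bad <- which(peaks$start >= peaks$end)
  if (length(bad) > 0L) {
    abort(sprintf(
      "narrowPeak parse error at line %d of '%s': start (%d) >= end (%d)",
      bad[1L], path, as.integer(peaks$start[bad[1L]]), as.integer(peaks$end[bad[1L]])
    ))
  }
  bad <- which(peaks$summit != -1 &
                 (peaks$summit < 0 | peaks$summit >= peaks$end - peaks$start))
  if (length(bad) > 0L) {
    abort(sprintf(
      "narrowPeak parse error at line %d of '%s': summit offset %d outside peak of width %d",
      bad[1L], path, as.integer(peaks$summit[bad[1L]]),
      as.integer(peaks$end[bad[1L]] - peaks$start[bad[1L]])
    ))
  }
  peaks$summit <- as.integer(peaks$summit)
  peaks
}

empty_peaks <- function() {
  tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = integer(), strand = character(),
    signal_value = numeric(), p_value = numeric(), q_value = numeric(),
    summit = integer()
  )
}

# exact decimal serialisation that survives a read/write round trip
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) {
      sprintf("%d", as.integer(v))
    } else {
      sub("0+$", "", sprintf("%.17f", v))
    }
  }, character(1))
  out
}

#' Write peaks to an ENCODE narrowPeak file
#'
#' Inverse of [read_narrowpeak()]: `read_narrowpeak(write_narrowpeak(x, f))`
#' reproduces `x` exactly.  A `.gz` extension triggers gzip compression.
#'
#' @param peaks A peak tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  lines <- paste(
    peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
    peaks$name, as.integer(peaks$score), peaks$strand,
    fmt_num(peaks$signal_value), fmt_num(peaks$p_value),
    fmt_num(peaks$q_value), as.integer(peaks$summit),
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' @param path Two-column TSV of chromosome name and length in bp.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "size"),
                         col_types = "cd", progress = FALSE)
  chrom_sizes(setNames(tab$size, tab$chrom))
}

#' Build a chromosome-length table from a named vector
#'
#' @param sizes Named numeric vector of chromosome lengths in bp.
#' @return A tibble with columns `chrom` and `size`.
#' @export
chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || anyDuplicated(names(sizes))) {
    abort("chromosome names must be present and unique")
  }
  if (any(sizes <= 0) || any(sizes != round(sizes))) {
    abort("chromosome lengths must be positive integers")
  }
  tibble(chrom = names(sizes), size = as.numeric(sizes))
}

sizes_lookup <- function(sizes) setNames(sizes$size, sizes$chrom)

#' Read a bedGraph coverage track into per-base vectors
#'
#' Reads fold-enrichment coverage (bedGraph, 0-based half-open; optionally
#' gzipped) and materialises one numeric vector per chromosome, length equal
#' to the chromosome size.  Bases not covered by any interval are 0.  When
#' intervals overlap, the interval appearing later in the file wins and a
#' warning is raised.
#'
#' @param path Path to a bedGraph file.
#' @param sizes Chromosome-length tibble ([chrom_sizes()]).
#' @return A `coverage_track`: named list of per-base numeric vectors.
#' @export
read_coverage <- function(path, sizes) {
  lu <- sizes_lookup(sizes)
  track <- lapply(lu, function(n) numeric(n))
  tab <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  if (nrow(tab) > 0L) {
    unknown <- setdiff(unique(tab$chrom), names(lu))
    if (length(unknown) > 0L) {
      abort(sprintf("bedGraph '%s' refers to unknown chromosome '%s'",
                    path, unknown[1L]))
    }
    if (any(tab$value < 0)) {
      abort(sprintf("bedGraph '%s' contains negative coverage values", path))
    }
    if (any(tab$start < 0) || any(tab$start >= tab$end)) {
      abort(sprintf("bedGraph '%s' contains an invalid interval", path))
    }
    if (any(tab$end > lu[tab$chrom])) {
      abort(sprintf("bedGraph '%s' has intervals beyond the chromosome end", path))
    }
    overlapped <- FALSE
    seen <- lapply(lu, function(n) logical(n))
    for (i in seq_len(nrow(tab))) {
      idx <- (tab$start[i] + 1L):tab$end[i]
      ch <- tab$chrom[i]
      if (!overlapped && any(seen[[ch]][idx])) overlapped <- TRUE
      seen[[ch]][idx] <- TRUE
      track[[ch]][idx] <- tab$value[i]
    }
    if (overlapped) {
      warn(sprintf("bedGraph '%s' contains overlapping intervals; last written wins", path))
    }
  }
  structure(track, class = "coverage_track")
}

#' Construct a coverage track from per-base vectors
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(values) {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    abort("coverage track chromosomes must be uniquely named")
  }
  if (any(vapply(values, function(v) any(v < 0), logical(1)))) {
    abort("coverage values must be non-negative")
  }
  structure(lapply(values, as.numeric), class = "coverage_track")
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into intervals; zero runs are omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  lines <- unlist(lapply(names(track), function(ch) {
    v <- track[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(character())
    paste(ch, starts[keep], ends[keep], fmt_num(r$values[keep]), sep = "\t")
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased; any non-ACGT base is mapped to `N` (excluded
#' from motif scoring downstream).
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of chromosome sequences.
#' @export
read_fasta_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- gsub("[^ACGT]", "N", seqs)
  seqs
}

#' Write a genome to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
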