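# small deterministic world: two chromosomes, known peaks
sampling_world <- function(seed = 101, n_pos = c(c1 = 12, c2 = 8)) {
  withr::with_seed(seed, {
    bins <- bin_genome(chrom_sizes(c(c1 = 50000, c2 = 40000)), 50)
    mkpeaks <- function(ch, n) {
      pos <- sort(sample(seq(500, bins$n_bins[[ch]] * 50 - 500, by = 450), n))
      tibble::tibble(chrom = ch, start = pos - 150, end = pos + 150,
                     name = paste0(ch, "_p", seq_len(n)), score = 0L,
                     strand = ".", signal_value = 1, p_value = -1,
                     q_value = -1, summit = 150L)
    }
    cons <- dplyr::bind_rows(mkpeaks("c1", n_pos[["c1"]]),
                             mkpeaks("c2", n_pos[["c2"]]))
    relax <- dplyr::mutate(cons, start = start - 50, end = end + 50,
                           summit = summit + 50L)
    cov <- coverage_track(list(c1 = runif(50000, 0, 4),
                               c2 = runif(40000, 0, 4)))
    list(bins = bins, cons = cons, relax = relax, cov = cov,
         med = bin_stats(cov, bins)[, c("chrom", "bin", "acc_median")])
  })
}

test_that("positives sit at summit bins with weight 1", {
  w <- sampling_world()
  pos <- training_positives(w$cons, w$bins, 5)
  expect_equal(nrow(pos), 20L)
  expect_true(all(pos$weight == 1))
  expect_true(all(pos$label == "B"))
  summit_bp <- w$cons$start + w$cons$summit
  expect_equal(pos$bin, as.integer(floor(summit_bp / 50)))
})

test_that("uniform negatives: 10x positives per chromosome, none in relaxed peaks", {
  w <- sampling_world()
  pos <- training_positives(w$cons, w$bins, 5)
  neg <- sample_uniform_negatives(w$bins, w$relax, pos, 5, seed = 7)
  expect_equal(sum(neg$chrom == "c1"), 120L)
  expect_equal(sum(neg$chrom == "c2"), 80L)
  expect_true(all(neg$weight == 1))
  expect_true(no_relaxed_overlap(neg, w$relax))
  expect_false(any(duplicated(paste(neg$chrom, neg$bin))))
  # same seed, same draw
  neg2 <- sample_uniform_negatives(w$bins, w$relax, pos, 5, seed = 7)
  expect_identical(neg, neg2)
})

test_that("uniform sampling degrades gracefully when few bins are eligible", {
  bins <- bin_genome(chrom_sizes(c(c1 = 5000)), 50)
  relax <- tibble::tibble(chrom = "c1", start = 0, end = 5000, name = "all",
                          score = 0L, strand = ".", signal_value = 1,
                          p_value = -1, q_value = -1, summit = -1L)
  pos <- tibble::tibble(chrom = "c1", bin = 50L, label = "B", weight = 1,
                        provenance = "positive")
  expect_warning(
    neg <- sample_uniform_negatives(bins, relax, pos, 5, seed = 1),
    "eligible")
  expect_equal(nrow(neg), 0L)
})

test_that("accessibility-matched weights follow the importance formula", {
  w <- sampling_world()
  pos <- training_positives(w$cons, w$bins, 5)
  neg <- sample_dnase_matched_negatives(w$bins, w$relax, pos, w$med, 5,
                                        seed = 9)
  expect_equal(sum(neg$chrom == "c1"), 120L)
  expect_true(no_relaxed_overlap(neg, w$relax))
  expect_true(all(neg$weight > 0))
  # every draw carries the importance weight (N_g/N_neg)/(n_g/n_total),
  # with strata rebuilt independently here
  for (ch in c("c1", "c2")) {
    nb <- n_bins(w$bins, ch)
    blocked <- peakcast:::bins_covered_by(w$relax[w$relax$chrom == ch, ],
                                          nb, 50)
    eligible <- setdiff(2:(nb - 3), blocked)
    ev <- w$med$acc_median[w$med$chrom == ch][eligible + 1]
    breaks <- unique(quantile(ev, probs = seq(0, 1, 0.1)))
    strat <- function(v) pmin(pmax(findInterval(v, breaks,
                                                rightmost.closed = TRUE), 1),
                              length(breaks) - 1)
    N_g <- tabulate(strat(ev), nbins = length(breaks) - 1)
    nch <- neg[neg$chrom == ch, ]
    med_drawn <- w$med$acc_median[w$med$chrom == ch][nch$bin + 1]
    g_drawn <- strat(med_drawn)
    n_g <- tabulate(g_drawn, nbins = length(breaks) - 1)
    want_w <- (N_g[g_drawn] / length(eligible)) / (n_g[g_drawn] / nrow(nch))
    expect_equal(nch$weight, want_w, tolerance = 1e-9)
    # weighted draws represent the covered strata of the population
    covered <- sum(N_g[n_g > 0]) / length(eligible)
    expect_equal(sum(nch$weight), nrow(nch) * covered, tolerance = 1e-9)
  }
  # flat coverage puts everything in one stratum: all weights exactly 1
  flat <- coverage_track(list(c1 = rep(2, 50000), c2 = rep(2, 40000)))
  med_flat <- bin_stats(flat, w$bins)[, c("chrom", "bin", "acc_median")]
  neg_flat <- sample_dnase_matched_negatives(w$bins, w$relax, pos, med_flat,
                                             5, seed = 9)
  expect_true(all(abs(neg_flat$weight - 1) < 1e-12))
  expect_identical(neg,
                   sample_dnase_matched_negatives(w$bins, w$relax, pos, w$med,
                                                  5, seed = 9))
})

test_that("matched sampling over-represents positive-like accessibility", {
  w <- sampling_world()
  # spike coverage under the positives so their medians sit in the top decile
  cov <- w$cov
  for (i in seq_len(nrow(w$cons))) {
    ch <- w$cons$chrom[i]
    idx <- (w$cons$start[i] + 1):w$cons$end[i]
    cov[[ch]][idx] <- cov[[ch]][idx] + 50
  }
  # and under a minority of eligible background bins
  withr::with_seed(31, {
    for (ch in c("c1", "c2")) {
      hot <- sample(seq(1, length(cov[[ch]]) - 200, by = 50), 40)
      for (h in hot) cov[[ch]][h:(h + 120)] <- cov[[ch]][h:(h + 120)] + 50
    }
  })
  med <- bin_stats(cov, w$bins)[, c("chrom", "bin", "acc_median")]
  pos <- training_positives(w$cons, w$bins, 5)
  neg <- sample_dnase_matched_negatives(w$bins, w$relax, pos, med, 5, seed = 11)
  drawn_med <- med$acc_median[match(paste(neg$chrom, neg$bin),
                                    paste(med$chrom, med$bin))]
  # most draws are high-accessibility, and those draws are down-weighted
  expect_gt(mean(drawn_med > 25), 0.5)
  expect_lt(mean(neg$weight[drawn_med > 25]), 1)
})

test_that("cross-cell-type negatives: 4x positives, weight sum anchored", {
  w <- sampling_world()
  pos <- training_positives(w$cons, w$bins, 5)
  base <- sample_uniform_negatives(w$bins, w$relax, pos, 5, seed = 13)
  # other cell type: broad peaks shifted away from current relaxed peaks
  other <- dplyr::mutate(w$cons, start = start + 6800, end = end + 7600)
  other <- other[other$end < 38000, ]
  neg <- sample_cross_celltype_negatives(w$bins, list(other), w$relax, pos,
                                         base, 5, seed = 15)
  for (ch in c("c1", "c2")) {
    n_ch <- sum(neg$chrom == ch)
    expect_equal(n_ch, 4L * sum(pos$chrom == ch))
    # weight sum = eligible rate among putative negatives x schema-1/2 weight
    nb <- n_bins(w$bins, ch)
    valid <- 2:(nb - 3)
    blocked <- peakcast:::bins_covered_by(w$relax[w$relax$chrom == ch, ], nb, 50)
    eligible <- setdiff(intersect(peakcast:::bins_covered_by(
      other[other$chrom == ch, ], nb, 50), valid), blocked)
    putative <- setdiff(valid, blocked)
    anchor <- sum(base$weight[base$chrom == ch])
    expect_equal(sum(neg$weight[neg$chrom == ch]),
                 length(eligible) / length(putative) * anchor,
                 tolerance = 1e-9)
  }
  expect_true(no_relaxed_overlap(neg, w$relax))
  # no other cell types: schema skipped
  none <- sample_cross_celltype_negatives(w$bins, list(), w$relax, pos,
                                          base, 5, seed = 15)
  expect_equal(nrow(none), 0L)
})

test_that("the initial training set combines all schemas reproducibly", {
  w <- sampling_world()
  other <- dplyr::mutate(w$cons, start = start + 6800, end = end + 7600)
  other <- other[other$end < 38000, ]
  ts <- initial_training_set(w$bins, w$cons, w$relax, w$med, 5,
                             other_conservative = list(other), seed = 99)
  expect_setequal(unique(ts$provenance),
                  c("positive", "uniform", "dnase-matched", "cross-celltype"))
  expect_equal(sum(ts$label == "B"), 20L)
  expect_true(no_relaxed_overlap(ts[ts$label == "U", ], w$relax))
  ts2 <- initial_training_set(w$bins, w$cons, w$relax, w$med, 5,
                              other_conservative = list(other), seed = 99)
  expect_identical(ts, ts2)
})
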