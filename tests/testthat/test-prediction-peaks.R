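test_that("the contributing centre set for W=5 is i-1 ... i+4", {
  # place probability on one bin at a time and see which windows react
  nb <- 30
  for (l in 10:18) {
    p <- rep(0, nb); p[l + 1] <- 0.5
    s <- window_probability(p, 5)
    reacting <- which(s > 0) - 1
    expect_equal(reacting, (l - 4):(l + 1))   # window starts i with l in i-1..i+4
  }
})

test_that("window probabilities follow the complementary-product formula", {
  p <- rep(0, 20)
  expect_equal(window_probability(p, 5), rep(0, 17))
  p[9] <- 0.5
  s <- window_probability(p, 5)
  expect_equal(s[8], 0.5)   # single P=0.5 in range
  # P_{i-1} = P_{i+4} = 0.5 with i = 9 (0-based): S = 1 - 0.25
  p2 <- rep(0, 20); p2[9] <- 0.5; p2[14] <- 0.5
  expect_equal(window_probability(p2, 5)[10], 0.75)
  expect_error(window_probability(p, 4), "odd")
})

test_that("window probabilities match brute-force enumeration on random vectors", {
  withr::with_seed(41, {
    for (W in c(3, 5, 7, 9)) {
      p <- runif(40)
      s <- window_probability(p, W)
      for (i in c(0, 1, 17, 35, 36)) {
        expect_equal(s[i + 1], oracle_window_prob(p, W, i), tolerance = 1e-12)
      }
    }
  })
})

test_that("S is monotone in every per-bin posterior", {
  withr::with_seed(42, {
    p <- runif(30, 0, 0.8)
    s0 <- window_probability(p, 5)
    for (l in c(5, 12, 20)) {
      p2 <- p; p2[l] <- p[l] + 0.19
      expect_true(all(window_probability(p2, 5) >= s0 - 1e-12))
    }
  })
})

test_that("ensemble averaging is the per-window mean and validates grids", {
  tr <- function(s) {
    out <- tibble::tibble(chrom = "c1", start = seq(0, by = 50,
                                                    length.out = length(s)),
                          end = start + 200, s = s)
    class(out) <- c("prob_track", class(out))
    out
  }
  a <- tr(c(0.2, 0.4)); b <- tr(c(0.6, 0.0))
  expect_equal(ensemble_average(list(a))$s, a$s)
  expect_equal(ensemble_average(list(a, b))$s, c(0.4, 0.2))
  bad <- tr(c(0.1, 0.2)); bad$start <- bad$start + 50
  expect_error(ensemble_average(list(a, bad)), "grids")
})

test_that("peak calling reproduces the worked trimming example", {
  s <- c(0.1, 0.7, 0.9, 0.65, 0.1)
  track <- tibble::tibble(chrom = "c1", start = seq(0, by = 50,
                                                    length.out = 5),
                          end = start + 200, s = s)
  class(track) <- c("prob_track", class(track))
  pk <- call_peaks(track, 0.6)
  expect_equal(nrow(pk), 1L)
  # only the 0.9 window survives: 0.7 and 0.65 < 0.72 = 0.8 * 0.9
  expect_equal(pk$start, 100)
  expect_equal(pk$end, 300)
  expect_equal(pk$score, 100L)           # -100 log10(1 - 0.9)
  expect_equal(pk$signal_value, 0.9)
  expect_equal(pk$summit, 100L)          # centre of the maximal window
  # nothing above threshold: no peaks
  expect_equal(nrow(call_peaks(track, 0.95)), 0L)
  # probability cap keeps the score finite at 800
  hi <- track; hi$s <- c(0.1, 1, 1, 1, 0.1)
  expect_equal(call_peaks(hi, 0.6)$score, 800L)
})

test_that("conservative peaks nest inside relaxed peaks on random tracks", {
  withr::with_seed(43, {
    for (r in 1:20) {
      s <- pmin(pmax(stats::filter(runif(80), rep(1 / 3, 3),
                                   sides = 2), 0), 1)
      s[is.na(s)] <- 0
      track <- tibble::tibble(chrom = "c1",
                              start = seq(0, by = 50, length.out = 80),
                              end = start + 200, s = as.numeric(s))
      class(track) <- c("prob_track", class(track))
      cons <- call_peaks(track, 0.8)
      relax <- call_peaks(track, 0.6)
      if (nrow(cons) > 0) {
        contained <- vapply(seq_len(nrow(cons)), function(i) {
          any(relax$start <= cons$start[i] & relax$end >= cons$end[i])
        }, logical(1))
        expect_true(all(contained))
      }
      # score/signal relation on every record
      for (pk in list(cons, relax)) {
        if (nrow(pk) > 0) {
          expect_equal(pk$score,
                       as.integer(round(-100 * log10(1 - pmin(pk$signal_value,
                                                              1 - 1e-8)))))
        }
      }
      # raising the threshold never yields more or longer peaks
      expect_lte(nrow(cons), nrow(relax))
      expect_lte(sum(cons$end - cons$start), sum(relax$end - relax$start))
    }
  })
})

test_that("peak tibbles from call_peaks serialise as valid narrowPeak", {
  s <- c(0.1, 0.65, 0.85, 0.9, 0.7, 0.1, 0.75, 0.1)
  track <- tibble::tibble(chrom = "c1",
                          start = seq(0, by = 50, length.out = 8),
                          end = start + 200, s = s)
  class(track) <- c("prob_track", class(track))
  pk <- call_peaks(track, 0.6, name_prefix = "rel")
  tf <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, tf)
  expect_equal(read_narrowpeak(tf), pk)
})

test_that("score tracks round trip through bedGraph", {
  withr::with_seed(44, {
    track <- tibble::tibble(chrom = rep(c("c1", "c2"), each = 10),
                            start = rep(seq(0, 450, by = 50), 2),
                            end = start + 200,
                            s = round(runif(20), 6))
    class(track) <- c("prob_track", class(track))
    tf <- tempfile(fileext = ".bedGraph.gz")
    write_track(track, tf)
    back <- read_track(tf)
    expect_equal(back$s, track$s)
    expect_equal(back$start, track$start)
  })
})

test_that("bin posteriors assign zero to unrepresentable edge bins", {
  withr::with_seed(45, {
    bins <- bin_genome(chrom_sizes(c(c1 = 2000)), 50)
    feats <- dplyr::left_join(
      bin_stats(coverage_track(list(c1 = runif(2000, 0, 5))), bins),
      sequence_features(c(c1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                                     collapse = "")), bins),
      by = c("chrom", "bin"))
    fx <- feature_window_matrix(feats, bins, 5)
    lab <- sample(c("B", "U"), nrow(fx$x), TRUE)
    m <- train_mcl(fx$x, lab)
    pb <- bin_posteriors(m, feats, bins, 5)
    expect_equal(nrow(pb), 40L)
    expect_equal(pb$p[1:2], c(0, 0))
    expect_equal(pb$p[39:40], c(0, 0))
    expect_true(all(pb$p >= 0 & pb$p <= 1))
  })
})
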