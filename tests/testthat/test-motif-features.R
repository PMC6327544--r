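test_that("PWM scanning gives closed-form log probabilities", {
  # probability-1 consensus PWM without flooring: exact match scores log(1)=0
  cons <- consensus_pwm("ACGT", match_prob = 1, floor = 0)
  prof <- scan_pwm("TTACGTTT", cons)
  expect_equal(length(prof$forward), 5L)
  expect_equal(prof$forward[3], 0)
  expect_true(all(prof$forward[-3] == -Inf))
  # uniform PWM: every 4-mer scores 4 log(0.25)
  unif <- pwm(matrix(1, 4, 4), floor = 0)
  pu <- scan_pwm("ACGTACGT", unif)
  expect_equal(pu$forward, rep(4 * log(0.25), 5))
  expect_equal(pu$reverse, rep(4 * log(0.25), 5))
  # strand-combined score is the per-position max
  expect_equal(combined_scores(prof), pmax(prof$forward, prof$reverse))
  # sequence shorter than the motif: empty profile
  expect_length(scan_pwm("AC", cons)$forward, 0L)
})

test_that("scanning the reverse complement mirrors the profile with strands swapped", {
  withr::with_seed(8, {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    p <- consensus_pwm("TGACGTCA", match_prob = 0.8)
    f1 <- scan_pwm(seq, p)
    f2 <- scan_pwm(rc, p)
    expect_equal(f2$forward, rev(f1$reverse), tolerance = 1e-12)
    expect_equal(f2$reverse, rev(f1$forward), tolerance = 1e-12)
  })
})

test_that("scan matches a brute-force product-of-probabilities oracle", {
  withr::with_seed(9, {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 1000, TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    p <- consensus_pwm("GATTACA", match_prob = 0.7)
    prof <- scan_pwm(seq, p)
    m <- p$length
    chars <- strsplit(seq, "")[[1]]
    want <- vapply(seq_len(nchar(seq) - m + 1), function(i) {
      sum(vapply(seq_len(m), function(j) {
        b <- chars[i + j - 1]
        if (b == "N") log(min(p$prob[j, ])) else log(p$prob[j, b])
      }, numeric(1)))
    }, numeric(1))
    expect_equal(prof$forward, want, tolerance = 1e-12)
  })
})

test_that("per-bin aggregation gives max and stable log-mean probabilities", {
  bins <- bin_genome(chrom_sizes(c(cA = 100)), 50)
  # constant profile: max == log-mean == c
  prof <- structure(list(forward = rep(-3, 97), reverse = rep(-5, 97), m = 4),
                    class = "score_profile")
  agg <- aggregate_profile(prof, bins, "cA", name = "m")
  expect_equal(agg$motif_m_max, c(-3, -3))
  expect_equal(agg$motif_m_logmean, c(-3, -3))
  # two positions with probabilities 0.1 and 0.3 average to 0.2
  p2 <- structure(list(forward = log(c(0.1, 0.3)), reverse = log(c(1e-9, 1e-9)),
                       m = 49), class = "score_profile")
  agg2 <- aggregate_profile(p2, bins, "cA", name = "m")
  expect_equal(agg2$motif_m_logmean[1], log(0.2), tolerance = 1e-12)
  # one strong site among many weak ones dominates the max
  p3 <- structure(list(forward = c(0, rep(-20, 49)), reverse = rep(-30, 50),
                       m = 51), class = "score_profile")
  agg3 <- aggregate_profile(p3, bins, "cA", name = "m")
  expect_equal(agg3$motif_m_max[1], 0)
  # log-mean never exceeds max
  withr::with_seed(10, {
    pr <- structure(list(forward = runif(97, -30, 0), reverse = runif(97, -30, 0),
                         m = 4), class = "score_profile")
    a <- aggregate_profile(pr, bins, "cA", name = "m")
    expect_true(all(a$motif_m_logmean <= a$motif_m_max + 1e-12))
  })
})

test_that("tail bins without scan positions are imputed with the chromosome minimum", {
  bins <- bin_genome(chrom_sizes(c(cA = 150)), 50)
  # motif length 60: last scan start is 91 (0-based 90), bin 2 has no starts
  prof <- structure(list(forward = seq(-10, -1, length.out = 91),
                         reverse = rep(-40, 91), m = 60),
                    class = "score_profile")
  agg <- aggregate_profile(prof, bins, "cA", name = "m")
  expect_equal(agg$motif_m_max[3], min(agg$motif_m_max[1:2]))
})

test_that("sequence statistics per bin: GC, CpG frequency, homopolymer runs", {
  bins <- bin_genome(chrom_sizes(c(cA = 150)), 50)
  g <- c(strrep("G", 50), strrep("AT", 25),
         paste0("ACGCGT", strrep("A", 44)))
  genome <- c(cA = paste(g, collapse = ""))
  sf <- sequence_features(genome, bins)
  expect_equal(sf$seq_gc, c(1, 0, 4 / 50))
  expect_equal(sf$seq_cpg, c(0, 0, 2 / 49))
  expect_equal(sf$seq_run, c(50, 1, 44))
})

test_that("motif feature tables cover every bin for every PWM", {
  withr::with_seed(12, {
    genome <- c(c1 = paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                           collapse = ""))
    bins <- bin_genome(chrom_sizes(c(c1 = 500)), 50)
    mf <- motif_features(genome, list(consensus_pwm("TGACTCA", name = "jun"),
                                      consensus_pwm("GGGCGG", name = "sp1")),
                         bins)
    expect_equal(nrow(mf), 10L)
    expect_named(mf, c("chrom", "bin", "motif_jun_max", "motif_jun_logmean",
                       "motif_sp1_max", "motif_sp1_logmean"))
    expect_false(anyNA(mf))
  })
})
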