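# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use brute force / direct arithmetic, never package
# internals.

# interval overlap in bp between [a0, a1) and [b0, b1)
ov_bp <- function(a0, a1, b0, b1) max(0, min(a1, b1) - max(a0, b0))

# direct implementation of the labelling rules: >=100 bp with a conservative
# peak -> B; else >=1 bp with a relaxed peak -> A; else U
oracle_label <- function(w0, w1, chrom, cons, relax, min_bound = 100) {
  bound_src <- if (nrow(cons) > 0) cons else relax
  bs <- bound_src[bound_src$chrom == chrom, ]
  if (nrow(bs) > 0) {
    for (i in seq_len(nrow(bs))) {
      if (ov_bp(w0, w1, bs$start[i], bs$end[i]) >= min_bound) return("B")
    }
  }
  rl <- relax[relax$chrom == chrom, ]
  if (nrow(rl) > 0) {
    for (i in seq_len(nrow(rl))) {
      if (ov_bp(w0, w1, rl$start[i], rl$end[i]) >= 1) return("A")
    }
  }
  "U"
}

# brute-force window probability: enumerate candidate peak centre bins and
# keep those whose peak overlaps the window by >= ov_bins bins
oracle_window_prob <- function(p, width_bins, i, window_bins = 4,
                               ov_bins = 2) {
  h <- (width_bins - 1) / 2
  nb <- length(p)
  q <- 1
  for (l in (i - width_bins - 4):(i + width_bins + window_bins + 4)) {
    overlap_bins <- ov_bp(l - h, l + h + 1, i, i + window_bins)
    if (overlap_bins >= ov_bins) {
      pl <- if (l >= 0 && l < nb) p[l + 1] else 0
      q <- q * (1 - pl)
    }
  }
  1 - q
}

# fine-grid numeric integration of the continuous-interpolation PR curve:
# TP and FP grow linearly between adjacent operating points
oracle_aucpr <- function(scores, labels, grid = 2000) {
  y <- labels == "B" | labels == TRUE | labels == 1
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  last <- cumsum(rle(s)$lengths)
  tp <- c(0, cumsum(as.numeric(y))[last])
  fp <- c(0, cumsum(as.numeric(!y))[last])
  P <- sum(y)
  total <- 0
  for (k in 2:length(tp)) {
    dtp <- tp[k] - tp[k - 1]; dfp <- fp[k] - fp[k - 1]
    if (dtp == 0) next
    ss <- (seq_len(grid) - 0.5) / grid
    tps <- tp[k - 1] + ss * dtp
    fps <- fp[k - 1] + ss * dfp
    prec <- tps / (tps + fps)
    total <- total + sum(prec) / grid * (dtp / P)
  }
  total
}

# independent penalised weighted logistic regression by Newton-Raphson/IRLS
# (intercept unpenalised), on an explicit design matrix
oracle_logistic <- function(X, y, w, lambda, maxit = 200, tol = 1e-12) {
  X1 <- cbind(1, X)
  th <- rep(0, ncol(X1))
  pen <- c(0, rep(lambda, ncol(X)))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% th)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X1, w * (y - p))) - pen * th
    H <- crossprod(X1 * (w * p * (1 - p)), X1) + diag(pen, ncol(X1))
    step <- solve(H, g)
    th <- th + step
    if (max(abs(g)) < tol) break
  }
  list(theta = th, prob = 1 / (1 + exp(-drop(X1 %*% th))))
}

# the standardised (z, z^2) sufficient-statistic design train_mcl uses for
# gaussian features, rebuilt independently
oracle_design <- function(x, families, w = rep(1, nrow(x))) {
  cols <- list()
  for (nm in colnames(x)) {
    if (families[[nm]] == "gaussian") {
      c_j <- sum(w * x[, nm]) / sum(w)
      s_j <- sqrt(sum(w * (x[, nm] - c_j)^2) / sum(w))
      z <- (x[, nm] - c_j) / max(s_j, 1e-12)
      cols[[paste0(nm, "_z")]] <- z
      cols[[paste0(nm, "_z2")]] <- z^2
    } else {
      cols[[nm]] <- x[, nm]
    }
  }
  do.call(cbind, cols)
}

# TRUE when no negative centre bin touches a relaxed peak
no_relaxed_overlap <- function(neg, relax, bin_width = 50) {
  all(vapply(seq_len(nrow(neg)), function(i) {
    b0 <- neg$bin[i] * bin_width; b1 <- b0 + bin_width
    rl <- relax[relax$chrom == neg$chrom[i], ]
    all(vapply(seq_len(nrow(rl)), function(j) {
      ov_bp(b0, b1, rl$start[j], rl$end[j]) == 0
    }, logical(1)))
  }, logical(1)))
}

# random peak tibble on given chromosomes
random_peaks <- function(n, chroms, max_pos = 5000, min_w = 50, max_w = 400,
                         name_prefix = "rp") {
  if (n == 0) return(peakcast::read_narrowpeak(tempfile_empty()))
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(min_w:max_w, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = as.numeric(start), end = as.numeric(start + width),
    name = paste0(name_prefix, seq_len(n)), score = 0L, strand = ".",
    signal_value = 1, p_value = -1, q_value = -1,
    summit = as.integer(floor(width / 2))
  )
}

tempfile_empty <- function() {
  tf <- tempfile()
  writeLines(character(), tf)
  tf
}

# small fast simulation config for structural tests
fast_config <- function(n_sites = 20, n_decoys = 30, ...) {
  peakcast::sim_config(n_chroms = 2, chrom_length = 60000, n_sites = n_sites,
                       n_decoys = n_decoys, ...)
}

# 1-D two-gaussian training fixture drawn from the model family
gaussian_fixture <- function(n, mu = c(0, 2), sd = c(1, 1), p_pos = 0.5,
                             seed = 1) {
  withr::with_seed(seed, {
    y <- runif(n) < p_pos
    x <- rnorm(n, mean = ifelse(y, mu[2], mu[1]), sd = ifelse(y, sd[2], sd[1]))
    list(x = matrix(x, ncol = 1, dimnames = list(NULL, "f1")),
         labels = ifelse(y, "B", "U"))
  })
}
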