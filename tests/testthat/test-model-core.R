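# hand-built model with explicit per-class components (no training)
manual_model <- function(components_B, components_U, beta = c(B = 0, U = 0),
                         markov3 = NULL) {
  features <- names(components_B)
  fams <- vapply(components_B, `[[`, character(1), "family")
  structure(list(
    features = features, families = setNames(fams, features),
    centers = setNames(rep(NA_real_, length(features)), features),
    scales = setNames(rep(NA_real_, length(features)), features),
    components = list(B = components_B, U = components_U),
    beta = beta, markov3 = markov3, prior_scale = 1,
    fit = list(), theta = NULL, design_map = NULL
  ), class = "mcl_model")
}

gauss_comp <- function(mu, var) {
  list(family = "gaussian", eta1 = mu / var, eta2 = -1 / (2 * var))
}

test_that("component log densities have their closed forms", {
  m <- manual_model(list(f1 = gauss_comp(0, 1)), list(f1 = gauss_comp(0, 1)))
  x <- matrix(0, 1, 1, dimnames = list(NULL, "f1"))
  expect_equal(log_density(m, x, "B"), -0.5 * log(2 * pi), tolerance = 1e-12)
  # natural parameter map mu=2, var=4 <-> eta1=0.5, eta2=-0.125, density = dnorm
  cc <- gauss_comp(2, 4)
  expect_equal(cc$eta1, 0.5)
  expect_equal(cc$eta2, -0.125)
  m2 <- manual_model(list(f1 = cc), list(f1 = cc))
  xs <- matrix(seq(-3, 5, by = 0.5), ncol = 1, dimnames = list(NULL, "f1"))
  expect_equal(log_density(m2, xs, "B"), dnorm(xs[, 1], 2, 2, log = TRUE),
               tolerance = 1e-12)
  # order-3 Markov with uniform tables scores every base at 1/4
  mk <- list(log_table_B = matrix(log(0.25), 64, 4),
             log_table_U = matrix(log(0.25), 64, 4))
  m3 <- manual_model(list(), list(), markov3 = mk)
  ld <- log_density(m3, matrix(numeric(0), nrow = 1, ncol = 0), "B",
                    sequences = "ACGTACGTAC")
  expect_equal(ld, 10 * log(0.25), tolerance = 1e-12)
  expect_error(log_density(m, matrix(0, 1, 1,
                                     dimnames = list(NULL, "wrong"))),
               "missing")
})

test_that("posterior symmetry, prior limits and the N(+-1,1) midpoint", {
  m <- manual_model(list(f1 = gauss_comp(1, 1)), list(f1 = gauss_comp(-1, 1)))
  x <- matrix(c(-2, 0, 2), ncol = 1, dimnames = list(NULL, "f1"))
  p <- posterior(m, x)
  expect_equal(p[2], 0.5)                     # symmetric point
  expect_true(p[1] < 0.5 && p[3] > 0.5)
  # identical components, equal priors: 0.5 everywhere
  sym <- manual_model(list(f1 = gauss_comp(0.3, 2)),
                      list(f1 = gauss_comp(0.3, 2)))
  expect_equal(posterior(sym, x), rep(0.5, 3))
  # beta_B - beta_U -> +Inf drives the posterior to 1
  strong <- manual_model(list(f1 = gauss_comp(0.3, 2)),
                         list(f1 = gauss_comp(0.3, 2)),
                         beta = c(B = 500, U = -500))
  expect_equal(posterior(strong, x), rep(1, 3))
  # invariant under adding a shared constant to both priors
  shift <- manual_model(list(f1 = gauss_comp(1, 1)),
                        list(f1 = gauss_comp(-1, 1)),
                        beta = c(B = 7.5, U = 7.5))
  expect_equal(posterior(shift, x), p, tolerance = 1e-12)
})

test_that("training validates inputs", {
  fx <- gaussian_fixture(50)
  expect_error(train_mcl(fx$x, rep("B", 50)), "both classes")
  expect_error(train_mcl(fx$x, fx$labels, weights = rep(0, 50)), "positive")
  bad <- fx$x; bad[1] <- NA
  expect_error(train_mcl(bad, fx$labels), "non-finite")
  expect_error(train_mcl(fx$x, fx$labels,
                         families = c(zzz = "gaussian")), "unknown feature")
})

test_that("duplicating an example equals doubling its weight", {
  fx <- gaussian_fixture(120, seed = 21)
  w <- rep(1, 120); w[7] <- 2
  m_dup <- train_mcl(rbind(fx$x, fx$x[7, , drop = FALSE]),
                     c(fx$labels, fx$labels[7]))
  m_wt <- train_mcl(fx$x, fx$labels, weights = w)
  expect_equal(m_wt$theta, m_dup$theta, tolerance = 1e-6)
  grid <- matrix(seq(-2, 4, length.out = 25), ncol = 1,
                 dimnames = list(NULL, "f1"))
  expect_equal(posterior(m_wt, grid), posterior(m_dup, grid),
               tolerance = 1e-6)
})

test_that("the decision boundary of N(0,1) vs N(2,1) is recovered near x=1", {
  fx <- gaussian_fixture(4000, mu = c(0, 2), seed = 22)
  m <- train_mcl(fx$x, fx$labels, prior_scale = 10)
  grid <- seq(0, 2, by = 0.001)
  p <- posterior(m, matrix(grid, ncol = 1, dimnames = list(NULL, "f1")))
  boundary <- grid[which.min(abs(p - 0.5))]
  expect_lt(abs(boundary - 1), 0.1)
})

test_that("fitted posteriors match an independently optimised logistic regression", {
  withr::with_seed(23, {
    n <- 400
    x <- cbind(f1 = rnorm(n, ifelse(runif(n) < 0.4, 1.5, 0), 1),
               f2 = runif(n, 0, 5),
               ind = as.numeric(runif(n) < 0.3))
    lab <- ifelse(plogis(x[, "f1"] * 2 - x[, "f2"] * 0.5 + x[, "ind"] - 0.5) >
                    runif(n), "B", "U")
    fams <- c(f1 = "gaussian", f2 = "gaussian", ind = "bernoulli")
    wts <- runif(n, 0.5, 2)
    m <- train_mcl(x, lab, weights = wts, families = fams, prior_scale = 1)
    D <- oracle_design(x, fams, wts)
    or <- oracle_logistic(D, as.numeric(lab == "B"), wts, lambda = 1)
    expect_equal(posterior(m, x), or$prob, tolerance = 1e-4)
  })
})

test_that("the optimum is unique: random restarts agree to 1e-6", {
  fx <- gaussian_fixture(300, seed = 24)
  m0 <- train_mcl(fx$x, fx$labels)
  withr::with_seed(25, {
    for (r in 1:3) {
      init <- rnorm(length(m0$theta), sd = 2)
      mr <- train_mcl(fx$x, fx$labels, init = init)
      expect_equal(mr$fit$objective, m0$fit$objective, tolerance = 1e-6)
    }
  })
})

test_that("posteriors converge to the generating posteriors at n = 10,000", {
  fx <- gaussian_fixture(10000, mu = c(0, 2), seed = 26)
  m <- train_mcl(fx$x, fx$labels, prior_scale = 10)
  p_hat <- posterior(m, fx$x)
  p_true <- plogis(dnorm(fx$x[, 1], 2, 1, log = TRUE) -
                     dnorm(fx$x[, 1], 0, 1, log = TRUE) + log(0.5 / 0.5))
  expect_lt(mean(abs(p_hat - p_true)), 0.02)
})

test_that("an order-3 Markov sequence component separates motif from background", {
  withr::with_seed(27, {
    n <- 300
    motif <- "TGACGTCATGACGTCA"
    seqs <- vapply(seq_len(n), function(i) {
      bg <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
      if (i <= n / 2) paste0(substr(bg, 1, 12), motif, substr(bg, 29, 40))
      else bg
    }, character(1))
    lab <- rep(c("B", "U"), each = n / 2)
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "noise"))
    m <- train_mcl(x, lab, sequences = seqs)
    p <- posterior(m, x, sequences = seqs)
    expect_gt(mean(p[lab == "B"]), mean(p[lab == "U"]) + 0.2)
    expect_gt(auc_roc(p, lab), 0.8)
  })
})

test_that("model JSON serialisation round trips predictions exactly", {
  fx <- gaussian_fixture(200, seed = 28)
  x2 <- cbind(fx$x, ind = as.numeric(runif(200) < 0.5))
  m <- train_mcl(x2, fx$labels, families = c(ind = "bernoulli"))
  tf <- tempfile(fileext = ".json")
  write_model(m, tf)
  m2 <- read_model(tf)
  expect_equal(m2$features, m$features)
  expect_equal(posterior(m2, x2), posterior(m, x2), tolerance = 1e-12)
  expect_equal(m2$beta, m$beta, tolerance = 1e-12)
})

test_that("tidy and glance summarise a fitted model", {
  fx <- gaussian_fixture(150, seed = 29)
  m <- train_mcl(fx$x, fx$labels)
  td <- tidy(m)
  expect_named(td, c("feature", "family", "term", "class_B", "class_U",
                     "contrast"))
  expect_equal(nrow(td), 2L)   # eta1 and eta2 of the single gaussian feature
  gl <- glance(m)
  expect_equal(gl$n, 150L)
  expect_lt(gl$grad_norm, 1e-4)
})
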