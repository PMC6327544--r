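#' @name mcl_model
#' @title Two-class exponential-family classifier
#'
#' @description
#' The classifier models each feature independently per class — numeric
#' features by Gaussian densities, 0/1 features by Bernoulli distributions,
#' optionally the raw window sequence by a homogeneous Markov model of
#' order 3 — and combines them as a product of densities with class
#' log-priors.  All continuous components are stored in their natural
#' parameterization.  Training maximises the weighted conditional
#' log-likelihood of the labels (discriminative maximum conditional
#' likelihood), which depends only on the between-class contrasts of the
#' natural parameters; a Gaussian prior with scale `prior_scale` is placed
#' on those contrasts.  In this parameterization the objective is strictly
#' concave and equivalent to an L2-regularised logistic regression on the
#' per-feature sufficient statistics (x, x^2 for Gaussian features).
NULL

gaussian_log_partition <- function(eta1, eta2) {
  eta1^2 / (-4 * eta2) + 0.5 * log(pi / (-eta2))
}

weighted_moments <- function(x, w) {
  mu <- sum(w * x) / sum(w)
  v <- sum(w * (x - mu)^2) / sum(w)
  c(mean = mu, var = v)
}

# map a label vector to logical "is positive (B)"
as_bound <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (!all(l %in% c("B", "U"))) {
    abort("labels must be 'B' or 'U' (ambiguous windows are excluded upstream)")
  }
  l == "B"
}

# 4-mer transition counts for the order-3 Markov component;
# contexts and successors indexed over ACGT only, N-containing 4-mers skipped
markov3_counts <- function(sequences) {
  out <- matrix(0, nrow = length(sequences), ncol = 256)
  for (i in seq_along(sequences)) {
    codes <- seq_codes(sequences[[i]])
    L <- length(codes)
    if (L < 4L) next
    c1 <- codes[1:(L - 3L)]; c2 <- codes[2:(L - 2L)]
    c3 <- codes[3:(L - 1L)]; c4 <- codes[4:L]
    ok <- c1 < 5L & c2 < 5L & c3 < 5L & c4 < 5L
    if (!any(ok)) next
    idx <- (c1[ok] - 1L) * 64L + (c2[ok] - 1L) * 16L + (c3[ok] - 1L) * 4L + c4[ok]
    tab <- tabulate(idx, nbins = 256L)
    out[i, ] <- tab
  }
  out
}

# weighted per-class conditional log-probability tables (64 contexts x 4)
markov3_tables <- function(counts, w, pseudo = 0.5) {
  tot <- colSums(counts * w)
  m <- matrix(tot, nrow = 64, byrow = TRUE) + pseudo
  log(m / rowSums(m))
}

markov3_seq_loglik <- function(counts, log_table, seq_lengths) {
  # first three positions are scored uniformly (1/4 each); N positions and
  # N-containing 4-mers contribute the uniform score as well
  trans <- as.numeric(counts %*% as.numeric(t(log_table)))
  uniform_positions <- seq_lengths - rowSums(counts)
  trans + uniform_positions * log(0.25)
}

#' Train the two-class classifier by maximum conditional likelihood
#'
#' @param x Data frame or matrix of numeric per-window features (rows =
#'   training regions).
#' @param labels Character/factor vector of `"B"`/`"U"` (or logical, `TRUE`
#'   = bound), one per row.
#' @param weights Positive example weights; default 1.
#' @param families Named character vector mapping feature names to
#'   `"gaussian"` or `"bernoulli"`.  Unnamed features default to Gaussian.
#' @param prior_scale Standard deviation of the Gaussian prior on the
#'   between-class natural-parameter contrasts (larger = weaker
#'   regularisation).
#' @param sequences Optional character vector of raw window sequences; when
#'   given, an order-3 homogeneous Markov component is estimated per class
#'   from weighted nucleotide frequencies and enters the classifier as a
#'   log-likelihood-ratio offset during the discriminative fit.
#' @param tol Gradient-norm tolerance declaring convergence.
#' @param maxit Maximum quasi-Newton iterations.
#' @param init Optional numeric start vector (intercept followed by design
#'   coefficients) — used e.g. to check that random restarts reach the same
#'   optimum.
#' @return An `mcl_model` object; see [posterior()], [tidy.mcl_model()],
#'   [glance.mcl_model()], [write_model()].
#' @export
train_mcl <- function(x, labels, weights = NULL, families = NULL,
                      prior_scale = 1, sequences = NULL, tol = 1e-6,
                      maxit = 500, init = NULL) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!all(is.finite(x))) abort("non-finite feature values in training data")
  y <- as_bound(labels)
  n <- nrow(x)
  if (length(y) != n) abort("labels do not match the number of rows")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w <= 0) || length(w) != n) abort("weights must be positive, one per row")
  if (sum(w[y]) <= 0 || sum(w[!y]) <= 0) {
    abort("both classes must be present with positive total weight")
  }
  fam <- rep("gaussian", ncol(x))
  names(fam) <- colnames(x)
  if (!is.null(families)) {
    unknown <- setdiff(names(families), colnames(x))
    if (length(unknown) > 0L) {
      abort(sprintf("families given for unknown feature '%s'", unknown[1L]))
    }
    fam[names(families)] <- unname(families)
  }
  if (!all(fam %in% c("gaussian", "bernoulli"))) {
    abort("families must be 'gaussian' or 'bernoulli'")
  }

  # internal standardisation of gaussian features for optimizer conditioning
  centers <- scales <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  design_cols <- list()
  design_map <- list()   # feature -> design column indices
  for (j in seq_len(ncol(x))) {
    nm <- colnames(x)[j]
    if (fam[j] == "gaussian") {
      # weighted moments so that duplicating a row == doubling its weight
      c_j <- sum(w * x[, j]) / sum(w)
      s_j <- sqrt(sum(w * (x[, j] - c_j)^2) / sum(w))
      if (!is.finite(s_j) || s_j < 1e-12) s_j <- 1
      centers[nm] <- c_j; scales[nm] <- s_j
      z <- (x[, j] - c_j) / s_j
      design_cols[[length(design_cols) + 1L]] <- z
      design_cols[[length(design_cols) + 1L]] <- z^2
      design_map[[nm]] <- length(design_cols) - c(1L, 0L)
    } else {
      if (!all(x[, j] %in% c(0, 1))) {
        abort(sprintf("bernoulli feature '%s' must be 0/1", nm))
      }
      design_cols[[length(design_cols) + 1L]] <- x[, j]
      design_map[[nm]] <- length(design_cols)
    }
  }
  X <- do.call(cbind, design_cols)

  markov3 <- NULL
  offset <- rep(0, n)
  if (!is.null(sequences)) {
    if (length(sequences) != n) abort("sequences do not match the number of rows")
    counts <- markov3_counts(sequences)
    lens <- nchar(sequences)
    tabB <- markov3_tables(counts[y, , drop = FALSE], w[y])
    tabU <- markov3_tables(counts[!y, , drop = FALSE], w[!y])
    offset <- markov3_seq_loglik(counts, tabB, lens) -
      markov3_seq_loglik(counts, tabU, lens)
    markov3 <- list(log_table_B = tabB, log_table_U = tabU)
  }

  p <- ncol(X)
  lambda <- 1 / prior_scale^2
  yv <- as.numeric(y)
  negobj <- function(theta) {
    d <- theta[1L] + drop(X %*% theta[-1L]) + offset
    lse <- pmax(d, 0) + log1p(exp(-abs(d)))   # stable log(1 + e^d)
    ll <- sum(w * (yv * d - lse))
    -(ll - lambda / 2 * sum(theta[-1L]^2))
  }
  neggrad <- function(theta) {
    d <- theta[1L] + drop(X %*% theta[-1L]) + offset
    r <- w * (yv - plogis(d))
    -c(sum(r), drop(crossprod(X, r)) - lambda * theta[-1L])
  }
  theta0 <- if (is.null(init)) rep(0, p + 1L) else as.numeric(init)
  if (length(theta0) != p + 1L) abort("init has the wrong length")
  opt <- optim(theta0, negobj, neggrad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-14))
  theta <- opt$par
  # Newton polish: the objective is strictly concave in this
  # parameterization, so a few exact-Hessian steps pin the optimum
  newton_it <- 0L
  repeat {
    g <- -neggrad(theta)
    if (sqrt(sum(g^2)) < tol || newton_it >= 50L) break
    d <- theta[1L] + drop(X %*% theta[-1L]) + offset
    pr <- plogis(d)
    s <- w * pr * (1 - pr)
    X1 <- cbind(1, X)
    H <- crossprod(X1 * s, X1)
    diag(H)[-1L] <- diag(H)[-1L] + lambda
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta + step
    if (negobj(cand) > negobj(theta) + 1e-12) {
      # damped fallback
      ok <- FALSE
      for (a in c(0.5, 0.25, 0.1, 0.01)) {
        if (negobj(theta + a * step) <= negobj(theta)) {
          cand <- theta + a * step; ok <- TRUE; break
        }
      }
      if (!ok) break
    }
    theta <- cand
    newton_it <- newton_it + 1L
  }
  grad_norm <- sqrt(sum(neggrad(theta)^2))
  if (!is.finite(grad_norm) || grad_norm > max(tol, 1e-4 * (1 + abs(negobj(theta))))) {
    abort(sprintf(
      "MCL optimisation did not converge: gradient norm %.3g after %d BFGS + %d Newton iterations (objective %.6g)",
      grad_norm, opt$counts[1L], newton_it, -negobj(theta)))
  }

  # ---- reconstruct per-class components in natural parameters ----
  intercept <- theta[1L]
  coefs <- theta[-1L]
  comp_B <- comp_U <- list()
  delta_const <- 0   # sum of (A_B - A_U) minus bernoulli constants
  for (nm in colnames(x)) {
    if (fam[nm] == "gaussian") {
      idx <- design_map[[nm]]
      a1 <- unname(coefs[idx[1L]]); a2 <- unname(coefs[idx[2L]])
      c_j <- unname(centers[nm]); s_j <- unname(scales[nm])
      d_eta1 <- a1 / s_j - 2 * a2 * c_j / s_j^2
      d_eta2 <- a2 / s_j^2
      # constant of the standardised quadratic, absorbed into the priors
      delta_const <- delta_const + (-a1 * c_j / s_j + a2 * c_j^2 / s_j^2)
      mom <- weighted_moments(x[, nm], w * as.numeric(!y))
      v_floor <- max(1e-6, 1e-4 * s_j^2)
      vU <- max(mom["var"], v_floor)
      eta2U <- -1 / (2 * vU)
      if (eta2U + d_eta2 >= -1e-10) eta2U <- -abs(d_eta2) - 0.5
      eta1U <- unname(mom["mean"]) * (-2 * eta2U)
      eta1B <- eta1U + d_eta1
      eta2B <- eta2U + d_eta2
      comp_U[[nm]] <- list(family = "gaussian", eta1 = eta1U, eta2 = eta2U)
      comp_B[[nm]] <- list(family = "gaussian", eta1 = eta1B, eta2 = eta2B)
      delta_const <- delta_const +
        gaussian_log_partition(eta1B, eta2B) - gaussian_log_partition(eta1U, eta2U)
    } else {
      idx <- design_map[[nm]]
      a <- unname(coefs[idx])
      pU <- sum(w * as.numeric(!y) * x[, nm]) / sum(w * as.numeric(!y))
      pU <- min(max(pU, 1e-6), 1 - 1e-6)
      logitU <- qlogis(pU)
      pB <- plogis(logitU + a)
      comp_U[[nm]] <- list(family = "bernoulli", logit = logitU)
      comp_B[[nm]] <- list(family = "bernoulli", logit = logitU + a)
      delta_const <- delta_const - (log1p(-pB) - log1p(-pU))
    }
  }
  beta_diff <- unname(intercept + delta_const)
  model <- structure(list(
    features = colnames(x), families = fam,
    centers = centers, scales = scales,
    components = list(B = comp_B, U = comp_U),
    beta = c(B = beta_diff / 2, U = -beta_diff / 2),
    markov3 = markov3,
    prior_scale = prior_scale,
    fit = list(objective = -negobj(theta), grad_norm = grad_norm,
               iterations = unname(opt$counts[1L]) + newton_it,
               n = n, n_pos = sum(y), n_neg = sum(!y),
               total_weight = sum(w)),
    theta = theta, design_map = design_map
  ), class = "mcl_model")
  model
}

#' @export
print.mcl_model <- function(x, ...) {
  cat(sprintf(
    "<mcl_model> %d features (%d gaussian, %d bernoulli)%s, objective %.4f\n",
    length(x$features), sum(x$families == "gaussian"),
    sum(x$families == "bernoulli"),
    if (is.null(x$markov3)) "" else " + markov3 sequence component",
    x$fit$objective))
  invisible(x)
}

#' Per-class log density of feature windows
#'
#' Sum of the independent per-feature log terms of one class's component
#' spec (Gaussian and Bernoulli components; plus the order-3 Markov
#' sequence term when the model has one and `sequences` are supplied).
#'
#' @param model An `mcl_model`.
#' @param x Data frame/matrix of features matching the training columns.
#' @param class `"B"` or `"U"`.
#' @param sequences Optional raw window sequences.
#' @return Numeric vector of log densities, one per row.
#' @export
log_density <- function(model, x, class = c("B", "U"), sequences = NULL) {
  class <- match.arg(class)
  x <- as.matrix(as.data.frame(x))
  if (is.null(colnames(x))) colnames(x) <- model$features
  missing <- setdiff(model$features, colnames(x))
  if (length(missing) > 0L) {
    abort(sprintf("feature '%s' missing from input", missing[1L]))
  }
  comp <- model$components[[class]]
  out <- rep(0, nrow(x))
  for (nm in model$features) {
    cc <- comp[[nm]]
    v <- x[, nm]
    if (cc$family == "gaussian") {
      out <- out + cc$eta1 * v + cc$eta2 * v^2 -
        gaussian_log_partition(cc$eta1, cc$eta2)
    } else {
      out <- out + cc$logit * v + log1p(-plogis(cc$logit))
    }
  }
  if (!is.null(model$markov3) && !is.null(sequences)) {
    counts <- markov3_counts(sequences)
    lens <- nchar(sequences)
    tab <- if (class == "B") model$markov3$log_table_B else model$markov3$log_table_U
    out <- out + markov3_seq_loglik(counts, tab, lens)
  }
  unname(out)
}

#' Posterior probability of binding
#'
#' `P(B | x)`, the logistic transform of the class log-prior difference
#' plus the log-density contrast of the two component specs.
#'
#' @inheritParams log_density
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
posterior <- function(model, x, sequences = NULL) {
  lb <- log_density(model, x, "B", sequences)
  lu <- log_density(model, x, "U", sequences)
  unname(plogis(unname(model$beta["B"] - model$beta["U"]) + lb - lu))
}

#' @export
predict.mcl_model <- function(object, newdata, sequences = NULL, ...) {
  unname(posterior(object, newdata, sequences))
}

#' Tidy method for `mcl_model`: one row per feature and class parameter
#' @param x An `mcl_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `family`, `term`, `class_B`, `class_U`,
#'   `contrast`.
#' @export
tidy.mcl_model <- function(x, ...) {
  purrr::map_dfr(x$features, function(nm) {
    b <- x$components$B[[nm]]; u <- x$components$U[[nm]]
    if (b$family == "gaussian") {
      tibble(feature = nm, family = "gaussian",
             term = c("eta1", "eta2"),
             class_B = c(b$eta1, b$eta2), class_U = c(u$eta1, u$eta2),
             contrast = c(b$eta1 - u$eta1, b$eta2 - u$eta2))
    } else {
      tibble(feature = nm, family = "bernoulli", term = "logit",
             class_B = b$logit, class_U = u$logit,
             contrast = b$logit - u$logit)
    }
  })
}

#' Glance method for `mcl_model`: one-row fit summary
#' @param x An `mcl_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.mcl_model <- function(x, ...) {
  tibble(
    n = x$fit$n, n_pos = x$fit$n_pos, n_neg = x$fit$n_neg,
    n_features = length(x$features),
    objective = x$fit$objective, grad_norm = x$fit$grad_norm,
    iterations = x$fit$iterations, prior_scale = x$prior_scale
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Serialise a fitted model to versioned JSON
#' @param model An `mcl_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    format = "peakcast-mcl", version = 1L,
    features = model$features, families = as.list(model$families),
    centers = as.list(model$centers), scales = as.list(model$scales),
    components = model$components,
    beta = as.list(model$beta),
    markov3 = if (is.null(model$markov3)) NULL else
      lapply(model$markov3, function(m) as.numeric(m)),
    prior_scale = model$prior_scale,
    fit = model$fit, theta = model$theta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path JSON model path.
#' @return An `mcl_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "peakcast-mcl")) abort("not a peakcast model file")
  fam <- unlist(p$families)
  markov3 <- NULL
  if (!is.null(p$markov3)) {
    markov3 <- lapply(p$markov3, function(v) matrix(v, nrow = 64, ncol = 4))
  }
  comps <- lapply(p$components, function(cls) {
    lapply(cls, function(cc) {
      cc$family <- as.character(cc$family)
      cc
    })
  })
  structure(list(
    features = p$features, families = fam,
    centers = unlist(p$centers)[p$features],
    scales = unlist(p$scales)[p$features],
    components = comps,
    beta = c(B = p$beta$B, U = p$beta$U),
    markov3 = markov3,
    prior_scale = p$prior_scale,
    fit = p$fit, theta = p$theta,
    design_map = NULL
  ), class = "mcl_model")
}
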