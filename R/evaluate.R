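# cumulative TP/FP at each distinct score threshold, highest score first
pr_points <- function(scores, labels) {
  y <- as_bound(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  # merge tied scores into one operating point
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(as.numeric(y))[last]
  fp <- cumsum(as.numeric(!y))[last]
  list(tp = tp, fp = fp, P = sum(y), N = sum(!y))
}

check_two_classes <- function(pp) {
  if (pp$P == 0L || pp$N == 0L) {
    abort("metrics need at least one positive and one negative example")
  }
}

#' Area under the precision-recall curve (continuous interpolation)
#'
#' Computes AUC-PR with the continuous (non-linear) interpolation between
#' operating points: along a segment the true and false positive counts
#' grow linearly, so precision follows a hyperbolic arc whose integral has
#' a closed form.  Tied scores form a single operating point.  This is the
#' interpolation used by the challenge evaluator, not the step-wise
#' average-precision estimate.
#'
#' @param scores Numeric prediction scores (larger = more bound).
#' @param labels `"B"`/`"U"` (or logical) labels; ambiguous windows must be
#'   removed beforehand.
#' @return AUC-PR in `[0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  pp <- pr_points(scores, labels)
  check_two_classes(pp)
  tp0 <- c(0, head(pp$tp, -1)); fp0 <- c(0, head(pp$fp, -1))
  dtp <- pp$tp - tp0; dfp <- pp$fp - fp0
  total <- 0
  for (k in seq_along(dtp)) {
    if (dtp[k] == 0) next
    A <- tp0[k] + fp0[k]; dA <- dtp[k] + dfp[k]
    seg <- if (A == 0) {
      dtp[k] / dA
    } else {
      dtp[k] / dA + (tp0[k] - A * dtp[k] / dA) / dA * log((A + dA) / A)
    }
    total <- total + dtp[k] / pp$P * seg
  }
  min(max(total, 0), 1)   # guard accumulated floating-point drift
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation with midrank tie handling,
#' equivalent to trapezoidal integration of the ROC curve.
#'
#' @inheritParams auc_pr
#' @return AUC-ROC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  y <- as_bound(labels)
  if (!any(y) || all(y)) {
    abort("metrics need at least one positive and one negative example")
  }
  r <- rank(scores)
  (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
}

#' Recall at a fixed false discovery rate
#'
#' Maximum recall over all score thresholds at which precision is at least
#' `1 - fdr`; 0 when no threshold qualifies.
#'
#' @inheritParams auc_pr
#' @param fdr Tolerated false discovery rate (e.g. 0.1 or 0.5).
#' @return Recall in `[0, 1]`.
#' @export
recall_at_fdr <- function(scores, labels, fdr) {
  pp <- pr_points(scores, labels)
  check_two_classes(pp)
  prec <- pp$tp / (pp$tp + pp$fp)
  ok <- prec >= 1 - fdr
  if (!any(ok)) return(0)
  max(pp$tp[ok]) / pp$P
}

#' Jaccard coefficient of two peak sets
#'
#' Total bp of the intersection over total bp of the union, after merging
#' overlapping intervals within each set.  Two empty sets give 0.
#'
#' @param a,b Peak tibbles.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard_peaks <- function(a, b) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  inter <- 0; uni <- 0
  for (ch in chroms) {
    ra <- a[a$chrom == ch, , drop = FALSE]
    rb <- b[b$chrom == ch, , drop = FALSE]
    ia <- IRanges::reduce(IRanges::IRanges(start = ra$start + 1, end = ra$end))
    ib <- IRanges::reduce(IRanges::IRanges(start = rb$start + 1, end = rb$end))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (uni == 0) 0 else inter / uni
}

#' Challenge-style evaluation of a window score track
#'
#' Joins predictions with window labels, drops ambiguous windows, and
#' computes AUC-PR (continuous interpolation), AUC-ROC, and recall at 10%
#' and 50% FDR.
#'
#' @param track A `prob_track` (or any tibble with `chrom`, `start`, `s`).
#' @param labels Labelled window tibble on the same grid.
#' @return A `binding_eval` object; [glance()] gives the one-row metric
#'   table, [tidy()] the PR operating points, [autoplot()] the PR curve.
#' @export
evaluate_predictions <- function(track, labels) {
  joined <- left_join(as_tibble(track)[, c("chrom", "start", "s")],
                      labels[, c("chrom", "start", "label")],
                      by = c("chrom", "start"))
  joined <- joined[!is.na(joined$label) & joined$label != "A", , drop = FALSE]
  pp <- pr_points(joined$s, joined$label)
  check_two_classes(pp)
  structure(list(
    auc_pr = auc_pr(joined$s, joined$label),
    auc_roc = auc_roc(joined$s, joined$label),
    recall_at_fdr10 = recall_at_fdr(joined$s, joined$label, 0.10),
    recall_at_fdr50 = recall_at_fdr(joined$s, joined$label, 0.50),
    n_pos = pp$P, n_neg = pp$N,
    curve = tibble(recall = pp$tp / pp$P,
                   precision = pp$tp / (pp$tp + pp$fp))
  ), class = "binding_eval")
}

#' @export
print.binding_eval <- function(x, ...) {
  cat(sprintf(
    "<binding_eval> AUC-PR %.4f | AUC-ROC %.4f | recall@10%%FDR %.4f | recall@50%%FDR %.4f (%d pos / %d neg)\n",
    x$auc_pr, x$auc_roc, x$recall_at_fdr10, x$recall_at_fdr50,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Glance method for `binding_eval`
#' @param x A `binding_eval`.
#' @param ... Unused.
#' @return One-row tibble of the four metrics and class counts.
#' @export
glance.binding_eval <- function(x, ...) {
  tibble(auc_pr = x$auc_pr, auc_roc = x$auc_roc,
         recall_at_fdr10 = x$recall_at_fdr10,
         recall_at_fdr50 = x$recall_at_fdr50,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy method for `binding_eval`: PR operating points
#' @param x A `binding_eval`.
#' @param ... Unused.
#' @return Tibble with `recall` and `precision`.
#' @export
tidy.binding_eval <- function(x, ...) x$curve

#' @export
autoplot.binding_eval <- function(object, ...) {
  prior <- object$n_pos / (object$n_pos + object$n_neg)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = prior, linetype = "dotted") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "recall", y = "precision",
      subtitle = sprintf("AUC-PR = %.3f (class prior %.3f)",
                         object$auc_pr, prior)) +
    ggplot2::theme_minimal()
}
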