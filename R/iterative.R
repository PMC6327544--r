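#' Select hard-negative windows above the positive 1% percentile
#'
#' Given window prediction scores and window labels, takes the scores of
#' all bound (`B`) windows, finds their 1% percentile — the
#' `ceiling(0.01 * n_B)`-th smallest `B` score — and selects every unbound
#' (`U`) window scoring strictly above it.  Ambiguous (`A`) windows are
#' never selected.
#'
#' @param scored Tibble with at least `s` (window score) and `label`
#'   columns (e.g., a `prob_track` joined with labels).
#' @param percentile Positive-score percentile defining the threshold.
#' @return The selected `U` rows of `scored`; attribute `"tau"` carries the
#'   threshold.
#' @export
select_additional_negatives <- function(scored, percentile = 0.01) {
  b_scores <- scored$s[scored$label == "B"]
  if (length(b_scores) == 0L) abort("no B-labelled windows: cannot set threshold")
  k <- ceiling(percentile * length(b_scores))
  tau <- sort(b_scores)[k]
  sel <- scored[scored$label == "U" & scored$s > tau, , drop = FALSE]
  attr(sel, "tau") <- tau
  sel
}

#' Iterative hard-negative training
#'
#' Five rounds of refinement: a classifier is trained on the current
#' training set, all previously trained classifiers predict window scores
#' on the selection chromosomes (scores averaged per window), unbound
#' windows scoring above the positives' 1% percentile are added to the
#' negative set with weight 1, and the next round's classifier is trained
#' on the enlarged set.  The positives never change and the negative set
#' grows monotonically; the result is one classifier per round.
#'
#' @param features Wide per-bin feature tibble.
#' @param bins A `bin_index`.
#' @param labels Labelled window tibble ([derive_labels()]) for the
#'   training chromosomes.
#' @param initial_set Initial training-region tibble
#'   ([initial_training_set()]).
#' @param width_bins Odd window width in bins.
#' @param n_rounds Number of rounds (and classifiers); default 5.
#' @param selection_chroms Chromosomes scanned for hard negatives; default
#'   all chromosomes present in `labels` (restricting to a subset is a
#'   runtime economy on large genomes).
#' @param prior_scale Prior scale passed to [train_mcl()].
#' @param percentile Positive-score percentile for the selection threshold.
#' @return An `iterative_fit`: list with `models` (one `mcl_model` per
#'   round), `training_set` (final, with provenance), `audit` (per-round
#'   tibble of threshold and addition counts), `additions` (per-round
#'   tibbles of the added negatives with their window scores and the
#'   threshold), `width_bins`.
#' @export
iterative_train <- function(features, bins, labels, initial_set, width_bins,
                            n_rounds = 5, selection_chroms = NULL,
                            prior_scale = 1, percentile = 0.01) {
  selection_chroms <- selection_chroms %||% unique(labels$chrom)
  if (!all(selection_chroms %in% unique(labels$chrom))) {
    abort("selection_chroms must be labelled training chromosomes")
  }
  train_set <- initial_set
  models <- list()
  audit <- list()
  additions <- list()
  lab_sel <- labels[labels$chrom %in% selection_chroms, , drop = FALSE]
  # P_i is computed for every model on the same candidate grid; assemble once
  fw_all <- feature_window_matrix(features, bins, width_bins,
                                  chroms = selection_chroms)
  bin_grid <- purrr::map_dfr(selection_chroms, function(ch) {
    tibble(chrom = ch, bin = seq_len(bins$n_bins[[ch]]) - 1L)
  })
  key_grid <- paste(bin_grid$chrom, bin_grid$bin)
  key_ctr <- paste(fw_all$centers$chrom, fw_all$centers$bin)
  ctr_rows <- match(key_ctr, key_grid)
  p_per_model <- list()

  for (r in seq_len(n_rounds)) {
    fw_train <- feature_window_matrix(features, bins, width_bins,
                                      centers = train_set)
    key_train <- paste(fw_train$centers$chrom, fw_train$centers$bin)
    # aggregate duplicate centre bins across schemas by summing weights
    agg <- train_set |>
      group_by(.data$chrom, .data$bin, .data$label) |>
      summarise(weight = sum(.data$weight), .groups = "drop")
    key_agg <- paste(agg$chrom, agg$bin)
    m_rows <- match(key_train, key_agg)
    fams <- window_families(colnames(fw_train$x))
    model <- train_mcl(fw_train$x, agg$label[m_rows], agg$weight[m_rows],
                       families = fams, prior_scale = prior_scale)
    models[[r]] <- model

    if (r < n_rounds) {
      pvec <- rep(0, nrow(bin_grid))
      pvec[ctr_rows] <- posterior(model, fw_all$x)
      p_per_model[[r]] <- pvec
      p_avg <- Reduce(`+`, p_per_model) / length(p_per_model)
      pb <- bin_grid
      # per-model window scores averaged across rounds 1..r
      tracks <- purrr::map(p_per_model, function(pv) {
        pb$p <- pv
        track_from_posteriors(pb, bins, width_bins)
      })
      track <- ensemble_average(tracks)
      scored <- left_join(track,
                          lab_sel[, c("chrom", "start", "label")],
                          by = c("chrom", "start"))
      scored <- scored[!is.na(scored$label), , drop = FALSE]
      sel <- select_additional_negatives(scored, percentile)
      tau <- attr(sel, "tau")
      new_neg <- hard_negative_centers(sel, p_avg, bin_grid, bins, width_bins)
      existing <- paste(train_set$chrom, train_set$bin)[train_set$label == "U"]
      new_neg <- new_neg[!(paste(new_neg$chrom, new_neg$bin) %in% existing), ,
                         drop = FALSE]
      audit[[r]] <- tibble(round = r, tau = tau, n_selected = nrow(sel),
                           n_added = nrow(new_neg),
                           n_negatives = sum(train_set$label == "U") + nrow(new_neg))
      additions[[r]] <- mutate(new_neg, tau = tau)
      train_set <- bind_rows(train_set,
                             select(new_neg, -"window_score"))
    } else {
      audit[[r]] <- tibble(round = r, tau = NA_real_, n_selected = NA_integer_,
                           n_added = 0L,
                           n_negatives = sum(train_set$label == "U"))
    }
  }
  structure(list(models = models, training_set = train_set,
                 audit = bind_rows(audit), additions = additions,
                 width_bins = width_bins),
            class = "iterative_fit")
}

# map selected hard-negative windows to centre bins: the bin with maximal
# averaged posterior among the window's own bins (leftmost tie), restricted
# to representable centres; one entry per window, deduplicated
hard_negative_centers <- function(sel, p_avg, bin_grid, bins, width_bins,
                                  window = 200) {
  if (nrow(sel) == 0L) {
    return(tibble(chrom = character(), bin = integer(), label = character(),
                  weight = numeric(), provenance = character(),
                  window_score = numeric()))
  }
  w <- bins$bin_width
  wb <- as.integer(window / w)
  key_grid <- paste(bin_grid$chrom, bin_grid$bin)
  picks <- purrr::map_int(seq_len(nrow(sel)), function(i) {
    ch <- sel$chrom[i]
    i0 <- as.integer(sel$start[i] / w)
    cand <- i0:(i0 + wb - 1L)
    cand <- cand[cand %in% valid_center_range(bins$n_bins[[ch]], width_bins)]
    if (length(cand) == 0L) return(NA_integer_)
    pv <- p_avg[match(paste(ch, cand), key_grid)]
    cand[which.max(pv)]
  })
  out <- tibble(chrom = sel$chrom, bin = picks, label = "U", weight = 1,
                provenance = "iterative", window_score = sel$s)
  out <- out[!is.na(out$bin), , drop = FALSE]
  distinct(out, .data$chrom, .data$bin, .keep_all = TRUE)
}

#' @export
print.iterative_fit <- function(x, ...) {
  cat(sprintf("<iterative_fit> %d rounds, final training set: %d positives, %d negatives\n",
              length(x$models), sum(x$training_set$label == "B"),
              sum(x$training_set$label == "U")))
  invisible(x)
}

#' Tidy method for `iterative_fit`: the per-round audit table
#' @param x An `iterative_fit`.
#' @param ... Unused.
#' @return Tibble with one row per round (`round`, `tau`, `n_selected`,
#'   `n_added`, `n_negatives`).
#' @export
tidy.iterative_fit <- function(x, ...) x$audit

#' Glance method for `iterative_fit`
#' @param x An `iterative_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.iterative_fit <- function(x, ...) {
  tibble(n_rounds = length(x$models),
         width_bins = x$width_bins,
         n_pos = sum(x$training_set$label == "B"),
         n_neg_initial = x$audit$n_negatives[1L] - x$audit$n_added[1L],
         n_neg_final = sum(x$training_set$label == "U"))
}
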