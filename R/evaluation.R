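#' Leave-one-out cross-validation of the subspace classifier
#'
#' Each subject is scored by a model trained on all other subjects: the
#' held-out subject's feature vector never enters the training SVD. Scores
#' are collected in cohort order and summarized by the AUC and the
#' specificity at 100% sensitivity.
#'
#' @param cohort A `mw_cohort`.
#' @param config A [classifier_config()].
#' @param labels Optional label override (character vector of `"cSDH"` /
#'   `"HC"` in cohort order); used by the random-diagnosis null analysis.
#'   Defaults to the cohort's true labels.
#' @param features Optional precomputed feature matrix from
#'   [cohort_features()] (must match `config`); avoids recomputing features
#'   in repeated calls.
#' @return A `mw_evaluation`: list with `scores` (data frame
#'   `subject_id,label,score` in cohort order, plus `total_volume` when the
#'   cohort carries it), `auc`, `spec_at_full_sens`, `roc` and `config`.
#' @export
loo_cross_validate <- function(cohort, config = classifier_config(),
                               labels = NULL, features = NULL) {
  X <- if (is.null(features)) {
    cohort_features(cohort, mask = config$mask,
                    f_lo = config$f_lo, f_hi = config$f_hi)
  } else features
  labs <- if (is.null(labels)) attr(X, "labels") else labels
  if (length(labs) != ncol(X)) {
    stop("labels length does not match cohort size", call. = FALSE)
  }
  scores <- loo_scores(X, labs, config)

  ids <- colnames(X)
  vols <- vapply(cohort$subjects, function(s) {
    v <- s$meta$total_volume
    if (is.null(v)) NA_real_ else v
  }, 1)
  df <- data.frame(subject_id = ids, label = labs, score = scores,
                   stringsAsFactors = FALSE)
  if (!all(is.na(vols))) df$total_volume <- vols

  roc <- roc_curve(scores, labs)
  structure(list(scores = df,
                 auc = auc(scores, labs),
                 spec_at_full_sens = specificity_at_full_sensitivity(scores, labs),
                 roc = roc,
                 config = config),
            class = "mw_evaluation")
}

# Core LOO loop on a prebuilt feature matrix.
loo_scores <- function(X, labs, config) {
  r <- config$rank
  for (k in c("cSDH", "HC")) {
    if (sum(labs == k) < r + 1L) {
      stop(sprintf("class %s has %d subjects; leave-one-out with rank %d needs >= %d",
                   k, sum(labs == k), r, r + 1L), call. = FALSE)
    }
  }
  n <- ncol(X)
  vapply(seq_len(n), function(i) {
    tr_labs <- labs[-i]
    model <- fit_subspace(X[, -i, drop = FALSE][, tr_labs == "cSDH", drop = FALSE],
                          X[, -i, drop = FALSE][, tr_labs == "HC", drop = FALSE],
                          config)
    decision_value(model, X[, i])
  }, 1)
}

#' @export
print.mw_evaluation <- function(x, ...) {
  cat(sprintf("<leave-one-out evaluation: %d subjects, AUC %.3f, specificity %.0f%% at 100%% sensitivity>\n",
              nrow(x$scores), x$auc, 100 * x$spec_at_full_sens))
  invisible(x)
}

check_binary <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  n_pos <- sum(labels == "cSDH")
  n_neg <- sum(labels == "HC")
  if (n_pos + n_neg != length(labels)) {
    stop("labels must be 'cSDH' or 'HC'", call. = FALSE)
  }
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one subject of each class", call. = FALSE)
  }
  list(pos = scores[labels == "cSDH"], neg = scores[labels == "HC"])
}

#' ROC curve from decision values
#'
#' The curve is traced by sweeping the decision threshold over all observed
#' operating points: for each distinct score `s` the classifier with
#' threshold just below `s` calls positive every subject with score
#' `>= s` (this matches the [classify()] tie rule "positive iff
#' `score > threshold`"). A sentinel threshold above the maximum score
#' contributes the `(0, 0)` endpoint; the smallest score contributes
#' `(1, 1)`. Positive class is `cSDH`; TPR is sensitivity, FPR is
#' `1 - specificity`.
#'
#' @param scores Numeric decision values.
#' @param labels Parallel character labels (`"cSDH"` / `"HC"`).
#' @return A `mw_roc` data frame with columns `threshold` (the operating
#'   score value; `Inf` for the sentinel), `fpr`, `tpr`; `(0,0)` first,
#'   `(1,1)` last, both coordinates non-decreasing.
#' @examples
#' roc_curve(c(2, 3, 0, 1), c("cSDH", "cSDH", "HC", "HC"))
#' @export
roc_curve <- function(scores, labels) {
  g <- check_binary(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(g$pos >= t), 1)
  fpr <- vapply(thr, function(t) mean(g$neg >= t), 1)
  structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr),
            class = c("mw_roc", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the curve of [roc_curve()]. Equals the normalized
#' Mann-Whitney statistic: the fraction of (positive, negative) pairs ranked
#' correctly, ties counting one half.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(2, 3, 0, 1), c("cSDH", "cSDH", "HC", "HC"))  # 1
#' @export
auc <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Specificity at 100% sensitivity
#'
#' The most permissive threshold that still detects every positive subject
#' sits strictly below the minimum positive score. At that threshold a
#' negative subject is correctly rejected iff its score is strictly below
#' the minimum positive score; negatives tied with it are false positives,
#' consistent with the [classify()] tie rule.
#'
#' @inheritParams roc_curve
#' @return Fraction of negatives rejected, in `[0, 1]`.
#' @export
specificity_at_full_sensitivity <- function(scores, labels) {
  g <- check_binary(scores, labels)
  mean(g$neg < min(g$pos))
}

#' @export
plot.mw_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Decision-value scatter plot
#'
#' Plots per-subject leave-one-out decision values: patients first, in
#' increasing order of total hematoma volume when volumes are available,
#' then controls in cohort order. The dashed line marks the most permissive
#' threshold detecting every patient.
#'
#' @param x A `mw_evaluation`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mw_evaluation <- function(x, ...) {
  df <- x$scores
  pos <- df[df$label == "cSDH", ]
  neg <- df[df$label == "HC", ]
  if (!is.null(pos$total_volume) && !all(is.na(pos$total_volume))) {
    pos <- pos[order(pos$total_volume), ]
  }
  ord <- rbind(pos, neg)
  graphics::plot(seq_len(nrow(ord)), ord$score,
                 pch = ifelse(ord$label == "cSDH", 19, 1),
                 xlab = "Subject (patients by increasing hematoma volume, then controls)",
                 ylab = "Decision value", ...)
  thr <- min(pos$score) - .Machine$double.eps^0.5
  graphics::abline(h = thr, lty = 2)
  invisible(x)
}

#' Frequency-interval and subspace-rank model selection
#'
#' Enumerates every frequency interval whose endpoints lie on the sweep grid
#' and whose width is at least `min_width`, runs a leave-one-out evaluation
#' for each interval and candidate rank, and selects settings in two steps:
#' the rank with the highest AUC *averaged over all intervals*, then, at
#' that rank, the interval with the highest specificity at 100% sensitivity.
#' Deterministic tie-breaks: lower rank, then wider interval, then lower
#' `f_lo`.
#'
#' At the default grid (0.10-1.95 GHz, 50 MHz step, 400 MHz minimum width)
#' there are 465 candidate intervals, so a full sweep runs 465 leave-one-out
#' evaluations per rank; coarser `step` values give proportionally cheaper
#' sweeps.
#'
#' @param cohort A `mw_cohort`.
#' @param f_start,f_stop Sweep range, GHz.
#' @param step Endpoint grid spacing, GHz.
#' @param min_width Minimum interval width, GHz (must be >= `step`).
#' @param ranks Candidate subspace ranks.
#' @param mask Channel mask used for all candidates.
#' @return A `mw_sweep`: list with `table` (data frame
#'   `f_lo,f_hi,rank,auc,spec_at_full_sens`), `selected_rank`,
#'   `selected_interval` (named vector `f_lo`, `f_hi`), `mean_auc_by_rank`
#'   and the selected row's metrics.
#' @export
sweep_model_selection <- function(cohort, f_start = 0.10, f_stop = 1.95,
                                  step = 0.05, min_width = 0.40,
                                  ranks = 1:3,
                                  mask = default_exclusion_mask()) {
  if (min_width < step) stop("min_width must be >= step", call. = FALSE)
  grid_pts <- f_start + step * 0:floor((f_stop - f_start) / step + 1e-9)
  tol <- min(diff(cohort$freq_grid)) / 2
  if (!all(vapply(grid_pts, function(p) any(abs(cohort$freq_grid - p) <= tol), TRUE))) {
    stop("sweep grid extends beyond the cohort's frequency grid", call. = FALSE)
  }
  pairs <- enumerate_intervals(grid_pts, min_width)
  if (nrow(pairs) == 0L) stop("no candidate intervals", call. = FALSE)

  # Features over the full band once; each interval is a row subset.
  X_full <- cohort_features(cohort, mask = mask,
                            f_lo = min(cohort$freq_grid),
                            f_hi = max(cohort$freq_grid))
  labs <- attr(X_full, "labels")
  sel_full <- attr(X_full, "layout")$selection
  n_ch <- nrow(mask)
  n_f <- length(sel_full$indices)
  freq_of_row <- rep(sel_full$freqs, times = n_ch)

  half <- tol
  rows <- vector("list", nrow(pairs) * length(ranks))
  k <- 0L
  for (ri in seq_along(ranks)) {
    cfg_r <- ranks[ri]
    for (pi in seq_len(nrow(pairs))) {
      lo <- pairs$f_lo[pi]; hi <- pairs$f_hi[pi]
      keep <- freq_of_row >= lo - half & freq_of_row <= hi + half
      Xi <- X_full[keep, , drop = FALSE]
      sc <- loo_scores(Xi, labs, classifier_config(rank = cfg_r, f_lo = lo,
                                                   f_hi = hi, mask = mask))
      k <- k + 1L
      rows[[k]] <- data.frame(
        f_lo = lo, f_hi = hi, rank = cfg_r,
        auc = auc(sc, labs),
        spec_at_full_sens = specificity_at_full_sensitivity(sc, labs))
    }
  }
  tab <- do.call(rbind, rows)

  mean_auc <- tapply(tab$auc, tab$rank, mean)
  rank_order <- order(-mean_auc, as.numeric(names(mean_auc)))
  sel_rank <- as.integer(names(mean_auc)[rank_order[1L]])

  cand <- tab[tab$rank == sel_rank, ]
  cand <- cand[order(-cand$spec_at_full_sens, -(cand$f_hi - cand$f_lo), cand$f_lo), ]
  best <- cand[1L, ]

  structure(list(table = tab,
                 selected_rank = sel_rank,
                 selected_interval = c(f_lo = best$f_lo, f_hi = best$f_hi),
                 selected_auc = best$auc,
                 selected_spec_at_full_sens = best$spec_at_full_sens,
                 mean_auc_by_rank = mean_auc),
            class = "mw_sweep")
}

#' Enumerate candidate frequency intervals
#'
#' All `(f_lo, f_hi)` pairs with both endpoints on the sweep grid and width
#' at least `min_width` (half-step tolerance on the width comparison).
#'
#' @param grid_pts Sweep endpoint grid, GHz.
#' @param min_width Minimum width, GHz.
#' @return Data frame with columns `f_lo`, `f_hi`.
#' @examples
#' nrow(enumerate_intervals(seq(0.10, 1.95, by = 0.05), 0.40))  # 465
#' @export
enumerate_intervals <- function(grid_pts, min_width) {
  step <- if (length(grid_pts) > 1L) min(diff(grid_pts)) else min_width
  idx <- which(outer(grid_pts, grid_pts,
                     function(lo, hi) hi - lo >= min_width - step / 2),
               arr.ind = TRUE)
  out <- data.frame(f_lo = grid_pts[idx[, 1L]], f_hi = grid_pts[idx[, 2L]])
  out <- out[order(out$f_lo, out$f_hi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mw_sweep <- function(x, ...) {
  cat(sprintf("<model-selection sweep: %d (interval, rank) candidates>\n",
              nrow(x$table)))
  cat(sprintf("  selected rank %d (mean AUC %.3f over intervals)\n",
              x$selected_rank, x$mean_auc_by_rank[[as.character(x$selected_rank)]]))
  cat(sprintf("  selected interval %.2f-%.2f GHz: AUC %.3f, specificity %.0f%% at 100%% sensitivity\n",
              x$selected_interval[["f_lo"]], x$selected_interval[["f_hi"]],
              x$selected_auc, 100 * x$selected_spec_at_full_sens))
  invisible(x)
}
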