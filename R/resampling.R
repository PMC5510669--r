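#' Robustness of the classification under random subject removal
#'
#' Repeats the leave-one-out evaluation on data sets from which `k` randomly
#' chosen subjects have been removed (by default without regard to class),
#' recording the AUC of each iteration. A mean AUC close to the full-cohort
#' AUC with a small standard deviation indicates that the chosen
#' preprocessing and classifier settings do not hinge on the exact
#' composition of the cohort.
#'
#' A master seed spawns one substream seed per iteration, so results do not
#' depend on iteration scheduling and are a pure function of
#' `(cohort, config, k, n_iterations, seed)`.
#'
#' @param cohort A `mw_cohort`.
#' @param config A [classifier_config()].
#' @param k Subjects removed per iteration (`k = 0` reproduces the
#'   full-cohort AUC in every iteration).
#' @param n_iterations Number of repeated evaluations.
#' @param seed Master seed.
#' @param stratified If `TRUE`, removals are split as evenly as possible
#'   between the classes instead of drawn from the pooled cohort.
#' @return A `mw_resampling`: list with `mode`, `n_iterations`, `aucs`,
#'   `mean_auc`, `sd_auc` (n - 1 denominator) and `seed`.
#' @export
robustness_remove_k <- function(cohort, config = classifier_config(),
                                k = 2, n_iterations = 100, seed = 1,
                                stratified = FALSE) {
  labs <- cohort_labels(cohort)
  n <- length(labs)
  k <- as.integer(k)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (k >= n - 2L) stop("k must leave at least 3 subjects", call. = FALSE)
  r <- config$rank
  if (min(table(labs)) - k < r + 1L) {
    stop(sprintf("removing %d subjects could leave a class below the %d needed for rank-%d leave-one-out",
                 k, r + 1L, r), call. = FALSE)
  }
  X <- cohort_features(cohort, mask = config$mask,
                       f_lo = config$f_lo, f_hi = config$f_hi)

  iter_seeds <- substream_seeds(seed, n_iterations)
  aucs <- vapply(seq_len(n_iterations), function(i) {
    set.seed(iter_seeds[i])
    keep <- if (k == 0L) seq_len(n) else {
      if (stratified) {
        drop_pos <- sample(which(labs == "cSDH"), ceiling(k / 2))
        drop_neg <- sample(which(labs == "HC"), floor(k / 2))
        setdiff(seq_len(n), c(drop_pos, drop_neg))
      } else {
        setdiff(seq_len(n), sample.int(n, k))
      }
    }
    sc <- loo_scores(X[, keep, drop = FALSE], labs[keep], config)
    auc(sc, labs[keep])
  }, 1)

  new_resampling("remove_k", aucs, seed, k = k)
}

#' Random-diagnosis null analysis (label-permutation bias check)
#'
#' Validates that the classifier is not structurally biased: each iteration
#' assigns every subject an independent fair-coin class label regardless of
#' the true diagnosis, runs the leave-one-out evaluation against the
#' reassigned labels, and records the AUC. If the pipeline only learns real
#' class structure, the mean null AUC is near 0.5 (chance).
#'
#' An assignment leaving either class with fewer than `rank + 2` subjects is
#' redrawn (the model could not be fitted); the redraw count is returned.
#' A `balanced` variant permutes the true label vector instead, preserving
#' class sizes.
#'
#' @inheritParams robustness_remove_k
#' @param balanced If `TRUE`, use a balanced label permutation instead of
#'   independent fair coins.
#' @return A `mw_resampling`; see [robustness_remove_k()]. Includes
#'   `n_redraws`.
#' @export
random_diagnosis_null <- function(cohort, config = classifier_config(),
                                  n_iterations = 100, seed = 1,
                                  balanced = FALSE) {
  if (n_iterations < 2) {
    stop("n_iterations must be >= 2 (standard deviation undefined otherwise)",
         call. = FALSE)
  }
  labs <- cohort_labels(cohort)
  n <- length(labs)
  r <- config$rank
  min_class <- r + 2L
  X <- cohort_features(cohort, mask = config$mask,
                       f_lo = config$f_lo, f_hi = config$f_hi)

  iter_seeds <- substream_seeds(seed, n_iterations)
  n_redraws <- 0L
  aucs <- vapply(seq_len(n_iterations), function(i) {
    set.seed(iter_seeds[i])
    repeat {
      new_labs <- if (balanced) {
        sample(labs)
      } else {
        ifelse(stats::runif(n) < 0.5, "cSDH", "HC")
      }
      if (sum(new_labs == "cSDH") >= min_class &&
          sum(new_labs == "HC") >= min_class) break
      n_redraws <<- n_redraws + 1L
    }
    sc <- loo_scores(X, new_labs, config)
    auc(sc, new_labs)
  }, 1)

  new_resampling("random_diagnosis", aucs, seed, n_redraws = n_redraws)
}

substream_seeds <- function(seed, n) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

new_resampling <- function(mode, aucs, seed, ...) {
  structure(list(mode = mode, n_iterations = length(aucs), aucs = aucs,
                 mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 seed = seed, ...),
            class = "mw_resampling")
}

#' @export
print.mw_resampling <- function(x, ...) {
  cat(sprintf("<%s resampling: %d iterations, mean AUC %.2f +/- %.2f>\n",
              x$mode, x$n_iterations, x$mean_auc, x$sd_auc))
  invisible(x)
}
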