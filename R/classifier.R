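#' Classifier configuration
#'
#' Bundles the settings of the rank-truncated subspace classifier: the
#' number of retained subspace dimensions per class, the frequency interval
#' the features are built from, and the channel mask. The defaults are the
#' settings used throughout the analyses: rank 1 ("first subspace
#' dimension"), 0.75-1.95 GHz, and the device's exclusion mask.
#'
#' @param rank Retained subspace dimensions per class (>= 1). Enforced
#'   against class sizes at fit time.
#' @param f_lo,f_hi Frequency interval, GHz.
#' @param mask A `mw_channel_mask`.
#' @param center If `TRUE`, subtract the class mean before the SVD (affine
#'   subspaces). Default `FALSE`: subspaces pass through the origin, which
#'   makes decision values exactly invariant to global complex rescaling of
#'   a measurement.
#' @return A list of class `mw_classifier_config`.
#' @export
classifier_config <- function(rank = 1, f_lo = 0.75, f_hi = 1.95,
                              mask = default_exclusion_mask(),
                              center = FALSE) {
  if (length(rank) != 1L || is.na(rank) || rank < 1 || rank != round(rank)) {
    stop("`rank` must be a single integer >= 1", call. = FALSE)
  }
  if (f_lo >= f_hi) stop("need f_lo < f_hi", call. = FALSE)
  structure(list(rank = as.integer(rank), f_lo = f_lo, f_hi = f_hi,
                 mask = mask, center = isTRUE(center)),
            class = "mw_classifier_config")
}

#' Fit per-class signal subspaces
#'
#' For each class the training feature vectors are stacked as the columns of
#' a complex matrix, its singular value decomposition is computed, and the
#' `rank` leading left singular vectors are retained as an orthonormal basis
#' of the class subspace. Basis columns are ordered by decreasing singular
#' value.
#'
#' @param train_pos Complex matrix, features x subjects, of the positive
#'   (cSDH) training class.
#' @param train_neg Complex matrix of the negative (HC) training class.
#' @param config A [classifier_config()]. Only `rank` and `center` are used
#'   here; the frequency interval and mask describe how the features were
#'   built.
#' @return A `mw_subspace_model`: list with `basis` (per-class orthonormal
#'   feature_dim x rank complex matrices, names `cSDH` and `HC`),
#'   `n_train`, `center` (per-class means, or NULL), and `config`.
#' @export
fit_subspace <- function(train_pos, train_neg, config = classifier_config()) {
  train_pos <- as.matrix(train_pos)
  train_neg <- as.matrix(train_neg)
  if (nrow(train_pos) != nrow(train_neg)) {
    stop("training classes have different feature dimensions", call. = FALSE)
  }
  r <- config$rank
  classes <- list(cSDH = train_pos, HC = train_neg)
  need <- max(2L, r)
  centers <- if (config$center) list() else NULL
  basis <- lapply(names(classes), function(k) {
    X <- classes[[k]]
    if (ncol(X) < need) {
      stop(sprintf("class %s has %d training vectors; need >= %d for rank %d",
                   k, ncol(X), need, r), call. = FALSE)
    }
    if (config$center) {
      mu <- rowMeans(X)
      X <- X - mu
      centers[[k]] <<- mu
    }
    sv <- svd(X, nu = min(ncol(X), r), nv = 0)
    if (sv$d[1L] <= nrow(X) * ncol(X) * .Machine$double.eps) {
      stop(sprintf("class %s training matrix is degenerate (all singular values ~ 0)", k),
           call. = FALSE)
    }
    if (sv$d[r] <= sv$d[1L] * 1e-12) {
      # rank-deficient training set: retained dimensions must carry signal
      stop(sprintf("class %s training matrix has rank < %d", k, r),
           call. = FALSE)
    }
    sv$u[, seq_len(r), drop = FALSE]
  })
  names(basis) <- names(classes)
  structure(list(basis = basis,
                 n_train = c(cSDH = ncol(train_pos), HC = ncol(train_neg)),
                 center = centers,
                 config = config),
            class = "mw_subspace_model")
}

#' @export
print.mw_subspace_model <- function(x, ...) {
  cat(sprintf("<subspace model: rank %d, feature dim %d, trained on %d cSDH + %d HC>\n",
              x$config$rank, nrow(x$basis$cSDH),
              x$n_train[["cSDH"]], x$n_train[["HC"]]))
  invisible(x)
}

# Relative projection residual of columns of X onto basis U (Hermitian).
proj_residual <- function(U, X, mu = NULL) {
  if (!is.null(mu)) X <- X - mu
  coef <- crossprod(Conj(U), X)          # U^H X, rank x n
  R <- X - U %*% coef
  sqrt(colSums(Mod(R)^2)) / sqrt(colSums(Mod(X)^2))
}

#' Classifier decision value
#'
#' Scores a measurement by the difference of its relative projection
#' residuals onto the two class subspaces:
#' `d_k(x) = ||x - U_k U_k^H x|| / ||x||` and the decision value is
#' `d_HC(x) - d_cSDH(x)`. Larger values are more cSDH-like (the measurement
#' sits closer to the patient subspace than to the control subspace). The
#' `||x||` normalization makes scores comparable across subjects with
#' different overall signal amplitude, and the score is invariant to
#' multiplying `x` by any non-zero complex scalar.
#'
#' @param model A `mw_subspace_model`.
#' @param x A complex feature vector, or a feature x subjects matrix to
#'   score several subjects at once.
#' @return Numeric decision value(s), one per column of `x`.
#' @export
decision_value <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  if (nrow(X) != nrow(model$basis$cSDH)) {
    stop(sprintf("feature dimension mismatch: model %d, input %d",
                 nrow(model$basis$cSDH), nrow(X)), call. = FALSE)
  }
  nx <- sqrt(colSums(Mod(X)^2))
  if (any(nx == 0)) stop("zero feature vector cannot be scored", call. = FALSE)
  d_pos <- proj_residual(model$basis$cSDH, X, model$center$cSDH)
  d_neg <- proj_residual(model$basis$HC, X, model$center$HC)
  unname(d_neg - d_pos)
}

#' Threshold a decision value into a class label
#'
#' A subject is called `cSDH` iff its decision value strictly exceeds the
#' threshold; a tie (equality) yields `HC`, so a tie never triggers a
#' positive call. ROC construction uses the same orientation.
#'
#' @param model A `mw_subspace_model`.
#' @param x Feature vector or matrix (see [decision_value()]).
#' @param threshold Decision threshold.
#' @return Character label(s), `"cSDH"` or `"HC"`.
#' @export
classify <- function(model, x, threshold = 0) {
  ifelse(decision_value(model, x) > threshold, "cSDH", "HC")
}
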