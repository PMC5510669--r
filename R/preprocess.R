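#' Average a subject's repeated measurements
#'
#' The device records several consecutive measurements per subject; they are
#' combined by the element-wise arithmetic mean of the complex matrices
#' (coherent averaging, preserving phase). Magnitude averaging, which
#' discards phase, is available for sensitivity checks.
#'
#' @param m A subject from a `mw_cohort` (a list with `$repetitions`), or a
#'   plain list of equally shaped complex matrices.
#' @param method `"coherent"` (default) averages complex values;
#'   `"magnitude"` averages `Mod()` of the values (result is real-valued).
#' @return One complex matrix, channels by frequencies.
#' @export
average_repetitions <- function(m, method = c("coherent", "magnitude")) {
  method <- match.arg(method)
  reps <- if (is.list(m) && !is.null(m$repetitions)) m$repetitions else m
  if (!is.list(reps) || length(reps) < 1L) {
    stop("need at least one repetition", call. = FALSE)
  }
  dims <- lapply(reps, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("repetition matrices have mismatching shapes", call. = FALSE)
  }
  if (method == "magnitude") reps <- lapply(reps, Mod)
  Reduce(`+`, reps) / length(reps)
}

#' Select a closed frequency interval on a measurement grid
#'
#' Grid points within `[f_lo, f_hi]` are retained, with half-step tolerance
#' at both endpoints so that nominal interval bounds (e.g. 0.75 GHz on a
#' 50 MHz grid) are immune to floating-point representation of the grid.
#'
#' @param grid Strictly increasing frequency grid, GHz.
#' @param f_lo,f_hi Interval bounds in GHz, `f_lo < f_hi`.
#' @return A `mw_freq_selection`: list with `f_lo`, `f_hi`, `indices`
#'   (positions into `grid`, increasing) and `freqs` (the selected values).
#' @examples
#' sel <- select_frequencies(seq(0.10, 1.95, by = 0.05), 0.75, 1.95)
#' length(sel$indices)  # 25
#' @export
select_frequencies <- function(grid, f_lo, f_hi) {
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  if (!(is.numeric(f_lo) && is.numeric(f_hi)) || f_lo >= f_hi) {
    stop("need f_lo < f_hi (got ", f_lo, " >= ", f_hi, ")", call. = FALSE)
  }
  half_step <- if (length(grid) > 1L) stats::median(diff(grid)) / 2 else 0
  idx <- which(grid >= f_lo - half_step & grid <= f_hi + half_step)
  if (length(idx) == 0L) {
    stop(sprintf("no grid points in [%g, %g] GHz", f_lo, f_hi), call. = FALSE)
  }
  structure(list(f_lo = f_lo, f_hi = f_hi, indices = idx, freqs = grid[idx]),
            class = "mw_freq_selection")
}

#' Assemble the complex feature vector of one subject
#'
#' Concatenates the selected frequencies of the retained channels of an
#' averaged measurement into one complex vector. Layout is fixed and
#' channel-major: channels in canonical mask order, each contributing its
#' selected frequencies in increasing order, so the vector length is
#' `nrow(mask) * length(sel$indices)`.
#'
#' @param mean_matrix Averaged complex matrix with channel-key row names
#'   (see [average_repetitions()]).
#' @param mask A non-empty `mw_channel_mask` whose channels all exist in
#'   `mean_matrix`.
#' @param sel A `mw_freq_selection` for the matrix's frequency grid.
#' @return Complex vector with attributes `subject layout` recorded via
#'   names: element names are `"a-b@f"`.
#' @export
assemble_feature_vector <- function(mean_matrix, mask, sel) {
  if (nrow(mask) == 0L) {
    stop("channel mask is empty; feature assembly needs >= 1 retained channel",
         call. = FALSE)
  }
  keys <- channel_keys(mask)
  row_idx <- match(keys, rownames(mean_matrix))
  if (anyNA(row_idx)) {
    stop("channel(s) absent from measurement matrix: ",
         paste(keys[is.na(row_idx)], collapse = ", "), call. = FALSE)
  }
  sub <- mean_matrix[row_idx, sel$indices, drop = FALSE]
  v <- as.vector(t(sub))  # channel-major: each channel's frequencies contiguous
  names(v) <- as.vector(t(outer(keys, format_ghz(sel$freqs), paste, sep = "@")))
  if (any(!is.finite(Re(v)) | !is.finite(Im(v)))) {
    stop("non-finite entries in feature vector", call. = FALSE)
  }
  v
}

#' Feature matrix for a whole cohort
#'
#' Applies triplicate averaging, channel masking and frequency selection to
#' every subject and stacks the resulting complex feature vectors as columns.
#'
#' @param cohort A `mw_cohort`.
#' @param mask Channel mask (default: the device's exclusion mask).
#' @param f_lo,f_hi Frequency interval in GHz (default 0.75-1.95, the
#'   band used throughout the analyses).
#' @param average Averaging method passed to [average_repetitions()].
#' @return Complex matrix, features by subjects, with column names the
#'   subject ids and attributes `labels` (character vector) and `layout`
#'   (list of mask and frequency selection).
#' @export
cohort_features <- function(cohort, mask = default_exclusion_mask(),
                            f_lo = 0.75, f_hi = 1.95,
                            average = c("coherent", "magnitude")) {
  average <- match.arg(average)
  sel <- select_frequencies(cohort$freq_grid, f_lo, f_hi)
  cols <- lapply(cohort$subjects, function(su) {
    assemble_feature_vector(average_repetitions(su, method = average), mask, sel)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- cohort_subject_ids(cohort)
  attr(X, "labels") <- cohort_labels(cohort)
  attr(X, "layout") <- list(mask = mask, selection = sel)
  X
}
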