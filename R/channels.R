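#' Enumerate measurement channels of an antenna array
#'
#' A channel is one scattering coefficient, identified by an unordered pair of
#' antennas: a *reflection* channel when the same antenna transmits and
#' receives (`antenna_a == antenna_b`), a *transmission* channel otherwise.
#' Reciprocity is assumed, so each unordered pair contributes exactly one
#' channel; readers of directed data should average the two directions before
#' entering this pipeline.
#'
#' Channels are returned in canonical order: lexicographic by
#' `(antenna_a, antenna_b)` with `antenna_a <= antenna_b`. All feature-vector
#' layouts in the package inherit this ordering, so it must never change.
#'
#' @param n_antennas Number of antennas in the array (positive integer).
#' @return A data frame with integer columns `antenna_a` and `antenna_b`,
#'   one row per channel, `n_antennas * (n_antennas + 1) / 2` rows in total.
#' @examples
#' nrow(enumerate_channels(8))  # 36: 8 reflection + 28 transmission
#' @export
enumerate_channels <- function(n_antennas) {
  if (length(n_antennas) != 1L || is.na(n_antennas) || n_antennas < 1 ||
      n_antennas != as.integer(n_antennas)) {
    stop("`n_antennas` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n_antennas)
  a <- rep.int(seq_len(n), times = n - seq_len(n) + 1L)
  b <- unlist(lapply(seq_len(n), function(i) i:n), use.names = FALSE)
  as_channel_mask(data.frame(antenna_a = a, antenna_b = b), n_antennas = n)
}

#' @rdname enumerate_channels
#' @param channel A two-element vector or one-row data frame naming a channel.
#' @return `is_reflection_channel()`: logical, `TRUE` for a reflection channel.
#' @export
is_reflection_channel <- function(channel) {
  if (is.data.frame(channel)) {
    channel$antenna_a == channel$antenna_b
  } else {
    channel[[1L]] == channel[[2L]]
  }
}

# Canonicalize a channel table: a <= b, deduplicated, lexicographic order.
as_channel_mask <- function(df, n_antennas) {
  a <- as.integer(pmin(df$antenna_a, df$antenna_b))
  b <- as.integer(pmax(df$antenna_a, df$antenna_b))
  key <- paste(a, b, sep = "-")
  keep <- !duplicated(key)
  out <- data.frame(antenna_a = a[keep], antenna_b = b[keep])
  out <- out[order(out$antenna_a, out$antenna_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            n_antennas = as.integer(n_antennas),
            class = c("mw_channel_mask", "data.frame"))
}

#' Channel keys
#'
#' Stable string identifiers (`"a-b"`) used as matrix row names and in the
#' plain-text mask serialization.
#'
#' @param mask A channel mask or channel table.
#' @return Character vector, one key per channel.
#' @export
channel_keys <- function(mask) {
  paste(mask$antenna_a, mask$antenna_b, sep = "-")
}

#' Default channel-exclusion mask for the eight-antenna head array
#'
#' The device places antennas 1-2 at the forehead, 3-6 laterally and 7-8 at
#' the back of the head. Channels confined to the forehead/back antennas
#' (their reflections and the transmissions internal to \{1, 2, 7, 8\}) probe
#' peripheral regions or suffer high attenuation and are excluded; every
#' channel with at least one antenna among the lateral antennas 3-6 is
#' retained. Of the 36 channels this keeps 26 (4 reflections and 6
#' transmissions are dropped). The lateral reflections (3,3)..(6,6) are
#' retained since each has a lateral antenna; [mask_from_config()] lets users
#' study alternatives.
#'
#' @param n_antennas Must be 8; the mask encodes this specific device layout.
#' @return A `mw_channel_mask`: a canonical channel table (see
#'   [enumerate_channels()]) of the retained channels.
#' @examples
#' nrow(default_exclusion_mask())  # 26
#' @export
default_exclusion_mask <- function(n_antennas = 8) {
  if (length(n_antennas) != 1L || is.na(n_antennas) || n_antennas != 8) {
    stop("the default exclusion mask is defined only for the 8-antenna layout",
         call. = FALSE)
  }
  all_ch <- enumerate_channels(8L)
  lateral <- 3:6
  keep <- all_ch$antenna_a %in% lateral | all_ch$antenna_b %in% lateral
  as_channel_mask(all_ch[keep, , drop = FALSE], n_antennas = 8L)
}

#' Build a channel mask from explicit channel descriptors
#'
#' @param spec Channel descriptors: a character vector of `"a-b"` tokens, a
#'   list of length-2 integer vectors, or a data frame with columns
#'   `antenna_a` and `antenna_b`. Order and orientation are irrelevant;
#'   duplicates (including `(5,3)` vs `(3,5)`) collapse to one channel.
#' @param n_antennas Array size the descriptors must respect.
#' @return A canonical `mw_channel_mask`. May be empty; feature assembly
#'   rejects empty masks.
#' @export
mask_from_config <- function(spec, n_antennas = 8) {
  n <- as.integer(n_antennas)
  if (is.data.frame(spec)) {
    df <- data.frame(antenna_a = spec$antenna_a, antenna_b = spec$antenna_b)
  } else if (is.character(spec)) {
    parts <- strsplit(spec, "-", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) {
      stop("malformed channel token(s): ",
           paste(spec[bad], collapse = ", "), call. = FALSE)
    }
    df <- data.frame(
      antenna_a = suppressWarnings(as.integer(vapply(parts, `[`, "", 1L))),
      antenna_b = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    )
  } else if (is.list(spec)) {
    if (length(spec) == 0L) {
      df <- data.frame(antenna_a = integer(), antenna_b = integer())
    } else {
      df <- data.frame(
        antenna_a = vapply(spec, function(p) as.integer(p[[1L]]), 1L),
        antenna_b = vapply(spec, function(p) as.integer(p[[2L]]), 1L)
      )
    }
  } else {
    stop("`spec` must be a character vector, list of pairs, or data frame",
         call. = FALSE)
  }
  ok <- !is.na(df$antenna_a) & !is.na(df$antenna_b) &
    df$antenna_a >= 1L & df$antenna_a <= n &
    df$antenna_b >= 1L & df$antenna_b <= n
  if (!all(ok)) {
    stop("unknown antenna index in channel descriptor(s): ",
         paste(paste(df$antenna_a[!ok], df$antenna_b[!ok], sep = "-"),
               collapse = ", "),
         " (array has ", n, " antennas)", call. = FALSE)
  }
  as_channel_mask(df, n_antennas = n)
}

#' Read and write channel masks
#'
#' Plain-text serialization: one `"a-b"` token per line, canonical order.
#' The format is byte-stable: writing the same mask always produces an
#' identical file.
#'
#' @param mask A `mw_channel_mask`.
#' @param path File path.
#' @param n_antennas Array size assumed when reading.
#' @return `read_channel_mask()` returns a `mw_channel_mask`;
#'   `write_channel_mask()` returns `path` invisibly.
#' @export
write_channel_mask <- function(mask, path) {
  writeLines(channel_keys(mask), path)
  invisible(path)
}

#' @rdname write_channel_mask
#' @export
read_channel_mask <- function(path, n_antennas = 8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  mask_from_config(trimws(lines), n_antennas = n_antennas)
}

#' @export
print.mw_channel_mask <- function(x, ...) {
  n_refl <- sum(x$antenna_a == x$antenna_b)
  cat(sprintf("<channel mask: %d channels (%d reflection, %d transmission), %d antennas>\n",
              nrow(x), n_refl, nrow(x) - n_refl, attr(x, "n_antennas")))
  print(as.data.frame(x), ...)
  invisible(x)
}
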