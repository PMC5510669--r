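#' Configuration for the synthetic measurement generator
#'
#' Collects every knob of the generative model described in
#' [generate_cohort()] and validates it. Defaults emulate the study setting:
#' a 20 + 20 cohort measured in triplicate by an eight-antenna array sweeping
#' 0.10-1.95 GHz in 50 MHz steps, with hematoma volumes on the scale of the
#' surgical cohort (log-normal around 100 mL) and a 30% bilateral rate.
#'
#' No measurement-noise, inter-subject-variability or lesion-contrast
#' magnitudes are available from data, so `head_scale_sd`, `hematoma_gain`
#' and `hematoma_spread` were fixed once by simulation
#' (`scripts/calibrate_generator.R` in the source repository) so that default
#' cohorts reproduce the clinical performance regime: leave-one-out AUC
#' around 0.94 with small seed-to-seed spread, stable AUC under removal of
#' two random subjects, and chance-level AUC (slightly below 0.5, the usual
#' leave-one-out pessimism) under random diagnosis.
#'
#' @param n_patients,n_controls Subjects per class.
#' @param n_antennas Antennas on the circular array.
#' @param array_radius Array radius in meters.
#' @param freq_start,freq_stop,freq_step Frequency grid in GHz.
#' @param repetitions Consecutive measurements per subject.
#' @param attenuation_coeff Amplitude decay rate, nepers per (meter x GHz).
#' @param slowness Propagation delay per unit path, nanoseconds per meter.
#' @param head_scale_sd SD of the per-subject head-size scale factor
#'   (multiplies every path length; mean 1).
#' @param repositioning_sd SD of the per-repetition gain factor (mean 1),
#'   emulating slight head repositioning and contact-pressure changes.
#' @param noise_sd Relative complex measurement noise SD (fraction of the
#'   local baseline magnitude).
#' @param hematoma_gain Dimensionless amplitude of the hematoma perturbation
#'   (kappa); 0 removes the class contrast entirely.
#' @param hematoma_spread Angular width (radians) of the lesion's influence
#'   over channel midpoint azimuths.
#' @param lesion_f_min Optional lower frequency bound (GHz) of the hematoma
#'   perturbation: below it the perturbation is zero. `NULL` (default)
#'   leaves the perturbation active over the whole grid. Used to plant
#'   band-limited signal for model-selection studies.
#' @param volume_lognormal_mu,volume_lognormal_sigma Log-scale mean and SD of
#'   the total hematoma volume distribution (mL).
#' @param bilateral_prob Probability that a patient's volume is split 2:1
#'   over two diametrically opposed lesion sites.
#' @param volume_scaling `"cuberoot"` (perturbation scales like a linear
#'   lesion dimension, the default) or `"linear"` (proportional to volume).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A validated list of class `mw_synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20,
                             n_controls = 20,
                             n_antennas = 8,
                             array_radius = 0.09,
                             freq_start = 0.10,
                             freq_stop = 1.95,
                             freq_step = 0.05,
                             repetitions = 3,
                             attenuation_coeff = 25,
                             slowness = 20,
                             head_scale_sd = 0.002,
                             repositioning_sd = 0.01,
                             noise_sd = 0.02,
                             hematoma_gain = 0.05,
                             hematoma_spread = 2.0,
                             lesion_f_min = NULL,
                             volume_lognormal_mu = log(100),
                             volume_lognormal_sigma = 0.6,
                             bilateral_prob = 0.3,
                             volume_scaling = c("cuberoot", "linear"),
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_antennas = as.integer(n_antennas), array_radius = array_radius,
    freq_start = freq_start, freq_stop = freq_stop, freq_step = freq_step,
    repetitions = as.integer(repetitions),
    attenuation_coeff = attenuation_coeff, slowness = slowness,
    head_scale_sd = head_scale_sd, repositioning_sd = repositioning_sd,
    noise_sd = noise_sd, hematoma_gain = hematoma_gain,
    hematoma_spread = hematoma_spread,
    lesion_f_min = lesion_f_min,
    volume_lognormal_mu = volume_lognormal_mu,
    volume_lognormal_sigma = volume_lognormal_sigma,
    bilateral_prob = bilateral_prob,
    volume_scaling = match.arg(volume_scaling),
    seed = as.integer(seed)
  )
  stopifnot(
    "n_patients must be >= 1" = cfg$n_patients >= 1L,
    "n_controls must be >= 1" = cfg$n_controls >= 1L,
    "n_antennas must be >= 2" = cfg$n_antennas >= 2L,
    "array_radius must be positive" = cfg$array_radius > 0,
    "freq_start must be below freq_stop" = cfg$freq_start < cfg$freq_stop,
    "freq_step must be positive" = cfg$freq_step > 0,
    "repetitions must be >= 1" = cfg$repetitions >= 1L,
    "sd and gain parameters must be >= 0" =
      all(c(cfg$head_scale_sd, cfg$repositioning_sd, cfg$noise_sd,
            cfg$hematoma_gain, cfg$hematoma_spread,
            cfg$volume_lognormal_sigma) >= 0),
    "bilateral_prob must be in [0, 1]" =
      cfg$bilateral_prob >= 0 && cfg$bilateral_prob <= 1
  )
  n_steps <- (cfg$freq_stop - cfg$freq_start) / cfg$freq_step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("freq_step must divide the frequency span", call. = FALSE)
  }
  if (round(n_steps) < 1) {
    stop("frequency grid must contain at least two points", call. = FALSE)
  }
  class(cfg) <- "mw_synthetic_config"
  cfg
}

# Wrapped angular distance in [0, pi].
wrap_angle_dist <- function(a, b) {
  abs(((a - b + pi) %% (2 * pi)) - pi)
}

#' Generate a synthetic cohort of triplicate microwave measurements
#'
#' Produces, for each subject, `repetitions` complex channel-by-frequency
#' scattering matrices from an intentionally simple attenuation-plus-delay
#' surrogate of wave propagation (no electromagnetic field modelling). The
#' goal is the *statistical* structure of the clinical data: smooth complex
#' spectra, inter-subject head-size variability, channel-local lesion
#' signatures that grow with hematoma volume, and triplicate measurement
#' noise.
#'
#' Generative model, with frequencies `f` in GHz:
#' \itemize{
#'   \item Antennas sit at azimuths `theta_a = 2*pi*(a-1)/n` on a circle of
#'     radius `R`. A transmission channel's path length is the chord
#'     `|2R sin((theta_a - theta_b)/2)|`; reflection channels use the short
#'     constant path `0.3 R` (reflections carry mostly superficial
#'     information; any small positive constant serves).
#'   \item Each subject draws a head scale `s ~ Normal(1, head_scale_sd^2)`
#'     multiplying all path lengths. The noise-free baseline is
#'     `B(c, f) = exp(-alpha * s * L_c * f) * exp(-2i * pi * f * tau0 * s * L_c)`
#'     with attenuation coefficient `alpha` and slowness `tau0` (ns/m, so the
#'     phase term is dimensionless with `f` in GHz).
#'   \item Patients draw a total volume `v ~ LogNormal(mu, sigma^2)` mL and a
#'     lesion azimuth `phi ~ Uniform[0, 2*pi)`; with probability
#'     `bilateral_prob` the volume splits 2:1 over `phi` and `phi + pi`.
#'     Each lesion weights channels by angular proximity of the channel's
#'     midpoint azimuth `(theta_a + theta_b)/2` to `phi`:
#'     `w_c = exp(-(dist/lambda)^2)` with wrapped distance and spread
#'     `lambda`. The perturbation is
#'     `H(c, f) = kappa * (v/100)^(1/3) * w_c * B(c, f) * exp(2i * pi * f * 0.1)`,
#'     summed over lesions (bilateral patients contribute one term per site).
#'   \item Repetition `r` applies an independent gain
#'     `g_r ~ Normal(1, repositioning_sd^2)` and adds circular complex noise
#'     with variance `noise_sd^2 * |B(c, f)|^2`:
#'     `X_r = g_r * (B + H) + eps` (patients) or `g_r * B + eps` (controls).
#' }
#'
#' @param config A [synthetic_config()].
#' @return A `mw_cohort`: list with `subjects` (each holding `subject_id`,
#'   `label` in \{`"cSDH"`, `"HC"`\}, a list `repetitions` of complex
#'   matrices with channel-key row names, and `meta` with age, sex,
#'   `total_volume` in mL and `lesion_azimuth`), `channels` (canonical
#'   channel table), `freq_grid` (GHz) and `config`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 2, n_controls = 2))
#' dim(coh$subjects[[1]]$repetitions[[1]])  # 36 channels x 38 frequencies
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "mw_synthetic_config")) {
    stop("`config` must come from synthetic_config()", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  channels <- enumerate_channels(config$n_antennas)
  keys <- channel_keys(channels)
  freq <- config$freq_start +
    config$freq_step * 0:round((config$freq_stop - config$freq_start) / config$freq_step)
  n_ch <- nrow(channels)
  n_f <- length(freq)

  theta <- 2 * pi * (seq_len(config$n_antennas) - 1) / config$n_antennas
  th_a <- theta[channels$antenna_a]
  th_b <- theta[channels$antenna_b]
  refl <- channels$antenna_a == channels$antenna_b
  path <- ifelse(refl,
                 2 * config$array_radius * 0.15,
                 abs(2 * config$array_radius * sin((th_a - th_b) / 2)))
  midpoint <- ((th_a + th_b) / 2) %% (2 * pi)

  lesion_exponent <- if (config$volume_scaling == "cuberoot") 1 / 3 else 1

  make_subject <- function(id, label) {
    s <- stats::rnorm(1, 1, config$head_scale_sd)
    age <- min(max(round(stats::rnorm(1, 75, 10)), 50), 92)
    sex <- if (stats::runif(1) < 0.6) "M" else "F"
    # baseline: attenuation envelope times path-delay phase, channel x freq
    amp <- exp(-config$attenuation_coeff * s * outer(path, freq))
    phase <- -2 * pi * config$slowness * s * outer(path, freq)
    B <- amp * exp(1i * phase)

    total_volume <- 0
    lesion_azimuth <- NA_real_
    H <- matrix(0 + 0i, n_ch, n_f)
    if (label == "cSDH") {
      total_volume <- stats::rlnorm(1, config$volume_lognormal_mu,
                                    config$volume_lognormal_sigma)
      lesion_azimuth <- stats::runif(1, 0, 2 * pi)
      bilateral <- stats::runif(1) < config$bilateral_prob
      lesions <- if (bilateral) {
        list(c(v = 2 / 3 * total_volume, phi = lesion_azimuth),
             c(v = 1 / 3 * total_volume, phi = (lesion_azimuth + pi) %% (2 * pi)))
      } else {
        list(c(v = total_volume, phi = lesion_azimuth))
      }
      lesion_phase <- exp(1i * 2 * pi * freq * 0.1)
      if (!is.null(config$lesion_f_min)) {
        lesion_phase <- lesion_phase *
          (freq >= config$lesion_f_min - config$freq_step / 2)
      }
      for (les in lesions) {
        w <- exp(-(wrap_angle_dist(midpoint, les[["phi"]]) /
                     config$hematoma_spread)^2)
        H <- H + config$hematoma_gain * (les[["v"]] / 100)^lesion_exponent *
          (w %o% lesion_phase) * B
      }
    }

    reps <- vector("list", config$repetitions)
    signal <- B + H
    for (r in seq_len(config$repetitions)) {
      g <- stats::rnorm(1, 1, config$repositioning_sd)
      sd_cell <- config$noise_sd * Mod(B) / sqrt(2)
      eps <- matrix(stats::rnorm(n_ch * n_f, 0, sd_cell), n_ch, n_f) +
        1i * matrix(stats::rnorm(n_ch * n_f, 0, sd_cell), n_ch, n_f)
      X <- g * signal + eps
      dimnames(X) <- list(keys, format_ghz(freq))
      reps[[r]] <- X
    }
    list(subject_id = id, label = label, repetitions = reps,
         meta = list(age = age, sex = sex, total_volume = total_volume,
                     lesion_azimuth = lesion_azimuth))
  }

  ids_p <- sprintf("P%02d", seq_len(config$n_patients))
  ids_c <- sprintf("C%02d", seq_len(config$n_controls))
  subjects <- c(lapply(ids_p, make_subject, label = "cSDH"),
                lapply(ids_c, make_subject, label = "HC"))

  structure(list(subjects = subjects, channels = channels,
                 freq_grid = freq, config = config),
            class = "mw_cohort")
}

format_ghz <- function(f) sprintf("%.6g", f)

#' @export
print.mw_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, "", "label")
  cat(sprintf(
    "<mw_cohort: %d subjects (%d cSDH, %d HC), %d channels x %d frequencies (%.2f-%.2f GHz), %d repetitions>\n",
    length(x$subjects), sum(labs == "cSDH"), sum(labs == "HC"),
    nrow(x$channels), length(x$freq_grid),
    min(x$freq_grid), max(x$freq_grid),
    length(x$subjects[[1]]$repetitions)))
  invisible(x)
}

#' Cohort labels and identifiers
#'
#' @param cohort A `mw_cohort`.
#' @return Character vector in cohort order.
#' @export
cohort_labels <- function(cohort) vapply(cohort$subjects, `[[`, "", "label")

#' @rdname cohort_labels
#' @export
cohort_subject_ids <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "subject_id")
}

#' Write and read cohorts in the long CSV dialect
#'
#' One row per `(subject, repetition, channel, frequency)` cell with header
#' `subject_id,label,repetition,antenna_a,antenna_b,freq_ghz,real,imag`;
#' UTF-8, `.` decimal separator, rows sorted by subject id, repetition,
#' antennas and frequency. The round trip is lossless to float64 text
#' precision; `read_cohort()` validates shapes and keys and names the
#' offending subject and channel on failure.
#'
#' @param cohort A `mw_cohort`.
#' @param path CSV file path.
#' @return `read_cohort()` returns a `mw_cohort` (without generator config);
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  n_ch <- nrow(cohort$channels)
  n_f <- length(cohort$freq_grid)
  per_rep <- n_ch * n_f
  rows <- lapply(cohort$subjects, function(su) {
    n_rep <- length(su$repetitions)
    vals <- unlist(lapply(su$repetitions, as.vector))  # column-major: freq blocks
    data.table::data.table(
      subject_id = su$subject_id,
      label = su$label,
      repetition = rep(seq_len(n_rep), each = per_rep),
      antenna_a = rep(rep(cohort$channels$antenna_a, times = n_f), times = n_rep),
      antenna_b = rep(rep(cohort$channels$antenna_b, times = n_f), times = n_rep),
      freq_ghz = rep(rep(cohort$freq_grid, each = n_ch), times = n_rep),
      real = Re(vals),
      imag = Im(vals)
    )
  })
  dt <- data.table::rbindlist(rows)
  data.table::setorder(dt, subject_id, repetition, antenna_a, antenna_b, freq_ghz)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  dt <- tryCatch(data.table::fread(path),
                 error = function(e) data.table::data.table(),
                 warning = function(w) suppressWarnings(data.table::fread(path)))
  if (nrow(dt) == 0L) stop("no records in cohort file: ", path, call. = FALSE)
  required <- c("subject_id", "label", "repetition", "antenna_a", "antenna_b",
                "freq_ghz", "real", "imag")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("cohort file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(dt[, required, with = FALSE])) {
    bad <- which(rowSums(is.na(dt[, required, with = FALSE])) > 0)[1L]
    stop("malformed row ", bad + 1L, " in ", path, call. = FALSE)
  }
  bad_label <- setdiff(unique(dt$label), c("cSDH", "HC"))
  if (length(bad_label)) {
    stop("unknown label(s): ", paste(bad_label, collapse = ", "), call. = FALSE)
  }

  key <- paste(dt$subject_id, dt$repetition, dt$antenna_a, dt$antenna_b,
               dt$freq_ghz, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (subject, repetition, channel, frequency) key at row %d: subject %s channel %d-%d",
                 d + 1L, dt$subject_id[d], dt$antenna_a[d], dt$antenna_b[d]),
         call. = FALSE)
  }

  n_antennas <- max(dt$antenna_a, dt$antenna_b)
  channels <- as_channel_mask(
    unique(data.frame(antenna_a = dt$antenna_a, antenna_b = dt$antenna_b)),
    n_antennas = n_antennas)
  keys <- channel_keys(channels)
  freq <- sort(unique(dt$freq_ghz))
  n_ch <- nrow(channels)
  n_f <- length(freq)

  subj_ids <- unique(dt$subject_id)
  subjects <- lapply(subj_ids, function(id) {
    sub <- dt[dt$subject_id == id, ]
    label <- unique(sub$label)
    if (length(label) != 1L) {
      stop("subject ", id, " has inconsistent labels", call. = FALSE)
    }
    reps <- lapply(sort(unique(sub$repetition)), function(r) {
      cell <- sub[sub$repetition == r, ]
      if (nrow(cell) != n_ch * n_f) {
        have <- paste(cell$antenna_a, cell$antenna_b, sep = "-")
        short <- keys[tabulate(match(have, keys), n_ch) < n_f]
        stop(sprintf("subject %s repetition %d: expected %d cells, found %d (incomplete channel %s)",
                     id, r, n_ch * n_f, nrow(cell),
                     if (length(short)) short[1L] else "<extra rows>"),
             call. = FALSE)
      }
      X <- matrix(NA_complex_, n_ch, n_f, dimnames = list(keys, format_ghz(freq)))
      i <- match(paste(cell$antenna_a, cell$antenna_b, sep = "-"), keys)
      j <- match(cell$freq_ghz, freq)
      X[cbind(i, j)] <- complex(real = cell$real, imaginary = cell$imag)
      X
    })
    list(subject_id = id, label = label, repetitions = reps, meta = list())
  })

  n_rep <- unique(vapply(subjects, function(s) length(s$repetitions), 1L))
  if (length(n_rep) != 1L) {
    stop("subjects have differing repetition counts", call. = FALSE)
  }
  structure(list(subjects = subjects, channels = channels,
                 freq_grid = freq, config = NULL),
            class = "mw_cohort")
}
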