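#' Load a patient-characteristics table
#'
#' Reads the CSV of per-patient clinical characteristics (age, sex,
#' left/right hematoma volume in mL, CT attenuation interval in Hounsfield
#' units, midline shift in mm). The packaged fixture
#' `table2_patients.csv` transcribes the 20-patient surgical cohort.
#'
#' Expected header:
#' `patient_id,age,sex,vol_right_ml,vol_left_ml,attenuation_lo_hu,attenuation_hi_hu,midline_shift_mm`.
#' An empty cell or a dash in a volume column means no hematoma on that
#' side; at least one side must be present. Homogeneous hematomas may give a
#' single attenuation value: an empty `attenuation_hi_hu` is taken equal to
#' `attenuation_lo_hu`.
#'
#' @param path CSV path; default is the packaged fixture.
#' @return A `mw_patient_table` data frame with columns `patient_id`, `age`,
#'   `sex`, `vol_right`, `vol_left` (mL, `NA` = absent), `attenuation_lo`,
#'   `attenuation_hi` (HU), `midline_shift` (mm).
#' @export
load_patient_table <- function(path = system.file("extdata",
                                                  "table2_patients.csv",
                                                  package = "mwtriage")) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("patient_id", "age", "sex", "vol_right_ml", "vol_left_ml",
                "attenuation_lo_hu", "attenuation_hi_hu", "midline_shift_mm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("patient table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("patient table has no rows", call. = FALSE)

  absent <- function(x) !nzchar(x) | x %in% c("-", "–", "—", "NA")
  num <- function(x) suppressWarnings(as.numeric(x))

  out <- data.frame(
    patient_id = raw$patient_id,
    age = num(raw$age),
    sex = raw$sex,
    vol_right = ifelse(absent(raw$vol_right_ml), NA_real_, num(raw$vol_right_ml)),
    vol_left = ifelse(absent(raw$vol_left_ml), NA_real_, num(raw$vol_left_ml)),
    attenuation_lo = num(raw$attenuation_lo_hu),
    attenuation_hi = ifelse(absent(raw$attenuation_hi_hu),
                            num(raw$attenuation_lo_hu),
                            num(raw$attenuation_hi_hu)),
    midline_shift = num(raw$midline_shift_mm),
    stringsAsFactors = FALSE
  )

  fail <- function(row, field, why) {
    stop(sprintf("patient table row %d (%s), field %s: %s",
                 row, out$patient_id[row], field, why), call. = FALSE)
  }
  for (i in seq_len(nrow(out))) {
    if (is.na(out$age[i]) || out$age[i] <= 0) fail(i, "age", "must be a positive number")
    if (!out$sex[i] %in% c("M", "F")) fail(i, "sex", "must be 'M' or 'F'")
    if (is.na(out$vol_right[i]) && is.na(out$vol_left[i])) {
      fail(i, "vol_right_ml/vol_left_ml", "at least one side must have a volume")
    }
    for (side in c("vol_right", "vol_left")) {
      if (!is.na(out[[side]][i]) && out[[side]][i] < 0) {
        fail(i, side, "volume must be >= 0")
      }
    }
    if (is.na(out$attenuation_lo[i]) || is.na(out$attenuation_hi[i])) {
      fail(i, "attenuation", "must be numeric")
    }
    if (out$attenuation_lo[i] > out$attenuation_hi[i]) {
      fail(i, "attenuation", "interval low end exceeds high end")
    }
    if (is.na(out$midline_shift[i]) || out$midline_shift[i] < 0) {
      fail(i, "midline_shift_mm", "must be a number >= 0")
    }
  }
  structure(out, class = c("mw_patient_table", "data.frame"))
}

# Round half away from zero (base round() is half-to-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort summary statistics of a patient table
#'
#' Computes the headline cohort descriptives: patient count, mean age (one
#' decimal) and age range, sex counts, mean total hematoma volume (left and
#' right side summed when bilateral; nearest mL), bilateral count and mean
#' midline shift. An absent one-sided volume contributes 0 mL to the total.
#' Rounding is half-away-from-zero at the stated precision.
#'
#' @param records A `mw_patient_table` from [load_patient_table()].
#' @return A `mw_cohort_summary` list with `n`, `mean_age`, `age_range`,
#'   `n_female`, `n_male`, `mean_total_volume`, `n_bilateral`,
#'   `mean_midline_shift`, and the unrounded `total_volumes` per patient.
#' @examples
#' \dontrun{cohort_summary(load_patient_table())}
#' @export
cohort_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("need at least one patient record", call. = FALSE)
  }
  vol_r <- ifelse(is.na(records$vol_right), 0, records$vol_right)
  vol_l <- ifelse(is.na(records$vol_left), 0, records$vol_left)
  totals <- vol_r + vol_l
  structure(list(
    n = nrow(records),
    mean_age = round_half_away(mean(records$age), 1),
    age_range = range(records$age),
    n_female = sum(records$sex == "F"),
    n_male = sum(records$sex == "M"),
    mean_total_volume = round_half_away(mean(totals)),
    n_bilateral = sum(!is.na(records$vol_right) & !is.na(records$vol_left)),
    mean_midline_shift = round_half_away(mean(records$midline_shift), 1),
    total_volumes = totals
  ), class = "mw_cohort_summary")
}

#' @export
print.mw_cohort_summary <- function(x, ...) {
  cat(sprintf("Patients: %d (%d male, %d female)\n", x$n, x$n_male, x$n_female))
  cat(sprintf("Mean age: %.1f years (range %g-%g)\n",
              x$mean_age, x$age_range[1], x$age_range[2]))
  cat(sprintf("Mean total hematoma volume: %g mL (%d bilateral)\n",
              x$mean_total_volume, x$n_bilateral))
  cat(sprintf("Mean midline shift: %.1f mm\n", x$mean_midline_shift))
  invisible(x)
}
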