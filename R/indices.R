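#' Allometric anthropometric indices
#'
#' Body mass index (BMI), a body shape index (ABSI) and hip index (HI) from
#' the four basic anthropometrics: height, weight, waist circumference and
#' hip circumference.
#'
#' Definitions (heights and waist in meters inside ABSI; weight in kg):
#' \deqn{BMI = W H^{-2}}
#' \deqn{ABSI = WC \cdot H^{5/6} \cdot W^{-2/3}}
#' \deqn{HI = HC \cdot (H/\langle H\rangle)^{0.310} \cdot (W/\langle W\rangle)^{-0.482}}
#' with reference values \eqn{\langle H\rangle = 166} cm and
#' \eqn{\langle W\rangle = 73} kg, so HI is reported in the units of hip
#' circumference (cm). ABSI normalizes waist circumference for height and
#' weight, making it statistically near-independent of BMI; HI does the same
#' for hip circumference.
#'
#' Inputs are taken in cm and kg (the NHANES measurement convention); height
#' and waist are converted to meters internally for ABSI, giving its
#' customary magnitude near 0.08.
#'
#' @param weight_kg weight in kilograms
#' @param height_cm standing height in centimeters
#' @param waist_cm waist circumference in centimeters
#' @param hip_cm hip circumference in centimeters
#'
#' @return A numeric vector: kg/m^2 for [compute_bmi()],
#'   m^(11/6) kg^(-2/3) for [compute_absi()], cm for [compute_hi()].
#' @name anthro-indices
NULL

# reference scaling constants baked into the hip index definition
HI_REF_HEIGHT_CM <- 166
HI_REF_WEIGHT_KG <- 73
HI_HEIGHT_EXP <- 0.310
HI_WEIGHT_EXP <- -0.482

check_positive <- function(x, name) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    abort(sprintf(
      "invalid measurement: %s must be strictly positive (%d offending value%s, first: %g)",
      name, sum(bad), if (sum(bad) > 1) "s" else "", x[which(bad)[1]]
    ), class = "anthrorisk_invalid_measurement")
  }
  invisible(x)
}

#' @rdname anthro-indices
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' @rdname anthro-indices
#' @export
compute_absi <- function(waist_cm, height_cm, weight_kg) {
  check_positive(waist_cm, "waist_cm")
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  (waist_cm / 100) * (height_cm / 100)^(5 / 6) * weight_kg^(-2 / 3)
}

#' @rdname anthro-indices
#' @export
compute_hi <- function(hip_cm, height_cm, weight_kg) {
  check_positive(hip_cm, "hip_cm")
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  hip_cm * (height_cm / HI_REF_HEIGHT_CM)^HI_HEIGHT_EXP *
    (weight_kg / HI_REF_WEIGHT_KG)^HI_WEIGHT_EXP
}

#' Default plausibility bounds for raw anthropometrics
#'
#' Adult plausibility ranges, in the ingest units (cm, kg). Values outside
#' these ranges are flagged by [add_anthro_indices()], never silently
#' dropped; exclusion policy belongs to cohort filtering
#' ([read_cohort()]).
#'
#' @return Named list of length-2 numeric ranges.
#' @export
anthro_bounds <- function() {
  list(
    height_cm = c(100, 230),
    weight_kg = c(25, 300),
    waist_cm = c(40, 220),
    hip_cm = c(50, 220)
  )
}

#' Add BMI, ABSI and hip index columns to a cohort
#'
#' Computes the three allometric indices for every row and appends them as
#' `bmi`, `absi` and `hi`, together with an `anthro_flag` column listing any
#' measurements outside the plausibility bounds (comma-separated field
#' names, `NA` when all measurements are plausible). Height itself is the
#' fourth index of the risk model and is carried through unchanged.
#'
#' @param data A data frame with columns `height_cm`, `weight_kg`,
#'   `waist_cm`, `hip_cm`.
#' @param bounds Plausibility bounds as produced by [anthro_bounds()].
#'
#' @return `data` as a tibble with columns `bmi`, `absi`, `hi`,
#'   `anthro_flag` appended.
#' @examples
#' ref <- tibble::tibble(height_cm = 166, weight_kg = 73,
#'                       waist_cm = 90, hip_cm = 100)
#' add_anthro_indices(ref)
#' @export
add_anthro_indices <- function(data, bounds = anthro_bounds()) {
  needed <- c("height_cm", "weight_kg", "waist_cm", "hip_cm")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "missing required anthropometric column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "anthrorisk_missing_field")
  }
  flags <- rep(NA_character_, nrow(data))
  for (field in names(bounds)) {
    x <- data[[field]]
    out <- !is.na(x) & (x < bounds[[field]][1] | x > bounds[[field]][2])
    flags[out] <- ifelse(is.na(flags[out]), field, paste(flags[out], field, sep = ","))
  }
  data |>
    as_tibble() |>
    mutate(
      bmi = compute_bmi(weight_kg, height_cm),
      absi = compute_absi(waist_cm, height_cm, weight_kg),
      hi = compute_hi(hip_cm, height_cm, weight_kg),
      anthro_flag = flags
    )
}
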