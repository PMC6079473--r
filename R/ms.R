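#' ATP III metabolic syndrome component scores
#'
#' Each of the five components is scored 1 when its criterion is met and 0
#' otherwise; a total of 3 or more of the 5 defines metabolic syndrome (MS).
#' Criteria:
#' * **Waist**: waist circumference above 102 cm (men) / 88 cm (women) —
#'   read strictly (`>`).
#' * **BP**: systolic at or above 130 mmHg, or diastolic at or above
#'   85 mmHg, or on blood-pressure medication.
#' * **TG**: fasting triglycerides at or above 150 mg/dL.
#' * **HDL**: HDL cholesterol under 40 mg/dL (men) / 50 mg/dL (women) —
#'   strict (`<`).
#' * **Glu**: fasting glucose at or above 110 mg/dL, or taking pills for
#'   diabetes.
#'
#' "At or above" is inclusive; "above"/"under" are strict. Missing inputs
#' propagate as `NA` (a disjunctive criterion is 1 as soon as any present
#' clause is met, `NA` only when no present clause fires and some clause is
#' missing); downstream analysis is complete-case.
#'
#' @param waist_cm Waist circumference (cm).
#' @param sex `"male"` or `"female"`.
#' @param sbp_mmhg,dbp_mmhg Systolic/diastolic blood pressure (mmHg).
#' @param bp_meds 0/1, self-reported blood-pressure medication.
#' @param tg_mg_dl Fasting serum triglycerides (mg/dL).
#' @param hdl_mg_dl HDL cholesterol (mg/dL).
#' @param glu_mg_dl Fasting plasma glucose (mg/dL).
#' @param diabetes_pills 0/1, self-reported pills for diabetes.
#' @return Integer vector of 0/1 scores (`NA` where unscoreable).
#' @name ms-components
NULL

check_sex <- function(sex) {
  bad <- !is.na(sex) & !sex %in% c("male", "female")
  if (any(bad)) {
    abort(sprintf("sex must be \"male\" or \"female\" (got \"%s\")", sex[which(bad)[1]]))
  }
}

#' @rdname ms-components
#' @export
score_waist <- function(waist_cm, sex) {
  check_sex(sex)
  cut <- ifelse(sex == "male", 102, 88)
  as.integer(waist_cm > cut)
}

#' @rdname ms-components
#' @export
score_bp <- function(sbp_mmhg, dbp_mmhg, bp_meds) {
  # TRUE | NA is TRUE, FALSE | NA is NA: a met clause decides even with
  # missing companions
  as.integer((sbp_mmhg >= 130) | (dbp_mmhg >= 85) | (bp_meds == 1))
}

#' @rdname ms-components
#' @export
score_tg <- function(tg_mg_dl) {
  as.integer(tg_mg_dl >= 150)
}

#' @rdname ms-components
#' @export
score_hdl <- function(hdl_mg_dl, sex) {
  check_sex(sex)
  cut <- ifelse(sex == "male", 40, 50)
  as.integer(hdl_mg_dl < cut)
}

#' @rdname ms-components
#' @export
score_glu <- function(glu_mg_dl, diabetes_pills) {
  as.integer((glu_mg_dl >= 110) | (diabetes_pills == 1))
}

#' Score the metabolic syndrome for a cohort
#'
#' Applies the five component criteria (see [ms-components]) to every row
#' and appends `ms_waist`, `ms_bp`, `ms_tg`, `ms_hdl`, `ms_glu`, their sum
#' `ms_score` (0-5), the diagnosis `ms` (1 iff `ms_score >= 3`), and
#' `msx_score` (0-4), the score excluding the Waist component, used when MS
#' information is modelled alongside ARI (whose inputs already include
#' waist circumference).
#'
#' @param data Cohort with columns `waist_cm`, `sex`, `sbp_mmhg`,
#'   `dbp_mmhg`, `bp_meds`, `tg_mg_dl`, `hdl_mg_dl`, `glu_mg_dl`,
#'   `diabetes_pills`.
#' @param strict If `TRUE`, any unscoreable component raises an error
#'   listing the offending fields instead of propagating `NA`.
#' @return `data` with the eight scoring columns appended.
#' @examples
#' subj <- tibble::tibble(
#'   sex = "male", waist_cm = 103, sbp_mmhg = 128, dbp_mmhg = 85,
#'   bp_meds = 0, tg_mg_dl = 150, hdl_mg_dl = 40, glu_mg_dl = 109,
#'   diabetes_pills = 0
#' )
#' score_ms(subj)[, c("ms_waist", "ms_bp", "ms_tg", "ms_hdl", "ms_glu",
#'                    "ms_score", "ms")]
#' @export
score_ms <- function(data, strict = FALSE) {
  needed <- c("waist_cm", "sex", "sbp_mmhg", "dbp_mmhg", "bp_meds",
              "tg_mg_dl", "hdl_mg_dl", "glu_mg_dl", "diabetes_pills")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("MS scoring lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "anthrorisk_missing_field")
  }
  out <- as_tibble(data) |>
    mutate(
      ms_waist = score_waist(waist_cm, sex),
      ms_bp = score_bp(sbp_mmhg, dbp_mmhg, bp_meds),
      ms_tg = score_tg(tg_mg_dl),
      ms_hdl = score_hdl(hdl_mg_dl, sex),
      ms_glu = score_glu(glu_mg_dl, diabetes_pills),
      ms_score = ms_waist + ms_bp + ms_tg + ms_hdl + ms_glu,
      ms = as.integer(ms_score >= 3),
      msx_score = ms_score - ms_waist
    )
  if (strict) {
    comp <- c("ms_waist", "ms_bp", "ms_tg", "ms_hdl", "ms_glu")
    bad <- comp[vapply(comp, function(cc) anyNA(out[[cc]]), logical(1))]
    if (length(bad) > 0) {
      abort(paste0("unscoreable MS component(s): ", paste(bad, collapse = ", ")),
            class = "anthrorisk_missing_component")
    }
  }
  out
}
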