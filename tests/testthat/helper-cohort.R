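# shared fixtures and independent oracles, built in code

zero_effect <- function(z) 0 * z

# config with a single active index effect on zBMI and nothing else
single_index_config <- function(bmi_fun) {
  cohort_config(hazard = utils::modifyList(cohort_config()$hazard, list(
    index = list(H = zero_effect, BMI = bmi_fun, ABSI = zero_effect,
                 HI = zero_effect),
    components = c(ms_waist = 0, ms_bp = 0, ms_tg = 0, ms_hdl = 0, ms_glu = 0),
    sex_male = 0, race_black = 0
  )))
}

# config with no effects at all: hazard is the Gompertz baseline only
null_effect_config <- function() single_index_config(zero_effect)

# independent brute-force ATP III scorer: literal row-by-row reading of the
# component criteria, no shared code with score_ms()
brute_force_ms <- function(row) {
  waist <- if (row$sex == "male") {
    if (row$waist_cm > 102) 1L else 0L
  } else {
    if (row$waist_cm > 88) 1L else 0L
  }
  bp <- 0L
  if (row$sbp_mmhg >= 130) bp <- 1L
  if (row$dbp_mmhg >= 85) bp <- 1L
  if (row$bp_meds == 1) bp <- 1L
  tg <- if (row$tg_mg_dl >= 150) 1L else 0L
  hdl_cut <- if (row$sex == "male") 40 else 50
  hdl <- if (row$hdl_mg_dl < hdl_cut) 1L else 0L
  glu <- 0L
  if (row$glu_mg_dl >= 110) glu <- 1L
  if (row$diabetes_pills == 1) glu <- 1L
  total <- waist + bp + tg + hdl + glu
  c(waist = waist, bp = bp, tg = tg, hdl = hdl, glu = glu,
    score = total, ms = if (total >= 3) 1L else 0L)
}

# hand-built linear hazard curve (bypasses fitting) for arithmetic checks
make_constant_curve <- function(value, index) {
  grid <- seq(-4, 4, by = 0.01)
  structure(
    list(index = index, grid_z = grid, log_hazard = rep(value, length(grid)),
         offset = 0, n = 0L, n_events = 0L, df = NA_real_, weighted = FALSE),
    class = "hazard_curve"
  )
}

make_linear_curve <- function(beta, index) {
  grid <- seq(-4, 4, by = 0.01)
  structure(
    list(index = index, grid_z = grid, log_hazard = beta * grid,
         offset = 0, n = 0L, n_events = 0L, df = NA_real_, weighted = FALSE),
    class = "hazard_curve"
  )
}

# skeleton ari_cox_fit with a prescribed AIC, for aic_compare arithmetic
fake_fit <- function(name, aic, df = 3, n = 1000, n_events = 300, sum_w = 1000) {
  structure(
    list(name = name, predictors = character(0), fit = NULL, n = n,
         n_events = n_events, sum_w = sum_w, loglik = -(aic - 2 * df) / 2,
         df = df, aic = aic, r2 = 0, concordance = 0.5),
    class = "ari_cox_fit"
  )
}
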