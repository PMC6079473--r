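#' Centered log-hazard effect functions for the cohort generator
#'
#' Building blocks for the generator's per-index true log-hazard curves.
#' Both are centered so that `E[exp(f(Z))] = 1` for `Z ~ N(0, 1)`, matching
#' the population-average anchoring of fitted hazard curves:
#' `linear_log_hazard(beta)` gives `beta * z - beta^2 / 2`;
#' `ushaped_log_hazard(a)` gives `a * z^2 + log(1 - 2a) / 2` (requires
#' `a < 1/2`).
#'
#' @param beta Slope of the linear log-hazard effect per Z-score unit.
#' @param a Curvature of the quadratic (U-shaped) effect.
#' @return A function of `z`.
#' @export
linear_log_hazard <- function(beta) {
  force(beta)
  function(z) beta * z - beta^2 / 2
}

#' @rdname linear_log_hazard
#' @export
ushaped_log_hazard <- function(a) {
  stopifnot(a < 0.5)
  force(a)
  function(z) a * z^2 + log(1 - 2 * a) / 2
}

#' Configuration of the synthetic cohort generator
#'
#' Returns the full parameter set of [generate_cohort()], with defaults
#' chosen to emulate the structure of a national examination-survey adult
#' cohort with linked ~20-year mortality follow-up:
#'
#' * sex- and age-dependent anthropometrics in which the Z scores of
#'   height, BMI, ABSI and hip index are mutually independent by
#'   construction (waist and hip circumference are generated by inverting
#'   the index definitions from independently drawn target Z scores);
#' * metabolic-syndrome inputs driven by a common-factor latent Gaussian
#'   (pairwise latent correlation `ms_latent_rho`) whose marginal maps are
#'   calibrated so the realized 0/1 components intercorrelate near 0.2 and
#'   MS prevalence lands near 28%;
#' * survival on the age timescale from a Gompertz baseline hazard
#'   multiplied by `exp(true log hazard)`, administratively censored at
#'   `horizon_years`;
#' * Gamma-distributed sampling weights with mean 1 and a 50/50
#'   training/evaluation split emulating the morning-subsample design.
#'
#' The default true hazard uses centered linear index effects with slopes
#' (H, BMI, ABSI, HI) = (-0.02, 0.17, 0.13, -0.09), giving an ARI standard
#' deviation near 0.23, and MS-component log hazard ratios
#' log(1.25), log(0.92), log(1.22), log(1.24) for BP, TG, HDL, Glu (Waist 0).
#'
#' @param ... Overrides for any top-level element (checked names).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    p_female = 0.52,
    p_black = 0.28,
    p_training = 0.5,
    age_range = c(18, 80),
    age_shape = c(1.2, 1.8),
    anthro = list(
      male = list(height_mean = 176, height_sd = 7.1, height_age_slope = -0.06,
                  bmi_meanlog = log(26.2), bmi_sdlog = 0.17, bmi_age_slope = 0.0030,
                  absi_mean = 0.0795, absi_sd = 0.0042, absi_age_slope = 0.00012,
                  hi_mean = 96, hi_sd = 5.5, hi_age_slope = 0.03),
      female = list(height_mean = 163, height_sd = 6.5, height_age_slope = -0.06,
                    bmi_meanlog = log(26.0), bmi_sdlog = 0.21, bmi_age_slope = 0.0035,
                    absi_mean = 0.0780, absi_sd = 0.0047, absi_age_slope = 0.00015,
                    hi_mean = 104, hi_sd = 6.0, hi_age_slope = 0.03)
    ),
    ms_latent_rho = 0.35,
    ms_marginals = list(
      sbp_median = 125, sbp_sdlog = 0.125,
      dbp_ratio = 0.62, dbp_sd = 4,
      bp_meds_intercept = -2.8, bp_meds_slope = 1.4,
      tg_median = 127, tg_sdlog = 0.45,
      hdl_median_male = 44, hdl_median_female = 53, hdl_sdlog = 0.24,
      glu_median = 96.5, glu_sdlog = 0.13,
      diabetes_pills_intercept = -3.4, diabetes_pills_slope = 1.8
    ),
    hazard = list(
      index = list(
        H = linear_log_hazard(-0.02),
        BMI = linear_log_hazard(0.17),
        ABSI = linear_log_hazard(0.13),
        HI = linear_log_hazard(-0.09)
      ),
      components = c(ms_waist = 0, ms_bp = log(1.25), ms_tg = log(0.92),
                     ms_hdl = log(1.22), ms_glu = log(1.24)),
      ms = 0,
      ms_score = 0,
      sex_male = log(1.6),
      race_black = log(1.2)
    ),
    baseline = list(log_b0 = -9.7, theta = 0.09),
    horizon_years = 20,
    weight_shape = 4
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown cohort_config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, dots)
  if (cfg$ms_latent_rho < 0 || cfg$ms_latent_rho >= 1) {
    abort("ms_latent_rho must lie in [0, 1) for a positive-definite latent correlation")
  }
  if (cfg$horizon_years <= 0) abort("censoring horizon must be positive")
  structure(cfg, class = c("cohort_config", "list"))
}

# within-group normal scores: rank -> standard normal quantile
normal_scores <- function(x, group) {
  out <- numeric(length(x))
  for (g in unique(group)) {
    sel <- group == g
    n <- sum(sel)
    out[sel] <- qnorm((rank(x[sel], ties.method = "average") - 0.5) / n)
  }
  out
}

#' Generate a synthetic survey-like cohort with known ground truth
#'
#' Draws `n` subjects per [cohort_config()]: independent standard-normal
#' target Z scores for the four anthropometric indices are turned into raw
#' measurements by inverting the index definitions (so waist circumference
#' is `ABSI * H^(-5/6) * W^(2/3)` with the ABSI target drawn independently
#' of height and weight, and hip circumference analogously from the hip
#' index target); metabolic-syndrome inputs come from a common-factor
#' latent Gaussian tied to the subject's within-sex waist percentile; and
#' survival times are drawn on the age timescale from a Gompertz baseline
#' multiplied by the subject's true relative hazard, censored at the
#' administrative horizon.
#'
#' @param n Number of subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical `n`, `config` and `seed` reproduce
#'   the cohort exactly.
#' @return A tibble of subject records in the cohort CSV schema (see
#'   [cohort_schema()]), plus generator-only columns `true_zH`, `true_zBMI`,
#'   `true_zABSI`, `true_zHI` and `true_log_hazard`.
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = NULL) {
  stopifnot(n >= 1)
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  if (!is.null(seed)) set.seed(seed)

  sex <- ifelse(runif(n) < config$p_female, "female", "male")
  age <- config$age_range[1] +
    diff(config$age_range) * rbeta(n, config$age_shape[1], config$age_shape[2])
  race_black <- rbinom(n, 1, config$p_black)

  zH <- rnorm(n); zBMI <- rnorm(n); zABSI <- rnorm(n); zHI <- rnorm(n)

  pick <- function(field) {
    vapply(sex, function(s) config$anthro[[s]][[field]], numeric(1))
  }
  arel <- age - 45
  height_cm <- pick("height_mean") + pick("height_age_slope") * arel +
    pick("height_sd") * zH
  bmi <- exp(pick("bmi_meanlog") + pick("bmi_age_slope") * arel +
               pick("bmi_sdlog") * zBMI)
  weight_kg <- bmi * (height_cm / 100)^2
  absi_target <- pick("absi_mean") + pick("absi_age_slope") * arel +
    pick("absi_sd") * zABSI
  # invert ABSI = WC * H^(5/6) * W^(-2/3) (meters, kg) for WC in cm
  waist_cm <- 100 * absi_target * (height_cm / 100)^(-5 / 6) * weight_kg^(2 / 3)
  hi_target <- pick("hi_mean") + pick("hi_age_slope") * arel + pick("hi_sd") * zHI
  hip_cm <- hi_target * (height_cm / HI_REF_HEIGHT_CM)^(-HI_HEIGHT_EXP) *
    (weight_kg / HI_REF_WEIGHT_KG)^(-HI_WEIGHT_EXP)

  # MS latents: each shares correlation rho with the within-sex waist
  # percentile (normal scores) and pairwise rho with the others via a
  # common factor
  rho <- config$ms_latent_rho
  z_wc <- normal_scores(waist_cm, sex)
  lam <- rho
  a2 <- rho - lam^2
  c2 <- 1 - lam^2 - a2
  G <- rnorm(n)
  latent <- function() lam * z_wc + sqrt(a2) * G + sqrt(c2) * rnorm(n)
  l_bp <- latent(); l_tg <- latent(); l_hdl <- latent(); l_glu <- latent()

  mm <- config$ms_marginals
  sbp_mmhg <- mm$sbp_median * exp(mm$sbp_sdlog * l_bp)
  dbp_mmhg <- mm$dbp_ratio * sbp_mmhg + rnorm(n, 0, mm$dbp_sd)
  bp_meds <- rbinom(n, 1, plogis(mm$bp_meds_intercept + mm$bp_meds_slope * l_bp))
  tg_mg_dl <- mm$tg_median * exp(mm$tg_sdlog * l_tg)
  hdl_median <- ifelse(sex == "male", mm$hdl_median_male, mm$hdl_median_female)
  hdl_mg_dl <- hdl_median * exp(-mm$hdl_sdlog * l_hdl)
  glu_mg_dl <- mm$glu_median * exp(mm$glu_sdlog * l_glu)
  diabetes_pills <- rbinom(n, 1, plogis(mm$diabetes_pills_intercept +
                                          mm$diabetes_pills_slope * l_glu))

  cohort <- tibble(
    id = seq_len(n), age = age, sex = sex, race_black = race_black,
    height_cm = height_cm, weight_kg = weight_kg,
    waist_cm = waist_cm, hip_cm = hip_cm,
    sbp_mmhg = sbp_mmhg, dbp_mmhg = dbp_mmhg, bp_meds = bp_meds,
    tg_mg_dl = tg_mg_dl, hdl_mg_dl = hdl_mg_dl, glu_mg_dl = glu_mg_dl,
    diabetes_pills = diabetes_pills, pregnant = 0L,
    true_zH = zH, true_zBMI = zBMI, true_zABSI = zABSI, true_zHI = zHI
  )

  cohort <- score_ms(cohort)
  cohort$true_log_hazard <- true_hazard(cohort, config)

  # survival on the age timescale: Gompertz baseline h0(a) = b0 exp(theta a),
  # inverted cumulative hazard from age at entry
  b0 <- exp(config$baseline$log_b0); th <- config$baseline$theta
  r <- exp(cohort$true_log_hazard)
  E <- rexp(n)
  t_death <- log(1 + th * E / (r * b0 * exp(th * age))) / th
  cohort$died <- as.integer(t_death < config$horizon_years)
  cohort$followup_years <- pmin(t_death, config$horizon_years)

  cohort$sample_weight <- rgamma(n, shape = config$weight_shape,
                                 rate = config$weight_shape)
  cohort$training <- rbinom(n, 1, config$p_training)
  cohort
}

#' True per-subject log hazard of a generated cohort
#'
#' Recomputes the exact log hazard used by [generate_cohort()] (index
#' effects at the true Z scores, MS component / score / occurrence effects,
#' and sex and race effects), for oracle comparisons against fitted
#' quantities. Requires the generator-only `true_z*` columns; data that did
#' not come from the generator is rejected.
#'
#' @param data A generated cohort (with `true_zH` ... `true_zHI` and MS
#'   scoring columns).
#' @param config The [cohort_config()] used at generation.
#' @return Numeric vector of log hazards.
#' @export
true_hazard <- function(data, config = cohort_config()) {
  zc <- c("true_zH", "true_zBMI", "true_zABSI", "true_zHI")
  if (!all(zc %in% names(data))) {
    abort("true_hazard() requires generator-produced records (true_z* columns absent)")
  }
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  hz <- config$hazard
  out <- hz$index$H(data$true_zH) + hz$index$BMI(data$true_zBMI) +
    hz$index$ABSI(data$true_zABSI) + hz$index$HI(data$true_zHI) +
    hz$sex_male * (data$sex == "male") + hz$race_black * data$race_black
  for (comp in names(hz$components)) {
    out <- out + hz$components[[comp]] * data[[comp]]
  }
  out + hz$ms * data$ms + hz$ms_score * data$ms_score
}
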