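test_that("AIC differences, the >6 flag, and tie ordering are correct", {
  fits <- list(fake_fit("A", 100), fake_fit("B", 103), fake_fit("C", 110))
  cmp <- aic_compare(fits)
  expect_equal(cmp$delta_i, c(0, 3, 10))
  expect_equal(cmp$significantly_worse, c(FALSE, FALSE, TRUE))
  expect_equal(cmp$tied_with_best, c(TRUE, TRUE, FALSE))

  # single fit
  expect_equal(aic_compare(list(fake_fit("only", 55)))$delta_i, 0)

  # equal AICs: both delta 0, deterministic order by name
  tie <- aic_compare(list(fake_fit("zeta", 80), fake_fit("alpha", 80)))
  expect_equal(tie$delta_i, c(0, 0))
  expect_equal(tie$model, c("alpha", "zeta"))

  # different cohorts are not comparable
  expect_error(aic_compare(list(fake_fit("A", 100, n = 1000),
                                fake_fit("B", 101, n = 999))),
               "different cohorts")
})

test_that("collinear predictors are rejected by name", {
  d <- generate_cohort(2000, seed = 51)
  expect_error(fit_cox(d, c("ms", "ms")), "ms",
               class = "anthrorisk_collinear")
  d$ms_copy <- d$ms
  expect_error(fit_cox(d, c("ms", "ms_copy")), "ms_copy",
               class = "anthrorisk_collinear")
})

test_that("weighted and unweighted fits agree exactly when weights are equal", {
  d <- generate_cohort(3000, seed = 52)
  d$const_w <- 3.7
  f1 <- fit_cox(d, "ms_score", weights_col = "const_w")
  f2 <- fit_cox(d, "ms_score", weights_col = NULL)
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-12)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-9)
  expect_equal(f1$concordance, f2$concordance, tolerance = 1e-12)
})

test_that("null covariates get CIs covering 1 and near-zero explained variation", {
  d <- generate_cohort(4000, null_effect_config(), seed = 53)
  fit <- fit_cox(d, character(0), name = "Base")
  td <- tidy(fit)
  expect_true(all(td$conf.low <= 1 & 1 <= td$conf.high))
  expect_lt(fit$r2, 0.01)
})

test_that("explained variation orders strong above weak predictors and rewards truth", {
  set.seed(54)
  d <- generate_cohort(6000, null_effect_config(), seed = 54)
  d$strong <- rnorm(6000)
  d$weak <- rnorm(6000)
  # regenerate survival driven by the strong predictor (HR e per SD)
  b0 <- exp(-9.7); th <- 0.09
  r <- exp(1 * d$strong + 0.1 * d$weak)
  t_death <- log(1 + th * rexp(6000) / (r * b0 * exp(th * d$age))) / th
  d$died <- as.integer(t_death < 20)
  d$followup_years <- pmin(t_death, 20)
  fs <- fit_cox(d, "strong", name = "strong", weights_col = NULL)
  fw <- fit_cox(d, "weak", name = "weak", weights_col = NULL)
  expect_gt(fs$r2, fw$r2)
  # adding the generating predictor to a nested model raises R2
  fboth <- fit_cox(d, c("weak", "strong"), name = "both", weights_col = NULL)
  expect_gte(fboth$r2, fw$r2)
  # and the partial likelihood never decreases under nesting
  expect_gte(fboth$loglik, fw$loglik)
})

test_that("concordance is 0.5 for uninformative scores and maximal for the truth", {
  d <- generate_cohort(4000, seed = 55)
  set.seed(56)
  c_rand <- concordance_index(d, rnorm(4000))
  expect_lt(abs(c_rand - 0.5), 0.03)
  expect_equal(concordance_index(d, rep(1, 4000)), 0.5)
  c_true <- concordance_index(d, d$true_log_hazard)
  c_ms <- concordance_index(d, d$ms_score)
  expect_gt(c_true, c_ms)
  expect_gt(c_true, c_rand)
})

test_that("correlation table has unit diagonal and flags degenerate columns", {
  set.seed(57)
  d <- tibble::tibble(a = rnorm(500), b = rnorm(500), c = rbinom(500, 1, 0.3),
                      k = 1)
  tab <- suppressWarnings(correlation_table(d, vars = c("a", "b", "c", "k")))
  expect_equal(diag(unclass(tab))[1:3], c(a = 1, b = 1, c = 1))
  expect_warning(correlation_table(d, vars = c("a", "k")), "zero-variance")
  expect_true(all(is.na(tab["k", ])))
  # independent columns: |r| below the 3/sqrt(n) null bound
  expect_lt(abs(tab["a", "b"]), 3 / sqrt(500))
  td <- tidy(tab)
  expect_equal(nrow(td), 6)
  expect_equal(td$r[td$row_var == "a" & td$col_var == "b"], tab["a", "b"])
})

test_that("model roster matches the published predictor sets", {
  roster <- model_roster()
  expect_equal(length(roster), 10)
  expect_equal(roster[["Base"]], character(0))
  expect_equal(roster[["ARI + MSx components"]],
               c("ari", "ms_bp", "ms_tg", "ms_hdl", "ms_glu"))
  expect_equal(roster[["ARI + MSx score"]], c("ari", "msx_score"))
  d <- generate_cohort(1500, seed = 58)
  expect_error(fit_model_roster(d, models = "No such model"), "unknown model")
})
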