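test_that("ARI is the exact sum of components and exp(ARI) the relative hazard", {
  curves <- list(
    H = make_constant_curve(0.1, "H"),
    BMI = make_constant_curve(0.2, "BMI"),
    ABSI = make_constant_curve(-0.05, "ABSI"),
    HI = make_constant_curve(0.05, "HI")
  )
  d <- tibble::tibble(zH = 0.3, zBMI = -1, zABSI = 2, zHI = 0)
  out <- add_ari(d, curves)
  expect_equal(out$ari, 0.3)
  expect_equal(out$relative_hazard, 1.34985880758, tolerance = 1e-10)
  expect_equal(out$ari, out$hH + out$hBMI + out$hABSI + out$hHI)

  # all-zero components: population-average risk
  zeroes <- lapply(curves, function(cv) make_constant_curve(0, cv$index))
  out0 <- add_ari(d, zeroes)
  expect_equal(out0$ari, 0)
  expect_equal(out0$relative_hazard, 1)

  expect_error(add_ari(d, curves[c("H", "BMI", "ABSI")]), "HI")
})

test_that("doubling every curve doubles ARI", {
  curves <- list(
    H = make_linear_curve(0.05, "H"), BMI = make_linear_curve(0.2, "BMI"),
    ABSI = make_linear_curve(0.1, "ABSI"), HI = make_linear_curve(-0.08, "HI")
  )
  doubled <- lapply(curves, function(cv) {
    cv$log_hazard <- 2 * cv$log_hazard
    cv
  })
  set.seed(2)
  d <- tibble::tibble(zH = rnorm(50), zBMI = rnorm(50), zABSI = rnorm(50),
                      zHI = rnorm(50))
  expect_equal(add_ari(d, doubled)$ari, 2 * add_ari(d, curves)$ari,
               tolerance = 1e-9)
})

test_that("evaluation clamps out-of-range z with a warning", {
  cv <- make_linear_curve(0.3, "BMI")
  expect_warning(v <- evaluate_hazard(cv, 10), "clamped")
  expect_equal(v, evaluate_hazard(cv, 4))
  expect_equal(evaluate_hazard(cv, c(-1, 0, 2)), c(-0.3, 0, 0.6),
               tolerance = 1e-9)
})

test_that("fitted curves satisfy the population-average centering anchor", {
  d <- generate_cohort(4000, single_index_config(linear_log_hazard(0.3)),
                       seed = 31)
  cv <- fit_hazard_curve(d, "true_zBMI", index = "BMI")
  z <- pmin(pmax(d$true_zBMI, -4), 4)
  expect_lt(abs(mean(exp(evaluate_hazard(cv, z))) - 1), 1e-6)

  # weighted variant anchors the weighted mean
  cvw <- fit_hazard_curve(d, "true_zBMI", index = "BMI", weighted = TRUE)
  expect_lt(abs(weighted.mean(exp(evaluate_hazard(cvw, z)), d$sample_weight) - 1),
            1e-6)
})

test_that("degenerate training inputs are rejected with informative errors", {
  d <- generate_cohort(400, null_effect_config(), seed = 32)
  d$died <- 0L
  expect_error(fit_hazard_curve(d, "true_zBMI"),
               class = "anthrorisk_too_few_events")
  d2 <- generate_cohort(400, null_effect_config(), seed = 33)
  d2$true_zBMI[5] <- Inf
  expect_error(fit_hazard_curve(d2, "true_zBMI"), "non-finite")
  expect_error(fit_hazard_curve(d2[, setdiff(names(d2), "died")], "true_zBMI"),
               "died")
})

test_that("hazard curves round-trip through the CSV grid + JSON sidecar", {
  d <- generate_cohort(3000, single_index_config(linear_log_hazard(0.25)),
                       seed = 34)
  cv <- fit_hazard_curve(d, "true_zBMI", index = "BMI")
  path <- withr::local_tempfile(fileext = ".csv")
  write_hazard_curve(cv, path)
  back <- read_hazard_curve(path)
  expect_equal(back$index, "BMI")
  expect_equal(back$grid_z, cv$grid_z)
  expect_equal(back$log_hazard, cv$log_hazard, tolerance = 1e-12)
  expect_equal(back$n_events, cv$n_events)
  z <- seq(-2, 2, 0.25)
  expect_equal(evaluate_hazard(back, z), evaluate_hazard(cv, z),
               tolerance = 1e-10)
})

test_that("a Cox fit of survival on ARI recovers coefficient near 1", {
  # ARI is itself a log hazard, so its own Cox coefficient is 1
  d <- generate_cohort(20000, seed = 35)
  d <- add_anthro_indices(d)
  ref <- build_reference(d)
  d <- add_zscores(d, ref)
  curves <- fit_hazard_curves(d[d$training == 1, ])
  d <- suppressWarnings(add_ari(d, curves))
  ev <- d[d$training == 0, ]
  fit <- fit_cox(ev, "ari", name = "ARI", weights_col = NULL)
  td <- tidy(fit)
  est <- td[td$term == "ari", ]
  expect_gt(est$estimate, 1 - 2.5 * est$std.error)
  expect_lt(est$estimate, 1 + 2.5 * est$std.error)
  # and fitted component hazards stay near-uncorrelated
  cm <- cor(as.matrix(ev[, c("hH", "hBMI", "hABSI", "hHI")]))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)
})
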