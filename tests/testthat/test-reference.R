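make_ref_sample <- function(n_per_sex = 600, seed = 9, age_max = 79.9) {
  set.seed(seed)
  tibble::tibble(
    sex = rep(c("male", "female"), each = n_per_sex),
    age = runif(2 * n_per_sex, 18, age_max),
    height_cm = rnorm(2 * n_per_sex, 170, 8),
    weight_kg = rnorm(2 * n_per_sex, 75, 12)
  ) |>
    dplyr::mutate(waist_cm = pmax(55, 0.9 * weight_kg + rnorm(2 * n_per_sex, 25, 6)),
                  hip_cm = pmax(70, 0.7 * weight_kg + rnorm(2 * n_per_sex, 50, 5))) |>
    add_anthro_indices()
}

test_that("cell moments are the sample moments (ddof = 1)", {
  set.seed(8)
  d <- tibble::tibble(
    sex = c("male", "male", rep("female", 30)),
    age = c(30, 31, runif(30, 28, 32)),
    height_cm = c(168, 172, rnorm(30, 160, 5)),
    weight_kg = c(20 * 1.68^2, 30 * 1.72^2, rnorm(30, 65, 8)),
    waist_cm = c(88, 94, runif(30, 75, 100)),
    hip_cm = c(98, 104, runif(30, 90, 115))
  ) |> add_anthro_indices()
  ref <- build_reference(d, age_bin_width = 5, min_cell_n = 2)
  cell <- ref[ref$sex == "male" & ref$index == "BMI", ]
  expect_equal(cell$mean_, 25)
  expect_equal(cell$sd_, 7.07106781187, tolerance = 1e-9)
  expect_equal(cell$n_, 2)
})

test_that("identical subjects trigger the zero-SD invariant error", {
  d <- tibble::tibble(
    sex = rep(c("male", "female"), each = 30), age = 40,
    height_cm = 170, weight_kg = 70, waist_cm = 90, hip_cm = 100
  ) |> add_anthro_indices()
  expect_error(build_reference(d, min_cell_n = 5), "SD is zero")
})

test_that("5-year binning on ages 18-80 yields 13 bins per sex", {
  d <- make_ref_sample(n_per_sex = 4000)
  ref <- build_reference(d, age_bin_width = 5, min_cell_n = 25)
  for (s in c("male", "female")) {
    bins <- unique(ref[ref$sex == s, c("age_min", "age_max")])
    expect_equal(nrow(bins), 13)
    expect_equal(min(bins$age_min), 18)
    expect_true(is.infinite(max(bins$age_max)))
    # bins partition the range without overlap
    bins <- bins[order(bins$age_min), ]
    expect_equal(bins$age_min[-1], bins$age_max[-nrow(bins)])
  }
})

test_that("undersized cells merge with neighbours and a missing sex errors", {
  d <- make_ref_sample(n_per_sex = 80)
  ref <- build_reference(d, age_bin_width = 5, min_cell_n = 25)
  counts <- unique(ref[, c("sex", "age_min", "n_")])
  expect_true(all(counts$n_ >= 25))
  expect_error(build_reference(d[d$sex == "male", ]), "female")
})

test_that("z-scores are zero at the cell mean and 2 at mean + 2 SD", {
  d <- make_ref_sample()
  ref <- build_reference(d, min_cell_n = 25)
  cell <- ref[ref$sex == "male" & ref$index == "BMI", ][1, ]
  mid_age <- (cell$age_min + min(cell$age_max, 80)) / 2
  hcell <- ref[ref$sex == "male" & ref$index == "H" &
                 ref$age_min == cell$age_min, ]
  q <- tibble::tibble(
    sex = "male", age = mid_age, height_cm = hcell$mean_,
    bmi = c(cell$mean_, cell$mean_ + 2 * cell$sd_),
    absi = ref$mean_[ref$sex == "male" & ref$index == "ABSI" &
                       ref$age_min == cell$age_min],
    hi = ref$mean_[ref$sex == "male" & ref$index == "HI" &
                     ref$age_min == cell$age_min]
  )
  z <- add_zscores(q, ref)
  expect_equal(z$zBMI, c(0, 2), tolerance = 1e-12)
  expect_equal(z$zH, c(0, 0), tolerance = 1e-12)
})

test_that("self-standardization gives stratum-wise mean 0 and SD 1", {
  d <- make_ref_sample(n_per_sex = 1500)
  ref <- build_reference(d, min_cell_n = 25)
  z <- add_zscores(d, ref)
  z$bin <- NA
  for (s in c("male", "female")) {
    bins <- unique(ref[ref$sex == s, c("age_min", "age_max")])
    sel <- z$sex == s
    z$bin[sel] <- findInterval(z$age[sel], sort(bins$age_min))
  }
  agg <- dplyr::summarise(dplyr::group_by(z, sex, bin),
                          m = mean(zBMI), s = sd(zBMI), .groups = "drop")
  expect_lt(max(abs(agg$m)), 1e-10)
  expect_lt(max(abs(agg$s - 1)), 1e-10)
})

test_that("z-scores are invariant to consistent affine unit changes", {
  d <- make_ref_sample()
  ref1 <- build_reference(d)
  z1 <- add_zscores(d, ref1)
  d2 <- dplyr::mutate(d, bmi = 2.2 * bmi + 1)
  z2 <- add_zscores(d2, build_reference(d2))
  expect_equal(z2$zBMI, z1$zBMI, tolerance = 1e-10)
})

test_that("out-of-range ages clamp to the boundary bin with a warning", {
  d <- make_ref_sample()
  ref <- build_reference(d)
  # the top bin is open-ended, so only ages below the grid clamp
  q <- d[1, ]
  q$age <- 16
  ws <- testthat::capture_warnings(z <- add_zscores(q, ref))
  expect_true(all(grepl("clamped", ws)))
  q2 <- d[1, ]
  q2$age <- 19
  z2 <- add_zscores(q2, ref)
  # clamped 16 lands in the same (bottom) cell as 19
  expect_equal(z$zBMI, z2$zBMI)
  q3 <- d[1, ]
  q3$age <- 97
  expect_no_warning(add_zscores(q3, ref))
})

test_that("reference tables round-trip through CSV", {
  d <- make_ref_sample()
  ref <- build_reference(d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(as.data.frame(back), as.data.frame(ref), tolerance = 1e-12)
  z1 <- add_zscores(d[1:5, ], ref)
  z2 <- add_zscores(d[1:5, ], back)
  expect_equal(z2$zABSI, z1$zABSI, tolerance = 1e-12)
})
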