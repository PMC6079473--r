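#' Build an age- and sex-specific reference table for anthropometric indices
#'
#' The mortality model works on Z scores of height, BMI, ABSI and hip index,
#' formed by subtracting the age- and sex-specific mean and dividing by the
#' standard deviation. This builds the reference moments from a sample.
#'
#' Age strata are a first bin covering ages 18-19, then `age_bin_width`-year
#' bins from 20 up to 80, with 80+ pooled into an open-ended last bin. Bins
#' with no observations are dropped; bins with fewer than `min_cell_n`
#' subjects are merged with their nearest age neighbour (within sex) until
#' every retained cell meets the minimum, keeping the moments estimable.
#'
#' @param data Cohort data frame with columns `sex` (`"male"`/`"female"`),
#'   `age` (years), `height_cm`, `bmi`, `absi`, `hi` (see
#'   [add_anthro_indices()]).
#' @param age_bin_width Width of the age bins in years (default 5).
#' @param min_cell_n Minimum subjects per cell before merging (default 25).
#' @param weighted If `TRUE`, use `sample_weight` to compute weighted
#'   means/SDs. Default unweighted.
#'
#' @return A tibble of class `ari_reference` with one row per
#'   sex x age-bin x index: columns `sex`, `age_min`, `age_max`, `index`
#'   (`H`, `BMI`, `ABSI`, `HI`), `mean_`, `sd_`, `n_`.
#' @seealso [add_zscores()], [write_reference()], [read_reference()]
#' @export
build_reference <- function(data, age_bin_width = 5, min_cell_n = 25,
                            weighted = FALSE) {
  needed <- c("sex", "age", "height_cm", "bmi", "absi", "hi")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("reference sample lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("reference sample is empty")
  present <- unique(data$sex)
  for (s in c("male", "female")) {
    if (!s %in% present) {
      abort(sprintf("reference sample has no %s subjects; both sexes required", s))
    }
  }
  if (weighted && !"sample_weight" %in% names(data)) {
    abort("weighted = TRUE requires a sample_weight column")
  }
  w <- if (weighted) data$sample_weight else rep(1, nrow(data))

  breaks <- c(18, seq(20, 80, by = age_bin_width), Inf)
  vals <- tibble(
    sex = data$sex, age = data$age, w = w,
    H = data$height_cm, BMI = data$bmi, ABSI = data$absi, HI = data$hi
  )
  if (any(vals$age < 18, na.rm = TRUE)) {
    abort("reference sample contains subjects under age 18")
  }
  vals$bin <- findInterval(vals$age, breaks)

  cells <- list()
  for (s in c("male", "female")) {
    vs <- vals[vals$sex == s & complete.cases(vals[c("age", "H", "BMI", "ABSI", "HI")]), ]
    occupied <- sort(unique(vs$bin))
    # group occupied bins; merge undersized groups into their nearest neighbour
    groups <- as.list(occupied)
    repeat {
      sizes <- vapply(groups, function(g) sum(vs$bin %in% g), integer(1))
      small <- which(sizes < min_cell_n)
      if (length(small) == 0) break
      if (length(groups) == 1) {
        abort(sprintf("too few %s subjects (%d) to form any reference cell of size %d",
                      s, sizes[1], min_cell_n))
      }
      i <- small[which.min(sizes[small])]
      j <- if (i == 1) 2 else if (i == length(groups)) i - 1 else {
        if (sizes[i - 1] <= sizes[i + 1]) i - 1 else i + 1
      }
      lo <- min(i, j)
      groups[[lo]] <- c(groups[[lo]], groups[[max(i, j)]])
      groups[[max(i, j)]] <- NULL
    }
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      sel <- vs[vs$bin %in% g, ]
      a_lo <- breaks[min(g)]
      # the top retained bin is open-ended (pools all older ages)
      a_hi <- if (gi == length(groups)) Inf else breaks[max(g) + 1]
      for (ix in c("H", "BMI", "ABSI", "HI")) {
        x <- sel[[ix]]
        ww <- sel$w
        m <- weighted.mean(x, ww)
        s2 <- if (weighted) {
          sum(ww * (x - m)^2) / (sum(ww) - sum(ww^2) / sum(ww))
        } else {
          sum((x - m)^2) / (length(x) - 1)
        }
        if (!is.finite(s2) || s2 <= 0) {
          abort(sprintf("degenerate reference cell (%s, ages [%g,%g), %s): SD is zero",
                        s, a_lo, a_hi, ix))
        }
        cells[[length(cells) + 1]] <- tibble(
          sex = s, age_min = a_lo, age_max = a_hi, index = ix,
          mean_ = m, sd_ = sqrt(s2), n_ = nrow(sel)
        )
      }
    }
  }
  out <- list_rbind(cells)
  class(out) <- c("ari_reference", class(out))
  out
}

# locate reference row for each (sex, age); ages beyond the table clamp
# to the boundary bin with a warning
lookup_cells <- function(ref, sex, age, index) {
  sub <- ref[ref$index == index, ]
  out_mean <- rep(NA_real_, length(age))
  out_sd <- rep(NA_real_, length(age))
  clamped <- FALSE
  for (s in unique(sex)) {
    rs <- sub[sub$sex == s, ]
    if (nrow(rs) == 0) abort(sprintf("reference table has no cells for sex %s", s))
    rs <- rs[order(rs$age_min), ]
    sel <- which(sex == s)
    a <- age[sel]
    lo <- min(rs$age_min)
    hi <- max(rs$age_max)
    if (any(a < lo | a >= hi, na.rm = TRUE)) clamped <- TRUE
    a <- pmin(pmax(a, lo), hi - 1e-9)
    cell <- findInterval(a, rs$age_min)
    out_mean[sel] <- rs$mean_[cell]
    out_sd[sel] <- rs$sd_[cell]
  }
  if (clamped) {
    warn("some ages fall outside the reference table; clamped to the nearest boundary age bin")
  }
  list(mean = out_mean, sd = out_sd)
}

#' Add age/sex-standardized Z scores of the four anthropometric indices
#'
#' Converts height, BMI, ABSI and hip index to Z scores
#' `z = (value - cell mean) / cell SD` against the stratum of the subject's
#' sex and age in `ref`. Ages outside the reference range are clamped to the
#' boundary bin with a warning. Z scores of magnitude above 6 are flagged in
#' `z_flag` as probable data errors (they are still returned).
#'
#' @param data Cohort with columns `sex`, `age`, `height_cm`, `bmi`,
#'   `absi`, `hi`.
#' @param ref A reference table from [build_reference()] or
#'   [read_reference()].
#' @return `data` with columns `zH`, `zBMI`, `zABSI`, `zHI`, `z_flag`
#'   appended.
#' @export
add_zscores <- function(data, ref) {
  stopifnot(inherits(ref, "ari_reference") || all(
    c("sex", "age_min", "age_max", "index", "mean_", "sd_") %in% names(ref)
  ))
  cols <- c(H = "height_cm", BMI = "bmi", ABSI = "absi", HI = "hi")
  out <- as_tibble(data)
  for (ix in names(cols)) {
    cell <- lookup_cells(ref, out$sex, out$age, ix)
    out[[paste0("z", ix)]] <- (out[[cols[[ix]]]] - cell$mean) / cell$sd
  }
  zmat <- abs(cbind(out$zH, out$zBMI, out$zABSI, out$zHI))
  out$z_flag <- !is.na(rowSums(zmat)) & apply(zmat, 1, max) > 6
  out
}

#' Read or write a reference table as CSV
#'
#' One row per sex x age-bin x index with columns
#' `sex, age_min, age_max, index, mean_, sd_, n_`, so published reference
#' moments can be substituted for sample-derived ones.
#'
#' @param ref An `ari_reference` table.
#' @param path File path.
#' @return [read_reference()] returns an `ari_reference` tibble;
#'   [write_reference()] returns `path` invisibly.
#' @export
write_reference <- function(ref, path) {
  readr::write_csv(as_tibble(ref), path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sex = "c", index = "c"))
  needed <- c("sex", "age_min", "age_max", "index", "mean_", "sd_", "n_")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("reference CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(out$sd_ <= 0)) abort("reference CSV contains nonpositive SD")
  class(out) <- c("ari_reference", class(out))
  out
}
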