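#' Fit a specific growth rate from one time series
#'
#' k is the slope of ln(value) versus time over the exponential window. The
#' default policy scores every contiguous span of at least `min_points`
#' positive values by the R-squared of its log-linear fit and keeps the
#' longest window whose R-squared is within `r2_tolerance` of the best, so a
#' long clean exponential phase beats a marginally better three-point
#' sliver; `window_policy = "all"` fits the whole series. Exact on noiseless
#' exponentials for any k and positive y0.
#'
#' @param curve Tibble with `time` and `value` columns (one series), and
#'   optionally a `time_unit` tag.
#' @param window_policy `"max_r2"` (default) or `"all"`.
#' @param min_points Minimum window size (>= 3).
#' @param r2_tolerance Window-selection tolerance on R-squared.
#' @return Object of class `growth_fit`: `k`, `r_squared`, `window`
#'   (c(t_start, t_end)), `n`, `y0`, `time_unit`.
#' @examples
#' tbl <- tibble::tibble(time = 0:10, value = 0.01 * exp(0.12 * 0:10))
#' fit_growth_rate(tbl)$k  # 0.12
#' @export
fit_growth_rate <- function(curve, window_policy = c("max_r2", "all"),
                            min_points = 3L, r2_tolerance = 0.005) {
  window_policy <- match.arg(window_policy)
  cv <- as_tibble(curve)
  if (!all(c("time", "value") %in% names(cv))) {
    abort("`curve` needs `time` and `value` columns.")
  }
  cv <- cv[order(cv$time), , drop = FALSE]
  if (is.unsorted(cv$time, strictly = TRUE)) {
    abort("Times must be strictly increasing within one series.")
  }
  if (any(cv$value < 0)) abort("Values must be non-negative.")
  unit <- if ("time_unit" %in% names(cv)) cv$time_unit[1] else NA_character_
  n <- nrow(cv)
  if (n < min_points) abort(sprintf("Need at least %d points.", min_points))

  t <- cv$time
  pos_ok <- cv$value > 0
  ly <- ifelse(pos_ok, log(pmax(cv$value, .Machine$double.xmin)), NA_real_)
  # prefix sums give each window's slope, R2 and slope SE in O(1)
  cs <- function(x) cumsum(ifelse(is.na(x), 0, x))
  S1 <- cs(ly); St <- cumsum(t); Stt <- cumsum(t^2)
  Sty <- cs(t * ly); Syy <- cs(ly^2)
  bad <- cumsum(!pos_ok)
  win_fit <- function(i, j) {
    if ((bad[j] - if (i > 1L) bad[i - 1L] else 0) > 0) return(NULL)
    m <- j - i + 1
    p <- function(S) S[j] - if (i > 1L) S[i - 1L] else 0
    sy <- p(S1); st <- p(St); stt <- p(Stt); sty <- p(Sty); syy <- p(Syy)
    vt <- stt - st^2 / m
    vy <- max(syy - sy^2 / m, 0)
    cty <- sty - st * sy / m
    k <- cty / vt
    ssr <- max(vy - cty^2 / vt, 0)
    r2 <- if (vy < 1e-20 || ssr < 1e-18) 1 else 1 - ssr / vy
    list(k = k, r2 = r2, i = i, j = j, y0 = exp(sy / m - k * st / m))
  }

  if (window_policy == "all") {
    best <- win_fit(1L, n)
    if (is.null(best)) abort("Non-positive values in the fit window.")
  } else {
    fits <- list()
    for (i in seq_len(n - min_points + 1L)) {
      for (j in seq(i + min_points - 1L, n)) {
        f <- win_fit(i, j)
        if (!is.null(f)) fits[[length(fits) + 1L]] <- f
      }
    }
    if (length(fits) == 0L) {
      abort("No window of positive values found; cannot fit a log-linear rate.")
    }
    lens <- vapply(fits, function(f) f$j - f$i, numeric(1))
    starts <- vapply(fits, `[[`, numeric(1), "i")
    r2s <- vapply(fits, `[[`, numeric(1), "r2")
    cand <- which(r2s >= max(r2s) - r2_tolerance)
    best <- fits[[cand[order(-lens[cand], starts[cand])[1]]]]
  }
  structure(
    list(k = best$k, r_squared = min(max(best$r2, 0), 1),
         window = c(t[best$i], t[best$j]),
         n = best$j - best$i + 1L, y0 = best$y0, time_unit = unit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> k = %.4g per %s  (window %g-%g, n=%d, R2=%.3f)\n",
              x$k, ifelse(is.na(x$time_unit), "time unit", x$time_unit),
              x$window[1], x$window[2], x$n, x$r_squared))
  invisible(x)
}

#' Fit growth rates for every strain and replicate in a curve table
#'
#' @param curves Tibble with `strain`, `replicate`, `time`, `value` and
#'   optionally `time_unit` and `acceptor`.
#' @param ... Passed to [fit_growth_rate()].
#' @return Tibble: one row per series with `strain`, (`acceptor`,)
#'   `replicate`, `k`, `r_squared`, `n`, `time_unit`.
#' @export
fit_growth_rates <- function(curves, ...) {
  cv <- as_tibble(curves)
  keys <- intersect(c("strain", "acceptor", "replicate"), names(cv))
  cv %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(d, g) {
      f <- fit_growth_rate(d, ...)
      tibble(k = f$k, r_squared = f$r_squared, n = f$n,
             time_unit = f$time_unit)
    }) %>%
    dplyr::ungroup()
}

#' Fold change between two groups of growth rates
#'
#' fold = mean(k_a) / mean(k_b), with an independent t-test on the rate
#' values. Inputs are numeric vectors of rates or tibbles from
#' [fit_growth_rates()]; tibbles carry a `time_unit` tag and mixing time
#' bases raises an error.
#'
#' @param rates_a,rates_b Rates for the two groups (numerator first).
#' @return One-row tibble: `fold`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `method`.
#' @export
fold_change_rates <- function(rates_a, rates_b) {
  get_rates <- function(x) {
    if (is.data.frame(x)) {
      list(k = x$k, unit = if ("time_unit" %in% names(x)) unique(x$time_unit)
           else NA_character_)
    } else {
      list(k = as.numeric(x), unit = NA_character_)
    }
  }
  a <- get_rates(rates_a); b <- get_rates(rates_b)
  units <- stats::na.omit(unique(c(a$unit, b$unit)))
  if (length(units) > 1L) {
    abort(sprintf("Rate groups use different time bases (%s); refusing to compare.",
                  paste(units, collapse = " vs ")))
  }
  if (length(a$k) == 0L || length(b$k) == 0L) abort("Both groups must be non-empty.")
  mb <- mean(b$k)
  if (mb == 0) {
    warn("Denominator group has zero mean rate; fold undefined.")
    fold <- NA_real_
  } else {
    fold <- mean(a$k) / mb
  }
  if (length(a$k) >= 2L || length(b$k) >= 2L) {
    tt <- tryCatch(stats::t.test(a$k, b$k), error = function(e) NULL)
  } else {
    tt <- NULL
  }
  tibble(fold = fold, mean_a = mean(a$k), mean_b = mb,
         n_a = length(a$k), n_b = length(b$k),
         statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value,
         method = if (is.null(tt)) "no test (too few rates)" else "independent t")
}

#' Convert ferrozine absorbance to Fe(II) concentration
#'
#' Linear inversion of a ferrozine calibration measured at 562 nm:
#' Fe(II) = (A - intercept) / slope * dilution_factor. The default dilution
#' factor of 10 matches the standard 0.1 mL sample into 0.9 mL HCl protocol.
#' Readings above `max_absorbance` trigger an extrapolation warning.
#'
#' @param absorbance_562 Absorbance reading(s) at 562 nm.
#' @param calibration_slope Calibration slope (absorbance per mM); > 0.
#' @param calibration_intercept Calibration intercept (default 0).
#' @param dilution_factor Sample dilution factor (default 10).
#' @param max_absorbance Upper end of the calibration range (optional).
#' @return Fe(II) concentration(s) in mM.
#' @export
ferrozine_fe2 <- function(absorbance_562, calibration_slope,
                          calibration_intercept = 0, dilution_factor = 10,
                          max_absorbance = NULL) {
  check_scalar_number(calibration_slope, "calibration_slope")
  if (calibration_slope <= 0) abort("`calibration_slope` must be > 0.")
  if (!is.null(max_absorbance) && any(absorbance_562 > max_absorbance)) {
    warn("Absorbance above the calibration range; extrapolating.")
  }
  (absorbance_562 - calibration_intercept) / calibration_slope * dilution_factor
}

#' Crystal-violet attachment index
#'
#' Ratio of the absorbance at 580 nm of solubilized crystal violet to the
#' absorbance at 600 nm of the culture; a per-culture measure of
#' surface-attached biomass.
#'
#' @param a580_cv Crystal violet absorbance at 580 nm.
#' @param a600_culture Culture absorbance at 600 nm (> 0).
#' @return Index value(s), vectorized.
#' @export
crystal_violet_index <- function(a580_cv, a600_culture) {
  if (any(a600_culture == 0)) abort("Culture absorbance must be non-zero.")
  a580_cv / a600_culture
}

#' Summarize attachment indices across replicates
#'
#' @param table Tibble with `strain`, `a580`, `a600` (one row per replicate).
#' @return Tibble per strain: `mean_index`, `sd_index`, `n`.
#' @export
summarize_attachment <- function(table) {
  tb <- as_tibble(table)
  tb %>%
    dplyr::mutate(index = crystal_violet_index(.data$a580, .data$a600)) %>%
    dplyr::summarise(mean_index = mean(.data$index),
                     sd_index = stats::sd(.data$index),
                     n = dplyr::n(), .by = "strain")
}
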