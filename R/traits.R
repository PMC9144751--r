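check_series <- function(times, areas, min_points = 2) {
  if (length(times) != length(areas)) {
    stop_invalid("plant_series", "times and areas must have equal length")
  }
  if (length(times) < min_points) {
    stop_invalid("plant_series", sprintf("at least %d timepoints are required", min_points))
  }
  if (any(!is.finite(times)) || any(!is.finite(areas))) {
    stop_invalid("plant_series", "times and areas must be finite")
  }
  if (any(diff(times) <= 0)) {
    stop_invalid("plant_series", "times must be strictly increasing")
  }
  invisible(TRUE)
}

#' Area under the growth curve
#'
#' Cumulative growth summary of a rosette-area time series. The default
#' `trapezoid` mode integrates area over time (px * day) with the
#' trapezoidal rule, sum of (s_i + s_{i-1})/2 * (t_i - t_{i-1}). The
#' `literal` mode evaluates the half-difference form sum of
#' (s_i - s_{i-1})/2, which telescopes to (s_n - s_0)/2 (px) and depends
#' only on the endpoints; it is kept for comparability with that printed
#' convention, but it cannot distinguish trajectories with equal endpoints,
#' so the trapezoid is the default.
#'
#' @param times Observation times in days, strictly increasing.
#' @param areas Rosette areas in px, same length.
#' @param mode `"trapezoid"` (default) or `"literal"`.
#' @return Scalar: px * day (trapezoid) or px (literal).
#' @export
growth_auc <- function(times, areas, mode = c("trapezoid", "literal")) {
  mode <- match.arg(mode)
  check_series(times, areas)
  n <- length(areas)
  if (mode == "trapezoid") {
    sum((areas[-1] + areas[-n]) / 2 * diff(times))
  } else {
    sum(diff(areas) / 2)
  }
}

#' Relative growth rate
#'
#' (ln s2 - ln s1) / (t2 - t1), per day, where s1/s2 are the first and last
#' observed areas and t1/t2 the first and last times. Equals the intrinsic
#' rate r exactly for exponential growth.
#'
#' @inheritParams growth_auc
#' @return Scalar rate per day.
#' @export
rgr <- function(times, areas) {
  check_series(times, areas)
  s1 <- areas[1]; s2 <- areas[length(areas)]
  if (s1 <= 0 || s2 <= 0) {
    abort("degenerate plant: RGR needs strictly positive first and last areas",
          class = "phenoprime_degenerate_trait")
  }
  (log(s2) - log(s1)) / (times[length(times)] - times[1])
}

#' Growth-curve slope
#'
#' Ordinary least-squares slope of area (px) against time (days): the
#' linear trend of the growth curve.
#'
#' @inheritParams growth_auc
#' @return Scalar slope in px/day.
#' @export
gc_slope <- function(times, areas) {
  check_series(times, areas)
  sum((times - mean(times)) * (areas - mean(areas))) / sum((times - mean(times))^2)
}

#' Green leaf index
#'
#' GLI = (2G - R - B) / (2G + R + B), a greenness score in `[-1, 1]` from
#' RGB channel values. Vectorized; pixels with a zero denominator (black)
#' return NA and should be excluded from averages, see [mean_gli()].
#'
#' @param R,G,B Channel values in `[0, 255]`.
#' @return Numeric vector of GLI values (NA where 2G + R + B = 0).
#' @export
gli <- function(R, G, B) {
  if (any(c(R, G, B) < 0 | c(R, G, B) > 255, na.rm = TRUE)) {
    stop_invalid("gli", "channel values must lie in [0, 255]")
  }
  den <- 2 * G + R + B
  out <- ifelse(den == 0, NA_real_, (2 * G - R - B) / den)
  out
}

#' Mean per-pixel green leaf index over a plant mask
#'
#' Averages [gli()] over pixels, excluding (and counting) zero-denominator
#' black pixels.
#'
#' @param R,G,B Per-pixel channel vectors over the plant mask.
#' @return Scalar mean GLI, with attribute `n_excluded` giving the count of
#'   excluded black pixels (a warning is raised when any are excluded).
#' @export
mean_gli <- function(R, G, B) {
  g <- gli(R, G, B)
  n_black <- sum(is.na(g))
  if (n_black > 0) {
    warn(sprintf("%d black pixel(s) excluded from the GLI mean", n_black))
  }
  structure(mean(g, na.rm = TRUE), n_excluded = n_black)
}

#' Compute the five phenotyping traits for one plant
#'
#' Assembles the trait vector from one plant's time series: growth-curve
#' slope (px/day), area under the curve (trapezoid by default), relative
#' growth rate (/day), final size (last observed area, px), and green leaf
#' index (from the last timepoint's mean channel values). A degenerate RGR
#' (nonpositive endpoint area) is reported as NA with `flag = "rgr_degenerate"`
#' rather than dropping the plant.
#'
#' @param times,areas The plant's time series (days, px).
#' @param R,G,B Optional per-time mean channel values; the last timepoint's
#'   values feed the GLI. Alternatively pass `gli_value` directly.
#' @param gli_value Optional precomputed per-plant mean GLI.
#' @param auc_mode Passed to [growth_auc()].
#' @return One-row tibble: `gc_slope`, `auc`, `rgr`, `fg`, `gli`, `flag`.
#' @export
compute_traits <- function(times, areas, R = NULL, G = NULL, B = NULL,
                           gli_value = NULL, auc_mode = "trapezoid") {
  check_series(times, areas)
  n <- length(areas)
  rgr_val <- tryCatch(rgr(times, areas), phenoprime_degenerate_trait = function(e) NA_real_)
  flag <- if (is.na(rgr_val)) "rgr_degenerate" else ""
  g <- if (!is.null(gli_value)) {
    unname(gli_value)
  } else if (!is.null(R)) {
    unname(gli(R[n], G[n], B[n]))
  } else {
    NA_real_
  }
  tibble::tibble(
    gc_slope = gc_slope(times, areas),
    auc = growth_auc(times, areas, mode = auc_mode),
    rgr = rgr_val,
    fg = areas[n],
    gli = g,
    flag = flag
  )
}

#' Per-plant trait table from a long-format time-series table
#'
#' Applies [compute_traits()] to every plant of a long table as produced by
#' [simulate_growth()] or [extract_time_series()].
#'
#' @param series Long tibble with columns `plant_id`, `treatment`,
#'   `concentration`, `condition`, `time_days`, `area_px` and either
#'   `mean_R`/`mean_G`/`mean_B` or `gli`.
#' @param auc_mode Passed to [growth_auc()].
#' @return Tibble with one row per plant: identifiers plus the five traits
#'   and a `flag` column.
#' @export
trait_table <- function(series, auc_mode = "trapezoid") {
  need <- c("plant_id", "treatment", "concentration", "condition",
            "time_days", "area_px")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols) > 0) {
    stop_invalid("series_table",
                 paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  has_rgb <- all(c("mean_R", "mean_G", "mean_B") %in% names(series))
  series |>
    dplyr::arrange(.data$plant_id, .data$time_days) |>
    dplyr::group_by(.data$plant_id, .data$treatment, .data$concentration,
                    .data$condition) |>
    dplyr::reframe(compute_traits(
      .data$time_days, .data$area_px,
      R = if (has_rgb) .data$mean_R else NULL,
      G = if (has_rgb) .data$mean_G else NULL,
      B = if (has_rgb) .data$mean_B else NULL,
      gli_value = if (!has_rgb && "gli" %in% names(series)) .data$gli[length(.data$gli)] else NULL,
      auc_mode = auc_mode
    ))
}
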