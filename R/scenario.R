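#' Default twice-daily imaging time grid
#'
#' Fourteen timepoints over seven consecutive days, two acquisitions per day
#' six hours apart (mimicking 10:00 and 16:00 imaging), expressed in days
#' since transfer to the plate.
#'
#' @return Numeric vector of length 14: 0.00, 0.25, 1.00, 1.25, ..., 6.25.
#' @export
default_timepoints <- function() {
  sort(as.vector(outer(c(0, 0.25), 0:6, `+`)))
}

#' Default priming treatment panel
#'
#' The unprimed control plus three polyamine-pathway priming agents
#' (1,3-diaminopropane, ornithine, putrescine) at 0.1 and 1 mM.
#'
#' @return Tibble with columns `treatment` (compound) and `concentration`
#'   (mM; 0 for the control).
#' @export
default_treatments <- function() {
  tibble::tibble(
    treatment = c("control", rep(c("DAP", "Orn", "Put"), each = 2)),
    concentration = c(0, rep(c(0.1, 1), times = 3))
  )
}

#' Default treatment effect multipliers
#'
#' Per treatment x condition multipliers on the intrinsic growth rate (r),
#' carrying capacity (K) and greenness used by [simulate_growth()]. The
#' defaults emulate, qualitatively, a screen in which most agents act as mild
#' salt-stress alleviators, the low-dose agents are close to neutral under
#' optimal conditions, and high-dose ornithine is growth inhibitory
#' everywhere. The control is identically 1.
#'
#' @param treatments Treatment panel as from [default_treatments()].
#' @param conditions Character vector of condition labels.
#' @return Tibble with columns `treatment`, `concentration`, `condition`,
#'   `r_mult`, `k_mult`, `gli_mult`.
#' @export
default_treatment_effects <- function(treatments = default_treatments(),
                                      conditions = c("optimal", "osmotic", "salt")) {
  grid <- tidyr::crossing(treatments, condition = conditions)
  key <- paste(grid$treatment, grid$concentration, grid$condition, sep = "|")
  r_mult <- rep(1, nrow(grid))
  k_mult <- rep(1, nrow(grid))
  gli_mult <- rep(1, nrow(grid))
  set_eff <- function(trt, conc, cond, r = 1, k = 1, g = 1) {
    i <- key == paste(trt, conc, cond, sep = "|")
    r_mult[i] <<- r; k_mult[i] <<- k; gli_mult[i] <<- g
  }
  # mild promoter at low DAP under optimal conditions
  set_eff("DAP", 0.1, "optimal", r = 1.05, k = 1.02, g = 1.03)
  set_eff("DAP", 1, "optimal", r = 0.97, k = 0.95, g = 0.99)
  # salt alleviation by all three compounds, strongest for 1 mM DAP
  set_eff("DAP", 0.1, "salt", r = 1.05, k = 1.10, g = 1.02)
  set_eff("DAP", 1, "salt", r = 1.20, k = 1.45, g = 1.06)
  set_eff("Orn", 0.1, "salt", r = 1.08, k = 1.20, g = 1.03)
  set_eff("Put", 0.1, "salt", r = 1.10, k = 1.25, g = 1.03)
  set_eff("Put", 1, "salt", r = 1.10, k = 1.30, g = 1.04)
  # high-dose ornithine inhibits growth under every condition
  set_eff("Orn", 1, "optimal", r = 0.92, k = 0.85, g = 0.97)
  set_eff("Orn", 1, "osmotic", r = 0.92, k = 0.85, g = 0.97)
  set_eff("Orn", 1, "salt", r = 0.95, k = 0.90, g = 1.01)
  # near-neutral elsewhere under osmotic stress
  set_eff("Put", 0.1, "osmotic", r = 1.01, k = 1.02, g = 1.00)
  dplyr::mutate(grid, r_mult = r_mult, k_mult = k_mult, gli_mult = gli_mult)
}

#' Growth simulation scenario
#'
#' Bundles the experimental design and growth-model parameters for
#' [simulate_growth()]: a logistic rosette-area model A(t) = K' / (1 +
#' ((K' - A0)/A0) exp(-r' t)) in which stress multiplies the carrying
#' capacity K and each treatment multiplies r, K and greenness, observed
#' under multiplicative lognormal measurement noise.
#'
#' Defaults follow the in-vitro screen design: 48 plants per treatment x
#' condition, 14 twice-daily timepoints over 7 days, three growth conditions
#' (optimal, 100 mM mannitol, 100 mM NaCl), and stress carrying-capacity
#' multipliers 0.30 / 0.22 so the unprimed final rosette size drops by 70%
#' under osmotic and 78% under salt stress.
#'
#' @param n_plants_per_group Plants per treatment x condition group.
#' @param timepoints Imaging times in days since transfer, strictly
#'   increasing and nonnegative.
#' @param conditions Condition labels; the first is taken as unstressed.
#' @param treatments Tibble (`treatment`, `concentration`) including the
#'   control row (`concentration` 0).
#' @param A0 Initial rosette area (px) at transfer.
#' @param K Control carrying capacity (px): asymptotic rosette area.
#' @param r Intrinsic growth rate (per day).
#' @param stress_K_multiplier Named per-condition multiplier on K, in (0, 1].
#' @param treatment_effects Tibble as from [default_treatment_effects()].
#' @param baseline_gli Mean green leaf index of unstressed control plants.
#' @param gli_sd Between-plant standard deviation of the green leaf index.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   area measurement noise (0 disables noise).
#' @param seed RNG seed; the same scenario and seed reproduce the same data.
#' @return An object of class `growth_scenario`.
#' @export
growth_scenario <- function(n_plants_per_group = 48,
                            timepoints = default_timepoints(),
                            conditions = c("optimal", "osmotic", "salt"),
                            treatments = default_treatments(),
                            A0 = 60, K = 6000, r = 1.5,
                            stress_K_multiplier = c(optimal = 1, osmotic = 0.30, salt = 0.22),
                            treatment_effects = default_treatment_effects(treatments, conditions),
                            baseline_gli = 0.40, gli_sd = 0.02,
                            noise_cv = 0.15, seed = 1L) {
  sc <- structure(
    list(
      n_plants_per_group = as.integer(n_plants_per_group),
      timepoints = as.numeric(timepoints),
      conditions = as.character(conditions),
      treatments = treatments,
      A0 = A0, K = K, r = r,
      stress_K_multiplier = stress_K_multiplier,
      treatment_effects = treatment_effects,
      baseline_gli = baseline_gli, gli_sd = gli_sd,
      noise_cv = noise_cv, seed = as.integer(seed)
    ),
    class = "growth_scenario"
  )
  validate_growth_scenario(sc)
  sc
}

validate_growth_scenario <- function(sc) {
  t <- sc$timepoints
  if (length(t) < 1 || any(!is.finite(t)) || any(t < 0)) {
    stop_invalid("growth_scenario", "timepoints must be finite and nonnegative")
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop_invalid("growth_scenario", "timepoints must be strictly increasing")
  }
  if (!isTRUE(sc$A0 > 0)) stop_invalid("growth_scenario", "A0 > 0 is required")
  if (!isTRUE(sc$K >= sc$A0)) stop_invalid("growth_scenario", "K >= A0 is required")
  if (!isTRUE(sc$r > 0)) stop_invalid("growth_scenario", "r > 0 is required")
  if (sc$n_plants_per_group < 1) {
    stop_invalid("growth_scenario", "n_plants_per_group must be at least 1")
  }
  sm <- sc$stress_K_multiplier
  if (!all(sc$conditions %in% names(sm))) {
    stop_invalid("growth_scenario", "stress_K_multiplier must name every condition")
  }
  if (any(sm <= 0 | sm > 1)) {
    stop_invalid("growth_scenario", "stress_K_multiplier values must lie in (0, 1]")
  }
  eff <- sc$treatment_effects
  need <- c("treatment", "concentration", "condition", "r_mult", "k_mult", "gli_mult")
  if (!all(need %in% names(eff))) {
    stop_invalid("growth_scenario", paste(
      "treatment_effects must have columns",
      paste(need, collapse = ", ")
    ))
  }
  if (any(eff$r_mult <= 0 | eff$k_mult <= 0 | eff$gli_mult <= 0)) {
    stop_invalid("growth_scenario", "treatment effect multipliers must be > 0")
  }
  if (!isTRUE(sc$noise_cv >= 0)) stop_invalid("growth_scenario", "noise_cv >= 0 is required")
  invisible(sc)
}

#' @export
print.growth_scenario <- function(x, ...) {
  cat("<growth_scenario>\n")
  cat(sprintf("  %d plants/group, %d timepoints (%.2f-%.2f d)\n",
              x$n_plants_per_group, length(x$timepoints),
              min(x$timepoints), max(x$timepoints)))
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  treatments: %d (incl. control)\n", nrow(x$treatments)))
  cat(sprintf("  A0 = %g px, K = %g px, r = %g /d, noise_cv = %g, seed = %d\n",
              x$A0, x$K, x$r, x$noise_cv, x$seed))
  invisible(x)
}

#' Rectangular multi-well plate layout
#'
#' Well centers on a regular grid, with the image scale set by the physical
#' well diameter (10.4 mm for the 48-well plates used in the assay).
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param well_diameter_px Well diameter in pixels.
#' @param pitch_px Center-to-center well spacing in pixels (must exceed the
#'   diameter so wells do not overlap).
#' @param margin_px Margin between the outer well edges and the image border.
#' @param well_diameter_mm Physical well diameter, used to set `mm_per_px`.
#' @return An object of class `plate_layout` with fields `n_rows`, `n_cols`,
#'   `well_centers` (tibble `well`, `x`, `y`), `well_diameter_px`,
#'   `image_shape` (height, width) and `mm_per_px`.
#' @export
plate_layout <- function(n_rows = 6, n_cols = 8, well_diameter_px = 104,
                         pitch_px = round(1.25 * well_diameter_px),
                         margin_px = round(0.35 * well_diameter_px),
                         well_diameter_mm = 10.4) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  half <- well_diameter_px / 2
  x0 <- margin_px + half
  y0 <- margin_px + half
  centers <- tidyr::crossing(row = seq_len(n_rows), col = seq_len(n_cols))
  centers <- dplyr::arrange(centers, .data$row, .data$col)
  centers <- tibble::tibble(
    well = seq_len(nrow(centers)),
    x = x0 + (centers$col - 1) * pitch_px,
    y = y0 + (centers$row - 1) * pitch_px
  )
  height <- ceiling(2 * (margin_px + half) + (n_rows - 1) * pitch_px)
  width <- ceiling(2 * (margin_px + half) + (n_cols - 1) * pitch_px)
  lay <- structure(
    list(
      n_rows = n_rows, n_cols = n_cols, well_centers = centers,
      well_diameter_px = well_diameter_px,
      image_shape = c(height = height, width = width),
      mm_per_px = well_diameter_mm / well_diameter_px
    ),
    class = "plate_layout"
  )
  validate_plate_layout(lay)
  lay
}

validate_plate_layout <- function(lay) {
  cc <- lay$well_centers
  if (nrow(cc) != lay$n_rows * lay$n_cols) {
    stop_invalid("plate_layout", "n_rows * n_cols must equal the number of well centers")
  }
  h <- lay$image_shape[["height"]]; w <- lay$image_shape[["width"]]
  half <- lay$well_diameter_px / 2
  if (any(cc$x - half < 0 | cc$x + half > w | cc$y - half < 0 | cc$y + half > h)) {
    stop_invalid("plate_layout", "all well discs must lie inside the image bounds")
  }
  if (nrow(cc) > 1) {
    d <- as.matrix(stats::dist(cbind(cc$x, cc$y)))
    diag(d) <- Inf
    if (min(d) <= lay$well_diameter_px) {
      stop_invalid("plate_layout", "wells overlap: pairwise center distance must exceed well_diameter_px")
    }
  }
  invisible(lay)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d wells, diameter %g px (%.3f mm/px), image %d x %d\n",
              x$n_rows, x$n_cols, x$well_diameter_px, x$mm_per_px,
              x$image_shape[["height"]], x$image_shape[["width"]]))
  invisible(x)
}
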