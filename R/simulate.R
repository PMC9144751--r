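#' Logistic rosette-area curve
#'
#' A(t) = K / (1 + ((K - A0)/A0) exp(-r t)). With K much larger than A0 the
#' curve reduces to exponential growth A0 exp(r t) over the observation
#' window, which is how the relative growth rate recovery is tested.
#'
#' @param t Times in days.
#' @param A0 Initial area (px).
#' @param K Carrying capacity (px).
#' @param r Growth rate (per day).
#' @return Areas in px, same length as `t`.
#' @export
logistic_area <- function(t, A0, K, r) {
  K / (1 + ((K - A0) / A0) * exp(-r * t))
}

# Mean RGB triple whose green leaf index equals `gli`, holding the red and
# blue channels at leaf-like values. Solves (2G - R - B)/(2G + R + B) = gli.
gli_to_rgb <- function(gli, R = 80, B = 60) {
  gli <- pmin(pmax(gli, 0), 0.55) # keeps the solved G channel within [0, 255]
  G <- (R + B) * (1 + gli) / (2 * (1 - gli))
  cbind(R = rep(R, length(G)), G = G, B = rep(B, length(G)))
}

# sdlog of a lognormal with mean 1 and coefficient of variation cv.
lognormal_sdlog <- function(cv) sqrt(log1p(cv^2))

#' Simulate per-plant rosette growth trajectories
#'
#' Draws one area/color time series per plant for every treatment x
#' condition group of the scenario. The noiseless expectation is the
#' logistic curve with K' = K * stress multiplier * treatment K-effect and
#' r' = r * treatment r-effect; observed areas are the expectation times
#' multiplicative lognormal noise with mean 1 and coefficient of variation
#' `noise_cv`. Each plant carries a constant mean greenness drawn around the
#' treatment greenness level, reported as mean RGB channels.
#'
#' @param scenario A [growth_scenario()].
#' @return Long-format tibble with columns `plant_id`, `treatment`,
#'   `concentration`, `condition`, `time_days`, `area_px`, `mean_R`,
#'   `mean_G`, `mean_B`.
#' @export
simulate_growth <- function(scenario) {
  validate_growth_scenario(scenario)
  sc <- scenario
  set.seed(sc$seed)
  groups <- tidyr::crossing(sc$treatments, condition = sc$conditions)
  groups <- dplyr::left_join(groups, sc$treatment_effects,
                             by = c("treatment", "concentration", "condition"))
  if (anyNA(groups$r_mult)) {
    stop_invalid("growth_scenario",
                 "treatment_effects must cover every treatment x condition")
  }
  nt <- length(sc$timepoints)
  np <- sc$n_plants_per_group
  sdlog <- lognormal_sdlog(sc$noise_cv)
  out <- purrr::pmap(groups, function(treatment, concentration, condition,
                                      r_mult, k_mult, gli_mult) {
    Kp <- sc$K * sc$stress_K_multiplier[[condition]] * k_mult
    rp <- sc$r * r_mult
    expectation <- logistic_area(sc$timepoints, sc$A0, Kp, rp)
    noise <- if (sc$noise_cv > 0) {
      matrix(exp(rnorm(np * nt, -sdlog^2 / 2, sdlog)), nrow = np)
    } else {
      matrix(1, nrow = np, ncol = nt)
    }
    gli_plant <- rep(sc$baseline_gli * gli_mult, np) +
      if (sc$gli_sd > 0) rnorm(np, 0, sc$gli_sd) else 0
    rgb <- gli_to_rgb(gli_plant)
    tibble::tibble(
      plant_id = rep(sprintf("%s_%g_%s_p%02d", treatment, concentration,
                             condition, seq_len(np)), each = nt),
      treatment = treatment,
      concentration = concentration,
      condition = condition,
      time_days = rep(sc$timepoints, times = np),
      area_px = as.vector(t(noise * rep(expectation, each = np))),
      mean_R = rep(rgb[, "R"], each = nt),
      mean_G = rep(rgb[, "G"], each = nt),
      mean_B = rep(rgb[, "B"], each = nt)
    )
  })
  dplyr::bind_rows(out)
}

#' Metabolite panel of the targeted assay
#'
#' The free amino acids, total polyamines and free polyamines quantified in
#' the screen. Free polyamines share compound names with the total pool and
#' are suffixed `(free)` to keep metabolite identifiers unique.
#'
#' @return Tibble with columns `metabolite` and `class` (one of
#'   `"free amino acid"`, `"total polyamine"`, `"free polyamine"`).
#' @export
default_metabolite_panel <- function() {
  faa <- c("TYRA", "LEU", "ILE", "PHE", "AcPUT", "GABA", "TRP", "BABA",
           "MET", "VAL", "PRO", "BALA", "TYR", "ALA", "THR", "AcORN",
           "AAA", "GLY", "ASP", "GLU", "SER", "ASN", "GLN", "CIT",
           "ARG", "HIS", "ORN", "CIS")
  tpa <- c("PUT", "DAP", "CAD", "NorSPD", "SPD", "HomoSPD", "ThSPM",
           "SPM", "AGM")
  fpa <- c("HIST", "PUT", "DAP", "CAD", "NorSPD", "SPD", "HomoSPD",
           "ThSPM", "SPM", "AGM")
  tibble::tibble(
    metabolite = c(faa, tpa, paste0(fpa, " (free)")),
    class = c(rep("free amino acid", length(faa)),
              rep("total polyamine", length(tpa)),
              rep("free polyamine", length(fpa)))
  )
}

#' Simulate a sample x metabolite concentration table
#'
#' Concentrations are baseline * exp(effect) * exp(N(0, noise_sd^2)), i.e.
#' lognormal noise around group means shifted on the natural-log scale, so
#' all values are strictly positive and ln-transformation (as used by the
#' downstream ANOVA, PCA and heatmap) recovers additive structure.
#'
#' @param design Tibble with one row per group; must contain `treatment`,
#'   `concentration` and `condition` columns.
#' @param n_per_group Biological replicates per group (default 4).
#' @param metabolites Tibble (`metabolite`, `class`) as from
#'   [default_metabolite_panel()].
#' @param effects Numeric matrix of natural-log fold changes, groups x
#'   metabolites (recycled from a scalar; default 0).
#' @param baseline Baseline concentration per metabolite (recycled).
#' @param noise_sd Standard deviation of the log-scale noise.
#' @param seed RNG seed.
#' @return Long tibble: `sample_id`, `treatment`, `concentration`,
#'   `condition`, `metabolite`, `class`, `value`.
#' @export
simulate_metabolites <- function(design = tidyr::crossing(
                                   default_treatments(),
                                   condition = c("optimal", "osmotic", "salt")
                                 ),
                                 n_per_group = 4,
                                 metabolites = default_metabolite_panel(),
                                 effects = 0,
                                 baseline = 100,
                                 noise_sd = 0.25,
                                 seed = 1L) {
  if (n_per_group < 2) {
    stop_invalid("metabolite_design", "n_per_group must be at least 2")
  }
  if (!isTRUE(noise_sd >= 0)) {
    stop_invalid("metabolite_design", "noise_sd >= 0 is required")
  }
  ng <- nrow(design); nm <- nrow(metabolites)
  eff <- matrix(effects, nrow = ng, ncol = nm,
                byrow = FALSE) # scalar or full matrix; recycled columnwise
  if (is.matrix(effects) && !all(dim(effects) == c(ng, nm))) {
    stop_invalid("metabolite_design", "effects matrix must be groups x metabolites")
  }
  if (any(!is.finite(eff))) {
    stop_invalid("metabolite_design", "effects must be finite")
  }
  baseline <- rep_len(baseline, nm)
  if (any(baseline <= 0)) {
    stop_invalid("metabolite_design", "baseline concentrations must be > 0")
  }
  set.seed(seed)
  rows <- purrr::map(seq_len(ng), function(g) {
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_per_group * nm, 0, noise_sd), nrow = n_per_group)
    } else {
      matrix(0, nrow = n_per_group, ncol = nm)
    }
    vals <- sweep(exp(noise), 2, baseline * exp(eff[g, ]), `*`)
    tibble::tibble(
      sample_id = rep(sprintf("%s_%g_%s_s%d", design$treatment[g],
                              design$concentration[g], design$condition[g],
                              seq_len(n_per_group)), times = nm),
      treatment = design$treatment[g],
      concentration = design$concentration[g],
      condition = design$condition[g],
      metabolite = rep(metabolites$metabolite, each = n_per_group),
      class = rep(metabolites$class, each = n_per_group),
      value = as.vector(vals)
    )
  })
  dplyr::bind_rows(rows)
}
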