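# Small scenario factories used across the suite.

# Control-only scenario under one condition; noiseless unless stated.
tiny_scenario <- function(noise_cv = 0, gli_sd = 0, n = 3, seed = 1,
                          conditions = "optimal", ...) {
  trts <- tibble::tibble(treatment = "control", concentration = 0)
  growth_scenario(
    n_plants_per_group = n,
    conditions = conditions,
    treatments = trts,
    stress_K_multiplier = c(optimal = 1, osmotic = 0.30, salt = 0.22)[conditions],
    treatment_effects = default_treatment_effects(trts, conditions),
    noise_cv = noise_cv, gli_sd = gli_sd, seed = seed, ...
  )
}

# Two-group scenario (control + one treated group) under one condition,
# with the treated group's r/K multipliers set explicitly.
two_group_scenario <- function(r_mult = 1, k_mult = 1, n = 48, seed = 1,
                               condition = "salt", noise_cv = 0.15) {
  trts <- tibble::tibble(treatment = c("control", "TRT"),
                         concentration = c(0, 1))
  eff <- default_treatment_effects(trts, condition)
  i <- eff$treatment == "TRT"
  eff$r_mult[i] <- r_mult
  eff$k_mult[i] <- k_mult
  growth_scenario(
    n_plants_per_group = n, conditions = condition, treatments = trts,
    stress_K_multiplier = setNames(
      c(optimal = 1, osmotic = 0.30, salt = 0.22)[condition], condition),
    treatment_effects = eff, noise_cv = noise_cv, seed = seed
  )
}

# Fabricated per-plant trait table with all-positive trait values.
fake_traits <- function(n = 6, treatment = "control", concentration = 0,
                        condition = "optimal", mult = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    plant_id = sprintf("%s_%g_%s_p%d", treatment, concentration, condition,
                       seq_len(n)),
    treatment = treatment, concentration = concentration,
    condition = condition,
    gc_slope = mult * stats::runif(n, 400, 600),
    auc = mult * stats::runif(n, 8000, 12000),
    rgr = mult * stats::runif(n, 0.5, 0.8),
    fg = mult * stats::runif(n, 4000, 6000),
    gli = mult * stats::runif(n, 0.35, 0.45),
    flag = ""
  )
}

# PBCI of one simulated two-group experiment.
simulated_pbci <- function(r_mult, k_mult, n, seed, noise_cv = 0.15) {
  sc <- two_group_scenario(r_mult = r_mult, k_mult = k_mult, n = n,
                           seed = seed, noise_cv = noise_cv)
  tt <- trait_table(simulate_growth(sc))
  ratios <- suppressWarnings(trait_log2_ratios(
    dplyr::filter(tt, treatment == "TRT"),
    dplyr::filter(tt, treatment == "control")
  ))
  as.numeric(pbci_score(ratios))
}
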