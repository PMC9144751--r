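trait_names <- c("gc_slope", "auc", "rgr", "fg", "gli")

#' Per-trait log2 ratios of a treatment against its control
#'
#' For each of the five phenotyping traits, log2 of the ratio between the
#' treatment group mean and the control group mean. Plants are unpaired
#' across groups, so ratios are taken between group means, not averaged
#' per-plant ratios. A trait whose group mean is nonpositive in either
#' group has no principled log ratio; it is returned as NA with a warning
#' rather than clamped.
#'
#' @param treatment_traits,control_traits Trait tables ([trait_table()]
#'   rows) for the two groups, from the same growth condition.
#' @return Named numeric vector of length 5 (`gc_slope`, `auc`, `rgr`,
#'   `fg`, `gli`), NA where undefined.
#' @export
trait_log2_ratios <- function(treatment_traits, control_traits) {
  if (nrow(treatment_traits) == 0 || nrow(control_traits) == 0) {
    stop_invalid("pbci", "both groups must be non-empty")
  }
  out <- vapply(trait_names, function(tr) {
    mt <- mean(treatment_traits[[tr]], na.rm = TRUE)
    mc <- mean(control_traits[[tr]], na.rm = TRUE)
    if (!is.finite(mt) || !is.finite(mc) || mt <= 0 || mc <= 0) {
      return(NA_real_)
    }
    log2(mt / mc)
  }, numeric(1))
  if (anyNA(out)) {
    warn(sprintf("log2 ratio undefined (nonpositive group mean) for: %s",
                 paste(trait_names[is.na(out)], collapse = ", ")))
  }
  out
}

#' Plant Biostimulant Characterization Index
#'
#' The PBCI of a treatment within a growth condition is the sum of the five
#' per-trait log2 treatment/control ratios. Undefined (NA) ratios are
#' excluded from the sum and their count reported.
#'
#' @param ratios Named ratio vector from [trait_log2_ratios()].
#' @return Scalar PBCI with attribute `n_missing`.
#' @export
pbci_score <- function(ratios) {
  defined <- ratios[!is.na(ratios)]
  if (length(defined) == 0) {
    abort("PBCI undefined: all trait ratios are missing",
          class = "phenoprime_pbci_error")
  }
  structure(sum(defined), n_missing = sum(is.na(ratios)))
}

#' Classify a PBCI value
#'
#' Positive PBCI marks a growth promoter under optimal conditions or a
#' stress alleviator under a stress condition; negative PBCI marks a
#' stress inductor; exactly zero is labeled neutral.
#'
#' @param pbci Finite PBCI value.
#' @param condition Condition label.
#' @param optimal_label Which condition label counts as unstressed.
#' @param conditions Known condition labels; anything else errors.
#' @return One of `"promoter"`, `"alleviator"`, `"inductor"`, `"neutral"`.
#' @export
classify_pbci <- function(pbci, condition, optimal_label = "optimal",
                          conditions = c("optimal", "osmotic", "salt")) {
  if (!is.finite(pbci)) stop_invalid("pbci", "PBCI must be finite")
  if (!condition %in% conditions) {
    stop_invalid("pbci", sprintf("unknown condition label '%s'", condition))
  }
  if (pbci > 0) {
    if (condition == optimal_label) "promoter" else "alleviator"
  } else if (pbci < 0) {
    "inductor"
  } else {
    "neutral"
  }
}

#' PBCI records for every treatment x condition
#'
#' Scores each treatment group against the unprimed control of the same
#' growth condition. The control scored against itself yields all-zero
#' ratios, PBCI 0 and the neutral label.
#'
#' @param traits Trait table ([trait_table()]) covering all groups.
#' @param control_treatment Treatment label of the unprimed control.
#' @param optimal_label,conditions Passed to [classify_pbci()].
#' @return Tibble with one row per treatment x condition: identifiers, the
#'   five log2 ratio columns, `n_missing`, `pbci`, `label`.
#' @export
pbci_table <- function(traits, control_treatment = "control",
                       optimal_label = "optimal",
                       conditions = unique(traits$condition)) {
  groups <- dplyr::distinct(traits, .data$treatment, .data$concentration,
                            .data$condition)
  purrr::pmap_dfr(groups, function(treatment, concentration, condition) {
    ctrl <- dplyr::filter(traits, .data$treatment == control_treatment,
                          .data$condition == !!condition)
    if (nrow(ctrl) == 0) {
      stop_invalid("pbci", sprintf("no control group for condition '%s'", condition))
    }
    grp <- dplyr::filter(traits, .data$treatment == !!treatment,
                         .data$concentration == !!concentration,
                         .data$condition == !!condition)
    ratios <- trait_log2_ratios(grp, ctrl)
    score <- pbci_score(ratios)
    tibble::tibble(
      treatment = treatment, concentration = concentration,
      condition = condition,
      !!!as.list(ratios),
      n_missing = attr(score, "n_missing"),
      pbci = as.numeric(score),
      label = classify_pbci(as.numeric(score), condition,
                            optimal_label = optimal_label,
                            conditions = conditions)
    )
  })
}

#' Bootstrap confidence interval and sign stability of the PBCI
#'
#' Resamples plants with replacement within the treatment and control
#' groups, recomputes the PBCI for each replicate, and reports a
#' percentile confidence interval together with the fraction of replicates
#' sharing the point estimate's sign (for a zero point estimate, the
#' fraction of positive replicates). The index itself carries no
#' uncertainty statement; this resampling layer is an addition of this
#' package.
#'
#' @param treatment_traits,control_traits Trait tables of the two groups
#'   (at least 3 plants each).
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed RNG seed.
#' @param conf Confidence level of the percentile interval.
#' @return List: `pbci` (point estimate), `ci` (length-2 vector, NA when
#'   more than half the replicates had undefined ratios), `sign_stability`,
#'   `n_boot`, `n_failed`.
#' @export
bootstrap_pbci <- function(treatment_traits, control_traits, n_boot = 1000,
                           seed = 1L, conf = 0.95) {
  if (nrow(treatment_traits) < 3 || nrow(control_traits) < 3) {
    stop_invalid("pbci_bootstrap", "group sizes must be at least 3")
  }
  if (n_boot < 100) stop_invalid("pbci_bootstrap", "n_boot must be at least 100")
  point <- as.numeric(pbci_score(
    suppressWarnings(trait_log2_ratios(treatment_traits, control_traits))
  ))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    ti <- sample.int(nrow(treatment_traits), replace = TRUE)
    ci <- sample.int(nrow(control_traits), replace = TRUE)
    r <- suppressWarnings(
      trait_log2_ratios(treatment_traits[ti, ], control_traits[ci, ])
    )
    if (all(is.na(r))) NA_real_ else as.numeric(pbci_score(r))
  }, numeric(1))
  n_failed <- sum(is.na(reps))
  ci <- if (n_failed > n_boot / 2) {
    warn("bootstrap CI unavailable: ratios undefined in more than half the replicates")
    c(NA_real_, NA_real_)
  } else {
    unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE))
  }
  ok <- reps[!is.na(reps)]
  stability <- if (point > 0) {
    mean(ok > 0)
  } else if (point < 0) {
    mean(ok < 0)
  } else {
    mean(ok > 0)
  }
  list(pbci = point, ci = ci, sign_stability = stability,
       n_boot = n_boot, n_failed = n_failed)
}

#' Tidy table for a parallel-coordinates view of the trait ratios
#'
#' Long format of the PBCI records: one row per defined treatment x
#' condition x trait log2 ratio, with the PBCI and classification label
#' carried alongside (the blue promoter/alleviator vs red inductor
#' semantics of the parallel-coordinates figure).
#'
#' @param records Output of [pbci_table()].
#' @return Tibble: `treatment`, `concentration`, `condition`, `trait`,
#'   `log2_ratio`, `pbci`, `label`, `n_missing`.
#' @export
parallel_coordinates_table <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      treatment = character(), concentration = numeric(),
      condition = character(), trait = character(),
      log2_ratio = numeric(), pbci = numeric(), label = character(),
      n_missing = integer()
    ))
  }
  records |>
    tidyr::pivot_longer(dplyr::all_of(trait_names), names_to = "trait",
                        values_to = "log2_ratio") |>
    dplyr::filter(!is.na(.data$log2_ratio)) |>
    dplyr::select("treatment", "concentration", "condition", "trait",
                  "log2_ratio", "pbci", "label", "n_missing")
}
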