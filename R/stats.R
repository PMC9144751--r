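group_label <- function(treatment, concentration) {
  ifelse(concentration == 0, treatment,
         sprintf("%s %g mM", treatment, concentration))
}

#' Kruskal-Wallis tests of AUC against the control
#'
#' Within one growth condition, tests each treatment group's area under the
#' growth curve against the unprimed control with a two-group
#' Kruskal-Wallis rank test (equivalent to a Wilcoxon rank-sum test), and
#' flags significance at `alpha`. No multiplicity correction is applied by
#' default; set `p_adjust_method` to correct across treatments.
#'
#' @param traits Trait table ([trait_table()]).
#' @param condition Condition to test within.
#' @param control_treatment Label of the control group.
#' @param alpha Significance level for the asterisk flag.
#' @param p_adjust_method Passed to [stats::p.adjust()] (default `"none"`).
#' @return Tibble per treatment: identifiers, group sizes, `statistic`,
#'   `df`, `p_value`, `significant`.
#' @export
kruskal_auc <- function(traits, condition, control_treatment = "control",
                        alpha = 0.05, p_adjust_method = "none") {
  ctrl <- dplyr::filter(traits, .data$condition == !!condition,
                        .data$treatment == control_treatment)
  if (nrow(ctrl) == 0) {
    stop_invalid("kruskal_auc", sprintf("no control group in condition '%s'", condition))
  }
  grps <- traits |>
    dplyr::filter(.data$condition == !!condition,
                  .data$treatment != control_treatment) |>
    dplyr::distinct(.data$treatment, .data$concentration)
  if (nrow(grps) == 0) {
    stop_invalid("kruskal_auc", "no non-control treatment groups to test")
  }
  out <- purrr::pmap_dfr(grps, function(treatment, concentration) {
    grp <- dplyr::filter(traits, .data$condition == !!condition,
                         .data$treatment == !!treatment,
                         .data$concentration == !!concentration)
    if (nrow(grp) < 2 || nrow(ctrl) < 2) {
      stop_invalid("kruskal_auc", "at least 2 plants per group are required")
    }
    kt <- kruskal.test(list(grp$auc, ctrl$auc))
    tibble::tibble(
      treatment = treatment, concentration = concentration,
      condition = condition, n_treatment = nrow(grp), n_control = nrow(ctrl),
      statistic = unname(kt$statistic), df = unname(kt$parameter),
      p_value = kt$p.value
    )
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust_method)
  out$significant <- out$p_value < alpha
  out
}

# Duncan's multiple range test for one pair of means within a fitted
# one-way layout: the critical studentized range uses the protection level
# alpha_p = 1 - (1 - alpha)^(p - 1), where p is the span of the pair in the
# ordering of group means. Returns an equivalent p-value on the alpha scale.
duncan_pair_p <- function(mean_a, mean_b, span, mse, df, n_harm) {
  q_obs <- abs(mean_a - mean_b) / sqrt(mse / n_harm)
  p_range <- stats::ptukey(q_obs, span, df, lower.tail = FALSE)
  1 - (1 - p_range)^(1 / max(span - 1, 1))
}

#' Per-metabolite ANOVA with post hoc comparisons against the control
#'
#' For each metabolite within each growth condition, a one-way ANOVA on
#' ln-transformed concentrations across treatment groups, followed by post
#' hoc comparisons of every treatment against the unprimed control (Tukey
#' HSD by default; Duncan's multiple range test optionally). A metabolite
#' with zero variance everywhere is flagged undefined rather than tested.
#'
#' @param table Long metabolite table as from [simulate_metabolites()]
#'   (`sample_id`, `treatment`, `concentration`, `condition`, `metabolite`,
#'   `class`, `value` with strictly positive values).
#' @param control_treatment Label of the control group.
#' @param posthoc `"tukey"` (default) or `"duncan"`.
#' @param alpha Significance level.
#' @return Tibble with one row per condition x metabolite x treatment:
#'   `p_anova`, `p_posthoc`, `significant` (ANOVA and post hoc both below
#'   `alpha`), `flag` (`"undefined"` when untestable).
#' @export
metabolite_anova <- function(table, control_treatment = "control",
                             posthoc = c("tukey", "duncan"), alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  if (any(table$value <= 0)) {
    stop_invalid("metabolite_table", "values must be strictly positive for the ln transform")
  }
  table <- dplyr::mutate(table,
                         group = group_label(.data$treatment, .data$concentration))
  ctrl_label <- group_label(control_treatment, 0)
  combos <- dplyr::distinct(table, .data$condition, .data$metabolite, .data$class)
  purrr::pmap_dfr(combos, function(condition, metabolite, class) {
    d <- dplyr::filter(table, .data$condition == !!condition,
                       .data$metabolite == !!metabolite)
    if (!ctrl_label %in% d$group) {
      stop_invalid("metabolite_table", sprintf(
        "no control group for metabolite '%s' in condition '%s'", metabolite, condition))
    }
    d$y <- log(d$value)
    d$group <- factor(d$group)
    others <- setdiff(levels(d$group), ctrl_label)
    base <- tibble::tibble(
      condition = condition, metabolite = metabolite, class = class,
      treatment = others
    )
    wv <- tapply(d$y, d$group, var)
    if (all(wv < .Machine$double.eps, na.rm = TRUE)) {
      return(dplyr::mutate(base, p_anova = NA_real_, p_posthoc = NA_real_,
                           significant = FALSE, flag = "undefined"))
    }
    fit <- aov(y ~ group, data = d)
    p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
    means <- tapply(d$y, d$group, mean)
    ns <- tapply(d$y, d$group, length)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    p_post <- if (posthoc == "tukey") {
      tk <- TukeyHSD(fit)$group
      vapply(others, function(g) {
        row <- rownames(tk) %in% c(paste(g, ctrl_label, sep = "-"),
                                   paste(ctrl_label, g, sep = "-"))
        tk[row, "p adj"][1]
      }, numeric(1))
    } else {
      rk <- rank(means)
      vapply(others, function(g) {
        span <- abs(rk[[g]] - rk[[ctrl_label]]) + 1
        n_harm <- 2 / (1 / ns[[g]] + 1 / ns[[ctrl_label]])
        duncan_pair_p(means[[g]], means[[ctrl_label]], span, mse,
                      fit$df.residual, n_harm)
      }, numeric(1))
    }
    dplyr::mutate(base, p_anova = p_anova, p_posthoc = unname(p_post),
                  significant = p_anova < alpha & p_posthoc < alpha,
                  flag = "")
  })
}

#' Two-way treatment x condition ANOVA per metabolite
#'
#' Companion to [metabolite_anova()]: fits ln(value) ~ treatment group *
#' condition across all conditions at once and reports the factor and
#' interaction p-values per metabolite.
#'
#' @inheritParams metabolite_anova
#' @return Tibble per metabolite: `p_group`, `p_condition`, `p_interaction`.
#' @export
metabolite_anova_two_way <- function(table) {
  if (any(table$value <= 0)) {
    stop_invalid("metabolite_table", "values must be strictly positive for the ln transform")
  }
  table <- dplyr::mutate(table,
                         group = group_label(.data$treatment, .data$concentration))
  combos <- dplyr::distinct(table, .data$metabolite, .data$class)
  purrr::pmap_dfr(combos, function(metabolite, class) {
    d <- dplyr::filter(table, .data$metabolite == !!metabolite)
    fit <- aov(log(value) ~ group * condition, data = d)
    p <- summary(fit)[[1]][["Pr(>F)"]]
    tibble::tibble(metabolite = metabolite, class = class,
                   p_group = p[1], p_condition = p[2], p_interaction = p[3])
  })
}

#' Principal component analysis by singular value decomposition
#'
#' Centers (and by default unit-variance scales) the columns of a samples x
#' variables matrix and decomposes it with the SVD. Scores are U * D,
#' loadings are the right singular vectors, and the variance explained by
#' component k is sigma_k^2 / sum(sigma^2). Constant columns cannot be
#' unit-scaled and are dropped with a warning.
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @param center,scale Column centering / unit-variance scaling.
#' @return Object of class `pca_result`: `scores`, `loadings`, `sdev`,
#'   `variance_explained`, `dropped` (names of dropped columns).
#' @export
pca_svd <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop_invalid("pca", "need at least 2 samples and 2 variables")
  }
  if (any(!is.finite(x))) stop_invalid("pca", "values must be finite")
  dropped <- character()
  if (scale) {
    const <- apply(x, 2, function(v) var(v) < .Machine$double.eps)
    if (any(const)) {
      dropped <- colnames(x)[const] %||% as.character(which(const))
      warn(sprintf("dropping %d constant column(s) under unit-variance scaling",
                   sum(const)))
      x <- x[, !const, drop = FALSE]
      if (ncol(x) < 2) stop_invalid("pca", "fewer than 2 non-constant variables")
    }
  }
  xs <- scale(x, center = center, scale = scale)
  sv <- svd(xs)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(sv$d))
  structure(
    list(scores = scores, loadings = loadings,
         sdev = sv$d / sqrt(max(nrow(x) - 1, 1)),
         variance_explained = sv$d^2 / sum(sv$d^2),
         dropped = dropped),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<pca_result> %d samples x %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(ve))),
                    100 * ve[seq_len(min(3, length(ve)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pivot a long metabolite table to a samples x metabolites matrix
#'
#' @param table Long metabolite table.
#' @param transform Applied to the values (default natural log).
#' @return Numeric matrix with sample ids as row names.
#' @export
metabolite_matrix <- function(table, transform = log) {
  wide <- table |>
    dplyr::select("sample_id", "metabolite", "value") |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  transform(m)
}

#' PCA of a metabolite table
#'
#' Builds the PCA input the screen uses: ln-transformed concentrations,
#' either averaged per treatment x condition group (default, matching a
#' biplot of group means) or per sample, then column-standardized and
#' decomposed with [pca_svd()]. Extra numeric columns (e.g. growth traits
#' aggregated to the same groups) can be appended via `extra`.
#'
#' @param table Long metabolite table.
#' @param mode `"group_means"` or `"samples"`.
#' @param extra Optional data frame of additional variables, with rows
#'   matching the PCA rows (groups or samples, in the returned row order).
#' @param scale Unit-variance scaling (default TRUE).
#' @return A `pca_result`; row names identify groups or samples.
#' @export
metabolite_pca <- function(table, mode = c("group_means", "samples"),
                           extra = NULL, scale = TRUE) {
  mode <- match.arg(mode)
  if (any(table$value <= 0)) {
    stop_invalid("metabolite_table", "values must be strictly positive for the ln transform")
  }
  if (mode == "samples") {
    m <- metabolite_matrix(table)
  } else {
    means <- table |>
      dplyr::group_by(.data$treatment, .data$concentration, .data$condition,
                      .data$metabolite) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(row = paste(group_label(.data$treatment, .data$concentration),
                                .data$condition, sep = " | ")) |>
      dplyr::select("row", "metabolite", "value") |>
      tidyr::pivot_wider(names_from = "metabolite", values_from = "value")
    m <- log(as.matrix(means[, -1]))
    rownames(m) <- means$row
  }
  if (!is.null(extra)) m <- cbind(m, as.matrix(extra))
  pca_svd(m, center = TRUE, scale = scale)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations between the columns of a samples x
#' variables matrix, with two-sided p-values from the t distribution on
#' n - 2 degrees of freedom. Zero-variance variables yield NA correlations
#' (flagged with a warning), never a silent zero.
#'
#' @param x Numeric matrix or data frame, samples in rows (>= 3).
#' @return List: `r` (correlations, unit diagonal), `p` (p-values, NA on
#'   the diagonal), `n` (sample count).
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop_invalid("correlation", "need at least 3 samples")
  if (any(!is.finite(x))) stop_invalid("correlation", "values must be finite")
  zero_var <- apply(x, 2, function(v) var(v) < .Machine$double.eps)
  if (any(zero_var)) {
    warn(sprintf("%d zero-variance variable(s): correlations undefined (NA)",
                 sum(zero_var)))
  }
  r <- suppressWarnings(cor(x))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  dg <- diag(r)
  dg[!zero_var] <- 1
  diag(r) <- dg
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Heatmap matrix of ln group-mean concentrations
#'
#' The display matrix of the metabolite heatmap: natural log of the group
#' mean concentration (default n = 4 replicates per group), metabolites in
#' rows ordered in class blocks (free amino acids, then total polyamines,
#' then free polyamines), treatment x condition groups in columns ordered
#' by condition. Optionally carries the per-cell significance dots from
#' [metabolite_anova()].
#'
#' @param table Long metabolite table (strictly positive values).
#' @param anova Optional output of [metabolite_anova()] to mark
#'   significant treatment cells.
#' @return List: `matrix` (metabolites x groups, ln scale), `row_class`
#'   (metabolite class per row), `significant` (logical matrix, NA for the
#'   control columns, NULL when `anova` is not supplied).
#' @export
heatmap_matrix <- function(table, anova = NULL) {
  if (any(table$value <= 0)) {
    stop_invalid("metabolite_table", "values must be strictly positive for the ln transform")
  }
  class_order <- c("free amino acid", "total polyamine", "free polyamine")
  means <- table |>
    dplyr::group_by(.data$metabolite, .data$class, .data$treatment,
                    .data$concentration, .data$condition) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(
      column = paste(group_label(.data$treatment, .data$concentration),
                     .data$condition, sep = " | "),
      class = factor(.data$class, levels = intersect(class_order, unique(.data$class)))
    ) |>
    dplyr::arrange(.data$condition, .data$treatment, .data$concentration)
  col_order <- unique(means$column)
  row_info <- means |>
    dplyr::distinct(.data$metabolite, .data$class) |>
    dplyr::arrange(.data$class)
  wide <- means |>
    dplyr::select("metabolite", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  m <- log(as.matrix(wide[, -1]))
  rownames(m) <- wide$metabolite
  m <- m[row_info$metabolite, col_order, drop = FALSE]
  sig <- NULL
  if (!is.null(anova)) {
    sig <- matrix(NA, nrow = nrow(m), ncol = ncol(m),
                  dimnames = dimnames(m))
    lookup <- means |>
      dplyr::distinct(.data$column, .data$treatment, .data$concentration,
                      .data$condition) |>
      dplyr::mutate(group = group_label(.data$treatment, .data$concentration))
    for (j in seq_len(nrow(lookup))) {
      hit <- anova$treatment == lookup$group[j] &
        anova$condition == lookup$condition[j]
      if (!any(hit)) next # control column: no vs-control comparison
      sig[anova$metabolite[hit], lookup$column[j]] <- anova$significant[hit]
    }
  }
  list(matrix = m, row_class = as.character(row_info$class), significant = sig)
}
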