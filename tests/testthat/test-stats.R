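make_auc_traits <- function(groups, n = 10, seed = 1) {
  set.seed(seed)
  purrr::imap_dfr(groups, function(shift, name) {
    tibble::tibble(
      plant_id = sprintf("%s_p%d", name, seq_len(n)),
      treatment = name, concentration = ifelse(name == "control", 0, 1),
      condition = "optimal",
      auc = exp(rnorm(n, log(10000) + shift, 0.2))
    )
  })
}

test_that("identical treatment and control AUC groups are not flagged", {
  ctrl <- make_auc_traits(c(control = 0), n = 12)
  trt <- dplyr::mutate(ctrl, treatment = "DAP", concentration = 1,
                       plant_id = paste0(plant_id, "_t"))
  res <- kruskal_auc(dplyr::bind_rows(ctrl, trt), "optimal")
  expect_equal(nrow(res), 1)
  expect_gt(res$p_value, 0.9)
  expect_false(res$significant)
})

test_that("a strong AUC shift is detected and the control is required", {
  tt <- make_auc_traits(c(control = 0, DAP = 0.8), n = 20, seed = 3)
  res <- kruskal_auc(tt, "optimal")
  expect_true(res$significant)
  expect_error(kruskal_auc(dplyr::filter(tt, treatment != "control"), "optimal"),
               "no control")
  expect_error(kruskal_auc(tt, "optimal", p_adjust_method = "wrong"))
})

make_metab <- function(effects = 0, noise_sd = 0.2, n = 4, seed = 1,
                       metabolites = tibble::tibble(
                         metabolite = c("PRO", "GABA"),
                         class = "free amino acid"
                       )) {
  design <- tidyr::crossing(default_treatments(), condition = "optimal")
  simulate_metabolites(design, n_per_group = n, metabolites = metabolites,
                       effects = effects, noise_sd = noise_sd, seed = seed)
}

test_that("metabolite ANOVA detects a doubled group and keeps honest flags", {
  design <- tidyr::crossing(default_treatments(), condition = "optimal")
  eff <- matrix(0, nrow(design), 2)
  eff[design$treatment == "DAP" & design$concentration == 1, 1] <- log(2)
  tab <- make_metab(effects = eff, noise_sd = 0.1, seed = 11)
  res <- metabolite_anova(tab)
  expect_equal(nrow(res), 2 * 6) # per metabolite x non-control group
  hit <- res$metabolite == "PRO" & res$treatment == "DAP 1 mM"
  expect_true(res$significant[hit])
  expect_true(all(res$p_anova >= 0 & res$p_anova <= 1, na.rm = TRUE))
  # the untouched metabolite carries the same ANOVA p across its rows
  expect_equal(length(unique(res$p_anova[res$metabolite == "GABA"])), 1)
})

test_that("a constant metabolite is flagged undefined, never significant", {
  tab <- make_metab(noise_sd = 0)
  res <- metabolite_anova(tab)
  expect_true(all(res$flag == "undefined"))
  expect_true(all(!res$significant))
  expect_true(all(is.na(res$p_anova)))
  bad <- dplyr::mutate(tab, value = value - 100)
  expect_error(metabolite_anova(bad), "strictly positive")
})

test_that("Duncan's multiple range test is available and agrees on strong effects", {
  design <- tidyr::crossing(default_treatments(), condition = "optimal")
  eff <- matrix(0, nrow(design), 2)
  eff[design$treatment == "Put" & design$concentration == 1, 1] <- log(3)
  tab <- make_metab(effects = eff, noise_sd = 0.1, seed = 12)
  tk <- metabolite_anova(tab, posthoc = "tukey")
  dc <- metabolite_anova(tab, posthoc = "duncan")
  hit <- tk$metabolite == "PRO" & tk$treatment == "Put 1 mM"
  expect_true(tk$significant[hit] && dc$significant[hit])
  # Duncan's protection level makes it at most as conservative as Tukey
  expect_true(all(dc$p_posthoc <= tk$p_posthoc + 1e-8, na.rm = TRUE))
})

test_that("two-way ANOVA reports factor and interaction p-values", {
  design <- tidyr::crossing(default_treatments(),
                            condition = c("optimal", "salt"))
  tab <- simulate_metabolites(design, n_per_group = 3,
                              metabolites = tibble::tibble(
                                metabolite = "PRO", class = "free amino acid"),
                              noise_sd = 0.2, seed = 4)
  res <- metabolite_anova_two_way(tab)
  expect_equal(nrow(res), 1)
  expect_true(all(unlist(res[, c("p_group", "p_condition", "p_interaction")]) >= 0))
})

test_that("SVD PCA matches the covariance eigendecomposition oracle", {
  set.seed(21)
  x <- matrix(rnorm(80), 10, 8)
  p <- pca_svd(x, scale = TRUE)
  ev <- eigen(cov(scale(x)), symmetric = TRUE)$values
  expect_equal(p$variance_explained, ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(p$variance_explained), 1)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  # orthonormal loadings and exact reconstruction of the scaled data
  expect_equal(crossprod(p$loadings), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(p$scores %*% t(p$loadings), unclass(scale(x)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # agreement with prcomp as a second, independent route
  expect_equal(p$sdev^2 / sum(p$sdev^2),
               prcomp(x, scale. = TRUE)$sdev^2 / 8, tolerance = 1e-8)
})

test_that("rank-1 data explains everything with one component", {
  u <- 1:6
  x <- outer(u, c(2, -1, 0.5, 3))
  p <- pca_svd(x, scale = FALSE)
  expect_equal(p$variance_explained[1], 1)
  expect_equal(p$variance_explained[-1], rep(0, 3), tolerance = 1e-12)
})

test_that("duplicating every sample leaves the variance fractions unchanged", {
  set.seed(22)
  x <- matrix(rnorm(40), 8, 5)
  p1 <- pca_svd(x)
  p2 <- pca_svd(rbind(x, x))
  expect_equal(p1$variance_explained, p2$variance_explained, tolerance = 1e-10)
})

test_that("constant columns are dropped under unit-variance scaling", {
  set.seed(23)
  x <- cbind(a = rnorm(6), b = rnorm(6), c = rep(2, 6))
  expect_warning(p <- pca_svd(x), "constant column")
  expect_equal(p$dropped, "c")
  expect_equal(nrow(p$loadings), 2)
  expect_error(pca_svd(x[, 3, drop = FALSE]), "at least 2")
})

test_that("Pearson matrix matches hand and cor.test computations", {
  x <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  cm <- pearson_matrix(x)
  expect_equal(cm$r["x", "y"], 0.8)
  expect_equal(cm$r["x", "x"], 1)
  ct <- cor.test(x[, 1], x[, 2])
  expect_equal(cm$p["x", "y"], ct$p.value, tolerance = 1e-10)
  expect_true(isSymmetric(cm$r))

  z <- cbind(a = c(1, 2, 3), b = -2 * c(1, 2, 3))
  expect_equal(pearson_matrix(z)$r["a", "b"], -1)
  expect_warning(czv <- pearson_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
                 "zero-variance")
  expect_true(is.na(czv$r["a", "b"]))
  expect_error(pearson_matrix(x[1:2, ]), "at least 3")
})

test_that("correlation matrices of complete data are positive semidefinite", {
  set.seed(24)
  x <- matrix(rnorm(60), 12, 5)
  cm <- pearson_matrix(x)
  expect_gte(min(eigen(cm$r, symmetric = TRUE)$values), -1e-10)
})

test_that("heatmap matrix is the ln of group means in class-block order", {
  design <- tidyr::crossing(default_treatments(),
                            condition = c("optimal", "osmotic", "salt"))
  panel <- tibble::tibble(
    metabolite = c("PUT", "PRO", "PUT (free)"),
    class = c("total polyamine", "free amino acid", "free polyamine")
  )
  tab <- simulate_metabolites(design, n_per_group = 4, metabolites = panel,
                              baseline = 1, noise_sd = 0, seed = 1)
  hm <- heatmap_matrix(tab)
  expect_equal(ncol(hm$matrix), 21)
  expect_true(all(hm$matrix == 0)) # ln(1)
  expect_equal(hm$row_class, c("free amino acid", "total polyamine",
                               "free polyamine"))
  # a (2,2,2,2) group transforms to ln 2
  tab2 <- dplyr::mutate(tab, value = 2)
  expect_equal(unique(as.vector(heatmap_matrix(tab2)$matrix)), log(2))
  expect_error(heatmap_matrix(dplyr::mutate(tab, value = 0)), "strictly positive")
})

test_that("heatmap significance dots follow the ANOVA vs-control flags", {
  design <- tidyr::crossing(default_treatments(), condition = "optimal")
  panel <- tibble::tibble(metabolite = c("PRO", "GABA"),
                          class = "free amino acid")
  eff <- matrix(0, nrow(design), 2)
  eff[design$treatment == "DAP" & design$concentration == 1, 1] <- log(4)
  tab <- simulate_metabolites(design, n_per_group = 4, metabolites = panel,
                              effects = eff, noise_sd = 0.1, seed = 2)
  an <- metabolite_anova(tab)
  hm <- heatmap_matrix(tab, anova = an)
  expect_true(hm$significant["PRO", "DAP 1 mM | optimal"])
  expect_true(all(is.na(hm$significant[, "control | optimal"])))
})
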