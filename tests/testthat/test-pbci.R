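test_that("a group scored against itself gives zero ratios and PBCI 0", {
  g <- fake_traits(n = 8)
  ratios <- trait_log2_ratios(g, g)
  expect_equal(unname(ratios), rep(0, 5))
  expect_equal(as.numeric(pbci_score(ratios)), 0)
})

test_that("uniform fold changes of the trait means add up in the PBCI", {
  ctrl <- fake_traits(n = 6, seed = 2)
  doubled <- dplyr::mutate(ctrl, dplyr::across(
    c(gc_slope, auc, rgr, fg, gli), ~ 2 * .x))
  r2 <- trait_log2_ratios(doubled, ctrl)
  expect_equal(unname(r2), rep(1, 5))
  expect_equal(as.numeric(pbci_score(r2)), 5)

  halved_auc <- dplyr::mutate(ctrl, auc = auc / 2)
  rh <- trait_log2_ratios(halved_auc, ctrl)
  expect_equal(unname(rh), c(0, -1, 0, 0, 0))
  expect_equal(as.numeric(pbci_score(rh)), -1)
})

test_that("swapping treatment and control negates every ratio and the PBCI", {
  set.seed(9)
  for (i in 1:10) {
    a <- fake_traits(n = sample(4:10, 1), seed = i)
    b <- fake_traits(n = sample(4:10, 1), seed = i + 100, mult = runif(1, 0.5, 2))
    r_ab <- trait_log2_ratios(a, b)
    r_ba <- trait_log2_ratios(b, a)
    expect_equal(r_ab, -r_ba)
    expect_equal(as.numeric(pbci_score(r_ab)), -as.numeric(pbci_score(r_ba)))
  }
})

test_that("area-scaled ratios are invariant to the pixel scale", {
  ctrl <- fake_traits(n = 6, seed = 3)
  trt <- fake_traits(n = 6, seed = 4, mult = 1.3)
  scale_areas <- function(df, k) dplyr::mutate(df, gc_slope = k * gc_slope,
                                               auc = k * auc, fg = k * fg)
  r1 <- trait_log2_ratios(trt, ctrl)
  r2 <- trait_log2_ratios(scale_areas(trt, 17), scale_areas(ctrl, 17))
  expect_equal(r1[c("gc_slope", "auc", "fg")], r2[c("gc_slope", "auc", "fg")])
})

test_that("nonpositive trait means yield flagged missing ratios, not values", {
  ctrl <- fake_traits(n = 5, seed = 5)
  bad <- dplyr::mutate(ctrl, gc_slope = -gc_slope)
  expect_warning(r <- trait_log2_ratios(bad, ctrl), "gc_slope")
  expect_true(is.na(r["gc_slope"]))
  expect_true(all(!is.na(r[c("auc", "rgr", "fg", "gli")])))
  s <- pbci_score(r)
  expect_equal(attr(s, "n_missing"), 1)
  expect_equal(as.numeric(s), sum(r, na.rm = TRUE))
  expect_error(pbci_score(rep(NA_real_, 5)), "all trait ratios")
  expect_error(trait_log2_ratios(ctrl[0, ], ctrl), "non-empty")
})

test_that("the sign rule maps PBCI and condition to the classification", {
  expect_equal(classify_pbci(2.1, "optimal"), "promoter")
  expect_equal(classify_pbci(0.4, "salt"), "alleviator")
  expect_equal(classify_pbci(0.4, "osmotic"), "alleviator")
  expect_equal(classify_pbci(-0.7, "salt"), "inductor")
  expect_equal(classify_pbci(-0.7, "optimal"), "inductor")
  expect_equal(classify_pbci(0, "osmotic"), "neutral")
  expect_error(classify_pbci(1, "lunar"), "unknown condition")
  expect_error(classify_pbci(NaN, "optimal"), "finite")
})

test_that("pbci_table scores every group and stores consistent sums", {
  traits <- dplyr::bind_rows(
    fake_traits(n = 5, seed = 1),
    fake_traits(n = 5, treatment = "DAP", concentration = 1, seed = 2, mult = 1.2),
    fake_traits(n = 5, condition = "salt", seed = 3),
    fake_traits(n = 5, treatment = "DAP", concentration = 1,
                condition = "salt", seed = 4, mult = 0.8)
  )
  rec <- pbci_table(traits)
  expect_equal(nrow(rec), 4)
  ctrl_rows <- rec[rec$treatment == "control", ]
  expect_true(all(ctrl_rows$pbci == 0 & ctrl_rows$label == "neutral"))
  sums <- rowSums(as.matrix(rec[, c("gc_slope", "auc", "rgr", "fg", "gli")]),
                  na.rm = TRUE)
  expect_equal(sums, rec$pbci, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(pbci_table(dplyr::filter(traits, treatment != "control")),
               "no control group")
})

test_that("bootstrap PBCI is seeded, honest about the null, and validated", {
  g <- fake_traits(n = 10, seed = 6)
  b1 <- bootstrap_pbci(g, g, n_boot = 300, seed = 42)
  b2 <- bootstrap_pbci(g, g, n_boot = 300, seed = 42)
  expect_identical(b1, b2)
  expect_equal(b1$pbci, 0)
  expect_lte(b1$ci[1], 0)
  expect_gte(b1$ci[2], 0)
  expect_gt(b1$sign_stability, 0.3)
  expect_lt(b1$sign_stability, 0.7)
  expect_error(bootstrap_pbci(g[1:2, ], g, n_boot = 300), "at least 3")
  expect_error(bootstrap_pbci(g, g, n_boot = 50), "n_boot")
})

test_that("a simulated alleviator has a stable positive bootstrap sign", {
  sc <- two_group_scenario(r_mult = 1.2, k_mult = 1.2, n = 48, seed = 77)
  tt <- trait_table(simulate_growth(sc))
  b <- bootstrap_pbci(dplyr::filter(tt, treatment == "TRT"),
                      dplyr::filter(tt, treatment == "control"),
                      n_boot = 200, seed = 7)
  expect_gt(b$pbci, 0)
  expect_gte(b$sign_stability, 0.95)
})

test_that("parallel coordinates table is tidy and propagates missing ratios", {
  traits <- purrr::pmap_dfr(
    tidyr::crossing(trt = c("control", "DAP", "Orn", "Put"), conc = c(0.1, 1),
                    cond = c("optimal", "osmotic", "salt")),
    function(trt, conc, cond) {
      fake_traits(n = 4, treatment = trt,
                  concentration = if (trt == "control") 0 else conc,
                  condition = cond, seed = nchar(trt) + conc * 10)
    }
  ) |> dplyr::distinct(plant_id, .keep_all = TRUE)
  rec <- pbci_table(traits)
  tab <- parallel_coordinates_table(dplyr::filter(rec, treatment != "control"))
  expect_equal(nrow(tab), 6 * 3 * 5)
  expect_setequal(unique(tab$trait), c("gc_slope", "auc", "rgr", "fg", "gli"))

  expect_equal(nrow(parallel_coordinates_table(rec[0, ])), 0)

  one <- rec[rec$treatment != "control", ][1, ]
  one$gli <- NA_real_
  one$n_missing <- 1L
  tab1 <- parallel_coordinates_table(one)
  expect_equal(nrow(tab1), 4)
  expect_true(all(tab1$n_missing == 1))
})
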