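test_that("trapezoid and literal AUC match their closed forms", {
  t3 <- c(0, 1, 2); a3 <- c(0, 2, 4)
  expect_equal(growth_auc(t3, a3), 4.0)
  expect_equal(growth_auc(t3, a3, mode = "literal"), 2.0)
  # constant area c over span T integrates to c * T
  tt <- c(0, 0.5, 2, 3.25)
  expect_equal(growth_auc(tt, rep(7, 4)), 7 * 3.25)
  expect_equal(growth_auc(tt, rep(7, 4), mode = "literal"), 0)
  # literal mode telescopes to the endpoint half-difference
  set.seed(1)
  for (i in 1:20) {
    a <- runif(10, 0, 100)
    expect_equal(growth_auc(sort(runif(10)), a, mode = "literal"),
                 (a[10] - a[1]) / 2)
  }
})

test_that("trapezoid AUC agrees with an independent integration oracle", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    tt <- sort(runif(n, 0, 7))
    a <- runif(n, 0, 6000)
    expect_equal(growth_auc(tt, a), pracma::trapz(tt, a), tolerance = 1e-12)
  }
})

test_that("AUC validates its input series", {
  expect_error(growth_auc(0, 5), "at least 2")
  expect_error(growth_auc(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(growth_auc(c(0, 1), c(1, NA)), "finite")
})

test_that("RGR matches its closed form and flags degenerate endpoints", {
  expect_equal(rgr(c(0, 7), c(10, 40)), log(4) / 7)
  expect_equal(rgr(c(0, 3, 7), c(10, 25, 40)), log(4) / 7) # endpoints only
  expect_equal(rgr(c(0, 7), c(10, 10)), 0)
  expect_error(rgr(c(0, 7), c(0, 40)), class = "phenoprime_degenerate_trait")
  expect_error(rgr(c(0, 7), c(10, 0)), class = "phenoprime_degenerate_trait")
})

test_that("RGR is scale invariant while GC-slope scales linearly", {
  set.seed(3)
  tt <- sort(runif(8, 0, 7))
  a <- runif(8, 100, 5000)
  for (k in c(0.01, 1, 250)) {
    expect_equal(rgr(tt, k * a), rgr(tt, a))
    expect_equal(gc_slope(tt, k * a), k * gc_slope(tt, a))
  }
})

test_that("GC-slope is the OLS slope of area against time", {
  tt <- c(0, 1, 2, 3)
  expect_equal(gc_slope(tt, 3 * tt + 1), 3)
  expect_equal(gc_slope(tt, rep(5, 4)), 0)
  expect_equal(gc_slope(c(0, 1, 2), c(0, 2, 4)), 2)
  set.seed(4)
  a <- runif(4, 0, 100)
  expect_equal(gc_slope(tt, a), unname(coef(lm(a ~ tt))[2]))
})

test_that("GLI matches its formula and stays in [-1, 1]", {
  expect_equal(gli(100, 100, 100), 0)
  expect_equal(gli(0, 255, 0), 1)
  expect_equal(gli(50, 120, 30), 0.5)
  expect_equal(gli(255, 0, 255), -1)
  set.seed(5)
  R <- runif(200, 0, 255); G <- runif(200, 0, 255); B <- runif(200, 0, 255)
  g <- gli(R, G, B)
  expect_true(all(g >= -1 & g <= 1, na.rm = TRUE))
  # any achromatic pixel scores 0
  v <- runif(20, 1, 255)
  expect_equal(gli(v, v, v), rep(0, 20))
  expect_error(gli(300, 0, 0), "\\[0, 255\\]")
})

test_that("black pixels are excluded from the GLI mean and counted", {
  expect_true(is.na(gli(0, 0, 0)))
  expect_warning(m <- mean_gli(c(0, 50), c(0, 120), c(0, 30)),
                 "1 black pixel")
  expect_equal(as.numeric(m), 0.5)
  expect_equal(attr(m, "n_excluded"), 1)
})

test_that("compute_traits assembles all five traits on a known curve", {
  sc <- tiny_scenario(noise_cv = 0, gli_sd = 0, n = 1)
  s <- simulate_growth(sc)
  tv <- compute_traits(s$time_days, s$area_px, s$mean_R, s$mean_G, s$mean_B)
  expect_true(all(is.finite(unlist(tv[c("gc_slope", "auc", "rgr", "fg", "gli")]))))
  expect_equal(tv$fg, s$area_px[nrow(s)])
  expect_equal(tv$fg, sc$K, tolerance = 0.01) # logistic tail
  expect_equal(tv$gli, 0.40, tolerance = 1e-6)
  expect_equal(tv$flag, "")
})

test_that("degenerate and minimal series are handled, not dropped", {
  tv <- compute_traits(c(0, 7), c(10, 0))
  expect_true(is.na(tv$rgr))
  expect_equal(tv$flag, "rgr_degenerate")
  expect_equal(tv$fg, 0)
  expect_true(is.finite(tv$gc_slope) && is.finite(tv$auc))

  two <- compute_traits(c(0, 1), c(10, 20), R = c(80, 80), G = c(160, 160),
                        B = c(60, 60))
  expect_equal(two$rgr, log(2))
  expect_equal(two$auc, 15)
  expect_equal(two$gli, gli(80, 160, 60))
  expect_error(compute_traits(0, 10), "at least 2")
})

test_that("trait_table computes one row per plant and validates its schema", {
  sc <- tiny_scenario(noise_cv = 0.1, gli_sd = 0.01, n = 5, seed = 2)
  s <- simulate_growth(sc)
  tt <- trait_table(s)
  expect_equal(nrow(tt), 5)
  expect_setequal(tt$plant_id, unique(s$plant_id))
  expect_error(trait_table(s[, 1:4]), "missing columns")
})
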