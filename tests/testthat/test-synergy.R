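test_that("median-effect transform is exact and guards its domain", {
  expect_equal(median_effect_transform(100, 0.5), list(x = 2, y = 0))
  tr <- median_effect_transform(10, 0.9)
  expect_equal(tr$x, 1)
  expect_equal(tr$y, log10(9))
  # fa <-> 1 - fa flips the sign of y
  lo <- median_effect_transform(1, 0.1)
  expect_equal(lo$x, 0)
  expect_equal(lo$y, -log10(9))
  expect_error(median_effect_transform(100, 1),
               class = "tilscreen_validation_error")
  expect_error(median_effect_transform(0, 0.5),
               class = "tilscreen_validation_error")
})

test_that("clamp_fa clamps into [eps, 1 - eps] and nothing else", {
  expect_equal(clamp_fa(c(0, 0.5, 1)), c(0.005, 0.5, 0.995))
})

test_that("fit recovers (Dm, m) exactly from noise-free points", {
  doses <- c(10, 50, 100, 500, 1000)
  fa <- 1 / (1 + (100 / doses)^1.5)
  fit <- fit_median_effect(doses, fa, "drugA")
  expect_equal(fit$Dm, 100, tolerance = 1e-9)
  expect_equal(fit$m, 1.5, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 5L)
  # model reproduces fa = 0.5 at Dm
  expect_equal(effect_at_dose(fit, fit$Dm), 0.5, tolerance = 1e-12)
})

test_that("two points give the exact line through both", {
  doses <- c(20, 200)
  fa <- 1 / (1 + (80 / doses)^2.2)
  fit <- fit_median_effect(doses, fa)
  expect_equal(fit$Dm, 80, tolerance = 1e-9)
  expect_equal(fit$m, 2.2, tolerance = 1e-9)
  expect_equal(fit$r, 1)
})

test_that("degenerate and non-monotone designs are rejected", {
  expect_error(fit_median_effect(c(10, 10), c(0.2, 0.4)),
               class = "tilscreen_degenerate_design_error")
  expect_error(fit_median_effect(c(10, 100), c(0.8, 0.2)),
               class = "tilscreen_nonmonotone_error")
  expect_error(fit_median_effect(10, 0.5),
               class = "tilscreen_validation_error")
})

test_that("noisy fit recovers Dm within 10% (seeded single case)", {
  doses <- 100 * 10^seq(-1, 1, length.out = 8)
  dr <- simulate_dose_response(100, 1.5, doses, y_noise_sd = 0.05, seed = 3)
  fit <- fit_median_effect(dr$dose, dr$fa)
  expect_lt(abs(fit$Dm - 100) / 100, 0.10)
})

test_that("dose_for_effect inverts the median-effect equation", {
  expect_equal(dose_for_effect(medeff_model(100, 2), 0.5), 100)
  expect_equal(dose_for_effect(medeff_model(100, 1), 0.9), 900)
  expect_equal(dose_for_effect(medeff_model(100, 2), 0.9), 300)
  expect_error(dose_for_effect(medeff_model(100, 2), 1),
               class = "tilscreen_validation_error")
  # round trip with effect_at_dose over random models; doses are kept
  # inside the window where fa is representable away from 0/1
  # (|log10(fa/fu)| <= 4) -- beyond it the round trip is limited by double
  # precision of fa itself, not by the inversion
  withr::with_seed(5, {
    for (i in 1:25) {
      Dm <- 10^runif(1, -1, 3)
      m <- runif(1, 0.3, 4)
      mod <- medeff_model(Dm, m)
      d <- Dm * 10^(runif(1, -1, 1) * min(3, 4 / m))
      expect_equal(dose_for_effect(mod, effect_at_dose(mod, d)), d,
                   tolerance = 1e-10)
    }
  })
})

test_that("sham self-combination gives CI = 1 for any split", {
  withr::with_seed(9, {
    for (i in 1:25) {
      mod <- medeff_model(10^runif(1, 0, 3), runif(1, 0.3, 4))
      fa <- runif(1, 0.05, 0.95)
      lam <- runif(1, 0.01, 0.99)
      Dx <- dose_for_effect(mod, fa)
      ci <- combination_index(mod, mod,
                              data.frame(d1 = lam * Dx, d2 = (1 - lam) * Dx,
                                         fa = fa))
      expect_equal(ci$ci, 1, tolerance = 1e-10)
      expect_equal(ci$classification, "additivity")
    }
  })
})

test_that("single-agent boundary: d2 = 0 gives CI = 1", {
  mod1 <- medeff_model(50, 1.2, "a1")
  mod2 <- medeff_model(5, 2, "a2")
  ci <- combination_index(mod1, mod2,
                          data.frame(d1 = dose_for_effect(mod1, 0.7),
                                     d2 = 0, fa = 0.7))
  expect_equal(ci$ci, 1, tolerance = 1e-12)
})

test_that("Loewe construction with interaction alpha returns CI = 1/alpha", {
  mod1 <- medeff_model(120, 1.4, "drug")
  mod2 <- medeff_model(3, 0.9, "til")
  for (alpha in c(0.5, 1, 2)) {
    combos <- simulate_combination(mod1, mod2, alpha,
                                   fa_levels = c(0.2, 0.5, 0.8),
                                   lambdas = c(0.25, 0.5, 0.75))
    ci <- combination_index(mod1, mod2, combos)
    expect_equal(ci$ci, rep(1 / alpha, nrow(combos)), tolerance = 1e-10)
  }
  # classification at tol = 0.05
  syn <- combination_index(mod1, mod2, simulate_combination(mod1, mod2, 2))
  expect_true(all(syn$classification == "synergy"))
  ant <- combination_index(mod1, mod2, simulate_combination(mod1, mod2, 0.5))
  expect_true(all(ant$classification == "antagonism"))
})

test_that("nonexclusive form adds the product term", {
  mod <- medeff_model(100, 1)
  Dx <- dose_for_effect(mod, 0.5)
  meas <- data.frame(d1 = Dx / 2, d2 = Dx / 2, fa = 0.5)
  excl <- combination_index(mod, mod, meas, form = "exclusive")
  nonexcl <- combination_index(mod, mod, meas, form = "nonexclusive")
  expect_equal(excl$ci, 1, tolerance = 1e-12)
  expect_equal(nonexcl$ci, 1 + 0.25, tolerance = 1e-12)
})

test_that("CI is invariant to rescaling an agent's dose units", {
  doses <- c(10, 30, 100, 300, 1000)
  fa1 <- 1 / (1 + (90 / doses)^1.3)
  fa2 <- 1 / (1 + (200 / doses)^0.8)
  m1 <- fit_median_effect(doses, fa1, "a1")
  m2 <- fit_median_effect(doses, fa2, "a2")
  meas <- data.frame(d1 = 40, d2 = 70, fa = 0.4)
  ci0 <- combination_index(m1, m2, meas)$ci
  for (k in c(0.001, 12.5)) {
    m1k <- fit_median_effect(doses * k, fa1, "a1")  # units rescaled
    ci1 <- combination_index(m1k, m2,
                             data.frame(d1 = 40 * k, d2 = 70, fa = 0.4))$ci
    expect_equal(ci1, ci0, tolerance = 1e-10)
  }
})

test_that("extreme-effect extrapolation is flagged, not rejected", {
  doses <- c(50, 100, 200)
  m1 <- fit_median_effect(doses, 1 / (1 + (100 / doses)^2), "a1")
  ci <- combination_index(m1, m1, data.frame(d1 = 1, d2 = 1, fa = 0.999999))
  expect_equal(ci$flag, "extrapolated")
  near <- combination_index(m1, m1, data.frame(d1 = 50, d2 = 50, fa = 0.5))
  expect_equal(near$flag, "ok")
})

test_that("isobologram coordinates sum to the CI and sit where expected", {
  mod1 <- medeff_model(80, 1.1, "a1")
  mod2 <- medeff_model(7, 2.3, "a2")
  combos <- simulate_combination(mod1, mod2, 2, fa_levels = 0.5,
                                 lambdas = 0.5)
  iso <- isobologram(mod1, mod2, combos)
  expect_equal(c(iso$x, iso$y), c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(iso$x + iso$y, iso$ci, tolerance = 1e-12)

  # sham combination lies on the unit diagonal
  Dx <- dose_for_effect(mod1, 0.3)
  sham <- isobologram(mod1, mod1,
                      data.frame(d1 = 0.4 * Dx, d2 = 0.6 * Dx, fa = 0.3))
  expect_equal(sham$x + sham$y, 1, tolerance = 1e-10)

  # single-agent point lands on the x-axis at x = ci
  ax <- isobologram(mod1, mod2,
                    data.frame(d1 = dose_for_effect(mod1, 0.3), d2 = 0,
                               fa = 0.3))
  expect_equal(ax$y, 0)
  expect_equal(ax$x, ax$ci)
})
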