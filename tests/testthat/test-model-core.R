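test_that("degradation rate vanishes without siRNA or mRNA and hits the Hill half-max", {
  for (m in names(all_params())) {
    p <- all_params()[[m]]
    expect_identical(delta_rate(m, p, xm = 2.7, xs = 0, shared = sh_fixed), 0)
    expect_identical(delta_rate(m, p, xm = 0, xs = 5, shared = sh_fixed), 0)
  }
  # at xs = theta4 the Hill law runs at exactly half its maximal rate
  expect_equal(delta_rate("model4", egfp_mrna_m4, xm = 1, xs = 0.105,
                          shared = sh_fixed), 8.1e-3 / 2, tolerance = 1e-12)
})

test_that("cooperative law with unit exponent collapses to mass action", {
  k <- 3.7e-4
  p2 <- model_params("model2", k2 = k, h2 = 1)
  p1 <- model_params("model1", k1 = k)
  xs <- c(0, 0.01, 0.5, 7, 200)
  xm <- c(0.2, 1, 5, 40, 60)
  expect_equal(delta_rate("model2", p2, xm, xs, sh_fixed),
               delta_rate("model1", p1, xm, xs, sh_fixed))
  expect_equal(knockdown_ratio("model2", p2, sh_fixed, xs),
               knockdown_ratio("model1", p1, sh_fixed, xs))
})

test_that("inputs are validated: bad model ids, mismatched params, negative values", {
  expect_error(delta_rate("model5", egfp_mrna_m1, 1, 1, sh_fixed), "model")
  expect_error(delta_rate("model2", egfp_mrna_m1, 1, 1, sh_fixed), "not")
  expect_error(delta_rate("model1", egfp_mrna_m1, -1, 1, sh_fixed), "nonnegative")
  expect_error(steady_state_mrna("model1", egfp_mrna_m1, sh_fixed, -2), "nonnegative")
  expect_error(model_params("model4", d4 = -1, theta4 = 1, h4 = 1), "positive")
  expect_error(shared_rates(dm = 0), "positive")
})

test_that("steady states solve the balance equation and reduce to km/dm at zero dose", {
  km_dm <- sh_fixed$km / sh_fixed$dm
  for (m in names(all_params())) {
    p <- all_params()[[m]]
    expect_equal(steady_state_mrna(m, p, sh_fixed, xs = 0), km_dm)
    for (xs in c(0.001, 0.1, 1, 20, 200)) {
      xm <- steady_state_mrna(m, p, sh_fixed, xs = xs)
      resid <- sh_fixed$km - sh_fixed$dm * xm -
        delta_rate(m, p, xm = xm, xs = xs, shared = sh_fixed)
      expect_lt(abs(resid) / sh_fixed$km, 1e-9)
    }
  }
  # hand-solved quadratic: unit rates, zero dose -> B = 0, root = 1
  sh1 <- shared_rates(km = 1, dm = 1)
  p3 <- model_params("model3", k3h3 = 1, c3_over_km = 1)
  expect_equal(steady_state_mrna("model3", p3, sh1, xs = 0), 1)
})

test_that("Hill-law steady state saturates at km/(dm + d4)", {
  lim <- sh_fixed$km / (sh_fixed$dm + 8.1e-3)
  expect_equal(steady_state_mrna("model4", egfp_mrna_m4, sh_fixed, xs = 1e9),
               lim, tolerance = 1e-6)
  expect_equal(lim, 39.37, tolerance = 1e-4)  # 1/0.0254 by hand
})

test_that("knockdown ratios match hand-evaluated closed forms", {
  # mass action at the top dose: dm/(dm + k1*200)
  expect_equal(knockdown_ratio("model1", egfp_mrna_m1, sh_fixed, 200),
               0.0173 / (0.0173 + 1.38e-4 * 200), tolerance = 1e-12)
  expect_equal(knockdown_ratio("model1", egfp_mrna_m1, sh_fixed, 200),
               0.3853, tolerance = 1e-3)
  # Hill law at its half-max dose: 2dm/(2dm + d4)
  expect_equal(knockdown_ratio("model4", egfp_mrna_m4, sh_fixed, 0.105),
               2 * 0.0173 / (2 * 0.0173 + 8.1e-3), tolerance = 1e-12)
  expect_equal(knockdown_ratio("model4", egfp_mrna_m4, sh_fixed, 0.105),
               0.8103, tolerance = 1e-3)
})

test_that("knockdown ratio is 1 at zero dose and non-increasing in dose for all models", {
  grid <- sort(c(paper_dose_grid(), exp(seq(log(1e-4), log(500), length.out = 200))))
  for (m in names(all_params())) {
    p <- all_params()[[m]]
    expect_equal(knockdown_ratio(m, p, sh_fixed, 0), 1)
    r <- knockdown_ratio(m, p, sh_fixed, grid)
    expect_true(all(diff(r) <= 1e-12))
    expect_true(all(r > 0 & r <= 1 + 1e-9))  # tiny float excess at dose ~0
  }
})

test_that("large-dose limits: Hill law saturates, the others silence completely", {
  expect_equal(knockdown_ratio("model4", egfp_mrna_m4, sh_fixed, 1e12),
               0.0173 / (0.0173 + 8.1e-3), tolerance = 1e-6)
  # the shallow published cooperativity exponent (h2 = 0.126) decays very
  # slowly, so the limit needs an astronomically large dose to show
  for (m in c("model1", "model2", "model3")) {
    expect_lt(knockdown_ratio(m, all_params()[[m]], sh_fixed, 1e40), 1e-3)
  }
})

test_that("enzymatic law approaches mass action when cleavage is fast", {
  # c3 >> k3h3 * Xm: ratios of model3 and model1 with k1 = k3h3 agree within 1%
  p3 <- model_params("model3", k3h3 = 1.40e-4, c3_over_km = 1.33e3)
  p1 <- model_params("model1", k1 = 1.40e-4)
  r3 <- knockdown_ratio("model3", p3, sh_fixed, paper_dose_grid())
  r1 <- knockdown_ratio("model1", p1, sh_fixed, paper_dose_grid())
  expect_equal(r3, r1, tolerance = 0.01)
})

test_that("Hill law linearizes to the cooperative law at small doses", {
  p4 <- egfp_mrna_m4
  p2 <- model_params("model2", k2 = 8.1e-3 / 0.105^4.47, h2 = 4.47)
  xs <- 0.105 * c(1e-3, 1e-2, 0.05)   # xs << theta4
  xm <- 1
  d4v <- delta_rate("model4", p4, xm, xs, sh_fixed)
  d2v <- delta_rate("model2", p2, xm, xs, sh_fixed)
  expect_equal(d4v, d2v, tolerance = 1e-3)  # first-order agreement
})

test_that("Hill-law efficacy is independent of km and weaker at higher dm", {
  xs <- c(0.05, 0.5, 5, 50)
  r_base <- knockdown_ratio("model4", egfp_mrna_m4,
                            shared_rates(km = 1, dm = 0.0173), xs)
  r_km <- knockdown_ratio("model4", egfp_mrna_m4,
                          shared_rates(km = 250, dm = 0.0173), xs)
  expect_identical(r_base, r_km)
  # higher basal turnover -> ratio closer to 1 (weaker silencing)
  r_fast <- knockdown_ratio("model4", egfp_mrna_m4,
                            shared_rates(dm = 5 * 0.0173), xs)
  expect_true(all(r_fast > r_base))
})

test_that("protein steady state is the mRNA level times kT/dp and ratios carry over", {
  expect_equal(protein_steady_state(shared_rates(kT = 1, dp = 1), 5), 5)
  expect_equal(protein_steady_state(shared_rates(kT = 2, dp = 1), 3), 6)
  sh <- shared_rates(dm = 0.0173, kT = 3.1, dp = 0.7)
  xs <- c(0, 0.1, 1, 100)
  xm <- steady_state_mrna("model4", egfp_mrna_m4, sh, xs)
  xp <- protein_steady_state(sh, xm)
  xp_ctrl <- protein_steady_state(sh, sh$km / sh$dm)
  expect_equal(xp / xp_ctrl, knockdown_ratio("model4", egfp_mrna_m4, sh, xs))
  expect_error(protein_steady_state(sh, -1), "nonnegative")
})

test_that("Michaelis-Menten view reproduces the enzymatic rate on a grid", {
  p3 <- model_params("model3", k3h3 = 1.40e-4, c3_over_km = 1.33e3)
  expect_equal(michaelis_menten_view(p3, sh_fixed, xs = 0)$Vm, 0)
  # Km = c3/(k3h3) = (c3/km)*km / k3h3, by hand with the published values
  expect_equal(michaelis_menten_view(p3, shared_rates(km = 1, dm = 0.0173),
                                     xs = 1)$Km,
               1.33e3 / 1.40e-4, tolerance = 1e-12)
  set.seed(42)
  xm <- runif(50, 0, 1e5)
  xs <- runif(50, 0, 200)
  mm <- michaelis_menten_view(p3, sh_fixed, xs)
  expect_equal(delta_rate("model3", p3, xm, xs, sh_fixed),
               mm$Vm * xm / (mm$Km + xm), tolerance = 1e-12)
})
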