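test_that("squared-error objective matches hand arithmetic and scales as 1/SE^2", {
  ds <- dose_response(c(0, 1), c(1, 1), ratio_ses = c(1, 1))
  expect_identical(weighted_sse(c(1, 1), ds), 0)
  expect_identical(weighted_sse(c(1, 2), ds), 1)
  ds2 <- dose_response(c(0, 1), c(1, 1), ratio_ses = c(1, 0.5))
  expect_identical(weighted_sse(c(1, 2), ds2), 4)
  # scaling all SEs by c scales the weighted error by 1/c^2
  set.seed(3)
  y <- runif(5, 0.2, 1); pred <- y + rnorm(5, 0, 0.1); se <- runif(5, 0.01, 0.1)
  d1 <- dose_response(0:4, y, ratio_ses = se)
  d3 <- dose_response(0:4, y, ratio_ses = 3 * se)
  expect_equal(weighted_sse(pred, d3), weighted_sse(pred, d1) / 9)
  # unweighted mode ignores SEs entirely
  expect_equal(weighted_sse(pred, d1, weighted = FALSE), sum((pred - y)^2))
})

test_that("weighted objective refuses zero or missing SEs", {
  ds <- dose_response(c(0, 1), c(1, 0.5), ratio_ses = c(0, 0.1))
  expect_error(weighted_sse(c(1, 1), ds), "weighted = FALSE")
  ds_na <- dose_response(c(0, 1), c(1, 0.5))
  expect_error(weighted_sse(c(1, 1), ds_na), "weighted = FALSE")
  expect_error(fit_model("model1", ds_na, sh_fixed,
                         quick_opts(weighted = TRUE)), "weighted = FALSE")
})

test_that("every model recovers its own parameters from noise-free data", {
  gen <- list(model1 = egfp_mrna_m1,
              model2 = model_params("model2", k2 = 2e-3, h2 = 0.7),
              model3 = model_params("model3", k3h3 = 1.40e-4, c3_over_km = 50),
              model4 = egfp_mrna_m4)
  for (m in names(gen)) {
    ds <- generate_dataset(m, gen[[m]], sh_fixed, noise = noisefree, seed = 5)
    fit <- fit_model(m, ds, sh_fixed, quick_opts(seed = 2, restarts = 6))
    truth <- unlist(gen[[m]][param_names_of(m)])
    expect_lt(max(abs(coef(fit) - truth) / truth), 0.02)
    expect_lt(fit$raw_error, 1e-6)
  }
})

test_that("fits are deterministic given the seed", {
  ds <- generate_dataset("model4", egfp_mrna_m4, sh_fixed,
                         noise = noise_model(cv = 0.1), seed = 21)
  f1 <- fit_model("model4", ds, sh_fixed, quick_opts(seed = 9, restarts = 2))
  f2 <- fit_model("model4", ds, sh_fixed, quick_opts(seed = 9, restarts = 2))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$raw_error, f2$raw_error)
})

test_that("constraining the cooperativity exponent lands on h2 = 1 and matches mass action", {
  # Hill-shaped data whose unconstrained cooperative fit prefers h2 < 1
  ds <- generate_dataset("model4", egfp_mrna_m4, sh_fixed, noise = noisefree,
                         seed = 4)
  free <- fit_model("model2", ds, sh_fixed, quick_opts(seed = 3, restarts = 6))
  expect_lt(coef(free)["h2"], 1)
  con <- fit_model("model2", ds, sh_fixed,
                   quick_opts(seed = 3, restarts = 6, constrain_h_ge_1 = TRUE))
  expect_equal(unname(coef(con)["h2"]), 1, tolerance = 1e-4)
  m1 <- fit_model("model1", ds, sh_fixed, quick_opts(seed = 3, restarts = 6))
  expect_equal(con$raw_error, m1$raw_error, tolerance = 1e-4)
})

test_that("the cooperative model never fits worse than nested mass action", {
  for (seed in c(13, 31)) {
    ds <- generate_dataset("model4", egfp_mrna_m4, sh_fixed,
                           noise = noise_model(cv = 0.15), seed = seed)
    f1 <- fit_model("model1", ds, sh_fixed, quick_opts(seed = 1, restarts = 4))
    f2 <- fit_model("model2", ds, sh_fixed, quick_opts(seed = 1, restarts = 4))
    expect_lte(f2$raw_error, f1$raw_error * (1 + 1e-6))
  }
})

test_that("error normalization divides by the worst model and preserves order", {
  mk <- function(model, err) structure(list(model = model, raw_error = err,
                                            normalized_error = NA_real_),
                                       class = "rnai_fit")
  fits <- compare_models(list(mk("model1", 4), mk("model2", 1),
                              mk("model3", 4), mk("model4", 0.16)))
  expect_equal(vapply(fits, function(f) f$normalized_error, numeric(1)),
               c(model1 = 1, model2 = 0.25, model3 = 1, model4 = 0.04))
  ties <- compare_models(list(mk("model1", 2), mk("model2", 2)))
  expect_equal(unname(vapply(ties, function(f) f$normalized_error, numeric(1))),
               c(1, 1))
  expect_error(compare_models(list(mk("model1", 1), mk("model1", 2))),
               "duplicate")
})

test_that("fitted-object methods are coherent: predict, residuals, summary, simulate", {
  ds <- generate_dataset("model1", egfp_mrna_m1, sh_fixed, noise = noisefree,
                         seed = 8)
  fit <- fit_model("model1", ds, sh_fixed, quick_opts(seed = 1, restarts = 2))
  expect_equal(predict(fit), knockdown_ratio("model1", fit$params, sh_fixed,
                                             ds$dose_pmol))
  expect_equal(residuals(fit), predict(fit) - ds$ratio_mean)
  s <- summary(fit)
  expect_s3_class(s, "summary.rnai_fit")
  expect_lt(s$rmse, 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 10)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "dose_response")
  expect_false(identical(sims[[1]]$ratio_mean, sims[[2]]$ratio_mean))
})
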