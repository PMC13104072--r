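test_that("aic implements n*ln(RSS/n) + 2k and its edge cases", {
  # printed pairs from the with/without-inhibition comparison
  expect_equal(aic(51.0431, 5, 1), 13.617, tolerance = 1e-3)
  expect_equal(aic(0.3964, 5, 2), -8.674, tolerance = 1e-3)
  expect_lt(abs(aic(51.0431, 5, 1) - 13.6162), 0.001)
  expect_lt(abs(aic(0.3964, 5, 2) - (-8.6733)), 0.001)
  # ln(1) = 0
  expect_equal(aic(7, 7, 0), 0)
  expect_warning(a0 <- aic(0, 5, 1), "RSS = 0")
  expect_identical(a0, -Inf)
  expect_error(aic(-1, 5, 1))
})

test_that("infer_n_k uniquely recovers (n, k) for the printed AIC pairs", {
  r1 <- infer_n_k(51.0431, 13.6162, n_range = 3:10, k_range = 0:5)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n, 5L)
  expect_equal(r1$k, 1L)
  r2 <- infer_n_k(0.3964, -8.6733, n_range = 3:10, k_range = 0:5)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$n, 5L)
  expect_equal(r2$k, 2L)
  expect_equal(nrow(infer_n_k(1.0, 1e6, n_range = 3:10, k_range = 0:5)), 0L)
})

test_that("compute_rss: perfect fit, single residual, Bateman oracle", {
  truth <- c(Ka1 = 0.04, Km2 = 0.03, Ka3 = 0.06)
  sc <- synthetic_scenario("DKO_PHABJ", truth, noise = noise_model("none"))
  dat <- generate_timecourse(sc)
  expect_lt(compute_rss("DKO_PHABJ", truth, dat), 1e-8)
  # single observation: residual squared
  one <- time_series_data(24, "HDO", 3.0)
  pred <- unname(integrate_model("DKO_PHABJ", truth,
                          times = c(0, 24))$states[2, "HDO"])
  expect_equal(compute_rss("DKO_PHABJ", truth, one), (3.0 - pred)^2,
               tolerance = 1e-9)
  # independent oracle: residuals against the Bateman closed form
  obs <- time_series_data(c(12, 24, 48, 72, 96), "HDO",
                          c(1.2, 4.0, 11.5, 17.0, 21.3))
  an <- analytic_linear_chain(unname(truth),
                              default_initial_state()[["GLUCOSE"]],
                              obs$time_h)
  oracle <- sum((obs$value_mM - an[, "HDO"])^2)
  expect_equal(compute_rss("DKO_PHABJ", truth, obs), oracle,
               tolerance = 1e-7)
})

test_that("fit_params recovers a single free parameter exactly (noiseless)", {
  truth <- c(Ka1 = 0.03, Km2 = 0.05, Ka3 = 0.04)
  dat <- generate_timecourse(
    synthetic_scenario("DKO_PHABJ", truth, noise = noise_model("none"))
  )
  p <- kinetic_params("DKO_PHABJ", c(Ka1 = 0.03, Km2 = 0.01, Ka3 = 0.04),
                      free = "Km2")
  fit <- fit_params("DKO_PHABJ", dat, p)
  expect_true(fit$converged)
  expect_equal(fit$k, 1L)
  expect_equal(fit$n, 5L)
  expect_lt(abs(pv(fit)[["Km2"]] / 0.05 - 1), 1e-3)
})

test_that("fit_params recovers Vmax and Ki of the inhibition law", {
  truth <- c(Ka1 = 0.05, Ka3 = 0.1, Vmax = 15, Km = 8.7e-4, Ki = 2.6)
  dat <- generate_timecourse(
    synthetic_scenario("DKO_PHABJ_INHIB", truth,
                       noise = noise_model("none"))
  )
  p <- kinetic_params("DKO_PHABJ_INHIB",
                      c(Ka1 = 0.05, Ka3 = 0.1, Vmax = 1, Km = 8.7e-4,
                        Ki = 1),
                      free = c("Vmax", "Ki"))
  fit <- fit_params("DKO_PHABJ_INHIB", dat, p)
  expect_lt(abs(pv(fit)[["Vmax"]] / 15 - 1), 0.01)
  expect_lt(abs(pv(fit)[["Ki"]] / 2.6 - 1), 0.01)
})

test_that("k = 0 evaluates the fixed model; n >= k is enforced", {
  truth <- c(Ka1 = 0.03, Km2 = 0.05, Ka3 = 0.04)
  dat <- generate_timecourse(
    synthetic_scenario("DKO_PHABJ", truth, noise = noise_model("none"))
  )
  p0 <- kinetic_params("DKO_PHABJ", truth)
  f0 <- fit_params("DKO_PHABJ", dat, p0)
  expect_equal(f0$k, 0L)
  expect_equal(pv(f0), pv(p0))
  expect_lt(f0$rss, 1e-8)
  one <- time_series_data(24, "HDO", 3.0)
  p2 <- kinetic_params("DKO_PHABJ", truth, free = c("Km2", "Ka3"))
  expect_error(fit_params("DKO_PHABJ", one, p2), "at least as many")
})

test_that("fits are deterministic given the seed", {
  dat <- generate_timecourse(
    synthetic_scenario("DKO_PHABJ", c(Ka1 = 0.03, Km2 = 0.05, Ka3 = 0.04),
                       noise = noise_model("proportional_cv")),
    seed = 5
  )
  p <- kinetic_params("DKO_PHABJ", c(Ka1 = 0.03, Km2 = 0.01, Ka3 = 0.02),
                      free = c("Km2", "Ka3"))
  f1 <- fit_params("DKO_PHABJ", dat, p, config = fit_config(seed = 3))
  f2 <- fit_params("DKO_PHABJ", dat, p, config = fit_config(seed = 3))
  expect_identical(f1$params$value, f2$params$value)
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$aic, f2$aic)
})

test_that("AIC identity holds on every stored fit result", {
  dat <- generate_timecourse(
    synthetic_scenario("DKO_PHABJ", c(Ka1 = 0.03, Km2 = 0.05, Ka3 = 0.04),
                       noise = noise_model("proportional_cv")),
    seed = 9
  )
  for (free in list("Km2", c("Km2", "Ka3"))) {
    p <- kinetic_params("DKO_PHABJ", c(Ka1 = 0.03, Km2 = 0.02, Ka3 = 0.03),
                        free = free)
    f <- fit_params("DKO_PHABJ", dat, p)
    expect_identical(f$aic, f$n * log(f$rss / f$n) + 2 * f$k)
  }
})

test_that("nested fit from the restricted optimum never increases RSS", {
  dat <- generate_timecourse(
    synthetic_scenario("DKO_PHABJ", c(Ka1 = 0.03, Km2 = 0.05, Ka3 = 0.04),
                       noise = noise_model("proportional_cv")),
    seed = 13
  )
  p1 <- kinetic_params("DKO_PHABJ", c(Ka1 = 0.03, Km2 = 0.02, Ka3 = 0.04),
                       free = "Km2")
  f1 <- fit_params("DKO_PHABJ", dat, p1)
  # start the larger fit from the restricted optimum
  p2 <- kinetic_params("DKO_PHABJ", pv(f1), free = c("Km2", "Ka3"))
  f2 <- fit_params("DKO_PHABJ", dat, p2)
  expect_lte(f2$rss, f1$rss + 1e-10)
})

test_that("compare_models ranks by AIC and flags ties", {
  cmp <- compare_models(data.frame(rss = c(51.0431, 0.3964), n = 5,
                                   k = c(1, 2),
                                   label = c("linear", "inhibition")))
  expect_equal(attr(cmp, "preferred"), "inhibition")
  expect_equal(cmp$delta_aic[2], 22.29, tolerance = 1e-3)
  expect_false(attr(cmp, "inconclusive"))
  one <- compare_models(data.frame(rss = 2, n = 5, k = 1, label = "only"))
  expect_equal(attr(one, "preferred"), "only")
  expect_equal(one$delta_aic, 0)
  tie <- compare_models(data.frame(rss = c(2, 2), n = 5, k = 1,
                                   label = c("a", "b")))
  expect_true(attr(tie, "inconclusive"))
  expect_warning(compare_models(data.frame(rss = c(0, 1), n = 5, k = 1)),
                 "RSS = 0")
})

test_that("staged protocol errors on missing datasets or stages", {
  fx <- paper_like_fixtures(seed = 1)
  expect_error(staged_fit_protocol(NULL, fx$dko_phabj, stages = 1:2),
               "mr40_data")
  expect_error(staged_fit_protocol(fx$mr40, NULL, stages = 1:2),
               "dko_data")
  expect_error(staged_fit_protocol(fx$mr40, fx$dko_phabj, stages = 2),
               "stage 1")
  expect_error(staged_fit_protocol(fx$mr40, fx$dko_phabj, fx$dko_fadb,
                                   stages = c(1, 4)),
               "stage 3")
})
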