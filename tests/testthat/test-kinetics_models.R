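test_that("mass action rate is the direct product and rejects negatives", {
  expect_equal(mass_action_rate(0.1, 10), 1.0)
  expect_equal(mass_action_rate(0.5, 0), 0)
  expect_equal(mass_action_rate(0, 222.2), 0)
  expect_error(mass_action_rate(-0.1, 1), ">= 0")
  expect_error(mass_action_rate(0.1, -1), ">= 0")
})

test_that("Michaelis-Menten rate and saturation fraction", {
  # S = 50*Km gives ~98% of Vmax (Km = 0.87 uM = 8.7e-4 mM)
  Km <- 8.7e-4
  expect_equal(michaelis_menten_rate(1, Km, 50 * Km), 50 / 51,
               tolerance = 1e-12)
  expect_equal(saturation_fraction(Km, 50 * Km), 0.9804, tolerance = 1e-4)
  expect_equal(michaelis_menten_rate(2, 1, 1), 1) # half saturation at S=Km
  expect_equal(michaelis_menten_rate(1, 1, 0), 0)
  expect_equal(saturation_fraction(123, 123), 0.5)
  # 4.35 mM is 5000*Km, not 50*Km: fraction is 0.9998, not 0.98
  expect_equal(saturation_fraction(Km, 4.35), 4.35 / (Km + 4.35),
               tolerance = 1e-12)
  expect_gt(saturation_fraction(Km, 4.35), 0.9997)
  expect_error(michaelis_menten_rate(1, 0, 1), "Km")
  expect_error(saturation_fraction(-1, 1), "Km")
})

test_that("substrate inhibition rate: values, dominance, limit", {
  # Ki -> infinity recovers Michaelis-Menten
  expect_equal(substrate_inhibition_rate(1, 1, 1e12, 3), 0.75,
               tolerance = 1e-6)
  # negligible Km, S = Ki: denominator is 2S, rate Vmax/2
  expect_equal(substrate_inhibition_rate(1, 1e-12, 2.60, 2.60), 0.5,
               tolerance = 1e-9)
  # dominance: inhibited rate <= MM rate, equality only at S = 0
  S <- c(0, 10^seq(-6, 3, length.out = 40))
  mm <- michaelis_menten_rate(1, 8.7e-4, S)
  si <- substrate_inhibition_rate(1, 8.7e-4, 2.6, S)
  expect_true(all(si <= mm + 1e-15))
  expect_true(all(si[S > 0] < mm[S > 0]))
  expect_equal(si[1], 0)
  # Ki -> infinity limit at relative 1e-6 (checked at Ki = 1e9 * Km)
  Km <- 8.7e-4
  expect_equal(substrate_inhibition_rate(1, Km, 1e9 * Km, 0.05),
               michaelis_menten_rate(1, Km, 0.05), tolerance = 1e-6)
  expect_error(substrate_inhibition_rate(1, 1, 0, 1), "Ki")
})

test_that("substrate inhibition is unimodal with maximum at sqrt(Km*Ki)", {
  # grid-search oracle over S confirms the analytic maximiser and peak
  Km <- 0.00087; Ki <- 2.60
  grid <- 10^seq(-5, 1, length.out = 20001)
  v <- substrate_inhibition_rate(1, Km, Ki, grid)
  s_hat <- grid[which.max(v)]
  expect_equal(s_hat, sqrt(Km * Ki), tolerance = 1e-3) # grid resolution
  expect_equal(s_hat, 0.04756, tolerance = 1e-3)
  expect_equal(max(v), 1 / (1 + 2 * sqrt(Km / Ki)), tolerance = 1e-8)
  expect_equal(max(v), 0.9647, tolerance = 1e-4)
  # property: over random (Km, Ki) the grid argmax tracks sqrt(Km*Ki)
  set.seed(7)
  for (i in 1:10) {
    Km <- runif(1, 1e-4, 1); Ki <- runif(1, 0.5, 20)
    v <- substrate_inhibition_rate(1, Km, Ki, grid)
    expect_equal(grid[which.max(v)], sqrt(Km * Ki), tolerance = 2e-3)
  }
})

test_that("variant declarations match the model structure", {
  expect_length(hdo_species(), 5)
  expect_setequal(model_variants(),
                  c("MR40_PHABJ", "DKO_PHABJ", "DKO_PHABJ_INHIB",
                    "DKO_FADB_INHIB"))
  # the thioesterase drain exists only in the parental-strain variant
  expect_true("Ka2" %in% variant_params("MR40_PHABJ"))
  for (v in setdiff(model_variants(), "MR40_PHABJ")) {
    expect_false("Ka2" %in% variant_params(v))
    expect_false(anyDuplicated(variant_params(v)) > 0)
  }
  expect_error(as_variant("NOPE"), "unknown model variant")
})

test_that("kinetic_params validates values, masks and bounds", {
  p <- kinetic_params("DKO_PHABJ", c(Ka1 = 0.05, Km2 = 0.04, Ka3 = 0.03),
                      free = "Km2")
  expect_s3_class(p, "kinetic_params")
  expect_equal(p$free, c(FALSE, TRUE, FALSE))
  expect_true(all(p$lower == 0) && all(p$upper == 1e3))
  expect_error(kinetic_params("DKO_PHABJ", c(Ka1 = 0.05, Km2 = 0.04)),
               "declared parameters")
  expect_error(kinetic_params("DKO_PHABJ",
                              c(Ka1 = 0.05, Km2 = -1, Ka3 = 0.03)),
               ">= 0")
  expect_error(kinetic_params("DKO_PHABJ",
                              c(Ka1 = 0.05, Km2 = 0.04, Ka3 = 0.03),
                              free = "Vmax"),
               "unknown free")
})

test_that("evaluate_rhs reproduces the variant equations", {
  st <- stats::setNames(c(10, 0, 0, 0, 0), hdo_species())
  d <- evaluate_rhs("MR40_PHABJ", st,
                    c(Ka1 = 0.1, Ka2 = 0.3, Km1 = 0.2, Ka3 = 0.4))
  expect_equal(unname(d), c(-1, 1, 0, 0, 0))
  # all-zero state gives all-zero derivatives in every variant
  zero <- stats::setNames(numeric(5), hdo_species())
  for (v in model_variants()) {
    expect_equal(unname(evaluate_rhs(v, zero, example_params(v))),
                 numeric(5))
  }
  # inhibition step: at B = Ki with negligible Km, rate is Vmax/2
  st2 <- stats::setNames(c(0, 2.60, 0, 0, 0), hdo_species())
  d2 <- evaluate_rhs("DKO_PHABJ_INHIB", st2,
                     c(Ka1 = 0, Ka3 = 0, Vmax = 1, Km = 1e-9, Ki = 2.60))
  expect_equal(unname(d2), c(0, -0.5, 0.5, 0, 0), tolerance = 1e-8)
  expect_error(
    evaluate_rhs("DKO_PHABJ", st, c(Ka1 = 0.1, Ka3 = 0.4)),
    "Km2"
  )
})

test_that("RHS components sum to zero for all variants (conservation)", {
  set.seed(11)
  for (v in model_variants()) {
    for (i in 1:25) {
      st <- random_state()
      p <- example_params(v)
      p[] <- p * stats::runif(length(p), 0.2, 5)
      expect_lt(abs(sum(evaluate_rhs(v, st, p))), 1e-12)
    }
  }
})
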