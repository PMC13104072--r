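# shared shorthands for the suite

pv <- function(fit_or_params) {
  if (inherits(fit_or_params, "fit_result")) {
    fit_or_params <- fit_or_params$params
  }
  hdokin:::param_values(fit_or_params)
}

# one representative parameter set per variant, magnitudes echoing the
# synthetic fixture world
example_params <- function(variant) {
  switch(variant,
    MR40_PHABJ = c(Ka1 = 0.05, Ka2 = 0.002, Km1 = 0.002, Ka3 = 0.1),
    DKO_PHABJ = c(Ka1 = 0.05, Km2 = 0.04, Ka3 = 0.03),
    DKO_PHABJ_INHIB = c(Ka1 = 0.05, Ka3 = 0.1, Vmax = 9.5, Km = 8.7e-4,
                        Ki = 2.6),
    DKO_FADB_INHIB = c(Kb1 = 0.0017, Ka3 = 0.1, Vmax = 9.5, Km = 8.7e-4,
                       Ki = 2.6)
  )
}

random_state <- function() {
  stats::setNames(stats::runif(5, 0, 50), hdo_species())
}

# draw pairwise-distinct positive chain rates; separation > 2% so the
# Bateman closed form itself is well conditioned (near-collided rates lose
# ~1e4 x machine precision to cancellation, which would swamp the 1e-6
# integrator check)
random_chain_rates <- function() {
  repeat {
    k <- stats::runif(3, 0.005, 0.3)
    if (min(abs(c(k[1] - k[2], k[1] - k[3], k[2] - k[3]))) / max(k) > 0.02) {
      return(k)
    }
  }
}

# worst relative deviation with an absolute floor of 1e-6 * total mass, so
# roundoff-level oracle values near zero do not masquerade as error
max_rel_dev <- function(num, oracle) {
  floor_abs <- 1e-6 * max(abs(oracle))
  max(abs(num - oracle) / (abs(oracle) + floor_abs))
}
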