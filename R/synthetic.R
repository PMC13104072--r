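#' Noise model for synthetic observations
#'
#' @param kind One of `"none"`, `"additive_sd"` (Gaussian, fixed sd in mM)
#'   or `"proportional_cv"` (Gaussian, sd = max(cv * prediction, floor)).
#' @param sd Additive standard deviation, mM.
#' @param cv Proportional coefficient of variation (default 0.05, a typical
#'   spread for triplicate shake-flask measurements).
#' @param floor Lower bound on the proportional sd, mM (default 0.2), so
#'   near-zero predictions still receive measurement noise.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(kind = c("proportional_cv", "additive_sd", "none"),
                        sd = 1, cv = 0.05, floor = 0.2) {
  kind <- match.arg(kind)
  stopifnot(sd >= 0, cv >= 0, floor >= 0)
  structure(list(kind = kind, sd = sd, cv = cv, floor = floor),
            class = "noise_model")
}

apply_noise <- function(pred, noise, truncate = TRUE) {
  out <- switch(noise$kind,
    none = pred,
    additive_sd = pred + stats::rnorm(length(pred), sd = noise$sd),
    proportional_cv = pred + stats::rnorm(
      length(pred), sd = pmax(noise$cv * pred, noise$floor))
  )
  if (truncate) pmax(out, 0) else out
}

#' Define a synthetic time-course scenario
#'
#' A scenario is the full stated world of one synthetic dataset: the true
#' model variant and parameters, the initial state, the observation grid
#' (default the 5-point fermentation grid 0-96 h at 24 h intervals), the
#' observed species, and the noise model.
#'
#' @inheritParams integrate_model
#' @param times Observation times, h.
#' @param species Observed species (subset of [hdo_species()]).
#' @param noise [noise_model()].
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(variant, params,
                               initial_state = default_initial_state(),
                               times = c(0, 24, 48, 72, 96),
                               species = "HDO",
                               noise = noise_model()) {
  variant <- as_variant(variant)
  initial_state <- as_state(initial_state)
  species <- toupper(species)
  stopifnot(all(species %in% hdo_species()), length(times) >= 1,
            all(times >= 0), !is.unsorted(times, strictly = TRUE),
            inherits(noise, "noise_model"))
  pack_params(variant, params) # validates completeness
  structure(list(variant = variant, params = param_values(params),
                 initial_state = initial_state, times = times,
                 species = species, noise = noise),
            class = "synthetic_scenario")
}

#' Generate a synthetic time course with known ground truth
#'
#' Integrates the scenario's true model, samples it at the observation
#' times, perturbs per the noise model and truncates at zero. Reproducible
#' under a fixed seed.
#'
#' @param scenario [synthetic_scenario()].
#' @param seed Integer seed (default 1).
#' @return [time_series_data()] with attribute `ground_truth` (the
#'   scenario) and attribute `noiseless` (the exact sampled predictions).
#' @export
generate_timecourse <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  grid <- sort(unique(c(0, scenario$times)))
  tr <- integrate_model(scenario$variant, scenario$params,
                        initial_state = scenario$initial_state,
                        times = grid)
  obs <- expand.grid(time_h = scenario$times, species = scenario$species,
                     stringsAsFactors = FALSE)
  pred <- tr$states[cbind(match(obs$time_h, grid),
                          match(obs$species, hdo_species()))]
  value <- with_seed(seed, apply_noise(pred, scenario$noise))
  out <- time_series_data(obs$time_h, obs$species, value)
  attr(out, "ground_truth") <- scenario
  attr(out, "noiseless") <- pred
  out
}

# Fixture ground truths (the stated world; see the methods vignette).
# Calibrated once against the noiseless model curves so that, from 40 g/L
# glucose: MR4.0 reaches ~25 mM HDO and ~30 mM butyrate at 96 h; the
# PhaB-PhaJ knockout HDO curve (substrate inhibition active) rises fast and
# plateaus near 25 mM; the FadB knockout curve rises steadily to ~30 mM.
fixture_truth <- function() {
  list(
    mr40 = c(Ka1 = 0.05, Ka2 = 0.00211611, Km1 = 0.00195322, Ka3 = 0.1),
    dko_phabj = c(Ka1 = 0.05, Ka3 = 0.1, Vmax = 9.53975, Km = 8.7e-4,
                  Ki = 2.6),
    dko_phabj_linear = c(Ka1 = 0.05, Km2 = 0.00181217, Ka3 = 0.1),
    dko_fadb = c(Kb1 = 0.00168962, Ka3 = 0.1, Vmax = 9.53975, Km = 8.7e-4,
                 Ki = 2.6)
  )
}

#' Fermentation-like synthetic fixtures
#'
#' Three fixed-seed datasets on the 0-96 h grid emulating the qualitative
#' behaviour of the measured fermentations: (i) the parental MR4.0 strain
#' with both butyrate and 2,3-HDO accumulating; (ii) the thioesterase
#' knockout on the PhaB-PhaJ route, whose HDO curve rises fast then
#' plateaus (generated with substrate inhibition active); (iii) the
#' knockout on the FadB route, rising roughly steadily (generated with a
#' much smaller glucose inflow constant). With `inhibition = FALSE` the two
#' knockout datasets are instead generated from the linear (first-order)
#' model, for model-selection specificity checks.
#'
#' @param seed Integer seed for the noise draws (default 42).
#' @param noise [noise_model()]; default proportional cv = 0.05 with a
#'   0.2 mM floor.
#' @param inhibition Generate the knockout data with the
#'   substrate-inhibition truth (default `TRUE`)?
#' @return List with elements `mr40` (butyrate + HDO), `dko_phabj` (HDO),
#'   `dko_fadb` (HDO), each a [time_series_data()] carrying its
#'   `ground_truth`, plus `truth`, the list of true parameter sets.
#' @export
paper_like_fixtures <- function(seed = 42, noise = noise_model(),
                                inhibition = TRUE) {
  truth <- fixture_truth()
  sc_mr40 <- synthetic_scenario("MR40_PHABJ", truth$mr40,
                                species = c("BUTYRATE", "HDO"),
                                noise = noise)
  if (inhibition) {
    sc_dko <- synthetic_scenario("DKO_PHABJ_INHIB", truth$dko_phabj,
                                 noise = noise)
    sc_fadb <- synthetic_scenario("DKO_FADB_INHIB", truth$dko_fadb,
                                  noise = noise)
  } else {
    sc_dko <- synthetic_scenario("DKO_PHABJ", truth$dko_phabj_linear,
                                 noise = noise)
    fadb_lin <- c(Ka1 = unname(truth$dko_fadb[["Kb1"]]),
                  Km2 = unname(truth$dko_phabj_linear[["Km2"]]),
                  Ka3 = unname(truth$dko_fadb[["Ka3"]]))
    sc_fadb <- synthetic_scenario("DKO_PHABJ", fadb_lin, noise = noise)
  }
  list(
    mr40 = generate_timecourse(sc_mr40, seed = seed),
    dko_phabj = generate_timecourse(sc_dko, seed = seed + 1L),
    dko_fadb = generate_timecourse(sc_fadb, seed = seed + 2L),
    truth = truth
  )
}

#' Parameter-recovery experiment
#'
#' Repeats generate-then-fit over replicate noise draws and reports, per
#' free parameter, the bias, relative RMSE and median absolute relative
#' error of the estimates against the scenario's ground truth. A parameter
#' whose relative RMSE exceeds `weak_threshold` is flagged weakly
#' identified. Replicate fit failures are recorded, not fatal.
#'
#' @param scenario [synthetic_scenario()] (its `params` are the truth).
#' @param free Character names of the parameters to free during fitting.
#' @param n_replicates Number of replicate datasets (>= 1).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param config [fit_config()].
#' @param weak_threshold Relative-RMSE flag threshold (default 0.5).
#' @return List of class `recovery_report` with `summary` (data frame: one
#'   row per free parameter with `truth`, `bias`, `rel_rmse`,
#'   `median_abs_rel_err`, `weakly_identified`), `estimates` (replicate x
#'   parameter matrix) and `failures` (count).
#' @export
recovery_experiment <- function(scenario, free, n_replicates = 20,
                                seed = 100, config = fit_config(),
                                weak_threshold = 0.5) {
  stopifnot(inherits(scenario, "synthetic_scenario"), n_replicates >= 1)
  truth <- scenario$params
  stopifnot(all(free %in% names(truth)))
  est <- matrix(NA_real_, n_replicates, length(free),
                dimnames = list(NULL, free))
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    dat <- generate_timecourse(scenario, seed = seed + r)
    fit <- tryCatch({
      p <- kinetic_params(scenario$variant, truth, free = free)
      fit_params(scenario$variant, dat, p,
                 initial_state = scenario$initial_state, config = config)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
    } else {
      est[r, ] <- param_values(fit$params)[free]
    }
  }
  rel_err <- sweep(est, 2, truth[free], "-")
  rel_err <- sweep(rel_err, 2, truth[free], "/")
  summary <- data.frame(
    parameter = free,
    truth = as.numeric(truth[free]),
    bias = colMeans(sweep(est, 2, truth[free], "-"), na.rm = TRUE),
    rel_rmse = sqrt(colMeans(rel_err^2, na.rm = TRUE)),
    median_abs_rel_err = apply(abs(rel_err), 2, stats::median,
                               na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  summary$weakly_identified <- summary$rel_rmse > weak_threshold
  structure(list(summary = summary, estimates = est, failures = failures),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", nrow(x$estimates), "replicates (",
      x$failures, "failed fits )\n")
  print.data.frame(x$summary, row.names = FALSE)
  invisible(x)
}
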