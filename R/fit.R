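#' Residual sum of squares of a model against observations
#'
#' Integrates the variant from the initial state to the last observation
#' time and returns sum((obs - pred)^2) over all records, predictions taken
#' exactly at the observation times.
#'
#' @inheritParams integrate_model
#' @param data [time_series_data()] observations (mM).
#' @return Scalar RSS, mM^2.
#' @export
compute_rss <- function(variant, params, data,
                        initial_state = default_initial_state(),
                        rtol = 1e-8, atol = 1e-10) {
  data <- as_time_series_data(data)
  grid <- sort(unique(c(0, data$time_h)))
  tr <- integrate_model(variant, params, initial_state = initial_state,
                        times = grid, rtol = rtol, atol = atol)
  pred <- tr$states[cbind(match(data$time_h, grid),
                          match(data$species, hdo_species()))]
  sum((data$value_mM - pred)^2)
}

#' Akaike Information Criterion for a least-squares fit
#'
#' `AIC = n * ln(RSS / n) + 2k` with `n` observations and `k` adjustable
#' parameters; no small-sample correction. `RSS = 0` (possible on noiseless
#' synthetic data) yields `-Inf` with a warning, since the log is undefined.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of observations (>= 1).
#' @param k Number of adjustable parameters (>= 0).
#' @return Scalar AIC (dimensionless); `-Inf` if `rss == 0`.
#' @export
#' @examples
#' aic(51.0431, 5, 1) # 13.617
#' aic(0.3964, 5, 2)  # -8.674
aic <- function(rss, n, k) {
  stopifnot(length(rss) == 1L, length(n) == 1L, length(k) == 1L,
            rss >= 0, n >= 1, k >= 0, n == round(n), k == round(k))
  if (rss == 0) {
    warning("RSS = 0: AIC is -Inf (log undefined); ",
            "excluded from model comparisons", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}

#' Recover (n, k) consistent with a printed RSS/AIC pair
#'
#' Exhaustive integer-grid search: returns all (n, k) in the given ranges
#' with `|n*ln(RSS/n) + 2k - AIC_target| < tol`. Used to validate reported
#' AIC values whose n and k were not stated.
#'
#' @param rss Residual sum of squares.
#' @param aic_target Reported AIC value.
#' @param n_range,k_range Integer candidate ranges.
#' @param tol Absolute match tolerance (default 0.01).
#' @return Data frame with columns `n`, `k`, `aic` (possibly zero rows).
#' @export
#' @examples
#' infer_n_k(51.0431, 13.6162) # unique (5, 1)
infer_n_k <- function(rss, aic_target, n_range = 3:10, k_range = 0:5,
                      tol = 0.01) {
  stopifnot(rss > 0, all(n_range >= 1), all(k_range >= 0))
  grid <- expand.grid(n = as.integer(n_range), k = as.integer(k_range))
  grid$aic <- grid$n * log(rss / grid$n) + 2 * grid$k
  out <- grid[abs(grid$aic - aic_target) < tol, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit configuration
#'
#' @param seed Integer seed for the restart draws (default 0).
#' @param restarts Number of additional log-uniform restart points beyond
#'   the supplied starting values (default 8).
#' @param reltol Relative convergence tolerance of the simplex (default
#'   1e-10).
#' @param maxit Iteration cap per simplex run.
#' @param rtol,atol Integration tolerances used inside the objective.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(seed = 0, restarts = 8, reltol = 1e-10,
                       maxit = 2000, rtol = 1e-8, atol = 1e-10) {
  stopifnot(restarts >= 0, reltol > 0, maxit >= 1, rtol > 0, atol > 0)
  structure(list(seed = as.integer(seed), restarts = as.integer(restarts),
                 reltol = reltol, maxit = maxit, rtol = rtol, atol = atol),
            class = "fit_config")
}

#' Fit free rate constants by least squares
#'
#' Minimises [compute_rss()] over the parameters flagged free in `params`,
#' within their box bounds, using a derivative-free simplex (Brent line
#' search for a single free parameter) on log-transformed values, restarted
#' from seeded log-uniform draws. Fixed parameters are untouched. The run is
#' deterministic given the seed. With no free parameters the RSS/AIC of the
#' fixed model is evaluated (k = 0).
#'
#' @inheritParams compute_rss
#' @param params [kinetic_params()] with the free mask and bounds set; the
#'   stored values of free parameters serve as the first starting point.
#' @param config [fit_config()].
#' @return Object of class `fit_result`: list with `variant`, `params`
#'   (fitted values), `free`, `k`, `n`, `rss`, `aic`, `converged`,
#'   `evaluations`, `restarts`, `seed`.
#' @export
fit_params <- function(variant, data, params,
                       initial_state = default_initial_state(),
                       config = fit_config()) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(config, "fit_config"))
  variant <- as_variant(variant)
  data <- as_time_series_data(data)
  free <- params$name[params$free]
  k <- length(free)
  n <- nrow(data)
  if (n < k) stop("need at least as many observations as free parameters",
                  call. = FALSE)
  values <- param_values(params)
  evals <- 0L

  if (k == 0L) {
    rss <- compute_rss(variant, values, data, initial_state,
                       config$rtol, config$atol)
    return(new_fit_result(variant, params, free, n, rss, TRUE, 1L, config))
  }

  lower <- stats::setNames(params$lower, params$name)[free]
  upper <- stats::setNames(params$upper, params$name)[free]
  # log-space search; a zero lower bound becomes a tiny positive floor
  log_lo <- log(pmax(lower, upper * 1e-12))
  log_hi <- log(upper)

  objective <- function(x) {
    evals <<- evals + 1L
    theta <- exp(x)
    pen <- 0
    over <- theta > upper
    under <- theta < lower
    if (any(over)) pen <- pen + 1e4 * sum((x - log_hi)[over]^2)
    if (any(under)) {
      pen <- pen + 1e4 * sum((log(pmax(lower, 1e-300)) - x)[under]^2)
    }
    theta <- pmin(pmax(theta, lower), upper)
    v <- values
    v[free] <- theta
    # integration failures (e.g. step collapse at extreme restart draws)
    # map to a large finite value so the simplex can retreat from them
    rss <- tryCatch(
      compute_rss(variant, v, data, initial_state, config$rtol,
                  config$atol),
      error = function(e) 1e12
    )
    rss * (1 + pen)
  }

  # starting points: supplied values first, then seeded log-uniform draws
  start0 <- pmin(pmax(values[free], exp(log_lo)), upper)
  starts <- list(log(start0))
  # Brent is a bounded global line search over the whole interval; restarts
  # only matter for the multi-parameter simplex
  if (k > 1L && config$restarts > 0L) {
    draws <- with_seed(config$seed, {
      matrix(stats::runif(config$restarts * k,
                          min = rep(pmax(log_lo, log_hi - log(1e6)), each =
                                      config$restarts),
                          max = rep(log_hi, each = config$restarts)),
             nrow = config$restarts)
    })
    for (i in seq_len(config$restarts)) starts <- c(starts, list(draws[i, ]))
  }

  best <- NULL
  converged <- FALSE
  for (x0 in starts) {
    fit <- if (k == 1L) {
      stats::optim(x0, objective, method = "Brent",
                   lower = log_lo, upper = log_hi,
                   control = list(reltol = config$reltol))
    } else {
      stats::optim(x0, objective, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the overall best point
  if (k > 1L) {
    fit <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = config$maxit,
                                       reltol = config$reltol))
    if (fit$value <= best$value) best <- fit
    converged <- best$convergence == 0
  } else {
    converged <- best$convergence == 0
  }

  theta <- pmin(pmax(exp(best$par), lower), upper)
  fitted <- params
  fitted$value[match(free, fitted$name)] <- theta
  v <- values
  v[free] <- theta
  rss <- compute_rss(variant, v, data, initial_state, config$rtol,
                     config$atol)
  new_fit_result(variant, fitted, free, n, rss, converged, evals, config)
}

new_fit_result <- function(variant, params, free, n, rss, converged,
                           evaluations, config) {
  a <- withCallingHandlers(
    aic(rss, n, length(free)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  structure(
    list(variant = variant, params = params, free = free,
         k = length(free), n = n, rss = rss, aic = a,
         converged = converged, evaluations = evaluations,
         restarts = config$restarts, seed = config$seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Least-squares fit of", x$variant, "\n")
  cat(sprintf("  RSS = %.6g (n = %d, k = %d)  AIC = %.4f  converged: %s\n",
              x$rss, x$n, x$k, x$aic, x$converged))
  est <- param_values(x$params)
  flag <- ifelse(x$params$name %in% x$free, "*", " ")
  cat(paste0("  ", flag, x$params$name, " = ", signif(est, 6),
             collapse = "\n"), "\n")
  cat("  (* = fitted)\n")
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' Recomputes AIC from each entry's stored (RSS, n, k), ranks ascending and
#' reports the difference to the best. Entries with `RSS = 0` (AIC
#' undefined) are dropped with a warning. A runner-up within `delta_aic < 2`
#' of the best sets the `inconclusive` flag, per standard
#' information-criterion practice.
#'
#' @param results List of [fit_params()] results, or a data frame with
#'   columns `rss`, `n`, `k` (and optionally `label`).
#' @param labels Optional character labels, recycled against the entries.
#' @return Object of class `model_comparison`: data frame with columns
#'   `label`, `rss`, `n`, `k`, `aic`, `delta_aic`, plus attributes
#'   `preferred` and `inconclusive`.
#' @export
#' @examples
#' compare_models(data.frame(rss = c(51.0431, 0.3964), n = 5, k = c(1, 2),
#'                           label = c("linear", "inhibition")))
compare_models <- function(results, labels = NULL) {
  if (is.data.frame(results)) {
    stopifnot(all(c("rss", "n", "k") %in% names(results)))
    tab <- data.frame(
      label = if ("label" %in% names(results)) results$label else
        paste0("model", seq_len(nrow(results))),
      rss = results$rss, n = results$n, k = results$k,
      stringsAsFactors = FALSE
    )
  } else {
    if (inherits(results, "fit_result")) results <- list(results)
    stopifnot(length(results) >= 1L,
              all(vapply(results, inherits, TRUE, "fit_result")))
    tab <- data.frame(
      label = vapply(results, function(r) r$variant, ""),
      rss = vapply(results, function(r) r$rss, 0),
      n = vapply(results, function(r) r$n, 0L),
      k = vapply(results, function(r) r$k, 0L),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(labels)) tab$label <- rep_len(labels, nrow(tab))
  drop <- tab$rss == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " entr(y/ies) with RSS = 0 ",
            "(AIC undefined)", call. = FALSE)
    tab <- tab[!drop, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no comparable entries (all RSS = 0)",
                            call. = FALSE)
  tab$aic <- mapply(aic, tab$rss, tab$n, tab$k)
  tab <- tab[order(tab$aic), , drop = FALSE]
  rownames(tab) <- NULL
  tab$delta_aic <- tab$aic - tab$aic[1]
  attr(tab, "preferred") <- tab$label[1]
  attr(tab, "inconclusive") <- nrow(tab) > 1 && tab$delta_aic[2] < 2
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison by AIC (preferred:", attr(x, "preferred"),
      if (attr(x, "inconclusive")) "- INCONCLUSIVE, delta AIC < 2" else "",
      ")\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Staged fitting protocol
#'
#' The four-stage fixing scheme used to analyse the fermentation time
#' courses:
#' \enumerate{
#'   \item Fit `MR40_PHABJ` (free Ka1, Ka2, Km1, Ka3) jointly to the
#'     parental-strain butyrate + 2,3-HDO data.
#'   \item Fix Ka1 and Ka3 at the stage-1 estimates; fit `DKO_PHABJ`
#'     (free Km2) to the knockout HDO data.
#'   \item Keep Ka1, Ka3 fixed and fix Km at `km_fixed` (default the
#'     literature PduP value 8.7e-4 mM); fit `DKO_PHABJ_INHIB`
#'     (free Vmax, Ki) to the same data; compare stage 2 vs stage 3 by AIC.
#'   \item Fix Ka3, Vmax, Km, Ki at the stage-3 values; fit
#'     `DKO_FADB_INHIB` (free Kb1) to the FadB-route HDO data.
#' }
#'
#' @param mr40_data,dko_data,fadb_data [time_series_data()] for the three
#'   strains; a dataset may be `NULL` only if its stage is not requested.
#' @param config [fit_config()].
#' @param stages Integer subset of 1:4 to run (later stages require the
#'   earlier ones they fix parameters from).
#' @param km_fixed Fixed substrate-inhibition Km, mM.
#' @param start Named list of starting values overriding the defaults for
#'   `Ka1`, `Ka2`, `Km1`, `Ka3`, `Km2`, `Vmax`, `Ki`, `Kb1`.
#' @param initial_state Shared initial state (mM).
#' @param upper Upper bound applied to every free parameter (default 1e3).
#' @return Object of class `staged_fit`: list with elements `stage1` ..
#'   `stage4` (those run) and `comparison` (stage 2 vs 3, when both ran).
#' @export
staged_fit_protocol <- function(mr40_data = NULL, dko_data = NULL,
                                fadb_data = NULL, config = fit_config(),
                                stages = 1:4, km_fixed = 8.7e-4,
                                start = list(),
                                initial_state = default_initial_state(),
                                upper = 1e3) {
  stopifnot(all(stages %in% 1:4), length(stages) >= 1)
  stages <- sort(unique(stages))
  need <- function(stage, data, name) {
    if (stage %in% stages && is.null(data)) {
      stop("stage ", stage, " requested but `", name, "` is missing",
           call. = FALSE)
    }
  }
  need(1, mr40_data, "mr40_data")
  if (any(c(2, 3) %in% stages)) need(min(intersect(stages, 2:3)),
                                     dko_data, "dko_data")
  need(4, fadb_data, "fadb_data")
  if (any(stages > 1) && !1 %in% stages) {
    stop("stages 2-4 fix parameters from stage 1; include stage 1",
         call. = FALSE)
  }
  if (4 %in% stages && !3 %in% stages) {
    stop("stage 4 fixes parameters from stage 3; include stage 3",
         call. = FALSE)
  }
  s0 <- utils::modifyList(
    list(Ka1 = 0.05, Ka2 = 0.01, Km1 = 0.01, Ka3 = 0.1,
         Km2 = 0.01, Vmax = 1, Ki = 1, Kb1 = 0.01),
    start
  )
  out <- list()

  if (1 %in% stages) {
    p1 <- kinetic_params(
      "MR40_PHABJ",
      c(Ka1 = s0$Ka1, Ka2 = s0$Ka2, Km1 = s0$Km1, Ka3 = s0$Ka3),
      free = c("Ka1", "Ka2", "Km1", "Ka3"), upper = upper
    )
    out$stage1 <- fit_params("MR40_PHABJ", mr40_data, p1, initial_state,
                             config)
  }
  est1 <- if (!is.null(out$stage1)) param_values(out$stage1$params)

  if (2 %in% stages) {
    p2 <- kinetic_params(
      "DKO_PHABJ",
      c(Ka1 = est1[["Ka1"]], Km2 = s0$Km2, Ka3 = est1[["Ka3"]]),
      free = "Km2", upper = upper
    )
    out$stage2 <- fit_params("DKO_PHABJ", dko_data, p2, initial_state,
                             config)
  }

  if (3 %in% stages) {
    p3 <- kinetic_params(
      "DKO_PHABJ_INHIB",
      c(Ka1 = est1[["Ka1"]], Ka3 = est1[["Ka3"]], Vmax = s0$Vmax,
        Km = km_fixed, Ki = s0$Ki),
      free = c("Vmax", "Ki"), upper = upper
    )
    out$stage3 <- fit_params("DKO_PHABJ_INHIB", dko_data, p3,
                             initial_state, config)
  }

  if (all(c(2, 3) %in% stages)) {
    out$comparison <- compare_models(list(out$stage2, out$stage3),
                                     labels = c("no_inhibition",
                                                "substrate_inhibition"))
  }

  if (4 %in% stages) {
    est3 <- param_values(out$stage3$params)
    p4 <- kinetic_params(
      "DKO_FADB_INHIB",
      c(Kb1 = s0$Kb1, Ka3 = est3[["Ka3"]], Vmax = est3[["Vmax"]],
        Km = est3[["Km"]], Ki = est3[["Ki"]]),
      free = "Kb1", upper = upper
    )
    out$stage4 <- fit_params("DKO_FADB_INHIB", fadb_data, p4,
                             initial_state, config)
  }
  class(out) <- "staged_fit"
  out
}

#' @export
print.staged_fit <- function(x, ...) {
  for (nm in intersect(paste0("stage", 1:4), names(x))) {
    cat("==", nm, "==\n")
    print(x[[nm]])
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed",
                                envir = globalenv())))
  }
  set.seed(seed)
  code
}
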