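#' Read a time-course CSV
#'
#' Long format with header `time_h,species,value_mM`; species names are
#' folded to upper case and must belong to [hdo_species()]. Duplicate
#' (time, species) rows, negative values and non-numeric fields are
#' rejected with an error naming the offending row and field.
#'
#' @param path File path.
#' @return [time_series_data()].
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("time_h", "species", "value_mM")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric `", col, "` in ", path, " at data row ", bad[1],
           ": '", df[[col]][bad[1]], "'", call. = FALSE)
    }
    x
  }
  time_h <- num("time_h")
  value_mM <- num("value_mM")
  sp <- toupper(df$species)
  bad <- which(!sp %in% hdo_species())
  if (length(bad)) {
    stop("unknown species in ", path, " at data row ", bad[1], ": '",
         df$species[bad[1]], "'", call. = FALSE)
  }
  neg <- which(value_mM < 0)
  if (length(neg)) {
    stop("negative value_mM in ", path, " at data row ", neg[1],
         call. = FALSE)
  }
  time_series_data(time_h, sp, value_mM)
}

#' Write a time course or trajectory as long-format CSV
#'
#' Deterministic row order: time-major, species in [hdo_species()] order.
#' Values are written with 12 significant digits so a write/read round trip
#' is an identity within float formatting.
#'
#' @param x A [time_series_data()] (`write_timecourse_csv`) or a
#'   `trajectory` from [integrate_model()] (`write_trajectory_csv`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(x, path) {
  x <- as_time_series_data(x)
  df <- data.frame(time_h = format_num(x$time_h), species = x$species,
                   value_mM = format_num(x$value_mM),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "trajectory"))
  sp <- hdo_species()
  df <- data.frame(
    time_h = format_num(rep(x$times, each = length(sp))),
    species = rep(sp, length(x$times)),
    value_mM = format_num(as.vector(t(x$states))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 12, format = "g")

# ---- run configuration ----------------------------------------------------

config_defaults <- function() {
  list(
    variant = "DKO_PHABJ",
    params = list(),
    initial_state = list(glucose_gL = 40),
    t_grid = list(from = 0, to = 96, by = 24),
    solver = list(rtol = 1e-8, atol = 1e-10),
    fit = list(seed = 0, restarts = 8, reltol = 1e-10, maxit = 2000),
    noise = list(kind = "proportional_cv", sd = 1, cv = 0.05, floor = 0.2),
    output = list()
  )
}

#' Read and validate a JSON run configuration
#'
#' Unknown keys (top level and within blocks) are rejected; defaults are
#' filled for everything omitted and the completed configuration is
#' returned so a run can be logged and reproduced from it.
#'
#' @param path Path to a JSON file.
#' @return Named list of class `run_config` (completed configuration).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (block in c("initial_state", "t_grid", "solver", "fit", "noise")) {
    if (!is.null(cfg[[block]])) {
      extra <- setdiff(names(cfg[[block]]),
                       c(names(defaults[[block]]),
                         if (block == "initial_state") hdo_species()))
      if (length(extra)) {
        stop("unknown key(s) in config block `", block, "`: ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
    }
  }
  out <- utils::modifyList(defaults, cfg)
  out$variant <- as_variant(out$variant)
  if (length(out$params)) {
    vals <- vapply(out$params, function(p) {
      if (is.list(p)) as.numeric(p$value) else as.numeric(p)
    }, 0)
    free <- names(out$params)[vapply(out$params, function(p) {
      is.list(p) && isTRUE(p$free)
    }, TRUE)]
    lower <- vapply(out$params, function(p) {
      if (is.list(p) && !is.null(p$lower)) as.numeric(p$lower) else 0
    }, 0)
    upper <- vapply(out$params, function(p) {
      if (is.list(p) && !is.null(p$upper)) as.numeric(p$upper) else 1e3
    }, 0)
    out$kinetic_params <- kinetic_params(out$variant, vals, free = free,
                                         lower = lower, upper = upper)
  }
  structure(out, class = "run_config")
}

config_initial_state <- function(cfg) {
  st <- cfg$initial_state
  if (!is.null(st$glucose_gL)) {
    default_initial_state(st$glucose_gL)
  } else {
    full <- stats::setNames(numeric(5), hdo_species())
    full[names(st)] <- unlist(st)
    as_state(full)
  }
}

config_times <- function(cfg) {
  g <- cfg$t_grid
  if (is.numeric(g)) return(as.numeric(g))
  seq(g$from, g$to, by = g$by)
}

#' Serialise a fit result to JSON
#'
#' @param fit A `fit_result` or `staged_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  to_list <- function(f) {
    list(variant = f$variant,
         params = as.list(param_values(f$params)),
         free = f$free, k = f$k, n = f$n, rss = f$rss, aic = f$aic,
         converged = f$converged, evaluations = f$evaluations,
         restarts = f$restarts, seed = f$seed)
  }
  payload <- if (inherits(fit, "fit_result")) {
    to_list(fit)
  } else if (inherits(fit, "staged_fit")) {
    out <- lapply(fit[grep("^stage", names(fit))], to_list)
    if (!is.null(fit$comparison)) {
      out$comparison <- c(
        list(preferred = attr(fit$comparison, "preferred"),
             inconclusive = attr(fit$comparison, "inconclusive")),
        as.list(as.data.frame(fit$comparison))
      )
    }
    out
  } else {
    stop("expected a fit_result or staged_fit", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
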