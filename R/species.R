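#' Pathway species identifiers
#'
#' The five lumped species of the hexane-2,3-diol (2,3-HDO) pathway model, in
#' the fixed order used by every state vector and trajectory in the package:
#' glucose, butyryl-CoA, butanal, butyrate, 2,3-HDO.
#'
#' @return Character vector of the five species identifiers.
#' @export
#' @examples
#' hdo_species()
hdo_species <- function() {
  c("GLUCOSE", "BUTYRYL_COA", "BUTANAL", "BUTYRATE", "HDO")
}

# declared parameter set per model variant, in canonical order
.variant_table <- list(
  MR40_PHABJ      = c("Ka1", "Ka2", "Km1", "Ka3"),
  DKO_PHABJ       = c("Ka1", "Km2", "Ka3"),
  DKO_PHABJ_INHIB = c("Ka1", "Ka3", "Vmax", "Km", "Ki"),
  DKO_FADB_INHIB  = c("Kb1", "Ka3", "Vmax", "Km", "Ki")
)

#' Model variants
#'
#' The four lumped ODE variants of the pathway:
#' \describe{
#'   \item{MR40_PHABJ}{PhaB-PhaJ route in the parental strain: first-order
#'     conversion of butyryl-CoA to butanal (constant `Km1`) plus the
#'     thioesterase drain to butyrate (constant `Ka2`).}
#'   \item{DKO_PHABJ}{PhaB-PhaJ route in the thioesterase double knockout:
#'     the butyrate drain is removed; butyryl-CoA to butanal is first order
#'     with constant `Km2`.}
#'   \item{DKO_PHABJ_INHIB}{As `DKO_PHABJ` but the butyryl-CoA to butanal
#'     step follows substrate-inhibition kinetics (`Vmax`, `Km`, `Ki`).}
#'   \item{DKO_FADB_INHIB}{As `DKO_PHABJ_INHIB` with the slower FadB-route
#'     glucose inflow constant `Kb1` in place of `Ka1`.}
#' }
#'
#' @param variant Character scalar naming a variant (case sensitive).
#' @return `model_variants()` returns the variant names;
#'   `variant_params()` the declared parameter names of one variant;
#'   `as_variant()` the validated variant name.
#' @export
#' @examples
#' model_variants()
#' variant_params("DKO_PHABJ_INHIB")
model_variants <- function() names(.variant_table)

#' @rdname model_variants
#' @export
variant_params <- function(variant) {
  .variant_table[[as_variant(variant)]]
}

#' @rdname model_variants
#' @export
as_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% names(.variant_table)) {
    stop("unknown model variant: ", paste(variant, collapse = ", "),
         " (expected one of ", paste(names(.variant_table), collapse = ", "),
         ")", call. = FALSE)
  }
  variant
}

#' Construct a kinetic parameter set
#'
#' A `kinetic_params` object stores, for every parameter declared by a model
#' variant, its value, whether it is free during fitting, and box bounds.
#' First-order constants are in 1/h, `Vmax` in mM/h, `Km` and `Ki` in mM.
#'
#' @param variant Model variant name (see [model_variants()]).
#' @param values Named numeric vector covering exactly the variant's declared
#'   parameter set; all values must be nonnegative.
#' @param free Character vector of parameter names to treat as free during
#'   fitting (default: none).
#' @param lower,upper Named or scalar nonnegative bounds; default `[0, 1e3]`
#'   in each parameter's unit.
#' @return An object of class `kinetic_params`: a data frame with columns
#'   `name`, `value`, `free`, `lower`, `upper`.
#' @export
#' @examples
#' kinetic_params("DKO_PHABJ", c(Ka1 = 0.05, Km2 = 0.04, Ka3 = 0.03),
#'                free = "Km2")
kinetic_params <- function(variant, values, free = character(),
                           lower = 0, upper = 1e3) {
  variant <- as_variant(variant)
  declared <- variant_params(variant)
  if (is.null(names(values)) || anyDuplicated(names(values)) ||
      !setequal(names(values), declared)) {
    stop("`values` must be named with exactly the declared parameters of ",
         variant, ": ", paste(declared, collapse = ", "), call. = FALSE)
  }
  values <- values[declared]
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("all parameter values must be finite and >= 0", call. = FALSE)
  }
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(declared)), declared)
    }
    if (!all(declared %in% names(x))) {
      stop("`", what, "` must be a scalar or named for every parameter",
           call. = FALSE)
    }
    x[declared]
  }
  lower <- expand(lower, "lower")
  upper <- expand(upper, "upper")
  if (any(lower < 0) || any(upper < lower)) {
    stop("bounds must satisfy 0 <= lower <= upper", call. = FALSE)
  }
  if (!all(free %in% declared)) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, declared), collapse = ", "), call. = FALSE)
  }
  is_free <- declared %in% free
  bad <- is_free & (values < lower | values > upper)
  if (any(bad)) {
    stop("free parameter(s) outside bounds: ",
         paste(declared[bad], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(name = declared, value = as.numeric(values),
                    free = is_free, lower = as.numeric(lower),
                    upper = as.numeric(upper), stringsAsFactors = FALSE)
  attr(out, "variant") <- variant
  class(out) <- c("kinetic_params", "data.frame")
  out
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters for variant", attr(x, "variant"), "\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# named value vector from a kinetic_params object (or passthrough)
param_values <- function(params) {
  if (inherits(params, "kinetic_params")) {
    stats::setNames(params$value, params$name)
  } else if (is.numeric(params) && !is.null(names(params))) {
    params
  } else {
    stop("`params` must be a kinetic_params object or a named numeric vector",
         call. = FALSE)
  }
}

#' Default initial state
#'
#' All species at zero except glucose, converted from g/L to mM with the
#' shipped molar mass table (40 g/L glucose = 222.02 mM).
#'
#' @param glucose_gL Initial glucose concentration in g/L (default 40).
#' @return Named numeric vector over [hdo_species()] in mM.
#' @export
#' @examples
#' default_initial_state()
default_initial_state <- function(glucose_gL = 40) {
  stopifnot(is.numeric(glucose_gL), length(glucose_gL) == 1L,
            glucose_gL >= 0)
  state <- stats::setNames(numeric(5), hdo_species())
  state["GLUCOSE"] <- mass_to_molar_conc(glucose_gL, "glucose")
  state
}

# validate a state vector; returns it named and in canonical order
as_state <- function(state) {
  sp <- hdo_species()
  if (is.null(names(state))) {
    if (length(state) != 5L) stop("state must have 5 components",
                                  call. = FALSE)
    names(state) <- sp
  }
  if (!setequal(names(state), sp)) {
    stop("state must be named over ", paste(sp, collapse = ", "),
         call. = FALSE)
  }
  state <- state[sp]
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state concentrations must be finite and >= 0", call. = FALSE)
  }
  state
}
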