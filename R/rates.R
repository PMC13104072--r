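#' Rate laws
#'
#' The three rate laws used by the pathway models, all returning flux in
#' mM/h. `mass_action_rate()` is first order, `michaelis_menten_rate()` is
#' the saturable law V = Vmax*S/(Km + S), and `substrate_inhibition_rate()`
#' is v = Vmax*S/(Km + S + S^2/Ki), the Haldane form in which flux is
#' unimodal in S with its maximum at S = sqrt(Km*Ki).
#' `saturation_fraction()` returns V/Vmax = S/(Km + S), the fraction of the
#' maximal rate attained at substrate concentration S.
#'
#' @param k First-order rate constant, 1/h.
#' @param S Substrate concentration, mM.
#' @param Vmax Maximal rate, mM/h.
#' @param Km Michaelis constant, mM (must be > 0 for the saturable laws).
#' @param Ki Substrate-inhibition constant, mM (> 0).
#' @return Numeric flux in mM/h (`saturation_fraction()`: dimensionless
#'   fraction in `[0, 1)`). All functions are vectorised over `S`.
#' @export
#' @examples
#' mass_action_rate(0.1, 10)
#' michaelis_menten_rate(2, 1, 1)
#' substrate_inhibition_rate(1, 8.7e-4, 2.6, 0.0476)
#' saturation_fraction(8.7e-4, 50 * 8.7e-4) # ~0.98 at S = 50 Km
mass_action_rate <- function(k, S) {
  if (any(k < 0) || any(S < 0)) {
    stop("rate constant and concentration must be >= 0", call. = FALSE)
  }
  k * S
}

#' @rdname mass_action_rate
#' @export
michaelis_menten_rate <- function(Vmax, Km, S) {
  if (any(Vmax < 0) || any(S < 0)) {
    stop("Vmax and S must be >= 0", call. = FALSE)
  }
  if (any(Km <= 0)) stop("Km must be > 0", call. = FALSE)
  Vmax * S / (Km + S)
}

#' @rdname mass_action_rate
#' @export
substrate_inhibition_rate <- function(Vmax, Km, Ki, S) {
  if (any(Vmax < 0) || any(S < 0)) {
    stop("Vmax and S must be >= 0", call. = FALSE)
  }
  if (any(Km <= 0) || any(Ki <= 0)) {
    stop("Km and Ki must be > 0", call. = FALSE)
  }
  Vmax * S / (Km + S + S^2 / Ki)
}

#' @rdname mass_action_rate
#' @export
saturation_fraction <- function(Km, S) {
  if (any(Km <= 0)) stop("Km must be > 0", call. = FALSE)
  if (any(S < 0)) stop("S must be >= 0", call. = FALSE)
  S / (Km + S)
}

#' Evaluate a model variant's ODE right-hand side
#'
#' Returns the derivative vector (mM/h) of the five pathway species for one
#' state. The four variants share the chain glucose -> butyryl-CoA ->
#' butanal -> 2,3-HDO and differ in (i) whether a first-order thioesterase
#' drain butyryl-CoA -> butyrate is present (`MR40_PHABJ` only) and (ii)
#' whether the butyryl-CoA -> butanal step is first order or follows
#' substrate-inhibition kinetics. By construction the components always sum
#' to zero: total concentration is conserved along exact trajectories.
#'
#' @param variant Model variant name, see [model_variants()].
#' @param state Named concentration vector over [hdo_species()], mM.
#' @param params [kinetic_params()] object or named numeric vector covering
#'   the variant's declared parameter set.
#' @return Named derivative vector over [hdo_species()], mM/h.
#' @export
#' @examples
#' st <- c(GLUCOSE = 10, BUTYRYL_COA = 0, BUTANAL = 0, BUTYRATE = 0, HDO = 0)
#' evaluate_rhs("MR40_PHABJ", st,
#'              c(Ka1 = 0.1, Ka2 = 0.02, Km1 = 0.05, Ka3 = 0.03))
evaluate_rhs <- function(variant, state, params) {
  variant <- as_variant(variant)
  state <- as_state(state)
  p <- pack_params(variant, params)
  G <- state["GLUCOSE"]; B <- state["BUTYRYL_COA"]; A <- state["BUTANAL"]
  vin <- p$vec[1] * G
  conv <- if (p$inhib) {
    substrate_inhibition_rate(p$vec[4], p$vec[5], p$vec[6], B)
  } else {
    p$vec[3] * B
  }
  drain <- p$vec[2] * B
  vout <- p$vec[7] * A
  stats::setNames(
    c(-vin, vin - conv - drain, conv - vout, drain, vout),
    hdo_species()
  )
}

# map a variant's named parameters onto the fixed positional layout used by
# the compiled RHS: (k_in, k_drain, k_lin, vmax, km, ki, ka3)
pack_params <- function(variant, params) {
  variant <- as_variant(variant)
  v <- param_values(params)
  declared <- variant_params(variant)
  missing <- setdiff(declared, names(v))
  if (length(missing)) {
    stop("missing parameter(s) for ", variant, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vec <- numeric(7)
  inhib <- FALSE
  switch(variant,
    MR40_PHABJ = {
      vec[1] <- v[["Ka1"]]; vec[2] <- v[["Ka2"]]; vec[3] <- v[["Km1"]]
      vec[7] <- v[["Ka3"]]
    },
    DKO_PHABJ = {
      vec[1] <- v[["Ka1"]]; vec[3] <- v[["Km2"]]; vec[7] <- v[["Ka3"]]
    },
    DKO_PHABJ_INHIB = {
      vec[1] <- v[["Ka1"]]; vec[4] <- v[["Vmax"]]; vec[5] <- v[["Km"]]
      vec[6] <- v[["Ki"]]; vec[7] <- v[["Ka3"]]
      inhib <- TRUE
    },
    DKO_FADB_INHIB = {
      vec[1] <- v[["Kb1"]]; vec[4] <- v[["Vmax"]]; vec[5] <- v[["Km"]]
      vec[6] <- v[["Ki"]]; vec[7] <- v[["Ka3"]]
      inhib <- TRUE
    }
  )
  if (any(vec < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (inhib && (vec[5] <= 0 || vec[6] <= 0)) {
    stop("Km and Ki must be > 0 for substrate-inhibition variants",
         call. = FALSE)
  }
  list(vec = vec, inhib = inhib)
}
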