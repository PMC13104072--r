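#' Compound molar mass table
#'
#' Molar masses (g/mol, standard atomic weights to two decimals) of the
#' compounds appearing in the fermentation reports.
#'
#' @return Data frame with columns `name`, `formula`, `molar_mass`.
#' @export
#' @examples
#' compound_table()
compound_table <- function() {
  data.frame(
    name = c("hexane-2,3-diol", "pentane-2,3-diol", "butyric acid",
             "butanal", "butane-2,3-diol", "glucose",
             "3-hydroxypentan-2-one"),
    formula = c("C6H14O2", "C5H12O2", "C4H8O2", "C4H8O", "C4H10O2",
                "C6H12O6", "C5H10O2"),
    molar_mass = c(118.17, 104.15, 88.11, 72.11, 90.12, 180.16, 102.13),
    stringsAsFactors = FALSE
  )
}

lookup_mw <- function(compound, molar_mass = NULL) {
  if (!is.null(molar_mass)) {
    stopifnot(is.numeric(molar_mass), molar_mass > 0)
    return(molar_mass)
  }
  tab <- compound_table()
  i <- match(tolower(compound), tolower(tab$name))
  if (is.na(i)) {
    stop("unknown compound '", compound,
         "'; supply `molar_mass` explicitly or use one of: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  tab$molar_mass[i]
}

#' Titer unit conversions
#'
#' Convert a molar concentration (mM) to a mass concentration (g/L) and
#' back, using the shipped molar mass table or an explicit molar mass.
#'
#' @param conc_mM Concentration, mM.
#' @param conc_gL Concentration, g/L.
#' @param compound Compound name in [compound_table()] (case-insensitive).
#' @param molar_mass Optional molar mass, g/mol, overriding the table.
#' @return Converted concentration (`molar_to_mass_conc()`: g/L;
#'   `mass_to_molar_conc()`: mM).
#' @export
#' @examples
#' molar_to_mass_conc(152.2, "hexane-2,3-diol") # ~17.99 g/L
#' mass_to_molar_conc(17.99, "hexane-2,3-diol")
molar_to_mass_conc <- function(conc_mM, compound, molar_mass = NULL) {
  stopifnot(all(conc_mM >= 0))
  conc_mM * lookup_mw(compound, molar_mass) / 1000
}

#' @rdname molar_to_mass_conc
#' @export
mass_to_molar_conc <- function(conc_gL, compound, molar_mass = NULL) {
  stopifnot(all(conc_gL >= 0))
  conc_gL * 1000 / lookup_mw(compound, molar_mass)
}

#' Substrate yield
#'
#' @param titer_gL Product titer, g/L.
#' @param substrate_consumed_gL Substrate consumed, g/L (> 0).
#' @return Yield, g product per g substrate.
#' @export
#' @examples
#' substrate_yield(15.0, 54.46) # 0.275 g/g
substrate_yield <- function(titer_gL, substrate_consumed_gL) {
  stopifnot(all(titer_gL >= 0))
  if (any(substrate_consumed_gL <= 0)) {
    stop("substrate consumption must be > 0", call. = FALSE)
  }
  titer_gL / substrate_consumed_gL
}

#' Volumetric productivity
#'
#' @param titer_gL Product titer, g/L.
#' @param duration_h Fermentation duration, h (> 0).
#' @return Productivity, g/L/h.
#' @export
#' @examples
#' volumetric_productivity(15.0, 60) # 0.25 g/L/h
volumetric_productivity <- function(titer_gL, duration_h) {
  stopifnot(all(titer_gL >= 0))
  if (any(duration_h <= 0)) stop("duration must be > 0", call. = FALSE)
  titer_gL / duration_h
}

#' Full fermentation metrics report
#'
#' Computes the standard performance tuple (titer in mM and g/L, substrate
#' yield in g/g, volumetric productivity in g/L/h) for one fermentation
#' run, with all conversions through the single molar mass table. The yield
#' denominator is taken explicitly (glucose consumed for bioreactors,
#' initial medium glucose for shake flasks) rather than guessed from
#' context.
#'
#' @param titer Product titer, in the unit named by `titer_unit`.
#' @param titer_unit `"mM"` or `"g/L"`.
#' @param compound Compound name (default `"hexane-2,3-diol"`).
#' @param substrate_consumed_gL Yield denominator, g/L; `NA` to skip.
#' @param duration_h Duration, h; `NA` to skip productivity.
#' @param molar_mass Optional molar mass override, g/mol.
#' @return Named list: `titer_mM`, `titer_gL`, `yield_gg`,
#'   `productivity_gLh` (the latter two `NA` when their input is `NA`).
#' @export
#' @examples
#' metrics_report(91.1, "mM", "hexane-2,3-diol", 40, 96)
metrics_report <- function(titer, titer_unit = c("mM", "g/L"),
                           compound = "hexane-2,3-diol",
                           substrate_consumed_gL = NA, duration_h = NA,
                           molar_mass = NULL) {
  titer_unit <- match.arg(titer_unit)
  stopifnot(is.numeric(titer), length(titer) == 1L, titer >= 0)
  if (titer_unit == "mM") {
    titer_mM <- titer
    titer_gL <- molar_to_mass_conc(titer, compound, molar_mass)
  } else {
    titer_gL <- titer
    titer_mM <- mass_to_molar_conc(titer, compound, molar_mass)
  }
  list(
    titer_mM = titer_mM,
    titer_gL = titer_gL,
    yield_gg = if (is.na(substrate_consumed_gL)) NA_real_ else
      substrate_yield(titer_gL, substrate_consumed_gL),
    productivity_gLh = if (is.na(duration_h)) NA_real_ else
      volumetric_productivity(titer_gL, duration_h)
  )
}
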