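#' Sparse time-course observations
#'
#' The fitting target: one record per (time, species) observation. The
#' number of records is the `n` of the AIC formula.
#'
#' @param time_h Numeric observation times, h (nonnegative).
#' @param species Character species identifiers (case-insensitive members of
#'   [hdo_species()]).
#' @param value_mM Observed concentrations, mM (nonnegative).
#' @return Object of class `time_series_data`: data frame with columns
#'   `time_h`, `species`, `value_mM`, sorted time-major with species in
#'   canonical order.
#' @export
#' @examples
#' time_series_data(c(24, 48, 72, 96), "HDO", c(5, 12, 18, 22))
time_series_data <- function(time_h, species, value_mM) {
  n <- max(length(time_h), length(species), length(value_mM))
  time_h <- rep_len(as.numeric(time_h), n)
  species <- rep_len(as.character(species), n)
  value_mM <- rep_len(as.numeric(value_mM), n)
  if (n < 1L) stop("at least one observation is required", call. = FALSE)
  species <- toupper(species)
  bad <- !species %in% hdo_species()
  if (any(bad)) {
    stop("unknown species: ", paste(unique(species[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("observation times must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(value_mM)) || any(value_mM < 0)) {
    stop("observed values must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(paste(time_h, species))) {
    stop("duplicate (time, species) observations", call. = FALSE)
  }
  ord <- order(time_h, match(species, hdo_species()))
  out <- data.frame(time_h = time_h[ord], species = species[ord],
                    value_mM = value_mM[ord], stringsAsFactors = FALSE)
  class(out) <- c("time_series_data", "data.frame")
  out
}

as_time_series_data <- function(x) {
  if (inherits(x, "time_series_data")) return(x)
  if (is.data.frame(x) && all(c("time_h", "species", "value_mM") %in%
                              names(x))) {
    return(time_series_data(x$time_h, x$species, x$value_mM))
  }
  stop("expected a time_series_data object or a data frame with columns ",
       "time_h, species, value_mM", call. = FALSE)
}
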