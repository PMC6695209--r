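# Derived observables: elution fluxes, cumulative effluent, thrombin
# partitioning, mass conversions, half-life estimation.
#
# Surface fluxes are in uM*um/s; 1 uM*um/s = 1e-9 mol m^-2 s^-1.

flux_series <- function(time, flux, species) {
  out <- data.frame(time = time, flux = flux)
  attr(out, "species") <- species
  attr(out, "units") <- "uM*um/s"
  class(out) <- c("flux_series", "data.frame")
  out
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("%s elution flux (%s), %d points, peak %.3g\n",
              attr(x, "species"), attr(x, "units"), nrow(x), max(x$flux)))
  invisible(x)
}

traj_params <- function(traj) {
  p <- attr(traj, "params")
  if (is.null(p)) stop("expected a clot_trajectory with attached parameters",
                       call. = FALSE)
  p
}

#' Fragment F1.2 elution flux
#'
#' F1.2 is released 1:1 with thrombin generation by prothrombinase and is
#' taken to leak out of the core as fast as it is made, so the surface flux
#' is the areal thrombin production rate,
#' `J_F1.2(t) = eta4 * alpha4 * Xa(t) * delta`.
#'
#' The film factor is the printed `V_pore/area = delta`; set
#' `porosity_correct = TRUE` to use `delta * porosity` instead (the
#' geometric pore volume per area), which scales the flux by the porosity.
#'
#' @param traj A `clot_trajectory`.
#' @param params Parameters; defaults to those attached to `traj`.
#' @param porosity_correct Apply the porosity factor to the film thickness.
#' @return A `flux_series` (uM*um/s).
#' @export
flux_f12 <- function(traj, params = traj_params(traj),
                     porosity_correct = FALSE) {
  r <- params$reactions
  delta <- params$geometry$delta *
    (if (porosity_correct) params$geometry$porosity else 1)
  flux_series(traj$time,
              r$eta[4] * r$alpha[4] * params$reaction_mask[4] * traj$xa * delta,
              "F1.2")
}

#' Thrombin-antithrombin (TAT) elution flux
#'
#' Of the free thrombin eluting from the core, the TAT-complexed share
#' (default 70%; the rest is captured by other plasma inhibitors) gives the
#' measurable flux `J_TAT(t) = 0.7 * k_elute * IIa_free(t) * delta`.
#'
#' @inheritParams flux_f12
#' @return A `flux_series` (uM*um/s).
#' @export
flux_tat <- function(traj, params = traj_params(traj),
                     porosity_correct = FALSE) {
  delta <- params$geometry$delta *
    (if (porosity_correct) params$geometry$porosity else 1)
  flux_series(traj$time,
              params$tat_fraction * params$k_elute * traj$iia_free * delta,
              "TAT")
}

#' Convert a surface flux between uM*um/s and mol m^-2 s^-1
#'
#' @param flux Numeric flux values.
#' @param from,to `"uM.um.s"` or `"mol.m2.s"`.
#' @return Converted values (`1 uM*um/s = 1e-9 mol m^-2 s^-1`).
#' @export
convert_flux <- function(flux, from = "uM.um.s", to = "mol.m2.s") {
  scale <- c(uM.um.s = 1e-9, mol.m2.s = 1)   # to mol m^-2 s^-1
  if (!from %in% names(scale) || !to %in% names(scale))
    stop("convert_flux: units must be 'uM.um.s' or 'mol.m2.s'", call. = FALSE)
  flux * scale[[from]] / scale[[to]]
}

#' Cumulative eluted amount over a patch
#'
#' Trapezoidal time integral of a surface flux over the patch area,
#' reported in femtomoles.
#'
#' @param flux A `flux_series` (uM*um/s).
#' @param area_um2 Patch area (um^2); default the 250 x 250 um patch.
#' @return data.frame `time`, `amount_fmol` (monotone non-decreasing for a
#'   non-negative flux).
#' @export
cumulative_eluted <- function(flux, area_um2 = 250 * 250) {
  t <- flux$time; f <- flux$flux
  n <- length(t)
  cum <- c(0, cumsum(diff(t) * (f[-1] + f[-n]) / 2))   # uM*um*s
  mol <- cum * 1e-9 * (area_um2 * 1e-12)               # mol m^-2 * m^2
  data.frame(time = t, amount_fmol = mol * 1e15)
}

#' Partition of intraclot thrombin between free and bound pools
#'
#' @param traj A `clot_trajectory`.
#' @return data.frame with concentrations (uM) of free, E-bound and
#'   gamma'-bound thrombin, the total, and the corresponding fractions
#'   (which sum to 1 wherever the total is positive; all-NA fractions where
#'   it is zero).
#' @export
thrombin_partition <- function(traj) {
  total <- traj$iia_free + traj$es + traj$gs
  frac <- function(x) ifelse(total > 0, x / total, NA_real_)
  data.frame(time = traj$time,
             free = traj$iia_free, bound_E = traj$es, bound_gamma = traj$gs,
             total = total,
             frac_free = frac(traj$iia_free),
             frac_E = frac(traj$es), frac_gamma = frac(traj$gs))
}

#' Fibrin molar-to-mass conversion
#'
#' Uses the model's own anchors (9 uM = 3 mg/mL plasma fibrinogen;
#' 90 uM = 30 mg/mL intraclot fibrin), i.e. exactly 3 uM per mg/mL.
#'
#' @param fibrin_uM Fibrin monomer concentration (uM).
#' @return Mass concentration (mg/mL).
#' @export
fibrin_mg_per_ml <- function(fibrin_uM) {
  if (any(fibrin_uM < 0))
    stop("fibrin_mg_per_ml: fibrin must be non-negative", call. = FALSE)
  fibrin_uM / 3
}

#' Apparent half-life of a decaying series
#'
#' First time at which the series falls to half of its initial value, by
#' linear interpolation between grid points. If the series never halves
#' within the window, returns `NA` with attributes `reached = FALSE` and
#' `final_fraction`, and says so in a message.
#'
#' @param time Time grid (s), increasing.
#' @param value Non-negative amounts.
#' @return Half-life (s), or `NA` (see Details). Attribute `reached` tells
#'   which.
#' @export
elution_halflife <- function(time, value) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (is.unsorted(time)) stop("elution_halflife: time must be increasing",
                              call. = FALSE)
  v0 <- value[1]
  if (v0 <= 0) stop("elution_halflife: series must start positive", call. = FALSE)
  half <- v0 / 2
  below <- which(value <= half)
  if (length(below) == 0) {
    message(sprintf(
      "elution_halflife: series never halves in window (final fraction %.3g)",
      value[length(value)] / v0))
    out <- NA_real_
    attr(out, "reached") <- FALSE
    attr(out, "final_fraction") <- value[length(value)] / v0
    return(out)
  }
  i <- below[1]
  if (i == 1) return(structure(0, reached = TRUE))
  t_half <- time[i - 1] + (value[i - 1] - half) /
    (value[i - 1] - value[i]) * (time[i] - time[i - 1])
  structure(t_half, reached = TRUE)
}

#' Write a flux or time series to CSV with unit headers
#'
#' @param x A data.frame (e.g. a `flux_series`).
#' @param path Output path.
#' @param units Named character vector of unit strings per column; defaults
#'   to the `units` attribute, if any.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(units) && !is.null(attr(x, "units")))
    units <- c(time = "s", flux = attr(x, "units"))
  if (!is.null(units))
    writeLines(sprintf("# units: %s",
                       paste(sprintf("%s [%s]", names(units), units),
                             collapse = ", ")), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}
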