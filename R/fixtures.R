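# Stand-in input series for the transport model. The experimental
# bottom-wall thrombin flux and intraclot fibrin series are immunoassay
# measurements with no published numerical form, so the transport model is
# driven either by the thin-film ODE model's own output or by parametric
# ramps.

new_fixture <- function(time, value, unit, provenance) {
  out <- data.frame(time = time, value = value)
  attr(out, "unit") <- unit
  attr(out, "provenance") <- provenance
  class(out) <- c("timeseries_fixture", "data.frame")
  out
}

#' @export
print.timeseries_fixture <- function(x, ...) {
  cat(sprintf("fixture [%s] (%s): %d points, t in [%g, %g] s, max %.4g\n",
              attr(x, "provenance"), attr(x, "unit"), nrow(x),
              x$time[1], x$time[nrow(x)], max(x$value)))
  invisible(x)
}

#' Couple ODE output to the transport model
#'
#' Derives the two driving series of the channel model from a thin-film
#' trajectory: the bottom-wall thrombin flux
#' `J(t) = eta4 * alpha4 * Xa(t) * delta` (the areal thrombin production
#' rate, identical in form to the F1.2 flux) and the intraclot fibrin
#' concentration, both resampled onto a uniform grid.
#'
#' @param traj A `clot_trajectory` from [simulate_cascade()].
#' @param dt Output grid spacing (s).
#' @return List with `J` and `fibrin`, each a `timeseries_fixture`.
#' @export
fixture_from_ode <- function(traj, dt = 1) {
  grid <- seq(min(traj$time), max(traj$time), by = dt)
  J <- flux_f12(traj)
  list(J = new_fixture(grid,
                       stats::approx(J$time, J$flux, xout = grid)$y,
                       "uM*um/s", "ode-coupled"),
       fibrin = new_fixture(grid,
                            stats::approx(traj$time, traj$fibrin,
                                          xout = grid)$y,
                            "uM", "ode-coupled"))
}

#' Saturating-ramp fixture
#'
#' `value(t) = plateau * (1 - exp(-t / rise_time))`, deterministic given its
#' parameters; optional multiplicative log-normal noise for robustness tests
#' (off by default, and reproducible via an explicit seed).
#'
#' @param t_end Duration (s).
#' @param plateau Asymptotic value.
#' @param rise_time Exponential rise time constant (s).
#' @param dt Grid spacing (s).
#' @param unit Unit string recorded with the series.
#' @param noise_sd Standard deviation of log-normal multiplicative noise
#'   (0 = none).
#' @param seed Seed used when `noise_sd > 0`.
#' @return A `timeseries_fixture`.
#' @export
parametric_ramp <- function(t_end, plateau, rise_time, dt = 1,
                            unit = "uM*um/s", noise_sd = 0, seed = 1L) {
  if (plateau < 0) stop("parametric_ramp: plateau must be non-negative",
                        call. = FALSE)
  if (rise_time <= 0) stop("parametric_ramp: rise_time must be positive",
                           call. = FALSE)
  t <- seq(0, t_end, by = dt)
  v <- plateau * (1 - exp(-t / rise_time))
  if (noise_sd > 0) {
    v <- withr_seed(seed, v * exp(stats::rnorm(length(v), 0, noise_sd)))
  }
  new_fixture(t, v, unit, "parametric")
}

# Evaluate `expr` under a temporary RNG seed without disturbing the caller's
# RNG state.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Write a fixture to CSV with provenance headers
#'
#' @param x A `timeseries_fixture`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# unit: %s", attr(x, "unit")),
               sprintf("# provenance: %s", attr(x, "provenance"))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a fixture CSV written by [write_fixture_csv()]
#'
#' @param path Input path.
#' @return A `timeseries_fixture`.
#' @export
read_fixture_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  unit <- sub("^# unit: ", "", hdr[1])
  prov <- sub("^# provenance: ", "", hdr[2])
  d <- utils::read.csv(path, comment.char = "#")
  new_fixture(d$time, d$value, unit, prov)
}
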