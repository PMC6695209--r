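# The eight-state thin-film cascade.
#
# States (uM): tf_star (TF/FVIIa), xa (prothrombinase surrogate FXa/FVa),
# ixa (intrinsic tenase surrogate FIXa/FVIIIa), xia (FXIa), fibrin
# (monomer incorporated into fibrin), iia_free (free thrombin), es
# (E-domain-bound thrombin), gs (gamma'-site-bound thrombin).
#
# "IIa" in the FXIa-activation, fibrin-generation and loss terms is FREE
# thrombin: fibrin-bound thrombin is catalytically silent here and fully
# protected from inhibition. Binding-site loads are tied to current fibrin:
# theta_E = 1.6*fibrin, theta_gamma = 0.3*fibrin (scenario-scalable).

state_names <- c("tf_star", "xa", "ixa", "xia", "fibrin",
                 "iia_free", "es", "gs")

#' In silico scenario transforms
#'
#' Describes a perturbation of the baseline cascade: GPRP-style inhibition of
#' fibrin polymerization/binding, hemophilia (no FIXa generation by TF/FVIIa
#' and no intrinsic tenase activity on FX), knockout of the thrombin-FXIa
#' feedback loop, knockout of the TF-driven FIXa branch alone, scaling of the
#' gamma'-fibrinogen site density, and the diffusional escape half-life of
#' free species.
#'
#' @param gprp Block fibrin polymerization/thrombin capture (Gly-Pro-Arg-Pro).
#' @param hemophilia Zero reactions 2 and 3 (no FIXa from TF, no intrinsic
#'   tenase), the severe hemophilia A/B limit.
#' @param no_fxia_feedback Zero reactions 6 and 7 (no thrombin-FXIa loop).
#' @param no_tf_ixase Zero reaction 2 only (no TF-driven FIXa).
#' @param gamma_prime_scale Multiplier on gamma'-site density (0.5, 1, 2
#'   correspond to 50/100/200% of normal gamma'-fibrinogen).
#' @param escape_halflife Free-species escape half-life (s); sets
#'   `k_elute = ln(2)/escape_halflife`.
#' @param gprp_mode How GPRP is realised: `"alpha5_zero"` removes fibrin
#'   generation; `"kd_inf"` keeps fibrin but makes both sites non-binding
#'   (Kd = 1e7 uM with re-derived kr).
#' @return An object of class `clot_scenario`.
#' @export
scenario <- function(gprp = FALSE, hemophilia = FALSE,
                     no_fxia_feedback = FALSE, no_tf_ixase = FALSE,
                     gamma_prime_scale = 1, escape_halflife = 2,
                     gprp_mode = c("alpha5_zero", "kd_inf")) {
  gprp_mode <- match.arg(gprp_mode)
  if (gamma_prime_scale <= 0)
    stop("scenario: gamma_prime_scale must be positive", call. = FALSE)
  if (escape_halflife <= 0)
    stop("scenario: escape_halflife must be positive", call. = FALSE)
  s <- list(gprp = isTRUE(gprp), hemophilia = isTRUE(hemophilia),
            no_fxia_feedback = isTRUE(no_fxia_feedback),
            no_tf_ixase = isTRUE(no_tf_ixase),
            gamma_prime_scale = gamma_prime_scale,
            escape_halflife = escape_halflife, gprp_mode = gprp_mode)
  class(s) <- "clot_scenario"
  s
}

#' Apply a scenario to a parameter set
#'
#' Returns a transformed copy of `params`. Toggles compose; reaction
#' knockouts act through the `reaction_mask` multipliers so that the derived
#' `alpha` column always stays consistent with `kcat*S0/(Km+S0)`.
#'
#' @param params A `clot_params` object.
#' @param scn A [scenario()] object (or `NULL` for baseline).
#' @return A transformed, validated `clot_params` object.
#' @export
apply_scenario <- function(params, scn = NULL) {
  validate_parameters(params)
  if (is.null(scn)) return(params)
  stopifnot(inherits(scn, "clot_scenario"))
  p <- params
  p$k_elute <- log(2) / scn$escape_halflife
  if (scn$gprp) {
    if (scn$gprp_mode == "alpha5_zero") {
      p$reaction_mask[5] <- 0
    } else {
      p$sites$Kd <- 1e7
      p$sites$kr <- compute_kr(p$sites$Kd, p$sites$kf)
    }
  }
  if (scn$hemophilia) p$reaction_mask[c(2, 3)] <- 0
  if (scn$no_fxia_feedback) p$reaction_mask[c(6, 7)] <- 0
  if (scn$no_tf_ixase) p$reaction_mask[2] <- 0
  p$sites$sites_per_monomer[p$sites$name == "gamma"] <-
    p$sites$sites_per_monomer[p$sites$name == "gamma"] * scn$gamma_prime_scale
  p$overrides <- c(p$overrides, sprintf("scenario:%s", format_scenario(scn)))
  validate_parameters(p)
  p
}

format_scenario <- function(scn) {
  on <- c(if (scn$gprp) paste0("gprp(", scn$gprp_mode, ")"),
          if (scn$hemophilia) "hemophilia",
          if (scn$no_fxia_feedback) "no_fxia_feedback",
          if (scn$no_tf_ixase) "no_tf_ixase",
          if (scn$gamma_prime_scale != 1)
            sprintf("gamma_prime_scale=%g", scn$gamma_prime_scale),
          if (scn$escape_halflife != 2)
            sprintf("escape_halflife=%g", scn$escape_halflife))
  if (length(on) == 0) "baseline" else paste(on, collapse = "+")
}

#' @export
print.clot_scenario <- function(x, ...) {
  cat("clot scenario:", format_scenario(x), "\n")
  invisible(x)
}

# Flattened rate constants for the RHS, computed once per solve.
rate_table <- function(params) {
  r <- params$reactions
  a <- r$alpha * params$reaction_mask
  s <- params$sites
  iE <- match("E", s$name); iG <- match("gamma", s$name)
  list(a1 = a[1], a2 = a[2], a3 = a[3],
       e4a4 = r$eta[4] * a[4], e5a5 = r$eta[5] * a[5],
       e6a6 = r$eta[6] * a[6], a7 = a[7],
       k_elute = params$k_elute, k_i = params$k_i, k_i_tf = params$k_i_tf,
       Ekf = s$kf[iE], Ekr = s$kr[iE], En = s$sites_per_monomer[iE],
       Gkf = s$kf[iG], Gkr = s$kr[iG], Gn = s$sites_per_monomer[iG])
}

#' Right-hand side of the eight-state cascade
#'
#' Evaluates the time derivatives of the cascade at a given state. The
#' binding-site loads are `theta_E = n_E * fibrin` and
#' `theta_gamma = n_gamma * fibrin` with the (possibly scenario-scaled)
#' per-monomer stoichiometries.
#'
#' @param t Time (s); the system is autonomous, `t` is accepted for solver
#'   compatibility.
#' @param state Named numeric vector of the 8 states (uM), in the order
#'   `tf_star, xa, ixa, xia, fibrin, iia_free, es, gs`.
#' @param params A `clot_params` object (or a pre-flattened rate table).
#' @return Named numeric vector of derivatives (uM/s).
#' @export
cascade_rhs <- function(t, state, params) {
  if (any(!is.finite(state)))
    stop("cascade_rhs: non-finite state encountered", call. = FALSE)
  k <- if (inherits(params, "clot_params")) rate_table(params) else params
  tf <- state[[1]]; xa <- state[[2]]; ixa <- state[[3]]; xia <- state[[4]]
  fib <- state[[5]]; iia <- state[[6]]; es <- state[[7]]; gs <- state[[8]]
  dES <- k$Ekf * iia * (k$En * fib - es) - k$Ekr * es
  dGS <- k$Gkf * iia * (k$Gn * fib - gs) - k$Gkr * gs
  d <- c(
    tf_star  = -k$k_i_tf * tf,
    xa       = k$a1 * tf + k$a3 * ixa - k$k_i * xa,
    ixa      = k$a2 * tf + k$a7 * xia - k$k_i * ixa,
    xia      = k$e6a6 * iia - k$k_elute * xia - k$k_i * xia,
    fibrin   = k$e5a5 * iia,
    iia_free = k$e4a4 * xa - (dES + dGS) - k$k_elute * iia - k$k_i * iia,
    es       = dES,
    gs       = dGS)
  d
}

#' Integrate the thin-film cascade
#'
#' Solves the stiff eight-state system from the initial condition
#' `tf_star = tf_star_0`, all other states zero, with a BDF-type implicit
#' solver (the fast association/dissociation of thrombin with fibrin sites
#' makes the system stiff).
#'
#' @param params A `clot_params` object; defaults to [default_parameters()].
#' @param scn Optional [scenario()] applied via [apply_scenario()].
#' @param t_end Final time (s).
#' @param times Optional explicit output grid (s); defaults to 1-s spacing.
#' @param rtol,atol Solver tolerances (relative; absolute in uM).
#' @return A `clot_trajectory`: data.frame with column `time` and the 8
#'   states, with the resolved parameters, scenario and solver settings as
#'   attributes. States are clipped to zero within `-1e-9` uM; a larger
#'   negative excursion is an error.
#' @export
simulate_cascade <- function(params = default_parameters(), scn = NULL,
                             t_end = 800, times = NULL,
                             rtol = 1e-8, atol = 1e-12) {
  if (is.null(times)) {
    if (t_end <= 0) stop("simulate_cascade: t_end must be positive", call. = FALSE)
    times <- seq(0, t_end, by = min(1, t_end / 200))
  }
  if (is.unsorted(times, strictly = TRUE))
    stop("simulate_cascade: times must be strictly increasing", call. = FALSE)
  p <- apply_scenario(params, scn)
  k <- rate_table(p)
  y0 <- stats::setNames(c(p$tf_star_0, rep(0, 7)), state_names)
  rhs <- function(t, y, parms) list(cascade_rhs(t, y, parms))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = k,
                      method = "bdf", rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  sol <- as.data.frame(sol)
  names(sol)[1] <- "time"
  states <- as.matrix(sol[, state_names])
  if (any(states < -1e-9))
    stop(sprintf(paste0("simulate_cascade: solver produced a negative state ",
                        "below tolerance (min %.3g uM); tighten rtol/atol"),
                 min(states)), call. = FALSE)
  states[states < 0] <- 0
  sol[, state_names] <- states
  attr(sol, "params") <- p
  attr(sol, "scenario") <- scn
  attr(sol, "solver") <- list(method = "bdf", rtol = rtol, atol = atol,
                              istate = diagn)
  class(sol) <- c("clot_trajectory", "data.frame")
  sol
}

#' @export
print.clot_trajectory <- function(x, ...) {
  n <- nrow(x)
  last <- x[n, ]
  cat(sprintf("clot trajectory: %d points, t in [%g, %g] s\n",
              n, x$time[1], x$time[n]))
  cat(sprintf("  at t=%g s: free IIa %.3g nM, total IIa %.3g uM, fibrin %.3g uM\n",
              last$time, last$iia_free * 1e3,
              last$iia_free + last$es + last$gs, last$fibrin))
  cat(sprintf("  Xa %.3g nM, IXa %.3g pM, XIa %.3g pM\n",
              last$xa * 1e3, last$ixa * 1e6, last$xia * 1e6))
  invisible(x)
}

#' Decompose procoagulant generation by pathway
#'
#' Runs the baseline cascade, the FXIa-feedback knockout (reactions 6 and 7
#' off), the TF-FIXase knockout (reaction 2 off) and the severe-hemophilia
#' variant (reactions 2 and 3 off) on a shared output grid, and forms the
#' FXIa-feedback contribution as the curve difference
#' baseline minus no-feedback for FIXa, FXa and thrombin.
#'
#' @param params A `clot_params` object.
#' @param t_end Final time (s).
#' @param times Optional shared output grid.
#' @return A named list of `clot_trajectory` objects (`baseline`,
#'   `no_fxia_feedback`, `no_tf_ixase`, `hemophilia`) plus `fxia_pathway`,
#'   a data.frame of baseline-minus-no-feedback differences for
#'   `ixa`, `xa`, `iia_free`, `iia_total`.
#' @export
pathway_decomposition <- function(params = default_parameters(), t_end = 800,
                                  times = NULL) {
  if (is.null(times)) times <- seq(0, t_end, by = min(1, t_end / 200))
  runs <- list(
    baseline        = simulate_cascade(params, NULL, times = times),
    no_fxia_feedback = simulate_cascade(params, scenario(no_fxia_feedback = TRUE),
                                        times = times),
    no_tf_ixase     = simulate_cascade(params, scenario(no_tf_ixase = TRUE),
                                       times = times),
    hemophilia      = simulate_cascade(params, scenario(hemophilia = TRUE),
                                       times = times))
  a <- runs$baseline; c_ <- runs$no_fxia_feedback
  runs$fxia_pathway <- data.frame(
    time = a$time,
    ixa = a$ixa - c_$ixa,
    xa = a$xa - c_$xa,
    iia_free = a$iia_free - c_$iia_free,
    iia_total = (a$iia_free + a$es + a$gs) - (c_$iia_free + c_$es + c_$gs))
  runs
}

#' Equilibrium free fraction of thrombin over two fibrin site classes
#'
#' Closed-system two-site binding equilibrium: given total thrombin and the
#' fibrin monomer concentration, solves
#' `free + theta_E*free/(Kd_E+free) + theta_g*free/(Kd_g+free) = total`
#' for the free concentration by bisection (to 1e-12 relative) and returns
#' `free/total`. Serves as the independent oracle for the kinetic binding
#' ODEs in the fast-exchange limit. In the dilute-thrombin limit the free
#' fraction tends to `1/(1 + theta_E/Kd_E + theta_g/Kd_g)`.
#'
#' @param iia_total Total thrombin (uM).
#' @param fibrin Fibrin monomer concentration (uM).
#' @param sites Binding-site table as in `default_parameters()$sites`.
#' @return Free fraction in `[0, 1]`.
#' @export
equilibrium_free_fraction <- function(iia_total, fibrin,
                                      sites = default_parameters()$sites) {
  stopifnot(iia_total >= 0, fibrin >= 0)
  thE <- sites$sites_per_monomer[sites$name == "E"] * fibrin
  thG <- sites$sites_per_monomer[sites$name == "gamma"] * fibrin
  KE <- sites$Kd[sites$name == "E"]
  KG <- sites$Kd[sites$name == "gamma"]
  dilute <- 1 / (1 + thE / KE + thG / KG)
  if (fibrin == 0) return(1)
  if (iia_total == 0) return(dilute)
  g <- function(free) free + thE * free / (KE + free) +
    thG * free / (KG + free) - iia_total
  lo <- 0; hi <- iia_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-12 * iia_total) break
  }
  ((lo + hi) / 2) / iia_total
}
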