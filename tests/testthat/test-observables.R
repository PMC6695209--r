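test_that("elution fluxes match their defining expressions", {
  traj <- baseline_traj()
  p <- attr(traj, "params")
  f12 <- flux_f12(traj)
  tat <- flux_tat(traj)
  # hand evaluations at a 15 nM prothrombinase / 100 nM free thrombin state
  expect_equal(0.18 * p$reactions$alpha[4] * 0.015 * 15, 1.0, tolerance = 0.01)
  expect_equal(0.7 * log(2) / 2 * 0.1 * 15, 0.364, tolerance = 0.01)
  # series follow the states pointwise
  expect_equal(f12$flux,
               0.18 * p$reactions$alpha[4] * traj$xa * 15, tolerance = 1e-12)
  expect_equal(tat$flux, 0.7 * p$k_elute * traj$iia_free * 15,
               tolerance = 1e-12)
  expect_equal(f12$flux[1], 0)   # no prothrombinase at t = 0
  expect_equal(tat$flux[1], 0)
  # doubling the film thickness doubles the flux
  p2 <- p; p2$geometry <- core_geometry(delta = 30)
  expect_equal(flux_f12(traj, p2)$flux, 2 * f12$flux, tolerance = 1e-12)
  # opt-in porosity correction scales by the porosity
  expect_equal(flux_f12(traj, porosity_correct = TRUE)$flux,
               0.5 * f12$flux, tolerance = 1e-12)
})

test_that("flux unit conversion round-trips", {
  x <- c(0, 0.37, 1.2)
  expect_equal(convert_flux(x, "uM.um.s", "mol.m2.s"), x * 1e-9)
  expect_equal(convert_flux(convert_flux(x, "uM.um.s", "mol.m2.s"),
                            "mol.m2.s", "uM.um.s"), x)
  expect_error(convert_flux(1, "furlongs"), "units")
})

test_that("cumulative effluent integrates flux over the patch", {
  # constant 1 uM*um/s over 100 s on a 250x250 um patch is 6.25 fmol
  f <- structure(data.frame(time = seq(0, 100, 1), flux = 1),
                 class = c("flux_series", "data.frame"))
  cum <- cumulative_eluted(f, 250 * 250)
  expect_equal(cum$amount_fmol[nrow(cum)], 6.25, tolerance = 1e-9)
  expect_true(all(diff(cum$amount_fmol) >= 0))
  # zero flux stays zero
  f0 <- f; f0$flux <- 0
  expect_equal(cumulative_eluted(f0)$amount_fmol, rep(0, 101))
  # quadrature converges under grid refinement
  tr <- baseline_traj()
  tat <- flux_tat(tr)
  fine <- simulate_cascade(t_end = 800, times = seq(0, 800, 0.25))
  tat_f <- flux_tat(fine)
  a <- cumulative_eluted(tat)$amount_fmol
  b <- cumulative_eluted(tat_f)$amount_fmol
  expect_equal(a[length(a)], b[length(b)], tolerance = 1e-3)
})

test_that("fibrin sequestration suppresses TAT elution", {
  traj <- baseline_traj()
  p <- attr(traj, "params")
  tat <- cumulative_eluted(flux_tat(traj), p$geometry$area)
  eluted_fmol <- tat$amount_fmol[nrow(tat)]
  # the clot retains more thrombin than it sheds as TAT ...
  retained_fmol <- total_iia(last_row(traj)) * 1e-6 * p$geometry$v_pore *
    1e-15 * 1e15
  expect_lt(eluted_fmol, retained_fmol)
  # ... and blocking fibrin (no capture) sheds far more
  gp <- simulate_cascade(scn = scenario(gprp = TRUE), t_end = 800)
  tat_gp <- cumulative_eluted(flux_tat(gp), p$geometry$area)
  expect_gt(tat_gp$amount_fmol[nrow(tat_gp)], 2 * eluted_fmol)
})

test_that("thrombin partition fractions are consistent", {
  part <- thrombin_partition(baseline_traj())
  ok <- part$total > 0
  s <- part$frac_free[ok] + part$frac_E[ok] + part$frac_gamma[ok]
  expect_true(all(abs(s - 1) < 1e-9))
  expect_true(all(part$frac_free[ok] >= 0 & part$frac_free[ok] <= 1))
  # late-time partition agrees with the equilibrium oracle
  n <- nrow(part)
  oracle <- equilibrium_free_fraction(part$total[n],
                                      baseline_traj()$fibrin[n])
  expect_equal(part$frac_free[n], oracle, tolerance = 0.02)
  # without fibrin all thrombin is free
  gp <- thrombin_partition(simulate_cascade(scn = scenario(gprp = TRUE),
                                            t_end = 200))
  ok <- gp$total > 0
  expect_true(all(gp$frac_free[ok] == 1))
})

test_that("fibrin mass conversion matches both molar anchors", {
  expect_equal(fibrin_mg_per_ml(9), 3)
  expect_equal(fibrin_mg_per_ml(90), 30)
  expect_equal(fibrin_mg_per_ml(0), 0)
  expect_error(fibrin_mg_per_ml(-1), "non-negative")
})

test_that("apparent half-life recovers closed-form decays", {
  t <- seq(0, 50, 0.1)
  # pure exponential with tau = 7
  hl <- elution_halflife(t, exp(-log(2) * t / 7))
  expect_equal(as.numeric(hl), 7, tolerance = 1e-3)
  expect_true(attr(hl, "reached"))
  # free-thrombin washout: production off, no fibrin -> ln2/(k_elute + k_i)
  p <- default_parameters()
  rate <- p$k_elute + p$k_i
  expect_equal(log(2) / rate, 1.9355, tolerance = 1e-3)
  hw <- elution_halflife(t, 0.1 * exp(-rate * t))
  expect_equal(as.numeric(hw), log(2) / rate, tolerance = 1e-3)
  # retarded washout at 90 uM fibrin: equilibrium retardation on k_elute
  R <- 1 + 144 / 2.8 + 27 / 0.1
  t_ret <- R * log(2) / p$k_elute
  expect_equal(t_ret, 645, tolerance = 0.01)
  # a series that never halves reports the final fraction
  expect_message(hn <- elution_halflife(t, 1 - 0.01 * t / 50), "never halves")
  expect_true(is.na(hn))
  expect_false(attr(hn, "reached"))
  expect_equal(attr(hn, "final_fraction"), 0.99)
  expect_error(elution_halflife(t, rep(0, length(t))), "positive")
})
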