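test_that("cascade right-hand side matches direct substitution", {
  p <- default_parameters()
  s0 <- c(tf_star = 2.2e-6, xa = 0, ixa = 0, xia = 0, fibrin = 0,
          iia_free = 0, es = 0, gs = 0)
  d <- cascade_rhs(0, s0, p)
  a <- p$reactions$alpha
  expect_equal(d[["xa"]], a[1] * 2.2e-6, tolerance = 1e-12)
  expect_equal(d[["ixa"]], a[2] * 2.2e-6, tolerance = 1e-12)
  expect_equal(d[["tf_star"]], -p$k_i_tf * 2.2e-6, tolerance = 1e-12)
  expect_equal(unname(d[c("xia", "fibrin", "iia_free", "es", "gs")]),
               rep(0, 5))
  # all-zero state is a fixed point
  expect_equal(unname(cascade_rhs(0, rep(0, 8), p)), rep(0, 8))
  # no binding sites: dES/dt = -kr*ES <= 0, release only
  s1 <- c(2.2e-6, 0, 0, 0, 0, 0.1, 0.01, 0.005)
  s1[5] <- 0
  d1 <- cascade_rhs(0, s1, p)
  expect_equal(d1[["es"]], -280 * 0.01 - 100 * 0.1 * 0.01, tolerance = 1e-12)
  expect_lt(d1[["es"]], 0)
  expect_lt(d1[["gs"]], 0)
  expect_error(cascade_rhs(0, c(NaN, rep(0, 7)), p), "non-finite")
})

test_that("baseline integration endpoints are stable (frozen regression)", {
  traj <- baseline_traj()
  last <- last_row(traj)
  # frozen from a converged solve (bdf rtol 1e-8 / atol 1e-12, radau-verified)
  expect_equal(traj$ixa[traj$time == 200], 4.73707e-5, tolerance = 1e-3)
  expect_equal(last$xia, 4.39179e-6, tolerance = 1e-3)
  expect_equal(last$xa, 1.55697e-2, tolerance = 1e-3)
  expect_equal(last$iia_free, 8.76988e-2, tolerance = 1e-3)
  expect_equal(total_iia(last), 36.1464, tolerance = 1e-3)
  expect_equal(last$fibrin, 191.037, tolerance = 1e-3)
})

test_that("scenario transforms act on the right parameters", {
  p <- default_parameters()
  # escape half-life sets the elution rate
  expect_equal(apply_scenario(p, scenario(escape_halflife = 2))$k_elute,
               0.34657, tolerance = 1e-4)
  expect_equal(apply_scenario(p, scenario(escape_halflife = 4))$k_elute,
               log(2) / 4)
  # gamma'-fibrinogen scaling acts on site stoichiometry only
  p2 <- apply_scenario(p, scenario(gamma_prime_scale = 2))
  expect_equal(p2$sites$sites_per_monomer[p2$sites$name == "gamma"], 0.6)
  expect_equal(p2$sites$sites_per_monomer[p2$sites$name == "E"], 1.6)
  # knockouts through the reaction mask, alpha column untouched
  ph <- apply_scenario(p, scenario(hemophilia = TRUE))
  expect_equal(ph$reaction_mask, c(1, 0, 0, 1, 1, 1, 1))
  expect_equal(ph$reactions$alpha, p$reactions$alpha)
  pf <- apply_scenario(p, scenario(no_fxia_feedback = TRUE))
  expect_equal(pf$reaction_mask[6:7], c(0, 0))
  # gprp modes
  pg <- apply_scenario(p, scenario(gprp = TRUE))
  expect_equal(pg$reaction_mask[5], 0)
  pk <- apply_scenario(p, scenario(gprp = TRUE, gprp_mode = "kd_inf"))
  expect_equal(pk$sites$Kd, c(1e7, 1e7))
  expect_equal(pk$sites$kr, 100 * c(1e7, 1e7))
  expect_error(scenario(gamma_prime_scale = 0), "positive")
})

test_that("blocking fibrin polymerization removes fibrin and its sites", {
  gp <- simulate_cascade(scn = scenario(gprp = TRUE), t_end = 300)
  expect_equal(max(gp$fibrin), 0)
  expect_equal(max(gp$es), 0)
  expect_equal(max(gp$gs), 0)
  expect_gt(max(gp$iia_free), 0)
})

test_that("pathway decomposition attributes late tenase to the FXIa loop", {
  dec <- pathway_decomposition(t_end = 800)
  # with the feedback loop off, FXIa is never generated
  expect_equal(max(dec$no_fxia_feedback$xia), 0)
  # the feedback share of FIXa is small early (thrombin must appear first)
  t <- dec$baseline$time
  expect_lt(max(abs(dec$fxia_pathway$ixa[t < 50])),
            0.1 * max(dec$baseline$ixa[t < 50]))
  # and dominates after 500 s
  late <- t > 500
  expect_true(all(dec$fxia_pathway$ixa[late] >
                  dec$no_fxia_feedback$ixa[late]))
  # hemophilia produces almost no thrombin
  lh <- last_row(dec$hemophilia)
  lb <- last_row(dec$baseline)
  expect_lt(total_iia(lh) / total_iia(lb), 0.001)
})

test_that("two-site equilibrium free fraction has the right limits", {
  sites <- default_parameters()$sites
  expect_equal(equilibrium_free_fraction(1, 0, sites), 1)
  # dilute-thrombin closed form at 90 uM fibrin:
  # 1 / (1 + 144/2.8 + 27/0.1)
  expect_equal(equilibrium_free_fraction(1e-12, 90, sites),
               1 / (1 + 144 / 2.8 + 27 / 0.1), tolerance = 1e-6)
  # no binding when both sites are infinitely weak
  weak <- sites; weak$Kd <- c(1e12, 1e12); weak$kr <- weak$kf * weak$Kd
  expect_equal(equilibrium_free_fraction(1, 90, weak), 1, tolerance = 1e-9)
  # conservation: recomputing bound from the returned free recovers the total
  ff <- equilibrium_free_fraction(5, 30, sites)
  free <- 5 * ff
  bound <- 1.6 * 30 * free / (2.8 + free) + 0.3 * 30 * free / (0.1 + free)
  expect_equal(free + bound, 5, tolerance = 1e-9)
})

test_that("trajectory carries resolved parameters and solver settings", {
  traj <- simulate_cascade(t_end = 10)
  expect_s3_class(traj, "clot_trajectory")
  expect_s3_class(attr(traj, "params"), "clot_params")
  expect_equal(attr(traj, "solver")$rtol, 1e-8)
  expect_error(simulate_cascade(t_end = -1), "positive")
  expect_error(simulate_cascade(times = c(0, 2, 1)), "increasing")
})
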