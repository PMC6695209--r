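test_that("linearized rate coefficient matches hand evaluations and limits", {
  # printed-table examples
  expect_equal(signif(compute_alpha(1.15, 0.24, 0.17), 2), 0.48)
  expect_equal(signif(compute_alpha(30, 0.3, 1.4), 3), 24.7)
  # saturation and no-substrate limits
  expect_equal(compute_alpha(7, 0.01, 1e6), 7, tolerance = 1e-6)
  expect_equal(compute_alpha(7, 0.3, 0), 0)
  # vectorized
  expect_equal(compute_alpha(c(1, 2), c(1, 1), c(1, 1)), c(0.5, 1))
  # rejects bad input
  expect_error(compute_alpha(-1, 0.2, 0.1), "non-negative")
  expect_error(compute_alpha(1, NA, 0.1), "finite")
  expect_error(compute_alpha(1, 0, 0), "positive")
})

test_that("binding off-rate derives from Kd and kf, and round-trips", {
  expect_equal(compute_kr(2.8, 100), 280)
  expect_equal(compute_kr(0.1, 100), 10)
  expect_equal(compute_kr(0, 50), 0)
  expect_error(compute_kr(-1, 2), "non-negative")
  # inverse map round-trip
  for (Kd in c(0.1, 2.8, 17)) {
    kr <- compute_kr(Kd, 100)
    expect_equal(kr / 100, Kd, tolerance = 1e-12)
  }
})

test_that("default parameterization reproduces the printed rate table", {
  p <- default_parameters()
  printed_alpha <- c(0.48, 0.32, 5.53, 24.7, 58.8, 4.98e-5, 0.065)
  sf <- c(2, 2, 3, 3, 3, 3, 2)
  for (i in 1:7)
    expect_equal(signif(p$reactions$alpha[i], sf[i]), printed_alpha[i])
  expect_equal(p$reactions$eta, c(1, 1, 1, 0.18, 0.05, 0.36, 1))
  expect_equal(p$sites$kr, c(280, 10))
  expect_equal(p$sites$sites_per_monomer, c(1.6, 0.3))
  expect_equal(p$tf_star_0, 2.2e-6)
  expect_equal(p$k_elute, log(2) / 2)
  expect_equal(p$k_i, log(2) / 60)
  expect_equal(p$k_i_tf, log(2) / 180)
  expect_equal(p$tat_fraction, 0.7)
  # geometry invariant
  g <- p$geometry
  expect_equal(g$v_pore, g$area * g$delta * g$porosity)
  # purity
  expect_identical(default_parameters(), default_parameters())
})

test_that("config round-trips and overrides re-derive alpha and kr", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(p, f)
  p2 <- load_config(f)
  p2$overrides <- character(0)
  expect_equal(p2, p, tolerance = 1e-12)

  # empty config gives defaults
  fe <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", fe)
  pe <- load_config(fe)
  pe$overrides <- character(0)
  expect_equal(pe, p, tolerance = 1e-12)

  # fibrinogen level override re-derives alpha5 (hand evaluation)
  fo <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("reactions:", "  - id: 5", "    S0_uM: 9"), fo)
  po <- load_config(fo)
  expect_equal(po$reactions$alpha[5], 80 * 9 / (6.5 + 9), tolerance = 1e-12)
  expect_match(po$overrides, "reactions\\[5\\].S0_uM", all = FALSE)

  # eta pass-through
  fh <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("reactions:", "  - id: 5", "    eta: 1"), fh)
  expect_equal(load_config(fh)$reactions$eta[5], 1)

  # Kd override re-derives kr
  fk <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("sites:", "  - name: gamma", "    Kd_uM: 0.2"), fk)
  expect_equal(load_config(fk)$sites$kr[2], 20)

  # escape half-life override
  ft <- withr::local_tempfile(fileext = ".yaml")
  writeLines("escape_halflife_s: 4", ft)
  expect_equal(load_config(ft)$k_elute, log(2) / 4)
})

test_that("config validation names the offending key", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("k_eluto: 0.3", bad)
  expect_error(load_config(bad), "k_eluto")
  writeLines(c("reactions:", "  - id: 3", "    eta: 1.5"), bad)
  expect_error(load_config(bad), "eta")
  writeLines("k_i: -1", bad)
  expect_error(load_config(bad), "k_i")
  writeLines(c("sites:", "  - name: D"), bad)
  expect_error(load_config(bad), "'E' or 'gamma'")
  expect_error(load_config("no/such/file.yaml"), "no such file")
})

test_that("TF surface homogenization recovers the 2.2 pM core concentration", {
  # 1 molecule/um^2 at 1% active homogenized over the default pore volume
  # (250x250x15 um at porosity 0.5) is 2.2 pM, the cascade initial condition
  conc <- tf_surface_to_concentration(1, 0.01, core_geometry())
  expect_equal(conc, 2.2e-6, tolerance = 0.01)
  expect_equal(conc, default_parameters()$tf_star_0, tolerance = 0.01)
  # linear in both density and active fraction
  expect_equal(tf_surface_to_concentration(2, 0.01), 2 * conc)
})

test_that("parameter export and JSON provenance stay in sync", {
  p <- default_parameters()
  js <- jsonlite::fromJSON(export_params_json(p))
  expect_equal(js$reactions$alpha, p$reactions$alpha)
  expect_equal(js$k_elute, p$k_elute)
})
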