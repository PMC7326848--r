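test_that("ortho-positronium 2g/3g branching reproduces the lifetime-ratio law", {
  # tau = 2 ns in tissue: 2-photon decays 70 times more frequent than 3-photon
  b <- ops_branching(2)
  expect_equal(b$ratio_2g_3g, 70)
  expect_equal(b$f_3g, 2 / 142)

  # vacuum limit: everything decays to 3 gamma
  v <- ops_branching(142)
  expect_equal(v$f_3g, 1)
  expect_equal(v$ratio_2g_3g, 0)

  # symmetry point: equal branching at half the vacuum lifetime
  expect_equal(ops_branching(71)$ratio_2g_3g, 1)

  # fractions always sum to one
  taus <- c(0.5, 1.8, 2.7, 4, 50, 142)
  bb <- ops_branching(taus)
  expect_equal(bb$f_3g + bb$f_2g, rep(1, length(taus)))

  expect_error(ops_branching(0), "positive")
  expect_error(ops_branching(-1), "positive")
  expect_error(ops_branching(150), "vacuum")
})

test_that("detection efficiency follows the slant-path interaction law", {
  lyso <- material("lyso")
  plastic <- material("plastic")

  # frozen from direct evaluation of 1 - exp(-mu d / sin theta)
  expect_equal(detection_efficiency(pi / 2, lyso, 511),
               1 - exp(-0.833 * 1.81), tolerance = 1e-12)
  expect_equal(detection_efficiency(pi / 2, lyso, 511), 0.77862,
               tolerance = 1e-4)
  expect_equal(detection_efficiency(pi / 2, plastic, 511), 0.44452,
               tolerance = 1e-4)

  # vanishing absorber
  thin <- material("plastic", thickness = 1e-9)
  expect_lt(detection_efficiency(pi / 2, thin, 511), 1e-8)

  # strictly decreasing on (0, pi/2], symmetric about pi/2
  th <- seq(0.1, pi / 2, length.out = 50)
  eff <- detection_efficiency(th, plastic, 511)
  expect_true(all(diff(eff) < 0))
  expect_equal(detection_efficiency(pi - th, plastic, 511), eff)

  expect_error(detection_efficiency(0, lyso), "theta")
  expect_error(detection_efficiency(pi, lyso), "theta")
  expect_error(detection_efficiency(pi / 2, lyso, 600), "511 or 1160")
})

test_that("phantom attenuation matches the water-cylinder survival factor", {
  ph <- phantom_model()
  expect_equal(phantom_attenuation(pi / 2, ph, 511), exp(-0.96), tolerance = 1e-12)
  expect_equal(phantom_attenuation(pi / 2, ph, 511), 0.38289, tolerance = 1e-4)
  expect_equal(phantom_attenuation(pi / 2, ph, 1160), 0.51685, tolerance = 1e-4)

  # no attenuation limit
  vac <- phantom_model(mu_511 = 0, mu_1160 = 0)
  expect_equal(phantom_attenuation(0.7, vac, 511), 1)

  # absorption (1 - survival) decreases towards theta = pi/2 and is symmetric
  th <- seq(0.1, pi / 2, length.out = 50)
  att <- phantom_attenuation(th, ph, 511)
  expect_true(all(diff(1 - att) < 0))
  expect_equal(phantom_attenuation(pi - th, ph, 511), att)
})

test_that("material presets carry the published coefficients and validate overrides", {
  lyso <- material("lyso")
  expect_equal(lyso$mu_511, 0.833)
  expect_equal(lyso$mu_1160, 0.413)
  expect_equal(lyso$thickness, 1.81)
  expect_equal(lyso$eps_sel_a, 0.34)
  expect_equal(lyso$eps_sel_p, 0.66)

  plastic <- material("plastic")
  expect_equal(plastic$mu_511, 0.098)
  expect_equal(plastic$mu_1160, 0.068)
  expect_equal(plastic$thickness, 6)
  expect_equal(plastic$eps_sel_a, 0.44)

  over <- material("plastic", thickness = 3, eps_sel_a = 0.5)
  expect_equal(over$thickness, 3)
  expect_equal(over$eps_sel_a, 0.5)
  expect_error(material("plastic", nonsense = 1), "unknown material field")
  expect_error(material("plastic", eps_sel_a = 1.2), "0, 1")
  expect_error(material("plastic", mu_511 = -1))

  cst <- ps_constants()
  expect_equal(cst$c_cm_per_ps, 0.0299792458, tolerance = 1e-10)
  expect_equal(cst$tau_vacuum_ns, 142)
})

test_that("materials load from a plain-text config with overrides", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("preset: plastic", "thickness: 3", "eps_sel_a: 0.4"), cfg)
  m <- material_from_config(cfg)
  expect_equal(m$name, "plastic")
  expect_equal(m$thickness, 3)
  expect_equal(m$eps_sel_a, 0.4)
  expect_equal(m$mu_511, 0.098)   # untouched fields keep the preset values

  bad <- tempfile(fileext = ".yaml")
  writeLines("thickness: 3", bad)
  expect_error(material_from_config(bad), "preset")
})
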