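test_that("Compton edges and the deposit sampler respect kinematic limits", {
  # closed-form edges, frozen from independent arithmetic
  expect_equal(compton_edge(511), 511 * 2 / 3, tolerance = 1e-12)
  expect_equal(compton_edge(511), 340.667, tolerance = 1e-5)
  expect_equal(compton_edge(1160), 950.66, tolerance = 1e-4)

  set.seed(21)
  for (E in c(511, 1160)) {
    dep <- sample_compton_deposit(3e4, E)
    expect_true(all(dep > 0))
    expect_lte(max(dep), compton_edge(E))
  }

  # a 511 keV photon can never satisfy a 400 keV prompt threshold
  dep <- sample_compton_deposit(1e5, 511)
  expect_lt(max(dep), 400)
})

test_that("sampled deposits follow the Klein-Nishina spectrum", {
  set.seed(22)
  for (E in c(511, 1160)) {
    dep <- sample_compton_deposit(3e4, E)
    cdf <- kn_deposit_cdf_oracle(E)
    ks <- stats::ks.test(dep, cdf)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("photon transport reproduces closed-form interaction probabilities", {
  geom <- detector_geometry()
  n <- 5e4
  set.seed(23)

  # normal incidence through 6 cm of plastic at 511 keV
  org <- matrix(0, n, 3)
  dir <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  h <- propagate_photons(org, dir, 511, geom)
  p_exp <- 1 - exp(-0.098 * 6)
  expect_lt(abs(mean(h$detected) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # interaction radius lies inside the shell; flight time consistent with path
  expect_true(all(sqrt(h$hx[h$detected]^2 + h$hy[h$detected]^2) >= 43))
  expect_true(all(sqrt(h$hx[h$detected]^2 + h$hy[h$detected]^2) <= 49))
  tof <- h$time_ps[h$detected] * ps_constants()$c_cm_per_ps
  expect_true(all(tof >= 43 & tof <= 49))

  # photons along the axis never reach the shell
  ax <- propagate_photons(matrix(0, 10, 3),
                          matrix(rep(c(0, 0, 1), each = 10), 10, 3), 511, geom)
  expect_false(any(ax$detected))

  expect_error(propagate_photons(matrix(c(50, 0, 0), 1), matrix(c(1, 0, 0), 1),
                                 511, geom), "bore")
})

test_that("isotropic interaction fraction matches the semi-analytic oracle", {
  geom <- detector_geometry()
  n <- 1e5
  set.seed(24)
  dir <- sample_isotropic(n)
  h <- propagate_photons(matrix(0, n, 3), dir, 511, geom)
  p_exp <- isotropic_interaction_oracle(geom, 511)
  expect_lt(abs(mean(h$detected) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("smearing has the configured widths and is unbiased", {
  # single-hit time sigma from the CRT convention
  expect_equal(detector_response(crt_ps = 10)$sigma_t_ps, 3.0028, tolerance = 1e-4)
  expect_equal(detector_response(crt_ps = 500)$sigma_t_ps,
               500 / (2 * sqrt(2 * log(2))) / sqrt(2), tolerance = 1e-12)

  tr <- utils::head(nema_triples(), 2e4)
  resp <- detector_response(crt_ps = 140)
  sm <- smear_hits(tr, resp, seed = 77)

  # time-difference FWHM between two detectors equals the CRT
  dt <- (sm$a1_rt - sm$a1_t) - (sm$a2_rt - sm$a2_t)
  expect_lt(abs(stats::var(dt) / (140 / 2.3548)^2 - 1), 0.05)
  expect_lt(abs(mean(sm$a1_rt - sm$a1_t)), 3 * resp$sigma_t_ps / sqrt(nrow(sm)))

  # positions: unbiased, axial sigma as configured, radius untouched
  expect_lt(abs(mean(sm$a1_rz - sm$a1_z)), 3 * resp$sigma_pos_cm / sqrt(nrow(sm)))
  expect_lt(abs(stats::sd(sm$a1_rz - sm$a1_z) / resp$sigma_pos_cm - 1), 0.05)
  expect_equal(sqrt(sm$a1_rx^2 + sm$a1_ry^2), sqrt(sm$a1_x^2 + sm$a1_y^2),
               tolerance = 1e-9)

  # zero-noise mode is the identity
  sm0 <- smear_hits(tr, detector_response(crt_ps = 0, spatial_fwhm_cm = 0))
  expect_identical(sm0$a1_rt, sm0$a1_t)
  expect_identical(sm0$p_rx, sm0$p_x)
})

test_that("triple selection applies the energy thresholds with counters", {
  ev <- generate_events(line_source(), 1e5, seed = 26)
  hits <- detect_events(ev, detector_geometry())
  resp <- detector_response()
  sel <- select_triples(hits, resp)
  expect_true(all(sel$a1_edep > 200 & sel$a2_edep > 200 & sel$p_edep > 400))

  # boundary: a prompt deposit just below threshold is rejected
  one <- hits[1, ]
  one$a1_edep <- 300; one$a2_edep <- 300; one$p_edep <- 399
  expect_equal(nrow(select_triples(one, resp)), 0)
  one$p_edep <- 401
  expect_equal(nrow(select_triples(one, resp)), 1)

  cnt <- attr(sel, "counters")
  expect_equal(unname(cnt["candidates"]), nrow(hits))
  expect_equal(unname(cnt["selected"]), nrow(sel))
  expect_equal(unname(cnt["candidates"] - cnt["selected"]),
               sum(!(hits$a1_edep > 200 & hits$a2_edep > 200 & hits$p_edep > 400)))
})

test_that("efficiency curves decrease with threshold and nest correctly", {
  th <- c(0, 50, 100, 150, 200, 250, 300)
  eff <- efficiency_curves(th, 1e5, detector_geometry(), seed = 25)
  for (col in c("eff_prompt", "eff_pair", "eff_triple")) {
    expect_true(all(diff(eff[[col]]) <= 0))
  }
  # the triple curve is a subset of the pair curve at every threshold
  expect_true(all(eff$eff_triple <= eff$eff_pair))
  # prompt-threshold events are a subset of the prompt curve above 400 keV
  expect_true(all(eff$eff_triple <= eff$eff_prompt[1]))
  # at zero threshold the pair curve is the registration-only efficiency
  expect_gt(eff$eff_pair[1], eff$eff_pair[5])
})
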