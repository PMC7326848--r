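test_that("acceptance bounds follow the cylindrical-shell geometry", {
  sc <- scanner_spec(material("lyso"), 200)
  b <- acceptance_bounds(0, sc)
  expect_equal(b$theta_min, atan(40 / 100), tolerance = 1e-12)
  expect_equal(b$theta_max_pair, pi - atan(40 / 100), tolerance = 1e-12)
  expect_equal(b$theta_max_single, pi - atan(40 / 100), tolerance = 1e-12)

  # off-centre source: pair window symmetric, single window extends further back
  b50 <- acceptance_bounds(50, sc)
  expect_equal(b50$theta_min, atan(40 / 50))
  expect_equal(b50$theta_max_pair, pi - b50$theta_min)
  expect_equal(b50$theta_max_single, pi - atan(40 / 150))
  expect_gt(b50$theta_max_single, b50$theta_max_pair)

  # source at the scanner edge: pair acceptance collapses to zero measure
  bH <- acceptance_bounds(100, sc)
  expect_equal(bH$theta_min, pi / 2)
  expect_lte(bH$theta_max_pair - bH$theta_min, 0)

  # very long scanner: full-sphere limit
  blong <- acceptance_bounds(0, scanner_spec(material("lyso"), 200, inner_diameter = 1))
  expect_lt(blong$theta_min, 0.006)
})

test_that("acceptance bounds agree with explicit ray tracing", {
  sc <- scanner_spec(material("plastic"), 120)
  H <- 60; R <- 40
  set.seed(5)
  for (z in runif(20, 0, 59)) {
    b <- acceptance_bounds(z, sc)
    th <- runif(200, 0.01, pi - 0.01)
    crossing <- function(theta) z + R / tan(theta)
    single_ok <- abs(crossing(th)) <= H
    pair_ok <- single_ok & abs(crossing(pi - th)) <= H
    expect_equal(th >= b$theta_min & th <= b$theta_max_single, single_ok)
    expect_equal(th >= b$theta_min & th <= b$theta_max_pair, pair_ok)
  }
})

test_that("sensitivity quadrature matches the ray-tracing Monte Carlo oracle", {
  # the quadrature value relates to detection probability by one factor
  # 1/2 per isotropic angular bracket
  for (afov in c(60, 200)) {
    sc <- scanner_spec(material("plastic"), afov)
    q2 <- scanner_sensitivity(sc, mode = "two_gamma",
                              include_selection = FALSE)$value / 2
    mc <- mc_sensitivity_oracle(1e6, afov, material("plastic"),
                                mode = "two_gamma", seed = afov)
    expect_lt(abs(q2 - mc$estimate), 3 * mc$se)

    q3 <- scanner_sensitivity(sc, mode = "triple",
                              include_selection = FALSE)$value / 4
    mc3 <- mc_sensitivity_oracle(1e6, afov, material("plastic"),
                                 mode = "triple", seed = afov + 1)
    expect_lt(abs(q3 - mc3$estimate), 3 * mc3$se)
  }
})

test_that("sensitivity grows with AFOV and triple mode costs sensitivity", {
  afovs <- c(20, 60, 120, 200)
  cv <- sensitivity_curve(material("plastic"), afovs, mode = "triple")
  expect_true(all(diff(cv$value) > 0))
  expect_true(all(diff(cv$gain) > 0))

  for (a in c(50, 200)) {
    sc <- scanner_spec(material("lyso"), a)
    s2 <- scanner_sensitivity(sc, mode = "two_gamma")$value
    s3 <- scanner_sensitivity(sc, mode = "triple")$value
    expect_lt(s3, s2)
  }
})

test_that("gains are self-normalised and invariant to the overall prefactor", {
  # the reference configuration has gain 1 by construction
  cv <- sensitivity_curve(material("lyso"), 20, mode = "two_gamma")
  expect_equal(cv$gain, 1, tolerance = 1e-7)

  # the source-length prefactor cancels in every gain
  long <- phantom_model(length = 200)
  short <- phantom_model(length = 100)
  g1 <- sensitivity_curve(material("plastic"), c(80, 200), phantom = long,
                          mode = "triple",
                          reference = reference_sensitivity(long))$gain
  g2 <- sensitivity_curve(material("plastic"), c(80, 200), phantom = short,
                          mode = "triple",
                          reference = reference_sensitivity(short))$gain
  expect_equal(g1, g2, tolerance = 1e-7)
})

test_that("crossover solver recovers the self-normalisation point", {
  x <- crossover_afov(material("lyso"), mode = "two_gamma",
                      prompt_window = "full", bracket = c(12, 60))
  expect_equal(x, 20, tolerance = 0.1)
  expect_error(crossover_afov(material("lyso"), mode = "two_gamma",
                              bracket = c(30, 199)),
               "sign")
})

test_that("projected whole-body count arithmetic is exact", {
  pc <- projected_counts(370e6, 1200, 0.005, 0.30)
  expect_equal(pc$total, 370e6 * 1200 * 0.005 * 0.30)
  expect_equal(pc$per_cm3, pc$total / (pi * 100 * 200))

  expect_equal(projected_counts(0, 1200, 0.005, 0.3)$total, 0)
  expect_error(projected_counts(370e6, 1200, 0, 0.3))
})
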