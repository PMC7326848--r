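# Independent oracles used to validate the analytic and sampled models.
# These deliberately avoid the package's own integration / sampling code
# paths: geometry is checked by explicit ray tracing, distributions by
# direct numerical integration.

# Ray-tracing Monte Carlo estimator of the line-source sensitivity:
# sample axial positions uniformly along half the source, sample the
# pair axis (and optionally the prompt direction) isotropically, decide
# acceptance by tracing each photon to the detector shell, and weight
# accepted rays with the analytic interaction and phantom-survival
# probabilities. Returns the estimate of the detection probability and
# its standard error.
mc_sensitivity_oracle <- function(n, afov, mat, phantom = phantom_model(),
                                  mode = c("two_gamma", "triple"),
                                  radius = 40, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  H <- afov / 2
  z <- runif(n, 0, phantom$length / 2)

  # axial crossing of a ray from (0, 0, z) at polar angle theta with the
  # shell of given radius; accepted if |crossing| <= H
  hits_shell <- function(z, cost) {
    sint <- sqrt(1 - cost^2)
    ok <- sint > 0
    zc <- ifelse(ok, z + radius * cost / sint, Inf)
    ok & abs(zc) <= H
  }

  cost <- runif(n, -1, 1)
  acc_pair <- hits_shell(z, cost) & hits_shell(z, -cost)
  theta <- acos(cost)
  w <- ifelse(acc_pair,
              ((1 - exp(-mat$mu_511 * mat$thickness / sin(theta))) *
                 exp(-phantom$mu_511 * phantom$radius / sin(theta)))^2,
              0)
  if (mode == "triple") {
    cost_p <- runif(n, -1, 1)
    acc_p <- hits_shell(z, cost_p)
    theta_p <- acos(cost_p)
    wp <- ifelse(acc_p,
                 (1 - exp(-mat$mu_1160 * mat$thickness / sin(theta_p))) *
                   exp(-phantom$mu_1160 * phantom$radius / sin(theta_p)),
                 0)
    w <- w * wp
  }
  list(estimate = mean(w), se = sd(w) / sqrt(n))
}

# Numerical CDF of the Compton electron-energy spectrum, built directly
# from the Klein-Nishina angular cross-section on a cos(theta) grid
# (independent of the package's deposit-density formula).
kn_deposit_cdf_oracle <- function(energy_kev, m_e = 511) {
  k <- energy_kev / m_e
  cost <- seq(-1, 1, length.out = 20001)
  p <- 1 / (1 + k * (1 - cost))
  f <- p^2 * (p + 1 / p - (1 - cost^2))      # dsigma/dcos, up to a constant
  t_dep <- energy_kev * (1 - p)              # electron energy for each angle
  # cumulative integral over cos(theta); t_dep decreases with cost
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(cost)))
  cum <- cum / cum[length(cum)]
  # P(T <= t): integrate over angles with deposit <= t (large cost)
  ord <- order(t_dep)
  stats::approxfun(t_dep[ord], (1 - cum)[ord], yleft = 0, yright = 1)
}

# Expected interaction fraction for isotropic photons from the centre of
# the detector, from an explicit path-length formula (entry/exit of the
# shell clipped to the axial extent), averaged over cos(theta) by
# quadrature.
isotropic_interaction_oracle <- function(geometry, energy_kev) {
  mu <- if (energy_kev == 511) geometry$material$mu_511 else geometry$material$mu_1160
  H <- geometry$afov / 2
  R1 <- geometry$inner_radius
  R2 <- geometry$outer_radius
  f <- function(cost) {
    sint <- sqrt(pmax(1 - cost^2, 1e-12))
    t1 <- R1 / sint
    t2 <- R2 / sint
    tcap <- ifelse(abs(cost) > 0, H / abs(cost), Inf)  # leaves axial extent
    len <- pmax(0, pmin(t2, tcap) - pmin(t1, tcap))
    1 - exp(-mu * len)
  }
  stats::integrate(f, -1, 1)$value / 2
}

# Lazily computed simulation fixtures shared across test files (the
# propagation stage is the expensive part; selection and smearing are
# re-run per test as needed).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

nema_triples <- function() fixture("nema_triples", {
  simulate_triples(nema_sources(), 4e6, detector_geometry(),
                   detector_response(), seed = 101, chunk_size = 2e6)
})

source6_triples <- function() fixture("source6_triples", {
  simulate_triples(nema_sources()[6, ], 5e6, detector_geometry(),
                   detector_response(), seed = 202, chunk_size = 2.5e6)
})
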