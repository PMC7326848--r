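# a hand-built triple with hits on the x axis, for closed-form checks
synthetic_triple <- function(t1_off = 0, t2_off = 0) {
  cc <- ps_constants()$c_cm_per_ps
  data.frame(
    event_id = 1L, source_id = 1L, ox = 0, oy = 0, oz = 0,
    t0_ps = 0, lifetime_ps = 0, tau_ns = 2,
    a1_rx = -45, a1_ry = 0, a1_rz = 0, a1_rt = 45 / cc + t1_off,
    a2_rx = 45, a2_ry = 0, a2_rz = 0, a2_rt = 45 / cc + t2_off,
    p_rx = 0, p_ry = 44, p_rz = 0, p_rt = 44 / cc
  )
}

test_that("noiseless reconstruction is the identity to machine precision", {
  tr <- utils::head(nema_triples(), 1e4)
  sm <- smear_hits(tr, detector_response(crt_ps = 0, spatial_fwhm_cm = 0))
  rec <- reconstruct_events(sm)
  expect_lt(max(abs(rec$x - tr$ox), abs(rec$y - tr$oy), abs(rec$z - tr$oz)), 1e-9)
  expect_lt(max(abs(rec$lifetime_ps - tr$lifetime_ps)), 1e-6)
  expect_lt(max(abs(rec$emit_time_ps - tr$t0_ps)), 1e-6)
  expect_lt(max(abs(rec$annih_time_ps - (tr$t0_ps + tr$lifetime_ps))), 1e-6)
})

test_that("a timing perturbation shifts the TOF position by c dt / 2 along the LOR", {
  base <- reconstruct_events(synthetic_triple())
  expect_equal(base$x, 0, tolerance = 1e-12)

  # +30 ps on the second hit: c dt / 2 = 4.5 mm shift towards the earlier hit
  cc <- ps_constants()$c_cm_per_ps
  r30 <- reconstruct_events(synthetic_triple(t2_off = 30))
  expect_equal(abs(r30$x - base$x), cc * 30 / 2, tolerance = 1e-9)
  expect_equal(abs(r30$x - base$x), 0.45, tolerance = 0.002)
  expect_lt(r30$x, base$x)   # towards hit 1 (earlier)

  # +10 ps: 1.5 mm
  r10 <- reconstruct_events(synthetic_triple(t2_off = 10))
  expect_equal(abs(r10$x - base$x), 0.15, tolerance = 0.002)

  # degenerate LOR is refused
  bad <- synthetic_triple()
  bad$a2_rx <- bad$a1_rx
  expect_error(reconstruct_events(bad), "degenerate")
})

test_that("reconstructed lifetimes are unbiased under smearing", {
  tr <- nema_triples()
  for (crt in c(50, 500)) {
    rec <- simulate_records(tr, detector_response(crt_ps = crt), seed = crt)
    err <- rec$lifetime_ps - rec$lifetime_true_ps
    expect_lt(abs(mean(err)), 3 * stats::sd(err) / sqrt(length(err)))
  }
})

test_that("direct images conserve counts and localise noiseless sources", {
  tr <- utils::head(source6_triples(), 5e3)
  sm <- smear_hits(tr, detector_response(crt_ps = 0, spatial_fwhm_cm = 0))
  rec <- reconstruct_events(sm)
  img <- direct_image(rec, voxel_size = 0.5)
  expect_equal(sum(img$values) + img$metadata$n_dropped, nrow(rec))

  # noiseless point-like source: everything in the source voxel region
  peak <- which(img$values == max(img$values), arr.ind = TRUE)[1, ]
  pos <- c(voxel_centers(img, 1)[peak[1]], voxel_centers(img, 2)[peak[2]],
           voxel_centers(img, 3)[peak[3]])
  expect_true(all(abs(pos - c(20, 0, 75)) <= 0.5))
  expect_equal(sum(img$values > 0), length(which(img$values > 0)))

  # smeared image still conserves counts
  rec5 <- simulate_records(tr, detector_response(crt_ps = 500), seed = 3)
  img5 <- direct_image(rec5, voxel_size = 0.5)
  expect_equal(sum(img5$values) + img5$metadata$n_dropped, nrow(rec5))
})

test_that("the PSF estimator recovers the width of a known Gaussian blob", {
  vox <- 0.5
  xs <- seq(-10, 10, by = vox)
  sigma_true <- 1.2
  blob <- outer(outer(stats::dnorm(xs, 0, sigma_true),
                      stats::dnorm(xs, 0, sigma_true)),
                stats::dnorm(xs, 0, sigma_true))
  img <- volume_image(blob, origin = c(-10, -10, -10), voxel_size = rep(vox, 3))
  for (ax in c(1, 3)) {
    est <- estimate_psf(img, c(0, 0, 0), axis = ax)
    expect_equal(est$fwhm_mm, sigma_true * 2.3548 * 10, tolerance = 0.02)
  }
})

test_that("direct-image radial PSF grows with CRT; TOF-FBP stays near the detector blur", {
  tr <- source6_triples()
  bounds <- rbind(c(10, -8, 65), c(30, 8, 85))
  radial_direct <- c(); radial_fbp <- c()
  for (crt in c(50, 140, 500)) {
    rec <- simulate_records(tr, detector_response(crt_ps = crt), seed = crt + 2)
    img <- direct_image(rec, voxel_size = 0.5)
    radial_direct[as.character(crt)] <-
      estimate_psf(img, c(20, 0, 75), axis = 1)$fwhm_mm
    fb <- tof_fbp(rec, crt_ps = crt, bounds = bounds)
    # the filtered image peaks at the source
    peak <- which(fb$values == max(fb$values), arr.ind = TRUE)[1, ]
    pos <- c(voxel_centers(fb, 1)[peak[1]], voxel_centers(fb, 2)[peak[2]],
             voxel_centers(fb, 3)[peak[3]])
    expect_true(all(abs(pos - c(20, 0, 75)) <= 0.75))
    radial_fbp[as.character(crt)] <-
      estimate_psf(fb, c(20, 0, 75), axis = 1, window_cm = 4,
                   max_window_cm = 6)$fwhm_mm
  }
  # direct image degrades monotonically with CRT
  expect_true(all(diff(radial_direct) > 0))
  # TOF-FBP varies much less than the direct image over the same range
  expect_lt(diff(range(radial_fbp)) / max(radial_fbp), 0.25)
  expect_lt(max(radial_fbp), 8)
  # at poor timing the filtered image is far sharper than the direct one
  expect_lt(radial_fbp[["500"]], radial_direct[["500"]] / 3)
})
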