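#' Idealized multi-layer cylindrical detector geometry
#'
#' The total-body scanner is modelled as `n_layers` concentric cylindrical
#' annuli of plastic scintillator, contiguous in radius, spanning axial
#' positions -AFOV/2..AFOV/2. Defaults follow the total-body
#' plastic-scintillator design: inner radius 43 cm, AFOV 200 cm, four
#' 1.5-cm layers for a total radial plastic thickness of 6 cm. Strips are
#' not discretized (no inter-strip gaps); the strip cross section is kept
#' as metadata only.
#'
#' @param inner_radius Inner radius of the first layer, cm.
#' @param afov Axial field of view, cm.
#' @param n_layers Number of concentric layers.
#' @param layer_thickness Radial thickness of each layer, cm.
#' @param material Scintillator [material()] (attenuation coefficients;
#'   the material `thickness` field is ignored here in favour of the layer
#'   structure).
#' @param strip_cross_section Strip cross section (cm), metadata.
#' @return An object of class `ps_geometry` with derived fields
#'   `outer_radius` and `total_thickness`.
#' @export
detector_geometry <- function(inner_radius = 43, afov = 200, n_layers = 4,
                              layer_thickness = 1.5, material = NULL,
                              strip_cross_section = c(0.7, 1.9)) {
  stopifnot(inner_radius > 0, afov > 0, n_layers >= 1, layer_thickness > 0)
  if (is.null(material)) material <- default_scintillator()
  radii <- inner_radius + layer_thickness * (0:n_layers)
  structure(list(
    inner_radius = inner_radius,
    outer_radius = radii[n_layers + 1],
    afov = afov,
    n_layers = n_layers,
    layer_inner_radii = radii[1:n_layers],
    layer_thickness = layer_thickness,
    total_thickness = n_layers * layer_thickness,
    material = material,
    strip_cross_section = strip_cross_section
  ), class = "ps_geometry")
}

#' Detector response configuration
#'
#' Gathers the resolution and selection parameters of the idealized
#' scanner. `crt_ps` is the coincidence resolving time: the FWHM of the
#' time-difference distribution between two detectors, the standard PET
#' timing figure of merit. A single hit time is therefore smeared with a
#' Gaussian of standard deviation `crt / (2 sqrt(2 log 2)) / sqrt(2)`, so
#' that the difference of two independent hit times has FWHM = CRT.
#' Hit positions are smeared with `spatial_fwhm_cm` FWHM Gaussians in the
#' axial and tangential directions (the radial coordinate is kept at the
#' interaction radius, consistent with a strip readout resolving the
#' along-strip coordinate and the azimuthal strip position).
#'
#' The energy thresholds implement the image-forming selection: both
#' annihilation-photon deposits must exceed `threshold_annih_kev`
#' (suppresses the scatter fraction) and the prompt deposit must exceed
#' `threshold_prompt_kev`. Because 400 keV lies above the 511 keV Compton
#' edge (340.7 keV), the prompt tag is unambiguous.
#'
#' @param crt_ps Coincidence resolving time FWHM, ps (0 allowed: no time
#'   smearing, useful for noiseless identity tests).
#' @param spatial_fwhm_cm Position resolution FWHM, cm (default 0.5).
#' @param threshold_annih_kev Minimum deposit for 511 keV photons, keV.
#' @param threshold_prompt_kev Minimum deposit for the prompt gamma, keV.
#' @return An object of class `ps_response` with derived fields
#'   `sigma_t_ps` (single-hit time sigma) and `sigma_pos_cm`.
#' @export
detector_response <- function(crt_ps = 50, spatial_fwhm_cm = 0.5,
                              threshold_annih_kev = 200,
                              threshold_prompt_kev = 400) {
  stopifnot(crt_ps >= 0, spatial_fwhm_cm >= 0,
            threshold_annih_kev >= 0, threshold_prompt_kev >= 0)
  fwhm2sig <- 1 / (2 * sqrt(2 * log(2)))
  structure(list(
    crt_ps = crt_ps,
    spatial_fwhm_cm = spatial_fwhm_cm,
    threshold_annih_kev = threshold_annih_kev,
    threshold_prompt_kev = threshold_prompt_kev,
    sigma_t_ps = crt_ps * fwhm2sig / sqrt(2),
    sigma_pos_cm = spatial_fwhm_cm * fwhm2sig
  ), class = "ps_response")
}

#' Compton edge: maximum single-scatter energy transfer
#'
#' @param energy_kev Incident photon energy, keV.
#' @return Maximum electron energy `E * (2E/mc^2) / (1 + 2E/mc^2)`, keV.
#' @export
#' @examples
#' compton_edge(511)    # 340.67 keV
#' compton_edge(1160)   # ~949.9 keV
compton_edge <- function(energy_kev) {
  k <- energy_kev / ps_constants()$m_e_c2_kev
  energy_kev * 2 * k / (1 + 2 * k)
}

#' Klein-Nishina electron-energy spectrum (unnormalised density)
#'
#' Differential probability (up to a constant) for a Compton scatter of an
#' `energy_kev` photon to transfer energy `t_kev` to the electron,
#' obtained from the Klein-Nishina angular cross-section via the Compton
#' kinematics t(theta). Used as the quadrature oracle against which the
#' rejection sampler is tested, and for plotting expected deposit spectra.
#'
#' @param t_kev Electron (deposit) energies, keV.
#' @param energy_kev Incident photon energy, keV.
#' @return Unnormalised density values; zero outside (0, Compton edge).
#' @export
klein_nishina_deposit_density <- function(t_kev, energy_kev) {
  me <- ps_constants()$m_e_c2_kev
  k <- energy_kev / me
  edge <- compton_edge(energy_kev)
  ok <- t_kev >= 0 & t_kev <= edge
  t <- t_kev[ok]
  p <- 1 - t / energy_kev            # E'/E
  cost <- 1 - (1 / p - 1) / k        # from t = E (1 - p), p = 1/(1 + k(1-cos))
  sin2 <- 1 - cost^2
  # dsigma/dt = (dsigma/dcos) * |dcos/dt|; dcos/dt = -1/(k E p^2)
  dcs <- p^2 * (p + 1 / p - sin2)
  out <- numeric(length(t_kev))
  out[ok] <- dcs / (k * energy_kev * p^2)
  out
}

#' Sample Compton energy deposits from the Klein-Nishina cross-section
#'
#' Rejection sampling of the scattering angle: cos(theta) is proposed
#' uniformly on \[-1, 1\] and accepted with probability proportional to the
#' Klein-Nishina differential cross-section
#' `P^2 (P + 1/P - sin^2 theta)` with `P = 1 / (1 + k (1 - cos theta))`,
#' which is bounded by its forward-scattering value 2. The deposit is the
#' electron energy `E (1 - P)`.
#'
#' @param n Number of deposits to sample.
#' @param energy_kev Incident photon energy, keV.
#' @return Vector of `n` deposits in (0, [compton_edge()]\].
#' @export
sample_compton_deposit <- function(n, energy_kev) {
  stopifnot(energy_kev > 0)
  k <- energy_kev / ps_constants()$m_e_c2_kev
  out <- numeric(n)
  need <- n
  filled <- 0L
  while (need > 0) {
    m <- max(need * 2L, 256L)   # acceptance is ~40-50%; oversample proposals
    cost <- stats::runif(m, -1, 1)
    p <- 1 / (1 + k * (1 - cost))
    f <- p^2 * (p + 1 / p - (1 - cost^2))
    keep <- stats::runif(m) * 2 <= f
    acc <- which(keep)
    take <- min(length(acc), need)
    if (take > 0) {
      out[filled + seq_len(take)] <- energy_kev * (1 - p[acc[seq_len(take)]])
      filled <- filled + take
      need <- need - take
    }
  }
  out
}

#' Propagate photons from their origin to a Compton interaction
#'
#' Vectorized ray tracing through the cylindrical scintillator shell
#' (contiguous layers are traced as one annulus from the inner to the
#' outer radius). For each photon the entry and exit points of the ray in
#' the annulus are intersected with the axial extent of the scanner; an
#' interaction point is then sampled along the in-plastic path with the
#' exponential free-path law at the energy's attenuation coefficient
#' (survival `exp(-mu * path)`), and a Compton energy deposit is drawn
#' from the Klein-Nishina spectrum. Photons that never reach the plastic
#' inside the axial acceptance, or traverse it without interacting, are
#' misses. One interaction per photon is simulated (no secondary
#' tracking): the deposit of the first Compton scatter is what the
#' selection thresholds act on.
#'
#' @param origin `n x 3` matrix of emission points, cm (inside the bore).
#' @param direction `n x 3` matrix of unit direction vectors.
#' @param energy_kev Photon energy, 511 or 1160.
#' @param geometry A [detector_geometry()].
#' @param t_emit_ps Emission times, ps (default 0); hit times are
#'   `t_emit + path_to_interaction / c`.
#' @return A data.frame with `detected` (logical) and, for detected rows,
#'   interaction position `hx, hy, hz` (cm), `time_ps`, and `edep_kev`.
#' @export
propagate_photons <- function(origin, direction, energy_kev, geometry,
                              t_emit_ps = 0) {
  stopifnot(inherits(geometry, "ps_geometry"))
  origin <- as_matrix3(origin)
  direction <- as_matrix3(direction)
  n <- nrow(origin)
  if (length(t_emit_ps) == 1) t_emit_ps <- rep(t_emit_ps, n)
  rho2 <- origin[, 1]^2 + origin[, 2]^2
  if (any(rho2 >= geometry$inner_radius^2))
    stop("photon origin outside the detector bore")
  mu <- mu_for_energy(geometry$material, energy_kev)
  H <- geometry$afov / 2
  R1 <- geometry$inner_radius
  R2 <- geometry$outer_radius

  # radial quadratic |o_xy + t d_xy|^2 = R^2
  a <- direction[, 1]^2 + direction[, 2]^2
  b <- origin[, 1] * direction[, 1] + origin[, 2] * direction[, 2]
  # photons (anti)parallel to the axis never reach the shell
  radial <- a > 0
  t1 <- rep(Inf, n); t2 <- rep(Inf, n)
  d1 <- b[radial]^2 + a[radial] * (R1^2 - rho2[radial])
  d2 <- b[radial]^2 + a[radial] * (R2^2 - rho2[radial])
  t1[radial] <- (-b[radial] + sqrt(pmax(d1, 0))) / a[radial]
  t2[radial] <- (-b[radial] + sqrt(d2)) / a[radial]

  # axial slab |oz + t dz| <= H
  dz <- direction[, 3]
  oz <- origin[, 3]
  ta <- ifelse(dz > 0, (-H - oz) / dz, -Inf)
  tb <- ifelse(dz > 0, (H - oz) / dz, Inf)
  neg <- dz < 0
  ta[neg] <- (H - oz[neg]) / dz[neg]
  tb[neg] <- (-H - oz[neg]) / dz[neg]

  lo <- pmax(t1, ta)
  hi <- pmin(t2, tb)
  len <- pmax(0, hi - lo)

  u <- stats::runif(n)
  p_int <- 1 - exp(-mu * len)
  detected <- radial & len > 0 & u < p_int
  s <- rep(NA_real_, n)
  s[detected] <- -log(1 - u[detected]) / mu   # u < p_int => s < len
  tint <- lo + s

  hx <- origin[, 1] + tint * direction[, 1]
  hy <- origin[, 2] + tint * direction[, 2]
  hz <- origin[, 3] + tint * direction[, 3]
  edep <- rep(NA_real_, n)
  edep[detected] <- sample_compton_deposit(sum(detected), energy_kev)

  data.frame(
    detected = detected,
    hx = ifelse(detected, hx, NA_real_),
    hy = ifelse(detected, hy, NA_real_),
    hz = ifelse(detected, hz, NA_real_),
    time_ps = ifelse(detected, t_emit_ps + tint / ps_constants()$c_cm_per_ps,
                     NA_real_),
    edep_kev = edep
  )
}

as_matrix3 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("expected an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

#' Detector response to generated events: hits for all three photons
#'
#' Propagates, for every generated event, the two back-to-back 511 keV
#' annihilation photons (emitted at the annihilation time, i.e. the true
#' ortho-positronium lifetime after the event clock zero) and the 1160 keV
#' prompt gamma, and keeps the events in which all three photons
#' interacted in the scintillator. Energy deposits are attached per hit;
#' no selection thresholds are applied here (see [select_triples()]).
#'
#' @param events Event frame from [generate_events()].
#' @param geometry A [detector_geometry()].
#' @param keep_partial Keep events in which only some photons interacted
#'   (default FALSE: only full candidate triples are returned). With
#'   `TRUE`, logical columns `a1_det`, `a2_det`, `p_det` are included and
#'   missing hits carry NA coordinates; used for per-photon efficiency
#'   curves.
#' @return A data.frame of candidate triples (one row per fully detected
#'   event) with true hit positions/times/deposits for photons `a1`, `a2`
#'   (annihilation) and `p` (prompt), plus the event bookkeeping columns.
#'   The counts of events lost at each stage are attached as attribute
#'   `counters`.
#' @export
detect_events <- function(events, geometry, keep_partial = FALSE) {
  n <- nrow(events)
  org <- cbind(events$ox, events$oy, events$oz)
  adir <- cbind(events$adx, events$ady, events$adz)
  pdir <- cbind(events$pdx, events$pdy, events$pdz)
  t_annih <- events$t0_ps + events$lifetime_ps

  h1 <- propagate_photons(org, adir, 511, geometry, t_annih)
  h2 <- propagate_photons(org, -adir, 511, geometry, t_annih)
  hp <- propagate_photons(org, pdir, 1160, geometry, events$t0_ps)

  keep <- if (keep_partial) h1$detected | h2$detected | hp$detected else
    h1$detected & h2$detected & hp$detected
  counters <- c(
    generated = n,
    a1_detected = sum(h1$detected),
    a2_detected = sum(h2$detected),
    pair_detected = sum(h1$detected & h2$detected),
    prompt_detected = sum(hp$detected),
    all_detected = sum(keep)
  )
  out <- data.frame(
    event_id = events$event_id[keep],
    source_id = events$source_id[keep],
    ox = events$ox[keep], oy = events$oy[keep], oz = events$oz[keep],
    t0_ps = events$t0_ps[keep],
    lifetime_ps = events$lifetime_ps[keep],
    tau_ns = events$tau_ns[keep],
    a1_x = h1$hx[keep], a1_y = h1$hy[keep], a1_z = h1$hz[keep],
    a1_t = h1$time_ps[keep], a1_edep = h1$edep_kev[keep],
    a2_x = h2$hx[keep], a2_y = h2$hy[keep], a2_z = h2$hz[keep],
    a2_t = h2$time_ps[keep], a2_edep = h2$edep_kev[keep],
    p_x = hp$hx[keep], p_y = hp$hy[keep], p_z = hp$hz[keep],
    p_t = hp$time_ps[keep], p_edep = hp$edep_kev[keep]
  )
  if (keep_partial) {
    out$a1_det <- h1$detected[keep]
    out$a2_det <- h2$detected[keep]
    out$p_det <- hp$detected[keep]
  }
  attr(out, "counters") <- counters
  out
}

#' Apply position and time smearing to triple-coincidence hits
#'
#' Adds registered (`*_rx, *_ry, *_rz, *_rt`) coordinates for each of the
#' three hits: positions are smeared with independent Gaussians of
#' `spatial_fwhm_cm` FWHM in the axial (z) and tangential (azimuthal)
#' directions, keeping the radial coordinate at the true interaction
#' radius; times are smeared with the single-hit sigma derived from the
#' CRT (see [detector_response()]). With `crt_ps = 0` and
#' `spatial_fwhm_cm = 0` the registered values equal the true ones.
#'
#' @param triples Frame from [detect_events()].
#' @param response A [detector_response()].
#' @param seed Optional RNG seed.
#' @return The input frame with registered-coordinate columns appended.
#' @export
smear_hits <- function(triples, response, seed = NULL) {
  stopifnot(inherits(response, "ps_response"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(triples)
  sp <- response$sigma_pos_cm
  st <- response$sigma_t_ps
  for (tag in c("a1", "a2", "p")) {
    x <- triples[[paste0(tag, "_x")]]
    y <- triples[[paste0(tag, "_y")]]
    z <- triples[[paste0(tag, "_z")]]
    rho <- sqrt(x^2 + y^2)
    # tangential smear as an azimuthal rotation by dtan/rho: arc length
    # Gaussian, interaction radius exactly preserved
    dtan <- if (sp > 0) stats::rnorm(n, 0, sp) else numeric(n)
    dax <- if (sp > 0) stats::rnorm(n, 0, sp) else numeric(n)
    dt <- if (st > 0) stats::rnorm(n, 0, st) else numeric(n)
    ang <- dtan / rho
    triples[[paste0(tag, "_rx")]] <- x * cos(ang) - y * sin(ang)
    triples[[paste0(tag, "_ry")]] <- y * cos(ang) + x * sin(ang)
    triples[[paste0(tag, "_rz")]] <- z + dax
    triples[[paste0(tag, "_rt")]] <- triples[[paste0(tag, "_t")]] + dt
  }
  triples
}

#' Select image-forming triple coincidences by energy deposition
#'
#' Keeps events in which both annihilation deposits exceed the 511 keV
#' threshold and the prompt deposit exceeds the prompt threshold. Because
#' the prompt threshold (400 keV by default) is above the 511 keV Compton
#' edge, annihilation photons can never satisfy the prompt condition, so
#' the photon tags are unambiguous.
#'
#' @param triples Frame from [detect_events()] (smeared or not; selection
#'   acts on the true deposits since no energy resolution is modelled).
#' @param response A [detector_response()] carrying the thresholds.
#' @return The selected subset, with per-cut rejection counters in
#'   attribute `counters` (merged with any upstream counters).
#' @export
select_triples <- function(triples, response) {
  stopifnot(inherits(response, "ps_response"))
  pass_a <- triples$a1_edep > response$threshold_annih_kev &
    triples$a2_edep > response$threshold_annih_kev
  pass_p <- triples$p_edep > response$threshold_prompt_kev
  keep <- pass_a & pass_p
  counters <- c(attr(triples, "counters"),
                candidates = nrow(triples),
                fail_annih_threshold = sum(!pass_a),
                fail_prompt_threshold = sum(!pass_p),
                selected = sum(keep))
  out <- triples[keep, , drop = FALSE]
  attr(out, "counters") <- counters
  out
}

#' Registration efficiency as a function of the energy threshold
#'
#' Simulates `n_events` decays from the given source and tabulates, on a
#' grid of thresholds, the fraction of generated events in which (a) the
#' prompt gamma is registered above threshold, (b) both annihilation
#' photons are registered above threshold, and (c) both conditions hold
#' simultaneously with the prompt deposit additionally above
#' `prompt_fixed_kev` (the triple-coincidence image-forming selection).
#' All three curves share one simulated sample (common random numbers), so
#' they decrease monotonically in the threshold by construction.
#'
#' @param thresholds Ascending deposit thresholds, keV.
#' @param n_events Number of generated decays.
#' @param geometry A [detector_geometry()].
#' @param sources Source specification (default 200-cm [line_source()]).
#' @param prompt_fixed_kev Fixed prompt threshold for the triple curve,
#'   keV (default 400).
#' @param seed Optional RNG seed.
#' @return A data.frame with `threshold_kev`, `eff_prompt`, `eff_pair`,
#'   `eff_triple`.
#' @export
efficiency_curves <- function(thresholds, n_events, geometry,
                              sources = line_source(),
                              prompt_fixed_kev = 400, seed = NULL) {
  stopifnot(!is.unsorted(thresholds))
  ev <- generate_events(sources, n_events, seed = seed)
  hits <- detect_events(ev, geometry, keep_partial = TRUE)
  n <- nrow(ev)
  pair_det <- hits$a1_det & hits$a2_det
  res <- vapply(thresholds, function(th) {
    pair <- pair_det & hits$a1_edep > th & hits$a2_edep > th
    prompt <- hits$p_det & hits$p_edep > th
    triple <- pair & hits$p_det & hits$p_edep > prompt_fixed_kev
    c(sum(prompt, na.rm = TRUE), sum(pair, na.rm = TRUE),
      sum(triple, na.rm = TRUE)) / n
  }, numeric(3))
  data.frame(threshold_kev = thresholds,
             eff_prompt = res[1, ], eff_pair = res[2, ],
             eff_triple = res[3, ])
}

default_scintillator <- function() material("plastic")
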