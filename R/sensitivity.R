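#' Cylindrical scanner specification for the analytic sensitivity model
#'
#' @param material A [material()] object (scintillator).
#' @param afov Axial field of view in cm (10--200 supported).
#' @param inner_diameter Bore diameter in cm (default 80, so shell radius
#'   R = 40 cm).
#' @return An object of class `ps_scanner`.
#' @export
scanner_spec <- function(material, afov, inner_diameter = 80) {
  stopifnot(inherits(material, "ps_material"), afov >= 10, afov <= 200,
            inner_diameter > 0)
  structure(list(material = material, afov = afov,
                 radius = inner_diameter / 2,
                 inner_diameter = inner_diameter),
            class = "ps_scanner")
}

#' Polar-angle acceptance bounds for a source on the scanner axis
#'
#' For a source at axial position `z` (0 <= z <= AFOV/2) inside a
#' cylindrical detector shell of radius R spanning axial positions
#' -AFOV/2..AFOV/2, a photon emitted at polar angle `theta` crosses the
#' shell at axial coordinate `z + R / tan(theta)`. Demanding the crossing
#' to fall inside the shell gives the single-photon window
#' `[atan(R / (H - z)), pi - atan(R / (H + z))]` with H = AFOV/2. For a
#' back-to-back photon pair both `theta` and `pi - theta` must be accepted,
#' which tightens the window to the symmetric
#' `[atan(R / (H - z)), pi - atan(R / (H - z))]`.
#'
#' For `z >= H` (source outside the scanner) the pair window collapses
#' (lower bound pi/2, zero measure), encoded as `theta_min = pi/2`.
#'
#' @param z Axial source position(s), cm.
#' @param scanner A [scanner_spec()].
#' @return A list with vectors `theta_min`, `theta_max_pair`,
#'   `theta_max_single` (radians).
#' @export
#' @examples
#' b <- acceptance_bounds(0, scanner_spec(material("lyso"), 200))
#' b$theta_min   # atan(40/100)
acceptance_bounds <- function(z, scanner) {
  stopifnot(inherits(scanner, "ps_scanner"), all(z >= 0))
  H <- scanner$afov / 2
  R <- scanner$radius
  tmin <- ifelse(z < H, atan(R / (H - z)), pi / 2)
  list(theta_min = tmin,
       theta_max_pair = pi - tmin,
       theta_max_single = pi - atan(R / (H + z)))
}

#' Sensitivity of a cylindrical scanner for 2g or 2g + prompt imaging
#'
#' Evaluates, by adaptive quadrature, the sensitivity integral
#' \deqn{S = \int_0^{AFOV/2} dz \Big[\int (\epsilon_a Att_a)^2 \sin\theta\,
#' d\theta\Big]\Big[\int \epsilon_p Att_p \sin\theta\, d\theta\Big]}
#' for a uniform line source on the axis: the first bracket is the
#' probability (up to a constant) that both back-to-back 511 keV photons
#' are detected, the second -- present only in `"triple"` mode -- that the
#' independently and isotropically emitted 1160 keV prompt gamma is
#' detected. Detection efficiencies are `1 - exp(-mu d / sin(theta))` and
#' phantom attenuation `exp(-mu_water R / sin(theta))` (see
#' [detection_efficiency()], [phantom_attenuation()]).
#'
#' The value is the z-average of the bracketed integrals over half the
#' source length (arbitrary but internally consistent units; gains are the
#' validated quantities). For isotropic emission the detection
#' probabilities carry an extra factor 1/2 per angular bracket:
#' `P_pair = value / 2` in `"two_gamma"` mode and `P_triple = value / 4`
#' in `"triple"` mode (both without selection efficiencies applied to
#' undetected channels). Published gains follow the plain integral-ratio
#' convention, i.e. no per-bracket 1/2, which matters when comparing a
#' triple-mode sensitivity against a two-gamma reference.
#'
#' With `include_selection = TRUE` (default) the image-forming selection
#' efficiencies are applied: `eps_sel_a^2` for the pair and additionally
#' `eps_sel_p` in triple mode.
#'
#' `prompt_window` chooses the polar window of the prompt integral:
#' `"full"` (default) uses the full single-photon acceptance
#' `[theta_min, theta_max_single]`; `"pair"` restricts the prompt to the
#' same symmetric window as the pair. The two conventions and which
#' published quantity each reproduces are discussed in the methods
#' vignette.
#'
#' @param scanner A [scanner_spec()].
#' @param phantom A [phantom_model()] (default whole-body water cylinder).
#' @param mode `"triple"` (2g + prompt) or `"two_gamma"`.
#' @param include_selection Apply selection efficiencies (default TRUE).
#' @param prompt_window `"full"` or `"pair"`; see Details.
#' @param rel_tol Relative quadrature tolerance (default 1e-8).
#' @return An object of class `ps_sensitivity`: list with `value`, `afov`,
#'   `mode`, and the call parameters.
#' @export
#' @examples
#' s <- scanner_sensitivity(scanner_spec(material("plastic"), 200), mode = "triple")
#' s$value
scanner_sensitivity <- function(scanner, phantom = phantom_model(),
                                mode = c("triple", "two_gamma"),
                                include_selection = TRUE,
                                prompt_window = c("full", "pair"),
                                rel_tol = 1e-8) {
  mode <- match.arg(mode)
  prompt_window <- match.arg(prompt_window)
  stopifnot(inherits(scanner, "ps_scanner"), inherits(phantom, "ps_phantom"))
  if (scanner$inner_diameter <= 2 * phantom$radius)
    stop("scanner bore must be wider than the phantom")
  m <- scanner$material
  H <- scanner$afov / 2

  inner_pair <- function(z) {
    b <- acceptance_bounds(z, scanner)
    if (b$theta_min >= b$theta_max_pair) return(0)
    stats::integrate(function(th) {
      (detection_efficiency(th, m, 511) *
         phantom_attenuation(th, phantom, 511))^2 * sin(th)
    }, b$theta_min, b$theta_max_pair, rel.tol = rel_tol)$value
  }
  inner_prompt <- function(z) {
    b <- acceptance_bounds(z, scanner)
    tmax <- if (prompt_window == "full") b$theta_max_single else b$theta_max_pair
    if (b$theta_min >= tmax) return(0)
    stats::integrate(function(th) {
      detection_efficiency(th, m, 1160) *
        phantom_attenuation(th, phantom, 1160) * sin(th)
    }, b$theta_min, tmax, rel.tol = rel_tol)$value
  }
  integrand <- if (mode == "triple") {
    function(z) vapply(z, function(zi) inner_pair(zi) * inner_prompt(zi), 0)
  } else {
    function(z) vapply(z, inner_pair, 0)
  }
  val <- stats::integrate(integrand, 0, H, rel.tol = rel_tol,
                          subdivisions = 400L)$value / (phantom$length / 2)
  if (include_selection) {
    val <- val * m$eps_sel_a^2
    if (mode == "triple") val <- val * m$eps_sel_p
  }
  structure(list(value = val, afov = scanner$afov, mode = mode,
                 material = m$name, include_selection = include_selection,
                 prompt_window = prompt_window),
            class = "ps_sensitivity")
}

#' Reference sensitivity: standard 2-gamma imaging, LYSO, AFOV = 20 cm
#'
#' All gains in this package are quoted relative to this configuration,
#' the sensitivity of a current-generation clinical LYSO PET scanner.
#' @inheritParams scanner_sensitivity
#' @return Reference sensitivity value (numeric scalar).
#' @export
reference_sensitivity <- function(phantom = phantom_model(),
                                  include_selection = TRUE, rel_tol = 1e-8) {
  scanner_sensitivity(scanner_spec(material("lyso"), 20), phantom,
                      mode = "two_gamma",
                      include_selection = include_selection,
                      rel_tol = rel_tol)$value
}

#' Sensitivity gain curve as a function of the axial field of view
#'
#' @param material A [material()] object.
#' @param afovs Vector of AFOV values, cm.
#' @inheritParams scanner_sensitivity
#' @param reference Reference sensitivity; computed with
#'   [reference_sensitivity()] when NULL.
#' @return A data.frame with columns `afov_cm`, `value`, `gain`.
#' @export
#' @examples
#' sensitivity_curve(material("lyso"), c(20, 100, 200), mode = "triple")
sensitivity_curve <- function(material, afovs, phantom = phantom_model(),
                              mode = c("triple", "two_gamma"),
                              include_selection = TRUE,
                              prompt_window = c("full", "pair"),
                              rel_tol = 1e-8, reference = NULL) {
  mode <- match.arg(mode)
  prompt_window <- match.arg(prompt_window)
  if (is.null(reference))
    reference <- reference_sensitivity(phantom, include_selection, rel_tol)
  vals <- vapply(afovs, function(a) {
    scanner_sensitivity(scanner_spec(material, a), phantom, mode,
                        include_selection, prompt_window, rel_tol)$value
  }, 0)
  data.frame(afov_cm = afovs, value = vals, gain = vals / reference)
}

#' AFOV at which a gain curve crosses unity
#'
#' Finds, by bisection on a monotone bracket, the axial field of view at
#' which the sensitivity of the given scanner/mode equals the
#' [reference_sensitivity()] (standard LYSO 2-gamma imaging at
#' AFOV = 20 cm), i.e. where long-axial-coverage triple-coincidence
#' positronium imaging becomes as sensitive as current metabolic PET.
#'
#' The default `prompt_window = "pair"` convention for this quantity is
#' deliberate and discussed in the methods vignette.
#'
#' @inheritParams sensitivity_curve
#' @param bracket AFOV search interval, cm.
#' @param tol Absolute root tolerance in cm (default 0.1).
#' @return Crossover AFOV in cm.
#' @export
#' @examples
#' \donttest{crossover_afov(material("lyso"))}
crossover_afov <- function(material, phantom = phantom_model(),
                           mode = "triple", include_selection = TRUE,
                           prompt_window = c("pair", "full"),
                           bracket = c(21, 199), tol = 0.1, rel_tol = 1e-7) {
  prompt_window <- match.arg(prompt_window)
  reference <- reference_sensitivity(phantom, include_selection, rel_tol)
  g <- function(a) {
    scanner_sensitivity(scanner_spec(material, a), phantom, mode,
                        include_selection, prompt_window, rel_tol)$value /
      reference - 1
  }
  lo <- g(bracket[1]); hi <- g(bracket[2])
  if (lo * hi > 0)
    stop("gain - 1 does not change sign on the bracket [",
         bracket[1], ", ", bracket[2], "] (gain: ", signif(lo + 1, 4), " to ",
         signif(hi + 1, 4), ")")
  stats::uniroot(g, bracket, tol = tol)$root
}

#' Projected triple-coincidence event yields for a whole-body scan
#'
#' Simple count arithmetic for an administered activity imaged over a scan
#' of given duration: `total = activity * time * efficiency * ops_fraction`
#' and, spreading the events uniformly over the cylindrical phantom volume,
#' `per_cm3 = total / (pi R^2 L)`.
#'
#' @param activity_bq Administered activity, Bq (370e6 Bq = 10 mCi is the
#'   standard whole-body protocol).
#' @param scan_time_s Scan duration, s (default 1200 s = 20 min).
#' @param efficiency Total detection-plus-selection efficiency for triple
#'   coincidences (fraction; about 0.005 for the plastic total-body
#'   scanner).
#' @param ops_fraction Fraction of positron annihilations proceeding via
#'   ortho-positronium formation (default 0.30).
#' @param phantom A [phantom_model()] defining the reference volume.
#' @return A list with `total` and `per_cm3`.
#' @export
#' @examples
#' projected_counts(370e6, 1200, 0.005, 0.30)
projected_counts <- function(activity_bq, scan_time_s = 1200,
                             efficiency = 0.005, ops_fraction = 0.30,
                             phantom = phantom_model()) {
  stopifnot(activity_bq >= 0, scan_time_s > 0,
            efficiency > 0, efficiency <= 1,
            ops_fraction > 0, ops_fraction <= 1)
  total <- activity_bq * scan_time_s * efficiency * ops_fraction
  volume <- pi * phantom$radius^2 * phantom$length
  list(total = total, per_cm3 = total / volume)
}

#' @export
print.ps_sensitivity <- function(x, ...) {
  cat(sprintf("<ps_sensitivity> %s, %s mode, AFOV = %g cm: S = %.4g%s\n",
              x$material, x$mode, x$afov, x$value,
              if (x$include_selection) " (incl. selection)" else ""))
  invisible(x)
}
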