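#' Physical constants used throughout the package
#'
#' Internal unit conventions are fixed globally: lengths in cm, times in ps,
#' energies in keV, angles in radians. Mean lifetimes are commonly quoted in
#' ns at the user interface and converted once at the boundary (1 ns =
#' 1000 ps).
#'
#' @return A list with elements:
#' \describe{
#'   \item{c_cm_per_ps}{speed of light, 0.0299792458 cm/ps}
#'   \item{tau_vacuum_ns}{ortho-positronium mean lifetime in vacuum, 142 ns}
#'   \item{m_e_c2_kev}{electron rest energy, 511 keV}
#'   \item{tau_pps_vacuum_ps}{para-positronium vacuum lifetime, 125 ps
#'     (informational; para-positronium is not simulated)}
#' }
#' @export
#' @examples
#' ps_constants()$c_cm_per_ps
ps_constants <- function() {
  list(
    c_cm_per_ps = 0.0299792458,
    tau_vacuum_ns = 142,
    m_e_c2_kev = 511,
    tau_pps_vacuum_ps = 125
  )
}

#' Scintillator and absorber material presets
#'
#' A `ps_material` bundles the linear attenuation coefficients at the two
#' photon energies relevant for 2g + prompt positronium imaging with a
#' Sc-44-labelled tracer (511 keV annihilation photons, 1160 keV prompt
#' gamma), the radial scintillator thickness, and the image-forming
#' selection efficiencies. Presets:
#' \describe{
#'   \item{"lyso"}{LYSO crystal, d = 1.81 cm, mu = 0.833 / 0.413 1/cm.
#'     The 511 keV selection efficiency 0.34 is the photofraction; the
#'     prompt selection efficiency 0.66 is the fraction of the Compton
#'     deposit spectrum above the 511 keV deposits.}
#'   \item{"plastic"}{plastic scintillator, d = 6 cm total, mu = 0.098 /
#'     0.068 1/cm, Compton-only detection with selection efficiencies
#'     0.44 (511 keV) and 0.66 (prompt).}
#'   \item{"water"}{phantom medium, mu = 0.096 / 0.066 1/cm; selection
#'     efficiencies are not meaningful and set to NA.}
#' }
#' Coefficients are fixed published values (NIST-derived); every field can
#' be overridden via `...` for what-if studies.
#'
#' @param name Preset name, one of `"lyso"`, `"plastic"`, `"water"`.
#' @param ... Named field overrides (`mu_511`, `mu_1160`, `thickness`,
#'   `eps_sel_a`, `eps_sel_p`).
#' @return An object of class `ps_material`.
#' @export
#' @examples
#' material("lyso")
#' material("plastic", thickness = 3)
material <- function(name = c("lyso", "plastic", "water"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    lyso    = list(name = "lyso", mu_511 = 0.833, mu_1160 = 0.413,
                   thickness = 1.81, eps_sel_a = 0.34, eps_sel_p = 0.66),
    plastic = list(name = "plastic", mu_511 = 0.098, mu_1160 = 0.068,
                   thickness = 6, eps_sel_a = 0.44, eps_sel_p = 0.66),
    water   = list(name = "water", mu_511 = 0.096, mu_1160 = 0.066,
                   thickness = 1, eps_sel_a = NA_real_, eps_sel_p = NA_real_)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(preset))
  if (length(bad)) stop("unknown material field(s): ", paste(bad, collapse = ", "))
  preset[names(over)] <- over
  validate_material(structure(preset, class = "ps_material"))
}

validate_material <- function(m) {
  stopifnot(m$mu_511 > 0, m$mu_1160 > 0, m$thickness > 0)
  for (f in c("eps_sel_a", "eps_sel_p")) {
    v <- m[[f]]
    if (!is.na(v) && (v < 0 || v > 1)) stop(f, " must lie in [0, 1]")
  }
  m
}

#' @export
print.ps_material <- function(x, ...) {
  cat(sprintf("<ps_material '%s'>  mu(511) = %.3f /cm, mu(1160) = %.3f /cm, d = %.2f cm\n",
              x$name, x$mu_511, x$mu_1160, x$thickness))
  cat(sprintf("  selection efficiencies: eps_sel_a = %s, eps_sel_p = %s\n",
              format(x$eps_sel_a), format(x$eps_sel_p)))
  invisible(x)
}

#' Cylindrical water phantom approximating the patient
#'
#' The body is approximated as a water cylinder of radius `radius` on the
#' scanner axis; photons emitted at polar angle `theta` traverse a water
#' path `radius / sin(theta)` before reaching the detector. The activity is
#' distributed along a `length`-cm line source on the axis.
#'
#' @param radius Phantom radius in cm (default 10).
#' @param mu_511,mu_1160 Linear attenuation coefficients of water at
#'   511 and 1160 keV in 1/cm (defaults 0.096 and 0.066).
#' @param length Source/phantom length in cm (default 200, a whole-body
#'   line source).
#' @return An object of class `ps_phantom`.
#' @export
phantom_model <- function(radius = 10, mu_511 = 0.096, mu_1160 = 0.066,
                          length = 200) {
  stopifnot(radius > 0, length > 0, mu_511 >= 0, mu_1160 >= 0)
  if (mu_511 > 0 && mu_1160 > 0 && mu_511 <= mu_1160)
    stop("water attenuation must decrease with energy: mu_511 > mu_1160")
  structure(list(radius = radius, mu_511 = mu_511, mu_1160 = mu_1160,
                 length = length), class = "ps_phantom")
}

mu_for_energy <- function(obj, energy_kev) {
  if (!energy_kev %in% c(511, 1160))
    stop("energy_kev must be 511 or 1160")
  if (energy_kev == 511) obj$mu_511 else obj$mu_1160
}

#' Ortho-positronium 2g / 3g branching in tissue
#'
#' In vacuum ortho-positronium decays to three photons with mean lifetime
#' `tau_vacuum` = 142 ns. In tissue, pick-off and conversion open a fast
#' 2-photon channel that shortens the observed mean lifetime to
#' `tau_tissue`; the surviving 3-photon fraction is
#' `f_3g = tau_tissue / tau_vacuum`, so 2-photon annihilations outnumber
#' 3-photon ones by `(1 - f_3g) / f_3g`. At tau_tissue = 2 ns the
#' 2g channel is 70 times more frequent.
#'
#' @param tau_tissue_ns Mean ortho-positronium lifetime in the medium, ns.
#'   Must satisfy 0 < tau <= tau_vacuum.
#' @param tau_vacuum_ns Vacuum mean lifetime, ns (default 142).
#' @return A list with `f_3g`, `f_2g` (= 1 - f_3g) and `ratio_2g_3g`.
#' @export
#' @examples
#' ops_branching(2)$ratio_2g_3g   # 70
ops_branching <- function(tau_tissue_ns, tau_vacuum_ns = ps_constants()$tau_vacuum_ns) {
  if (any(!is.finite(tau_tissue_ns)) || any(tau_tissue_ns <= 0))
    stop("tau_tissue_ns must be positive")
  if (any(tau_tissue_ns > tau_vacuum_ns))
    stop("tau_tissue_ns cannot exceed the vacuum lifetime of ",
         tau_vacuum_ns, " ns")
  f3 <- tau_tissue_ns / tau_vacuum_ns
  list(f_3g = f3, f_2g = 1 - f3, ratio_2g_3g = (1 - f3) / f3)
}

#' Single-photon detection efficiency of a scintillator layer
#'
#' Probability that a photon crossing a cylindrical scintillator shell of
#' radial thickness `d` at polar angle `theta` (measured from the scanner
#' axis) interacts at least once: `1 - exp(-mu * d / sin(theta))`, the
#' slant path through the shell being `d / sin(theta)`.
#'
#' @param theta Polar angle(s) in radians, strictly inside (0, pi).
#' @param material A [material()] object supplying `mu_511`/`mu_1160` and
#'   `thickness`.
#' @param energy_kev Photon energy tag, 511 or 1160.
#' @return Interaction probabilities in (0, 1).
#' @export
#' @examples
#' detection_efficiency(pi / 2, material("lyso"), 511)   # ~0.779
detection_efficiency <- function(theta, material, energy_kev = 511) {
  check_theta(theta)
  mu <- mu_for_energy(material, energy_kev)
  1 - exp(-mu * material$thickness / sin(theta))
}

#' Photon survival through the water phantom
#'
#' Probability that a photon emitted on the axis at polar angle `theta`
#' escapes the cylindrical water phantom without interacting:
#' `exp(-mu_water * R_phantom / sin(theta))`.
#'
#' @inheritParams detection_efficiency
#' @param phantom A [phantom_model()].
#' @return Survival probabilities in (0, 1].
#' @export
#' @examples
#' phantom_attenuation(pi / 2, phantom_model(), 511)   # ~0.383
phantom_attenuation <- function(theta, phantom, energy_kev = 511) {
  check_theta(theta)
  mu <- mu_for_energy(phantom, energy_kev)
  exp(-mu * phantom$radius / sin(theta))
}

check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= pi))
    stop("theta must lie strictly inside (0, pi): the slant path diverges at the axis")
  invisible(theta)
}

#' Load a material definition from a plain-text config file
#'
#' Reads a YAML file with a `preset` field (`"lyso"`, `"plastic"` or
#' `"water"`) and optional overrides for any [material()] field, e.g.
#'
#' ```yaml
#' preset: plastic
#' thickness: 3
#' eps_sel_a: 0.40
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `ps_material`.
#' @export
material_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$preset))
    stop("config must name a `preset` (lyso, plastic or water)")
  preset <- cfg$preset
  cfg$preset <- NULL
  do.call(material, c(list(name = preset), cfg))
}
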