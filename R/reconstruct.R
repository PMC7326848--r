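#' TOF reconstruction of annihilation position, time, and lifetime
#'
#' For each registered triple, the annihilation point is placed on the
#' line of response (LOR) joining the two annihilation hits at the
#' time-of-flight position: with hits `(r1, t1)` and `(r2, t2)`,
#' `pos = M + u * c (t1 - t2) / 2` where `M` is the LOR midpoint and `u`
#' the unit vector from hit 1 to hit 2 (the annihilation lies towards the
#' hit recorded earlier); the offset is clamped to the chord. The annihilation time is
#' `(t1 + t2)/2 - (|r1 - pos| + |r2 - pos|) / (2 c)`. The positron
#' (prompt) emission time follows from the prompt hit by propagating back
#' from the hit to the annihilation position,
#' `t_emit = t_p - |r_p - pos| / c` (exact for zero positron range, since
#' the prompt is emitted from the annihilation point), and the
#' reconstructed ortho-positronium lifetime is their difference. Smearing
#' can make reconstructed lifetimes negative; they are deliberately not
#' clipped (clipping would bias the voxel means upward).
#'
#' @param triples Smeared triple frame from [smear_hits()] (optionally
#'   after [select_triples()]).
#' @param use_registered Use the smeared (`_r*`) coordinates (default);
#'   with `FALSE` the true hit coordinates are used, which reproduces the
#'   generated positions and lifetimes to machine precision.
#' @return A data.frame of annihilation records: `event_id`, `source_id`,
#'   reconstructed position `x, y, z` (cm), `annih_time_ps`,
#'   `emit_time_ps`, `lifetime_ps`, plus the generator truth
#'   (`lifetime_true_ps`, `tau_ns`, origin `ox, oy, oz`).
#' @export
reconstruct_events <- function(triples, use_registered = TRUE) {
  sfx <- if (use_registered) "_r" else "_"
  col <- function(tag, what) triples[[paste0(tag, sfx, what)]]
  if (use_registered && is.null(triples$a1_rx))
    stop("no registered coordinates found; run smear_hits() first")
  cc <- ps_constants()$c_cm_per_ps

  r1 <- cbind(col("a1", "x"), col("a1", "y"), col("a1", "z"))
  r2 <- cbind(col("a2", "x"), col("a2", "y"), col("a2", "z"))
  t1 <- col("a1", "t"); t2 <- col("a2", "t")
  u <- r2 - r1
  len <- sqrt(rowSums(u^2))
  if (any(len == 0)) stop("degenerate LOR: coincident annihilation hits")
  u <- u / len

  s <- cc * (t1 - t2) / 2
  s <- pmin(pmax(s, -len / 2), len / 2)   # clamp to the chord
  pos <- (r1 + r2) / 2 + u * s

  d1 <- sqrt(rowSums((r1 - pos)^2))
  d2 <- sqrt(rowSums((r2 - pos)^2))
  annih_t <- (t1 + t2) / 2 - (d1 + d2) / (2 * cc)

  rp <- cbind(col("p", "x"), col("p", "y"), col("p", "z"))
  dp <- sqrt(rowSums((rp - pos)^2))
  emit_t <- col("p", "t") - dp / cc

  data.frame(
    event_id = triples$event_id,
    source_id = triples$source_id,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    annih_time_ps = annih_t,
    emit_time_ps = emit_t,
    lifetime_ps = annih_t - emit_t,
    lifetime_true_ps = triples$lifetime_ps,
    tau_ns = triples$tau_ns,
    ox = triples$ox, oy = triples$oy, oz = triples$oz
  )
}

#' Regular 3D voxel image container
#'
#' Minimal S3 container for volumetric results: a numeric array with a
#' world origin (cm, position of the centre of voxel \[1,1,1\]) and voxel
#' sizes (cm). Used for both count (activity) images and mean-lifetime
#' images.
#'
#' @param values 3D numeric array.
#' @param origin Length-3 world position of the first voxel centre, cm.
#' @param voxel_size Length-3 voxel edge lengths, cm.
#' @param metadata Named list stored alongside (CRT, seed, event counts...).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, origin, voxel_size, metadata = list()) {
  stopifnot(length(dim(values)) == 3, length(origin) == 3,
            length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(values = values, origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size), metadata = metadata),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d voxels of %.2f x %.2f x %.2f cm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) cm; value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of the voxel centres along one axis
#' @param image A [volume_image()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-centre coordinates, cm.
#' @export
voxel_centers <- function(image, axis) {
  image$origin[axis] + (seq_len(dim(image$values)[axis]) - 1) * image$voxel_size[axis]
}

grid_from_bounds <- function(bounds, voxel_size) {
  lo <- bounds[1, ]
  n <- pmax(1L, as.integer(ceiling((bounds[2, ] - lo) / voxel_size)))
  list(origin = lo + voxel_size / 2, n = n)
}

default_bounds <- function(records, margin = 3) {
  rbind(c(min(records$x) - margin, min(records$y) - margin, min(records$z) - margin),
        c(max(records$x) + margin, max(records$y) + margin, max(records$z) + margin))
}

voxel_linear_index <- function(x, y, z, origin, voxel_size, n) {
  i <- floor((x - origin[1] + voxel_size[1] / 2) / voxel_size[1])
  j <- floor((y - origin[2] + voxel_size[2] / 2) / voxel_size[2])
  k <- floor((z - origin[3] + voxel_size[3] / 2) / voxel_size[3])
  inside <- i >= 0 & i < n[1] & j >= 0 & j < n[2] & k >= 0 & k < n[3]
  idx <- rep(NA_real_, length(x))
  idx[inside] <- 1 + i[inside] + n[1] * (j[inside] + n[2] * k[inside])
  list(index = idx, inside = inside)
}

#' Direct annihilation-point image
#'
#' 3D histogram of the reconstructed annihilation positions: with
#' sufficiently precise timing (tens of ps) this density is usable as the
#' activity image without any tomographic reconstruction. Default voxels
#' are 5 x 5 x 5 mm.
#'
#' @param records Frame from [reconstruct_events()].
#' @param voxel_size Voxel edge lengths, cm (scalar or length 3).
#' @param bounds 2 x 3 matrix (min row, max row) of the imaged region, cm;
#'   derived from the records (plus a margin) when NULL.
#' @return A [volume_image()] of counts; records falling outside the grid
#'   are dropped and counted in `metadata$n_dropped`.
#' @export
direct_image <- function(records, voxel_size = 0.5, bounds = NULL) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (is.null(bounds)) bounds <- default_bounds(records)
  g <- grid_from_bounds(bounds, voxel_size)
  vi <- voxel_linear_index(records$x, records$y, records$z,
                           g$origin, voxel_size, g$n)
  counts <- tabulate(vi$index[vi$inside], nbins = prod(g$n))
  volume_image(array(counts, dim = g$n), g$origin, voxel_size,
               metadata = list(n_records = nrow(records),
                               n_dropped = sum(!vi$inside)))
}

#' List-mode TOF filtered back projection
#'
#' Each event is backprojected along its line of response over a fixed
#' span around the TOF-estimated annihilation position, with Gaussian
#' TOF confidence weights of standard deviation
#' `c * CRT / (2 * 2.3548)` (the single-event TOF localisation error).
#' The accumulated backprojection is then filtered plane by plane
#' (transaxial planes, where the LOR density lives) with an
#' apodized 2D ramp filter `|k| * Hann(k)`: the ramp deconvolves the
#' `1/r` line-backprojection kernel, whose small-`r` behaviour --- and
#' hence the resolution of the filtered image --- is independent of the
#' TOF kernel width, while the TOF weighting suppresses the long-range
#' backprojection background. The spatial resolution of the result is
#' therefore set by the detector blur and the voxel size, nearly
#' independent of CRT, unlike the direct image.
#'
#' Default voxels are 1.8 x 1.8 x 2.9 mm. Values are not guaranteed
#' non-negative (filtered back projection rings).
#'
#' @param records Frame from [reconstruct_events()].
#' @param crt_ps CRT used for the TOF weights, ps.
#' @param voxel_size Voxel sizes, cm (scalar or length 3).
#' @param bounds As in [direct_image()].
#' @param span_cm Half-length of the backprojected LOR segment, cm
#'   (default: at least 8 cm and at least 3 TOF sigma).
#' @param apodization Fraction of the Nyquist frequency at which the Hann
#'   apodization window closes (default 1: full band).
#' @return A [volume_image()].
#' @export
tof_fbp <- function(records, crt_ps, voxel_size = c(0.18, 0.18, 0.29),
                    bounds = NULL, span_cm = NULL, apodization = 1) {
  if (nrow(records) == 0) stop("no records to reconstruct")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (is.null(bounds)) bounds <- default_bounds(records)
  g <- grid_from_bounds(bounds, voxel_size)
  cc <- ps_constants()$c_cm_per_ps
  sigma <- cc * crt_ps / (2 * 2 * sqrt(2 * log(2)))
  step <- min(voxel_size) / 2
  if (is.null(span_cm)) span_cm <- max(8, 3 * sigma)
  offsets <- seq(-span_cm, span_cm, by = step)
  w <- stats::dnorm(offsets, 0, max(sigma, step / 2))
  w <- w / sum(w)

  # LOR directions (unit); recompute from the registered hits
  ux <- records$x * 0; uy <- ux; uz <- ux
  if (!is.null(records$lor_ux)) {
    ux <- records$lor_ux; uy <- records$lor_uy; uz <- records$lor_uz
  } else {
    stop("records must carry LOR directions (lor_ux, lor_uy, lor_uz); ",
         "use add_lor_directions() or reconstruct via simulate_records()")
  }

  acc <- numeric(prod(g$n))
  for (m in seq_along(offsets)) {
    vi <- voxel_linear_index(records$x + offsets[m] * ux,
                             records$y + offsets[m] * uy,
                             records$z + offsets[m] * uz,
                             g$origin, voxel_size, g$n)
    ok <- vi$inside
    if (!any(ok)) next
    dep <- rowsum(rep(w[m], sum(ok)), vi$index[ok])
    ii <- as.integer(rownames(dep))
    acc[ii] <- acc[ii] + dep[, 1]
  }
  img <- array(acc, dim = g$n)

  # Plane-by-plane apodized ramp filter in the transaxial planes: the
  # ramp |k| deconvolves the 1/r line-backprojection kernel, whose
  # small-r behaviour is independent of the TOF weight width.
  nx <- g$n[1]; ny <- g$n[2]
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / (nx * voxel_size[1])
  if (nx == 1) fx <- 0
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / (ny * voxel_size[2])
  if (ny == 1) fy <- 0
  kr <- sqrt(outer(fx^2, fy^2, "+"))
  k_nyq <- apodization * 0.5 / max(voxel_size[1:2])
  H <- kr * ifelse(kr <= k_nyq, 0.5 * (1 + cos(pi * kr / k_nyq)), 0)
  for (k in seq_len(g$n[3])) {
    plane <- img[, , k]
    if (all(plane == 0)) next
    img[, , k] <- Re(stats::fft(stats::fft(plane) * H, inverse = TRUE)) / (nx * ny)
  }
  volume_image(img, g$origin, voxel_size,
               metadata = list(crt_ps = crt_ps, n_records = nrow(records),
                               span_cm = span_cm, apodization = apodization))
}

#' Attach LOR direction columns to annihilation records
#'
#' Stores the unit vector of each event's line of response (from the
#' first to the second registered annihilation hit) on the record frame;
#' required by [tof_fbp()].
#'
#' @param records Frame from [reconstruct_events()].
#' @param triples The matching triple frame the records were built from.
#' @param use_registered Use smeared hit coordinates (default TRUE).
#' @return `records` with `lor_ux, lor_uy, lor_uz` columns.
#' @export
add_lor_directions <- function(records, triples, use_registered = TRUE) {
  sfx <- if (use_registered) "_r" else "_"
  u <- cbind(triples[[paste0("a2", sfx, "x")]] - triples[[paste0("a1", sfx, "x")]],
             triples[[paste0("a2", sfx, "y")]] - triples[[paste0("a1", sfx, "y")]],
             triples[[paste0("a2", sfx, "z")]] - triples[[paste0("a1", sfx, "z")]])
  u <- u / sqrt(rowSums(u^2))
  records$lor_ux <- u[, 1]; records$lor_uy <- u[, 2]; records$lor_uz <- u[, 3]
  records
}

#' Point-spread function from a 1D profile through an image peak
#'
#' Extracts a 1D profile through the image maximum nearest
#' `true_position` along the requested axis and fits a Gaussian with
#' constant background (Levenberg-Marquardt); the FWHM is
#' `2 sqrt(2 log 2) * sigma`. The profile is restricted to a window
#' around the peak so neighbouring sources do not contaminate the fit.
#' `profile = "projection"` sums the image over the two orthogonal axes
#' within the window (the usual way a point-source profile is quoted);
#' `"slice"` takes the single row of voxels through the peak.
#'
#' The window must cover the peak's tails for the fit to be unbiased: the
#' window is enlarged to 4 times the running FWHM estimate whenever it is
#' smaller than that, and the fit repeated (up to three passes),
#' never beyond `max_window_cm` --- set the cap below the distance to the
#' nearest neighbouring source when several sources share the image.
#'
#' @param image A [volume_image()].
#' @param true_position Length-3 position of the source, cm.
#' @param axis 1 (radial/x) or 3 (axial/z); 2 allowed for completeness.
#' @param window_cm Initial half-window retained around the peak, cm
#'   (default 6).
#' @param max_window_cm Upper limit for the adaptive window, cm
#'   (default 12).
#' @param profile `"projection"` (default) or `"slice"`.
#' @return A list with `fwhm_mm`, `sigma_cm`, `center_cm`, `window_cm`
#'   (the window actually used), and the fitted profile (`coord_cm`,
#'   `value`, `fit`).
#' @export
estimate_psf <- function(image, true_position, axis = 1, window_cm = 6,
                         max_window_cm = 12,
                         profile = c("projection", "slice")) {
  profile <- match.arg(profile)
  for (pass in 1:3) {
    res <- psf_fit_once(image, true_position, axis, window_cm, profile)
    needed <- min(4 * res$fwhm_mm / 10, max_window_cm)
    if (needed <= window_cm || window_cm >= max_window_cm) break
    window_cm <- needed
  }
  res$window_cm <- window_cm
  res
}

psf_fit_once <- function(image, true_position, axis, window_cm, profile) {
  stopifnot(inherits(image, "volume_image"))
  n <- dim(image$values)
  # locate the image maximum within the window around the true position
  cen_idx <- vapply(1:3, function(a) {
    which.min(abs(voxel_centers(image, a) - true_position[a]))
  }, 0L)
  win_idx <- lapply(1:3, function(a) {
    cc <- voxel_centers(image, a)
    which(abs(cc - true_position[a]) <= window_cm)
  })
  sub <- image$values[win_idx[[1]], win_idx[[2]], win_idx[[3]], drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak_idx <- c(win_idx[[1]][pk[1]], win_idx[[2]][pk[2]], win_idx[[3]][pk[3]])

  ax_idx <- win_idx[[axis]]
  others <- setdiff(1:3, axis)
  if (profile == "projection") {
    slicer <- win_idx
    slicer[[axis]] <- ax_idx
    vals <- apply(image$values[slicer[[1]], slicer[[2]], slicer[[3]], drop = FALSE],
                  which(1:3 == axis), sum)
  } else {
    slicer <- as.list(peak_idx)
    slicer[[axis]] <- ax_idx
    vals <- image$values[slicer[[1]], slicer[[2]], slicer[[3]]]
  }
  coord <- voxel_centers(image, axis)[ax_idx]

  amp0 <- max(vals) - min(vals)
  mu0 <- coord[which.max(vals)]
  above <- vals >= min(vals) + amp0 / 2
  sig0 <- max(diff(range(coord[above])), image$voxel_size[axis]) / 2.3548
  gauss <- function(p) p[1] * exp(-(coord - p[2])^2 / (2 * p[3]^2)) + p[4]
  fit <- tryCatch({
    f <- minpack.lm::nlsLM(v ~ A * exp(-(x - m)^2 / (2 * s^2)) + b,
                           data = data.frame(x = coord, v = vals),
                           start = list(A = amp0, m = mu0, s = sig0, b = min(vals)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(f)
    list(par = c(cf[["A"]], cf[["m"]], cf[["s"]], cf[["b"]]))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # direct least-squares fallback for profiles where the Jacobian is
    # degenerate at the moment-based start
    fit <- stats::optim(c(amp0, mu0, sig0, min(vals)),
                        function(p) sum((vals - gauss(p))^2),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (fit$convergence != 0)
      stop("PSF Gaussian fit failed to converge\nprofile: ",
           paste(signif(vals, 4), collapse = " "))
  }
  p <- fit$par
  list(fwhm_mm = abs(p[3]) * 2 * sqrt(2 * log(2)) * 10,
       sigma_cm = abs(p[3]), center_cm = p[2],
       profile = data.frame(coord_cm = coord, value = vals,
                            fit = gauss(p)))
}

#' Write a volume image as NIfTI with a JSON sidecar
#'
#' Voxel sizes are written in mm in the NIfTI header; the metadata list
#' (CRT, seed, event counts, image origin in cm) goes into a JSON sidecar
#' next to the image.
#'
#' @param image A [volume_image()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "volume_image"))
  nii <- RNifti::asNifti(image$values)
  RNifti::pixdim(nii) <- image$voxel_size * 10
  RNifti::writeNifti(nii, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- c(image$metadata, list(origin_cm = image$origin,
                                 voxel_size_cm = image$voxel_size))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
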