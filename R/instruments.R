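#' Raster-scan configuration
#'
#' Geometry of the point-scanning instrument: the pencil beam is scanned over
#' a square area of the entry face on a regular grid, and for each position
#' the surface radiance is integrated over a fixed disc detector centred at
#' (0, 0) — on the entry face in reflection mode, on the opposite face in
#' transmission mode.
#'
#' @param span `c(lo, hi)` scan extent on both lateral axes, mm; must lie
#'   within the slab face of the phantom it is used with.
#' @param step Scan step, mm (> 0); also the pixel size of the scan image.
#' @param detector_radius Radius of the integrating detector disc, mm.
#' @return Object of class `fs_scan_config`.
#' @export
scan_config <- function(span = c(-22, 22), step = 1, detector_radius = 7.5) {
  stopifnot(is.numeric(span), length(span) == 2, span[1] < span[2])
  if (!is.finite(step) || step <= 0) abort("`step` must be > 0.")
  if (!is.finite(detector_radius) || detector_radius <= 0)
    abort("`detector_radius` must be > 0.")
  structure(list(span = as.numeric(span), step = step,
                 detector_radius = detector_radius,
                 positions = seq(span[1], span[2], by = step)),
            class = "fs_scan_config")
}

# full lateral face of the phantom, for detector-side images
face_fov <- function(phantom) {
  list(x = c(-1, 1) * phantom$size[1] / 2, y = c(-1, 1) * phantom$size[2] / 2)
}

# resolve lambda/props argument pairs shared by the instrument functions
resolve_props <- function(lambda, props) {
  if (!is.null(props)) return(props)
  optical_properties(lambda)
}

ops_pair <- function(phantom, props_ex, props_em) {
  list(ex = diffusion_operator(phantom, props_ex),
       em = diffusion_operator(phantom, props_em))
}

#' Full-field illumination image
#'
#' Simulates the camera-plane instrument: a 20 mm radius disc source of
#' uniform power density illuminates the entry face and the fluorescence
#' surface radiance is imaged over the field of view on the requested face.
#'
#' @param phantom An [slab_phantom()].
#' @param lambda_ex,lambda_em Excitation / emission wavelengths (nm), used to
#'   look up optical properties unless `props_ex`/`props_em` are given.
#' @param mode `"reflection"` (detector on the entry face) or
#'   `"transmission"` (opposite face).
#' @param props_ex,props_em Optional [optical_properties()] overrides.
#' @param source The illumination source, default [disc_source()] (r = 20 mm).
#' @param fov Field of view, mm.
#' @return An `fs_image` (see [fluorescence_forward()]).
#' @examples
#' \donttest{
#' ph <- slab_phantom(targets = two_targets(z = 0))
#' img <- full_field_image(ph, mode = "reflection")
#' sparrow_resolution(img)
#' }
#' @export
full_field_image <- function(phantom, lambda_ex = 600, lambda_em = 620,
                             mode = c("reflection", "transmission"),
                             props_ex = NULL, props_em = NULL,
                             source = disc_source(), fov = c(-26, 26)) {
  mode <- match.arg(mode)
  props_ex <- resolve_props(lambda_ex, props_ex)
  props_em <- resolve_props(lambda_em, props_em)
  fluorescence_forward(phantom, props_ex, props_em, source, mode, fov,
                       operators = ops_pair(phantom, props_ex, props_em))
}

#' Scanning-system image, direct (per-position) computation
#'
#' The slow reference computation: for every scan position the full
#' three-step fluorescence model is run with a point source at that position
#' and the detector disc reading is recorded.  One operator factorisation
#' per wavelength is reused across positions, but the cost still scales with
#' the number of positions; this is the oracle against which the fast
#' equivalence method ([scan_image_fast()]) is validated.
#'
#' @inheritParams full_field_image
#' @param config An [scan_config()].
#' @param power Power of the scanned beam (photons s^-1); the default, 1 mm^2
#'   of unit power density, matches the full-field instrument's density.
#' @return Object of class `fs_scan`: reading matrix indexed by scan position.
#' @export
scan_image_direct <- function(phantom, lambda_ex = 600, lambda_em = 620,
                              mode = c("reflection", "transmission"),
                              props_ex = NULL, props_em = NULL,
                              config = scan_config(), power = 1) {
  mode <- match.arg(mode)
  props_ex <- resolve_props(lambda_ex, props_ex)
  props_em <- resolve_props(lambda_em, props_em)
  ops <- ops_pair(phantom, props_ex, props_em)
  fov <- face_fov(phantom)
  sp <- config$positions
  vals <- matrix(0, length(sp), length(sp))
  for (ib in seq_along(sp)) for (ia in seq_along(sp)) {
    img <- fluorescence_forward(phantom, props_ex, props_em,
                                point_source(c(sp[ia], sp[ib]), power),
                                mode, fov = fov, operators = ops)
    vals[ia, ib] <- detector_reading(img, radius = config$detector_radius)
  }
  new_scan(vals, sp, mode, props_ex, props_em, config, method = "direct")
}

new_scan <- function(vals, sp, mode, props_ex, props_em, config, method,
                     coupling = NULL) {
  structure(list(values = vals, sx = sp, sy = sp, h = config$step,
                 mode = mode, lambda_ex = props_ex$lambda,
                 lambda_em = props_em$lambda, config = config,
                 method = method, coupling = coupling,
                 unit = "photons/s"),
            class = "fs_scan")
}

#' @export
print.fs_scan <- function(x, ...) {
  cat(sprintf("<scan image>  %d x %d positions (step %g mm), %s mode, %s method\n",
              length(x$sx), length(x$sy), x$h, x$mode, x$method))
  invisible(x)
}

#' Scanning-system coupling factor
#'
#' The fast scan simulation rests on a translation-equivalence argument:
#' outside the target region the slab is optically homogeneous and laterally
#' much larger than the scanned area, so moving the beam is equivalent to
#' moving the target-plus-detector assembly.  Because the target-detector
#' geometry is fixed, the integrated detector reading is proportional to the
#' total excitation fluence over the target cells, with a constant of
#' proportionality — the reflection (or transmission) factor — that depends
#' only on the emission wavelength, the mode and the target geometry.  It is
#' obtained from a single reference computation with the beam at
#' `reference`.
#'
#' @inheritParams scan_image_direct
#' @param reference Reference beam position (x, y), mm.
#' @return Object of class `fs_coupling`: the factor `value`, the cached
#'   reference excitation fluence field `field`, and the target-cell
#'   coordinates used for translation.
#' @export
coupling_factor <- function(phantom, lambda_ex = 600, lambda_em = 620,
                            mode = c("reflection", "transmission"),
                            props_ex = NULL, props_em = NULL,
                            config = scan_config(), power = 1,
                            reference = c(0, 0)) {
  mode <- match.arg(mode)
  if (!phantom$homogeneous)
    abort(paste("The scanning equivalence requires homogeneous optical",
                "properties outside the target region; this phantom declares",
                "inhomogeneous optics."))
  if (length(phantom$targets) == 0)
    abort("Coupling factor needs at least one target.")
  props_ex <- resolve_props(lambda_ex, props_ex)
  props_em <- resolve_props(lambda_em, props_em)
  ops <- ops_pair(phantom, props_ex, props_em)
  img <- fluorescence_forward(phantom, props_ex, props_em,
                              point_source(reference, power), mode,
                              fov = face_fov(phantom), operators = ops)
  cells <- which(phantom$labels > 0)
  phi_ex <- attr(img, "fluence_ex")
  f_ref <- sum(phi_ex$values[cells])
  i_ref <- detector_reading(img, radius = config$detector_radius)
  structure(list(value = i_ref / f_ref, mode = mode,
                 lambda_ex = props_ex$lambda, lambda_em = props_em$lambda,
                 field = phi_ex, cells = cells,
                 xyz = cell_centres(phantom, cells),
                 reference = reference, power = power,
                 detector_radius = config$detector_radius),
            class = "fs_coupling")
}

#' @export
print.fs_coupling <- function(x, ...) {
  cat(sprintf("<%s factor @ %g/%g nm>  %.4g (reference beam at %g, %g)\n",
              x$mode, x$lambda_ex, x$lambda_em, x$value,
              x$reference[1], x$reference[2]))
  invisible(x)
}

#' Scanning-system image, fast equivalence computation
#'
#' Renders the full raster scan from the single reference solve cached in
#' the [coupling_factor()]: for each scan position the excitation fluence at
#' the (translated) target cells is read from the reference field by
#' trilinear interpolation and multiplied by the coupling factor.  One
#' excitation and one emission solve per wavelength pair replace one pair
#' per scan position.
#'
#' @inheritParams scan_image_direct
#' @param coupling Optional pre-computed [coupling_factor()]; computed if
#'   missing.
#' @param strict Passed to [sample_fluence()]: error (rather than treat the
#'   fluence as 0) when a translated target cell leaves the cached grid.
#' @return An `fs_scan`.
#' @examples
#' \donttest{
#' ph <- slab_phantom(targets = two_targets(z = 0))
#' sc <- scan_image_fast(ph, mode = "reflection")
#' sparrow_resolution(sc)
#' }
#' @export
scan_image_fast <- function(phantom, lambda_ex = 600, lambda_em = 620,
                            mode = c("reflection", "transmission"),
                            props_ex = NULL, props_em = NULL,
                            config = scan_config(), power = 1,
                            coupling = NULL, strict = FALSE) {
  mode <- match.arg(mode)
  props_ex <- resolve_props(lambda_ex, props_ex)
  props_em <- resolve_props(lambda_em, props_em)
  cf <- coupling %||% coupling_factor(phantom, props_ex = props_ex,
                                      props_em = props_em, mode = mode,
                                      config = config, power = power)
  sp <- config$positions
  np <- length(sp)
  nc <- nrow(cf$xyz)
  # all (cell, position) query points in one vectorised interpolation
  sx <- rep(rep(sp, each = nc), times = np)
  sy <- rep(sp, each = nc * np)
  xq <- rep.int(cf$xyz[, 1], np * np) - sx + cf$reference[1]
  yq <- rep.int(cf$xyz[, 2], np * np) - sy + cf$reference[2]
  zq <- rep.int(cf$xyz[, 3], np * np)
  f <- sample_fluence(cf$field, xq, yq, zq, strict = strict)
  vals <- matrix(colSums(matrix(f, nc)), np, np)
  new_scan(cf$value * vals, sp, mode, props_ex, props_em, config,
           method = "fast", coupling = cf$value)
}
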