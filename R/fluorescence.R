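#' Fluorescence emission coefficient
#'
#' Converts fluorophore photophysics into the linear coefficient \eqn{\eta}
#' (mm^-1) that maps excitation fluence to volumetric emission strength,
#' \eqn{S_{fl} = \eta A_{ex}}.  The molar extinction coefficient
#' \eqn{\xi} (M^-1 cm^-1) becomes a per-molecule absorption cross-section
#' \eqn{\sigma = \ln(10)\cdot 1000 \cdot \xi / N_A} (cm^2), and
#' \eqn{\eta = \Phi\,\sigma\,N_0} after converting \eqn{\sigma} to mm^2 and
#' the concentration \eqn{N_0} to mm^-3.  For the default quantum-dot
#' parameters (\eqn{\Phi} = 0.6, \eqn{\xi} = 2e4, \eqn{N_0} = 1e20 m^-3)
#' this gives \eqn{\sigma \approx 7.65 \times 10^{-21}} m^2 and
#' \eqn{\eta \approx 4.59 \times 10^{-4}} mm^-1.
#'
#' @param fluorophore A [fluorophore_params()] object.
#' @return \eqn{\eta} in mm^-1, with the cross-section (m^2) attached as
#'   attribute `cross_section_m2`.
#' @export
emission_coefficient <- function(fluorophore = fluorophore_params()) {
  stopifnot(inherits(fluorophore, "fs_fluorophore"))
  avogadro <- 6.02214076e23
  sigma_cm2 <- log(10) * 1000 * fluorophore$extinction / avogadro
  sigma_mm2 <- sigma_cm2 * 100
  n0_mm3 <- fluorophore$concentration * 1e-9
  structure(fluorophore$quantum_yield * sigma_mm2 * n0_mm3,
            cross_section_m2 = sigma_cm2 * 1e-4)
}

#' Emission strength from excitation fluence
#'
#' \eqn{S_{fl}(r) = \Phi\,\sigma\,N_0\,A_{ex}(r)}: linear in the excitation
#' fluence and in every fluorophore factor.
#'
#' @param aex Excitation fluence (photons s^-1 mm^-2), non-negative.
#' @inheritParams emission_coefficient
#' @return Volumetric emission strength, photons s^-1 mm^-3.
#' @export
emission_strength <- function(aex, fluorophore = fluorophore_params()) {
  if (any(!is.finite(aex)) || any(aex < 0))
    abort("`aex` must be finite and non-negative.")
  as.numeric(emission_coefficient(fluorophore)) * aex
}

#' Three-step fluorescence forward model
#'
#' Computes the detected fluorescence surface image in three steps:
#' (a) solve the excitation diffusion problem for the fluence \eqn{A_{ex}}
#' at the target cells; (b) convert to volumetric emission strength
#' \eqn{S_{fl} = \eta A_{ex}}; (c) solve the emission diffusion problem with
#' \eqn{S_{fl}} as source and read the surface radiance on the detector face
#' (reflection: the entry face; transmission: the opposite face).  Ideal
#' wavelength filtering is assumed: only emitted light is detected, and
#' re-absorption of the emitted light by the fluorophore is neglected.
#'
#' @param phantom An [slab_phantom()] with at least the optical grid; targets
#'   may be empty (giving a zero image).
#' @param props_ex,props_em [optical_properties()] at the excitation and
#'   emission wavelengths.
#' @param source Excitation source ([disc_source()] or [point_source()]).
#' @param mode `"reflection"` or `"transmission"`.
#' @param fov Field of view of the returned image (mm).
#' @param operators Optional list with components `ex` and `em` of pre-built
#'   [diffusion_operator()]s.
#' @return An `fs_image` of surface radiance.  The excitation and emission
#'   fluence fields are attached as attributes `fluence_ex`, `fluence_em`;
#'   the total emitted power as `emission_total`.
#' @export
fluorescence_forward <- function(phantom, props_ex, props_em,
                                 source = disc_source(),
                                 mode = c("reflection", "transmission"),
                                 fov = c(-26, 26), operators = NULL) {
  mode <- match.arg(mode)
  if (!inherits(props_em, "fs_optical") || !inherits(props_ex, "fs_optical"))
    abort("Optical properties must be supplied at both wavelengths.")
  phi_ex <- solve_diffusion(phantom, props_ex, source,
                            operator = operators$ex)
  cells <- which(phantom$labels > 0)
  strength <- numeric(length(cells))
  for (t in seq_along(phantom$targets)) {
    eta <- as.numeric(emission_coefficient(phantom$targets[[t]]$fluorophore))
    sel <- phantom$labels[cells] == t
    strength[sel] <- eta * phi_ex$values[cells[sel]]
  }
  phi_em <- solve_diffusion(phantom, props_em,
                            volume_source(phantom, cells, strength),
                            operator = operators$em)
  img <- surface_radiance(phi_em,
                          face = if (mode == "reflection") "bottom" else "top",
                          fov = fov)
  img$mode <- mode
  attr(img, "fluence_ex") <- phi_ex
  attr(img, "fluence_em") <- phi_em
  attr(img, "emission_total") <- sum(strength) * phantom$h^3
  img
}

#' Autofluorescence parameters
#'
#' Intrinsic tissue fluorophores are described by the intrinsic fluorescence
#' coefficient \eqn{\beta(\lambda_{ex}, \lambda_{em}) =
#' \mu_{a,AF}(\lambda_{ex})\,\Phi_\lambda(\lambda_{em})} (mm^-1): the product
#' of the intrinsic-fluorophore absorption coefficient at the excitation
#' wavelength and the dimensionless spectral fluorescence energy yield at the
#' emission wavelength.  The intrinsic fluorophores are represented on a
#' lattice coarser than the solver grid (they are distributed, smooth
#' background, so a 5 mm node distance suffices and keeps the source compact).
#'
#' @param beta Intrinsic fluorescence coefficient, mm^-1 (>= 0).
#' @param spacing Lattice node distance, mm; must exceed the grid spacing.
#' @return Object of class `fs_autofluor`.
#' @export
autofluor_params <- function(beta, spacing = 5) {
  if (!is.finite(beta) || beta < 0) abort("`beta` must be >= 0.")
  if (!is.finite(spacing) || spacing <= 0) abort("`spacing` must be > 0.")
  structure(list(beta = beta, spacing = spacing), class = "fs_autofluor")
}

#' Autofluorescence background image
#'
#' Background-only forward model: the autofluorescence emission strength
#' \eqn{S_{AF}(r) = \beta A_{ex}(r)} is sampled on the coarse fluorophore
#' lattice, each node standing for a `spacing`^3 tissue volume, and
#' propagated to the detector face with the emission diffusion solve.
#'
#' @inheritParams fluorescence_forward
#' @param af An [autofluor_params()] object.
#' @return An `fs_image` of the background surface radiance.
#' @export
autofluorescence_forward <- function(phantom, props_ex, props_em,
                                     source = disc_source(),
                                     mode = c("reflection", "transmission"),
                                     af, fov = c(-26, 26), operators = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(af, "fs_autofluor"))
  if (af$spacing <= phantom$h)
    abort("Autofluorophore lattice spacing must exceed the grid spacing.")
  if (af$spacing > min(phantom$size))
    abort("Autofluorophore lattice is coarser than the slab.")
  phi_ex <- solve_diffusion(phantom, props_ex, source,
                            operator = operators$ex)
  nodes_1d <- function(half, sp) seq(-floor(half / sp) * sp,
                                     floor(half / sp) * sp, by = sp)
  gx <- nodes_1d(phantom$size[1] / 2 - phantom$h / 2, af$spacing)
  gy <- nodes_1d(phantom$size[2] / 2 - phantom$h / 2, af$spacing)
  gz <- nodes_1d(phantom$size[3] / 2 - phantom$h / 2, af$spacing)
  X <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  saf <- af$beta * sample_fluence(phi_ex, X[, 1], X[, 2], X[, 3])
  rhs_power <- saf * af$spacing^3      # photons/s represented by each node
  # deposit lattice nodes onto the solver grid and run the emission solve
  b_src <- deposit_points(phantom, X, rhs_power)
  cells <- which(b_src > 0)
  src <- volume_source(phantom, cells, b_src[cells] / phantom$h^3)
  phi_em <- solve_diffusion(phantom, props_em, src, operator = operators$em)
  img <- surface_radiance(phi_em,
                          face = if (mode == "reflection") "bottom" else "top",
                          fov = fov)
  img$mode <- mode
  attr(img, "fluence_ex") <- phi_ex
  img
}
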