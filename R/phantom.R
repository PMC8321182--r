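#' Fluorophore parameters
#'
#' Photophysical description of the fluorescent contrast agent (quantum-dot
#' cluster by default).  The molar extinction coefficient is converted to a
#' per-molecule absorption cross-section \eqn{\sigma = \ln(10) \cdot 1000
#' \cdot \xi / N_A} (cm^2), and the product \eqn{\eta = \Phi \sigma N_0}
#' (mm^-1) scales excitation fluence into volumetric emission strength.
#'
#' @param quantum_yield Quantum yield, fraction in \[0, 1\].
#' @param extinction Molar extinction coefficient at the excitation
#'   wavelength, M^-1 cm^-1.
#' @param concentration Fluorophore number concentration, m^-3.
#' @return Object of class `fs_fluorophore`.
#' @seealso [emission_coefficient()]
#' @export
fluorophore_params <- function(quantum_yield = 0.6, extinction = 2e4,
                               concentration = 1e20) {
  if (!is.finite(quantum_yield) || quantum_yield < 0 || quantum_yield > 1)
    abort("`quantum_yield` must lie in [0, 1].")
  if (!is.finite(extinction) || extinction < 0)
    abort("`extinction` must be >= 0.")
  if (!is.finite(concentration) || concentration < 0)
    abort("`concentration` must be >= 0.")
  structure(list(quantum_yield = quantum_yield, extinction = extinction,
                 concentration = concentration), class = "fs_fluorophore")
}

#' Cylindrical fluorescent target
#'
#' A finite cylinder (axis along z) of fluorophore embedded in the phantom.
#'
#' @param centre Numeric length-3, target centre (x, y, z) in mm.
#' @param radius Cylinder radius, mm (> 0).
#' @param height Cylinder height, mm (> 0).
#' @param fluorophore A [fluorophore_params()] object.
#' @return Object of class `fs_target`.
#' @export
cylindrical_target <- function(centre, radius = 1, height = 2,
                               fluorophore = fluorophore_params()) {
  stopifnot(is.numeric(centre), length(centre) == 3)
  if (!is.finite(radius) || radius <= 0) abort("`radius` must be > 0.")
  if (!is.finite(height) || height <= 0) abort("`height` must be > 0.")
  structure(list(centre = as.numeric(centre), radius = radius, height = height,
                 fluorophore = fluorophore), class = "fs_target")
}

#' Slab phantom on a regular voxel grid
#'
#' Builds the tissue-mimicking slab on a cell-centred regular grid.  The
#' default geometry is a 55 x 55 x 15 mm slab (a typical ventral-dorsal
#' thickness for an adult laboratory mouse) with illumination entering the
#' bottom face z = -7.5 mm.  Each grid cell carries a region label: 0 for
#' background, i for the i-th target; a cell belongs to a target when its
#' centre falls inside the cylinder (boundary inclusive).  Optical properties
#' are homogeneous unless `region_optics` supplies per-region overrides, in
#' which case the phantom is flagged inhomogeneous (which disables the
#' fast-scan equivalence, see [coupling_factor()]).
#'
#' @param size Numeric length-3: slab extent (x, y, z) in mm.
#' @param spacing Grid spacing h in mm (> 0); must divide each extent to
#'   within half a cell.
#' @param targets List of [cylindrical_target()]s; every target must lie
#'   strictly inside the slab.
#' @param n Interior refractive index (used for the boundary reflection
#'   parameter).
#' @param region_optics Optional named list mapping region labels
#'   (`"background"`, `"1"`, `"2"`, ...) to functions `function(lambda)`
#'   returning [optical_properties()]; `NULL` (default) means optically
#'   homogeneous.
#' @return Object of class `fs_phantom`.
#' @examples
#' ph <- slab_phantom(targets = two_targets(z = 0))
#' table(ph$labels)
#' @export
slab_phantom <- function(size = c(55, 55, 15), spacing = 1, targets = list(),
                         n = 1.33, region_optics = NULL) {
  stopifnot(is.numeric(size), length(size) == 3)
  if (!is.finite(spacing) || spacing <= 0) abort("`spacing` must be > 0.")
  if (inherits(targets, "fs_target")) targets <- list(targets)
  dims <- round(size / spacing)
  if (any(abs(dims * spacing - size) > spacing / 2 + 1e-9))
    abort("`spacing` must divide the slab extents to within half a cell.")
  if (any(dims < 2)) abort("Slab must span at least two cells per axis.")
  ax <- function(m) (seq_len(m) - (m + 1) / 2) * spacing
  x <- ax(dims[1]); y <- ax(dims[2]); z <- ax(dims[3])
  half <- dims * spacing / 2
  labels <- integer(prod(dims))
  for (t in seq_along(targets)) {
    tg <- targets[[t]]
    stopifnot(inherits(tg, "fs_target"))
    lo <- tg$centre - c(tg$radius, tg$radius, tg$height / 2)
    hi <- tg$centre + c(tg$radius, tg$radius, tg$height / 2)
    if (any(lo < -half) || any(hi > half))
      abort(sprintf("Target %d extends outside the slab.", t))
    kz <- which(abs(z - tg$centre[3]) <= tg$height / 2 + 1e-9)
    ij <- which(outer(x - tg$centre[1], y - tg$centre[2],
                      function(a, b) a^2 + b^2) <= tg$radius^2 + 1e-9)
    cells <- as.vector(outer(ij, (kz - 1) * dims[1] * dims[2], `+`))
    if (any(labels[cells] != 0))
      abort(sprintf("Target %d overlaps another target.", t))
    labels[cells] <- t
  }
  structure(list(
    size = as.numeric(size), h = spacing,
    nx = dims[1], ny = dims[2], nz = dims[3],
    x = x, y = y, z = z,
    zmin = -half[3], zmax = half[3],
    labels = labels, targets = targets, n = n,
    region_optics = region_optics,
    homogeneous = is.null(region_optics)
  ), class = "fs_phantom")
}

#' Standard two-target geometry
#'
#' The study configuration: two identical cylinders (r = 1 mm, h = 2 mm)
#' centred at (0, -D/2, z) and (0, +D/2, z), default separation D = 16 mm.
#'
#' @param z Target plane depth coordinate, mm (slab mid-plane is z = 0).
#' @param separation Centre-to-centre target separation D, mm.
#' @param ... Passed to [cylindrical_target()].
#' @return List of two `fs_target`s.
#' @export
two_targets <- function(z = 0, separation = 16, ...) {
  list(cylindrical_target(c(0, -separation / 2, z), ...),
       cylindrical_target(c(0, separation / 2, z), ...))
}

#' @export
print.fs_phantom <- function(x, ...) {
  cat(sprintf("<slab phantom>  %g x %g x %g mm, h = %g mm (%d cells), %d target(s)%s\n",
              x$size[1], x$size[2], x$size[3], x$h, x$nx * x$ny * x$nz,
              length(x$targets),
              if (x$homogeneous) "" else ", inhomogeneous optics"))
  invisible(x)
}

#' Cells belonging to a target region
#'
#' @param phantom An [slab_phantom()].
#' @param index Target index (1-based), or 0 for the background.
#' @return Integer vector of linear cell indices.
#' @export
target_mask <- function(phantom, index) {
  stopifnot(inherits(phantom, "fs_phantom"))
  if (!is.numeric(index) || length(index) != 1 || index != round(index) ||
      index < 0 || index > length(phantom$targets))
    abort(sprintf("`index` must be an integer in 0..%d.", length(phantom$targets)))
  which(phantom$labels == index)
}

# linear cell index -> (x, y, z) coordinates, n x 3 matrix
cell_centres <- function(phantom, cells) {
  nxy <- phantom$nx * phantom$ny
  k <- (cells - 1) %/% nxy + 1
  r <- (cells - 1) %% nxy
  cbind(phantom$x[r %% phantom$nx + 1],
        phantom$y[r %/% phantom$nx + 1],
        phantom$z[k])
}

# per-cell optical coefficient vectors for assembly
props_per_cell <- function(phantom, props) {
  stopifnot(inherits(props, "fs_optical"))
  N <- phantom$nx * phantom$ny * phantom$nz
  if (phantom$homogeneous)
    return(list(mua = rep(props$mua, N), musp = rep(props$musp, N),
                homogeneous = TRUE))
  mua <- rep(props$mua, N); musp <- rep(props$musp, N)
  ro <- phantom$region_optics
  for (nm in names(ro)) {
    p <- ro[[nm]](props$lambda)
    cells <- if (identical(nm, "background")) which(phantom$labels == 0)
             else target_mask(phantom, as.integer(nm))
    mua[cells] <- p$mua; musp[cells] <- p$musp
  }
  list(mua = mua, musp = musp, homogeneous = FALSE)
}
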