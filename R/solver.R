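#' Internal reflection parameter for the Robin boundary condition
#'
#' The partial-current boundary condition \eqn{\Phi + 2 A \kappa
#' \partial\Phi/\partial n = 0} uses a reflection parameter A that accounts
#' for refractive-index mismatch at the tissue-air interface.  The standard
#' polynomial approximation in the internal refractive index is used:
#' \eqn{r_d = -1.440 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n},
#' \eqn{A = (1 + r_d)/(1 - r_d)}.  For matched boundaries (n = 1) A is 1.
#'
#' @param n Interior refractive index.
#' @return The dimensionless parameter A.
#' @export
internal_reflection_A <- function(n = 1.33) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (n == 1) return(1)
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
}

#' Assemble the diffusion operator for a phantom
#'
#' Discretises \eqn{-\nabla\cdot(\kappa\nabla\Phi) + \mu_a \Phi = q} with a
#' cell-centred finite-volume scheme (7-point stencil, harmonic-mean face
#' diffusivity) and the Robin partial-current condition on all six faces.
#' The resulting sparse system is symmetric positive definite.  Operators are
#' cached, so repeated right-hand sides at the same wavelength (e.g. every
#' position of a raster scan) reuse one factorisation.
#'
#' @param phantom An [slab_phantom()].
#' @param props [optical_properties()] at the wavelength of interest.
#' @param method `"direct"` (sparse Cholesky), `"cg"` (Jacobi-preconditioned
#'   conjugate gradients) or `"auto"`: direct up to `fs_direct_limit()` cells,
#'   CG above.
#' @return An object of class `fs_operator`.
#' @export
diffusion_operator <- function(phantom, props,
                               method = c("auto", "direct", "cg")) {
  stopifnot(inherits(phantom, "fs_phantom"))
  method <- match.arg(method)
  pc <- props_per_cell(phantom, props)
  N <- phantom$nx * phantom$ny * phantom$nz
  if (method == "auto") method <- if (N <= fs_direct_limit()) "direct" else "cg"
  key <- hash(list(phantom$size, phantom$h, phantom$n, method, pc$mua, pc$musp))
  cached <- cache_get(key)
  if (!is.null(cached)) return(cached)

  h <- phantom$h
  A <- internal_reflection_A(phantom$n)
  kap <- 1 / (3 * (pc$mua + pc$musp))
  nx <- phantom$nx; ny <- phantom$ny; nz <- phantom$nz
  diagv <- pc$mua * h^3
  ii <- jj <- integer(0); vv <- numeric(0)
  lin <- seq_len(N)
  i_of <- (lin - 1) %% nx + 1
  j_of <- ((lin - 1) %/% nx) %% ny + 1
  k_of <- (lin - 1) %/% (nx * ny) + 1
  for (ax in 1:3) {
    p <- switch(ax, lin[i_of < nx], lin[j_of < ny], lin[k_of < nz])
    q <- p + switch(ax, 1L, nx, nx * ny)
    g <- h * 2 * kap[p] * kap[q] / (kap[p] + kap[q])
    ii <- c(ii, p, q); jj <- c(jj, q, p); vv <- c(vv, -g, -g)
    diagv[p] <- diagv[p] + g
    diagv[q] <- diagv[q] + g
  }
  gb <- h^2 * (2 * kap / h) / (1 + 4 * A * kap / h)   # Robin face closure
  nfaces <- (i_of == 1) + (i_of == nx) + (j_of == 1) + (j_of == ny) +
    (k_of == 1) + (k_of == nz)
  diagv <- diagv + gb * nfaces
  M <- sparseMatrix(i = c(ii, lin), j = c(jj, lin), x = c(vv, diagv),
                    dims = c(N, N))
  op <- structure(list(
    M = M, method = method, A = A, h = h, kappa = kap,
    dims = c(nx, ny, nz), n = phantom$n,
    factor = if (method == "direct") Cholesky(forceSymmetric(M)) else NULL
  ), class = "fs_operator")
  cache_put(key, op)
  op
}

#' @export
print.fs_operator <- function(x, ...) {
  cat(sprintf("<diffusion operator>  %d x %d x %d cells (h = %g mm), %s solver\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, x$method))
  invisible(x)
}

#' @rdname diffusion_operator
#' @export
fs_direct_limit <- function() getOption("fluorscan.direct_limit", 120000L)

# --- operator cache ---------------------------------------------------------
cache_get <- function(key) {
  if (is.null(the$ops)) the$ops <- list()
  op <- the$ops[[key]]
  if (!is.null(op)) {  # refresh LRU order
    the$ops[[key]] <- NULL
    the$ops[[key]] <- op
  }
  op
}
cache_put <- function(key, op) {
  cap <- getOption("fluorscan.cache_size", 8L)
  if (is.null(the$ops)) the$ops <- list()
  the$ops[[key]] <- op
  while (length(the$ops) > cap) the$ops[[1]] <- NULL
  invisible(op)
}

#' Clear the cached operator factorisations
#' @return Invisibly, the number of entries dropped.
#' @export
clear_operator_cache <- function() {
  n <- length(the$ops)
  the$ops <- list()
  invisible(n)
}

# Jacobi-preconditioned conjugate gradients for the SPD operator
solve_pcg <- function(M, b, tol = 1e-8, maxit = 5000L) {
  d <- Matrix::diag(M)
  x <- numeric(length(b)); r <- b
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  z <- r / d; p <- z; rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(M %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bn < tol) return(x)
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  warn(sprintf("CG reached maxit = %d without converging to tol = %g.",
               maxit, tol))
  x
}

# --- sources ----------------------------------------------------------------

#' Illumination and emission sources
#'
#' `point_source()` describes a collimated pencil beam entering the bottom
#' face at lateral position (x, y); it is modelled as an isotropic point
#' source buried one transport mean free path (1/musp) below the surface.
#' `disc_source()` is the full-field illuminator: a uniform disc of
#' power density on the entry face, realised as the superposition of buried
#' point sources under every surface cell of the disc footprint.
#' `volume_source()` is a volumetric source (photons s^-1 mm^-3 per cell),
#' used internally for the emission solve.
#'
#' @param position,centre Lateral (x, y) position on the entry face, mm.
#' @param power Total source power, photons s^-1.  The default (1 mm^2 times
#'   the unit power density) makes point-scan readings directly comparable to
#'   the full-field instrument, which assumes the same illumination power
#'   density.
#' @param radius Disc radius, mm.
#' @param power_density Power density of the full-field disc,
#'   photons s^-1 mm^-2.
#' @param phantom The phantom the volumetric source lives on.
#' @param cells Linear cell indices carrying emission.
#' @param strength Emission strength per cell, photons s^-1 mm^-3 (recycled).
#' @return An object of class `fs_source`.
#' @name sources
NULL

#' @rdname sources
#' @export
point_source <- function(position = c(0, 0), power = 1) {
  stopifnot(is.numeric(position), length(position) == 2, power >= 0)
  structure(list(kind = "point", position = as.numeric(position),
                 power = power), class = "fs_source")
}

#' @rdname sources
#' @export
disc_source <- function(centre = c(0, 0), radius = 20, power_density = 1) {
  stopifnot(is.numeric(centre), length(centre) == 2)
  if (!is.finite(radius) || radius <= 0) abort("`radius` must be > 0.")
  structure(list(kind = "disc", centre = as.numeric(centre), radius = radius,
                 power_density = power_density), class = "fs_source")
}

#' @rdname sources
#' @export
volume_source <- function(phantom, cells, strength) {
  stopifnot(inherits(phantom, "fs_phantom"))
  strength <- rep_len(strength, length(cells))
  if (any(strength < 0)) abort("Emission strength must be non-negative.")
  structure(list(kind = "volume", cells = as.integer(cells),
                 strength = strength), class = "fs_source")
}

# accumulate weighted values at duplicate indices
accumulate_at <- function(rhs, idx, val) {
  s <- rowsum(val, idx)
  at <- as.integer(rownames(s))
  rhs[at] <- rhs[at] + s[, 1]
  rhs
}

# trilinear deposit of point powers P at rows of X into the cell grid
deposit_points <- function(phantom, X, P) {
  h <- phantom$h
  N <- phantom$nx * phantom$ny * phantom$nz
  rhs <- numeric(N)
  fx <- (X[, 1] - phantom$x[1]) / h + 1
  fy <- (X[, 2] - phantom$y[1]) / h + 1
  fz <- (X[, 3] - phantom$z[1]) / h + 1
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    i <- i0 + di; j <- j0 + dj; k <- k0 + dk
    ok <- i >= 1 & i <= phantom$nx & j >= 1 & j <= phantom$ny &
      k >= 1 & k <= phantom$nz
    if (!any(ok)) next
    w <- (1 - abs(fx - i)) * (1 - abs(fy - j)) * (1 - abs(fz - k))
    idx <- i[ok] + (j[ok] - 1) * phantom$nx + (k[ok] - 1) * phantom$nx * phantom$ny
    rhs <- accumulate_at(rhs, idx, (P * w)[ok])
  }
  rhs
}

# right-hand side (photons/s per cell) for a source
source_rhs <- function(phantom, props, source) {
  stopifnot(inherits(source, "fs_source"))
  switch(source$kind,
    point = {
      z0 <- phantom$zmin + 1 / props$musp
      deposit_points(phantom,
                     matrix(c(source$position, z0), 1, 3), source$power)
    },
    disc = {
      z0 <- phantom$zmin + 1 / props$musp
      inside <- which(outer(phantom$x - source$centre[1],
                            phantom$y - source$centre[2],
                            function(a, b) a^2 + b^2) <= source$radius^2)
      i <- (inside - 1) %% phantom$nx + 1
      j <- (inside - 1) %/% phantom$nx + 1
      X <- cbind(phantom$x[i], phantom$y[j], z0)
      deposit_points(phantom, X, rep(source$power_density * phantom$h^2,
                                     nrow(X)))
    },
    volume = {
      rhs <- numeric(phantom$nx * phantom$ny * phantom$nz)
      rhs[source$cells] <- source$strength * phantom$h^3
      rhs
    },
    abort("Unknown source kind."))
}

# --- solve ------------------------------------------------------------------

#' Solve the CW diffusion equation on the phantom
#'
#' Computes the photon fluence field (photons s^-1 mm^-2) produced by a
#' source at the wavelength of `props`.  Surface sources are buried one
#' transport mean free path below the entry face; the boundary condition on
#' all faces is the Robin partial-current condition.
#'
#' @inheritParams diffusion_operator
#' @param source An [point_source()], [disc_source()] or [volume_source()].
#' @param operator Optional pre-built [diffusion_operator()] (otherwise
#'   looked up or assembled, with caching).
#' @return Object of class `fs_fluence`: the fluence values (one per cell)
#'   plus grid metadata.
#' @examples
#' ph <- slab_phantom(size = c(20, 20, 10), targets = list())
#' fl <- solve_diffusion(ph, optical_properties(600), point_source())
#' range(fl$values)
#' @export
solve_diffusion <- function(phantom, props, source, operator = NULL,
                            method = c("auto", "direct", "cg")) {
  op <- operator %||% diffusion_operator(phantom, props, match.arg(method))
  b <- source_rhs(phantom, props, source)
  x <- if (op$method == "direct") {
    as.numeric(Matrix::solve(op$factor, b, system = "A"))
  } else {
    solve_pcg(op$M, b, tol = getOption("fluorscan.cg_tol", 1e-8))
  }
  # the scheme is an M-matrix: clip the solver's rounding-level negatives
  x[x < 0] <- 0
  structure(list(values = x, phantom = phantom, lambda = props$lambda,
                 props = props, A = op$A, kappa = op$kappa,
                 operator_method = op$method),
            class = "fs_fluence")
}

#' @export
print.fs_fluence <- function(x, ...) {
  cat(sprintf("<fluence field @ %g nm>  %d cells, range [%.3g, %.3g] photons/s/mm^2\n",
              x$lambda %||% NA, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Sample a fluence field at arbitrary points
#'
#' Trilinear interpolation of the cell-centred field.  Points outside the
#' grid return 0 by default (the field there is below solver tolerance for
#' the slab geometries in scope); `strict = TRUE` raises an error instead.
#'
#' @param field An `fs_fluence`.
#' @param x,y,z Query coordinates (mm), recycled to a common length.
#' @param strict Error on out-of-grid queries instead of returning 0.
#' @return Numeric vector of fluence values.
#' @export
sample_fluence <- function(field, x, y, z, strict = FALSE) {
  ph <- field$phantom
  nn <- max(length(x), length(y), length(z))
  x <- rep_len(x, nn); y <- rep_len(y, nn); z <- rep_len(z, nn)
  h <- ph$h
  fx <- (x - ph$x[1]) / h + 1
  fy <- (y - ph$y[1]) / h + 1
  fz <- (z - ph$z[1]) / h + 1
  if (strict &&
      any(fx < 1 | fx > ph$nx | fy < 1 | fy > ph$ny | fz < 1 | fz > ph$nz))
    abort("Query points fall outside the cached fluence grid.")
  out <- numeric(nn)
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    i <- i0 + di; j <- j0 + dj; k <- k0 + dk
    ok <- i >= 1 & i <= ph$nx & j >= 1 & j <= ph$ny & k >= 1 & k <= ph$nz
    if (!any(ok)) next
    w <- (1 - abs(fx - i)) * (1 - abs(fy - j)) * (1 - abs(fz - k))
    idx <- i[ok] + (j[ok] - 1) * ph$nx + (k[ok] - 1) * ph$nx * ph$ny
    out[ok] <- out[ok] + w[ok] * field$values[idx]
  }
  out
}

#' Infinite-medium diffusion Green's function
#'
#' Closed-form CW fluence of an isotropic point source in an unbounded
#' homogeneous medium, \eqn{\Phi(r) = P e^{-\mu_{eff} r} / (4\pi\kappa r)}
#' with \eqn{\mu_{eff} = \sqrt{\mu_a/\kappa}}.  Used as the independent
#' oracle for solver validation.
#'
#' @param r Distance from the source, mm (> 0).
#' @param mua,musp Optical coefficients, mm^-1.
#' @param power Source power P, photons s^-1.
#' @return Fluence, photons s^-1 mm^-2.
#' @export
greens_infinite <- function(r, mua, musp, power = 1) {
  if (any(r <= 0)) abort("`r` must be > 0 (the Green's function is singular).")
  stopifnot(mua >= 0, musp > 0)
  kappa <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / kappa)
  power * exp(-mueff * r) / (4 * pi * kappa * r)
}

# --- boundary radiance ------------------------------------------------------

#' Surface radiance image on a slab face
#'
#' Converts the boundary fluence into detected radiance.  The face fluence is
#' recovered from the Robin closure of the boundary cell, the outward partial
#' current is \eqn{J^+ = \Phi_{face}/(2A)}, and the (Lambertian) radiance per
#' steradian is \eqn{J^+/(2\pi)}.  The per-steradian constant is a fixed
#' convention; every comparison made by the package (ratios, widths) is
#' insensitive to it.
#'
#' @param field An `fs_fluence` from [solve_diffusion()].
#' @param face `"bottom"` (entry face, reflection geometry) or `"top"`
#'   (opposite face, transmission geometry).
#' @param fov Field of view, either `c(lo, hi)` applied to both lateral axes
#'   or a list with `x` and `y` ranges; must lie within the slab face.
#' @return Object of class `fs_image`: radiance matrix (x by y) with the
#'   pixel-centre coordinates.
#' @export
surface_radiance <- function(field, face = c("bottom", "top"),
                             fov = c(-26, 26)) {
  face <- match.arg(face)
  ph <- field$phantom
  if (is.numeric(fov)) fov <- list(x = fov, y = fov)
  half <- ph$size / 2
  if (fov$x[1] < -half[1] - 1e-9 || fov$x[2] > half[1] + 1e-9 ||
      fov$y[1] < -half[2] - 1e-9 || fov$y[2] > half[2] + 1e-9)
    abort("`fov` extends outside the slab face.")
  sel_x <- which(ph$x >= fov$x[1] - 1e-9 & ph$x <= fov$x[2] + 1e-9)
  sel_y <- which(ph$y >= fov$y[1] - 1e-9 & ph$y <= fov$y[2] + 1e-9)
  k <- if (face == "bottom") 1L else ph$nz
  nxy <- ph$nx * ph$ny
  lin <- outer(sel_x, (sel_y - 1) * ph$nx, `+`) + (k - 1L) * nxy
  phi_cell <- matrix(field$values[lin], length(sel_x), length(sel_y))
  kap <- field$kappa[lin]
  A <- field$A
  fshare <- (4 * A * kap / ph$h) / (1 + 4 * A * kap / ph$h)
  phi_face <- phi_cell * fshare
  structure(list(values = phi_face / (2 * A) / (2 * pi),
                 x = ph$x[sel_x], y = ph$y[sel_y], h = ph$h,
                 face = face, lambda = field$lambda,
                 unit = "photons/s/mm^2/sr"),
            class = "fs_image")
}

#' @export
print.fs_image <- function(x, ...) {
  cat(sprintf("<surface image%s>  %d x %d px (h = %g mm), face %s, max %.3g %s\n",
              if (is.null(x$lambda)) "" else sprintf(" @ %g nm", x$lambda),
              length(x$x), length(x$y), x$h, x$face, max(x$values), x$unit))
  invisible(x)
}

#' Integrated disc-detector reading of an image
#'
#' Sums image values times pixel area over the pixels whose centres fall
#' inside the detector disc.
#'
#' @param image An `fs_image` (or `fs_scan`).
#' @param centre Detector centre (x, y), mm.
#' @param radius Detector radius, mm.
#' @return Single numeric reading (photons s^-1 for radiance images).
#' @export
detector_reading <- function(image, centre = c(0, 0), radius = 7.5) {
  xc <- image$x %||% image$sx
  yc <- image$y %||% image$sy
  m <- outer(xc - centre[1], yc - centre[2],
             function(a, b) a^2 + b^2 <= radius^2)
  sum(image$values[m]) * image$h^2
}
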