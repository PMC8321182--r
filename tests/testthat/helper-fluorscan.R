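# shared fixtures: everything is generated in code, no stored data.
# the operator cache inside the package makes repeated use of the same
# grid/wavelength combination cheap across test files.

# array comparison normalised by the expected peak: image/field magnitudes
# are ~1e-8, far below all.equal()'s default tolerance, so plain
# expect_equal would silently fall back to absolute comparison
expect_close <- function(actual, expected, tol = 1e-8) {
  testthat::expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}

mini_config <- make_mini_fixture()
mini_phantom <- function(targets = list(cylindrical_target(c(0, 0, 0)))) {
  slab_phantom(size = c(20, 20, 10), spacing = 1, targets = targets)
}

study_phantom <- function(z = 0, ...) slab_phantom(targets = two_targets(z = z), ...)

props_ex600 <- optical_properties(600)
props_em620 <- optical_properties(620)

# synthetic image container for analysis tests
make_image <- function(values, x, y, h = diff(x[1:2])) {
  structure(list(values = values, x = x, y = y, h = h, face = "bottom",
                 lambda = NA, unit = "a.u."), class = "fs_image")
}

gaussian_profile <- function(centres, sigma, coord = seq(-26, 26, 0.5),
                             amp = 1) {
  v <- rowSums(vapply(centres,
                      function(c0) amp * exp(-(coord - c0)^2 / (2 * sigma^2)),
                      numeric(length(coord))))
  tibble::tibble(coord = coord, value = v)
}
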