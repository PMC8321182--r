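test_that("zero source yields an identically zero field and image", {
  ph <- mini_phantom(targets = list())
  fl <- solve_diffusion(ph, props_ex600, point_source(power = 0))
  expect_equal(fl$values, rep(0, ph$nx * ph$ny * ph$nz))
  img <- surface_radiance(fl, "bottom", fov = c(-9, 9))
  expect_equal(max(abs(img$values)), 0)
})

test_that("the field is non-negative, symmetric and linear in source power", {
  ph <- mini_phantom(targets = list())
  fl <- solve_diffusion(ph, props_ex600, point_source(c(0, 0), power = 1))
  expect_true(all(fl$values >= 0))
  arr <- array(fl$values, c(ph$nx, ph$ny, ph$nz))
  # mirror symmetry under x -> -x and y -> -y for a centred source
  expect_close(arr, arr[ph$nx:1, , ], tol = 1e-8)
  expect_close(arr, arr[, ph$ny:1, ], tol = 1e-8)
  fl3 <- solve_diffusion(ph, props_ex600, point_source(c(0, 0), power = 3))
  expect_close(fl3$values, 3 * fl$values, tol = 1e-12)
})

test_that("solver matches the infinite-medium Green's function within 10%", {
  # large cube (boundaries ~12 mm from the source, many attenuation lengths)
  cube <- slab_phantom(size = c(25.5, 25.5, 25.5), spacing = 0.5,
                       targets = list())
  centre <- which(cube$labels == 0 &
                    abs(cell_centres(cube, seq_along(cube$labels))[, 1]) < 1e-9 &
                    abs(cell_centres(cube, seq_along(cube$labels))[, 2]) < 1e-9 &
                    abs(cell_centres(cube, seq_along(cube$labels))[, 3]) < 1e-9)
  expect_length(centre, 1)
  fl <- solve_diffusion(cube, props_ex600,
                        volume_source(cube, centre, 1 / cube$h^3))
  r <- c(2, 3, 4, 5, 6)
  got <- sample_fluence(fl, r, 0, 0)
  want <- greens_infinite(r, props_ex600$mua, props_ex600$musp)
  expect_lt(max(abs(got / want - 1)), 0.10)
})

test_that("the discrete operator is reciprocal", {
  ph <- mini_phantom(targets = list())
  a <- 1200L; b <- 2900L
  fa <- solve_diffusion(ph, props_em620, volume_source(ph, a, 1 / ph$h^3))
  fb <- solve_diffusion(ph, props_em620, volume_source(ph, b, 1 / ph$h^3))
  expect_lt(abs(fa$values[b] / fb$values[a] - 1), 1e-8)
})

test_that("uniformly increasing absorption decreases detected radiance", {
  ph <- mini_phantom(targets = list())
  tot <- function(mua) {
    p <- optical_properties(600, mua = mua)
    fl <- solve_diffusion(ph, p, point_source())
    sum(surface_radiance(fl, "top", fov = c(-9, 9))$values)
  }
  v <- vapply(c(0.05, 0.1, 0.2, 0.4), tot, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("a deeper source gives a dimmer, wider surface image", {
  ph <- mini_phantom(targets = list())
  peak_width <- function(z) {
    cell <- which(apply(cell_centres(ph, seq_along(ph$labels)), 1,
                        function(p) all(abs(p - c(0.5, 0.5, z)) < 1e-9)))
    fl <- solve_diffusion(ph, props_em620, volume_source(ph, cell, 1))
    img <- surface_radiance(fl, "bottom", fov = c(-9, 9))
    prof <- extract_profile(img, at = 0.5)
    c(peak = max(img$values), width = fwhm(prof, refine = 0.25))
  }
  shallow <- peak_width(-2.5)
  deep <- peak_width(1.5)
  expect_lt(deep["peak"], shallow["peak"])
  expect_gt(deep["width"], shallow["width"])
})

test_that("field sampling and radiance guards work", {
  ph <- mini_phantom(targets = list())
  fl <- solve_diffusion(ph, props_ex600, point_source())
  expect_equal(sample_fluence(fl, 50, 0, 0), 0)
  expect_error(sample_fluence(fl, 50, 0, 0, strict = TRUE), "outside")
  expect_error(surface_radiance(fl, "bottom", fov = c(-30, 30)), "fov|face")
  expect_error(greens_infinite(0, 0.1, 1), "singular")
  expect_true(all(diff(greens_infinite(1:10, 0.1, 1)) < 0))
})
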