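test_that("emission coefficient matches the hand-derived unit conversion", {
  eta <- emission_coefficient(fluorophore_params())
  # frozen values from independent hand calculation:
  # sigma = ln(10)*1000*2e4/6.022e23 cm^2 = 7.649e-21 m^2
  # eta = 0.6 * sigma[mm^2] * N0[mm^-3] = 4.588e-4 mm^-1
  # (ratio comparisons: the magnitudes are far below all.equal tolerances)
  expect_lt(abs(attr(eta, "cross_section_m2") / 7.649e-21 - 1), 1e-3)
  expect_lt(abs(as.numeric(eta) / 4.588e-4 - 1), 1e-3)
})

test_that("emission strength is linear in fluence and concentration", {
  expect_equal(emission_strength(0), 0)
  a <- emission_strength(c(1, 2, 5))
  expect_equal(a[2], 2 * a[1])
  fp2 <- fluorophore_params(concentration = 2e20)
  expect_equal(emission_strength(1, fp2), 2 * emission_strength(1))
  expect_error(emission_strength(-1), "non-negative")
  expect_error(fluorophore_params(quantum_yield = 1.3), "quantum_yield")
})

test_that("forward model returns zero without targets and positive with them", {
  ph0 <- mini_phantom(targets = list())
  img0 <- fluorescence_forward(ph0, props_ex600, props_em620,
                               disc_source(radius = 6), "reflection",
                               fov = c(-9, 9))
  expect_equal(max(abs(img0$values)), 0)
  ph <- mini_phantom()
  for (mode in c("reflection", "transmission")) {
    img <- fluorescence_forward(ph, props_ex600, props_em620,
                                disc_source(radius = 6), mode, fov = c(-9, 9))
    expect_gt(max(img$values), 0)
    expect_true(all(img$values >= 0))
  }
})

test_that("two-target response is the superposition of single-target responses", {
  t1 <- cylindrical_target(c(0, -3, 0))
  t2 <- cylindrical_target(c(0, 3, 0))
  run <- function(tg) fluorescence_forward(
    mini_phantom(targets = tg), props_ex600, props_em620,
    disc_source(radius = 6), "reflection", fov = c(-9, 9))$values
  joint <- run(list(t1, t2))
  expect_close(joint, run(list(t1)) + run(list(t2)), tol = 1e-10)
})

test_that("excitation fluence is independent of the emission wavelength", {
  ph <- mini_phantom()
  i1 <- fluorescence_forward(ph, props_ex600, props_em620,
                             disc_source(radius = 6), "reflection",
                             fov = c(-9, 9))
  i2 <- fluorescence_forward(ph, props_ex600, optical_properties(800),
                             disc_source(radius = 6), "reflection",
                             fov = c(-9, 9))
  expect_close(attr(i1, "fluence_ex")$values, attr(i2, "fluence_ex")$values,
               tol = 1e-12)
  # lower emission absorption at 800 nm lets substantially more light out
  expect_gt(max(i2$values) / max(i1$values), 1.2)
})

test_that("autofluorescence background scales with beta and stays smooth", {
  ph <- mini_phantom(targets = list())
  img0 <- autofluorescence_forward(ph, props_ex600, props_em620,
                                   disc_source(radius = 6), "reflection",
                                   af = autofluor_params(beta = 0),
                                   fov = c(-9, 9))
  expect_equal(max(abs(img0$values)), 0)
  img1 <- autofluorescence_forward(ph, props_ex600, props_em620,
                                   disc_source(radius = 6), "reflection",
                                   af = autofluor_params(beta = 1e-4),
                                   fov = c(-9, 9))
  img2 <- autofluorescence_forward(ph, props_ex600, props_em620,
                                   disc_source(radius = 6), "reflection",
                                   af = autofluor_params(beta = 2e-4),
                                   fov = c(-9, 9))
  expect_close(img2$values, 2 * img1$values, tol = 1e-12)
  # smooth background: single central hump, no two-peak structure
  prof <- extract_profile(img1, at = 0.5)
  expect_error(sparrow_resolution(img1), "unresolved|peaks")
  expect_equal(which.max(prof$value), which.min(abs(prof$coord - 0.5)),
               tolerance = 1)
  expect_error(autofluor_params(beta = -1), "beta")
  expect_error(
    autofluorescence_forward(ph, props_ex600, props_em620,
                             af = autofluor_params(1e-4, spacing = 0.5),
                             fov = c(-9, 9)),
    "spacing")
  expect_error(
    autofluorescence_forward(ph, props_ex600, props_em620,
                             af = autofluor_params(1e-4, spacing = 30),
                             fov = c(-9, 9)),
    "coarser")
})
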