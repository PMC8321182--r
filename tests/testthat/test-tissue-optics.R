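test_that("power-law reduced scattering reproduces the reference values", {
  expect_equal(round(reduced_scattering(600), 2), 1.49)
  expect_equal(round(reduced_scattering(620), 2), 1.43)
  # at the 500 nm pivot the law returns `a` for any scattering power
  for (a in c(0.5, 1.89, 3)) for (b in c(0, 0.7, 1.286, 2.5))
    expect_equal(reduced_scattering(500, scattering_params(a, b)), a)
})

test_that("reduced scattering is positive and monotone decreasing in wavelength", {
  lam <- seq(400, 1000, by = 5)
  mu <- reduced_scattering(lam)
  expect_true(all(mu > 0))
  expect_true(all(diff(mu) < 0))
  # b = 0 gives a flat spectrum
  expect_equal(diff(range(reduced_scattering(lam, scattering_params(b = 0)))), 0)
  expect_error(reduced_scattering(-10), "positive")
  expect_error(scattering_params(a = 0), "positive")
})

test_that("absorption sums chromophores linearly and respects the table range", {
  none <- tissue_composition(blood = 0)
  for (lam in c(500, 633, 808, 1000)) expect_equal(absorption(lam, none), 0)
  base <- tissue_composition(blood = 0.03, saturation = 0.7)
  dbl <- tissue_composition(blood = 0.06, saturation = 0.7)
  lam <- c(550, 600, 750, 900)
  expect_equal(absorption(lam, dbl), 2 * absorption(lam, base))
  # saturation mixes the two blood spectra linearly
  s0 <- tissue_composition(blood = 0.05, saturation = 0)
  s1 <- tissue_composition(blood = 0.05, saturation = 1)
  s05 <- tissue_composition(blood = 0.05, saturation = 0.5)
  expect_equal(absorption(700, s05),
               (absorption(700, s0) + absorption(700, s1)) / 2)
  expect_error(absorption(450, base), "range")
  expect_error(absorption(1100, base), "range")
  expect_error(tissue_composition(blood = 1.2), "blood")
})

test_that("default composition reproduces the tabulated tissue absorption anchors", {
  anchors <- c(`600` = 0.1504, `620` = 0.0563, `700` = 0.0162,
               `800` = 0.0220, `900` = 0.0304, `1000` = 0.0236)
  got <- absorption(as.numeric(names(anchors)))
  expect_equal(unname(got), unname(anchors), tolerance = 1e-4)
})

test_that("optical_properties packages coefficients with the kappa identity", {
  p <- optical_properties(600)
  expect_equal(p$kappa, 1 / (3 * (p$mua + p$musp)))
  expect_equal(round(p$mua, 4), 0.1504)
  expect_equal(round(p$musp, 2), 1.49)
  # independent arithmetic for the 700 nm emission override
  p7 <- optical_properties(700, mua = 0.0162)
  musp7 <- 1.89 * (700 / 500)^(-1.286)
  expect_equal(p7$musp, musp7)
  expect_equal(p7$kappa, 1 / (3 * (0.0162 + musp7)))
  # zero-absorption limit
  p0 <- optical_properties(800, mua = 0)
  expect_equal(p0$kappa, 1 / (3 * p0$musp))
  expect_error(optical_properties(600, mua = -0.1), "mua")
  expect_error(optical_properties(600, musp = 0), "musp")
})

test_that("custom chromophore tables are validated", {
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = c(600, 550), mua_oxy = 1,
                       mua_deoxy = 1), bad, row.names = FALSE)
  expect_error(chromophore_table(bad), "increasing")
  write.csv(data.frame(wavelength_nm = c(500, 600), mua_wrong = 1), bad,
            row.names = FALSE)
  expect_error(chromophore_table(bad), "columns")
  tab <- chromophore_table()
  expect_s3_class(tab, "fs_chromophores")
  expect_true(min(tab$wavelength_nm) <= 500 && max(tab$wavelength_nm) >= 1000)
})
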