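test_that("Debye function matches closed-form values and the integral oracle", {
  expect_identical(debye_form_factor(0, 2.5), 1)
  # x = (q Rg)^2 = 1 at q = 1/25 Ang^-1 for Rg = 2.5 nm
  expect_equal(debye_form_factor(1 / 25, 2.5), 2 / exp(1), tolerance = 1e-10)
  # x = 100: asymptote 2 (x - 1) / x^2
  expect_equal(debye_form_factor(10 / 25, 2.5), 0.0198, tolerance = 1e-6)

  x <- exp(seq(log(0.01), log(100), length.out = 40))
  q <- sqrt(x) / 25
  expect_equal(debye_form_factor(q, 2.5), debye_oracle(x), tolerance = 1e-6)

  # monotone decreasing, bounded in (0, 1]
  p <- debye_form_factor(saxs_qgrid(), 2.5)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(debye_form_factor(0.1, -1), "rg")
})

test_that("Percus-Yevick structure factor has exact limits", {
  expect_identical(py_structure_factor(saxs_qgrid(20), 10, 0), rep(1, 20))
  for (phi in seq(0.05, 0.5, by = 0.05)) {
    expect_equal(py_structure_factor(0, 10, phi), py_s0_oracle(phi),
                 tolerance = 1e-10)
  }
  expect_equal(py_structure_factor(0, 10, 0.3), 0.0938, tolerance = 1e-3)
  # high-q decay to the ideal-gas limit: q * r = 50
  expect_lt(abs(py_structure_factor(50 / 100, 10, 0.3) - 1), 0.02)
  # continuity across the small-argument series switch (A = 0.3)
  q_switch <- 0.3 / (2 * 100)
  expect_equal(py_structure_factor(q_switch * (1 - 1e-6), 10, 0.3),
               py_structure_factor(q_switch * (1 + 1e-6), 10, 0.3),
               tolerance = 1e-6)
  expect_error(py_structure_factor(0.1, 10, 0.8), "0.74")
})

test_that("dumbbell model isolates its terms and keeps the sphere zero", {
  q <- seq(0.001, 0.1, by = 1e-4)
  # peptide terms off -> pure globule = scale * P_sphere * S_PY
  glob <- dumbbell_intensity(q, i1 = 0, i2 = 0, r_globule = 10, poly = 0,
                             phi_hs = 0.2, scale = 3)
  expect_equal(glob,
               3 * sphere_form_factor(q, 10) * py_structure_factor(q, 10, 0.2),
               tolerance = 1e-12)
  # phi_hs = 0, poly = 0: monodisperse sphere form factor, first zero at
  # q R = 4.493
  mono <- dumbbell_intensity(q, i1 = 0, i2 = 0, r_globule = 10, poly = 0,
                             phi_hs = 0, scale = 1)
  first_min <- q[which(diff(sign(diff(mono))) > 0)[1] + 1]
  expect_equal(first_min * 100, 4.493, tolerance = 1e-2)
  # polydispersity fills the zero in
  poly <- dumbbell_intensity(q, i1 = 0, i2 = 0, r_globule = 10, poly = 0.2,
                             phi_hs = 0, scale = 1)
  expect_gt(min(poly), min(mono))
  # full model keeps the two-regime shape: low-q power-law rise over the
  # lorentzian plateau, globule shoulder at intermediate q
  full <- dumbbell_intensity(saxs_qgrid())
  expect_true(all(is.finite(full)) && all(full > 0))
  expect_gt(full[1], dumbbell_intensity(saxs_qgrid(), i2 = 0)[1])
})

test_that("Guinier analysis recovers exact data and bounds cluster sizes", {
  # model-matched data: machine-precision recovery
  q <- seq(0.001, 0.02, length.out = 30)
  g <- guinier_fit(scattering_curve(q, 100 * exp(-q^2 * 30^2 / 3)))
  expect_equal(g$rg, 3.0, tolerance = 1e-8)
  expect_equal(g$i0, 100, tolerance = 1e-8)
  expect_false(g$is_lower_bound)

  # Debye curve analysed at q Rg < 1: small documented low bias (< 5%)
  cu <- scattering_curve(saxs_qgrid(), gaussian_coil_intensity(saxs_qgrid(), 2.5, 10))
  gd <- guinier_fit(cu)
  expect_lt(abs(gd$rg - 2.5) / 2.5, 0.05)
  expect_lt(gd$rg, 2.5)   # bias is towards smaller Rg

  # cluster whose size exceeds the window: lower-bound flag, like the
  # reported Rg >= 185 nm
  rg_big <- 2000  # Ang = 200 nm
  qlow <- saxs_qgrid()[1:20]
  big <- scattering_curve(qlow, 1e3 * exp(-qlow^2 * rg_big^2 / 3))
  gb <- guinier_fit(big)
  expect_true(gb$is_lower_bound)
  expect_gt(gb$rg, 100)  # nm; a genuine lower bound on a huge object
})

test_that("power-law fits recover exponents and classify fractal bands", {
  q <- saxs_qgrid()
  surf <- power_law_fit(scattering_curve(q, 2 * q^-3.7))
  expect_equal(surf$exponent, -3.7, tolerance = 1e-6)
  expect_identical(surf$fractal_class, "surface")

  mass <- power_law_fit(scattering_curve(q, 5 * q^-2.7))
  expect_identical(mass$fractal_class, "mass")

  flat <- power_law_fit(scattering_curve(q, rep(3, length(q))))
  expect_lt(abs(flat$exponent), 1e-8)
  expect_identical(flat$fractal_class, "other")

  # invariance under multiplicative rescaling
  a <- power_law_fit(scattering_curve(q, 2 * q^-3.2))
  b <- power_law_fit(scattering_curve(q, 2e4 * q^-3.2))
  expect_equal(a$exponent, b$exponent, tolerance = 1e-10)

  expect_error(power_law_fit(scattering_curve(q, q - 0.01)), "positive")
})

test_that("coil fits recover Rg from clean and noisy data", {
  q <- saxs_qgrid(100)
  clean <- scattering_curve(q, gaussian_coil_intensity(q, 2.5, 100))
  f <- fit_gaussian_coil(clean, rg = 4)
  expect_true(f$converged)
  expect_lt(abs(f$params[["rg"]] - 2.5) / 2.5, 1e-3)

  # Monte-Carlo: 2% noise, 10 seeds, mean within 2% of truth
  rgs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      noisy <- scattering_curve(q, gaussian_coil_intensity(q, 2.5, 100) *
                                  (1 + rnorm(length(q), 0, 0.02)),
                                sigma = 0.02 * gaussian_coil_intensity(q, 2.5, 100))
      fit_gaussian_coil(noisy, rg = 4)$params[["rg"]]
    })
  }, numeric(1))
  expect_lt(abs(mean(rgs) - 2.5) / 2.5, 0.02)

  # constant curve: Rg unidentifiable
  const <- scattering_curve(q, rep(5, length(q)))
  fc <- fit_gaussian_coil(const, rg = 4)
  expect_true(!fc$converged ||
                !is.finite(fc$stderr[["rg"]]) ||
                fc$stderr[["rg"]] > fc$params[["rg"]])
})

test_that("mixture model is linear, exact, and refuses mismatched grids", {
  q <- saxs_qgrid(50)
  i1 <- 2 * q^-1.5
  i2 <- gaussian_coil_intensity(q, 2.5, 10)
  expect_identical(mixture_model(i1, i2, 0), i1)
  expect_equal(mixture_model(i1, i2, 2), i1 + 2 * i2, tolerance = 1e-15)
  # linearity: mix(a1) + mix(a2) - I_PGM = mix(a1 + a2)
  expect_equal(mixture_model(i1, i2, 1) + mixture_model(i1, i2, 2) - i1,
               mixture_model(i1, i2, 3), tolerance = 1e-12)
  c1 <- scattering_curve(q, i1)
  c2 <- scattering_curve(q * 1.01, i2)
  expect_error(mixture_model(c1, c2, 1), "same q grid")
})
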