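test_that("dissipation factor follows the ring-down relation", {
  expect_identical(dissipation_factor(5e6, 2e-4), 1e-3)
  expect_equal(dissipation_factor(1e7, 2e-4), 5e-4)       # doubling f halves D
  expect_lt(dissipation_factor(5e6, 1e6), 1e-12)          # lossless limit
  expect_equal(dissipation_factor(5e6, 2e-4, pi_convention = TRUE),
               1e-3 / pi)
  expect_error(dissipation_factor(-1, 1), "> 0")
})

test_that("Sauerbrey constant reproduces the 5 MHz AT-cut value and scaling", {
  C <- sauerbrey_constant(5e6, 2648, 2.947e10)
  expect_equal(signif(C, 3), 17.7)
  expect_equal(sauerbrey_constant(1e7, 2648, 2.947e10), C / 4,
               tolerance = 1e-12)
})

test_that("Sauerbrey mass and thickness arithmetic is honest", {
  expect_equal(sauerbrey_mass(-1, 1, 17.7), 17.7)
  expect_identical(sauerbrey_mass(0, 3), 0)
  expect_error(sauerbrey_mass(-1, 2), "odd")
  # mass sign opposite to delta f; linear round trip in delta f
  C <- sauerbrey_constant()
  d1 <- thickness_from_mass(sauerbrey_mass(-2, 3, C), 1.05)
  d2 <- thickness_from_mass(sauerbrey_mass(-4, 3, C), 1.05)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_equal(thickness_from_mass(210, 1.05), 20)
  # the mucin-step mass of 55 ng/cm^2 at 1.05 g/cm^3 gives ~5 Ang, not 20
  expect_equal(thickness_from_mass(55, 1.05), 5.24, tolerance = 1e-2)
  expect_error(thickness_from_mass(10, -1), "rho")
})

test_that("noise-free staircase traces segment exactly", {
  steps <- tibble::tibble(label = c("baseline", "adsorb", "rinse1"),
                          df_per_n = c(0, -4, -3), dd = c(0, 0.2, 0.15))
  tr <- make_qcmd_trace(steps, durations = 400, tau = 10,
                        noise = noise_spec(level = 1e-12, seed = 1))
  st <- segment_trace(tr, attr(tr, "events"))
  sm <- step_masses(st)
  expect_equal(sm$delta_f_norm, c(0, -4, 1), tolerance = 1e-3)
  # desorption on rinse is a negative mass change
  expect_lt(sm$mass_areal[3], 0)
  # ideal rigid film: delta_f / n identical across overtones
  expect_lt(max(abs(st$harmonic_spread)), 1e-6)
})

test_that("segmentation is robust to time shifts and small noise", {
  steps <- tibble::tibble(label = c("baseline", "adsorb"),
                          df_per_n = c(0, -5), dd = c(0, 0.2))
  tr <- make_qcmd_trace(steps, durations = 500, tau = 20,
                        noise = noise_spec(level = 0.03, seed = 4))
  st <- segment_trace(tr, attr(tr, "events"))
  base <- step_masses(st)$delta_f_norm[2]

  shifted <- tr
  shifted$data$time <- shifted$data$time + 1234
  ev <- attr(tr, "events")
  ev$time <- ev$time + 1234
  st2 <- segment_trace(qcmd_trace(shifted$data), ev)
  expect_equal(step_masses(st2)$delta_f_norm[2], base, tolerance = 1e-10)
  expect_equal(base, -5, tolerance = 0.01)  # noise ~0.6% of step height
})

test_that("rigidity criterion is inclusive at the threshold", {
  steps <- tibble::tibble(label = c("baseline", "soft", "edge"),
                          df_per_n = c(0, -5, -6), dd = c(0, 2, 2.5))
  tr <- make_qcmd_trace(steps, durations = 400, tau = 5,
                        noise = noise_spec(level = 1e-13, seed = 1))
  st <- segment_trace(tr, attr(tr, "events"))
  rc <- rigidity_check(st, dd_threshold = 0.5)
  expect_false(rc$rigid_film_ok[rc$label == "soft"])    # delta D = 2
  expect_true(rigidity_check(st, dd_threshold = 2.05)$rigid_film_ok[2])
  # exactly at the threshold counts as rigid (inclusive boundary)
  exact <- tibble::tibble(step = 1L, label = "edge", delta_d = 0.5)
  expect_true(rigidity_check(exact, dd_threshold = 0.5)$rigid_film_ok)
  expect_false(rigidity_check(exact, dd_threshold = 0.5 - 1e-9)$rigid_film_ok)
})

test_that("QCM-D CSV round-trips through the wide instrument format", {
  tr <- make_qcmd_trace(noise = noise_spec(level = 0.05, seed = 2),
                        durations = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_qcmd(tr, path)
  back <- read_qcmd(path)
  expect_equal(back$overtones, tr$overtones)
  expect_equal(back$data$delta_f, tr$data$delta_f, tolerance = 1e-9)
})
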