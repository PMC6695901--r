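test_that("bare-interface reflectivity equals the closed-form Fresnel law", {
  bare <- layer_stack(backing = solvent(1), backing_roughness = 0)
  q <- seq(0.002, 0.3, length.out = 500)
  R <- abeles_reflectivity(bare, q)
  Rf <- fresnel_oracle(q, 2.07e-6, solvent(1)$sld)
  expect_lt(max(abs(R - Rf) / Rf), 1e-10)
  # total reflection below the critical edge
  qc <- critical_q(2.07e-6, solvent(1)$sld)
  expect_equal(qc, 0.01468, tolerance = 1e-3)
  expect_true(all(abs(R[q < qc] - 1) < 1e-10))
})

test_that("slabs matching the backing SLD are invisible", {
  sv <- solvent(1)
  bare <- layer_stack(backing = sv, backing_roughness = 0)
  ghost <- layer_stack(
    slabs = dplyr::bind_rows(
      slab("g1", 40, sld_h = sv$sld, roughness = 0),
      slab("g2", 15, sld_h = sv$sld, roughness = 0)
    ),
    backing = sv, backing_roughness = 0
  )
  q <- exp(seq(log(0.005), log(0.25), length.out = 120))
  expect_equal(abeles_reflectivity(ghost, q), abeles_reflectivity(bare, q),
               tolerance = 1e-12)
})

test_that("reflectivity respects the energy bound on randomized stacks", {
  q <- exp(seq(log(0.003), log(0.3), length.out = 80))
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(1:5, 1)
      stk <- suppressWarnings(layer_stack(
        slabs = dplyr::bind_rows(lapply(seq_len(n), function(j) {
          slab(paste0("s", j), runif(1, 5, 150),
               sld_h = runif(1, -0.5e-6, 7e-6),
               roughness = runif(1, 0, 3))
        })),
        fronting_sld = 2.07e-6,
        backing = runif(1, -0.56e-6, 6.36e-6),
        backing_roughness = runif(1, 0, 3)
      ))
      R <- abeles_reflectivity(stk, q)
      expect_true(all(R >= 0 & R <= 1))
    }
  })
})

test_that("reflectivity is reciprocal under stack reversal above both edges", {
  # the same physical wave approached from the other side: q is defined in
  # the fronting medium, so the reversed stack is probed at
  # q' = 2 sqrt((q/2)^2 - 4 pi (rho_new_front - rho_old_front))
  rho_a <- 2.07e-6
  rho_b <- 4e-6
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(1:4, 1)
      th <- runif(n, 10, 80)
      sl <- runif(n, 0, 6e-6)
      fwd <- layer_stack(
        slabs = dplyr::bind_rows(lapply(seq_len(n), function(j)
          slab(paste0("s", j), th[j], sld_h = sl[j], roughness = 0))),
        fronting_sld = rho_a, backing = rho_b, backing_roughness = 0
      )
      rev <- layer_stack(
        slabs = dplyr::bind_rows(lapply(rev(seq_len(n)), function(j)
          slab(paste0("s", j), th[j], sld_h = sl[j], roughness = 0))),
        fronting_sld = rho_b, backing = rho_a, backing_roughness = 0
      )
      q <- seq(0.03, 0.3, length.out = 60)  # above both critical edges
      q_rev <- 2 * sqrt((q / 2)^2 - 4 * pi * (rho_b - rho_a))
      expect_equal(abeles_reflectivity(rev, q_rev),
                   abeles_reflectivity(fwd, q), tolerance = 1e-9)
    }
  })
})

test_that("Nevot-Croce with zero roughness equals the sharp result; damping is monotone", {
  stk0 <- layer_stack(slabs = slab("f", 30, sld_h = 4e-6, roughness = 0),
                      backing = solvent(1), backing_roughness = 0)
  stk3 <- layer_stack(slabs = slab("f", 30, sld_h = 4e-6, roughness = 3),
                      backing = solvent(1), backing_roughness = 3)
  q <- seq(0.02, 0.3, length.out = 100)
  R0 <- abeles_reflectivity(stk0, q)
  expect_identical(R0, abeles_reflectivity(stk0, q))  # deterministic
  expect_true(all(abeles_reflectivity(stk3, q) <= R0 + 1e-15))
})

test_that("kinematic reflectivity agrees with the matrix method off the edge", {
  stk <- layer_stack(slabs = slab("film", 30, sld_h = 2.97e-6, roughness = 0),
                     fronting_sld = 2.07e-6, backing = 3.07e-6,
                     backing_roughness = 0)
  qc <- critical_q(2.07e-6, 3.07e-6)
  q <- seq(3 * qc, 0.25, length.out = 300)
  Ra <- abeles_reflectivity(stk, q)
  Rb <- born_reflectivity(stk, q)
  expect_lt(max(abs(Rb - Ra) / Ra), 0.05)
  # q^-4 asymptote for a sharp single interface
  bare <- layer_stack(fronting_sld = 2.07e-6, backing = 3.07e-6,
                      backing_roughness = 0)
  qa <- c(0.1, 0.2)
  rb <- born_reflectivity(bare, qa, refraction = "none")
  expect_equal(rb[1] / rb[2], 16, tolerance = 1e-10)
  expect_equal(rb, 16 * pi^2 * (1e-6)^2 / qa^4, tolerance = 1e-10)
  # uniform profile: no contrast, no reflection
  flat <- layer_stack(slabs = slab("same", 50, sld_h = 2.07e-6, roughness = 0),
                      fronting_sld = 2.07e-6, backing = 2.07e-6,
                      backing_roughness = 0)
  expect_equal(born_reflectivity(flat, qa, refraction = "none"), c(0, 0))
})

test_that("resolution smearing is the identity at zero width and damps fringes", {
  stk <- layer_stack(slabs = slab("thick", 300, sld_h = 4.5e-6, roughness = 0),
                     backing = solvent(0), backing_roughness = 0)
  q <- exp(seq(log(0.008), log(0.15), length.out = 400))
  R <- abeles_reflectivity(stk, q)
  expect_identical(smear(R, q, 0), R)
  # constant curves are preserved by the convolution
  expect_equal(smear(rep(0.7, 100),
                     exp(seq(log(0.01), log(0.2), length.out = 100)), 0.1),
               rep(0.7, 100), tolerance = 1e-10)
  # fringe minima rise monotonically with the resolution width
  min_in <- function(r) min(r[q > 0.05 & q < 0.08])
  m <- vapply(c(0, 0.05, 0.1, 0.15), function(dq)
    min_in(reflectivity_model(stk, q, dq_over_q = dq)), numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("scenario stacks carry the published layer picture", {
  bm <- stack_scenario("bare_mucin", solvent(1))
  expect_equal(backing_sld <- resolve_stack(bm)$sld[2],
               hydrated_layer_sld(5.09e-6, 0.6, solvent(1)),
               tolerance = 1e-9)
  # mucin layer SLD in D2O close to the fitted 5.6e-6
  expect_equal(resolve_stack(bm)$sld[2], 5.6e-6, tolerance = 0.02)
  expect_equal(bm$slabs$thickness[bm$slabs$label == "mucin"], 22)

  rinsed <- stack_scenario("mucin_polymer", solvent(1), rinsed = TRUE)
  mu <- rinsed$slabs[rinsed$slabs$label == "mucin", ]
  expect_equal(mu$thickness, 20)
  expect_equal(mu$phi, 0.50)  # solvent content risen to 50%

  gm1 <- stack_scenario("dppc_gm1_mucin", solvent(1))
  expect_identical(gm1$slabs$label,
                   c("SiO2", "water_gap", "heads_in", "tails", "heads_out",
                     "mucin"))
  expect_equal(gm1$slabs$thickness[gm1$slabs$label == "mucin"], 30)

  poly <- stack_scenario("dppc_gm1_mucin_polymer", solvent(1))
  expect_equal(poly$slabs$thickness[poly$slabs$label == "polymer"], 70)
  expect_lt(poly$slabs$phi[poly$slabs$label == "polymer"], 0.3)  # highly hydrated

  expect_error(stack_scenario("nope"), "Valid names")
})

test_that("a 22 Ang film puts its first Kiessig fringe beyond the window", {
  # fringe spacing 2 pi / d = 0.286 Ang^-1 > the 0.25 Ang^-1 limit
  expect_gt(2 * pi / 22, 0.25)
  film <- layer_stack(slabs = slab("mucin", 22, sld_h = 2.5e-6, roughness = 0),
                      backing = solvent(0), backing_roughness = 0)
  q <- exp(seq(log(0.008), log(0.25), length.out = 200))
  R <- abeles_reflectivity(film, q)
  # monotone decay: no interference minimum inside the measured window
  expect_true(all(diff(R) < 0))
})

test_that("co-refinement recovers structure and contrast variation helps", {
  nr <- make_nr_dataset("bare_mucin", noise = noise_spec(level = 0.01, seed = 3))
  tmpl <- nr$template
  tmpl$slabs$thickness[tmpl$slabs$label == "mucin"] <- 28
  tmpl$slabs$phi[tmpl$slabs$label == "mucin"] <- 0.45
  free2 <- c("mucin.thickness", "mucin.phi", "scale.h2o", "scale.d2o")
  fit2 <- corefine(contrast_series(tmpl, nr$contrasts), free2,
                   multistart = 3, seed = 3)
  expect_true(fit2$converged)
  expect_lt(abs(fit2$params[["mucin.thickness"]] - 22), 1)
  expect_lt(abs(fit2$params[["mucin.phi"]] - 0.60), 0.05)
  expect_named(fit2$chi2_per_contrast, c("h2o", "d2o"))
  expect_equal(sum(fit2$chi2_per_contrast), fit2$chi2, tolerance = 1e-6)

  # single-contrast fit: phi is less well determined than with two contrasts
  fit1 <- corefine(contrast_series(tmpl, nr$contrasts["d2o"]),
                   c("mucin.thickness", "mucin.phi", "scale.d2o"),
                   multistart = 3, seed = 3)
  expect_gt(fit1$stderr[["mucin.phi"]], fit2$stderr[["mucin.phi"]])

  # thickness fixed at truth, only phi free: recovery to noise level
  tmpl3 <- nr$template
  fit3 <- corefine(contrast_series(tmpl3, nr$contrasts), "mucin.phi",
                   multistart = 1, seed = 1)
  expect_lt(abs(fit3$params[["mucin.phi"]] - 0.60), 0.02)
})

test_that("noiseless data give chi-square near zero at the truth", {
  stk <- stack_scenario("bare_mucin")
  q <- exp(seq(log(0.008), log(0.25), length.out = 60))
  contrasts <- lapply(list(h2o = solvent(0), d2o = solvent(1)), function(sv) {
    list(solvent = sv,
         curve = scattering_curve(q, reflectivity_model(stk, q, sv, 0.1),
                                  kind = "reflectivity"))
  })
  tmpl <- stk
  tmpl$slabs$thickness[tmpl$slabs$label == "mucin"] <- 26
  fit <- corefine(contrast_series(tmpl, contrasts),
                  c("mucin.thickness", "mucin.phi"), multistart = 1, seed = 1)
  expect_lt(fit$chi2, 1e-10)
  expect_lt(abs(fit$params[["mucin.thickness"]] - 22), 0.01)
  expect_lt(abs(fit$params[["mucin.phi"]] - 0.60), 0.001)
})

test_that("tidy and glance expose fit results in broom style", {
  nr <- make_nr_dataset("bare_mucin", noise = noise_spec(level = 0.01, seed = 5))
  fit <- corefine(nr, c("mucin.thickness", "mucin.phi"), multistart = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_identical(td$term, c("mucin.thickness", "mucin.phi"))
  gl <- glance(fit)
  expect_identical(gl$n.points, fit$n_points)
  expect_true(gl$converged)
})

test_that("SLD profiles step through the stack with smooth interfaces", {
  stk <- stack_scenario("bare_mucin", solvent(1))
  prof <- sld_profile(stk)
  expect_equal(prof$sld[1], 2.07e-6, tolerance = 1e-8)          # silicon side
  expect_equal(prof$sld[nrow(prof)], solvent(1)$sld, tolerance = 1e-7)
  mid <- prof$sld[prof$z > 2 & prof$z < 10]                     # inside SiO2
  expect_equal(median(mid), 3.47e-6, tolerance = 0.02)
})
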