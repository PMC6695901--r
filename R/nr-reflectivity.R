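# Parratt/optical-matrix recursion over a resolved slab profile.
# q in 1/Ang; rho vectors in 1/Ang^2. Vectorised over q.
reflectivity_profile <- function(q, rho_front, rho_back, thickness, rho,
                                 roughness, backing_roughness) {
  nq <- length(q)
  k0 <- q / 2
  rhos <- c(rho_front, rho, rho_back)
  sig <- c(roughness, backing_roughness)  # interface j / j+1 sigma
  nlay <- length(rhos)
  # wavevector in each medium, complex for evanescent regions
  k <- matrix(0 + 0i, nrow = nq, ncol = nlay)
  for (j in seq_len(nlay)) {
    k[, j] <- sqrt(as.complex(k0^2 - 4 * pi * (rhos[j] - rho_front)))
  }
  # recursion from the backing interface upwards
  X <- {
    kj <- k[, nlay - 1]; kj1 <- k[, nlay]
    (kj - kj1) / (kj + kj1) * exp(-2 * kj * kj1 * sig[nlay - 1]^2)
  }
  if (nlay > 2) {
    for (j in seq(nlay - 2, 1)) {
      kj <- k[, j]; kj1 <- k[, j + 1]
      r <- (kj - kj1) / (kj + kj1) * exp(-2 * kj * kj1 * sig[j]^2)
      ph <- exp(2i * kj1 * thickness[j])
      X <- (r + X * ph) / (1 + r * X * ph)
    }
  }
  pmin(Mod(X)^2, 1)
}

#' Specular reflectivity by the optical matrix (Parratt) method
#'
#' Exact recursive computation of R(q) for a stack of homogeneous slabs,
#' with Gaussian interfacial roughness included by Nevot-Croce damping of
#' each Fresnel coefficient, exp(-2 k_j k_j+1 sigma^2). The beam enters
#' through the fronting (silicon); each layer's normal wavevector is
#' k_j = sqrt((q/2)^2 - 4 pi (rho_j - rho_fronting)). Below the critical
#' edge q_c = sqrt(16 pi (rho_backing - rho_fronting)) total reflection
#' gives R = 1; everywhere 0 <= R <= 1. Roughness zero reproduces the
#' sharp-interface result exactly.
#'
#' @param stack A [layer_stack()], or a resolved profile from
#'   [resolve_stack()].
#' @param q Momentum transfer grid, 1/Angstrom (> 0).
#' @param solv Optional [solvent()] overriding the stack's backing.
#' @return Reflectivity vector R(q).
#' @examples
#' bare <- layer_stack(backing = solvent(1))
#' abeles_reflectivity(bare, c(0.01, 0.02, 0.1))
#' @export
abeles_reflectivity <- function(stack, q, solv = NULL) {
  prof <- if (inherits(stack, "layer_stack")) resolve_stack(stack, solv) else stack
  if (any(q <= 0)) abort("`q` must be > 0.")
  reflectivity_profile(
    q,
    attr(prof, "fronting_sld"), attr(prof, "backing_sld"),
    prof$thickness, prof$sld, prof$roughness,
    attr(prof, "backing_roughness")
  )
}

#' Kinematic (Born-approximation) reflectivity
#'
#' The single-scattering approximation relates R(q) to the Fourier
#' transform of the SLD profile: for a piecewise-constant profile with
#' Gaussian-smoothed interfaces,
#' `R = 16 pi^2 / (q^2 q'^2) * |sum_i drho_i exp(i q z_i) exp(-q^2 sigma_i^2 / 2)|^2`,
#' where drho_i are the SLD steps at depths z_i. By default the
#' denominator uses the refraction-corrected q'^2 = q^2 - q_c^2 from the
#' fronting/backing critical edge (a standard distorted-wave
#' substitution that extends validity towards the edge);
#' `refraction = "none"` gives the raw kinematic 1/q^4 form. A uniform
#' profile returns 0; a single sharp interface decays as q^-4.
#' Valid well above the critical edge only.
#'
#' @inheritParams abeles_reflectivity
#' @param refraction `"fronting-backing"` (default) or `"none"`.
#' @return Reflectivity vector (clipped at 1).
#' @export
born_reflectivity <- function(stack, q, solv = NULL,
                              refraction = c("fronting-backing", "none")) {
  refraction <- match.arg(refraction)
  prof <- if (inherits(stack, "layer_stack")) resolve_stack(stack, solv) else stack
  if (any(q <= 0)) abort("`q` must be > 0.")
  rho <- c(attr(prof, "fronting_sld"), prof$sld, attr(prof, "backing_sld"))
  z <- cumsum(c(0, prof$thickness))
  sig <- c(prof$roughness, attr(prof, "backing_roughness"))
  drho <- diff(rho)
  amp <- rep(0 + 0i, length(q))
  for (i in seq_along(drho)) {
    amp <- amp + drho[i] * exp(1i * q * z[i]) * exp(-q^2 * sig[i]^2 / 2)
  }
  q2eff <- q^2
  if (refraction == "fronting-backing") {
    drho_fb <- attr(prof, "backing_sld") - attr(prof, "fronting_sld")
    if (drho_fb > 0) {
      qc2 <- 16 * pi * drho_fb
      q2eff <- q^2 - qc2
      q2eff[q2eff <= 0] <- NA_real_  # below the edge the form is meaningless
    }
  }
  r <- 16 * pi^2 * Mod(amp)^2 / (q^2 * q2eff)
  pmin(r, 1)
}

#' Critical edge of total external reflection
#'
#' `q_c = sqrt(16 pi (rho_backing - rho_fronting))`; defined only when
#' the backing SLD exceeds the fronting SLD.
#'
#' @param rho_front,rho_back SLDs in 1/Ang^2.
#' @return q_c in 1/Angstrom (NA when no edge exists).
#' @examples
#' critical_q(2.07e-6, 6.36e-6)  # 0.01468, Si against D2O
#' @export
critical_q <- function(rho_front, rho_back) {
  d <- rho_back - rho_front
  ifelse(d > 0, sqrt(16 * pi * d), NA_real_)
}

#' Gaussian dq/q resolution smearing
#'
#' Convolves a reflectivity curve with a Gaussian of q-proportional width
#' sigma_q = (dq/q) * q, the standard model for wavelength-spread
#' dominated resolution. `dq_over_q` is interpreted as a relative sigma
#' when `convention = "sigma"` and divided by 2.355 when the instrument
#' quotes a FWHM-like spread (`convention = "fwhm"`). Zero width is the
#' identity. The convolution is evaluated by fixed Gauss-Hermite
#' quadrature with linear interpolation of R between grid points, so the
#' input grid should extend a little beyond the region of interest.
#'
#' @param r Reflectivity values on `q`.
#' @param q Momentum transfer grid, 1/Angstrom.
#' @param dq_over_q Relative resolution width (default 10% wavelength
#'   spread quoted FWHM-like, i.e. sigma/q = 0.1/2.355).
#' @param convention `"fwhm"` (default; divide by 2.355) or `"sigma"`.
#' @return Smeared reflectivity on the same grid.
#' @export
smear <- function(r, q, dq_over_q = 0.1, convention = c("fwhm", "sigma")) {
  convention <- match.arg(convention)
  if (dq_over_q < 0 || dq_over_q >= 0.5) abort("`dq_over_q` must lie in [0, 0.5).")
  if (dq_over_q == 0) return(r)
  rel_sigma <- if (convention == "fwhm") dq_over_q / 2.355 else dq_over_q
  # 15-point Gauss-Hermite nodes/weights for integral against exp(-t^2)
  gh <- gauss_hermite_15()
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    sig <- rel_sigma * q[i]
    qs <- q[i] + sqrt(2) * sig * gh$nodes
    rs <- approx(q, r, xout = qs, rule = 2)$y
    out[i] <- sum(gh$weights * rs) / sqrt(pi)
  }
  out
}

gauss_hermite_15 <- function() {
  # nodes/weights of the 15-point Hermite rule (physicists' convention)
  n <- 15
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Forward model: smeared reflectivity on a measurement grid
#'
#' Computes the Abeles reflectivity on an internally extended, oversampled
#' grid, applies [smear()], and interpolates back to the requested points,
#' so edge effects of the convolution do not bias the model.
#'
#' @inheritParams abeles_reflectivity
#' @param dq_over_q,convention Passed to [smear()].
#' @return Reflectivity vector on `q`.
#' @export
reflectivity_model <- function(stack, q, solv = NULL, dq_over_q = 0.1,
                               convention = "fwhm") {
  if (dq_over_q == 0) return(abeles_reflectivity(stack, q, solv))
  pad <- 1 + 4 * dq_over_q
  qext <- exp(seq(log(min(q) / pad), log(max(q) * pad),
                  length.out = max(3L * length(q), 120L)))
  rext <- abeles_reflectivity(stack, qext, solv)
  rsm <- smear(rext, qext, dq_over_q, convention)
  approx(qext, rsm, xout = q, rule = 2)$y
}
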