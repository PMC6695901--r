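#' Debye form factor of a Gaussian polymer coil
#'
#' P(q) = 2 (exp(-x) + x - 1) / x^2 with x = (q Rg)^2, the orientationally
#' averaged form factor of an ideal Gaussian chain. Normalised to P(0) = 1
#' and strictly decreasing in q. A series expansion is used for x < 1e-4
#' to avoid catastrophic cancellation.
#'
#' @param q Momentum transfer grid in 1/Angstrom.
#' @param rg Radius of gyration in nm (> 0).
#' @return Dimensionless P(q), same length as `q`.
#' @examples
#' debye_form_factor(0, rg = 2.5)        # 1
#' debye_form_factor(0.04, rg = 2.5)     # x = 1 -> 2/e
#' @export
debye_form_factor <- function(q, rg) {
  if (!is.numeric(rg) || length(rg) != 1 || rg <= 0) abort("`rg` must be > 0 (nm).")
  x <- (q * q_A_to_nm(1) * rg)^2  # q in 1/Ang, rg in nm -> qRg dimensionless
  p <- numeric(length(x))
  small <- x < 1e-4
  # 2(e^-x + x - 1)/x^2 = 1 - x/3 + x^2/12 - x^3/60 + ...
  xs <- x[small]
  p[small] <- 1 - xs / 3 + xs^2 / 12 - xs^3 / 60
  xl <- x[!small]
  p[!small] <- 2 * (exp(-xl) + xl - 1) / xl^2
  p
}

#' Gaussian-coil intensity model
#'
#' `I(q) = scale * P_Debye(q; rg) + background`, the working model for a
#' dilute polymer solution where interparticle interference is negligible
#' (S(q) ~ 1).
#'
#' @param q Momentum transfer in 1/Angstrom.
#' @param rg Radius of gyration, nm.
#' @param scale Forward intensity I0 (> 0).
#' @param background Constant background (>= 0).
#' @return Intensity vector.
#' @export
gaussian_coil_intensity <- function(q, rg, scale = 1, background = 0) {
  scale * debye_form_factor(q, rg) + background
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic Ashcroft-Lekner solution of the Percus-Yevick closure for
#' monodisperse hard spheres of radius `r_hs` at volume fraction
#' `phi_hs`. S(q) -> 1 as q -> infinity, and S(0) equals the
#' compressibility limit (1 - phi)^4 / (1 + 2 phi)^2.
#'
#' @param q Momentum transfer, 1/Angstrom.
#' @param r_hs Hard-sphere radius, nm.
#' @param phi_hs Volume fraction in \[0, 0.74).
#' @return Dimensionless S(q).
#' @examples
#' py_structure_factor(0, r_hs = 10, phi_hs = 0.3)  # 0.0938
#' @export
py_structure_factor <- function(q, r_hs, phi_hs) {
  if (phi_hs < 0 || phi_hs >= 0.74) abort("`phi_hs` must lie in [0, 0.74).")
  if (r_hs <= 0) abort("`r_hs` must be > 0 (nm).")
  if (phi_hs == 0) return(rep(1, length(q)))
  phi <- phi_hs
  alpha <- (1 + 2 * phi)^2 / (1 - phi)^4
  beta <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  gam <- phi * alpha / 2
  A <- 2 * q * q_A_to_nm(1) * r_hs  # q * diameter, dimensionless
  G_over_A <- numeric(length(A))
  # The trig brackets cancel to leading orders A^4..A^6, so the direct
  # evaluation loses all precision at small A; a Taylor series in A^2 is
  # exact to ~1e-10 below the switch point.
  small <- A < 0.3
  As <- A[small]^2
  G_over_A[small] <-
    alpha * (1 / 3 - As / 30 + As^2 / 840) +
    beta * (1 / 4 - As / 36 + As^2 / 960) +
    gam * (1 / 6 - As / 48 + As^2 / 1200)
  Al <- A[!small]
  sA <- sin(Al); cA <- cos(Al)
  G <- alpha / Al^2 * (sA - Al * cA) +
    beta / Al^3 * (2 * Al * sA + (2 - Al^2) * cA - 2) +
    gam / Al^5 * (-Al^4 * cA + 4 * ((3 * Al^2 - 6) * cA + (Al^3 - 6 * Al) * sA + 6))
  G_over_A[!small] <- G / Al
  1 / (1 + 24 * phi * G_over_A)
}

#' Sphere form factor, optionally Schulz-polydisperse
#'
#' Monodisperse: P(q) = \[3 (sin u - u cos u)/u^3\]^2 with u = qR, first
#' zero at qR = 4.493. With `poly > 0` the radius follows a Schulz
#' (gamma) distribution of relative width `poly`, and the
#' intensity-weighted average <V^2 P>/<V^2> is computed by quadrature.
#'
#' @param q Momentum transfer, 1/Angstrom.
#' @param r Mean sphere radius, nm.
#' @param poly Relative polydispersity (sigma_R / R), >= 0.
#' @return Dimensionless form factor, 1 at q = 0.
#' @export
sphere_form_factor <- function(q, r, poly = 0) {
  if (r <= 0) abort("`r` must be > 0 (nm).")
  if (poly < 0) abort("`poly` must be >= 0.")
  p_mono <- function(u) {
    out <- rep(1, length(u))
    nz <- u > 1e-4
    un <- u[nz]
    out[nz] <- (3 * (sin(un) - un * cos(un)) / un^3)^2
    small <- !nz & u > 0
    out[small] <- (1 - u[small]^2 / 10)^2
    out
  }
  qr <- q * q_A_to_nm(1)  # 1/nm
  if (poly == 0) return(p_mono(qr * r))
  # Schulz: R ~ Gamma(shape = z + 1, scale = r / (z + 1)), z = 1/poly^2 - 1
  z <- 1 / poly^2 - 1
  shape <- z + 1
  # 61-point Gauss-Legendre-like fixed grid over the central 99.99% mass
  pr <- stats::qgamma(seq(5e-5, 1 - 5e-5, length.out = 61), shape = shape,
                      scale = r / shape)
  w <- stats::dgamma(pr, shape = shape, scale = r / shape)
  w <- w * pr^6          # intensity weighting by V^2
  w <- w / sum(w)
  acc <- numeric(length(q))
  for (k in seq_along(pr)) acc <- acc + w[k] * p_mono(qr * pr[k])
  acc
}

#' Dumbbell (peptide + globule) mucin intensity model
#'
#' The working small-angle model for gastric mucin: the total intensity is
#' the sum of a "peptide" term describing the extended glycosylated chain
#' -- an Ornstein-Zernike lorentzian of correlation length `xi` plus a
#' low-q power law of large-scale length `Xi` and exponent `n_exp` -- and
#' a "globule" term of Schulz-polydisperse spheres (mean radius ~10 nm)
#' interacting as Percus-Yevick hard spheres:
#' `I = i1/(1 + xi^2 q^2) + i2/(Xi q)^n + scale * <P_sphere> * S_PY`.
#' The structure factor is applied in the local-monodisperse sense, at the
#' mean radius.
#'
#' @param q Momentum transfer, 1/Angstrom.
#' @param xi Peptide correlation length, nm (> 0).
#' @param Xi Large-scale correlation length, nm (> 0).
#' @param n_exp Low-q power-law exponent (> 0; appears as q^-n).
#' @param i1,i2 Peptide-term amplitudes (>= 0).
#' @param r_globule Mean globule radius, nm.
#' @param poly Relative polydispersity of the globule radius (default 0.2).
#' @param phi_hs Hard-sphere volume fraction in \[0, 0.74).
#' @param scale Globule-term amplitude, absorbing N V^2 (rho_m - rho_s)^2.
#' @param background Constant background.
#' @return Intensity vector.
#' @export
dumbbell_intensity <- function(q, xi = 3, Xi = 50, n_exp = 2.7,
                               i1 = 1, i2 = 0.005, r_globule = 10,
                               poly = 0.2, phi_hs = 0.15,
                               scale = 1, background = 0) {
  if (xi <= 0 || Xi <= 0 || r_globule <= 0) abort("Lengths must be > 0 (nm).")
  if (n_exp <= 0) abort("`n_exp` must be > 0.")
  if (i1 < 0 || i2 < 0) abort("Amplitudes must be >= 0.")
  qnm <- q * q_A_to_nm(1)
  peptide <- i1 / (1 + (xi * qnm)^2) + i2 / (Xi * qnm)^n_exp
  globule <- scale * sphere_form_factor(q, r_globule, poly) *
    py_structure_factor(q, r_globule, phi_hs)
  peptide + globule + background
}

#' Additive two-component mixture intensity
#'
#' The null model for a mucin/polymer mixture: if the components do not
#' interact, the measured intensity is the pointwise sum
#' `I_mixed(q) = I_mucin(q) + A * I_polymer(q)`, where A is the polymer
#' weight factor (1 for a 1:1 weight ratio, 2 for 1:2). Deviations from
#' this sum diagnose cluster formation.
#'
#' @param i_pgm,i_argo Either intensity vectors on a shared q grid, or two
#'   [scattering_curve()]s with identical q columns.
#' @param a Weight factor A (>= 0).
#' @return Intensity vector, or a curve when curves were supplied.
#' @export
mixture_model <- function(i_pgm, i_argo, a) {
  if (a < 0) abort("`a` must be >= 0.")
  if (is_scattering_curve(i_pgm) && is_scattering_curve(i_argo)) {
    if (nrow(i_pgm) != nrow(i_argo) ||
        any(abs(i_pgm$q - i_argo$q) > 1e-12 * pmax(i_pgm$q, i_argo$q))) {
      abort("Curves must share the same q grid (no silent interpolation).")
    }
    return(scattering_curve(i_pgm$q, i_pgm$intensity + a * i_argo$intensity,
                            kind = "saxs"))
  }
  if (length(i_pgm) != length(i_argo)) {
    abort("Intensity grids must have the same length.")
  }
  i_pgm + a * i_argo
}

#' Low-q excess over the additive mixture model
#'
#' `measured - (I_mucin + A * I_polymer)` pointwise: positive low-q excess
#' with a steep power-law slope signals large clusters that the additive
#' null cannot explain.
#'
#' @param measured [scattering_curve()] of the mixed sample.
#' @param i_pgm,i_argo Component curves on the same q grid.
#' @inheritParams mixture_model
#' @return A [scattering_curve()] of the excess (may be negative where the
#'   null over-predicts; stored as a SAXS curve).
#' @export
excess_intensity <- function(measured, i_pgm, i_argo, a) {
  stopifnot(is_scattering_curve(measured))
  null_model <- mixture_model(i_pgm, i_argo, a)
  if (nrow(measured) != nrow(null_model) ||
      any(abs(measured$q - null_model$q) > 1e-12 * measured$q)) {
    abort("`measured` must share the components' q grid.")
  }
  scattering_curve(measured$q, measured$intensity - null_model$intensity,
                   sigma = if (has_sigma(measured)) measured$sigma else NULL,
                   kind = "saxs")
}
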