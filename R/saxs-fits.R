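#' Fit a Gaussian-coil (Debye) model to a SAXS curve
#'
#' Bounded weighted least squares of
#' `scale * P_Debye(q; rg) + background` against the measured intensity,
#' weighting by 1/sigma where uncertainties are present. The curve should
#' span q*Rg from below 1 to above 2 for Rg to be identifiable.
#'
#' @param curve A [scattering_curve()] (SAXS).
#' @param rg,scale,background Initial values (rg in nm).
#' @param lower,upper Named bound vectors over `c(rg, scale, background)`.
#' @return A `film_fit`; inspect with [tidy()] and [glance()]. When the
#'   data cannot constrain Rg the fit reports `converged = FALSE` or a
#'   standard error much larger than the estimate.
#' @export
fit_gaussian_coil <- function(curve, rg = 3, scale = NULL, background = 0,
                              lower = c(rg = 0.1, scale = 0, background = 0),
                              upper = c(rg = 500, scale = Inf, background = Inf)) {
  stopifnot(is_scattering_curve(curve))
  if (nrow(curve) < 5) abort("Need at least 5 points to fit a coil model.")
  if (is.null(scale)) scale <- max(curve$intensity)
  w <- curve_weights(curve)
  start <- c(rg = rg, scale = scale, background = background)
  resid_fn <- function(p) {
    w * (p[["scale"]] * debye_form_factor(curve$q, p[["rg"]]) +
           p[["background"]] - curve$intensity)
  }
  fit <- bounded_lm_fit(resid_fn, start, lower[names(start)],
                        upper[names(start)], "gaussian_coil", nrow(curve))
  fit$fitted <- scattering_curve(
    curve$q,
    fit$params[["scale"]] * debye_form_factor(curve$q, fit$params[["rg"]]) +
      fit$params[["background"]],
    kind = "saxs"
  )
  fit$data <- curve
  fit
}

#' Guinier analysis with a self-consistent low-q window
#'
#' In the Guinier regime (q * Rg < 1) the intensity obeys
#' `I(q) = I0 exp(-q^2 Rg^2 / 3)`, so ln(I) is linear in q^2 with slope
#' -Rg^2/3. The fit window is chosen self-consistently: starting from all
#' points, fit, recompute the largest admissible q from the current Rg
#' (qmax * Rg <= `qrg_limit`), and iterate to a fixed point (tolerance
#' 1e-3 on Rg, widest admissible window on ties). When even the smallest
#' measured q violates qmin * Rg < 1 the returned Rg is only a lower
#' bound and `is_lower_bound` is set -- the situation met for large
#' clusters whose size exceeds the resolution of the q window.
#'
#' @param curve A [scattering_curve()] with positive intensities at low q.
#' @param qrg_limit Upper limit on q * Rg inside the window (default 1).
#' @return A tibble of class `guinier_result` with columns `rg` (nm),
#'   `i0`, `qmin`, `qmax` (1/Ang), `qrg_max`, `is_lower_bound`,
#'   `n_points`.
#' @export
guinier_fit <- function(curve, qrg_limit = 1.0) {
  stopifnot(is_scattering_curve(curve))
  pos <- curve$intensity > 0
  q <- curve$q[pos]
  i <- curve$intensity[pos]
  if (length(q) < 3) abort("Need at least 3 points with positive intensity.")

  fit_window <- function(idx) {
    f <- lm(log(i[idx]) ~ I(q[idx]^2))
    slope <- coef(f)[[2]]
    rg_A <- if (slope < 0) sqrt(-3 * slope) else NA_real_
    list(rg_A = rg_A, i0 = exp(coef(f)[[1]]), n = length(idx))
  }

  idx <- seq_along(q)
  rg_A <- NA_real_
  for (iter in 1:50) {
    res <- fit_window(idx)
    if (!is.finite(res$rg_A)) break
    qmax_adm <- qrg_limit / res$rg_A
    new_idx <- which(q <= qmax_adm)
    if (length(new_idx) < 3) new_idx <- 1:3
    if (is.finite(rg_A) && abs(res$rg_A - rg_A) / rg_A < 1e-3 &&
        length(new_idx) == length(idx)) {
      idx <- new_idx
      rg_A <- res$rg_A
      break
    }
    rg_A <- res$rg_A
    idx <- new_idx
  }
  if (!is.finite(rg_A)) {           # non-decaying curve: report from 3 lowest q
    idx <- 1:3
    res <- fit_window(idx)
    rg_A <- res$rg_A
  }
  res <- fit_window(idx)
  rg_A <- res$rg_A
  lower_bound <- is.finite(rg_A) && q[1] * rg_A > 1
  out <- tibble(
    rg = if (is.finite(rg_A)) rg_A / 10 else NA_real_,  # Ang -> nm
    i0 = res$i0,
    qmin = q[idx[1]], qmax = q[idx[length(idx)]],
    qrg_max = if (is.finite(rg_A)) q[idx[length(idx)]] * rg_A else NA_real_,
    is_lower_bound = lower_bound,
    n_points = res$n
  )
  class(out) <- c("guinier_result", class(out))
  out
}

#' Power-law (fractal) fit of a scattering tail
#'
#' Linear regression of log(I) on log(q) in a stated window. The exponent
#' classifies the scatterer: slopes in (-4, -3\] indicate surface
#' fractals (compact clusters with rough surfaces), slopes in (-3, -1.5\]
#' indicate mass-fractal networks; anything else is "other".
#'
#' @param curve A [scattering_curve()].
#' @param q_window Length-2 numeric `(qmin, qmax)` in 1/Angstrom.
#' @return A tibble of class `power_law_result` with `exponent`,
#'   `exponent_se`, `prefactor`, `qmin`, `qmax`, `fractal_class`,
#'   `n_points`.
#' @export
power_law_fit <- function(curve, q_window = range(curve$q)) {
  stopifnot(is_scattering_curve(curve), length(q_window) == 2)
  sel <- curve$q >= q_window[1] & curve$q <= q_window[2]
  if (sum(sel) < 4) abort("Need at least 4 points inside the q window.")
  if (any(curve$intensity[sel] <= 0)) {
    abort("All intensities in the window must be positive for a log-log fit.")
  }
  f <- lm(log(curve$intensity[sel]) ~ log(curve$q[sel]))
  expo <- coef(f)[[2]]
  # suppressed: vcov warns on exactly log-linear (noise-free) input
  se <- suppressWarnings(sqrt(diag(vcov(f)))[[2]])
  cls <- classify_fractal(expo)
  out <- tibble(exponent = expo, exponent_se = se,
                prefactor = exp(coef(f)[[1]]),
                qmin = q_window[1], qmax = q_window[2],
                fractal_class = cls, n_points = sum(sel))
  class(out) <- c("power_law_result", class(out))
  out
}

classify_fractal <- function(exponent) {
  if (exponent > -4 && exponent <= -3) "surface"
  else if (exponent > -3 && exponent <= -1.5) "mass"
  else "other"
}
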