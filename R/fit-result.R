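# Shared container for bounded least-squares fits across the SAXS, QCM-D
# and reflectometry stages.
new_film_fit <- function(params, stderr, chi2, n_points, converged,
                         model, bounds = NULL, extra = list()) {
  stopifnot(is.numeric(params), !is.null(names(params)))
  out <- c(list(
    params = params,
    stderr = stderr[names(params)],
    chi2 = as.numeric(chi2),
    n_points = as.integer(n_points),
    df = as.integer(n_points) - length(params),
    converged = isTRUE(converged),
    model = model,
    bounds = bounds
  ), extra)
  structure(out, class = "film_fit")
}

#' @export
print.film_fit <- function(x, ...) {
  cat(sprintf("<film_fit: %s | chi2 = %.4g on %d points (%s)>\n",
              x$model, x$chi2, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a fitted scattering/film model
#'
#' @param x A `film_fit` object returned by [fit_gaussian_coil()],
#'   [corefine()] and friends.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.film_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unname(x$params),
         std.error = unname(x$stderr))
}

#' One-row fit summary
#'
#' @inheritParams tidy.film_fit
#' @return A tibble with `model`, `chi2`, `chi2.reduced`, `n.points`,
#'   `df`, `converged`.
#' @export
glance.film_fit <- function(x, ...) {
  tibble(model = x$model, chi2 = x$chi2,
         chi2.reduced = if (x$df > 0) x$chi2 / x$df else NA_real_,
         n.points = x$n_points, df = x$df, converged = x$converged)
}

# Residual weights: 1/sigma where available, else 1 (unweighted chi2).
curve_weights <- function(curve) {
  if (has_sigma(curve) && all(curve$sigma > 0)) 1 / curve$sigma
  else rep(1, nrow(curve))
}

# Wrap minpack.lm::nls.lm with box bounds and stderr extraction.
bounded_lm_fit <- function(residual_fn, start, lower, upper,
                           model, n_points, maxit = 200) {
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = residual_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxit)
  )
  est <- setNames(as.numeric(fit$par), names(start))
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  cv <- try(vcov(fit), silent = TRUE)
  if (!inherits(cv, "try-error") && all(is.finite(diag(cv)))) {
    se <- setNames(sqrt(pmax(diag(cv), 0)), names(est))
  }
  converged <- fit$info %in% c(1, 2, 3, 4)
  new_film_fit(est, se, chi2 = fit$deviance, n_points = n_points,
               converged = converged, model = model,
               bounds = list(lower = lower, upper = upper),
               extra = list(niter = fit$niter, message = fit$message))
}
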