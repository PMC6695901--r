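#' Bundle multi-contrast reflectivity data with a shared structural model
#'
#' Contrast variation measures the same interface in solvents of
#' different deuteration; the structural parameters (thicknesses, volume
#' fractions, roughnesses) are shared across contrasts while the
#' solvent-dependent SLDs follow from labile-H exchange and hydration.
#'
#' @param template A [layer_stack()] holding the shared structure and
#'   starting values.
#' @param contrasts Named list; each element is a list with `solvent` (a
#'   [solvent()]) and `curve` (a reflectivity [scattering_curve()]).
#' @return A list of class `contrast_series`.
#' @export
contrast_series <- function(template, contrasts) {
  stopifnot(inherits(template, "layer_stack"))
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts)))) {
    abort("`contrasts` must be a named list.")
  }
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (!inherits(ct$solvent, "solvent") || !is_scattering_curve(ct$curve)) {
      abort(sprintf("Contrast '%s' needs a `solvent` and a `curve`.", nm))
    }
  }
  structure(list(template = template, contrasts = contrasts),
            class = "contrast_series")
}

#' @export
print.contrast_series <- function(x, ...) {
  cat(sprintf("<contrast_series: %d contrasts (%s), %d slabs>\n",
              length(x$contrasts), paste(names(x$contrasts), collapse = ", "),
              nrow(x$template$slabs)))
  invisible(x)
}

# Parameter addressing: "<slab label>.<field>" for structural parameters
# (field in thickness, phi, roughness, sld_h, sld_d) and
# "scale.<contrast>" / "background.<contrast>" for per-dataset nuisances.
stack_param_get <- function(series, name) {
  if (grepl("^(scale|background)\\.", name)) {
    return(if (grepl("^scale", name)) 1 else 0)
  }
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  field <- parts[length(parts)]
  label <- paste(parts[-length(parts)], collapse = ".")
  s <- series$template$slabs
  i <- match(label, s$label)
  if (is.na(i) || !field %in% names(s)) {
    abort(sprintf("Unknown parameter '%s'.", name))
  }
  s[[field]][i]
}

stack_param_apply <- function(template, params) {
  s <- template$slabs
  for (name in names(params)) {
    if (grepl("^(scale|background)\\.", name)) next
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    field <- parts[length(parts)]
    label <- paste(parts[-length(parts)], collapse = ".")
    s[[field]][match(label, s$label)] <- params[[name]]
  }
  template$slabs <- s
  template
}

default_param_bounds <- function(name, start) {
  field <- if (grepl("^(scale|background)\\.", name)) sub("\\..*$", "", name)
           else sub("^.*\\.", "", name)
  switch(field,
    thickness = c(0, max(3 * start, 100)),
    phi = c(0, 1),
    roughness = c(0, 15),
    sld_h = c(-1e-6, 8e-6),
    sld_d = c(-1e-6, 8e-6),
    scale = c(0.3, 3),
    background = c(0, 1e-4),
    abort(sprintf("No default bounds for parameter '%s'; supply them.", name))
  )
}

#' Co-refine a slab model against several contrasts at once
#'
#' Single bounded trust-region least-squares minimisation (Levenberg-
#' Marquardt with box bounds) of the summed per-contrast chi-square.
#' Structural parameters are shared across contrasts; each dataset gets
#' its own intensity scale and constant background as nuisance
#' parameters when they are listed in `free`. Multi-start restarts
#' (default 5, deterministic given `seed`) guard against local minima;
#' the best run is returned.
#'
#' @param series A [contrast_series()].
#' @param free Character vector of free parameter names, e.g.
#'   `c("mucin.thickness", "mucin.phi", "scale.h2o", "scale.d2o")`.
#' @param bounds Optional named list of `c(lower, upper)` per free
#'   parameter; sensible defaults per field otherwise.
#' @param dq_over_q,convention Resolution passed to
#'   [reflectivity_model()].
#' @param multistart Number of random restarts (>= 1).
#' @param seed Seed for the restart jitter (restored on exit).
#' @return A `film_fit` with per-contrast chi-square in
#'   `$chi2_per_contrast` and the best-fit stack in `$stack`.
#' @export
corefine <- function(series, free, bounds = NULL, dq_over_q = 0.1,
                     convention = "fwhm", multistart = 5, seed = 1) {
  stopifnot(inherits(series, "contrast_series"), length(free) >= 1)
  start <- vapply(free, function(nm) stack_param_get(series, nm), numeric(1))
  bnd <- lapply(free, function(nm) {
    b <- bounds[[nm]] %||% default_param_bounds(nm, start[[nm]])
    if (length(b) != 2 || b[1] > b[2]) abort(sprintf("Bad bounds for '%s'.", nm))
    b
  })
  names(bnd) <- free
  lower <- vapply(bnd, `[`, numeric(1), 1)
  upper <- vapply(bnd, `[`, numeric(1), 2)
  start <- pmin(pmax(start, lower), upper)

  curves <- lapply(series$contrasts, `[[`, "curve")
  solvs <- lapply(series$contrasts, `[[`, "solvent")
  wts <- lapply(curves, curve_weights)
  n_points <- sum(vapply(curves, nrow, integer(1)))

  p_get <- function(p, nm, default) if (nm %in% names(p)) p[[nm]] else default

  resid_fn <- function(p) {
    names(p) <- free
    stk <- stack_param_apply(series$template, p)
    unlist(lapply(names(curves), function(nm) {
      cu <- curves[[nm]]
      r <- reflectivity_model(stk, cu$q, solvs[[nm]], dq_over_q, convention)
      sc <- p_get(p, paste0("scale.", nm), 1)
      bg <- p_get(p, paste0("background.", nm), 0)
      wts[[nm]] * (sc * r + bg - cu$intensity)
    }), use.names = FALSE)
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  best <- NULL
  for (k in seq_len(max(1L, multistart))) {
    st <- if (k == 1) start else {
      jit <- start * stats::runif(length(start), 0.7, 1.3) +
        ifelse(start == 0, stats::runif(length(start), 0, 0.1 * (upper - lower)), 0)
      pmin(pmax(jit, lower), upper)
    }
    fit <- try(bounded_lm_fit(resid_fn, st, lower, upper, "nr_corefine",
                              n_points), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$chi2 < best$chi2) best <- fit
  }
  if (is.null(best)) abort("All co-refinement restarts failed.")

  p <- best$params
  best$stack <- stack_param_apply(series$template, p)
  best$chi2_per_contrast <- vapply(names(curves), function(nm) {
    cu <- curves[[nm]]
    r <- reflectivity_model(best$stack, cu$q, solvs[[nm]], dq_over_q, convention)
    sc <- p_get(p, paste0("scale.", nm), 1)
    bg <- p_get(p, paste0("background.", nm), 0)
    sum((wts[[nm]] * (sc * r + bg - cu$intensity))^2)
  }, numeric(1))
  best$series <- series
  best$dq_over_q <- dq_over_q
  best$convention <- convention
  best
}

#' Real-space SLD profile of a stack
#'
#' Returns the roughness-smoothed SLD depth profile (error-function
#' interfaces) for plotting, the standard companion figure to a
#' reflectivity fit.
#'
#' @inheritParams resolve_stack
#' @param dz Depth step, Ang.
#' @param pad Padding into the semi-infinite media, Ang.
#' @return Tibble with `z` (Ang, 0 at the fronting/first-slab interface)
#'   and `sld` (1/Ang^2).
#' @export
sld_profile <- function(stack, solv = NULL, dz = 0.5, pad = 30) {
  prof <- if (inherits(stack, "layer_stack")) resolve_stack(stack, solv) else stack
  rho <- c(attr(prof, "fronting_sld"), prof$sld, attr(prof, "backing_sld"))
  zi <- cumsum(c(0, prof$thickness))
  sig <- pmax(c(prof$roughness, attr(prof, "backing_roughness")), 1e-3)
  z <- seq(-pad, max(zi) + pad, by = dz)
  val <- rep(rho[1], length(z))
  for (i in seq_along(zi)) {
    val <- val + (rho[i + 1] - rho[i]) * 0.5 *
      (1 + erf((z - zi[i]) / (sqrt(2) * sig[i])))
  }
  tibble(z = z, sld = val)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
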