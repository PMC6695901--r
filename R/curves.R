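#' Reduced one-dimensional scattering curves
#'
#' A scattering curve is a tibble with columns `q` (momentum transfer,
#' canonical unit 1/Angstrom), `intensity` (scattered intensity; absolute
#' cm^-1, relative, or unitless reflectivity) and optionally `sigma`
#' (1-sigma uncertainty, same unit as the intensity). The `kind` attribute
#' tags the curve as small-angle ("saxs") or specular reflectivity
#' ("reflectivity"); reflectivity intensities must be non-negative.
#'
#' @param q Numeric vector of momentum transfer values, strictly
#'   increasing and positive, in 1/Angstrom.
#' @param intensity Numeric vector, same length as `q`.
#' @param sigma Optional numeric vector of 1-sigma uncertainties
#'   (non-negative), or `NULL` when uncertainties are unknown.
#' @param kind One of `"saxs"` or `"reflectivity"`.
#' @param intensity_unit Free-text unit label (e.g. `"cm^-1"`,
#'   `"arbitrary"`, `"reflectivity"`).
#'
#' @return A tibble of class `scattering_curve`.
#' @examples
#' sc <- scattering_curve(q = c(0.01, 0.02, 0.05), intensity = c(90, 70, 20))
#' sc
#' @export
scattering_curve <- function(q, intensity, sigma = NULL,
                             kind = c("saxs", "reflectivity"),
                             intensity_unit = "arbitrary") {
  kind <- match.arg(kind)
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) {
    abort("`q` and `intensity` must have the same length.")
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    abort("`q` must be finite and strictly positive.")
  }
  if (any(diff(q) <= 0)) {
    bad <- which(diff(q) <= 0)[1] + 1L
    abort(sprintf("`q` must be strictly increasing (violated at point %d).", bad))
  }
  if (kind == "reflectivity" && any(intensity < 0, na.rm = TRUE)) {
    abort("Reflectivity intensities must be non-negative.")
  }
  out <- tibble(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) {
      abort("`sigma` must match the length of `q`.")
    }
    if (any(sigma < 0, na.rm = TRUE)) abort("`sigma` must be non-negative.")
    out$sigma <- sigma
  }
  structure(out,
    class = c("scattering_curve", class(out)),
    kind = kind, intensity_unit = intensity_unit
  )
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf(
    "<scattering_curve: %s, %d points, q %.4g-%.4g 1/Ang%s>\n",
    attr(x, "kind"), nrow(x), min(x$q), max(x$q),
    if (has_sigma(x)) ", with sigma" else ""
  ))
  NextMethod()
}

#' @rdname scattering_curve
#' @param x Object to test.
#' @export
is_scattering_curve <- function(x) inherits(x, "scattering_curve")

has_sigma <- function(curve) "sigma" %in% names(curve)

curve_kind <- function(curve) attr(curve, "kind") %||% "saxs"

#' Read a reduced scattering curve from an ASCII file
#'
#' Reads the de facto reduced-data format of small-angle and reflectometry
#' beamlines: whitespace- or comma-delimited numeric columns (`q`,
#' intensity, optionally 1-sigma uncertainty), with `#`-prefixed comment
#' lines. Momentum transfer is converted to the canonical 1/Angstrom on
#' read (1 nm^-1 = 0.1 Angstrom^-1).
#'
#' @param path Path to the file.
#' @param unit_hint Unit of the q column in the file: `"A_inv"`
#'   (1/Angstrom, default) or `"nm_inv"` (1/nm).
#' @inheritParams scattering_curve
#' @return A [scattering_curve()] tibble; `sigma` is absent for two-column
#'   files, so downstream fits fall back to unweighted chi-square.
#' @export
read_curve <- function(path, unit_hint = c("A_inv", "nm_inv"),
                       kind = c("saxs", "reflectivity")) {
  unit_hint <- match.arg(unit_hint)
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) abort(sprintf("No data rows in '%s'.", path))
  fields <- strsplit(trimws(lines[rows]), "[,;[:space:]]+")
  ncols <- lengths(fields)
  if (any(ncols < 2 | ncols > 3)) {
    bad <- rows[which(ncols < 2 | ncols > 3)[1]]
    abort(sprintf("Line %d of '%s': expected 2 or 3 columns.", bad, path))
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- vapply(vals, function(v) any(is.na(v)), logical(1))
  if (any(bad)) {
    abort(sprintf("Line %d of '%s': non-numeric value.", rows[which(bad)[1]], path))
  }
  q <- vapply(vals, `[`, numeric(1), 1)
  i <- vapply(vals, `[`, numeric(1), 2)
  s <- if (all(ncols == 3)) vapply(vals, `[`, numeric(1), 3) else NULL
  if (unit_hint == "nm_inv") q <- q_nm_to_A(q)
  if (any(diff(q) <= 0)) {
    j <- which(diff(q) <= 0)[1] + 1L
    abort(sprintf("Line %d of '%s': q is not strictly increasing.", rows[j], path))
  }
  scattering_curve(q, i, s, kind = kind)
}

#' Write a scattering curve as 3-column (or 2-column) ASCII
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(is_scattering_curve(curve))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", curve_kind(curve)), con)
  writeLines(sprintf("# columns: q[1/Ang] intensity%s",
                     if (has_sigma(curve)) " sigma" else ""), con)
  df <- as.data.frame(curve)
  write.table(format(df, digits = 12, trim = TRUE, scientific = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Momentum-transfer unit conversions
#'
#' `q_nm_to_A()` converts 1/nm to 1/Angstrom; `q_A_to_nm()` is its inverse.
#' The two compose to the identity to machine precision.
#'
#' @param q Numeric vector of momentum transfer values.
#' @return Numeric vector in the target unit.
#' @export
q_nm_to_A <- function(q) q * 0.1

#' @rdname q_nm_to_A
#' @export
q_A_to_nm <- function(q) q * 10
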