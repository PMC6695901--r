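# Coherent neutron scattering lengths, fm (Sears compilation); H and D are
# distinct entries. Atomic masses in g/mol. The table covers the elements
# that occur in buffers, silica, lipids and glycoproteins.
.neutron_b <- c(
  H = -3.739, D = 6.671, C = 6.646, N = 9.36, O = 5.803,
  P = 5.13, S = 2.847, Si = 4.1491, Na = 3.63, Cl = 9.577,
  K = 3.67, Ca = 4.70
)
.atomic_mass <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, Si = 28.085, Na = 22.990, Cl = 35.45,
  K = 39.098, Ca = 40.078
)
.N_AVOGADRO <- 6.02214076e23

parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
      abort("A numeric formula must be a named vector, e.g. c(H = 2, O = 1).")
    }
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)
  toks <- regmatches(formula, m)[[1]]
  if (sum(nchar(toks)) != nchar(gsub("\\s", "", formula))) {
    abort(sprintf("Cannot parse chemical formula '%s'.", formula))
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(n), as.numeric(n), 1)
  agg <- tapply(n, factor(el, levels = unique(el)), sum)
  setNames(as.numeric(agg), unique(el))
}

#' Define a material by composition, density and exchangeable hydrogens
#'
#' A material carries everything needed to compute its neutron scattering
#' length density (SLD) in a solvent of arbitrary deuteration: an element
#' to count map (H and D are distinct), a mass density, and the number of
#' labile hydrogens per formula unit (the -OH/-NH hydrogens that exchange
#' with solvent H/D).
#'
#' @param name Label.
#' @param formula Chemical formula, either a string like `"C6H12O6"` (use
#'   `"D"` for deuterium) or a named numeric vector like `c(H = 2, O = 1)`.
#' @param mass_density Mass density in g/cm^3 (> 0).
#' @param n_labile_H Exchangeable hydrogens per formula unit; must not
#'   exceed the total H count.
#' @return A list of class `material`.
#' @examples
#' water <- material("H2O", "H2O", 1.000)
#' heavy_water <- material("D2O", "D2O", 1.105)
#' @export
material <- function(name, formula, mass_density, n_labile_H = 0) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.neutron_b))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown element symbol(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (any(counts < 0)) abort("Element counts must be non-negative.")
  if (!is.numeric(mass_density) || mass_density <= 0) {
    abort("`mass_density` must be positive (g/cm^3).")
  }
  n_H <- if ("H" %in% names(counts)) counts[["H"]] else 0
  if (n_labile_H < 0 || n_labile_H > n_H) {
    abort("`n_labile_H` must lie between 0 and the total H count.")
  }
  structure(
    list(name = name, formula = counts, mass_density = mass_density,
         n_labile_H = n_labile_H),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material %s: %s, %.3f g/cm^3, %g labile H>\n", x$name,
              paste0(names(x$formula), ifelse(x$formula == 1, "", x$formula),
                     collapse = ""),
              x$mass_density, x$n_labile_H))
  invisible(x)
}

# SLD of reference waters, computed once from the embedded table.
.sld_pure_water <- function(deuterated) {
  m <- if (deuterated) material("D2O", "D2O", 1.105) else material("H2O", "H2O", 1.000)
  sld(m, solvent_raw(if (deuterated) 1 else 0))
}

solvent_raw <- function(d_fraction, salt_label = "") {
  structure(list(d_fraction = d_fraction, salt_label = salt_label, sld = NA_real_),
            class = "solvent")
}

#' Define an aqueous solvent by its D2O fraction
#'
#' The solvent SLD is interpolated linearly in the D2O mole fraction
#' between pure H2O (-0.56e-6 1/Ang^2 at 1.000 g/cm^3) and pure D2O
#' (6.36e-6 1/Ang^2 at 1.105 g/cm^3); the molar volumes of the two
#' isotopologues differ by < 0.7%, so mole and volume fractions are
#' treated as equal. Salt at physiological concentration shifts the SLD by
#' under 1% and is recorded as a label only, never used numerically.
#'
#' @param d_fraction Mole fraction of D2O, in \[0, 1\].
#' @param salt_label Free-text description of the salt content.
#' @return A list of class `solvent` with the derived `sld` (1/Ang^2).
#' @examples
#' solvent(0)$sld  # H2O, about -0.56e-6
#' solvent(1)$sld  # D2O, about  6.36e-6
#' @export
solvent <- function(d_fraction, salt_label = "") {
  if (!is.numeric(d_fraction) || d_fraction < 0 || d_fraction > 1) {
    abort("`d_fraction` must lie in [0, 1].")
  }
  s <- solvent_raw(d_fraction, salt_label)
  s$sld <- (1 - d_fraction) * .sld_pure_water(FALSE) +
    d_fraction * .sld_pure_water(TRUE)
  s
}

#' @export
print.solvent <- function(x, ...) {
  cat(sprintf("<solvent: %.0f%% D2O, SLD %.3g 1/Ang^2%s>\n",
              100 * x$d_fraction, x$sld,
              if (nzchar(x$salt_label)) paste0(", ", x$salt_label) else ""))
  invisible(x)
}

#' Neutron scattering length density of a material in a solvent
#'
#' Computes the coherent SLD rho = sum(b_j n_j) over the formula unit,
#' where n_j is the number density set by the mass density and molar mass.
#' Each labile hydrogen contributes an effective scattering length
#' b_H + x * e * (b_D - b_H), with x the solvent D2O fraction and e the
#' exchange efficiency; in pure H2O the result is independent of e. The
#' formula-unit volume is held fixed at its protiated value (exchange
#' alters scattering lengths, not the molecular volume).
#'
#' @param mat A [material()].
#' @param solv A [solvent()]; only its `d_fraction` matters here.
#' @param exchange_efficiency Fraction of labile hydrogens that actually
#'   exchange (default 0.9, reflecting partially buried sites).
#' @return SLD in 1/Ang^2.
#' @examples
#' sld(material("H2O", "H2O", 1.000), solvent(0))   # -0.56e-6
#' sld(material("D2O", "D2O", 1.105), solvent(1))   #  6.36e-6
#' @export
sld <- function(mat, solv, exchange_efficiency = 0.9) {
  stopifnot(inherits(mat, "material"), inherits(solv, "solvent"))
  if (exchange_efficiency < 0 || exchange_efficiency > 1) {
    abort("`exchange_efficiency` must lie in [0, 1].")
  }
  counts <- mat$formula
  b <- .neutron_b[names(counts)]
  sum_b <- sum(b * counts)
  if (mat$n_labile_H > 0) {
    shift <- solv$d_fraction * exchange_efficiency *
      (.neutron_b[["D"]] - .neutron_b[["H"]])
    sum_b <- sum_b + mat$n_labile_H * shift
  }
  molar_mass <- sum(.atomic_mass[names(counts)] * counts)
  v_A3 <- molar_mass / (mat$mass_density * .N_AVOGADRO) * 1e24  # Ang^3
  # fm -> Ang: 1 fm = 1e-5 Ang
  sum_b * 1e-5 / v_A3
}

#' Volume-weighted SLD of a solvent-hydrated layer
#'
#' A layer occupied by a material at volume fraction `phi_material`, the
#' remainder being solvent, has SLD phi * dry + (1 - phi) * solvent. This
#' is the mixing model implied whenever a layer's "solvent volume" or
#' "volume occupation" is quoted.
#'
#' @param dry_sld SLD of the dry material in this solvent context
#'   (1/Ang^2).
#' @param phi_material Volume fraction of material, in \[0, 1\].
#' @param solv A [solvent()].
#' @return Layer SLD in 1/Ang^2.
#' @export
hydrated_layer_sld <- function(dry_sld, phi_material, solv) {
  stopifnot(inherits(solv, "solvent"))
  if (any(phi_material < 0 | phi_material > 1)) {
    abort("`phi_material` must lie in [0, 1].")
  }
  phi_material * dry_sld + (1 - phi_material) * solv$sld
}

#' Invert the hydration mixing rule to recover a dry SLD
#'
#' Exact algebraic inverse of [hydrated_layer_sld()]: given a fitted layer
#' SLD and the material volume fraction, returns the implied dry-material
#' SLD in that solvent context. Used to check labile-H exchange
#' consistency across contrasts.
#'
#' @param layer_sld Fitted layer SLD (1/Ang^2).
#' @inheritParams hydrated_layer_sld
#' @return Dry-material SLD in 1/Ang^2.
#' @examples
#' infer_dry_sld(2.5e-6, 0.60, solvent(0))  # about 4.54e-6
#' infer_dry_sld(5.6e-6, 0.60, solvent(1))  # about 5.09e-6
#' @export
infer_dry_sld <- function(layer_sld, phi_material, solv) {
  stopifnot(inherits(solv, "solvent"))
  if (any(phi_material <= 0 | phi_material > 1)) {
    abort("`phi_material` must lie in (0, 1]; phi = 0 leaves the dry SLD undefined.")
  }
  (layer_sld - (1 - phi_material) * solv$sld) / phi_material
}

#' Write and read material/solvent definitions as plain-text config
#'
#' Key-value blocks (YAML) that round-trip bit-exactly: numbers are
#' serialised at full precision.
#'
#' @param materials Named list of [material()] and/or [solvent()] objects.
#' @param path File path.
#' @return `write_materials()` returns `path` invisibly;
#'   `read_materials()` returns the named list.
#' @export
write_materials <- function(materials, path) {
  ser <- lapply(materials, function(m) {
    if (inherits(m, "solvent")) {
      list(type = "solvent",
           d_fraction = format(m$d_fraction, digits = 17),
           salt_label = m$salt_label)
    } else {
      list(type = "material", name = m$name,
           formula = as.list(setNames(format(m$formula, digits = 17),
                                      names(m$formula))),
           mass_density = format(m$mass_density, digits = 17),
           n_labile_H = format(m$n_labile_H, digits = 17))
    }
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_materials
#' @export
read_materials <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m) {
    if (identical(m$type, "solvent")) {
      solvent(as.numeric(m$d_fraction), m$salt_label %||% "")
    } else {
      material(m$name,
               setNames(as.numeric(unlist(m$formula)), names(m$formula)),
               as.numeric(m$mass_density), as.numeric(m$n_labile_H))
    }
  })
}
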