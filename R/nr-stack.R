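#' Slab and layer-stack construction for specular reflectometry
#'
#' A stack is an ordered set of homogeneous slabs between two
#' semi-infinite media: the fronting (the beam travels through the
#' silicon substrate) and the backing solvent. Each slab carries a
#' thickness (Ang), a roughness (Gaussian sigma, Ang, of the interface
#' with the slab *above* it, i.e. towards the fronting), a material
#' volume fraction `phi` (the remainder is solvent), and a dry SLD that
#' may depend on solvent deuteration through labile-H exchange:
#' `sld_h` is the dry SLD in pure H2O and `sld_d` in pure D2O; the value
#' at D2O fraction x is the affine interpolation, which is exact under
#' the exchange model since the effective scattering length of each
#' labile hydrogen is linear in x. Alternatively a [material()] can be
#' given, from which both endpoints are computed.
#'
#' @param label Slab name.
#' @param thickness Thickness in Angstrom (>= 0).
#' @param sld_h Dry SLD in H2O context, 1/Ang^2 (ignored when `mat` given).
#' @param sld_d Dry SLD in D2O context (default `sld_h`: no exchange).
#' @param phi Material volume fraction in \[0, 1\] (1 = anhydrous slab).
#' @param roughness Interfacial roughness with the slab above, Ang (>= 0).
#' @param mat Optional [material()] used to derive `sld_h`/`sld_d`.
#' @param exchange_efficiency Passed to [sld()] when `mat` is given.
#' @return One-row tibble describing the slab.
#' @export
slab <- function(label, thickness, sld_h = NA_real_, sld_d = NULL,
                 phi = 1, roughness = 0, mat = NULL,
                 exchange_efficiency = 0.9) {
  if (thickness < 0) abort("`thickness` must be >= 0 (Ang).")
  if (roughness < 0) abort("`roughness` must be >= 0 (Ang).")
  if (phi < 0 || phi > 1) abort("`phi` must lie in [0, 1].")
  if (!is.null(mat)) {
    sld_h <- sld(mat, solvent(0), exchange_efficiency)
    sld_d <- sld(mat, solvent(1), exchange_efficiency)
  }
  if (is.null(sld_d)) sld_d <- sld_h
  tibble(label = label, thickness = thickness, sld_h = sld_h,
         sld_d = sld_d, phi = phi, roughness = roughness)
}

#' @rdname slab
#' @param slabs Tibble of slabs ([slab()] rows bound together), ordered
#'   from the fronting side; may have zero rows.
#' @param fronting_sld SLD of the semi-infinite fronting medium
#'   (default silicon, 2.07e-6 1/Ang^2).
#' @param backing Either a [solvent()] (the usual case) or a fixed SLD.
#' @param backing_roughness Roughness of the last slab/backing interface.
#' @return `layer_stack()` returns a list of class `layer_stack`.
#' @examples
#' stk <- layer_stack(
#'   slabs = dplyr::bind_rows(
#'     slab("SiO2", 12, sld_h = 3.47e-6, roughness = 3),
#'     slab("mucin", 22, sld_h = 4.54e-6, sld_d = 5.09e-6, phi = 0.6,
#'          roughness = 3)
#'   ),
#'   backing = solvent(1)
#' )
#' @export
layer_stack <- function(slabs = slab("none", 0)[0, ],
                        fronting_sld = 2.07e-6,
                        backing = solvent(1),
                        backing_roughness = 3) {
  slabs <- as_tibble(slabs)
  req <- c("label", "thickness", "sld_h", "sld_d", "phi", "roughness")
  if (nrow(slabs) > 0 && !all(req %in% names(slabs))) {
    abort(sprintf("`slabs` needs columns: %s.", paste(req, collapse = ", ")))
  }
  if (nrow(slabs) > 1) {
    thick <- slabs$thickness
    adj <- pmin(thick[-1], thick[-length(thick)])
    if (any(slabs$roughness[-1] > adj / 2 + 1e-9)) {
      warn("A roughness exceeds half the smaller adjacent slab thickness; the slab picture is marginal there.")
    }
  }
  structure(list(slabs = slabs, fronting_sld = fronting_sld,
                 backing = backing, backing_roughness = backing_roughness),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  back <- if (inherits(x$backing, "solvent")) {
    sprintf("%.0f%% D2O", 100 * x$backing$d_fraction)
  } else {
    sprintf("SLD %.3g", x$backing)
  }
  cat(sprintf("<layer_stack: Si | %s | %s>\n",
              paste(x$slabs$label, collapse = " | "), back))
  print(x$slabs)
  invisible(x)
}

backing_sld <- function(stack, solv = NULL) {
  if (inherits(stack$backing, "solvent")) stack$backing$sld
  else if (!is.null(solv)) solv$sld
  else as.numeric(stack$backing)
}

stack_solvent <- function(stack, solv = NULL) {
  if (!is.null(solv)) return(solv)
  if (inherits(stack$backing, "solvent")) return(stack$backing)
  abort("Stack has a fixed backing SLD; supply `solv` to resolve hydrated slabs.")
}

#' Resolve a stack's per-slab SLDs for a given solvent
#'
#' Applies labile-H exchange (affine dry SLD in D2O fraction) and the
#' hydration mixing rule to every slab, returning the numeric SLD profile
#' actually entering the reflectivity calculation.
#'
#' @param stack A [layer_stack()].
#' @param solv Optional [solvent()] overriding the stack's backing.
#' @return Tibble with `label`, `thickness`, `sld`, `roughness`, plus
#'   attributes `fronting_sld`, `backing_sld`, `backing_roughness`.
#' @export
resolve_stack <- function(stack, solv = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  s <- stack$slabs
  if (is.null(solv) && !inherits(stack$backing, "solvent")) {
    # fixed-SLD backing: legal as long as no slab needs a solvent
    if (nrow(s) > 0 && (any(s$phi < 1) || any(s$sld_h != s$sld_d))) {
      abort("Stack has hydrated or exchanging slabs; supply `solv` to resolve them.")
    }
    out <- tibble(label = s$label, thickness = s$thickness, sld = s$sld_h,
                  roughness = s$roughness)
    attr(out, "fronting_sld") <- stack$fronting_sld
    attr(out, "backing_sld") <- as.numeric(stack$backing)
    attr(out, "backing_roughness") <- stack$backing_roughness
    return(out)
  }
  sv <- stack_solvent(stack, solv)
  x <- sv$d_fraction
  dry <- if (nrow(s) > 0) s$sld_h + x * (s$sld_d - s$sld_h) else numeric(0)
  lay <- if (nrow(s) > 0) s$phi * dry + (1 - s$phi) * sv$sld else numeric(0)
  out <- tibble(label = s$label, thickness = s$thickness, sld = lay,
                roughness = s$roughness)
  attr(out, "fronting_sld") <- stack$fronting_sld
  attr(out, "backing_sld") <- sv$sld
  attr(out, "backing_roughness") <- stack$backing_roughness
  out
}

#' Reference stacks for the mucin-film scenarios
#'
#' Builds the named interface models used throughout the package, with
#' fitted-value defaults for the mucin film (22 Ang at 60% volume
#' occupation; 20 Ang at 50% occupation after the polymer rinse; a highly
#' hydrated 70 Ang polymer overlayer; 30 Ang mucin on the
#' GM1-containing membrane) and declared-assumption defaults for the
#' parts never published (SiO2 12 Ang, roughness 3 Ang, bilayer
#' dimensions and SLDs from standard supported-DPPC practice). The mucin
#' dry SLD pair (4.54e-6 in H2O, 5.09e-6 in D2O) is inferred from the
#' fitted layer SLDs via [infer_dry_sld()].
#'
#' @param scenario One of `"bare_mucin"`, `"mucin_polymer"`,
#'   `"dppc_membrane"`, `"dppc_gm1_mucin"`, `"dppc_gm1_mucin_polymer"`.
#' @param solv Backing [solvent()] (default D2O).
#' @param rinsed For `"mucin_polymer"`: `TRUE` gives the post-rinse state
#'   (polymer flushed away; mucin thinned to 20 Ang at 50% occupation).
#' @return A [layer_stack()].
#' @export
stack_scenario <- function(scenario = c("bare_mucin", "mucin_polymer",
                                        "dppc_membrane", "dppc_gm1_mucin",
                                        "dppc_gm1_mucin_polymer"),
                           solv = solvent(1), rinsed = FALSE) {
  scenario <- tryCatch(match.arg(scenario), error = function(e) {
    abort(paste0("Unknown scenario. Valid names: bare_mucin, mucin_polymer, ",
                 "dppc_membrane, dppc_gm1_mucin, dppc_gm1_mucin_polymer."))
  })
  sio2 <- slab("SiO2", 12, sld_h = 3.47e-6, roughness = 3)
  mucin <- function(thickness = 22, phi = 0.60) {
    slab("mucin", thickness, sld_h = 4.54e-6, sld_d = 5.09e-6,
         phi = phi, roughness = 4)
  }
  polymer <- slab("polymer", 70, sld_h = 1.2e-6, sld_d = 2.0e-6,
                  phi = 0.15, roughness = 8)
  gap <- slab("water_gap", 6, sld_h = 0, phi = 0, roughness = 2)
  heads <- function(lab, phi = 0.75) {
    slab(lab, 8, sld_h = 1.88e-6, sld_d = 1.88e-6, phi = phi, roughness = 3)
  }
  tails <- function(phi = 1) {
    slab("tails", 30, sld_h = -0.4e-6, sld_d = -0.4e-6, phi = phi,
         roughness = 3)
  }
  membrane <- function(phi_lipid = 1) {
    dplyr::bind_rows(sio2, gap, heads("heads_in", 0.75 * phi_lipid),
                     tails(phi_lipid), heads("heads_out", 0.75 * phi_lipid))
  }
  slabs <- switch(scenario,
    bare_mucin = dplyr::bind_rows(sio2, mucin()),
    mucin_polymer = if (rinsed) {
      dplyr::bind_rows(sio2, mucin(20, 0.50))
    } else {
      dplyr::bind_rows(sio2, mucin(22, 0.55), polymer)
    },
    dppc_membrane = membrane(),
    dppc_gm1_mucin = dplyr::bind_rows(membrane(0.68),
                                      mucin(30, 0.40)),
    dppc_gm1_mucin_polymer = dplyr::bind_rows(membrane(0.68),
                                              mucin(30, 0.40), polymer)
  )
  layer_stack(slabs = slabs, backing = solv)
}
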