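#' Run the full bulk-to-interface analysis from a single config
#'
#' Orchestrates the three stages in the order the experiments build on
#' each other -- bulk SAXS, thin-film QCM-D, and multi-contrast neutron
#' reflectometry -- from a plain-text (YAML) configuration or an
#' equivalent nested list. Each stage records a fit result and a tidy
#' summary; a stage failure is recorded and dependent outputs are
#' skipped while the remaining stages still run. The machine-readable
#' summary is deterministic for a given config and seed (byte-identical
#' on rerun).
#'
#' @param config Path to a YAML file or a nested list. Recognised blocks:
#'   `seed`, `output_dir`, and any of
#'   \describe{
#'     \item{saxs}{`curve` (file), `model` (`"coil"`), `init` (named
#'       list), and optionally `mixture` with `measured`, `pgm`, `argo`
#'       (files), `a`, `low_q_max` for the cluster diagnostic.}
#'     \item{qcmd}{`trace` (CSV), `events` (list of `time`/`label`),
#'       `density`, `dd_threshold`.}
#'     \item{nr}{`scenario` (template name), `contrasts` (named list of
#'       `file` + `d_fraction`), `free` (parameter names), `dq_over_q`.}
#'   }
#' @param figures Write diagnostic figures (PNG) into `output_dir`.
#' @return A list of class `pipeline_report` with per-stage results,
#'   `errors`, and the path of the JSON summary.
#' @export
run_pipeline <- function(config, figures = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- cfg$seed %||% 1
  out_dir <- cfg$output_dir %||% tempfile("mucofilm_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # validate all referenced files before any computation
  files <- c(cfg$saxs$curve, cfg$saxs$mixture$measured, cfg$saxs$mixture$pgm,
             cfg$saxs$mixture$argo, cfg$qcmd$trace,
             vapply(cfg$nr$contrasts %||% list(), function(x) x$file, ""))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    abort(sprintf("Config references missing file(s): %s.",
                  paste(missing, collapse = ", ")))
  }

  report <- list(seed = seed, output_dir = out_dir, stages = list(),
                 errors = list())
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      report$errors[[name]] <<- conditionMessage(res)
    } else {
      report$stages[[name]] <<- res
    }
  }

  if (!is.null(cfg$saxs)) {
    run_stage("saxs", function() {
      curve <- read_curve(cfg$saxs$curve,
                          unit_hint = cfg$saxs$unit_hint %||% "A_inv")
      init <- cfg$saxs$init %||% list()
      fit <- fit_gaussian_coil(curve, rg = init$rg %||% 3,
                               background = init$background %||% 0)
      out <- list(fit = fit, tidy = tidy(fit), glance = glance(fit))
      if (!is.null(cfg$saxs$mixture)) {
        mx <- cfg$saxs$mixture
        meas <- read_curve(mx$measured)
        ex <- excess_intensity(meas, read_curve(mx$pgm), read_curve(mx$argo),
                               a = mx$a %||% 1)
        low <- ex[ex$intensity > 0 & ex$q <= (mx$low_q_max %||% 0.004), ]
        out$excess <- ex
        if (nrow(low) >= 4) {
          out$cluster_power_law <- power_law_fit(
            scattering_curve(low$q, low$intensity, kind = "saxs"))
        }
      }
      out
    })
  }

  if (!is.null(cfg$qcmd)) {
    run_stage("qcmd", function() {
      trace <- read_qcmd(cfg$qcmd$trace)
      events <- dplyr::bind_rows(lapply(cfg$qcmd$events, as_tibble))
      steps <- segment_trace(trace, events)
      masses <- step_masses(steps, rho = cfg$qcmd$density %||% 1.05,
                            dd_threshold = cfg$qcmd$dd_threshold %||% 0.5)
      list(steps = steps, masses = masses)
    })
  }

  if (!is.null(cfg$nr)) {
    run_stage("nr", function() {
      template <- stack_scenario(cfg$nr$scenario %||% "bare_mucin")
      contrasts <- lapply(cfg$nr$contrasts, function(x) {
        list(solvent = solvent(x$d_fraction),
             curve = read_curve(x$file, kind = "reflectivity"))
      })
      series <- contrast_series(template, contrasts)
      free <- unlist(cfg$nr$free %||%
        c("mucin.thickness", "mucin.phi",
          paste0("scale.", names(contrasts))))
      fit <- corefine(series, free,
                      dq_over_q = cfg$nr$dq_over_q %||% 0.1,
                      seed = seed)
      list(fit = fit, tidy = tidy(fit), glance = glance(fit),
           profile = lapply(contrasts, function(ct)
             sld_profile(fit$stack, ct$solvent)))
    })
  }

  report$summary_path <- file.path(out_dir, "summary.json")
  write_pipeline_summary(report)
  if (figures) try(write_pipeline_figures(report), silent = TRUE)
  class(report) <- "pipeline_report"
  report
}

write_pipeline_summary <- function(report) {
  summarise_stage <- function(name, st) {
    if (name == "saxs") {
      out <- list(parameters = as.list(st$fit$params), chi2 = st$fit$chi2,
                  converged = st$fit$converged)
      if (!is.null(st$cluster_power_law)) {
        out$cluster_exponent <- st$cluster_power_law$exponent
        out$cluster_class <- st$cluster_power_law$fractal_class
      }
      out
    } else if (name == "qcmd") {
      list(steps = lapply(seq_len(nrow(st$masses)), function(i)
        as.list(st$masses[i, c("label", "mass_areal", "thickness",
                               "rigid_film_ok")])))
    } else {
      list(parameters = as.list(st$fit$params),
           stderr = as.list(st$fit$stderr),
           chi2 = st$fit$chi2,
           chi2_per_contrast = as.list(st$fit$chi2_per_contrast),
           converged = st$fit$converged)
    }
  }
  body <- list(
    seed = report$seed,
    stages = purrr::imap(report$stages, function(st, nm)
      summarise_stage(nm, st)),
    errors = report$errors
  )
  jsonlite::write_json(body, report$summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report$summary_path)
}

write_pipeline_figures <- function(report) {
  dir <- report$output_dir
  if (!is.null(report$stages$saxs)) {
    p <- autoplot(report$stages$saxs$fit)
    ggplot2::ggsave(file.path(dir, "saxs_fit.png"), p, width = 6, height = 4,
                    dpi = 150)
  }
  if (!is.null(report$stages$nr)) {
    prof <- report$stages$nr$profile[[1]]
    p <- ggplot2::ggplot(prof, ggplot2::aes(.data$z, .data$sld * 1e6)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "depth z (Ang)", y = "SLD (1e-6 / Ang^2)")
    ggplot2::ggsave(file.path(dir, "nr_sld_profile.png"), p,
                    width = 6, height = 4, dpi = 150)
  }
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: stages run = %s; errors = %s>\n",
              paste(names(x$stages), collapse = ", "),
              if (length(x$errors)) paste(names(x$errors), collapse = ", ")
              else "none"))
  cat("summary:", x$summary_path, "\n")
  invisible(x)
}

#' Compare two fits of the same model before and after a treatment
#'
#' Expresses "before/after polymer" and "before/after rinse" contrasts as
#' per-parameter deltas with uncertainties propagated in quadrature.
#' Antisymmetric under swapping the arguments.
#'
#' @param fit_before,fit_after `film_fit` objects sharing parameter
#'   names (extra parameters on either side are dropped; fully disjoint
#'   sets are an error).
#' @return Tibble with `term`, `before`, `after`, `delta`, `delta_se`.
#' @export
compare_states <- function(fit_before, fit_after) {
  shared <- intersect(names(fit_before$params), names(fit_after$params))
  if (length(shared) == 0) abort("The fits share no parameter names.")
  tibble(
    term = shared,
    before = unname(fit_before$params[shared]),
    after = unname(fit_after$params[shared]),
    delta = unname(fit_after$params[shared] - fit_before$params[shared]),
    delta_se = sqrt(unname(fit_before$stderr[shared])^2 +
                    unname(fit_after$stderr[shared])^2)
  )
}

#' Write a ready-to-run demo configuration over synthetic data
#'
#' Generates one synthetic dataset per stage into `dir` (coil SAXS curve,
#' five-step QCM-D trace, two-contrast reflectivity of the bare mucin
#' film), writes the matching `config.yaml`, and returns its path. Useful
#' both as a worked example and as the end-to-end test harness.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed used for every generator.
#' @return Path to the written config file.
#' @export
demo_pipeline_config <- function(dir = tempfile("mucofilm_demo_"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sx <- make_saxs_dataset(noise = noise_spec(level = 0.02, seed = seed))
  write_curve(sx$coil, file.path(dir, "coil.dat"))
  write_curve(sx$clustered, file.path(dir, "mixture_measured.dat"))
  write_curve(sx$dumbbell, file.path(dir, "pgm.dat"))
  write_curve(sx$coil, file.path(dir, "argo.dat"))

  tr <- make_qcmd_trace(noise = noise_spec(level = 0.05, seed = seed))
  write_qcmd(tr, file.path(dir, "qcmd.csv"))
  events <- attr(tr, "events")

  nr <- make_nr_dataset("bare_mucin",
                        noise = noise_spec(level = 0.01, seed = seed))
  write_curve(nr$contrasts$h2o$curve, file.path(dir, "nr_h2o.dat"))
  write_curve(nr$contrasts$d2o$curve, file.path(dir, "nr_d2o.dat"))

  cfg <- list(
    seed = seed,
    output_dir = file.path(dir, "out"),
    saxs = list(
      curve = file.path(dir, "coil.dat"),
      model = "coil", init = list(rg = 3),
      mixture = list(measured = file.path(dir, "mixture_measured.dat"),
                     pgm = file.path(dir, "pgm.dat"),
                     argo = file.path(dir, "argo.dat"),
                     a = sx$truth$a, low_q_max = 0.004)
    ),
    qcmd = list(
      trace = file.path(dir, "qcmd.csv"),
      events = lapply(seq_len(nrow(events)), function(i)
        list(time = events$time[i], label = events$label[i])),
      density = 1.05
    ),
    nr = list(
      scenario = "bare_mucin",
      contrasts = list(
        h2o = list(file = file.path(dir, "nr_h2o.dat"), d_fraction = 0),
        d2o = list(file = file.path(dir, "nr_d2o.dat"), d_fraction = 1)
      ),
      free = c("mucin.thickness", "mucin.phi", "scale.h2o", "scale.d2o")
    )
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
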