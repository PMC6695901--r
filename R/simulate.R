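#' Noise specification for synthetic datasets
#'
#' @param kind `"gaussian_relative"` (sigma proportional to the signal)
#'   or `"poisson_counts"` (counts drawn with a stated mean at the first
#'   point).
#' @param level Relative sigma (gaussian) or mean counts at the first
#'   point (poisson); > 0.
#' @param seed Integer seed; recorded in the output metadata so every
#'   generated dataset is reproducible.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian_relative", "poisson_counts"),
                       level = 0.02, seed = 1) {
  kind <- match.arg(kind)
  if (level <= 0) abort("`level` must be > 0.")
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

apply_noise <- function(truth, noise, floor_rel = NULL, ceil_rel = NULL) {
  n <- length(truth)
  if (noise$kind == "gaussian_relative") {
    rel <- rep(noise$level, n)
    if (!is.null(floor_rel)) {
      # counting-statistics flavour: relative error grows as the signal falls
      rel <- pmin(ceil_rel, pmax(floor_rel,
        floor_rel * (truth[1] / pmax(truth, .Machine$double.xmin))^(1 / 3)))
    }
    sigma <- rel * abs(truth)
    list(value = truth + rnorm(n, 0, sigma), sigma = sigma)
  } else {
    counts0 <- noise$level
    scale <- counts0 / truth[1]
    counts <- rpois(n, pmax(truth * scale, 0))
    list(value = counts / scale, sigma = sqrt(pmax(counts, 1)) / scale)
  }
}

#' Synthetic SAXS dataset: components, additive mixture, clustered mixture
#'
#' Generates the bulk-solution test set on the experimental q window
#' (7e-3 to 6 per nm by default): a Gaussian-coil polymer curve (Rg 2.5
#' nm), a dumbbell mucin curve, their additive mixture
#' `I_mucin + A * I_polymer` (the non-interacting null), and an
#' "interacting" mixture with an added low-q cluster power-law tail of
#' exponent -3.7 -- the diagnostic signature of mucin/polymer cluster
#' formation. Truth parameters travel with the result.
#'
#' @param a Mixture weight factor A (1 for 1:1, 2 for 1:2 weight ratio).
#' @param rg_coil Polymer coil radius of gyration, nm.
#' @param coil_scale,dumbbell Component parameters; `dumbbell` is a list
#'   passed to [dumbbell_intensity()].
#' @param cluster_prefactor,cluster_exponent Low-q cluster tail
#'   `prefactor * q^exponent` (q in 1/Ang).
#' @param qgrid Momentum-transfer grid, 1/Angstrom (log-spaced over the
#'   experimental window by default).
#' @param noise A [noise_spec()]; relative Gaussian noise on every curve.
#' @return A list of class `saxs_dataset` with [scattering_curve()]s
#'   `coil`, `dumbbell`, `additive`, `clustered`, and `truth` (the
#'   generating parameters, including the seed).
#' @export
make_saxs_dataset <- function(a = 2, rg_coil = 2.5, coil_scale = 1,
                              dumbbell = list(),
                              cluster_prefactor = 1e-9,
                              cluster_exponent = -3.7,
                              qgrid = exp(seq(log(7e-4), log(0.6),
                                              length.out = 140)),
                              noise = noise_spec(level = 0.02, seed = 1)) {
  if (a < 0) abort("`a` must be >= 0.")
  db_args <- modifyList(
    list(xi = 3, Xi = 50, n_exp = 2.7, i1 = 1, i2 = 0.005,
         r_globule = 10, poly = 0.2, phi_hs = 0.15, scale = 1.5),
    dumbbell
  )
  i_coil <- gaussian_coil_intensity(qgrid, rg_coil, coil_scale)
  i_db <- do.call(dumbbell_intensity, c(list(q = qgrid), db_args))
  i_add <- mixture_model(i_db, i_coil, a)
  i_cluster <- cluster_prefactor * qgrid^cluster_exponent
  i_clu <- i_add + i_cluster

  with_seed(noise$seed, {
    mk <- function(truth) {
      n <- apply_noise(truth, noise)
      scattering_curve(qgrid, n$value, n$sigma, kind = "saxs")
    }
    out <- list(coil = mk(i_coil), dumbbell = mk(i_db),
                additive = mk(i_add), clustered = mk(i_clu))
  })
  out$truth <- list(a = a, rg_coil = rg_coil, coil_scale = coil_scale,
                    dumbbell = db_args,
                    cluster_prefactor = cluster_prefactor,
                    cluster_exponent = cluster_exponent,
                    noise = noise)
  class(out) <- "saxs_dataset"
  out
}

#' Synthetic multi-contrast neutron reflectivity dataset
#'
#' Forward-models a [stack_scenario()] in each requested solvent on a
#' log-spaced grid (0.008-0.25 1/Ang by default), applies dq/q Gaussian
#' resolution smearing, and corrupts with noise whose relative error
#' grows as the reflectivity falls (floor 1%, ceiling 20% in the default
#' Gaussian mode), emulating counting statistics. Truth parameters are
#' stored so recovery can be scored without re-entering them by hand.
#'
#' @param scenario Scenario name, or a ready-made [layer_stack()].
#' @param contrasts Named list of [solvent()]s (default H2O and D2O).
#' @param noise A [noise_spec()].
#' @param dq_over_q,convention Resolution, as in [smear()].
#' @param qgrid Measurement grid, 1/Angstrom.
#' @param ... Passed to [stack_scenario()] (e.g. `rinsed = TRUE`).
#' @return A [contrast_series()] whose template is the generating stack;
#'   the truth (stack + settings) sits in the `truth` attribute.
#' @export
make_nr_dataset <- function(scenario = "bare_mucin",
                            contrasts = list(h2o = solvent(0),
                                             d2o = solvent(1)),
                            noise = noise_spec(level = 0.01, seed = 1),
                            dq_over_q = 0.1, convention = "fwhm",
                            qgrid = exp(seq(log(0.008), log(0.25),
                                            length.out = 90)),
                            ...) {
  stk <- if (inherits(scenario, "layer_stack")) scenario
         else stack_scenario(scenario, ...)
  sets <- with_seed(noise$seed, {
    lapply(contrasts, function(sv) {
      r <- reflectivity_model(stk, qgrid, sv, dq_over_q, convention)
      nz <- if (noise$kind == "gaussian_relative") {
        apply_noise(r, noise, floor_rel = noise$level, ceil_rel = 0.20)
      } else {
        apply_noise(r, noise)
      }
      list(solvent = sv,
           curve = scattering_curve(qgrid, pmax(nz$value, 0), nz$sigma,
                                    kind = "reflectivity",
                                    intensity_unit = "reflectivity"))
    })
  })
  series <- contrast_series(stk, sets)
  attr(series, "truth") <- list(stack = stk, dq_over_q = dq_over_q,
                                convention = convention, noise = noise)
  series
}

#' Synthetic multi-overtone QCM-D trace
#'
#' Builds the stepped injection/rinse staircase of a film-deposition
#' protocol: each step approaches its plateau exponentially (time
#' constant `tau`, default 30 s), per overtone, with optional linear
#' drift and Gaussian noise. Frequency shifts are generated raw (an
#' ideal rigid film has identical delta_f/n across overtones, so the raw
#' shift at overtone n is n times the normalised step height).
#'
#' @param steps Tibble with one row per protocol step: `label`,
#'   `df_per_n` (target cumulative normalised frequency shift, Hz) and
#'   `dd` (target cumulative dissipation shift, 1e-6 units). The first
#'   row is typically a zero baseline.
#' @param durations Step durations in seconds (recycled).
#' @param overtones Odd overtone numbers.
#' @param tau Exponential approach time constant, s.
#' @param noise A [noise_spec()]; `level` is the absolute sigma in Hz on
#'   delta_f (dissipation noise is `level/10` in 1e-6 units).
#' @param drift Linear baseline drift in Hz/h on the raw fundamental.
#' @param dt Sampling interval, s.
#' @param f0 Fundamental frequency, Hz.
#' @return A [qcmd_trace()]; the `events` attribute holds the step-start
#'   annotations and `truth` the generating parameters.
#' @export
make_qcmd_trace <- function(steps = deposition_protocol_steps(),
                            durations = 600, overtones = c(3, 5, 7, 9, 11),
                            tau = 30,
                            noise = noise_spec(level = 0.05, seed = 1),
                            drift = 0, dt = 1, f0 = 5e6) {
  steps <- as_tibble(steps)
  if (!all(c("label", "df_per_n", "dd") %in% names(steps))) {
    abort("`steps` needs columns label, df_per_n, dd.")
  }
  durations <- rep_len(durations, nrow(steps))
  t_start <- cumsum(c(0, durations[-length(durations)]))
  t_end <- cumsum(durations)
  time <- seq(0, sum(durations) - dt, by = dt)

  target_at <- function(tt, targets) {
    # piecewise-exponential approach from the previous plateau
    val <- numeric(length(tt))
    prev <- 0
    for (i in seq_len(nrow(steps))) {
      inw <- tt >= t_start[i] & tt < t_end[i]
      val[inw] <- targets[i] + (prev - targets[i]) *
        exp(-(tt[inw] - t_start[i]) / tau)
      prev <- targets[i] + (prev - targets[i]) * exp(-durations[i] / tau)
    }
    val
  }

  data <- with_seed(noise$seed, {
    purrr::map_dfr(overtones, function(n) {
      f_clean <- target_at(time, steps$df_per_n * n) + drift * n * time / 3600
      d_clean <- target_at(time, steps$dd)
      tibble(time = time, n = n,
             delta_f = f_clean + rnorm(length(time), 0, noise$level),
             delta_d = d_clean + rnorm(length(time), 0, noise$level / 10))
    })
  })
  tr <- qcmd_trace(data, f0 = f0, normalized = FALSE)
  attr(tr, "events") <- tibble(time = t_start, label = steps$label)
  attr(tr, "truth") <- list(steps = steps, durations = durations, tau = tau,
                            noise = noise, drift = drift)
  tr
}

#' Protocol step targets mimicking the mucin/polymer deposition run
#'
#' The five-step protocol: (i) buffer baseline, (ii) mucin adsorption (a
#' thin rigid film of about 55 ng/cm^2, i.e. delta_f/n of about -3.1 Hz
#' at C = 17.7 ng/(cm^2 Hz), with a small dissipation rise of 0.3e-6),
#' (iii) buffer rinse with no desorption, (iv) polymer injection adding a
#' normalised shift of -6 Hz at still-low dissipation, and (v) a final
#' rinse where part of the added material is flushed away.
#'
#' @param c Mass-sensitivity constant used to translate the target mucin
#'   mass into a frequency shift.
#' @return Tibble of cumulative step targets for [make_qcmd_trace()].
#' @export
deposition_protocol_steps <- function(c = sauerbrey_constant()) {
  df_mucin <- -55 / c          # about -3.1 Hz normalised
  tibble(
    label = c("baseline", "adsorb", "rinse1", "polymer", "rinse2"),
    df_per_n = c(0, df_mucin, df_mucin, df_mucin - 6, df_mucin - 6 + 2),
    dd = c(0, 0.3, 0.3, 0.45, 0.6)
  )
}
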