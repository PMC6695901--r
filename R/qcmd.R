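#' Dissipation factor from the ring-down decay time
#'
#' The microbalance software determines the resonance frequency f and the
#' decay time tau0 of the exponentially damped ring-down after the drive
#' voltage is switched off, giving the dissipation factor
#' `D = 1/(f * tau0)`. The conventional relation includes a factor pi in
#' the denominator, `D = 1/(pi * f * tau0)`; set `pi_convention = TRUE`
#' to use it.
#'
#' @param f Resonance frequency, Hz (> 0).
#' @param tau0 Ring-down decay time, s (> 0).
#' @param pi_convention Use the 1/(pi f tau) form instead (default FALSE).
#' @return Dimensionless dissipation factor.
#' @examples
#' dissipation_factor(5e6, 2e-4)  # 1e-3
#' @export
dissipation_factor <- function(f, tau0, pi_convention = FALSE) {
  if (any(f <= 0) || any(tau0 <= 0)) abort("`f` and `tau0` must be > 0.")
  d <- 1 / (f * tau0)
  if (pi_convention) d <- d / pi
  d
}

#' Sauerbrey mass-sensitivity constant of an AT-cut quartz crystal
#'
#' `C = sqrt(rho_q * mu_q) / (2 * f0^2)`, converted to ng/(cm^2 Hz). For
#' the standard 5 MHz AT-cut crystal (rho_q = 2648 kg/m^3, mu_q =
#' 2.947e10 Pa) this gives 17.7 ng/(cm^2 Hz).
#'
#' @param f0 Fundamental resonance frequency, Hz.
#' @param rho_q Quartz density, kg/m^3.
#' @param mu_q Quartz shear modulus, Pa.
#' @return C in ng/(cm^2 Hz); scales as 1/f0^2.
#' @examples
#' sauerbrey_constant()  # 17.7
#' @export
sauerbrey_constant <- function(f0 = 5e6, rho_q = 2648, mu_q = 2.947e10) {
  if (f0 <= 0 || rho_q <= 0 || mu_q <= 0) abort("All inputs must be > 0.")
  c_si <- sqrt(rho_q * mu_q) / (2 * f0^2)  # kg / (m^2 Hz)
  c_si * 1e12 / 1e4                        # -> ng / (cm^2 Hz)
}

#' Sauerbrey areal mass from an overtone frequency shift
#'
#' `delta_m = -C * delta_f / n`: adsorption (delta_f < 0) gives positive
#' mass. Valid for thin rigid films; check [rigidity_check()] first.
#'
#' @param delta_f Frequency shift at overtone `n`, Hz (raw, not
#'   overtone-normalised).
#' @param n Odd positive overtone number.
#' @param c Mass-sensitivity constant, ng/(cm^2 Hz).
#' @return Areal mass in ng/cm^2.
#' @export
sauerbrey_mass <- function(delta_f, n = 1, c = sauerbrey_constant()) {
  if (any(n <= 0) || any(n %% 2 == 0)) abort("`n` must be an odd positive overtone.")
  -c * delta_f / n
}

#' Film thickness from areal mass
#'
#' `d = delta_m / rho` with unit conversion to Angstrom. For mucin a
#' density of 1.05 g/cm^3 (hydrated sugars) is conventional.
#'
#' @param delta_m Areal mass, ng/cm^2.
#' @param rho Film density, g/cm^3 (> 0).
#' @return Thickness in Angstrom.
#' @examples
#' thickness_from_mass(210, 1.05)  # 20 Ang
#' @export
thickness_from_mass <- function(delta_m, rho = 1.05) {
  if (rho <= 0) abort("`rho` must be > 0 (g/cm^3).")
  # ng/cm^2 / (g/cm^3) = 1e-9 cm = 0.1 Ang
  delta_m / rho * 0.1
}

#' Multi-overtone QCM-D trace
#'
#' Stores time series of frequency shift and dissipation shift for a set
#' of odd overtones in long (tidy) form.
#'
#' @param data Tibble with columns `time` (s), `n` (odd overtone),
#'   `delta_f` (Hz), `delta_d` (units of 1e-6).
#' @param f0 Fundamental resonance frequency, Hz.
#' @param normalized `TRUE` when `delta_f` is already divided by the
#'   overtone number (as plotted in most instrument software).
#' @return A list of class `qcmd_trace`.
#' @export
qcmd_trace <- function(data, f0 = 5e6, normalized = FALSE) {
  data <- as_tibble(data)
  req <- c("time", "n", "delta_f", "delta_d")
  if (!all(req %in% names(data))) {
    abort(sprintf("`data` needs columns: %s.", paste(req, collapse = ", ")))
  }
  ns <- sort(unique(data$n))
  if (length(ns) == 0 || any(ns %% 2 == 0) || any(ns <= 0)) {
    abort("Overtones must be a non-empty set of odd positive integers.")
  }
  t_by_n <- dplyr::group_by(data, .data$n)
  bad <- dplyr::summarise(t_by_n, ok = all(diff(.data$time) > 0))
  if (!all(bad$ok)) abort("`time` must be strictly increasing within each overtone.")
  structure(list(data = data, f0 = f0, normalized = normalized,
                 overtones = ns),
            class = "qcmd_trace")
}

#' @export
print.qcmd_trace <- function(x, ...) {
  cat(sprintf("<qcmd_trace: overtones %s, %.0f-%.0f s, %s delta_f>\n",
              paste(x$overtones, collapse = ","),
              min(x$data$time), max(x$data$time),
              if (x$normalized) "normalised" else "raw"))
  invisible(x)
}

#' Read a QCM-D CSV export
#'
#' Expects one `time` column plus paired columns `f<n>` and `D<n>` per
#' overtone (e.g. `f3`, `D3`), the common wide export of instrument
#' software.
#'
#' @param path CSV path.
#' @inheritParams qcmd_trace
#' @return A [qcmd_trace()].
#' @export
read_qcmd <- function(path, f0 = 5e6, normalized = FALSE) {
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (!"time" %in% names(df) || length(fcols) == 0) {
    abort("CSV must have a `time` column and f<n>/D<n> pairs.")
  }
  long <- purrr::map_dfr(fcols, function(fc) {
    n <- as.integer(sub("^f", "", fc))
    dc <- paste0("D", n)
    if (!dc %in% names(df)) abort(sprintf("Missing dissipation column `%s`.", dc))
    tibble(time = df$time, n = n, delta_f = df[[fc]], delta_d = df[[dc]])
  })
  qcmd_trace(long, f0 = f0, normalized = normalized)
}

#' Write a QCM-D trace as the wide CSV it was read from
#'
#' @param trace A [qcmd_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qcmd <- function(trace, path) {
  stopifnot(inherits(trace, "qcmd_trace"))
  wide <- tidyr::pivot_wider(trace$data, names_from = "n",
                             values_from = c("delta_f", "delta_d"))
  names(wide) <- sub("^delta_f_", "f", names(wide))
  names(wide) <- sub("^delta_d_", "D", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Segment a QCM-D trace into protocol steps
#'
#' Given annotated injection/rinse events, splits the trace into step
#' windows and summarises each step's plateau per overtone. The plateau
#' is the median of the trailing fraction of the window (default 20%),
#' which is robust to injection transients; windows shorter than 5
#' samples fall back to the whole window with a warning. Frequency-shift
#' steps (`delta_f`) are plateau differences between consecutive steps,
#' reported raw and overtone-normalised, along with the harmonic spread
#' (max minus min of the normalised shift across overtones).
#'
#' @param trace A [qcmd_trace()].
#' @param events Tibble or data frame with columns `time` (s, ordered,
#'   within the trace span) and `label` (e.g. baseline, adsorb, rinse1,
#'   polymer, rinse2).
#' @param plateau_fraction Trailing fraction of each window used for the
#'   plateau median.
#' @return A tibble of class `qcmd_steps`, one row per step x overtone,
#'   with `label`, `t_start`, `t_end`, `n`, `plateau_f`, `plateau_d`,
#'   `delta_f` (raw step change), `delta_f_norm` (`delta_f/n`),
#'   `delta_d`, and per-step `harmonic_spread` (Hz, on normalised
#'   shifts). The first step has no predecessor; its deltas are relative
#'   to zero.
#' @export
segment_trace <- function(trace, events, plateau_fraction = 0.2) {
  stopifnot(inherits(trace, "qcmd_trace"))
  events <- as_tibble(events)
  if (!all(c("time", "label") %in% names(events))) {
    abort("`events` needs columns `time` and `label`.")
  }
  if (is.unsorted(events$time, strictly = TRUE)) {
    abort("`events$time` must be strictly increasing.")
  }
  t_all <- trace$data$time
  if (events$time[1] < min(t_all) || max(events$time) > max(t_all)) {
    abort("Events must lie within the trace time span.")
  }
  starts <- events$time
  ends <- c(events$time[-1], max(t_all))

  plateau_one <- function(d, t0, t1) {
    w <- d[d$time >= t0 & d$time < t1 | (t1 == max(t_all) & d$time == t1), ]
    if (nrow(w) < 5) {
      warn(sprintf("Step window [%g, %g) has under 5 samples; using the whole window.", t0, t1))
      frac <- 1
    } else {
      frac <- plateau_fraction
    }
    k <- max(1L, ceiling(nrow(w) * frac))
    tail_w <- w[seq(nrow(w) - k + 1L, nrow(w)), ]
    c(f = median(tail_w$delta_f), d = median(tail_w$delta_d))
  }

  rows <- purrr::map_dfr(seq_along(starts), function(i) {
    purrr::map_dfr(trace$overtones, function(n) {
      d <- trace$data[trace$data$n == n, ]
      p <- plateau_one(d, starts[i], ends[i])
      tibble(step = i, label = events$label[i],
             t_start = starts[i], t_end = ends[i], n = n,
             plateau_f = p[["f"]], plateau_d = p[["d"]])
    })
  })

  rows <- dplyr::group_by(rows, .data$n)
  rows <- dplyr::mutate(rows,
    delta_f = .data$plateau_f - dplyr::lag(.data$plateau_f, default = 0),
    delta_d = .data$plateau_d - dplyr::lag(.data$plateau_d, default = 0)
  )
  rows <- dplyr::ungroup(rows)
  div <- if (trace$normalized) 1 else rows$n
  rows$delta_f_norm <- rows$delta_f / div
  rows <- dplyr::group_by(rows, .data$step)
  rows <- dplyr::mutate(rows,
    harmonic_spread = max(.data$delta_f_norm) - min(.data$delta_f_norm))
  rows <- dplyr::ungroup(rows)
  class(rows) <- c("qcmd_steps", class(rows))
  attr(rows, "f0") <- trace$f0
  rows
}

#' Rigid-film criterion from the dissipation change
#'
#' The Sauerbrey relation holds only for thin rigid films. A step is
#' accepted as rigid when the largest dissipation change across overtones
#' stays at or below the threshold (default 0.5e-6, i.e. 0.5 in the
#' trace's 1e-6 units); the boundary is inclusive.
#'
#' @param steps A `qcmd_steps` tibble from [segment_trace()] (may be
#'   pre-filtered to one step).
#' @param dd_threshold Threshold in units of 1e-6 (default 0.5).
#' @return A tibble with one row per step: `label`, `max_delta_d`,
#'   `rigid_film_ok`.
#' @export
rigidity_check <- function(steps, dd_threshold = 0.5) {
  stopifnot(inherits(steps, "qcmd_steps") || is.data.frame(steps))
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(steps), .data$step, .data$label),
    max_delta_d = max(abs(.data$delta_d)), .groups = "drop"
  )
  out$rigid_film_ok <- out$max_delta_d <= dd_threshold
  out
}

#' Per-step Sauerbrey masses and thicknesses
#'
#' Applies [sauerbrey_mass()] to the overtone-averaged normalised
#' frequency shift of each step and [thickness_from_mass()] at the given
#' density, flagging steps that fail the rigidity criterion (their
#' Sauerbrey numbers are reported but unreliable).
#'
#' @param steps A `qcmd_steps` tibble from [segment_trace()].
#' @param c Mass-sensitivity constant, ng/(cm^2 Hz).
#' @param rho Film density for the thickness estimate, g/cm^3.
#' @inheritParams rigidity_check
#' @return Tibble, one row per step: `label`, `delta_f_norm` (overtone
#'   mean), `mass_areal` (ng/cm^2), `thickness` (Ang),
#'   `harmonic_spread`, `max_delta_d`, `rigid_film_ok`.
#' @export
step_masses <- function(steps, c = sauerbrey_constant(), rho = 1.05,
                        dd_threshold = 0.5) {
  per <- dplyr::summarise(
    dplyr::group_by(as_tibble(steps), .data$step, .data$label),
    delta_f_norm = mean(.data$delta_f_norm),
    harmonic_spread = .data$harmonic_spread[1],
    max_delta_d = max(abs(.data$delta_d)),
    .groups = "drop"
  )
  per$mass_areal <- sauerbrey_mass(per$delta_f_norm, n = 1, c = c)
  per$thickness <- thickness_from_mass(per$mass_areal, rho)
  per$rigid_film_ok <- per$max_delta_d <= dd_threshold
  per
}
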