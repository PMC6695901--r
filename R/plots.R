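#' Plot a scattering curve
#'
#' SAXS curves are drawn log-log; reflectivity curves log-linear in R
#' against q. Error bars appear when the curve carries uncertainties.
#'
#' @param object A [scattering_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scattering_curve <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/Ang)",
                  y = if (curve_kind(object) == "reflectivity") "R(q)"
                      else "I(q)")
  if (curve_kind(object) == "saxs") p <- p + ggplot2::scale_x_log10()
  if (has_sigma(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$intensity - .data$sigma,
                               .Machine$double.xmin),
                   ymax = .data$intensity + .data$sigma),
      linewidth = 0.3, alpha = 0.5)
  }
  p
}

#' Plot a fit together with its data
#'
#' For single-curve fits (Gaussian coil) overlays the model on the data;
#' for multi-contrast co-refinements draws one panel per contrast.
#'
#' @param object A `film_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.film_fit <- function(object, ...) {
  if (!is.null(object$series)) {
    dat <- purrr::imap_dfr(object$series$contrasts, function(ct, nm) {
      r <- reflectivity_model(object$stack, ct$curve$q, ct$solvent,
                              object$dq_over_q, object$convention)
      dplyr::mutate(as_tibble(ct$curve), contrast = nm, model = r)
    })
    return(
      ggplot2::ggplot(dat, ggplot2::aes(.data$q, .data$intensity)) +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "blue") +
        ggplot2::scale_y_log10() +
        ggplot2::facet_wrap(~contrast) +
        ggplot2::labs(x = "q (1/Ang)", y = "R(q)")
    )
  }
  if (is.null(object$data) || is.null(object$fitted)) {
    abort("This fit carries no data/fitted curves to plot.")
  }
  ggplot2::ggplot(as_tibble(object$data),
                  ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = as_tibble(object$fitted), colour = "blue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/Ang)", y = "I(q)")
}

#' Plot a multi-overtone QCM-D trace
#'
#' Frequency shifts (overtone-normalised) and dissipation shifts against
#' time, coloured by overtone.
#'
#' @param object A [qcmd_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qcmd_trace <- function(object, ...) {
  d <- object$data
  div <- if (object$normalized) 1 else d$n
  long <- dplyr::bind_rows(
    tibble(time = d$time, n = d$n, value = d$delta_f / div,
           what = "delta_f / n (Hz)"),
    tibble(time = d$time, n = d$n, value = d$delta_d,
           what = "delta_D (1e-6)")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = factor(.data$n))) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", colour = "overtone")
}

#' Plot the SLD depth profile of a stack
#'
#' @inheritParams sld_profile
#' @return A ggplot object.
#' @export
plot_sld_profile <- function(stack, solv = NULL, dz = 0.5, pad = 30) {
  prof <- sld_profile(stack, solv, dz, pad)
  ggplot2::ggplot(prof, ggplot2::aes(.data$z, .data$sld * 1e6)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth z (Ang)", y = "SLD (1e-6 / Ang^2)")
}
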