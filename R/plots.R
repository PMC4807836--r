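#' Plot a broadened vibrational spectrum with its stick modes
#'
#' @param object a `vibrolf_modes` object.
#' @param fwhm Lorentzian full width at half maximum (cm^-1).
#' @param ... passed to [broaden_spectrum()].
#' @return A ggplot.
#' @method autoplot vibrolf_modes
#' @export
autoplot.vibrolf_modes <- function(object, fwhm = 10, ...) {
  spec <- broaden_spectrum(object, fwhm = fwhm, ...)
  sticks <- tidy(object) |> dplyr::filter(.data$frequency > 0)
  if (all(is.na(sticks$intensity))) sticks$intensity <- 1
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$wavenumber, y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::geom_segment(
      data = sticks,
      ggplot2::aes(x = .data$frequency, xend = .data$frequency,
                   y = 0, yend = .data$intensity * max(spec$absorbance) /
                     max(sticks$intensity)),
      linetype = "dashed", alpha = 0.4, inherit.aes = FALSE) +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)),
                  y = "absorbance (arb.)",
                  title = "Broadened vibrational spectrum")
}

#' Plot Huang-Rhys factors against mode frequency
#'
#' Stem plot of the single-phonon emission weight sigma_1 for every mode,
#' the standard way of displaying which odorant vibrations couple to the
#' electron transfer.
#'
#' @param object a `vibrolf_coupling` table.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vibrolf_coupling
#' @export
autoplot.vibrolf_coupling <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$sigma1)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(omega[mu] ~ (cm^-1)),
                  y = expression(sigma[1]),
                  title = "Electron-phonon coupling per vibrational mode")
}

#' Plot a free-energy profile
#'
#' @param object a `vibrolf_free_energy` profile.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vibrolf_free_energy
#' @export
autoplot.vibrolf_free_energy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "minimum"),
                        linetype = "dotted") +
    ggplot2::labs(x = "potential energy (kcal/mol)", y = "G (kcal/mol)",
                  title = sprintf("Free-energy profile (%s state)",
                                  attr(object, "state")))
}

#' Plot protein-vacuum mode shifts
#'
#' @param object a `vibrolf_mode_match` table.
#' @param unit `"mev"` or `"cm1"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vibrolf_mode_match
#' @export
autoplot.vibrolf_mode_match <- function(object, unit = c("mev", "cm1"), ...) {
  unit <- match.arg(unit)
  y <- if (unit == "mev") "shift_mev" else "shift_cm1"
  lab <- if (unit == "mev") expression(Delta * nu ~ (meV)) else expression(Delta * nu ~ (cm^-1))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_vacuum, y = .data[[y]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(nu[vacuum] ~ (cm^-1)), y = lab,
                  title = "Embedded-vs-vacuum frequency shifts")
}

#' Plot a time series with its running mean
#'
#' Works for the tibbles returned by [rmsd_series()], [distance_series()]
#' and [interaction_energy()] (uses the `total` column for the latter).
#'
#' @param series a tibble with a `time` column and one value column.
#' @param window smoothing window (default 50 steps).
#' @return A ggplot.
#' @export
plot_series <- function(series, window = 50L) {
  val <- setdiff(names(series), "time")
  val <- if ("total" %in% val) "total" else val[length(val)]
  series$smooth <- running_mean(series[[val]],
                                min(window, nrow(series)))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[val]]), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), linewidth = 0.8) +
    ggplot2::labs(x = "time (ns)", y = val)
}
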