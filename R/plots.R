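#' Plot a reconstructed temperature-depth profile
#'
#' @param object A `pptr_fit`.
#' @param ... Unused.
#' @return A ggplot: temperature rise versus depth.
#' @method autoplot pptr_fit
#' @export
autoplot.pptr_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$depth_mm, y = .data$delta_T_K)) +
    ggplot2::geom_line(color = "#b2182b") +
    ggplot2::labs(x = "depth [mm]", y = expression(Delta * T ~ "[K]"),
                  title = "Reconstructed initial temperature profile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot temperature-depth profiles
#'
#' Draws one curve per (site, wavelength, session, repeat) group of a long
#' profile tibble, faceted by wavelength, colored by time since injury —
#' the standard view of bruise evolution.
#'
#' @param profiles Long profile tibble (`depth_mm`, `delta_T_K`, plus any
#'   of `site`, `wavelength_nm`, `time_h`, `repeat`).
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles) {
  check_profile_frame(profiles)
  keys <- intersect(c("site", "wavelength_nm", "time_h", "repeat"),
                    names(profiles))
  profiles$.group <- interaction(profiles[keys], drop = TRUE)
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$depth_mm, y = .data$delta_T_K,
                                    group = .data$.group))
  p <- if ("time_h" %in% keys)
    p + ggplot2::geom_line(ggplot2::aes(color = .data$time_h)) +
      ggplot2::scale_color_viridis_c(name = "time [h]")
  else p + ggplot2::geom_line()
  if ("wavelength_nm" %in% keys)
    p <- p + ggplot2::facet_wrap(
      ggplot2::vars(.data$wavelength_nm),
      labeller = ggplot2::labeller(
        .default = function(x) paste0(x, " nm")),
      scales = "free_x")
  if ("site" %in% keys)
    p <- p + ggplot2::aes(linetype = .data$site)
  p + ggplot2::labs(x = "depth [mm]", y = expression(Delta * T ~ "[K]")) +
    ggplot2::theme_minimal()
}

#' Plot an epsilon time series
#'
#' Bruise-to-healthy contrast \eqn{\varepsilon} versus time since injury,
#' with error bars of one propagated standard deviation, one panel or color
#' per wavelength.
#'
#' @param epsilon A tibble from [epsilon_series()].
#' @return A ggplot.
#' @export
plot_epsilon_series <- function(epsilon) {
  stopifnot(all(c("time_h", "epsilon", "epsilon_sd", "wavelength_nm") %in%
                  names(epsilon)))
  ggplot2::ggplot(epsilon,
                  ggplot2::aes(x = .data$time_h, y = .data$epsilon,
                               color = factor(.data$wavelength_nm))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$epsilon - .data$epsilon_sd,
                   ymax = .data$epsilon + .data$epsilon_sd), width = 4) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(name = "wavelength",
                                values = c(`532` = "#1b7837", `1064` = "#762a83"),
                                labels = function(x) paste0(x, " nm")) +
    ggplot2::labs(x = "time since injury [h]",
                  y = expression(epsilon == IUC[bruise] / IUC[healthy] - 1)) +
    ggplot2::theme_minimal()
}
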