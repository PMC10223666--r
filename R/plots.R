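# ggplot2 autoplot() methods for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col geom_hline labs scale_fill_viridis_c theme_minimal
NULL

#' Plot an MSD curve
#' @param object an `msd_curve` from [msd()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot(object[object$lag_ns > 0, ], aes(x = .data$lag_ns, y = .data$msd_nm2)) +
    geom_line(colour = "steelblue") +
    labs(x = expression(tau ~ "(ns)"), y = expression(M(tau) ~ (nm^2)),
      title = "Mean squared displacement") +
    theme_minimal()
}

#' Plot an order-parameter profile
#' @param object an `order_profile` from [order_parameters()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.order_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$carbon, y = .data$s_ch)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    labs(x = "tail carbon index", y = expression(S[CH]),
      title = "Chain order parameters") +
    theme_minimal()
}

#' Plot a radial distribution function
#' @param object an `rdf_curve` from [rdf()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rdf_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$g)) +
    geom_line(colour = "firebrick") +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey70") +
    labs(x = "r (Å)", y = "g(r)", title = "Radial distribution function") +
    theme_minimal()
}

#' Plot a 2-D headgroup density map
#' @param object a `density_map2d` from [density_map()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.density_map2d <- function(object, ...) {
  ggplot(object, aes(x = .data$phi_mid, y = .data$cos_mid,
    fill = .data$rel_density)) +
    geom_tile() +
    scale_fill_viridis_c(name = "relative\ndensity") +
    labs(x = expression(phi), y = expression(cos ~ theta),
      title = "Headgroup density (equal-area projection)") +
    theme_minimal()
}

#' Plot a peptide tilt series
#' @param object a `tilt_series` from [tilt_series()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tilt_series <- function(object, ...) {
  ggplot(object[!object$missing, ], aes(x = .data$time_ns, y = .data$tilt_deg)) +
    geom_line(colour = "darkorange") +
    geom_hline(yintercept = c(0, 90, 180), linetype = 3, colour = "grey70") +
    labs(x = "time (ns)", y = "tilt (degrees)",
      title = "Peptide tilt vs local bilayer normal") +
    theme_minimal()
}
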