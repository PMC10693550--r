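#' Tidy a phase call
#'
#' @param x A `cc_phase_call`.
#' @param ... Unused.
#' @return One-row tibble with the label and its evidence.
#' @export
tidy.cc_phase_call <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(label = x$label), x$evidence)
}

#' @rdname tidy.cc_phase_call
#' @export
glance.cc_phase_call <- function(x, ...) tidy(x)

#' Tidy a diffusion result
#'
#' @param x A `cc_diffusion`.
#' @param ... Unused.
#' @return The MSD curve as a tibble (`lag_ps`, `msd_nm2`).
#' @export
tidy.cc_diffusion <- function(x, ...) x$msd

#' @rdname tidy.cc_diffusion
#' @export
glance.cc_diffusion <- function(x, ...) {
  tibble::tibble(D_cm2_s = x$D_cm2_s, D_sd = x$D_sd,
                 slope_nm2_ps = x$fit$slope, r_squared = x$fit$r_squared,
                 subdiffusive = x$subdiffusive, n_chains = x$n_chains,
                 n_frames = x$n_frames)
}

#' Tidy a cluster report
#'
#' @param x A `cc_cluster_report`.
#' @param ... Unused.
#' @return The per-frame cluster summary tibble.
#' @export
tidy.cc_cluster_report <- function(x, ...) x$per_frame

#' @rdname tidy.cc_cluster_report
#' @export
glance.cc_cluster_report <- function(x, ...) {
  tibble::tibble(dimer_dominance = x$dimer_dominance,
                 largest_cluster_fraction = x$largest_cluster_fraction,
                 n_chains = x$n_chains, n_frames = x$n_frames)
}

#' Tidy a phase summary (majority vote over replicates)
#'
#' @param x A `cc_phase_summary`.
#' @param ... Unused.
#' @return The per-replicate calls tibble.
#' @export
tidy.cc_phase_summary <- function(x, ...) x$calls

#' @rdname tidy.cc_phase_summary
#' @export
glance.cc_phase_summary <- function(x, ...) {
  tibble::tibble(label = x$label, n_replicates = nrow(x$calls))
}

#' Plot a density profile
#'
#' @param object A `cc_density_profile`.
#' @param ... Unused.
#' @return A ggplot: molecule number density vs z, with the dense- and
#'   dilute-phase estimates as horizontal lines.
#' @export
autoplot.cc_density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$z[1:2]), fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "dense_density"),
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = attr(object, "dilute_density"),
                        linetype = 3) +
    ggplot2::labs(x = "z (nm, slab-centred)",
                  y = expression("chain density (nm"^-3 * ")"),
                  title = sprintf("density contrast %.1f",
                                  attr(object, "contrast"))) +
    ggplot2::theme_minimal()
}

#' Plot an MSD curve
#'
#' @param object A `cc_diffusion`.
#' @param ... Unused.
#' @return A ggplot of the mean squared displacement with the fitted
#'   linear regime.
#' @export
autoplot.cc_diffusion <- function(object, ...) {
  ggplot2::ggplot(object$msd,
                  ggplot2::aes(x = .data$lag_ps, y = .data$msd_nm2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(slope = object$fit$slope,
                         intercept = object$fit$intercept, linetype = 2) +
    ggplot2::labs(x = "lag (ps)", y = expression(MSD ~ (nm^2)),
                  title = sprintf("D = %.3g cm^2/s", object$D_cm2_s)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-size distribution
#'
#' @param object A `cc_cluster_report`.
#' @param ... Unused.
#' @return A ggplot of the chain-mass fraction per cluster size.
#' @export
autoplot.cc_cluster_report <- function(object, ...) {
  ggplot2::ggplot(object$sizes,
                  ggplot2::aes(x = .data$size, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster size (chains)",
                  y = "fraction of chains",
                  title = sprintf("dimer dominance %.2f",
                                  object$dimer_dominance)) +
    ggplot2::theme_minimal()
}
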