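# ggplot2 views of solver and method results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the CO2 concentration field of a converged solve
#'
#' Heatmap of the Pa-equivalent CO2 field over the unit cell, with depth
#' increasing downward from the airspace-facing wall.
#'
#' @param object An [solve_steady_state()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rd_solve <- function(object, ...) {
  ctx <- object$internals$ctx
  mesh <- ctx$mesh
  df <- mesh_cells(mesh)
  df$c_pa <- as.vector(object$field)[df$row + (df$col - 1L) * mesh$ny]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e6, y = .data$y * 1e6,
                                   fill = .data$c_pa)) +
    ggplot2::geom_tile(ggplot2::aes(width = .data$dx * 1e6,
                                    height = .data$dy * 1e6)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "CO2 (Pa)") +
    ggplot2::labs(x = "lateral position (um)", y = "depth (um)",
                  title = sprintf("scenario '%s': AN = %.2f, Cc = %.2f Pa",
                                  object$scenario, object$an, object$cc)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated Laisk curve family
#'
#' AN-Ci curves at the family of irradiances, the fitted common
#' intersection, the pairwise intersections, and the reference line
#' `AN = -Rd`.
#'
#' @param object A [simulate_laisk_family()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.laisk_sim <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$Ci, y = .data$AN,
                               colour = factor(.data$Iinc))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = -object$rd_input, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$gamma_star,
                        linetype = "dotdash") +
    ggplot2::geom_point(data = object$fit$pairwise,
                        ggplot2::aes(x = .data$ci, y = .data$an),
                        inherit.aes = FALSE, shape = 4, size = 2) +
    ggplot2::annotate("point", x = object$fit$ci_star, y = object$fit$a_star,
                      size = 3) +
    ggplot2::labs(x = "Ci (Pa)", y = "AN (umol m-2 s-1)",
                  colour = "Iinc",
                  title = sprintf("scenario '%s': Ci* = %.2f Pa, -A* = %.2f",
                                  object$scenario, object$fit$ci_star,
                                  object$fit$rd_laisk)) +
    ggplot2::theme_minimal()
}

#' Plot gm or freass response sweeps
#'
#' @param sweep_table Output of [response_sweep()], possibly row-bound over
#'   scenarios and regimes.
#' @param variable `"gm"` or `"freass"`.
#' @return A ggplot of the variable against the sweep value, coloured by
#'   scenario and faceted by O2 regime when several are present.
#' @export
plot_response_sweep <- function(sweep_table, variable = c("gm", "freass")) {
  variable <- match.arg(variable)
  p <- ggplot2::ggplot(sweep_table,
                       ggplot2::aes(x = .data$value,
                                    y = .data[[variable]],
                                    colour = .data$scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = unique(sweep_table$sweep),
                  y = if (variable == "gm")
                    "apparent gm (umol m-2 s-1 Pa-1)" else "freass") +
    ggplot2::theme_minimal()
  if (length(unique(sweep_table$O)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$O), labeller =
                                   ggplot2::label_both)
  }
  p
}
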