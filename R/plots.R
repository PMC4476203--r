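#' Plot a solved network
#'
#' Bar chart of signed vessel flows (default) or node pressures, grouped by
#' district, with retrograde vessels highlighted.
#'
#' @param object A [solve_network()] result.
#' @param what `"flows"` or `"pressures"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venonet_solve <- function(object, what = c("flows", "pressures"),
                                   ...) {
  what <- match.arg(what)
  if (what == "flows") {
    dat <- dplyr::mutate(
      object$edges,
      direction = ifelse(.data$flow_ml_s < 0, "retrograde", "antegrade")
    )
    ggplot2::ggplot(dat, ggplot2::aes(
      x = stats::reorder(.data$vessel_id, .data$flow_ml_s),
      y = .data$flow_ml_s, fill = .data$direction
    )) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::facet_wrap(ggplot2::vars(.data$district), scales = "free_y") +
      ggplot2::scale_fill_manual(
        values = c(antegrade = "steelblue", retrograde = "firebrick")
      ) +
      ggplot2::labs(x = NULL, y = "flow (ml/s)", fill = NULL)
  } else {
    dat <- dplyr::filter(object$nodes, !.data$is_reference,
                         !is.na(.data$pressure_Pa))
    ggplot2::ggplot(dat, ggplot2::aes(
      x = stats::reorder(.data$node_id, .data$pressure_Pa),
      y = .data$pressure_Pa
    )) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "pressure (Pa)")
  }
}

#' Heat map of a two-axis sweep metric
#'
#' The classic occlusion-grid picture: one tile per grid point, coloured by a
#' node pressure or a vessel flow.
#'
#' @param sweep A two-axis [run_sweep()] result.
#' @param node Node id whose pressure to map (exclusive with `vessel`).
#' @param vessel Vessel id whose flow to map.
#' @return A ggplot object.
#' @export
plot_sweep_grid <- function(sweep, node = NULL, vessel = NULL) {
  stopifnot(inherits(sweep, "venonet_sweep"))
  labels <- attr(sweep, "axis_labels")
  if (length(labels) != 2) abort("plot_sweep_grid needs a two-axis sweep.")
  if (is.null(node) == is.null(vessel)) {
    abort("give exactly one of `node` or `vessel`.")
  }
  if (!is.null(node)) {
    dat <- sweep_pressures(sweep, node)
    dat$value <- dat$pressure_Pa
    legend <- paste0(node, " pressure (Pa)")
  } else {
    dat <- sweep_flows(sweep, vessel)
    dat$value <- dat$flow_ml_s
    legend <- paste0(vessel, " flow (ml/s)")
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data[[labels[1]]], y = .data[[labels[2]]], fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = paste0(labels[1], " diameter reduction"),
      y = paste0(labels[2], " diameter reduction"),
      fill = legend
    )
}

#' Profile of a single-axis sweep metric
#'
#' @param sweep A single-axis [run_sweep()] result.
#' @param nodes Node ids whose pressures to draw.
#' @param vessels Vessel ids whose flows to draw.
#' @return A ggplot object (pressures and flows on separate facets).
#' @export
plot_sweep_profile <- function(sweep, nodes = NULL, vessels = NULL) {
  stopifnot(inherits(sweep, "venonet_sweep"))
  labels <- attr(sweep, "axis_labels")
  if (length(labels) != 1) abort("plot_sweep_profile needs a one-axis sweep.")
  dat <- dplyr::bind_rows(
    if (!is.null(nodes)) {
      d <- sweep_pressures(sweep, nodes)
      tibble(x = d[[labels]], item = d$node_id, value = d$pressure_Pa,
             quantity = "pressure (Pa)")
    },
    if (!is.null(vessels)) {
      d <- sweep_flows(sweep, vessels)
      tibble(x = d[[labels]], item = d$vessel_id, value = d$flow_ml_s,
             quantity = "flow (ml/s)")
    }
  )
  if (nrow(dat) == 0) abort("give at least one of `nodes` or `vessels`.")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$value,
                                    colour = .data$item)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = paste0(labels, " diameter reduction"), y = NULL,
                  colour = NULL)
}
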