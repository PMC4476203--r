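#' Solve the steady-state pressures and flows of a venous network
#'
#' Assembles the nodal conductance system implied by mass conservation and the
#' linear pressure-flow law of each element, and solves it directly. For every
#' non-reference node i, `sum_j g_ij (P_i - P_j) = Q_i` where `g_ij` is the
#' conductance (1/R) of the element joining i and j and `Q_i` the injected
#' source flow; reference-node pressures are eliminated at their fixed values.
#' Element flows follow as `Q_e = g_e (P_up - P_down)`, signed by the edge's
#' drainage orientation.
#'
#' Connected components without a reference node are handled gracefully: if
#' such a component carries a flow source the system is singular and the solve
#' aborts with a "no drainage path" error naming the source; a source-free
#' floating component has indeterminate pressure level (reported `NA`) and
#' exactly zero element flows.
#'
#' @param net A [venous_network()] that passes [validate_network()].
#' @param warn_residual Relative flow-balance residual above which a warning
#'   is raised (default 1e-8). Near-singular systems after severe occlusions
#'   are the main way a solve degrades silently; the residual check catches
#'   them.
#' @return An object of class `venonet_solve`: list with
#'   \describe{
#'     \item{nodes}{tibble `node_id`, `pressure_Pa`, `is_reference`}
#'     \item{edges}{tibble `vessel_id`, `name`, `district`, `flow_ml_s`,
#'       `delta_p_Pa`, `antegrade`}
#'     \item{residual}{max absolute node flow-balance error, m^3/s}
#'     \item{total_inflow}{total injected flow, m^3/s}
#'   }
#' @examples
#' toy <- make_toy("parallel_pair")
#' fit <- solve_network(toy$network)
#' tidy(fit)
#' glance(fit)
#' @export
solve_network <- function(net, warn_residual = 1e-8) {
  stopifnot(inherits(net, "venous_network"))
  report <- validate_network(net)
  if (nrow(report) > 0) {
    abort(paste0("cannot solve an invalid network:\n",
                 paste0("- ", report$message, collapse = "\n")))
  }

  v <- net$vessels
  n <- net$nodes
  res <- vessel_resistances(net)$resistance
  g <- 1 / res

  node_ids <- n$id
  ref <- n$is_reference
  ref_p <- ifelse(ref, n$reference_pressure, NA_real_)

  # injected flows per node in m^3/s
  inj <- stats::setNames(numeric(length(node_ids)), node_ids)
  if (nrow(net$inputs) > 0) {
    for (i in seq_len(nrow(net$inputs))) {
      inj[net$inputs$node_id[i]] <-
        inj[net$inputs$node_id[i]] + net$inputs$rate_ml_s[i] * M3S_PER_MLS
    }
  }

  # floating (reference-free) components: solvable only if source-free
  comp <- node_components(net)
  comp_has_ref <- tapply(ref, comp[node_ids], any)
  floating <- names(comp_has_ref)[!comp_has_ref]
  float_nodes <- character()
  if (length(floating) > 0) {
    float_nodes <- node_ids[as.character(comp[node_ids]) %in% floating]
    sourced <- float_nodes[inj[float_nodes] > 0]
    if (length(sourced) > 0) {
      abort(paste0("no drainage path: source node(s) ",
                   paste(sourced, collapse = ", "),
                   " lie in a component with no reference node"))
    }
  }

  unknown <- node_ids[!ref & !node_ids %in% float_nodes]
  pressures <- stats::setNames(rep(NA_real_, length(node_ids)), node_ids)
  pressures[ref] <- ref_p[ref]

  if (length(unknown) > 0) {
    idx <- stats::setNames(seq_along(unknown), unknown)
    ui <- idx[v$upstream_node]   # NA when endpoint is reference/floating
    di <- idx[v$downstream_node]
    keep_u <- !is.na(ui)
    keep_d <- !is.na(di)

    trip_i <- c(ui[keep_u], di[keep_d], ui[keep_u & keep_d], di[keep_u & keep_d])
    trip_j <- c(ui[keep_u], di[keep_d], di[keep_u & keep_d], ui[keep_u & keep_d])
    trip_x <- c(g[keep_u], g[keep_d], -g[keep_u & keep_d], -g[keep_u & keep_d])
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(length(unknown), length(unknown)))

    b <- inj[unknown]
    # contributions from eliminated reference neighbours at fixed pressure
    fixed_p <- stats::setNames(ifelse(ref, ref_p, 0), node_ids)
    is_fixed <- stats::setNames(ref, node_ids)
    up_fixed <- is_fixed[v$upstream_node] & keep_d
    dn_fixed <- is_fixed[v$downstream_node] & keep_u
    if (any(up_fixed)) {
      contrib <- tapply(g[up_fixed] * fixed_p[v$upstream_node[up_fixed]],
                        di[up_fixed], sum)
      b[as.integer(names(contrib))] <- b[as.integer(names(contrib))] + contrib
    }
    if (any(dn_fixed)) {
      contrib <- tapply(g[dn_fixed] * fixed_p[v$downstream_node[dn_fixed]],
                        ui[dn_fixed], sum)
      b[as.integer(names(contrib))] <- b[as.integer(names(contrib))] + contrib
    }

    sol <- tryCatch(
      as.numeric(Matrix::solve(A, b)),
      error = function(e) {
        abort(paste0("nodal solve failed (", conditionMessage(e),
                     "); the conductance matrix is singular or ",
                     "ill-conditioned"))
      }
    )
    pressures[unknown] <- sol
  }

  p_up <- pressures[v$upstream_node]
  p_dn <- pressures[v$downstream_node]
  flow <- g * (p_up - p_dn)                       # m^3/s, signed
  flow[is.na(flow)] <- 0                          # floating, source-free

  # post-hoc conservation residual at every non-reference node
  bal <- inj
  for (i in seq_len(nrow(v))) {
    f <- flow[i]
    bal[v$upstream_node[i]] <- bal[v$upstream_node[i]] - f
    bal[v$downstream_node[i]] <- bal[v$downstream_node[i]] + f
  }
  residual <- if (length(unknown) > 0) max(abs(bal[unknown])) else 0
  total_in <- sum(inj)
  if (total_in > 0 && residual / total_in > warn_residual) {
    warn(paste0("flow-balance residual ", format(residual / total_in),
                " (relative) exceeds ", format(warn_residual),
                "; treat this solve as suspect"))
  }

  structure(
    list(
      nodes = tibble(node_id = node_ids,
                     pressure_Pa = unname(pressures),
                     is_reference = ref),
      edges = tibble(vessel_id = v$id, name = v$name, district = v$district,
                     flow_ml_s = unname(flow) / M3S_PER_MLS,
                     delta_p_Pa = unname(p_up - p_dn),
                     antegrade = unname(flow) >= 0),
      residual = residual,
      total_inflow = total_in,
      network = net
    ),
    class = "venonet_solve"
  )
}

#' @exportS3Method base::print
print.venonet_solve <- function(x, ...) {
  cat("<venonet_solve> ", nrow(x$edges), " vessels, ",
      sum(!x$nodes$is_reference), " solved nodes\n", sep = "")
  cat("  total inflow ", format(x$total_inflow / M3S_PER_MLS),
      " ml/s; residual ", format(x$residual), " m^3/s",
      if (x$total_inflow > 0)
        paste0(" (", format(x$residual / x$total_inflow), " relative)"),
      "\n", sep = "")
  cat("  retrograde vessels: ", sum(x$edges$flow_ml_s < 0), "\n", sep = "")
  invisible(x)
}

#' Tidy a solved network
#'
#' @param x A `venonet_solve`.
#' @param what `"edges"` (default) for per-vessel flows or `"nodes"` for
#'   pressures. Node pressures gain a `pressure_mmHg` rendering.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.venonet_solve <- function(x, what = c("edges", "nodes"), ...) {
  what <- match.arg(what)
  if (what == "edges") {
    x$edges
  } else {
    dplyr::mutate(x$nodes, pressure_mmHg = .data$pressure_Pa / PA_PER_MMHG)
  }
}

#' One-row summary of a solved network
#'
#' @param x A `venonet_solve`.
#' @param ... Unused.
#' @return Tibble with total inflow (ml/s), max node pressure (Pa), residual
#'   (absolute and relative), and counts of antegrade/retrograde vessels.
#' @export
glance.venonet_solve <- function(x, ...) {
  tibble(
    n_vessels = nrow(x$edges),
    n_nodes = nrow(x$nodes),
    total_inflow_ml_s = x$total_inflow / M3S_PER_MLS,
    max_pressure_Pa = max(x$nodes$pressure_Pa, na.rm = TRUE),
    residual_m3_s = x$residual,
    residual_rel = if (x$total_inflow > 0) x$residual / x$total_inflow else 0,
    n_retrograde = sum(x$edges$flow_ml_s < 0)
  )
}

#' Write a solved network to CSV
#'
#' Writes the two canonical result tables: `<prefix>_nodes.csv`
#' (`node_id,pressure_Pa`) and `<prefix>_edges.csv`
#' (`vessel_id,flow_ml_s,delta_p_Pa,antegrade`).
#'
#' @param fit A `venonet_solve`.
#' @param prefix Path prefix for the two files.
#' @return Invisibly, the two file paths.
#' @export
write_solve_csv <- function(fit, prefix) {
  stopifnot(inherits(fit, "venonet_solve"))
  node_path <- paste0(prefix, "_nodes.csv")
  edge_path <- paste0(prefix, "_edges.csv")
  readr::write_csv(fit$nodes[, c("node_id", "pressure_Pa")], node_path)
  readr::write_csv(
    fit$edges[, c("vessel_id", "flow_ml_s", "delta_p_Pa", "antegrade")],
    edge_path
  )
  invisible(c(node_path, edge_path))
}
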