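#' Build a venous network
#'
#' Assembles a lumped-parameter venous network from a vessel table, a node
#' table and a flow-input table. Each vessel is a resistive element oriented
#' from `upstream_node` to `downstream_node` (the physiological drainage
#' direction): a positive solved flow is antegrade, a negative one retrograde.
#' Reference nodes are held at fixed pressure (0 Pa in the physiological
#' configuration: subclavian vein and right atrium); all other node pressures
#' are unknowns of the steady-state solve.
#'
#' @param vessels Data frame with columns `id`, `name`, `side`
#'   (`left`/`right`/`midline`), `district` (`intracranial`/`cervical`/
#'   `thoracic`/`lumbar`/`connective`), `length_cm`, `diameter_cm`,
#'   `upstream_node`, `downstream_node`.
#' @param inputs Data frame of flow sources with columns `node_id`,
#'   `rate_ml_s` (>= 0) and `label` (e.g. `Q_c`, `Q_v1`..`Q_v21`, `Q_f`), or
#'   `NULL` for a source-free network.
#' @param reference_nodes Character vector of node ids held at fixed pressure.
#'   Ignored when `nodes` is supplied.
#' @param nodes Optional data frame with columns `id`, `label`, `district`,
#'   `is_reference`, `reference_pressure` (Pa). When `NULL`, nodes are
#'   inferred from the vessel endpoints and `reference_nodes`.
#' @param viscosity_cP Blood dynamic viscosity in centipoise (default 3).
#' @param validate Run [validate_network()] and abort on violations
#'   (default `TRUE`).
#' @return An object of class `venous_network`: a list with tibbles
#'   `vessels`, `nodes`, `inputs` and the scalar `viscosity` (Pa s).
#' @examples
#' vessels <- tibble::tibble(
#'   id = c("a", "b"), name = c("a", "b"), side = "midline",
#'   district = "cervical", length_cm = c(10, 5), diameter_cm = c(1, 0.8),
#'   upstream_node = c("n1", "n2"), downstream_node = c("n2", "ground")
#' )
#' inputs <- tibble::tibble(node_id = "n1", rate_ml_s = 5, label = "Q_c")
#' net <- venous_network(vessels, inputs, reference_nodes = "ground")
#' @export
venous_network <- function(vessels, inputs = NULL, reference_nodes = character(),
                           nodes = NULL, viscosity_cP = 3, validate = TRUE) {
  vessels <- as_tibble(vessels)
  required <- c("id", "name", "side", "district", "length_cm", "diameter_cm",
                "upstream_node", "downstream_node")
  missing_cols <- setdiff(required, names(vessels))
  if (length(missing_cols) > 0) {
    abort(paste0("vessel table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  vessels <- vessels[required]
  vessels$id <- as.character(vessels$id)
  vessels$upstream_node <- as.character(vessels$upstream_node)
  vessels$downstream_node <- as.character(vessels$downstream_node)

  if (is.null(inputs)) {
    inputs <- tibble(node_id = character(), rate_ml_s = numeric(),
                     label = character())
  }
  inputs <- as_tibble(inputs)[c("node_id", "rate_ml_s", "label")]
  inputs$node_id <- as.character(inputs$node_id)

  if (is.null(nodes)) {
    ids <- unique(c(vessels$upstream_node, vessels$downstream_node))
    nodes <- tibble(
      id = ids, label = ids,
      district = node_district_guess(ids, vessels),
      is_reference = ids %in% reference_nodes,
      reference_pressure = 0
    )
    extra_refs <- setdiff(reference_nodes, ids)
    if (length(extra_refs) > 0) {
      abort(paste0("reference node(s) not found among vessel endpoints: ",
                   paste(extra_refs, collapse = ", ")))
    }
  } else {
    nodes <- as_tibble(nodes)[c("id", "label", "district", "is_reference",
                                "reference_pressure")]
    nodes$id <- as.character(nodes$id)
  }

  if (!is.numeric(viscosity_cP) || length(viscosity_cP) != 1 ||
      !is.finite(viscosity_cP) || viscosity_cP <= 0) {
    abort("`viscosity_cP` must be a single positive number.")
  }

  net <- structure(
    list(vessels = vessels, nodes = nodes, inputs = inputs,
         viscosity = viscosity_cP * 1e-3),
    class = "venous_network"
  )
  if (validate) {
    report <- validate_network(net)
    if (nrow(report) > 0) {
      abort(paste0("invalid network:\n",
                   paste0("- ", report$message, collapse = "\n")))
    }
  }
  net
}

# district of an inferred node: the modal district of its incident vessels
node_district_guess <- function(ids, vessels) {
  vapply(ids, function(n) {
    d <- c(vessels$district[vessels$upstream_node == n],
           vessels$district[vessels$downstream_node == n])
    names(sort(table(d), decreasing = TRUE))[1]
  }, character(1))
}

#' Validate a venous network
#'
#' Checks every structural invariant of the network and returns a report
#' rather than aborting: geometry strictly positive, unique vessel ids,
#' no self-loops, vessel endpoints and input nodes present, inputs
#' non-negative and not attached to reference nodes, reference pressures
#' finite, and drainage connectivity (every connected component that contains
#' a flow source must also contain a reference node, otherwise the nodal
#' system is singular).
#'
#' @param net A [venous_network()].
#' @return A tibble with columns `check`, `item`, `message`; zero rows iff
#'   the network is valid.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "venous_network"))
  v <- net$vessels
  n <- net$nodes
  q <- net$inputs
  bad <- list()
  note <- function(check, item, message) {
    bad[[length(bad) + 1]] <<- tibble(check = check, item = item,
                                      message = message)
  }

  dup <- v$id[duplicated(v$id)]
  for (d in unique(dup)) {
    note("duplicate_id", d, paste0("vessel id '", d, "' is duplicated"))
  }
  for (i in seq_len(nrow(v))) {
    row_tag <- paste0("row ", i, " (", v$id[i], ")")
    if (!is.finite(v$length_cm[i]) || v$length_cm[i] <= 0) {
      note("geometry", v$id[i],
           paste0(row_tag, ": length_cm must be > 0, got ", v$length_cm[i]))
    }
    if (!is.finite(v$diameter_cm[i]) || v$diameter_cm[i] <= 0) {
      note("geometry", v$id[i],
           paste0(row_tag, ": diameter_cm must be > 0, got ", v$diameter_cm[i]))
    }
    if (identical(v$upstream_node[i], v$downstream_node[i])) {
      note("self_loop", v$id[i],
           paste0(row_tag, ": upstream and downstream node are both '",
                  v$upstream_node[i], "'"))
    }
  }

  node_ids <- n$id
  dangling <- setdiff(c(v$upstream_node, v$downstream_node), node_ids)
  for (d in dangling) {
    note("dangling_node", d,
         paste0("vessel endpoint '", d, "' is not in the node table"))
  }
  dupn <- n$id[duplicated(n$id)]
  for (d in unique(dupn)) {
    note("duplicate_node", d, paste0("node id '", d, "' is duplicated"))
  }
  if (any(!is.finite(n$reference_pressure[n$is_reference]))) {
    note("reference_pressure", NA_character_,
         "reference nodes must carry a finite fixed pressure")
  }

  for (i in seq_len(nrow(q))) {
    if (!q$node_id[i] %in% node_ids) {
      note("input_node", q$node_id[i],
           paste0("flow input '", q$label[i], "' references unknown node '",
                  q$node_id[i], "'"))
    } else if (isTRUE(n$is_reference[match(q$node_id[i], node_ids)])) {
      note("input_on_reference", q$node_id[i],
           paste0("flow input '", q$label[i],
                  "' is attached to reference node '", q$node_id[i], "'"))
    }
    if (!is.finite(q$rate_ml_s[i]) || q$rate_ml_s[i] < 0) {
      note("input_rate", q$label[i],
           paste0("flow input '", q$label[i], "' must have rate >= 0"))
    }
  }

  # drainage connectivity, only meaningful once the graph is well-formed
  if (length(dangling) == 0 && nrow(v) > 0) {
    comp <- node_components(net)
    ref_nodes <- node_ids[n$is_reference]
    src_nodes <- intersect(q$node_id, node_ids)
    for (k in unique(comp)) {
      members <- names(comp)[comp == k]
      if (length(intersect(members, src_nodes)) > 0 &&
          length(intersect(members, ref_nodes)) == 0) {
        note("no_drainage_path", members[1],
             paste0("component containing source node(s) ",
                    paste(intersect(members, src_nodes), collapse = ", "),
                    " has no reference node: no drainage path"))
      }
    }
  }

  if (length(bad) == 0) {
    tibble(check = character(), item = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

# connected-component membership for every node, named integer vector
node_components <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$vessels[, c("upstream_node", "downstream_node")],
    directed = FALSE,
    vertices = net$nodes["id"]
  )
  igraph::components(g)$membership
}

#' Element resistances of a network
#'
#' Converts the vessel table's cm geometry to SI and applies
#' [poiseuille_resistance()] with the network's viscosity. This is the single
#' point where anatomical units cross into solver units.
#'
#' @param net A [venous_network()].
#' @return Tibble with columns `vessel_id`, `resistance` (Pa s/m^3).
#' @export
vessel_resistances <- function(net) {
  stopifnot(inherits(net, "venous_network"))
  tibble(
    vessel_id = net$vessels$id,
    resistance = poiseuille_resistance(
      length = net$vessels$length_cm / CM_PER_M,
      diameter = net$vessels$diameter_cm / CM_PER_M,
      viscosity = net$viscosity
    )
  )
}

#' @exportS3Method base::print
print.venous_network <- function(x, ...) {
  nref <- sum(x$nodes$is_reference)
  cat("<venous_network> ", nrow(x$vessels), " vessels, ", nrow(x$nodes),
      " nodes (", nref, " reference), ", nrow(x$inputs),
      " flow inputs totalling ", format(sum(x$inputs$rate_ml_s)),
      " ml/s, viscosity ", format(x$viscosity * 1e3), " cP\n", sep = "")
  districts <- table(x$vessels$district)
  cat("  districts:",
      paste(names(districts), districts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
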