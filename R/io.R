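#' Read an anatomy table and boundary configuration into a network
#'
#' The anatomy CSV must carry the header
#' `id,name,side,district,length_cm,diameter_cm,upstream_node,downstream_node`
#' (UTF-8, '.' decimal separator). The companion config (flat JSON) names the
#' zero-pressure reference nodes and the arterial flow inputs:
#' ```json
#' {
#'   "reference_nodes": ["scv", "ra"],
#'   "viscosity_cP": 3,
#'   "flow_inputs": [{"node": "brain", "ml_s": 12, "label": "Q_c"}, ...]
#' }
#' ```
#' Row order of the CSV is preserved, so derived outputs are deterministically
#' ordered. Malformed rows (non-positive geometry, duplicate ids, dangling
#' nodes) produce an error naming the offending row.
#'
#' @param path Anatomy CSV path.
#' @param config Config JSON path, or `NULL` for a bare network with no
#'   sources and no reference nodes (then `validate = FALSE` is implied for
#'   connectivity, but structural checks still run).
#' @return A [venous_network()].
#' @export
read_anatomy <- function(path, config = NULL) {
  if (!file.exists(path)) abort(paste0("anatomy file not found: ", path))
  vessels <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(), name = readr::col_character(),
      side = readr::col_character(), district = readr::col_character(),
      length_cm = readr::col_double(), diameter_cm = readr::col_double(),
      upstream_node = readr::col_character(),
      downstream_node = readr::col_character()
    )
  ))
  required <- c("id", "name", "side", "district", "length_cm", "diameter_cm",
                "upstream_node", "downstream_node")
  missing_cols <- setdiff(required, names(vessels))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  reference_nodes <- character()
  inputs <- NULL
  viscosity_cP <- 3
  if (!is.null(config)) {
    cfg <- read_network_config(config)
    reference_nodes <- cfg$reference_nodes
    inputs <- cfg$flow_inputs
    viscosity_cP <- cfg$viscosity_cP
  }
  venous_network(vessels, inputs, reference_nodes,
                 viscosity_cP = viscosity_cP)
}

#' Read a boundary/input configuration file
#'
#' @param path JSON config path (see [read_anatomy()] for the schema).
#' @return List with `reference_nodes` (character), `flow_inputs` (tibble
#'   `node_id`, `rate_ml_s`, `label`), `viscosity_cP` (scalar).
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  fi <- cfg$flow_inputs
  inputs <- if (is.null(fi) || NROW(fi) == 0) {
    tibble(node_id = character(), rate_ml_s = numeric(), label = character())
  } else {
    tibble(node_id = as.character(fi$node),
           rate_ml_s = as.numeric(fi$ml_s),
           label = as.character(fi$label))
  }
  list(
    reference_nodes = as.character(cfg$reference_nodes %||% character()),
    flow_inputs = inputs,
    viscosity_cP = as.numeric(cfg$viscosity_cP %||% 3)
  )
}

#' Write a network to an anatomy CSV (and optional config JSON)
#'
#' Inverse of [read_anatomy()]: writes the vessel table in the canonical
#' column order, and optionally the reference/input configuration, such that
#' reading the pair back reproduces the network exactly.
#'
#' @param net A [venous_network()].
#' @param path Anatomy CSV path.
#' @param config Optional config JSON path.
#' @return Invisibly, `path`.
#' @export
write_anatomy <- function(net, path, config = NULL) {
  stopifnot(inherits(net, "venous_network"))
  readr::write_csv(net$vessels, path)
  if (!is.null(config)) {
    cfg <- list(
      reference_nodes = net$nodes$id[net$nodes$is_reference],
      viscosity_cP = net$viscosity * 1e3,
      flow_inputs = data.frame(node = net$inputs$node_id,
                               ml_s = net$inputs$rate_ml_s,
                               label = net$inputs$label)
    )
    jsonlite::write_json(cfg, config, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

as_igraph <- function(net) {
  edges <- net$vessels
  g <- igraph::graph_from_data_frame(
    edges[, c("upstream_node", "downstream_node", "id", "name", "side",
              "district", "length_cm", "diameter_cm")],
    directed = TRUE,
    vertices = data.frame(
      name = net$nodes$id, node_label = net$nodes$label,
      district = net$nodes$district,
      # integer, not logical: the DOT writer cannot carry booleans
      is_reference = as.integer(net$nodes$is_reference),
      reference_pressure = net$nodes$reference_pressure,
      input_ml_s = vapply(net$nodes$id, function(n) {
        sum(net$inputs$rate_ml_s[net$inputs$node_id == n])
      }, numeric(1)),
      input_label = vapply(net$nodes$id, function(n) {
        paste(net$inputs$label[net$inputs$node_id == n], collapse = ";")
      }, character(1))
    )
  )
  igraph::graph_attr(g, "viscosity_cP") <- net$viscosity * 1e3
  g
}

#' Export a network as GraphML or DOT
#'
#' GraphML exports are round-trippable via [import_graphml()]: vessel
#' geometry, districts, reference flags and flow inputs travel as graph
#' attributes. DOT exports are for rendering (Graphviz) only.
#'
#' @param net A [venous_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Re-import a GraphML export as a network
#'
#' @param path A GraphML file written by [export_graph()].
#' @return A [venous_network()] equal to the exported one.
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  vd <- igraph::as_data_frame(g, what = "vertices")
  vessels <- tibble(
    id = ed$id, name = ed$name, side = ed$side, district = ed$district,
    length_cm = ed$length_cm, diameter_cm = ed$diameter_cm,
    upstream_node = ed$from, downstream_node = ed$to
  )
  nodes <- tibble(
    id = vd$name, label = vd$node_label, district = vd$district,
    is_reference = as.logical(vd$is_reference),
    reference_pressure = vd$reference_pressure
  )
  has_input <- vd$input_ml_s > 0 | nzchar(vd$input_label)
  inputs <- tibble(
    node_id = vd$name[has_input],
    rate_ml_s = vd$input_ml_s[has_input],
    label = vd$input_label[has_input]
  )
  venous_network(vessels, inputs, nodes = nodes,
                 viscosity_cP = igraph::graph_attr(g, "viscosity_cP"))
}
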