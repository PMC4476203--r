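#' Apply a stenosis (diameter reduction) to target vessels
#'
#' Multiplies each target vessel's equivalent diameter by `1 - reduction`.
#' Under Poiseuille's law this raises the element's resistance by
#' `(1 - reduction)^-4`; a reduction of 1 models a complete block and removes
#' the edge from the network entirely (infinite resistance), which keeps the
#' conductance matrix well-posed. The input network is never modified.
#'
#' Repeated application composes multiplicatively on diameters:
#' reducing by r1 then r2 equals a single reduction of `1 - (1-r1)(1-r2)`.
#'
#' @param net A [venous_network()].
#' @param targets Character vector of vessel ids to narrow.
#' @param reduction Diameter-reduction fraction in \[0, 1\]; 0 = fully patent,
#'   1 = complete block.
#' @return A new `venous_network`.
#' @examples
#' toy <- make_toy("single_edge")$network
#' stenosed <- apply_stenosis(toy, "v1", 0.5)  # resistance x 16
#' @export
apply_stenosis <- function(net, targets, reduction) {
  stopifnot(inherits(net, "venous_network"))
  if (!is.numeric(reduction) || length(reduction) != 1 ||
      !is.finite(reduction) || reduction < 0 || reduction > 1) {
    abort("`reduction` must be a single number in [0, 1].")
  }
  unknown <- setdiff(targets, net$vessels$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown vessel id(s): ", paste(unknown, collapse = ", ")))
  }
  hit <- net$vessels$id %in% targets
  if (reduction >= 1) {
    net$vessels <- net$vessels[!hit, ]
  } else {
    net$vessels$diameter_cm[hit] <- net$vessels$diameter_cm[hit] * (1 - reduction)
  }
  net
}

#' Add collateral vessels in parallel with an existing vessel
#'
#' Inserts `count` new resistive elements sharing the target vessel's
#' endpoints, modelling accessory drainage routes (e.g. paravertebral
#' collaterals beside a stenosed internal jugular vein). New vessel ids are
#' derived deterministically as `<target>_coll1`, `<target>_coll2`, ...
#'
#' @param net A [venous_network()].
#' @param parallel_to Vessel id to parallel.
#' @param diameter_cm Collateral diameter in cm.
#' @param length_cm Collateral length in cm; defaults to the target's length.
#' @param count Number of identical collaterals (default 1).
#' @return A new `venous_network`.
#' @export
add_collaterals <- function(net, parallel_to, diameter_cm, length_cm = NULL,
                            count = 1) {
  stopifnot(inherits(net, "venous_network"))
  i <- match(parallel_to, net$vessels$id)
  if (is.na(i)) abort(paste0("unknown vessel id: ", parallel_to))
  if (!is.numeric(diameter_cm) || diameter_cm <= 0) {
    abort("`diameter_cm` must be > 0.")
  }
  if (!is.numeric(count) || count < 1 || count != round(count)) {
    abort("`count` must be a positive integer.")
  }
  length_cm <- length_cm %||% net$vessels$length_cm[i]
  target <- net$vessels[i, ]
  coll <- tibble(
    id = paste0(parallel_to, "_coll", seq_len(count)),
    name = paste0(target$name, " collateral ", seq_len(count)),
    side = target$side,
    district = "connective",
    length_cm = length_cm,
    diameter_cm = diameter_cm,
    upstream_node = target$upstream_node,
    downstream_node = target$downstream_node
  )
  net$vessels <- dplyr::bind_rows(net$vessels, coll)
  net
}

#' Override vessel diameters
#'
#' Sets target vessels to an absolute diameter, used e.g. to re-run the
#' jugular occlusion analysis with alternative published baseline diameters
#' before sweeping.
#'
#' @param net A [venous_network()].
#' @param targets Character vector of vessel ids.
#' @param diameter_cm New diameter in cm (scalar or one per target).
#' @return A new `venous_network`.
#' @export
override_diameters <- function(net, targets, diameter_cm) {
  stopifnot(inherits(net, "venous_network"))
  unknown <- setdiff(targets, net$vessels$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown vessel id(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(diameter_cm <= 0)) abort("`diameter_cm` must be > 0.")
  idx <- match(targets, net$vessels$id)
  net$vessels$diameter_cm[idx] <- diameter_cm
  net
}

#' Define one sweep axis
#'
#' @param targets Character vector of vessel ids reduced together along this
#'   axis.
#' @param grid Numeric vector of diameter-reduction fractions in \[0, 1\],
#'   sorted ascending.
#' @param label Axis label used as the result column name; defaults to the
#'   first target id.
#' @return A `sweep_axis` list.
#' @export
sweep_axis <- function(targets, grid, label = targets[1]) {
  if (length(grid) == 0 || any(!is.finite(grid)) ||
      any(grid < 0) || any(grid > 1)) {
    abort("`grid` must be a non-empty vector of values in [0, 1].")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be sorted strictly ascending.")
  }
  structure(list(targets = targets, grid = grid, label = label),
            class = "sweep_axis")
}

#' Run a parametric occlusion sweep
#'
#' Solves the network at every point of a reduction grid. With
#' `cartesian = TRUE` (default) the grid is the Cartesian product of the axes,
#' iterated row-major (last axis fastest); with `cartesian = FALSE` the axes
#' are zipped position-wise and must have equal lengths. Grid points whose
#' system is singular (e.g. a source isolated by a complete block) are
#' recorded as failed rows, not errors.
#'
#' @param net Baseline [venous_network()].
#' @param axes A `sweep_axis` or list of them.
#' @param cartesian Grid product (`TRUE`) or zipped axes (`FALSE`).
#' @return A tibble of class `venonet_sweep`: one row per grid point with one
#'   reduction column per axis (named by its label), `status`
#'   (`"ok"`/`"singular"`), `residual`, and a `solve` list-column of
#'   `venonet_solve` objects (`NULL` where failed). The baseline solve of the
#'   unmodified network is stored in `attr(, "baseline")`.
#' @examples
#' toy <- make_toy("wye")$network
#' sw <- run_sweep(toy, sweep_axis("v1", c(0, 0.5, 0.9)))
#' @export
run_sweep <- function(net, axes, cartesian = TRUE) {
  stopifnot(inherits(net, "venous_network"))
  if (inherits(axes, "sweep_axis")) axes <- list(axes)
  if (!all(vapply(axes, inherits, logical(1), "sweep_axis"))) {
    abort("`axes` must be sweep_axis objects.")
  }
  for (ax in axes) {
    unknown <- setdiff(ax$targets, net$vessels$id)
    if (length(unknown) > 0) {
      abort(paste0("sweep axis '", ax$label, "' targets unknown vessel id(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  labels <- vapply(axes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("axis labels must be unique.")

  if (cartesian) {
    grid <- rev(expand.grid(rev(lapply(axes, `[[`, "grid")),
                            KEEP.OUT.ATTRS = FALSE))
    names(grid) <- labels
  } else {
    lens <- lengths(lapply(axes, `[[`, "grid"))
    if (length(unique(lens)) != 1) {
      abort("zipped axes must have equal grid lengths.")
    }
    grid <- as.data.frame(stats::setNames(lapply(axes, `[[`, "grid"), labels))
  }
  grid <- as_tibble(grid)

  baseline <- solve_network(net)
  rows <- purrr::pmap(grid, function(...) {
    red <- c(...)
    fit <- tryCatch({
      mod <- net
      for (k in seq_along(axes)) {
        mod <- apply_stenosis(mod, axes[[k]]$targets, red[[k]])
      }
      suppressWarnings(solve_network(mod))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      list(status = "singular", residual = NA_real_, solve = list(NULL))
    } else {
      list(status = "ok", residual = fit$residual, solve = list(fit))
    }
  })
  out <- dplyr::bind_cols(
    grid,
    tibble(
      status = vapply(rows, `[[`, character(1), "status"),
      residual = vapply(rows, `[[`, numeric(1), "residual"),
      solve = lapply(rows, function(r) r$solve[[1]])
    )
  )
  structure(out, class = c("venonet_sweep", class(out)),
            baseline = baseline, axis_labels = labels)
}

#' Extract per-grid-point node pressures from a sweep
#'
#' @param sweep A [run_sweep()] result.
#' @param nodes Node ids to extract; default all.
#' @return Long tibble: axis columns, `node_id`, `pressure_Pa`.
#' @export
sweep_pressures <- function(sweep, nodes = NULL) {
  stopifnot(inherits(sweep, "venonet_sweep"))
  labels <- attr(sweep, "axis_labels")
  purrr::map_dfr(seq_len(nrow(sweep)), function(i) {
    fit <- sweep$solve[[i]]
    if (is.null(fit)) return(NULL)
    tab <- fit$nodes
    if (!is.null(nodes)) tab <- tab[tab$node_id %in% nodes, ]
    dplyr::bind_cols(sweep[i, labels, drop = FALSE],
                     tab[, c("node_id", "pressure_Pa")])
  })
}

#' Extract per-grid-point vessel flows from a sweep
#'
#' @param sweep A [run_sweep()] result.
#' @param vessels Vessel ids to extract; default all.
#' @return Long tibble: axis columns, `vessel_id`, `flow_ml_s`.
#' @export
sweep_flows <- function(sweep, vessels = NULL) {
  stopifnot(inherits(sweep, "venonet_sweep"))
  labels <- attr(sweep, "axis_labels")
  purrr::map_dfr(seq_len(nrow(sweep)), function(i) {
    fit <- sweep$solve[[i]]
    if (is.null(fit)) return(NULL)
    tab <- fit$edges
    if (!is.null(vessels)) tab <- tab[tab$vessel_id %in% vessels, ]
    dplyr::bind_cols(sweep[i, labels, drop = FALSE],
                     tab[, c("vessel_id", "flow_ml_s")])
  })
}

#' Serialize a sweep to long-format CSV
#'
#' One row per (grid point, item, quantity): axis columns, `item_id`,
#' `quantity` (`pressure_Pa` or `flow_ml_s`), `value`.
#'
#' @param sweep A [run_sweep()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(sweep, path) {
  labels <- attr(sweep, "axis_labels")
  p <- sweep_pressures(sweep)
  p <- dplyr::mutate(dplyr::rename(p, item_id = "node_id",
                                   value = "pressure_Pa"),
                     quantity = "pressure_Pa")
  f <- sweep_flows(sweep)
  f <- dplyr::mutate(dplyr::rename(f, item_id = "vessel_id",
                                   value = "flow_ml_s"),
                     quantity = "flow_ml_s")
  long <- dplyr::bind_rows(p, f)[, c(labels, "item_id", "quantity", "value")]
  readr::write_csv(long, path)
  invisible(path)
}
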