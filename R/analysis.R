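#' Detect retrograde (refluent) vessels in a solved network
#'
#' A vessel is refluent when its signed flow is below `-tolerance`, i.e.
#' directed against its physiological drainage orientation; vessels with
#' `|flow| <= tolerance` are classed stagnant, never refluent. The default
#' tolerance (1e-12 m^3/s = 1e-6 ml/s) is far below any physiological flow
#' and only guards against float noise from the solver.
#'
#' @param fit A [solve_network()] result.
#' @param tolerance Stagnation tolerance in m^3/s (default 1e-12).
#' @param all Return every vessel with its `status`
#'   (`antegrade`/`stagnant`/`refluent`) instead of only the refluent ones.
#' @return Tibble `vessel_id`, `name`, `district`, `flow_ml_s` (plus `status`
#'   when `all = TRUE`), ordered by district; attribute `tolerance_m3s`.
#' @export
detect_reflux <- function(fit, tolerance = 1e-12, all = FALSE) {
  stopifnot(inherits(fit, "venonet_solve"))
  if (!is.numeric(tolerance) || tolerance < 0) {
    abort("`tolerance` must be >= 0 (m^3/s).")
  }
  tol_ml_s <- tolerance / M3S_PER_MLS
  out <- dplyr::mutate(
    fit$edges[, c("vessel_id", "name", "district", "flow_ml_s")],
    status = dplyr::case_when(
      .data$flow_ml_s < -tol_ml_s ~ "refluent",
      .data$flow_ml_s > tol_ml_s ~ "antegrade",
      TRUE ~ "stagnant"
    )
  )
  out <- dplyr::arrange(out, .data$district, .data$vessel_id)
  if (!all) {
    out <- dplyr::filter(out, .data$status == "refluent")
    out$status <- NULL
  }
  attr(out, "tolerance_m3s") <- tolerance
  out
}

#' Baseline-relative change in pressures and flows
#'
#' Computes `(perturbed - baseline) / baseline` for every node pressure and
#' every vessel flow shared by two solves of the same topology. Entries whose
#' baseline value is zero are flagged undefined (`NA` with `defined = FALSE`)
#' rather than divided.
#'
#' @param baseline,perturbed Two [solve_network()] results over the same node
#'   and vessel sets.
#' @return Long tibble: `quantity` (`pressure_Pa`/`flow_ml_s`), `id`,
#'   `baseline`, `perturbed`, `rel_change`, `defined`.
#' @export
relative_change <- function(baseline, perturbed) {
  stopifnot(inherits(baseline, "venonet_solve"),
            inherits(perturbed, "venonet_solve"))
  if (!setequal(baseline$nodes$node_id, perturbed$nodes$node_id) ||
      !setequal(baseline$edges$vessel_id, perturbed$edges$vessel_id)) {
    abort("solves are over different topologies (node or vessel sets differ).")
  }
  join_one <- function(b, p, idcol, valcol) {
    tab <- dplyr::inner_join(
      stats::setNames(b[, c(idcol, valcol)], c("id", "baseline")),
      stats::setNames(p[, c(idcol, valcol)], c("id", "perturbed")),
      by = "id"
    )
    dplyr::mutate(
      tab,
      quantity = valcol,
      defined = is.finite(.data$baseline) & .data$baseline != 0,
      rel_change = dplyr::if_else(
        .data$defined,
        (.data$perturbed - .data$baseline) / .data$baseline,
        NA_real_
      )
    )
  }
  out <- dplyr::bind_rows(
    join_one(baseline$nodes, perturbed$nodes, "node_id", "pressure_Pa"),
    join_one(baseline$edges, perturbed$edges, "vessel_id", "flow_ml_s")
  )
  out[, c("quantity", "id", "baseline", "perturbed", "rel_change", "defined")]
}

#' Find the grid threshold at which a predicate first holds
#'
#' Scans a single-axis sweep in ascending grid order and reports the first
#' grid value where the predicate holds and the last where it fails; no
#' interpolation between grid points is attempted. If the predicate is
#' non-monotone along the grid, every transition is reported in the
#' `transitions` list-column. Failed (singular) grid points count as the
#' predicate being unevaluable and are skipped with a warning.
#'
#' @param sweep A single-axis [run_sweep()] result (filter a multi-axis sweep
#'   down to one free axis first).
#' @param predicate Function `(fit, baseline) -> logical(1)` evaluated at each
#'   grid point; see [pred_pressure_ratio()], [pred_any_reflux()],
#'   [pred_flow_negative()].
#' @param label Predicate label for the report.
#' @return One-row tibble: `axis`, `predicate`, `reached`, `first_true`,
#'   `last_false`, `n_transitions`, `transitions` (list of grid values where
#'   the predicate switches to TRUE).
#' @export
find_threshold <- function(sweep, predicate, label = "predicate") {
  stopifnot(inherits(sweep, "venonet_sweep"))
  labels <- attr(sweep, "axis_labels")
  if (length(labels) != 1) {
    abort("find_threshold needs a single-axis sweep; filter first.")
  }
  axis <- labels[[1]]
  ord <- order(sweep[[axis]])
  grid <- sweep[[axis]][ord]
  baseline <- attr(sweep, "baseline")
  holds <- rep(NA, length(grid))
  for (k in seq_along(ord)) {
    fit <- sweep$solve[[ord[k]]]
    if (!is.null(fit)) holds[k] <- isTRUE(predicate(fit, baseline))
  }
  if (anyNA(holds)) {
    warn("some grid points failed to solve and were skipped.")
  }
  ok <- !is.na(holds)
  g <- grid[ok]
  h <- holds[ok]
  first_true <- if (any(h)) g[which(h)[1]] else NA_real_
  last_false <- if (any(!h)) g[utils::tail(which(!h), 1)] else NA_real_
  trans <- g[which(diff(h) == 1) + 1]
  tibble(
    axis = axis, predicate = label, reached = any(h),
    first_true = first_true, last_false = last_false,
    n_transitions = length(trans), transitions = list(trans)
  )
}

#' Threshold predicates
#'
#' Prebuilt predicates for [find_threshold()]:
#' * `pred_pressure_ratio(node, ratio)` — the pressure at `node` is at least
#'   `ratio` times its baseline value (default 2, "pressure doubled").
#' * `pred_any_reflux(district, tolerance)` — any vessel (optionally
#'   restricted to a district) is refluent.
#' * `pred_flow_negative(vessel, tolerance)` — the named vessel's flow is
#'   retrograde.
#'
#' @param node,vessel Node / vessel id.
#' @param ratio Pressure multiple of baseline (default 2).
#' @param district Optional district filter.
#' @param tolerance Stagnation tolerance in m^3/s.
#' @return A function `(fit, baseline) -> logical(1)`.
#' @name threshold-predicates
NULL

#' @rdname threshold-predicates
#' @export
pred_pressure_ratio <- function(node, ratio = 2) {
  force(node); force(ratio)
  function(fit, baseline) {
    p0 <- baseline$nodes$pressure_Pa[match(node, baseline$nodes$node_id)]
    p1 <- fit$nodes$pressure_Pa[match(node, fit$nodes$node_id)]
    if (is.na(p0) || is.na(p1) || p0 == 0) return(NA)
    p1 >= ratio * p0
  }
}

#' @rdname threshold-predicates
#' @export
pred_any_reflux <- function(district = NULL, tolerance = 1e-12) {
  force(district); force(tolerance)
  function(fit, baseline) {
    r <- detect_reflux(fit, tolerance = tolerance)
    if (!is.null(district)) r <- r[r$district %in% district, ]
    nrow(r) > 0
  }
}

#' @rdname threshold-predicates
#' @export
pred_flow_negative <- function(vessel, tolerance = 1e-12) {
  force(vessel); force(tolerance)
  function(fit, baseline) {
    f <- fit$edges$flow_ml_s[match(vessel, fit$edges$vessel_id)]
    if (is.na(f)) return(NA)
    f < -tolerance / M3S_PER_MLS
  }
}

#' Per-vessel Reynolds numbers of a solved network
#'
#' @param fit A [solve_network()] result.
#' @param density Blood density in kg/m^3 (default 1060; the standard
#'   whole-blood value, configurable).
#' @return Tibble `vessel_id`, `name`, `district`, `flow_ml_s`, `reynolds`,
#'   sorted by descending Reynolds number.
#' @export
reynolds_numbers <- function(fit, density = 1060) {
  stopifnot(inherits(fit, "venonet_solve"))
  net <- fit$network
  idx <- match(fit$edges$vessel_id, net$vessels$id)
  out <- dplyr::mutate(
    fit$edges[, c("vessel_id", "name", "district", "flow_ml_s")],
    reynolds = reynolds_number(
      flow = .data$flow_ml_s * M3S_PER_MLS,
      diameter = net$vessels$diameter_cm[idx] / CM_PER_M,
      density = density,
      viscosity = net$viscosity
    )
  )
  dplyr::arrange(out, dplyr::desc(.data$reynolds))
}

#' Exact one-sample Wilcoxon signed-rank comparison
#'
#' Tests whether measured flow rates differ from a model estimate using the
#' one-sample Wilcoxon signed-rank test with an exact two-sided p-value.
#' Zero differences are dropped (reducing n, the standard convention); ties
#' among |differences| receive average ranks. The exact null distribution of
#' the positive-rank sum is obtained by enumerating all 2^n sign assignments
#' via dynamic programming over the (doubled, hence integer) rank values —
#' identical to brute-force enumeration but polynomial-time.
#'
#' @param measured Numeric vector of measured values (e.g. per-subject mean
#'   flows, ml/s).
#' @param model_value Single model estimate to compare against.
#' @return One-row tibble: `model_value`, `n` (non-zero differences),
#'   `n_zero` (dropped), `statistic` (positive-rank sum V), `p_value`
#'   (exact, two-sided). When all differences are zero, `p_value = 1` with
#'   `n = 0`.
#' @examples
#' signed_rank_compare(c(5.1, 5.4, 5.2, 5.9, 5.3), 5.0)  # p = 0.0625
#' @export
signed_rank_compare <- function(measured, model_value) {
  if (!is.numeric(measured) || length(measured) == 0) {
    abort("`measured` must be a non-empty numeric vector.")
  }
  if (!is.numeric(model_value) || length(model_value) != 1) {
    abort("`model_value` must be a single number.")
  }
  d <- measured - model_value
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(model_value = model_value, n = 0L, n_zero = n_zero,
                  statistic = NA_real_, p_value = 1))
  }
  r <- rank(abs(d))                    # average ranks on ties
  v <- sum(r[d > 0])
  p <- exact_signed_rank_p(r, v)
  tibble(model_value = model_value, n = as.integer(n),
         n_zero = as.integer(n_zero), statistic = v, p_value = p)
}

# Exact two-sided p for the signed-rank statistic given the (possibly
# tie-averaged) ranks r and observed positive-rank sum v. Works on doubled
# ranks so all values are integers, then convolves the sign-assignment
# generating function (1 + x^(2 r_i)) over all elements.
exact_signed_rank_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1)         # counts[s + 1] = #assignments with sum s
  counts[1] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  v2 <- round(2 * v)
  # tiny tolerance so tie-averaged half-ranks compare robustly
  upper <- sum(probs[(0:total) >= v2 - 1e-9])
  lower <- sum(probs[(0:total) <= v2 + 1e-9])
  min(1, 2 * min(upper, lower))
}

#' Compare measured flows against a solved model, vessel by vessel
#'
#' Applies [signed_rank_compare()] to every vessel of a measured-flow table
#' (`vessel`, `subject_id`, `flow_ml_s`), using the solved model flow of the
#' matching vessel id as the reference value. Vessels absent from the model
#' are listed, warned about and skipped. Significance classes follow the
#' conventional 0.05 (significant) and 0.1 (trend) cut-offs.
#'
#' @param measured Data frame with columns `vessel`, `subject_id`,
#'   `flow_ml_s`, or the path of such a CSV.
#' @param fit A [solve_network()] result.
#' @return Tibble: `vessel`, `model_ml_s`, `median_measured_ml_s`, `n`,
#'   `statistic`, `p_value`, `class` (`significant`/`trend`/`ns`).
#' @export
compare_flows <- function(measured, fit) {
  stopifnot(inherits(fit, "venonet_solve"))
  if (is.character(measured)) {
    measured <- readr::read_csv(measured, show_col_types = FALSE)
  }
  required <- c("vessel", "subject_id", "flow_ml_s")
  if (!all(required %in% names(measured))) {
    abort("`measured` needs columns vessel, subject_id, flow_ml_s.")
  }
  if (nrow(measured) == 0) abort("`measured` has no rows.")
  missing <- setdiff(unique(measured$vessel), fit$edges$vessel_id)
  if (length(missing) > 0) {
    warn(paste0("measured vessel(s) absent from the model, skipped: ",
                paste(missing, collapse = ", ")))
    measured <- measured[!measured$vessel %in% missing, ]
  }
  purrr::map_dfr(split(measured, measured$vessel), function(tab) {
    vessel <- tab$vessel[1]
    model <- fit$edges$flow_ml_s[match(vessel, fit$edges$vessel_id)]
    cmp <- signed_rank_compare(tab$flow_ml_s, model)
    tibble(
      vessel = vessel,
      model_ml_s = model,
      median_measured_ml_s = stats::median(tab$flow_ml_s),
      n = cmp$n,
      statistic = cmp$statistic,
      p_value = cmp$p_value,
      class = dplyr::case_when(
        cmp$p_value < 0.05 ~ "significant",
        cmp$p_value < 0.1 ~ "trend",
        TRUE ~ "ns"
      )
    )
  })
}
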