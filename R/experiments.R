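#' Built-in obstruction experiments
#'
#' Runs one of the canonical occlusion protocols on the reference anatomy
#' (or any network sharing its vessel ids):
#'
#' * `"ijv-bilateral"` — both internal jugular veins reduced independently,
#'   0-100% in 10% steps (11 x 11 = 121 grid points).
#' * `"ijv-collaterals"` — the same grid after adding one collateral per IJV
#'   (same length, 0.4 cm diameter) in parallel.
#' * `"vv-bilateral"` — all twelve vertebral-vein segments reduced together,
#'   0-100% in 10% steps (11 points).
#' * `"azygos-proximal"` — the four proximal azygos segments reduced
#'   together, 0-100% in 10% steps (11 points).
#'
#' An optional diameter override re-runs a jugular protocol at alternative
#' published baseline IJV diameters (e.g. 1 cm or 0.7 cm) by setting both
#' IJVs before sweeping.
#'
#' @param name Experiment name (see above).
#' @param net Baseline network (default [reference_anatomy()]).
#' @param step Grid increment (default 0.1; use 0.01 for fine sweeps).
#' @param ijv_diameter_cm Optional absolute baseline IJV diameter override.
#' @return The [run_sweep()] result (class `venonet_sweep`).
#' @examples
#' \donttest{
#' sw <- run_experiment("azygos-proximal")
#' find_threshold(sw, pred_flow_negative("AZ5"), "AZ5 retrograde")
#' }
#' @export
run_experiment <- function(name = c("ijv-bilateral", "ijv-collaterals",
                                    "vv-bilateral", "azygos-proximal"),
                           net = reference_anatomy(), step = 0.1,
                           ijv_diameter_cm = NULL) {
  name <- match.arg(name)
  grid <- seq(0, 1, by = step)
  if (!isTRUE(all.equal(utils::tail(grid, 1), 1))) grid <- c(grid, 1)
  if (!is.null(ijv_diameter_cm)) {
    net <- override_diameters(net, c("IJV_l", "IJV_r"), ijv_diameter_cm)
  }
  switch(
    name,
    "ijv-bilateral" = run_sweep(net, list(
      sweep_axis("IJV_l", grid), sweep_axis("IJV_r", grid)
    )),
    "ijv-collaterals" = {
      net <- add_collaterals(net, "IJV_l", diameter_cm = 0.4)
      net <- add_collaterals(net, "IJV_r", diameter_cm = 0.4)
      run_sweep(net, list(
        sweep_axis("IJV_l", grid), sweep_axis("IJV_r", grid)
      ))
    },
    "vv-bilateral" = run_sweep(net, sweep_axis(
      paste0("VV_", rep(c("l", "r"), each = 6), 1:6), grid, label = "VV"
    )),
    "azygos-proximal" = run_sweep(net, sweep_axis(
      paste0("AZ", 1:4), grid, label = "AZ_proximal"
    ))
  )
}

#' Reflux onset table of a sweep
#'
#' For every vessel that is refluent at any grid point, the grid point(s)
#' where reflux first appears (in sweep iteration order along each axis
#' combination this is simply the set of refluent rows; for single-axis
#' sweeps the minimum grid value is reported).
#'
#' @param sweep A [run_sweep()] result.
#' @param tolerance Stagnation tolerance in m^3/s.
#' @return Long tibble: axis columns, `vessel_id`, `district`, `flow_ml_s`
#'   for every (grid point, refluent vessel) pair.
#' @export
reflux_onset <- function(sweep, tolerance = 1e-12) {
  stopifnot(inherits(sweep, "venonet_sweep"))
  labels <- attr(sweep, "axis_labels")
  purrr::map_dfr(seq_len(nrow(sweep)), function(i) {
    fit <- sweep$solve[[i]]
    if (is.null(fit)) return(NULL)
    r <- detect_reflux(fit, tolerance = tolerance)
    if (nrow(r) == 0) return(NULL)
    dplyr::bind_cols(sweep[i, labels, drop = FALSE],
                     r[, c("vessel_id", "district", "flow_ml_s")])
  })
}
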