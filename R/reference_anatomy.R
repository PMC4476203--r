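#' Synthetic reference anatomy of the cerebrospinal venous system
#'
#' Builds the bundled cerebrospinal venous network: a 126-element synthetic
#' reconstruction comprising every named structure of the modelled anatomy —
#' ophthalmic veins, basal veins of Rosenthal, internal cerebral veins,
#' inferior/superior sagittal sinus, vein of Galen, straight sinus,
#' transverse/sigmoid sinuses, occipital sinuses, basilar plexus, cavernous
#' and petrosal sinuses intracranially; internal jugular veins, six-segment
#' vertebral veins, the cervical plexus (seven segments plus anterior and
#' posterior limbs) and its connectives at the neck; twelve-segment thoracic
#' plexus, azygos vein and their connectives in the chest; inferior vena
#' cava, lumbar plexus/veins and their connectives caudally — plus one
#' intervertebral feeder vein per vertebral inflow (21 in all).
#'
#' Dimensions are equivalent diameters chosen from standard anatomical ranges
#' and from the requirement that the baseline operating point is
#' physiological (all drainage antegrade, superior-sagittal-sinus flow around
#' 7 ml/s, laminar Reynolds numbers peaking in that sinus, sinus pressures of
#' a few mmHg). The anatomy is *synthetic*: it is not transcribed from any
#' subject-specific or published per-vessel dataset, and its element count
#' need not match published whole-network tallies whose exact segment
#' multiplicities are not publicly enumerated. Edge orientation encodes the
#' physiological drainage direction (equivalently, the baseline flow
#' direction), so reflux detection is a sign test.
#'
#' Boundary conditions: zero pressure at the subclavian-vein node (`scv`) and
#' the right-atrium node (`ra`). Because every path between the cranio-
#' cervical and thoraco-lumbar territories passes through a reference node,
#' the network splits into two hydraulically decoupled systems: brain +
#' cervical spine (inputs `Q_c`, `Q_v1..Q_v7`) and heart + lower spine
#' (inputs `Q_f`, `Q_v8..Q_v21`).
#'
#' Default inflows (config-file defaults, overridable): `Q_c` = 11.7 ml/s
#' (~700 ml/min total cerebral blood flow), `Q_v` = 0.3 / 0.4 / 0.5 ml/s per
#' cervical / thoracic / lumbar vertebral level, `Q_f` = 10 ml/s; blood
#' viscosity 3 cP.
#'
#' @param inputs Optional replacement input table (`node_id`, `rate_ml_s`,
#'   `label`); default [reference_inputs()].
#' @return A [venous_network()] with 126 vessels.
#' @seealso The same network ships as plain files under
#'   `system.file("extdata", package = "venonet")`
#'   (`cerebrospinal_anatomy_synthetic.csv` + `cerebrospinal_config.json`).
#' @export
reference_anatomy <- function(inputs = NULL) {
  v <- function(id, side, district, l, d, up, dn, name = id) {
    tibble(id = id, name = name, side = side, district = district,
           length_cm = l, diameter_cm = d,
           upstream_node = up, downstream_node = dn)
  }
  lr <- c("l", "r")

  intracranial <- dplyr::bind_rows(
    v(paste0("OV_", lr), c("left", "right"), "intracranial", 4, 0.21,
      "brain", paste0("cav_", lr)),
    v(paste0("ICV_", lr), c("left", "right"), "intracranial", 3.5, 0.126,
      "brain", "galen_conf"),
    v(paste0("RV_", lr), c("left", "right"), "intracranial", 4, 0.126,
      "brain", "galen_conf"),
    v("ISS", "midline", "intracranial", 5, 0.126, "brain", "srs_orig"),
    v("GV", "midline", "intracranial", 1.5, 0.245, "galen_conf", "srs_orig"),
    v("SRS", "midline", "intracranial", 5, 0.315, "srs_orig", "torcular"),
    v("SSS", "midline", "intracranial", 24, 0.455, "brain", "torcular"),
    v(paste0("TS_", lr), c("left", "right"), "intracranial", 7, 0.385,
      "torcular", paste0("sigj_", lr)),
    v(paste0("SS_", lr), c("left", "right"), "intracranial", 5, 0.42,
      paste0("sigj_", lr), paste0("jug_", lr)),
    v(paste0("CS_", lr), c("left", "right"), "intracranial", 2, 0.28,
      paste0("cav_", lr), paste0("pj_", lr)),
    v(paste0("SPS_", lr), c("left", "right"), "intracranial", 4, 0.21,
      paste0("pj_", lr), paste0("sigj_", lr)),
    v(paste0("IPS_", lr), c("left", "right"), "intracranial", 3.5, 0.245,
      paste0("pj_", lr), paste0("jug_", lr)),
    v(paste0("BP_", lr), c("left", "right"), "intracranial", 2.5, 0.12,
      paste0("cav_", lr), "bp_conf"),
    v("POS", "midline", "intracranial", 3, 0.15, "torcular", "pos_conf"),
    v(paste0("POS_", lr), c("left", "right"), "intracranial", 2.5, 0.12,
      "pos_conf", "occ_conf")
  )

  cervical <- dplyr::bind_rows(
    v("CP_a", "midline", "cervical", 3, 0.25, "bp_conf", "c0"),
    v("CP_p", "midline", "cervical", 3, 0.22, "occ_conf", "c0"),
    v(paste0("IJV_", lr), c("left", "right"), "cervical", 15, 1.20,
      paste0("jug_", lr), "scv"),
    v(paste0("CP", 1:7), "midline", "cervical", 2.5, 0.80,
      paste0("c", 0:6), paste0("c", 1:7)),
    # vertebral vein chains: six segments per side, draining to the
    # subclavian reference
    v(paste0("VV_l", 1:6), "left", "cervical", 2.5, 0.55,
      paste0("vl", 1:6), c(paste0("vl", 2:6), "scv")),
    v(paste0("VV_r", 1:6), "right", "cervical", 2.5, 0.55,
      paste0("vr", 1:6), c(paste0("vr", 2:6), "scv")),
    # plexus-to-vertebral connectives at levels C2..C7
    v(paste0("CPVV_l", 1:6), "left", "connective", 1.5, 0.50,
      paste0("c", 2:7), paste0("vl", 1:6)),
    v(paste0("CPVV_r", 1:6), "right", "connective", 1.5, 0.50,
      paste0("c", 2:7), paste0("vr", 1:6)),
    # intervertebral feeders carrying the cervical vertebral inflows
    v(paste0("IV_c", 1:7), "midline", "connective", 1.5, 0.30,
      paste0("qc", 1:7), paste0("c", 1:7))
  )

  thoracic <- dplyr::bind_rows(
    # azygos: twelve segments, arch (segment 1) entering at the right-atrium
    # reference; proximal segments wider than distal
    v(paste0("AZ", 1:12), "midline", "thoracic", 2.2,
      rep(c(0.85, 0.75, 0.65), each = 4),
      paste0("az", 1:12), c("ra", paste0("az", 1:11))),
    # thoracic plexus: segments 1..11 drain upward toward the azygos arch,
    # segment 12 downward into the lumbar route (baseline watershed)
    v(paste0("TP", 1:11), "midline", "thoracic", 2.8, 0.60,
      paste0("t", 2:12), paste0("t", 1:11)),
    v("TP12", "midline", "thoracic", 2.8, 0.60, "t12", "tlj"),
    v(paste0("TPAZ", 1:12), "midline", "connective", 2, 0.50,
      paste0("t", 1:12), paste0("az", 1:12)),
    v(paste0("IV_t", 1:12), "midline", "connective", 1.5, 0.30,
      paste0("qt", 1:12), paste0("t", 1:12))
  )

  lumbar <- dplyr::bind_rows(
    v("LP1", "midline", "lumbar", 4, 0.60, "tlj", "l1"),
    v("LP2", "midline", "lumbar", 4, 0.60, "l1", "l2"),
    v("LPLV1", "midline", "connective", 2, 0.40, "l1", "w1"),
    v("LPLV2", "midline", "connective", 2, 0.40, "l2", "w2"),
    v("LV1", "midline", "lumbar", 4, 0.50, "w1", "w2"),
    v("LV2", "midline", "lumbar", 4, 0.50, "w2", "k1"),
    v("CV2", "midline", "lumbar", 8, 1.50, "fem", "k1"),
    v("CV1", "midline", "lumbar", 6, 1.80, "k1", "k2"),
    v("CV", "midline", "lumbar", 6, 2.00, "k2", "ra"),
    v(paste0("IV_l", 1:2), "midline", "connective", 1.5, 0.30,
      paste0("ql", 1:2), paste0("l", 1:2))
  )

  vessels <- dplyr::bind_rows(intracranial, cervical, thoracic, lumbar)

  if (is.null(inputs)) inputs <- reference_inputs()
  venous_network(vessels, inputs, reference_nodes = c("scv", "ra"),
                 viscosity_cP = 3)
}

#' Default arterial inflows of the reference anatomy
#'
#' @return Tibble `node_id`, `rate_ml_s`, `label` with `Q_c`, `Q_v1..Q_v21`
#'   and `Q_f` (see [reference_anatomy()] for values and rationale).
#' @export
reference_inputs <- function() {
  dplyr::bind_rows(
    tibble(node_id = "brain", rate_ml_s = 11.7, label = "Q_c"),
    tibble(node_id = paste0("qc", 1:7), rate_ml_s = 0.3,
           label = paste0("Q_v", 1:7)),
    tibble(node_id = paste0("qt", 1:12), rate_ml_s = 0.4,
           label = paste0("Q_v", 8:19)),
    tibble(node_id = paste0("ql", 1:2), rate_ml_s = 0.5,
           label = paste0("Q_v", 20:21)),
    tibble(node_id = "fem", rate_ml_s = 10, label = "Q_f")
  )
}
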