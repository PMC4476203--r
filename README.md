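# venonet

Lumped-parameter modelling of cerebrospinal venous circulation in R.

`venonet` answers a question that comes up wherever extracranial venous
abnormalities are suspected of affecting the brain (jugular stenosis,
vertebral or azygos obstruction, and the debates around chronic cerebrospinal
venous insufficiency): *can a morphological change in a neck or chest vein
measurably alter intracranial venous pressures and flow directions?* It is
aimed at physiologists and biomedical engineers who want a transparent,
fully scriptable steady-state model rather than a patient-specific CFD
pipeline.

## The model

Every vein segment is a hydraulic resistance given by Poiseuille's law,

```
R = 128 μ L / (π D⁴),       ΔP = R · Q
```

with L the segment length, D its equivalent lumen diameter and μ the blood
viscosity (3 cP). Mass conservation at every junction turns the network into
a sparse linear system in the node pressures (nodal analysis — the hydraulic
analogue of Kirchhoff's current law); arterial inflows enter as fixed flow
sources (`Q_c` cerebral, `Q_v1..Q_v21` vertebral, `Q_f` femoral), and the
subclavian vein and right atrium are zero-pressure references. Solving it
yields the pressure at every node and a signed flow in every vessel; a
negative sign means retrograde flow (reflux). Because compliance and
inertance are omitted, the model is strictly steady-state and describes the
supine position.

The package ships a 126-element **synthetic** reconstruction of the
cerebrospinal venous tree (`reference_anatomy()`, also bundled as plain
CSV/JSON under `inst/extdata/`): ophthalmic, deep cerebral and Rosenthal
veins, the sagittal/straight/transverse/sigmoid sinus system, cavernous and
petrosal sinuses, basilar and occipital routes, jugular and vertebral veins,
cervical/thoracic/lumbar vertebral plexuses, azygos and caval trunks, and
per-vertebra feeder veins. Dimensions are drawn from standard anatomical
ranges — not transcribed from any subject dataset — so all numerical
thresholds below are properties of this stated anatomy.

## A worked example

```r
library(venonet)
library(dplyr)

net <- reference_anatomy()
fit <- solve_network(net)
glance(fit)
#>   n_vessels n_nodes total_inflow_ml_s max_pressure_Pa residual_m3_s residual_rel n_retrograde
#> 1       126      90              29.6            714.          1.27e-20     4.29e-16            0

tidy(fit) |> filter(vessel_id %in% c("SSS", "IJV_l", "VV_l2"))
#>   vessel_id name  district     flow_ml_s delta_p_Pa antegrade
#> 1 SSS       SSS   intracranial     6.94      475.   TRUE
#> 2 IJV_l     IJV_l cervical         5.64        4.99 TRUE
#> 3 VV_l2     VV_l2 cervical         0.201       0.670 TRUE
```

The baseline operating point is physiological: 29.6 ml/s of total inflow
drains entirely antegrade, the superior sagittal sinus carries 6.9 ml/s
(~420 ml/min), each internal jugular vein about 5.6 ml/s, and the vertebral
veins a small supine share. All Reynolds numbers are laminar, peaking at
~690 in the SSS — which is what justifies the Poiseuille closure.

Occlusion experiments are one call each:

```r
sw <- run_experiment("ijv-bilateral")          # 11 x 11 reduction grid
reflux_onset(sw) |> filter(district == "intracranial") |> distinct(vessel_id)
#> CS_l CS_r IPS_l IPS_r SPS_l SPS_r SS_l SS_r TS_l TS_r

az <- run_experiment("azygos-proximal")
find_threshold(az, pred_flow_negative("AZ5"), "AZ5 retrograde")
#>   axis        predicate      reached first_true last_false ...
#> 1 AZ_proximal AZ5 retrograde TRUE           0.7        0.6
```

Severe bilateral jugular narrowing (≥ 90% on the symmetric diagonal)
reverses the cavernous and petrosal drainage — the same reflux topography
seen clinically — while the deep Galenic system never refluxes; the pressure
at the confluence of the Rosenthal veins into the vein of Galen doubles from
70% symmetric reduction, and the jugular upstream pressure doubles already
at 20% monolateral narrowing. Blocking the four proximal azygos segments
reverses the mid-azygos flow beyond 70% reduction and re-routes thoraco-lumbar
blood to the right atrium through the inferior vena cava.

Interventions compose with ordinary pipes:

```r
net |>
  add_collaterals("IJV_l", diameter_cm = 0.4) |>
  apply_stenosis(c("IJV_l", "IJV_r"), 0.8) |>
  solve_network() |>
  detect_reflux()
```

`autoplot(fit)`, `plot_sweep_grid()` and `plot_sweep_profile()` draw the
standard flow-map, occlusion-grid and sweep-profile figures. A thin CLI
wrapper lives at `inst/cli/venonet.R`
(`Rscript venonet.R simulate|sweep|compare ...`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — baseline solve of the bundled anatomy, the bilateral
jugular / vertebral / proximal-azygos occlusion protocols, the collateral
comparison and the Reynolds summary — printing every computed headline
quantity and writing the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
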