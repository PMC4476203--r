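---
title: "A lumped-parameter model of cerebrospinal venous circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of cerebrospinal venous circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venonet)
library(dplyr)
```

## The model and its assumptions

`venonet` treats the cerebrospinal venous system as an electrical-analogue
resistance network. Each vein segment of length $L$ and equivalent diameter
$D$ is one resistive element,

$$R = \frac{128\,\mu L}{\pi D^4}, \qquad \Delta P = R\,Q,$$

with $\mu$ the dynamic viscosity of blood (3 cP by default). Enforcing mass
conservation at every junction gives a sparse linear system in the unknown
node pressures: the diagonal of the conductance matrix collects the
conductances $g = 1/R$ incident to a node, off-diagonals carry $-g$ per
connecting element, the right-hand side carries the injected arterial
inflows, and reference-node pressures are eliminated at their fixed values.
The system is solved directly (`Matrix::solve`); for the ~100 unknowns
involved this is exact, deterministic and instantaneous, so no
preconditioning or iteration is used. Element flows follow as
$Q_e = g_e\,(P_\mathrm{up} - P_\mathrm{down})$.

The assumptions bundled into this closure are:

* **Steady state.** Compliance and inertance are omitted, so cardiac and
  respiratory modulation are invisible; every result is a time-average.
* **Poiseuille flow.** Fully developed laminar flow in straight rigid
  pipes. The baseline Reynolds numbers (maximum ≈ 690 in the superior
  sagittal sinus, `reynolds_numbers()`) support the laminar part; curvature
  and non-circular lumina are absorbed into the *equivalent* diameter.
* **Supine posture.** The jugular veins are the dominant outflow; in the
  upright position they collapse and the model's anatomy table would need
  different calibers.
* **Linearity.** Superposition and homogeneity hold exactly, which the test
  suite exploits: the effect of combined lesions is the sum of the effects
  of single lesions.

Positive flow is *antegrade* (the physiological drainage direction encoded
by each edge's orientation); reflux detection is therefore a sign test with
a small stagnation band (default $10^{-12}\ \mathrm{m^3/s}$, far below any
physiological flow, guarding only against float noise).

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| viscosity | cP | 3 | standard whole-blood value at body temperature |
| blood density (Reynolds only) | kg/m³ | 1060 | standard whole-blood value |
| `Q_c` cerebral inflow | ml/s | 11.7 | ≈700 ml/min total cerebral blood flow |
| `Q_v1..7` cervical feeders | ml/s | 0.3 each | small per-vertebra drainage |
| `Q_v8..19` thoracic feeders | ml/s | 0.4 each | idem, thoracic levels |
| `Q_v20..21` lumbar feeders | ml/s | 0.5 each | idem, lumbar levels |
| `Q_f` femoral inflow | ml/s | 10 | combined lower-limb venous return |
| reflux tolerance | m³/s | 1e-12 | solver-noise guard only |
| residual warning | – | 1e-8 relative | flags near-singular post-occlusion solves |

Geometry lives in the anatomy table (cm), flows in ml/s, pressures in Pa
(with a mmHg rendering in `tidy(fit, "nodes")`); every internal computation
is strict SI, converted at a single boundary (`vessel_resistances()`).

## The bundled anatomy — what it is and is not

The reference network (`reference_anatomy()`, 126 elements) is a *synthetic
reconstruction*. It contains every named structure of the modelled
anatomy — the full dural sinus system, cavernous/petrosal routes, basilar
and occipital accessory routes, jugular and vertebral veins, the
cervical/thoracic/lumbar vertebral plexuses with their connectives, azygos
and caval trunks — plus one intervertebral feeder per vertebral inflow. Its
dimensions are equivalent diameters chosen once from standard anatomical
ranges under four physiological requirements, all imposed *before* the test
suite was frozen:

1. baseline drainage is antegrade in every one of the 126 vessels;
2. the superior sagittal sinus carries ≈7 ml/s of the 11.7 ml/s cerebral
   inflow, with jugular dominance in the supine position;
3. sinus pressures sit at a few mmHg above the right atrium, and the flow
   regime is laminar everywhere, peaking in the SSS;
4. accessory drainage routes (basilar → anterior plexus limb, occipital →
   posterior limb) are much more resistive than a patent jugular but
   cheaper than a blocked one, which orders the escape routes so that
   severe *bilateral* jugular obstruction reverts the cavernous/petrosal
   drainage (CS, IPS, SPS) — the clinically observed reflux topography —
   while *monolateral* total occlusion reverts the ipsilateral sigmoid
   sinus via a trans-torcular crossing to the patent side.

Whole-network element counts published for models of this class (160+
elements) cannot be reproduced exactly because the underlying per-vessel
dimension tables are not publicly enumerated; the 126-element reconstruction
keeps the caption-level segment multiplicities (six vertebral segments per
side, seven cervical plexus segments, twelve thoracic/azygos segments, and
so on) and documents every interpretive choice here.

Two structural facts are worth knowing. First, because the subclavian and
right-atrium nodes are both zero-pressure references, the network decouples
into two independent systems (brain + cervical spine vs heart + lower
spine); a perturbation on one side leaves the other bit-identical, which is
tested. Second, plexus-chain orientations at the thoraco-lumbar watershed
are genuinely direction-free in textbooks; they are frozen to the baseline
model's computed directions (segments T1–T11 drain toward the azygos arch,
T12 toward the lumbar route), the same convention used for the published
flow-direction figures of this model class.

## What the occlusion experiments show (computed, not asserted from elsewhere)

All numbers below are produced by `scripts/acceptance.R` and re-checked by
the test suite on the bundled anatomy; on a different anatomy table they
will differ, and they should — they are properties of the stated world.

* **Bilateral jugular sweep** (11×11 grid, 121 solves): intracranial reflux
  appears from 90% symmetric diameter reduction, confined to the cavernous,
  petrosal and sigmoid/transverse drainage; the deep Galenic system
  (Rosenthal veins, internal cerebral veins, vein of Galen) never refluxes.
  The pressure at the Rosenthal-to-Galen confluence doubles from 70%
  symmetric reduction; the jugular upstream pressure doubles already at 20%
  monolateral reduction.
* **Collaterals** (one 0.4 cm, same-length vessel parallel to each
  jugular): the patent-network solution changes by at most 1.2%, consistent
  with a fourth-power conductance ratio $(0.4/1.2)^4 \approx 1\%$.
* **Bilateral vertebral sweep**: occipital-sinus reflux from 70% reduction;
  the cervico-vertebral territory is pressurised two orders of magnitude
  more than the core intracranial nodes (≈35% core rise at 90% reduction),
  and at complete block the plexus blood re-routes through the skull to the
  jugulars.
* **Proximal azygos sweep**: mid-azygos (AZ5) flow reverses beyond 70%
  reduction of the four proximal segments; pressure rises fall off with
  distance from the obstruction, and the refluent distal azygos and
  thoracic-plexus segments drain to the right atrium through the inferior
  vena cava.

## Known divergences of the synthetic anatomy

With the published whole-network model this package emulates, two
quantitative statements do not transfer to the synthetic anatomy and are
deliberately *not* asserted by the tests:

* exact grid thresholds (e.g. pressure doubling at an 80%/90% asymmetric
  pair) shift by one or two 10%-grid steps, because they depend entirely on
  the unavailable per-vessel dimension table — the original authors make
  the same caveat about their own thresholds;
* with collaterals added, severe bilateral jugular stenosis no longer
  produces intracranial reflux here: a patent 0.4 cm collateral out-drains
  the narrow accessory routes of this reconstruction, whereas anatomies
  with stronger accessory routes retain the reflux. The collateral
  *sensitivity bound* (<3.5% change of the patent network) does hold.

## Numerical choices and degenerate inputs

* Complete occlusion removes the edge rather than assigning a huge finite
  resistance: the conductance matrix stays well-posed and "blocked" is
  exact. A source left without any path to a reference is a *graceful*
  error (naming the node); inside sweeps such grid points become flagged
  `"singular"` records instead of aborting the grid.
* Reference-free but source-free components (possible after removals) have
  indeterminate pressure level; they are reported as `NA` pressures with
  exactly zero flows.
* Zero-resistance elements are disallowed — merge the nodes instead.
* Flow-balance residuals are always recomputed post hoc from the returned
  pressures; a relative residual above 1e-8 raises a warning, since
  near-singular post-occlusion systems are the main silent failure mode.
* Threshold search is grid-discrete by design (first-true / last-false,
  all transitions reported if non-monotone); no interpolation, matching how
  such protocols report "at least X%" results.
* The exact signed-rank test enumerates sign assignments by dynamic
  programming over doubled (hence integer, tie-averaged) ranks — identical
  to brute-force $2^n$ enumeration, which the tests verify directly for
  $n \le 10$ — with zero differences dropped and two-sided p-values capped
  at 1.

## What a green test establishes — and what it does not

The property layer (conservation, linearity, Rayleigh monotonicity,
agreement with an independent relaxation oracle, closed-form toys, exact
signed-rank enumeration) validates the *solver and statistics* on arbitrary
networks; it would catch essentially any assembly or elimination bug. The
anatomy layer validates that the *stated* synthetic anatomy reproduces the
qualitative physiology and pathophysiology: drainage directions, reflux
topography and severity ordering, decoupling, laminarity. It does not
validate patient-level quantitative prediction: real anatomies are
asymmetric (right-dominant jugular and transverse sinuses are common),
inter-subject caliber variability is large, and the steady-state closure
hides all pulsatility. Those limits are inherent to the model class, not to
this implementation; asymmetric or patient-specific tables can be supplied
as plain CSV without touching any code.
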