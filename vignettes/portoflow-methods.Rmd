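---
title: "Methods: a network model of portal venous pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a network model of portal venous pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portoflow)
```

## The model and its assumptions

`portoflow` estimates the pressure at the centre of the portal vein — the
virtual free portal pressure, vFPP — from Doppler ultrasound measurements
of the portal venous system. Blood in these vessels can be treated as an
incompressible Newtonian fluid in steady flow; at canine scale the
Reynolds number of the control portal vein is

```{r}
reynolds(d = 4.5, v = 0.7 * 33.8, rho = 1050, mu = 3.5e-3)
```

about 319, far below transition, so the flow is laminar throughout. Under
those conditions the full momentum balance reduces, per vessel segment, to
the fully developed (Hagen–Poiseuille) profile, and the governing
equations collapse to a resistive network:

* each segment, a circular tube of length $L$ tapering linearly from
  diameter $d_0$ to $d_1$, carries resistance
  $R = \int_0^L 128\mu\,\mathrm{d}x / (\pi d(x)^4)
     = 128 \mu L (d_0^2 + d_0 d_1 + d_1^2)/(3 \pi d_0^3 d_1^3)$ (SI);
* junctions are shared-pressure nodes with exact mass conservation
  ($\sum Q = 0$, no source terms, no junction losses);
* gravity and external body forces are dropped (supine subject, venous
  pressure scale);
* the energy equation is decoupled (isothermal, incompressible) and never
  solved.

The unknown nodal pressures solve a linear system with segment
conductances $1/R$; a single direct dense solve makes the result
deterministic to the bit. Because the system is linear (Stokes-regime
network), pressures scale exactly linearly in viscosity and in all
boundary flows jointly — both properties are enforced by tests.

Convective momentum, pulsatility, vessel compliance, non-Newtonian
rheology and three-dimensional secondary flows at junctions are outside
the model. They are the price of a desk-scale, analytically verifiable
reduction; the network solution on any single tube equals the closed-form
Poiseuille drop to $10^{-10}$ relative, which is the package's primary
solver oracle.

## Geometry and boundary conditions

The canonical tree has six named vessels: splenic, superior and inferior
mesenteric veins meeting at the portosplenic confluence; the portal trunk
from the confluence to the liver hilum; left and right portal branches
leaving the hilum. Cross-sections are circular; per-vessel diameters are
single values (taper supports joining unequal parent/child diameters).
Segment lengths are not observable from the published summary tables, so
the template lengths (trunk 45 mm, hepatic branches 25 mm, splanchnic
inlets 40–50 mm) are package defaults at canine scale; they scale all
viscous drops proportionally and do not affect any agreement statistic in
forward-consistent mode.

Doppler measurements map to boundary conditions in three steps, each a
config-visible operation: the mean-from-maximum factor
($v \approx 0.7\,v_{\max}$; configurable because it is an empirical
approximation), flow through the measured section ($Q = \tfrac{\pi}{4} d^2 v$),
and rescaling to the boundary face diameter ($v_b = d_{us}^2 v_{us}/d_b^2$),
which conserves $Q$ exactly. With measured velocities imposed on all five
free branches the network is mass-over-determined, so the two hepatic
outflows are rescaled by a common factor until total outflow equals total
splanchnic inflow; inflow measurements are kept as anchors because
splanchnic inflow is the physiological driver. Reconciliation is
idempotent and leaves zero net flow for the pressure-outlet face.

**Placement of the pressure reference.** One face must pin the gauge
pressure ("gauge 0"). The natural candidate, per the boundary-condition
recipe, is "the portal vein" — but with six segments and five free branch
ends the trunk has no free cross-section once both hepatic branches carry
velocity conditions. The package therefore places the reference face on
the trunk at the hilum node. Since reconciliation guarantees the reference
face absorbs no flow, it is purely a gauge pin; placing it on a junction
is hydraulically equivalent to an infinitesimal stub there. The
alternative — modelling the trunk as a dead-end stub carrying the
reference face on a free node — would leave the trunk flowless and make
vFPP insensitive to every measurement, which contradicts the observable
behaviour the model exists to capture. Structural validation accordingly
requires velocity faces to sit on degree-1 nodes while the single
reference face may sit anywhere on the tree.

vFPP is extracted at the portal-trunk midpoint by linear interpolation
between the trunk's end-node pressures, converted at 1 mmHg = 133.322 Pa,
plus the absolute reference `p_ref` described next.

## The absolute pressure scale (`p_ref`)

A gauge-0 network can only produce *viscous* pressure differences, and at
the published diameters and velocities these are below 1 mmHg (tens of
pascals), while invasive FPP spans 6–19 mmHg. The viscous model alone
therefore cannot reproduce the absolute invasive scale; whatever absolute
calibration the original measurement chain used is not recoverable from
summary statistics. Rather than guessing it, the solver exposes `p_ref`
(mmHg, default 0) as an explicit additive reference:
vFPP = `p_ref` + trunk-midpoint gauge pressure. In forward-consistent
cohorts each animal's `p_ref` is drawn from its group's invasive-FPP
distribution and carried in the record, so truth and prediction share the
reference and only measurement noise separates them. This is a documented
modelling gap, not a resolved one.

## The synthetic cohort generator

The generator defines the study conditions: five groups (control plus 1–4
months of carbon tetrachloride dosing), five animals per group by default,
and for each animal six vessel diameters (mm), six maximum velocities
(cm/s) and an invasive FPP (mmHg) drawn independently from the published
group means ± SDs, plus blood density 1050 ± 15 kg m⁻³ and viscosity
3.5 ± 0.3 mPa s (typical mammalian whole blood; the study protocols
measure these per animal — density by triplicate gravimetry of a 1 mL
aliquot, emulated by `simulate_blood_density()` — but never publish the
values, so the defaults are generic and group-invariant).

Choices worth stating:

* **Independence.** No covariances are published; all quantities are drawn
  independently, and the correlation between disease stage and every
  quantity is carried by group membership alone. Real data would show
  within-animal correlation (e.g. dilated vessels with slower flow in the
  same dog); passing tests therefore certify the pipeline's arithmetic and
  statistical machinery, not biological realism of joint distributions.
* **Truncation.** Draws are truncated below at 0.2 × mean to exclude
  non-physical values. At coefficients of variation up to ~25 % the
  induced moment bias is negligible; for the two published velocity cells
  with CV above 30 % (splenic at 3 months, right portal at 2 months) the
  truncation measurably shifts the sample SD (≈ 3 % low) and mean
  (≈ 1 % high) relative to the configured values — a deliberate,
  documented property of the positivity rule rather than a calibration
  error.
* **Geometry = measurement.** Each animal's drawn diameters serve both as
  its tree geometry (the synthetic analogue of per-subject CT
  reconstruction) and as its noise-free Doppler diameters; measurement
  noise (`add_doppler_noise()`, multiplicative Normal(1, cv), default CVs
  ≤ 0.10 per the reported observer variability) perturbs only the
  measurement copy.
* **Substreams.** Every animal consumes its own seeded substream, so a
  cohort is a pure function of (parameters, n, seed, mode) and adding
  animals never perturbs earlier draws.
* **Two modes.** `table_emulation` mirrors the real study design (truth
  and measurements linked only through group membership): it is the mode
  for calibration checks and group tables. `forward_consistent` runs the
  forward model on the noise-free measurements to define truth
  (`forward_truth()`), making parameter recovery well-posed: at zero noise
  the pipeline reproduces every `fpp_true` exactly, and recovery
  experiments measure degradation as pure functions of the injected noise.

## Validation statistics

The agreement layer implements the method-comparison toolkit used to judge
vFPP against invasive FPP:

* **Bland–Altman**: bias = mean(vFPP − FPP), limits of agreement
  bias ± 1.96 SD; CIs use the 1999 variance forms with $t_{n-1}$
  quantiles — bias: $s/\sqrt{n}$; each limit:
  $s\sqrt{1/n + 1.96^2/(2(n-1))}$. With n = 25 these forms exactly
  reproduce the printed interval arithmetic of the motivating study, which
  is what the acceptance suite checks (the 25 real measurement pairs are
  not public, so the headline coefficients themselves are not
  reproducible targets).
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measures, from the two-way ANOVA mean squares; CI per McGraw–Wong. The
  absolute-agreement form is the defensible default for method comparison
  because it penalises constant offsets; the original analysis does not
  name its ICC model.
* **Lin's CCC** with 1/n moments and a Fisher-z interval.
* **ROC/AUC** by Mann–Whitney pair counting (ties ½) with DeLong variance;
  tested against brute-force pair enumeration on every dataset up to 50
  points and cross-checked against an independent implementation.
* **Threshold diagnostics** at FPP > 12 mmHg strictly: Clopper–Pearson
  exact intervals for sensitivity/specificity, Simel log-method intervals
  for likelihood ratios; undefined ratios (zero cells) are flagged rather
  than silently clipped.
* **Group tables** in "M ± SD" layout: Shapiro–Wilk normality screening
  selects t-test/ANOVA versus Mann–Whitney/Kruskal–Wallis, with P < 0.05
  flags versus control.

Degenerate inputs are handled explicitly: identical series give ICC = CCC
= 1 with collapsed CIs (the F/z machinery is undefined there), zero total
variance raises a classed error, and a perfectly separating threshold
yields LR⁻ = 0 with an undefined LR⁺ interval.

## Numerical and testing choices

Tolerances: solver-vs-oracle agreement and junction continuity at
$10^{-10}$ relative; reconciliation no-op threshold $10^{-12}$ relative;
the taper resistance is verified against midpoint-rule quadrature at
$2\times10^5$ points. The surface mesh (for export and QC only — never the
solver discretisation) targets one edge length in [0.2, 1.0] mm; capped
single tubes are watertight (every edge shared by exactly two triangles,
Euler characteristic 2) and the cylinder-area error decreases
monotonically with refinement.

Problem sizes in the test and acceptance suites are chosen to keep the
whole suite in the low minutes on a single core while leaving Monte-Carlo
bands meaningful: 100 random networks of up to 50 segments for continuity;
10,000 animals per group for generator calibration (3-standard-error
bands); 200 seeds at 5 % Doppler CV for recovery bias and 100 seeds at
10 % CV for the noise-monotonicity of ICC; 400 replicates for interval
coverage.

## Known limitations

* The absolute pressure scale is supplied, not predicted (`p_ref`); the
  viscous network contributes only the sub-mmHg gauge component.
* Junction losses and convective effects are neglected; at Re ≈ 300 with
  short branches this is defensible but unquantified here.
* The generator's independence assumption understates real covariance
  structure, and two high-CV table cells carry a visible truncation bias
  (see above).
* Geometry beyond diameters (lengths, angles, curvature) is conventional;
  only diameters are data-driven.
* All validation is against synthetic cohorts; nothing here certifies
  performance on real canine or human measurements.
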