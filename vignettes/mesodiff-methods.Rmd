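---
title: "A reaction-diffusion view of day respiration, mesophyll conductance and CO2 reassimilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reaction-diffusion view of day respiration, mesophyll conductance and CO2 reassimilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Day respiration (Rd) — non-photorespiratory CO2 release by leaves in the
light — is a small flux hidden underneath photosynthetic CO2 uptake, and
every regression method that extracts it from gas exchange makes an implicit
assumption about what happens to (photo)respired CO2 inside the mesophyll.
The Kok method (intercept of AN on Iinc at low light) and the Yin method
(intercept of AN on Iinc*Phi2/4, which corrects for the decline of the PSII
quantum yield Phi2 with irradiance) both assume that the chloroplast CO2
pressure Cc is constant across the regression window and that none of the
released CO2 is refixed before escaping. The Laisk method (common
intersection of AN-Ci lines measured at several irradiances) assumes the
mesophyll resistance is negligible. None of these assumptions is innocent:
part of the CO2 released by mitochondria is reassimilated by Rubisco before
it reaches the intercellular airspace, and how much depends on where the
mitochondria sit relative to the chloroplasts.

`mesodiff` implements a deliberately simple mechanistic alternative: a
steady-state reaction-diffusion model of CO2 in a two-dimensional mesophyll
unit cell, with explicit membranes and an explicit location for
(photo)respiratory release. Because the model resolves the intracellular CO2
field, it needs no mesophyll-conductance closure and no assumption about
reassimilation — both emerge from the solution. It can therefore be used
(i) as an estimator of Rd and Vcmax in its own right, (ii) as a testbed
that quantifies the biases of the Kok, Yin and Laisk estimators, and
(iii) to ask which release location is most consistent with data, via AIC.

## The unit cell

The domain is a half unit cell exploiting lateral symmetry. Depth ordering
from the intercellular airspace inward:

    airspace | cell wall | plasma membrane | outer cytosol | envelope |
    stroma | envelope | inner cytosol | tonoplast (no flux)

Laterally, the chloroplast spans a fraction Sc/Sm of the cell width; the
remaining strip is the cytosol gap between neighbouring chloroplasts,
contiguous with the outer and inner cytosol layers. The default anatomy
(`fixture_anatomy("ho_default")`) is the standard tomato parameter set:
wall 120 nm, cytosol 250 nm, stroma 2.5 um, Sc/Sm = 0.90, Sm/S = 16.

Two geometric choices are free in principle and fixed here by convention:

* the lateral chloroplast half-width is 5 um (a typical chloroplast size);
  only the fraction Sc/Sm matters, through the relative gap width;
* the inner cytosol thickness defaults to the (single) measured cytosol
  thickness, and the vacuole is not simulated — the tonoplast is a no-flux
  boundary;
* the gap is taken to span the full stroma depth range, the simplest
  reading of "spaces between two neighbouring chloroplasts".

Three scenarios place the (photo)respiratory source: `inner` (between
chloroplast and tonoplast, where mitochondria are mostly observed),
`gaps`, and `outer` (between plasma membrane and chloroplast, the implicit
assumption of two-resistance mesophyll models).

## Model equations

The steady field C (stored as Pa-equivalents) solves

    div(D_eff grad C) - sink(C) + source = 0

* `D_eff` is the water diffusivity of CO2 times a layer-wise relative
  factor (defaults: wall 1.0, cytosol 0.3, stroma 0.3; all configurable).
  Membranes are explicit face conductances P (default 3.5e-3 m s-1 for
  both plasma membrane and envelope). Henry's-law solubility
  (3.3e-4 mol m-3 Pa-1) closes the units between pressure gradients and
  molar fluxes. These transport constants are literature-typical values;
  they are stated inputs of the model, not fitted quantities.
* The sink acts only in the stroma and is the pointwise minimum of the
  Rubisco-limited and electron-transport-limited Michaelis-Menten laws,
  the volumetric form of the FvCB model with X1 = Vcmax, X2 =
  KmC (1 + O/KmO) or X1 = J/4, X2 = 2 Gamma*. Defaults KmC = 26.7 Pa,
  KmO = 16.4 kPa, Sc/o = 2.6 kPa Pa-1, Gamma* = 0.5 O / (Sc/o). No
  smoothing is applied between the two branches: the limitation switch is
  pointwise, mirroring the discrete limitation states of the leaf-level
  model.
* The source injects Rd plus the photorespiratory release
  Rp = Gamma* * integral(w/C) uniformly into the active scenario's
  region. Rp depends on the solution, and is converged by damped
  fixed-point iteration together with the sink linearization.
* Triose-phosphate utilization is applied as a leaf-level cap
  AN <= 3 Tp - Rd on the reported assimilation, not as a local law; Tp
  only ever acts as a plateau in the data this model confronts. The
  plateau relation also fixes the estimator Tp = (Ap + Rd)/3 from the
  mean observed AN at the highest Ca (an alternative literal grouping
  Ap + Rd/3 is selectable in `tp_from_ap()`, but it is inconsistent with
  AN = 3 Tp - Rd and not used).

Boundary conditions: the airspace side is either held at a known Ci
(`ci_driven`, used for fitting against measured Ci and for simulating the
Laisk protocol) or coupled to an ambient pressure through a stomatal
conductance, AN = gs (Ca - Ci) (`ca_driven`, used by the data generator
and the response sweeps). All other outer boundaries are symmetry planes
or the tonoplast, all no-flux.

## Numerics

Cell-centered finite volumes on a structured mesh whose lines include
every layer boundary, harmonic averaging of diffusivity at faces, and
membrane permeabilities added as series resistances on their faces. The
Michaelis-Menten sink is iterated in frozen-coefficient form
k = w(C)/C — this keeps the operator an M-matrix, so the discrete field
stays positive — with damping 0.5 on both k and Rp. Convergence requires
|dAN| < 1e-6 umol m-2 s-1 *and* a settled sink coefficient (relative
change < 1e-6); the second condition matters when the sink is weak and AN
barely responds to it, where the AN test alone can trigger early. The
`ca_driven` stomatal balance is solved by Brent root bracketing on
Ci in [0, 1.5 Ca] (the widened bracket covers Ci > Ca, which occurs below
the light compensation point). Up to 200 iterations are allowed; a
converged solve closes its flux balance (boundary influx =
carboxylation - release) to ~1e-12 relative, and `flux_report()` audits
this.

The default mesh is 12 x 40 cells (rows allocated to layers in proportion
to thickness, at least two per layer); fitting loops use 8 x 24. A 2x
refinement moves AN by well under 0.5%. The 1D linear-sink solution is
verified against the closed-form cosh profile (second-order convergence).

**Reassimilated fraction.** The nonlinear solve cannot attribute flux by
origin, so `freass` uses the standard tagging construction: freeze the
converged first-order coefficient field k(x), release a tracer only at
the scenario source with magnitude Rp + Rd, hold the airspace at zero
tracer pressure, and measure what is consumed versus what escapes. The
same discrete problem sampled by random-walk particles (an independent
oracle in the test suite) agrees with the tracer to well under a percent.

**Apparent gm.** `gm = AN / (Ci - Cc)` with Cc defined as the stroma
volume-mean of the field. The averaging convention is a genuine choice —
a carboxylation-weighted mean would emphasize the upper stroma — and the
volume mean is used because it is the simplest reproducible convention;
gm is reported from the uncapped AN so that it always reflects the
diffusion field actually solved.

## Parameter estimation

The estimation pipeline mirrors standard practice:

1. `fit_calibration_s()`: s from the OLS slope of AN on Iinc*Phi2/4 over
   the nonphotorespiratory light curve (Iinc <= 150 umol m-2 s-1); the
   negated intercept of the same regression is the Yin estimate of Rd.
2. `fit_rd()`: 1D least squares over Rd in [0, 10], per scenario and per
   O2 regime, driving the solver `ci_driven` at the measured Ci of each
   low-light record with J = s * Iinc * Phi2. Measured Ci is preferred
   over the stomatal closure to avoid compounding stomatal-model error.
   The objective is evaluated with warm-started fields and minimized by
   bracketed Brent search (derivative-free: the objective is smooth but
   numerically noisy at the 1e-8 scale, which defeats finite-difference
   gradients); a grid check in the tests confirms unimodality. Standard
   errors come from Gaussian linearization, residual variance times the
   inverse curvature of the objective. No bootstrap by default.
3. `fit_vcmax()`: same machinery over Vcmax on the photorespiratory
   CO2-response records with Ca < 30 Pa (the Rubisco-limited wing), Rd
   held fixed.
4. `validate_model()`: prediction error on records not used by any fit.

PR and NPR fits never share records; fitting them separately (rather than
jointly) keeps the two regimes' Rd estimands distinct, which is the
quantity of interest here.

## The synthetic campaign generator

Real campaigns measure four curves: CO2 response at saturating light
(Iinc = 1500 umol m-2 s-1) under 21 and 2 kPa O2, and light response at
Ca = 40 Pa / 21 kPa and Ca = 100 Pa / 2 kPa. `synth_gas_exchange()`
reproduces these designs with known truth. Two sub-models supply what
instruments would measure:

* Phi2(Iinc) = phi2_max / (1 + Iinc/i_half), a declining hyperbola
  (defaults 0.8, 1000 umol m-2 s-1). With the default calibration
  s = 0.5 this gives J = 52.2, 36.4, 19.0, 9.8 umol m-2 s-1 at
  Iinc = 150, 100, 50, 25 — the standard low-light electron-transport
  ladder for tomato;
* gs(Iinc) = gs_min + (gs_max - gs_min) Iinc/(Iinc + i_g) (defaults 0.3,
  3.0 umol m-2 s-1 Pa-1, 200 umol m-2 s-1), low stomatal conductance at
  low light. Together with the finite mesophyll transport this produces
  the characteristic decline of Ci (and Cc) with irradiance at low light
  — precisely the feature the Kok and Yin regressions ignore.

Defaults: Rd_PR = 1.5, Rd_NPR = 1.2 umol m-2 s-1 (day respiration is
lower under 2 kPa O2), Vcmax = 120, Tp = 10 umol m-2 s-1, release in the
inner cytosol, Gaussian noise sd 0.15 umol m-2 s-1 on AN and 0.005 on
Phi2. One seed fixes a campaign bit-exactly. What the generator does not
emulate: instrument drift, leakage at low CO2, leaf-to-leaf anatomical
variation, and any light- or CO2-dependence of the release location —
so recovery tests demonstrate internal consistency of the estimation
machinery, not robustness to those real-world effects.

## What the model says about the three estimators

Running the generator and estimators together reproduces the qualitative
structure expected from the physics:

* **Kok < Yin < truth** under photorespiratory conditions. The Kok bias
  comes from the Phi2 decline; the residual Yin bias from the decline of
  Cc with irradiance and the reassimilation it implies. Under
  nonphotorespiratory conditions the Yin estimate agrees with truth.
* **Laisk behavior depends on the release location.** Simulated
  `ci_driven`, electron-transport-limited AN-Ci families
  (`simulate_laisk_family()`) show: for `outer` release the pairwise
  intersections do not coincide, sit above AN = -Rd, and drift to higher
  Ci for higher-irradiance pairs; for `inner` and `gaps` release the
  intersections cluster far more tightly and land near AN = -Rd. The
  clustering is approximate, not exact: at the intersection the release
  Rd + Rp must be carried across the stroma, so the crossing Ci inherits
  a drawdown of order (Rd + Rp) times the stroma transport resistance,
  and Rp grows with J. With the default constants this residual spread
  is a few tenths of a Pa; it would vanish only if stroma transport were
  much faster than any physically plausible parameterization allows.
  The dichotomy between scenarios is robust; the exact tightness of the
  inner/gaps intersection is parameter-dependent.
* **gm responses separate the scenarios.** Apparent gm falls with Ca for
  `inner` release, rises (to a plateau, with a slight dip once electron
  transport limits) for `gaps` and `outer`, is ordered
  inner > gaps > outer pointwise, and approaches a common high-Ca value
  across O2 regimes (within a few percent by Ca = 200 Pa).
* **freass** rises with irradiance in a saturation shape. With Ca it
  *falls* in this model: the tracer's absorption coefficient is
  w/C = X1_vol/(C + X2), which decreases as the field concentration
  rises, so a molecule released at high Ca is less likely to be fixed
  before escaping. Low-light freass for inner release (roughly 10-20%)
  is of the same order as the Yin method's underestimation of Rd — the
  mechanistic link between the two.
* **AIC ranking** (`delta_aic()`, least-squares form
  n ln(RSS/n) + 2K with K counting fitted parameters plus the residual
  variance, support threshold delta <= 2 inclusive; the small-sample
  AICc correction is not applied by default) recovers the generating
  scenario on synthetic data.

## Worked example

```{r example}
library(mesodiff)

truth <- synth_truth(seed = 7)
campaign <- synth_gas_exchange(truth, "all")

cal <- fit_calibration_s(campaign)
rd_fit <- fit_rd(campaign, "inner", "PR", vcmax = truth$vcmax,
                 tp = truth$tp, s_cal = cal$s_cal)
tidy(rd_fit)

yin_method(campaign[campaign$regime == "PR", ])
kok_method(campaign[campaign$regime == "PR", ])

sim <- simulate_laisk_family("inner", rd = rd_fit$estimate)
autoplot(sim)
```

## Known limitations

* Steady state only; no transients, no HCO3-/carbonic-anhydrase pool, no
  temperature dependence of the kinetic constants.
* 2D with a homogeneous third dimension and a single cell type; palisade
  vs spongy differences and 3D chloroplast shapes are out of scope.
* The transport constants are inputs; the model's absolute gm and freass
  inherit their uncertainty, though the scenario *contrasts* are much
  less sensitive to them.
* TPU is a reporting cap, not a local mechanism; simulations deep in the
  TPU region should be read with that in mind.
* The Kok-effect breakpoint below the light compensation point is not
  modeled; the default regression window [50, 150] umol m-2 s-1 simply
  avoids it.
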