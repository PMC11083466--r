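---
title: "A gas-mixing model of low-flow nasal cannula oxygen delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gas-mixing model of low-flow nasal cannula oxygen delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfncsim)
```

## The problem

When a small infant receives oxygen through a low-flow nasal cannula (LFNC,
gas flow at or below 2 L/min), the oxygen concentration that actually reaches
the lungs — the *effective FiO2* — is not the concentration of the supplied
gas. The cannula delivers a thin continuous stream; how much of it ends up in
a breath depends on tidal volume (VT), inspiratory time (Ti), respiratory
rate (RR), and on the oxygen that accumulates in the upper airway between
inspirations. Clinicians usually estimate the effective FiO2 from closed-form
formulas (Benaron–Benitz, which uses flow, VT and Ti; Finer, which uses flow
and minute ventilation MV = VT × RR), but VT and Ti cannot be measured at the
bedside, so the formulas are applied with fixed assumed values — the STOP-ROP
convention fixes Ti = 300 ms and VT = 5 mL/kg. `lfncsim` packages a
computational model of a mechanical infant breathing simulator to study how
well those estimators do, and to build lookup charts of effective FiO2 from
quantities that *are* available: cannula flow, infant weight and RR.

## The model

The simulator couples two gas compartments:

* an **upper-airway dead space** of volume $V_D$ (default 5.2 mL, the
  measured volume of an infant upper-airway replica), treated as a
  **plug-flow (FIFO) column**: gas parcels enter at one end and leave at the
  other in order, without longitudinal mixing. Plug flow is essential — it
  preserves the *front* of oxygen-rich gas stored near the nares during
  expiration, which a well-mixed reservoir would immediately dilute;
* a **well-mixed lung compartment** with residual volume $V_R$ (default
  30 mL) plus the piston displacement. With no gas exchange modelled, $V_R$
  affects only the wash-in transient, never the steady state (a property the
  test suite asserts to < 0.05 pp).

One breath is driven by a piston flow profile $Q(t)$. During inspiration the
lung draws gas through the column; the stream entering at the nares is pure
supply gas at rate $\min(F_c, Q)$ plus entrained room air (21% O2) at rate
$\max(Q - F_c, 0)$, where $F_c$ is the cannula flow. Whenever the airway flow
magnitude falls below $F_c$ — late expiration above all, when expiratory flow
decays to zero — the excess supply gas *flushes* the nares-end parcels:
resident gas is vented and replaced by supply gas at equal volume, the
replacement front advancing with the cumulative flushed volume. This flushed
oxygen is the upper-airway reservoir: it is the first gas drawn into the lung
on the next breath, which is why the effective FiO2 exceeds the
Benaron–Benitz prediction at low minute ventilation. Cannula-jet momentum
(which in a physical rig pushes supply gas deeper than equal-volume
replacement) and molecular diffusion along the airway are deliberately not
modelled; the consequences are quantified under *Limitations*.

The reading reported as effective FiO2 is the lung-compartment O2 fraction at
end-inspiration, matching an analyzer at the tip of the breathing syringe.

### Waveform

The piston profile is configurable:

* `half_sine` (default): $Q(t) = \frac{\pi}{2}\frac{V_T}{T}\sin(\pi t / T)$
  per phase. A velocity-ramped piston has near-zero flow at the phase
  boundaries, and near-zero end-expiratory flow is precisely what lets the
  cannula stock the upper airway — the reservoir effect disappears under
  profiles that keep expiratory flow high until the last instant.
* `square`: constant flow $V_T / T$. This is the degenerate profile under
  which (with zero dead space) the simulator must reproduce the
  Benaron–Benitz closed form exactly; the test suite uses it as an
  independent oracle over randomized scenarios, and agreement is at the
  10⁻¹¹ pp level.

The true velocity profile of the physical rig's stepper motor is not
published; `half_sine` is this package's assumption.

## Scenario grid and the feasibility window

The study protocol crosses VT ∈ {5, 10, 15, 20, 30, 40, 50, 60, 70, 80} mL,
RR ∈ {30, …, 80} breaths/min and Ti ∈ {300, 500, 700, 900} ms, keeping
combinations with positive expiratory time and a Ti/Te ratio inside
**[0.5, 1.5)**. The upper bound is treated as *exclusive*: with these grids
the single boundary case (RR 40, Ti 900, ratio exactly 1.5) would otherwise
enter, and the protocol total would be 1320 rather than the canonical 1200
runs (100 scenarios × 4 flows × triplicate). Retained scenarios span MV
150–6400 mL/min with both endpoints attained. Scenario ordering is fixed
(VT-major, then RR, then Ti) so that all outputs are byte-stable.

## Rig geometry details

* **Dead-space adjustment by VT** (`effective_dead_space()`): below 10 mL a
  1-mL rod reduces the reservoir to 4.2 mL; between 10 and 50 mL the base
  5.2 mL applies; above 50 mL an expandable extension is modelled as
  $V_D = \max(5.2, 0.10 \times V_T)$ mL. The 10%-of-VT rule mirrors the
  anatomical proportionality of dead space to body size; the exact extension
  volumes of the physical rig are not published, so the rule is exposed as
  configuration rather than hard-coded.
* **Parcel granularity**: the column is discretised into `n_cells` = 50
  parcels (granularity $V_D/50 \approx 0.1$ mL). Because advection is
  Lagrangian (parcels move, they are not remapped onto a grid) there is no
  numerical diffusion; the granularity only sets the mixing scale at the
  forming end of the column and the resolution of the flush front.

## Numerical choices

* **Time step** `dt_ms` = 1 ms, with the guard `dt ≤ Ti/10`. Per-step
  displaced volumes are computed from the closed-form integral of the flow
  profile, so tidal volume is conserved to machine precision; O2 bookkeeping
  (lung + column + vented − supplied − entrained) is asserted to stay within
  10⁻⁹ relative at every step. Halving `dt` moves steady-state FiO2 by less
  than 0.01 pp.
* **Convergence**: a run stops when the end-inspiratory reading changes by
  less than `tol_pp` = 0.01 pp for three consecutive breaths (cap 500
  breaths, flagged unconverged beyond). Because the wash-in approaches its
  fixed point geometrically, the reported steady state adds the Aitken
  extrapolation of the remaining tail; this makes the value insensitive
  (< 10⁻⁶ pp) to the lung residual volume, which only sets the approach
  rate.
* **Power-law fit** (`fit_power_law()`): FiO2(MV) = 21 + k·MV⁻ᵃ is fitted by
  bounded Levenberg–Marquardt least squares in the *original* residual space
  (R² is reported on FiO2, so the objective must live there too), with
  k ∈ (0, 10⁷], a ∈ (0, 5]. Log–log regression of (FiO2 − 21) on MV provides
  the starting values; points within 0.05 pp of the 21% floor are excluded
  from that initialisation (their logs are unstable) but retained in the
  nonlinear objective. Replicates are averaged per cell before fitting,
  matching a protocol that records the mean of three experiments.
* **Rank-sum test** (`rank_sum_test()`): midranks for ties; exact two-sided
  p by enumeration of all group assignments when n₁ + n₂ ≤ 12, else the
  normal approximation with tie and continuity corrections. The exact path
  is verified against an independent brute-force enumeration for every
  sample-size pair with n₁ + n₂ ≤ 8, and against `wilcox.test` in its
  comparable regimes.
* **Threshold scan** (`bias_threshold_summary()`): bias is binned at the
  exact grid MVs (no smoothing); for each flow and tolerance the summary
  reports the smallest grid MV above which every bin's |mean bias| is below
  tolerance, `NA`/`"none"` when even the largest-MV bin fails, and the
  smallest grid MV when nothing fails.

## Predictive charts

`build_chart()` maps (weight, RR) to effective FiO2 at a fixed
weight-normalised VT (5 or 7.5 mL/kg) and one cannula flow. RR determines the
feasible Ti set through the same [0.5, 1.5) window (RR 30 → {700, 900};
RR 60 → {500}; RR 80 → {300}); a chart cell is the *mean* of the simulated
steady states over that set. How the original protocol combined several
feasible Ti values into one chart value is not stated; averaging is this
package's choice, and at the RRs where only one Ti is feasible the cell
equals the single simulation exactly (a consistency the tests assert). Cells
whose VT would exceed 30 mL (MV 2400 mL/min) are left absent rather than
extrapolated — the underlying protocol was not validated beyond that range.
Charts assume a 100% oxygen supply; for a blender set below 100%,
`blender_corrected_fio2()` rescales a chart cell linearly about the room-air
point 21.

## What the synthetic data do and do not emulate

`generate_dataset()` reproduces the protocol's *structure*: the full
feasible grid, four flows (0.1, 0.3, 0.5, 1 L/min) at 100% oxygen,
triplicates with Gaussian measurement noise of SD 0.15 pp (the replicate
SDs printed for the bench are 0.1–0.2 pp), clipped to [21, 100], fully
reproducible from one integer seed. It does **not** emulate breath-to-breath
variability (parameters are constant within a run), gas exchange and oxygen
consumption (absent from the bench as well; literature estimates the
resulting bias at 0.7–1.6%), humidity or temperature effects, or nasal-prong
leak and jet geometry. Tests passing on these data therefore validate the
model's internal physics and the analysis pipeline — not the absolute
accuracy of any single bench reading.

## Limitations

The model's only oxygen-enrichment pathways are the equal-volume flush and
the low-flow inspiratory phases. An oxygen balance over one steady-state
breath at the lowest-MV scenario (VT 5 mL, Ti 900 ms, RR 30, 0.1 L/min)
shows these contribute ≈ 0.48 mL O2 per breath, which yields ≈ 58% effective
FiO2 — whereas the corresponding physical-rig reading is 65.7%, implying
≈ 0.57 mL per breath. The missing ≈ 0.09 mL is consistent with cannula-jet
penetration and molecular diffusion, both outside this model's scope. The
consequence is a conservative reservoir effect: simulated FiO2 at very low
MV underestimates a physical rig by several percentage points, while the
qualitative structure — the direction and MV-dependence of each formula's
bias, the Ti and VT effects, the power-law relationship and its
deterioration at high flow — is unaffected. Chart values at the lowest RR
and weight combinations inherit the same conservatism.

## Problem sizes

The examples and tests in this package simulate the full 100-scenario grid
where the analysis needs it (power-law fitting, bias evaluation: 1200
replicate rows, a few seconds of compute) and purpose-built small grids
everywhere else; the property checks (oracle equivalence, conservation,
monotonicity) use 20–30 randomized or structured scenarios per run.
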