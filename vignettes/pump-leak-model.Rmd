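---
title: "The pump-leak flux-balance model behind ionflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pump-leak flux-balance model behind ionflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionflux)
```

## The model

ionflux simulates the monovalent-ion economy of a whole animal cell — the
classic pump-leak balance extended with Li⁺ and with one-for-one coupled
self-exchange. Four ion species (Na⁺, K⁺, Li⁺, Cl⁻) move across the plasma
membrane through a reduced set of thermodynamically defined pathways, each
characterised by a single rate coefficient:

* **Electroconductive channels.** Goldman constant-field fluxes. With the
  dimensionless potential $u = FU/RT$ ($U = 26.7\,u$ mV at 37 °C) and
  $g = 1 - e^u$, the net inward cation flux is
  $p\,u\,([C]_i e^u - [C]_o)/g$ and the net inward anion (Cl⁻) flux is
  $p\,u\,([Cl]_i - [Cl]_o e^u)/g$. Both tend to $p([C]_o - [C]_i)$ as
  $u \to 0$.
* **The Na/K (and Li/K) ATPase pump.** Na⁺ efflux $-\beta[Na]_i$, Li⁺ efflux
  $-\alpha[Li]_i$, K⁺ influx $(\beta[Na]_i + \alpha[Li]_i)/\gamma$ with
  stoichiometry $\gamma = 1.5$ (3 Na out : 2 K in).
* **Electroneutral cotransport** (NC, KC, LC, NKCC, LKCC): mass-action
  bilinear fluxes in the inside/outside concentration products, e.g.
  $J_{NC} = i_{NC}([Na]_o[Cl]_o - [Na]_i[Cl]_i)$, and the quadruple products
  for NKCC/LKCC with Cl⁻ carried twice.
* **Li/Na countertransport** $J_{LN} = k_P([Na]_o[Li]_i - [Na]_i[Li]_o)$,
  positive when Na⁺ enters and Li⁺ leaves — the secondary active Li⁺
  extrusion route. The same product form with a `kpNa` (or `kpCl`)
  coefficient describes Na/Na (Cl/Cl) self-exchange, which moves equal
  amounts in both directions: it contributes to tracer turnover but never to
  a net flux.

Saturation kinetics are deliberately ignored — every pathway is linear in its
driving concentration products — and Ca²⁺/Mg²⁺ and pH dynamics are out of
scope. Osmotic coefficients are taken as 1.

Two algebraic constraints close the system. Macroscopic electroneutrality,

$$[Na]_i + [K]_i + [Li]_i - [Cl]_i + z\,A/V = 0,$$

and osmotic balance,

$$S_o = [Na]_i + [K]_i + [Li]_i + [Cl]_i + A/V,$$

where $A$ is the amount of membrane-impermeant intracellular osmolytes with
mean valence $z$, $V$ the cell water volume, and $S_o$ the total external
osmolarity. Both $z$ and $A$ are fixed properties of the cell: they are
computed once from the initial concentrations,

$$z = \frac{[Cl]_i - [Na]_i - [K]_i - [Li]_i}
           {S_o - [Na]_i - [K]_i - [Li]_i - [Cl]_i},$$

and never updated during a run. $A$ is normalised to 1 mmol — only $V/A$ and
$A/V$ are physically meaningful, which is why results report cell water as
$(V/A)\times 1000$. A non-positive denominator above means the stated cell
cannot exist in the stated medium; `initial_state()` then fails with the
diagnostic `BAD INITIAL DATA`.

### The membrane potential

Summing the four content-balance equations with charge signs, all
electroneutral cotransporters cancel and the requirement that total charge
flux vanish yields one transcendental equation for $u$. The textbook form of
that equation divides the electrogenic pump term by $u$ and is singular at
$u = 0$; ionflux instead solves the equivalent total-charge-flux form
(channel terms of all four ions plus the pump term), which is finite
everywhere, with a series continuation of $u/g$ for $|u| < 10^{-6}$. The two
forms have identical roots. The root is bracketed by a 200-interval sign
scan over the physiological window $U \in [-173, +5]$ mV and refined by
Brent's method (`stats::uniroot`, tolerance $10^{-13}$ on $u$, i.e. well
below $10^{-9}$ mV); during integration a secant iteration warm-started from
the previous step's root replaces the scan and almost always converges in
two or three evaluations. If no sign change exists in the window the run
stops with `RANGE LIMIT`. For every parameter set shipped with the package
the root is unique in the window (the test suite re-checks this with a
401-point scan).

### Integration

`simulate_system()` advances the four ion *contents* ($[X]_i V$, per unit
$A$) by the explicit Euler method with a default step of 0.1 min. The step
size comes from the reference output schedule: results are printed every
`hp = 500` steps and the printed rows advance 50 min, fixing 0.1 min/step.
Each step (1) solves the potential, (2) updates the contents from the flux
sums, (3) recomputes the volume algebraically from the osmotic constraint
$V = (\text{total ion content} + A)/S_o$, and (4) recovers concentrations
from contents. Because the potential zeroes the signed flux sum, the total
intracellular charge content is conserved to root tolerance at every step —
electroneutrality is maintained automatically and nothing is ever
renormalised. The test suite verifies conservation to better than $10^{-6}$
relative over full runs and exact osmotic balance on every output row, and
that halving `dt` moves the balanced concentrations by less than 0.01 mM.

A run is *balanced* when every per-step concentration derivative falls below
`balance_tol` (default 0.005 mM/min, matching the size of the derivatives in
the final printed rows of the reference run). Two readings of the derivative
columns are possible — instantaneous rates and per-output finite differences
— and they differ visibly early in a transient; the trajectory reports the
per-step finite differences at the output instant, while
`content_derivatives()` exposes the instantaneous right-hand sides, so both
are available and neither is asserted against the other.

Three diagnostics reproduce the historical tool's wording: `BAD INITIAL
DATA` (constraint-incompatible start), `RANGE LIMIT` (potential root outside
the window) and `LOW SODIUM` (internal Na⁺ below 0.1 mM, where the pump-leak
description stops being meaningful). All three carry condition classes and
the simulation time of the failure.

### Medium changes and the kv shift

A cell previously balanced with an old medium and dropped into a new one of
different osmolarity exchanges water in seconds — effectively instantly on
the minutes scale of the ion fluxes. The parameter `kv` (new-to-old external
osmolarity ratio) implements this: at initialization all internal
concentrations are multiplied by `kv`. Chained protocols (drug washout,
return to a Na⁺ medium) are modelled by `continue_datap()`, which seeds a
fresh parameter set from a run's final state and computes `kv` from the two
media. The Li-series media are built by `datap_li_medium()`: adding $X$ mM
LiCl to Li-free RPMI (310 mOsm: 140 Na, 5.8 K, 116 Cl, 48.2 impermeant)
gives `l0 = X`, `cl0 = 116 + X` and `kv = (310 + 2X)/310`; at $X = 5$ this
reproduces the reference set's `cl0 = 121`, `kv = 1.032`.

## Unidirectional decomposition and derived indices

Every pathway flux is the difference of two non-negative unidirectional
terms, and the decomposition simply reports those two terms: for channels
the two additive parts of the constant-field expression (influx
$-p\,u\,[C]_o/g$, efflux $p\,u\,e^u[C]_i/g$ for cations, mirrored for Cl⁻);
for co/countertransporters the outward-product and inward-product terms;
for the pump a pure efflux (Na⁺, Li⁺) or influx (K⁺). The channel split is
not spelled out in words anywhere in the source material, but the published
flux matrix forces it: no other additive split reproduces the printed
influx/efflux entries. Within every ion × pathway cell
`influx + efflux = net` holds exactly.

From the table follow OSOR (pump K⁺ influx over the summed ouabain-resistant
K⁺ influxes), per-ion turnover fluxes (all unidirectional influxes plus any
coupled self-exchange), tracer equilibration rates `turnover / [X]_i`, and
the Li/Na discrimination coefficient
$c_d = ([Li]_i/[Na]_i)\,([Na]_o/[Li]_o)$, a water-content-free ratio of
ratios. A `kpCl` hook exists for Cl/Cl exchange but no default value is
shipped: the package only reproduces quantities that its own computations
can support.

## Tracer kinetics

`simulate_tracer()` places an isotope or analogue in the "Li slot" of the
model: a channel permeability, a Cl-coupled cotransport coefficient, a pump
coefficient and an exchange coefficient against Na⁺. At trace level the
background cell cannot be perturbed, so the default mode clamps the
background at its balanced state, making the tracer equation linear with an
exactly monoexponential solution — numerically cleaner than re-running the
full model, with which it agrees at trace loads (a cross-validation mode
integrates the full system instead; the two agree within a few per cent,
the residual difference coming from the full model's background drift when
the true Li⁺ pool is replaced by the tracer). Whether the tracer slot
should carry the pump coefficient is exposed as an option
(`tracer_na(pump = "beta")` or `"none"`), since the ²²Na view of the Na⁺
carrier includes the pump while a pure analogue may not.

Rate coefficients are fitted as in the wet-lab protocol:
$y_t = y_0 e^{-kt}$ for loss (log-linear least squares) and
$y_t = y_\infty(1 - e^{-kt})$ for gain (nonlinear least squares via
`minpack.lm::nlsLM`, seeded log-linearly); the classic three-point 5/10/20
min design is sufficient. `estimate_kpna()` inverts the tracer rate for the
coupled-exchange coefficient by Brent root refinement to $10^{-6}$; a target
rate below the no-exchange rate is a hard error, because the observed
turnover is then already explained.

## The inverse problem

`fit_balanced()` minimises the sum of squared *relative* residuals between a
forward run's balanced observables (`na`, `k`, `l`, `cl`, `VA1000`, `OSOR`,
`U`; OSOR weighted like any other) over chosen free coefficients, with a
Nelder–Mead simplex on multiplier space, bound clipping, and relative
tolerance $10^{-4}$ (Brent's method for a single free parameter). The
forward map is smooth and low-dimensional, so a derivative-free local method
suffices; failed forward runs return a large sentinel residual so the
simplex backs away.

Identifiability deserves care. At a fixed balanced state the steady-state
equations are *linear* in the rate coefficients, so counting constraints
tells you exactly what a balanced state can determine. The Na⁺ and Cl⁻
balance rows provide only two constraints for the trio (`pna`, `pcl`,
`inc`): fitting all three together with `inc` free leaves an exact
one-dimensional flat manifold, on which the optimizer will happily park at
parameters far from the truth while reproducing every target. The
parameter-recovery tests therefore free the identifiable subset
(`pna`, `pk`, `pcl` with `inc` fixed), which recovers within a few per
cent. The same degeneracy appears for (`ilc`, `kp`) against the balanced
Li⁺ level alone — many pairs give the same $[Li]_i$ — and is broken by the
transient Li⁺ curve: `resolve_ilc_kp()` fits both simultaneously to the
balanced target plus kinetic points and round-trips synthetic truths within
5% (typically 0.1%). Called without a curve it refuses to guess and flags
the fit non-identifiable.

One empirical sign surprised us and is worth recording: raising the K⁺
channel permeability `pk` *hyperpolarises* the cell, which raises Na⁺ entry
and with it the pump's K⁺ influx, so the balanced $[K]_i$ creeps slightly
*up*, not down. The robust monotone statements — verified in the tests — are
that `pk` lowers the K:Na concentration ratio and the potential, `pna`
raises $[Na]_i$, `ilc` raises $c_d$ and `kp` lowers it.

## Reproduction protocol and problem sizes

All headline numbers are recomputed by `scripts/acceptance.R` and by the
acceptance tests using one fixed protocol: explicit Euler, `dt = 0.1` min,
500 simulated minutes (5000 steps) from the kv-adjusted initial state. The
500-min horizon is the reference schedule itself (`hp = 500` output steps of
0.1 min between rows, ten output rows); it matters for the Li-series
predictions, which are quoted at that schedule rather than at the
mathematical steady state — at 10 mM external Li⁺ with `ilc = 0.00042` the
fully converged discrimination coefficient is 3.541, while the 500-min value
is 3.571. The package reports whatever horizon you ask for;
`stop_when_balanced` with the default tolerance reproduces the practical
convention of stopping when the derivatives fall below 0.005 mM/min.

Property-style tests use deliberately modest problem sizes chosen to probe
each invariant without redundancy: three initial states for the
uniqueness-of-balance check (constructed to share $z$ and $S_o$ exactly),
two perturbed starts for parameter recovery, two synthetic truths for the
(`ilc`, `kp`) round trip, twenty random water-rescaling draws for the $c_d$
invariance. All randomness is under fixed seeds.

## What the fixtures do and do not show

The shipped parameter sets emulate a lymphoid cell line balanced in RPMI
with 0–10 mM LiCl, pump blockade, full Na⁺→Li⁺ medium substitution and
Li⁺-preload recovery. They are point parameterisations of real experiments,
not samples from biological variability: passing tests show that the flux
laws, constraints and numerics reproduce the published behaviour of this
cell type at these operating points. They do not show that the rate
coefficients transfer to other cell types, that the linear (non-saturating)
pathway laws hold far outside the physiological concentration range, or
that parameters stay constant under interventions that remodel transporter
expression. The model also deliberately omits pH- and Ca²⁺-coupled
regulation; where those dominate (e.g. strong NHE activation), a
constant-coefficient fit will drift.

## Known limitations

* Explicit Euler with algebraic closures is first-order; the default step
  is safe for the shipped coefficients, but very stiff parameter choices
  (coefficients orders of magnitude above physiological) can destabilise a
  run — the integrator then stops with a clear numerical-failure error
  rather than silently losing the constraints.
* The balanced state identifies only combinations of coefficients (see the
  inverse-problem section); experimental designs needing individual
  coefficients must add kinetic or inhibitor-sensitivity information.
* Temperature is fixed at 37 °C ($RT/F = 26.7$ mV) and is not configurable
  in this version.
* `hp` doubles as the historical layout's output interval and, via the
  0.1-min step, the run duration in minutes of the standard schedule; the
  original tool's exact stopping rule is not documented, so both a
  derivative criterion and fixed horizons are offered.
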