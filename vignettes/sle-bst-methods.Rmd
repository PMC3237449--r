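---
title: "Power-law modeling of the yeast sphingolipid-ergosterol network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-law modeling of the yeast sphingolipid-ergosterol network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleBST)
```

## The modeling framework

sleBST implements Biochemical Systems Theory (BST) for metabolic networks.
Every process rate is a power law

$$v_k = \gamma_k \prod_j X_j^{f_{kj}},$$

with a positive rate constant $\gamma_k$ and real kinetic orders $f_{kj}$
that quantify the strength and direction of each variable's influence
(negative orders encode inhibition; non-integer orders arise naturally for
reactions in crowded membrane environments). Two canonical formats are used
for different jobs:

* **GMA (generalized mass action)** keeps one power-law term per physical
  flux, so the equations read
  $\dot X_i = \sum_k s_{ik} c_{ik} v_k$ with signs $s_{ik}$ and
  stoichiometric coefficients $c_{ik}$. This is the format integrated in
  time ([`simulate_gma()`]); fluxes shared between equations are recorded by
  a common `flux_id` and validated for consistency.
* **S-system** aggregates, per pool, all influxes into a single power law
  $\alpha_i \prod X_j^{g_{ij}}$ and all effluxes into
  $\beta_i \prod X_j^{h_{ij}}$ ([`as_ssystem()`]). The aggregation is the
  standard operating-point method: kinetic orders are flux-weighted averages,
  e.g. $g_{ij} = \sum_k v_{ik} f_{ikj} / \sum_k v_{ik}$ over influx terms,
  and $\alpha_i$ matches the summed GMA influx at the operating point. This
  construction preserves both the fluxes and the Jacobian at the operating
  point, which is why the S-system is the right tool for local diagnostics.

At a steady state the S-system is linear in logarithmic coordinates:
$A_D y_D = b - A_I y_I$ with $A = G - H$, $y = \ln X$ and
$b_i = \ln(\beta_i/\alpha_i)$. From that linear system the package derives,
in closed form,

* the steady state itself (`steady_state_log()`),
* local stability from the eigenvalues of
  $J_{ij} = V_i^\ast (g_{ij}-h_{ij})/X_j^\ast$ (`stability_eigenvalues()`),
* logarithmic gains $L(X, X_I) = -A_D^{-1} A_I$, rate-constant
  sensitivities $S(X,\beta) = A_D^{-1} = -S(X,\alpha)$, and the
  corresponding flux matrices (`sensitivity_report()`).

A dedicated test verifies the analytic Jacobian against central finite
differences of the raw GMA right-hand side, and the log gains against a 1%
multiplicative perturbation with the perturbed steady state re-found by
long-time integration — an oracle independent of the linear algebra.

## Tracer bookkeeping

Radioactive-label experiments are simulated by splitting every dependent
pool $X_i$ into labeled and unlabeled twins, $X_i = L_i + U_i$
(`split_labels()`). The committed semantics are:

* kinetics always see total pools, so summed twin dynamics are term-by-term
  identical to the base model (asserted to integrator accuracy in the test
  suite);
* mass *leaving* a pool carries that pool's current label fraction;
* mass *arriving* through a flux is labeled according to the flux's donors
  (`labeling_map()`): with donor fractions $f_d$ the labeled share is
  $1 - \prod_d (1 - f_d)$; `"unlabeled"` fluxes deliver no label; `"blocked"`
  fluxes move mass normally but deliver it unlabeled (label discarded at
  that step);
* a pool holding nothing has label fraction 0 (the 0/0 convention).

For steryl-ester synthesis the acyl co-substrate (palmitoyl-CoA) is by
default *not* a label donor, matching the experimental convention in which
ester counts are corrected down to the sterol moiety by the carbon ratio
27/43; `cpm_corrected_esters()` applies that factor only in the alternate
`acyl = "donor"` mode, where the simulated signal genuinely contains acyl
label.

## The synthetic SL-E model

The shipped model (`sle_model()`, plain-text copies under
`inst/extdata/sle_synthetic_*.plas`) is a **synthetic reconstruction** of the
integrated sphingolipid-ergosterol network of *S. cerevisiae*: 41 dependent
pools (sphingolipid intermediates and complex sphingolipids X1-X25,
sterol-pathway pools X25-X40, internal and external acetate), and
independent enzyme activities including IPC synthase (X133), ceramide
synthase (X134), SPT (X157), thiolase/HMG-CoA synthase (X171), HMG-CoA
reductase (X172), the steryl-ester synthases (X181, X183) and the PM ester
hydrolase Yeh2p (X182).

Constraints fixed exactly at construction:

* basal sterol distribution on the %-of-wild-type-total-sterols scale:
  X32 = 9.51, X36 = 4.75, X37 = 42.80, X39 = 47.55; lanosterol + zymosterol
  carry the remaining 8.30 (split evenly — no published split exists);
* complex sphingolipids at 1.02 (IPC), 1.40 (MIPC), 0.085 (M(IP)2C) mol%;
* the outer PM leaflet splits 9:1 between raft-associated (X37) and free
  (X36) ergosterol; the lipid-particle ergosteryl esters split 10:1 between
  bulk (X35) and PM-associated (X40) sub-pools;
* acetate uptake is first order with rate constant 0.0022/min acting on the
  93% undissociated fraction of external acetate (0.25575 uM/min at the
  125 uM basal concentration);
* the raft association flux v36,37 carries a fractal kinetic order (0.67 on
  X36) and a square-root dependence on PM IPC, encoding the co-dependence of
  raft ergosterol on complex sphingolipids;
* vesicular (v32,37 / v37,32) and non-vesicular (v32,39 / v39,32) transport
  are first-order mass action; the vesicular pair carries about 2% of the
  total forward-backward ergosterol flux;
* ergosterol feeds back on the thiolase step (order -0.5), giving the sterol
  branch its homeostasis;
* the entire Yeh2p ester-hydrolysis flux (v40,39) is routed to the
  inner-leaflet pool X39.

All remaining kinetic orders follow BST conventions chosen once: 0.5 for
substrates of enzyme-catalyzed steps, 1 for enzyme activities and for
transport/dilution, -0.5 for the feedback. Rate constants are then *solved*
so the declared basal state is an exact steady state (the constructor
asserts residuals below 1e-9 relative). Basal concentrations for pools with
no published value (the uM-scale precursors) are plausible literature-scale
choices fixed once; sterol pools live on a scale where the wild-type total
sterol reference equals 100, so basal values read directly as percentages
and `percent_total_sterols()` divides by that *fixed* reference (it is never
re-normalized per condition, which is why aggregate entries can exceed 100).

### The two variants and flux balancing

The **dynamic** variant carries net forward transport toward the plasma
membrane and the lipid particles, compensated by first-order growth-dilution
effluxes on the membrane pools — the exponential-growth picture used for
tracer simulations. The **balanced** variant describes a non-growing
population: `balance_fluxes()` raises each bidirectional pair's backward
rate constant until the pair is equilibrated at basal, removes all terms
tagged `growth` plus the Yeh2p flux v40,39 (its hydrolase is inactive under
the conditions of the total-mass experiments), and re-absorbs the remaining
per-pool residuals into designated slack fluxes (terminal drains and the
main sterol chain), sweeping until the basal state is again an exact steady
state. The shipped balanced variant *is* this operation applied to the
dynamic variant, so cross-variant consistency holds by construction; the
operation itself is exercised on independent toy models in the tests.

### Experiment timing

Knockdowns scale an enzyme activity at t = 0; the tracer perturbation fires
at t = 1 min — the inhibitor is assumed to need one minute to reach its
target. A bolus replaces the external acetate pool's content with labeled
acetate; a pulse-chase additionally washes the external pool with fresh
unlabeled medium (label to zero, total restored) after the 30-min default
pulse. External acetate is itself a dependent pool with a constant medium
feed and a first-order disappearance flux (turnover ~ 100 min), so external
label decays exponentially over the several-hundred-minute horizon of the
experiments; the decay constant is a construction-time choice, since no
published value exists.

## The synthetic fixture generator

`generate_gma()` produces random GMA networks of the same mathematical class
as the SL-E model — 1 to ~40 pools, 1-3 variables per flux, kinetic orders
in [-1, 2], a designated strictly positive steady state — by the
reverse-engineering trick: draw the network and the target state, then solve
the influx rate constants so the target is an exact steady state, and reject
candidates whose S-system eigenvalues are not all in the left half plane.
The seed fully determines the model. `generate_labeled_chain()` builds
linear source-to-product chains whose label fractions have closed-form
solutions ($f(t) = 1 - e^{-kt}$ for one pool; the distinct-rate convolution
formula in general), used as exact oracles for the tracer machinery.

What the fixtures deliberately do **not** emulate: SL-E biology (feedback
placement, conserved moieties, flux couplings across equations), multiple
steady states, or the stiffness profile of the full network. Passing
property tests on fixtures therefore demonstrates the correctness of the
numerics and bookkeeping, not the biological adequacy of any particular
model.

## Numerical choices

* Integration: `deSolve::ode` with `lsoda` (stiff-capable, adaptive),
  rtol 1e-8, atol 1e-10 scaled per state by its basal value. Interventions
  split the horizon into segments and restart the integrator at each
  discontinuity; no interpolation across events. Halving the tolerances
  moves reported pool values by far less than 0.1% (tested).
* Positivity: states dipping below 1e-12 x basal are clamped to that floor
  (power laws with negative exponents blow up at zero; concentrations cannot
  be negative); the plain engine warns when this happens, the label engine
  clamps the individual twins at zero silently since a label half touching
  zero is normal bookkeeping.
* Output grid: 1-min resolution by default; total-mass tables read states at
  60 and 120 min and report fold changes rounded to 2 decimals (raw values
  are returned alongside).
* Ties in the log-gain ranking break by variable declaration order; the
  "magnitude greater than one" threshold mirrors the reporting convention
  for such tables.
* Problem sizes in the tests were chosen for tight feedback loops during
  development: property sweeps run 20 seeded fixtures of 6-10 pools, chains
  of 2-5 pools, and the full 41-pool model; the whole suite completes in
  well under a minute.

## Known limitations

* **The parameterization is synthetic.** The published rate constants and
  kinetic orders of the original SL-E model live in supplementary material
  that is not part of this package's sources; only the basal state, the
  topology, and a handful of constants are published in the main text and
  are honored exactly. Consequently the *directions* of all perturbation
  responses reproduce (raft ergosterol and complex sphingolipids fall under
  SPT/IPC-synthase inhibition, free ergosterol sub-pools and esters rise,
  ceramide-synthase inhibition is the mildest of the three), but the
  *magnitudes* do not match the published fold changes: complex
  sphingolipids in this reconstruction turn over in tens of minutes and
  collapse almost completely within 60 min of a 99% SPT block, where the
  published model loses only about half, and the raft pool consequently
  overshoots its published 26-55% decreases. The acceptance suite asserts
  the published numbers at their stated tolerances and those assertions are
  expected to fail for this parameterization; they document the distance,
  they are not evidence of a numerical defect (every machinery-level oracle
  is exact).
* No positional isotopomers: label bookkeeping is pool-fraction level only.
* No vacuolar/endosomal/mitochondrial sterol pools beyond a single drain
  flux, no inner-leaflet microdomain compartment, no delay or stochastic
  terms, and no general SBML kinetics import.
* Fold-change tables assume the wild-type basal state as the reference
  denominator; experiments on strains with a different basal lipidome would
  need a recalibrated reference.
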