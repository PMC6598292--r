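---
title: "Proton and charge balance in constraint-based C4 plant models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton and charge balance in constraint-based C4 plant models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4balance)
```

## The modelling problem

Flux balance analysis (FBA) predicts steady-state reaction fluxes $v$ of a
stoichiometric network from the linear program

$$\min_v\; c^\top v \quad \text{s.t.}\quad S\,v = 0,\; l \le v \le u,$$

where $S$ is the stoichiometric matrix. Most published plant models are
*mass*-consistent but silently create or destroy *charge*, because
metabolites are entered without their dominant protonation state. In a
charge-sloppy model the proton is just another metabolite; in a fully mass-
and charge-balanced model, proton and charge bookkeeping become hard
constraints that propagate all the way to the plant's mineral nutrition:
taking up a cation (NH$_4^+$) or an anion (NO$_3^-$) changes the net charge
of the system, and at steady state that charge has to go somewhere.

This package provides the machinery to build and interrogate such models
for C4 plants (NADP-malic-enzyme subtype): a balance/energy-leak curation
battery, mesophyll (MP) / bundle-sheath (BS) / stem (ST) multi-tissue
assembly, lexicographic photon-minimising FBA, and a scenario suite built
around the *proton balance* condition $P_B$ — no H$^+$ exchange with the
environment, so all internal proton production and consumption must cancel.

Because the curated genome-scale model this machinery targets is
distributed as journal supplementary material and cannot be shipped here,
the package also generates a **synthetic C4 core model** whose behaviour
under these constraints is known analytically. The core is not a toy
placeholder: it is first-class, tested code, and every scientific claim the
test suite makes is a theorem about its stoichiometry.

## The synthetic core

`generate_core_model()` builds a single cell with five compartments
(cytosol `_c`, plastid `_p`, mitochondrion `_m`, peroxisome `_x`, vacuole
`_v`) and the classic boundary layout: ten `_tx` exchanges (photon, CO$_2$,
O$_2$, H$_2$O, H$^+$, NH$_4^+$, NO$_3^-$, SO$_4^{2-}$, P$_i$, plus
glucose/sucrose for heterotrophy), generic ATPase and NADPH-oxidase
maintenance pseudo-reactions, and one `_biomass` sink per biomass
component. All species carry real formulas and charges
(ATP$^{4-}$, NADPH$^{4-}$, 3-PGA$^{3-}$, ...), and the generator re-verifies
every internal reaction for elemental and charge balance before returning.

The physiology folded into the lumped reactions:

* **Light module.** Linear electron flow produces 2 NADPH per 8 photons and
  *releases* 2 stromal H$^+$; cyclic electron flow produces ATP at 4
  photons each and *consumes* 1 H$^+$ (the chemistry of
  ADP$^{3-}$ + P$_i^{2-}$ + H$^+$ → ATP$^{4-}$). A plastoquinone pool with
  an NADPH dehydrogenase and a plastoquinol terminal oxidase provides the
  chlororespiratory valve that the lignocellulose scenarios block.
* **Calvin–Benson cycle** with explicit RuBP regeneration and an oxygenase
  branch; the photorespiratory product is oxidised fully in the peroxisome
  (no carbon salvage — a deliberate simplification, see *Limitations*).
* **C4 module:** cytosolic PEP carboxylase, plastidial NADP-malate
  dehydrogenase and NADP-malic enzyme, PPDK, plus the cytosolic NADP-ME,
  mitochondrial NAD-ME and PEPCK isoforms whose blocking defines the
  NADP-ME subtype in the scenarios.
* **Nitrogen and sulfur:** nitrate reduction costs 4 NADPH before the
  shared amination step, so ammonium is the energetically cheaper sole
  source; sulfate assimilation feeds a neutral cysteine analog.
* **Respiration:** matrix TCA/oxidative phosphorylation, an external NADH
  dehydrogenase, and an alternative oxidase (AOX) that dissipates excess
  reducing power without ATP — the overflow valve real plant mitochondria
  use.
* **Filler layer:** seeded, balanced, dead-end condensates emulate the
  blocked periphery every real reconstruction carries; they are exercised
  by the blocked-reaction detector, never by the scenarios.

### The nitrogen-uptake oracle

One biomass unit drains $n_N$ mol nitrogen and $c_{bio}$ net elementary
charges through its composition (anionic aspartate-like, cationic and
neutral amino-acid components, glucan, optional cysteine). Summing the
charge column of $S^\top v = 0$ over a feasible flux vector, every
*internal* (balanced) reaction cancels, leaving only boundary terms: with
uptakes $a$ (NH$_4^+$), $b$ (NO$_3^-$) and $s$ (SO$_4^{2-}$),

$$a - b - 2s = c_{bio}\, v_{bio}, \qquad a + b = n_N\, v_{bio},$$

so under $P_B$ the co-uptake ratio is forced to

$$\frac{a}{b} \;=\; \frac{n_N + c_{\mathrm{eff}}}{n_N - c_{\mathrm{eff}}},
\qquad c_{\mathrm{eff}} = c_{bio} + 2 x_{cys},$$

*independently of every internal flux choice*. `expected_n_ratio()` is this
closed form; the acceptance suite checks that the LP solution reproduces it
to 10$^{-6}$ across dozens of random configurations. The default
configuration ($n_N = 2$, $c_{bio} = -0.34$) puts the core in the
anion-rich regime where the ratio is $1.66/2.34 \approx 0.71$, the regime a
real leaf composition occupies. Three corollaries, all tested: a sole
nitrogen source under $P_B$ with a hard-fixed composition is *infeasible*
for any $|c_{\mathrm{eff}}| < n_N$; under relaxed H$^+$, sole ammonium runs
with proton *efflux* and sole nitrate with *influx*; and when component
upper bounds are freed, sole-ammonium growth becomes feasible again through
compensatory sulfate uptake with the surplus leaving as excess cysteine.

### Why the triose-phosphate shuttle is a proton phenomenon

In the two-cell configuration, carbon enters through MP (PEPC → malate →
BS), and per malate the mesophyll's C4 overhead (PEPC, PPDK, NADP-MDH and
their photon-driven cofactor supply) nets **+1** H$^+$, while the
bundle-sheath's Calvin-cycle side nets **−1** per CO$_2$. With external
H$^+$ exchange open, each tissue simply vents. Under $P_B$ neither can, and
the only flexible proton carrier between the cell types is the
3-PGA/DHAP shuttle: exporting a 3-PGA and reimporting a DHAP moves the
H$^+$-consuming reduction step (and its PSII/cyclic supply) from BS into
MP, shifting exactly one proton of imbalance per triose. The LP therefore
runs the shuttle at the flux that zeroes both ledgers — at which point BS
PSII drops to zero (the "limited PSII activity in bundle-sheath
chloroplasts" of NADP-ME plants emerges rather than being imposed), photon
demand concentrates in MP, and O$_2$ stops moving between the cell types.
Open the H$^+$ exchanges and the optimum flips: shuttle exactly zero, BS
photon demand above MP, O$_2$ flowing BS → MP. Both regimes are asserted in
the acceptance suite.

A configurable hard cap $v_{PSII,BS} \le v_{PSII,MP}/\mathrm{asym}$
(`psii_asymmetry`, default 1.5) is also provided. Under $P_B$ it is
non-binding (BS PSII is already zero). Under relaxed H$^+$ the relaxed
optimum has equal PSII in both tissues, so any cap with asym > 1 *forces*
partial shuttle use for purely stoichiometric (NADPH-supply) reasons; the
shuttle-deactivation analyses therefore lift the cap in the relaxed arm so
that what they demonstrate is the proton mechanism, not cap arithmetic.

## The lexicographic objective

All scenarios use the two-stage objective: minimise total photon influx,
pin that optimum (as a two-sided constraint with absolute tolerance
$10^{-6}$), then minimise $\sum_j |v_j|$ via flux splitting
($v = v^+ - v^-$, $v^\pm \ge 0$). The parsimonious second stage is the
degeneracy control: photon optima are massively non-unique and the flux-sum
minimiser selects a reproducible, cycle-free representative.

Whether the flux sum should include boundary pseudo-reactions is a genuine
design choice. The engine's default includes all reactions; the scenario
presets exclude boundary pseudo-fluxes (`include_boundary = FALSE`),
because exchanges and biomass sinks are not enzymes and counting them lets
a reducing-power shuttle "pay for itself" by shrinking H$^+$/O$_2$ vent
fluxes, leaving a small spurious shuttle flux in relaxed-H$^+$ optima.
With boundary fluxes excluded, the shuttle is parsimony-neutral when
venting is allowed and its deactivation is exact.

## Numerical choices

* **LP backend.** A bounded-variable two-phase primal simplex (compiled,
  dense tableau) behind the thin `solve_lp()` interface. Dantzig pricing
  with a Bland fallback for anti-cycling; pivot/feasibility tolerances
  $10^{-9}$. The tableau, basis inverse and basic values are refactorised
  from scratch every 100 pivots and at every phase boundary, and every
  returned solution is audited against $\|Av-b\|_\infty$ and the bounds
  before being reported optimal — parsimonious-FBA problems (split
  variables double the column count) are exactly the size at which silent
  elimination drift otherwise appears. Results are cross-checked in the
  test suite against an independent dense simplex on small programs.
* **Zero/blocked tolerances:** $10^{-7}$ flux units for blocked-reaction
  and zero-flux decisions, $10^{-6}$ for scenario activity thresholds;
  `active_sets()` also offers a variability-based activity mode (min and
  max at the optimum both beyond tolerance) that is robust to alternate
  optima.
* **Reversibility sentinels:** reversible reactions get bounds
  $(-1000, 1000)$, irreversible $(0, 1000)$, in model flux units (mol per
  gram dry weight per arbitrary time); absolute fluxes are only meaningful
  relative to the fixed gram demands.
* **Gram→mol conversion:** a "one gram" demand is converted through the
  molar mass of the polymer repeat unit, computed from the drained
  species' formula (anhydro-glucose 162.14 g/mol for the cellulose analog;
  the pentose unit for the xyloglucan analog; the monolignol mix for
  lignin). When a model carries the three monolignol sinks the lignin
  demand is split by an H:G:S mass ratio, default 0.05:0.49:0.46 — the
  grass-lignin composition range reported for C4 monocots; it is a
  configuration parameter, not ground truth.
* **Determinism.** The generator derives everything from `seed` through
  R's RNG (restoring the caller's RNG state), the simplex is
  deterministic, and scenario reports are pure functions of (model,
  preset): repeated runs are bit-identical, which the suite asserts.

## Problem sizes

The shipped analyses run at desk scale deliberately: the default core has
about one hundred reactions (plus the filler periphery), the wired
three-tissue model about 460, and a parsimonious solve on it takes seconds
on one CPU. The oracle sweep uses 20–24 random configurations with the
filler layer off. These sizes were chosen so that every claim can be
re-verified from scratch in a single short run; nothing in the method
depends on them.

## What the synthetic tests do and do not show

Passing the desk-scale battery shows that the *machinery* is correct: the
balance checker cannot be fooled by charge-clean energy leaks (the free-ATP
corruption is balanced and only the leak battery flags it), the LP engine
is exact against closed forms and independent solvers, and the
proton-balance phenomenology (forced NH$_4^+$:NO$_3^-$ co-uptake, shuttle
activation, PSII asymmetry, H$^+$ carrier substitution, reversed malate /
pyruvate exchange when both proton routes are blocked) follows from
charge bookkeeping alone. It does *not* show that any particular organism's
curated reconstruction is correct, and the core makes no attempt to
reproduce absolute published flux values — its quantum demands, P/O ratios
and lumped pathway costs are simplified. To reproduce published numbers,
export the curated supplementary tables to CSV, load them with
`read_model_tables()`, and run the same scenario functions; the acceptance
test describes the expected values.

## Known limitations

* Photorespiration is fully oxidative: the glycolate carbon is combusted
  in the peroxisome rather than salvaged, so the oxygenase branch loses
  two carbons per oxygenation and the rubisco carboxylase:oxygenase
  coupling is costlier than in a salvaging network. When a constraint set
  is infeasible, the scenario functions retry under a documented greedy
  relaxation order and report which relaxation restored feasibility
  rather than failing silently.
* One protonation state per metabolite per compartment; no pH-dependent
  speciation, no membrane potential, no transport energetics on the
  intercellular carriers.
* Amino acids do not move between tissues; the vacuole is storage only.
* No thermodynamic loop-law constraints (no MILP): directionality is
  curated through bounds, and the leak battery is the guard against
  erroneous energy-generating cycles.
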