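---
title: "Stoichiometric interrogation of carotenoid- and ionone-producing yeast: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric interrogation of carotenoid- and ionone-producing yeast: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionoflux)
```

## The model and its assumptions

Everything in this package rests on steady-state flux balance analysis:
for a metabolic network with stoichiometric matrix $S$ (metabolites by
reactions), a flux vector $v$ (mmol/gDCW/h) is feasible when $Sv = 0$ and
$lb \le v \le ub$, and the analyses optimize a single flux over that
polytope. The assumptions this inherits are the usual ones: pseudo-steady
state over the culture interval (balanced growth, no metabolite
accumulation other than through explicit sink reactions), no kinetic or
regulatory information, and rates expressed per gram dry cell weight.
Gene dosage, promoter strength and integration locus are **never**
modelled; strains differ only through the measured rates used as
constraints, which is also how the interrogation is meant to be read:
it asks what the stoichiometry permits, not what the enzymes do.

A single internal unit system is used throughout — mmol/gDCW/h for every
flux, with the biomass pseudo-reaction flux equal to the specific growth
rate in 1/h. Yields (mg/gDCW) and titers (mg/L) exist only at the
measurement boundary and are converted exactly once, during
contextualization. This prevents the classic silent unit bug where a
yield is treated as a rate.

## The heterologous pathway

`build_pathway_spec()` emits the reaction set grafted onto the host:

* CrtE: FPP + IPP → GGPP + PPi
* CrtYB (synthase): 2 GGPP → phytoene + 2 PPi
* CrtI (lumped, 4 desaturations): phytoene + 4 FAD → lycopene + 4 FADH2
* CrtYB (cyclase): lycopene → β-carotene
* CCD1 double cleavage: β-carotene + 2 O₂ → 2 β-ionone + C14 dialdehyde
* CCD1 single cleavage (optional): β-carotene + O₂ → β-ionone + C27 apocarotenal
* irreversible accumulation sinks for phytoene, lycopene, β-carotene,
  the C14 dialdehyde (and optionally the C27 apocarotenal), plus a
  β-ionone exchange

Every internal reaction balances C, H, O and P by construction, and the
constructor refuses to emit an unbalanced spec. The C14 dialdehyde
formula C14H16O2 is not looked up but *forced*: it is the unique formula
that closes the C/H/O balance of
C40H56 + 2 O₂ → 2 C13H20O + X. The carbon split 40 = 13 + 13 + 14 is
what ties the cleavage chemistry to the carbon accounting downstream.

Choices worth making explicit:

* **Accumulation as sinks.** Accumulated pigment is intracellular and
  never re-enters metabolism, and the measurement (mg/gDCW retained in
  biomass) is a per-biomass content; an irreversible drain reproduces
  that without inventing transport machinery. All sinks are created
  closed and are only opened by contextualization.
* **FAD/FADH2 as the desaturation electron acceptor.** The four lumped
  desaturation steps must deposit 8 H somewhere; FAD is host-agnostic
  and elementally balanced, and reoxidation is left to the host model.
* **No C27 downstream chemistry.** Single cleavage plus a C27 sink is
  the whole story; further cleavage of the apocarotenal is deliberately
  not modelled, because no stoichiometry for it is assumed.
* **Overexpression of the mevalonate-pathway bottleneck (tHMGR) is not a
  model edit** — its effect is already present in the measured yields of
  the strains that carry it.

## Contextualization

`apply_growth_context()` encodes aerobic growth on glucose as sole
carbon source: uptake of every other carbon-containing exchange
metabolite is closed, oxygen uptake and CO₂ export are opened,
fermentation-product exports stay open, and the ATP maintenance reaction
receives `ngam` (default 1 mmol ATP/gDCW/h) as a lower bound.

`constrain_strain()` then turns one measurement row into interval
constraints:

| measurement | constrained flux | conversion |
|---|---|---|
| μ (1/h) | biomass reaction | direct |
| q_CO₂ (mmol/gDCW/h) | CO₂ exchange | direct |
| total carotenoids × profile fraction (mg/gDCW) | species sink | μ·Y/M (growth-coupled) |
| β-ionone titer (mg/L) | ionone exchange | titer/(X·t·M) (endpoint) |

Intervals, not equalities: measured values get a fractional half-width
`tol_frac` (default 0.05), because strict equalities on noisy
measurements routinely make the LP infeasible. Carotenoid yields are
growth-coupled (they are per-gDCW, i.e. proportional to biomass), while
secreted ionone uses the endpoint form by default (it accumulates in the
medium/overlay over the whole culture); both modes are exposed. Solvent
overlay partitioning is ignored — all ionone is assumed captured in the
measured titer. When a measurement lacks μ or q_CO₂, packaged
literature-typical values for aerobic glucose batch growth (μ = 0.37/h,
q_CO₂ = 23, q_glc = 16 mmol/gDCW/h) can substitute, and every constraint
carries a provenance note naming the field (or default) it came from.

## The four interrogation procedures

**Minimal glucose uptake.** With the strain's constraints applied,
maximize the glucose exchange flux (uptake is negative, so this is the
minimal uptake). Comparing against experimental uptake gives the
relative error; computing it amounts to optimizing the biomass yield on
glucose, which is why the maintenance-free duality test (min-glucose at
fixed μ versus max-μ at that glucose) must and does return identical
yield ratios.

**Carbon recovery.** `100·(c_X·μ + q_{CO2} + Σ c_i q_i)/(6·q_{glc,exp})`,
with the biomass carbon content $c_X$ derived from the model's own
biomass reaction composition (an explicit override exists for models
whose biomass components lack formulas). The denominator uses the
*experimental* uptake deliberately: against the model's own predicted
uptake the balance closes trivially. Recovery below ~80% means the
measured set misses too much carbon for the subsequent yield analysis to
be meaningful.

**Counterfactual maximum ionone and departure.** Three LPs: (1) force
the ionone exchange to zero, free the β-carotene sink, maximize it —
the theoretical accumulation the strain's measured physiology permits;
(2) `divertible = 40·(q_theoretical − q_observed)` mmol C/gDCW/h; (3)
restore the observed sink value, cap total CCD1 substrate carbon at the
divertible amount, maximize the ionone exchange. The cap is implemented
exactly, as a pseudo-metabolite produced at 40 per unit cleavage flux
and drained by a bounded reaction — not as a bound manipulation — so it
applies jointly to single and double cleavage. The departure is the
percent shortfall of the observed ionone rate from this optimum. The cap
is placed on CCD1 substrate carbon rather than on precursor (GGPP)
supply: the question asked is how much carbon *toward β-carotene* could
have been cleaved.

**C14:ionone ratio.** Read from the step-3 parsimonious optimum as the
C14 sink flux over the ionone exchange flux: 0.5 under pure double
cleavage, 0 under pure single cleavage. Because FBA optima are
degenerate, the ratio's attainable range at the fixed optimum (two
auxiliary LPs on the C14 flux) is reported next to the point value;
a wide range is a warning that the point value is a tie-break artifact.

Degenerate inputs are reported, not patched: an observed accumulation
above the theoretical maximum yields a "measurement exceeds model
optimum" note, and a zero ionone optimum leaves the departure undefined
rather than forcing 0 or 100.

## The LP solver and numerical choices

No LP library is part of the package's dependency footprint; the solver
is a self-contained bounded-variable two-phase primal simplex
(`R/simplex.R`) operating on the dense constraint matrix. Entering and
leaving variables follow Bland's rule, which guarantees finite
termination without cycling; the basis system is re-factorized every
iteration, which at these problem sizes (tens to a couple of hundred
variables) is cheap and numerically self-correcting. All bounds are
finite — "unbounded" fluxes use the conventional ±1000 mmol/gDCW/h — so
the feasible region is a polytope and unboundedness cannot occur.

* Feasibility/optimality tolerance: 1e-6 relative, 1e-9 absolute. Every
  optimal solution is *post-checked* against $Sv=0$ and the bounds; a
  solution failing the check is rejected with status `"failed"`, kept
  distinct from `"infeasible"` (phase-1 evidence) — quiet constraint
  violations would corrupt the carbon accounting silently.
* Parsimonious tie-break: reversible fluxes are split into nonnegative
  forward/backward parts and total flux is minimized with the objective
  pinned to its optimum within 1e-8 relative. All reported flux-derived
  statistics use this solution; determinism across repeated solves is
  part of the test suite.
* The solver is pluggable (`options(ionoflux.solver = ...)`) behind a
  four-argument contract (objective, equality matrix, bounds, sense),
  and the default is validated against an independent brute-force
  vertex-enumeration oracle on random small networks in the tests.

## The synthetic-data generator

`build_toy_model()` emulates, in ~20 reactions, the features of a
genome-scale yeast model that the analyses actually exercise: glucose
uptake with a transporter, lumped respiration with a stated ATP yield
(default 18 mol ATP/mol glucose), an optional overflow fermentation
branch (2 ethanol + 2 CO₂ + 2 ATP), a biomass pseudo-reaction with
stated carbon content (default 40 mmol C/gDCW ≈ 48% carbon by weight)
and growth-associated ATP demand (60 mmol/gDCW), a capacity-bounded
lumped mevalonate supply of FPP/IPP that costs glucose carbon and ATP
and vents CO₂, and a FAD redox cycle. Every optimum used as a test
oracle has a closed form recorded in the model description, e.g. minimal
glucose at growth μ with maintenance `ngam`:
$q_{glc} = c_X\,\mu/6 + (g\,\mu + \mathrm{ngam})/a$.

`simulate_measurements()` realizes a chosen true flux state exactly
(solving the model, so $Sv=0$ holds by construction), converts it to
measurement units through the same conversions contextualization
inverts, and applies multiplicative log-normal noise with a stated CV —
measurements are positive and HPLC/OD errors are roughly proportional,
which the log-normal captures while keeping positivity. An optional
`q_glc` above the minimum routes surplus carbon through overflow, which
is how strains with unmeasured side products are emulated.

What the toy deliberately does **not** emulate: compartmentation,
cofactor specificity, proton/charge balancing, biomass composition
detail, and — importantly for reading the test results — realistic
*relative magnitudes*. In the recovery scenarios the pathway fluxes are
of the same order as central metabolism, so that the cleavage signal is
large compared to the slack that constraint tolerances introduce. At
genome scale the carotenoid pathway is ~1% of carbon flux, and the same
tolerance (5%) on q_CO₂ would dwarf the signal; passing the toy-scale
tests therefore validates the *procedures*, not the attainable precision
on real strains. For the same reason, full genome-scale departure and
ratio figures for the engineered strains are out of scope here: they
would require a curated genome-scale pathway extension and per-strain
literature rates that are not distributed with this package, and no
attempt is made to certify them.

The packaged fixture table (`strain_fixtures()`) carries the published
per-strain shake-flask values only. Growth rates, CO₂ rates and biomass
concentrations were not published per strain, so the fixture rows leave
them empty rather than inventing them; fixture-driven runs consequently
skip the rate-dependent stages and verify unit conversions and
fold-change arithmetic, which is all those numbers support.

## Problem sizes and runtimes

The test suite builds all fixtures in code at run time: toy models of
~20–35 reactions, random LP instances of at most 8 reactions (small
enough for exhaustive vertex enumeration), 100 oracle comparisons, 20
noise seeds for the recovery check, and 200 replicates for the noise-CV
calibration. The full suite runs in well under a minute on one CPU.

## Known limitations

* LP only — no flux variability analysis, no MOMA/ROOM, no
  thermodynamic or enzyme-capacity constraints; the observation that the
  cleavage enzyme appears capacity-limited enters only through the
  measured rates.
* SBML support targets Level 3 core, flat models, with FBC-style
  formula/bound attributes; groups, hierarchy and gene-protein-reaction
  rules are ignored (gene associations, if present, are not evaluated).
* The departure statistic inherits the tolerance slack of the interval
  constraints; at fixed tolerance its bias grows as the pathway share of
  total carbon shrinks (see the scaling discussion above).
* The pathway formulas use neutral species, under which every reaction
  balances H exactly. Host models with explicit proton/charge conventions
  may show H offsets in the prenyl-transfer steps when checked against
  *their* metabolite formulas; those offsets reflect the convention
  mismatch, not a carbon-accounting error, and carbon is what every
  downstream statistic uses.
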