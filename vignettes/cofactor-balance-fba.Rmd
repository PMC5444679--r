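---
title: "Cofactor-balance flux analysis of K. marxianus central metabolism"
author: "marxFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cofactor-balance flux analysis of K. marxianus central metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marxFBA)
```

# The model and its assumptions

`marxFBA` reconstructs central carbon metabolism of the xylose-utilising
yeast *Kluyveromyces marxianus* as a 56-reaction, single-compartment
stoichiometric model: glycolysis/gluconeogenesis, the oxidative and
non-oxidative pentose phosphate pathway (PPP), the TCA cycle with the
glyoxylate shunt, the fermentative branches (ethanol, glycerol, acetate,
ethyl acetate), xylose assimilation (NADPH-dependent xylose reductase,
NAD-dependent xylitol dehydrogenase, xylulokinase), a four-reaction
beta-oxidation block, lumped electron transport / oxidative phosphorylation,
and a biomass drain.  Reactions are identified by the MetaCyc reactions
they transcribe (`metacycId` column) and by display indices 1–56.

Steady-state flux distributions solve

$$ S\,v - E\,e = 0, \qquad l \le v \le u $$

where $S$ is the stoichiometric matrix, $v$ the vector of reaction fluxes,
$E$ an identity-like selector with one unit column per boundary metabolite
and $e$ the exchange fluxes ($e > 0$ is net export/accumulation, $e < 0$
net uptake).  The LP always maximises a linear objective — the growth flux
in the reference scenarios, or a cofactor export in the yield analyses.

Modelling conventions, chosen once and used throughout:

* **Single pools.** One compartment; one pool each for ATP/ADP, NAD(H),
  NADP(H).  Protons are not tracked; water is tracked but always freely
  exchangeable, so its balance never constrains; orthophosphate is tracked
  with an always-open exchange.
* **P/O ratios.** NADH oxidation is lumped into one electron-transport
  reaction at P/O 2.5 (Crabtree-negative respiration).  Succinate-derived
  electrons enter at P/O 1.5, folded into the succinate dehydrogenase step
  so that the chain remains a single reaction.
* **AMP-forming ligases** (acetate–CoA ligase, acyl-CoA synthetase, PEP
  synthase) are written as two ATP→ADP equivalents with adenylate kinase
  folded in; AMP is not a species.  This preserves the energetic point that
  the pyruvate dehydrogenase bypass hydrolyses two ATP equivalents.
* **Beta-oxidation** is a single four-carbon-equivalent round ending in a
  thiolysis to two acetyl-CoA.  A longer acyl chain would need either a
  species ladder or a self-regenerating pseudo-species that creates carbon;
  the block carries zero flux on sugar substrates either way.
* **Irreversible reactions have lower bound exactly 0**; reversible
  reactions are unbounded in both directions (boxed only inside the
  solver, see below).  Reversibility follows standard assignments
  (kinases, decarboxylating dehydrogenases and synthases irreversible;
  isomerases, transketolase/transaldolase, aconitase, fumarase, MDH, ADH,
  xylitol dehydrogenase, GAPDH/PGK, succinyl-CoA ligase reversible); each
  choice is visible per reaction in `reactions(buildReferenceModel())`.

# Exchange semantics

Boundary behaviour is a per-metabolite mode: `closed` (no exchange),
`accumulate` (export only), `uptake` (import only, finite bound), `free`,
and `fixed` (pinned, for a saturated transporter).  The carbon source is
taken up at the model's uptake bound of 10 (relative flux units; all
results are ratios to this bound).  O2 is uptake-only when aerobic and
closed anaerobically; CO2, water and phosphate are free; fermentation
products and biomass accumulate.

Letting a cofactor "accumulate" stands for unmodelled processes that
consume it (ATPases, transporters, polymer turnover for ATP; oxidation
elsewhere for NADPH).  Stoichiometrically that only makes sense if the
partner species flows back: an ATP export must return ADP, an NADPH export
must return NADP, and exporting acetyl-CoA must return free CoA.  The
policy builder therefore opens the partner for uptake whenever the
high-energy form accumulates.  "All biomass precursors may accumulate"
opens export-only exchanges for exactly the non-cofactor metabolites the
growth reaction drains — precursors can overflow but never be imported.

# Solving, tie-breaking, degeneracy

The LP is solved by a dense bounded-variable two-phase primal simplex
written for this package (no LP solver library is part of its
dependencies).  Unbounded directions are boxed at ±10^6 and any solution
touching the box is flagged as effectively unbounded.  Feasibility and
mass-balance residuals are held to 1e-9, objective comparisons to 1e-7;
variable order is fixed and pricing is deterministic (Dantzig with a
permanent Bland fallback after degenerate runs), so repeated runs are
bit-identical.  The solver is validated against an exhaustive
vertex-enumeration oracle on seeded random models (`randomSmallModel()` /
`bruteForceOptimum()`); the two share no code.

FBA optima on networks are degenerate, so every reported solution is
refined parsimoniously: with the objective pinned at its optimum, total
absolute reaction flux is minimised (split-variable LP).  This removes
gratuitous circulations; remaining degeneracy is characterised, not
hidden, by flux variability analysis (per-variable min/max at the fixed
optimum).

# Substrate cycles

A substrate cycle converts no carbon and only turns cofactors over
(PFK + FBPase: net ATP hydrolysis).  `detectInternalCycles()` finds such
cycles as minimal-support circulations with every exchange closed and the
cofactor (and water) balance rows relaxed — relaxation is what makes the
net cofactor conversion visible; with those rows enforced no cycle could
carry flux at all.  In the packaged model this yields the FBP/PFK pair,
the malic-enzyme cycle (pyruvate carboxylase + malate dehydrogenase +
malic enzyme: ATP hydrolysis plus NADH→NADPH transfer) and the two
pyruvate/PEP cycles.

Because loopless-MILP formulations are out of scope, "no substrate cycles"
is enforced structurally in the scenario suite: PEP synthase, PEP
carboxylase and PEP carboxykinase are deactivated in every figure
configuration (the first two are absent or near-absent from the organism's
annotation; all three exist in the map only as cycle parts), and malic
enzyme is deactivated in the aerobic figures and re-activated in the
anaerobic one, where the cycle is the object of study.  Without this
blocking, the malic-enzyme cycle would act as a free ATP sink and the
closed-ATP scenario could not show its growth collapse.  Parsimonious
refinement then guarantees that no *removable* circulation survives in a
reported solution, which `auditCycleFlux()` re-checks; a cycle that is
required to close a balance — the FBP/PFK pair as ATP sink when the ATP
balance is closed — carries flux legitimately and is not flagged.

# The scenario suite

`scenarioRegistry()` encodes the eleven published simulations (glucose and
xylose references with ATP accumulation; the two NADPH-maximisation modes
of cyclic PPP flux; PFK/FBP activity manipulations with NADPH or ATP
balances closed; the NAD-swapped oxidative PPP; anaerobic xylose growth).
`swapCofactor()` implements the oxidative-PPP cofactor change by
transferring the NADP/NADPH coefficients of glucose-6-phosphate
dehydrogenase to NAD/NADH.

Two headline results are pure stoichiometry, independent of every
coefficient choice discussed below: maximising NADPH production from
xylose (uptake 10, cofactor exchanges free) yields an NADPH balance of 90
with FBPase active — complete PPP cycling, 2 NADPH per CO2 over five
turns per pentose, minus one NADPH for xylose reductase — and 30 with
FBPase inactive, where only the non-oxidative rearrangement
3 X5P → 2 F6P + GAP can feed the oxidative branch.  These are the
quantities `scripts/acceptance.R` recomputes.

The **limited malic-enzyme probe** caps that flux at 50% of its
unrestricted anaerobic value with the xylose uptake pinned at −10
(saturated transporter).  Pinning matters: with a merely bounded uptake
the optimiser would take up less sugar instead of overflowing xylitol.
The cap fraction is a free choice within the feasible range — any cap
between the feasibility floor and the unrestricted flux produces xylitol
overflow; 50% sits safely inside that range for every perturbed
coefficient set the tests use (a 10% cap would fall below the floor, where
the scenario is simply infeasible).

# The biomass stand-in

The growth reaction drains ten precursors plus ATP and NADPH and releases
NADH, per unit of growth flux.  The packaged coefficient set is a
documented synthetic stand-in (`provenance = "standin"`): carbon-precursor
and energy demands follow the classic precursor-requirement tables
(G6P 0.276 — carrying the full hexose-phosphate demand, since wall
glucans and mannans derive from it — R5P 0.898, E4P 0.361, GAP 0.129,
3PG 1.496, PEP 0.519, PYR 2.833, AcCoA 3.748, OAA 1.787, AKG 1.079,
ATP 41.7, NADH −3.547, all mmol per g cells).

The NADPH demand deserves its own paragraph, because the model's
qualitative regimes pin it from both sides.  Too high, and the oxidative
PPP must carry the entire hexose flux on glucose, leaving the
glucose-6-phosphate isomerase without its glycolytic flux; published 13C
studies put the yeast oxidative-PPP split on glucose well below that.
Too low, and the NADP-dependent isocitrate dehydrogenase alone covers
biosynthetic NADPH, so the cyclic-PPP route never pays its carbon cost and
the FBPase benefit under the NAD-swapped oxidative PPP disappears.  The
stand-in uses 16 mmol NADPH per g, inside the window where both observed
regimes hold, and in the upper part of the range spanned by published
yeast estimates (which vary severalfold with biomass-composition
assumptions).  `perturbBiomass()` applies independent ±20% factors to all
drains; the test suite re-derives every sign and ordering conclusion
under twenty such perturbed sets, which is the package's evidence that
the qualitative findings do not hinge on the exact coefficients.

Growth fluxes are therefore in arbitrary, comparative units: orderings
and signs across scenarios are meaningful, absolute magnitudes are not,
and the suite asserts only the former.

# What the synthetic generators do and do not emulate

`randomSmallModel()` plants a linear uptake→export pathway and adds random
side reactions with small integer coefficients — enough structure to
exercise feasibility, degeneracy, loops and bound handling, and small
enough (≤8 metabolites, ≤12 reactions) for exhaustive vertex enumeration.
It does not emulate cofactor pairing, reaction thermodynamics or realistic
network topology; passing the oracle equivalence therefore certifies the
LP machinery, not any biology.  Likewise, the perturbation tests certify
robustness of conclusions to the stand-in's coefficients, not agreement
with measured *K. marxianus* fluxes: no kinetic, regulatory or
thermodynamic information enters the model, uptake is fixed rather than
measured, and the original study's printed growth-rate and ATP-exchange
magnitudes depend on its own (externally sourced) biomass formula, which
this package deliberately does not claim to reproduce.

# Numerical choices, in one place

| Quantity | Value |
|---|---|
| LP box bound for unbounded fluxes | 1e6 |
| Mass-balance / bound residual | ≤ 1e-9 |
| Objective comparison tolerance | 1e-7 |
| Flux threshold (signs, supports) | 1e-6 |
| Oracle sizes | ≤ 8 metabolites, ≤ 12 reactions |
| Perturbation robustness | ±20%, 20 seeds |
| Carbon uptake bound | 10 (relative units) |
| P/O ratio (NADH / succinate) | 2.5 / 1.5 |

Ties between alternate optima are broken by minimum total absolute flux;
residual degeneracy is reported via FVA ranges.  Degenerate pivoting is
handled by a permanent within-phase switch to Bland's rule.  The figure
suite (eleven scenarios with FVA, audits and reports) completes in well
under a minute on one CPU; the full test suite, including the twenty
perturbed re-derivations and the 50-model oracle comparison, runs in a
few tens of seconds.

# Known limitations

* Single compartment: no mitochondrial/cytosolic cofactor separation, so
  transhydrogenase-like effects of compartmentation are invisible.
* No thermodynamic feasibility: the malic-enzyme cycle is reported as
  stoichiometrically possible; whether concentrations make it spontaneous
  is outside scope.
* Growth magnitudes are comparative only (stand-in biomass).
* The structural substrate-cycle exclusion is a modelling decision that
  mirrors the organism's annotation; a loopless-MILP treatment would make
  it solution-level instead.
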