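---
title: "Models and methods behind photoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoflux)
```

`photoflux` compares C3 and C4 plant metabolism with constraint-based
models. This vignette is the package's own account of the science: the
models and their assumptions, the parameters that matter, what the bundled
toy networks do and do not emulate, and the numerical and design choices a
maintainer would want written down.

## The carboxylation:oxygenation ratio

Rubisco catalyzes two competing reactions — carboxylation of RuBP by CO₂
and oxygenation by O₂. Under fixed CO₂ and O₂ partial pressures their
rates stand in a constant ratio *r* = V_c/V_o, so a stoichiometric model
that leaves the two reactions independent will happily route flux through
either one regardless of the gas environment. `photoflux` therefore fixes
the ratio kinetically and merges the two reactions into one (next
section).

**C3 leaves** (`c3_ratio()`). The Michaelis–Menten competition gives

$$V_c = \frac{C_i}{C_i + K_c\,(1 + O/K_o)}, \qquad
  V_o = 0.21\,\frac{O}{O + K_o\,(1 + C_i/K_c)},$$

with Rubisco constants $K_c = 460\ \mu\mathrm{bar}$,
$K_o = 330\ \mathrm{mbar}$, ambient O₂ $O = 210\ \mathrm{mbar}$, the 0.21
relative maximal oxygenation velocity, and intercellular CO₂
$C_i = 0.70\,c_a$ (70% of ambient — the stomatal draw-down of a typical C3
leaf). All are tunable through `c3_kinetics()`.

**C4 leaves** (`c4_ratio()`). The two-cell model couples a mesophyll PEP
carboxylation supply to bundle-sheath Rubisco:

$$V_p = \min\left(\frac{C_m V_{pmax}}{C_m + K_p},\ V_{pr}\right), \quad
  A_c = \min(V_p + g_s C_m - R_m,\ V_{cmax} - R_d), \quad
  A_j = (1-x)\,J_t/3 - R_d,$$

with mesophyll CO₂ $C_m = 0.37\,c_a$ (the stronger draw-down of C4
leaves). When the PEP-carboxylation arm limits ($A_c = V_p + g_s C_m -
R_m$), the bundle-sheath CO₂ is solved from the Rubisco response,

$$C_s = \frac{\gamma O_s + K_c (1 + O_s/K_o)\,(A_c + R_d)/V_{cmax}}
             {1 - (A_c + R_d)/V_{cmax}}, \qquad r = \frac{C_s}{2\gamma O_s};$$

otherwise the CO₂ over-cycling (leak) balance gives

$$r = \frac{g_s C_m + V_p - A - R_m}
           {2\gamma\,(\alpha A / 0.047 + O_m g_s)}.$$

Defaults (`c4_kinetics()`): $V_{pmax}=120$, $K_p=80\ \mu$bar, $V_{pr}=80$,
$g_s=3$ mmol m⁻² s⁻¹ bar⁻¹, $V_{cmax}=60$, $\gamma=0.5/2590$, $R_d=0.6$,
$R_m=0.3$, $\alpha=0$, $x=0.4$, $J_{max}=400$, $K_c=650\ \mu$bar,
$K_o=450$ mbar, $O_m=210$ mbar; rates in μmol m⁻² s⁻¹.

Three conventions close the parameterization and are worth stating
explicitly because the equations mix pressure units:

* products of $g_s$ with a partial pressure take the pressure in **mbar**
  (equivalently, bar with $g_s$ in mmol, yielding μmol-scale fluxes);
* $\gamma O_s$ terms take $O_s$ in **μbar**;
* with $\alpha = 0$ there is no PSII (hence no O₂ evolution) in the bundle
  sheath, so $O_s = O_m$; and $J_t = J_{max}$, i.e. saturating light. With
  the default parameters $A_j = 79.4$ never limits at the reference CO₂
  levels, so the ratio table is insensitive to the $J_t$ policy; the
  branch actually taken is recorded in every `ratio_result`.

The five reference concentrations give:

```{r}
ratio_table()
```

One caution: the C4 equations switch limitation regime near
$c_a \approx 215\ \mu$bar, and *r* is not monotone through the switch
itself (the PEP-limited expression grows toward the singularity
$(A_c+R_d)/V_{cmax} \to 1$ while the leak-balance expression starts near
zero). Within each regime, and across the reference concentrations, *r*
increases strictly with CO₂. The branch tie is decided with a relative
tolerance of $10^{-9}$, and the equality-branch singularity raises an
explicit error rather than returning a wild value.

## The combined Rubisco reaction

At ratio *r*, carboxylation ($\mathrm{RuBP + CO_2 + H_2O \to 2\,PGA}$) and
oxygenation ($\mathrm{RuBP + O_2 \to PGA + PGCA}$) merge into

$$(r+1)\,\mathrm{RuBP} + r\,\mathrm{CO_2} + r\,\mathrm{H_2O} +
  \mathrm{O_2} \longrightarrow (2r+1)\,\mathrm{PGA} + \mathrm{PGCA},$$

which conserves C, H, O and P for every $r > 0$ (the test suite checks
this on a grid). `install_rubisco()` removes any split pair (and any
previously installed combined reaction — the operation replaces, never
accumulates) and inserts the combined reaction in the target compartment:
the mesophyll chloroplast for C3, the bundle-sheath chloroplast for C4.

## Flux balance analysis

`fba()` solves $\max c^\top v$ subject to $S v = 0$, $l \le v \le u$.
Solutions report one optimal vertex; alternate optima are ubiquitous in
metabolic LPs, so only the objective value is contract-stable and tests
never pin individual fluxes unless `flux_ranges()` proves uniqueness.
Feasibility is enforced to $10^{-6}$ and optimality to $\sim 10^{-8}$.
The LP engine is a dense bounded-variable two-phase primal simplex written
for this package (Dantzig pricing with a Bland's-rule fallback against
cycling, eta-updated basis inverse with periodic refactorization); it is
validated in the tests against a brute-force vertex-enumeration oracle on
small networks.

The two study objectives are **biomass synthesis** (flux of the biomass
exchange) and **CO₂ fixation**, defined as net CO₂ uptake through the CO₂
exchange reaction — the observable a gas-exchange experiment measures,
chosen because it is well-defined in both a one-cell and a two-cell model.

## Knockout scans

A reaction deletion clamps one reaction to zero; an enzyme deletion is
genetic and clamps **every** reaction annotated with the EC number, across
compartments and cells. The score is the knockout:wild-type objective
ratio, classified as `zero` ($\le 10^{-6}$), `unchanged`
($\ge 1 - 10^{-6}$), `reduced_below_090` ($< 0.90$) or
`reduced_above_090`; exactly 0.90 is assigned upward (the boundary is a
documented choice). An infeasible knockout LP scores 0 — no feasible
steady state means no objective. `essential_overlap()` compares essential
(`zero`) sets across models through an id map; unmapped essentials stay in
the first model's private set by contract.

## Flux sampling and correlated reaction sets

`achr_sample()` implements artificial-centered hit-and-run. Bounds are
first tightened to the effective constraints by flux variability analysis;
the 2n FVA optima double as warm-up vertices and the warm-up set is filled
to `n_warmup` points with random convex combinations of them. The chain
draws a direction through the running center (stored point minus center),
computes the admissible segment from the bounds, and jumps uniformly.
Directions are re-projected onto the null space of S every step — the
running center accumulates round-off which would otherwise feed back into
the directions and grow — and the state is re-projected every 50 steps, so
every returned point satisfies $\|Sv\|_\infty \le 10^{-6}$. Defaults are
5000 warm-up points and 2000 retained points (thinning 5, burn-in 200);
both toy models sample at these sizes in seconds. A zero-volume space
(all fluxes pinned) returns the single point with a warning and a
`degenerate` flag.

`correlated_sets()` groups reactions whose sampled fluxes satisfy
$|\rho| \ge$ threshold, using absolute Pearson correlation because
reversibility conventions fix flux signs arbitrarily; the partition is the
connected-component closure of that relation. The default threshold
$1 - 10^{-8}$ detects exact stoichiometric coupling ("co-utilized in
precise stoichiometric ratios"); it is a tunable argument for looser,
linear-correlation exploration. Zero-variance reactions are excluded into
a reported invariant pool rather than forming spurious singleton sets.

## Reaction-graph topology

`build_graph()` draws a directed edge from reaction A to reaction B when a
product species of A is a substrate species of B; a reversible reaction
runs both ways, so its species count as both substrates and products.
Currency metabolites are excluded from edge induction, otherwise ATP and
water connect nearly everything and every metric degenerates. The default
exclusion list covers the energy and redox carriers (ATP/ADP/AMP,
NAD(P)(H)), protons, water, phosphate/pyrophosphate and photons — but
**keeps CO₂ and O₂**: in a photosynthesis network these are the substrates
whose routing is under study (the C4 concentrating mechanism is literally
a CO₂ path), and excluding them hides the defining structure of the
two-cell model. The list is an explicit argument for users who prefer a
different convention.

`metric_panel()` reports: average degree and Freeman degree centralization
on the undirected view, average local clustering (undirected), Freeman
betweenness centralization (directed), and average/maximum directed
shortest-path distance on the largest strongly connected component.
Graphs with fewer than three nodes report centralizations of zero with a
`small_graph` flag. `redundancy_score()` quantifies how many edges are
redundant for reachability: $1 - |E_{tr}|/|E|$ with $E_{tr}$ the
transitive reduction of the graph's condensation (a strongly connected
block of $k \ge 2$ nodes needs $k$ edges; parallel condensation edges and
transitive shortcuts are redundant). Trees score 0; a triangle with a
shortcut scores 1/3. This is a documented stand-in for redundancy-removal
network simplification; reproducing any particular published absolute
value is out of scope.

## Environment sweeps and C4 subtypes

`light_sweep()` re-solves the model over a grid of photon-uptake bounds;
curves are piecewise linear, non-decreasing, and saturate once light stops
limiting. `co2_sweep()` recomputes *r* at each ambient CO₂, re-installs
the combined reaction, scales the CO₂ exchange bound proportionally
(`co2_scale`, default 0.1 mmol gDW⁻¹ hr⁻¹ per μbar — a convention, since
only curve shapes are meaningful) and re-solves, giving the
constraint-based analogue of an A–Ci response. Two behaviors are worth
expecting: under strict carbon limitation the two leaves tie exactly
(identical biomass stoichiometries), and under ample light and high CO₂
the C3 leaf can overtake the C4 leaf, which still pays its ATP overhead —
the C4 advantage is a low-CO₂, light-co-limited phenomenon, and the test
suite asserts it under a photon-co-limited configuration.

`subtype_scenario()` restricts the C4 model to one decarboxylation
subtype by closing the other two decarboxylases (`R00216` NADP-ME,
`R00214` NAD-ME, `R00341` PCK); `"ALL"` leaves all three open, and by LP
relaxation can never do worse than any single subtype.

## The toy models

`make_toy_c3()` and `make_toy_c4()` build deterministic, elementally
balanced fixtures that embody the structures the analysis assumes, at a
scale where every result can be checked by hand or by brute force.

The **C3 leaf** is a single mesophyll cell with chloroplast, cytosol and
mitochondrion: linear (8 photons → 2 NADPH + 2 ATP) and cyclic
(1 photon → 1 ATP) light reactions; the combined Rubisco reaction at the
C3 ratio; PGA reduction and RuBP regeneration through explicit
transketolase, transaldolase, epimerase, isomerase and phosphoribulokinase
steps; a photorespiratory C2 chain (phosphoglycolate phosphatase with a
redundant unspecific-phosphatase twin, glycolate oxidase, catalase,
glyoxylate-to-glycerate lump, glycerate kinase); starch synthesis and
turnover; sucrose synthesis and export; glycolysis split at PEP;
anaplerotic PEPC plus a carboxylating malic-enzyme alternative (so the
PEPC knockout is survivable, as in a real C3 leaf); a respiration-bounded
TCA cycle (±50 mmol gDW⁻¹ hr⁻¹) with a glyoxylate-shunt branch routed to
glycine synthesis; GDH nitrogen assimilation; and a biomass drain of
2 GAP + starch + Asp + Ala + Gly + 10 ATP.

The **C4 leaf** adds a second cell: mesophyll PEPC, NADP-MDH and PPDK
(2 ATP-equivalents per PEP via AMP + PPi), malate/OAA and
aspartate/alanine shuttles to the bundle sheath, three decarboxylases with
subtype-specific compartments and cofactors (NADP-ME in the bundle-sheath
chloroplast, NAD-ME in its mitochondrion, PCK in its cytosol), a
PGA/triose-phosphate shuttle, cyclic-only bundle-sheath light reactions
(no PSII, matching $\alpha = 0$), a bounded CO₂ leak back to the
mesophyll, starch only in the bundle sheath, and **no direct CO₂ path from
the air into the bundle sheath** — the diffusion barrier that makes PEPC
essential. Inter-cell metabolite traffic passes through an explicit
plasmodesmatal interface pool, so cells connect through two-step paths;
this is the structural reading of the anatomical claim that two cells are
less closely connected than the interior of one cell, and it is what makes
the C3 graph denser on average while the C4 graph, with its parallel
decarboxylation and shuttle routes, is the more redundant one.

Design choices that were genuinely open, and how they were settled:

* **Light stoichiometry.** Linear electron transport yields 2 NADPH +
  2 ATP per 8 photons, with cyclic photophosphorylation supplying all
  further ATP at 1 photon each. (With 3 ATP in the linear reaction the
  mesophyll ATP byproduct exactly subsidized PPDK and erased the
  subtype-cost differences the scenarios are meant to expose.)
* **OAA transfer capacity** (`oaa_cap`, default 40): the
  mesophyll-to-bundle-sheath oxaloacetate shuttle that feeds PCK is capped
  below the PCK route's light-limited optimum. The PCK route costs 1 ATP
  per CO₂ delivered versus 2 for the malic-enzyme routes (PPDK), so with
  the cap the subtype pattern emerges from the ATP economics: PCK leads
  the singles, relaxing all three subtypes does at least as well, and a
  PPDK knockout degrades growth to ≈0.97 of wild type without abolishing
  it.
* **Mitochondrial redox.** There are no direct NAD(H) transporters (the
  inner membrane is impermeable); cytosolic and mitochondrial pools
  exchange redox through the malate shuttle that both models carry.
* **Glyoxylate shunt.** The mitochondrial isocitrate-lyase branch feeds
  glycine synthesis (a biomass sink). Wiring it into the chloroplast C2
  pool instead would create a Rubisco-independent carbon-fixation loop and
  silently break Rubisco essentiality — a trap worth recording.
* **Maintenance ATPases** in each cytosol absorb surplus ATP, without
  which the fixed 2:2 light stoichiometry can render NADPH-heavy flux
  modes infeasible.

What the toys deliberately do **not** emulate: genome-scale coverage
(thousands of reactions, full amino-acid/nucleotide/lipid anabolism),
gene–protein–reaction logic, thermodynamic constraints, or the absolute
flux values of any published reconstruction. Consequently, passing tests
demonstrate that the pipeline's machinery and the *qualitative*
C3-versus-C4 contrasts (growth and CO₂-fixation advantage, essentiality
containment, subtype ordering, denser-vs-more-redundant topology, more
correlated sets in C4) are implemented correctly — not that any
genome-scale number is reproduced. Users with full reconstructions can
load them as SBML and rerun every stage unchanged.

## Problem sizes and tolerances

The toy C3 model has ~90 reactions and the C4 model ~130; knockout scans,
flux variability and sampling at the default sizes (5000 warm-up / 2000
retained points) each complete in seconds to tens of seconds. LP
feasibility tolerance is $10^{-6}$, optimality $\sim10^{-8}$; sampler
feasibility $10^{-6}$; knockout class tolerance $10^{-6}$; coset threshold
$1 - 10^{-8}$; kinetics branch tie $10^{-9}$ relative. The pipeline
(`run_pipeline()`) logs every such default with the seed so reports are
self-describing.
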