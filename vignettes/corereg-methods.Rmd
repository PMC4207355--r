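---
title: "Methods: constraint-based modeling and core regulatory set extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based modeling and core regulatory set extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corereg)
```

# The model

A genome-scale metabolic model is a stoichiometric matrix $S$ ($N$
metabolites $\times$ $M$ reactions) with per-reaction flux bounds and
gene–protein–reaction (GPR) rules. Flux balance analysis (FBA) assumes
steady state and optimizes one flux, conventionally the biomass
pseudo-reaction whose flux is the growth rate:

$$\max v_{biomass} \quad \text{s.t.} \quad \sum_{j=1}^{M} S_{ij} v_j = 0
\;\; \forall i, \qquad v_j^{min} \le v_j \le v_j^{max} \;\; \forall j.$$

Flux variability analysis (FVA) solves the same program twice per
reaction, maximizing and minimizing $v_j$, giving the attainable interval
$[v_j^{min}, v_j^{max}]$ under the model's constraints. All fluxes are in
mmol gDW⁻¹ h⁻¹; growth rates in h⁻¹. The sign convention for exchange
pseudo-reactions is negative = uptake.

## Why regulation as bound contraction

A purely metabolic model over-predicts what a stressed cell can do:
transcriptional down-regulation removes enzymatic capacity that the
stoichiometry alone would allow. The approach implemented here contracts
the flux bounds of down-regulated reactions multiplicatively and then
asks a sharper question than "what changes?" — namely *which minimal set
of contractions explains all of the changes*. That set (the core set) is
where regulation actually bites; everything else follows through
stoichiometric coupling.

## From transcripts to fold changes

Per-gene expression levels are combined into an enzyme-level value by the
GPR semantics: complex subunits (`and`) contribute their **minimum** (the
scarcest subunit limits assembly), isozymes (`or`) contribute their
**sum** (total catalytic capacity). The reaction fold change is the ratio
of the combined level under stress to the combined level under control,
$c_j = \ell_j^{stress} / \ell_j^{control}$.

Two conventions were genuinely open and are fixed as follows:

* **Levels first, ratio second.** One could combine per-gene fold changes
  instead of levels, but the sum-over-isozymes rule is only meaningful on
  levels (a sum of ratios has no capacity interpretation), so the
  level-then-ratio convention is applied at every node.
* **Undefined is inert.** A missing gene measurement or a zero control
  level makes $c_j$ undefined; it is set to 1 (no regulation) rather than
  guessed. A zero *stress* level with positive control would give
  $c_j = 0$, which the downstream machinery cannot accept ($c_j > 0$ is
  required); it is floored at `min_fold = 1e-9` — a contraction so severe
  it blocks the reaction numerically while keeping the map valid.

Only $c_j < 1$ acts on the model. The unregulated FVA bounds are already
the widest attainable, so relaxing them ($c_j > 1$) cannot change any
optimum; up-regulated values are retained in the map but marked inert.

## The core-set extraction loop

Step 1 computes FVA on the unregulated model **without any biomass
constraint** — these ranges $[v_j^{L,UR}, v_j^{U,UR}]$ are the widest
bounds the network admits under its nutrient constraints (exchanges stay
open here; closing them is specific to cycle detection). Then for
$k = 1, 2, \dots$:

1. **Contract** (for $c_j < 1$): $v_j^{U,R} = v_j^{U,UR} c_j$ and
   $v_j^{L,R} = v_j^{L,UR} c_j$. For a reversible reaction the negative
   lower bound shrinks toward zero — the reverse direction loses capacity
   by the same factor. The rule is applied unconditionally, including the
   rare forced-flux case $v_j^{L,UR} > 0$, because the contraction
   equations carry no side condition; the reversibility remark only
   explains the common case. One $c_j$ serves both directions (no
   direction-specific expression signal exists).
2. **Attenuate**: maximize biomass under unregulated and regulated
   bounds; the relative change $(v^{max,UR} - v^{max,R})/v^{max,UR}$
   measures how much the remaining regulation costs. The threshold is
   **relative** (an absolute 2% of a dimensionless growth rate would be
   scale-dependent).
3. **Extract**: FVA with biomass pinned at $v^{max,R}$; a regulated
   reaction joins the core set of order $k$ if its achieved upper bound
   equals the imposed $v_j^{U,R}$ **or** its achieved lower bound equals
   the imposed $v_j^{L,R}$ — the disjunction, because either binding
   direction proves the constraint is doing work.
4. **Neutralize and repeat**: $c_j \gets 1$ for core members, exposing
   subordinate focal points at order $k+1$.

Termination: when the attenuation drops below the threshold the current
core set is **recorded first and the loop stops after** — minimal-effect
core sets are part of the result (flagged `biomass_effect = "minimal"`),
not discarded; an empty core set or `max_k` (default 6, comfortably above
the quaternary sets seen in practice) also stops the loop.

`verify_core_sufficiency()` is the method's own consistency check:
applying the contraction only to the core members and running FVA at that
model's biomass optimum must reproduce the fully regulated flux ranges,
reaction by reaction.

# Cycle curation

A thermodynamically infeasible cycle is an internal loop that carries
flux with no net exchange — a perpetual machine the stoichiometry permits
but thermodynamics forbids. Detection:

* **Exchanges are closed** (bounds $[0,0]$) so that only internal loops
  can carry any flux at all. With open exchanges, legitimate high-flux
  pathways would also hit bounds and pollute the candidate set.
* FVA with no biomass constraint flags every reaction whose extremum
  reaches the default bound magnitude $B$ (the conventional "infinity",
  1000 mmol gDW⁻¹ h⁻¹) within a band of $10^{-6}$ — only loops can do
  that when nothing enters or leaves.
* The null space of $S$ restricted to the candidate columns is computed
  by rank-revealing Gaussian elimination (reduced row echelon form); each
  free column yields a basis vector, which is a flux mode of the closed
  network. This sparse basis keeps cycles interpretable (a planted
  7-ring shows up as one vector of support 7), unlike an orthonormal SVD
  basis which mixes loops. Vectors are reported smallest-support first —
  two-reaction equivalent pairs are the easy calls and are reviewed
  before larger loops.
* Two-reaction cycles are classified `equivalent_pair` only when the two
  stoichiometric columns are equal or negated — same participants, same
  cofactors; a support-2 vector over columns that differ (say NAD vs
  NADP coupling) stays `multi_reaction`.

What the package deliberately does **not** do: choose between removing a
reaction and restricting its direction. That decision rests on literature
and annotation evidence no algorithm has; `curate_until_closed()` takes an
explicit, human-supplied action list, applies it, re-detects, and reports
any surviving cycles rather than silently resolving them. The only
automated restriction is the Gibbs rule: if the free-energy range
including its error bar lies entirely more than 4 kcal/mol from zero, the
reaction is limited to the direction the sign dictates; bounds already
consistent are untouched, making the rule idempotent.

# Numerical choices

* **LP engine.** No linear-programming package exists in the target
  environment, so the package carries a dense bounded-variable two-phase
  primal simplex. Bland's smallest-index rule is used for entering and
  leaving variables — termination is guaranteed and determinism matters
  more than pivot counts at these problem sizes (tens of reactions). The
  basis is refactorized by `solve()` every iteration; artificial
  variables absorb redundant mass-balance rows (conserved moieties), so
  no rank pre-processing is needed. Feasibility/optimality tolerance is
  $10^{-9}$.
* **Flux comparisons** use absolute tolerance $10^{-6}$: with bounds of
  magnitude 1000, purely relative tests would be fragile near zero.
* **Bound-equality in core-set membership**:
  $|achieved - imposed| \le \max(10^{-6}, 10^{-6}|imposed|)$. The
  description of the method writes exact equivalence, which floating
  point cannot deliver.
* **Pinning "at max biomass"** sets the biomass lower bound to
  $v^{max}(1 - 10^{-6})$ instead of an exact equality, avoiding
  solver-level infeasibility from optimal-value round-off.
* **Degenerate inputs**: infeasible and unbounded LPs are reported in the
  solution status, never as errors; an infeasible *pin* is an error that
  names the first conflicting constraint; a model whose unregulated
  biomass optimum is zero cannot be attenuated and errors out; yield-space
  grid points with zero minimal nutrient flux are flagged degenerate.

# The synthetic world

The generators exist so that every claim the package makes is testable
without any external model or download:

* `make_toy_network()` builds branched substrate→product networks with a
  biomass reaction draining every branch, GPRs mixing single genes,
  complexes, and isozyme pairs, unit stoichiometry, and single-token
  formulas (`X`) so balance holds by construction. Uptake is bounded at
  10 mmol gDW⁻¹ h⁻¹, the conventional normalization for glucose.
* `plant_regulation()` inverts the GPR semantics: to impose a fold $f$ on
  a complex it scales the *weakest* subunit; on an isozyme set it scales
  *all* transcripts (so the sum scales). Control levels are uniform in
  [50, 150] — arbitrary positive intensities; only ratios matter, which
  the scale-invariance property test confirms.
* `make_bottleneck_fixture()` plants one severe, provably binding
  contraction on the mandatory biomass path (fold $0.8/n_{branches}$,
  which binds because the branch optimum is $10/n$ while the contracted
  bound is $10 f$, and yields a 20% attenuation), one mild non-binding
  contraction (fold 0.9) that the core set must *exclude*, and inert
  up-regulated decoys (fold 1.5). The parameter-recovery suite demands
  the planted reaction be recovered in 100 of 100 seeds, and the
  sufficiency property must hold at every order.
* `brute_force_flux_extrema()` is the independent oracle: it enumerates
  every basic solution of $\{Sv = 0, lb \le v \le ub\}$ (all column
  subsets of size rank $S$, all bound assignments of the rest) and shares
  no code with the simplex. The ceiling of 12 reactions keeps enumeration
  under a second.

What the synthetic world does **not** emulate: the degree distribution,
cofactor coupling density, or compartmentalization of a real
genome-scale network; microarray noise structure; correlated expression
across operons. A green test suite therefore establishes the
*correctness of the algorithms on networks whose ground truth is known by
construction* — not the biological accuracy of any particular model's
predictions. Reproducing published flux tables for a specific organism
additionally requires that organism's curated model file and expression
series as inputs (see the scenario presets, which encode those protocols:
hydrogenase blocking with butyrate feed for CO gassing, 80%-of-maximal
ammonia/phosphate uptake for cell recycle, free cofactor interconversion
for redox analysis, and the standard growth-rate pins 0.52, 0.47, 0.32,
0.184, 0.182, 0.18, 0.17, 0.07 h⁻¹).

# Known limitations

* The simplex is dense and refactorizes every iteration: right for
  desk-scale and mid-size models, slow for a 1,462-reaction model's full
  FVA (thousands of LPs), where a revised implementation with factor
  updates or an external solver would be the upgrade path behind the same
  `fba()`/`fva()` surface.
* Table-style production values can be computed either as FVA maxima at
  fixed substrate uptake or as fluxes of a single FBA optimum; published
  tables do not always say which. `run_scenario()` reports FVA ranges —
  the more conservative statement — and a point solution is one `fba()`
  call away.
* The redox-free pseudo-reactions exchange NAD⇌NADH without tracking the
  proton/electron pair (a sink convention); they answer "what if reducing
  equivalents were free", not "by which mechanism".
* No kinetics, no time course: the biphasic fermentation is two static
  configurations (acidogenic/solventogenic), and regulatory *mechanism*
  (which transcription factor does the contracting) is interpretation
  left to the user.
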