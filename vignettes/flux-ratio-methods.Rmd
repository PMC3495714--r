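---
title: "Flux-ratio constrained flux balance analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-ratio constrained flux balance analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbratio)
```

## The model

Flux balance analysis treats a metabolic network at steady state: the
stoichiometric matrix $S$ (metabolites × reactions) and the flux vector $v$
satisfy $S v = 0$ within the reaction bounds $l \le v \le u$. All fluxes are
in mmol per hour per gram dry cell weight; growth (the biomass drain flux)
is in 1/h. Bounds default to the conventional box of ±1000 — effectively
unbounded at these flux scales — with irreversible reactions at $[0, 1000]$;
infinite bounds in input files are clamped to this box so every linear
program is bounded.

A **flux-ratio constraint** fixes how a metabolite pool is split among
competing consumers:

$$\frac{\sum_i w_i v_i}{\sum_j w_j v_j} = k
\quad\Longleftrightarrow\quad
\sum_i w_i v_i - k \sum_j w_j v_j = 0 .$$

The right-hand form is linear, so the constraint is stored as one extra row
of $S$ with entries $+w_i$ (numerator columns) and $-k w_j$ (denominator
columns) and a zero right-hand side. Nothing else in the pipeline changes:
the assembled matrix has $|\text{metabolites}| + |\text{ratio rows}|$ rows,
and any LP solution satisfies every ratio to solver precision. Ratio rows
are appended after the metabolite rows in insertion order, which keeps
matrix assembly reproducible.

Three conventions deserve note:

* Ratios act on **net signed fluxes**. Every use in practice constrains
  irreversible forward reactions; when a participating reaction is
  reversible the package warns, because a net-flux quotient may not be what
  an enzyme-level ratio intends. This keeps the problem linear (no absolute
  values).
* $k = 0$ is allowed and forces the numerator fluxes to zero — the ratio
  expression of a knockout. The symmetric case (denominator knockout, which
  would need $k = \infty$) is instead imposed by zeroing the reaction
  bounds, which `engineering_edit(mode = "knockout")` does.
* Multi-reaction sides default to unit weights (a plain sum); weights are
  exposed for generality.

An infeasible ratio — one incompatible with the rest of the network — makes
the LP infeasible, and the solver reports that status with an empty flux
vector. It can never return a silently wrong answer, because the ratio is a
hard equality row.

## The objective

All solves use a lexicographic two-stage objective: (i) maximize the growth
flux; (ii) fix growth at no less than $(1 - \varepsilon)\,\mu^{*}$ (default
$\varepsilon = 10^{-6}$, the `growth_fix_tolerance`) and minimize the total
flux $\sum_r |v_r|$. Stage 2 is the standard parsimonious construction:
each flux is split into non-negative forward and reverse parts so the
problem stays a pure LP. Two consequences matter for users:

* Stage 2 may shave growth by up to $\varepsilon\,\mu^{*}$ in relative
  terms; reported growth comes from the achieved flux vector, so tests
  comparing growth values should allow about `1e-5` of slack.
* Alternate optima are not enumerated. Objective values are unique;
  individual fluxes are unique only where the stage-2 objective makes them
  so. The headline quantities asserted in the test suite (growth, total
  flux, constrained ratios, the exchange fluxes of the main products) are
  stable under this solver, but downstream analyses of single internal
  fluxes should treat them with the usual FBA caution.

Total flux includes all columns, exchanges included; `solve_options()` has a
flag to exclude exchanges from the stage-2 objective for users who prefer
the internal-flux-only convention.

## The linear programming backend

The package carries its own dense bounded-variable two-phase primal simplex
(`R/simplex.R`) with Bland's smallest-index pivoting rule throughout.
Flux balance problems produce heavily degenerate bases — many variables
pinned at zero, equality rows everywhere — and Bland's rule guarantees
termination on them at the cost of some speed, which is irrelevant at the
problem sizes involved (tens of rows; a full 36-point scan of the bundled
model solves in a few seconds). A presolve substitutes out variables fixed
by equal bounds (the glucose and proton pins), drops zero-capacity split
variables, and sign-normalizes rows. Feasibility of a returned solution is
auditable against `lp_tolerance` (default $10^{-9}$); phase-1 declares
infeasibility when its optimum exceeds $10^{-7}$ relative to the right-hand
side scale. The solver is deterministic, so identical inputs give identical
outputs and pipeline reruns are byte-stable.

With finite bounds everywhere an FBA problem cannot be unbounded; the
`"unbounded"` status is retained in the solution contract for completeness
but is unreachable under defaulted bounds.

## The specific proton flux

The specific proton flux (SPF) is the net rate of proton movement across
the membrane: negative when protons leave the cell (acidogenesis), slightly
positive when they are taken up (solventogenesis). The proton exchange
reaction is written secretion-positive over the extracellular proton, so
`set_spf(model, spf)` pins that exchange at $-\text{SPF}$ (both bounds).
Scans fix the glucose uptake as an equality (default 10 mmol/(h·gDCW), the
conventional simulation condition; a flag relaxes it to an upper bound) and
record one row per grid point, infeasible points included, keyed by SPF so
the result is invariant to grid order. The default grid spans −30 to +5 in
unit steps, the physiologically meaningful range.

## The bundled clostridial core model

`build_toy_model()` constructs a ~60-reaction model of *C. acetobutylicum*
primary carbon metabolism designed so that all ratio-constraint behavior is
exercisable offline. Its skeleton is standard: lumped glycolysis
(glucose → 2 pyruvate + 2 ATP + 2 NADH + 2 H⁺), the lactate (LDH) and
pyruvate:ferredoxin oxidoreductase (PFO) branches, the irreversible
ferredoxin block (PFO, hydrogenase HYDA at 2 H⁺ + Fd_red → H₂ + Fd_ox, and
the NAD⁺/NADP⁺ ferredoxin oxidoreductases), acetate via PTA/AK, butyrate via
THL–BHBD–CRO–BCD–PTB–BK (PTB and BK reversible, as thermodynamics
requires), ethanol via the aldehyde/alcohol dehydrogenase activities AAD_1
and AAD_3, butanol via AAD_2 and an NADPH-dependent butanol dehydrogenase
(the dedicated butanol dehydrogenases are NADPH-preferring), acetone via the
two CoA-transferase activities and acetoacetate decarboxylase, and a
CO₂/bicarbonate split feeding pyruvate carboxylase (which releases one
proton, as the textbook stoichiometry does).

The proton economy is the load-bearing design, because the SPF constraint
only means something if protons are tracked honestly:

* Acids (acetate, butyrate, lactate, succinate) leave by undissociated-acid
  diffusion, carrying exactly one proton each, irreversibly outward.
  Extracellular acetate and butyrate re-enter **only** through the
  CoA-transferase reactions, which import the acid's proton.
* An F-type ATPase pumps protons outward at ATP expense; a bounded passive
  leak (≤ 3 mmol/(h·gDCW)) admits protons inward down the gradient; CO₂ can
  hydrate to bicarbonate and leave as carbonic acid.
* Ammonium enters by H⁺ symport and phosphate by 2 H⁺ symport, feeding the
  biomass nitrogen and phosphorus demand, so growth itself consumes part of
  a proton influx.
* Acetyl-CoA synthetase (lumped at a 2-ATP cost) re-assimilates cytosolic
  acetate, so the acetate production forced by the THL:PTA ratio need not
  be secreted during solventogenesis.
* An acetoin/2,3-butanediol overflow branch at pyruvate (both are
  documented minor products of this organism) consumes pyruvate, protons,
  and NADH without exporting any proton — the relief valve that keeps
  deeply CoAT-suppressed strains feasible at positive SPF.

The biomass drain is deliberately schematic: one acetyl-CoA, one pyruvate,
1.2 oxaloacetate, 2 ammonium, 13 ATP, 1 NADPH, and 6 NADH per unit growth,
releasing 2 H⁺ (most ATP-hydrolysis protons are treated as reabsorbed by
biosynthetic condensations). The large NADH term lumps all biosynthetic
reducing power; it is what lets growth, rather than obligatory butanol
production, absorb the glycolytic NADH during fast acidogenic growth. The
ATP cost makes ATP the growth-limiting currency, so growth peaks where acid
production pays best — late acidogenesis — as observed. These coefficients
were tuned once, against the qualitative invariants below, and frozen; they
are exposed through `toy_model_config()` only where a user has a principled
reason to move them (glucose uptake, ATP cost, the succinate branch).

With the five wild-type ratio constraints attached
(`wildtype_ratio_set()`: butyrate:acetate re-uptake 0.63, PFO:LDH 10,
CO₂ export:hydration 5, THL:PTA 2, THL:AAD_1 10) and glucose fixed at 10,
the frozen fixture satisfies, by construction and verified in the test
suite:

* feasible SPF window $[-15, +5]$ (the LP is infeasible beyond the efflux
  capacity of the proton-coupled pathways, mirroring the feasibility
  cutoff genome-scale models show at fixed glucose — the exact cutoff is a
  fixture property, not a calibration target);
* growth maximum at SPF $-2$, an interior point in late acidogenesis;
* at SPF $-15$: butyrate > acetate > lactate secretion, H₂:CO₂ = 1.16;
* at SPF $+5$: both acids net-consumed, butanol > ethanol, succinate
  absent, hydrogen well below its acidogenic level;
* every ratio residual below $10^{-14}$.

## Strain-design arithmetic

Knockdown by a fraction $f$ multiplies a numerator-side ratio by $1-f$ and
divides a denominator-side ratio by $1-f$ (so 80% knockdown maps 10 → 50
and 0.25 → 1.25). Over-expression by $p$ percent uses the multiplier
$2^{p/100}$ — the doubling-per-100% convention inferred from the printed
progression 10 → 5, 2.5, 0.3125 at 100%, 200%, 500% — applied to the edited
side; a linear convention ($1 + p/100$) is selectable, since the doubling
rule is an inference rather than a stated law. The two operations are
mutually inverse where defined. Knockouts zero the bounds of the targeted
side's reactions rather than sending $k$ to infinity.

The wild-type value of an *unconstrained* branch ratio varies with the SPF;
`wildtype_ratio_profile()` extracts it from a scan as a piecewise-linear
profile (undefined points, where the denominator flux vanishes, are
dropped), `scale_profile()` applies a proportional knockdown, and
`simulate_strategy(..., profile_ratios = )` re-pins the constraint from the
profile before each SPF point is solved. The assumed solventogenic
reference of 0.25 for the PTB:AAD_2 split is shipped as the named constant
`FBR_WT_PTB_AAD2`, flagged as an assumption rather than a computation.

## Known limitations

* The fixture is **qualitative**. Its flux magnitudes are not those of a
  genome-scale reconstruction (reproducing them is explicitly out of
  scope), and passing the ordering tests says nothing about quantitative
  accuracy on real data — the same caveat the underlying modeling approach
  carries even at genome scale, where biomass composition and glucose
  uptake both vary with the SPF in ways the fixed-input protocol ignores.
* With roughly fifty reactions and six simultaneous ratio equalities, the
  fixture has very few degrees of freedom. Its proton-destruction capacity
  at fixed glucose is exhausted below a CoAT:BHBD ratio of about 0.1 at
  SPF +5: the 0.01 grid point of the deep-knockdown dose-response is
  infeasible there (it is feasible at SPF ≤ +4.5), and the corresponding
  acceptance check is intentionally left failing rather than widened. A
  genome-scale model, with an order of magnitude more routes, does not hit
  this ceiling.
* The core model has a single acetaldehyde producer and consumer, so the
  AAD_3:AAD_1 ratio is identically 1: the futile-acetaldehyde correction
  that ratio exists to impose on large networks holds here by construction,
  and imposing a different value is structurally infeasible. Strategy
  simulations on this fixture therefore omit that constraint.
* The PFO:LDH = 10 ratio pins lactate secretion to exactly one tenth of the
  PFO flux (≈ 1.5 mmol/(h·gDCW) at glucose 10). Lactate is the minor acid,
  as intended, but its absolute level cannot be pushed below that pin
  while the ratio is active.
* Elemental bookkeeping audits carbon and the conserved moieties (CoA,
  adenine nucleotide, phosphate, NAD(P), ferredoxin, nitrogen) per
  reaction; hydrogen and oxygen are left implicit (water is not a model
  species), which is why the proton bookkeeping above is handled by
  explicit design rather than by audit.

## Reproducing the numbers

Every empirical statement in this vignette is asserted by the test suite
(`tests/testthat/`), and `scripts/acceptance.R` recomputes the headline
quantities — the appended-row coefficients, the solved THL:PTA quotient,
and the knockdown/over-expression mappings — from a fresh model build:

```{r acceptance, eval = FALSE}
# from the repository root
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

```{r example}
model <- add_wildtype_ratios(build_toy_model())
sol <- solve_at_spf(model, spf = 5, glucose_uptake = 10)
glance(sol)
realized_ratio(sol, c("CoAT_ACETATE", "CoAT_BUTYRATE"), "BHBD")
```
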