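---
title: "Target-point guided growth-coupled strain design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-point guided growth-coupled strain design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainenv)
```

## The problem

A production strain is *growth coupled* when it cannot grow without
secreting the product of interest. Coupling matters because adaptive
laboratory evolution selects for growth: if secretion is obligatory, the
evolving population is pushed towards higher production instead of away
from it. On the product-versus-growth plane, all feasible steady states of
a constraint-based model `S v = 0`, `lb <= v <= ub` form the **production
envelope**: for each growth rate `g`, the interval between the LP minimum
and maximum of the product exchange flux with biomass pinned to `g`.
Coupling is **strong** when the minimum secretion *in the absence of
growth* is positive, **weak** when the minimum is positive only at some
growth rates, and absent otherwise.

## The method

The pipeline works backwards from a desired operating point rather than
searching directly for knockouts:

1. **Target point.** The user picks a `(growth, production)` point inside
   the wild-type envelope. The default primary target sits on the
   maximum-production edge at 3% of the maximal growth rate — high
   production, low but nonzero growth, minimal by-product drain.
2. **Minimal active reactions (MAR).** A MILP finds the smallest set of
   enzymatic reactions able to operate exactly at the target. Every
   non-exempt reaction `j` gets a binary `z_j` with
   `v_j - v_max,j * z_j <= 0`, the target fluxes are pinned (equality
   within `1e-6`), and `sum(z)` is minimised with zero optimality gap.
   Exchange pseudo-reactions and diffusion-based protein-free transports
   (CO2 and the like) carry no indicator: they are not enzymes, so
   switching them off is meaningless. The biomass and maintenance
   reactions carry indicators fixed to 1 — they count as active but can
   never be removed. For a reversible reaction split into forward/backward
   columns, `z_f + z_b <= 1` forbids futile two-way cycles that would
   otherwise hide activity. Bounding all non-MAR reactions to zero gives
   the **reduced model**, whose envelope is the candidate design envelope.
3. **Reinsertion.** Knocking out every non-MAR reaction is wasteful. The
   removed reactions are revisited one at a time (model order, so the run
   is deterministic; a seeded random order is available for exploration)
   and restored whenever their return does not lower the guaranteed
   minimum secretion at zero growth. What stays removed is the reported
   knockout set. Only the zero-growth minimum is protected: the maximal
   growth point may move after reinsertion, which is visible in the
   reported metrics and is a property of the method, not a defect.

Interior **target scanning** repeats steps 2–3 for equally spaced
production levels strictly between the envelope's maximal-growth point
(the *most probable* operating point under evolution, MP) and the primary
target, at the primary target's growth rate. Duplicated knockout sets are
collapsed (a flag disables this), and alternatives are kept only if their
minimum production is at least the primary envelope's and their knockout
count is within the configured cap (default 10). Points below the MP
production level are not scanned — designs found there are essentially
never better.

The **knockout budget** variant answers "what is the best guaranteed
minimum with at most K knockouts?". The inner adversarial LP (the cell
minimising secretion at zero growth, given knockouts `y`) is replaced by
its dual, the bilinear `u_j y beta_j` terms are linearised with big-M, and
the result is a single MILP over `y`. The MAR of the envelope under study
plus all exempt reactions are protected. By strong duality the MILP
objective *certifies* the minimum secretion; the implementation recomputes
the inner LP for the chosen knockouts and refuses to return if the
certificate disagrees (the symptom of a too-small big-M).

## Numerical choices

* Flux is treated as nonzero above `1e-9`; strong coupling needs a minimum
  secretion above `1e-6` mmol/gDCW/h. Both mirror common solver
  feasibility tolerances.
* Target fluxes are pinned as equalities within `1e-6`. Pinning by
  equality is the strictest reading of "operating at the point"; a
  `>=`-style target can be emulated by choosing a point on the envelope
  edge.
* The MILP optimality gap is zero: "minimal" active sets are only
  meaningful at exact optimality. Alternative optima exist in real
  networks; the solver is deterministic (fixed branching rules), so
  repeated runs return the same optimum, but it is *one* optimum, not a
  canonical one.
* `v_max` in the activity-linking constraints is each reaction's own upper
  bound, with 1000 substituted for unbounded reactions, and big-M defaults
  to 1000 with the certificate check above as the safety net.
* A knockout always removes both directions of a split reversible pair —
  deleting an enzyme deletes the whole reaction. Consequently, a removed
  direction whose partner is in the MAR cannot be deleted; reinsertion
  restores such half-pairs unconditionally first and warns if that alone
  breaks the baseline.
* The envelope grid spans LP-minimal to LP-maximal growth with 100 points
  including endpoints by default.

## Solver

No LP/MILP library is assumed: the package carries a dense two-phase
bounded-variable primal simplex with Bland's rule (metabolic LPs are
heavily degenerate; Bland guarantees termination) and a depth-first
branch-and-bound for the binaries. This is entirely adequate for the
shipped models and for small networks. For genome-scale models set
`options(strainenv.backend = "scipy")` to delegate to HiGHS through a
bundled Python bridge; the test suite uses that same bridge as an
*independent oracle* against the built-in solver, never as a replacement
for it.

## What the toys do and do not establish

`make_coupling_toy()` is a 5-metabolite, 8-reaction network whose envelope
is hand-derivable: maximal growth 4.5 1/h, product upper edge `10 - g`,
and a single bypass (`R5`) whose removal makes secretion obligatory
(`min = g + 1`, strong coupling through the ATP-maintenance demand).
`make_branched_toy()` adds a second bypass and a direct product route, so
reinsertion and the budget solver have real choices; the reversible
variant exercises the split-pair constraint. Brute-force enumeration
oracles (`brute_force_mar()`, `brute_force_cap()`) recompute every MILP
answer independently.

Green toy tests establish algorithmic correctness — LP/MILP optimality,
envelope geometry, preservation invariants — on networks small enough to
enumerate. They do not establish biological realism: the toys have no
cofactors, no by-product spectrum, no alternate optima, and no
thermodynamic constraints, all of which shape results on genome-scale
models. Published genome-scale checks (wild-type growth 0.91 1/h on
glucose minimal medium for the *E. coli* model, g/g yields, knockout-set
envelope verification) are implemented in the acceptance tests and run
whenever the BiGG model files are placed under
`tests/testthat/bigg_models/`; they cannot be bundled.

## Open design points, resolved

* **Which transports are exempt.** Only a category, not a list, is ever
  stated for protein-free diffusion transports; the shipped per-model
  configs default to CO2, O2, H2O and NH4 transport and are a documented
  judgement call the user can edit.
* **MP production at the MP point.** Minimum and maximum product flux at
  maximal growth coincide for strongly coupled designs; both are reported
  for the cases where they do not.
* **Reinsertion order.** "Sequential" leaves the order open; model order
  is used for determinism, and the order can change which locally minimal
  set is found when alternatives exist.
* **Budget outer objective.** The budgeted variant certifies the
  zero-growth minimum (the strong-coupling statistic) by default;
  `inner = "max_growth"` instead certifies secretion at the reference
  maximal growth, closer to the classic robust-knockout formulation.
* **Anaerobic yeast.** Anaerobiosis is imposed by deleting the named
  oxidase reaction(s) rather than closing the O2 exchange, because trace
  oxygen remains biosynthetically essential in the yeast model; for the
  *E. coli* model the O2 exchange is simply closed.

## Limitations

Reaction-level knockouts are reported; mapping to gene deletions through
GPR rules is out of scope. Alternative MILP optima mean knockout *sets*
(not their objective values) can differ between solvers. The built-in
simplex is dense and not intended for genome-scale performance. The
budget MILP assumes knockout candidates have zero lower bounds (true of
any irreversible-form model whose forced fluxes are protected).
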