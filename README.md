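# strainenv

Target-point guided design of growth-coupled production strains from
constraint-based metabolic models.

## What it does, and for whom

Metabolic engineers want strains that *cannot grow without secreting* a
product, because evolution then works for the fermentation instead of
against it. Given a genome-scale model (SBML L3/FBC or BiGG-style JSON), a
biomass reaction and a product exchange, `strainenv`:

1. computes the **production envelope** — for each growth rate `g` on a
   grid, the LP minimum/maximum of the product exchange flux subject to
   `S v = 0`, `lb ≤ v ≤ ub`, `v_biomass = g`;
2. solves a MILP for the **minimal active reactions (MAR)** at a chosen
   target point `(g*, p*)`: minimise `Σ z_j` subject to
   `v_j − v_max,j · z_j ≤ 0` for every non-exempt reaction,
   `z_f + z_b ≤ 1` for split reversible pairs, and the target fluxes
   pinned — then bounds all non-MAR reactions to zero;
3. **reinserts** removed reactions one at a time, keeping every reaction
   whose return preserves the guaranteed minimum secretion at zero growth,
   leaving a minimal knockout set;
4. **scans interior target points** between the target and the envelope's
   maximal-growth (MP) point to tabulate alternative designs, and solves a
   duality-reformulated bilevel MILP to answer "best guaranteed minimum
   with at most K knockouts".

Strong coupling means the minimum secretion at zero growth is positive;
weak means it is positive only at some growth rates.

No external optimiser is required: a bounded-variable simplex and
branch-and-bound are built in (an optional scipy/HiGHS backend exists for
genome-scale work, `options(strainenv.backend = "scipy")`).

## Worked example

```r
library(strainenv)
toy <- make_coupling_toy()     # 5 metabolites, 8 reactions, hand-derivable
res <- run_strain_design(toy, "EX_P", biomass_id = "R3", n_mid = 3)
res$wild_envelope
#> <production_envelope> EX_P vs R3
#>   growth range: [0, 4.5] 1/h over 100 grid points
#>   MP point: growth 4.5, product [0, 5.5]
#>   min production at zero growth: 0
#>   coupling: none
res$primary_design
#> <knockout_design> 1 knockouts: R5
#>   production min 1 / max 10; MP point growth 4.5, product [5.5, 5.5]
#>   coupling: strong
as.data.frame(res$comparison)
#>   envelope knockouts min_production max_production mp_production mp_growth
#> 1        1         1              1             10           5.5       4.5
#>   coupling knockout_ids target_ratio
#> 1   strong           R5       0.9865
```

Reading: the wild-type toy can grow at up to 4.5 1/h and never *has* to
secrete P (`coupling: none`). The pipeline targets the upper envelope edge
at 3% of maximal growth, finds that only `{R1, R2, R3, ATPM}` need to be
active there, and after reinsertion a single knockout — the bypass `R5` —
is enough: the designed strain must secrete at least 1 mmol/gDCW/h even
without growing (`g + 1` along the whole envelope), i.e. strong coupling.
The `target_ratio` column locates each scanned target as its production
over the primary envelope's maximum production at zero growth.

Yields in g/g substrate for host comparison:

```r
to_yield_units(27.49, 0.06005, 10, 0.18016)   # 27.49 mmol/gDCW/h acetate
#> [1] 0.9163079                                #   on 10 mmol/gDCW/h glucose
```

## Command line

```sh
Rscript inst/cli/strainenv.R run --model model.json --product EX_ac_e \
    --medium inst/extdata/config/iJR904_glc_aerobic.json --out results/
Rscript inst/cli/strainenv.R cap --model model.json --product EX_ac_e --max-knockouts 7
Rscript inst/cli/strainenv.R compare --hosts hosts.json
```

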