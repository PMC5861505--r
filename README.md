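# dcadesign

Constraint-based strain design for long-chain dicarboxylic acid (DCA)
production in oleaginous yeast.

Long-chain DCAs such as dodecanedioic acid (DDDA, the C12 diacid) are
polyamide/polyester monomers that *Yarrowia lipolytica* can secrete by
omega-oxidising fatty acids. Designing overproducer strains rationally
means interrogating a genome-scale metabolic model: which reactions are
flux bottlenecks worth overexpressing, which deletions couple product
secretion to growth, which NAD(H)→NADP(H) cofactor respecifications
relieve the NADPH demand of fatty-acid synthesis and omega-oxidation, and
what amino-acid co-feeding does to the acetyl-CoA supply. `dcadesign`
implements that toolbox for R users — modellers and metabolic engineers
working with SBML reconstructions of oleaginous yeasts (or any organism;
nothing is species-specific).

## What it computes

At its core is flux balance analysis: over the steady-state polytope
`{v : S v = 0, v_min ≤ v ≤ v_max}` it maximises a linear objective
`Z = Σ_j c_j v_j` with an exact built-in simplex (two-phase, Bland's
anti-cycling rule — no external solver needed). On top of that:

* **Flux-activity scanning** — activity `f_j = |v_j|` is ranged by an
  indicator MILP solved exactly by sign-branch enumeration; graded
  constraints `f_j ≤ f_min + k_att (f_wt − f_min)` (downregulation) and
  `f_j ≥ f_wt + k_int (f_max − f_wt)` (upregulation) give the max biomass
  `B_jk` per grid level, then the product is maximised at `biomass ≥ B_jk`
  to classify coupled over/under-expression targets.
* **Cofactor modification analysis (CMA)** — up to `k` NAD(H)↔NADP(H)
  specificity swaps maximising product yield under a biomass floor,
  solved by exact enumeration over swap twins, with a floor-sweep helper.
* **Growth-coupled knockout search** — iterated local search over ≤5
  deletions scored pessimistically (minimum product among growth-optimal
  states), so "coupled" is a certificate.
* **Context models + restoration scan** — GPR-projected expression
  (AND→min, OR→max), percentile thresholding with an
  essentiality guard, and per-reaction restoration improvements.
* **Flux-sum** turnover `Φ_i = 0.5 Σ_j |S_ij v_j|` and **BCAA
  supplementation** at a fixed carbon budget (C-mmol/gDCW/h).
* **Model plumbing** — SBML L2/L3+fbc read/write, curation ledgers (TSV),
  biomass assembly from compositions with GAM/NGAM, elemental
  mass-balance audits, and a scriptable pipeline
  (`run_pipeline()`, `inst/cli/dcadesign.R`).

Everything is validated against a bundled synthetic network
(`toy_model()`) whose scenario optima have closed forms documented in
`toy_manifest()`.

## Worked example

```r
library(dcadesign)

m <- toy_model()                      # YL-mini: 23 reactions, 24 metabolites, 15 genes
theoretical_max_yield(m, "EX_ddda", "EX_glc", uptake = 10)
#> [1] 2.553191

released <- condition_constraints(bounds = list(ATPM = c(0, 1000),
                                                BIOMASS = c(0, 0)))
cma_optimize(m, "EX_ddda", k = 1, biomass_floor = 0, constraints = released)
#> <cofactor_swap_result> k = 1  floor = 0
#>   baseline yield: 2.553191
#>   best swap: FAS  yield: 3.243243

sup <- supplementation_scan(m, "EX_ddda",
  supplements = list(leucine = list(exchange = "EX_leu", open = "LEUDEG")))
sup$table
#>  supplement   uptake product_opt
#>        none 0.000000    2.553191
#>     leucine 1.666667    3.191489

des <- knockout_local_search(toy_model(biomass_atp = 20, competing_sink = TRUE),
                             "EX_ddda", max_ko = 2)
des$deleted; round(des$product, 4); des$coupled
#> [1] "DDCAS"
#> [1] 0.8791
#> [1] TRUE
```

Reading the numbers: at a glucose uptake of 10 mmol/gDCW/h, one DDDA costs
6 acetyl-CoA (3 glucose) plus 11 NADPH (11/12 glucose through the PPP), so
the ceiling is 120/47 ≈ 2.553 mmol/gDCW/h. Swapping the FAS NADPH
requirement onto NADH cuts the PPP draw to 1 NADPH per DDDA: 120/37 ≈
3.243. Feeding 10 C-mmol/gDCW/h of leucine adds 5 mmol acetyl-CoA and
lifts the ceiling to 150/47 ≈ 3.191. In the ATP-limited variant, deleting
the competing dodecanoate sink forces 0.879 mmol/gDCW/h of DDDA at every
growth-optimal state — a growth-coupled design.

For genome-scale work, point the same functions at an SBML file:
`read_sbml("model.xml")`, then e.g. `scan_targets(model, "EX_ddda_e")` or
`cma_floor_sweep(model, "EX_ddda_e")`.

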