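---
title: "Model-guided strain design for dicarboxylic acid production: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided strain design for dicarboxylic acid production: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcadesign)
```

# Scope

`dcadesign` implements the constraint-based analyses used to design
dodecanedioic acid (DDDA) overproducing strains of oleaginous yeast:
flux balance analysis (FBA) with deterministic flux resolution, flux-sum
turnover profiling, flux-activity scanning for graded up/down-regulation
targets, cofactor-specificity (NAD(H)/NADP(H)) swap optimization,
growth-coupled knockout search, expression-derived context models with
restoration scanning, and branched-chain amino acid (BCAA)
supplementation. All methods run on any SBML model; a documented
synthetic network with closed-form optima anchors them to exact answers.

# The steady-state model

A metabolic model is a stoichiometric matrix $S \in \mathbb{R}^{m \times n}$
over $m$ metabolites and $n$ reactions, flux bounds
$v^{\min}_j \le v_j \le v^{\max}_j$ (mmol/gDCW/h; $\pm 1000$ stands in for
unbounded), gene–protein–reaction (GPR) boolean rules, and a linear
objective $Z = \sum_j c_j v_j$. FBA solves

$$\max_v \; \textstyle\sum_j c_j v_j \quad \text{s.t.} \quad S v = 0,\;
v^{\min} \le v \le v^{\max}.$$

Exchange reactions are written outward, so uptake is a negative flux;
convenience interfaces accept positive uptake magnitudes and negate them.
Growth-associated maintenance (GAM) is ATP stoichiometry inside the biomass
reaction; non-growth-associated maintenance (NGAM) is the fixed lower bound
of a dedicated ATP-hydrolysis reaction. Literature NGAM values for *Yarrowia lipolytica* are sometimes printed as
mmol ATP/gDCW without an explicit time unit; this package encodes NGAM as a rate bound (mmol/gDCW/h), the
conventional reading, and documents the choice here rather than silently.
Models carrying two biomass equations (carbon- versus nitrogen-limited
compositions) keep both; exactly one is made active per simulation through
the condition constraints.

## The LP kernel

No linear-programming package is available in this R installation that
survives the heavy degeneracy of steady-state flux polytopes, so the
package carries its own dense two-phase primal simplex using Bland's
anti-cycling rule throughout. Bland's rule guarantees termination on
degenerate instances at some cost in speed, which is irrelevant at the
sizes targeted here (tens to ~1500 reactions). Pivot tolerance is `1e-9`;
reported numbers are never rounded internally. Infeasibility and
unboundedness are reported as statuses, never as silent zeros. The tests
cross-check the kernel against an independent interior-point/simplex
backend (HiGHS, reached through the Python layer of the same environment)
on a panel of toy instances, and verify primal feasibility of every
returned state directly.

Alternate optima are a fact of flux cones, so every reported flux
*distribution* comes from `resolve_unique()`: the objective is pinned at
its optimum (tolerance `1e-9`) and total absolute flux $\sum_j |v_j|$ is
minimised via the standard positive/negative split. This parsimonious
representative is solver-order independent and carries no futile cycles.

## Flux-sum

The turnover of metabolite $i$ at a flux state is
$\Phi_i = \tfrac12 \sum_j |S_{ij} v_j|$; production and consumption halves
are equal at steady state, which the tests assert per metabolite.

# Flux-activity scanning

Flux activity is $f_j = |v_j|$. The wild-type activity $f^{WT}_j$ is taken
from the parsimoniously resolved biomass optimum. The feasible activity
range $[f^{\min}_j, f^{\max}_j]$ is defined by a mixed-integer program that
decomposes $v_j = f^+_j - f^-_j$ with binary indicators forcing one part to
zero. Because only the scanned reaction is decomposed, the binary pair
induces exactly two sign branches ($v_j \ge 0$ and $v_j \le 0$): the
package solves both branches as LPs and combines them, which is a complete
branch-and-bound for this structure and needs no big-M constant. The tests
require exact agreement with a signed-interval flux-variability oracle,
including the straddling case where $f^{\min}_j = 0$.

Graded perturbations then maximise biomass subject to

* downregulation (C1): $f_j \le f^{\min}_j + k_{att}\,(f^{WT}_j - f^{\min}_j)$,
* upregulation (C2): $f_j \ge f^{WT}_j + k_{int}\,(f^{\max}_j - f^{WT}_j)$,

with $k$ on a 0–1 grid (step 0.1 by default, the grid this family of
scans conventionally uses),
giving $B_{jk}$. The fourth step re-optimises the *product* exchange
subject to $v_{biomass} \ge B_{jk}$ and the same activity constraint. Two
deliberate choices:

* Statements of this scan in the literature sometimes print the
  fourth-step objective as minimising a succinate exchange even when
  succinate is not the target; this package treats the objective as "the
  targeted product" and makes the sense an explicit argument
  (`product_sense`) defaulting to maximise.
* Anchoring growth at $B_{jk}$ is implemented as an inequality
  ($\ge B_{jk}$), not an equality, to avoid spurious infeasibility from
  round-off; a `fixed-wt` mode anchoring at the unperturbed optimum is
  also selectable, since either reading of "fixing an optimal biomass" is
  defensible.

A reaction is classified `coupled-overexpression` when its product optimum
is non-decreasing along increasing $k_{int}$ and strictly increases
somewhere (tolerance `1e-6`), `coupled-downregulation` analogously along
tightening $k_{att}$, otherwise `neutral`.

# Cofactor modification analysis

CMA asks which $\le k$ reactions, when their NAD(H)/NADP(H) specificity is
swapped, most improve the product yield while biomass production stays
above a floor $v^{\min}_{biomass}$. The swapped matrix $S^{cMod}$ equals
$S$ except that the cofactor pair rows are exchanged for the chosen
reactions; a binary per reaction routes flux through the original or the
swapped copy, never both. The package realises this with explicit twin
reactions (`<id>_cmod`, added closed) and, because analyses of this kind
fix $k$ at 1, solves the bi-level program by exact enumeration over swap
sets — complete, duality-gap-free, and independent of any MILP
reformulation. A brute-force oracle that rewrites stoichiometry in place
(no twins) must agree with it in the tests. The primal–dual single-level
reformulation used elsewhere in the literature is intentionally not
reimplemented: with enumeration exact at small $k$, a big-M reformulation
would add approximation risk without adding capability.

Two conventions: the product measure
$\varphi = \tfrac12\sum_j |S_{product,j} v_j|$ reduces to the product
exchange flux when the product has a single exchange, and is reported via
the flux-sum machinery for generality. The biomass floor defaults to 10%
of the unconstrained optimum when unspecified; `cma_floor_sweep()`
tabulates several floors — the protocol for locating an unstated setting
when matching yield tables reported without one.

The bi-level statement nests an inner biomass *maximisation*, but a
literal reading would drive the product to zero whenever growth and
product compete for carbon, contradicting the worked yields it is meant to
produce. The package therefore honours the inner level through the floor:
the product optimum is computed subject to $v_{biomass} \ge
v^{\min}_{biomass}$. This matches the worked examples exactly and keeps
the floor the single interpretable dial.

# Growth-coupled knockouts

`knockout_local_search()` is a deterministic iterated local search over
deletion sets (add / drop / swap one reaction, at most `max_ko = 5`
deletions), in the spirit of genetic design by local search. The score of
a design is deliberately pessimistic: after deletion, growth is maximised,
then the product flux is *minimised* among growth-optimal states. A
positive score therefore certifies growth coupling — the product is
secreted at every growth optimum — rather than reflecting an arbitrary
solver vertex. Exchanges, biomass, maintenance, and spontaneous (no-GPR)
reactions are excluded from deletion by default. On the synthetic network
the search is certified against exhaustive enumeration of all sets of up
to two deletions.

# Context models and restoration scanning

Transcriptomics-driven strain optimisation builds a context-specific
model from an expression profile and then asks which reactions *removed*
by the data integration would, if restored, raise the product yield.
Rather than committing to any particular published integration algorithm,
this package uses a documented percentile-threshold scheme: reaction expression is the GPR projection of
gene values (AND → min, OR → max); evaluable reactions below the
`threshold_percentile` (default 25) of the reaction-expression
distribution are closed in id order, except that a closure which abolishes
growth is rolled back and flagged. `restoration_scan()` then reopens each
removed reaction alone and reports the product improvement under the same
biomass floor; a zero context baseline is flagged `from_zero` instead of
dividing. Applying this to a real organism additionally requires a
measured expression series and a genome-scale reconstruction, neither of
which ships here; the package's own evidence is the planted-partition
property — a synthetic profile with the
pentose phosphate pathway planted low must be recovered and its
restoration must raise the DDDA optimum from zero to the theoretical
maximum.

# BCAA supplementation

`supplementation_scan()` opens one amino-acid exchange at a time to an
uptake of `c_mmol_budget / carbon_atoms` (default budget 10 C-mmol/gDCW/h,
so leucine and isoleucine at C6 flow 1.667 mmol/gDCW/h and valine at C5
flows 2.0), maximises the product, resolves fluxes parsimoniously, and
reports flux-sums on a metabolite panel alongside a no-supplement
baseline. Carbon counts come from metabolite formulas with hard-coded
fallbacks (leu 6, ile 6, val 5) when absent. Supplementation is a pure
relaxation of the LP, so the product optimum can only rise — an invariant
the tests assert.

# The synthetic network

`toy_model()` is a 23-reaction, 24-metabolite, 15-gene network: glucose
uptake, lumped glycolysis (2 ATP + 2 NADH per glucose), lumped oxidative
PPP (12 NADPH per glucose), pyruvate dehydrogenase, acetyl-CoA
carboxylase, a lumped FAS producing dodecanoate from 6 malonyl-CoA and 10
NADPH, lumped omega-oxidation of dodecanoate to DDDA (1 NADPH + 1 NAD),
respiration (2 ATP per NADH), ATP maintenance, a biomass reaction drawing
acetyl-CoA and ATP, and a closed lumped leucine-degradation route. Every
non-exchange, non-maintenance reaction carries a unique synthetic gene.
The lumping is chosen so the standard scenarios have closed forms from
carbon/NADPH/ATP accounting, recorded in `toy_manifest()`: at glucose
uptake 10 the DDDA ceiling is $120/47$, leucine supplementation lifts it
to $150/47$, the FAS cofactor swap to $120/37$ (the glycolytic swap gives
$120/41$), and growth is $2u/3$ at the default biomass ATP cost.

Worth recording: enumerating *all* single swaps shows the FAS
respecification (NADPH → NADH) dominates the glycolytic one on this
network, because glycolytic NADH is free whenever the energy valve (excess
ATP hydrolysis) is open — the glycolytic value $120/41$ is retained in the
per-swap table as the documented second-best. On genome-scale models the
ranking is an empirical question per model.

Two documented variants serve specific studies. `biomass_atp = 20` makes
ATP binding at the growth optimum, so growth co-produces DDDA (the route
is a net ATP source); `competing_sink = TRUE` adds an energy-matched
dodecanoate leak (`ddca + nad -> ddca_e + nadh`). With the sink present
the growth optimum uses the carbon-cheaper leak and DDDA is free to be
zero; deleting the sink forces DDDA at every growth optimum — the
growth-coupling testbed for the knockout search. A plain secretion sink
would not work: it loses the omega-oxidation NADH and is never used at a
growth optimum, which is why the leak is energy-matched by construction.

The expression generator draws genes from a two-component lognormal
mixture (meanlog 7 vs 2, sdlog 0.4), components separated far beyond the
thresholding resolution, with the active fraction planted by seed. What
the synthetic data does *not* emulate: genome-scale redundancy (isozymes,
parallel pathways), noisy or condition-dependent expression, thermodynamic
infeasibility, and regulatory effects — so green tests here certify the
algorithms' correctness on exactly specified inputs, not predictive
accuracy on real transcriptomes.

# Numerical choices and degenerate inputs

* Simplex pivot tolerance `1e-9`; steady-state residuals asserted
  $\le 10^{-6}$; element-balance tolerance `1e-6`; protons and charge are
  not enforced in mass-balance checks.
* Tie-breaks are lexicographic on reaction ids everywhere a set is chosen
  (CMA ties are all reported; the knockout search keeps the incumbent on
  ties), making every output reproducible byte-for-byte.
* Reactions lacking bounds in an SBML file get the conventional defaults
  (0 or −1000, +1000) with a warning; reactions lacking formulas are
  reported as unchecked rather than assumed balanced; a biomass
  composition with no precursors and zero GAM is built but warned about.
* Degenerate scan cells (zero feasible activity) are reported with a
  `degenerate` status and classified neutral; infeasible perturbations are
  recorded as infeasible, never as zero.

# Problem sizes

The test suite and the acceptance script run entirely on the synthetic
network (23–25 reactions), where every optimum has a hand-derivable
closed form: full-precision assertions stay meaningful and the whole suite
solves a few thousand LPs in well under a minute. Scans on genome-scale
SBML inputs use the same code paths; only wall time grows.

# Known limitations

* The simplex is dense; models beyond a few thousand reactions would want
  a sparse or revised implementation.
* CMA beyond small $k$ enumerates $\binom{n}{k}$ subsets; the MILP
  reformulation that would scale further is intentionally out of scope.
* The context-model scheme is a percentile threshold, not a reimplementation
  of any published integration algorithm; its outputs on real data should
  be read accordingly.
* Charge balance, thermodynamics, and dynamic FBA are out of scope.
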