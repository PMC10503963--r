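---
title: "Methods: constraint-based co-culture modelling and 13C-MFA phenotype tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based co-culture modelling and 13C-MFA phenotype tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocultr)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters, what the
synthetic generator does and does not emulate, the numerical choices, and
the known limitations.

## Steady-state constraint-based modelling

Cellular metabolism is represented by a stoichiometric matrix $S$
(metabolites $\times$ reactions) and a flux vector $v$ in mmol/gDW/h.
Within the time scale of a culture experiment metabolite concentrations
change slowly relative to fluxes, so the steady-state constraint
$S v = 0$ applies and no kinetic parameters are needed. Flux balance
analysis (FBA) optimises a reaction flux — by convention the biomass
pseudo-reaction, whose flux equals the specific growth rate once scaled
by the dry mass of one millimole of biomass (`growth_rate_from_biomass_flux()`,
default 1 gDW/mmol, so 0.0306 mmol/gDW/h reads as 0.0306 /h) — over the
polytope $\{S v = 0,\; lb \le v \le ub\}$.

FBA solutions are generally degenerate. Flux variability analysis (FVA)
quantifies that: with the objective held at a fraction of its optimum
(default 1), each reaction's flux is minimised and maximised, and the
package reports the *midpoint* of the two extremes as its single-value
flux summary. The midpoint is a reporting convention, not an estimator of
a "true" flux; it is used consistently wherever a single number must be
quoted under alternate optima (notably the respirometry stages).

All linear programs go through `solve_lp()`, a dense bounded-variable
two-phase simplex written for the toy-to-moderate problem sizes this
package targets (tens to a few hundred reactions). `boot::simplex` is
retained as an independent backend; a test asserts both agree to 1e-6 on
a random fixture suite. Feasibility tolerance is 1e-9; steady-state
residuals of returned solutions are checked to 1e-6 in the tests.

## Exchange and medium conventions

An exchange reaction is written `met[e] ->`, so secretion is positive and
uptake negative. A medium is a table of maximum uptake rates plus a set
of *free species* (CO2, protons, water, ammonium and similar) that remain
exchangeable in both directions because no composition measurement
constrains them. `apply_medium_constraints()` sets the uptake bound of
each listed species to minus its maximum uptake, leaves free species
untouched, and closes the uptake of every other exchange; secretion
bounds are never modified. Medium magnitudes ship as editable
configuration, not as ground truth.

## Thermodynamic directionality

Given formation energies $\Delta G_f$ (kJ/mol) and concentration ranges
per metabolite, the reaction Gibbs energy
$\Delta G(c) = \sum_i s_i \Delta G_{f,i} + RT \sum_i s_i \ln c_i$
is monotone in each $\ln c_i$, so its extrema over the concentration box
sit at corners: the minimum takes substrates at maximal and products at
minimal concentration, and conversely. Reactions whose range is strictly
negative are fixed forward (lower bound raised to 0), strictly positive
reverse; straddling ranges leave bounds untouched, and bounds are only
ever tightened. A forced direction that contradicts an existing strict
bound is a modelling error and raises a named conflict.

Defaults: temperature 310.15 K, R = 8.314 J/mol/K, concentration box
1e-6 to 2e-2 mol/L for metabolites without explicit ranges. Water and
protons are exempt from the RT term (their activities are not usefully
described by a concentration) but keep their formation-energy
contribution. A full thermodynamic FBA with explicit $\Delta G$
variables inside the LP is deliberately not implemented: the
directionality projection plus the loop detector
(`detect_flux_loops()`, which certifies that no non-zero flux pattern
survives with all boundary reactions closed) achieves the stated purpose
— thermodynamically sensible directions and loop-free reported solutions
— at a fraction of the machinery.

## Expression-based extraction

Presence/absence calls are *inputs*: platform-specific normalisation and
detection calling are upstream of this package. Gene ubiquity is the
fraction of samples with a present call; GPR rules map gene scores to
reaction scores with AND = min and OR = max; reactions without a GPR
carry no expression evidence (`NA`), which is distinct from evidence of
absence. Connectivity smoothing assigns each reaction the mean expression
score of neighbours sharing a non-currency metabolite (the currency list
— ATP/ADP/AMP, NAD(P)(H), water, protons, CO2, phosphate, CoA, O2 — is
configurable; without it connectivity saturates). The combined score is
$w \cdot \text{expression} + (1-w) \cdot \text{connectivity}$ with
$w = 0.75$ by default; the weighting is a documented, tunable choice.

Pruning visits non-core reactions in ascending combined score (ties by
id, so runs are reproducible) and removes a reaction only if the model
still reaches `min_objective_fraction` of the original biomass optimum
and every core reaction can still carry flux (FVA check). The removal
threshold has no privileged value and is a required analysis parameter;
the pipeline template uses 0.25. The core set should contain the pathways
any downstream data will constrain — the template pins central carbon,
oxidative phosphorylation including maintenance and leak, glutaminolysis
and its nitrogen disposal, because the respirometry and tracer stages
constrain exactly those.

## Co-culture assembly and multi-objective analysis

`merge_models()` tags each cell's internal compartments with its label —
cytosol becomes the bare label (`pyr[bm]`), other compartments are
prefixed (`bm.m`) — while extracellular metabolites unify by id into one
shared space and duplicated exchanges collapse to a single copy with
union bounds. Internal reaction ids get a `_tag` suffix; both biomass
reactions are registered. Cross-feeding is therefore only possible
through the shared `[e]` pool, which a test verifies structurally and by
exhibiting a stromal-to-myeloma pyruvate shuttle on the paired toy
models.

Because the two cells' biomasses are separate objectives, single-FBA
answers are arbitrary. `pareto_front()` maps the trade-off by an
epsilon-constraint scan: cell A's biomass is constrained to a uniform
grid of levels spanning its own optimum (21 by default) and cell B's is
maximised at each; dominated and duplicate points are filtered. The scan
is equivalent to mapping the two-objective Pareto surface and keeps the
implementation transparent. The package reports the whole front rather
than asserting any particular point (such as equal growth of both
cells); the acceptance script separately computes the maximal
equal-growth point as a summary.

## In-silico respirometry

The four-stage oxygraph protocol is simulated on the unperturbed model
each time:

1. **basal** — biomass objective;
2. **oligomycin** — ATP synthase fixed to 0, complexes I/III/IV blocked
   from running in reverse, biomass objective;
3. **FCCP** — an uncoupler is a protonophore, so the proton-leak bound is
   lifted, and complex IV flux is maximised;
4. **rotenone + antimycin A** — complexes I and III fixed to 0, biomass
   objective.

Oxygen is reported as the magnitude of the oxygen-exchange flux (in a
co-culture, per-cell complex IV flux should be reported instead, since
the exchange is shared). Because each stage's optimum leaves the oxygen
flux underdetermined in general, the default convention fixes the stage
objective at its optimum and reports the FVA midpoint of the oxygen
reaction ("midpoint"); a "single" convention reporting the raw solver
solution is selectable. Under the midpoint convention the leak fixture
has a hand-computable oracle: with synthase blocked, the only proton
route is the leak (capacity $L$), each half-O2 pumps $p$ protons, the
stage oxygen range is $[0, L/p]$ and the reported value is $L/(2p)$.
Derived quantities follow the standard definitions: ATP-linked = basal −
oligomycin, spare capacity = FCCP − basal.

## EMU-based 13C metabolic flux analysis

Atom transitions are written in a plain-text grammar
(`v1: A (abc) -> B (ab) + C (c)`), with `|` separating alternative
mappings of rotationally symmetric species (expanded into
equal-probability variants). Metabolites only consumed are substrates,
only produced are products, and both are balanced. The free fluxes are a
null-space parameterisation chosen by QR column pivoting on $S$
(overridable); every remaining flux is linear in them.

The EMU decomposition walks backwards from each measured fragment,
collecting exactly the metabolite atom subsets needed; size-$s$ EMUs
satisfy a linear balance system whose inputs are substrate EMU
distributions (from the tracer definitions, purity default 0.99,
natural-abundance correction assumed done upstream) and convolutions of
smaller EMUs. Isotopic steady state is assumed throughout; no transient
MFA. A brute-force oracle — fixed-point iteration of the full
per-metabolite $2^k$ isotopomer balances, an entirely different algorithm
and state space — pins the simulator to 1e-8 in the tests.

Fitting minimises the variance-weighted SSR over every MID entry and
measured flux. The optimiser is bound-constrained Levenberg–Marquardt
(`minpack.lm::nls.lm`) run on the *logarithm* of the free fluxes: the
network convention is irreversible non-negative fluxes spanning orders of
magnitude, and log-scaling conditions the steps dramatically better than
the raw scale (raw-scale runs stall in plateaus). Restarts begin at
random feasible points built by averaging random vertices of the flux
cone and blending towards a strictly positive interior point (a
max-min-flux LP), so every labelled pool keeps flowing at the start.
Identifiability is checked as full column rank of the residual Jacobian
at generic feasible points. Determinism is guaranteed given the seed.

The chi-square verdict uses df = (independent measurements − free
fluxes), where a normalised MID of size $n$ counts as $n$ independent
values, and a two-sided 95% band — an SSR far *below* df flags
overstated uncertainties just as one far above flags lack of fit.
Monte-Carlo confidence intervals resample synthetic datasets around the
fitted values with the measurement standard deviations, refit each
(starting from the point estimate plus optional fresh restarts), and
take 2.5/97.5 percentiles per flux; the point estimate is included in
the percentile sample, so intervals always contain it.
`export_intervals()` maps fitted-flux intervals onto constraint-based
reaction ids (with a sign flip for the uptake convention) and
`apply_flux_intervals()` intersects them with the model bounds — the
"phenotype tuning" step. If tuning makes the model infeasible, the error
reports a greedily found set of tuned reactions whose relaxation restores
feasibility.

## The synthetic study system

The generator produces everything the pipeline consumes, deterministically
from a seed:

* **Two toy cells** (~50 reactions each) covering lumped glycolysis,
  pyruvate oxidation/TCA, citrate overflow, glutaminolysis with ammonium
  disposal, serine and alanine branches, an electron transport chain with
  explicit matrix/intermembrane proton pools (complex I pumping
  $p - 6$ protons so the total per half-O2 is the configurable pump
  stoichiometry, default 10), ATP synthase (3 protons/ATP), an optional
  proton leak (default capacity 2), ATP maintenance, and a biomass drain
  (4 pyruvate + 15 ATP per unit, an invented composition). Every internal
  reaction is elementally balanced, using opaque moiety symbols for the
  cofactor cores, so `check_balance()` returns clean. The myeloma-like
  variant doubles glucose/glycolytic capacity and cuts oxygen transport
  (6 vs 30), the classic glycolytic phenotype, which makes the co-culture
  trade-off and the pyruvate shuttle non-trivial. The cell models are a
  little larger than a minimal toy because exact elemental balancing
  requires explicit proton/water/cofactor bookkeeping; the brute-force
  LP oracles run on separate 8-reaction random fixtures, so nothing is
  lost.
* **A thermodynamic table** of synthetic formation energies, labelled as
  such, crafted so catabolism is downhill and near-equilibrium steps
  straddle zero.
* **An RPMI-like medium** (glucose 10, glutamine 2, serine 1, oxygen 25)
  with the free-species set {CO2, H+, H2O, NH4}.
* **Expression matrices**: independent Bernoulli presence calls per gene
  and sample (12 samples by default, matching a typical microarray series
  size), probability 0.9 by default.
* **An atom-mapped tracer subnetwork** (13 reactions, no metabolite above
  6 carbons) with glucose→2×pyruvate glycolysis, lactate/alanine
  branches, pyruvate dehydrogenase and carboxylase, citrate synthesis and
  cleavage, symmetric-intermediate scrambling on the 2-oxoglutarate →
  oxaloacetate step (0.5/0.5), and glutamine anaplerosis. The reference
  flux map anchors glucose uptake at 0.45 and glutamine at 0.63 flux
  units — the boundary-flux scale of the system it emulates — and a
  measured lactate efflux is included because the lactate/alanine split
  of pyruvate is otherwise structurally unidentifiable from MIDs alone.
* **Labelling datasets**: forward-simulated MIDs plus additive Gaussian
  noise (sd 0.005 mole fraction, a documented choice), clipped at zero
  and renormalised per fragment; the true fluxes travel alongside for
  recovery tests. The clip-and-renormalise step means the noise is not an
  exact orthogonal projection, so the at-truth SSR is calibrated against
  the residual count rather than a projected dof (a test watches this at
  the 20% level).

What the generator does **not** emulate: microarray intensity
distributions or batch effects, kinetic regulation, natural-abundance
effects (measured MIDs are assumed corrected), compartment-specific
tracer dilution, and the scale of a genome-wide network. Passing tests
therefore demonstrate correctness of the algorithms and their couplings,
not predictive accuracy on any real cell system.

## Pipeline, sizes and determinism

`run_pipeline()` executes generate → extract → thermo → merge → mfa_fit →
tune → respire → pareto, validating the stage partial order (extraction
and thermodynamics before merging; the MFA fit before tuning) before
anything runs, and writes an md5 manifest so reruns are verifiably
identical. The MFA-to-model id map ships in the template (glycolysis,
glutaminase and lactate dehydrogenase of the myeloma cell), together with
a cells-to-dry-weight conversion factor (default 1) for reconciling
tracer-network flux units with model units.

Default problem sizes were chosen so the whole suite runs in minutes on
one core: 20 random networks for the LP oracle, 25 random merges, 20
random flux vectors for the EMU/isotopomer comparison, a 100-restart
noisy fit, and a 15-replicate Monte-Carlo coverage experiment with 50
resamples per replicate (coverage is asserted in the wide binomial band
88–100%; the resample count matters, because percentile intervals built
from too few resamples are systematically narrow and undercover — 15
resamples gave ~85% empirical coverage, 50 restore the nominal ~95%).
Larger replicate counts sharpen the statistics but change nothing
qualitatively.

## Known limitations

* The simplex solver is dense and unsuitable for genome-scale matrices;
  it is built for the toy-to-reduced scale this package targets.
* The SBML reader/writer covers the fields this package produces
  (species/compartments, FBC bounds, gene associations, the active
  objective, a formation-energy annotation); it is not a general-purpose
  SBML round-tripper for third-party files.
* No parsimonious FBA, MOMA, gene-deletion screens, dynamic co-culture,
  or more than two cells.
* The chi-square calibration of fits inherits a small upward SSR bias
  from the clip-and-renormalise noise model (single datasets are judged
  against the 99% band in the tests for that reason).
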