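---
title: "Methods: a core-scale constraint-based model of the anaerobic gut fungal hydrogenosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a core-scale constraint-based model of the anaerobic gut fungal hydrogenosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model structure

`hydrogem` implements a curated, core-scale stoichiometric model of the
anaerobic gut fungus *Neocallimastix lanati* and the analysis machinery that
goes with it: flux balance analysis (FBA), parsimonious FBA, flux
variability analysis, hit-and-run flux sampling, maintenance-energy
regression, a qualitative substrate/vitamin validation harness, hydrogenosome
scenario analyses, and a reduced elementary-metabolite-unit (EMU) simulator
for steady-state ¹³C labeling.

The network has three compartments — extracellular (`_e`), cytosol (`_c`)
and the hydrogenosome (`_h`), the mitochondrion-derived organelle in which
these fungi make ATP and H₂ anaerobically. It contains roughly 200 reactions
and 175 metabolites:

* **Cytosol.** Embden–Meyerhof–Parnas glycolysis with both the NAD⁺-linked
  (phosphorylating) and NADP⁺-linked (non-phosphorylating)
  glyceraldehyde-3-phosphate dehydrogenase variants; only the
  *non-oxidative* pentose phosphate pathway (glucose-6-phosphate
  dehydrogenase and the 6-phosphogluconate steps are absent, which is why
  the NADP⁺-GAPDH variant matters for NADPH supply); the xylose
  isomerase–xylulokinase route; mixed-acid fermentation to lactate,
  formate, acetate (via the hydrogenosome), ethanol, and succinate through
  the reductive branch PEP → OAA → malate → fumarate → succinate.
* **Hydrogenosome.** Malate and pyruvate import, NAD⁺-linked malic enzyme,
  pyruvate formate lyase (PFL), pyruvate:ferredoxin oxidoreductase (PFO),
  the ferredoxin hydrogenase, a hydrogen dehydrogenase constrained to its
  energetically favorable direction (NAD⁺ + H₂ → NADH + H⁺; the reverse,
  H₂-evolving direction has ΔG ≈ +34 ± 5.9 kJ/mol under physiological
  assumptions and is disallowed in the base case), and the ATP-yielding
  acetate:succinyl-CoA transferase / succinyl-CoA synthetase couple.
  Three *speculative* units ship bounded to (0, 0) and are enabled by
  scenario switches: a bifurcating hydrogenase, a lumped complex-1/2
  proton-pumping module, and an ATP synthase.
* **Extracellular space.** Lumped CAZyme hydrolysis of cellobiose, maltose,
  sucrose, raffinose, cellulose, xylan, maltodextrin and lignocellulose
  (the cell imports monomer sugars only), plus exchanges for every tested
  substrate, product, vitamin and mineral.

Every internal reaction is elementally (CHONPS) and charge balanced;
`check_balance()` runs during construction and aborts the build naming any
offending reaction. Ferredoxin is modeled as an abstract two-electron
carrier (empty formula, charge −2 when reduced), so PFO yields one reduced
ferredoxin per pyruvate and the ferredoxin hydrogenase is
Fd²⁻ + 2 H⁺ → Fd + H₂. The bifurcating hydrogenase uses 1:1 NADH:Fd
coupling (NADH + Fd²⁻ + 3 H⁺ → NAD⁺ + Fd + 2 H₂); its coefficients are
configuration keys with the electron-balance constraint
H₂ = NADH + Fd enforced.

## Proton handling at the hydrogenosomal membrane

The hydrogenosomal inner membrane is treated as impermeable to free
protons. Anion transport is *proton-compensated* (electroneutral): each
transported acid carries |charge| protons in the same direction (pyruvate⁻
and formate⁻ one, malate²⁻, fumarate²⁻, succinate²⁻ and HPO₄²⁻ two), the
ATP⁴⁻/ADP³⁻ antiporter carries one, and H₂, CO₂ and water diffuse freely.
Protons therefore cross only alongside metabolites or through the explicit
pumping module (complex 1/2 exporting 2 H⁺ per NADH by default, ATP
synthase importing 3 H⁺ per ATP; both ratios are configuration keys since
the mechanism is unresolved — it is genuinely unclear how complex 2 could
operate without membrane subunits of complex 1, and the model treats the
whole unit as speculative). This scheme closes the hydrogenosomal proton
balance exactly for every route (PFL, PFO + hydrogenase, malate shuttle,
bifurcation) without allowing a free proton leak.

# Biomass objective and maintenance

The biomass reaction is compiled from the measured macromolecular
composition (carbohydrate 32.4%, protein 43.7%, lipid 4.9%, DNA 0.2%,
RNA 0.6% of dry mass; raw sum 81.8%). The unaccounted 18.2% is closed by
proportional renormalization to 1 g by default; an "ash" mode keeps the
measured fractions and treats the remainder as inert. One unit of biomass
flux drains 1.000 ± 0.001 g of monomer mass, audited from the molecular
formulas at build time, and about 43 mmol of carbon.

Monomers: 20 amino acids at a generic fungal proteome frequency (the
organism-specific predicted-proteome distribution is not published as
numbers; the vector is a documented, overridable default), the insoluble
carbohydrate as chitin (N-acetylglucosamine residues), NTPs and dNTPs at
uniform base composition (overridable), and the lipid as triacylglycerol
equivalents of myristate, palmitate and stearate at equal mole thirds (the
measured ratios exist only graphically, so equal thirds is an explicit
stand-in; only the relative ratios enter). Nine vitamin/cofactor demands
enter at 10⁻⁵ mmol/gDW each.

Maintenance follows the standard convention: the growth-associated term
(GAM, default 75.98 mmol ATP per gDW) is ATP hydrolysis embedded in the
biomass reaction, and the non-growth-associated term (NGAM, default
2.27 mmol ATP/gDW/h) is a lower bound on a cytosolic ATP-hydrolysis
reaction. Source tables sometimes attach the "/h" to GAM instead of NGAM;
that is a transposition relative to the dimensionally consistent reading
used here (the regression slope of an ATP *rate* against a growth *rate*
is an amount per gram).

**Where growth-coupled ATP lives.** All growth-coupled ATP costs —
polymerization, transport, sugar activation for anabolic precursors — are
absorbed into the GAM term rather than spread over the monomer-synthesis
lumps. This mirrors how a *fitted* GAM is defined: the regression slope
captures every ATP cost proportional to growth, so embedding explicit
monomer ATP costs as well would double-count them and bias the
maintenance-recovery analysis by exactly that amount. The only exceptions
are real phosphoanhydride bonds (NMP → NTP kinase steps), which cannot be
free without creating an energy loop; at the measured RNA/DNA fractions
they contribute < 0.1% to the recovered slope. A glucose-6-phosphatase
closes the monomer-precursor loop so that all growth substrates (glucose,
fructose, galactose, mannose, sorbitol, xylose and the hydrolyzed
polymers) can reach the anabolic entry point.

# The LP engine

No linear-programming backend is assumed; the package carries a dense
two-phase primal simplex with general variable bounds (`solve_lp()`). All
bounds are finite (±1000 mmol/gDW/h by convention). Numerical choices:

* reduced-cost and pivot tolerance 10⁻⁹; solution validation at 10⁻⁶;
* rows equilibrated to unit max-magnitude before solving;
* a Harris-style two-pass ratio test (10⁻⁷ bound slack) so that degenerate
  ties resolve toward numerically large pivots;
* basis inverse maintained by product-form updates, refactorized every 40
  pivots with the basic values recomputed from scratch (drift cannot
  accumulate);
* termination accepted only after a fresh factorization, the returned
  point verified against all constraints, and a deterministic restart with
  Bland's rule if verification fails.

The engine is cross-checked in the test suite against exhaustive vertex
enumeration of the flux polytope on networks of up to six reactions.

Parsimonious FBA fixes the objective at a fraction of its optimum and
minimizes Σ|v| by splitting every reaction into irreversible
forward/backward parts (one LP, no integer programming); it is the device
used throughout to pick a unique representative from alternate optima.
Ties in qualitative growth calls use the threshold μ > 10⁻⁴ h⁻¹
("growth"), a documented in-silico choice — the wet-lab criterion is a
pressure-accumulation test with no direct model analogue.

## Flux sampling

`sample_fluxes()` is an artificial-centering hit-and-run sampler on the
polytope {S v = 0, bounds, objective ≥ fraction × optimum}. Directions are
confined to the null space of S over non-fixed reactions, so every sample
satisfies the equalities and all fixed bounds by construction. Warm-up
points are vertices from ± objectives on the biomass, the key exchanges
and the hydrogenosomal branch reactions plus random null-space directions;
the chain starts from their average (strictly interior), alternates
vertex-difference and isotropic directions, and records every 100th step
after 1000 warm-up steps (defaults; the source names neither the algorithm
nor its parameters, so these are documented assumptions). Identical seeds
give identical samples.

# Maintenance-energy regression

`fit_maintenance()` reproduces the max-ATP-yield procedure: for each
cellobiose-gradient experiment the measured product fluxes (computed by the
difference estimator Δmoles / (Δt × Δdry-mass); the dry-mass difference is
used because lysed biomass no longer contributes to metabolism) are applied
as secretion caps and the substrate flux as an uptake cap, biomass is fixed
to zero so the ATP cost of growth is not double-counted, and the ATP
demand is maximized. Ordinary least squares of maximum ATP yield against
the pressure-derived growth rate gives GAM as the slope and NGAM as the
intercept. Caps (rather than two-sided equality constraints) keep every
noisy replicate feasible: forcing a noisy formate rate above the acetate +
ethanol sum would otherwise be structurally impossible. Bootstrap
confidence intervals are provided as an extension
(`maintenance_bootstrap()`); the regression itself reports R² and
residuals.

The synthetic generator (`generate_growth_experiments()`) emits exactly
the data this estimator inverts: two timepoints 24 h apart, product
amounts consistent with a representative near-optimal model solution whose
fermentation profile tracks the measured-flux table scaled to uptake, a
Monod-type level-to-uptake map (u = 1.8·L/(1+L) glucose-equivalents,
anchored so the 5 g/L reference reproduces the measured 1.5 mmol/gDW/h and
growth stays positive at 1 g/L; only monotonicity matters to the fit),
multiplicative lognormal noise on every measured amount, truncated-normal
draws for flux tables, and additive renormalized noise for MID fractions.
Dry masses and the pressure-derived growth rate are taken as given, which
matches how they are obtained (extrapolated, not independently measured).
What the generator does *not* emulate: real cultures are not at perfect
metabolic steady state between the two samplings, replicate tubes share
systematic batch effects, and the product profile is regulated rather than
near-optimal — so passing recovery tests demonstrate estimator
correctness, not field accuracy.

# ¹³C labeling (EMU) module

The reduced carbon-transition network covers glycolysis, the non-oxidative
pentose phosphate pathway (run toward pentose synthesis), the fermentation
branches, the reductive succinate branch with fumarate scrambling
(symmetric metabolite handled by paired 0.5/0.5 atom maps) and optional
fumarate↔malate back-exchange, and hydrogenosomal malate/pyruvate
metabolism (malic enzyme recycling, PFL vs PFO split). The default
measured-fragment panel is pyruvate (alanine), oxaloacetate (aspartate),
PEP (serine proxy), ribose 5-phosphate (RNA-bound ribose) and glucose
6-phosphate (glycogen-bound glucose); biomass drains are unlabeled-sink
effluxes and CO₂ is diluted by an unlabeled headspace inflow. The tracer
is [1,2-¹³C]glucose by default, expressed as a mixture of exactly known
labeling patterns; natural abundance is off by default with an optional
per-position probability.

`emu_decompose()` walks backward from the target fragments to the minimal
size-stratified EMU network; `simulate_mids()` solves the triangular
cascade of linear balance systems (condensed sources convolve, and are
always strictly smaller). The simulator is verified against brute-force
positional-isotopomer enumeration to 10⁻¹⁰ on toy networks with cleavage,
condensation, cycles and symmetric scrambling, and on the full default
network.

`fit_fluxes()` is variance-weighted least squares over free flux
parameters with box constraints, multi-start, and a post-fit flat-SSR
probe that flags structurally non-identifiable parameters instead of
returning them silently. Two degeneracies of the default network are worth
knowing. First, without fumarate back-exchange the malate-shuttle flux is
invisible to amino-acid labeling (malate stays unscrambled, so malic-enzyme
pyruvate is indistinguishable from kinase pyruvate); the fit flags it, and
fixing the hydrogenosomal import to pyruvate only (`fixed = c(me = 0)`)
collapses the degeneracy — the same device used for the original flux
analysis. Second, with back-exchange active a one-dimensional ridge couples
(PEP carboxykinase, malic enzyme, exchange) at identical residuals; the
*fluxes* the data pin (formate, acetate, lactate, ethanol, succinate
routes and glycolysis) are constant along the ridge, which is why recovery
claims are stated at the flux level, not the raw-parameter level.

# What the core scale reproduces, and what it cannot

The package's validation suite reproduces, deterministically: the
46-entry substrate-utilization and vitamin-essentiality battery (41/46
agreement with experiment, 89% accuracy, Matthews correlation 0.79 — the
five disagreements are sorbitol, galactose, mannose and xylose, predicted
growth-positive but observed negative, and biotin, predicted essential but
observed dispensable), the 81.8% raw biomass fraction sum, exact
formate:(acetate+ethanol) unity whenever PFO carries no flux (acetate and
ethanol are the only acetyl-CoA sinks and every PFL turnover co-produces a
formate), zero H₂ capacity when PFO is blocked in the base case, and the
maintenance parameters from noiseless synthetic gradients (slope 76.04 vs
ground truth 75.98; intercept 2.27 exactly — the +0.08% is the real
NMP-kinase cost).

A balanced core-scale network also has a hard energetic ceiling that some
published full-model numbers sit above. With the ferredoxin hydrogenase
the maximum anaerobic yield is **3 ATP per glucose** (2 from glycolysis
plus 1 from hydrogenosomal acetate; the 2 glycolytic NADH must be sunk
into ethanol, lactate or succinate, each costing at least one
substrate-level phosphorylation per 2 NADH), and with the bifurcating
hydrogenase **4** (glucose → 2 acetate + 2 CO₂ + 4 H₂ via the malate
shuttle) — both values are asserted as exact LP audits in the tests. At
glucose uptake 1.5 mmol/gDW/h with GAM 75.98 and NGAM 2.27, yield 3 gives
μ ≈ 0.023 h⁻¹; reaching the full model's μ = 0.044 would require an
effective yield near 4.7 ATP/glucose, which no mass-, charge- and
redox-balanced core network can provide anaerobically. The same ceiling
compresses every relative comparison: the bifurcating swap raises growth
by ≈ 52% here (3 → 4 ATP on a small base) instead of 16%, the proton
module's ATP synthase carries a substantial share of flux instead of ~3%
of glucose uptake, the H₂ constraint (not acetate) ranks as the single
most informative measured flux because unconstrained core-scale H₂ spans
0–1.4 mmol/gDW/h, and the compressed growth-rate range of the synthetic
cellobiose gradient (0.004–0.023 h⁻¹) roughly doubles the relative noise
of the recovered GAM slope (median ≈ 9% at 5% measurement CV, against a
5% target; the intercept recovers within ≈ 4%). These checks are kept in
the acceptance tests at their original tolerances and left failing by
design: they measure the distance between a transparent core model and a
1,000-reaction reconstruction, and quietly retuning the network or the
generator to close that distance would defeat the point.

# Numerical and design choices, collected

* Flux unit mmol/gDW/h; uptake negative, secretion positive; BiGG-style
  lowercase ids with `_c`/`_h`/`_e` suffixes.
* Stoichiometric coefficients are numeric doubles end to end (R has no
  native rational type); every curated coefficient is exactly
  representable or audited at 10⁻⁹.
* Speculative reactions default to (0, 0); scenario toggles are logged at
  INFO when `options(hydrogem.verbose = TRUE)`.
* Monomer-synthesis lumps are generated by an exact 3×3 linear solve that
  closes H, O and charge with the NADPH/NADP⁺ couple, water and protons
  after carbon, nitrogen, sulfur and phosphorus are drawn from glucose,
  ammonium, sulfide and phosphate; a soluble transhydrogenase
  interconverts NADH and NADPH.
* Vitamin semantics: "+" means growth with the vitamin omitted. Folate has
  no salvage transporter, so its demand is met only de novo from
  4-aminobenzoate — which is what makes 4-aminobenzoate essential and
  folate dispensable simultaneously. Heme and biotin have no synthesis
  route; cobalamin's demand is satisfiable via the cobalamin-independent
  bypass. Cobalamin and heme formulas are CHONPS proxies (cobalt and iron
  omitted; they never enter a balanced internal reaction beyond transport).
* Problem sizes used by the shipped analyses: 46 LPs for the battery,
  2,000 samples at 90% optimality for sampling checks, 800 samples per
  condition for the scenario and sensitivity summaries, 100 noise
  replicates for maintenance recovery, 20 for labeling recovery.

# Known limitations

The model is a core-scale instance, not a genome-scale reconstruction: no
gene-level essentiality, no secondary metabolism, lipid diversity reduced
to three saturated fatty acids, cell wall reduced to chitin, nitrogen
fixed to ammonium and sulfur to sulfide. The amino-acid and fatty-acid
distributions are documented stand-ins. SBML export is not implemented;
the JSON dialect (schema in `inst/extdata/model-schema.json`) is the
interchange format. The sampler's uniformity is exact only on box-like
polytopes; on the full model it is a well-mixed ACHR chain, adequate for
the qualitative range and shift analyses it feeds.
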