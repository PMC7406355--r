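---
title: "End-product biomass labeling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-product biomass labeling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctrace)
```

## The problem

A bulk metabolite measurement on a tumor is a weighted average over every
cell type present, and cancer cells are often a minority population.  Cell
sorting can separate the types, but free metabolite pools turn over within
minutes, so by the time sorted cells are extracted their free-metabolite
labeling no longer reflects their state in the tissue.  Label that has been
incorporated into slow-turnover macromolecules — protein-bound amino acids
read out by GC-MS of protein hydrolysates — survives sorting, at the price
of not being at isotopic steady state.  `pctrace` implements the full chain
needed to reason quantitatively about such experiments: a steady-state
^13^C label simulator on a carbon atom-transition network, a protein
labeling kinetics layer, a sorting-delay model, natural-abundance
correction of raw spectra, and inference of pyruvate-carboxylation activity
from the corrected data, together with a synthetic-experiment generator
that makes every stage testable.

## Carbon network and tracer logic

The core network (`build_core_network()`) covers lower glycolysis, pyruvate
exchange with medium pyruvate and lactate, alanine and serine synthesis,
and the TCA cycle with its amino-acid offshoots.  The atom maps encode the
tracer logic the inference relies on:

* **PDH route.** Pyruvate dehydrogenase releases pyruvate C1 as CO~2~ and
  passes C2/C3 into acetyl-CoA, so fully labeled glucose (M+3 pyruvate)
  makes M+2 TCA intermediates through this route.
* **Carboxylation route.** Pyruvate carboxylase condenses intact pyruvate
  with CO~2~ into oxaloacetate (M+3 TCA labeling from M+3 pyruvate);
  carboxylating malic enzyme does the same into malate.  With
  1-^13^C-pyruvate or 3,4-^13^C-glucose — both of which label only the
  pyruvate carboxyl carbon — the label is lost as CO~2~ via PDH and
  retained (M+1 aspartate) only via carboxylation.
* The glycolytic map sends glucose C1–C3 to one triose in reversed order
  and C4–C6 to the other in order, the standard aldolase/triose-phosphate
  chemistry under which pyruvate C1 derives from glucose C3/C4.
* TCA maps follow standard biochemistry: the acetyl carbons survive the
  first turn (they label glutamate C4/C5), and the two CO~2~ released at
  the isocitrate and α-ketoglutarate dehydrogenase steps derive from the
  two oxaloacetate *carboxyl* carbons (C1 and C4 respectively).  Citrate is
  treated as prochiral (no scrambling at aconitase); succinate and fumarate
  are rotationally symmetric and are scrambled 50/50.
* CO~2~ is an infinite unlabeled boundary pool by default (an optional
  fixed enrichment is available); anaplerosis from sources outside the
  model (glutamine and others) enters as a single unlabeled OAA influx.
* Reversible steps are encoded as paired irreversible reactions so flux
  vectors stay non-negative and the steady-state systems stay linear.

Whether malic enzyme runs net-carboxylating in a given tissue is not an
established fact; both directions are present in the network
(`me1_reverse`, `pyruvate_cycling` flags) and the split is a scenario
parameter, not a hard-coded assumption.  Compartmentation (cytosolic vs
mitochondrial pyruvate and malate pools) is deliberately not modeled;
each metabolite is one well-mixed pool.

Flux states are parameterized by the fractional fate of pyruvate
(`flux_fractions()`): φ~PDH~, φ~PC~, φ~ME1c~ plus lactate, alanine and
release fractions summing to 1, with secondary parameters (uptake fraction,
lactate return, biosynthetic demands, citrate efflux) shaping the rest.
`fractions_to_flux()` maps any valid fraction set to a balanced flux
vector; infeasible secondary demands are clamped (cycling capped by malate
influx, TCA demands by cycle flux, anaplerosis raised to cover OAA
consumption) so the map is total on the simplex — convenient for
optimization, and the clamps are exercised in the tests.

## Steady-state simulation: EMU solver and isotopomer oracle

`simulate_mids()` uses an elementary-metabolite-unit decomposition: the
labeling of any subset of a metabolite's carbons balances independently,
and condensation reactions couple only strictly smaller subsets, so MIDs
are solved level-by-level (by EMU size) through small dense linear systems.
Equations and unknowns are ordered deterministically, so results are
reproducible bit-for-bit.  Symmetric metabolites are handled by splitting
each producing reaction into half-flux variants with mirrored product
carbon order, which is algebraically identical to averaging each EMU with
its mirror image.

Numerical choices worth knowing:

* Pools with (numerically) zero influx, or connected to no external carbon
  source (closed exchange loops), have no defined steady state and are
  returned as `NA` vectors rather than silently propagating `NaN`.
* Each level system is row-equilibrated by pool influx before solving, so
  flux magnitudes spanning many orders (as arise transiently inside
  optimization) do not masquerade as singularity.
* The simulation currency is tracer-derived label only.  Natural ^13^C in
  substrates is *excluded* from simulation and handled entirely by the
  correction module, mirroring the usual workflow in which instrument data
  are natural-abundance corrected before interpretation.

`simulate_mids_oracle()` is an independent verification route: it iterates
the full positional-isotopomer balance (all 2^n^ patterns per metabolite)
to a fixed point and collapses patterns to masses.  It shares only the
network expansion with the EMU solver, and the two agree below 10^-8^
across random balanced flux states and all three tracers — this
cross-validation is part of the test suite.  The co-culture solver is
additionally checked against a flattened single-network solution of the
coupled system.

## Mixed populations

`simulate_coculture()` couples per-type compartments through shared medium
pyruvate and lactate: each compartment is solved with the current medium
labeling as its uptake boundary, and the medium is recomputed as the
flux-weighted mixture of fresh supply and weighted cellular release,
iterated (damping 0.5, tolerance 10^-10^) to a fixed point.  Because
position matters for the 1-^13^C-pyruvate logic, medium pools are tracked
as full positional distributions, recovered from the subset-EMU solutions
by Möbius inversion.  `bulk_average()` gives the weighted-average MID a
bulk tissue measurement would show.  Exchange magnitudes and cell-type
weights in real tumors are unknown; the defaults are synthetic-scenario
parameters, not estimates.

## Protein labeling and sorting delay

Protein-bound amino-acid MIDs follow a single-pool first-order model,
`P(t) = f(t)·free + (1−f(t))·pre` with `f(t) = 1 − exp(−k_new·t)`
(`protein_mid_at()`).  One aggregate `k_new` per cell type (growth dilution
plus turnover) matches what a fluorescent synthesis reporter measures; no
per-protein turnover spectrum is attempted.  The free amino-acid MID is
treated as constant over the labeling period, since free pools reach
isotopic steady state fast relative to protein turnover.  The reporter
fitter (`estimate_synthesis_rate()`) fits the control-subtracted curve to
`B∞(1 − exp(−kt))` by nonlinear least squares and falls back to a flagged
early-slope estimate when the plateau is not identifiable in the observed
window.

Two cell types with identical fluxes but different `k_new` have identical
free MIDs yet different protein MIDs at any finite time — the confound that
makes measuring synthesis rates necessary.  The preset co-culture scenario
embodies the converse situation: its PSC compartment synthesizes protein
about 1.5× faster (half-times 48 h vs 72 h) *and* still shows lower
protein aspartate M+3, because the cancer compartment's carboxylation
fractions (φ~PC~ = 0.15, φ~ME1c~ = 0.06 vs 0.02/0.01) outweigh the kinetic
advantage.  That parameter regime is a deliberate choice: a generator in
which the kinetic confound dominated would contradict the qualitative
outcome of the experiments it emulates.  All preset fractions are
illustrative — no study reports numeric flux fractions per cell type — and
every generated dataset carries its ground truth.

Sorting delay (`apply_sort_delay()`) relaxes each free metabolite's labeled
fractions toward M+0 as `exp(−rate·delay)` (the lost labeled mass reappears
in M+0, keeping the vector normalized) and decays pool sizes; protein rates
are structurally fixed at zero, so protein MIDs pass through unchanged for
any delay.  Real sorting drift is heterogeneous across metabolites; the
single-rate relaxation is the simplest emulator with the right qualitative
contrast, and rates are per-metabolite scenario parameters.

## Natural-abundance correction

For a derivatized fragment, column *j* of the correction matrix is the
distribution of observed mass shifts for an analyte carrying exactly *j*
tracer carbons: the convolution of the natural isotope distributions of
every atom *except* the tracer-able backbone carbons, shifted by *j*,
truncated at the observed range and renormalized.  Backbone carbons are
excluded because their labeling is the signal.  Correction solves
`raw ≈ M·x` by non-negative least squares (Lawson–Hanson) rather than
matrix inversion, which can return negative fractions on noisy spectra.
The bundled fragment library holds the TBDMS [M−57] ions of Ala, Ser, Asp,
Glu and Pro plus MOX-TBDMS pyruvate and TBDMS lactate; these formulas are
standard-practice defaults (no study prints its fragment formulas) and can
be overridden per fragment.  Abundances default to IUPAC 2013
representative values (^13^C 0.0107, ^29^Si 0.0468, ^30^Si 0.0309, ...)
and are also overridable.

## Inference and identifiability

`pc_activity_ratio()` is the paper-style surrogate statistic: corrected
aspartate M+1 divided by pyruvate M+1 under a carboxyl-labeled tracer; a
vanishing denominator flags the ratio undefined instead of dividing.
`summarize_pdh_pc()` tabulates M+2/M+3 of the TCA panel under uniformly
labeled glucose.  M+3 from U-^13^C-glucose is an imperfect surrogate — it
also arises from multiple rounds of TCA cycling — which is why the
positional tracers are the preferred readout.

`fit_flux_fractions()` estimates (φ~PDH~, φ~PC~, φ~ME1c~) by multistart
(≥16 seeded starts) bounded least squares against the forward model
(knockout → flux → `simulate_mids` → `protein_mid_at`).  Identifiability is
reported honestly rather than assumed:

* With only uniformly labeled glucose and no knockouts, φ~PC~ and φ~ME1c~
  are *structurally* confounded — both routes deliver identical label into
  oxaloacetate (carboxylating malic enzyme feeds malate, which
  dehydrogenates to OAA with an identity carbon map).  The fitter detects
  the near-optimal spread and sets `identifiable = FALSE`; ties are broken
  toward the smallest total carboxylation (parsimony, to avoid attributing
  label to carboxylation without evidence).  Separating the two routes
  requires genetic perturbation, exactly as done experimentally.
* With 1-^13^C-pyruvate alone, aspartate M+1 constrains essentially one
  ratio, and under realistic noise a near-flat ridge appears along φ~PDH~
  (the anaplerotic influx auto-balances, trading dilution against
  carboxylation).  The recommended design therefore combines the
  1-^13^C-pyruvate wild-type/PC-knockout/ME1-knockout conditions with a
  U-^13^C-glucose condition (whose M+2 pins the PDH fraction) and observes
  glutamate as well as aspartate — this is the design the acceptance
  checks use, and the one the emulated experiments actually performed.
* Candidates that predict an *undefined* pool for an observed species
  (e.g. φ~PDH~ = 0 leaving glutamate with no influx) are rejected with a
  large penalty.

Group comparisons use the unpaired two-tailed Welch t-test, unadjusted by
default (a Benjamini–Hochberg adjustment can be applied to the returned
p-values with `p.adjust`); this matches how such panels are usually
reported.

## Synthetic data and noise model

`generate_dataset()` runs the full forward pipeline — co-culture steady
state, protein labeling per time point, sorting drift on free species
only, natural-abundance contamination per fragment, then seeded additive
Gaussian noise per channel with clipping at zero and renormalization (a
multiplicative option exists).  Reporter fluorescence carries proportional
noise (constant CV, default 5%), the natural error model for a
flow-cytometry readout, over nine measurement times within 12 h of
reporter stabilization.  Determinism is strict: identical config and
seed give byte-identical tables, and generation neither reads nor disturbs
the global RNG stream.  Replicate variation enters only through
measurement noise by default.

Preset noise levels: 0.2 mol% per channel for culture/infusion scenarios
and 0.1 mol% for the knockout tracing scenarios, reflecting the replicate
spread of GC-MS MID measurements in tightly controlled cell-line
experiments.  The in vivo preset fixes plasma glucose enrichment at 40%,
the plateau an infusion reaches; culture presets use fully labeled medium
glucose.  Scenario problem sizes used by the tests (e.g. 100 noisy
replicates for the ordering check, 20 replicate fits for recovery, 10–25
random flux states for solver cross-validation) were chosen so the whole
suite completes comfortably on one CPU.

What the generator does *not* emulate — chromatogram-level artifacts,
retention-time drift, between-replicate biological variation in fluxes
(available but off by default), amino-acid salvage from extracellular
protein, compartment-specific pools — bounds what passing tests show about
real data: they validate the analysis chain under the model's assumptions,
not the assumptions themselves.

## Worked example

```{r example}
net <- build_core_network()
cancer <- flux_fractions(phi_pdh = 0.40, phi_pc = 0.15, phi_me1c = 0.06,
                         phi_ala = 0.05, phi_rel = 0.08, f_pyr_uptake = 0.3)
flux <- fractions_to_flux(net, cancer)
mids <- simulate_mids(net, flux, list(tracer_1pyr(1)))
round(as.numeric(mids$asp), 4)
pc_activity_ratio(mids$asp, mids$pyr)

## knock out PC: residual M+1 via malic enzyme remains
ko <- knockout_scenario(cancer, "PC")
mids_ko <- simulate_mids(net, fractions_to_flux(net, ko), list(tracer_1pyr(1)))
round(mids_ko$asp[2], 4)

## knock out both: aspartate labeling is abolished
both <- knockout_scenario(cancer, "both")
mids_b <- simulate_mids(net, fractions_to_flux(net, both), list(tracer_1pyr(1)))
mids_b$asp[2]
```

## Known limitations

Single well-mixed pools per metabolite (no compartmentation); no
isotopically nonstationary metabolite dynamics (protein non-stationarity
*is* modeled, metabolite transients are not); no nitrogen or hydrogen
tracing; PEPCK and the mitochondrial malic enzyme isoforms are not
distinguished from the modeled routes; nominal-mass correction only (no
resolution-dependent high-resolution variant); exchange fluxes between
cell types are exposed but unconstrained by any published measurement.
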