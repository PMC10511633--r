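---
title: "Stoichiometric proto-cell models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric proto-cell models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protocell)
```

## The model family

`protocell` implements a family of ten coarse-grained, stationary-state
models of self-reproducing proto-cells (SSPCMs). Each proto-cell is the
minimal subset of cellular machinery able to copy itself — a
self-reproduction system (SRS) — built around the ribosome (more precisely
the ribosomal protein complex, RPC, the only component that reproduces its
own catalyst). The ten models add components stepwise: an amino-acid
synthesis chain; an unspecified protein pool; transcription and the three
RNA classes; a bilayer lipid membrane with its synthesis enzyme; membrane
proteins (an electron transport chain complex producing ATP and a substrate
transporter) with central metabolism; and finally a genome replicated by a
pair of replisomes, giving complete minimal-medium and rich-medium cells.

Self-reproduction is modeled as exact doubling: over one doubling time
`t_d_srs` every component count is reproduced once by the catalysts present,
all of which work continuously at fixed apparent rates. This stationary,
precisely balanced picture turns every process into an algebraic balance:

* **Polymer doubling.** For each polymer class,
  `t_d_srs = sum_j(N_j * n_j) / (N_pol * k_pol)`: the polymerase pool
  (ribosomes for protein, RNA-polymerase complexes for RNA, replisomes for
  DNA, the lipid-synthesis enzyme for membrane lipids) must re-synthesize
  every member of its class exactly once per doubling.
* **Pathway flux.** Monomer synthesis runs through linear chains of
  identical unidirectional reactions; at stationary state every step of a
  chain carries the downstream demand flux, so each step needs
  `demand/k_enz` enzymes and a chain of `l` reactions needs `l` times that.
* **Energy and transport.** ATP production by membrane-bound complexes
  equals consumption by polymerization, pathway reactions and transport;
  substrate import equals metabolic demand. Both membrane-protein counts
  are therefore outputs, effectively proportional to the ribosome count.
* **Geometry.** The membrane area of a spherocylindrical cell, derived
  from the cytoplasmic volume (itself derived from total mass via the
  water fraction and wet density), is exactly covered by the footprints of
  membrane proteins and lipids; the lipid count is whatever area remains.

Fixed stoichiometric couplings close the system: one assembled rRNA per
ribosome, a fixed tRNA-per-ribosome ratio, a fixed total of mRNA
nucleotides per ribosome (distributed across protein species in proportion
to their translation share — only the total enters any balance), one
genome per cell and a pair of replisomes per genome.

Each model compiles (`build_model()`) into a determined system — equations
equal unknowns once one driver (`t_d_srs` or `N_rs`) is fixed — and
`degrees_of_freedom_report()` asserts the census.

## Two component groups, two limit types

Components whose counts are stoichiometrically tied to the ribosome count
(enzymes, polymerases, RNA, membrane proteins) add terms proportional to
`N_rs` on both sides of the protein balance, so the doubling time is
independent of cell size: flat lines with no size limit. Components whose
counts are *not* tied to `N_rs` — the membrane lipid pool (set by surface
area), the genome (one copy regardless of size), an unspecified protein
pool — produce hockey-stick curves: small cells carry a disproportionate
burden (surface-to-volume, or a whole genome per few ribosomes) and slow
down steeply, while large cells dilute it.

For models with membrane proteins the fast end is a genuine boundary:
protein footprints grow linearly with `N_rs` while the geometric area grows
only as `V^(2/3)`, so at some size the lipid area reaches zero — the
membrane is covered entirely by proteins and faster growth is impossible.
`find_growth_boundary()` locates this feasible/infeasible transition by
bracketed bisection (tolerance `1e-6` s) and classifies the limit as
`membrane_surface_area`; for all other models the minimal doubling time is
a closed-form or asymptotic value determined by molecular properties.

## Geometry

The cell is an ideal cylinder with spherical caps. Because area must be a
single-valued function of volume, one shape degree of freedom is fixed,
and the package offers two conventions. The default, used by the canonical
parameter set, fixes the cylinder-length-to-radius ratio
(`aspect_ratio`, default 2.4), so `A ∝ V^(2/3)` and the surface-to-volume
ratio vanishes for large cells. This choice is forced by the model
family's own structure: the doubling time of a membrane-bearing model must
converge, for large cells, to that of the same model without the membrane
(the lipid fraction must become negligible), which requires `A/V -> 0`. A
fixed-radius convention (radius constant, length absorbing growth, sphere
fallback below the minimal spherocylinder volume) is also implemented for
comparison, but with it `A/V` tends to a constant and the asymptote
property fails, so it is not used for the canonical results.

## Parameters and provenance

All I/O is in fixed units: seconds, molecules per cell, Da, nm², µm, µm³.
Counts and chain lengths are continuous quantities — the framework is
deterministic and stoichiometric, not discrete. Every species carries a
provenance label (`specific`, `precise`, `approximate`, `average`,
`generic`, or `calibrated`).

Reference-derived values in the canonical set
(`default_parameters()`, also shipped as
`inst/extdata/params_default.yaml`): ribosome rate 20.26 aa/s; RNA
polymerase complex 3407 aa at 85 nt/s; assembled rRNA 4566 nt; tRNA 76 nt,
8 per ribosome; genome 9.28e6 nt (both strands of a 4.64-Mb bihelix);
polymerized monomer masses 110 Da (aa) and 324 Da (nt); water mass
fraction 0.70; wet density 1.1 g/cm³; 0.5 nm² per lipid per leaflet;
translation 4.2 ATP/aa and transcription 2.4 ATP/nt.

## Calibration of the canonical parameter set

Several compositions and stoichiometries that the model family needs are
not tabulated anywhere accessible; the package therefore ships them
*calibrated*: chosen once so that the family reproduces its canonical
operating points, and labeled as such. The calibration has two layers.

**Closed-form layer.** `n_rpc = 362.10 × 20.26 = 7336.146` aa (doubling
time of a lone RPC); the per-reaction time coefficient
`n_enz/k_enz = (3600 − 362.10)/1079.3 = 3.0` s exactly (the chain length
needed to stretch the two-component cell to one hour is 1079.3 reactions);
`l_PW2 = (962.10 − 362.10)/3 = 200` reactions; and the mRNA coupling
(2516.7 nt per ribosome) from the quadratic that links transcription and
translation in the RNA-bearing cell, anchored at 1127.15 s. The same logic
is available at runtime through `calibrate_fallback()`.

**Numerical layer.** The membrane/energy/DNA sector (central-metabolism
and dNTP/lipid chain lengths, ETC composition and footprint, transporter
footprint, per-reaction and per-transport ATP costs, dNMP mass, aspect
ratio) was fitted once, by staged block-Newton iteration with a
Levenberg–Marquardt polish, to the canonical boundary points
(2462.68 s/36,699; 2474.27 s/36,992; 936.40 s/24,681) and the two
slow-growth worked points (`N_rs = 8.17` at 1300 s; `N_rs = 17.45` at
10⁴ s). The frozen result reproduces all eight anchors within 0.13 % (six
within 0.01 %). Two calibrated values deserve a note: the per-transporter
footprint (319 nm²) is an *effective* area absorbing whatever mix of
transporter multiplicity and footprint the reference tabulation used, and
the dNMP monomer mass (222.7 Da) absorbs the genome's mass-to-area
contribution at the minimal-medium boundary. The replisome rate is set to
5000 nt/s so that the rich-medium boundary (which implies ~4955 nt/s per
replisome on a 9.28e6-nt genome replicated once per 936.4-s doubling by a
single pair) remains feasible.

## Numerics

Given the driver, every model reduces to at most two coupled scalar roots:
an inner root for the lipid count from the membrane-area balance (strictly
decreasing residual: each lipid occupies 0.25 nm² of cross-section but
adds only ~0.06 nm² of area through its mass) and an outer root for the
pivot (`N_rs` or `t_d_srs`) from the protein-doubling balance, whose
scaled residual is strictly increasing. Brackets are found by geometric
expansion from stoichiometric guesses and refined with `uniroot` at
near-machine tolerance; the solution is therefore the unique positive
root, continuous with the large-`N_rs` stoichiometric limit, and
bit-reproducible (no randomness anywhere). All remaining unknowns are
constructed from the couplings, and every residual of the compiled system
is re-evaluated at the solution (tests require `< 1e-8` on each balance's
natural scale).

Infeasibility is a typed result, never a clamp: a negative remaining lipid
area or a required per-replisome rate above `k_rc` marks the state
`infeasible` with a note, sweeps record such points and continue, and the
boundary search bisects exactly this transition.

**Convention for asymptotic maxima.** For hockey-stick models without
membrane proteins the doubling time approaches its asymptote but never
attains it, so any finite "maximal" ribosome count encodes a tolerance
choice. The package reports the smallest count whose doubling time is
within `epsilon_asym` (default 0.005 s, half the printed precision of the
doubling times) of the asymptote, labels it `tolerance_defined`, and
excludes it from any reference comparison (`limit_table()` annotates these
cells). These values are a documented convention, not a reproduction
claim.

## Fixtures, tests, and what they show

`generate_fixtures()` builds three deterministic toy parameter sets whose
solutions are hand arithmetic: round-number analytic doubling times
(100/130/150 s), a membrane cell whose boundary equals a closed-form
quadratic (and is cross-checked against a brute-force feasibility scan),
and a replication-threshold cell that is exactly feasible at 1000 s. The
property suite (closed-form ≡ numeric on 50-point grids at 1e-9, flat
group-1 lines, pool-free reduction, monotone hockey sticks, asymptote
convergence, conservation residuals, bit-determinism) runs on these
fixtures independently of the calibrated values, so it tests the
machinery, not the calibration. Test problem sizes are modest by choice —
grids of 50 points, boundary bisection at 1e-6 s — and the whole suite
solves a few thousand operating points.

What passing tests do *not* show: the models are idealized stationary
descriptions of self-reproduction only. They contain no regulation, no
kinetics or ODE dynamics, no cell-cycle mechanism, no environmental
dependence (pH, temperature, concentrations), no components beyond the
SRS, and reversible/exchange fluxes are excluded. Slow growth of *large*
cells is outside the framework's reach: physiologically sized cells appear
only in a narrow band near each model's minimal doubling time (e.g.
`physiological_window()` on the minimal-medium cell gives roughly
2477–2761 s over the canonical mass range), and the steep branch of every
hockey stick lies at sub-molecular counts. Volume is derived from mass via
a fixed water fraction and wet density rather than from summed component
volumes; the conversion constants are ordinary parameters.

## Worked example

```{r, eval = FALSE}
p <- default_parameters()
closed_form_doubling_time("sspcm-rs", p)        # 362.10 s
solve_model("sspcm-srs-m", p, t_d = 1e4)$counts$rpc   # 17.45 ribosomes
find_growth_boundary("sspcm-srs-m", p)          # 2475.42 s, N_rs 36992
limit_table(p)                                  # all ten models
```
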