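# protocell

Stoichiometric models of self-reproducing proto-cells, for systems
biologists studying ribosome-centric growth laws and doubling-time limits.

A proto-cell here is a *self-reproduction system* (SRS): the minimal set of
cellular machinery able to copy itself within one doubling time. Ribosomes
(their protein part, the ribosomal protein complex RPC) are the core
self-replicator; enzymes of linear biosynthesis chains (PW1–PW5), RNA
polymerase complexes, replisomes, the three RNA classes, a bilayer lipid
membrane and membrane-bound energy/transport proteins support them. The
package defines ten such models (SSPCMs), from the bare RPC up to complete
cells growing on minimal or rich medium, compiles each into a determined
system of algebraic balance equations, solves it at an operating point,
sweeps doubling time against ribosome count, and characterizes each model's
doubling-time limit.

The core balance is exact doubling at stationary state. For every polymer
class,

    t_d_srs = Σ_j N_j · n_j / (N_pol · k_pol)

(the polymerase pool, working at its apparent rate `k_pol`, re-synthesizes
every member of its class once per doubling); pathway fluxes equal the
downstream monomer demand on every step of a chain; ATP production equals
consumption; and the spherocylinder's surface area is exactly covered by
the footprints of membrane proteins and lipids. Components tied
stoichiometrically to the ribosome count give size-independent doubling
times (flat lines, no size limit); the membrane and the genome are not so
tied and give hockey-stick curves, with a hard growth boundary where
membrane proteins crowd the lipids off the surface entirely.

## Worked example

```r
library(protocell)
p <- default_parameters()          # canonical calibrated parameter set

closed_form_doubling_time("sspcm-rs", p)
#> [1] 362.1                        # lone replicator: n_rpc / k_rs

solve_model("sspcm-srs-m", p, t_d = 2600)
#> <sspcm-srs-m> t_d_srs = 2600 s  [ok]
#>   N_rs = 3745.15; M_tot = 1.993e-13 g; dry = 5.98e-14 g
#>   V = 0.1812 um^3; A = 1.715 um^2; lipid area = 0.9702 um^2
#>   dry-mass fractions: ribosomal 0.238, rna_other 0.105, polymerase 0.00136,
#>     dna_associated 0.0719, enzymes 0.239, membrane_protein 0.263, lipid 0.0808

find_growth_boundary("sspcm-srs-m", p)
#> <doubling-time limit: sspcm-srs-m>
#>   minimal t_d_srs: 2475.42 s (boundary_root)
#>   maximal N_rs: 36992 (at_boundary)
#>   limit type: membrane_surface_area; slower growth: both
```

The minimal-medium cell at a 2600-s doubling time carries ~3745 ribosomes
and weighs 0.2 pg; its fastest possible version (36,992 ribosomes) doubles
in 2475 s, limited by membrane surface area — below that, the energy and
transport proteins required would exceed the whole membrane. `sweep_model()`
produces the full doubling-time-vs-ribosome-count and
lipid-per-ribosome-vs-ribosome-count relationships (`plot_doubling_time()`,
`plot_lipid_ratio()`), `composition_report()` the dry-mass breakdown, and
`physiological_window()` the narrow driver range over which total cell mass
is physiological. A thin CLI (`exec/protocell`) exposes
`params show`, `models list`, `solve`, `sweep`, `limits` and `table`.

Parameter sets are YAML or JSON (`load_parameters()`,
`write_parameters()`); the canonical set ships in
`inst/extdata/params_default.yaml` with per-value provenance labels.
Values that no accessible table provides are *calibrated* against the
family's canonical operating points — see the methods vignette
(`vignettes/proto-cell-models.Rmd`) for the procedure and
`calibrate_fallback()` for the runtime equivalent.

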