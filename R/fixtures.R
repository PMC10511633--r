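# Deterministic toy parameter sets with hand-computable solutions. These are
# first-class test scaffolding: every expected value is the output of an
# explicit independent calculation (plain arithmetic or a closed form noted
# in `oracle`), not of the solver being tested.

#' Generate a toy parameter set with a known solution
#'
#' Three kinds are available:
#' \describe{
#'   \item{`toy_analytic`}{Ribosome + amino-acid-pathway + RNA sector with
#'     round numbers: lone-replicator doubling time 100 s, with the
#'     amino-acid pathway 130 s (`100 + 300*10/100`), with RNA 150 s (the
#'     positive root of `t^2 - 130 t - 3000 = 0`).}
#'   \item{`toy_membrane`}{A membrane-protein proto-cell whose minimal
#'     doubling time equals the positive root of the closed-form quadratic
#'     `t^2 - (t2 + X) t - Y = 0` (membrane exhaustion with no
#'     size-independent demand left over); the expected boundary is also
#'     cross-checked against a fine-grid feasibility scan in the tests.}
#'   \item{`toy_dna`}{Replicator + genome of 1e6 nt with a replisome pair
#'     rated at 500 nt/s: replication is exactly feasible at t_d = 1000 s
#'     and infeasible below; the ribosome count obeys
#'     `N = (2 n_rc + (n_enz/k_enz) l3 n_dna / t) / (k_rs t - n_rpc)`.}
#' }
#' Fully deterministic; no randomness anywhere.
#'
#' @param kind `"toy_analytic"`, `"toy_membrane"` or `"toy_dna"`.
#' @return List with `params` (an `sspcm_parameters`), `expected` (named
#'   values with their derivations) and `oracle` (description of the
#'   independent calculation).
#' @export
generate_fixtures <- function(kind) {
  if (!kind %in% c("toy_analytic", "toy_membrane", "toy_dna"))
    .stop_cond("protocell_config_error",
               "unknown fixture kind '%s'", kind)
  toy_species <- function(extra = list()) {
    base <- list(
      rpc = species_spec("rpc", "self_replicator", 1000, "aa", 10,
                         provenance = "generic"),
      enz = species_spec("enz", "enzyme", 300, "aa", 100,
                         provenance = "generic"),
      rp = species_spec("rp", "polymerase", 400, "aa", 40,
                        provenance = "generic"),
      rrna = species_spec("rrna", "rna", 500, "nt", provenance = "generic"),
      trna = species_spec("trna", "rna", 50, "nt", provenance = "generic"),
      mrna = species_spec("mrna", "rna", 100, "nt", provenance = "generic")
    )
    c(base, extra)
  }
  if (kind == "toy_analytic") {
    params <- suppressMessages(parameter_set(
      species = toy_species(),
      pathways = list(
        PW2 = pathway_spec("PW2", 10, "enz", "aa"),
        PW4 = pathway_spec("PW4", 10, "enz", "nt")),
      couplings = list(trna_per_ribosome = 4, mrna_nt_per_ribosome = 50),
      source_note = "toy_analytic fixture"))
    # By hand: t_rs = 1000/10 = 100 s; pathway term 300*10/100 = 30 s;
    # RNA quadratic: R = 500 + 4*50 + 50 = 750 nt/ribosome,
    # Y = (750/10)*(400/40 + 10*300/100) = 75*40 = 3000,
    # t = (130 + sqrt(130^2 + 4*3000))/2 = (130 + 170)/2 = 150 s.
    return(list(params = params,
                expected = list(t_d_rs = 100, t_d_rs_aa = 130,
                                t_d_rs_aa_rna = 150),
                oracle = "hand arithmetic on the doubling balances"))
  }
  if (kind == "toy_membrane") {
    params <- suppressMessages(parameter_set(
      species = toy_species(list(
        lpe = species_spec("lpe", "enzyme", 300, "aa", 100,
                           provenance = "generic"),
        lip = species_spec("lip", "lipid", 1, "lipid_precursor",
                           mass_da = 800, localization = "membrane",
                           footprint_nm2 = 0.5, provenance = "generic"),
        etc = species_spec("etc", "membrane_protein", 3000, "aa", 100,
                           localization = "membrane", footprint_nm2 = 50,
                           provenance = "generic"),
        tp = species_spec("tp", "membrane_protein", 500, "aa", 50,
                          localization = "membrane", footprint_nm2 = 10,
                          provenance = "generic"))),
      pathways = list(
        PW1 = pathway_spec("PW1", 10, "enz", "metabolic_intermediate", 0.1),
        PW2 = pathway_spec("PW2", 10, "enz", "aa", 0.1),
        PW4 = pathway_spec("PW4", 10, "enz", "nt", 0.1),
        PW5 = pathway_spec("PW5", 5, "enz", "lipid_precursor", 0.1)),
      geometry = geometry_params(shape_mode = "fixed_aspect",
                                 aspect_ratio = 2,
                                 area_per_lipid_nm2 = 0.5,
                                 water_mass_fraction = 0.5,
                                 density_g_per_cm3 = 1.0),
      energy = energy_params(atp_per_aa_polymerized = 4,
                             atp_per_nt_polymerized = 2,
                             atp_per_dnt_polymerized = 2,
                             atp_per_lipid = 1,
                             atp_per_transport = 1,
                             substrates_per_monomer = 1),
      couplings = list(trna_per_ribosome = 4, mrna_nt_per_ribosome = 50),
      source_note = "toy_membrane fixture"))
    # Closed form for the boundary doubling time (membrane exhaustion with
    # all size-independent demand zero): with per-ATP costs
    # c_aa = 4 + 0.1*(10+10) + 1 = 7 and c_nt = 2 + 0.1*(10+10) + 1 = 5,
    # X = 3*l1 + (n_etc/k_etc) c_aa + n_tp/k_tp = 30 + 210 + 10 = 250,
    # Y = (R/k_rs) [n_rp/k_rp + 3*(l4+l1) + (n_etc/k_etc) c_nt + n_tp/k_tp]
    #   = 75 * (10 + 60 + 150 + 10) = 17250
    # (the central chain carries the transcription demand too),
    # t_min = ((130+250) + sqrt((130+250)^2 + 4*17250))/2.
    t_min <- (380 + sqrt(380^2 + 4 * 17250)) / 2
    return(list(params = params,
                expected = list(t_d_min = t_min),
                oracle = paste("closed-form quadratic for the membrane",
                               "boundary; fine-grid feasibility scan")))
  }
  # toy_dna
  params <- suppressMessages(parameter_set(
    species = list(
      rpc = species_spec("rpc", "self_replicator", 1000, "aa", 10,
                         provenance = "generic"),
      enz = species_spec("enz", "enzyme", 300, "aa", 100,
                         provenance = "generic"),
      rc = species_spec("rc", "polymerase", 1000, "aa", 500,
                        provenance = "generic"),
      dna = species_spec("dna", "genome", 1e6, "dnt",
                         provenance = "generic")),
    pathways = list(PW3 = pathway_spec("PW3", 10, "enz", "dnt")),
    couplings = list(rc_per_genome = 2, genome_copies = 1),
    source_note = "toy_dna fixture"))
  # By hand: per-replisome rate n_dna/(2 t) = 500 nt/s at t = 1000 s, the
  # exact feasibility threshold; N(t) = (2*1000 + 3*10*1e6/t)/(10 t - 1000),
  # so N(1000) = 32000/9000.
  list(params = params,
       expected = list(t_feasibility_threshold = 1000,
                       N_rs_at_1000 = 32000 / 9000),
       oracle = "arithmetic on the replication and protein balances")
}
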