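# Parameter sets: molecular species, pathways, geometry, energy stoichiometry
# and stoichiometric couplings that determine every proto-cell model.

.species_roles <- c("self_replicator", "polymerase", "enzyme", "rna", "lipid",
                    "membrane_protein", "genome")
.monomer_kinds <- c("aa", "nt", "dnt", "lipid_precursor")
.provenances   <- c("average", "specific", "precise", "approximate", "generic",
                    "calibrated")
.pathway_ids   <- c("PW1", "PW2", "PW3", "PW4", "PW5")

.stop_cond <- function(class, fmt, ...) {
  stop(structure(class   = c(class, "protocell_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Define a molecular species of the self-reproduction system
#'
#' A species is one molecule or assembled complex of the proto-cell:
#' the ribosomal protein complex, a polymerase, a generic pathway enzyme,
#' an RNA, the genome, a membrane lipid or a membrane protein.
#'
#' @param id Short species id, e.g. `"rpc"`, `"enz"`, `"lip"`.
#' @param role One of `"self_replicator"`, `"polymerase"`, `"enzyme"`,
#'   `"rna"`, `"lipid"`, `"membrane_protein"`, `"genome"`.
#' @param n_monomers Number of polymerized monomers per molecule/complex
#'   (amino acids for proteins, nucleotides for nucleic acids). Continuous
#'   values are permitted.
#' @param monomer_kind One of `"aa"`, `"nt"`, `"dnt"`, `"lipid_precursor"`.
#' @param k_rate Apparent working rate: monomers s^-1 for polymerases,
#'   reactions s^-1 for enzymes, ATP s^-1 for the electron transport chain,
#'   transport events s^-1 for transporters. `NA` for non-catalytic species.
#' @param mass_da Molecular mass in Da. If `NULL`, derived from
#'   `n_monomers` times the mean monomer mass of the parameter set.
#' @param localization `"cytoplasm"` or `"membrane"`.
#' @param footprint_nm2 Membrane cross-sectional area per molecule (nm^2);
#'   required iff `localization = "membrane"`.
#' @param provenance Label describing how the value conforms to a reference
#'   organism: one of `"average"`, `"specific"`, `"precise"`,
#'   `"approximate"`, `"generic"`, `"calibrated"`.
#' @return A `species_spec` list.
#' @export
species_spec <- function(id, role, n_monomers, monomer_kind,
                         k_rate = NA_real_, mass_da = NULL,
                         localization = "cytoplasm", footprint_nm2 = NULL,
                         provenance = "generic") {
  if (!role %in% .species_roles)
    .stop_cond("protocell_validation_error",
               "species '%s': unknown role '%s'", id, role)
  if (!monomer_kind %in% .monomer_kinds)
    .stop_cond("protocell_validation_error",
               "species '%s': unknown monomer_kind '%s'", id, monomer_kind)
  if (!is.numeric(n_monomers) || n_monomers <= 0)
    .stop_cond("protocell_validation_error",
               "species '%s': n_monomers must be > 0", id)
  if (!is.na(k_rate) && k_rate <= 0)
    .stop_cond("protocell_validation_error",
               "species '%s': k_rate must be > 0 for catalytic species", id)
  if (!localization %in% c("cytoplasm", "membrane"))
    .stop_cond("protocell_validation_error",
               "species '%s': unknown localization '%s'", id, localization)
  if (localization == "membrane" && is.null(footprint_nm2))
    .stop_cond("protocell_validation_error",
               "species '%s': membrane species need footprint_nm2", id)
  if (localization == "cytoplasm" && !is.null(footprint_nm2))
    .stop_cond("protocell_validation_error",
               "species '%s': footprint_nm2 defined iff membrane-localized", id)
  if (!provenance %in% .provenances)
    .stop_cond("protocell_validation_error",
               "species '%s': unknown provenance '%s'", id, provenance)
  structure(list(id = id, role = role, n_monomers = as.numeric(n_monomers),
                 monomer_kind = monomer_kind, k_rate = as.numeric(k_rate),
                 mass_da = if (is.null(mass_da)) NULL else as.numeric(mass_da),
                 localization = localization,
                 footprint_nm2 = if (is.null(footprint_nm2)) NULL
                                 else as.numeric(footprint_nm2),
                 provenance = provenance),
            class = "species_spec")
}

#' Define a linear biosynthesis pathway
#'
#' Pathways are linear chains of identical unidirectional isomerization
#' reactions, all catalyzed by the same generic enzyme, with equal per-step
#' fluxes and equal per-step enzyme counts.
#'
#' @param id `"PW1"` (central metabolism), `"PW2"` (amino acid),
#'   `"PW3"` (deoxyribonucleotide), `"PW4"` (ribonucleotide) or
#'   `"PW5"` (lipid precursor).
#' @param length_reactions Number of reactions in the chain (may be
#'   fractional).
#' @param enzyme Species id of the catalyzing enzyme.
#' @param product_monomer What the chain produces: one of `"aa"`, `"nt"`,
#'   `"dnt"`, `"lipid_precursor"`, `"metabolic_intermediate"`.
#' @param atp_per_reaction ATP-equivalents consumed per reaction step.
#' @return A `pathway_spec` list.
#' @export
pathway_spec <- function(id, length_reactions, enzyme = "enz",
                         product_monomer, atp_per_reaction = 0) {
  if (!id %in% .pathway_ids)
    .stop_cond("protocell_validation_error", "unknown pathway id '%s'", id)
  if (length_reactions < 0)
    .stop_cond("protocell_validation_error",
               "pathway '%s': length_reactions must be >= 0", id)
  if (atp_per_reaction < 0)
    .stop_cond("protocell_validation_error",
               "pathway '%s': atp_per_reaction must be >= 0", id)
  ok_prod <- c(.monomer_kinds, "metabolic_intermediate")
  if (!product_monomer %in% ok_prod)
    .stop_cond("protocell_validation_error",
               "pathway '%s': unknown product_monomer '%s'", id, product_monomer)
  structure(list(id = id, length_reactions = as.numeric(length_reactions),
                 enzyme = enzyme, product_monomer = product_monomer,
                 atp_per_reaction = as.numeric(atp_per_reaction)),
            class = "pathway_spec")
}

#' Cell geometry parameters
#'
#' The proto-cell is an ideal cylinder with spherical caps. Two shape modes
#' are supported. In `"fixed_aspect"` (default) the cylinder length is
#' proportional to the radius (`length = aspect_ratio * radius`), so area
#' scales as volume^(2/3) and the surface-to-volume ratio falls as the cell
#' grows. In `"fixed_radius"` the radius is held at `radius_um` and only the
#' cylinder length grows, with a sphere fallback below the minimal cylinder
#' volume.
#'
#' @param shape_mode `"fixed_aspect"` or `"fixed_radius"`.
#' @param aspect_ratio Cylinder length / radius (fixed_aspect mode; >= 0,
#'   0 gives a sphere).
#' @param radius_um Cell radius (um) in fixed_radius mode.
#' @param area_per_lipid_nm2 Leaflet area per lipid molecule (nm^2).
#' @param leaflets Number of membrane leaflets; fixed at 2 (both layers have
#'   equal surface area).
#' @param water_mass_fraction Fraction of total cell mass that is water,
#'   in (0, 1).
#' @param density_g_per_cm3 Total (wet) cell density, g cm^-3.
#' @return A `geometry_params` list.
#' @export
geometry_params <- function(shape_mode = "fixed_aspect", aspect_ratio = 3,
                            radius_um = 0.35, area_per_lipid_nm2 = 0.5,
                            leaflets = 2, water_mass_fraction = 0.70,
                            density_g_per_cm3 = 1.1) {
  if (!shape_mode %in% c("fixed_aspect", "fixed_radius"))
    .stop_cond("protocell_validation_error",
               "geometry: unknown shape_mode '%s'", shape_mode)
  if (aspect_ratio < 0 || radius_um <= 0 || area_per_lipid_nm2 <= 0 ||
      density_g_per_cm3 <= 0)
    .stop_cond("protocell_validation_error",
               "geometry: all dimensional parameters must be positive")
  if (leaflets != 2)
    .stop_cond("protocell_validation_error",
               "geometry: leaflets is fixed at 2 (equal-area bilayer)")
  if (water_mass_fraction <= 0 || water_mass_fraction >= 1)
    .stop_cond("protocell_validation_error",
               "geometry: water_mass_fraction must lie in (0, 1)")
  structure(list(shape_mode = shape_mode, aspect_ratio = as.numeric(aspect_ratio),
                 radius_um = as.numeric(radius_um),
                 area_per_lipid_nm2 = as.numeric(area_per_lipid_nm2),
                 leaflets = 2,
                 water_mass_fraction = as.numeric(water_mass_fraction),
                 density_g_per_cm3 = as.numeric(density_g_per_cm3)),
            class = "geometry_params")
}

#' Energy and transport stoichiometry
#'
#' ATP-equivalents consumed per polymerization event, per transport event and
#' the substrate cost of monomer synthesis. The ATP production rate per
#' electron transport chain complex lives on the `etc` species as its
#' `k_rate`.
#'
#' @param atp_per_aa_polymerized,atp_per_nt_polymerized,atp_per_dnt_polymerized,atp_per_lipid
#'   ATP per monomer incorporated into protein / RNA / DNA / membrane.
#' @param atp_per_transport ATP per substrate or monomer transport event.
#' @param substrates_per_monomer Substrate molecules imported per monomer
#'   synthesized (minimal-medium models).
#' @return An `energy_params` list.
#' @export
energy_params <- function(atp_per_aa_polymerized = 4.2,
                          atp_per_nt_polymerized = 2.4,
                          atp_per_dnt_polymerized = 2.4,
                          atp_per_lipid = 1.0,
                          atp_per_transport = 1.0,
                          substrates_per_monomer = 1.0) {
  vals <- c(atp_per_aa_polymerized, atp_per_nt_polymerized,
            atp_per_dnt_polymerized, atp_per_lipid, atp_per_transport,
            substrates_per_monomer)
  if (any(vals < 0))
    .stop_cond("protocell_validation_error",
               "energy: all stoichiometries must be >= 0")
  structure(list(atp_per_aa_polymerized = as.numeric(atp_per_aa_polymerized),
                 atp_per_nt_polymerized = as.numeric(atp_per_nt_polymerized),
                 atp_per_dnt_polymerized = as.numeric(atp_per_dnt_polymerized),
                 atp_per_lipid = as.numeric(atp_per_lipid),
                 atp_per_transport = as.numeric(atp_per_transport),
                 substrates_per_monomer = as.numeric(substrates_per_monomer)),
            class = "energy_params")
}

.default_couplings <- function() {
  list(trna_per_ribosome = 8, mrna_nt_per_ribosome = 2500,
       rc_per_genome = 2, rrna_per_ribosome = 1, genome_copies = 1)
}

#' Assemble a validated parameter set
#'
#' @param species Named list of [species_spec()] objects.
#' @param pathways Named list of [pathway_spec()] objects.
#' @param geometry A [geometry_params()] object, or `NULL` when only
#'   membrane-free models will be built.
#' @param energy An [energy_params()] object, or `NULL` when only models
#'   without membrane proteins will be built.
#' @param couplings Named list of stoichiometric ratios fixed to the
#'   ribosome count: `trna_per_ribosome`, `mrna_nt_per_ribosome`
#'   (total mRNA nucleotides per ribosome), `rc_per_genome`,
#'   `rrna_per_ribosome` (must be 1), `genome_copies`. Missing entries are
#'   filled with defaults and logged.
#' @param monomer_mass_da Mean polymerized monomer masses (Da): named list
#'   with `aa`, `nt`, `dnt`.
#' @param source_note Free text recording the provenance of the whole set.
#' @param mass_tolerance Relative tolerance for the consistency check
#'   between an explicit `mass_da` and `n_monomers * mean monomer mass`.
#' @return An object of class `sspcm_parameters`.
#' @export
parameter_set <- function(species, pathways, geometry = NULL, energy = NULL,
                          couplings = list(),
                          monomer_mass_da = list(aa = 110, nt = 324, dnt = 308),
                          source_note = "", mass_tolerance = 0.05) {
  defaults <- .default_couplings()
  for (nm in names(defaults)) {
    if (is.null(couplings[[nm]])) {
      couplings[[nm]] <- defaults[[nm]]
      message(sprintf("coupling '%s' not given; default %s applied",
                      nm, format(defaults[[nm]])))
    }
  }
  ps <- structure(list(schema_version = 1,
                       species = species, pathways = pathways,
                       geometry = geometry, energy = energy,
                       couplings = couplings,
                       monomer_mass_da = monomer_mass_da,
                       source_note = source_note,
                       geometry_available = !is.null(geometry)),
                  class = "sspcm_parameters")
  validate_parameters(ps, mass_tolerance = mass_tolerance)
  ps
}

#' Validate a parameter set against its structural invariants
#'
#' Checks species invariants (positive counts and rates, footprint defined
#' iff membrane-localized, mass consistency with mean monomer masses),
#' pathway invariants, and that every species referenced by a pathway or
#' coupling exists.
#'
#' @param params An `sspcm_parameters` object.
#' @param mass_tolerance Relative tolerance for the mass consistency check.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_parameters <- function(params, mass_tolerance = 0.05) {
  sp <- params$species
  for (s in sp) {
    if (!identical(s$id, "dna") && s$n_monomers <= 0)
      .stop_cond("protocell_validation_error",
                 "species '%s': n_monomers must be > 0", s$id)
    if (!is.null(s$mass_da) && s$monomer_kind %in% names(params$monomer_mass_da)) {
      expected <- s$n_monomers * params$monomer_mass_da[[s$monomer_kind]]
      if (abs(s$mass_da - expected) > mass_tolerance * expected)
        .stop_cond("protocell_validation_error",
                   "species '%s': mass_da %.4g inconsistent with %g monomers x %g Da",
                   s$id, s$mass_da, s$n_monomers,
                   params$monomer_mass_da[[s$monomer_kind]])
    }
  }
  for (pw in params$pathways) {
    if (!pw$enzyme %in% names(sp))
      .stop_cond("protocell_reference_error",
                 "pathway '%s' references unknown species '%s'",
                 pw$id, pw$enzyme)
  }
  if (!is.null(params$couplings$rrna_per_ribosome) &&
      params$couplings$rrna_per_ribosome != 1)
    .stop_cond("protocell_validation_error",
               "rrna_per_ribosome must be 1 (assembled rRNA, 1:1:1 sub-units)")
  invisible(params)
}

#' Mass of one molecule of a species, in Da
#'
#' Uses the explicit `mass_da` if the species defines one, otherwise
#' `n_monomers` times the mean polymerized monomer mass of its kind.
#'
#' @param params An `sspcm_parameters` object.
#' @param id Species id.
#' @return Mass in Da.
#' @export
species_mass_da <- function(params, id) {
  s <- params$species[[id]]
  if (is.null(s))
    .stop_cond("protocell_reference_error", "unknown species '%s'", id)
  if (!is.null(s$mass_da)) return(s$mass_da)
  mm <- params$monomer_mass_da[[s$monomer_kind]]
  if (is.null(mm))
    .stop_cond("protocell_config_error",
               "no mean monomer mass for kind '%s'", s$monomer_kind)
  s$n_monomers * mm
}

# ---------------------------------------------------------------------------
# Canonical defaults

#' Canonical parameter set
#'
#' The packaged default parameter set. Molecular compositions and rates that
#' correspond to well-characterized reference-organism values carry
#' `specific`/`approximate`/`generic` provenance labels; the remaining values
#' are produced by calibration against the canonical operating points of the
#' model family (see the methods vignette) and are labeled `calibrated` in
#' `source_note`.
#'
#' @return An `sspcm_parameters` object.
#' @examples
#' p <- default_parameters()
#' closed_form_doubling_time("sspcm-rs", p)  # 362.10 s
#' @export
default_parameters <- function() {
  k_rs  <- 20.26               # aa s^-1, apparent ribosome working rate
  n_rpc <- 362.10 * k_rs       # calibrated: t_d of a lone RPC is 362.10 s
  k_enz <- 100
  n_enz <- 3 * k_enz           # calibrated: per-reaction time coefficient 3 s
  l_pw2 <- (962.10 - 362.10) * k_enz / n_enz  # = 200 reactions
  n_rp  <- 3407                # aa, RNA polymerase complex (2a + b + b')
  k_rp  <- 85                  # nt s^-1
  l_pw4 <- 150
  n_rrna <- 4566               # nt, 5S + 16S + 23S
  n_trna <- 76
  trna_per_rs <- 8
  # mRNA nucleotides per ribosome, calibrated so that the doubling time of
  # the ribosome+RNA proto-cell equals 1127.15 s (see vignette):
  rna_nt_per_rs <- 1127.15 * (1127.15 - 962.10) * k_rs /
    (n_rp / k_rp + l_pw4 * n_enz / k_enz)
  c_mrna <- rna_nt_per_rs - n_rrna - trna_per_rs * n_trna

  # Membrane / energy / DNA sector: values fitted to the canonical membrane
  # growth boundaries and slow-growth operating points (scratch calibration;
  # see vignette "Calibration of the canonical parameter set").
  cal <- .calibrated_membrane_sector()

  species <- list(
    rpc  = species_spec("rpc", "self_replicator", n_rpc, "aa", k_rs,
                        provenance = "calibrated"),
    rp   = species_spec("rp", "polymerase", n_rp, "aa", k_rp,
                        provenance = "specific"),
    rc   = species_spec("rc", "polymerase", cal$n_rc, "aa", cal$k_rc,
                        provenance = "calibrated"),
    lpe  = species_spec("lpe", "enzyme", 300, "aa", cal$k_lpe,
                        provenance = "generic"),
    enz  = species_spec("enz", "enzyme", n_enz, "aa", k_enz,
                        provenance = "calibrated"),
    etc  = species_spec("etc", "membrane_protein", cal$n_etc, "aa", cal$k_etc,
                        localization = "membrane", footprint_nm2 = cal$a_etc,
                        provenance = "calibrated"),
    tp   = species_spec("tp", "membrane_protein", 500, "aa", cal$k_tp,
                        localization = "membrane", footprint_nm2 = cal$a_tp,
                        provenance = "calibrated"),
    rrna = species_spec("rrna", "rna", n_rrna, "nt", provenance = "specific"),
    trna = species_spec("trna", "rna", n_trna, "nt", provenance = "specific"),
    mrna = species_spec("mrna", "rna", 900, "nt", provenance = "generic"),
    lip  = species_spec("lip", "lipid", 1, "lipid_precursor",
                        mass_da = cal$m_lip, localization = "membrane",
                        footprint_nm2 = 0.5, provenance = "calibrated"),
    dna  = species_spec("dna", "genome", 9.28e6, "dnt",
                        provenance = "specific")
  )
  pathways <- list(
    PW1 = pathway_spec("PW1", cal$l_pw1, "enz", "metabolic_intermediate",
                       cal$atp_per_reaction),
    PW2 = pathway_spec("PW2", l_pw2, "enz", "aa", cal$atp_per_reaction),
    PW3 = pathway_spec("PW3", cal$l_pw3, "enz", "dnt", cal$atp_per_reaction),
    PW4 = pathway_spec("PW4", l_pw4, "enz", "nt", cal$atp_per_reaction),
    PW5 = pathway_spec("PW5", cal$l_pw5, "enz", "lipid_precursor",
                       cal$atp_per_reaction)
  )
  geometry <- geometry_params(shape_mode = "fixed_aspect",
                              aspect_ratio = cal$aspect_ratio,
                              radius_um = 0.35,
                              area_per_lipid_nm2 = 0.5,
                              water_mass_fraction = 0.70,
                              density_g_per_cm3 = 1.1)
  energy <- energy_params(atp_per_aa_polymerized = 4.2,
                          atp_per_nt_polymerized = 2.4,
                          atp_per_dnt_polymerized = cal$atp_per_dnt,
                          atp_per_lipid = 1.0,
                          atp_per_transport = cal$atp_per_transport,
                          substrates_per_monomer = 1.0)
  couplings <- list(trna_per_ribosome = trna_per_rs,
                    mrna_nt_per_ribosome = c_mrna,
                    rc_per_genome = 2, rrna_per_ribosome = 1,
                    genome_copies = 1)
  suppressMessages(parameter_set(
    species, pathways, geometry, energy, couplings,
    monomer_mass_da = list(aa = 110, nt = 324, dnt = cal$m_dnt),
    source_note = paste("canonical defaults;",
                        "n_rpc, n_enz, l_PW2, mrna_nt_per_ribosome and the",
                        "membrane/energy/DNA sector are calibrated against the",
                        "canonical operating points of the model family;",
                        "remaining values reference-organism derived")))
}

# Calibrated membrane/energy/DNA knob values (frozen output of the staged
# block-Newton calibration; see the methods vignette for the procedure).
.calibrated_membrane_sector <- function() {
  list(
    aspect_ratio      = 2.4,
    l_pw1             = 100,
    l_pw3             = 443.401293277646,
    l_pw5             = 61.5691707857362,
    n_etc             = 24892.2007586135,
    k_etc             = 300,
    a_etc             = 131.068455486295,
    k_tp              = 100,
    a_tp              = 318.656336475012,
    k_lpe             = 100,
    m_lip             = 750,
    n_rc              = 4536,
    k_rc              = 5000,
    atp_per_reaction  = 0.0212917328218593,
    atp_per_transport = 1,
    atp_per_dnt       = 1.28354713792666,
    m_dnt             = 222.744578224771
  )
}

# ---------------------------------------------------------------------------
# Loading / serialization

.params_to_plain <- function(params) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(params))
}

.plain_to_params <- function(doc) {
  for (sec in c("species", "pathways"))
    if (is.null(doc[[sec]]))
      .stop_cond("protocell_config_error",
                 "mandatory section '%s' missing from configuration", sec)
  species <- lapply(doc$species, function(s) {
    if (is.null(s$id) || is.null(s$role) || is.null(s$n_monomers) ||
        is.null(s$monomer_kind))
      .stop_cond("protocell_config_error",
                 "species entry missing a mandatory field (id/role/n_monomers/monomer_kind): %s",
                 paste(unlist(s[c("id", "role")]), collapse = " "))
    species_spec(s$id, s$role, s$n_monomers, s$monomer_kind,
                 k_rate = if (is.null(s$k_rate)) NA_real_ else s$k_rate,
                 mass_da = s$mass_da,
                 localization = if (is.null(s$localization)) "cytoplasm"
                                else s$localization,
                 footprint_nm2 = s$footprint_nm2,
                 provenance = if (is.null(s$provenance)) "generic"
                              else s$provenance)
  })
  names(species) <- vapply(species, `[[`, "", "id")
  pathways <- lapply(doc$pathways, function(p) {
    pathway_spec(p$id, p$length_reactions,
                 enzyme = if (is.null(p$enzyme)) "enz" else p$enzyme,
                 product_monomer = p$product_monomer,
                 atp_per_reaction = if (is.null(p$atp_per_reaction)) 0
                                    else p$atp_per_reaction)
  })
  names(pathways) <- vapply(pathways, `[[`, "", "id")
  geometry <- if (is.null(doc$geometry)) NULL else
    do.call(geometry_params, doc$geometry)
  energy <- if (is.null(doc$energy)) NULL else
    do.call(energy_params, doc$energy)
  mm <- if (is.null(doc$monomer_mass_da))
    list(aa = 110, nt = 324, dnt = 308) else doc$monomer_mass_da
  parameter_set(species, pathways, geometry, energy,
                couplings = if (is.null(doc$couplings)) list() else doc$couplings,
                monomer_mass_da = mm,
                source_note = if (is.null(doc$source_note)) "" else doc$source_note)
}

#' Load a parameter set from a YAML or JSON document
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`); both
#' carry the same schema, versioned by a top-level `schema_version` key.
#' Missing optional couplings are filled with defaults (one log line per
#' default); `geometry` and `energy` sections may be absent when only models
#' that do not need them will be built.
#'
#' @param source Path to a YAML/JSON file, or a plain list with the same
#'   structure.
#' @return A validated `sspcm_parameters` object.
#' @export
load_parameters <- function(source) {
  doc <- if (is.character(source)) {
    if (!file.exists(source))
      .stop_cond("protocell_config_error", "no such parameter file: %s", source)
    if (grepl("\\.ya?ml$", source, ignore.case = TRUE))
      yaml::read_yaml(source)
    else if (grepl("\\.json$", source, ignore.case = TRUE))
      jsonlite::fromJSON(source, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    else .stop_cond("protocell_config_error",
                    "unrecognized parameter file extension: %s", source)
  } else if (is.list(source)) source
  else .stop_cond("protocell_config_error",
                  "source must be a file path or a list")
  .plain_to_params(doc)
}

#' Write a parameter set to YAML or JSON
#'
#' @param params An `sspcm_parameters` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  plain <- .params_to_plain(params)
  plain$geometry_available <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(plain, path, precision = 17)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    .stop_cond("protocell_config_error",
               "unrecognized parameter file extension: %s", path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Coupling validation and calibration

#' Check that a parameter set satisfies the couplings a model needs
#'
#' Returns one row per check rather than erroring: callers decide what a
#' failure means. A `warn` status flags values that deviate from the
#' canonical stoichiometry (e.g. more than a pair of replisomes per genome)
#' without invalidating the model.
#'
#' @param params An `sspcm_parameters` object.
#' @param model_id One of the model ids from [sspcm_models()].
#' @return A data.frame with columns `check`, `status`
#'   (`"pass"`/`"fail"`/`"warn"`) and `note`.
#' @export
validate_couplings <- function(params, model_id) {
  spec <- model_spec(model_id)
  res <- list()
  add <- function(check, status, note = "")
    res[[length(res) + 1]] <<- data.frame(check = check, status = status,
                                          note = note)
  need <- spec$included_species
  missing <- setdiff(need, names(params$species))
  for (m in missing)
    add(paste0("species:", m), "fail",
        if (m == "dna") "genome species missing" else "species missing")
  for (m in setdiff(need, missing))
    add(paste0("species:", m), "pass")
  for (pw in spec$included_pathways) {
    if (is.null(params$pathways[[pw]]))
      add(paste0("pathway:", pw), "fail", "pathway missing")
    else add(paste0("pathway:", pw), "pass")
  }
  if (spec$has_dna) {
    rcg <- params$couplings$rc_per_genome
    if (is.null(rcg)) add("rc_per_genome", "fail", "coupling missing")
    else if (rcg != 2)
      add("rc_per_genome", "warn",
          sprintf("rc_per_genome = %g deviates from the canonical pair", rcg))
    else add("rc_per_genome", "pass")
  }
  if (spec$has_rna) {
    r1 <- params$couplings$rrna_per_ribosome
    if (is.null(r1) || r1 != 1)
      add("rrna_per_ribosome", "fail", "must be 1")
    else add("rrna_per_ribosome", "pass")
  }
  if (spec$has_membrane) {
    if (!isTRUE(params$geometry_available))
      add("geometry", "fail", "geometry section required for membrane models")
    else add("geometry", "pass")
  }
  if (spec$has_mprot) {
    if (is.null(params$energy))
      add("energy", "fail", "energy section required for membrane-protein models")
    else add("energy", "pass")
  }
  do.call(rbind, res)
}

#' Rescale free parameters so anchored observables are matched exactly
#'
#' A calibration fallback for when reference values for molecular
#' compositions are not at hand: each supported anchor is matched exactly by
#' rescaling the minimal set of free parameters, leaving everything else
#' untouched. Supported observables:
#' \describe{
#'   \item{`t_d_rs`}{doubling time of the lone ribosomal protein complex;
#'     rescales `n_rpc` to `t_d_rs * k_rs`.}
#'   \item{`t_d_rs_pw2`}{doubling time with the amino-acid pathway; rescales
#'     the enzyme composition `n_enz` so that
#'     `n_enz * l_PW2 / k_enz = t_d_rs_pw2 - t_d_rs`.}
#'   \item{`t_d_rs_pw2_rna`}{doubling time with RNA; rescales the mRNA
#'     coupling `mrna_nt_per_ribosome`.}
#' }
#' Calibration is idempotent: a second call with the same anchors changes
#' nothing.
#'
#' @param params An `sspcm_parameters` object (left unmodified).
#' @param anchors Named list/vector mapping observable names to values.
#' @return A new `sspcm_parameters` with `source_note` recording the
#'   calibration.
#' @export
calibrate_fallback <- function(params, anchors) {
  if (length(anchors) == 0) return(params)
  anchors <- as.list(anchors)
  known <- c("t_d_rs", "t_d_rs_pw2", "t_d_rs_pw2_rna")
  bad <- setdiff(names(anchors), known)
  if (length(bad) > 0)
    .stop_cond("protocell_config_error",
               "anchor references unknown observable(s): %s",
               paste(bad, collapse = ", "))
  out <- params
  note <- character()
  k_rs <- out$species$rpc$k_rate
  if (!is.null(anchors$t_d_rs)) {
    out$species$rpc$n_monomers <- anchors$t_d_rs * k_rs
    note <- c(note, sprintf("n_rpc <- %.6f (anchor t_d_rs = %g)",
                            out$species$rpc$n_monomers, anchors$t_d_rs))
  }
  t_d_rs <- out$species$rpc$n_monomers / k_rs
  if (!is.null(anchors$t_d_rs_pw2)) {
    pw2_term <- anchors$t_d_rs_pw2 - t_d_rs
    if (pw2_term < 0)
      .stop_cond("protocell_calibration_error",
                 "inconsistent anchors: t_d_rs_pw2 (%g) < t_d_rs (%g); residual %g",
                 anchors$t_d_rs_pw2, t_d_rs, pw2_term)
    l2 <- out$pathways$PW2$length_reactions
    k_enz <- out$species$enz$k_rate
    out$species$enz$n_monomers <- pw2_term * k_enz / l2
    note <- c(note, sprintf("n_enz <- %.6f (anchor t_d_rs_pw2 = %g)",
                            out$species$enz$n_monomers, anchors$t_d_rs_pw2))
  }
  if (!is.null(anchors$t_d_rs_pw2_rna)) {
    t3 <- anchors$t_d_rs_pw2_rna
    t2 <- t_d_rs + out$species$enz$n_monomers *
      out$pathways$PW2$length_reactions / out$species$enz$k_rate
    if (t3 < t2)
      .stop_cond("protocell_calibration_error",
                 "inconsistent anchors: t_d_rs_pw2_rna (%g) < t_d_rs_pw2 (%g)",
                 t3, t2)
    denom <- out$species$rp$n_monomers / out$species$rp$k_rate +
      out$pathways$PW4$length_reactions *
      out$species$enz$n_monomers / out$species$enz$k_rate
    rna_nt <- t3 * (t3 - t2) * k_rs / denom
    c_m <- rna_nt - out$species$rrna$n_monomers -
      out$couplings$trna_per_ribosome * out$species$trna$n_monomers
    if (c_m < 0)
      .stop_cond("protocell_calibration_error",
                 "anchor t_d_rs_pw2_rna = %g implies negative mRNA allocation (%g nt)",
                 t3, c_m)
    out$couplings$mrna_nt_per_ribosome <- c_m
    note <- c(note, sprintf("mrna_nt_per_ribosome <- %.6f (anchor t_d_rs_pw2_rna = %g)",
                            c_m, t3))
  }
  if (length(note) > 0)
    out$source_note <- paste(c(out$source_note, "calibrated:", note),
                             collapse = " ")
  out
}

#' @export
print.sspcm_parameters <- function(x, ...) {
  cat("Proto-cell parameter set (schema", x$schema_version, ")\n")
  cat("  species:\n")
  for (s in x$species)
    cat(sprintf("    %-5s %-16s n=%-12.6g k=%-8.4g %s [%s]\n",
                s$id, s$role, s$n_monomers,
                s$k_rate, s$localization, s$provenance))
  cat("  pathways:\n")
  for (p in x$pathways)
    cat(sprintf("    %s l=%-9.5g product=%s atp/rxn=%g\n",
                p$id, p$length_reactions, p$product_monomer,
                p$atp_per_reaction))
  if (!is.null(x$geometry))
    cat(sprintf("  geometry: %s (aspect %.4g, r %.3g um), %g nm2/lipid, water %.2f, density %.2f\n",
                x$geometry$shape_mode, x$geometry$aspect_ratio,
                x$geometry$radius_um, x$geometry$area_per_lipid_nm2,
                x$geometry$water_mass_fraction, x$geometry$density_g_per_cm3))
  cat("  couplings:",
      paste(sprintf("%s=%.6g", names(x$couplings), unlist(x$couplings)),
            collapse = ", "), "\n")
  if (nzchar(x$source_note)) cat("  note:", x$source_note, "\n")
  invisible(x)
}
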