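# The ten proto-cell models (SSPCMs), declared as data: each model is a set
# of included species and pathways plus structural flags. The compiler
# (build_model) turns a model plus a parameter set into a determined system
# of balance equations with one free driver variable.

.make_spec <- function(id, species, pathways = character(),
                       medium = "n/a", has_pool = FALSE,
                       extra_pools = NULL) {
  has_membrane <- "lip" %in% species
  has_mprot <- "etc" %in% species
  structure(list(
    id = id,
    included_species = species,
    included_pathways = pathways,
    has_rna = "rrna" %in% species,
    has_dna = "dna" %in% species,
    has_membrane = has_membrane,
    has_energy = has_mprot,
    has_mprot = has_mprot,
    has_pool = has_pool,
    medium = medium,
    driver_options = c("t_d_srs", "N_rs"),
    extra_pools = extra_pools
  ), class = "sspcm_model")
}

#' The ten proto-cell models
#'
#' Returns the registry of simplified single-cell proto-cell models, from
#' the bare ribosomal protein complex up to complete self-reproduction
#' systems on minimal and rich media. Models are data, not code: each entry
#' lists the included species and pathways; the compiler is shared.
#'
#' @return Named list of `sspcm_model` objects.
#' @export
sspcm_models <- function() {
  rna <- c("rp", "rrna", "trna", "mrna")
  list(
    `sspcm-rs` = .make_spec("sspcm-rs", "rpc"),
    `sspcm-rs+aa` = .make_spec("sspcm-rs+aa", c("rpc", "enz"), "PW2"),
    `sspcm-rs+aa+prot` = .make_spec("sspcm-rs+aa+prot", c("rpc", "enz"),
                                    "PW2", has_pool = TRUE,
                                    extra_pools = list(N_aa_prot = 5e4)),
    `sspcm-rs+aa+rna` = .make_spec("sspcm-rs+aa+rna",
                                   c("rpc", "enz", rna), c("PW2", "PW4")),
    `sspcm-rs+aa+rna+lip` = .make_spec("sspcm-rs+aa+rna+lip",
                                       c("rpc", "enz", rna, "lpe", "lip"),
                                       c("PW2", "PW4", "PW5")),
    `sspcm-rs+lip` = .make_spec("sspcm-rs+lip", c("rpc", "lpe", "lip")),
    `sspcm-rs+aa+rna+lip+mprot` = .make_spec(
      "sspcm-rs+aa+rna+lip+mprot",
      c("rpc", "enz", rna, "lpe", "lip", "etc", "tp"),
      c("PW1", "PW2", "PW4", "PW5"), medium = "minimal"),
    `sspcm-srs-m` = .make_spec(
      "sspcm-srs-m",
      c("rpc", "enz", rna, "lpe", "lip", "etc", "tp", "rc", "dna"),
      c("PW1", "PW2", "PW3", "PW4", "PW5"), medium = "minimal"),
    `sspcm-rs+dna` = .make_spec("sspcm-rs+dna",
                                c("rpc", "enz", "rc", "dna"), "PW3"),
    `sspcm-srs-r` = .make_spec(
      "sspcm-srs-r",
      c("rpc", rna, "lpe", "lip", "etc", "tp", "rc", "dna"),
      character(), medium = "rich")
  )
}

#' Look up one model specification
#'
#' @param model_id Model id string.
#' @param N_aa_prot Optional unspecified-protein pool size (polymerized
#'   amino acids), only meaningful for `sspcm-rs+aa+prot`.
#' @return An `sspcm_model`.
#' @export
model_spec <- function(model_id, N_aa_prot = NULL) {
  reg <- sspcm_models()
  if (!model_id %in% names(reg))
    .stop_cond("protocell_config_error",
               "unknown model id '%s'; valid ids: %s",
               model_id, paste(names(reg), collapse = ", "))
  spec <- reg[[model_id]]
  if (!is.null(N_aa_prot)) {
    if (!spec$has_pool)
      .stop_cond("protocell_config_error",
                 "model '%s' has no unspecified-protein pool", model_id)
    spec$extra_pools$N_aa_prot <- N_aa_prot
  }
  spec
}

# Which simpler model a hockey-stick model approaches as N_rs grows.
.asymptote_of <- c(
  "sspcm-rs+aa+prot" = "sspcm-rs+aa",
  "sspcm-rs+aa+rna+lip" = "sspcm-rs+aa+rna",
  "sspcm-rs+lip" = "sspcm-rs",
  "sspcm-rs+dna" = "sspcm-rs"
)

.is_group1 <- function(spec) {
  !spec$has_membrane && !spec$has_dna && !spec$has_pool
}

#' Compile a model into a determined equation system
#'
#' Assembles the balance equations of one proto-cell model: polymer doubling
#' balances for every polymer class present, per-pathway flux balances,
#' stoichiometric coupling equations (tRNA, mRNA, rRNA, replisomes,
#' membrane-protein demand), membrane-area and mass/volume balances when the
#' model has a membrane, and energy/transport balances when it has membrane
#' proteins. The system is determined: after fixing the driver, the number
#' of equations equals the number of unknowns.
#'
#' @param model_id Model id (see [sspcm_models()]).
#' @param params An `sspcm_parameters` object.
#' @param driver Named scalar, e.g. `c(t_d_srs = 2500)` or `c(N_rs = 1e4)`.
#' @param N_aa_prot Optional pool size for `sspcm-rs+aa+prot`.
#' @return An `sspcm_system`.
#' @export
build_model <- function(model_id, params, driver, N_aa_prot = NULL) {
  spec <- model_spec(model_id, N_aa_prot = N_aa_prot)
  chk <- validate_couplings(params, model_id)
  if (any(chk$status == "fail"))
    .stop_cond("protocell_assembly_error",
               "parameter set cannot build '%s': %s", model_id,
               paste(chk$check[chk$status == "fail"], collapse = ", "))
  dname <- names(driver)
  if (length(driver) != 1 || is.null(dname) ||
      !dname %in% spec$driver_options)
    .stop_cond("protocell_config_error",
               "driver must be a named scalar among: %s",
               paste(spec$driver_options, collapse = ", "))

  eqs <- list()
  unknowns <- setdiff(c("t_d_srs", "N_rs"), dname)

  prot_members <- list(list(key = "rpc", species = "rpc"))
  if (spec$has_rna)
    prot_members <- c(prot_members, list(list(key = "rp", species = "rp")))
  if (spec$has_dna)
    prot_members <- c(prot_members, list(list(key = "rc", species = "rc")))
  if (spec$has_membrane)
    prot_members <- c(prot_members, list(list(key = "lpe", species = "lpe")))
  for (pwid in spec$included_pathways)
    prot_members <- c(prot_members,
                      list(list(key = paste0("enz_", pwid), species = "enz")))
  if (spec$has_mprot)
    prot_members <- c(prot_members, list(list(key = "etc", species = "etc")),
                      list(list(key = "tp", species = "tp")))
  if (spec$has_pool)
    prot_members <- c(prot_members, list(list(key = "aa_pool",
                                              species = NA_character_)))
  eqs <- c(eqs, list(polymer_doubling_balance(
    "protein", prot_members, list(key = "rpc", species = "rpc"))))

  if (spec$has_rna) {
    rna_members <- list(list(key = "rrna", species = "rrna"),
                        list(key = "trna", species = "trna"),
                        list(key = "mrna", species = "mrna"))
    eqs <- c(eqs, list(polymer_doubling_balance(
      "rna", rna_members, list(key = "rp", species = "rp"))))
    unknowns <- c(unknowns, "N_rp")
    eqs <- c(eqs, list(
      .balance("coupling_rrna", "coupling", function(state, params)
        state$counts$rrna - params$couplings$rrna_per_ribosome *
          state$counts$rpc),
      .balance("coupling_trna", "coupling", function(state, params)
        state$counts$trna - params$couplings$trna_per_ribosome *
          state$counts$rpc),
      .balance("coupling_mrna", "coupling", function(state, params)
        state$mrna_nt - params$couplings$mrna_nt_per_ribosome *
          state$counts$rpc)))
    unknowns <- c(unknowns, "N_rrna", "N_trna", "mrna_nt")
  }

  if (spec$has_dna) {
    eqs <- c(eqs, list(
      dna_replication_balance(),
      .balance("coupling_genome", "coupling", function(state, params)
        state$counts$dna - params$couplings$genome_copies),
      .balance("coupling_rc", "coupling", function(state, params)
        state$counts$rc - params$couplings$rc_per_genome *
          state$counts$dna)))
    unknowns <- c(unknowns, "J_dnt", "N_genome", "N_rc")
  }

  if (spec$has_membrane) {
    eqs <- c(eqs, list(
      polymer_doubling_balance("lipid",
                               list(list(key = "lip", species = "lip")),
                               list(key = "lpe", species = "lpe")),
      membrane_area_balance()))
    eqs <- c(eqs, mass_volume_balance())
    unknowns <- c(unknowns, "N_lpe", "N_lip", "M_tot", "volume_um3")
  }

  for (pwid in spec$included_pathways) {
    pw <- params$pathways[[pwid]]
    demand <- switch(pwid,
      PW1 = function(state) {
        f <- state$fluxes
        sum(unlist(f[c("pathway_PW2", "pathway_PW3", "pathway_PW4",
                       "pathway_PW5")]), na.rm = TRUE)
      },
      PW2 = function(state) state$fluxes$translation_aa,
      PW3 = function(state) state$fluxes$replication_dnt,
      PW4 = function(state) state$fluxes$transcription_nt,
      PW5 = function(state) state$fluxes$lipid_synthesis)
    eqs <- c(eqs, list(pathway_flux_balance(pw, demand,
                                            paste0("enz_", pwid))))
    unknowns <- c(unknowns, paste0("N_enz_", pwid))
  }

  if (spec$has_mprot) {
    eqs <- c(eqs, energy_and_transport_balance())
    unknowns <- c(unknowns, "N_etc", "N_tp")
  }

  structure(list(model = spec, params = params,
                 driver = list(name = dname, value = unname(driver)),
                 unknowns = unknowns, equations = eqs),
            class = "sspcm_system")
}

#' Evaluate every residual of a system at a solution state
#'
#' @param system An `sspcm_system`.
#' @param state An `sspcm_state`.
#' @return Named numeric vector of residuals (zero at a valid solution).
#' @export
system_residuals <- function(system, state) {
  stats::setNames(
    vapply(system$equations,
           function(eq) eq$residual(state, system$params), numeric(1)),
    vapply(system$equations, `[[`, "", "name"))
}

#' Census of unknowns and equations
#'
#' A determined system has exactly as many equations as unknowns once the
#' driver is fixed; a mismatch is flagged.
#'
#' @param system An `sspcm_system`.
#' @return List with `n_unknowns`, `n_equations`, `driver`, `determined`.
#' @export
degrees_of_freedom_report <- function(system) {
  list(n_unknowns = length(system$unknowns),
       n_equations = length(system$equations),
       driver = system$driver$name,
       unknowns = system$unknowns,
       equations = vapply(system$equations, `[[`, "", "name"),
       determined = length(system$unknowns) == length(system$equations))
}

#' Analytic doubling time where a closed form exists
#'
#' Four models admit closed-form doubling times:
#' `sspcm-rs` (`n_rpc / k_rs`), `sspcm-rs+aa`
#' (`n_rpc / k_rs + n_enz l_PW2 / k_enz`), `sspcm-rs+aa+prot` (the former
#' plus `N_aa_prot / (N_rs k_rs)`, given the pool and ribosome count) and
#' `sspcm-rs+aa+rna` (positive root of the transcription-translation
#' quadratic). Models whose doubling time depends on cell size through the
#' membrane or the genome return `NA`.
#'
#' @param model_id Model id.
#' @param params An `sspcm_parameters` object.
#' @param N_rs Ribosome count (needed for `sspcm-rs+aa+prot`).
#' @param N_aa_prot Unspecified-protein pool (amino acids), for
#'   `sspcm-rs+aa+prot`.
#' @return Doubling time in seconds, or `NA_real_` when no closed form
#'   exists.
#' @export
closed_form_doubling_time <- function(model_id, params, N_rs = NULL,
                                      N_aa_prot = NULL) {
  sp <- params$species
  t_rs <- sp$rpc$n_monomers / sp$rpc$k_rate
  if (model_id == "sspcm-rs") return(t_rs)
  pw2_term <- function()
    sp$enz$n_monomers * params$pathways$PW2$length_reactions / sp$enz$k_rate
  if (model_id == "sspcm-rs+aa") return(t_rs + pw2_term())
  if (model_id == "sspcm-rs+aa+prot") {
    if (is.null(N_aa_prot))
      N_aa_prot <- model_spec(model_id)$extra_pools$N_aa_prot
    if (is.null(N_rs))
      .stop_cond("protocell_config_error",
                 "closed form for '%s' needs N_rs", model_id)
    return(t_rs + pw2_term() + N_aa_prot / (N_rs * sp$rpc$k_rate))
  }
  if (model_id == "sspcm-rs+aa+rna") {
    t2 <- t_rs + pw2_term()
    rna_nt_per_rs <- sp$rrna$n_monomers +
      params$couplings$trna_per_ribosome * sp$trna$n_monomers +
      params$couplings$mrna_nt_per_ribosome
    y <- rna_nt_per_rs / sp$rpc$k_rate *
      (sp$rp$n_monomers / sp$rp$k_rate +
         params$pathways$PW4$length_reactions *
         sp$enz$n_monomers / sp$enz$k_rate)
    return((t2 + sqrt(t2^2 + 4 * y)) / 2)
  }
  model_spec(model_id)  # errors on unknown id
  NA_real_
}

#' @export
print.sspcm_model <- function(x, ...) {
  cat(sprintf("<%s>  medium: %s\n", x$id, x$medium))
  cat("  species:", paste(x$included_species, collapse = ", "), "\n")
  if (length(x$included_pathways) > 0)
    cat("  pathways:", paste(x$included_pathways, collapse = ", "), "\n")
  flags <- c(membrane = x$has_membrane, dna = x$has_dna,
             energy = x$has_energy, protein_pool = x$has_pool)
  cat("  flags:", paste(names(flags)[flags], collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sspcm_system <- function(x, ...) {
  rep <- degrees_of_freedom_report(x)
  cat(sprintf("<equation system: %s>  driver %s = %g\n", x$model$id,
              x$driver$name, x$driver$value))
  cat(sprintf("  %d unknowns, %d equations (%s)\n", rep$n_unknowns,
              rep$n_equations,
              if (rep$determined) "determined" else "NOT determined"))
  invisible(x)
}
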