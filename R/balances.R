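# Balance-equation builders. Every cellular process of the stationary-state
# self-reproduction system is expressed as a residual that must vanish at a
# valid operating point: polymer doubling, pathway flux, DNA replication,
# energy production, substrate transport, membrane area and mass/volume.

.balance <- function(name, kind, residual) {
  structure(list(name = name, kind = kind, residual = residual),
            class = "balance_equation")
}

#' Polymer doubling balance
#'
#' During one doubling time the polymerase pool must re-synthesize every
#' member of its polymer class exactly once:
#' `t_d = sum(N_j * n_j) / (N_pol * k_pol)`.
#'
#' @param polymer_class `"protein"`, `"rna"`, `"dna"` or `"lipid"`.
#' @param members List of `list(key, species)` pairs: `key` names the count
#'   entry in the solution state, `species` the parameter-set species whose
#'   composition `n_monomers` applies. For the protein class the key
#'   `"aa_pool"` denotes the unspecified-protein amino-acid pool (already in
#'   monomer units).
#' @param polymerase `list(key, species)` for the catalyzing polymerase.
#' @return A `balance_equation` whose residual is
#'   `t_d - sum(N_j n_j)/(N_pol k_pol)` (seconds).
#' @export
polymer_doubling_balance <- function(polymer_class, members, polymerase) {
  force(members); force(polymerase)
  if (length(members) == 0)
    .stop_cond("protocell_assembly_error",
               "%s doubling balance needs at least one member", polymer_class)
  .balance(paste0(polymer_class, "_doubling"), "polymer_doubling",
    function(state, params) {
      tot <- 0
      for (m in members) {
        cnt <- if (identical(m$key, "aa_pool")) state$counts[["aa_pool"]]
               else state$counts[[m$key]]
        if (is.null(cnt)) cnt <- 0
        n <- if (identical(m$key, "aa_pool")) 1
             else if (identical(m$key, "mrna")) {
               # mRNA is tracked as total nucleotides
               tot <- tot + state$mrna_nt; next
             } else params$species[[m$species]]$n_monomers
        tot <- tot + cnt * n
      }
      npol <- state$counts[[polymerase$key]]
      kpol <- params$species[[polymerase$species]]$k_rate
      if (is.null(npol) || npol <= 0) return(NA_real_)
      state$t_d_srs - tot / (npol * kpol)
    })
}

#' Pathway flux balance and enzyme coupling
#'
#' All `l` reactions of a linear pathway carry the same flux, equal to the
#' downstream demand; every step needs `demand/k_enz` enzymes, so the total
#' enzyme count is `l * demand / k_enz`.
#'
#' @param pathway A [pathway_spec()].
#' @param demand_flux Function `(state) -> flux` giving the downstream
#'   consumption of the pathway product (events s^-1 cell^-1).
#' @param count_key Name of the enzyme-count entry in the state.
#' @return A `balance_equation` with residual
#'   `N_enz - l * demand / k_enz` (molecules).
#' @export
pathway_flux_balance <- function(pathway, demand_flux, count_key) {
  force(pathway); force(demand_flux); force(count_key)
  .balance(paste0("flux_", pathway$id), "flux_balance",
    function(state, params) {
      k_enz <- params$species[[pathway$enzyme]]$k_rate
      if (is.na(k_enz) || k_enz <= 0)
        .stop_cond("protocell_assembly_error",
                   "pathway %s: enzyme '%s' has no positive working rate",
                   pathway$id, pathway$enzyme)
      state$counts[[count_key]] -
        pathway$length_reactions * demand_flux(state) / k_enz
    })
}

#' Per-step enzyme demand of a linear pathway
#'
#' @param pathway A [pathway_spec()].
#' @param demand Downstream product flux (events s^-1).
#' @param k_enz Enzyme working rate (reactions s^-1).
#' @return List with `per_step` and `total` enzyme counts.
#' @export
pathway_enzyme_demand <- function(pathway, demand, k_enz) {
  if (k_enz <= 0)
    .stop_cond("protocell_assembly_error", "zero enzyme working rate")
  per_step <- demand / k_enz
  list(per_step = per_step, total = pathway$length_reactions * per_step)
}

#' DNA replication balance and feasibility constraint
#'
#' One genome copy (counting both strands) is replicated per doubling by a
#' fixed pair of replisomes; the required per-replisome rate
#' `n_dna / (N_rc * t_d)` must not exceed the replisome working rate.
#'
#' @return A `balance_equation` with residual
#'   `J_dnt - n_dna * genome_copies / t_d` (nt s^-1); the feasibility flag
#'   is carried on the solution state (`dna_infeasible`), never clamped.
#' @export
dna_replication_balance <- function() {
  .balance("dna_replication", "replication",
    function(state, params) {
      state$fluxes[["replication_dnt"]] -
        params$species$dna$n_monomers * params$couplings$genome_copies /
          state$t_d_srs
    })
}

#' Energy and transport balances
#'
#' The electron transport chain on the membrane must produce exactly the ATP
#' consumed by monomer biosynthesis, polymerization and substrate transport;
#' the transporter pool must import exactly the substrate demand. Both
#' membrane-protein counts are outputs determined by demand.
#'
#' @return A list of two `balance_equation`s (`energy`, `transport`) with
#'   residuals `N_etc * k_etc - J_atp` and `N_tp * k_tp - J_transport`.
#' @export
energy_and_transport_balance <- function() {
  list(
    .balance("energy", "energy", function(state, params) {
      state$counts[["etc"]] * params$species$etc$k_rate -
        state$fluxes[["atp"]]
    }),
    .balance("transport", "transport", function(state, params) {
      state$counts[["tp"]] * params$species$tp$k_rate -
        state$fluxes[["transport"]]
    })
  )
}

#' Membrane area balance
#'
#' The geometric surface area equals the summed footprints of the membrane
#' components; the lipid count is determined by the area not occupied by
#' membrane proteins (both leaflets, so each lipid contributes
#' `area_per_lipid / 2` to the cross-section). A negative remaining area is
#' reported as infeasibility (the growth boundary), never clamped.
#'
#' @return A `balance_equation` with residual
#'   `A_geometric - (N_etc a_etc + N_tp a_tp + N_lip a_lip / 2)` in nm^2.
#' @export
membrane_area_balance <- function() {
  .balance("membrane_area", "area",
    function(state, params) {
      occ <- state$counts[["lip"]] * params$geometry$area_per_lipid_nm2 / 2
      if (!is.null(state$counts[["etc"]]))
        occ <- occ + state$counts[["etc"]] * params$species$etc$footprint_nm2 +
                     state$counts[["tp"]]  * params$species$tp$footprint_nm2
      state$area_um2 * protocell_constants$um2_to_nm2 - occ
    })
}

#' Mass and volume balances
#'
#' Dry mass is the sum of component masses; total mass includes water
#' (`M_tot = dry / (1 - water_mass_fraction)`); volume follows from the wet
#' density.
#'
#' @return A list of two `balance_equation`s (`mass`, `volume`).
#' @export
mass_volume_balance <- function() {
  list(
    .balance("mass", "mass_volume", function(state, params) {
      state$M_tot - state$dry_mass / (1 - params$geometry$water_mass_fraction)
    }),
    .balance("volume", "mass_volume", function(state, params) {
      rho_um3 <- params$geometry$density_g_per_cm3 * 1e-12  # g per um^3
      state$volume_um3 - state$M_tot / rho_um3
    })
  )
}

# ---------------------------------------------------------------------------
# Compiled numeric context and the state core. The context flattens model
# flags and parameter values into plain scalars once per solve, so the inner
# root-finding loops stay cheap.

.compile_ctx <- function(spec, params) {
  sp <- params$species
  gp <- params$geometry
  en <- params$energy
  cp <- params$couplings
  pw <- params$pathways
  haspw <- function(id) id %in% spec$included_pathways
  lp <- function(id) if (haspw(id)) pw[[id]]$length_reactions else 0
  ap <- function(id) if (haspw(id)) pw[[id]]$atp_per_reaction else 0
  list(
    id = spec$id,
    has_rna = spec$has_rna, has_dna = spec$has_dna,
    has_membrane = spec$has_membrane, has_mprot = spec$has_mprot,
    has_pool = spec$has_pool, rich = identical(spec$medium, "rich"),
    pw1 = haspw("PW1"), pw2 = haspw("PW2"), pw3 = haspw("PW3"),
    pw4 = haspw("PW4"), pw5 = haspw("PW5"),
    l1 = lp("PW1"), l2 = lp("PW2"), l3 = lp("PW3"),
    l4 = lp("PW4"), l5 = lp("PW5"),
    ax1 = ap("PW1"), ax2 = ap("PW2"), ax3 = ap("PW3"),
    ax4 = ap("PW4"), ax5 = ap("PW5"),
    k_rs = sp$rpc$k_rate, n_rpc = sp$rpc$n_monomers,
    n_rp = if (!is.null(sp$rp)) sp$rp$n_monomers else 0,
    k_rp = if (!is.null(sp$rp)) sp$rp$k_rate else NA_real_,
    n_rc = if (!is.null(sp$rc)) sp$rc$n_monomers else 0,
    k_rc = if (!is.null(sp$rc)) sp$rc$k_rate else NA_real_,
    n_lpe = if (!is.null(sp$lpe)) sp$lpe$n_monomers else 0,
    k_lpe = if (!is.null(sp$lpe)) sp$lpe$k_rate else NA_real_,
    n_enz = if (!is.null(sp$enz)) sp$enz$n_monomers else 0,
    k_enz = if (!is.null(sp$enz)) sp$enz$k_rate else NA_real_,
    n_etc = if (!is.null(sp$etc)) sp$etc$n_monomers else 0,
    k_etc = if (!is.null(sp$etc)) sp$etc$k_rate else NA_real_,
    a_etc = if (!is.null(sp$etc)) sp$etc$footprint_nm2 else 0,
    n_tp = if (!is.null(sp$tp)) sp$tp$n_monomers else 0,
    k_tp = if (!is.null(sp$tp)) sp$tp$k_rate else NA_real_,
    a_tp = if (!is.null(sp$tp)) sp$tp$footprint_nm2 else 0,
    n_rrna = if (!is.null(sp$rrna)) sp$rrna$n_monomers else 0,
    n_trna = if (!is.null(sp$trna)) sp$trna$n_monomers else 0,
    n_mrna = if (!is.null(sp$mrna)) sp$mrna$n_monomers else 900,
    n_dna = if (!is.null(sp$dna)) sp$dna$n_monomers else 0,
    c_trna = cp$trna_per_ribosome, c_mrna = cp$mrna_nt_per_ribosome,
    rc_per_genome = cp$rc_per_genome, genome_copies = cp$genome_copies,
    m_aa = params$monomer_mass_da$aa, m_nt = params$monomer_mass_da$nt,
    m_dnt = params$monomer_mass_da$dnt,
    m_lip = if (!is.null(sp$lip)) species_mass_da(params, "lip") else 0,
    a_lip = if (!is.null(gp)) gp$area_per_lipid_nm2 else NA_real_,
    water = if (!is.null(gp)) gp$water_mass_fraction else NA_real_,
    rho_um3 = if (!is.null(gp)) gp$density_g_per_cm3 * 1e-12 else NA_real_,
    geometry = gp,
    e_aa = if (!is.null(en)) en$atp_per_aa_polymerized else 0,
    e_nt = if (!is.null(en)) en$atp_per_nt_polymerized else 0,
    e_dnt = if (!is.null(en)) en$atp_per_dnt_polymerized else 0,
    e_lip = if (!is.null(en)) en$atp_per_lipid else 0,
    e_tp = if (!is.null(en)) en$atp_per_transport else 0,
    s_mon = if (!is.null(en)) en$substrates_per_monomer else 0,
    da_g = protocell_constants$da_to_g,
    pool = if (spec$has_pool) spec$extra_pools$N_aa_prot else 0
  )
}

# All derived scalars of the operating point (t, N_rs, N_lip). Everything
# except the protein-doubling and membrane-area residuals is constructed
# directly from the stoichiometric couplings, so those two residuals are the
# only root-finding targets.
.state_core <- function(ctx, t, N, L = 0) {
  J_aa <- N * ctx$k_rs
  if (ctx$has_rna) {
    rna_nt_per_rs <- ctx$n_rrna + ctx$c_trna * ctx$n_trna + ctx$c_mrna
    rna_nt <- rna_nt_per_rs * N
    J_nt <- rna_nt / t
    N_rp <- J_nt / ctx$k_rp
  } else { rna_nt <- 0; J_nt <- 0; N_rp <- 0 }
  if (ctx$has_dna) {
    N_gen <- ctx$genome_copies
    N_rc <- ctx$rc_per_genome * N_gen
    J_dnt <- ctx$n_dna * N_gen / t
    dna_rate_required <- J_dnt / N_rc
    dna_infeasible <- dna_rate_required > ctx$k_rc * (1 + 1e-12)
  } else {
    N_gen <- 0; N_rc <- 0; J_dnt <- 0
    dna_rate_required <- 0; dna_infeasible <- FALSE
  }
  if (ctx$has_membrane) {
    J_lip <- L / t
    N_lpe <- J_lip / ctx$k_lpe
  } else { J_lip <- 0; N_lpe <- 0 }

  J_pw2 <- if (ctx$pw2) J_aa else 0
  J_pw3 <- if (ctx$pw3) J_dnt else 0
  J_pw4 <- if (ctx$pw4) J_nt else 0
  J_pw5 <- if (ctx$pw5) J_lip else 0
  J_pw1 <- if (ctx$pw1) J_pw2 + J_pw3 + J_pw4 + J_pw5 else 0
  N_enz1 <- if (ctx$pw1) ctx$l1 * J_pw1 / ctx$k_enz else 0
  N_enz2 <- if (ctx$pw2) ctx$l2 * J_pw2 / ctx$k_enz else 0
  N_enz3 <- if (ctx$pw3) ctx$l3 * J_pw3 / ctx$k_enz else 0
  N_enz4 <- if (ctx$pw4) ctx$l4 * J_pw4 / ctx$k_enz else 0
  N_enz5 <- if (ctx$pw5) ctx$l5 * J_pw5 / ctx$k_enz else 0

  if (ctx$has_mprot) {
    J_transport <- if (ctx$rich) J_aa + J_nt + J_dnt + J_lip
                   else ctx$s_mon * J_pw1
    J_atp <- ctx$e_aa * J_aa + ctx$e_nt * J_nt + ctx$e_dnt * J_dnt +
      ctx$e_lip * J_lip +
      ctx$ax1 * ctx$l1 * J_pw1 + ctx$ax2 * ctx$l2 * J_pw2 +
      ctx$ax3 * ctx$l3 * J_pw3 + ctx$ax4 * ctx$l4 * J_pw4 +
      ctx$ax5 * ctx$l5 * J_pw5 +
      ctx$e_tp * J_transport
    N_etc <- J_atp / ctx$k_etc
    N_tp <- J_transport / ctx$k_tp
  } else { J_transport <- 0; J_atp <- 0; N_etc <- 0; N_tp <- 0 }

  aa_total <- N * ctx$n_rpc + N_rp * ctx$n_rp + N_rc * ctx$n_rc +
    N_lpe * ctx$n_lpe +
    (N_enz1 + N_enz2 + N_enz3 + N_enz4 + N_enz5) * ctx$n_enz +
    N_etc * ctx$n_etc + N_tp * ctx$n_tp + ctx$pool

  dry_da <- ctx$m_aa * aa_total + ctx$m_nt * rna_nt +
    ctx$m_dnt * ctx$n_dna * N_gen + ctx$m_lip * L
  dry_g <- dry_da * ctx$da_g

  if (ctx$has_membrane) {
    M_tot <- dry_g / (1 - ctx$water)
    V <- M_tot / ctx$rho_um3
    dims <- cell_dimensions(V, ctx$geometry)
    area_nm2 <- dims$area_um2 * 1e6
    occupied_nm2 <- N_etc * ctx$a_etc + N_tp * ctx$a_tp + L * ctx$a_lip / 2
    area_resid <- area_nm2 - occupied_nm2
  } else {
    M_tot <- dry_g / (1 - 0.70)  # conventional water fraction for reporting
    if (!is.na(ctx$water)) M_tot <- dry_g / (1 - ctx$water)
    V <- if (!is.na(ctx$rho_um3)) M_tot / ctx$rho_um3 else NA_real_
    dims <- NULL
    area_resid <- NA_real_
    occupied_nm2 <- NA_real_
  }

  list(t = t, N = N, L = L,
       J_aa = J_aa, J_nt = J_nt, J_dnt = J_dnt, J_lip = J_lip,
       J_pw1 = J_pw1, J_pw2 = J_pw2, J_pw3 = J_pw3, J_pw4 = J_pw4,
       J_pw5 = J_pw5, J_transport = J_transport, J_atp = J_atp,
       N_rp = N_rp, N_rc = N_rc, N_gen = N_gen, N_lpe = N_lpe,
       N_enz1 = N_enz1, N_enz2 = N_enz2, N_enz3 = N_enz3,
       N_enz4 = N_enz4, N_enz5 = N_enz5, N_etc = N_etc, N_tp = N_tp,
       rna_nt = rna_nt, aa_total = aa_total,
       dry_g = dry_g, M_tot = M_tot, V = V, dims = dims,
       protein_resid = N * ctx$k_rs * t - aa_total,
       area_resid = area_resid, occupied_nm2 = occupied_nm2,
       dna_rate_required = dna_rate_required,
       dna_infeasible = dna_infeasible)
}

# Full solution state (exported container) from a solved core.
.state_from_core <- function(core, ctx, spec, params, feasible = TRUE,
                             notes = character()) {
  counts <- list(rpc = core$N)
  if (ctx$has_rna) {
    counts$rp <- core$N_rp
    counts$rrna <- core$N
    counts$trna <- ctx$c_trna * core$N
    counts$mrna <- ctx$c_mrna * core$N / ctx$n_mrna
  }
  if (ctx$has_dna) { counts$rc <- core$N_rc; counts$dna <- core$N_gen }
  if (ctx$has_membrane) { counts$lip <- core$L; counts$lpe <- core$N_lpe }
  if (ctx$pw1) counts$enz_PW1 <- core$N_enz1
  if (ctx$pw2) counts$enz_PW2 <- core$N_enz2
  if (ctx$pw3) counts$enz_PW3 <- core$N_enz3
  if (ctx$pw4) counts$enz_PW4 <- core$N_enz4
  if (ctx$pw5) counts$enz_PW5 <- core$N_enz5
  if (ctx$has_mprot) { counts$etc <- core$N_etc; counts$tp <- core$N_tp }
  if (ctx$has_pool) counts$aa_pool <- ctx$pool

  fluxes <- list(translation_aa = core$J_aa)
  if (ctx$has_rna) fluxes$transcription_nt <- core$J_nt
  if (ctx$has_dna) fluxes$replication_dnt <- core$J_dnt
  if (ctx$has_membrane) fluxes$lipid_synthesis <- core$J_lip
  for (i in 1:5) {
    if (ctx[[paste0("pw", i)]])
      fluxes[[paste0("pathway_PW", i)]] <- core[[paste0("J_pw", i)]]
  }
  if (ctx$has_mprot) {
    fluxes$atp <- core$J_atp
    fluxes$transport <- core$J_transport
  }

  # dry-mass fractions by component group
  gmass <- c(
    ribosomal = ctx$m_aa * core$N * ctx$n_rpc +
      ctx$m_nt * ctx$n_rrna * (if (ctx$has_rna) core$N else 0),
    rna_other = if (ctx$has_rna)
      ctx$m_nt * (ctx$c_trna * ctx$n_trna + ctx$c_mrna) * core$N else 0,
    polymerase = ctx$m_aa * core$N_rp * ctx$n_rp,
    dna_associated = ctx$m_dnt * ctx$n_dna * core$N_gen +
      ctx$m_aa * (core$N_rc * ctx$n_rc + core$N_enz3 * ctx$n_enz),
    enzymes = ctx$m_aa * ((core$N_enz1 + core$N_enz2 + core$N_enz4 +
                             core$N_enz5) * ctx$n_enz +
                            core$N_lpe * ctx$n_lpe),
    membrane_protein = ctx$m_aa * (core$N_etc * ctx$n_etc +
                                     core$N_tp * ctx$n_tp),
    lipid = ctx$m_lip * core$L,
    protein_pool = ctx$m_aa * ctx$pool
  )
  mass_fractions <- gmass * ctx$da_g / core$dry_g

  lip_area_um2 <- if (ctx$has_membrane) core$L * ctx$a_lip / 2 / 1e6
                  else NA_real_

  structure(list(
    model_id = spec$id,
    t_d_srs = core$t,
    counts = counts,
    mrna_nt = if (ctx$has_rna) ctx$c_mrna * core$N else 0,
    fluxes = fluxes,
    dry_mass = core$dry_g,
    M_tot = core$M_tot,
    volume_um3 = core$V,
    area_um2 = if (!is.null(core$dims)) core$dims$area_um2 else NA_real_,
    lipid_area_um2 = lip_area_um2,
    shape = core$dims,
    mass_fractions = mass_fractions,
    lip_per_rs = if (ctx$has_membrane) core$L / core$N else NA_real_,
    dna_rate_required = core$dna_rate_required,
    status = if (feasible) "ok" else "infeasible",
    infeasibility = notes
  ), class = "sspcm_state")
}

#' @export
print.sspcm_state <- function(x, ...) {
  cat(sprintf("<%s> t_d_srs = %.6g s  [%s]\n", x$model_id, x$t_d_srs,
              x$status))
  if (length(x$infeasibility) > 0)
    cat("  infeasibility:", paste(x$infeasibility, collapse = "; "), "\n")
  cat(sprintf("  N_rs = %.6g; M_tot = %.4g g; dry = %.4g g\n",
              x$counts$rpc, x$M_tot, x$dry_mass))
  if (!is.na(x$volume_um3))
    cat(sprintf("  V = %.4g um^3; A = %.4g um^2; lipid area = %.4g um^2\n",
                x$volume_um3, x$area_um2, x$lipid_area_um2))
  frac <- x$mass_fractions[x$mass_fractions > 0]
  cat("  dry-mass fractions:",
      paste(sprintf("%s %.3g", names(frac), frac), collapse = ", "), "\n")
  invisible(x)
}
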