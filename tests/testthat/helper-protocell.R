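# Shared helpers: fixture shortcuts and residual-scale normalization.

toy_analytic <- function() generate_fixtures("toy_analytic")
toy_membrane <- function() generate_fixtures("toy_membrane")
toy_dna <- function() generate_fixtures("toy_dna")

# Residuals normalized by the natural scale of each balance so that
# "residual < 1e-8 * scale" is a single comparison.
scaled_residuals <- function(state, system) {
  res <- system_residuals(system, state)
  scale <- vapply(names(res), function(nm) {
    if (grepl("doubling", nm)) state$t_d_srs
    else if (nm == "membrane_area") state$area_um2 * 1e6
    else if (nm == "energy") max(1, state$fluxes$atp)
    else if (nm == "transport") max(1, state$fluxes$transport)
    else if (nm == "dna_replication") max(1, state$fluxes$replication_dnt)
    else if (startsWith(nm, "flux_")) max(1, state$counts$rpc)
    else max(1, state$counts$rpc)
  }, numeric(1))
  abs(res) / scale
}

solve_with_system <- function(model_id, params, driver, ...) {
  sys <- build_model(model_id, params, driver, ...)
  list(system = sys, state = solve_at(sys))
}
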