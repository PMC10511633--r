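# Solving a compiled model at an operating point, sweeping a driver, and
# extracting doubling-time limits. All root-finding is deterministic:
# brackets are found by geometric expansion from stoichiometric initial
# guesses and refined with uniroot at near-machine tolerance.

.UNIROOT_TOL <- 1e-13

# Inner solve: lipid count from the membrane-area balance at fixed (t, N).
# The geometric area grows more slowly with N_lip than the occupied
# cross-section (lipid volume adds ~0.06 nm^2 of area per lipid vs 0.25 nm^2
# occupied), so the residual is strictly decreasing and the root unique.
# A negative residual at N_lip = 0 means membrane proteins alone exceed the
# surface: infeasible (the growth boundary), reported, never clamped.
.solve_L <- function(ctx, t, N) {
  if (!ctx$has_membrane)
    return(list(L = 0, feasible = TRUE, core = .state_core(ctx, t, N, 0)))
  f <- function(L) .state_core(ctx, t, N, L)$area_resid
  r0 <- f(0)
  if (is.na(r0) || r0 < 0)
    return(list(L = 0, feasible = FALSE, core = .state_core(ctx, t, N, 0)))
  if (r0 == 0)
    return(list(L = 0, feasible = TRUE, core = .state_core(ctx, t, N, 0)))
  hi <- max(2 * r0 / ctx$a_lip * 2, 1)
  for (i in 1:500) {
    if (f(hi) < 0) break
    hi <- hi * 2
    if (i == 500)
      .stop_cond("protocell_solver_error",
                 "lipid-area bracket expansion failed at t=%g, N=%g", t, N)
  }
  root <- stats::uniroot(f, lower = 0, upper = hi, f.lower = r0,
                         tol = max(1e-12, hi * 1e-15))$root
  list(L = root, feasible = TRUE, core = .state_core(ctx, t, N, root))
}

# Outer solve in N at fixed doubling time. The scaled protein residual
# g(N)/N is strictly increasing in N (the lipid burden per ribosome falls
# and fixed DNA terms dilute), so the sign change is unique.
.solve_given_t <- function(ctx, t) {
  last <- NULL
  g <- function(x) {
    sol <- .solve_L(ctx, t, exp(x))
    last <<- sol
    sol$core$protein_resid
  }
  x <- 0
  v <- g(x)
  if (is.na(v))
    .stop_cond("protocell_solver_error", "residual undefined at t=%g", t)
  if (v < 0) {
    lo <- x
    repeat {
      x <- x + 2
      if (x > 140) return(list(status = "no_solution", t = t))
      if (g(x) > 0) break
      lo <- x
    }
    hi <- x
  } else {
    hi <- x
    repeat {
      x <- x - 2
      if (x < -140) return(list(status = "no_solution", t = t))
      if (g(x) < 0) break
      hi <- x
    }
    lo <- x
  }
  root <- stats::uniroot(g, lower = lo, upper = hi, tol = .UNIROOT_TOL)
  g(root$root)  # refresh `last` at the root
  notes <- character()
  if (!last$feasible)
    notes <- c(notes, "membrane surface exhausted: lipid area would be negative")
  if (last$core$dna_infeasible)
    notes <- c(notes, sprintf(
      "replication infeasible: required %.6g nt/s per replisome > k_rc = %.6g",
      last$core$dna_rate_required, ctx$k_rc))
  list(status = if (length(notes) == 0) "ok" else "infeasible",
       core = last$core, notes = notes)
}

# Outer solve in doubling time at fixed ribosome count. The protein
# residual N k t - aa_total(t) is increasing in t over the feasible range.
.solve_given_N <- function(ctx, N) {
  last <- NULL
  h <- function(t) {
    sol <- .solve_L(ctx, t, N)
    last <<- sol
    if (!sol$feasible) return(NA_real_)  # infeasible side
    sol$core$protein_resid
  }
  t <- 10
  v <- h(t)
  tries <- 0
  while (is.na(v)) {  # expand up to find a feasible doubling time
    t <- t * 2
    tries <- tries + 1
    if (tries > 80)
      .stop_cond("protocell_solver_error",
                 "no feasible doubling time found for N_rs = %g", N)
    v <- h(t)
  }
  if (v > 0) {
    # root lies below; walk down until the residual changes sign or the
    # feasibility boundary is hit
    hi <- t
    lo <- NULL
    repeat {
      t2 <- t / 2
      v2 <- h(t2)
      if (is.na(v2)) {
        # bisect the feasibility transition in (t2, t)
        a <- t2; b <- t
        for (i in 1:200) {
          if ((b - a) <= 1e-9 * b) break
          m <- (a + b) / 2
          if (is.na(h(m))) a <- m else b <- m
        }
        if (h(b) > 0)
          return(list(status = "infeasible", t = b, core = last$core,
                      notes = "N_rs exceeds the membrane growth boundary"))
        lo <- b
        break
      }
      if (v2 < 0) { lo <- t2; break }
      t <- t2; hi <- t2 * 2
      if (t < 1e-9)
        .stop_cond("protocell_solver_error",
                   "no positive doubling time for N_rs = %g", N)
    }
  } else {
    lo <- t
    repeat {
      t <- t * 2
      if (t > 1e18)
        .stop_cond("protocell_solver_error",
                   "doubling time bracket expansion failed for N_rs = %g", N)
      if (h(t) > 0) break
      lo <- t
    }
    hi <- t
  }
  root <- stats::uniroot(function(x) h(exp(x)), lower = log(lo),
                         upper = log(hi), tol = .UNIROOT_TOL)
  tstar <- exp(root$root)
  h(tstar)
  notes <- character()
  if (last$core$dna_infeasible)
    notes <- c(notes, sprintf(
      "replication infeasible: required %.6g nt/s per replisome > k_rc = %.6g",
      last$core$dna_rate_required, ctx$k_rc))
  list(status = if (length(notes) == 0) "ok" else "infeasible",
       core = last$core, notes = notes)
}

#' Solve a compiled equation system at its operating point
#'
#' Finds the unique positive solution of the determined balance system with
#' the driver fixed, verifies every residual, and returns the full solution
#' state. Infeasible operating points (membrane surface exhausted, or
#' replication faster than the replisomes allow) are returned as a typed
#' infeasible state, never clamped.
#'
#' @param system An `sspcm_system` from [build_model()].
#' @return An `sspcm_state`; its `status` field is `"ok"` or
#'   `"infeasible"`, and `residuals` carries the per-equation residuals.
#' @export
solve_at <- function(system) {
  spec <- system$model
  params <- system$params
  ctx <- .compile_ctx(spec, params)
  dn <- system$driver$name
  dv <- system$driver$value
  if (dn == "t_d_srs") {
    if (.is_group1(spec))
      .stop_cond("protocell_config_error",
        "'%s' has a size-independent doubling time; drive it by N_rs",
        spec$id)
    res <- .solve_given_t(ctx, dv)
  } else {
    res <- .solve_given_N(ctx, dv)
  }
  if (identical(res$status, "no_solution"))
    .stop_cond("protocell_solver_error",
               "no positive solution of '%s' at %s = %g (below the doubling-time limit?)",
               spec$id, dn, dv)
  state <- .state_from_core(res$core, ctx, spec, params,
                            feasible = identical(res$status, "ok"),
                            notes = res$notes)
  state$residuals <- system_residuals(system, state)
  state
}

#' Build and solve one model in a single call
#'
#' @param model_id Model id (see [sspcm_models()]).
#' @param params An `sspcm_parameters` object; defaults to
#'   [default_parameters()].
#' @param t_d Doubling time driver (s), or
#' @param N_rs ribosome-count driver (exactly one of the two).
#' @param N_aa_prot Optional unspecified-protein pool.
#' @return An `sspcm_state`.
#' @export
solve_model <- function(model_id, params = default_parameters(),
                        t_d = NULL, N_rs = NULL, N_aa_prot = NULL) {
  if (is.null(t_d) == is.null(N_rs))
    .stop_cond("protocell_config_error",
               "give exactly one driver: t_d or N_rs")
  driver <- if (!is.null(t_d)) c(t_d_srs = t_d) else c(N_rs = N_rs)
  solve_at(build_model(model_id, params, driver, N_aa_prot = N_aa_prot))
}

#' Sweep a model over a driver grid
#'
#' One solve per grid point; infeasible points and per-point solver errors
#' are recorded, never aborting the sweep (infeasibility near a growth
#' boundary is itself the result).
#'
#' @param model_id Model id.
#' @param params An `sspcm_parameters` object.
#' @param driver `"N_rs"` or `"t_d_srs"`.
#' @param grid Strictly increasing numeric vector of driver values.
#' @param N_aa_prot Optional pool for `sspcm-rs+aa+prot`.
#' @return An `sspcm_sweep`; coerce with `as.data.frame()`.
#' @export
sweep_model <- function(model_id, params = default_parameters(),
                        driver = "N_rs", grid, N_aa_prot = NULL) {
  if (length(grid) < 1 || any(diff(grid) <= 0))
    .stop_cond("protocell_config_error", "grid must be strictly increasing")
  states <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    states[[i]] <- tryCatch(
      solve_model(model_id, params,
                  t_d = if (driver == "t_d_srs") grid[i] else NULL,
                  N_rs = if (driver == "N_rs") grid[i] else NULL,
                  N_aa_prot = N_aa_prot),
      protocell_error = function(e)
        structure(list(model_id = model_id, status = "error",
                       infeasibility = conditionMessage(e)),
                  class = "sspcm_state"))
  }
  structure(list(model_id = model_id, driver = driver, grid = grid,
                 states = states,
                 params_fingerprint = .params_fingerprint(params)),
            class = "sspcm_sweep")
}

.params_fingerprint <- function(params) {
  nums <- unlist(.params_to_plain(params))
  nums <- suppressWarnings(as.numeric(nums))
  sprintf("v1:%0.10e", sum(nums[is.finite(nums)]))
}

#' @export
as.data.frame.sspcm_sweep <- function(x, ...) {
  pick <- function(s, field, sub = NULL) {
    if (identical(s$status, "error")) return(NA_real_)
    v <- if (is.null(sub)) s[[field]] else s[[field]][[sub]]
    if (is.null(v)) NA_real_ else v
  }
  data.frame(
    driver = x$grid,
    t_d_srs = vapply(x$states, pick, 0, "t_d_srs"),
    N_rs = vapply(x$states, pick, 0, "counts", "rpc"),
    N_lip = vapply(x$states, pick, 0, "counts", "lip"),
    lip_per_rs = vapply(x$states, pick, 0, "lip_per_rs"),
    M_tot = vapply(x$states, pick, 0, "M_tot"),
    volume_um3 = vapply(x$states, pick, 0, "volume_um3"),
    area_um2 = vapply(x$states, pick, 0, "area_um2"),
    status = vapply(x$states, function(s) s$status, ""),
    row.names = NULL
  )
}

#' Doubling-time limit of one model
#'
#' For models with membrane proteins the minimal doubling time is found by
#' bisecting the feasible/infeasible transition where the lipid-covered
#' surface area reaches zero (membrane exhaustion); the maximal ribosome
#' count is the value at that boundary. For the remaining models the
#' minimal doubling time is the closed-form/asymptotic value; a finite
#' "maximal" ribosome count then exists only under an explicit convergence
#' convention: the smallest count whose doubling time is within
#' `epsilon_asym` of the asymptote (reported as `tolerance_defined`, a
#' convention rather than a physical boundary). Group-1 models have no size
#' limit at all (`Inf`).
#'
#' @param model_id Model id.
#' @param params An `sspcm_parameters` object.
#' @param t_tol Bisection tolerance on the boundary doubling time (s).
#' @param epsilon_asym Convergence tolerance (s) defining the conventional
#'   maximal ribosome count of asymptotic models.
#' @param N_aa_prot Optional pool for `sspcm-rs+aa+prot`.
#' @return An `sspcm_limit` list: `t_d_min`, `t_d_min_obtained`,
#'   `N_rs_max`, `N_rs_max_obtained`, plus the classification fields of
#'   [classify_limit()].
#' @export
find_growth_boundary <- function(model_id, params = default_parameters(),
                                 t_tol = 1e-6, epsilon_asym = 0.005,
                                 N_aa_prot = NULL) {
  spec <- model_spec(model_id, N_aa_prot = N_aa_prot)
  ctx <- .compile_ctx(spec, params)
  if (spec$has_mprot) {
    feasible <- function(t) {
      r <- .solve_given_t(ctx, t)
      identical(r$status, "ok")
    }
    t_hi <- 10
    tries <- 0
    while (!feasible(t_hi)) {
      t_hi <- t_hi * 2
      tries <- tries + 1
      if (tries > 60)
        .stop_cond("protocell_boundary_error",
                   "no feasible doubling time found for '%s'", model_id)
    }
    t_lo <- t_hi / 2
    while (feasible(t_lo)) {
      t_lo <- t_lo / 2
      if (t_lo < 1e-6)
        .stop_cond("protocell_boundary_error",
                   "no infeasible bracket end found for '%s' (no boundary?)",
                   model_id)
    }
    while (t_hi - t_lo > t_tol) {
      mid <- (t_lo + t_hi) / 2
      if (feasible(mid)) t_hi <- mid else t_lo <- mid
    }
    res <- .solve_given_t(ctx, t_hi)
    lim <- list(model_id = model_id, t_d_min = t_hi,
                t_d_min_obtained = "boundary_root",
                N_rs_max = res$core$N,
                N_rs_max_obtained = "at_boundary",
                binding_constraint = "lipid_area_zero")
  } else if (.is_group1(spec)) {
    t_min <- closed_form_doubling_time(model_id, params)
    lim <- list(model_id = model_id, t_d_min = t_min,
                t_d_min_obtained = "closed_form",
                N_rs_max = Inf, N_rs_max_obtained = "infinite",
                binding_constraint = "none")
  } else {
    base <- .asymptote_of[[model_id]]
    t_asym <- closed_form_doubling_time(base, params)
    f <- function(x) {
      st <- .solve_given_N(ctx, 10^x)
      st$core$t - t_asym - epsilon_asym
    }
    x <- 0
    if (f(x) > 0) {
      lo <- x
      repeat {
        x <- x + 3
        if (x > 60)
          .stop_cond("protocell_boundary_error",
                     "asymptote convergence search failed for '%s'", model_id)
        if (f(x) < 0) break
        lo <- x
      }
      hi <- x
    } else {
      hi <- x
      repeat {
        x <- x - 3
        if (x < -12)
          .stop_cond("protocell_boundary_error",
                     "asymptote convergence search failed for '%s'", model_id)
        if (f(x) > 0) break
        hi <- x
      }
      lo <- x
    }
    root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
    lim <- list(model_id = model_id, t_d_min = t_asym,
                t_d_min_obtained = "asymptote_estimate",
                N_rs_max = 10^root,
                N_rs_max_obtained = "tolerance_defined",
                binding_constraint = "none")
  }
  classify_limit(model_id, lim)
}

#' Classify a doubling-time limit
#'
#' Labels the limit type (membrane surface area when the binding constraint
#' at the minimal doubling time is vanishing lipid area, molecular
#' properties otherwise) and the components responsible for slower growth
#' of small cells (cell geometry, DNA replication, unspecified protein, or
#' none).
#'
#' @param model_id Model id.
#' @param limit Output of the limit search (list with `t_d_min`,
#'   `N_rs_max`, `binding_constraint`, ...).
#' @return An `sspcm_limit` object.
#' @export
classify_limit <- function(model_id, limit) {
  limit$limit_type <- if (identical(limit$binding_constraint,
                                    "lipid_area_zero"))
    "membrane_surface_area" else "molecular_properties"
  limit$slower_growth_factor <- switch(model_id,
    "sspcm-rs" = , "sspcm-rs+aa" = , "sspcm-rs+aa+rna" = "none",
    "sspcm-rs+aa+prot" = "unspecified_protein",
    "sspcm-rs+lip" = , "sspcm-rs+aa+rna+lip" = ,
    "sspcm-rs+aa+rna+lip+mprot" = "cell_geometry",
    "sspcm-rs+dna" = "dna_replication",
    "sspcm-srs-m" = , "sspcm-srs-r" = "both")
  class(limit) <- "sspcm_limit"
  limit
}

#' @export
print.sspcm_limit <- function(x, ...) {
  cat(sprintf("<doubling-time limit: %s>\n", x$model_id))
  cat(sprintf("  minimal t_d_srs: %.2f s (%s)\n", x$t_d_min,
              x$t_d_min_obtained))
  cat(sprintf("  maximal N_rs: %s (%s)\n",
              if (is.finite(x$N_rs_max)) format(x$N_rs_max, digits = 6)
              else "Inf", x$N_rs_max_obtained))
  cat(sprintf("  limit type: %s; slower growth: %s\n", x$limit_type,
              x$slower_growth_factor))
  invisible(x)
}

#' Dry-mass composition of a solved state
#'
#' @param state An `sspcm_state`.
#' @return A data.frame of dry-mass fractions per component group plus the
#'   lipid-to-ribosome ratio as an attribute.
#' @export
composition_report <- function(state) {
  if (!inherits(state, "sspcm_state"))
    .stop_cond("protocell_config_error", "need an sspcm_state")
  df <- data.frame(group = names(state$mass_fractions),
                   dry_mass_fraction = as.numeric(state$mass_fractions),
                   row.names = NULL)
  attr(df, "lip_per_rs") <- state$lip_per_rs
  attr(df, "ribosomal_fraction") <-
    unname(state$mass_fractions["ribosomal"])
  df
}

#' Driver range over which the cell mass is physiological
#'
#' Interpolates a sweep to the driver range over which total cell mass lies
#' within the given bounds (default: the experimentally observed mass range
#' of a reference bacterial cell).
#'
#' @param sweep An `sspcm_sweep` whose driver grid covers the mass bounds.
#' @param M_tot_bounds Numeric length-2: lower and upper total-mass bounds
#'   (g).
#' @return List with `t_d_range`, `N_rs_range`, `M_tot_bounds`, `partial`
#'   (TRUE when the sweep does not cover a bound; a warning is emitted).
#' @export
physiological_window <- function(sweep, M_tot_bounds = c(1e-13, 1e-12)) {
  df <- as.data.frame(sweep)
  ok <- df$status == "ok" & is.finite(df$M_tot)
  df <- df[ok, ]
  if (nrow(df) < 2)
    .stop_cond("protocell_solver_error",
               "sweep has fewer than two feasible points")
  if (max(df$M_tot) < M_tot_bounds[1] || min(df$M_tot) > M_tot_bounds[2]) {
    warning("mass bounds lie entirely outside the sweep; empty window")
    return(list(t_d_range = c(NA_real_, NA_real_),
                N_rs_range = c(NA_real_, NA_real_),
                M_tot_bounds = M_tot_bounds, partial = TRUE))
  }
  o <- order(df$M_tot)
  df <- df[o, ]
  partial <- FALSE
  interp <- function(target, col) {
    if (target < df$M_tot[1] || target > df$M_tot[nrow(df)]) {
      partial <<- TRUE
      idx <- if (target < df$M_tot[1]) 1 else nrow(df)
      return(df[[col]][idx])
    }
    exp(stats::approx(log(df$M_tot), log(df[[col]]), xout = log(target))$y)
  }
  t_range <- sort(c(interp(M_tot_bounds[1], "t_d_srs"),
                    interp(M_tot_bounds[2], "t_d_srs")))
  n_range <- sort(c(interp(M_tot_bounds[1], "N_rs"),
                    interp(M_tot_bounds[2], "N_rs")))
  if (partial)
    warning("sweep covers the mass bounds only partially")
  list(t_d_range = t_range, N_rs_range = n_range,
       M_tot_bounds = M_tot_bounds, partial = partial)
}
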