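test_that("polymer doubling balance reproduces hand arithmetic", {
  # two molecules of a 50-mer, one polymerase at 10 monomers/s -> t = 10 s
  params <- suppressMessages(parameter_set(
    species = list(
      a = species_spec("a", "enzyme", 50, "aa"),
      pol = species_spec("pol", "polymerase", 100, "aa", 10)),
    pathways = list(), source_note = "hand"))
  eq <- polymer_doubling_balance("protein",
                                 list(list(key = "a", species = "a")),
                                 list(key = "pol", species = "pol"))
  state <- list(t_d_srs = 10, counts = list(a = 2, pol = 1))
  expect_equal(eq$residual(state, params), 0)
  state$t_d_srs <- 12
  expect_equal(eq$residual(state, params), 2)
  expect_error(polymer_doubling_balance("protein", list(),
                                        list(key = "pol", species = "pol")),
               class = "protocell_assembly_error")
})

test_that("pathway enzyme demand follows the equal-flux chain rule", {
  pw <- pathway_spec("PW2", 5, "enz", "aa")
  d <- pathway_enzyme_demand(pw, demand = 100, k_enz = 10)
  expect_equal(d$per_step, 10)
  expect_equal(d$total, 50)
  expect_equal(pathway_enzyme_demand(pw, 0, 10)$total, 0)
  expect_error(pathway_enzyme_demand(pw, 100, 0),
               class = "protocell_assembly_error")
})

test_that("membrane area balance counts both leaflets", {
  # 1 um^2 of lipid-only membrane at 0.5 nm^2 per lipid -> 4e6 lipids
  params <- suppressMessages(parameter_set(
    species = list(rpc = species_spec("rpc", "self_replicator", 10, "aa", 1)),
    pathways = list(),
    geometry = geometry_params(area_per_lipid_nm2 = 0.5)))
  eq <- membrane_area_balance()
  state <- list(area_um2 = 1, counts = list(lip = 4e6))
  expect_equal(eq$residual(state, params), 0)
  state$counts$lip <- 2e6  # one leaflet's worth -> half the area uncovered
  expect_equal(eq$residual(state, params), 5e5)
})

test_that("energy and transport balances are plain stoichiometry", {
  params <- suppressMessages(parameter_set(
    species = list(
      etc = species_spec("etc", "membrane_protein", 100, "aa", 1000,
                         localization = "membrane", footprint_nm2 = 10),
      tp = species_spec("tp", "membrane_protein", 100, "aa", 50,
                        localization = "membrane", footprint_nm2 = 10)),
    pathways = list(), energy = energy_params()))
  eqs <- energy_and_transport_balance()
  # translation flux 1e3 aa/s at 4 ATP/aa and 1e3 ATP/s per complex -> 4 ETC
  state <- list(counts = list(etc = 4, tp = 2),
                fluxes = list(atp = 4000, transport = 100))
  expect_equal(eqs[[1]]$residual(state, params), 0)
  expect_equal(eqs[[2]]$residual(state, params), 0)
  state$counts$etc <- 0  # all fluxes zero needs zero complexes
  state$fluxes$atp <- 0
  expect_equal(eqs[[1]]$residual(state, params), 0)
})

test_that("dry mass converts Da to grams with the packaged constant", {
  # single species, one molecule of 1e6 Da
  params <- suppressMessages(parameter_set(
    species = list(rpc = species_spec("rpc", "self_replicator", 1e6 / 110,
                                      "aa", 1)),
    pathways = list()))
  st <- solve_model("sspcm-rs", params, N_rs = 1)
  expect_equal(st$dry_mass, 1e6 * protocell_constants$da_to_g,
               tolerance = 1e-12)
  expect_equal(st$dry_mass, 1.66054e-18, tolerance = 1e-6)
})

test_that("replication feasibility threshold sits exactly at the toy value", {
  fx <- toy_dna()
  # at t = 1000 s the pair of replisomes runs at exactly k_rc = 500 nt/s
  st <- solve_model("sspcm-rs+dna", fx$params, t_d = 1000)
  expect_identical(st$status, "ok")
  expect_equal(st$dna_rate_required, 500, tolerance = 1e-12)
  expect_equal(st$counts$rpc, fx$expected$N_rs_at_1000, tolerance = 1e-10)
  # slightly faster growth is infeasible, reported and never clamped
  st2 <- solve_model("sspcm-rs+dna", fx$params, t_d = 990)
  expect_identical(st2$status, "infeasible")
  expect_true(any(grepl("replication infeasible", st2$infeasibility)))
  expect_gt(st2$dna_rate_required, 500)
})

test_that("slow growth drives pathway enzymes and fluxes toward zero", {
  fx <- toy_dna()
  s1 <- solve_model("sspcm-rs+dna", fx$params, t_d = 1e4)
  s2 <- solve_model("sspcm-rs+dna", fx$params, t_d = 1e6)
  expect_lt(s2$fluxes$replication_dnt, s1$fluxes$replication_dnt)
  expect_lt(s2$counts$enz_PW3, s1$counts$enz_PW3)
  expect_equal(s2$counts$rc, 2)  # fixed pair regardless of growth
  expect_equal(s2$counts$dna, 1)
})
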