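test_that("species and geometry constructors enforce their invariants", {
  expect_error(species_spec("enz", "enzyme", 300, "aa", k_rate = -1),
               class = "protocell_validation_error")
  expect_error(species_spec("x", "enzyme", 0, "aa", 1),
               class = "protocell_validation_error")
  expect_error(species_spec("x", "enzyme", 10, "aa", 1,
                            footprint_nm2 = 5),
               class = "protocell_validation_error")
  expect_error(species_spec("x", "membrane_protein", 10, "aa", 1,
                            localization = "membrane"),
               class = "protocell_validation_error")
  expect_error(geometry_params(water_mass_fraction = 1.2),
               class = "protocell_validation_error")
  expect_error(geometry_params(leaflets = 1),
               class = "protocell_validation_error")
  expect_error(pathway_spec("PW9", 10, "enz", "aa"),
               class = "protocell_validation_error")
})

test_that("explicit masses must agree with composition times monomer mass", {
  sp <- list(rpc = species_spec("rpc", "self_replicator", 1000, "aa", 10,
                                mass_da = 110 * 1000))
  expect_silent(suppressMessages(
    parameter_set(sp, pathways = list(), source_note = "t")))
  sp$rpc$mass_da <- 2e5  # far off 1000 aa x 110 Da
  expect_error(suppressMessages(
    parameter_set(sp, pathways = list(), source_note = "t")),
    class = "protocell_validation_error")
})

test_that("missing couplings are filled with defaults and logged", {
  sp <- list(rpc = species_spec("rpc", "self_replicator", 7336, "aa", 20.26))
  msgs <- capture_messages(
    ps <- parameter_set(sp, pathways = list(), couplings = list()))
  expect_true(any(grepl("trna_per_ribosome", msgs)))
  expect_true(any(grepl("rc_per_genome", msgs)))
  expect_equal(ps$couplings$rc_per_genome, 2)
  expect_equal(ps$couplings$rrna_per_ribosome, 1)
})

test_that("geometry is optional for membrane-free models only", {
  sp <- list(rpc = species_spec("rpc", "self_replicator", 7336, "aa", 20.26))
  ps <- suppressMessages(parameter_set(sp, pathways = list()))
  expect_false(ps$geometry_available)
  expect_silent(st <- solve_model("sspcm-rs", ps, N_rs = 10))
  expect_equal(st$t_d_srs, 7336 / 20.26)
  chk <- validate_couplings(ps, "sspcm-rs+lip")
  expect_true(any(chk$status == "fail" & chk$check == "geometry"))
  expect_error(build_model("sspcm-rs+lip", ps, c(N_rs = 10)),
               class = "protocell_assembly_error")
})

test_that("configuration errors name the offending field", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(species = list(list(id = "rpc",
                                            role = "self_replicator",
                                            n_monomers = 10,
                                            monomer_kind = "aa",
                                            k_rate = 20))), f)
  expect_error(suppressMessages(load_parameters(f)),
               "pathways", class = "protocell_config_error")
  yaml::write_yaml(list(
    species = list(list(id = "enz", role = "enzyme", n_monomers = 300,
                        monomer_kind = "aa", k_rate = -1)),
    pathways = list()), f)
  expect_error(suppressMessages(load_parameters(f)), "enz",
               class = "protocell_validation_error")
  yaml::write_yaml(list(
    species = list(list(id = "rpc", role = "self_replicator",
                        n_monomers = 10, monomer_kind = "aa", k_rate = 20)),
    pathways = list(list(id = "PW2", length_reactions = 5,
                         enzyme = "ghost", product_monomer = "aa"))), f)
  expect_error(suppressMessages(load_parameters(f)), "ghost",
               class = "protocell_reference_error")
})

test_that("load -> serialize -> load round-trips the parameter set", {
  p <- default_parameters()
  fy <- tempfile(fileext = ".yaml")
  fj <- tempfile(fileext = ".json")
  write_parameters(p, fy)
  write_parameters(p, fj)
  expect_true(isTRUE(all.equal(p, suppressMessages(load_parameters(fy)),
                               tolerance = 0)))
  expect_true(isTRUE(all.equal(p, suppressMessages(load_parameters(fj)),
                               tolerance = 1e-12)))
})

test_that("packaged default config equals the in-code default set", {
  f <- system.file("extdata", "params_default.yaml", package = "protocell")
  skip_if(f == "", "installed extdata not found")
  q <- suppressMessages(load_parameters(f))
  expect_true(isTRUE(all.equal(default_parameters(), q, tolerance = 1e-12)))
})

test_that("coupling validation reports per-check results", {
  p <- default_parameters()
  chk <- validate_couplings(p, "sspcm-srs-m")
  expect_true(all(chk$status %in% c("pass", "warn")))
  expect_true(all(chk$status == "pass"))

  p2 <- p
  p2$species$dna <- NULL
  chk2 <- validate_couplings(p2, "sspcm-rs+dna")
  expect_true(any(chk2$status == "fail" &
                    grepl("genome species missing", chk2$note)))

  p3 <- p
  p3$couplings$rc_per_genome <- 3
  chk3 <- validate_couplings(p3, "sspcm-srs-m")
  expect_true(any(chk3$status == "warn" & grepl("pair", chk3$note)))
})

test_that("calibration fallback matches anchors exactly and is idempotent", {
  p <- default_parameters()
  # arithmetic oracle: n_rpc = t * k
  q <- calibrate_fallback(p, list(t_d_rs = 362.10))
  expect_equal(q$species$rpc$n_monomers, 362.10 * 20.26, tolerance = 1e-14)
  # Eq-rearrangement oracle: n_enz/k_enz = (t2 - t1)/l_PW2
  q2 <- calibrate_fallback(p, list(t_d_rs = 362.10, t_d_rs_pw2 = 962.10))
  expect_equal(q2$species$enz$n_monomers / q2$species$enz$k_rate *
                 q2$pathways$PW2$length_reactions, 600, tolerance = 1e-10)
  # idempotence
  q3 <- calibrate_fallback(q2, list(t_d_rs = 362.10, t_d_rs_pw2 = 962.10))
  expect_equal(q3$species$enz$n_monomers, q2$species$enz$n_monomers)
  expect_equal(q3$species$rpc$n_monomers, q2$species$rpc$n_monomers)
  # identity on empty anchors
  expect_identical(calibrate_fallback(p, list()), p)
  # full chain restores the default analytic doubling times
  q4 <- calibrate_fallback(p, list(t_d_rs = 362.10, t_d_rs_pw2 = 962.10,
                                   t_d_rs_pw2_rna = 1127.15))
  expect_equal(closed_form_doubling_time("sspcm-rs+aa+rna", q4), 1127.15,
               tolerance = 1e-12)
  # errors
  expect_error(calibrate_fallback(p, list(nonsense = 1)),
               class = "protocell_config_error")
  expect_error(calibrate_fallback(p, list(t_d_rs = 362.10,
                                          t_d_rs_pw2 = 100)),
               class = "protocell_calibration_error")
})
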