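test_that("dry-mass fractions always sum to one", {
  p <- default_parameters()
  cases <- list(
    solve_model("sspcm-rs", p, N_rs = 10),
    solve_model("sspcm-rs+aa+rna+lip", p, t_d = 1300),
    solve_model("sspcm-srs-m", p, t_d = 2600),
    solve_model("sspcm-srs-r", p, t_d = 1000),
    solve_model("sspcm-rs+dna", p, t_d = 1e4))
  for (st in cases)
    expect_equal(sum(st$mass_fractions), 1, tolerance = 1e-9)
})

test_that("DNA-associated mass is small at fast growth, dominant when slow", {
  p <- default_parameters()
  lim <- find_growth_boundary("sspcm-srs-m", p)
  fast <- solve_model("sspcm-srs-m", p, t_d = lim$t_d_min + 0.1)
  slow <- solve_model("sspcm-srs-m", p, t_d = 1e4)
  expect_lt(fast$mass_fractions[["dna_associated"]], 0.05)
  expect_gt(slow$mass_fractions[["dna_associated"]], 0.5)
  # growth-independent machinery: one genome, a pair of replisomes
  expect_equal(fast$counts$rc, 2)
  expect_equal(slow$counts$rc, 2)
})

test_that("the rich-medium cell is more ribosomal than the minimal one", {
  p <- default_parameters()
  rib <- function(id, t) solve_model(id, p,
                                     t_d = t)$mass_fractions[["ribosomal"]]
  expect_gt(rib("sspcm-srs-r", 940), rib("sspcm-srs-m", 2480))
})

test_that("composition_report tabulates fractions with the lipid ratio", {
  p <- default_parameters()
  st <- solve_model("sspcm-srs-m", p, t_d = 2600)
  co <- composition_report(st)
  expect_s3_class(co, "data.frame")
  expect_equal(sum(co$dry_mass_fraction), 1, tolerance = 1e-9)
  expect_equal(attr(co, "lip_per_rs"), st$counts$lip / st$counts$rpc)
  expect_error(composition_report(42), class = "protocell_config_error")
})

test_that("sweeps record infeasible points without aborting", {
  p <- default_parameters()
  lim <- find_growth_boundary("sspcm-srs-r", p)
  grid <- sort(c(lim$t_d_min - 5, lim$t_d_min + 5, lim$t_d_min + 100))
  sw <- sweep_model("sspcm-srs-r", p, driver = "t_d_srs", grid = grid)
  df <- as.data.frame(sw)
  expect_equal(nrow(df), 3)
  expect_false(df$status[1] == "ok")
  expect_true(all(df$status[2:3] == "ok"))
  # single-point sweep
  sw1 <- sweep_model("sspcm-rs", p, driver = "N_rs", grid = 100)
  expect_equal(nrow(as.data.frame(sw1)), 1)
  expect_error(sweep_model("sspcm-rs", p, grid = c(2, 1)),
               class = "protocell_config_error")
})

test_that("the physiological mass window is interpolated from a sweep", {
  p <- default_parameters()
  sw <- sweep_model("sspcm-srs-m", p, driver = "t_d_srs",
                    grid = exp(seq(log(2476), log(3500), length.out = 20)))
  w <- physiological_window(sw, c(1e-13, 1.55e-12))
  expect_false(w$partial)
  # the window hugs the fast-growth end and is a few hundred seconds wide
  expect_lt(w$t_d_range[1], 2500)
  expect_gt(w$t_d_range[2], w$t_d_range[1] + 100)
  expect_lt(w$t_d_range[2], 3000)
  expect_true(w$N_rs_range[2] > 10 * w$N_rs_range[1])
  # bounds wholly outside the sweep give an empty window with a warning
  expect_warning(w2 <- physiological_window(sw, c(1e-20, 1e-19)),
                 "empty window")
  expect_true(all(is.na(w2$t_d_range)))
})

test_that("asymptotic models report convention-defined maximal counts", {
  p <- default_parameters()
  lim <- find_growth_boundary("sspcm-rs+aa+rna+lip", p)
  expect_identical(lim$N_rs_max_obtained, "tolerance_defined")
  expect_identical(lim$t_d_min_obtained, "asymptote_estimate")
  expect_true(is.finite(lim$N_rs_max))
  expect_equal(lim$t_d_min, closed_form_doubling_time("sspcm-rs+aa+rna", p))
  # a looser convergence tolerance admits smaller maximal counts
  lim2 <- find_growth_boundary("sspcm-rs+aa+rna+lip", p,
                               epsilon_asym = 0.05)
  expect_lt(lim2$N_rs_max, lim$N_rs_max)
  # group-1 models have no size limit at all
  lim3 <- find_growth_boundary("sspcm-rs", p)
  expect_identical(lim3$N_rs_max, Inf)
  expect_identical(lim3$limit_type, "molecular_properties")
  expect_identical(lim3$slower_growth_factor, "none")
})
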