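test_that("numeric solves agree with closed forms on 50-point grids", {
  grids <- 10^seq(0, 6, length.out = 50)
  for (prm in list(toy_analytic()$params, default_parameters())) {
    for (id in c("sspcm-rs", "sspcm-rs+aa", "sspcm-rs+aa+rna")) {
      cf <- closed_form_doubling_time(id, prm)
      tn <- vapply(grids, function(n)
        solve_model(id, prm, N_rs = n)$t_d_srs, 0)
      expect_true(all(abs(tn - cf) <= 1e-9 * cf), label = id)
      # flat line: doubling time independent of the driver
      expect_lt(diff(range(tn)) / cf, 1e-9)
    }
  }
})

test_that("the unspecified-protein pool reduces exactly to the pool-free
           model when empty", {
  p <- default_parameters()
  grids <- 10^seq(0, 4, length.out = 9)
  t_aa <- closed_form_doubling_time("sspcm-rs+aa", p)
  for (n in grids) {
    st <- solve_model("sspcm-rs+aa+prot", p, N_rs = n, N_aa_prot = 0)
    expect_equal(st$t_d_srs, t_aa, tolerance = 1e-12)
    cf <- closed_form_doubling_time("sspcm-rs+aa+prot", p, N_rs = n,
                                    N_aa_prot = 5e4)
    st2 <- solve_model("sspcm-rs+aa+prot", p, N_rs = n, N_aa_prot = 5e4)
    expect_equal(st2$t_d_srs, cf, tolerance = 1e-9)
  }
  # the pool's doubling-time surcharge is linear in pool-per-ribosome
  st <- solve_model("sspcm-rs+aa+prot", p, N_rs = 10, N_aa_prot = 1e5)
  expect_equal(st$t_d_srs - t_aa, 1e5 / (10 * p$species$rpc$k_rate),
               tolerance = 1e-9)
})

test_that("every residual vanishes at solver-returned states", {
  p <- default_parameters()
  cases <- list(
    list("sspcm-rs+aa+rna", c(N_rs = 1e4)),
    list("sspcm-rs+aa+rna+lip", c(t_d_srs = 1300)),
    list("sspcm-rs+lip", c(t_d_srs = 400)),
    list("sspcm-rs+aa+rna+lip+mprot", c(t_d_srs = 2600)),
    list("sspcm-srs-m", c(t_d_srs = 3000)),
    list("sspcm-srs-r", c(t_d_srs = 1000)),
    list("sspcm-rs+dna", c(t_d_srs = 1e4)))
  for (cs in cases) {
    sol <- solve_with_system(cs[[1]], p, cs[[2]])
    expect_identical(sol$state$status, "ok", label = cs[[1]])
    sres <- scaled_residuals(sol$state, sol$system)
    expect_lt(max(sres), 1e-8, label = paste(cs[[1]], "residual scale"))
  }
})

test_that("doubling conservation holds exactly for each polymer class", {
  p <- default_parameters()
  st <- solve_model("sspcm-srs-m", p, t_d = 3000)
  k <- p$species
  # protein: polymerized aa equals doubling demand
  aa <- st$counts$rpc * k$rpc$n_monomers + st$counts$rp * k$rp$n_monomers +
    st$counts$rc * k$rc$n_monomers + st$counts$lpe * k$lpe$n_monomers +
    (st$counts$enz_PW1 + st$counts$enz_PW2 + st$counts$enz_PW3 +
       st$counts$enz_PW4 + st$counts$enz_PW5) * k$enz$n_monomers +
    st$counts$etc * k$etc$n_monomers + st$counts$tp * k$tp$n_monomers
  expect_equal(st$counts$rpc * k$rpc$k_rate * st$t_d_srs, aa,
               tolerance = 1e-9)
  # rna
  nt <- st$counts$rrna * k$rrna$n_monomers +
    st$counts$trna * k$trna$n_monomers + st$mrna_nt
  expect_equal(st$counts$rp * k$rp$k_rate * st$t_d_srs, nt,
               tolerance = 1e-9)
  # lipid
  expect_equal(st$counts$lpe * k$lpe$k_rate * st$t_d_srs, st$counts$lip,
               tolerance = 1e-9)
  # area: component footprints sum to the geometric area
  occ <- st$counts$etc * k$etc$footprint_nm2 +
    st$counts$tp * k$tp$footprint_nm2 +
    st$counts$lip * p$geometry$area_per_lipid_nm2 / 2
  expect_equal(st$area_um2 * 1e6, occ, tolerance = 1e-9)
  # energy: production equals consumption
  expect_equal(st$counts$etc * k$etc$k_rate, st$fluxes$atp,
               tolerance = 1e-9)
})

test_that("hockey-stick models are monotone and approach their asymptote", {
  p <- default_parameters()
  for (id in c("sspcm-rs+aa+rna+lip", "sspcm-rs+lip", "sspcm-rs+dna")) {
    base <- .asymptote_of[[id]]
    t_asym <- closed_form_doubling_time(base, p)
    ns <- 10^seq(2, 12, length.out = 11)
    ts <- vapply(ns, function(n) solve_model(id, p, N_rs = n)$t_d_srs, 0)
    expect_true(all(diff(ts) < 1e-12), label = paste(id, "non-increasing"))
    expect_true(all(ts > t_asym), label = paste(id, "above asymptote"))
    gaps <- ts - t_asym
    expect_lt(gaps[length(gaps)], 0.05)
    expect_lt(gaps[length(gaps)], gaps[1] * 1e-2)
  }
})

test_that("membrane-protein models are monotone with a falling lipid ratio", {
  p <- default_parameters()
  for (id in c("sspcm-rs+aa+rna+lip+mprot", "sspcm-srs-r")) {
    ns <- 10^seq(1, 4, length.out = 8)
    sts <- lapply(ns, function(n) solve_model(id, p, N_rs = n))
    ts <- vapply(sts, function(s) s$t_d_srs, 0)
    lr <- vapply(sts, function(s) s$lip_per_rs, 0)
    expect_true(all(diff(ts) < 0), label = paste(id, "t_d falls with N_rs"))
    expect_true(all(diff(lr) < 0), label = paste(id, "N_lip/N_rs falls"))
  }
})

test_that("the growth boundary is a true feasibility transition", {
  p <- default_parameters()
  lim <- find_growth_boundary("sspcm-rs+aa+rna+lip+mprot", p)
  expect_identical(lim$limit_type, "membrane_surface_area")
  st <- solve_model("sspcm-rs+aa+rna+lip+mprot", p, t_d = lim$t_d_min)
  expect_identical(st$status, "ok")
  # membrane essentially fully covered by proteins at the boundary
  expect_lt(st$lipid_area_um2 / st$area_um2, 1e-4)
  # a hair below the boundary there is no feasible cell
  below <- tryCatch(
    solve_model("sspcm-rs+aa+rna+lip+mprot", p, t_d = lim$t_d_min - 0.01),
    error = function(e) "no_solution")
  expect_true(identical(below, "no_solution") ||
                identical(below$status, "infeasible"))
})

test_that("toy membrane boundary matches quadratic and grid-scan oracles", {
  fx <- toy_membrane()
  lim <- find_growth_boundary("sspcm-rs+aa+rna+lip+mprot", fx$params)
  # closed-form quadratic for the boundary of a DNA-free model
  expect_equal(lim$t_d_min, fx$expected$t_d_min, tolerance = 1e-6)
  # independent brute-force feasibility scan, coarse-to-fine
  feasible <- function(t) {
    st <- tryCatch(
      solve_model("sspcm-rs+aa+rna+lip+mprot", fx$params, t_d = t),
      error = function(e) NULL)
    !is.null(st) && identical(st$status, "ok")
  }
  coarse <- exp(seq(log(150), log(1500), length.out = 80))
  i <- which(vapply(coarse, feasible, TRUE))[1]
  expect_gt(i, 1)
  fine <- seq(coarse[i - 1], coarse[i], length.out = 150)
  t_scan <- fine[which(vapply(fine, feasible, TRUE))[1]]
  expect_equal(lim$t_d_min, t_scan, tolerance = 1e-4)
})

test_that("identical inputs give bit-identical outputs", {
  p <- default_parameters()
  s1 <- sweep_model("sspcm-srs-m", p, driver = "t_d_srs",
                    grid = c(2600, 3000, 5000))
  s2 <- sweep_model("sspcm-srs-m", p, driver = "t_d_srs",
                    grid = c(2600, 3000, 5000))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  l1 <- find_growth_boundary("sspcm-srs-r", p)
  l2 <- find_growth_boundary("sspcm-srs-r", p)
  expect_identical(l1$t_d_min, l2$t_d_min)
  expect_identical(l1$N_rs_max, l2$N_rs_max)
})
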