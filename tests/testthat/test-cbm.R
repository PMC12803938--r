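# FBA, parsimonious FBA, FVA and loopless post-processing.

test_that("FBA solves bound-limited chains and degenerate models", {
  expect_equal(fba(build_chain_model())$objective_value, 10)
  sol <- fba(zero_bound_model())
  expect_equal(sol$objective_value, 0)
  expect_true(all(sol$fluxes == 0))
})

test_that("FBA optimum of the toy model is glucose- and glutamine-limited", {
  sol <- fba(build_toy_model())
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
})

test_that("every returned flux distribution is mass balanced within 1e-6", {
  for (m in list(build_chain_model(), build_diamond_model(), build_toy_model())) {
    S <- stoich_matrix(m)
    for (sol in list(fba(m), pfba(m), pfba(m, 0.5))) {
      expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-6)
      expect_true(all(sol$fluxes >= m$reactions$lb - 1e-9))
      expect_true(all(sol$fluxes <= m$reactions$ub + 1e-9))
    }
  }
})

test_that("pFBA routes the diamond through the short path", {
  sol <- pfba(build_diamond_model())
  expect_equal(sol$total_flux, 30, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[c("R2", "R3")]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[["R1"]]), 10, tolerance = 1e-9)
})

test_that("pFBA equals FBA on a unique-pathway chain and zeroes at fraction 0", {
  m <- build_chain_model()
  expect_equal(pfba(m)$fluxes, fba(m)$fluxes, tolerance = 1e-9)
  sol <- pfba(build_diamond_model(), fraction_of_optimum = 0)
  expect_equal(sol$total_flux, 0, tolerance = 1e-9)
  expect_true(all(abs(sol$fluxes) < 1e-9))
})

test_that("toy pFBA reference is the hand-derived unique parsimonious state", {
  sol <- pfba(build_toy_model())
  expect_equal(sol$total_flux, 70, tolerance = 1e-6)
  expected <- c(EX_glc = -10, EX_gln = -5, EX_gly = -2, EX_ser = -2,
                EX_arg = -1, EX_co2 = 5, HEX1 = 10, PGI_PFK = 5, PYK = 10,
                G6PD = 5, GLS_GDH = 5, BIOMASS = 10)
  expect_equal(sol$fluxes[names(expected)], expected, tolerance = 1e-6)
  zero_rxns <- setdiff(names(sol$fluxes), names(expected))
  expect_true(all(abs(sol$fluxes[zero_rxns]) < 1e-6))
})

test_that("FVA on the diamond reproduces the hand-derived algebra", {
  d <- build_diamond_model()
  # unconstrained total flux: either route can carry everything
  fr <- fva(d, fva_settings(fraction_of_optimum = 1.0, pfba_factor = NULL,
                            loopless = FALSE))
  mn <- range_lookup(fr, "min"); mx <- range_lookup(fr, "max")
  expect_equal(unname(c(mn[["R1"]], mx[["R1"]])), c(0, 10), tolerance = 1e-6)
  expect_equal(unname(c(mn[["R3"]], mx[["R3"]])), c(0, 10), tolerance = 1e-6)
  # cap = 1.1 * 30 = 33: long-route flux x obeys 30 + x <= 33
  fr <- fva(d, fva_settings(fraction_of_optimum = 1.0, pfba_factor = 1.1,
                            loopless = FALSE))
  mn <- range_lookup(fr, "min"); mx <- range_lookup(fr, "max")
  expect_equal(unname(mx[["R3"]]), 3, tolerance = 1e-6)
  expect_equal(unname(c(mn[["R1"]], mx[["R1"]])), c(7, 10), tolerance = 1e-6)
})

test_that("loopless FVA zeroes the 2-cycle that standard FVA opens to the bound", {
  m <- build_toy_model()
  std <- fva(m, fva_settings(0.9, pfba_factor = NULL, loopless = FALSE))
  ll <- fva(m, fva_settings(0.9, pfba_factor = NULL, loopless = TRUE))
  expect_equal(unname(range_lookup(std, "max")[c("ACON_F", "ACON_B")]),
               c(1000, 1000), tolerance = 1e-6)
  expect_equal(unname(range_lookup(ll, "max")[c("ACON_F", "ACON_B")]),
               c(0, 0), tolerance = 1e-6)
})

test_that("loopless ranges are reaction-wise subsets of standard ranges", {
  for (m in list(build_diamond_model(), build_toy_model())) {
    for (pf in list(NULL, 1.1)) {
      std <- fva(m, fva_settings(0.9, pfba_factor = pf, loopless = FALSE))
      ll <- fva(m, fva_settings(0.9, pfba_factor = pf, loopless = TRUE))
      expect_true(all(ll$ranges$min >= std$ranges$min - 1e-6))
      expect_true(all(ll$ranges$max <= std$ranges$max + 1e-6))
    }
  }
})

test_that("FVA ranges sandwich the parsimonious solution", {
  m <- build_toy_model()
  sol <- pfba(m, fraction_of_optimum = 0.9)
  fr <- fva(m, fva_settings(0.9, pfba_factor = 1.1, loopless = TRUE))
  mn <- range_lookup(fr, "min"); mx <- range_lookup(fr, "max")
  expect_true(all(sol$fluxes >= mn[names(sol$fluxes)] - 1e-6))
  expect_true(all(sol$fluxes <= mx[names(sol$fluxes)] + 1e-6))
})

test_that("tightening the constraints never widens any range", {
  m <- build_toy_model()
  # biomass fraction: monotone when the total-flux cap is off (with the cap
  # on, the cap itself is recomputed at the new fraction and the nesting of
  # feasible sets is lost by design)
  base <- fva(m, fva_settings(0.9, pfba_factor = NULL, loopless = FALSE))
  tighter_frac <- fva(m, fva_settings(1.0, pfba_factor = NULL, loopless = FALSE))
  # total-flux cap: monotone at a fixed fraction
  base_cap <- fva(m, fva_settings(0.9, pfba_factor = 1.1, loopless = FALSE))
  tighter_cap <- fva(m, fva_settings(0.9, pfba_factor = 1.01, loopless = FALSE))
  for (pair in list(list(tighter_frac, base), list(tighter_cap, base_cap))) {
    expect_true(all(pair[[1]]$ranges$min >= pair[[2]]$ranges$min - 1e-6))
    expect_true(all(pair[[1]]$ranges$max <= pair[[2]]$ranges$max + 1e-6))
  }
})

test_that("remove_loops is a fixed point on loop-free solutions", {
  m <- build_toy_model()
  sol <- pfba(m)
  out <- remove_loops(m, sol)
  expect_equal(out$fluxes, sol$fluxes, tolerance = 1e-6)
})

test_that("remove_loops strips a superimposed 2-cycle and honors a pin", {
  m <- build_toy_model()
  sol <- pfba(m)
  k <- 3
  looped <- sol
  looped$fluxes[c("ACON_F", "ACON_B")] <- looped$fluxes[c("ACON_F", "ACON_B")] + k
  out <- remove_loops(m, looped)
  expect_equal(unname(out$fluxes[c("ACON_F", "ACON_B")]), c(0, 0),
               tolerance = 1e-6)
  expect_equal(out$objective_value, sol$objective_value, tolerance = 1e-6)
  # exchange fluxes unchanged
  ex <- m$reactions$id[m$reactions$is_exchange]
  expect_equal(out$fluxes[ex], looped$fluxes[ex], tolerance = 1e-9)
  # pinning one cycle member keeps it (and, via the icit balance, its partner)
  pin <- remove_loops(m, looped, pinned_reaction = "ACON_B")
  expect_equal(unname(pin$fluxes[["ACON_B"]]), k, tolerance = 1e-6)
  expect_equal(unname(pin$fluxes[["ACON_F"]]), k, tolerance = 1e-6)
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% pin$fluxes[colnames(S)])), 1e-6)
})

test_that("infeasible and objective-free models fail with clear errors", {
  m <- build_chain_model()
  m$objective <- numeric(0)
  expect_error(fba(m), "empty objective")
  m2 <- build_chain_model()
  m2$reactions$lb[m2$reactions$id == "OUT"] <- 20  # forces more than uptake allows
  expect_error(fba(m2), "infeasible")
})
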