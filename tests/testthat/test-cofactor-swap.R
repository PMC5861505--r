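# Cofactor modification analysis: twin construction, exact optimization,
# oracle equivalence.

test_that("twins are created exactly for cofactor-touching reactions", {
  m <- toy_model()
  sw <- build_swapped_model(m)
  expect_setequal(unname(sw$twins),
                  c("GLYC", "PPP", "PDH", "FAS", "OMEGA", "RESP"))
  # twins swap the pair in place
  st <- sw$model$stoichiometry[, "GLYC_cmod"]
  expect_equal(unname(st["nadp_c"]), -2)
  expect_equal(unname(st["nadph_c"]), 2)
  expect_equal(unname(st["nad_c"]), 0)
  # a reaction using both pairs swaps both simultaneously:
  # nadph -> nadh and nad -> nadp on the consuming side, and vice versa
  sto <- sw$model$stoichiometry[, "OMEGA_cmod"]
  expect_equal(unname(sto[c("nadh_c", "nadp_c")]), c(-1, -1))
  expect_equal(unname(sto[c("nadph_c", "nad_c")]), c(1, 1))
  # twins are added closed
  tw <- match(names(sw$twins), sw$model$reactions$id)
  expect_true(all(sw$model$reactions$lower_bound[tw] == 0))
  expect_true(all(sw$model$reactions$upper_bound[tw] == 0))
})

test_that("models without cofactor usage yield zero twins", {
  sw <- build_swapped_model(chain_model())
  expect_length(sw$twins, 0L)
})

test_that("k = 0 reproduces the baseline with an empty swap set", {
  m <- toy_model()
  res <- cma_optimize(m, "EX_ddda", k = 0, biomass_floor = 0,
                      constraints = toy_yield_constraints())
  expect_length(res$swapped, 0L)
  expect_equal(res$yield_swapped, res$yield_baseline)
  expect_equal(res$yield_baseline, 120 / 47, tolerance = 1e-6)
})

test_that("single-swap CMA finds the FAS swap optimal, glycolysis second", {
  m <- toy_model()
  res <- cma_optimize(m, "EX_ddda", k = 1, biomass_floor = 0,
                      constraints = toy_yield_constraints())
  expect_equal(res$yield_baseline, 120 / 47, tolerance = 1e-6)
  # best: relieving the 10-NADPH FAS demand leaves only omega-oxidation on
  # NADPH, so glucose drops to 3 + 1/12 per DDDA
  expect_identical(res$swapped, "FAS")
  expect_equal(res$yield_swapped, 120 / 37, tolerance = 1e-6)
  expect_gte(res$yield_swapped, res$yield_baseline - 1e-9)
  # the glycolytic-dehydrogenase swap contributes 6 NADPH per DDDA: 120/41
  expect_equal(res$per_swap$yield[res$per_swap$reaction == "GLYC"],
               120 / 41, tolerance = 1e-6)
})

test_that("cma_optimize matches the brute-force rewrite oracle (k = 1)", {
  for (mdl in list(toy_model(),
                   plant_bottleneck(toy_model(), "PPP", 1.5))) {
    a <- cma_optimize(mdl, "EX_ddda", k = 1, biomass_floor = 0,
                      constraints = toy_yield_constraints())
    b <- enumerate_swaps_oracle(mdl, "EX_ddda", biomass_floor = 0,
                                constraints = toy_yield_constraints())
    expect_equal(a$yield_swapped, b$yield_swapped, tolerance = 1e-6)
    expect_equal(a$yield_baseline, b$yield_baseline, tolerance = 1e-6)
    expect_identical(a$swapped, b$swapped)
    # per-swap tables agree reaction by reaction
    merged <- merge(a$per_swap, b$per_swap, by = "reaction")
    expect_equal(merged$yield.x, merged$yield.y, tolerance = 1e-6)
  }
})

test_that("the swap yield is monotone in k and exclusive in flux", {
  m <- toy_model()
  y <- vapply(0:2, function(k)
    cma_optimize(m, "EX_ddda", k = k, biomass_floor = 0,
                 constraints = toy_yield_constraints())$yield_swapped, 1)
  expect_true(all(diff(y) >= -1e-9))

  # exclusivity: activated twins close their originals by construction
  sw <- build_swapped_model(apply_constraints(m, toy_yield_constraints()))
  m2 <- dcadesign:::activate_swaps(sw, "GLYC")
  st <- resolve_unique(m2, "EX_ddda", "max")
  expect_equal(unname(st$fluxes["GLYC"] * st$fluxes["GLYC_cmod"]), 0,
               tolerance = 1e-9)
  expect_gt(abs(st$fluxes["GLYC_cmod"]), 1e-6)
})

test_that("with all twins disabled the product optimum equals the theoretical yield", {
  m <- toy_model()
  sw <- build_swapped_model(m)
  base <- dcadesign:::product_yield(
    apply_constraints(sw$model, toy_yield_constraints()), "EX_ddda", 0, NULL)
  expect_equal(base, theoretical_max_yield(m, "EX_ddda", "EX_glc", 10),
               tolerance = 1e-6)
})

test_that("a nonzero biomass floor trades yield and the sweep reports it", {
  m <- toy_model()
  # floor at 10% of max growth: 2/3 biomass costs 1 glc, leaving 9 for DDDA
  sweep <- cma_floor_sweep(m, "EX_ddda", fractions = c(0, 0.1),
                           constraints = condition_constraints(
                             bounds = list(ATPM = c(0, 1000))))
  expect_equal(sweep$yield_baseline[1], 120 / 47, tolerance = 1e-4)
  expect_equal(sweep$yield_baseline[2], 108 / 47, tolerance = 1e-4)
  expect_equal(sweep$best_swap, c("FAS", "FAS"))
  expect_equal(sweep$yield_swapped[1], 120 / 37, tolerance = 1e-4)
  expect_equal(sweep$yield_swapped[2], 108 / 37, tolerance = 1e-4)
})
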