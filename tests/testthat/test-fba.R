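# FBA core: optimization, deterministic resolution, flux-sum, validation
# harness, theoretical yields.

test_that("optimize honours bounds, reports status, and hits known optima", {
  m <- toy_model()
  cc <- toy_yield_constraints()
  expect_equal(optimize(m, "EX_ddda", "max", cc)$objective_value, 120 / 47,
               tolerance = 1e-6)

  # a reaction fixed at zero optimises to zero
  m0 <- set_bounds(m, "PPP", lower = 0, upper = 0)
  expect_equal(optimize(m0, "PPP", "max")$objective_value, 0)

  # no carbon but positive maintenance: infeasible, not zero
  mx <- set_bounds(m, "EX_glc", lower = 0, upper = 0)
  st <- optimize(mx, "EX_biomass", "max")
  expect_identical(st$status, "infeasible")
  expect_true(is.na(st$objective_value))
})

test_that("every optimal state satisfies steady state and bounds", {
  m <- toy_model()
  scenarios <- list(
    optimize(m, "EX_biomass", "max"),
    optimize(m, "EX_ddda", "max", toy_yield_constraints()),
    resolve_unique(m, "EX_ddda", "max", toy_yield_constraints()),
    resolve_unique(m, "EX_biomass", "max"))
  for (st in scenarios) {
    expect_identical(st$status, "optimal")
    expect_lt(steady_state_residual(m, st), 1e-6)
    expect_true(all(st$fluxes >= m$reactions$lower_bound - 1e-8))
    expect_true(all(st$fluxes <= m$reactions$upper_bound + 1e-8))
  }
})

test_that("parsimonious resolution suppresses futile cycles and idle routes", {
  m <- toy_model()
  st <- resolve_unique(m, "EX_ddda", "max", toy_yield_constraints())
  expect_equal(unname(st$fluxes["LEUDEG"]), 0)
  expect_equal(unname(st$fluxes["LEUt"]), 0)

  # plant a reversible 2-reaction futile cycle; resolved flux through it is 0
  m2 <- add_reaction(m, "CYC1", c(pyr_c = -1, cycmet_c = 1),
                     lower_bound = -1000)
  m2 <- add_reaction(m2, "CYC2", c(cycmet_c = -1, pyr_c = 1),
                     lower_bound = -1000)
  st2 <- resolve_unique(m2, "EX_ddda", "max", toy_yield_constraints())
  expect_equal(unname(abs(st2$fluxes[c("CYC1", "CYC2")])), c(0, 0),
               tolerance = 1e-8)
  expect_equal(st2$objective_value, 120 / 47, tolerance = 1e-6)

  # on a unique-optimum LP the resolved state equals the vertex state
  ch <- chain_model()
  a <- optimize(ch, "SNK", "max")
  b <- resolve_unique(ch, "SNK", "max")
  expect_equal(b$fluxes, a$fluxes, tolerance = 1e-8)
})

test_that("flux-sum equals half the absolute incident flux, halves balanced", {
  ch <- chain_model()
  st <- optimize(ch, "SNK", "max")
  fs <- flux_sum(ch, st)
  expect_equal(unname(fs["B"]), 1)            # 0.5 (|1| + |-1|)

  m <- toy_model()
  st2 <- resolve_unique(m, "EX_ddda", "max", toy_yield_constraints())
  fs2 <- flux_sum(m, st2)
  expect_equal(unname(fs2["accoa_c"]), 6 * 120 / 47, tolerance = 1e-6)

  # production and consumption halves agree for every metabolite
  v <- st2$fluxes[m$reactions$id]
  contrib <- m$stoichiometry %*% diag(v)
  prod_half <- rowSums(contrib * (contrib > 0))
  cons_half <- -rowSums(contrib * (contrib < 0))
  expect_equal(prod_half, cons_half, tolerance = 1e-6)
  expect_equal(unname(prod_half), unname(fs2), tolerance = 1e-6)

  # zero-flux state has zero flux-sums
  m0 <- set_bounds(m, "EX_glc", lower = 0)
  m0 <- set_bounds(m0, "ATPM", lower = 0)
  st0 <- optimize(m0, "EX_ddda", "max")
  expect_true(all(flux_sum(m0, st0) <= 1e-9))
})

test_that("growth validation matches the manifest and responds to CER limits", {
  m <- toy_model()
  d1 <- condition_constraints(label = "glc10", uptake = c(EX_glc = 10),
                              measured_mu = 6.5)
  tab <- validate_growth(m, list(d1))
  expect_equal(tab$predicted_mu, 20 / 3, tolerance = 1e-6)
  expect_equal(tab$deviation, 20 / 3 - 6.5, tolerance = 1e-6)

  # tightening the CO2-evolution ceiling never increases predicted growth
  mus <- vapply(c(1000, 25, 20, 15, 10, 5), function(cer) {
    cc <- condition_constraints(uptake = c(EX_glc = 10),
                                bounds = list(EX_co2 = c(0, cer)))
    st <- optimize(m, "EX_biomass", "max", cc)
    if (st$status == "optimal") st$objective_value else 0
  }, 1)
  expect_true(all(diff(mus) <= 1e-8))

  # no uptake and no maintenance: growth is zero, not an error
  m0 <- set_bounds(m, "ATPM", lower = 0)
  cc0 <- condition_constraints(uptake = c(EX_glc = 0))
  expect_equal(optimize(m0, "EX_biomass", "max", cc0)$objective_value, 0,
               tolerance = 1e-9)

  expect_error(validate_growth(m, list(condition_constraints(
    uptake = c(EX_nope = 1)))), "unknown")
})

test_that("theoretical max yield releases demands and scales homogeneously", {
  m <- toy_model()
  y10 <- theoretical_max_yield(m, "EX_ddda", "EX_glc", 10)
  expect_equal(y10, 120 / 47, tolerance = 1e-6)
  y20 <- theoretical_max_yield(m, "EX_ddda", "EX_glc", 20)
  expect_equal(y20, 2 * y10, tolerance = 1e-6)

  # a product with no producing path yields zero
  m2 <- add_reaction(m, "EX_orphan", c(orphan_e = -1), lower_bound = 0)
  expect_equal(theoretical_max_yield(m2, "EX_orphan", "EX_glc", 10), 0,
               tolerance = 1e-9)
})
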