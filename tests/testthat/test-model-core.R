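# Model container, equation grammar, GPR rules, curation, biomass assembly,
# mass balance.

test_that("equation strings round-trip through parse and format", {
  cases <- list(
    "2 A[c] + B[c] -> C[e]",
    "glc_c + 2 nad_c <=> 2 pyr_c + 2 nadh_c",
    "A[c] ->"                      # pure sink
  )
  for (eq in cases) {
    p <- parse_equation(eq)
    q <- parse_equation(format_equation(p$stoichiometry, p$reversible))
    expect_equal(sort(names(p$stoichiometry)), sort(names(q$stoichiometry)))
    expect_equal(p$stoichiometry[sort(names(p$stoichiometry))],
                 q$stoichiometry[sort(names(q$stoichiometry))])
    expect_identical(p$reversible, q$reversible)
  }
  expect_equal(parse_equation("2 A[c] + B[c] -> C[e]")$stoichiometry,
               c("A[c]" = -2, "B[c]" = -1, "C[e]" = 1))
})

test_that("GPR rules parse, list their genes, and evaluate min/max semantics", {
  vals <- c(g1 = 10, g2 = 2, g3 = 7)
  expect_equal(eval_gpr("g1 and g2", vals), 2)
  expect_equal(eval_gpr("g1 or g2", vals), 10)
  expect_equal(eval_gpr("(g1 and g2) or g3", vals), 7)
  expect_equal(eval_gpr("g1 and (g2 or g3)", vals), 7)
  expect_true(is.na(eval_gpr("g1 and gX", vals)))
  expect_setequal(gpr_genes("(g1 and g2) or (g1 and g3)"), c("g1", "g2", "g3"))
  expect_identical(gpr_genes(""), character(0))
})

test_that("curation applies add/remove/modify in order and reports a summary", {
  m <- toy_model()
  ledger <- data.frame(
    action = c("add", "remove", "modify_bounds"),
    reaction_id = c("NEWRXN", "LEUDEG", "EX_glc"),
    equation = c("pyr_c -> co2_c", "", ""),
    lower_bound = c(NA, NA, -5), upper_bound = c(NA, NA, 1000),
    gpr = c("gNEW", "", ""), note = "", stringsAsFactors = FALSE)
  out <- apply_curation(m, ledger)
  expect_equal(out$summary, list(n_added = 1L, n_removed = 1L, n_modified = 1L))
  expect_true("NEWRXN" %in% out$model$reactions$id)
  expect_false("LEUDEG" %in% out$model$reactions$id)
  expect_equal(out$model$reactions$lower_bound[
    out$model$reactions$id == "EX_glc"], -5)
  expect_true("gNEW" %in% out$model$genes)

  # empty ledger leaves the model unchanged
  same <- apply_curation(m, ledger[0, ])
  expect_equal(model_stats(same$model), model_stats(m))

  # removing a nonexistent reaction errors with the id
  bad <- data.frame(action = "remove", reaction_id = "NOPE", equation = "",
                    lower_bound = NA, upper_bound = NA, gpr = "", note = "")
  expect_error(apply_curation(m, bad), "NOPE")
})

test_that("an add/remove ledger followed by its inverse restores model stats", {
  m <- toy_model()
  ledger <- data.frame(
    action = c("add", "remove"),
    reaction_id = c("SINK_pyr", "PPP"),
    equation = c("pyr_c ->", ""),
    lower_bound = NA_real_, upper_bound = NA_real_, gpr = "", note = "",
    stringsAsFactors = FALSE)
  inv <- invert_curation_ledger(ledger, m)
  out <- apply_curation(m, ledger)
  back <- apply_curation(out$model, inv)
  expect_equal(model_stats(back$model), model_stats(m))
  # and the restored reaction has its original stoichiometry
  expect_equal(back$model$stoichiometry[, "PPP"][
    back$model$stoichiometry[, "PPP"] != 0],
    m$stoichiometry[, "PPP"][m$stoichiometry[, "PPP"] != 0])
})

test_that("biomass assembly places GAM inside the reaction and NGAM on the bound", {
  comp <- build_biomass_reaction(
    fractions = c(accoa_c = 3), gam = 23.09, ngam = 5.03,
    condition_label = "C-limited")
  expect_equal(unname(comp$biomass$stoichiometry["atp_c"]), -23.09)
  expect_equal(comp$maintenance$lower_bound, 5.03)
  expect_equal(unname(comp$biomass$stoichiometry["biomass_c"]), 1)
  expect_error(build_biomass_reaction(c(a = -1), gam = 1, ngam = 1),
               "negative")
  expect_warning(build_biomass_reaction(numeric(0), gam = 0, ngam = 0),
                 "degenerate")
})

test_that("mass balance flags elemental residuals and skips unannotated reactions", {
  mets <- data.frame(id = c("glc", "pyr"),
                     formula = c("C6H12O6", "C3H4O3"), compartment = "c")
  rxn <- data.frame(id = c("BAD", "EX"), lower_bound = 0, upper_bound = 10)
  st <- list(BAD = c(glc = -1, pyr = 2), EX = c(pyr = -1))
  m <- metabolic_model(mets, rxn, st)
  res <- check_mass_balance(m)
  expect_true("BAD" %in% res$imbalanced$reaction)
  expect_true("H" %in% res$imbalanced$element)   # 2 H short of 12
  expect_false("EX" %in% res$imbalanced$reaction)  # exchanges excluded

  # carbon balances even though H does not
  resC <- check_mass_balance(m, elements = "C")
  expect_equal(nrow(resC$imbalanced), 0L)

  # no formulas at all: nothing checked, everything reported unchecked
  m2 <- metabolic_model(data.frame(id = c("a", "b"), compartment = "c"),
                        data.frame(id = "R", lower_bound = 0, upper_bound = 1),
                        list(R = c(a = -1, b = 1)))
  res2 <- check_mass_balance(m2)
  expect_equal(nrow(res2$imbalanced), 0L)
  expect_identical(res2$unchecked, "R")
})

test_that("mass-balance verdicts are invariant to positive rescaling", {
  mets <- data.frame(id = c("glc", "pyr"),
                     formula = c("C6H12O6", "C3H4O3"), compartment = "c")
  for (scale in c(0.5, 1, 3)) {
    st <- list(BAD = c(glc = -1 * scale, pyr = 2 * scale))
    m <- metabolic_model(mets,
                         data.frame(id = "BAD", lower_bound = 0, upper_bound = 1),
                         st)
    res <- check_mass_balance(m)
    expect_setequal(unique(res$imbalanced$element), c("H"))
  }
})
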