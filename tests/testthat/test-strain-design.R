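# Knockout search, context models + restoration scanning, supplementation.

test_that("deleting the competing sink growth-couples DDDA production", {
  m <- toy_model(biomass_atp = 20, competing_sink = TRUE)
  man <- toy_manifest()
  # wild type: max growth uses the sink, DDDA can be zero
  wt <- knockout_score(m, character(0), "EX_ddda")
  expect_equal(wt$growth, man$max_growth_atp20_sink, tolerance = 1e-6)
  expect_equal(wt$product, 0, tolerance = 1e-6)
  expect_false(wt$coupled)

  des <- knockout_local_search(m, "EX_ddda", max_ko = 2)
  expect_true("DDCAS" %in% des$deleted)
  expect_equal(des$product, man$coupled_ddda_atp20, tolerance = 1e-6)
  expect_gt(des$product, wt$product + 1e-3)
  expect_true(des$coupled)
  expect_equal(des$growth, man$max_growth_atp20, tolerance = 1e-6)
})

test_that("local search reproduces exhaustive enumeration up to two deletions", {
  m <- toy_model(biomass_atp = 20, competing_sink = TRUE)
  des <- knockout_local_search(m, "EX_ddda", max_ko = 2)
  enum <- knockout_enumerate(m, "EX_ddda", max_ko = 2)
  expect_equal(des$product, enum$product, tolerance = 1e-6)
  expect_true(all(des$deleted %in% unlist(strsplit(enum$all$deleted[
    which.max(enum$all$product)], ","))) || des$product >= enum$product - 1e-6)
})

test_that("knockout eligibility excludes exchanges, biomass, maintenance", {
  m <- toy_model()
  des <- knockout_local_search(m, "EX_ddda", max_ko = 0)
  expect_length(des$deleted, 0L)
  enum <- knockout_enumerate(m, "EX_ddda", max_ko = 1)
  deleted_ids <- setdiff(unique(unlist(strsplit(enum$all$deleted, ","))), "")
  expect_false(any(c("BIOMASS", "ATPM", "EX_glc", "EX_ddda") %in% deleted_ids))
})

test_that("a planted low-expression PPP is removed and restoration recovers it", {
  m <- toy_model()
  # hand-built profile: PPP gene in the low component, everything else high
  vals <- stats::setNames(rep(1000, length(m$genes)), m$genes)
  vals["gPPP"] <- 1
  ctx <- build_context_model(m, vals, threshold_percentile = 25)
  expect_true("PPP" %in% ctx$removed)

  # without the PPP there is no NADPH source: context yield is zero
  scan <- restoration_scan(m, ctx$model, ctx$removed, "EX_ddda",
                           constraints = toy_yield_constraints())
  expect_equal(scan$reaction[1], "PPP")
  expect_true(scan$from_zero[1])
  expect_equal(scan$yield_context[1], 0, tolerance = 1e-9)
  expect_equal(scan$yield_restored[1], 120 / 47, tolerance = 1e-6)
  # improvements are nonnegative by construction
  expect_true(all(scan$yield_restored >= scan$yield_context - 1e-9))
})

test_that("threshold zero removes nothing; alien profiles error", {
  m <- toy_model()
  p <- random_expression_profile(m, seed = 2)
  ctx <- build_context_model(m, p, threshold_percentile = 0)
  expect_length(ctx$removed, 0L)
  expect_error(build_context_model(m, c(alien1 = 5, alien2 = 2)),
               "no genes")
})

test_that("essential low-expression reactions are kept and flagged", {
  m <- toy_model()
  vals <- stats::setNames(rep(1000, length(m$genes)), m$genes)
  vals["gGLYC"] <- 1      # closing glycolysis kills growth entirely
  ctx <- build_context_model(m, vals, threshold_percentile = 25)
  expect_true("GLYC" %in% ctx$kept_flagged)
  expect_false("GLYC" %in% ctx$removed)
})

test_that("restoring all removed reactions is at least as good as the best single", {
  m <- toy_model()
  vals <- stats::setNames(rep(1000, length(m$genes)), m$genes)
  vals[c("gPPP", "gLEUt")] <- 1
  ctx <- build_context_model(m, vals, threshold_percentile = 25)
  expect_setequal(ctx$removed, c("LEUt", "PPP"))
  scan <- restoration_scan(m, ctx$model, ctx$removed, "EX_ddda",
                           constraints = toy_yield_constraints())
  all_restored <- ctx$model
  for (rid in ctx$removed) {
    j <- match(rid, m$reactions$id)
    all_restored <- set_bounds(all_restored, rid,
                               lower = m$reactions$lower_bound[j],
                               upper = m$reactions$upper_bound[j])
  }
  y_all <- optimize(all_restored, "EX_ddda", "max",
                    toy_yield_constraints())$objective_value
  expect_gte(y_all + 1e-9, max(scan$yield_restored))
})

test_that("the planted expression partition is recovered at the default threshold", {
  m <- toy_model()
  hits <- vapply(1:25, function(seed) {
    p <- random_expression_profile(m, seed, active_fraction = 0.75)
    ctx <- build_context_model(m, p, threshold_percentile = 25)
    planted_low <- setdiff(m$genes, p$active)
    called_low <- sort(sub("^g", "g", c(ctx$removed, ctx$kept_flagged)))
    called_genes <- sort(unlist(lapply(called_low, function(r)
      gpr_genes(m$reactions$gpr[m$reactions$id == r]))))
    identical(sort(planted_low), called_genes)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("leucine supplementation lifts the DDDA ceiling as derived by hand", {
  m <- toy_model()
  rep <- supplementation_scan(
    m, "EX_ddda", substrate = "EX_glc", uptake = 10,
    supplements = list(leucine = list(exchange = "EX_leu", open = "LEUDEG")),
    c_mmol_budget = 10, panel = c("accoa_c", "ddda_c", "nadph_c"))
  tab <- rep$table
  expect_equal(tab$product_opt[tab$supplement == "none"], 120 / 47,
               tolerance = 1e-6)
  expect_equal(tab$product_opt[tab$supplement == "leucine"], 150 / 47,
               tolerance = 1e-6)
  expect_equal(tab$uptake[tab$supplement == "leucine"], 10 / 6,
               tolerance = 1e-9)
  # acetyl-CoA turnover strictly rises with the supplement
  expect_gt(rep$flux_sums["accoa_c", "leucine"],
            rep$flux_sums["accoa_c", "none"] + 1e-6)

  # supplementation can never lower the optimum (pure relaxation)
  expect_gte(tab$product_opt[tab$supplement == "leucine"],
             tab$product_opt[tab$supplement == "none"] - 1e-9)
})

test_that("a zero supplement budget reproduces the baseline; missing routes skip", {
  m <- toy_model()
  rep0 <- supplementation_scan(
    m, "EX_ddda", supplements = list(
      leucine = list(exchange = "EX_leu", open = "LEUDEG")),
    c_mmol_budget = 0)
  tab <- rep0$table
  expect_equal(tab$product_opt[tab$supplement == "leucine"],
               tab$product_opt[tab$supplement == "none"], tolerance = 1e-9)

  expect_warning(
    rep2 <- supplementation_scan(
      m, "EX_ddda", supplements = list(
        valine = list(exchange = "EX_val", open = "VALDEG"))),
    "skipped")
  expect_false("valine" %in% rep2$table$supplement)
})
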