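# Flux-activity analysis: wild-type activities, activity ranges vs the FVA
# oracle, graded perturbations, and the coupling scan.

test_that("wild-type activities are absolute fluxes of the resolved optimum", {
  m <- toy_model()
  wt <- wildtype_activity(m)
  expect_true(all(wt$f_wt >= 0))
  # no DDDA demand at the growth optimum: the omega-oxidation step is idle
  expect_equal(wt$f_wt[wt$reaction == "OMEGA"], 0)

  # a reaction fixed at a negative flux reports its absolute value
  ms <- straddle_model()
  ms <- set_bounds(ms, "REV", lower = -3, upper = -3)
  ms$biomass <- "OUTX"    # any feasible objective works as "growth" here
  wt2 <- wildtype_activity(ms)
  expect_equal(wt2$f_wt[wt2$reaction == "REV"], 3)
})

test_that("activity ranges equal the signed-interval FVA oracle on all toy reactions", {
  m <- toy_model()
  for (rid in m$reactions$id[!is_exchange(m)]) {
    got <- activity_range(m, rid)
    want <- fva_activity_oracle(m, rid)
    expect_equal(unname(got), unname(want), tolerance = 1e-6, info = rid)
  }
})

test_that("straddling, irreversible, and blocked reactions range correctly", {
  ms <- straddle_model()
  # REV feasible over [-4, 2]: activity min 0 (straddles), max 4
  expect_equal(unname(activity_range(ms, "REV")), c(0, 4), tolerance = 1e-6)
  expect_equal(unname(fva_activity_oracle(ms, "REV")), c(0, 4),
               tolerance = 1e-6)
  # INX irreversible in [0, 2]
  expect_equal(unname(activity_range(ms, "INX")), c(0, 2), tolerance = 1e-6)
  # blocked reaction
  m <- set_bounds(toy_model(), "LEUt", lower = 0, upper = 0)
  expect_equal(unname(activity_range(m, "LEUt")), c(0, 0))
})

test_that("graded perturbations reduce to wild type at the slack ends", {
  m <- toy_model()
  ref <- flux_activity_reference(m, reactions = c("PPP", "GLYC", "OMEGA"))
  Bwt <- optimize(m, "EX_biomass", "max")$objective_value
  # C1 at k_att = 1 allows f up to f_wt: non-binding at the wild type
  expect_equal(perturbation_growth(m, "GLYC", "down", 1, ref)$B, Bwt,
               tolerance = 1e-6)
  # C2 at k_int = 0 demands f >= f_wt: satisfied by the wild type
  expect_equal(perturbation_growth(m, "GLYC", "up", 0, ref)$B, Bwt,
               tolerance = 1e-6)
  # forcing maximal PPP activity diverts carbon from growth
  expect_lt(perturbation_growth(m, "PPP", "up", 1, ref)$B, Bwt - 1e-6)
})

test_that("perturbed growth is monotone along the tightening directions", {
  m <- toy_model()
  rids <- c("PPP", "GLYC", "PDH", "OMEGA", "ACC")
  ref <- flux_activity_reference(m, reactions = rids)
  ks <- seq(0, 1, by = 0.25)
  for (rid in rids) {
    B_dn <- vapply(ks, function(k)
      perturbation_growth(m, rid, "down", k, ref)$B, 1)
    # k_att 1 -> 0 tightens C1: B non-increasing as k decreases
    expect_true(all(diff(B_dn) >= -1e-7), info = paste("down", rid))
    B_up <- vapply(ks, function(k)
      perturbation_growth(m, rid, "up", k, ref)$B, 1)
    # k_int 0 -> 1 tightens C2: B non-increasing as k increases
    expect_true(all(diff(B_up) <= 1e-7), info = paste("up", rid))
    expect_true(all(B_up <= optimize(m, "EX_biomass", "max")$objective_value + 1e-6))
  }
})

test_that("a planted bottleneck is classified as a coupled overexpression target", {
  m <- plant_bottleneck(toy_model(), "OMEGA", 1.0)
  scan <- scan_targets(m, "EX_ddda", grid_step = 0.25,
                       reactions = c("OMEGA", "LEUDEG", "GLYC"))
  cls <- scan$classification
  expect_equal(cls$class[cls$reaction == "OMEGA"], "coupled-overexpression")
  # zero-capacity reaction is neutral
  expect_equal(cls$class[cls$reaction == "LEUDEG"], "neutral")
  # the product rises with the forced activity of the bottleneck
  up <- scan$grid[scan$grid$reaction == "OMEGA" & scan$grid$mode == "up", ]
  up <- up[order(up$k), ]
  expect_true(all(diff(up$product_opt) >= -1e-7))
  expect_gt(max(up$product_opt), up$product_opt[1] + 1e-6)
  # every cell respects B_jk <= B_wt and nonnegative product
  ok <- scan$grid[scan$grid$status == "optimal", ]
  expect_true(all(ok$B <= scan$B_wt + 1e-6))
  expect_true(all(ok$product_opt >= -1e-9))
})

test_that("a coarse scan grid is nested inside a finer one", {
  m <- plant_bottleneck(toy_model(), "OMEGA", 1.0)
  fine <- scan_targets(m, "EX_ddda", grid_step = 0.25, reactions = "OMEGA")
  coarse <- scan_targets(m, "EX_ddda", grid_step = 0.5, reactions = "OMEGA")
  for (i in seq_len(nrow(coarse$grid))) {
    row <- coarse$grid[i, ]
    match_row <- fine$grid[fine$grid$reaction == row$reaction &
                             fine$grid$mode == row$mode &
                             abs(fine$grid$k - row$k) < 1e-12, ]
    expect_equal(nrow(match_row), 1L)
    expect_equal(row$B, match_row$B, tolerance = 1e-6)
    expect_equal(row$product_opt, match_row$product_opt, tolerance = 1e-6)
  }
})
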