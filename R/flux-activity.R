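## Flux-activity analysis: overexpression / downregulation target scanning.
##
## Flux activity f_j = |v_j|. The reference state gives f_wt (biomass-optimal,
## parsimoniously resolved); f_min/f_max are the MILP extrema of |v_j| where
## v_j is decomposed as f+ - f- with binary indicators forcing one part to
## zero. Because only the scanned reaction is decomposed, the binary pair
## induces exactly two sign branches (v_j >= 0, v_j <= 0); the MILPs are
## solved exactly by enumerating both branches as LPs, a complete
## branch-and-bound for this structure.
##
## The graded perturbation problems maximise biomass subject to
##   (C1, downregulation):  f_j <= f_min + k_att (f_wt - f_min)
##   (C2, upregulation):    f_j >= f_wt + k_int (f_max - f_wt)
## giving B_jk; the product is then optimised subject to biomass >= B_jk and
## the same activity constraint (step four of the scan). k runs 0..1 in
## steps of 0.1 by default.

#' Wild-type flux activities
#'
#' Biomass is maximised under the given constraints, alternate optima are
#' resolved parsimoniously, and f_wt = |v_j| is reported per reaction.
#'
#' @param model a `metabolic_model`.
#' @param constraints optional `condition_constraints`.
#' @return data.frame(reaction, f_wt).
#' @export
wildtype_activity <- function(model, constraints = NULL) {
  st <- resolve_unique(model, objective = model$biomass[1], sense = "max",
                       constraints = constraints)
  if (st$status != "optimal")
    stop("wild-type problem not optimal: ", st$status)
  data.frame(reaction = model$reactions$id,
             f_wt = abs(unname(st$fluxes[model$reactions$id])),
             stringsAsFactors = FALSE)
}

## Solve an LP on one sign branch of reaction j.
## dir = +1 restricts v_j >= 0, dir = -1 restricts v_j <= 0; extra activity
## rows act on f_j = dir * v_j.
branch_lp <- function(model, j, dir, obj, sense, act_ge = NULL, act_le = NULL) {
  bb <- model_bounds(model)
  if (dir > 0) bb$lb[j] <- max(bb$lb[j], 0) else bb$ub[j] <- min(bb$ub[j], 0)
  if (bb$lb[j] > bb$ub[j]) return(list(status = "infeasible", value = NA_real_))
  n <- length(bb$lb)
  Ale <- NULL; ble <- NULL
  row <- function(sgn) { r <- numeric(n); r[j] <- sgn * dir; r }
  if (!is.null(act_le)) { Ale <- rbind(Ale, row(+1)); ble <- c(ble, act_le) }
  if (!is.null(act_ge)) { Ale <- rbind(Ale, row(-1)); ble <- c(ble, -act_ge) }
  solve_lp(obj, model$stoichiometry, rep(0, nrow(model$stoichiometry)),
           bb$lb, bb$ub, sense = sense, Ale = Ale, ble = ble)
}

#' Feasible flux-activity range of a reaction
#'
#' Exact extrema of f_j = |v_j| over the steady-state polytope, solved by
#' sign-branch enumeration of the indicator MILP. If the feasible interval
#' of v_j straddles zero, f_min is 0.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id scanned reaction.
#' @param constraints optional `condition_constraints`.
#' @return c(f_min, f_max).
#' @export
activity_range <- function(model, reaction_id, constraints = NULL) {
  model <- apply_constraints(model, constraints)
  j <- reaction_index(model, reaction_id)
  obj <- numeric(nrow(model$reactions)); obj[j] <- 1
  fmax <- -Inf; fmin <- Inf
  feasible <- FALSE
  for (dir in c(1, -1)) {
    ## on branch dir, f_j = dir * v_j: maximise / minimise it
    hi <- branch_lp(model, j, dir, dir * obj, "max")
    if (hi$status == "infeasible") next
    if (hi$status == "unbounded") stop("unbounded activity for ", reaction_id)
    lo <- branch_lp(model, j, dir, dir * obj, "min")
    feasible <- TRUE
    fmax <- max(fmax, hi$value)
    fmin <- min(fmin, lo$value)
  }
  if (!feasible) stop("model infeasible while ranging ", reaction_id)
  c(f_min = max(fmin, 0), f_max = max(fmax, 0))
}

#' Reference activity table
#'
#' f_wt, f_min and f_max for a set of reactions (default: all non-exchange
#' reactions), the inputs of the perturbation grid.
#'
#' @inheritParams wildtype_activity
#' @param reactions reaction ids to include (default all non-exchange).
#' @return data.frame(reaction, f_wt, f_min, f_max).
#' @export
flux_activity_reference <- function(model, constraints = NULL,
                                    reactions = NULL) {
  if (is.null(reactions))
    reactions <- model$reactions$id[!is_exchange(model)]
  wt <- wildtype_activity(model, constraints)
  rng <- t(vapply(reactions, function(r)
    activity_range(model, r, constraints), c(f_min = 0, f_max = 0)))
  out <- data.frame(reaction = reactions,
                    f_wt = wt$f_wt[match(reactions, wt$reaction)],
                    f_min = rng[, "f_min"], f_max = rng[, "f_max"],
                    stringsAsFactors = FALSE, row.names = NULL)
  ## numerical guard: activities must nest f_min <= f_wt <= f_max
  out$f_wt <- pmin(pmax(out$f_wt, out$f_min), out$f_max)
  out
}

activity_rhs <- function(mode, k, act) {
  if (mode == "down") act$f_min + k * (act$f_wt - act$f_min)
  else act$f_wt + k * (act$f_max - act$f_wt)
}

#' Maximum biomass under a graded activity perturbation
#'
#' @param model a `metabolic_model`.
#' @param reaction_id perturbed reaction.
#' @param mode `"down"` (attenuation constraint C1, level `k_att = k`) or
#'   `"up"` (intensification constraint C2, level `k_int = k`). Note the C1
#'   level runs 1 -> 0 as the activity tightens towards f_min.
#' @param k level in [0, 1].
#' @param activities one-row slice of [flux_activity_reference()] for the
#'   reaction (or the full table; the row is looked up).
#' @param constraints optional `condition_constraints`.
#' @return list with `B` (max biomass, NA when infeasible) and `status`.
#' @export
perturbation_growth <- function(model, reaction_id, mode = c("down", "up"),
                                k, activities, constraints = NULL) {
  mode <- match.arg(mode)
  if (k < 0 || k > 1) stop("k must lie in [0, 1]")
  model <- apply_constraints(model, constraints)
  act <- activities[activities$reaction == reaction_id, , drop = FALSE]
  if (!nrow(act)) stop("no activity record for ", reaction_id)
  j <- reaction_index(model, reaction_id)
  obj <- objective_vector(model, model$biomass[1])
  rhs <- activity_rhs(mode, k, act)
  best <- NA_real_
  for (dir in c(1, -1)) {
    sol <- if (mode == "down")
      branch_lp(model, j, dir, obj, "max", act_le = rhs)
    else
      branch_lp(model, j, dir, obj, "max", act_ge = rhs)
    if (sol$status == "optimal" && (is.na(best) || sol$value > best))
      best <- sol$value
  }
  list(B = best, status = if (is.na(best)) "infeasible" else "optimal")
}

#' Scan graded up/down-regulations for product coupling
#'
#' For every reaction and level k on the grid, the maximum biomass B_jk under
#' the activity constraint is computed, then the product exchange is
#' optimised subject to biomass >= B_jk (or >= the wild-type optimum when
#' `biomass_mode = "fixed-wt"`) and the same constraint. A reaction is
#' classified `coupled-overexpression` when the product optimum is
#' non-decreasing along increasing k_int and strictly increases somewhere;
#' `coupled-downregulation` analogously along tightening k_att (1 -> 0);
#' otherwise `neutral`.
#'
#' @param model a `metabolic_model`.
#' @param product product exchange reaction id.
#' @param grid_step perturbation grid step (default 0.1, grid 0..1 inclusive).
#' @param constraints optional `condition_constraints`.
#' @param reactions reactions to scan (default all non-exchange, excluding
#'   biomass and maintenance).
#' @param biomass_mode `"per-cell"` anchors the product step at B_jk (the
#'   scan's own growth optimum per cell); `"fixed-wt"` at the unperturbed
#'   optimum.
#' @param product_sense objective sense for the product step; the default
#'   maximises the targeted product.
#' @param tol strict-increase tolerance for classification.
#' @return a `flux_activity_scan`: list with `reference` (activity table),
#'   `grid` (long data.frame reaction/mode/k/B/product_opt/status) and
#'   `classification` (data.frame reaction/class).
#' @export
scan_targets <- function(model, product, grid_step = 0.1, constraints = NULL,
                         reactions = NULL,
                         biomass_mode = c("per-cell", "fixed-wt"),
                         product_sense = c("max", "min"), tol = 1e-6) {
  biomass_mode <- match.arg(biomass_mode)
  product_sense <- match.arg(product_sense)
  model <- apply_constraints(model, constraints)
  if (is.null(reactions))
    reactions <- setdiff(model$reactions$id[!is_exchange(model)],
                         c(model$biomass, model$maintenance))
  ref <- flux_activity_reference(model, reactions = reactions)
  ks <- seq(0, 1, by = grid_step)
  if (abs(ks[length(ks)] - 1) > 1e-12) ks <- c(ks, 1)
  pobj <- objective_vector(model, product)
  bobj <- objective_vector(model, model$biomass[1])
  Bwt <- optimize(model, objective = model$biomass[1], sense = "max")$objective_value

  rows <- list()
  for (rid in reactions) {
    j <- reaction_index(model, rid)
    act <- ref[ref$reaction == rid, , drop = FALSE]
    for (mode in c("up", "down")) {
      if (mode == "up" && act$f_max <= tol) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = rid, mode = mode, k = ks, B = NA_real_,
          product_opt = NA_real_, status = "degenerate",
          stringsAsFactors = FALSE)
        next
      }
      for (k in ks) {
        rhs <- activity_rhs(mode, k, act)
        Bbest <- NA_real_; pbest <- NA_real_
        for (dir in c(1, -1)) {
          solB <- if (mode == "down")
            branch_lp(model, j, dir, bobj, "max", act_le = rhs)
          else branch_lp(model, j, dir, bobj, "max", act_ge = rhs)
          if (solB$status != "optimal") next
          if (is.na(Bbest) || solB$value > Bbest) Bbest <- solB$value
        }
        if (!is.na(Bbest)) {
          floorB <- if (biomass_mode == "per-cell") Bbest else Bwt
          growth_row <- -bobj            # biomass >= floor  as  -b'v <= -floor
          for (dir in c(1, -1)) {
            solP <- if (mode == "down")
              branch_lp2(model, j, dir, pobj, product_sense, act_le = rhs,
                         extra_A = rbind(growth_row),
                         extra_b = -(floorB - 1e-9))
            else branch_lp2(model, j, dir, pobj, product_sense, act_ge = rhs,
                            extra_A = rbind(growth_row),
                            extra_b = -(floorB - 1e-9))
            if (solP$status != "optimal") next
            better <- is.na(pbest) ||
              (if (product_sense == "max") solP$value > pbest
               else solP$value < pbest)
            if (better) pbest <- solP$value
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = rid, mode = mode, k = k, B = Bbest, product_opt = pbest,
          status = if (is.na(Bbest)) "infeasible" else "optimal",
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)

  classify <- function(rid) {
    up <- grid[grid$reaction == rid & grid$mode == "up" &
                 grid$status == "optimal", ]
    up <- up[order(up$k), ]
    if (nrow(up) >= 2 && all(diff(up$product_opt) >= -tol) &&
        (max(up$product_opt) - up$product_opt[1]) > tol)
      return("coupled-overexpression")
    dn <- grid[grid$reaction == rid & grid$mode == "down" &
                 grid$status == "optimal", ]
    dn <- dn[order(-dn$k), ]                    # tightening direction 1 -> 0
    if (nrow(dn) >= 2 && all(diff(dn$product_opt) >= -tol) &&
        (max(dn$product_opt) - dn$product_opt[1]) > tol)
      return("coupled-downregulation")
    "neutral"
  }
  cls <- data.frame(reaction = reactions,
                    class = vapply(reactions, classify, ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(reference = ref, grid = grid, classification = cls,
                 product = product, B_wt = Bwt),
            class = "flux_activity_scan")
}

## branch_lp with arbitrary extra inequality rows
branch_lp2 <- function(model, j, dir, obj, sense, act_ge = NULL, act_le = NULL,
                       extra_A = NULL, extra_b = NULL) {
  bb <- model_bounds(model)
  if (dir > 0) bb$lb[j] <- max(bb$lb[j], 0) else bb$ub[j] <- min(bb$ub[j], 0)
  if (bb$lb[j] > bb$ub[j]) return(list(status = "infeasible", value = NA_real_))
  n <- length(bb$lb)
  Ale <- extra_A; ble <- extra_b
  row <- function(sgn) { r <- numeric(n); r[j] <- sgn * dir; r }
  if (!is.null(act_le)) { Ale <- rbind(Ale, row(+1)); ble <- c(ble, act_le) }
  if (!is.null(act_ge)) { Ale <- rbind(Ale, row(-1)); ble <- c(ble, -act_ge) }
  solve_lp(obj, model$stoichiometry, rep(0, nrow(model$stoichiometry)),
           bb$lb, bb$ub, sense = sense, Ale = Ale, ble = ble)
}

#' @export
print.flux_activity_scan <- function(x, ...) {
  cat("<flux_activity_scan> product:", x$product, "\n")
  print(table(x$classification$class))
  invisible(x)
}
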