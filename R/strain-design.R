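## Growth-coupled knockout search, context models with restoration scanning,
## and branched-chain amino acid supplementation.

#' Pessimistic product score of a deletion set
#'
#' Deletes the reactions, maximises growth, then reports the MINIMUM product
#' flux among growth-optimal states (inner pessimism): a positive score
#' certifies growth coupling rather than reflecting an arbitrary solver
#' vertex.
#'
#' @param model a `metabolic_model`.
#' @param deletions reaction ids to close.
#' @param product product exchange id.
#' @param constraints optional `condition_constraints`.
#' @param tol slack on the fixed growth optimum.
#' @return list with `growth`, `product` (the pessimistic score), `coupled`,
#'   `status`.
#' @export
knockout_score <- function(model, deletions, product, constraints = NULL,
                           tol = 1e-7) {
  model <- apply_constraints(model, constraints)
  for (id in deletions) model <- set_bounds(model, id, lower = 0, upper = 0)
  g <- optimize(model, objective = model$biomass[1], sense = "max")
  if (g$status != "optimal" || g$objective_value < tol)
    return(list(growth = 0, product = 0, coupled = FALSE, status = g$status))
  bobj <- objective_vector(model, model$biomass[1])
  pmin_st <- optimize(model, objective = product, sense = "min",
                      extra_constraints = list(A = rbind(-bobj),
                                               b = -(g$objective_value - tol)))
  p <- if (pmin_st$status == "optimal") max(pmin_st$objective_value, 0) else 0
  list(growth = g$objective_value, product = p, coupled = p > tol,
       status = "optimal")
}

#' Growth-coupled knockout search by iterated local moves
#'
#' Local search over deletion sets in the spirit of genetic design by local
#' search: from the current set, all neighbours reachable by adding,
#' removing, or swapping one reaction (up to `max_ko` deletions) are scored
#' with [knockout_score()] and the best strictly improving neighbour is
#' taken; the search stops at a local optimum. Deterministic: candidates are
#' visited in lexicographic order and ties keep the incumbent.
#'
#' @param model a `metabolic_model`.
#' @param product product exchange id.
#' @param max_ko maximum deletions (default 5).
#' @param neighborhood number of set elements changed per move (1 supported).
#' @param constraints optional `condition_constraints`.
#' @param eligible candidate reactions; default excludes exchanges, biomass,
#'   maintenance, and spontaneous (no-GPR) reactions.
#' @return a `knockout_design`: list with `deleted`, `product`
#'   (production at max growth, pessimistic), `growth`, `coupled`, `trace`
#'   (search path data.frame).
#' @export
knockout_local_search <- function(model, product, max_ko = 5,
                                  neighborhood = 1, constraints = NULL,
                                  eligible = NULL) {
  if (neighborhood != 1) stop("only neighborhood = 1 is implemented")
  model <- apply_constraints(model, constraints)
  if (is.null(eligible)) {
    excl <- is_exchange(model) | model$reactions$id %in% model$biomass |
      model$reactions$id %in% stats::na.omit(model$maintenance) |
      model$reactions$gpr == ""
    eligible <- sort(model$reactions$id[!excl])
  }
  current <- character(0)
  cur <- knockout_score(model, current, product)
  trace <- data.frame(step = 0L, deleted = "", product = cur$product,
                      growth = cur$growth, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    neighbours <- list()
    if (length(current) < max_ko)
      for (r in setdiff(eligible, current))
        neighbours[[length(neighbours) + 1L]] <- sort(c(current, r))
    for (r in current)
      neighbours[[length(neighbours) + 1L]] <- setdiff(current, r)
    for (r in current)
      for (r2 in setdiff(eligible, current))
        neighbours[[length(neighbours) + 1L]] <- sort(c(setdiff(current, r), r2))
    neighbours <- unique(neighbours)
    best <- NULL; best_score <- cur$product
    for (nb in neighbours) {
      sc <- knockout_score(model, nb, product)
      if (sc$product > best_score + 1e-9) {
        best <- nb; best_score <- sc$product; best_sc <- sc
      }
    }
    if (is.null(best)) break
    current <- best; cur <- best_sc
    trace <- rbind(trace, data.frame(step = step,
                                     deleted = paste(current, collapse = ","),
                                     product = cur$product, growth = cur$growth,
                                     stringsAsFactors = FALSE))
  }
  structure(list(deleted = current, product = cur$product,
                 growth = cur$growth, coupled = cur$coupled, trace = trace),
            class = "knockout_design")
}

#' Exhaustive knockout enumeration (oracle)
#'
#' Scores every deletion subset of size <= `max_ko`; used to certify the
#' local search on small networks.
#'
#' @inheritParams knockout_local_search
#' @return list with `deleted` (best set), `product`, `growth`, `coupled`,
#'   and `all` (data.frame of every subset scored).
#' @export
knockout_enumerate <- function(model, product, max_ko = 2,
                               constraints = NULL, eligible = NULL) {
  model <- apply_constraints(model, constraints)
  if (is.null(eligible)) {
    excl <- is_exchange(model) | model$reactions$id %in% model$biomass |
      model$reactions$id %in% stats::na.omit(model$maintenance) |
      model$reactions$gpr == ""
    eligible <- sort(model$reactions$id[!excl])
  }
  sets <- list(character(0))
  for (sz in seq_len(min(max_ko, length(eligible))))
    sets <- c(sets, utils::combn(eligible, sz, simplify = FALSE))
  rows <- lapply(sets, function(s) {
    sc <- knockout_score(model, s, product)
    data.frame(deleted = paste(s, collapse = ","), product = sc$product,
               growth = sc$growth, coupled = sc$coupled,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  best <- which.max(all$product)
  list(deleted = sets[[best]], product = all$product[best],
       growth = all$growth[best], coupled = all$coupled[best], all = all)
}

## ---------------------------------------------------------------------------
## Context-specific models and restoration scanning

#' Build an expression context model
#'
#' Reaction expression is the GPR projection of gene values (AND -> min,
#' OR -> max). Evaluable reactions whose expression falls below the given
#' percentile of all evaluable reaction expressions are closed, in id order,
#' unless closing one leaves the model unable to grow, in which case it is
#' kept open and flagged. Reactions without a GPR are kept.
#'
#' @param model a `metabolic_model`.
#' @param expr an `expression_profile` (or named numeric of gene values).
#' @param threshold_percentile percentile (0-100) below which reactions are
#'   candidates for removal; default 25.
#' @param constraints optional `condition_constraints` for the feasibility
#'   guard.
#' @param growth_tol minimal biomass flux regarded as "able to grow".
#' @return list with `model` (context model), `removed`, `kept_flagged`,
#'   `reaction_expression` (named numeric, NA = non-evaluable),
#'   `threshold`.
#' @export
build_context_model <- function(model, expr, threshold_percentile = 25,
                                constraints = NULL, growth_tol = 1e-6) {
  values <- if (inherits(expr, "expression_profile")) expr$values else expr
  if (!any(names(values) %in% model$genes))
    stop("expression profile shares no genes with the model")
  rexp <- vapply(model$reactions$gpr, function(g)
    suppressWarnings(eval_gpr(g, values)), 1, USE.NAMES = FALSE)
  names(rexp) <- model$reactions$id
  evaluable <- !is.na(rexp)
  if (!any(evaluable)) stop("no reaction expression is evaluable")
  thr <- stats::quantile(rexp[evaluable], threshold_percentile / 100,
                         names = FALSE, type = 7)
  low <- evaluable & rexp < thr
  ctx <- apply_constraints(model, constraints)
  removed <- character(0); flagged <- character(0)
  for (rid in sort(model$reactions$id[low])) {
    trial <- set_bounds(ctx, rid, lower = 0, upper = 0)
    g <- optimize(trial, objective = model$biomass[1], sense = "max")
    if (g$status == "optimal" && g$objective_value > growth_tol) {
      ctx <- trial; removed <- c(removed, rid)
    } else {
      flagged <- c(flagged, rid)
    }
  }
  list(model = ctx, removed = removed, kept_flagged = flagged,
       reaction_expression = rexp, threshold = thr)
}

#' Restoration scan over context-removed reactions
#'
#' Each removed reaction is restored alone (original bounds re-opened) and
#' the product optimum under the same biomass floor is recomputed. The yield
#' improvement is reported relative to the context model's yield; when that
#' baseline is zero the improvement is flagged `from_zero` instead of a
#' division.
#'
#' @param model the ORIGINAL (uncurtailed) `metabolic_model`, source of the
#'   bounds to restore.
#' @param context_model the context model produced by
#'   [build_context_model()].
#' @param removed removed reaction ids to scan.
#' @param product product exchange id.
#' @param biomass_floor minimum biomass during the product optimisation
#'   (default 0).
#' @param constraints optional `condition_constraints`.
#' @param tol improvements <= tol are omitted.
#' @return data.frame(reaction, yield_context, yield_restored,
#'   improvement_pct, from_zero), sorted by decreasing improvement
#'   (from-zero restorations first, by restored yield).
#' @export
restoration_scan <- function(model, context_model, removed, product,
                             biomass_floor = 0, constraints = NULL,
                             tol = 1e-9) {
  stopifnot(all(removed %in% model$reactions$id))
  ctx <- apply_constraints(context_model, constraints)
  y0 <- product_yield(ctx, product, biomass_floor, NULL)
  rows <- lapply(removed, function(rid) {
    j <- reaction_index(model, rid)
    m2 <- set_bounds(ctx, rid, lower = model$reactions$lower_bound[j],
                     upper = model$reactions$upper_bound[j])
    y1 <- product_yield(m2, product, biomass_floor, NULL)
    data.frame(reaction = rid, yield_context = y0, yield_restored = y1,
               improvement_pct = if (!is.na(y0) && y0 > tol)
                 100 * (y1 - y0) / y0 else NA_real_,
               from_zero = is.na(y0) || y0 <= tol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$yield_restored) &
               out$yield_restored - out$yield_context > tol, , drop = FALSE]
  ord <- order(-as.integer(out$from_zero),
               -ifelse(out$from_zero, out$yield_restored, out$improvement_pct))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## BCAA supplementation

bcaa_carbon_fallback <- c(leucine = 6, isoleucine = 6, valine = 5)

#' Branched-chain amino acid supplementation scan
#'
#' For each supplement, its exchange is opened to an uptake of
#' `c_mmol_budget / carbon_atoms` (a fixed carbon budget), the product is
#' maximised on top of the primary glucose feed, fluxes are resolved
#' parsimoniously, and the flux-sum profile is computed on a metabolite
#' panel. A no-supplement baseline is always included. Supplements whose
#' exchange or degradation route is absent are skipped with a warning.
#'
#' @param model a `metabolic_model`.
#' @param product product exchange id.
#' @param substrate primary carbon exchange id.
#' @param uptake primary substrate uptake magnitude (default 10).
#' @param supplements named list: supplement name -> list(exchange =
#'   exchange id, open = reaction ids whose upper bounds must be released to
#'   enable the degradation route, carbon = atoms per molecule (optional;
#'   taken from the exchanged metabolite's formula, then from built-in
#'   fallbacks)).
#' @param c_mmol_budget supplement carbon budget, C-mmol/gDCW/h (default 10).
#' @param panel metabolite ids for the flux-sum panel (default: all).
#' @param release_biomass,release_maintenance passed to the yield setup as
#'   in [theoretical_max_yield()].
#' @param constraints optional `condition_constraints`.
#' @return a `supplementation_report`: list with `table`
#'   (data.frame supplement/uptake/product_opt), `flux_sums` (matrix panel x
#'   supplement), `states` (resolved `flux_state`s).
#' @export
supplementation_scan <- function(model, product, substrate = "EX_glc",
                                 uptake = 10, supplements = NULL,
                                 c_mmol_budget = 10, panel = NULL,
                                 release_biomass = TRUE,
                                 release_maintenance = TRUE,
                                 constraints = NULL) {
  model <- apply_constraints(model, constraints)
  base <- model
  base <- set_bounds(base, substrate, lower = -uptake, upper = -uptake)
  if (release_biomass)
    for (id in base$biomass) base <- set_bounds(base, id, lower = 0, upper = 0)
  if (release_maintenance && !is.na(base$maintenance))
    base <- set_bounds(base, base$maintenance, lower = 0)
  if (is.null(panel)) panel <- base$metabolites$id

  run_one <- function(m) {
    st <- resolve_unique(m, objective = product, sense = "max")
    if (st$status != "optimal") return(NULL)
    list(state = st, product = st$objective_value,
         fs = flux_sum(m, st)[panel])
  }
  results <- list(none = c(run_one(base), list(uptake = 0)))
  for (nm in names(supplements)) {
    sp <- supplements[[nm]]
    if (!sp$exchange %in% base$reactions$id ||
        !all(sp$open %in% base$reactions$id)) {
      warning("supplement '", nm, "' lacks an exchange or degradation route; skipped")
      next
    }
    carbon <- sp$carbon
    if (is.null(carbon)) {
      ex_met <- names(which(model$stoichiometry[, reaction_index(model, sp$exchange)] != 0))
      f <- parse_formula(model$metabolites$formula[match(ex_met, model$metabolites$id)])
      carbon <- if ("C" %in% names(f)) unname(f["C"]) else
        unname(bcaa_carbon_fallback[nm])
    }
    if (is.na(carbon) || is.null(carbon))
      stop("cannot determine carbon count for supplement '", nm, "'")
    up <- c_mmol_budget / carbon
    m <- set_bounds(base, sp$exchange, lower = -up, upper = 0)
    for (id in sp$open) m <- set_bounds(m, id, upper = DEFAULT_BOUND)
    r <- run_one(m)
    if (is.null(r)) {
      warning("supplement '", nm, "' infeasible; skipped")
      next
    }
    results[[nm]] <- c(r, list(uptake = up))
  }
  tab <- do.call(rbind, lapply(names(results), function(nm)
    data.frame(supplement = nm, uptake = results[[nm]]$uptake,
               product_opt = results[[nm]]$product, stringsAsFactors = FALSE)))
  fs <- vapply(results, function(r) r$fs, numeric(length(panel)))
  if (is.null(dim(fs))) fs <- matrix(fs, nrow = length(panel),
                                     dimnames = list(panel, names(results)))
  rownames(fs) <- panel
  structure(list(table = tab, flux_sums = fs,
                 states = lapply(results, `[[`, "state")),
            class = "supplementation_report")
}

#' @export
print.supplementation_report <- function(x, ...) {
  cat("<supplementation_report>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
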