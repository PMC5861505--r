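## Constraints-based flux analysis.
##
## optimize() solves  max/min sum_j c_j v_j  s.t.  S v = 0,  lb <= v <= ub,
## the steady-state linear program at the heart of flux balance analysis.
## resolve_unique() picks a deterministic representative among alternate
## optima by fixing the objective and minimising total absolute flux
## (parsimonious resolution). flux_sum() reports per-metabolite turnover
## Phi_i = 0.5 * sum_j |S_ij v_j|.

#' Condition constraints
#'
#' A labelled set of exchange-flux bounds (and optionally a measured growth
#' rate) describing a culture condition: substrate uptake, CO2 evolution
#' rate, which biomass equation is active, etc. Uptake is a negative flux on
#' an outward-written exchange; `uptake` entries are convenience positives
#' that are negated onto the lower bound.
#'
#' @param label condition name.
#' @param bounds named list: reaction id -> c(lb, ub).
#' @param uptake named numeric of positive uptake magnitudes; each becomes
#'   `lb = -value` on the named exchange.
#' @param biomass reaction id of the biomass equation active under this
#'   condition (NA = model default).
#' @param measured_mu measured specific growth rate (1/h), if any.
#' @return a `condition_constraints` object.
#' @export
condition_constraints <- function(label = "condition", bounds = list(),
                                  uptake = numeric(0), biomass = NA_character_,
                                  measured_mu = NA_real_) {
  for (b in bounds) if (b[1] > b[2]) stop("constraint lb > ub in ", label)
  for (id in names(uptake)) bounds[[id]] <- c(-uptake[[id]], if (!is.null(bounds[[id]])) bounds[[id]][2] else DEFAULT_BOUND)
  structure(list(label = label, bounds = bounds, biomass = biomass,
                 measured_mu = measured_mu),
            class = "condition_constraints")
}

#' Apply condition constraints to a model
#' @param model a `metabolic_model`.
#' @param constraints a `condition_constraints` or NULL.
#' @return the constrained model (bounds overridden; if the constraints name
#'   a biomass equation, other biomass reactions are closed and the objective
#'   moved onto it).
#' @export
apply_constraints <- function(model, constraints) {
  if (is.null(constraints)) return(model)
  unknown <- setdiff(names(constraints$bounds), model$reactions$id)
  if (length(unknown))
    stop("constraints reference unknown reactions: ",
         paste(unknown, collapse = ", "))
  for (id in names(constraints$bounds)) {
    b <- constraints$bounds[[id]]
    model <- set_bounds(model, id, lower = b[1], upper = b[2])
  }
  if (!is.na(constraints$biomass)) {
    others <- setdiff(model$biomass, constraints$biomass)
    for (id in others) model <- set_bounds(model, id, lower = 0, upper = 0)
    model$objective <- stats::setNames(1, constraints$biomass)
  }
  model
}

model_bounds <- function(model) {
  list(lb = model$reactions$lower_bound, ub = model$reactions$upper_bound)
}

objective_vector <- function(model, objective) {
  if (is.character(objective))
    objective <- stats::setNames(rep(1, length(objective)), objective)
  obj <- numeric(nrow(model$reactions))
  idx <- reaction_index(model, names(objective))
  obj[idx] <- as.numeric(objective)
  obj
}

#' Flux balance optimization
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric (reaction id -> weight), a character vector
#'   of reaction ids (weight 1), or NULL for the model objective.
#' @param sense `"max"` or `"min"`.
#' @param constraints optional `condition_constraints`.
#' @param extra_constraints optional list(A, b) of additional rows `A v <= b`
#'   indexed over the model's reactions (used by the scanning machinery).
#' @return a `flux_state`: list with `fluxes` (named), `objective_value`,
#'   `status` (`"optimal"`, `"infeasible"`, `"unbounded"`).
#' @export
optimize <- function(model, objective = NULL, sense = c("max", "min"),
                     constraints = NULL, extra_constraints = NULL) {
  sense <- match.arg(sense)
  model <- apply_constraints(model, constraints)
  if (is.null(objective)) objective <- model$objective
  if (!length(objective)) stop("no objective given and model has none")
  obj <- objective_vector(model, objective)
  bb <- model_bounds(model)
  sol <- solve_lp(obj, model$stoichiometry, rep(0, nrow(model$stoichiometry)),
                  bb$lb, bb$ub, sense = sense,
                  Ale = extra_constraints$A, ble = extra_constraints$b)
  fluxes <- if (sol$status == "optimal")
    stats::setNames(sol$x, model$reactions$id) else NULL
  structure(list(fluxes = fluxes, objective_value = sol$value,
                 status = sol$status),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status:", x$status,
      if (x$status == "optimal") paste0(" objective: ",
                                        format(x$objective_value)), "\n")
  invisible(x)
}

#' Deterministic flux resolution among alternate optima
#'
#' Fixes the objective at its optimum and minimises total absolute flux
#' (sum |v_j|) via the standard positive/negative split. The result is a
#' parsimonious representative independent of simplex vertex choice up to
#' the stated tolerance; in particular, futile cycles and closed side routes
#' carry zero flux.
#'
#' @inheritParams optimize
#' @param tol slack allowed on the fixed objective (default 1e-9).
#' @return a `flux_state` whose `objective_value` is the (re-evaluated)
#'   original objective.
#' @export
resolve_unique <- function(model, objective = NULL, sense = c("max", "min"),
                           constraints = NULL, extra_constraints = NULL,
                           tol = 1e-9) {
  sense <- match.arg(sense)
  model <- apply_constraints(model, constraints)
  if (is.null(objective)) objective <- model$objective
  first <- optimize(model, objective, sense, constraints = NULL,
                    extra_constraints = extra_constraints)
  if (first$status != "optimal") return(first)
  zstar <- first$objective_value

  n <- nrow(model$reactions)
  obj <- objective_vector(model, objective)
  bb <- model_bounds(model)
  ## variables x = (p, m), v = p - m, p,m >= 0
  pu <- pmax(bb$ub, 0); mu <- pmax(-bb$lb, 0)
  S <- model$stoichiometry
  Aeq <- cbind(S, -S)
  beq <- rep(0, nrow(S))
  ## objective fixed: sense==max -> obj'v >= z*; both directions to pin it
  Ale <- rbind(cbind(diag(n), -diag(n)),      # v <= ub
               cbind(-diag(n), diag(n)),      # -v <= -lb
               c(-obj, obj),                  # obj'v >= z* - tol
               c(obj, -obj))                  # obj'v <= z* + tol
  if (sense == "min") { }                     # same two-sided pin either way
  ble <- c(bb$ub, -bb$lb, -(zstar - tol), zstar + tol)
  if (!is.null(extra_constraints)) {
    Ale <- rbind(Ale, cbind(extra_constraints$A, -extra_constraints$A))
    ble <- c(ble, extra_constraints$b)
  }
  cost <- rep(1, 2 * n)
  sol <- solve_lp(cost, Aeq, beq, lb = rep(0, 2 * n), ub = c(pu, mu),
                  sense = "min", Ale = Ale, ble = ble)
  if (sol$status != "optimal") return(first)  # fall back to the vertex state
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  v <- pmin(pmax(v, bb$lb), bb$ub)
  structure(list(fluxes = stats::setNames(v, model$reactions$id),
                 objective_value = sum(obj * v), status = "optimal"),
            class = "flux_state")
}

#' Steady-state residual of a flux state
#' @param model a `metabolic_model`.
#' @param state a `flux_state`.
#' @return max_i |sum_j S_ij v_j|.
#' @export
steady_state_residual <- function(model, state) {
  stopifnot(state$status == "optimal")
  max(abs(model$stoichiometry %*% state$fluxes[model$reactions$id]))
}

#' Flux-sum metabolite turnover
#'
#' Phi_i = 0.5 * sum_j |S_ij v_j|: half the total absolute
#' stoichiometry-weighted flux incident to metabolite i, i.e. its turnover
#' rate at steady state (production and consumption halves are equal).
#'
#' @param model a `metabolic_model`.
#' @param state an optimal `flux_state`.
#' @return named numeric vector Phi over metabolite ids.
#' @export
flux_sum <- function(model, state) {
  stopifnot(state$status == "optimal")
  v <- state$fluxes[model$reactions$id]
  0.5 * rowSums(abs(model$stoichiometry %*% diag(v)))
}

#' Growth validation against measured rates
#'
#' For each condition, biomass is maximised under the condition's uptake and
#' CO2-evolution constraints and compared with the measured growth rate.
#'
#' @param model a `metabolic_model`.
#' @param datasets list of `condition_constraints`, each with `measured_mu`.
#' @return data.frame with columns dataset, predicted_mu, measured_mu,
#'   deviation (signed), relative_deviation.
#' @export
validate_growth <- function(model, datasets) {
  rows <- lapply(datasets, function(cc) {
    biomass <- if (!is.na(cc$biomass)) cc$biomass else model$biomass[1]
    st <- optimize(model, objective = biomass, sense = "max", constraints = cc)
    mu <- if (st$status == "optimal") st$objective_value else NA_real_
    data.frame(dataset = cc$label, predicted_mu = mu,
               measured_mu = cc$measured_mu,
               deviation = mu - cc$measured_mu,
               relative_deviation = (mu - cc$measured_mu) / cc$measured_mu,
               status = st$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Theoretical maximum product yield
#'
#' Maximum product exchange flux at a fixed substrate uptake, with growth and
#' (optionally) maintenance demands released, i.e. the stoichiometric ceiling
#' for the product.
#'
#' @param model a `metabolic_model`.
#' @param product exchange reaction id of the product.
#' @param substrate exchange reaction id of the substrate.
#' @param uptake positive uptake magnitude (mmol/gDCW/h) fixed on the
#'   substrate exchange.
#' @param release_biomass,release_maintenance zero out the biomass flux /
#'   maintenance lower bound before optimising (both default TRUE).
#' @param constraints optional additional `condition_constraints`.
#' @return maximum product flux (mmol/gDCW/h).
#' @export
theoretical_max_yield <- function(model, product, substrate, uptake,
                                  release_biomass = TRUE,
                                  release_maintenance = TRUE,
                                  constraints = NULL) {
  reaction_index(model, c(product, substrate))
  model <- apply_constraints(model, constraints)
  model <- set_bounds(model, substrate, lower = -uptake, upper = -uptake)
  if (release_biomass)
    for (id in model$biomass) model <- set_bounds(model, id, lower = 0, upper = 0)
  if (release_maintenance && !is.na(model$maintenance))
    model <- set_bounds(model, model$maintenance, lower = 0)
  st <- optimize(model, objective = product, sense = "max")
  if (st$status != "optimal")
    stop("yield LP not optimal: ", st$status)
  st$objective_value
}
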