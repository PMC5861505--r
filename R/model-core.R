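## Model representation and curation.
##
## A `metabolic_model` is a plain S3 list:
##   metabolites   data.frame(id, name, compartment, formula, charge)
##   reactions     data.frame(id, name, lower_bound, upper_bound, gpr, subsystem)
##   stoichiometry dense metabolite x reaction matrix with dimnames
##   genes         character vector of gene ids
##   objective     named numeric, reaction id -> weight c_j
##   compartments  character vector
##   biomass       id(s) of biomass reaction(s), possibly labelled
##   maintenance   id of the ATP-maintenance reaction (or NA)
## Flux units are mmol/gDCW/h throughout; the conventional +/-1000 stands in
## for "unbounded".

DEFAULT_BOUND <- 1000

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, and optionally `name`,
#'   `compartment`, `formula`, `charge`.
#' @param reactions data.frame with columns `id`, and optionally `name`,
#'   `lower_bound`, `upper_bound`, `gpr`, `subsystem`.
#' @param stoichiometry either a metabolite-by-reaction matrix or a named list
#'   (per reaction id) of named coefficient vectors (per metabolite id).
#' @param objective named numeric vector of objective weights by reaction id.
#' @param compartments declared compartment ids; defaults to those used.
#' @param biomass,maintenance reaction ids of the biomass reaction(s) and the
#'   ATP maintenance reaction, if known.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective = numeric(0), compartments = NULL,
                            biomass = character(0), maintenance = NA_character_) {
  metabolites <- fill_columns(as.data.frame(metabolites),
    list(name = "", compartment = "c", formula = "", charge = NA_integer_))
  reactions <- fill_columns(as.data.frame(reactions),
    list(name = "", lower_bound = -DEFAULT_BOUND, upper_bound = DEFAULT_BOUND,
         gpr = "", subsystem = ""))
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")

  if (is.list(stoichiometry) && !is.matrix(stoichiometry)) {
    S <- matrix(0, nrow(metabolites), nrow(reactions),
                dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      coefs <- stoichiometry[[rid]]
      S[names(coefs), rid] <- coefs
    }
  } else {
    S <- as.matrix(stoichiometry)
    if (is.null(dimnames(S)))
      dimnames(S) <- list(metabolites$id, reactions$id)
  }
  if (!identical(rownames(S), metabolites$id) ||
      !identical(colnames(S), reactions$id))
    stop("stoichiometry dimnames must match metabolite and reaction ids")

  genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))

  m <- structure(list(
    metabolites = metabolites, reactions = reactions, stoichiometry = S,
    genes = genes, objective = objective, compartments = compartments,
    biomass = biomass, maintenance = maintenance
  ), class = "metabolic_model")
  validate_model(m)
  m
}

fill_columns <- function(df, defaults) {
  if (!"id" %in% names(df)) stop("'id' column is required")
  df$id <- as.character(df$id)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df[, c("id", names(defaults))]
}

validate_model <- function(m) {
  if (any(m$reactions$lower_bound > m$reactions$upper_bound + 1e-12))
    stop("reaction lower_bound exceeds upper_bound: ",
         paste(m$reactions$id[m$reactions$lower_bound > m$reactions$upper_bound],
               collapse = ", "))
  bad <- setdiff(names(m$objective), m$reactions$id)
  if (length(bad)) stop("objective references unknown reactions: ",
                        paste(bad, collapse = ", "))
  if (!all(m$metabolites$compartment %in% m$compartments))
    stop("metabolite compartment not declared")
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_stats(x)
  cat("<metabolic_model> ", s$n_reactions, " reactions, ", s$n_metabolites,
      " metabolites, ", s$n_genes, " genes\n", sep = "")
  if (length(x$objective))
    cat("objective:", paste(names(x$objective), x$objective, sep = "*",
                            collapse = " + "), "\n")
  invisible(x)
}

#' Model statistics
#'
#' Counts of distinct reactions, metabolites and genes, the headline numbers
#' used to characterise a reconstruction.
#'
#' @param model a `metabolic_model`.
#' @return list with `n_reactions`, `n_metabolites`, `n_genes`.
#' @export
model_stats <- function(model) {
  list(n_reactions = nrow(model$reactions),
       n_metabolites = nrow(model$metabolites),
       n_genes = length(model$genes))
}

#' Exchange reactions
#'
#' A reaction is an exchange/sink if it touches exactly one metabolite
#' (boundary convention: written outward, uptake is negative flux).
#'
#' @param model a `metabolic_model`.
#' @return logical vector along `model$reactions$id`.
#' @export
is_exchange <- function(model) {
  colSums(model$stoichiometry != 0) == 1L
}

reaction_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  i
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction id (must be new).
#' @param stoichiometry named coefficient vector (metabolite id -> coefficient).
#'   New metabolite ids are created on the fly with compartment parsed from a
#'   trailing `_x` suffix or `[x]` bracket when present.
#' @param lower_bound,upper_bound flux bounds.
#' @param name,gpr,subsystem annotation strings.
#' @return the extended model.
#' @export
add_reaction <- function(model, id, stoichiometry,
                         lower_bound = -DEFAULT_BOUND,
                         upper_bound = DEFAULT_BOUND,
                         name = "", gpr = "", subsystem = "") {
  if (id %in% model$reactions$id) stop("reaction already present: ", id)
  new_mets <- setdiff(names(stoichiometry), model$metabolites$id)
  for (mid in new_mets) {
    comp <- met_compartment_guess(mid, model$compartments)
    model$metabolites <- rbind(model$metabolites, data.frame(
      id = mid, name = mid, compartment = comp, formula = "",
      charge = NA_integer_, stringsAsFactors = FALSE))
    if (!comp %in% model$compartments)
      model$compartments <- c(model$compartments, comp)
    model$stoichiometry <- rbind(model$stoichiometry,
      matrix(0, 1, ncol(model$stoichiometry), dimnames = list(mid, NULL)))
  }
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, name = name, lower_bound = lower_bound,
    upper_bound = upper_bound, gpr = gpr, subsystem = subsystem,
    stringsAsFactors = FALSE))
  newcol <- matrix(0, nrow(model$metabolites), 1,
                   dimnames = list(model$metabolites$id, id))
  newcol[names(stoichiometry), 1] <- stoichiometry
  model$stoichiometry <- cbind(model$stoichiometry, newcol)
  model$genes <- sort(unique(c(model$genes, gpr_genes(gpr))))
  model
}

met_compartment_guess <- function(mid, compartments) {
  if (grepl("\\[[A-Za-z0-9]+\\]$", mid))
    return(sub(".*\\[([A-Za-z0-9]+)\\]$", "\\1", mid))
  if (grepl("_[a-z]$", mid)) return(sub(".*_([a-z])$", "\\1", mid))
  "c"
}

#' Remove reactions from a model
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to drop (error if any is unknown).
#' @param prune_metabolites drop metabolites left orphaned (default FALSE).
#' @return the reduced model.
#' @export
remove_reactions <- function(model, ids, prune_metabolites = FALSE) {
  idx <- reaction_index(model, ids)
  model$reactions <- model$reactions[-idx, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[, -idx, drop = FALSE]
  model$objective <- model$objective[setdiff(names(model$objective), ids)]
  rownames(model$reactions) <- NULL
  if (prune_metabolites) {
    keep <- rowSums(model$stoichiometry != 0) > 0
    model$metabolites <- model$metabolites[keep, , drop = FALSE]
    model$stoichiometry <- model$stoichiometry[keep, , drop = FALSE]
  }
  model$genes <- sort(unique(unlist(lapply(model$reactions$gpr, gpr_genes))))
  model
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lower,upper new bounds (NA leaves a bound untouched).
#' @return the updated model.
#' @export
set_bounds <- function(model, id, lower = NA, upper = NA) {
  i <- reaction_index(model, id)
  if (!is.na(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.na(upper)) model$reactions$upper_bound[i] <- upper
  model
}

## ---------------------------------------------------------------------------
## Reaction equation strings: "2 A[c] + B[c] -> C[e]", "<=>" reversible.

#' Parse a reaction equation string
#'
#' Grammar: coefficient-prefixed metabolite terms joined by `+`, sides joined
#' by `->` (irreversible) or `<=>` (reversible); compartment as a `[x]`
#' suffix on the metabolite id.
#'
#' @param eq equation string.
#' @return list with `stoichiometry` (named numeric) and `reversible` flag.
#' @export
parse_equation <- function(eq) {
  reversible <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, "<=>|<->|->", perl = TRUE)[[1]]
  if (length(sides) > 2) stop("malformed equation: ", eq)
  parse_side <- function(txt, sgn) {
    txt <- trimws(txt)
    if (txt == "" || is.na(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms[terms != ""]) {
      mm <- regmatches(tm, regexec("^([0-9.]+)?\\s*(\\S.*)$", tm))[[1]]
      coef <- if (is.na(mm[2]) || mm[2] == "") 1 else as.numeric(mm[2])
      out[mm[3]] <- sgn * coef + if (mm[3] %in% names(out)) out[mm[3]] else 0
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2) parse_side(sides[2], +1) else numeric(0)
  st <- lhs
  for (mid in names(rhs)) st[mid] <- (if (mid %in% names(st)) st[mid] else 0) + rhs[mid]
  list(stoichiometry = st[st != 0], reversible = reversible)
}

#' Format a stoichiometry as an equation string
#' @param stoichiometry named numeric vector.
#' @param reversible use `<=>` instead of `->`.
#' @return equation string.
#' @export
format_equation <- function(stoichiometry, reversible = FALSE) {
  fmt <- function(coefs) {
    if (!length(coefs)) return("")
    paste(ifelse(abs(coefs) == 1, names(coefs),
                 paste(format(abs(coefs), trim = TRUE), names(coefs))),
          collapse = " + ")
  }
  lhs <- stoichiometry[stoichiometry < 0]
  rhs <- stoichiometry[stoichiometry > 0]
  paste(fmt(lhs), if (reversible) "<=>" else "->", fmt(rhs))
}

## ---------------------------------------------------------------------------
## Curation ledger

#' Read a curation ledger from TSV
#'
#' Columns: `action` (add | remove | modify_bounds | modify_stoichiometry),
#' `reaction_id`, `equation`, `lower_bound`, `upper_bound`, `gpr`, `note`.
#'
#' @param path TSV file path.
#' @return a `curation_ledger` data.frame.
#' @export
read_curation_ledger <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("action", "reaction_id")
  if (!all(needed %in% names(df)))
    stop("ledger must have columns: ", paste(needed, collapse = ", "))
  for (nm in c("equation", "gpr", "note")) if (!nm %in% names(df)) df[[nm]] <- ""
  for (nm in c("lower_bound", "upper_bound")) if (!nm %in% names(df)) df[[nm]] <- NA_real_
  class(df) <- c("curation_ledger", "data.frame")
  df
}

#' Apply a curation ledger to a model
#'
#' Actions are applied in ledger order; `add` creates the reaction from its
#' equation string, `remove` deletes it, `modify_bounds` and
#' `modify_stoichiometry` update it in place. Removing or modifying a
#' reaction that does not exist is an error naming the id.
#'
#' @param model a `metabolic_model`.
#' @param ledger a `curation_ledger` (or any data.frame with its columns).
#' @return list with `model` (curated) and `summary`
#'   (`n_added`, `n_removed`, `n_modified`).
#' @export
apply_curation <- function(model, ledger) {
  n_add <- n_rem <- n_mod <- 0L
  for (i in seq_len(nrow(ledger))) {
    e <- ledger[i, ]
    switch(as.character(e$action),
      add = {
        pe <- parse_equation(e$equation)
        lbv <- if (is.na(e$lower_bound)) {
          if (pe$reversible) -DEFAULT_BOUND else 0
        } else e$lower_bound
        ubv <- if (is.na(e$upper_bound)) DEFAULT_BOUND else e$upper_bound
        model <- add_reaction(model, e$reaction_id, pe$stoichiometry,
                              lower_bound = lbv, upper_bound = ubv,
                              gpr = if (is.na(e$gpr)) "" else e$gpr)
        n_add <- n_add + 1L
      },
      remove = {
        model <- remove_reactions(model, e$reaction_id)
        n_rem <- n_rem + 1L
      },
      modify_bounds = {
        model <- set_bounds(model, e$reaction_id,
                            lower = e$lower_bound, upper = e$upper_bound)
        n_mod <- n_mod + 1L
      },
      modify_stoichiometry = {
        idx <- reaction_index(model, e$reaction_id)
        pe <- parse_equation(e$equation)
        new_mets <- setdiff(names(pe$stoichiometry), model$metabolites$id)
        if (length(new_mets)) stop("modify_stoichiometry introduces unknown ",
                                   "metabolites: ", paste(new_mets, collapse = ", "))
        model$stoichiometry[, idx] <- 0
        model$stoichiometry[names(pe$stoichiometry), idx] <- pe$stoichiometry
        n_mod <- n_mod + 1L
      },
      stop("unknown ledger action: ", e$action)
    )
  }
  list(model = model,
       summary = list(n_added = n_add, n_removed = n_rem, n_modified = n_mod))
}

#' Invert a curation ledger
#'
#' Produces a ledger that undoes `add` and `remove` entries (used to check
#' that curation round-trips); bound/stoichiometry modifications need the
#' original values and are not invertible from the ledger alone.
#'
#' @param ledger a curation ledger whose entries are all `add` or `remove`.
#' @param model the model the ledger was applied to (source of equations for
#'   removed reactions).
#' @return the inverse ledger.
#' @export
invert_curation_ledger <- function(ledger, model) {
  if (!all(ledger$action %in% c("add", "remove")))
    stop("only add/remove ledgers are invertible")
  inv <- ledger[rev(seq_len(nrow(ledger))), , drop = FALSE]
  for (i in seq_len(nrow(inv))) {
    if (inv$action[i] == "add") {
      inv$action[i] <- "remove"
    } else {
      idx <- reaction_index(model, inv$reaction_id[i])
      st <- model$stoichiometry[, idx]
      inv$equation[i] <- format_equation(st[st != 0],
        reversible = model$reactions$lower_bound[idx] < 0)
      inv$lower_bound[i] <- model$reactions$lower_bound[idx]
      inv$upper_bound[i] <- model$reactions$upper_bound[idx]
      inv$gpr[i] <- model$reactions$gpr[idx]
      inv$action[i] <- "add"
    }
  }
  inv
}

## ---------------------------------------------------------------------------
## Biomass assembly

#' Assemble a biomass reaction from a composition
#'
#' Builds a biomass synthesis reaction consuming each precursor at its molar
#' fraction (mmol per gDCW), consuming the growth-associated maintenance
#' (GAM) as ATP + H2O -> ADP + Pi, and producing one unit of a biomass
#' pseudo-metabolite. Non-growth-associated maintenance (NGAM) is the
#' conventional separate ATP-hydrolysis reaction carrying its value as a
#' fixed lower bound, returned alongside.
#'
#' @param fractions named numeric, precursor metabolite id -> mmol/gDCW.
#' @param gam growth-associated maintenance, mmol ATP per gDCW.
#' @param ngam non-growth maintenance, mmol ATP per gDCW per h (the source
#'   literature prints mmol ATP/gDCW; encoded as a rate bound by convention).
#' @param condition_label `"C-limited"` or `"N-limited"`.
#' @param atp,adp,h2o,pi,h,biomass_met metabolite ids for the energy species
#'   and the biomass pseudo-metabolite.
#' @return list with `biomass` and `maintenance`, each a list of
#'   `id`, `stoichiometry`, `lower_bound`, `upper_bound`.
#' @export
build_biomass_reaction <- function(fractions, gam, ngam,
                                   condition_label = c("C-limited", "N-limited"),
                                   atp = "atp_c", adp = "adp_c", h2o = "h2o_c",
                                   pi = "pi_c", h = NULL,
                                   biomass_met = "biomass_c") {
  condition_label <- match.arg(condition_label)
  if (any(fractions < 0)) stop("negative biomass fraction")
  if (gam < 0 || ngam < 0) stop("GAM and NGAM must be nonnegative")
  if (!length(fractions) && gam == 0)
    warning("degenerate biomass composition: produces biomass from nothing")
  st <- -fractions
  st[atp] <- (if (atp %in% names(st)) st[atp] else 0) - gam
  st[h2o] <- (if (h2o %in% names(st)) st[h2o] else 0) - gam
  st[adp] <- gam
  st[pi] <- gam
  if (!is.null(h)) st[h] <- gam
  st[biomass_met] <- 1
  st <- st[st != 0 | names(st) == biomass_met]
  list(
    biomass = list(id = paste0("BIOMASS_", sub("-limited", "lim", condition_label)),
                   stoichiometry = st, lower_bound = 0,
                   upper_bound = DEFAULT_BOUND,
                   condition_label = condition_label),
    maintenance = list(id = "ATPM",
                       stoichiometry = stats::setNames(
                         c(-1, -1, 1, 1), c(atp, h2o, adp, pi)),
                       lower_bound = ngam, upper_bound = DEFAULT_BOUND)
  )
}

## ---------------------------------------------------------------------------
## Mass balance

#' Parse an elemental formula
#' @param formula string such as `"C6H12O6"`; generic one/two-letter element
#'   symbols with optional (possibly fractional) counts.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "") return(numeric(0))
  mm <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  out <- numeric(0)
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    ct <- sub("^[A-Z][a-z]?", "", p)
    n <- if (ct == "") 1 else as.numeric(ct)
    out[el] <- (if (el %in% names(out)) out[el] else 0) + n
  }
  out
}

#' Check elemental mass balance of model reactions
#'
#' Exchange/sink reactions and the biomass reaction(s) are excluded;
#' reactions involving any metabolite without a formula are skipped and
#' reported as unchecked. A reaction is imbalanced when any element's net
#' coefficient exceeds the tolerance in absolute value.
#'
#' @param model a `metabolic_model`.
#' @param elements optional subset of element symbols to check (e.g. `"C"`
#'   for a carbon-only audit of lumped networks); default all.
#' @param tol imbalance tolerance (default 1e-6).
#' @return list with `imbalanced` (data.frame reaction/element/residual) and
#'   `unchecked` (reaction ids skipped for missing formulas).
#' @export
check_mass_balance <- function(model, elements = NULL, tol = 1e-6) {
  forms <- lapply(model$metabolites$formula, parse_formula)
  names(forms) <- model$metabolites$id
  has_formula <- vapply(forms, length, 1L) > 0
  excl <- is_exchange(model) | model$reactions$id %in% model$biomass
  unchecked <- character(0)
  rows <- list()
  for (j in which(!excl)) {
    st <- model$stoichiometry[, j]
    mets <- names(st)[st != 0]
    if (!all(has_formula[mets])) {
      unchecked <- c(unchecked, model$reactions$id[j])
      next
    }
    net <- numeric(0)
    for (mid in mets) {
      f <- forms[[mid]]
      for (el in names(f))
        net[el] <- (if (el %in% names(net)) net[el] else 0) + st[mid] * f[el]
    }
    if (!is.null(elements)) net <- net[names(net) %in% elements]
    bad <- which(abs(net) > tol)
    for (b in bad)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = model$reactions$id[j], element = names(net)[b],
        residual = unname(net[b]), stringsAsFactors = FALSE)
  }
  list(
    imbalanced = if (length(rows)) do.call(rbind, rows) else
      data.frame(reaction = character(0), element = character(0),
                 residual = numeric(0)),
    unchecked = unchecked
  )
}

## ---------------------------------------------------------------------------
## GPR boolean rules

#' Extract gene ids from a GPR rule
#' @param gpr boolean rule string over gene ids with `and`/`or`/parentheses.
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || gpr == "") return(character(0))
  toks <- gpr_tokens(gpr)
  unique(toks[!toks %in% c("and", "or", "(", ")")])
}

gpr_tokens <- function(gpr) {
  gpr <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(gpr), "\\s+")[[1]]
  ifelse(tolower(toks) %in% c("and", "or"), tolower(toks), toks)
}

#' Evaluate a GPR rule against gene expression values
#'
#' AND maps to `min`, OR to `max` (the standard continuous relaxation used
#' when projecting transcript levels onto reactions). Genes absent from
#' `values` make the rule non-evaluable (`NA`).
#'
#' @param gpr rule string.
#' @param values named numeric vector of gene expression levels.
#' @return numeric reaction expression, or `NA` if non-evaluable, or `NA`
#'   with attribute `empty=TRUE` when the rule is empty.
#' @export
eval_gpr <- function(gpr, values) {
  if (is.na(gpr) || gpr == "") return(structure(NA_real_, empty = TRUE))
  toks <- gpr_tokens(gpr)
  pos <- 1L
  parse_or <- function() {
    v <- parse_and()
    while (pos <= length(toks) && toks[pos] == "or") {
      pos <<- pos + 1L
      v2 <- parse_and()
      v <- if (is.na(v) || is.na(v2)) NA_real_ else max(v, v2)
    }
    v
  }
  parse_and <- function() {
    v <- parse_atom()
    while (pos <= length(toks) && toks[pos] == "and") {
      pos <<- pos + 1L
      v2 <- parse_atom()
      v <- if (is.na(v) || is.na(v2)) NA_real_ else min(v, v2)
    }
    v
  }
  parse_atom <- function() {
    if (pos > length(toks)) stop("malformed GPR: ", gpr)
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      v <- parse_or()
      if (pos > length(toks) || toks[pos] != ")") stop("unbalanced GPR: ", gpr)
      pos <<- pos + 1L
      return(v)
    }
    pos <<- pos + 1L
    if (tk %in% names(values)) unname(values[tk]) else NA_real_
  }
  v <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in GPR: ", gpr)
  v
}
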