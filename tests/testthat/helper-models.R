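# Shared fixtures, built in code.

# released-demand constraints for yield scenarios on the toy network
toy_yield_constraints <- function() {
  condition_constraints(label = "yield",
                        bounds = list(ATPM = c(0, 1000), BIOMASS = c(0, 0)))
}

# three-reaction linear chain A -> B -> C -> (export), unit bounds
chain_model <- function() {
  mets <- data.frame(id = c("A", "B", "C"), compartment = "c")
  rxn <- data.frame(id = c("SRC", "R1", "R2", "SNK"),
                    lower_bound = c(0, 0, 0, 0),
                    upper_bound = c(1, 10, 10, 10))
  st <- list(SRC = c(A = 1), R1 = c(A = -1, B = 1),
             R2 = c(B = -1, C = 1), SNK = c(C = -1))
  metabolic_model(mets, rxn, st, objective = c(SNK = 1))
}

# mini model with one reversible reaction whose feasible interval straddles 0:
# X is fed at up to 2 and drained at up to 4, REV carries X <-> Y with Y
# drained up to 4 and fed up to 4, so v_REV ranges over [-4, 2].
straddle_model <- function() {
  mets <- data.frame(id = c("X", "Y"), compartment = "c")
  rxn <- data.frame(id = c("INX", "OUTX", "REV", "INY", "OUTY"),
                    lower_bound = c(0, 0, -1000, 0, 0),
                    upper_bound = c(2, 1000, 1000, 4, 1000))
  st <- list(INX = c(X = 1), OUTX = c(X = -1), REV = c(X = -1, Y = 1),
             INY = c(Y = 1), OUTY = c(Y = -1))
  metabolic_model(mets, rxn, st, objective = c(OUTY = 1))
}

# independent LP oracle through scipy (HiGHS); returns optimum or NA
scipy_lp <- function(obj, Aeq, lb, ub, sense = "max") {
  payload <- jsonlite::toJSON(list(
    c = if (sense == "max") -obj else obj,
    Aeq = as.matrix(Aeq), lb = lb, ub = ub), digits = NA)
  script <- "
import json, sys
import numpy as np
from scipy.optimize import linprog
d = json.load(sys.stdin)
A = np.array(d['Aeq'], dtype=float)
res = linprog(np.array(d['c'], dtype=float), A_eq=A, b_eq=np.zeros(A.shape[0]),
              bounds=list(zip(d['lb'], d['ub'])), method='highs')
print(json.dumps({'status': int(res.status), 'fun': None if res.fun is None else float(res.fun)}))
"
  out <- tryCatch(
    system2("python", c("-c", shQuote(script)), input = as.character(payload),
            stdout = TRUE, stderr = FALSE),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(out) || !length(out)) return(NULL)
  res <- jsonlite::fromJSON(out[length(out)])
  if (res$status != 0) return(NA_real_)
  if (sense == "max") -res$fun else res$fun
}

# signed-interval flux variability oracle for flux activity
fva_activity_oracle <- function(model, rid, constraints = NULL) {
  model <- apply_constraints(model, constraints)
  vmax <- optimize(model, objective = rid, sense = "max")$objective_value
  vmin <- optimize(model, objective = rid, sense = "min")$objective_value
  f_max <- max(abs(vmin), abs(vmax))
  f_min <- if (vmin <= 1e-9 && vmax >= -1e-9) 0 else min(abs(vmin), abs(vmax))
  c(f_min = f_min, f_max = f_max)
}
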