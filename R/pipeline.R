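## Pipeline orchestration: run configured analysis stages over a model and
## write a reproducible report bundle (TSV tables + JSON summary + log).

#' Run the strain-design pipeline
#'
#' Stages: `stats`, `curate`, `validate`, `fseof` (flux-activity scan),
#' `cma`, `knockout`, `tsot` (context model + restoration scan),
#' `supplement`. Each requested stage runs independently; a failing stage is
#' recorded in the log and the remaining stages continue. Outputs are
#' deterministic given the same config and seed.
#'
#' @param config either a path to a YAML file or a list with entries:
#'   `model` (SBML path) or `toy` (list of [toy_model()] arguments),
#'   `stages` (character vector), `out` (output directory), `seed`,
#'   `product`, `substrate`, `uptake`, plus optional per-stage blocks
#'   `curation` (ledger TSV path), `validation` (list of condition blocks),
#'   `fseof` (grid_step, reactions), `cma` (k, biomass_floor_fraction),
#'   `knockout` (max_ko), `tsot` (expression TSV path or `synthetic = TRUE`,
#'   threshold_percentile, active_fraction), `supplement` (c_mmol_budget,
#'   supplements).
#' @return invisibly, a list of stage results; files are written under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out %||% "pipeline_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  logf <- file.path(out, "run.log")
  cat("pipeline run\nseed: ", seed, "\nsolver: dcadesign internal simplex ",
      "(two-phase, Bland's rule), tolerance 1e-9\n",
      "package: dcadesign ", as.character(utils::packageVersion("dcadesign")),
      "\n", sep = "", file = logf)
  logmsg <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)

  if (!is.null(config$model)) {
    if (!file.exists(config$model)) stop("model file not found: ", config$model)
    model <- read_sbml(config$model)
  } else if (!is.null(config$toy)) {
    model <- do.call(toy_model, config$toy)
  } else {
    model <- toy_model()
  }
  product <- config$product %||% "EX_ddda"
  substrate <- config$substrate %||% "EX_glc"
  uptake <- config$uptake %||% 10
  stages <- config$stages %||% c("stats")
  results <- list()
  wtsv <- function(df, name) utils::write.table(
    df, file.path(out, paste0(name, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) logmsg("stage ", name, " ok")
    results[[name]] <<- res
  }

  if ("stats" %in% stages) run_stage("stats", function() {
    s <- model_stats(model)
    wtsv(as.data.frame(s), "stats")
    s
  })
  if ("curate" %in% stages) run_stage("curate", function() {
    ledger <- read_curation_ledger(config$curation$ledger)
    cur <- apply_curation(model, ledger)
    model <<- cur$model
    wtsv(as.data.frame(cur$summary), "curation_summary")
    cur$summary
  })
  if ("validate" %in% stages) run_stage("validate", function() {
    datasets <- lapply(config$validation, function(b)
      condition_constraints(label = b$label,
                            bounds = lapply(b$bounds, unlist),
                            uptake = unlist(b$uptake) %||% numeric(0),
                            measured_mu = b$measured_mu %||% NA_real_))
    tab <- validate_growth(model, datasets)
    wtsv(tab, "growth_validation")
    tab
  })
  if ("fseof" %in% stages) run_stage("fseof", function() {
    cfg <- config$fseof %||% list()
    scan <- scan_targets(model, product,
                         grid_step = cfg$grid_step %||% 0.1,
                         reactions = cfg$reactions)
    wtsv(scan$grid, "flux_activity_grid")
    wtsv(scan$classification, "flux_activity_classification")
    scan
  })
  if ("cma" %in% stages) run_stage("cma", function() {
    cfg <- config$cma %||% list()
    res <- cma_optimize(model, product, k = cfg$k %||% 1,
                        biomass_floor_fraction =
                          cfg$biomass_floor_fraction %||% 0.1)
    wtsv(data.frame(swapped = paste(res$swapped, collapse = "+"),
                    yield_baseline = res$yield_baseline,
                    yield_swapped = res$yield_swapped,
                    biomass_floor = res$biomass_floor), "cma")
    wtsv(res$per_swap, "cma_per_swap")
    res
  })
  if ("knockout" %in% stages) run_stage("knockout", function() {
    cfg <- config$knockout %||% list()
    des <- knockout_local_search(model, product, max_ko = cfg$max_ko %||% 5)
    wtsv(data.frame(deleted = paste(des$deleted, collapse = ","),
                    product = des$product, growth = des$growth,
                    coupled = des$coupled), "knockout_design")
    des
  })
  if ("tsot" %in% stages) run_stage("tsot", function() {
    cfg <- config$tsot %||% list()
    expr <- if (!is.null(cfg$expression)) read_expression_tsv(cfg$expression)
      else random_expression_profile(model, seed,
             active_fraction = cfg$active_fraction %||% 0.75)
    ctx <- build_context_model(model, expr,
             threshold_percentile = cfg$threshold_percentile %||% 25)
    scan <- restoration_scan(model, ctx$model, ctx$removed, product,
                             biomass_floor = cfg$biomass_floor %||% 0)
    wtsv(scan, "restoration_scan")
    list(context = ctx, scan = scan)
  })
  if ("supplement" %in% stages) run_stage("supplement", function() {
    cfg <- config$supplement %||% list()
    supplements <- cfg$supplements %||% list(
      leucine = list(exchange = "EX_leu", open = "LEUDEG"))
    rep <- supplementation_scan(model, product, substrate = substrate,
                                uptake = uptake,
                                supplements = supplements,
                                c_mmol_budget = cfg$c_mmol_budget %||% 10,
                                panel = cfg$panel)
    wtsv(rep$table, "supplementation")
    fs <- as.data.frame(rep$flux_sums)
    fs <- cbind(metabolite = rownames(fs), fs)
    wtsv(fs, "supplementation_flux_sums")
    rep
  })

  summary <- list(
    seed = seed, stages = stages,
    stats = results$stats,
    cma_yield = results$cma$yield_swapped %||% NULL,
    knockout_product = results$knockout$product %||% NULL)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
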