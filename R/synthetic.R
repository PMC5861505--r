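## Synthetic networks and expression profiles ("YL-mini").
##
## A compact, fully documented central-metabolism network for an oleaginous
## yeast producing dodecanedioic acid (DDDA): lumped glycolysis, oxidative
## PPP, pyruvate dehydrogenase, fatty-acid synthesis to dodecanoate (ddca),
## omega-oxidation of ddca to DDDA, respiration, ATP maintenance, a biomass
## reaction drawing acetyl-CoA and ATP, and a closed lumped
## leucine-degradation route. Lumping is chosen so that the standard
## scenarios have closed-form optima from carbon/NADPH/ATP accounting (see
## toy_manifest()), which anchors every solver in the package to exact
## rational answers.
##
## Carbon bookkeeping uses effective formulas (acetyl-CoA counted as its C2
## acetyl moiety, cofactor cores as the inert element "R"), so the network
## passes a carbon-only mass-balance audit on all annotated reactions.

#' The YL-mini toy network
#'
#' @param glc_uptake maximum glucose uptake, mmol/gDCW/h (lower bound of
#'   `EX_glc` is `-glc_uptake`); default 10, the standard scan condition.
#' @param biomass_atp ATP cost of one biomass unit (mmol); the default 6
#'   keeps growth carbon-limited with closed form `mu = 2/3 * uptake`; 20
#'   makes ATP binding, the regime used for growth-coupled knockout studies.
#' @param atpm non-growth ATP maintenance (lower bound of `ATPM`); default 1.
#' @param competing_sink add `DDCAS`, an energy-matched dodecanoate sink
#'   (`ddca + nad -> ddca_e + nadh`) plus its exchange; with `biomass_atp =
#'   20` it decouples DDDA from growth and its deletion re-couples it.
#' @return a `metabolic_model` with per-reaction synthetic genes, biomass
#'   objective, and `biomass`/`maintenance` fields set.
#' @export
toy_model <- function(glc_uptake = 10, biomass_atp = 6, atpm = 1,
                      competing_sink = FALSE) {
  rx <- list(
    EX_glc  = list(st = c(glc_e = -1), lb = -glc_uptake, ub = DEFAULT_BOUND,
                   name = "glucose exchange"),
    GLCt    = list(st = c(glc_e = -1, glc_c = 1), name = "glucose transport"),
    GLYC    = list(st = c(glc_c = -1, nad_c = -2, adp_c = -2, pi_c = -2,
                          pyr_c = 2, nadh_c = 2, atp_c = 2, h2o_c = 2),
                   name = "glycolysis (lumped)"),
    PPP     = list(st = c(glc_c = -1, nadp_c = -12, co2_c = 6, nadph_c = 12),
                   name = "oxidative pentose phosphate pathway (lumped)"),
    PDH     = list(st = c(pyr_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1,
                          nadh_c = 1), name = "pyruvate dehydrogenase"),
    ACC     = list(st = c(accoa_c = -1, atp_c = -1, co2_c = -1, malcoa_c = 1,
                          adp_c = 1, pi_c = 1), name = "acetyl-CoA carboxylase"),
    FAS     = list(st = c(malcoa_c = -6, nadph_c = -10, ddca_c = 1,
                          nadp_c = 10, co2_c = 6),
                   name = "fatty acid synthase to dodecanoate (lumped)"),
    OMEGA   = list(st = c(ddca_c = -1, o2_c = -1, nadph_c = -1, nad_c = -1,
                          ddda_c = 1, nadp_c = 1, nadh_c = 1),
                   name = "omega-oxidation of dodecanoate (lumped)"),
    DDDAt   = list(st = c(ddda_c = -1, ddda_e = 1), name = "DDDA transport"),
    EX_ddda = list(st = c(ddda_e = -1), lb = 0, name = "DDDA exchange"),
    RESP    = list(st = c(nadh_c = -1, o2_c = -0.5, adp_c = -2, pi_c = -2,
                          nad_c = 1, atp_c = 2, h2o_c = 2),
                   name = "respiration (lumped oxidative phosphorylation)"),
    ATPM    = list(st = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
                   lb = atpm, name = "ATP maintenance"),
    LEUt    = list(st = c(leu_e = -1, leu_c = 1), name = "leucine transport"),
    EX_leu  = list(st = c(leu_e = -1), lb = 0, ub = 0, name = "leucine exchange"),
    LEUDEG  = list(st = c(leu_c = -1, accoa_c = 3), lb = 0, ub = 0,
                   name = "leucine degradation to acetyl-CoA (lumped, closed)"),
    BIOMASS = list(st = c(accoa_c = -3, atp_c = -biomass_atp,
                          h2o_c = -biomass_atp, adp_c = biomass_atp,
                          pi_c = biomass_atp, biomass_c = 1),
                   lb = 0, name = "biomass synthesis"),
    EX_biomass = list(st = c(biomass_c = -1), lb = 0, name = "biomass drain"),
    O2t     = list(st = c(o2_e = -1, o2_c = 1), name = "oxygen transport"),
    EX_o2   = list(st = c(o2_e = -1), lb = -DEFAULT_BOUND, name = "oxygen exchange"),
    CO2t    = list(st = c(co2_c = -1, co2_e = 1), name = "CO2 transport"),
    EX_co2  = list(st = c(co2_e = -1), lb = 0, name = "CO2 exchange"),
    H2Ot    = list(st = c(h2o_c = -1, h2o_e = 1), name = "water transport"),
    EX_h2o  = list(st = c(h2o_e = -1), lb = -DEFAULT_BOUND, name = "water exchange")
  )
  if (competing_sink) {
    rx$DDCAS <- list(st = c(ddca_c = -1, nad_c = -1, ddca_e = 1, nadh_c = 1),
                     lb = 0, name = "dodecanoate sink (energy-matched leak)")
    rx$EX_ddca <- list(st = c(ddca_e = -1), lb = 0, name = "dodecanoate exchange")
  }

  formulas <- c(
    glc_e = "C6H12O6", glc_c = "C6H12O6", pyr_c = "C3H4O3",
    accoa_c = "C2H3OR", malcoa_c = "C3H3O3R", ddca_c = "C12H24O2",
    ddca_e = "C12H24O2", ddda_c = "C12H22O4", ddda_e = "C12H22O4",
    leu_e = "C6H13NO2", leu_c = "C6H13NO2",
    co2_c = "CO2", co2_e = "CO2", o2_c = "O2", o2_e = "O2",
    h2o_c = "H2O", h2o_e = "H2O",
    nad_c = "R", nadh_c = "RH", nadp_c = "RP", nadph_c = "RPH",
    atp_c = "P3R", adp_c = "P2R", pi_c = "P",
    biomass_c = "C6H9O2R"
  )

  mids <- unique(unlist(lapply(rx, function(r) names(r$st))))
  mets <- data.frame(
    id = mids, name = mids,
    compartment = ifelse(grepl("_e$", mids), "e", "c"),
    formula = unname(formulas[mids]), charge = NA_integer_,
    stringsAsFactors = FALSE)

  exch <- vapply(rx, function(r) length(r$st) == 1L, TRUE)
  rxn <- data.frame(
    id = names(rx),
    name = vapply(rx, function(r) r$name %||% "", ""),
    lower_bound = vapply(rx, function(r) r$lb %||% 0, 1),
    upper_bound = vapply(rx, function(r) r$ub %||% DEFAULT_BOUND, 1),
    gpr = ifelse(exch | names(rx) %in% c("ATPM"), "",
                 paste0("g", names(rx))),
    subsystem = "", stringsAsFactors = FALSE)

  metabolic_model(mets, rxn, lapply(rx, function(r) r$st),
                  objective = c(BIOMASS = 1),
                  biomass = "BIOMASS", maintenance = "ATPM")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form optima of the YL-mini network
#'
#' The manifest documents the scenarios whose optima follow from hand
#' accounting, all at glucose uptake `u` (default 10):
#' * max DDDA, growth and maintenance released: one DDDA needs 6 acetyl-CoA
#'   (3 glucose via glycolysis+PDH) and 11 NADPH (11/12 glucose via PPP), so
#'   `12 u / 47`.
#' * the same with glycolysis swapped NAD->NADP: glycolysis contributes
#'   6 NADPH per DDDA, PPP supplies the rest, `12 u / 41`.
#' * max DDDA with 10 C-mmol/gDCW/h leucine (5 mmol acetyl-CoA for free):
#'   `(12 u + 30) / 47` at u = 10 (i.e. 150/47).
#' * max growth (biomass_atp = 6): carbon-limited, `mu = 2 u / 3`.
#' * max growth (biomass_atp = 20, maintenance 1): ATP-limited; without the
#'   competing sink `mu = (312 u - 47) / 703` and the DDDA flux forced at
#'   every growth optimum is `(5 mu + 1) / 26`; with the sink present
#'   `mu = (156 u - 23) / 349` and DDDA is free to be zero.
#'
#' @param glc_uptake glucose uptake magnitude.
#' @return list of named closed-form values.
#' @export
toy_manifest <- function(glc_uptake = 10) {
  u <- glc_uptake
  mu20 <- (312 * u - 47) / 703
  list(
    max_ddda = 12 * u / 47,
    max_ddda_glyc_swap = 12 * u / 41,
    max_ddda_leucine = (12 * u + 30) / 47,
    max_growth_atp6 = 2 * u / 3,
    max_growth_atp20 = mu20,
    coupled_ddda_atp20 = (5 * mu20 + 1) / 26,
    max_growth_atp20_sink = (156 * u - 23) / 349,
    fluxsum_accoa_at_max_ddda = 6 * 12 * u / 47,
    ## max feasible PPP flux: every NADPH must drain through FAS+omega, so
    ## y + (36/11) y <= u  ->  y = 11 u / 47
    max_ppp_activity = 11 * u / 47
  )
}

#' Random two-component expression profile
#'
#' Draws gene expression from a two-component lognormal mixture: an "active"
#' high component and an "inactive" low component, separated widely enough
#' (meanlog 7 vs 2, sdlog 0.4) that percentile thresholding recovers the
#' planted partition essentially always.
#'
#' @param model a `metabolic_model` with genes.
#' @param seed integer seed; fully determines the profile.
#' @param active_fraction fraction of genes drawn from the high component,
#'   in (0, 1].
#' @param label profile label (e.g. a timepoint).
#' @return an `expression_profile`: list with `values` (named numeric per
#'   gene), `active` (planted active gene ids), `label`.
#' @export
random_expression_profile <- function(model, seed, active_fraction = 0.75,
                                      label = "synthetic") {
  if (!length(model$genes)) stop("model has no genes")
  if (active_fraction <= 0 || active_fraction > 1)
    stop("active_fraction must be in (0, 1]")
  genes <- model$genes
  n <- length(genes)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n_hi <- max(1L, round(active_fraction * n))
  hi <- sample(genes, n_hi)
  vals <- stats::setNames(numeric(n), genes)
  vals[hi] <- stats::rlnorm(n_hi, meanlog = 7, sdlog = 0.4)
  lo <- setdiff(genes, hi)
  vals[lo] <- stats::rlnorm(length(lo), meanlog = 2, sdlog = 0.4)
  structure(list(values = vals, active = sort(hi), label = label),
            class = "expression_profile")
}

#' Write / read expression profiles as 2-column TSV
#' @param profile an `expression_profile`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_expression_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(gene_id = names(profile$values), value = profile$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param label profile label for the read object.
#' @export
read_expression_tsv <- function(path, label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(values = stats::setNames(df$value, df$gene_id),
                 active = character(0), label = label),
            class = "expression_profile")
}

#' Plant a flux bottleneck
#'
#' Caps the absolute flux of one reaction at `cap` (bounds intersected with
#' `[-cap, cap]`), the harness used to verify that capacity-limited steps
#' are recovered as overexpression targets.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to cap.
#' @param cap nonnegative cap on |flux|.
#' @return the modified model copy.
#' @export
plant_bottleneck <- function(model, reaction_id, cap) {
  if (cap < 0) stop("cap must be nonnegative")
  i <- reaction_index(model, reaction_id)
  model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], -cap)
  model$reactions$upper_bound[i] <- min(model$reactions$upper_bound[i], cap)
  model
}
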