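# Study orchestration: wild-type preconfiguration, knockout-response
# analysis, the increased-ATP-demand sweep with its sensitivity grid, and
# consistency checks between a reduced model and its reference.

#' Wild-type preconfiguration settings
#'
#' @param secretion_floor,secretion_ceiling basal secretion window applied
#'   to added free-diffusion exports, mmol/gDCW/h.
#' @param max_carbon species with this many carbons or more are not given
#'   diffusion exports.
#' @param exclude_elements species whose formula contains any of these
#'   elements are excluded (phosphate- and CoA-carrying metabolites by
#'   default, via P and S).
#' @param directionality data.frame(reaction, lb, ub): directionality
#'   assumptions imposed as bounds.
#' @param forced_secretion data.frame(reaction, lb): secretion floors for
#'   observed by-products.
#' @return a `tk_wildtype_config`.
#' @export
wildtype_config <- function(secretion_floor = 1e-6, secretion_ceiling = 1e-3,
                            max_carbon = 10,
                            exclude_elements = c("P", "S"),
                            directionality = NULL, forced_secretion = NULL) {
  structure(list(secretion_floor = secretion_floor,
                 secretion_ceiling = secretion_ceiling,
                 max_carbon = max_carbon,
                 exclude_elements = exclude_elements,
                 directionality = directionality,
                 forced_secretion = forced_secretion),
            class = "tk_wildtype_config")
}

#' Stress-study settings for the ATP-demand sweep
#'
#' @param atpm id of the ATP hydrolysis (maintenance) reaction whose lower
#'   bound models the extra ATP demand.
#' @param atp_synthase id of the ATP synthase reaction.
#' @param o2_exchange id of the oxygen exchange reaction (uptake negative).
#' @param glucose_exchange id of the glucose exchange reaction.
#' @param atpm_grid strictly increasing grid of minimally required ATP
#'   hydrolysis fluxes, mmol/gDCW/h.
#' @param growth_max cap on the specific growth rate.
#' @param o2_max,atps_max upper bounds on oxygen uptake and ATP synthase
#'   flux, mmol/gDCW/h.
#' @param growth_fraction stage-two growth retention when minimizing
#'   glucose uptake.
#' @return a `tk_stress_config`.
#' @export
stress_config <- function(atpm = "ATPM", atp_synthase = "ATPS",
                          o2_exchange = "EX_o2",
                          glucose_exchange = "EX_glc",
                          atpm_grid = seq(0, 60, by = 2),
                          growth_max = 0.73, o2_max = 40, atps_max = 70,
                          growth_fraction = 0.99) {
  if (any(diff(atpm_grid) <= 0)) stop("atpm_grid must be strictly increasing")
  structure(list(atpm = atpm, atp_synthase = atp_synthase,
                 o2_exchange = o2_exchange,
                 glucose_exchange = glucose_exchange,
                 atpm_grid = atpm_grid, growth_max = growth_max,
                 o2_max = o2_max, atps_max = atps_max,
                 growth_fraction = growth_fraction),
            class = "tk_stress_config")
}

count_element <- function(formula, element) {
  if (is.na(formula)) return(NA_integer_)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0L
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    if (el != element) next
    n <- gsub("[A-Za-z]", "", p)
    total <- total + if (nzchar(n)) as.integer(n) else 1L
  }
  total
}

#' Preconfigure a model for wild-type kinetic studies
#'
#' Adds free-diffusion exports for small carbon metabolites that lack a
#' transport route (fewer than `max_carbon` carbons, no excluded element in
#' the formula), bounded to the basal secretion window; applies forced
#' secretions and directionality assumptions referencing existing reactions
#' (absent ids are skipped with a warning); and builds the TFA problem with
#' the measurement table integrated through the compartment-resolved scheme.
#'
#' @param model a `tk_model`.
#' @param config a `tk_wildtype_config`.
#' @param measurements optional `tk_measurements`.
#' @return a TFA `tk_problem`; `problem$wildtype_report` lists the added
#'   diffusion reactions.
#' @export
preconfigure_wildtype <- function(model, config = wildtype_config(),
                                  measurements = NULL) {
  ex_comp <- model$compartments$id[model$compartments$extracellular]
  if (!length(ex_comp)) stop("model has no extracellular compartment")
  ex_comp <- ex_comp[1]
  ex_sp <- extracellular_species(model)
  # species already connected to the extracellular space through any reaction
  exported <- unique(unlist(lapply(model$stoich, function(s)
    if (any(names(s) %in% ex_sp)) names(s)), use.names = FALSE))
  added <- character(0)
  for (i in seq_len(nrow(model$species))) {
    sp <- model$species[i, ]
    if (sp$compartment %in% ex_comp) next
    if (sp$id %in% exported) next
    nC <- count_element(sp$formula, "C")
    if (is.na(nC)) {
      warning("species without formula skipped by diffusion rule: ", sp$id)
      next
    }
    if (nC < 1L || nC >= config$max_carbon) next
    if (any(vapply(config$exclude_elements,
                   function(el) count_element(sp$formula, el) > 0,
                   logical(1)))) next
    base <- sub("_[a-z]+$", "", sp$id)
    ex_id <- paste0(base, "_", ex_comp)
    if (!ex_id %in% model$species$id) {
      model$species <- rbind(model$species,
                             data.frame(id = ex_id, name = sp$name,
                                        compartment = ex_comp,
                                        whole_cell_group = NA_character_,
                                        formula = sp$formula))
      exr <- paste0("EX_", base)
      model$reactions <- rbind(model$reactions, data.frame(
        id = exr, name = exr, lb = 0, ub = 100, drG0 = NA_real_,
        drG0_err = 0, subsystem = NA_character_, is_transport = FALSE,
        is_exchange = TRUE, gene_rule = NA_character_))
      model$stoich[[exr]] <- stats::setNames(-1, ex_id)
    }
    diff_id <- paste0("DIFF_", sp$id)
    model$reactions <- rbind(model$reactions, data.frame(
      id = diff_id, name = paste("free diffusion of", sp$id),
      lb = config$secretion_floor, ub = config$secretion_ceiling,
      drG0 = NA_real_, drG0_err = 0, subsystem = NA_character_,
      is_transport = TRUE, is_exchange = FALSE, gene_rule = NA_character_))
    model$stoich[[diff_id]] <- stats::setNames(c(-1, 1), c(sp$id, ex_id))
    added <- c(added, diff_id)
  }
  rownames(model$reactions) <- rownames(model$species) <- NULL
  apply_assumption <- function(df, what) {
    if (is.null(df)) return(invisible(NULL))
    for (k in seq_len(nrow(df))) {
      if (!df$reaction[k] %in% model$reactions$id) {
        warning(what, " references absent reaction, skipped: ",
                df$reaction[k])
        next
      }
      model <<- set_reaction_bounds(model, df$reaction[k],
                                    lb = if ("lb" %in% names(df)) df$lb[k],
                                    ub = if ("ub" %in% names(df)) df$ub[k])
    }
  }
  apply_assumption(config$directionality, "directionality assumption")
  apply_assumption(config$forced_secretion, "forced secretion")
  validate_model(model)
  problem <- build_tfa(model, measurements = measurements)
  problem$wildtype_report <- added
  problem
}

#' Knockout-response study over an ensemble
#'
#' Summarizes the distributions of flux control coefficients of the study
#' targets (typically glucose uptake and growth) with respect to the
#' knocked-out enzymes and reports the fraction of ensemble members whose
#' control-coefficient signs agree with the experimentally observed
#' responses, per target and overall.
#'
#' @param ensemble a `tk_ensemble` built at the wild-type reference.
#' @param enzymes enzyme (reaction) ids that were knocked out.
#' @param targets flux target ids (default the glucose uptake-like and
#'   biomass reactions present in the ensemble).
#' @param reference_signs expected control-coefficient sign for each
#'   (target, enzyme) pair: either a single sign recycled to all pairs, or
#'   data.frame(target, enzyme, sign). Empty means every member is
#'   consistent.
#' @return list with `summary` (mean and 25/75 percentiles per pair),
#'   `fraction_all`, and `fraction_by_target`.
#' @export
knockout_response_study <- function(ensemble, enzymes, targets,
                                    reference_signs = 1) {
  kin <- dimnames(ensemble$CJ)[[1]]
  missing <- setdiff(c(enzymes, targets), kin)
  if (length(missing))
    stop("not in the kinetic network: ", paste(missing, collapse = ", "))
  spec <- if (is.data.frame(reference_signs)) reference_signs
          else expand.grid(target = targets, enzyme = enzymes,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.data.frame(reference_signs)) spec$sign <- reference_signs
  smry <- ensemble_summary(ensemble, targets = targets, enzymes = enzymes)
  ok_all <- rep(TRUE, ensemble$n)
  by_target <- stats::setNames(vector("list", length(targets)), targets)
  for (tg in targets) by_target[[tg]] <- rep(TRUE, ensemble$n)
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    vals <- ensemble$CJ[r$target, r$enzyme, ]
    ok <- sign(vals) == r$sign
    ok_all <- ok_all & ok
    by_target[[r$target]] <- by_target[[r$target]] & ok
  }
  list(summary = smry,
       fraction_all = mean(ok_all),
       fraction_by_target = vapply(by_target, mean, numeric(1)))
}

#' ATP-demand sweep
#'
#' For each grid value of the minimally required ATP hydrolysis flux, caps
#' growth, oxygen uptake and ATP synthase per the configuration, maximizes
#' growth, then minimizes the glucose uptake at `growth_fraction` of that
#' optimum, and records the resulting profile (growth, minimal glucose
#' uptake, ATP synthase flux, oxygen uptake).
#'
#' @param problem a `tk_problem` (TFA for the thermodynamically constrained
#'   profile; FBA also works).
#' @param config a `tk_stress_config`.
#' @return a `tk_study_profile` data.frame with one row per grid point;
#'   infeasible points carry `NA` and `feasible = FALSE`.
#' @export
atp_demand_sweep <- function(problem, config = stress_config()) {
  ids <- problem$model$reactions$id
  need <- c(config$atpm, config$atp_synthase, config$o2_exchange,
            config$glucose_exchange)
  missing <- setdiff(need, ids)
  if (length(missing)) stop("config references absent reaction(s): ",
                            paste(missing, collapse = ", "))
  base <- problem_clone(problem)
  apply_flux_bounds(base, config$o2_exchange, lb = -config$o2_max)
  apply_flux_bounds(base, config$atp_synthase, ub = config$atps_max)
  apply_flux_bounds(base, problem$model$objective, ub = config$growth_max)
  # glucose uptake left unconstrained (within the exchange lower bound)
  stage1 <- lapply(config$atpm_grid, function(g) {
    p <- problem_clone(base)
    apply_flux_bounds(p, config$atpm, lb = g)
    lp_objective(p$lp, objective_coefs(p, NULL), "max")
    p
  })
  res1 <- lp_solve_batch(lapply(stage1, `[[`, "lp"))
  stage2 <- vector("list", length(stage1))
  for (i in seq_along(stage1)) {
    if (res1[[i]]$status != "optimal") next
    p <- stage1[[i]]
    lp_add_row(p$lp, objective_coefs(p, NULL),
               lb = config$growth_fraction * res1[[i]]$objective,
               name = "growth_floor")
    # glucose uptake is -EX_glc; minimizing uptake = maximizing EX_glc
    lp_objective(p$lp, flux_coefs(p, config$glucose_exchange), "max")
    stage2[[i]] <- p
  }
  live <- !vapply(stage2, is.null, logical(1))
  res2 <- vector("list", length(stage2))
  if (any(live)) res2[live] <- lp_solve_batch(lapply(stage2[live], `[[`, "lp"))
  rows <- lapply(seq_along(config$atpm_grid), function(i) {
    out <- data.frame(atpm = config$atpm_grid[i], feasible = FALSE,
                      growth = NA_real_, glucose_uptake = NA_real_,
                      atp_synthase = NA_real_, o2_uptake = NA_real_)
    if (!live[i] || res2[[i]]$status != "optimal") return(out)
    sol <- as_solution(stage2[[i]], res2[[i]])
    out$feasible <- TRUE
    out$growth <- sol$fluxes[problem$model$objective]
    out$glucose_uptake <- -sol$fluxes[config$glucose_exchange]
    out$atp_synthase <- sol$fluxes[config$atp_synthase]
    out$o2_uptake <- -sol$fluxes[config$o2_exchange]
    out
  })
  profile <- do.call(rbind, rows)
  class(profile) <- c("tk_study_profile", class(profile))
  profile
}

#' Sensitivity of the sweep peak to oxygen and ATP synthase caps
#'
#' Runs [atp_demand_sweep()] for every combination of maximal oxygen uptake
#' and maximal ATP synthase flux and extracts the peak of the minimal
#' glucose uptake profile and its location on the ATP hydrolysis grid.
#'
#' @param problem a `tk_problem`.
#' @param o2_grid,atps_grid cap grids, mmol/gDCW/h.
#' @param config base `tk_stress_config` (its `o2_max`/`atps_max` are
#'   overridden cell by cell).
#' @return data.frame(o2_max, atps_max, peak_glucose_uptake, atpm_at_peak).
#' @export
sensitivity_grid <- function(problem, o2_grid, atps_grid,
                             config = stress_config()) {
  stopifnot(length(o2_grid) >= 1, length(atps_grid) >= 1)
  rows <- list()
  for (o2 in o2_grid) for (at in atps_grid) {
    cfg <- config; cfg$o2_max <- o2; cfg$atps_max <- at
    prof <- atp_demand_sweep(problem, cfg)
    ok <- prof$feasible
    if (!any(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        o2_max = o2, atps_max = at, peak_glucose_uptake = NA_real_,
        atpm_at_peak = NA_real_)
      next
    }
    i <- which.max(ifelse(ok, prof$glucose_uptake, -Inf))
    rows[[length(rows) + 1L]] <- data.frame(
      o2_max = o2, atps_max = at,
      peak_glucose_uptake = prof$glucose_uptake[i],
      atpm_at_peak = prof$atpm[i])
  }
  do.call(rbind, rows)
}

#' Consistency checks between a reduced model and its reference
#'
#' Compares maximal growth at a fixed substrate uptake, reaction
#' essentiality over the shared reactions, and (T)VA flux ranges, flagging
#' reactions that are strictly less flexible in the reduced model.
#'
#' @param reduced,reference `tk_model`s.
#' @param shared optional shared reaction ids (default the id
#'   intersection).
#' @param uptake optional list(reaction, value) fixing an uptake flux in
#'   both models.
#' @param mode `"tfa"` or `"fba"`.
#' @param essentiality_threshold fraction of wild-type growth below which a
#'   knockout is called essential.
#' @return a `tk_consistency_report`.
#' @export
consistency_checks <- function(reduced, reference, shared = NULL,
                               uptake = NULL, mode = c("tfa", "fba"),
                               essentiality_threshold = 1e-3) {
  mode <- match.arg(mode)
  shared <- shared %||% intersect(reduced$reactions$id,
                                  reference$reactions$id)
  if (!length(shared)) stop("no shared reactions to compare")
  mk <- function(model) {
    p <- if (mode == "fba") build_fba(model) else build_tfa(model)
    if (!is.null(uptake))
      apply_flux_bounds(p, uptake$reaction, lb = uptake$value,
                        ub = uptake$value)
    p
  }
  pr <- mk(reduced); pf <- mk(reference)
  g_red <- solve_problem(pr, NULL, "max")
  g_ref <- solve_problem(pf, NULL, "max")

  essential_set <- function(problem, wt) {
    probs <- lapply(shared, function(id) {
      p <- problem_clone(problem)
      if (mode == "fba") {
        lp_set_bounds(p$lp, paste0("V_", id), lb = 0, ub = 0)
      } else {
        lp_set_bounds(p$lp, paste0("F_", id), lb = 0, ub = 0)
        lp_set_bounds(p$lp, paste0("R_", id), lb = 0, ub = 0)
        idx <- which(vapply(p$lp$rows, function(r)
          identical(r$name, paste0("net_", id)), logical(1)))
        if (length(idx)) {
          p$lp$rows[[idx]]$lb <- 0; p$lp$rows[[idx]]$ub <- 0
        }
      }
      lp_objective(p$lp, objective_coefs(p, NULL), "max")
      p$lp
    })
    res <- lp_solve_batch(probs)
    growth <- vapply(res, function(r)
      if (r$status == "optimal") r$objective else 0, numeric(1))
    shared[growth < essentiality_threshold * wt]
  }
  ess_red <- essential_set(pr, g_red$objective)
  ess_ref <- essential_set(pf, g_ref$objective)

  va_red <- variability(pr, fluxes = shared)
  va_ref <- variability(pf, fluxes = shared)
  tol <- 1e-6
  less_flexible <- shared[(va_red$min > va_ref$min + tol) |
                            (va_red$max < va_ref$max - tol)]
  structure(list(growth_reduced = g_red$objective,
                 growth_reference = g_ref$objective,
                 essential_both = intersect(ess_red, ess_ref),
                 essential_reduced_only = setdiff(ess_red, ess_ref),
                 essential_reference_only = setdiff(ess_ref, ess_red),
                 variability_reduced = va_red,
                 variability_reference = va_ref,
                 less_flexible = less_flexible,
                 shared = shared),
            class = "tk_consistency_report")
}

#' @export
print.tk_consistency_report <- function(x, ...) {
  cat("<tk_consistency_report>\n")
  cat(sprintf("  max growth: reduced %.4f vs reference %.4f\n",
              x$growth_reduced, x$growth_reference))
  cat(sprintf("  essential in both: %d; reduced only: %d; reference only: %d\n",
              length(x$essential_both), length(x$essential_reduced_only),
              length(x$essential_reference_only)))
  cat(sprintf("  less flexible reactions in reduced: %d of %d shared\n",
              length(x$less_flexible), length(x$shared)))
  invisible(x)
}

#' Stress-condition control study
#'
#' Ranks enzymes by their mean control over growth at the stress reference
#' and correlates growth control with the concentration control of
#' cytosolic ATP over the top-|control| enzymes.
#'
#' @param ensemble a `tk_ensemble` built at the stress reference state.
#' @param growth id of the growth flux.
#' @param atp_species id of the cytosolic ATP species.
#' @param top_n number of top-|growth control| enzymes entering the
#'   correlation.
#' @return list with `table` (enzyme, growth_control, atp_control,
#'   sign_consistent, in ranked order) and `pearson`.
#' @export
stress_control_study <- function(ensemble, growth = "BIOMASS",
                                 atp_species = "atp_c", top_n = 10) {
  if (!growth %in% dimnames(ensemble$CJ)[[1]])
    stop("growth flux not in the kinetic network: ", growth)
  if (!atp_species %in% dimnames(ensemble$CX)[[1]])
    stop("ATP species not in the kinetic network: ", atp_species)
  enzymes <- dimnames(ensemble$CJ)[[2]]
  gc <- vapply(enzymes, function(e) mean(ensemble$CJ[growth, e, ]),
               numeric(1))
  ac <- vapply(enzymes, function(e) mean(ensemble$CX[atp_species, e, ]),
               numeric(1))
  ord <- order(-abs(gc))
  tab <- data.frame(enzyme = enzymes[ord], growth_control = gc[ord],
                    atp_control = ac[ord],
                    sign_consistent = sign(gc[ord]) == sign(ac[ord]),
                    row.names = NULL)
  top <- utils::head(tab, top_n)
  pearson <- stats::cor(top$growth_control, top$atp_control,
                        method = "pearson")
  list(table = tab, pearson = pearson)
}
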