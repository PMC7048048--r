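# FBA and thermodynamics-based flux analysis (TFA).
#
# Both analyses share one problem wrapper (tk_problem). FBA is the LP
# degeneration: one net-flux variable per reaction and steady-state mass
# balances. TFA splits fluxes into forward/backward parts, adds direction
# binaries z+/z-, log-concentration variables u = ln C (mol/L) and the Gibbs
# energy of each annotated reaction,
#     DrG'_j = DrG'0_j + RT sum_i s_ij u_i,
# and couples flux direction to the sign of DrG': a reaction can carry flux
# in a direction only if DrG' is strictly negative in that direction.

DEFAULT_CONC_LB <- 1e-6   # mol/L, physiological lower bound (1 uM)
DEFAULT_CONC_UB <- 5e-2   # mol/L, physiological upper bound (50 mM)

flux_big_m <- function(model) {
  b <- c(abs(model$reactions$lb), abs(model$reactions$ub))
  b <- b[is.finite(b)]
  100 + if (length(b)) max(b) else 0
}

#' Build a flux balance analysis problem
#'
#' @param model a valid `tk_model`.
#' @param extra_bounds optional data.frame(id, lb, ub) overriding net-flux
#'   bounds.
#' @return a `tk_problem` of type `"fba"`.
#' @export
build_fba <- function(model, extra_bounds = NULL) {
  validate_model(model)
  rx <- model$reactions
  if (!is.null(extra_bounds)) {
    model <- set_reaction_bounds(model, extra_bounds$id,
                                 extra_bounds$lb, extra_bounds$ub)
    rx <- model$reactions
  }
  if (any(rx$lb > rx$ub))
    stop("infeasible bounds (lb > ub) for: ",
         paste(rx$id[rx$lb > rx$ub], collapse = ", "))
  lp <- new_lp(paste0(model$name, "_fba"))
  lp_add_vars(lp, paste0("V_", rx$id), lb = rx$lb, ub = rx$ub)
  N <- stoichiometric_matrix(model)
  for (s in rownames(N)) {
    row <- N[s, ]
    nz <- row != 0
    if (!any(nz)) next
    lp_add_row(lp, stats::setNames(row[nz], paste0("V_", colnames(N)[nz])),
               lb = 0, ub = 0, name = paste0("mb_", s))
  }
  problem <- structure(list(lp = lp, model = model, type = "fba",
                            annotated = character(0),
                            conc_lb = NA_real_, conc_ub = NA_real_,
                            report = NULL),
                       class = "tk_problem")
  problem
}

#' Build a thermodynamics-based flux analysis problem
#'
#' Adds to the FBA constraint set: forward/backward flux split with direction
#' binaries, log-concentration variables bounded in `[ln conc_lb, ln conc_ub]`,
#' Gibbs-energy variables for every thermodynamically annotated reaction and
#' big-M coupling so flux in a direction requires strictly negative DrG' in
#' that direction (margin `eps_g`). Reactions without a DrG'0 annotation get
#' flux-only treatment. Whole-cell metabolite measurements are integrated
#' through the compartment-resolved scheme of [integrate_measurements()];
#' flux measurements tighten net-flux bounds.
#'
#' @param model a valid `tk_model` with at least one annotated reaction.
#' @param measurements optional `tk_measurements`.
#' @param compartment_constraints use the volume-fraction-aware i+2 scheme for
#'   whole-cell concentration measurements (default). When `FALSE`, measured
#'   bounds are applied identically to every member species (the classic
#'   shared-concentration assumption).
#' @param conc_lb,conc_ub physiological concentration bounds, mol/L.
#' @param eps_g strictness margin on DrG', kJ/mol.
#' @param use_drg_err widen the DrG'0 of each reaction by its estimation
#'   error (default) instead of ignoring the uncertainty.
#' @param exclude_species species whose `u` never enters DrG' sums (water and
#'   protons by convention; their activity is folded into DrG'0).
#' @return a `tk_problem` of type `"tfa"`.
#' @export
build_tfa <- function(model, measurements = NULL,
                      compartment_constraints = TRUE,
                      conc_lb = DEFAULT_CONC_LB, conc_ub = DEFAULT_CONC_UB,
                      eps_g = 1e-6, use_drg_err = TRUE,
                      exclude_species = grep("^(h2o|h)_", model$species$id,
                                             value = TRUE)) {
  validate_model(model)
  rx <- model$reactions
  if (any(rx$lb > rx$ub))
    stop("infeasible bounds (lb > ub) for: ",
         paste(rx$id[rx$lb > rx$ub], collapse = ", "))
  annotated <- rx$id[!is.na(rx$drG0)]
  if (!length(annotated))
    stop("TFA requires at least one thermodynamically annotated reaction")
  rt <- model_rt(model)
  M <- flux_big_m(model)
  lp <- new_lp(paste0(model$name, "_tfa"))

  # flux split
  lp_add_vars(lp, paste0("F_", rx$id), lb = 0, ub = pmax(0, rx$ub))
  lp_add_vars(lp, paste0("R_", rx$id), lb = 0, ub = pmax(0, -rx$lb))
  for (i in seq_len(nrow(rx)))
    lp_add_row(lp, stats::setNames(c(1, -1), paste0(c("F_", "R_"), rx$id[i])),
               lb = rx$lb[i], ub = rx$ub[i], name = paste0("net_", rx$id[i]))

  # log concentrations
  lp_add_vars(lp, paste0("U_", model$species$id),
              lb = log(conc_lb), ub = log(conc_ub))

  # mass balances
  N <- stoichiometric_matrix(model)
  for (s in rownames(N)) {
    row <- N[s, ]
    nz <- row != 0
    if (!any(nz)) next
    lp_add_row(lp, stats::setNames(c(row[nz], -row[nz]),
                                   c(paste0("F_", colnames(N)[nz]),
                                     paste0("R_", colnames(N)[nz]))),
               lb = 0, ub = 0, name = paste0("mb_", s))
  }

  # thermodynamic block
  for (id in annotated) {
    i <- match(id, rx$id)
    s <- model$stoich[[id]]
    s <- s[!(names(s) %in% exclude_species)]
    err <- if (use_drg_err) rx$drG0_err[i] else 0
    mg <- abs(rx$drG0[i]) + err +
      rt * (log(conc_ub) - log(conc_lb)) * sum(abs(s)) + 1
    lp_add_vars(lp, paste0("G_", id), lb = -Inf, ub = Inf)
    lp_add_vars(lp, paste0(c("ZF_", "ZR_"), id), type = "B")
    # G - RT sum s u  in  drG0 +/- err
    coefs <- c(stats::setNames(1, paste0("G_", id)),
               stats::setNames(-rt * s, paste0("U_", names(s))))
    lp_add_row(lp, coefs, lb = rx$drG0[i] - err, ub = rx$drG0[i] + err,
               name = paste0("gdef_", id))
    lp_add_row(lp, stats::setNames(c(1, 1), paste0(c("ZF_", "ZR_"), id)),
               ub = 1, name = paste0("zsos_", id))
    lp_add_row(lp, stats::setNames(c(1, -M), c(paste0("F_", id),
                                               paste0("ZF_", id))),
               ub = 0, name = paste0("fcap_", id))
    lp_add_row(lp, stats::setNames(c(1, -M), c(paste0("R_", id),
                                               paste0("ZR_", id))),
               ub = 0, name = paste0("rcap_", id))
    # forward flux needs G <= -eps_g:  G + MG*ZF <= MG - eps_g
    lp_add_row(lp, stats::setNames(c(1, mg), c(paste0("G_", id),
                                               paste0("ZF_", id))),
               ub = mg - eps_g, name = paste0("gfwd_", id))
    # backward flux needs G >= eps_g:  G - MG*ZR >= -MG + eps_g
    lp_add_row(lp, stats::setNames(c(1, -mg), c(paste0("G_", id),
                                                paste0("ZR_", id))),
               lb = -mg + eps_g, name = paste0("gbwd_", id))
  }

  problem <- structure(list(lp = lp, model = model, type = "tfa",
                            annotated = annotated,
                            conc_lb = conc_lb, conc_ub = conc_ub,
                            report = NULL),
                       class = "tk_problem")
  if (!is.null(measurements))
    problem <- integrate_measurements(problem, measurements,
                                      compartmentalized = compartment_constraints)
  problem
}

#' @export
print.tk_problem <- function(x, ...) {
  cat(sprintf("<tk_problem (%s) on '%s': %d reactions, %d annotated>\n",
              toupper(x$type), x$model$name, nrow(x$model$reactions),
              length(x$annotated)))
  print(x$lp)
  invisible(x)
}

#' Deep-copy a problem (the embedded LP is mutable)
#' @param problem a `tk_problem`.
#' @export
problem_clone <- function(problem) {
  problem$lp <- lp_clone(problem$lp)
  problem
}

# net-flux objective/constraint coefficients for a reaction
flux_coefs <- function(problem, ids, weights = 1) {
  weights <- rep_len(weights, length(ids))
  if (problem$type == "fba")
    stats::setNames(weights, paste0("V_", ids))
  else
    stats::setNames(c(weights, -weights), paste0(c("F_", "R_"), rep(ids, 2)))
}

objective_coefs <- function(problem, objective) {
  if (is.null(objective)) objective <- problem$model$objective
  if (is.character(objective))
    objective <- list(type = "flux", id = objective)
  switch(objective$type,
         flux = flux_coefs(problem, objective$id),
         log_concentration = {
           if (problem$type != "tfa")
             stop("concentration objectives require a TFA problem")
           stats::setNames(1, paste0("U_", objective$id))
         },
         total_flux = {
           if (problem$type != "tfa")
             stop("total-flux objectives require a TFA problem")
           ids <- problem$model$reactions$id
           stats::setNames(rep(1, 2 * length(ids)),
                           paste0(c("F_", "R_"), rep(ids, 2)))
         },
         stop("unknown objective type: ", objective$type))
}

#' Solve an FBA/TFA problem
#'
#' @param problem a `tk_problem`.
#' @param objective a reaction id (net flux), or
#'   `list(type = "flux"|"log_concentration"|"total_flux", id = )`; default
#'   the model's biomass reaction.
#' @param sense `"max"` or `"min"`.
#' @return a `tk_solution` with `status`, `objective`, net `fluxes`,
#'   and for TFA problems log-concentrations `u`, concentrations `conc`
#'   (mol/L), Gibbs energies `drG` (kJ/mol) and the directionality
#'   assignment. Infeasibility is a status, not an error.
#' @export
solve_problem <- function(problem, objective = NULL,
                          sense = c("max", "min")) {
  sense <- match.arg(sense)
  res <- lp_solve(problem$lp,
                  objectives = list(list(coefs = objective_coefs(problem,
                                                                 objective),
                                         sense = sense)))[[1]]
  as_solution(problem, res)
}

as_solution <- function(problem, res) {
  model <- problem$model
  out <- list(status = res$status, objective = res$objective,
              fluxes = NULL, u = NULL, conc = NULL, drG = NULL,
              directions = NULL, model_name = model$name,
              type = problem$type)
  if (!is.null(res$x)) {
    ids <- model$reactions$id
    if (problem$type == "fba") {
      out$fluxes <- stats::setNames(res$x[paste0("V_", ids)], ids)
    } else {
      out$fluxes <- stats::setNames(
        res$x[paste0("F_", ids)] - res$x[paste0("R_", ids)], ids)
      out$u <- stats::setNames(res$x[paste0("U_", model$species$id)],
                               model$species$id)
      out$conc <- exp(out$u)
      gn <- paste0("G_", problem$annotated)
      out$drG <- stats::setNames(res$x[gn], problem$annotated)
    }
    out$directions <- sign(round(out$fluxes, 9))
  }
  structure(out, class = "tk_solution")
}

#' @export
print.tk_solution <- function(x, ...) {
  cat(sprintf("<tk_solution (%s): %s, objective %s>\n", toupper(x$type),
              x$status, format(x$objective, digits = 6)))
  invisible(x)
}

#' @export
coef.tk_solution <- function(object, ...) object$fluxes

#' Flux (and concentration) variability analysis
#'
#' Computes `min` and `max` of net fluxes and/or log-concentrations by two
#' optimizations per variable, optionally after constraining the model
#' objective to a fraction of its optimum. On a TFA problem this is
#' thermodynamics-based variability analysis (TVA); on an FBA problem it is
#' classic FVA.
#'
#' @param problem a `tk_problem`.
#' @param fluxes reaction ids to scan (default all).
#' @param concentrations species ids to scan (TFA only).
#' @param fix_objective_fraction in `[0,1]`; when non-`NULL`, first maximizes
#'   the model objective and adds `objective >= fraction * optimum`.
#' @param tol flux magnitude below which a direction is not counted.
#' @return data.frame(variable, type, min, max, bidirectional).
#' @export
variability <- function(problem, fluxes = problem$model$reactions$id,
                        concentrations = character(0),
                        fix_objective_fraction = NULL, tol = 1e-9) {
  problem <- problem_clone(problem)
  if (!is.null(fix_objective_fraction)) {
    ref <- solve_problem(problem, NULL, "max")
    if (ref$status != "optimal")
      stop("problem ", ref$status, "; cannot fix objective at fraction ",
           fix_objective_fraction)
    lp_add_row(problem$lp, objective_coefs(problem, NULL),
               lb = fix_objective_fraction * ref$objective,
               name = "fix_objective")
  }
  if (problem$type != "tfa" && length(concentrations))
    stop("concentration variability requires a TFA problem")
  objs <- list(); keys <- character(0)
  for (id in fluxes) {
    cf <- flux_coefs(problem, id)
    objs <- c(objs, list(list(coefs = cf, sense = "min"),
                         list(coefs = cf, sense = "max")))
    keys <- c(keys, id)
  }
  for (id in concentrations) {
    cf <- stats::setNames(1, paste0("U_", id))
    objs <- c(objs, list(list(coefs = cf, sense = "min"),
                         list(coefs = cf, sense = "max")))
    keys <- c(keys, id)
  }
  res <- lp_solve(problem$lp, objectives = objs)
  bad <- vapply(res, function(r) r$status != "optimal", logical(1))
  if (any(bad))
    stop("variability subproblem not optimal (", res[[which(bad)[1]]]$status,
         ")")
  mins <- vapply(res[seq(1, length(res), 2)], `[[`, numeric(1), "objective")
  maxs <- vapply(res[seq(2, length(res), 2)], `[[`, numeric(1), "objective")
  type <- c(rep("flux", length(fluxes)),
            rep("log_concentration", length(concentrations)))
  data.frame(variable = keys, type = type, min = mins, max = maxs,
             bidirectional = type == "flux" & mins < -tol & maxs > tol)
}

#' Fix leftover bidirectional reactions by minimizing total flux
#'
#' Solves `min sum_j (F_j + R_j)` subject to the growth objective attaining at
#' least `growth_fraction` of a reference growth, and reports the resulting
#' directionality of every reaction. This is the standard device to settle
#' reactions that variability analysis leaves bidirectional.
#'
#' @param problem a TFA `tk_problem`.
#' @param growth_fraction fraction of the reference growth to retain.
#' @param reference_growth optional; computed by maximizing the objective when
#'   missing.
#' @return a `tk_solution`; element `fixed_directions` holds
#'   data.frame(reaction, direction).
#' @export
fix_directionalities_by_min_total_flux <- function(problem,
                                                   growth_fraction = 0.99,
                                                   reference_growth = NULL) {
  if (problem$type != "tfa")
    stop("directionality fixing by total flux requires a TFA problem")
  if (is.null(reference_growth)) {
    ref <- solve_problem(problem, NULL, "max")
    if (ref$status != "optimal") stop("reference growth solve: ", ref$status)
    reference_growth <- ref$objective
  }
  problem <- problem_clone(problem)
  lp_add_row(problem$lp, objective_coefs(problem, NULL),
             lb = growth_fraction * reference_growth, name = "growth_floor")
  sol <- solve_problem(problem, list(type = "total_flux"), "min")
  if (sol$status != "optimal")
    stop("total-flux minimization ", sol$status, " at growth fraction ",
         growth_fraction)
  sol$fixed_directions <- data.frame(reaction = names(sol$fluxes),
                                     direction = unname(sol$directions))
  sol
}

#' Knock out reactions or genes and re-solve
#'
#' Reaction knockouts force net flux to zero. Gene knockouts evaluate each
#' reaction's boolean gene rule with the knocked genes set to `FALSE` and
#' disable reactions whose rule turns `FALSE`; reactions without a rule are
#' untouched. Essentiality compares the re-solved growth to the wild-type
#' optimum.
#'
#' @param problem a `tk_problem`.
#' @param ids reaction or gene ids.
#' @param type `"reaction"` or `"gene"`.
#' @param wildtype_growth reference growth; computed if missing.
#' @param threshold essentiality threshold as a fraction of wild-type growth.
#' @return a `tk_solution` with elements `essential`, `growth`,
#'   `disabled_reactions`.
#' @export
knockout <- function(problem, ids, type = c("reaction", "gene"),
                     wildtype_growth = NULL, threshold = 1e-3) {
  type <- match.arg(type)
  model <- problem$model
  if (type == "reaction") {
    unknown <- setdiff(ids, model$reactions$id)
    if (length(unknown)) stop("unknown reaction(s): ",
                              paste(unknown, collapse = ", "))
    disabled <- ids
  } else {
    rules <- model$reactions$gene_rule
    if (all(is.na(rules)))
      stop("gene knockouts require gene rules in the model")
    all_genes <- unique(unlist(regmatches(rules,
                                          gregexpr("[A-Za-z0-9_.]+", rules))))
    all_genes <- setdiff(all_genes, c("and", "or", "AND", "OR"))
    unknown <- setdiff(ids, all_genes)
    if (length(unknown)) stop("unknown gene(s): ",
                              paste(unknown, collapse = ", "))
    disabled <- model$reactions$id[vapply(seq_along(rules), function(i) {
      r <- rules[i]
      if (is.na(r)) return(FALSE)
      !eval_gene_rule(r, ids)
    }, logical(1))]
  }
  if (is.null(wildtype_growth)) {
    wt <- solve_problem(problem, NULL, "max")
    if (wt$status != "optimal") stop("wild-type solve: ", wt$status)
    wildtype_growth <- wt$objective
  }
  problem <- problem_clone(problem)
  for (id in disabled) {
    if (problem$type == "fba") {
      lp_set_bounds(problem$lp, paste0("V_", id), lb = 0, ub = 0)
    } else {
      lp_set_bounds(problem$lp, paste0("F_", id), lb = 0, ub = 0)
      lp_set_bounds(problem$lp, paste0("R_", id), lb = 0, ub = 0)
      idx <- which(vapply(problem$lp$rows,
                          function(r) identical(r$name, paste0("net_", id)),
                          logical(1)))
      if (length(idx)) {
        problem$lp$rows[[idx]]$lb <- 0
        problem$lp$rows[[idx]]$ub <- 0
      }
    }
  }
  sol <- solve_problem(problem, NULL, "max")
  sol$growth <- if (sol$status == "optimal") sol$objective else 0
  sol$essential <- sol$growth < threshold * wildtype_growth
  sol$disabled_reactions <- disabled
  sol
}

# evaluate "g1 and (g2 or g3)" with genes in `off` set FALSE, others TRUE
eval_gene_rule <- function(rule, off) {
  toks <- gsub("\\bAND\\b", "&", gsub("\\bOR\\b", "|", rule,
                                      ignore.case = FALSE))
  toks <- gsub("\\band\\b", "&", gsub("\\bor\\b", "|", toks))
  genes <- setdiff(unique(regmatches(toks,
                                     gregexpr("[A-Za-z0-9_.]+", toks))[[1]]),
                   c("&", "|"))
  env <- new.env(parent = baseenv())
  for (g in genes) assign(g, !(g %in% off), envir = env)
  isTRUE(eval(parse(text = toks), envir = env))
}
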