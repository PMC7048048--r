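# Metabolic-task-driven MILP gap-filling.
#
# A task (growth floor, uptake window, optional concentration targets) that
# is infeasible on a host model is repaired by searching a candidate pool
# from a donor model for a minimal set of additions: every candidate k gets
# a binary y_k gating its flux bounds, and sum(y) is minimized subject to
# (T)FA feasibility of the composite. Alternate minima are enumerated with
# integer cuts.

#' Define a gap-filling task
#'
#' @param growth_min growth (objective flux) the repaired model must attain.
#' @param uptake optional list(reaction, lb, ub) constraining an uptake flux.
#' @param concentrations optional data.frame(species, lb, ub) in mol/L;
#'   expressible only in TFA mode (log-concentration variables are needed).
#' @return a `tk_gapfill_task`.
#' @export
gapfill_task <- function(growth_min = NULL, uptake = NULL,
                         concentrations = NULL) {
  structure(list(growth_min = growth_min, uptake = uptake,
                 concentrations = concentrations),
            class = "tk_gapfill_task")
}

# canonical key of a stoichiometry up to positive scaling (orientation is
# preserved: a reversed copy of an irreversible reaction is a new capability)
stoich_key <- function(s) {
  s <- s[order(names(s))]
  s <- s / abs(s[[1]])
  paste(names(s), sprintf("%.10g", s), collapse = "|")
}

#' Append donor reactions to a host model
#'
#' Builds the composite model used for gap-filling: donor reactions that
#' duplicate a host reaction (identical stoichiometry up to positive
#' scaling) are dropped, as are explicitly excluded ids. Donor species
#' must live in the host's species namespace; donor species absent from the
#' host are added. A donor species whose compartment conflicts with the
#' host's is an error.
#'
#' @param host,donor `tk_model`s sharing a species namespace.
#' @param exclude donor reaction ids to drop (e.g. reactions experimentally
#'   shown to be absent from the organism).
#' @return list with `model` (composite) and `candidates` (added ids).
#' @export
build_composite <- function(host, donor, exclude = character(0)) {
  conflicts <- character(0)
  for (i in seq_len(nrow(donor$species))) {
    ds <- donor$species[i, ]
    hs <- host$species[host$species$id == ds$id, ]
    if (nrow(hs) && hs$compartment != ds$compartment)
      conflicts <- c(conflicts, ds$id)
  }
  if (length(conflicts))
    stop("unmappable donor species (compartment conflict): ",
         paste(conflicts, collapse = ", "))
  host_keys <- vapply(host$stoich, stoich_key, character(1))
  cand <- character(0)
  model <- host
  for (id in setdiff(donor$reactions$id, exclude)) {
    if (stoich_key(donor$stoich[[id]]) %in% host_keys) next
    new_id <- if (id %in% model$reactions$id) paste0(id, "_donor") else id
    row <- donor$reactions[donor$reactions$id == id, ]
    row$id <- new_id
    model$reactions <- rbind(model$reactions, row)
    model$stoich[[new_id]] <- donor$stoich[[id]]
    cand <- c(cand, new_id)
  }
  new_sp <- setdiff(unique(unlist(lapply(model$stoich[cand], names),
                                  use.names = FALSE)),
                    model$species$id)
  if (length(new_sp))
    model$species <- rbind(model$species,
                           donor$species[match(new_sp, donor$species$id), ])
  rownames(model$reactions) <- rownames(model$species) <- NULL
  validate_model(model)
  list(model = model, candidates = cand)
}

apply_task <- function(problem, task) {
  if (!is.null(task$growth_min))
    lp_add_row(problem$lp, objective_coefs(problem, NULL),
               lb = task$growth_min, name = "task_growth")
  if (!is.null(task$uptake))
    apply_flux_bounds(problem, task$uptake$reaction,
                      task$uptake$lb, task$uptake$ub)
  if (!is.null(task$concentrations)) {
    if (problem$type != "tfa")
      stop("concentration targets require mode = \"tfa\"")
    for (i in seq_len(nrow(task$concentrations))) {
      tc <- task$concentrations[i, ]
      cur <- lp_get_bounds(problem$lp, paste0("U_", tc$species))
      lp_set_bounds(problem$lp, paste0("U_", tc$species),
                    lb = max(cur$lb, log(tc$lb)),
                    ub = min(cur$ub, log(tc$ub)))
    }
  }
  problem
}

#' Gap-fill a model against a metabolic task
#'
#' Minimizes the number of activated candidate reactions subject to the
#' composite model satisfying the task under FBA or TFA constraints, then
#' enumerates alternate minimal sets via integer cuts. If the task is
#' already feasible with all candidates disabled, the empty set is returned.
#'
#' @param composite result of [build_composite()] (or a list with `model`
#'   and `candidates`).
#' @param task a `tk_gapfill_task`.
#' @param mode `"fba"` or `"tfa"`.
#' @param max_alternatives cap on enumerated alternate minimal sets.
#' @param measurements optional `tk_measurements` for TFA mode.
#' @return a `tk_gapfill` with `sets` (list of character vectors), `size`
#'   (minimal cardinality, 0 when already feasible) and `feasible`.
#' @export
gapfill <- function(composite, task, mode = c("tfa", "fba"),
                    max_alternatives = 10, measurements = NULL) {
  mode <- match.arg(mode)
  model <- composite$model
  cand <- composite$candidates
  if (!is.null(task$concentrations) && mode != "tfa")
    stop("concentration targets require mode = \"tfa\"")
  base <- if (mode == "fba") build_fba(model)
          else build_tfa(model, measurements = measurements)
  base <- apply_task(base, task)
  M <- flux_big_m(model)

  # candidates disabled: is the task already met?
  p0 <- problem_clone(base)
  for (id in cand) {
    if (mode == "fba") lp_set_bounds(p0$lp, paste0("V_", id), lb = 0, ub = 0)
    else {
      lp_set_bounds(p0$lp, paste0("F_", id), lb = 0, ub = 0)
      lp_set_bounds(p0$lp, paste0("R_", id), lb = 0, ub = 0)
    }
  }
  r0 <- lp_solve(p0$lp, objectives = list(list(coefs = stats::setNames(
    numeric(0), character(0)), sense = "min")))
  if (r0[[1]]$status == "optimal")
    return(structure(list(sets = list(character(0)), size = 0L,
                          feasible = TRUE, mode = mode),
                     class = "tk_gapfill"))

  p <- problem_clone(base)
  yv <- paste0("Y_", cand)
  lp_add_vars(p$lp, yv, type = "B")
  for (i in seq_along(cand)) {
    id <- cand[i]
    if (mode == "fba") {
      lp_add_row(p$lp, stats::setNames(c(1, -M), c(paste0("V_", id), yv[i])),
                 ub = 0, name = paste0("gate_up_", id))
      lp_add_row(p$lp, stats::setNames(c(1, M), c(paste0("V_", id), yv[i])),
                 lb = 0, name = paste0("gate_lo_", id))
    } else {
      lp_add_row(p$lp, stats::setNames(c(1, -M), c(paste0("F_", id), yv[i])),
                 ub = 0, name = paste0("gate_f_", id))
      lp_add_row(p$lp, stats::setNames(c(1, -M), c(paste0("R_", id), yv[i])),
                 ub = 0, name = paste0("gate_r_", id))
    }
  }
  obj <- list(coefs = stats::setNames(rep(1, length(yv)), yv), sense = "min")
  sets <- list(); size <- NA_integer_
  repeat {
    res <- lp_solve(p$lp, objectives = list(obj))[[1]]
    if (res$status != "optimal") break
    sel <- cand[res$x[yv] > 0.5]
    if (is.na(size)) size <- length(sel)
    if (length(sel) > size || length(sets) >= max_alternatives) break
    sets[[length(sets) + 1L]] <- sel
    if (!length(sel)) break
    # integer cut: forbid this exact set
    lp_add_row(p$lp, stats::setNames(rep(1, length(sel)), paste0("Y_", sel)),
               ub = length(sel) - 1,
               name = paste0("cut_", length(sets)))
  }
  if (!length(sets))
    return(structure(list(sets = list(), size = NA_integer_,
                          feasible = FALSE, mode = mode),
                     class = "tk_gapfill"))
  structure(list(sets = sets, size = size, feasible = TRUE, mode = mode),
            class = "tk_gapfill")
}

#' @export
print.tk_gapfill <- function(x, ...) {
  if (!x$feasible)
    cat("<tk_gapfill: infeasible even with all candidates>\n")
  else if (x$size == 0L)
    cat("<tk_gapfill: task already feasible, no additions needed>\n")
  else {
    cat(sprintf("<tk_gapfill (%s): %d minimal set(s) of size %d>\n",
                x$mode, length(x$sets), x$size))
    for (s in x$sets) cat("  -", paste(s, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Exhaustively verify minimality of a gap-fill answer
#'
#' Solves the task feasibility for every candidate subset up to a size cap
#' (batched into one solver call) and returns the smallest feasible subsets.
#' Intended as an independent check of [gapfill()] on small candidate pools.
#'
#' @inheritParams gapfill
#' @param max_size largest subset cardinality to enumerate.
#' @return list with `size` and `sets` as in [gapfill()].
#' @export
gapfill_bruteforce <- function(composite, task, mode = c("tfa", "fba"),
                               max_size = 2) {
  mode <- match.arg(mode)
  model <- composite$model
  cand <- composite$candidates
  base <- if (mode == "fba") build_fba(model)
          else build_tfa(model)
  base <- apply_task(base, task)
  subsets <- list(character(0))
  for (k in seq_len(min(max_size, length(cand))))
    subsets <- c(subsets, utils::combn(cand, k, simplify = FALSE))
  problems <- lapply(subsets, function(s) {
    p <- problem_clone(base)
    for (id in setdiff(cand, s)) {
      if (mode == "fba") lp_set_bounds(p$lp, paste0("V_", id), lb = 0, ub = 0)
      else {
        lp_set_bounds(p$lp, paste0("F_", id), lb = 0, ub = 0)
        lp_set_bounds(p$lp, paste0("R_", id), lb = 0, ub = 0)
      }
    }
    lp_objective(p$lp, stats::setNames(numeric(0), character(0)), "min")
    p$lp
  })
  res <- lp_solve_batch(problems)
  feasible <- vapply(res, function(r) r$status == "optimal", logical(1))
  if (!any(feasible)) return(list(size = NA_integer_, sets = list()))
  sizes <- lengths(subsets)
  best <- min(sizes[feasible])
  list(size = best, sets = subsets[feasible & sizes == best])
}
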