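# Compartment-resolved integration of whole-cell metabolomics.
#
# A whole-cell measurement C_M in (C_M_lo, C_M_hi) constrains the
# concentrations C_Mi of the species representing metabolite M in the
# intracellular compartments i, with volume fractions alpha_i (normalized
# over the compartments where M occurs, as in the volume-weighted mean
# C_M = sum_i alpha_i C_Mi / sum_i alpha_i). Instead of forcing the measured
# bounds identically on every compartment, each metabolite emits i + 2
# constraints:
#   (a) per-compartment bounds  ln C_Mi_lo <= u_i <= ln C_Mi_hi,  with
#       C_Mi_hi = min((C_M_hi - (1-alpha_i) LB)/alpha_i, UB)
#       C_Mi_lo = max((C_M_lo - (1-alpha_i) UB)/alpha_i, LB)
#   (b) the Jensen inequality for the concave logarithm,
#       u_M >= sum_i alpha_i u_i, and
#   (c) the whole-cell bounds  ln C_M_lo <= u_M <= ln C_M_hi
# on the auxiliary whole-cell variable u_M = ln C_M.

#' Per-compartment upper concentration bound
#'
#' Widens a whole-cell upper bound for one compartment: the rest of the cell
#' can at best sit at the physiological floor `LB`, so
#' `C_Mi_hi = min((C_M_hi - (1 - alpha) * LB) / alpha, UB)`.
#'
#' @param c_m whole-cell upper bound, mol/L.
#' @param alpha volume fraction of the compartment, in (0, 1].
#' @param lb,ub physiological concentration bounds, mol/L.
#' @return upper bound for the compartment species, mol/L. Vectorized.
#' @export
per_compartment_upper <- function(c_m, alpha, lb = DEFAULT_CONC_LB,
                                  ub = DEFAULT_CONC_UB) {
  if (any(alpha <= 0)) stop("volume fraction must be positive")
  if (any(alpha > 1)) stop("volume fraction must be <= 1")
  if (any(lb >= ub)) stop("need lb < ub")
  pmin((c_m - (1 - alpha) * lb) / alpha, ub)
}

#' Per-compartment lower concentration bound
#'
#' Mirror of [per_compartment_upper()]: the rest of the cell can at most sit
#' at the ceiling `UB`, so
#' `C_Mi_lo = max((C_M_lo - (1 - alpha) * UB) / alpha, LB)`.
#'
#' @inheritParams per_compartment_upper
#' @param c_m whole-cell lower bound, mol/L.
#' @export
per_compartment_lower <- function(c_m, alpha, lb = DEFAULT_CONC_LB,
                                  ub = DEFAULT_CONC_UB) {
  if (any(alpha <= 0)) stop("volume fraction must be positive")
  if (any(alpha > 1)) stop("volume fraction must be <= 1")
  if (any(lb >= ub)) stop("need lb < ub")
  pmax((c_m - (1 - alpha) * ub) / alpha, lb)
}

#' Build a compartment measurement
#'
#' @param group measured whole-cell metabolite name.
#' @param lb,ub measured whole-cell bounds, mol/L. Values outside the
#'   physiological window are clipped with a warning.
#' @param members data.frame(species, alpha): the member species and the
#'   volume fractions of their compartments. Alphas are renormalized to sum
#'   to one over the member compartments (the volume-weighted mean is taken
#'   over the compartments where the metabolite occurs).
#' @param conc_lb,conc_ub physiological bounds, mol/L.
#' @return a `tk_compartment_measurement` with the derived per-compartment
#'   bounds and the constraint count (`n_members + 2`).
#' @export
compartment_measurement <- function(group, lb, ub, members,
                                    conc_lb = DEFAULT_CONC_LB,
                                    conc_ub = DEFAULT_CONC_UB) {
  stopifnot(nrow(members) >= 1, all(c("species", "alpha") %in% names(members)))
  if (lb <= 0 || ub < lb) stop("need 0 < lb <= ub for group ", group)
  clip <- function(x) {
    if (x < conc_lb || x > conc_ub) {
      warning(sprintf("group %s: measured bound %.3g mol/L outside [%g, %g], clipped",
                      group, x, conc_lb, conc_ub))
      x <- min(max(x, conc_lb), conc_ub)
    }
    x
  }
  lb <- clip(lb); ub <- clip(ub)
  alpha <- members$alpha / sum(members$alpha)
  mem <- data.frame(species = members$species, alpha = alpha,
                    lb = per_compartment_lower(lb, alpha, conc_lb, conc_ub),
                    ub = per_compartment_upper(ub, alpha, conc_lb, conc_ub))
  structure(list(group = group, lb = lb, ub = ub, members = mem,
                 conc_lb = conc_lb, conc_ub = conc_ub,
                 n_constraints = nrow(mem) + 2L),
            class = "tk_compartment_measurement")
}

#' @export
print.tk_compartment_measurement <- function(x, ...) {
  cat(sprintf("<compartment measurement '%s': %.3g-%.3g mM, %d member(s), %d constraints>\n",
              x$group, x$lb * 1e3, x$ub * 1e3, nrow(x$members),
              x$n_constraints))
  invisible(x)
}

#' Emit the abstract constraint block for a measurement
#'
#' Returns the i + 2 constraints in symbolic form: per-member log bounds, the
#' Jensen row `u_M - sum alpha_i u_i >= 0`, and the whole-cell bounds on
#' `u_M`. For a single-member metabolite the block degenerates to the plain
#' measured bound on the one species and the Jensen inequality is tight.
#'
#' @param measurement a `tk_compartment_measurement`.
#' @return list with `member_bounds` (data.frame species, lb_ln, ub_ln),
#'   `jensen` (named coefficient vector over u variables, constrained >= 0),
#'   `whole_cell` (c(lb_ln, ub_ln)), `n_constraints`.
#' @export
emit_constraints <- function(measurement) {
  m <- measurement$members
  if (abs(sum(m$alpha) - 1) > 1e-9)
    stop("member volume fractions must sum to 1 for group ",
         measurement$group)
  list(member_bounds = data.frame(species = m$species,
                                  lb_ln = log(m$lb), ub_ln = log(m$ub)),
       jensen = c(stats::setNames(1, paste0("UM_", measurement$group)),
                  stats::setNames(-m$alpha, paste0("U_", m$species))),
       whole_cell = c(lb_ln = log(measurement$lb),
                      ub_ln = log(measurement$ub)),
       n_constraints = measurement$n_constraints)
}

#' Check a ground-truth compartment assignment against a constraint block
#'
#' Used by the validity property: any true per-compartment concentrations
#' whose volume-weighted whole-cell value lies in the measured range must
#' satisfy every emitted constraint.
#'
#' @param measurement a `tk_compartment_measurement`.
#' @param conc named per-compartment concentrations (mol/L) for the member
#'   species.
#' @return logical scalar.
#' @export
constraints_satisfied <- function(measurement, conc) {
  m <- measurement$members
  ci <- conc[m$species]
  whole <- sum(m$alpha * ci)
  u <- log(ci); um <- log(whole)
  all(u >= log(m$lb) - 1e-12, u <= log(m$ub) + 1e-12,
      um - sum(m$alpha * u) >= -1e-12,
      um >= log(measurement$lb) - 1e-12, um <= log(measurement$ub) + 1e-12)
}

#' Integrate a measurement table into a TFA problem
#'
#' Resolves each measured group to its member species through the species'
#' `whole_cell_group` column, derives the per-compartment bounds, and adds
#' the constraint blocks to the problem. Flux measurements tighten net-flux
#' bounds. Returns the modified problem with an attached report.
#'
#' @param problem a TFA `tk_problem`.
#' @param measurements a `tk_measurements`.
#' @param compartmentalized use the i+2 scheme (default); otherwise apply
#'   measured bounds identically to every member species.
#' @return the modified `tk_problem`; `problem$report` holds
#'   data.frame(group, species, alpha, lb_mM, ub_mM, n_constraints).
#' @export
integrate_measurements <- function(problem, measurements,
                                   compartmentalized = TRUE) {
  if (problem$type != "tfa")
    stop("measurement integration requires a TFA problem")
  problem <- problem_clone(problem)
  model <- problem$model
  rows <- list()
  vf <- stats::setNames(model$compartments$volume_fraction,
                        model$compartments$id)
  ex_comp <- model$compartments$id[model$compartments$extracellular]
  for (k in seq_len(nrow(measurements$concentrations))) {
    g <- measurements$concentrations[k, ]
    members <- model$species[!is.na(model$species$whole_cell_group) &
                             model$species$whole_cell_group == g$group &
                             !(model$species$compartment %in% ex_comp), ]
    if (!nrow(members)) {
      warning("measured group without member species, skipped: ", g$group)
      next
    }
    cm <- compartment_measurement(
      g$group, g$lb, g$ub,
      data.frame(species = members$id, alpha = vf[members$compartment]),
      conc_lb = problem$conc_lb, conc_ub = problem$conc_ub)
    if (compartmentalized) {
      blk <- emit_constraints(cm)
      uvars <- paste0("U_", blk$member_bounds$species)
      cur <- lp_get_bounds(problem$lp, uvars)
      lp_set_bounds(problem$lp, uvars,
                    lb = pmax(cur$lb, blk$member_bounds$lb_ln),
                    ub = pmin(cur$ub, blk$member_bounds$ub_ln))
      if (nrow(cm$members) > 1L) {
        lp_add_vars(problem$lp, paste0("UM_", cm$group),
                    lb = blk$whole_cell[["lb_ln"]],
                    ub = blk$whole_cell[["ub_ln"]])
        lp_add_row(problem$lp, blk$jensen, lb = 0,
                   name = paste0("jensen_", cm$group))
      }
    } else {
      # classic shared-concentration scheme: measured bounds on every member
      uvars <- paste0("U_", cm$members$species)
      cur <- lp_get_bounds(problem$lp, uvars)
      lp_set_bounds(problem$lp, uvars,
                    lb = pmax(cur$lb, log(cm$lb)),
                    ub = pmin(cur$ub, log(cm$ub)))
    }
    rows[[length(rows) + 1L]] <-
      data.frame(group = cm$group, species = cm$members$species,
                 alpha = cm$members$alpha,
                 lb_mM = cm$members$lb * 1e3, ub_mM = cm$members$ub * 1e3,
                 n_constraints = cm$n_constraints)
  }
  for (k in seq_len(nrow(measurements$fluxes))) {
    f <- measurements$fluxes[k, ]
    if (!f$reaction %in% model$reactions$id) {
      warning("flux measurement for unknown reaction, skipped: ", f$reaction)
      next
    }
    apply_flux_bounds(problem, f$reaction, f$lb, f$ub)
  }
  report <- if (length(rows)) do.call(rbind, rows)
            else data.frame(group = character(0), species = character(0),
                            alpha = numeric(0), lb_mM = numeric(0),
                            ub_mM = numeric(0), n_constraints = integer(0))
  problem$report <- report
  problem
}

#' Tighten net-flux bounds on an existing problem
#'
#' Intersects the supplied bounds with the current ones (measurement
#' semantics: constraints only ever narrow the feasible set). Works on both
#' FBA and TFA problems; modifies the problem in place and returns it
#' invisibly.
#'
#' @param problem a `tk_problem`.
#' @param id reaction id.
#' @param lb,ub bounds to intersect, mmol/gDCW/h.
#' @export
apply_flux_bounds <- function(problem, id, lb = NULL, ub = NULL) {
  if (problem$type == "fba") {
    cur <- lp_get_bounds(problem$lp, paste0("V_", id))
    lp_set_bounds(problem$lp, paste0("V_", id),
                  lb = if (is.null(lb)) NULL else pmax(cur$lb, lb),
                  ub = if (is.null(ub)) NULL else pmin(cur$ub, ub))
  } else {
    # the ranged net-flux row is authoritative; adjust it
    rows <- problem$lp$rows
    idx <- which(vapply(rows, function(r) identical(r$name,
                                                    paste0("net_", id)),
                        logical(1)))
    stopifnot(length(idx) == 1L)
    if (!is.null(lb)) problem$lp$rows[[idx]]$lb <-
        max(problem$lp$rows[[idx]]$lb, lb)
    if (!is.null(ub)) problem$lp$rows[[idx]]$ub <-
        min(problem$lp$rows[[idx]]$ub, ub)
    # keep F/R variable caps consistent with a widened/narrowed net range
    nb <- c(problem$lp$rows[[idx]]$lb, problem$lp$rows[[idx]]$ub)
    lp_set_bounds(problem$lp, paste0("F_", id), ub = max(0, nb[2]))
    lp_set_bounds(problem$lp, paste0("R_", id), ub = max(0, -nb[1]))
  }
  invisible(problem)
}

#' Summarize measurement integration
#'
#' @param problem a `tk_problem` returned by [integrate_measurements()].
#' @return list with `n_groups`, `n_constrained_variables` (total member
#'   species across groups, the "measurements provide constraints for this
#'   many concentrations" count) and `n_dual` (groups with more than one
#'   member).
#' @export
integration_summary <- function(problem) {
  rp <- problem$report
  if (is.null(rp)) stop("problem has no measurement report")
  list(n_groups = length(unique(rp$group)),
       n_constrained_variables = nrow(rp),
       n_dual = sum(table(rp$group) > 1L))
}
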