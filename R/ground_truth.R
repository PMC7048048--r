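# Fully specified nonlinear kinetic ground truth for a synthetic network.
#
# The generator picks a thermodynamically feasible steady state (minimal
# total flux at near-maximal growth, Gibbs energies pushed away from
# equilibrium), draws true saturations, back-calculates the true Michaelis
# constants, and solves for the rate constants that make the chosen state an
# exact fixed point of the nonlinear rate laws. The resulting ODE model is
# the independent oracle for control-coefficient and Km-recovery tests: its
# finite-difference responses can be compared against the analytic
# elasticity machinery without sharing any code path with it.

#' Generate a nonlinear kinetic ground truth for a synthetic model
#'
#' @param model a `tk_model` from [generate_network()].
#' @param spec the `tk_synth_spec` (seed).
#' @param margin_cap largest equilibrium-displacement margin requested when
#'   pushing DrG' away from zero, kJ/mol.
#' @param max_tries redraws of the true saturations if the true member is
#'   dynamically unstable.
#' @return a `tk_ground_truth`: the reference state, mechanism assignment,
#'   true saturations/Km table, rate constants, and the exact member.
#' @export
generate_ground_truth_kinetics <- function(model, spec = synthetic_spec(),
                                           margin_cap = 10, max_tries = 50) {
  problem <- build_tfa(model)
  sol <- fix_directionalities_by_min_total_flux(problem, 0.99)
  stopifnot(sol$status == "optimal")

  # re-solve with fluxes pinned, maximizing the smallest |DrG'| margin so no
  # active annotated reaction sits at equilibrium; then, with most of that
  # margin retained, pull the log-concentrations towards the centre of the
  # physiological window (L1 objective). The centring step matters for the
  # oracle role of the ground truth: a MILP solver left to its own devices
  # parks concentrations at the window extremes, giving some metabolite
  # pools turnover times many orders of magnitude apart and making the
  # fixed point too ill-conditioned for finite-difference validation.
  ids <- model$reactions$id
  pinned <- problem_clone(problem)
  f <- pmax(sol$fluxes, 0); r <- pmax(-sol$fluxes, 0)
  lp_set_bounds(pinned$lp, paste0("F_", ids), lb = f, ub = f)
  lp_set_bounds(pinned$lp, paste0("R_", ids), lb = r, ub = r)
  lp_add_vars(pinned$lp, "MARG", lb = 0, ub = margin_cap)
  active_ann <- intersect(pinned$annotated,
                          ids[abs(sol$fluxes[ids]) > FLUX_TOL])
  for (id in active_ann) {
    if (sol$fluxes[id] > 0)
      lp_add_row(pinned$lp,
                 stats::setNames(c(1, 1), c(paste0("G_", id), "MARG")),
                 ub = 0, name = paste0("marg_", id))
    else
      lp_add_row(pinned$lp,
                 stats::setNames(c(1, -1), c(paste0("G_", id), "MARG")),
                 lb = 0, name = paste0("marg_", id))
  }
  res <- lp_solve(pinned$lp, objectives = list(list(coefs = c(MARG = 1),
                                                    sense = "max")))[[1]]
  if (res$status != "optimal")
    stop("margin push failed: ", res$status)

  # retain 90% of the achievable margin, centre the concentrations
  lp_set_bounds(pinned$lp, "MARG", lb = 0.9 * res$objective)
  centre <- (log(pinned$conc_lb) + log(pinned$conc_ub)) / 2
  uvars <- paste0("U_", model$species$id)
  tvars <- paste0("TC_", model$species$id)
  lp_add_vars(pinned$lp, tvars, lb = 0)
  for (i in seq_along(uvars)) {
    lp_add_row(pinned$lp, stats::setNames(c(1, -1), c(tvars[i], uvars[i])),
               lb = -centre, name = paste0("ctr_lo_", i))
    lp_add_row(pinned$lp, stats::setNames(c(1, 1), c(tvars[i], uvars[i])),
               lb = centre, name = paste0("ctr_hi_", i))
  }
  res2 <- lp_solve(pinned$lp, objectives = list(list(
    coefs = stats::setNames(rep(1, length(tvars)), tvars),
    sense = "min")))[[1]]
  if (res2$status == "optimal") res <- res2
  sol2 <- as_solution(pinned, res)
  sol2$fluxes <- sol$fluxes       # keep the pinned flux vector verbatim

  reference <- prepare_reference(sol2, model)
  assignment <- assign_mechanisms(reference)

  for (try in seq_len(max_tries)) {
    set.seed(spec$seed + 1000L + try)
    sigma_true <- stats::runif(nrow(assignment$slots), 0.25, 0.75)
    member <- sample_member(reference, assignment, sigma = sigma_true)
    if (isTRUE(check_stability(member, reference))) break
    if (try == max_tries)
      stop("no stable ground-truth member found in ", max_tries, " draws")
  }

  truth <- structure(list(model = model, reference = reference,
                          assignment = assignment,
                          sigma_true = member$sigma, km_true = member$km,
                          member = member, solution = sol2,
                          conc = reference$conc,
                          rate_k = NULL),
                     class = "tk_ground_truth")
  truth$rate_k <- solve_rate_constants(truth)
  truth
}

#' @export
print.tk_ground_truth <- function(x, ...) {
  cat(sprintf("<tk_ground_truth on '%s': %d kinetic reactions, %d true Km values>\n",
              x$model$name, nrow(x$reference$reactions),
              length(x$km_true)))
  invisible(x)
}

# displacement of reaction j at concentrations conc (named, full)
gamma_at <- function(truth, j, conc) {
  ref <- truth$reference
  r <- ref$reactions[j, ]
  if (!r$annotated) return(0)
  s <- ref$stoich[[r$id]]
  s <- s[names(s) %in% ref$retained]
  if (!length(s)) return(r$gamma)
  r$gamma * prod((conc[names(s)] / ref$conc[names(s)])^s)
}

# rate of each kinetic reaction at the given retained-species concentrations
# (oriented: positive along the reference flux direction)
ground_truth_rates <- function(truth, conc, activity = NULL) {
  ref <- truth$reference
  slots <- truth$assignment$slots
  full <- ref$conc
  full[names(conc)] <- conc
  out <- numeric(nrow(ref$reactions))
  names(out) <- ref$reactions$id
  for (j in seq_len(nrow(ref$reactions))) {
    r <- ref$reactions[j, ]
    g <- gamma_at(truth, j, full)
    s <- ref$stoich[[r$id]]
    if (r$mechanism == "mass_action") {
      sub <- s[s < 0]
      shape <- prod(full[names(sub)]^(-sub)) * (1 - g)
    } else {
      sl <- slots[slots$reaction == r$id, ]
      a <- full[sl$species] / truth$km_true[sl$slot]
      num <- prod(a[sl$role == "substrate"]^sl$mult[sl$role == "substrate"])
      den <- prod((1 + a)^sl$mult)
      shape <- num * (1 - g) / den
    }
    out[j] <- truth$rate_k[j] * shape
  }
  if (!is.null(activity)) {
    unknown <- setdiff(names(activity), names(out))
    if (length(unknown))
      stop("activity for reactions outside the kinetic network: ",
           paste(unknown, collapse = ", "))
    out[names(activity)] <- out[names(activity)] * activity
  }
  out
}

# rate constants making the reference an exact fixed point
solve_rate_constants <- function(truth) {
  ref <- truth$reference
  truth$rate_k <- rep(1, nrow(ref$reactions))
  names(truth$rate_k) <- ref$reactions$id
  shape <- ground_truth_rates(truth, ref$conc[ref$retained])
  k <- ref$reactions$v / shape
  names(k) <- ref$reactions$id
  if (any(!is.finite(k)) || any(k <= 0))
    stop("degenerate rate-constant solve (shape of wrong sign)")
  k
}

# ODE right-hand side over retained species
ground_truth_rhs <- function(truth, activity = NULL) {
  ref <- truth$reference
  function(t, y, parms) {
    conc <- stats::setNames(pmax(y, 1e-12), ref$retained)
    v <- ground_truth_rates(truth, conc, activity)
    list(as.numeric(ref$N %*% v))
  }
}

#' Integrate the ground-truth ODE to steady state
#'
#' @param truth a `tk_ground_truth`.
#' @param activity optional named enzyme-activity multipliers.
#' @param t_final optional fixed integration horizon (deSolve); by default
#'   the steady state is found by stiff integration in doubling time legs
#'   until the balance residual is small, followed by Newton polishing on
#'   the reduced balance equations `N_R v(x) = 0` over independent species
#'   (dependent species follow the conservation relations through the link
#'   matrix). The Newton Jacobian is obtained by complex-step
#'   differentiation of the nonlinear rate laws — numerically exact and
#'   sharing no code with the analytic elasticity formulas. The staged
#'   approach copes with stiffness ratios of 1e9 and slow relaxation modes.
#' @param rel_tol relative balance-residual norm declaring convergence.
#' @return list with steady concentrations `conc`, fluxes `v` and the final
#'   right-hand-side norm `residual`.
#' @export
ground_truth_steady_state <- function(truth, activity = NULL,
                                      t_final = NULL, rel_tol = 1e-11) {
  ref <- truth$reference
  rhs <- ground_truth_rhs(truth, activity)
  vscale <- max(abs(ref$reactions$v))
  integrate_leg <- function(y, t_end, rtol, atol) {
    sol <- deSolve::lsoda(y = y, times = c(0, t_end), func = rhs,
                          parms = NULL, rtol = rtol, atol = atol,
                          maxsteps = 20000)
    stats::setNames(as.numeric(sol[nrow(sol), -1]), ref$retained)
  }
  if (!is.null(t_final)) {
    y <- integrate_leg(ref$conc[ref$retained], t_final, 1e-12, 1e-16)
  } else {
    # stage 1: approach the attractor by stiff integration (loose
    # tolerance; the endpoint only needs to land in the Newton basin)
    y <- ref$conc[ref$retained]
    t_leg <- 1e-3
    for (leg in 1:45) {
      if (max(abs(rhs(0, y, NULL)[[1]])) < 1e-4 * vscale) break
      y <- integrate_leg(y, t_leg, 1e-6, 1e-12)
      t_leg <- t_leg * 2
    }
    # stage 2: Newton polish in log space of the independent species;
    # conservation relations are linear in concentrations, hence exact
    xi0 <- ref$conc[ref$indep]
    conc_full <- function(xi)
      stats::setNames(as.vector(ref$conc[ref$retained] +
                                  ref$L %*% (xi - xi0)), ref$retained)
    Fc <- function(u)
      as.vector(ref$Nr %*% ground_truth_rates(truth, conc_full(exp(u)),
                                              activity))
    # project the integrated state onto the conservation-consistent chart
    u <- log(pmax(y[ref$indep], 1e-14)) + 0i
    f <- Re(Fc(u))
    for (it in 1:25) {
      if (max(abs(f)) < rel_tol * vscale) break
      r <- length(u)
      J <- matrix(0, r, r)
      h <- 1e-20
      for (j in seq_len(r)) {
        up <- u; up[j] <- up[j] + 1i * h
        J[, j] <- Im(Fc(up)) / h
      }
      step <- tryCatch(-solve(J, f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        cand <- u + lam * step
        if (all(Re(conc_full(exp(Re(cand)))) > 0)) {
          fc <- Re(Fc(cand))
          if (sum(fc^2) < sum(f^2)) { u <- cand; f <- fc; break }
        }
        lam <- lam / 2
        if (lam < 1e-10) break
      }
      if (lam < 1e-10) break
    }
    y <- Re(conc_full(exp(Re(u))))
  }
  v <- Re(ground_truth_rates(truth, y, activity))
  list(conc = y, v = v,
       residual = max(abs(as.numeric(ref$N %*% v))))
}

#' Finite-difference control coefficients from the ground-truth ODE
#'
#' Perturbs each enzyme activity by a small relative amount in both
#' directions, re-integrates the nonlinear ODE to its steady state, and
#' central-differences the logarithms of fluxes and concentrations, with one
#' Richardson extrapolation step (differences at `rel` and `rel/2`) to
#' suppress curvature error on stiff directions where concentration control
#' is large. This is the independent oracle against which the analytic
#' control coefficients are validated.
#'
#' @param truth a `tk_ground_truth`.
#' @param enzymes enzymes to perturb (default all kinetic reactions).
#' @param rel relative activity perturbation (default 1e-3).
#' @return list of matrices `CJ` (reactions x enzymes), `CX` (retained
#'   species x enzymes).
#' @export
fd_control_coefficients <- function(truth,
                                    enzymes = truth$reference$reactions$id,
                                    rel = 1e-3) {
  ref <- truth$reference
  unknown <- setdiff(enzymes, ref$reactions$id)
  if (length(unknown))
    stop("not in the kinetic network (frozen or boundary): ",
         paste(unknown, collapse = ", "))
  CJ <- matrix(NA_real_, nrow(ref$reactions), length(enzymes),
               dimnames = list(ref$reactions$id, enzymes))
  CX <- matrix(NA_real_, length(ref$retained), length(enzymes),
               dimnames = list(ref$retained, enzymes))
  central <- function(e, h) {
    up <- ground_truth_steady_state(truth,
                                    activity = stats::setNames(1 + h, e))
    dn <- ground_truth_steady_state(truth,
                                    activity = stats::setNames(1 - h, e))
    dln <- log(1 + h) - log(1 - h)
    list(CJ = (log(up$v) - log(dn$v)) / dln,
         CX = (log(up$conc) - log(dn$conc)) / dln)
  }
  for (e in enzymes) {
    d1 <- central(e, rel)
    d2 <- central(e, rel / 2)
    CJ[, e] <- (4 * d2$CJ - d1$CJ) / 3
    CX[, e] <- (4 * d2$CX - d1$CX) / 3
  }
  list(CJ = CJ, CX = CX)
}
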