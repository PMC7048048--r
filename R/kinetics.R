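# Monte-Carlo construction of log-linear kinetic model ensembles around a
# thermodynamically feasible steady state, with metabolic control analysis.
#
# The displacement of reaction j from equilibrium is Gamma_j =
# exp(DrG'_j / RT) in (0,1) for a net-forward reaction. With generalized
# reversible kinetics and independent binding sites, the scaled elasticity
# of rate j with respect to metabolite k (stoichiometric coefficient s_jk,
# multiplicity m = |s_jk|, sampled site saturation sigma in (0,1)) is
#     eps_jk = max(-s_jk, 0)  -  s_jk * Gamma/(1 - Gamma)  -  m * sigma
# where the sigma term applies only to saturable (enzymatic) sites; transport
# and diffusion steps keep the first two (mass-action) terms. Saturations
# translate to Michaelis constants by Km = C* (1 - sigma)/sigma.

FLUX_TOL <- 1e-6   # |v| below this is treated as frozen

#' Prepare a kinetic reference state from a TFA solution
#'
#' Demotes extracellular metabolites to parameters (their mass balances are
#' dropped), removes water and proton balances and pure-water transport,
#' restricts the network to reactions carrying flux, orients every retained
#' reaction along its net flux and computes the displacement
#' `Gamma = exp(DrG'/RT)`. The steady-state fluxes are repaired to satisfy
#' the retained mass balances to machine precision (minimal-norm
#' correction), and the link decomposition `N = L N_R` separating dependent
#' from independent species is computed together with its log-space
#' weighting.
#'
#' @param solution a feasible TFA `tk_solution` (with concentrations and
#'   Gibbs energies).
#' @param model the `tk_model` the solution was computed on.
#' @param flux_tol fluxes with `|v| < flux_tol` are frozen (excluded).
#' @param gamma_max displacements above this (too close to equilibrium) make
#'   a reaction ineligible for saturation sampling; [sample_member()] errors
#'   on such references.
#' @return a `tk_reference`.
#' @export
prepare_reference <- function(solution, model, flux_tol = FLUX_TOL,
                              gamma_max = 0.999) {
  stopifnot(inherits(solution, "tk_solution"))
  if (is.null(solution$u))
    stop("reference preparation needs a TFA solution with concentrations")
  rt <- model_rt(model)
  excluded_sp <- grep("^(h2o|h)_", model$species$id, value = TRUE)
  ex_sp <- extracellular_species(model)
  v <- solution$fluxes

  # sign consistency between flux and DrG'
  for (id in names(solution$drG)) {
    if (abs(v[id]) > flux_tol && sign(v[id]) == sign(solution$drG[id]))
      stop("invalid reference: flux and DrG' have the same sign for ", id)
  }

  retained_candidates <- setdiff(model$species$id, c(ex_sp, excluded_sp))
  active <- names(v)[abs(v) > flux_tol]
  # water-only transport and exchange reactions drop out automatically:
  # keep reactions touching at least one retained species
  kin <- active[vapply(active, function(id)
    any(names(model$stoich[[id]]) %in% retained_candidates), logical(1))]
  retained <- intersect(retained_candidates,
                        unique(unlist(lapply(model$stoich[kin], names),
                                      use.names = FALSE)))
  params <- setdiff(unique(unlist(lapply(model$stoich[kin], names),
                                  use.names = FALSE)), retained)

  # orient along flux
  stoich <- lapply(kin, function(id)
    if (v[id] < 0) -model$stoich[[id]] else model$stoich[[id]])
  names(stoich) <- kin
  flipped <- v[kin] < 0
  vk <- abs(v[kin])
  gamma <- rep(0, length(kin)); names(gamma) <- kin
  ann <- intersect(kin, names(solution$drG))
  g_or <- ifelse(flipped[ann], -solution$drG[ann], solution$drG[ann])
  gamma[ann] <- exp(g_or / rt)

  Nk <- matrix(0, length(retained), length(kin),
               dimnames = list(retained, kin))
  for (j in seq_along(kin)) {
    s <- stoich[[j]]
    s <- s[names(s) %in% retained]
    Nk[names(s), j] <- s
  }
  # independent rows via QR of t(N)
  qrN <- qr(t(Nk))
  r <- qrN$rank
  indep <- rownames(Nk)[qrN$pivot[seq_len(r)]]
  Nr <- Nk[indep, , drop = FALSE]
  L <- t(qr.coef(qr(t(Nr)), t(Nk)))     # N = L %*% Nr
  L[is.na(L)] <- 0
  rownames(L) <- rownames(Nk); colnames(L) <- indep

  conc <- exp(solution$u)
  x_full <- conc[retained]; x_ind <- conc[indep]
  L_log <- diag(1 / x_full, nrow = length(x_full)) %*% L %*%
    diag(x_ind, nrow = length(x_ind))
  dimnames(L_log) <- dimnames(L)

  # exact mass-balance repair: minimal-norm correction on independent rows
  resid <- as.numeric(Nr %*% vk)
  if (max(abs(resid)) > 0) {
    corr <- crossprod(Nr, solve(tcrossprod(Nr), resid))
    vk <- vk - as.numeric(corr)
  }

  mech <- ifelse(model$reactions$is_transport[match(kin, model$reactions$id)] |
                   model$reactions$is_exchange[match(kin, model$reactions$id)],
                 "mass_action", "enzymatic")
  names(mech) <- kin

  structure(list(model_name = model$name,
                 reactions = data.frame(id = kin, v = unname(vk),
                                        gamma = unname(gamma),
                                        mechanism = unname(mech),
                                        flipped = unname(flipped),
                                        annotated = kin %in% ann),
                 stoich = stoich,
                 conc = conc,
                 retained = retained, params = params, indep = indep,
                 N = Nk, Nr = Nr, L = L, L_log = L_log,
                 frozen = setdiff(names(v)[abs(v) <= flux_tol], NA),
                 rt = rt, gamma_max = gamma_max,
                 n_dropped_balances = length(intersect(
                   ex_sp, unique(unlist(lapply(model$stoich, names),
                                        use.names = FALSE))))),
            class = "tk_reference")
}

#' @export
print.tk_reference <- function(x, ...) {
  cat(sprintf("<tk_reference '%s': %d reactions, %d retained species (%d independent), %d frozen>\n",
              x$model_name, nrow(x$reactions), length(x$retained),
              length(x$indep), length(x$frozen)))
  invisible(x)
}

#' Assign kinetic mechanisms and saturation slots
#'
#' Transport/diffusion steps get mass-action kinetics (no saturable sites).
#' Enzyme-catalysed reactions get generalized reversible kinetics with one
#' saturable site per participating metabolite (the reversible uni-uni
#' Michaelis-Menten mechanism is the one-substrate/one-product special
#' case); irreversible steps (no thermodynamic annotation) carry sites for
#' their substrates only. Slots with an experimentally known Km are fixed
#' rather than sampled.
#'
#' @param reference a `tk_reference`.
#' @param known_km optional data.frame(reaction, species, km) in mol/L.
#' @return a `tk_mechanisms` with the slot table (`reaction`, `species`,
#'   `mult`, `role`, `km_known`).
#' @export
assign_mechanisms <- function(reference, known_km = NULL) {
  rows <- list()
  for (j in seq_len(nrow(reference$reactions))) {
    r <- reference$reactions[j, ]
    if (r$mechanism != "enzymatic") next
    s <- reference$stoich[[r$id]]
    if (!r$annotated) s <- s[s < 0]   # irreversible: substrate sites only
    if (!length(s)) next
    rows[[length(rows) + 1L]] <-
      data.frame(reaction = r$id, species = names(s), mult = abs(unname(s)),
                 role = ifelse(s < 0, "substrate", "product"))
  }
  slots <- if (length(rows)) do.call(rbind, rows)
           else data.frame(reaction = character(0), species = character(0),
                           mult = numeric(0), role = character(0))
  slots$km_known <- NA_real_
  if (!is.null(known_km)) {
    key <- paste(slots$reaction, slots$species)
    kk <- paste(known_km$reaction, known_km$species)
    unknown <- setdiff(kk, key)
    if (length(unknown)) stop("known Km for absent slot(s): ",
                              paste(unknown, collapse = ", "))
    slots$km_known[match(kk, key)] <- known_km$km
  }
  slots$slot <- paste0(slots$reaction, "@", sub("_[a-z]+$", "", slots$species))
  structure(list(slots = slots, reference_model = reference$model_name),
            class = "tk_mechanisms")
}

#' @export
print.tk_mechanisms <- function(x, ...) {
  cat(sprintf("<tk_mechanisms: %d saturation slots (%d with known Km)>\n",
              nrow(x$slots), sum(!is.na(x$slots$km_known))))
  invisible(x)
}

# elasticity matrix (reactions x retained species) for given slot saturations
elasticity_matrix <- function(reference, assignment, sigma) {
  kin <- reference$reactions$id
  E <- matrix(0, length(kin), length(reference$retained),
              dimnames = list(kin, reference$retained))
  slot_key <- paste(assignment$slots$reaction, assignment$slots$species)
  for (j in seq_along(kin)) {
    r <- reference$reactions[j, ]
    s <- reference$stoich[[r$id]]
    s <- s[names(s) %in% reference$retained]
    if (!length(s)) next
    g <- r$gamma
    therm <- pmax(-s, 0) - s * g / (1 - g)
    sat <- rep(0, length(s))
    idx <- match(paste(r$id, names(s)), slot_key)
    has <- !is.na(idx)
    sat[has] <- abs(s[has]) * sigma[idx[has]]
    E[j, names(s)] <- therm - sat
  }
  E
}

#' Sample one ensemble member
#'
#' Draws a uniform saturation in (0,1) for every unknown slot, fixes the
#' saturation of known-Km slots at `C*/(C* + Km)`, back-calculates the
#' remaining Michaelis constants as `Km = C* (1 - sigma)/sigma` and
#' evaluates the elasticity matrix.
#'
#' @param reference a `tk_reference`; every sampled reaction must satisfy
#'   `Gamma < gamma_max`.
#' @param assignment a `tk_mechanisms`.
#' @param sigma optional saturation vector (one value per slot) overriding
#'   the random draw; used to rebuild a specific member.
#' @param sigma_lo,sigma_hi per-slot saturation sampling bounds in (0,1),
#'   recycled; used by [resample_with_ranges()] to constrain back-calculated
#'   Km values to refined ranges.
#' @return a `tk_member` (`sigma`, `km` in mol/L, elasticity matrix `E`).
#' @export
sample_member <- function(reference, assignment, sigma = NULL,
                          sigma_lo = 0, sigma_hi = 1) {
  bad <- reference$reactions$id[reference$reactions$gamma >=
                                  reference$gamma_max]
  if (length(bad))
    stop("reference too close to equilibrium (Gamma >= ",
         reference$gamma_max, ") for: ", paste(bad, collapse = ", "))
  slots <- assignment$slots
  n <- nrow(slots)
  if (is.null(sigma)) sigma <- stats::runif(n, rep_len(sigma_lo, n),
                                            rep_len(sigma_hi, n))
  cstar <- reference$conc[slots$species]
  known <- !is.na(slots$km_known)
  sigma[known] <- cstar[known] / (cstar[known] + slots$km_known[known])
  km <- cstar * (1 - sigma) / sigma
  names(sigma) <- names(km) <- slots$slot
  structure(list(sigma = sigma, km = km,
                 E = elasticity_matrix(reference, assignment, sigma)),
            class = "tk_member")
}

#' Stability of a member's linearized dynamics
#'
#' Builds the Jacobian of the log-concentration dynamics over independent
#' species, `J = diag(1/x*) N_R diag(v*) E Lw`, with `Lw` the log-weighted
#' link matrix, and flags the member stable when every eigenvalue has a
#' negative real part.
#'
#' @param member a `tk_member`.
#' @param reference the `tk_reference` it was sampled on.
#' @return logical flag; the eigenvalues are attached as attribute
#'   `"eigenvalues"`.
#' @export
check_stability <- function(member, reference) {
  J <- diag(1 / reference$conc[reference$indep],
            nrow = length(reference$indep)) %*%
    reference$Nr %*% (reference$reactions$v * member$E) %*% reference$L_log
  ev <- eigen(J, only.values = TRUE)$values
  structure(max(Re(ev)) < 0, eigenvalues = ev)
}

#' Control coefficients of a stable member
#'
#' Uses enzyme activities as the perturbation basis (each rate proportional
#' to its enzyme's activity), giving
#' `C^X = -Lw (N_R diag(v*) E Lw)^-1 N_R diag(v*)` over retained species and
#' `C^J = I + E C^X` over reactions. Rows satisfy the summation theorems
#' (flux rows sum to 1, concentration rows to 0).
#'
#' @param member a stable `tk_member`.
#' @param reference the `tk_reference`.
#' @return list with matrices `CJ` (reactions x enzymes) and `CX`
#'   (retained species x enzymes).
#' @export
control_coefficients <- function(member, reference) {
  v <- reference$reactions$v
  NvE <- reference$Nr %*% (v * member$E)        # r x n_species_retained
  M <- NvE %*% reference$L_log                  # r x r
  Nv <- reference$Nr %*% diag(v, nrow = length(v))
  CXi <- tryCatch(-solve(M, Nv),
                  error = function(e) stop("singular Jacobian core; member discarded",
                                           call. = FALSE))
  CX <- reference$L_log %*% CXi
  CJ <- diag(nrow(member$E)) + member$E %*% CX
  dimnames(CJ) <- list(reference$reactions$id, reference$reactions$id)
  dimnames(CX) <- list(reference$retained, reference$reactions$id)
  list(CJ = CJ, CX = CX)
}

#' Build an ensemble of kinetic models
#'
#' Repeats saturation sampling, stability filtering and control-coefficient
#' computation until `n_members` stable members are collected (or the
#' attempt cap trips). Fully reproducible from `seed`.
#'
#' @param reference a `tk_reference`.
#' @param assignment a `tk_mechanisms`.
#' @param n_members stable members to retain.
#' @param seed integer seed.
#' @param max_attempts attempt cap (default `200 * n_members`); if fewer
#'   than 0.1% of attempts are stable the construction aborts with a
#'   diagnostic.
#' @param sigma_lo,sigma_hi per-slot saturation sampling bounds, passed to
#'   [sample_member()].
#' @return a `tk_ensemble`: saturation and Km matrices (members x slots),
#'   control-coefficient arrays `CJ`, `CX`, acceptance rate, and summary via
#'   [ensemble_summary()].
#' @export
build_ensemble <- function(reference, assignment, n_members = 1000,
                           seed = 1L, max_attempts = 200 * n_members,
                           sigma_lo = 0, sigma_hi = 1) {
  set.seed(seed)
  slots <- assignment$slots
  kin <- reference$reactions$id
  sigma <- matrix(NA_real_, n_members, nrow(slots),
                  dimnames = list(NULL, slots$slot))
  km <- sigma
  CJ <- array(NA_real_, c(length(kin), length(kin), n_members),
              dimnames = list(kin, kin, NULL))
  CX <- array(NA_real_, c(length(reference$retained), length(kin), n_members),
              dimnames = list(reference$retained, kin, NULL))
  got <- 0L; attempts <- 0L
  while (got < n_members) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "stability acceptance %.3g%% after %d attempts; ensemble aborted",
        100 * got / attempts, attempts))
    member <- sample_member(reference, assignment,
                            sigma_lo = sigma_lo, sigma_hi = sigma_hi)
    if (!isTRUE(check_stability(member, reference))) next
    cc <- tryCatch(control_coefficients(member, reference),
                   error = function(e) NULL)
    if (is.null(cc)) next
    got <- got + 1L
    sigma[got, ] <- member$sigma
    km[got, ] <- member$km
    CJ[, , got] <- cc$CJ
    CX[, , got] <- cc$CX
  }
  structure(list(reference = reference, assignment = assignment,
                 n = n_members, sigma = sigma, km = km, CJ = CJ, CX = CX,
                 acceptance = n_members / attempts, seed = seed),
            class = "tk_ensemble")
}

#' @export
print.tk_ensemble <- function(x, ...) {
  cat(sprintf("<tk_ensemble: %d stable members, %d slots, acceptance %.1f%%>\n",
              x$n, ncol(x$sigma), 100 * x$acceptance))
  invisible(x)
}

#' Summarize control-coefficient distributions
#'
#' @param ensemble a `tk_ensemble`.
#' @param targets reaction ids (flux targets) and/or species ids
#'   (concentration targets); default all fluxes.
#' @param enzymes enzyme (reaction) ids; default all.
#' @return data.frame(target, type, enzyme, mean, q25, q75).
#' @export
ensemble_summary <- function(ensemble,
                             targets = dimnames(ensemble$CJ)[[1]],
                             enzymes = dimnames(ensemble$CJ)[[2]]) {
  rows <- list()
  for (tg in targets) {
    is_flux <- tg %in% dimnames(ensemble$CJ)[[1]]
    if (!is_flux && !tg %in% dimnames(ensemble$CX)[[1]])
      stop("unknown target: ", tg)
    for (e in enzymes) {
      vals <- if (is_flux) ensemble$CJ[tg, e, ] else ensemble$CX[tg, e, ]
      q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(target = tg, type = if (is_flux) "flux" else "concentration",
                   enzyme = e, mean = mean(vals), q25 = q[1], q75 = q[2])
    }
  }
  do.call(rbind, rows)
}

#' Km ranges sampled by an ensemble
#'
#' @param ensemble a `tk_ensemble`.
#' @return data.frame(slot, lower, upper) in mol/L (min/max over members).
#' @export
ensemble_km_ranges <- function(ensemble) {
  data.frame(slot = colnames(ensemble$km),
             lower = apply(ensemble$km, 2, min),
             upper = apply(ensemble$km, 2, max))
}
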