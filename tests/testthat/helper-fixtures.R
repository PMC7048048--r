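# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

d2_model <- function() fx("d2_model", function()
  generate_network(synthetic_spec(seed = 1)))

d2_truth <- function() fx("d2_truth", function()
  generate_ground_truth_kinetics(d2_model(), synthetic_spec(seed = 1)))

d2_measurements <- function() fx("d2_measurements", function()
  generate_measurements(d2_truth(), synthetic_spec(seed = 1)))

d2_tfa <- function() fx("d2_tfa", function() build_tfa(d2_model()))

d2_ensemble_1k <- function() fx("d2_ensemble_1k", function()
  build_ensemble(d2_truth()$reference, d2_truth()$assignment,
                 n_members = 1000, seed = 42))

d2_ensemble_5k <- function() fx("d2_ensemble_5k", function()
  build_ensemble(d2_truth()$reference, d2_truth()$assignment,
                 n_members = 5000, seed = 7))

# A 4-species, 6-reaction branched toy with two routes of different yield:
#   A_e -> A (uptake); A -> B (efficient); 2 A -> B (wasteful); B -> B_e
# plus exchanges. Objective T_out.
branch_toy <- function() {
  metabolic_model(
    compartments = data.frame(id = c("c", "e"), volume_fraction = c(1, 1),
                              extracellular = c(FALSE, TRUE)),
    species = data.frame(id = c("A_e", "A_c", "B_c", "B_e"),
                         compartment = c("e", "c", "c", "e")),
    reactions = data.frame(
      id = c("UP", "P1", "P2", "OUT", "EX_A", "EX_B"),
      lb = c(0, 0, 0, 0, -10, 0),
      ub = c(10, 100, 100, 100, 0, 100),
      drG0 = c(NA, -10, -12, NA, NA, NA),
      drG0_err = 0,
      is_exchange = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)),
    stoichiometry = list(UP = c(A_e = -1, A_c = 1),
                         P1 = c(A_c = -1, B_c = 1),
                         P2 = c(A_c = -2, B_c = 1),
                         OUT = c(B_c = -1, B_e = 1),
                         EX_A = c(A_e = -1),
                         EX_B = c(B_e = -1)),
    objective = "OUT", name = "branch_toy")
}

# Brute-force LP maximization by basic-feasible-solution enumeration:
# max c'v s.t. N v = 0, lb <= v <= ub. Exact for tiny problems.
brute_force_lp_max <- function(N, lb, ub, cvec) {
  n <- ncol(N)
  r <- qr(N)$rank
  nfree <- n - r
  best <- -Inf
  idx <- utils::combn(n, nfree, simplify = FALSE)
  for (nonbasic in idx) {
    grid <- expand.grid(rep(list(c(1, 2)), nfree))
    for (g in seq_len(nrow(grid))) {
      v <- rep(NA_real_, n)
      v[nonbasic] <- ifelse(unlist(grid[g, ]) == 1, lb[nonbasic],
                            ub[nonbasic])
      basic <- setdiff(seq_len(n), nonbasic)
      A <- N[, basic, drop = FALSE]
      b <- -N[, nonbasic, drop = FALSE] %*% v[nonbasic]
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      v[basic] <- sol
      if (max(abs(N %*% v)) > 1e-8) next
      if (any(v < lb - 1e-9) || any(v > ub + 1e-9)) next
      best <- max(best, sum(cvec * v))
    }
  }
  best
}

# hand-built uni-uni reference (one reaction S -> P) with a chosen
# displacement; concentrations 1 mM. Used for elasticity spot checks.
uniuni_reference <- function(gamma) {
  structure(list(
    model_name = "uniuni",
    reactions = data.frame(id = "R1", v = 1, gamma = gamma,
                           mechanism = "enzymatic", flipped = FALSE,
                           annotated = TRUE),
    stoich = list(R1 = c(S = -1, P = 1)),
    conc = c(S = 1e-3, P = 1e-3),
    retained = c("S", "P"), params = character(0), indep = "S",
    N = matrix(c(-1, 1), 2, 1, dimnames = list(c("S", "P"), "R1")),
    Nr = matrix(-1, 1, 1, dimnames = list("S", "R1")),
    L = matrix(c(1, -1), 2, 1, dimnames = list(c("S", "P"), "S")),
    L_log = matrix(c(1, -1), 2, 1, dimnames = list(c("S", "P"), "S")),
    frozen = character(0), rt = 8.314e-3 * 298.15, gamma_max = 0.999,
    n_dropped_balances = 0L), class = "tk_reference")
}
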