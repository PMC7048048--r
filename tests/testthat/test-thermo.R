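# FBA, TFA, variability and knockouts.

test_that("flux is conserved along a linear pathway", {
  m <- generate_network(synthetic_spec(seed = 1, topology = "chain",
                                       chain_length = 3))
  m <- set_reaction_bounds(m, "EX_in", lb = -1, ub = -1)
  sol <- solve_problem(build_fba(m), NULL, "max")
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$fluxes[c("T_in", "C1", "T_out")]), c(1, 1, 1),
               tolerance = 1e-9)
  # zero uptake: optimum collapses to zero
  m0 <- set_reaction_bounds(m, "EX_in", lb = 0, ub = 0)
  expect_equal(solve_problem(build_fba(m0), NULL, "max")$objective, 0,
               tolerance = 1e-9)
})

test_that("FBA optimum matches brute-force vertex enumeration on a branched toy", {
  m <- branch_toy()
  sol <- solve_problem(build_fba(m), NULL, "max")
  N <- stoichiometric_matrix(m)
  cvec <- as.numeric(m$reactions$id == "OUT")
  best <- brute_force_lp_max(N, m$reactions$lb, m$reactions$ub, cvec)
  expect_equal(sol$objective, best, tolerance = 1e-8)
  expect_equal(sol$objective, 10, tolerance = 1e-8)  # efficient branch wins
})

test_that("conflicting bounds error before solving, infeasibility is a status", {
  m <- branch_toy()
  m$reactions$lb[1] <- 20
  expect_error(build_fba(m), "lb > ub")
  m2 <- branch_toy()
  p <- build_fba(m2, extra_bounds = data.frame(id = c("UP", "OUT"),
                                               lb = c(0, 5), ub = c(0, 100)))
  expect_identical(solve_problem(p, NULL, "max")$status, "infeasible")
})

# fully reversible 3-step chain whose middle step carries a chosen DrG'0;
# with default concentration bounds the attainable RT-sum spans about
# +/- 26.8 kJ/mol, so |DrG'0| = 30 pins the direction while 0 leaves it free
rev_chain <- function(drg_mid) {
  m <- generate_network(synthetic_spec(seed = 1, topology = "chain",
                                       chain_length = 3))
  m <- set_reaction_bounds(m, m$reactions$id, lb = -100, ub = 100)
  m <- set_reaction_bounds(m, "EX_in", lb = -10, ub = 10)
  m <- set_reaction_bounds(m, "EX_out", lb = -10, ub = 10)
  m$reactions$drG0[m$reactions$id == "C1"] <- drg_mid
  m
}

test_that("a strongly unfavorable DrG'0 blocks exactly the uphill direction", {
  va <- variability(build_tfa(rev_chain(30)), fluxes = "C1")
  expect_lt(va$max, 1e-9)    # forward thermodynamically blocked
  expect_lt(va$min, -1e-6)   # backward still open
  # at DrG'0 = 0 with symmetric concentration bounds both directions remain
  va0 <- variability(build_tfa(rev_chain(0)), fluxes = "C1")
  expect_gt(va0$max, 1e-6)
  expect_lt(va0$min, -1e-6)
})

test_that("TVA ranges are contained in FVA ranges and thermodynamics removes directions", {
  m <- d2_model()
  fva <- variability(build_fba(m))
  tva <- variability(d2_tfa())
  expect_true(all(tva$min >= fva$min - 1e-6))
  expect_true(all(tva$max <= fva$max + 1e-6))
  # direction removal: on the reversible chain the -30 kJ/mol step loses its
  # backward direction under TFA while plain FVA keeps every step reversible
  m3 <- rev_chain(-30)
  fva3 <- variability(build_fba(m3))
  tva3 <- variability(build_tfa(m3))
  expect_lt(sum(tva3$bidirectional), sum(fva3$bidirectional))
  expect_false(tva3$bidirectional[tva3$variable == "C1"])
})

test_that("metabolite measurements never widen variability and can fix a direction", {
  m <- d2_model()
  base <- variability(d2_tfa())
  meas <- measurement_table(
    concentrations = data.frame(group = c("glcn", "atp"),
                                lb = c(1e-5, 1e-3), ub = c(5e-5, 5e-3)))
  with_meas <- variability(build_tfa(m, measurements = meas))
  expect_true(all(with_meas$min >= base$min - 1e-6))
  expect_true(all(with_meas$max <= base$max + 1e-6))
  expect_lte(sum(with_meas$bidirectional), sum(base$bidirectional))
})

test_that("thermodynamics only restricts: minimal uptake under TFA >= under FBA", {
  m <- d2_model()
  fix_growth <- function(p) {
    apply_flux_bounds(p, "BIOMASS", lb = 0.5)
    p
  }
  pf <- fix_growth(build_fba(m)); pt <- fix_growth(build_tfa(m))
  # uptake is -EX_glc: minimizing uptake = maximizing the exchange flux
  min_up_fba <- -solve_problem(pf, "EX_glc", "max")$objective
  min_up_tfa <- -solve_problem(pt, "EX_glc", "max")$objective
  expect_gte(min_up_tfa, min_up_fba - 1e-8)
})

test_that("every TFA solution satisfies the FBA constraint set and DrG' signs", {
  m <- d2_model()
  sol <- solve_problem(d2_tfa(), NULL, "max")
  expect_identical(sol$status, "optimal")
  N <- stoichiometric_matrix(m)
  expect_lt(max(abs(N %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= m$reactions$lb - 1e-6))
  expect_true(all(sol$fluxes <= m$reactions$ub + 1e-6))
  active <- names(sol$drG)[abs(sol$fluxes[names(sol$drG)]) > 1e-6]
  expect_true(all(sign(sol$fluxes[active]) == -sign(sol$drG[active])))
})

test_that("solving is deterministic", {
  p <- d2_tfa()
  o1 <- solve_problem(p, NULL, "max")$objective
  o2 <- solve_problem(p, NULL, "max")$objective
  expect_equal(o1, o2, tolerance = 1e-9)
})

test_that("total-flux minimization silences futile cycles and fixes directions", {
  # the branched toy plus a two-reaction futile cycle
  m <- metabolic_model(
    compartments = data.frame(id = c("c", "e"), volume_fraction = c(1, 1),
                              extracellular = c(FALSE, TRUE)),
    species = data.frame(id = c("A_e", "A_c", "B_c", "B_e"),
                         compartment = c("e", "c", "c", "e")),
    reactions = data.frame(
      id = c("UP", "P1", "P2", "OUT", "EX_A", "EX_B", "CYC1", "CYC2"),
      lb = c(0, 0, 0, 0, -10, 0, 0, 0),
      ub = c(10, 100, 100, 100, 0, 100, 100, 100),
      drG0 = c(NA, -10, -12, NA, NA, NA, -1, -1),
      drG0_err = 0,
      is_exchange = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)),
    stoichiometry = list(UP = c(A_e = -1, A_c = 1),
                         P1 = c(A_c = -1, B_c = 1),
                         P2 = c(A_c = -2, B_c = 1),
                         OUT = c(B_c = -1, B_e = 1),
                         EX_A = c(A_e = -1),
                         EX_B = c(B_e = -1),
                         CYC1 = c(A_c = -1, B_c = 1),
                         CYC2 = c(B_c = -1, A_c = 1)),
    objective = "OUT", name = "cycle_toy")
  sol <- fix_directionalities_by_min_total_flux(build_tfa(m), 0.99)
  expect_identical(sol$status, "optimal")
  expect_lt(abs(sol$fluxes["CYC1"]), 1e-6)
  expect_lt(abs(sol$fluxes["CYC2"]), 1e-6)
  expect_identical(nrow(sol$fixed_directions), nrow(m$reactions))
  # growth_fraction = 1 still feasible at a degenerate optimum
  sol1 <- fix_directionalities_by_min_total_flux(build_tfa(m), 1.0)
  expect_identical(sol1$status, "optimal")
})

test_that("knockouts distinguish cut vertices from bypassed reactions", {
  m <- d2_model()
  p <- d2_tfa()
  wt <- solve_problem(p, NULL, "max")$objective
  # GLCtex is the only glucose entry: a cut vertex
  expect_true(knockout(p, "GLCtex", wildtype_growth = wt)$essential)
  # the hexokinase route has the oxidative bypass
  expect_false(knockout(p, "HEX1", wildtype_growth = wt)$essential)
  expect_error(knockout(p, "NOPE"), "unknown reaction")
})

test_that("transketolase directionality gates ED-branch essentiality", {
  m <- d2_model()
  # TKT2 free to produce triose phosphate: ED knockouts are bypassed
  p_free <- d2_tfa()
  wt <- solve_problem(p_free, NULL, "max")$objective
  expect_false(knockout(p_free, "EDD", wildtype_growth = wt)$essential)
  expect_false(knockout(p_free, "EDA", wildtype_growth = wt)$essential)
  # TKT2 forced towards consumption of triose phosphate: both essential
  m_cons <- set_reaction_bounds(m, "TKT2", ub = 0)
  p_cons <- build_tfa(m_cons)
  wt2 <- solve_problem(p_cons, NULL, "max")$objective
  expect_true(knockout(p_cons, "EDD", wildtype_growth = wt2)$essential)
  expect_true(knockout(p_cons, "EDA", wildtype_growth = wt2)$essential)
})

test_that("gene knockouts work through boolean rules", {
  m <- branch_toy()
  m$reactions$gene_rule <- c("gUP", "gP1a and gP1b", "gP2", NA, NA, NA)
  p <- build_fba(m)
  wt <- solve_problem(p, NULL, "max")$objective
  # losing one subunit of the efficient branch leaves the wasteful branch
  k <- knockout(p, "gP1a", type = "gene", wildtype_growth = wt)
  expect_identical(k$disabled_reactions, "P1")
  expect_false(k$essential)
  expect_equal(k$growth, 5, tolerance = 1e-8)  # half yield through P2
  expect_true(knockout(p, "gUP", type = "gene",
                       wildtype_growth = wt)$essential)
  expect_error(knockout(p, "nope", type = "gene"), "unknown gene")
})

test_that("variability can pin the objective to a fraction of its optimum", {
  m <- branch_toy()
  va <- variability(build_fba(m), fluxes = c("P1", "P2"),
                    fix_objective_fraction = 1.0)
  # at the full optimum only the efficient branch can carry flux
  expect_equal(va$min[va$variable == "P1"], 10, tolerance = 1e-8)
  expect_equal(va$max[va$variable == "P2"], 0, tolerance = 1e-8)
})
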