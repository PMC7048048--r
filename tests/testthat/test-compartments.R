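# Compartment-resolved integration of whole-cell measurements.

test_that("per-compartment bound formulas match hand evaluation", {
  # upper bound, cytosol-sized fraction: (10 - 0.12*0.001)/0.88 mM
  expect_equal(per_compartment_upper(10e-3, 0.88), 11.36350e-3,
               tolerance = 1e-6)
  # a small compartment is clipped at the physiological ceiling
  expect_equal(per_compartment_upper(50e-3, 0.12), 50e-3)
  # single compartment: identity
  expect_equal(per_compartment_upper(10e-3, 1), 10e-3)
  expect_equal(per_compartment_lower(10e-3, 1), 10e-3)
  # lower bound clipped at the floor when the rest of the cell can carry it
  expect_equal(per_compartment_lower(1e-3, 0.12), 1e-6)
  # lower bound, hand evaluation: (45 - 0.12*50)/0.88 mM
  expect_equal(per_compartment_lower(45e-3, 0.88), 44.31818e-3,
               tolerance = 1e-6)
  expect_error(per_compartment_upper(1e-3, 0), "positive")
  expect_error(per_compartment_lower(1e-3, 0), "positive")
})

test_that("derived bounds are always ordered", {
  set.seed(11)
  for (i in 1:200) {
    alpha <- runif(1, 0.05, 1)
    lo <- runif(1, 1e-6, 4e-2)
    hi <- runif(1, lo, 5e-2)
    expect_lte(per_compartment_lower(lo, alpha),
               per_compartment_upper(hi, alpha) + 1e-15)
  }
})

test_that("a dual-compartment metabolite emits i + 2 constraints", {
  cm <- compartment_measurement(
    "glc", 1e-3, 10e-3,
    members = data.frame(species = c("glc_c", "glc_p"),
                         alpha = c(0.88, 0.12)))
  expect_identical(cm$n_constraints, 4L)
  blk <- emit_constraints(cm)
  expect_identical(nrow(blk$member_bounds), 2L)
  expect_named(blk$jensen, c("UM_glc", "U_glc_c", "U_glc_p"))
  expect_equal(unname(blk$jensen), c(1, -0.88, -0.12))
  expect_equal(unname(blk$whole_cell), log(c(1e-3, 10e-3)))

  # single compartment: the block degenerates to the plain measured bound
  cs <- compartment_measurement(
    "atp", 1e-3, 5e-3, members = data.frame(species = "atp_c", alpha = 0.88))
  expect_identical(cs$n_constraints, 3L)
  b1 <- emit_constraints(cs)
  expect_equal(b1$member_bounds$lb_ln, log(1e-3))
  expect_equal(b1$member_bounds$ub_ln, log(5e-3))
})

test_that("the Jensen inequality holds at the worked example", {
  # alpha = (0.88, 0.12), compartment values 1 and 10 mM
  alpha <- c(0.88, 0.12); conc <- c(1e-3, 10e-3)
  whole <- sum(alpha * conc)
  expect_equal(whole, 2.08e-3, tolerance = 1e-9)
  geo <- exp(sum(alpha * log(conc)))
  expect_equal(geo, 1.318e-3, tolerance = 1e-3)
  expect_lte(geo, whole)
  cm <- compartment_measurement(
    "x", 1.5e-3, 3e-3,
    members = data.frame(species = c("x_c", "x_p"), alpha = alpha))
  expect_true(constraints_satisfied(cm, c(x_c = 1e-3, x_p = 10e-3)))
})

test_that("any ground-truth assignment inside the measured range satisfies the constraints", {
  # the validity property behind the relaxation, sampled densely
  set.seed(5)
  cm <- compartment_measurement(
    "m", 0.8e-3, 6e-3,
    members = data.frame(species = c("m_c", "m_p"), alpha = c(0.88, 0.12)))
  n <- 10000
  c1 <- exp(runif(n, log(1e-6), log(5e-2)))
  c2 <- exp(runif(n, log(1e-6), log(5e-2)))
  whole <- 0.88 * c1 + 0.12 * c2
  keep <- whole >= cm$lb & whole <= cm$ub
  u1 <- log(c1[keep]); u2 <- log(c2[keep]); um <- log(whole[keep])
  ok <- u1 >= log(cm$members$lb[1]) - 1e-12 &
        u1 <= log(cm$members$ub[1]) + 1e-12 &
        u2 >= log(cm$members$lb[2]) - 1e-12 &
        u2 <= log(cm$members$ub[2]) + 1e-12 &
        um - (0.88 * u1 + 0.12 * u2) >= -1e-12
  expect_gt(sum(keep), 100)
  expect_true(all(ok))
})

test_that("the scheme strictly relaxes the shared-concentration assumption", {
  cm <- compartment_measurement(
    "m", 1e-3, 5e-3,
    members = data.frame(species = c("m_c", "m_p"), alpha = c(0.88, 0.12)))
  # every shared-value assignment inside the measured window satisfies it
  for (v in seq(1e-3, 5e-3, length.out = 20))
    expect_true(constraints_satisfied(cm, c(m_c = v, m_p = v)))
  # and some genuinely unequal assignment is feasible too, which the
  # shared-concentration scheme would forbid
  uneq <- c(m_c = 0.6e-3, m_p = 20e-3)
  whole <- sum(c(0.88, 0.12) * uneq)
  expect_true(whole >= cm$lb && whole <= cm$ub)
  expect_true(constraints_satisfied(cm, uneq))
  expect_true(uneq["m_c"] < cm$lb || uneq["m_p"] > cm$ub)
})

test_that("integration counts match the bookkeeping of dual-compartment groups", {
  # synthetic table: 5 groups of which 2 dual -> 5*1 + 2 extra variables
  m <- d2_model()
  meas <- measurement_table(concentrations = data.frame(
    group = c("glc", "glcn", "atp", "pyr", "g3p"),
    lb = rep(1e-4, 5), ub = rep(1e-3, 5)))
  p <- build_tfa(m, measurements = meas)
  s <- integration_summary(p)
  expect_identical(s$n_groups, 5L)
  expect_identical(s$n_dual, 2L)
  expect_identical(s$n_constrained_variables, 7L)
  # dual groups add exactly one Jensen row and one auxiliary variable each
  expect_identical(sum(grepl("^jensen_", vapply(p$lp$rows, `[[`, "", "name"))),
                   2L)
  expect_identical(sum(grepl("^UM_", p$lp$var_name)), 2L)
})

test_that("the wild-type-scale bookkeeping reproduces 57 measurements -> 69 variables", {
  # a model shaped like the paper's count: 57 measured groups, 12 of them in
  # two compartments
  n_single <- 45; n_dual <- 12
  singles <- sprintf("ms%02d", seq_len(n_single))
  duals <- sprintf("md%02d", seq_len(n_dual))
  species <- rbind(
    data.frame(id = paste0(singles, "_c"), compartment = "c",
               whole_cell_group = singles),
    data.frame(id = paste0(duals, "_c"), compartment = "c",
               whole_cell_group = duals),
    data.frame(id = paste0(duals, "_p"), compartment = "p",
               whole_cell_group = duals))
  # one big annotated sink reaction so every species is used and TFA builds
  all_ids <- species$id
  stoich <- list(SINK = stats::setNames(rep(-1, length(all_ids)), all_ids),
                 SRC = stats::setNames(rep(1, length(all_ids)), all_ids))
  model <- metabolic_model(
    compartments = data.frame(id = c("c", "p"),
                              volume_fraction = c(0.88, 0.12),
                              extracellular = FALSE),
    species = species,
    reactions = data.frame(id = c("SINK", "SRC"), lb = 0, ub = 10,
                           drG0 = c(-10, NA), drG0_err = 0),
    stoichiometry = stoich, objective = "SINK", name = "count57")
  meas <- measurement_table(concentrations = data.frame(
    group = c(singles, duals), lb = 1e-4, ub = 1e-3))
  p <- build_tfa(model, measurements = meas)
  s <- integration_summary(p)
  expect_identical(s$n_groups, 57L)
  expect_identical(s$n_dual, 12L)
  expect_identical(s$n_constrained_variables, 69L)
})

test_that("clipping and missing groups are reported, not fatal", {
  expect_warning(
    compartment_measurement("big", 1e-3, 0.2,
                            members = data.frame(species = "x_c", alpha = 1)),
    "clipped")
  m <- d2_model()
  meas <- measurement_table(concentrations = data.frame(
    group = "not_a_group", lb = 1e-4, ub = 1e-3))
  expect_warning(p <- build_tfa(m, measurements = meas), "skipped")
  expect_identical(integration_summary(p)$n_groups, 0L)
})

test_that("alpha renormalization over member compartments is enforced", {
  cm <- compartment_measurement(
    "glc", 1e-3, 10e-3,
    members = data.frame(species = c("glc_c", "glc_p"),
                         alpha = c(0.66, 0.12)))
  expect_equal(sum(cm$members$alpha), 1)
  cm$members$alpha <- c(0.7, 0.2)
  expect_error(emit_constraints(cm), "sum to 1")
})
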