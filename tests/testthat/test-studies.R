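# Study orchestration: wild-type preconfiguration, sweeps, grids,
# consistency checks, stress control analysis.

test_that("the free-diffusion rule adds exports for small carbon metabolites only", {
  m <- d2_model()
  cfg <- wildtype_config(forced_secretion = data.frame(
    reaction = c("GLCNtex", "DHGtex"), lb = 0.3))
  suppressWarnings(p <- preconfigure_wildtype(m, cfg, d2_measurements()))
  # pyruvate (C3, no transporter) qualifies; cytosolic sugars too
  expect_true("DIFF_pyr_c" %in% p$wildtype_report)
  # phosphate- and CoA-carrying metabolites are excluded
  expect_false(any(grepl("g6p|pgc|kdpg|ru5p|g3p|atp|adp|accoa",
                         p$wildtype_report)))
  # species with a transport route are not duplicated
  expect_false("DIFF_glc_p" %in% p$wildtype_report)
  # species without formulas are skipped with a warning
  w <- capture_warnings(preconfigure_wildtype(m, cfg))
  expect_true(any(grepl("without formula", w)))
  # the configured problem supports growth and keeps the measurement report
  sol <- solve_problem(p, NULL, "max")
  expect_identical(sol$status, "optimal")
  expect_gt(sol$objective, 0.1)
  expect_gt(integration_summary(p)$n_groups, 0)
  # forced secretions are active
  expect_gte(sol$fluxes["GLCNtex"], 0.3 - 1e-9)
  # the truth concentrations satisfy every emitted measurement block
  truth <- d2_truth()
  rp <- p$report
  for (g in unique(rp$group)) {
    mem <- rp[rp$group == g, ]
    lo <- d2_measurements()$concentrations
    lo <- lo[lo$group == g, ]
    cm <- compartment_measurement(g, lo$lb, lo$ub,
                                  data.frame(species = mem$species,
                                             alpha = mem$alpha))
    expect_true(constraints_satisfied(cm, truth$conc[mem$species]))
  }
})

test_that("an assumption referencing an absent reaction warns and is skipped", {
  m <- d2_model()
  cfg <- wildtype_config(directionality = data.frame(reaction = "NOPE",
                                                     lb = 0, ub = 0))
  w <- capture_warnings(p <- preconfigure_wildtype(m, cfg))
  expect_true(any(grepl("absent reaction", w)))
  # the problem is still built and solvable
  expect_s3_class(p, "tk_problem")
})

test_that("the ATP-demand sweep reproduces the stress-profile shape", {
  m <- set_reaction_bounds(d2_model(), "EX_glc", lb = -100)
  p <- build_tfa(m)
  cfg <- stress_config(atpm_grid = seq(0, 100, by = 5))
  prof <- atp_demand_sweep(p, cfg)
  expect_s3_class(prof, "tk_study_profile")
  feas <- prof[prof$feasible, ]
  expect_gt(nrow(feas), 10)
  # the far end of the grid is infeasible and flagged, not an error
  expect_true(any(!prof$feasible))
  ipk <- which.max(feas$glucose_uptake)
  # pre-peak: minimal glucose uptake rises monotonically with ATP demand
  expect_true(all(diff(feas$glucose_uptake[1:ipk]) > -1e-6))
  # growth holds at the cap early on, then declines after the caps bind
  expect_equal(feas$growth[1],
               cfg$growth_fraction * cfg$growth_max, tolerance = 1e-6)
  expect_true(all(diff(feas$growth) < 1e-6))
  expect_lt(feas$growth[nrow(feas)], feas$growth[1] - 0.1)
  # post-peak the required uptake declines
  if (ipk < nrow(feas))
    expect_true(all(diff(feas$glucose_uptake[ipk:nrow(feas)]) < 1e-6))
  # at the peak a capacity cap is binding
  expect_true(abs(feas$atp_synthase[ipk] - cfg$atps_max) < 1e-4 ||
                abs(feas$o2_uptake[ipk] - cfg$o2_max) < 1e-4)
  # an unstressed grid point equals the direct two-stage computation
  direct <- atp_demand_sweep(p, stress_config(atpm_grid = c(0, 1)))
  expect_equal(prof$glucose_uptake[1], direct$glucose_uptake[1],
               tolerance = 1e-8)
})

test_that("the sensitivity grid resolves which cap sets the peak", {
  m <- set_reaction_bounds(d2_model(), "EX_glc", lb = -100)
  p <- build_tfa(m)
  cfg <- stress_config(atpm_grid = seq(0, 90, by = 5))
  # in this network ATP synthase flux is half the ETC oxygen-equivalent:
  # an O2 cap of 30 binds before ATPS caps of 70 or 80 do
  g <- sensitivity_grid(p, o2_grid = 30, atps_grid = c(70, 80), cfg)
  expect_equal(g$peak_glucose_uptake[1], g$peak_glucose_uptake[2],
               tolerance = 1e-6)
  # when the ATPS cap binds first, raising it moves the peak to higher
  # ATP hydrolysis
  g2 <- sensitivity_grid(p, o2_grid = 40, atps_grid = c(50, 70), cfg)
  expect_gt(g2$atpm_at_peak[2], g2$atpm_at_peak[1])
  # a 1x1 grid reduces to the sweep peak
  g3 <- sensitivity_grid(p, o2_grid = 40, atps_grid = 70, cfg)
  prof <- atp_demand_sweep(p, stress_config(atpm_grid = seq(0, 90, by = 5),
                                            o2_max = 40, atps_max = 70))
  expect_equal(g3$peak_glucose_uptake,
               max(prof$glucose_uptake[prof$feasible]), tolerance = 1e-8)
})

test_that("a model checks out as consistent with itself", {
  m <- d2_model()
  rep <- consistency_checks(m, m, uptake = list(reaction = "EX_glc",
                                                value = -10))
  expect_equal(rep$growth_reduced, rep$growth_reference, tolerance = 1e-8)
  expect_length(rep$essential_reduced_only, 0)
  expect_length(rep$essential_reference_only, 0)
  expect_equal(rep$variability_reduced$min, rep$variability_reference$min,
               tolerance = 1e-6)
  expect_length(rep$less_flexible, 0)
})

test_that("removing a bypass shows up as reduced-only essentiality and lost flexibility", {
  ref_model <- d2_model()
  # drop the ABC importer: the oxidative (gluconate) route must carry all flux
  keep <- ref_model$reactions$id != "GLCabc"
  red <- ref_model
  red$reactions <- red$reactions[keep, ]
  red$stoich <- red$stoich[keep]
  rep <- consistency_checks(red, ref_model,
                            uptake = list(reaction = "EX_glc", value = -10))
  # with the ABC importer gone, periplasmic glucose oxidation is the only
  # entry, so the dehydrogenase becomes essential in the reduced model only
  # (gluconate phosphorylation itself keeps its ketogluconate bypass)
  expect_true("GLCDpp" %in% rep$essential_reduced_only)
  expect_false("GLCDpp" %in% rep$essential_both)
  expect_length(rep$essential_reference_only, 0)
  # a sub-network can only lose flexibility, never gain it
  expect_true(all(rep$variability_reduced$min >=
                    rep$variability_reference$min - 1e-6))
  expect_true(all(rep$variability_reduced$max <=
                    rep$variability_reference$max + 1e-6))
})

test_that("knockout-response fractions equal a brute-force recount", {
  ens <- d2_ensemble_1k()
  enzymes <- c("GLCtex", "GLCDpp", "GNK", "EDD", "EDA")
  st <- knockout_response_study(ens, enzymes,
                                targets = c("GLCtex", "BIOMASS"),
                                reference_signs = 1)
  expect_identical(nrow(st$summary), 2L * length(enzymes))
  manual <- rep(TRUE, ens$n)
  for (tg in c("GLCtex", "BIOMASS")) for (e in enzymes)
    manual <- manual & (sign(ens$CJ[tg, e, ]) == 1)
  expect_equal(st$fraction_all, mean(manual))
  expect_gte(min(st$fraction_by_target), st$fraction_all)
  # empty specification: every member consistent
  st0 <- knockout_response_study(ens, enzymes,
                                 targets = c("GLCtex", "BIOMASS"),
                                 reference_signs = data.frame(
                                   target = character(0),
                                   enzyme = character(0),
                                   sign = numeric(0)))
  expect_equal(st0$fraction_all, 1.0)
  expect_error(knockout_response_study(ens, "NOPE", targets = "BIOMASS"),
               "not in the kinetic network")
})

test_that("stress control study correlates growth and ATP control", {
  ens <- d2_ensemble_1k()
  st <- stress_control_study(ens, growth = "BIOMASS", atp_species = "atp_c")
  expect_identical(names(st$table),
                   c("enzyme", "growth_control", "atp_control",
                     "sign_consistent"))
  # ranking by |growth control| is honored
  expect_true(all(diff(abs(st$table$growth_control)) <= 1e-12))
  # the correlation equals its closed-form recomputation
  top <- head(st$table, 10)
  x <- top$growth_control; y <- top$atp_control
  pearson_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(st$pearson, pearson_manual, tolerance = 1e-12)
  # a ensemble constructed with ATP control proportional to growth control
  # correlates perfectly
  ens2 <- ens
  ens2$CX["atp_c", , ] <- 2 * ens2$CJ["BIOMASS", , ]
  st2 <- stress_control_study(ens2, growth = "BIOMASS",
                              atp_species = "atp_c")
  expect_equal(st2$pearson, 1.0, tolerance = 1e-12)
  expect_true(all(st2$table$sign_consistent |
                    st2$table$growth_control == 0))
  expect_error(stress_control_study(ens, atp_species = "nope_c"),
               "not in the kinetic network")
})
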