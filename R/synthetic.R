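# Synthetic network and data generation.
#
# Every input the pipeline consumes can be generated here with known ground
# truth: a two-compartment toy network shaped like the central carbon
# metabolism of a glucose-grown pseudomonad (periplasmic oxidative route,
# ED-like and EMP-like catabolic branches joined by a transketolase-like
# shunt, a TCA-like cycle with oxidative phosphorylation, an ATP maintenance
# drain and a biomass reaction), whole-cell concentration measurements, a
# planted gap-filling instance, and a fully specified nonlinear kinetic model
# used as oracle.

#' Specification for the synthetic generators
#'
#' @param seed integer; all generators are deterministic given the seed.
#' @param topology `"d2_mini"` (two-compartment central-carbon toy) or
#'   `"chain"` (linear pathway).
#' @param fractions named volume fractions of the intracellular compartments
#'   (cytosol/periplasm defaults 0.88/0.12).
#' @param palette DrG'0 palette in kJ/mol: near-equilibrium, moderate and
#'   strongly favorable reaction classes.
#' @param drg_jitter half-width of the uniform jitter added to palette
#'   values, kJ/mol.
#' @param noise_sd_log10 log10-scale standard deviation of the multiplicative
#'   measurement noise.
#' @param chain_length number of internal reactions for the chain topology.
#' @param n_decoys decoy candidate reactions for the planted gap-fill.
#' @return a `tk_synth_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, topology = c("d2_mini", "chain"),
                           fractions = c(c = 0.88, p = 0.12),
                           palette = c(near = -1, moderate = -10,
                                       strong = -30),
                           drg_jitter = 0.5,
                           noise_sd_log10 = 0.1,
                           chain_length = 5L,
                           n_decoys = 10L) {
  structure(list(seed = as.integer(seed), topology = match.arg(topology),
                 fractions = fractions, palette = palette,
                 drg_jitter = drg_jitter, noise_sd_log10 = noise_sd_log10,
                 chain_length = as.integer(chain_length),
                 n_decoys = as.integer(n_decoys)),
            class = "tk_synth_spec")
}

#' Generate a synthetic metabolic network
#'
#' The `d2_mini` preset builds a ~31-reaction, two-compartment model: glucose
#' enters the periplasm and is either oxidized to (keto)gluconate before
#' phosphorylation (the oxidative route through analogs of GLCDpp, GAD2ktpp,
#' GNK) or imported and phosphorylated directly (HEX1 analog); both routes
#' meet at 6-phosphogluconate, which feeds an ED-like branch (EDD/EDA) and a
#' pentose-phosphate-like branch whose transketolase analog (TKT2) gates
#' whether triose phosphate can be replenished without the ED branch. A
#' TCA-like cycle, an electron transport chain with an ATP synthase analog,
#' an ATP hydrolysis (maintenance) reaction, oxygen uptake and by-product
#' secretion routes complete the network. DrG'0 values are drawn from the
#' palette with a seeded jitter; topology is seed-independent.
#'
#' @param spec a `tk_synth_spec`.
#' @return a validated `tk_model`.
#' @export
generate_network <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  model <- switch(spec$topology,
                  chain = chain_network(spec),
                  d2_mini = d2_mini_network(spec))
  validate_model(model)
  model
}

chain_network <- function(spec) {
  n <- spec$chain_length
  stopifnot(n >= 2)
  internal <- paste0("S", seq_len(n - 1), "_c")
  species <- data.frame(
    id = c("S0_e", internal, paste0("S", n, "_e")),
    compartment = c("e", rep("c", n - 1), "e"),
    whole_cell_group = c(NA, paste0("S", seq_len(n - 1)), NA),
    formula = c("C3H6O3", rep("C3H6O3", n - 1), "C3H6O3"))
  rx_ids <- c("T_in", if (n > 2) paste0("C", seq_len(n - 2)), "T_out",
              "EX_in", "EX_out")
  stoich <- c(
    list(T_in = c(S0_e = -1, S1_c = 1)),
    if (n > 2) stats::setNames(lapply(seq_len(n - 2), function(k)
      stats::setNames(c(-1, 1), paste0("S", c(k, k + 1), "_c"))),
      paste0("C", seq_len(n - 2))),
    list(T_out = stats::setNames(c(-1, 1), c(paste0("S", n - 1, "_c"),
                                             paste0("S", n, "_e"))),
         EX_in = c(S0_e = -1),
         EX_out = stats::setNames(-1, paste0("S", n, "_e"))))
  jit <- stats::runif(n, -spec$drg_jitter, spec$drg_jitter)
  reactions <- data.frame(
    id = rx_ids,
    lb = c(rep(0, n), -10, 0),
    ub = c(rep(100, n), 0, 100),
    drG0 = c(spec$palette[["moderate"]] + jit, NA, NA),
    drG0_err = 0,
    is_transport = c(TRUE, rep(FALSE, n - 2), TRUE, FALSE, FALSE),
    is_exchange = c(rep(FALSE, n), TRUE, TRUE))
  metabolic_model(
    compartments = data.frame(id = c("c", "e"), volume_fraction = c(1, 1),
                              extracellular = c(FALSE, TRUE)),
    species = species, reactions = reactions, stoichiometry = stoich,
    objective = "T_out", name = sprintf("chain%d", n))
}

d2_mini_network <- function(spec) {
  vf <- spec$fractions
  compartments <- data.frame(
    id = c("c", "p", "e"),
    name = c("cytosol", "periplasm", "extracellular"),
    volume_fraction = c(vf[["c"]], vf[["p"]], 1),
    extracellular = c(FALSE, FALSE, TRUE))

  sp <- function(id, comp, group = NA, formula = NA)
    data.frame(id = id, compartment = comp, whole_cell_group = group,
               formula = formula)
  species <- rbind(
    sp("glc_e", "e", NA, "C6H12O6"),
    sp("o2_e", "e", NA, "O2"),
    sp("co2_e", "e", NA, "CO2"),
    sp("glcn_e", "e", NA, "C6H12O7"),
    sp("dhg_e", "e", NA, "C6H10O7"),
    sp("glc_p", "p", "glc", "C6H12O6"),
    sp("glcn_p", "p", "glcn", "C6H12O7"),
    sp("dhg_p", "p", "dhg", "C6H10O7"),
    sp("glc_c", "c", "glc", "C6H12O6"),
    sp("glcn_c", "c", "glcn", "C6H12O7"),
    sp("dhg_c", "c", "dhg", "C6H10O7"),
    sp("g6p_c", "c", "g6p", "C6H13O9P"),
    sp("pgc_c", "c", "6pgc", "C6H13O10P"),
    sp("kdpg_c", "c", "kdpg", "C6H11O9P"),
    sp("ru5p_c", "c", "ru5p", "C5H11O8P"),
    sp("g3p_c", "c", "g3p", "C3H7O6P"),
    sp("pyr_c", "c", "pyr", "C3H4O3"),
    sp("accoa_c", "c", "accoa", "C23H38N7O17P3S"),
    sp("atp_c", "c", "atp", "C10H16N5O13P3"),
    sp("adp_c", "c", "adp", "C10H15N5O10P2"),
    sp("nad_c", "c", NA, NA),
    sp("nadh_c", "c", NA, NA),
    sp("nadp_c", "c", NA, NA),
    sp("nadph_c", "c", NA, NA),
    sp("pmf_c", "c", NA, NA),
    sp("o2_c", "c", NA, "O2"),
    sp("co2_c", "c", NA, "CO2"))

  # id, stoichiometry, lb, ub, palette class (NA = unannotated),
  # transport flag, exchange flag
  defs <- list(
    list("EX_glc", c(glc_e = -1), -10, 0, NA, FALSE, TRUE),
    list("EX_o2", c(o2_e = -1), -100, 0, NA, FALSE, TRUE),
    list("EX_co2", c(co2_e = -1), 0, 100, NA, FALSE, TRUE),
    list("EX_glcn", c(glcn_e = -1), 0, 100, NA, FALSE, TRUE),
    list("EX_dhg", c(dhg_e = -1), 0, 100, NA, FALSE, TRUE),
    list("GLCtex", c(glc_e = -1, glc_p = 1), 0, 100, "near", TRUE, FALSE),
    list("GLCabc", c(glc_p = -1, atp_c = -1, glc_c = 1, adp_c = 1),
         0, 100, "moderate", TRUE, FALSE),
    list("GLCDpp", c(glc_p = -1, glcn_p = 1), 0, 100, "strong", FALSE, FALSE),
    list("GAD2ktpp", c(glcn_p = -1, dhg_p = 1), 0, 100, "moderate",
         FALSE, FALSE),
    list("GLCNt2rpp", c(glcn_p = -1, glcn_c = 1), -100, 100, "near",
         TRUE, FALSE),
    list("DHGt", c(dhg_p = -1, dhg_c = 1), -100, 100, "near", TRUE, FALSE),
    list("GNK", c(glcn_c = -1, atp_c = -1, pgc_c = 1, adp_c = 1),
         0, 100, "moderate", FALSE, FALSE),
    list("KGUK", c(dhg_c = -1, atp_c = -1, nadph_c = -1,
                   pgc_c = 1, adp_c = 1, nadp_c = 1),
         0, 100, "moderate", FALSE, FALSE),
    list("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
         0, 100, "moderate", FALSE, FALSE),
    list("G6PDH", c(g6p_c = -1, nadp_c = -1, pgc_c = 1, nadph_c = 1),
         0, 100, "moderate", FALSE, FALSE),
    list("EDD", c(pgc_c = -1, kdpg_c = 1), 0, 100, "moderate", FALSE, FALSE),
    list("EDA", c(kdpg_c = -1, pyr_c = 1, g3p_c = 1), 0, 100, "moderate",
         FALSE, FALSE),
    list("GND", c(pgc_c = -1, nadp_c = -1, ru5p_c = 1, co2_c = 1,
                  nadph_c = 1), 0, 100, "moderate", FALSE, FALSE),
    list("TKT2", c(ru5p_c = -1, g3p_c = 1, co2_c = 2), -100, 100, "near",
         FALSE, FALSE),
    list("GAPD", c(g3p_c = -1, adp_c = -2, nad_c = -1,
                   pyr_c = 1, atp_c = 2, nadh_c = 1),
         0, 100, "strong", FALSE, FALSE),
    list("PDH", c(pyr_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1,
                  nadh_c = 1), 0, 100, "strong", FALSE, FALSE),
    list("TCA", c(accoa_c = -1, nad_c = -3, adp_c = -1,
                  co2_c = 2, nadh_c = 3, atp_c = 1),
         0, 100, "strong", FALSE, FALSE),
    list("ETC", c(nadh_c = -1, o2_c = -0.5, nad_c = 1, pmf_c = 3),
         0, 100, "strong", FALSE, FALSE),
    list("ATPS", c(pmf_c = -3, adp_c = -1, atp_c = 1), 0, 70, "moderate",
         FALSE, FALSE),
    list("THD", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
         -100, 100, "near", FALSE, FALSE),
    list("ATPM", c(atp_c = -1, adp_c = 1), 0, 100, "strong", FALSE, FALSE),
    list("O2t", c(o2_e = -1, o2_c = 1), 0, 100, "near", TRUE, FALSE),
    list("CO2t", c(co2_c = -1, co2_e = 1), -100, 100, "near", TRUE, FALSE),
    list("GLCNtex", c(glcn_p = -1, glcn_e = 1), 0, 100, "near", TRUE, FALSE),
    list("DHGtex", c(dhg_p = -1, dhg_e = 1), 0, 100, "near", TRUE, FALSE),
    list("BIOMASS", c(g3p_c = -3, pyr_c = -5, accoa_c = -3, ru5p_c = -2,
                      atp_c = -60, nadph_c = -15, adp_c = 60, nadp_c = 15),
         0, 10, NA, FALSE, FALSE))

  ids <- vapply(defs, `[[`, character(1), 1)
  classes <- vapply(defs, function(d) as.character(d[[5]]), character(1))
  jit <- stats::runif(length(defs), -spec$drg_jitter, spec$drg_jitter)
  drg0 <- ifelse(is.na(classes), NA_real_,
                 spec$palette[classes] + jit)
  reactions <- data.frame(
    id = ids,
    lb = vapply(defs, function(d) d[[3]], numeric(1)),
    ub = vapply(defs, function(d) d[[4]], numeric(1)),
    drG0 = drg0,
    drG0_err = 0,
    subsystem = NA_character_,
    is_transport = vapply(defs, `[[`, logical(1), 6),
    is_exchange = vapply(defs, `[[`, logical(1), 7))
  stoich <- stats::setNames(lapply(defs, `[[`, 2), ids)
  metabolic_model(compartments = compartments, species = species,
                  reactions = reactions, stoichiometry = stoich,
                  objective = "BIOMASS", name = "d2_mini")
}

#' Generate whole-cell concentration measurements from a ground truth
#'
#' Whole-cell values are computed as the volume-weighted mean of the true
#' per-compartment concentrations, perturbed with log-normal noise, and
#' widened into a [lower, upper] interval. Intervals always contain the true
#' whole-cell value (noise shifts their midpoint, not their validity), so
#' the ground-truth state stays feasible for any problem built on the
#' generated measurements.
#'
#' @param truth a `tk_ground_truth` from [generate_ground_truth_kinetics()].
#' @param spec the `tk_synth_spec` (noise level, seed).
#' @param groups which whole-cell groups to measure; default every group
#'   whose member species all have a true concentration.
#' @param width multiplicative half-width of the emitted interval (the
#'   interval is `value / width` to `value * width`).
#' @return a `tk_measurements` with one concentration row per group.
#' @export
generate_measurements <- function(truth, spec, groups = NULL, width = 1.5) {
  model <- truth$model
  set.seed(spec$seed + 1L)
  ex_comp <- model$compartments$id[model$compartments$extracellular]
  sp <- model$species[!is.na(model$species$whole_cell_group) &
                      !(model$species$compartment %in% ex_comp), ]
  sp <- sp[sp$id %in% names(truth$conc), ]
  groups <- groups %||% unique(sp$whole_cell_group)
  vf <- stats::setNames(model$compartments$volume_fraction,
                        model$compartments$id)
  rows <- lapply(groups, function(g) {
    members <- sp[sp$whole_cell_group == g, ]
    alpha <- vf[members$compartment]
    alpha <- alpha / sum(alpha)
    whole <- sum(alpha * truth$conc[members$id])
    noisy <- whole * 10^stats::rnorm(1, 0, spec$noise_sd_log10)
    data.frame(group = g,
               lb = min(noisy / width, whole * (1 - 1e-9)),
               ub = max(noisy * width, whole * (1 + 1e-9)))
  })
  measurement_table(concentrations = do.call(rbind, rows))
}

#' Plant a gap-filling instance
#'
#' Removes one reaction whose loss makes the growth task infeasible and
#' builds a donor model holding the removed reaction plus decoy reactions
#' (random recombinations of existing metabolites that do not restore
#' feasibility on their own).
#'
#' @param model a `tk_model` (d2_mini preset).
#' @param spec the `tk_synth_spec`.
#' @param remove id of the reaction to remove (default `"EDA"`, which is
#'   essential once the transketolase analog is blocked from producing
#'   triose phosphate).
#' @param growth_min growth the task must attain.
#' @return list with `host` (model missing the reaction), `donor` (model
#'   with the planted reaction and decoys), `planted` (id), `task` (a
#'   `tk_gapfill_task`).
#' @export
plant_gap <- function(model, spec = synthetic_spec(), remove = "EDA",
                      growth_min = 0.1) {
  set.seed(spec$seed + 2L)
  stopifnot(remove %in% model$reactions$id)
  # block the PPP shunt from producing g3p so the removed reaction is load-bearing
  host <- set_reaction_bounds(model, "TKT2", ub = 0)
  keep <- host$reactions$id != remove
  planted_stoich <- host$stoich[[remove]]
  planted_row <- host$reactions[!keep, ]
  host$reactions <- host$reactions[keep, ]
  host$stoich <- host$stoich[keep]
  # species may lose their last reaction; drop orphans
  used <- unique(unlist(lapply(host$stoich, names), use.names = FALSE))
  host$species <- host$species[host$species$id %in% used, ]
  validate_model(host)

  cytosolic <- model$species$id[model$species$compartment == "c"]
  decoys <- list(); decoy_ids <- character(0)
  k <- 0L
  while (length(decoys) < spec$n_decoys) {
    k <- k + 1L
    picks <- sample(cytosolic, 3)
    s <- stats::setNames(c(-1, 1, 1), picks)
    # decoys must not touch the broken precursor (no accidental repair)
    if ("g3p_c" %in% picks || "kdpg_c" %in% picks) next
    decoys[[length(decoys) + 1L]] <- s
    decoy_ids <- c(decoy_ids, sprintf("DECOY%d", length(decoys)))
  }
  donor_rx <- data.frame(
    id = c(remove, decoy_ids),
    lb = c(planted_row$lb, rep(0, length(decoy_ids))),
    ub = c(planted_row$ub, rep(100, length(decoy_ids))),
    drG0 = c(planted_row$drG0, rep(NA_real_, length(decoy_ids))),
    drG0_err = 0, is_transport = FALSE, is_exchange = FALSE)
  donor_stoich <- c(stats::setNames(list(planted_stoich), remove),
                    stats::setNames(decoys, decoy_ids))
  donor_species <- model$species[model$species$id %in%
    unique(unlist(lapply(donor_stoich, names), use.names = FALSE)), ]
  donor <- metabolic_model(
    compartments = model$compartments, species = donor_species,
    reactions = donor_rx, stoichiometry = donor_stoich,
    objective = remove, name = "donor")
  list(host = host, donor = donor, planted = remove,
       task = gapfill_task(growth_min = growth_min))
}
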