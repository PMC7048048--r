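# Constraint-based model container.
#
# A tk_model is a plain list of data frames (compartments, species, reactions)
# plus a named list of stoichiometries. Concentrations are carried in mol/L,
# fluxes in mmol/gDCW/h, Gibbs energies in kJ/mol.

#' Gas constant used throughout, kJ/mol/K
#' @export
GAS_CONSTANT <- 8.314e-3

#' Assemble a constraint-based metabolic model
#'
#' @param compartments data.frame with columns `id`, `name`,
#'   `volume_fraction` (fraction of intracellular volume, in (0,1]) and
#'   logical `extracellular`. Extracellular compartments do not enter the
#'   volume-fraction budget.
#' @param species data.frame with columns `id`, `name`, `compartment`, and
#'   optionally `whole_cell_group` (the measured whole-cell metabolite this
#'   species belongs to) and `formula` (chemical formula, used by the
#'   free-diffusion rule in [preconfigure_wildtype()]).
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`
#'   (mmol/gDCW/h), `drG0` (transformed standard Gibbs energy, kJ/mol, `NA`
#'   when not annotated), `drG0_err` (kJ/mol, >= 0), `subsystem`,
#'   `is_transport`, `is_exchange`, `gene_rule`.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (by species id); negative = consumed.
#' @param objective id of the biomass/objective reaction.
#' @param temperature in K; enters all RT terms.
#' @param name model label.
#' @return an object of class `tk_model`.
#' @export
metabolic_model <- function(compartments, species, reactions, stoichiometry,
                            objective, temperature = 298.15, name = "model") {
  species <- fill_cols(species, whole_cell_group = NA_character_,
                       formula = NA_character_, name = species$id)
  compartments <- fill_cols(compartments, extracellular = FALSE,
                            name = compartments$id)
  reactions <- fill_cols(reactions, name = reactions$id, drG0 = NA_real_,
                         drG0_err = 0, subsystem = NA_character_,
                         is_transport = FALSE, is_exchange = FALSE,
                         gene_rule = NA_character_)
  m <- structure(list(name = name,
                      compartments = as.data.frame(compartments),
                      species = as.data.frame(species),
                      reactions = as.data.frame(reactions),
                      stoich = stoichiometry,
                      objective = objective,
                      temperature = temperature),
                 class = "tk_model")
  rownames(m$species) <- NULL; rownames(m$reactions) <- NULL
  m
}

fill_cols <- function(df, ...) {
  defaults <- list(...)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df
}

#' RT in kJ/mol for a model
#' @param model a `tk_model`.
#' @export
model_rt <- function(model) GAS_CONSTANT * model$temperature

#' @export
print.tk_model <- function(x, ...) {
  n_thermo <- sum(!is.na(x$reactions$drG0))
  cat(sprintf("<tk_model '%s'>\n", x$name))
  cat(sprintf("  %d reactions (%d with DrG'0), %d species, %d compartments\n",
              nrow(x$reactions), n_thermo, nrow(x$species),
              nrow(x$compartments)))
  cat(sprintf("  objective: %s; T = %.2f K\n", x$objective, x$temperature))
  invisible(x)
}

#' @export
summary.tk_model <- function(object, ...) {
  v <- validate_model(object, stop_on_error = FALSE)
  out <- list(model = object, validation = v)
  class(out) <- "summary.tk_model"
  out
}

#' @export
print.summary.tk_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  exchanges: %d, transports: %d\n",
              sum(x$model$reactions$is_exchange),
              sum(x$model$reactions$is_transport)))
  if (length(x$validation$errors))
    cat("  validation errors:\n",
        paste0("   - ", x$validation$errors, collapse = "\n"), "\n")
  else cat("  validation: ok\n")
  if (length(x$validation$dead_ends))
    cat("  dead-end species:", paste(x$validation$dead_ends, collapse = ", "),
        "\n")
  invisible(x)
}

#' Stoichiometric matrix
#'
#' @param model a `tk_model`.
#' @param drop_extracellular drop rows of species living in extracellular
#'   compartments (their mass balances are not imposed).
#' @return dense numeric matrix, species x reactions.
#' @export
stoichiometric_matrix <- function(model, drop_extracellular = FALSE) {
  sp <- model$species$id
  rx <- model$reactions$id
  N <- matrix(0, length(sp), length(rx), dimnames = list(sp, rx))
  for (j in seq_along(rx)) {
    s <- model$stoich[[rx[j]]]
    N[names(s), j] <- s
  }
  if (drop_extracellular) {
    ex_comp <- model$compartments$id[model$compartments$extracellular]
    N <- N[!(model$species$compartment %in% ex_comp), , drop = FALSE]
  }
  N
}

species_compartment <- function(model, ids) {
  model$species$compartment[match(ids, model$species$id)]
}

extracellular_species <- function(model) {
  ex <- model$compartments$id[model$compartments$extracellular]
  model$species$id[model$species$compartment %in% ex]
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, resolvable references,
#' `lb <= ub`, non-empty stoichiometries, exchange reactions touching exactly
#' one species, existing objective, volume fractions of intracellular
#' compartments summing to 1. Also reports dead-end species (internal species
#' lacking a producer or a consumer).
#'
#' @param model a `tk_model`.
#' @param stop_on_error raise an error listing offenders (default) or return
#'   the report.
#' @return a list with `errors` (character) and `dead_ends` (character),
#'   invisibly when valid.
#' @export
validate_model <- function(model, stop_on_error = TRUE) {
  errs <- character(0)
  sp <- model$species; rx <- model$reactions; cp <- model$compartments
  if (anyDuplicated(sp$id)) errs <- c(errs, "duplicate species ids")
  if (anyDuplicated(rx$id)) errs <- c(errs, "duplicate reaction ids")
  if (anyDuplicated(cp$id)) errs <- c(errs, "duplicate compartment ids")
  bad <- setdiff(sp$compartment, cp$id)
  if (length(bad)) errs <- c(errs, paste("unknown compartments:",
                                         paste(bad, collapse = ", ")))
  if (!model$objective %in% rx$id)
    errs <- c(errs, paste("objective reaction not in model:", model$objective))
  if (any(rx$lb > rx$ub))
    errs <- c(errs, paste("lb > ub for:",
                          paste(rx$id[rx$lb > rx$ub], collapse = ", ")))
  if (any(rx$drG0_err < 0, na.rm = TRUE))
    errs <- c(errs, "negative DrG'0 error")
  vf <- cp$volume_fraction[!cp$extracellular]
  if (any(vf <= 0)) errs <- c(errs, "non-positive volume fraction")
  if (abs(sum(vf) - 1) > 1e-9)
    errs <- c(errs, sprintf(
      "intracellular volume fractions sum to %.6g, expected 1", sum(vf)))
  missing_st <- setdiff(rx$id, names(model$stoich))
  if (length(missing_st))
    errs <- c(errs, paste("reactions without stoichiometry:",
                          paste(missing_st, collapse = ", ")))
  for (id in intersect(rx$id, names(model$stoich))) {
    s <- model$stoich[[id]]
    if (!length(s)) { errs <- c(errs, paste("empty stoichiometry:", id)); next }
    unk <- setdiff(names(s), sp$id)
    if (length(unk))
      errs <- c(errs, paste0("reaction ", id, " references unknown species: ",
                             paste(unk, collapse = ", ")))
  }
  n_touch <- vapply(rx$id, function(id) length(model$stoich[[id]]), integer(1))
  bad_ex <- rx$id[rx$is_exchange & n_touch != 1L]
  if (length(bad_ex))
    errs <- c(errs, paste("exchange reactions must touch exactly one species:",
                          paste(bad_ex, collapse = ", ")))
  used <- unique(unlist(lapply(model$stoich, names), use.names = FALSE))
  orphan <- setdiff(sp$id, used)
  if (length(orphan))
    errs <- c(errs, paste("species in no reaction:",
                          paste(orphan, collapse = ", ")))

  # dead-end report over internal species
  dead <- character(0)
  if (!length(errs)) {
    N <- stoichiometric_matrix(model)
    internal <- setdiff(sp$id, extracellular_species(model))
    rev_ok <- rx$lb < 0
    for (s in internal) {
      row <- N[s, ]
      can_produce <- any(row > 0) || any(row < 0 & rev_ok)
      can_consume <- any(row < 0) || any(row > 0 & rev_ok)
      if (!(can_produce && can_consume)) dead <- c(dead, s)
    }
  }
  report <- list(errors = errs, dead_ends = dead)
  if (length(errs) && stop_on_error)
    stop("model validation failed:\n", paste0(" - ", errs, collapse = "\n"),
         call. = FALSE)
  invisible(report)
}

#' Net-flux bounds of reactions
#' @param model a `tk_model`.
#' @param ids reaction ids (default all).
#' @export
reaction_bounds <- function(model, ids = model$reactions$id) {
  i <- match(ids, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction(s): ", paste(ids[is.na(i)], collapse = ", "))
  data.frame(id = ids, lb = model$reactions$lb[i], ub = model$reactions$ub[i])
}

#' Update net-flux bounds, returning a modified model
#' @inheritParams reaction_bounds
#' @param lb,ub new bounds (recycled).
#' @export
set_reaction_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  i <- match(ids, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction(s): ", paste(ids[is.na(i)], collapse = ", "))
  if (!is.null(lb)) model$reactions$lb[i] <- rep_len(lb, length(i))
  if (!is.null(ub)) model$reactions$ub[i] <- rep_len(ub, length(i))
  model
}
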