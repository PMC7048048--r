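# Model and measurement I/O.
#
# JSON is the canonical dialect (schema in inst/extdata/model.schema.json);
# TSV writes a directory of flat tables; SBML writes Level 3 Version 1 with
# the FBC elements this package needs (bounds, objective) and carries the
# thermodynamic annotation as a reaction annotation element
# (key "deltaGprime0_kJ_per_mol"). All dialects round-trip bit-equal
# stoichiometry, bounds and Gibbs energies.

#' Read a constraint-based model
#'
#' @param path file (json, sbml) or directory (tsv).
#' @param dialect one of `"json"`, `"sbml"`, `"tsv"`; default guessed from the
#'   path.
#' @param quiet suppress the summary message.
#' @return a validated `tk_model`.
#' @export
read_model <- function(path, dialect = NULL, quiet = FALSE) {
  dialect <- dialect %||% guess_dialect(path)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  model <- switch(dialect,
                  json = read_model_json(path),
                  sbml = read_model_sbml(path),
                  tsv  = read_model_tsv(path),
                  stop("unknown dialect: ", dialect))
  validate_model(model)
  if (!quiet)
    message(sprintf(
      "read '%s': %d reactions (%d thermodynamically annotated), %d species",
      model$name, nrow(model$reactions), sum(!is.na(model$reactions$drG0)),
      nrow(model$species)))
  model
}

#' Write a constraint-based model
#' @param model a valid `tk_model`.
#' @param path target file (json, sbml) or directory (tsv).
#' @inheritParams read_model
#' @export
write_model <- function(model, path, dialect = NULL) {
  validate_model(model)
  dialect <- dialect %||% guess_dialect(path)
  switch(dialect,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path),
         tsv  = write_model_tsv(model, path),
         stop("unknown dialect: ", dialect))
  invisible(path)
}

guess_dialect <- function(path) {
  if (grepl("\\.json$", path)) "json"
  else if (grepl("\\.(xml|sbml)$", path)) "sbml"
  else "tsv"
}

# -- JSON ---------------------------------------------------------------------

read_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop("JSON parse failure in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  num_cols <- c("lb", "ub", "drG0", "drG0_err", "volume_fraction")
  log_cols <- c("extracellular", "is_transport", "is_exchange")
  df_from <- function(lst, cols) {
    out <- lapply(cols, function(cl) {
      if (cl %in% num_cols)
        vapply(lst, function(r)
          if (is.null(r[[cl]])) NA_real_ else as.numeric(r[[cl]]), numeric(1))
      else if (cl %in% log_cols)
        vapply(lst, function(r)
          if (is.null(r[[cl]])) FALSE else as.logical(r[[cl]]), logical(1))
      else
        vapply(lst, function(r)
          if (is.null(r[[cl]])) NA_character_ else as.character(r[[cl]]),
          character(1))
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  stoich <- lapply(x$reactions, function(r)
    unlist(lapply(r$stoichiometry, as.numeric)))
  names(stoich) <- vapply(x$reactions, `[[`, character(1), "id")
  rx <- df_from(x$reactions,
                c("id", "name", "lb", "ub", "drG0", "drG0_err", "subsystem",
                  "is_transport", "is_exchange", "gene_rule"))
  rx$drG0_err[is.na(rx$drG0_err)] <- 0
  metabolic_model(
    compartments = df_from(x$compartments,
                           c("id", "name", "volume_fraction", "extracellular")),
    species = df_from(x$species,
                      c("id", "name", "compartment", "whole_cell_group",
                        "formula")),
    reactions = rx,
    stoichiometry = stoich,
    objective = x$objective,
    temperature = x$temperature %||% 298.15,
    name = x$name %||% "model")
}

write_model_json <- function(model, path) {
  rxl <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- as.list(model$reactions[i, ])
    r$stoichiometry <- as.list(model$stoich[[r$id]])
    r
  })
  spl <- lapply(seq_len(nrow(model$species)), function(i)
    as.list(model$species[i, ]))
  cpl <- lapply(seq_len(nrow(model$compartments)), function(i)
    as.list(model$compartments[i, ]))
  jsonlite::write_json(
    list(name = model$name, temperature = model$temperature,
         objective = model$objective, compartments = cpl, species = spl,
         reactions = rxl),
    path, auto_unbox = TRUE, digits = NA, na = "null", null = "null",
    pretty = TRUE)
}

# -- TSV ----------------------------------------------------------------------

num17 <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

write_model_tsv <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  wr <- function(df, f) utils::write.table(
    df, file.path(path, f), sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  wr(model$compartments, "compartments.tsv")
  wr(model$species, "species.tsv")
  rx <- model$reactions
  rx$stoichiometry <- vapply(rx$id, function(id) {
    s <- model$stoich[[id]]
    paste(sprintf("%s:%.17g", names(s), s), collapse = ";")
  }, character(1))
  for (cl in c("lb", "ub", "drG0", "drG0_err")) rx[[cl]] <- num17(rx[[cl]])
  wr(rx, "reactions.tsv")
  wr(data.frame(key = c("name", "temperature", "objective"),
                value = c(model$name, sprintf("%.17g", model$temperature),
                          model$objective)),
     "model.tsv")
}

read_model_tsv <- function(path) {
  rd <- function(f, ...) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing table: ", fp, call. = FALSE)
    utils::read.table(fp, sep = "\t", header = TRUE, quote = "",
                      na.strings = "", stringsAsFactors = FALSE, ...)
  }
  meta <- rd("model.tsv", colClasses = "character")
  kv <- stats::setNames(meta$value, meta$key)
  rx <- rd("reactions.tsv",
           colClasses = c(lb = "character", ub = "character",
                          drG0 = "character", drG0_err = "character"))
  stoich <- lapply(rx$stoichiometry, function(s) {
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(parts, `[[`, character(1), 1))
  })
  names(stoich) <- rx$id
  rx$stoichiometry <- NULL
  for (cl in c("lb", "ub", "drG0", "drG0_err"))
    rx[[cl]] <- suppressWarnings(as.numeric(rx[[cl]]))
  rx$drG0_err[is.na(rx$drG0_err)] <- 0
  metabolic_model(compartments = rd("compartments.tsv"),
                  species = rd("species.tsv"),
                  reactions = rx, stoichiometry = stoich,
                  objective = unname(kv["objective"]),
                  temperature = as.numeric(kv["temperature"]),
                  name = unname(kv["name"]))
}

# -- SBML (L3v1 core + the FBC subset this package uses) ----------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
TK_NS <- "https://thermokin.invalid/sbml-annotations"

write_model_sbml <- function(model, path) {
  a <- function(...) c(...)
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS, "xmlns:tk" = TK_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = gsub("\\W", "_", model$name),
                             name = model$name, "fbc:strict" = "false")
  xml2::xml_add_child(mdl, "tk:modelMeta",
                      "tk:temperature" = sprintf("%.17g", model$temperature))
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments))) {
    cp <- model$compartments[i, ]
    xml2::xml_add_child(loc, "compartment", id = cp$id, name = cp$name,
                        constant = "true",
                        size = sprintf("%.17g", cp$volume_fraction),
                        "tk:extracellular" = tolower(as.character(cp$extracellular)))
  }
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    sp <- model$species[i, ]
    attrs <- a(id = sp$id, name = sp$name, compartment = sp$compartment,
               hasOnlySubstanceUnits = "false", boundaryCondition = "false",
               constant = "false")
    if (!is.na(sp$formula)) attrs <- a(attrs, "fbc:chemicalFormula" = sp$formula)
    if (!is.na(sp$whole_cell_group))
      attrs <- a(attrs, "tk:wholeCellGroup" = sp$whole_cell_group)
    do.call(xml2::xml_add_child, c(list(los, "species"), as.list(attrs)))
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    for (side in c("lb", "ub"))
      xml2::xml_add_child(lop, "parameter",
                          id = paste0(r$id, "_", side), constant = "true",
                          value = sprintf("%.17g", r[[side]]))
    attrs <- a(id = r$id, name = r$name,
               reversible = tolower(as.character(r$lb < 0)), fast = "false",
               "fbc:lowerFluxBound" = paste0(r$id, "_lb"),
               "fbc:upperFluxBound" = paste0(r$id, "_ub"),
               "tk:isTransport" = tolower(as.character(r$is_transport)),
               "tk:isExchange" = tolower(as.character(r$is_exchange)))
    if (!is.na(r$drG0)) {
      attrs <- a(attrs, "tk:deltaGprime0_kJ_per_mol" = sprintf("%.17g", r$drG0),
                 "tk:deltaGprime0Err_kJ_per_mol" = sprintf("%.17g", r$drG0_err))
    }
    if (!is.na(r$subsystem)) attrs <- a(attrs, "tk:subsystem" = r$subsystem)
    if (!is.na(r$gene_rule)) attrs <- a(attrs, "tk:geneRule" = r$gene_rule)
    rn <- do.call(xml2::xml_add_child, c(list(lor, "reaction"), as.list(attrs)))
    s <- model$stoich[[r$id]]
    lre <- xml2::xml_add_child(rn, "listOfReactants")
    lpr <- xml2::xml_add_child(rn, "listOfProducts")
    for (k in seq_along(s)) {
      parent <- if (s[k] < 0) lre else lpr
      xml2::xml_add_child(parent, "speciesReference",
                          species = names(s)[k], constant = "true",
                          stoichiometry = sprintf("%.17g", abs(s[k])))
    }
  }
  lobj <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lobj, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = model$objective,
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS, tk = TK_NS)
  at <- function(node, name, default = NA_character_) {
    v <- xml2::xml_attr(node, name)
    ifelse(is.na(v), default, v)
  }
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse failure: no <model> element in ", path, call. = FALSE)
  meta <- xml2::xml_find_first(mdl, ".//tk:modelMeta", ns)
  temperature <- if (inherits(meta, "xml_missing")) 298.15
                 else as.numeric(at(meta, "temperature", "298.15"))

  cps <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- data.frame(
    id = xml2::xml_attr(cps, "id"),
    name = at(cps, "name"),
    volume_fraction = as.numeric(at(cps, "size", "1")),
    extracellular = at(cps, "extracellular", "false") == "true",
    stringsAsFactors = FALSE)

  sps <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(sps, "id"),
    name = at(sps, "name"),
    compartment = xml2::xml_attr(sps, "compartment"),
    whole_cell_group = at(sps, "wholeCellGroup"),
    formula = at(sps, "chemicalFormula"),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rns <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  ids <- xml2::xml_attr(rns, "id")
  stoich <- vector("list", length(rns)); names(stoich) <- ids
  for (i in seq_along(rns)) {
    rea <- xml2::xml_find_all(rns[[i]], "./s:listOfReactants/s:speciesReference", ns)
    pro <- xml2::xml_find_all(rns[[i]], "./s:listOfProducts/s:speciesReference", ns)
    s <- c(stats::setNames(-as.numeric(xml2::xml_attr(rea, "stoichiometry")),
                           xml2::xml_attr(rea, "species")),
           stats::setNames(as.numeric(xml2::xml_attr(pro, "stoichiometry")),
                           xml2::xml_attr(pro, "species")))
    stoich[[i]] <- s
  }
  reactions <- data.frame(
    id = ids,
    name = at(rns, "name"),
    lb = unname(parval[at(rns, "lowerFluxBound")]),
    ub = unname(parval[at(rns, "upperFluxBound")]),
    drG0 = as.numeric(at(rns, "deltaGprime0_kJ_per_mol")),
    drG0_err = ifelse(is.na(at(rns, "deltaGprime0Err_kJ_per_mol")), 0,
                      as.numeric(at(rns, "deltaGprime0Err_kJ_per_mol"))),
    subsystem = at(rns, "subsystem"),
    is_transport = at(rns, "isTransport", "false") == "true",
    is_exchange = at(rns, "isExchange", "false") == "true",
    gene_rule = at(rns, "geneRule"),
    stringsAsFactors = FALSE)

  objective <- xml2::xml_attr(
    xml2::xml_find_first(mdl, ".//fbc:fluxObjective", ns), "reaction")
  metabolic_model(compartments, species, reactions, stoich,
                  objective = objective, temperature = temperature,
                  name = at(mdl, "name", "model"))
}

# -- measurements -------------------------------------------------------------

#' Read a measurement table
#'
#' The TSV must have columns `id`, `type` (`"concentration"` or `"flux"`),
#' `lb`, `ub`, `unit`. Concentrations accept `mM` or `M` and are converted to
#' mol/L internally; fluxes are in mmol/gDCW/h. Concentration rows refer to
#' whole-cell metabolite groups (`whole_cell_group` of species); flux rows
#' refer to reaction ids.
#'
#' @param path TSV file.
#' @return a `tk_measurements` list with data frames `concentrations`
#'   (`group`, `lb`, `ub` in mol/L) and `fluxes` (`reaction`, `lb`, `ub`).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (!nrow(raw)) {
    warning("empty measurement table: ", path)
    return(measurement_table())
  }
  needed <- c("id", "type", "lb", "ub", "unit")
  if (!all(needed %in% names(raw)))
    stop("measurement table needs columns: ", paste(needed, collapse = ", "))
  conc <- raw[raw$type == "concentration", ]
  flux <- raw[raw$type == "flux", ]
  to_molar <- function(x, unit) ifelse(unit == "mM", x * 1e-3, x)
  if (nrow(conc)) {
    if (any(!conc$unit %in% c("mM", "M")))
      stop("concentration units must be mM or M")
    conc_lb <- to_molar(conc$lb, conc$unit)
    conc_ub <- to_molar(conc$ub, conc$unit)
    if (any(conc_lb <= 0) || any(conc_ub < conc_lb))
      stop("concentration bounds must satisfy 0 < lb <= ub; offending groups: ",
           paste(conc$id[conc_lb <= 0 | conc_ub < conc_lb], collapse = ", "))
  } else conc_lb <- conc_ub <- numeric(0)
  measurement_table(
    concentrations = data.frame(group = conc$id, lb = conc_lb, ub = conc_ub,
                                stringsAsFactors = FALSE),
    fluxes = data.frame(reaction = flux$id, lb = flux$lb, ub = flux$ub,
                        stringsAsFactors = FALSE))
}

#' Construct a measurement table in code
#' @param concentrations data.frame(group, lb, ub), bounds in mol/L.
#' @param fluxes data.frame(reaction, lb, ub), mmol/gDCW/h.
#' @export
measurement_table <- function(concentrations = NULL, fluxes = NULL) {
  concentrations <- concentrations %||%
    data.frame(group = character(0), lb = numeric(0), ub = numeric(0))
  fluxes <- fluxes %||%
    data.frame(reaction = character(0), lb = numeric(0), ub = numeric(0))
  structure(list(concentrations = concentrations, fluxes = fluxes),
            class = "tk_measurements")
}

#' Write a measurement table to TSV
#' @param m a `tk_measurements`.
#' @param path target TSV.
#' @param conc_unit unit to write concentrations in (`"mM"` or `"M"`).
#' @export
write_measurements <- function(m, path, conc_unit = "mM") {
  f <- if (conc_unit == "mM") 1e3 else 1
  df <- rbind(
    if (nrow(m$concentrations))
      data.frame(id = m$concentrations$group, type = "concentration",
                 lb = m$concentrations$lb * f, ub = m$concentrations$ub * f,
                 unit = conc_unit),
    if (nrow(m$fluxes))
      data.frame(id = m$fluxes$reaction, type = "flux",
                 lb = m$fluxes$lb, ub = m$fluxes$ub, unit = "mmol/gDCW/h"))
  if (is.null(df)) df <- data.frame(id = character(0), type = character(0),
                                    lb = numeric(0), ub = numeric(0),
                                    unit = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.tk_measurements <- function(x, ...) {
  cat(sprintf("<tk_measurements: %d concentration groups, %d flux ranges>\n",
              nrow(x$concentrations), nrow(x$fluxes)))
  invisible(x)
}
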