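# Linear/mixed-integer programming layer.
#
# Problems are built incrementally in an environment (variables, ranged rows,
# objective) and solved through a pluggable backend. The default backend
# serializes batches of problems to JSON and runs them through HiGHS via
# scipy (inst/python/milp_solve.py); batching matters because variability
# analysis and sweeps solve hundreds of small related programs.

#' Create an empty optimization problem
#'
#' Low-level constructor for the LP/MILP container used by [build_fba()],
#' [build_tfa()] and [gapfill()]. Variables and ranged constraint rows are
#' added by reference; the problem is an environment, so use [lp_clone()]
#' before destructive edits such as knockouts.
#'
#' @param name optional label carried through to solver logs.
#' @return An object of class `tk_lp`.
#' @export
new_lp <- function(name = "lp") {
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$var_name <- character(0)
  p$lb <- numeric(0)
  p$ub <- numeric(0)
  p$vtype <- character(0)
  p$rows <- list()
  p$obj <- numeric(0)          # named sparse objective
  p$sense <- "max"
  p$meta <- list()
  class(p) <- "tk_lp"
  p
}

#' @export
print.tk_lp <- function(x, ...) {
  cat(sprintf("<tk_lp '%s': %d variables (%d binary), %d rows, sense %s>\n",
              x$name, length(x$var_name), sum(x$vtype == "B"),
              length(x$rows), x$sense))
  invisible(x)
}

#' Add variables to a problem
#'
#' @param p a `tk_lp`.
#' @param names unique variable names.
#' @param lb,ub bounds, recycled; `-Inf`/`Inf` allowed.
#' @param type `"C"` (continuous) or `"B"` (binary), recycled.
#' @return `p`, invisibly.
#' @export
lp_add_vars <- function(p, names, lb = -Inf, ub = Inf, type = "C") {
  stopifnot(inherits(p, "tk_lp"))
  if (anyDuplicated(c(p$var_name, names)))
    stop("duplicate variable names: ",
         paste(intersect(p$var_name, names), collapse = ", "))
  n <- length(names)
  p$var_name <- c(p$var_name, names)
  p$lb <- c(p$lb, rep_len(as.numeric(lb), n))
  p$ub <- c(p$ub, rep_len(as.numeric(ub), n))
  p$vtype <- c(p$vtype, rep_len(type, n))
  invisible(p)
}

lp_var_id <- function(p, names) {
  idx <- match(names, p$var_name)
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(names[is.na(idx)], collapse = ", "))
  idx
}

#' Add a ranged linear constraint row
#'
#' @param p a `tk_lp`.
#' @param coefs named numeric vector of coefficients over variable names.
#' @param lb,ub row bounds (`lb <= a'x <= ub`); use equal values for equality.
#' @param name optional row label.
#' @export
lp_add_row <- function(p, coefs, lb = -Inf, ub = Inf, name = NULL) {
  stopifnot(inherits(p, "tk_lp"), length(coefs) > 0L)
  j <- lp_var_id(p, names(coefs))
  p$rows[[length(p$rows) + 1L]] <-
    list(j = j, v = as.numeric(coefs), lb = lb, ub = ub,
         name = name %||% sprintf("r%d", length(p$rows) + 1L))
  invisible(p)
}

#' Set variable bounds in place
#' @inheritParams lp_add_row
#' @param names variable names to update.
#' @export
lp_set_bounds <- function(p, names, lb = NULL, ub = NULL) {
  idx <- lp_var_id(p, names)
  if (!is.null(lb)) p$lb[idx] <- rep_len(as.numeric(lb), length(idx))
  if (!is.null(ub)) p$ub[idx] <- rep_len(as.numeric(ub), length(idx))
  invisible(p)
}

lp_get_bounds <- function(p, names) {
  idx <- lp_var_id(p, names)
  data.frame(name = names, lb = p$lb[idx], ub = p$ub[idx])
}

#' Set the optimization objective
#' @param p a `tk_lp`.
#' @param coefs named numeric vector (sparse objective).
#' @param sense `"max"` or `"min"`.
#' @export
lp_objective <- function(p, coefs, sense = c("max", "min")) {
  lp_var_id(p, names(coefs))   # validate
  p$obj <- coefs
  p$sense <- match.arg(sense)
  invisible(p)
}

#' Deep-copy a problem
#' @param p a `tk_lp`.
#' @return an independent copy.
#' @export
lp_clone <- function(p) {
  q <- new_lp(p$name)
  for (f in c("var_name", "lb", "ub", "vtype", "rows", "obj", "sense", "meta"))
    assign(f, get(f, envir = p), envir = q)
  q
}

# -- serialization ------------------------------------------------------------

lp_payload <- function(p, objective = NULL, sense = NULL) {
  obj <- objective %||% p$obj
  sense <- sense %||% p$sense
  dense <- numeric(length(p$var_name))
  if (length(obj)) dense[lp_var_id(p, names(obj))] <- as.numeric(obj)
  i <- integer(0); j <- integer(0); v <- numeric(0)
  rlb <- numeric(0); rub <- numeric(0)
  if (length(p$rows)) {
    nper <- vapply(p$rows, function(r) length(r$j), integer(1))
    i <- rep.int(seq_along(p$rows) - 1L, nper)
    j <- unlist(lapply(p$rows, `[[`, "j"), use.names = FALSE) - 1L
    v <- unlist(lapply(p$rows, `[[`, "v"), use.names = FALSE)
    rlb <- vapply(p$rows, `[[`, numeric(1), "lb")
    rub <- vapply(p$rows, `[[`, numeric(1), "ub")
  }
  inf2na <- function(x) { x[!is.finite(x)] <- NA_real_; x }
  list(nvar = length(p$var_name),
       obj = I(dense),
       sense = sense,
       lb = I(inf2na(p$lb)),
       ub = I(inf2na(p$ub)),
       vtype = I(p$vtype),
       A = list(i = I(i), j = I(j), v = I(v)),
       rlb = I(inf2na(rlb)),
       rub = I(inf2na(rub)))
}

solver_script <- function() {
  path <- system.file("python", "milp_solve.py", package = "thermokin")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is on the source path
    path <- file.path("inst", "python", "milp_solve.py")
  }
  if (!file.exists(path)) stop("solver backend script not found")
  path
}

solve_payloads <- function(payloads) {
  if (!nzchar(Sys.which("python")))
    stop("no 'python' interpreter on PATH; the MILP backend requires ",
         "python with scipy (HiGHS)")
  infile <- tempfile("tklp_", fileext = ".json")
  outfile <- tempfile("tklp_", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(list(problems = payloads), infile,
                       auto_unbox = TRUE, digits = NA, na = "null")
  status <- system2("python", c(shQuote(solver_script()),
                                shQuote(infile), shQuote(outfile)),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(outfile))
    stop("MILP backend failed (exit status ", status, ")")
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

#' Solve one problem, or one problem under many objectives
#'
#' @param p a `tk_lp`.
#' @param objectives optional list of `list(coefs=, sense=)` overrides; when
#'   supplied, all variants are solved in a single backend call and a list of
#'   results is returned.
#' @return a `tk_lp_result` (`status`, `objective`, named solution vector `x`)
#'   or a list of them. Infeasibility is reported as a status, not an error.
#' @export
lp_solve <- function(p, objectives = NULL) {
  single <- is.null(objectives)
  payloads <- if (single) list(lp_payload(p))
              else lapply(objectives,
                          function(o) lp_payload(p, o$coefs, o$sense))
  raw <- solve_payloads(payloads)
  out <- lapply(raw, function(r) {
    x <- if (is.null(r$x)) NULL else {
      xv <- vapply(r$x, as.numeric, numeric(1))
      names(xv) <- p$var_name
      xv
    }
    structure(list(status = r$status,
                   objective = if (is.null(r$objective)) NA_real_
                               else as.numeric(r$objective),
                   x = x),
              class = "tk_lp_result")
  })
  if (single) out[[1L]] else out
}

#' Solve several independent problems in one backend call
#' @param problems list of `tk_lp`.
#' @return list of `tk_lp_result` in the same order.
#' @export
lp_solve_batch <- function(problems) {
  raw <- solve_payloads(lapply(problems, lp_payload))
  mapply(function(r, p) {
    x <- if (is.null(r$x)) NULL else {
      xv <- vapply(r$x, as.numeric, numeric(1)); names(xv) <- p$var_name; xv
    }
    structure(list(status = r$status,
                   objective = if (is.null(r$objective)) NA_real_
                               else as.numeric(r$objective),
                   x = x), class = "tk_lp_result")
  }, raw, problems, SIMPLIFY = FALSE)
}

#' @export
print.tk_lp_result <- function(x, ...) {
  cat(sprintf("<tk_lp_result: %s, objective %s>\n", x$status,
              format(x$objective)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
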