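# Classifier-based refinement of kinetic-parameter ranges.
#
# Members of an ensemble are labeled consistent or inconsistent against a
# specification of expected response signs (e.g. "a knockout of any of
# these enzymes must decrease both glucose uptake and growth"). A decision
# tree trained on the log-Km parameters then carves out axis-aligned
# subranges in which predictions are reliably consistent; resampling the
# ensemble inside those subranges raises the fraction of consistent models.

#' Label ensemble members against a response-sign specification
#'
#' A member is consistent when, for every row of the specification, the
#' stored control coefficient of `target` with respect to `enzyme` has the
#' stated sign. Flux targets are looked up in `CJ`, concentration targets in
#' `CX`. An empty specification labels every member consistent.
#'
#' @param ensemble a `tk_ensemble`.
#' @param response_spec data.frame(target, enzyme, sign) with `sign` in
#'   `{-1, 1}`, or a function taking the ensemble and returning a logical
#'   vector (for planted-rule studies).
#' @return a `tk_labeled_ensemble` (the ensemble plus `consistent`).
#' @export
label_members <- function(ensemble, response_spec) {
  if (is.function(response_spec)) {
    lab <- response_spec(ensemble)
    stopifnot(is.logical(lab), length(lab) == ensemble$n)
  } else {
    lab <- rep(TRUE, ensemble$n)
    for (i in seq_len(nrow(response_spec))) {
      r <- response_spec[i, ]
      vals <- if (r$target %in% dimnames(ensemble$CJ)[[1]] &&
                  r$enzyme %in% dimnames(ensemble$CJ)[[2]])
        ensemble$CJ[r$target, r$enzyme, ]
      else if (r$target %in% dimnames(ensemble$CX)[[1]])
        ensemble$CX[r$target, r$enzyme, ]
      else stop("unknown target/enzyme pair: ", r$target, " / ", r$enzyme)
      lab <- lab & (sign(vals) == r$sign)
    }
  }
  out <- ensemble
  out$consistent <- lab
  out$response_spec <- response_spec
  class(out) <- c("tk_labeled_ensemble", class(ensemble))
  out
}

#' @export
print.tk_labeled_ensemble <- function(x, ...) {
  cat(sprintf("<tk_labeled_ensemble: %d members, %.1f%% consistent>\n",
              x$n, 100 * mean(x$consistent)))
  invisible(x)
}

#' Learn refined Km ranges from a labeled ensemble
#'
#' Trains a single decision tree on the log10-Km parameters and extracts the
#' axis-aligned range of each split variable along the path to the
#' highest-support consistent leaf of purity at least `purity`. Returned
#' ranges are intersected with the originally sampled ranges and ranked by
#' the tree's variable importance.
#'
#' @param labeled a `tk_labeled_ensemble` with both classes present.
#' @param max_parameters cap on the number of returned parameter ranges.
#' @param purity minimal fraction of consistent members in an eligible leaf.
#' @param maxdepth,minbucket decision-tree controls.
#' @return a `tk_refined_ranges`: data.frame(slot, lower, upper,
#'   orig_lower, orig_upper) in mol/L; zero rows when no eligible leaf
#'   exists (with a diagnostic attribute).
#' @export
learn_ranges <- function(labeled, max_parameters = 7, purity = 0.95,
                         maxdepth = 6, minbucket = 50) {
  stopifnot(inherits(labeled, "tk_labeled_ensemble"))
  y <- factor(ifelse(labeled$consistent, "consistent", "inconsistent"),
              levels = c("consistent", "inconsistent"))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("both classes must be present to learn ranges")
  X <- log10(labeled$km)
  slots <- colnames(X)
  safe <- make.names(slots)
  colnames(X) <- safe
  df <- data.frame(X, check.names = FALSE)
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = maxdepth, minbucket = minbucket,
                        cp = 0.001, xval = 0))
  empty <- function(msg) {
    out <- data.frame(slot = character(0), lower = numeric(0),
                      upper = numeric(0), orig_lower = numeric(0),
                      orig_upper = numeric(0))
    structure(out, class = c("tk_refined_ranges", class(out)),
              diagnostic = msg)
  }
  if (nrow(fit$frame) == 1L) return(empty("degenerate tree: no split"))

  frame <- fit$frame
  leaves <- which(frame$var == "<leaf>")
  cls <- attr(fit, "ylevels")[frame$yval[leaves]]
  # purity = fraction of the majority-consistent class in the leaf
  n_cons <- frame$yval2[leaves, 2]   # counts of class 1 ("consistent")
  n_tot <- frame$n[leaves]
  eligible <- leaves[cls == "consistent" & n_cons / n_tot >= purity]
  if (!length(eligible)) return(empty("no leaf reaches the purity threshold"))
  best <- eligible[which.max(frame$n[eligible])]
  node_id <- as.integer(rownames(frame)[best])

  pth <- rpart::path.rpart(fit, nodes = node_id, print.it = FALSE)[[1]]
  pth <- pth[-1]   # drop "root"
  lo <- stats::setNames(rep(-Inf, length(safe)), safe)
  hi <- stats::setNames(rep(Inf, length(safe)), safe)
  for (cond in pth) {
    mm <- regmatches(cond, regexec("^(.*?)(>=|<)(.*)$", cond))[[1]]
    var <- trimws(mm[2]); op <- trimws(mm[3]); val <- as.numeric(mm[4])
    if (op == ">=") lo[var] <- max(lo[var], val)
    else hi[var] <- min(hi[var], val)
  }
  used <- safe[is.finite(lo[safe]) | is.finite(hi[safe])]
  imp <- fit$variable.importance
  used <- used[order(-ifelse(used %in% names(imp), imp[used], 0))]
  used <- utils::head(used, max_parameters)

  orig_lo <- apply(labeled$km, 2, min)
  orig_hi <- apply(labeled$km, 2, max)
  idx <- match(used, safe)
  out <- data.frame(
    slot = slots[idx],
    lower = pmax(10^lo[used], orig_lo[idx]),
    upper = pmin(10^hi[used], orig_hi[idx]),
    orig_lower = orig_lo[idx],
    orig_upper = orig_hi[idx],
    row.names = NULL)
  structure(out, class = c("tk_refined_ranges", class(out)),
            tree = fit, leaf = node_id)
}

#' @export
print.tk_refined_ranges <- function(x, ...) {
  if (!nrow(x)) {
    cat("<tk_refined_ranges: none (", attr(x, "diagnostic"), ")>\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<tk_refined_ranges: %d parameter(s)>\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-24s %.3g-%.3g mM (was %.3g-%.3g mM)\n", x$slot[i],
                x$lower[i] * 1e3, x$upper[i] * 1e3,
                x$orig_lower[i] * 1e3, x$orig_upper[i] * 1e3))
  invisible(x)
}

#' Rebuild an ensemble with Km values constrained to refined ranges
#'
#' Inverts `Km = C* (1 - sigma) / sigma` per refined slot to a saturation
#' sampling interval `[C*/(C* + Km_hi), C*/(C* + Km_lo)]` and resamples a
#' fresh ensemble inside it, reporting the consistency fraction against the
#' same response specification.
#'
#' @param reference a `tk_reference`.
#' @param assignment a `tk_mechanisms`.
#' @param ranges a `tk_refined_ranges`.
#' @param n ensemble size.
#' @param seed integer seed.
#' @param response_spec as in [label_members()].
#' @return list with `ensemble` (labeled) and `consistency_fraction`.
#' @export
resample_with_ranges <- function(reference, assignment, ranges, n, seed,
                                 response_spec) {
  slots <- assignment$slots
  lo <- rep(0, nrow(slots)); hi <- rep(1, nrow(slots))
  if (nrow(ranges)) {
    idx <- match(ranges$slot, slots$slot)
    if (anyNA(idx)) stop("refined range for unknown slot(s): ",
                         paste(ranges$slot[is.na(idx)], collapse = ", "))
    cstar <- reference$conc[slots$species[idx]]
    s_lo <- cstar / (cstar + ranges$upper)
    s_hi <- cstar / (cstar + ranges$lower)
    bad <- !(s_lo < s_hi)
    if (any(bad)) stop("empty saturation interval for slot(s): ",
                       paste(ranges$slot[bad], collapse = ", "))
    lo[idx] <- s_lo; hi[idx] <- s_hi
  }
  ens <- build_ensemble(reference, assignment, n_members = n, seed = seed,
                        sigma_lo = lo, sigma_hi = hi)
  lab <- label_members(ens, response_spec)
  list(ensemble = lab, consistency_fraction = mean(lab$consistent))
}
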