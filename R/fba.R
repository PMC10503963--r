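#' Flux balance analysis
#'
#' Optimises the flux of a chosen reaction subject to steady state
#' (`S v = 0`) and the model's flux bounds. Exchange fluxes follow the
#' convention "positive = secretion, negative = uptake".
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to optimise; defaults to the model's
#'   biomass objective.
#' @param direction `"max"` or `"min"`.
#' @param backend LP backend, see [solve_lp()].
#' @return object of class `fba_result`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, and (when optimal)
#'   `fluxes`, a named vector over all reactions.
#' @export
fba_optimize <- function(model, objective_id = model$objective,
                         direction = c("max", "min"),
                         backend = "simplex") {
  direction <- match.arg(direction)
  if (!objective_id %in% model$reactions$id)
    stop("objective reaction not in model: ", objective_id)
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  obj <- stats::setNames(numeric(n), colnames(S))
  obj[objective_id] <- 1
  res <- solve_lp(obj, A_eq = S, b_eq = numeric(nrow(S)),
                  lb = model$reactions$lb, ub = model$reactions$ub,
                  maximize = direction == "max", backend = backend)
  out <- list(status = res$status,
              objective_value = res$objective,
              objective_id = objective_id,
              direction = direction)
  if (res$status == "optimal") out$fluxes <- res$x
  class(out) <- "fba_result"
  out
}

#' @export
print.fba_result <- function(x, ...) {
  cat("FBA (", x$direction, " ", x$objective_id, "): ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective = ", format(x$objective_value, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
coef.fba_result <- function(object, ...) {
  if (object$status != "optimal") stop("no fluxes: status is ",
                                       object$status)
  object$fluxes
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' steady state, the bounds, and the objective held at or above
#' `objective_fraction` of its optimum. The reported `midpoint` — the mean
#' of the two extremes — is the package's single-value flux summary under
#' alternate optima.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to scan (default: all).
#' @param objective_fraction required fraction of the biomass optimum in
#'   `[0, 1]`; default 1 (at optimality).
#' @param objective_id objective reaction (default: the model's).
#' @param backend LP backend.
#' @return data.frame with columns `reaction_id`, `minimum`, `maximum`,
#'   `midpoint`.
#' @export
fva <- function(model, reaction_ids = model$reactions$id,
                objective_fraction = 1, objective_id = model$objective,
                backend = "simplex") {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  missing_ids <- setdiff(reaction_ids, model$reactions$id)
  if (length(missing_ids)) stop("unknown reaction: ", missing_ids[1])
  base <- fba_optimize(model, objective_id, "max", backend = backend)
  if (base$status != "optimal")
    stop("base FBA problem is ", base$status, "; cannot run FVA")
  opt <- base$objective_value
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  ids <- colnames(S)
  ## objective >= fraction * optimum as -obj <= -fraction*opt
  arow <- matrix(0, 1, n)
  arow[1, match(objective_id, ids)] <- -1
  out <- data.frame(reaction_id = reaction_ids,
                    minimum = NA_real_, maximum = NA_real_)
  for (k in seq_along(reaction_ids)) {
    obj <- numeric(n)
    obj[match(reaction_ids[k], ids)] <- 1
    for (dir in c("min", "max")) {
      r <- solve_lp(obj, A_eq = S, b_eq = numeric(nrow(S)),
                    lb = model$reactions$lb, ub = model$reactions$ub,
                    A_le = arow, b_le = -objective_fraction * opt,
                    maximize = dir == "max", backend = backend)
      if (r$status != "optimal")
        stop("FVA subproblem ", dir, " ", reaction_ids[k], " is ",
             r$status)
      if (dir == "min") out$minimum[k] <- r$objective
      else out$maximum[k] <- r$objective
    }
  }
  ## guard against solver jitter inverting degenerate ranges
  sw <- out$minimum > out$maximum
  if (any(sw)) {
    mid <- (out$minimum[sw] + out$maximum[sw]) / 2
    out$minimum[sw] <- out$maximum[sw] <- mid
  }
  out$midpoint <- (out$minimum + out$maximum) / 2
  out
}

#' Define a growth medium
#'
#' A medium is a set of maximum uptake rates for extracellular metabolites
#' plus a set of "free" species that remain exchangeable in both directions
#' regardless of the composition table (gases, water, protons and similar
#' species not captured by a composition measurement).
#'
#' @param uptake named numeric vector: extracellular metabolite id (with or
#'   without the `[e]` suffix) to maximum uptake rate (mmol/gDW/h, >= 0).
#' @param free_species character vector of metabolite ids always open.
#' @return object of class `medium`.
#' @export
medium <- function(uptake = numeric(0), free_species = character(0)) {
  if (any(uptake < 0)) stop("uptake rates must be >= 0")
  structure(list(uptake = uptake, free_species = free_species),
            class = "medium")
}

#' Read a medium composition table
#'
#' TSV with header columns `metabolite_id` and `max_uptake`.
#'
#' @param path TSV path.
#' @param free_species free species ids (configured, not part of the table).
#' @return a [medium()].
#' @export
read_medium <- function(path, free_species = character(0)) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "max_uptake") %in% names(tb)))
    stop("medium table needs columns metabolite_id, max_uptake")
  medium(stats::setNames(tb$max_uptake, tb$metabolite_id), free_species)
}

#' Write a medium composition table
#' @param med a [medium()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  utils::write.table(
    data.frame(metabolite_id = names(med$uptake),
               max_uptake = unname(med$uptake)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve a medium metabolite id ("glc" or "glc[e]") to a full "[e]" id.
# Free-species lists are shared configuration and may name species a given
# model simply lacks; with lenient = TRUE those are dropped silently.
resolve_ext_id <- function(ids, model, lenient = FALSE) {
  ext <- model$metabolites$id[model$metabolites$compartment == "e"]
  full <- ifelse(ids %in% ext, ids, paste0(ids, "[e]"))
  bad <- !(full %in% ext)
  if (any(bad) && !lenient)
    stop("medium species without an extracellular metabolite: ",
         paste(ids[bad], collapse = ", "))
  full[!bad]
}

#' Apply medium constraints to a model
#'
#' For every exchange reaction: species listed in the medium get their
#' uptake bound set to `-max_uptake` (uptake is the negative direction of
#' an exchange written `met[e] ->`); free species are left untouched (open
#' in whatever directions the model allows); all remaining exchanges have
#' uptake closed (lower bound raised to 0). Secretion bounds are never
#' modified.
#'
#' @param model a `metabolic_model`.
#' @param med a [medium()].
#' @return the constrained model.
#' @export
apply_medium_constraints <- function(model, med) {
  ex_ids <- list_exchanges(model)
  ex_met <- vapply(ex_ids, function(r) names(model$stoich[[r]]),
                   character(1))
  up_ids <- if (length(med$uptake)) resolve_ext_id(names(med$uptake), model)
            else character(0)
  no_ex <- setdiff(up_ids, ex_met)
  if (length(no_ex))
    stop("medium species with no exchange reaction: ",
         paste(no_ex, collapse = ", "))
  free_ids <- if (length(med$free_species))
    resolve_ext_id(med$free_species, model, lenient = TRUE)
  else character(0)
  for (k in seq_along(ex_ids)) {
    rid <- ex_ids[k]
    met <- ex_met[k]
    ## exchanges written "met[e] ->": coefficient -1, negative flux = uptake
    sgn <- sign(model$stoich[[rid]][[1]])
    if (sgn > 0) next  # "-> met[e]" style source reactions left alone
    i <- match(rid, model$reactions$id)
    if (met %in% up_ids) {
      model$reactions$lb[i] <- -unname(med$uptake[[match(met, up_ids)]])
    } else if (!(met %in% free_ids)) {
      model$reactions$lb[i] <- max(model$reactions$lb[i], 0)
    }
    if (model$reactions$lb[i] > model$reactions$ub[i])
      model$reactions$ub[i] <- model$reactions$lb[i]
  }
  model
}
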