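## Gas constant in kJ/mol/K.
RGAS_KJ <- 8.314e-3

#' Build a thermodynamic table
#'
#' Per-metabolite standard Gibbs energies of formation plus physiological
#' concentration ranges, used to bracket reaction Gibbs energies. Metabolites
#' without explicit ranges get the default concentration box; exempt species
#' (typically water and protons, whose activities are not well described by
#' a concentration) are skipped in the RT concentration term but keep their
#' formation-energy contribution.
#'
#' @param dgf named numeric vector: metabolite id to formation energy
#'   (kJ/mol).
#' @param conc_min,conc_max named numeric vectors (mol/L); defaults applied
#'   to metabolites not listed.
#' @param temperature Kelvin; default 310.15 (physiological).
#' @param default_conc length-2 numeric, default concentration box (mol/L).
#' @param exempt metabolite ids excluded from the RT term.
#' @return object of class `thermo_table`.
#' @export
thermo_table <- function(dgf, conc_min = numeric(0), conc_max = numeric(0),
                         temperature = 310.15,
                         default_conc = c(1e-6, 2e-2),
                         exempt = character(0)) {
  ids <- names(dgf)
  cmin <- stats::setNames(rep(default_conc[1], length(ids)), ids)
  cmax <- stats::setNames(rep(default_conc[2], length(ids)), ids)
  cmin[names(conc_min)] <- conc_min
  cmax[names(conc_max)] <- conc_max
  if (any(cmin <= 0) || any(cmin > cmax))
    stop("concentration ranges must satisfy 0 < conc_min <= conc_max")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(dgf = dgf, conc_min = cmin, conc_max = cmax,
                 temperature = temperature, exempt = exempt),
            class = "thermo_table")
}

#' Read a thermodynamic table
#'
#' TSV with header columns `metabolite_id`, `dgf_kj_mol`, and optionally
#' `conc_min_M`, `conc_max_M`.
#'
#' @param path TSV path.
#' @param ... passed to [thermo_table()] (`temperature`, `exempt`, ...).
#' @return a `thermo_table`.
#' @export
read_thermo_table <- function(path, ...) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "dgf_kj_mol") %in% names(tb)))
    stop("thermo table needs columns metabolite_id, dgf_kj_mol")
  args <- list(dgf = stats::setNames(tb$dgf_kj_mol, tb$metabolite_id), ...)
  if ("conc_min_M" %in% names(tb))
    args$conc_min <- stats::setNames(tb$conc_min_M, tb$metabolite_id)
  if ("conc_max_M" %in% names(tb))
    args$conc_max <- stats::setNames(tb$conc_max_M, tb$metabolite_id)
  do.call(thermo_table, args)
}

#' Write a thermodynamic table
#' @param thermo a `thermo_table`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_thermo_table <- function(thermo, path) {
  utils::write.table(
    data.frame(metabolite_id = names(thermo$dgf),
               dgf_kj_mol = unname(thermo$dgf),
               conc_min_M = unname(thermo$conc_min),
               conc_max_M = unname(thermo$conc_max)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reaction Gibbs-energy range
#'
#' Computes `dG(c) = sum_i s_i dGf_i + RT sum_i s_i ln(c_i)` and brackets it
#' over the concentration box. Because dG is monotone in each `ln c_i`, the
#' extrema sit at box corners: the minimum takes substrates at their maximum
#' and products at their minimum concentration, and vice versa. Exempt
#' species contribute their formation energy but no RT term.
#'
#' @param model a `metabolic_model`.
#' @param thermo a `thermo_table`.
#' @param reaction_id reaction id.
#' @return list with `reaction_id`, `dg_min`, `dg_max` (kJ/mol).
#' @export
reaction_delta_g_range <- function(model, thermo, reaction_id) {
  if (!reaction_id %in% model$reactions$id)
    stop("unknown reaction: ", reaction_id)
  s <- model$stoich[[reaction_id]]
  miss <- setdiff(setdiff(names(s), thermo$exempt), names(thermo$dgf))
  if (length(miss))
    stop("metabolites without thermodynamic data: ",
         paste(miss, collapse = ", "))
  rt <- RGAS_KJ * thermo$temperature
  dg0 <- 0; lo <- 0; hi <- 0
  for (met in names(s)) {
    if (met %in% names(thermo$dgf)) dg0 <- dg0 + s[[met]] * thermo$dgf[[met]]
    if (met %in% thermo$exempt) next
    ci <- thermo$conc_min[[met]]; ca <- thermo$conc_max[[met]]
    if (s[[met]] > 0) {        # product: min at conc_min, max at conc_max
      lo <- lo + s[[met]] * log(ci)
      hi <- hi + s[[met]] * log(ca)
    } else {                   # substrate: min at conc_max, max at conc_min
      lo <- lo + s[[met]] * log(ca)
      hi <- hi + s[[met]] * log(ci)
    }
  }
  list(reaction_id = reaction_id, dg_min = dg0 + rt * lo,
       dg_max = dg0 + rt * hi)
}

#' Fix thermodynamically forced reaction directionalities
#'
#' A reaction whose Gibbs-energy range is strictly negative can only run
#' forward (lower bound raised to 0); strictly positive, only in reverse
#' (upper bound lowered to 0); a range straddling zero leaves the bounds
#' untouched. Bounds are only ever tightened. A forced direction that
#' contradicts an existing strict bound (e.g. a forward-only reaction forced
#' reverse) raises a conflict error naming the reaction.
#'
#' @param model a `metabolic_model`.
#' @param ranges list of ranges as returned by [reaction_delta_g_range()].
#' @return the model with tightened bounds.
#' @export
fix_directionality <- function(model, ranges) {
  for (rg in ranges) {
    i <- match(rg$reaction_id, model$reactions$id)
    if (is.na(i)) stop("range references unknown reaction: ",
                       rg$reaction_id)
    lb <- model$reactions$lb[i]; ub <- model$reactions$ub[i]
    if (rg$dg_max < 0) {           # forward only
      ## a reverse-only reaction (ub <= 0 with room below) cannot be
      ## forced forward
      if (ub <= 0 && lb < ub)
        stop("thermodynamic conflict for reaction ", rg$reaction_id,
             ": forced forward but bounds are [", lb, ", ", ub, "]")
      model$reactions$lb[i] <- max(lb, 0)
    } else if (rg$dg_min > 0) {    # reverse only
      if (lb >= 0 && ub > lb)
        stop("thermodynamic conflict for reaction ", rg$reaction_id,
             ": forced reverse but bounds are [", lb, ", ", ub, "]")
      model$reactions$ub[i] <- min(ub, 0)
    }
  }
  model
}

#' Thermodynamically constrain a model
#'
#' Convenience wrapper: computes Gibbs-energy ranges for every internal
#' (multi-metabolite) reaction whose participants are covered by the table
#' and applies [fix_directionality()]. Boundary reactions and reactions
#' with missing data are skipped and reported.
#'
#' @param model a `metabolic_model`.
#' @param thermo a `thermo_table`.
#' @return list with `model` (constrained) and `skipped` (reaction ids
#'   lacking thermodynamic coverage).
#' @export
thermo_constrain <- function(model, thermo) {
  internal <- setdiff(model$reactions$id, single_metabolite_reactions(model))
  ranges <- list(); skipped <- character(0)
  for (rid in internal) {
    s <- model$stoich[[rid]]
    need <- setdiff(names(s), thermo$exempt)
    if (!all(need %in% names(thermo$dgf))) {
      skipped <- c(skipped, rid)
      next
    }
    ranges[[rid]] <- reaction_delta_g_range(model, thermo, rid)
  }
  list(model = fix_directionality(model, ranges), skipped = skipped,
       ranges = ranges)
}

#' Detect internal flux loops
#'
#' A thermodynamically infeasible loop is a non-zero steady-state flux
#' pattern confined to internal reactions — it survives with every boundary
#' reaction closed. Given a flux vector, this restricts each internal
#' reaction to the signed span of its observed flux, closes all boundary
#' reactions, and repeatedly maximises circulation; each non-trivial
#' solution's support is reported as one cycle component. An empty result
#' certifies the flux vector loop-free at tolerance `tol`.
#'
#' @param model a `metabolic_model`.
#' @param fluxes named flux vector (a steady-state solution).
#' @param tol fluxes with magnitude below `tol` are treated as zero.
#' @return list of character vectors (reaction ids per circulation
#'   component); empty list if loop-free.
#' @export
detect_flux_loops <- function(model, fluxes, tol = 1e-6) {
  boundary <- single_metabolite_reactions(model)
  ids <- model$reactions$id
  v <- stats::setNames(numeric(length(ids)), ids)
  v[names(fluxes)] <- fluxes
  lb <- pmin(0, ifelse(ids %in% boundary, 0, v))
  ub <- pmax(0, ifelse(ids %in% boundary, 0, v))
  lb[abs(lb) < tol] <- 0
  ub[abs(ub) < tol] <- 0
  S <- stoichiometric_matrix(model)
  loops <- list()
  active <- which(lb < 0 | ub > 0)
  while (length(active)) {
    obj <- numeric(length(ids))
    obj[active] <- sign(v[active])  # maximise total circulation magnitude
    r <- solve_lp(obj, A_eq = S, b_eq = numeric(nrow(S)), lb = lb, ub = ub,
                  maximize = TRUE)
    if (r$status != "optimal" || r$objective <= tol) break
    supp <- which(abs(r$x) > tol)
    loops[[length(loops) + 1L]] <- ids[supp]
    lb[supp] <- 0; ub[supp] <- 0
    active <- setdiff(which(lb < 0 | ub > 0), supp)
  }
  loops
}
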