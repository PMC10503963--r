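## Compartment tag a cell's internal compartment receives in the merged
## model: cytosol takes the bare cell label (the "met[bm]" notation), other
## compartments are prefixed ("bm.m" for the bm cell's mitochondrion).
merge_comp_tag <- function(comp, tag) ifelse(comp == "c", tag,
                                             paste0(tag, ".", comp))

#' Merge two cell models into a co-culture model
#'
#' Internal metabolites and reactions of each input are tagged with the
#' cell's label; extracellular (`[e]`) metabolites are unified by id so both
#' cells share one extracellular space, and duplicated exchange reactions
#' are collapsed to a single copy (bounds widened to the union so neither
#' cell's boundary capacity is cut). Both biomass reactions are retained and
#' registered.
#'
#' @param model_a,model_b valid `metabolic_model`s whose objectives are
#'   their biomass reactions.
#' @param tag_a,tag_b distinct cell labels, neither equal to `"e"` nor
#'   colliding with an existing compartment tag.
#' @return object of class `coculture_model`: list with `model` (the merged
#'   `metabolic_model`, objective set to cell A's biomass),
#'   `cells`, `cell_of_reaction` (reaction id -> label or `"shared"`) and
#'   `biomass_ids` (named by cell label).
#' @export
merge_models <- function(model_a, model_b, tag_a = "a", tag_b = "b") {
  validate_model(model_a); validate_model(model_b)
  if (tag_a == tag_b) stop("cell tags must differ")
  if ("e" %in% c(tag_a, tag_b)) stop("cell tag may not be 'e'")
  comps <- union(model_a$metabolites$compartment,
                 model_b$metabolites$compartment)
  if (any(c(tag_a, tag_b) %in% comps))
    stop("cell tag collides with an existing compartment label")
  for (m in list(model_a, model_b))
    if (!(m$objective %in% m$reactions$id))
      stop("biomass reaction missing in input model ", m$id)

  retag <- function(model, tag) {
    mets <- model$metabolites
    internal <- mets$compartment != "e"
    newcomp <- ifelse(internal, merge_comp_tag(mets$compartment, tag),
                      "e")
    newid <- ifelse(internal,
                    paste0(strip_compartment(mets$id), "[", newcomp, "]"),
                    mets$id)
    map <- stats::setNames(newid, mets$id)
    mets$id <- newid; mets$compartment <- newcomp
    ex <- list_exchanges(model)
    rxns <- model$reactions
    shared <- rxns$id %in% ex
    rxns$id <- ifelse(shared, rxns$id, paste0(rxns$id, "_", tag))
    stoich <- lapply(model$stoich, function(s)
      stats::setNames(as.numeric(s), unname(map[names(s)])))
    names(stoich) <- rxns$id
    if (model$objective %in% ex)
      stop("biomass objective of ", model$id,
           " is an exchange reaction; merge needs a per-cell biomass")
    list(mets = mets, rxns = rxns, stoich = stoich, shared = shared,
         objective = paste0(model$objective, "_", tag))
  }
  a <- retag(model_a, tag_a)
  b <- retag(model_b, tag_b)

  mets <- rbind(a$mets, b$mets[!(b$mets$id %in% a$mets$id), , drop = FALSE])
  dup_ex <- intersect(a$rxns$id[a$shared], b$rxns$id[b$shared])
  for (rid in dup_ex) {
    sa <- a$stoich[[rid]]; sb <- b$stoich[[rid]]
    if (!identical(sort(names(sa)), sort(names(sb))) ||
        any(abs(sa[names(sb)] - sb) > 1e-12))
      stop("exchange ", rid, " differs between the two models")
    ia <- match(rid, a$rxns$id); ib <- match(rid, b$rxns$id)
    a$rxns$lb[ia] <- min(a$rxns$lb[ia], b$rxns$lb[ib])
    a$rxns$ub[ia] <- max(a$rxns$ub[ia], b$rxns$ub[ib])
  }
  bkeep <- !(b$rxns$id %in% dup_ex)
  rxns <- rbind(a$rxns, b$rxns[bkeep, , drop = FALSE])
  stoich <- c(a$stoich, b$stoich[b$rxns$id[bkeep]])
  cell_of <- c(
    stats::setNames(ifelse(a$shared, "shared", tag_a), a$rxns$id),
    stats::setNames(ifelse(b$shared, "shared", tag_b),
                    b$rxns$id)[b$rxns$id[bkeep]])
  merged <- metabolic_model(
    mets, rxns, stoich, objective = a$objective,
    id = paste0(model_a$id, "+", model_b$id),
    annotations = list(cells = c(tag_a, tag_b)))
  structure(list(model = merged, cells = c(tag_a, tag_b),
                 cell_of_reaction = cell_of,
                 biomass_ids = stats::setNames(c(a$objective, b$objective),
                                               c(tag_a, tag_b))),
            class = "coculture_model")
}

#' @export
print.coculture_model <- function(x, ...) {
  cat("Co-culture model (cells: ", paste(x$cells, collapse = ", "),
      ")\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Pareto front of the two biomass objectives
#'
#' Epsilon-constraint scan: cell A's biomass is constrained to `n_points`
#' levels spanning `[0, max_a]` and cell B's biomass is maximised at each
#' level. The returned points are filtered to the mutually non-dominated
#' set; the extreme points coincide with the single-objective optima.
#'
#' @param cc a `coculture_model` with both single-cell optima positive and
#'   finite.
#' @param n_points number of scan levels, default 21.
#' @return data.frame with columns `biomass_a`, `biomass_b`; the per-point
#'   full flux vectors are attached as attribute `"fluxes"` (a list).
#' @export
pareto_front <- function(cc, n_points = 21) {
  stopifnot(inherits(cc, "coculture_model"), n_points >= 2)
  bm <- cc$biomass_ids
  opt_a <- fba_optimize(cc$model, bm[[1]], "max")
  opt_b <- fba_optimize(cc$model, bm[[2]], "max")
  for (o in list(opt_a, opt_b))
    if (o$status != "optimal")
      stop("single-objective problem is ", o$status, " for ",
           o$objective_id)
  if (opt_a$objective_value <= 0 || opt_b$objective_value <= 0 ||
      !is.finite(opt_a$objective_value) || !is.finite(opt_b$objective_value))
    stop("both biomass optima must be positive and finite")
  levels_a <- seq(0, opt_a$objective_value, length.out = n_points)
  pts <- data.frame(biomass_a = numeric(0), biomass_b = numeric(0))
  fluxes <- list()
  ia <- match(bm[[1]], cc$model$reactions$id)
  for (eps in levels_a) {
    m <- cc$model
    m$reactions$lb[ia] <- max(m$reactions$lb[ia], eps)
    if (m$reactions$lb[ia] > m$reactions$ub[ia])
      m$reactions$lb[ia] <- m$reactions$ub[ia]
    r <- fba_optimize(m, bm[[2]], "max")
    if (r$status != "optimal") next
    pts <- rbind(pts, data.frame(biomass_a = unname(r$fluxes[bm[[1]]]),
                                 biomass_b = r$objective_value))
    fluxes[[length(fluxes) + 1L]] <- r$fluxes
  }
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    dominated <- any(pts$biomass_a > pts$biomass_a[i] + 1e-9 &
                       pts$biomass_b >= pts$biomass_b[i] - 1e-9) ||
      any(pts$biomass_a >= pts$biomass_a[i] - 1e-9 &
            pts$biomass_b > pts$biomass_b[i] + 1e-9)
    if (dominated) keep[i] <- FALSE
  }
  dup <- duplicated(round(pts[, c("biomass_a", "biomass_b")], 9))
  keep <- keep & !dup
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fluxes") <- fluxes[keep]
  out
}

#' Electron-transport-chain reaction map
#'
#' Names the reactions playing the pharmacological roles in the staged
#' respirometry protocol: complexes I, III and IV, the ATP synthase
#' (complex V), the proton leak (may be `NA` when the model has none) and
#' the oxygen exchange.
#'
#' @param complex_i,complex_iii,complex_iv,atp_synthase,oxygen_exchange
#'   reaction ids.
#' @param leak reaction id or `NA`.
#' @return object of class `etc_map`.
#' @export
etc_map <- function(complex_i, complex_iii, complex_iv, atp_synthase,
                    oxygen_exchange, leak = NA_character_) {
  structure(list(complex_i = complex_i, complex_iii = complex_iii,
                 complex_iv = complex_iv, atp_synthase = atp_synthase,
                 leak = leak, oxygen_exchange = oxygen_exchange),
            class = "etc_map")
}

check_etc <- function(model, etc) {
  ids <- unlist(etc[c("complex_i", "complex_iii", "complex_iv",
                      "atp_synthase", "oxygen_exchange")])
  bad <- setdiff(ids, model$reactions$id)
  if (length(bad)) stop("ETC map id not in model: ", bad[1])
  if (!is.na(etc$leak) && !(etc$leak %in% model$reactions$id))
    stop("ETC map id not in model: ", etc$leak)
}

## O2 magnitude of a reporting reaction at a stage: either the FVA midpoint
## with the stage objective pinned at its optimum ("midpoint", the default
## convention) or the raw flux of the single returned solution ("single").
stage_o2 <- function(model, objective_id, report_id, convention) {
  opt <- fba_optimize(model, objective_id, "max")
  if (opt$status != "optimal")
    stop("stage optimisation (", objective_id, ") is ", opt$status)
  if (convention == "single")
    return(list(o2 = abs(unname(opt$fluxes[report_id])), opt = opt))
  i <- match(objective_id, model$reactions$id)
  model$reactions$lb[i] <- model$reactions$ub[i] <- opt$objective_value
  rng <- fva(model, report_id, objective_fraction = 0)
  list(o2 = abs(rng$midpoint), opt = opt)
}

#' Staged in-silico respirometry protocol
#'
#' Reproduces the four stages of a high-resolution respirometry experiment
#' on a constraint-based model, each starting from the unperturbed model:
#' basal (biomass objective), oligomycin (ATP synthase fixed to zero, ETC
#' complexes blocked from running in reverse, biomass objective), FCCP
#' (uncoupled: maximise complex IV flux) and rotenone + antimycin A
#' (complexes I and III fixed to zero, biomass objective). Oxygen flux
#' magnitudes are reported per the chosen convention (see Details) and the
#' derived quantities follow: ATP-linked respiration = basal - oligomycin,
#' spare capacity = FCCP - basal.
#'
#' @details With `convention = "midpoint"` (default) each stage's oxygen
#' magnitude is the FVA midpoint of the reporting reaction with the stage
#' objective pinned at its optimum, which is well-defined under alternate
#' optima; `"single"` reports the flux of the single solver solution.
#'
#' @param model a `metabolic_model` feasible with positive biomass.
#' @param etc an [etc_map()].
#' @param convention `"midpoint"` or `"single"`.
#' @param report_reaction reaction whose flux magnitude is reported as the
#'   oxygen signal; defaults to the map's oxygen exchange. In a co-culture,
#'   pass the cell's complex IV instead (the exchange is shared).
#' @return object of class `respiration_profile`: list with `basal_o2`,
#'   `oligomycin_o2`, `fccp_o2`, `rot_aa_o2`, `atp_linked`,
#'   `spare_capacity`, and `stages` (per-stage details).
#' @export
respiration_protocol <- function(model, etc,
                                 convention = c("midpoint", "single"),
                                 report_reaction = etc$oxygen_exchange) {
  convention <- match.arg(convention)
  check_etc(model, etc)
  biomass <- model$objective

  basal <- tryCatch(stage_o2(model, biomass, report_reaction, convention),
                    error = function(e)
                      stop("basal stage failed (objective ", biomass, "): ",
                           conditionMessage(e)))

  m2 <- set_bounds(model, etc$atp_synthase, lb = 0, ub = 0)
  for (cx in c(etc$complex_i, etc$complex_iii, etc$complex_iv)) {
    i <- match(cx, m2$reactions$id)
    m2$reactions$lb[i] <- max(m2$reactions$lb[i], 0)
  }
  oligo <- tryCatch(stage_o2(m2, biomass, report_reaction, convention),
                    error = function(e)
                      stop("oligomycin stage failed (ATP synthase = 0, ",
                           "complexes irreversible): ",
                           conditionMessage(e)))

  ## FCCP is a protonophore: the proton-leak constraint is relaxed so the
  ## gradient can dissipate without ATP synthesis, then complex IV flux is
  ## maximised
  m3 <- model
  if (!is.na(etc$leak)) {
    i <- match(etc$leak, m3$reactions$id)
    m3$reactions$ub[i] <- Inf
  }
  fccp <- tryCatch(stage_o2(m3, etc$complex_iv, report_reaction,
                            convention),
                   error = function(e)
                     stop("FCCP stage failed (maximise complex IV): ",
                          conditionMessage(e)))

  m4 <- set_bounds(model, c(etc$complex_i, etc$complex_iii),
                   lb = c(0, 0), ub = c(0, 0))
  rot <- tryCatch(stage_o2(m4, biomass, report_reaction, convention),
                  error = function(e)
                    stop("rotenone/antimycin stage failed ",
                         "(complex I = complex III = 0): ",
                         conditionMessage(e)))

  structure(list(
    basal_o2 = basal$o2, oligomycin_o2 = oligo$o2, fccp_o2 = fccp$o2,
    rot_aa_o2 = rot$o2,
    atp_linked = basal$o2 - oligo$o2,
    spare_capacity = fccp$o2 - basal$o2,
    stages = list(basal = basal$opt, oligomycin = oligo$opt,
                  fccp = fccp$opt, rot_aa = rot$opt)),
    class = "respiration_profile")
}

#' @export
print.respiration_profile <- function(x, ...) {
  cat("In-silico respirometry (O2 flux magnitudes, mmol/gDW/h)\n")
  cat(sprintf("  basal:            %.4f\n", x$basal_o2))
  cat(sprintf("  oligomycin (leak):%.4f\n", x$oligomycin_o2))
  cat(sprintf("  FCCP (maximal):   %.4f\n", x$fccp_o2))
  cat(sprintf("  rot/AA (non-mito):%.4f\n", x$rot_aa_o2))
  cat(sprintf("  ATP-linked:       %.4f\n", x$atp_linked))
  cat(sprintf("  spare capacity:   %.4f\n", x$spare_capacity))
  invisible(x)
}

#' Constrain a model with flux intervals ("phenotype tuning")
#'
#' Intersects each matched reaction's bounds with a supplied interval —
#' typically the confidence intervals of a metabolic flux analysis fit,
#' which thereby act as lower and upper bounds in the constraint-based
#' model. Unmatched ids are collected and reported (attribute
#' `"unmatched"`). An empty intersection errors naming the reaction. If the
#' tuned model is infeasible, the error carries a greedily computed hint:
#' the subset of tuned reactions whose relaxation restores feasibility.
#'
#' @param model a `metabolic_model`.
#' @param intervals data.frame with columns `reaction_id`, `lo`, `hi`, or a
#'   named list of `c(lo, hi)`.
#' @return the tuned model (attribute `"unmatched"` lists skipped ids).
#' @export
apply_flux_intervals <- function(model, intervals) {
  if (!is.data.frame(intervals)) {
    intervals <- data.frame(
      reaction_id = names(intervals),
      lo = vapply(intervals, `[[`, numeric(1), 1),
      hi = vapply(intervals, `[[`, numeric(1), 2),
      stringsAsFactors = FALSE)
  }
  if (any(intervals$lo > intervals$hi))
    stop("interval lo > hi for reaction ",
         intervals$reaction_id[intervals$lo > intervals$hi][1])
  matched <- intervals$reaction_id %in% model$reactions$id
  unmatched <- intervals$reaction_id[!matched]
  tuned_ids <- intervals$reaction_id[matched]
  orig <- model
  for (k in which(matched)) {
    i <- match(intervals$reaction_id[k], model$reactions$id)
    lo <- max(model$reactions$lb[i], intervals$lo[k])
    hi <- min(model$reactions$ub[i], intervals$hi[k])
    if (lo > hi + 1e-12)
      stop("empty bound intersection for reaction ",
           intervals$reaction_id[k])
    model$reactions$lb[i] <- min(lo, hi)
    model$reactions$ub[i] <- hi
  }
  chk <- fba_optimize(model)
  if (chk$status != "optimal") {
    hint <- character(0)
    relaxed <- model
    for (rid in tuned_ids) {
      i <- match(rid, relaxed$reactions$id)
      j <- match(rid, orig$reactions$id)
      relaxed$reactions$lb[i] <- orig$reactions$lb[j]
      relaxed$reactions$ub[i] <- orig$reactions$ub[j]
      hint <- c(hint, rid)
      if (fba_optimize(relaxed)$status == "optimal") break
    }
    stop("model infeasible after tuning; relaxing these tuned reactions ",
         "restores feasibility: ", paste(hint, collapse = ", "))
  }
  attr(model, "unmatched") <- unmatched
  model
}

#' Convert biomass flux to a specific growth rate
#'
#' The biomass pseudo-reaction flux (mmol/gDW/h) times the dry mass of one
#' millimole of biomass (gDW/mmol) gives the specific growth rate in 1/h.
#' Under the common convention that one gram dry weight corresponds to one
#' millimole of biomass the conversion factor is 1, e.g. a biomass flux of
#' 0.0306 mmol/gDW/h is a growth rate of 0.0306 /h.
#'
#' @param biomass_flux biomass reaction flux, mmol/gDW/h, >= 0.
#' @param grams_per_mmol dry mass per millimole of biomass, gDW/mmol,
#'   default 1.
#' @return growth rate in 1/h.
#' @export
growth_rate_from_biomass_flux <- function(biomass_flux,
                                          grams_per_mmol = 1) {
  if (any(biomass_flux < 0) || any(grams_per_mmol < 0))
    stop("inputs must be non-negative")
  biomass_flux * grams_per_mmol
}
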