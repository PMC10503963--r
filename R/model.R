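#' Construct a metabolic model
#'
#' A `metabolic_model` is the package's core container for a stoichiometric
#' model: a metabolite table, a reaction table, per-reaction stoichiometries,
#' and a biomass objective. Metabolite ids carry their compartment as a
#' bracket suffix (`"glc[e]"`, `"pyr[c]"`); the shared extracellular
#' compartment is always tagged `"e"`. Flux units are mmol/gDW/h throughout.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   and optionally `formula` (elemental formula string, `NA` allowed) and
#'   `dgf` (standard Gibbs energy of formation, kJ/mol, `NA` allowed).
#' @param reactions data.frame with columns `id`, `lb`, `ub` (flux bounds,
#'   mmol/gDW/h), and optionally `gpr` (boolean gene association string,
#'   `""` for none) and `subsystem`.
#' @param stoich named list, one entry per reaction id, each a named numeric
#'   vector of signed coefficients keyed by metabolite id. Coefficients must
#'   be non-zero; negatives are consumed, positives produced.
#' @param objective reaction id of the biomass (objective) reaction.
#' @param id model identifier string.
#' @param annotations free-form named list.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich, objective,
                            id = "model", annotations = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$dgf)) metabolites$dgf <- NA_real_
  if (is.null(metabolites$compartment))
    metabolites$compartment <- compartment_of(metabolites$id)
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  reactions$gpr[is.na(reactions$gpr)] <- ""
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  m <- structure(list(
    id = id,
    metabolites = metabolites[, c("id", "name", "compartment", "formula", "dgf")],
    reactions = reactions[, c("id", "lb", "ub", "gpr", "subsystem")],
    stoich = stoich[reactions$id],
    objective = objective,
    annotations = annotations
  ), class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks every structural invariant: unique ids, non-empty compartment tags,
#' ordered bounds, non-empty stoichiometries with non-zero coefficients that
#' resolve to metabolites, and a resolvable objective. Violations raise an
#' error naming the offending id.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ", mets$id[duplicated(mets$id)][1])
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ", rxns$id[duplicated(rxns$id)][1])
  if (any(bad <- is.na(mets$compartment) | mets$compartment == ""))
    stop("empty compartment tag for metabolite: ", mets$id[bad][1])
  if (any(bad <- !(rxns$lb <= rxns$ub)))
    stop("lower bound exceeds upper bound for reaction: ", rxns$id[bad][1])
  if (!setequal(names(model$stoich), rxns$id) ||
      length(model$stoich) != nrow(rxns))
    stop("stoichiometry list does not match reaction table")
  for (rid in rxns$id) {
    s <- model$stoich[[rid]]
    if (length(s) == 0) stop("empty stoichiometry for reaction: ", rid)
    if (any(s == 0)) stop("zero coefficient in reaction: ", rid)
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      stop("reaction ", rid, " references unknown metabolite: ", unknown[1])
  }
  if (!(model$objective %in% rxns$id))
    stop("objective reaction not in model: ", model$objective)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " (compartments: ", paste(sort(unique(x$metabolites$compartment)),
                                collapse = ", "), ")\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", length(list_exchanges(x)), " exchanges)\n", sep = "")
  cat("  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

# Compartment tag from a bracket-suffixed metabolite id ("glc[e]" -> "e").
compartment_of <- function(ids) {
  tag <- sub("^.*\\[([^][]+)\\]$", "\\1", ids)
  tag[tag == ids] <- ""
  tag
}

# Bare metabolite name without the compartment suffix.
strip_compartment <- function(ids) sub("\\[[^][]+\\]$", "", ids)

#' Stoichiometric matrix of a model
#'
#' Dense signed matrix S with one row per metabolite and one column per
#' reaction, in the model's own list orders. Entry (i, j) is reaction j's
#' coefficient for metabolite i, 0 where the metabolite does not participate.
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix with dimnames (metabolite ids x reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    s <- model$stoich[[rxns[j]]]
    S[names(s), j] <- s
  }
  S
}

#' List exchange reactions
#'
#' An exchange is a boundary reaction touching exactly one metabolite, and
#' that metabolite is extracellular (compartment tag `"e"`). Transports
#' between compartments (two or more metabolites) are not exchanges, nor are
#' single-metabolite demand/sink reactions on internal metabolites.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
list_exchanges <- function(model) {
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  is_ex <- vapply(model$reactions$id, function(rid) {
    s <- model$stoich[[rid]]
    length(s) == 1 && comp[[names(s)]] == "e"
  }, logical(1))
  model$reactions$id[is_ex]
}

# Reactions with a single metabolite in their stoichiometry (boundary
# reactions: exchanges, demands, sinks). These are exempt from mass balance.
single_metabolite_reactions <- function(model) {
  model$reactions$id[vapply(model$stoich, length, integer(1)) == 1]
}

#' Parse an elemental formula string
#'
#' Accepts formulas of the form `"C6H12O6"` (element symbols, one upper-case
#' letter optionally followed by lower-case letters, each with an optional
#' count that may be fractional). Returns a named numeric vector of atom
#' counts, or `NULL` when the string is not parseable.
#'
#' @param formula formula string.
#' @return named numeric vector, or `NULL`.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "") return(NULL)
  m <- gregexpr("[A-Z][a-z]*[0-9.]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) return(NULL)
  out <- numeric(0)
  for (tok in toks) {
    el <- sub("[0-9.]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (n == "") 1 else suppressWarnings(as.numeric(n))
    if (is.na(cnt)) return(NULL)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) + cnt
  }
  out
}

#' Check elemental balance of every reaction
#'
#' Sums coefficient x atom-count per element across each reaction.
#' Single-metabolite boundary reactions (exchanges, demands, sinks) are
#' exempt: they move mass across the system boundary by design. Reactions
#' involving a metabolite whose formula fails to parse are skipped with a
#' warning and listed as unchecked.
#'
#' @param model a `metabolic_model`; at least one metabolite needs a formula.
#' @param tol absolute imbalance tolerated per element.
#' @return list with `imbalanced` (data.frame reaction_id, element,
#'   imbalance) and `unchecked` (character vector of reaction ids).
#' @export
check_balance <- function(model, tol = 1e-9) {
  if (all(is.na(model$metabolites$formula)))
    stop("no metabolite has a formula; nothing to check")
  atoms <- lapply(model$metabolites$formula, parse_formula)
  names(atoms) <- model$metabolites$id
  exempt <- single_metabolite_reactions(model)
  imb <- list()
  unchecked <- character(0)
  for (rid in setdiff(model$reactions$id, exempt)) {
    s <- model$stoich[[rid]]
    a <- atoms[names(s)]
    if (any(vapply(a, is.null, logical(1)))) {
      warning("unparseable or missing formula in reaction ", rid,
              "; skipped", call. = FALSE)
      unchecked <- c(unchecked, rid)
      next
    }
    bal <- numeric(0)
    for (k in seq_along(s)) {
      for (el in names(a[[k]]))
        bal[el] <- (if (el %in% names(bal)) bal[[el]] else 0) +
          s[[k]] * a[[k]][[el]]
    }
    off <- names(bal)[abs(bal) > tol]
    if (length(off))
      imb[[rid]] <- data.frame(reaction_id = rid, element = off,
                               imbalance = unname(bal[off]),
                               stringsAsFactors = FALSE)
  }
  list(
    imbalanced = if (length(imb)) do.call(rbind, c(imb, make.row.names = FALSE))
                 else data.frame(reaction_id = character(0),
                                 element = character(0),
                                 imbalance = numeric(0)),
    unchecked = unchecked
  )
}

#' Set reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @param lb,ub new bounds; `NULL` leaves the bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (any(is.na(i))) stop("unknown reaction: ", reaction_id[is.na(i)][1])
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  bad <- model$reactions$lb[i] > model$reactions$ub[i]
  if (any(bad))
    stop("lower bound exceeds upper bound for reaction: ",
         reaction_id[bad][1])
  model
}

# Convenience accessor for bounds of one reaction.
get_bounds <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  c(lb = model$reactions$lb[i], ub = model$reactions$ub[i])
}
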