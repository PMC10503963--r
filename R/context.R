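#' Construct an expression presence/absence dataset
#'
#' Binary present/absent calls per gene and sample, the input to
#' expression-based model extraction. Calls are upstream of this package:
#' platform-specific normalisation and detection calls are assumed done.
#'
#' @param calls binary matrix (genes x samples), entries 0/1, with rownames
#'   (gene ids) and colnames (sample ids).
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(calls) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls need gene rownames and sample colnames")
  if (!all(calls %in% c(0, 1))) stop("calls must be 0/1")
  if (ncol(calls) < 1) stop("need at least one sample")
  structure(list(genes = rownames(calls), samples = colnames(calls),
                 calls = calls), class = "expression_dataset")
}

#' Read an expression presence table
#'
#' TSV with gene ids in the first column and one 0/1 column per sample.
#'
#' @param path TSV path.
#' @return an `expression_dataset`.
#' @export
read_expression <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, row.names = 1,
                          check.names = FALSE)
  expression_dataset(as.matrix(tb))
}

#' Write an expression presence table
#' @param expr an `expression_dataset`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = expr$genes, expr$calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene ubiquity scores
#'
#' The ubiquity of a gene is the fraction of samples in which it is called
#' present — the expression evidence score propagated onto reactions.
#'
#' @param expr an `expression_dataset`.
#' @return named numeric vector in `[0, 1]`, one entry per gene.
#' @export
gene_ubiquity <- function(expr) {
  rowMeans(expr$calls)
}

#' Score reactions from gene scores via GPR rules
#'
#' Evaluates each reaction's gene association with AND mapped to `min` and
#' OR to `max` over the gene scores. Reactions without a GPR get `NA`
#' (no evidence — distinct from evidence of absence). Genes missing from
#' `gene_scores` default to 0 with a warning.
#'
#' @param model a `metabolic_model`.
#' @param gene_scores named numeric vector in `[0, 1]`.
#' @return data.frame `reaction_id`, `expression_score` (`NA` for empty
#'   GPR).
#' @export
score_reactions <- function(model, gene_scores) {
  all_genes <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  miss <- setdiff(all_genes, names(gene_scores))
  if (length(miss))
    warning("genes without scores (default 0): ",
            paste(miss, collapse = ", "), call. = FALSE)
  data.frame(
    reaction_id = model$reactions$id,
    expression_score = vapply(model$reactions$gpr, function(g)
      eval_gpr(g, gene_scores, missing_value = 0, quiet = TRUE),
      numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

## Default currency metabolites excluded from connectivity adjacency
## (bare names, matched in any compartment): without this exclusion every
## reaction neighbours every other through ATP/water/protons.
CURRENCY_METS <- c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph",
                   "h2o", "h", "co2", "pi", "ppi", "o2", "coa")

#' Update reaction scores with network connectivity
#'
#' The connectivity score of a reaction is the mean expression score of the
#' reactions it shares at least one non-currency metabolite with (neighbours
#' without an expression score are excluded from the mean; no scored
#' neighbours gives 0). The combined score is
#' `w * expression + (1 - w) * connectivity`; reactions with no expression
#' score use the connectivity score alone.
#'
#' @param model a `metabolic_model`.
#' @param scores data.frame from [score_reactions()].
#' @param w weight on the expression component, default 0.75.
#' @param currency bare metabolite names ignored when building adjacency.
#' @return data.frame `reaction_id`, `expression_score`,
#'   `connectivity_score`, `combined`.
#' @export
connectivity_update <- function(model, scores, w = 0.75,
                                currency = CURRENCY_METS) {
  stopifnot(w >= 0, w <= 1)
  expr <- stats::setNames(scores$expression_score, scores$reaction_id)
  ids <- model$reactions$id
  met_rxns <- list()  # non-currency metabolite -> reactions touching it
  for (rid in ids) {
    for (met in names(model$stoich[[rid]])) {
      if (strip_compartment(met) %in% currency) next
      met_rxns[[met]] <- c(met_rxns[[met]], rid)
    }
  }
  conn <- stats::setNames(numeric(length(ids)), ids)
  for (rid in ids) {
    nb <- unique(unlist(met_rxns[names(model$stoich[[rid]])]))
    nb <- setdiff(nb, rid)
    nb_scores <- expr[nb]
    nb_scores <- nb_scores[!is.na(nb_scores)]
    conn[rid] <- if (length(nb_scores)) mean(nb_scores) else 0
  }
  combined <- ifelse(is.na(expr[ids]), conn[ids],
                     w * expr[ids] + (1 - w) * conn[ids])
  data.frame(reaction_id = ids,
             expression_score = unname(expr[ids]),
             connectivity_score = unname(conn[ids]),
             combined = unname(combined),
             stringsAsFactors = FALSE)
}

#' Prune a model to a context-specific sub-model
#'
#' Non-core reactions are visited in ascending combined-score order (ties
#' broken lexicographically by reaction id). A reaction is removed iff its
#' score is below `threshold` AND the pruned model still attains at least
#' `min_objective_fraction` of the original biomass optimum AND every core
#' reaction can still carry non-zero flux (checked by FVA over the core
#' set). Core reactions are never removed. The procedure is deterministic.
#'
#' @param model a `metabolic_model` with a positive biomass optimum.
#' @param scores data.frame from [connectivity_update()].
#' @param core_ids reaction ids that must be preserved and stay flux-capable.
#' @param threshold removal score threshold in `[0, 1]`.
#' @param min_objective_fraction fraction of the original optimum that must
#'   remain attainable, default 0.9.
#' @param tol flux threshold for "can carry flux".
#' @return the pruned `metabolic_model`.
#' @export
prune_model <- function(model, scores, core_ids, threshold,
                        min_objective_fraction = 0.9, tol = 1e-6) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!all(core_ids %in% model$reactions$id))
    stop("core id not in model: ",
         setdiff(core_ids, model$reactions$id)[1])
  base <- fba_optimize(model)
  if (base$status != "optimal" || base$objective_value <= tol)
    stop("model cannot attain a positive objective; nothing to preserve")
  target <- min_objective_fraction * base$objective_value
  core_ids <- union(core_ids, model$objective)
  sc <- stats::setNames(scores$combined, scores$reaction_id)
  cand <- setdiff(model$reactions$id, core_ids)
  cand <- cand[!is.na(sc[cand]) & sc[cand] < threshold]
  cand <- cand[order(sc[cand], cand)]
  current <- model
  for (rid in cand) {
    trial <- remove_reactions(current, rid)
    ok <- tryCatch({
      opt <- fba_optimize(trial)
      if (opt$status != "optimal" || opt$objective_value < target - 1e-9)
        FALSE
      else {
        core_rng <- fva(trial, intersect(core_ids, trial$reactions$id),
                        objective_fraction = 0)
        all(pmax(abs(core_rng$minimum), abs(core_rng$maximum)) > tol)
      }
    }, error = function(e) FALSE)
    if (ok) current <- trial
  }
  current
}

#' Remove reactions (and newly orphaned metabolites) from a model
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids ids to drop.
#' @return the reduced model.
#' @export
remove_reactions <- function(model, reaction_ids) {
  keep <- !(model$reactions$id %in% reaction_ids)
  if (model$objective %in% reaction_ids)
    stop("cannot remove the objective reaction")
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoich <- model$stoich[model$reactions$id]
  used <- unique(unlist(lapply(model$stoich, names)))
  mkeep <- model$metabolites$id %in% used
  model$metabolites <- model$metabolites[mkeep, , drop = FALSE]
  rownames(model$metabolites) <- NULL
  validate_model(model)
  model
}
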