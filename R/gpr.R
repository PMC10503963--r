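#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `and` / `or`
#' operators (case-insensitive) and parentheses, e.g.
#' `"(g1 and g2) or g3"`. `or` binds looser than `and`. The empty string
#' parses to `NULL` (no gene association).
#'
#' @param text GPR string.
#' @return `NULL` for an empty rule, otherwise a tree: either a gene id
#'   (character scalar) or a list with elements `op` (`"and"`/`"or"`) and
#'   `args` (list of subtrees).
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokens(text)
  st <- list(pos = 1L, toks = toks)
  res <- gpr_parse_or(st)
  if (res$st$pos <= length(toks))
    stop("malformed GPR '", text, "': trailing input at token ",
         res$st$pos)
  res$node
}

gpr_tokens <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (!length(toks)) stop("malformed GPR: '", text, "'")
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA

gpr_parse_or <- function(st) {
  left <- gpr_parse_and(st)
  st <- left$st
  args <- list(left$node)
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_and(st)
    st <- nxt$st
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  list(node = node, st = st)
}

gpr_parse_and <- function(st) {
  left <- gpr_parse_atom(st)
  st <- left$st
  args <- list(left$node)
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_atom(st)
    st <- nxt$st
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  list(node = node, st = st)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("malformed GPR: unexpected end of rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    st <- inner$st
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("malformed GPR: unbalanced parenthesis")
    st$pos <- st$pos + 1L
    return(list(node = inner$node, st = st))
  }
  if (tolower(tk) %in% c("and", "or", ")"))
    stop("malformed GPR: unexpected token '", tk, "'")
  st$pos <- st$pos + 1L
  list(node = tk, st = st)
}

#' Genes referenced by a GPR rule
#'
#' @param gpr GPR string or parsed tree.
#' @return character vector of gene ids (no duplicates).
#' @export
gpr_genes <- function(gpr) {
  tree <- if (is.character(gpr) && length(gpr) == 1 && !is.list(gpr))
    parse_gpr(gpr) else gpr
  if (is.null(tree)) return(character(0))
  walk <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Evaluate a GPR rule over gene scores
#'
#' AND maps to `min`, OR to `max`, applied recursively — the standard
#' soft-boolean reading used when scoring reactions from expression
#' presence fractions. Genes absent from `scores` default to `missing_value`
#' (with a warning unless `quiet`).
#'
#' @param gpr GPR string or parsed tree; empty rule returns `NA`.
#' @param scores named numeric vector of per-gene scores in `[0, 1]`.
#' @param missing_value score assumed for genes without an entry.
#' @param quiet suppress the missing-gene warning.
#' @return numeric scalar, or `NA` for an empty rule.
#' @export
eval_gpr <- function(gpr, scores, missing_value = 0, quiet = FALSE) {
  tree <- if (!is.list(gpr)) parse_gpr(gpr) else gpr
  if (is.null(tree)) return(NA_real_)
  miss <- setdiff(gpr_genes(tree), names(scores))
  if (length(miss) && !quiet)
    warning("genes without scores (default ", missing_value, "): ",
            paste(miss, collapse = ", "), call. = FALSE)
  ev <- function(node) {
    if (is.character(node)) {
      if (node %in% names(scores)) return(unname(scores[[node]]))
      return(missing_value)
    }
    vals <- vapply(node$args, ev, numeric(1))
    if (node$op == "and") min(vals) else max(vals)
  }
  ev(tree)
}

# Deterministic re-serialisation of a parsed GPR tree.
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
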