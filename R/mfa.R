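## 13C metabolic flux analysis on atom-mapped networks via the elementary
## metabolite unit (EMU) framework: parse atom transitions, decompose the
## network into the EMUs needed for a set of measured fragments, simulate
## mass isotopomer distributions (MIDs) layer by layer, and fit fluxes to
## measured MIDs by variance-weighted multistart least squares.

#' Parse an atom-mapped reaction network
#'
#' One reaction per line:
#' `v1: A (abc) -> B (ab) + C (c)`. Atom strings are single letters, each
#' used exactly once per side, with the same letter multiset on both sides.
#' Alternative equivalent mappings for a rotationally symmetric species are
#' separated by `|` inside the parentheses
#' (`OAA (bcde|edcb)`) and expand into equal-probability mapping variants.
#' Blank lines and `#` comments are ignored.
#'
#' @param text character vector of lines, a single string with newlines, or
#'   a file path.
#' @return object of class `atom_network`: transitions with expanded
#'   mapping variants, plus inferred per-metabolite carbon counts and
#'   substrate/product classification.
#' @export
parse_atom_network <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  trans <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[ln]))
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^([^:]+):(.*)->(.*)$", line))[[1]]
    if (length(m) != 4)
      stop("atom network parse error at line ", ln, ": '", line, "'")
    rid <- trimws(m[2])
    lhs <- parse_atom_side(m[3], ln)
    rhs <- parse_atom_side(m[4], ln)
    check_letters <- function(side) {
      lets <- unlist(lapply(side, function(sp) sp$alts[[1]]))
      if (anyDuplicated(lets))
        stop("atom network parse error at line ", ln,
             ": letter used twice on one side")
      lets
    }
    l_lets <- sort(check_letters(lhs))
    r_lets <- sort(check_letters(rhs))
    if (!identical(l_lets, r_lets))
      stop("atom network parse error at line ", ln,
           ": unbalanced atom letters (", paste(l_lets, collapse = ""),
           " vs ", paste(r_lets, collapse = ""), ")")
    for (sp in c(lhs, rhs))
      for (alt in sp$alts)
        if (!identical(sort(alt), sort(sp$alts[[1]])))
          stop("atom network parse error at line ", ln,
               ": alternatives of ", sp$met,
               " must permute the same letters")
    ## expand alternative mappings into variants (equal probability)
    nalt <- vapply(rhs, function(sp) length(sp$alts), integer(1))
    lalt <- vapply(lhs, function(sp) length(sp$alts), integer(1))
    grid <- expand.grid(c(lapply(lalt, seq_len), lapply(nalt, seq_len)))
    nl <- length(lhs)
    variants <- lapply(seq_len(nrow(grid)), function(g) {
      list(prob = 1 / nrow(grid),
           lhs = lapply(seq_along(lhs), function(i)
             list(met = lhs[[i]]$met,
                  atoms = lhs[[i]]$alts[[grid[g, i]]])),
           rhs = lapply(seq_along(rhs), function(i)
             list(met = rhs[[i]]$met,
                  atoms = rhs[[i]]$alts[[grid[g, nl + i]]])))
    })
    trans[[rid]] <- list(id = rid,
                         lhs_mets = vapply(lhs, `[[`, "", "met"),
                         rhs_mets = vapply(rhs, `[[`, "", "met"),
                         variants = variants, line = line)
  }
  if (!length(trans)) stop("empty atom network")
  carbons <- list()
  for (tr in trans) {
    v1 <- tr$variants[[1]]
    for (sp in c(v1$lhs, v1$rhs)) {
      k <- length(sp$atoms)
      if (!is.null(carbons[[sp$met]]) && carbons[[sp$met]] != k)
        stop("inconsistent carbon count for ", sp$met)
      carbons[[sp$met]] <- k
    }
  }
  consumed <- unique(unlist(lapply(trans, `[[`, "lhs_mets")))
  produced <- unique(unlist(lapply(trans, `[[`, "rhs_mets")))
  structure(list(
    transitions = trans,
    carbons = unlist(carbons),
    substrates = setdiff(consumed, produced),
    products = setdiff(produced, consumed),
    balanced = intersect(consumed, produced)),
    class = "atom_network")
}

parse_atom_side <- function(side, ln) {
  parts <- strsplit(side, "+", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    p <- trimws(p)
    m <- regmatches(p, regexec("^([^() ]+)\\s*\\(([^()]+)\\)$", p))[[1]]
    if (length(m) != 3)
      stop("atom network parse error at line ", ln, ": species '", p, "'")
    alts <- lapply(strsplit(m[3], "|", fixed = TRUE)[[1]],
                   function(a) strsplit(trimws(a), "")[[1]])
    list(met = m[2], alts = alts)
  })
}

#' Re-serialise an atom network
#' @param network an `atom_network`.
#' @return character vector of reaction lines (original text).
#' @export
format_atom_network <- function(network) {
  vapply(network$transitions, `[[`, "", "line")
}

#' @export
print.atom_network <- function(x, ...) {
  cat("Atom-mapped network: ", length(x$transitions), " reactions, ",
      length(x$carbons), " metabolites (",
      sum(x$carbons), " mapped carbons)\n", sep = "")
  cat("  substrates: ", paste(x$substrates, collapse = ", "), "\n", sep = "")
  cat("  products:   ", paste(x$products, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Fragment notation: "Met[1,2,3]" <-> list(met, pos).
parse_fragment <- function(x) {
  if (is.list(x)) return(list(met = x$met, pos = sort(as.integer(x$pos))))
  m <- regmatches(x, regexec("^([^][]+)\\[([0-9,]+)\\]$", x))[[1]]
  if (length(m) != 3) stop("bad fragment spec: ", x)
  list(met = m[2], pos = sort(as.integer(strsplit(m[3], ",")[[1]])))
}

fragment_key <- function(met, pos)
  paste0(met, "[", paste(sort(pos), collapse = ","), "]")

#' Decompose an atom network into the EMU graph for target fragments
#'
#' Walks backwards from each target fragment: an EMU (a metabolite plus an
#' ordered atom subset) is produced, for every reaction variant forming its
#' metabolite, from the reactant EMUs its atoms trace back to — one source
#' EMU (a transfer) or several (a convolution, when the product's atoms come
#' from more than one reactant). The resulting graph is layered by EMU size,
#' which is the order the simulator solves it in.
#'
#' @param network an `atom_network`.
#' @param target_fragments character vector (`"Met[1,2,3]"`) or list of
#'   `list(met, pos)`.
#' @return object of class `emu_network`.
#' @export
decompose_emus <- function(network, target_fragments) {
  targets <- vapply(lapply(target_fragments, parse_fragment),
                    function(f) fragment_key(f$met, f$pos), character(1))
  for (f in lapply(target_fragments, parse_fragment)) {
    if (!f$met %in% names(network$carbons))
      stop("unknown metabolite in target fragment: ", f$met)
    if (any(f$pos < 1 | f$pos > network$carbons[[f$met]]))
      stop("atom index out of range in fragment ",
           fragment_key(f$met, f$pos))
  }
  nodes <- list()
  queue <- unique(targets)
  while (length(queue)) {
    key <- queue[[1]]; queue <- queue[-1]
    if (!is.null(nodes[[key]])) next
    frag <- parse_fragment(key)
    if (frag$met %in% network$substrates) {
      nodes[[key]] <- list(key = key, met = frag$met, pos = frag$pos,
                           size = length(frag$pos), input = TRUE)
      next
    }
    terms <- list()
    for (tr in network$transitions) {
      for (v in tr$variants) {
        for (inst in v$rhs) {
          if (inst$met != frag$met) next
          letters <- inst$atoms[frag$pos]
          src <- list()
          for (re in v$lhs) {
            hit <- which(re$atoms %in% letters)
            if (length(hit))
              src[[length(src) + 1L]] <- fragment_key(re$met, hit)
          }
          if (!length(src)) next
          terms[[length(terms) + 1L]] <-
            list(rxn = tr$id, prob = v$prob, sources = unlist(src))
          queue <- c(queue, unlist(src))
        }
      }
    }
    if (!length(terms))
      stop("fragment unreachable from any substrate: ", key)
    nodes[[key]] <- list(key = key, met = frag$met, pos = frag$pos,
                         size = length(frag$pos), input = FALSE,
                         terms = terms)
  }
  out <- structure(list(network = network, nodes = nodes,
                        targets = targets),
                   class = "emu_network")
  out$compiled <- compile_emu_network(out)
  out
}

## Precompute integer-indexed structures so simulate_mids() avoids name
## lookups in its inner loops.
compile_emu_network <- function(emunet) {
  network <- emunet$network
  keys <- names(emunet$nodes)
  id_of <- stats::setNames(seq_along(keys), keys)
  rxn_ids <- names(network$transitions)
  mets <- names(network$carbons)
  met_i <- stats::setNames(seq_along(mets), mets)
  ## consumption / production instance counts (mets x reactions)
  cons <- matrix(0, length(mets), length(rxn_ids),
                 dimnames = list(mets, rxn_ids))
  prod <- cons
  for (tr in network$transitions) {
    for (m in tr$lhs_mets) cons[m, tr$id] <- cons[m, tr$id] + 1
    for (m in tr$rhs_mets) prod[m, tr$id] <- prod[m, tr$id] + 1
  }
  sizes <- vapply(emunet$nodes, `[[`, 1L, "size")
  input <- vapply(emunet$nodes, `[[`, TRUE, "input")
  layers <- list()
  for (s in sort(unique(sizes[!input]))) {
    lay_keys <- keys[sizes == s & !input]
    row_of <- stats::setNames(seq_along(lay_keys), lay_keys)
    terms <- list()
    for (k in lay_keys) {
      node <- emunet$nodes[[k]]
      for (term in node$terms) {
        src <- term$sources
        in_layer <- length(src) == 1 && !input[id_of[src]] &&
          sizes[id_of[src]] == s
        terms[[length(terms) + 1L]] <- list(
          row = row_of[[k]],
          rxn = match(term$rxn, rxn_ids),
          prob = term$prob,
          col = if (in_layer) row_of[[src]] else 0L,
          src = unname(id_of[src]))
      }
    }
    layers[[as.character(s)]] <- list(
      size = s, keys = lay_keys,
      met_row = vapply(lay_keys, function(k)
        met_i[[emunet$nodes[[k]]$met]], integer(1)),
      rows = vapply(terms, `[[`, 1L, "row"),
      rxns = vapply(terms, `[[`, 1L, "rxn"),
      probs = vapply(terms, `[[`, 1, "prob"),
      cols = vapply(terms, `[[`, 1L, "col"),
      srcs = lapply(terms, `[[`, "src"))
  }
  list(keys = keys, id_of = id_of, rxn_ids = rxn_ids, mets = mets,
       cons = cons, prod = prod, input_ids = which(input),
       layers = layers)
}

#' @export
print.emu_network <- function(x, ...) {
  sizes <- vapply(x$nodes, `[[`, 1L, "size")
  cat("EMU network: ", length(x$nodes), " EMUs (sizes ",
      paste(sort(unique(sizes)), collapse = ", "), "), ",
      length(x$targets), " targets\n", sep = "")
  invisible(x)
}

#' Define an isotopic tracer
#'
#' A tracer substrate is a mixture: with probability `fraction` the
#' molecule is the labelled species (each position in `positions` is 13C
#' with probability `purity`, independently), otherwise it is unlabelled.
#' Measured MIDs are assumed already corrected for natural abundance, so
#' unlabelled positions are 12C with probability 1.
#'
#' @param substrate substrate metabolite id.
#' @param positions integer positions carrying label, or `"U"` for
#'   uniformly labelled.
#' @param purity isotopic purity of each labelled position, default 0.99.
#' @param fraction molar fraction of the labelled species, default 1.
#' @return object of class `tracer`.
#' @export
tracer <- function(substrate, positions = "U", purity = 0.99,
                   fraction = 1) {
  stopifnot(purity >= 0, purity <= 1, fraction >= 0, fraction <= 1)
  structure(list(substrate = substrate, positions = positions,
                 purity = purity, fraction = fraction), class = "tracer")
}

## MID of a substrate EMU under a tracer list (named by substrate or not).
substrate_emu_mid <- function(tracers, met, pos, carbons) {
  n <- length(pos)
  tr <- NULL
  for (t in tracers) if (t$substrate == met) tr <- t
  if (is.null(tr)) return(c(1, numeric(n)))
  lab_pos <- if (identical(tr$positions, "U")) seq_len(carbons[[met]])
             else as.integer(tr$positions)
  p_lab <- ifelse(pos %in% lab_pos, tr$purity, 0)
  mid_lab <- 1
  for (p in p_lab) mid_lab <- convolve_mid(mid_lab, c(1 - p, p))
  tr$fraction * mid_lab + (1 - tr$fraction) * c(1, numeric(n))
}

convolve_mid <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i + seq_along(b) - 1] <-
      out[i + seq_along(b) - 1] + a[i] * b
  out
}

## Total consumption flux per metabolite; boundary products fall back to
## their production flux (their MID is the flux-weighted producer average).
met_outflux <- function(network, fluxes) {
  mets <- names(network$carbons)
  out <- stats::setNames(numeric(length(mets)), mets)
  prod <- stats::setNames(numeric(length(mets)), mets)
  for (tr in network$transitions) {
    v <- fluxes[[tr$id]]
    if (is.null(v) || is.na(v)) stop("missing flux for reaction ", tr$id)
    for (m in tr$lhs_mets) out[m] <- out[m] + v
    for (m in tr$rhs_mets) prod[m] <- prod[m] + v
  }
  noc <- out == 0 & prod > 0
  out[noc] <- prod[noc]
  out
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Solves the EMU balance system layer by layer (one linear system per EMU
#' size, with convolutions bridging sizes) for the given steady-state flux
#' vector and tracers.
#'
#' @param emunet an `emu_network` from [decompose_emus()].
#' @param fluxes named flux vector over the atom network's reactions
#'   (steady-state on the balanced metabolites).
#' @param tracers list of [tracer()] objects.
#' @param targets fragment keys to return (default: the decomposition's
#'   targets).
#' @return named list of MID vectors (`m+0 ... m+n`), each non-negative and
#'   summing to 1.
#' @export
simulate_mids <- function(emunet, fluxes, tracers,
                          targets = emunet$targets) {
  cp <- emunet$compiled
  v <- as.numeric(fluxes[cp$rxn_ids])
  if (anyNA(v)) stop("missing flux for reaction ",
                     cp$rxn_ids[which(is.na(v))[1]])
  outflux <- as.vector(cp$cons %*% v)
  produced <- as.vector(cp$prod %*% v)
  noc <- outflux == 0 & produced > 0
  outflux[noc] <- produced[noc]
  store <- vector("list", length(cp$keys))
  for (i in cp$input_ids) {
    node <- emunet$nodes[[cp$keys[i]]]
    store[[i]] <- substrate_emu_mid(tracers, node$met, node$pos,
                                    emunet$network$carbons)
  }
  for (lay in cp$layers) {
    n <- length(lay$keys)
    A <- diag(outflux[lay$met_row], n)
    low <- which(outflux[lay$met_row] <= 1e-12)
    if (length(low))
      stop("zero total flow through EMU ", lay$keys[low[1]],
           "; cannot balance its labelling")
    B <- matrix(0, n, lay$size + 1)
    f_all <- v[lay$rxns] * lay$probs
    for (t in seq_along(f_all)) {
      f <- f_all[t]
      if (f == 0) next
      if (lay$cols[t] > 0L) {
        A[lay$rows[t], lay$cols[t]] <- A[lay$rows[t], lay$cols[t]] - f
      } else {
        src <- lay$srcs[[t]]
        mid <- store[[src[1]]]
        if (length(src) > 1)
          for (k in src[-1]) mid <- convolve_mid(mid, store[[k]])
        B[lay$rows[t], ] <- B[lay$rows[t], ] + f * mid
      }
    }
    X <- solve(A, B)
    X[X < 0] <- 0
    X <- X / rowSums(X)
    idx <- cp$id_of[lay$keys]
    for (i in seq_len(n)) store[[idx[i]]] <- X[i, ]
  }
  out <- store[cp$id_of[targets]]
  names(out) <- targets
  out
}

#' Assemble a 13C-MFA model
#'
#' Bundles the atom network, one or more parallel tracer experiments with
#' their measured MIDs, measured net fluxes, flux bounds, and the free-flux
#' parameterisation (a null-space split of the stoichiometric constraints,
#' chosen by QR column pivoting unless given explicitly).
#'
#' @param network an `atom_network`.
#' @param experiments list; each element a list with `tracers` (list of
#'   [tracer()]) and `measurements` (data.frame `fragment`, `mass` (0..n),
#'   `value`, `sd`).
#' @param measured_fluxes optional data.frame `reaction_id`, `value`, `sd`.
#' @param lb,ub named or scalar flux bounds; defaults 0 and 1000
#'   (irreversible network convention).
#' @param free_fluxes optional character vector naming the free fluxes;
#'   default chosen by QR pivoting on the stoichiometric matrix.
#' @return object of class `mfa_model`.
#' @export
mfa_model <- function(network, experiments, measured_fluxes = NULL,
                      lb = 0, ub = 1000, free_fluxes = NULL) {
  rxns <- names(network$transitions)
  n <- length(rxns)
  lbv <- if (length(lb) == 1) stats::setNames(rep(lb, n), rxns) else lb[rxns]
  ubv <- if (length(ub) == 1) stats::setNames(rep(ub, n), rxns) else ub[rxns]
  ## stoichiometry over balanced metabolites
  S <- matrix(0, length(network$balanced), n,
              dimnames = list(network$balanced, rxns))
  for (tr in network$transitions) {
    for (m in tr$lhs_mets)
      if (m %in% network$balanced) S[m, tr$id] <- S[m, tr$id] - 1
    for (m in tr$rhs_mets)
      if (m %in% network$balanced) S[m, tr$id] <- S[m, tr$id] + 1
  }
  qrS <- qr(S, LAPACK = TRUE)
  r <- sum(abs(diag(qr.R(qrS))[seq_len(min(dim(S)))]) > 1e-9)
  if (is.null(free_fluxes)) {
    free <- rxns[qrS$pivot[setdiff(seq_len(n), seq_len(r))]]
  } else {
    free <- free_fluxes
    if (length(free) != n - r)
      stop("free_fluxes must name exactly ", n - r, " reactions")
  }
  basic <- setdiff(rxns, free)
  SB <- S[, basic, drop = FALSE]
  if (qr(SB)$rank < length(basic))
    stop("chosen free fluxes do not determine the remaining fluxes")
  M <- qr.solve(SB, -S[, free, drop = FALSE])  # v_basic = M %*% v_free
  frags <- unique(unlist(lapply(experiments, function(e)
    unique(e$measurements$fragment))))
  emunet <- decompose_emus(network, as.list(frags))
  ## scale for random restarts: generous multiple of the measured fluxes
  ## (or of unity when none are measured)
  start_cap <- 10 * max(1, if (!is.null(measured_fluxes))
    max(abs(measured_fluxes$value)) else 1)
  ## strictly positive interior flux vector (max-min-flux LP): blended into
  ## random starts so every labelled pool keeps flowing
  nv <- length(rxns)
  obj_t <- stats::setNames(c(numeric(nv), 1), c(rxns, ".t"))
  sol <- solve_lp(obj_t,
                  A_eq = cbind(S, 0), b_eq = numeric(nrow(S)),
                  A_le = cbind(-diag(nv), 1), b_le = numeric(nv),
                  lb = c(lbv, 0), ub = c(pmin(ubv, start_cap), start_cap),
                  maximize = TRUE)
  if (sol$status != "optimal")
    stop("flux cone is empty under the given bounds")
  interior <- sol$x[rxns]
  structure(list(network = network, experiments = experiments,
                 measured_fluxes = measured_fluxes,
                 lb = lbv, ub = ubv, free = free, basic = basic,
                 M = M, S = S, emunet = emunet, start_cap = start_cap,
                 interior = interior),
            class = "mfa_model")
}

#' Full flux vector from free-flux values
#' @param mfa an `mfa_model`.
#' @param u named or plain numeric vector of free-flux values.
#' @return named flux vector over all reactions (steady state).
#' @export
mfa_fluxes <- function(mfa, u) {
  u <- stats::setNames(as.numeric(u), mfa$free)
  vb <- as.vector(mfa$M %*% u)
  out <- c(u, stats::setNames(vb, mfa$basic))
  out[names(mfa$lb)]
}

## residuals of data given free fluxes; penalties keep dependent fluxes
## inside their bounds (weight large relative to 1/sd scaling); a flux
## vector the labelling system cannot be solved at (zero flow through a
## needed pool) yields a large flat residual plus the informative penalty
mfa_residuals <- function(mfa, u, penalty = 1e3) {
  v <- mfa_fluxes(mfa, u)
  n_data <- sum(vapply(mfa$experiments, function(e)
    nrow(e$measurements), integer(1))) +
    (if (is.null(mfa$measured_fluxes)) 0L else nrow(mfa$measured_fluxes))
  res <- tryCatch({
    out <- numeric(0)
    for (e in mfa$experiments) {
      sim <- simulate_mids(mfa$emunet, pmax(v, 0), e$tracers)
      ms <- e$measurements
      simval <- vapply(seq_len(nrow(ms)), function(i)
        sim[[ms$fragment[i]]][ms$mass[i] + 1], numeric(1))
      out <- c(out, (simval - ms$value) / ms$sd)
    }
    if (!is.null(mfa$measured_fluxes)) {
      mf <- mfa$measured_fluxes
      out <- c(out, (v[mf$reaction_id] - mf$value) / mf$sd)
    }
    out
  }, error = function(e) rep(1e3, n_data))
  pen <- pmax(mfa$lb - v, 0) + pmax(v - mfa$ub, 0)
  c(res, penalty * pen)
}

mfa_ssr_of <- function(mfa, u) {
  r <- mfa_residuals(mfa, u, penalty = 0)
  sum(r^2)
}

## One local bound-constrained least-squares descent from a feasible start.
## Fluxes are optimised on the log scale (the network convention is
## irreversible, non-negative fluxes spanning orders of magnitude), which
## conditions the Levenberg-Marquardt steps far better than the raw scale.
MFA_LOG_FLOOR <- log(1e-8)
mfa_optimize_from <- function(mfa, u_start, maxiter = 300) {
  th0 <- log(pmax(u_start, 1e-7))
  hi <- log(pmin(mfa$ub[mfa$free], 1e6))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(th0, hi),
                       fn = function(th) mfa_residuals(mfa, exp(th)),
                       lower = rep(MFA_LOG_FLOOR, length(th0)),
                       upper = unname(hi),
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  par <- exp(fit$par)
  names(par) <- mfa$free
  list(par = par, ssr = mfa_ssr_of(mfa, par))
}

#' Variance-weighted sum of squared residuals
#'
#' `sum(((measured - simulated)/sd)^2)` over every measured MID entry and
#' every measured flux.
#'
#' @param measurements data.frame `fragment`, `mass`, `value`, `sd`.
#' @param simulated named list of simulated MID vectors.
#' @param flux_measurements optional data.frame `reaction_id`, `value`,
#'   `sd`.
#' @param fluxes named flux vector (needed with `flux_measurements`).
#' @return numeric SSR.
#' @export
ssr <- function(measurements, simulated, flux_measurements = NULL,
                fluxes = NULL) {
  if (any(measurements$sd <= 0)) stop("measurement sds must be positive")
  bad <- setdiff(unique(measurements$fragment), names(simulated))
  if (length(bad)) stop("no simulated MID for fragment: ", bad[1])
  simval <- vapply(seq_len(nrow(measurements)), function(i)
    simulated[[measurements$fragment[i]]][measurements$mass[i] + 1],
    numeric(1))
  total <- sum(((simval - measurements$value) / measurements$sd)^2)
  if (!is.null(flux_measurements)) {
    if (is.null(fluxes)) stop("fluxes needed for flux measurements")
    total <- total +
      sum(((fluxes[flux_measurements$reaction_id] -
              flux_measurements$value) / flux_measurements$sd)^2)
  }
  total
}

## independent measurement count: a normalised MID of size n carries n
## independent values; plus one per measured flux
mfa_n_measurements <- function(mfa) {
  n <- 0
  for (e in mfa$experiments) {
    for (fr in unique(e$measurements$fragment))
      n <- n + length(parse_fragment(fr)$pos)
  }
  n + if (is.null(mfa$measured_fluxes)) 0 else nrow(mfa$measured_fluxes)
}

## draw a random feasible free-flux start: average a few vertices of the
## flux cone obtained by optimising random objectives (the average of
## feasible points is feasible and generically keeps every pool flowing)
mfa_feasible_start <- function(mfa, n_vertices = 3) {
  rxns <- names(mfa$lb)
  ub_cap <- pmin(mfa$ub, mfa$start_cap)
  vs <- list()
  for (k in seq_len(n_vertices)) {
    obj <- stats::rnorm(length(rxns))
    sol <- solve_lp(stats::setNames(obj, rxns), A_eq = mfa$S,
                    b_eq = numeric(nrow(mfa$S)), lb = mfa$lb, ub = ub_cap,
                    maximize = TRUE)
    if (sol$status == "optimal") vs[[length(vs) + 1L]] <- sol$x
  }
  if (!length(vs))
    stop("could not draw a feasible start (flux cone empty?)")
  v <- Reduce(`+`, vs) / length(vs)
  w <- stats::runif(1, 0.1, 0.7)   # blend towards the interior point
  v <- w * mfa$interior + (1 - w) * v
  v[mfa$free]
}

#' Fit fluxes to labelling data by multistart least squares
#'
#' Bound-constrained Levenberg-Marquardt least squares
#' (`minpack.lm::nls.lm`) from `n_restarts` random feasible starts; the
#' best sum of squared residuals is retained. The fit is deterministic
#' given `seed`. Goodness of fit is assessed by a chi-square test at
#' `alpha`: the minimised SSR is compared with the upper `1 - alpha`
#' quantile at `df = independent measurements - free fluxes`.
#'
#' @param mfa an `mfa_model`.
#' @param n_restarts number of random restarts, default 100.
#' @param seed integer seed controlling the restarts.
#' @param alpha chi-square test level, default 0.05.
#' @return object of class `mfa_fit`: point fluxes, free-flux values, SSR,
#'   `df`, `chisq_pass`, per-restart SSRs, and the seed/start index of the
#'   best restart.
#' @export
fit_fluxes <- function(mfa, n_restarts = 100, seed = 1, alpha = 0.05) {
  stopifnot(n_restarts >= 1)
  nf <- length(mfa$free)
  ## identifiability: numeric Jacobian rank at a random feasible point
  old <- .Random.seed_safe()
  set.seed(seed)
  ## identifiability: the residual Jacobian must have full column rank at
  ## a generic feasible point (isolated degenerate points are tolerated)
  rank_max <- 0
  for (k in 1:3) {
    u0 <- mfa_feasible_start(mfa)
    J <- finite_diff_jacobian(function(u)
      mfa_residuals(mfa, u, penalty = 0), u0)
    rank_max <- max(rank_max, qr(J)$rank)
    if (rank_max == nf) break
  }
  if (rank_max < nf)
    stop("free-flux parameterisation not identifiable: residual Jacobian ",
         "rank ", rank_max, " < ", nf, " free fluxes")
  starts <- lapply(seq_len(n_restarts), function(i) mfa_feasible_start(mfa))
  .Random.seed_restore(old)
  fits <- vector("list", n_restarts)
  ssrs <- rep(NA_real_, n_restarts)
  for (i in seq_len(n_restarts)) {
    fit <- mfa_optimize_from(mfa, starts[[i]])
    if (is.null(fit)) next
    fits[[i]] <- fit$par
    ssrs[i] <- fit$ssr
  }
  if (all(is.na(ssrs)))
    stop("no restart converged (", n_restarts, " attempted)")
  best <- which.min(ssrs)
  u_best <- stats::setNames(as.numeric(fits[[best]]), mfa$free)
  df <- mfa_n_measurements(mfa) - nf
  s <- ssrs[best]
  ## two-sided acceptance band: an SSR far below df signals overfitted or
  ## overstated uncertainties, far above df a lack of fit
  lo_crit <- stats::qchisq(alpha / 2, df)
  hi_crit <- stats::qchisq(1 - alpha / 2, df)
  structure(list(
    mfa = mfa,
    free_values = u_best,
    fluxes = mfa_fluxes(mfa, u_best),
    ssr = s, df = df, alpha = alpha,
    chisq_lo = lo_crit, chisq_hi = hi_crit,
    chisq_pass = s >= lo_crit && s <= hi_crit,
    restart_ssr = ssrs, n_restarts = n_restarts,
    best_restart = best, seed = seed, ci = NULL),
    class = "mfa_fit")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

finite_diff_jacobian <- function(f, x) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- 1e-6 * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat("13C-MFA fit: ", length(x$fluxes), " fluxes (",
      length(x$free_values), " free), ", x$n_restarts, " restarts\n",
      sep = "")
  cat(sprintf(
    "  SSR = %.4g on df = %d (chi-square band [%.4g, %.4g]): %s\n",
    x$ssr, x$df, x$chisq_lo, x$chisq_hi,
    if (x$chisq_pass) "accepted" else "rejected"))
  if (!is.null(x$ci))
    cat("  95% confidence intervals available (", attr(x$ci, "n_samples"),
        " Monte-Carlo samples)\n", sep = "")
  invisible(x)
}

#' @export
coef.mfa_fit <- function(object, ...) object$fluxes

#' @export
summary.mfa_fit <- function(object, ...) {
  out <- data.frame(reaction_id = names(object$fluxes),
                    flux = unname(object$fluxes),
                    stringsAsFactors = FALSE)
  if (!is.null(object$ci)) {
    out$lo <- object$ci$lo[match(out$reaction_id, object$ci$reaction_id)]
    out$hi <- object$ci$hi[match(out$reaction_id, object$ci$reaction_id)]
  }
  out
}

#' Monte-Carlo confidence intervals for fitted fluxes
#'
#' Resamples synthetic datasets around the fitted model (simulated MIDs and
#' fitted fluxes perturbed with the measurement standard deviations), refits
#' each, and takes per-flux 2.5/97.5 percentiles over the refits (the point
#' estimate itself is included in the sample, so intervals always contain
#' it).
#'
#' @param mfa the `mfa_model` that produced `best`.
#' @param best a converged `mfa_fit`.
#' @param n_samples Monte-Carlo datasets, default 100.
#' @param seed integer seed.
#' @param restarts_per_sample multistarts per refit (refits also start from
#'   the point estimate), default 3.
#' @param max_failures maximum tolerated fraction of failed refits.
#' @return `best` with `ci` filled: data.frame `reaction_id`, `lo`, `hi`.
#' @export
monte_carlo_ci <- function(mfa, best, n_samples = 100, seed = 1,
                           restarts_per_sample = 3, max_failures = 0.2) {
  sim_best <- lapply(mfa$experiments, function(e)
    simulate_mids(mfa$emunet, best$fluxes, e$tracers))
  old <- .Random.seed_safe()
  set.seed(seed)
  samples <- list(best$fluxes)  # point estimate included
  failures <- 0
  for (k in seq_len(n_samples)) {
    mfa_k <- mfa
    for (ei in seq_along(mfa$experiments)) {
      ms <- mfa$experiments[[ei]]$measurements
      mu <- vapply(seq_len(nrow(ms)), function(i)
        sim_best[[ei]][[ms$fragment[i]]][ms$mass[i] + 1], numeric(1))
      newv <- stats::rnorm(nrow(ms), mu, ms$sd)
      ## renormalise per fragment, clip at zero (the measurement model)
      for (fr in unique(ms$fragment)) {
        ii <- ms$fragment == fr
        x <- pmax(newv[ii], 0)
        newv[ii] <- x / sum(x)
      }
      ms$value <- newv
      mfa_k$experiments[[ei]]$measurements <- ms
    }
    if (!is.null(mfa$measured_fluxes)) {
      mf <- mfa$measured_fluxes
      mf$value <- stats::rnorm(nrow(mf), best$fluxes[mf$reaction_id],
                               mf$sd)
      mfa_k$measured_fluxes <- mf
    }
    starts <- c(list(best$free_values),
                lapply(seq_len(restarts_per_sample - 1), function(i)
                  mfa_feasible_start(mfa_k)))
    best_u <- NULL; best_s <- Inf
    for (st in starts) {
      fit <- mfa_optimize_from(mfa_k, st, maxiter = 150)
      if (is.null(fit)) next
      if (fit$ssr < best_s) { best_s <- fit$ssr; best_u <- fit$par }
    }
    if (is.null(best_u)) failures <- failures + 1
    else samples[[length(samples) + 1L]] <- mfa_fluxes(mfa_k, best_u)
  }
  .Random.seed_restore(old)
  if (failures > max_failures * n_samples)
    stop(failures, " of ", n_samples, " Monte-Carlo refits failed")
  V <- do.call(rbind, samples)
  ci <- data.frame(
    reaction_id = colnames(V),
    lo = apply(V, 2, stats::quantile, 0.025, names = FALSE),
    hi = apply(V, 2, stats::quantile, 0.975, names = FALSE),
    stringsAsFactors = FALSE)
  attr(ci, "n_samples") <- length(samples)
  best$ci <- ci
  best
}

#' Export confidence intervals as flux bounds for a constraint-based model
#'
#' Maps fitted-flux confidence intervals onto constraint-based reaction ids
#' so they can be applied with [apply_flux_intervals()]. A negative `sign`
#' converts an MFA uptake flux (positive by convention) into the
#' constraint-based exchange convention (uptake = negative flux), mapping
#' `(lo, hi)` to `(-hi, -lo)`.
#'
#' @param est an `mfa_fit` with confidence intervals.
#' @param id_map data.frame `mfa_id`, `cbm_id`, optional `sign` (+1/-1), or
#'   a named character vector (mfa id -> cbm id, all signs +1).
#' @param path optional CSV output path (columns `reaction_id`, `lo`,
#'   `hi`).
#' @return data.frame `reaction_id`, `lo`, `hi`; unmapped MFA fluxes are in
#'   attribute `"unmapped"` (the sidecar report).
#' @export
export_intervals <- function(est, id_map, path = NULL) {
  if (is.null(est$ci)) stop("fit has no confidence intervals; run ",
                            "monte_carlo_ci() first")
  if (!is.data.frame(id_map))
    id_map <- data.frame(mfa_id = names(id_map) %||% character(0),
                         cbm_id = unname(id_map),
                         stringsAsFactors = FALSE)
  if (is.null(id_map$sign)) id_map$sign <- rep(1, nrow(id_map))
  if (anyDuplicated(id_map$cbm_id))
    stop("duplicate constraint-based target: ",
         id_map$cbm_id[duplicated(id_map$cbm_id)][1])
  bad <- setdiff(id_map$mfa_id, est$ci$reaction_id)
  if (length(bad)) stop("id map references unknown MFA flux: ", bad[1])
  i <- match(id_map$mfa_id, est$ci$reaction_id)
  lo <- est$ci$lo[i]; hi <- est$ci$hi[i]
  neg <- id_map$sign < 0
  out <- data.frame(reaction_id = id_map$cbm_id,
                    lo = ifelse(neg, -hi, lo),
                    hi = ifelse(neg, -lo, hi),
                    stringsAsFactors = FALSE)
  attr(out, "unmapped") <- setdiff(est$ci$reaction_id, id_map$mfa_id)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
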