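# Independent oracles used across the suite. Each one deliberately avoids
# the package's own computational path for the quantity it checks.

# Brute-force LP oracle: enumerate candidate vertices of
# {S v = 0, lb <= v <= ub} by pinning every size-k subset of variables at a
# bound (k = n - rank(S)) and solving for the rest; return the best
# objective among feasible candidates.
lp_vertex_oracle <- function(S, lb, ub, obj, maximize = TRUE, tol = 1e-8) {
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- NULL
  check_candidate <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (nrow(S) > 0 && max(abs(S %*% v)) > tol) return()
    val <- sum(obj * v)
    if (is.null(best) || (maximize && val > best) ||
        (!maximize && val < best)) best <<- val
  }
  if (k == 0) {
    v <- rep(0, n)
    check_candidate(v)
  } else {
    subsets <- utils::combn(n, k, simplify = FALSE)
    for (F in subsets) {
      B <- setdiff(seq_len(n), F)
      SB <- S[, B, drop = FALSE]
      if (qr(SB)$rank < length(B)) next
      grid <- expand.grid(rep(list(c(1, 2)), k))
      for (g in seq_len(nrow(grid))) {
        vF <- ifelse(unlist(grid[g, ]) == 1, lb[F], ub[F])
        if (any(!is.finite(vF))) next
        rhs <- -S[, F, drop = FALSE] %*% vF
        vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
        if (is.null(vB)) next
        if (max(abs(SB %*% vB - rhs)) > tol) next
        v <- numeric(n)
        v[F] <- vF
        v[B] <- vB
        check_candidate(v)
      }
    }
  }
  best
}

# Corner-enumeration oracle for a reaction Gibbs-energy range: evaluate
# dG at every corner of the concentration box.
dg_corner_oracle <- function(model, thermo, reaction_id) {
  s <- model$stoich[[reaction_id]]
  rt <- 8.314e-3 * thermo$temperature
  mets <- names(s)
  active <- setdiff(mets, thermo$exempt)
  dg0 <- sum(vapply(mets, function(m)
    s[[m]] * thermo$dgf[[m]], numeric(1)))
  if (!length(active)) return(c(dg0, dg0))
  grid <- expand.grid(rep(list(c(1, 2)), length(active)))
  vals <- apply(grid, 1, function(g) {
    conc <- ifelse(g == 1, thermo$conc_min[active], thermo$conc_max[active])
    dg0 + rt * sum(vapply(seq_along(active), function(i)
      s[[active[i]]] * log(conc[i]), numeric(1)))
  })
  range(vals)
}

# Brute-force recursive GPR evaluator over an expression string (no reuse
# of the package parser: its own tiny recursive-descent evaluation).
gpr_brute_eval <- function(text, scores) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  parse_or <- function() {
    v <- parse_and()
    while (pos <= length(toks) && tolower(toks[pos]) == "or") {
      pos <<- pos + 1L
      v <- max(v, parse_and())
    }
    v
  }
  parse_and <- function() {
    v <- parse_atom()
    while (pos <= length(toks) && tolower(toks[pos]) == "and") {
      pos <<- pos + 1L
      v <- min(v, parse_atom())
    }
    v
  }
  parse_atom <- function() {
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      v <- parse_or()
      pos <<- pos + 1L  # closing paren
      return(v)
    }
    pos <<- pos + 1L
    if (tk %in% names(scores)) unname(scores[[tk]]) else 0
  }
  parse_or()
}

# Full isotopomer fixed-point oracle: iterates the per-metabolite 2^k
# isotopomer balance equations to convergence, entirely independent of the
# EMU decomposition/layered linear solves.
iso_fixed_point_oracle <- function(net, fluxes, tracers, tol = 1e-14,
                                   max_iter = 5000) {
  mets <- names(net$carbons)
  dist <- list()
  for (m in mets) {
    d <- numeric(2^net$carbons[[m]]); d[1] <- 1
    dist[[m]] <- d
  }
  for (m in net$substrates) {
    k <- net$carbons[[m]]
    tr <- NULL
    for (t in tracers) if (t$substrate == m) tr <- t
    d <- numeric(2^k)
    if (is.null(tr)) d[1] <- 1 else {
      labpos <- if (identical(tr$positions, "U")) seq_len(k) else
        tr$positions
      for (s in 0:(2^k - 1)) {
        bits <- as.integer(intToBits(s))[seq_len(k)]
        p <- 1
        for (j in seq_len(k)) {
          pl <- if (j %in% labpos) tr$purity else 0
          p <- p * if (bits[j] == 1) pl else (1 - pl)
        }
        d[s + 1] <- tr$fraction * p +
          (1 - tr$fraction) * (s == 0)
      }
    }
    dist[[m]] <- d
  }
  outflux <- stats::setNames(numeric(length(mets)), mets)
  produced <- outflux
  for (trn in net$transitions) {
    v <- fluxes[[trn$id]]
    for (m in trn$lhs_mets) outflux[m] <- outflux[m] + v
    for (m in trn$rhs_mets) produced[m] <- produced[m] + v
  }
  noc <- outflux == 0 & produced > 0
  outflux[noc] <- produced[noc]
  unknown <- setdiff(mets, net$substrates)
  for (iter in seq_len(max_iter)) {
    maxd <- 0
    nxt <- dist
    for (m in unknown) {
      k <- net$carbons[[m]]
      acc <- numeric(2^k)
      for (trn in net$transitions) for (v in trn$variants) {
        f <- fluxes[[trn$id]] * v$prob
        if (f == 0) next
        for (inst in v$rhs) {
          if (inst$met != m) next
          probs <- rep(1, 2^k)
          for (re in v$lhs) {
            mpos <- match(inst$atoms, re$atoms)
            rel <- which(!is.na(mpos))
            if (!length(rel)) next
            kr <- net$carbons[[re$met]]
            dr <- dist[[re$met]]
            pm <- numeric(2^length(rel))
            for (s in 0:(2^kr - 1)) {
              bits <- as.integer(intToBits(s))[seq_len(kr)]
              idx <- sum(bits[mpos[rel]] * 2^(seq_along(rel) - 1))
              pm[idx + 1] <- pm[idx + 1] + dr[s + 1]
            }
            for (s in 0:(2^k - 1)) {
              bits <- as.integer(intToBits(s))[seq_len(k)]
              idx <- sum(bits[rel] * 2^(seq_along(rel) - 1))
              probs[s + 1] <- probs[s + 1] * pm[idx + 1]
            }
          }
          acc <- acc + f * probs
        }
      }
      nd <- acc / outflux[[m]]
      maxd <- max(maxd, max(abs(nd - dist[[m]])))
      nxt[[m]] <- nd
    }
    dist <- nxt
    if (maxd < tol) break
  }
  dist
}

# MID of an atom subset from a full isotopomer distribution.
mid_from_isotopomers <- function(d, pos, k) {
  out <- numeric(length(pos) + 1)
  for (s in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(k)]
    w <- sum(bits[pos])
    out[w + 1] <- out[w + 1] + d[s + 1]
  }
  out
}
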