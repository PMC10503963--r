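# Fixture builders, all constructed in code.

# Linear chain: EX_a (uptake <= cap) -> a -> b -> EX_b.
chain_model <- function(cap = 10) {
  metabolic_model(
    data.frame(id = c("a[e]", "b[e]", "a[c]", "b[c]")),
    data.frame(id = c("EX_a", "At", "conv", "Bt", "EX_b"),
               lb = c(-cap, 0, 0, 0, 0), ub = c(1000, 1000, 1000, 1000,
                                                1000)),
    list(EX_a = c("a[e]" = -1), At = c("a[e]" = -1, "a[c]" = 1),
         conv = c("a[c]" = -1, "b[c]" = 1),
         Bt = c("b[c]" = -1, "b[e]" = 1), EX_b = c("b[e]" = -1)),
    objective = "EX_b", id = "chain")
}

# Two parallel routes a -> b with different capacities (alternate optima).
diamond_model <- function() {
  metabolic_model(
    data.frame(id = c("a[e]", "b[e]", "a[c]", "m1[c]", "m2[c]", "b[c]")),
    data.frame(id = c("EX_a", "At", "r1a", "r1b", "r2a", "r2b", "Bt",
                      "EX_b"),
               lb = c(-8, 0, 0, 0, 0, 0, 0, 0),
               ub = c(1000, 1000, 5, 5, 6, 6, 1000, 1000)),
    list(EX_a = c("a[e]" = -1), At = c("a[e]" = -1, "a[c]" = 1),
         r1a = c("a[c]" = -1, "m1[c]" = 1),
         r1b = c("m1[c]" = -1, "b[c]" = 1),
         r2a = c("a[c]" = -1, "m2[c]" = 1),
         r2b = c("m2[c]" = -1, "b[c]" = 1),
         Bt = c("b[c]" = -1, "b[e]" = 1), EX_b = c("b[e]" = -1)),
    objective = "EX_b", id = "diamond")
}

# Internal 3-cycle plus a throughput path; the cycle can circulate without
# touching any exchange.
cycle_model <- function(cycle_open = TRUE) {
  ub_cyc <- if (cycle_open) 1000 else 0
  metabolic_model(
    data.frame(id = c("a[e]", "a[c]", "b[c]", "c[c]")),
    data.frame(id = c("EX_a", "At", "r_ab", "r_bc", "r_ca", "SINK_a"),
               lb = c(-10, 0, 0, 0, 0, 0),
               ub = c(1000, 1000, ub_cyc, ub_cyc, ub_cyc, 1000)),
    list(EX_a = c("a[e]" = -1), At = c("a[e]" = -1, "a[c]" = 1),
         r_ab = c("a[c]" = -1, "b[c]" = 1),
         r_bc = c("b[c]" = -1, "c[c]" = 1),
         r_ca = c("c[c]" = -1, "a[c]" = 1),
         SINK_a = c("a[c]" = -1)),
    objective = "SINK_a", id = "cycle")
}

# Random small network for the brute-force LP oracle: integer stoichiometry
# over a handful of internal metabolites, finite bounds containing zero.
random_small_lp <- function(seed) {
  set.seed(seed)
  repeat {
    n <- sample(4:8, 1)
    m <- sample(2:4, 1)
    S <- matrix(sample(-2:2, m * n, replace = TRUE,
                       prob = c(.1, .2, .4, .2, .1)), m, n)
    if (any(colSums(abs(S)) == 0)) next
    lb <- -sample(0:6, n, replace = TRUE)
    ub <- sample(1:8, n, replace = TRUE)
    obj <- rnorm(n)
    return(list(S = S, lb = lb, ub = ub, obj = obj))
  }
}

# Random layered flux network as a metabolic_model with a guaranteed
# positive optimum: source exchange -> chain of conversions (with random
# branches) -> sink exchange (the objective).
random_flux_model <- function(seed, id = paste0("rnd", seed)) {
  set.seed(seed)
  k <- sample(3:5, 1)             # internal chain length
  ids_c <- paste0("x", seq_len(k), "[c]")
  mets <- data.frame(id = c("s[e]", "p[e]", ids_c))
  rxns <- list(); stoich <- list()
  add <- function(rid, s, lb, ub) {
    rxns[[rid]] <<- data.frame(id = rid, lb = lb, ub = ub)
    stoich[[rid]] <<- s
  }
  cap <- round(runif(1, 4, 12), 2)
  add("EX_s", c("s[e]" = -1), -cap, 1000)
  add("Up", c("s[e]" = -1, "x1[c]" = 1), 0, 1000)
  for (i in seq_len(k - 1))
    add(paste0("r", i), stats::setNames(c(-1, 1), c(ids_c[i],
                                                    ids_c[i + 1])),
        if (runif(1) < 0.3) -round(runif(1, 1, 5), 2) else 0,
        round(runif(1, 3, 15), 2))
  ## random extra branch between two levels
  if (k >= 4 && runif(1) < 0.7) {
    ij <- sort(sample(seq_len(k), 2))
    add("branch", stats::setNames(c(-1, 1), ids_c[ij]),
        0, round(runif(1, 1, 6), 2))
  }
  add("Down", stats::setNames(c(-1, 1), c(ids_c[k], "p[e]")), 0, 1000)
  add("EX_p", c("p[e]" = -1), 0, 1000)
  ## objective is the internal delivery step (merging requires a
  ## per-cell, non-exchange objective)
  metabolic_model(mets, do.call(rbind, rxns), stoich,
                  objective = "Down", id = id)
}

# Paired toy cells and their merge, shared across co-culture tests.
toy_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- make_toy_cell_model(toy_spec(), "stromal_like")
      my <- make_toy_cell_model(toy_spec(), "myeloma_like")
      cache <<- list(stromal = st, myeloma = my,
                     cc = merge_models(st$model, my$model, "bm", "cm"))
    }
    cache
  }
})

# The toy atom network, its truth, and cached zero-noise / noisy datasets.
toy_mfa_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- make_atom_mapped_toynet()$network
      truth0 <- toy_mfa_truth(noise_sd = 0)
      exps0 <- simulate_labelling_experiment(truth0, net, seed = 101)
      mfa0 <- mfa_model(net, exps0,
                        measured_fluxes = attr(exps0, "measured_fluxes"))
      truthN <- toy_mfa_truth(noise_sd = 0.005)
      expsN <- simulate_labelling_experiment(truthN, net, seed = 202)
      mfaN <- mfa_model(net, expsN,
                        measured_fluxes = attr(expsN, "measured_fluxes"))
      cache <<- list(net = net, truth0 = truth0, mfa0 = mfa0,
                     truthN = truthN, mfaN = mfaN)
    }
    cache
  }
})
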