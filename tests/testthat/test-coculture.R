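test_that("merging keeps the bookkeeping formulas and shared exchanges", {
  tp <- toy_pair()
  a <- tp$stromal$model; b <- tp$myeloma$model
  cc <- tp$cc
  n_int_a <- sum(a$metabolites$compartment != "e")
  n_int_b <- sum(b$metabolites$compartment != "e")
  ext_union <- union(a$metabolites$id[a$metabolites$compartment == "e"],
                     b$metabolites$id[b$metabolites$compartment == "e"])
  expect_identical(nrow(cc$model$metabolites),
                   n_int_a + n_int_b + length(ext_union))
  ex_a <- list_exchanges(a); ex_b <- list_exchanges(b)
  expect_identical(nrow(cc$model$reactions),
                   (nrow(a$reactions) - length(ex_a)) +
                     (nrow(b$reactions) - length(ex_b)) +
                     length(union(ex_a, ex_b)))
  ## self-merge: reaction count = 2*internal + exchanges (not 2*exchanges)
  self <- merge_models(a, a, "x", "y")
  expect_identical(nrow(self$model$reactions),
                   2L * (nrow(a$reactions) - length(ex_a)) +
                     length(ex_a))
  ## compartment notation: met[bm], met[cm], shared met[e]
  comp <- unique(cc$model$metabolites$compartment)
  expect_true(all(c("bm", "cm", "e") %in% comp))
  expect_true("pyr[bm]" %in% cc$model$metabolites$id)
  expect_true("pyr[cm]" %in% cc$model$metabolites$id)
  expect_true("pyr[e]" %in% cc$model$metabolites$id)
  ## both biomass reactions registered
  expect_identical(unname(cc$biomass_ids),
                   c("BIOMASS_bm", "BIOMASS_cm"))
  expect_true(all(cc$biomass_ids %in% cc$model$reactions$id))
})

test_that("the merged stoichiometric matrix is block-structured", {
  tp <- toy_pair()
  cc <- tp$cc
  S <- stoichiometric_matrix(cc$model)
  bm_rows <- grepl("\\[bm", rownames(S))
  cm_cols <- names(cc$cell_of_reaction)[cc$cell_of_reaction == "cm"]
  expect_true(all(S[bm_rows, cm_cols] == 0))
  cm_rows <- grepl("\\[cm", rownames(S))
  bm_cols <- names(cc$cell_of_reaction)[cc$cell_of_reaction == "bm"]
  expect_true(all(S[cm_rows, bm_cols] == 0))
})

test_that("merge bookkeeping holds across random model pairs", {
  for (seed in 1:15) {
    a <- random_flux_model(2 * seed, id = "A")
    b <- random_flux_model(2 * seed + 1, id = "B")
    cc <- merge_models(a, b, "p", "q")
    n_int <- function(m) sum(m$metabolites$compartment != "e")
    ext <- function(m) m$metabolites$id[m$metabolites$compartment == "e"]
    expect_identical(nrow(cc$model$metabolites),
                     n_int(a) + n_int(b) +
                       length(union(ext(a), ext(b))))
    ex_a <- list_exchanges(a); ex_b <- list_exchanges(b)
    expect_identical(nrow(cc$model$reactions),
                     nrow(a$reactions) - length(ex_a) +
                       nrow(b$reactions) - length(ex_b) +
                       length(union(ex_a, ex_b)))
    validate_model(cc$model)
  }
})

test_that("merge rejects bad tags and mismatched shared exchanges", {
  tp <- toy_pair()
  a <- tp$stromal$model
  expect_error(merge_models(a, a, "x", "x"), "differ")
  expect_error(merge_models(a, a, "e", "y"), "'e'")
  expect_error(merge_models(a, a, "c", "y"), "collides")
  b <- a
  b$stoich[["EX_glc"]] <- c("glc[e]" = -2)
  expect_error(merge_models(a, b, "x", "y"), "EX_glc")
})

test_that("cross-fed metabolites traverse only the shared extracellular space", {
  tp <- toy_pair()
  cc <- tp$cc
  ## force a stroma -> myeloma pyruvate shuttle and inspect the carriers
  r <- fba_optimize(cc$model, "PYRt_cm", "min")
  expect_identical(r$status, "optimal")
  expect_lt(r$objective_value, -1)       # myeloma takes up pyruvate
  v <- coef(r)
  expect_gt(v[["PYRt_bm"]], 1)           # stroma secretes it
  ## no reaction touches both cells' private compartments
  for (rid in cc$model$reactions$id) {
    comps <- unique(cc$model$metabolites$compartment[
      match(names(cc$model$stoich[[rid]]), cc$model$metabolites$id)])
    private <- setdiff(comps, "e")
    cells <- unique(sub("\\..*$", "", private))
    expect_lte(length(cells), 1)
  }
})

test_that("pareto front matches the closed-form resource-partition line", {
  ## two cells sharing one substrate with linear yields: the front is the
  ## segment biomass_a/(U*y_a) + biomass_b/(U*y_b) = 1
  mk_cell <- function(k) metabolic_model(
    data.frame(id = c("s[e]", "s[c]")),
    data.frame(id = c("EX_s", "Up", "GROW"),
               lb = c(-6, 0, 0), ub = c(1000, 1000, 1000)),
    list(EX_s = c("s[e]" = -1), Up = c("s[e]" = -1, "s[c]" = 1),
         GROW = c("s[c]" = -k)),
    objective = "GROW", id = paste0("cell", k))
  ## both cells consume one substrate unit per biomass unit; shared
  ## uptake U = 6, so the front is the line biomass_a + biomass_b = U
  cc <- merge_models(mk_cell(1), mk_cell(1), "a", "b")
  front <- pareto_front(cc, n_points = 11)
  U <- 6
  expect_equal(max(front$biomass_a), U, tolerance = 1e-6)
  expect_equal(max(front$biomass_b), U, tolerance = 1e-6)
  expect_true(all(abs(front$biomass_a + front$biomass_b - U) < 1e-6))
  expect_identical(nrow(front), 11L)
  ## pairwise non-domination
  for (i in seq_len(nrow(front)))
    for (j in seq_len(nrow(front)))
      if (i != j)
        expect_false(front$biomass_a[j] >= front$biomass_a[i] + 1e-9 &&
                       front$biomass_b[j] >= front$biomass_b[i] + 1e-9)
})

test_that("pareto endpoints equal single-objective optima; disjoint substrates degenerate", {
  tp <- toy_pair()
  cc <- tp$cc
  front <- pareto_front(cc, n_points = 11)
  max_a <- fba_optimize(cc$model, cc$biomass_ids[[1]])$objective_value
  max_b <- fba_optimize(cc$model, cc$biomass_ids[[2]])$objective_value
  expect_equal(max(front$biomass_a), max_a, tolerance = 1e-6)
  expect_equal(max(front$biomass_b), max_b, tolerance = 1e-6)
  ## private substrates -> single point (max_a, max_b)
  mk_cell <- function(nm) metabolic_model(
    data.frame(id = c(paste0(nm, "[e]"), "s[c]")),
    data.frame(id = c(paste0("EX_", nm), "Up", "GROW"),
               lb = c(-4, 0, 0), ub = c(1000, 1000, 1000)),
    stats::setNames(list(stats::setNames(-1, paste0(nm, "[e]")),
                         stats::setNames(c(-1, 1),
                                         c(paste0(nm, "[e]"), "s[c]")),
                         c("s[c]" = -1)),
                    c(paste0("EX_", nm), "Up", "GROW")),
    objective = "GROW", id = nm)
  cc2 <- merge_models(mk_cell("s1"), mk_cell("s2"), "a", "b")
  front2 <- pareto_front(cc2, n_points = 11)
  expect_identical(nrow(front2), 1L)
  expect_equal(front2$biomass_a, 4, tolerance = 1e-6)
  expect_equal(front2$biomass_b, 4, tolerance = 1e-6)
})

test_that("flux-interval tuning pins, intersects, reports and errors", {
  m <- chain_model()
  ## pinning to zero forces zero flux everywhere downstream
  t0 <- apply_flux_intervals(m, data.frame(reaction_id = "conv",
                                           lo = 0, hi = 0))
  expect_equal(fba_optimize(t0)$objective_value, 0, tolerance = 1e-9)
  ## uptake magnitude bound in the exchange convention
  t1 <- apply_flux_intervals(m, data.frame(reaction_id = "EX_a",
                                           lo = -0.45, hi = 0))
  r <- fba_optimize(t1)
  expect_lte(abs(r$fluxes[["EX_a"]]), 0.45 + 1e-9)
  expect_equal(r$objective_value, 0.45, tolerance = 1e-6)
  ## unmatched ids are reported, not fatal
  t2 <- apply_flux_intervals(m, data.frame(
    reaction_id = c("conv", "ghost"), lo = c(0, 0), hi = c(5, 1)))
  expect_identical(attr(t2, "unmatched"), "ghost")
  ## empty intersection errors naming the reaction
  expect_error(apply_flux_intervals(m, data.frame(reaction_id = "Bt",
                                                  lo = -9, hi = -5)),
               "Bt")
  ## infeasibility carries a relaxation hint
  m2 <- diamond_model()
  expect_error(apply_flux_intervals(m2, data.frame(
    reaction_id = c("r1a", "r2a", "EX_a"),
    lo = c(5, 5, -3), hi = c(5, 6, 0))), "restores feasibility")
  ## tuning never enlarges the flux polytope (compared without the
  ## relative-to-optimum constraint, which itself shifts under tuning)
  tp <- toy_pair()
  mt <- tp$stromal$model
  before <- fva(mt, c("GLYC", "LDH", "GLS", "CIV"),
                objective_fraction = 0)
  tuned <- apply_flux_intervals(mt, data.frame(reaction_id = "GLYC",
                                               lo = 1, hi = 5))
  after <- fva(tuned, c("GLYC", "LDH", "GLS", "CIV"),
               objective_fraction = 0)
  expect_true(all(after$minimum >= before$minimum - 1e-6))
  expect_true(all(after$maximum <= before$maximum + 1e-6))
})

test_that("biomass flux converts to growth rate by the dry-weight factor", {
  expect_identical(growth_rate_from_biomass_flux(0.0306, 1), 0.0306)
  expect_identical(growth_rate_from_biomass_flux(0), 0)
  expect_identical(growth_rate_from_biomass_flux(0.05, 0.5), 0.025)
  expect_error(growth_rate_from_biomass_flux(-1), "non-negative")
})
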