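test_that("model validation names the offending id", {
  mets <- data.frame(id = c("a[e]", "b[c]"))
  ok <- list(EX_a = c("a[e]" = -1), r = c("a[e]" = -1, "b[c]" = 1))
  rxns <- data.frame(id = c("EX_a", "r"), lb = c(-5, 0), ub = c(5, 5))
  expect_silent(metabolic_model(mets, rxns, ok, objective = "r"))
  expect_error(metabolic_model(mets, rxns,
                               list(EX_a = c("a[e]" = -1),
                                    r = c("ghost[c]" = 1)),
                               objective = "r"),
               "ghost")
  expect_error(metabolic_model(mets, rxns,
                               list(EX_a = c("a[e]" = -1),
                                    r = c("a[e]" = 0, "b[c]" = 1)),
                               objective = "r"),
               "zero coefficient")
  bad_bounds <- rxns; bad_bounds$lb[2] <- 9
  expect_error(metabolic_model(mets, bad_bounds, ok, objective = "r"),
               "r")
  expect_error(metabolic_model(mets, rxns, ok, objective = "nope"),
               "nope")
  bad_comp <- data.frame(id = c("a", "b[c]"))
  expect_error(metabolic_model(bad_comp, rxns,
                               list(EX_a = c("a" = -1),
                                    r = c("a" = -1, "b[c]" = 1)),
                               objective = "r"),
               "compartment")
})

test_that("stoichiometric matrix mirrors the reaction list", {
  m <- chain_model()
  S <- stoichiometric_matrix(m)
  expect_identical(dim(S), c(4L, 5L))
  expect_identical(colnames(S), m$reactions$id)
  expect_equal(unname(S[, "conv"]), c(0, 0, -1, 1))
  ## exchange columns have exactly one non-zero entry
  for (ex in list_exchanges(m))
    expect_identical(sum(S[, ex] != 0), 1L)
})

test_that("exchange listing requires a single extracellular metabolite", {
  m <- chain_model()
  expect_setequal(list_exchanges(m), c("EX_a", "EX_b"))
  ## transport c<->e touches two metabolites: not an exchange
  expect_false("At" %in% list_exchanges(m))
  ## no extracellular metabolites -> no exchanges
  internal <- metabolic_model(
    data.frame(id = c("a[c]", "b[c]")),
    data.frame(id = c("src", "r"), lb = c(0, 0), ub = c(5, 5)),
    list(src = c("a[c]" = 1), r = c("a[c]" = -1, "b[c]" = 1)),
    objective = "r")
  expect_length(list_exchanges(internal), 0)
  tp <- toy_pair()
  ex <- list_exchanges(tp$stromal$model)
  expect_true(all(startsWith(ex, "EX_")))
  expect_length(ex, 12)
})

test_that("elemental balance checking counts atoms and exempts boundaries", {
  mets <- data.frame(id = c("glc[c]", "pyr[c]", "glc[e]"),
                     formula = c("C6H12O6", "C3H4O3", "C6H12O6"))
  rxns <- data.frame(id = c("bad", "EX_glc", "Gt"),
                     lb = 0, ub = 10)
  st <- list(bad = c("glc[c]" = -1, "pyr[c]" = 2),  # short 4 H
             EX_glc = c("glc[e]" = -1),
             Gt = c("glc[e]" = -1, "glc[c]" = 1))
  m <- metabolic_model(mets, rxns, st, objective = "Gt")
  rep <- check_balance(m)
  expect_identical(rep$imbalanced$reaction_id, "bad")
  expect_true("H" %in% rep$imbalanced$element)
  h <- rep$imbalanced[rep$imbalanced$element == "H", ]
  expect_equal(h$imbalance, -4)
  expect_false("EX_glc" %in% rep$imbalanced$reaction_id)
  ## unparseable formula -> warning + unchecked
  mets2 <- mets; mets2$formula[2] <- "???"
  m2 <- metabolic_model(mets2, rxns, st, objective = "Gt")
  expect_warning(rep2 <- check_balance(m2), "bad")
  expect_identical(rep2$unchecked, "bad")
  ## the generator's internal reactions all balance
  tp <- toy_pair()
  expect_identical(nrow(check_balance(tp$stromal$model)$imbalanced), 0L)
  expect_identical(nrow(check_balance(tp$myeloma$model)$imbalanced), 0L)
})

test_that("JSON round-trip preserves every typed field byte-stably", {
  tp <- toy_pair()
  m <- tp$stromal$model
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_model(m, f1, "json")
  back <- read_model(f1, "json")
  expect_equal(back$metabolites, m$metabolites)
  expect_equal(back$reactions, m$reactions)
  for (rid in m$reactions$id) {
    a <- m$stoich[[rid]]; b <- back$stoich[[rid]]
    expect_equal(b[sort(names(b))], a[sort(names(a))], label = rid)
  }
  expect_identical(back$objective, m$objective)
  write_model(back, f2, "json")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SBML round-trip preserves ids, stoichiometry, bounds, GPR and objective", {
  tp <- toy_pair()
  m <- tp$myeloma$model
  f <- tempfile(fileext = ".xml")
  write_model(m, f, "sbml")
  back <- read_model(f, "sbml")
  expect_identical(back$metabolites$id, m$metabolites$id)
  expect_identical(back$metabolites$compartment, m$metabolites$compartment)
  expect_equal(back$metabolites$dgf, m$metabolites$dgf)
  expect_identical(back$reactions$id, m$reactions$id)
  expect_equal(back$reactions$lb, m$reactions$lb)
  expect_equal(back$reactions$ub, m$reactions$ub)
  expect_identical(back$objective, m$objective)
  for (rid in m$reactions$id) {
    a <- m$stoich[[rid]]; b <- back$stoich[[rid]]
    expect_equal(b[sort(names(b))], a[sort(names(a))])
  }
  ## a GPR with nested and/or survives
  i <- match("GLYC", m$reactions$id)
  expect_identical(eval_gpr(back$reactions$gpr[i],
                            c(gHK1 = .2, gPFKL = .8, gPKM = .9)),
                   eval_gpr(m$reactions$gpr[i],
                            c(gHK1 = .2, gPFKL = .8, gPKM = .9)))
})

test_that("minimal foreign SBML parses with bracket and attribute compartments", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mini">',
    '<listOfCompartments><compartment id="e" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="a[e]" compartment="e"/></listOfSpecies>',
    '<listOfReactions><reaction id="EX_a" reversible="true">',
    '<listOfReactants><speciesReference species="a[e]" stoichiometry="1"/></listOfReactants>',
    '</reaction></listOfReactions>',
    '</model></sbml>'), f)
  m <- read_model(f, "sbml")
  expect_identical(nrow(m$metabolites), 1L)
  expect_identical(m$metabolites$compartment, "e")
  expect_identical(m$metabolites$id, "a[e]")
  expect_identical(nrow(m$reactions), 1L)
  expect_identical(list_exchanges(m), "EX_a")
  ## compartment attribute wins over a conflicting bracket suffix
  f2 <- tempfile(fileext = ".xml")
  writeLines(gsub('compartment="e"(/>)?', 'compartment="c"\\1',
                  readLines(f)), f2)
  expect_warning(m2 <- read_model(f2, "sbml"), "overrides")
  expect_identical(m2$metabolites$compartment, "c")
})

test_that("GPR expressions parse, evaluate and re-serialise", {
  tree <- parse_gpr("(g1 and g2) or g3")
  expect_identical(sort(gpr_genes(tree)), c("g1", "g2", "g3"))
  expect_equal(eval_gpr(tree, c(g1 = .2, g2 = .8, g3 = .1)), .2)
  rt <- parse_gpr(deparse_gpr <- cocultr:::deparse_gpr(tree))
  expect_equal(eval_gpr(rt, c(g1 = .2, g2 = .8, g3 = .1)), .2)
  expect_null(parse_gpr(""))
  expect_true(is.na(eval_gpr("", c(g1 = 1))))
  expect_error(parse_gpr("g1 and (g2 or"), "GPR")
  expect_error(parse_gpr("and g1"), "GPR")
})
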