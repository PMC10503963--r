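test_that("gene ubiquity is the presence fraction", {
  calls <- matrix(0, 3, 12, dimnames = list(c("g1", "g2", "g3"),
                                            paste0("S", 1:12)))
  calls["g1", ] <- 1
  calls["g2", 1:3] <- 1
  expr <- expression_dataset(calls)
  ub <- gene_ubiquity(expr)
  expect_equal(ub[["g1"]], 1)
  expect_equal(ub[["g2"]], 0.25)
  expect_equal(ub[["g3"]], 0)
  ## random matrix vs an independent per-row recount
  set.seed(4)
  rc <- matrix(rbinom(200 * 8, 1, 0.4), 200, 8,
               dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  got <- gene_ubiquity(expression_dataset(rc))
  for (g in sample(rownames(rc), 20)) {
    cnt <- 0
    for (j in seq_len(ncol(rc))) if (rc[g, j] == 1) cnt <- cnt + 1
    expect_equal(got[[g]], cnt / ncol(rc))
  }
})

test_that("reaction scoring follows AND=min / OR=max and flags empty GPRs", {
  s <- c(g1 = 0.2, g2 = 0.8, g3 = 0.5, g4 = 0.9)
  expect_equal(eval_gpr("g1 and g2", s), 0.2)
  expect_equal(eval_gpr("g1 or (g4 and g3)", s), 0.5)
  ## random GPR trees vs the brute-force evaluator
  set.seed(11)
  genes <- names(s)
  rand_expr <- function(depth) {
    if (depth == 0 || runif(1) < 0.35) return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    paste0("(", rand_expr(depth - 1), " ", op, " ",
           rand_expr(depth - 1), ")")
  }
  for (k in 1:25) {
    e <- rand_expr(4)
    expect_equal(eval_gpr(e, s), gpr_brute_eval(e, s), label = e)
  }
  ## via the model interface, empty GPR -> NA, missing gene -> warning
  m <- chain_model()
  m$reactions$gpr <- c("", "g1 and g2", "gX or g1", "", "")
  expect_warning(sc <- score_reactions(m, s), "gX")
  expect_true(is.na(sc$expression_score[1]))
  expect_equal(sc$expression_score[2], 0.2)
  expect_equal(sc$expression_score[3], 0.2)  # gX defaults to 0
})

test_that("connectivity updates average scored neighbours over shared metabolites", {
  ## 3-reaction chain r1 -(x)- r2 -(y)- r3, middle GPR-less
  m <- metabolic_model(
    data.frame(id = c("x[c]", "y[c]")),
    data.frame(id = c("r1", "r2", "r3"), lb = 0, ub = 10,
               gpr = c("gA", "", "gB")),
    list(r1 = c("x[c]" = 1), r2 = c("x[c]" = -1, "y[c]" = 1),
         r3 = c("y[c]" = -1)),
    objective = "r2")
  sc <- connectivity_update(m, score_reactions(m, c(gA = 1, gB = 0)),
                            w = 0.75)
  mid <- sc[sc$reaction_id == "r2", ]
  expect_equal(mid$connectivity_score, 0.5)  # mean of 1.0 and 0.0
  expect_equal(mid$combined, 0.5)            # no expression -> connectivity
  ## r1's only neighbour (r2) carries no expression score, so r1 has no
  ## scored neighbours: connectivity 0
  r1 <- sc[sc$reaction_id == "r1", ]
  expect_equal(r1$connectivity_score, 0)
  expect_equal(r1$combined, 0.75 * 1)
  ## isolated reaction: connectivity 0, combined = w * expression
  iso <- metabolic_model(
    data.frame(id = c("x[c]", "z[c]")),
    data.frame(id = c("r1", "r2"), lb = 0, ub = 10,
               gpr = c("gA", "gB")),
    list(r1 = c("x[c]" = 1), r2 = c("z[c]" = 1)),
    objective = "r1")
  sci <- connectivity_update(iso, score_reactions(iso,
                                                  c(gA = 0.8, gB = 0.4)))
  expect_equal(sci$connectivity_score, c(0, 0))
  expect_equal(sci$combined[1], 0.75 * 0.8)
  ## combined always in [0, 1] on the generator model
  tp <- toy_pair()
  mt <- tp$stromal$model
  ub <- gene_ubiquity(make_expression_dataset(mt, seed = 5))
  sct <- connectivity_update(mt, score_reactions(mt, ub))
  expect_true(all(sct$combined >= 0 & sct$combined <= 1))
})

## small prunable fixture: biomass from a via either r_good (scored high)
## or r_bad (scored low), plus a uselessly scored dead branch
prune_fixture <- function() {
  metabolic_model(
    data.frame(id = c("a[e]", "a[c]", "b[c]", "d[c]")),
    data.frame(id = c("EX_a", "At", "r_good", "r_bad", "r_dead",
                      "SINK_d", "BIOMASS"),
               lb = c(-10, 0, 0, 0, 0, 0, 0),
               ub = c(1000, 1000, 1000, 1000, 1000, 1000, 1000)),
    list(EX_a = c("a[e]" = -1), At = c("a[e]" = -1, "a[c]" = 1),
         r_good = c("a[c]" = -1, "b[c]" = 1),
         r_bad = c("a[c]" = -1, "b[c]" = 1),
         r_dead = c("a[c]" = -1, "d[c]" = 1),
         SINK_d = c("d[c]" = -1),
         BIOMASS = c("b[c]" = -1)),
    objective = "BIOMASS", id = "prunable")
}

prune_scores <- function(m, vals) {
  data.frame(reaction_id = m$reactions$id,
             combined = vals[m$reactions$id], stringsAsFactors = FALSE)
}

test_that("pruning respects threshold, essentiality and the core set", {
  m <- prune_fixture()
  sc <- prune_scores(m, c(EX_a = 1, At = 1, r_good = 0.9, r_bad = 0.05,
                          r_dead = 0.01, SINK_d = 0.01, BIOMASS = 1))
  ## threshold 0: nothing is below, output identical
  p0 <- prune_model(m, sc, core_ids = "BIOMASS", threshold = 0)
  expect_setequal(p0$reactions$id, m$reactions$id)
  ## threshold 0.2 removes the low-score redundant route and dead branch
  p <- prune_model(m, sc, core_ids = "BIOMASS", threshold = 0.2)
  expect_false("r_bad" %in% p$reactions$id)
  expect_false("r_dead" %in% p$reactions$id)
  expect_true("r_good" %in% p$reactions$id)
  ## a low-score reaction that is essential for biomass is retained
  sc2 <- prune_scores(m, c(EX_a = 1, At = 0.05, r_good = 0.9,
                           r_bad = 0.9, r_dead = 0.9, SINK_d = 0.9,
                           BIOMASS = 1))
  p2 <- prune_model(m, sc2, core_ids = "BIOMASS", threshold = 0.2)
  expect_true("At" %in% p2$reactions$id)  # essential despite score 0.05
  ## core reactions are never removed even when low-scored
  sc3 <- prune_scores(m, c(EX_a = 1, At = 1, r_good = 0.9, r_bad = 0.01,
                           r_dead = 0.01, SINK_d = 0.01, BIOMASS = 1))
  p3 <- prune_model(m, sc3, core_ids = c("BIOMASS", "r_dead", "SINK_d"),
                    threshold = 0.2)
  expect_true(all(c("r_dead", "SINK_d") %in% p3$reactions$id))
  ## zero-objective model errors
  dead <- set_bounds(m, "BIOMASS", ub = 0)
  expect_error(prune_model(dead, sc, "BIOMASS", 0.2), "positive")
})

test_that("pruning matches the exhaustive-deletion oracle on a small model", {
  m <- prune_fixture()
  sc <- prune_scores(m, c(EX_a = 1, At = 1, r_good = 0.05, r_bad = 0.04,
                          r_dead = 0.01, SINK_d = 0.01, BIOMASS = 1))
  ## all non-core below threshold: greedy ascending-score removal with the
  ## functionality guard, recomputed here by explicit single deletions
  core <- c("BIOMASS", "EX_a", "At")
  opt <- fba_optimize(m)$objective_value
  keep <- m$reactions$id
  cand <- setdiff(keep, core)
  cand <- cand[order(sc$combined[match(cand, sc$reaction_id)], cand)]
  cur <- m
  for (rid in cand) {
    trial <- remove_reactions(cur, rid)
    o <- tryCatch(fba_optimize(trial)$objective_value,
                  error = function(e) -Inf)
    if (!is.na(o) && o >= 0.9 * opt - 1e-9) cur <- trial
  }
  got <- prune_model(m, sc, core_ids = core, threshold = 1,
                     min_objective_fraction = 0.9)
  expect_setequal(got$reactions$id, cur$reactions$id)
  ## exactly one of the two redundant routes survives
  expect_identical(sum(c("r_good", "r_bad") %in% got$reactions$id), 1L)
})

test_that("pruned size is monotone in the threshold and runs are deterministic", {
  tp <- toy_pair()
  m <- tp$stromal$model
  ub <- gene_ubiquity(make_expression_dataset(
    m, presence_profile = 0.5, seed = 21))
  sc <- connectivity_update(m, score_reactions(m, ub))
  core <- c("BIOMASS", "DM_biomass", "GLYC", "CI", "CIII", "CIV", "CV")
  sizes <- vapply(c(0, 0.3, 0.6, 0.9), function(th)
    nrow(prune_model(m, sc, core, th, 0.5)$reactions), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  a <- prune_model(m, sc, core, 0.6, 0.5)
  b <- prune_model(m, sc, core, 0.6, 0.5)
  expect_identical(a$reactions, b$reactions)
  ## core preservation and functionality on every pruning
  for (th in c(0.3, 0.9)) {
    p <- prune_model(m, sc, core, th, 0.5)
    expect_true(all(core %in% p$reactions$id))
    expect_gte(fba_optimize(p)$objective_value,
               0.5 * fba_optimize(m)$objective_value - 1e-6)
  }
})

test_that("expression tables round-trip through TSV", {
  tp <- toy_pair()
  expr <- make_expression_dataset(tp$stromal$model, n_samples = 5,
                                  seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_expression(expr, f)
  back <- read_expression(f)
  expect_identical(back$calls, expr$calls)
  expect_error(expression_dataset(matrix(2, 1, 1,
                                         dimnames = list("g", "s"))),
               "0/1")
})
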