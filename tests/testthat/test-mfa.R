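test_that("atom networks parse, validate conservation and re-serialise", {
  net <- parse_atom_network("v1: A (abc) -> B (ab) + C (c)")
  expect_length(net$transitions, 1)
  expect_identical(net$carbons[["A"]], 3L)
  expect_identical(net$substrates, "A")
  ## symmetric species expand into equal-probability variants
  net2 <- parse_atom_network("v1: A (abcd) -> B (abcd|dcba)")
  expect_length(net2$transitions$v1$variants, 2)
  expect_equal(vapply(net2$transitions$v1$variants, `[[`, 1, "prob"),
               c(0.5, 0.5))
  ## unbalanced letters error with the line number
  expect_error(parse_atom_network("v1: A (abc) -> B (ab)"), "line 1")
  expect_error(parse_atom_network(c("ok: A (a) -> B (a)",
                                    "bad: C (ab) -> D (aa)")),
               "line 2")
  ## the toy network round-trips through its own serialisation
  tn <- make_atom_mapped_toynet()
  reparsed <- parse_atom_network(format_atom_network(tn$network))
  expect_identical(names(reparsed$transitions),
                   names(tn$network$transitions))
  expect_identical(reparsed$carbons, tn$network$carbons)
})

test_that("EMU decomposition finds pass-throughs, convolutions and errors", {
  ## linear pass-through: B[1,2] needs only A[1,2]
  net <- parse_atom_network(c("v1: A (ab) -> B (ab)",
                              "v2: B (ab) -> C (ab)"))
  emu <- decompose_emus(net, list("B[1,2]"))
  expect_setequal(names(emu$nodes), c("B[1,2]", "A[1,2]"))
  ## condensation creates a convolution term
  net2 <- parse_atom_network(c("v1: A1 (a) + A2 (b) -> B (ab)",
                               "v2: B (ab) -> C (ab)"))
  emu2 <- decompose_emus(net2, list("B[1,2]"))
  terms <- emu2$nodes[["B[1,2]"]]$terms
  expect_identical(length(terms[[1]]$sources), 2L)
  ## unreachable fragment errors by name
  net3 <- parse_atom_network(c("v1: A (a) -> B (a)",
                               "v2: X (b) -> X2 (b)"))
  expect_error(decompose_emus(net3, list("B[2]")), "out of range")
  ## every toy-network EMU traces to a substrate (no orphan nodes)
  tn <- make_atom_mapped_toynet()
  emu3 <- decompose_emus(tn$network, list("Cit[1,2,3,4,5,6]"))
  for (n in emu3$nodes)
    if (!n$input) expect_gt(length(n$terms), 0)
})

test_that("unlabelled and fully-labelled limits are exact", {
  tn <- make_atom_mapped_toynet()
  truth <- toy_mfa_truth()
  emu <- decompose_emus(tn$network, as.list(truth$fragments))
  ## no tracer anywhere: every fragment all m+0
  sim0 <- simulate_mids(emu, truth$fluxes, list())
  for (mid in sim0) {
    expect_equal(mid[1], 1, tolerance = 1e-12)
    expect_equal(sum(mid), 1, tolerance = 1e-12)
  }
  ## pure fully-labelled glucose in a glucose-only chain: terminal m+n = 1
  chain <- parse_atom_network(c("v1: Glc (abcdef) -> P1 (abc) + P2 (def)",
                                "v2: P1 (abc) -> Out (abc)"))
  emu_c <- decompose_emus(chain, list("Out[1,2,3]"))
  sim1 <- simulate_mids(emu_c, c(v1 = 1, v2 = 1),
                        list(tracer("Glc", "U", purity = 1)))
  expect_equal(sim1[["Out[1,2,3]"]], c(0, 0, 0, 1), tolerance = 1e-12)
})

test_that("EMU MIDs equal the brute-force isotopomer enumeration", {
  tn <- make_atom_mapped_toynet()
  net <- tn$network
  truth <- toy_mfa_truth()
  emu <- decompose_emus(net, as.list(truth$fragments))
  tracer_sets <- list(list(tracer("Glc", "U", 0.99)),
                      list(tracer("Gln", "U", 0.99)),
                      list(tracer("Glc", c(1, 2), 0.95, fraction = 0.5)))
  set.seed(31)
  for (rep in 1:6) {
    ## random steady-state feasible fluxes via random free-flux draws
    f <- truth$fluxes * exp(runif(length(truth$fluxes), -0.5, 0.5))
    ## rebalance: project onto the steady-state space through the package
    ## free-flux split would reuse the tested path, so rebuild by hand:
    ## draw frees, derive dependents from the balance equations
    frees <- c(v_ldh = runif(1, .1, 1), v_ala = runif(1, .05, .6),
               v_pc = runif(1, .05, .5), v_cit_out = runif(1, .05, .5),
               v_gls = runif(1, .2, 1), v_hex = runif(1, .3, 1.2))
    v <- c(frees,
           v_pdh = unname(2 * frees[["v_hex"]] - frees[["v_ldh"]] -
                            frees[["v_ala"]] - frees[["v_pc"]]),
           v_gdh = unname(frees[["v_gls"]]))
    if (v[["v_pdh"]] <= 0.05) next
    v <- c(v, v_cs = unname(v[["v_pdh"]]))
    v <- c(v, v_cak = unname(v[["v_cs"]] - frees[["v_cit_out"]]))
    if (v[["v_cak"]] <= 0.02) next
    v <- c(v, v_ao = unname(v[["v_cak"]] + v[["v_gdh"]]))
    v <- c(v, v_oaa_out = unname(frees[["v_pc"]] + v[["v_ao"]] -
                                   v[["v_cs"]]))
    if (v[["v_oaa_out"]] <= 0) next
    v <- c(v, v_co2_out = unname(v[["v_pdh"]] + v[["v_cak"]] +
                                   v[["v_ao"]] - frees[["v_pc"]]))
    trs <- tracer_sets[[1 + rep %% length(tracer_sets)]]
    sim <- simulate_mids(emu, v, trs)
    iso <- iso_fixed_point_oracle(net, v, trs)
    for (fr in truth$fragments) {
      fx <- cocultr:::parse_fragment(fr)
      want <- mid_from_isotopomers(iso[[fx$met]], fx$pos,
                                   net$carbons[[fx$met]])
      expect_equal(sim[[fr]], want, tolerance = 1e-8, label = fr)
      expect_equal(sum(sim[[fr]]), 1, tolerance = 1e-9)
      expect_true(all(sim[[fr]] >= -1e-12))
    }
    ## flux-scaling invariance: doubling all fluxes leaves MIDs unchanged
    sim2 <- simulate_mids(emu, 2 * v, trs)
    for (fr in truth$fragments)
      expect_equal(sim2[[fr]], sim[[fr]], tolerance = 1e-10)
  }
})

test_that("the SSR is the variance-weighted squared mismatch", {
  meas <- data.frame(fragment = rep("B[1,2]", 3), mass = 0:2,
                     value = c(0.5, 0.3, 0.2), sd = 0.01)
  sim <- list("B[1,2]" = c(0.5, 0.3, 0.2))
  expect_identical(ssr(meas, sim), 0)
  sim2 <- list("B[1,2]" = c(0.52, 0.3, 0.2))
  expect_equal(ssr(meas, sim2), 4, tolerance = 1e-9)
  ## random perturbations match an independent recount
  set.seed(7)
  pert <- rnorm(3, 0, 0.01)
  sim3 <- list("B[1,2]" = c(0.5, 0.3, 0.2) + pert)
  want <- 0
  for (i in 1:3) want <- want + (pert[i] / 0.01)^2
  expect_equal(ssr(meas, sim3), want, tolerance = 1e-9)
  ## fragment mismatch errors
  expect_error(ssr(meas, list("C[1]" = 1)), "B\\[1,2\\]")
  ## flux measurements add their own weighted terms
  mf <- data.frame(reaction_id = "v1", value = 1, sd = 0.1)
  expect_equal(ssr(meas, sim, mf, c(v1 = 1.2)), 4, tolerance = 1e-9)
})

test_that("zero-noise fitting recovers the true fluxes and is deterministic", {
  s <- toy_mfa_setup()
  fit <- fit_fluxes(s$mfa0, n_restarts = 6, seed = 42)
  expect_lte(fit$ssr, 1e-8)
  truth <- s$truth0$fluxes[names(fit$fluxes)]
  expect_lt(max(abs(fit$fluxes - truth) / pmax(truth, 1e-12)), 1e-4)
  ## free-flux count equals reactions minus stoichiometric rank
  S <- s$mfa0$S
  expect_identical(length(s$mfa0$free),
                   ncol(S) - qr(S)$rank)
  ## identical seeds give identical estimates
  fit2 <- fit_fluxes(s$mfa0, n_restarts = 6, seed = 42)
  expect_identical(fit$fluxes, fit2$fluxes)
  expect_identical(fit$restart_ssr, fit2$restart_ssr)
})

test_that("noisy fitting lands in the chi-square acceptance region", {
  ## a single pinned dataset is one draw from the SSR distribution, so it
  ## is checked against the wide 99% band; the calibration of the 95%
  ## verdict across datasets is checked separately below
  s <- toy_mfa_setup()
  fit <- fit_fluxes(s$mfaN, n_restarts = 12, seed = 7)
  expect_gte(fit$ssr, qchisq(0.005, fit$df))
  expect_lte(fit$ssr, qchisq(0.995, fit$df))
  expect_identical(fit$df,
                   cocultr:::mfa_n_measurements(s$mfaN) -
                     length(s$mfaN$free))
  ## estimates sit near the truth at this noise level
  truth <- s$truthN$fluxes[names(fit$fluxes)]
  expect_lt(max(abs(fit$fluxes - truth)), 0.35)
})

test_that("the SSR at the true fluxes is calibrated against its degrees of freedom", {
  s <- toy_mfa_setup()
  net <- s$net
  truth <- s$truthN
  emu <- s$mfaN$emunet
  ## without fitting, the reference is the residual count (every MID entry
  ## plus every measured flux); the clip-and-renormalise noise model may
  ## shift the mean a little, which is what the 20% band watches
  n_res <- sum(vapply(s$mfaN$experiments, function(e)
    nrow(e$measurements), integer(1))) + nrow(s$mfaN$measured_fluxes)
  ssrs <- numeric(0)
  for (seed in 1:200) {
    exps <- simulate_labelling_experiment(truth, net, seed = 1000 + seed)
    total <- 0
    for (en in names(exps)) {
      sim <- simulate_mids(emu, truth$fluxes, exps[[en]]$tracers)
      total <- total + ssr(exps[[en]]$measurements, sim)
    }
    mf <- attr(exps, "measured_fluxes")
    total <- total + sum(((truth$fluxes[mf$reaction_id] - mf$value) /
                            mf$sd)^2)
    ssrs <- c(ssrs, total)
  }
  expect_lt(abs(mean(ssrs) - n_res) / n_res, 0.2)
})

test_that("Monte-Carlo intervals contain the point estimate and shrink with noise", {
  s <- toy_mfa_setup()
  fit <- fit_fluxes(s$mfaN, n_restarts = 8, seed = 7)
  fit <- monte_carlo_ci(s$mfaN, fit, n_samples = 12, seed = 13,
                        restarts_per_sample = 1)
  ci <- fit$ci
  expect_true(all(ci$lo <= fit$fluxes[ci$reaction_id] + 1e-9))
  expect_true(all(ci$hi >= fit$fluxes[ci$reaction_id] - 1e-9))
  ## near-zero measurement noise: interval widths collapse
  truth_tight <- toy_mfa_truth(noise_sd = 1e-4)
  exps_t <- simulate_labelling_experiment(truth_tight, s$net, seed = 5)
  mfa_t <- mfa_model(s$net, exps_t,
                     measured_fluxes = attr(exps_t, "measured_fluxes"))
  mfa_t$measured_fluxes$sd <- 1e-4
  fit_t <- fit_fluxes(mfa_t, n_restarts = 4, seed = 3)
  fit_t <- monte_carlo_ci(mfa_t, fit_t, n_samples = 8, seed = 3,
                          restarts_per_sample = 1)
  expect_lt(max(fit_t$ci$hi - fit_t$ci$lo), 0.02)
})

test_that("interval export maps ids, flips uptake signs and round-trips", {
  s <- toy_mfa_setup()
  fit <- fit_fluxes(s$mfaN, n_restarts = 4, seed = 7)
  fit <- monte_carlo_ci(s$mfaN, fit, n_samples = 8, seed = 1,
                        restarts_per_sample = 1)
  ## empty map: empty table, full sidecar
  empty <- export_intervals(fit, character(0))
  expect_identical(nrow(empty), 0L)
  expect_setequal(attr(empty, "unmapped"), names(fit$fluxes))
  ## sign flip converts an uptake magnitude to the exchange convention
  iv <- export_intervals(fit, data.frame(
    mfa_id = c("v_hex", "v_gls"), cbm_id = c("EX_glc", "GLS"),
    sign = c(-1, 1)))
  hex <- fit$ci[fit$ci$reaction_id == "v_hex", ]
  expect_equal(iv$lo[iv$reaction_id == "EX_glc"], -hex$hi)
  expect_equal(iv$hi[iv$reaction_id == "EX_glc"], -hex$lo)
  ## duplicate targets error
  expect_error(export_intervals(fit, data.frame(
    mfa_id = c("v_hex", "v_gls"), cbm_id = c("X", "X"))), "duplicate")
  ## round-trip: the exported intervals constrain the toy cell without id
  ## errors, and tuning keeps the model feasible
  tp <- toy_pair()
  iv2 <- export_intervals(fit, data.frame(
    mfa_id = c("v_hex", "v_gls", "v_ldh"),
    cbm_id = c("GLYC", "GLS", "LDH"), sign = 1))
  tuned <- apply_flux_intervals(tp$myeloma$model, iv2)
  expect_identical(length(attr(tuned, "unmatched")), 0L)
  expect_identical(fba_optimize(tuned)$status, "optimal")
})

test_that("tuning with a zero-noise fit keeps the truth feasible", {
  s <- toy_mfa_setup()
  fit <- fit_fluxes(s$mfa0, n_restarts = 4, seed = 11)
  fit <- monte_carlo_ci(s$mfa0, fit, n_samples = 10, seed = 2,
                        restarts_per_sample = 1)
  ci <- fit$ci
  truth <- s$truth0$fluxes[ci$reaction_id]
  expect_true(all(ci$lo <= truth + 1e-6 & truth <= ci$hi + 1e-6))
})
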