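## Deterministic generators for every input the pipeline consumes: paired
## two-cell toy central-carbon models (glycolysis, TCA, oxidative
## phosphorylation with lumped complexes I/III/IV/V and a proton leak,
## glutaminolysis, serine and alanine side branches, lactate/pyruvate/
## citrate transport, biomass), binary expression matrices, thermodynamic
## tables, media, an atom-mapped tracer subnetwork, and simulated labelling
## datasets from a known flux vector.

#' Specification for the toy cell generator
#'
#' @param seed integer; fixes all randomness downstream (the model
#'   construction itself is deterministic).
#' @param include_leak include the mitochondrial proton leak reaction.
#' @param leak_capacity upper bound of the leak flux (protons, mmol/gDW/h).
#' @param pump_stoichiometry protons pumped into the intermembrane space
#'   per 1/2 O2 reduced (summed over complexes I, III, IV); must be >= 7
#'   (complexes III and IV contribute 6, complex I the remainder).
#' @param biomass_composition named coefficients of the biomass reaction's
#'   precursor drains (`pyr`, `atp`).
#' @param shared_substrates medium species both cells compete for.
#' @return object of class `toy_spec`.
#' @export
toy_spec <- function(seed = 1, include_leak = TRUE, leak_capacity = 2,
                     pump_stoichiometry = 10,
                     biomass_composition = c(pyr = 4, atp = 15),
                     shared_substrates = c("glc", "gln", "ser", "o2")) {
  stopifnot(pump_stoichiometry >= 7, leak_capacity >= 0,
            all(biomass_composition > 0))
  structure(list(seed = seed, include_leak = include_leak,
                 leak_capacity = leak_capacity,
                 pump_stoichiometry = pump_stoichiometry,
                 biomass_composition = biomass_composition,
                 shared_substrates = shared_substrates),
            class = "toy_spec")
}

## formula table for the toy chemistry; X/Y/Q/Z are opaque moieties
## (adenosine, nicotinamide, quinone, cytochrome) so that every internal
## reaction balances exactly
TOY_FORMULAS <- c(
  glc = "C6H12O6", gln = "C5H10N2O3", lac = "C3H6O3", pyr = "C3H4O3",
  ala = "C3H7N1O2", ser = "C3H7N1O3", o2 = "O2", co2 = "C1O2", h = "H1",
  h2o = "H2O1", nh4 = "H4N1", cit = "C6H8O7", glu = "C5H9N1O4",
  akg = "C5H6O5", atp = "X1H1O3P1", adp = "X1", pi = "H3O4P1",
  nad = "Y1", nadh = "Y1H2", q = "Q1", qh2 = "Q1H2", cytc_ox = "Z1",
  cytc_red = "Z1")

## synthetic formation energies (kJ/mol) per bare metabolite name; chosen
## so the catabolic backbone is downhill and near-equilibrium steps
## straddle zero once concentration ranges are applied
TOY_DGF <- c(
  glc = -426, gln = -206, lac = -352, pyr = -350, ala = -310, ser = -340,
  o2 = -10, co2 = -394, h = 0, h2o = -40, nh4 = -30, cit = -963,
  glu = -300, akg = -400, atp = -20, adp = 0, pi = -5, nad = 0,
  nadh = -3, q = 0, qh2 = -5, cytc_ox = 0, cytc_red = 0)

#' Generate a toy single-cell central-carbon model
#'
#' Builds a mass-balanced constraint-based model of lumped central carbon
#' metabolism (glycolysis, pyruvate oxidation/TCA, citrate overflow,
#' glutaminolysis, serine and alanine branches, electron transport chain
#' with explicit matrix/intermembrane proton pools, ATP synthase, optional
#' proton leak, biomass) together with its electron-transport-chain map, a
#' synthetic thermodynamic table and an RPMI-like medium. The
#' `myeloma_like` variant differs from `stromal_like` by documented bound
#' asymmetries: doubled glycolytic/glucose-transport capacity and strongly
#' reduced oxygen-transport capacity, so that co-culture trade-offs (and a
#' stroma-to-myeloma pyruvate shuttle) are non-trivial.
#'
#' @param spec a [toy_spec()].
#' @param cell_kind `"stromal_like"` or `"myeloma_like"`.
#' @return list with `model` (a `metabolic_model`), `etc` (an
#'   [etc_map()]), `thermo` (a `thermo_table`) and `medium` (a
#'   [medium()]).
#' @export
make_toy_cell_model <- function(spec = toy_spec(),
                                cell_kind = c("stromal_like",
                                              "myeloma_like")) {
  cell_kind <- match.arg(cell_kind)
  p1 <- spec$pump_stoichiometry - 6   # protons pumped by complex I
  myel <- cell_kind == "myeloma_like"
  glyc_cap <- if (myel) 20 else 10
  o2_cap <- if (myel) 6 else 30
  bc <- spec$biomass_composition

  mk <- function(bare, comp) paste0(bare, "[", comp, "]")
  met_rows <- list()
  add_met <- function(bare, comp) {
    id <- mk(bare, comp)
    met_rows[[id]] <<- data.frame(
      id = id, name = bare, compartment = comp,
      formula = if (bare == "biomass") biomass_formula
                else unname(TOY_FORMULAS[[bare]]),
      dgf = NA_real_, stringsAsFactors = FALSE)
    id
  }
  ## biomass pseudo-species formula = what its drain consumes net of the
  ## ATP hydrolysis cycle: bc["pyr"] pyruvates
  pf <- parse_formula(TOY_FORMULAS[["pyr"]])
  biomass_formula <- paste0(vapply(names(pf), function(el)
    paste0(el, bc[["pyr"]] * pf[[el]]), character(1)), collapse = "")

  e_mets <- c("glc", "gln", "lac", "pyr", "ala", "ser", "o2", "co2", "h",
              "h2o", "nh4", "cit")
  c_mets <- c("glc", "gln", "lac", "pyr", "ala", "ser", "h", "h2o", "nh4",
              "cit", "glu", "akg", "atp", "adp", "pi", "nad", "nadh",
              "biomass")
  m_mets <- c("pyr", "akg", "glu", "co2", "h2o", "o2", "nh4", "h", "nad",
              "nadh", "atp", "adp", "pi", "q", "qh2", "cytc_ox",
              "cytc_red", "cit")
  for (b in e_mets) add_met(b, "e")
  for (b in c_mets) add_met(b, "c")
  for (b in m_mets) add_met(b, "m")
  add_met("h", "i")

  rxn_rows <- list(); stoich <- list()
  add_rxn <- function(id, s, lb, ub, gpr = "", subsystem = NA_character_) {
    rxn_rows[[id]] <<- data.frame(id = id, lb = lb, ub = ub, gpr = gpr,
                                  subsystem = subsystem,
                                  stringsAsFactors = FALSE)
    stoich[[id]] <<- s
  }
  for (b in e_mets)
    add_rxn(paste0("EX_", b), stats::setNames(-1, mk(b, "e")),
            -1000, 1000, subsystem = "exchange")

  tr <- function(id, from, to, lb, ub, gpr = "")
    add_rxn(id, stats::setNames(c(-1, 1), c(from, to)), lb, ub, gpr,
            subsystem = "transport")
  tr("GLCt", mk("glc", "e"), mk("glc", "c"), 0, glyc_cap, "gGLUT1")
  tr("GLNt", mk("gln", "e"), mk("gln", "c"), 0, 5, "gASCT2")
  tr("LACt", mk("lac", "c"), mk("lac", "e"), -1000, 1000,
     "gMCT1 or gMCT4")
  tr("PYRt", mk("pyr", "c"), mk("pyr", "e"), -1000, 1000, "gMCT1")
  tr("ALAt", mk("ala", "c"), mk("ala", "e"), -1000, 1000, "gASCT2")
  tr("SERt", mk("ser", "e"), mk("ser", "c"), -1000, 1000, "gASCT1")
  tr("O2t", mk("o2", "e"), mk("o2", "m"), 0, o2_cap)
  tr("CO2t", mk("co2", "m"), mk("co2", "e"), -1000, 1000)
  tr("Ht", mk("h", "e"), mk("h", "c"), -1000, 1000)
  tr("Htm", mk("h", "c"), mk("h", "m"), -1000, 1000)
  tr("H2Ot", mk("h2o", "e"), mk("h2o", "c"), -1000, 1000, "gAQP1")
  tr("H2Otm", mk("h2o", "c"), mk("h2o", "m"), -1000, 1000)
  tr("NH4t", mk("nh4", "c"), mk("nh4", "e"), -1000, 1000)
  tr("NH4tm", mk("nh4", "m"), mk("nh4", "c"), -1000, 1000)
  tr("CITtm", mk("cit", "m"), mk("cit", "c"), 0, 1000, "gSLC25A1")
  tr("CITt", mk("cit", "c"), mk("cit", "e"), 0, 1000)
  tr("PYRtm", mk("pyr", "c"), mk("pyr", "m"), 0, 1000,
     "gMPC1 and gMPC2")
  tr("GLUtm", mk("glu", "c"), mk("glu", "m"), 0, 1000, "gSLC25A22")
  tr("AKGtm", mk("akg", "c"), mk("akg", "m"), 0, 1000, "gSLC25A11")
  tr("PIt", mk("pi", "c"), mk("pi", "m"), 0, 1000, "gSLC25A3")
  add_rxn("ANT", stats::setNames(c(-1, -1, 1, 1),
                                 c(mk("atp", "m"), mk("adp", "c"),
                                   mk("atp", "c"), mk("adp", "m"))),
          0, 1000, "gANT1", "transport")

  add_rxn("GLYC", stats::setNames(
    c(-1, -2, -2, -2, 2, 2, 2, 2),
    c(mk("glc", "c"), mk("adp", "c"), mk("pi", "c"), mk("nad", "c"),
      mk("pyr", "c"), mk("atp", "c"), mk("nadh", "c"), mk("h2o", "c"))),
    0, glyc_cap, "gHK1 and gPFKL and gPKM", "glycolysis")
  add_rxn("LDH", stats::setNames(
    c(-1, -1, 1, 1),
    c(mk("pyr", "c"), mk("nadh", "c"), mk("lac", "c"), mk("nad", "c"))),
    -1000, 1000, "gLDHA or gLDHB", "glycolysis")
  add_rxn("NSHT", stats::setNames(
    c(-1, -1, 1, 1),
    c(mk("nadh", "c"), mk("nad", "m"), mk("nad", "c"), mk("nadh", "m"))),
    0, 1000, "gGOT1 and gGOT2", "shuttle")
  add_rxn("PDHTCA", stats::setNames(
    c(-1, -3, -5, 3, 5),
    c(mk("pyr", "m"), mk("h2o", "m"), mk("nad", "m"), mk("co2", "m"),
      mk("nadh", "m"))),
    0, 1000, "gPDHA1 and gCS", "TCA")
  add_rxn("CITS", stats::setNames(
    c(-2, -1, -1, 1, 1),
    c(mk("pyr", "m"), mk("h2o", "m"), mk("nad", "m"), mk("cit", "m"),
      mk("nadh", "m"))),
    0, 1000, "gCS", "TCA")
  add_rxn("GLS", stats::setNames(
    c(-1, -1, -1, 1, 1),
    c(mk("gln", "c"), mk("h2o", "c"), mk("h", "c"), mk("glu", "c"),
      mk("nh4", "c"))),
    0, 1000, "gGLS1", "glutaminolysis")
  add_rxn("GLUDH", stats::setNames(
    c(-1, -1, -1, -1, 1, 1, 1),
    c(mk("glu", "m"), mk("nad", "m"), mk("h2o", "m"), mk("h", "m"),
      mk("akg", "m"), mk("nadh", "m"), mk("nh4", "m"))),
    0, 1000, "gGLUD1", "glutaminolysis")
  add_rxn("AKGOX", stats::setNames(
    c(-1, -5, -8, 5, 8),
    c(mk("akg", "m"), mk("h2o", "m"), mk("nad", "m"), mk("co2", "m"),
      mk("nadh", "m"))),
    0, 1000, "gOGDH", "TCA")
  add_rxn("ALT", stats::setNames(
    c(-1, -1, 1, 1),
    c(mk("pyr", "c"), mk("glu", "c"), mk("ala", "c"), mk("akg", "c"))),
    -1000, 1000, "gGPT1", "amino acids")
  add_rxn("SERD", stats::setNames(
    c(-1, -1, 1, 1),
    c(mk("ser", "c"), mk("h", "c"), mk("pyr", "c"), mk("nh4", "c"))),
    0, 1000, "gSDS", "amino acids")
  add_rxn("CI", stats::setNames(
    c(-1, -1, -p1, 1, 1, p1),
    c(mk("nadh", "m"), mk("q", "m"), mk("h", "m"), mk("nad", "m"),
      mk("qh2", "m"), mk("h", "i"))),
    0, 1000, "gNDUFS1 and gNDUFV1", "oxphos")
  add_rxn("CIII", stats::setNames(
    c(-1, -2, -2, 1, 2, 4),
    c(mk("qh2", "m"), mk("cytc_ox", "m"), mk("h", "m"), mk("q", "m"),
      mk("cytc_red", "m"), mk("h", "i"))),
    0, 1000, "gUQCRC1", "oxphos")
  add_rxn("CIV", stats::setNames(
    c(-2, -0.5, -4, 2, 1, 2),
    c(mk("cytc_red", "m"), mk("o2", "m"), mk("h", "m"),
      mk("cytc_ox", "m"), mk("h2o", "m"), mk("h", "i"))),
    0, 1000, "gCOX4I1 and gCOX5A", "oxphos")
  add_rxn("CV", stats::setNames(
    c(-1, -1, -3, 1, 1, 3),
    c(mk("adp", "m"), mk("pi", "m"), mk("h", "i"), mk("atp", "m"),
      mk("h2o", "m"), mk("h", "m"))),
    0, 1000, "gATP5F1A", "oxphos")
  if (spec$include_leak)
    add_rxn("LEAK", stats::setNames(c(-1, 1), c(mk("h", "i"),
                                                mk("h", "m"))),
            0, spec$leak_capacity, "", "oxphos")
  ## non-growth ATP maintenance: decouples respiratory capacity from the
  ## biomass drain, as in genome-scale practice
  add_rxn("ATPM", stats::setNames(
    c(-1, -1, 1, 1),
    c(mk("atp", "c"), mk("h2o", "c"), mk("adp", "c"), mk("pi", "c"))),
    0, 1000, "", "maintenance")
  add_rxn("BIOMASS", stats::setNames(
    c(-bc[["pyr"]], -bc[["atp"]], -bc[["atp"]], 1, bc[["atp"]],
      bc[["atp"]]),
    c(mk("pyr", "c"), mk("atp", "c"), mk("h2o", "c"), mk("biomass", "c"),
      mk("adp", "c"), mk("pi", "c"))),
    0, 1000, "", "biomass")
  add_rxn("DM_biomass", stats::setNames(-1, mk("biomass", "c")),
          0, 1000, "", "biomass")

  model <- metabolic_model(
    do.call(rbind, met_rows), do.call(rbind, rxn_rows), stoich,
    objective = "BIOMASS",
    id = paste0("toy_", sub("_like", "", cell_kind)),
    annotations = list(cell_kind = cell_kind,
                       generator = "cocultr toy central carbon"))

  ## thermo table over every metabolite id, synthetic energies; the biomass
  ## pseudo-species gets a strongly negative value so its drain stays
  ## forward-feasible
  ids <- model$metabolites$id
  bare <- strip_compartment(ids)
  dgf <- ifelse(bare == "biomass", -2300, TOY_DGF[bare])
  thermo <- thermo_table(stats::setNames(dgf, ids),
                         exempt = ids[bare %in% c("h", "h2o")])
  med <- medium(uptake = c(glc = 10, gln = 2, ser = 1, o2 = 25),
                free_species = c("co2", "h", "h2o", "nh4"))
  etc <- etc_map(complex_i = "CI", complex_iii = "CIII",
                 complex_iv = "CIV", atp_synthase = "CV",
                 oxygen_exchange = "EX_o2",
                 leak = if (spec$include_leak) "LEAK" else NA_character_)
  list(model = apply_medium_constraints(model, med), etc = etc,
       thermo = thermo, medium = med)
}

#' Generate a binary expression presence/absence dataset
#'
#' Samples independent Bernoulli presence calls per gene and sample from a
#' presence-probability profile, emulating detection calls from a
#' microarray series.
#'
#' @param model a `metabolic_model` whose GPR genes define the gene list.
#' @param n_samples number of samples, default 12 (a typical series size).
#' @param presence_profile named probabilities per gene, or a single
#'   default probability applied to genes not named; default 0.9.
#' @param seed integer seed.
#' @return an `expression_dataset`.
#' @export
make_expression_dataset <- function(model, n_samples = 12,
                                    presence_profile = 0.9, seed = 1) {
  genes <- sort(unique(unlist(lapply(model$reactions$gpr, gpr_genes))))
  if (!length(genes)) stop("model has no GPR genes")
  if (is.null(names(presence_profile))) {
    p <- stats::setNames(rep(presence_profile[1], length(genes)), genes)
  } else {
    p <- stats::setNames(rep(0.9, length(genes)), genes)
    extra <- setdiff(names(presence_profile), genes)
    if (length(extra)) stop("profile names unknown gene: ", extra[1])
    p[names(presence_profile)] <- presence_profile
  }
  if (any(p < 0 | p > 1)) stop("presence probabilities must be in [0, 1]")
  old <- .Random.seed_safe()
  set.seed(seed)
  calls <- matrix(stats::rbinom(length(genes) * n_samples, 1,
                                rep(p, n_samples)),
                  nrow = length(genes), ncol = n_samples,
                  dimnames = list(genes, paste0("S", seq_len(n_samples))))
  .Random.seed_restore(old)
  expression_dataset(calls)
}

#' Atom-mapped tracer subnetwork of the toy cell
#'
#' A 13-reaction atom-mapped network of lumped central carbon metabolism:
#' glycolysis (glucose to two pyruvates), lactate dehydrogenase, alanine
#' transamination, pyruvate dehydrogenase, pyruvate carboxylase, citrate
#' synthase, citrate to 2-oxoglutarate, 2-oxoglutarate to oxaloacetate
#' through a symmetric four-carbon intermediate (0.5/0.5 scrambling),
#' glutamine anaplerosis, and exports. No metabolite exceeds six carbons,
#' so the brute-force isotopomer simulation stays tractable.
#'
#' @return list with `text` (reaction lines parseable by
#'   [parse_atom_network()]) and `network` (the parsed `atom_network`).
#' @export
make_atom_mapped_toynet <- function() {
  text <- c(
    "# lumped central-carbon atom transitions",
    "v_hex: Glc (abcdef) -> Pyr (cba) + Pyr (def)",
    "v_ldh: Pyr (abc) -> Lac (abc)",
    "v_ala: Pyr (abc) -> Ala (abc)",
    "v_pdh: Pyr (abc) -> AcCoA (bc) + CO2 (a)",
    "v_pc: Pyr (abc) + CO2 (d) -> OAA (abcd)",
    "v_cs: OAA (abcd) + AcCoA (ef) -> Cit (abcdef)",
    "v_cak: Cit (abcdef) -> AKG (abcde) + CO2 (f)",
    "v_ao: AKG (abcde) -> OAA (bcde|edcb) + CO2 (a)",
    "v_gls: Gln (abcde) -> Glu (abcde)",
    "v_gdh: Glu (abcde) -> AKG (abcde)",
    "v_cit_out: Cit (abcdef) -> Cit.ext (abcdef)",
    "v_oaa_out: OAA (abcd) -> OAA.ext (abcd)",
    "v_co2_out: CO2 (a) -> CO2.ext (a)")
  list(text = text, network = parse_atom_network(text))
}

#' Reference flux truth and tracer design for the toy tracer network
#'
#' A steady-state flux vector for [make_atom_mapped_toynet()] anchored at
#' the measured boundary fluxes of the system the generator emulates:
#' glucose uptake 0.45 and glutamine uptake 0.63 (umol/10^6 cells/h treated
#' 1:1 as the network's flux unit), with two parallel tracer experiments
#' (uniformly labelled glucose, uniformly labelled glutamine) regressed
#' simultaneously.
#'
#' @param noise_sd Gaussian measurement noise on mole fractions, default
#'   0.005.
#' @return list with `fluxes`, `experiments_tracers` (list of tracer sets),
#'   `measured_fluxes`, `fragments`, `noise_sd`.
#' @export
toy_mfa_truth <- function(noise_sd = 0.005) {
  fluxes <- c(v_hex = 0.45, v_ldh = 0.3, v_ala = 0.1, v_pdh = 0.4,
              v_pc = 0.1, v_cs = 0.4, v_cak = 0.25, v_ao = 0.88,
              v_gls = 0.63, v_gdh = 0.63, v_cit_out = 0.15,
              v_oaa_out = 0.58, v_co2_out = 1.43)
  list(
    fluxes = fluxes,
    experiments_tracers = list(
      glc = list(tracer("Glc", "U", purity = 0.99)),
      gln = list(tracer("Gln", "U", purity = 0.99))),
    ## glucose and glutamine uptake are the measured boundary fluxes; the
    ## lactate efflux (spent-medium measurement) resolves the otherwise
    ## indistinguishable lactate/alanine split of pyruvate
    measured_fluxes = data.frame(
      reaction_id = c("v_hex", "v_gls", "v_ldh"),
      value = c(0.45, 0.63, 0.3), sd = c(0.02, 0.03, 0.02),
      stringsAsFactors = FALSE),
    fragments = c("Pyr[1,2,3]", "Lac[1,2,3]", "Ala[1,2,3]",
                  "Glu[1,2,3,4,5]", "Cit[1,2,3,4,5,6]", "OAA[1,2,3,4]"),
    noise_sd = noise_sd)
}

#' Simulate a 13C labelling experiment from a known flux truth
#'
#' Forward-simulates the MIDs of the requested fragments under each tracer
#' experiment, adds Gaussian noise (sd `truth$noise_sd`), clips at zero and
#' renormalises each fragment to sum 1. Reproducible given `seed`; the true
#' fluxes travel alongside as attribute `"truth"` for recovery tests.
#'
#' @param truth a list as from [toy_mfa_truth()] (fields `fluxes`,
#'   `experiments_tracers`, `fragments`, `noise_sd`, optionally
#'   `measured_fluxes`).
#' @param network an `atom_network`; default the toy network.
#' @param seed integer seed.
#' @return list of experiments (each with `tracers` and `measurements`)
#'   ready for [mfa_model()], with attributes `"truth"` (flux vector) and
#'   `"measured_fluxes"` (noisy boundary-flux measurements).
#' @export
simulate_labelling_experiment <- function(truth, network = NULL,
                                          seed = 1) {
  if (is.null(network)) network <- make_atom_mapped_toynet()$network
  emunet <- decompose_emus(network, as.list(truth$fragments))
  old <- .Random.seed_safe()
  set.seed(seed)
  experiments <- list()
  for (en in names(truth$experiments_tracers)) {
    tracers <- truth$experiments_tracers[[en]]
    sim <- simulate_mids(emunet, truth$fluxes, tracers)
    rows <- list()
    for (fr in truth$fragments) {
      mid <- sim[[fr]]
      noisy <- mid + stats::rnorm(length(mid), 0, truth$noise_sd)
      noisy <- pmax(noisy, 0)
      noisy <- noisy / sum(noisy)
      rows[[fr]] <- data.frame(
        fragment = fr, mass = seq_along(mid) - 1, value = noisy,
        sd = max(truth$noise_sd, 1e-4), stringsAsFactors = FALSE)
    }
    experiments[[en]] <- list(
      tracers = tracers,
      measurements = do.call(rbind, c(rows, make.row.names = FALSE)))
  }
  mf <- truth$measured_fluxes
  if (!is.null(mf)) {
    mf$value <- unname(truth$fluxes[mf$reaction_id])
    if (truth$noise_sd > 0)   # noiseless datasets are noiseless throughout
      mf$value <- stats::rnorm(nrow(mf), mf$value, mf$sd)
  }
  .Random.seed_restore(old)
  attr(experiments, "truth") <- truth$fluxes
  attr(experiments, "measured_fluxes") <- mf
  experiments
}
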