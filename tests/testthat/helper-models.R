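# Small hand-built models used across test files.

# linear chain: A_ex (uptake <= cap) -> A -> B -> B_ex
chain_model <- function(uptake_cap = 10, conv_cap = default_bound()) {
  metabolic_model(
    metabolites = tibble::tibble(
      id = c("A", "B"), compartment = "c",
      formula = c("C1H2O1", "C1H2O1")),
    reactions = tibble::tibble(
      id = c("EX_A", "CONV", "EX_B"),
      lower_bound = c(-uptake_cap, 0, 0),
      upper_bound = c(default_bound(), conv_cap, default_bound()),
      kind = c("exchange", "internal", "exchange")),
    stoichiometry = tibble::tibble(
      reaction = c("EX_A", "CONV", "CONV", "EX_B"),
      metabolite = c("A", "A", "B", "B"),
      coefficient = c(-1, -1, 1, -1)),
    objective = "EX_B")
}

# two equal-cost parallel routes from A to B (for parsimony tests)
parallel_model <- function() {
  metabolic_model(
    metabolites = tibble::tibble(id = c("A", "B"), compartment = "c",
                                 formula = "CH2O"),
    reactions = tibble::tibble(
      id = c("EX_A", "P1", "P2", "EX_B"),
      lower_bound = c(-10, 0, 0, 0),
      upper_bound = c(default_bound(), default_bound(), default_bound(),
                      default_bound()),
      kind = c("exchange", "internal", "internal", "exchange")),
    stoichiometry = tibble::tibble(
      reaction = c("EX_A", "P1", "P1", "P2", "P2", "EX_B"),
      metabolite = c("A", "A", "B", "A", "B", "B"),
      coefficient = c(-1, -1, 1, -1, 1, -1)),
    objective = "EX_B")
}

# pathway-extended, growth-contextualized toy ready for interrogation
extended_toy <- function(config = toy_model_config(), ngam = 1,
                         allow_single_cleavage = FALSE) {
  host <- build_toy_model(config)
  spec <- build_pathway_spec(allow_single_cleavage = allow_single_cleavage)
  apply_growth_context(extend_model(host, spec), ngam = ngam)
}

# truth construction with a known cleavage fraction f of the divertible
# carbon actually cleaved (double cleavage only, fermentation disabled so
# the carbon surplus respires deterministically: 6 CO2 per waste glucose,
# 40/3 CO2 per beta-carotene equivalent)
recovery_scenario <- function(f, c_pot = 1, mu = 0.1, ngam = 1) {
  cfg <- toy_model_config(fpp_capacity = 3, glucose_uptake_max = 20,
                          include_fermentation_branch = FALSE)
  ext <- extended_toy(cfg, ngam = ngam)
  c_true <- f * c_pot
  pilot <- simulate_measurements(
    ext, list(mu = mu, ngam = ngam, sink_bcarotene = 0,
              cleavage_double = c_true), n_strains = 1, noise_cv = 0, seed = 1)
  q_min <- attr(pilot, "truth")$q_glc
  waste_glc <- (c_pot - c_true) * (40 / 3) / 6
  list(model = ext, mu = mu, ngam = ngam, c_true = c_true, c_pot = c_pot,
       q_glc = q_min + waste_glc)
}
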