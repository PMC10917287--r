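# Shared fixtures built in code.

# minimal two-state world: one alive state with monthly death probability
# p_death, used for closed-form geometric-chain checks
make_geom_params <- function(p_death = 0.1, utility = 0.8, discount = 0,
                             horizon = 120, drug_annual = 0,
                             mgmt_annual = 0, disc_rate = 0) {
  states <- data.frame(
    id = c("alive", "dead"),
    label = c("Alive", "Dead"),
    egfr_band = NA_character_,
    category = c("ckd_stage_3a", "dead"),
    absorbing = c(FALSE, TRUE),
    drug_cost_applies = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  M <- matrix(c(1 - p_death, p_death, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(states$id, states$id))
  Z <- matrix(0, 2, 2, dimnames = dimnames(M))
  msets <- list(phase1 = M, phase2 = M, phase1_se = Z, phase2_se = Z)
  zero_ms <- list(mean = 0, se = 0)
  ae_zero <- stats::setNames(rep(list(zero_ms), 5), ckdcea:::AE_NAMES)
  parameter_set(
    states,
    matrices = list(dapagliflozin = msets, soc = msets),
    costs = list(
      drug_annual = list(dapagliflozin = list(mean = drug_annual, se = 0),
                         soc = list(mean = drug_annual, se = 0)),
      state_mgmt_annual = list(alive = list(mean = mgmt_annual, se = 0)),
      dialysis_annual = zero_ms,
      transplant_initial_once = zero_ms,
      transplant_maint_annual = zero_ms,
      ae_unit_cost = ae_zero),
    utilities = list(
      state_utility = list(alive = list(mean = utility, se = 0)),
      ae_decrement = ae_zero),
    adverse_events = list(),
    econ = list(annual_discount = discount, cycle_length_months = 1,
                wtp_per_qaly = 46000, fx_rm_per_usd = 4.14,
                horizon_cycles = horizon,
                discontinuation_rate_per_cycle = disc_rate),
    init_dist = c(alive = 1, dead = 0))
}

# packaged fixture, loaded once per test run
fixture_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_parameters(fixture_path())
    cache
  }
})

# a parameter set with every SE zeroed (degenerate PSA limit)
zero_se_params <- function(p) {
  for (arm in names(p$matrices)) {
    p$matrices[[arm]]$phase1_se[] <- 0
    p$matrices[[arm]]$phase2_se[] <- 0
  }
  strip <- function(x) { x$se <- 0; x }
  p$costs$drug_annual <- lapply(p$costs$drug_annual, strip)
  p$costs$state_mgmt_annual <- lapply(p$costs$state_mgmt_annual, strip)
  p$costs$dialysis_annual <- strip(p$costs$dialysis_annual)
  p$costs$transplant_initial_once <- strip(p$costs$transplant_initial_once)
  p$costs$transplant_maint_annual <- strip(p$costs$transplant_maint_annual)
  p$costs$ae_unit_cost <- lapply(p$costs$ae_unit_cost, strip)
  p$utilities$state_utility <- lapply(p$utilities$state_utility, strip)
  p$utilities$ae_decrement <- lapply(p$utilities$ae_decrement, strip)
  p
}

# a synthetic world where the two arms are genuinely identical: null
# progression effect, comparator drug price and event rates on both arms,
# and no discontinuation (so the two traces are computed identically)
null_effect_params <- function() {
  rates <- lapply(synth_spec()$ae_rates, function(r)
    c(dapagliflozin = unname(r[["soc"]]), soc = unname(r[["soc"]])))
  gen_parameter_set(synth_spec(effect = 1, equal_drug_cost = TRUE,
                               ae_rates = rates, discontinuation_rate = 0))
}

# total occupancy per (cycle, state), summed over treatment status
occ_by_state <- function(trace) apply(trace, c(1, 2), sum)
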